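# Puncta detection: normalization, enhancement, seeding, region growing
# and colocalization.

test_that("normalize_cell divides by the cell's median intensity", {
  img <- tiny_cell_image(value = 500)
  norm <- normalize_cell(img, 1)
  expect_true(all(norm[img$labels == 1] == 1))
  expect_true(all(is.na(norm[img$labels == 0])))

  # three-pixel cell {1, 2, 3} -> {0.5, 1, 1.5}
  intensity <- matrix(0, 5, 5)
  labels <- matrix(0L, 5, 5)
  intensity[2, 2:4] <- c(1, 2, 3)
  labels[2, 2:4] <- 1L
  img3 <- labeled_image(intensity, labels)
  norm3 <- normalize_cell(img3, 1)
  expect_equal(norm3[2, 2:4], c(0.5, 1, 1.5))
})

test_that("normalized cells always have median 1 (property)", {
  set.seed(101)
  for (i in 1:10) {
    img <- tiny_cell_image()
    img$intensity[img$labels == 1] <- rlnorm(sum(img$labels == 1), 5, 1)
    norm <- normalize_cell(img, 1)
    expect_equal(median(norm[img$labels == 1]), 1)
  }
})

test_that("zero-median cells are rejected", {
  img <- tiny_cell_image(value = 0)
  expect_error(normalize_cell(img, 1), "median")
})

test_that("enhancement flattens constants and peaks inside bright disks", {
  params <- puncta_params()
  flat <- enhance_puncta(matrix(1, 64, 64), params)
  expect_lt(max(abs(flat)), 1e-8)

  disk <- matrix(1, 64, 64)
  dm <- punctapulse:::paint_disk(64, 64, 30, 24, 3)
  disk[dm] <- 5
  enh <- enhance_puncta(disk, params)
  peak <- which(enh == max(enh), arr.ind = TRUE)[1, ]
  expect_true(dm[peak[1], peak[2]])

  # translation equivariance away from borders
  disk2 <- matrix(1, 64, 64)
  dm2 <- punctapulse:::paint_disk(64, 64, 37, 31, 3)
  disk2[dm2] <- 5
  enh2 <- enhance_puncta(disk2, params)
  peak2 <- which(enh2 == max(enh2), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak2 - peak), c(7, 7))
  expect_equal(max(enh), max(enh2), tolerance = 1e-6)
})

test_that("oversized filters are rejected", {
  expect_error(enhance_puncta(matrix(1, 8, 8),
                              puncta_params(tophat_radius_px = 10)),
               "exceeds")
})

test_that("find_seeds returns thresholded local maxima in rank order", {
  m <- matrix(TRUE, 32, 32)
  flat <- matrix(0, 32, 32)
  expect_equal(nrow(find_seeds(flat + 0.5, m, seed_cutoff = 1)), 0)

  two <- matrix(0, 32, 32)
  two[8, 8] <- 3; two[24, 20] <- 5
  seeds <- find_seeds(two, m, seed_cutoff = 1)
  expect_equal(nrow(seeds), 2)
  expect_equal(unname(seeds[1, ]), c(24, 20))  # descending enhanced value
  expect_equal(unname(seeds[2, ]), c(8, 8))
  expect_equal(nrow(find_seeds(two, m, seed_cutoff = 10)), 0)
})

test_that("local_background is the median of unassigned cell pixels", {
  norm <- matrix(NA_real_, 4, 4)
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1:4] <- TRUE
  norm[1, 1:4] <- c(1, 1, 1, 9)
  assigned <- matrix(FALSE, 4, 4)
  expect_equal(local_background(norm, mask), 1)
  assigned[1, 4] <- TRUE
  expect_equal(local_background(norm, mask, assigned), 1)
  assigned[1, ] <- TRUE
  expect_error(local_background(norm, mask, assigned), "assigned")
})

test_that("local_background equals a direct median on random cases", {
  set.seed(7)
  for (i in 1:10) {
    mask <- matrix(runif(100) < 0.6, 10, 10)
    norm <- matrix(rlnorm(100), 10, 10)
    assigned <- matrix(runif(100) < 0.2, 10, 10) & mask
    if (!any(mask & !assigned)) next
    expect_equal(local_background(norm, mask, assigned),
                 median(norm[mask & !assigned]))
  }
})

test_that("grow_cluster matches the BFS flood-fill oracle", {
  expect_error(grow_cluster(matrix(0, 4, 4), c(2, 2), 1), "below")

  iso <- matrix(0, 5, 5); iso[3, 3] <- 2
  expect_equal(nrow(grow_cluster(iso, c(3, 3), 1)), 1)

  plateau <- matrix(0, 7, 7); plateau[3:5, 3:5] <- 1
  expect_equal(nrow(grow_cluster(plateau, c(4, 4), 1, connectivity = 8)), 9)

  set.seed(11)
  for (i in 1:20) {
    conn <- sample(c(4, 8), 1)
    x <- matrix(runif(64 * 64), 64, 64)
    thr <- runif(1, 0.3, 0.7)
    above <- which(x >= thr)
    if (!length(above)) next
    seed_idx <- above[sample.int(length(above), 1)]
    seed <- c((seed_idx - 1) %% 64 + 1, (seed_idx - 1) %/% 64 + 1)
    got <- grow_cluster(x, seed, thr, connectivity = conn)
    got_idx <- sort(as.integer((got[, 2] - 1) * 64 + got[, 1]))
    want <- sort(oracle_flood_fill(x >= thr, seed[1], seed[2], conn))
    expect_identical(got_idx, as.integer(want))
  }
})

test_that("detection recovers synthetic puncta and their centroids", {
  sc <- simulate_puncta_scene(puncta_scene_config(seed = 7))
  ps <- detect_puncta(sc$channel_a)
  counts <- table(ps$puncta$cell_id)
  expect_true(all(counts == 5))
  # every true punctum matched by a detection within 2 px
  tp <- sc$truth$puncta[sc$truth$puncta$channel == "a", ]
  for (i in seq_len(nrow(tp))) {
    d <- ps$puncta[ps$puncta$cell_id == tp$cell_id[i], ]
    err <- sqrt((d$centroid_row - tp$row[i])^2 +
                  (d$centroid_col - tp$col[i])^2)
    expect_lt(min(err), 2)
  }
})

test_that("a punctum-free noiseless scene yields zero detections", {
  sc <- simulate_puncta_scene(puncta_scene_config(noise_sd = 0,
                                                  puncta_per_cell = 0,
                                                  seed = 1))
  expect_equal(nrow(detect_puncta(sc$channel_a)$puncta), 0)
})

test_that("detections are disjoint, inside their cell, and deterministic", {
  sc <- simulate_puncta_scene(puncta_scene_config(seed = 5))
  ps <- detect_puncta(sc$channel_a)
  seen <- matrix(FALSE, 256, 256)
  for (i in seq_along(ps$pixels)) {
    px <- ps$pixels[[i]]
    idx <- (px[, 2] - 1) * 256 + px[, 1]
    expect_false(any(seen[idx]))  # disjoint
    seen[idx] <- TRUE
    owner <- sc$channel_a$labels[idx]
    expect_true(all(owner == ps$puncta$cell_id[i]))  # containment
    expect_equal(nrow(px), ps$puncta$area_px[i])
  }
  expect_identical(detect_puncta(sc$channel_a)$puncta, ps$puncta)
})

test_that("detection is invariant under per-cell intensity rescaling", {
  sc <- simulate_puncta_scene(puncta_scene_config(seed = 7))
  ps <- detect_puncta(sc$channel_a)
  img2 <- labeled_image(sc$channel_a$intensity * 2, sc$channel_a$labels)
  ps2 <- detect_puncta(img2)
  cols <- c("cell_id", "punctum_id", "centroid_row", "centroid_col",
            "area_px")
  expect_identical(ps$puncta[cols], ps2$puncta[cols])
  expect_equal(ps2$puncta$mean_intensity, 2 * ps$puncta$mean_intensity)
})

test_that("colocalization is 1 for identical channels and 0 for disjoint", {
  sc <- simulate_puncta_scene(puncta_scene_config(seed = 7))
  pa <- detect_puncta(sc$channel_a)
  expect_true(all(coloc_fraction(pa, pa)$coloc_fraction == 1))

  sc0 <- simulate_puncta_scene(puncta_scene_config(coloc_fraction = 0,
                                                   seed = 8))
  pa0 <- detect_puncta(sc0$channel_a)
  pb0 <- detect_puncta(sc0$channel_b)
  expect_true(all(coloc_fraction(pa0, pb0)$coloc_fraction == 0))
})

test_that("cells without A-puncta are flagged with NA coloc", {
  sc <- simulate_puncta_scene(puncta_scene_config(seed = 7, n_cells = 2,
                                                  image_height = 180,
                                                  image_width = 180))
  pa <- detect_puncta(sc$channel_a)
  pb <- detect_puncta(sc$channel_b)
  keep <- pa$puncta$cell_id != 1
  pa$pixels <- pa$pixels[keep]
  pa$puncta <- pa$puncta[keep, , drop = FALSE]
  cc <- coloc_fraction(pa, pb)
  expect_true(is.na(cc$coloc_fraction[cc$cell_id == 1]))
  expect_equal(cc$n_puncta_a[cc$cell_id == 1], 0)
})
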