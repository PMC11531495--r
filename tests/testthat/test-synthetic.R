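# Generators: determinism, ground-truth self-consistency, and the
# constructive guarantees downstream tests rely on.

test_that("puncta scene generator is deterministic and obeys its config", {
  cfg <- puncta_scene_config(seed = 7, n_cells = 4, image_height = 180,
                             image_width = 180)
  a <- simulate_puncta_scene(cfg)
  b <- simulate_puncta_scene(cfg)
  expect_identical(a$channel_a$intensity, b$channel_a$intensity)
  expect_identical(a$channel_b$intensity, b$channel_b$intensity)
  expect_identical(a$truth$puncta, b$truth$puncta)

  # configured number of puncta per cell, placed fully inside their cell
  tp <- a$truth$puncta
  expect_true(all(table(tp$cell_id, tp$channel) == cfg$puncta_per_cell))
  for (ch in c("a", "b")) {
    msk <- a$truth$puncta_masks[[ch]]
    owner <- a$channel_a$labels[msk > 0]
    expect_true(all(owner > 0))  # every punctum pixel inside some cell
  }

  # per-cell median cytoplasm intensity ~ background level
  for (cid in cell_ids(a$channel_a)) {
    med <- median(a$channel_a$intensity[a$channel_a$labels == cid])
    expect_equal(med, cfg$background_level, tolerance = 0.05)
  }
})

test_that("puncta within a cell do not overlap each other", {
  sc <- simulate_puncta_scene(puncta_scene_config(seed = 3))
  for (ch in c("a", "b")) {
    msk <- sc$truth$puncta_masks[[ch]]
    # label masks can only encode disjoint puncta; check the recorded
    # geometry directly too
    tp <- sc$truth$puncta[sc$truth$puncta$channel == ch, ]
    for (cid in unique(tp$cell_id)) {
      p <- tp[tp$cell_id == cid, ]
      if (nrow(p) < 2) next
      d <- as.matrix(dist(p[, c("row", "col")]))
      sums <- outer(p$radius, p$radius, "+")
      expect_true(all(d[upper.tri(d)] > sums[upper.tri(sums)]))
    }
  }
})

test_that("noiseless scene with no puncta is uniform at background inside cells", {
  sc <- simulate_puncta_scene(puncta_scene_config(noise_sd = 0,
                                                  puncta_per_cell = 0,
                                                  seed = 1))
  inside <- sc$channel_a$labels > 0
  expect_true(all(sc$channel_a$intensity[inside] == 200))
  expect_true(all(sc$channel_b$intensity[inside] == 200))
})

test_that("coloc_fraction = 1 and 0 are exact by construction", {
  sc1 <- simulate_puncta_scene(puncta_scene_config(coloc_fraction = 1,
                                                   seed = 2))
  expect_true(all(sc1$truth$coloc_fraction == 1))
  sc0 <- simulate_puncta_scene(puncta_scene_config(coloc_fraction = 0,
                                                   seed = 2))
  expect_true(all(sc0$truth$coloc_fraction == 0))
})

test_that("impossible punctum placement raises a placement error", {
  cfg <- puncta_scene_config(n_cells = 1, cell_radius_px = 8,
                             puncta_per_cell = 40, image_height = 64,
                             image_width = 64, seed = 1)
  expect_error(simulate_puncta_scene(cfg), "placement")
})

test_that("translocation scene ground truth matches the configuration", {
  cfg <- translocation_scene_config(edge_enrichment_pre = 1.0,
                                    edge_enrichment_post = 1.5,
                                    noise_sd = 0, seed = 5)
  sc <- simulate_translocation_pair(cfg)
  expect_equal(sc$truth$translocation, 0.5)
  # noiseless analytic edge/core ratio equals the configured enrichment
  part <- partition_ring(sc$mask, cfg$edge_ring_width_px)
  expect_equal(membrane_localization(sc$pre, part), 1.0)
  expect_equal(membrane_localization(sc$post, part), 1.5)

  flat <- simulate_translocation_pair(
    translocation_scene_config(edge_enrichment_pre = 1,
                               edge_enrichment_post = 1, noise_sd = 0))
  expect_equal(flat$truth$translocation, 0)

  s1 <- simulate_translocation_pair(cfg)
  expect_identical(sc$pre, s1$pre)
  expect_identical(sc$post, s1$post)
})

test_that("ring wider than the cell is rejected", {
  expect_error(translocation_scene_config(cell_radius_px = 10,
                                          edge_ring_width_px = 12),
               "ring width")
})

test_that("KTR dataset has the configured frame grid and is deterministic", {
  cfg <- ktr_sim_config(n_cells = 30, seed = 42)
  expect_equal(cfg$n_frames, 264)  # 22 h at 5-min frames
  a <- simulate_ktr_dataset(cfg)
  b <- simulate_ktr_dataset(cfg)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$pulses, b$truth$pulses)
  surv <- a$traces[!a$traces$cell_id %in%
                     a$truth$death_events$cell_id, ]
  expect_equal(max(surv$frame), 264)
  expect_equal(sort(unique(a$traces$time_min)),
               seq(0, by = 5, length.out = 264))
})

test_that("zero pulse, death and division rates give silent traces", {
  cfg <- ktr_sim_config(n_cells = 10, basal_pulse_rate = 0, death_rate = 0,
                        division_rate = 0, noise_sd = 0, seed = 1)
  sim <- simulate_ktr_dataset(cfg)
  expect_equal(nrow(sim$truth$pulses), 0)
  expect_true(all(sim$traces$ratio == cfg$baseline_ratio))
  expect_equal(nrow(sim$truth$death_events), 0)
  expect_equal(nrow(sim$truth$lineage), 0)
})

test_that("generated pulse durations lie within the configured range", {
  sim <- simulate_ktr_dataset(ktr_sim_config(n_cells = 60, seed = 9))
  d <- sim$truth$pulses$duration_min
  expect_true(all(d >= 10 & d <= 20))
})

test_that("neighbor-labeled pulses dominate when the neighbor rate is high", {
  # property over seeds: cells near deaths draw pulses at the elevated
  # rate, so neighbor-driven labels outnumber per-capita basal labels in
  # the same windows
  for (seed in c(1, 2, 3)) {
    sim <- simulate_ktr_dataset(
      ktr_sim_config(n_cells = 80, basal_pulse_rate = 0.05,
                     neighbor_pulse_rate = 1.5, seed = seed))
    p <- sim$truth$pulses
    nb_cells <- unique(unlist(lapply(sim$truth$neighbors, `[[`,
                                     "neighbors")))
    counts_nb <- sum(p$is_neighbor_driven)
    expect_gt(counts_nb, 0)
    # neighbor cells carry strictly more pulses per cell than the rest
    per_cell <- table(factor(p$cell_id,
                             levels = sim$truth$segments$cell_id))
    mean_nb <- mean(per_cell[as.character(nb_cells)])
    others <- setdiff(sim$truth$segments$cell_id, nb_cells)
    expect_gt(mean_nb, mean(per_cell[as.character(others)]))
  }
})

test_that("lineage map is acyclic and children copy the parent history", {
  sim <- simulate_ktr_dataset(ktr_sim_config(n_cells = 40,
                                             division_rate = 0.08,
                                             seed = 4))
  lin <- sim$truth$lineage
  expect_gt(nrow(lin), 0)
  expect_false(any(lin$child_id <= lin$parent_id))  # ids grow down the tree
  # siblings share identical ratio history up to the division frame
  one <- lin[1, ]
  sibs <- lin$child_id[lin$parent_id == one$parent_id]
  tr <- sim$traces
  h1 <- tr[tr$cell_id == sibs[1] & tr$frame <= one$division_frame, "ratio"]
  h2 <- tr[tr$cell_id == sibs[2] & tr$frame <= one$division_frame, "ratio"]
  # histories exist only if both children are terminal cells in the table
  if (length(h1) && length(h2)) expect_identical(h1, h2)
})

test_that("decay traces follow offset + amplitude * 2^(-t/t_half)", {
  cfg <- decay_sim_config(n_traces = 3, t_half_min = 17, amplitude = 1,
                          offset = 0.2, noise_sd = 0, seed = 1)
  tr <- simulate_decay_traces(cfg)
  at <- function(t) unique(tr$intensity[tr$time_min == t])
  expect_equal(at(0), 1.2)
  # t = t_half is not on the 5-min grid; check the closed form on-grid
  expect_equal(at(85), 0.2 + 2^(-85 / 17), tolerance = 1e-12)
  expect_identical(simulate_decay_traces(cfg), tr)
})
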