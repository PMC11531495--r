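# Condensate (puncta) detection per cell.
#
# Pipeline, applied independently to each labeled cell:
#   1. normalize the cell's intensities to its internal median,
#   2. enhance blob-like structure (Gaussian -> white top-hat -> negated
#      Laplacian of Gaussian),
#   3. pick seed pixels: local maxima of the enhanced image above a
#      user-defined cutoff,
#   4. grow a cluster from each seed on the *normalized* image, at a
#      threshold set by the cell's local background scaled by a second
#      user-defined parameter; the local background is recomputed after
#      each accepted cluster so that already-claimed punctum pixels do not
#      inflate it.

#' Parameters for puncta detection
#'
#' The two parameters the analyst is expected to tune are `seed_cutoff`
#' (how bright, after enhancement, a pixel must be to seed a cluster) and
#' `growth_scale` (the multiple of the cell's local background that a pixel
#' must exceed to join a cluster). The filter sizes have defaults chosen
#' for puncta of roughly 2-4 px radius; rescale them with the optics.
#'
#' @param gaussian_sigma_px Standard deviation of the Gaussian pre-smoother,
#'   pixels.
#' @param tophat_radius_px Radius of the disk structuring element of the
#'   white top-hat, pixels; should exceed the punctum radius.
#' @param laplacian_scale_px Scale (sigma) of the Laplacian-of-Gaussian
#'   blob filter, pixels; on the order of the punctum radius.
#' @param seed_cutoff Threshold on the enhanced, normalized intensity above
#'   which a local maximum seeds a cluster (first user parameter).
#' @param growth_scale Multiplier on the local background that sets the
#'   region-growing threshold (second user parameter).
#' @param connectivity Pixel connectivity for growth and local maxima,
#'   4 or 8.
#' @param min_area_px Clusters smaller than this many pixels are discarded.
#' @return A list of class `puncta_params`.
#' @export
puncta_params <- function(gaussian_sigma_px = 1,
                          tophat_radius_px = 6,
                          laplacian_scale_px = 2,
                          seed_cutoff = 1,
                          growth_scale = 2,
                          connectivity = 8,
                          min_area_px = 4) {
  check_scalar(gaussian_sigma_px, "gaussian_sigma_px", 0, strict_lower = TRUE)
  check_scalar(tophat_radius_px, "tophat_radius_px", 1, integer = TRUE)
  check_scalar(laplacian_scale_px, "laplacian_scale_px", 0,
               strict_lower = TRUE)
  check_scalar(seed_cutoff, "seed_cutoff", 0, strict_lower = TRUE)
  check_scalar(growth_scale, "growth_scale", 0, strict_lower = TRUE)
  check_scalar(min_area_px, "min_area_px", 1, integer = TRUE)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 tophat_radius_px = as.integer(tophat_radius_px),
                 laplacian_scale_px = laplacian_scale_px,
                 seed_cutoff = seed_cutoff,
                 growth_scale = growth_scale,
                 connectivity = as.integer(connectivity),
                 min_area_px = as.integer(min_area_px)),
            class = "puncta_params")
}

#' Normalize a cell's intensities to its internal median
#'
#' @param img A [labeled_image].
#' @param cell_id Label of the cell to normalize.
#' @return Numeric matrix of the image dimensions: intensity divided by the
#'   cell's median intensity inside the cell mask, `NA` outside it.
#' @export
normalize_cell <- function(img, cell_id) {
  stopifnot(inherits(img, "labeled_image"))
  m <- cell_mask(img, cell_id)
  med <- stats::median(img$intensity[m])
  if (!is.finite(med) || med <= 0) {
    stop(sprintf("cell %s has non-positive median intensity", cell_id),
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(img$intensity), ncol(img$intensity))
  out[m] <- img$intensity[m] / med
  out
}

# symmetric 2D Gaussian kernel, odd size, sums to 1
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# zero-sum Laplacian-of-Gaussian kernel at scale sigma
log_kernel <- function(sigma) {
  half <- max(2L, ceiling(4 * sigma))
  x <- -half:half
  r2 <- outer(x^2, x^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

#' Enhance blob-like puncta in a normalized cell image
#'
#' Sequentially applies Gaussian smoothing, a morphological white top-hat
#' (which removes the slowly varying cytoplasmic background), and a negated
#' Laplacian-of-Gaussian, so that compact bright spots become positive
#' maxima while flat background maps to approximately zero. `NA` pixels
#' (outside the cell) are treated as intensity 1, the median level of a
#' normalized cell, to avoid spurious edge responses at the cell boundary.
#'
#' @param x Numeric matrix, typically the output of [normalize_cell()].
#' @param params A [puncta_params] object.
#' @return Numeric matrix of the same dimensions.
#' @export
enhance_puncta <- function(x, params = puncta_params()) {
  stopifnot(is.matrix(x), inherits(params, "puncta_params"))
  x[is.na(x)] <- 1
  gk <- gaussian_kernel(params$gaussian_sigma_px)
  lk <- log_kernel(params$laplacian_scale_px)
  brush_size <- 2L * params$tophat_radius_px + 1L
  if (max(nrow(gk), nrow(lk), brush_size) > min(dim(x))) {
    stop("filter size exceeds image extent", call. = FALSE)
  }
  sm <- EBImage::filter2(x, gk, boundary = "replicate")
  th <- EBImage::whiteTopHat(sm, EBImage::makeBrush(brush_size, "disc"))
  enh <- -EBImage::filter2(th, lk, boundary = "replicate")
  matrix(as.numeric(enh), nrow(x), ncol(x))
}

#' Find cluster seed pixels in an enhanced image
#'
#' Seeds are local maxima of the enhanced image (over the 8-neighborhood,
#' or 4 if configured) whose enhanced value reaches `seed_cutoff`,
#' restricted to the cell mask, returned in descending enhanced intensity
#' (ties broken in column-major pixel order).
#'
#' @param enhanced Numeric matrix from [enhance_puncta()].
#' @param mask Logical matrix: the cell's pixels.
#' @param seed_cutoff Positive threshold on the enhanced value.
#' @param connectivity 4 or 8 (default) neighborhood for the maximum test.
#' @return Integer matrix with columns `row`, `col`; zero rows if no seeds.
#' @export
find_seeds <- function(enhanced, mask, seed_cutoff, connectivity = 8) {
  stopifnot(is.matrix(enhanced), is.matrix(mask),
            identical(dim(enhanced), dim(mask)))
  check_scalar(seed_cutoff, "seed_cutoff", 0, strict_lower = TRUE)
  offs <- conn_offsets(as.integer(connectivity))
  nr <- nrow(enhanced)
  nc <- ncol(enhanced)
  is_max <- matrix(TRUE, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs[i, 1]; dc <- offs[i, 2]
    shifted <- matrix(-Inf, nr, nc)
    r_src <- max(1, 1 - dr):min(nr, nr - dr)
    c_src <- max(1, 1 - dc):min(nc, nc - dc)
    shifted[r_src + dr, c_src + dc] <- enhanced[r_src, c_src]
    is_max <- is_max & (enhanced >= shifted)
  }
  cand <- which(is_max & mask & enhanced >= seed_cutoff)
  cand <- cand[order(-enhanced[cand], cand)]
  out <- idx_to_rc(cand, nr)
  storage.mode(out) <- "integer"
  out
}

#' Local background of a cell outside its current puncta
#'
#' @param normalized Numeric matrix from [normalize_cell()].
#' @param mask Logical matrix: the cell's pixels.
#' @param assigned Logical matrix of pixels already claimed by puncta
#'   (default none).
#' @return Median normalized intensity over unassigned cell pixels.
#' @export
local_background <- function(normalized, mask, assigned = NULL) {
  stopifnot(is.matrix(normalized), is.matrix(mask))
  if (is.null(assigned)) assigned <- matrix(FALSE, nrow(mask), ncol(mask))
  free <- mask & !assigned
  if (!any(free)) {
    stop("all cell pixels are assigned to puncta; no background left",
         call. = FALSE)
  }
  stats::median(normalized[free])
}

#' Grow a cluster from a seed by iterative thresholding
#'
#' Returns the connected component, under the configured connectivity, of
#' the set of pixels with value at or above `threshold` that contains the
#' seed, clipped to `mask`. Pixels join the cluster iteratively: every
#' neighbor of an included pixel is checked against the threshold until no
#' new neighbor qualifies. The result does not depend on visit order.
#'
#' @param x Numeric matrix (normalized intensities).
#' @param seed Length-2 integer vector `(row, col)`.
#' @param threshold Inclusion threshold.
#' @param connectivity 4 or 8 (default).
#' @param mask Optional logical matrix restricting growth (cell mask).
#' @return Integer matrix with columns `row`, `col`, sorted in column-major
#'   order.
#' @export
grow_cluster <- function(x, seed, threshold, connectivity = 8, mask = NULL) {
  stopifnot(is.matrix(x), length(seed) == 2)
  nr <- nrow(x); nc <- ncol(x)
  seed <- as.integer(seed)
  if (seed[1] < 1 || seed[1] > nr || seed[2] < 1 || seed[2] > nc) {
    stop("seed outside the image", call. = FALSE)
  }
  eligible <- !is.na(x) & x >= threshold
  if (!is.null(mask)) eligible <- eligible & mask
  sidx <- rc_to_idx(seed[1], seed[2], nr)
  if (!eligible[sidx]) {
    stop("seed pixel is below the growth threshold (or outside the mask)",
         call. = FALSE)
  }
  offs <- conn_offsets(as.integer(connectivity))
  inside <- logical(nr * nc)
  inside[sidx] <- TRUE
  frontier <- sidx
  while (length(frontier)) {
    rc <- idx_to_rc(frontier, nr)
    cand <- integer(0)
    for (i in seq_len(nrow(offs))) {
      rr <- rc[, 1] + offs[i, 1]
      cc <- rc[, 2] + offs[i, 2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      cand <- c(cand, rc_to_idx(rr[ok], cc[ok], nr))
    }
    cand <- unique(cand)
    cand <- cand[eligible[cand] & !inside[cand]]
    inside[cand] <- TRUE
    frontier <- cand
  }
  out <- idx_to_rc(which(inside), nr)
  storage.mode(out) <- "integer"
  out
}

#' Detect puncta in every cell of a labeled image
#'
#' Runs the full per-cell pipeline (see [puncta_params()] for the tunable
#' parameters). Seeds are processed in descending enhanced intensity; a
#' seed falling inside an already-grown cluster is skipped; each accepted
#' cluster updates the local background before the next seed is grown.
#' Clusters smaller than `min_area_px` are discarded. Resulting puncta are
#' pairwise disjoint and contained in their cell's mask.
#'
#' @param img A [labeled_image].
#' @param params A [puncta_params] object.
#' @return An object of class `puncta_set`: list with `puncta` (data frame:
#'   `cell_id`, `punctum_id`, `centroid_row`, `centroid_col`, `area_px`,
#'   `mean_intensity`, `peak_intensity`), `pixels` (list of `(row, col)`
#'   matrices, one per punctum, in row order of `puncta`), and `params`.
#' @export
detect_puncta <- function(img, params = puncta_params()) {
  stopifnot(inherits(img, "labeled_image"), inherits(params, "puncta_params"))
  ids <- cell_ids(img)
  if (!length(ids)) stop("label mask contains no cells", call. = FALSE)
  rows <- list()
  pixels <- list()
  for (cid in ids) {
    m <- cell_mask(img, cid)
    norm <- normalize_cell(img, cid)
    enh <- enhance_puncta(norm, params)
    seeds <- find_seeds(enh, m, params$seed_cutoff, params$connectivity)
    assigned <- matrix(FALSE, nrow(m), ncol(m))
    k <- 0L
    for (s in seq_len(nrow(seeds))) {
      sr <- seeds[s, 1]; sc <- seeds[s, 2]
      if (assigned[sr, sc]) next
      free <- m & !assigned
      if (!any(free)) break
      thr <- params$growth_scale * local_background(norm, m, assigned)
      if (is.na(norm[sr, sc]) || norm[sr, sc] < thr) next
      px <- grow_cluster(norm, c(sr, sc), thr,
                         connectivity = params$connectivity, mask = free)
      if (nrow(px) < params$min_area_px) next
      assigned[rc_to_idx(px[, 1], px[, 2], nrow(m))] <- TRUE
      k <- k + 1L
      vals <- img$intensity[rc_to_idx(px[, 1], px[, 2], nrow(m))]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid,
        punctum_id = k,
        centroid_row = mean(px[, 1]),
        centroid_col = mean(px[, 2]),
        area_px = nrow(px),
        mean_intensity = mean(vals),
        peak_intensity = max(vals)
      )
      pixels[[length(pixels) + 1L]] <- px
    }
  }
  puncta <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cell_id = integer(0), punctum_id = integer(0),
    centroid_row = numeric(0), centroid_col = numeric(0),
    area_px = integer(0), mean_intensity = numeric(0),
    peak_intensity = numeric(0))
  structure(list(puncta = puncta, pixels = pixels, params = params,
                 dim = dim(img$intensity)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %d puncta in %d cells\n",
              nrow(x$puncta), length(unique(x$puncta$cell_id))))
  invisible(x)
}

#' @export
as.data.frame.puncta_set <- function(x, ...) x$puncta

#' Per-cell colocalization of two puncta channels
#'
#' For each cell, the fraction of channel-A puncta whose pixel set shares
#' at least `min_overlap_px` pixels with any channel-B punctum of the same
#' cell. Cells without A-puncta have an undefined fraction and are flagged.
#'
#' @param puncta_a,puncta_b `puncta_set` objects detected on the same label
#'   mask.
#' @param min_overlap_px Minimum shared pixel count to call two puncta
#'   overlapping (default 1).
#' @return Data frame with columns `cell_id`, `n_puncta_a`, `n_overlapping`,
#'   `coloc_fraction` (`NA` where `n_puncta_a == 0`).
#' @export
coloc_fraction <- function(puncta_a, puncta_b, min_overlap_px = 1) {
  stopifnot(inherits(puncta_a, "puncta_set"), inherits(puncta_b, "puncta_set"))
  if (!identical(puncta_a$dim, puncta_b$dim)) {
    stop("the two channels were not detected on images of the same size",
         call. = FALSE)
  }
  check_scalar(min_overlap_px, "min_overlap_px", 1, integer = TRUE)
  nr <- puncta_a$dim[1]
  cells <- sort(unique(c(puncta_a$puncta$cell_id, puncta_b$puncta$cell_id)))
  out <- lapply(cells, function(cid) {
    ia <- which(puncta_a$puncta$cell_id == cid)
    ib <- which(puncta_b$puncta$cell_id == cid)
    b_idx <- unlist(lapply(puncta_b$pixels[ib],
                           function(px) rc_to_idx(px[, 1], px[, 2], nr)))
    n_overlap <- sum(vapply(puncta_a$pixels[ia], function(px) {
      sum(rc_to_idx(px[, 1], px[, 2], nr) %in% b_idx) >= min_overlap_px
    }, logical(1)))
    data.frame(cell_id = cid, n_puncta_a = length(ia),
               n_overlapping = n_overlap,
               coloc_fraction = if (length(ia)) n_overlap / length(ia)
                                else NA_real_)
  })
  do.call(rbind, out)
}
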