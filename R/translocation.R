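# Adapter membrane translocation scoring.
#
# Membrane localization of an adapter (GRB2, SOS1) is the ratio of mean
# fluorescence in a fixed-width ring just inside the cell boundary ("edge")
# to the mean fluorescence of the remaining interior ("core").
# Translocation is the change in membrane localization from pre-stimulus
# to a fixed time after growth-factor stimulation.

#' Partition a cell mask into an edge ring and a core
#'
#' The edge is the set of mask pixels whose distance to the mask complement
#' (background pixels inside the image) is at most `ring_width_px`; the
#' core is everything else in the mask, i.e. the morphological erosion of
#' the mask by a disk of the ring width. Distances are Euclidean by
#' default; a Chebyshev (square-neighborhood) variant is available.
#'
#' @param mask Logical matrix: the cell's pixels. Must not fill the whole
#'   image (the ring is measured from in-image background).
#' @param ring_width_px Ring width in pixels (default 10).
#' @param metric `"euclidean"` (default) or `"chebyshev"`.
#' @return A list of class `ring_partition` with logical matrices `edge`
#'   and `core`, and `ring_width_px`.
#' @export
partition_ring <- function(mask, ring_width_px = 10,
                           metric = c("euclidean", "chebyshev")) {
  stopifnot(is.matrix(mask), is.logical(mask))
  metric <- match.arg(metric)
  check_scalar(ring_width_px, "ring_width_px", 0, strict_lower = TRUE)
  if (!any(mask)) stop("empty cell mask", call. = FALSE)
  if (all(mask)) {
    stop("mask fills the image; no background to measure the ring from",
         call. = FALSE)
  }
  if (metric == "euclidean") {
    d <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                          metric = "euclidean")
    d <- matrix(as.numeric(d), nrow(mask), ncol(mask))
    edge <- mask & d <= ring_width_px
  } else {
    core0 <- mask
    kern <- matrix(1, 3, 3)  # 3x3 erosion = Chebyshev distance 1
    for (i in seq_len(as.integer(ring_width_px))) {
      core0 <- EBImage::erode(matrix(as.numeric(core0),
                                     nrow(mask), ncol(mask)), kern) > 0.5
    }
    edge <- mask & !core0
  }
  core <- mask & !edge
  if (!any(core)) {
    stop("ring width leaves no core: cell too small for the requested ring",
         call. = FALSE)
  }
  structure(list(edge = edge, core = core,
                 ring_width_px = ring_width_px),
            class = "ring_partition")
}

#' Membrane localization: edge/core mean intensity ratio
#'
#' @param intensity Numeric matrix.
#' @param part A [partition_ring()] result.
#' @return `mean(intensity[edge]) / mean(intensity[core])`.
#' @export
membrane_localization <- function(intensity, part) {
  stopifnot(is.matrix(intensity), inherits(part, "ring_partition"),
            identical(dim(intensity), dim(part$edge)))
  core_mean <- mean(intensity[part$core])
  if (!is.finite(core_mean) || core_mean <= 0) {
    stop("core mean intensity is not positive", call. = FALSE)
  }
  mean(intensity[part$edge]) / core_mean
}

#' Translocation: change in membrane localization after stimulation
#'
#' @param pre,post Numeric intensity matrices taken before stimulation and
#'   at the fixed post-stimulation time, on the same cell partition.
#' @param part A [partition_ring()] result.
#' @param cell_id Optional cell identifier carried into the record.
#' @param post_time_min Minutes after stimulation of the `post` frame
#'   (default 1.5).
#' @return Data frame with one row: `cell_id`, `ml_pre`, `ml_post`,
#'   `translocation` (= `ml_post - ml_pre`), `post_time_min`.
#' @export
translocation <- function(pre, post, part, cell_id = NA_integer_,
                          post_time_min = 1.5) {
  ml_pre <- membrane_localization(pre, part)
  ml_post <- membrane_localization(post, part)
  data.frame(cell_id = cell_id, ml_pre = ml_pre, ml_post = ml_post,
             translocation = ml_post - ml_pre,
             post_time_min = post_time_min)
}

#' Translocation suppression by an oncogene, with bootstrap quartiles
#'
#' Summarizes how much an oncogene-expressing group's translocation is
#' reduced relative to wild-type cells imaged in the same field of view:
#' `fraction = median(oncogene) / median(wt)` and
#' `suppression = 1 - fraction`. Uncertainty is assessed by resampling
#' both groups with replacement and reporting the 1st and 3rd quartiles of
#' the bootstrap distribution of each quantity.
#'
#' Absolute translocation magnitudes vary between acquisitions with the
#' imaging plane, so the two groups must come from the same scene; the
#' function only takes the paired vectors and cannot enforce this.
#'
#' @param values_oncogene,values_wt Numeric vectors of per-cell
#'   translocation values from the same field of view.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @return A list of class `translocation_suppression`: `fraction`,
#'   `suppression`, `fraction_quartiles`, `suppression_quartiles`
#'   (25/50/75%), `n_boot`, `seed`.
#' @export
translocation_suppression <- function(values_oncogene, values_wt,
                                      n_boot = 1000, seed = 1) {
  if (!length(values_oncogene) || !length(values_wt)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  med_wt <- stats::median(values_wt)
  if (med_wt == 0) stop("wild-type median translocation is zero", call. = FALSE)
  check_scalar(n_boot, "n_boot", 1, integer = TRUE)
  fraction <- stats::median(values_oncogene) / med_wt
  boot_frac <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      a <- sample(values_oncogene, replace = TRUE)
      b <- sample(values_wt, replace = TRUE)
      mb <- stats::median(b)
      if (mb == 0) NA_real_ else stats::median(a) / mb
    }, numeric(1))
  })
  qs <- stats::quantile(boot_frac, c(0.25, 0.5, 0.75), na.rm = TRUE,
                        names = FALSE)
  structure(list(fraction = fraction,
                 suppression = 1 - fraction,
                 fraction_quartiles = qs,
                 suppression_quartiles = rev(1 - qs),
                 n_boot = as.integer(n_boot),
                 seed = seed),
            class = "translocation_suppression")
}

#' @export
print.translocation_suppression <- function(x, ...) {
  cat(sprintf(
    "<translocation_suppression> fraction = %.3f, suppression = %.3f\n",
    x$fraction, x$suppression))
  cat(sprintf("  bootstrap quartiles of suppression (n_boot = %d): %.3f / %.3f / %.3f\n",
              x$n_boot, x$suppression_quartiles[1],
              x$suppression_quartiles[2], x$suppression_quartiles[3]))
  invisible(x)
}

#' Quantify translocation for every cell in a scene
#'
#' Convenience wrapper: partitions every cell of a label mask and scores
#' pre/post translocation.
#'
#' @param pre,post Numeric intensity matrices.
#' @param labels Integer label matrix (0 = background).
#' @param ring_width_px Ring width in pixels (default 10).
#' @param metric Distance metric, see [partition_ring()].
#' @param post_time_min Minutes after stimulation of the `post` frame.
#' @return Data frame with one row per cell (schema of [translocation()]).
#' @export
translocation_by_cell <- function(pre, post, labels, ring_width_px = 10,
                                  metric = "euclidean",
                                  post_time_min = 1.5) {
  ids <- sort(unique(labels[labels > 0]))
  out <- lapply(ids, function(cid) {
    part <- partition_ring(labels == cid, ring_width_px, metric)
    translocation(pre, post, part, cell_id = cid,
                  post_time_min = post_time_min)
  })
  do.call(rbind, out)
}
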