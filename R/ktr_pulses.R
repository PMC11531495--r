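# ERK pulse calling from kinase translocation reporter (KTR) traces.
#
# A trace is a per-cell time series of the cytoplasmic/nuclear reporter
# intensity ratio, sampled at a uniform frame interval (default 5 min).
# Pulses are transient excursions lasting 10-20 min; they are called as
# local maxima with sufficient topographic prominence. ERK-independent
# pulses that precede cell division are excluded (any pulse within 10
# frames before a division frame), and pulses occurring in the shared
# history of a divided cell are counted once.

#' Parameters for pulse detection
#'
#' @param min_prominence Minimum topographic prominence (in ratio units)
#'   for a local maximum to be called a pulse.
#' @param min_peak_distance_frames Minimum spacing between retained peaks;
#'   of two close peaks the more prominent wins (ties to the earlier
#'   frame).
#' @param min_expression Reporter expression QC cutoff; cells below it are
#'   excluded before detection.
#' @param division_exclusion_frames Pulses peaking within this many frames
#'   before a division are marked `division_proximal` and excluded from
#'   counts (default 10 frames = 50 min at 5-min sampling).
#' @param smoothing_window_frames Optional odd window for a moving-median
#'   pre-smoother; `NULL` (default) disables smoothing.
#' @return A list of class `pulse_params`.
#' @export
pulse_params <- function(min_prominence = 0.3,
                         min_peak_distance_frames = 3,
                         min_expression = 100,
                         division_exclusion_frames = 10,
                         smoothing_window_frames = NULL) {
  check_scalar(min_prominence, "min_prominence", 0, strict_lower = TRUE)
  check_scalar(min_peak_distance_frames, "min_peak_distance_frames", 0,
               integer = TRUE)
  check_scalar(min_expression, "min_expression", 0)
  check_scalar(division_exclusion_frames, "division_exclusion_frames", 0,
               integer = TRUE)
  if (!is.null(smoothing_window_frames)) {
    check_scalar(smoothing_window_frames, "smoothing_window_frames", 1,
                 integer = TRUE)
    if (smoothing_window_frames %% 2 == 0) {
      stop("`smoothing_window_frames` must be odd", call. = FALSE)
    }
  }
  structure(list(min_prominence = min_prominence,
                 min_peak_distance_frames =
                   as.integer(min_peak_distance_frames),
                 min_expression = min_expression,
                 division_exclusion_frames =
                   as.integer(division_exclusion_frames),
                 smoothing_window_frames = smoothing_window_frames),
            class = "pulse_params")
}

#' Expression quality-control filter
#'
#' Removes traces of cells with low or absent reporter expression before
#' any pulse analysis.
#'
#' @param traces Tidy trace data frame (columns `cell_id`, `expression`,
#'   one row per cell per frame).
#' @param min_expression Cells with `expression < min_expression` are
#'   removed.
#' @return List with `traces` (retained rows), `removed_ids`, and `log`
#'   (data frame: `n_cells`, `n_removed`, `n_retained`).
#' @export
qc_filter <- function(traces, min_expression) {
  stopifnot(is.data.frame(traces),
            all(c("cell_id", "expression") %in% names(traces)))
  expr <- tapply(traces$expression, traces$cell_id, function(e) e[1])
  removed <- names(expr)[expr < min_expression]
  keep <- !(traces$cell_id %in% removed)
  if (!any(keep)) {
    warning("expression QC removed every trace", call. = FALSE)
  }
  list(traces = traces[keep, , drop = FALSE],
       removed_ids = type.convert(removed, as.is = TRUE),
       log = data.frame(n_cells = length(expr),
                        n_removed = length(removed),
                        n_retained = length(expr) - length(removed)))
}

# topographic prominence of peak i (index into x): height minus the higher
# of the two key saddles, found by scanning to the nearest higher ground on
# each side (or the signal end)
peak_prominence <- function(x, i) {
  h <- x[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(x[seq_len(i)])
  right_min <- h
  j <- i + 1L
  n <- length(x)
  while (j <= n && x[j] <= h) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  if (j > n) right_min <- min(x[i:n])
  h - max(left_min, right_min)
}

# candidate local maxima with plateau handling: runs of equal values that
# are strictly above both flanking runs; the peak index is the first frame
# of the run (ties toward earlier frame). Signal ends do not qualify.
local_maxima_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_peak <- r$values[mid] > r$values[mid - 1L] &
    r$values[mid] > r$values[mid + 1L]
  starts[mid][is_peak]
}

#' Detect ERK pulses in a single KTR trace
#'
#' Local maxima of the (optionally median-smoothed) ratio trace with
#' topographic prominence at least `min_prominence` are called as pulses;
#' peaks closer than `min_peak_distance_frames` are resolved in favor of
#' the more prominent (ties to the earlier frame). Pulses peaking within
#' `division_exclusion_frames` before any division frame are retained in
#' the output but marked `division_proximal`, since pre-division pulses
#' are ERK-independent artifacts.
#'
#' @param ratio Numeric vector of cytoplasmic/nuclear ratios at uniform
#'   frame spacing.
#' @param params A [pulse_params] object.
#' @param division_frames Integer frames (1-based, same indexing as
#'   `ratio`) at which the cell divided.
#' @param frames Optional frame numbers for the trace (default
#'   `seq_along(ratio)`); used to express `peak_frame` and to match
#'   `division_frames`.
#' @return Data frame: `peak_frame`, `height`, `prominence`,
#'   `width_frames` (frames above half-prominence around the peak),
#'   `excluded_reason` (`"none"` or `"division_proximal"`).
#' @export
detect_pulses <- function(ratio, params = pulse_params(),
                          division_frames = integer(0),
                          frames = seq_along(ratio)) {
  stopifnot(inherits(params, "pulse_params"))
  if (length(ratio) < 3L) {
    stop("trace too short for pulse detection (need >= 3 frames)",
         call. = FALSE)
  }
  if (length(frames) != length(ratio)) {
    stop("`frames` must match `ratio` in length", call. = FALSE)
  }
  if (length(frames) > 1L && length(unique(diff(frames))) != 1L) {
    stop("non-uniform frame sampling", call. = FALSE)
  }
  x <- ratio
  w <- params$smoothing_window_frames
  if (!is.null(w) && w > 1L) {
    x <- as.numeric(stats::runmed(x, w, endrule = "keep"))
  }
  cand <- local_maxima_runs(x)
  if (!length(cand)) {
    return(data.frame(peak_frame = integer(0), height = numeric(0),
                      prominence = numeric(0), width_frames = integer(0),
                      excluded_reason = character(0)))
  }
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= params$min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  # enforce minimum spacing: keep in order of descending prominence,
  # ties toward earlier frame
  if (length(cand) > 1L && params$min_peak_distance_frames > 0L) {
    ord <- order(-prom, cand)
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) ||
          all(abs(cand[i] - cand[kept]) >= params$min_peak_distance_frames)) {
        kept <- c(kept, i)
      }
    }
    kept <- sort(kept)
    cand <- cand[kept]
    prom <- prom[kept]
  }
  width <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    half <- x[i] - prom[k] / 2
    l <- i
    while (l > 1L && x[l - 1L] >= half) l <- l - 1L
    r <- i
    n <- length(x)
    while (r < n && x[r + 1L] >= half) r <- r + 1L
    r - l + 1L
  }, integer(1))
  peak_frames <- frames[cand]
  excl <- rep("none", length(cand))
  for (d in division_frames) {
    near <- peak_frames >= d - params$division_exclusion_frames &
      peak_frames < d
    excl[near] <- "division_proximal"
  }
  data.frame(peak_frame = peak_frames, height = x[cand],
             prominence = prom, width_frames = width,
             excluded_reason = excl)
}

#' Detect pulses for every cell of a tidy trace table
#'
#' Applies [detect_pulses()] per cell. Traces are truncated at the cell's
#' death frame (frames after death reflect apoptotic debris, not
#' signaling); division frames are taken from the `divided_this_frame`
#' column, which in divided lineages flags every ancestral division
#' carried in the copied history.
#'
#' @param traces Tidy trace data frame with columns `cell_id`, `frame`,
#'   `time_min`, `ratio`, `divided_this_frame`, `died_this_frame`.
#' @param params A [pulse_params] object.
#' @return Data frame of pulses with a leading `cell_id` column.
#' @export
detect_pulses_all <- function(traces, params = pulse_params()) {
  stopifnot(is.data.frame(traces),
            all(c("cell_id", "frame", "ratio") %in% names(traces)))
  out <- lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if ("died_this_frame" %in% names(tr) && any(tr$died_this_frame)) {
      death <- min(tr$frame[tr$died_this_frame])
      tr <- tr[tr$frame <= death, , drop = FALSE]
    }
    if (nrow(tr) < 3L) return(NULL)
    div <- if ("divided_this_frame" %in% names(tr)) {
      tr$frame[tr$divided_this_frame]
    } else integer(0)
    p <- detect_pulses(tr$ratio, params, division_frames = div,
                       frames = tr$frame)
    if (!nrow(p)) return(NULL)
    cbind(cell_id = tr$cell_id[1], p)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(cell_id = integer(0), peak_frame = integer(0),
                      height = numeric(0), prominence = numeric(0),
                      width_frames = integer(0),
                      excluded_reason = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cell pulse counts with QC, exclusion and lineage deduplication
#'
#' Full pulse quantification for a trace table: expression QC, per-trace
#' pulse detection, removal of division-proximal pulses, and lineage
#' deduplication. Because the history of a divided cell is reproduced in
#' both daughters, a pulse that peaked at or before a division would be
#' detected in every descendant trace; each such pulse is attributed once,
#' to the ancestor cell in whose own lifetime segment it occurred.
#'
#' @param traces Tidy trace data frame (schema of
#'   [simulate_ktr_dataset()]).
#' @param params A [pulse_params] object.
#' @param lineage Optional lineage map: data frame with columns
#'   `parent_id`, `child_id`, `division_frame`. Without it, traces are
#'   treated as unrelated cells (no deduplication).
#' @return A list of class `pulse_summary`: `per_cell` (data frame
#'   `cell_id`, `n_pulses` over deduplicated owners), `pulses` (the
#'   deduplicated retained pulses), `n_cells_qc`, `n_pulsing`,
#'   `fraction_pulsing` with Wilson 95% CI `fraction_ci`, and the QC `log`.
#' @export
pulses_per_cell <- function(traces, params = pulse_params(),
                            lineage = NULL) {
  qc <- qc_filter(traces, params$min_expression)
  pulses <- detect_pulses_all(qc$traces, params)
  retained <- pulses[pulses$excluded_reason == "none", , drop = FALSE]
  qc_ids <- unique(qc$traces$cell_id)

  if (!is.null(lineage) && nrow(lineage)) {
    stopifnot(all(c("parent_id", "child_id", "division_frame") %in%
                    names(lineage)))
    if (anyDuplicated(lineage$child_id)) {
      stop("cyclic or inconsistent lineage map: duplicated child",
           call. = FALSE)
    }
    parent_of <- stats::setNames(lineage$parent_id,
                                 as.character(lineage$child_id))
    birth_frame <- stats::setNames(lineage$division_frame,
                                   as.character(lineage$child_id))
    # walk each pulse up the lineage while its peak falls at or before the
    # current cell's birth (division) frame; roots terminate the walk
    owner <- vapply(seq_len(nrow(retained)), function(i) {
      cid <- as.character(retained$cell_id[i])
      cur <- cid
      depth <- 0L
      while (cur %in% names(parent_of) &&
             retained$peak_frame[i] <= birth_frame[cur]) {
        cur <- as.character(parent_of[cur])
        depth <- depth + 1L
        if (depth > 10000L) stop("cyclic lineage map", call. = FALSE)
      }
      cur
    }, character(1))
    retained$owner_id <- type.convert(owner, as.is = TRUE)
    dedup <- retained[!duplicated(retained[, c("owner_id", "peak_frame")]),
                      , drop = FALSE]
  } else {
    retained$owner_id <- retained$cell_id
    dedup <- retained
  }

  counts <- table(dedup$owner_id)
  per_cell <- data.frame(cell_id = type.convert(names(counts), as.is = TRUE),
                         n_pulses = as.integer(counts))
  # fraction pulsing: terminal QC-passing cells whose trace contains >= 1
  # retained pulse (inherited history included), over all QC-passing cells
  pulsing_ids <- unique(retained$cell_id)
  n_pulsing <- sum(qc_ids %in% pulsing_ids)
  ci <- if (length(qc_ids)) fraction_ci(n_pulsing, length(qc_ids))
        else c(NA_real_, NA_real_)
  structure(list(per_cell = per_cell,
                 pulses = dedup,
                 all_pulses = pulses,
                 n_cells_qc = length(qc_ids),
                 n_pulsing = n_pulsing,
                 fraction_pulsing = if (length(qc_ids))
                   n_pulsing / length(qc_ids) else NA_real_,
                 fraction_ci = ci,
                 log = qc$log),
            class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat(sprintf("<pulse_summary> %d pulses in %d of %d QC-passing cells (%.1f%% pulsing)\n",
              nrow(x$pulses), x$n_pulsing, x$n_cells_qc,
              100 * x$fraction_pulsing))
  invisible(x)
}
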