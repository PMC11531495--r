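# Death-event neighborhood analysis.
#
# Dying cells release paracrine EGFR ligands; the question is whether ERK
# pulses are enriched in cells near a death event. For each death event,
# neighbors are the tracked cells whose centroid comes within a fixed
# radius (default 100 px, ~2-3 cell diameters) of the dying cell during
# the 10 frames preceding the death. Each event also gets a count-matched
# random control group drawn from cells alive over the same window that
# are not neighbors of any death event over that time span.

#' Death events in a trace table
#'
#' @param traces Tidy trace data frame with a logical `died_this_frame`
#'   column.
#' @return Data frame `event_id`, `cell_id`, `death_frame`, ordered by
#'   frame.
#' @export
find_death_events <- function(traces) {
  stopifnot(is.data.frame(traces),
            all(c("cell_id", "frame", "died_this_frame") %in% names(traces)))
  d <- traces[traces$died_this_frame, c("cell_id", "frame")]
  d <- d[order(d$frame, d$cell_id), , drop = FALSE]
  data.frame(event_id = seq_len(nrow(d)), cell_id = d$cell_id,
             death_frame = d$frame)
}

#' Neighbors of one death event
#'
#' A cell is a neighbor if its centroid lies within `radius_px` (Euclidean)
#' of the dying cell's centroid in at least one (`rule = "any"`, default)
#' or every (`rule = "all"`) frame of the `window_frames` frames preceding
#' the death in which both cells are tracked. The dying cell itself and
#' cells no longer tracked (already dead) are excluded.
#'
#' @param event One-row data frame (or list) with `cell_id` and
#'   `death_frame`.
#' @param traces Tidy trace data frame with `cell_id`, `frame`, `x_px`,
#'   `y_px`.
#' @param radius_px Neighborhood radius in pixels (default 100).
#' @param window_frames Number of frames before death to examine
#'   (default 10).
#' @param rule `"any"` (default) or `"all"` frames within radius.
#' @return Vector of neighbor cell ids (possibly empty). If the dying cell
#'   has no tracked frames in the window the result is empty with
#'   attribute `untracked = TRUE`.
#' @export
find_neighbors <- function(event, traces, radius_px = 100,
                           window_frames = 10, rule = c("any", "all")) {
  rule <- match.arg(rule)
  check_scalar(radius_px, "radius_px", 0, strict_lower = TRUE)
  check_scalar(window_frames, "window_frames", 1, integer = TRUE)
  window <- (event$death_frame - window_frames):(event$death_frame - 1L)
  self <- traces$cell_id == event$cell_id
  own <- traces[self & traces$frame %in% window, c("frame", "x_px", "y_px")]
  if (!nrow(own)) {
    out <- traces$cell_id[0]
    attr(out, "untracked") <- TRUE
    return(out)
  }
  others <- traces[!self & traces$frame %in% own$frame,
                   c("cell_id", "frame", "x_px", "y_px")]
  if (!nrow(others)) return(traces$cell_id[0])
  ox <- own$x_px[match(others$frame, own$frame)]
  oy <- own$y_px[match(others$frame, own$frame)]
  within <- (others$x_px - ox)^2 + (others$y_px - oy)^2 <= radius_px^2
  if (rule == "any") {
    sort(unique(others$cell_id[within]))
  } else {
    # within radius at every shared tracked frame
    n_shared <- table(others$cell_id)
    n_within <- table(others$cell_id[within])
    ids <- names(n_within)[n_within[] ==
                             n_shared[match(names(n_within),
                                            names(n_shared))]]
    sort(type.convert(ids, as.is = TRUE))
  }
}

#' Neighbor assignments for all death events
#'
#' @param traces Tidy trace data frame.
#' @param events Data frame from [find_death_events()] (computed from
#'   `traces` when omitted).
#' @inheritParams find_neighbors
#' @return A list of class `neighbor_assignments`: `events`, and
#'   `neighbors`, a list (one element per event, in event order) of
#'   neighbor id vectors; plus the parameters used.
#' @export
find_neighbors_all <- function(traces, events = NULL, radius_px = 100,
                               window_frames = 10, rule = "any") {
  if (is.null(events)) events <- find_death_events(traces)
  nb <- lapply(seq_len(nrow(events)), function(i) {
    find_neighbors(events[i, ], traces, radius_px, window_frames, rule)
  })
  structure(list(events = events, neighbors = nb,
                 radius_px = radius_px, window_frames = window_frames,
                 rule = rule),
            class = "neighbor_assignments")
}

#' Count-matched random control cells for each death event
#'
#' For each event, samples (uniformly, without replacement) as many
#' control cells as the event has neighbors, from cells that are tracked
#' during at least one frame of the event's window, pass QC if `qc_ids`
#' is given, are not the dying cell, and are not neighbors of *any* death
#' event whose window overlaps this event's window. Events with too few
#' eligible cells are dropped and logged.
#'
#' @param assignments A [find_neighbors_all()] result.
#' @param traces Tidy trace data frame.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param qc_ids Optional vector of QC-passing cell ids to restrict the
#'   control pool.
#' @return The `assignments` object augmented with `controls` (list of
#'   control id vectors, count-matched per event; `NULL` for dropped
#'   events), `dropped` (event ids dropped for lack of eligible cells)
#'   and `seed`.
#' @export
sample_controls <- function(assignments, traces, seed = 1, qc_ids = NULL) {
  stopifnot(inherits(assignments, "neighbor_assignments"))
  events <- assignments$events
  w <- assignments$window_frames
  windows <- lapply(seq_len(nrow(events)), function(i) {
    (events$death_frame[i] - w):(events$death_frame[i] - 1L)
  })
  controls <- vector("list", nrow(events))
  dropped <- integer(0)
  with_seed(seed, {
    for (i in seq_len(nrow(events))) {
      n_need <- length(assignments$neighbors[[i]])
      if (n_need == 0L) {
        controls[[i]] <- traces$cell_id[0]
        next
      }
      alive <- unique(traces$cell_id[traces$frame %in% windows[[i]]])
      if (!is.null(qc_ids)) alive <- alive[alive %in% qc_ids]
      # exclude neighbors of any event over the same time span
      overlapping <- which(vapply(windows, function(win) {
        any(win %in% windows[[i]])
      }, logical(1)))
      excl <- unique(c(events$cell_id[i],
                       unlist(assignments$neighbors[overlapping])))
      pool <- setdiff(alive, excl)
      if (length(pool) < n_need) {
        dropped <- c(dropped, events$event_id[i])
        next
      }
      controls[[i]] <- sort(sample(pool, n_need))
    }
  })
  assignments$controls <- controls
  assignments$dropped <- dropped
  assignments$seed <- seed
  assignments
}

#' Pulse enrichment in neighbors of death events vs random controls
#'
#' For each event, counts retained pulses peaking inside the event's
#' window for the neighbor group and the count-matched control group, and
#' summarizes pulses per cell per event, the pooled fraction of pulsing
#' cells in each group (Wilson 95% CI), and a one-sided bootstrap test of
#' whether the median per-event pulses-per-cell is higher in neighbors.
#'
#' @param assignments A [sample_controls()] result (with controls).
#' @param pulses Pulse table (e.g. `detect_pulses_all()` output or the
#'   `pulses` element of [pulses_per_cell()]): columns `cell_id`,
#'   `peak_frame`, `excluded_reason`.
#' @param n_boot Bootstrap resamples for the group comparison
#'   (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A list of class `neighbor_summary`: `per_event` (data frame
#'   `event_id`, `group` ("neighbor"/"random"), `n_cells`, `n_pulses`,
#'   `pulses_per_cell`), `per_cell` (cell-level rows used for pooled
#'   fractions), `fraction_pulsing` and `fraction_ci` per group, and
#'   `test` (a [bootstrap_median_test()] result, neighbor vs random).
#' @export
pulse_enrichment <- function(assignments, pulses, n_boot = 1000, seed = 1) {
  stopifnot(inherits(assignments, "neighbor_assignments"))
  if (is.null(assignments$controls)) {
    stop("run sample_controls() before pulse_enrichment()", call. = FALSE)
  }
  if ("excluded_reason" %in% names(pulses)) {
    pulses <- pulses[pulses$excluded_reason == "none", , drop = FALSE]
  }
  events <- assignments$events
  w <- assignments$window_frames
  rows <- list()
  cells <- list()
  for (i in seq_len(nrow(events))) {
    if (events$event_id[i] %in% assignments$dropped) next
    nb <- assignments$neighbors[[i]]
    if (!length(nb)) next
    ctrl <- assignments$controls[[i]]
    window <- (events$death_frame[i] - w):(events$death_frame[i] - 1L)
    in_win <- pulses[pulses$peak_frame %in% window, , drop = FALSE]
    for (grp in c("neighbor", "random")) {
      ids <- if (grp == "neighbor") nb else ctrl
      n_per <- vapply(ids, function(id) sum(in_win$cell_id == id),
                      integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = events$event_id[i], group = grp,
        n_cells = length(ids), n_pulses = sum(n_per),
        pulses_per_cell = mean(n_per))
      cells[[length(cells) + 1L]] <- data.frame(
        event_id = events$event_id[i], group = grp, cell_id = ids,
        n_pulses = n_per)
    }
  }
  per_event <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(0), group = character(0),
               n_cells = integer(0), n_pulses = integer(0),
               pulses_per_cell = numeric(0))
  per_cell <- if (length(cells)) do.call(rbind, cells) else
    data.frame(event_id = integer(0), group = character(0),
               cell_id = integer(0), n_pulses = integer(0))
  rownames(per_event) <- rownames(per_cell) <- NULL
  frac <- lapply(c(neighbor = "neighbor", random = "random"), function(g) {
    sub <- per_cell[per_cell$group == g, , drop = FALSE]
    if (!nrow(sub)) return(list(fraction = NA_real_, ci = c(NA, NA)))
    k <- sum(sub$n_pulses > 0)
    list(fraction = k / nrow(sub), ci = fraction_ci(k, nrow(sub)))
  })
  n_ppc <- per_event$pulses_per_cell[per_event$group == "neighbor"]
  r_ppc <- per_event$pulses_per_cell[per_event$group == "random"]
  test <- if (length(n_ppc) >= 2 && length(r_ppc) >= 2) {
    bootstrap_median_test(n_ppc, r_ppc, n_boot = n_boot,
                          alternative = "greater", seed = seed)
  } else NULL
  structure(list(per_event = per_event, per_cell = per_cell,
                 fraction_pulsing = c(neighbor = frac$neighbor$fraction,
                                      random = frac$random$fraction),
                 fraction_ci = list(neighbor = frac$neighbor$ci,
                                    random = frac$random$ci),
                 test = test),
            class = "neighbor_summary")
}

#' @export
print.neighbor_summary <- function(x, ...) {
  n <- x$per_event[x$per_event$group == "neighbor", "pulses_per_cell"]
  r <- x$per_event[x$per_event$group == "random", "pulses_per_cell"]
  cat(sprintf("<neighbor_summary> %d events\n", length(n)))
  cat(sprintf("  median pulses/cell: neighbors %.3f, random %.3f\n",
              stats::median(n), stats::median(r)))
  cat(sprintf("  fraction pulsing: neighbors %.3f, random %.3f\n",
              x$fraction_pulsing["neighbor"], x$fraction_pulsing["random"]))
  if (!is.null(x$test)) {
    cat(sprintf("  one-sided bootstrap p (neighbor > random): %.4f\n",
                x$test$p_value))
  }
  invisible(x)
}
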