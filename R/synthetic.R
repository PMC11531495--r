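# Synthetic data generators with known ground truth.
#
# Each generator emulates one of the data-generating regimes the analysis
# modules are built for: cells with bright cytoplasmic puncta over diffuse
# background (two channels with controllable colocalization), paired
# pre/post membrane-enrichment scenes, 22-hour single-cell KTR ratio time
# series with pulses, divisions, deaths and spatially elevated pulse rates
# near deaths, and exponential dissociation decay traces. All randomness
# flows through one integer seed per configuration, so outputs are
# bit-reproducible.
#
# Geometry is deliberately simple - cells are disks on a jittered grid -
# because mask geometry is not what the detectors are tested on.

# ---- puncta scenes ---------------------------------------------------------

#' Configuration for a two-channel puncta scene
#'
#' @param image_height,image_width Image size in pixels.
#' @param n_cells Number of cells (disks on a jittered grid).
#' @param cell_radius_px Cell radius, pixels.
#' @param puncta_per_cell Number of puncta per cell in each channel.
#' @param punctum_radius_px Length-2 range of punctum radii, pixels.
#' @param punctum_intensity_gain Punctum intensity as a fold over the
#'   cytoplasmic background.
#' @param background_level Cytoplasmic background intensity, arbitrary
#'   units.
#' @param noise_sd SD of additive Gaussian noise (clipped at 0).
#' @param coloc_fraction Fraction of channel-A puncta co-placed in channel
#'   B, in `[0, 1]`. Per cell, the co-placed count is the integer part
#'   plus a Bernoulli draw on the remainder, so the expected per-cell
#'   fraction equals `coloc_fraction`.
#' @param seed Integer seed.
#' @return A list of class `puncta_scene_config`.
#' @export
puncta_scene_config <- function(image_height = 256, image_width = 256,
                                n_cells = 9, cell_radius_px = 36,
                                puncta_per_cell = 5,
                                punctum_radius_px = c(2, 4),
                                punctum_intensity_gain = 5,
                                background_level = 200,
                                noise_sd = 10,
                                coloc_fraction = 0.8,
                                seed = 1) {
  check_scalar(image_height, "image_height", 1, integer = TRUE)
  check_scalar(image_width, "image_width", 1, integer = TRUE)
  check_scalar(n_cells, "n_cells", 1, integer = TRUE)
  check_scalar(cell_radius_px, "cell_radius_px", 0, strict_lower = TRUE)
  check_scalar(puncta_per_cell, "puncta_per_cell", 0, integer = TRUE)
  stopifnot(length(punctum_radius_px) == 2,
            all(punctum_radius_px > 0),
            punctum_radius_px[1] <= punctum_radius_px[2])
  check_scalar(punctum_intensity_gain, "punctum_intensity_gain", 0,
               strict_lower = TRUE)
  check_scalar(background_level, "background_level", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(coloc_fraction, "coloc_fraction", 0, upper = 1)
  structure(as.list(environment()), class = "puncta_scene_config")
}

# place cell centers on a jittered grid; error if they cannot fit
place_cells <- function(cfg) {
  ngrid_c <- ceiling(sqrt(cfg$n_cells))
  ngrid_r <- ceiling(cfg$n_cells / ngrid_c)
  sp_r <- cfg$image_height / ngrid_r
  sp_c <- cfg$image_width / ngrid_c
  slack <- min(sp_r, sp_c) / 2 - cfg$cell_radius_px - 1
  if (slack < 0) {
    stop("cells do not fit in the image: reduce n_cells or cell_radius_px",
         call. = FALSE)
  }
  jitter_amp <- min(slack, 0.1 * min(sp_r, sp_c))
  centers <- matrix(NA_real_, cfg$n_cells, 2)
  k <- 0L
  for (i in seq_len(ngrid_r)) {
    for (j in seq_len(ngrid_c)) {
      if (k >= cfg$n_cells) break
      k <- k + 1L
      centers[k, ] <- c((i - 0.5) * sp_r, (j - 0.5) * sp_c) +
        stats::runif(2, -jitter_amp, jitter_amp)
    }
  }
  centers
}

# place n non-overlapping puncta (center, radius) fully inside a disk cell;
# `avoid` is an optional matrix (row, col, radius) of puncta that must not
# be overlapped either
place_puncta <- function(n, cell_center, cell_radius, radius_range,
                         avoid = NULL, max_tries = 500) {
  placed <- matrix(numeric(0), 0, 3,
                   dimnames = list(NULL, c("row", "col", "radius")))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      # uniform position with the whole punctum inside the cell
      rho_max <- cell_radius - r - 1
      if (rho_max <= 0) break
      rho <- sqrt(stats::runif(1)) * rho_max
      th <- stats::runif(1, 0, 2 * pi)
      pos <- cell_center + rho * c(cos(th), sin(th))
      all_prev <- rbind(placed, avoid)
      if (nrow(all_prev)) {
        d <- sqrt((all_prev[, 1] - pos[1])^2 + (all_prev[, 2] - pos[2])^2)
        if (any(d <= all_prev[, 3] + r + 1)) next
      }
      placed <- rbind(placed, c(pos, r))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("punctum placement failed: cell too crowded for the requested puncta",
           call. = FALSE)
    }
  }
  placed
}

#' Simulate a two-channel puncta scene with ground truth
#'
#' Cells are disks of uniform cytoplasmic background; puncta are smaller
#' disks at `punctum_intensity_gain` times the background, placed fully
#' inside their cell without mutual overlap. A configurable share of
#' channel-A puncta is co-placed (same center and radius) in channel B;
#' the remaining channel-B puncta are placed away from all A-puncta.
#'
#' @param cfg A [puncta_scene_config()].
#' @return List with `channel_a`, `channel_b` (both [labeled_image]) and
#'   `truth`: a list with per-channel punctum label masks
#'   (`puncta_masks$a/b`), a punctum table (`puncta`), and per-cell
#'   `coloc_fraction`.
#' @export
simulate_puncta_scene <- function(cfg) {
  stopifnot(inherits(cfg, "puncta_scene_config"))
  with_seed(cfg$seed, {
    nr <- cfg$image_height; nc <- cfg$image_width
    labels <- matrix(0L, nr, nc)
    centers <- place_cells(cfg)
    for (k in seq_len(cfg$n_cells)) {
      labels[paint_disk(nr, nc, centers[k, 1], centers[k, 2],
                        cfg$cell_radius_px)] <- k
    }
    base_a <- matrix(cfg$background_level / 10, nr, nc)
    base_a[labels > 0] <- cfg$background_level
    base_b <- base_a
    mask_a <- matrix(0L, nr, nc)
    mask_b <- matrix(0L, nr, nc)
    punctum_level <- cfg$background_level * cfg$punctum_intensity_gain
    rows <- list()
    coloc_true <- rep(NA_real_, cfg$n_cells)
    uid_a <- 0L; uid_b <- 0L
    for (k in seq_len(cfg$n_cells)) {
      pa <- place_puncta(cfg$puncta_per_cell, centers[k, ],
                         cfg$cell_radius_px, cfg$punctum_radius_px)
      n <- nrow(pa)
      n_co <- if (n) {
        frac <- cfg$coloc_fraction * n
        min(n, floor(frac) + stats::rbinom(1, 1, frac - floor(frac)))
      } else 0L
      co_idx <- if (n_co > 0) sample.int(n, n_co) else integer(0)
      pb <- pa[co_idx, , drop = FALSE]
      if (n - n_co > 0) {
        pb_extra <- place_puncta(n - n_co, centers[k, ],
                                 cfg$cell_radius_px, cfg$punctum_radius_px,
                                 avoid = pa)
        pb <- rbind(pb, pb_extra)
      }
      for (i in seq_len(n)) {
        d <- paint_disk(nr, nc, pa[i, 1], pa[i, 2], pa[i, 3])
        base_a[d] <- punctum_level
        uid_a <- uid_a + 1L
        mask_a[d] <- uid_a
        rows[[length(rows) + 1L]] <- data.frame(
          channel = "a", cell_id = k, punctum_id = uid_a,
          row = pa[i, 1], col = pa[i, 2], radius = pa[i, 3],
          coloc = i %in% co_idx)
      }
      for (i in seq_len(nrow(pb))) {
        d <- paint_disk(nr, nc, pb[i, 1], pb[i, 2], pb[i, 3])
        base_b[d] <- punctum_level
        uid_b <- uid_b + 1L
        mask_b[d] <- uid_b
        rows[[length(rows) + 1L]] <- data.frame(
          channel = "b", cell_id = k, punctum_id = uid_b,
          row = pb[i, 1], col = pb[i, 2], radius = pb[i, 3],
          coloc = i <= n_co)
      }
      coloc_true[k] <- if (n) n_co / n else NA_real_
    }
    add_noise <- function(m) {
      if (cfg$noise_sd > 0) {
        m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd),
                        nrow(m), ncol(m))
      }
      pmax(m, 0)
    }
    puncta <- if (length(rows)) do.call(rbind, rows) else data.frame(
      channel = character(0), cell_id = integer(0), punctum_id = integer(0),
      row = numeric(0), col = numeric(0), radius = numeric(0),
      coloc = logical(0))
    list(channel_a = labeled_image(add_noise(base_a), labels),
         channel_b = labeled_image(add_noise(base_b), labels),
         truth = list(puncta_masks = list(a = mask_a, b = mask_b),
                      puncta = puncta,
                      coloc_fraction = coloc_true,
                      cell_centers = centers,
                      config = cfg))
  })
}

# ---- translocation scenes --------------------------------------------------

#' Configuration for a pre/post membrane-enrichment scene pair
#'
#' @param image_px Square image side, pixels.
#' @param cell_radius_px Cell radius, pixels.
#' @param edge_ring_width_px Edge ring width (default 10 px).
#' @param edge_enrichment_pre,edge_enrichment_post Edge/core mean intensity
#'   ratio before and after stimulation (> 0).
#' @param base_intensity Core intensity, arbitrary units.
#' @param noise_sd SD of additive Gaussian noise (clipped at 0).
#' @param seed Integer seed.
#' @return A list of class `translocation_scene_config`.
#' @export
translocation_scene_config <- function(image_px = 128,
                                       cell_radius_px = 40,
                                       edge_ring_width_px = 10,
                                       edge_enrichment_pre = 1.0,
                                       edge_enrichment_post = 1.5,
                                       base_intensity = 100,
                                       noise_sd = 2,
                                       seed = 1) {
  check_scalar(image_px, "image_px", 1, integer = TRUE)
  check_scalar(cell_radius_px, "cell_radius_px", 0, strict_lower = TRUE)
  check_scalar(edge_ring_width_px, "edge_ring_width_px", 0,
               strict_lower = TRUE)
  if (edge_ring_width_px >= cell_radius_px) {
    stop("ring width must be smaller than the cell radius", call. = FALSE)
  }
  check_scalar(edge_enrichment_pre, "edge_enrichment_pre", 0,
               strict_lower = TRUE)
  check_scalar(edge_enrichment_post, "edge_enrichment_post", 0,
               strict_lower = TRUE)
  check_scalar(base_intensity, "base_intensity", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  structure(as.list(environment()), class = "translocation_scene_config")
}

#' Simulate a pre/post-stimulation scene pair with ground truth
#'
#' One disk cell centered in the image; edge-ring pixels are set to
#' `enrichment * base_intensity` and core pixels to `base_intensity`, so
#' in the noiseless limit the edge/core mean ratio equals the configured
#' enrichment exactly.
#'
#' @param cfg A [translocation_scene_config()].
#' @return List with `pre`, `post` (intensity matrices), `mask` (logical
#'   cell mask) and `truth` (`ml_pre`, `ml_post`, `translocation`).
#' @export
simulate_translocation_pair <- function(cfg) {
  stopifnot(inherits(cfg, "translocation_scene_config"))
  with_seed(cfg$seed, {
    n <- cfg$image_px
    mask <- paint_disk(n, n, (n + 1) / 2, (n + 1) / 2, cfg$cell_radius_px)
    part <- partition_ring(mask, cfg$edge_ring_width_px)
    build <- function(enrichment) {
      img <- matrix(cfg$base_intensity / 10, n, n)
      img[part$core] <- cfg$base_intensity
      img[part$edge] <- cfg$base_intensity * enrichment
      if (cfg$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
      }
      pmax(img, 0)
    }
    pre <- build(cfg$edge_enrichment_pre)
    post <- build(cfg$edge_enrichment_post)
    list(pre = pre, post = post, mask = mask,
         truth = list(ml_pre = cfg$edge_enrichment_pre,
                      ml_post = cfg$edge_enrichment_post,
                      translocation = cfg$edge_enrichment_post -
                        cfg$edge_enrichment_pre,
                      config = cfg))
  })
}

# ---- KTR time series -------------------------------------------------------

#' Configuration for a synthetic KTR time-lapse dataset
#'
#' Defaults emulate a 22-h imaging run at 5-min frames of an
#' ALKi-treated population: sporadic basal ERK pulses of 10-20 min,
#' occasional divisions (with an ERK-independent pre-division artifact
#' pulse), deaths at a rate giving on the order of a hundred events, and
#' an elevated pulse rate in cells within 100 px of a dying cell during
#' the 10 frames preceding its death.
#'
#' @param n_cells Number of founder cells.
#' @param frame_interval_min Frame interval, minutes (default 5).
#' @param duration_h Imaging duration, hours (default 22); must give an
#'   integer frame count.
#' @param baseline_ratio Baseline cytoplasmic/nuclear ratio.
#' @param pulse_amplitude Pulse height above baseline, ratio units.
#' @param pulse_duration_min Length-2 range of pulse durations, minutes
#'   (default 10-20).
#' @param basal_pulse_rate Basal pulse rate, pulses/cell/h.
#' @param neighbor_pulse_rate Pulse rate for cells near a death during the
#'   pre-death window, pulses/cell/h.
#' @param death_rate Deaths/cell/h.
#' @param division_rate Divisions/cell/h.
#' @param division_artifact_pulse If `TRUE` (default), each division adds
#'   one artifact pulse within the 10 frames preceding it.
#' @param arena_size_px Square arena side, pixels.
#' @param motility_px_per_frame SD of the per-frame random-walk step.
#' @param neighbor_radius_px Radius defining death-event neighbors
#'   (default 100 px).
#' @param pre_death_window_frames Frames before a death during which
#'   neighbors pulse at the elevated rate (default 10).
#' @param expression_levels List: `meanlog`, `sdlog` of the log-normal
#'   reporter expression of normal cells, `frac_low` (fraction of low/no
#'   expressors) and `low_level`.
#' @param noise_sd SD of the additive Gaussian trace noise.
#' @param seed Integer seed.
#' @return A list of class `ktr_sim_config`.
#' @export
ktr_sim_config <- function(n_cells = 250,
                           frame_interval_min = 5,
                           duration_h = 22,
                           baseline_ratio = 1.0,
                           pulse_amplitude = 0.5,
                           pulse_duration_min = c(10, 20),
                           basal_pulse_rate = 0.1,
                           neighbor_pulse_rate = 0.5,
                           death_rate = 0.02,
                           division_rate = 0.02,
                           division_artifact_pulse = TRUE,
                           arena_size_px = 1024,
                           motility_px_per_frame = 2,
                           neighbor_radius_px = 100,
                           pre_death_window_frames = 10,
                           expression_levels = list(meanlog = log(1000),
                                                    sdlog = 0.5,
                                                    frac_low = 0.1,
                                                    low_level = 10),
                           noise_sd = 0.05,
                           seed = 1) {
  check_scalar(n_cells, "n_cells", 1, integer = TRUE)
  check_scalar(frame_interval_min, "frame_interval_min", 0,
               strict_lower = TRUE)
  check_scalar(duration_h, "duration_h", 0, strict_lower = TRUE)
  n_frames <- duration_h * 60 / frame_interval_min
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("duration_h * 60 / frame_interval_min must be an integer frame count",
         call. = FALSE)
  }
  stopifnot(length(pulse_duration_min) == 2,
            all(pulse_duration_min > 0),
            pulse_duration_min[1] <= pulse_duration_min[2],
            pulse_duration_min[2] < duration_h * 60)
  for (nm in c("basal_pulse_rate", "neighbor_pulse_rate", "death_rate",
               "division_rate")) {
    check_scalar(get(nm), nm, 0)
  }
  check_scalar(arena_size_px, "arena_size_px", 1)
  check_scalar(motility_px_per_frame, "motility_px_per_frame", 0)
  check_scalar(neighbor_radius_px, "neighbor_radius_px", 0,
               strict_lower = TRUE)
  check_scalar(pre_death_window_frames, "pre_death_window_frames", 1,
               integer = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  out <- as.list(environment())
  out$nm <- NULL
  out$n_frames <- as.integer(round(n_frames))
  structure(out, class = "ktr_sim_config")
}

# sample up to n peak frames from `frames_ok`, keeping every chosen peak
# at least `min_sep` frames from the already `existing` peaks and from
# each other: ERK pulses are discrete refractory events, and two bumps
# closer than one pulse width would sum to a single excursion rather
# than two resolvable pulses
sample_spaced <- function(frames_ok, n, existing, min_sep) {
  chosen <- integer(0)
  avail <- frames_ok
  if (length(existing)) {
    avail <- avail[vapply(avail, function(f) {
      all(abs(f - existing) >= min_sep)
    }, logical(1))]
  }
  for (i in seq_len(n)) {
    if (!length(avail)) break
    f <- avail[sample.int(length(avail), 1L)]
    chosen <- c(chosen, f)
    avail <- avail[abs(avail - f) >= min_sep]
  }
  chosen
}

# raised-cosine bump of given amplitude/duration centered at peak_time,
# evaluated at times t (minutes); compact support of width duration
raised_cosine <- function(t, peak_time, amplitude, duration) {
  u <- (t - peak_time) / duration
  out <- numeric(length(t))
  inside <- abs(u) <= 0.5
  out[inside] <- amplitude * 0.5 * (1 + cos(2 * pi * u[inside]))
  out
}

# reflecting random walk within [0, arena]
reflect_walk <- function(start, n_steps, step_sd, arena) {
  if (n_steps == 0) return(numeric(0))
  x <- start + cumsum(stats::rnorm(n_steps, 0, step_sd))
  # reflect into [0, arena] (handles multiple bounces)
  x <- x %% (2 * arena)
  ifelse(x > arena, 2 * arena - x, x)
}

#' Simulate a KTR time-lapse dataset with ground truth
#'
#' Cells move by a reflecting random walk; each cell independently risks
#' death and division (exponential waiting times). A division ends the
#' parent's segment and starts two daughters at its position; in the
#' output table each terminal cell (one that died or survived to the end)
#' carries the full ratio history of its ancestors, with ancestral
#' divisions flagged, mirroring how tracked lineages are exported from
#' live-cell experiments. Pulses are raised-cosine bumps added to the
#' baseline: basal pulses at `basal_pulse_rate`; in cells within
#' `neighbor_radius_px` of a dying cell during the pre-death window, extra
#' pulses bringing the window rate up to `neighbor_pulse_rate`; and, if
#' enabled, one artifact pulse within the 10 frames before each division.
#'
#' @param cfg A [ktr_sim_config()].
#' @return List with `traces` (tidy data frame: `cell_id`, `parent_id`,
#'   `frame`, `time_min`, `ratio`, `x_px`, `y_px`, `expression`,
#'   `divided_this_frame`, `died_this_frame`) and `truth` (class
#'   `ktr_truth`): `pulses` (owner `cell_id`, `peak_frame`,
#'   `duration_min`, `is_division_artifact`, `is_neighbor_driven`),
#'   `death_events`, `lineage` (`parent_id`, `child_id`,
#'   `division_frame`), `low_expression_ids`, and the config.
#' @export
simulate_ktr_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ktr_sim_config"))
  with_seed(cfg$seed, {
    nf <- cfg$n_frames
    dt_min <- cfg$frame_interval_min
    dt_h <- dt_min / 60
    # --- lineage/lifecycle simulation over segments -----------------------
    # each "segment" is one cell between its birth (division of parent, or
    # frame 0 for founders) and its end (death, division, or end of movie)
    seg <- list()  # id, parent, birth (frame; own span is birth+1 .. end),
                   # end, fate ("division"/"death"/"survived")
    queue <- list()
    next_id <- 0L
    for (i in seq_len(cfg$n_cells)) {
      next_id <- next_id + 1L
      queue[[length(queue) + 1L]] <- list(id = next_id, parent = NA_integer_,
                                          birth = 0L)
    }
    while (length(queue)) {
      cell <- queue[[1L]]
      queue[[1L]] <- NULL
      span_left <- nf - cell$birth
      t_death <- if (cfg$death_rate > 0)
        ceiling(stats::rexp(1, cfg$death_rate) / dt_h) else Inf
      t_div <- if (cfg$division_rate > 0)
        ceiling(stats::rexp(1, cfg$division_rate) / dt_h) else Inf
      if (t_div < t_death && t_div < span_left) {
        end <- cell$birth + t_div
        fate <- "division"
      } else if (t_death <= span_left) {
        end <- cell$birth + t_death
        fate <- "death"
      } else {
        end <- nf
        fate <- "survived"
      }
      cell$end <- as.integer(end)
      cell$fate <- fate
      seg[[cell$id]] <- cell
      if (fate == "division") {
        for (d in 1:2) {
          next_id <- next_id + 1L
          queue[[length(queue) + 1L]] <- list(id = next_id,
                                              parent = cell$id,
                                              birth = cell$end)
        }
      }
    }
    n_seg <- next_id
    seg_birth <- vapply(seg, `[[`, integer(1), "birth")
    seg_end <- vapply(seg, `[[`, integer(1), "end")
    seg_parent <- vapply(seg, function(s) as.integer(s$parent), integer(1))
    seg_fate <- vapply(seg, `[[`, character(1), "fate")

    # --- positions: own-segment trajectories, then full path histories ----
    X <- matrix(NA_real_, nf, n_seg)
    Y <- matrix(NA_real_, nf, n_seg)
    for (id in seq_len(n_seg)) {
      b <- seg_birth[id]; e <- seg_end[id]
      if (e <= b) next
      if (is.na(seg_parent[id])) {
        x0 <- stats::runif(1, 0, cfg$arena_size_px)
        y0 <- stats::runif(1, 0, cfg$arena_size_px)
        X[b + 1L, id] <- x0
        Y[b + 1L, id] <- y0
        if (e > b + 1L) {
          X[(b + 2L):e, id] <- reflect_walk(x0, e - b - 1L,
                                            cfg$motility_px_per_frame,
                                            cfg$arena_size_px)
          Y[(b + 2L):e, id] <- reflect_walk(y0, e - b - 1L,
                                            cfg$motility_px_per_frame,
                                            cfg$arena_size_px)
        }
      } else {
        x0 <- X[b, seg_parent[id]]
        y0 <- Y[b, seg_parent[id]]
        X[(b + 1L):e, id] <- reflect_walk(x0, e - b,
                                          cfg$motility_px_per_frame,
                                          cfg$arena_size_px)
        Y[(b + 1L):e, id] <- reflect_walk(y0, e - b,
                                          cfg$motility_px_per_frame,
                                          cfg$arena_size_px)
      }
    }
    present <- outer(seq_len(nf), seg_birth, ">") &
      outer(seq_len(nf), seg_end, "<=")

    # --- basal and division-artifact pulses per segment -------------------
    pulses <- list()
    add_pulse <- function(owner, frame, is_div, is_nb) {
      pulses[[length(pulses) + 1L]] <<- data.frame(
        cell_id = owner, peak_frame = as.integer(frame),
        duration_min = stats::runif(1, cfg$pulse_duration_min[1],
                                    cfg$pulse_duration_min[2]),
        amplitude = cfg$pulse_amplitude,
        is_division_artifact = is_div, is_neighbor_driven = is_nb)
    }
    min_sep <- ceiling(cfg$pulse_duration_min[2] / dt_min)
    seg_peaks <- vector("list", n_seg)
    for (id in seq_len(n_seg)) {
      frames_own <- if (seg_end[id] > seg_birth[id])
        (seg_birth[id] + 1L):seg_end[id] else integer(0)
      # a dying cell does not fire a pulse on its death frame
      if (seg_fate[id] == "death") {
        frames_own <- frames_own[frames_own < seg_end[id]]
      }
      if (!length(frames_own)) next
      n_basal <- stats::rpois(1, cfg$basal_pulse_rate *
                                length(frames_own) * dt_h)
      for (f in sample_spaced(frames_own, n_basal, integer(0), min_sep)) {
        add_pulse(id, f, FALSE, FALSE)
        seg_peaks[[id]] <- c(seg_peaks[[id]], f)
      }
      if (seg_fate[id] == "division" && cfg$division_artifact_pulse) {
        win <- intersect(frames_own,
                         (seg_end[id] - 10L):(seg_end[id] - 1L))
        for (f in sample_spaced(win, 1L, seg_peaks[[id]], min_sep)) {
          add_pulse(id, f, TRUE, FALSE)
          seg_peaks[[id]] <- c(seg_peaks[[id]], f)
        }
      }
    }

    # --- neighbor-driven pulses near deaths -------------------------------
    death_ids <- which(seg_fate == "death")
    extra_rate <- max(0, cfg$neighbor_pulse_rate - cfg$basal_pulse_rate)
    true_neighbors <- list()
    for (d in death_ids) {
      f_death <- seg_end[d]
      lo <- max(1L, f_death - cfg$pre_death_window_frames)
      if (f_death - 1L < lo) next
      win <- lo:(f_death - 1L)
      # dying cell's path position over the window (may predate its birth)
      path <- d
      while (!is.na(seg_parent[path[1L]])) path <- c(seg_parent[path[1L]], path)
      dx <- rep(NA_real_, nf); dy <- rep(NA_real_, nf)
      for (p in path) {
        rng <- which(present[, p])
        dx[rng] <- X[rng, p]; dy[rng] <- Y[rng, p]
      }
      nb <- integer(0)
      for (id in setdiff(seq_len(n_seg), path)) {
        shared <- win[present[win, id] & !is.na(dx[win])]
        if (!length(shared)) next
        dist2 <- (X[shared, id] - dx[shared])^2 +
          (Y[shared, id] - dy[shared])^2
        if (any(dist2 <= cfg$neighbor_radius_px^2)) nb <- c(nb, id)
      }
      true_neighbors[[length(true_neighbors) + 1L]] <-
        list(dying = d, death_frame = f_death, neighbors = nb)
      if (extra_rate > 0) {
        for (id in nb) {
          frames_ok <- win[present[win, id]]
          if (seg_fate[id] == "death") {
            frames_ok <- frames_ok[frames_ok < seg_end[id]]
          }
          if (!length(frames_ok)) next
          n_extra <- stats::rpois(1, extra_rate * length(frames_ok) * dt_h)
          for (f in sample_spaced(frames_ok, n_extra, seg_peaks[[id]],
                                  min_sep)) {
            add_pulse(id, f, FALSE, TRUE)
            seg_peaks[[id]] <- c(seg_peaks[[id]], f)
          }
        }
      }
    }
    pulses <- if (length(pulses)) do.call(rbind, pulses) else data.frame(
      cell_id = integer(0), peak_frame = integer(0),
      duration_min = numeric(0), amplitude = numeric(0),
      is_division_artifact = logical(0), is_neighbor_driven = logical(0))

    # --- per-segment noise, expression ------------------------------------
    noise <- lapply(seq_len(n_seg), function(id) {
      len <- seg_end[id] - seg_birth[id]
      if (len > 0 && cfg$noise_sd > 0) stats::rnorm(len, 0, cfg$noise_sd)
      else numeric(max(0, len))
    })
    roots <- which(is.na(seg_parent))
    el <- cfg$expression_levels
    root_expr <- ifelse(stats::runif(length(roots)) < el$frac_low,
                        el$low_level,
                        stats::rlnorm(length(roots), el$meanlog, el$sdlog))
    seg_expr <- numeric(n_seg)
    for (id in seq_len(n_seg)) {
      r <- id
      while (!is.na(seg_parent[r])) r <- seg_parent[r]
      seg_expr[id] <- root_expr[match(r, roots)]
    }

    # --- assemble terminal traces -----------------------------------------
    terminal <- which(seg_fate != "division")
    times_all <- (seq_len(nf) - 1L) * dt_min
    traces <- vector("list", length(terminal))
    for (k in seq_along(terminal)) {
      id <- terminal[k]
      path <- id
      while (!is.na(seg_parent[path[1L]])) path <- c(seg_parent[path[1L]], path)
      e <- seg_end[id]
      frames <- seq_len(e)
      tt <- times_all[frames]
      latent <- rep(cfg$baseline_ratio, e)
      own_pulses <- pulses[pulses$cell_id %in% path, , drop = FALSE]
      for (i in seq_len(nrow(own_pulses))) {
        latent <- latent + raised_cosine(tt,
                                         times_all[own_pulses$peak_frame[i]],
                                         own_pulses$amplitude[i],
                                         own_pulses$duration_min[i])
      }
      nz <- unlist(noise[path])
      ratio <- pmax(latent + nz, 1e-6)
      xx <- rep(NA_real_, e); yy <- rep(NA_real_, e)
      for (p in path) {
        rng <- which(present[seq_len(e), p])
        xx[rng] <- X[rng, p]; yy[rng] <- Y[rng, p]
      }
      div_frames <- seg_end[path[seg_fate[path] == "division"]]
      traces[[k]] <- data.frame(
        cell_id = id,
        parent_id = seg_parent[id],
        frame = frames,
        time_min = tt,
        ratio = ratio,
        x_px = xx,
        y_px = yy,
        expression = seg_expr[id],
        divided_this_frame = frames %in% div_frames,
        died_this_frame = seg_fate[id] == "death" & frames == e)
    }
    traces <- do.call(rbind, traces)
    rownames(traces) <- NULL

    lineage <- if (any(seg_fate == "division")) {
      parents <- which(seg_fate == "division")
      do.call(rbind, lapply(parents, function(p) {
        data.frame(parent_id = p,
                   child_id = which(seg_parent == p),
                   division_frame = seg_end[p])
      }))
    } else {
      data.frame(parent_id = integer(0), child_id = integer(0),
                 division_frame = integer(0))
    }
    death_events <- data.frame(
      cell_id = death_ids,
      death_frame = seg_end[death_ids])
    low_ids <- terminal[seg_expr[terminal] <= el$low_level]
    truth <- structure(list(pulses = pulses,
                            death_events = death_events,
                            lineage = lineage,
                            neighbors = true_neighbors,
                            segments = data.frame(cell_id = seq_len(n_seg),
                                                  parent_id = seg_parent,
                                                  birth_frame = seg_birth,
                                                  end_frame = seg_end,
                                                  fate = seg_fate,
                                                  expression = seg_expr),
                            low_expression_ids = low_ids,
                            config = cfg),
                       class = "ktr_truth")
    list(traces = traces, truth = truth)
  })
}

# ---- dissociation decay traces ---------------------------------------------

#' Configuration for exponential dissociation decay traces
#'
#' Defaults emulate adapter dissociation from condensates after kinase
#' inhibition: half-life 17 min, a plateau above zero (condensates do not
#' dissolve completely), 5-min sampling over 90 min.
#'
#' @param n_traces Number of traces.
#' @param t_half_min Half-life, minutes (> 0).
#' @param amplitude Decaying amplitude at `t = 0`.
#' @param offset Plateau (>= 0).
#' @param frame_interval_min Sampling interval, minutes (default 5).
#' @param duration_min Trace duration, minutes.
#' @param noise_sd SD of additive Gaussian noise (clipped at 0).
#' @param seed Integer seed.
#' @return A list of class `decay_sim_config`.
#' @export
decay_sim_config <- function(n_traces = 20, t_half_min = 17,
                             amplitude = 1, offset = 0.2,
                             frame_interval_min = 5, duration_min = 90,
                             noise_sd = 0.05, seed = 1) {
  check_scalar(n_traces, "n_traces", 1, integer = TRUE)
  check_scalar(t_half_min, "t_half_min", 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", 0, strict_lower = TRUE)
  check_scalar(offset, "offset", 0)
  check_scalar(frame_interval_min, "frame_interval_min", 0,
               strict_lower = TRUE)
  check_scalar(duration_min, "duration_min", frame_interval_min * 3)
  check_scalar(noise_sd, "noise_sd", 0)
  structure(as.list(environment()), class = "decay_sim_config")
}

#' Simulate dissociation decay traces
#'
#' Each trace is `offset + amplitude * 2^(-t / t_half_min)` plus Gaussian
#' noise, clipped at 0, sampled at the configured interval.
#'
#' @param cfg A [decay_sim_config()].
#' @return Tidy data frame: `trace_id`, `time_min`, `intensity`.
#' @export
simulate_decay_traces <- function(cfg) {
  stopifnot(inherits(cfg, "decay_sim_config"))
  with_seed(cfg$seed, {
    tt <- seq(0, cfg$duration_min, by = cfg$frame_interval_min)
    ideal <- cfg$offset + cfg$amplitude * 2^(-tt / cfg$t_half_min)
    out <- lapply(seq_len(cfg$n_traces), function(i) {
      y <- ideal
      if (cfg$noise_sd > 0) {
        y <- y + stats::rnorm(length(tt), 0, cfg$noise_sd)
      }
      data.frame(trace_id = i, time_min = tt, intensity = pmax(y, 0))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
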