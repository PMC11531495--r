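# Pulse calling: QC, prominence peaks, division exclusion, deduplication.

make_bump_trace <- function(n = 100, peaks = integer(0), amp = 0.6,
                            dur_min = 15, baseline = 1, interval = 5) {
  t <- (seq_len(n) - 1) * interval
  x <- rep(baseline, n)
  for (p in peaks) {
    x <- x + punctapulse:::raised_cosine(t, (p - 1) * interval, amp, dur_min)
  }
  x
}

test_that("expression QC removes exactly the low expressors", {
  tr <- data.frame(cell_id = rep(1:4, each = 3), frame = rep(1:3, 4),
                   expression = rep(c(500, 40, 900, 10), each = 3))
  qc <- qc_filter(tr, 100)
  expect_setequal(qc$removed_ids, c(2, 4))
  expect_setequal(unique(qc$traces$cell_id), c(1, 3))
  expect_equal(qc$log$n_removed, 2)

  all_in <- qc_filter(tr, 0)
  expect_equal(nrow(all_in$traces), nrow(tr))
  expect_warning(qc_filter(tr, Inf), "every trace")
})

test_that("QC on a synthetic dataset removes exactly the labeled cells", {
  sim <- simulate_ktr_dataset(ktr_sim_config(n_cells = 60, seed = 21))
  qc <- qc_filter(sim$traces, 100)
  expect_setequal(qc$removed_ids, sim$truth$low_expression_ids)
})

test_that("monotone traces yield no pulses and short traces error", {
  expect_equal(nrow(detect_pulses(seq(1, 2, length.out = 50))), 0)
  expect_error(detect_pulses(c(1, 2)), "short")
  expect_error(detect_pulses(1:10, frames = c(1:9, 20)), "non-uniform")
})

test_that("a single bump is called once, at its apex", {
  x <- make_bump_trace(peaks = 40, amp = 0.6)
  p <- detect_pulses(x, pulse_params(min_prominence = 0.3))
  expect_equal(nrow(p), 1)
  expect_equal(p$peak_frame, 40)
  expect_equal(p$prominence, 0.6, tolerance = 1e-9)
  expect_equal(p$excluded_reason, "none")
})

test_that("bumps near division are detected but excluded", {
  x <- make_bump_trace(peaks = 55, amp = 0.6)
  p <- detect_pulses(x, pulse_params(min_prominence = 0.3),
                     division_frames = 60)
  expect_equal(nrow(p), 1)
  expect_equal(p$excluded_reason, "division_proximal")
  # a bump exactly at the division frame or 10+ frames before is retained
  p2 <- detect_pulses(make_bump_trace(peaks = 45, amp = 0.6),
                      pulse_params(min_prominence = 0.3),
                      division_frames = 60)
  expect_equal(p2$excluded_reason, "none")
})

test_that("pulse detector agrees with the brute-force prominence oracle", {
  set.seed(31)
  for (i in 1:30) {
    x <- cumsum(rnorm(60, 0, 0.3))
    x <- x - min(x) + 1
    want <- oracle_peaks(x)
    got <- detect_pulses(x, pulse_params(min_prominence = 1e-9,
                                         min_peak_distance_frames = 0))
    expect_equal(got$peak_frame, want$peak)
    expect_equal(got$prominence, want$prominence)
  }
})

test_that("pulse calls are shift-invariant and prominences scale", {
  x <- make_bump_trace(peaks = c(20, 60, 85), amp = 0.5)
  set.seed(5)
  x <- x + rnorm(length(x), 0, 0.03)
  params <- pulse_params(min_prominence = 0.25)
  base <- detect_pulses(x, params)
  shifted <- detect_pulses(x + 3.2, params)
  expect_equal(base$peak_frame, shifted$peak_frame)
  expect_equal(base$prominence, shifted$prominence)
  scaled <- detect_pulses(3 * x, pulse_params(min_prominence = 0.75))
  expect_equal(scaled$peak_frame, base$peak_frame)
  expect_equal(scaled$prominence, 3 * base$prominence, tolerance = 1e-9)
})

test_that("no retained pulse ever falls within 10 frames before division", {
  for (seed in c(2, 12)) {
    sim <- simulate_ktr_dataset(ktr_sim_config(n_cells = 60,
                                               division_rate = 0.08,
                                               seed = seed))
    pulses <- detect_pulses_all(sim$traces, pulse_params())
    retained <- pulses[pulses$excluded_reason == "none", ]
    divs <- sim$traces[sim$traces$divided_this_frame,
                       c("cell_id", "frame")]
    for (j in seq_len(nrow(divs))) {
      same <- retained[retained$cell_id == divs$cell_id[j], ]
      bad <- same$peak_frame >= divs$frame[j] - 10 &
        same$peak_frame < divs$frame[j]
      expect_false(any(bad))
    }
  }
})

test_that("lineage deduplication counts parent pulses once", {
  # hand-built lineage: parent 1 divides at frame 50 into 2 and 3; two
  # bumps in the shared history, one in each child's own segment
  shared <- make_bump_trace(n = 50, peaks = c(15, 30), amp = 0.6)
  mk_child <- function(id, own_peak) {
    own <- make_bump_trace(n = 50, peaks = own_peak - 50, amp = 0.6)
    data.frame(cell_id = id, parent_id = 1L, frame = 1:100,
               time_min = (0:99) * 5, ratio = c(shared, own),
               x_px = 0, y_px = 0, expression = 1000,
               divided_this_frame = (1:100) == 50,
               died_this_frame = FALSE)
  }
  traces <- rbind(mk_child(2L, 70), mk_child(3L, 90))
  lineage <- data.frame(parent_id = 1L, child_id = c(2L, 3L),
                        division_frame = 50L)
  res <- pulses_per_cell(traces, pulse_params(min_prominence = 0.3),
                         lineage = lineage)
  counts <- setNames(res$per_cell$n_pulses, res$per_cell$cell_id)
  expect_equal(counts[["1"]], 2)  # shared pulses attributed to the parent
  expect_equal(counts[["2"]], 1)
  expect_equal(counts[["3"]], 1)
  expect_equal(sum(res$per_cell$n_pulses), 4)  # 2+1+1, not 2*2+1+1
  # without the lineage map the shared pulses double-count
  res_nolin <- pulses_per_cell(traces, pulse_params(min_prominence = 0.3))
  expect_equal(sum(res_nolin$per_cell$n_pulses), 6)
})

test_that("fraction pulsing carries a Wilson interval", {
  sim <- simulate_ktr_dataset(ktr_sim_config(n_cells = 40, seed = 3))
  res <- pulses_per_cell(sim$traces, pulse_params(),
                         lineage = sim$truth$lineage)
  expect_equal(res$fraction_pulsing, res$n_pulsing / res$n_cells_qc)
  expect_equal(res$fraction_ci,
               oracle_wilson(res$n_pulsing, res$n_cells_qc),
               tolerance = 1e-12)
})

test_that("traces are truncated at death before detection", {
  # bump after the death frame must not be called
  x <- make_bump_trace(n = 80, peaks = 70, amp = 0.8)
  tr <- data.frame(cell_id = 1L, frame = 1:80, time_min = (0:79) * 5,
                   ratio = x, x_px = 0, y_px = 0, expression = 1000,
                   divided_this_frame = FALSE,
                   died_this_frame = (1:80) == 60)
  p <- detect_pulses_all(tr, pulse_params(min_prominence = 0.3))
  expect_equal(nrow(p), 0)
})
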