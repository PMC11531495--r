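# Bootstrap median comparison, Wilson intervals, and dissociation
# half-life fitting.

#' One-sided bootstrap test for a difference of medians
#'
#' Resamples each group with replacement `n_boot` times and computes the
#' statistic `median(a*) - median(b*)` for each resample. The one-sided
#' p-value is the fraction of bootstrap statistics on the null side of 0,
#' with a +1 continuity correction: for `alternative = "greater"`
#' (median of `a` exceeds median of `b`),
#' `p = (1 + #[boot <= 0]) / (n_boot + 1)`.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`
#'   (twice the smaller one-sided p, capped at 1).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A list of class `bootstrap_result`: `observed_stat`, `p_value`,
#'   `quartiles` (25/50/75% of the bootstrap distribution), `n_boot`,
#'   `alternative`, `seed`.
#' @examples
#' x <- c(1.2, 0.8, 1.5, 1.1, 0.9)
#' bootstrap_median_test(x + 1, x, alternative = "greater", seed = 1)
#' @export
bootstrap_median_test <- function(a, b, n_boot = 1000,
                                  alternative = c("greater", "less",
                                                  "two.sided"),
                                  seed = 1) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples must have at least 2 observations", call. = FALSE)
  }
  check_scalar(n_boot, "n_boot", 1, integer = TRUE)
  observed <- stats::median(a) - stats::median(b)
  boot <- with_seed(seed, {
    na <- length(a); nb <- length(b)
    am <- matrix(sample(a, na * n_boot, replace = TRUE), nrow = n_boot)
    bm <- matrix(sample(b, nb * n_boot, replace = TRUE), nrow = n_boot)
    apply(am, 1, stats::median) - apply(bm, 1, stats::median)
  })
  p_greater <- (1 + sum(boot <= 0)) / (n_boot + 1)
  p_less <- (1 + sum(boot >= 0)) / (n_boot + 1)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(observed_stat = observed,
                 p_value = p,
                 quartiles = stats::quantile(boot, c(0.25, 0.5, 0.75),
                                             names = FALSE),
                 n_boot = as.integer(n_boot),
                 alternative = alternative,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> median difference = %.4g, one-sided p = %.4g (%s, %d resamples)\n",
    x$observed_stat, x$p_value, x$alternative, x$n_boot))
  cat(sprintf("  bootstrap quartiles: %.4g / %.4g / %.4g\n",
              x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  invisible(x)
}

#' Wilson score 95% confidence interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
fraction_ci <- function(k, n, conf_level = 0.95) {
  check_scalar(n, "n", 1, integer = TRUE)
  check_scalar(k, "k", 0, upper = n, integer = TRUE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Fit an exponential dissociation curve and report the half-life
#'
#' Fits `I(t) = offset + amplitude * 2^(-t / t_half)` by nonlinear least
#' squares to the mean (across traces) normalized intensity at each time
#' point. The free offset allows for incomplete dissociation: condensates
#' need not dissolve fully, so the adapter signal may plateau above zero.
#' The half-life standard error is estimated by bootstrap over traces.
#'
#' @param traces Data frame with columns `trace_id`, `time_min`,
#'   `intensity` (>= 4 distinct time points).
#' @param n_boot Bootstrap resamples over traces for the half-life SE
#'   (default 200; 0 disables).
#' @param seed Seed for the bootstrap.
#' @return A list of class `half_life_fit`: `success`, `t_half_min`,
#'   `t_half_se_min`, `rate_k` (= `log(2) / t_half_min`, 1/min),
#'   `amplitude`, `offset`, `rmse`, `n_traces`, and `reason` when the fit
#'   failed.
#' @export
fit_dissociation <- function(traces, n_boot = 200, seed = 1) {
  stopifnot(is.data.frame(traces),
            all(c("trace_id", "time_min", "intensity") %in% names(traces)))
  if (length(unique(traces$time_min)) < 4) {
    stop("need at least 4 distinct time points", call. = FALSE)
  }
  if (any(traces$intensity < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  fit_mean <- function(tr) {
    m <- tapply(tr$intensity, tr$time_min, mean)
    tt <- as.numeric(names(m))
    yy <- as.numeric(m)
    rng <- max(yy) - min(yy)
    if (rng <= 0) return(NULL)
    start <- list(offset = min(yy), amplitude = rng,
                  t_half = max(diff(range(tt)) / 4, 1))
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ offset + amplitude * 2^(-tt / t_half),
                        start = start,
                        lower = c(offset = 0, amplitude = 1e-12,
                                  t_half = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    # reject non-decaying data: the fitted decay must explain real signal
    if (cf[["amplitude"]] <= 0 || cf[["t_half"]] <= 0) return(NULL)
    list(coef = cf, rmse = sqrt(mean(stats::resid(fit)^2)))
  }
  main <- fit_mean(traces)
  ids <- unique(traces$trace_id)
  if (is.null(main)) {
    return(structure(list(success = FALSE,
                          reason = "no exponential decay could be fitted",
                          n_traces = length(ids)),
                     class = "half_life_fit"))
  }
  # a decay time much longer than the observation window means the data
  # do not constrain the fit (e.g. near-constant traces)
  span <- diff(range(traces$time_min))
  if (main$coef[["t_half"]] > 10 * span) {
    return(structure(list(success = FALSE,
                          reason = "no decay within the observation window",
                          n_traces = length(ids)),
                     class = "half_life_fit"))
  }
  se <- NA_real_
  if (n_boot > 0 && length(ids) >= 2) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        pick <- sample(ids, replace = TRUE)
        res <- fit_mean(do.call(rbind, lapply(pick, function(id) {
          traces[traces$trace_id == id, , drop = FALSE]
        })))
        if (is.null(res)) NA_real_ else res$coef[["t_half"]]
      }, numeric(1))
    })
    se <- stats::sd(boot, na.rm = TRUE)
  }
  structure(list(success = TRUE,
                 t_half_min = main$coef[["t_half"]],
                 t_half_se_min = se,
                 rate_k = log(2) / main$coef[["t_half"]],
                 amplitude = main$coef[["amplitude"]],
                 offset = main$coef[["offset"]],
                 rmse = main$rmse,
                 n_traces = length(ids)),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  if (!x$success) {
    cat(sprintf("<half_life_fit> FAILED: %s (n_traces = %d)\n",
                x$reason, x$n_traces))
  } else {
    cat(sprintf(
      "<half_life_fit> t1/2 = %.2f +/- %.2f min (k = %.4f /min, offset = %.3g, amplitude = %.3g, rmse = %.3g, n = %d traces)\n",
      x$t_half_min, x$t_half_se_min, x$rate_k, x$offset, x$amplitude,
      x$rmse, x$n_traces))
  }
  invisible(x)
}
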