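# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single integer seed makes a whole run reproducible
#' without clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# scalar check with informative error
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %s", name, upper), call. = FALSE)
  }
  invisible(x)
}

# linear index <-> (row, col) for an nr x nc matrix
idx_to_rc <- function(idx, nr) {
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

rc_to_idx <- function(row, col, nr) {
  (col - 1L) * nr + row
}

# neighbor offsets as (drow, dcol) rows
conn_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
  } else {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
}

# disk mask helper: logical matrix of pixels within `radius` of (cr, cc),
# Euclidean distance on pixel centers
paint_disk <- function(nr, nc, cr, cc, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  ccm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - cr)^2 + (ccm - cc)^2 <= radius^2
}
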