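# Internal helpers shared across modules.

# error helper with package-classed conditions
abort_mono <- function(msg, class, ...) {
  rlang::abort(msg, class = c(paste0("monolayr_error_", class), "monolayr_error"), ...)
}

#' Round to nearest integer, ties away from zero
#'
#' Unlike [round()], which rounds half to even, headline numbers in monolayer
#' comparison tables are conventionally rounded with ties going away from zero
#' (2.5 -> 3, -2.5 -> -3).
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_away(c(4.8, 2.5, -2.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# runs of TRUE in a logical vector -> tibble(start, end) (inclusive indices)
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

# indices of local maxima with at least the given prominence.
# prominence of a peak: height above the higher of the two minima separating
# it from neighbouring higher terrain (endpoints count as terrain edges).
# Endpoints themselves are eligible as maxima.
local_maxima <- function(y, prominence = 0) {
  n <- length(y)
  if (n < 3L) {
    return(integer(0))
  }
  # candidate peaks: strictly higher than both neighbours (plateaus take the
  # first index of the plateau), plus the two endpoints
  dy <- diff(y)
  sgn <- sign(dy)
  # propagate zero slopes so flat tops are treated as one peak
  for (i in seq_along(sgn)) {
    if (sgn[i] == 0 && i > 1L) sgn[i] <- sgn[i - 1L]
  }
  interior <- which(diff(sgn) < 0) + 1L
  cand <- unique(c(1L, interior, n))
  keep <- vapply(cand, function(i) {
    h <- y[i]
    # walk left until higher point or edge, track min
    lmin <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      lmin <- min(lmin, y[j])
      j <- j - 1L
    }
    if (j < 1L && i > 1L) lmin <- min(lmin, min(y[seq_len(i - 1L)]))
    rmin <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      rmin <- min(rmin, y[j])
      j <- j + 1L
    }
    base <- max(
      if (i == 1L) -Inf else lmin,
      if (i == n) -Inf else rmin
    )
    # an endpoint peak's prominence is measured against its single flank
    if (i == 1L) base <- rmin
    if (i == n) base <- lmin
    (h - base) >= prominence
  }, logical(1))
  cand[keep]
}

# linear interpolation of y at x0 on an (x, y) curve; NA outside range
interp_at <- function(x, y, x0) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) {
    return(NA_real_)
  }
  x <- x[ok]
  y <- y[ok]
  if (x0 < min(x) || x0 > max(x)) {
    return(NA_real_)
  }
  stats::approx(x, y, xout = x0, ties = mean)$y
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed_restore <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}
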