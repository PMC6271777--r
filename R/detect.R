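# Phase-feature detectors: lift-off, collapse, LE-LC transition.

#' Detect the lift-off point of a compression isotherm
#'
#' The gas-phase baseline is the median pressure over the largest-area 10% of
#' samples, with a robust SD (MAD). Lift-off is the largest area at which the
#' smoothed pressure rises to `baseline + max(floor, 5 * robust SD)` and
#' stays above a hysteresis level (half the detection margin) for the rest of
#' the compression. Because the departure from baseline can be very gentle
#' for expanded films, the raw crossing is then refined: the early rise
#' (between 0.5 and 8 detection margins above baseline) is fitted with a
#' two-dimensional equation-of-state form \eqn{\pi = b/(A - \omega) - c} (the
#' hyperbolic shape shared by the Volmer and van der Waals-type 2D equations
#' of state for fluid films), profiled over the co-area, and the fitted curve
#' is solved at the detection level. A local quadratic fit is the fallback
#' when the hyperbola fit is degenerate.
#'
#' @param iso A smoothed isotherm tibble.
#' @param floor Minimum detection margin above baseline, mN/m.
#' @param baseline_frac Fraction of (largest-area) samples used as baseline.
#' @return A one-row tibble: `liftoff_area_A2` (NA if no lift-off is found),
#'   `baseline_mN_m`, `baseline_sd_mN_m`.
#' @export
detect_liftoff <- function(iso, floor = 0.5, baseline_frac = 0.1) {
  a <- iso$area_A2
  p <- iso$pressure_mN_m
  n <- length(p)
  nb <- max(1L, base::floor(baseline_frac * n))
  if (nb < 20L) {
    rlang::warn("Fewer than 20 baseline samples; lift-off baseline may be unreliable.")
  }
  w <- as.integer(iso_metadata(iso)$smoothing$window %||% 50)
  w2 <- min(as.integer(1.5 * w) + 1L, n)
  if (w2 %% 2L == 0L) w2 <- w2 - 1L
  q <- if (w2 > 1L) adjacent_average(p, w2, quiet = TRUE) else p

  base_p <- q[seq_len(nb)]
  baseline <- median(base_p)
  rsd <- mad(p[seq_len(nb)])
  margin <- max(floor, 5 * rsd)
  thr <- baseline + margin
  lo <- baseline + 0.5 * margin

  absent <- tibble(
    liftoff_area_A2 = NA_real_,
    baseline_mN_m = baseline, baseline_sd_mN_m = rsd
  )
  # suffix_ok[i]: pressure never falls back below the hysteresis level from i on
  suffix_ok <- rev(cumprod(rev(q >= lo))) > 0
  cand <- which(q >= thr & suffix_ok)
  if (length(cand) == 0L) {
    return(absent)
  }
  i0 <- cand[1L]
  est <- refine_liftoff_eos(a, p, q, i0, baseline, margin) %||%
    refine_liftoff_quadratic(a, q, i0, thr, margin, w2) %||%
    a[i0]
  tibble(
    liftoff_area_A2 = est,
    baseline_mN_m = baseline, baseline_sd_mN_m = rsd
  )
}

# refine the lift-off crossing by fitting pi = b/(A - w0) - c to the early
# rise (co-area w0 profiled out, (b, c) linear given w0) and solving the fit
# at the detection level; NULL when degenerate
refine_liftoff_eos <- function(a, p, q, i0, baseline, margin) {
  band <- which(q - baseline >= 0.5 * margin & q - baseline <= 8 * margin)
  if (length(band) < 30L) {
    return(NULL)
  }
  ab <- a[band]
  pb <- p[band]
  rss_w0 <- function(w0) {
    z <- 1 / (ab - w0)
    sum(lm(pb ~ z)$residuals^2)
  }
  w0_max <- min(ab) - 1
  cands <- seq(w0_max - 150, w0_max, length.out = 60)
  rs <- vapply(cands, rss_w0, numeric(1))
  i <- which.min(rs)
  o <- stats::optimize(
    rss_w0,
    interval = c(cands[max(1L, i - 2L)], min(cands[min(60L, i + 2L)], w0_max))
  )
  z <- 1 / (ab - o$minimum)
  f <- lm(pb ~ z)
  b <- coef(f)[2]
  cc <- baseline - coef(f)[1]
  if (!is.finite(b) || b <= 0 || !is.finite(cc) || margin + cc <= 0) {
    return(NULL)
  }
  ahat <- unname(o$minimum + b / (margin + cc))
  if (!is.finite(ahat) || abs(ahat - a[i0]) > 30) NULL else ahat
}

# fallback: local quadratic fit around the crossing; the compressed arm is
# capped one detection margin above the level so the fit sees only the early
# rise, not the much steeper condensed branch
refine_liftoff_quadratic <- function(a, q, i0, thr, margin, w2) {
  n <- length(q)
  hw <- 2L * w2
  idx <- max(1L, i0 - hw):min(n, i0 + hw)
  idx <- idx[idx <= i0 | q[idx] <= thr + margin]
  if (length(idx) < 9L) {
    return(NULL)
  }
  x <- a[idx] - a[i0]
  cf <- coef(lm(q[idx] ~ x + I(x^2)))
  roots <- tryCatch(
    {
      r <- polyroot(c(cf[1] - thr, cf[2], cf[3]))
      Re(r[abs(Im(r)) < 1e-8])
    },
    error = function(e) numeric(0)
  )
  span <- max(x) - min(x)
  roots <- roots[abs(roots) <= span]
  if (length(roots) > 0L) {
    return(a[i0] + roots[which.min(abs(roots))])
  }
  cf1 <- coef(lm(q[idx] ~ x))
  if (is.finite(cf1[2]) && cf1[2] < 0) {
    r1 <- (thr - cf1[1]) / cf1[2]
    if (abs(r1) <= span) {
      return(unname(a[i0] + r1))
    }
  }
  NULL
}

#' Detect the collapse point of a compression isotherm
#'
#' Collapse is read as the first local maximum of the pressure along
#' compression with at least the given prominence. Peak location and height
#' are taken from a lightly smoothed copy of the trace (adjacent averaging at
#' roughly one fifth of the analysis window): collapse is a high-amplitude
#' feature, and the heavy smoothing appropriate for differentiation would
#' bias the attained maximum low. If the pressure is monotone to the end of
#' the run, a collapse shoulder is instead located by an exhaustive
#' two-segment piecewise-linear fit (least squares, index space) over the
#' final third of the trace, accepted only when the second segment's implied
#' modulus falls below 25% of the maximum modulus; otherwise the run is
#' deemed to have ended before collapse and the feature is absent.
#'
#' @param iso An isotherm tibble (raw or smoothed).
#' @param curve Optional [compute_compressibility()] curve, used for the
#'   LC-exists precondition and the kink acceptance test.
#' @param prominence Minimum peak prominence, mN/m.
#' @param window Light-smoothing window in points; default
#'   `max(5, analysis window / 5)`, made odd.
#' @return A one-row tibble: `collapse_pressure_mN_m`, `collapse_area_A2`
#'   (both NA when collapse is absent).
#' @export
detect_collapse <- function(iso, curve = NULL, prominence = 0.5, window = NULL) {
  a <- iso$area_A2
  p <- iso$pressure_mN_m
  n <- length(p)
  absent <- tibble(collapse_pressure_mN_m = NA_real_, collapse_area_A2 = NA_real_)

  max_mod <- if (!is.null(curve)) max(curve$modulus_mN_m, na.rm = TRUE) else NA_real_
  if (!is.null(curve) && is.finite(max_mod) && max_mod <= 30) {
    return(absent) # no condensed region reached
  }

  w <- window %||% max(5L, round((iso_metadata(iso)$smoothing$window %||% 50) / 5))
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  ps <- if (w > 1L && w <= n) adjacent_average(p, w, quiet = TRUE) else p

  peaks <- local_maxima(ps, prominence = prominence)
  peaks <- peaks[peaks > 1L & peaks < n] # a peak needs an observed decline
  if (length(peaks) > 0L) {
    i <- peaks[1L]
    return(tibble(collapse_pressure_mN_m = ps[i], collapse_area_A2 = a[i]))
  }

  # monotone to the end: look for a kink in the final third
  lo <- base::floor(2 * n / 3)
  idx <- lo:n
  y <- ps[idx]
  x <- seq_along(y)
  m <- length(x)
  if (m < 10L) {
    return(absent)
  }
  rss_at <- function(b) {
    f1 <- lm(y[1:b] ~ x[1:b])
    f2 <- lm(y[b:m] ~ x[b:m])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }
  step <- max(1L, m %/% 150L)
  brks <- seq(5L, m - 4L, by = step)
  b <- brks[which.min(vapply(brks, rss_at, numeric(1)))]
  if (step > 1L) { # refine around the coarse optimum
    fine <- max(5L, b - step):min(m - 4L, b + step)
    b <- fine[which.min(vapply(fine, rss_at, numeric(1)))]
  }
  xb <- x[b:m]
  f2 <- lm(y[b:m] ~ xb)
  gi <- idx[b]
  da <- (a[n] - a[1]) / (n - 1) # uniform grid step (negative)
  mod2 <- -a[gi] * coef(f2)[2] / da
  if (is.finite(max_mod) && is.finite(mod2) && mod2 < 0.25 * max_mod) {
    # the post-kink line evaluated at the kink: immune to the corner-rounding
    # of the smoothed trace
    p_kink <- unname(coef(f2)[1] + coef(f2)[2] * x[b])
    tibble(collapse_pressure_mN_m = p_kink, collapse_area_A2 = a[gi])
  } else {
    absent
  }
}

#' Detect the LE-LC transition plateau on a compressibility curve
#'
#' The two-dimensional phase coexistence region appears as a stretch of low
#' elasticity between two shoulders of the \eqn{C_s^{-1}}–\eqn{\pi} curve.
#' The detector finds local maxima of the modulus with at least
#' `max_prominence`, and between each consecutive pair takes the longest
#' contiguous run with modulus below `threshold`; the winning run (largest
#' pressure extent, at least `min_extent`) gives the onset and end pressures.
#' Absence (no such interval) is a valid result, not an error.
#'
#' @param curve A [compute_compressibility()] curve.
#' @param threshold Coexistence modulus threshold, mN/m.
#' @param max_prominence Minimum prominence for the flanking maxima, mN/m.
#' @param min_extent Minimum pressure extent of the interval, mN/m.
#' @param smooth_window Light modulus smoothing window (see
#'   [modulus_summary()]).
#' @return A one-row tibble: `transition_onset_mN_m`, `transition_end_mN_m`
#'   (NA when absent).
#' @export
detect_transition <- function(curve, threshold = 50, max_prominence = 10,
                              min_extent = 1, smooth_window = NULL) {
  p <- curve$pressure_mN_m
  m <- smoothed_modulus(curve, smooth_window)
  absent <- tibble(transition_onset_mN_m = NA_real_, transition_end_mN_m = NA_real_)
  # the coexistence search applies to the compression leg only
  cut <- which.max(p)
  p <- p[seq_len(cut)]
  m <- m[seq_len(cut)]
  if (length(p) < 5L || diff(range(p)) < 10) {
    return(absent)
  }
  peaks <- local_maxima(m, prominence = max_prominence)
  if (length(peaks) < 2L) {
    return(absent)
  }
  best <- NULL
  for (k in seq_len(length(peaks) - 1L)) {
    i <- peaks[k]
    j <- peaks[k + 1L]
    if (j - i < 3L) next
    inner <- (i + 1L):(j - 1L)
    runs <- logical_runs(m[inner] < threshold)
    if (nrow(runs) == 0L) next
    runs <- mutate(runs,
      start = inner[start], end = inner[end],
      extent = abs(p[end] - p[start])
    )
    runs <- runs[which.max(runs$extent), ]
    if (is.null(best) || runs$extent > best$extent) best <- runs
  }
  if (is.null(best) || best$extent < min_extent) {
    return(absent)
  }
  tibble(
    transition_onset_mN_m = min(p[best$start], p[best$end]),
    transition_end_mN_m = max(p[best$start], p[best$end])
  )
}
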