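# Adjacent-averaging smoothing, the preprocessing step applied to raw
# pressure/potential traces before differentiation.

#' Adjacent-averaging (centered moving mean) smoothing
#'
#' Each output point is the unweighted mean of the input inside a centered
#' window. Near the edges the window shrinks symmetrically to the largest
#' centered window that fits, so the output has the same length as the input
#' and no phase lag is introduced. An even `window` is realized as the odd
#' window `window + 1` (a symmetric centered window needs odd length); the
#' substitution is signalled with a message once per call.
#'
#' @param signal Numeric vector.
#' @param window Window size in points (>= 1, <= `length(signal)`).
#' @param quiet Suppress the even-window substitution message.
#' @return Smoothed numeric vector, same length as `signal`.
#' @examples
#' adjacent_average(c(0, 0, 3, 0, 0), 3)
#' @export
adjacent_average <- function(signal, window, quiet = FALSE) {
  n <- length(signal)
  if (window < 1) {
    abort_mono("window must be >= 1.", "config")
  }
  if (window > n) {
    abort_mono(
      paste0("window (", window, ") exceeds signal length (", n, ")."),
      "config"
    )
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    if (!quiet) {
      rlang::inform(paste0(
        "Even window ", window, " realized as centered window ", window + 1L, "."
      ))
    }
    window <- min(window + 1L, n)
    if (window %% 2L == 0L) window <- window - 1L # n even and window == n
  }
  if (window == 1L) {
    return(signal)
  }
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, signal))
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i) # symmetric shrink at the edges
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}

#' Smooth an isotherm's signals before differentiation
#'
#' Applies [adjacent_average()] to the pressure and/or potential columns as a
#' function of sample index (the area grid is untouched), and records the
#' configuration in the isotherm metadata for provenance. Smoothing an
#' already-smoothed isotherm is permitted but flagged in the provenance
#' record.
#'
#' @param iso An isotherm tibble.
#' @param window Window size in points (published choice: 50).
#' @param apply_to `"pressure"`, `"potential"` or `"both"`.
#' @return The smoothed isotherm tibble.
#' @export
smooth_isotherm <- function(iso, window = 50, apply_to = c("both", "pressure", "potential")) {
  apply_to <- match.arg(apply_to)
  out <- iso
  if (apply_to %in% c("both", "pressure")) {
    out$pressure_mN_m <- adjacent_average(iso$pressure_mN_m, window, quiet = TRUE)
  }
  if (apply_to %in% c("both", "potential") && "potential_mV" %in% names(iso)) {
    out$potential_mV <- adjacent_average(iso$potential_mV, window, quiet = TRUE)
  }
  md <- iso_metadata(iso)
  prior <- md$smoothing
  md$smoothing <- list(
    window = window, apply_to = apply_to,
    repeated = !is.null(prior)
  )
  if (!is.null(prior)) {
    rlang::inform("Isotherm was already smoothed; smoothing again (flagged in provenance).")
  }
  iso_metadata(out) <- md
  out
}
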