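# Per-curve feature summaries and the full extraction pipeline.

.phase_bands <- c(gas_transition = 12.5, liquid_expanded = 100, liquid_condensed = 250)

# lightly smoothed modulus for extremum/interval readouts; window defaults to
# a fifth of the analysis window recorded in the curve provenance
smoothed_modulus <- function(curve, smooth_window = NULL) {
  m <- curve$modulus_mN_m
  w <- smooth_window %||%
    max(5L, round((attr(curve, "metadata")$smoothing$window %||% 50) / 5))
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L && w < length(m)) adjacent_average(m, w, quiet = TRUE) else m
}

phase_label <- function(modulus) {
  dplyr::case_when(
    is.na(modulus) ~ NA_character_,
    modulus < .phase_bands[["gas_transition"]] ~ "gaseous/transition",
    modulus < .phase_bands[["liquid_expanded"]] ~ "liquid-expanded",
    modulus < .phase_bands[["liquid_condensed"]] ~ "liquid-condensed",
    TRUE ~ "solid"
  )
}

#' Summaries of the compressibility-modulus curve
#'
#' The maximal modulus (over the pre-collapse part of the curve when a
#' collapse pressure is supplied), the pressure at which it occurs, the
#' modulus linearly interpolated at a reference pressure (30 mN/m by default,
#' the packing pressure of biological membranes; 35 is the conventional
#' alternative), and a phase label from standard monolayer elasticity bands
#' (< 12.5 gaseous/transition, 12.5–100 liquid-expanded, 100–250
#' liquid-condensed, > 250 solid).
#'
#' @param curve A [compute_compressibility()] curve.
#' @param reference_pressure Reference surface pressure, mN/m.
#' @param collapse_pressure Optional detected collapse pressure; the maximum
#'   is then taken over pressures below it, and the post-collapse tail (which
#'   re-visits lower pressures) is excluded.
#' @param smooth_window Light adjacent-average window applied to the modulus
#'   before the readouts; the point-to-point variance of a double difference
#'   is high-frequency noise that survives the trace smoothing, and would
#'   otherwise bias the maximum upward. Default: a fifth of the analysis
#'   window recorded in the curve's provenance.
#' @return A one-row tibble: `max_modulus_mN_m`, `pressure_at_max_modulus_mN_m`,
#'   `modulus_at_reference_mN_m` (NA if the curve does not reach the
#'   reference), `phase_at_reference`.
#' @export
modulus_summary <- function(curve, reference_pressure = 30, collapse_pressure = NULL,
                            smooth_window = NULL) {
  p <- curve$pressure_mN_m
  m <- smoothed_modulus(curve, smooth_window)
  if (length(p) == 0L) {
    abort_mono("Empty compressibility curve.", "insufficient_data")
  }
  # compression is analysed up to the attained pressure maximum only
  keep <- seq_along(p) <= which.max(p)
  if (!is.null(collapse_pressure) && is.finite(collapse_pressure)) {
    keep <- keep & p < collapse_pressure
  }
  if (!any(keep)) keep <- rep(TRUE, length(p))
  i <- which(keep)[which.max(m[keep])]
  m_ref <- interp_at(p[keep], m[keep], reference_pressure)
  if (is.na(m_ref)) {
    rlang::inform(paste0(
      "Curve does not reach the reference pressure (", reference_pressure,
      " mN/m); modulus_at_reference is absent."
    ))
  }
  tibble(
    max_modulus_mN_m = m[i],
    pressure_at_max_modulus_mN_m = p[i],
    modulus_at_reference_mN_m = m_ref,
    phase_at_reference = phase_label(m_ref)
  )
}

#' Extremal surface potential in a comparison window
#'
#' Maximum smoothed surface potential within an area window (for
#' negative-running potentials, the extremum of largest magnitude is returned
#' with its sign), together with the area at which it occurs. The default
#' windows are the condensed-state comparison ranges for the three lipids
#' (DPPE 30–40, DPPG 40–80, cardiolipin 50–100 Å²/molecule); other lipids
#' default to the full recorded range.
#'
#' @param iso A smoothed isotherm tibble with a `potential_mV` column.
#' @param window Optional numeric length-2 area window (Å²/molecule).
#' @return A one-row tibble: `max_potential_mV`, `area_at_max_potential_A2`
#'   (NA when the potential is absent or the window has no data).
#' @export
max_surface_potential <- function(iso, window = NULL) {
  absent <- tibble(max_potential_mV = NA_real_, area_at_max_potential_A2 = NA_real_)
  if (!"potential_mV" %in% names(iso)) {
    return(absent)
  }
  window <- window %||% potential_window(iso_metadata(iso)$lipid %||% "") %||%
    range(iso$area_A2)
  sel <- which(iso$area_A2 >= window[1] & iso$area_A2 <= window[2])
  if (length(sel) == 0L) {
    rlang::warn("Potential window contains no samples; feature absent.")
    return(absent)
  }
  psi <- iso$potential_mV[sel]
  i <- sel[which.max(abs(psi))]
  tibble(
    max_potential_mV = iso$potential_mV[i],
    area_at_max_potential_A2 = iso$area_A2[i]
  )
}

#' Apparent dipole-moment profile from the surface potential
#'
#' Under the Helmholtz parallel-plate model the surface potential of an
#' uncharged film is \eqn{\Delta\psi = \mu_\perp / (\varepsilon_0 A)}; the
#' apparent normal dipole moment per molecule is therefore
#' \eqn{\mu_\perp = \varepsilon_0 A \Delta\psi}, which in customary units is
#' \eqn{\mu_\perp[\mathrm{mD}] = A[\mathrm{Å^2}]\,\Delta\psi[\mathrm{mV}] /
#' (12\pi)}.
#'
#' @param iso An isotherm tibble with a `potential_mV` column.
#' @return A tibble of class `dipole_profile` with columns `area_A2`,
#'   `dipole_mD`.
#' @export
dipole_moment_profile <- function(iso) {
  if (!"potential_mV" %in% names(iso)) {
    abort_mono("Isotherm has no surface-potential column.", "no_potential")
  }
  if (any(iso$area_A2 <= 0)) {
    abort_mono("Areas must be positive for the Helmholtz conversion.", "validation")
  }
  out <- tibble(
    area_A2 = iso$area_A2,
    dipole_mD = iso$area_A2 * iso$potential_mV / .helmholtz_denom
  )
  attr(out, "metadata") <- iso_metadata(iso)
  class(out) <- c("dipole_profile", class(out))
  out
}

#' Analysis configuration for feature extraction
#'
#' @param window Adjacent-averaging window in points (published choice: 50).
#' @param apply_to Signals to smooth (`"both"`, `"pressure"`, `"potential"`).
#' @param reference_pressure Reference pressure for [modulus_summary()], mN/m.
#' @param liftoff_pressure Gas-phase cutoff / lift-off detection floor, mN/m.
#' @param transition_threshold Coexistence modulus threshold, mN/m.
#' @param collapse_prominence Collapse peak prominence, mN/m.
#' @param potential_window Optional area window for [max_surface_potential()];
#'   `NULL` selects the per-lipid default.
#' @return A named list of class `feature_config`.
#' @export
feature_config <- function(window = 50,
                           apply_to = "both",
                           reference_pressure = 30,
                           liftoff_pressure = 0.5,
                           transition_threshold = 50,
                           collapse_prominence = 0.5,
                           potential_window = NULL) {
  structure(
    list(
      window = window, apply_to = apply_to,
      reference_pressure = reference_pressure,
      liftoff_pressure = liftoff_pressure,
      transition_threshold = transition_threshold,
      collapse_prominence = collapse_prominence,
      potential_window = potential_window
    ),
    class = "feature_config"
  )
}

#' Read a feature-extraction configuration from YAML
#'
#' Accepts a file with a top-level `smoothing: {window, apply_to}` block and
#' any other [feature_config()] fields at the top level.
#'
#' @param path Path to a YAML file.
#' @return A `feature_config` list.
#' @export
read_feature_config <- function(path) {
  if (!file.exists(path)) {
    abort_mono(paste0("No such file: ", path), "io")
  }
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), "smoothing")]
  if (!is.null(y$smoothing)) {
    args$window <- y$smoothing$window %||% 50
    args$apply_to <- y$smoothing$apply_to %||% "both"
  }
  do.call(feature_config, args)
}

#' Extract the full monolayer feature set from an isotherm
#'
#' Runs the pipeline smoothing -> compressibility -> detectors and assembles
#' the per-curve summary: lift-off area, LE-LC transition bounds, collapse
#' point, modulus maxima, modulus at the reference pressure with its phase
#' label, and the condensed-state surface-potential extremum. Absent features
#' are reported as NA; the result is deterministic given the input and
#' configuration.
#'
#' @param iso An isotherm tibble (raw; smoothing is applied here).
#' @param config A [feature_config()].
#' @return A one-row tibble of class `monolayer_features`.
#' @examples
#' p <- preset_spec("DPPE", "water", seed = 1)
#' iso <- generate_isotherm(p$spec, p$psi_spec, metadata = p$metadata)
#' extract_features(iso)
#' @export
extract_features <- function(iso, config = feature_config()) {
  md <- iso_metadata(iso)
  id <- tibble(
    lipid = md$lipid %||% NA_character_,
    subphase = md$subphase_additive %||% NA_character_
  )
  smoothed <- smooth_isotherm(iso, config$window, config$apply_to)
  lift <- detect_liftoff(smoothed, floor = config$liftoff_pressure)

  empty <- tibble(
    transition_onset_mN_m = NA_real_, transition_end_mN_m = NA_real_,
    collapse_pressure_mN_m = NA_real_, collapse_area_A2 = NA_real_,
    max_modulus_mN_m = NA_real_, pressure_at_max_modulus_mN_m = NA_real_,
    modulus_at_reference_mN_m = NA_real_, phase_at_reference = NA_character_
  )
  pot <- max_surface_potential(smoothed, config$potential_window)

  if (is.na(lift$liftoff_area_A2)) {
    out <- dplyr::bind_cols(
      id, tibble(liftoff_area_A2 = NA_real_), empty, pot
    )
  } else {
    curve <- compute_compressibility(smoothed, config$liftoff_pressure)
    coll <- detect_collapse(iso, curve,
      prominence = config$collapse_prominence,
      window = max(5L, round(config$window / 5))
    )
    trans <- detect_transition(curve, threshold = config$transition_threshold)
    summ <- modulus_summary(curve,
      reference_pressure = config$reference_pressure,
      collapse_pressure = coll$collapse_pressure_mN_m
    )
    out <- dplyr::bind_cols(
      id,
      tibble(liftoff_area_A2 = lift$liftoff_area_A2),
      trans, coll, summ, pot
    )
  }
  attr(out, "config") <- config
  class(out) <- c("monolayer_features", class(out))
  out
}
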