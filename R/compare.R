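# Feature tables across lipids/subphases and control-relative statistics.

.parameter_aliases <- c(
  liftoff = "liftoff_area_A2",
  liftoff_area = "liftoff_area_A2",
  collapse = "collapse_pressure_mN_m",
  collapse_pressure = "collapse_pressure_mN_m",
  max_modulus = "max_modulus_mN_m",
  modulus_at_reference = "modulus_at_reference_mN_m",
  surface_potential = "max_potential_mV",
  max_potential = "max_potential_mV",
  dipole_area = "reported_dipole_area_A2"
)

.feature_table_cols <- c(
  "lipid", "subphase", "liftoff_area_A2", "collapse_pressure_mN_m",
  "max_modulus_mN_m", "max_potential_mV", "reported_dipole_area_A2",
  "transition_onset_mN_m", "transition_end_mN_m", "collapse_area_A2",
  "pressure_at_max_modulus_mN_m", "modulus_at_reference_mN_m",
  "phase_at_reference", "area_at_max_potential_A2"
)

resolve_parameter <- function(parameter, cols) {
  col <- unname(.parameter_aliases[parameter])
  if (is.na(col)) col <- parameter
  if (!col %in% cols) {
    abort_mono(
      paste0(
        "Unknown parameter '", parameter, "'. Use a feature column or one of: ",
        paste(names(.parameter_aliases), collapse = ", "), "."
      ),
      "unknown_parameter"
    )
  }
  col
}

#' Assemble a feature table across lipids and subphases
#'
#' Binds per-curve feature rows (from [extract_features()]) into a summary
#' table keyed by (lipid, subphase), with the headline parameters (lift-off,
#' collapse pressure, maximal modulus, surface potential, reported
#' dipole-moment area) leading the column order. The reported dipole-moment
#' area is an experimental quantity with no computed counterpart here; supply
#' it via `dipole_areas` if available.
#'
#' @param features A data frame of feature rows, or a list of them.
#' @param dipole_areas Optional tibble with columns `lipid`, `subphase`,
#'   `dipole_area_A2` to populate the reported dipole-area column.
#' @return A tibble of class `feature_table`.
#' @export
build_feature_table <- function(features, dipole_areas = NULL) {
  tab <- if (is.data.frame(features)) as_tibble(features) else bind_rows(features)
  if (!all(c("lipid", "subphase") %in% names(tab))) {
    abort_mono("Feature rows must carry lipid and subphase metadata.", "aggregation")
  }
  dup <- tab |>
    dplyr::count(lipid, subphase) |>
    filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort_mono(
      paste0(
        "Duplicate (lipid, subphase) keys: ",
        paste(paste(dup$lipid, dup$subphase, sep = "/"), collapse = ", "), "."
      ),
      "aggregation"
    )
  }
  if (!is.null(dipole_areas)) {
    tab <- left_join(
      tab,
      rename(dipole_areas, reported_dipole_area_A2 = "dipole_area_A2"),
      by = c("lipid", "subphase")
    )
  }
  if (!"reported_dipole_area_A2" %in% names(tab)) {
    tab$reported_dipole_area_A2 <- NA_real_
  }
  cols <- c(
    intersect(.feature_table_cols, names(tab)),
    setdiff(names(tab), .feature_table_cols)
  )
  tab <- tab[, cols]
  class(tab) <- c("feature_table", setdiff(class(tab), "feature_table"))
  tab
}

#' Fold reduction of a parameter relative to control
#'
#' `control / treatment`, optionally rounded to the nearest integer with ties
#' away from zero (the convention behind headline statements such as a
#' "5-fold decrease").
#'
#' @param control,treatment Positive values.
#' @param rounding `"none"` or `"nearest_integer"`.
#' @return Dimensionless fold reduction.
#' @examples
#' fold_reduction(240, 50, "nearest_integer") # 5
#' @export
fold_reduction <- function(control, treatment, rounding = c("none", "nearest_integer")) {
  rounding <- match.arg(rounding)
  if (any(control <= 0) || any(treatment <= 0)) {
    abort_mono(
      "Fold reduction is undefined for nonpositive values.",
      "undefined_comparison"
    )
  }
  out <- control / treatment
  if (rounding == "nearest_integer") out <- round_half_away(out)
  out
}

#' Percent reduction of a parameter relative to control
#'
#' `100 * (control - treatment) / |control|`; positive values mean the
#' treatment lowered the parameter.
#'
#' @inheritParams fold_reduction
#' @return Percent change (positive = reduction).
#' @examples
#' percent_reduction(600, 300, "nearest_integer") # 50
#' @export
percent_reduction <- function(control, treatment, rounding = c("none", "nearest_integer")) {
  rounding <- match.arg(rounding)
  if (any(control == 0)) {
    abort_mono(
      "Percent reduction is undefined for a zero control value.",
      "undefined_comparison"
    )
  }
  out <- 100 * (control - treatment) / abs(control)
  if (rounding == "nearest_integer") out <- round_half_away(out)
  out
}

#' Compare every compound against the water control
#'
#' For one parameter, produces one row per (lipid, compound) with the control
#' value, treatment value, difference, percent change (positive = reduction)
#' and fold reduction. The fold reduction is reported as NA (absent, not an
#' error) when the two values do not share a sign or the treatment is zero —
#' a ratio across a sign change is meaningless. A per-lipid summary of the
#' minimum and maximum fold reduction is attached as
#' `attr(result, "fold_summary")`.
#'
#' @param table A [build_feature_table()] result (or any tibble with `lipid`,
#'   `subphase` and the parameter column).
#' @param parameter Parameter name: a feature column or an alias such as
#'   `"max_modulus"`, `"surface_potential"`, `"liftoff"`, `"collapse"`.
#' @param control Subphase name of the control rows.
#' @return A tibble of comparison rows.
#' @examples
#' tab <- tibble::tibble(
#'   lipid = "DPPE", subphase = c("water", "carvacrol"),
#'   max_modulus_mN_m = c(240, 50)
#' )
#' compare_to_control(tab, "max_modulus")
#' @export
compare_to_control <- function(table, parameter, control = "water") {
  col <- resolve_parameter(parameter, names(table))
  lipids <- unique(table$lipid)
  missing <- lipids[!vapply(
    lipids,
    function(l) any(table$lipid == l & table$subphase == control),
    logical(1)
  )]
  if (length(missing) > 0L) {
    abort_mono(
      paste0(
        "No '", control, "' control row for lipid(s): ",
        paste(missing, collapse = ", "), "."
      ),
      "missing_control"
    )
  }
  ctrl <- table |>
    filter(subphase == control) |>
    select(lipid, control_value = dplyr::all_of(col))
  out <- table |>
    filter(subphase != control) |>
    select(lipid, compound = "subphase", treatment_value = dplyr::all_of(col)) |>
    left_join(ctrl, by = "lipid") |>
    mutate(
      parameter = parameter,
      delta = treatment_value - control_value,
      percent_change = 100 * (control_value - treatment_value) / abs(control_value),
      fold_reduction = dplyr::if_else(
        is.finite(control_value) & is.finite(treatment_value) &
          treatment_value != 0 & control_value != 0 &
          sign(control_value) == sign(treatment_value),
        control_value / treatment_value,
        NA_real_
      )
    ) |>
    select(
      lipid, compound, parameter, control_value, treatment_value,
      delta, percent_change, fold_reduction
    ) |>
    arrange(lipid, compound)
  with_folds <- filter(out, !is.na(fold_reduction))
  fold_summary <- if (nrow(with_folds) > 0L) {
    with_folds |>
      group_by(lipid) |>
      summarise(
        min_fold = min(fold_reduction),
        max_fold = max(fold_reduction),
        .groups = "drop"
      )
  } else {
    tibble(lipid = character(0), min_fold = numeric(0), max_fold = numeric(0))
  }
  attr(out, "fold_summary") <- fold_summary
  out
}
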