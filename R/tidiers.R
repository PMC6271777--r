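# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a monolayer feature set into long form
#'
#' @param x A `monolayer_features` row (from [extract_features()]).
#' @param ... Unused.
#' @return A tibble with columns `lipid`, `subphase`, `parameter`, `value`.
#' @method tidy monolayer_features
#' @export
tidy.monolayer_features <- function(x, ...) {
  x |>
    as_tibble() |>
    select(-dplyr::any_of("phase_at_reference")) |>
    tidyr::pivot_longer(
      -dplyr::all_of(c("lipid", "subphase")),
      names_to = "parameter", values_to = "value"
    )
}

#' One-row summary of a monolayer feature set
#'
#' @inheritParams tidy.monolayer_features
#' @return The feature row as a plain tibble.
#' @method glance monolayer_features
#' @export
glance.monolayer_features <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a feature table into long form
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A long tibble keyed by (lipid, subphase, parameter).
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  x |>
    as_tibble() |>
    select(-dplyr::any_of("phase_at_reference")) |>
    tidyr::pivot_longer(
      -dplyr::all_of(c("lipid", "subphase")),
      names_to = "parameter", values_to = "value"
    )
}

#' Plot a compression isotherm
#'
#' Surface pressure (and, when present, surface potential) against area per
#' molecule.
#'
#' @param object An isotherm tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isotherm
#' @export
autoplot.isotherm <- function(object, ...) {
  long <- object |>
    as_tibble() |>
    tidyr::pivot_longer(-area_A2, names_to = "signal", values_to = "value") |>
    mutate(signal = dplyr::recode(signal,
      pressure_mN_m = "surface pressure (mN/m)",
      potential_mV = "surface potential (mV)"
    ))
  md <- iso_metadata(object)
  ggplot2::ggplot(long, ggplot2::aes(x = area_A2, y = value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = expression("area per molecule (" * ring(A)^2 * "/molecule)"),
      y = NULL,
      title = paste(
        md$lipid %||% "isotherm",
        if (!is.null(md$subphase_additive)) paste("on", md$subphase_additive)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a compressibility-modulus curve
#'
#' \eqn{C_s^{-1}} against surface pressure, with the standard phase-band
#' guides.
#'
#' @param object A `compressibility_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compressibility_curve
#' @export
autoplot.compressibility_curve <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = pressure_mN_m, y = modulus_mN_m)
  ) +
    ggplot2::geom_hline(
      yintercept = unname(.phase_bands),
      linetype = "dotted", colour = "grey55"
    ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "surface pressure (mN/m)",
      y = expression(C[s]^-1 ~ "(mN/m)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an apparent dipole-moment profile
#'
#' @param object A `dipole_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dipole_profile
#' @export
autoplot.dipole_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = area_A2, y = dipole_mD)
  ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = expression("area per molecule (" * ring(A)^2 * "/molecule)"),
      y = "apparent dipole moment (mD)"
    ) +
    ggplot2::theme_minimal()
}
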