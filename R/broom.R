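# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a stretch trajectory into one row per checkpoint
#'
#' @param x A `stretch_trajectory`.
#' @param ... Unused.
#' @return Tibble with strain level, reaction force, effective stress,
#'   secant modulus, mean folded segment angle, mean axial energy fraction
#'   and yield counts.
#' @export
tidy.stretch_trajectory <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) tibble::tibble(
    strain = r$strain_level,
    reaction_force = r$reaction_force,
    sigma_x = r$sigma_x,
    epsilon_y = r$epsilon_y,
    modulus = r$effective_modulus,
    mean_angle = mean(r$segment_angles),
    mean_axial_fraction = mean(r$energy_fractions, na.rm = TRUE),
    yielded_beams = r$yielded_beams,
    yielded_cables = r$yielded_cables
  ))
}

#' Per-sample results of an ensemble
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return The per-sample tibble (one row per converged sample).
#' @export
tidy.ensemble_result <- function(x, ...) x$samples

#' Per-sweep-point summary of an ensemble
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return Tibble with `sweep_value`, `n`, `mean`, `sd` (kPa) and the
#'   number of failed samples.
#' @export
glance.ensemble_result <- function(x, ...) {
  dplyr::mutate(x$summary,
                failures = NROW(x$failures),
                master_seed = x$spec$master_seed)
}

#' One-line summary of a form-finding result
#'
#' @param x A `form_finding_result`.
#' @param ... Unused.
#' @return One-row tibble with residual norm, displacement norm, maximum
#'   filament force and cable counts.
#' @export
glance.form_finding_result <- function(x, ...) {
  tibble::tibble(
    prestress = x$prestress,
    residual_norm = x$state$residual_norm,
    displacement_norm = x$displacement_norm,
    max_filament_force = x$max_filament_force,
    max_cable_elongation = x$max_cable_elongation,
    n_cables = NROW(x$network$cables),
    iterations = sum(x$state$iterations)
  )
}
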