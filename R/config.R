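#' Configuration for random network generation
#'
#' Collects the geometric and stochastic parameters that define one family
#' of random cross-linked filament networks: the rectangular domain, the
#' filament length distribution, the binding-site (segment) spacing, the
#' target filament volume fraction, and the cross-linking rules.
#'
#' Lengths are in micrometres.  The defaults describe an actin network on a
#' 10 um x 10 um x 1 um domain: filament length 5 +/- 2 um (truncated
#' Gaussian), binding sites every 0.3 +/- 0.06 um along each filament,
#' filament diameter 7 nm, and cross-linkers connecting any two binding
#' sites on distinct filaments that are closer than 0.3 um.
#'
#' @param domain_width,domain_height Domain side lengths (um).
#' @param domain_thickness Out-of-plane thickness used only for volume and
#'   stress normalisation (um).
#' @param filament_length_mean,filament_length_std Mean and standard
#'   deviation of the truncated Gaussian filament length distribution (um).
#'   Draws that are non-positive, or too long to fit in the domain, are
#'   rejected and redrawn.
#' @param segment_length_mean,segment_length_std Binding-site spacing
#'   distribution along a filament (um).
#' @param filament_diameter Filament diameter (um).
#' @param target_relative_density Target filament volume fraction; filaments
#'   are placed sequentially until this fraction is reached.
#' @param max_crosslinker_length Maximum cross-linker length (um); binding
#'   sites strictly closer than this are candidate connections.
#' @param min_crosslinker_length Minimum cross-linker length (um, default
#'   0.05): a cross-linking protein has finite size, so binding sites
#'   closer than this cannot be linked.
#' @param crosslink_fraction Fraction of cross-linker connections
#'   retained (independently at random), in (0, 1].
#' @param site_capacity Maximum number of cross-linkers a binding site may
#'   host (default 1: one cross-linking protein per site; `Inf` connects
#'   every candidate pair).  See [generate_crosslinkers()].
#' @param seed Integer seed making the generated network reproducible.
#' @return A `generation_config` object (a named list).
#' @examples
#' cfg <- generation_config(seed = 1)
#' cfg$filament_length_mean
#' @export
generation_config <- function(domain_width = 10,
                              domain_height = 10,
                              domain_thickness = 1,
                              filament_length_mean = 5,
                              filament_length_std = 2,
                              segment_length_mean = 0.3,
                              segment_length_std = 0.06,
                              filament_diameter = 0.007,
                              target_relative_density = 0.002,
                              max_crosslinker_length = 0.3,
                              min_crosslinker_length = 0.05,
                              crosslink_fraction = 1,
                              site_capacity = 1,
                              seed = NULL) {
  cfg <- structure(list(
    domain_width = domain_width,
    domain_height = domain_height,
    domain_thickness = domain_thickness,
    filament_length_mean = filament_length_mean,
    filament_length_std = filament_length_std,
    segment_length_mean = segment_length_mean,
    segment_length_std = segment_length_std,
    filament_diameter = filament_diameter,
    target_relative_density = target_relative_density,
    max_crosslinker_length = max_crosslinker_length,
    min_crosslinker_length = min_crosslinker_length,
    crosslink_fraction = crosslink_fraction,
    site_capacity = site_capacity,
    seed = seed
  ), class = "generation_config")
  validate_generation_config(cfg)
  cfg
}

validate_generation_config <- function(cfg) {
  len_fields <- c("domain_width", "domain_height", "domain_thickness",
                  "filament_length_mean", "filament_length_std",
                  "segment_length_mean", "segment_length_std",
                  "filament_diameter", "max_crosslinker_length")
  for (f in len_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("`", f, "` must be a single positive number", call. = FALSE)
  }
  rho <- cfg$target_relative_density
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 0.01)
    stop("`target_relative_density` must lie in (0, 0.01]", call. = FALSE)
  f <- cfg$crosslink_fraction
  if (!is.numeric(f) || length(f) != 1 || f <= 0 || f > 1)
    stop("`crosslink_fraction` must lie in (0, 1]", call. = FALSE)
  mn <- cfg$min_crosslinker_length %||% 0.05
  if (!is.numeric(mn) || length(mn) != 1 || mn < 0 ||
      mn >= cfg$max_crosslinker_length)
    stop("`min_crosslinker_length` must lie in [0, max_crosslinker_length)",
         call. = FALSE)
  sc <- cfg$site_capacity %||% 1
  if (!is.numeric(sc) || length(sc) != 1 || is.na(sc) || sc < 1)
    stop("`site_capacity` must be a number >= 1 (or Inf)", call. = FALSE)
  # The domain must comfortably exceed the typical filament so that the
  # translate-into-domain rule can succeed; draws longer than the domain
  # are rejected during sampling.
  if (min(cfg$domain_width, cfg$domain_height) <= cfg$filament_length_mean)
    stop("domain dimensions must exceed `filament_length_mean`; ",
         "filaments cannot fit in the domain", call. = FALSE)
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)))
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  invisible(cfg)
}

#' @export
print.generation_config <- function(x, ...) {
  cat("<generation_config>\n")
  cat(sprintf("  domain: %g x %g x %g um\n",
              x$domain_width, x$domain_height, x$domain_thickness))
  cat(sprintf("  filament length: %g +/- %g um, diameter %g um\n",
              x$filament_length_mean, x$filament_length_std,
              x$filament_diameter))
  cat(sprintf("  segment length: %g +/- %g um\n",
              x$segment_length_mean, x$segment_length_std))
  cat(sprintf("  target relative density: %g\n", x$target_relative_density))
  cat(sprintf("  max cross-linker length: %g um, fraction retained: %g\n",
              x$max_crosslinker_length, x$crosslink_fraction))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", as.integer(x$seed)))
  invisible(x)
}

#' Material and section properties of filaments and cross-linkers
#'
#' Derived section constants (area, second moment) are always computed from
#' the diameter; they are never stored independently.  The internal unit
#' system is um-nN, so the filament modulus 1.4 GPa becomes 1.4e6 nN/um^2
#' and effective stresses come out directly in kPa (1 nN/um^2 = 1 kPa).
#'
#' @param filament_modulus Elastic modulus of a filament, nN/um^2
#'   (default 1.4e6, i.e. 1.4 GPa).
#' @param filament_diameter Filament diameter, um (default 0.007).
#' @param filament_yield_force Tensile yield force of a filament, nN
#'   (default 0.25); used for exceedance flagging only.
#' @param crosslinker_yield_force Tensile yield force of a cross-linker, nN
#'   (default 0.060, i.e. 60 pN).
#' @param crosslinker_prestress Constant tensile pre-stress applied to the
#'   cross-linkers during form-finding, nN (default 0.003, about 5% of the
#'   cross-linker yield force).
#' @param crosslinker_axial_stiffness Axial stiffness of a cross-linker in
#'   the elastic (stretching) mode, nN per unit strain.  The default 0.6
#'   makes a cross-linker reach its 60 pN yield force at 10% strain.
#' @return A `material_table` object with derived fields `filament_area`
#'   (um^2), `filament_I` (um^4), `EA` (nN) and `EI` (nN um^2).
#' @examples
#' mat <- material_table()
#' mat$EA   # ~53.88 nN
#' @export
material_table <- function(filament_modulus = 1.4e6,
                           filament_diameter = 0.007,
                           filament_yield_force = 0.25,
                           crosslinker_yield_force = 0.060,
                           crosslinker_prestress = 0.003,
                           crosslinker_axial_stiffness = 0.6) {
  stopifnot(filament_modulus > 0, filament_diameter > 0,
            filament_yield_force > 0, crosslinker_yield_force > 0,
            crosslinker_prestress >= 0, crosslinker_axial_stiffness >= 0)
  if (crosslinker_prestress > crosslinker_yield_force)
    stop("`crosslinker_prestress` must not exceed `crosslinker_yield_force`",
         call. = FALSE)
  d <- filament_diameter
  A <- pi * d^2 / 4
  I <- pi * d^4 / 64
  structure(list(
    filament_modulus = filament_modulus,
    filament_diameter = d,
    filament_area = A,
    filament_I = I,
    EA = filament_modulus * A,
    EI = filament_modulus * I,
    filament_yield_force = filament_yield_force,
    crosslinker_yield_force = crosslinker_yield_force,
    crosslinker_prestress = crosslinker_prestress,
    crosslinker_axial_stiffness = crosslinker_axial_stiffness
  ), class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat("<material_table>  (um-nN units; 1 nN/um^2 = 1 kPa)\n")
  cat(sprintf("  filament: E = %.3g nN/um^2, d = %g um, EA = %.4g nN, EI = %.4g nN um^2\n",
              x$filament_modulus, x$filament_diameter, x$EA, x$EI))
  cat(sprintf("  yield forces: filament %.3g nN, cross-linker %.3g nN\n",
              x$filament_yield_force, x$crosslinker_yield_force))
  cat(sprintf("  cross-linker: pre-stress %.3g nN, axial stiffness %.3g nN/strain\n",
              x$crosslinker_prestress, x$crosslinker_axial_stiffness))
  invisible(x)
}

#' Nonlinear solver settings
#'
#' Controls the incremental Newton solution used for form-finding and
#' stretching.  Convergence is declared when the Euclidean norm of the
#' free-DOF residual falls below `rtol` times a characteristic internal
#' force (the largest element force in the current state, floored at
#' `force_floor`).
#'
#' @param rtol Relative residual tolerance (default 2e-3): convergence is declared when the free-DOF residual norm falls below rtol times the larger of the peak element force and the increment's initial (driving) residual.
#' @param max_iterations Maximum Newton iterations per increment.
#' @param n_increments Load increments for form-finding (default 10).
#' @param max_strain_increment Largest strain step used when stretching
#'   (default 0.05, i.e. 5% strain per increment).
#' @param regularization Small artificial translational spring stiffness
#'   (nN/um) anchoring every node to its stage-start position; suppresses
#'   floating mechanisms without measurably loading the network.
#' @param rot_regularization Same, for rotational DOF (nN um/rad).
#' @param tangent_update `"every_iteration"` refactorises the tangent each
#'   Newton iteration (true Newton); `"adaptive"` factorises once per
#'   increment and refactorises only when convergence stalls (near-linear
#'   problems converge with back-substitutions only).
#' @param force_floor Lower bound on the characteristic force (nN).
#' @param linear_solver `"direct"` (sparse Cholesky in nested-dissection
#'   order), `"pcg"` (matrix-free preconditioned conjugate gradients), or
#'   `"auto"` (pcg for large form-finding solves, direct otherwise).
#' @param reduce_rotations Condense rotational DOF out of the linear
#'   solves by exact per-filament block elimination (`"auto"`: on for
#'   large generated networks; identical iterates either way).
#' @param max_step Largest admissible nodal update per Newton iteration
#'   (um / rad); larger proposed steps trigger adaptive damping of the
#'   tangent (the converged equilibrium is unaffected).
#' @param verbose Print per-iteration residuals.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(rtol = 2e-3,
                            max_iterations = 200,
                            n_increments = 10,
                            max_strain_increment = 0.05,
                            regularization = 1e-6,
                            rot_regularization = 1e-8,
                            tangent_update = c("adaptive", "every_iteration"),
                            force_floor = 1e-6,
                            max_step = 0.5,
                            reduce_rotations = c("auto", "always", "never"),
                            linear_solver = c("auto", "direct", "pcg"),
                            verbose = FALSE) {
  stopifnot(rtol > 0, max_iterations >= 1, n_increments >= 1,
            max_strain_increment > 0, regularization >= 0,
            rot_regularization >= 0, force_floor > 0, max_step > 0)
  structure(list(
    rtol = rtol,
    max_iterations = as.integer(max_iterations),
    n_increments = as.integer(n_increments),
    max_strain_increment = max_strain_increment,
    regularization = regularization,
    rot_regularization = rot_regularization,
    tangent_update = match.arg(tangent_update),
    force_floor = force_floor,
    max_step = max_step,
    reduce_rotations = match.arg(reduce_rotations),
    linear_solver = match.arg(linear_solver),
    verbose = isTRUE(verbose)
  ), class = "solver_settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
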