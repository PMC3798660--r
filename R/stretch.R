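# Virtual experiments on a form-found network: uniaxial extension,
# effective-modulus extraction, orientation statistics, strain-energy
# partition, and yield screening.

#' Uniaxial stretch of a form-found network
#'
#' Nodes whose reference x coordinate lies within an edge band of the left
#' domain edge are fixed in longitudinal (x) translation; nodes in the
#' right edge band are displaced longitudinally to the target engineering
#' strain.  Lateral (y) translations and rotations remain free everywhere
#' (plane-stress `sigma_y = 0` condition); one left-band node is pinned in
#' y to remove the remaining rigid mode, and carries zero force at
#' equilibrium.  Cross-linkers act in their stretching mode (default:
#' tension-only elastic with pre-stress offset) with the form-found length
#' as reference length.
#'
#' @param ff A `form_finding_result` from [run_form_finding()].
#' @param target_strain Final engineering strain (stretch divided by domain
#'   width), >= 0.
#' @param checkpoints Strains at which states are recorded (default just
#'   `target_strain`); `target_strain` is always included.
#' @param settings A [solver_settings()]; increments are chosen so that no
#'   single step exceeds `settings$max_strain_increment`.
#' @param edge_band Band width for boundary-node selection, as a fraction
#'   of the domain width (default 0.02).
#' @param cable_mode Cross-linker behaviour while stretching:
#'   `"elastic"` (default) or `"constant_force"`.
#' @param stiffness Cable axial stiffness (nN per unit strain); defaults to
#'   the material table value.
#' @return A `stretch_trajectory`: list of `stretch_result` records (one
#'   per checkpoint), each holding the strain level, reaction force,
#'   effective stress/strain, secant modulus, folded segment angles,
#'   per-filament energy fractions, yield counts and the full
#'   `system_state`.
#' @export
uniaxial_stretch <- function(ff, target_strain,
                             checkpoints = NULL,
                             settings = solver_settings(),
                             edge_band = 0.02,
                             cable_mode = c("elastic", "constant_force"),
                             stiffness = NULL) {
  stopifnot(inherits(ff, "form_finding_result"), target_strain >= 0)
  cable_mode <- match.arg(cable_mode)
  network <- ff$network
  cfg <- network$config
  mat <- network$materials
  if (is.null(stiffness)) stiffness <- mat$crosslinker_axial_stiffness

  fe <- fe_from_network(network)
  # cables re-referenced to their form-found lengths
  fe$cL0 <- ff$cable_lengths

  W <- cfg$domain_width
  band <- edge_band * W
  left <- which(network$nodes$x <= band)
  right <- which(network$nodes$x >= W - band)
  if (!length(left) || !length(right))
    stop("an edge band contains no nodes; the network is too sparse for ",
         "displacement-controlled stretching", call. = FALSE)
  # y pin: left-band node nearest mid-height (carries no load at equilibrium)
  ypin <- left[which.min(abs(network$nodes$y[left] - cfg$domain_height / 2))]

  q <- ff$state$q
  left_x_dof <- dof_index(left, "x")
  right_x_dof <- dof_index(right, "x")
  fixed_idx <- c(left_x_dof, right_x_dof, dof_index(ypin, "y"))

  checkpoints <- sort(unique(c(checkpoints, target_strain)))
  checkpoints <- checkpoints[checkpoints <= target_strain + 1e-12]
  results <- vector("list", length(checkpoints))
  eps_prev <- 0
  right_x0 <- q[right_x_dof]

  for (k in seq_along(checkpoints)) {
    eps <- checkpoints[k]
    if (eps > eps_prev + 1e-15) {
      n_inc <- max(1L, ceiling((eps - eps_prev) /
                                 settings$max_strain_increment))
      target <- c(q[left_x_dof], right_x0 + eps * W, q[dof_index(ypin, "y")])
      # affine seed: uniform stretch of the x field over this checkpoint
      guess <- numeric(3L * fe$nnode)
      guess[dof_index(seq_len(fe$nnode), "x")] <-
        (eps - eps_prev) * network$nodes$x
      state <- newton_solve(fe, q, fixed_idx, target,
                            f_ext = NULL, settings = settings,
                            cable_mode = cable_mode,
                            prestress = ff$prestress,
                            stiffness = stiffness,
                            n_increments = n_inc,
                            guess_delta = guess)
      q <- state$q
    } else {
      state <- ff$state
    }
    results[[k]] <- stretch_result(network, state, eps, fe,
                                   left_x_dof, right_x_dof)
    eps_prev <- eps
  }
  structure(list(results = results,
                 checkpoints = checkpoints,
                 ff = ff,
                 edge_band = edge_band,
                 cable_mode = cable_mode,
                 stiffness = stiffness),
            class = "stretch_trajectory")
}

# Assemble the per-checkpoint record.
stretch_result <- function(network, state, strain, fe,
                           left_x_dof, right_x_dof) {
  cfg <- network$config
  area <- cfg$domain_height * cfg$domain_thickness
  r <- numeric(3L * fe$nnode)
  r[state$fixed_dof] <- state$reactions
  reaction <- sum(r[right_x_dof])
  sigma_x <- reaction / area

  n <- fe$nnode
  ys <- state$coordinates[, 2]
  H <- cfg$domain_height
  bandH <- 0.02 * H
  bot <- which(network$nodes$y <= bandH)
  top <- which(network$nodes$y >= H - bandH)
  epsilon_y <- if (length(bot) && length(top))
    ((mean(ys[top]) - mean(ys[bot])) -
       (mean(network$nodes$y[top]) - mean(network$nodes$y[bot]))) /
      (mean(network$nodes$y[top]) - mean(network$nodes$y[bot]))
  else NA_real_

  angles <- segment_orientations(network, state)
  en <- strain_energy(network, state)
  ys_counts <- yield_screen(state, network$materials)
  structure(list(
    strain_level = strain,
    reaction_force = reaction,
    sigma_x = sigma_x,
    sigma_y = 0,
    epsilon_y = epsilon_y,
    effective_modulus = if (strain > 0) sigma_x / strain else NA_real_,
    segment_angles = angles,
    energy = en,
    energy_fractions = ifelse(en$se_total > 0, en$se_axial / en$se_total,
                              NA_real_),
    yielded_beams = ys_counts$yielded_beams,
    yielded_cables = ys_counts$yielded_cables,
    state = state
  ), class = "stretch_result")
}

#' @export
print.stretch_result <- function(x, ...) {
  cat("<stretch_result>\n")
  cat(sprintf("  strain %.3g: sigma_x = %.4g kPa, E = %.4g kPa\n",
              x$strain_level, x$sigma_x, x$effective_modulus))
  cat(sprintf("  mean folded segment angle: %.1f deg; yielded beams %d, cables %d\n",
              mean(x$segment_angles), x$yielded_beams, x$yielded_cables))
  invisible(x)
}

#' @export
print.stretch_trajectory <- function(x, ...) {
  cat("<stretch_trajectory> checkpoints:",
      paste(signif(x$checkpoints, 3), collapse = ", "), "\n")
  print(tidy(x))
  invisible(x)
}

#' Effective elastic modulus from a stretch experiment
#'
#' Plane-stress Hooke's law
#' `E = (sigma_x^2 - sigma_y^2) / (sigma_x eps_x - sigma_y eps_y)`, which
#' under the free-lateral-edge condition `sigma_y = 0` reduces exactly to
#' `sigma_x / eps_x`.  `sigma_x` is the summed reaction on the displaced
#' edge divided by the original domain cross-section.
#'
#' @param x A `stretch_trajectory` or a single `stretch_result`.
#' @param strain Which checkpoint to use (default: the largest).
#' @return Secant modulus in kPa.
#' @export
effective_modulus <- function(x, strain = NULL) {
  if (inherits(x, "stretch_trajectory")) {
    eps <- if (is.null(strain)) max(x$checkpoints) else strain
    k <- which.min(abs(x$checkpoints - eps))
    x <- x$results[[k]]
  }
  stopifnot(inherits(x, "stretch_result"))
  if (x$strain_level == 0)
    stop("effective modulus is undefined at zero strain", call. = FALSE)
  num <- x$sigma_x^2 - x$sigma_y^2
  den <- x$sigma_x * x$strain_level -
    x$sigma_y * (if (is.na(x$epsilon_y)) 0 else x$epsilon_y)
  num / den
}

#' Folded orientation of every filament segment
#'
#' Angle between each beam element's (deformed) chord and the +x axis,
#' folded into \[0, 90\] degrees.
#'
#' @param network A `filament_network`.
#' @param state Optional `system_state`; default uses the reference
#'   (as-generated) geometry.
#' @return Numeric vector of angles in degrees.
#' @export
segment_orientations <- function(network, state = NULL) {
  if (is.null(state)) {
    xs <- network$nodes$x; ys <- network$nodes$y
  } else {
    xs <- state$coordinates[, 1]; ys <- state$coordinates[, 2]
  }
  a <- network$beams$node_a; b <- network$beams$node_b
  ang <- atan2(abs(ys[b] - ys[a]), abs(xs[b] - xs[a])) * 180 / pi
  pmin(pmax(ang, 0), 90)
}

#' Histogram of filament segment orientations
#'
#' @inheritParams segment_orientations
#' @param breaks Bin edges in degrees (default nine 10-degree bins).
#' @return Tibble with `bin_left`, `bin_right`, `count`, `fraction`.
#' @export
orientation_histogram <- function(network, state = NULL,
                                  breaks = seq(0, 90, by = 10)) {
  ang <- segment_orientations(network, state)
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  tibble::tibble(bin_left = utils::head(breaks, -1),
                 bin_right = breaks[-1],
                 count = h$counts,
                 fraction = h$counts / max(1L, sum(h$counts)))
}

#' Histogram of the per-filament axial strain-energy fraction
#'
#' Distribution of `SE_axial / SE_total` over filaments; filaments whose
#' total strain energy falls below `floor` are excluded from the histogram
#' and counted separately.
#'
#' @param network A `filament_network`.
#' @param state A converged `system_state`.
#' @param breaks Bin edges on \[0, 1\] (default ten bins of 0.1).
#' @param floor Energy floor (nN um) below which a filament is excluded.
#' @return Tibble with `bin_left`, `bin_right`, `count`, `fraction`;
#'   attribute `n_excluded`.
#' @export
energy_partition_histogram <- function(network, state,
                                       breaks = seq(0, 1, by = 0.1),
                                       floor = 1e-18) {
  en <- strain_energy(network, state)
  keep <- en$se_total >= floor
  frac <- pmin(1, pmax(0, en$se_axial[keep] / en$se_total[keep]))
  h <- graphics::hist(frac, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  out <- tibble::tibble(bin_left = utils::head(breaks, -1),
                        bin_right = breaks[-1],
                        count = h$counts,
                        fraction = h$counts / max(1L, sum(h$counts)))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Count elements whose tensile force exceeds the yield force
#'
#' Exceedance is strict; the analysis stays elastic and yields are flagged,
#' not enforced.
#'
#' @param state A `system_state`.
#' @param materials A [material_table()].
#' @return List with `yielded_beams` and `yielded_cables` counts.
#' @export
yield_screen <- function(state, materials) {
  list(
    yielded_beams = sum(state$beam_forces$N > materials$filament_yield_force),
    yielded_cables = sum(state$cable_tensions >
                           materials$crosslinker_yield_force)
  )
}

#' Run the full single-sample pipeline
#'
#' Generate a network, form-find it under cross-linker pre-stress, stretch
#' it uniaxially to the measurement strain, and report the effective
#' modulus together with network statistics.
#'
#' @param cfg A [generation_config()] (must carry a seed for
#'   reproducibility).
#' @param prestress Form-finding pre-stress (nN); default from materials.
#' @param measure_strain Strain at which the secant modulus is measured
#'   (default 0.01).
#' @param settings A [solver_settings()].
#' @param stiffness Cable stretching stiffness (nN per unit strain).
#' @return One-row tibble: `seed`, network counts, achieved density,
#'   `modulus` (kPa), yield counts.
#' @export
simulate_sample <- function(cfg, prestress = NULL, measure_strain = 0.01,
                            settings = solver_settings(),
                            stiffness = NULL) {
  net <- suppress_network_warnings(build_network(cfg))
  ff <- suppress_stall_warnings(
    run_form_finding(net, prestress = prestress, settings = settings))
  traj <- suppress_stall_warnings(
    uniaxial_stretch(ff, target_strain = measure_strain,
                     settings = settings, stiffness = stiffness))
  res <- traj$results[[length(traj$results)]]
  tibble::tibble(
    seed = if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed),
    n_filaments = NROW(net$filaments),
    n_nodes = NROW(net$nodes),
    n_beams = NROW(net$beams),
    n_cables = NROW(net$cables),
    achieved_density = net$achieved_relative_density,
    modulus = effective_modulus(res),
    yielded_beams = res$yielded_beams,
    yielded_cables = res$yielded_cables
  )
}

suppress_network_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("disconnected components", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

suppress_stall_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("stalled residual", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
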