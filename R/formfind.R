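# Form-finding: bring a freshly generated network to a stable
# self-equilibrated configuration under constant cross-linker pre-stress.

# Pin set removing rigid-body modes of every connected component: fix both
# translations of the node nearest the component centroid, and for a
# distant node the translational DOF most perpendicular to the line joining
# the two (robust when the component is a straight filament).
formfinding_pins <- function(network) {
  nodes <- network$nodes
  comp <- network$component
  pins <- vector("list", network$n_components)
  for (k in seq_len(network$n_components)) {
    idx <- which(comp == k)
    cx <- mean(nodes$x[idx]); cy <- mean(nodes$y[idx])
    c_node <- idx[which.min((nodes$x[idx] - cx)^2 + (nodes$y[idx] - cy)^2)]
    d2 <- (nodes$x[idx] - nodes$x[c_node])^2 +
          (nodes$y[idx] - nodes$y[c_node])^2
    f_node <- idx[which.max(d2)]
    pin <- tibble::tibble(node = c(c_node, c_node),
                          which = c("x", "y"))
    if (f_node != c_node) {
      dx <- nodes$x[f_node] - nodes$x[c_node]
      dy <- nodes$y[f_node] - nodes$y[c_node]
      pin <- dplyr::bind_rows(pin, tibble::tibble(
        node = f_node, which = if (abs(dy) >= abs(dx)) "x" else "y"))
    }
    pins[[k]] <- pin
  }
  dplyr::bind_rows(pins)
}

#' Form-find the self-equilibrated configuration of a network
#'
#' Applies a tensile pre-stress to every cross-linker cable and solves for
#' the stable equilibrium configuration of the network (rigid-body modes
#' of each connected component are pinned).  The converged geometry is the
#' baseline for subsequent stretching: cables take their form-found length
#' as the new reference length, while beams keep their form-found internal
#' forces.
#'
#' Two readings of "the pre-stress force is kept constant" are supported.
#' The default, `cable_mode = "elastic"`, holds the pre-stress *offset*
#' constant on elastic tension-only cables (tension `P + k (l-l0)/l0`, no
#' recalibration during iteration): each cable relaxes after shortening by
#' about `P l0 / k` (~1 nm), producing a mildly re-arranged
#' self-equilibrated state in which cable tensions remain close to the
#' pre-stress.  `cable_mode = "constant_force"` instead holds the total
#' tension at `P` regardless of length; a cable web that never relaxes
#' keeps reeling its nodes together, so the equilibrium involves much
#' larger rearrangement and a far harder solve, and is intended for small
#' networks.
#'
#' @param network A `filament_network` from [build_network()].
#' @param prestress Cross-linker pre-stress (nN); must not exceed the cable
#'   yield force.  Defaults to the network's material table (0.003 nN).
#' @param settings A [solver_settings()].
#' @param cable_mode `"elastic"` (default) or `"constant_force"`, see
#'   Details.
#' @param stiffness Cable axial stiffness in elastic mode (nN per unit
#'   strain); defaults to the material table value.
#' @return A `form_finding_result`: the input `network`, the converged
#'   `state`, the form-found cable lengths, `max_filament_force` (nN),
#'   `max_cable_elongation` (um) and `displacement_norm` (largest nodal
#'   translation, um).
#' @export
run_form_finding <- function(network, prestress = NULL,
                             settings = solver_settings(),
                             cable_mode = c("elastic", "constant_force"),
                             stiffness = NULL) {
  cable_mode <- match.arg(cable_mode)
  stopifnot(inherits(network, "filament_network"))
  mat <- network$materials
  if (is.null(prestress)) prestress <- mat$crosslinker_prestress
  if (prestress > mat$crosslinker_yield_force)
    stop("`prestress` exceeds the cross-linker yield force (",
         mat$crosslinker_yield_force, " nN)", call. = FALSE)
  if (is.null(stiffness)) stiffness <- mat$crosslinker_axial_stiffness
  fe <- fe_from_network(network)
  pins <- formfinding_pins(network)
  fixed_idx <- dof_index(pins$node, pins$which)
  state <- newton_solve(fe, fe$q0, fixed_idx, fe$q0[fixed_idx],
                        f_ext = NULL, settings = settings,
                        cable_mode = cable_mode,
                        prestress = prestress,
                        stiffness = stiffness,
                        n_increments = if (cable_mode == "elastic") 1L
                                       else settings$n_increments,
                        ramp_prestress = cable_mode == "constant_force")
  n <- fe$nnode
  ux <- state$q[dof_index(seq_len(n), "x")] - network$nodes$x
  uy <- state$q[dof_index(seq_len(n), "y")] - network$nodes$y
  cab_len <- if (NROW(network$cables)) {
    ca <- network$cables$node_a; cb <- network$cables$node_b
    sqrt((state$coordinates[cb, 1] - state$coordinates[ca, 1])^2 +
         (state$coordinates[cb, 2] - state$coordinates[ca, 2])^2)
  } else numeric(0)
  max_force <- if (NROW(state$beam_forces)) max(abs(state$beam_forces$N)) else 0
  if (max_force > mat$filament_yield_force)
    warning("form-found filament force ", signif(max_force, 3),
            " nN exceeds the filament yield force ",
            mat$filament_yield_force, " nN", call. = FALSE)
  structure(list(
    network = network,
    state = state,
    prestress = prestress,
    cable_mode = cable_mode,
    settings = settings,
    pins = pins,
    cable_lengths = cab_len,
    max_filament_force = max_force,
    max_cable_elongation =
      if (length(cab_len)) max(abs(cab_len - network$cables$length0)) else 0,
    displacement_norm = if (n) max(sqrt(ux^2 + uy^2)) else 0
  ), class = "form_finding_result")
}

#' @export
print.form_finding_result <- function(x, ...) {
  cat("<form_finding_result>\n")
  cat(sprintf("  pre-stress: %g nN on %d cables\n", x$prestress,
              NROW(x$network$cables)))
  cat(sprintf("  residual norm: %.3g nN, max nodal displacement: %.3g um\n",
              x$state$residual_norm, x$displacement_norm))
  cat(sprintf("  max filament force: %.3g nN (yield %.3g nN)\n",
              x$max_filament_force,
              x$network$materials$filament_yield_force))
  invisible(x)
}

#' Sensitivity of the effective modulus to the form-finding pre-stress
#'
#' Repeats the form-find-and-stretch pipeline on one network at several
#' pre-stress levels and reports the resulting effective moduli and their
#' relative spread `(max - min) / min`.
#'
#' @inheritParams run_form_finding
#' @param prestress_levels Numeric vector of pre-stress values (nN).
#' @param measure_strain Strain at which the secant modulus is measured.
#' @return Tibble with columns `prestress` and `modulus`; attribute
#'   `relative_spread`.
#' @export
prestress_sensitivity <- function(network, prestress_levels,
                                  settings = solver_settings(),
                                  measure_strain = 0.01) {
  moduli <- purrr::map_dbl(prestress_levels, function(p) {
    ff <- run_form_finding(network, prestress = p, settings = settings)
    traj <- uniaxial_stretch(ff, target_strain = measure_strain,
                             settings = settings)
    effective_modulus(traj)
  })
  out <- tibble::tibble(prestress = prestress_levels, modulus = moduli)
  attr(out, "relative_spread") <-
    if (length(moduli) > 1) (max(moduli) - min(moduli)) / min(moduli) else 0
  out
}
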