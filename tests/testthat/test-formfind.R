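# Form-finding: self-equilibration under cross-linker pre-stress.

test_that("a network with no cables is trivially equilibrated", {
  chain <- make_chain(6, 1.8)
  net <- make_network(chain$nodes, chain$beams)
  ff <- run_form_finding(net)
  expect_true(ff$state$converged)
  expect_equal(ff$displacement_norm, 0, tolerance = 1e-10)
})

test_that("pre-stress above the cable yield force is rejected", {
  net <- make_ladder(cable_nodes = 2L)
  expect_error(run_form_finding(net, prestress = 0.1), "yield")
})

test_that("clamped two-filament toy matches an energy-minimisation oracle", {
  # two parallel filaments with clamped ends joined by one constant-force
  # cable at mid-span: the filaments bow toward each other until bending
  # resistance balances the pre-stress (the pre-stress is chosen small
  # enough that the cable stays open rather than reeling shut)
  net <- make_ladder(n = 4, L = 1.2, gap = 0.2, cable_nodes = 3L)
  fixed <- tibble::tibble(
    node = c(1L, 1L, 5L, 6L, 6L, 10L),
    which = c("x", "y", "y", "x", "y", "y"),
    value = c(0, 0, 0, 0, 0.2, 0.2))
  P <- 4e-4
  st <- solve_equilibrium(net, fixed, cable_mode = "constant_force",
                          prestress = P, settings = tight_settings())
  expect_true(st$converged)
  expect_equal(st$cable_tensions, P, tolerance = 1e-3)

  # independent oracle: minimise total potential (beam energy + P * cable
  # length) over the free DOF with a generic optimiser
  fe <- actinform:::fe_from_network(net)
  fixed_idx <- dof_index(fixed$node, fixed$which)
  free <- setdiff(seq_along(fe$q0), fixed_idx)
  energy <- function(qf) {
    q <- fe$q0
    q[free] <- qf
    actinform:::fe_call(fe, q, "constant_force", P, 0, FALSE)$energy
  }
  opt <- stats::optim(st$q[free], energy, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  # the optimiser started from our solution: it should not move away
  expect_lt(max(abs(opt$par - st$q[free])), 2e-4)
  # and a cold-started optimiser reaches the same energy
  opt2 <- stats::optim(fe$q0[free], energy, method = "BFGS",
                       control = list(maxit = 5000, reltol = 1e-14))
  # the cold-started optimiser lands in the same basin; our Newton
  # solution is at least as low in energy
  expect_equal(opt2$value, energy(st$q[free]), tolerance = 0.05)
  expect_lte(energy(st$q[free]), opt2$value + 1e-9)
})

test_that("displacement vanishes as the pre-stress goes to zero", {
  net <- suppressWarnings(build_network(small_cfg(seed = 4)))
  d <- sapply(c(1e-3, 1e-5), function(p)
    suppressWarnings(run_form_finding(net, prestress = p))$displacement_norm)
  expect_lt(d[2], d[1] / 10)
})

test_that("form-finding is idempotent and leaves tensions near the pre-stress", {
  net <- suppressWarnings(build_network(small_cfg(seed = 8)))
  ff <- suppressWarnings(run_form_finding(net))
  expect_true(ff$state$converged)
  # cable tensions relax below the pre-stress and stay non-negative
  expect_true(all(ff$state$cable_tensions >= 0))
  expect_lte(max(ff$state$cable_tensions), 0.06)
  # continuing the solve from the converged state barely moves: the state
  # is an equilibrium of the same model (same element references)
  fe <- actinform:::fe_from_network(net)
  pins <- actinform:::formfinding_pins(net)
  fixed_idx <- dof_index(pins$node, pins$which)
  st2 <- suppressWarnings(actinform:::newton_solve(
    fe, ff$state$q, fixed_idx, ff$state$q[fixed_idx],
    settings = solver_settings(rtol = 3e-2), cable_mode = "elastic",
    prestress = ff$prestress, n_increments = 1))
  # motion on continuation stays within the marginal-mode positional
  # uncertainty of the accepted tolerance band (individual weakly-held
  # filaments are located to ~0.1 um; the network-scale configuration does
  # not drift)
  expect_true(st2$converged)
  expect_lt(max(abs(st2$q - ff$state$q)),
            max(0.15, 0.5 * ff$displacement_norm))
})

test_that("the form-found state is a stable equilibrium on a toy", {
  net <- make_ladder(n = 4, L = 1.2, gap = 0.2, cable_nodes = 3L)
  fixed <- tibble::tibble(
    node = c(1L, 1L, 5L, 6L, 6L, 10L),
    which = c("x", "y", "y", "x", "y", "y"),
    value = c(0, 0, 0, 0, 0.2, 0.2))
  st <- solve_equilibrium(net, fixed, cable_mode = "constant_force",
                          prestress = 0.003, settings = tight_settings())
  sys <- assemble_system(net, st$q, cable_mode = "constant_force",
                         prestress = 0.003)
  free <- setdiff(seq_along(st$q), dof_index(fixed$node, fixed$which))
  ev <- eigen(as.matrix(sys$K[free, free]), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("prestress sensitivity runs and reports the relative spread", {
  net <- suppressWarnings(build_network(small_cfg(seed = 9)))
  tab <- suppressWarnings(prestress_sensitivity(net, c(0.0006, 0.003)))
  expect_equal(NROW(tab), 2)
  expect_true(all(is.finite(tab$modulus)))
  expect_gte(attr(tab, "relative_spread"), 0)
})
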