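# The finite-element kernel: corotational beams, tension cables, assembly,
# and the Newton solver, checked against closed forms and finite
# differences.

el <- function() {
  mat <- material_table()
  list(EA = mat$EA, EI = mat$EI, L0 = 0.3, beta0 = 0)
}

test_that("rigid motion produces zero beam forces (frame indifference)", {
  e <- el()
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p0 <- rbind(c(0, 0), c(0.3, 0))
  p1 <- t(R %*% t(p0)) + matrix(c(1.2, -0.4), 2, 2, byrow = TRUE)
  f <- beam_local_forces(e, p1, c(th, th))
  expect_equal(f$N, 0, tolerance = 1e-10)
  expect_equal(f$M_a, 0, tolerance = 1e-10)
  expect_equal(f$M_b, 0, tolerance = 1e-10)
})

test_that("pure stretch gives N = EA * strain; pure bending is antisymmetric", {
  e <- el()
  f <- beam_local_forces(e, rbind(c(0, 0), c(0.303, 0)))
  expect_equal(f$N, 53.878 * 0.01, tolerance = 1e-3)
  # symmetric local end rotations: no elongation, M_a = -M_b
  f2 <- beam_local_forces(e, rbind(c(0, 0), c(0.3, 0)), c(0.01, -0.01))
  expect_equal(f2$N, 0, tolerance = 1e-12)
  expect_equal(f2$M_a, -f2$M_b, tolerance = 1e-12)
})

test_that("beam tangent matches finite differences and is symmetric", {
  e <- el()
  set.seed(1)
  q <- c(0, 0, 0, 0.3, 0, 0) + rnorm(6, 0, 0.02)
  pos <- rbind(q[1:2], q[4:5]); rot <- q[c(3, 6)]
  K <- beam_tangent(e, pos, rot)
  expect_equal(K, t(K), tolerance = 1e-12)
  fd <- matrix(0, 6, 6)
  h <- 1e-7
  for (k in 1:6) {
    qp <- q; qp[k] <- qp[k] + h
    qm <- q; qm[k] <- qm[k] - h
    fd[, k] <- (actinform:::beam_global_forces(e, rbind(qp[1:2], qp[4:5]), qp[c(3, 6)]) -
                actinform:::beam_global_forces(e, rbind(qm[1:2], qm[4:5]), qm[c(3, 6)])) / (2 * h)
  }
  expect_lt(max(abs(K - fd)) / max(abs(fd)), 1e-5)
  # undeformed beam: axial entry is EA/L0
  K0 <- beam_tangent(e, rbind(c(0, 0), c(0.3, 0)))
  expect_equal(K0[1, 1], e$EA / e$L0, tolerance = 1e-9)
})

test_that("cable laws: constant force, elastic with slack", {
  # constant force: tension equals prestress at any separation
  cab <- list(L0 = 0.2, prestress = 0.003, stiffness = 0, mode = "constant_force")
  expect_equal(cable_force(cab, rbind(c(0, 0), c(0.5, 0.1)))$tension, 0.003,
               tolerance = 1e-6)
  expect_equal(cable_force(cab, rbind(c(0, 0), c(0.05, 0)))$tension, 0.003,
               tolerance = 1e-3)
  # elastic: linear law with prestress offset
  cab$mode <- "elastic"; cab$stiffness <- 0.6
  expect_equal(cable_force(cab, rbind(c(0, 0), c(0.22, 0)))$tension,
               0.003 + 0.6 * 0.1, tolerance = 1e-3)
  # zero-prestress elastic law is exactly linear and exactly slack
  cab$prestress <- 0
  expect_equal(cable_force(cab, rbind(c(0, 0), c(0.202, 0)))$tension,
               0.6 * 0.01, tolerance = 1e-12)
  expect_identical(cable_force(cab, rbind(c(0, 0), c(0.15, 0)))$tension, 0)
  # nodal forces equal and opposite along the chord
  cf <- cable_force(list(L0 = 0.2, prestress = 0.01, stiffness = 0,
                         mode = "constant_force"),
                    rbind(c(0, 0), c(0.2, 0.1)))
  expect_equal(cf$forces["a", ], -cf$forces["b", ], tolerance = 1e-12)
})

test_that("assembled residual and tangent are consistent on a toy network", {
  net <- make_ladder(cable_nodes = c(2L, 3L))
  fe <- actinform:::fe_from_network(net)
  set.seed(3)
  q <- fe$q0 + rnorm(length(fe$q0), 0, 0.02)
  for (mode in c("constant_force", "elastic")) {
    sys <- assemble_system(net, q, cable_mode = mode,
                           prestress = 0.003, stiffness = 0.6)
    expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-12)
    ndof <- length(q)
    fd <- matrix(0, ndof, ndof)
    h <- 1e-7
    for (k in seq_len(ndof)) {
      qp <- q; qp[k] <- qp[k] + h
      qm <- q; qm[k] <- qm[k] - h
      fp <- assemble_system(net, qp, cable_mode = mode, prestress = 0.003,
                            stiffness = 0.6, tangent = FALSE)$f
      fm <- assemble_system(net, qm, cable_mode = mode, prestress = 0.003,
                            stiffness = 0.6, tangent = FALSE)$f
      fd[, k] <- (fp - fm) / (2 * h)
    }
    expect_lt(max(abs(as.matrix(sys$K) - fd)) / max(abs(fd)), 1e-5)
  }
  # zero displacement, no prestress: zero residual
  sys0 <- assemble_system(net, cable_mode = "elastic", prestress = 0,
                          stiffness = 0.6)
  expect_equal(max(abs(sys0$f)), 0, tolerance = 1e-14)
})

test_that("cantilever tip deflection matches qL^3/(3EI)", {
  chain <- make_chain(10, 3)
  net <- make_network(chain$nodes, chain$beams)
  P <- 1e-6  # small transverse load: linear regime
  st <- solve_equilibrium(net,
                          fixed = tibble::tibble(node = 1L,
                                                 which = c("x", "y", "rot"),
                                                 value = 0),
                          forces = tibble::tibble(node = 11L, which = "y",
                                                  value = P),
                          settings = tight_settings(), n_increments = 1)
  mat <- material_table()
  expect_equal(unname(st$coordinates[11, 2]), P * 27 / (3 * mat$EI),
               tolerance = 0.01)
})

test_that("axial bar elongation matches FL/EA and energy balances work", {
  chain <- make_chain(10, 3)
  net <- make_network(chain$nodes, chain$beams)
  F <- 0.01
  st <- solve_equilibrium(net,
                          fixed = tibble::tibble(node = 1L,
                                                 which = c("x", "y", "rot"),
                                                 value = 0),
                          forces = tibble::tibble(node = 11L, which = "x",
                                                  value = F),
                          settings = tight_settings())
  mat <- material_table()
  u <- unname(st$coordinates[11, 1]) - 3
  expect_equal(u, F * 3 / mat$EA, tolerance = 1e-6)
  # external work 1/2 F u equals the total strain energy
  en <- strain_energy(net, st)
  expect_equal(sum(en$se_total), 0.5 * F * u, tolerance = 0.005)
  # pure axial: all energy is axial
  expect_lt(sum(en$se_bending) / sum(en$se_total), 1e-6)
})

test_that("pure bending stores almost no axial energy", {
  chain <- make_chain(10, 3)
  net <- make_network(chain$nodes, chain$beams)
  st <- solve_equilibrium(net,
                          fixed = tibble::tibble(node = 1L,
                                                 which = c("x", "y", "rot"),
                                                 value = 0),
                          forces = tibble::tibble(node = 11L, which = "y",
                                                  value = 1e-6),
                          settings = tight_settings())
  en <- strain_energy(net, st)
  expect_lt(sum(en$se_axial) / sum(en$se_total), 1e-3)
})

test_that("equilibrium is frame indifferent and reproducible", {
  net <- make_ladder(cable_nodes = c(2L, 3L))
  fixed <- tibble::tibble(node = c(1L, 1L, 1L, 4L, 5L, 5L, 8L),
                          which = c("x", "y", "rot", "y", "x", "y", "y"),
                          value = c(0, 0, 0, 0, 0, 0.2, 0.2))
  st1 <- solve_equilibrium(net, fixed, cable_mode = "constant_force",
                           prestress = 0.003, settings = tight_settings())
  st2 <- solve_equilibrium(net, fixed, cable_mode = "constant_force",
                           prestress = 0.003, settings = tight_settings())
  expect_identical(st1$q, st2$q)   # bit-reproducible
  # elementwise internal forces unchanged under a rigid transform of the
  # converged configuration
  th <- 0.31; c0 <- cos(th); s0 <- sin(th)
  q <- st1$q
  n <- NROW(net$nodes)
  xi <- q[dof_index(1:n, "x")]; yi <- q[dof_index(1:n, "y")]
  q2 <- q
  q2[dof_index(1:n, "x")] <- c0 * xi - s0 * yi + 0.8
  q2[dof_index(1:n, "y")] <- s0 * xi + c0 * yi - 0.2
  q2[dof_index(1:n, "rot")] <- q[dof_index(1:n, "rot")] + th
  s1 <- assemble_system(net, q, cable_mode = "constant_force",
                        prestress = 0.003, tangent = FALSE)
  s2 <- assemble_system(net, q2, cable_mode = "constant_force",
                        prestress = 0.003, tangent = FALSE)
  expect_equal(s2$beam_forces$N, s1$beam_forces$N, tolerance = 1e-10)
  expect_equal(s2$beam_forces$M_a, s1$beam_forces$M_a, tolerance = 1e-10)
  expect_equal(s2$cable_tensions, s1$cable_tensions, tolerance = 1e-10)
})

test_that("Newton converges quadratically near the solution", {
  chain <- make_chain(8, 2)
  net <- make_network(chain$nodes, chain$beams)
  # moderately nonlinear: sizeable transverse tip load
  st <- solve_equilibrium(net,
                          fixed = tibble::tibble(node = 1L,
                                                 which = c("x", "y", "rot"),
                                                 value = 0),
                          forces = tibble::tibble(node = 9L, which = "y",
                                                  value = 2e-4),
                          settings = tight_settings(verbose = FALSE),
                          n_increments = 1)
  expect_true(st$converged)
  # re-solve recording residuals via the verbose stream
  msgs <- capture_messages(
    solve_equilibrium(net,
                      fixed = tibble::tibble(node = 1L,
                                             which = c("x", "y", "rot"),
                                             value = 0),
                      forces = tibble::tibble(node = 9L, which = "y",
                                              value = 2e-4),
                      settings = tight_settings(verbose = TRUE),
                      n_increments = 1))
  rn <- as.numeric(sub(".*residual ([0-9.e+-]+) .*", "\\1",
                       grep("residual", msgs, value = TRUE)))
  rn <- rn[rn > 0]
  # quadratic tail: successive ratios shrink fast once near the solution
  tail_r <- rn[length(rn) - 1] / rn[length(rn) - 2]
  expect_lt(tail_r, 0.05)
})

test_that("stress units come out in kPa for unit-consistent inputs", {
  # a 1 um^2 cross-section bar with E = 1 nN/um^2 stretched 1% carries
  # 0.01 nN/um^2 = 0.01 kPa
  mat <- material_table(filament_modulus = 1, filament_diameter = 2 / sqrt(pi))
  expect_equal(mat$EA, 1, tolerance = 1e-12)
})
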