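# Virtual experiments: uniaxial extension, modulus, orientations, energy
# partition, yield screening.

spanning_network <- function() {
  # one horizontal filament spanning the full 10 um domain
  chain <- make_chain(20, 10)
  chain$nodes$y <- 5
  make_network(chain$nodes, chain$beams,
               cfg = generation_config(seed = 1))
}

ff_of <- function(net, ...) suppressWarnings(run_form_finding(net, ...))

test_that("zero target strain is the identity", {
  net <- spanning_network()
  ff <- ff_of(net)
  traj <- uniaxial_stretch(ff, 0, settings = tight_settings())
  r <- traj$results[[1]]
  expect_equal(r$strain_level, 0)
  expect_lt(abs(r$reaction_force), 1e-6)
})

test_that("a spanning filament reproduces the axial-bar closed form", {
  net <- spanning_network()
  mat <- net$materials
  ff <- ff_of(net)
  traj <- uniaxial_stretch(ff, 0.01, settings = tight_settings())
  r <- traj$results[[1]]
  # reaction = EA * strain; modulus = EA / (H t) = 5.39 kPa
  expect_equal(r$reaction_force, mat$EA * 0.01, tolerance = 1e-3)
  expect_equal(effective_modulus(r), mat$EA / 10, tolerance = 1e-3)
  expect_equal(effective_modulus(r), 5.39, tolerance = 1e-3)
  # the filament carries 0.539 nN > 0.25 nN yield: flagged, not enforced
  expect_gt(r$yielded_beams, 0)
  expect_equal(r$yielded_cables, 0)
})

test_that("doubling the domain thickness halves the modulus", {
  net <- spanning_network()
  net$config$domain_thickness <- 2
  ff <- ff_of(net)
  traj <- uniaxial_stretch(ff, 0.01, settings = tight_settings())
  expect_equal(effective_modulus(traj), 5.39 / 2, tolerance = 1e-3)
})

test_that("the plane-stress formula reduces exactly to sigma_x / eps_x", {
  net <- spanning_network()
  ff <- ff_of(net)
  traj <- uniaxial_stretch(ff, 0.01, settings = tight_settings())
  r <- traj$results[[1]]
  expect_identical(r$sigma_y, 0)
  expect_equal(effective_modulus(r), r$sigma_x / r$strain_level,
               tolerance = 1e-12)
})

test_that("reactions balance between the fixed and displaced edges", {
  net <- suppressWarnings(build_network(
    small_cfg(seed = 3, target_relative_density = 8e-4)))
  tight <- solver_settings(rtol = 1e-3)
  ff <- ff_of(net, settings = tight)
  traj <- suppressWarnings(uniaxial_stretch(ff, 0.01, settings = tight))
  st <- traj$results[[1]]$state
  r <- numeric(3 * NROW(net$nodes))
  r[st$fixed_dof] <- st$reactions
  W <- net$config$domain_width
  left <- dof_index(which(net$nodes$x <= 0.02 * W), "x")
  right <- dof_index(which(net$nodes$x >= W - 0.02 * W), "x")
  expect_equal(sum(r[left]), -sum(r[right]), tolerance = 0.02)
})

test_that("angles fold into [0, 90] and an aligned toy sits in one bin", {
  chain <- make_chain(10, 3)
  net <- make_network(chain$nodes, chain$beams)
  h <- orientation_histogram(net)
  expect_equal(sum(h$count), 10)
  expect_equal(h$count[1], 10)   # all horizontal
  ang <- segment_orientations(net)
  expect_true(all(ang >= 0 & ang <= 90))
})

test_that("stretching aligns segments toward the load axis", {
  net <- suppressWarnings(build_network(small_cfg(seed = 6)))
  ff <- ff_of(net)
  st <- solver_settings(max_strain_increment = 0.15)
  traj <- suppressWarnings(
    uniaxial_stretch(ff, 0.3, checkpoints = c(0.15, 0.3), settings = st))
  a0 <- mean(segment_orientations(net, ff$state))
  a1 <- mean(traj$results[[1]]$segment_angles)
  a2 <- mean(traj$results[[2]]$segment_angles)
  expect_lt(a1, a0)
  expect_lt(a2, a1)
})

test_that("per-filament energies sum to the system total", {
  net <- suppressWarnings(build_network(small_cfg(seed = 7)))
  ff <- ff_of(net)
  traj <- suppressWarnings(uniaxial_stretch(ff, 0.01))
  r <- traj$results[[1]]
  en <- strain_energy(net, r$state)
  bf <- r$state$beam_forces
  fe <- actinform:::fe_from_network(net)
  direct <- sum(bf$N^2 * fe$bL0 / (2 * fe$bEA)) +
    sum(fe$bL0 * (bf$M_a^2 - bf$M_a * bf$M_b + bf$M_b^2) / (6 * fe$bEI))
  expect_equal(sum(en$se_total), direct, tolerance = 1e-6)
  # histogram covers every filament with measurable energy
  h <- energy_partition_histogram(net, r$state)
  expect_equal(sum(h$count) + attr(h, "n_excluded"), NROW(net$filaments))
  expect_true(all(r$energy_fractions >= 0 & r$energy_fractions <= 1,
                  na.rm = TRUE))
})

test_that("yield screening counts strict exceedances only", {
  st <- list(beam_forces = tibble::tibble(N = c(0.25, 0.2500001, -4)),
             cable_tensions = c(0.06, 0.0601))
  ys <- yield_screen(st, material_table())
  expect_equal(ys$yielded_beams, 1)
  expect_equal(ys$yielded_cables, 1)
})

test_that("an empty edge band raises a clear error", {
  # a short central filament never reaches the domain edges
  chain <- make_chain(4, 1.2)
  chain$nodes$x <- chain$nodes$x + 4
  chain$nodes$y <- 5
  net <- make_network(chain$nodes, chain$beams,
                      cfg = generation_config(seed = 1))
  ff <- ff_of(net)
  expect_error(uniaxial_stretch(ff, 0.01), "edge band")
})
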