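# Hand-built fixtures: straight beam chains, two-filament toys, and small
# random networks, all constructed in code.

# a single straight filament discretised into n equal beams
make_chain <- function(n, L, angle = 0, y0 = 0, filament = 1L,
                       node_offset = 0L) {
  xs <- seq(0, L, length.out = n + 1)
  nodes <- tibble::tibble(id = node_offset + seq_len(n + 1),
                          x = xs * cos(angle),
                          y = y0 + xs * sin(angle),
                          filament = filament)
  beams <- tibble::tibble(id = seq_len(n),
                          node_a = node_offset + 1:n,
                          node_b = node_offset + 2:(n + 1),
                          filament = filament,
                          length0 = diff(xs))
  list(nodes = nodes, beams = beams)
}

# assemble a filament_network object from parts
make_network <- function(nodes, beams, cables = NULL, cfg = NULL,
                         materials = NULL) {
  if (is.null(cables))
    cables <- tibble::tibble(id = integer(), node_a = integer(),
                             node_b = integer(), length0 = numeric())
  if (is.null(cfg)) cfg <- generation_config(seed = 1)
  if (is.null(materials)) materials <- material_table()
  comp <- actinform:::network_components(NROW(nodes), beams, cables)
  structure(list(
    filaments = tibble::tibble(id = unique(nodes$filament)),
    nodes = nodes, beams = beams, cables = cables,
    materials = materials, config = cfg,
    achieved_relative_density = NA_real_,
    component = comp$membership, n_components = comp$no,
    seed = cfg$seed
  ), class = "filament_network")
}

# two parallel horizontal filaments joined by vertical cables at matching
# nodes; well-posed when ends are clamped
make_ladder <- function(n = 3, L = 0.9, gap = 0.2, cable_nodes = 2L) {
  a <- make_chain(n, L, filament = 1L)
  b <- make_chain(n, L, y0 = gap, filament = 2L, node_offset = n + 1L)
  cables <- tibble::tibble(id = seq_along(cable_nodes),
                           node_a = as.integer(cable_nodes),
                           node_b = as.integer(cable_nodes + n + 1L),
                           length0 = gap)
  make_network(rbind(a$nodes, b$nodes), rbind(a$beams, b$beams), cables)
}

# a small, fast, well-connected random network for integration tests
small_cfg <- function(seed = 1, target_relative_density = 0.0015, ...) {
  generation_config(domain_width = 4, domain_height = 4,
                    filament_length_mean = 1.6, filament_length_std = 0.3,
                    target_relative_density = target_relative_density,
                    seed = seed, ...)
}

tight_settings <- function(...) {
  solver_settings(rtol = 3e-7, regularization = 0, rot_regularization = 0,
                  tangent_update = "every_iteration", ...)
}
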