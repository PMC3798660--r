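# Random network generation: sequential filament placement, segmentation
# into binding sites, and proximity cross-linking.

# Truncated-Gaussian draw by rejection: negative (and, optionally,
# too-large) values are thrown out and redrawn.
draw_trunc_norm <- function(mean, sd, upper = Inf, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    v <- stats::rnorm(1L, mean, sd)
    if (v > 0 && v < upper) return(v)
  }
  stop("truncated-normal rejection sampling failed after ", max_tries,
       " draws (mean = ", mean, ", sd = ", sd, ", upper = ", upper, ")",
       call. = FALSE)
}

# Rigid translation of a filament into the domain: per axis, the minimal
# shift that brings both endpoints inside; angle and length unchanged.
place_filament <- function(length, cx, cy, angle, cfg) {
  hx <- length / 2 * cos(angle)
  hy <- length / 2 * sin(angle)
  x <- c(cx - hx, cx + hx)
  y <- c(cy - hy, cy + hy)
  dx <- 0
  if (min(x) < 0) dx <- -min(x)
  else if (max(x) > cfg$domain_width) dx <- cfg$domain_width - max(x)
  dy <- 0
  if (min(y) < 0) dy <- -min(y)
  else if (max(y) > cfg$domain_height) dy <- cfg$domain_height - max(y)
  tibble::tibble(cx = cx + dx, cy = cy + dy,
                 angle = angle, length = length,
                 x1 = x[1] + dx, y1 = y[1] + dy,
                 x2 = x[2] + dx, y2 = y[2] + dy)
}

#' Sample one filament
#'
#' Draws a filament length from the truncated Gaussian length distribution
#' (non-positive draws, and draws too long to fit the domain, are rejected
#' and redrawn), a centroid uniform over the domain, and an orientation
#' uniform on \[0, 2*pi). If an endpoint falls outside the domain the whole
#' filament is rigidly translated inside by the minimal axis-aligned shift.
#'
#' @param cfg A [generation_config()].
#' @return One-row tibble with columns `cx`, `cy`, `angle`, `length` and the
#'   endpoint coordinates `x1`, `y1`, `x2`, `y2`.
#' @export
sample_filament <- function(cfg) {
  validate_generation_config(cfg)
  len <- draw_trunc_norm(cfg$filament_length_mean, cfg$filament_length_std,
                         upper = min(cfg$domain_width, cfg$domain_height))
  cx <- stats::runif(1L, 0, cfg$domain_width)
  cy <- stats::runif(1L, 0, cfg$domain_height)
  angle <- stats::runif(1L, 0, 2 * pi)
  place_filament(len, cx, cy, angle, cfg)
}

#' Filament volume fraction of a set of filaments
#'
#' The relative density is the total filament volume (cylinders of the
#' configured diameter) per unit domain volume.
#'
#' @param filaments Tibble with a `length` column (um), as produced by
#'   [generate_filaments()].
#' @param cfg A [generation_config()].
#' @return A single fraction.
#' @examples
#' cfg <- generation_config()
#' relative_density(tibble::tibble(length = 5), cfg)  # ~1.92e-6
#' @export
relative_density <- function(filaments, cfg) {
  validate_generation_config(cfg)
  if (NROW(filaments) == 0) return(0)
  vol <- pi * cfg$filament_diameter^2 / 4 * sum(filaments$length)
  vol / (cfg$domain_width * cfg$domain_height * cfg$domain_thickness)
}

#' Sequentially place filaments until the target density is reached
#'
#' Filaments are sampled one at a time ([sample_filament()]) and placed into
#' the domain until the filament volume fraction first reaches
#' `cfg$target_relative_density`; the filament that crosses the threshold is
#' kept, so the achieved density overshoots by at most one filament's
#' contribution.
#'
#' @inheritParams sample_filament
#' @return Tibble of filaments (`id`, `cx`, `cy`, `angle`, `length`,
#'   endpoints), with attribute `achieved_relative_density`.
#' @export
generate_filaments <- function(cfg) {
  validate_generation_config(cfg)
  per_fil <- pi * cfg$filament_diameter^2 / 4 * cfg$filament_length_mean
  dom_vol <- cfg$domain_width * cfg$domain_height * cfg$domain_thickness
  n_guess <- ceiling(cfg$target_relative_density * dom_vol / per_fil)
  max_fil <- max(1000L, 20L * n_guess)
  out <- vector("list", n_guess + 16L)
  acc_len <- 0
  target_len <- cfg$target_relative_density * dom_vol /
    (pi * cfg$filament_diameter^2 / 4)
  n <- 0L
  while (acc_len < target_len) {
    if (n >= max_fil)
      stop("filament placement did not reach the target density after ",
           max_fil, " filaments; check the configuration", call. = FALSE)
    n <- n + 1L
    fil <- sample_filament(cfg)
    acc_len <- acc_len + fil$length
    if (n > length(out)) out <- c(out, vector("list", length(out)))
    out[[n]] <- fil
  }
  filaments <- dplyr::bind_rows(out[seq_len(n)])
  filaments <- dplyr::mutate(filaments, id = dplyr::row_number(),
                             .before = 1L)
  attr(filaments, "achieved_relative_density") <-
    relative_density(filaments, cfg)
  filaments
}

# Partition one filament length into segment lengths: draw truncated-normal
# segment lengths while more than one mean segment length remains; the final
# remainder merges into the previous segment when shorter than half the mean
# segment length, otherwise it stands alone.  A filament shorter than the
# mean segment length is a single segment.
segment_lengths <- function(L, cfg) {
  if (L <= 0) stop("filament length must be positive", call. = FALSE)
  m <- cfg$segment_length_mean
  segs <- numeric(0)
  rem <- L
  while (rem > m) {
    s <- draw_trunc_norm(m, cfg$segment_length_std, upper = rem)
    segs <- c(segs, s)
    rem <- rem - s
  }
  if (rem > 0) {
    if (length(segs) > 0 && rem < m / 2)
      segs[length(segs)] <- segs[length(segs)] + rem
    else
      segs <- c(segs, rem)
  }
  segs
}

#' Divide filaments into segments bounded by binding-site nodes
#'
#' Each filament is partitioned into consecutive segments whose lengths are
#' drawn from the truncated Gaussian segment-length distribution; every
#' segment end (including the filament endpoints) becomes a node, i.e. a
#' cross-linker binding site, and every segment becomes one beam finite
#' element.
#'
#' @param filaments Tibble from [generate_filaments()].
#' @inheritParams sample_filament
#' @return List with tibbles `nodes` (`id`, `x`, `y`, `filament`) and
#'   `beams` (`id`, `node_a`, `node_b`, `filament`, `length0`).
#' @export
segment_filaments <- function(filaments, cfg) {
  validate_generation_config(cfg)
  n_fil <- NROW(filaments)
  node_x <- vector("list", n_fil); node_y <- vector("list", n_fil)
  node_f <- vector("list", n_fil); seg_l <- vector("list", n_fil)
  for (i in seq_len(n_fil)) {
    segs <- segment_lengths(filaments$length[i], cfg)
    tpos <- c(0, cumsum(segs)) / filaments$length[i]
    node_x[[i]] <- filaments$x1[i] + tpos * (filaments$x2[i] - filaments$x1[i])
    node_y[[i]] <- filaments$y1[i] + tpos * (filaments$y2[i] - filaments$y1[i])
    node_f[[i]] <- rep(filaments$id[i], length(tpos))
    seg_l[[i]] <- segs
  }
  nodes <- tibble::tibble(
    id = seq_along(unlist(node_x, use.names = FALSE)),
    x = unlist(node_x, use.names = FALSE),
    y = unlist(node_y, use.names = FALSE),
    filament = unlist(node_f, use.names = FALSE)
  )
  counts <- lengths(node_x)
  first <- cumsum(c(1L, counts[-length(counts)]))
  beam_a <- unlist(lapply(seq_len(n_fil), function(i)
    first[i] + seq_len(counts[i] - 1L) - 1L), use.names = FALSE)
  beams <- tibble::tibble(
    id = seq_along(beam_a),
    node_a = beam_a,
    node_b = beam_a + 1L,
    filament = unlist(lapply(seq_len(n_fil), function(i)
      rep(filaments$id[i], counts[i] - 1L)), use.names = FALSE),
    length0 = unlist(seg_l, use.names = FALSE)
  )
  list(nodes = nodes, beams = beams)
}

# Brute-force all-pairs candidate search; reference implementation used to
# validate the grid-binned search on small networks.
crosslink_candidates_bruteforce <- function(nodes, rmax, rmin = 0.05) {
  n <- NROW(nodes)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(cbind(nodes$x, nodes$y)))
  keep <- which(upper.tri(d) & d < rmax & d > rmin &
                  outer(nodes$filament, nodes$filament, "!="),
                arr.ind = TRUE)
  keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
}

#' Create cross-linkers between nearby binding sites
#'
#' Candidate cross-linkers connect every unordered pair of nodes that lie on
#' distinct filaments and are strictly closer than the maximum cross-linker
#' length (and strictly farther than zero: exactly coincident binding
#' sites, which arise when two filaments are clamped into the same domain
#' corner, cannot host a finite cross-linker).  The spatial search uses
#' grid binning and returns exactly the brute-force all-pairs result.
#'
#' A binding site is then allowed to host at most `site_capacity`
#' cross-linkers (default 1: one cross-linking protein per site), assigned
#' greedily in order of increasing separation — the closest available
#' pairs bind first.  This matching is what keeps individual filaments at
#' the connection counts seen in real networks: a short (0.6 um) filament
#' ends up with one or two cross-linkers, a long (6 um) one with ten or
#' more.  `site_capacity = Inf` disables the limit and connects every
#' candidate pair.  Finally each retained cross-linker survives
#' independently with probability `cfg$crosslink_fraction`.
#'
#' @param nodes Node tibble from [segment_filaments()].
#' @param site_capacity Maximum cross-linkers per binding site; defaults
#'   to `cfg$site_capacity`.
#' @inheritParams sample_filament
#' @return Tibble of cables (`id`, `node_a`, `node_b`, `length0`).
#' @export
generate_crosslinkers <- function(nodes, cfg, site_capacity = NULL) {
  validate_generation_config(cfg)
  if (is.null(site_capacity))
    site_capacity <- cfg$site_capacity %||% 1
  pairs <- cpp_proximity_pairs(nodes$x, nodes$y,
                               as.integer(nodes$filament),
                               cfg$max_crosslinker_length,
                               cfg$min_crosslinker_length %||% 0.05)
  if (nrow(pairs) > 1) {
    o <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[o, , drop = FALSE]
  }
  len0 <- sqrt((nodes$x[pairs[, 1]] - nodes$x[pairs[, 2]])^2 +
                 (nodes$y[pairs[, 1]] - nodes$y[pairs[, 2]])^2)
  if (is.finite(site_capacity) && nrow(pairs) > 0) {
    keep <- cpp_greedy_capacity(pairs[, 1], pairs[, 2],
                                order(len0), NROW(nodes),
                                as.integer(site_capacity))
    pairs <- pairs[keep, , drop = FALSE]
    len0 <- len0[keep]
  }
  if (cfg$crosslink_fraction < 1 && nrow(pairs) > 0) {
    keep <- stats::runif(nrow(pairs)) < cfg$crosslink_fraction
    pairs <- pairs[keep, , drop = FALSE]
    len0 <- len0[keep]
  }
  tibble::tibble(id = seq_len(nrow(pairs)),
                 node_a = pairs[, 1], node_b = pairs[, 2],
                 length0 = len0)
}

# Connected components of the node graph spanned by beams and cables.
network_components <- function(n_nodes, beams, cables) {
  edges <- rbind(cbind(beams$node_a, beams$node_b),
                 cbind(cables$node_a, cables$node_b))
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (NROW(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)
}

#' Build a complete random cross-linked filament network
#'
#' Composes the four generation steps: sequential filament placement to the
#' target density, segmentation into binding sites, proximity
#' cross-linking, and assembly into a single network object carrying its
#' materials and configuration.  With a fixed `cfg$seed` the result is
#' fully reproducible.
#'
#' @inheritParams sample_filament
#' @param materials A [material_table()]; by default derived from the
#'   configured filament diameter.
#' @return A `filament_network` object: tibbles `filaments`, `nodes`,
#'   `beams`, `cables`, plus `materials`, `config`,
#'   `achieved_relative_density`, and per-node connected-`component` labels.
#' @examples
#' net <- build_network(generation_config(
#'   domain_width = 6, domain_height = 6, filament_length_mean = 2,
#'   filament_length_std = 0.5, target_relative_density = 2e-4, seed = 42))
#' net
#' @export
build_network <- function(cfg, materials = NULL) {
  validate_generation_config(cfg)
  if (is.null(materials))
    materials <- material_table(filament_diameter = cfg$filament_diameter)
  gen <- function() {
    filaments <- generate_filaments(cfg)
    seg <- segment_filaments(filaments, cfg)
    cables <- generate_crosslinkers(seg$nodes, cfg)
    list(filaments = filaments, nodes = seg$nodes, beams = seg$beams,
         cables = cables)
  }
  parts <- if (is.null(cfg$seed)) gen() else
    withr::with_seed(as.integer(cfg$seed), gen())

  comp <- network_components(NROW(parts$nodes), parts$beams, parts$cables)
  net <- structure(list(
    filaments = parts$filaments,
    nodes = parts$nodes,
    beams = parts$beams,
    cables = parts$cables,
    materials = materials,
    config = cfg,
    achieved_relative_density =
      attr(parts$filaments, "achieved_relative_density"),
    component = comp$membership,
    n_components = comp$no,
    seed = cfg$seed
  ), class = "filament_network")
  if (comp$no > 1L)
    warning("network has ", comp$no, " disconnected components",
            call. = FALSE)
  net
}

#' @export
print.filament_network <- function(x, ...) {
  cat("<filament_network>\n")
  cat(sprintf("  domain: %g x %g x %g um\n", x$config$domain_width,
              x$config$domain_height, x$config$domain_thickness))
  cat(sprintf("  %d filaments, %d nodes, %d beams, %d cables\n",
              NROW(x$filaments), NROW(x$nodes), NROW(x$beams),
              NROW(x$cables)))
  cat(sprintf("  achieved relative density: %.4g (target %.4g)\n",
              x$achieved_relative_density,
              x$config$target_relative_density))
  cat(sprintf("  connected components: %d\n", x$n_components))
  invisible(x)
}
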