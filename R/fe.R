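# Large-deformation 2D finite-element kernel: corotational Euler-Bernoulli
# beams (3 DOF/node: ux, uy, rotation) for filament segments and
# tension-only cables (translational DOF) for cross-linkers.
#
# Internal unit system: um (length), nN (force), nN um (moment).  With
# these units 1 nN/um^2 = 1 kPa, so effective stresses are natively kPa.

#' Global DOF indices for nodes
#'
#' Each node carries three DOF in the order `x`, `y`, `rot`.
#'
#' @param node Integer node ids.
#' @param which One of `"x"`, `"y"`, `"rot"` (recycled against `node`).
#' @return Integer DOF indices.
#' @export
dof_index <- function(node, which = "x") {
  off <- match(which, c("x", "y", "rot"))
  if (anyNA(off)) stop("`which` must be \"x\", \"y\" or \"rot\"", call. = FALSE)
  (as.integer(node) - 1L) * 3L + off
}

# Internal flat FE representation used by the C++ kernels.
# q layout: (x1, y1, th1, x2, y2, th2, ...) with absolute coordinates.
fe_from_network <- function(network) {
  nodes <- network$nodes
  beams <- network$beams
  cables <- network$cables
  mat <- network$materials
  n <- NROW(nodes)
  q0 <- numeric(3L * n)
  q0[dof_index(seq_len(n), "x")] <- nodes$x
  q0[dof_index(seq_len(n), "y")] <- nodes$y
  dx <- nodes$x[beams$node_b] - nodes$x[beams$node_a]
  dy <- nodes$y[beams$node_b] - nodes$y[beams$node_a]
  out <- list(
    nnode = n,
    q0 = q0,
    ba = as.integer(beams$node_a), bb = as.integer(beams$node_b),
    bL0 = sqrt(dx^2 + dy^2),
    bBeta0 = atan2(dy, dx),
    bEA = rep_len(mat$EA, NROW(beams)),
    bEI = rep_len(mat$EI, NROW(beams)),
    ca = as.integer(cables$node_a), cb = as.integer(cables$node_b),
    cL0 = if (NROW(cables)) cables$length0 else numeric(0),
    materials = mat
  )
  # chain metadata for static condensation of rotational DOF: valid when
  # every filament's nodes are consecutive ids and its beams connect them
  # in order (guaranteed by the generator)
  fil <- nodes$filament
  if (!is.null(fil) && NROW(beams) > 0) {
    first <- which(c(TRUE, fil[-1] != fil[-length(fil)]))
    len <- diff(c(first, length(fil) + 1L))
    ok <- identical(as.integer(beams$node_a + 1L), as.integer(beams$node_b)) &&
      all(len >= 2L) &&
      NROW(beams) == length(fil) - length(first)
    if (ok) {
      out$chain_first <- as.integer(first)
      out$chain_len <- as.integer(len)
    }
  }
  out
}

fe_call_condensed <- function(fe, q, cable_mode, prestress, stiffness,
                              rot_reg, r_extra, cable_floor = 0.005) {
  cpp_system_condensed(q, fe$nnode, fe$ba, fe$bb, fe$bL0, fe$bBeta0,
                       fe$bEA, fe$bEI,
                       integer(0), fe$chain_first, fe$chain_len,
                       fe$ca, fe$cb, fe$cL0,
                       if (cable_mode == "constant_force") 0L else 1L,
                       prestress, stiffness, cable_floor, rot_reg, r_extra)
}

fe_call <- function(fe, q, cable_mode, prestress, stiffness, want_tangent,
                    cable_floor = 0.005, psd_tangent = FALSE) {
  cpp_system(q, fe$nnode, fe$ba, fe$bb, fe$bL0, fe$bBeta0, fe$bEA, fe$bEI,
             fe$ca, fe$cb, fe$cL0,
             if (cable_mode == "constant_force") 0L else 1L,
             prestress, stiffness, cable_floor, want_tangent, psd_tangent)
}

#' Assemble the global residual and tangent of a network
#'
#' Evaluates the internal force vector (3 DOF per node) and, optionally,
#' the consistent tangent stiffness (sparse, symmetric) at a configuration.
#'
#' @param network A `filament_network` (or an internal FE model).
#' @param q Configuration vector `(x1, y1, th1, ...)` of absolute nodal
#'   coordinates and rotations; defaults to the reference geometry.
#' @param cable_mode `"constant_force"` (form-finding: tension equals the
#'   pre-stress regardless of length) or `"elastic"` (tension-only linear
#'   law with pre-stress offset).
#' @param prestress Cable pre-stress force (nN).
#' @param stiffness Cable axial stiffness (nN per unit strain), elastic mode.
#' @param tangent Also return the sparse tangent matrix.
#' @return List with `f` (internal force vector), element force tibbles,
#'   and (if requested) `K` (a `dsCMatrix`).
#' @export
assemble_system <- function(network, q = NULL,
                            cable_mode = c("elastic", "constant_force"),
                            prestress = NULL, stiffness = NULL,
                            tangent = TRUE) {
  cable_mode <- match.arg(cable_mode)
  fe <- if (inherits(network, "filament_network")) fe_from_network(network)
        else network
  if (is.null(prestress)) prestress <- fe$materials$crosslinker_prestress
  if (is.null(stiffness)) stiffness <- fe$materials$crosslinker_axial_stiffness
  if (is.null(q)) q <- fe$q0
  sys <- fe_call(fe, q, cable_mode, prestress, stiffness, tangent)
  out <- list(
    f = sys$f,
    beam_forces = tibble::tibble(id = seq_along(sys$N), N = sys$N,
                                 M_a = sys$M1, M_b = sys$M2, shear = sys$V),
    cable_tensions = sys$T
  )
  if (tangent)
    out$K <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$x,
                                  dims = c(3L * fe$nnode, 3L * fe$nnode),
                                  symmetric = TRUE)
  out
}

# Geometric nested-dissection ordering for the (node-level) coupling graph.
# The network couples all nodes within the cross-linker radius, giving a
# disk graph whose local cliques make generic fill-reducing orderings (AMD)
# fill catastrophically; recursive coordinate bisection with vertex
# separators taken from the endpoints of cut-crossing edges exploits the
# geometry directly.  Returns a node ordering (separators last).
nd_node_order <- function(x, y, ea, eb, leaf = 40L) {
  n <- length(x)
  out <- integer(n)
  pos <- n  # fill from the back: separators of outer levels go last
  rec <- function(idx, ea, eb) {
    if (length(idx) <= leaf) {
      if (length(idx)) {
        out[pos - length(idx) + seq_along(idx)] <<- idx
        pos <<- pos - length(idx)
      }
      return(invisible())
    }
    xs <- x[idx]; ys <- y[idx]
    cv <- if (diff(range(xs)) >= diff(range(ys))) x else y
    m <- stats::median(cv[idx])
    is_left <- cv[idx] <= m
    if (all(is_left) || !any(is_left)) {      # degenerate tie: split by rank
      o <- order(cv[idx])
      is_left <- seq_along(idx) %in% o[seq_len(length(idx) %/% 2)]
    }
    side <- logical(n)
    side[idx[is_left]] <- TRUE
    cross <- side[ea] != side[eb]
    ca <- ea[cross]; cb <- eb[cross]
    sep <- unique(ifelse(abs(cv[ca] - m) <= abs(cv[cb] - m), ca, cb))
    if (length(sep)) {
      out[pos - length(sep) + seq_along(sep)] <<- sep
      pos <<- pos - length(sep)
    }
    in_sep <- logical(n); in_sep[sep] <- TRUE
    keep_e <- !cross & !in_sep[ea] & !in_sep[eb]
    ea <- ea[keep_e]; eb <- eb[keep_e]
    left <- idx[is_left]; left <- left[!in_sep[left]]
    right <- idx[!is_left]; right <- right[!in_sep[right]]
    e_in_left <- side[ea]
    rec(right, ea[!e_in_left], eb[!e_in_left])
    rec(left, ea[e_in_left], eb[e_in_left])
    invisible()
  }
  rec(seq_len(n), ea, eb)
  out
}

# DOF-level permutation of the free DOF set implied by the node ordering.
nd_free_permutation <- function(fe, free) {
  nodes_xy <- matrix(fe$q0, ncol = 3L, byrow = TRUE)
  ord <- nd_node_order(nodes_xy[, 1], nodes_xy[, 2],
                       c(fe$ba, fe$ca), c(fe$bb, fe$cb))
  dof_ord <- as.vector(rbind(3L * ord - 2L, 3L * ord - 1L, 3L * ord))
  pf <- match(dof_ord[dof_ord %in% free], free)
  pf
}

# Characteristic internal force used for the relative convergence norm:
# the largest element or applied force in the current state (pre-stress
# counts only when cables exist), floored from below.
characteristic_force <- function(sys, f_ext, prestress, floor) {
  max(floor,
      if (length(sys$T)) max(prestress, max(abs(sys$T))) else 0,
      if (length(sys$N)) max(abs(sys$N)) else 0,
      if (length(f_ext)) max(abs(f_ext)) else 0)
}

# Incremental Newton solution.  fixed_target holds absolute target values of
# q at the fixed DOF at full load; prescribed values and external forces are
# ramped linearly over the increments, and in constant-force (form-finding)
# mode the cable pre-stress itself is ramped (continuation in P).
# Regularisation springs anchor every DOF to the stage-start configuration.
#
# Linear solves use one of two strategies:
#  * "direct": assemble the sparse tangent (in geometric nested-dissection
#    order for large networks) and factor with CHOLMOD; the factor persists
#    across iterations and increments and is refreshed adaptively.
#  * "pcg": matrix-free conjugate gradients preconditioned by the
#    beams-plus-cable-diagonal matrix, whose chain structure factors in
#    O(n).  Chosen automatically for large form-finding solves, where the
#    cable coupling is weak (geometric only) and assembling/factoring the
#    full tangent would dominate the cost.
# Globalisation: per-component step clipping, an Armijo line search on the
# total potential (the system is conservative) with a residual-norm
# fallback at machine precision, and Levenberg damping that escalates on
# failures and decays on clean full steps.
newton_solve <- function(fe, q_start, fixed_idx, fixed_target,
                         f_ext = NULL, settings = solver_settings(),
                         cable_mode = "elastic",
                         prestress = NULL, stiffness = NULL,
                         n_increments = NULL, ramp_prestress = NULL,
                         guess_delta = NULL) {
  ndof <- 3L * fe$nnode
  if (is.null(prestress)) prestress <- fe$materials$crosslinker_prestress
  if (is.null(stiffness)) stiffness <- fe$materials$crosslinker_axial_stiffness
  if (is.null(f_ext)) f_ext <- numeric(ndof)
  if (is.null(n_increments)) n_increments <- settings$n_increments
  fixed_idx <- as.integer(fixed_idx)
  free <- setdiff(seq_len(ndof), fixed_idx)
  rr <- settings$reduce_rotations %||% "auto"
  if (identical(rr, "always") && !is.null(fe$chain_first) &&
      all((fixed_idx - 1L) %% 3L != 2L))
    return(newton_solve_condensed(fe, q_start, fixed_idx, fixed_target,
                                  f_ext, settings, cable_mode,
                                  prestress, stiffness, n_increments))
  reg <- rep(settings$regularization, ndof)
  reg[seq(3L, ndof, by = 3L)] <- settings$rot_regularization

  ls <- settings$linear_solver %||% "auto"
  use_pcg <- identical(ls, "pcg") ||
    (identical(ls, "auto") && identical(cable_mode, "constant_force") &&
       length(fe$ca) > 5000L && length(free) > 9000L)

  if (!use_pcg) {
    use_nd <- length(free) > 3000L && length(fe$ca) > 0L
    fdofs <- if (use_nd) free[nd_free_permutation(fe, free)] else free
    dof_map <- integer(ndof)
    dof_map[fdofs] <- seq_along(fdofs)
    dof_map[fixed_idx] <- length(free) + seq_along(fixed_idx)
    reg_perm <- reg[c(fdofs, fixed_idx)]
  } else {
    fe_beams <- fe
    fe_beams$ca <- integer(0); fe_beams$cb <- integer(0)
    fe_beams$cL0 <- numeric(0)
  }

  factorize <- function(Kff, lam) {
    A <- Kff
    if (lam > 0) {
      d <- Matrix::diag(A)
      # damp with lam * |diag| (plus a floor): diagonal entries can be
      # negative under strong compression, where a multiplicative scaling
      # could never restore positive definiteness
      Matrix::diag(A) <- d + lam * (abs(d) + 1e-8 * max(abs(d)))
    }
    bad <- FALSE
    ch <- withCallingHandlers(
      tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = !use_nd,
                                super = use_nd),
               error = function(e) NULL),
      warning = function(w) { bad <<- TRUE; invokeRestart("muffleWarning") })
    if (bad) ch <- NULL
    ch
  }

  # preconditioned CG on the free DOF, matrix-free operator; returns NULL
  # on breakdown (indefinite operator at the current damping)
  pcg <- function(q, P_inc, lam, dK, chM, b, tol_rel, maxit = 400L) {
    x <- numeric(length(b))
    r <- b
    b0 <- sqrt(sum(b^2))
    if (b0 == 0) return(x)
    z <- as.numeric(Matrix::solve(chM, r))
    p <- z
    rz <- sum(r * z)
    w <- numeric(ndof)
    for (it in seq_len(maxit)) {
      w[free] <- p
      Kw <- cpp_tangent_matvec(q, fe$nnode, fe$ba, fe$bb, fe$bL0, fe$bBeta0,
                               fe$bEA, fe$bEI, fe$ca, fe$cb, fe$cL0,
                               if (cable_mode == "constant_force") 0L else 1L,
                               P_inc, stiffness, 0.005, w)
      Ap <- Kw[free] + (reg[free] + lam * dK) * p
      pAp <- sum(p * Ap)
      if (!is.finite(pAp) || pAp <= 0) return(NULL)
      alpha <- rz / pAp
      x <- x + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) < tol_rel * b0) break
      z <- as.numeric(Matrix::solve(chM, r))
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    x
  }

  q <- q_start
  fixed_start <- q_start[fixed_idx]
  iters <- integer(n_increments)
  residual_hist <- numeric(0)
  converged_all <- TRUE
  sys <- NULL
  stalled <- FALSE
  damping <- 0
  Kff <- NULL
  ch <- NULL
  ch_damping <- -1
  stale_K <- FALSE
  if (is.null(ramp_prestress))
    ramp_prestress <- identical(cable_mode, "constant_force")

  # the secant predictor warm-starts each increment with the previous
  # increment's converged displacement field; an optional caller-supplied
  # guess (e.g. the affine field of a uniform stretch) seeds the first
  prev_dq <- if (!is.null(guess_delta)) guess_delta[free] / n_increments
             else NULL
  for (inc in seq_len(n_increments)) {
    lam_inc <- inc / n_increments
    q_inc_start <- q
    q[fixed_idx] <- fixed_start + lam_inc * (fixed_target - fixed_start)
    # secant predictor: warm-start the free DOF with the previous
    # increment's converged displacement field
    if (!is.null(prev_dq)) q[free] <- q[free] + prev_dq
    fx <- lam_inc * f_ext
    P_inc <- if (ramp_prestress) lam_inc * prestress else prestress
    rn_prev <- Inf
    converged <- FALSE
    stalled <- FALSE
    damp_floor <- 0
    rn_window <- rep(Inf, 15L)
    rn_best <- Inf
    stall_count <- 0L
    refresh_cooldown <- 0L
    just_refreshed <- FALSE
    if (!is.null(Kff)) stale_K <- TRUE
    potential <- function(sys, qv) {
      sys$energy - sum(fx * qv) + 0.5 * sum(reg * (qv - q_start)^2)
    }
    for (it in seq_len(settings$max_iterations)) {
      # a slow contraction rate triggers a tangent refresh; if the fresh
      # tangent does not restore a fast rate the slowness is caused by
      # marginally-constrained modes, not staleness, and refreshes pause
      # for a few iterations (factorisation is the dominant cost)
      if (just_refreshed && is.finite(rn_prev)) {
        if (rn > 0.8 * rn_prev) refresh_cooldown <- 8L
        just_refreshed <- FALSE
      }
      if (refresh_cooldown > 0L) refresh_cooldown <- refresh_cooldown - 1L
      need_K <- !use_pcg &&
        (is.null(Kff) || settings$tangent_update == "every_iteration" ||
           (it > 2L && is.finite(rn_prev) && rn > 0.8 * rn_prev &&
              refresh_cooldown == 0L))
      if (need_K && !is.null(Kff)) just_refreshed <- TRUE
      sys <- fe_call(fe, q, cable_mode, P_inc, stiffness, need_K,
                     psd_tangent =
                       settings$tangent_update != "every_iteration")
      r <- sys$f - fx + reg * (q - q_start)
      rn <- sqrt(sum(r[free]^2))
      V <- potential(sys, q)
      fchar <- characteristic_force(sys, fx, P_inc, settings$force_floor)
      if (it == 1L) rn_init <- rn
      tol_abs <- settings$rtol * max(fchar, rn_init)
      if (settings$verbose)
        message(sprintf("  inc %d it %d residual %.3e (tol %.3e) damping %.1e",
                        inc, it, rn, tol_abs, damping))
      residual_hist <- c(residual_hist, rn)
      if (rn < tol_abs) { converged <- TRUE; iters[inc] <- it; break }
      # CHOLMOD factor memory is outside R's heap accounting, so garbage
      # factors do not trigger collections on their own; the allocator
      # additionally needs a trim to return freed arenas to the OS
      if (it %% 5L == 0L) { gc(FALSE); cpp_malloc_trim() }
      # stagnation acceptance: marginally-constrained bodies (short
      # filaments whose cross-linkers sit at the slack boundary) can pin
      # the residual at a small multiple of the tolerance; when no real
      # progress is being made inside the relaxed band, accept and flag
      if (rn < 0.95 * rn_best) {
        rn_best <- rn
        stall_count <- 0L
      } else stall_count <- stall_count + 1L
      if (rn < 10 * tol_abs &&
          (stall_count >= 6L || it == settings$max_iterations)) {
        converged <- TRUE
        stalled <- TRUE
        iters[inc] <- it
        warning("equilibrium accepted at a stalled residual ",
                signif(rn, 3), " nN (tolerance ", signif(tol_abs, 3),
                " nN)", call. = FALSE)
        break
      }
      if (!use_pcg) {
        # stagnation across widely separated stiffness scales: keep a
        # persistent damping floor so the softest modes stop re-exciting
        # the stiff residual (their own anchored residuals are tiny)
        if (rn > 0.5 * max(rn_window) && all(is.finite(rn_window)) &&
            damp_floor == 0 && !is.null(Kff) &&
            identical(cable_mode, "constant_force")) {
          damp_floor <- 1e-3
          damping <- max(damping, damp_floor)
          ch <- NULL
        }
        rn_window <- c(rn_window[-1], rn)
        if (need_K) {
          i2 <- dof_map[sys$i]; j2 <- dof_map[sys$j]
          sw <- i2 > j2
          if (any(sw)) { tmp <- i2[sw]; i2[sw] <- j2[sw]; j2[sw] <- tmp }
          K <- Matrix::sparseMatrix(i = i2, j = j2, x = sys$x,
                                    dims = c(ndof, ndof), symmetric = TRUE)
          Matrix::diag(K) <- Matrix::diag(K) + reg_perm
          Kff <- K[seq_along(fdofs), seq_along(fdofs), drop = FALSE]
          ch <- NULL
          stale_K <- FALSE
        }
      } else {
        # beams-plus-cable-diagonal preconditioner at the current state
        sysb <- fe_call(fe_beams, q, cable_mode, P_inc, stiffness, TRUE,
                        psd_tangent = TRUE)
        dcab <- cpp_cable_diag(q, fe$nnode, fe$ca, fe$cb, fe$cL0,
                               if (cable_mode == "constant_force") 0L else 1L,
                               P_inc, stiffness, 0.005)
        M <- Matrix::sparseMatrix(i = sysb$i, j = sysb$j, x = sysb$x,
                                  dims = c(ndof, ndof), symmetric = TRUE)
        Matrix::diag(M) <- Matrix::diag(M) + reg + pmax(dcab, 0) + 1e-10
        Mff_base <- M[free, free, drop = FALSE]
      }
      accepted <- FALSE
      fresh_K <- need_K || use_pcg
      repeat {
        for (esc in 0:14) {
          if (use_pcg) {
            Mff <- Mff_base
            dK <- Matrix::diag(Mff)
            if (damping > 0)
              Matrix::diag(Mff) <- dK * (1 + damping)
            chM <- factorize_simplicial(Mff)
            if (is.null(chM)) { damping <- bump(damping, rn); next }
            eta <- if (rn > 1e3 * tol_abs) 1e-2 else 1e-5
            dq <- pcg(q, P_inc, damping, dK, chM, -r[free], eta)
            if (is.null(dq)) { damping <- bump(damping, rn); next }
          } else {
            if (is.null(ch) || ch_damping != damping) {
              ch <- factorize(Kff, damping)
              if (is.null(ch)) {
                damping <- bump(damping, rn)
                gc(FALSE)
                next
              }
              ch_damping <- damping
              gc(FALSE)
            }
            dq <- as.numeric(Matrix::solve(ch, -r[fdofs]))
            if (all(is.finite(dq)) && damping == 0) {
              # one round of iterative refinement (undamped solves only)
              lin_res <- as.numeric(Kff %*% dq) + r[fdofs]
              dq <- dq - as.numeric(Matrix::solve(ch, lin_res))
            }
          }
          dq <- pmin(pmax(dq, -settings$max_step), settings$max_step)
          sol_idx <- if (use_pcg) free else fdofs
          gdq <- sum(r[sol_idx] * dq)
          if (!all(is.finite(dq)) || gdq >= 0) {
            damping <- bump(damping, rn)
            if (!use_pcg) ch <- NULL
            next
          }
          step <- 1
          for (half in 0:9) {
            q_try <- q
            q_try[sol_idx] <- q[sol_idx] + step * dq
            rs <- fe_call(fe, q_try, cable_mode, P_inc, stiffness, FALSE)
            rt <- rs$f - fx + reg * (q_try - q_start)
            rn_try <- sqrt(sum(rt[free]^2))
            # monotone-residual acceptance keeps the endgame from
            # wandering along energy valleys; the energy-Armijo criterion
            # additionally admits large early steps (collapse phase) where
            # the residual may transiently grow while the potential drops
            V_try <- potential(rs, q_try)
            # energy-Armijo while the predicted decrease is representable
            # in double precision; below that, require the residual norm
            # itself to fall
            resolvable <- abs(step * gdq) >= 1e-12 * (abs(V) + 1e-300)
            ok <- (resolvable && is.finite(V_try) &&
                     V_try <= V + 1e-4 * step * gdq) ||
              (!resolvable && is.finite(rn_try) && rn_try < rn)
            if (settings$verbose && esc <= 2 && half <= 2)
              message(sprintf(
                "    esc %d damp %.2e step %.3g gdq %.2e rn_try %.3e dV %.3e",
                esc, damping, step, gdq, rn_try, V_try - V))
            if (ok) { accepted <- TRUE; break }
            step <- step / 2
          }
          if (accepted) {
            q <- q_try
            if (step == 1) damping <- max(damping / 2, damp_floor)
            else stale_K <- TRUE
            if (damping < 1e-14) damping <- 0
            break
          }
          damping <- bump(damping, rn)
          if (!use_pcg) ch <- NULL
        }
        if (accepted || fresh_K) break
        # the frozen tangent could not produce a descent step: rebuild it
        # at the current configuration and retry once
        sys <- fe_call(fe, q, cable_mode, P_inc, stiffness, TRUE,
                       psd_tangent =
                         settings$tangent_update != "every_iteration")
        i2 <- dof_map[sys$i]; j2 <- dof_map[sys$j]
        sw <- i2 > j2
        if (any(sw)) { tmp <- i2[sw]; i2[sw] <- j2[sw]; j2[sw] <- tmp }
        K <- Matrix::sparseMatrix(i = i2, j = j2, x = sys$x,
                                  dims = c(ndof, ndof), symmetric = TRUE)
        Matrix::diag(K) <- Matrix::diag(K) + reg_perm
        Kff <- K[seq_along(fdofs), seq_along(fdofs), drop = FALSE]
        r <- sys$f - fx + reg * (q - q_start)
        ch <- NULL
        damping <- damp_floor
        fresh_K <- TRUE
        stale_K <- FALSE
      }
      if (!accepted) {
        # a dead line search with the residual already inside a modest
        # multiple of the tolerance: accept and flag rather than fail
        if (rn < 30 * tol_abs) {
          converged <- TRUE
          stalled <- TRUE
          iters[inc] <- it
          warning("equilibrium accepted at a stalled residual ",
                  signif(rn, 3), " nN (tolerance ", signif(tol_abs, 3),
                  " nN)", call. = FALSE)
        }
        break
      }
      rn_prev <- rn
      iters[inc] <- it
    }
    # iteration budget exhausted while still making slow progress: the
    # same relaxed band applies
    if (!converged && exists("rn") && is.finite(rn) && rn < 30 * tol_abs) {
      converged <- TRUE
      stalled <- TRUE
      warning("equilibrium accepted at a stalled residual ",
              signif(rn, 3), " nN (tolerance ", signif(tol_abs, 3),
              " nN)", call. = FALSE)
    }
    if (!converged) {
      converged_all <- FALSE
      break
    }
    prev_dq <- q[free] - q_inc_start[free]
  }
  if (!converged_all)
    stop("Newton iteration did not converge (increment ", inc,
         ", residual ", signif(residual_hist[length(residual_hist)], 4),
         " nN); consider more increments", call. = FALSE)

  ch <- NULL; Kff <- NULL
  gc(FALSE)
  cpp_malloc_trim()
  sysf <- fe_call(fe, q, cable_mode, prestress, stiffness, FALSE)
  r_full <- sysf$f - f_ext + reg * (q - q_start)
  structure(list(
    q = q,
    coordinates = matrix(q[-seq(3L, ndof, by = 3L)], ncol = 2L,
                         byrow = TRUE,
                         dimnames = list(NULL, c("x", "y"))),
    rotations = q[seq(3L, ndof, by = 3L)],
    beam_forces = tibble::tibble(id = seq_along(sysf$N), N = sysf$N,
                                 M_a = sysf$M1, M_b = sysf$M2,
                                 shear = sysf$V),
    cable_tensions = sysf$T,
    residual_norm = sqrt(sum(r_full[free]^2)),
    reactions = stats::setNames(r_full[fixed_idx],
                                as.character(fixed_idx)),
    fixed_dof = fixed_idx,
    iterations = iters,
    converged = TRUE,
    stalled = stalled
  ), class = "system_state")
}

bump <- function(damping, rn) max(16 * damping, 0.01)

factorize_simplicial <- function(A) {
  bad <- FALSE
  ch <- withCallingHandlers(
    tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
             error = function(e) NULL),
    warning = function(w) { bad <<- TRUE; invokeRestart("muffleWarning") })
  if (bad) NULL else ch
}

# Translation-reduced variant of newton_solve: rotational DOF are condensed
# out of every linear solve by exact per-filament block elimination (the
# rotation block of the tangent is chain-tridiagonal and always positive
# definite), giving identical Newton iterates at 2/3 the DOF.  Requires
# chain metadata and no fixed rotational DOF.
newton_solve_condensed <- function(fe, q_start, fixed_idx, fixed_target,
                                   f_ext, settings, cable_mode,
                                   prestress, stiffness, n_increments) {
  n <- fe$nnode
  ndof <- 3L * n
  free <- setdiff(seq_len(ndof), fixed_idx)
  rot3 <- seq(3L, ndof, by = 3L)
  reg <- rep(settings$regularization, ndof)
  reg[rot3] <- settings$rot_regularization
  # 2-dof (translation) indexing
  nd2 <- 2L * n
  node_of <- (fixed_idx - 1L) %/% 3L
  comp_of <- (fixed_idx - 1L) %% 3L
  fixed2 <- 2L * node_of + comp_of + 1L
  free2 <- setdiff(seq_len(nd2), fixed2)
  t3 <- rep(seq_len(n), each = 2L) * 3L - 3L + rep(1:2, n)  # 2dof -> 3dof map
  use_nd <- length(free2) > 3000L && length(fe$ca) > 0L
  if (use_nd) {
    nodes_xy <- matrix(fe$q0, ncol = 3L, byrow = TRUE)
    ordn <- nd_node_order(nodes_xy[, 1], nodes_xy[, 2],
                          c(fe$ba, fe$ca), c(fe$bb, fe$cb))
    dof_ord <- as.vector(rbind(2L * ordn - 1L, 2L * ordn))
    fdofs2 <- dof_ord[dof_ord %in% free2]
  } else fdofs2 <- free2
  dof_map <- integer(nd2)
  dof_map[fdofs2] <- seq_along(fdofs2)
  dof_map[fixed2] <- length(free2) + seq_along(fixed2)
  reg2 <- rep(settings$regularization, nd2)
  reg_perm <- reg2[c(fdofs2, fixed2)]

  q <- q_start
  fixed_start <- q_start[fixed_idx]
  iters <- integer(n_increments)
  residual_hist <- numeric(0)
  converged_all <- TRUE
  sys <- NULL

  factorize <- function(Kff, lam) {
    A <- Kff
    if (lam > 0) {
      d <- Matrix::diag(A)
      # damp with lam * |diag| (plus a floor): diagonal entries can be
      # negative under strong compression, where a multiplicative scaling
      # could never restore positive definiteness
      Matrix::diag(A) <- d + lam * (abs(d) + 1e-8 * max(abs(d)))
    }
    bad <- FALSE
    ch <- withCallingHandlers(
      tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = !use_nd,
                                super = use_nd),
               error = function(e) NULL),
      warning = function(w) { bad <<- TRUE; invokeRestart("muffleWarning") })
    if (bad) ch <- NULL
    ch
  }

  damping <- 0
  Kff <- NULL
  ch <- NULL
  ch_damping <- -1
  ramp_prestress <- identical(cable_mode, "constant_force")
  for (inc in seq_len(n_increments)) {
    lam <- inc / n_increments
    q[fixed_idx] <- fixed_start + lam * (fixed_target - fixed_start)
    fx <- lam * f_ext
    P_inc <- if (ramp_prestress) lam * prestress else prestress
    rn_prev <- Inf
    stale_K <- FALSE
    converged <- FALSE
    damp_floor <- 0
    rn_window <- rep(Inf, 15L)
    potential <- function(sys, qv) {
      sys$energy - sum(fx * qv) + 0.5 * sum(reg * (qv - q_start)^2)
    }
    if (!is.null(Kff)) stale_K <- TRUE
    for (it in seq_len(settings$max_iterations)) {
      need_K <- is.null(Kff) || settings$tangent_update == "every_iteration" ||
        (it > 2L && rn_prev < Inf && !is.null(Kff) && stale_K)
      r_extra <- reg * (q - q_start) - fx
      sys <- fe_call_condensed(fe, q, cable_mode, P_inc, stiffness,
                               settings$rot_regularization, r_extra)
      r <- sys$f + r_extra
      rn <- sqrt(sum(r[free]^2))
      V <- potential(sys, q)
      if (it == 1L) rn_init2 <- rn
      fchar <- max(settings$force_floor, rn_init2,
                   if (length(sys$T)) max(P_inc, max(abs(sys$T))) else 0,
                   max(abs(fx)))
      if (settings$verbose)
        message(sprintf("  inc %d it %d residual %.3e (tol %.3e) damping %.1e",
                        inc, it, rn, settings$rtol * fchar, damping))
      residual_hist <- c(residual_hist, rn)
      if (rn < settings$rtol * fchar) { converged <- TRUE; iters[inc] <- it; break }
      if (rn > 0.5 * max(rn_window) && all(is.finite(rn_window)) &&
          damp_floor == 0 && !is.null(Kff)) {
        damp_floor <- 1e-4 * max(Matrix::diag(Kff))
        damping <- max(damping, damp_floor)
        ch <- NULL
      }
      rn_window <- c(rn_window[-1], rn)
      if (need_K) {
        i2 <- dof_map[sys$i]; j2 <- dof_map[sys$j]
        sw <- i2 > j2
        if (any(sw)) { tmp <- i2[sw]; i2[sw] <- j2[sw]; j2[sw] <- tmp }
        K <- Matrix::sparseMatrix(i = i2, j = j2, x = sys$x,
                                  dims = c(nd2, nd2), symmetric = TRUE)
        Matrix::diag(K) <- Matrix::diag(K) + reg_perm
        Kff <- K[seq_along(fdofs2), seq_along(fdofs2), drop = FALSE]
        ch <- NULL
        stale_K <- FALSE
      }
      # reduced residual in elimination order
      rred <- (r[t3] - sys$ct)[fdofs2]
      accepted <- FALSE
      fresh_K <- need_K
      repeat {
        for (esc in 0:14) {
          if (is.null(ch) || ch_damping != damping) {
            ch <- factorize(Kff, damping)
            if (is.null(ch)) {
              damping <- max(4 * damping, 1e-8 * max(Matrix::diag(Kff)))
              gc(FALSE)
              next
            }
            ch_damping <- damping
            gc(FALSE)
            cpp_malloc_trim()
          }
          dqt <- as.numeric(Matrix::solve(ch, -rred))
          if (all(is.finite(dqt))) {
            lin_res <- as.numeric(Kff %*% dqt) + rred + damping * dqt
            dqt <- dqt - as.numeric(Matrix::solve(ch, lin_res))
          }
          dqt <- pmin(pmax(dqt, -settings$max_step), settings$max_step)
          if (!all(is.finite(dqt))) {
            damping <- max(4 * damping, 1e-8 * max(Matrix::diag(Kff)))
            ch <- NULL
            next
          }
          # recover rotation increments, assemble the full step
          dqt2 <- numeric(nd2)
          dqt2[fdofs2] <- dqt
          dth <- cpp_recover_rotations(q, n, fe$ba, fe$bb, fe$bL0, fe$bBeta0,
                                       fe$bEA, fe$bEI,
                                       fe$chain_first, fe$chain_len,
                                       settings$rot_regularization,
                                       r[rot3], dqt2)
          dth <- pmin(pmax(dth, -settings$max_step), settings$max_step)
          dq_full <- numeric(ndof)
          dq_full[t3] <- dqt2
          dq_full[rot3] <- dth
          gdq <- sum(r[free] * dq_full[free])
          if (gdq >= 0) {
            damping <- max(4 * damping, 1e-8 * max(Matrix::diag(Kff)))
            ch <- NULL
            next
          }
          step <- 1
          for (half in 0:9) {
            q_try <- q
            q_try[free] <- q[free] + step * dq_full[free]
            rs <- fe_call(fe, q_try, cable_mode, P_inc, stiffness, FALSE)
            V_try <- potential(rs, q_try)
            resolvable <- abs(step * gdq) >= 1e-12 * (abs(V) + 1e-300)
            armijo_ok <- resolvable && is.finite(V_try) &&
              V_try <= V + 1e-4 * step * gdq
            if (!resolvable) {
              rt <- rs$f - fx + reg * (q_try - q_start)
              armijo_ok <- sqrt(sum(rt[free]^2)) < rn
            }
            if (armijo_ok) {
              accepted <- TRUE
              break
            }
            step <- step / 2
          }
          if (accepted) {
            q <- q_try
            if (step == 1) damping <- max(damping / 2, damp_floor)
            else stale_K <- TRUE
            if (damping < 1e-14) damping <- 0
            break
          }
          damping <- max(4 * damping, 1e-8 * max(Matrix::diag(Kff)))
          ch <- NULL
        }
        if (accepted || fresh_K) break
        r_extra <- reg * (q - q_start) - fx
        sys <- fe_call_condensed(fe, q, cable_mode, P_inc, stiffness,
                                 settings$rot_regularization, r_extra)
        i2 <- dof_map[sys$i]; j2 <- dof_map[sys$j]
        sw <- i2 > j2
        if (any(sw)) { tmp <- i2[sw]; i2[sw] <- j2[sw]; j2[sw] <- tmp }
        K <- Matrix::sparseMatrix(i = i2, j = j2, x = sys$x,
                                  dims = c(nd2, nd2), symmetric = TRUE)
        Matrix::diag(K) <- Matrix::diag(K) + reg_perm
        Kff <- K[seq_along(fdofs2), seq_along(fdofs2), drop = FALSE]
        r <- sys$f + r_extra
        rred <- (r[t3] - sys$ct)[fdofs2]
        ch <- NULL
        damping <- damp_floor
        fresh_K <- TRUE
        stale_K <- FALSE
      }
      if (!accepted) {
        # a dead line search with the residual already inside a modest
        # multiple of the tolerance: accept and flag rather than fail
        if (rn < 30 * tol_abs) {
          converged <- TRUE
          stalled <- TRUE
          iters[inc] <- it
          warning("equilibrium accepted at a stalled residual ",
                  signif(rn, 3), " nN (tolerance ", signif(tol_abs, 3),
                  " nN)", call. = FALSE)
        }
        break
      }
      rn_prev <- rn
      iters[inc] <- it
    }
    # iteration budget exhausted while still making slow progress: the
    # same relaxed band applies
    if (!converged && exists("rn") && is.finite(rn) && rn < 30 * tol_abs) {
      converged <- TRUE
      stalled <- TRUE
      warning("equilibrium accepted at a stalled residual ",
              signif(rn, 3), " nN (tolerance ", signif(tol_abs, 3),
              " nN)", call. = FALSE)
    }
    if (!converged) {
      converged_all <- FALSE
      break
    }
    prev_dq <- q[free] - q_inc_start[free]
  }
  if (!converged_all)
    stop("Newton iteration did not converge (increment ", inc,
         ", residual ", signif(residual_hist[length(residual_hist)], 4),
         " nN); consider more increments", call. = FALSE)

  # element forces for reporting come from the uncondensed evaluation
  sysf <- fe_call(fe, q, cable_mode, prestress, stiffness, FALSE)
  r_full <- sysf$f - f_ext + reg * (q - q_start)
  structure(list(
    q = q,
    coordinates = matrix(q[-rot3], ncol = 2L, byrow = TRUE,
                         dimnames = list(NULL, c("x", "y"))),
    rotations = q[rot3],
    beam_forces = tibble::tibble(id = seq_along(sysf$N), N = sysf$N,
                                 M_a = sysf$M1, M_b = sysf$M2,
                                 shear = sysf$V),
    cable_tensions = sysf$T,
    residual_norm = sqrt(sum(r_full[free]^2)),
    reactions = stats::setNames(r_full[fixed_idx],
                                as.character(fixed_idx)),
    fixed_dof = fixed_idx,
    iterations = iters,
    converged = TRUE
  ), class = "system_state")
}

#' Solve static equilibrium of a network
#'
#' Incremental Newton solution of the nonlinear equilibrium equations under
#' prescribed nodal displacements and/or point forces.  Boundary conditions
#' must remove the rigid-body modes (or rely on the small regularisation
#' springs in the settings).
#'
#' @inheritParams assemble_system
#' @param fixed Tibble with columns `node`, `which` (`"x"`, `"y"`, `"rot"`)
#'   and `value` (absolute target coordinate / rotation at full load).
#' @param forces Optional tibble with columns `node`, `which`, `value`
#'   (point forces, nN, applied proportionally over the increments).
#' @param settings A [solver_settings()].
#' @param n_increments Override the number of load increments.
#' @return A `system_state`: converged configuration, per-element forces,
#'   reactions at the fixed DOF, residual norm and iteration counts.
#' @export
solve_equilibrium <- function(network, fixed, forces = NULL,
                              settings = solver_settings(),
                              cable_mode = c("elastic", "constant_force"),
                              prestress = NULL, stiffness = NULL,
                              n_increments = NULL) {
  cable_mode <- match.arg(cable_mode)
  fe <- if (inherits(network, "filament_network")) fe_from_network(network)
        else network
  fixed_idx <- dof_index(fixed$node, fixed$which)
  f_ext <- numeric(3L * fe$nnode)
  if (!is.null(forces) && NROW(forces))
    f_ext[dof_index(forces$node, forces$which)] <- forces$value
  newton_solve(fe, fe$q0, fixed_idx, fixed$value, f_ext, settings,
               cable_mode, prestress, stiffness, n_increments)
}

#' @export
print.system_state <- function(x, ...) {
  cat("<system_state>\n")
  cat(sprintf("  %d nodes, residual norm %.3g nN, %s\n",
              nrow(x$coordinates), x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  iterations per increment: %s\n",
              paste(x$iterations, collapse = ", ")))
  invisible(x)
}

#' Per-filament axial and bending strain energy
#'
#' For each beam element with axial force `N` and end moments `M_a`, `M_b`,
#' the axial strain energy is `N^2 L0 / (2 EA)` and the bending strain
#' energy, with linearly interpolated moment, is
#' `L0 (M_a^2 - M_a M_b + M_b^2) / (6 EI)`.  Energies are summed per
#' filament.
#'
#' @param network A `filament_network`.
#' @param state A converged `system_state` for that network.
#' @return Tibble with columns `filament`, `se_axial`, `se_bending`,
#'   `se_total` (nN um).
#' @export
strain_energy <- function(network, state) {
  if (!isTRUE(state$converged))
    stop("strain energy requires a converged state", call. = FALSE)
  fe <- fe_from_network(network)
  bf <- state$beam_forces
  se_ax <- bf$N^2 * fe$bL0 / (2 * fe$bEA)
  se_bd <- fe$bL0 * (bf$M_a^2 - bf$M_a * bf$M_b + bf$M_b^2) / (6 * fe$bEI)
  tibble::tibble(filament = network$beams$filament,
                 se_axial = se_ax, se_bending = se_bd) |>
    dplyr::group_by(.data$filament) |>
    dplyr::summarise(se_axial = sum(.data$se_axial),
                     se_bending = sum(.data$se_bending),
                     .groups = "drop") |>
    dplyr::mutate(se_total = .data$se_axial + .data$se_bending)
}

# ---- single-element convenience wrappers (used heavily in tests) --------

#' Corotational beam element forces
#'
#' Evaluates the local element forces of one 2-node corotational
#' Euler-Bernoulli beam at given end positions and rotations: the rigid
#' chord rotation is removed, the axial force follows from the chord
#' elongation, and the end moments from the local linear bending stiffness.
#'
#' @param element List with `EA`, `EI` (nN, nN um^2), `L0` (reference
#'   length, um) and `beta0` (reference chord angle, rad).
#' @param end_positions 2 x 2 matrix, rows = node a, b positions.
#' @param end_rotations Length-2 vector of nodal rotations (rad).
#' @return List with `N`, `M_a`, `M_b`, `shear`.
#' @export
beam_local_forces <- function(element, end_positions, end_rotations = c(0, 0)) {
  q <- c(end_positions[1, 1], end_positions[1, 2], end_rotations[1],
         end_positions[2, 1], end_positions[2, 2], end_rotations[2])
  sys <- cpp_system(q, 2L, 1L, 2L, element$L0, element$beta0,
                    element$EA, element$EI,
                    integer(0), integer(0), numeric(0),
                    1L, 0, 0, 0.01, FALSE, FALSE)
  list(N = sys$N[1], M_a = sys$M1[1], M_b = sys$M2[1], shear = sys$V[1])
}

#' Consistent tangent of a single beam element
#'
#' @inheritParams beam_local_forces
#' @return 6 x 6 tangent matrix over the DOF
#'   `(xa, ya, th_a, xb, yb, th_b)`.
#' @export
beam_tangent <- function(element, end_positions, end_rotations = c(0, 0)) {
  q <- c(end_positions[1, 1], end_positions[1, 2], end_rotations[1],
         end_positions[2, 1], end_positions[2, 2], end_rotations[2])
  sys <- cpp_system(q, 2L, 1L, 2L, element$L0, element$beta0,
                    element$EA, element$EI,
                    integer(0), integer(0), numeric(0),
                    1L, 0, 0, 0.01, TRUE, FALSE)
  K <- matrix(0, 6, 6)
  for (k in seq_along(sys$i)) {
    K[sys$i[k], sys$j[k]] <- K[sys$i[k], sys$j[k]] + sys$x[k]
    if (sys$i[k] != sys$j[k])
      K[sys$j[k], sys$i[k]] <- K[sys$j[k], sys$i[k]] + sys$x[k]
  }
  K
}

# Global internal force of a single beam element (for finite differencing).
beam_global_forces <- function(element, end_positions, end_rotations = c(0, 0)) {
  q <- c(end_positions[1, 1], end_positions[1, 2], end_rotations[1],
         end_positions[2, 1], end_positions[2, 2], end_rotations[2])
  sys <- cpp_system(q, 2L, 1L, 2L, element$L0, element$beta0,
                    element$EA, element$EI,
                    integer(0), integer(0), numeric(0),
                    1L, 0, 0, 0.01, FALSE, FALSE)
  sys$f
}

#' Tension and nodal forces of a cross-linker cable
#'
#' In `constant_force` mode the tension equals the pre-stress regardless of
#' length; in `elastic` mode the tension is
#' `max(0, prestress + stiffness * (l - L0) / L0)` (tension-only: the cable
#' goes slack rather than push).
#'
#' @param element List with `L0` (reference length, um), `prestress` (nN),
#'   `stiffness` (nN per unit strain) and `mode` (`"constant_force"` or
#'   `"elastic"`).
#' @param end_positions 2 x 2 matrix of end positions.
#' @return List with `tension` (nN) and `forces` (2 x 2 matrix of nodal
#'   forces, equal and opposite along the chord).
#' @export
cable_force <- function(element, end_positions) {
  q <- c(end_positions[1, 1], end_positions[1, 2], 0,
         end_positions[2, 1], end_positions[2, 2], 0)
  mode <- if (identical(element$mode, "constant_force")) 0L else 1L
  sys <- cpp_system(q, 2L, integer(0), integer(0), numeric(0), numeric(0),
                    numeric(0), numeric(0),
                    1L, 2L, element$L0, mode,
                    element$prestress, element$stiffness %||% 0,
                    element$length_floor %||% 1e-12, FALSE, FALSE)
  list(tension = sys$T[1],
       forces = matrix(c(sys$f[1], sys$f[2], sys$f[4], sys$f[5]),
                       2, 2, byrow = TRUE,
                       dimnames = list(c("a", "b"), c("x", "y"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
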