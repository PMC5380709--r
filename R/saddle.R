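#' Combined biased objective for a replica pair
#'
#' The double-ended search minimizes the sum of the two replicas' energies
#' plus a harmonic bias on their PES separation:
#' `E(A') + E(G') + c * R(A',G')^2`.  Each evaluation therefore involves
#' three quantities: the two energies and the inter-replica distance.
#'
#' @param e_a,e_g replica energies (kcal/mol).
#' @param r inter-replica PES distance (Angstrom, >= 0).
#' @param c bias constant (kcal/mol/Angstrom^2, >= 0).
#' @return combined objective in kcal/mol.
#' @export
biased_objective <- function(e_a, e_g, r, c) {
  if (c < 0 || r < 0) stop("bias constant and distance must be non-negative")
  e_a + e_g + c * r^2
}

#' Angle between two gradient vectors
#'
#' While the two replicas sit on opposite sides of a barrier their
#' gradients point in nearly opposite directions, so the angle stays near
#' 180 degrees.  A significant drop flags incipient instability: one
#' replica is about to cross the barrier, after which unconstrained
#' minimization would collapse both onto one side.
#'
#' @param g_a,g_g gradient vectors (any equal length, both nonzero).
#' @return angle in degrees, in `[0, 180]`.
#' @export
gradient_angle <- function(g_a, g_g) {
  g_a <- as.numeric(g_a); g_g <- as.numeric(g_g)
  na <- sqrt(sum(g_a^2)); ng <- sqrt(sum(g_g^2))
  if (na == 0 || ng == 0) {
    stop("zero-norm gradient: replica is stationary, angle undefined")
  }
  cosv <- sum(g_a * g_g) / (na * ng)
  acos(min(1, max(-1, cosv))) * 180 / pi
}

#' Bias schedule for the barrier ascent
#'
#' @param c_initial starting bias (kcal/mol/Angstrom^2); a small value in
#'   the 1--3 range lets the flexible parts of both systems drift together
#'   cheaply before the barrier proper is climbed.
#' @param growth multiplicative bias growth per step (> 1); geometric
#'   growth keeps the number of steps logarithmic in the final bias.
#' @param c_max bias ceiling.
#' @param r_stop stop when the inter-replica distance falls below this
#'   (Angstrom).  3.0 is appropriate for protein-sized systems; desk-scale
#'   fixtures use a value scaled to about 1 percent of the initial
#'   separation.
#' @param angle_floor terminate the ascent when the gradient angle drops
#'   below this (degrees); conservative default 150.
#' @param max_steps hard cap on bias steps.
#' @return list of class `bias_schedule`.
#' @export
bias_schedule <- function(c_initial = 2, growth = 1.5, c_max = 1e6,
                          r_stop = 3.0, angle_floor = 150, max_steps = 100) {
  stopifnot(c_initial > 0, growth > 1, r_stop > 0,
            angle_floor > 0, angle_floor < 180, max_steps >= 1)
  structure(list(c_initial = c_initial, growth = growth, c_max = c_max,
                 r_stop = r_stop, angle_floor = angle_floor,
                 max_steps = max_steps),
            class = "bias_schedule")
}

#' Minimize the biased pair objective at fixed bias
#'
#' Relaxes both replicas simultaneously under
#' [biased_objective()] using limited-memory quasi-Newton (L-BFGS-B)
#' descent over the concatenated coordinates.  The engine state is frozen
#' once at the start and released at the end, so an expensive engine
#' performs a single self-consistent evaluation per bias step.
#'
#' @param pes a [pes_engine()].
#' @param a,g conformable replica geometries.
#' @param c bias constant (>= 0).
#' @param maxit iteration cap for the inner optimizer.
#' @return list with relaxed geometries `a`, `g`, energies `e_a`, `e_g`,
#'   distance `r`, combined `objective`, and the unbiased gradients
#'   `grad_a`, `grad_g`.
#' @export
minimize_biased_pair <- function(pes, a, g, c, maxit = 500) {
  stop_if_not_conformable(a, g)
  if (c < 0) stop("bias constant must be non-negative")
  n <- n_atoms(a)
  pack <- function(ga, gg) c(as.numeric(ga$xyz), as.numeric(gg$xyz))
  unpack <- function(p) list(xa = matrix(p[seq_len(3 * n)], ncol = 3L),
                             xg = matrix(p[-seq_len(3 * n)], ncol = 3L))
  fn <- function(p) {
    q <- unpack(p)
    ea <- pes_evaluate(pes, q$xa); eg <- pes_evaluate(pes, q$xg)
    ea$energy + eg$energy + c * sum((q$xa - q$xg)^2)
  }
  gr <- function(p) {
    q <- unpack(p)
    ea <- pes_evaluate(pes, q$xa); eg <- pes_evaluate(pes, q$xg)
    d <- q$xa - q$xg
    c(as.numeric(ea$gradient + 2 * c * d),
      as.numeric(eg$gradient - 2 * c * d))
  }
  pes_freeze_state(pes)
  on.exit(pes_release_state(pes))
  p0 <- pack(a, g)
  f0 <- fn(p0)
  opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  if (opt$value > f0 + 1e-8) {
    stop("biased-pair minimization failed to decrease the objective ",
         "within ", maxit, " iterations")
  }
  q <- unpack(opt$par)
  a2 <- set_coords(a, q$xa); g2 <- set_coords(g, q$xg)
  va <- pes_evaluate(pes, a2); vg <- pes_evaluate(pes, g2)
  list(a = a2, g = g2, e_a = va$energy, e_g = vg$energy,
       r = pes_distance(a2, g2),
       objective = va$energy + vg$energy + c * pes_distance(a2, g2)^2,
       grad_a = va$gradient, grad_g = vg$gradient)
}

#' Double-ended barrier ascent
#'
#' Starting from two minima in distinct basins, repeatedly relaxes the
#' replica pair under a stepwise-growing harmonic bias on their
#' separation.  The ascent terminates when the separation drops below
#' `r_stop` ("distance"), when the gradient angle falls below the floor
#' ("angle", flagging that one replica is about to cross the barrier), or
#' when the replicas merge at a common minimum ("merged": the endpoints
#' were in the same basin, so there is no barrier between them).  The
#' transition-state guess is the unweighted coordinate-wise mean of the
#' final two replica geometries.
#'
#' @param pes a [pes_engine()].
#' @param a,g endpoint geometries (approximate minima of distinct basins).
#' @param schedule a [bias_schedule()].
#' @return list of class `ascent_result`: `trace` (data.frame: step, c,
#'   e_a, e_g, r, angle), `reason`, `ts_guess` (a geometry, or `NULL` when
#'   no barrier exists), `no_barrier` flag, and the final replicas
#'   `a`, `g`.
#' @export
ascend_barrier <- function(pes, a, g, schedule = bias_schedule()) {
  stop_if_not_conformable(a, g)
  merge_tol <- 1e-3
  # is a merged pair sitting at a minimum (endpoints shared a basin) or at
  # the saddle itself (legitimate convergence)?  Probe by relaxing small
  # displacements along the last inter-replica direction: from a minimum
  # both probes fall back onto the merged point, from a saddle they roll
  # away downhill.
  merged_at_minimum <- function(mid, dirv) {
    nrm <- sqrt(sum(dirv^2))
    dirv <- if (nrm > 0) dirv / nrm else {
      d0 <- matrix(0, n_atoms(mid), 3L); d0[1L, 1L] <- 1; d0
    }
    for (sgn in c(1, -1)) {
      probe <- set_coords(mid, mid$xyz + sgn * 0.01 * dirv)
      relaxed <- exhaustive_minimize(pes, probe, window = 50)
      if (pes_distance(relaxed$geometry, mid) >= merge_tol) return(FALSE)
    }
    TRUE
  }
  cbias <- schedule$c_initial
  grow <- schedule$growth
  rows <- list(); reason <- NULL; no_barrier <- FALSE
  step <- 0L; n_eval <- 0L
  last_dir <- g$xyz - a$xyz
  while (n_eval < schedule$max_steps) {
    n_eval <- n_eval + 1L
    res <- minimize_biased_pair(pes, a, g, cbias)
    if (res$r < merge_tol) {
      mid <- set_coords(a, (res$a$xyz + res$g$xyz) / 2)
      if (merged_at_minimum(mid, last_dir)) {
        if (step == 0L) {
          # merged at the very first, gentle bias: the endpoints shared a
          # basin and there is no barrier between them
          rows[[1L]] <- data.frame(step = 1L, c = cbias, e_a = res$e_a,
                                   e_g = res$e_g, r = res$r,
                                   angle = NA_real_)
          a <- res$a; g <- res$g
          reason <- "merged"; no_barrier <- TRUE
          break
        }
        # sudden collapse through the barrier: roll back to the last
        # stable pair and retry with a gentler bias increment
        grow <- sqrt(grow)
        if (grow < 1.005) { reason <- "angle"; break }
        cbias <- rows[[step]]$c * grow
        next
      }
      # merged at the saddle itself: fall through to distance termination
    }
    step <- step + 1L
    a <- res$a; g <- res$g
    last_dir <- g$xyz - a$xyz
    gn_a <- sqrt(sum(res$grad_a^2)); gn_g <- sqrt(sum(res$grad_g^2))
    angle <- if (gn_a < 1e-10 || gn_g < 1e-10) NA_real_ else
      gradient_angle(res$grad_a, res$grad_g)
    rows[[step]] <- data.frame(step = step, c = cbias, e_a = res$e_a,
                               e_g = res$e_g, r = res$r, angle = angle)
    if (res$r < schedule$r_stop) { reason <- "distance"; break }
    if (!is.na(angle) && angle < schedule$angle_floor) {
      reason <- "angle"; break
    }
    cbias <- min(cbias * grow, schedule$c_max)
  }
  trace <- do.call(rbind, rows)
  if (is.null(reason)) {
    cond <- simpleError(paste0("barrier ascent did not terminate within ",
                               schedule$max_steps, " bias steps"))
    cond$trace <- trace
    stop(cond)
  }
  ts_guess <- if (no_barrier) NULL else
    set_coords(a, (a$xyz + g$xyz) / 2)
  structure(list(trace = trace, reason = reason, ts_guess = ts_guess,
                 no_barrier = no_barrier, a = a, g = g),
            class = "ascent_result")
}

#' Drag a system toward a target to probe for barriers
#'
#' For reactions not expected to involve a barrier (e.g. a product
#' diffusing out of an active site), a small harmonic pull toward the
#' target geometry is applied while the allowed distance from the target
#' is tightened stepwise; the system relaxes at each stage.  The maximum
#' upward fluctuation of the unbiased energy along the relaxed path
#' estimates any barrier encountered; a large fluctuation advises running
#' the full [ascend_barrier()] treatment instead.
#'
#' @param pes a [pes_engine()].
#' @param a starting geometry.
#' @param target target geometry (conformable with `a`).
#' @param c_small pull force constant (kcal/mol/Angstrom^2, > 0).
#' @param n_steps number of tightening stages.
#' @param barrier_warn fluctuation (kcal/mol) above which a warning is
#'   issued.
#' @return list with `path` (list of geometries), `energy` (unbiased
#'   energies along the path) and `max_fluctuation` (kcal/mol).
#' @export
drag_toward <- function(pes, a, target, c_small = 20, n_steps = 80,
                        barrier_warn = 5) {
  stop_if_not_conformable(a, target)
  if (c_small <= 0) stop("c_small must be positive")
  r0 <- pes_distance(a, target)
  if (r0 == 0) {
    return(list(path = list(), energy = numeric(0), max_fluctuation = 0))
  }
  txyz <- as.numeric(target$xyz)
  path <- list(); energy <- numeric(0)
  cur <- as.numeric(a$xyz)
  fine <- pes_evaluate(pes, a)$energy
  # per-stage relaxation is a step-capped damped descent so the path moves
  # continuously over any ridge instead of hopping discontinuously from
  # one side to the other between stages
  cap <- max(2 * r0 / n_steps, 0.02)
  for (dk in seq(r0, 0, length.out = n_steps + 1L)[-1L]) {
    penalized <- function(p) {
      x <- matrix(p, ncol = 3L)
      v <- pes_evaluate(pes, x)
      r <- sqrt(sum((p - txyz)^2))
      e <- v$energy; gvec <- as.numeric(v$gradient)
      if (r > dk && r > 0) {
        e <- e + c_small * (r - dk)^2
        gvec <- gvec + 2 * c_small * (r - dk) * (p - txyz) / r
      }
      list(e = e, g = gvec)
    }
    v <- penalized(cur); s <- cap
    for (it in 1:200) {
      gn <- sqrt(sum(v$g^2))
      if (gn < 1e-8) break
      trial <- cur - v$g / gn * s
      vt <- penalized(trial)
      if (vt$e < v$e - 1e-12) {
        cur <- trial; v <- vt
        # unbiased energy of every accepted substep, so the fluctuation
        # measure sees the ridge crossing even inside a stage
        fine <- c(fine, pes_evaluate(pes, matrix(cur, ncol = 3L))$energy)
        s <- min(s * 1.5, cap)
      } else {
        s <- s / 2
        if (s < 1e-10) break
      }
    }
    gcur <- set_coords(a, cur)
    path <- c(path, list(gcur))
    energy <- c(energy, pes_evaluate(pes, gcur)$energy)
  }
  fluct <- max(0, max(fine - cummin(fine)))
  if (fluct > barrier_warn) {
    warning("drag encountered an energy fluctuation of ",
            format(fluct, digits = 4), " kcal/mol; a real barrier may be ",
            "present -- consider a full ascend_barrier() treatment")
  }
  list(path = path, energy = energy, max_fluctuation = fluct)
}
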