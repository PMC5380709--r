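#' Stationary point container
#'
#' @param geometry the refined [geometry()].
#' @param energy energy at the point (kcal/mol).
#' @param classification `"minimum"`, `"transition_state"` or
#'   `"higher_order_saddle"`.
#' @param grad_norm total gradient norm at the point.
#' @param active integer indices of the active atom set used.
#' @param modes optional attached [normal_modes()] result.
#' @return object of class `stationary_point`.
#' @export
stationary_point <- function(geometry, energy, classification, grad_norm,
                             active = seq_len(n_atoms(geometry)),
                             modes = NULL) {
  structure(list(geometry = geometry, energy = energy,
                 classification = classification, grad_norm = grad_norm,
                 active = as.integer(active), modes = modes),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("stationary point: %s, E = %.6f kcal/mol, |g| = %.3g\n",
              x$classification, x$energy, x$grad_norm))
  invisible(x)
}

# flatten selected atom coordinates / write them back
.get_sub <- function(xyz, atoms) as.numeric(t(xyz[atoms, , drop = FALSE]))
.set_sub <- function(xyz, atoms, vals) {
  xyz[atoms, ] <- matrix(vals, ncol = 3L, byrow = TRUE)
  xyz
}

#' Exhaustive energy minimization
#'
#' Limited-memory quasi-Newton descent over the free atoms, continued
#' until the energy fails to descend over a further `window` consecutive
#' cycles.  This exhaustive criterion gives heats of formation precise
#' enough for the small double differences taken by the thermodynamic
#' cycles.  Frozen atoms are left bit-identical.  When `max_step` is
#' finite, a damped steepest-descent loop with a per-cycle displacement
#' cap is used instead -- the conservative mode used to polish IRC
#' endpoints, where unconstrained quasi-Newton steps on a shallow path can
#' jump onto the wrong downhill branch.
#'
#' @param pes a [pes_engine()].
#' @param g starting [geometry()].
#' @param frozen integer indices of atoms to hold fixed.
#' @param window cycles without descent required to stop (default 100).
#' @param max_step per-cycle displacement cap in Angstrom (`Inf` = none).
#' @param eps energy improvement below which a cycle counts as
#'   "failed to descend".
#' @return a [stationary_point()] (classification `"minimum"`).
#' @export
exhaustive_minimize <- function(pes, g, frozen = integer(0), window = 100,
                                max_step = Inf, eps = 1e-10) {
  if (window < 1) stop("window must be >= 1")
  free <- setdiff(seq_len(n_atoms(g)), frozen)
  xyz <- g$xyz
  if (!length(free)) {
    v <- pes_evaluate(pes, g)
    return(stationary_point(g, v$energy, "minimum",
                            sqrt(sum(v$gradient^2)), active = free))
  }
  guard <- function(e) {
    if (e < -1e10) stop("descent diverging: energy fell below -1e10")
  }
  if (is.finite(max_step)) {
    # damped, step-capped steepest descent
    v <- pes_evaluate(pes, set_coords(g, xyz))
    e_best <- v$energy
    stale <- 0L; s <- max_step
    while (stale < window) {
      gsub <- v$gradient[free, , drop = FALSE]
      gn <- sqrt(sum(gsub^2))
      if (gn < 1e-12) break
      step <- -gsub / gn * min(s, max_step)
      trial <- xyz
      trial[free, ] <- trial[free, ] + step
      vt <- pes_evaluate(pes, set_coords(g, trial))
      if (vt$energy < v$energy - eps) {
        xyz <- trial; v <- vt
        s <- min(s * 1.5, max_step)
        if (vt$energy < e_best - eps) { e_best <- vt$energy; stale <- 0L }
        else stale <- stale + 1L
      } else {
        s <- s / 2
        stale <- stale + 1L
        if (s < 1e-12) break
      }
      guard(v$energy)
    }
  } else {
    fn <- function(p) {
      pes_evaluate(pes, set_coords(g, .set_sub(xyz, free, p)))$energy
    }
    gr <- function(p) {
      grad <- pes_evaluate(pes, set_coords(g, .set_sub(xyz, free, p)))$gradient
      .get_sub(grad, free)
    }
    p <- .get_sub(xyz, free)
    e_prev <- fn(p)
    guard(e_prev)
    repeat {
      opt <- stats::optim(p, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = window, factr = 1e1))
      guard(opt$value)
      if (opt$value >= e_prev - eps) { p <- opt$par; break }
      e_prev <- opt$value; p <- opt$par
      if (opt$convergence == 0) {
        # converged; one confirming window with no descent
        opt2 <- stats::optim(p, fn, gr, method = "L-BFGS-B",
                             control = list(maxit = window, factr = 1e1))
        p <- opt2$par
        break
      }
    }
    xyz <- .set_sub(xyz, free, p)
  }
  gout <- set_coords(g, xyz)
  v <- pes_evaluate(pes, gout)
  stationary_point(gout, v$energy, "minimum", sqrt(sum(v$gradient^2)),
                   active = free)
}

# Refine the active atoms toward a stationary point of any index with the
# environment frozen: damped Newton steps from the active-subspace Hessian
# (eigen pseudo-inverse, so saddles are approached rather than avoided),
# accepted only when they reduce the active gradient norm -- a descent on
# |g|^2 that stays robust far from the quadratic region where plain
# eigenvector-following fails, yet converges quadratically near the point.
.stationary_refine <- function(pes, g, active, h = 5e-3, tol = 1e-9,
                               max_iter = 80, cap = 0.25) {
  gnorm_at <- function(xyz) {
    v <- tryCatch(pes_evaluate(pes, set_coords(g, xyz)),
                  error = function(e) NULL)
    if (is.null(v)) return(list(gn = Inf, gact = NULL))
    gact <- .get_sub(v$gradient, active)
    list(gn = sqrt(sum(gact^2)), gact = gact)
  }
  xyz <- g$xyz
  cur <- gnorm_at(xyz)
  for (it in seq_len(max_iter)) {
    if (cur$gn < tol) break
    H <- partial_hessian(pes, set_coords(g, xyz), active, h = h)
    ed <- eigen(H, symmetric = TRUE)
    keep <- abs(ed$values) > 1e-7 * max(abs(ed$values), 1)
    dx <- -ed$vectors[, keep, drop = FALSE] %*%
      ((t(ed$vectors[, keep, drop = FALSE]) %*% cur$gact) / ed$values[keep])
    nrm <- sqrt(sum(dx^2))
    if (nrm > cap) dx <- dx * cap / nrm
    # backtrack on the active gradient norm; fall back to steepest
    # descent on |g|^2 (direction -H g) if the Newton step is rejected
    accepted <- FALSE
    for (dirv in list(dx, {
      sd <- -as.numeric(H %*% cur$gact)
      sn <- sqrt(sum(sd^2))
      if (sn > 0) sd * min(cap, nrm) / sn else sd
    })) {
      t_step <- 1
      for (bt in 1:8) {
        trial <- .set_sub(xyz, active,
                          .get_sub(xyz, active) + t_step * dirv)
        res <- gnorm_at(trial)
        if (res$gn < cur$gn * (1 - 1e-4 * t_step)) {
          xyz <- trial; cur <- res; accepted <- TRUE
          break
        }
        t_step <- t_step / 2
      }
      if (accepted) break
    }
    if (!accepted) break
  }
  set_coords(g, xyz)
}

#' Partitioned refinement of a transition-state guess
#'
#' Alternates (i) stationary-point refinement of the active atoms
#' (squared-gradient-norm minimization followed by a Newton polish using
#' the active-subspace Hessian) with the environment frozen, and (ii)
#' energy minimization of the environment with the active atoms frozen.
#' Each stage induces small forces on the other set; the alternation is a
#' rapidly converging series that normally settles in two to five
#' iterations.  The active set is usually the atoms whose covalent
#' topology differs between the reaction's endpoints
#' (see [diff_topology()]).
#'
#' @param pes a [pes_engine()].
#' @param guess transition-state guess geometry (e.g. from
#'   [ascend_barrier()]).
#' @param active nonempty integer vector of active atom indices.
#' @param tol convergence tolerance on the total gradient norm.
#' @param max_alt alternation cap; a warning is issued beyond 5.
#' @param h finite-difference step for the subspace Hessian (Angstrom).
#' @param env_window descent window for the environment stage.
#' @return a [stationary_point()]; classification comes from the
#'   eigenvalue spectrum of the final active-subspace Hessian (a guess
#'   that collapses onto a minimum is returned classified `"minimum"`).
#' @export
refine_saddle <- function(pes, guess, active, tol = 1e-6, max_alt = 10,
                          h = 5e-3, env_window = 100) {
  active <- as.integer(active)
  if (!length(active)) stop("active set must be nonempty")
  env <- setdiff(seq_len(n_atoms(guess)), active)
  g <- guess
  for (it in seq_len(max_alt)) {
    g <- .stationary_refine(pes, g, active, h = h, tol = tol * 1e-2)
    if (length(env)) {
      g <- exhaustive_minimize(pes, g, frozen = active,
                               window = env_window)$geometry
    }
    v <- pes_evaluate(pes, g)
    if (sqrt(sum(v$gradient^2)) <= tol) break
    if (it == max_alt) {
      stop("partitioned refinement did not converge in ", max_alt,
           " alternations; residual |g| = ",
           format(sqrt(sum(v$gradient^2)), digits = 3))
    }
    if (it == 5L) {
      warning("partitioned refinement still running after 5 alternations; ",
              "2-5 normally suffice -- check the active set")
    }
  }
  v <- pes_evaluate(pes, g)
  H <- partial_hessian(pes, g, active, h = h)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  neg <- sum(ev < -1e-4 * max(abs(ev), 1e-8))
  classification <- if (neg == 0L) "minimum" else
    if (neg == 1L) "transition_state" else "higher_order_saddle"
  stationary_point(g, v$energy, classification, sqrt(sum(v$gradient^2)),
                   active = active)
}

#' Partial (subset) Hessian by central differences
#'
#' Second-derivative matrix over the Cartesian coordinates of a subset of
#' atoms, from central differences of the analytic gradient, symmetrized
#' as `(H + t(H))/2`.  Restricting the analysis to the reactive atoms
#' removes irrelevant soft modes (e.g. methyl rotations) and makes
#' vibrational validation affordable for large systems.
#'
#' @param pes a [pes_engine()].
#' @param g a [geometry()].
#' @param subset nonempty integer vector of atom indices.
#' @param h displacement step (Angstrom, > 0); default 5e-3 balances
#'   truncation error against engine noise.
#' @return symmetric `3m x 3m` matrix (kcal/mol/Angstrom^2).
#' @export
partial_hessian <- function(pes, g, subset, h = 5e-3) {
  subset <- as.integer(subset)
  if (!length(subset)) stop("subset must be nonempty")
  if (h <= 0) stop("finite-difference step h must be positive")
  m <- length(subset)
  H <- matrix(0, 3L * m, 3L * m)
  coords <- cbind(rep(subset, each = 3L), rep(1:3, m))
  for (k in seq_len(3L * m)) {
    i <- coords[k, 1L]; dim <- coords[k, 2L]
    xp <- g$xyz; xp[i, dim] <- xp[i, dim] + h
    xm <- g$xyz; xm[i, dim] <- xm[i, dim] - h
    gp <- tryCatch(pes_evaluate(pes, set_coords(g, xp))$gradient,
                   error = function(e) stop("engine failed at +", h,
                     " displacement of atom ", i, " coord ", dim, ": ",
                     conditionMessage(e)))
    gm <- tryCatch(pes_evaluate(pes, set_coords(g, xm))$gradient,
                   error = function(e) stop("engine failed at -", h,
                     " displacement of atom ", i, " coord ", dim, ": ",
                     conditionMessage(e)))
    H[, k] <- (.get_sub(gp, subset) - .get_sub(gm, subset)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Conversion constant from sqrt(kcal/mol/Angstrom^2/amu) to 1/cm
#'
#' Computed from physical constants:
#' `nu = sqrt(k/mu) / (2 pi c)` with k converted to J/m^2 per molecule and
#' mu to kg.  For k = 1 kcal/mol/Angstrom^2 and mu = 1 amu this gives
#' about 108.6 1/cm.
#'
#' @return the constant K such that `wavenumber = K * sqrt(lambda)`.
#' @export
wavenumber_constant <- function() {
  kcal <- 4184                   # J
  avogadro <- 6.02214076e23
  amu <- 1.66053906660e-27       # kg
  c_cm <- 2.99792458e10          # cm/s
  sqrt((kcal / avogadro / 1e-20) / amu) / (2 * pi * c_cm)
}

#' Normal modes from a mass-weighted Hessian eigenproblem
#'
#' Eigendecomposition of `M^{-1/2} H M^{-1/2}`; each eigenvalue lambda is
#' reported as the signed wavenumber `sign(lambda) * K * sqrt(|lambda|)`,
#' negative values encoding imaginary frequencies.  Mode vectors are
#' orthonormal in mass-weighted coordinates.
#'
#' @param hessian symmetric `3m x 3m` matrix (kcal/mol/Angstrom^2).
#' @param masses length-m vector of subset atom masses (amu).
#' @param subset optional atom indices the Hessian covers (bookkeeping).
#' @return object of class `normal_modes`: `freq` (signed 1/cm, decreasing
#'   eigenvalue order), `vectors` (columns, mass-weighted), `masses`,
#'   `subset`.
#' @export
normal_modes <- function(hessian, masses, subset = seq_along(masses)) {
  if (max(abs(hessian - t(hessian))) >
      1e-8 * max(abs(hessian), 1)) {
    stop("hessian must be symmetric")
  }
  if (any(masses <= 0)) stop("masses must be positive")
  if (nrow(hessian) != 3L * length(masses)) {
    stop("hessian dimension != 3 * number of subset atoms")
  }
  invsq <- 1 / sqrt(rep(masses, each = 3L))
  mw <- hessian * tcrossprod(invsq)
  ed <- eigen((mw + t(mw)) / 2, symmetric = TRUE)
  K <- wavenumber_constant()
  freq <- sign(ed$values) * K * sqrt(abs(ed$values))
  structure(list(freq = freq, vectors = ed$vectors,
                 masses = masses, subset = as.integer(subset)),
            class = "normal_modes")
}

#' Mass-weighted amplitude fraction of a mode on a set of atoms
#'
#' The squared mass-weighted mode components summed over the named atoms,
#' as a fraction of the (unit) total.  Used to check that a reaction
#' coordinate mode is localized on the reactive atoms.
#'
#' @param modes a [normal_modes()] result.
#' @param mode_index column index of the mode.
#' @param atoms atom indices (in the full geometry numbering used by
#'   `modes$subset`).
#' @return fraction in `[0, 1]`.
#' @export
mode_localization <- function(modes, mode_index, atoms) {
  pos <- match(atoms, modes$subset)
  pos <- pos[!is.na(pos)]
  if (!length(pos)) return(0)
  rows <- as.vector(t(outer(pos, 1:3, function(i, d) 3L * (i - 1L) + d)))
  v <- modes$vectors[, mode_index]
  sum(v[rows]^2) / sum(v^2)
}

#' Validate a candidate transition state from its normal modes
#'
#' A true transition state has exactly one imaginary mode, its magnitude
#' must be large (well separated from real modes), and the mode must be
#' localized on the reactive atoms -- the motion it describes is the
#' reaction.
#'
#' @param modes a [normal_modes()] result computed over a subset that
#'   includes all reactive atoms.
#' @param reactive reactive atom indices (full-geometry numbering).
#' @param min_imag minimum acceptable |imaginary wavenumber| (1/cm).
#' @param loc_threshold minimum mass-weighted amplitude fraction of the
#'   imaginary mode on the reactive atoms.
#' @param imag_tol wavenumbers above `-imag_tol` are treated as numerical
#'   zeros, not imaginary modes.
#' @return list of class `ts_validation`: `pass`, `n_imag`,
#'   `imag_wavenumber`, `localization`, `classification` and the three
#'   individual checks.
#' @export
validate_ts <- function(modes, reactive, min_imag = 50,
                        loc_threshold = 0.5, imag_tol = 1) {
  imag_idx <- which(modes$freq < -imag_tol)
  n_imag <- length(imag_idx)
  classification <- if (n_imag == 0L) "minimum" else
    if (n_imag == 1L) "transition_state" else "higher_order_saddle"
  imag_wavenumber <- if (n_imag >= 1L) min(modes$freq) else NA_real_
  localization <- if (n_imag >= 1L) {
    mode_localization(modes, which.min(modes$freq), reactive)
  } else NA_real_
  checks <- list(
    single_imaginary = n_imag == 1L,
    magnitude = isTRUE(n_imag >= 1L && abs(imag_wavenumber) >= min_imag),
    localized = isTRUE(n_imag >= 1L && localization >= loc_threshold)
  )
  structure(list(pass = all(unlist(checks)), n_imag = n_imag,
                 imag_wavenumber = imag_wavenumber,
                 localization = localization,
                 classification = classification, checks = checks),
            class = "ts_validation")
}

#' @export
print.ts_validation <- function(x, ...) {
  cat(sprintf("TS validation: %s (%d imaginary mode(s)%s)\n",
              if (x$pass) "PASS" else "FAIL", x$n_imag,
              if (!is.na(x$imag_wavenumber))
                sprintf(", strongest %.1f i/cm, localization %.2f",
                        abs(x$imag_wavenumber), x$localization) else ""))
  invisible(x)
}

#' Release check after a frozen-core exhaustive optimization
#'
#' After the environment of a refined transition state has been
#' exhaustively minimized with the reactive atoms frozen, releasing those
#' atoms for a residual gradient minimization must change the energy by
#' less than about 0.2 kcal/mol and atomic positions by less than about
#' 0.001 Angstrom, confirming that the frozen-core optimization introduced
#' no spurious forces.  This function performs the release and reports the
#' changes; callers assert the thresholds.
#'
#' @param pes a [pes_engine()].
#' @param g the frozen-core-optimized geometry.
#' @param active the previously frozen reactive atoms, now released.
#' @return list with `delta_energy` (kcal/mol) and `max_displacement`
#'   (Angstrom).
#' @export
check_release <- function(pes, g, active) {
  e0 <- pes_evaluate(pes, g)$energy
  g2 <- .stationary_refine(pes, g, active, tol = 1e-10)
  e1 <- pes_evaluate(pes, g2)$energy
  list(delta_energy = e1 - e0,
       max_displacement = max(abs(g2$xyz - g$xyz)))
}
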