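#' Intrinsic-reaction-coordinate path container
#'
#' @param s signed position on the reaction coordinate: cumulative
#'   mass-weighted arc length from the transition state (Angstrom
#'   sqrt(amu)), strictly increasing in magnitude along each half-path.
#' @param energy energies (kcal/mol).
#' @param geometries optional list of geometries, one per point.
#' @param direction `"forward"` or `"reverse"`.
#' @param terminus terminus classification label (or `NA`).
#' @param dist_ts optional mass-weighted straight-line distance of each
#'   point from the transition state geometry (defaults to `|s|`); on a
#'   curved path it lags the arc length.
#' @return object of class `irc_path`.
#' @export
irc_path <- function(s, energy, geometries = NULL,
                     direction = c("forward", "reverse"),
                     terminus = NA_character_, dist_ts = abs(s)) {
  direction <- match.arg(direction)
  stopifnot(length(s) == length(energy), length(dist_ts) == length(s))
  structure(list(s = s, energy = energy, geometries = geometries,
                 direction = direction, terminus = terminus,
                 dist_ts = dist_ts),
            class = "irc_path")
}

#' Displace a transition-state geometry along its imaginary mode
#'
#' The mass-weighted mode vector is mapped back to Cartesian displacements
#' (`d_i = v_i / sqrt(m_i)`), normalized to total length `delta` over the
#' analyzed subset, and applied with the requested sign.  Atoms outside
#' the subset are untouched.  The two signs seed the two halves of the
#' IRC.
#'
#' @param ts transition-state [geometry()].
#' @param modes a [normal_modes()] result at `ts`.
#' @param delta displacement length (Angstrom, > 0).
#' @param sign +1 or -1.
#' @param mode_index which mode to follow; defaults to the most negative
#'   (the imaginary reaction-coordinate mode).
#' @param max_delta guard cap: displacements beyond this would leave the
#'   quadratic region around the saddle.
#' @return the displaced [geometry()].
#' @export
displace_along_mode <- function(ts, modes, delta = 0.05, sign = 1,
                                mode_index = which.min(modes$freq),
                                max_delta = 0.5) {
  if (delta <= 0) stop("delta must be positive")
  if (delta > max_delta) {
    stop("delta = ", delta, " exceeds the cap ", max_delta,
         "; large displacements leave the quadratic region")
  }
  v <- modes$vectors[, mode_index]
  cart <- matrix(v, ncol = 3L, byrow = TRUE) / sqrt(modes$masses)
  cart <- cart / sqrt(sum(cart^2)) * delta * sign(sign)
  xyz <- ts$xyz
  xyz[modes$subset, ] <- xyz[modes$subset, ] + cart
  set_coords(ts, xyz)
}

#' Follow one half of the intrinsic reaction coordinate
#'
#' Damped mass-weighted steepest descent with a fixed small step from a
#' displaced-transition-state geometry, terminating when the per-step
#' energy decrease drops below `limit`.  The endpoint is then polished by
#' [exhaustive_minimize()] with a conservative per-cycle step cap:
#' unconstrained quasi-Newton optimization on a shallow downhill path can
#' take unexpectedly large steps and land on the *other* branch, so the
#' polish is deliberately trust-radius limited.
#'
#' @param pes a [pes_engine()].
#' @param start displaced geometry (not a stationary point).
#' @param reference geometry defining position zero (normally the
#'   transition state); defaults to `start`.
#' @param direction `"forward"` or `"reverse"` tag; reverse paths carry
#'   negative signed distances.
#' @param step mass-weighted step length (Angstrom sqrt(amu)).
#' @param limit termination threshold on the per-step energy decrease
#'   (kcal/mol).
#' @param max_steps cap on descent steps.
#' @param polish polish the endpoint with a capped minimization?
#' @param polish_cap per-cycle displacement cap for the polish (Angstrom).
#' @return an [irc_path()] with energies monotone non-increasing.
#' @export
follow_irc <- function(pes, start, reference = start,
                       direction = c("forward", "reverse"),
                       step = 0.02, limit = 1e-4, max_steps = 20000,
                       polish = TRUE, polish_cap = 0.1) {
  direction <- match.arg(direction)
  sgn <- if (direction == "forward") 1 else -1
  w <- sqrt(start$mass)                      # per-atom mass weights
  mw_dist <- function(xyz) sqrt(sum((w * (xyz - reference$xyz))^2))
  xyz <- start$xyz
  v <- pes_evaluate(pes, set_coords(start, xyz))
  arc <- mw_dist(xyz)                        # seed offset from the TS
  s <- sgn * arc
  dist_ts <- mw_dist(xyz)
  energy <- v$energy
  geoms <- list(set_coords(start, xyz))
  local <- step
  for (k in seq_len(max_steps)) {
    gy <- v$gradient / w                     # gradient in mass-weighted coords
    gn <- sqrt(sum(gy^2))
    if (gn < 1e-10) break                    # stationary: immediate stop
    stuck <- FALSE
    repeat {
      trial <- xyz - (local / gn) * (v$gradient / w^2)   # dx = dy / w
      vt <- pes_evaluate(pes, set_coords(start, trial))
      if (vt$energy <= utils::tail(energy, 1L) + 1e-12) break
      local <- local / 2
      if (local < step / 4096) {
        # even the smallest damped step cannot descend: the path has
        # reached its resolution limit at (or next to) the terminus
        stuck <- TRUE
        break
      }
    }
    if (stuck) break
    de <- utils::tail(energy, 1L) - vt$energy
    arc <- arc + sqrt(sum((w * (trial - xyz))^2))
    xyz <- trial; v <- vt
    s <- c(s, sgn * arc)
    dist_ts <- c(dist_ts, mw_dist(xyz))
    energy <- c(energy, vt$energy)
    geoms <- c(geoms, list(set_coords(start, xyz)))
    if (de < limit) break
    local <- min(step, local * 2)            # recover after damping
  }
  if (polish && length(energy) > 1L) {
    sp <- exhaustive_minimize(pes, geoms[[length(geoms)]],
                              window = 100, max_step = polish_cap)
    if (sp$energy <= utils::tail(energy, 1L) + 1e-9) {
      arc <- arc + sqrt(sum((w * (sp$geometry$xyz - xyz))^2))
      s <- c(s, sgn * arc)
      dist_ts <- c(dist_ts, mw_dist(sp$geometry$xyz))
      energy <- c(energy, sp$energy)
      geoms <- c(geoms, list(sp$geometry))
    }
  }
  irc_path(s, energy, geoms, direction, dist_ts = dist_ts)
}

#' Classify an IRC terminus against labeled candidate geometries
#'
#' @param endpoint terminus [geometry()].
#' @param candidates named list of conformable geometries (the expected
#'   intermediates).
#' @param tol matching tolerance on the PES distance (Angstrom).
#' @return the unique matching label, or `"unresolved"` when none or
#'   several candidates fall within `tol`.
#' @export
classify_terminus <- function(endpoint, candidates, tol = 0.1) {
  d <- vapply(candidates, pes_distance, numeric(1), a = endpoint)
  hit <- which(d <= tol)
  if (length(hit) == 1L) names(candidates)[hit] else "unresolved"
}

#' Locate the base of the reaction barrier on a half-path
#'
#' Walking away from the transition state, the slope of the energy
#' profile first grows, then collapses as the nearly flat region at the
#' bottom of the barrier is reached.  The base is the first point past
#' the maximum-slope region whose local slope magnitude falls below
#' `slope_limit`; its distance from the transition state is that side's
#' contribution to the barrier width.  Measuring barrier width base-to-
#' base excludes the essentially flat plain between the barrier bottom
#' and the exact stationary point.
#'
#' @param path an [irc_path()] half-path ordered from the transition
#'   state outward, with at least 3 points.
#' @param slope_limit slope threshold (kcal/mol per Angstrom sqrt(amu)).
#' @return list with `index`, `s` (signed distance of the base point),
#'   `energy` and `width_contribution` (= |s|).
#' @export
barrier_base <- function(path, slope_limit) {
  if (length(path$s) < 3L) stop("path needs at least 3 points")
  ds <- diff(path$s); de <- diff(path$energy)
  slope <- abs(de / ds)
  peak <- which.max(slope)
  after <- which(slope < slope_limit)
  after <- after[after >= peak]
  if (!length(after)) {
    stop("slope never falls below ", slope_limit,
         " beyond the steepest segment; follow the path further")
  }
  i <- after[1L] + 1L   # outer endpoint of the first flat segment
  list(index = i, s = path$s[i], energy = path$energy[i],
       width_contribution = path$dist_ts[i])
}
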