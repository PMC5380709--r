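#' Potential-energy-surface engine contract
#'
#' A PES engine supplies the energy (kcal/mol) and Cartesian gradient
#' (kcal/mol/Angstrom) of a [geometry()].  Engines may hold expensive
#' reusable internal state (e.g. a converged wavefunction): callers such as
#' [minimize_biased_pair()] freeze the state once at the start of each bias
#' step and perform every geometric operation of that step against the
#' frozen state, mirroring the single-SCF-per-step economy of semiempirical
#' drivers.  The built-in analytic engines have no such state and implement
#' freeze/release as no-ops.
#'
#' @param label short engine name.
#' @param eval_fn `function(xyz_matrix) -> list(energy=, gradient=)` with
#'   the gradient an n x 3 matrix.
#' @param freeze_fn,release_fn optional state controls.
#' @return an object of class `pes_engine`.
#' @export
pes_engine <- function(label, eval_fn, freeze_fn = NULL, release_fn = NULL) {
  structure(list(label = label, eval_fn = eval_fn,
                 freeze_fn = freeze_fn, release_fn = release_fn),
            class = "pes_engine")
}

#' Evaluate a PES engine on a geometry
#' @param engine a [pes_engine()].
#' @param g a [geometry()] (or bare n x 3 coordinate matrix).
#' @return list with `energy` (kcal/mol) and `gradient` (n x 3 matrix,
#'   kcal/mol/Angstrom).
#' @export
pes_evaluate <- function(engine, g) {
  xyz <- if (is_geometry(g)) g$xyz else matrix(as.numeric(g), ncol = 3L)
  out <- engine$eval_fn(xyz)
  if (!is.finite(out$energy)) stop("engine '", engine$label,
                                   "' returned a non-finite energy")
  out$gradient <- matrix(out$gradient, ncol = 3L)
  out
}

#' @rdname pes_engine
#' @param engine a `pes_engine`.
#' @export
pes_freeze_state <- function(engine) {
  if (!is.null(engine$freeze_fn)) engine$freeze_fn()
  invisible(engine)
}

#' @rdname pes_engine
#' @export
pes_release_state <- function(engine) {
  if (!is.null(engine$release_fn)) engine$release_fn()
  invisible(engine)
}

# ---------------------------------------------------------------------------
# Mueller-Brown analytic test surface

.MB <- list(A  = c(-200, -100, -170, 15),
            a  = c(-1, -1, -6.5, 0.7),
            b  = c(0, 0, 11, 0.6),
            cc = c(-10, -10, -6.5, 0.7),
            x0 = c(1, 0, -0.5, -1),
            y0 = c(0, 0.5, 1.5, 1))

#' Mueller-Brown surface: energy, gradient and Hessian at a 2-D point
#'
#' The standard four-term exponential test surface with three minima and
#' two first-order saddles, treated as kcal/mol vs Angstrom so the rest of
#' the toolkit applies unchanged.  The surface is wrapped as a one-atom
#' geometry (pseudo-element "X", unit mass) whose z coordinate is inert.
#'
#' @param x,y coordinates.
#' @return `mueller_brown`: list with `energy`, `gradient` (length 2) and
#'   `hessian` (2 x 2), all analytic.
#' @export
mueller_brown <- function(x, y) {
  p <- .MB
  dx <- x - p$x0; dy <- y - p$y0
  # clamp the exponent so far-field probe points stay finite (the fourth
  # term grows without bound); irrelevant anywhere near the basins
  ex <- p$A * exp(pmin(p$a * dx^2 + p$b * dx * dy + p$cc * dy^2, 40))
  gx <- sum(ex * (2 * p$a * dx + p$b * dy))
  gy <- sum(ex * (p$b * dx + 2 * p$cc * dy))
  hxx <- sum(ex * ((2 * p$a * dx + p$b * dy)^2 + 2 * p$a))
  hyy <- sum(ex * ((p$b * dx + 2 * p$cc * dy)^2 + 2 * p$cc))
  hxy <- sum(ex * ((2 * p$a * dx + p$b * dy) * (p$b * dx + 2 * p$cc * dy) +
                     p$b))
  list(energy = sum(ex), gradient = c(gx, gy),
       hessian = matrix(c(hxx, hxy, hxy, hyy), 2L))
}

#' @rdname mueller_brown
#' @export
mb_engine <- function() {
  pes_engine("mueller-brown", function(xyz) {
    v <- mueller_brown(xyz[1L, 1L], xyz[1L, 2L])
    grad <- matrix(0, nrow(xyz), 3L)
    grad[1L, 1:2] <- v$gradient
    list(energy = v$energy, gradient = grad)
  })
}

#' Wrap a 2-D point as a one-atom pseudo-geometry
#' @param x,y surface coordinates.
#' @return a one-atom [geometry()] with unit mass.
#' @export
mb_geometry <- function(x, y) {
  geometry("X", matrix(c(x, y, 0), 1L), mass = 1)
}

# ---------------------------------------------------------------------------
# Toy proton-transfer potential

#' Parameters of the toy proton-transfer potential
#'
#' A donor--H--acceptor system modeled as two Morse bonds competing for the
#' hydrogen, a repulsion between the heavy atoms, and optional harmonic
#' tethers holding spectator atoms near reference positions.  With
#' symmetric donor/acceptor parameters and the heavy atoms held at a
#' separation in the double-well regime, the hydrogen experiences a
#' symmetric double well whose maximum sits at the midpoint -- a desk-scale
#' stand-in for the proton migrations of an enzyme catalytic cycle.
#'
#' @param de_d,de_a Morse well depths for donor--H and acceptor--H
#'   (kcal/mol, > 0).
#' @param r0_d,r0_a equilibrium bond lengths (Angstrom, > 0).
#' @param a_d,a_a Morse stiffness parameters (1/Angstrom).
#' @param rep_a,rep_b donor--acceptor repulsion `rep_a * exp(-rep_b * R)`
#'   (kcal/mol and 1/Angstrom).
#' @param tether_k spectator tether force constant (kcal/mol/Angstrom^2).
#' @return list of class `proton_params`.
#' @export
proton_params <- function(de_d = 110, de_a = 110, r0_d = 1.0, r0_a = 1.0,
                          a_d = 3.5, a_a = 3.5,
                          rep_a = 1.5e8, rep_b = 6.0, tether_k = 50) {
  stopifnot(de_d > 0, de_a > 0, r0_d > 0, r0_a > 0, a_d > 0, a_a > 0,
            rep_a >= 0, rep_b > 0, tether_k >= 0)
  structure(list(de_d = de_d, de_a = de_a, r0_d = r0_d, r0_a = r0_a,
                 a_d = a_d, a_a = a_a, rep_a = rep_a, rep_b = rep_b,
                 tether_k = tether_k),
            class = "proton_params")
}

# Morse energy and its derivative wrt bond length; V(r0) = -De, V(Inf) = 0
.morse <- function(r, de, a, r0) {
  e <- exp(-a * (r - r0))
  list(v = de * ((1 - e)^2 - 1), dv = 2 * de * a * (1 - e) * e)
}

#' Proton-transfer engine
#'
#' @param params a [proton_params()].
#' @param donor,h,acceptor atom indices of the tagged reactive triplet.
#' @param tether_ref optional n x 3 matrix of spectator reference
#'   positions; defaults to the positions at engine construction (rows for
#'   the reactive triplet are ignored).  Pass `NULL` to disable tethers.
#' @param g0 geometry supplying the default tether reference.
#' @return a [pes_engine()].
#' @export
proton_engine <- function(params, donor, h, acceptor, g0 = NULL,
                          tether_ref = if (!is.null(g0)) g0$xyz) {
  stopifnot(inherits(params, "proton_params"))
  idx <- c(donor = donor, h = h, acceptor = acceptor)
  if (anyNA(idx)) stop("donor, h and acceptor atoms must all be tagged")
  pes_engine("proton-transfer", function(xyz) {
    n <- nrow(xyz)
    if (any(idx > n)) stop("tagged atom index exceeds atom count")
    grad <- matrix(0, n, 3L)
    pair <- function(i, j) {
      d <- xyz[i, ] - xyz[j, ]
      r <- sqrt(sum(d^2))
      list(r = r, u = if (r > 0) d / r else c(0, 0, 0))
    }
    dh <- pair(idx["donor"], idx["h"])
    ah <- pair(idx["acceptor"], idx["h"])
    da <- pair(idx["donor"], idx["acceptor"])
    m1 <- .morse(dh$r, params$de_d, params$a_d, params$r0_d)
    m2 <- .morse(ah$r, params$de_a, params$a_a, params$r0_a)
    vrep <- params$rep_a * exp(-params$rep_b * da$r)
    energy <- m1$v + m2$v + vrep
    add <- function(i, j, u, dv) {
      grad[i, ] <<- grad[i, ] + dv * u
      grad[j, ] <<- grad[j, ] - dv * u
    }
    add(idx["donor"], idx["h"], dh$u, m1$dv)
    add(idx["acceptor"], idx["h"], ah$u, m2$dv)
    add(idx["donor"], idx["acceptor"], da$u, -params$rep_b * vrep)
    if (!is.null(tether_ref) && params$tether_k > 0) {
      spect <- setdiff(seq_len(n), idx)
      for (i in spect) {
        d <- xyz[i, ] - tether_ref[i, ]
        energy <- energy + 0.5 * params$tether_k * sum(d^2)
        grad[i, ] <- grad[i, ] + params$tether_k * d
      }
    }
    list(energy = energy, gradient = grad)
  })
}

# ---------------------------------------------------------------------------
# Simple quadratic bowl (tests, drag probes)

#' Harmonic bowl engine
#'
#' `E = 0.5 * k * |x - center|^2` summed over all coordinates; a
#' single-basin surface used for barrierless probes and closed-form tests.
#'
#' @param center n x 3 matrix (or length-3n vector) of the minimum.
#' @param k force constant, kcal/mol/Angstrom^2.
#' @return a [pes_engine()].
#' @export
quadratic_engine <- function(center, k = 1) {
  center <- matrix(as.numeric(center), ncol = 3L)
  pes_engine("quadratic", function(xyz) {
    d <- xyz - center
    list(energy = 0.5 * k * sum(d^2), gradient = k * d)
  })
}

#' Symmetric one-dimensional double well
#'
#' `E = h * ((x/w)^2 - 1)^2` on the x coordinate of a one-atom geometry:
#' minima at x = -w and x = +w, barrier of height `h` at x = 0.
#'
#' @param h barrier height (kcal/mol).
#' @param w half-separation of the minima (Angstrom).
#' @return a [pes_engine()].
#' @export
double_well_engine <- function(h = 10, w = 1) {
  pes_engine("double-well", function(xyz) {
    x <- xyz[1L, 1L]
    grad <- matrix(0, nrow(xyz), 3L)
    grad[1L, 1L] <- 4 * h * x * ((x / w)^2 - 1) / w^2
    list(energy = h * ((x / w)^2 - 1)^2, gradient = grad)
  })
}

# ---------------------------------------------------------------------------
# External engine adapter

#' Adapter driving an external program as a PES engine
#'
#' The engine writes the current geometry to an XYZ input file, runs the
#' command, and parses the output file, which must contain a line
#' `ENERGY <kcal/mol>` and one `GRAD <i> <gx> <gy> <gz>` line per atom.
#' The command template must contain `{input}` and `{output}` placeholders;
#' an optional `{reuse}` placeholder receives `1` while the engine state is
#' frozen and `0` otherwise, so the driven program can skip re-converging
#' its internal state.
#'
#' @param command command template string.
#' @param template geometry whose elements frame the written XYZ (the
#'   coordinates are replaced at each evaluation).
#' @param workdir directory for the exchange files.
#' @return a [pes_engine()].
#' @export
external_engine <- function(command, template, workdir = tempdir()) {
  if (!grepl("{input}", command, fixed = TRUE) ||
      !grepl("{output}", command, fixed = TRUE)) {
    stop("command template must contain {input} and {output} placeholders")
  }
  frozen <- FALSE
  eval_fn <- function(xyz) {
    g <- set_coords(template, xyz)
    input <- file.path(workdir, "engine_in.xyz")
    output <- file.path(workdir, "engine_out.dat")
    if (file.exists(output)) unlink(output)
    write_xyz(g, input, comment = paste0("reuse=", as.integer(frozen)))
    cmd <- gsub("{input}", input, command, fixed = TRUE)
    cmd <- gsub("{output}", output, cmd, fixed = TRUE)
    cmd <- gsub("{reuse}", as.integer(frozen), cmd, fixed = TRUE)
    res <- suppressWarnings(system(cmd, intern = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0) {
      stop("external engine command failed (exit ", status, "): ",
           paste(res, collapse = "\n"))
    }
    if (!file.exists(output)) stop("external engine produced no output file")
    lines <- readLines(output, warn = FALSE)
    eline <- grep("^ENERGY\\s", lines, value = TRUE)
    glines <- grep("^GRAD\\s", lines, value = TRUE)
    if (length(eline) != 1L || length(glines) != nrow(xyz)) {
      stop("unparseable external engine output:\n",
           paste(lines, collapse = "\n"))
    }
    energy <- as.numeric(strsplit(trimws(eline), "\\s+")[[1L]][2L])
    gmat <- t(vapply(strsplit(trimws(glines), "\\s+"),
                     function(f) as.numeric(f[3:5]), numeric(3)))
    ord <- as.integer(vapply(strsplit(trimws(glines), "\\s+"),
                             `[[`, "", 2L))
    gmat <- gmat[order(ord), , drop = FALSE]
    if (!is.finite(energy) || anyNA(gmat)) {
      stop("unparseable numbers in external engine output:\n",
           paste(lines, collapse = "\n"))
    }
    list(energy = energy, gradient = gmat)
  }
  pes_engine("external", eval_fn,
             freeze_fn = function() frozen <<- TRUE,
             release_fn = function() frozen <<- FALSE)
}
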