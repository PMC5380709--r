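#' Fixture specification
#'
#' Identical (name, seed, overrides) specifications produce byte-identical
#' outputs.
#'
#' @param name fixture name.
#' @param seed integer RNG seed.
#' @param overrides named list of parameter overrides.
#' @param outdir output directory (created if absent).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(name, seed = 1L, overrides = list(),
                         outdir = tempdir()) {
  structure(list(name = name, seed = as.integer(seed),
                 overrides = overrides, outdir = outdir),
            class = "fixture_spec")
}

# run expr with a seeded, self-contained RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Stationary-point catalogue of the Mueller-Brown surface
#'
#' Oracle computation: Newton refinement (analytic gradient and Hessian)
#' from a dense grid of starting points, deduplicated and classified by
#' the Hessian eigenvalue spectrum.  Yields the surface's three minima
#' and two first-order saddles, the ground truth against which the
#' saddle-search pipeline is checked.
#'
#' @param grid_step spacing of the Newton starting grid.
#' @return data.frame with `label`, `type` (`"minimum"`/`"saddle"`), `x`,
#'   `y`, `energy`, `neg_eigenvalues`, sorted by energy within type.
#' @export
mb_stationary_points <- function(grid_step = 0.1) {
  starts <- expand.grid(x = seq(-1.7, 1.3, by = grid_step),
                        y = seq(-0.4, 2.1, by = grid_step))
  pts <- list()
  for (i in seq_len(nrow(starts))) {
    p <- c(starts$x[i], starts$y[i])
    ok <- TRUE
    for (it in 1:60) {
      v <- mueller_brown(p[1L], p[2L])
      if (sqrt(sum(v$gradient^2)) < 1e-11) break
      stepv <- tryCatch(solve(v$hessian, v$gradient),
                        error = function(e) NULL)
      if (is.null(stepv) || !all(is.finite(stepv))) { ok <- FALSE; break }
      nrm <- sqrt(sum(stepv^2))
      if (nrm > 0.25) stepv <- stepv * 0.25 / nrm   # damped Newton
      p <- p - stepv
      if (any(abs(p) > 5)) { ok <- FALSE; break }
    }
    v <- mueller_brown(p[1L], p[2L])
    if (ok && sqrt(sum(v$gradient^2)) < 1e-9) {
      pts[[length(pts) + 1L]] <- c(p, v$energy)
    }
  }
  m <- do.call(rbind, pts)
  m <- m[!duplicated(round(m[, 1:2, drop = FALSE], 6L)), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    v <- mueller_brown(m[i, 1L], m[i, 2L])
    ev <- eigen(v$hessian, symmetric = TRUE, only.values = TRUE)$values
    data.frame(type = if (all(ev > 0)) "minimum" else
                 if (sum(ev < 0) == 1L) "saddle" else "maximum",
               x = m[i, 1L], y = m[i, 2L], energy = v$energy,
               neg_eigenvalues = sum(ev < 0))
  }))
  out <- out[out$type != "maximum", , drop = FALSE]
  out <- out[order(out$type, out$energy), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(out)), out$type, FUN = seq_along)
  out$label <- paste0(ifelse(out$type == "minimum", "min", "ts"), idx)
  rownames(out) <- NULL
  out[, c("label", "type", "x", "y", "energy", "neg_eigenvalues")]
}

#' Endpoint pair and oracle catalogue on the Mueller-Brown surface
#'
#' Writes one-atom pseudo-geometries at two catalogued minima (by default
#' the two deepest) plus the full stationary-point catalogue.
#'
#' @param spec a [fixture_spec()]; overrides `from` / `to` select the
#'   endpoint minima by label.
#' @return invisibly, list of written paths plus the catalogue.
#' @export
make_mb_pair <- function(spec = fixture_spec("mb")) {
  dir.create(spec$outdir, showWarnings = FALSE, recursive = TRUE)
  cat_df <- mb_stationary_points()
  from <- spec$overrides$from %||% "min1"
  to <- spec$overrides$to %||% "min2"
  pick <- function(lab) {
    r <- cat_df[cat_df$label == lab, ]
    if (!nrow(r)) stop("no catalogued point labeled ", lab)
    mb_geometry(r$x, r$y)
  }
  paths <- list(
    reactant = file.path(spec$outdir, "mb_reactant.xyz"),
    product = file.path(spec$outdir, "mb_product.xyz"),
    catalogue = file.path(spec$outdir, "mb_catalogue.csv"))
  write_xyz(pick(from), paths$reactant, comment = paste("mb", from))
  write_xyz(pick(to), paths$product, comment = paste("mb", to))
  utils::write.csv(cat_df, paths$catalogue, row.names = FALSE)
  invisible(c(paths, list(table = cat_df)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proton-transfer toy fixture
#'
#' A donor--H--acceptor triplet (donor and acceptor nitrogens 2.7 A
#' apart on the x axis, hydrogen bonded to the donor in the reactant and
#' to the acceptor in the product) plus seeded spectator carbons drawn
#' from a uniform shell and tethered in place.  The reactive-triplet
#' coordinates are identical across seeds; only the spectators move.
#'
#' @param spec a [fixture_spec()]; honored overrides: `n_spectators`
#'   (default 4), `shell` (radius range, default c(3.5, 4.5)),
#'   `params` (a [proton_params()]).
#' @return invisibly, list with written paths, the geometries, the
#'   engine parameters and the tagged indices.
#' @export
make_proton_transfer <- function(spec = fixture_spec("proton")) {
  dir.create(spec$outdir, showWarnings = FALSE, recursive = TRUE)
  n_spect <- spec$overrides$n_spectators %||% 4L
  shell <- spec$overrides$shell %||% c(3.5, 4.5)
  params <- spec$overrides$params %||% proton_params()
  d_da <- spec$overrides$d_da %||% 2.7
  center <- c(d_da / 2, 0, 0)
  core <- rbind(c(0, 0, 0),            # donor N
                c(params$r0_d, 0, 0),  # H (reactant position)
                c(d_da, 0, 0))         # acceptor N
  spect <- .with_seed(spec$seed, {
    out <- NULL; tries <- 0L
    while (is.null(out)) {
      tries <- tries + 1L
      if (tries > 100L) stop("could not place non-overlapping spectators")
      m <- t(vapply(seq_len(n_spect), function(i) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        center + stats::runif(1, shell[1L], shell[2L]) * u
      }, numeric(3)))
      all_xyz <- rbind(core, m)
      if (n_spect == 0L || min(stats::dist(all_xyz)) >= 0.7) out <- m
      else message("spectator overlap < 0.7 A; regenerating (try ",
                   tries, ")")
    }
    out
  })
  elements <- c("N", "H", "N", rep("C", n_spect))
  reactant <- geometry(elements, rbind(core, spect))
  pxyz <- rbind(core, spect)
  pxyz[2L, 1L] <- d_da - params$r0_a     # H bonded to the acceptor
  product <- geometry(elements, pxyz)
  paths <- list(reactant = file.path(spec$outdir, "proton_reactant.xyz"),
                product = file.path(spec$outdir, "proton_product.xyz"),
                params = file.path(spec$outdir, "proton_params.txt"))
  write_xyz(reactant, paths$reactant, comment = "proton transfer reactant")
  write_xyz(product, paths$product, comment = "proton transfer product")
  writeLines(c(sprintf("%s = %.6f", names(unclass(params)),
                       unlist(params)),
               "donor = 1", "h = 2", "acceptor = 3",
               sprintf("seed = %d", spec$seed)),
             paths$params)
  invisible(list(files = paths, reactant = reactant, product = product,
                 params = params, donor = 1L, h = 2L, acceptor = 3L))
}

# fixed-precision CSV writer so regenerated tables are byte-identical
.write_fixed_csv <- function(df, path, digits) {
  out <- df
  for (nm in names(digits)) {
    out[[nm]] <- sprintf(paste0("%.", digits[[nm]], "f"), df[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the chymotrypsin reference tables as CSV fixtures
#'
#' Emits the catalytic-cycle heats (native and Met192-truncated),
#' the four-system electrostatic and hydrogen-bond sets, and the
#' per-residue charge table, with the printed 2-decimal (heats) and
#' 3-decimal (charges) precision preserved so re-emission is
#' byte-identical.
#'
#' @param spec a [fixture_spec()].
#' @return invisibly, named vector of written paths.
#' @export
make_reference_tables <- function(spec = fixture_spec("tables")) {
  dir.create(spec$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- c(cycle = "chymo_cycle_heats.csv",
         met192 = "chymo_met192_heats.csv",
         electro = "chymo_electrostatic_systems.csv",
         hbond = "chymo_hbond_systems.csv",
         charges = "chymo_residue_charges.csv")
  p <- vapply(p, function(f) file.path(spec$outdir, f), "")
  .write_fixed_csv(as.data.frame(chymo_cycle_heats()), p["cycle"],
                   c(dhf = 2))
  .write_fixed_csv(as.data.frame(chymo_met192_heats()), p["met192"],
                   c(dhf = 2))
  .write_fixed_csv(chymo_electrostatic_systems(), p["electro"],
                   c(dhf = 2))
  .write_fixed_csv(chymo_hbond_systems(), p["hbond"], c(dhf = 2))
  .write_fixed_csv(chymo_residue_charges(), p["charges"],
                   c(step1 = 3, step2 = 3, delta = 3))
  invisible(p)
}
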