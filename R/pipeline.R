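#' Read a simple key/value configuration file
#'
#' Lines of `key = value`; `[section]` headers prefix subsequent keys as
#' `section.key`; `#` starts a comment.  Values are converted to numeric
#' when possible.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1L])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Locate, refine and validate a transition state from two endpoints
#'
#' The full pipeline: relax both endpoints, compare their covalent
#' topologies to find the reactive atoms, run the double-ended biased
#' ascent, refine the guess by partitioned alternation, and validate the
#' result by subset vibrational analysis.
#'
#' @param pes a [pes_engine()].
#' @param reactant,product endpoint geometries.
#' @param schedule a [bias_schedule()]; by default `r_stop` is scaled to
#'   1 percent of the initial endpoint separation (the protein-scale 3.0 A
#'   default is far too coarse for desk-scale fixtures).
#' @param active reactive atom indices; inferred with [diff_topology()]
#'   when `NULL`.
#' @param relax_endpoints exhaustively minimize the endpoints first?
#' @param min_imag,loc_threshold forwarded to [validate_ts()].
#' @return list with `ascent`, `ts` (a [stationary_point()]), `modes`,
#'   `validation`, `active`, and the relaxed endpoints.
#' @export
locate_ts <- function(pes, reactant, product, schedule = NULL,
                      active = NULL, relax_endpoints = TRUE,
                      min_imag = 50, loc_threshold = 0.5) {
  if (relax_endpoints) {
    reactant <- exhaustive_minimize(pes, reactant)$geometry
    product <- exhaustive_minimize(pes, product)$geometry
  }
  if (is.null(schedule)) {
    r0 <- pes_distance(reactant, product)
    schedule <- bias_schedule(r_stop = max(0.01 * r0, 1e-4))
  }
  if (is.null(active)) {
    active <- diff_topology(infer_topology(reactant),
                            infer_topology(product))
    if (!length(active)) active <- seq_len(n_atoms(reactant))
  }
  ascent <- ascend_barrier(pes, reactant, product, schedule)
  if (ascent$no_barrier) {
    return(list(ascent = ascent, ts = NULL, modes = NULL,
                validation = NULL, active = active,
                reactant = reactant, product = product))
  }
  ts <- refine_saddle(pes, ascent$ts_guess, active)
  H <- partial_hessian(pes, ts$geometry, active)
  modes <- normal_modes(H, ts$geometry$mass[active], subset = active)
  ts$modes <- modes
  validation <- validate_ts(modes, reactive = active, min_imag = min_imag,
                            loc_threshold = loc_threshold)
  list(ascent = ascent, ts = ts, modes = modes, validation = validation,
       active = active, reactant = reactant, product = product)
}

#' Both halves of the IRC from a validated transition state
#'
#' Displaces the transition state along its imaginary mode in both
#' directions, follows each mass-weighted steepest-descent half-path and
#' classifies both termini against the supplied intermediates.
#'
#' @param pes a [pes_engine()].
#' @param ts a [stationary_point()] with attached modes.
#' @param candidates named list of candidate terminus geometries.
#' @param delta initial displacement (mass-weighted Angstrom).
#' @param tol terminus matching tolerance (Angstrom).
#' @param ... forwarded to [follow_irc()].
#' @return list with `forward`, `reverse` ([irc_path()]s, termini set)
#'   and `ts_energy`.
#' @export
irc_both_ways <- function(pes, ts, candidates = list(), delta = 0.05,
                          tol = 0.1, ...) {
  if (is.null(ts$modes)) stop("transition state carries no normal modes")
  run <- function(sgn, dir) {
    start <- displace_along_mode(ts$geometry, ts$modes, delta = delta,
                                 sign = sgn)
    path <- follow_irc(pes, start, reference = ts$geometry,
                       direction = dir, ...)
    if (length(candidates)) {
      path$terminus <- classify_terminus(
        path$geometries[[length(path$geometries)]], candidates, tol = tol)
    }
    path
  }
  list(forward = run(1, "forward"), reverse = run(-1, "reverse"),
       ts_energy = ts$energy)
}

#' Seeded end-to-end demonstration on the proton-transfer fixture
#'
#' Chains fixture generation, endpoint relaxation, the double-ended
#' ascent, partitioned refinement, vibrational validation and IRC
#' following, asserting the invariants a successful transition-state
#' search must satisfy: exactly one imaginary mode, both IRC termini at
#' the intended intermediates, and a positive barrier.
#'
#' @param seed fixture seed.
#' @param outdir fixture output directory.
#' @return list with the pipeline results and a `summary` data.frame.
#' @export
run_demo <- function(seed = 1L, outdir = tempdir()) {
  fx <- make_proton_transfer(fixture_spec("proton", seed = seed,
                                          outdir = outdir))
  pes <- proton_engine(fx$params, fx$donor, fx$h, fx$acceptor,
                       g0 = fx$reactant)
  res <- locate_ts(pes, fx$reactant, fx$product)
  reactant <- res$reactant; product <- res$product
  irc <- irc_both_ways(pes, res$ts,
                       candidates = list(reactant = reactant,
                                         product = product),
                       tol = 0.2)
  e_r <- pes_evaluate(pes, reactant)$energy
  barrier <- res$ts$energy - e_r
  ok <- res$validation$n_imag == 1L &&
    setequal(c(irc$forward$terminus, irc$reverse$terminus),
             c("reactant", "product")) &&
    barrier > 0
  if (!ok) stop("demo invariants violated")
  summary <- data.frame(
    barrier_kcal = barrier,
    imag_wavenumber = res$validation$imag_wavenumber,
    localization = res$validation$localization,
    forward_terminus = irc$forward$terminus,
    reverse_terminus = irc$reverse$terminus)
  list(fixture = fx, result = res, irc = irc, summary = summary)
}
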