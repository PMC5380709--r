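mb_modes_at <- function(label) {
  mb <- mb_engine()
  ts <- mb_point(label)
  normal_modes(partial_hessian(mb, ts, 1L), masses = 1)
}

test_that("mode displacement is symmetric and strictly downhill", {
  mb <- mb_engine()
  ts <- mb_point("ts1")
  nm <- mb_modes_at("ts1")
  plus <- displace_along_mode(ts, nm, delta = 0.05, sign = 1)
  minus <- displace_along_mode(ts, nm, delta = 0.05, sign = -1)
  expect_equal(sqrt(sum((plus$xyz - ts$xyz)^2)), 0.05)
  # mirror images through the transition state
  expect_equal(plus$xyz - ts$xyz, -(minus$xyz - ts$xyz))
  e0 <- pes_evaluate(mb, ts)$energy
  expect_lt(pes_evaluate(mb, plus)$energy, e0)
  expect_lt(pes_evaluate(mb, minus)$energy, e0)
  expect_error(displace_along_mode(ts, nm, delta = 2), "cap")
})

test_that("IRC halves reach the catalogued adjacent minima monotonically", {
  mb <- mb_engine()
  expected <- list(ts1 = c("min3", "min2"), ts2 = c("min3", "min1"))
  candidates <- list(min1 = mb_point("min1"), min2 = mb_point("min2"),
                     min3 = mb_point("min3"))
  for (lab in names(expected)) {
    ts <- mb_point(lab)
    nm <- mb_modes_at(lab)
    termini <- character(0)
    for (sgn in c(1, -1)) {
      start <- displace_along_mode(ts, nm, 0.05, sgn)
      path <- follow_irc(mb, start, reference = ts,
                         direction = if (sgn > 0) "forward" else "reverse")
      expect_true(all(diff(path$energy) <= 1e-6))
      if (sgn > 0) expect_true(all(diff(abs(path$s)) >= -1e-9))
      endp <- path$geometries[[length(path$geometries)]]
      lab_end <- classify_terminus(endp, candidates, tol = 1e-3)
      termini <- c(termini, lab_end)
      # terminus within 1e-3 of the catalogued minimum
      expect_true(lab_end %in% expected[[lab]])
    }
    expect_setequal(termini, expected[[lab]])
  }
})

test_that("IRC handles symmetric and degenerate starts", {
  # symmetric double well: forward and reverse paths are mirror images
  dw <- double_well_engine(h = 10, w = 1)
  nm <- normal_modes(partial_hessian(dw, geometry("X", matrix(0, 1L, 3L),
                                                  mass = 1), 1L),
                     masses = 1)
  ts <- geometry("X", matrix(0, 1L, 3L), mass = 1)
  fwd <- follow_irc(dw, displace_along_mode(ts, nm, 0.05, 1),
                    reference = ts, direction = "forward")
  rev <- follow_irc(dw, displace_along_mode(ts, nm, 0.05, -1),
                    reference = ts, direction = "reverse")
  expect_equal(fwd$energy, rev$energy, tolerance = 1e-8)
  expect_equal(fwd$s, -rev$s, tolerance = 1e-8)
  ends <- unname(c(fwd$geometries[[length(fwd$geometries)]]$xyz[1L, 1L],
                   rev$geometries[[length(rev$geometries)]]$xyz[1L, 1L]))
  expect_equal(sort(ends), c(-1, 1), tolerance = 1e-3)

  # start at an exact minimum: immediate termination, single-point path
  minpt <- geometry("X", matrix(c(1, 0, 0), 1L), mass = 1)
  p0 <- follow_irc(dw, minpt)
  expect_identical(length(p0$s), 1L)

  # equal masses: mass-weighted and Cartesian paths coincide after
  # rescaling the coordinate (the paths visit the same geometries)
  heavy <- geometry("X", matrix(0, 1L, 3L), mass = 4)
  nm4 <- normal_modes(partial_hessian(dw, heavy, 1L), masses = 4)
  f4 <- follow_irc(dw, displace_along_mode(set_coords(heavy, ts$xyz),
                                           nm4, 0.05, 1),
                   reference = heavy, direction = "forward")
  x1 <- vapply(fwd$geometries, function(g) g$xyz[1L, 1L], numeric(1))
  x4 <- vapply(f4$geometries, function(g) g$xyz[1L, 1L], numeric(1))
  expect_equal(utils::tail(x4, 1L), utils::tail(x1, 1L), tolerance = 1e-3)
})

test_that("terminus classification resolves unique matches only", {
  cand <- list(a = mb_point("min1"), b = mb_point("min2"))
  expect_identical(classify_terminus(mb_point("min1"), cand, tol = 0.1),
                   "a")
  far <- mb_geometry(5, 5)
  expect_identical(classify_terminus(far, cand, tol = 0.1), "unresolved")
  # tie: equidistant from two candidates inside tol
  midpt <- mb_geometry(mean(c(mb_xy("min1")[1L], mb_xy("min2")[1L])),
                       mean(c(mb_xy("min1")[2L], mb_xy("min2")[2L])))
  expect_identical(classify_terminus(midpt, cand, tol = 10), "unresolved")
})

test_that("barrier base sits where the slope first collapses", {
  # truncated parabola with flat tails: symmetric base points
  s <- seq(0, 3, by = 0.05)
  e <- ifelse(s < 1.5, 20 - 8 * s^2, 20 - 8 * 1.5^2)
  pf <- irc_path(s, e, direction = "forward")
  pr <- irc_path(-s, e, direction = "reverse")
  bf <- barrier_base(pf, slope_limit = 1)
  br <- barrier_base(pr, slope_limit = 1)
  expect_equal(bf$width_contribution, br$width_contribution)
  expect_equal(bf$s, -br$s)
  width <- bf$width_contribution + br$width_contribution
  expect_equal(width, 2 * bf$width_contribution)

  # strictly linear descent: no flat region, error
  lin <- irc_path(s, 10 - 5 * s, direction = "forward")
  expect_error(barrier_base(lin, slope_limit = 1), "slope")

  # on a computed Mueller-Brown half-path the base point's slope is
  # below the limit while its predecessor's is not
  mb <- mb_engine()
  ts <- mb_point("ts1")
  nm <- mb_modes_at("ts1")
  path <- follow_irc(mb, displace_along_mode(ts, nm, 0.05, -1),
                     reference = ts, direction = "reverse")
  bb <- barrier_base(path, slope_limit = 5)
  slopes <- abs(diff(path$energy) / diff(path$s))
  expect_lt(slopes[bb$index - 1L], 5)
  expect_gte(slopes[bb$index - 2L], 5)
})

test_that("capped endpoint polish keeps termini on their own branch", {
  # the overstep hazard: unconstrained optimization on a shallow path can
  # jump to the other downhill branch; the trust-radius cap must hold the
  # terminus on the half-path's own side across seeded perturbations
  mb <- mb_engine()
  candidates <- list(min1 = mb_point("min1"), min2 = mb_point("min2"),
                     min3 = mb_point("min3"))
  ts <- mb_point("ts1")
  nm <- mb_modes_at("ts1")
  base <- lapply(c(1, -1), function(sgn)
    displace_along_mode(ts, nm, 0.05, sgn))
  own_side <- vapply(base, function(st) {
    p <- follow_irc(mb, st, reference = ts)
    classify_terminus(p$geometries[[length(p$geometries)]], candidates,
                      tol = 1e-3)
  }, "")
  set.seed(77)
  for (i in 1:20) {
    k <- sample(1:2, 1L)
    st <- base[[k]]
    pert <- set_coords(st, st$xyz + cbind(matrix(rnorm(2, sd = 5e-3),
                                                 1L), 0))
    p <- follow_irc(mb, pert, reference = ts)
    lab <- classify_terminus(p$geometries[[length(p$geometries)]],
                             candidates, tol = 1e-3)
    expect_identical(lab, own_side[k])
  }
})
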