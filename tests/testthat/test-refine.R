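test_that("exhaustive minimization reaches closed-form minima", {
  ctr <- matrix(c(0.3, -0.2, 0.7, 1.1, 0.0, -0.5), 2L, byrow = TRUE)
  qe <- quadratic_engine(ctr, k = 3)
  g0 <- geometry(c("C", "O"), ctr + 0.5)
  sp <- exhaustive_minimize(qe, g0, window = 50)
  expect_equal(sp$geometry$xyz, ctr, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sp$energy, 0, tolerance = 1e-10)

  # frozen set = all atoms: identity, single evaluation
  spf <- exhaustive_minimize(qe, g0, frozen = 1:2)
  expect_identical(spf$geometry$xyz, g0$xyz)
  expect_equal(spf$energy, pes_evaluate(qe, g0)$energy)
})

test_that("frozen atoms never move through exhaustive minimization", {
  set.seed(41)
  fx <- make_proton_transfer(fixture_spec("proton", seed = 2))
  pe <- proton_engine(fx$params, 1L, 2L, 3L, g0 = fx$reactant)
  for (i in 1:5) {
    frozen <- sort(sample(seq_len(7L), sample(1:5, 1L)))
    g0 <- set_coords(fx$reactant,
                     fx$reactant$xyz + matrix(rnorm(21, sd = 0.05), 7L))
    sp <- exhaustive_minimize(pe, g0, frozen = frozen, window = 50)
    expect_identical(sp$geometry$xyz[frozen, , drop = FALSE],
                     g0$xyz[frozen, , drop = FALSE])
  }
  # divergence guard
  runaway <- pes_engine("runaway", function(xyz)
    list(energy = -1e11 * sum(xyz[, 1L]),
         gradient = matrix(c(rep(-1e11, nrow(xyz)), numeric(2 * nrow(xyz))),
                           nrow(xyz))))
  expect_error(exhaustive_minimize(runaway, water_geometry()),
               "diverging")
})

test_that("partitioned refinement lands on the oracle saddles", {
  mb <- mb_engine()
  for (pair in list(c("min3", "min2", "ts1"), c("min2", "min3", "ts1"),
                    c("min1", "min3", "ts2"), c("min3", "min1", "ts2"))) {
    asc <- ascend_barrier(mb, mb_point(pair[1L]), mb_point(pair[2L]),
                          mb_schedule())
    sp <- refine_saddle(mb, asc$ts_guess, active = 1L)
    expect_lt(sqrt(sum((sp$geometry$xyz[1L, 1:2] - mb_xy(pair[3L]))^2)),
              1e-3)
    expect_lt(sp$grad_norm, 1e-6)
    expect_lt(abs(sp$energy - mb_energy(pair[3L])), 1e-6)
    expect_identical(sp$classification, "transition_state")
  }
  # a guess placed exactly at a minimum comes back classified as one
  spmin <- refine_saddle(mb, mb_point("min2"), active = 1L)
  expect_identical(spmin$classification, "minimum")
})

test_that("proton-transfer refinement converges with frozen spectators", {
  fx <- make_proton_transfer(fixture_spec("proton", seed = 1))
  pe <- proton_engine(fx$params, 1L, 2L, 3L, g0 = fx$reactant)
  res <- locate_ts(pe, fx$reactant, fx$product)
  expect_identical(res$active, 1:3)
  expect_identical(res$ts$classification, "transition_state")
  # symmetric parameters force the H onto the donor-acceptor midpoint
  expect_lt(abs(res$ts$geometry$xyz[2L, 1L] -
                  mean(res$ts$geometry$xyz[c(1L, 3L), 1L])), 1e-6)

  # saddle energy invariant across seeded spectator placements
  energies <- vapply(1:10, function(s) {
    fxs <- make_proton_transfer(fixture_spec("proton", seed = s))
    pes <- proton_engine(fxs$params, 1L, 2L, 3L, g0 = fxs$reactant)
    locate_ts(pes, fxs$reactant, fxs$product)$ts$energy
  }, numeric(1))
  expect_lt(diff(range(energies)), 1e-3)
})

test_that("release after frozen-core optimization moves almost nothing", {
  fx <- make_proton_transfer(fixture_spec("proton", seed = 4))
  pe <- proton_engine(fx$params, 1L, 2L, 3L, g0 = fx$reactant)
  res <- locate_ts(pe, fx$reactant, fx$product)
  # freeze the reactive atoms, exhaustively relax the environment, then
  # release the reactive atoms for a residual gradient minimization
  frozen_core <- exhaustive_minimize(pe, res$ts$geometry,
                                     frozen = res$active)$geometry
  rel <- check_release(pe, frozen_core, active = res$active)
  expect_lt(abs(rel$delta_energy), 0.2)
  expect_lt(rel$max_displacement, 0.001)
})

test_that("partial Hessian recovers force constants and dimensions", {
  # 1-D harmonic oscillator: recovered k within 1e-4 relative at h = 1e-3
  k <- 3.7
  qe <- quadratic_engine(matrix(0, 1L, 3L), k = k)
  g <- geometry("X", matrix(0, 1L, 3L), mass = 1)
  H <- partial_hessian(qe, g, 1L, h = 1e-3)
  expect_equal(H[1L, 1L], k, tolerance = 1e-4)

  # subset of 3 atoms in a 7-atom system: 9x9, environment absent
  fx <- make_proton_transfer(fixture_spec("proton", seed = 1))
  pe <- proton_engine(fx$params, 1L, 2L, 3L, g0 = fx$reactant)
  H3 <- partial_hessian(pe, fx$reactant, 1:3)
  expect_identical(dim(H3), c(9L, 9L))

  # near-symmetry before symmetrization is implied by smooth engines:
  # the symmetrized matrix reproduces an independent full stencil entry
  mb <- mb_engine()
  g2 <- mb_point("ts1")
  Hmb <- partial_hessian(mb, g2, 1L, h = 1e-4)
  expect_equal(Hmb[1:2, 1:2], mueller_brown(g2$xyz[1], g2$xyz[2])$hessian,
               tolerance = 1e-4)
  expect_error(partial_hessian(mb, g2, integer(0)), "nonempty")
})

test_that("normal mode wavenumbers carry correct units and signs", {
  # independent unit-conversion oracle, nu = sqrt(k/mu)/(2 pi c) with
  # k = 1 kcal/mol/A^2 and mu = 1 amu, evaluates to 108.59 1/cm
  H <- diag(c(1, 0, 0))
  nm <- normal_modes(H, masses = 1)
  expect_equal(max(nm$freq), 108.59, tolerance = 0.01)

  # one negative eigenvalue -> exactly one negative-signed wavenumber
  H2 <- diag(c(2, -1, 0.5))
  nm2 <- normal_modes(H2, masses = 1)
  expect_identical(sum(nm2$freq < 0), 1L)
  expect_equal(min(nm2$freq), -108.59, tolerance = 0.01)

  # Mueller-Brown saddle: one imaginary mode parallel to the analytic
  # negative-curvature eigenvector
  mb <- mb_engine()
  ts1 <- mb_point("ts1")
  Hp <- partial_hessian(mb, ts1, 1L)
  nmmb <- normal_modes(Hp, masses = 1)
  expect_identical(sum(nmmb$freq < -1), 1L)
  vref <- eigen(mueller_brown(ts1$xyz[1], ts1$xyz[2])$hessian,
                symmetric = TRUE)$vectors[, 2L]
  vmode <- nmmb$vectors[1:2, which.min(nmmb$freq)]
  expect_equal(abs(sum(vref * vmode / sqrt(sum(vmode^2)))), 1,
               tolerance = 1e-4)
  expect_error(normal_modes(matrix(c(0, 1, 0, 0), 2L), masses = 1),
               "symmetric|dimension")
})

test_that("transition-state validation applies all three checks", {
  fake_modes <- function(freq, loc_vec) {
    m <- length(freq)
    vecs <- diag(m * 0) # placeholder; build explicit localized vectors
    vecs <- matrix(0, m, m)
    for (j in seq_len(m)) vecs[j, j] <- 1
    structure(list(freq = freq, vectors = vecs,
                   masses = rep(1, m / 3), subset = seq_len(m / 3)),
              class = "normal_modes")
  }
  # one strong localized imaginary mode: pass
  m1 <- fake_modes(c(-800, 120, 300), loc_vec = NULL)
  # mode 1 component sits on atom 1 (rows 1:3); reactive = atom 1
  v1 <- validate_ts(m1, reactive = 1L)
  expect_true(v1$checks$single_imaginary)
  expect_true(v1$checks$magnitude)

  # zero imaginary modes: fail, classification minimum
  v0 <- validate_ts(fake_modes(c(50, 120, 300), NULL), reactive = 1L)
  expect_false(v0$pass)
  expect_identical(v0$classification, "minimum")

  # two imaginary modes: fail, higher-order saddle
  v2 <- validate_ts(fake_modes(c(-800, -420, 300), NULL), reactive = 1L)
  expect_false(v2$pass)
  expect_identical(v2$classification, "higher_order_saddle")

  # weak imaginary mode fails the magnitude check
  vw <- validate_ts(fake_modes(c(-20, 120, 300), NULL), reactive = 1L,
                    min_imag = 50)
  expect_false(vw$checks$magnitude)
})
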