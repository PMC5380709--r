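test_that("PES distance matches closed forms and is a metric", {
  g1 <- geometry("C", matrix(c(0, 0, 0), 1L))
  expect_identical(pes_distance(g1, g1), 0)
  g2 <- set_coords(g1, matrix(c(3, 4, 0), 1L))
  expect_equal(pes_distance(g1, g2), 5)
  a <- geometry(c("C", "C"), matrix(0, 2L, 3L))
  b <- set_coords(a, matrix(c(1, 0, 0, 1, 0, 0), 2L, byrow = TRUE))
  expect_equal(pes_distance(a, b), sqrt(2))

  # metric properties on random coordinate sets
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:6, 1L)
    el <- sample(c("C", "N", "O"), n, replace = TRUE)
    ga <- geometry(el, matrix(rnorm(3 * n), n))
    gb <- geometry(el, matrix(rnorm(3 * n), n))
    gc_ <- geometry(el, matrix(rnorm(3 * n), n))
    expect_equal(pes_distance(ga, gb), pes_distance(gb, ga))
    expect_gte(pes_distance(ga, gb) + pes_distance(gb, gc_),
               pes_distance(ga, gc_) - 1e-12)
    expect_identical(pes_distance(ga, ga), 0)
  }
  # non-conformable
  expect_error(pes_distance(g1, a), "conformable")
  expect_error(pes_distance(geometry("C", matrix(0, 1L, 3L)),
                            geometry("N", matrix(0, 1L, 3L))),
               "conformable")
})

test_that("contained angle reproduces law-of-cosines geometry", {
  expect_equal(contained_angle(1, 1, 1), 60)
  expect_equal(contained_angle(2, 3, 5), 180)
  expect_error(contained_angle(1, 1, 3), "triangle")
  expect_error(contained_angle(-1, 1, 1), "positive")

  # brute-force 2-D point placement oracle: place B at origin, A at
  # distance d_ab on the x axis, C at a random direction, and compare the
  # vector angle at B with the distance-only reconstruction
  set.seed(7)
  for (i in 1:50) {
    d_ab <- runif(1, 0.5, 3); d_bc <- runif(1, 0.5, 3)
    theta <- runif(1, 0.05, pi)
    A <- c(d_ab, 0); C <- d_bc * c(cos(theta), sin(theta))
    d_ac <- sqrt(sum((A - C)^2))
    expect_equal(contained_angle(d_ab, d_bc, d_ac), theta * 180 / pi,
                 tolerance = 1e-9)
  }
})

test_that("covalent topology inference follows the radius-sum rule", {
  h2 <- geometry(c("H", "H"), matrix(c(0, 0, 0, 0.74, 0, 0), 2L,
                                     byrow = TRUE))
  topo <- infer_topology(h2, scale = 1.2)
  # oracle: bond iff distance <= scale * (r_H + r_H)
  expect_identical(nrow(topo$bonds),
                   as.integer(0.74 <= 1.2 * 2 * covalent_radius("H")))
  expect_identical(topo$degree, c(1L, 1L))

  far <- geometry(c("C", "C"), matrix(c(0, 0, 0, 10, 0, 0), 2L,
                                      byrow = TRUE))
  expect_identical(nrow(infer_topology(far)$bonds), 0L)

  w <- water_geometry()
  tw <- infer_topology(w)
  expect_identical(nrow(tw$bonds), 2L)        # two O-H, no H-H
  expect_identical(tw$degree, c(2L, 1L, 1L))

  # invariance under global rotation + translation
  set.seed(3)
  ang <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3L)
  w2 <- set_coords(w, sweep(w$xyz %*% R, 2L, c(5, -2, 1), `+`))
  expect_identical(infer_topology(w2)$bonds, tw$bonds)
  expect_error(infer_topology(geometry("Xx", matrix(0, 1L, 3L),
                                       mass = 1)),
               "covalent-radius|unknown")
})

test_that("topology diff isolates the atoms changing partners", {
  # proton transfer A-H...B -> A...H-B on a chain C-A-H...B-D
  make <- function(h_x) {
    geometry(c("C", "O", "H", "N", "C"),
             matrix(c(-1.5, 0, 0,
                      0, 0, 0,
                      h_x, 0, 0,
                      2.6, 0, 0,
                      4.1, 0, 0), 5L, byrow = TRUE))
  }
  ta <- infer_topology(make(1.0))   # H bonded to O (atom 2)
  tg <- infer_topology(make(1.6))   # H bonded to N (atom 4)
  d <- diff_topology(ta, tg)
  expect_identical(d, c(2L, 3L, 4L))
  expect_gte(length(d), 2L); expect_lte(length(d), 4L)
  expect_identical(diff_topology(ta, ta), integer(0))
  expect_identical(diff_topology(ta, tg, include_neighbors = TRUE),
                   1:5)
  expect_error(diff_topology(ta, infer_topology(water_geometry())),
               "atom count")
})

test_that("neutralization mutations edit only the targeted site", {
  # serine-like O-H donor fragment: O promoted to F, H removed
  frag <- geometry(c("C", "O", "H", "C"),
                   matrix(c(-1.4, 0.1, 0,
                            0, 0, 0,
                            0.96, 0, 0,
                            2.5, 1.0, -0.3), 4L, byrow = TRUE))
  mut <- mutate_for_neutralization(
    frag, mutation_spec("delete-H-and-promote-donor", target = c(3L, 2L)))
  expect_identical(n_atoms(mut), 3L)
  expect_identical(mut$element, c("C", "F", "C"))
  expect_identical(mut$xyz[c(1L, 3L), ], frag$xyz[c(1L, 4L), ])
  expect_identical(attr(mut, "charge_delta"), 0)

  # N-H donor -> O
  nh <- geometry(c("N", "H"), matrix(c(0, 0, 0, 1.01, 0, 0), 2L,
                                     byrow = TRUE))
  mo <- mutate_for_neutralization(
    nh, mutation_spec("delete-H-and-promote-donor", target = c(2L, 1L)))
  expect_identical(mo$element, "O")

  # proton deletion: elements unchanged, formal charge decremented
  pd <- mutate_for_neutralization(nh, mutation_spec("proton-deletion",
                                                    target = 2L))
  expect_identical(pd$element, "N")
  expect_identical(attr(pd, "charge_delta"), -1L)

  # errors: H not bonded to named donor; no promotion defined
  farh <- geometry(c("O", "H"), matrix(c(0, 0, 0, 5, 0, 0), 2L,
                                       byrow = TRUE))
  expect_error(mutate_for_neutralization(
    farh, mutation_spec("delete-H-and-promote-donor", target = c(2L, 1L))),
    "not bonded")
  ca <- geometry(c("Ca", "H"), matrix(c(0, 0, 0, 1, 0, 0), 2L,
                                      byrow = TRUE))
  expect_error(mutate_for_neutralization(
    ca, mutation_spec("delete-H-and-promote-donor", target = c(2L, 1L))),
    "promotion")
})

test_that("geometry invariants are enforced", {
  expect_error(geometry(character(0), matrix(0, 0, 3)), "at least one")
  expect_error(geometry("C", matrix(0, 1, 3), mass = -1), "positive")
  expect_error(geometry(c("C", "C"), matrix(0, 1, 3)), "atoms")
})
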