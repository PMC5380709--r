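# Shared oracle objects, computed once per test run.

# grid+Newton stationary-point catalogue of the Mueller-Brown surface:
# the ground truth for every saddle-search and IRC check
MB_CAT <- mb_stationary_points()

mb_point <- function(label) {
  r <- MB_CAT[MB_CAT$label == label, ]
  mb_geometry(r$x, r$y)
}

mb_xy <- function(label) {
  r <- MB_CAT[MB_CAT$label == label, ]
  c(r$x, r$y)
}

mb_energy <- function(label) MB_CAT$energy[MB_CAT$label == label]

# desk-scale ascent schedule: r_stop scaled to ~1% of typical endpoint
# separations on the test surfaces (the 3.0 A default targets
# protein-sized systems)
mb_schedule <- function() {
  bias_schedule(c_initial = 2, growth = 1.5, r_stop = 0.01,
                max_steps = 100)
}

# small water-like geometry used by I/O and topology tests
water_geometry <- function() {
  geometry(c("O", "H", "H"),
           matrix(c(0, 0, 0,
                    0.9572, 0, 0,
                    -0.2399872, 0.9266272, 0), 3L, byrow = TRUE))
}
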