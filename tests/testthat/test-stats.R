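mk_trace <- function(time, v) tibble::tibble(time = time, v = v)

test_that("peak and area recover closed-form values", {
  tt <- seq(0, 500, by = 0.1)
  flat <- mk_trace(tt, rep(-70, length(tt)))
  out <- peak_and_area(flat, c(0, 50), c(100, 400))
  expect_equal(out$peak, 0)
  expect_equal(out$area, 0)

  # rectangular 10 mV x 100 ms pulse
  rect <- mk_trace(tt, -70 + 10 * (tt >= 100 & tt < 200))
  out <- peak_and_area(rect, c(0, 50), c(60, 500))
  expect_equal(out$peak, 10)
  expect_equal(out$area, 1000, tolerance = 1e-3)

  # exponential decay 10 * e^(-t/50): area -> 500 mV ms
  tt2 <- seq(0, 2000, by = 0.05)
  expdec <- mk_trace(tt2 + 100, c(10 * exp(-tt2 / 50)))
  expdec <- dplyr::bind_rows(mk_trace(seq(0, 99.95, 0.05), rep(0, 2000)), expdec)
  out <- peak_and_area(expdec, c(0, 99), c(100, 2100))
  expect_equal(out$peak, 10)
  expect_equal(out$area, 500, tolerance = 0.01)

  # shift invariance
  shifted <- mk_trace(expdec$time, expdec$v + 12.3)
  out2 <- peak_and_area(shifted, c(0, 99), c(100, 2100))
  expect_equal(out2$peak, out$peak, tolerance = 1e-9)
  expect_equal(out2$area, out$area, tolerance = 1e-9)

  expect_error(peak_and_area(flat, c(0, 50), c(40, 30)),
               class = "pir_argument_error")
  expect_error(peak_and_area(flat, c(100, 150), c(50, 80)),
               class = "pir_argument_error")
})

test_that("background subtraction is a pointwise difference on a shared time base", {
  tt <- seq(0, 10, 0.5)
  a <- mk_trace(tt, sin(tt))
  expect_true(all(background_subtract(a, a)$v == 0))
  b <- mk_trace(tt, cos(tt))
  expect_equal(background_subtract(a, b)$v, sin(tt) - cos(tt))
  expect_error(background_subtract(a, mk_trace(tt[-1], cos(tt[-1]))),
               class = "pir_argument_error")
})

test_that("pairing nonlinearity is 1 for exact sums and scales with the response", {
  tt <- seq(0, 300, 0.5)
  bg <- mk_trace(tt, rep(-60, length(tt)))
  bump <- function(amp, t0) mk_trace(tt, -60 + amp * exp(-(tt - t0)^2 / 200))
  s1 <- bump(4, 100)
  s2 <- bump(3, 140)
  lin <- mk_trace(tt, s1$v + s2$v + 60)
  expect_equal(pairing_nonlinearity(lin, s1, s2, bg, c(50, 300)), 1,
               tolerance = 1e-12)
  twice <- mk_trace(tt, -60 + 2 * (s1$v + 60) + 2 * (s2$v + 60))
  expect_equal(pairing_nonlinearity(twice, s1, s2, bg, c(50, 300)), 2,
               tolerance = 1e-12)
  # symmetry in the two singles
  expect_equal(pairing_nonlinearity(twice, s1, s2, bg, c(50, 300)),
               pairing_nonlinearity(twice, s2, s1, bg, c(50, 300)))
  # undefined when the expected-linear area is non-positive or near zero
  neg <- mk_trace(tt, -60 - 1 * exp(-(tt - 100)^2 / 200))
  expect_true(is.na(pairing_nonlinearity(lin, neg, neg, bg, c(50, 300))))
  expect_true(is.na(pairing_nonlinearity(lin, s1, s2, bg, c(50, 300),
                                         min_expected_auc = 1e9)))
})

test_that("threshold reduction is the stated percentage", {
  expect_equal(threshold_reduction(10, 10), 0)
  expect_equal(threshold_reduction(10, 5), 50)
  expect_equal(threshold_reduction(8, 10), -25)
  expect_error(threshold_reduction(0, 1), class = "pir_argument_error")
  expect_error(threshold_reduction(-2, 1), class = "pir_argument_error")
})

test_that("a passive simulation gives unit pairing nonlinearity (superposition oracle)", {
  cell <- default_cell()
  sys <- set_ohmic_nmda(cell$sys, TRUE)
  term <- terminal_sections(cell$m)
  mk <- function(sec, prefix) synapse_population(list(dendritic_location(sec, 0.5)),
                                                 "exc", scale = 0.5,
                                                 input_prefix = prefix)
  trains <- list(a_1 = c(60, 80, 100), b_1 = c(70, 90, 110))
  run1 <- function(syn, tr) {
    get_trace(run_simulation(set_synapses(sys, syn, tr), 300, dt = 0.05,
                             seed = 1, deterministic_release = TRUE), 1)
  }
  bgtrace <- run1(NULL, list())
  sa <- run1(mk(term[2], "a"), trains["a_1"])
  sb <- run1(mk(term[5], "b"), trains["b_1"])
  sab <- run1(dplyr::bind_rows(mk(term[2], "a"), mk(term[5], "b")), trains)
  ratio <- pairing_nonlinearity(sab, sa, sb, bgtrace, c(50, 300))
  expect_equal(ratio, 1, tolerance = 0.02)
})
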