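test_that("threshold detection separates sigmoidal from linear curves", {
  mk_curve <- function(y) {
    structure(list(summary = tibble::tibble(intensity = seq_along(y) - 1,
                                            peak_soma_mean = y)),
              class = "pir_io_curve")
  }
  # linear curve: no spike detected
  lin <- detect_threshold(mk_curve(0.5 * (0:10)))
  expect_false(lin$detected)
  expect_true(is.na(lin$threshold_intensity))
  # flat curve: no spike
  expect_false(detect_threshold(mk_curve(rep(2, 8)))$detected)
  # ideal step at intensity 5: inflection of the symmetric logistic
  stepy <- c(rep(1, 5), rep(30, 6))
  st <- detect_threshold(mk_curve(stepy))
  expect_true(st$detected)
  expect_equal(st$threshold_intensity, 4.5, tolerance = 0.6)
  # noisy sigmoid: detected with a sensible midpoint and threshold voltage
  y <- c(0, 2.3, 1.8, 5.3, 24, 33.6, 24.1, 37.6, 38.5, 36.9, 37.4)
  sg <- detect_threshold(mk_curve(y))
  expect_true(sg$detected)
  expect_equal(sg$threshold_intensity, 3.9, tolerance = 0.7)
  expect_equal(sg$threshold_voltage,
               y[max(which((0:10) < sg$threshold_intensity))])
})

test_that("input-output curves are flat at zero intensity and argument-checked", {
  cell <- default_cell()
  st <- select_pairing_sites(cell$g, "same", "LOT")
  site <- stimulus_site(st$driver, scale = 0)
  crv <- io_curve(cell$sys, site, intensities = 0:3, trials = 1, seed = 1,
                  dt = 0.05, response_ms = 100)
  expect_true(all(abs(crv$summary$peak_soma_mean) < 1e-6))
  expect_error(io_curve(cell$sys, site, intensities = 0:2),
               class = "pir_argument_error")
  expect_error(io_curve(cell$sys, site, intensities = c(3, 1, 0, 2)),
               class = "pir_argument_error")
})

test_that("a distal site shows an all-or-none jump that Ohmic NMDA removes", {
  cell <- default_cell()
  st <- select_pairing_sites(cell$g, "same", "LOT")
  site <- stimulus_site(st$driver, scale = 1)
  crv <- io_curve(cell$sys, site, intensities = seq(0, 16, 2), trials = 1,
                  seed = 1, dt = 0.05, deterministic_release = TRUE)
  th <- detect_threshold(crv)
  expect_true(th$detected)
  expect_gt(th$threshold_intensity, 1)
  # threshold voltage in the experimentally plausible range
  expect_gt(th$threshold_voltage, 4)
  expect_lt(th$threshold_voltage, 22)
  # local dendritic response jumps by > 20 mV across threshold
  expect_gt(max(diff(crv$summary$peak_dend_mean)), 20)

  ohmic <- io_curve(set_ohmic_nmda(cell$sys, TRUE), site,
                    intensities = seq(0, 16, 2), trials = 1, seed = 1,
                    dt = 0.05, deterministic_release = TRUE)
  # no comparable jump without NMDA regenerativity
  expect_lt(max(diff(ohmic$summary$peak_dend_mean)),
            max(diff(crv$summary$peak_dend_mean)) / 2)
  expect_true(all(ohmic$summary$peak_soma_mean <= crv$summary$peak_soma_mean + 1e-6))
})

test_that("calibration reaches the target EPSC and errors on bad bounds", {
  cell <- default_cell()
  cc <- cell$g$comps
  i <- which.min(abs(cc$path_dist - 280))
  site <- dendritic_location(cc$section[i], (cc$arc0[i] + cc$arc1[i]) / 2)
  cal <- calibrate_unitary_input(cell$sys, site, trials = 30, seed = 2)
  expect_lt(abs(cal$mean_epsc - 30) / 30, 0.1)
  expect_gt(cal$mean_epsp, 0.3)
  expect_lt(cal$mean_epsp, 2.3)
  expect_error(
    calibrate_unitary_input(cell$sys, site, scale_bounds = c(0, 0)),
    class = "pir_calibration_error")
  # a perisomatic site is rejected
  expect_error(
    calibrate_unitary_input(cell$sys, dendritic_location(2, 0.05)),
    class = "pir_protocol_error")
})

test_that("pairing with a null bias leaves the threshold unchanged", {
  cell <- default_cell()
  st <- select_pairing_sites(cell$g, "same", "LOT")
  pr <- pairing_experiment(cell$sys, stimulus_site(st$driver, scale = 1),
                           stimulus_site(st$bias, n_synapses = 0, scale = 1),
                           intensities = seq(0, 14, 2), trials = 1, seed = 1,
                           dt = 0.05, response_ms = 250,
                           deterministic_release = TRUE)
  expect_equal(pr$reduction_pct, 0, tolerance = 1e-6)
  expect_equal(pr$bias_epsp, 0)
})

test_that("a suprathreshold bias is rejected", {
  cell <- default_cell()
  st <- select_pairing_sites(cell$g, "same", "LOT")
  expect_error(
    pairing_experiment(cell$sys, stimulus_site(st$driver, scale = 1),
                       stimulus_site(st$bias, n_synapses = 30, scale = 3),
                       intensities = 0:4, trials = 1, seed = 1, dt = 0.05,
                       response_ms = 150),
    class = "pir_protocol_error")
})

test_that("pairing site selection honours branch relations", {
  g <- default_cell()$g
  m <- default_cell()$m
  for (pw in c("LOT", "IC")) {
    for (rel in c("same", "sister", "different")) {
      st <- select_pairing_sites(g, rel, pw)
      expect_equal(branch_relation(m, st$driver, st$bias), rel)
      if (pw == "IC") {
        expect_equal(classify_zone(g, st$bias), "IC")
      }
    }
  }
  # driver is distal LOT
  st <- select_pairing_sites(g, "same", "LOT")
  expect_equal(classify_zone(g, st$driver), "LOT")
  expect_gte(path_distance(g, st$driver), 300)
})

test_that("ohmic NMDA freezes the gating factor", {
  sys <- set_ohmic_nmda(default_cell()$sys, TRUE)
  expect_true(sys$ohmic_nmda)
  expect_equal(nmda_gating(sys$ohmic_vm), 0.014577, tolerance = 1e-4)
  sys2 <- set_ohmic_nmda(sys, FALSE)
  expect_false(sys2$ohmic_nmda)
})

test_that("glomerular combination validates labels and honours placements", {
  cell <- default_cell()
  expect_error(
    glomerular_combination(cell$sys, pairs = list(c("A", "Z")), trials = 1),
    class = "pir_lookup_error")
  gl <- glomerular_combination(cell$sys, trials = 2, seed = 4, dt = 0.05,
                               duration = 300, keep_traces = TRUE)
  expect_named(gl$traces, c("bg", "A", "B", "C", "AB", "AC"))
  secs <- setNames(vapply(gl$gloms, function(x) as.numeric(x$section), numeric(1)),
                   vapply(gl$gloms, `[[`, character(1), "label"))
  m <- cell$m
  expect_equal(secs[["A"]], secs[["B"]])
  expect_equal(branch_relation(m, dendritic_location(secs[["A"]], 0.5),
                               dendritic_location(secs[["C"]], 0.5)),
               "different")
  expect_equal(nrow(gl$trials), 2)
})

test_that("clustered placement errors when the branch capacity is exceeded", {
  cell <- default_cell()
  expect_error(
    clustered_vs_dispersed(cell$sys, n_signal_exc = 500, trials = 1,
                           clustering_fraction = 1, seed = 1, dt = 0.05,
                           duration = 150),
    class = "pir_placement_error")
})

test_that("tidiers and plots expose the protocol results", {
  cell <- default_cell()
  st <- select_pairing_sites(cell$g, "same", "LOT")
  site <- stimulus_site(st$driver, scale = 1)
  crv <- io_curve(cell$sys, site, intensities = seq(0, 12, 3), trials = 1,
                  seed = 1, dt = 0.05, response_ms = 150,
                  deterministic_release = TRUE)
  expect_s3_class(tidy(crv), "tbl_df")
  expect_true("threshold_intensity" %in% names(glance(crv)))
  expect_s3_class(autoplot(crv), "ggplot")
})
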