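test_that("kinetic waveforms match their closed forms", {
  loc <- dendritic_location(2, 0.5)
  ampa <- synapse_spec("ampa", loc)
  # single exponential: g(1.5 ms) = g_unit * e^-1
  expect_equal(conductance_step(ampa, 1, 1.5), 1 * exp(-1), tolerance = 1e-12)
  expect_equal(conductance_step(ampa, 1, numeric(0)), 0)
  expect_equal(conductance_step(ampa, 0.4, 0), 0.4)

  # dual exponential peaks where the closed form says it should
  nmda <- synapse_spec("nmda", loc)
  tpk <- optimize(function(t) exp(-t / 80) - exp(-t / 2),
                  c(0, 50), maximum = TRUE)$maximum
  expect_equal(tpk, 7.57, tolerance = 0.01)
  g <- sapply(seq(0, 30, 0.01), function(t) conductance_step(nmda, 1, t, Vm = 0))
  expect_equal(seq(0, 30, 0.01)[which.max(g)], tpk, tolerance = 0.02)
  # normalised peak equals g_unit * fraction (times the gating factor)
  expect_equal(max(g), 2 * nmda_gating(0), tolerance = 1e-3)

  # superposition: two releases sum linearly
  g2 <- conductance_step(ampa, c(0.5, 0.5), c(3, 1))
  expect_equal(g2, conductance_step(ampa, 0.5, 3) + conductance_step(ampa, 0.5, 1),
               tolerance = 1e-12)

  expect_error(synapse_spec("ampa", loc, tau_rise = 2, tau_decay = 1),
               class = "pir_constraint_error")
})

test_that("vesicular release matches the binomial oracle", {
  st <- release_state()
  set.seed(1)
  rel <- replicate(10000, sample_release(st)$released)
  expect_equal(mean(rel), 5 * 0.1, tolerance = 0.03)       # binomial mean 0.5
  expect_equal(mean(rel >= 1), 1 - 0.9^5, tolerance = 0.02) # 0.4095
  # chi-square goodness of fit against Binomial(5, 0.1)
  obs <- tabulate(rel + 1, nbins = 6)
  p <- dbinom(0:5, 5, 0.1)
  keep <- p * 10000 >= 5
  chi <- sum((obs[keep] - 10000 * p[keep])^2 / (10000 * p[keep]))
  expect_lt(chi, qchisq(0.999, sum(keep) - 1))

  expect_equal(sample_release(release_state(Pr = 0))$released, 0)
  out <- sample_release(release_state(Pr = 1))
  expect_equal(out$released, 5)
  expect_equal(out$state$available, 0)
})

test_that("pool replenishment is memoryless per slot", {
  full <- release_state()
  expect_equal(replenish(full, 10)$available, 5)
  none <- release_state(available = 4, replenish_rate = 0)
  expect_equal(replenish(none, 1000)$available, 4)
  # one empty slot, 100 s^-1, 10 ms -> refill probability 1 - e^-1
  set.seed(2)
  refills <- replicate(10000, replenish(release_state(available = 4), 10)$available == 5)
  expect_equal(mean(refills), 1 - exp(-1), tolerance = 0.02)
})

test_that("with Pr = 1 and instant replenishment every spike empties a full pool", {
  st <- release_state(Pr = 1, replenish_rate = 1e7)
  out <- simulate_release_train(seq(10, 100, by = 10), st)
  expect_true(all(out$released == 5))
  expect_true(all(out$frac == 1))
})

test_that("presynaptic train generation matches the stated distributions", {
  expect_length(generate_train(count_mean = 0, count_sd = 0, seed = 1), 0)
  t1 <- generate_train(seed = 42)
  expect_identical(t1, generate_train(seed = 42))
  expect_true(all(diff(t1) > 0))

  set.seed(3)
  trains <- lapply(1:4000, function(i) generate_train())
  counts <- lengths(trains)
  starts <- sapply(trains[counts > 0], `[`, 1)
  isis <- unlist(lapply(trains[counts > 1], diff))
  expect_equal(mean(starts), 100, tolerance = 1)
  expect_equal(mean(counts), 5, tolerance = 0.2)
  # truncation at 0.1 ms biases the mean ISI slightly above 8
  expect_gt(mean(isis), 8)
  expect_lt(mean(isis), 9.6)
  expect_true(all(isis >= 0.1 - 1e-9))
})

test_that("background population has the stated size, rate and placement", {
  g <- default_cell()$g
  bg <- generate_background(g, duration = 1000, seed = 5)
  expect_equal(length(bg$trains), 120)
  expect_equal(sum(bg$synapses$kind == "ampa"), 100)  # AMPA-only excitation
  expect_equal(sum(bg$synapses$kind == "nmda"), 0)
  expect_equal(sum(bg$synapses$kind == "gabaa"), 20)
  # dendritic placement only
  expect_true(all(bg$synapses$section != 1))

  set.seed(6)
  counts <- unlist(lapply(1:50, function(i) {
    lengths(generate_background(g, duration = 1000, seed = 1000 + i)$trains)
  }))
  expect_equal(mean(counts), 10, tolerance = 0.5)  # 10 Hz over 1 s

  none <- generate_background(g, rate = 0, duration = 1000, seed = 7)
  expect_true(all(lengths(none$trains) == 0))

  # unique between seeds
  bg2 <- generate_background(g, duration = 1000, seed = 6)
  expect_false(identical(bg$trains, bg2$trains))
})

test_that("trains export as a two-column table", {
  tbl <- trains_to_table(list(a = c(1, 2), b = numeric(0), c = 5))
  expect_equal(nrow(tbl), 3)
  expect_named(tbl, c("input_id", "time"))
})
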