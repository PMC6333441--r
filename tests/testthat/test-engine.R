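test_that("a passive system with no input stays at rest", {
  sim <- run_simulation(default_cell()$sys, 200, dt = 0.05)
  expect_lt(max(abs(get_trace(sim, 1)$v + 70)), 1e-6)
})

test_that("isolated soma follows the analytic RC step response", {
  m <- default_cell()$m
  m$sections <- m$sections[m$sections$is_soma, , drop = FALSE]
  g <- discretize(m)
  sys <- compartmental_system(g)
  inj <- tibble::tibble(site = 1, start = 10, stop = 400, amp = 0.05) # nA
  sim <- run_simulation(sys, 400, dt = 0.025, inject = inj)
  tr <- get_trace(sim, 1)
  rin <- 25000 / (829 * 1e-8) * 1e-9   # Rm / A_soma, GOhm
  dv_inf <- tail(tr$v, 1) + 70
  expect_equal(dv_inf, 0.05 * rin * 1000, tolerance = 0.01)
  # tau = 25 ms: check the analytic curve pointwise over the rise
  sel <- tr$time > 10 & tr$time < 150
  analytic <- dv_inf * (1 - exp(-(tr$time[sel] - 10) / 25))
  expect_lt(max(abs(tr$v[sel] + 70 - analytic)) / dv_inf, 0.01)
})

test_that("steady-state attenuation along a finite cable matches the cosh form", {
  soma_ld <- c(1, 2) # tiny end-disc soma so the cable is effectively sealed
  sec <- tibble::tibble(
    section = c(1L, 2L), parent = c(NA_integer_, 1L),
    length = c(1, 500), diam_prox = c(2, 2), diam_dist = c(2, 2),
    branch_order = c(0L, 1L), root_id = c(0L, 1L), is_soma = c(TRUE, FALSE))
  m <- as_morphology(sec)
  g <- discretize(m, max_seg_len = 2)
  sys <- compartmental_system(g)
  tip <- resolve_comp(g, dendritic_location(2, 1))
  mid <- resolve_comp(g, dendritic_location(2, 0.5))
  inj <- tibble::tibble(site = tip, start = 0, stop = 600, amp = 0.01)
  sim <- run_simulation(sys, 600, dt = 0.05, inject = inj,
                        record = list(1L, mid, tip))
  v <- sim$v[nrow(sim$v), ] + 70
  lambda <- sqrt(25000 * 1e-4 / (2 * 100)) * 1e4 # um
  L <- 500 / lambda
  expect_equal(v[[1]] / v[[3]], 1 / cosh(L), tolerance = 0.01)
  expect_equal(v[[2]] / v[[3]], cosh(L / 2) / cosh(L), tolerance = 0.01)
})

test_that("halving the time step changes the standard response by < 0.5%", {
  cell <- default_cell()
  st <- select_pairing_sites(cell$g, "same", "LOT")
  syn <- synapse_population(list(st$driver), "exc", scale = 4, input_prefix = "s")
  trains <- list(s_1 = c(50, 70, 90))
  sys <- set_synapses(cell$sys, syn, trains)
  peak <- function(dt) {
    sim <- run_simulation(sys, 250, dt = dt, seed = 1,
                          deterministic_release = TRUE)
    max(get_trace(sim, 1)$v) + 70
  }
  p1 <- peak(0.025)
  p2 <- peak(0.0125)
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("voltage clamp holds the command and reports a null at reversal", {
  sys <- default_cell()$sys
  sim <- voltage_clamp(sys, "soma", hold = -70, duration = 100, dt = 0.05)
  expect_lt(max(abs(sim$i_clamp)), 1e-6)

  # AMPA input at the clamped compartment with the clamp at its reversal
  # contributes zero current: traces with and without the synapse agree
  syn <- synapse_population(list(dendritic_location(1, 0.5)), "exc",
                            nmda = FALSE, input_prefix = "at_soma")
  sys_syn <- set_synapses(sys, syn, list(at_soma_1 = c(20, 40)))
  with_syn <- run_simulation(sys_syn, 100, dt = 0.05, seed = 3,
                             clamp = list(site = "soma", hold = 0),
                             deterministic_release = TRUE)
  without <- run_simulation(sys, 100, dt = 0.05, seed = 3,
                            clamp = list(site = "soma", hold = 0))
  expect_equal(with_syn$i_clamp, without$i_clamp, tolerance = 1e-9)
})

test_that("the implicit step satisfies per-compartment charge balance", {
  m <- toy_morphology(parent = c(1, 2), length = c(60, 60), diam = c(2, 1))
  g <- discretize(m, max_seg_len = 15)
  sys <- compartmental_system(g)
  tipcomp <- resolve_comp(g, dendritic_location(3, 1))
  inj <- tibble::tibble(site = 1, start = 0, stop = 50, amp = 0.02)
  sim <- run_simulation(sys, 50, dt = 0.05, inject = inj, record = "all")
  v <- sim$v
  theta <- 0.5
  dt <- 0.05
  n <- sys$n
  # recompute the theta-rule residual at the sealed tip compartment
  ax <- function(row) {
    out <- numeric(n)
    for (i in 2:n) {
      p <- sys$parent[i] + 1
      out[i] <- out[i] + sys$g_ax[i] * (v[row, p] - v[row, i])
      out[p] <- out[p] - sys$g_ax[i] * (v[row, p] - v[row, i])
    }
    out
  }
  worst <- 0
  for (row in seq(2, 50)) {
    lhs <- sys$cap * (v[row, ] - v[row - 1, ]) / dt
    memb <- function(r) -sys$g_leak * (v[r, ] - sys$e_leak)
    rhs <- theta * (memb(row) + ax(row)) + (1 - theta) * (memb(row - 1) + ax(row - 1))
    rhs[1] <- rhs[1] + 0.02
    rel <- abs(lhs - rhs)[tipcomp] / max(abs(lhs), abs(rhs), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-9)
})

test_that("with frozen NMDA gating, responses superpose linearly", {
  cell <- default_cell()
  sys <- set_ohmic_nmda(cell$sys, TRUE)
  term <- terminal_sections(cell$m)
  locA <- dendritic_location(term[1], 0.5)
  locB <- dendritic_location(term[length(term)], 0.5)
  mk <- function(locs, prefix) synapse_population(locs, "exc", scale = 0.5,
                                                  input_prefix = prefix)
  run1 <- function(syn, trains) {
    sim <- run_simulation(set_synapses(sys, syn, trains), 300, dt = 0.05,
                          seed = 1, deterministic_release = TRUE)
    get_trace(sim, 1)$v + 70
  }
  va <- run1(mk(list(locA), "a"), list(a_1 = c(50, 70, 90)))
  vb <- run1(mk(list(locB), "b"), list(b_1 = c(60, 80, 100)))
  vab <- run1(dplyr::bind_rows(mk(list(locA), "a"), mk(list(locB), "b")),
              list(a_1 = c(50, 70, 90), b_1 = c(60, 80, 100)))
  expect_equal(max(vab), max(va + vb), tolerance = 0.02)
  expect_lt(max(abs(vab - (va + vb))) / max(vab), 0.02)
})

test_that("simulations are reproducible for a fixed seed", {
  cell <- default_cell()
  bg <- generate_background(cell$g, duration = 200, seed = 11)
  sys <- set_synapses(cell$sys, bg$synapses, bg$trains)
  s1 <- run_simulation(sys, 200, dt = 0.05, seed = 4)
  s2 <- run_simulation(sys, 200, dt = 0.05, seed = 4)
  expect_identical(s1$v, s2$v)
  s3 <- run_simulation(sys, 200, dt = 0.05, seed = 5)
  expect_false(identical(s1$v, s3$v))
})
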