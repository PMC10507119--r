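test_that("the double-exponential kernel is peak-normalised and causal", {
  tau_r <- 0.3; tau_d <- 1.8; gmax <- 0.73
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  expect_equal(conductance_double_exp(0, 0, tau_r, tau_d, gmax), 0)
  expect_equal(conductance_double_exp(tp, 0, tau_r, tau_d, gmax), gmax)
  expect_equal(conductance_double_exp(-1, 0, tau_r, tau_d, gmax), 0)
  expect_lt(conductance_double_exp(500, 0, tau_r, tau_d, gmax), 1e-12)

  t <- seq(0, 30, by = 0.01)
  g <- conductance_double_exp(t, 2, 8.019, 34.9884, 1.31)
  expect_true(all(g >= 0))
  expect_equal(max(g), 1.31, tolerance = 1e-4) # peak on the grid
  expect_true(all(g[t < 2] == 0))

  expect_error(conductance_double_exp(1, 0, 2, 1), "tau_rise < tau_decay")
})

test_that("the magnesium block has the Jahr-Stevens shape", {
  expect_equal(nmda_block(0), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_equal(nmda_block(0), 0.7812, tolerance = 1e-4)
  v <- seq(-90, 60, by = 1)
  expect_true(all(diff(nmda_block(v)) > 0)) # monotone increasing
  expect_equal(nmda_block(1e4), 1, tolerance = 1e-12)
  expect_lt(nmda_block(-1e3), 1e-10)
})

test_that("Poisson trains are seeded and have the right mean count", {
  expect_true(all(lengths(poisson_trains(5, rate = 0, t_stop = 50)) == 0))
  a <- poisson_trains(10, rate = 40, t_start = 10, t_stop = 110, seed = 3)
  b <- poisson_trains(10, rate = 40, t_start = 10, t_stop = 110, seed = 3)
  expect_identical(a, b)
  expect_true(all(vapply(a, function(x) all(x > 10 & x <= 110), TRUE)))

  # 400 trains at 1 Hz on [10, 50] ms: expected total 400 * 0.04 = 16
  totals <- vapply(1:40, function(s) {
    sum(lengths(poisson_trains(400, rate = 1, t_start = 10, t_stop = 50,
                               seed = s)))
  }, 1)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 16), 3 * se + 1e-9)
})

test_that("simulation without stimuli is flat and counts iterations exactly", {
  tr <- tree_chain(4, el = -65)
  sim <- simulate_tree(tr, t_stop = 10, dt = 0.025)
  expect_equal(sim$n_iterations, 400L)
  expect_lt(max(abs(sim$traces + 65)), 1e-12)
  expect_length(sim$spike_times, 0)
  expect_equal(glance(sim)$n_spikes, 0)
})

test_that("serial and DHS backends agree with spines and synapses active", {
  m <- small_spiny_model()
  a <- simulate_tree(m$tree, m$synapses, t_stop = 25, solver = "serial",
                     record = c(1, 5, 20))
  for (k in c(2, 8)) {
    b <- simulate_tree(m$tree, m$synapses, t_stop = 25, solver = "dhs",
                       k = k, record = c(1, 5, 20))
    expect_lt(max(abs(a$traces - b$traces)), 1e-9)
  }
})

test_that("halving dt changes the somatic EPSP peak by under 1 percent", {
  m <- small_spiny_model()
  p1 <- simulate_tree(m$tree, m$synapses, t_stop = 25, dt = 0.025)
  p2 <- simulate_tree(m$tree, m$synapses, t_stop = 25, dt = 0.0125)
  peak1 <- max(p1$traces[, 1]) - p1$traces[1, 1]
  peak2 <- max(p2$traces[, 1]) - p2$traces[1, 1]
  expect_lt(abs(peak1 - peak2) / abs(peak2), 0.01)
})

test_that("spike detection counts threshold crossings with a refractory gap", {
  times <- seq(0.1, 10, by = 0.1)
  v <- rep(-65, length(times))
  v[times > 2 & times < 2.4] <- 0   # one spike
  v[times > 2.6 & times < 2.9] <- 0 # within refractory: not counted
  v[times > 6 & times < 6.5] <- 0   # second spike
  sp <- dendrosched:::detect_spikes(times, v, threshold = -10,
                                    refractory = 2)
  expect_length(sp, 2)

  tr <- new_compartment_tree(NA_integer_, length = 10, diam = 10,
                             cm = 1, rm = 1e4, el = -65)
  syn <- syn_single_exp(1, times = list(c(5, 6)), g_max = 0.5, e_syn = 20)
  sim <- simulate_tree(tr, syn, t_stop = 20)
  expect_gte(length(sim$spike_times), 1)
})

test_that("tidy traces are long-format and plots build", {
  sim <- simulate_tree(tree_chain(3), t_stop = 1, record = 1:3)
  td <- tidy(sim)
  expect_equal(nrow(td), 40 * 3)
  expect_named(td, c("time", "node", "v"))
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(dhs_partition(example_tree(), 4)), "ggplot")
})
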