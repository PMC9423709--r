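tp <- thermal_params()
np <- neuron_params()
sp <- synapse_params()

test_that("network construction honours probabilities, seeds and no-self", {
  expect_equal(nrow(build_network(network_spec(50, 10, 0, 0))$edges), 0)

  spec <- network_spec(200, 50, seed = 11)
  net1 <- build_network(spec)
  net2 <- build_network(spec)
  expect_identical(net1$edges, net2$edges)          # determinism
  expect_false(identical(net1$edges,
                         build_network(network_spec(200, 50, seed = 12))$edges))
  expect_true(all(net1$edges$pre != net1$edges$post))
  expect_equal(as.character(net1$type[c(1, 200, 201, 250)]),
               c("E", "E", "I", "I"))
  expect_true(all(net1$positions >= 0 & net1$positions <= 1))

  # binomial expectation within 3 sigma for each source population
  n <- 250
  ne <- sum(net1$edges$exc); ni <- sum(!net1$edges$exc)
  mu_e <- 0.05 * 200 * (n - 1); sd_e <- sqrt(mu_e * 0.95)
  mu_i <- 0.20 * 50 * (n - 1); sd_i <- sqrt(mu_i * 0.80)
  expect_lt(abs(ne - mu_e), 3 * sd_e)
  expect_lt(abs(ni - mu_i), 3 * sd_i)
})

test_that("an empty network yields an empty result with metadata", {
  net <- build_network(network_spec(0, 0))
  sim <- run_network(net, duration = 0.1)
  expect_equal(nrow(sim$spikes), 0)
  expect_equal(sim$metadata$duration_s, 0.1)
  expect_true(all(sim$rate$rate_hz == 0) || nrow(sim$rate) == 0)
})

test_that("two-neuron toy network matches the straight-line reference
           integrator to < 0.1 ms", {
  spec <- network_spec(n_exc = 2, n_inh = 0, p_exc = 0, seed = 1)
  net <- build_network(spec)
  net$edges <- data.frame(pre = c(1L, 2L), post = c(2L, 1L),
                          exc = c(TRUE, TRUE))
  sim <- run_network(net, duration = 1, v_init_jitter = 0,
                     protocol = temperature_protocol("constant",
                                                     baseline = 6.3),
                     neuron = np, synapse = sp, thermal = tp)
  ref <- ref_sim_two_neuron(40000, 0.025, 6.3, np, tp, sp)
  for (i in 1:2) {
    got <- sim$spikes$time_s[sim$spikes$neuron == i] * 1000
    expect_equal(length(got), length(ref[[i]]))
    if (length(got)) expect_lt(max(abs(got - ref[[i]])), 0.1)
  }
})

test_that("halving dt shifts single-neuron spike times by < 0.5 ms", {
  p <- temperature_protocol("constant", baseline = 6.3)
  s1 <- simulate_neuron(2, p, np, tp, dt = 0.025)$spikes * 1000
  s2 <- simulate_neuron(2, p, np, tp, dt = 0.0125)$spikes * 1000
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 0.5)
})

test_that("a synapse-free network reproduces the isolated-neuron spikes", {
  net <- build_network(network_spec(3, 0, p_exc = 0))
  sim <- run_network(net, duration = 1.5, v_init_jitter = 0,
                     protocol = temperature_protocol("constant",
                                                     baseline = 6.3))
  iso <- simulate_neuron(1.5, temperature_protocol("constant", 6.3),
                         np, tp)
  for (i in 1:3)
    expect_equal(sim$spikes$time_s[sim$spikes$neuron == i], iso$spikes)
})

test_that("network runs are bit-identical under a fixed seed and
           bookkeeping is conserved", {
  net <- build_network(network_spec(20, 5, seed = 3))
  s1 <- run_network(net, duration = 1, seed = 9)
  s2 <- run_network(net, duration = 1, seed = 9)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$rate, s2$rate)
  expect_true(all(s1$spikes$time_s >= 0 & s1$spikes$time_s <= 1))
  # per-neuron times strictly increasing with gaps >= dead time
  gaps <- unlist(lapply(split(s1$spikes$time_s, s1$spikes$neuron), diff))
  if (length(gaps)) expect_true(all(gaps * 1000 >= np$dead_time))
  # total equals sum over neurons and equals the rate-series mass
  expect_equal(nrow(s1$spikes),
               sum(lengths(split(s1$spikes$time_s, s1$spikes$neuron))))
  expect_equal(sum(s1$rate$rate_hz * 0.05 * 25), nrow(s1$spikes))
})

test_that("subthreshold drive produces no release events and zero EPSC", {
  quiet <- neuron_params(I_ext = -1)
  run <- run_synapse_pair(dT = 0, duration = 1, neuron = quiet)
  expect_equal(nrow(run$events), 0)
  expect_true(all(run$epsc$epsc_pA == 0))
})

test_that("each EPSC onset coincides with a presynaptic spike", {
  run <- run_synapse_pair(dT = 0, duration = 2)
  expect_gt(nrow(run$events), 0)
  expect_equal(run$events$time_s, run$presyn_spikes)
  # EPSC is inward (negative) at the clamped resting potential after a spike
  first <- run$events$time_s[1]
  after <- run$epsc$epsc_pA[run$epsc$time_s > first &
                              run$epsc$time_s < first + 0.005]
  expect_true(all(after < 0))
  before <- run$epsc$epsc_pA[run$epsc$time_s < first]
  expect_true(all(before == 0))
})

test_that("synapse-pair release-event counts order with temperature as the
           presynaptic rhythm does", {
  counts <- vapply(c(0, 10, 30), function(dT) {
    nrow(run_synapse_pair(dT = dT, duration = 3)$events)
  }, 0)
  # facilitated at +10, suppressed at +30 relative to baseline
  expect_gt(counts[2], counts[1])
  expect_gt(counts[1], counts[3])
})

test_that("single-neuron dose-response runner returns a tidy table", {
  tab <- run_single_neuron(c(0, 10), window = 1.5, discard = 0.4)
  expect_equal(tab$dT, c(0, 10))
  expect_true(all(tab$n_spikes > 0))
  expect_equal(tab$rate_hz, tab$n_spikes / 1.5)
  sp0 <- attr(tab, "spikes")[[1]]
  expect_true(all(sp0 >= 0 & sp0 <= 1.5))
})

test_that("doubling the window approximately doubles tonic spike counts", {
  t1 <- run_single_neuron(0, window = 2, discard = 0.5)
  t2 <- run_single_neuron(0, window = 4, discard = 0.5)
  expect_lte(abs(t2$n_spikes - 2 * t1$n_spikes), 1)
})
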