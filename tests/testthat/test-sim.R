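test_that("membrane decays exponentially and the lockstep rate matches the transfer function", {
  p <- default_p()
  cfg <- sim_config()
  s <- neuron_state(V = 10)
  out <- lif_step(s, 0, p, cfg)
  expect_equal(out$state$V, 10 * exp(-1 / 64), tolerance = 1e-12)
  expect_identical(out$spiked, 0)
  # constant supra-threshold drive: spike count over 10 s agrees with the
  # closed form up to ISI quantization by the 1 ms grid
  s <- neuron_state()
  count <- 0
  for (t in 1:10000) {
    out <- lif_step(s, 7, p, cfg)
    s <- out$state
    count <- count + out$spiked
  }
  isi_q <- ceiling(isi_constant_input(7, p))      # grid rounds the ISI up
  expect_lte(abs(count - 10000 / isi_q), 1)
})

test_that("refractory period clamps the membrane and separates spikes", {
  p <- default_p()
  cfg <- sim_config()
  s <- neuron_state()
  spikes <- integer(200)
  vs <- numeric(200)
  for (t in 1:200) {
    out <- lif_step(s, 1e6, p, cfg)               # overwhelming drive
    s <- out$state
    spikes[t] <- out$spiked
    vs[t] <- s$V
  }
  tspk <- which(spikes == 1)
  expect_true(all(diff(tspk) >= p$t_r + cfg$dt))
  # V is held at 0 during the refractory window following each spike
  expect_true(all(vs[tspk[1] + 1] == 0, vs[tspk[1] + 2] == 0))
})

test_that("calcium estimator follows the add-then-decay scheme and tracks input rate", {
  cfg <- sim_config(tau_cal = 64)
  s <- neuron_state(C_cal = 3)
  out <- calcium_step(s, 0, cfg)
  expect_equal(out$state$C_cal, 3 * exp(-1 / 64), tolerance = 1e-12)
  out1 <- calcium_step(neuron_state(), 1, cfg)
  expect_equal(out1$y, exp(-1 / 64) / 64, tolerance = 1e-12)
  # long-run mean of the estimate converges to the underlying spike rate
  set.seed(11)
  spikes <- rbinom(40000, 1, 0.1)
  C <- 0
  ys <- numeric(40000)
  for (t in seq_along(spikes)) {
    C <- (C + spikes[t]) * exp(-1 / 64)
    ys[t] <- C / 64
  }
  expect_equal(mean(ys[5001:40000]), 0.1, tolerance = 0.05)
})

test_that("Poisson train generation is calibrated, seeded and guarded", {
  cfg <- sim_config(seed = 5)
  expect_error(poisson_spike_train(1.5, 1000, sim_config(dt = 1)), "exceeds 1")
  expect_length(poisson_spike_train(0, 1000, cfg), 0)
  a <- poisson_spike_train(0.16, 1000, cfg)
  b <- poisson_spike_train(0.16, 1000, cfg)
  expect_identical(a, b)                          # same seed, same train
  sigma <- sqrt(1000 * 0.16 * (1 - 0.16))
  for (seed in 1:5) {
    n <- length(poisson_spike_train(0.16, 1000, sim_config(seed = seed)))
    expect_lt(abs(n - 160), 4 * sigma)
  }
  ev <- poisson_spike_trains(rep(0.08, 30), 1000, sim_config(seed = 9))
  expect_true(all(ev$t_ms >= 0 & ev$t_ms < 1000))
  m <- spike_train_matrix(ev, 30, 1000)
  expect_equal(sum(m), nrow(ev))
})

test_that("synaptic kernels inject the documented currents and superpose", {
  cfg <- sim_config(kernel = "rect")
  x <- synaptic_current(c(5), 8, 20, cfg)
  expect_identical(x[6], 8)                       # t = 5 ms lands in bin 6
  expect_identical(sum(x != 0), 1L)
  # coincident opposite-weight spikes cancel
  both <- synaptic_current(5, 8, 20, cfg) + synaptic_current(5, -8, 20, cfg)
  expect_true(all(both == 0))
  # exponential kernel: discrete unit area, so mean current = w * rate
  cfge <- sim_config(kernel = "exp", tau_syn = 8, seed = 21)
  tr <- poisson_spike_train(0.1, 50000, cfge)
  xc <- synaptic_current(tr, 4, 50000, cfge)
  # exact up to the tail truncated at the window's end
  expect_equal(mean(xc), 4 * length(tr) / 50000, tolerance = 1e-3)
  expect_equal(mean(xc), 4 * 0.1, tolerance = 0.05)
})

test_that("network stepper reproduces the standalone neuron bit-for-bit", {
  p <- default_p()
  cfg <- sim_config(seed = 3)
  tr <- poisson_spike_train(0.16, 2000, cfg)
  input <- spike_train_matrix(data.frame(source_id = 1, t_ms = tr), 1, 2000)
  net <- build_dense_network(n = 1, n_inputs = 1, fanout = 1, input_w = 8,
                             params = p, seed = 1)
  net$Win[1, 1] <- 8                              # fix the wiring sign
  sim <- simulate_network(net, input, cfg, rule = "none")
  s <- neuron_state()
  for (t in seq_len(ncol(input))) {
    out <- lif_step(s, 8 * input[1, t], p, cfg)
    cal <- calcium_step(out$state, out$spiked, cfg)
    s <- cal$state
    expect_identical(sim$spikes[1, t], as.integer(out$spiked))
    expect_identical(sim$rates[1, t], cal$y)
  }
  # silence in, silence out
  net0 <- build_dense_network(n = 5, n_inputs = 1, fanout = 1, input_w = 0,
                              weight_dist = function(m) numeric(m), seed = 1)
  sim0 <- simulate_network(net0, matrix(0, 1, 100), cfg)
  expect_identical(sum(sim0$spikes), 0L)
})

test_that("identical configuration and seed give identical traces", {
  r1 <- run_network_experiment("spikl", n = 20, n_inputs = 5, fanout = 5,
                               passes = 2, seed = 77)
  r2 <- run_network_experiment("spikl", n = 20, n_inputs = 5, fanout = 5,
                               passes = 2, seed = 77)
  expect_identical(r1$sim$rates, r2$sim$rates)
  expect_identical(r1$sim$spikes, r2$sim$spikes)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trace(r1$sim, f1, neurons = 1:3)
  write_trace(r2$sim, f2, neurons = 1:3)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical output
  unlink(c(f1, f2))
})
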