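test_that("low-rate branch applies the constant recovery increments exactly", {
  p <- default_p()
  ip <- ip_config(eta1 = 5, eta2 = 5, alpha1 = 0.1, alpha2 = 0.1)
  up <- spikl_ip_step(0, p, ip)
  expect_identical(up$R - p$R, 0.5)
  expect_identical(up$tau_m - p$tau_m, -0.5)
  up2 <- spikl_ip_step(ip$delta, p, ip)           # y == delta is still low-rate
  expect_identical(up2$R - p$R, 0.5)
})

test_that("high-rate update equals the finite-difference gradient of the surrogate loss", {
  p <- default_p()
  ip <- default_ip()
  # oracle: numeric gradient of L(R, tau) = -log(dy/dx) + y/mu at the input
  # solving the transfer function for y = 0.2
  x_star <- uniroot(function(x) frtf_rate(x, p) - 0.2, c(0.5, 100),
                    tol = 1e-12)$root
  Lhat <- function(R, tau) {
    q <- neuron_params(R = R, tau_m = tau)
    y <- frtf_rate(x_star, q)
    -log(y^2 * tau * q$V_th / (x_star * (R * x_star - q$V_th))) + y / ip$mu
  }
  dR_oracle <- -ip$eta1 * fd_grad(function(R) Lhat(R, p$tau_m), p$R)
  dt_oracle <- -ip$eta2 * fd_grad(function(tau) Lhat(p$R, tau), p$tau_m)
  up <- spikl_ip_step(0.2, p, ip)
  expect_equal(up$R - p$R, dR_oracle, tolerance = 1e-3)
  expect_equal(up$tau_m - p$tau_m, dt_oracle, tolerance = 1e-3)
  expect_equal(up$R - p$R, -0.0339, tolerance = 1e-2)
  expect_equal(up$tau_m - p$tau_m, 0.03125, tolerance = 1e-4)
  # the instantaneous-input form agrees with the same oracle
  upb <- spikl_ip_step_basic(x_star, 0.2, p, ip)
  expect_equal(upb$R - p$R, dR_oracle, tolerance = 1e-3)
  expect_equal(upb$tau_m - p$tau_m, dt_oracle, tolerance = 1e-3)
})

test_that("input-free and instantaneous-input forms coincide when FR-TF-consistent", {
  ip <- default_ip()
  for (x in c(0.45, 1, 3, 7, 25)) {
    for (tau in c(8, 64, 256)) {
      p <- neuron_params(tau_m = tau)
      y <- frtf_rate(x, p)
      if (y <= ip$delta) next
      a <- spikl_ip_step(y, p, ip)
      b <- spikl_ip_step_basic(x, y, p, ip)
      expect_equal(a$R, b$R, tolerance = 1e-9)
      expect_equal(a$tau_m, b$tau_m, tolerance = 1e-9)
    }
  }
  expect_error(spikl_ip_step_basic(0.1, 0.2, neuron_params(), ip),
               "firing domain")
})

test_that("updates saturate at the configured tuning bounds", {
  ip <- ip_config(eta1 = 5, eta2 = 5, alpha1 = 10, alpha2 = 10)
  p <- neuron_params(R = 60, tau_m = 60, bounds_R = c(50, 62),
                     bounds_tau = c(55, 1024))
  up <- spikl_ip_step(0, p, ip)                   # +50 Ohm requested
  expect_identical(up$R, 62)
  expect_identical(up$tau_m, 55)
  # random update sequences never leave the bounds
  set.seed(42)
  q <- neuron_params(bounds_R = c(30, 100), bounds_tau = c(30, 100),
                     R = 64, tau_m = 64)
  for (i in 1:200) {
    q <- spikl_ip_step(runif(1, 0, 0.45), q, default_ip())
    expect_true(q$R >= 30 && q$R <= 100)
    expect_true(q$tau_m >= 30 && q$tau_m <= 100)
  }
})

test_that("a small basic step never increases the surrogate loss", {
  set.seed(7)
  ip_small <- ip_config(eta1 = 1e-3, eta2 = 1e-3)
  for (i in 1:50) {
    R <- runif(1, 20, 300)
    tau <- runif(1, 10, 300)
    x <- runif(1, 1, 12)
    p <- neuron_params(R = R, tau_m = tau)
    if (R * x <= p$V_th * 1.05) next
    y <- frtf_rate(x, p)
    L0 <- surrogate_loss(x, y, p, ip_small)$L_hat
    p1 <- spikl_ip_step_basic(x, y, p, ip_small)
    y1 <- frtf_rate(x, p1)
    L1 <- surrogate_loss(x, y1, p1, ip_small)$L_hat
    expect_lte(L1, L0 + 1e-10)
  }
})

test_that("surrogate loss is finite on the firing domain and reports the FR-TF slope", {
  p <- default_p()
  for (x in c(0.35, 1, 7, 100)) {
    y <- frtf_rate(x, p)
    out <- surrogate_loss(x, y, p, default_ip())
    expect_true(is.finite(out$L_hat))
    expect_equal(out$dy_dx, frtf_gradients(x, p)$dy_dx, tolerance = 1e-12)
  }
  expect_error(surrogate_loss(0.1, 0, p, default_ip()), "firing domain")
})

test_that("voltage-threshold rule arithmetic and long-run spike fraction", {
  vt <- vtip_config(eta = 0.01, k = 1, N = 10)
  expect_equal(voltage_threshold_ip_step(20, 1, vt) - 20, 0.009)
  expect_equal(voltage_threshold_ip_step(20, 0, vt) - 20, -0.001)
  # under constant drive the adapted neuron settles near k/N spikes per step
  vt2 <- vtip_config(eta = 0.1, k = 1, N = 5)
  p <- default_p()
  V <- 0; refr <- 0; V_th <- p$V_th
  n <- 50000
  spk <- integer(n)
  for (t in seq_len(n)) {
    s <- 0
    if (refr > 0) { V <- 0; refr <- refr - 1 }
    else {
      V <- p$R * 7 + (V - p$R * 7) * exp(-1 / p$tau_m)
      if (V >= V_th) { s <- 1; V <- 0; refr <- p$t_r }
    }
    V_th <- voltage_threshold_ip_step(V_th, s, vt2)
    spk[t] <- s
  }
  expect_equal(mean(spk[10001:n]), 1 / 5, tolerance = 0.05)
})
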