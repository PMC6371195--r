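test_that("closed-form interspike interval matches fine-step integration", {
  p <- default_p()
  expect_equal(isi_constant_input(7, p), oracle_isi(7, 64, 64),
               tolerance = 1e-3)
  expect_equal(isi_constant_input(7, p), 4.9229, tolerance = 1e-4)
  # a second parameter point, checked against the same independent oracle
  p2 <- neuron_params(R = 32, tau_m = 16)
  expect_equal(isi_constant_input(4, p2), oracle_isi(4, 32, 16),
               tolerance = 1e-3)
  # the log term vanishes for overwhelming drive
  expect_equal(isi_constant_input(1e12, p), p$t_r, tolerance = 1e-9)
  # boundary of the firing domain is a domain error
  expect_error(isi_constant_input(p$V_th / p$R, p), "never fires")
  expect_error(isi_constant_input(0.1, p), "never fires")
})

test_that("transfer function is reciprocal ISI, zero sub-threshold, bounded by 1/t_r", {
  p <- default_p()
  expect_equal(frtf_rate(7, p), 0.20313, tolerance = 1e-4)
  expect_identical(frtf_rate(0.3, p), 0)          # R*x = 19.2 < 20
  expect_identical(frtf_rate(c(-1, 0), p), c(0, 0))
  expect_equal(frtf_rate(1e12, p), 1 / p$t_r, tolerance = 1e-9)
  x <- seq(0.1, 50, length.out = 400)
  y <- frtf_rate(x, p)
  expect_true(all(diff(y) >= 0))                  # non-decreasing in x
  expect_true(all(y >= 0 & y < 1 / p$t_r))
  yfire <- y[p$R * x > p$V_th]
  expect_true(all(diff(yfire) > 0))               # strictly increasing when firing
  # strictly increasing in R on the firing domain
  Rs <- seq(10, 500, length.out = 100)
  yR <- vapply(Rs, function(R) frtf_rate(7, neuron_params(R = R)), 0)
  expect_true(all(diff(yR) > 0))
})

test_that("analytic gradients match central finite differences", {
  p0 <- default_p()
  grid <- expand.grid(x = c(2, 5, 7, 12), R = c(24, 64, 180),
                      tau = c(8, 64, 300))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; R <- grid$R[i]; tau <- grid$tau[i]
    if (R * x <= p0$V_th * 1.05) next
    g <- frtf_gradients(x, neuron_params(R = R, tau_m = tau))
    fx <- fd_grad(function(v) frtf_rate(v, neuron_params(R = R, tau_m = tau)), x)
    fR <- fd_grad(function(v) frtf_rate(x, neuron_params(R = v, tau_m = tau)), R)
    ft <- fd_grad(function(v) frtf_rate(x, neuron_params(R = R, tau_m = v)), tau)
    expect_equal(g$dy_dx, fx, tolerance = 1e-4)
    expect_equal(g$dy_dR, fR, tolerance = 1e-4)
    expect_equal(g$dy_dtau, ft, tolerance = 1e-4)
    # structural symmetry and the sign of the tau_m sensitivity
    expect_equal(x * g$dy_dx, R * g$dy_dR, tolerance = 1e-12)
    expect_lt(g$dy_dtau, 0)
  }
  expect_error(frtf_gradients(0.1, p0), "firing domain")
})

test_that("rate inversion recovers the supra-threshold drive", {
  p <- default_p()
  # oracle: solve the transfer function for the input, then form R*x - V_th
  x_star <- uniroot(function(x) frtf_rate(x, p) - 0.2, c(0.5, 100),
                    tol = 1e-12)$root
  expect_equal(w_from_rate(0.2, p), p$R * x_star - p$V_th, tolerance = 1e-8)
  expect_equal(w_from_rate(0.2, p), 416.745, tolerance = 1e-4)
  # algebraic round trip on the whole firing domain
  for (x in c(0.4, 1, 7, 40)) {
    y <- frtf_rate(x, p)
    expect_equal(w_from_rate(y, p), p$R * x - p$V_th, tolerance = 1e-9)
  }
  expect_lt(w_from_rate(1e-6, p), 1e-10)          # W -> 0+ as y -> 0+
  expect_error(w_from_rate(0, p), "clamp")
  expect_error(w_from_rate(0.5, p), "clamp")      # 1/t_r is out of range
  expect_gt(w_from_rate(0.7, p, clamp = TRUE), 0) # clamped estimator overshoot
})

test_that("tuning-curve table is a total function over the sweep grid", {
  cur <- frtf_curve(x = seq(0, 10, 0.5), R = c(32, 64), tau_m = c(16, 64))
  expect_named(cur, c("x_mA", "R_ohm", "tau_m_ms", "y_khz"))
  expect_equal(nrow(cur), 21 * 2 * 2)
  expect_true(all(cur$y_khz >= 0 & cur$y_khz < 0.5))
  expect_false(anyNA(cur$y_khz))
})
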