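# Independent oracles used across tests. These deliberately avoid the
# package's own closed forms: membrane integration is forward Euler at a fine
# step, gradients are central finite differences.

# Time to first threshold crossing from reset, plus the refractory period,
# under constant current. Scalar, Euler integration.
oracle_isi <- function(x0, R, tau_m, V_th = 20, t_r = 2, dt = 0.001) {
  V <- 0
  t <- 0
  drive <- R * x0
  repeat {
    V <- V + dt * (-V + drive) / tau_m
    t <- t + dt
    if (V >= V_th) return(t_r + t)
    if (t > 1e5) stop("oracle_isi: no crossing")
  }
}

# Steady firing rate from a fine-step Euler simulation, vectorized over
# parameter combinations. Rate measured as (spikes - 1) / (t_last - t_first)
# to remove boundary truncation.
oracle_rate <- function(x0, R, tau_m, V_th = 20, t_r = 2,
                        dt = 0.01, duration = 2000) {
  m <- length(x0)
  V <- numeric(m)
  refr <- numeric(m)
  nspk <- integer(m)
  tfirst <- rep(NA_real_, m)
  tlast <- rep(NA_real_, m)
  drive <- R * x0
  n_steps <- round(duration / dt)
  for (k in seq_len(n_steps)) {
    act <- refr <= 0
    V <- ifelse(act, V + dt * (-V + drive) / tau_m, 0)
    refr <- ifelse(act, refr, refr - dt)
    spk <- act & V >= V_th
    if (any(spk)) {
      t_now <- k * dt
      V[spk] <- 0
      refr[spk] <- t_r
      nspk[spk] <- nspk[spk] + 1L
      tfirst[spk & is.na(tfirst)] <- t_now
      tlast[spk] <- t_now
    }
  }
  if (any(nspk < 2)) stop("oracle_rate: fewer than 2 spikes for some combination")
  (nspk - 1) / (tlast - tfirst)
}

# Central finite difference of a scalar function.
fd_grad <- function(f, x, h = 1e-6 * max(1, abs(x))) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# KL to the exponential fitted to the sample itself; Inf for a silent sample.
kl_fit <- function(y) {
  m <- mean(y)
  if (m <= 0) return(Inf)
  kl_to_exponential(y, m)
}

default_p <- function() neuron_params()
default_ip <- function() ip_config()
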