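#' Initial dynamic state of a LIF neuron
#'
#' @param V membrane potential (mV).
#' @param refr_left remaining refractory time (ms).
#' @param C_cal calcium trace (unitless accumulation).
#' @return A list with components \code{V}, \code{refr_left}, \code{C_cal}.
#' @export
neuron_state <- function(V = 0, refr_left = 0, C_cal = 0) {
  list(V = V, refr_left = refr_left, C_cal = C_cal)
}

#' One lockstep update of the LIF membrane
#'
#' Advances the membrane potential by one step of width \code{cfg$dt} under
#' the input current \code{x_t}, emits a spike when the potential crosses
#' \code{V_th}, and handles reset and refractoriness. During the refractory
#' period the potential is held at the 0 mV resting level. Two integration
#' schemes are available: the exact per-step solution for piecewise-constant
#' input, \code{V <- R*x + (V - R*x) * exp(-dt/tau_m)} (default, robust for
#' any \code{tau_m >= bounds} even at \code{dt} comparable to \code{tau_m}),
#' and forward Euler for comparison. The membrane may go negative under
#' inhibitory drive; there is no floor, and reset happens only on spikes.
#'
#' @param s state list as from \code{\link{neuron_state}}.
#' @param x_t input current during this step (mA).
#' @param p a \code{\link{neuron_params}} object.
#' @param cfg a \code{\link{sim_config}} object.
#' @return A list \code{(state, spiked)} where \code{spiked} is 0/1.
#' @export
lif_step <- function(s, x_t, p, cfg = sim_config()) {
  spiked <- 0
  if (s$refr_left > 0) {
    s$V <- 0
    s$refr_left <- s$refr_left - cfg$dt
  } else {
    drive <- p$R * x_t
    s$V <- if (cfg$integration == "exponential") {
      drive + (s$V - drive) * exp(-cfg$dt / p$tau_m)
    } else {
      s$V + cfg$dt * (-s$V + drive) / p$tau_m
    }
    if (s$V >= p$V_th) {
      spiked <- 1
      s$V <- 0
      s$refr_left <- p$t_r
    }
  }
  list(state = s, spiked = spiked)
}

#' Calcium-trace firing-rate estimator, one step
#'
#' The calcium concentration increases by one unit per output spike and
#' decays with time constant \code{tau_cal}; the firing-rate estimate is the
#' normalized concentration \code{y = C_cal / tau_cal}. The discrete scheme
#' adds the spike increment and then applies the decay within the same step:
#' \code{C <- (C + spiked) * exp(-dt/tau_cal)}. Under 1 ms lockstep this
#' keeps the estimate strictly below 1 KHz even when a spike is emitted at
#' every step (supremum \code{e^{-1/tau} / (1 - e^{-1/tau}) / tau} < 1).
#'
#' @param s state list as from \code{\link{neuron_state}}.
#' @param spiked 0/1 spike indicator for this step.
#' @param cfg a \code{\link{sim_config}} object.
#' @return A list \code{(state, y)} with the rate estimate \code{y} in KHz.
#' @export
calcium_step <- function(s, spiked, cfg = sim_config()) {
  s$C_cal <- (s$C_cal + spiked) * exp(-cfg$dt / cfg$tau_cal)
  list(state = s, y = s$C_cal / cfg$tau_cal)
}

#' Poisson spike train on the lockstep grid
#'
#' Bernoulli thinning of the time grid: each bin of width \code{dt} contains
#' a spike with probability \code{rate * dt} (requires \code{rate * dt <= 1}).
#' Reproducible under a fixed seed.
#'
#' @param rate mean firing rate (KHz).
#' @param duration train duration (ms).
#' @param cfg a \code{\link{sim_config}} object; \code{cfg$seed}, when set,
#'   seeds the draw.
#' @return Numeric vector of spike times (ms), multiples of \code{dt} in
#'   \code{[0, duration)}.
#' @export
poisson_spike_train <- function(rate, duration = cfg$duration,
                                cfg = sim_config()) {
  stopifnot(rate >= 0)
  if (rate * cfg$dt > 1)
    stop("rate * dt > 1: spike probability per bin exceeds 1")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- floor(duration / cfg$dt)
  hit <- stats::runif(n) < rate * cfg$dt
  (which(hit) - 1) * cfg$dt
}

#' Several independent Poisson spike trains as an event list
#'
#' @param rates vector of mean rates (KHz), one per source.
#' @param duration train duration (ms).
#' @param cfg a \code{\link{sim_config}} object.
#' @return data.frame with columns \code{source_id} (1-based) and
#'   \code{t_ms}, sorted by source then time.
#' @export
poisson_spike_trains <- function(rates, duration = cfg$duration,
                                 cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg$seed <- NULL  # one seeding for the whole set
  ev <- lapply(seq_along(rates), function(i) {
    t <- poisson_spike_train(rates[i], duration, cfg)
    if (length(t)) data.frame(source_id = i, t_ms = t) else NULL
  })
  out <- do.call(rbind, ev)
  if (is.null(out)) out <- data.frame(source_id = integer(), t_ms = numeric())
  out
}

#' Dense 0/1 matrix view of an event list
#'
#' @param events data.frame with \code{source_id}, \code{t_ms}.
#' @param n_sources number of rows of the result.
#' @param duration duration (ms).
#' @param dt bin width (ms).
#' @return \code{n_sources x duration/dt} 0/1 matrix.
#' @export
spike_train_matrix <- function(events, n_sources, duration, dt = 1) {
  n_steps <- floor(duration / dt)
  m <- matrix(0, n_sources, n_steps)
  if (nrow(events)) {
    idx <- cbind(events$source_id, floor(events$t_ms / dt) + 1)
    keep <- idx[, 2] >= 1 & idx[, 2] <= n_steps
    m[idx[keep, , drop = FALSE]] <- 1
  }
  m
}

#' Current trace injected by one weighted spike train
#'
#' Converts presynaptic spikes into a postsynaptic current contribution.
#' With the rectangular kernel (default) each spike of weight w injects
#' w mA for exactly one step. With the exponential kernel each spike starts
#' a decaying pulse with time constant \code{cfg$tau_syn}, discretely
#' normalized to unit area so the long-run mean current of a Poisson train of
#' rate r is exactly \code{w * r}. Contributions from multiple sources
#' superpose linearly (sum the returned traces).
#'
#' @param times spike times (ms).
#' @param weight synaptic weight (mA per spike).
#' @param duration trace duration (ms).
#' @param cfg a \code{\link{sim_config}} object.
#' @return Numeric current trace of length \code{duration/dt} (mA).
#' @export
synaptic_current <- function(times, weight, duration, cfg = sim_config()) {
  n <- floor(duration / cfg$dt)
  x <- numeric(n)
  idx <- floor(times / cfg$dt) + 1
  idx <- idx[idx >= 1 & idx <= n]
  if (cfg$kernel == "rect") {
    x[idx] <- x[idx] + weight
  } else {
    lam <- exp(-cfg$dt / cfg$tau_syn)
    amp <- weight * (1 - lam) / cfg$dt   # unit discrete area per spike
    imp <- numeric(n)
    imp[idx] <- imp[idx] + amp
    x <- as.numeric(stats::filter(imp, lam, method = "recursive"))
  }
  x
}
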