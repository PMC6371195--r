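#' Intrinsic parameters of a leaky integrate-and-fire neuron
#'
#' Bundles the tunable and fixed intrinsic parameters of a LIF neuron together
#' with the tuning ranges that intrinsic plasticity must respect. The package
#' uses a single unit system throughout: time in ms, rate in KHz (spikes/ms),
#' voltage in mV, current in mA and resistance in Ohm, so that Ohm x mA = mV
#' and every parameter value can be used verbatim.
#'
#' The membrane time constant satisfies \code{tau_m = R * C}; the implied
#' membrane capacitance is a derived quantity (see \code{\link{capacitance}})
#' and is never stored, so adapting \code{R} at fixed \code{tau_m} implicitly
#' co-adapts \code{C}.
#'
#' @param V_th firing threshold (mV), positive.
#' @param t_r absolute refractory period (ms), non-negative.
#' @param R leaky resistance (Ohm); must lie within \code{bounds_R}.
#' @param tau_m membrane time constant (ms); must lie within \code{bounds_tau}.
#' @param bounds_R length-2 numeric, closed tuning interval for \code{R} (Ohm).
#' @param bounds_tau length-2 numeric, closed tuning interval for \code{tau_m} (ms).
#' @return An object of class \code{"neuron_params"}.
#' @examples
#' p <- neuron_params()            # the canonical 20 mV / 2 ms / 64 Ohm / 64 ms neuron
#' frtf_rate(7, p)
#' @export
neuron_params <- function(V_th = 20, t_r = 2, R = 64, tau_m = 64,
                          bounds_R = c(1, 1024), bounds_tau = c(1, 1024)) {
  stopifnot(is.numeric(V_th), length(V_th) == 1L, V_th > 0,
            is.numeric(t_r), length(t_r) == 1L, t_r >= 0,
            is.numeric(R), length(R) == 1L,
            is.numeric(tau_m), length(tau_m) == 1L,
            length(bounds_R) == 2L, length(bounds_tau) == 2L)
  if (bounds_R[1] <= 0 || bounds_tau[1] <= 0)
    stop("tuning bounds must have positive lower ends")
  if (bounds_R[1] > bounds_R[2] || bounds_tau[1] > bounds_tau[2])
    stop("tuning bounds must be non-empty closed intervals")
  if (R < bounds_R[1] || R > bounds_R[2])
    stop("R outside bounds_R")
  if (tau_m < bounds_tau[1] || tau_m > bounds_tau[2])
    stop("tau_m outside bounds_tau")
  structure(list(V_th = V_th, t_r = t_r, R = R, tau_m = tau_m,
                 bounds_R = as.numeric(bounds_R),
                 bounds_tau = as.numeric(bounds_tau)),
            class = "neuron_params")
}

#' Implied membrane capacitance
#'
#' \code{C = tau_m / R}; derived, never stored.
#'
#' @param p a \code{\link{neuron_params}} object.
#' @return Capacitance (ms/Ohm).
#' @export
capacitance <- function(p) p$tau_m / p$R

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters\n")
  cat(sprintf("  V_th  = %g mV, t_r = %g ms\n", x$V_th, x$t_r))
  cat(sprintf("  R     = %g Ohm  in [%g, %g]\n", x$R, x$bounds_R[1], x$bounds_R[2]))
  cat(sprintf("  tau_m = %g ms   in [%g, %g]  (C = %.4g ms/Ohm)\n",
              x$tau_m, x$bounds_tau[1], x$bounds_tau[2], x$tau_m / x$R))
  invisible(x)
}

#' SpiKL-IP hyperparameters
#'
#' Configuration of the intrinsic-plasticity rule that tunes the output
#' firing-rate distribution toward an exponential distribution with mean
#' \code{mu}. When the measured rate falls at or below the small guard
#' \code{delta}, the rule switches to a recovery branch that raises \code{R}
#' by \code{eta1 * alpha1} and lowers \code{tau_m} by \code{eta2 * alpha2}
#' per step to bring firing back.
#'
#' @param mu target mean of the exponential output distribution (KHz).
#' @param eta1,eta2 learning rates for \code{R} and \code{tau_m}.
#' @param alpha1 low-rate recovery increment for \code{R} (Ohm).
#' @param alpha2 low-rate recovery decrement for \code{tau_m} (ms).
#' @param delta low-rate guard threshold (KHz); default 0.001 (1 Hz).
#' @return An object of class \code{"ip_config"}.
#' @export
ip_config <- function(mu = 0.2, eta1 = 5, eta2 = 5,
                      alpha1 = 0.1, alpha2 = 0.1, delta = 0.001) {
  stopifnot(mu > 0, eta1 > 0, eta2 > 0, alpha1 > 0, alpha2 > 0)
  if (!(delta > 0 && delta < mu))
    stop("delta must satisfy 0 < delta < mu")
  structure(list(mu = mu, eta1 = eta1, eta2 = eta2,
                 alpha1 = alpha1, alpha2 = alpha2, delta = delta),
            class = "ip_config")
}

#' @export
print.ip_config <- function(x, ...) {
  cat(sprintf("SpiKL-IP config: mu = %g KHz, eta = (%g, %g), alpha = (%g, %g), delta = %g KHz\n",
              x$mu, x$eta1, x$eta2, x$alpha1, x$alpha2, x$delta))
  invisible(x)
}

#' Voltage-threshold IP baseline configuration
#'
#' The baseline rule nudges a neuron's firing threshold by a fixed-size step
#' so that it spikes on average \code{k} out of \code{N} time steps; it
#' controls only the mean firing rate, not the shape of the rate distribution.
#'
#' @param eta learning rate (mV per step).
#' @param k,N target spike fraction numerator and denominator (counts),
#'   \code{0 < k < N}.
#' @return An object of class \code{"vtip_config"}.
#' @export
vtip_config <- function(eta = 0.1, k = 1, N = 5) {
  stopifnot(eta > 0, k > 0, N > k)
  structure(list(eta = eta, k = k, N = N), class = "vtip_config")
}

#' @export
print.vtip_config <- function(x, ...) {
  cat(sprintf("Voltage-threshold IP config: eta = %g mV, target fraction k/N = %g/%g = %g\n",
              x$eta, x$k, x$N, x$k / x$N))
  invisible(x)
}

#' Simulation configuration
#'
#' Lockstep simulation settings. All neuronal activity is evaluated on a fixed
#' grid of width \code{dt} (default 1 ms). The firing rate of a spiking neuron
#' is read out from a calcium-like trace that is incremented by one unit per
#' spike and decays with time constant \code{tau_cal}; the rate estimate is
#' the trace divided by \code{tau_cal}.
#'
#' @param dt time step (ms).
#' @param tau_cal calcium (rate-estimator) time constant (ms), \code{>= dt}.
#' @param tau_syn synaptic decay constant (ms), used only by the exponential
#'   synaptic kernel.
#' @param duration default duration of generated inputs (ms).
#' @param seed optional integer seed used by generators that draw randomness.
#' @param kernel spike-to-current conversion: \code{"rect"} injects, per spike
#'   of weight w, a rectangular pulse of amplitude w mA lasting one step;
#'   \code{"exp"} injects a discretely unit-area exponential kernel with decay
#'   \code{tau_syn} (long-run mean current w * rate, exactly).
#' @param integration membrane integration scheme: \code{"exponential"} (exact
#'   per-step solution for piecewise-constant input, the default) or
#'   \code{"euler"} (forward Euler, for comparison).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 1, tau_cal = 64, tau_syn = 8, duration = 1000,
                       seed = NULL, kernel = c("rect", "exp"),
                       integration = c("exponential", "euler")) {
  kernel <- match.arg(kernel)
  integration <- match.arg(integration)
  stopifnot(dt > 0, tau_cal >= dt, tau_syn > 0, duration > 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(dt = dt, tau_cal = tau_cal, tau_syn = tau_syn,
                 duration = duration, seed = seed,
                 kernel = kernel, integration = integration),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: dt = %g ms, tau_cal = %g ms, kernel = %s, integration = %s\n",
              x$dt, x$tau_cal, x$kernel, x$integration))
  invisible(x)
}
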