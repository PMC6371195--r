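#' Interspike interval of a LIF neuron under constant input
#'
#' For a constant input current \code{x0} with supra-threshold drive
#' (\code{R * x0 > V_th}), integrating the membrane equation
#' \code{tau_m dV/dt = -V + R x} from reset to threshold gives the closed-form
#' interspike interval
#' \deqn{T_{isi} = t_r + \tau_m \log\frac{R x_0}{R x_0 - V_{th}}.}
#'
#' @param x0 constant input current (mA); may be a vector.
#' @param p a \code{\link{neuron_params}} object.
#' @return Interspike interval(s) in ms.
#' @seealso \code{\link{frtf_rate}} for the reciprocal (with sub-threshold
#'   inputs mapped to rate 0 instead of an error).
#' @export
isi_constant_input <- function(x0, p) {
  stopifnot(inherits(p, "neuron_params"), is.numeric(x0))
  drive <- p$R * x0
  if (any(drive <= p$V_th))
    stop("R * x0 <= V_th: neuron never fires under this constant input")
  p$t_r + p$tau_m * log(drive / (drive - p$V_th))
}

#' Firing-rate transfer function (FR-TF) of the LIF neuron
#'
#' The steady output firing rate under constant input current: the reciprocal
#' interspike interval on the firing domain, and exactly 0 below threshold
#' (so tuning-curve sweeps are total functions). Strictly increasing in
#' \code{x0} and in \code{R} on the firing domain and bounded above by
#' \code{1/t_r}.
#'
#' @inheritParams isi_constant_input
#' @return Firing rate(s) in KHz.
#' @examples
#' p <- neuron_params()
#' frtf_rate(7, p)        # ~0.203 KHz
#' frtf_rate(0.1, p)      # sub-threshold: 0
#' @export
frtf_rate <- function(x0, p) {
  stopifnot(inherits(p, "neuron_params"), is.numeric(x0))
  drive <- p$R * x0
  y <- numeric(length(x0))
  fire <- drive > p$V_th
  y[fire] <- 1 / (p$t_r + p$tau_m * log(drive[fire] / (drive[fire] - p$V_th)))
  y
}

#' Analytic gradients of the firing-rate transfer function
#'
#' Closed-form partial derivatives of the FR-TF output rate with respect to
#' the input current, the leaky resistance and the membrane time constant:
#' \deqn{\partial y/\partial x = y^2 \tau_m V_{th} / (x (Rx - V_{th}))}
#' \deqn{\partial y/\partial R = y^2 \tau_m V_{th} / (R (Rx - V_{th}))}
#' \deqn{\partial y/\partial \tau_m = (t_r y^2 - y) / \tau_m}
#' Note the structural symmetry \code{x * dy_dx == R * dy_dR}, and that
#' \code{dy_dtau} is negative whenever \code{0 < y < 1/t_r}.
#'
#' @inheritParams isi_constant_input
#' @return A list with numeric components \code{dy_dx}, \code{dy_dR},
#'   \code{dy_dtau} (vectorized over \code{x0}).
#' @export
frtf_gradients <- function(x0, p) {
  stopifnot(inherits(p, "neuron_params"), is.numeric(x0))
  drive <- p$R * x0
  if (any(drive <= p$V_th))
    stop("R * x0 <= V_th: gradients are defined only on the firing domain")
  y <- 1 / (p$t_r + p$tau_m * log(drive / (drive - p$V_th)))
  W <- drive - p$V_th
  list(dy_dx   = y^2 * p$tau_m * p$V_th / (x0 * W),
       dy_dR   = y^2 * p$tau_m * p$V_th / (p$R * W),
       dy_dtau = (p$t_r * y^2 - y) / p$tau_m)
}

#' Supra-threshold drive from an output firing rate
#'
#' Inverts the FR-TF for the supra-threshold drive \code{W = R x - V_th}
#' without reference to the instantaneous input:
#' \deqn{W = V_{th} / (e^{(1/\tau_m)(1/y - t_r)} - 1).}
#' This is the substitution that frees the final SpiKL-IP rule from the
#' instantaneous input current.
#'
#' The inversion is defined for \code{0 < y < 1/t_r}. A rate estimator can
#' transiently report rates at or above \code{1/t_r}, which would make
#' \code{W <= 0}; with \code{clamp = TRUE} the rate is first clamped into
#' \code{[delta, (1 - 1e-6)/t_r]}, which is how the adaptation rule calls it.
#'
#' @param y output firing rate (KHz); may be a vector.
#' @param p a \code{\link{neuron_params}} object.
#' @param clamp clamp \code{y} into the invertible range instead of erroring.
#' @param delta lower clamp bound (KHz), used when \code{clamp = TRUE}.
#' @return Supra-threshold drive(s) W in mV, strictly positive.
#' @export
w_from_rate <- function(y, p, clamp = FALSE, delta = 0.001) {
  stopifnot(inherits(p, "neuron_params"), is.numeric(y))
  if (clamp) {
    y <- pmin(pmax(y, delta), (1 - 1e-6) / p$t_r)
  } else if (any(y <= 0) || any(y >= 1 / p$t_r)) {
    stop("w_from_rate requires 0 < y < 1/t_r (or clamp = TRUE)")
  }
  p$V_th / (exp((1 / p$tau_m) * (1 / y - p$t_r)) - 1)
}

#' Tuning-curve table of the firing-rate transfer function
#'
#' Evaluates the FR-TF on the product grid of input currents and parameter
#' values, holding the other parameters at those in \code{p}. The result has
#' one row per (x, R, tau_m) combination and is ready for CSV export.
#'
#' @param x input current sweep (mA).
#' @param R leaky resistance values (Ohm); default the value in \code{p}.
#' @param tau_m membrane time constants (ms); default the value in \code{p}.
#' @param p a \code{\link{neuron_params}} object supplying \code{V_th},
#'   \code{t_r} and defaults.
#' @return data.frame with columns \code{x_mA}, \code{R_ohm}, \code{tau_m_ms},
#'   \code{y_khz}.
#' @export
frtf_curve <- function(x, R = NULL, tau_m = NULL, p = neuron_params()) {
  stopifnot(inherits(p, "neuron_params"))
  if (is.null(R)) R <- p$R
  if (is.null(tau_m)) tau_m <- p$tau_m
  g <- expand.grid(x_mA = x, R_ohm = R, tau_m_ms = tau_m,
                   KEEP.OUT.ATTRS = FALSE)
  drive <- g$R_ohm * g$x_mA
  y <- numeric(nrow(g))
  fire <- drive > p$V_th
  y[fire] <- 1 / (p$t_r + g$tau_m_ms[fire] *
                    log(drive[fire] / (drive[fire] - p$V_th)))
  g$y_khz <- y
  g
}
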