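# Vectorized core of the SpiKL-IP update. R, tau_m and y may be vectors of
# equal length; V_th and t_r are scalars shared by the population. Returns the
# updated (R, tau_m), hard-clipped to the tuning bounds.
spikl_update_vec <- function(R, tau_m, y, V_th, t_r, bounds_R, bounds_tau, ip) {
  hi <- y > ip$delta
  yc <- pmin(pmax(y, ip$delta), (1 - 1e-6) / t_r)
  W <- V_th / (exp((1 / tau_m) * (1 / yc - t_r)) - 1)
  dR_hi <- (2 * y * tau_m * V_th - W - V_th - (1 / ip$mu) * tau_m * V_th * y^2) /
    (R * W)
  dt_hi <- (2 * t_r * y - 1 - (1 / ip$mu) * (t_r * y^2 - y)) / tau_m
  Rn <- ifelse(hi, R + ip$eta1 * dR_hi, R + ip$eta1 * ip$alpha1)
  tn <- ifelse(hi, tau_m + ip$eta2 * dt_hi, tau_m - ip$eta2 * ip$alpha2)
  list(R = pmin(pmax(Rn, bounds_R[1]), bounds_R[2]),
       tau_m = pmin(pmax(tn, bounds_tau[1]), bounds_tau[2]))
}

#' One step of the SpiKL-IP rule (input-free, guarded form)
#'
#' Applies the final form of the SpiKL-IP adaptation to a neuron's leaky
#' resistance and membrane time constant, using only the measured output
#' firing rate \code{y}. For \code{y > delta}, the update descends the
#' KL-divergence surrogate loss with the supra-threshold drive W recovered
#' from the rate (see \code{\link{w_from_rate}}):
#' \deqn{R \leftarrow R + \eta_1 \frac{2 y \tau_m V_{th} - W - V_{th}
#'   - \tau_m V_{th} y^2/\mu}{R W}, \qquad
#'   \tau_m \leftarrow \tau_m + \eta_2 \frac{2 t_r y - 1
#'   - (t_r y^2 - y)/\mu}{\tau_m}.}
#' For \code{y <= delta} the recovery branch applies
#' \code{R + eta1*alpha1} and \code{tau_m - eta2*alpha2}. Both parameters are
#' then hard-clipped to their tuning bounds. The rate fed to the W-inversion
#' is clamped into \code{[delta, (1-1e-6)/t_r]}.
#'
#' @param y measured output firing rate (KHz).
#' @param p a \code{\link{neuron_params}} object.
#' @param ip an \code{\link{ip_config}} object.
#' @return An updated \code{\link{neuron_params}} object.
#' @examples
#' p <- neuron_params()
#' spikl_ip_step(0.2, p, ip_config())   # small decrease in R, increase in tau_m
#' @export
spikl_ip_step <- function(y, p, ip = ip_config()) {
  stopifnot(inherits(p, "neuron_params"), inherits(ip, "ip_config"),
            is.numeric(y), length(y) == 1L, y >= 0)
  up <- spikl_update_vec(p$R, p$tau_m, y, p$V_th, p$t_r,
                         p$bounds_R, p$bounds_tau, ip)
  p$R <- up$R
  p$tau_m <- up$tau_m
  p
}

#' One step of the basic SpiKL-IP rule (instantaneous-input form)
#'
#' Gradient-descent step on the per-step surrogate loss using the
#' instantaneous input current \code{x} directly (the drive term is
#' \code{R x - V_th} rather than its rate-based reconstruction). Provided for
#' validation and ablation: whenever \code{y} and \code{x} are consistent
#' under the FR-TF, this step is algebraically identical to the high-rate
#' branch of \code{\link{spikl_ip_step}}. Its direct use under fast-varying
#' inputs is ineffective in practice, which is what motivates the input-free
#' form.
#'
#' @param x instantaneous input current (mA); must satisfy
#'   \code{R * x > V_th}.
#' @param y measured output firing rate (KHz).
#' @inheritParams spikl_ip_step
#' @return An updated \code{\link{neuron_params}} object.
#' @export
spikl_ip_step_basic <- function(x, y, p, ip = ip_config()) {
  stopifnot(inherits(p, "neuron_params"), inherits(ip, "ip_config"),
            is.numeric(x), length(x) == 1L,
            is.numeric(y), length(y) == 1L)
  W <- p$R * x - p$V_th
  if (W <= 0) stop("R * x <= V_th: basic rule is defined only on the firing domain")
  Rn <- p$R + ip$eta1 * ((2 * y - y^2 / ip$mu) * p$tau_m * p$V_th - p$R * x) /
    (p$R * W)
  tn <- p$tau_m + ip$eta2 * (2 * p$t_r * y - 1 - (1 / ip$mu) * (p$t_r * y^2 - y)) /
    p$tau_m
  p$R <- min(max(Rn, p$bounds_R[1]), p$bounds_R[2])
  p$tau_m <- min(max(tn, p$bounds_tau[1]), p$bounds_tau[2])
  p
}

#' One step of the voltage-threshold IP baseline rule
#'
#' Shifts a firing threshold by a fixed-size step toward a target spike
#' fraction: \code{V_th + eta * (spiked - k/N)}. Under stationary drive the
#' threshold settles where the neuron spikes on average \code{k} out of
#' \code{N} steps. The rule controls only the mean rate, not the distribution
#' shape.
#'
#' @param v_th current firing threshold (mV); may be a vector.
#' @param spiked 0/1 spike indicator(s) for this step.
#' @param vt a \code{\link{vtip_config}} object.
#' @return Updated threshold(s) (mV).
#' @export
voltage_threshold_ip_step <- function(v_th, spiked, vt = vtip_config()) {
  stopifnot(inherits(vt, "vtip_config"), is.numeric(v_th),
            all(spiked %in% c(0, 1)))
  v_th + vt$eta * (spiked - vt$k / vt$N)
}

#' Per-step surrogate loss of SpiKL-IP
#'
#' The online surrogate of the KL divergence from the target exponential
#' distribution to the output-rate distribution, evaluated at one
#' input/output observation:
#' \deqn{\hat L = -\log(\partial y/\partial x) + y/\mu,}
#' with the slope taken from the analytic FR-TF gradient. Finite at every
#' firing point; used for monitoring descent, not by the rule itself.
#'
#' @inheritParams spikl_ip_step_basic
#' @return A list with \code{L_hat} (the loss, nats) and \code{dy_dx}
#'   (the FR-TF slope used).
#' @export
surrogate_loss <- function(x, y, p, ip = ip_config()) {
  stopifnot(inherits(p, "neuron_params"), inherits(ip, "ip_config"))
  W <- p$R * x - p$V_th
  if (any(W <= 0)) stop("R * x <= V_th: loss is defined only on the firing domain")
  dy_dx <- y^2 * p$tau_m * p$V_th / (x * W)
  list(L_hat = -log(dy_dx) + y / ip$mu, dy_dx = dy_dx)
}
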