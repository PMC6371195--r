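new_ip_run <- function(kind, rates, rule, burn_in, extra) {
  structure(c(list(kind = kind, rates = rates, rule = rule,
                   burn_in = burn_in), extra),
            class = c(paste0(kind, "_run"), "ip_run"))
}

#' Rate-model neuron experiment: random current through the FR-TF
#'
#' Drives a single rate-model neuron (its output is the firing-rate transfer
#' function of its instantaneous input) with i.i.d. random current levels,
#' one per 1 ms step, and optionally applies the SpiKL-IP rule every step.
#' The canonical settings are Gaussian input (mean 7 mA, sd 1 mA) or uniform
#' input on [0.5, 5.5] mA, 10,000 steps, R and tau_m initialized to 64 with
#' tuning ranges [1, 1024].
#'
#' @param input input distribution: \code{"gaussian"} or \code{"uniform"}.
#' @param rule \code{"spikl"} or \code{"none"} (fixed-parameter control).
#' @param n_steps number of 1 ms steps.
#' @param p initial \code{\link{neuron_params}}.
#' @param ip an \code{\link{ip_config}}.
#' @param gaussian_mean,gaussian_sd Gaussian input parameters (mA).
#' @param uniform_min,uniform_max uniform input range (mA).
#' @param seed optional integer seed.
#' @param burn_in fraction of initial steps excluded by diagnostics.
#' @return An object of classes \code{"frtf_run"}, \code{"ip_run"} recording
#'   per-step input \code{x}, rate \code{rates}, and parameter trajectories
#'   \code{traj_R}, \code{traj_tau}.
#' @examples
#' run <- run_frtf_neuron_experiment(n_steps = 1000, seed = 1)
#' summary(run)
#' @export
run_frtf_neuron_experiment <- function(input = c("gaussian", "uniform"),
                                       rule = c("spikl", "none"),
                                       n_steps = 10000,
                                       p = neuron_params(),
                                       ip = ip_config(),
                                       gaussian_mean = 7, gaussian_sd = 1,
                                       uniform_min = 0.5, uniform_max = 5.5,
                                       seed = NULL, burn_in = 0.2) {
  input <- match.arg(input)
  rule <- match.arg(rule)
  stopifnot(inherits(p, "neuron_params"), inherits(ip, "ip_config"))
  if (!is.null(seed)) set.seed(seed)
  x <- if (input == "gaussian") {
    stats::rnorm(n_steps, gaussian_mean, gaussian_sd)
  } else {
    stats::runif(n_steps, uniform_min, uniform_max)
  }
  R <- p$R
  tau <- p$tau_m
  ys <- numeric(n_steps)
  Rs <- numeric(n_steps)
  ts <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    drive <- R * x[t]
    y <- if (drive > p$V_th) {
      1 / (p$t_r + tau * log(drive / (drive - p$V_th)))
    } else 0
    ys[t] <- y
    Rs[t] <- R
    ts[t] <- tau
    if (rule == "spikl") {
      up <- spikl_update_vec(R, tau, y, p$V_th, p$t_r,
                             p$bounds_R, p$bounds_tau, ip)
      R <- up$R
      tau <- up$tau_m
    }
  }
  p$R <- R
  p$tau_m <- tau
  new_ip_run("frtf", ys, rule, burn_in,
             list(x = x, traj_R = Rs, traj_tau = ts, params = p, ip = ip,
                  input = input, seed = seed))
}

#' Single spiking LIF neuron driven by a Poisson spike train
#'
#' One LIF neuron receives a Poisson input spike train (canonically 160 Hz
#' for 1,000 ms) through a single synapse; the same train is repeated for
#' \code{passes} passes so that adaptation can converge. The firing rate is
#' read out from the calcium trace (tau_cal = 64 ms) and the chosen
#' intrinsic-plasticity rule is applied every step.
#'
#' @param rule \code{"spikl"}, \code{"none"} or \code{"vth"}.
#' @param input_rate Poisson input rate (KHz).
#' @param duration duration of one input pass (ms).
#' @param passes number of repetitions of the input train.
#' @param input_weight synaptic weight of the input (mA per spike).
#' @param p initial \code{\link{neuron_params}}.
#' @param ip an \code{\link{ip_config}}.
#' @param vt a \code{\link{vtip_config}}.
#' @param cfg a \code{\link{sim_config}}.
#' @param seed optional integer seed (input generation).
#' @param burn_in fraction of initial steps excluded by diagnostics.
#' @return An object of classes \code{"lif_run"}, \code{"ip_run"}.
#' @export
run_single_lif_experiment <- function(rule = c("spikl", "none", "vth"),
                                      input_rate = 0.16, duration = 1000,
                                      passes = 10, input_weight = 8,
                                      p = neuron_params(), ip = ip_config(),
                                      vt = vtip_config(), cfg = sim_config(),
                                      seed = NULL, burn_in = 0.2) {
  rule <- match.arg(rule)
  if (!is.null(seed)) cfg$seed <- seed
  train <- poisson_spike_train(input_rate, duration, cfg)
  x1 <- synaptic_current(train, input_weight, duration, cfg)
  x <- rep(x1, passes)
  n <- length(x)
  net1 <- new_spiking_network(matrix(0, 1, 1), matrix(0, 0, 1), NULL, NULL,
                              p, "single", seed)
  net1$Win <- matrix(0, 1, 1)   # inject precomputed current directly below
  R <- p$R
  tau <- p$tau_m
  V_th <- p$V_th
  V <- 0; refr <- 0; C <- 0
  dc <- exp(-cfg$dt / cfg$tau_cal)
  ys <- numeric(n); Rs <- numeric(n); ts <- numeric(n); vths <- numeric(n)
  spk_out <- integer(n)
  for (t in seq_len(n)) {
    spk <- 0
    if (refr > 0) {
      V <- 0
      refr <- refr - cfg$dt
    } else {
      drive <- R * x[t]
      V <- if (cfg$integration == "exponential") {
        drive + (V - drive) * exp(-cfg$dt / tau)
      } else V + cfg$dt * (-V + drive) / tau
      if (V >= V_th) { spk <- 1; V <- 0; refr <- p$t_r }
    }
    C <- (C + spk) * dc
    y <- C / cfg$tau_cal
    ys[t] <- y; Rs[t] <- R; ts[t] <- tau; vths[t] <- V_th
    spk_out[t] <- spk
    if (rule == "spikl") {
      up <- spikl_update_vec(R, tau, y, p$V_th, p$t_r,
                             p$bounds_R, p$bounds_tau, ip)
      R <- up$R
      tau <- up$tau_m
    } else if (rule == "vth") {
      V_th <- voltage_threshold_ip_step(V_th, spk, vt)
    }
  }
  p$R <- R
  p$tau_m <- tau
  new_ip_run("lif", ys, rule, burn_in,
             list(spikes = spk_out, traj_R = Rs, traj_tau = ts,
                  traj_V_th = vths, final_V_th = V_th, params = p, ip = ip,
                  vt = vt, cfg = cfg, input_rate = input_rate,
                  input_weight = input_weight, passes = passes, seed = seed))
}

#' Recurrent-network experiment: 100 LIF neurons, 30 Poisson inputs
#'
#' Builds a fully connected recurrent network (recurrent weights uniform on
#' [-1, 1]) with Poisson input lines (canonically 30 lines at 80 Hz, each
#' wired to 30 neurons with weights +-8), repeats the input for
#' \code{passes} passes, and records every neuron's calcium-based rate under
#' the chosen rule. Diagnostics focus on \code{record_neuron}.
#'
#' @param rule \code{"spikl"}, \code{"none"} or \code{"vth"}.
#' @param n network size.
#' @param n_inputs number of Poisson input lines.
#' @param input_rate input rate per line (KHz).
#' @param fanout neurons wired per input line.
#' @param input_weight input weight magnitude (mA per spike).
#' @param duration one pass duration (ms).
#' @param passes number of repetitions of the input block.
#' @param record_neuron neuron whose rate sample the summary reports.
#' @param p neuron parameter template.
#' @param ip,vt,cfg rule and simulation configurations.
#' @param seed integer seed (network build and input generation).
#' @param burn_in fraction of initial steps excluded by diagnostics.
#' @return An object of classes \code{"network_run"}, \code{"ip_run"};
#'   \code{rates} holds the recorded neuron's sample, \code{sim} the full
#'   \code{\link{simulate_network}} result.
#' @export
run_network_experiment <- function(rule = c("spikl", "none", "vth"),
                                   n = 100, n_inputs = 30, input_rate = 0.08,
                                   fanout = 30, input_weight = 8,
                                   duration = 1000, passes = 10,
                                   record_neuron = 1,
                                   p = neuron_params(), ip = ip_config(),
                                   vt = vtip_config(), cfg = sim_config(),
                                   seed = NULL, burn_in = 0.2) {
  rule <- match.arg(rule)
  net <- build_dense_network(n, n_inputs, fanout, input_weight,
                             params = p, seed = seed)
  # input drawn after the build from the same stream: same seed => same
  # network AND same input, across rules
  ev <- poisson_spike_trains(rep(input_rate, n_inputs), duration, cfg)
  S <- spike_train_matrix(ev, n_inputs, duration, cfg$dt)
  S <- S[, rep(seq_len(ncol(S)), passes), drop = FALSE]
  sim <- simulate_network(net, S, cfg, rule, ip, vt)
  new_ip_run("network", sim$rates[record_neuron, ], rule, burn_in,
             list(sim = sim, net = net, record_neuron = record_neuron,
                  params = p, ip = ip, vt = vt, cfg = cfg,
                  passes = passes, seed = seed))
}

#' One-shot tuning characteristics of SpiKL-IP across rate levels
#'
#' Tabulates the parameter changes produced by a single application of the
#' rule at each output rate level, starting from the same (R, tau_m). The
#' tau_m change has a unique zero crossing in (delta, 1/t_r) at the smaller
#' root of \code{(t_r/mu) y^2 - (2 t_r + 1/mu) y + 1 = 0}.
#'
#' @param y rate grid (KHz).
#' @param p a \code{\link{neuron_params}} starting point.
#' @param ip an \code{\link{ip_config}}.
#' @return data.frame with columns \code{y_khz}, \code{delta_R_ohm},
#'   \code{delta_tau_ms}.
#' @export
sweep_tuning_characteristics <- function(y = seq(0, 0.45, by = 0.005),
                                         p = neuron_params(),
                                         ip = ip_config()) {
  up <- spikl_update_vec(rep(p$R, length(y)), rep(p$tau_m, length(y)),
                         y, p$V_th, p$t_r, p$bounds_R, p$bounds_tau, ip)
  data.frame(y_khz = y,
             delta_R_ohm = up$R - p$R,
             delta_tau_ms = up$tau_m - p$tau_m)
}

# ---- methods for experiment results -------------------------------------

#' Post-burn-in rate sample of an experiment run
#'
#' @param run an \code{"ip_run"} object.
#' @param all return the full record instead of the post-burn-in window.
#' @return Numeric vector of rates (KHz).
#' @export
rates <- function(run, all = FALSE) {
  stopifnot(inherits(run, "ip_run"))
  if (all) run$rates else post_burn_in(run$rates, run$burn_in)
}

#' @export
print.ip_run <- function(x, ...) {
  cat(sprintf("%s experiment, rule = %s, %d recorded steps (burn-in %.0f%%)\n",
              x$kind, x$rule, length(x$rates), 100 * x$burn_in))
  y <- rates(x)
  cat(sprintf("  post-burn-in mean rate %.4g KHz\n", mean(y)))
  invisible(x)
}

#' @export
summary.ip_run <- function(object, bins = 50, ...) {
  y <- rates(object)
  fit <- exp_fit(y, bins)
  kl_target <- if (!is.null(object$ip))
    kl_to_exponential(y, object$ip$mu, bins) else NA_real_
  out <- list(kind = object$kind, rule = object$rule, n = length(y),
              mean_rate = mean(y), fit = fit, kl_target = kl_target,
              mu_target = if (!is.null(object$ip)) object$ip$mu else NA_real_,
              coef = coef(object))
  class(out) <- "summary.ip_run"
  out
}

#' @export
print.summary.ip_run <- function(x, ...) {
  cat(sprintf("%s experiment under rule '%s' (%d post-burn-in samples)\n",
              x$kind, x$rule, x$n))
  cat(sprintf("  mean rate        %.4f KHz (target mu = %g)\n",
              x$mean_rate, x$mu_target))
  cat(sprintf("  exp fit mu_hat   %.4f KHz\n", x$fit$mu_hat))
  cat(sprintf("  KL to fitted exp %.4f nats\n", x$fit$kl))
  cat(sprintf("  KL to Exp(mu)    %.4f nats\n", x$kl_target))
  cat(sprintf("  entropy          %.4f nats\n", x$fit$entropy))
  cat("  final parameters:", paste(sprintf("%s = %.4g", names(x$coef), x$coef),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ip_run <- function(object, ...) {
  if (object$kind == "network") {
    i <- object$record_neuron
    c(R = object$sim$R[i], tau_m = object$sim$tau_m[i],
      V_th = object$sim$V_th[i])
  } else {
    out <- c(R = object$params$R, tau_m = object$params$tau_m)
    if (!is.null(object$final_V_th)) out <- c(out, V_th = object$final_V_th)
    out
  }
}

#' Histogram of an experiment's rate sample with its exponential fit
#'
#' Reproduces the standard figure: post-burn-in firing-rate histogram with
#' the best-fitting exponential density overlaid in red.
#'
#' @param x an \code{"ip_run"} object.
#' @param bins number of histogram bins.
#' @param what \code{"hist"} or \code{"trajectory"} (parameter trajectories).
#' @param ... passed to the underlying plot call.
#' @export
plot.ip_run <- function(x, bins = 50, what = c("hist", "trajectory"), ...) {
  what <- match.arg(what)
  if (what == "hist") {
    y <- rates(x)
    mu <- fit_exponential_mle(y)
    h <- graphics::hist(y, breaks = rate_bins(y, max(mu, 1e-12), bins),
                        freq = FALSE,
                        main = sprintf("%s / %s", x$kind, x$rule),
                        xlab = "output firing rate (KHz)", ...)
    if (mu > 0) graphics::curve(stats::dexp(z, 1 / mu), xname = "z",
                                from = 0, to = max(h$breaks),
                                add = TRUE, col = "red", lwd = 2)
  } else {
    if (is.null(x$traj_R)) stop("run has no recorded parameter trajectories")
    t <- seq_along(x$traj_R)
    graphics::par(mfrow = c(2, 1))
    graphics::plot(t, x$traj_R, type = "l", xlab = "t (ms)",
                   ylab = "R (Ohm)", main = "leaky resistance", ...)
    graphics::plot(t, x$traj_tau, type = "l", xlab = "t (ms)",
                   ylab = "tau_m (ms)", main = "membrane time constant", ...)
    graphics::par(mfrow = c(1, 1))
  }
  invisible(x)
}
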