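#' Specification of a 3-D liquid-state-machine reservoir
#'
#' Neurons sit on an integer 3-D grid; each is excitatory with probability
#' \code{excitatory_fraction}. A directed synapse from neuron a to neuron b
#' exists with probability \code{c_base[type(a)type(b)] * exp(-(D(a,b)/lambda)^2)}
#' with Euclidean distance D in grid units. Weights are fixed per connection
#' type (all outgoing weights share the sign of the presynaptic type). Each
#' input line is wired to \code{fanout} distinct reservoir neurons, sampled
#' without replacement, with weight \code{+input_w} or \code{-input_w} with
#' equal probability.
#'
#' @param dims integer grid dimensions \code{c(nx, ny, nz)}.
#' @param lambda connectivity length scale (grid units).
#' @param c_base named base probabilities for \code{EE}, \code{EI}, \code{IE},
#'   \code{II} (pre-type first).
#' @param excitatory_fraction proportion of excitatory neurons.
#' @param w_fixed named fixed weights per connection type (mA per spike).
#' @param n_inputs number of external input lines.
#' @param fanout reservoir targets per input line.
#' @param input_w input weight magnitude (mA per spike).
#' @param seed optional integer seed for the build.
#' @return An object of class \code{"reservoir_spec"}.
#' @export
reservoir_spec <- function(dims = c(3, 3, 5), lambda = 3,
                           c_base = c(EE = 0.3, EI = 0.2, IE = 0.4, II = 0.1),
                           excitatory_fraction = 0.8,
                           w_fixed = c(EE = 1, EI = 1, IE = -1, II = -1),
                           n_inputs = 8, fanout = 4, input_w = 2,
                           seed = NULL) {
  stopifnot(length(dims) == 3L, all(dims >= 1), lambda > 0,
            all(c("EE", "EI", "IE", "II") %in% names(c_base)),
            all(c_base >= 0 & c_base <= 1),
            excitatory_fraction >= 0, excitatory_fraction <= 1,
            all(c("EE", "EI", "IE", "II") %in% names(w_fixed)),
            n_inputs >= 0, fanout >= 0, fanout <= prod(dims))
  structure(list(dims = as.integer(dims), lambda = lambda,
                 c_base = c_base[c("EE", "EI", "IE", "II")],
                 excitatory_fraction = excitatory_fraction,
                 w_fixed = w_fixed[c("EE", "EI", "IE", "II")],
                 n_inputs = n_inputs, fanout = fanout, input_w = input_w,
                 seed = seed),
            class = "reservoir_spec")
}

new_spiking_network <- function(W, Win, type, coords, params, builder, seed, extra = NULL) {
  n <- nrow(W)
  structure(list(n = n, W = W, Win = Win, n_inputs = nrow(Win),
                 type = type, coords = coords, params = params,
                 R = rep(params$R, n), tau_m = rep(params$tau_m, n),
                 builder = builder, seed = seed, extra = extra),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("Spiking network: %d neurons, %d recurrent synapses, %d inputs (%s)\n",
              x$n, sum(x$W != 0), x$n_inputs, x$builder))
  if (!is.null(x$type))
    cat(sprintf("  %d excitatory / %d inhibitory\n",
                sum(x$type == "E"), sum(x$type == "I")))
  invisible(x)
}

#' Build a distance-dependent 3-D reservoir
#'
#' See \code{\link{reservoir_spec}} for the generative model. Reproducible:
#' the same spec and seed always produce the identical network.
#'
#' @param spec a \code{\link{reservoir_spec}}.
#' @param params a \code{\link{neuron_params}} template shared by all neurons.
#' @return A \code{"spiking_network"} object with fields \code{W} (n x n
#'   recurrent weights, \code{W[a, b]} = weight from a to b), \code{Win}
#'   (n_inputs x n), \code{type} ("E"/"I"), \code{coords} (n x 3, 0-based).
#' @export
build_lsm_reservoir <- function(spec, params = neuron_params()) {
  stopifnot(inherits(spec, "reservoir_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- spec$dims
  coords <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                  z = 0:(d[3] - 1), KEEP.OUT.ATTRS = FALSE))
  n <- nrow(coords)
  type <- ifelse(stats::runif(n) < spec$excitatory_fraction, "E", "I")
  D <- as.matrix(stats::dist(coords))
  tt <- outer(type, type, paste0)       # pre-type first
  pmatrix <- matrix(spec$c_base[tt], n, n) * exp(-(D / spec$lambda)^2)
  diag(pmatrix) <- 0                    # no self-connections
  conn <- matrix(stats::runif(n * n), n, n) < pmatrix
  W <- matrix(0, n, n)
  W[conn] <- spec$w_fixed[tt[conn]]
  Win <- matrix(0, spec$n_inputs, n)
  if (spec$n_inputs > 0 && spec$fanout > 0) {
    for (i in seq_len(spec$n_inputs)) {
      tgt <- sample.int(n, spec$fanout)
      Win[i, tgt] <- sample(c(-spec$input_w, spec$input_w), spec$fanout,
                            replace = TRUE)
    }
  }
  new_spiking_network(W, Win, type, coords, params, "lsm", spec$seed,
                      extra = list(spec = spec))
}

#' Build a fully connected (dense) recurrent network
#'
#' All ordered pairs of distinct neurons are connected; recurrent weights are
#' drawn i.i.d. from \code{weight_dist} (default uniform on [-1, 1]). Each
#' input line is wired to \code{fanout} distinct neurons with weight
#' \code{+input_w} or \code{-input_w} with equal probability.
#'
#' @param n number of neurons.
#' @param n_inputs number of external input lines.
#' @param fanout neurons wired per input line (without replacement).
#' @param input_w input weight magnitude (mA per spike).
#' @param weight_dist function(m) returning m recurrent weights.
#' @param params a \code{\link{neuron_params}} template shared by all neurons.
#' @param seed optional integer seed.
#' @return A \code{"spiking_network"} object (untyped neurons).
#' @export
build_dense_network <- function(n = 100, n_inputs = 30, fanout = 30,
                                input_w = 8,
                                weight_dist = function(m) stats::runif(m, -1, 1),
                                params = neuron_params(), seed = NULL) {
  stopifnot(n >= 1, fanout <= n)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(weight_dist(n * n), n, n)
  diag(W) <- 0
  Win <- matrix(0, n_inputs, n)
  if (n_inputs > 0 && fanout > 0) {
    for (i in seq_len(n_inputs)) {
      tgt <- sample.int(n, fanout)
      Win[i, tgt] <- sample(c(-input_w, input_w), fanout, replace = TRUE)
    }
  }
  new_spiking_network(W, Win, NULL, NULL, params, "dense", seed)
}

#' Lockstep simulation of a spiking network
#'
#' Runs the network for \code{ncol(input)} steps. Event order within each
#' step: gather input and recurrent currents (recurrent spikes arrive with a
#' one-step delay), integrate all membranes, threshold/reset, update calcium
#' rate estimates, then apply the optional per-neuron intrinsic-plasticity
#' update. A one-neuron network with no recurrence reproduces the standalone
#' \code{\link{lif_step}}/\code{\link{calcium_step}} sequence exactly.
#'
#' @param net a \code{"spiking_network"} object.
#' @param input dense input spike matrix (\code{n_inputs x n_steps}, 0/1) or
#'   an event data.frame with \code{source_id}, \code{t_ms}.
#' @param cfg a \code{\link{sim_config}}; \code{kernel} applies to input and
#'   recurrent spikes alike.
#' @param rule \code{"none"}, \code{"spikl"} or \code{"vth"}.
#' @param ip an \code{\link{ip_config}} (used when \code{rule = "spikl"}).
#' @param vt a \code{\link{vtip_config}} (used when \code{rule = "vth"}).
#' @param record_params record per-step trajectories of R and tau_m (or
#'   V_th under the baseline rule) for all neurons.
#' @return An object of class \code{"network_sim"}: matrices \code{spikes}
#'   and \code{rates} (\code{n x n_steps}), final parameter vectors, optional
#'   trajectories, and the configuration used.
#' @export
simulate_network <- function(net, input, cfg = sim_config(),
                             rule = c("none", "spikl", "vth"),
                             ip = ip_config(), vt = vtip_config(),
                             record_params = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(net, "spiking_network"))
  if (is.data.frame(input))
    input <- spike_train_matrix(input, net$n_inputs, max(input$t_ms) + cfg$dt,
                                cfg$dt)
  if (nrow(input) != net$n_inputs)
    stop("input has ", nrow(input), " sources but network expects ", net$n_inputs)
  n <- net$n
  n_steps <- ncol(input)
  dt <- cfg$dt
  # input currents for all steps at once; recurrent currents are per-step
  if (cfg$kernel == "rect") {
    Iin <- crossprod(net$Win, input)
  } else {
    lam <- exp(-dt / cfg$tau_syn)
    amp <- (1 - lam) / dt
    imp <- crossprod(net$Win, input) * amp
    Iin <- t(apply(imp, 1, function(r)
      as.numeric(stats::filter(r, lam, method = "recursive"))))
    if (n == 1) Iin <- matrix(Iin, 1, n_steps)
  }
  R <- net$R
  tau <- net$tau_m
  V_th <- rep(net$params$V_th, n)
  t_r <- net$params$t_r
  V <- numeric(n)
  refr <- numeric(n)
  C <- numeric(n)
  spk_prev <- numeric(n)
  rec_syn <- numeric(n)                 # exponential-kernel recurrent trace
  dc <- exp(-dt / cfg$tau_cal)
  spikes <- matrix(0L, n, n_steps)
  rates <- matrix(0, n, n_steps)
  trajR <- if (record_params) matrix(0, n, n_steps) else NULL
  trajT <- if (record_params) matrix(0, n, n_steps) else NULL
  trajV <- if (record_params && rule == "vth") matrix(0, n, n_steps) else NULL
  lamr <- if (cfg$kernel == "exp") exp(-dt / cfg$tau_syn) else 0
  for (t in seq_len(n_steps)) {
    rec_in <- drop(crossprod(net$W, spk_prev))
    if (cfg$kernel == "exp") {
      rec_syn <- rec_syn * lamr + rec_in * (1 - lamr) / dt
      x <- Iin[, t] + rec_syn
    } else {
      x <- Iin[, t] + rec_in
    }
    act <- refr <= 0
    drive <- R * x
    Vn <- if (cfg$integration == "exponential") {
      drive + (V - drive) * exp(-dt / tau)
    } else {
      V + dt * (-V + drive) / tau
    }
    V <- ifelse(act, Vn, 0)
    refr <- ifelse(act, refr, refr - dt)
    spk <- as.numeric(act & (V >= V_th))
    fired <- spk == 1
    V[fired] <- 0
    refr[fired] <- t_r
    C <- (C + spk) * dc
    y <- C / cfg$tau_cal
    spikes[, t] <- as.integer(spk)
    rates[, t] <- y
    if (rule == "spikl") {
      up <- spikl_update_vec(R, tau, y, net$params$V_th, t_r,
                             net$params$bounds_R, net$params$bounds_tau, ip)
      R <- up$R
      tau <- up$tau_m
    } else if (rule == "vth") {
      V_th <- voltage_threshold_ip_step(V_th, spk, vt)
    }
    if (record_params) {
      trajR[, t] <- R
      trajT[, t] <- tau
      if (!is.null(trajV)) trajV[, t] <- V_th
    }
    spk_prev <- spk
  }
  structure(list(spikes = spikes, rates = rates,
                 R = R, tau_m = tau, V_th = V_th,
                 traj_R = trajR, traj_tau = trajT, traj_V_th = trajV,
                 rule = rule, cfg = cfg, n_steps = n_steps),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("Network simulation: %d neurons x %d steps, rule = %s\n",
              nrow(x$rates), x$n_steps, x$rule))
  cat(sprintf("  total spikes: %d; mean rate estimate %.4g KHz\n",
              sum(x$spikes), mean(x$rates)))
  invisible(x)
}
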