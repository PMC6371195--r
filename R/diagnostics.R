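# Shared binning rule for the histogram-based estimators: 50 fixed-width bins
# spanning [0, max(sample max, 5 * mu)], so that the reference exponential
# retains at most e^-5 of its mass beyond the grid.
rate_bins <- function(s, mu, bins = 50) {
  hi <- max(max(s), 5 * mu)
  seq(0, hi, length.out = bins + 1)
}

bin_masses <- function(s, breaks) {
  bins <- length(breaks) - 1L
  idx <- findInterval(s, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, bins) / length(s)
}

#' Maximum-likelihood exponential fit to a firing-rate sample
#'
#' The MLE of the exponential mean is the sample mean.
#'
#' @param s numeric sample of firing rates (KHz), non-negative.
#' @return Fitted mean \code{mu_hat} (KHz).
#' @export
fit_exponential_mle <- function(s) {
  if (length(s) == 0) stop("empty sample")
  if (any(s < 0)) stop("negative rates in sample")
  mean(s)
}

#' Binned KL divergence from an empirical sample to an exponential reference
#'
#' Plug-in estimate of KL(empirical || Exp(mean mu)) in nats: empirical bin
#' masses (with additive smoothing 1e-12) against reference masses integrated
#' exactly per bin, on 50 fixed-width bins over [0, max(sample max, 5 mu)].
#' Non-negative up to estimator convention; approximately 0 for large
#' exponential samples at the true mean.
#'
#' @param s numeric sample of firing rates (KHz).
#' @param mu mean of the reference exponential (KHz), positive.
#' @param bins number of bins.
#' @return KL divergence estimate (nats).
#' @export
kl_to_exponential <- function(s, mu, bins = 50) {
  if (length(s) == 0) stop("empty sample")
  if (!is.numeric(mu) || mu <= 0) stop("mu must be positive")
  br <- rate_bins(s, mu, bins)
  p <- bin_masses(s, br) + 1e-12
  q <- stats::pexp(br[-1], rate = 1 / mu) -
    stats::pexp(br[-(bins + 1)], rate = 1 / mu)
  sum(p * log(p / q))
}

#' Binned differential-entropy estimate
#'
#' Histogram plug-in estimate of differential entropy (nats), with the same
#' binning rule as \code{\link{kl_to_exponential}} (reference scale
#' \code{mu} = the sample mean). For samples of equal mean, the exponential
#' attains the maximum.
#'
#' @param s numeric sample of firing rates (KHz).
#' @param bins number of bins.
#' @return Entropy estimate (nats).
#' @export
entropy_estimate <- function(s, bins = 50) {
  if (length(s) == 0) stop("empty sample")
  mu <- max(mean(s), .Machine$double.eps)
  br <- rate_bins(s, mu, bins)
  w <- diff(br)[1]
  p <- bin_masses(s, br)
  nz <- p > 0
  -sum(p[nz] * log(p[nz] / w))
}

#' Exponential-fit summary of a firing-rate sample
#'
#' Fits the exponential mean by maximum likelihood and reports the binned KL
#' divergence of the sample to the fitted exponential and the binned entropy
#' estimate. For a degenerate (all-zero) sample the KL is undefined and
#' reported as NA.
#'
#' @param s numeric sample of firing rates (KHz).
#' @param bins number of bins.
#' @return An object of class \code{"exp_fit"} with fields \code{mu_hat},
#'   \code{kl}, \code{entropy}, \code{n}.
#' @export
exp_fit <- function(s, bins = 50) {
  mu_hat <- fit_exponential_mle(s)
  kl <- if (mu_hat > 0) kl_to_exponential(s, mu_hat, bins) else NA_real_
  structure(list(mu_hat = mu_hat, kl = kl,
                 entropy = entropy_estimate(s, bins), n = length(s)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit to %d rate samples\n", x$n))
  cat(sprintf("  mu_hat  = %.4g KHz\n", x$mu_hat))
  cat(sprintf("  KL(emp || Exp(mu_hat)) = %.4g nats\n", x$kl))
  cat(sprintf("  entropy = %.4g nats\n", x$entropy))
  invisible(x)
}

#' Histogram table for figure-style comparison with an exponential fit
#'
#' @param s numeric sample of firing rates (KHz).
#' @param mu mean of the comparison exponential; defaults to the MLE fit.
#' @param bins number of bins.
#' @return data.frame with columns \code{bin_left_khz}, \code{bin_right_khz},
#'   \code{empirical_mass}, \code{exp_fit_mass}.
#' @export
rate_histogram <- function(s, mu = fit_exponential_mle(s), bins = 50) {
  br <- rate_bins(s, mu, bins)
  data.frame(bin_left_khz = br[-(bins + 1)],
             bin_right_khz = br[-1],
             empirical_mass = bin_masses(s, br),
             exp_fit_mass = stats::pexp(br[-1], 1 / mu) -
               stats::pexp(br[-(bins + 1)], 1 / mu))
}

#' Post-burn-in window of a recorded sample
#'
#' Diagnostics conventionally exclude the initial transient so that
#' convergence, not the transient, is measured. The default drops the first
#' 20\% of the recorded steps.
#'
#' @param s numeric vector of per-step records.
#' @param fraction fraction of initial steps to drop.
#' @return The trailing part of \code{s}.
#' @export
post_burn_in <- function(s, fraction = 0.2) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- length(s)
  s[(floor(n * fraction) + 1):n]
}
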