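## ---- numerically stable building blocks --------------------------------
##
## Everything tail-sensitive is computed from log-space normal primitives
## (dnorm(log = TRUE), pnorm(log.p = TRUE)), which remain accurate far
## beyond the range where Phi() itself underflows. Scanner intensities run
## up to 2^16 with background scales ~1e2, so standardized arguments of
## several hundred occur routinely.

# log(exp(a) - exp(b)) for a >= b, elementwise
.logdiffexp <- function(a, b) {
  d <- b - a
  out <- a + log1p(-exp(d))
  out[a == -Inf] <- -Inf
  out
}

# log(pnorm(b) - pnorm(a)) for a <= b, stable in either tail
.log_pnorm_diff <- function(a, b) {
  upper <- (a + b) > 0
  out <- numeric(length(a) * 0 + max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  if (any(upper)) {
    out[upper] <- .logdiffexp(
      pnorm(a[upper], lower.tail = FALSE, log.p = TRUE),
      pnorm(b[upper], lower.tail = FALSE, log.p = TRUE))
  }
  if (any(!upper)) {
    out[!upper] <- .logdiffexp(
      pnorm(b[!upper], log.p = TRUE),
      pnorm(a[!upper], log.p = TRUE))
  }
  out
}

# E[Z | alpha < Z < beta] for standard normal Z; stable in far tails.
.std_trunc_mean <- function(alpha, beta) {
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  out <- numeric(n)

  narrow <- is.finite(alpha) & is.finite(beta) & (beta - alpha) < 1e-8
  flip <- !narrow & (alpha + beta > 0)
  rest <- !narrow & !flip

  if (any(narrow)) out[narrow] <- (alpha[narrow] + beta[narrow]) / 2
  if (any(flip)) out[flip] <- -Recall(-beta[flip], -alpha[flip])
  if (any(rest)) {
    a <- alpha[rest]; b <- beta[rest]
    # here a + b <= 0 so phi(b) >= phi(a) and lower-tail masses are the
    # representable ones; offset is <= 0
    num <- .logdiffexp(dnorm(b, log = TRUE), dnorm(a, log = TRUE))
    den <- .log_pnorm_diff(a, b)
    out[rest] <- -exp(num - den)
  }
  out
}

# mean of N(m, sd^2) truncated to (lo, hi), clamped strictly inside
.trunc_normal_mean <- function(m, sd, lo, hi) {
  r <- m + sd * .std_trunc_mean((lo - m) / sd, (hi - m) / sd)
  eps <- pmax(1e-12, 1e-12 * abs(hi))
  pmin(pmax(r, lo + eps), ifelse(is.finite(hi), hi - eps, r))
}

## ---- model parameter containers ----------------------------------------

#' Zero-truncated normal parameters
#'
#' Location/scale pair for a normal distribution restricted to positive
#' values, used both for the background noise and for the normal component
#' of the true-signal mixture.
#'
#' @param mu Location, in intensity units; may be any real number.
#' @param sigma Scale, in intensity units; must be positive.
#' @return An object of class `trunc_normal_params`.
#' @export
trunc_normal_params <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(mu = mu, sigma = sigma), class = "trunc_normal_params")
}

#' True-signal mixture parameters
#'
#' The true signal is modeled as a two-component mixture: with probability
#' `p1` an exponential with rate `lam`, otherwise a zero-truncated normal.
#' The normal weight is derived as `1 - p1` and never stored.
#'
#' @param p1 Mixing weight of the exponential component, in `[0, 1]`.
#' @param lam Exponential rate (1 / intensity units), positive.
#' @param normal A [trunc_normal_params()] object holding (nu, tau).
#' @return An object of class `signal_mixture_params`.
#' @export
signal_mixture_params <- function(p1, lam, normal) {
  stopifnot(is.numeric(p1), length(p1) == 1L, p1 >= 0, p1 <= 1,
            is.numeric(lam), length(lam) == 1L, lam > 0,
            inherits(normal, "trunc_normal_params"))
  structure(list(p1 = p1, lam = lam, normal = normal),
            class = "signal_mixture_params")
}

#' Observed-intensity convolution model
#'
#' Houses every parameter of the observed-intensity model S = X + Y, where
#' X is the signal mixture and Y the zero-truncated normal background.
#'
#' @param signal A [signal_mixture_params()] object.
#' @param background A [trunc_normal_params()] object holding (mu, sigma).
#' @return An object of class `convolution_model`.
#' @export
convolution_model <- function(signal, background) {
  stopifnot(inherits(signal, "signal_mixture_params"),
            inherits(background, "trunc_normal_params"))
  structure(list(signal = signal, background = background),
            class = "convolution_model")
}

## ---- operations ---------------------------------------------------------

#' Mean of a zero-truncated normal distribution
#'
#' @param params A [trunc_normal_params()] object.
#' @return The expected value, strictly greater than `max(0, mu)`.
#' @export
truncnorm_mean <- function(params) {
  stopifnot(inherits(params, "trunc_normal_params"))
  with(params, mu + sigma * .std_trunc_mean(-mu / sigma, Inf))
}

# per-component log convolution densities, vectorized over s
.log_f_exp_conv <- function(s, lam, mu, sigma) {
  # Exp(lam) * truncN(mu, sigma^2): closed form via a completed square
  log(lam) + lam * mu + lam^2 * sigma^2 / 2 - lam * s +
    .log_pnorm_diff((-mu - lam * sigma^2) / sigma,
                    (s - mu - lam * sigma^2) / sigma) -
    pnorm(mu / sigma, log.p = TRUE)
}

.log_f_norm_conv <- function(s, nu, tau, mu, sigma) {
  v <- 1 / (1 / tau^2 + 1 / sigma^2)
  m <- v * (nu / tau^2 + (s - mu) / sigma^2)
  sv <- sqrt(v)
  dnorm(s, nu + mu, sqrt(tau^2 + sigma^2), log = TRUE) +
    .log_pnorm_diff((0 - m) / sv, (s - m) / sv) -
    pnorm(nu / tau, log.p = TRUE) - pnorm(mu / sigma, log.p = TRUE)
}

.model_logparts <- function(s, model) {
  sg <- model$signal; bg <- model$background
  le <- if (sg$p1 > 0)
    log(sg$p1) + .log_f_exp_conv(s, sg$lam, bg$mu, bg$sigma)
  else rep(-Inf, length(s))
  ln <- if (sg$p1 < 1)
    log(1 - sg$p1) + .log_f_norm_conv(s, sg$normal$mu, sg$normal$sigma,
                                      bg$mu, bg$sigma)
  else rep(-Inf, length(s))
  list(le = le, ln = ln)
}

#' Density of the observed intensity S = X + Y
#'
#' Evaluates the convolution density of signal plus background in closed
#' form (normal-kernel integrals expressed through differences of normal
#' CDFs, evaluated in log space).
#'
#' @param s Observed intensities, strictly positive.
#' @param model A [convolution_model()] object.
#' @param log If `TRUE`, return the log density.
#' @return Density values (or log densities), same length as `s`.
#' @export
observed_density <- function(s, model, log = FALSE) {
  stopifnot(inherits(model, "convolution_model"), is.numeric(s))
  if (any(s <= 0)) stop("observed intensity s must be > 0")
  p <- .model_logparts(s, model)
  hi <- pmax(p$le, p$ln)
  lo <- pmin(p$le, p$ln)
  lf <- ifelse(hi == -Inf, -Inf, hi + log1p(exp(lo - hi)))
  if (log) lf else exp(lf)
}

#' Posterior probability of the exponential signal component
#'
#' Probability, given an observed intensity `s`, that the underlying true
#' signal was drawn from the exponential mixture component. Computed in log
#' space; never NaN.
#'
#' @inheritParams observed_density
#' @return Probabilities in `[0, 1]`, same length as `s`.
#' @export
component_posterior <- function(s, model) {
  stopifnot(inherits(model, "convolution_model"))
  if (any(s <= 0)) stop("observed intensity s must be > 0")
  p <- .model_logparts(s, model)
  w <- plogis(p$le - p$ln)
  w[p$le == -Inf] <- 0
  w[p$ln == -Inf & p$le > -Inf] <- 1
  w
}

#' Background-corrected intensity E(X | S = s)
#'
#' The expected true signal given the observed intensity, under the
#' exponential + truncated-normal signal mixture with truncated-normal
#' background. Because both X and Y are positive, X is confined to (0, s);
#' each mixture component's conditional law is a normal restricted to that
#' interval (location `s - mu - sigma^2 * lam` for the exponential
#' component; the precision-weighted combination of signal-normal and
#' background information for the normal component), and the correction is
#' their posterior-weighted mean.
#'
#' @inheritParams observed_density
#' @return Corrected intensities, strictly inside `(0, s)`, finite for all
#'   `s` up to the scanner ceiling of 2^16.
#' @export
conditional_signal_mean <- function(s, model) {
  stopifnot(inherits(model, "convolution_model"))
  if (any(s <= 0)) stop("observed intensity s must be > 0")
  sg <- model$signal; bg <- model$background
  w <- component_posterior(s, model)
  e_exp <- .trunc_normal_mean(s - bg$mu - bg$sigma^2 * sg$lam, bg$sigma, 0, s)
  nu <- sg$normal$mu; tau <- sg$normal$sigma
  v <- 1 / (1 / tau^2 + 1 / bg$sigma^2)
  m <- v * (nu / tau^2 + (s - bg$mu) / bg$sigma^2)
  e_norm <- .trunc_normal_mean(m, sqrt(v), 0, s)
  w * e_exp + (1 - w) * e_norm
}
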