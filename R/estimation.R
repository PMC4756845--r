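## Background parameter estimation (three routes) and signal-mixture EM.

#' Background parameter container
#'
#' @param mu,sigma Truncated-normal background location/scale.
#' @param channel `"red"` or `"green"`.
#' @param probe_class `"typeI"`, `"typeII"` or `"both"`; only the joint
#'   intensity route estimates class-specific backgrounds.
#' @param method Estimation route: `"neg"`, `"oob"` or `"est"`.
#' @return An object of class `background_params`.
#' @export
background_params <- function(mu, sigma, channel = c("red", "green"),
                              probe_class = c("both", "typeI", "typeII"),
                              method = c("neg", "oob", "est")) {
  channel <- match.arg(channel)
  probe_class <- match.arg(probe_class)
  method <- match.arg(method)
  if (sigma <= 0) stop("sigma must be > 0")
  if (probe_class != "both" && method != "est")
    stop("class-specific backgrounds are only produced by method 'est'")
  structure(list(mu = mu, sigma = sigma, channel = channel,
                 probe_class = probe_class, method = method),
            class = "background_params")
}

# quantiles of N+(mu, sigma^2) (left-truncated at 0)
.truncnorm_quantile <- function(p, mu, sigma) {
  p0 <- pnorm(-mu / sigma)
  mu + sigma * qnorm(p0 + p * (1 - p0))
}

# Robust (mu, sigma) from a sample treated as zero-truncated normal:
# median/MAD start, then one quantile-matching refinement that undoes the
# bias truncation induces on the raw order statistics.
.robust_truncnorm_fit <- function(x, min_n = 20L) {
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    stop(sprintf("need at least %d values for a stable background estimate, got %d",
                 min_n, length(x)))
  if (any(x < 0)) stop("background intensities must be non-negative")
  mu0 <- median(x)
  sig0 <- mad(x)            # 1.4826 * MAD
  obs_scale <- IQR(x) / 1.349
  if (sig0 <= 0) sig0 <- obs_scale   # MAD degenerates on coarse/tied values
  if (sig0 <= 0 || obs_scale <= 0) stop("zero scale: input values are (nearly) constant")
  med_t <- .truncnorm_quantile(0.5, mu0, sig0)
  scale_t <- (.truncnorm_quantile(0.75, mu0, sig0) -
              .truncnorm_quantile(0.25, mu0, sig0)) / 1.349
  mu1 <- mu0 + (mu0 - med_t)
  sig1 <- max(sig0 * obs_scale / scale_t, 1.0)
  list(mu = mu1, sigma = sig1, n = length(x))
}

#' Estimate background from negative control probes
#'
#' Robust location/scale of the per-channel negative-control intensities
#' (median / scaled MAD with one truncation-aware refinement), interpreted
#' as a zero-truncated normal sample. At least 20 values are required; the
#' 450K design provides 613 per channel.
#'
#' @param values Non-negative control intensities for one channel.
#' @param channel `"red"` or `"green"`.
#' @return A [background_params()] object with `method = "neg"`.
#' @export
estimate_background_neg <- function(values, channel = c("red", "green")) {
  channel <- match.arg(channel)
  fit <- .robust_truncnorm_fit(values, min_n = 20L)
  background_params(fit$mu, fit$sigma, channel, "both", "neg")
}

#' Estimate background from out-of-band intensities
#'
#' Same robust estimator as [estimate_background_neg()], applied to the
#' much larger sample of out-of-band Infinium I intensities. The green
#' channel background uses the out-of-band readings of red-assigned type I
#' probes and vice versa (the out-of-band measurement is taken on the
#' channel the probe is not assigned to).
#'
#' @inheritParams estimate_background_neg
#' @return A [background_params()] object with `method = "oob"`.
#' @export
estimate_background_oob <- function(values, channel = c("red", "green")) {
  channel <- match.arg(channel)
  if (length(values) == 0L) stop("no out-of-band values supplied")
  fit <- .robust_truncnorm_fit(values, min_n = 20L)
  background_params(fit$mu, fit$sigma, channel, "both", "oob")
}

## ---- EM machinery -------------------------------------------------------

.em_init_signal <- function(x, background = NULL) {
  med <- median(x)
  lam <- 1 / med
  nu <- unname(quantile(x, 0.75))
  tau <- mad(x[x > med])
  if (!is.finite(tau) || tau <= 0) tau <- max(sd(x), 1)
  if (!is.null(background)) {
    lam <- 1 / max(med - background$mu, med / 4)
    nu <- max(nu - background$mu, background$mu + 2 * background$sigma)
  }
  list(p1 = 0.5, lam = lam, nu = nu, tau = tau)
}

# expected complete-data log-likelihood pieces
.q_exp <- function(x, w, lam, mu, sigma) sum(w * .log_f_exp_conv(x, lam, mu, sigma))
.q_norm <- function(x, w, nu, tau, mu, sigma) sum(w * .log_f_norm_conv(x, nu, tau, mu, sigma))

.obs_loglik <- function(x, model) sum(observed_density(x, model, log = TRUE))

.mk_model <- function(p1, lam, nu, tau, mu, sigma)
  convolution_model(signal_mixture_params(p1, lam, trunc_normal_params(nu, tau)),
                    trunc_normal_params(mu, sigma))

.subsample <- function(x, n_max, seed) {
  if (length(x) <= n_max) return(x)
  if (is.null(seed)) seed <- 1L
  withr::with_seed(as.integer(seed), sample(x, n_max))
}

#' Fit the true-signal mixture by EM with a fixed background
#'
#' E-step: posterior component weights via [component_posterior()].
#' M-step: the exponential weight `p1` in closed form; the exponential rate
#' and the truncated-normal (nu, tau) by warm-started numerical
#' maximization of the expected complete-data log-likelihood (a generalized
#' M-step accepted only when it improves its objective, preserving EM
#' monotonicity). Iterates until the relative observed-data log-likelihood
#' change drops below `tol`.
#'
#' @param x Observed intensities for one intensity part, `n >= 1000`.
#' @param background A [background_params()] (or `trunc_normal_params`)
#'   object fixing (mu, sigma).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param subsample_n Fits subsample to at most this many points.
#' @param subsample_seed Seed for the subsampling draw.
#' @return A list with `params` ([signal_mixture_params()]) and
#'   `diagnostics` (log-likelihood trace, iteration count, convergence and
#'   boundary flags, number of points used).
#' @export
fit_signal_mixture <- function(x, background, tol = 1e-6, max_iter = 1000L,
                               subsample_n = 50000L, subsample_seed = NULL) {
  if (length(x) < 1000L)
    stop(sprintf("need at least 1000 intensities to fit the signal mixture, got %d",
                 length(x)))
  if (any(!is.finite(x)) || any(x <= 0)) stop("intensities must be finite and > 0")
  if (sd(x) == 0) stop("zero variance: cannot fit a signal mixture to constant intensities")
  mu <- background$mu; sigma <- background$sigma
  x <- .subsample(x, subsample_n, subsample_seed)
  th <- .em_init_signal(x, background)
  p1 <- th$p1; lam <- th$lam; nu <- th$nu; tau <- th$tau
  clamped <- FALSE
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    model <- .mk_model(p1, lam, nu, tau, mu, sigma)
    w <- component_posterior(x, model)
    p1 <- mean(w)
    if (p1 < 1e-4 || p1 > 1 - 1e-4) {
      p1 <- min(max(p1, 1e-4), 1 - 1e-4)
      clamped <- TRUE
    }
    # rate update: 1-D maximization on log scale around the current value
    if (sum(w) > 1e-8) {
      f_lam <- function(ll) .q_exp(x, w, exp(ll), mu, sigma)
      opt <- optimize(f_lam, interval = log(lam) + c(-1.5, 1.5), maximum = TRUE)
      if (opt$objective >= f_lam(log(lam))) lam <- exp(opt$maximum)
    }
    # (nu, tau) update: warm-started Nelder-Mead on (nu, log tau)
    if (sum(1 - w) > 1e-8) {
      f_nt <- function(p) -.q_norm(x, 1 - w, p[1], exp(p[2]), mu, sigma)
      cur <- c(nu, log(tau))
      opt <- try(optim(cur, f_nt, method = "Nelder-Mead",
                       control = list(maxit = 60L)), silent = TRUE)
      if (!inherits(opt, "try-error") && opt$value <= f_nt(cur)) {
        nu <- opt$par[1]; tau <- exp(opt$par[2])
      }
    }
    ll <- .obs_loglik(x, .mk_model(p1, lam, nu, tau, mu, sigma))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-8)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # Degenerate mixtures sit on the boundary of the parameter space, where
  # EM from an interior start can stall at a local optimum with a spurious
  # second component; compare against both single-component fits and keep
  # the likelihood winner.
  ll_cur <- trace[length(trace)]
  opt_hi <- optimize(function(ll_)
    .obs_loglik(x, .mk_model(1 - 1e-4, exp(ll_), nu, tau, mu, sigma)),
    interval = log(lam) + c(-1.5, 1.5), maximum = TRUE)
  if (opt_hi$objective > ll_cur) {
    p1 <- 1 - 1e-4; lam <- exp(opt_hi$maximum)
    ll_cur <- opt_hi$objective; trace <- c(trace, ll_cur); clamped <- TRUE
  }
  opt_lo <- try(optim(c(nu, log(tau)), function(p)
    -.obs_loglik(x, .mk_model(1e-4, lam, p[1], exp(p[2]), mu, sigma)),
    method = "Nelder-Mead", control = list(maxit = 80L)), silent = TRUE)
  if (!inherits(opt_lo, "try-error") && -opt_lo$value > ll_cur) {
    p1 <- 1e-4; nu <- opt_lo$par[1]; tau <- exp(opt_lo$par[2])
    trace <- c(trace, -opt_lo$value); clamped <- TRUE
  }
  list(
    params = signal_mixture_params(p1, lam, trunc_normal_params(nu, tau)),
    diagnostics = list(loglik = trace, n_iter = length(trace),
                       converged = converged, clamped = clamped,
                       n_points = length(x))
  )
}

#' Estimate background jointly from combined M and U intensities
#'
#' Full maximum-likelihood fit of the convolution model with the background
#' (mu, sigma) free alongside the signal parameters, via the EM scheme of
#' [fit_signal_mixture()] extended with background parameters in the
#' M-step. During optimization the signal-normal location is constrained to
#' `nu >= mu + 2 * sigma`, which prevents the signal-normal and background
#' components from swapping roles. Unlike the control-probe routes, this
#' route is run separately per probe class, so the returned parameters are
#' tagged with the supplied class.
#'
#' @param x Pooled M and U intensities for one probe class x channel part,
#'   `n >= 5000`.
#' @param channel `"red"` or `"green"`.
#' @param probe_class `"typeI"` or `"typeII"`.
#' @inheritParams fit_signal_mixture
#' @return A list with `background` ([background_params()],
#'   `method = "est"`), `signal` ([signal_mixture_params()]) and
#'   `diagnostics` as in [fit_signal_mixture()] (plus `converged = FALSE`
#'   best-so-far results when the iteration cap is hit).
#' @export
estimate_background_est <- function(x, channel = c("red", "green"),
                                    probe_class = c("typeI", "typeII"),
                                    tol = 1e-5, max_iter = 100L,
                                    subsample_n = 50000L, subsample_seed = NULL) {
  channel <- match.arg(channel)
  probe_class <- match.arg(probe_class)
  if (length(x) < 5000L)
    stop(sprintf("joint background estimation needs n >= 5000, got %d", length(x)))
  if (any(!is.finite(x)) || any(x <= 0)) stop("intensities must be finite and > 0")
  x <- .subsample(x, subsample_n, subsample_seed)

  # initial background from the low tail, signal from the bulk
  mu <- unname(quantile(x, 0.02))
  low <- x[x <= quantile(x, 0.1)]
  sigma <- max(mad(low), mu / 5, 1)
  th <- .em_init_signal(x, list(mu = mu, sigma = sigma))
  p1 <- th$p1; lam <- th$lam; nu <- max(th$nu, mu + 2 * sigma + 1); tau <- th$tau

  clamped <- FALSE
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    model <- .mk_model(p1, lam, nu, tau, mu, sigma)
    w <- component_posterior(x, model)
    p1 <- mean(w)
    if (p1 < 1e-4 || p1 > 1 - 1e-4) {
      p1 <- min(max(p1, 1e-4), 1 - 1e-4)
      clamped <- TRUE
    }
    # M-step by conditional maximizations (ECM), each warm-started and
    # accepted only on improvement; the guard nu >= mu + 2*sigma keeps the
    # signal-normal and background components from swapping roles
    f_lam <- function(ll) .q_exp(x, w, exp(ll), mu, sigma)
    opt <- optimize(f_lam, interval = log(lam) + c(-1, 1), maximum = TRUE)
    if (opt$objective >= f_lam(log(lam))) lam <- exp(opt$maximum)

    f_nt <- function(p) {
      nu_ <- p[1]; tau_ <- exp(p[2])
      if (nu_ < mu + 2 * sigma) return(1e12)
      -.q_norm(x, 1 - w, nu_, tau_, mu, sigma)
    }
    cur <- c(nu, log(tau))
    opt <- try(optim(cur, f_nt, method = "Nelder-Mead",
                     control = list(maxit = 40L)), silent = TRUE)
    if (!inherits(opt, "try-error") && opt$value <= f_nt(cur)) {
      nu <- opt$par[1]; tau <- exp(opt$par[2])
    }

    f_bg <- function(p) {
      mu_ <- exp(p[1]); sigma_ <- exp(p[2])
      if (nu < mu_ + 2 * sigma_) return(1e12)
      -(.q_exp(x, w, lam, mu_, sigma_) + .q_norm(x, 1 - w, nu, tau, mu_, sigma_))
    }
    cur <- c(log(mu), log(sigma))
    opt <- try(optim(cur, f_bg, method = "Nelder-Mead",
                     control = list(maxit = 40L)), silent = TRUE)
    if (!inherits(opt, "try-error") && opt$value <= f_bg(cur)) {
      mu <- exp(opt$par[1]); sigma <- exp(opt$par[2])
    }
    ll <- .obs_loglik(x, .mk_model(p1, lam, nu, tau, mu, sigma))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-8)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final polish: joint maximization of the observed-data log-likelihood
  # from the EM solution (the conditional updates approach ridge points in
  # the correlated (lam, mu, sigma) directions only slowly)
  obj <- function(p) {
    p1_ <- plogis(p[1]); mu_ <- exp(p[5]); sigma_ <- exp(p[6])
    nu_ <- mu_ + 2 * sigma_ + exp(p[3])
    -.obs_loglik(x, .mk_model(p1_, exp(p[2]), nu_, exp(p[4]), mu_, sigma_))
  }
  cur <- c(qlogis(p1), log(lam), log(max(nu - mu - 2 * sigma, 1e-3)),
           log(tau), log(mu), log(sigma))
  opt <- try(optim(cur, obj, method = "Nelder-Mead",
                   control = list(maxit = 400L)), silent = TRUE)
  if (!inherits(opt, "try-error") && opt$value <= obj(cur)) {
    p <- opt$par
    p1 <- plogis(p[1]); lam <- exp(p[2]); mu <- exp(p[5]); sigma <- exp(p[6])
    nu <- mu + 2 * sigma + exp(p[3]); tau <- exp(p[4])
    trace <- c(trace, -opt$value)
  }
  list(
    background = background_params(mu, sigma, channel, probe_class, "est"),
    signal = signal_mixture_params(p1, lam, trunc_normal_params(nu, tau)),
    diagnostics = list(loglik = trace, n_iter = length(trace),
                       converged = converged, clamped = clamped,
                       n_points = length(x))
  )
}
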