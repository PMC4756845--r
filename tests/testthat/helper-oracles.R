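# Quadrature oracle for the convolution model, written directly from the
# component densities (dexp / dnorm), independent of the package's
# closed-form algebra. Adaptive quadrature at tolerances ~4 orders tighter
# than any assertion made against it.

make_model <- function(p1, lam, nu, tau, mu, sigma) {
  convolution_model(signal_mixture_params(p1, lam, trunc_normal_params(nu, tau)),
                    trunc_normal_params(mu, sigma))
}

# log mixture density of the true signal, from first principles
.oracle_log_fx <- function(x, model) {
  sg <- model$signal
  le <- if (sg$p1 > 0) log(sg$p1) + dexp(x, sg$lam, log = TRUE) else -Inf
  ln <- if (sg$p1 < 1)
    log(1 - sg$p1) + dnorm(x, sg$normal$mu, sg$normal$sigma, log = TRUE) -
      pnorm(sg$normal$mu / sg$normal$sigma, log.p = TRUE)
  else -Inf
  le <- ifelse(x > 0, le, -Inf); ln <- ifelse(x > 0, ln, -Inf)
  hi <- pmax(le, ln); lo <- pmin(le, ln)
  ifelse(hi == -Inf, -Inf, hi + log1p(exp(lo - hi)))
}

.oracle_log_fy <- function(y, model) {
  bg <- model$background
  ifelse(y > 0,
         dnorm(y, bg$mu, bg$sigma, log = TRUE) - pnorm(bg$mu / bg$sigma, log.p = TRUE),
         -Inf)
}

# E(X | S = s) and log f_S(s) by adaptive quadrature over (0, s), with the
# integrand rescaled by its maximum so far-tail cases stay representable.
# The integrand can be a near-delta spike (tiny sigma or tau), so the
# integration is split at the component peaks and the rescaling maximum is
# searched on a grid refined around them.
oracle_conditional <- function(s, model) {
  li <- function(x) .oracle_log_fx(x, model) + .oracle_log_fy(s - x, model)
  bg <- model$background; nrm <- model$signal$normal
  clip <- function(v) pmin(pmax(v, s * 1e-12), s * (1 - 1e-12))
  anchors <- c(seq(s * 1e-9, s * (1 - 1e-9), length.out = 2001),
               clip(s - (bg$mu + bg$sigma * seq(-50, 50, length.out = 401))),
               clip(nrm$mu + nrm$sigma * seq(-50, 50, length.out = 401)))
  m0 <- max(li(unique(anchors)))
  breaks <- sort(unique(c(0, s,
                          clip(c(s - bg$mu - 50 * bg$sigma,
                                 s - bg$mu + 50 * bg$sigma,
                                 nrm$mu - 50 * nrm$sigma,
                                 nrm$mu + 50 * nrm$sigma)))))
  piece <- function(f) {
    tot <- 0
    for (i in seq_len(length(breaks) - 1L)) {
      if (breaks[i + 1L] - breaks[i] < s * 1e-14) next
      tot <- tot + integrate(f, breaks[i], breaks[i + 1L],
                             rel.tol = 1e-10, abs.tol = 1e-13,
                             subdivisions = 1000L)$value
    }
    tot
  }
  f0 <- piece(function(x) exp(li(x) - m0))
  f1 <- piece(function(x) x * exp(li(x) - m0))
  list(cond_mean = f1 / f0, log_density = m0 + log(f0))
}

# one component's convolution density by quadrature (for posterior checks)
oracle_component_log_density <- function(s, model, component = c("exp", "norm")) {
  component <- match.arg(component)
  sub <- if (component == "exp")
    make_model(1, model$signal$lam, model$signal$normal$mu,
               model$signal$normal$sigma, model$background$mu,
               model$background$sigma)
  else
    make_model(0, model$signal$lam, model$signal$normal$mu,
               model$signal$normal$sigma, model$background$mu,
               model$background$sigma)
  oracle_conditional(s, sub)$log_density
}

# deterministic grid of random-but-seeded realistic models
random_models <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      make_model(p1 = runif(1, 0.05, 0.95),
                 lam = 1 / runif(1, 1e3, 1e4),
                 nu = runif(1, 3e3, 2e4),
                 tau = runif(1, 500, 5000),
                 mu = runif(1, 200, 1500),
                 sigma = runif(1, 30, 300)))
  })
}
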