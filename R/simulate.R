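## Generative simulator: arrays with known ground truth under the
## signal-plus-background convolution model, plus duplicate-pair and
## titration designs.

# draws from N(mu, sigma^2) truncated to (0, Inf), inverse-CDF method
.rtruncnorm <- function(n, mu, sigma) {
  lo <- pnorm(-mu / sigma)
  mu + sigma * qnorm(runif(n, lo, 1))
}

#' Simulation specification
#'
#' Defines the generative conditions for a synthetic methylation array:
#' probe composition, true-signal mixture, channel backgrounds (with the
#' type II background elevated by a multiplier, as seen in real chemistry),
#' dye imbalance, technical duplicate noise and the titration design.
#' Defaults emulate typical scanner output magnitudes; the seed is
#' mandatory so every emitted dataset is reproducible.
#'
#' @param n_probes Number of CpG probes.
#' @param fraction_typeI Fraction of probes on the type I design (0.28 on
#'   the 450K array).
#' @param n_samples Number of samples for [simulate_array()].
#' @param lam Exponential rate of the low-signal mixture component.
#' @param nu,tau Location/scale of the truncated-normal high-signal
#'   component.
#' @param p_hypo Probability a CpG is hypomethylated (methylated allele on
#'   the exponential component, unmethylated on the normal component;
#'   hypermethylated CpGs are the reverse).
#' @param bg_red_mu,bg_red_sigma,bg_green_mu,bg_green_sigma Per-channel
#'   type I background parameters.
#' @param typeII_background_multiplier Factor applied to the background
#'   location for type II probes (default 1.5).
#' @param dye_imbalance Multiplicative factor applied to all red-channel
#'   measurements (1 = balanced dyes).
#' @param duplicate_noise Log-scale SD of the multiplicative technical
#'   noise between duplicate pair members.
#' @param bio_noise Log-scale SD of the person-to-person signal variation
#'   around the per-CpG population template in the duplicate design;
#'   kept modest because methylation at a given CpG varies little between
#'   individuals in blood.
#' @param bg_level_noise Log-scale SD of the per-array, per-channel
#'   background level factor. Arrays processed independently (bisulfite
#'   conversion, hybridization, scanning) differ in overall background
#'   brightness; the factor multiplies every background-sourced value on
#'   the array (probe backgrounds, out-of-band readings, negative
#'   controls), which is exactly the variation per-sample background
#'   estimation is meant to capture.
#' @param titration_levels,titration_replicates Expected methylation
#'   levels of the laboratory standards and replicate counts per level
#'   (defaults: 0/5/10/20/40/50/60/80/100% with 10,3,2,3,3,2,3,3,10
#'   replicates, 39 samples in all).
#' @param nonpoly_mu,nonpoly_sigma High-intensity distribution of the
#'   non-polymorphic (dye-monitoring) control probes.
#' @param n_neg_controls,n_nonpoly_controls Control probe counts per
#'   sample (613 and 186 on the 450K array).
#' @param round_intensities Round emitted intensities to the scanner's
#'   integer grid (off by default so model-based checks stay exact).
#' @param seed Integer RNG seed (mandatory).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_probes = 10000L, fraction_typeI = 0.28,
                            n_samples = 2L,
                            lam = 1 / 3000, nu = 9000, tau = 2000,
                            p_hypo = 0.5,
                            bg_red_mu = 1000, bg_red_sigma = 150,
                            bg_green_mu = 1200, bg_green_sigma = 180,
                            typeII_background_multiplier = 1.5,
                            dye_imbalance = 1.0,
                            duplicate_noise = 0.05,
                            bio_noise = 0.2,
                            bg_level_noise = 0.3,
                            titration_levels = c(0, .05, .1, .2, .4, .5, .6, .8, 1),
                            titration_replicates = c(10, 3, 2, 3, 3, 2, 3, 3, 10),
                            nonpoly_mu = 20000, nonpoly_sigma = 2000,
                            n_neg_controls = 613L, n_nonpoly_controls = 186L,
                            round_intensities = FALSE,
                            seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory")
  if (fraction_typeI <= 0 || fraction_typeI >= 1)
    stop("fraction_typeI must be in (0, 1)")
  stopifnot(lam > 0, tau > 0, bg_red_sigma > 0, bg_green_sigma > 0,
            p_hypo >= 0, p_hypo <= 1, dye_imbalance > 0,
            all(titration_levels >= 0 & titration_levels <= 1),
            length(titration_levels) == length(titration_replicates))
  structure(as.list(environment()), class = "simulation_spec")
}

# manifest with deterministic type/channel assignment
.sim_manifest <- function(spec) {
  n <- spec$n_probes
  n1 <- round(n * spec$fraction_typeI)
  ids <- sprintf("cg%07d", seq_len(n))
  design <- rep(c("I", "II"), c(n1, n - n1))
  channel <- rep(NA_character_, n)
  channel[seq_len(n1)] <- rep_len(c("red", "green"), n1)
  probe_manifest(ids, design, channel)
}

# per-measurement background parameters implied by the spec
.sim_background <- function(spec, channel, probe_class) {
  mu <- if (channel == "red") spec$bg_red_mu else spec$bg_green_mu
  sigma <- if (channel == "red") spec$bg_red_sigma else spec$bg_green_sigma
  if (probe_class == "typeII") mu <- mu * spec$typeII_background_multiplier
  c(mu = mu, sigma = sigma)
}

.sim_channels <- function(manifest) {
  list(M = ifelse(manifest$design_type == "II", "green", manifest$channel),
       U = ifelse(manifest$design_type == "II", "red", manifest$channel))
}

# controls table for one set of samples; bgf = per-sample x channel
# background level factors (background-sourced values only; the
# non-polymorphic target readings are signal and stay unscaled)
.sim_controls <- function(spec, samples, bgf) {
  fr <- spec$dye_imbalance
  bgR <- .sim_background(spec, "red", "typeI")
  bgG <- .sim_background(spec, "green", "typeI")
  out <- lapply(samples, function(s) {
    nn <- spec$n_neg_controls
    np <- spec$n_nonpoly_controls
    np_r <- ceiling(np / 2); np_g <- np - np_r
    fR <- bgf[s, "red"]; fG <- bgf[s, "green"]
    data.frame(
      sample_id = s,
      control_type = c(rep("negative", nn),
                       rep("nonpolymorphic_red", np_r),
                       rep("nonpolymorphic_green", np_g)),
      red = c(.rtruncnorm(nn, bgR["mu"], bgR["sigma"]) * fR,
              .rtruncnorm(np_r, spec$nonpoly_mu, spec$nonpoly_sigma),
              .rtruncnorm(np_g, bgR["mu"], bgR["sigma"]) * fR) * fr,
      green = c(.rtruncnorm(nn, bgG["mu"], bgG["sigma"]) * fG,
                .rtruncnorm(np_r, bgG["mu"], bgG["sigma"]) * fG,
                .rtruncnorm(np_g, spec$nonpoly_mu, spec$nonpoly_sigma)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# assemble an intensity_set + ground truth from true signal matrices
# (X given pre-dye); backgrounds, oob and controls drawn here
.sim_assemble <- function(spec, manifest, X_M, X_U, samples) {
  ch <- .sim_channels(manifest)
  n <- spec$n_probes
  dye <- function(channel) ifelse(channel == "red", spec$dye_imbalance, 1)
  beta_true <- compute_beta(X_M, X_U)

  # per-array, per-channel background level factors
  bgf <- matrix(exp(rnorm(2 * length(samples), 0, spec$bg_level_noise)),
                length(samples), 2,
                dimnames = list(samples, c("red", "green")))

  draw_bg <- function(channels, class_vec) {
    out <- matrix(0, length(samples), n)
    for (chn in c("red", "green")) for (cl in c("typeI", "typeII")) {
      idx <- which(channels == chn & class_vec == cl)
      if (!length(idx)) next
      bg <- .sim_background(spec, chn, cl)
      out[, idx] <- .rtruncnorm(length(samples) * length(idx),
                                bg["mu"], bg["sigma"]) * bgf[, chn]
    }
    out
  }
  class_vec <- ifelse(manifest$design_type == "II", "typeII", "typeI")
  Y_M <- draw_bg(ch$M, class_vec)
  Y_U <- draw_bg(ch$U, class_vec)

  fM <- matrix(dye(ch$M), length(samples), n, byrow = TRUE)
  fU <- matrix(dye(ch$U), length(samples), n, byrow = TRUE)
  X_Me <- X_M * fM; X_Ue <- X_U * fU
  Y_Me <- Y_M * fM; Y_Ue <- Y_U * fU
  S_M <- X_Me + Y_Me; S_U <- X_Ue + Y_Ue
  if (spec$round_intensities) {
    S_M <- round(S_M); S_U <- round(S_U)
    X_Me <- S_M - Y_Me; X_Ue <- S_U - Y_Ue
  }
  dimnames(S_M) <- dimnames(S_U) <- list(samples, manifest$probe_id)
  dimnames(X_Me) <- dimnames(X_Ue) <- dimnames(S_M)
  dimnames(Y_Me) <- dimnames(Y_Ue) <- dimnames(S_M)
  dimnames(beta_true) <- dimnames(S_M)

  # out-of-band: type I probes read on the opposite channel (pure background)
  typeI <- manifest$probe_id[manifest$design_type == "I"]
  opp <- ifelse(manifest$channel[match(typeI, manifest$probe_id)] == "red",
                "green", "red")
  oob_draw <- function() {
    out <- matrix(0, length(samples), length(typeI),
                  dimnames = list(samples, typeI))
    for (chn in c("red", "green")) {
      idx <- which(opp == chn)
      if (!length(idx)) next
      bg <- .sim_background(spec, chn, "typeI")
      out[, idx] <- .rtruncnorm(length(samples) * length(idx),
                                bg["mu"], bg["sigma"]) * bgf[, chn] * dye(chn)
    }
    out
  }
  controls <- .sim_controls(spec, samples, bgf)
  x <- intensity_set(S_M, S_U, manifest, oob_M = oob_draw(), oob_U = oob_draw(),
                     controls = controls)
  truth <- structure(list(X_M = X_Me, X_U = X_Ue, Y_M = Y_Me, Y_U = Y_Ue,
                          beta_true = beta_true, bg_level_factors = bgf,
                          spec = spec),
                     class = "ground_truth")
  list(x = x, truth = truth)
}

# true signal draw for one allele matrix: exponential where `expo` is TRUE,
# truncated normal elsewhere
.sim_signal <- function(spec, expo, n_samples) {
  n <- length(expo)
  out <- matrix(0, n_samples, n)
  ne <- sum(expo)
  if (ne) out[, expo] <- rexp(n_samples * ne, spec$lam)
  if (n - ne) out[, !expo] <- .rtruncnorm(n_samples * (n - ne), spec$nu, spec$tau)
  out
}

#' Simulate a methylation array with ground truth
#'
#' Each CpG is assigned a true methylation state (hypo/hyper, shared across
#' samples); the methylated-allele signal is exponential for hypomethylated
#' CpGs and truncated-normal for hypermethylated CpGs, with the
#' unmethylated allele the reverse — yielding the characteristic bimodal
#' beta distribution. Backgrounds, out-of-band intensities and control
#' probes are drawn from the configured channel/class background
#' distributions, and the emitted observation satisfies S = X + Y exactly.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `x` (an [intensity_set()]), `truth` (signal and
#'   background components, true betas, the spec) and `manifest`.
#' @export
simulate_array <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(as.integer(spec$seed), {
    manifest <- .sim_manifest(spec)
    samples <- sprintf("sample%02d", seq_len(spec$n_samples))
    hypo <- runif(spec$n_probes) < spec$p_hypo
    X_M <- .sim_signal(spec, hypo, spec$n_samples)
    X_U <- .sim_signal(spec, !hypo, spec$n_samples)
    out <- .sim_assemble(spec, manifest, X_M, X_U, samples)
    out$truth$hypo <- hypo
    out$manifest <- manifest
    out
  })
}

#' Simulate technical duplicate pairs
#'
#' Every CpG carries a population template signal (exponential or
#' truncated-normal by its methylation state, shared by all samples); each
#' pair's true signal is the template times a lognormal person-level
#' factor (scale `spec$bio_noise`, small, as between-person methylation
#' variation in blood is small), and pair members share that signal up to
#' multiplicative lognormal technical noise (scale
#' `spec$duplicate_noise`). Background draws, out-of-band readings and
#' controls are independent between members, mimicking independent
#' hybridization and scanning.
#'
#' @param spec A [simulation_spec()].
#' @param n_pairs Number of duplicate pairs (>= 1).
#' @return A list with `x`, `truth`, `manifest` and `design` (data.frame
#'   of `sample_a`, `sample_b`).
#' @export
simulate_duplicates <- function(spec, n_pairs) {
  stopifnot(inherits(spec, "simulation_spec"), n_pairs >= 1)
  withr::with_seed(as.integer(spec$seed), {
    manifest <- .sim_manifest(spec)
    n <- spec$n_probes
    hypo <- runif(n) < spec$p_hypo
    template_M <- .sim_signal(spec, hypo, 1L)[1, ]
    template_U <- .sim_signal(spec, !hypo, 1L)[1, ]
    lnoise <- function(nrow_, sd_) {
      if (sd_ == 0) 1 else exp(matrix(rnorm(nrow_ * n, 0, sd_), nrow_, n))
    }
    base_M <- rep(1, n_pairs) %o% template_M * lnoise(n_pairs, spec$bio_noise)
    base_U <- rep(1, n_pairs) %o% template_U * lnoise(n_pairs, spec$bio_noise)
    idx <- rep(seq_len(n_pairs), each = 2)
    X_M <- base_M[idx, , drop = FALSE] * lnoise(2 * n_pairs, spec$duplicate_noise)
    X_U <- base_U[idx, , drop = FALSE] * lnoise(2 * n_pairs, spec$duplicate_noise)
    samples <- sprintf("pair%02d_%s", idx, rep(c("a", "b"), n_pairs))
    out <- .sim_assemble(spec, manifest, X_M, X_U, samples)
    out$truth$hypo <- hypo
    out$manifest <- manifest
    out$design <- data.frame(sample_a = samples[seq(1, 2 * n_pairs, 2)],
                             sample_b = samples[seq(2, 2 * n_pairs, 2)],
                             stringsAsFactors = FALSE)
    out
  })
}

#' Simulate laboratory titration standards
#'
#' For a standard with expected methylation level m, each CpG carries a
#' shared signal magnitude A drawn from the high-signal distribution; the
#' methylated allele receives `m * A` and the unmethylated allele
#' `(1 - m) * A`, so the true beta is approximately m. Replicates are
#' assayed independently (independent signal magnitudes and backgrounds).
#'
#' @param spec A [simulation_spec()]; levels and replicate counts come
#'   from `titration_levels` / `titration_replicates` (default design: 39
#'   samples).
#' @return A list with `x`, `truth`, `manifest` and `design` (data.frame
#'   of `sample_id`, `expected_level`).
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(as.integer(spec$seed), {
    manifest <- .sim_manifest(spec)
    n <- spec$n_probes
    levels <- rep(spec$titration_levels, spec$titration_replicates)
    n_samples <- length(levels)
    samples <- sprintf("std%02d_L%03.0f", seq_len(n_samples), 100 * levels)
    A <- matrix(.rtruncnorm(n_samples * n, spec$nu, spec$tau), n_samples, n)
    X_M <- A * levels
    X_U <- A * (1 - levels)
    out <- .sim_assemble(spec, manifest, X_M, X_U, samples)
    out$manifest <- manifest
    out$design <- data.frame(sample_id = samples, expected_level = levels,
                             stringsAsFactors = FALSE)
    out
  })
}

#' Draw one intensity part from an explicit convolution model
#'
#' Low-level generator used for parameter-recovery checks: draws component
#' labels, signals and backgrounds from a fully specified
#' [convolution_model()].
#'
#' @param n Number of draws.
#' @param model A [convolution_model()].
#' @param seed Integer seed.
#' @return A list with `s` (observed), `x`, `y` and logical `expo` labels.
#' @export
simulate_part <- function(n, model, seed) {
  stopifnot(inherits(model, "convolution_model"))
  withr::with_seed(as.integer(seed), {
    sg <- model$signal; bg <- model$background
    expo <- runif(n) < sg$p1
    x <- numeric(n)
    x[expo] <- rexp(sum(expo), sg$lam)
    x[!expo] <- .rtruncnorm(sum(!expo), sg$normal$mu, sg$normal$sigma)
    y <- .rtruncnorm(n, bg$mu, bg$sigma)
    list(s = x + y, x = x, y = y, expo = expo)
  })
}
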