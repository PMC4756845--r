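## User-facing preprocessing pipeline: model-based background correction
## per intensity part, simple subtraction baselines, dye-bias scaling and
## stratified quantile normalization.

# channel membership of every measurement slot in an intensity set
.channel_slots <- function(x, manifest) {
  mf <- manifest[match(x$probes, manifest$probe_id), ]
  ch <- .sim_channels(mf)
  typeI <- mf$probe_id[mf$design_type == "I"]
  opp <- ifelse(mf$channel[match(typeI, mf$probe_id)] == "red", "green", "red")
  list(M = ch$M, U = ch$U, oob = opp, typeI = typeI)
}

# per-sample, per-channel background estimates for the control-probe routes
.channel_backgrounds <- function(x, manifest, method, sample) {
  if (method == "neg") {
    if (is.null(x$controls)) stop("method 'neg' requires negative controls")
    ct <- x$controls[x$controls$sample_id == sample &
                       x$controls$control_type == "negative", ]
    list(red = estimate_background_neg(ct$red, "red"),
         green = estimate_background_neg(ct$green, "green"))
  } else {
    if (is.null(x$oob_M)) stop("method 'oob' requires out-of-band intensities")
    slots <- .channel_slots(x, manifest)
    vals <- c(x$oob_M[sample, ], x$oob_U[sample, ])
    meas_ch <- rep(slots$oob, 2)
    list(red = estimate_background_oob(vals[meas_ch == "red"], "red"),
         green = estimate_background_oob(vals[meas_ch == "green"], "green"))
  }
}

#' Model-based background correction
#'
#' For each sample, the intensities are split into the six design/channel
#' parts; background parameters are obtained by the chosen route (per
#' channel for `neg`/`oob`, per probe class x channel for `est`); the
#' signal mixture is fitted to each part by EM; and every observed
#' intensity is replaced by its conditional expected signal E(X|S=s).
#' The correction is strictly order-preserving within a part and never
#' truncates: all corrected intensities are strictly positive.
#'
#' @param x An [intensity_set()].
#' @param manifest A [probe_manifest()].
#' @param method Background estimation route: `"neg"`, `"oob"` or `"est"`.
#' @param subsample_seed Seed for fit subsampling (see
#'   [fit_signal_mixture()]).
#' @return A list with `x` (corrected [intensity_set()]) and `diagnostics`
#'   (per sample, per part: background and signal parameters, convergence
#'   flags).
#' @export
background_correct <- function(x, manifest, method = c("oob", "neg", "est"),
                               subsample_seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(x, "intensity_set"))
  split <- split_six_parts(x, manifest)
  M <- x$M; U <- x$U
  diagnostics <- list()
  for (sample in x$samples) {
    if (method %in% c("neg", "oob")) {
      bg_ch <- .channel_backgrounds(x, manifest, method, sample)
    } else {
      # one joint fit per probe class x channel, shared by its M/U parts
      combos <- unique(lapply(split, function(p)
        list(channel = p$channel, probe_class = p$probe_class)))
      bg_ch <- list()
      for (cc in combos) {
        pooled <- unlist(lapply(split, function(q) {
          if (q$channel == cc$channel && q$probe_class == cc$probe_class &&
              length(q$probes))
            x[[q$matrix]][sample, q$probes] else NULL
        }), use.names = FALSE)
        if (is.null(pooled) || !length(pooled)) next
        est <- tryCatch(
          estimate_background_est(pooled, cc$channel, cc$probe_class,
                                  subsample_seed = subsample_seed),
          error = function(e)
            stop(sprintf("background correction failed for sample '%s', class %s/%s: %s",
                         sample, cc$probe_class, cc$channel,
                         conditionMessage(e)), call. = FALSE))
        bg_ch[[paste(cc$probe_class, cc$channel, sep = "_")]] <- est$background
      }
    }
    sample_diag <- list()
    for (part in names(split)) {
      p <- split[[part]]
      if (!length(p$probes)) next
      s <- x[[p$matrix]][sample, p$probes]
      res <- tryCatch({
        bg <- if (method == "est")
          bg_ch[[paste(p$probe_class, p$channel, sep = "_")]]
        else bg_ch[[p$channel]]
        fit <- fit_signal_mixture(s, bg, subsample_seed = subsample_seed)
        model <- convolution_model(fit$params,
                                   trunc_normal_params(bg$mu, bg$sigma))
        corrected <- conditional_signal_mean(pmax(s, 1e-6), model)
        list(corrected = corrected, bg = bg, fit = fit)
      }, error = function(e) {
        stop(sprintf("background correction failed for sample '%s', part '%s': %s",
                     sample, part, conditionMessage(e)), call. = FALSE)
      })
      if (p$matrix == "M") M[sample, p$probes] <- res$corrected
      else U[sample, p$probes] <- res$corrected
      sample_diag[[part]] <- list(
        background = res$bg[c("mu", "sigma", "channel", "probe_class", "method")],
        signal = list(p1 = res$fit$params$p1, lam = res$fit$params$lam,
                      nu = res$fit$params$normal$mu,
                      tau = res$fit$params$normal$sigma),
        converged = res$fit$diagnostics$converged,
        n_iter = res$fit$diagnostics$n_iter)
    }
    diagnostics[[sample]] <- sample_diag
  }
  out <- x
  out$M <- M; out$U <- U
  list(x = out, diagnostics = diagnostics)
}

#' Baseline background subtraction methods
#'
#' The simple per-channel subtraction rules used as comparators: `q5`
#' subtracts the 5th percentile of the negative controls, `lumi1` their
#' median, and `lumi2` the mode of the methylated-probe intensities
#' (located by a kernel density estimate). Results below zero are floored
#' at 0 — the truncation artifact these rules are known for — and the
#' fraction of truncated values is reported.
#'
#' @param x An [intensity_set()].
#' @param manifest A [probe_manifest()].
#' @param method `"q5"`, `"lumi1"` or `"lumi2"`.
#' @return A list with `x` (corrected set) and `diagnostics` (per-sample
#'   subtracted constants and `truncated_fraction`).
#' @export
background_subtract <- function(x, manifest, method = c("q5", "lumi1", "lumi2")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "intensity_set"))
  if (method %in% c("q5", "lumi1") && is.null(x$controls))
    stop("method '", method, "' requires negative controls")
  slots <- .channel_slots(x, manifest)
  M <- x$M; U <- x$U
  diagnostics <- list()
  for (sample in x$samples) {
    const <- if (method == "lumi2") {
      mode_of <- function(v) {
        d <- density(v, n = 512)
        d$x[which.max(d$y)]
      }
      mM <- x$M[sample, ]
      c(red = mode_of(mM[slots$M == "red"]),
        green = mode_of(mM[slots$M == "green"]))
    } else {
      ct <- x$controls[x$controls$sample_id == sample &
                         x$controls$control_type == "negative", ]
      if (!nrow(ct)) stop("negative controls missing for sample ", sample)
      if (method == "q5")
        c(red = unname(quantile(ct$red, 0.05)),   # type-7 interpolation
          green = unname(quantile(ct$green, 0.05)))
      else
        c(red = median(ct$red), green = median(ct$green))
    }
    mM <- x$M[sample, ] - const[slots$M]
    mU <- x$U[sample, ] - const[slots$U]
    n_trunc <- sum(mM < 0) + sum(mU < 0)
    M[sample, ] <- pmax(mM, 0)
    U[sample, ] <- pmax(mU, 0)
    diagnostics[[sample]] <- list(
      subtracted = as.list(const),
      truncated_fraction = n_trunc / (2 * length(x$probes)))
  }
  out <- x
  out$M <- M; out$U <- U
  list(x = out, diagnostics = diagnostics)
}

#' Dye-bias correction from non-polymorphic controls
#'
#' Per sample, robust channel means (medians) of the red-target and
#' green-target non-polymorphic control probes are computed on their
#' target channels; all red-channel intensities are then scaled by
#' `(R + G) / (2R)` and all green-channel intensities by `(R + G) / (2G)`,
#' equalizing the two channels at the controls' common mean.
#'
#' @param x An [intensity_set()] with non-polymorphic controls.
#' @param manifest A [probe_manifest()].
#' @return A list with `x` (corrected set) and `diagnostics` (per-sample
#'   channel means and scale factors).
#' @export
dye_bias_correct <- function(x, manifest) {
  stopifnot(inherits(x, "intensity_set"))
  if (is.null(x$controls)) stop("dye-bias correction requires non-polymorphic controls")
  slots <- .channel_slots(x, manifest)
  out <- x
  diagnostics <- list()
  for (sample in x$samples) {
    ct <- x$controls[x$controls$sample_id == sample, ]
    r <- ct$red[ct$control_type == "nonpolymorphic_red"]
    g <- ct$green[ct$control_type == "nonpolymorphic_green"]
    if (!length(r) || !length(g))
      stop("non-polymorphic controls missing for sample ", sample)
    Rbar <- median(r); Gbar <- median(g)
    if (Rbar <= 0 || Gbar <= 0) stop("non-positive control channel mean")
    fR <- (Rbar + Gbar) / (2 * Rbar)
    fG <- (Rbar + Gbar) / (2 * Gbar)
    f <- c(red = fR, green = fG)
    out$M[sample, ] <- x$M[sample, ] * f[slots$M]
    out$U[sample, ] <- x$U[sample, ] * f[slots$U]
    if (!is.null(out$oob_M)) {
      out$oob_M[sample, ] <- x$oob_M[sample, ] * f[slots$oob]
      out$oob_U[sample, ] <- x$oob_U[sample, ] * f[slots$oob]
    }
    rows <- out$controls$sample_id == sample
    out$controls$red[rows] <- out$controls$red[rows] * fR
    out$controls$green[rows] <- out$controls$green[rows] * fG
    diagnostics[[sample]] <- list(Rbar = Rbar, Gbar = Gbar,
                                  factor_red = fR, factor_green = fG)
  }
  list(x = out, diagnostics = diagnostics)
}

#' Stratified quantile normalization
#'
#' Quantile-normalizes intensities across samples within each of four
#' independent strata: (M, type I), (U, type I), (M, type II),
#' (U, type II). After normalization every sample's sorted values within a
#' stratum are identical; ties receive the average of their quantiles.
#'
#' @param x An [intensity_set()] with at least 2 samples.
#' @param manifest A [probe_manifest()].
#' @return The normalized [intensity_set()].
#' @export
quantile_normalize <- function(x, manifest) {
  stopifnot(inherits(x, "intensity_set"))
  if (length(x$samples) < 2L) {
    warning("quantile normalization with a single sample is the identity")
    return(x)
  }
  mf <- manifest[match(x$probes, manifest$probe_id), ]
  out <- x
  for (cls in c("I", "II")) {
    probes <- mf$probe_id[mf$design_type == cls]
    if (!length(probes)) next
    for (mat in c("M", "U")) {
      sub <- t(x[[mat]][, probes, drop = FALSE])     # probes x samples
      norm <- limma::normalizeQuantiles(sub, ties = TRUE)
      out[[mat]][, probes] <- t(norm)
    }
  }
  out
}

#' Pipeline configuration
#'
#' @param background_method `"neg"`, `"oob"` or `"est"`.
#' @param steps Ordered subset of `c("background", "dye_bias", "quantile")`
#'   (model-based background correction, dye-bias scaling, stratified
#'   quantile normalization); the order background -> dye bias -> quantile
#'   is enforced.
#' @param beta_offset Denominator offset for beta values (default 100).
#' @param subsample_seed Seed for fit subsampling.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(background_method = c("oob", "neg", "est"),
                            steps = c("background", "dye_bias", "quantile"),
                            beta_offset = 100, subsample_seed = 1L) {
  background_method <- match.arg(background_method)
  canonical <- c("background", "dye_bias", "quantile")
  if (!all(steps %in% canonical)) stop("unknown step(s): ",
                                       paste(setdiff(steps, canonical), collapse = ", "))
  if (!identical(steps, canonical[canonical %in% steps]))
    stop("steps must respect the order background -> dye_bias -> quantile")
  if (beta_offset < 0) stop("beta_offset must be non-negative")
  structure(list(background_method = background_method, steps = steps,
                 beta_offset = beta_offset,
                 subsample_seed = as.integer(subsample_seed)),
            class = "pipeline_config")
}

#' Run the preprocessing pipeline
#'
#' Applies the configured steps in order (background correction, dye-bias
#' correction, quantile normalization — any ordered subset, including the
#' empty identity pipeline), then computes beta values with the configured
#' offset. Deterministic given the configuration and input.
#'
#' @param x An [intensity_set()].
#' @param manifest A [probe_manifest()].
#' @param config A [pipeline_config()].
#' @return A list with `x` (processed intensities), `beta` (samples x
#'   probes matrix) and `diagnostics` (JSON-serializable, per stage).
#' @export
run_pipeline <- function(x, manifest, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  diagnostics <- list(config = unclass(config))
  for (step in config$steps) {
    res <- switch(step,
      background = background_correct(x, manifest, config$background_method,
                                 subsample_seed = config$subsample_seed),
      dye_bias = dye_bias_correct(x, manifest),
      quantile = list(x = quantile_normalize(x, manifest), diagnostics = NULL))
    x <- res$x
    diagnostics[[step]] <- res$diagnostics
  }
  list(x = x, beta = beta_matrix(x, config$beta_offset),
       diagnostics = diagnostics)
}

#' Serialize pipeline diagnostics to JSON
#' @param diagnostics Diagnostics list from [run_pipeline()] or
#'   [background_correct()].
#' @param path Output file.
#' @export
write_diagnostics <- function(diagnostics, path) {
  jsonlite::write_json(diagnostics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
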