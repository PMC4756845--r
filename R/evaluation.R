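## Duplicate- and titration-based performance metrics.

.check_pair <- function(betas, pair) {
  pair <- as.character(pair)
  if (length(pair) != 2L || pair[1] == pair[2])
    stop("a pair must name two distinct samples")
  missing <- setdiff(pair, rownames(betas))
  if (length(missing)) stop("sample(s) not in beta matrix: ",
                            paste(missing, collapse = ", "))
  pair
}

#' Mean-centered correlation between a duplicate pair
#'
#' Each CpG's mean across all samples in the matrix is subtracted before
#' correlating the pair's columns, removing the dominant between-CpG
#' methylation pattern that inflates raw correlations even between
#' unrelated samples. Requires at least 3 samples: with exactly 2, the
#' centering maps the pair onto mirror images and the correlation
#' degenerates to -1. CpGs with missing values in either member are
#' dropped pairwise.
#'
#' @param betas Samples x probes beta matrix (>= 3 samples).
#' @param pair Character vector of two sample ids.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
mean_centered_correlation <- function(betas, pair) {
  pair <- .check_pair(betas, pair)
  if (nrow(betas) < 3L)
    stop("mean-centered correlation needs at least 3 samples for centering")
  center <- colMeans(betas, na.rm = TRUE)
  a <- betas[pair[1], ] - center
  b <- betas[pair[2], ] - center
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance after centering; correlation undefined")
  cor(a, b)
}

#' Mean absolute beta difference between a duplicate pair
#'
#' Average over CpGs of the absolute beta difference between the two
#' members, expressed in percentage points.
#'
#' @inheritParams mean_centered_correlation
#' @return Mean absolute difference x 100 (percent).
#' @export
mean_abs_beta_diff <- function(betas, pair) {
  pair <- .check_pair(betas, pair)
  d <- abs(betas[pair[1], ] - betas[pair[2], ])
  mean(d, na.rm = TRUE) * 100
}

#' Median deviation from expected titration levels
#'
#' For each expected methylation level in the design, the signed median
#' over CpGs and replicates of (beta - expected), in beta units. Positive
#' values indicate upward bias (typical at the unmethylated extreme under
#' uncorrected background), negative values downward bias.
#'
#' @param betas Samples x probes beta matrix.
#' @param design Data.frame with columns `sample_id` and `expected_level`.
#' @return Data.frame with `expected_level`, `median_deviation`,
#'   `median_abs_deviation` and `n_samples`.
#' @export
titration_deviation <- function(betas, design) {
  stopifnot(all(c("sample_id", "expected_level") %in% names(design)))
  missing <- setdiff(design$sample_id, rownames(betas))
  if (length(missing)) stop("sample(s) not in beta matrix: ",
                            paste(missing, collapse = ", "))
  levels <- sort(unique(design$expected_level))
  out <- lapply(levels, function(lv) {
    ids <- design$sample_id[design$expected_level == lv]
    dev <- betas[ids, , drop = FALSE] - lv
    data.frame(expected_level = lv,
               median_deviation = median(dev, na.rm = TRUE),
               median_abs_deviation = median(abs(dev), na.rm = TRUE),
               n_samples = length(ids))
  })
  do.call(rbind, out)
}

#' Compare correction methods on duplicate and titration designs
#'
#' Summarizes, for the raw betas and each corrected beta matrix, the mean
#' of per-pair mean-centered correlations, the mean of per-pair mean
#' absolute beta differences, and (when a titration design is given) the
#' per-level median deviations. Each corrected method is compared against
#' raw with a one-sided paired t-test over pairs (correlation: greater;
#' difference: less).
#'
#' @param raw_betas Samples x probes beta matrix of uncorrected data.
#' @param corrected_betas_by_method Named list of corrected beta matrices.
#' @param duplicates Optional data.frame with `sample_a`, `sample_b`.
#' @param titration Optional data.frame with `sample_id`,
#'   `expected_level`.
#' @return A list with `duplicates` (data.frame: method, mean correlation,
#'   mean abs difference, t-test p-values vs raw) and `titration`
#'   (data.frame: method x level median deviations), either possibly
#'   `NULL`.
#' @export
compare_methods <- function(raw_betas, corrected_betas_by_method,
                            duplicates = NULL, titration = NULL) {
  all_betas <- c(list(raw = raw_betas), corrected_betas_by_method)
  dup_tab <- NULL
  if (!is.null(duplicates)) {
    per_pair <- lapply(all_betas, function(b) {
      data.frame(
        r = vapply(seq_len(nrow(duplicates)), function(i)
          mean_centered_correlation(b, unlist(duplicates[i, c("sample_a", "sample_b")])),
          numeric(1)),
        d = vapply(seq_len(nrow(duplicates)), function(i)
          mean_abs_beta_diff(b, unlist(duplicates[i, c("sample_a", "sample_b")])),
          numeric(1)))
    })
    if (nrow(duplicates) < 2L) warning("fewer than 2 pairs; t-test omitted")
    pval <- function(a, b, alternative) {
      if (length(a) < 2L) return(NA_real_)
      if (all(a == b)) return(NA_real_)   # identical metrics: no evidence
      t.test(a, b, paired = TRUE, alternative = alternative)$p.value
    }
    dup_tab <- do.call(rbind, lapply(names(all_betas), function(m) {
      pp <- per_pair[[m]]
      data.frame(
        method = m,
        mean_centered_cor = mean(pp$r),
        mean_abs_diff_pct = mean(pp$d),
        p_cor_vs_raw = if (m == "raw") NA_real_ else
          pval(pp$r, per_pair$raw$r, "greater"),
        p_diff_vs_raw = if (m == "raw") NA_real_ else
          pval(pp$d, per_pair$raw$d, "less"),
        stringsAsFactors = FALSE)
    }))
  }
  tit_tab <- NULL
  if (!is.null(titration)) {
    tit_tab <- do.call(rbind, lapply(names(all_betas), function(m) {
      td <- titration_deviation(all_betas[[m]], titration)
      td$method <- m
      td
    }))
  }
  list(duplicates = dup_tab, titration = tit_tab)
}
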