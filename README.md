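# methylbgc

Model-based background correction for Illumina Infinium methylation
arrays, with the surrounding preprocessing (dye-bias correction,
stratified quantile normalization), quality control, duplicate/titration
evaluation metrics, and a ground-truth simulator.

## The method

Methylation BeadChips measure a methylated (M) and unmethylated (U)
intensity per CpG; the methylation fraction is estimated as
`beta = M / (M + U + 100)`. Both intensities contain additive background
that varies between arrays, biases betas toward 0.5 (worst at the fully
(un)methylated extremes) and differs between the Infinium I and II probe
chemistries. Subtracting a constant (negative-control percentile or
median) truncates low intensities at zero and discards information.

`methylbgc` instead models each observed intensity as `S = X + Y` with

- `X ~ p1 * Exp(lambda) + p2 * N+(nu, tau^2)` — the true signal, a
  mixture of an exponential (absent/weak allele) and a zero-truncated
  normal (present allele),
- `Y ~ N+(mu, sigma^2)` — the background,

fitted separately for the six design/channel parts of each sample, and
replaces every intensity by its conditional expectation `E(X | S = s)`
(closed form, evaluated in log space; strictly positive, strictly
rank-preserving). Background parameters come from one of three routes:
internal negative controls (`neg`), out-of-band Infinium I intensities
(`oob`), or a joint maximum-likelihood fit on the combined M/U data
(`est`, separately per probe class). Signal parameters are fitted by EM.

## Worked example

Simulate a duplicate-pair study with known ground truth, correct the
intensities with the out-of-band route, and evaluate:

```r
library(methylbgc)

spec <- simulation_spec(n_probes = 10000, seed = 7)
sim  <- simulate_duplicates(spec, n_pairs = 8)

res  <- background_correct(sim$x, sim$manifest, method = "oob")

raw_beta <- beta_matrix(sim$x)
cor_beta <- beta_matrix(res$x)

mean(abs(raw_beta - sim$truth$beta_true))   # 0.0695
mean(abs(cor_beta - sim$truth$beta_true))   # 0.0254

report <- compare_methods(raw_beta, list(corrected_oob = cor_beta),
                          duplicates = sim$design)
print(report$duplicates, digits = 3)
#>          method mean_centered_cor mean_abs_diff_pct p_cor_vs_raw p_diff_vs_raw
#> 1           raw             0.786              2.62           NA            NA
#> 2 corrected_oob             0.832              2.11       0.0202       0.00486
```

Corrected betas are almost 3x closer to the generative truth; duplicate
agreement improves on both metrics (mean-centered correlation up, mean
absolute difference down), with one-sided paired t-tests against the raw
data shown per metric. The full pipeline (`run_pipeline()`) chains
background correction, dye-bias correction and four-stratum quantile
normalization, and `detection_pvalue()` / `qc_filter()` / `nmode()`
provide the standard quality filters. A thin command-line wrapper with
`simulate` / `correct` / `normalize` / `qc` / `evaluate` / `pipeline`
subcommands ships in `inst/scripts/methylbgc-cli.R`.

See the vignette (`vignettes/background-correction-model.Rmd`) for the
model derivation, estimation details, and exactly what the simulator
does and does not emulate.

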