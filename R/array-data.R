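## Data containers and I/O for Infinium-style intensity data.
##
## Matrices are oriented samples x probes (row names = sample ids, column
## names = probe ids); on disk the transpose is stored (probes in rows,
## header = sample ids) as is conventional for delimited intensity tables.

#' Construct a probe manifest
#'
#' @param probe_id Unique probe identifiers.
#' @param design_type `"I"` or `"II"` per probe.
#' @param channel `"red"`/`"green"` for type I probes, `NA` for type II.
#' @param chromosome Optional chromosome labels (opaque strings).
#' @return A data.frame of class `probe_manifest`.
#' @export
probe_manifest <- function(probe_id, design_type, channel = NA_character_,
                           chromosome = NA_character_) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop("probe ids must be unique")
  design_type <- as.character(design_type)
  if (!all(design_type %in% c("I", "II"))) stop("design_type must be 'I' or 'II'")
  channel <- rep_len(as.character(channel), length(probe_id))
  chromosome <- rep_len(as.character(chromosome), length(probe_id))
  bad <- design_type == "I" & !(channel %in% c("red", "green"))
  if (any(bad))
    stop("type I probes lacking a channel: ", paste(head(probe_id[bad], 5), collapse = ", "))
  channel[design_type == "II"] <- NA_character_
  structure(data.frame(probe_id = probe_id, design_type = design_type,
                       channel = channel, chromosome = chromosome,
                       stringsAsFactors = FALSE),
            class = c("probe_manifest", "data.frame"))
}

.check_matrix <- function(m, name, samples = NULL, probes = NULL) {
  if (is.null(m)) return(NULL)
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop(name, ": intensities must be finite")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative intensity at sample '%s', probe '%s'",
                 name, rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  if (!is.null(samples) && !identical(rownames(m), samples))
    stop(name, ": sample ids do not match")
  if (!is.null(probes) && !identical(colnames(m), probes))
    stop(name, ": probe ids do not match")
  m
}

#' Construct an intensity set
#'
#' Bundles the methylated/unmethylated intensity matrices with optional
#' out-of-band intensities (type I probes only), a per-sample control-probe
#' table and bead counts.
#'
#' @param M,U Numeric matrices, samples x probes, non-negative, with sample
#'   row names and probe column names matching `manifest`.
#' @param manifest A [probe_manifest()] covering exactly the probes of `M`.
#' @param oob_M,oob_U Optional samples x (type I probes) matrices of
#'   out-of-band intensities.
#' @param controls Optional data.frame with columns `sample_id`,
#'   `control_type` (`negative`, `nonpolymorphic_red`,
#'   `nonpolymorphic_green`, `other`), `red`, `green`.
#' @param beads_M,beads_U Optional integer bead-count matrices.
#' @return An object of class `intensity_set`.
#' @export
intensity_set <- function(M, U, manifest, oob_M = NULL, oob_U = NULL,
                          controls = NULL, beads_M = NULL, beads_U = NULL) {
  stopifnot(inherits(manifest, "probe_manifest"))
  M <- .check_matrix(M, "M")
  samples <- rownames(M); probes <- colnames(M)
  if (is.null(samples) || is.null(probes))
    stop("M must carry sample row names and probe column names")
  missing_probes <- setdiff(probes, manifest$probe_id)
  extra <- setdiff(manifest$probe_id, probes)
  if (length(missing_probes) || length(extra))
    stop("probe ids do not reconcile with the manifest; offenders: ",
         paste(head(c(missing_probes, extra), 10), collapse = ", "))
  U <- .check_matrix(U, "U", samples, probes)
  typeI <- manifest$probe_id[manifest$design_type == "I"]
  if (!is.null(oob_M)) {
    oob_M <- .check_matrix(oob_M, "oob_M", samples)
    oob_U <- .check_matrix(oob_U, "oob_U", samples)
    if (!setequal(colnames(oob_M), typeI) || !setequal(colnames(oob_U), typeI))
      stop("out-of-band matrices must cover exactly the type I probes")
    oob_M <- oob_M[, typeI, drop = FALSE]
    oob_U <- oob_U[, typeI, drop = FALSE]
  }
  if (!is.null(controls)) {
    need <- c("sample_id", "control_type", "red", "green")
    if (!all(need %in% names(controls)))
      stop("controls table needs columns: ", paste(need, collapse = ", "))
    if (any(controls$red < 0 | controls$green < 0))
      stop("controls: negative intensity")
  }
  if (!is.null(beads_M)) beads_M <- .check_matrix(beads_M, "beads_M", samples, probes)
  if (!is.null(beads_U)) beads_U <- .check_matrix(beads_U, "beads_U", samples, probes)
  structure(list(samples = samples, probes = probes, M = M, U = U,
                 oob_M = oob_M, oob_U = oob_U, controls = controls,
                 beads_M = beads_M, beads_U = beads_U),
            class = "intensity_set")
}

#' @export
print.intensity_set <- function(x, ...) {
  cat(sprintf("intensity_set: %d samples x %d probes%s%s\n",
              length(x$samples), length(x$probes),
              if (!is.null(x$oob_M)) ", with out-of-band" else "",
              if (!is.null(x$controls)) ", with controls" else ""))
  invisible(x)
}

## ---- delimited-table I/O ------------------------------------------------

.read_delim_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("%s: negative intensity at probe '%s', sample '%s'",
                 basename(path), rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  t(m)   # to samples x probes
}

.write_delim_matrix <- function(m, path, id_col = "probe_id") {
  df <- data.frame(colnames(m), t(m), check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an intensity set from delimited text tables
#'
#' Each matrix lives in its own TSV with probes in rows (first column
#' `probe_id`) and samples in columns; the controls table is long format.
#' Missing optional files simply leave the corresponding field absent.
#'
#' @param paths Named list/vector with entries `M`, `U` and optionally
#'   `oob_M`, `oob_U`, `controls`, `beads_M`, `beads_U`.
#' @param manifest A [probe_manifest()].
#' @return An [intensity_set()].
#' @export
read_intensity_tables <- function(paths, manifest) {
  paths <- as.list(paths)
  if (is.null(paths$M) || is.null(paths$U)) stop("paths must include 'M' and 'U'")
  grab <- function(key) if (!is.null(paths[[key]]) && file.exists(paths[[key]]))
    .read_delim_matrix(paths[[key]]) else NULL
  controls <- if (!is.null(paths$controls) && file.exists(paths$controls))
    utils::read.delim(paths$controls, sep = "\t", stringsAsFactors = FALSE) else NULL
  intensity_set(grab("M"), grab("U"), manifest,
                oob_M = grab("oob_M"), oob_U = grab("oob_U"),
                controls = controls,
                beads_M = grab("beads_M"), beads_U = grab("beads_U"))
}

#' Write an intensity set to delimited text tables
#'
#' @param x An [intensity_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_intensity_tables <- function(x, dir) {
  stopifnot(inherits(x, "intensity_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(M = file.path(dir, "M.tsv"), U = file.path(dir, "U.tsv"))
  .write_delim_matrix(x$M, paths["M"])
  .write_delim_matrix(x$U, paths["U"])
  for (key in c("oob_M", "oob_U", "beads_M", "beads_U")) {
    if (!is.null(x[[key]])) {
      p <- file.path(dir, paste0(key, ".tsv"))
      .write_delim_matrix(x[[key]], p)
      paths[key] <- p
    }
  }
  if (!is.null(x$controls)) {
    p <- file.path(dir, "controls.tsv")
    utils::write.table(x$controls, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["controls"] <- p
  }
  invisible(paths)
}

#' Read a probe manifest from CSV
#'
#' Columns: `probe_id`, `design_type`, `channel`, optional `chromosome`.
#' @param path CSV file path.
#' @return A [probe_manifest()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  probe_manifest(df$probe_id, df$design_type,
                 channel = if ("channel" %in% names(df)) df$channel else NA,
                 chromosome = if ("chromosome" %in% names(df)) df$chromosome else NA)
}

#' Write a probe manifest to CSV
#' @param manifest A [probe_manifest()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
}

## ---- six-part split -----------------------------------------------------

#' Split intensities into the six modeling parts
#'
#' Each sample's measurements partition into six parts that are modeled
#' separately: type I red M, type I red U, type I green M, type I green U,
#' type II M (green channel) and type II U (red channel).
#'
#' @param x An [intensity_set()].
#' @param manifest A [probe_manifest()] covering all probes of `x`.
#' @return A named list of six part descriptors, each with `probes`,
#'   `matrix` (`"M"` or `"U"`), `channel` and `probe_class`; class
#'   `six_part_split`.
#' @export
split_six_parts <- function(x, manifest) {
  stopifnot(inherits(x, "intensity_set"), inherits(manifest, "probe_manifest"))
  if (!setequal(x$probes, manifest$probe_id))
    stop("manifest must cover all probes")
  mf <- manifest[match(x$probes, manifest$probe_id), ]
  if (any(mf$design_type == "I" & !(mf$channel %in% c("red", "green"))))
    stop("type I probe lacking a channel assignment")
  iR <- mf$probe_id[mf$design_type == "I" & mf$channel == "red"]
  iG <- mf$probe_id[mf$design_type == "I" & mf$channel == "green"]
  ii <- mf$probe_id[mf$design_type == "II"]
  parts <- list(
    I_red_M    = list(probes = iR, matrix = "M", channel = "red",   probe_class = "typeI"),
    I_red_U    = list(probes = iR, matrix = "U", channel = "red",   probe_class = "typeI"),
    I_green_M  = list(probes = iG, matrix = "M", channel = "green", probe_class = "typeI"),
    I_green_U  = list(probes = iG, matrix = "U", channel = "green", probe_class = "typeI"),
    II_green_M = list(probes = ii, matrix = "M", channel = "green", probe_class = "typeII"),
    II_red_U   = list(probes = ii, matrix = "U", channel = "red",   probe_class = "typeII")
  )
  structure(parts, class = "six_part_split")
}

#' Extract one part's intensity values for one sample
#' @param x An [intensity_set()].
#' @param split A [split_six_parts()] result.
#' @param part Part name (e.g. `"II_green_M"`).
#' @param sample Sample id.
#' @return Named numeric vector of intensities.
#' @export
part_values <- function(x, split, part, sample) {
  p <- split[[part]]
  x[[p$matrix]][sample, p$probes]
}

## ---- beta, detection p, QC ---------------------------------------------

#' Methylation beta values
#'
#' `beta = M / (M + U + offset)`; the default offset of 100 regularizes
#' the ratio when both intensities are low, and keeps beta in `[0, 1)`.
#'
#' @param M,U Non-negative intensities (vectors or matrices, same shape).
#' @param offset Non-negative constant added to the denominator.
#' @return Beta values of the same shape, in `[0, 1)`.
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (any(M < 0) || any(U < 0)) stop("intensities must be non-negative")
  if (offset < 0) stop("offset must be non-negative")
  M / (M + U + offset)
}

#' Beta matrix from an intensity set
#' @param x An [intensity_set()].
#' @param offset Denominator offset, default 100.
#' @return Samples x probes beta matrix.
#' @export
beta_matrix <- function(x, offset = 100) {
  stopifnot(inherits(x, "intensity_set"))
  compute_beta(x$M, x$U, offset)
}

# Deterministic empirical background sums for detection p-values:
# type I compares M+U against all ordered pairwise sums (i != j) of that
# channel's negative controls; type II against row-wise red+green sums.
.neg_control_sums <- function(controls, sample) {
  ct <- controls[controls$sample_id == sample & controls$control_type == "negative", ]
  if (nrow(ct) < 2L) stop("negative controls missing for sample ", sample)
  r <- ct$red; g <- ct$green
  pair_sums <- function(v) {
    s <- outer(v, v, "+")
    sort(s[row(s) != col(s)])
  }
  list(red = pair_sums(r), green = pair_sums(g), both = sort(r + g))
}

#' Detection p-values against negative controls
#'
#' For each probe, the summed intensity M + U is compared with the
#' empirical distribution of summed negative-control intensities matching
#' the probe chemistry (type I: two draws from its assigned channel;
#' type II: a green plus a red draw). `p = (# control sums >= observed
#' + 1) / (n + 1)`, so p is never exactly 0 and equals 1 for zero signal.
#'
#' @param x An [intensity_set()] with a controls table.
#' @param manifest A [probe_manifest()].
#' @return Samples x probes matrix of p-values in `(0, 1]`.
#' @export
detection_pvalue <- function(x, manifest) {
  stopifnot(inherits(x, "intensity_set"))
  if (is.null(x$controls)) stop("detection p-values require negative controls")
  mf <- manifest[match(x$probes, manifest$probe_id), ]
  key <- ifelse(mf$design_type == "II", "both",
                ifelse(mf$channel == "red", "red", "green"))
  p <- matrix(NA_real_, length(x$samples), length(x$probes),
              dimnames = list(x$samples, x$probes))
  for (s in x$samples) {
    sums <- .neg_control_sums(x$controls, s)
    obs <- x$M[s, ] + x$U[s, ]
    for (k in c("red", "green", "both")) {
      idx <- which(key == k)
      if (!length(idx)) next
      ref <- sums[[k]]
      n <- length(ref)
      n_ge <- n - findInterval(obs[idx] - 1e-9, ref)
      p[s, idx] <- (n_ge + 1) / (n + 1)
    }
  }
  p
}

#' Low-quality measurement mask
#'
#' Flags measurements for exclusion when either allele's bead count is
#' below `bead_threshold` or the detection p-value exceeds `p_threshold`
#' (strict inequalities on both rules). Without bead counts the bead rule
#' is skipped.
#'
#' @param x An [intensity_set()].
#' @param detection_p Samples x probes p-value matrix.
#' @param p_threshold Detection p-value cutoff, default 0.05.
#' @param bead_threshold Minimum acceptable bead count, default 3.
#' @return Logical samples x probes matrix; `TRUE` = exclude.
#' @export
qc_filter <- function(x, detection_p, p_threshold = 0.05, bead_threshold = 3L) {
  stopifnot(inherits(x, "intensity_set"))
  if (!identical(dim(detection_p), dim(x$M)))
    stop("detection_p shape does not match the intensity matrices")
  mask <- detection_p > p_threshold
  if (!is.null(x$beads_M)) mask <- mask | x$beads_M < bead_threshold
  if (!is.null(x$beads_U)) mask <- mask | x$beads_U < bead_threshold
  mask
}

#' Count modes of a beta distribution
#'
#' Histogram-based multimodality detector for one CpG's beta values across
#' samples: counts local maxima of a fixed-bin histogram whose peak mass
#' exceeds `min_mass` of the sample and that are separated by a valley
#' dropping below `valley_frac` of the smaller adjacent peak; peaks failing
#' the separation rule are merged.
#'
#' @param betas Beta values across samples for one CpG, `n >= 20`.
#' @param n_bins Number of equal bins on `[0, 1]`, default 20.
#' @param min_mass Minimum peak mass as a fraction of `n`, default 0.05.
#' @param valley_frac Required valley depth relative to the smaller
#'   adjacent peak, default 0.5.
#' @return Integer number of modes (>= 1 for non-empty input).
#' @export
nmode <- function(betas, n_bins = 20L, min_mass = 0.05, valley_frac = 0.5) {
  betas <- betas[is.finite(betas)]
  if (length(betas) < 20L) stop("nmode needs at least 20 samples")
  h <- hist(pmin(pmax(betas, 0), 1), breaks = seq(0, 1, length.out = n_bins + 1),
            plot = FALSE)
  cnt <- h$counts
  padded <- c(-1, cnt, -1)
  peaks <- which(vapply(seq_along(cnt), function(i) {
    padded[i + 1] > padded[i] && padded[i + 1] >= padded[i + 2]
  }, logical(1)))
  peaks <- peaks[cnt[peaks] > min_mass * length(betas)]
  if (length(peaks) <= 1L) return(max(1L, length(peaks)))
  repeat {
    if (length(peaks) == 1L) break
    merged <- FALSE
    for (i in seq_len(length(peaks) - 1L)) {
      a <- peaks[i]; b <- peaks[i + 1]
      valley <- min(cnt[a:b])
      if (valley >= valley_frac * min(cnt[a], cnt[b])) {
        drop_i <- if (cnt[a] >= cnt[b]) i + 1L else i
        peaks <- peaks[-drop_i]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  length(peaks)
}

#' Frequency-polygon summary of a value distribution
#'
#' @param values Numeric values.
#' @param n_bins Number of equal bins, `>= 2`.
#' @param limits Bin range; defaults to the data range.
#' @return A data.frame with `midpoint` and `count`; counts sum to
#'   `length(values)` when all values fall inside `limits`.
#' @export
frequency_polygon <- function(values, n_bins = 20L, limits = range(values)) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  breaks <- seq(limits[1], limits[2], length.out = n_bins + 1)
  h <- hist(values, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  data.frame(midpoint = h$mids, count = h$counts)
}
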