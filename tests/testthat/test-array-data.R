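# small handmade intensity set: 2 type I + 2 type II probes, 2 samples
tiny_set <- function(with_beads = FALSE) {
  manifest <- probe_manifest(c("p1", "p2", "p3", "p4"),
                             c("I", "I", "II", "II"),
                             c("red", "green", NA, NA))
  mk <- function(vals) matrix(vals, 2, 4,
                              dimnames = list(c("s1", "s2"),
                                              c("p1", "p2", "p3", "p4")))
  controls <- do.call(rbind, lapply(c("s1", "s2"), function(s)
    data.frame(sample_id = s,
               control_type = c(rep("negative", 25),
                                "nonpolymorphic_red", "nonpolymorphic_green"),
               red = c(seq(100, 340, by = 10), 5000, 150),
               green = c(seq(200, 440, by = 10), 250, 6000))))
  x <- intensity_set(
    mk(c(1000, 1100, 2000, 2100, 3000, 3100, 4000, 4100)),
    mk(c(500, 510, 600, 610, 700, 710, 800, 810)),
    manifest,
    oob_M = matrix(c(10, 11, 20, 21), 2, 2,
                   dimnames = list(c("s1", "s2"), c("p1", "p2"))),
    oob_U = matrix(c(30, 31, 40, 41), 2, 2,
                   dimnames = list(c("s1", "s2"), c("p1", "p2"))),
    controls = controls,
    beads_M = if (with_beads) mk(c(5, 5, 5, 5, 2, 5, 3, 5)) else NULL,
    beads_U = if (with_beads) mk(rep(5, 8)) else NULL)
  list(x = x, manifest = manifest)
}

test_that("intensity set construction validates probes, shapes and signs", {
  d <- tiny_set()
  expect_s3_class(d$x, "intensity_set")
  expect_identical(d$x$probes, c("p1", "p2", "p3", "p4"))

  bad_manifest <- probe_manifest(c("p1", "p2", "p3", "px"),
                                 c("I", "I", "II", "II"),
                                 c("red", "green", NA, NA))
  expect_error(intensity_set(d$x$M, d$x$U, bad_manifest), "reconcile.*p4|offenders")
  Mneg <- d$x$M; Mneg[1, 2] <- -5
  expect_error(intensity_set(Mneg, d$x$U, d$manifest), "negative intensity.*p2")
  expect_error(probe_manifest(c("a", "a"), c("II", "II")), "unique")
  expect_error(probe_manifest("a", "I", NA), "lacking a channel")
})

test_that("the shipped toy fixture loads into a validated intensity set", {
  dir <- system.file("extdata", "toy", package = "methylbgc")
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  x <- read_intensity_tables(
    list(M = file.path(dir, "M.tsv"), U = file.path(dir, "U.tsv"),
         oob_M = file.path(dir, "oob_M.tsv"), oob_U = file.path(dir, "oob_U.tsv"),
         controls = file.path(dir, "controls.tsv")),
    manifest)
  expect_identical(x$samples, c("sampleA", "sampleB"))
  expect_equal(sum(manifest$design_type == "I"), 2L)
  expect_equal(sum(manifest$design_type == "II"), 2L)
  expect_equal(unname(x$M["sampleA", "cg0001"]), 1200.5)
  expect_setequal(colnames(x$oob_M), c("cg0001", "cg0002"))
  # beta and detection p-values run end to end on the fixture
  b <- beta_matrix(x)
  expect_true(all(b >= 0 & b < 1))
  p <- detection_pvalue(x, manifest)
  expect_true(all(p > 0 & p <= 1))
})

test_that("intensity tables round-trip through delimited text at full precision", {
  d <- tiny_set(with_beads = TRUE)
  dir <- tempfile("io")
  paths <- write_intensity_tables(d$x, dir)
  y <- read_intensity_tables(as.list(paths), d$manifest)
  expect_equal(y$M, d$x$M)
  expect_equal(y$U, d$x$U)
  expect_equal(y$oob_M, d$x$oob_M)
  expect_equal(y$beads_M, d$x$beads_M)
  expect_equal(y$controls$red, d$x$controls$red)

  # a negative entry is reported with its location
  bad <- file.path(dir, "M.tsv")
  tab <- read.delim(bad, check.names = FALSE)
  tab[2, 2] <- -1
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_intensity_tables(as.list(paths), d$manifest),
               "negative intensity.*p2.*s1")

  # manifest round-trip
  mpath <- file.path(dir, "manifest.csv")
  write_manifest(d$manifest, mpath)
  expect_equal(read_manifest(mpath), d$manifest)
})

test_that("six-part split partitions every measurement exactly once", {
  d <- tiny_set()
  sp <- split_six_parts(d$x, d$manifest)
  sizes <- vapply(sp, function(p) length(p$probes), integer(1))
  expect_equal(unname(sizes), c(1, 1, 1, 1, 2, 2))
  # partition property: every (probe, matrix) slot exactly once
  slots <- unname(unlist(lapply(sp, function(p) paste(p$matrix, p$probes))))
  expect_equal(sort(slots),
               sort(c(paste("M", d$x$probes), paste("U", d$x$probes))))
  expect_equal(part_values(d$x, sp, "II_green_M", "s1"),
               c(p3 = 3000, p4 = 4000))

  # no type I probes: four empty parts, two full parts
  m2 <- probe_manifest(c("a", "b"), c("II", "II"))
  x2 <- intensity_set(matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b"))),
                      matrix(5:8, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b"))),
                      m2)
  sp2 <- split_six_parts(x2, m2)
  expect_equal(unname(vapply(sp2, function(p) length(p$probes), integer(1))),
               c(0, 0, 0, 0, 2, 2))

  # conservation on a simulated array
  sim <- simulate_array(simulation_spec(n_probes = 10000L, n_samples = 1L, seed = 2))
  sp3 <- split_six_parts(sim$x, sim$manifest)
  expect_equal(sum(vapply(sp3, function(p) length(p$probes), integer(1))),
               2 * 10000L)
})

test_that("beta values follow the offset ratio and its monotonicity", {
  expect_equal(compute_beta(100, 0), 0.5)
  expect_equal(compute_beta(0, 0), 0)
  expect_equal(compute_beta(900, 0), 0.9)
  expect_error(compute_beta(-1, 5), "non-negative")
  M <- withr::with_seed(5, runif(200, 0, 1e4))
  U <- withr::with_seed(6, runif(200, 0, 1e4))
  b <- compute_beta(M, U)
  expect_true(all(b >= 0 & b < 1))
  # strictly increasing in M, decreasing in U
  expect_true(all(compute_beta(M + 1, U) > b))
  expect_true(all(compute_beta(M, U + 1) < b))
})

test_that("detection p-values are an empirical tail probability of control sums", {
  d <- tiny_set()
  p <- detection_pvalue(d$x, d$manifest)
  expect_true(all(p > 0 & p <= 1))

  # zero signal is never detected
  x0 <- d$x
  x0$M[] <- 0; x0$U[] <- 0
  expect_true(all(detection_pvalue(x0, d$manifest) == 1))

  # signal above every control sum gets the smallest achievable p
  xb <- d$x
  xb$M[] <- 1e6
  pb <- detection_pvalue(xb, d$manifest)
  ct <- d$x$controls[d$x$controls$control_type == "negative" &
                       d$x$controls$sample_id == "s1", ]
  n_pairs <- nrow(ct) * (nrow(ct) - 1)
  expect_equal(unname(pb["s1", "p1"]), 1 / (n_pairs + 1))

  # brute-force oracle for a type II probe
  sums <- ct$red + ct$green
  obs <- d$x$M["s1", "p3"] + d$x$U["s1", "p3"]
  expect_equal(unname(p["s1", "p3"]), (sum(sums >= obs) + 1) / (length(sums) + 1))

  # monotone non-increasing in M + U
  xs <- d$x
  xs$M[] <- 200; xs$U[] <- 0
  p_low <- detection_pvalue(xs, d$manifest)
  xs$M[] <- 400
  p_high <- detection_pvalue(xs, d$manifest)
  expect_true(all(p_high <= p_low))

  xn <- d$x; xn$controls <- NULL
  expect_error(detection_pvalue(xn, d$manifest), "controls")
})

test_that("qc filter applies the strict bead and detection thresholds", {
  d <- tiny_set(with_beads = TRUE)
  p <- matrix(0.01, 2, 4, dimnames = dimnames(d$x$M))
  p["s1", "p2"] <- 0.06   # p rule
  p["s2", "p1"] <- 0.05   # boundary: retained
  mask <- qc_filter(d$x, p)
  expect_true(mask["s1", "p3"])    # beads_M = 2 < 3
  expect_true(mask["s1", "p2"])    # p > 0.05
  expect_false(mask["s2", "p1"])   # p == 0.05 retained
  expect_false(mask["s1", "p4"])   # beads == 3 retained
  expect_error(qc_filter(d$x, p[, 1:2]), "shape")

  # without bead counts only the p rule applies
  d2 <- tiny_set(with_beads = FALSE)
  expect_equal(sum(qc_filter(d2$x, p)), 1L)
})

test_that("nmode counts well-separated beta modes", {
  expect_equal(nmode(withr::with_seed(10, rbeta(500, 50, 50))), 1L)
  expect_equal(nmode(withr::with_seed(11, c(rbeta(250, 80, 8), rbeta(250, 8, 80)))), 2L)
  expect_equal(nmode(rep(0.4, 100)), 1L)
  expect_error(nmode(runif(10)), "at least 20")
})

test_that("frequency polygon conserves counts deterministically", {
  fp <- frequency_polygon(c(0.1, 0.9), n_bins = 2, limits = c(0, 1))
  expect_equal(fp$count, c(1L, 1L))
  expect_equal(fp$midpoint, c(0.25, 0.75))
  v <- withr::with_seed(12, runif(500))
  fp2 <- frequency_polygon(v, n_bins = 13, limits = c(0, 1))
  expect_equal(sum(fp2$count), 500L)
  expect_identical(fp2, frequency_polygon(v, n_bins = 13, limits = c(0, 1)))
  expect_error(frequency_polygon(v, n_bins = 1), "n_bins")
})
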