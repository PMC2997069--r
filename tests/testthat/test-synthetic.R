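test_that("generation is fully deterministic given config and seed", {
  cfg <- generator_config(seed = 90, n_loci = 300,
                          features = default_feature_specs(4))
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$profile$values, ds2$profile$values)
  expect_identical(ds1$loci, ds2$loci)
  ds3 <- simulate_dataset(generator_config(seed = 91, n_loci = 300,
                                           features = default_feature_specs(4)))
  expect_false(identical(ds1$profile$values, ds3$profile$values))
})

test_that("generated profiles satisfy the CM profile invariants", {
  ds <- simulate_dataset(generator_config(seed = 92, n_loci = 500))
  expect_silent(chromclose:::validate_profile(ds$profile))
  expect_true(all(ds$profile$values >= 0 & ds$profile$values <= 1))
  expect_true(all(ds$profile$methylation >= 0 & ds$profile$methylation <= 1))
})

test_that("dependency edges control domain co-placement", {
  dep <- data.frame(from = "f01", to = "f02", prob = 1.0)
  cfg <- generator_config(seed = 93, n_loci = 0,
                          features = default_feature_specs(2, n_domains = 150),
                          beta = c(f01 = 0.3),
                          dependency_graph = dep)
  dom <- generate_domains(cfg)
  a <- merge_domains(dom$f01)
  b <- dom$f02
  ctr <- (chromclose:::gr_starts0(b$gr) + chromclose:::gr_ends0(b$gr)) / 2
  ctr_loci <- data.frame(locus_id = seq_along(ctr),
                         chrom = as.character(GenomicRanges::seqnames(b$gr)),
                         start = floor(ctr), end = floor(ctr) + 1,
                         methylation = 0)
  inside <- chromclose::encode_element_all(as_cpg_loci(ctr_loci), a)
  expect_true(all(inside == 1L))

  # prob 0: independent placement; co-overlap rate near the area fraction
  cfg0 <- generator_config(seed = 94, n_loci = 0,
                           features = default_feature_specs(2, n_domains = 400),
                           beta = c(f01 = 0.3),
                           dependency_graph = transform(dep, prob = 0))
  dom0 <- generate_domains(cfg0)
  a0 <- merge_domains(dom0$f01)
  cov_frac <- sum(chromclose:::gr_ends0(a0$gr) -
                    chromclose:::gr_starts0(a0$gr)) / (3 * 1e7)
  ctr0 <- (chromclose:::gr_starts0(dom0$f02$gr) +
             chromclose:::gr_ends0(dom0$f02$gr)) / 2
  loci0 <- as_cpg_loci(data.frame(
    locus_id = seq_along(ctr0),
    chrom = as.character(GenomicRanges::seqnames(dom0$f02$gr)),
    start = floor(ctr0), end = floor(ctr0) + 1, methylation = 0))
  hit_rate <- mean(chromclose::encode_element_all(loci0, a0))
  bounds <- qbinom(c(0.005, 0.995), 400, cov_frac) / 400
  expect_gte(hit_rate, bounds[1])
  expect_lte(hit_rate, bounds[2])

  empty <- generator_config(seed = 95, n_loci = 0,
                            features = list(f01 = list(n_domains = 0,
                                                      length_mean = 5000,
                                                      length_sd = 1000,
                                                      length_min = 200)),
                            beta = c(f01 = 0))
  expect_length(generate_domains(empty)$f01, 0L)
})

test_that("methylation follows the planted linear model", {
  # zero noise, zero betas: every methylation equals clamp(beta0)
  cfg <- generator_config(seed = 96, n_loci = 200, noise_sd = 0,
                          beta = c(f01 = 0), beta0 = 0.7)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$profile$methylation == 0.7))

  # zero noise: regression recovers beta exactly where nothing clamped
  cfg2 <- generator_config(seed = 97, n_loci = 1000, noise_sd = 0,
                           beta = c(f01 = 0.3, f02 = -0.2), beta0 = 0.4)
  ds2 <- simulate_dataset(cfg2)
  expect_equal(ds2$ground_truth$clamped_fraction, 0)
  r <- fit_ols(ds2$profile)
  want <- setNames(numeric(10), sprintf("f%02d", 1:10))
  want[c("f01", "f02")] <- c(0.3, -0.2)
  expect_equal(r$coefficients, want, tolerance = 1e-8)
  expect_equal(r$intercept, 0.4, tolerance = 1e-8)
})

test_that("clamping fraction matches the normal-tail computation", {
  # beta0 = 0.5, noise sd 0.2, betas 0: clamp iff |eps| > 0.5, i.e. 2*Phi(-2.5)
  cfg <- generator_config(seed = 98, n_loci = 5000, noise_sd = 0.2,
                          beta = c(f01 = 0), beta0 = 0.5)
  ds <- simulate_dataset(cfg)
  p_clamp <- 2 * pnorm(-2.5)
  n_clamped <- sum(ds$ground_truth$clamped)
  bounds <- qbinom(c(0.005, 0.995), 5000, p_clamp)
  expect_gte(n_clamped, bounds[1])
  expect_lte(n_clamped, bounds[2])
})

test_that("module structure plants separable CM signatures", {
  ds <- simulate_dataset(two_pattern_config(seed = 99))
  lab <- ds$ground_truth$module_labels
  X <- ds$profile$values
  c1 <- colMeans(X[lab == 1, ])
  c2 <- colMeans(X[lab == 2, ])
  expect_lt(cor(c1, c2), 0.2)
  expect_gt(homogeneity(X[lab == 1, ]), 0.8)
  expect_gt(homogeneity(X[lab == 2, ]), 0.8)

  # one module only
  one <- generator_config(seed = 100, n_loci = 120, module_spec = list(
    list(n_loci = 120, features = c("f01", "f02"))))
  ds1 <- simulate_dataset(one)
  cl <- suppressWarnings(cluster_loci(ds1$profile, 0.5, 10, seed = 1))
  expect_length(cl$modules, 1L)

  # empty feature list: background placement, no planted coherence
  bg <- generator_config(seed = 101, n_loci = 100, module_spec = list(
    list(n_loci = 100, features = character())))
  dsb <- simulate_dataset(bg)
  expect_equal(nrow(dsb$loci), 100L)
})

test_that("signal-matrix generation validates inputs and hits its target", {
  sm <- generate_signal_matrix(diag(3), 10000, seed = 12)
  cc <- cor(t(sm$values))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  expect_error(generate_signal_matrix(diag(3), 0), "n_bins")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  expect_error(generate_signal_matrix(bad, 10), "positive-definite")
  asym <- matrix(c(1, 0.5, 0, 1), 2, 2)
  expect_error(generate_signal_matrix(asym, 10), "symmetric")
})

test_that("write_dataset emits the pipeline's input formats", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(generator_config(seed = 102, n_loci = 50,
                                          features = default_feature_specs(3)))
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "loci.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  beds <- list.files(dir, pattern = "\\.bed$")
  expect_length(beds, 3L)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(unlist(gt$informative_features),
               ds$ground_truth$informative_features)
  reread <- read_bed(file.path(dir, "f01.bed"))
  expect_equal(length(reread), length(ds$domains$f01))
  loci2 <- read_loci(file.path(dir, "loci.tsv"))
  expect_equal(loci2$methylation, ds$loci$methylation, tolerance = 1e-12)
})
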