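test_that("closeness matches hand-evaluated cases", {
  d <- merge_domains(domain_set("chr1", 100, 200))
  # midpoint at the domain centre -> maximum
  expect_equal(closeness(locus_at(150), d), 1.0)
  # no overlapping domain -> boundary value 0
  expect_equal(closeness(locus_at(501), d), 0.0)
  # domain m = 100, c = 150; locus midpoint 175 -> 1 - 2*25/100 = 0.5
  expect_equal(closeness(locus_at(175), d), 0.5)
  # straddling the edge with 1 bp overlap: midpoint 200 -> clamp to 0
  expect_equal(closeness(genomic_interval("chr1", 199, 201), d), 0.0)
  expect_error(closeness(locus_at(150), domain_set("chr1", 100, 200)),
               "merged")
})

test_that("closeness is linear in |x - c| and symmetric about the centre", {
  d <- merge_domains(domain_set("chr1", 1000, 2000))
  # brute-force oracle: evaluate at every offset, compare to the linear form
  for (delta in seq(0, 480, by = 40)) {
    lhs <- closeness(locus_at(1500 + delta), d)
    rhs <- closeness(locus_at(1500 - delta), d)
    expect_equal(lhs, rhs)
    expect_equal(lhs, 1 - 2 * delta / 1000)
  }
})

test_that("closeness properties hold on random fixtures", {
  set.seed(99)
  for (rep in 1:200) {
    m <- sample(50:5000, 1)
    s <- sample(0:10000, 1)
    d <- merge_domains(domain_set("chrR", s, s + m))
    ctr <- s + m / 2
    x <- sample(1:20000, 1)
    v <- closeness(locus_at(x), d)
    expect_gte(v, 0)
    expect_lte(v, 1)
    inside <- (x + 1) > s && (x - 1) < (s + m)  # >= 1 bp overlap
    if (!inside) expect_identical(v, 0)
    # monotone in |x - c|: value at a point closer to the centre is >= v
    x2 <- ctr + (x - ctr) / 2
    expect_gte(closeness(locus_at(round(x2)), d) + 1e-12, v)
    # scale invariance: double m and the midpoint distance together
    d2 <- merge_domains(domain_set("chrR", 2 * s, 2 * s + 2 * m))
    x_in <- round(ctr + max(-m / 2 + 1, min(m / 2 - 1, x - ctr)))
    v_in <- closeness(locus_at(x_in), d)
    v_scaled <- closeness(locus_at(2 * s + m + 2 * (x_in - ctr)), d2)
    expect_equal(v_scaled, v_in, tolerance = 1e-9)
  }
})

test_that("encode_element applies the >= 1 bp overlap rule", {
  el <- domain_set("chr1", 100, 200)
  expect_equal(encode_element(locus_at(151), el), 1L)
  expect_equal(encode_element(locus_at(251), el), 0L)
  expect_equal(encode_element(genomic_interval("chr1", 199, 201), el), 1L)
  expect_equal(encode_element(genomic_interval("chr1", 200, 202), el), 0L)
})

test_that("build_profile composes closeness and element encoding entry-wise", {
  loci <- as_cpg_loci(data.frame(
    locus_id = c("a", "b", "c"), chrom = "chr1",
    start = c(149, 449, 4999), end = c(151, 451, 5001),
    methylation = c(0.8, 0.2, 0.5)))
  cm1 <- merge_domains(domain_set("chr1", c(100, 400), c(200, 500),
                                  feature_name = "mark1"))
  cm2 <- merge_domains(domain_set("chr1", 140, 160, feature_name = "mark2"))
  cgi <- domain_set("chr1", 440, 460, feature_name = "cgi")
  p <- build_profile(loci, list(cm1, cm2), list(cgi))
  expect_equal(dim(p), c(3L, 3L))
  expect_equal(p$feature_names, c("mark1", "mark2", "cgi"))
  expect_equal(p$binary_features, "cgi")
  # entry-wise oracle via the single-pair functions
  for (i in 1:3) {
    li <- loci[i, ]
    expect_equal(unname(p$values[i, "mark1"]), closeness(li, cm1))
    expect_equal(unname(p$values[i, "mark2"]), closeness(li, cm2))
    expect_equal(unname(p$values[i, "cgi"]),
                 as.numeric(encode_element(li, cgi)))
  }
  expect_equal(p$methylation, loci$methylation)
  # centred locus in a binary element: row [1, 1, M]
  expect_equal(unname(p$values["b" == p$locus_ids, ]), c(1, 0, 1))

  empty <- build_profile(loci[0, ], list(cm1), list(cgi))
  expect_equal(dim(empty), c(0L, 2L))

  clash <- merge_domains(domain_set("chr1", 1, 5, feature_name = "cgi"))
  expect_error(build_profile(loci, list(clash), list(cgi)), "collision")
  expect_error(build_profile(loci, list(domain_set("chr1", 1, 5))),
               "not merged")
})

test_that("entry-wise equality holds on random fixtures", {
  set.seed(7)
  cfg <- generator_config(seed = 5, n_loci = 100,
                          features = default_feature_specs(4, n_domains = 60))
  ds <- simulate_dataset(cfg)
  p <- ds$profile
  idx <- sample(nrow(ds$loci), 20)
  for (i in idx) {
    for (nm in p$feature_names) {
      expect_equal(unname(p$values[i, nm]),
                   closeness(ds$loci[i, ], ds$merged[[nm]]))
    }
  }
})

test_that("profile TSV round-trip is lossless and validated", {
  set.seed(11)
  vals <- cbind(matrix(runif(12), 4, 3), bin = c(0, 1, 1, 0))
  colnames(vals)[1:3] <- c("a", "b", "c")
  p <- make_profile(vals, methylation = runif(4), binary = "bin")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(q$values, p$values, tolerance = 1e-10)
  expect_equal(q$methylation, p$methylation, tolerance = 1e-10)
  expect_equal(q$binary_features, "bin")
  expect_equal(q$locus_ids, p$locus_ids)

  # binary column with a non-binary value must be rejected on read
  lines <- readLines(f)
  lines[3] <- sub("([01]\\.0{10})(\t[^\t]*)$", "0.5000000000\\2", lines[3])
  writeLines(lines, f)
  expect_error(read_profile(f), "non-binary")

  empty <- make_profile(matrix(numeric(), 0, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        methylation = numeric())
  write_profile(empty, f)
  expect_equal(dim(read_profile(f)), c(0L, 2L))
})

test_that("profile constructor enforces the 0-1 scale", {
  expect_error(make_profile(matrix(c(0.5, 1.2), 1, 2)), "outside")
  expect_error(make_profile(matrix(c(0.5, 0.5), 1, 2),
                            methylation = 1.4), "outside")
  expect_error(make_profile(matrix(c(0.5, 0.5), 1, 2), binary = "f1"),
               "non-binary")
})
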