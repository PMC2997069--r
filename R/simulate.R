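#' Configuration for the synthetic-data generator
#'
#' Bundles everything the generator needs to draw a genome of chromatin
#' domains, CpG loci and methylation with known ground truth.  The defaults
#' describe a desk-scale genome that emulates the structure the pipeline
#' consumes in practice: a few chromosomes, MACS-like domains of variable
#' length covering roughly 15% of the genome per feature, 2-bp CpG loci at
#' uniform positions, and methylation generated from the linear CM model
#' \deqn{M_i = clamp(\beta_0 + \sum_j \beta_j CM_{ij} + \epsilon_i,\ 0,\ 1)}
#' with Gaussian noise.
#'
#' @param seed Integer master seed.
#' @param n_chroms,chrom_length Genome shape (default 3 chromosomes of
#'   10 Mb).
#' @param n_loci Number of CpG loci (default 5000).
#' @param features Named list of per-feature domain specs, each a list with
#'   `n_domains`, `length_mean`, `length_sd`, `length_min`.  The default is
#'   10 features (`f01`..`f10`) with 500 domains each, truncated-normal
#'   lengths (mean 8000, sd 3000, min 200 bp).
#' @param beta0 Planted intercept (default 0.3).
#' @param beta Named numeric of planted coefficients per feature; features
#'   absent from `beta` get 0.  `NULL` (the default) plants the standard
#'   set: coefficients 0.5, -0.4, 0.35, 0.3, -0.3 on the first five
#'   features (fewer when fewer exist), the rest null.
#' @param noise_sd Gaussian methylation noise sd (default 0.05).
#' @param dependency_graph Data frame `from`, `to`, `prob`: for each row, a
#'   fraction `prob` of `to`'s domains are re-centered inside a uniformly
#'   chosen domain of `from`, planting a pairwise co-occurrence dependency.
#' @param module_spec Optional list of module specs (each a list with
#'   `n_loci` and `features`, the feature names whose domains the module's
#'   loci preferentially occupy) for [generate_module_structure()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_chroms = 3L, chrom_length = 1e7,
                             n_loci = 5000L,
                             features = default_feature_specs(),
                             beta0 = 0.3,
                             beta = NULL,
                             noise_sd = 0.05,
                             dependency_graph = NULL,
                             module_spec = NULL) {
  if (is.null(beta)) {
    # standard plant: five informative features (or as many as exist)
    std <- c(0.5, -0.4, 0.35, 0.3, -0.3)
    k <- min(5L, length(features))
    beta <- setNames(std[seq_len(k)], names(features)[seq_len(k)])
  }
  stopifnot(n_chroms >= 1L, chrom_length > 0, n_loci >= 0L, noise_sd >= 0,
            all(is.finite(beta)), is.finite(beta0))
  bad <- setdiff(names(beta), names(features))
  if (length(bad)) stop("beta names not in features: ",
                        paste(bad, collapse = ", "))
  if (!is.null(dependency_graph)) {
    stopifnot(all(c("from", "to", "prob") %in% names(dependency_graph)))
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = chrom_length, n_loci = as.integer(n_loci),
                 features = features, beta0 = beta0, beta = beta,
                 noise_sd = noise_sd, dependency_graph = dependency_graph,
                 module_spec = module_spec),
            class = "generator_config")
}

#' Default per-feature domain specifications
#'
#' @param n_features Number of CM features (default 10).
#' @param n_domains,length_mean,length_sd,length_min Shared domain spec.
#' @return Named list of feature specs for [generator_config()].
#' @export
default_feature_specs <- function(n_features = 10L, n_domains = 500L,
                                  length_mean = 8000, length_sd = 3000,
                                  length_min = 200) {
  specs <- replicate(n_features, list(n_domains = n_domains,
                                      length_mean = length_mean,
                                      length_sd = length_sd,
                                      length_min = length_min),
                     simplify = FALSE)
  names(specs) <- sprintf("f%02d", seq_len(n_features))
  specs
}

chrom_names <- function(cfg) sprintf("chrS%d", seq_len(cfg$n_chroms))

# Truncated-normal domain lengths.
draw_lengths <- function(n, spec) {
  len <- round(rnorm(n, spec$length_mean, spec$length_sd))
  pmax(len, spec$length_min)
}

#' Generate per-feature domain sets
#'
#' Places each feature's domains uniformly on the genome with
#' truncated-normal lengths.  For every dependency edge `(from, to, prob)`,
#' a fraction `prob` of `to`'s domains is re-centered at a uniform position
#' inside a uniformly chosen `from` domain, inducing CM co-elevation between
#' the two features.  Deterministic given the config seed.
#'
#' @param cfg A [generator_config()].
#' @return Named list of unmerged [domain_set()]s.
#' @export
generate_domains <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(derive_seed(cfg$seed, 101L), {
    chroms <- chrom_names(cfg)
    out <- list()
    for (nm in names(cfg$features)) {
      spec <- cfg$features[[nm]]
      n <- spec$n_domains
      if (n == 0L) {
        out[[nm]] <- domain_set(feature_name = nm)
        next
      }
      len <- draw_lengths(n, spec)
      if (any(len > cfg$chrom_length)) {
        stop("domain length exceeds chromosome length for feature ", nm)
      }
      chr <- sample(chroms, n, replace = TRUE)
      start <- floor(runif(n, 0, cfg$chrom_length - len))
      out[[nm]] <- domain_set(chr, start, start + len, feature_name = nm)
    }
    dg <- cfg$dependency_graph
    if (!is.null(dg)) {
      for (e in seq_len(nrow(dg))) {
        from <- as.character(dg$from[e])
        to <- as.character(dg$to[e])
        p <- dg$prob[e]
        src <- out[[from]]$gr
        tgt <- out[[to]]
        if (!length(src) || !length(tgt$gr)) next
        n_to <- length(tgt$gr)
        pick <- which(runif(n_to) < p)
        if (!length(pick)) next
        chr <- as.character(GenomicRanges::seqnames(tgt$gr))
        st <- gr_starts0(tgt$gr)
        en <- gr_ends0(tgt$gr)
        for (k in pick) {
          len_k <- en[k] - st[k]
          a <- sample.int(length(src), 1L)
          ctr <- floor(runif(1, gr_starts0(src)[a], gr_ends0(src)[a]))
          new_start <- max(0, min(cfg$chrom_length - len_k,
                                  ctr - floor(len_k / 2)))
          chr[k] <- as.character(GenomicRanges::seqnames(src)[a])
          st[k] <- new_start
          en[k] <- new_start + len_k
        }
        out[[to]] <- domain_set(chr, st, en, feature_name = to)
      }
    }
    out
  })
}

#' Generate CpG loci at uniform positions
#'
#' 2-bp CpG-dinucleotide-like loci at uniformly drawn positions, with a
#' placeholder methylation of 0 (filled by [generate_methylation()]).
#'
#' @param cfg A [generator_config()].
#' @return A `cpg_loci` data frame.
#' @export
generate_loci <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(derive_seed(cfg$seed, 102L), {
    n <- cfg$n_loci
    chr <- sample(chrom_names(cfg), n, replace = TRUE)
    start <- floor(runif(n, 0, cfg$chrom_length - 2))
    as_cpg_loci(data.frame(
      locus_id = sprintf("cpg%06d", seq_len(n)),
      chrom = chr, start = start, end = start + 2, methylation = 0
    ))
  })
}

#' Generate methylation from the planted linear CM model
#'
#' Computes each locus's CM against the merged domains of every feature and
#' draws
#' `M_i = clamp(beta0 + sum_j beta_j CM_ij + eps_i, 0, 1)` with
#' `eps_i ~ N(0, noise_sd)`.  The fraction and indices of clamped loci are
#' reported so recovery analyses can condition on unclamped loci, where the
#' model is exactly linear.
#'
#' @param cfg A [generator_config()].
#' @param loci A `cpg_loci` data frame.
#' @param domain_sets Named list of [domain_set()]s (merged internally).
#' @return List with `loci` (methylation filled in), `clamped` (logical
#'   vector), `clamped_fraction`, and `cm` (the N x f CM matrix used).
#' @export
generate_methylation <- function(cfg, loci, domain_sets) {
  stopifnot(inherits(cfg, "generator_config"))
  merged <- lapply(domain_sets, merge_domains)
  cm <- vapply(names(merged),
               function(nm) closeness_all(loci, merged[[nm]]),
               numeric(nrow(loci)))
  if (nrow(loci) == 1L) cm <- matrix(cm, nrow = 1L,
                                     dimnames = list(NULL, names(merged)))
  beta <- setNames(numeric(length(merged)), names(merged))
  beta[names(cfg$beta)] <- cfg$beta
  lin <- cfg$beta0 + drop(cm %*% beta)
  eps <- with_seed(derive_seed(cfg$seed, 103L),
                   rnorm(nrow(loci), 0, cfg$noise_sd))
  raw <- lin + eps
  m <- pmin(1, pmax(0, raw))
  loci$methylation <- m
  list(loci = as_cpg_loci(loci), clamped = raw != m,
       clamped_fraction = mean(raw != m), cm = cm)
}

#' Generate loci and domains with planted module structure
#'
#' Plants one chromatin signature per module spec.  For every module a set
#' of anchor sites is drawn (roughly one per 25 module loci); at each anchor
#' every feature in the module's list receives one additional domain centred
#' on the site, so the module's features co-occur there.  The module's loci
#' are then placed near anchor centres (midpoint offset uniform within 5% of
#' the shortest co-occurring domain's half-length), giving them high CM
#' values for all module features simultaneously and near-zero CM elsewhere
#' except for background overlap — distinct, internally coherent CM
#' signatures per module.  Modules with an empty feature list place loci
#' uniformly (background).
#'
#' @param cfg A [generator_config()] with non-NULL `module_spec`.
#' @param domain_sets Named list of [domain_set()]s from
#'   [generate_domains()]; anchor domains are appended to these.
#' @return List with `loci` (a `cpg_loci` data frame), `domains` (the
#'   augmented domain sets), and `module_labels` (integer vector, one per
#'   locus).
#' @export
generate_module_structure <- function(cfg, domain_sets) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(cfg$module_spec)) stop("cfg$module_spec is required")
  with_seed(derive_seed(cfg$seed, 104L), {
    extra <- lapply(domain_sets, function(d) NULL)
    rows <- list()
    labels <- integer()
    for (mi in seq_along(cfg$module_spec)) {
      spec <- cfg$module_spec[[mi]]
      n <- spec$n_loci
      feats <- spec$features %||% character()
      if (!length(feats)) {
        chr <- sample(chrom_names(cfg), n, replace = TRUE)
        start <- floor(runif(n, 0, cfg$chrom_length - 2))
        rows[[mi]] <- data.frame(chrom = chr, start = start, end = start + 2)
        labels <- c(labels, rep(mi, n))
        next
      }
      n_anchor <- max(5L, ceiling(n / 25))
      a_chr <- sample(chrom_names(cfg), n_anchor, replace = TRUE)
      margin <- max(vapply(cfg$features[feats],
                           function(s) s$length_mean + 4 * s$length_sd,
                           numeric(1)))
      a_pos <- floor(runif(n_anchor, margin, cfg$chrom_length - margin))
      min_len <- rep(Inf, n_anchor)
      for (f in feats) {
        len <- draw_lengths(n_anchor, cfg$features[[f]])
        min_len <- pmin(min_len, len)
        st <- pmax(0, a_pos - floor(len / 2))
        extra[[f]] <- rbind(extra[[f]],
                            data.frame(chrom = a_chr, start = st,
                                       end = st + len))
      }
      pick <- sample.int(n_anchor, n, replace = TRUE)
      off <- round(runif(n, -0.05, 0.05) * min_len[pick] / 2)
      pos <- pmax(0, pmin(cfg$chrom_length - 2, a_pos[pick] + off - 1))
      rows[[mi]] <- data.frame(chrom = a_chr[pick], start = pos,
                               end = pos + 2)
      labels <- c(labels, rep(mi, n))
    }
    for (f in names(extra)) {
      if (is.null(extra[[f]])) next
      old <- domain_sets[[f]]
      domain_sets[[f]] <- domain_set(
        c(as.character(GenomicRanges::seqnames(old$gr)), extra[[f]]$chrom),
        c(gr_starts0(old$gr), extra[[f]]$start),
        c(gr_ends0(old$gr), extra[[f]]$end),
        feature_name = f)
    }
    df <- do.call(rbind, rows)
    df <- data.frame(locus_id = sprintf("cpg%06d", seq_len(nrow(df))), df,
                     methylation = 0)
    list(loci = as_cpg_loci(df), domains = domain_sets,
         module_labels = labels)
  })
}

#' Generate a Gaussian signal matrix from a known precision matrix
#'
#' Multivariate Gaussian draws with covariance `solve(precision)`, arranged
#' features x bins — the oracle input for [partial_correlations()], whose
#' expected value is the closed form `-P_ij / sqrt(P_ii P_jj)`.
#'
#' @param precision Symmetric positive-definite precision matrix; row names
#'   become feature names.
#' @param n_bins Number of bins (columns); must be >= 1.
#' @param seed Integer seed.
#' @return A [signal_matrix()].
#' @export
generate_signal_matrix <- function(precision, n_bins, seed = 1L) {
  precision <- as.matrix(precision)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (!isTRUE(all.equal(precision, t(precision)))) {
    stop("precision must be symmetric")
  }
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision must be positive-definite")
  Sigma <- solve(precision)
  draws <- with_seed(seed,
                     MASS::mvrnorm(n_bins, mu = rep(0, nrow(precision)),
                                   Sigma = Sigma))
  values <- t(draws)
  rownames(values) <- rownames(precision) %||%
    paste0("f", seq_len(nrow(precision)))
  signal_matrix(values)
}

#' Generate a complete synthetic dataset
#'
#' Runs the generator end to end: domains, loci (module-structured when
#' `cfg$module_spec` is given, uniform otherwise), planted-model
#' methylation, and the assembled CM profile; byte-identical for identical
#' config and seed.
#'
#' @param cfg A [generator_config()].
#' @return List of class `cm_dataset`: `loci`, `domains` (unmerged),
#'   `merged` (merged domain sets), `profile` (a [cm_profile()]), and
#'   `ground_truth` (`beta0`, `beta`, `informative_features`,
#'   `dependency_edges`, `module_labels`, `clamped_fraction`, `clamped`).
#' @export
simulate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  domains <- generate_domains(cfg)
  module_labels <- NULL
  if (!is.null(cfg$module_spec)) {
    ms <- generate_module_structure(cfg, domains)
    loci <- ms$loci
    domains <- ms$domains
    module_labels <- ms$module_labels
  } else {
    loci <- generate_loci(cfg)
  }
  meth <- generate_methylation(cfg, loci, domains)
  merged <- lapply(domains, merge_domains)
  profile <- build_profile(meth$loci, merged)
  beta_full <- setNames(numeric(length(domains)), names(domains))
  beta_full[names(cfg$beta)] <- cfg$beta
  structure(list(
    loci = meth$loci, domains = domains, merged = merged, profile = profile,
    ground_truth = list(
      beta0 = cfg$beta0, beta = beta_full,
      informative_features = names(beta_full)[beta_full != 0],
      dependency_edges = cfg$dependency_graph,
      module_labels = module_labels,
      clamped_fraction = meth$clamped_fraction,
      clamped = meth$clamped
    )), class = "cm_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Emits the same plain-text formats the pipeline reads — one BED3 per
#' feature, the loci TSV, the profile TSV — plus a `ground_truth.json`
#' sidecar.
#'
#' @param ds A `cm_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cm_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ds$domains)) {
    write_bed(ds$domains[[nm]], file.path(dir, paste0(nm, ".bed")))
  }
  write_loci(ds$loci, file.path(dir, "loci.tsv"))
  write_profile(ds$profile, file.path(dir, "profile.tsv"))
  gt <- ds$ground_truth
  gt$clamped <- NULL  # bulky per-locus vector; fraction is retained
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
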