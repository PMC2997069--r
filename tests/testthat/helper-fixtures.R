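# Shared fixtures, built in code.

# One-row locus table around a midpoint x (2 bp locus).
locus_at <- function(x, chrom = "chr1", id = "q") {
  data.frame(locus_id = id, chrom = chrom, start = x - 1, end = x + 1,
             methylation = 0)
}

# Small profile from an explicit matrix.
make_profile <- function(values, methylation = NULL, binary = character()) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(methylation)) methylation <- rep(0.5, nrow(values))
  cm_profile(values, methylation, sprintf("L%03d", seq_len(nrow(values))),
             binary_features = binary)
}

# Wrap a 0/1 matrix as a binary_profile for the network learner.
make_binary_profile <- function(data) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  structure(list(locus_ids = as.character(seq_len(nrow(data))),
                 variable_names = colnames(data),
                 values = data, degenerate = character()),
            class = "binary_profile")
}

# Sample binary data from a small DAG with explicit conditional
# probabilities.  `cpds` is a named list: for each variable, either a single
# marginal P(X=1) or a function(parent_matrix) -> P(X=1) per row.
# `order` must be a topological order.
sample_bn <- function(n, order, cpds, seed) {
  set.seed(seed)
  out <- matrix(0L, n, length(order), dimnames = list(NULL, order))
  for (v in order) {
    p <- cpds[[v]]
    prob <- if (is.function(p)) p(out) else rep(p, n)
    out[, v] <- rbinom(n, 1L, prob)
  }
  out
}

# Strong-CPD chain X -> Y -> Z.
sample_chain <- function(n, seed, hi = 0.9) {
  sample_bn(n, c("X", "Y", "Z"), list(
    X = 0.5,
    Y = function(d) ifelse(d[, "X"] == 1, hi, 1 - hi),
    Z = function(d) ifelse(d[, "Y"] == 1, hi, 1 - hi)
  ), seed)
}

# Collider X -> Z <- Y with X independent of Y.
sample_collider <- function(n, seed, hi = 0.9) {
  sample_bn(n, c("X", "Y", "Z"), list(
    X = 0.5, Y = 0.5,
    Z = function(d) ifelse(d[, "X"] == d[, "Y"],
                           ifelse(d[, "X"] == 1, hi, 1 - hi), 0.5)
  ), seed)
}

# Enumerate all DAG adjacency matrices on `v` labelled nodes (v small).
all_dags <- function(v) {
  pairs <- which(upper.tri(matrix(0, v, v)), arr.ind = TRUE)
  n_pair <- nrow(pairs)
  out <- list()
  # each unordered pair is absent / i->j / j->i
  states <- expand.grid(rep(list(0:2), n_pair))
  for (r in seq_len(nrow(states))) {
    a <- matrix(0L, v, v)
    for (k in seq_len(n_pair)) {
      s <- states[r, k]
      if (s == 1) a[pairs[k, 1], pairs[k, 2]] <- 1L
      if (s == 2) a[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    if (!chromclose:::has_cycle(a)) out[[length(out) + 1L]] <- a
  }
  out
}

# Exhaustive-enumeration optimum of the BDeu score over all DAGs on the
# columns of `data` (independent of the greedy search path).
exhaustive_best_score <- function(data, ess = 1) {
  v <- ncol(data)
  best <- -Inf
  for (a in all_dags(v)) {
    s <- chromclose:::score_dag(data, a, ess)
    if (s > best) best <- s
  }
  best
}

# Two-pattern planted-module config for clustering benchmarks.
two_pattern_config <- function(seed, n_per = 200L) {
  generator_config(seed = seed, n_loci = 2L * n_per, module_spec = list(
    list(n_loci = n_per, features = c("f01", "f02", "f03")),
    list(n_loci = n_per, features = c("f06", "f07", "f08"))
  ))
}

# Adjusted Rand index (independent of any clustering code under test).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
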