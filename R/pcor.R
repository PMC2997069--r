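#' Signal matrix constructor
#'
#' A features x bins matrix of per-bin signal (e.g. ChIP-seq tag counts in
#' fixed genomic windows), the input for partial-correlation validation.
#'
#' @param values Features x bins numeric matrix; row names are feature
#'   names, column names bin ids (filled in when absent).
#' @return Object of class `signal_matrix`.
#' @export
signal_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("bin", seq_len(ncol(values)))
  }
  if (nrow(values) < 2L) stop("need >= 2 features")
  if (ncol(values) < nrow(values) + 2L) {
    stop("need >= features + 2 bins")
  }
  const <- rownames(values)[apply(values, 1L, function(v) max(v) == min(v))]
  if (length(const)) {
    stop("constant feature row(s): ", paste(const, collapse = ", "))
  }
  structure(list(feature_names = rownames(values),
                 bin_ids = colnames(values), values = values),
            class = "signal_matrix")
}

#' Read a signal matrix from TSV
#'
#' Layout: header row of bin ids, one row per feature with the feature name
#' in the first column.
#'
#' @param path Input path.
#' @return A [signal_matrix()].
#' @export
read_signal_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  signal_matrix(as.matrix(df))
}

#' Write a signal matrix to TSV
#'
#' @param m A [signal_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(m, path) {
  stopifnot(inherits(m, "signal_matrix"))
  df <- data.frame(feature = m$feature_names, m$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full-order partial correlations between features
#'
#' Partial correlation of every feature pair controlling for all remaining
#' features, from the inverse of the feature correlation matrix `P`:
#' \deqn{pcor(i, j) = -P_{ij} / \sqrt{P_{ii} P_{jj}}}
#' Because tag counts are heavy-tailed, each feature row is rank-normalized
#' before correlation by default (so the underlying correlation is
#' Spearman's); set `rank_normalize = FALSE` for raw Pearson.  A singular
#' correlation matrix is an error unless `ridge > 0` adds a diagonal
#' regularizer.
#'
#' @param m A [signal_matrix()].
#' @param rank_normalize Rank-transform each feature row first (default
#'   TRUE).
#' @param ridge Non-negative ridge added to the correlation diagonal
#'   (default 0 = off).
#' @return Object of class `pcor_result` with `pcor` (symmetric matrix,
#'   unit diagonal) and the options used.
#' @export
partial_correlations <- function(m, rank_normalize = TRUE, ridge = 0) {
  stopifnot(inherits(m, "signal_matrix"))
  X <- m$values
  if (rank_normalize) X <- t(apply(X, 1L, rank))
  R <- cor(t(X))
  if (ridge > 0) R <- R + diag(ridge, nrow(R))
  P <- tryCatch(solve(R), error = function(e) {
    stop("singular correlation matrix; consider the ridge option ",
         "(ridge > 0 adds a diagonal regularizer)")
  })
  D <- sqrt(diag(P))
  pc <- -P / outer(D, D)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2  # enforce exact symmetry against round-off
  dimnames(pc) <- list(m$feature_names, m$feature_names)
  structure(list(pcor = pc, rank_normalize = rank_normalize, ridge = ridge),
            class = "pcor_result")
}

#' @export
print.pcor_result <- function(x, ...) {
  cat("pcor_result:", nrow(x$pcor), "features",
      if (x$rank_normalize) "(rank-normalized)" else "(raw)", "\n")
  print(round(x$pcor, 3))
  invisible(x)
}

pair_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Compare discovered pairs against the rest by partial correlation
#'
#' Tests whether the discovered feature pairs have larger absolute partial
#' correlations than the remaining pairs: a one-sided Wilcoxon rank-sum test
#' (`rank_sum_p`), plus a permutation control that shuffles each feature
#' row's bins independently (destroying cross-feature dependence while
#' preserving marginals), recomputes the rank-sum statistic, and reports the
#' add-one empirical p-value of the observed statistic (`permutation_p`).
#'
#' @param m A [signal_matrix()].
#' @param discovered_pairs Two-column matrix or data frame of feature-name
#'   pairs.
#' @param n_perm Number of permutation datasets (default 100).
#' @param seed Integer seed.
#' @param rank_normalize,ridge Passed to [partial_correlations()].
#' @return List with `rank_sum_p`, `permutation_p`, `observed_statistic`,
#'   and the discovered/other absolute partial correlations.
#' @export
compare_discovered <- function(m, discovered_pairs, n_perm = 100L, seed = 1L,
                               rank_normalize = TRUE, ridge = 0) {
  stopifnot(inherits(m, "signal_matrix"))
  dp <- as.matrix(discovered_pairs)
  if (ncol(dp) != 2L || !nrow(dp)) stop("discovered_pairs must be pairs")
  bad <- setdiff(c(dp), m$feature_names)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  dkeys <- unique(pair_keys(dp[, 1L], dp[, 2L]))
  cmb <- t(utils::combn(m$feature_names, 2L))
  akeys <- pair_keys(cmb[, 1L], cmb[, 2L])
  okeys <- setdiff(akeys, dkeys)
  if (!length(okeys)) stop("discovered set covers all pairs; empty complement")

  abs_pcor <- function(values) {
    mm <- m
    mm$values <- values
    pc <- partial_correlations(mm, rank_normalize = rank_normalize,
                               ridge = ridge)$pcor
    setNames(abs(pc[cbind(cmb[, 1L], cmb[, 2L])]), akeys)
  }
  obs <- abs_pcor(m$values)
  wt <- wilcox.test(obs[dkeys], obs[okeys], alternative = "greater",
                    exact = FALSE)
  obs_stat <- unname(wt$statistic)
  perm_stats <- with_seed(derive_seed(seed, 1L),
    vapply(seq_len(n_perm), function(i) {
      v <- m$values
      for (r in seq_len(nrow(v))) v[r, ] <- v[r, sample.int(ncol(v))]
      pv <- abs_pcor(v)
      unname(suppressWarnings(
        wilcox.test(pv[dkeys], pv[okeys], alternative = "greater",
                    exact = FALSE)$statistic))
    }, numeric(1)))
  list(rank_sum_p = wt$p.value,
       permutation_p = (1 + sum(perm_stats >= obs_stat)) / (1 + n_perm),
       observed_statistic = obs_stat,
       discovered_abs_pcor = obs[dkeys],
       other_abs_pcor = obs[okeys])
}
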