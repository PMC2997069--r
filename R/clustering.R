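#' Homogeneity of a set of profile rows
#'
#' Mean Pearson correlation between each row and the centroid (column mean)
#' of the rows.  A row or centroid with zero variance has no defined
#' correlation; its contribution is treated as 0 with a warning.
#'
#' @param rows Numeric matrix, one profile row per locus (>= 2 rows).
#' @return A single homogeneity value in \[-1, 1\].
#' @export
homogeneity <- function(rows) {
  rows <- as.matrix(rows)
  stopifnot(nrow(rows) >= 2L)
  centroid <- colMeans(rows)
  mean(row_centroid_cor(rows, centroid))
}

# Per-row Pearson correlation to a fixed centroid; zero-variance rows (or a
# zero-variance centroid) contribute 0 with a warning.
row_centroid_cor <- function(rows, centroid) {
  n <- nrow(rows)
  if (sd(centroid) == 0) {
    warning("zero-variance centroid; correlations treated as 0")
    return(numeric(n))
  }
  rv <- apply(rows, 1L, sd)
  out <- numeric(n)
  ok <- rv > 0
  if (any(!ok)) warning("zero-variance row(s); correlation treated as 0")
  if (any(ok)) {
    out[ok] <- drop(cor(t(rows[ok, , drop = FALSE]), centroid))
  }
  out
}

#' Cluster CpG loci into homogeneity-based modules
#'
#' Partitions loci into modules from their CM feature profiles (the
#' methylation column is never part of the clustering vector), with an
#' unclustered remainder.  The procedure is agglomerative: average-linkage
#' hierarchical clustering on the Pearson-correlation distance `1 - r`
#' between profile rows, followed by a top-down walk of the dendrogram that
#' splits any cluster whose homogeneity (mean row-to-centroid correlation,
#' see [homogeneity()]) falls below `homogeneity_threshold`.  Accepted
#' clusters smaller than `min_size` are dissolved; their loci (and
#' zero-variance rows, which have no defined correlation) are reassigned to
#' the best-correlated module when the module still meets the threshold
#' after the addition, otherwise left unclustered.  Modules are numbered by
#' decreasing size.  The procedure is deterministic for a given input; the
#' `seed` argument is accepted for interface stability and recorded in the
#' result.
#'
#' @param profile A [cm_profile()].
#' @param homogeneity_threshold Minimum module homogeneity, in (0, 1\].
#' @param min_size Minimum module size (default 10).
#' @param seed Integer seed, recorded for provenance.
#' @param features Optional character vector restricting the clustering to a
#'   feature subset (e.g. the selected features).
#' @return Object of class `cm_clustering`: `modules` (list of
#'   `module_id`, `member_ids`, `homogeneity`), `unclustered` (locus ids),
#'   and `assignments` (named integer vector; 0 = unclustered).
#' @export
cluster_loci <- function(profile, homogeneity_threshold = 0.5,
                         min_size = 10L, seed = 1L, features = NULL) {
  if (homogeneity_threshold <= 0 || homogeneity_threshold > 1) {
    stop("homogeneity_threshold must be in (0, 1]")
  }
  validate_profile(profile)
  X <- profile_matrix(profile, features)
  if (ncol(X) < 2L) stop("need at least 2 feature columns to cluster")
  ids <- profile$locus_ids
  n <- nrow(X)
  rv <- apply(X, 1L, function(v) max(v) - min(v))
  valid <- which(rv > 0)
  member_sets <- list()
  if (length(valid) >= 2L) {
    Xv <- X[valid, , drop = FALSE]
    cm <- suppressWarnings(cor(t(Xv)))
    cm[!is.finite(cm)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    member_sets <- split_by_homogeneity(hc, Xv, homogeneity_threshold)
    member_sets <- lapply(member_sets, function(i) valid[i])
  } else if (length(valid) == 1L) {
    member_sets <- list(valid)
  }
  keep <- vapply(member_sets, length, integer(1)) >= min_size
  modules <- member_sets[keep]
  leftovers <- c(unlist(member_sets[!keep]), setdiff(seq_len(n), valid))
  # Reassign leftovers to the best module that still meets the threshold.
  unclustered <- integer()
  for (i in sort(leftovers)) {
    placed <- FALSE
    if (length(modules) && rv[i] > 0) {
      cors <- vapply(modules, function(m) {
        ctr <- colMeans(X[m, , drop = FALSE])
        if (sd(ctr) == 0) return(-Inf)
        suppressWarnings(cor(X[i, ], ctr))
      }, numeric(1))
      for (j in order(cors, decreasing = TRUE)) {
        if (!is.finite(cors[j])) break
        cand <- c(modules[[j]], i)
        h <- suppressWarnings(homogeneity(X[cand, , drop = FALSE]))
        if (h >= homogeneity_threshold) {
          modules[[j]] <- cand
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) unclustered <- c(unclustered, i)
  }
  ord <- order(vapply(modules, length, integer(1)), decreasing = TRUE)
  modules <- modules[ord]
  assignments <- setNames(integer(n), ids)
  mod_list <- vector("list", length(modules))
  for (k in seq_along(modules)) {
    m <- sort(modules[[k]])
    assignments[m] <- k
    mod_list[[k]] <- list(
      module_id = k,
      member_ids = ids[m],
      homogeneity = suppressWarnings(homogeneity(X[m, , drop = FALSE]))
    )
  }
  structure(list(modules = mod_list,
                 unclustered = ids[sort(unclustered)],
                 assignments = assignments,
                 threshold = homogeneity_threshold,
                 min_size = as.integer(min_size),
                 seed = seed),
            class = "cm_clustering")
}

# Walk the hclust merge tree from the root.  A node is kept as one module
# when its rows meet the homogeneity threshold AND its two dendrogram
# children do not carry distinct patterns (child centroids correlated above
# `split_cor`); otherwise it is split into its children and the walk
# recurses.  The centroid check matters for balanced mixtures: rows of two
# anti-correlated patterns can still correlate moderately with the pooled
# centroid, so homogeneity alone under-splits.  Returns a list of index
# vectors into the rows of X.
split_by_homogeneity <- function(hc, X, threshold, split_cor = 0) {
  merge <- hc$merge
  node_members <- function(node) {
    if (node < 0) return(-node)
    c(node_members(merge[node, 1L]), node_members(merge[node, 2L]))
  }
  out <- list()
  visit <- function(node) {
    members <- node_members(node)
    if (length(members) >= 2L) {
      h <- suppressWarnings(homogeneity(X[members, , drop = FALSE]))
      mixed <- FALSE
      if (node > 0) {
        left <- node_members(merge[node, 1L])
        right <- node_members(merge[node, 2L])
        if (length(left) >= 2L && length(right) >= 2L) {
          cc <- suppressWarnings(cor(colMeans(X[left, , drop = FALSE]),
                                     colMeans(X[right, , drop = FALSE])))
          mixed <- is.finite(cc) && cc < split_cor
        }
      }
      if (h >= threshold && !mixed) {
        out[[length(out) + 1L]] <<- members
        return(invisible())
      }
    }
    if (node < 0) {
      out[[length(out) + 1L]] <<- members  # unsplittable singleton
    } else {
      visit(merge[node, 1L])
      visit(merge[node, 2L])
    }
    invisible()
  }
  visit(nrow(merge))
  out
}

#' @export
print.cm_clustering <- function(x, ...) {
  cat(sprintf("cm_clustering: %d module(s), %d unclustered of %d loci\n",
              length(x$modules), length(x$unclustered),
              length(x$assignments)))
  for (m in x$modules) {
    cat(sprintf("  module %d: %d loci, homogeneity %.3f\n",
                m$module_id, length(m$member_ids), m$homogeneity))
  }
  invisible(x)
}

#' Module assignment table
#'
#' @param cl A `cm_clustering`.
#' @return Data frame `locus_id`, `module_id` (0 = unclustered).
#' @export
clustering_table <- function(cl) {
  data.frame(locus_id = names(cl$assignments),
             module_id = unname(cl$assignments))
}

#' Value-swap randomization of a CM profile
#'
#' Permutes all feature cells uniformly at random across the whole matrix,
#' keeping the same value distribution (identical multiset); the methylation
#' column is untouched.  Because the swap moves binary-element values into
#' continuous columns and vice versa, the randomized profile carries no
#' binary-column flags.
#'
#' @param profile A [cm_profile()].
#' @param seed Integer seed.
#' @return A [cm_profile()] with permuted feature cells.
#' @export
randomize_profile <- function(profile, seed = 1L) {
  validate_profile(profile)
  v <- profile$values
  perm <- with_seed(seed, sample.int(length(v)))
  v[] <- v[perm]
  cm_profile(v, profile$methylation, profile$locus_ids,
             binary_features = character())
}

#' Compare real clustering against value-swap randomizations
#'
#' Clusters the real profile and `n_random` randomized profiles
#' ([randomize_profile()]) with identical parameters, then compares the real
#' module homogeneities against the pooled random-module homogeneities with
#' a one-sided Wilcoxon rank-sum test (alternative: real homogeneities are
#' larger).
#'
#' @param profile A [cm_profile()].
#' @param n_random Number of randomized datasets (>= 2; default 100).
#' @param homogeneity_threshold,min_size,features Passed to [cluster_loci()].
#' @param seed Integer seed; randomization `r` uses a seed derived from it.
#' @return List with `real` (`cm_clustering`), `random_module_counts`,
#'   `random_homogeneities`, `real_homogeneities`, and `rank_sum_p` (NA when
#'   either homogeneity group is empty).
#' @export
compare_to_random <- function(profile, n_random = 100L,
                              homogeneity_threshold = 0.5, min_size = 10L,
                              seed = 1L, features = NULL) {
  if (n_random < 2L) stop("n_random must be >= 2")
  real <- cluster_loci(profile, homogeneity_threshold, min_size,
                       seed = seed, features = features)
  counts <- integer(n_random)
  rand_hom <- list()
  for (r in seq_len(n_random)) {
    rp <- randomize_profile(profile, seed = derive_seed(seed, r))
    rcl <- suppressWarnings(
      cluster_loci(rp, homogeneity_threshold, min_size,
                   seed = seed, features = features))
    counts[r] <- length(rcl$modules)
    rand_hom[[r]] <- vapply(rcl$modules, `[[`, numeric(1), "homogeneity")
  }
  real_h <- vapply(real$modules, `[[`, numeric(1), "homogeneity")
  rand_h <- unlist(rand_hom)
  p <- if (length(real_h) && length(rand_h)) {
    suppressWarnings(wilcox.test(real_h, rand_h,
                                 alternative = "greater")$p.value)
  } else NA_real_
  list(real = real,
       random_module_counts = counts,
       random_homogeneities = rand_h,
       real_homogeneities = real_h,
       rank_sum_p = p)
}
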