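#' Equal-frequency binarization of a CM profile
#'
#' Splits every variable (each feature column plus methylation) into two
#' classes at its median: values less than or equal to the median become 0,
#' values above it become 1.  Columns already binary pass through unchanged.
#' For zero-inflated CM columns whose median equals the minimum, the split
#' degenerates to zero/non-zero — the only frequency-balanced choice
#' available.  Constant columns become all-0 and are flagged degenerate;
#' network learning excludes them with a warning rather than an error.
#'
#' @param profile A [cm_profile()].
#' @return Object of class `binary_profile`: `locus_ids`, `variable_names`
#'   (features plus `"methylation"`), `values` (N x (f+1) 0/1 matrix), and
#'   `degenerate` (names of constant columns).
#' @export
binarize <- function(profile) {
  validate_profile(profile)
  n <- length(profile$locus_ids)
  if (n < 2L) stop("need N >= 2 loci to binarize")
  full <- cbind(profile$values, methylation = profile$methylation)
  vars <- colnames(full)
  out <- matrix(0L, n, ncol(full), dimnames = list(NULL, vars))
  degenerate <- character()
  for (v in vars) {
    col <- full[, v]
    if (v %in% profile$binary_features) {
      out[, v] <- as.integer(col)
      if (length(unique(col)) < 2L) degenerate <- c(degenerate, v)
      next
    }
    if (max(col) == min(col)) {
      degenerate <- c(degenerate, v)
      warning("constant column '", v, "' binarized to all 0 (degenerate)")
      next
    }
    med <- median(col)
    b <- as.integer(col > med)
    if (all(b == 0L)) {
      # median equals the maximum (mass-tie at the top): the only
      # frequency-balanced split left sends ties upward instead
      b <- as.integer(col >= med)
    }
    out[, v] <- b
    if (length(unique(b)) < 2L) degenerate <- c(degenerate, v)
  }
  structure(list(locus_ids = profile$locus_ids, variable_names = vars,
                 values = out, degenerate = degenerate),
            class = "binary_profile")
}

#' @export
print.binary_profile <- function(x, ...) {
  cat(sprintf("binary_profile: %d loci x %d variables\n",
              length(x$locus_ids), length(x$variable_names)))
  if (length(x$degenerate)) {
    cat("  degenerate:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- BDeu scoring over binary variables -----------------------------------

# Local BDeu score of `child` with parent set `parents` (column indices into
# the 0/1 data matrix); equivalent sample size `ess`, r = 2 states.
bdeu_local <- function(data, child, parents, ess = 1) {
  n <- nrow(data)
  p <- length(parents)
  q <- 2^p
  # joint configuration index: child state + 2 * parent config
  code <- data[, child]
  if (p) {
    mult <- 2L
    for (pa in parents) {
      code <- code + mult * data[, pa]
      mult <- mult * 2L
    }
  }
  njk <- tabulate(code + 1L, nbins = 2L * q)         # by (child, config)
  nj <- njk[seq_len(q) * 2L - 1L] + njk[seq_len(q) * 2L]
  aj <- ess / q
  ajk <- ess / (2 * q)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + njk) - lgamma(ajk))
}

# Total decomposable score of a DAG (adjacency matrix: dag[i, j] means
# i -> j).
score_dag <- function(data, dag, ess = 1) {
  sum(vapply(seq_len(ncol(dag)), function(j) {
    bdeu_local(data, j, which(dag[, j] != 0), ess)
  }, numeric(1)))
}

# TRUE when a directed path from -> to exists in adjacency matrix `dag`.
has_path <- function(dag, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(dag))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    nxt <- which(dag[v, ] != 0)
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt[!seen[nxt]])
  }
  FALSE
}

#' Learn a Bayesian-network structure from a binary profile
#'
#' Greedy hill climbing over DAGs with add/delete/reverse single-edge moves,
#' scored by the BDeu marginal likelihood (decomposable; default equivalent
#' sample size 1) on binary variables.  The search starts from the empty
#' graph, applies the best strictly improving move at each step (lowest
#' variable-index pair on ties), and stops at a local optimum.  Degenerate
#' (constant) variables are excluded from the search with a warning.  The
#' result also carries the CPDAG of the learned DAG ([to_cpdag()]), whose
#' directed edges are the compelled edges.
#'
#' @param bp A [binarize()] result.
#' @param seed Integer seed, recorded for provenance (the search itself is
#'   deterministic).
#' @param ess Equivalent sample size of the BDeu score.
#' @param max_parents Cap on in-degree (default 4) to bound the score table.
#' @return Object of class `cm_network`: `variables`, `dag` (0/1 adjacency,
#'   `dag[i, j] = 1` means i -> j), `cpdag` (see [to_cpdag()]), `score`,
#'   `n` (sample size), `excluded` (degenerate variables).
#' @export
learn_structure <- function(bp, seed = 1L, ess = 1, max_parents = 4L) {
  stopifnot(inherits(bp, "binary_profile"))
  keep <- setdiff(bp$variable_names, bp$degenerate)
  if (length(bp$degenerate)) {
    warning("excluding degenerate variable(s): ",
            paste(bp$degenerate, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need >= 2 non-degenerate variables")
  if (nrow(bp$values) < 20L) stop("need N >= 20 loci to learn a structure")
  data <- bp$values[, keep, drop = FALSE]
  V <- length(keep)
  dag <- matrix(0L, V, V, dimnames = list(keep, keep))
  local <- vapply(seq_len(V), function(j) bdeu_local(data, j, integer(), ess),
                  numeric(1))
  repeat {
    best <- list(delta = 1e-10, move = NULL)
    for (i in seq_len(V)) {
      for (j in seq_len(V)) {
        if (i == j) next
        if (dag[i, j]) {
          # delete i -> j
          new_j <- bdeu_local(data, j, setdiff(which(dag[, j] != 0), i), ess)
          d <- new_j - local[j]
          if (d > best$delta) best <- list(delta = d, move = c(1L, i, j),
                                           lj = new_j)
          # reverse i -> j  (becomes j -> i)
          if (sum(dag[, i]) < max_parents) {
            dag2 <- dag
            dag2[i, j] <- 0L
            if (!has_path(dag2, i, j)) {
              new_i <- bdeu_local(data, i, c(which(dag[, i] != 0), j), ess)
              d <- (new_j + new_i) - (local[j] + local[i])
              if (d > best$delta) {
                best <- list(delta = d, move = c(2L, i, j),
                             lj = new_j, li = new_i)
              }
            }
          }
        } else if (!dag[j, i] && sum(dag[, j]) < max_parents &&
                   !has_path(dag, j, i)) {
          # add i -> j
          new_j <- bdeu_local(data, j, c(which(dag[, j] != 0), i), ess)
          d <- new_j - local[j]
          if (d > best$delta) best <- list(delta = d, move = c(3L, i, j),
                                           lj = new_j)
        }
      }
    }
    if (is.null(best$move)) break
    i <- best$move[2L]; j <- best$move[3L]
    if (best$move[1L] == 1L) {
      dag[i, j] <- 0L
      local[j] <- best$lj
    } else if (best$move[1L] == 2L) {
      dag[i, j] <- 0L
      dag[j, i] <- 1L
      local[j] <- best$lj
      local[i] <- best$li
    } else {
      dag[i, j] <- 1L
      local[j] <- best$lj
    }
  }
  structure(list(variables = keep, dag = dag, cpdag = to_cpdag(dag),
                 score = sum(local), n = nrow(data), ess = ess,
                 seed = seed, excluded = bp$degenerate),
            class = "cm_network")
}

#' @export
print.cm_network <- function(x, ...) {
  ed <- edge_table(x)
  cat(sprintf("cm_network: %d variable(s), %d edge(s) (%d compelled), score %.2f\n",
              length(x$variables), nrow(ed),
              sum(ed$type == "compelled"), x$score))
  if (nrow(ed)) print(ed, row.names = FALSE)
  invisible(x)
}

#' Completed PDAG (CPDAG) of a DAG
#'
#' Computes the completed partially directed acyclic graph representing the
#' Markov-equivalence class of `dag`: the skeleton is oriented at every
#' v-structure (collider with non-adjacent parents) and the orientation is
#' closed under the Meek rules.  Directed edges of the CPDAG are the
#' compelled edges — oriented identically in every DAG of the class and
#' interpreted as candidate causal relationships; undirected edges are
#' reversible — correlation whose direction is not identified.
#'
#' @param dag 0/1 adjacency matrix (`dag[i, j] = 1` means i -> j) of an
#'   acyclic graph.
#' @return List with `directed` and `undirected` adjacency matrices (the
#'   CPDAG's compelled and reversible parts).
#' @export
to_cpdag <- function(dag) {
  dag <- as.matrix(dag)
  V <- nrow(dag)
  if (V != ncol(dag)) stop("dag must be square")
  if (has_cycle(dag)) stop("input graph is cyclic")
  skel <- (dag + t(dag)) > 0
  directed <- matrix(FALSE, V, V, dimnames = dimnames(dag))
  # v-structures: x -> z <- y with x, y non-adjacent
  for (z in seq_len(V)) {
    parents <- which(dag[, z] != 0)
    if (length(parents) >= 2L) {
      for (a in seq_along(parents)) {
        for (b in seq_along(parents)) {
          if (a >= b) next
          x <- parents[a]; y <- parents[b]
          if (!skel[x, y]) {
            directed[x, z] <- TRUE
            directed[y, z] <- TRUE
          }
        }
      }
    }
  }
  undirected <- skel & !(directed | t(directed))
  # Meek closure (rules R1-R3 suffice without background knowledge)
  repeat {
    changed <- FALSE
    orient <- function(a, b) {
      directed[a, b] <<- TRUE
      undirected[a, b] <<- FALSE
      undirected[b, a] <<- FALSE
      changed <<- TRUE
    }
    for (a in seq_len(V)) for (b in seq_len(V)) {
      if (!undirected[a, b] || a == b) next
      # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
      for (c in which(directed[, a])) {
        if (!skel[c, b] && c != b) { orient(a, b); break }
      }
      if (!undirected[a, b]) next
      # R2: a -> c -> b and a - b  =>  a -> b
      for (c in which(directed[a, ])) {
        if (directed[c, b]) { orient(a, b); break }
      }
      if (!undirected[a, b]) next
      # R3: a - c1, a - c2, c1 -> b, c2 -> b, c1 and c2 non-adjacent => a -> b
      cands <- which(undirected[a, ] & directed[, b])
      if (length(cands) >= 2L) {
        done <- FALSE
        for (u in seq_along(cands)) {
          for (w in seq_along(cands)) {
            if (u < w && !skel[cands[u], cands[w]]) {
              orient(a, b); done <- TRUE; break
            }
          }
          if (done) break
        }
      }
    }
    if (!changed) break
  }
  list(directed = directed * 1L, undirected = undirected * 1L)
}

has_cycle <- function(dag) {
  deg <- colSums(dag != 0)
  active <- rep(TRUE, nrow(dag))
  repeat {
    src <- which(active & deg == 0)
    if (!length(src)) break
    for (v in src) {
      deg <- deg - (dag[v, ] != 0) * active
      active[v] <- FALSE
    }
  }
  any(active)
}

#' Edge table of a learned network
#'
#' @param net A `cm_network` (or a raw `to_cpdag()` result).
#' @return Data frame `from`, `to`, `type` (`"compelled"` or
#'   `"reversible"`); reversible edges are listed once with `from < to`.
#' @export
edge_table <- function(net) {
  cp <- if (inherits(net, "cm_network")) net$cpdag else net
  vars <- rownames(cp$directed)
  out <- data.frame(from = character(), to = character(),
                    type = character(), stringsAsFactors = FALSE)
  idx <- which(cp$directed != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    out <- rbind(out, data.frame(from = vars[idx[, 1L]], to = vars[idx[, 2L]],
                                 type = "compelled"))
  }
  idx <- which(cp$undirected != 0 & upper.tri(cp$undirected), arr.ind = TRUE)
  if (nrow(idx)) {
    out <- rbind(out, data.frame(from = vars[idx[, 1L]], to = vars[idx[, 2L]],
                                 type = "reversible"))
  }
  out[order(out$from, out$to), , drop = FALSE]
}

# Undirected skeleton edge keys "a|b" with a < b.
skeleton_keys <- function(net) {
  skel <- (net$dag + t(net$dag)) > 0
  vars <- net$variables
  idx <- which(skel & upper.tri(skel), arr.ind = TRUE)
  if (!nrow(idx)) return(character())
  paste(vars[idx[, 1L]], vars[idx[, 2L]], sep = "|")
}

#' Learn the global and per-module networks
#'
#' Learns one network from the full profile (the global network, without
#' module partition) and one per clustering module (module-specific
#' networks).  Modules smaller than `min_n` loci are skipped with a warning.
#'
#' @param profile A [cm_profile()].
#' @param clustering A `cm_clustering` from [cluster_loci()], or `NULL` for
#'   the global network only.
#' @param features Optional feature subset used as network variables
#'   (methylation is always included as a variable).
#' @param seed,ess,max_parents Passed to [learn_structure()].
#' @param min_n Minimum module size for learning (default 20).
#' @return List with `global` (`cm_network`) and `modules` (named list of
#'   `cm_network`, one per retained module).
#' @export
infer_module_networks <- function(profile, clustering = NULL,
                                  features = NULL, seed = 1L, ess = 1,
                                  max_parents = 4L, min_n = 20L) {
  validate_profile(profile)
  sub <- subset_profile(profile, features = features)
  global <- learn_structure(binarize(sub), seed = seed, ess = ess,
                            max_parents = max_parents)
  nets <- list()
  if (!is.null(clustering)) {
    for (m in clustering$modules) {
      if (length(m$member_ids) < min_n) {
        warning("module ", m$module_id, " has fewer than ", min_n,
                " loci; skipped")
        next
      }
      mp <- subset_profile(sub, loci = m$member_ids)
      nets[[as.character(m$module_id)]] <- suppressWarnings(
        learn_structure(binarize(mp), seed = derive_seed(seed, m$module_id),
                        ess = ess, max_parents = max_parents))
    }
  }
  list(global = global, modules = nets)
}

#' Tally pairwise interactions across module networks
#'
#' Counts, for every variable pair, in how many module-network skeletons the
#' (undirected) edge occurs.  Pairs present in the global skeleton but in no
#' module are flagged `global_only`; pairs occurring in at least two modules
#' are flagged `module_recurrent`.  Rows are sorted by descending
#' occurrence.
#'
#' @param module_networks List of `cm_network` (the module networks).
#' @param global_network A `cm_network` (the global control).
#' @return Data frame `feature_a`, `feature_b`, `occurrence`, `in_global`,
#'   `global_only`, `module_recurrent`, sorted by descending occurrence.
#' @export
tally_interactions <- function(module_networks, global_network) {
  stopifnot(inherits(global_network, "cm_network"))
  counts <- list()
  for (net in module_networks) {
    for (k in skeleton_keys(net)) {
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  gkeys <- skeleton_keys(global_network)
  all_keys <- union(names(counts), gkeys)
  if (!length(all_keys)) {
    return(data.frame(feature_a = character(), feature_b = character(),
                      occurrence = integer(), in_global = logical(),
                      global_only = logical(), module_recurrent = logical()))
  }
  occ <- vapply(all_keys, function(k) counts[[k]] %||% 0L, integer(1))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  out <- data.frame(
    feature_a = vapply(parts, `[[`, character(1), 1L),
    feature_b = vapply(parts, `[[`, character(1), 2L),
    occurrence = unname(occ),
    in_global = all_keys %in% gkeys,
    global_only = (all_keys %in% gkeys) & occ == 0L,
    module_recurrent = occ >= 2L
  )
  out[order(-out$occurrence, out$feature_a, out$feature_b), , drop = FALSE]
}

#' Random-data control for learned edges
#'
#' Repeats network learning on `n_datasets` value-swap randomizations of the
#' profile ([randomize_profile()]) and reports, for every edge of the real
#' network's skeleton, the fraction of random datasets whose learned
#' skeleton contains it.  An edge present in every random dataset is flagged
#' suspect.
#'
#' @param profile A [cm_profile()].
#' @param n_datasets Number of random datasets (>= 2; default 100).
#' @param features,seed,ess,max_parents As in [infer_module_networks()].
#' @return List with `real` (`cm_network`) and `edges` (data frame
#'   `feature_a`, `feature_b`, `random_fraction`, `suspect`).
#' @export
random_network_control <- function(profile, n_datasets = 100L,
                                   features = NULL, seed = 1L, ess = 1,
                                   max_parents = 4L) {
  if (n_datasets < 2L) stop("n_datasets must be >= 2")
  validate_profile(profile)
  sub <- subset_profile(profile, features = features)
  real <- learn_structure(binarize(sub), seed = seed, ess = ess,
                          max_parents = max_parents)
  keys <- skeleton_keys(real)
  hits <- setNames(integer(length(keys)), keys)
  for (r in seq_len(n_datasets)) {
    rp <- randomize_profile(sub, seed = derive_seed(seed, r))
    rnet <- suppressWarnings(
      learn_structure(binarize(rp), seed = derive_seed(seed, r), ess = ess,
                      max_parents = max_parents))
    rk <- skeleton_keys(rnet)
    hits[keys %in% rk] <- hits[keys %in% rk] + 1L
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  edges <- data.frame(
    feature_a = vapply(parts, `[[`, character(1), 1L),
    feature_b = vapply(parts, `[[`, character(1), 2L),
    random_fraction = if (length(keys)) unname(hits) / n_datasets else numeric(),
    suspect = if (length(keys)) unname(hits) == n_datasets else logical()
  )
  list(real = real, edges = edges, n_datasets = n_datasets)
}

# ---- topology -------------------------------------------------------------

as_igraph_skeleton <- function(g) {
  if (inherits(g, "cm_network")) {
    skel <- (g$dag + t(g$dag)) > 0
    return(igraph::graph_from_adjacency_matrix(skel * 1, mode = "undirected"))
  }
  if (igraph::is_igraph(g)) return(igraph::as_undirected(g))
  if (is.matrix(g)) {
    return(igraph::graph_from_adjacency_matrix(((g + t(g)) > 0) * 1,
                                               mode = "undirected"))
  }
  stop("cannot interpret object of class ", class(g)[1L], " as a graph")
}

#' Topology metrics of a network
#'
#' Computes, on the undirected skeleton: the average clustering coefficient
#' (mean of per-node local clustering coefficients, nodes of degree < 2
#' contributing 0), the average degree `2E/V`, the least-squares slope of
#' log frequency versus log degree over degree >= 1 bins (the degree
#' power-law exponent estimate), and the mean shortest-path length over
#' connected pairs.
#'
#' @param g A `cm_network`, adjacency matrix, or `igraph` graph.
#' @return Named list: `clustering_coefficient`, `average_degree`,
#'   `degree_power_exponent`, `mean_shortest_path`.
#' @export
topology_metrics <- function(g) {
  ig <- as_igraph_skeleton(g)
  nv <- igraph::vcount(ig)
  if (nv < 2L) stop("need at least 2 nodes")
  ne <- igraph::ecount(ig)
  if (ne == 0L) {
    warning("graph has no edges; metrics degenerate to 0")
    return(list(clustering_coefficient = 0, average_degree = 0,
                degree_power_exponent = 0, mean_shortest_path = 0))
  }
  cc <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  deg <- igraph::degree(ig)
  tab <- table(deg[deg >= 1])
  expo <- if (length(tab) >= 2L) {
    unname(coef(lm(log(as.numeric(tab)) ~
                     log(as.numeric(names(tab)))))[2L])
  } else 0
  list(clustering_coefficient = mean(cc),
       average_degree = 2 * ne / nv,
       degree_power_exponent = expo,
       mean_shortest_path = igraph::mean_distance(ig, directed = FALSE))
}

#' Edge-count-matched random graph
#'
#' Draws a uniform simple undirected graph with the same node set and edge
#' count as the input skeleton (not a degree-preserving rewire).
#'
#' @param g A `cm_network`, adjacency matrix, or `igraph` graph.
#' @param seed Integer seed.
#' @return An `igraph` graph with the input's vertex names.
#' @export
randomize_network <- function(g, seed = 1L) {
  ig <- as_igraph_skeleton(g)
  nv <- igraph::vcount(ig)
  ne <- igraph::ecount(ig)
  rg <- with_seed(seed, igraph::sample_gnm(nv, ne, directed = FALSE))
  nm <- igraph::V(ig)$name
  if (!is.null(nm)) igraph::V(rg)$name <- nm
  rg
}

#' Compare a network's topology to edge-count-matched random graphs
#'
#' Draws `rounds` random graphs ([randomize_network()]) and returns, for the
#' clustering coefficient and the mean shortest path, the real value, the
#' random mean, and one-sided empirical p-values (clustering: fraction of
#' random graphs at least as clustered; path: fraction with a path at most
#' as short).
#'
#' @param g A `cm_network`, adjacency matrix, or `igraph` graph.
#' @param rounds Number of random graphs (default 1000).
#' @param seed Integer seed.
#' @return List of real metrics, random means, and empirical p-values.
#' @export
compare_topology_to_random <- function(g, rounds = 1000L, seed = 1L) {
  real <- suppressWarnings(topology_metrics(g))
  cc <- path <- numeric(rounds)
  for (r in seq_len(rounds)) {
    m <- suppressWarnings(
      topology_metrics(randomize_network(g, seed = derive_seed(seed, r))))
    cc[r] <- m$clustering_coefficient
    path[r] <- m$mean_shortest_path
  }
  list(real = real,
       random_mean = list(clustering_coefficient = mean(cc),
                          mean_shortest_path = mean(path)),
       p_clustering = (1 + sum(cc >= real$clustering_coefficient)) /
         (1 + rounds),
       p_path = (1 + sum(path <= real$mean_shortest_path)) / (1 + rounds))
}

#' Write a network as SIF
#'
#' One line per edge: `from <tab> compelled|reversible <tab> to`.
#'
#' @param net A `cm_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  ed <- edge_table(net)
  writeLines(sprintf("%s\t%s\t%s", ed$from, ed$type, ed$to), path)
  invisible(path)
}
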