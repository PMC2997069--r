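test_that("binarize splits at the median with ties to class 0", {
  p <- make_profile(cbind(a = c(0.1, 0.2, 0.3, 0.4),
                          b = c(0, 0, 0, 0.7)),
                    methylation = c(0.1, 0.2, 0.8, 0.9))
  bp <- binarize(p)
  expect_equal(unname(bp$values[, "a"]), c(0, 0, 1, 1))
  expect_equal(bp$variable_names, c("a", "b", "methylation"))
  # zero-inflated column: median 0, ties to class 0 -> zero/non-zero split
  p2 <- make_profile(cbind(a = c(0, 0, 0, 0.7, 0.9),
                           b = c(0.1, 0.3, 0.5, 0.7, 0.9)),
                     methylation = rep(0.5, 5))
  expect_equal(unname(binarize(p2)$values[, "a"]), c(0, 0, 0, 1, 1))
})

test_that("binarize passes binary columns through and flags constants", {
  p <- make_profile(cbind(a = c(0.1, 0.9, 0.4, 0.6), bin = c(0, 1, 1, 0)),
                    methylation = c(0.1, 0.4, 0.6, 0.9), binary = "bin")
  bp <- binarize(p)
  expect_equal(unname(bp$values[, "bin"]), c(0, 1, 1, 0))
  p2 <- make_profile(cbind(a = c(0.1, 0.9, 0.4, 0.6), k = rep(0.3, 4)),
                     methylation = c(0.1, 0.4, 0.6, 0.9))
  expect_warning(bp2 <- binarize(p2), "constant")
  expect_equal(bp2$degenerate, "k")
  expect_equal(unname(bp2$values[, "k"]), rep(0, 4))
})

test_that("greedy search recovers a planted chain without the shortcut edge", {
  d <- sample_chain(5000, seed = 201)
  net <- learn_structure(make_binary_profile(d))
  ed <- edge_table(net)
  expect_setequal(paste(ed$from, ed$to), c("X Y", "Y Z"))
  expect_true(all(ed$type == "reversible"))
  # greedy optimum equals the exhaustive-enumeration optimum
  expect_equal(net$score, exhaustive_best_score(d))
})

test_that("greedy search recovers a planted collider with its v-structure", {
  d <- sample_collider(5000, seed = 202)
  net <- learn_structure(make_binary_profile(d))
  ed <- edge_table(net)
  expect_setequal(paste(ed$from, ed$to), c("X Z", "Y Z"))
  expect_true(all(ed$type == "compelled"))
  expect_equal(net$score, exhaustive_best_score(d))
})

test_that("independent coins yield an empty graph and degenerate input errors", {
  set.seed(203)
  d <- matrix(rbinom(2000 * 3, 1, 0.5), 2000, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  net <- learn_structure(make_binary_profile(d))
  expect_equal(sum(net$dag), 0)
  one <- make_binary_profile(d[, 1, drop = FALSE])
  expect_error(learn_structure(one), "2 non-degenerate")
  expect_error(learn_structure(make_binary_profile(d[1:10, ])), "N >= 20")
})

test_that("learned networks are acyclic with matching CPDAG skeletons", {
  for (s in 1:5) {
    d <- sample_bn(800, c("A", "B", "C", "D"), list(
      A = 0.5,
      B = function(x) ifelse(x[, "A"] == 1, 0.85, 0.15),
      C = function(x) ifelse(x[, "A"] == 1, 0.2, 0.8),
      D = function(x) ifelse(x[, "B"] + x[, "C"] == 2, 0.9, 0.25)
    ), seed = 300 + s)
    net <- learn_structure(make_binary_profile(d))
    expect_false(chromclose:::has_cycle(net$dag))
    skel_dag <- (net$dag + t(net$dag)) > 0
    skel_cp <- (net$cpdag$directed + t(net$cpdag$directed) +
                  net$cpdag$undirected) > 0
    expect_equal(skel_cp, skel_dag)
  }
})

test_that("to_cpdag matches equivalence-class enumeration on all 3-node DAGs", {
  # oracle: two DAGs are equivalent iff same skeleton and v-structures; an
  # edge is compelled iff oriented identically across the class
  skel_key <- function(a) paste(which((a + t(a)) > 0), collapse = ",")
  vstruct_key <- function(a) {
    ks <- character()
    for (z in 1:3) {
      pa <- which(a[, z] != 0)
      if (length(pa) == 2 && a[pa[1], pa[2]] == 0 && a[pa[2], pa[1]] == 0) {
        ks <- c(ks, paste(sort(pa), z, collapse = "-"))
      }
    }
    paste(sort(ks), collapse = ";")
  }
  dags <- all_dags(3)
  cls <- paste(sapply(dags, skel_key), sapply(dags, vstruct_key), sep = "|")
  for (i in seq_along(dags)) {
    a <- dags[[i]]
    peers <- dags[cls == cls[i]]
    compelled_oracle <- matrix(TRUE, 3, 3)
    for (p in peers) compelled_oracle <- compelled_oracle & (p == a)
    compelled_oracle <- (a == 1) & compelled_oracle
    cp <- to_cpdag(a)
    expect_equal(cp$directed == 1, compelled_oracle,
                 info = paste("dag", i))
  }
})

test_that("to_cpdag handles canonical cases and rejects cycles", {
  chain <- matrix(0, 3, 3, dimnames = rep(list(c("X", "Y", "Z")), 2))
  chain["X", "Y"] <- chain["Y", "Z"] <- 1
  cp <- to_cpdag(chain)
  expect_equal(sum(cp$directed), 0)
  expect_equal(sum(cp$undirected), 4)  # two undirected edges, symmetric

  collider <- matrix(0, 3, 3, dimnames = rep(list(c("X", "Y", "Z")), 2))
  collider["X", "Z"] <- collider["Y", "Z"] <- 1
  cp2 <- to_cpdag(collider)
  expect_equal(sum(cp2$directed), 2)
  expect_equal(sum(cp2$undirected), 0)

  single <- matrix(0, 2, 2, dimnames = rep(list(c("X", "Y")), 2))
  single["X", "Y"] <- 1
  expect_equal(sum(to_cpdag(single)$directed), 0)

  cyc <- matrix(0, 3, 3)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  expect_error(to_cpdag(cyc), "cyclic")
})

test_that("module networks recover module-specific planted edges", {
  d1 <- sample_bn(3000, c("A", "B", "C"), list(
    A = 0.5, B = function(x) ifelse(x[, "A"] == 1, 0.9, 0.1), C = 0.5
  ), seed = 401)
  d2 <- sample_bn(3000, c("A", "B", "C"),
                  list(A = 0.5, B = 0.5, C = 0.5), seed = 402)
  vals <- rbind(d1, d2) * 1.0
  p <- cm_profile(vals[, c("A", "B", "C")] * 0.9,
                  methylation = rep(c(0.2, 0.8), each = 3000),
                  locus_ids = sprintf("L%05d", 1:6000))
  cl <- structure(list(modules = list(
    list(module_id = 1, member_ids = p$locus_ids[1:3000], homogeneity = 1),
    list(module_id = 2, member_ids = p$locus_ids[3001:6000], homogeneity = 1)
  ), unclustered = character()), class = "cm_clustering")
  nets <- suppressWarnings(
    infer_module_networks(p, cl, features = c("A", "B", "C")))
  skel1 <- chromclose:::skeleton_keys(nets$modules[["1"]])
  skel2 <- chromclose:::skeleton_keys(nets$modules[["2"]])
  expect_true("A|B" %in% skel1)
  expect_false("A|B" %in% skel2)
})

test_that("one all-loci module reproduces the global network", {
  ds <- simulate_dataset(generator_config(seed = 51, n_loci = 800))
  cl <- structure(list(modules = list(
    list(module_id = 1, member_ids = ds$profile$locus_ids, homogeneity = 1)
  ), unclustered = character()), class = "cm_clustering")
  nets <- suppressWarnings(infer_module_networks(ds$profile, cl))
  expect_equal(nets$modules[["1"]]$dag, nets$global$dag)
  solo <- suppressWarnings(infer_module_networks(ds$profile, NULL))
  expect_length(solo$modules, 0L)
})

test_that("interaction tallies count skeleton occurrences across modules", {
  mk <- function(edges) {
    vars <- c("A", "B", "C", "M")
    dag <- matrix(0L, 4, 4, dimnames = list(vars, vars))
    for (e in edges) dag[e[1], e[2]] <- 1L
    structure(list(variables = vars, dag = dag, cpdag = to_cpdag(dag)),
              class = "cm_network")
  }
  g <- mk(list(c("A", "B"), c("C", "M")))
  m1 <- mk(list(c("A", "B"), c("B", "C")))
  m2 <- mk(list(c("B", "A")))
  m3 <- mk(list(c("A", "B"), c("B", "C")))
  tl <- tally_interactions(list(m1, m2, m3), g)
  expect_equal(tl$occurrence[tl$feature_a == "A" & tl$feature_b == "B"], 3L)
  expect_equal(tl$occurrence[tl$feature_a == "B" & tl$feature_b == "C"], 2L)
  expect_true(tl$module_recurrent[tl$feature_a == "B" & tl$feature_b == "C"])
  row_cm <- tl[tl$feature_a == "C" & tl$feature_b == "M", ]
  expect_equal(row_cm$occurrence, 0L)
  expect_true(row_cm$global_only)
  expect_false(any(diff(tl$occurrence) > 0))  # sorted descending

  k <- tally_interactions(list(m1, m1, m1, m1), g)
  expect_true(all(k$occurrence[k$in_global == FALSE |
                                 k$feature_a == "A"] %in% c(0L, 4L)))
})

test_that("random-data controls rarely reproduce a strong planted edge", {
  set.seed(61)
  x <- runif(2000, 0, 0.9)
  y <- pmin(0.95, pmax(0, x + rnorm(2000, 0, 0.05)))
  z <- runif(2000, 0, 0.9)
  p <- cm_profile(cbind(X = x, Y = y, Z = z),
                  methylation = runif(2000),
                  locus_ids = sprintf("L%05d", 1:2000))
  ctrl <- suppressWarnings(random_network_control(p, n_datasets = 20,
                                                  seed = 7))
  expect_true("X|Y" %in% with(ctrl$edges, paste(feature_a, feature_b,
                                                sep = "|")))
  xy <- ctrl$edges[ctrl$edges$feature_a == "X" & ctrl$edges$feature_b == "Y", ]
  expect_lt(xy$random_fraction, 0.05)
  expect_false(any(ctrl$edges$suspect))
  expect_error(random_network_control(p, n_datasets = 0), "n_datasets")
})

test_that("topology metrics match closed forms", {
  tri <- matrix(0, 3, 3); tri[1, 2] <- tri[2, 3] <- tri[1, 3] <- 1
  m <- topology_metrics(tri)
  expect_equal(m$clustering_coefficient, 1.0)
  expect_equal(m$average_degree, 2.0)
  expect_equal(m$mean_shortest_path, 1.0)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  m2 <- topology_metrics(path3)
  expect_equal(m2$clustering_coefficient, 0.0)
  expect_equal(m2$mean_shortest_path, 4 / 3)

  star5 <- matrix(0, 5, 5); star5[1, 2:5] <- 1
  expect_equal(topology_metrics(star5)$average_degree, 8 / 5)

  none <- matrix(0, 3, 3)
  expect_warning(m3 <- topology_metrics(none), "no edges")
  expect_equal(m3$average_degree, 0)
  expect_error(topology_metrics(matrix(0, 1, 1)), "2 nodes")
})

test_that("network randomization preserves node and edge counts", {
  set.seed(71)
  a <- matrix(0, 8, 8)
  a[upper.tri(a)] <- rbinom(28, 1, 0.3)
  g <- igraph::graph_from_adjacency_matrix(((a + t(a)) > 0) * 1,
                                           mode = "undirected")
  for (s in 1:5) {
    rg <- randomize_network(g, seed = s)
    expect_equal(igraph::vcount(rg), igraph::vcount(g))
    expect_equal(igraph::ecount(rg), igraph::ecount(g))
  }
  # complete graph: only one simple graph with that edge count
  comp <- igraph::make_full_graph(5)
  rg <- randomize_network(comp, seed = 1)
  expect_equal(igraph::ecount(rg), 10)
  expect_true(all(igraph::degree(rg) == 4))
})
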