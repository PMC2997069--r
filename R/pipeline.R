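#' Pipeline configuration
#'
#' Describes one end-to-end run: the inputs (either file paths, or an
#' in-memory [simulate_dataset()] result via `dataset`), the stage
#' parameters, and a single global seed from which every stage derives its
#' own seed by a fixed offset, so each stage is independently reproducible.
#'
#' @param loci_tsv Path to the loci TSV (ignored when `dataset` is given).
#' @param cm_beds Named character vector of BED3 paths for closeness-scored
#'   features.
#' @param element_beds Named character vector of BED3 paths for binary
#'   genomic elements (may be empty).
#' @param dataset Optional `cm_dataset`; replaces the file inputs.
#' @param alpha Feature-selection threshold (default 0.001).
#' @param folds CV folds (default 10).
#' @param permutations Permutation count for the model empirical p-value;
#'   0 disables the permutation stage (default 99 for a routine run).
#' @param homogeneity_threshold,min_size Clustering controls.
#' @param ess,max_parents Network-learning controls.
#' @param n_random Random-control datasets for the network stage (0
#'   disables; default 0 for a routine run).
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(loci_tsv = NULL, cm_beds = character(),
                            element_beds = character(), dataset = NULL,
                            alpha = 0.001, folds = 10L, permutations = 99L,
                            homogeneity_threshold = 0.5, min_size = 10L,
                            ess = 1, max_parents = 4L, n_random = 0L,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, folds >= 2L, permutations >= 0L,
            homogeneity_threshold > 0, homogeneity_threshold <= 1,
            min_size >= 1L, ess > 0, n_random >= 0L)
  if (is.null(dataset)) {
    if (is.null(loci_tsv)) stop("either dataset or loci_tsv is required")
    for (p in c(loci_tsv, cm_beds, element_beds)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
    if (length(cm_beds) && is.null(names(cm_beds))) {
      stop("cm_beds must be a named vector (feature name -> path)")
    }
  } else {
    stopifnot(inherits(dataset, "cm_dataset"))
  }
  structure(list(loci_tsv = loci_tsv, cm_beds = cm_beds,
                 element_beds = element_beds, dataset = dataset,
                 alpha = alpha, folds = as.integer(folds),
                 permutations = as.integer(permutations),
                 homogeneity_threshold = homogeneity_threshold,
                 min_size = as.integer(min_size), ess = ess,
                 max_parents = as.integer(max_parents),
                 n_random = as.integer(n_random),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes profile assembly, regression + feature selection, homogeneity
#' clustering, Bayesian-network inference (global + per-module), and
#' interaction tallying, writing every intermediate artifact plus a log and
#' a run manifest (with md5 hashes) into `out_dir`.  Re-running with the
#' same config and seed reproduces all outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_run` with the in-memory results
#'   (`profile`, `model`, `clustering`, `networks`, `tally`, paths and the
#'   manifest).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage_seed <- function(k) derive_seed(cfg$seed, 1000L + k)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # stage 1: profile
  say("profile", "assembling CM profile (seed ", stage_seed(1L), ")")
  profile <- run_stage("profile", {
    if (!is.null(cfg$dataset)) {
      cfg$dataset$profile
    } else {
      loci <- read_loci(cfg$loci_tsv)
      cm <- lapply(names(cfg$cm_beds), function(nm) {
        merge_domains(read_bed(cfg$cm_beds[[nm]], feature_name = nm))
      })
      names(cm) <- names(cfg$cm_beds)
      el <- lapply(names(cfg$element_beds), function(nm) {
        read_bed(cfg$element_beds[[nm]], feature_name = nm)
      })
      names(el) <- names(cfg$element_beds)
      build_profile(loci, cm, el)
    }
  })
  write_profile(profile, file.path(out_dir, "profile.tsv"))

  # stage 2: regression + selection
  say("select", "fitting regression, alpha = ", cfg$alpha,
      ", folds = ", cfg$folds, ", seed ", stage_seed(2L))
  model <- run_stage("select", {
    frm <- feature_reduced_model(profile, alpha = cfg$alpha,
                                 folds = cfg$folds, seed = stage_seed(2L))
    if (cfg$permutations > 0L && length(frm$selection$selected)) {
      frm$permutation <- permutation_pvalue(
        profile, n_perm = cfg$permutations, seed = stage_seed(2L),
        folds = cfg$folds, features = frm$selection$selected)
    }
    frm
  })
  write.table(regression_report(model$full),
              file.path(out_dir, "regression_full.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(model$selection$selected, file.path(out_dir, "selected.txt"))
  if (is.null(model$reduced)) {
    say("select", "no features selected; downstream stages use all features")
  } else {
    say("select", length(model$selection$selected),
        " feature(s) selected; reduced-model cv Pcc = ",
        sprintf("%.4f", model$reduced$cv_pcc))
  }
  sel_features <- model$selection$selected
  if (length(sel_features) < 2L) {
    # clustering and network learning need >= 2 variables
    say("select", "fewer than 2 features selected; ",
        "downstream stages use all features")
    sel_features <- profile$feature_names
  }

  # stage 3: clustering
  say("cluster", "homogeneity threshold ", cfg$homogeneity_threshold,
      ", min size ", cfg$min_size, ", seed ", stage_seed(3L))
  clustering <- run_stage("cluster", suppressWarnings(
    cluster_loci(profile, cfg$homogeneity_threshold, cfg$min_size,
                 seed = stage_seed(3L), features = sel_features)))
  write.table(clustering_table(clustering),
              file.path(out_dir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("cluster", length(clustering$modules), " module(s), ",
      length(clustering$unclustered), " unclustered")

  # stage 4: networks
  say("bn", "learning global and module networks, ess = ", cfg$ess,
      ", seed ", stage_seed(4L))
  networks <- run_stage("bn", suppressWarnings(
    infer_module_networks(profile, clustering, features = sel_features,
                          seed = stage_seed(4L), ess = cfg$ess,
                          max_parents = cfg$max_parents,
                          min_n = max(20L, cfg$min_size))))
  write_sif(networks$global, file.path(out_dir, "network_global.sif"))
  for (nm in names(networks$modules)) {
    write_sif(networks$modules[[nm]],
              file.path(out_dir, paste0("network_module_", nm, ".sif")))
  }
  if (cfg$n_random > 0L) {
    ctrl <- run_stage("bn", suppressWarnings(random_network_control(
      profile, n_datasets = cfg$n_random, features = sel_features,
      seed = stage_seed(4L), ess = cfg$ess,
      max_parents = cfg$max_parents)))
    write.table(ctrl$edges, file.path(out_dir, "network_random_control.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage 5: tally
  say("tally", "tallying interactions across ",
      length(networks$modules), " module network(s)")
  tally <- run_stage("tally",
                     tally_interactions(networks$modules, networks$global))
  write.table(tally, file.path(out_dir, "interaction_tally.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(log_lines, log_path)
  artifacts <- list.files(out_dir, full.names = TRUE)
  artifacts <- setdiff(artifacts, file.path(out_dir, "manifest.json"))
  manifest <- list(
    stages = c("profile", "select", "cluster", "bn", "tally"),
    seed = cfg$seed,
    stage_seeds = setNames(vapply(1:5, stage_seed, integer(1)),
                           c("profile", "select", "cluster", "bn", "tally")),
    parameters = cfg[c("alpha", "folds", "permutations",
                       "homogeneity_threshold", "min_size", "ess",
                       "max_parents", "n_random")],
    files = setNames(as.list(unname(tools::md5sum(artifacts))),
                     basename(artifacts))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(profile = profile, model = model, clustering = clustering,
                 networks = networks, tally = tally, out_dir = out_dir,
                 manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:", x$out_dir, "\n")
  cat("  stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat("  selected:", paste(x$model$selection$selected, collapse = ", "), "\n")
  cat("  modules:", length(x$clustering$modules), "\n")
  invisible(x)
}
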