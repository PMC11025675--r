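#' End-to-end run configuration
#'
#' Validates every stage's settings up front so a bad configuration fails
#' before any computation starts.
#'
#' @param cohort a `cohort_dataset`, a cohort directory path, or a
#'   [generator_config()] (the cohort is then generated).
#' @param kinds network kinds to analyze, subset of `c("LOFC", "HOFC")`.
#' @param grid sparsity grid.
#' @param n_nulls rewired nulls per graph (0 skips small-world indices).
#' @param nbs an [nbs_config()] or `NULL` to skip NBS.
#' @param run_classifier run the LASSO + SVM LOOCV stage.
#' @param preprocess apply [preprocess_cohort()] before connectivity.
#' @param seed master seed fanned out to per-stage child seeds.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = generator_config(), kinds = c("LOFC", "HOFC"),
                       grid = seq(0.06, 0.40, by = 0.01), n_nulls = 100,
                       nbs = nbs_config(), run_classifier = TRUE,
                       preprocess = FALSE, seed = 1, out_dir = tempfile("hofcnet_run_")) {
  bad <- setdiff(kinds, c("LOFC", "HOFC"))
  if (length(bad) > 0) {
    stop("unknown network kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(grid) < 2 || any(diff(grid) <= 0) || grid[1] <= 0 || grid[length(grid)] > 1) {
    stop("sparsity grid must be strictly increasing within (0, 1]", call. = FALSE)
  }
  if (!is.null(nbs)) stopifnot(inherits(nbs, "nbs_config"))
  structure(list(cohort = cohort, kinds = kinds, grid = grid,
                 n_nulls = n_nulls, nbs = nbs,
                 run_classifier = isTRUE(run_classifier),
                 preprocess = isTRUE(preprocess),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full two-group network analysis pipeline
#'
#' Stage order: cohort (load or generate) -> optional temporal
#' preprocessing -> LOFC / Fisher-z / HOFC construction -> graph metrics
#' over the sparsity grid with AUC summaries -> modular and rich-club
#' organization -> NBS -> classification -> covariate-adjusted group
#' comparisons. Every artifact is written under `config$out_dir` and
#' listed with its content hash in `manifest.json`; a rerun with the same
#' configuration and seed reproduces all numeric outputs.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; the full results list is
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "cohort"
  result <- tryCatch({
    cohort <- if (inherits(config$cohort, "cohort_dataset")) {
      config$cohort
    } else if (inherits(config$cohort, "generator_config")) {
      generate_cohort(config$cohort)
    } else {
      read_cohort(config$cohort)
    }
    utils::write.csv(cohort_demographics(cohort),
                     file.path(config$out_dir, "demographics.csv"),
                     row.names = FALSE)

    if (config$preprocess) {
      stage <- "signal_prep"
      cohort <- preprocess_cohort(cohort)
    }

    stage <- "connectivity"
    subj <- cohort$subjects
    nets <- list()
    for (id in subj$subject_id) {
      lofc <- lofc_matrix(cohort$timeseries[[id]],
                          region_labels = cohort$region_labels)
      nets$LOFC[[id]] <- lofc
      if ("HOFC" %in% config$kinds) {
        nets$HOFC[[id]] <- hofc_matrix(fisher_z(lofc))
      }
    }
    nets <- nets[config$kinds]

    covars <- data.frame(age = subj$age,
                         gender = as.numeric(subj$gender == "M"),
                         education = subj$education)
    results <- list(cohort = cohort)

    for (kind in config$kinds) {
      stage <- paste0("graphmetrics_", kind)
      mt <- compute_metric_table(nets[[kind]], grid = config$grid,
                                 n_nulls = config$n_nulls,
                                 seed = derive_seed(config$seed, paste0("metrics", kind)))
      write_long_metrics(mt, kind, config$out_dir)

      stage <- paste0("mesoscale_", kind)
      meso <- mesoscale_stage(nets[[kind]], cohort$partition, subj$group,
                              config$grid, config$out_dir, kind)

      stage <- paste0("groupstats_", kind)
      gs <- compare_measures(mt$auc[match(subj$subject_id, mt$auc$subject),
                                    -1, drop = FALSE],
                             subj$group, covars,
                             seed = derive_seed(config$seed, paste0("gs", kind)))
      gs$network_kind <- kind
      utils::write.csv(gs, file.path(config$out_dir,
                                     paste0("group_comparisons_", kind, ".csv")),
                       row.names = FALSE)

      nbs_res <- NULL
      if (!is.null(config$nbs)) {
        stage <- paste0("nbs_", kind)
        cfg <- config$nbs
        cfg$seed <- derive_seed(config$seed, paste0("nbs", kind))
        nbs_res <- nbs_test(nets[[kind]], subj$group, covars, cfg)
        write_nbs_outputs(nbs_res, cohort$region_labels, config$out_dir, kind)
      }

      clf <- NULL
      if (config$run_classifier) {
        stage <- paste0("classify_", kind)
        feats <- t(vapply(nets[[kind]], clustering_features,
                          numeric(length(cohort$region_labels))))
        rownames(feats) <- subj$subject_id
        clf <- nested_loocv_classify(feats, subj$group,
                                     seed = derive_seed(config$seed, paste0("clf", kind)))
        jsonlite::write_json(
          list(kind = kind, metrics = clf$metrics, folds = clf$folds),
          file.path(config$out_dir, paste0("classification_report_", kind, ".json")),
          auto_unbox = TRUE, digits = NA)
        utils::write.csv(roc_points(clf$folds$truth, clf$folds$decision),
                         file.path(config$out_dir, paste0("roc_", kind, ".csv")),
                         row.names = FALSE)
      }
      results[[kind]] <- list(metrics = mt, mesoscale = meso,
                              group_comparisons = gs, nbs = nbs_res,
                              classification = clf)
    }

    stage <- "manifest"
    files <- setdiff(list.files(config$out_dir, recursive = TRUE), "manifest.json")
    manifest <- list(
      package_version = as.character(utils::packageVersion("hofcnet")),
      seed = config$seed, kinds = config$kinds,
      n_sparsities = length(config$grid), n_nulls = config$n_nulls,
      files = lapply(stats::setNames(files, files), function(f) {
        unname(tools::md5sum(file.path(config$out_dir, f)))
      })
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out <- config$out_dir
  attr(out, "results") <- result
  invisible(out)
}

write_long_metrics <- function(mt, kind, out_dir) {
  g <- mt$global
  long <- do.call(rbind, lapply(c("cp", "lp", "eglob", "eloc", "gamma",
                                  "lambda", "sigma"), function(mc) {
    data.frame(subject = g$subject, network_kind = kind, sparsity = g$sparsity,
               metric = mc, node_or_global = "global", value = g[[mc]],
               stringsAsFactors = FALSE)
  }))
  nd <- mt$nodal
  long_n <- do.call(rbind, lapply(c("bc", "dc", "ne"), function(mc) {
    data.frame(subject = nd$subject, network_kind = kind, sparsity = nd$sparsity,
               metric = mc, node_or_global = as.character(nd$node),
               value = nd[[mc]], stringsAsFactors = FALSE)
  }))
  f <- file.path(out_dir, paste0("metrics_", kind, ".csv"))
  utils::write.csv(rbind(long, long_n), f, row.names = FALSE)
  utils::write.csv(mt$auc, file.path(out_dir, paste0("auc_", kind, ".csv")),
                   row.names = FALSE)
}

mesoscale_stage <- function(kind_nets, partition, groups, grid, out_dir, kind) {
  groups <- as.character(groups)
  strengths <- lapply(kind_nets, modular_strengths, partition = partition)
  rich <- lapply(split(kind_nets, groups), rich_club_nodes, grid = grid)
  rich_df <- do.call(rbind, lapply(names(rich), function(grp) {
    data.frame(network_kind = kind, group = grp,
               region = names(rich[[grp]]) %||% rich[[grp]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rich_df, file.path(out_dir, paste0("richclub_", kind, ".csv")),
                   row.names = FALSE)
  intra_df <- do.call(rbind, lapply(names(strengths), function(id) {
    s <- strengths[[id]]
    rbind(
      data.frame(subject = id, block = names(s$intra), type = "intra",
                 strength = unname(s$intra), stringsAsFactors = FALSE),
      data.frame(subject = id,
                 block = paste0(s$inter$module_a, "-", s$inter$module_b),
                 type = "inter", strength = s$inter$strength,
                 stringsAsFactors = FALSE)
    )
  }))
  utils::write.csv(intra_df,
                   file.path(out_dir, paste0("modular_strengths_", kind, ".csv")),
                   row.names = FALSE)
  list(strengths = strengths, rich_nodes = rich)
}

write_nbs_outputs <- function(nbs_res, region_labels, out_dir, kind) {
  comps <- nbs_res$components
  if (length(comps) > 0) {
    df <- do.call(rbind, lapply(seq_along(comps), function(ci) {
      cmp <- comps[[ci]]
      data.frame(component = ci,
                 region_a = region_labels[cmp$edges[, 1]],
                 region_b = region_labels[cmp$edges[, 2]],
                 t = nbs_res$t_matrix[cmp$edges],
                 corrected_p = cmp$corrected_p, stringsAsFactors = FALSE)
    }))
  } else {
    df <- data.frame(component = integer(), region_a = character(),
                     region_b = character(), t = numeric(),
                     corrected_p = numeric())
  }
  utils::write.csv(df, file.path(out_dir, paste0("nbs_components_", kind, ".csv")),
                   row.names = FALSE)
  sig <- Filter(function(cmp) cmp$corrected_p < nbs_res$config$alpha, comps)
  if (length(sig) > 0) {
    p <- length(region_labels)
    edge_m <- matrix(0, p, p)
    for (cmp in sig) edge_m[cmp$edges] <- nbs_res$t_matrix[cmp$edges]
    edge_m <- edge_m + t(edge_m)
    in_comp <- as.numeric(seq_len(p) %in% unlist(lapply(sig, `[[`, "nodes")))
    write_brainnet(
      nodes = data.frame(synthetic_coordinates(p), color = in_comp,
                         size = in_comp, label = region_labels),
      edges = edge_m,
      node_path = file.path(out_dir, paste0("nbs_significant_", kind, ".node")),
      edge_path = file.path(out_dir, paste0("nbs_significant_", kind, ".edge"))
    )
  }
}

#' Write BrainNet Viewer node and edge files
#'
#' `.node`: six whitespace-delimited columns (x, y, z, color, size,
#' label); `.edge`: P x P whitespace-delimited matrix.
#'
#' @param nodes data.frame with columns x, y, z, color, size, label.
#' @param edges symmetric P x P numeric matrix.
#' @param node_path,edge_path output paths.
#' @return named list of the two paths, invisibly.
#' @export
write_brainnet <- function(nodes, edges, node_path, edge_path) {
  stopifnot(is.data.frame(nodes), is.matrix(edges))
  if (nrow(nodes) != ncol(edges)) {
    stop("coordinate count (", nrow(nodes), ") does not match edge matrix size (",
         ncol(edges), ")", call. = FALSE)
  }
  need <- c("x", "y", "z", "color", "size", "label")
  if (!all(need %in% names(nodes))) {
    stop(".node table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  utils::write.table(nodes[, need], node_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_edge_matrix(edges, edge_path)
  invisible(list(node = node_path, edge = edge_path))
}
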