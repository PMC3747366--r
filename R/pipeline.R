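#' Pipeline configuration
#'
#' Bundles the sub-configurations of the full workflow; together with the
#' seed it determines every non-bootstrap output.
#'
#' @param generator a [polyspecific_config] (NULL to supply real data to
#'   [run_pipeline] instead).
#' @param partition a [partition_config].
#' @param n_pools number of random-subspace descriptor pools (reference
#'   workflow: 102).
#' @param pool_target_size target descriptors per pool (default 200).
#' @param tolerances stepwise tolerance sweep (default \code{c(0.1, 0.3, 0.5)},
#'   spanning the 0.1-0.5 range).
#' @param max_steps_sweep stepwise maximum-steps sweep (default
#'   \code{c(10, 15)}).
#' @param sp_lo high-specificity band lower end for ensemble selection
#'   (default 0.70).
#' @param n_decoys decoys in the simulated screening library (reference
#'   campaign: 479).
#' @param n_boot bootstrap replicates for pAUC (default 2000).
#' @param ef_x EF selection fraction (default 0.10).
#' @param bedroc_alpha RIE/BEDROC exponent (default 20).
#' @param seed global seed; stage seeds are derived from it.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(generator = polyspecific_config(),
                            partition = partition_config(),
                            n_pools = 102, pool_target_size = 200,
                            tolerances = c(0.1, 0.3, 0.5),
                            max_steps_sweep = c(10, 15),
                            sp_lo = 0.70, n_decoys = 479, n_boot = 2000,
                            ef_x = 0.10, bedroc_alpha = 20, seed = 1) {
  structure(list(generator = generator, partition = partition,
                 n_pools = n_pools, pool_target_size = pool_target_size,
                 tolerances = tolerances, max_steps_sweep = max_steps_sweep,
                 sp_lo = sp_lo, n_decoys = n_decoys, n_boot = n_boot,
                 ef_x = ef_x, bedroc_alpha = bedroc_alpha, seed = seed),
            class = "pipeline_config")
}

#' Run the full modeling and evaluation workflow
#'
#' Executes, in order: synthetic-data generation (or ingestion of supplied
#' data), cluster-based train/test partition, low-information descriptor
#' filtering on the training rows, random-subspace pool generation, stepwise
#' LDA model building over the tolerance and max-steps sweep, exhaustive
#' two-model ensemble enumeration with AVE/MAX fusion, ROC comparison of the
#' best ensemble against the best individual model (paired z-test and pAUC
#' bootstrap), and the decoy-spiked simulated screening campaign. Artifacts
#' are written under \code{out_dir} in subdirectories \code{split/},
#' \code{pools/}, \code{models/}, \code{ensembles/}, \code{roc/},
#' \code{screening/}, plus a manifest recording the configuration and seed.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if missing).
#' @param dataset optional \code{synthetic_dataset}-shaped list with
#'   \code{compounds} and \code{descriptors}; when NULL the generator in
#'   \code{config} is run.
#' @return invisibly, a list with the key stage results: \code{split},
#'   \code{models}, \code{leaderboard}, \code{best_ensemble},
#'   \code{roc_comparison}, \code{pauc}, \code{screening}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dirs <- file.path(out_dir, c("split", "pools", "models", "ensembles",
                               "roc", "screening"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logline <- function(stage, msg)
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = log_path, append = TRUE)

  # stage 1: data
  if (is.null(dataset)) dataset <- generate_polyspecific(config$generator)
  dm <- dataset$descriptors
  compounds <- dataset$compounds
  logline("data", sprintf("%d compounds x %d descriptors",
                          nrow(dm$values), ncol(dm$values)))

  # stage 2: partition (descriptor-space clustering for SMILES-free data)
  have_smiles <- !any(is.na(compounds$smiles))
  clusters <- if (have_smiles)
    hierarchical_structural_clusters(compounds, config$partition)
  else hierarchical_descriptor_clusters(dm$values, compounds$label)
  prop <- intersect(config$partition$property_descriptors,
                    colnames(dm$values))
  if (length(prop) < 2) prop <- colnames(dm$values)[1:min(9, ncol(dm$values))]
  clusters <- kmeans_refine(clusters, dm$values[, prop, drop = FALSE],
                            compounds$label)
  plan <- assign_split(clusters, compounds, config$partition)
  write_split_plan(plan, file.path(out_dir, "split", "split_plan.csv"),
                   file.path(out_dir, "split", "split_summary.json"))
  compounds <- plan$compounds
  train_ids <- compounds$id[compounds$set == "train"]
  test_ids <- compounds$id[compounds$set == "test"]
  logline("split", sprintf("%d train / %d test", length(train_ids),
                           length(test_ids)))

  # stage 3: low-information filter on training rows, then pools
  dmf <- filter_low_information(impute_nonfinite(dm, train_ids), train_ids)
  pools <- generate_pools(dmf$blocks, config$n_pools,
                          target_size = min(config$pool_target_size,
                                            ncol(dmf$values)),
                          seed = config$seed + 101L)
  jsonlite::write_json(lapply(pools, unclass),
                       file.path(out_dir, "pools", "pools.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("pools", sprintf("%d pools", length(pools)))

  # stage 4: models over the tolerance x max-steps sweep
  ytr <- compounds$label[match(train_ids, compounds$id)]
  yte <- compounds$label[match(test_ids, compounds$id)]
  Xtr <- dmf$values[train_ids, , drop = FALSE]
  Xte <- dmf$values[test_ids, , drop = FALSE]
  models <- list()
  for (pool in pools) {
    for (tol in config$tolerances) {
      for (ms in config$max_steps_sweep) {
        cfg <- selection_config(tolerance_min = tol, max_steps = ms)
        m <- build_model(Xtr[, pool$descriptors, drop = FALSE], ytr,
                         config = cfg, pool_id = pool$pool_id)
        if (!is.null(m)) {
          mid <- sprintf("%s_t%s_s%d", pool$pool_id, tol, ms)
          models[[mid]] <- m
        }
      }
    }
  }
  # drop duplicate descriptor sets arising from different sweep settings
  sig <- vapply(models, function(m) paste(m$descriptors, collapse = "|"), "")
  models <- models[!duplicated(sig)]
  if (length(models) < 2) stop("fewer than 2 distinct models built")
  for (mid in names(models))
    write_model_json(models[[mid]],
                     file.path(out_dir, "models", paste0(mid, ".json")))
  logline("models", sprintf("%d distinct models", length(models)))

  # stage 5: exhaustive 2-model fusion, ranked by external FP count
  test_scores <- vapply(models, function(m)
    predict(m, Xte, type = "score"), numeric(length(test_ids)))
  lb <- enumerate_ensembles(test_scores, yte, sp_lo = config$sp_lo)
  utils::write.csv(lb, file.path(out_dir, "ensembles", "leaderboard.csv"),
                   row.names = FALSE)
  best <- lb[1, ]
  best_ens <- ensemble(models[[best$model_a]], models[[best$model_b]],
                       best$operator)
  logline("ensembles", sprintf("best: %s %s+%s (FP %d)", best$operator,
                               best$model_a, best$model_b, best$fp))

  # stage 6: ROC statistics, best ensemble vs best individual model
  ind_auc <- vapply(names(models), function(mid) {
    s <- test_scores[, mid]
    .delong_components(-s, yte == -1)$auc
  }, 0)
  best_ind <- names(which.max(ind_auc))
  rk_ind <- scored_ranking(test_ids, test_scores[, best_ind], yte)
  rk_ens <- scored_ranking(test_ids,
                           fuse_scores(test_scores[, best$model_a],
                                       test_scores[, best$model_b],
                                       best$operator), yte)
  cmp <- compare_auc(rk_ens, rk_ind)
  pa <- partial_auc(rk_ens, config$sp_lo, n_boot = config$n_boot,
                    seed = config$seed + 202L, comparator = rk_ind)
  jsonlite::write_json(list(best_individual = best_ind,
                            comparison = unclass(cmp),
                            pauc = unclass(pa)),
                       file.path(out_dir, "roc", "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("roc", sprintf("ensemble AUC %.3f vs individual %.3f (p = %.3g)",
                         cmp$auc_a, cmp$auc_b, cmp$p_value))

  # stage 7: decoy-spiked simulated screening campaign
  screening <- NULL
  if (inherits(dataset, "synthetic_dataset") && config$n_decoys > 0) {
    dec <- generate_decoys(dataset, config$n_decoys,
                           seed = config$seed + 303L)
    lib_vals <- rbind(Xte,
                      impute_nonfinite(
                        descriptor_matrix(dec$values, dm$blocks))$values[,
                        colnames(Xte), drop = FALSE])
    lib_scores <- predict(best_ens, lib_vals, type = "score")
    lib_labels <- c(yte, dec$compounds$label)
    lib_prov <- c(rep("known", length(yte)), dec$compounds$provenance)
    screening <- run_screening_campaign(lib_scores, lib_labels,
                                        ids = rownames(lib_vals),
                                        provenance = lib_prov,
                                        x = config$ef_x,
                                        alpha = config$bedroc_alpha)
    jsonlite::write_json(unclass(screening),
                         file.path(out_dir, "screening", "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    logline("screening", sprintf("N %d, A %d, BEDROC %.3f", screening$N,
                                 screening$A, screening$BEDROC))
  }

  manifest <- list(seed = config$seed,
                   n_pools = config$n_pools,
                   n_models = length(models),
                   config = rapply(unclass(config), unclass, how = "replace"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(split = plan, models = models, leaderboard = lb,
                 best_ensemble = best_ens, roc_comparison = cmp, pauc = pa,
                 screening = screening))
}
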