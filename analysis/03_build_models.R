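# Stage 3: random-subspace stepwise LDA model building.
#
# Removes low-information descriptors (training rows only), draws 102
# random block-combination pools of ~200 descriptors, and builds one
# discriminant function per pool and stepwise setting (tolerance 0.1-0.5,
# max steps 10-15). Duplicate descriptor sets are dropped. Each model is
# serialized as JSON; df scores on the training set, test set and the
# decoy-spiked screening library are written as CSV for the later stages.

source("analysis/00_settings.R")

plan <- utils::read.csv(file.path(RESULTS, "split", "split_plan.csv"))
dm <- read_descriptor_matrix(file.path(RESULTS, "data", "descriptors.csv"),
                             file.path(RESULTS, "data", "block_manifest.json"))
dec <- read_descriptor_matrix(
  file.path(RESULTS, "data", "decoy_descriptors.csv"),
  file.path(RESULTS, "data", "decoy_block_manifest.json"))

train_ids <- plan$id[plan$set == "train"]
test_ids <- plan$id[plan$set == "test"]
ytr <- plan$label[plan$set == "train"]
yte <- plan$label[plan$set == "test"]

dmf <- filter_low_information(impute_nonfinite(dm, train_ids), train_ids)
cat(sprintf("Low-information filter kept %d of %d descriptors.\n",
            ncol(dmf$values), ncol(dm$values)))

pools <- generate_pools(dmf$blocks, N_POOLS, target_size = POOL_TARGET,
                        seed = SEED + 3L)
Xtr <- dmf$values[train_ids, ]
models <- list()
for (pool in pools) {
  for (tol in TOLERANCES) {
    for (ms in MAX_STEPS) {
      cfg <- selection_config(tolerance_min = tol, max_steps = ms)
      m <- build_model(Xtr[, pool$descriptors, drop = FALSE], ytr,
                       config = cfg, pool_id = pool$pool_id)
      if (!is.null(m))
        models[[sprintf("%s_t%s_s%d", pool$pool_id, tol, ms)]] <- m
    }
  }
}
sig <- vapply(models, function(m) paste(m$descriptors, collapse = "|"), "")
models <- models[!duplicated(sig)]
cat(sprintf("Built %d distinct discriminant functions from %d pools.\n",
            length(models), length(pools)))

for (mid in names(models))
  write_model_json(models[[mid]], res_path("models", paste0(mid, ".json")))

summ <- do.call(rbind, lapply(names(models), function(mid) {
  m <- models[[mid]]
  data.frame(model = mid, pool = m$pool_id,
             n_descriptors = length(m$descriptors),
             cases_per_predictor = round(m$cases_per_predictor, 1),
             F = round(m$F, 2), p = signif(m$p_value, 3),
             train_Sp = round(m$training$Sp, 3),
             train_Se = round(m$training$Se, 3),
             train_acc = round(m$training$accuracy, 3))
}))
utils::write.csv(summ, res_path("models", "models_summary.csv"),
                 row.names = FALSE)

score_table <- function(X) vapply(models, function(m)
  predict(m, X, type = "score"), numeric(nrow(X)))
lib_ids <- c(test_ids, rownames(dec$values))
lib <- rbind(dmf$values[test_ids, ], dec$values[, colnames(dmf$values)])
utils::write.csv(data.frame(id = train_ids, label = ytr,
                            score_table(dmf$values[train_ids, ]),
                            check.names = FALSE),
                 res_path("models", "train_scores.csv"), row.names = FALSE)
utils::write.csv(data.frame(id = test_ids, label = yte,
                            score_table(dmf$values[test_ids, ]),
                            check.names = FALSE),
                 res_path("models", "test_scores.csv"), row.names = FALSE)
utils::write.csv(data.frame(id = lib_ids,
                            label = c(yte, rep(1L, nrow(dec$values))),
                            provenance = c(rep("known", length(test_ids)),
                                           rep("putative", nrow(dec$values))),
                            score_table(lib), check.names = FALSE),
                 res_path("models", "library_scores.csv"), row.names = FALSE)
cat("Scores written for train, test and screening library.\n")
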