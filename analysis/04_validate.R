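# Stage 4: robustness protocols for the best individual model's pool.
#
# Runs the label-randomization test (50 scrambles, selection redone per
# scramble) and stratified leave-group-out cross-validation (50 rounds of
# 10 removals, coverage-checked) on the pool that produced the best
# individual model by test-set AUC, plus external validation on the test
# set.

source("analysis/00_settings.R")

plan <- utils::read.csv(file.path(RESULTS, "split", "split_plan.csv"))
dm <- read_descriptor_matrix(file.path(RESULTS, "data", "descriptors.csv"),
                             file.path(RESULTS, "data", "block_manifest.json"))
test_scores <- utils::read.csv(file.path(RESULTS, "models", "test_scores.csv"),
                               check.names = FALSE)

train_ids <- plan$id[plan$set == "train"]
test_ids <- plan$id[plan$set == "test"]
ytr <- plan$label[plan$set == "train"]
yte <- plan$label[plan$set == "test"]
dmf <- filter_low_information(impute_nonfinite(dm, train_ids), train_ids)

model_cols <- setdiff(colnames(test_scores), c("id", "label"))
auc_of <- function(s) empirical_roc(scored_ranking(test_ids, s, yte))$auc
test_auc <- vapply(model_cols, function(m) auc_of(test_scores[[m]]), 0)
best_id <- names(which.max(test_auc))
best_pool <- sub("_t[0-9.]+_s[0-9]+$", "", best_id)
cat(sprintf("Best individual model on the test set: %s (AUC %.3f)\n",
            best_id, max(test_auc)))

pools <- generate_pools(dmf$blocks, N_POOLS, target_size = POOL_TARGET,
                        seed = SEED + 3L)
pool <- pools[[which(vapply(pools, function(p) p$pool_id, "") == best_pool)]]
Xtr <- dmf$values[train_ids, pool$descriptors, drop = FALSE]
Xte <- dmf$values[test_ids, pool$descriptors, drop = FALSE]

vr <- validation_report(Xtr, ytr, Xte, yte, selection_config(),
                        n_random = 50, lgo_rounds = 50, lgo_group_size = 10,
                        seed = SEED + 4L)
print(vr)

jsonlite::write_json(
  list(model = best_id, pool = best_pool,
       test_auc = unname(max(test_auc)),
       randomization = vr$randomization[c("mean", "sd", "n_empty")],
       lgo = vr$lgo[c("mean", "sd", "coverage")],
       external = unclass(vr$external)),
  res_path("validation", "report.json"), auto_unbox = TRUE, digits = NA)
cat("Validation report written.\n")
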