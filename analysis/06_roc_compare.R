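# Stage 6: statistical comparison of ROC curves.
#
# Compares the selected ensemble against the best individual model on the
# training set and on the test set: total AUC with the paired DeLong
# z-test, and partial AUC over the high-specificity bands Sp in [0.70, 1],
# [0.75, 1], [0.80, 1] with stratified bootstrap (n = 2000) difference
# tests.

source("analysis/00_settings.R")

best <- jsonlite::read_json(file.path(RESULTS, "ensembles", "best.json"),
                            simplifyVector = TRUE)

for_set <- function(file) {
  sc <- utils::read.csv(file.path(RESULTS, "models", file),
                        check.names = FALSE)
  model_cols <- setdiff(colnames(sc), c("id", "label", "provenance"))
  aucs <- vapply(model_cols, function(m)
    empirical_roc(scored_ranking(sc$id, sc[[m]], sc$label))$auc, 0)
  best_ind <- names(which.max(aucs))
  fused <- fuse_scores(sc[[best$model_a]], sc[[best$model_b]], best$operator)
  list(ind = scored_ranking(sc$id, sc[[best_ind]], sc$label),
       ens = scored_ranking(sc$id, fused, sc$label),
       best_ind = best_ind)
}

out <- list()
for (setname in c("train", "test")) {
  rks <- for_set(sprintf("%s_scores.csv", setname))
  cmp <- compare_auc(rks$ens, rks$ind)
  cat(sprintf("\n%s set: ensemble AUC %.4f vs %s AUC %.4f (z = %.2f, p = %.3g)\n",
              setname, cmp$auc_a, rks$best_ind, cmp$auc_b, cmp$z,
              cmp$p_value))
  bands <- lapply(seq_along(SP_LO), function(i) {
    pa <- partial_auc(rks$ens, SP_LO[i], n_boot = N_BOOT,
                      seed = SEED + 10L + i, comparator = rks$ind)
    cat(sprintf("  pAUC Sp in [%.2f, 1]: ensemble %.4f (+/- %.4f) vs %.4f, p = %.3g\n",
                SP_LO[i], pa$pauc, pa$sd, pa$pauc_comparator, pa$p_value))
    list(sp_lo = SP_LO[i], pauc = pa$pauc, sd = pa$sd,
         ci = pa$ci, comparator = pa$pauc_comparator, p = pa$p_value)
  })
  out[[setname]] <- list(best_individual = rks$best_ind,
                         auc_comparison = unclass(cmp), pauc = bands)
}
jsonlite::write_json(out, res_path("roc", "comparison.json"),
                     auto_unbox = TRUE, digits = NA)
cat("\nROC comparison written.\n")
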