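# Stage 2: rational train/test partition.
#
# Class-wise hierarchical clustering in descriptor space (the synthetic
# compounds carry no SMILES; structural fingerprint clustering is used for
# real molecules), refined by k-means on nine normalized property
# descriptors, then cluster-wise assignment of ~50% of each substrate
# cluster and ~25% of each nonsubstrate cluster to the external test set.

source("analysis/00_settings.R")

compounds <- read_compounds(file.path(RESULTS, "data", "compounds.csv"))
dm <- read_descriptor_matrix(file.path(RESULTS, "data", "descriptors.csv"),
                             file.path(RESULTS, "data", "block_manifest.json"))

clusters <- hierarchical_descriptor_clusters(dm$values, compounds$label)
prop_cols <- colnames(dm$values)[1:9]
clusters <- kmeans_refine(clusters, dm$values[, prop_cols], compounds$label)
plan <- assign_split(clusters, compounds,
                     partition_config(seed = SEED + 2L))

write_split_plan(plan, res_path("split", "split_plan.csv"),
                 res_path("split", "split_summary.json"))
print(plan)
cat(sprintf("Per-cluster assignment written for %d clusters.\n",
            nrow(plan$summary)))
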