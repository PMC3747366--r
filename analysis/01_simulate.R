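# Stage 1: simulate the study dataset.
#
# Generates a 262-compound dataset with the block-structured descriptor
# matrix and polyspecific (two-binding-site OR rule) class labels that the
# modeling workflow assumes, plus a pool of 479 decoy putative substrates
# for the later screening simulation. Everything is written as CSV/JSON so
# downstream stages are file-driven.

source("analysis/00_settings.R")

ds <- generate_polyspecific(GEN_CONFIG)
dec <- generate_decoys(ds, N_DECOYS, seed = SEED + 1L)

write_compounds(ds$compounds, res_path("data", "compounds.csv"))
write_descriptor_matrix(ds$descriptors, res_path("data", "descriptors.csv"),
                        res_path("data", "block_manifest.json"))
write_compounds(dec$compounds, res_path("data", "decoys.csv"))
write_descriptor_matrix(descriptor_matrix(dec$values, ds$descriptors$blocks),
                        res_path("data", "decoy_descriptors.csv"),
                        res_path("data", "decoy_block_manifest.json"))
jsonlite::write_json(
  list(informative_site1 = ds$ground_truth$informative_site1,
       informative_site2 = ds$ground_truth$informative_site2,
       threshold = ds$ground_truth$threshold_site1),
  res_path("data", "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d compounds (%d substrates / %d nonsubstrates),\n",
            nrow(ds$compounds), sum(ds$compounds$label == 1),
            sum(ds$compounds$label == -1)))
cat(sprintf("%d descriptors in %d blocks; %d decoy putative substrates.\n",
            ncol(ds$descriptors$values), length(ds$descriptors$blocks),
            nrow(dec$values)))
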