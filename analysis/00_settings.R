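# Shared settings for the analysis scripts. Each numbered script is a thin
# driver over the bcrpscreen package; run them in order from the repository
# root. All randomness flows from SEED.

suppressMessages(library(bcrpscreen))

SEED <- 20130801L                 # one seed for the whole campaign
RESULTS <- "results"

GEN_CONFIG <- polyspecific_config(seed = SEED)   # 262 compounds, 12 blocks
N_DECOYS <- 479
N_POOLS <- 102
POOL_TARGET <- 200
TOLERANCES <- c(0.1, 0.3, 0.5)
MAX_STEPS <- c(10, 15)
SP_LO <- c(0.70, 0.75, 0.80)
N_BOOT <- 2000

res_path <- function(...) {
  p <- file.path(RESULTS, ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}
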