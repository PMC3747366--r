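# shared fixtures and independent oracles for the test suite

# ranking shortcut: substrate-style orientation, higher score = hit
rk <- function(scores, hits, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("c%03d", seq_along(scores))
  scored_ranking(ids, scores, hits, hit_definition = "substrate_is_hit",
                 direction = "descending")
}

# random ranking with optional score ties
random_ranking <- function(n, ra, tie_levels = 0) {
  h <- rep(FALSE, n)
  h[sample(n, max(1, round(ra * n)))] <- TRUE
  if (any(h) && all(h)) h[1] <- FALSE
  s <- if (tie_levels > 0) sample(seq_len(tie_levels), n, replace = TRUE)
       else stats::rnorm(n)
  rk(s, h)
}

# brute-force Mann-Whitney AUC oracle: count correctly ordered hit/non-hit
# pairs, ties counted one half
mw_auc_oracle <- function(ranking) {
  s <- ranking$scores
  if (ranking$direction == "ascending") s <- -s
  x <- s[ranking$hits]; y <- s[!ranking$hits]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# direct-sum RIE oracle: explicit loops, denominator summed rank by rank
rie_oracle <- function(ranking, alpha) {
  s <- ranking$scores
  if (ranking$direction == "ascending") s <- -s
  h <- ranking$hits[order(-s)]
  N <- length(h); A <- sum(h)
  num <- 0
  for (i in seq_len(N)) if (h[i]) num <- num + exp(-alpha * i / N)
  den <- 0
  for (i in seq_len(N)) den <- den + exp(-alpha * i / N)
  (num / A) / (den / N)
}

bedroc_oracle <- function(ranking, alpha) {
  h <- ranking$hits
  ra <- mean(h)
  rie_oracle(ranking, alpha) * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

# small, fast synthetic configuration for unit tests
syn_small <- function(seed, n = 120, label_noise = 0.1) {
  polyspecific_config(n_compounds = n, n_blocks = 4,
                      descriptors_per_block = 15, label_noise = label_noise,
                      seed = seed)
}

# two obvious scaffold families for structural clustering tests
family_smiles <- c(
  b1 = "c1ccccc1C", b2 = "c1ccccc1CC", b3 = "c1ccccc1CCC",
  b4 = "c1ccccc1O", b5 = "c1ccccc1N", b6 = "c1ccccc1Cl",
  a1 = "CCCCCC", a2 = "CCCCCCC", a3 = "CCCCCCCC",
  a4 = "CCCCC(C)C", a5 = "CCCC(C)CC", a6 = "CCCCCCCCC")

compound_table <- function(smiles, labels) {
  data.frame(id = names(smiles), smiles = unname(smiles), label = labels,
             set = "unassigned", cluster = NA_integer_, provenance = "known",
             stringsAsFactors = FALSE)
}

# hand-built discriminant model for score-arithmetic tests
manual_model <- function(intercept, coefficients) {
  structure(list(descriptors = names(coefficients),
                 coefficients = coefficients, intercept = intercept,
                 config = selection_config(min_cases_per_predictor = 1)),
            class = "discriminant_model")
}
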