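#' Configuration for the polyspecific synthetic-data generator
#'
#' The generator emulates the statistical structure the modeling workflow
#' assumes: a block-organized descriptor matrix (blocks of correlated
#' Gaussian descriptors, mimicking families of related molecular descriptors)
#' and class labels arising from TWO latent linear "binding-site" rules joined
#' by OR -- a compound is a substrate if either site rule fires. BCRP has at
#' least two binding sites, and an OR of half-spaces is exactly what a single
#' linear discriminant cannot express, which is what makes two-model
#' ensembles genuinely useful on such data.
#'
#' Each site rule k fires when
#'   s_k = effect_size * (w_k' x)/sd(w_k' x) + eps_k > t_k,  eps_k ~ N(0, 1),
#' with w_k supported on a small disjoint set of informative descriptors (the
#' two sites live in different blocks). The weights alternate in sign
#' (+1, -1, ...), which makes each site rule a contrast orthogonal to the
#' block's shared common factor: the rule is a specific descriptor
#' combination rather than a relabeling of the block-level variation, so
#' non-informative block mates carry no rule signal and each informative
#' descriptor contributes identifiable, non-redundant signal.
#' \code{effect_size} is the signal-to-latent-noise ratio of each site rule:
#' the standardized separation, along the rule direction, between compounds
#' the rule accepts and rejects grows with it. Thresholds t_k are set
#' analytically so the expected substrate fraction equals
#' \code{class_balance}. Emitted labels are then flipped independently with
#' probability \code{label_noise} (polyspecificity / assay noise stand-in).
#'
#' @param n_compounds number of compounds (default 262, the curated dataset
#'   size the workflow was designed around).
#' @param n_blocks number of descriptor blocks (default 12).
#' @param descriptors_per_block descriptors in each block (default 72, giving
#'   864 descriptors, close to the 867 low-dimensional descriptors of the
#'   reference panel).
#' @param n_informative_site1,n_informative_site2 informative descriptors
#'   per site rule (defaults 4 and 4; site 1 lives in block 1, site 2 in
#'   block 2, so the sets are disjoint by construction). Spreading a fixed
#'   rule effect over many correlated descriptors dilutes each below what
#'   forward selection can detect at n of a few hundred, so the default
#'   keeps each site compact.
#' @param effect_size signal-to-noise ratio of each site rule (default 1.5).
#' @param label_noise probability of flipping an emitted label (default 0.1;
#'   must be in \[0, 0.5)).
#' @param class_balance expected substrate fraction (default 0.6, matching
#'   156/262).
#' @param within_block_cor equicorrelation of descriptors within a block
#'   (default 0.3).
#' @param seed integer seed.
#' @return object of class \code{polyspecific_config}.
#' @export
polyspecific_config <- function(n_compounds = 262, n_blocks = 12,
                                descriptors_per_block = 72,
                                n_informative_site1 = 4,
                                n_informative_site2 = 4,
                                effect_size = 1.5, label_noise = 0.1,
                                class_balance = 0.6, within_block_cor = 0.3,
                                seed = 1) {
  stopifnot(n_compounds >= 4, n_blocks >= 2, descriptors_per_block >= 1,
            n_informative_site1 >= 1, n_informative_site2 >= 1,
            effect_size > 0, label_noise >= 0, label_noise < 0.5,
            within_block_cor >= 0, within_block_cor < 1)
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance unreachable under the two-site rules: it must lie ",
         "strictly between 0 and 1; adjust the thresholds via class_balance")
  if (n_informative_site1 > descriptors_per_block ||
      n_informative_site2 > descriptors_per_block)
    stop("informative descriptor count exceeds descriptors_per_block")
  structure(list(n_compounds = n_compounds, n_blocks = n_blocks,
                 descriptors_per_block = descriptors_per_block,
                 n_informative_site1 = n_informative_site1,
                 n_informative_site2 = n_informative_site2,
                 effect_size = effect_size, label_noise = label_noise,
                 class_balance = class_balance,
                 within_block_cor = within_block_cor, seed = seed),
            class = "polyspecific_config")
}

# draw n x p equicorrelated standard Gaussians (correlation rho)
.equicorr_gauss <- function(n, p, rho) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    common <- stats::rnorm(n)
    sqrt(rho) * common + sqrt(1 - rho) * z
  } else z
}

#' Generate a polyspecific synthetic dataset
#'
#' See [polyspecific_config] for the generating model. The returned ground
#' truth contains the site weight vectors, thresholds and the realized latent
#' site scores, which suffice to recompute the noiseless labels exactly.
#'
#' @param config a [polyspecific_config].
#' @return object of class \code{synthetic_dataset}: \code{compounds} (a
#'   compound table as from [read_compounds]), \code{descriptors} (a
#'   [descriptor_matrix]), \code{ground_truth} (weights, thresholds, latent
#'   site scores, informative descriptor names, noiseless labels).
#' @export
generate_polyspecific <- function(config = polyspecific_config()) {
  stopifnot(inherits(config, "polyspecific_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  pb <- config$descriptors_per_block
  rho <- config$within_block_cor
  blocks <- stats::setNames(
    lapply(seq_len(config$n_blocks), function(b)
      sprintf("B%02d_D%03d", b, seq_len(pb))),
    sprintf("block%02d", seq_len(config$n_blocks)))
  values <- do.call(cbind, lapply(seq_len(config$n_blocks), function(b)
    .equicorr_gauss(n, pb, rho)))
  colnames(values) <- unlist(blocks, use.names = FALSE)
  ids <- sprintf("SYN%04d", seq_len(n))
  rownames(values) <- ids

  m1 <- config$n_informative_site1
  m2 <- config$n_informative_site2
  inf1 <- blocks[[1]][seq_len(m1)]
  inf2 <- blocks[[2]][seq_len(m2)]
  w1 <- stats::setNames(rep(c(1, -1), length.out = m1), inf1)
  w2 <- stats::setNames(rep(c(1, -1), length.out = m2), inf2)
  # sd of w'x under the equicorrelated block covariance
  sd_rule <- function(w) sqrt(sum(outer(w, w) *
    ((1 - rho) * diag(length(w)) + rho)))
  es <- config$effect_size
  s1 <- unname(es * drop(values[, inf1, drop = FALSE] %*% w1) / sd_rule(w1) +
    stats::rnorm(n))
  s2 <- unname(es * drop(values[, inf2, drop = FALSE] %*% w2) / sd_rule(w2) +
    stats::rnorm(n))
  # P(either site fires) = 1 - (1 - p)^2 = class_balance, sites independent
  p_site <- 1 - sqrt(1 - config$class_balance)
  thr <- stats::qnorm(1 - p_site, sd = sqrt(1 + es^2))
  noiseless <- ifelse(s1 > thr | s2 > thr, 1L, -1L)
  flip <- stats::runif(n) < config$label_noise
  labels <- ifelse(flip, -noiseless, noiseless)

  compounds <- data.frame(id = ids, smiles = NA_character_,
                          label = as.integer(labels), set = "unassigned",
                          cluster = NA_integer_, provenance = "known",
                          stringsAsFactors = FALSE)
  structure(list(
    compounds = compounds,
    descriptors = descriptor_matrix(values, blocks),
    ground_truth = list(weights_site1 = w1, weights_site2 = w2,
                        threshold_site1 = thr, threshold_site2 = thr,
                        latent_site1 = s1, latent_site2 = s2,
                        informative_site1 = inf1, informative_site2 = inf2,
                        noiseless_labels = noiseless, config = config)),
    class = "synthetic_dataset")
}

#' Recompute noiseless labels from a dataset's ground truth
#'
#' @param dataset a \code{synthetic_dataset}.
#' @return integer -1/+1 vector.
#' @export
noiseless_labels <- function(dataset) {
  gt <- dataset$ground_truth
  unname(ifelse(gt$latent_site1 > gt$threshold_site1 |
                gt$latent_site2 > gt$threshold_site2, 1L, -1L))
}

#' Generate decoy putative substrates for a screening library
#'
#' Decoys emulate putative substrates: descriptor rows drawn from the
#' substrate-generating region (at least one site rule fires). They carry
#' label +1 with provenance \code{"putative"} and are never counted as hits
#' in screening. Rows are produced by rejection sampling from the generating
#' distribution conditioned on the OR rule firing.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param n_decoys number of decoys (the reference campaign used 479); zero
#'   yields an empty decoy set, so the screening library equals the test set.
#' @param seed integer seed.
#' @return list with \code{compounds} (decoy compound table) and
#'   \code{values} (decoy descriptor rows, same columns as the dataset).
#' @export
generate_decoys <- function(dataset, n_decoys, seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (n_decoys < 0) stop("n_decoys must be nonnegative")
  if (n_decoys == 0) {
    empty <- dataset$descriptors$values[0, , drop = FALSE]
    return(list(compounds = data.frame(id = character(0),
                                       smiles = character(0),
                                       label = integer(0), set = character(0),
                                       cluster = integer(0),
                                       provenance = character(0),
                                       stringsAsFactors = FALSE),
                values = empty))
  }
  cfg <- dataset$ground_truth$config
  set.seed(seed)
  pb <- cfg$descriptors_per_block
  rho <- cfg$within_block_cor
  es <- cfg$effect_size
  gt <- dataset$ground_truth
  sd_rule <- function(w) sqrt(sum(outer(w, w) *
    ((1 - rho) * diag(length(w)) + rho)))
  kept <- NULL
  while (is.null(kept) || nrow(kept) < n_decoys) {
    nb <- max(4 * n_decoys, 64)
    cand <- do.call(cbind, lapply(seq_len(cfg$n_blocks), function(b)
      .equicorr_gauss(nb, pb, rho)))
    colnames(cand) <- colnames(dataset$descriptors$values)
    s1 <- es * drop(cand[, gt$informative_site1, drop = FALSE] %*%
                      gt$weights_site1) / sd_rule(gt$weights_site1) +
      stats::rnorm(nb)
    s2 <- es * drop(cand[, gt$informative_site2, drop = FALSE] %*%
                      gt$weights_site2) / sd_rule(gt$weights_site2) +
      stats::rnorm(nb)
    ok <- s1 > gt$threshold_site1 | s2 > gt$threshold_site2
    kept <- rbind(kept, cand[ok, , drop = FALSE])
  }
  kept <- kept[seq_len(n_decoys), , drop = FALSE]
  ids <- sprintf("DEC%04d", seq_len(n_decoys))
  rownames(kept) <- ids
  list(compounds = data.frame(id = ids, smiles = NA_character_, label = 1L,
                              set = "decoy", cluster = NA_integer_,
                              provenance = "putative",
                              stringsAsFactors = FALSE),
       values = kept)
}
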