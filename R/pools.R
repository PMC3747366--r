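#' Random block-combination descriptor pools
#'
#' Implements the random-subspace strategy: each pool is a random combination
#' of whole descriptor blocks whose summed size falls within a band around the
#' target (default 0.8-1.2 x 200 descriptors). For up to 20 blocks all
#' feasible block subsets are enumerated exactly; pools are then drawn
#' uniformly from the feasible subsets without replacement while possible,
#' with replacement only once all distinct feasible combinations are in use.
#'
#' @param blocks named list mapping block name to descriptor names (e.g. the
#'   \code{blocks} field of a [descriptor_matrix]).
#' @param n_pools number of pools to draw (the reference workflow uses 102).
#' @param target_size target pool size in descriptors (default 200).
#' @param seed integer seed.
#' @param band multiplicative acceptance band around \code{target_size}
#'   (default \code{c(0.8, 1.2)}).
#' @return list of \code{descriptor_pool} objects: \code{pool_id},
#'   \code{block_names}, \code{descriptors}, \code{size}.
#' @export
generate_pools <- function(blocks, n_pools, target_size = 200, seed = 1,
                           band = c(0.8, 1.2)) {
  stopifnot(is.list(blocks), length(blocks) >= 2, n_pools >= 1)
  sizes <- lengths(blocks)
  nb <- length(blocks)
  lo <- band[1] * target_size; hi <- band[2] * target_size
  if (nb > 20)
    stop("more than 20 blocks: exhaustive subset enumeration not supported")
  # enumerate all non-empty block subsets and their summed sizes
  subsets <- vector("list", 2^nb - 1)
  sums <- numeric(2^nb - 1)
  for (m in seq_len(2^nb - 1)) {
    idx <- which(bitwAnd(m, bitwShiftL(1, seq_len(nb) - 1)) != 0)
    subsets[[m]] <- idx
    sums[m] <- sum(sizes[idx])
  }
  feasible <- which(sums >= lo & sums <= hi)
  if (!length(feasible))
    stop(sprintf(paste0("no block combination reaches the pool-size band ",
                        "[%g, %g]; achievable sizes span [%g, %g]"),
                 lo, hi, min(sums), max(sums)))
  set.seed(seed)
  if (length(feasible) >= n_pools) {
    picks <- sample(feasible, n_pools)
  } else {
    picks <- c(sample(feasible), sample(feasible, n_pools - length(feasible),
                                        replace = TRUE))
  }
  lapply(seq_along(picks), function(i) {
    idx <- subsets[[picks[i]]]
    structure(list(pool_id = sprintf("pool%03d", i),
                   block_names = names(blocks)[idx],
                   descriptors = unlist(blocks[idx], use.names = FALSE),
                   size = sum(sizes[idx])),
              class = "descriptor_pool")
  })
}

#' @export
print.descriptor_pool <- function(x, ...) {
  cat(sprintf("%s: %d descriptors from blocks %s\n", x$pool_id, x$size,
              paste(x$block_names, collapse = " + ")))
  invisible(x)
}
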