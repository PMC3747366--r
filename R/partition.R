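#' Partition configuration
#'
#' Controls the rational train/test split: hierarchical structural clustering
#' within each class, k-means refinement on nine normalized property
#' descriptors, then class-stratified cluster-wise assignment of around 50%
#' of each substrate cluster and 25% of each nonsubstrate cluster to the
#' external test set.
#'
#' @param property_descriptors descriptor names used for the k-means
#'   refinement (default [property_descriptor_names()]).
#' @param similarity_cutoff Tanimoto similarity (path-based FP2 fingerprints)
#'   at which the hierarchical tree is cut; the stand-in for the
#'   minimum-common-substructure floor of the reference workflow (a 9-atom
#'   MCS floor maps onto roughly this cutoff for drug-like molecules).
#' @param min_common_substructure_atoms recorded for reference (default 9);
#'   the operative knob is \code{similarity_cutoff}.
#' @param test_fraction_substrates,test_fraction_nonsubstrates per-cluster
#'   test fractions (defaults 0.50 and 0.25).
#' @param seed integer seed for the per-cluster test draws.
#' @return object of class \code{partition_config}.
#' @export
partition_config <- function(property_descriptors = property_descriptor_names(),
                             similarity_cutoff = 0.4,
                             min_common_substructure_atoms = 9,
                             test_fraction_substrates = 0.50,
                             test_fraction_nonsubstrates = 0.25,
                             seed = 1) {
  stopifnot(test_fraction_substrates > 0, test_fraction_substrates < 1,
            test_fraction_nonsubstrates > 0, test_fraction_nonsubstrates < 1,
            min_common_substructure_atoms >= 1,
            similarity_cutoff >= 0, similarity_cutoff <= 1)
  structure(list(property_descriptors = property_descriptors,
                 similarity_cutoff = similarity_cutoff,
                 min_common_substructure_atoms = min_common_substructure_atoms,
                 test_fraction_substrates = test_fraction_substrates,
                 test_fraction_nonsubstrates = test_fraction_nonsubstrates,
                 seed = seed),
            class = "partition_config")
}

#' Pairwise structural similarity matrix
#'
#' Tanimoto similarity of path-based (FP2) fingerprints computed with
#' OpenBabel. Deterministic; used as the open stand-in for
#' maximum-common-substructure similarity.
#'
#' @param smiles character vector of SMILES.
#' @param ids identifiers.
#' @return symmetric similarity matrix in \[0, 1\].
#' @export
structural_similarity <- function(smiles, ids = NULL) {
  mols <- parse_smiles(smiles, ids)
  sdfset <- attr(mols, "sdfset")
  fp <- ChemmineR::fingerprintOB(sdfset, "FP2")
  n <- length(sdfset)
  S <- diag(1, n)
  dimnames(S) <- list(ChemmineR::cid(sdfset), ChemmineR::cid(sdfset))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      sims <- ChemmineR::fpSim(fp[i], fp[(i + 1):n], method = "Tanimoto",
                               sorted = FALSE)
      S[i, (i + 1):n] <- sims
      S[(i + 1):n, i] <- sims
    }
  }
  S
}

#' Hierarchical structural clustering within each class
#'
#' Complete-linkage agglomerative clustering on 1 - Tanimoto structural
#' similarity, run separately within the substrates and within the
#' nonsubstrates, cut at \code{1 - similarity_cutoff}. Singleton clusters are
#' permitted. Cluster ids are unique across the two classes.
#'
#' @param compounds compound table with valid \code{smiles} and -1/+1
#'   \code{label}.
#' @param config a [partition_config].
#' @return integer cluster id per compound (named by id).
#' @export
hierarchical_structural_clusters <- function(compounds,
                                             config = partition_config()) {
  cl <- integer(nrow(compounds))
  names(cl) <- compounds$id
  offset <- 0L
  for (lab in c(1L, -1L)) {
    idx <- which(compounds$label == lab)
    if (length(idx) == 0) next
    if (length(idx) < 2) {
      warning(sprintf("class %+d has fewer than 2 compounds: one cluster", lab))
      cl[idx] <- offset + 1L
      offset <- offset + 1L
      next
    }
    S <- structural_similarity(compounds$smiles[idx], compounds$id[idx])
    hc <- stats::hclust(stats::as.dist(1 - S), method = "complete")
    memb <- stats::cutree(hc, h = 1 - config$similarity_cutoff)
    cl[idx] <- offset + memb
    offset <- offset + max(memb)
  }
  cl
}

#' Hierarchical clustering in descriptor space
#'
#' Class-wise complete-linkage clustering on Euclidean distance over z-scored
#' descriptor columns; the structure-free route used for synthetic compounds
#' that have no SMILES.
#'
#' @param X numeric matrix of descriptors (rows named by compound id).
#' @param labels -1/+1 class labels aligned with the rows.
#' @param k_per_class named vector \code{c("1" = k_sub, "-1" = k_non)} of
#'   cluster counts per class.
#' @return integer cluster id per compound (named), unique across classes.
#' @export
hierarchical_descriptor_clusters <- function(X, labels,
                                             k_per_class = c("1" = 6, "-1" = 6)) {
  cl <- integer(nrow(X))
  names(cl) <- rownames(X)
  offset <- 0L
  for (lab in c(1L, -1L)) {
    idx <- which(labels == lab)
    if (length(idx) == 0) next
    k <- min(k_per_class[as.character(lab)], length(idx))
    if (length(idx) < 2 || k < 2) {
      cl[idx] <- offset + 1L
      offset <- offset + 1L
      next
    }
    Z <- scale(X[idx, , drop = FALSE])
    Z[!is.finite(Z)] <- 0
    hc <- stats::hclust(stats::dist(Z), method = "complete")
    memb <- stats::cutree(hc, k = k)
    cl[idx] <- offset + memb
    offset <- offset + max(memb)
  }
  cl
}

#' k-means refinement of hierarchical clusters
#'
#' Refines class-wise cluster labels by k-means on the normalized property
#' descriptors: descriptors are z-scored over the compounds being clustered,
#' cluster centers are initialized from the incoming labels, and compounds
#' are reassigned to minimize total within-cluster squared Euclidean
#' distance. The refinement never increases the k-means objective of the
#' initial labeling.
#'
#' @param cluster_labels integer cluster ids (named by compound id), as from
#'   [hierarchical_structural_clusters].
#' @param X numeric matrix restricted to the property descriptors, rows
#'   aligned with \code{cluster_labels}.
#' @param labels -1/+1 class labels (refinement is done within each class).
#' @return refined integer cluster ids (named), same cluster-id space.
#' @export
kmeans_refine <- function(cluster_labels, X, labels) {
  stopifnot(nrow(X) == length(cluster_labels),
            length(labels) == length(cluster_labels))
  out <- cluster_labels
  for (lab in c(1L, -1L)) {
    idx <- which(labels == lab)
    if (length(idx) < 2) next
    memb <- cluster_labels[idx]
    ids <- sort(unique(memb))
    if (length(ids) < 2) next
    if (length(ids) > length(idx)) stop("more clusters than compounds")
    Z <- scale(X[idx, , drop = FALSE])
    Z[!is.finite(Z)] <- 0
    centers <- t(vapply(ids, function(cid)
      colMeans(Z[memb == cid, , drop = FALSE]), numeric(ncol(Z))))
    km <- tryCatch(
      stats::kmeans(Z, centers = centers, iter.max = 100,
                    algorithm = "Hartigan-Wong"),
      error = function(e)
        stats::kmeans(Z, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"))
    out[idx] <- ids[km$cluster]
  }
  out
}

# k-means objective of a labeling (z-scored within the given rows)
.kmeans_objective <- function(cluster_labels, X) {
  Z <- scale(X)
  Z[!is.finite(Z)] <- 0
  sum(vapply(unique(cluster_labels), function(cid) {
    rows <- Z[cluster_labels == cid, , drop = FALSE]
    sum(sweep(rows, 2, colMeans(rows))^2)
  }, 0))
}

#' Cluster-wise stratified train/test assignment
#'
#' Within each cluster of each class, \code{round(fraction * size)} compounds
#' (round-half-to-even) are drawn at random into the external test set; the
#' remainder stays in training. Singleton clusters always go to training so
#' rare scaffolds remain available for model building.
#'
#' @param cluster_labels integer cluster ids (named by compound id).
#' @param compounds compound table aligned with \code{cluster_labels}.
#' @param config a [partition_config].
#' @return object of class \code{split_plan}: the compound table with
#'   \code{set} and \code{cluster} filled in, plus a per-cluster summary
#'   table.
#' @export
assign_split <- function(cluster_labels, compounds,
                         config = partition_config()) {
  stopifnot(nrow(compounds) == length(cluster_labels))
  set.seed(config$seed)
  compounds$cluster <- as.integer(cluster_labels)
  compounds$set <- "train"
  for (cid in sort(unique(cluster_labels))) {
    idx <- which(cluster_labels == cid)
    lab <- compounds$label[idx][1]
    frac <- if (lab == 1) config$test_fraction_substrates
            else config$test_fraction_nonsubstrates
    if (length(idx) < 2) next
    n_test <- round(frac * length(idx))
    if (n_test >= 1)
      compounds$set[sample(idx, n_test)] <- "test"
  }
  summary <- do.call(rbind, lapply(sort(unique(cluster_labels)), function(cid) {
    idx <- which(cluster_labels == cid)
    data.frame(cluster = cid, class = compounds$label[idx][1],
               n = length(idx), n_test = sum(compounds$set[idx] == "test"),
               n_train = sum(compounds$set[idx] == "train"))
  }))
  structure(list(compounds = compounds, summary = summary, config = config),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  tr <- table(x$compounds$label[x$compounds$set == "train"])
  te <- table(x$compounds$label[x$compounds$set == "test"])
  cat(sprintf("Split plan: %d clusters\n", nrow(x$summary)))
  cat(sprintf("  train: %s substrates / %s nonsubstrates\n",
              tr["1"], tr["-1"]))
  cat(sprintf("  test:  %s substrates / %s nonsubstrates\n",
              te["1"], te["-1"]))
  invisible(x)
}

#' Serialize a split plan to CSV (id, class, cluster, set) plus JSON summary
#'
#' @param plan a \code{split_plan}.
#' @param csv_path output CSV.
#' @param json_path optional JSON summary path.
#' @export
write_split_plan <- function(plan, csv_path, json_path = NULL) {
  utils::write.csv(plan$compounds[, c("id", "label", "cluster", "set")],
                   csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(plan$summary, json_path, digits = NA)
  invisible(csv_path)
}
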