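#' Block-organized descriptor matrix
#'
#' A dense numeric matrix (rows = compounds, columns = named descriptors)
#' together with a block manifest partitioning the descriptor names into
#' named families (constitutional, topological, ...). The random-subspace
#' machinery operates on whole blocks, so the block partition is a first-class
#' part of the container.
#'
#' @param values numeric matrix with row names (compound ids) and column
#'   names (descriptor names).
#' @param blocks named list of character vectors partitioning
#'   \code{colnames(values)}.
#' @return object of class \code{descriptor_matrix} with fields
#'   \code{values} and \code{blocks}.
#' @export
descriptor_matrix <- function(values, blocks) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            is.list(blocks), !is.null(names(blocks)))
  all_names <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_names))
    stop("block manifest assigns a descriptor to more than one block")
  if (!setequal(all_names, colnames(values)) ||
      length(all_names) != ncol(values))
    stop("block manifest does not partition the descriptor names")
  structure(list(values = values, blocks = blocks),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("Descriptor matrix: %d compounds x %d descriptors in %d blocks\n",
              nrow(x$values), ncol(x$values), length(x$blocks)))
  for (b in names(x$blocks))
    cat(sprintf("  %-16s %4d descriptors\n", b, length(x$blocks[[b]])))
  invisible(x)
}

#' Write a descriptor matrix as CSV plus a JSON block manifest
#'
#' Values are serialized with 17 significant digits so that doubles
#' round-trip bit-identically; the manifest records the block partition so
#' that [read_descriptor_matrix] reproduces the object exactly.
#'
#' @param dm a [descriptor_matrix].
#' @param csv_path output CSV (first column \code{id}).
#' @param manifest_path output JSON manifest.
#' @export
write_descriptor_matrix <- function(dm, csv_path, manifest_path) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  chr <- matrix(formatC(dm$values, digits = 17, format = "g"),
                nrow(dm$values), ncol(dm$values),
                dimnames = dimnames(dm$values))
  df <- data.frame(id = rownames(dm$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(dm$blocks, manifest_path, digits = NA)
  invisible(csv_path)
}

#' Read a descriptor matrix written by [write_descriptor_matrix]
#'
#' @param csv_path CSV of values (first column \code{id}).
#' @param manifest_path JSON block manifest.
#' @return a [descriptor_matrix].
#' @export
read_descriptor_matrix <- function(csv_path, manifest_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$id
  blocks <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  blocks <- lapply(blocks, as.character)
  descriptor_matrix(values, blocks)
}

#' Remove constant and near-constant descriptors
#'
#' Descriptors carrying no information for model building are removed using
#' the TRAINING rows only (test rows never influence the decision): a
#' descriptor is dropped when its training variance is below \code{var_min}
#' relative to its squared scale (so a column of identical values is dropped
#' regardless of magnitude), or when a single value covers more than
#' \code{modal_max} of the training rows. The block manifest is updated;
#' blocks left empty are removed.
#'
#' @param dm a [descriptor_matrix].
#' @param training_ids compound ids defining the training rows.
#' @param var_min relative variance threshold (default 1e-8).
#' @param modal_max maximal modal-value share (default 0.95).
#' @return the filtered [descriptor_matrix].
#' @export
filter_low_information <- function(dm, training_ids, var_min = 1e-8,
                                   modal_max = 0.95) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  if (!all(training_ids %in% rownames(dm$values)))
    stop("training_ids contains ids not present in the matrix")
  tr <- dm$values[training_ids, , drop = FALSE]
  keep <- vapply(seq_len(ncol(tr)), function(j) {
    x <- tr[, j]
    scale2 <- max(mean(x)^2, 1)
    if (stats::var(x) < var_min * scale2) return(FALSE)
    max(table(x)) / length(x) <= modal_max
  }, logical(1))
  if (!any(keep)) stop("no informative descriptors remain after filtering")
  kept_names <- colnames(dm$values)[keep]
  blocks <- lapply(dm$blocks, intersect, kept_names)
  blocks <- blocks[lengths(blocks) > 0]
  descriptor_matrix(dm$values[, kept_names, drop = FALSE], blocks)
}

#' Impute non-finite descriptor values with training medians
#'
#' Descriptor calculators can return non-finite values for degenerate
#' structures. To keep the matrix dense (LDA requires complete rows), each
#' non-finite entry is replaced by the median of the finite values of that
#' descriptor over the training rows (over all rows when
#' \code{training_ids} is NULL). The number of imputed entries is attached as
#' attribute \code{n_imputed}.
#'
#' @param dm a [descriptor_matrix].
#' @param training_ids ids whose rows define the imputation medians.
#' @return the imputed [descriptor_matrix].
#' @export
impute_nonfinite <- function(dm, training_ids = NULL) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  v <- dm$values
  ref <- if (is.null(training_ids)) v else v[training_ids, , drop = FALSE]
  n_imp <- 0L
  for (j in seq_len(ncol(v))) {
    bad <- !is.finite(v[, j])
    if (any(bad)) {
      med <- stats::median(ref[is.finite(ref[, j]), j])
      if (!is.finite(med)) med <- 0
      v[bad, j] <- med
      n_imp <- n_imp + sum(bad)
    }
  }
  out <- descriptor_matrix(v, dm$blocks)
  attr(out, "n_imputed") <- n_imp
  out
}
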