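#' Read a compound table from CSV
#'
#' The CSV must have columns \code{id} and \code{label}; \code{smiles},
#' \code{set}, \code{cluster} and \code{provenance} are optional. Labels are
#' +1 (substrate), -1 (nonsubstrate) or the string \code{"putative"} for
#' decoy putative substrates, which are stored as label +1 with provenance
#' \code{"putative"}.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{id}, \code{smiles}, \code{label},
#'   \code{set}, \code{cluster}, \code{provenance}.
#' @export
read_compounds <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("id", "label") %in% names(raw)))
    stop("compound CSV must have columns 'id' and 'label'")
  if (nrow(raw) == 0) {
    warning("empty compound table: ", path)
    return(data.frame(id = character(0), smiles = character(0),
                      label = integer(0), set = character(0),
                      cluster = integer(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  }
  dup <- raw$id[duplicated(raw$id)]
  if (length(dup))
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  lab_raw <- trimws(raw$label)
  provenance <- ifelse(lab_raw == "putative", "putative", "known")
  label <- integer(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    label[i] <- switch(lab_raw[i],
                       "1" = 1L, "+1" = 1L, "-1" = -1L, "putative" = 1L,
                       stop(sprintf("unparsable label '%s' in row %d",
                                    lab_raw[i], i)))
  }
  if ("provenance" %in% names(raw)) provenance <- raw$provenance
  set <- if ("set" %in% names(raw)) raw$set else rep("unassigned", nrow(raw))
  bad_set <- setdiff(unique(set), c("train", "test", "decoy", "unassigned"))
  if (length(bad_set))
    stop("invalid set value(s): ", paste(bad_set, collapse = ", "))
  data.frame(id = raw$id,
             smiles = if ("smiles" %in% names(raw)) raw$smiles else NA_character_,
             label = label, set = set,
             cluster = if ("cluster" %in% names(raw))
               suppressWarnings(as.integer(raw$cluster)) else NA_integer_,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Write a compound table to CSV
#'
#' @param compounds data.frame as produced by [read_compounds].
#' @param path output CSV path.
#' @export
write_compounds <- function(compounds, path) {
  out <- compounds
  out$label <- ifelse(out$provenance == "putative", "putative",
                      as.character(out$label))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
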