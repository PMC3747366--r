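#' Fuse two models' scores
#'
#' Two-model data fusion on the raw discriminant-function scale: the MAX
#' operator takes the elementwise maximum of the two score vectors, AVE their
#' elementwise mean. Scores are fused without per-model standardization (the
#' df scales of models fitted on the same training set are loosely
#' comparable); set \code{standardize = TRUE} to z-score each vector first.
#'
#' @param scores_a,scores_b aligned numeric score vectors.
#' @param operator \code{"AVE"} or \code{"MAX"}.
#' @param standardize z-score each vector before fusing (default FALSE).
#' @return fused numeric vector.
#' @export
fuse_scores <- function(scores_a, scores_b, operator = c("AVE", "MAX"),
                        standardize = FALSE) {
  operator <- match.arg(operator)
  if (length(scores_a) != length(scores_b))
    stop("score vectors have different lengths")
  if (standardize) {
    scores_a <- as.vector(scale(scores_a))
    scores_b <- as.vector(scale(scores_b))
  }
  if (operator == "MAX") pmax(scores_a, scores_b)
  else (scores_a + scores_b) / 2
}

#' Exhaustive two-model ensemble enumeration and ranking
#'
#' Evaluates every unordered pair of models under each fusion operator on the
#' external validation set and ranks the ensembles by the selection hierarchy:
#' ascending false-positive count at the df = 0 cutoff (FP = called
#' nonsubstrate, actually a substrate -- the error the screening application
#' most wants to avoid), ties broken by descending partial AUC over the
#' high-specificity band, then by descending total AUC, then by model ids.
#'
#' @param scores numeric matrix of df scores, one column per model (column
#'   names are the model ids), rows = external-set compounds.
#' @param labels -1/+1 true labels for the rows.
#' @param operators fusion operators to consider (default AVE and MAX).
#' @param sp_lo lower end of the specificity band for the pAUC tie-break
#'   (default 0.70).
#' @param threshold df cutoff for class calls (default 0).
#' @return data.frame leaderboard, one row per (pair, operator), ordered by
#'   the selection hierarchy, with columns \code{model_a}, \code{model_b},
#'   \code{operator}, \code{fp}, \code{pauc}, \code{auc}.
#' @export
enumerate_ensembles <- function(scores, labels, operators = c("AVE", "MAX"),
                                sp_lo = 0.70, threshold = 0) {
  stopifnot(is.matrix(scores), ncol(scores) >= 2,
            nrow(scores) == length(labels), all(labels %in% c(-1, 1)))
  ids <- colnames(scores)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_len(ncol(scores)))
  hits <- labels == -1            # nonsubstrates are the positives/hits
  pairs <- utils::combn(ncol(scores), 2)
  rows <- vector("list", ncol(pairs) * length(operators))
  k <- 0L
  for (j in seq_len(ncol(pairs))) {
    ia <- pairs[1, j]; ib <- pairs[2, j]
    for (op in operators) {
      fused <- fuse_scores(scores[, ia], scores[, ib], op)
      fp <- sum(fused <= threshold & labels == 1)
      s_int <- -fused               # ascending df = more hit-like
      pauc <- .pauc_value(s_int, hits, sp_lo)
      auc <- .delong_components(s_int, hits)$auc
      k <- k + 1L
      rows[[k]] <- data.frame(model_a = ids[ia], model_b = ids[ib],
                              operator = op, fp = fp, pauc = pauc, auc = auc,
                              stringsAsFactors = FALSE)
    }
  }
  lb <- do.call(rbind, rows)
  lb <- lb[order(lb$fp, -lb$pauc, -lb$auc, lb$model_a, lb$model_b,
                 lb$operator), ]
  rownames(lb) <- NULL
  lb
}

#' Construct a two-model ensemble
#'
#' @param model_a,model_b fitted \code{discriminant_model}s (distinct).
#' @param operator \code{"AVE"} or \code{"MAX"}.
#' @return object of class \code{ensemble}; use [predict.ensemble] to score.
#' @export
ensemble <- function(model_a, model_b, operator = c("AVE", "MAX")) {
  operator <- match.arg(operator)
  stopifnot(inherits(model_a, "discriminant_model"),
            inherits(model_b, "discriminant_model"))
  if (identical(model_a, model_b))
    stop("an ensemble requires two distinct models")
  structure(list(model_a = model_a, model_b = model_b, operator = operator),
            class = "ensemble")
}

#' @rdname ensemble
#' @param object an \code{ensemble}.
#' @param newdata descriptor matrix containing both models' descriptors.
#' @param type \code{"score"} or \code{"class"}.
#' @param threshold df cutoff for class calls (default 0).
#' @param ... unused.
#' @export
predict.ensemble <- function(object, newdata, type = c("score", "class"),
                             threshold = 0, ...) {
  type <- match.arg(type)
  fused <- fuse_scores(predict(object$model_a, newdata, type = "score"),
                       predict(object$model_b, newdata, type = "score"),
                       object$operator)
  if (type == "score") return(fused)
  ifelse(fused > threshold, 1L, -1L)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("%s ensemble of two discriminant functions (%d + %d descriptors)\n",
              x$operator, length(x$model_a$descriptors),
              length(x$model_b$descriptors)))
  invisible(x)
}
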