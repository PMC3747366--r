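#' Confusion-matrix summary with explicit positive class
#'
#' Sensitivity and specificity depend on which class is declared positive.
#' In this screening application the positives are the BCRP nonsubstrates
#' (the compounds being searched for), so with the default orientation
#' Se = true nonsubstrates / (true nonsubstrates + false substrates) and
#' Sp = true substrates / (true substrates + false nonsubstrates). Accuracy
#' is orientation-invariant.
#'
#' @param calls integer -1/+1 predicted classes (+1 substrate).
#' @param labels integer -1/+1 true classes.
#' @param positive_class \code{"nonsubstrate"} (default, label -1 positive)
#'   or \code{"substrate"}.
#' @return object of class \code{confusion_summary}: counts TP/FP/TN/FN and
#'   rates Se, Sp, accuracy, with the positive class recorded.
#' @export
confusion <- function(calls, labels,
                      positive_class = c("nonsubstrate", "substrate")) {
  positive_class <- match.arg(positive_class)
  if (length(calls) == 0) stop("empty input")
  stopifnot(length(calls) == length(labels),
            all(calls %in% c(-1, 1)), all(labels %in% c(-1, 1)))
  posval <- if (positive_class == "nonsubstrate") -1 else 1
  cs <- .confusion_counts(calls == posval, labels == posval)
  cs$positive_class <- positive_class
  cs$n <- length(calls)
  structure(cs, class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Confusion (positive class: %s): TP %d  FP %d  TN %d  FN %d\n",
              x$positive_class, x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  Se = %.3f  Sp = %.3f  accuracy = %.3f\n", x$Se, x$Sp, x$accuracy))
  invisible(x)
}

#' Label-randomization (y-scrambling) test
#'
#' Rebuilds the whole model (stepwise descriptor selection plus LDA) on
#' class labels scrambled among the training compounds, \code{n_random}
#' times, recording each randomized model's training accuracy. Because the
#' structure-activity link is destroyed by the scramble, the randomized
#' accuracies estimate the chance level against which the real model's
#' training accuracy is judged. Selection is redone for every scramble (the
#' stronger null).
#'
#' @param X training descriptor matrix (rows = compounds).
#' @param labels integer -1/+1 class labels.
#' @param config a [selection_config].
#' @param n_random number of scrambles (default 50).
#' @param seed integer seed.
#' @return list with \code{accuracies} (length \code{n_random}), \code{mean},
#'   \code{sd}, and \code{n_empty} (scrambles in which selection found
#'   nothing; those score at the majority-class rate).
#' @export
randomization_test <- function(X, labels, config = selection_config(),
                               n_random = 50, seed = 1) {
  stopifnot(n_random >= 0)
  if (n_random == 0)
    return(list(accuracies = numeric(0), mean = NA_real_, sd = NA_real_,
                n_empty = 0L, run = FALSE))
  set.seed(seed)
  maj <- max(mean(labels == 1), mean(labels == -1))
  n_empty <- 0L
  acc <- vapply(seq_len(n_random), function(i) {
    yl <- sample(labels)
    sel <- stepwise_select(X, yl, config)
    if (length(sel$selected) == 0) {
      n_empty <<- n_empty + 1L
      return(maj)
    }
    m <- fit_lda(X[, sel$selected, drop = FALSE], yl,
                 entry_tolerances = sel$tolerances, config = config)
    m$training$accuracy
  }, 0)
  list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
       n_empty = n_empty, run = TRUE)
}

# stratified group of `size` compounds preserving the class ratio within +/- 1,
# drawing from not-yet-seen compounds first so coverage accrues fastest
.lgo_draw <- function(pos_idx, neg_idx, unseen, size) {
  n <- length(pos_idx) + length(neg_idx)
  k_pos <- round(size * length(pos_idx) / n)
  k_pos <- min(max(k_pos, size - length(neg_idx)), length(pos_idx), size)
  k_neg <- size - k_pos
  draw_from <- function(idx, k) {
    un <- intersect(idx, unseen)
    if (length(un) >= k) return(sample(un, k))
    c(un, sample(setdiff(idx, un), k - length(un)))
  }
  c(draw_from(pos_idx, k_pos), draw_from(neg_idx, k_neg))
}

#' Stratified leave-group-out cross-validation
#'
#' In each round a stratified group of \code{group_size} compounds (class
#' ratio preserved within one compound) is removed from the training set, the
#' model is rebuilt from scratch (stepwise selection + LDA) on the remainder,
#' and the removed compounds are predicted. The sampler prefers compounds not
#' yet left out, so that over the configured number of rounds every training
#' compound is removed at least once; the coverage flag records whether that
#' held.
#'
#' @inheritParams randomization_test
#' @param group_size compounds removed per round (default 10).
#' @param rounds number of rounds (default 50).
#' @return list with \code{accuracies} per round, \code{mean}, \code{sd},
#'   \code{coverage} (logical), \code{seen} (times each compound was left out).
#' @export
lgo_cv <- function(X, labels, config = selection_config(), group_size = 10,
                   rounds = 50, seed = 1) {
  n <- nrow(X)
  stopifnot(group_size < n, rounds >= 1)
  set.seed(seed)
  pos_idx <- which(labels == 1); neg_idx <- which(labels == -1)
  seen <- integer(n)
  acc <- numeric(rounds)
  for (r in seq_len(rounds)) {
    out <- .lgo_draw(pos_idx, neg_idx, which(seen == 0), group_size)
    seen[out] <- seen[out] + 1L
    Xtr <- X[-out, , drop = FALSE]; ytr <- labels[-out]
    sel <- stepwise_select(Xtr, ytr, config)
    if (length(sel$selected) == 0) {
      calls <- rep(if (mean(ytr == 1) >= 0.5) 1 else -1, length(out))
    } else {
      m <- fit_lda(Xtr[, sel$selected, drop = FALSE], ytr,
                   entry_tolerances = sel$tolerances, config = config)
      calls <- predict(m, X[out, sel$selected, drop = FALSE], type = "class")
    }
    acc[r] <- mean(calls == labels[out])
  }
  coverage <- all(seen > 0)
  if (!coverage)
    warning("LGO coverage not achieved: some training compounds were never left out")
  list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
       coverage = coverage, seen = seen)
}

#' Full validation report for one model configuration
#'
#' Bundles the three protocols used to assess model robustness: the
#' label-randomization test, stratified leave-group-out cross-validation, and
#' external validation on the held-out test set.
#'
#' @param X_train,y_train training descriptor matrix (restricted to the
#'   model's candidate pool) and -1/+1 labels.
#' @param X_test,y_test external test matrix (same columns) and labels.
#' @param config a [selection_config].
#' @param n_random,lgo_rounds,lgo_group_size protocol sizes (defaults 50, 50, 10).
#' @param seed integer seed.
#' @return object of class \code{validation_report}: \code{model},
#'   \code{randomization}, \code{lgo}, \code{external} (a
#'   \code{confusion_summary}).
#' @export
validation_report <- function(X_train, y_train, X_test, y_test,
                              config = selection_config(), n_random = 50,
                              lgo_rounds = 50, lgo_group_size = 10, seed = 1) {
  sel <- stepwise_select(X_train, y_train, config)
  if (length(sel$selected) == 0) stop("stepwise selection found no descriptors")
  model <- fit_lda(X_train[, sel$selected, drop = FALSE], y_train,
                   entry_tolerances = sel$tolerances, config = config)
  ext_calls <- predict(model, X_test[, sel$selected, drop = FALSE], type = "class")
  structure(list(
    model = model,
    randomization = randomization_test(X_train, y_train, config,
                                       n_random = n_random, seed = seed + 1L),
    lgo = lgo_cv(X_train, y_train, config, group_size = lgo_group_size,
                 rounds = lgo_rounds, seed = seed + 2L),
    external = confusion(ext_calls, y_test)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  m <- x$model
  cat("Discriminant model:", paste(m$descriptors, collapse = ", "), "\n")
  cat(sprintf("  F = %.2f, p = %.3g\n", m$F, m$p_value))
  cat(sprintf("  Training: Sp %.1f%%  Se %.1f%%  accuracy %.1f%%\n",
              100 * m$training$Sp, 100 * m$training$Se, 100 * m$training$accuracy))
  cat(sprintf("  Test:     Sp %.1f%%  Se %.1f%%  accuracy %.1f%%\n",
              100 * x$external$Sp, 100 * x$external$Se, 100 * x$external$accuracy))
  if (isTRUE(x$lgo$coverage)) cov <- "all compounds left out at least once"
  else cov <- "coverage NOT achieved"
  cat(sprintf("  LGO CV:   %.1f%% (+/- %.1f)  [%s]\n",
              100 * x$lgo$mean, 100 * x$lgo$sd, cov))
  if (isTRUE(x$randomization$run))
    cat(sprintf("  Randomization: %.1f%% (+/- %.1f) over %d scrambles\n",
                100 * x$randomization$mean, 100 * x$randomization$sd,
                length(x$randomization$accuracies)))
  else cat("  Randomization: not run\n")
  invisible(x)
}
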