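#' Stepwise-selection configuration
#'
#' Controls the forward stepwise multiple-linear-regression selection of
#' descriptors on the -1/+1 class dummy.
#'
#' @param tolerance_min minimum tolerance (1 - R^2 of a candidate regressed on
#'   the already-selected descriptors) for entry; guards against collinear
#'   pairs (default 0.1).
#' @param max_steps maximum number of descriptors entered (default 15).
#' @param alpha_enter significance level a candidate's coefficient must reach
#'   to enter (default 0.05).
#' @param min_cases_per_predictor minimum ratio of training compounds to
#'   descriptors in the model; entry stops before violating it (default 11,
#'   an overfitting guard).
#' @return object of class \code{selection_config}.
#' @export
selection_config <- function(tolerance_min = 0.1, max_steps = 15,
                             alpha_enter = 0.05, min_cases_per_predictor = 11) {
  stopifnot(tolerance_min > 0, tolerance_min <= 1,
            alpha_enter > 0, alpha_enter < 1,
            max_steps >= 1, min_cases_per_predictor >= 1)
  structure(list(tolerance_min = tolerance_min, max_steps = max_steps,
                 alpha_enter = alpha_enter,
                 min_cases_per_predictor = min_cases_per_predictor),
            class = "selection_config")
}

#' Forward stepwise descriptor selection on the class dummy
#'
#' At each step every remaining candidate descriptor is evaluated by its
#' F-to-enter in the multiple linear regression of the -1/+1 class dummy on
#' the already-selected descriptors plus the candidate. Candidates qualify
#' only if the entry p-value is below \code{alpha_enter} and the tolerance
#' (1 - R^2 of the candidate on the selected set) is at least
#' \code{tolerance_min}; among qualifiers the largest F enters, ties broken by
#' lexicographic descriptor name. Selection stops when no candidate
#' qualifies, when \code{max_steps} is reached, or when adding a descriptor
#' would push the cases-per-predictor ratio below the configured minimum.
#' Zero-variance descriptors are skipped (and reported).
#'
#' @param X numeric training matrix, columns named by descriptor.
#' @param labels -1/+1 class labels (the regression response).
#' @param config a [selection_config].
#' @return list with \code{selected} (descriptor names in entry order),
#'   \code{tolerances} (tolerance of each at entry), \code{f_to_enter},
#'   \code{p_enter}, \code{skipped_zero_variance}.
#' @export
stepwise_select <- function(X, labels, config = selection_config()) {
  stopifnot(is.matrix(X), !is.null(colnames(X)),
            all(labels %in% c(-1, 1)), nrow(X) == length(labels))
  y <- as.numeric(labels)
  n <- nrow(X)
  tss_all <- colSums(sweep(X, 2, colMeans(X))^2)
  zero_var <- tss_all <= 1e-12 * pmax(colMeans(abs(X))^2, 1) * n
  cand <- colnames(X)[!zero_var]
  sel <- character(0)
  tol_at_entry <- f_at_entry <- p_at_entry <- numeric(0)
  while (length(cand) > 0) {
    p <- length(sel)
    if (p >= config$max_steps) break
    if ((p + 1) * config$min_cases_per_predictor > n) break
    df2 <- n - p - 2          # residual df after adding the candidate
    if (df2 <= 0) break
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    ry <- y - Q %*% crossprod(Q, y)
    rss0 <- sum(ry^2)
    C <- X[, cand, drop = FALSE]
    RC <- C - Q %*% crossprod(Q, C)
    rnorm2 <- colSums(RC^2)
    tol <- rnorm2 / tss_all[cand]
    proj <- as.vector(crossprod(RC, ry))
    usable <- rnorm2 > 1e-10 * pmax(tss_all[cand], 1)
    rss1 <- rss0 - ifelse(usable, proj^2 / rnorm2, 0)
    fval <- ifelse(usable & rss1 > 0, (rss0 - rss1) / (rss1 / df2), Inf)
    fval[!usable] <- 0
    pval <- stats::pf(fval, 1, df2, lower.tail = FALSE)
    elig <- usable & pval < config$alpha_enter & tol >= config$tolerance_min
    if (!any(elig)) break
    e <- which(elig)
    best <- e[order(-fval[e], cand[e])][1]
    sel <- c(sel, cand[best])
    tol_at_entry <- c(tol_at_entry, tol[best])
    f_at_entry <- c(f_at_entry, fval[best])
    p_at_entry <- c(p_at_entry, pval[best])
    cand <- cand[-best]
  }
  names(tol_at_entry) <- names(f_at_entry) <- names(p_at_entry) <- sel
  list(selected = sel, tolerances = tol_at_entry, f_to_enter = f_at_entry,
       p_enter = p_at_entry,
       skipped_zero_variance = colnames(X)[zero_var])
}
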