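#' Construct a scored ranking for ROC and enrichment analysis
#'
#' A \code{scored_ranking} bundles compound identifiers, a numeric score and a
#' binary hit flag, together with the orientation convention needed to rank
#' "hit-like" compounds first. In the screening application the hits are known
#' BCRP nonsubstrates and the score is the discriminant-function (df) value, so
#' hits are ranked by ascending score (most negative df first); for training-set
#' ROC curves with substrates as the positive class, higher df is more hit-like.
#'
#' @param ids character vector of compound identifiers.
#' @param scores numeric vector of model scores (finite).
#' @param hits logical vector: \code{TRUE} for hits. Alternatively an integer
#'   \code{-1/+1} label vector may be given together with \code{hit_definition}.
#' @param hit_definition which class counts as a hit when \code{hits} is a
#'   \code{-1/+1} label vector: \code{"nonsubstrate_is_hit"} (label -1) or
#'   \code{"substrate_is_hit"} (label +1). Also stored for reporting.
#' @param direction \code{"descending"} if larger scores are more hit-like,
#'   \code{"ascending"} if smaller scores are more hit-like. The default
#'   follows the hit definition: nonsubstrate hits are scored by ascending df.
#' @return an object of class \code{scored_ranking}.
#' @export
scored_ranking <- function(ids, scores, hits,
                           hit_definition = c("nonsubstrate_is_hit",
                                              "substrate_is_hit"),
                           direction = NULL) {
  hit_definition <- match.arg(hit_definition)
  if (is.null(direction)) {
    direction <- if (hit_definition == "nonsubstrate_is_hit") "ascending" else "descending"
  }
  direction <- match.arg(direction, c("descending", "ascending"))
  if (is.numeric(hits)) {
    stopifnot(all(hits %in% c(-1, 1)))
    hits <- if (hit_definition == "nonsubstrate_is_hit") hits == -1 else hits == 1
  }
  stopifnot(is.logical(hits), length(ids) == length(scores),
            length(scores) == length(hits))
  if (!all(is.finite(scores))) stop("scores must be finite")
  structure(list(ids = as.character(ids),
                 scores = as.numeric(scores),
                 hits = hits,
                 hit_definition = hit_definition,
                 direction = direction),
            class = "scored_ranking")
}

# internal score: always "higher = more hit-like"
.rk_internal <- function(ranking) {
  if (ranking$direction == "ascending") -ranking$scores else ranking$scores
}

.rk_check_roc <- function(ranking) {
  if (!any(ranking$hits) || all(ranking$hits))
    stop("ROC computation requires at least one hit and one non-hit")
}

#' Empirical ROC curve with trapezoid AUC
#'
#' Dichotomizes the observed scores at every distinct cut point, yielding the
#' empirical (Se, 1 - Sp) step curve from (0, 0) to (1, 1). The AUC is the
#' trapezoid area, which equals the Mann-Whitney U statistic scaled by the
#' number of hit/non-hit pairs (ties counted 1/2). The attached variance is the
#' DeLong structural-components estimate.
#'
#' @param ranking a [scored_ranking].
#' @return object of class \code{roc_curve}: list with \code{points} (a
#'   data.frame with columns \code{threshold}, \code{fpr}, \code{se}; the
#'   threshold is on the internal higher-is-hit scale), \code{auc},
#'   \code{var}, \code{n_hits}, \code{n_nonhits}.
#' @export
empirical_roc <- function(ranking) {
  stopifnot(inherits(ranking, "scored_ranking"))
  .rk_check_roc(ranking)
  s <- .rk_internal(ranking)
  h <- ranking$hits
  m <- sum(h); nn <- sum(!h)
  if (length(unique(s)) == 1L)
    warning("all scores identical: ROC curve is the chance diagonal")
  cuts <- sort(unique(s), decreasing = TRUE)
  se <- vapply(cuts, function(ct) sum(s[h] >= ct) / m, 0)
  fpr <- vapply(cuts, function(ct) sum(s[!h] >= ct) / nn, 0)
  pts <- data.frame(threshold = c(Inf, cuts), fpr = c(0, fpr), se = c(0, se))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$se, -1) + utils::tail(pts$se, -1)) / 2)
  comp <- .delong_components(s, h)
  structure(list(points = pts, auc = auc, var = comp$var,
                 n_hits = m, n_nonhits = nn),
            class = "roc_curve")
}

# DeLong placement components for one score vector.
# Midrank formulation (Sun & Xu): handles ties as 1/2 automatically.
.delong_components <- function(s, h) {
  x <- s[h]; y <- s[!h]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n          # P(Y < x_i) + 1/2 P(Y = x_i)
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m  # P(x > y_j) + 1/2 ties
  auc <- mean(v10)
  var <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, v10 = v10, v01 = v01, var = var)
}

#' DeLong variances and covariance for two paired score vectors
#'
#' Both rankings must score the same compounds with the same hit labels
#' (paired design: two models evaluated on one sample). Returns the
#' structural-components (placement value) estimates used in the paired
#' z-test on AUC differences.
#'
#' @param ranking_a,ranking_b paired [scored_ranking] objects.
#' @return list with \code{var_a}, \code{var_b}, \code{covar}, \code{auc_a},
#'   \code{auc_b}.
#' @export
auc_variance_covariance <- function(ranking_a, ranking_b) {
  .check_paired(ranking_a, ranking_b)
  ca <- .delong_components(.rk_internal(ranking_a), ranking_a$hits)
  cb <- .delong_components(.rk_internal(ranking_b), ranking_b$hits)
  m <- length(ca$v10); n <- length(ca$v01)
  covar <- stats::cov(ca$v10, cb$v10) / m + stats::cov(ca$v01, cb$v01) / n
  list(var_a = ca$var, var_b = cb$var, covar = covar,
       auc_a = ca$auc, auc_b = cb$auc)
}

.check_paired <- function(a, b) {
  stopifnot(inherits(a, "scored_ranking"), inherits(b, "scored_ranking"))
  .rk_check_roc(a); .rk_check_roc(b)
  if (length(a$ids) != length(b$ids) || !all(a$ids == b$ids) ||
      !all(a$hits == b$hits))
    stop("rankings are not paired: same compounds and hit labels required")
}

#' Paired z-test for the difference of two correlated AUCs
#'
#' z = (AUC_A - AUC_B) / sqrt(Var_A + Var_B - 2 Covar_AB), with variances and
#' covariance from [auc_variance_covariance]; two-sided normal p-value.
#' Identical curves (zero denominator, zero difference) are reported with
#' z = 0, p = 1.
#'
#' @inheritParams auc_variance_covariance
#' @return object of class \code{auc_comparison}.
#' @export
compare_auc <- function(ranking_a, ranking_b) {
  vc <- auc_variance_covariance(ranking_a, ranking_b)
  dnm2 <- vc$var_a + vc$var_b - 2 * vc$covar
  dauc <- vc$auc_a - vc$auc_b
  if (dnm2 <= .Machine$double.eps^0.75) {
    if (abs(dauc) > 1e-12)
      stop("zero variance of the AUC difference with unequal AUCs: inconsistent inputs")
    z <- 0; p <- 1
  } else {
    z <- dauc / sqrt(dnm2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = vc$auc_a, auc_b = vc$auc_b, var_a = vc$var_a,
                 var_b = vc$var_b, covar = vc$covar, z = z, p_value = p),
            class = "auc_comparison")
}

# trapezoid area of the empirical ROC over Sp in [sp_lo, 1],
# i.e. FPR in [0, 1 - sp_lo], with linear interpolation at the right edge.
.pauc_value <- function(s, h, sp_lo) {
  m <- sum(h); nn <- sum(!h)
  cuts <- sort(unique(s), decreasing = TRUE)
  se <- c(0, vapply(cuts, function(ct) sum(s[h] >= ct) / m, 0))
  fpr <- c(0, vapply(cuts, function(ct) sum(s[!h] >= ct) / nn, 0))
  fmax <- 1 - sp_lo
  if (fmax <= 0) return(0)
  # clip the polyline at fpr = fmax
  keep <- fpr <= fmax
  fk <- fpr[keep]; sk <- se[keep]
  if (max(fpr) > fmax && max(fk) < fmax) {
    i <- which(fpr > fmax)[1]
    f0 <- fpr[i - 1]; f1 <- fpr[i]
    s0 <- se[i - 1]; s1 <- se[i]
    sint <- if (f1 > f0) s0 + (s1 - s0) * (fmax - f0) / (f1 - f0) else max(s0, s1)
    fk <- c(fk, fmax); sk <- c(sk, sint)
  }
  sum(diff(fk) * (utils::head(sk, -1) + utils::tail(sk, -1)) / 2)
}

#' Partial AUC over a high-specificity band with stratified bootstrap
#'
#' Computes the unnormalized trapezoid area of the empirical ROC curve over
#' Sp in \code{[sp_lo, 1]} and estimates its sampling variability by
#' nonparametric stratified bootstrap: hits and non-hits are resampled
#' separately with replacement so that every replicate preserves the original
#' case/control counts exactly. If a paired \code{comparator} ranking is given,
#' a bootstrap test of the pAUC difference is performed on paired replicates.
#'
#' @param ranking a [scored_ranking].
#' @param sp_lo lower end of the specificity band (e.g. 0.70 for the band
#'   from Sp = 1 down to Sp = 0.70).
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap resampling.
#' @param comparator optional paired [scored_ranking] to test against.
#' @param conf confidence level for the percentile interval.
#' @return object of class \code{pauc_result}: \code{pauc}, \code{sd},
#'   \code{ci}, \code{sp_range}, \code{n_boot}, and (with a comparator)
#'   \code{pauc_comparator}, \code{p_value}.
#' @export
partial_auc <- function(ranking, sp_lo, n_boot = 2000, seed = 1,
                        comparator = NULL, conf = 0.95) {
  stopifnot(inherits(ranking, "scored_ranking"), sp_lo >= 0, sp_lo < 1)
  .rk_check_roc(ranking)
  if (n_boot < 100) warning("n_boot < 100: bootstrap estimates will be unstable")
  s <- .rk_internal(ranking); h <- ranking$hits
  est <- .pauc_value(s, h, sp_lo)
  sc <- NULL
  if (!is.null(comparator)) {
    .check_paired(ranking, comparator)
    sc <- .rk_internal(comparator)
    est_c <- .pauc_value(sc, h, sp_lo)
  }
  ih <- which(h); inh <- which(!h)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, if (is.null(sc)) 1L else 2L)
  for (b in seq_len(n_boot)) {
    bi <- c(sample(ih, length(ih), replace = TRUE),
            sample(inh, length(inh), replace = TRUE))
    hb <- h[bi]
    stopifnot(sum(hb) == length(ih), sum(!hb) == length(inh))  # stratification
    reps[b, 1] <- .pauc_value(s[bi], hb, sp_lo)
    if (!is.null(sc)) reps[b, 2] <- .pauc_value(sc[bi], hb, sp_lo)
  }
  alpha <- (1 - conf) / 2
  out <- list(pauc = est, sd = stats::sd(reps[, 1]),
              ci = stats::quantile(reps[, 1], c(alpha, 1 - alpha), names = FALSE),
              sp_range = c(sp_lo, 1), n_boot = n_boot,
              hit_definition = ranking$hit_definition)
  if (!is.null(sc)) {
    d <- reps[, 1] - reps[, 2]
    sdd <- stats::sd(d)
    D <- if (sdd > 0) (est - est_c) / sdd else 0
    out$pauc_comparator <- est_c
    out$p_value <- if (sdd > 0) 2 * stats::pnorm(-abs(D)) else 1
  }
  structure(out, class = "pauc_result")
}

#' Optimize the classification threshold on a ROC curve
#'
#' Scans all observed cut points and returns the threshold that optimizes the
#' requested criterion. Ties are broken conservatively toward higher
#' specificity (the screening application privileges Sp over Se so as not to
#' pass BCRP substrates through the filter).
#'
#' @param ranking a [scored_ranking].
#' @param criterion \code{"youden"} (maximize Se + Sp - 1), \code{"se_at_sp"}
#'   (maximize Se subject to Sp >= \code{floor}), or \code{"sp_at_se"}
#'   (maximize Sp subject to Se >= \code{floor}).
#' @param floor the Sp (or Se) floor for the constrained criteria.
#' @return list with \code{threshold} (on the original score scale; compounds
#'   are called hits when the score is on the hit side of it), \code{se},
#'   \code{sp}, and a \code{confusion} summary with hits as positives.
#' @export
optimize_threshold <- function(ranking,
                               criterion = c("youden", "se_at_sp", "sp_at_se"),
                               floor = 0.9) {
  criterion <- match.arg(criterion)
  .rk_check_roc(ranking)
  s <- .rk_internal(ranking); h <- ranking$hits
  m <- sum(h); nn <- sum(!h)
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE))
  se <- vapply(cuts, function(ct) sum(s[h] >= ct) / m, 0)
  sp <- vapply(cuts, function(ct) sum(s[!h] < ct) / nn, 0)
  idx <- switch(criterion,
    youden = {
      j <- se + sp - 1
      cand <- which(j == max(j))
      cand[order(-sp[cand])][1]
    },
    se_at_sp = {
      ok <- which(sp >= floor)
      if (!length(ok)) stop(sprintf(
        "specificity floor %.3f unattainable; best attainable Sp is %.3f",
        floor, max(sp)))
      cand <- ok[se[ok] == max(se[ok])]
      cand[order(-sp[cand])][1]
    },
    sp_at_se = {
      ok <- which(se >= floor)
      if (!length(ok)) stop(sprintf(
        "sensitivity floor %.3f unattainable; best attainable Se is %.3f",
        floor, max(se)))
      cand <- ok[sp[ok] == max(sp[ok])]
      cand[order(-sp[cand])][1]
    })
  thr_int <- cuts[idx]
  calls_hit <- s >= thr_int
  cs <- .confusion_counts(calls_hit, h)
  thr <- if (ranking$direction == "ascending") -thr_int else thr_int
  list(threshold = thr, criterion = criterion, se = se[idx], sp = sp[idx],
       confusion = cs, direction = ranking$direction)
}

# shared confusion arithmetic on logical call/truth vectors (positive = TRUE)
.confusion_counts <- function(calls, truth) {
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  tn <- sum(!calls & !truth); fn <- sum(!calls & truth)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       Se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(calls))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d hits / %d non-hits\n", x$n_hits, x$n_nonhits))
  cat(sprintf("  AUC (trapezoid) = %.4f  (DeLong SE = %.4f)\n", x$auc, sqrt(x$var)))
  invisible(x)
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("Paired AUC comparison: %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

#' @export
print.pauc_result <- function(x, ...) {
  cat(sprintf("Partial AUC, Sp in [%.2f, 1]: %.4f (+/- %.4f SD, %d bootstrap replicates)\n",
              x$sp_range[1], x$pauc, x$sd, x$n_boot))
  if (!is.null(x$p_value))
    cat(sprintf("  vs comparator pAUC %.4f: bootstrap p = %.4g\n",
                x$pauc_comparator, x$p_value))
  invisible(x)
}
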