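test_that("empirical ROC reproduces hand-computable curves", {
  r <- empirical_roc(rk(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(r$auc, 0.75)  # 3 of 4 hit/non-hit pairs correctly ordered
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$se[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$se, 1), 1)

  perfect <- empirical_roc(rk(c(5, 4, 3, 1, 0.5), c(T, T, T, F, F)))
  expect_equal(perfect$auc, 1)

  expect_warning(flat <- empirical_roc(rk(rep(2, 10), rep(c(T, F), 5))),
                 "chance diagonal")
  expect_equal(flat$auc, 0.5)
})

test_that("trapezoid AUC equals the exhaustive pair-counting oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    r <- random_ranking(n, stats::runif(1, 0.1, 0.9),
                        tie_levels = sample(c(0, 3, 8), 1))
    expect_equal(empirical_roc(r)$auc, mw_auc_oracle(r), tolerance = 1e-12)
  }
})

.pauc_value_wrap <- function(r, sp_lo)
  partial_auc(r, sp_lo, n_boot = 100, seed = 1)$pauc

test_that("ROC curve is monotone and invariant to increasing score transforms", {
  set.seed(7)
  r <- random_ranking(80, 0.3)
  cur <- empirical_roc(r)
  expect_true(all(diff(cur$points$fpr) >= 0))
  expect_true(all(diff(cur$points$se) >= 0))
  r2 <- rk(exp(r$scores), r$hits)
  expect_equal(empirical_roc(r2)$auc, cur$auc)
  expect_equal(.pauc_value_wrap(r2, 0.7), .pauc_value_wrap(r, 0.7))
})

test_that("AUC, variance and covariance agree with pROC (DeLong)", {
  library(pROC)
  set.seed(11)
  h <- stats::runif(150) < 0.45
  s1 <- stats::rnorm(150) + h
  s2 <- s1 + stats::rnorm(150)
  ra <- rk(s1, h); rb <- rk(s2, h)
  pr1 <- roc(response = h, predictor = s1, direction = "<", quiet = TRUE)
  pr2 <- roc(response = h, predictor = s2, direction = "<", quiet = TRUE)
  expect_equal(empirical_roc(ra)$auc, as.numeric(auc(pr1)))
  expect_equal(empirical_roc(ra)$var, as.numeric(var(pr1, method = "delong")),
               tolerance = 1e-10)
  cmp <- compare_auc(ra, rb)
  rt <- roc.test(pr1, pr2, method = "delong", paired = TRUE)
  expect_equal(cmp$z, as.numeric(rt$statistic), tolerance = 1e-10)
  expect_equal(cmp$p_value, rt$p.value, tolerance = 1e-10)
})

test_that("paired AUC comparison handles identical and independent scores", {
  set.seed(3)
  h <- rep(c(TRUE, FALSE), 40)
  s <- stats::rnorm(80) + h
  ra <- rk(s, h)
  same <- compare_auc(ra, rk(s, h))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$covar, same$var_a, tolerance = 1e-12)

  # z recomputes from its own reported components
  rb <- rk(s + stats::rnorm(80), h)
  cmp <- compare_auc(ra, rb)
  expect_equal(cmp$z, (cmp$auc_a - cmp$auc_b) /
                 sqrt(cmp$var_a + cmp$var_b - 2 * cmp$covar))

  # independent score vectors have near-zero covariance at large n
  set.seed(4)
  h2 <- rep(c(TRUE, FALSE), 2500)
  vc <- auc_variance_covariance(rk(stats::rnorm(5000), h2),
                                rk(stats::rnorm(5000), h2))
  expect_lt(abs(vc$covar), 3e-5)

  expect_error(auc_variance_covariance(ra, rk(s[1:40], h[1:40])), "paired")
})

test_that("DeLong variance shrinks roughly as 1/n", {
  vars <- vapply(c(250, 500, 1000), function(n) {
    set.seed(n)
    mean(replicate(40, {
      h <- rep(c(TRUE, FALSE), n / 2)
      empirical_roc(rk(stats::rnorm(n) + 0.5 * h, h))$var
    }))
  }, 0)
  expect_equal(vars[1] / vars[2], 2, tolerance = 0.25)
  expect_equal(vars[2] / vars[3], 2, tolerance = 0.25)
})

test_that("partial AUC matches pROC and obeys its geometry", {
  library(pROC)
  set.seed(21)
  h <- stats::runif(120) < 0.4
  s <- stats::rnorm(120) + 1.2 * h
  r <- rk(s, h)
  pr <- roc(response = h, predictor = s, direction = "<", quiet = TRUE)
  for (lo in c(0.7, 0.75, 0.8)) {
    expect_equal(partial_auc(r, lo, n_boot = 100, seed = 1)$pauc,
                 as.numeric(auc(pr, partial.auc = c(1, lo),
                                partial.auc.correct = FALSE,
                                partial.auc.focus = "specificity")),
                 tolerance = 1e-12)
  }
  # perfect classifier: pAUC equals the band width
  perf <- rk(c(10, 9, 8, 2, 1, 0), c(T, T, T, F, F, F))
  expect_equal(partial_auc(perf, 0.7, n_boot = 100, seed = 1)$pauc, 0.3)
  expect_equal(partial_auc(perf, 1 - 1e-9, n_boot = 100, seed = 1)$pauc, 0,
               tolerance = 1e-8)
  # pAUC(0) = AUC and pAUC nonincreasing in sp_lo
  expect_equal(partial_auc(r, 0, n_boot = 100, seed = 1)$pauc,
               empirical_roc(r)$auc)
  pvals <- vapply(seq(0, 0.95, by = 0.05), function(lo)
    partial_auc(r, lo, n_boot = 100, seed = 1)$pauc, 0)
  expect_true(all(diff(pvals) <= 1e-12))
  # chance scores: expected band area under the diagonal
  set.seed(5)
  ch <- rk(stats::rnorm(4000), rep(c(TRUE, FALSE), 2000))
  expect_lt(abs(partial_auc(ch, 0.7, n_boot = 100, seed = 1)$pauc -
                  ((1 - 0.7^2) / 2 - 0.7 * 0.3)), 0.012)
})

test_that("pAUC bootstrap is stratified and supports paired comparison", {
  set.seed(31)
  h <- stats::runif(90) < 0.3
  s <- stats::rnorm(90) + h
  r <- rk(s, h)
  # the resampler asserts hit/non-hit counts replicate-by-replicate; a run
  # completing proves every replicate preserved the strata sizes
  pa <- partial_auc(r, 0.7, n_boot = 300, seed = 9)
  expect_gt(pa$sd, 0)
  expect_true(pa$ci[1] <= pa$pauc && pa$pauc <= pa$ci[2])
  expect_warning(partial_auc(r, 0.7, n_boot = 50, seed = 1), "unstable")

  cmpd <- partial_auc(r, 0.7, n_boot = 300, seed = 9,
                      comparator = rk(s + stats::rnorm(90, sd = 2), h))
  expect_true(cmpd$p_value >= 0 && cmpd$p_value <= 1)
  self <- partial_auc(r, 0.7, n_boot = 200, seed = 9, comparator = r)
  expect_equal(self$p_value, 1)
})

test_that("threshold optimization respects criteria and the Sp-first tie-break", {
  perf <- rk(c(10, 9, 8, 2, 1), c(T, T, T, F, F))
  opt <- optimize_threshold(perf, "youden")
  expect_equal(opt$se, 1)
  expect_equal(opt$sp, 1)

  r4 <- rk(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))
  o4 <- optimize_threshold(r4, "youden")
  expect_equal(o4$se + o4$sp - 1, 0.5)  # enumerated maximum of Youden J
  expect_equal(o4$sp, 1)                # tie broken toward higher Sp

  # Sp floor on chance data caps Se near 1 - floor
  set.seed(41)
  ch <- rk(stats::rnorm(3000), rep(c(TRUE, FALSE), 1500))
  o <- optimize_threshold(ch, "se_at_sp", floor = 0.9)
  expect_gte(o$sp, 0.9)
  expect_lt(o$se, 0.2)
  expect_error(optimize_threshold(ch, "sp_at_se", floor = 1.1),
               "unattainable")
})
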