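test_that("pool generation respects the size band, determinism and feasibility", {
  blocks <- list(a = sprintf("a%02d", 1:50), b = sprintf("b%02d", 1:80),
                 c = sprintf("c%02d", 1:70), d = sprintf("d%02d", 1:40))
  pools <- generate_pools(blocks, 8, target_size = 200, seed = 3)
  expect_length(pools, 8)
  for (p in pools) {
    expect_gte(p$size, 160); expect_lte(p$size, 240)
    expect_equal(length(p$descriptors), p$size)
    expect_true(all(p$descriptors %in% unlist(blocks)))
  }
  # the {b, c, d} combination (190 descriptors) is inside the band
  expect_true(any(vapply(generate_pools(blocks, 11, 200, seed = 1),
                         function(p) setequal(p$block_names, c("b", "c", "d")),
                         TRUE)))
  expect_identical(lapply(generate_pools(blocks, 102, 200, seed = 9), unclass),
                   lapply(generate_pools(blocks, 102, 200, seed = 9), unclass))
  expect_error(generate_pools(list(a = sprintf("a%d", 1:30),
                                   b = sprintf("b%d", 1:25)), 5, 200),
               "achievable sizes")
})

test_that("stepwise selection picks the strongest discriminator first", {
  set.seed(61)
  n <- 164
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(stats::rnorm(n * 21), n, 21,
              dimnames = list(NULL, sprintf("d%02d", 1:21)))
  X[, "d11"] <- X[, "d11"] + y  # standardized gap 2.0 on d11
  sel <- stepwise_select(X, y, selection_config())
  expect_equal(sel$selected[1], "d11")
  # brute-force F-to-enter over all candidates at step 1 via lm
  f_lm <- vapply(colnames(X), function(j)
    summary(stats::lm(y ~ X[, j]))$fstatistic[["value"]], 0)
  expect_equal(unname(sel$f_to_enter[1]), max(f_lm), tolerance = 1e-10)
})

test_that("collinear candidates are blocked by the tolerance rule", {
  set.seed(62)
  n <- 120
  y <- rep(c(1, -1), each = n / 2)
  strong <- stats::rnorm(n) + y
  e <- stats::rnorm(n, sd = 0.05)
  # orthogonal to y and to strong: adding it strictly dilutes the signal
  e <- stats::residuals(stats::lm(e ~ y + strong))
  X <- cbind(s1 = strong, s2 = strong,   # exact duplicate: tolerance 0
             s3 = strong + e,            # near-duplicate of s1
             noise = stats::rnorm(n))
  sel <- stepwise_select(X, y, selection_config(tolerance_min = 0.1))
  expect_true("s1" %in% sel$selected)
  expect_false("s2" %in% sel$selected)
  expect_false("s3" %in% sel$selected)
  expect_true(all(sel$tolerances >= 0.1))
})

test_that("cases-per-predictor caps the model size at floor(n/11)", {
  set.seed(63)
  n <- 164
  y <- rep(c(1, -1), each = n / 2)
  # every descriptor independently informative so selection runs long
  X <- matrix(stats::rnorm(n * 40), n, 40,
              dimnames = list(NULL, sprintf("d%02d", 1:40))) + y
  sel <- stepwise_select(X, y, selection_config(max_steps = 40))
  expect_lte(length(sel$selected), floor(164 / 11))
})

test_that("selection is deterministic and skips zero-variance descriptors", {
  set.seed(64)
  n <- 80
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(stats::rnorm(n * 15), n, 15,
              dimnames = list(NULL, sprintf("d%02d", 1:15)))
  X[, "d05"] <- 7
  X[, "d09"] <- X[, "d09"] + 0.8 * y
  s1 <- stepwise_select(X, y, selection_config())
  s2 <- stepwise_select(X, y, selection_config())
  expect_identical(s1, s2)
  expect_equal(s1$skipped_zero_variance, "d05")
  expect_false("d05" %in% s1$selected)
})

test_that("LDA discriminant has its boundary at zero with substrates positive", {
  # 1-D symmetric case: class means +1 and -1, equal variance
  set.seed(65)
  x <- matrix(c(stats::rnorm(50, 1), stats::rnorm(50, -1)), ncol = 1,
              dimnames = list(NULL, "d"))
  y <- rep(c(1, -1), each = 50)
  m <- fit_lda(x, y, config = selection_config(min_cases_per_predictor = 1))
  mid <- (mean(x[y == 1, ]) + mean(x[y == -1, ]))
  df_hi <- predict(m, matrix(2, 1, 1, dimnames = list(NULL, "d")))
  df_lo <- predict(m, matrix(-2, 1, 1, dimnames = list(NULL, "d")))
  expect_gt(df_hi, 0)
  expect_lt(df_lo, 0)
  # boundary at the pooled midpoint
  expect_equal(predict(m, matrix(mid / 2, 1, 1,
                                 dimnames = list(NULL, "d")))[1], 0,
               tolerance = 1e-10)

  # separable 2-D toy set scores 100% at the df = 0 cutoff
  toy <- matrix(c(2, 1,  2.5, 1.2,  3, 0.8,
                  -2, -1, -2.5, -0.9, -3, -1.1), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("u", "v")))
  ty <- c(1, 1, 1, -1, -1, -1)
  tm <- fit_lda(toy, ty, config = selection_config(min_cases_per_predictor = 1))
  expect_equal(tm$training$accuracy, 1)
})

test_that("LDA coefficients agree with MASS::lda under equal priors", {
  library(MASS)
  set.seed(66)
  n <- 200
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d"))) + 0.7 * y
  m <- fit_lda(X, y, config = selection_config(min_cases_per_predictor = 1))
  ld <- lda(X, grouping = factor(y), prior = c(0.5, 0.5))
  calls_mass <- ifelse(predict(ld, as.data.frame(X))$class == "1", 1, -1)
  expect_equal(predict(m, X, type = "class"), calls_mass,
               ignore_attr = TRUE)
  # the discriminant direction is proportional to MASS's scaling
  ratio <- m$coefficients / drop(ld$scaling)
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-8)
})

test_that("LDA and regression-on-dummy give the same ranking of compounds", {
  set.seed(67)
  n <- 150
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(stats::rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("a", "b", "c"))) + 0.6 * y
  m <- fit_lda(X, y, config = selection_config(min_cases_per_predictor = 1))
  fitted_mlr <- stats::lm.fit(cbind(1, X), as.numeric(y))$fitted.values
  expect_equal(stats::cor(predict(m, X), fitted_mlr, method = "spearman"), 1)
})

test_that("permuted labels give chance-level training accuracy", {
  set.seed(68)
  n <- 1000
  y <- sample(rep(c(1, -1), each = n / 2))
  X <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(NULL, sprintf("d%d", 1:5)))
  m <- fit_lda(X, y, config = selection_config(min_cases_per_predictor = 1))
  expect_lt(abs(m$training$accuracy - 0.5), 0.06)
})

test_that("singular pooled covariance is reported with the collinear names", {
  set.seed(69)
  x <- stats::rnorm(40)
  X <- cbind(a = x, b = 2 * x, c = stats::rnorm(40))
  y <- rep(c(1, -1), 20)
  expect_error(fit_lda(X, y, config = selection_config(min_cases_per_predictor = 1)),
               "collinear")
})

test_that("df scoring follows the linear form and its tie-break", {
  m <- manual_model(0.5, c(d1 = 1, d2 = -2))
  row <- matrix(c(0.3, 0.1), 1, dimnames = list(NULL, c("d1", "d2")))
  expect_equal(predict(m, row), 0.6, ignore_attr = TRUE)
  expect_equal(predict(m, row, type = "class"), 1L, ignore_attr = TRUE)
  # df exactly 0 is called nonsubstrate
  zero_row <- matrix(c(-0.5, 0), 1, dimnames = list(NULL, c("d1", "d2")))
  expect_equal(predict(m, zero_row), 0, ignore_attr = TRUE)
  expect_equal(predict(m, zero_row, type = "class"), -1L, ignore_attr = TRUE)
  # all-zero descriptors give df = a0
  z <- matrix(0, 1, 2, dimnames = list(NULL, c("d1", "d2")))
  expect_equal(predict(m, z), 0.5, ignore_attr = TRUE)
  expect_error(predict(m, matrix(0, 1, 1, dimnames = list(NULL, "d1"))),
               "missing descriptor")
})

test_that("every emitted model respects the tolerance and ratio invariants", {
  for (seed in 1:3) {
    ds <- generate_polyspecific(syn_small(seed))
    dmf <- filter_low_information(ds$descriptors, ds$compounds$id)
    pools <- generate_pools(dmf$blocks, 4, target_size = 30, seed = seed)
    for (p in pools) {
      m <- build_model(dmf$values[, p$descriptors, drop = FALSE],
                       ds$compounds$label, selection_config(), p$pool_id)
      if (is.null(m)) next
      expect_gte(m$cases_per_predictor, 11)
      expect_true(all(m$tolerances >= 0.1))
      expect_equal(m$pool_id, p$pool_id)
    }
  }
})
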