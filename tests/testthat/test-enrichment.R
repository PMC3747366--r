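test_that("accumulation AUC satisfies the ROC identity on arbitrary rankings", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(10:500, 1)
    r <- random_ranking(n, stats::runif(1, 0.05, 0.8),
                        tie_levels = sample(c(0, 4), 1))
    ra <- mean(r$hits); ri <- 1 - ra
    expect_lt(abs(accumulation_auc(r) / ri - ra / (2 * ri) -
                    empirical_roc(r)$auc), 1e-12)
  }
})

test_that("accumulation AUC has the right geometry at the extremes", {
  # all hits first: linear rise over the first A compounds
  best <- rk(10:1, c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(accumulation_auc(best), 1 - 0.4 / 2)
  # chance at 50% hits: AUCc = 0.5 by the identity with AUC = 0.5
  set.seed(52)
  ch <- rk(stats::rnorm(5000), rep(c(TRUE, FALSE), 2500))
  expect_lt(abs(accumulation_auc(ch) - 0.5), 0.02)
  expect_error(accumulation_auc(rk(1:3, rep(FALSE, 3))), "no hits")
})

test_that("enrichment factor follows its defining arithmetic", {
  # 164-compound library, 85 actives, fully active top-16 selection
  h <- c(rep(TRUE, 16), rep(TRUE, 69), rep(FALSE, 79))
  r <- rk(seq(164, 1), h)
  expect_equal(enrichment_factor(r, n_select = 16), (16 / 16) / (85 / 164))
  # N=10, A=5, top-1 a hit at x = 0.1
  r10 <- rk(10:1, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(enrichment_factor(r10, x = 0.1), 2)
  # fully-hit selection attains the maximum N/A
  expect_equal(enrichment_factor(r, n_select = 10), 164 / 85)
  expect_error(enrichment_factor(r10, x = 0.01), "zero")
  # chance expectation is 1
  set.seed(53)
  efs <- replicate(300, enrichment_factor(
    rk(sample(100), c(rep(TRUE, 20), rep(FALSE, 80))), x = 0.1))
  expect_lt(abs(mean(efs) - 1), 0.12)
})

test_that("EF upper bound holds on random rankings", {
  set.seed(54)
  for (i in 1:30) {
    r <- random_ranking(sample(20:200, 1), stats::runif(1, 0.1, 0.6))
    ef <- enrichment_factor(r, x = stats::runif(1, 0.05, 0.9))
    expect_lte(ef * mean(r$hits), 1 + 1e-12)
  }
})

test_that("RIE matches hand evaluation and its random expectation", {
  # N=4, single hit at rank 1: e^-5 * 4 (e^5 - 1)/(1 - e^-20)
  r <- rk(4:1, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rie(r, 20), exp(-5) * 4 * (exp(5) - 1) / (1 - exp(-20)),
               tolerance = 1e-12)
  expect_equal(rie(r, 20), 3.973048, tolerance = 1e-6)
  # hit at the last rank with large alpha: essentially zero
  worst <- rk(50:1, c(rep(FALSE, 49), TRUE))
  expect_lt(rie(worst, 60), 1e-10)
  # mean over random shuffles tends to 1
  set.seed(55)
  m <- mean(replicate(2000, rie(rk(sample(50),
                                   c(rep(TRUE, 5), rep(FALSE, 45))), 20)))
  expect_lt(abs(m - 1), 0.1)
})

test_that("RIE and BEDROC agree with the direct-sum oracle on all small rankings", {
  for (N in 2:8) {
    for (A in 1:(N - 1)) {
      pos <- utils::combn(N, A)
      for (j in seq_len(ncol(pos))) {
        h <- rep(FALSE, N); h[pos[, j]] <- TRUE
        r <- rk(N:1, h)
        for (alpha in c(5, 20)) {
          expect_equal(rie(r, alpha), rie_oracle(r, alpha), tolerance = 1e-12)
          expect_equal(bedroc(r, alpha), bedroc_oracle(r, alpha),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BEDROC stays in [0, 1] and orders rankings sensibly", {
  set.seed(56)
  for (i in 1:20) {
    r <- random_ranking(sample(10:200, 1), stats::runif(1, 0.05, 0.5))
    b <- bedroc(r, 20)
    expect_gte(b, 0); expect_lte(b, 1)
  }
  worst <- rk(200:1, c(rep(FALSE, 190), rep(TRUE, 10)))
  best <- rk(200:1, c(rep(TRUE, 10), rep(FALSE, 190)))
  expect_lt(bedroc(worst, 20), 0.001)
  expect_gt(bedroc(best, 20), 0.99)
  # reversing a better-than-random ranking lowers BEDROC
  set.seed(57)
  h <- stats::runif(150) < 0.2
  s <- stats::rnorm(150) + 1.5 * h
  expect_gt(bedroc(rk(s, h), 20), bedroc(rk(-s, h), 20))
  # near-invariance under duplicating every compound
  r1 <- rk(40:1, c(rep(TRUE, 6), rep(FALSE, 34)))
  r2 <- rk(rep(40:1, each = 2) + c(0.1, 0), rep(c(rep(TRUE, 6), rep(FALSE, 34)),
                                                each = 2))
  expect_lt(abs(bedroc(r1, 20) - bedroc(r2, 20)), 0.05)
})

test_that("screening campaign reports the decoy-spiked library correctly", {
  set.seed(58)
  # 27 known nonsubstrates + 71 known substrates + 479 putative decoys
  labels <- c(rep(-1, 27), rep(1, 71), rep(1, 479))
  prov <- c(rep("known", 98), rep("putative", 479))
  scores <- stats::rnorm(577) + 1.5 * (labels == 1)  # substrates score high
  rep_ <- run_screening_campaign(scores, labels, provenance = prov)
  expect_equal(rep_$N, 577)
  expect_equal(rep_$A, 27)
  expect_equal(rep_$Ra, 27 / 577)
  expect_lt(rep_$Ra, 0.05)
  expect_false(rep_$saturated)
  # the AUCc-derived ROC AUC matches the direct trapezoid computation
  hits <- labels == -1
  direct <- empirical_roc(scored_ranking(sprintf("c%d", 1:577), scores, hits,
                                         direction = "ascending"))$auc
  expect_equal(rep_$roc_auc, direct, tolerance = 1e-12)

  # test set alone: 27 hits in 98 compounds triggers the saturation caveat
  expect_warning(
    sat <- run_screening_campaign(scores[1:98], labels[1:98],
                                  provenance = prov[1:98]),
    "saturation")
  expect_equal(sat$Ra, 27 / 98, tolerance = 1e-12)
  expect_error(run_screening_campaign(scores[28:98], labels[28:98],
                                      provenance = prov[28:98]),
               "no known nonsubstrates")
})
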