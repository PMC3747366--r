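test_that("compound tables parse labels, reject duplicates, warn on empty", {
  td <- withr::local_tempdir()
  p <- file.path(td, "c.csv")

  writeLines(c("id,smiles,label", "a,CC,1", "b,CCO,-1", "c,CCC,1"), p)
  cp <- read_compounds(p)
  expect_equal(nrow(cp), 3)
  expect_equal(sum(cp$label == 1), 2)
  expect_equal(cp$set, rep("unassigned", 3))

  writeLines(c("id,label", "mitoxantrone,1", "mitoxantrone,-1"), p)
  expect_error(read_compounds(p), "mitoxantrone")

  writeLines(c("id,label", "x,maybe"), p)
  expect_error(read_compounds(p), "row 1")

  writeLines("id,label", p)
  expect_warning(empty <- read_compounds(p), "empty")
  expect_equal(nrow(empty), 0)

  # putative labels become +1 substrates with putative provenance
  writeLines(c("id,label", "d1,putative", "d2,-1"), p)
  dec <- read_compounds(p)
  expect_equal(dec$label, c(1L, -1L))
  expect_equal(dec$provenance, c("putative", "known"))
  # and survive a write/read cycle
  write_compounds(dec, p)
  expect_equal(read_compounds(p)$provenance, c("putative", "known"))
})

test_that("descriptor matrices round-trip bit-identically with their blocks", {
  set.seed(91)
  v <- matrix(stats::rnorm(60) * 10^sample(-8:8, 60, TRUE), 6, 10,
              dimnames = list(sprintf("c%d", 1:6), sprintf("d%02d", 1:10)))
  dm <- descriptor_matrix(v, list(one = sprintf("d%02d", 1:4),
                                  two = sprintf("d%02d", 5:10)))
  td <- withr::local_tempdir()
  write_descriptor_matrix(dm, file.path(td, "m.csv"), file.path(td, "m.json"))
  back <- read_descriptor_matrix(file.path(td, "m.csv"),
                                 file.path(td, "m.json"))
  expect_identical(back$values, dm$values)
  expect_identical(back$blocks, dm$blocks)
})

test_that("the block manifest must partition the descriptors", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(descriptor_matrix(v, list(g = c("x", "x", "y"))), "more than one")
  expect_error(descriptor_matrix(v, list(g = "x")), "partition")
  expect_error(descriptor_matrix(v, list(g = c("x", "y", "z"))), "partition")
})

test_that("low-information filtering uses training rows only and is idempotent", {
  set.seed(92)
  n <- 200
  ids <- sprintf("c%03d", 1:n)
  train <- ids[1:120]
  v <- cbind(const = rep(7, n),
             nearconst = c(rep(1, n - 1), 2),     # 99.5% identical
             rising = seq_len(n) / 10,
             noisy = stats::rnorm(n))
  rownames(v) <- ids
  dm <- descriptor_matrix(v, list(all = colnames(v)))
  f <- filter_low_information(dm, train)
  expect_false("const" %in% colnames(f$values))
  expect_false("nearconst" %in% colnames(f$values))
  expect_true(all(c("rising", "noisy") %in% colnames(f$values)))

  # idempotent
  f2 <- filter_low_information(f, train)
  expect_identical(f2$values, f$values)
  expect_identical(f2$blocks, f$blocks)

  # perturbing test rows never changes the decision
  v2 <- v
  v2[121:n, "const"] <- stats::rnorm(80)
  v2[121:n, "noisy"] <- 3.14
  f3 <- filter_low_information(descriptor_matrix(v2, list(all = colnames(v2))),
                               train)
  expect_identical(colnames(f3$values), colnames(f$values))

  all_flat <- descriptor_matrix(
    matrix(1, n, 2, dimnames = list(ids, c("p", "q"))),
    list(all = c("p", "q")))
  expect_error(filter_low_information(all_flat, train), "no informative")
  expect_error(filter_low_information(dm, c(train, "nope")), "not present")
})

test_that("non-finite values are imputed with training medians", {
  v <- matrix(c(1, 2, 3, NaN, 10, Inf, 30, 40), 4, 2,
              dimnames = list(sprintf("c%d", 1:4), c("a", "b")))
  dm <- descriptor_matrix(v, list(g = c("a", "b")))
  imp <- impute_nonfinite(dm, training_ids = c("c1", "c2", "c3"))
  expect_true(all(is.finite(imp$values)))
  expect_equal(attr(imp, "n_imputed"), 2L)
  expect_equal(imp$values["c4", "a"], 2)    # median of 1, 2, 3
  expect_equal(imp$values["c2", "b"], 20)   # median of finite 10, 30
})

test_that("descriptors from SMILES match basic chemistry", {
  dm <- compute_descriptor_blocks(c(eth = "CC", wat = "O", benz = "c1ccccc1",
                                    etoh = "CCO"))
  v <- dm$values
  expect_equal(v["eth", "MW"], 30.07, tolerance = 1e-3)
  expect_equal(v["eth", "HBA"], 0)
  expect_gte(v["wat", "HBD"], 1)
  expect_equal(v["wat", "nRing"], 0)
  expect_equal(v["wat", "nCyc"], 0)
  expect_equal(v["benz", "nCyc"], 1)
  expect_equal(v["benz", "W"], 27)          # Wiener index of C6 cycle
  expect_equal(v["etoh", "ROH"], 1)
  expect_gte(length(dm$blocks), 8)
  expect_true(all(is.finite(v)))
})

test_that("descriptor computation is deterministic and shape-consistent", {
  sm <- family_smiles  # 12 molecules
  a <- compute_descriptor_blocks(sm)
  b <- compute_descriptor_blocks(sm)
  expect_identical(a$values, b$values)
  expect_equal(nrow(a$values), length(sm))
  expect_equal(ncol(a$values), length(unlist(a$blocks)))
  expect_true(all(property_descriptor_names() %in% colnames(a$values)))
})

test_that("invalid SMILES are rejected with the offending ids", {
  expect_error(compute_descriptor_blocks(c(ok = "CC", bad = NA)), "bad")
  expect_error(compute_descriptor_blocks(c(frag = "CC.CC")), "frag")
})
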