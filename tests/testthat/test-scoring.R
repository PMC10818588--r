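dq25_pair <- load_packaged_allele("HLA-DQ2.5", verify = FALSE)$pair

test_that("the gliadin worked example scores BS 0.807 / NBS -0.035, binder", {
  # sums of the printed DQ2.5 matrix cells for PQPELPYPQ
  res <- score_core(dq25_pair, "PQPELPYPQ")
  expect_equal(res$bs, 0.807, tolerance = 1e-9)
  expect_equal(res$nbs, -0.035, tolerance = 1e-9)
  expect_equal(res$predicted, "binder")
  expect_equal(res$offset, 0L)
})

test_that("score_core agrees with the per-position accumulation oracle", {
  withr::local_seed(41)
  f <- matrix(1 / 20, 20, 9, dimnames = list(AA1, NULL))
  peps <- generate_fixture_peptides(f, 30, seed = 6)$peptide
  for (s in peps) {
    res <- score_core(dq25_pair, s)
    expect_equal(res$bs, oracle_score(dq25_pair$binder, s), tolerance = 1e-12)
    expect_equal(res$nbs, oracle_score(dq25_pair$nonbinder, s), tolerance = 1e-12)
  }
  # poly-Cys row sum: 8 x (-0.130) + (-0.109)
  expect_equal(score_core(dq25_pair, "CCCCCCCCC")$bs, -1.149, tolerance = 1e-9)
})

test_that("BS is bounded by the column-wise extrema of the binder matrix", {
  withr::local_seed(42)
  f <- matrix(1 / 20, 20, 9, dimnames = list(AA1, NULL))
  peps <- generate_fixture_peptides(f, 200, seed = 12)
  sc <- score_peptides(peps, dq25_pair)
  m <- matrix(as.numeric(dq25_pair$binder), 20, 9)
  expect_true(all(sc$bs >= sum(apply(m, 2, min)) - 1e-12))
  expect_true(all(sc$bs <= sum(apply(m, 2, max)) + 1e-12))
})

test_that("ties classify as non-binder and length is enforced", {
  zero <- build_logo_model(rep("PQPELPYPQ", 2), "binder")  # any valid QM
  pair0 <- model_pair(zero, zero)                          # BS == NBS always
  res <- score_core(pair0, "AAAAAAAAA")
  expect_equal(res$bs, res$nbs)
  expect_equal(res$predicted, "non-binder")

  expect_error(score_core(dq25_pair, "AAAAAAAA"), "length must be 9")
  expect_error(score_peptides("AAAAAAAA", dq25_pair), "shorter than")
  expect_error(score_core(dq25_pair, c("AAAAAAAAA", "AAAAAAAAA")), "single core")
})

test_that("window scanning maximizes BS - NBS with earliest-offset ties", {
  # 10-mer whose best register is offset 1
  res <- score_peptides("APQPELPYPQ", dq25_pair)
  expect_equal(res$offset, 1L)
  expect_equal(res$core, "PQPELPYPQ")
  expect_equal(res$bs, 0.807, tolerance = 1e-9)

  # 9-mer input is identical to score_core
  r9 <- score_peptides("PQPELPYPQ", dq25_pair)
  expect_equal(r9[c("bs", "nbs", "predicted", "offset")],
               score_core(dq25_pair, "PQPELPYPQ")[c("bs", "nbs", "predicted", "offset")])

  # exhaustive dominance check for random peptides up to length 20
  withr::local_seed(314)
  for (i in 1:40) {
    L <- sample(9:20, 1)
    s <- paste(sample(AA1, L, replace = TRUE), collapse = "")
    res <- score_peptides(s, dq25_pair)
    deltas <- vapply(0:(L - 9), function(off) {
      r <- score_core(dq25_pair, substr(s, off + 1, off + 9))
      r$bs - r$nbs
    }, numeric(1))
    expect_equal(res$bs - res$nbs, max(deltas), tolerance = 1e-12)
    expect_equal(res$offset, which.max(deltas) - 1L)  # which.max takes first
  }

  # a homopolymer makes every window tie: earliest offset must win
  expect_equal(score_peptides(strrep("A", 15), dq25_pair)$offset, 0L)
})

test_that("swapping binder and non-binder matrices swaps BS/NBS and flips calls", {
  swapped <- model_pair(dq25_pair$nonbinder, dq25_pair$binder)
  withr::local_seed(59)
  f <- matrix(1 / 20, 20, 9, dimnames = list(AA1, NULL))
  peps <- generate_fixture_peptides(f, 100, seed = 8)
  a <- score_peptides(peps, dq25_pair)
  b <- score_peptides(peps, swapped)
  expect_equal(a$bs, b$nbs, tolerance = 1e-12)
  expect_equal(a$nbs, b$bs, tolerance = 1e-12)
  ties <- abs(a$bs - a$nbs) < 1e-12
  expect_true(all(a$predicted[!ties] != b$predicted[!ties]))
})

test_that("confidence ratios follow the true-class convention and bin at strict +/-1", {
  sc <- tibble::tibble(bs = c(0.807, 0.5, 0.2, 0.3, 0.4),
                       nbs = c(-0.035, 0.4, 0.4, 0, -0.4),
                       predicted = c("binder", "binder", "non-binder",
                                     "binder", "binder"))
  out <- add_confidence(sc, label = "binder")   # ratio = BS/NBS
  expect_equal(out$ratio[1], 0.807 / -0.035, tolerance = 1e-9)
  expect_equal(as.character(out$bin[1]), "below_minus1")
  expect_equal(out$ratio[2], 1.25)
  expect_equal(as.character(out$bin[2]), "above_plus1")
  expect_equal(out$ratio[3], 0.5)
  expect_equal(as.character(out$bin[3]), "uncertain")
  expect_true(is.na(out$ratio[4]))              # zero denominator
  expect_equal(as.character(out$bin[4]), "undefined")
  expect_equal(out$ratio[5], -1)                # boundary -1 is uncertain
  expect_equal(as.character(out$bin[5]), "uncertain")

  # non-binder label inverts the ratio; unknown follows the predicted class
  nb <- add_confidence(sc[3, ], label = "non-binder")
  expect_equal(nb$ratio, 0.4 / 0.2)
  unk <- add_confidence(sc[1:3, ], label = "unknown")
  expect_equal(unk$ratio[1], 0.807 / -0.035, tolerance = 1e-9)
  expect_equal(unk$ratio[3], 0.4 / 0.2)         # predicted non-binder
  expect_error(add_confidence(sc, label = "maybe"), "unknown label")
})
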