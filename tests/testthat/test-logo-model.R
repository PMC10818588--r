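test_that("count_positions tallies residues with multiplicity and conserves N", {
  cm <- count_positions(rep(strrep("A", 9), 3))
  expect_s3_class(cm, "peplogo_counts")
  expect_equal(unname(cm["Ala", ]), rep(3L, 9))
  expect_equal(sum(cm), 3L * 9L)

  cm2 <- count_positions(c("PQPELPYPQ", "PQPELPYPA"))
  expect_equal(cm2[["Gln", "p9"]], 1L)
  expect_equal(cm2[["Ala", "p9"]], 1L)
  expect_equal(unname(colSums(cm2)), rep(2, 9))

  expect_error(count_positions(c("PQPELPYPQ", "AAAA")), "equal length")

  # against the loop oracle on a random fixture
  withr::local_seed(77)
  f <- matrix(stats::runif(20 * 9), 20, 9, dimnames = list(AA1, NULL))
  f <- sweep(f, 2, colSums(f), "/")
  peps <- generate_fixture_peptides(f, 1000, seed = 5)
  cm3 <- count_positions(peps)
  expect_equal(unname(colSums(cm3)), rep(1000, 9))
  expect_equal(matrix(as.integer(cm3), 20, 9), unname(oracle_counts(peps$peptide)))
})

test_that("normalization matches the closed form for identical peptides", {
  # all N peptides identical: f is 1 on one cell per column, 0 elsewhere;
  # mean 1/20, range 1, so occupied cells get 0.95 and empty cells -0.05
  qm <- build_logo_model(rep("PQPELPYPQ", 3), label = "binder")
  expect_equal(qm[["Pro", "p1"]], 0.95)
  expect_equal(qm[["Gln", "p2"]], 0.95)
  expect_equal(qm[["Cys", "p1"]], -0.05)
  expect_equal(sort(unique(as.numeric(qm))), c(-0.05, 0.95))
  expect_equal(max(abs(colSums(matrix(as.numeric(qm), 20, 9)))), 0, tolerance = 1e-12)
})

test_that("normalize agrees with the brute-force formula oracle on random inputs", {
  for (seed in 1:25) {
    n <- sample(3:20, 1)
    m <- random_counts(n, L = 3, seed = 1000 + seed)
    peps <- counts_as_peptides(m, n)
    qm <- build_logo_model(peps, label = "binder")
    expect_equal(matrix(as.numeric(qm), 20, 3), unname(oracle_normalize(m, n)),
                 tolerance = 1e-12)
    expect_true(all(qm >= -1 & qm <= 1))
    expect_lt(max(abs(colSums(matrix(as.numeric(qm), 20, 3)))), 1e-9)
  }
})

test_that("degenerate all-equal frequencies are a hard error", {
  # 20 peptides hitting every residue once per position: all frequencies 1/20
  peps <- counts_as_peptides(matrix(1L, 20, 2, dimnames = list(aa_to_three(AA1), c("p1", "p2"))), 20)
  expect_error(build_logo_model(peps, "binder"), "degenerate")
})

test_that("the model is invariant to duplicating every peptide k times", {
  peps <- c("PQPELPYPQ", "QPQQPFPQQ", "AAAAAAAAA", "PQPELPYPA")
  qm1 <- build_logo_model(peps, "binder")
  qm3 <- build_logo_model(rep(peps, 3), "binder")
  expect_equal(matrix(as.numeric(qm1), 20, 9), matrix(as.numeric(qm3), 20, 9),
               tolerance = 1e-12)
})

test_that("decode_counts inverts the printed packaged matrices", {
  dq25 <- load_packaged_allele("HLA-DQ2.5", verify = FALSE)
  dq81 <- load_packaged_allele("HLA-DQ8.1", verify = FALSE)
  cases <- list(
    list(qm = dq25$pair$binder, n = 125, R = 48),
    list(qm = dq25$pair$nonbinder, n = 125, R = 66),
    list(qm = dq81$pair$binder, n = 463, R = 190),
    list(qm = dq81$pair$nonbinder, n = 463, R = 165))
  for (cs in cases) {
    cnt <- decode_counts(cs$qm, cs$n)
    expect_equal(attr(cnt, "scale_R"), cs$R)
    expect_equal(unname(colSums(cnt)), rep(cs$n, 9))
    expect_true(all(cnt >= 0))
    # re-encoding reproduces the printed values at 3 decimals
    rebuilt <- normalize_counts(cnt)
    expect_equal(round(matrix(as.numeric(rebuilt), 20, 9), 3),
                 round(matrix(as.numeric(cs$qm), 20, 9), 3),
                 tolerance = 0.0011)
  }
  # spot values fixed by the decode arithmetic
  cnt2 <- decode_counts(dq25$pair$binder, 125)
  expect_equal(cnt2[["Val", "p1"]], 25L)
  expect_equal(cnt2[["Pro", "p1"]], 17L)
  expect_equal(cnt2[["Cys", "p1"]], 0L)
  cnt5 <- decode_counts(dq81$pair$binder, 463)
  expect_equal(cnt5[["Glu", "p9"]], 190L)
  cnt3 <- decode_counts(dq25$pair$nonbinder, 125)
  expect_equal(cnt3[["Ala", "p2"]], 59L)
  expect_equal(cnt3[["Leu", "p2"]], 66L)
  expect_equal(sum(cnt3[, "p2"] > 0), 2L)  # only Ala and Leu at p2
})

test_that("decode_counts fails loudly on matrices inconsistent with the encoding", {
  withr::local_seed(31)
  v <- matrix(stats::runif(180, -0.2, 0.8), 20, 9)
  v[1, 1] <- -0.13  # a negative level, but column sums cannot work out
  expect_error(decode_counts(v, 125), "decode failure")
  expect_error(decode_counts(matrix(0.5, 20, 9), 125), "no negative entries")
})

test_that("QM TSV roundtrips with metadata, at full precision", {
  qm <- build_logo_model(c("PQPELPYPQ", "QPQQPFPQQ", "AAAAAAAAA"),
                         label = "binder", allele = "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qm(qm, path, digits = NA)
  back <- read_qm(path)
  expect_equal(matrix(as.numeric(back), 20, 9), matrix(as.numeric(qm), 20, 9),
               tolerance = 1e-12)
  expect_equal(attr(back, "allele"), "toy")
  expect_equal(attr(back, "label"), "binder")
  expect_equal(attr(back, "n_peptides"), 3L)
})

test_that("exported frequency TSV reproduces the counts/N table", {
  cm <- count_positions(rep("PQPELPYPQ", 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_frequencies(cm, path)
  tab <- utils::read.delim(path, row.names = 1)
  expect_equal(unname(as.matrix(tab)["Pro", ]), c(1, 0, 1, 0, 0, 1, 0, 1, 0))
  expect_equal(as.numeric(as.matrix(tab)), as.numeric(cm) / 3, tolerance = 1e-12)

  # decoded Table 2 counts: Val p1 frequency 25/125 = 0.2
  dq25 <- load_packaged_allele("HLA-DQ2.5", verify = FALSE)
  cnt <- decode_counts(dq25$pair$binder, 125)
  export_frequencies(cnt, path)
  tab2 <- utils::read.delim(path, row.names = 1)
  expect_equal(tab2["Val", "p1"], 0.2)
})

test_that("tidy and glance expose matrix content and metadata", {
  qm <- build_logo_model(rep("PQPELPYPQ", 3), "binder", allele = "toy")
  td <- tidy(qm)
  expect_equal(nrow(td), 180)
  expect_equal(td$value[td$residue == "Pro" & td$position == 1], 0.95)
  g <- glance(qm)
  expect_equal(g$n_peptides, 3L)
  expect_equal(g$max_value, 0.95)
})
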