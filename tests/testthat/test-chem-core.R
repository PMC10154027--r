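test_that("standardization applies the rejection rules in order", {
  eth <- parse_and_standardize("CCO")
  expect_true(eth$passed)
  expect_setequal(eth$element_set, c("C", "H", "O"))
  expect_equal(eth$mol_weight, 46.07, tolerance = 1e-3)
  expect_true(is.na(eth$reject_reason))

  chl <- parse_and_standardize("CCl")
  expect_false(chl$passed)
  expect_identical(chl$reject_reason, "disallowed_element")

  met <- parse_and_standardize("C")
  expect_false(met$passed)
  expect_identical(met$reject_reason, "single_atom")

  mix <- parse_and_standardize("CCO.OCC")
  expect_false(mix$passed)
  expect_identical(mix$reject_reason, "mixture")

  bad <- parse_and_standardize("C1CC")
  expect_false(bad$passed)
  expect_identical(bad$reject_reason, "unparseable")

  # mixture outranks single_atom and disallowed_element: a two-fragment
  # input with a chlorine is reported as a mixture
  expect_identical(parse_and_standardize("CCl.CCl")$reject_reason,
                   "mixture")
})

test_that("molecular weight threshold is strict at 500 Da", {
  # C35 alkane: 492.95 Da, kept; C36 alkane: 506.97 Da, rejected
  c35 <- parse_and_standardize(strrep("C", 35))
  c36 <- parse_and_standardize(strrep("C", 36))
  expect_true(c35$passed)
  expect_false(c36$passed)
  expect_identical(c36$reject_reason, "too_heavy")
  expect_gt(c36$mol_weight, 500)
  expect_lt(c35$mol_weight, 500)
})

test_that("standardize_dataset partitions while preserving order and dupes", {
  res <- standardize_dataset(c("CCO", "CCl", "C"))
  expect_identical(vapply(res$kept, `[[`, character(1), "key"), "CCO")
  expect_identical(vapply(res$rejected, `[[`, character(1), "key"),
                   c("CCl", "C"))

  empty <- standardize_dataset(character(0))
  expect_length(empty$kept, 0)
  expect_length(empty$rejected, 0)

  dup <- standardize_dataset(c("CCO", "CCO"))
  expect_length(dup$kept, 2)
})

test_that("valid HCNOS molecules under 500 Da all pass, checked per rule", {
  res <- standardize_dataset(valid_odorant_smiles)
  expect_length(res$rejected, 0)
  for (rec in res$kept) {
    # independent per-rule verification from the record's own fields
    expect_true(all(rec$element_set %in% c("H", "C", "N", "O", "S")),
                info = rec$key)
    expect_gt(rec$heavy_atom_count, 1)
    expect_lte(rec$mol_weight, 500)
    expect_false(grepl(".", rec$smiles, fixed = TRUE))
  }
})

test_that("records are deterministic across repeated calls", {
  a <- parse_and_standardize("CC(=O)OC1CCCCC1")
  b <- parse_and_standardize("CC(=O)OC1CCCCC1")
  a$graph <- b$graph <- NULL
  expect_identical(a, b)
})

test_that("count fingerprints are deterministic and discriminative", {
  eth <- parse_and_standardize("CCO")
  prop <- parse_and_standardize("CCCO")
  f1 <- count_fingerprint(eth, radius = 2, dim = 2048)
  f2 <- count_fingerprint(eth, radius = 2, dim = 2048)
  expect_identical(f1, f2)
  f3 <- count_fingerprint(prop, radius = 2, dim = 2048)
  expect_gt(sum(f1$counts != f3$counts), 0)
})

test_that("total environment count is atoms times (radius + 1)", {
  # brute-force expectation: every atom contributes one environment per
  # radius 0..r
  eth <- parse_and_standardize("CCO")   # 3 heavy atoms
  for (r in 0:3) {
    fp <- count_fingerprint(eth, radius = r, dim = 512)
    expect_equal(sum(fp$counts), 3 * (r + 1))
  }
  asp <- parse_and_standardize("CCOC(=O)C")  # 6 heavy atoms
  expect_equal(sum(count_fingerprint(asp, 2, 2048)$counts), 6 * 3)
})

test_that("bit fingerprint is the support indicator of the count vector", {
  for (smi in c("CCO", "c1ccccc1C=O", "CC1=CCC(CC1)C(C)C")) {
    mol <- parse_and_standardize(smi)
    cf <- count_fingerprint(mol, radius = 2, dim = 1024)
    bf <- bit_fingerprint(mol, radius = 2, n_bits = 1024)
    expect_identical(bf$bits, cf$counts > 0)
    expect_gt(sum(bf$bits), 0)
  }
})

test_that("fingerprints refuse failed molecules", {
  bad <- parse_and_standardize("CCl")
  expect_error(count_fingerprint(bad), "standardization")
  expect_error(bit_fingerprint(bad), "standardization")
})

test_that("tanimoto distance matches set arithmetic", {
  mk <- function(on, n = 8) { b <- logical(n); b[on] <- TRUE; b }
  expect_equal(tanimoto_distance(mk(1:3), mk(1:3)), 0)
  expect_equal(tanimoto_distance(mk(1:2), mk(5:6)), 1)
  expect_equal(tanimoto_distance(mk(1:3), mk(2:4)), 0.5)
  expect_equal(tanimoto_distance(mk(integer(0)), mk(integer(0))), 0)
  expect_error(tanimoto_distance(mk(1, 8), mk(1, 16)), "mismatch")
})

test_that("cfp edit distance equals the coordinate loop and is a metric", {
  expect_equal(cfp_edit_distance(c(2, 0, 1), c(0, 1, 1)), 3)
  expect_equal(cfp_edit_distance(c(5, 5), c(5, 5)), 0)
  set.seed(7)
  for (i in 1:100) {
    a <- sample(0:5, 12, replace = TRUE)
    b <- sample(0:5, 12, replace = TRUE)
    cc <- sample(0:5, 12, replace = TRUE)
    expect_equal(cfp_edit_distance(a, b), l1_loop_oracle(a, b))
    expect_equal(cfp_edit_distance(a, b), cfp_edit_distance(b, a))
    expect_lte(cfp_edit_distance(a, cc),
               cfp_edit_distance(a, b) + cfp_edit_distance(b, cc))
  }
})

test_that("correlation distance spans [0, 2] with hand-checked cases", {
  u <- c(1, 0, -1, 0)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u), 2)
  expect_equal(correlation_distance(u, c(0, 1, 0, -1)), 1)
  expect_error(correlation_distance(u, rep(1, 4)), "constant")
  expect_error(correlation_distance(u, c(1, 2)), "width")
})

test_that("center_rows zeroes column means idempotently", {
  set.seed(3)
  m <- matrix(rnorm(60, mean = 4), 10, 6)
  cm <- center_rows(m)
  expect_true(all(abs(colMeans(cm)) < 1e-12))
  expect_equal(center_rows(cm), cm)
  expect_error(center_rows(m[1, , drop = FALSE]), "2 rows")

  # centering changes pairwise correlation distances on skewed data
  skew <- m
  skew[, 1] <- skew[, 1] + 50
  d_raw <- correlation_distance(skew[1, ], skew[2, ])
  cs <- center_rows(skew)
  d_cen <- correlation_distance(cs[1, ], cs[2, ])
  expect_gt(abs(d_raw - d_cen), 1e-6)
})

test_that("smiles io round-trips plain text and csv", {
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CCO", "CCC"), txt)
  expect_identical(read_smiles(txt), c("CCO", "CCC"))
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = 1:2, smiles = c("CCO", "CCC")), csv,
                   row.names = FALSE)
  expect_identical(read_smiles(csv, column = "smiles"), c("CCO", "CCC"))
  expect_error(read_smiles(csv, column = "nope"), "not found")
})
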