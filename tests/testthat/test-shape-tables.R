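test_that("table files round-trip bit-exactly and reject malformed input", {
  tb <- random_sym_table(k = 4, kind = "step-centered", seed = 2,
                         feature = "Roll")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shape_table(tb, path)
  back <- read_shape_table(path, kind = "step-centered", feature = "Roll")
  expect_identical(back$values, tb$values)
  expect_identical(back$k, 4L)

  lines <- readLines(path)
  writeLines(lines[-2], path)  # drop one k-mer row (line 2 is the first row)
  expect_error(read_shape_table(path, kind = "step-centered"),
               "incomplete table: 1 missing")

  writeLines(c(lines, "ACGTN\t5.0"), path)
  expect_error(read_shape_table(path, kind = "step-centered"), "parse error")

  writeLines(c(lines, lines[2]), path)
  expect_error(read_shape_table(path, kind = "step-centered"), "duplicate")
})

test_that("reverse-complement symmetrization averages strand pairs and is idempotent", {
  v <- setNames(numeric(1024), all_kmers(5))
  v["AAAAA"] <- 1
  tb <- shape_table(v, "base-centered", "MGW")
  sym <- rc_symmetrize(tb)
  expect_equal(unname(sym$values["AAAAA"]), 0.5)
  expect_equal(unname(sym$values["TTTTT"]), 0.5)
  expect_equal(sum(sym$values), 1)
  expect_identical(rc_symmetrize(sym)$values, sym$values)
  expect_true(is_rc_symmetric(sym))
})

test_that("class permutation preserves the value multiset, symmetry and moments", {
  tb <- random_sym_table(seed = 7)
  pt <- permute_table(tb, seed = 1)
  expect_true(is_rc_symmetric(pt))
  expect_equal(sort(unname(pt$values)), sort(unname(tb$values)))
  expect_equal(mean(pt$values), mean(tb$values))
  expect_equal(var(pt$values), var(tb$values))

  const <- shape_table(setNames(rep(2.5, 1024), all_kmers(5)),
                       "base-centered")
  expect_identical(permute_table(const, seed = 9)$values, const$values)

  pt2 <- permute_table(tb, seed = 2)
  expect_false(isTRUE(all.equal(pt$values, pt2$values)))

  asym <- tb
  asym$values[1] <- asym$values[1] + 1
  expect_error(permute_table(asym, seed = 1), "symmetric")
})

test_that("step recentering marginalizes both per-pentamer values onto the tetramer", {
  ## constants: all tetramer values are the mean of the two constants
  raw <- raw_step_table(rep(3, 1024), rep(7, 1024))
  ct <- center_step_table(raw)
  expect_equal(unname(ct$values), rep(5, 256))
  expect_identical(ct$kind, "step-centered")

  ## indicator oracle: both step values = indicator(step dinucleotide == "CG");
  ## brute-force enumeration over all 1024 pentamers
  pents <- all_kmers(5)
  first <- as.numeric(substr(pents, 2, 3) == "CG")
  second <- as.numeric(substr(pents, 3, 4) == "CG")
  ct2 <- center_step_table(raw_step_table(first, second))
  tets <- all_kmers(4)
  expected <- numeric(256)
  for (i in seq_along(tets)) {
    t <- tets[i]
    v1 <- mean(vapply(c("A", "C", "G", "T"), function(b) {
      substr(paste0(t, b), 2, 3) == "CG"
    }, TRUE))
    v2 <- mean(vapply(c("A", "C", "G", "T"), function(b) {
      substr(paste0(b, t), 3, 4) == "CG"
    }, TRUE))
    expected[i] <- (v1 + v2) / 2
  }
  ## reverse-complement symmetrize the expectation the same way
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  expected_sym <- (expected + expected[match(rc(tets), tets)]) / 2
  expect_equal(unname(ct2$values), expected_sym)
  expect_true(is_rc_symmetric(ct2))
})

test_that("step recentering commutes with reverse-complement relabeling of the raw table", {
  set.seed(11)
  raw <- raw_step_table(rnorm(1024), rnorm(1024))
  ## RC relabeling of a raw pentamer step table: pentamer -> revcomp swaps
  ## the two step values (step 2-3 maps to step 3-4 of the complement)
  pents <- all_kmers(5)
  idx <- match(revcomp(pents), pents)
  raw_rc <- raw_step_table(setNames(raw$second[idx], pents),
                           setNames(raw$first[idx], pents))
  a <- center_step_table(raw)
  b <- center_step_table(raw_rc)
  ## the centered table is RC-symmetric, so relabeling leaves it unchanged
  expect_equal(unname(a$values), unname(b$values))
})

test_that("synthesized tables are exactly representable (no noise) and deterministic", {
  g <- seq2shape_model(1, withr::with_seed(8, matrix(rnorm(20), 4)))
  tb <- synthesize_table(g, noise_sd = 0, seed = 5)
  fit <- fit_seq2shape(tb, "mono")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(predict_all_kmers(fit), unname(tb$values), tolerance = 1e-9)

  tb2 <- synthesize_table(g, noise_sd = 0.3, seed = 5)
  tb3 <- synthesize_table(g, noise_sd = 0.3, seed = 5)
  expect_identical(tb2$values, tb3$values)
})

test_that("RC averaging of unit-variance noise roughly halves the table variance", {
  g0 <- seq2shape_model(0, matrix(0, 4, 5))
  vs <- vapply(1:30, function(s) {
    var(synthesize_table(g0, noise_sd = 1, seed = s)$values)
  }, 0)
  ## non-palindromic classes average two independent N(0,1) draws
  expect_gt(mean(vs), 0.42)
  expect_lt(mean(vs), 0.58)
})
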