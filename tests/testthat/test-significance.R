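test_that("conditional variance matches direct enumeration and degenerate cases", {
  ## constant table
  const <- shape_table(setNames(rep(3, 256), all_kmers(4)), "step-centered")
  expect_equal(conditional_variance(const), matrix(0, 4, 4))

  ## indicator of base A at position 3 of a pentamer: conditioning on
  ## position 3 removes all variance; elsewhere the variance is untouched
  m <- do.call(rbind, strsplit(all_kmers(5), ""))
  ind <- shape_table(setNames(as.numeric(m[, 3] == "A"), all_kmers(5)),
                     "base-centered")
  C <- conditional_variance(ind)
  expect_equal(unname(C[3, ]), rep(0, 5))
  expect_equal(unname(C[, 3]), rep(0, 5))
  v <- mean((ind$values - mean(ind$values))^2)
  expect_equal(unname(C[1, 2]), v, tolerance = 1e-12)

  ## literal double-loop oracle on a random table
  tb <- random_sym_table(k = 4, kind = "step-centered", seed = 5)
  C2 <- conditional_variance(tb)
  mm <- do.call(rbind, strsplit(all_kmers(4), ""))
  vv <- unname(tb$values)
  for (i in 1:4) for (j in 1:4) {
    vars <- c()
    for (c in c("A", "C", "G", "T")) for (d in c("A", "C", "G", "T")) {
      sel <- mm[, i] == c & mm[, j] == d
      if (any(sel)) vars <- c(vars, mean((vv[sel] - mean(vv[sel]))^2))
    }
    expect_equal(C2[i, j], mean(vars), tolerance = 1e-12)
  }
  ## structural invariants: symmetry, RC mirror symmetry, bounded by total
  expect_equal(C2, t(C2))
  k <- 4
  expect_equal(C2, C2[k:1, k:1], tolerance = 1e-10)
  expect_true(all(C2 <= mean((vv - mean(vv))^2) + 1e-12))
})

test_that("matched random tables mirror the reference dependence structure", {
  ## mono+di structured reference: the matching error floor is low
  g <- seq2shape_model(0, withr::with_seed(6, matrix(rnorm(20), 4)),
                       withr::with_seed(7, matrix(rnorm(64) * 0.5, 16)))
  ref <- synthesize_table(g, noise_sd = 0.1, seed = 8)
  errs <- cors <- numeric(15)
  Cr <- conditional_variance(ref)
  ut <- upper.tri(Cr, diag = TRUE)
  for (s in 1:15) {
    mt <- random_matched_table(ref, seed = s)
    expect_true(is_rc_symmetric(mt))
    errs[s] <- attr(mt, "match_error")
    cors[s] <- cor(Cr[ut], conditional_variance(mt)[ut])
  }
  expect_lt(median(errs), 0.15)
  expect_gt(median(cors), 0.9)

  ## near-constant reference: result is near-constant too
  flat <- shape_table(setNames(rep(1.5, 1024), all_kmers(5)), "base-centered")
  mt0 <- random_matched_table(flat, seed = 1)
  expect_lt(max(conditional_variance(mt0)), 1e-6)

  expect_error(random_matched_table(random_sym_table(seed = 2)$values),
               "shape_table")
})

test_that("null ensembles have ordered bands and expose planted readout", {
  pp <- planted_pair(k = 7, pos = 4, amp = -1.5, seed = 21)
  expect_error(null_bands(pp$agn, list(MGW = pp$table), N = 0), "at least 1")
  ens <- null_bands(pp$agn, list(MGW = pp$table), N = 40, seed = 3)
  b <- ens$bands$MGW
  ## percentile ordering at every position
  for (j in seq_len(ncol(b))) {
    expect_true(all(diff(b[, j]) >= -1e-12))
  }
  obs <- project(pp$agn, list(MGW = pp$sm))
  fdr <- position_fdr(obs, ens)
  expect_equal(nrow(fdr), 3)                 # interior positions 3..5
  expect_equal(fdr$position[which.min(fdr$q)], 4)
  expect_equal(min(fdr$p), 1 / 41)
})

test_that("empirical p-value and BH arithmetic follow their definitions", {
  ## observed zero profile -> all p = 1
  fake_nulls <- matrix(rnorm(40 * 7), 40, 7)
  ens <- structure(list(profiles = list(MGW = fake_nulls), N = 40, k = 7),
                   class = "null_ensemble")
  zero_obs <- list(MGW = numeric(7))
  fdr0 <- position_fdr(zero_obs, ens)
  expect_true(all(fdr0$p == 1))
  expect_true(all(fdr0$q == 1))

  ## one far-outside position: p = 1/(N+1), q = npos/(N+1) when unique
  obs <- numeric(7); obs[4] <- 1e6
  fdr1 <- position_fdr(list(MGW = obs), ens)
  expect_equal(fdr1$p[fdr1$position == 4], 1 / 41)
  expect_equal(fdr1$q[fdr1$position == 4], 3 / 41)
})

test_that("matched nulls compete with the real table far better than permutation nulls", {
  ## complexity-matched tables keep the mono+di dependence structure, so
  ## projections using them approximate the binding model nearly as well
  ## as the real table; permuted tables lose that structure and explain
  ## far less (their tiny fitted coefficients also inflate the null
  ## sensitivity coefficients, which is why permutation makes a
  ## misleadingly permissive null)
  g <- seq2shape_model(0, withr::with_seed(31, matrix(rnorm(20), 4)),
                       withr::with_seed(32, matrix(rnorm(64) * 0.6, 16)))
  ref <- synthesize_table(g, noise_sd = 0.05, seed = 33)
  pp <- planted_pair(k = 7, pos = 4, amp = -1, seed = 34, table = ref)
  N <- 15
  matched <- make_null_models(list(MGW = ref), N = N, seed = 5)
  permuted <- lapply(seq_len(N), function(n) {
    list(MGW = fit_seq2shape(permute_table(ref, seed = 1000 + n), "mono+di"))
  })
  ## permuted tables have near-zero mono+di fits, so their sequence-to-
  ## shape coefficients are far smaller than the structured reference's
  g2norm <- function(models) {
    median(vapply(models, function(mm) sqrt(mean(mm$MGW$gamma2^2)), 0))
  }
  real_fit <- fit_seq2shape(ref, "mono+di")
  expect_gt(g2norm(matched) / g2norm(permuted), 2)
  ## consequence: sensitivity coefficients against permuted nulls are
  ## mechanically inflated, i.e. permutation is not a complexity-matched
  ## null on the coefficient scale
  ens_m <- null_bands(pp$agn, list(MGW = ref), seed = 5,
                      null_models = matched)
  ens_p <- null_bands(pp$agn, list(MGW = ref), seed = 5,
                      null_models = permuted)
  amp <- function(e) median(abs(e$profiles$MGW[, 3:5]))
  expect_gt(amp(ens_p), amp(ens_m))
})
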