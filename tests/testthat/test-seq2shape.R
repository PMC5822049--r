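test_that("design matrices have the documented dimensions and structure", {
  expect_equal(dim(build_design(5, "mono")), c(1024, 21))
  expect_equal(dim(build_design(5, "mono+di")), c(1024, 85))
  X <- build_design(5, "all-pairs")
  expect_equal(dim(X), c(1024, 441))
  ## mono indicator blocks sum to 1 per row, dinucleotide blocks too
  Xmd <- build_design(4, "mono+di")
  for (i in 1:4) expect_equal(unname(rowSums(Xmd[, 1 + (i - 1) * 4 + 1:4])),
                              rep(1, 256))
  for (j in 1:3) expect_equal(unname(rowSums(Xmd[, 17 + (j - 1) * 16 + 1:16])),
                              rep(1, 256))
})

test_that("all-pairs fit matches an independent dense least-squares oracle", {
  tb <- random_sym_table(seed = 13)
  fit <- fit_seq2shape(tb, "all-pairs")
  X <- build_design(5, "all-pairs")
  oracle <- qr.fitted(qr(X), unname(tb$values))
  expect_equal(predict_all_kmers(fit), oracle, tolerance = 1e-8)
})

test_that("parameter counts match the closed forms and the published counts", {
  ## closed forms over k = 2..6
  for (k in 2:6) {
    expect_equal(count_dof(k, "mono"), ceiling((3 * k + 1) / 2))
    expect_equal(count_dof(k, "mono+di"), 4 * floor(3 * k / 2) - 2)
  }
  expect_equal(count_dof(4, "mono"), 7)
  expect_equal(count_dof(5, "mono"), 8)
  expect_equal(count_dof(5, "mono+di"), 26)
  expect_equal(count_dof(4, "mono+di"), 22)
  expect_equal(count_dof(1, "mono"), 2)
  ## di-only spans the same space as mono+di (adjacent indicators imply mono)
  expect_equal(count_dof(5, "di-only"), 26)
})

test_that("fitted functions are RC-invariant on RC-symmetric tables", {
  tb <- random_sym_table(seed = 17)
  for (ord in c("mono", "mono+di")) {
    pred <- predict_all_kmers(fit_seq2shape(tb, ord))
    p <- match(revcomp(all_kmers(5)), all_kmers(5))
    expect_lt(max(abs(pred - pred[p])), 1e-9)
  }
})

test_that("in-sample R2 is monotone over nested designs", {
  tb <- random_sym_table(seed = 19)
  r <- vapply(c("mono", "mono+di", "all-pairs"),
              function(o) fit_seq2shape(tb, o)$r2, 0)
  expect_true(all(diff(r) >= -1e-12))
})

test_that("the leave-one-class-out shortcut agrees with explicit refits", {
  tb <- random_sym_table(k = 3, seed = 23)
  fast <- loo_cv_r2(tb, "mono")
  ## brute force: refit without each RC class
  X <- build_design(3, "mono")
  y <- unname(tb$values)
  km <- all_kmers(3)
  p <- match(revcomp(km), km)
  cls <- split(seq_len(64), pmin(seq_len(64), p))
  err <- numeric(64)
  for (S in cls) {
    sv <- svd(X[-S, , drop = FALSE])
    keep <- sv$d > 1e-9 * sv$d[1]
    coef <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% y[-S]) / sv$d[keep])
    err[S] <- y[S] - drop(X[S, , drop = FALSE] %*% coef)
  }
  slow <- 1 - sum(err^2) / sum((y - mean(y))^2)
  expect_equal(fast, slow, tolerance = 1e-8)
})

test_that("cross-validated R2 behaves at the noise-free and pure-noise extremes", {
  g <- seq2shape_model(0.5, matrix(rnorm(20), 4))
  tb <- synthesize_table(g, noise_sd = 0, seed = 29)
  expect_equal(loo_cv_r2(tb, "mono"), 1, tolerance = 1e-9)
  ## pure-noise tables: distribution centred near zero
  r2s <- vapply(1:20, function(s) loo_cv_r2(random_sym_table(seed = 100 + s),
                                            "mono"), 0)
  expect_lt(abs(median(r2s)), 0.1)
  ## LOO never beats in-sample
  tbm <- random_sym_table(seed = 31)
  expect_lte(loo_cv_r2(tbm, "mono+di"), fit_seq2shape(tbm, "mono+di")$r2 + 1e-12)
})

test_that("profile prediction slides the window with correct centering", {
  v <- setNames(numeric(1024), all_kmers(5))
  v["AAAAA"] <- 4.87
  tb <- shape_table(v, "base-centered", "MGW")
  prof <- predict_profile(strrep("A", 9), tb)
  expect_equal(length(prof), 9)
  expect_true(all(is.na(prof[c(1, 2, 8, 9)])))
  expect_equal(unname(prof[3:7]), rep(4.87, 5))

  ## model-based prediction equals table lookup for representable tables
  g <- seq2shape_model(0.2, matrix(rnorm(20), 4))
  tb2 <- synthesize_table(g, noise_sd = 0, seed = 37)
  fit <- fit_seq2shape(tb2, "mono")
  s <- "ACGTACGTACG"
  expect_equal(predict_profile(s, fit), predict_profile(s, tb2),
               tolerance = 1e-9)

  ## step-centered windows are indexed by steps
  tbs <- random_sym_table(k = 4, kind = "step-centered", seed = 41,
                          feature = "Roll")
  ps <- predict_profile("ACGTAC", tbs)
  expect_equal(length(ps), 5)
  expect_true(all(is.na(ps[c(1, 5)])))
  expect_false(anyNA(ps[2:4]))

  expect_error(predict_profile("ACGNT", tb), "IUPAC")
})

test_that("the display gauge leaves predictions untouched", {
  tb <- random_sym_table(seed = 43)
  fit <- fit_seq2shape(tb, "mono+di")
  lg <- logo_coefficients(fit)
  expect_equal(unname(colMeans(lg$gamma1)), rep(0, 5), tolerance = 1e-12)
  regauged <- seq2shape_model(lg$gamma0, lg$gamma1, lg$gamma2,
                              kind = "base-centered")
  expect_equal(predict_all_kmers(regauged), predict_all_kmers(fit),
               tolerance = 1e-9)
})
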