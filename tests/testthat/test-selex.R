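## small shared geometry for enumeration oracles
sx_lf <- "ACGT"; sx_rf <- "TGCA"

enum_probe_mat <- function(L, lf = sx_lf, rf = sx_rf) {
  vm <- shapeproj:::kmer_base_matrix(L)
  cbind(matrix(rep(match(strsplit(lf, "")[[1]], c("A","C","G","T")),
                   each = nrow(vm)), nrow(vm)), vm,
        matrix(rep(match(strsplit(rf, "")[[1]], c("A","C","G","T")),
                   each = nrow(vm)), nrow(vm)))
}

test_that("transfer-matrix Z0 and Z1 equal brute-force enumeration", {
  set.seed(41)
  L <- 5
  bias <- bias_model(rnorm(16) * 0.2, 2)
  sel <- selection_model(beta1 = matrix(rnorm(12) * 0.8, 4, 3),
                         beta2 = matrix(rnorm(32) * 0.3, 16, 2),
                         beta_ns = -2)
  pm <- enum_probe_mat(L)
  lw <- shapeproj:::probe_log_w(pm, bias)
  kap <- shapeproj:::probe_kappa(pm, sel)
  expect_equal(exp(shapeproj:::selex_log_z0(L, sx_lf, sx_rf, bias)),
               sum(exp(lw)), tolerance = 1e-10)
  z1 <- shapeproj:::selex_log_z1(L, sx_lf, sx_rf, bias, sel)
  expect_equal(exp(z1$logZ1), sum(exp(lw) * kap), tolerance = 1e-10)

  ## with direct shape-regression features (base- and step-centered)
  tb <- random_sym_table(seed = 42)
  tbs <- random_sym_table(k = 4, kind = "step-centered", seed = 43,
                          feature = "Roll")
  sel2 <- selection_model(beta1 = matrix(rnorm(12) * 0.5, 4, 3),
                          shape_sens = list(MGW = c(0.5, -0.3, 0.2),
                                            Roll = c(0.4, -0.6)),
                          shape_tables = list(MGW = tb, Roll = tbs),
                          beta_ns = -1)
  kap2 <- shapeproj:::probe_kappa(pm, sel2)
  z1b <- shapeproj:::selex_log_z1(L, sx_lf, sx_rf, bias, sel2)
  expect_equal(exp(z1b$logZ1), sum(exp(lw) * kap2), tolerance = 1e-10)
})

test_that("simulation is deterministic and respects the sampling model", {
  sel0 <- selection_model(beta1 = matrix(0, 4, 3), beta_ns = 0)
  d1 <- simulate_selex(NULL, sel0, L = 6, n0 = 1e5, n1 = 1e5,
                       sx_lf, sx_rf, seed = 7)
  d2 <- simulate_selex(NULL, sel0, L = 6, n0 = 1e5, n1 = 1e5,
                       sx_lf, sx_rf, seed = 7)
  expect_identical(d1$round0, d2$round0)
  expect_identical(d1$round1, d2$round1)

  ## constant selection: round-1 frequencies track round-0 frequencies.
  ## Pure multinomial noise between two draws of n = 1e5 over 4096 cells
  ## gives TV ~= 4096 * E|f1 - f0| / 2 ~= 0.08; assert no enrichment beyond
  ## that sampling floor.
  f0 <- setNames(d1$round0$count / sum(d1$round0$count), d1$round0$seq)
  f1 <- setNames(d1$round1$count / sum(d1$round1$count), d1$round1$seq)
  allp <- union(names(f0), names(f1))
  g0 <- ifelse(is.na(f0[allp]), 0, f0[allp])
  g1 <- ifelse(is.na(f1[allp]), 0, f1[allp])
  tv <- 0.5 * sum(abs(g0 - g1))
  expect_lt(tv, 0.12)
})

test_that("a single strong site enriches probes by the closed-form ratio", {
  ## beta = 5 for one 4-mer; enrichment of probes containing the site
  ## matches exact enumeration of p_{i,1}
  L <- 8
  b1 <- matrix(0, 4, 4)
  b1[cbind(match(c("G", "G", "C", "C"), c("A", "C", "G", "T")), 1:4)] <- 1.25
  sel <- selection_model(beta1 = b1, beta_ns = 0)      # site scores 5 in total
  pm <- enum_probe_mat(L)
  kap <- shapeproj:::probe_kappa(pm, sel)
  p1 <- kap / sum(kap)                       # uniform bias
  hasv <- grepl("GGCC", kmers_from_base_matrix(shapeproj:::kmer_base_matrix(L)))
  d <- simulate_selex(NULL, sel, L = L, n0 = 2e5, n1 = 2e5, sx_lf, sx_rf,
                      seed = 9)
  obs <- sum(d$round1$count[grepl("GGCC", d$round1$seq)]) / sum(d$round1$count)
  expect_equal(obs, sum(p1[hasv]), tolerance = 0.02)
})

test_that("bias fitting recovers simulated dimer bias and handles uniform data", {
  set.seed(51)
  bias_true <- bias_model(rnorm(16) * 0.2, 2)
  sel0 <- selection_model(beta1 = matrix(0, 4, 4), beta_ns = 0)
  d <- simulate_selex(bias_true, sel0, L = 7, n0 = 2e5, n1 = 100,
                      sx_lf, sx_rf, seed = 12)
  fit <- fit_bias(d, 2)
  ## compare on probe log-weights (gauge-free)
  pm <- enum_probe_mat(7)
  lt <- shapeproj:::probe_log_w(pm, bias_true)
  lf <- shapeproj:::probe_log_w(pm, fit)
  expect_lt(max(abs((lf - mean(lf)) - (lt - mean(lt)))), 0.05)

  ## uniform data -> coefficients near zero
  du <- simulate_selex(NULL, sel0, L = 6, n0 = 2e5, n1 = 100,
                       sx_lf, sx_rf, seed = 13)
  fu <- fit_bias(du, 1)
  expect_lt(max(abs(fu$coef)), 0.02)
})

test_that("selection fitting is self-consistent on a small planted motif", {
  set.seed(53)
  b1 <- matrix(rnorm(16) * 0.2, 4, 4)
  b1[cbind(c(1, 2, 3, 4), 1:4)] <- c(1.5, 1.8, 1.5, 1.6)
  b1 <- gauge_fix_scoring(b1)
  sel_true <- selection_model(beta1 = b1, beta_ns = -10)
  bias_true <- bias_model(rnorm(16) * 0.1, 2)
  d <- simulate_selex(bias_true, sel_true, L = 7, n0 = 1e5, n1 = 1e5,
                      sx_lf, sx_rf, seed = 14)
  bf <- fit_bias(d, 2)
  sf <- fit_selection(d, bf, k = 4, features = "mono")
  ## likelihood at the fit is at least the truth's (same family, same bias)
  pm <- enum_probe_mat(7)
  ll <- function(sel) {
    lw <- shapeproj:::probe_log_w(pm, bf)
    kap <- shapeproj:::probe_kappa(pm, sel)
    lp <- lw + log(kap); lp <- lp - shapeproj:::logsumexp(lp)
    idx <- shapeproj:::kmer_index_from_base(
      shapeproj:::base_matrix_from_kmers(d$round1$seq))
    sum(d$round1$count * lp[idx]) / sum(d$round1$count)
  }
  expect_gte(ll(sf), ll(sel_true) - 1e-6)
  ## at this small geometry individual cells sit on soft directions; the
  ## functional fit (predicted probe selection) must agree closely
  kt <- shapeproj:::probe_kappa(pm, sel_true)
  kf <- shapeproj:::probe_kappa(pm, sf)
  expect_gt(cor(log(kt), log(kf)), 0.98)
  expect_error(fit_selection(
    selex_dataset(d$round0, d$round1[1, , drop = FALSE], sx_lf, sx_rf),
    bf, k = 4), "degenerate")
})

test_that("reverse-complement symmetry can be imposed on the fit", {
  set.seed(59)
  b1 <- matrix(0, 4, 4)
  b1[cbind(c(2, 1, 4, 3), 1:4)] <- 1.6        # CATG: RC-palindromic site
  sel_true <- selection_model(beta1 = gauge_fix_scoring(b1), beta_ns = -10)
  d <- simulate_selex(NULL, sel_true, L = 7, n0 = 5e4, n1 = 5e4,
                      sx_lf, sx_rf, seed = 15)
  bf <- fit_bias(d, 1)
  sf <- fit_selection(d, bf, k = 4, features = "mono", rc_symmetric = TRUE)
  fl <- shapeproj:::flip_selection(sf)
  expect_lt(max(abs(sf$beta1 - fl$beta1)), 1e-8)
})

test_that("k-mer performance applies the count filter and both expectation paths agree", {
  ## threshold semantics on a constructed table
  expect_error(kmer_performance(selection_model(matrix(0, 4, 3)),
                                bias_model(numeric(4), 1),
                                selex_dataset(c(AAAA = 150L, AAAC = 99L),
                                              c(AAAA = 150L, AAAC = 99L),
                                              "AC", "GT"),
                                m = 4, min_count = 100),
               "fewer than 3")

  set.seed(61)
  b1 <- matrix(rnorm(12) * 0.2, 4, 3)
  b1[cbind(c(3, 3, 2), 1:3)] <- 2             # strong GGC site: wide range
  sel <- selection_model(beta1 = b1, beta_ns = -2)
  bias <- bias_model(rnorm(16) * 0.1, 2)
  d <- simulate_selex(bias, sel, L = 6, n0 = 2e5, n1 = 2e5, sx_lf, sx_rf,
                      seed = 16)
  perf <- kmer_performance(sel, bias, d, m = 6, min_count = 50)
  expect_gt(perf$r, 0.9)
  ## a column-shuffled scoring matrix predicts the counts worse
  shuf <- selection_model(beta1 = sel$beta1[, c(2, 3, 1)], beta_ns = -2)
  perf_s <- kmer_performance(shuf, bias, d, m = 6, min_count = 50)
  expect_gt(perf$r, perf_s$r)
  ## m < L exercises the clamped-DP path; compare against enumeration
  perf5 <- kmer_performance(sel, bias, d, m = 5, min_count = 100)
  pm <- enum_probe_mat(6)
  lw <- shapeproj:::probe_log_w(pm, bias)
  kap <- shapeproj:::probe_kappa(pm, sel)
  p1 <- exp(lw) * kap / sum(exp(lw) * kap)
  seqs <- kmers_from_base_matrix(shapeproj:::kmer_base_matrix(6))
  nh <- sum(d$round1$count)
  for (x in names(perf5$expected)[1:5]) {
    direct <- nh * sum(p1[substr(seqs, 1, 5) == x | substr(seqs, 2, 6) == x])
    ## windows overlap-counted: expected counts sum window incidences
    direct2 <- nh * (sum(p1[substr(seqs, 1, 5) == x]) +
                     sum(p1[substr(seqs, 2, 6) == x]))
    expect_equal(unname(perf5$expected[x]), direct2, tolerance = 1e-8)
  }
})

test_that("Fisher r-to-z comparison has the documented arithmetic", {
  expect_equal(compare_r_fisher(0.5, 0.5, 100), 1)
  expect_lt(compare_r_fisher(0.9, 0.0, 1000), 1e-16)
  expect_equal(compare_r_fisher(0.3, 0.6, 50),
               compare_r_fisher(0.6, 0.3, 50))
  ## monotone decrease in |r1 - r2|
  ps <- vapply(c(0.1, 0.3, 0.5), function(d) {
    compare_r_fisher(0.4 + d, 0.4, 200)
  }, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(compare_r_fisher(1, 0.5, 10), "abs")
})

test_that("holdout splitting conserves counts and is reproducible", {
  d <- simulate_selex(NULL, selection_model(matrix(0, 4, 3), beta_ns = 0),
                      L = 5, n0 = 1e4, n1 = 1e4, sx_lf, sx_rf, seed = 18)
  sp1 <- split_holdout(d, 0.5, seed = 4)
  sp2 <- split_holdout(d, 0.5, seed = 4)
  expect_identical(sp1$heldout$round1, sp2$heldout$round1)
  expect_equal(sum(sp1$train$round1$count) + sum(sp1$heldout$round1$count),
               sum(d$round1$count))
})

test_that("probe readers aggregate FASTA and tabular input identically", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "probes.fa")
  writeLines(c(">r1", "ACGTAC", ">r2", "ACGTAC", ">r3", "GGGTTT"), fa)
  p1 <- read_probes(fa)
  expect_equal(p1$count[p1$seq == "ACGTAC"], 2L)
  tw <- file.path(dir, "probes.txt")
  writeLines(c("ACGTAC\t2", "GGGTTT\t1"), tw)
  p2 <- read_probes(tw)
  expect_equal(p1[order(p1$seq), ], p2[order(p2$seq), ],
               ignore_attr = TRUE)
})
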