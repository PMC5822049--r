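## Shared fixture builders (everything is generated in code; no data files).

## RC-symmetric noise table.
random_sym_table <- function(k = 5, kind = "base-centered", seed = 1,
                             feature = "MGW") {
  tb <- withr::with_seed(seed, shape_table(rnorm(4^k), kind = kind,
                                           feature = feature))
  rc_symmetrize(tb)
}

## A planted shape-readout model plus its agnostic representation.
planted_pair <- function(k = 8, pos = 5, amp = -1, seed = 3,
                         base_sd = 0.5, table = NULL) {
  tb <- table %||% random_sym_table(seed = seed)
  sm <- fit_seq2shape(tb, "mono+di")
  prof <- numeric(k)
  prof[pos] <- amp
  b1 <- withr::with_seed(seed + 1, matrix(rnorm(4 * k, sd = base_sd), 4, k))
  srm <- shape_readout_model(beta1 = b1, profiles = list(MGW = prof),
                             shape_models = list(MGW = sm))
  list(srm = srm, agn = to_sequence_representation(srm), sm = sm, table = tb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random mono+di binding model.
random_agn <- function(k, seed = 1, scale1 = 0.6, scale2 = 0.3) {
  withr::with_seed(seed, agn_model(
    beta1 = matrix(rnorm(4 * k, sd = scale1), 4, k),
    beta2 = matrix(rnorm(16 * (k - 1), sd = scale2), 16, k - 1),
    beta0 = rnorm(1)))
}

## Brute-force enumeration score of every k-mer of a model.
enum_scores <- function(model) {
  score_model(model, all_kmers(model$k))
}
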