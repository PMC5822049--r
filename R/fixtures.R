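#' Specification of a synthetic study fixture
#'
#' One seeded specification drives every synthetic input: shape tables
#' with a controlled mono/di/higher-order variance decomposition, binding
#' models with planted shape readout, and two-round SELEX read sets.  A
#' single master seed fans out deterministically to per-component streams,
#' so adding one fixture never perturbs another.
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: pentamer tables whose mono/di/noise variance fractions are
#' 0.65/0.30/0.05 (the structure of the published sequence-to-shape
#' decomposition of the real tables); k = 8 footprints with base-readout
#' scoring matrices of scale 0.5 \code{-ddG/RT} and a planted minor-groove
#' sensitivity of -1 \code{RT} per unit shape; SELEX at L = 10 with
#' 2e5 reads per round, dimer bias of scale 0.1 and negligible
#' non-specific binding.
#'
#' @param seed Master seed.
#' @param table List: \code{k}, \code{kind}, variance fractions
#'   \code{frac_mono}, \code{frac_di}, \code{frac_noise} (nonnegative,
#'   sum <= 1).
#' @param binding List: footprint \code{k}, \code{base_sd} (scale of the
#'   base-readout scoring matrix), \code{shape} = named list of
#'   \code{list(position, amplitude)} planted sensitivities.
#' @param selex List: \code{L}, \code{n0}, \code{n1}, flanks,
#'   \code{bias_width}, \code{bias_sd}, \code{beta_ns}.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(seed = 1,
                         table = list(),
                         binding = list(),
                         selex = list()) {
  table <- utils::modifyList(
    list(k = 5, kind = "base-centered", frac_mono = 0.65, frac_di = 0.30,
         frac_noise = 0.05), table)
  binding <- utils::modifyList(
    list(k = 8, base_sd = 0.5,
         shape = list(MGW = list(position = 5, amplitude = -1))), binding)
  selex <- utils::modifyList(
    list(L = 10, n0 = 2e5, n1 = 2e5, left_flank = "GTCAG",
         right_flank = "CTGAC", bias_width = 2, bias_sd = 0.1,
         beta_ns = -10), selex)
  fr <- c(table$frac_mono, table$frac_di, table$frac_noise)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    stop("variance fractions must be nonnegative with sum <= 1")
  }
  structure(list(seed = seed, table = table, binding = binding,
                 selex = selex),
            class = "fixture_spec")
}

#' Synthesize a shape table with controlled variance decomposition
#'
#' Builds an RC-symmetric table as an exact variance-weighted sum of three
#' mutually orthogonal, unit-variance components inside the RC-symmetric
#' value subspace: a mononucleotide component, a dinucleotide component
#' orthogonalized against the mononucleotide span, and unstructured
#' "higher-order" noise orthogonalized against the mono+di span.  The
#' realized in-sample variance fractions therefore equal the requested
#' ones exactly.
#'
#' @param spec A \code{fixture_spec}.
#' @param feature Feature label for the table.
#' @return An RC-symmetric \code{shape_table} with unit total variance.
#' @export
make_table <- function(spec, feature = "synthetic-MGW") {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- spec$table$k
  kind <- spec$table$kind
  p <- rc_permutation(k)
  n <- 4^k
  sym <- function(v) (v + v[p]) / 2
  centre <- function(v) v - mean(v)
  unitv <- function(v) {
    s <- sqrt(mean(v^2))
    if (s < 1e-12) stop("degenerate fixture component")
    v / s
  }
  residual_of <- function(v, order) {
    tb <- shape_table(setNames(v, all_kmers(k)), kind = kind)
    v - predict_all_kmers(fit_seq2shape(tb, order))
  }
  with_seed(derive_seed(spec$seed, paste0("table-", feature)), {
    m <- kmer_base_matrix(k)
    g1 <- matrix(rnorm(4 * k), 4, k)
    t_mono <- numeric(n)
    for (i in seq_len(k)) t_mono <- t_mono + g1[m[, i], i]
    t_mono <- centre(sym(t_mono))
    g2 <- matrix(rnorm(16 * (k - 1)), 16, k - 1)
    t_di <- numeric(n)
    for (j in seq_len(k - 1)) t_di <- t_di + g2[(m[, j] - 1) * 4 + m[, j + 1], j]
    t_di <- centre(sym(t_di))
    t_di <- residual_of(t_di, "mono")
    t_noise <- centre(sym(rnorm(n)))
    t_noise <- residual_of(t_noise, "mono+di")
  })
  fr <- spec$table
  v <- sqrt(fr$frac_mono) * unitv(t_mono) +
    sqrt(fr$frac_di) * unitv(t_di) +
    sqrt(fr$frac_noise) * unitv(t_noise)
  shape_table(setNames(v, all_kmers(k)), kind = kind, feature = feature,
              units = "arbitrary")
}

#' Build a planted shape-readout binding model and its agnostic form
#'
#' Draws a base-readout scoring matrix, plants the specified
#' shape-sensitivity coefficients, and returns both the
#' \code{shape_readout_model} and its exact sequence-only
#' (mechanism-agnostic) representation, which scores identically on all
#' k-mers.
#'
#' @param spec A \code{fixture_spec}.
#' @param tables Named list of \code{shape_table}s covering the planted
#'   features (defaults to one \code{make_table} per feature).
#' @return A list with \code{srm} (shape_readout_model), \code{agn}
#'   (agn_model), \code{shape_models} (fitted mono+di seq2shape models)
#'   and \code{tables}.
#' @export
make_planted_model <- function(spec, tables = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- spec$binding$k
  plant <- spec$binding$shape
  if (is.null(tables)) {
    tables <- lapply(setNames(names(plant), names(plant)), function(f) {
      make_table(spec, feature = paste0("synthetic-", f))
    })
  }
  shape_models <- lapply(tables, fit_seq2shape, order = "mono+di")
  profiles <- list()
  for (f in names(plant)) {
    sm <- shape_models[[f]]
    npos <- if (sm$kind == "base-centered") k else k - 1
    prof <- numeric(npos)
    pos <- plant[[f]]$position
    interior <- profile_interior(k, sm$kind)
    if (!all(pos %in% interior)) {
      stop("planted position(s) for '", f, "' outside the interior ",
           paste(range(interior), collapse = ".."))
    }
    prof[pos] <- plant[[f]]$amplitude
    profiles[[f]] <- prof
  }
  b1 <- with_seed(derive_seed(spec$seed, "binding"),
                  matrix(rnorm(4 * k, sd = spec$binding$base_sd), 4, k))
  b1 <- gauge_fix_scoring(b1)
  srm <- shape_readout_model(beta1 = b1, profiles = profiles,
                             shape_models = shape_models)
  list(srm = srm, agn = to_sequence_representation(srm),
       shape_models = shape_models, tables = tables)
}

#' Build a global-null binding model (base readout plus dinucleotide noise)
#'
#' A mechanism-agnostic model with no planted shape readout: a random
#' scoring matrix plus random adjacent-dinucleotide terms unrelated to any
#' shape table, for calibrating the significance machinery under the null.
#'
#' @param spec A \code{fixture_spec}.
#' @param di_sd Scale of the dinucleotide noise terms.
#' @param stream Extra seed-stream label (vary to get independent models).
#' @return An \code{agn_model}.
#' @export
make_global_null_model <- function(spec, di_sd = 0.1, stream = "null") {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- spec$binding$k
  with_seed(derive_seed(spec$seed, paste0("global-", stream)), {
    b1 <- gauge_fix_scoring(matrix(rnorm(4 * k, sd = spec$binding$base_sd), 4, k))
    b2 <- matrix(rnorm(16 * (k - 1), sd = di_sd), 16, k - 1)
  })
  agn_model(beta1 = b1, beta2 = b2)
}

#' Simulate a SELEX dataset from a fixture specification
#'
#' Draws a dimer (or wider) sequencing-bias model of the specified scale
#' and delegates to \code{\link{simulate_selex}}.
#'
#' @param spec A \code{fixture_spec}.
#' @param sel A \code{selection_model} (e.g. built from
#'   \code{make_planted_model} components).
#' @return A list with \code{data} (\code{selex_dataset}) and \code{bias}
#'   (the generating \code{bias_model}).
#' @export
make_selex <- function(spec, sel) {
  stopifnot(inherits(spec, "fixture_spec"))
  sx <- spec$selex
  bias <- with_seed(derive_seed(spec$seed, "bias"),
                    bias_model(rnorm(4^sx$bias_width, sd = sx$bias_sd),
                               sx$bias_width))
  data <- simulate_selex(bias, sel, L = sx$L, n0 = sx$n0, n1 = sx$n1,
                         left_flank = sx$left_flank,
                         right_flank = sx$right_flank,
                         seed = derive_seed(spec$seed, "selex"))
  list(data = data, bias = bias)
}
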