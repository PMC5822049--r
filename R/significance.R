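#' Expected conditional variance of a shape table
#'
#' For every position pair (i, j) in the k-window, averages over the 16 (or
#' 4 when i == j) base assignments the variance of table values among
#' matching k-mers:
#' \deqn{C_{ij} = E_{c,d}\, Var_s[\phi(s) \mid s_i = c, s_j = d].}
#' Small \eqn{C_{ij}} relative to the total variance means the table
#' depends strongly on the bases at i and j.  Population variances and
#' exact enumeration are used.
#'
#' @param table A \code{shape_table}.
#' @return A symmetric k x k matrix of conditional variances (shape
#'   units squared).
#' @export
conditional_variance <- function(table) {
  stopifnot(inherits(table, "shape_table"))
  k <- table$k
  m <- kmer_base_matrix(k)
  v <- unname(table$values)
  C <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      g <- (m[, i] - 1L) * 4L + m[, j]
      n_g <- tabulate(g, 16)
      s1 <- s2 <- numeric(16)
      acc1 <- rowsum(v, g); acc2 <- rowsum(v^2, g)
      s1[as.integer(rownames(acc1))] <- acc1
      s2[as.integer(rownames(acc2))] <- acc2
      occ <- n_g > 0
      vars <- s2[occ] / n_g[occ] - (s1[occ] / n_g[occ])^2
      C[i, j] <- C[j, i] <- mean(vars)
    }
  }
  C
}

#' Complexity-matched random shape table
#'
#' Draws random mono- and dinucleotide sequence-to-shape coefficients from
#' the standard uniform distribution, reverse-complement symmetrizes, and
#' scales the per-position coefficient blocks by nonnegative factors
#' \eqn{\alpha_i} (tied across reverse-complement-mirrored positions) to
#' minimize \eqn{D = \sum_{i \le j} (C_{ij}(ref) - C_{ij}(random))^2},
#' matching the reference table's positional dependence structure.  Because
#' the candidate table is linear in the scaled blocks, each
#' \eqn{C_{ij}(\alpha)} is an exact quadratic form, making the matching
#' problem fast and its gradient analytic.
#'
#' @param reference A complete, RC-symmetric \code{shape_table}.
#' @param seed Integer seed.
#' @param retries Redraw budget if the scaling optimization fails.
#' @return An RC-symmetric \code{shape_table} with attributes
#'   \code{match_error} (relative, \eqn{\sqrt{D}/\|C(ref)\|}) and
#'   \code{alpha}.
#' @export
random_matched_table <- function(reference, seed = NULL, retries = 3) {
  stopifnot(inherits(reference, "shape_table"))
  if (!is_rc_symmetric(reference, tol = 1e-8)) {
    stop("reference table must be RC-symmetric")
  }
  k <- reference$k
  Cref <- conditional_variance(reference)
  m <- kmer_base_matrix(k)
  p <- rc_permutation(k)
  ## component value vectors (per position block), RC-symmetrized
  for (attempt in seq_len(retries)) {
    comps <- with_seed(if (is.null(seed)) NULL else seed + (attempt - 1),
                       draw_components(k, m, p))
    fit <- match_alpha(comps, Cref, m, k)
    if (!is.null(fit)) {
      vals <- drop(comps$V %*% fit$alpha_full)
      tab <- shape_table(setNames(vals, all_kmers(k)), kind = reference$kind,
                         feature = paste0(reference$feature, "-matched-null"),
                         units = reference$units)
      tab <- rc_symmetrize(tab)  # components already symmetric; idempotent
      attr(tab, "match_error") <- fit$rel_err
      attr(tab, "alpha") <- fit$alpha_full
      return(tab)
    }
  }
  stop("conditional-variance matching failed after ", retries, " draws")
}

## Draw U(0,1) gamma blocks and return symmetric per-block value vectors.
draw_components <- function(k, m, p) {
  n <- 4L^k
  V <- matrix(0, n, k + (k - 1))
  for (i in seq_len(k)) {
    g1 <- runif(4)
    v <- g1[m[, i]]
    V[, i] <- (v + v[p]) / 2
  }
  for (j in seq_len(k - 1)) {
    g2 <- runif(16)
    v <- g2[(m[, j] - 1L) * 4L + m[, j + 1L]]
    V[, k + j] <- (v + v[p]) / 2
  }
  list(V = V)
}

## Optimize nonnegative RC-tied block scales to match the reference C.
match_alpha <- function(comps, Cref, m, k) {
  V <- comps$V
  ncomp <- ncol(V)
  ## tie mono position i with k+1-i, step j with k-j
  tie <- c(pmin(seq_len(k), k + 1 - seq_len(k)),
           k + pmin(seq_len(k - 1), (k - 1):1))
  groups <- unique(tie)
  G <- outer(tie, groups, `==`) * 1          # ncomp x nfree expansion
  pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  ## quadratic forms: C_ij(alpha) = alpha' S_ij alpha
  S <- vector("list", nrow(pairs))
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    g <- (m[, i] - 1L) * 4L + m[, j]
    n_g <- tabulate(g, 16)
    occ <- which(n_g > 0)
    Sq <- matrix(0, ncomp, ncomp)
    means <- rowsum(V, g)[as.character(occ), , drop = FALSE] / n_g[occ]
    ## within-group covariance averaged over groups:
    ## (1/G) sum_g [ E_g(Va Vb) - E_g(Va) E_g(Vb) ]
    for (a in seq_len(ncomp)) {
      pa <- rowsum(V * V[, a], g)[as.character(occ), , drop = FALSE] / n_g[occ]
      Sq[a, ] <- colMeans(pa - means * means[, a])
    }
    S[[q]] <- crossprod(G, ((Sq + t(Sq)) / 2) %*% G)
  }
  cref <- Cref[pairs]
  nfree <- length(groups)
  objfn <- function(a) {
    qv <- vapply(S, function(Sq) drop(a %*% Sq %*% a), 0)
    sum((cref - qv)^2)
  }
  objgr <- function(a) {
    qv <- vapply(S, function(Sq) drop(a %*% Sq %*% a), 0)
    gr <- numeric(nfree)
    for (q in seq_along(S)) {
      gr <- gr - 4 * (cref[q] - qv[q]) * drop(S[[q]] %*% a)
    }
    gr
  }
  a0 <- rep(sqrt(max(mean(cref), 1e-12) / max(mean(vapply(S, sum, 0)), 1e-12)),
            nfree)
  opt <- tryCatch(
    optim(a0, objfn, objgr, method = "L-BFGS-B", lower = 0,
          control = list(maxit = 500, factr = 1e7)),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  qv <- vapply(S, function(Sq) drop(opt$par %*% Sq %*% opt$par), 0)
  rel_err <- sqrt(sum((cref - qv)^2)) / max(sqrt(sum(cref^2)), 1e-300)
  list(alpha_full = drop(G %*% opt$par), alpha = opt$par, rel_err = rel_err)
}

#' Null ensemble of shape-sensitivity profiles
#'
#' Repeats the penalized projection of a mechanism-agnostic model with
#' complexity-matched random shape tables in place of the real ones,
#' collecting the profile each random table yields.  The resulting
#' per-position percentile bands (2.5, 25, 75, 97.5) quantify how large a
#' sensitivity coefficient arises by chance from a random sequence feature
#' of matched complexity.
#'
#' @param agn An \code{agn_model}.
#' @param reference_tables Named list of RC-symmetric \code{shape_table}s
#'   (the tables used for the observed projection).
#' @param cfg The \code{\link{projection_config}} used for the observed
#'   fit (must be identical for the null to be valid).
#' @param N Ensemble size (scaled-down default 200; published analyses use
#'   thousands).
#' @param seed Integer seed.
#' @param warm_start Reuse each fit's solution to start the next
#'   (accelerates the sweep; the penalized optimum is unchanged).
#' @param null_models Optional precomputed list (length N) of named lists
#'   of \code{seq2shape_model}s, as returned by
#'   \code{\link{make_null_models}}.  Useful when many binding models are
#'   screened against one set of matched random tables.
#' @return A \code{null_ensemble}: per-feature N x k profile matrices and
#'   percentile bands.
#' @export
null_bands <- function(agn, reference_tables, cfg = projection_config(),
                       N = 200, seed = 1, warm_start = TRUE,
                       null_models = NULL) {
  if (is.null(null_models)) {
    null_models <- make_null_models(reference_tables, N = N, seed = seed)
  }
  N <- length(null_models)
  if (N < 1) stop("empty ensemble: N must be at least 1")
  stopifnot(is.list(reference_tables), !is.null(names(reference_tables)))
  feats <- names(reference_tables)
  profs <- lapply(reference_tables, function(tb) {
    npos <- if (tb$kind == "base-centered") agn$k else agn$k - 1
    matrix(NA_real_, N, npos)
  })
  start <- NULL
  for (n in seq_len(N)) {
    res <- project(agn, null_models[[n]], cfg, start = if (warm_start) start)
    for (f in feats) profs[[f]][n, ] <- res$model$profiles[[f]]
    if (warm_start) start <- result_theta(res)
  }
  bands <- lapply(profs, function(P) {
    apply(P, 2, quantile, probs = c(0.025, 0.25, 0.75, 0.975))
  })
  structure(list(profiles = profs, bands = bands, N = N, cfg = cfg,
                 k = agn$k),
            class = "null_ensemble")
}

#' Generate complexity-matched null sequence-to-shape models
#'
#' Draws N complexity-matched random tables per reference feature (see
#' \code{\link{random_matched_table}}) and fits the mono+di
#' sequence-to-shape model to each, ready for repeated projections.
#'
#' @inheritParams null_bands
#' @return A list of length N; each element is a named list of
#'   \code{seq2shape_model}s.
#' @export
make_null_models <- function(reference_tables, N = 200, seed = 1) {
  if (N < 1) stop("empty ensemble: N must be at least 1")
  lapply(seq_len(N), function(n) {
    models <- list()
    for (f in names(reference_tables)) {
      tb <- random_matched_table(reference_tables[[f]],
                                 seed = derive_seed(seed, paste0(f, "-", n)))
      models[[f]] <- fit_seq2shape(tb, "mono+di")
    }
    models
  })
}

## Reconstruct the free-parameter vector of a projection result (for warm
## starts).
result_theta <- function(res) {
  th <- c(if (res$config$loss == "affinity") res$model$beta0,
          as.vector(res$model$beta1))
  for (f in names(res$model$profiles)) {
    sm <- res$model$shape_models[[f]]
    interior <- profile_interior(res$model$k, sm$kind)
    th <- c(th, res$model$profiles[[f]][interior])
  }
  th
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: N=%d, features: %s\n", x$N,
              paste(names(x$profiles), collapse = ", ")))
  invisible(x)
}

#' Per-position empirical significance of shape readout
#'
#' Two-sided add-one empirical p-values per interior binding-site position,
#' \deqn{p_i = (1 + \#\{n : |\beta^{null}_{n,i}| \ge |\beta^{obs}_i|\}) / (N+1),}
#' followed by Benjamini--Hochberg step-up correction across the interior
#' positions within each feature.
#'
#' @param observed A \code{projection_result} (or named list of profiles).
#' @param ensemble A \code{null_ensemble} built with the same
#'   configuration.
#' @return A data.frame with columns \code{feature}, \code{position},
#'   \code{beta}, \code{p}, \code{q}.
#' @export
position_fdr <- function(observed, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  profiles <- if (inherits(observed, "projection_result")) {
    observed$model$profiles
  } else observed
  kinds <- if (inherits(observed, "projection_result")) {
    lapply(observed$model$shape_models, `[[`, "kind")
  } else {
    lapply(profiles, function(pr) {
      if (length(pr) == ensemble$k) "base-centered" else "step-centered"
    })
  }
  out <- NULL
  for (f in names(profiles)) {
    if (!f %in% names(ensemble$profiles)) next
    interior <- profile_interior(ensemble$k, kinds[[f]])
    obs <- profiles[[f]][interior]
    nulls <- ensemble$profiles[[f]][, interior, drop = FALSE]
    N <- nrow(nulls)
    pvals <- vapply(seq_along(interior), function(ii) {
      (1 + sum(abs(nulls[, ii]) >= abs(obs[ii]))) / (N + 1)
    }, 0)
    q <- p.adjust(pvals, method = "BH")
    out <- rbind(out, data.frame(feature = f, position = interior,
                                 beta = obs, p = pvals, q = q))
  }
  out
}
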