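#' SELEX dataset container
#'
#' Round-zero (input library) and round-one (bound fraction) probe counts
#' for a SELEX experiment with an L-bp variable region between fixed
#' flanking adapters.
#'
#' @param round0,round1 Data frames with columns \code{seq} (variable
#'   region, ACGT) and \code{count} (positive integers), or named count
#'   vectors.
#' @param left_flank,right_flank Fixed flank sequences.
#' @return An object of class \code{selex_dataset}.
#' @export
selex_dataset <- function(round0, round1, left_flank = "ACGTA",
                          right_flank = "TACGT") {
  fix <- function(x) {
    if (!is.data.frame(x)) x <- data.frame(seq = names(x), count = as.vector(x))
    stopifnot(all(c("seq", "count") %in% names(x)))
    x$seq <- as.character(x$seq)
    x$count <- as.integer(x$count)
    if (any(x$count <= 0)) stop("counts must be positive integers")
    if (any(grepl("[^ACGT]", x$seq))) stop("non-ACGT character in probe sequence")
    x <- stats::aggregate(count ~ seq, x, sum)
    x
  }
  round0 <- fix(round0); round1 <- fix(round1)
  L <- unique(nchar(c(round0$seq, round1$seq)))
  if (length(L) != 1) stop("all variable regions must have equal length")
  structure(list(L = as.integer(L), left_flank = left_flank,
                 right_flank = right_flank, round0 = round0, round1 = round1),
            class = "selex_dataset")
}

#' @export
print.selex_dataset <- function(x, ...) {
  cat(sprintf("selex_dataset: L=%d, flanks %s|%s, round0 %d reads (%d unique), round1 %d reads (%d unique)\n",
              x$L, x$left_flank, x$right_flank, sum(x$round0$count),
              nrow(x$round0), sum(x$round1$count), nrow(x$round1)))
  invisible(x)
}

#' Read SELEX probes from FASTA/FASTQ or two-column text
#'
#' FASTA/FASTQ records are aggregated into (sequence, count) pairs; plain
#' text files must have \code{SEQ<TAB>COUNT} rows.
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"fasta"},
#'   \code{"fastq"} or \code{"table"}.
#' @return A data frame with columns \code{seq}, \code{count}.
#' @export
read_probes <- function(path, format = c("auto", "fasta", "fastq", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta)$", path)) "fasta"
    else if (grepl("\\.(fq|fastq)$", path)) "fastq"
    else "table"
  }
  if (format %in% c("fasta", "fastq")) {
    ss <- Biostrings::readDNAStringSet(path, format = format)
    tab <- table(as.character(ss))
    return(data.frame(seq = names(tab), count = as.integer(tab)))
  }
  df <- read.table(path, header = FALSE, col.names = c("seq", "count"),
                   colClasses = c("character", "integer"))
  stats::aggregate(count ~ seq, df, sum)
}

#' Round-zero sequencing bias model
#'
#' Probe weights \eqn{w_i = \exp(\sum_\phi \beta_\phi X_{i\phi})} where
#' \eqn{X_{i\phi}} counts occurrences of each \code{k_bias}-mer in the full
#' probe (flanks included).
#'
#' @param coef Numeric vector of length \code{4^k_bias} (lexicographic
#'   k-mer order, or named).
#' @param k_bias Bias feature width (1..4 at desk scale).
#' @return An object of class \code{bias_model}.
#' @export
bias_model <- function(coef, k_bias = round(log(length(coef), 4))) {
  stopifnot(length(coef) == 4^k_bias)
  if (!is.null(names(coef))) coef <- coef[all_kmers(k_bias)]
  structure(list(k_bias = as.integer(k_bias),
                 coef = setNames(as.numeric(coef), all_kmers(k_bias))),
            class = "bias_model")
}

#' Selection (binding) model for SELEX round one
#'
#' Probe selection \eqn{\kappa_i = e^{\beta_{NS}} + \sum_v e^{score_{iv}}}
#' summed over all footprint placements v (offsets x both strands) within
#' the full probe.  The per-view score has mononucleotide terms, optional
#' adjacent-dinucleotide terms, and optional direct shape-regression terms:
#' position-specific sensitivities multiplying mean-centered k-mer shape
#' table values evaluated in probe context (windows without complete
#' context contribute zero).
#'
#' @param beta1 4 x k scoring matrix.
#' @param beta2 Optional 16 x (k-1) dinucleotide matrix.
#' @param shape_sens Optional named list of sensitivity profiles (length k
#'   for base-centered features, k-1 for step-centered).
#' @param shape_tables Named list of RC-symmetric \code{shape_table}s
#'   matching \code{shape_sens}.
#' @param beta_ns Log non-specific binding weight.
#' @return An object of class \code{selection_model}.
#' @export
selection_model <- function(beta1, beta2 = NULL, shape_sens = NULL,
                            shape_tables = NULL, beta_ns = -10) {
  beta1 <- as.matrix(beta1)
  k <- ncol(beta1)
  stopifnot(nrow(beta1) == 4)
  if (!is.null(beta2)) stopifnot(nrow(beta2) == 16, ncol(beta2) == k - 1)
  if (!is.null(shape_sens)) {
    stopifnot(!is.null(shape_tables),
              all(names(shape_sens) %in% names(shape_tables)))
    for (f in names(shape_sens)) {
      tb <- shape_tables[[f]]
      if (!is_rc_symmetric(tb, tol = 1e-8)) {
        stop("shape table '", f, "' must be RC-symmetric")
      }
      want <- if (tb$kind == "base-centered") k else k - 1
      stopifnot(length(shape_sens[[f]]) == want)
    }
    shape_tables <- shape_tables[names(shape_sens)]
  }
  rownames(beta1) <- DNA_BASES
  structure(list(k = as.integer(k), beta_ns = as.numeric(beta_ns),
                 beta1 = beta1, beta2 = beta2, shape_sens = shape_sens,
                 shape_tables = shape_tables),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("selection_model: k=%d, beta_ns=%.3g, di:%s, shape:%s\n",
              x$k, x$beta_ns, !is.null(x$beta2),
              if (is.null(x$shape_sens)) "none"
              else paste(names(x$shape_sens), collapse = ",")))
  invisible(x)
}

## ---- probe encoding and vectorized view scoring -------------------------

## Full-probe integer matrix (n x P) for variable-region sequences.
full_probe_matrix <- function(seqs, left_flank, right_flank) {
  var <- base_matrix_from_kmers(seqs)
  lf <- drop(base_matrix_from_kmers(left_flank))
  rf <- drop(base_matrix_from_kmers(right_flank))
  n <- nrow(var)
  cbind(matrix(rep(lf, each = n), n), var, matrix(rep(rf, each = n), n))
}

## Mean-centered value lookup for shape predictors.
centered_values <- function(table) {
  unname(table$values) - mean(table$values)
}

## Equivalent plus-strand parameters for minus-strand views.
flip_selection <- function(sel) {
  k <- sel$k
  b1 <- sel$beta1[4:1, k:1, drop = FALSE]
  b2 <- sel$beta2
  if (!is.null(b2) && k >= 2) {
    ## beta2'[code(c,d), j] = beta2[code(comp d, comp c), k - j]
    idx <- integer(16)
    for (c in 1:4) for (d in 1:4) {
      idx[(c - 1) * 4 + d] <- (4 - d) * 4 + (5 - c)
    }
    b2 <- sel$beta2[idx, (k - 1):1, drop = FALSE]
  }
  ss <- sel$shape_sens
  if (!is.null(ss)) {
    for (f in names(ss)) {
      ss[[f]] <- rev(ss[[f]])
    }
  }
  list(beta1 = b1, beta2 = b2, shape_sens = ss)
}

## Score every view (offset x strand) for each probe row; returns the
## n x n_views matrix of view scores.  `shape_cache` optionally carries the
## per-probe centered shape value profiles to avoid recomputation.
view_scores <- function(probe_mat, sel, shape_cache = NULL) {
  n <- nrow(probe_mat); P <- ncol(probe_mat); k <- sel$k
  noff <- P - k + 1
  if (noff < 1) stop("probe too short to hold one footprint view")
  flip <- flip_selection(sel)
  shape_profiles <- shape_cache %||% probe_shape_profiles(probe_mat, sel)
  out <- matrix(0, n, 2 * noff)
  for (strand in 1:2) {
    b1 <- if (strand == 1) sel$beta1 else flip$beta1
    b2 <- if (strand == 1) sel$beta2 else flip$beta2
    ss <- if (strand == 1) sel$shape_sens else flip$shape_sens
    for (o in seq_len(noff)) {
      s <- numeric(n)
      for (j in seq_len(k)) s <- s + b1[cbind(probe_mat[, o + j - 1], j)]
      if (!is.null(b2)) {
        for (j in seq_len(k - 1)) {
          code <- (probe_mat[, o + j - 1] - 1) * 4 + probe_mat[, o + j]
          s <- s + b2[cbind(code, j)]
        }
      }
      if (!is.null(ss)) {
        for (f in names(ss)) {
          prof <- shape_profiles[[f]]   # n x P (or P-1) centered values, 0 outside
          sens <- ss[[f]]
          for (j in seq_along(sens)) {
            if (sens[j] == 0) next
            s <- s + sens[j] * prof[, o + j - 1]
          }
        }
      }
      out[, (strand - 1) * noff + o] <- s
    }
  }
  out
}

## Centered shape values along each probe (positions or steps); windows
## extending past the probe ends are set to 0 (the centered-table mean).
probe_shape_profiles <- function(probe_mat, sel) {
  if (is.null(sel$shape_sens)) return(NULL)
  n <- nrow(probe_mat); P <- ncol(probe_mat)
  out <- list()
  for (f in names(sel$shape_sens)) {
    tb <- sel$shape_tables[[f]]
    vals <- centered_values(tb)
    kw <- tb$k
    prof <- matrix(0, n, if (tb$kind == "base-centered") P else P - 1)
    nw <- P - kw + 1
    idx <- matrix(1L, n, nw)
    for (w in seq_len(kw)) {
      idx <- idx + (probe_mat[, seq_len(nw) + w - 1, drop = FALSE] - 1L) * 4L^(kw - w)
    }
    center <- if (tb$kind == "base-centered") (kw + 1) / 2 else kw / 2
    prof[, seq_len(nw) + center - 1] <- matrix(vals[idx], n, nw)
    out[[f]] <- prof
  }
  out
}

## kappa_i for each probe row.
probe_kappa <- function(probe_mat, sel, shape_cache = NULL) {
  vs <- view_scores(probe_mat, sel, shape_cache)
  exp(sel$beta_ns) + rowSums(exp(vs))
}

## log w_i under a bias model for each probe row.
probe_log_w <- function(probe_mat, bias) {
  kb <- bias$k_bias
  P <- ncol(probe_mat)
  lw <- numeric(nrow(probe_mat))
  for (t in kb:P) {
    idx <- rep(1L, nrow(probe_mat))
    for (i in seq_len(kb)) idx <- idx + (probe_mat[, t - kb + i] - 1L) * 4L^(kb - i)
    lw <- lw + bias$coef[idx]
  }
  lw
}

## ---- transfer-matrix DP over the probe distribution ---------------------

## General clamped forward/backward DP over full probes of length P with
## fixed flank bases and free variable bases.  The state is the last m
## bases.  `factor_fun(t, b)` returns the per-state log factor fired when
## base b completes position t (vector over 4^m states, or a scalar 0).
## Returns log of the total weighted sum and, if requested, the forward and
## backward tables for posterior computation.
probe_dp <- function(allowed, m, factor_fun, keep_tables = FALSE,
                     clamp = NULL) {
  P <- length(allowed)
  ns <- 4L^m
  nrest <- 4L^(m - 1)
  f <- rep(-Inf, ns)
  f[1] <- 0                      # virtual all-A context; never read by factors
  fwd <- if (keep_tables) matrix(NA_real_, ns, P + 1) else NULL
  if (keep_tables) fwd[, 1] <- f
  for (t in seq_len(P)) {
    bs <- if (!is.null(clamp) && !is.na(clamp[t])) clamp[t] else allowed[[t]]
    cols <- matrix(-Inf, nrest, 4)
    newf <- rep(-Inf, ns)
    for (b in bs) {
      tmp <- f + factor_fun(t, b)
      M <- matrix(tmp, nrest, 4)          # [rest, oldest]
      mx <- pmax(M[, 1], M[, 2], M[, 3], M[, 4])
      g <- mx + log(exp(M[, 1] - mx) + exp(M[, 2] - mx) +
                    exp(M[, 3] - mx) + exp(M[, 4] - mx))
      g[!is.finite(mx)] <- -Inf
      ## new state = rest*4 + (b-1): rows of a 4 x nrest layout
      nm <- matrix(newf, 4, nrest)
      nm[b, ] <- g
      newf <- as.vector(nm)
    }
    f <- newf
    if (keep_tables) fwd[, t + 1] <- f
  }
  mx <- max(f)
  logZ <- if (is.finite(mx)) mx + log(sum(exp(f - mx))) else -Inf
  out <- list(logZ = logZ)
  if (keep_tables) {
    bwd <- matrix(NA_real_, ns, P + 1)
    bwd[, P + 1] <- 0
    for (t in P:1) {
      bs <- if (!is.null(clamp) && !is.na(clamp[t])) clamp[t] else allowed[[t]]
      acc <- rep(-Inf, ns)
      bnext <- bwd[, t + 1]
      bn <- matrix(bnext, 4, nrest)       # [newbase, rest]
      for (b in bs) {
        lf <- factor_fun(t, b)
        ## bwd contribution: bnext at state rest*4+(b-1), replicated over oldest
        contrib <- rep(bn[b, ], times = 4) + lf
        acc <- pmax2_lse(acc, contrib)
      }
      bwd[, t] <- acc
    }
    out$fwd <- fwd
    out$bwd <- bwd
  }
  out
}

## elementwise log(exp(a) + exp(b)) tolerating -Inf
pmax2_lse <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[!is.finite(m)] <- -Inf
  r
}

## Factor closure for bias terms only.
bias_factor <- function(bias, m) {
  kb <- bias$k_bias
  coef <- unname(bias$coef)
  ns <- 4L^m
  s0 <- 0:(ns - 1)
  pre <- s0 %% 4L^(kb - 1)                # last kb-1 bases of the state
  function(t, b) {
    if (t < kb) return(0)
    coef[pre * 4L + b]
  }
}

## Combined factor closure: bias plus one view's binding terms.
## view = list(o, strand-resolved beta1/beta2/shape_sens); tables carries
## centered value vectors + kinds.
view_factor <- function(bias, m, view, k, tables) {
  bf <- bias_factor(bias, m)
  ns <- 4L^m
  s0 <- 0:(ns - 1)
  last1 <- s0 %% 4L                        # previous base
  pre4 <- if (m >= 4) s0 %% 256L else NULL # last 4 bases (for pentamers)
  pre3 <- if (m >= 3) s0 %% 64L else NULL  # last 3 bases (for tetramers)
  o <- view$o
  function(t, b) {
    lf <- bf(t, b)
    j <- t - o + 1                         # view coordinate of position t
    if (j >= 1 && j <= k) {
      lf <- lf + view$beta1[b, j]
    }
    if (!is.null(view$beta2) && j >= 2 && j <= k) {
      lf <- lf + view$beta2[last1 * 4L + b, j - 1]
    }
    if (!is.null(view$shape_sens)) {
      for (f in names(view$shape_sens)) {
        tb <- tables[[f]]
        if (tb$kind == "base-centered") {
          jj <- (t - 2) - o + 1            # pentamer ends at t, centered t-2
          if (t >= 5 && jj >= 1 && jj <= k && view$shape_sens[[f]][jj] != 0) {
            lf <- lf + view$shape_sens[[f]][jj] * tb$cvals[pre4 * 4L + b]
          }
        } else {
          jj <- (t - 2) - o + 1            # tetramer ends at t, step t-2:t-1
          if (t >= 4 && jj >= 1 && jj <= k - 1 && view$shape_sens[[f]][jj] != 0) {
            lf <- lf + view$shape_sens[[f]][jj] * tb$cvals[pre3 * 4L + b]
          }
        }
      }
    }
    lf
  }
}

## Structural description shared by Z and expected-count computations.
selex_geometry <- function(L, left_flank, right_flank, k) {
  lf <- drop(base_matrix_from_kmers(left_flank))
  rf <- drop(base_matrix_from_kmers(right_flank))
  P <- length(lf) + L + length(rf)
  allowed <- vector("list", P)
  for (t in seq_len(P)) {
    allowed[[t]] <- if (t <= length(lf)) lf[t]
    else if (t <= length(lf) + L) 1:4
    else rf[t - length(lf) - L]
  }
  list(P = P, allowed = allowed, noff = P - k + 1,
       var_range = length(lf) + seq_len(L))
}

## All view parameter sets (offset x strand) for a selection model.
view_list <- function(sel, noff) {
  flip <- flip_selection(sel)
  views <- list()
  for (strand in 1:2) {
    b1 <- if (strand == 1) sel$beta1 else flip$beta1
    b2 <- if (strand == 1) sel$beta2 else flip$beta2
    ss <- if (strand == 1) sel$shape_sens else flip$shape_sens
    for (o in seq_len(noff)) {
      views[[length(views) + 1]] <- list(o = o, strand = strand, beta1 = b1,
                                         beta2 = b2, shape_sens = ss)
    }
  }
  views
}

## Context length m needed by the DP.
context_m <- function(bias, sel) {
  m <- max(bias$k_bias - 1, 1)
  if (!is.null(sel) && !is.null(sel$shape_sens)) {
    for (f in names(sel$shape_sens)) {
      m <- max(m, if (sel$shape_tables[[f]]$kind == "base-centered") 4 else 3)
    }
  }
  m
}

## Attach centered value vectors to tables once.
with_cvals <- function(tables) {
  lapply(tables, function(tb) { tb$cvals <- centered_values(tb); tb })
}

## log Z0 = log sum_i w_i over all probes.
selex_log_z0 <- function(L, left_flank, right_flank, bias) {
  m <- max(bias$k_bias - 1, 1)
  geo <- selex_geometry(L, left_flank, right_flank, k = 1)
  probe_dp(geo$allowed, m, bias_factor(bias, m))$logZ
}

## log of Z1 = sum_i w_i kappa_i, plus per-view log T_v.
selex_log_z1 <- function(L, left_flank, right_flank, bias, sel,
                         keep_tables = FALSE) {
  m <- context_m(bias, sel)
  geo <- selex_geometry(L, left_flank, right_flank, sel$k)
  tables <- with_cvals(sel$shape_tables)
  views <- view_list(sel, geo$noff)
  lz0 <- probe_dp(geo$allowed, m, bias_factor(bias, m))$logZ
  res <- lapply(views, function(v) {
    probe_dp(geo$allowed, m, view_factor(bias, m, v, sel$k, tables),
             keep_tables = keep_tables)
  })
  logT <- vapply(res, `[[`, 0, "logZ")
  logZ1 <- logsumexp(c(sel$beta_ns + lz0, logT))
  list(logZ1 = logZ1, log_z0 = lz0, logT = logT, views = views,
       dp = if (keep_tables) res else NULL, geo = geo, m = m,
       tables = tables)
}

## ---- gradient helpers ---------------------------------------------------

## Posterior over (state, base) at position t of one view DP; returns the
## probability vector over states for each allowed base (list indexed by b).
dp_posterior <- function(dpv, t, allowed_t, factor_fun, logT, nrest) {
  post <- vector("list", 4)
  fw <- dpv$fwd[, t]
  bn <- matrix(dpv$bwd[, t + 1], 4, nrest)   # [newbase, rest]
  for (b in allowed_t) {
    lp <- fw + factor_fun(t, b) + rep(bn[b, ], times = 4) - logT
    post[[b]] <- exp(lp)
  }
  post
}

## Expected feature vector (flattened selection parameters) under one
## view's tilted probe distribution.
view_expected_features <- function(dpv, view, geo, bias, m, k, tables,
                                   logT, has_di, shape_names) {
  ff <- view_factor(bias, m, view, k, tables)
  nrest <- 4L^(m - 1)
  ns <- 4L^m
  s0 <- 0:(ns - 1)
  last1 <- s0 %% 4L
  pre4 <- if (m >= 4) s0 %% 256L else NULL
  pre3 <- if (m >= 3) s0 %% 64L else NULL
  e1 <- matrix(0, 4, k)
  e2 <- if (has_di) matrix(0, 16, k - 1) else NULL
  es <- if (length(shape_names)) {
    lapply(tables[shape_names], function(tb) {
      numeric(if (tb$kind == "base-centered") k else k - 1)
    })
  } else NULL
  o <- view$o
  trange <- max(1, o - 4):min(geo$P, o + k - 1 + 4)
  for (t in trange) {
    at <- geo$allowed[[t]]
    post <- dp_posterior(dpv, t, at, ff, logT, nrest)
    j <- t - o + 1
    for (b in at) {
      pb <- post[[b]]
      if (j >= 1 && j <= k) e1[b, j] <- e1[b, j] + sum(pb)
      if (has_di && j >= 2 && j <= k) {
        ## group posterior mass by previous base (all 4 residues occur)
        sums <- rowsum(pb, last1, reorder = TRUE)
        e2[(0:3) * 4L + b, j - 1] <- e2[(0:3) * 4L + b, j - 1] + drop(sums)
      }
      for (f in shape_names) {
        tb <- tables[[f]]
        if (tb$kind == "base-centered") {
          jj <- (t - 2) - o + 1
          if (t >= 5 && jj >= 1 && jj <= k) {
            es[[f]][jj] <- es[[f]][jj] + sum(pb * tb$cvals[pre4 * 4L + b])
          }
        } else {
          jj <- (t - 2) - o + 1
          if (t >= 4 && jj >= 1 && jj <= k - 1) {
            es[[f]][jj] <- es[[f]][jj] + sum(pb * tb$cvals[pre3 * 4L + b])
          }
        }
      }
    }
  }
  list(e1 = e1, e2 = e2, es = es)
}

## ---- bias fitting -------------------------------------------------------

#' Fit the round-zero sequencing bias model
#'
#' Maximizes the round-zero multinomial log-likelihood over the
#' \code{4^k_bias} bias coefficients, with the partition function and its
#' gradient computed by the transfer-matrix DP over the probe distribution.
#' The fitted coefficients are gauge-fixed to zero mean (every probe has
#' the same number of windows, so a constant shift is a likelihood
#' invariance).
#'
#' @param data A \code{selex_dataset} (round-zero records are used).
#' @param k_bias Bias feature width (1..4).
#' @param maxit,factr Optimizer controls.
#' @return A \code{bias_model} with attributes \code{loglik} (per read) and
#'   \code{convergence}.
#' @export
fit_bias <- function(data, k_bias = 2, maxit = 300, factr = 1e7) {
  stopifnot(inherits(data, "selex_dataset"), k_bias >= 1, k_bias <= 4)
  pm <- full_probe_matrix(data$round0$seq, data$left_flank, data$right_flank)
  cts <- data$round0$count
  n <- sum(cts)
  P <- ncol(pm)
  nf <- 4L^k_bias
  ## observed total k_bias-mer counts, weighted by read counts
  Tobs <- numeric(nf)
  for (t in k_bias:P) {
    idx <- rep(1L, nrow(pm))
    for (i in seq_len(k_bias)) idx <- idx + (pm[, t - k_bias + i] - 1L) * 4L^(k_bias - i)
    acc <- rowsum(cts, idx)
    Tobs[as.integer(rownames(acc))] <- Tobs[as.integer(rownames(acc))] + acc[, 1]
  }
  m <- max(k_bias - 1, 1)
  geo <- selex_geometry(data$L, data$left_flank, data$right_flank, k = 1)
  ns <- 4L^m
  s0 <- 0:(ns - 1)
  pre <- s0 %% 4L^(k_bias - 1)
  nrest <- 4L^(m - 1)
  negll <- function(coef) {
    b <- bias_model(coef, k_bias)
    lz <- probe_dp(geo$allowed, m, bias_factor(b, m))$logZ
    -(sum(Tobs * coef) - n * lz) / n
  }
  grad <- function(coef) {
    b <- bias_model(coef, k_bias)
    ff <- bias_factor(b, m)
    dp <- probe_dp(geo$allowed, m, ff, keep_tables = TRUE)
    E <- numeric(nf)
    for (t in k_bias:P) {
      at <- geo$allowed[[t]]
      post <- dp_posterior(dp, t, at, ff, dp$logZ, nrest)
      for (bb in at) {
        acc <- rowsum(post[[bb]], pre, reorder = TRUE)
        E[(0:(4L^(k_bias - 1) - 1)) * 4L + bb] <-
          E[(0:(4L^(k_bias - 1) - 1)) * 4L + bb] + drop(acc)
      }
    }
    -(Tobs / n - E)
  }
  opt <- optim(numeric(nf), negll, grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = factr))
  if (opt$convergence != 0) {
    gn <- sqrt(sum(grad(opt$par)^2))
    warning("bias fit did not fully converge (code ", opt$convergence,
            ", |grad| = ", format(gn, digits = 3), ")")
  }
  out <- bias_model(opt$par - mean(opt$par), k_bias)
  attr(out, "loglik") <- -opt$value
  attr(out, "convergence") <- opt$convergence
  out
}

## ---- selection fitting --------------------------------------------------

## Flip a full gradient/parameter list to the opposite strand coordinates
## (an involution matching flip_selection).
flip_blocks <- function(b1, b2, ss, k) {
  idx <- integer(16)
  for (c in 1:4) for (d in 1:4) idx[(c - 1) * 4 + d] <- (4 - d) * 4 + (5 - c)
  list(beta1 = b1[4:1, k:1, drop = FALSE],
       beta2 = if (!is.null(b2)) b2[idx, (k - 1):1, drop = FALSE],
       shape_sens = if (!is.null(ss)) lapply(ss, rev))
}

#' Fit the round-one selection model
#'
#' Maximizes the round-one multinomial log-likelihood over the non-specific
#' term and the binding-model parameters (mononucleotide scoring matrix,
#' optionally adjacent-dinucleotide terms, optionally direct
#' shape-regression sensitivities), using the analytic gradient.  The
#' partition function \eqn{Z_1 = \sum_i w_i \kappa_i} over all \code{4^L}
#' probes and its gradient are computed by clamped transfer-matrix DP; the
#' observed-probe terms are computed by vectorized view scoring.
#' Initialization is deterministic (zeros; \code{beta_ns} at a small log
#' constant), and imposing \code{rc_symmetric} keeps every iterate
#' reverse-complement symmetric by gradient projection (the view set is
#' strand-symmetric, so the objective is invariant under parameter
#' flipping).
#'
#' @param data A \code{selex_dataset}.
#' @param bias A fitted \code{bias_model}.
#' @param k Footprint length.
#' @param features \code{"mono"}, \code{"mono+di"} or \code{"mono+shape"}.
#' @param shape_tables Named list of \code{shape_table}s (required for
#'   \code{"mono+shape"}).
#' @param rc_symmetric Impose reverse-complement symmetry (homodimers).
#' @param beta_ns_init Initial log non-specific weight.
#' @param init_sd Scale of the tiny seed-controlled random initialization
#'   of the binding parameters.  The likelihood is exactly invariant under
#'   strand-flipping the parameters, so a symmetric start (all zeros)
#'   would confine the optimizer to the flip-symmetric saddle; the
#'   perturbation breaks that symmetry deterministically.  Ignored when
#'   \code{rc_symmetric} (the symmetric subspace is then the target).
#' @param seed Seed for the initialization perturbation.
#' @param maxit,factr Optimizer controls.
#' @return A \code{selection_model} with attributes \code{loglik} (per
#'   read) and \code{convergence}.
#' @export
fit_selection <- function(data, bias, k,
                          features = c("mono", "mono+di", "mono+shape"),
                          shape_tables = NULL, rc_symmetric = FALSE,
                          beta_ns_init = -10, init_sd = 1e-2, seed = 1,
                          maxit = 300, factr = 1e7) {
  features <- match.arg(features)
  stopifnot(inherits(data, "selex_dataset"), inherits(bias, "bias_model"))
  if (nrow(data$round1) < 2) stop("degenerate data: need more than one unique probe")
  has_di <- features == "mono+di"
  has_shape <- features == "mono+shape"
  if (has_shape && is.null(shape_tables)) {
    stop("'mono+shape' needs shape_tables")
  }
  if (has_shape) shape_tables <- lapply(shape_tables, rc_symmetrize)
  shape_names <- if (has_shape) names(shape_tables) else character(0)
  pm <- full_probe_matrix(data$round1$seq, data$left_flank, data$right_flank)
  cts <- data$round1$count
  n <- sum(cts)
  ## parameter packing
  sens_len <- if (has_shape) {
    vapply(shape_tables, function(tb) {
      if (tb$kind == "base-centered") k else k - 1L
    }, 0L)
  } else integer(0)
  npar <- 1 + 4 * k + if (has_di) 16 * (k - 1) else 0 + 0
  npar <- npar + sum(sens_len)
  unpack <- function(th) {
    off <- 1
    b1 <- matrix(th[off + seq_len(4 * k)], 4, k); off <- off + 4 * k
    b2 <- NULL
    if (has_di) { b2 <- matrix(th[off + seq_len(16 * (k - 1))], 16, k - 1)
                  off <- off + 16 * (k - 1) }
    ss <- NULL
    if (has_shape) {
      ss <- list()
      for (f in shape_names) {
        ss[[f]] <- th[off + seq_len(sens_len[[f]])]
        off <- off + sens_len[[f]]
      }
    }
    selection_model(beta1 = b1, beta2 = b2, shape_sens = ss,
                    shape_tables = if (has_shape) shape_tables,
                    beta_ns = th[1])
  }
  pack <- function(bns, b1, b2, ss) {
    c(bns, as.vector(b1), if (has_di) as.vector(b2),
      if (has_shape) unlist(ss[shape_names], use.names = FALSE))
  }
  sym_project <- function(th) {
    if (!rc_symmetric) return(th)
    sel <- unpack(th)
    fl <- flip_blocks(sel$beta1, sel$beta2, sel$shape_sens, k)
    pack(th[1], (sel$beta1 + fl$beta1) / 2,
         if (has_di) (sel$beta2 + fl$beta2) / 2,
         if (has_shape) Map(function(a, b) (a + b) / 2, sel$shape_sens,
                            fl$shape_sens))
  }
  shape_cache <- if (has_shape) {
    probe_shape_profiles(pm, selection_model(
      beta1 = matrix(0, 4, k),
      shape_sens = lapply(sens_len, numeric),
      shape_tables = shape_tables))
  } else NULL
  last <- NULL
  evalfg <- function(th) {
    if (!is.null(last) && identical(th, last$th)) return(last)
    sel <- unpack(th)
    vs <- view_scores(pm, sel, shape_cache)
    ens <- exp(sel$beta_ns)
    evs <- exp(vs)
    kap <- ens + rowSums(evs)
    z1 <- selex_log_z1(data$L, data$left_flank, data$right_flank, bias, sel,
                       keep_tables = TRUE)
    value <- -(sum(cts * log(kap)) - n * z1$logZ1) / n
    ## gradient: observed part
    u <- evs / kap * cts
    noff <- z1$geo$noff
    g1s <- list(matrix(0, 4, k), matrix(0, 4, k))
    g2s <- if (has_di) list(matrix(0, 16, k - 1), matrix(0, 16, k - 1))
    gss <- if (has_shape) {
      list(lapply(sens_len, numeric), lapply(sens_len, numeric))
    }
    for (strand in 1:2) {
      for (o in seq_len(noff)) {
        wv <- u[, (strand - 1) * noff + o]
        for (j in seq_len(k)) {
          acc <- rowsum(wv, pm[, o + j - 1], reorder = TRUE)
          g1s[[strand]][as.integer(rownames(acc)), j] <-
            g1s[[strand]][as.integer(rownames(acc)), j] + acc[, 1]
        }
        if (has_di) {
          for (j in seq_len(k - 1)) {
            code <- (pm[, o + j - 1] - 1) * 4 + pm[, o + j]
            acc <- rowsum(wv, code, reorder = TRUE)
            g2s[[strand]][as.integer(rownames(acc)), j] <-
              g2s[[strand]][as.integer(rownames(acc)), j] + acc[, 1]
          }
        }
        if (has_shape) {
          for (f in shape_names) {
            prof <- shape_cache[[f]]
            for (j in seq_len(sens_len[[f]])) {
              gss[[strand]][[f]][j] <- gss[[strand]][[f]][j] +
                sum(wv * prof[, o + j - 1])
            }
          }
        }
      }
    }
    g_bns_obs <- sum(cts * ens / kap)
    ## gradient: partition part
    e1 <- matrix(0, 4, k)
    e2 <- if (has_di) matrix(0, 16, k - 1)
    es <- if (has_shape) lapply(sens_len, numeric)
    wview <- exp(z1$logT - z1$logZ1)
    for (vi in seq_along(z1$views)) {
      vf <- view_expected_features(z1$dp[[vi]], z1$views[[vi]], z1$geo, bias,
                                   z1$m, k, z1$tables, z1$logT[vi], has_di,
                                   shape_names)
      if (z1$views[[vi]]$strand == 1) {
        e1 <- e1 + wview[vi] * vf$e1
        if (has_di) e2 <- e2 + wview[vi] * vf$e2
        if (has_shape) for (f in shape_names) {
          es[[f]] <- es[[f]] + wview[vi] * vf$es[[f]]
        }
      } else {
        fl <- flip_blocks(vf$e1, vf$e2, vf$es, k)
        e1 <- e1 + wview[vi] * fl$beta1
        if (has_di) e2 <- e2 + wview[vi] * fl$beta2
        if (has_shape) for (f in shape_names) {
          es[[f]] <- es[[f]] + wview[vi] * fl$shape_sens[[f]]
        }
      }
    }
    g_bns_z <- exp(sel$beta_ns + z1$log_z0 - z1$logZ1)
    ## strand-fold the observed accumulators back to plus coordinates
    flo <- flip_blocks(g1s[[2]], if (has_di) g2s[[2]],
                       if (has_shape) gss[[2]], k)
    g1 <- g1s[[1]] + flo$beta1
    g2 <- if (has_di) g2s[[1]] + flo$beta2
    gs <- if (has_shape) Map(`+`, gss[[1]], flo$shape_sens)
    grad <- -(pack(g_bns_obs, g1, g2, gs) / n -
              pack(g_bns_z, e1, e2, es))
    if (rc_symmetric) grad <- sym_project_grad(grad)
    last <<- list(th = th, value = value, grad = grad)
    last
  }
  sym_project_grad <- function(g) {
    g2 <- sym_project(g)
    g2[1] <- g[1]
    g2
  }
  th0 <- if (rc_symmetric) numeric(npar)
         else with_seed(seed, rnorm(npar, sd = init_sd))
  th0[1] <- beta_ns_init
  if (rc_symmetric) th0 <- sym_project(th0)
  opt <- optim(th0, function(th) evalfg(th)$value,
               function(th) evalfg(th)$grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = factr))
  th <- if (rc_symmetric) sym_project(opt$par) else opt$par
  out <- unpack(th)
  attr(out, "loglik") <- -opt$value
  attr(out, "convergence") <- opt$convergence
  if (opt$convergence != 0) {
    warning("selection fit did not fully converge (code ", opt$convergence,
            "); |grad| = ",
            format(sqrt(sum(evalfg(opt$par)$grad^2)), digits = 3))
  }
  out
}

#' Per-position zero-mean gauge for a scoring matrix
#'
#' The multinomial likelihood is invariant under per-position constant
#' shifts of the scoring matrix; reported matrices are gauge-fixed by
#' removing each column's mean.
#'
#' @param beta1 4 x k scoring matrix.
#' @return The centered matrix.
#' @export
gauge_fix_scoring <- function(beta1) {
  sweep(beta1, 2, colMeans(beta1))
}

## ---- simulation ---------------------------------------------------------

#' Simulate a two-round SELEX experiment
#'
#' Enumerates the \code{4^L} probe space (desk scale, \code{L <= 12}; the
#' full probe includes fixed flanks), computes round-zero probabilities
#' \eqn{p_{i,0} = w_i/Z_0} from the bias model and round-one probabilities
#' \eqn{p_{i,1} = p_{i,0}\kappa_i/Z_1} from the selection model, and draws
#' multinomial counts for both rounds.
#'
#' @param bias A \code{bias_model} (or \code{NULL} for a uniform library).
#' @param sel A \code{selection_model}.
#' @param L Variable-region length.
#' @param n0,n1 Read counts for round zero and round one.
#' @param left_flank,right_flank Fixed flank sequences.
#' @param seed Integer seed.
#' @return A \code{selex_dataset}.
#' @export
simulate_selex <- function(bias, sel, L, n0, n1, left_flank = "ACGTA",
                           right_flank = "TACGT", seed = NULL) {
  if (L > 12) stop("desk-scale simulation enumerates 4^L probes; L <= 12 required")
  if (is.null(bias)) bias <- bias_model(numeric(4), 1)
  var_mat <- kmer_base_matrix(L)
  pm <- cbind(matrix(rep(drop(base_matrix_from_kmers(left_flank)),
                         each = nrow(var_mat)), nrow(var_mat)),
              var_mat,
              matrix(rep(drop(base_matrix_from_kmers(right_flank)),
                         each = nrow(var_mat)), nrow(var_mat)))
  lw <- probe_log_w(pm, bias)
  p0 <- exp(lw - logsumexp(lw))
  kap <- probe_kappa(pm, sel)
  p1 <- p0 * kap
  p1 <- p1 / sum(p1)
  with_seed(seed, {
    c0 <- drop(rmultinom(1, n0, p0))
    c1 <- drop(rmultinom(1, n1, p1))
  })
  i0 <- which(c0 > 0); i1 <- which(c1 > 0)
  selex_dataset(
    round0 = data.frame(seq = kmers_from_base_matrix(var_mat[i0, , drop = FALSE]),
                        count = c0[i0]),
    round1 = data.frame(seq = kmers_from_base_matrix(var_mat[i1, , drop = FALSE]),
                        count = c1[i1]),
    left_flank = left_flank, right_flank = right_flank)
}

#' Split round-one reads into training and held-out halves
#'
#' Each read is assigned independently (binomial thinning of the count
#' records), reproducing a per-read random split.
#'
#' @param data A \code{selex_dataset}.
#' @param fraction Held-out fraction.
#' @param seed Integer seed.
#' @return A list with \code{train} and \code{heldout} \code{selex_dataset}s
#'   (round zero is shared).
#' @export
split_holdout <- function(data, fraction = 0.5, seed = NULL) {
  stopifnot(inherits(data, "selex_dataset"))
  with_seed(seed, {
    held <- stats::rbinom(nrow(data$round1), data$round1$count, fraction)
  })
  train <- data$round1$count - held
  mk <- function(cnt) {
    keep <- cnt > 0
    selex_dataset(round0 = data$round0,
                  round1 = data.frame(seq = data$round1$seq[keep],
                                      count = cnt[keep]),
                  left_flank = data$left_flank, right_flank = data$right_flank)
  }
  list(train = mk(train), heldout = mk(held))
}

## ---- performance --------------------------------------------------------

#' k-mer count prediction performance of a SELEX model
#'
#' Tabulates observed m-mer counts by sliding an m-bp window across the
#' variable region of held-out round-one probes, retains m-mers with count
#' at least \code{min_count}, computes the counts expected under the model
#' (probe probabilities from the bias and selection models, window
#' incidence by clamped transfer-matrix DP over the probe distribution),
#' and returns the Pearson correlation of the log-transformed counts.
#'
#' @param sel A \code{selection_model}.
#' @param bias A \code{bias_model}.
#' @param heldout A \code{selex_dataset} whose round-one records are the
#'   held-out reads (disjoint from training).
#' @param m Window width (default 10).
#' @param min_count Minimum observed count for retention (default 100).
#' @return A list with \code{r} (Pearson r of log counts), \code{n_kmers},
#'   and the \code{obs}/\code{expected} count vectors.
#' @export
kmer_performance <- function(sel, bias, heldout, m = 10, min_count = 100) {
  stopifnot(inherits(heldout, "selex_dataset"))
  L <- heldout$L
  if (m > L) stop("window m exceeds the variable-region length")
  reads <- heldout$round1
  nh <- sum(reads$count)
  ## observed m-mer counts across variable-region windows
  noffv <- L - m + 1
  cnt <- list()
  for (o in seq_len(noffv)) {
    km <- substr(reads$seq, o, o + m - 1)
    acc <- rowsum(reads$count, km)
    cnt[[o]] <- setNames(acc[, 1], rownames(acc))
  }
  allk <- unlist(cnt)
  tot <- tapply(allk, names(allk), sum)
  keep <- names(tot)[tot >= min_count]
  if (length(keep) < 3) {
    stop("fewer than 3 m-mers pass min_count; lower min_count or add reads")
  }
  obs_counts <- as.numeric(tot[keep])
  ## expected counts: n * sum_o P(variable window o equals x)
  z1 <- selex_log_z1(L, heldout$left_flank, heldout$right_flank, bias, sel)
  if (m == L) {
    ## the window is the whole variable region: P(x) = w_x kappa_x / Z1
    pmk <- full_probe_matrix(keep, heldout$left_flank, heldout$right_flank)
    lw <- probe_log_w(pmk, bias)
    kap <- probe_kappa(pmk, sel)
    expected <- nh * exp(lw + log(kap) - z1$logZ1)
    r <- cor(log(obs_counts), log(expected))
    return(list(r = r, n_kmers = length(keep),
                obs = setNames(obs_counts, keep),
                expected = setNames(expected, keep)))
  }
  geo <- selex_geometry(L, heldout$left_flank, heldout$right_flank, sel$k)
  mm <- context_m(bias, sel)
  tables <- with_cvals(sel$shape_tables)
  views <- view_list(sel, geo$noff)
  expected <- numeric(length(keep))
  kbm <- base_matrix_from_kmers(keep)
  for (xi in seq_along(keep)) {
    tot_lp <- -Inf
    for (o in seq_len(noffv)) {
      clamp <- rep(NA_integer_, geo$P)
      clamp[geo$var_range[o:(o + m - 1)]] <- kbm[xi, ]
      lz0c <- probe_dp(geo$allowed, mm, bias_factor(bias, mm),
                       clamp = clamp)$logZ
      lts <- vapply(views, function(v) {
        probe_dp(geo$allowed, mm, view_factor(bias, mm, v, sel$k, tables),
                 clamp = clamp)$logZ
      }, 0)
      tot_lp <- logsumexp(c(tot_lp, sel$beta_ns + lz0c, lts))
    }
    expected[xi] <- nh * exp(tot_lp - z1$logZ1)
  }
  r <- cor(log(obs_counts), log(expected))
  list(r = r, n_kmers = length(keep),
       obs = setNames(obs_counts, keep),
       expected = setNames(expected, keep))
}

#' Compare two correlation coefficients (Fisher r-to-z)
#'
#' Two-tailed z-test on the difference of Fisher-transformed correlations:
#' \eqn{p = 2(1 - \Phi(|z_1 - z_2| / \sqrt{2/(n-3)}))}.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n_effective Effective sample size (> 3); the appropriate choice
#'   (retained k-mers vs reads) is left to the caller.
#' @return Two-tailed p-value.
#' @export
compare_r_fisher <- function(r1, r2, n_effective) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n_effective > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n_effective - 3))
  2 * pnorm(-abs(z))
}

#' Align a fitted scoring matrix to a reference strand
#'
#' SELEX likelihoods are exactly invariant under strand-flipping the
#' binding parameters (the view set covers both strands), so a fitted
#' matrix is only defined up to reverse complementation.  Returns the
#' gauge-fixed (per-position zero-mean) orientation of \code{beta1} closer
#' to the gauge-fixed reference.
#'
#' @param beta1 Fitted 4 x k scoring matrix.
#' @param reference Reference 4 x k matrix.
#' @return The aligned, gauge-fixed matrix.
#' @export
strand_align <- function(beta1, reference) {
  k <- ncol(beta1)
  a <- gauge_fix_scoring(beta1)
  b <- gauge_fix_scoring(beta1[4:1, k:1, drop = FALSE])
  r <- gauge_fix_scoring(reference)
  if (sum((a - r)^2) <= sum((b - r)^2)) a else b
}
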