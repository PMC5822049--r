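#' Indicator design matrices for sequence-to-shape regression
#'
#' Builds the regression design over all \code{4^k} k-mers (rows in
#' lexicographic order).  Columns are, in order: the intercept;
#' mononucleotide indicators by position then base (A, C, G, T); adjacent
#' dinucleotide indicators by step then dinucleotide (AA..TT).  For
#' \code{order = "all-pairs"} the design is the row-wise tensor product of
#' the mononucleotide design with itself, giving \code{(1+4k)^2} columns
#' covering the intercept, mononucleotides and all position pairs (adjacent
#' and non-adjacent).
#'
#' @param k Window length.
#' @param order One of \code{"mono"}, \code{"mono+di"}, \code{"di-only"},
#'   \code{"all-pairs"}.
#' @return Numeric matrix with \code{4^k} rows and named columns.
#' @export
build_design <- function(k, order = c("mono", "mono+di", "di-only", "all-pairs")) {
  order <- match.arg(order)
  if (k < 2 && order != "mono") stop("orders with dinucleotides need k >= 2")
  m <- kmer_base_matrix(k)
  n <- nrow(m)
  mono <- matrix(0, n, 4 * k)
  for (i in seq_len(k)) {
    mono[cbind(seq_len(n), (i - 1) * 4 + m[, i])] <- 1
  }
  colnames(mono) <- paste0("m", rep(seq_len(k), each = 4), ".", DNA_BASES)
  di <- NULL
  if (order %in% c("mono+di", "di-only")) {
    di <- matrix(0, n, 16 * (k - 1))
    for (i in seq_len(k - 1)) {
      code <- (m[, i] - 1) * 4 + m[, i + 1]
      di[cbind(seq_len(n), (i - 1) * 16 + code)] <- 1
    }
    colnames(di) <- paste0("d", rep(seq_len(k - 1), each = 16), ".", DNA_DINUCS)
  }
  icept <- matrix(1, n, 1, dimnames = list(NULL, "icept"))
  switch(order,
         "mono" = cbind(icept, mono),
         "mono+di" = cbind(icept, mono, di),
         "di-only" = cbind(icept, di),
         "all-pairs" = {
           base <- cbind(icept, mono)
           p <- ncol(base)
           out <- matrix(0, n, p * p)
           for (a in seq_len(p)) {
             out[, (a - 1) * p + seq_len(p)] <- base[, a] * base
           }
           colnames(out) <- paste0(rep(colnames(base), each = p), ":",
                                   colnames(base))
           out
         })
}

## Minimum-norm least squares via SVD with a relative singular-value cutoff;
## indicator designs have exactly-zero redundancy directions well separated
## from signal, so the cutoff is uncritical.
minnorm_lstsq <- function(X, y, tol = 1e-9, sv = NULL) {
  if (is.null(sv)) sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  list(coef = drop(coef), rank = sum(keep),
       u = sv$u[, keep, drop = FALSE])
}

## The k-mer designs are fixed objects; cache each design and its SVD so
## repeated fits (null-table ensembles) pay only the back-substitution.
.design_cache <- new.env(parent = emptyenv())

design_with_svd <- function(k, order) {
  key <- paste0(k, ":", order)
  hit <- .design_cache[[key]]
  if (!is.null(hit)) return(hit)
  X <- build_design(k, order)
  out <- list(X = X, sv = svd(X))
  .design_cache[[key]] <- out
  out
}

#' Fit a sequence-to-shape regression model
#'
#' Models a k-mer shape table as a linear function of sequence indicator
#' features, solved as the minimum-norm least-squares solution (the
#' indicator parameterization is redundant; predictions are unaffected by
#' the gauge).  When the table lies in the span of the design the table is
#' reproduced exactly.
#'
#' @param table A \code{shape_table}.
#' @param order Feature order, see \code{\link{build_design}}.
#' @param tol Relative singular-value cutoff for the pseudoinverse.
#' @return An object of class \code{seq2shape_model} with elements
#'   \code{gamma0} (intercept), \code{gamma1} (4 x k mononucleotide
#'   coefficient matrix, shape units), \code{gamma2} (16 x (k-1) adjacent
#'   dinucleotide matrix, when present), the full coefficient vector
#'   \code{coef}, and the in-sample \code{r2}.
#' @export
fit_seq2shape <- function(table, order = c("mono", "mono+di", "di-only", "all-pairs"),
                          tol = 1e-9) {
  stopifnot(inherits(table, "shape_table"))
  order <- match.arg(order)
  k <- table$k
  dsv <- design_with_svd(k, order)
  X <- dsv$X
  y <- unname(table$values)
  fit <- minnorm_lstsq(X, y, tol, sv = dsv$sv)
  pred <- drop(X %*% fit$coef)
  sst <- sum((y - mean(y))^2)
  ## guard against numerically-constant tables
  r2 <- if (sst > 1e-12 * length(y)) 1 - sum((y - pred)^2) / sst else 1
  model <- new_seq2shape(fit$coef, k = k, kind = table$kind, order = order,
                         feature = table$feature)
  model$r2 <- r2
  model$rank <- fit$rank
  model
}

## Assemble a seq2shape_model from a coefficient vector laid out as the
## matching build_design columns.
new_seq2shape <- function(coef, k, kind, order, feature = "synthetic") {
  gamma0 <- coef[1]
  gamma1 <- gamma2 <- NULL
  if (order %in% c("mono", "mono+di", "all-pairs")) {
    gamma1 <- matrix(coef[1 + seq_len(4 * k)], nrow = 4,
                     dimnames = list(DNA_BASES, NULL))
  } else {
    gamma1 <- matrix(0, 4, k, dimnames = list(DNA_BASES, NULL))
  }
  if (order == "mono+di") {
    gamma2 <- matrix(coef[1 + 4 * k + seq_len(16 * (k - 1))], nrow = 16,
                     dimnames = list(DNA_DINUCS, NULL))
  } else if (order == "di-only") {
    gamma2 <- matrix(coef[1 + seq_len(16 * (k - 1))], nrow = 16,
                     dimnames = list(DNA_DINUCS, NULL))
  }
  structure(list(feature = feature, k = as.integer(k), kind = kind,
                 order = order, gamma0 = unname(gamma0), gamma1 = gamma1,
                 gamma2 = gamma2, coef = unname(coef)),
            class = "seq2shape_model")
}

#' Construct a sequence-to-shape model from explicit coefficients
#'
#' @param gamma0 Intercept (shape units).
#' @param gamma1 4 x k matrix of mononucleotide coefficients (rows A,C,G,T).
#' @param gamma2 Optional 16 x (k-1) matrix of adjacent-dinucleotide
#'   coefficients (rows AA..TT).
#' @param kind Window kind, as in \code{\link{shape_table}}.
#' @param feature Feature label.
#' @return A \code{seq2shape_model}.
#' @export
seq2shape_model <- function(gamma0, gamma1, gamma2 = NULL,
                            kind = c("base-centered", "step-centered"),
                            feature = "synthetic") {
  kind <- match.arg(kind)
  k <- ncol(gamma1)
  stopifnot(nrow(gamma1) == 4)
  order <- if (is.null(gamma2)) "mono" else "mono+di"
  if (!is.null(gamma2)) stopifnot(nrow(gamma2) == 16, ncol(gamma2) == k - 1)
  coef <- c(gamma0, as.vector(gamma1), if (!is.null(gamma2)) as.vector(gamma2))
  new_seq2shape(coef, k = k, kind = kind, order = order, feature = feature)
}

#' @export
print.seq2shape_model <- function(x, ...) {
  cat(sprintf("seq2shape_model '%s' (%s, k=%d, order=%s)\n",
              x$feature, x$kind, x$k, x$order))
  if (!is.null(x$r2)) cat(sprintf("  in-sample R2 = %.4f\n", x$r2))
  invisible(x)
}

## Predicted shape value for every k-mer, in lexicographic order.
predict_all_kmers <- function(model) {
  X <- design_with_svd(model$k, model$order)$X
  drop(X %*% model$coef)
}

#' Window offsets of a sequence-to-shape model
#'
#' Base-centered windows are indexed by offsets relative to the central
#' base (-2..+2 for k = 5); step-centered windows by offsets of the left
#' base relative to the central step (-1..+2 for k = 4).
#'
#' @param model A \code{seq2shape_model} (or any list with \code{k},
#'   \code{kind}).
#' @return List with integer vectors \code{base} (length k) and \code{step}
#'   (length k-1).
#' @export
window_offsets <- function(model) {
  k <- model$k
  if (model$kind == "base-centered") {
    if (k %% 2 == 0) stop("base-centered windows need odd k")
    off <- seq_len(k) - (k + 1) / 2
  } else {
    if (k %% 2 == 1) stop("step-centered windows need even k")
    off <- seq_len(k) - k / 2
  }
  list(base = off, step = off[-k])
}

#' Count independent parameters of a sequence-to-shape design
#'
#' Counts the eigenvalues of \code{X'PX} above a relative cutoff, where
#' \code{P} projects onto reverse-complement-symmetric k-mer value vectors
#' (or \code{X'X} when \code{rc_symmetric = FALSE}).  For RC-symmetric
#' designs this equals the closed forms \code{ceiling((3k+1)/2)} for the
#' mononucleotide model and \code{4*floor(3k/2) - 2} for the dinucleotide
#' models.
#'
#' @param k Window length.
#' @param order Feature order, see \code{\link{build_design}}.
#' @param rc_symmetric Restrict to the RC-symmetric value subspace?
#' @param tol Relative eigenvalue cutoff.
#' @return Integer parameter count.
#' @export
count_dof <- function(k, order = c("mono", "mono+di", "di-only", "all-pairs"),
                      rc_symmetric = TRUE, tol = 1e-9) {
  order <- match.arg(order)
  X <- build_design(k, order)
  if (rc_symmetric) {
    p <- rc_permutation(k)
    M <- (crossprod(X) + crossprod(X, X[p, , drop = FALSE])) / 2
    M <- (M + t(M)) / 2
  } else {
    M <- crossprod(X)
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(ev))
}

#' Leave-one-out cross-validated R-squared
#'
#' Exhaustive leave-one-out over reverse-complement classes: each pair of
#' k-mers related by reverse complementation (which share a table value) is
#' held out together, the model is refit, and the held-out values are
#' predicted.  Computed with the standard block leave-out identity
#' \code{e_S = (I - H_SS)^{-1} (y_S - yhat_S)} on the projection hat matrix,
#' which is exact because removing one class does not change the design's
#' column space.
#'
#' @param table An RC-symmetric \code{shape_table}.
#' @param order Feature order.
#' @param tol Relative singular-value cutoff.
#' @return Cross-validated fraction of variance explained (can be negative
#'   for structureless tables).
#' @export
loo_cv_r2 <- function(table, order = c("mono", "mono+di", "di-only", "all-pairs"),
                      tol = 1e-9) {
  stopifnot(inherits(table, "shape_table"))
  order <- match.arg(order)
  if (!is_rc_symmetric(table, tol = 1e-8)) {
    stop("loo_cv_r2 expects a reverse-complement-symmetric table")
  }
  dsv <- design_with_svd(table$k, order)
  X <- dsv$X
  y <- unname(table$values)
  fit <- minnorm_lstsq(X, y, tol, sv = dsv$sv)
  U <- fit$u
  yhat <- drop(U %*% (t(U) %*% y))
  cls <- rc_classes(table$k)
  err <- numeric(length(y))
  for (S in cls) {
    Us <- U[S, , drop = FALSE]
    Hss <- tcrossprod(Us)
    A <- diag(length(S)) - Hss
    err[S] <- solve(A, y[S] - yhat[S])
  }
  sst <- sum((y - mean(y))^2)
  1 - sum(err^2) / sst
}

#' Predict a shape profile along a DNA sequence
#'
#' Slides the k-window along the sequence and looks up (for a table) or
#' predicts (for a fitted model) the shape value at each fully covered
#' position.  Base-centered features are defined at positions
#' \code{(k+1)/2 .. L-(k-1)/2}; step-centered features at steps
#' \code{k/2 .. L-k/2}.  Positions outside are \code{NA}.
#'
#' @param sequence A single DNA string (ACGT only, no IUPAC ambiguity
#'   codes).
#' @param model_or_table A \code{shape_table} or \code{seq2shape_model}.
#' @return Numeric vector of length \code{L} (base-centered) or \code{L-1}
#'   (step-centered), one entry per position or step.
#' @export
predict_profile <- function(sequence, model_or_table) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (grepl("[^ACGT]", sequence)) {
    stop("ambiguous or non-ACGT base in sequence; IUPAC codes are not expanded")
  }
  x <- model_or_table
  vals <- if (inherits(x, "shape_table")) unname(x$values) else predict_all_kmers(x)
  k <- x$k
  b <- drop(base_matrix_from_kmers(sequence))
  L <- length(b)
  if (L < k) stop("sequence shorter than window length ", k)
  nw <- L - k + 1
  idx <- rep(1, nw)
  for (i in seq_len(k)) idx <- idx + (b[seq_len(nw) + i - 1] - 1) * 4^(k - i)
  win_vals <- vals[idx]
  if (x$kind == "base-centered") {
    out <- rep(NA_real_, L)
    center <- (k + 1) / 2
    out[seq_len(nw) + center - 1] <- win_vals
  } else {
    out <- rep(NA_real_, L - 1)
    center <- k / 2    # step index of the central step of the first window
    out[seq_len(nw) + center - 1] <- win_vals
  }
  out
}

#' Display gauge for sequence-to-shape logos
#'
#' The indicator design is rank-deficient, so coefficients are only defined
#' up to a gauge.  For display, per-position mononucleotide coefficients are
#' centered to zero mean and dinucleotide blocks are doubly centered
#' (row/column margins absorbed into the mononucleotide blocks and
#' intercept).  Predictions are unaffected.
#'
#' @param model A \code{seq2shape_model} with \code{gamma1} (and optionally
#'   \code{gamma2}).
#' @return A list with centered \code{gamma0}, \code{gamma1}, \code{gamma2}.
#' @export
logo_coefficients <- function(model) {
  g0 <- model$gamma0
  g1 <- model$gamma1
  g2 <- model$gamma2
  if (!is.null(g2)) {
    k <- model$k
    for (i in seq_len(k - 1)) {
      blk <- matrix(g2[, i], 4, 4, byrow = TRUE)   # rows: first base
      rm_ <- rowMeans(blk); cm <- colMeans(blk); gm <- mean(blk)
      blk <- blk - outer(rm_, rep(1, 4)) - outer(rep(1, 4), cm) + gm
      g2[, i] <- as.vector(t(blk))
      g1[, i] <- g1[, i] + (rm_ - gm)
      g1[, i + 1] <- g1[, i + 1] + (cm - gm)
      g0 <- g0 + gm
    }
  }
  shifts <- colMeans(g1)
  g1 <- sweep(g1, 2, shifts)
  g0 <- g0 + sum(shifts)
  list(gamma0 = g0, gamma1 = g1, gamma2 = g2)
}
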