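#' Mechanism-agnostic free-energy binding model
#'
#' Represents the binding free energy of a k-bp footprint as
#' \deqn{-\Delta\Delta G(s)/RT = \beta^{(0)} + \sum_i \beta^{(1)}_{i,s_i}
#'   + \sum_i \beta^{(2)}_{i,s_{i:i+1}},}
#' an intercept plus a position-specific scoring matrix plus adjacent
#' dinucleotide terms.  Larger scores mean stronger binding.
#'
#' @param beta1 4 x k scoring matrix (rows A, C, G, T; -ddG/RT units).
#' @param beta2 Optional 16 x (k-1) adjacent-dinucleotide matrix (rows
#'   AA..TT); zero if omitted.
#' @param beta0 Intercept.
#' @return An object of class \code{agn_model}.
#' @export
agn_model <- function(beta1, beta2 = NULL, beta0 = 0) {
  beta1 <- as.matrix(beta1)
  stopifnot(nrow(beta1) == 4)
  k <- ncol(beta1)
  if (is.null(beta2)) beta2 <- matrix(0, 16, max(k - 1, 0))
  beta2 <- as.matrix(beta2)
  stopifnot(nrow(beta2) == 16, ncol(beta2) == k - 1)
  stopifnot(all(is.finite(beta0)), all(is.finite(beta1)), all(is.finite(beta2)))
  rownames(beta1) <- DNA_BASES
  rownames(beta2) <- DNA_DINUCS
  structure(list(k = as.integer(k), beta0 = as.numeric(beta0),
                 beta1 = beta1, beta2 = beta2),
            class = "agn_model")
}

#' @export
print.agn_model <- function(x, ...) {
  cat(sprintf("agn_model: footprint k=%d, beta0=%.4g, max|beta1|=%.3g, max|beta2|=%.3g\n",
              x$k, x$beta0, max(abs(x$beta1)), max(abs(x$beta2))))
  invisible(x)
}

#' Shape-readout binding model
#'
#' Binding free energy as base readout (intercept + scoring matrix) plus
#' shape readout: per-feature profiles of shape-sensitivity coefficients
#' (\code{-ddG/RT} per unit shape) multiplied by the shape value predicted
#' at each footprint position by an attached sequence-to-shape model.
#' Sensitivities at the first/last two base positions (base-centered
#' features) and at the first/last step (step-centered features) must be
#' zero: readout there would create sequence preferences extending beyond
#' the footprint.
#'
#' @param beta1 4 x k scoring matrix (rows A, C, G, T).
#' @param profiles Named list of numeric sensitivity profiles, one per
#'   shape feature; length k for base-centered features (per base
#'   position), length k-1 for step-centered ones (per step).
#' @param shape_models Named list of \code{seq2shape_model}s (mono+di
#'   order), names matching \code{profiles}.
#' @param beta0 Intercept.
#' @return An object of class \code{shape_readout_model}.
#' @export
shape_readout_model <- function(beta1, profiles, shape_models, beta0 = 0) {
  beta1 <- as.matrix(beta1)
  stopifnot(nrow(beta1) == 4)
  k <- ncol(beta1)
  stopifnot(is.list(profiles), !is.null(names(profiles)),
            all(names(profiles) %in% names(shape_models)))
  for (f in names(profiles)) {
    sm <- shape_models[[f]]
    prof <- profiles[[f]]
    if (sm$kind == "base-centered") {
      if (length(prof) != k) stop("base-centered profile '", f, "' must have length k")
      bad <- c(1, 2, k - 1, k)
    } else {
      if (length(prof) != k - 1) stop("step-centered profile '", f, "' must have length k-1")
      bad <- c(1, k - 1)
    }
    if (any(abs(prof[bad]) > 0)) {
      stop("profile '", f, "' must be zero at boundary positions")
    }
  }
  rownames(beta1) <- DNA_BASES
  structure(list(k = as.integer(k), beta0 = as.numeric(beta0), beta1 = beta1,
                 profiles = profiles, shape_models = shape_models[names(profiles)]),
            class = "shape_readout_model")
}

#' @export
print.shape_readout_model <- function(x, ...) {
  cat(sprintf("shape_readout_model: k=%d, features: %s\n", x$k,
              paste(names(x$profiles), collapse = ", ")))
  invisible(x)
}

## Interior (free) positions of a sensitivity profile for footprint k.
profile_interior <- function(k, kind) {
  if (kind == "base-centered") {
    if (k < 5) integer(0) else seq(3, k - 2)
  } else {
    if (k < 4) integer(0) else seq(2, k - 2)
  }
}

#' Score k-mers under a binding model
#'
#' @param model An \code{agn_model} or \code{shape_readout_model}.
#' @param kmers Character vector of k-mers (footprint length, ACGT only).
#' @return Numeric vector of \code{-ddG/RT} scores.
#' @export
score_model <- function(model, kmers) {
  b <- base_matrix_from_kmers(kmers)
  if (ncol(b) != model$k) stop("k-mers must match the footprint length ", model$k)
  score_base_matrix(model, b)
}

## Score on an integer base matrix (n x k); used by enumeration oracles too.
score_base_matrix <- function(model, b) {
  k <- model$k
  n <- nrow(b)
  s <- rep(model$beta0, n)
  for (i in seq_len(k)) s <- s + model$beta1[cbind(b[, i], i)]
  if (inherits(model, "agn_model")) {
    if (k >= 2) {
      for (i in seq_len(k - 1)) {
        code <- (b[, i] - 1) * 4 + b[, i + 1]
        s <- s + model$beta2[cbind(code, i)]
      }
    }
    return(s)
  }
  ## shape readout terms: sensitivity x model-predicted shape value of the
  ## local window
  for (f in names(model$profiles)) {
    sm <- model$shape_models[[f]]
    prof <- model$profiles[[f]]
    vals <- predict_all_kmers(sm)
    kw <- sm$k
    if (sm$kind == "base-centered") {
      for (i in profile_interior(k, sm$kind)) {
        if (prof[i] == 0) next
        h <- (kw - 1) / 2
        idx <- rep(1, n)
        for (w in seq_len(kw)) idx <- idx + (b[, i - h + w - 1] - 1) * 4^(kw - w)
        s <- s + prof[i] * vals[idx]
      }
    } else {
      for (j in profile_interior(k, sm$kind)) {
        if (prof[j] == 0) next
        start <- j - (kw / 2 - 1)
        idx <- rep(1, n)
        for (w in seq_len(kw)) idx <- idx + (b[, start + w - 1] - 1) * 4^(kw - w)
        s <- s + prof[j] * vals[idx]
      }
    }
  }
  s
}

#' Sequence-only representation of a shape-readout model
#'
#' Convolves each shape-sensitivity profile with the mono- and dinucleotide
#' coefficients of its sequence-to-shape model, yielding a mechanism-
#' agnostic model whose scores equal the shape-readout model's exactly:
#' \deqn{\beta^{seq,(1)}_{i,c} = \beta^{proj,(1)}_{i,c} +
#'   \sum_\delta \beta^{proj}_{i-\delta} \gamma^{(1)}_{\delta,c}, \qquad
#'   \beta^{seq,(2)}_{i,cd} = \sum_\delta \beta^{proj}_{i-\delta}
#'   \gamma^{(2)}_{\delta,cd}.}
#'
#' @param srm A \code{shape_readout_model}.
#' @return An \code{agn_model} scoring identically on all k-mers.
#' @export
to_sequence_representation <- function(srm) {
  stopifnot(inherits(srm, "shape_readout_model"))
  k <- srm$k
  beta0 <- srm$beta0
  beta1 <- srm$beta1
  beta2 <- matrix(0, 16, max(k - 1, 0))
  for (f in names(srm$profiles)) {
    sm <- srm$shape_models[[f]]
    if (is.null(sm$gamma2) && sm$order != "mono") {
      stop("seq2shape model for '", f, "' lacks coefficients")
    }
    prof <- srm$profiles[[f]]
    contrib <- profile_linear_map(k, sm)
    active <- which(prof != 0)
    for (i in active) {
      beta0 <- beta0 + prof[i] * contrib$b0[i]
      beta1 <- beta1 + prof[i] * contrib$b1[[i]]
      beta2 <- beta2 + prof[i] * contrib$b2[[i]]
    }
  }
  agn_model(beta1 = beta1, beta2 = beta2, beta0 = beta0)
}

## For unit sensitivity at each profile position of feature model `sm` in a
## k-bp footprint, the induced (b0, b1, b2) blocks.  Linear in the profile,
## so projection can assemble its full design from these.
profile_linear_map <- function(k, sm) {
  offs <- window_offsets(sm)
  kw <- sm$k
  npos <- if (sm$kind == "base-centered") k else k - 1
  b0 <- numeric(npos)
  b1 <- vector("list", npos)
  b2 <- vector("list", npos)
  g1 <- sm$gamma1
  g2 <- if (!is.null(sm$gamma2)) sm$gamma2 else matrix(0, 16, kw - 1)
  for (i in profile_interior(k, sm$kind)) {
    m1 <- matrix(0, 4, k)
    m2 <- matrix(0, 16, max(k - 1, 0))
    for (w in seq_len(kw)) {
      pos <- i + offs$base[w]
      m1[, pos] <- m1[, pos] + g1[, w]
    }
    for (w in seq_len(kw - 1)) {
      st <- i + offs$step[w]
      m2[, st] <- m2[, st] + g2[, w]
    }
    b0[i] <- sm$gamma0
    b1[[i]] <- m1
    b2[[i]] <- m2
  }
  list(b0 = b0, b1 = b1, b2 = b2)
}

#' Write or read a binding / sequence-to-shape model as JSON
#'
#' @param model An \code{agn_model}, \code{shape_readout_model} or
#'   \code{seq2shape_model}.
#' @param path File path.
#' @return \code{path} invisibly (write); the reconstructed object (read).
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "agn_model")) {
    list(type = "agn_model", k = model$k, beta0 = model$beta0,
         beta1 = model$beta1, beta2 = model$beta2)
  } else if (inherits(model, "seq2shape_model")) {
    list(type = "seq2shape_model", feature = model$feature, k = model$k,
         kind = model$kind, order = model$order, gamma0 = model$gamma0,
         gamma1 = model$gamma1, gamma2 = model$gamma2)
  } else if (inherits(model, "shape_readout_model")) {
    list(type = "shape_readout_model", k = model$k, beta0 = model$beta0,
         beta1 = model$beta1, profiles = model$profiles,
         shape_models = lapply(model$shape_models, function(sm) {
           list(feature = sm$feature, k = sm$k, kind = sm$kind,
                order = sm$order, gamma0 = sm$gamma0, gamma1 = sm$gamma1,
                gamma2 = sm$gamma2)
         }))
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild_s2s <- function(o) {
    seq2shape_model(gamma0 = o$gamma0, gamma1 = as.matrix(o$gamma1),
                    gamma2 = if (!is.null(o$gamma2)) as.matrix(o$gamma2),
                    kind = o$kind, feature = o$feature)
  }
  switch(obj$type,
         agn_model = agn_model(beta1 = as.matrix(obj$beta1),
                               beta2 = as.matrix(obj$beta2), beta0 = obj$beta0),
         seq2shape_model = rebuild_s2s(obj),
         shape_readout_model = {
           sms <- lapply(obj$shape_models, rebuild_s2s)
           shape_readout_model(beta1 = as.matrix(obj$beta1),
                               profiles = lapply(obj$profiles, as.numeric),
                               shape_models = sms, beta0 = obj$beta0)
         },
         stop("unknown model type in ", path))
}
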