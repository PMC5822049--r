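#' Loss functions comparing two binding models
#'
#' \code{loss_affinity} is the summed squared affinity error over all
#' \code{4^k} footprint sequences,
#' \deqn{V = \sigma(2\beta_{agn}) + \sigma(2\beta_{seq}) -
#'   2\sigma(\beta_{agn}+\beta_{seq}),}
#' evaluated via three transfer-matrix partition sums.  \code{loss_kl} is
#' the Kullback--Leibler divergence between the Boltzmann sequence
#' distributions implied by the two models,
#' \deqn{V = (\beta_{agn}-\beta_{seq})\cdot\nabla\sigma(\beta_{agn})/
#'   \sigma(\beta_{agn}) - \ln(\sigma(\beta_{agn})/\sigma(\beta_{seq})),}
#' which is nonnegative and zero iff the models induce the same
#' distribution (intercepts cancel).
#'
#' @param agn,seq \code{agn_model}s with equal footprints.
#' @return Nonnegative loss value.
#' @export
loss_affinity <- function(agn, seq) {
  affinity_loss_grad(agn, seq, want_grad = FALSE)$value
}

#' @rdname loss_affinity
#' @export
loss_kl <- function(agn, seq) {
  kl_loss_grad(agn, seq, ref = NULL, want_grad = FALSE)$value
}

affinity_loss_grad <- function(agn, seq, want_grad = TRUE, ps_2a = NULL) {
  stopifnot(agn$k == seq$k)
  if (is.null(ps_2a)) ps_2a <- partition_sum(scale_beta(agn, 2))
  ps_2s <- partition_sum(scale_beta(seq, 2))
  ps_as <- partition_sum(add_beta(agn, seq))
  v <- ps_2a$sigma + ps_2s$sigma - 2 * ps_as$sigma
  out <- list(value = v)
  if (want_grad) {
    g2s <- ps_2s$sigma * flatten_beta(ps_2s$grad_log)
    gas <- ps_as$sigma * flatten_beta(ps_as$grad_log)
    out$grad <- 2 * g2s - 2 * gas
  }
  out
}

## ref caches the agn-side quantities (partition + flat params) across calls.
kl_ref <- function(agn) {
  ps <- partition_sum(agn)
  list(flat = flatten_beta(agn), gl = flatten_beta(ps$grad_log),
       log_sigma = ps$log_sigma)
}

kl_loss_grad <- function(agn, seq, ref = NULL, want_grad = TRUE) {
  stopifnot(agn$k == seq$k)
  if (is.null(ref)) ref <- kl_ref(agn)
  ps_s <- partition_sum(seq)
  fs <- flatten_beta(seq)
  v <- sum((ref$flat - fs) * ref$gl) - (ref$log_sigma - ps_s$log_sigma)
  out <- list(value = v)
  if (want_grad) out$grad <- flatten_beta(ps_s$grad_log) - ref$gl
  out
}

#' Configuration for penalized shape projection
#'
#' @param loss \code{"kl"} (default) or \code{"affinity"}.
#' @param p Penalty exponent: 2 (sum of squares, default) or 1 (sum of
#'   absolute values, handled by positive/negative variable splitting).
#' @param lambda_mono,lambda_shape Nonnegative penalty scales; both default
#'   to 1.
#' @param mono_ref_quarter Divide the mononucleotide reference norm by 4
#'   (matching the per-base convention of the combined objective); set
#'   \code{FALSE} to disable.
#' @param maxit,factr Optimizer controls passed to \code{optim} (L-BFGS-B).
#' @return A \code{projection_config} list.
#' @export
projection_config <- function(loss = c("kl", "affinity"), p = 2,
                              lambda_mono = 1, lambda_shape = 1,
                              mono_ref_quarter = TRUE,
                              maxit = 2000, factr = 1e6) {
  loss <- match.arg(loss)
  stopifnot(p %in% c(1, 2), lambda_mono >= 0, lambda_shape >= 0)
  structure(list(loss = loss, p = p, lambda_mono = lambda_mono,
                 lambda_shape = lambda_shape,
                 mono_ref_quarter = mono_ref_quarter,
                 maxit = maxit, factr = factr),
            class = "projection_config")
}

## Assemble the linear map A from free parameters theta to the flat
## (beta0, beta1, beta2) vector, plus the block index bookkeeping.
projection_design <- function(k, shape_models, include_beta0) {
  nflat <- 1 + 4 * k + 16 * (k - 1)
  cols <- list()
  block <- character(0)
  if (include_beta0) {
    e <- numeric(nflat); e[1] <- 1
    cols[[length(cols) + 1]] <- e
    block <- c(block, "beta0")
  }
  for (j in seq_len(4 * k)) {
    e <- numeric(nflat); e[1 + j] <- 1
    cols[[length(cols) + 1]] <- e
    block <- c(block, "mono")
  }
  pos_index <- list()
  for (f in names(shape_models)) {
    sm <- shape_models[[f]]
    lm <- profile_linear_map(k, sm)
    interior <- profile_interior(k, sm$kind)
    if (!length(interior)) {
      stop("footprint k=", k, " leaves no interior position for feature '",
           f, "'")
    }
    pos_index[[f]] <- interior
    for (i in interior) {
      cols[[length(cols) + 1]] <- c(lm$b0[i], as.vector(lm$b1[[i]]),
                                    as.vector(lm$b2[[i]]))
      block <- c(block, paste0("shape:", f))
    }
  }
  A <- do.call(cbind, cols)
  list(A = A, block = block, pos_index = pos_index)
}

## Optimize loss(A theta) (+ optional normalized penalties) over theta.
## penalties: NULL for the unpenalized stage, else list(terms = list of
## list(idx, lambda, ref)), p, vref.
optimize_projection <- function(agn, des, cfg, start, penalties = NULL) {
  k <- agn$k
  A <- des$A
  ref <- if (cfg$loss == "kl") kl_ref(agn) else NULL
  ps_2a <- if (cfg$loss == "affinity") partition_sum(scale_beta(agn, 2)) else NULL
  last <- NULL  # optim calls fn and gr separately; cache the shared work
  loss_fg <- function(theta) {
    if (!is.null(last) && identical(theta, last$theta)) return(last)
    seqm <- unflatten_beta(drop(A %*% theta), k)
    lg <- if (cfg$loss == "kl") {
      kl_loss_grad(agn, seqm, ref = ref)
    } else {
      affinity_loss_grad(agn, seqm, ps_2a = ps_2a)
    }
    last <<- list(theta = theta, value = lg$value,
                  grad = drop(crossprod(A, lg$grad)))
    last
  }
  nth <- ncol(A)
  if (is.null(penalties)) {
    fn <- function(th) loss_fg(th)$value
    gr <- function(th) loss_fg(th)$grad
    opt <- optim(start, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = cfg$maxit, factr = cfg$factr))
    return(list(theta = opt$par, value = opt$value,
                convergence = opt$convergence, message = opt$message))
  }
  vref <- penalties$vref
  terms <- penalties$terms
  if (cfg$p == 2) {
    fn <- function(th) {
      o <- loss_fg(th)$value / vref
      for (tm in terms) o <- o + tm$lambda * sum(th[tm$idx]^2) / tm$ref
      o
    }
    gr <- function(th) {
      g <- loss_fg(th)$grad / vref
      for (tm in terms) g[tm$idx] <- g[tm$idx] + tm$lambda * 2 * th[tm$idx] / tm$ref
      g
    }
    opt <- optim(start, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = cfg$maxit, factr = cfg$factr))
    return(list(theta = opt$par, value = opt$value,
                convergence = opt$convergence, message = opt$message))
  }
  ## p == 1: exact reformulation theta_pen = u - v with u, v >= 0 and
  ## penalty sum(u + v); box constraints keep the problem smooth.
  pen_idx <- sort(unique(unlist(lapply(terms, `[[`, "idx"))))
  free_idx <- setdiff(seq_len(nth), pen_idx)
  nf <- length(free_idx); np <- length(pen_idx)
  weight <- numeric(nth)
  for (tm in terms) weight[tm$idx] <- weight[tm$idx] + tm$lambda / tm$ref
  to_theta <- function(z) {
    th <- numeric(nth)
    th[free_idx] <- z[seq_len(nf)]
    th[pen_idx] <- z[nf + seq_len(np)] - z[nf + np + seq_len(np)]
    th
  }
  fn <- function(z) {
    th <- to_theta(z)
    loss_fg(th)$value / vref + sum(weight[pen_idx] * (z[nf + seq_len(np)] +
                                                      z[nf + np + seq_len(np)]))
  }
  gr <- function(z) {
    th <- to_theta(z)
    g <- loss_fg(th)$grad / vref
    c(g[free_idx], g[pen_idx] + weight[pen_idx], -g[pen_idx] + weight[pen_idx])
  }
  z0 <- c(start[free_idx], pmax(start[pen_idx], 0), pmax(-start[pen_idx], 0))
  lower <- c(rep(-Inf, nf), rep(0, 2 * np))
  opt <- optim(z0, fn, gr, method = "L-BFGS-B", lower = lower,
               control = list(maxit = cfg$maxit, factr = cfg$factr))
  list(theta = to_theta(opt$par), value = opt$value,
       convergence = opt$convergence, message = opt$message)
}

## Turn a theta vector into the shape_readout_model it parameterizes.
theta_to_model <- function(theta, k, des, shape_models, include_beta0) {
  off <- 0
  beta0 <- 0
  if (include_beta0) { beta0 <- theta[1]; off <- 1 }
  beta1 <- matrix(theta[off + seq_len(4 * k)], 4, k)
  off <- off + 4 * k
  profiles <- list()
  for (f in names(shape_models)) {
    sm <- shape_models[[f]]
    npos <- if (sm$kind == "base-centered") k else k - 1
    prof <- numeric(npos)
    interior <- des$pos_index[[f]]
    prof[interior] <- theta[off + seq_along(interior)]
    off <- off + length(interior)
    profiles[[f]] <- prof
  }
  shape_readout_model(beta1 = beta1, profiles = profiles,
                      shape_models = shape_models, beta0 = beta0)
}

#' Shape projection of a mechanism-agnostic binding model
#'
#' Decomposes a mono+dinucleotide binding model into base readout (a
#' residual scoring matrix) plus position-specific shape-sensitivity
#' profiles.  Stage 1 minimizes the chosen loss without penalties to obtain
#' the reference loss and reference norms; stage 2 minimizes the combined
#' normalized objective
#' \deqn{V/V_{ref} + \lambda_{shape}\|\beta^{proj,(\phi)}\|_p/ref_\phi +
#'   \lambda_{mono}\|\beta^{proj,(1)}\|_p/(ref_{mono}/4),}
#' where \eqn{\|x\|_p = \sum_i |x_i|^p} and the references are the stage-1
#' block norms.  Sensitivities at footprint-boundary positions are
#' constrained to zero throughout.  Both stages start deterministically
#' (zeros; then the stage-1 optimum).
#'
#' @param agn An \code{agn_model} with footprint \code{k >= 5}.
#' @param shape_models Named list of \code{seq2shape_model}s (mono+di
#'   order), or of \code{shape_table}s which are then fit internally.
#' @param cfg A \code{\link{projection_config}}.
#' @param start Optional stage-1 start vector (e.g. a previous fit's
#'   parameters when sweeping many related problems); defaults to zeros.
#' @return A \code{projection_result}: the fitted
#'   \code{shape_readout_model} (\code{$model}), its exact sequence-only
#'   representation (\code{$seq_model}), the achieved loss \code{$loss},
#'   reference loss and norms, and a convergence report.
#' @export
project <- function(agn, shape_models, cfg = projection_config(),
                    start = NULL) {
  stopifnot(inherits(agn, "agn_model"))
  shape_models <- as_shape_models(shape_models)
  include_beta0 <- cfg$loss == "affinity"
  des <- projection_design(agn$k, shape_models, include_beta0)
  nth <- ncol(des$A)
  st1 <- optimize_projection(agn, des, cfg, start = start %||% numeric(nth))
  v0 <- if (cfg$loss == "kl") {
    kl_loss_grad(agn, unflatten_beta(numeric(1 + 4 * agn$k + 16 * (agn$k - 1)),
                                     agn$k), want_grad = FALSE)$value
  } else {
    affinity_loss_grad(agn, unflatten_beta(
      numeric(1 + 4 * agn$k + 16 * (agn$k - 1)), agn$k),
      want_grad = FALSE)$value
  }
  vref <- max(st1$value, 1e-10 * max(v0, 1), 1e-300)
  mono_idx <- which(des$block == "mono")
  ref_mono <- sum(abs(st1$theta[mono_idx])^cfg$p)
  mono_floor <- 1e-8 * length(mono_idx)
  terms <- list()
  if (cfg$lambda_mono > 0) {
    if (ref_mono < mono_floor) {
      warning("mononucleotide reference norm below floor; penalty dropped")
    } else {
      denom <- if (cfg$mono_ref_quarter) ref_mono / 4 else ref_mono
      terms[[length(terms) + 1]] <- list(idx = mono_idx,
                                         lambda = cfg$lambda_mono, ref = denom)
    }
  }
  if (cfg$lambda_shape > 0) {
    for (f in names(shape_models)) {
      idx <- which(des$block == paste0("shape:", f))
      refn <- sum(abs(st1$theta[idx])^cfg$p)
      if (refn < 1e-8 * length(idx)) {
        warning("reference norm for feature '", f,
                "' below floor; penalty dropped")
        next
      }
      terms[[length(terms) + 1]] <- list(idx = idx, lambda = cfg$lambda_shape,
                                         ref = refn)
    }
  }
  st2 <- if (length(terms)) {
    optimize_projection(agn, des, cfg, start = st1$theta,
                        penalties = list(terms = terms, vref = vref))
  } else st1
  model <- theta_to_model(st2$theta, agn$k, des, shape_models, include_beta0)
  seqm <- to_sequence_representation(model)
  achieved <- if (cfg$loss == "kl") loss_kl(agn, seqm) else loss_affinity(agn, seqm)
  structure(list(model = model, seq_model = seqm, loss = achieved,
                 ref_loss = st1$value, ref_norm_mono = ref_mono,
                 config = cfg,
                 convergence = list(stage1 = st1$convergence,
                                    stage2 = st2$convergence)),
            class = "projection_result")
}

#' Unpenalized shape projection
#'
#' Stage 1 of \code{\link{project}} alone: minimizes the loss with no
#' penalty terms.  Exposed for diagnostics; the unpenalized problem is
#' poorly conditioned (near-null directions trade base readout against
#' shape sensitivity), so profiles from perturbed starts may differ while
#' score-level predictions agree.
#'
#' @inheritParams project
#' @param start Optional start vector (defaults to zeros).
#' @return A \code{projection_result} (with \code{ref_loss == loss}).
#' @export
unpenalized_project <- function(agn, shape_models, cfg = projection_config(),
                                start = NULL) {
  shape_models <- as_shape_models(shape_models)
  include_beta0 <- cfg$loss == "affinity"
  des <- projection_design(agn$k, shape_models, include_beta0)
  st <- optimize_projection(agn, des, cfg,
                            start = start %||% numeric(ncol(des$A)))
  model <- theta_to_model(st$theta, agn$k, des, shape_models, include_beta0)
  seqm <- to_sequence_representation(model)
  structure(list(model = model, seq_model = seqm, loss = st$value,
                 ref_loss = st$value, ref_norm_mono = NA_real_, config = cfg,
                 convergence = list(stage1 = st$convergence)),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection_result: loss=%.4g (unpenalized ref %.4g), features: %s\n",
              x$loss, x$ref_loss, paste(names(x$model$profiles), collapse = ", ")))
  invisible(x)
}

## Accept shape tables or fitted seq2shape models interchangeably.
as_shape_models <- function(shape_models) {
  stopifnot(is.list(shape_models), !is.null(names(shape_models)))
  lapply(shape_models, function(x) {
    if (inherits(x, "shape_table")) fit_seq2shape(x, "mono+di")
    else if (inherits(x, "seq2shape_model")) x
    else stop("shape_models entries must be shape_table or seq2shape_model")
  })
}

#' Penalized projection over a grid of penalty scales
#'
#' Convenience wrapper running \code{\link{project}} for every combination
#' of the supplied \code{lambda_mono} and \code{lambda_shape} values,
#' reusing one configuration otherwise.
#'
#' @inheritParams project
#' @param lambda_mono,lambda_shape Numeric vectors of penalty scales.
#' @return A data.frame with one row per grid point plus a list-column
#'   \code{result}.
#' @export
project_lambda_grid <- function(agn, shape_models,
                                lambda_mono = c(0.1, 1, 10),
                                lambda_shape = c(0.1, 1, 10),
                                cfg = projection_config()) {
  grid <- expand.grid(lambda_mono = lambda_mono, lambda_shape = lambda_shape)
  grid$result <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$lambda_mono <- grid$lambda_mono[i]
    cfg_i$lambda_shape <- grid$lambda_shape[i]
    project(agn, shape_models, cfg_i)
  })
  grid
}
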