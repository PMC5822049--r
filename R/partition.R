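#' Transfer-matrix partition sum of a binding model
#'
#' Evaluates \eqn{\sigma(\beta) = \sum_s e^{score(s)}} over all \code{4^k}
#' k-mers by a left-to-right transfer recursion over bases (cost O(k)
#' instead of O(4^k)), entirely in log space to avoid overflow.  The
#' gradient is obtained by a forward--backward sweep: the derivative of
#' \eqn{\log\sigma} with respect to each mononucleotide (dinucleotide)
#' coefficient is the corresponding single-position (adjacent-pair)
#' marginal probability under the Boltzmann distribution
#' \eqn{p(s) \propto e^{score(s)}}.
#'
#' @param model An \code{agn_model}.
#' @return A list with \code{log_sigma}; \code{sigma} (may overflow to
#'   \code{Inf} for extreme scores -- use \code{log_sigma}); and
#'   \code{grad_log}, a list with elements \code{beta0} (always 1),
#'   \code{beta1} (4 x k marginals) and \code{beta2} (16 x (k-1) pair
#'   marginals), so that \eqn{\nabla\sigma = \sigma \cdot grad\_log}.
#' @export
partition_sum <- function(model) {
  k <- model$k
  b1 <- model$beta1
  b2 <- model$beta2
  ## column-wise log-sum-exp of a 4 x 4 matrix; one global shift is enough
  ## for numerical safety (entries below the shift just underflow to 0)
  lse4 <- function(M) {
    mx <- max(M)
    e <- exp(M - mx)
    mx + log(e[1, ] + e[2, ] + e[3, ] + e[4, ])
  }
  f <- matrix(0, 4, k)
  f[, 1] <- b1[, 1]
  if (k >= 2) {
    for (j in 2:k) {
      ## B[d, c] = dinucleotide weight (first base c, second d) at step j-1
      B <- b2[, j - 1]
      dim(B) <- c(4, 4)
      f[, j] <- b1[, j] + lse4(t(B) + f[, j - 1])
    }
  }
  mx <- max(f[, k])
  logZ0 <- mx + log(sum(exp(f[, k] - mx)))
  bwd <- matrix(0, 4, k)
  if (k >= 2) {
    for (j in (k - 1):1) {
      B <- b2[, j]
      dim(B) <- c(4, 4)
      bwd[, j] <- lse4(B + (b1[, j + 1] + bwd[, j + 1]))
    }
  }
  marg1 <- exp(f + bwd - logZ0)
  marg2 <- matrix(0, 16, max(k - 1, 0))
  if (k >= 2) {
    for (j in seq_len(k - 1)) {
      B <- b2[, j]
      dim(B) <- c(4, 4)
      lp <- rep(f[, j], each = 4) + B + (b1[, j + 1] + bwd[, j + 1]) - logZ0
      ## column-major [d, c] is exactly the (c-1)*4 + d dinucleotide coding
      marg2[, j] <- exp(as.vector(lp))
    }
  }
  log_sigma <- model$beta0 + logZ0
  list(log_sigma = log_sigma, sigma = exp(log_sigma),
       grad_log = list(beta0 = 1, beta1 = marg1, beta2 = marg2))
}

## Lightweight agn_model construction for optimizer hot paths (no
## validation, no dimnames).
agn_fast <- function(beta0, beta1, beta2) {
  structure(list(k = ncol(beta1), beta0 = beta0, beta1 = beta1,
                 beta2 = beta2),
            class = "agn_model")
}

## Flatten an agn_model's parameters (or a grad_log list) to one vector in
## the fixed order (beta0, beta1 column-major, beta2 column-major).
flatten_beta <- function(x) {
  c(x$beta0, as.vector(x$beta1), as.vector(x$beta2))
}

## Rebuild an agn_model from a flat parameter vector.
unflatten_beta <- function(v, k) {
  agn_fast(v[1], matrix(v[1 + seq_len(4 * k)], 4, k),
           matrix(v[1 + 4 * k + seq_len(16 * (k - 1))], 16, k - 1))
}

## Scale an agn_model's parameters by a scalar (beta -> a * beta).
scale_beta <- function(model, a) {
  agn_fast(a * model$beta0, a * model$beta1, a * model$beta2)
}

## Sum of two agn_models with equal footprints.
add_beta <- function(m1, m2) {
  agn_fast(m1$beta0 + m2$beta0, m1$beta1 + m2$beta1, m1$beta2 + m2$beta2)
}
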