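#' Energy-stratified sequence sampling for a scoring matrix
#'
#' Shows what shape preferences a scoring matrix encodes: sequences of the
#' footprint length are sampled uniformly within bins of the free-energy
#' score \eqn{W(s) = \sum_j w_{j,s_j}} (shifted so the best sequence scores
#' 0), so that the average shape profile per bin can be compared across
#' affinities.  Because extreme-W sequences are exponentially rare under
#' the uniform distribution, sampling runs Metropolis--Hastings chains
#' targeting Boltzmann distributions \eqn{p(s) \propto e^{\beta_T W(s)}}
#' on a grid of inverse temperatures (single-base-substitution proposals,
#' many parallel chains), then rejection-filters each (bin, temperature)
#' stratum back to uniformity using the analytic bin-edge bound on the
#' unweighting factor, and pools the accepted draws per bin.
#'
#' @param w 4 x k scoring matrix (rows A, C, G, T; \code{-ddG/RT}).
#' @param n_bins Number of uniform W bins over \code{[W_min, 0]}.
#' @param n_temps Number of inverse-temperature values, uniformly spaced
#'   over \code{log(4^k)/(-W_min) * c(-2, 2)}.
#' @param n_chains,steps,burnin,thin Chain geometry: parallel chains,
#'   post-burn-in steps, burn-in steps, thinning interval.
#' @param seed Integer seed.
#' @return An \code{energy_binned_sample}: per-bin sequences and scores;
#'   bins that attracted no draw are flagged empty (with a warning), not
#'   an error.
#' @export
sample_by_bin <- function(w, n_bins = 10, n_temps = 13, n_chains = 64,
                          steps = 1500, burnin = 150, thin = 5, seed = NULL) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == 4)
  k <- ncol(w)
  w0 <- sweep(w, 2, apply(w, 2, max))       # best sequence scores 0
  wmin <- sum(apply(w0, 2, min))
  betas <- if (wmin == 0) rep(0, n_temps) else {
    seq(-2, 2, length.out = n_temps) * log(4^k) / (-wmin)
  }
  edges <- seq(wmin, 0, length.out = n_bins + 1)
  seqs <- vector("list", n_bins)
  ws <- vector("list", n_bins)
  with_seed(seed, {
    for (bt in betas) {
      ## parallel MH chains with single-base-substitution proposals
      st <- matrix(sample.int(4, n_chains * k, replace = TRUE), n_chains, k)
      Wc <- rowSums(matrix(w0[cbind(as.vector(st), rep(seq_len(k), each = n_chains))],
                           n_chains, k))
      keep_states <- vector("list", ceiling(steps / thin))
      keep_W <- vector("list", ceiling(steps / thin))
      ki <- 0
      for (step in seq_len(burnin + steps)) {
        pos <- sample.int(k, n_chains, replace = TRUE)
        old <- st[cbind(seq_len(n_chains), pos)]
        new <- ((old - 1 + sample.int(3, n_chains, replace = TRUE)) %% 4) + 1
        dW <- w0[cbind(new, pos)] - w0[cbind(old, pos)]
        acc <- runif(n_chains) < exp(bt * dW)
        st[cbind(seq_len(n_chains), pos)[acc, , drop = FALSE]] <- new[acc]
        Wc <- Wc + dW * acc
        if (step > burnin && (step - burnin) %% thin == 0) {
          ki <- ki + 1
          keep_states[[ki]] <- st
          keep_W[[ki]] <- Wc
        }
      }
      allW <- unlist(keep_W[seq_len(ki)])
      allS <- do.call(rbind, keep_states[seq_len(ki)])
      bin <- pmin(pmax(findInterval(allW, edges, rightmost.closed = TRUE), 1),
                  n_bins)
      ## rejection to uniform within each bin: the sampled density within a
      ## bin is proportional to exp(bt * W); the analytic supremum of the
      ## unweighting factor exp(-bt * W) over the bin sits at the bin edge
      for (b in unique(bin)) {
        idx <- which(bin == b)
        edge <- if (bt > 0) edges[b] else edges[b + 1]
        pacc <- exp(-bt * (allW[idx] - edge))
        keep <- idx[runif(length(idx)) < pacc]
        if (length(keep)) {
          seqs[[b]] <- c(seqs[[b]], list(allS[keep, , drop = FALSE]))
          ws[[b]] <- c(ws[[b]], list(allW[keep]))
        }
      }
    }
  })
  sequences <- vector("list", n_bins)
  scores <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    if (length(seqs[[b]])) {
      mat <- do.call(rbind, seqs[[b]])
      sequences[[b]] <- kmers_from_base_matrix(mat)
      scores[[b]] <- unlist(ws[[b]])
    } else {
      sequences[[b]] <- character(0)
      scores[[b]] <- numeric(0)
    }
  }
  empty <- which(lengths(sequences) == 0)
  if (length(empty)) {
    warning("empty W bin(s): ", paste(empty, collapse = ", "))
  }
  structure(list(bins = data.frame(lo = edges[-(n_bins + 1)], hi = edges[-1]),
                 sequences = sequences, W = scores, k = k, w = w0,
                 w_min = wmin),
            class = "energy_binned_sample")
}

#' @export
print.energy_binned_sample <- function(x, ...) {
  cat(sprintf("energy_binned_sample: k=%d, %d bins over [%.3g, 0], sizes: %s\n",
              x$k, nrow(x$bins), x$w_min,
              paste(lengths(x$sequences), collapse = " ")))
  invisible(x)
}

## Per-sequence shape profile matrix (rows sequences, columns positions or
## steps) for equal-length sequences; NA outside the defined range.
profile_matrix <- function(seqs, table) {
  b <- base_matrix_from_kmers(seqs)
  L <- ncol(b)
  kw <- table$k
  vals <- unname(table$values)
  nw <- L - kw + 1
  if (nw < 1) stop("sequences shorter than the table window")
  idx <- matrix(1L, nrow(b), nw)
  for (w in seq_len(kw)) {
    idx <- idx + (b[, seq_len(nw) + w - 1, drop = FALSE] - 1L) * 4L^(kw - w)
  }
  center <- if (table$kind == "base-centered") (kw + 1) / 2 else kw / 2
  out <- matrix(NA_real_, nrow(b),
                if (table$kind == "base-centered") L else L - 1)
  out[, seq_len(nw) + center - 1] <- matrix(vals[idx], nrow(b), nw)
  out
}

#' Mean shape profiles per free-energy bin
#'
#' @param sample An \code{energy_binned_sample}.
#' @param tables Named list of \code{shape_table}s.
#' @return Named list (per feature) of \code{n_bins x positions} matrices
#'   of mean shape values; undefined edge positions are \code{NA}, empty
#'   bins give \code{NA} rows.
#' @export
mean_shape_by_bin <- function(sample, tables) {
  stopifnot(inherits(sample, "energy_binned_sample"))
  n_bins <- nrow(sample$bins)
  out <- list()
  for (f in names(tables)) {
    tb <- tables[[f]]
    npos <- if (tb$kind == "base-centered") sample$k else sample$k - 1
    M <- matrix(NA_real_, n_bins, npos)
    for (b in seq_len(n_bins)) {
      if (!length(sample$sequences[[b]])) next
      M[b, ] <- colMeans(profile_matrix(sample$sequences[[b]], tb))
    }
    out[[f]] <- M
  }
  out
}

#' Relative-affinity k-mer table from SELEX counts
#'
#' Simple count-ratio estimator: the ratio of round-one to round-zero
#' m-mer frequencies (sliding windows over the variable region, both
#' strands pooled), normalized so the top m-mer has relative affinity 1.
#'
#' @param data A \code{selex_dataset}.
#' @param m Window width.
#' @param pseudo Pseudocount added to both rounds.
#' @return Data frame with columns \code{kmer}, \code{count} (round one),
#'   \code{affinity}.
#' @export
affinity_kmer_table <- function(data, m = 10, pseudo = 0.5) {
  stopifnot(inherits(data, "selex_dataset"), m <= data$L)
  count_mers <- function(df) {
    acc <- new.env(parent = emptyenv())
    tot <- NULL
    for (o in seq_len(data$L - m + 1)) {
      km <- substr(df$seq, o, o + m - 1)
      part <- rowsum(df$count, km)
      v <- setNames(part[, 1], rownames(part))
      tot <- if (is.null(tot)) v else {
        allk <- union(names(tot), names(v))
        setNames(ifelse(is.na(tot[allk]), 0, tot[allk]) +
                 ifelse(is.na(v[allk]), 0, v[allk]), allk)
      }
    }
    ## pool both strands
    rc <- revcomp(names(tot))
    pooled <- tot
    extra <- setNames(tot, rc)
    allk <- union(names(pooled), names(extra))
    setNames(ifelse(is.na(pooled[allk]), 0, pooled[allk]) +
             ifelse(is.na(extra[allk]), 0, extra[allk]), allk)
  }
  c1 <- count_mers(data$round1)
  c0 <- count_mers(data$round0)
  allk <- union(names(c1), names(c0))
  n1 <- ifelse(is.na(c1[allk]), 0, c1[allk])
  n0 <- ifelse(is.na(c0[allk]), 0, c0[allk])
  ratio <- (n1 + pseudo) / sum(n1 + pseudo) /
    ((n0 + pseudo) / sum(n0 + pseudo))
  data.frame(kmer = allk, count = as.numeric(n1),
             affinity = as.numeric(ratio / max(ratio)))
}

#' Align high-affinity SELEX probes
#'
#' Retains m-mers with count and relative affinity above the thresholds,
#' aligns them to the top m-mer by maximizing base matches over shifts and
#' strands, builds a count-weighted frequency matrix from the aligned
#' m-mers, and finally aligns every probe containing a retained m-mer to
#' the frequency matrix (best log-score placement over offsets and
#' strands).
#'
#' @param probes Character vector of probe sequences.
#' @param kmer_stats Data frame with columns \code{kmer}, \code{count},
#'   \code{affinity} (see \code{\link{affinity_kmer_table}}).
#' @param min_count Minimum m-mer count (default 100).
#' @param min_affinity Minimum relative affinity (default 0.1).
#' @param pseudo Pseudocount for the frequency-matrix log-score.
#' @return A list with \code{aligned} (extracted windows), \code{offset},
#'   \code{strand}, \code{retained} (the m-mers used) and
#'   \code{freq_matrix}; empty (with a warning) if nothing passes the
#'   filters.
#' @export
align_high_affinity_probes <- function(probes, kmer_stats, min_count = 100,
                                       min_affinity = 0.1, pseudo = 0.5) {
  stopifnot(all(c("kmer", "count", "affinity") %in% names(kmer_stats)))
  keep <- kmer_stats$count >= min_count & kmer_stats$affinity >= min_affinity
  retained <- kmer_stats[keep, , drop = FALSE]
  if (!nrow(retained)) {
    warning("no m-mer passes the count/affinity filters")
    return(list(aligned = character(0), offset = integer(0),
                strand = character(0), retained = retained,
                freq_matrix = NULL))
  }
  m <- nchar(retained$kmer[1])
  top <- retained$kmer[which.max(retained$affinity)]
  topv <- drop(base_matrix_from_kmers(top))
  ## align each retained m-mer to the top m-mer (shift x strand)
  place <- function(km) {
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") km else revcomp(km)
      sv <- drop(base_matrix_from_kmers(s))
      for (d in -(m - 1):(m - 1)) {
        i1 <- max(1, 1 + d):min(m, m + d)     # top coords overlapped
        i2 <- i1 - d
        sc <- sum(topv[i1] == sv[i2])
        cand <- list(d = d, strand = strand, score = sc)
        if (is.null(best) || sc > best$score ||
            (sc == best$score && abs(d) < abs(best$d)) ||
            (sc == best$score && abs(d) == abs(best$d) &&
             strand == "+" && best$strand == "-")) {
          best <- cand
        }
      }
    }
    best
  }
  pl <- lapply(retained$kmer, place)
  dmin <- min(vapply(pl, `[[`, 0, "d"))
  dmax <- max(vapply(pl, `[[`, 0, "d"))
  width <- (dmax + m) - dmin
  fm <- matrix(pseudo, 4, width)
  for (i in seq_along(pl)) {
    s <- if (pl[[i]]$strand == "+") retained$kmer[i] else revcomp(retained$kmer[i])
    sv <- drop(base_matrix_from_kmers(s))
    cols <- (pl[[i]]$d - dmin) + seq_len(m)
    fm[cbind(sv, cols)] <- fm[cbind(sv, cols)] + retained$count[i]
  }
  lfm <- log(sweep(fm, 2, colSums(fm), "/"))
  ## keep probes containing a retained m-mer on either strand
  pats <- unique(c(retained$kmer, revcomp(retained$kmer)))
  has <- vapply(probes, function(p) any(vapply(pats, grepl, TRUE, x = p,
                                               fixed = TRUE)), TRUE)
  probes <- probes[has]
  aligned <- character(0); offs <- integer(0); strands <- character(0)
  for (p in probes) {
    bestsc <- -Inf; bestw <- NULL; besto <- NA; bests <- NA
    for (strand in c("+", "-")) {
      s <- if (strand == "+") p else revcomp(p)
      if (nchar(s) < width) next
      sv <- drop(base_matrix_from_kmers(s))
      for (o in seq_len(nchar(s) - width + 1)) {
        sc <- sum(lfm[cbind(sv[o:(o + width - 1)], seq_len(width))])
        if (sc > bestsc) {
          bestsc <- sc; besto <- o; bests <- strand
          bestw <- substr(s, o, o + width - 1)
        }
      }
    }
    if (!is.null(bestw)) {
      aligned <- c(aligned, bestw); offs <- c(offs, besto)
      strands <- c(strands, bests)
    }
  }
  list(aligned = aligned, offset = offs, strand = strands,
       retained = retained, freq_matrix = lfm)
}
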