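#' k-mer shape tables
#'
#' A \code{shape_table} is a complete mapping from all \code{4^k} DNA k-mers
#' to one structural parameter value.  Base-pair parameters (minor groove
#' width MGW, propeller twist ProT) live on pentamers centered at a base
#' pair (\code{kind = "base-centered"}, window offsets -2..+2); base-pair
#' step parameters (Roll, helix twist HelT) live on tetramers centered at
#' the step between window offsets 0 and +1 (\code{kind = "step-centered"},
#' offsets -1..+2).
#'
#' @param values Numeric vector of length \code{4^k} in lexicographic k-mer
#'   order (or named by k-mer, in which case it is reordered).
#' @param kind \code{"base-centered"} or \code{"step-centered"}.
#' @param feature Label such as \code{"MGW"}, \code{"ProT"}, \code{"Roll"},
#'   \code{"HelT"} or a \code{"synthetic-*"} tag.
#' @param units Measurement units; defaults chosen from the feature name
#'   (Angstrom for MGW, degrees for the angular parameters).
#' @return An object of class \code{shape_table}.
#' @export
shape_table <- function(values, kind = c("base-centered", "step-centered"),
                        feature = "synthetic", units = NULL) {
  kind <- match.arg(kind)
  k <- round(log(length(values), 4))
  if (4^k != length(values)) {
    stop("length of 'values' must be a power of 4")
  }
  if (!is.null(names(values))) {
    km <- all_kmers(k)
    if (!setequal(names(values), km)) {
      stop("named 'values' must cover every ", k, "-mer exactly once")
    }
    values <- values[km]
  }
  if (anyNA(values)) stop("incomplete table: ", sum(is.na(values)), " missing entries")
  if (is.null(units)) {
    units <- switch(feature, MGW = "angstrom",
                    ProT = , Roll = , HelT = "degrees", "arbitrary")
  }
  structure(list(feature = feature, k = as.integer(k), kind = kind,
                 values = setNames(as.numeric(values), all_kmers(k)),
                 units = units),
            class = "shape_table")
}

#' @export
print.shape_table <- function(x, ...) {
  cat(sprintf("shape_table '%s' (%s, k=%d, units=%s)\n",
              x$feature, x$kind, x$k, x$units))
  cat(sprintf("  %d values, mean %.4g, sd %.4g, RC-symmetric: %s\n",
              length(x$values), mean(x$values), sd(x$values),
              is_rc_symmetric(x)))
  invisible(x)
}

#' Read a k-mer shape table from tab-separated text
#'
#' The canonical dialect is \code{KMER<TAB>VALUE}, uppercase ACGT, one row
#' per k-mer, with \code{#}-prefixed comment lines allowed.  The table must
#' be complete: every k-mer of the inferred length must appear exactly once.
#'
#' @param path File path.
#' @inheritParams shape_table
#' @return A \code{shape_table}.
#' @export
read_shape_table <- function(path, kind = c("base-centered", "step-centered"),
                             feature = NULL, units = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad_shape <- which(lengths(fields) != 2)
  if (length(bad_shape)) {
    stop("parse error at line ", lineno[bad_shape[1]],
         ": expected 'KMER<TAB>VALUE'")
  }
  km <- vapply(fields, `[[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(grepl("[^ACGT]", km) | nchar(km) != nchar(km[1]) | is.na(val))
  if (length(bad)) {
    stop("parse error at line ", lineno[bad[1]], ": '", lines[lineno[bad[1]]], "'")
  }
  k <- nchar(km[1])
  if (anyDuplicated(km)) {
    stop("duplicate k-mer '", km[anyDuplicated(km)], "' in ", path)
  }
  expect <- all_kmers(k)
  missing <- setdiff(expect, km)
  if (length(missing)) {
    stop("incomplete table: ", length(missing), " missing ", k, "-mer(s), ",
         "e.g. ", paste(head(missing, 3), collapse = ", "))
  }
  if (is.null(feature)) feature <- sub("\\.[^.]*$", "", basename(path))
  shape_table(setNames(val, km), kind = kind, feature = feature, units = units)
}

#' Write a k-mer shape table
#'
#' Values are written with \code{\%.17g} so that
#' \code{read_shape_table(write_shape_table(x))} round-trips bit-exactly.
#'
#' @param table A \code{shape_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_shape_table <- function(table, path) {
  stopifnot(inherits(table, "shape_table"))
  header <- sprintf("# feature=%s kind=%s k=%d units=%s",
                    table$feature, table$kind, table$k, table$units)
  body <- sprintf("%s\t%.17g", names(table$values), table$values)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Reverse-complement symmetrize a shape table
#'
#' Replaces each value by the average of the values of the k-mer and its
#' reverse complement, the physical statement that the two DNA strands
#' describe the same double helix.  Idempotent.
#'
#' @param table A \code{shape_table}.
#' @return A symmetrized \code{shape_table}.
#' @export
rc_symmetrize <- function(table) {
  stopifnot(inherits(table, "shape_table"))
  p <- rc_permutation(table$k)
  table$values[] <- (table$values + table$values[p]) / 2
  table
}

#' Test reverse-complement symmetry
#'
#' @param table A \code{shape_table}.
#' @param tol Absolute tolerance.
#' @return Logical scalar.
#' @export
is_rc_symmetric <- function(table, tol = 1e-12) {
  p <- rc_permutation(table$k)
  max(abs(table$values - table$values[p])) <= tol
}

#' Permute a shape table among reverse-complement classes
#'
#' Values are permuted among reverse-complement equivalence classes
#' \code{{s, revcomp(s)}} so that the result stays RC-symmetric and the
#' multiset of class values is exactly preserved.  Palindromic k-mers form
#' singleton classes and are permuted among themselves.
#'
#' @param table An RC-symmetric \code{shape_table}.
#' @param seed Integer seed controlling the permutation.
#' @return A permuted \code{shape_table}.
#' @export
permute_table <- function(table, seed = NULL) {
  stopifnot(inherits(table, "shape_table"))
  if (!is_rc_symmetric(table)) {
    stop("permute_table requires a reverse-complement-symmetric table")
  }
  cls <- rc_classes(table$k)
  sizes <- lengths(cls)
  reps <- vapply(cls, `[[`, 0L, 1L)
  vals <- table$values[reps]
  new_vals <- vals
  with_seed(seed, {
    for (sz in unique(sizes)) {
      i <- which(sizes == sz)
      new_vals[i] <- vals[i][sample.int(length(i))]
    }
  })
  out <- table$values
  for (j in seq_along(cls)) out[cls[[j]]] <- new_vals[j]
  table$values[] <- out
  table$feature <- paste0(table$feature, "-permuted")
  table
}

#' Raw pentamer step-parameter table
#'
#' The source tables for the step parameters Roll and HelT report two values
#' per pentamer: one at the step between bases 2 and 3 and one at the step
#' between bases 3 and 4 (1-based).
#'
#' @param first Numeric vector of length 1024 (value at step 2-3), in
#'   lexicographic pentamer order or named by pentamer.
#' @param second Same for the step 3-4 value.
#' @param feature Feature label.
#' @return An object of class \code{raw_step_table}.
#' @export
raw_step_table <- function(first, second, feature = "step") {
  pent <- all_kmers(5)
  fix <- function(v) {
    if (!is.null(names(v))) v <- v[pent]
    stopifnot(length(v) == 1024, !anyNA(v))
    setNames(as.numeric(v), pent)
  }
  structure(list(feature = feature, first = fix(first), second = fix(second)),
            class = "raw_step_table")
}

#' Recenter a raw pentamer step table onto tetramers
#'
#' Each tetramer value is the average of the two per-pentamer step values
#' after marginalizing over the rightmost base (for the step 2-3 value) and
#' the leftmost base (for the step 3-4 value), aligning both on the central
#' step of the tetramer.  The result is then reverse-complement symmetrized.
#'
#' @param raw A \code{raw_step_table}.
#' @return A step-centered \code{shape_table} over all 256 tetramers.
#' @export
center_step_table <- function(raw) {
  stopifnot(inherits(raw, "raw_step_table"))
  tets <- seq_len(256L)
  ## pentamer index of (t1 t2 t3 t4, b): (t-1)*4 + b ; of (b, t1..t4): (b-1)*256 + t
  m_first <- vapply(1:4, function(b) raw$first[(tets - 1L) * 4L + b], numeric(256))
  m_second <- vapply(1:4, function(b) raw$second[(b - 1L) * 256L + tets], numeric(256))
  v <- 0.5 * (rowMeans(m_first) + rowMeans(m_second))
  rc_symmetrize(shape_table(setNames(v, all_kmers(4)), kind = "step-centered",
                            feature = raw$feature))
}

#' Synthesize a shape table from a sequence-to-shape model
#'
#' Builds the table predicted by a coefficient model, adds independent
#' Gaussian measurement noise, and reverse-complement symmetrizes the
#' result (noise is added before symmetrization, mimicking independent
#' per-k-mer measurement error).
#'
#' @param model A \code{seq2shape_model} (see \code{\link{fit_seq2shape}})
#'   supplying the window length, kind and coefficients.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @param feature Feature label for the resulting table.
#' @return An RC-symmetric \code{shape_table}.
#' @export
synthesize_table <- function(model, noise_sd = 0, seed = NULL,
                             feature = "synthetic") {
  pred <- predict_all_kmers(model)
  vals <- with_seed(seed, pred + rnorm(length(pred), sd = noise_sd))
  rc_symmetrize(shape_table(setNames(vals, all_kmers(model$k)),
                            kind = model$kind, feature = feature,
                            units = "arbitrary"))
}
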