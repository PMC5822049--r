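#!/usr/bin/env Rscript

## Optional external validation against the real DNAshape-derived pentamer
## tables, which are not distributed with this package.  Supply a
## directory of k-mer tables in the canonical text format
## (KMER<TAB>VALUE):
##
##   MGW.tsv, ProT.tsv        pentamer tables (base-centered)
##   Roll.tsv, HelT.tsv       either recentered tetramer tables, or raw
##                            3-column pentamer step tables
##                            (PENTAMER<TAB>STEP23<TAB>STEP34) named
##                            Roll.raw.tsv / HelT.raw.tsv
##
## Usage:
##   Rscript scripts/external_validation.R --tables <dir> [--out <path>]
##
## Reports leave-one-out cross-validated R-squared for the
## mononucleotide-only and mono+dinucleotide sequence-to-shape models of
## each feature.

suppressPackageStartupMessages(library(shapeproj))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(tables = NULL, out = NULL)
i <- 1
while (i < length(args) + 1) {
  if (args[i] == "--tables") { opt$tables <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}
if (is.null(opt$tables)) {
  stop("no shape tables supplied: pass --tables <dir> containing the ",
       "DNAshape-derived pentamer tables (MGW.tsv, ProT.tsv, Roll[.raw].tsv, ",
       "HelT[.raw].tsv); they are not shipped with this package")
}

load_feature <- function(dir, feature, kind) {
  raw <- file.path(dir, paste0(feature, ".raw.tsv"))
  flat <- file.path(dir, paste0(feature, ".tsv"))
  if (kind == "step-centered" && file.exists(raw)) {
    df <- read.table(raw, header = FALSE,
                     col.names = c("kmer", "first", "second"),
                     colClasses = c("character", "numeric", "numeric"))
    return(center_step_table(raw_step_table(setNames(df$first, df$kmer),
                                            setNames(df$second, df$kmer),
                                            feature = feature)))
  }
  if (!file.exists(flat)) stop("missing table file for ", feature, ": ", flat)
  rc_symmetrize(read_shape_table(flat, kind = kind, feature = feature))
}

features <- list(MGW = "base-centered", ProT = "base-centered",
                 Roll = "step-centered", HelT = "step-centered")
rows <- list()
for (f in names(features)) {
  tb <- load_feature(opt$tables, f, features[[f]])
  r2_mono <- loo_cv_r2(tb, "mono")
  r2_modi <- loo_cv_r2(tb, "mono+di")
  rows[[f]] <- data.frame(feature = f, k = tb$k, kind = tb$kind,
                          r2_mono = r2_mono, r2_monodi = r2_modi)
  cat(sprintf("%-5s (k=%d, %s): LOO R2 mono = %.3f, mono+di = %.3f\n",
              f, tb$k, tb$kind, r2_mono, r2_modi))
}
out <- do.call(rbind, rows)
if (!is.null(opt$out)) {
  write.table(out, opt$out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("wrote", opt$out, "\n")
}
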