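#' @importFrom stats median sd setNames rpois rgamma rlnorm runif chisq.test
#'   ks.test ecdf complete.cases
#' @importFrom utils write.table read.table head tail
NULL

# Reverse-complement of a DNA string (A,C,G,T,N).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# substring of a genome sequence, 1-based closed coordinates
subseq_chr <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seq)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  substr(genome$seq[[chrom]], start, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_codons <- c("TAA", "TAG", "TGA")

# DNA -> RNA-style label used for strata and enrichment tables (TGA -> UGA)
rna_label <- function(x) chartr("T", "U", x)
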