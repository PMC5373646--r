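#' Genes eligible for post-ORF occupancy analysis
#'
#' A gene enters the RPOR analysis when its downstream intergenic gap is at
#' least \code{min_gap} nt, its mean footprint and mean mRNA densities over
#' the full (unmasked) ORF are both at least \code{min_density} RPM/nt, and
#' it does not overlap its downstream neighbour. All bounds are inclusive.
#'
#' @param orfs An \code{orf_table} with gaps computed.
#' @param fp_track,mrna_track \code{density_track}s in RPM units;
#'   \code{mrna_track = NULL} skips the mRNA density requirement.
#' @param min_gap Minimum intergenic gap (nt). Default 65.
#' @param min_density Minimum mean density (RPM/nt). Default 0.1.
#' @return Logical vector over the rows of \code{orfs}.
#' @export
eligible_genes <- function(orfs, fp_track, mrna_track = NULL,
                           min_gap = 65, min_density = 0.1) {
  n <- nrow(orfs)
  keep <- logical(n)
  for (i in seq_len(n)) {
    gene <- orfs[i, ]
    if (gene$overlaps_next) next
    if (is.na(gene$downstream_gap) || gene$downstream_gap < min_gap) next
    fp_mean <- mean(gene_signal(fp_track, gene), na.rm = TRUE)
    if (!is.finite(fp_mean) || fp_mean < min_density) next
    if (!is.null(mrna_track)) {
      mr_mean <- mean(gene_signal(mrna_track, gene), na.rm = TRUE)
      if (!is.finite(mr_mean) || mr_mean < min_density) next
    }
    keep[i] <- TRUE
  }
  keep
}

#' Relative post-ORF ribosome occupancy (RPOR) of one gene
#'
#' RPOR = mean footprint density in a window 20-60 nt past the stop codon,
#' divided by the mean density over the ORF (first and last 5 codons
#' masked). The post-ORF window is half-open \code{[post_from, post_to)}
#' counted from the first base after the stop codon (default offsets 20-59,
#' 40 nt); starting 20 nt out keeps ribosomes sitting on the stop codon
#' itself from contributing. RPOR roughly estimates the fraction of
#' ribosomes that continue past the stop.
#'
#' @param gene One row of an \code{orf_table}.
#' @param fp_track Footprint \code{density_track}.
#' @param post_from,post_to Post-ORF window, half-open, 0-offset = first
#'   base after the stop codon. Defaults 20 and 60.
#' @param mask_codons Codons masked at each ORF end for the denominator.
#'   Default 5.
#' @return List with \code{gene_id, orf_mean, post_mean, rpor}, or
#'   \code{NULL} when the ORF mean is zero (ratio undefined).
#' @export
rpor <- function(gene, fp_track, post_from = 20L, post_to = 60L,
                 mask_codons = 5L) {
  q <- rpkm(gene, fp_track, mask_codons)
  orf_mean <- q$mean_density
  if (!is.finite(orf_mean) || orf_mean <= 0) return(NULL)
  post <- post_orf_signal(fp_track, gene, post_to)
  post <- post[(post_from + 1L):post_to]
  post[is.na(post)] <- 0
  if (fp_track$units == "raw") post <- post * 1e6 / fp_track$total_mapped
  post_mean <- mean(post)
  list(gene_id = gene$gene_id, orf_mean = orf_mean, post_mean = post_mean,
       rpor = post_mean / orf_mean)
}

#' RPOR for all eligible genes
#'
#' @param orfs An \code{orf_table}.
#' @param fp_track,mrna_track \code{density_track}s in RPM units.
#' @param min_gap,min_density Eligibility thresholds, see
#'   \code{\link{eligible_genes}}.
#' @param ... Passed to \code{\link{rpor}}.
#' @return Data frame with \code{gene_id, orf_mean, post_mean, rpor}, one
#'   row per eligible gene with a nonzero ORF mean.
#' @export
rpor_table <- function(orfs, fp_track, mrna_track = NULL, min_gap = 65,
                       min_density = 0.1, ...) {
  keep <- eligible_genes(orfs, fp_track, mrna_track, min_gap, min_density)
  rows <- list()
  for (i in which(keep)) {
    r <- rpor(orfs[i, ], fp_track, ...)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- as.data.frame(r)
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(), orf_mean = numeric(),
                      post_mean = numeric(), rpor = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RPOR values prepared for distribution comparison
#'
#' Zero values are removed by default: a zero cannot be resolved between
#' genuinely no readthrough and insufficient read depth, and zeros inflate
#' the K-S statistic.
#'
#' @param records Data frame from \code{\link{rpor_table}}, or a numeric
#'   vector of RPOR values.
#' @param drop_zeros Remove zeros. Default \code{TRUE}.
#' @return Sorted ascending numeric vector.
#' @export
rpor_distribution <- function(records, drop_zeros = TRUE) {
  v <- if (is.data.frame(records)) records$rpor else records
  if (drop_zeros) v <- v[v > 0]
  if (!length(v)) stop("no RPOR values remain after zero removal")
  sort(v)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is the standard asymptotic two-sided approximation.
#'
#' @param a,b Numeric samples.
#' @return A \code{ks_result}: list with \code{d_statistic, p_value, n1,
#'   n2}.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(d_statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n1 = length(a), n2 = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat("two-sample K-S: D =", format(x$d_statistic, digits = 4),
      ", p =", format(x$p_value, digits = 3),
      sprintf("(n1 = %d, n2 = %d)\n", x$n1, x$n2))
  invisible(x)
}

#' Histogram of RPOR values above a floor
#'
#' Counts per half-open bin \code{[lo, lo + width)} over values at least
#' \code{min_value} (boundary included).
#'
#' @param records \code{rpor_table} output or numeric vector.
#' @param min_value Floor; values below it are excluded. Default 0.2.
#' @param bin_width Bin width. Default 0.2.
#' @param max_value Upper edge of the last regular bin; values at or above
#'   it go into a final overflow bin. Default 2.
#' @return Data frame with \code{bin_lo, bin_hi, count}.
#' @export
rpor_histogram <- function(records, min_value = 0.2, bin_width = 0.2,
                           max_value = 2) {
  v <- if (is.data.frame(records)) records$rpor else records
  v <- v[v >= min_value]
  lo <- seq(min_value, max_value, by = bin_width)
  hi <- c(lo[-1L], Inf)
  counts <- if (length(v)) tabulate(findInterval(v, lo), nbins = length(lo))
    else integer(length(lo))
  data.frame(bin_lo = lo, bin_hi = hi, count = counts)
}
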