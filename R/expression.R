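#' Gene-level RPKM with end masking
#'
#' Sums signal over the ORF excluding the first and last \code{mask_codons}
#' codons (default 5, i.e. 15 nt each end) and normalizes for masked length
#' and sequencing depth: RPKM = counts x 1e9 / (masked length x depth).
#' Computed from an RPM track this reduces to mean(RPM/nt) x 1000, which is
#' how it is evaluated (single source of truth for depth). An ORF too short
#' to mask falls back to the unmasked ORF with \code{masked = FALSE}.
#'
#' @param gene One row of an \code{orf_table}.
#' @param track A \code{density_track} (RPM or raw units).
#' @param mask_codons Codons masked at each end. Default 5.
#' @return List with \code{counts} (raw weighted counts over the quantified
#'   span), \code{rpkm}, \code{mean_density} (RPM/nt), and \code{masked}.
#' @export
rpkm <- function(gene, track, mask_codons = 5L) {
  mask_nt <- mask_codons * 3L
  masked <- gene$length > 2L * mask_nt
  sig <- gene_signal(track, gene)
  if (masked) sig <- sig[(mask_nt + 1L):(length(sig) - mask_nt)]
  sig[is.na(sig)] <- 0
  counts <- raw_counts(track, sig)
  mean_rpm <- if (track$units == "rpm") mean(sig)
    else mean(sig) * 1e6 / track$total_mapped
  list(counts = counts, rpkm = mean_rpm * 1000, mean_density = mean_rpm,
       masked = masked)
}

#' Quantify footprint and mRNA expression for all genes
#'
#' Computes masked RPKM for footprints and mRNA, translation efficiency
#' (TE = footprint RPKM / mRNA RPKM), and the comparability gate: a gene is
#' comparable only when it has at least \code{min_counts} raw counts in both
#' signals.
#'
#' @param genes An \code{orf_table}.
#' @param fp_track Footprint \code{density_track}.
#' @param mrna_track mRNA \code{density_track}, or \code{NULL} to skip
#'   mRNA/TE columns.
#' @param mask_codons Codons masked at each ORF end. Default 5.
#' @param min_counts Count gate for comparisons. Default 100.
#' @return Data frame with columns \code{gene_id, fp_counts, fp_rpkm,
#'   mrna_counts, mrna_rpkm, te, comparable, masked}.
#' @export
quantify_expression <- function(genes, fp_track, mrna_track = NULL,
                                mask_codons = 5L, min_counts = 100) {
  n <- nrow(genes)
  out <- data.frame(
    gene_id = genes$gene_id,
    fp_counts = NA_real_, fp_rpkm = NA_real_,
    mrna_counts = NA_real_, mrna_rpkm = NA_real_,
    te = NA_real_, comparable = FALSE, masked = NA,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    gene <- genes[i, ]
    fp <- rpkm(gene, fp_track, mask_codons)
    out$fp_counts[i] <- fp$counts
    out$fp_rpkm[i] <- fp$rpkm
    out$masked[i] <- fp$masked
    if (!is.null(mrna_track)) {
      mr <- rpkm(gene, mrna_track, mask_codons)
      out$mrna_counts[i] <- mr$counts
      out$mrna_rpkm[i] <- mr$rpkm
      out$te[i] <- if (mr$rpkm > 0) fp$rpkm / mr$rpkm else NA_real_
      out$comparable[i] <- fp$counts >= min_counts & mr$counts >= min_counts
    } else {
      out$comparable[i] <- fp$counts >= min_counts
    }
  }
  out
}

#' Translation efficiency with the comparison gate
#'
#' @param fp_rpkm,mrna_rpkm RPKM values for one gene.
#' @param fp_counts,mrna_counts Raw counts backing them.
#' @param min_counts Both signals need at least this many counts for the
#'   gene to be comparable. Default 100.
#' @return List with \code{te} (\code{NA} when mRNA RPKM is 0) and
#'   \code{comparable}.
#' @export
translation_efficiency <- function(fp_rpkm, mrna_rpkm, fp_counts,
                                   mrna_counts, min_counts = 100) {
  list(
    te = if (mrna_rpkm > 0) fp_rpkm / mrna_rpkm else NA_real_,
    comparable = fp_counts >= min_counts && mrna_counts >= min_counts
  )
}

#' Replicate mean and standard error
#'
#' @param values Numeric vector, one value per replicate.
#' @return List with \code{mean} and \code{sem} (sd / sqrt(n); \code{NA}
#'   for a single replicate).
#' @export
average_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no replicate values")
  list(mean = mean(values),
       sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_)
}

#' Percent frameshifting at a two-ORF locus
#'
#' Estimates programmed frameshifting (prfB-style: a short pre-shift ORF
#' followed by the long post-shift ORF) as 100 x RPKM(ORF2) / RPKM(ORF1).
#' Sub-ORF RPKMs are computed without end masking, since the pre-shift ORF
#' is typically only a couple of dozen codons. The estimate is invariant to
#' depth normalization.
#'
#' @param track A \code{density_track}.
#' @param chrom,strand Locus location.
#' @param orf1,orf2 Length-2 vectors \code{c(start, end)} (1-based closed,
#'   genomic) of the pre-shift and post-shift ORFs; \code{orf1} precedes
#'   \code{orf2} in transcription direction.
#' @return Percent frameshift (0-100+).
#' @export
frameshift_percent <- function(track, chrom, strand, orf1, orf2) {
  m1 <- mean(track_slice(track, chrom, strand, orf1[1], orf1[2]), na.rm = TRUE)
  m2 <- mean(track_slice(track, chrom, strand, orf2[1], orf2[2]), na.rm = TRUE)
  if (!is.finite(m1) || m1 <= 0) stop("pre-shift ORF has zero density")
  100 * m2 / m1
}

#' Translation-efficiency ratios of ORF pairs
#'
#' For each pair, downstream TE / upstream TE; pairs with ratio below
#' \code{flag_below} are flagged. Pairs with an undefined or non-comparable
#' member are skipped.
#'
#' @param pairs Data frame from \code{\link{overlapping_pairs}}.
#' @param expression Data frame from \code{\link{quantify_expression}}.
#' @param flag_below Flag threshold. Default 0.5.
#' @return Data frame with \code{upstream, downstream, te_ratio, flagged}.
#' @export
pair_te_ratio <- function(pairs, expression, flag_below = 0.5) {
  te <- setNames(expression$te, expression$gene_id)
  cmp <- setNames(expression$comparable, expression$gene_id)
  out <- pairs[, c("upstream", "downstream")]
  out$te_ratio <- NA_real_
  for (i in seq_len(nrow(out))) {
    up <- out$upstream[i]; dn <- out$downstream[i]
    if (!up %in% names(te) || !dn %in% names(te)) next
    if (!isTRUE(cmp[[up]]) || !isTRUE(cmp[[dn]])) next
    if (is.na(te[[up]]) || te[[up]] <= 0 || is.na(te[[dn]])) next
    out$te_ratio[i] <- te[[dn]] / te[[up]]
  }
  out <- out[!is.na(out$te_ratio), , drop = FALSE]
  out$flagged <- out$te_ratio < flag_below
  rownames(out) <- NULL
  out
}
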