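#' Find candidate stop codons in a post-ORF sequence
#'
#' Scans every offset of the given sequence (transcription direction,
#' starting at the first base after the annotated stop codon) for TAA, TAG
#' or TGA. The reading frame follows offset mod 3: 0 is frame 0
#' (readthrough), 1 is +1, 2 is -1 (a -1 frameshift lands on offsets
#' congruent to 2 mod 3).
#'
#' @param post_orf_sequence Nucleotide string.
#' @return Data frame with \code{offset} (0-based nt from the first
#'   post-stop base), \code{frame} (\code{0, +1, -1}) and \code{codon},
#'   sorted by offset.
#' @export
candidate_stops <- function(post_orf_sequence) {
  n <- nchar(post_orf_sequence)
  if (n < 3L) {
    return(data.frame(offset = integer(), frame = character(),
                      codon = character(), stringsAsFactors = FALSE))
  }
  tri <- substring(post_orf_sequence, 1:(n - 2L), 3:n)
  hit <- which(tri %in% stop_codons)
  off <- hit - 1L
  data.frame(
    offset = off,
    frame = c("0", "+1", "-1")[off %% 3L + 1L],
    codon = tri[hit],
    stringsAsFactors = FALSE
  )
}

#' Density drop across a candidate post-ORF stop codon
#'
#' The ratio of the mean density just after the candidate stop codon
#' (\code{[offset + 3, offset + 3 + post_window)}) to the mean density just
#' before it (\code{[max(0, offset - pre_window), offset)}), both windows
#' clipped to the post-ORF region. A genuine termination of post-ORF
#' translation at the candidate gives a ratio near 0.
#'
#' @param region Numeric vector of post-ORF density, position 1 = first
#'   base after the annotated stop codon, transcription direction.
#' @param offset Candidate stop offset (0-based, as returned by
#'   \code{\link{candidate_stops}}).
#' @param pre_window,post_window Window sizes in nt. Defaults 30.
#' @return Drop ratio in \code{[0, Inf)}, or \code{NA} when either window
#'   is empty (the post-window falls entirely beyond the region) or the
#'   pre-window mean is zero (undefined; candidate should be skipped).
#' @export
drop_score <- function(region, offset, pre_window = 30L, post_window = 30L) {
  n <- length(region)
  pre_idx <- if (offset <= 0L) integer(0)
    else seq.int(max(0L, offset - pre_window), offset - 1L)
  pre_idx <- pre_idx[pre_idx >= 0L & pre_idx < n] + 1L
  post_idx <- seq.int(offset + 3L, offset + 2L + post_window)
  post_idx <- post_idx[post_idx < n] + 1L
  if (!length(pre_idx) || !length(post_idx)) return(NA_real_)
  pre_mean <- mean(region[pre_idx])
  if (!is.finite(pre_mean) || pre_mean <= 0) return(NA_real_)
  mean(region[post_idx]) / pre_mean
}

# mean density over the pre-window only (gates candidates on signal level)
pre_window_density <- function(region, offset, pre_window = 30L) {
  n <- length(region)
  pre_idx <- seq.int(max(0L, offset - pre_window), offset - 1L)
  pre_idx <- pre_idx[pre_idx >= 0L & pre_idx < n] + 1L
  if (!length(pre_idx)) return(NA_real_)
  mean(region[pre_idx])
}

#' Classify one gene as a candidate recoding event
#'
#' Formalizes the density-drop rule: a gene is called a recoding candidate
#' when ribosome density in its post-ORF region falls off sharply after a
#' stop codon in some reading frame. The best candidate is the post-ORF
#' stop with the smallest drop ratio among candidates whose pre-window
#' density is at least \code{min_pre_density} (ties broken towards the
#' earliest offset). Classes:
#' \itemize{
#'   \item \code{unclassifiable} - fewer than \code{min_region_counts} raw
#'     counts in the post-ORF region (\code{low-reads} flag set);
#'   \item \code{likely} - best drop ratio at most \code{drop_threshold}
#'     and no confounder flags;
#'   \item \code{possible} - drop ratio passes but confounder flags are
#'     present;
#'   \item \code{misannotation-suspect} - a user-supplied downstream
#'     feature covers essentially all of the post-ORF signal;
#'   \item \code{non-recoding} - no qualifying drop at any frame.
#' }
#'
#' Confounder flags: \code{downstream-feature} (annotation within
#' \code{feature_margin} nt past the region), \code{user-interval-overlap}
#' (any supplied interval set, e.g. REP elements or sRNAs, intersects the
#' region), \code{SD-proximal} (a Shine-Dalgarno-like GGAGG match within
#' 15 nt upstream of a downstream ATG/GTG in the region), \code{low-reads}.
#'
#' @param gene One row of an \code{orf_table}.
#' @param genome A \code{genome_seq}.
#' @param track Footprint \code{density_track} (RPM units).
#' @param drop_threshold Maximum drop ratio to call recoding. Default 0.3.
#' @param min_pre_density Minimum pre-window mean density (RPM/nt) for a
#'   candidate to be scored. Default 0.2.
#' @param min_region_counts Minimum raw counts in the post-ORF region.
#'   Default 10.
#' @param confounders Named list of interval data frames (columns
#'   \code{chrom, start, end}), e.g. REP elements or sRNA annotations.
#' @param feature_margin Margin (nt) past the region end for the
#'   downstream-feature flag. Default 15.
#' @param pre_window,post_window Drop-score windows. Defaults 30.
#' @return A one-row data frame (class \code{recoding_call}) with
#'   \code{gene_id, class, offset, frame, codon, drop_ratio, flags}
#'   (comma-separated).
#' @export
classify_gene <- function(gene, genome, track, drop_threshold = 0.3,
                          min_pre_density = 0.2, min_region_counts = 10,
                          confounders = list(), feature_margin = 15L,
                          pre_window = 30L, post_window = 30L) {
  region_len <- if (is.na(gene$downstream_gap)) 0L
    else as.integer(gene$downstream_gap)
  call <- data.frame(
    gene_id = gene$gene_id, class = "non-recoding",
    offset = NA_integer_, frame = NA_character_, codon = NA_character_,
    drop_ratio = NA_real_, flags = "", stringsAsFactors = FALSE
  )
  if (region_len < 3L) {
    call$class <- "unclassifiable"
    call$flags <- "low-reads"
    return(call)
  }
  region <- post_orf_signal(track, gene, region_len)
  region[is.na(region)] <- 0
  if (track$units == "raw") region <- region * 1e6 / track$total_mapped
  flags <- character(0)

  if (raw_counts(track, region) < min_region_counts) {
    call$class <- "unclassifiable"
    call$flags <- "low-reads"
    return(call)
  }

  seq_region <- post_orf_sequence(genome, gene, region_len)
  cands <- candidate_stops(seq_region)

  # confounder flags
  region_iv <- if (gene$strand == "+") {
    c(gene$end + 1L, gene$end + region_len)
  } else {
    c(gene$start - region_len, gene$start - 1L)
  }
  misannotation <- FALSE
  sig_pos <- which(region >= min_pre_density)   # region-relative, 1-based
  sig_genomic <- if (gene$strand == "+") gene$end + sig_pos
    else gene$start - sig_pos
  for (nm in names(confounders)) {
    iv <- confounders[[nm]]
    hit <- iv$chrom == gene$chrom & iv$start <= region_iv[2] &
      iv$end >= region_iv[1]
    if (any(hit)) {
      flags <- c(flags, "user-interval-overlap")
      # a single supplied feature covering every high-signal position
      # fully explains the post-ORF signal
      if (length(sig_pos)) {
        for (j in which(hit)) {
          if (all(sig_genomic >= iv$start[j] & sig_genomic <= iv$end[j])) {
            misannotation <- TRUE
          }
        }
      }
    }
  }
  # signal running up against the downstream annotated feature suggests
  # ribosomes initiating there, not readthrough of this gene
  tail_idx <- seq.int(max(1L, region_len - feature_margin + 1L), region_len)
  if (mean(region[tail_idx]) >= min_pre_density) {
    flags <- c(flags, "downstream-feature")
  }
  flags <- setdiff(unique(flags), NA)
  if (sd_proximal(seq_region)) flags <- c(flags, "SD-proximal")

  # score candidates
  best <- NULL
  if (nrow(cands)) {
    ratios <- rep(NA_real_, nrow(cands))
    for (i in seq_len(nrow(cands))) {
      pre <- pre_window_density(region, cands$offset[i], pre_window)
      if (is.na(pre) || pre < min_pre_density) next
      ratios[i] <- drop_score(region, cands$offset[i], pre_window, post_window)
    }
    ok <- which(!is.na(ratios))
    if (length(ok)) {
      # minimal ratio; ties broken towards the earliest offset
      best_i <- ok[order(ratios[ok], cands$offset[ok])][1L]
      best <- cands[best_i, ]
      call$offset <- best$offset
      call$frame <- best$frame
      call$codon <- best$codon
      call$drop_ratio <- ratios[best_i]
    }
  }

  if (misannotation) {
    call$class <- "misannotation-suspect"
  } else if (!is.null(best) && call$drop_ratio <= drop_threshold) {
    call$class <- if (length(flags)) "possible" else "likely"
  } else {
    call$class <- "non-recoding"
  }
  call$flags <- paste(sort(flags), collapse = ",")
  class(call) <- c("recoding_call", "data.frame")
  call
}

# Shine-Dalgarno-like signal: GGAGG (complement of the anti-SD CCUCC)
# within 15 nt upstream of a downstream start codon in the region
sd_proximal <- function(seq_region) {
  starts <- gregexpr("ATG|GTG", seq_region)[[1]]
  if (starts[1] == -1L) return(FALSE)
  for (s in starts) {
    lo <- max(1L, s - 15L)
    if (s - lo >= 5L &&
        grepl("GGAGG", substr(seq_region, lo, s - 1L), fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Classify all eligible genes
#'
#' Runs \code{\link{classify_gene}} over the genes flagged by
#' \code{\link{eligible_genes}} (or all genes when \code{eligible} is
#' \code{NULL}).
#'
#' @param orfs An \code{orf_table}.
#' @param genome A \code{genome_seq}.
#' @param track Footprint \code{density_track}.
#' @param eligible Logical vector over \code{orfs} rows, or \code{NULL}.
#' @param ... Passed to \code{\link{classify_gene}}.
#' @return Data frame of calls, one row per gene.
#' @export
classify_genes <- function(orfs, genome, track, eligible = NULL, ...) {
  idx <- if (is.null(eligible)) seq_len(nrow(orfs)) else which(eligible)
  rows <- lapply(idx, function(i) {
    as.data.frame(classify_gene(orfs[i, ], genome, track, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stop-codon enrichment among recoding calls
#'
#' Pearson chi-squared goodness-of-fit of the observed stop-codon counts of
#' recoding candidates against expected counts from genome-wide stop-codon
#' frequencies; 2 degrees of freedom, two-tailed p from the chi-squared
#' distribution.
#'
#' @param observed Named counts over \code{UAA, UAG, UGA} (or
#'   \code{TAA, TAG, TGA}).
#' @param freqs Genome-wide frequencies over the same three codons, summing
#'   to 1.
#' @return List (class \code{enrichment_result}) with \code{observed,
#'   expected, chi2, df, p_value}.
#' @export
enrichment_chi2 <- function(observed, freqs) {
  if (length(observed) != 3L || length(freqs) != 3L) {
    stop("observed and freqs must cover the three stop codons")
  }
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  n <- sum(observed)
  if (n <= 0) stop("no calls to test")
  expected <- n * freqs
  if (any(expected <= 0)) stop("an expected count is zero")
  ct <- suppressWarnings(chisq.test(observed, p = freqs))
  structure(list(
    observed = observed,
    expected = expected,
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("stop-codon enrichment: chi2 =", format(x$chi2, digits = 6),
      "on", x$df, "df, p =", format(x$p_value, digits = 3), "\n")
  print(rbind(observed = x$observed, expected = x$expected))
  invisible(x)
}

#' Stop-codon frequencies of an annotation
#'
#' Frequencies of TAA/TAG/TGA among the (validated) annotated stop codons,
#' used as the expected distribution for enrichment testing.
#'
#' @param orfs An \code{orf_table}.
#' @return Named proportions over \code{UAA, UAG, UGA}.
#' @export
stop_codon_frequencies <- function(orfs) {
  tab <- table(factor(orfs$stop_codon, levels = stop_codons))
  setNames(as.numeric(tab) / sum(tab), rna_label(stop_codons))
}
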