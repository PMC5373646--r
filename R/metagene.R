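#' Per-gene stop-aligned normalized density window
#'
#' Extracts the signal over offsets \code{[-window_up, +window_down]}
#' relative to the first base of the stop codon (offset 0), in the gene's
#' 5' to 3' direction, and divides it by the mean density over the
#' normalization window (offsets \code{norm_window[1]} to
#' \code{norm_window[2]}, inclusive; default \code{[-100, -70]}, 31 nt,
#' i.e. 70-100 nt upstream of the stop codon).
#'
#' @param gene One row of an \code{orf_table} (as a list or one-row data
#'   frame).
#' @param track A \code{density_track}.
#' @param window_up,window_down Window extent (nt) upstream / downstream of
#'   the first stop-codon base. Defaults 100 and 60.
#' @param norm_window Inclusive offset range used for normalization.
#' @return Named numeric vector over offsets (names are offsets as
#'   characters), or \code{NULL} when the gene is ineligible: fewer than
#'   \code{window_up} nt upstream of the stop codon within the ORF, window
#'   out of chromosome bounds, or normalization-window mean 0 (division is
#'   never performed).
#' @export
gene_normalized_window <- function(gene, track, window_up = 100L,
                                   window_down = 60L,
                                   norm_window = c(-100L, -70L)) {
  vals <- stop_window_signal(gene, track, window_up, window_down)
  if (is.null(vals)) return(NULL)
  offsets <- (-window_up):window_down
  nw <- vals[offsets >= norm_window[1] & offsets <= norm_window[2]]
  m <- mean(nw)
  if (!is.finite(m) || m <= 0) return(NULL)
  setNames(vals / m, offsets)
}

# Raw (unnormalized) signal over stop-aligned offsets [-up, +down];
# NULL when the gene cannot host the window.
stop_window_signal <- function(gene, track, up = 100L, down = 60L) {
  if (gene$length < up + 3L) return(NULL)   # needs `up` nt upstream of the stop within the ORF
  if (gene$strand == "+") {
    p0 <- gene$end - 2L                      # first base of the stop codon
    lo <- p0 - up; hi <- p0 + down
    if (lo < 1L || hi > track$chrom_lengths[[gene$chrom]]) return(NULL)
    track_slice(track, gene$chrom, "+", lo, hi)
  } else {
    p0 <- gene$start + 2L
    lo <- p0 - down; hi <- p0 + up
    if (lo < 1L || hi > track$chrom_lengths[[gene$chrom]]) return(NULL)
    track_slice(track, gene$chrom, "-", lo, hi)
  }
}

#' Stop-codon-aligned metagene profile
#'
#' Aligns genes at their stop codons, normalizes each gene's window by its
#' own upstream (70-100 nt) mean, and takes the median across genes at each
#' offset. Two gene filters are applied, each individually switchable:
#' raw weighted counts in the normalization window must be at least
#' \code{min_window_counts}, and \code{downstream_gap} must be at least
#' \code{min_downstream_gap} (so a downstream coding frame does not bleed
#' into the window).
#'
#' The profile is invariant to uniform rescaling of the track.
#'
#' @param genes An \code{orf_table}.
#' @param track A \code{density_track} in RPM units.
#' @param min_window_counts Raw-count filter on the normalization window
#'   (default 1); \code{NULL} disables it.
#' @param min_downstream_gap Gap filter in nt (default 50); \code{NULL}
#'   disables it.
#' @param window_up,window_down,norm_window See
#'   \code{\link{gene_normalized_window}}.
#' @param stratum Label stored on the profile. Default \code{"all"}.
#' @return A \code{metagene_profile}: data frame with columns
#'   \code{offset, median_density, stderr, n_genes, stratum}.
#' @export
metagene_profile <- function(genes, track, min_window_counts = 1,
                             min_downstream_gap = 50,
                             window_up = 100L, window_down = 60L,
                             norm_window = c(-100L, -70L),
                             stratum = "all") {
  offsets <- (-window_up):window_down
  rows <- list()
  n_gap_fail <- 0L; n_count_fail <- 0L; n_window_fail <- 0L
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, ]
    if (!is.null(min_downstream_gap) &&
        (is.na(gene$downstream_gap) || gene$overlaps_next ||
         gene$downstream_gap < min_downstream_gap)) {
      n_gap_fail <- n_gap_fail + 1L
      next
    }
    raw <- stop_window_signal(gene, track, window_up, window_down)
    if (is.null(raw)) { n_window_fail <- n_window_fail + 1L; next }
    nw <- raw[offsets >= norm_window[1] & offsets <= norm_window[2]]
    if (!is.null(min_window_counts) &&
        raw_counts(track, nw) < min_window_counts) {
      n_count_fail <- n_count_fail + 1L
      next
    }
    m <- mean(nw)
    if (!is.finite(m) || m <= 0) { n_window_fail <- n_window_fail + 1L; next }
    rows[[length(rows) + 1L]] <- raw / m
  }
  if (!length(rows)) {
    stop("no genes survive the metagene filters (gap filter removed ",
         n_gap_fail, ", count filter removed ", n_count_fail,
         ", window/normalization removed ", n_window_fail, ")")
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(
    offset = offsets,
    median_density = apply(mat, 2L, median),
    stderr = NA_real_,
    n_genes = nrow(mat),
    stratum = stratum,
    stringsAsFactors = FALSE
  )
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile [", x$stratum[1], "]: offsets ",
      min(x$offset), "..", max(x$offset), ", ", x$n_genes[1],
      " gene(s); stop-peak (max over [-2,+4]) = ",
      format(stop_occupancy(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  plot(x$offset, x$median_density, type = "l",
       xlab = "offset from first stop-codon base (nt)",
       ylab = "median normalized density", ...)
  graphics::abline(v = c(0, 2), lty = 3)
  invisible(x)
}

#' Stratify genes by stop codon, four-base stop, or translation efficiency
#'
#' Partitions genes by their stop codon (labels UAA/UAG/UGA), by stop codon
#' plus fourth base (12 labels such as UGAA), and, when a translation
#' efficiency vector is supplied, adds the top decile by TE.
#'
#' @param genes An \code{orf_table}.
#' @param te Optional named numeric vector of translation efficiencies
#'   (names are gene ids).
#' @param decile Fraction of top-TE genes in the TE stratum. Default 0.1.
#' @return Named list of character vectors of gene ids.
#' @export
stratify <- function(genes, te = NULL, decile = 0.1) {
  out <- list()
  for (sc in stop_codons) {
    out[[rna_label(sc)]] <- genes$gene_id[genes$stop_codon == sc]
  }
  for (sc in stop_codons) {
    for (b in c("A", "C", "G", "T")) {
      lbl <- rna_label(paste0(sc, b))
      out[[lbl]] <- genes$gene_id[genes$stop_codon == sc &
                                  !is.na(genes$fourth_base) &
                                  genes$fourth_base == b]
    }
  }
  if (!is.null(te)) {
    te <- te[!is.na(te)]
    n_top <- max(1L, floor(length(te) * decile))
    top <- names(sort(te, decreasing = TRUE))[seq_len(n_top)]
    out[["top-TE-decile"]] <- intersect(genes$gene_id, top)
  }
  out
}

#' Combine replicate metagene profiles
#'
#' Per-offset mean of the replicate medians, with standard error
#' \code{sd / sqrt(n)} across replicates.
#'
#' @param profiles List of \code{metagene_profile}s with identical offsets
#'   and stratum.
#' @return A combined \code{metagene_profile}; \code{n_genes} is the mean
#'   replicate gene count.
#' @export
combine_replicates <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  strata <- unique(vapply(profiles, function(p) p$stratum[1], character(1)))
  if (length(strata) != 1L) {
    stop("profiles have mismatched strata: ", paste(strata, collapse = ", "))
  }
  offs <- profiles[[1]]$offset
  for (p in profiles[-1]) {
    if (!identical(p$offset, offs)) stop("profiles have mismatched offsets")
  }
  mat <- vapply(profiles, function(p) p$median_density,
                numeric(length(offs)))
  mat <- matrix(mat, nrow = length(offs))
  n <- ncol(mat)
  out <- data.frame(
    offset = offs,
    median_density = rowMeans(mat),
    stderr = if (n > 1L) apply(mat, 1L, sd) / sqrt(n) else NA_real_,
    n_genes = mean(vapply(profiles, function(p) p$n_genes[1], numeric(1))),
    stratum = strata,
    stringsAsFactors = FALSE
  )
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Scalar stop-codon occupancy of a metagene profile
#'
#' The peak of the median normalized density around the stop codon. By
#' default the maximum over offsets \code{[-2, +4]}, which captures the
#' stop peak under centre mapping; \code{method = "mean"} averages the three
#' stop-codon offsets \code{[0, 2]} instead.
#'
#' @param profile A \code{metagene_profile}.
#' @param window Inclusive offset window. Default \code{c(-2, 4)}.
#' @param method \code{"max"} (default) or \code{"mean"}.
#' @return Nonnegative scalar occupancy.
#' @export
stop_occupancy <- function(profile, window = c(-2L, 4L),
                           method = c("max", "mean")) {
  method <- match.arg(method)
  if (method == "mean") window <- c(0L, 2L)
  v <- profile$median_density[profile$offset >= window[1] &
                              profile$offset <= window[2]]
  if (method == "max") max(v) else mean(v)
}

#' Fold change in stop-codon occupancy between two profiles
#'
#' @param profile_a,profile_b \code{metagene_profile}s over the same
#'   offsets and stratum.
#' @param ... Passed to \code{\link{stop_occupancy}}.
#' @return \code{occupancy(a) / occupancy(b)}.
#' @export
stop_occupancy_ratio <- function(profile_a, profile_b, ...) {
  if (!identical(profile_a$offset, profile_b$offset)) {
    stop("profiles have mismatched offsets")
  }
  if (!identical(profile_a$stratum[1], profile_b$stratum[1])) {
    stop("profiles have mismatched strata")
  }
  den <- stop_occupancy(profile_b, ...)
  if (den == 0) stop("reference profile has zero stop occupancy")
  stop_occupancy(profile_a, ...) / den
}

#' Write a metagene profile to TSV
#'
#' @param profile A \code{metagene_profile}.
#' @param path Output path.
#' @export
write_metagene <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
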