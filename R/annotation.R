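#' Read a genome FASTA file
#'
#' Loads one or more chromosome sequences into a simple genome object used
#' throughout the package. Sequences are upper-cased and restricted to the
#' alphabet A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return An object of class \code{genome_seq}: a list with \code{seq}
#'   (named character vector of sequences) and \code{lengths} (named integer
#'   vector of chromosome lengths).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  # FASTA headers may carry descriptions; keep the first token as the id
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("genome sequence contains characters outside {A,C,G,T,N}: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq:", length(x$seq), "sequence(s),",
      format(sum(x$lengths), big.mark = ","), "nt total\n")
  invisible(x)
}

#' Load and validate an ORF annotation against a genome
#'
#' Reads ORF features from GFF3 or BED, validates each against the genome
#' (length a multiple of 3, genuine stop codon at the 3' end), and annotates
#' every record with its stop codon and the base following it (the "fourth
#' base") read in the direction of transcription. Coordinates are 1-based
#' closed internally; BED input (0-based half-open) is converted on read.
#'
#' ORFs failing validation (length not a multiple of 3, or no TAA/TAG/TGA at
#' the annotated 3' end) are excluded with a warning rather than raising an
#' error, since real annotations contain pseudogenes. A feature extending
#' beyond its chromosome is a hard error.
#'
#' @param genome A \code{genome_seq} object from \code{\link{read_genome}},
#'   or a path to a FASTA file.
#' @param annotation Path to a GFF3 (\code{.gff}/\code{.gff3}) or BED file,
#'   or a data frame with columns \code{gene_id, chrom, strand, start, end}
#'   (1-based closed).
#' @param feature_type For GFF3 input, the feature type to keep
#'   (default \code{"CDS"}; if absent from the file, all features are used).
#' @param keep_invalid Keep invalid records (flagged \code{valid = FALSE})
#'   instead of dropping them. Default \code{FALSE}.
#' @return A data frame of class \code{orf_table}, sorted by (chrom, start),
#'   with columns \code{gene_id, chrom, strand, start, end, length,
#'   stop_codon, fourth_base, downstream_gap, overlaps_next, valid}. Gap
#'   columns are filled by \code{\link{compute_gaps}}, which is called
#'   automatically.
#' @export
load_annotation <- function(genome, annotation, feature_type = "CDS",
                            keep_invalid = FALSE) {
  if (is.character(genome)) genome <- read_genome(genome)
  orfs <- if (is.data.frame(annotation)) {
    annotation
  } else {
    read_annotation_file(annotation, feature_type)
  }
  req <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(orfs))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  orfs <- orfs[order(orfs$chrom, orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL

  oob <- !(orfs$chrom %in% names(genome$lengths)) |
    orfs$start < 1 |
    orfs$end > unname(genome$lengths[orfs$chrom])
  if (any(oob)) {
    stop("feature(s) outside genome bounds: ",
         paste(orfs$gene_id[oob], collapse = ", "), call. = FALSE)
  }

  orfs$length <- orfs$end - orfs$start + 1L
  n <- nrow(orfs)
  orfs$stop_codon <- character(n)
  orfs$fourth_base <- character(n)
  for (i in seq_len(n)) {
    if (orfs$strand[i] == "+") {
      orfs$stop_codon[i] <- subseq_chr(genome, orfs$chrom[i],
                                       orfs$end[i] - 2L, orfs$end[i])
      orfs$fourth_base[i] <- if (orfs$end[i] < genome$lengths[[orfs$chrom[i]]]) {
        subseq_chr(genome, orfs$chrom[i], orfs$end[i] + 1L, orfs$end[i] + 1L)
      } else NA_character_
    } else {
      orfs$stop_codon[i] <- revcomp(subseq_chr(genome, orfs$chrom[i],
                                               orfs$start[i], orfs$start[i] + 2L))
      orfs$fourth_base[i] <- if (orfs$start[i] > 1L) {
        revcomp(subseq_chr(genome, orfs$chrom[i],
                           orfs$start[i] - 1L, orfs$start[i] - 1L))
      } else NA_character_
    }
  }
  orfs$valid <- orfs$length %% 3L == 0L & orfs$stop_codon %in% stop_codons
  if (any(!orfs$valid)) {
    warning(sum(!orfs$valid), " ORF(s) failed validation (length not a ",
            "multiple of 3 or no stop codon) and were excluded: ",
            paste(head(orfs$gene_id[!orfs$valid], 10L), collapse = ", "),
            call. = FALSE)
    if (!keep_invalid) {
      orfs <- orfs[orfs$valid, , drop = FALSE]
      rownames(orfs) <- NULL
    }
  }
  class(orfs) <- c("orf_table", "data.frame")
  compute_gaps(orfs, genome)
}

# rtracklayer-backed reader; returns a bare data frame in 1-based closed coords
read_annotation_file <- function(path, feature_type = "CDS") {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "gff3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == feature_type)) {
    gr <- gr[S4Vectors::mcols(gr)$type == feature_type]
  }
  mc <- S4Vectors::mcols(gr)
  ids <- if ("Name" %in% names(mc) && !all(is.na(mc$Name))) as.character(mc$Name)
    else if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
    else if ("name" %in% names(mc)) as.character(mc$name)
    else paste0("orf_", seq_along(gr))
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Convert an ORF table to a GRanges object
#'
#' @param orfs An \code{orf_table}.
#' @return A \code{GRanges} with \code{gene_id} in \code{name}.
#' @export
orfs_to_granges <- function(orfs) {
  GenomicRanges::GRanges(
    seqnames = orfs$chrom,
    ranges = IRanges::IRanges(start = orfs$start, end = orfs$end),
    strand = orfs$strand,
    name = orfs$gene_id
  )
}

#' Write an ORF table as BED6
#'
#' @param orfs An \code{orf_table}.
#' @param path Output path.
#' @export
write_orf_bed <- function(orfs, path) {
  rtracklayer::export(orfs_to_granges(orfs), path, format = "bed")
  invisible(path)
}

#' Compute downstream intergenic gaps
#'
#' For every ORF, the gap in nucleotides from the base immediately after its
#' stop codon to the first base of the nearest downstream annotated feature
#' in the direction of transcription. By default neighbours on either strand
#' are considered (the conservative reading: smaller gaps); set
#' \code{same_strand = TRUE} to restrict to same-strand neighbours. The last
#' gene on a chromosome gets the gap to the sequence end. A neighbour that
#' overlaps the ORF's stop codon sets \code{overlaps_next} and a gap of 0.
#'
#' Idempotent, and invariant under a shift of all coordinates.
#'
#' @param orfs An \code{orf_table} (sorted by chrom, start).
#' @param genome A \code{genome_seq} (needed for chromosome ends). If
#'   \code{NULL}, sequence-end gaps are set \code{NA}.
#' @param same_strand Consider only same-strand neighbours. Default
#'   \code{FALSE}.
#' @return The \code{orf_table} with \code{downstream_gap} and
#'   \code{overlaps_next} filled.
#' @export
compute_gaps <- function(orfs, genome = NULL, same_strand = FALSE) {
  n <- nrow(orfs)
  gap <- rep(NA_real_, n)
  ovl <- rep(FALSE, n)
  for (i in seq_len(n)) {
    others <- which(orfs$chrom == orfs$chrom[i] & seq_len(n) != i)
    if (same_strand) others <- others[orfs$strand[others] == orfs$strand[i]]
    if (orfs$strand[i] == "+") {
      # downstream = rightwards; neighbour boundary = its leftmost base
      ds <- others[orfs$start[others] > orfs$end[i] - 2L]
      if (length(ds)) {
        nxt <- min(orfs$start[ds])
        gap[i] <- max(0, nxt - orfs$end[i] - 1L)
        ovl[i] <- nxt <= orfs$end[i]
      } else if (!is.null(genome)) {
        gap[i] <- genome$lengths[[orfs$chrom[i]]] - orfs$end[i]
      }
      # a neighbour overlapping the stop codon itself
      if (any(orfs$start[others] <= orfs$end[i] &
              orfs$end[others] >= orfs$end[i] - 2L)) {
        ovl[i] <- TRUE
        gap[i] <- 0
      }
    } else {
      ds <- others[orfs$end[others] < orfs$start[i] + 2L]
      if (length(ds)) {
        nxt <- max(orfs$end[ds])
        gap[i] <- max(0, orfs$start[i] - nxt - 1L)
        ovl[i] <- nxt >= orfs$start[i]
      } else {
        gap[i] <- orfs$start[i] - 1L
      }
      if (any(orfs$end[others] >= orfs$start[i] &
              orfs$start[others] <= orfs$start[i] + 2L)) {
        ovl[i] <- TRUE
        gap[i] <- 0
      }
    }
  }
  orfs$downstream_gap <- gap
  orfs$overlaps_next <- ovl
  orfs
}

#' Enumerate consecutive same-direction ORF pairs
#'
#' Walks the annotation in genomic order and pairs each ORF with the next
#' ORF on the same strand of the same chromosome, labelling the pair by its
#' overlap type: \code{"stop_start_overlap"} when the downstream start codon
#' interval intersects the upstream stop codon interval (the classic ATGA
#' arrangement of translationally coupled genes), \code{"adjacent"} when the
#' intervals touch or overlap otherwise, \code{"gapped"} when separated.
#'
#' @param orfs An \code{orf_table}.
#' @return A data frame with columns \code{upstream, downstream,
#'   overlap_type, gap}.
#' @export
overlapping_pairs <- function(orfs) {
  out <- list()
  for (chrom in unique(orfs$chrom)) {
    for (str in c("+", "-")) {
      sub <- orfs[orfs$chrom == chrom & orfs$strand == str, , drop = FALSE]
      if (nrow(sub) < 2L) next
      sub <- sub[order(sub$start), , drop = FALSE]
      if (str == "-") sub <- sub[rev(seq_len(nrow(sub))), , drop = FALSE]
      for (i in seq_len(nrow(sub) - 1L)) {
        up <- sub[i, ]
        dn <- sub[i + 1L, ]
        if (str == "+") {
          stop_iv <- c(up$end - 2L, up$end)
          start_iv <- c(dn$start, dn$start + 2L)
          gap <- dn$start - up$end - 1L
        } else {
          stop_iv <- c(up$start, up$start + 2L)
          start_iv <- c(dn$end - 2L, dn$end)
          gap <- up$start - dn$end - 1L
        }
        type <- if (start_iv[1] <= stop_iv[2] && start_iv[2] >= stop_iv[1]) {
          "stop_start_overlap"
        } else if (gap <= 0L) "adjacent" else "gapped"
        out[[length(out) + 1L]] <- data.frame(
          upstream = up$gene_id, downstream = dn$gene_id,
          overlap_type = type, gap = max(gap, 0L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(upstream = character(), downstream = character(),
                      overlap_type = character(), gap = integer()))
  }
  do.call(rbind, out)
}

#' @export
print.orf_table <- function(x, ...) {
  cat("orf_table:", nrow(x), "ORF(s) on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write an ORF table to TSV
#'
#' @param orfs An \code{orf_table}.
#' @param path Output path.
#' @export
write_orf_table <- function(orfs, path) {
  write.table(as.data.frame(orfs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
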