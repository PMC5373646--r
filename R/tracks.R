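#' Read aligned reads from a tabular file
#'
#' Plain TSV dialect with columns \code{chrom, left, length, strand,
#' mismatches, multimapped}. \code{left} is the 1-based leftmost aligned
#' genomic base on the forward strand.
#'
#' @param path Path to a TSV file (with header).
#' @return A data frame of aligned reads.
#' @export
read_reads_tsv <- function(path) {
  reads <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  req <- c("chrom", "left", "length", "strand", "mismatches", "multimapped")
  miss <- setdiff(req, names(reads))
  if (length(miss)) stop("read table lacks columns: ", paste(miss, collapse = ", "))
  reads$multimapped <- as.logical(reads$multimapped)
  reads
}

#' Read aligned reads from SAM/BAM
#'
#' Mismatches are taken from the \code{NM} tag (missing tag treated as 0).
#' A read is considered multimapped when its mapping quality is 0 or the
#' secondary-alignment flag (0x100) is set. SAM input is converted to BAM
#' in a temporary location via Rsamtools.
#'
#' @param path Path to a SAM or BAM file.
#' @return A data frame in the same layout as \code{\link{read_reads_tsv}}.
#' @export
read_reads_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "mapq", "flag"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(b$pos))
  nm[is.na(nm)] <- 0L
  data.frame(
    chrom = as.character(b$rname),
    left = b$pos,
    length = b$qwidth,
    strand = as.character(b$strand),
    mismatches = nm,
    multimapped = b$mapq == 0L | bitwAnd(b$flag, 256L) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Filter aligned reads by length, mismatches and uniqueness
#'
#' Retains reads with length in \code{[min_len, max_len]} (bounds
#' inclusive), at most \code{max_mm} mismatches, and a unique alignment.
#'
#' @param reads Data frame of aligned reads.
#' @param min_len,max_len Inclusive length bounds (nt). Defaults 20 and 40.
#' @param max_mm Maximum mismatches. Default 2.
#' @return The retained subset of \code{reads}.
#' @export
filter_reads <- function(reads, min_len = 20L, max_len = 40L, max_mm = 2L) {
  keep <- reads$length >= min_len & reads$length <= max_len &
    reads$mismatches <= max_mm & !reads$multimapped
  reads[keep, , drop = FALSE]
}

# Per-read mapped positions and weights; vectorised over a read table.
# mapping:
#   center    - trim 10 nt each side, weight 1/w over the w remaining
#               positions; a 20-mer (trimmed width 0) keeps weight 1 at its
#               midpoint rather than vanishing (discard_20mers drops them)
#   threeprime- single position at the 3' end, weight 1
#   coverage  - every covered position, weight 1/length (mRNA-seq style)
mapped_positions <- function(reads, mapping = c("center", "threeprime", "coverage"),
                             discard_20mers = FALSE) {
  mapping <- match.arg(mapping)
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), weight = numeric()))
  }
  if (mapping == "center") {
    if (discard_20mers) {
      reads <- reads[reads$length > 20L, , drop = FALSE]
      n <- nrow(reads)
    }
    w <- pmax(reads$length - 20L, 1L)
    first <- reads$left + 10L          # midpoint rule for 20-mers is left+10 too
    idx <- rep(seq_len(n), w)
    data.frame(
      chrom = reads$chrom[idx],
      strand = reads$strand[idx],
      pos = first[idx] + (sequence(w) - 1L),
      weight = 1 / w[idx],
      stringsAsFactors = FALSE
    )
  } else if (mapping == "threeprime") {
    data.frame(
      chrom = reads$chrom,
      strand = reads$strand,
      pos = ifelse(reads$strand == "+", reads$left + reads$length - 1L,
                   reads$left),
      weight = rep(1, n),
      stringsAsFactors = FALSE
    )
  } else {
    idx <- rep(seq_len(n), reads$length)
    data.frame(
      chrom = reads$chrom[idx],
      strand = reads$strand[idx],
      pos = reads$left[idx] + (sequence(reads$length) - 1L),
      weight = 1 / reads$length[idx],
      stringsAsFactors = FALSE
    )
  }
}

#' Map one read to genomic positions and weights
#'
#' Centre mapping trims 10 nt from each read end and distributes unit weight
#' uniformly over the remaining positions; a read of length 20 (trimmed
#' width 0) is assigned weight 1 at its midpoint.
#'
#' @param read A one-row read data frame (or a list with \code{chrom, left,
#'   length, strand}).
#' @return Data frame with \code{pos} and \code{weight}; weights sum to 1.
#' @export
center_map <- function(read) {
  mapped_positions(as.data.frame(read), "center")[, c("pos", "weight")]
}

#' Map one read to its 3'-end position
#'
#' @param read A one-row read data frame.
#' @return Data frame with \code{pos} and \code{weight} (weight 1).
#' @export
three_prime_map <- function(read) {
  mapped_positions(as.data.frame(read), "threeprime")[, c("pos", "weight")]
}

#' Build a per-nucleotide density track from aligned reads
#'
#' Applies \code{\link{filter_reads}}, maps each retained read by the chosen
#' rule, and accumulates weights per (chromosome, strand, position). Mapped
#' mass equals the number of retained reads (each read contributes total
#' weight 1). Positions mapped outside the chromosome are dropped.
#'
#' @param reads Data frame of aligned reads.
#' @param chrom_lengths Named integer vector of chromosome lengths, or a
#'   \code{genome_seq}.
#' @param mapping One of \code{"center"}, \code{"threeprime"},
#'   \code{"coverage"}.
#' @param filter Apply the standard read filters first. Default \code{TRUE}.
#' @param ... Passed to \code{\link{filter_reads}}.
#' @return A \code{density_track}: list with \code{data} (per
#'   "chrom:strand" numeric vectors), \code{units} ("raw"),
#'   \code{total_mapped} (weighted mass) and \code{chrom_lengths}.
#' @export
build_track <- function(reads, chrom_lengths, mapping = "center",
                        filter = TRUE, ...) {
  if (inherits(chrom_lengths, "genome_seq")) chrom_lengths <- chrom_lengths$lengths
  if (filter) reads <- filter_reads(reads, ...)
  mp <- mapped_positions(reads, mapping)
  data <- list()
  for (chrom in names(chrom_lengths)) {
    for (str in c("+", "-")) {
      v <- numeric(chrom_lengths[[chrom]])
      sel <- mp$chrom == chrom & mp$strand == str &
        mp$pos >= 1L & mp$pos <= chrom_lengths[[chrom]]
      if (any(sel)) {
        agg <- rowsum(mp$weight[sel], mp$pos[sel])
        v[as.integer(rownames(agg))] <- agg[, 1L]
      }
      data[[paste0(chrom, ":", str)]] <- v
    }
  }
  new_track(data, units = "raw", chrom_lengths = chrom_lengths)
}

new_track <- function(data, units, chrom_lengths, total_mapped = NULL) {
  structure(list(
    data = data,
    units = units,
    chrom_lengths = chrom_lengths,
    total_mapped = total_mapped %||% sum(vapply(data, sum, numeric(1)))
  ), class = "density_track")
}

#' Construct a density track from per-nucleotide vectors
#'
#' Mostly useful for tests and simulations.
#'
#' @param data Named list of numeric vectors, names \code{"chrom:+"} /
#'   \code{"chrom:-"}; or a single numeric vector (placed on
#'   \code{"chr:+"}).
#' @param units \code{"raw"} or \code{"rpm"}.
#' @param total_mapped Total mapped mass backing the track; defaults to the
#'   track sum (raw) and must be supplied for \code{"rpm"} tracks whose
#'   depth differs from their sum.
#' @return A \code{density_track}.
#' @export
density_track <- function(data, units = "raw", total_mapped = NULL) {
  if (is.numeric(data)) data <- list(`chr:+` = data)
  if (any(vapply(data, function(v) any(v < 0), logical(1)))) {
    stop("density values must be nonnegative")
  }
  chroms <- unique(sub(":[+-]$", "", names(data)))
  lens <- integer(0)
  for (chrom in chroms) {
    ln <- unique(vapply(data[grep(paste0("^", chrom, ":[+-]$"), names(data))],
                        length, integer(1)))
    if (length(ln) != 1L) stop("strand vectors of ", chrom, " differ in length")
    lens[chrom] <- ln
    for (str in c("+", "-")) {
      key <- paste0(chrom, ":", str)
      if (is.null(data[[key]])) data[[key]] <- numeric(ln)
    }
  }
  new_track(data, units = units, chrom_lengths = lens,
            total_mapped = total_mapped)
}

#' @export
print.density_track <- function(x, ...) {
  cat("density_track [", x$units, "]: ",
      length(x$chrom_lengths), " chromosome(s), total mass ",
      format(sum(vapply(x$data, sum, numeric(1))), digits = 6),
      ", depth ", format(x$total_mapped, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Normalise a raw track to reads per million
#'
#' Every value is multiplied by \code{1e6 / M} where \code{M} is the total
#' weighted mapped mass of the track. Position-wise ratios are preserved.
#'
#' @param track A \code{density_track} with \code{units = "raw"}.
#' @return The track in RPM-per-nucleotide units; \code{total_mapped}
#'   retains the raw mass \code{M}, so raw counts remain recoverable as
#'   \code{value * M / 1e6}.
#' @export
normalize_per_million <- function(track) {
  if (track$units != "raw") stop("track is already normalized (units = '",
                                 track$units, "')")
  m <- sum(vapply(track$data, sum, numeric(1)))
  if (m <= 0) stop("empty track: total mapped mass is zero")
  track$data <- lapply(track$data, function(v) v * 1e6 / m)
  track$units <- "rpm"
  track$total_mapped <- m
  track
}

# raw weighted counts corresponding to a slice of an RPM (or raw) track
raw_counts <- function(track, values) {
  if (track$units == "raw") sum(values)
  else sum(values) * track$total_mapped / 1e6
}

track_key <- function(chrom, strand) paste0(chrom, ":", strand)

#' Extract per-nucleotide signal for a genomic interval
#'
#' Returns the signal over \code{[start, end]} (1-based closed) on the given
#' strand, in the 5' to 3' direction of that strand (reversed for
#' \code{"-"}). Positions outside the chromosome are returned as \code{NA}.
#'
#' @param track A \code{density_track}.
#' @param chrom,strand,start,end Interval specification.
#' @return Numeric vector of length \code{end - start + 1}.
#' @export
track_slice <- function(track, chrom, strand, start, end) {
  v <- track$data[[track_key(chrom, strand)]]
  if (is.null(v)) stop("no track data for ", chrom, " strand ", strand)
  pos <- start:end
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 1L & pos <= length(v)
  out[ok] <- v[pos[ok]]
  if (strand == "-") out <- rev(out)
  out
}

# Signal over the ORF body of one gene, 5'->3'
gene_signal <- function(track, gene) {
  track_slice(track, gene$chrom, gene$strand, gene$start, gene$end)
}

# Signal over the post-ORF region (first base after the stop codon onward),
# 5'->3', length n
post_orf_signal <- function(track, gene, n) {
  if (gene$strand == "+") {
    track_slice(track, gene$chrom, "+", gene$end + 1L, gene$end + n)
  } else {
    track_slice(track, gene$chrom, "-", gene$start - n, gene$start - 1L)
  }
}

# Post-ORF genomic sequence in transcription direction, length n
post_orf_sequence <- function(genome, gene, n) {
  len <- genome$lengths[[gene$chrom]]
  if (gene$strand == "+") {
    to <- min(gene$end + n, len)
    if (to <= gene$end) return("")
    subseq_chr(genome, gene$chrom, gene$end + 1L, to)
  } else {
    from <- max(gene$start - n, 1L)
    if (from >= gene$start) return("")
    revcomp(subseq_chr(genome, gene$chrom, from, gene$start - 1L))
  }
}

track_to_granges <- function(track, strand) {
  grs <- list()
  for (chrom in names(track$chrom_lengths)) {
    v <- track$data[[track_key(chrom, strand)]]
    nz <- which(v != 0)
    if (!length(nz)) next
    grs[[chrom]] <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = nz, width = 1L),
      score = v[nz]
    )
  }
  if (!length(grs)) {
    return(GenomicRanges::GRanges(score = numeric(0)))
  }
  do.call(c, unname(grs))
}

#' Write a density track as wiggle (or bedGraph) files, one per strand
#'
#' Wiggle carries no strand, so plus- and minus-strand signal go to separate
#' files. Only nonzero positions are written (variableStep, span 1), with
#' scores at R's default 15 significant digits; write/read round-trips are
#' exact at that precision.
#'
#' @param track A \code{density_track}.
#' @param plus_file,minus_file Output paths.
#' @param format \code{"wig"} or \code{"bedGraph"}.
#' @return Invisibly, the two paths.
#' @export
write_track <- function(track, plus_file, minus_file, format = c("wig", "bedGraph")) {
  format <- match.arg(format)
  rtracklayer::export(track_to_granges(track, "+"), plus_file, format = format)
  rtracklayer::export(track_to_granges(track, "-"), minus_file, format = format)
  invisible(c(plus_file, minus_file))
}

#' Read a density track from per-strand wiggle/bedGraph files
#'
#' @param plus_file,minus_file Paths written by \code{\link{write_track}}.
#' @param chrom_lengths Named chromosome lengths (wiggle does not carry
#'   them), or a \code{genome_seq}.
#' @param units Units to stamp on the track. Default \code{"rpm"}.
#' @param total_mapped Optional depth backing the track.
#' @param format \code{"wig"} or \code{"bedGraph"}.
#' @return A \code{density_track}.
#' @export
read_track <- function(plus_file, minus_file, chrom_lengths, units = "rpm",
                       total_mapped = NULL, format = c("wig", "bedGraph")) {
  format <- match.arg(format)
  if (inherits(chrom_lengths, "genome_seq")) chrom_lengths <- chrom_lengths$lengths
  data <- list()
  for (chrom in names(chrom_lengths)) {
    for (str in c("+", "-")) {
      data[[track_key(chrom, str)]] <- numeric(chrom_lengths[[chrom]])
    }
  }
  fill <- function(file, str) {
    gr <- rtracklayer::import(file, format = format)
    if (!length(gr)) return()
    pos <- GenomicRanges::start(gr)
    wid <- GenomicRanges::width(gr)
    sc <- S4Vectors::mcols(gr)$score
    chr <- as.character(GenomicRanges::seqnames(gr))
    idx <- rep(seq_along(gr), wid)
    p <- pos[idx] + (sequence(wid) - 1L)
    for (chrom in unique(chr)) {
      sel <- chr[idx] == chrom
      data[[track_key(chrom, str)]][p[sel]] <<- sc[idx[sel]]
    }
  }
  fill(plus_file, "+")
  fill(minus_file, "-")
  new_track(data, units = units, chrom_lengths = chrom_lengths,
            total_mapped = total_mapped)
}
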