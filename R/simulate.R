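#' Simulation parameters
#'
#' Ground-truth generator settings. Defaults describe a desk-scale
#' bacterial cohort: 200 genes, ORFs 150-1500 nt, intergenic gaps
#' 130-250 nt, stop-codon usage close to E. coli K-12 (0.63/0.08/0.29 for
#' TAA/TAG/TGA), log-normal expression with mean 2 RPM/nt and sdlog 1
#' (about one order of magnitude interquartile spread), gamma per-nucleotide
#' dwell noise with shape 4 and mean 1 (coefficient of variation 0.5, the
#' scale of codon-level dwell variation in bacterial ribosome profiling),
#' a 2-fold elevated dwell at the stop codon, Poisson count noise, and no
#' readthrough.
#'
#' @param n_genes Number of genes.
#' @param orf_length Length-2 range (nt) for ORF lengths; drawn uniformly
#'   and rounded to multiples of 3.
#' @param gap_range Length-2 range (nt) for intergenic gaps.
#' @param stop_freqs Proportions over TAA, TAG, TGA (sum 1).
#' @param mean_coverage Mean expression level (RPM/nt) of the log-normal.
#' @param expr_sdlog sdlog of the log-normal expression distribution.
#' @param dwell_shape Gamma shape (mean fixed at 1) of per-nucleotide dwell
#'   noise; \code{Inf} disables dwell noise.
#' @param stop_pause Multiplicative elevated dwell over the 3 stop-codon
#'   nucleotides (>= 1).
#' @param readthrough_fraction Per-gene fraction of ribosomes continuing
#'   past the stop codon (scalar recycled, or vector of length
#'   \code{n_genes}).
#' @param extension_frame Reading frame of the planted post-ORF extension:
#'   \code{"0"}, \code{"+1"} or \code{"-1"} (recycled).
#' @param extension_offset Target offset (nt from the first post-stop base)
#'   of the planted extension stop codon; adjusted minimally upward so the
#'   offset is congruent with the chosen frame. Default 63, so a
#'   full-length extension spans the whole 20-60 nt post-ORF window.
#' @param count_noise \code{"poisson"} or \code{"none"}.
#' @param strands \code{"both"} (random strands) or \code{"+"}.
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(n_genes = 200L,
                       orf_length = c(150L, 1500L),
                       gap_range = c(130L, 250L),
                       stop_freqs = c(TAA = 0.63, TAG = 0.08, TGA = 0.29),
                       mean_coverage = 2,
                       expr_sdlog = 1,
                       dwell_shape = 4,
                       stop_pause = 2,
                       readthrough_fraction = 0,
                       extension_frame = "0",
                       extension_offset = 63L,
                       count_noise = c("poisson", "none"),
                       strands = c("both", "+")) {
  count_noise <- match.arg(count_noise)
  strands <- match.arg(strands)
  stopifnot(abs(sum(stop_freqs) - 1) < 1e-9,
            all(readthrough_fraction >= 0 & readthrough_fraction <= 1),
            stop_pause >= 1, dwell_shape > 0, mean_coverage > 0)
  structure(list(
    n_genes = as.integer(n_genes), orf_length = orf_length,
    gap_range = gap_range, stop_freqs = stop_freqs,
    mean_coverage = mean_coverage, expr_sdlog = expr_sdlog,
    dwell_shape = dwell_shape, stop_pause = stop_pause,
    readthrough_fraction = readthrough_fraction,
    extension_frame = extension_frame,
    extension_offset = as.integer(extension_offset),
    count_noise = count_noise, strands = strands
  ), class = "sim_params")
}

sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# remove frame-r stops before `off` and plant a stop codon at `off`
# (0-based offsets into the post-ORF sequence, transcription direction)
plant_extension <- function(gapseq, off, frame_r, stop_codon) {
  s <- strsplit(gapseq, "", fixed = TRUE)[[1]]
  ps <- seq.int(frame_r, by = 3L, length.out = max(0L, (off - frame_r) %/% 3L))
  for (p in ps) {
    codon <- paste(s[(p + 1L):(p + 3L)], collapse = "")
    if (codon %in% stop_codons) {
      s[(p + 1L):(p + 3L)] <- strsplit(sample(sense_codons, 1L), "")[[1]]
    }
  }
  s[(off + 1L):(off + 3L)] <- strsplit(stop_codon, "")[[1]]
  paste(s, collapse = "")
}

#' Simulate a genome with planted ORFs and known recoding truth
#'
#' Generates a single random chromosome with non-overlapping ORFs laid out
#' left to right, each separated by a random intergenic gap. Every ORF is a
#' start codon, random sense codons, and a stop codon drawn from
#' \code{stop_freqs}. For genes with a nonzero readthrough fraction a stop
#' codon is planted in the extension reading frame at the configured offset
#' past the annotated stop, with no earlier stop in that frame, so the true
#' extension end is known. Fully deterministic given the seed.
#'
#' Each gene's post-ORF region in its direction of transcription is the
#' adjacent intergenic gap; when two candidate recoding genes on opposite
#' strands would share a gap, the later gene is placed on the forward
#' strand instead.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param seed Integer seed.
#' @return A list of class \code{riboterm_sim} with \code{genome}
#'   (\code{genome_seq}), \code{orfs} (\code{orf_table}), \code{truth}
#'   (per-gene data frame: \code{gene_id, strand, expression, f, pause,
#'   ext_frame, ext_offset}), \code{params} and \code{seed}.
#' @export
simulate_genome <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  n <- params$n_genes
  orf_lens <- as.integer(round(runif(n, params$orf_length[1],
                                     params$orf_length[2]) / 3) * 3)
  gaps <- as.integer(round(runif(n + 1L, params$gap_range[1],
                                 params$gap_range[2])))
  strands <- if (params$strands == "+") rep("+", n)
    else sample(c("+", "-"), n, replace = TRUE)
  f <- rep_len(params$readthrough_fraction, n)
  frames <- rep_len(params$extension_frame, n)
  frame_r <- c(`0` = 0L, `+1` = 1L, `-1` = 2L)[frames]
  ext_off <- params$extension_offset +
    (frame_r - params$extension_offset %% 3L) %% 3L
  if (any(ext_off + 3L + 10L > params$gap_range[1])) {
    stop("intergenic gaps too small to host the planted extension")
  }

  # resolve post-ORF gap claims: gene i (+) claims gap i+1, gene i (-)
  # claims gap i; opposite-strand neighbours must not both edit one gap
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (strands[i] == "+" && strands[i + 1L] == "-" &&
          f[i] > 0 && f[i + 1L] > 0) {
        strands[i + 1L] <- "+"
      }
    }
  }

  expr <- rlnorm(n, meanlog = log(params$mean_coverage) -
                   params$expr_sdlog^2 / 2, sdlog = params$expr_sdlog)
  stops <- sample(stop_codons, n, replace = TRUE, prob = params$stop_freqs)
  ext_stops <- sample(stop_codons, n, replace = TRUE,
                      prob = params$stop_freqs)

  gap_seqs <- vapply(gaps, rand_seq, character(1))
  orf_seqs <- character(n)
  for (i in seq_len(n)) {
    n_mid <- orf_lens[i] / 3L - 2L
    orf_seqs[i] <- paste0("ATG",
                          paste(sample(sense_codons, n_mid, replace = TRUE),
                                collapse = ""),
                          stops[i])
  }

  # plant extensions into the claimed gaps (transcription direction)
  for (i in seq_len(n)) {
    if (f[i] <= 0) next
    g <- if (strands[i] == "+") i + 1L else i
    if (strands[i] == "+") {
      gap_seqs[g] <- plant_extension(gap_seqs[g], ext_off[i], frame_r[i],
                                     ext_stops[i])
    } else {
      fwd <- revcomp(gap_seqs[g])
      gap_seqs[g] <- revcomp(plant_extension(fwd, ext_off[i], frame_r[i],
                                             ext_stops[i]))
    }
  }

  pieces <- character(2L * n + 1L)
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- gap_seqs[i]
    pos <- pos + gaps[i]
    starts[i] <- pos
    ends[i] <- pos + orf_lens[i] - 1L
    pieces[2L * i] <- if (strands[i] == "+") orf_seqs[i]
      else revcomp(orf_seqs[i])
    pos <- pos + orf_lens[i]
  }
  pieces[2L * n + 1L] <- gap_seqs[n + 1L]
  chrom_seq <- paste(pieces, collapse = "")

  genome <- structure(list(
    seq = c(sim_chr = chrom_seq),
    lengths = c(sim_chr = nchar(chrom_seq))
  ), class = "genome_seq")

  ann <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = "sim_chr", strand = strands,
    start = starts, end = ends, stringsAsFactors = FALSE
  )
  orfs <- load_annotation(genome, ann)
  truth <- data.frame(
    gene_id = ann$gene_id, strand = strands, expression = expr, f = f,
    pause = params$stop_pause,
    ext_frame = ifelse(f > 0, frames, NA_character_),
    ext_offset = ifelse(f > 0, ext_off, NA_integer_),
    stringsAsFactors = FALSE
  )
  structure(list(genome = genome, orfs = orfs, truth = truth,
                 params = params, seed = seed),
            class = "riboterm_sim")
}

#' @export
print.riboterm_sim <- function(x, ...) {
  cat("riboterm_sim: ", nrow(x$orfs), " genes on ",
      format(unname(x$genome$lengths[1]), big.mark = ","),
      " nt (seed ", x$seed, "); ",
      sum(x$truth$f > 0), " gene(s) with planted readthrough\n", sep = "")
  invisible(x)
}

#' Simulate footprint and mRNA density tracks
#'
#' Per-gene expected footprint density is the gene's expression level times
#' gamma dwell noise per nucleotide; the three stop-codon nucleotides are
#' multiplied by the stop-pause factor; the planted extension (first
#' post-stop base through the planted stop codon) carries the readthrough
#' fraction times the gene's expression; density beyond the planted stop is
#' zero. Observed values are Poisson draws of the expected values when
#' count noise is on. The mRNA track is uniform at the expression level
#' over the ORF (plus Poisson noise). Tracks are emitted in RPM units with
#' the backing depth fixed at 1e6, so values and raw weighted counts
#' coincide.
#'
#' @param sim A \code{riboterm_sim} from \code{\link{simulate_genome}}.
#' @param seed Integer seed (independent of the genome seed).
#' @return List with \code{fp} and \code{mrna} \code{density_track}s.
#' @export
simulate_tracks <- function(sim, seed = 1L) {
  set.seed(seed)
  params <- sim$params
  lens <- sim$genome$lengths
  data <- list(`sim_chr:+` = numeric(lens[[1]]),
               `sim_chr:-` = numeric(lens[[1]]))
  mdata <- list(`sim_chr:+` = numeric(lens[[1]]),
                `sim_chr:-` = numeric(lens[[1]]))
  dwell <- function(k) {
    if (is.infinite(params$dwell_shape)) rep(1, k)
    else rgamma(k, shape = params$dwell_shape, rate = params$dwell_shape)
  }
  for (i in seq_len(nrow(sim$orfs))) {
    gene <- sim$orfs[i, ]
    tr <- sim$truth[i, ]
    key <- track_key(gene$chrom, gene$strand)
    lam <- tr$expression * dwell(gene$length)
    # elevated dwell over the stop codon (last 3 nt, 5'->3')
    lam[(gene$length - 2L):gene$length] <- lam[(gene$length - 2L):gene$length] *
      params$stop_pause
    pos <- if (gene$strand == "+") gene$start:gene$end else gene$end:gene$start
    data[[key]][pos] <- data[[key]][pos] + lam
    mdata[[key]][gene$start:gene$end] <- mdata[[key]][gene$start:gene$end] +
      tr$expression
    if (tr$f > 0) {
      ext_len <- tr$ext_offset + 3L
      lam_ext <- tr$f * tr$expression * dwell(ext_len)
      epos <- if (gene$strand == "+") (gene$end + 1L):(gene$end + ext_len)
        else (gene$start - 1L):(gene$start - ext_len)
      data[[key]][epos] <- data[[key]][epos] + lam_ext
    }
  }
  if (params$count_noise == "poisson") {
    data <- lapply(data, function(v) as.numeric(rpois(length(v), v)))
    mdata <- lapply(mdata, function(v) as.numeric(rpois(length(v), v)))
  }
  list(
    fp = new_track(data, units = "rpm", chrom_lengths = lens,
                   total_mapped = 1e6),
    mrna = new_track(mdata, units = "rpm", chrom_lengths = lens,
                     total_mapped = 1e6)
  )
}

#' Simulate aligned reads from an expected density track
#'
#' Draws read centre positions proportional to the track signal and wraps
#' each in a read of random length 20-40 nt, placed so that its trimmed
#' centre interval covers the drawn position uniformly; centre-mapping the
#' simulated reads therefore reproduces the track shape in expectation.
#' Reads falling off a chromosome end are discarded. All reads are unique
#' with zero mismatches.
#'
#' @param track A \code{density_track} (expected-value form).
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed.
#' @return Data frame of aligned reads (\code{chrom, left, length, strand,
#'   mismatches, multimapped}).
#' @export
simulate_reads <- function(track, n_reads = 1e5L, seed = 1L) {
  set.seed(seed)
  keys <- names(track$data)
  mass <- vapply(track$data, sum, numeric(1))
  if (sum(mass) <= 0 || n_reads < 1L) {
    return(data.frame(chrom = character(), left = integer(),
                      length = integer(), strand = character(),
                      mismatches = integer(), multimapped = logical()))
  }
  n_per <- as.vector(stats::rmultinom(1L, n_reads, mass))
  out <- list()
  for (k in seq_along(keys)) {
    if (n_per[k] == 0L) next
    v <- track$data[[keys[k]]]
    nz <- which(v > 0)
    centers <- nz[sample.int(length(nz), n_per[k], replace = TRUE,
                             prob = v[nz])]
    len <- sample(20:40, n_per[k], replace = TRUE)
    w <- pmax(len - 20L, 1L)
    u <- floor(runif(n_per[k]) * w)
    left <- centers - 10L - u
    chrom <- sub(":[+-]$", "", keys[k])
    str <- sub("^.*:", "", keys[k])
    ok <- left >= 1L & left + len - 1L <= track$chrom_lengths[[chrom]]
    out[[keys[k]]] <- data.frame(
      chrom = chrom, left = left[ok], length = len[ok], strand = str,
      mismatches = 0L, multimapped = FALSE, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a genome to FASTA
#'
#' @param genome A \code{genome_seq}.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write an ORF table as GFF3
#'
#' @param orfs An \code{orf_table}.
#' @param path Output path.
#' @export
write_orf_gff3 <- function(orfs, path) {
  gr <- orfs_to_granges(orfs)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$ID <- orfs$gene_id
  S4Vectors::mcols(gr)$Name <- orfs$gene_id
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write simulated reads to the tabular dialect
#'
#' @param reads Read data frame.
#' @param path Output path.
#' @export
write_reads_tsv <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
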