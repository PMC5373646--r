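# Shared fixture builders. All fixtures are constructed in code; sequences
# are explicit so expected stop codons / offsets are known by construction.

# write a named character vector of sequences as FASTA and read it back
toy_genome <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  con <- file(f, "wt")
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  close(con)
  read_genome(f)
}

# an ORF cassette: ATG + n_mid copies of a sense codon + stop
cassette <- function(n_mid, stop = "TAA", mid = "GCT") {
  paste0("ATG", strrep(mid, n_mid), stop)
}

# lay cassettes left-to-right on one + strand chromosome, separated by gaps
# (gap_seqs[i] precedes cassette i; one trailing gap after the last gene);
# returns genome + validated orf_table
toy_locus <- function(cassettes, gap_seqs) {
  stopifnot(length(gap_seqs) == length(cassettes) + 1L)
  pieces <- character(0)
  starts <- integer(0); ends <- integer(0)
  pos <- 1L
  for (i in seq_along(cassettes)) {
    pieces <- c(pieces, gap_seqs[i])
    pos <- pos + nchar(gap_seqs[i])
    starts[i] <- pos
    ends[i] <- pos + nchar(cassettes[i]) - 1L
    pieces <- c(pieces, cassettes[i])
    pos <- pos + nchar(cassettes[i])
  }
  pieces <- c(pieces, gap_seqs[length(gap_seqs)])
  genome <- toy_genome(c(chrA = paste(pieces, collapse = "")))
  ann <- data.frame(
    gene_id = sprintf("g%d", seq_along(cassettes)),
    chrom = "chrA", strand = "+", start = starts, end = ends,
    stringsAsFactors = FALSE
  )
  list(genome = genome,
       orfs = load_annotation(genome, ann),
       starts = starts, ends = ends)
}

# deterministic filler sequence free of stop codons (repeats of GCA)
filler <- function(n) substr(strrep("GCA", ceiling(n / 3) + 1L), 1, n)

# a bare orf_table for track-only tests (no genome validation needed)
toy_orf_table <- function(gene_id, start, end, strand = "+", gap = 200,
                          overlaps = FALSE, chrom = "chr",
                          stop_codon = "TAA", fourth_base = "A") {
  df <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end, length = end - start + 1L,
    stop_codon = stop_codon, fourth_base = fourth_base,
    downstream_gap = gap, overlaps_next = overlaps, valid = TRUE,
    stringsAsFactors = FALSE
  )
  class(df) <- c("orf_table", "data.frame")
  df
}

# uniform RPM track on one chromosome (both strands), depth 1e6 so values
# and raw counts coincide
uniform_track <- function(len, value = 1, chrom = "chr") {
  data <- setNames(list(rep(value, len), rep(value, len)),
                   paste0(chrom, ":", c("+", "-")))
  density_track(data, units = "rpm", total_mapped = 1e6)
}

# independent per-offset-median metagene oracle used against the package
# implementation: plain loops, no shared code path
naive_metagene_oracle <- function(genes, track, up = 100L, down = 60L,
                                  nw = c(-100L, -70L)) {
  offs <- (-up):down
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    p0 <- if (g$strand == "+") g$end - 2L else g$start + 2L
    vals <- numeric(length(offs))
    for (j in seq_along(offs)) {
      pos <- if (g$strand == "+") p0 + offs[j] else p0 - offs[j]
      vals[j] <- track$data[[paste0(g$chrom, ":", g$strand)]][pos]
    }
    nm <- mean(vals[offs >= nw[1] & offs <= nw[2]])
    rows[[i]] <- vals / nm
  }
  mat <- do.call(rbind, rows)
  apply(mat, 2, median)
}

# the five-gene eligibility toy: pass, gap-fail, density-fail, overlap-fail,
# boundary-pass (gap exactly 65, densities exactly 0.1)
five_gene_toy <- function() {
  orfs <- toy_orf_table(
    paste0("g", 1:5),
    start = seq(201, by = 600, length.out = 5),
    end = seq(320, by = 600, length.out = 5),
    gap = c(100, 64, 100, 100, 65)
  )
  orfs$overlaps_next[4] <- TRUE
  fp_v <- numeric(3500); mr_v <- numeric(3500)
  dens <- c(0.5, 0.5, 0.05, 0.5, 0.1)
  for (i in 1:5) {
    idx <- orfs$start[i]:orfs$end[i]
    fp_v[idx] <- dens[i]
    mr_v[idx] <- 0.5
  }
  fp <- density_track(list(`chr:+` = fp_v), units = "rpm", total_mapped = 1e6)
  mr <- density_track(list(`chr:+` = mr_v), units = "rpm", total_mapped = 1e6)
  list(orfs = orfs, fp = fp, mr = mr)
}

# brute-force two-sample K-S D: scan every breakpoint of both ECDFs
brute_force_ks_d <- function(a, b) {
  brk <- sort(unique(c(a, b)))
  fa <- vapply(brk, function(x) mean(a <= x), numeric(1))
  fb <- vapply(brk, function(x) mean(b <= x), numeric(1))
  max(abs(fa - fb))
}

# exhaustive 3-frame stop-codon scan oracle
brute_force_stops <- function(s) {
  hits <- list()
  for (off in 0:(nchar(s) - 3L)) {
    codon <- substr(s, off + 1L, off + 3L)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      hits[[length(hits) + 1L]] <- data.frame(
        offset = off,
        frame = c("0", "+1", "-1")[off %% 3L + 1L],
        codon = codon, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(), frame = character(),
                      codon = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}
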