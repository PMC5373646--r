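toy_reads <- function(left, length, strand = "+", chrom = "chr",
                      mm = 0L, multi = FALSE) {
  data.frame(chrom = chrom, left = left, length = length, strand = strand,
             mismatches = mm, multimapped = multi, stringsAsFactors = FALSE)
}

test_that("read filters keep 20-40 nt unique reads with at most 2 mismatches", {
  reads <- rbind(
    toy_reads(1, 20),                 # boundary length, kept
    toy_reads(1, 40),                 # boundary length, kept
    toy_reads(1, 30, mm = 2L),        # boundary mismatches, kept
    toy_reads(1, 41),                 # too long
    toy_reads(3, 22),
    toy_reads(1, 30, mm = 3L),        # too many mismatches
    toy_reads(1, 30, multi = TRUE),   # multimapped
    toy_reads(5, 25), toy_reads(9, 33), toy_reads(2, 37)
  )
  kept <- filter_reads(reads)
  expect_equal(nrow(kept), 7)
  expect_true(all(kept$length >= 20 & kept$length <= 40))
  expect_true(all(kept$mismatches <= 2) && !any(kept$multimapped))
})

test_that("centre mapping trims 10 nt per side and spreads unit weight", {
  m30 <- center_map(toy_reads(100, 30))
  expect_equal(m30$pos, 110:119)
  expect_equal(m30$weight, rep(0.1, 10))

  m21 <- center_map(toy_reads(100, 21))
  expect_equal(m21$pos, 110)
  expect_equal(m21$weight, 1)

  # a 20-mer has trimmed width 0; it keeps weight 1 at its midpoint
  m20 <- center_map(toy_reads(100, 20))
  expect_equal(m20$pos, 110)
  expect_equal(m20$weight, 1)

  for (len in c(22, 28, 35, 40)) {
    m <- center_map(toy_reads(50, len))
    expect_equal(sum(m$weight), 1)
    expect_equal(length(m$pos), len - 20)
  }
})

test_that("3'-end mapping is strand aware", {
  expect_equal(three_prime_map(toy_reads(100, 30, "+"))$pos, 129)
  expect_equal(three_prime_map(toy_reads(100, 30, "-"))$pos, 100)
})

test_that("mapped mass equals the retained read count and respects strand", {
  set.seed(42)
  n <- 400
  reads <- toy_reads(sample(50:900, n, replace = TRUE),
                     sample(20:40, n, replace = TRUE),
                     sample(c("+", "-"), n, replace = TRUE))
  for (mapping in c("center", "threeprime", "coverage")) {
    tr <- build_track(reads, c(chr = 1000L), mapping = mapping)
    expect_equal(sum(vapply(tr$data, sum, numeric(1))), n, tolerance = 1e-9)
  }
  # centre-mapped and 3'-mapped tracks carry identical total mass
  tc <- build_track(reads, c(chr = 1000L), mapping = "center")
  t3 <- build_track(reads, c(chr = 1000L), mapping = "threeprime")
  expect_equal(sum(vapply(tc$data, sum, numeric(1))),
               sum(vapply(t3$data, sum, numeric(1))))
  # a + strand read never contributes to the - strand signal
  plus_only <- build_track(toy_reads(100, 30, "+"), c(chr = 1000L))
  expect_equal(sum(plus_only$data[["chr:-"]]), 0)
  expect_equal(sum(plus_only$data[["chr:+"]]), 1)
})

test_that("per-million normalization rescales by total mass exactly once", {
  tr <- density_track(list(`chr:+` = c(4, 6, 0)), units = "raw")
  rpm <- normalize_per_million(tr)
  expect_equal(rpm$data[["chr:+"]], c(4e5, 6e5, 0))
  expect_equal(rpm$units, "rpm")
  expect_equal(rpm$total_mapped, 10)
  expect_error(normalize_per_million(rpm), "already normalized")
  empty <- density_track(list(`chr:+` = c(0, 0)), units = "raw")
  expect_error(normalize_per_million(empty), "empty track")
})

test_that("wiggle and bedGraph write/read round-trips are exact", {
  v <- c(0, 1.25, 1 / 3, 0, 7e-3, 2, 0.123456789)
  tr <- density_track(list(`c1:+` = v, `c1:-` = rev(v)), units = "rpm",
                      total_mapped = 1e6)
  for (fmt in c("wig", "bedGraph")) {
    f1 <- tempfile(fileext = ".txt"); f2 <- tempfile(fileext = ".txt")
    write_track(tr, f1, f2, format = fmt)
    back <- read_track(f1, f2, c(c1 = length(v)), total_mapped = 1e6,
                       format = fmt)
    # identity at the writer's 15-significant-digit output precision
    expect_equal(back$data, tr$data, tolerance = 1e-12)
    expect_identical(signif(back$data[["c1:+"]], 12), signif(v, 12))
  }
})

test_that("SAM input matches the equivalent tabular read records", {
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:500",
    paste("r1", 0, "chr1", 101, 60, "30M", "*", 0, 0,
          strrep("A", 30), "*", "NM:i:1", sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "25M", "*", 0, 0,
          strrep("C", 25), "*", "NM:i:0", sep = "\t"),
    paste("r3", 0, "chr1", 301, 0, "30M", "*", 0, 0,
          strrep("G", 30), "*", "NM:i:0", sep = "\t")
  )
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  reads <- read_reads_sam(f)
  expect_equal(reads$left, c(101, 201, 301))
  expect_equal(reads$length, c(30, 25, 30))
  expect_equal(reads$strand, c("+", "-", "+"))
  expect_equal(reads$mismatches, c(1, 0, 0))
  expect_equal(reads$multimapped, c(FALSE, FALSE, TRUE))  # mapq 0
})

test_that("track slices are returned 5' to 3' of the requested strand", {
  v <- 1:10
  tr <- density_track(list(`c:+` = as.numeric(v), `c:-` = as.numeric(v)),
                      units = "rpm", total_mapped = 1e6)
  expect_equal(track_slice(tr, "c", "+", 3, 6), c(3, 4, 5, 6))
  expect_equal(track_slice(tr, "c", "-", 3, 6), c(6, 5, 4, 3))
})
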