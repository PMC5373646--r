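test_that("candidate stop scan finds every stop in every frame", {
  c1 <- candidate_stops("AAATGAATAA")
  expect_equal(c1$offset, c(3, 7))
  expect_equal(c1$frame, c("0", "+1"))
  expect_equal(c1$codon, c("TGA", "TAA"))

  c2 <- candidate_stops("TAATAGTGA")
  expect_equal(c2$offset, c(0, 3, 6))
  expect_equal(unique(c2$frame), "0")

  expect_equal(nrow(candidate_stops("ACGCGCGCAC")), 0)
  expect_equal(nrow(candidate_stops("AC")), 0)

  # frame labels follow offset mod 3 (2 mod 3 is the -1 frame)
  c3 <- candidate_stops("AATAAA")   # TAA at offset 2
  expect_equal(c3$frame, "-1")
})

test_that("candidate scan agrees with the exhaustive oracle on random sequences", {
  set.seed(31)
  for (rep in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:120, 1),
                      replace = TRUE), collapse = "")
    expect_identical(candidate_stops(s), brute_force_stops(s))
  }
})

test_that("drop score is the post/pre mean ratio clipped to the region", {
  expect_equal(drop_score(rep(2, 100), 50), 1)

  region <- numeric(100)
  region[21:50] <- 5      # pre-window of a candidate at offset 50
  region[54:83] <- 0.5    # post-window
  expect_equal(drop_score(region, 50), 0.1)

  # density entirely before the candidate -> ratio 0
  region2 <- numeric(100); region2[1:50] <- 3
  expect_equal(drop_score(region2, 50), 0)

  # zero pre-window mean -> undefined
  expect_true(is.na(drop_score(numeric(100), 50)))
  # candidate at the region start has no pre-window
  expect_true(is.na(drop_score(rep(1, 50), 0)))
})

test_that("simulated readthrough genes are called likely at the exact offset", {
  sp <- sim_params(n_genes = 8L, readthrough_fraction = 0.6,
                   mean_coverage = 8, expr_sdlog = 0.2)
  sim <- simulate_genome(sp, seed = 51)
  tracks <- simulate_tracks(sim, seed = 52)
  calls <- classify_genes(sim$orfs, sim$genome, tracks$fp)
  m <- merge(calls, sim$truth, by = "gene_id")
  # every planted gene is called (a chance Shine-Dalgarno-like motif in the
  # random intergenic sequence may demote likely to possible)
  expect_true(all(m$class %in% c("likely", "possible")))
  expect_equal(m$offset, m$ext_offset)
  expect_equal(m$frame, m$ext_frame)
  expect_true(all(m$drop_ratio <= 0.3))
})

test_that("flat plateaus, starved regions and confounders classify as designed", {
  # one gene whose 200 nt post-ORF region contains exactly one stop codon,
  # a TGA at offset 60 (the filler sequence is stop-free by construction)
  gap <- paste0(filler(60), "TGA", filler(137))
  loc <- toy_locus(cassette(40), c("", gap))
  gene <- loc$orfs[1, ]
  orf_idx <- gene$start:gene$end
  L <- unname(loc$genome$lengths[1])
  expect_equal(gene$downstream_gap, 200)
  expect_equal(candidate_stops(riboterm:::post_orf_sequence(
    loc$genome, gene, 200))$offset, 60)

  # flat plateau across the whole post-ORF region: no drop anywhere
  v <- numeric(L); v[orf_idx] <- 4; v[(gene$end + 1):(gene$end + 200)] <- 2
  tr <- density_track(list(`chrA:+` = v, `chrA:-` = numeric(L)),
                      units = "rpm", total_mapped = 1e6)
  flat <- classify_gene(gene, loc$genome, tr)
  expect_equal(flat$class, "non-recoding")

  # fewer than 10 raw counts in the region -> unclassifiable
  v2 <- numeric(L); v2[orf_idx] <- 4
  v2[(gene$end + 1):(gene$end + 9)] <- 1
  tr2 <- density_track(list(`chrA:+` = v2, `chrA:-` = numeric(L)),
                       units = "rpm", total_mapped = 1e6)
  starved <- classify_gene(gene, loc$genome, tr2)
  expect_equal(starved$class, "unclassifiable")
  expect_match(starved$flags, "low-reads")

  # a genuine drop at the post-ORF stop -> likely; with a user confounder
  # interval -> possible, flagged
  v3 <- numeric(L); v3[orf_idx] <- 4
  v3[(gene$end + 1):(gene$end + 60)] <- 2
  tr3 <- density_track(list(`chrA:+` = v3, `chrA:-` = numeric(L)),
                       units = "rpm", total_mapped = 1e6)
  clean <- classify_gene(gene, loc$genome, tr3)
  expect_equal(clean$class, "likely")
  expect_equal(clean$offset, 60)
  rep_el <- list(rep = data.frame(chrom = "chrA",
                                  start = gene$end + 5,
                                  end = gene$end + 15))
  flagged <- classify_gene(gene, loc$genome, tr3, confounders = rep_el)
  expect_equal(flagged$class, "possible")
  expect_match(flagged$flags, "user-interval-overlap")

  # a supplied feature covering all post-ORF signal -> misannotation suspect
  cover <- list(orf = data.frame(chrom = "chrA",
                                 start = gene$end + 1,
                                 end = gene$end + 200))
  covered <- classify_gene(gene, loc$genome, tr3, confounders = cover)
  expect_equal(covered$class, "misannotation-suspect")
})

test_that("detector separates planted from clean genes on a small cohort", {
  sp <- sim_params(n_genes = 40L,
                   readthrough_fraction = rep(c(0.5, 0), each = 20),
                   mean_coverage = 5, expr_sdlog = 0.3)
  sim <- simulate_genome(sp, seed = 61)
  tracks <- simulate_tracks(sim, seed = 62)
  calls <- classify_genes(sim$orfs, sim$genome, tracks$fp,
                          eligible = eligible_genes(sim$orfs, tracks$fp,
                                                    tracks$mrna))
  m <- merge(calls, sim$truth, by = "gene_id")
  pos <- m$class %in% c("likely", "possible")
  expect_equal(mean(pos[m$f > 0]), 1)
  expect_equal(mean(!pos[m$f == 0]), 1)
})

test_that("enrichment chi-squared equals the Pearson hand formula", {
  freqs <- c(UAA = 0.6, UAG = 0.1, UGA = 0.3)
  even <- enrichment_chi2(c(UAA = 18, UAG = 3, UGA = 9), freqs)
  expect_equal(even$chi2, 0)
  expect_equal(even$p_value, 1)
  expect_equal(sum(even$observed), sum(even$expected), tolerance = 1e-9)

  # worked case: observed (10,5,15), n 30, expected (18,3,9) -> 8.889
  e <- enrichment_chi2(c(UAA = 10, UAG = 5, UGA = 15), freqs)
  hand <- (10 - 18)^2 / 18 + (5 - 3)^2 / 3 + (15 - 9)^2 / 9
  expect_equal(e$chi2, hand, tolerance = 1e-9)
  expect_equal(e$chi2, 80 / 9, tolerance = 1e-9)
  expect_equal(e$df, 2)

  # relabelling categories together with their frequencies is invariant
  perm <- c(3, 1, 2)
  e2 <- enrichment_chi2(c(10, 5, 15)[perm], unname(freqs)[perm])
  expect_equal(e2$chi2, e$chi2, tolerance = 1e-12)

  expect_error(enrichment_chi2(c(1, 2, 3), c(1, 0, 0)), "expected count")
  expect_error(enrichment_chi2(c(1, 2, 3), c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("annotation stop-codon frequencies sum to one over the three stops", {
  sim <- simulate_genome(sim_params(n_genes = 40L), seed = 71)
  fr <- stop_codon_frequencies(sim$orfs)
  expect_equal(sum(fr), 1)
  expect_equal(names(fr), c("UAA", "UAG", "UGA"))
})
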