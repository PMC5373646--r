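# three well-separated genes that comfortably host the [-100, +60] window
metagene_orfs <- function() {
  toy_orf_table(c("g1", "g2", "g3"),
                start = c(201, 801, 1401),
                end = c(320, 920, 1520),
                gap = 200)
}

test_that("uniform density normalizes to a flat profile of 1", {
  orfs <- metagene_orfs()
  tr <- uniform_track(2000, value = 2)
  prof <- metagene_profile(orfs, tr)
  expect_equal(prof$n_genes[1], 3)
  expect_equal(prof$median_density, rep(1, 161))
})

test_that("a stop-codon peak appears at offsets 0..2 at its planted height", {
  orfs <- metagene_orfs()
  tr <- uniform_track(2000, value = 1)
  for (i in seq_len(nrow(orfs))) {
    stop_pos <- (orfs$end[i] - 2):orfs$end[i]
    tr$data[["chr:+"]][stop_pos] <- 2
  }
  prof <- metagene_profile(orfs, tr)
  expect_equal(prof$median_density[prof$offset %in% 0:2], rep(2, 3))
  expect_equal(prof$median_density[prof$offset == -10], 1)
  expect_equal(stop_occupancy(prof), 2)
  expect_equal(stop_occupancy(prof, method = "mean"), 2)
})

test_that("gene window normalization divides by the upstream window mean", {
  gene <- toy_orf_table("g1", start = 201, end = 320, gap = 200)
  tr <- uniform_track(2000, value = 0)
  p0 <- 318                      # first stop-codon base
  win <- (p0 - 100):(p0 + 60)
  vals <- seq(0.25, 4.25, length.out = 161)
  tr$data[["chr:+"]][win] <- vals
  # force the normalization window to mean 0.5
  tr$data[["chr:+"]][(p0 - 100):(p0 - 70)] <- 0.5
  vals[1:31] <- 0.5
  out <- gene_normalized_window(gene[1, ], tr)
  expect_equal(unname(out), vals * 2)
  # zero normalization window -> ineligible, no division attempted
  tr$data[["chr:+"]][(p0 - 100):(p0 - 70)] <- 0
  expect_null(gene_normalized_window(gene[1, ], tr))
})

test_that("gap and count filters drop genes individually and switchably", {
  orfs <- metagene_orfs()
  orfs$downstream_gap[2] <- 30           # below the 50 nt gap filter
  tr <- uniform_track(2000, value = 1)
  prof <- metagene_profile(orfs, tr)
  expect_equal(prof$n_genes[1], 2)
  # disabling the gap filter restores the gene
  prof_nogap <- metagene_profile(orfs, tr, min_downstream_gap = NULL)
  expect_equal(prof_nogap$n_genes[1], 3)

  # count filter: starve one gene's normalization window
  orfs2 <- metagene_orfs()
  tr2 <- uniform_track(2000, value = 1)
  p0 <- orfs2$end[3] - 2
  tr2$data[["chr:+"]][(p0 - 100):(p0 - 70)] <- 1e-8
  with_filter <- metagene_profile(orfs2, tr2)
  without_filter <- metagene_profile(orfs2, tr2, min_window_counts = NULL)
  expect_equal(with_filter$n_genes[1], 2)
  expect_gte(without_filter$n_genes[1], with_filter$n_genes[1])

  # all genes filtered -> informative error
  orfs3 <- metagene_orfs()
  orfs3$downstream_gap <- 10
  expect_error(metagene_profile(orfs3, tr), "gap filter removed 3")
})

test_that("per-offset medians match an independent oracle on random tracks", {
  set.seed(11)
  orfs <- toy_orf_table(paste0("g", 1:5),
                        start = seq(201, by = 600, length.out = 5),
                        end = seq(320, by = 600, length.out = 5),
                        gap = 200)
  tr <- uniform_track(3500, value = 0)
  tr$data[["chr:+"]] <- rgamma(3500, shape = 2, rate = 1) + 0.05
  prof <- metagene_profile(orfs, tr)
  expect_equal(prof$median_density, naive_metagene_oracle(orfs, tr),
               tolerance = 1e-12)
  # permutation invariance in gene order
  shuf <- metagene_profile(orfs[c(3, 1, 5, 2, 4), ], tr)
  expect_equal(shuf$median_density, prof$median_density)
})

test_that("profiles are invariant to uniform track rescaling", {
  set.seed(12)
  orfs <- metagene_orfs()
  tr <- uniform_track(2000, value = 0)
  tr$data[["chr:+"]] <- rgamma(2000, shape = 3, rate = 1) + 0.2
  prof <- metagene_profile(orfs, tr)
  tr_scaled <- tr
  tr_scaled$data[["chr:+"]] <- tr$data[["chr:+"]] * 37.5
  tr_scaled$total_mapped <- tr$total_mapped * 37.5
  expect_equal(metagene_profile(orfs, tr_scaled)$median_density,
               prof$median_density)
})

test_that("stratification partitions by stop codon, fourth base and TE", {
  orfs <- toy_orf_table(paste0("g", 1:3), start = c(1, 100, 200),
                        end = c(60, 159, 259),
                        stop_codon = c("TAA", "TAA", "TGA"),
                        fourth_base = c("G", "C", "A"))
  s <- stratify(orfs)
  expect_equal(lengths(s[c("UAA", "UAG", "UGA")]),
               c(UAA = 2L, UAG = 0L, UGA = 1L))
  expect_equal(s[["UGAA"]], "g3")
  expect_equal(sort(s[["UAAG"]]), "g1")

  te <- setNames(seq(0.1, 2, length.out = 20), paste0("t", 1:20))
  orfs20 <- toy_orf_table(paste0("t", 1:20),
                          start = seq(1, by = 100, length.out = 20),
                          end = seq(60, by = 100, length.out = 20))
  s20 <- stratify(orfs20, te = te)
  expect_equal(sort(s20[["top-TE-decile"]]), sort(c("t19", "t20")))
})

test_that("replicate combination averages medians with sd/sqrt(n) spread", {
  base <- metagene_profile(metagene_orfs(), uniform_track(2000, 1))
  # identical replicates: mean unchanged, stderr 0
  comb <- combine_replicates(list(base, base, base))
  expect_equal(comb$median_density, base$median_density)
  expect_equal(comb$stderr, rep(0, nrow(base)))
  # two replicates at 1 and 3 -> mean 2
  p3 <- base; p3$median_density <- base$median_density * 3
  two <- combine_replicates(list(base, p3))
  expect_equal(two$median_density, rep(2, nrow(base)))
  # four replicates, hand formula
  reps <- lapply(c(1, 2, 3, 4), function(k) {
    p <- base; p$median_density <- rep(k, nrow(base)); p
  })
  four <- combine_replicates(reps)
  expect_equal(four$median_density, rep(2.5, nrow(base)))
  expect_equal(four$stderr, rep(sd(c(1, 2, 3, 4)) / 2, nrow(base)))
  # mismatched strata refuse to combine
  other <- base; other$stratum <- "UGA"
  expect_error(combine_replicates(list(base, other)), "strata")
})

test_that("stop occupancy ratio recovers constructed fold changes", {
  base <- metagene_profile(metagene_orfs(), uniform_track(2000, 1))
  expect_equal(stop_occupancy_ratio(base, base), 1)
  peaked <- base
  peaked$median_density[peaked$offset %in% 0:2] <- 2.5
  expect_equal(stop_occupancy_ratio(peaked, base), 2.5)
  zero <- base; zero$median_density[] <- 0
  expect_error(stop_occupancy_ratio(base, zero), "zero stop occupancy")
})
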