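test_that("pairwise differences equal a brute-force site scan", {
  aln <- cr_alignment(paste0("s", 1:4),
                      c("ACGTAC", "ACGTAT", "AC-TAT", "NCGTAA"))
  pd <- pairwise_differences(aln)
  # independent brute force
  mats <- strsplit(aln$seqs, "")
  for (i in 1:3) for (j in (i + 1):4) {
    a <- mats[[i]]; b <- mats[[j]]
    ok <- a %in% c("A","C","G","T") & b %in% c("A","C","G","T")
    expect_equal(pd$diff[i, j], sum(a[ok] != b[ok]))
    expect_equal(pd$comparable[i, j], sum(ok))
  }
  expect_true(all(diag(pd$diff) == 0))
  expect_equal(pd$diff, t(pd$diff))
})

test_that("haplotype diversity matches Nei's formula and published roundings", {
  # 17 samples, 16 haplotypes forces counts {2, 1 x 15}
  kw <- haplotype_diversity(c(2, rep(1, 15)))
  expect_equal(round(kw$h, 2), 0.99)
  expect_equal(kw$h, 17 / 16 * (1 - (4 + 15) / 289))
  # 20 samples, 19 haplotypes
  ld <- haplotype_diversity(c(2, rep(1, 18)))
  expect_equal(round(ld$h, 2), 0.99)
  # degenerate cases
  expect_equal(haplotype_diversity(5)$h, 0)
  expect_equal(haplotype_diversity(c(1, 1))$h, 1)
  expect_error(haplotype_diversity(1), "n < 2")
  # invariance to relabeling, strict increase when a doubleton splits
  expect_equal(haplotype_diversity(c(3, 2, 1))$h,
               haplotype_diversity(c(1, 3, 2))$h)
  expect_gt(haplotype_diversity(c(3, 1, 1, 1))$h,
            haplotype_diversity(c(3, 2, 1))$h)
})

test_that("nucleotide diversity is the mean per-site pairwise distance", {
  two <- cr_alignment(c("x", "y"),
                      c(strrep("A", 993),
                        paste0(strrep("A", 983), strrep("C", 10))))
  nd <- nucleotide_diversity(two)
  expect_equal(nd$pi, 10 / 993)
  expect_equal(nucleotide_diversity(cr_alignment(c("x","y"),
                                                 c("ACGT","ACGT")))$pi, 0)
  # 4-sequence brute force over the 6 pairs
  aln <- toy_alignment()
  pd <- pairwise_differences(aln)
  ut <- upper.tri(pd$diff)
  expect_equal(nucleotide_diversity(aln)$pi,
               mean(pd$diff[ut] / pd$comparable[ut]))
  expect_equal(nucleotide_diversity(aln)$k_mean, mean(pd$diff[ut]))
})

test_that("TN93 distances agree with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(5)
  for (rep in 1:5) {
    g <- simulate_genealogy(sim_config("constant", n = 6, theta = 8, L = 400))
    aln <- evolve_sequences(g, list(freqs = rep(0.25, 4), kappa = 4), 400)
    dna <- ape::as.DNAbin(t(sapply(strsplit(aln$seqs, ""), tolower)))
    ref <- as.matrix(ape::dist.dna(dna, model = "TN93"))
    # ape uses per-pair empirical frequencies? no: overall base freqs
    got <- tn93_matrix(aln)
    expect_equal(got[lower.tri(got)], ref[lower.tri(ref)], tolerance = 1e-6)
    refg <- as.matrix(ape::dist.dna(dna, model = "TN93", gamma = 0.61))
    gotg <- tn93_matrix(aln, gamma = TRUE, alpha = 0.61)
    expect_equal(gotg[lower.tri(gotg)], refg[lower.tri(refg)],
                 tolerance = 1e-6)
  }
})

test_that("distance corrections are monotone: TN93+G >= TN93 >= p-distance", {
  set.seed(11)
  g <- simulate_genealogy(sim_config("constant", n = 8, theta = 15, L = 500))
  aln <- evolve_sequences(g, list(freqs = c(.37, .1, .08, .45), kappa = 6), 500)
  pd <- pairwise_differences(aln)
  p <- pd$diff / pd$comparable
  tn <- tn93_matrix(aln)
  tng <- tn93_matrix(aln, gamma = TRUE, alpha = 0.61)
  ut <- upper.tri(p)
  expect_true(all(tn[ut] - p[ut] >= -1e-12))
  expect_true(all(tng[ut] - tn[ut] >= -1e-12))
  # identical pair is 0; saturation raises an error, zero overlap errors
  expect_equal(tn93_distance("ACGT", "ACGT", freqs = rep(.25, 4)), 0)
  expect_error(tn93_distance("AAAA", "NNNN", freqs = rep(.25, 4)),
               "no comparable")
})

test_that("large-alpha gamma distance approaches the plain TN93 distance", {
  d0 <- crpopgen:::tn93_from_props(0.01, 0.01, 0.01, rep(0.25, 4))
  dg <- crpopgen:::tn93_from_props(0.01, 0.01, 0.01, rep(0.25, 4),
                                   gamma = TRUE, alpha = 1e6)
  expect_equal(dg, d0, tolerance = 1e-6)
})
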