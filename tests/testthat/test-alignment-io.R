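test_that("reading FASTA + popmap validates, uppercases and round-trips", {
  aln <- toy_alignment()
  pm <- toy_popmap()
  fa <- write_temp_fasta(aln)
  tsv <- write_temp_popmap(pm)
  got <- read_alignment(fa, tsv)
  expect_equal(got$alignment$L, 10)
  expect_equal(got$alignment$seqs, aln$seqs)
  expect_equal(got$popmap$levels, c("P1", "P2"))

  # lowercase input is normalized so identical haplotypes collapse
  low <- cr_alignment(c("x", "y"), c("acgt", "ACGT"))
  expect_equal(low$seqs[1], low$seqs[2])

  # IUPAC codes other than N convert (default) or reject
  expect_equal(cr_alignment("x", "ACRT")$seqs, "ACNT")
  expect_error(cr_alignment("x", "ACRT", ambiguous = "reject"), "IUPAC")

  # error paths
  expect_error(cr_alignment(c("x", "y"), c("ACGT", "ACG")), "unequal")
  expect_error(cr_alignment(c("x", "x"), c("ACGT", "ACGT")), "duplicate")
  bad <- write_temp_popmap(cr_popmap(c(a1 = "P1")))
  expect_error(read_alignment(fa, bad), "missing from population map")
})

test_that("mask_sites removes 0-based half-open column ranges", {
  aln <- toy_alignment()
  expect_equal(mask_sites(aln, list(c(0, 2)))$L, 8)
  expect_equal(mask_sites(aln, list())$seqs, aln$seqs)
  # idempotence on the same ranges applied to fresh copies; identity edge
  m1 <- mask_sites(aln, list(c(3, 4)))
  expect_equal(m1$L, 9)
  expect_equal(m1$seqs[1], "ACGACGTAC")
  expect_error(mask_sites(aln, list(c(5, 11))), "out of bounds")
  # masking gap-rich columns changes S as hand-counted
  g <- cr_alignment(paste0("s", 1:5),
                    c("A-GT", "A-GT", "AAGT", "ACGA", "A-GT"))
  expect_equal(classify_sites(g)$S, 2)
  masked <- mask_sites(g, list(c(1, 2), c(3, 4)))
  expect_equal(classify_sites(masked)$S, 0)
})

test_that("haplotype collapsing numbers by first appearance and counts per population", {
  aln <- toy_alignment()
  tbl <- collapse_haplotypes(aln, toy_popmap())
  expect_equal(length(tbl$seqs), 3)
  expect_equal(unname(rowSums(tbl$counts)), c(2, 1, 1))
  expect_equal(tbl$counts[1, "P1"], 2L)

  # all distinct -> K = n
  d <- cr_alignment(paste0("s", 1:4), c("AAAA", "AAAT", "AATT", "ATTT"))
  pm <- cr_popmap(stats::setNames(rep("P", 4), d$ids))
  expect_equal(length(collapse_haplotypes(d, pm)$seqs), 4)

  # round trip: expanding counts reproduces the input multiset
  expanded <- rep(tbl$seqs, rowSums(tbl$counts))
  expect_equal(sort(expanded), sort(aln$seqs))
})

test_that("shared/private summary matches the published location table", {
  counts <- published_counts()
  res <- shared_private_summary(counts_as_haplotypes(counts))
  expect_equal(res$n_shared, 12)
  expect_equal(res$n_private, 56)
  expect_equal(res$pct_private, 82.4)

  one <- counts_as_haplotypes(matrix(c(3L, 2L), 2, 1,
                                     dimnames = list(NULL, "P")))
  expect_warning(r1 <- shared_private_summary(one), "single population")
  expect_equal(r1$n_shared, 0)
  expect_equal(r1$pct_private, 100)

  both <- counts_as_haplotypes(matrix(1L, 3, 2,
                                      dimnames = list(NULL, c("A", "B"))))
  r2 <- shared_private_summary(both)
  expect_equal(r2$n_shared, 3)
  expect_equal(r2$pct_private, 0)
})

test_that("site classification counts transitions, transversions and indels by hand", {
  cs <- classify_sites(toy_classified())
  # col1 A/G transition, col3 G/C transversion (s4), col5 C/A transversion?
  # hand count: col1 {A,G} ts; col3 {G,C,-} indel + tv; col5 {C,A} tv
  expect_equal(cs$S, 3)
  expect_equal(cs$n_transitions, 1)
  expect_equal(cs$n_transversions, 2)
  expect_equal(cs$n_indels, 1)
  expect_equal(cs$variable_sites, c(0, 2, 4))
  expect_equal(sum(cs$base_composition), 1, tolerance = 1e-9)

  # single-base-pair columns
  expect_equal(classify_sites(cr_alignment(c("x","y","z"),
                                           c("A","A","G")))$n_transitions, 1)
  r <- classify_sites(cr_alignment(c("x","y","z"), c("A","-","A")))
  expect_equal(r$n_indels, 1)
  expect_equal(r$S, 1)
})
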