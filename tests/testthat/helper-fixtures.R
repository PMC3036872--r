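# Small in-code fixtures shared across the test files.

toy_alignment <- function() {
  cr_alignment(
    c("a1", "a2", "a3", "a4"),
    c("ACGTACGTAC",
      "ACGTACGTAC",
      "ACGAACGTAC",
      "ACGTACGTAT"))
}

toy_popmap <- function() {
  cr_popmap(stats::setNames(c("P1", "P1", "P2", "P2"),
                            c("a1", "a2", "a3", "a4")))
}

# five sequences with two transition columns, one transversion column and
# one gap column (plus invariant background)
toy_classified <- function() {
  cr_alignment(
    paste0("s", 1:5),
    c("AAGTCC",
      "AAGTCC",
      "GAGTAC",
      "GACTAC",
      "AA-TCC"))
}

# published per-location haplotype count table (68 haplotypes x 5 sites)
published_counts <- function() {
  f <- system.file("extdata", "haplotype_counts_table.csv",
                   package = "crpopgen")
  if (f == "") f <- file.path("..", "..", "inst", "extdata",
                              "haplotype_counts_table.csv")
  x <- utils::read.csv(f, check.names = FALSE)
  as.matrix(x[, -1])
}

# wrap a counts matrix in a cr_haplotypes object with dummy sequences
counts_as_haplotypes <- function(counts) {
  structure(list(seqs = paste0("HAP", seq_len(nrow(counts))),
                 counts = counts, members = NULL),
            class = "cr_haplotypes")
}

write_temp_fasta <- function(aln) {
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  f
}

write_temp_popmap <- function(pm) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(names(pm$pop), unname(pm$pop)), f,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  f
}
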