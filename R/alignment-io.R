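#' Construct an alignment object
#'
#' An alignment is a set of equal-length nucleotide sequences over the
#' alphabet `A,C,G,T,-,N`, one per uniquely identified individual. Sequences
#' are uppercased on construction; IUPAC ambiguity codes other than `N` are
#' either converted to `N` or rejected.
#'
#' @param ids character vector of unique sample identifiers.
#' @param seqs character vector of sequences (same length as `ids`).
#' @param ambiguous how to treat IUPAC codes other than A/C/G/T/-/N:
#'   `"convert"` replaces them with `N`, `"reject"` raises an error.
#' @return an object of class `cr_alignment` with elements `ids`, `seqs`,
#'   `mat` (character matrix, individuals x sites) and `L` (sites).
#' @export
cr_alignment <- function(ids, seqs, ambiguous = c("convert", "reject")) {
  ambiguous <- match.arg(ambiguous)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) == 0L) stop("empty alignment", call. = FALSE)
  if (length(ids) != length(seqs)) stop("ids/seqs length mismatch", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have unequal lengths", call. = FALSE)
  if (L == 0L) stop("zero-length sequences", call. = FALSE)
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(ids), ncol = L, byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- !(mat %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    if (ambiguous == "reject")
      stop("alignment contains IUPAC ambiguity codes other than N", call. = FALSE)
    mat[bad] <- "N"
    seqs <- apply(mat, 1L, paste, collapse = "")
  }
  structure(list(ids = ids, seqs = unname(seqs), mat = mat, L = L),
            class = "cr_alignment")
}

#' @export
print.cr_alignment <- function(x, ...) {
  cat("<cr_alignment> ", length(x$ids), " sequences x ", x$L, " sites\n", sep = "")
  invisible(x)
}

#' Construct a population map
#'
#' @param pop named character vector: names are sample ids, values are
#'   population labels.
#' @return object of class `cr_popmap` with `pop` (the vector) and `levels`
#'   (population labels in order of first appearance).
#' @export
cr_popmap <- function(pop) {
  pop <- vapply(pop, as.character, "")
  if (length(pop) == 0L || is.null(names(pop)))
    stop("population map must be a named vector", call. = FALSE)
  structure(list(pop = pop, levels = unique(unname(pop))), class = "cr_popmap")
}

#' Read an aligned FASTA and population map
#'
#' @param fasta_path aligned FASTA file.
#' @param popmap_path two-column tab-separated file (sample id, population),
#'   no header.
#' @param ambiguous passed to [cr_alignment()].
#' @return list with elements `alignment` and `popmap`.
#' @export
read_alignment <- function(fasta_path, popmap_path, ambiguous = "convert") {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("empty FASTA file", call. = FALSE)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("FASTA records have unequal lengths (not an alignment)", call. = FALSE)
  mat <- toupper(as.character(as.matrix(dna)))
  seqs <- apply(mat, 1L, paste, collapse = "")
  aln <- cr_alignment(labels(dna), seqs, ambiguous = ambiguous)
  pm <- utils::read.table(popmap_path, sep = "\t", header = FALSE,
                          colClasses = "character", col.names = c("id", "pop"))
  if (nrow(pm) == 0L) stop("empty population map", call. = FALSE)
  pop <- stats::setNames(pm$pop, pm$id)
  missing <- setdiff(aln$ids, names(pop))
  if (length(missing))
    stop("samples missing from population map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  list(alignment = aln, popmap = cr_popmap(pop[aln$ids]))
}

#' Write an alignment to FASTA
#' @param aln a `cr_alignment`.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), con)
  invisible(path)
}

#' Remove alignment columns
#'
#' Deletes the columns given as 0-based half-open intervals (the convention
#' used internally throughout the package); typically used to strip regions
#' of ambiguous alignment before analysis.
#'
#' @param aln a `cr_alignment`.
#' @param mask_ranges list of integer pairs `c(start, end)` with
#'   `0 <= start <= end <= L`, 0-based half-open.
#' @return a `cr_alignment` with the masked columns removed.
#' @export
mask_sites <- function(aln, mask_ranges) {
  stopifnot(inherits(aln, "cr_alignment"))
  if (length(mask_ranges) == 0L) return(aln)
  drop <- logical(aln$L)
  for (r in mask_ranges) {
    if (length(r) != 2L || r[1] < 0 || r[2] > aln$L || r[1] > r[2])
      stop("mask range out of bounds: [", r[1], ",", r[2], ")", call. = FALSE)
    if (r[2] > r[1]) drop[(r[1] + 1L):r[2]] <- TRUE
  }
  keep <- which(!drop)
  if (length(keep) == 0L) stop("masking removes every column", call. = FALSE)
  mat <- aln$mat[, keep, drop = FALSE]
  cr_alignment(aln$ids, apply(mat, 1L, paste, collapse = ""))
}

#' Collapse an alignment into haplotypes
#'
#' Two sequences carry the same haplotype iff they are identical strings
#' after uppercasing; an `N` mismatching a base makes sequences distinct
#' (conservative). Haplotypes are numbered 1..K in order of first appearance.
#'
#' @param aln a `cr_alignment`.
#' @param popmap a `cr_popmap` covering every sample in `aln`.
#' @return object of class `cr_haplotypes`: `seqs` (K haplotype strings),
#'   `counts` (K x populations integer matrix), `members` (list of sample id
#'   vectors per haplotype).
#' @export
collapse_haplotypes <- function(aln, popmap) {
  stopifnot(inherits(aln, "cr_alignment"), inherits(popmap, "cr_popmap"))
  pops <- popmap$pop[aln$ids]
  if (anyNA(pops)) stop("unmapped samples in alignment", call. = FALSE)
  first <- !duplicated(aln$seqs)
  hseqs <- aln$seqs[first]
  idx <- match(aln$seqs, hseqs)
  counts <- matrix(0L, nrow = length(hseqs), ncol = length(popmap$levels),
                   dimnames = list(seq_along(hseqs), popmap$levels))
  for (i in seq_along(idx)) {
    counts[idx[i], pops[i]] <- counts[idx[i], pops[i]] + 1L
  }
  members <- split(aln$ids, idx)
  structure(list(seqs = hseqs, counts = counts,
                 members = members[as.character(seq_along(hseqs))]),
            class = "cr_haplotypes")
}

#' @export
print.cr_haplotypes <- function(x, ...) {
  cat("<cr_haplotypes> ", length(x$seqs), " haplotypes, ",
      sum(x$counts), " individuals, ", ncol(x$counts), " populations\n", sep = "")
  invisible(x)
}

#' Shared vs sample-specific haplotypes
#'
#' @param tbl a `cr_haplotypes` table.
#' @return list with `n_shared` (haplotypes present in two or more
#'   populations), `n_private`, and `pct_private` (percentage, 1 decimal).
#' @export
shared_private_summary <- function(tbl) {
  stopifnot(inherits(tbl, "cr_haplotypes"))
  if (ncol(tbl$counts) < 2L)
    warning("single population: no haplotype can be shared")
  npops <- rowSums(tbl$counts > 0L)
  K <- nrow(tbl$counts)
  n_shared <- sum(npops >= 2L)
  list(n_shared = n_shared, n_private = K - n_shared,
       pct_private = round(100 * (K - n_shared) / K, 1L))
}

#' Classify variable alignment columns
#'
#' A column is an indel site if it contains at least one `-` among its
#' non-`N` characters. Otherwise every unordered pair of distinct bases
#' observed in the column is counted once, as a transition (A/G, C/T) or a
#' transversion. `S` counts all columns with two or more distinct non-`N`
#' states, indel columns included. Base composition is averaged over all
#' non-gap, non-`N` characters.
#'
#' @param aln a `cr_alignment`.
#' @return list: `S`, `n_transitions`, `n_transversions`, `n_indels`,
#'   `variable_sites` (0-based column indices), `base_composition`
#'   (named fractions for A, C, G, T).
#' @export
classify_sites <- function(aln) {
  stopifnot(inherits(aln, "cr_alignment"))
  mat <- aln$mat
  ts_pairs <- c("A|G", "C|T")
  n_ts <- 0L; n_tv <- 0L; n_indel <- 0L
  varsites <- integer(0)
  for (j in seq_len(aln$L)) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (length(col) == 0L) {
      warning("column ", j, " is all N; excluded from S")
      next
    }
    states <- unique(col)
    if (length(states) < 2L) next
    varsites <- c(varsites, j - 1L)
    if ("-" %in% states) {
      n_indel <- n_indel + 1L
      states <- setdiff(states, "-")
    }
    if (length(states) >= 2L) {
      prs <- utils::combn(sort(states), 2L)
      for (k in seq_len(ncol(prs))) {
        key <- paste(prs[, k], collapse = "|")
        if (key %in% ts_pairs) n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
      }
    }
  }
  chars <- mat[mat %in% c("A", "C", "G", "T")]
  bc <- table(factor(chars, levels = c("A", "C", "G", "T")))
  bc <- as.numeric(bc) / length(chars)
  names(bc) <- c("A", "C", "G", "T")
  list(S = length(varsites), n_transitions = n_ts, n_transversions = n_tv,
       n_indels = n_indel, variable_sites = varsites, base_composition = bc)
}

#' Write a haplotype frequency table as CSV
#'
#' One row per haplotype, one column per population, mirroring the usual
#' published haplotype-distribution tables.
#'
#' @param tbl a `cr_haplotypes`.
#' @param path output CSV file.
#' @export
write_haplotype_table <- function(tbl, path) {
  df <- data.frame(haplotype = seq_len(nrow(tbl$counts)),
                   tbl$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
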