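# Integer-encode an alignment: 1..4 for A,C,G,T; NA for gaps and N.
# Distances use pairwise deletion: a site contributes to a pair iff both
# sequences carry a plain base there.
aln_encode <- function(aln) {
  code <- match(aln$mat, c("A", "C", "G", "T"))
  matrix(code, nrow = nrow(aln$mat), dimnames = dimnames(aln$mat))
}

#' Pairwise difference counts
#'
#' Entry (i, j) is the number of sites at which sequences i and j both carry
#' a plain base (not `-`, not `N`) and the bases differ.
#'
#' @param aln a `cr_alignment`.
#' @return list with `diff` (symmetric integer matrix) and `comparable`
#'   (matrix of counts of pairwise-complete sites).
#' @export
pairwise_differences <- function(aln) {
  stopifnot(inherits(aln, "cr_alignment"))
  x <- aln_encode(aln)
  n <- nrow(x)
  d <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  cmp <- matrix(aln$L, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      xi <- x[i, ]
      for (j in (i + 1L):n) {
        ok <- !is.na(xi) & !is.na(x[j, ])
        nd <- sum(xi[ok] != x[j, ok])
        d[i, j] <- d[j, i] <- nd
        cmp[i, j] <- cmp[j, i] <- sum(ok)
      }
    }
  }
  diag(cmp) <- rowSums(!is.na(x))
  list(diff = d, comparable = cmp)
}

#' Haplotype (gene) diversity
#'
#' Nei's sample-corrected heterozygosity
#' \eqn{h = n(1 - \sum p_i^2)/(n-1)} with its sampling variance
#' \eqn{V(h) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p^3 - (\sum p^2)^2\right) + \sum p^2 - (\sum p^2)^2\right]}.
#'
#' @param counts integer vector of haplotype counts (all >= 1).
#' @param n sample size; defaults to `sum(counts)`.
#' @return list with `h` and `sd_h`.
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- as.numeric(counts)
  if (any(counts < 1) || abs(sum(counts) - n) > 1e-9)
    stop("counts must be >= 1 and sum to n", call. = FALSE)
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, sd_h = sqrt(max(v, 0)))
}

#' Nucleotide diversity
#'
#' Mean per-site distance over all sequence pairs. The default (and the
#' definition of Nei's pi) is the p-distance on pairwise-complete sites;
#' corrected distances can be requested for comparison. The standard error
#' combines the sampling and stochastic variance terms
#' \eqn{V(\pi) = \frac{n+1}{3(n-1)}\frac{\pi}{L} + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param aln a `cr_alignment` with at least 2 sequences.
#' @param model `"p"` (default), `"TN93"` or `"TN93+G"`.
#' @param alpha gamma shape for `"TN93+G"`.
#' @return list with `pi`, `sd_pi`, `n`, `k_mean` (mean pairwise
#'   differences, p-distance scale times comparable sites).
#' @export
nucleotide_diversity <- function(aln, model = c("p", "TN93", "TN93+G"),
                                 alpha = 0.61) {
  model <- match.arg(model)
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  pd <- pairwise_differences(aln)
  ut <- upper.tri(pd$diff)
  cmpu <- pd$comparable[ut]
  if (any(cmpu == 0)) {
    warning("pairs with zero comparable sites excluded")
  }
  keep <- cmpu > 0
  if (model == "p") {
    per_site <- (pd$diff[ut] / cmpu)[keep]
  } else {
    dm <- tn93_matrix(aln, gamma = (model == "TN93+G"), alpha = alpha)
    per_site <- dm[ut][keep]
  }
  pi <- mean(per_site)
  Lbar <- mean(cmpu[keep])
  v <- (n + 1) / (3 * (n - 1)) * pi / Lbar +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, sd_pi = sqrt(max(v, 0)), n = n,
       k_mean = mean(pd$diff[ut][keep]))
}

#' Tamura-Nei (1993) distance between two sequences
#'
#' Closed-form TN93 distance, optionally with gamma rate heterogeneity.
#' With base frequencies \eqn{g_A..g_T}, purine/pyrimidine sums
#' \eqn{g_R, g_Y}, observed proportions \eqn{P_1} (A/G transitions),
#' \eqn{P_2} (C/T transitions) and \eqn{Q} (transversions):
#' \deqn{d = -k_1 \ln w_1 - k_2 \ln w_2 - k_3 \ln w_3}
#' with the usual coefficients; the gamma variant replaces each
#' \eqn{-k\ln w} by \eqn{k\,\alpha(w^{-1/\alpha} - 1)}.
#'
#' @param seq_i,seq_j sequences (strings or character vectors).
#' @param freqs base frequencies (A, C, G, T); must be strictly positive.
#' @param gamma logical, apply gamma correction.
#' @param alpha gamma shape.
#' @return non-negative distance (per site).
#' @export
tn93_distance <- function(seq_i, seq_j, freqs, gamma = FALSE, alpha = 0.61) {
  xi <- toupper(if (length(seq_i) == 1L) strsplit(seq_i, "")[[1]] else seq_i)
  xj <- toupper(if (length(seq_j) == 1L) strsplit(seq_j, "")[[1]] else seq_j)
  ci <- match(xi, c("A", "C", "G", "T"))
  cj <- match(xj, c("A", "C", "G", "T"))
  ok <- !is.na(ci) & !is.na(cj)
  if (!sum(ok)) stop("no comparable sites", call. = FALSE)
  tn93_from_props(
    P1 = mean((ci[ok] == 1 & cj[ok] == 3) | (ci[ok] == 3 & cj[ok] == 1)),
    P2 = mean((ci[ok] == 2 & cj[ok] == 4) | (ci[ok] == 4 & cj[ok] == 2)),
    Q = mean(ci[ok] != cj[ok] &
               ((ci[ok] %in% c(1, 3)) != (cj[ok] %in% c(1, 3)))),
    freqs = freqs, gamma = gamma, alpha = alpha)
}

tn93_from_props <- function(P1, P2, Q, freqs, gamma = FALSE, alpha = 0.61) {
  stopifnot(all(freqs > 0), alpha > 0)
  gA <- freqs[1]; gC <- freqs[2]; gG <- freqs[3]; gT <- freqs[4]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 * gR / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - P2 * gY / (2 * gT * gC) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (any(c(w1, w2, w3) <= 0))
    stop("TN93 distance saturated (log argument <= 0)", call. = FALSE)
  if (gamma) {
    g <- function(w) alpha * (w^(-1 / alpha) - 1)
    d <- k1 * g(w1) + k2 * g(w2) + k3 * g(w3)
  } else {
    d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  }
  max(unname(d), 0)
}

#' All-pairs TN93 distance matrix
#'
#' Uses empirical base frequencies pooled over the whole alignment and
#' pairwise deletion of gap/N sites.
#'
#' @inheritParams nucleotide_diversity
#' @param gamma logical, gamma-correct.
#' @return symmetric matrix of per-site distances.
#' @export
tn93_matrix <- function(aln, gamma = FALSE, alpha = 0.61) {
  x <- aln_encode(aln)
  n <- nrow(x)
  freqs <- as.numeric(table(factor(x, levels = 1:4)))
  freqs <- freqs / sum(freqs)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n < 2L) return(d)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      ci <- x[i, ok]; cj <- x[j, ok]
      P1 <- mean((ci == 1 & cj == 3) | (ci == 3 & cj == 1))
      P2 <- mean((ci == 2 & cj == 4) | (ci == 4 & cj == 2))
      Q <- mean(ci != cj & ((ci %in% c(1, 3)) != (cj %in% c(1, 3))))
      d[i, j] <- d[j, i] <- tn93_from_props(P1, P2, Q, freqs,
                                            gamma = gamma, alpha = alpha)
    }
  }
  d
}

#' Per-population diversity summary
#'
#' @param aln a `cr_alignment`.
#' @param popmap a `cr_popmap`.
#' @return data.frame, one row per population plus a pooled `Total` row:
#'   n, K (haplotypes), S, h, sd_h, pi, sd_pi, k_mean.
#' @export
diversity_table <- function(aln, popmap) {
  pops <- popmap$pop[aln$ids]
  rows <- lapply(c(popmap$levels, "Total"), function(p) {
    ids <- if (p == "Total") aln$ids else aln$ids[pops == p]
    sub <- cr_alignment(ids, aln$seqs[match(ids, aln$ids)])
    cs <- classify_sites(sub)
    hap <- table(sub$seqs)
    hd <- haplotype_diversity(as.integer(hap))
    nd <- nucleotide_diversity(sub)
    data.frame(population = p, n = length(ids), K = length(hap), S = cs$S,
               h = hd$h, sd_h = hd$sd_h, pi = nd$pi, sd_pi = nd$sd_pi,
               k_mean = nd$k_mean)
  })
  do.call(rbind, rows)
}

#' Write a square distance matrix in PHYLIP format
#' @param d symmetric numeric matrix with row names.
#' @param path output file.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  nm <- formatC(substr(rownames(d), 1, 10), width = -10)
  for (i in seq_len(nrow(d)))
    writeLines(paste(nm[i], paste(sprintf("%.8f", d[i, ]), collapse = " ")), con)
  invisible(path)
}
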