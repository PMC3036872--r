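# log unsigned Stirling numbers of the first kind, row n (k = 1..n),
# computed by the triangular recurrence in log space and cached per n.
.stirling_cache <- new.env(parent = emptyenv())

log_stirling1_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  row <- 0 # n = 1: |S1(1,1)| = 1
  if (n > 1L) {
    for (i in 2:n) {
      # row holds k = 1..(i-1); new row k = 1..i:
      # |S1(i,k)| = (i-1)|S1(i-1,k)| + |S1(i-1,k-1)|
      a <- c(row + log(i - 1), -Inf)     # (i-1)|S1(i-1,k)| for k=1..i
      b <- c(-Inf, row)                  # |S1(i-1,k-1)|
      m <- pmax(a, b)
      row <- ifelse(is.infinite(m) & m < 0, -Inf,
                    m + log(exp(a - m) + exp(b - m)))
    }
  }
  .stirling_cache[[key]] <- row
  row
}

#' Tajima's D
#'
#' Compares the mean number of pairwise differences with Watterson's
#' estimate from the number of segregating sites, standardized by the usual
#' constants \eqn{a_1,a_2,b_1,b_2,c_1,c_2,e_1,e_2}.
#'
#' @param n sample size (>= 4).
#' @param S number of segregating sites.
#' @param k_mean mean pairwise differences.
#' @return the statistic, or `NA` with attribute `reason` when `S = 0`.
#' @export
tajimas_D <- function(n, S, k_mean) {
  stopifnot(n >= 4)
  if (S == 0) return(structure(NA_real_, reason = "S=0: D undefined"))
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_mean - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu's Fs
#'
#' \eqn{F_s = \ln(S'/(1-S'))} where \eqn{S'} is the Ewens-sampling-formula
#' probability of observing at least the sample's number of haplotypes given
#' \eqn{\theta} equal to the mean pairwise differences:
#' \eqn{S' = \sum_{k=K}^n |S_1(n,k)|\,\theta^k / \theta^{(n)}} with unsigned
#' Stirling numbers of the first kind and the rising factorial
#' \eqn{\theta^{(n)}}. Computed in log space.
#'
#' @param n sample size.
#' @param K number of distinct haplotypes (1..n).
#' @param k_mean mean pairwise differences, used as \eqn{\theta}.
#' @return the statistic; `+Inf` when `K = 1` or `theta = 0` (boundary).
#' @export
fus_Fs <- function(n, K, k_mean) {
  stopifnot(n >= 2, K >= 1, K <= n, k_mean >= 0)
  theta <- k_mean
  if (K == 1L || theta == 0) return(Inf)
  lrow <- log_stirling1_row(n)
  lpoch <- sum(log(theta + 0:(n - 1)))
  lp <- lrow + (1:n) * log(theta) - lpoch
  m <- max(lp[K:n])
  lSp <- m + log(sum(exp(lp[K:n] - m)))
  lSp <- min(lSp, 0)
  Sp <- exp(lSp)
  if (Sp >= 1) return(Inf)
  # log(Sp/(1-Sp)) computed stably
  lSp - log1p(-Sp)
}

# Null distributions of D and Fs from neutral constant-size coalescent
# replicates. Mutation placement is conditional on the observed number of
# segregating sites (exactly S mutations, multinomial in branch lengths),
# which makes the null scale-free; without an observed S, mutations are
# Poisson with rate set by theta (the observed mean pairwise differences).
sim_neutral_null <- function(n, theta, n_reps, S = NULL) {
  cfg <- sim_config("constant", n = n, theta = max(theta, 1e-8), L = 1)
  D <- numeric(n_reps); Fs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    g <- simulate_genealogy(cfg)
    st <- genealogy_mutation_stats(g, fixed_S = S)
    D[r] <- if (n < 4) NA_real_ else
      if (st$S == 0) 0 else tajimas_D(n, st$S, st$k_mean)
    Fs[r] <- fus_Fs(n, st$K, st$k_mean)
  }
  list(D = D, Fs = Fs)
}

#' Coalescent p-values for the neutrality tests
#'
#' Simulates `n_reps` neutral constant-size coalescent samples with
#' \eqn{\theta} set to the observed mean pairwise differences and reports
#' one-sided p-values toward the negative (expansion-signal) tail:
#' the fraction of simulated statistics at or below the observed one.
#'
#' @param D,Fs observed statistics.
#' @param n sample size.
#' @param theta observed mean pairwise differences.
#' @param n_reps simulation replicates (>= 100).
#' @param seed integer seed.
#' @param S observed number of segregating sites; when given, each null
#'   replicate carries exactly `S` mutations placed multinomially along the
#'   branches (the conditional test), otherwise mutations are Poisson.
#' @return list with `p_D`, `p_Fs`, `n_reps`, and display strings (`"< 1/n"`
#'   when no replicate was as extreme).
#' @export
neutrality_pvalues <- function(D, Fs, n, theta, n_reps = 1000, seed,
                               S = NULL) {
  stopifnot(n_reps >= 100)
  set.seed(seed)
  null <- sim_neutral_null(n, theta, n_reps, S = S)
  p_D <- if (is.na(D) || anyNA(null$D)) NA_real_ else mean(null$D <= D)
  p_Fs <- mean(null$Fs <= Fs)
  fmt <- function(p) if (is.na(p)) "NA" else if (p == 0)
    sprintf("< %g", 1 / n_reps) else sprintf("%g", p)
  list(p_D = p_D, p_Fs = p_Fs, n_reps = n_reps,
       p_D_label = fmt(p_D), p_Fs_label = fmt(p_Fs))
}

#' Neutrality tests for an alignment
#'
#' Computes S, the mean pairwise differences and the haplotype count on
#' non-gap, non-N pairwise-complete sites, then Tajima's D, Fu's Fs, and
#' their coalescent p-values.
#'
#' @param aln a `cr_alignment`.
#' @param n_reps simulation replicates for the p-values.
#' @param seed integer seed.
#' @return list of class `cr_neutrality`: `D`, `p_D`, `Fs`, `p_Fs`, `n`,
#'   `S`, `k_mean`, `K`, `n_reps`.
#' @export
neutrality_test <- function(aln, n_reps = 1000, seed = 1) {
  n <- length(aln$ids)
  cs <- classify_sites(aln)
  nd <- nucleotide_diversity(aln)
  K <- length(unique(aln$seqs))
  D <- if (n >= 4) tajimas_D(n, cs$S, nd$k_mean) else
    structure(NA_real_, reason = "n < 4: D undefined")
  Fs <- fus_Fs(n, K, nd$k_mean)
  pv <- neutrality_pvalues(D, Fs, n, nd$k_mean, n_reps, seed,
                           S = if (cs$S > 0) cs$S else NULL)
  structure(list(D = D, p_D = pv$p_D, Fs = Fs, p_Fs = pv$p_Fs, n = n,
                 S = cs$S, k_mean = nd$k_mean, K = K, n_reps = n_reps),
            class = "cr_neutrality")
}

#' @export
print.cr_neutrality <- function(x, ...) {
  cat(sprintf("Tajima's D = %.3f (p = %s), Fu's Fs = %.3f (p = %s)\n",
              x$D, format(x$p_D), x$Fs, format(x$p_Fs)))
  invisible(x)
}
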