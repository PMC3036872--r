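# Sums of squares from a squared-distance matrix: SS of a set of
# individuals = sum over pairs of squared distances / set size.
ss_set <- function(d2, idx) {
  if (length(idx) < 2L) return(0)
  sub <- d2[idx, idx, drop = FALSE]
  sum(sub[upper.tri(sub)]) / length(idx)
}

amova_components <- function(d2, pop, groups = NULL) {
  pops <- unique(pop)
  n <- length(pop)
  np <- table(factor(pop, levels = pops))
  SS_total <- ss_set(d2, seq_len(n))
  SS_within <- sum(vapply(pops, function(p) ss_set(d2, which(pop == p)), 0))
  if (is.null(groups)) {
    P <- length(pops)
    df_a <- P - 1L; df_w <- n - P
    SS_among <- SS_total - SS_within
    MS_a <- SS_among / df_a; MS_w <- SS_within / df_w
    n0 <- (n - sum(np^2) / n) / (P - 1)
    sig_w <- MS_w
    sig_a <- (MS_a - MS_w) / n0
    tot <- sig_a + sig_w
    list(levels = c("among populations", "within populations"),
         df = c(df_a, df_w), SS = c(SS_among, SS_within),
         sigma2 = c(sig_a, sig_w),
         phi = c(Phi_ST = if (tot == 0) NA_real_ else sig_a / tot))
  } else {
    glev <- unique(unlist(groups)) # groups: named list pop label vectors
    if (!setequal(unlist(groups), pops))
      stop("groups must partition the populations", call. = FALSE)
    gid <- stats::setNames(rep(names(groups), lengths(groups)), unlist(groups))
    gpop <- gid[pop]
    G <- length(groups); P <- length(pops)
    Ng <- table(factor(gpop, levels = names(groups)))
    SS_group_tot <- sum(vapply(names(groups), function(g)
      ss_set(d2, which(gpop == g)), 0))
    SS_b <- SS_group_tot - SS_within            # among pops within groups
    SS_a <- SS_total - SS_group_tot             # among groups
    df_a <- G - 1L; df_b <- P - G; df_c <- n - P
    MS_a <- SS_a / df_a; MS_b <- SS_b / df_b; MS_c <- SS_within / df_c
    sum_np2_by_g <- vapply(names(groups), function(g)
      sum(np[names(np) %in% groups[[g]]]^2) / sum(np[names(np) %in% groups[[g]]]), 0)
    n1 <- (n - sum(sum_np2_by_g)) / (P - G)
    n2 <- (sum(sum_np2_by_g) - sum(np^2) / n) / (G - 1)
    n3 <- (n - sum(Ng^2) / n) / (G - 1)
    sig_c <- MS_c
    sig_b <- (MS_b - MS_c) / n1
    sig_a <- (MS_a - MS_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    list(levels = c("among groups", "among populations within groups",
                    "within populations"),
         df = c(df_a, df_b, df_c), SS = c(SS_a, SS_b, SS_within),
         sigma2 = c(sig_a, sig_b, sig_c),
         phi = c(Phi_ST = if (tot == 0) NA_real_ else (sig_a + sig_b) / tot,
                 Phi_CT = if (tot == 0) NA_real_ else sig_a / tot,
                 Phi_SC = if (sig_b + sig_c == 0) NA_real_
                          else sig_b / (sig_b + sig_c)))
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Partitions squared molecular distances among populations (and optionally
#' among groups of populations) into variance components, with
#' distance-based fixation indices (Phi statistics) and permutation
#' p-values. Components are reported as estimated, negative values
#' included. Permutation schemes: individuals among populations for Phi_ST
#' (and Phi_SC, within groups); whole populations among groups for Phi_CT.
#' p-values use the `(hits + 1)/(n_perms + 1)` correction.
#'
#' @param dist_matrix_squared symmetric matrix of squared distances between
#'   individuals.
#' @param popmap a `cr_popmap`, or a character vector of population labels
#'   in the order of the matrix rows.
#' @param groups optional named list of population-label vectors defining a
#'   higher grouping level.
#' @param n_perms number of permutations (0 disables testing).
#' @param seed integer seed.
#' @return list of class `cr_amova` with `table` (df, SS, variance
#'   components, percentages), `phi`, `p` and `n_perms`.
#' @export
amova <- function(dist_matrix_squared, popmap, groups = NULL,
                  n_perms = 5000, seed = 1) {
  pop <- if (inherits(popmap, "cr_popmap"))
    unname(popmap$pop[rownames(dist_matrix_squared)]) else as.character(popmap)
  if (anyNA(pop) || length(pop) != nrow(dist_matrix_squared))
    stop("population labels do not match distance matrix", call. = FALSE)
  if (length(unique(pop)) < 2L)
    stop("AMOVA needs at least 2 populations", call. = FALSE)
  obs <- amova_components(dist_matrix_squared, pop, groups)
  p <- rep(NA_real_, length(obs$phi))
  names(p) <- names(obs$phi)
  if (n_perms > 0 && !anyNA(obs$phi)) {
    set.seed(seed)
    hits <- stats::setNames(numeric(length(obs$phi)), names(obs$phi))
    pops <- unique(pop)
    for (b in seq_len(n_perms)) {
      perm_ind <- sample(pop)                       # individuals across all
      st <- amova_components(dist_matrix_squared, perm_ind, groups)
      hits["Phi_ST"] <- hits["Phi_ST"] + (st$phi["Phi_ST"] >= obs$phi["Phi_ST"])
      if (!is.null(groups)) {
        # Phi_SC: individuals among populations within groups
        gid <- stats::setNames(rep(names(groups), lengths(groups)),
                               unlist(groups))
        perm_w <- pop
        for (g in names(groups)) {
          sel <- gid[pop] == g
          perm_w[sel] <- sample(pop[sel])
        }
        st2 <- amova_components(dist_matrix_squared, perm_w, groups)
        hits["Phi_SC"] <- hits["Phi_SC"] +
          (st2$phi["Phi_SC"] >= obs$phi["Phi_SC"])
        # Phi_CT: whole populations among groups
        gsizes <- lengths(groups)
        shuffled <- sample(pops)
        gr2 <- split(shuffled, rep(names(groups), gsizes))[names(groups)]
        st3 <- amova_components(dist_matrix_squared, pop, gr2)
        hits["Phi_CT"] <- hits["Phi_CT"] +
          (st3$phi["Phi_CT"] >= obs$phi["Phi_CT"])
      }
    }
    p <- (hits + 1) / (n_perms + 1)
  }
  pct <- 100 * obs$sigma2 / sum(obs$sigma2)
  structure(list(table = data.frame(source = obs$levels, df = obs$df,
                                    SS = obs$SS, sigma2 = obs$sigma2,
                                    percent = pct),
                 phi = obs$phi, p = p, n_perms = n_perms),
            class = "cr_amova")
}

#' @export
print.cr_amova <- function(x, ...) {
  print(x$table, row.names = FALSE)
  for (nm in names(x$phi))
    cat(sprintf("%s = %.5f (p = %s)\n", nm, x$phi[nm], format(x$p[nm])))
  invisible(x)
}

#' Pairwise population Phi_ST matrix
#'
#' Runs a two-population AMOVA for every pair of populations; negative
#' estimates are reported as-is. Populations of size one are excluded with
#' a warning.
#'
#' @inheritParams amova
#' @param n_perms permutations per pair.
#' @return list of class `cr_pairwise_phist` with `phist` (matrix, values
#'   in the lower triangle), `p` (matrix, upper triangle), `n_perms`.
#' @export
pairwise_phist <- function(dist_matrix_squared, popmap, n_perms = 1000,
                           seed = 1) {
  pop <- if (inherits(popmap, "cr_popmap"))
    unname(popmap$pop[rownames(dist_matrix_squared)]) else as.character(popmap)
  pops <- unique(pop)
  sizes <- table(factor(pop, levels = pops))
  if (any(sizes < 2)) {
    warning("excluding populations of size 1: ",
            paste(pops[sizes < 2], collapse = ", "))
    pops <- pops[sizes >= 2]
  }
  P <- length(pops)
  if (P < 2L) stop("need at least 2 usable populations", call. = FALSE)
  phist <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  set.seed(seed)
  for (a in 1:(P - 1L)) for (b in (a + 1L):P) {
    idx <- which(pop %in% c(pops[a], pops[b]))
    res <- amova(dist_matrix_squared[idx, idx, drop = FALSE], pop[idx],
                 n_perms = n_perms, seed = sample.int(2^31 - 1, 1))
    phist[b, a] <- res$phi["Phi_ST"]
    pmat[a, b] <- res$p["Phi_ST"]
  }
  structure(list(phist = phist, p = pmat, n_perms = n_perms),
            class = "cr_pairwise_phist")
}

#' @export
print.cr_pairwise_phist <- function(x, ...) {
  m <- x$phist
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  cat("pairwise Phi_ST (lower) / p-values (upper):\n")
  print(round(m, 5))
  invisible(x)
}

#' Write an AMOVA table as CSV
#' @param res a `cr_amova`.
#' @param path output CSV.
#' @export
write_amova_csv <- function(res, path) {
  tb <- res$table
  tb$Phi <- c(names(res$phi)[1], rep("", nrow(tb) - 1L))
  tb$Phi_value <- c(res$phi[1], rep(NA, nrow(tb) - 1L))
  tb$p <- c(res$p[1], rep(NA, nrow(tb) - 1L))
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}
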