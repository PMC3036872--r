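# Brute-force variance components from the definitional identities, for the
# one-level analysis on arbitrary (small) inputs.
brute_amova <- function(d2, pop) {
  n <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss <- function(idx) {
    if (length(idx) < 2) return(0)
    tot <- 0
    for (i in idx) for (j in idx) if (i < j) tot <- tot + d2[i, j]
    tot / length(idx)
  }
  SS_total <- ss(1:n)
  SS_w <- sum(sapply(pops, function(p) ss(which(pop == p))))
  SS_a <- SS_total - SS_w
  np <- sapply(pops, function(p) sum(pop == p))
  n0 <- (n - sum(np^2) / n) / (P - 1)
  sig_w <- SS_w / (n - P)
  sig_a <- (SS_a / (P - 1) - sig_w) / n0
  list(SS_a = SS_a, SS_w = SS_w, sig_a = sig_a, sig_w = sig_w,
       phi = sig_a / (sig_a + sig_w))
}

test_that("variance components agree with the brute-force oracle to 1e-10", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 8
    x <- matrix(stats::rnorm(n * 6), n)
    d2 <- as.matrix(stats::dist(x))^2
    rownames(d2) <- colnames(d2) <- paste0("i", 1:n)
    pop <- sample(c("A", "A", "A", "B", "B", "C", "C", "C"))
    ref <- brute_amova(d2, pop)
    got <- amova(d2, pop, n_perms = 0)
    expect_equal(got$table$SS, c(ref$SS_a, ref$SS_w), tolerance = 1e-10)
    expect_equal(got$table$sigma2, c(ref$sig_a, ref$sig_w), tolerance = 1e-10)
    expect_equal(unname(got$phi["Phi_ST"]), ref$phi, tolerance = 1e-10)
    expect_equal(sum(got$table$df), n - 1)
    expect_equal(sum(got$table$percent), 100, tolerance = 0.05)
  }
})

test_that("complete fixation gives Phi_ST = 1 with the exhaustive permutation p", {
  # two pops of two, internally identical, distance 1 between pops
  d2 <- matrix(1, 4, 4); diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- 0
  d2[3, 4] <- d2[4, 3] <- 0
  rownames(d2) <- colnames(d2) <- paste0("i", 1:4)
  pop <- c("A", "A", "B", "B")
  got <- amova(d2, pop, n_perms = 999, seed = 42)
  expect_equal(unname(got$phi["Phi_ST"]), 1)
  # only 3 distinct 2+2 splits exist; one (the observed) attains the maximum
  expect_equal(unname(got$p["Phi_ST"]), 1 / 3, tolerance = 0.05)
})

test_that("panmictic data give near-zero Phi_ST and roughly uniform p", {
  set.seed(12)
  phis <- numeric(30); ps <- numeric(30)
  for (r in 1:30) {
    x <- matrix(stats::rnorm(12 * 4), 12)
    d2 <- as.matrix(stats::dist(x))^2
    rownames(d2) <- colnames(d2) <- paste0("i", 1:12)
    pop <- rep(c("A", "B"), each = 6)   # arbitrary split of one population
    res <- amova(d2, pop, n_perms = 100, seed = r)
    phis[r] <- res$phi["Phi_ST"]; ps[r] <- res$p["Phi_ST"]
  }
  expect_lt(abs(mean(phis)), 0.05)
  expect_gt(mean(ps > 0.2), 0.5)        # not systematically significant
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("two-level analysis partitions df and percentages consistently", {
  set.seed(3)
  n <- 16
  x <- matrix(stats::rnorm(n * 5), n)
  d2 <- as.matrix(stats::dist(x))^2
  rownames(d2) <- colnames(d2) <- paste0("i", 1:n)
  pop <- rep(c("P1", "P2", "P3", "P4"), each = 4)
  groups <- list(G1 = c("P1", "P2"), G2 = c("P3", "P4"))
  res <- amova(d2, pop, groups = groups, n_perms = 200, seed = 9)
  expect_equal(sum(res$table$df), n - 1)
  expect_equal(sum(res$table$percent), 100, tolerance = 0.05)
  expect_equal(sum(res$table$SS), crpopgen:::ss_set(d2, 1:n), tolerance = 1e-9)
  expect_true(all(c("Phi_ST", "Phi_CT", "Phi_SC") %in% names(res$phi)))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_error(amova(d2, pop, groups = list(G1 = "P1")), "partition")
})

test_that("pairwise Phi_ST reports negatives as-is and excludes singletons", {
  set.seed(14)
  x <- matrix(stats::rnorm(13 * 4), 13)
  d2 <- as.matrix(stats::dist(x))^2
  rownames(d2) <- colnames(d2) <- paste0("i", 1:13)
  pop <- c(rep("A", 6), rep("B", 6), "C")
  expect_warning(res <- pairwise_phist(d2, pop, n_perms = 100, seed = 2),
                 "size 1")
  expect_equal(dim(res$phist), c(2, 2))
  expect_true(is.na(res$phist[1, 2]))    # values kept to the lower triangle
  expect_false(is.na(res$phist[2, 1]))
  # fixed differences between pops give Phi_ST 1 at the smallest attainable p
  dfix <- matrix(1, 6, 6); diag(dfix) <- 0
  dfix[1:3, 1:3] <- 0; dfix[4:6, 4:6] <- 0
  rownames(dfix) <- colnames(dfix) <- paste0("i", 1:6)
  rfix <- pairwise_phist(dfix, rep(c("A", "B"), each = 3),
                         n_perms = 200, seed = 5)
  expect_equal(rfix$phist[2, 1], 1)
  expect_lt(rfix$p[1, 2], 0.15)
})

test_that("island-model simulations bracket the expected differentiation", {
  # two haploid demes exchanging migrants: F_ST ~ 1/(1 + 2Nm); target 0.1
  # via the split model at large t with per-lineage migration tuned so the
  # long-run differentiation is moderate
  set.seed(19)
  phis <- numeric(10)
  for (r in 1:10) {
    cfg <- sim_config("im_split", n = c(12, 12), theta_im = c(6, 6, 6),
                      t_split = 60, m = c(1.5, 1.5), L = 600)
    sim <- simulate_dataset(cfg, seed = 100 + r)
    pd <- pairwise_differences(sim$alignment)
    p <- pd$diff / pd$comparable
    res <- amova(p^2, sim$popmap, n_perms = 0)
    phis[r] <- res$phi["Phi_ST"]
  }
  expect_gt(mean(phis), 0.02)
  expect_lt(mean(phis), 0.35)
})
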