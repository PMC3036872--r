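test_that("pair coalescence times follow the scenario clocks", {
  set.seed(51)
  cfg <- sim_config("constant", n = 2, theta = 3, L = 1)
  tm <- replicate(4000, max(simulate_genealogy(cfg)$times))
  # tau units: T2 ~ Exp(1/theta); mean theta within 3 standard errors
  expect_lt(abs(mean(tm) - 3), 3 * stats::sd(tm) / sqrt(4000))

  cfg2 <- sim_config("sudden_expansion", n = 2, theta0 = 1, theta1 = 1e12,
                     tau = 5, L = 1)
  tm2 <- replicate(3000, max(simulate_genealogy(cfg2)$times))
  expect_lt(abs(mean(tm2) - 6), 3 * stats::sd(tm2) / sqrt(3000) + 0.01)
})

test_that("Watterson and pairwise expectations hold under the constant model", {
  set.seed(52)
  cfg <- sim_config("constant", n = 93, theta = 7.5, L = 1)
  S <- numeric(200); k <- numeric(200)
  for (r in 1:200) {
    st <- crpopgen:::genealogy_mutation_stats(simulate_genealogy(cfg))
    S[r] <- st$S; k[r] <- st$k_mean
  }
  expS <- 7.5 * sum(1 / (1:92))
  expect_lt(abs(mean(S) - expS), 3 * stats::sd(S) / sqrt(200))
  expect_lt(abs(mean(k) - 7.5), 3 * stats::sd(k) / sqrt(200))
})

test_that("sequence evolution matches HKY transition probabilities", {
  set.seed(53)
  freqs <- c(0.3725, 0.0957, 0.0793, 0.4524) / 0.9999
  eig <- crpopgen:::hky_eigen(freqs, 8)
  # stationary: rows of P(t) converge to the frequencies
  Pinf <- crpopgen:::hky_pmat(eig, 50)
  expect_equal(unname(Pinf[1, ]), unname(eig$freqs), tolerance = 1e-8)
  # two tips separated by b: expected differences from the matrix exponential
  b <- 0.05; L <- 2000
  P <- crpopgen:::hky_pmat(eig, b)
  p_diff_theory <- 1 - sum(eig$freqs * diag(P))
  g <- crpopgen:::new_genealogy(2L, c(3L, 3L, 0L), c(0, 0, b * L / 2),
                                mut_rate = 1)
  obs <- replicate(300, {
    a <- evolve_sequences(g, list(freqs = freqs, kappa = 8), L)
    mean(strsplit(a$seqs[1], "")[[1]] != strsplit(a$seqs[2], "")[[1]])
  })
  se <- stats::sd(obs) / sqrt(300)
  expect_lt(abs(mean(obs) - p_diff_theory), 3 * se)
})

test_that("equal-frequency kappa=1 evolution reduces to Jukes-Cantor", {
  set.seed(54)
  eig <- crpopgen:::hky_eigen(rep(0.25, 4), 1)
  for (b in c(0.05, 0.2, 0.5)) {
    P <- crpopgen:::hky_pmat(eig, b)
    expect_equal(P[1, 1], 1 / 4 + 3 / 4 * exp(-4 * b / 3), tolerance = 1e-10)
  }
})

test_that("the split scenario respects migration and divergence structure", {
  set.seed(55)
  cfg <- sim_config("im_split", n = c(6, 6), theta_im = c(8, 8, 4),
                    t_split = 2, m = c(0, 0), L = 1)
  for (r in 1:20) {
    g <- simulate_genealogy(cfg)
    expect_equal(sum(lengths(g$mig)), 0)   # m = 0: no migration ever
    # cross-deme coalescences are all older than the split
    dm <- crpopgen:::node_demes(g, 2)
    expect_true(dm$valid)
    crpopgen:::validate_genealogy(g, 2)
  }
  cfgm <- sim_config("im_split", n = c(6, 6), theta_im = c(8, 8, 4),
                     t_split = 2, m = c(0.8, 0.8), L = 1)
  migs <- replicate(50, sum(lengths(simulate_genealogy(cfgm)$mig)))
  expect_gt(mean(migs), 0.5)
  expect_true(all(unlist(lapply(replicate(5, simulate_genealogy(cfgm),
                                          simplify = FALSE),
                                function(g) unlist(g$mig))) < 2))
})

test_that("simulate_dataset is reproducible and writes all artifacts", {
  cfg <- sim_config("constant", n = 6, theta = 4, L = 120)
  d1 <- simulate_dataset(cfg, seed = 7)
  d2 <- simulate_dataset(cfg, seed = 7)
  expect_identical(d1$alignment$seqs, d2$alignment$seqs)
  dir <- tempfile()
  d3 <- simulate_dataset(cfg, seed = 7, dir = dir)
  expect_identical(d3$alignment$seqs, d1$alignment$seqs)
  expect_true(all(file.exists(d3$files)))
  tr <- ape::read.tree(d3$files["newick"])
  expect_equal(length(tr$tip.label), 6)
  truth <- jsonlite::read_json(d3$files["truth"])
  expect_equal(truth$seed, 7)
  # genealogy export is ultrametric (all tips contemporaneous)
  depths <- ape::node.depth.edgelength(tr)[1:6]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
})

test_that("expansion-regime multi-deme datasets show high haplotype diversity", {
  set.seed(56)
  hs <- numeric(15)
  for (r in 1:15) {
    cfg <- sim_config("sudden_expansion", n = 93, L = 993,
                      theta0 = 0.03, theta1 = 80, tau = 8)
    g <- simulate_genealogy(cfg)
    aln <- evolve_sequences(g, list(freqs = cfg$freqs, kappa = cfg$kappa),
                            cfg$L)
    hap <- table(aln$seqs)
    hs[r] <- haplotype_diversity(as.integer(hap))$h
  }
  expect_gt(mean(hs >= 0.9), 0.9)
})
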