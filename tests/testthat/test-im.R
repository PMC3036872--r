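test_that("pruning likelihood matches phangorn under HKY", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  cfg <- sim_config("im_split", n = c(5, 5), theta_im = c(5, 5, 3),
                    t_split = 1, m = c(0.3, 0.3), L = 300)
  g <- simulate_genealogy(cfg)
  aln <- evolve_sequences(g, list(freqs = cfg$freqs, kappa = cfg$kappa), 300)
  ll <- im_likelihood(g, aln, list(kappa = 8, freqs = cfg$freqs))
  tr <- genealogy_to_phylo(g)
  tr$edge.length <- tr$edge.length * g$mut_rate / 300
  m <- t(sapply(strsplit(aln$seqs, ""), identity))
  rownames(m) <- aln$ids
  dat <- phangorn::phyDat(m)
  fit <- phangorn::pml(tr, dat, bf = cfg$freqs, k = 1)
  fit <- stats::update(fit, Q = c(1, 8, 1, 1, 8, 1))
  expect_equal(ll, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("one-site Jukes-Cantor pruning matches an explicit state sum", {
  # 3 tips (A, A, G) on a fixed genealogy; oracle sums over all internal
  # state assignments with JC transition probabilities
  g <- crpopgen:::new_genealogy(3L, c(4L, 4L, 5L, 5L, 0L),
                                c(0, 0, 0, 0.1, 0.25), mut_rate = 1)
  aln <- cr_alignment(c("t1", "t2", "t3"), c("A", "A", "G"))
  ll <- im_likelihood(g, aln, list(freqs = rep(0.25, 4), kappa = 1))
  jc <- function(b, same) if (same) 1/4 + 3/4 * exp(-4 * b / 3) else
    1/4 - 1/4 * exp(-4 * b / 3)
  L <- 1 # one site: per-site branch length = dt * mut_rate / L = dt
  lik <- 0
  for (x4 in 1:4) for (x5 in 1:4) {
    lik <- lik + 0.25 *
      jc(0.1, x4 == 1) * jc(0.1, x4 == 1) *      # t1 = t2 = A
      jc(0.25 - 0.1, x5 == x4) *
      jc(0.25, x5 == 3)                          # t3 = G
  }
  expect_equal(ll, log(lik), tolerance = 1e-10)
})

test_that("likelihood limits and symmetries hold", {
  # two tips, nearly zero depth, invariant site -> log of the base frequency
  g <- crpopgen:::new_genealogy(2L, c(3L, 3L, 0L), c(0, 0, 1e-12),
                                mut_rate = 1)
  aln <- cr_alignment(c("t1", "t2"), c("T", "T"))
  ll <- im_likelihood(g, aln, list(freqs = c(.2, .2, .2, .4), kappa = 2))
  expect_equal(ll, log(0.4), tolerance = 1e-6)
  # relabeling identical sequences leaves the likelihood unchanged
  g3 <- crpopgen:::new_genealogy(3L, c(4L, 4L, 5L, 5L, 0L),
                                 c(0, 0, 0, 0.2, 0.5), mut_rate = 1)
  a1 <- cr_alignment(c("t1", "t2", "t3"), c("ACGT", "ACGT", "AGGT"))
  a2 <- cr_alignment(c("t1", "t2", "t3"), c("ACGT", "AGGT", "ACGT"))
  l1 <- im_likelihood(g3, a1, list(freqs = rep(.25, 4), kappa = 3))
  # swapping tips 2 and 3 with their sequences is a relabeling of the same
  # data when the two tips subtend equal-length pendant branches
  g3b <- crpopgen:::new_genealogy(3L, c(4L, 5L, 4L, 5L, 0L),
                                  c(0, 0, 0, 0.2, 0.5), mut_rate = 1)
  l2 <- im_likelihood(g3b, a2, list(freqs = rep(.25, 4), kappa = 3))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("the structured-coalescent prior rejects inconsistent states", {
  set.seed(30)
  cfg <- sim_config("im_split", n = c(4, 4), theta_im = c(5, 5, 3),
                    t_split = 1.5, m = c(0.5, 0.5), L = 1)
  g <- simulate_genealogy(cfg)
  par <- c(5, 5, 3, 1.5, 0.5, 0.5)
  expect_true(is.finite(crpopgen:::im_log_prior(par, g)))
  if (sum(lengths(g$mig)) > 0) {
    # zero migration rate with events present is impossible
    expect_equal(crpopgen:::im_log_prior(c(5, 5, 3, 1.5, 0, 0), g), -Inf)
    # moving the split below the earliest event is impossible
    tmin <- min(unlist(g$mig))
    expect_equal(crpopgen:::im_log_prior(c(5, 5, 3, tmin * 0.9, .5, .5), g),
                 -Inf)
  }
  expect_equal(crpopgen:::im_log_prior(c(-1, 5, 3, 1.5, .5, .5), g), -Inf)
})

test_that("the prior density integrates correctly on a two-tip case", {
  # two tips in different demes, m = 0: coalescence is only possible above
  # the split, so TMRCA - t is Exp(2/thetaA); check the density pointwise
  thA <- 4; t <- 1.2
  par <- c(3, 3, thA, t, 0, 0)
  for (tau in c(1.3, 2, 5)) {
    g <- crpopgen:::new_genealogy(2L, c(3L, 3L, 0L), c(0, 0, tau),
                                  tip_deme = c(1L, 2L), mut_rate = 1)
    g$mig <- list(numeric(0), numeric(0), numeric(0))
    lp <- crpopgen:::im_log_prior(par, g)
    expect_equal(lp, log(2 / thA) - 2 / thA * (tau - t), tolerance = 1e-10)
  }
})

test_that("genealogy invariants survive accepted sampler moves", {
  set.seed(61)
  cfg <- sim_config("im_split", n = c(4, 4), theta_im = c(6, 6, 4),
                    t_split = 1, m = c(0.4, 0.4), L = 150)
  sim <- simulate_dataset(cfg, seed = 21)
  # debug = TRUE asserts deme consistency and time ordering after every
  # accepted move; any violation aborts the run
  post <- im_mcmc(sim$alignment, sim$popmap,
                  params0 = c(6, 6, 4, 1, 0.4, 0.4),
                  priors = c(theta1 = 30, theta2 = 30, thetaA = 30,
                             t = 5, m1 = 3, m2 = 3),
                  n_burn = 200, n_steps = 3000, thin = 10, seed = 5,
                  debug = TRUE)
  expect_equal(post$n_recorded, 300)
  expect_true(all(post$samples$tmrca > 0))
  expect_true(all(is.finite(post$ess)))
  expect_true(all(post$hpd95[1, ] <= post$hpd95[2, ]))
  # histogram masses sum to one; HPD inside the prior support
  for (h in post$hist) expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_true(all(post$hpd95[2, names(post$priors)] <=
                    post$priors * 1.0001))
})

test_that("demographic unit conversion reproduces the published times", {
  md <- c(theta1 = 197.7, theta2 = 50, thetaA = 23.5, t = 2.4, tmrca = 5.5)
  out <- scale_to_demographic_units(md, u = 1.88e-4)
  expect_equal(out$rounded$divergence_years, 12800)
  expect_equal(out$rounded$tmrca_years, 29300)
  expect_equal(out$N_ef[["theta1"]], 197.7 / 1.88e-4, tolerance = 1e-9)
  md0 <- c(md); md0[["t"]] <- 0
  expect_equal(scale_to_demographic_units(md0, u = 1.88e-4)$divergence_years, 0)
})

test_that("posterior summaries are written to disk", {
  set.seed(62)
  cfg <- sim_config("im_split", n = c(3, 3), theta_im = c(5, 5, 3),
                    t_split = 1, m = c(0.2, 0.2), L = 80)
  sim <- simulate_dataset(cfg, seed = 3)
  post <- im_mcmc(sim$alignment, sim$popmap, likelihood = FALSE,
                  n_burn = 100, n_steps = 2000, thin = 10, seed = 4)
  dir <- tempfile()
  write_im_posterior(post, dir)
  expect_true(file.exists(file.path(dir, "im_summary.json")))
  expect_true(file.exists(file.path(dir, "im_trace.tsv")))
  expect_true(file.exists(file.path(dir, "posterior_theta1.csv")))
  summ <- jsonlite::read_json(file.path(dir, "im_summary.json"))
  expect_equal(summ$n_recorded, post$n_recorded)
})
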