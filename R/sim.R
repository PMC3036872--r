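#' Simulation configuration
#'
#' Describes one synthetic data set: a demographic scenario, sample sizes,
#' sequence length and an HKY substitution model. Defaults mimic an AT-rich
#' mitochondrial control-region locus (993 bp, A 37.25%, C 9.57%, G 7.93%,
#' T 45.24%).
#'
#' Scenarios and their time scales:
#' \describe{
#'   \item{constant}{single population, per-pair coalescence rate
#'     \eqn{1/\theta}; time is measured so that a pair of lineages
#'     accumulates one mutation per unit time ("tau units"), hence the mean
#'     number of pairwise differences equals \eqn{\theta}.}
#'   \item{sudden_expansion}{per-pair rate \eqn{1/\theta_1} more recently
#'     than \eqn{\tau}, \eqn{1/\theta_0} earlier, in the same tau units, so
#'     \eqn{\tau,\theta_0,\theta_1} plug directly into the mismatch
#'     formulas.}
#'   \item{im_split}{two demes with per-pair rates \eqn{2/\theta_i} and
#'     per-lineage migration rates \eqn{m_i}, merging into an ancestral deme
#'     (rate \eqn{2/\theta_A}) at time `t`; time is measured in per-lineage
#'     mutational units ("mu units", divergence in years = t/u), matching
#'     the isolation-with-migration parameterization.}
#' }
#'
#' @param scenario one of `"constant"`, `"sudden_expansion"`, `"im_split"`.
#' @param n samples per deme (scalar, or vector for several demes; exactly 2
#'   demes for `im_split`).
#' @param L sites.
#' @param theta scaled mutation parameter (constant scenario).
#' @param theta0,theta1,tau sudden-expansion parameters.
#' @param theta_im `c(theta1, theta2, thetaA)` for the split scenario.
#' @param t_split split time (mu units).
#' @param m migration rates `c(m1, m2)` per lineage.
#' @param freqs HKY stationary base frequencies (A, C, G, T).
#' @param kappa HKY transition/transversion rate ratio.
#' @param alpha optional gamma shape for rate heterogeneity (NULL = none).
#' @param inv fraction of invariant sites.
#' @return a list of class `cr_simconfig`.
#' @export
sim_config <- function(scenario = c("constant", "sudden_expansion", "im_split"),
                       n = 20, L = 993, theta = 7.5,
                       theta0 = 0.03, theta1 = 62.6, tau = 9.17,
                       theta_im = c(10, 10, 5), t_split = 1, m = c(0, 0),
                       freqs = c(A = 0.3725, C = 0.0957, G = 0.0793, T = 0.4524),
                       kappa = 8, alpha = NULL, inv = 0) {
  scenario <- match.arg(scenario)
  stopifnot(all(n >= 1), sum(n) >= 2, L >= 1,
            abs(sum(freqs) - 1) < 1e-3, all(freqs > 0),
            theta >= 0, theta0 >= 0, theta1 >= 0, tau >= 0,
            all(theta_im >= 0), t_split >= 0, all(m >= 0))
  if (scenario == "im_split" && length(n) != 2L)
    stop("im_split needs exactly 2 demes", call. = FALSE)
  freqs <- freqs / sum(freqs)
  # strip names so event labels built with c(name = value) stay clean
  theta_im <- unname(theta_im); m <- unname(m)
  theta <- unname(theta); theta0 <- unname(theta0)
  theta1 <- unname(theta1); tau <- unname(tau); t_split <- unname(t_split)
  structure(list(scenario = scenario, n = n, L = L, theta = theta,
                 theta0 = theta0, theta1 = theta1, tau = tau,
                 theta_im = theta_im, t_split = t_split, m = m,
                 freqs = freqs, kappa = kappa, alpha = alpha, inv = inv),
            class = "cr_simconfig")
}

# Genealogy object: parent/times vectors over 2n-1 nodes (tips 1..n at time
# 0, internal nodes in coalescence order), per-edge migration event times
# (`mig[[i]]` = flip times on the edge above node i), tip demes, split time,
# and `mut_rate` = whole-sequence mutation rate per lineage per time unit
# (0.5 in tau units, 1 in mu units).
new_genealogy <- function(n_tip, parent, times, tip_deme = NULL,
                          mig = NULL, t_split = NULL, mut_rate = 0.5) {
  structure(list(n_tip = n_tip, parent = parent, times = times,
                 tip_deme = tip_deme,
                 mig = if (is.null(mig)) vector("list", 2 * n_tip - 1) else mig,
                 t_split = t_split, mut_rate = mut_rate),
            class = "cr_genealogy")
}

#' @export
print.cr_genealogy <- function(x, ...) {
  cat("<cr_genealogy> ", x$n_tip, " tips, TMRCA = ",
      signif(max(x$times), 4), "\n", sep = "")
  invisible(x)
}

#' Simulate a coalescent genealogy
#'
#' Draws one genealogy under the scenario in `config` (see [sim_config()]).
#' For `im_split` the returned genealogy carries migration events and tip
#' deme labels; an event log is attached as attribute `"events"`.
#'
#' @param config a `cr_simconfig`.
#' @return a `cr_genealogy`.
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "cr_simconfig"))
  if (config$scenario == "im_split") return(sim_genealogy_im(config))
  n <- sum(config$n)
  parent <- integer(2 * n - 1)
  times <- numeric(2 * n - 1)
  active <- 1:n
  s <- 0
  nxt <- n + 1L
  pair_rate_at <- function(s) {
    if (config$scenario == "constant") {
      if (config$theta <= 0) Inf else 1 / config$theta
    } else if (s < config$tau) {
      if (config$theta1 <= 0) Inf else 1 / config$theta1
    } else {
      if (config$theta0 <= 0) Inf else 1 / config$theta0
    }
  }
  while (length(active) > 1L) {
    k <- length(active)
    repeat {
      pr <- pair_rate_at(s)
      rate <- k * (k - 1) / 2 * pr
      if (is.infinite(rate)) { w <- 0 } else if (rate == 0) {
        # no coalescence this epoch: jump to the epoch boundary
        s <- config$tau
        next
      } else w <- stats::rexp(1, rate)
      if (config$scenario == "sudden_expansion" && s < config$tau &&
          s + w > config$tau && !is.infinite(rate)) {
        s <- config$tau
        next
      }
      s <- s + w
      break
    }
    pick <- sample.int(k, 2L)
    i <- active[pick[1]]; j <- active[pick[2]]
    parent[c(i, j)] <- nxt
    times[nxt] <- s
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  new_genealogy(n, parent, times, mut_rate = 0.5)
}

sim_genealogy_im <- function(config) {
  n1 <- config$n[1]; n2 <- config$n[2]; n <- n1 + n2
  th <- config$theta_im; m <- config$m; tsp <- config$t_split
  parent <- integer(2 * n - 1)
  times <- numeric(2 * n - 1)
  mig <- vector("list", 2 * n - 1)
  tip_deme <- rep(1:2, c(n1, n2))
  deme <- tip_deme                       # deme of each active lineage
  active <- 1:n
  s <- 0; nxt <- n + 1L
  ev_time <- numeric(0); ev_type <- character(0); ev_node <- integer(0)
  log_ev <- function(time, type, node) {
    ev_time[length(ev_time) + 1L] <<- time
    ev_type[length(ev_type) + 1L] <<- type
    ev_node[length(ev_node) + 1L] <<- node
  }
  crate <- function(k, theta) if (theta <= 0) {
    if (k >= 2) Inf else 0
  } else k * (k - 1) / theta            # per-pair 2/theta
  while (length(active) > 1L) {
    k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
    if (s < tsp) {
      r <- c(coal1 = crate(k1, th[1]), coal2 = crate(k2, th[2]),
             mig1 = k1 * m[1], mig2 = k2 * m[2])
      tot <- sum(r)
      w <- if (is.infinite(tot)) 0 else if (tot == 0) Inf else stats::rexp(1, tot)
      if (s + w >= tsp) { # split reached: merge demes into the ancestor
        s <- tsp
        deme[] <- 0L
        log_ev(s, "split", NA_integer_)
        next
      }
      s <- s + w
      type <- sample(names(r), 1L, prob = if (is.infinite(tot))
        as.numeric(is.infinite(r)) else r)
      if (type %in% c("mig1", "mig2")) {
        d <- if (type == "mig1") 1L else 2L
        who <- active[deme == d][sample.int(sum(deme == d), 1L)]
        mig[[who]] <- c(mig[[who]], s)
        deme[active == who] <- 3L - d
        log_ev(s, type, who)
        next
      }
      d <- if (type == "coal1") 1L else 2L
      cand <- which(deme == d)
    } else {
      kA <- length(active)
      rate <- crate(kA, th[3])
      w <- if (is.infinite(rate)) 0 else stats::rexp(1, rate)
      s <- s + w
      cand <- seq_along(active)
    }
    pick <- cand[sample.int(length(cand), 2L)]
    i <- active[pick[1]]; j <- active[pick[2]]
    parent[c(i, j)] <- nxt
    times[nxt] <- s
    dnew <- if (s < tsp) deme[pick[1]] else 0L
    active <- c(active[-pick], nxt)
    deme <- c(deme[-pick], dnew)
    log_ev(s, "coal", nxt)
    nxt <- nxt + 1L
  }
  g <- new_genealogy(n, parent, times, tip_deme = tip_deme, mig = mig,
                     t_split = tsp, mut_rate = 1)
  attr(g, "events") <- data.frame(time = ev_time, type = ev_type,
                                  node = ev_node)
  g
}

# HKY rate matrix (rows = from A,C,G,T), normalized to mean rate 1 per site,
# with its eigendecomposition for fast transition probabilities.
hky_eigen <- function(freqs, kappa) {
  stopifnot(all(freqs > 0), kappa > 0)
  f <- freqs / sum(freqs)
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ts <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
          (i == 2 && j == 4) || (i == 4 && j == 2)
    Q[i, j] <- if (ts) kappa * f[j] else f[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q <- Q / mu
  # symmetrize: B = D^{1/2} Q D^{-1/2} with D = diag(f)
  sq <- sqrt(f)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  E <- diag(1 / sq) %*% e$vectors        # right eigenvectors of Q
  Einv <- t(e$vectors) %*% diag(sq)
  list(Q = Q, values = e$values, E = E, Einv = Einv, freqs = f)
}

# P(b) for one branch length (per-site expected substitutions)
hky_pmat <- function(eig, b) {
  P <- eig$E %*% (exp(eig$values * b) * eig$Einv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve sequences along a genealogy
#'
#' Simulates nucleotide sequences under an HKY model (optionally with
#' gamma-distributed site rates and a fraction of invariant sites) down a
#' genealogy. The root sequence is drawn from the stationary frequencies;
#' per-site branch lengths are `dt * mut_rate / L` so that `mut_rate` is the
#' whole-sequence substitution rate per unit time.
#'
#' @param genealogy a `cr_genealogy`.
#' @param model list with `freqs`, `kappa`, optional `alpha`, `inv`.
#' @param L number of sites.
#' @param seed optional integer seed.
#' @return a `cr_alignment` with ids `t1..tn`.
#' @export
evolve_sequences <- function(genealogy, model, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genealogy
  eig <- hky_eigen(model$freqs, model$kappa)
  rates <- rep(1, L)
  if (!is.null(model$alpha) && is.finite(model$alpha))
    rates <- stats::rgamma(L, shape = model$alpha, rate = model$alpha)
  if (!is.null(model$inv) && model$inv > 0)
    rates[stats::runif(L) < model$inv] <- 0
  nn <- 2 * g$n_tip - 1
  root <- which(g$parent == 0L)
  states <- matrix(NA_integer_, nn, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = eig$freqs)
  ord <- order(g$times[1:nn], decreasing = TRUE)   # root first
  for (v in ord) {
    if (v == root) next
    p <- g$parent[v]
    b <- (g$times[p] - g$times[v]) * g$mut_rate / L
    bs <- b * rates
    M <- exp(outer(bs, eig$values))                # L x 4
    # per-site child distribution: row s of E times diag(exp(lambda b)) Einv
    W <- eig$E[states[p, ], , drop = FALSE] * M    # L x 4 (coords in eigenbasis)
    Pr <- W %*% eig$Einv                           # L x 4 probabilities
    Pr[Pr < 0] <- 0
    cs <- Pr %*% upper.tri(diag(4), diag = TRUE)   # row cumsums
    u <- stats::runif(L) * cs[, 4]
    states[v, ] <- 1L + (u > cs[, 1]) + (u > cs[, 2]) + (u > cs[, 3])
  }
  bases <- c("A", "C", "G", "T")
  seqs <- apply(states[1:g$n_tip, , drop = FALSE], 1L,
                function(r) paste(bases[r], collapse = ""))
  cr_alignment(paste0("t", seq_len(g$n_tip)), seqs)
}

# Drop infinite-site mutations on a genealogy and return summary statistics
# (S, mean pairwise differences, number of distinct haplotypes) without
# building sequences. Used by the neutrality test null distribution.
genealogy_mutation_stats <- function(g, fixed_S = NULL) {
  n <- g$n_tip
  nn <- 2 * n - 1
  root <- which(g$parent == 0L)
  edges <- setdiff(seq_len(nn), root)
  blen <- numeric(nn)
  blen[edges] <- g$times[g$parent[edges]] - g$times[edges]
  muts <- integer(nn)
  if (is.null(fixed_S)) {
    muts[edges] <- stats::rpois(length(edges), blen[edges] * g$mut_rate)
  } else {
    # conditional placement: exactly fixed_S mutations, multinomially
    # distributed in proportion to branch length
    muts[edges] <- stats::rmultinom(1, fixed_S, blen[edges])[, 1]
  }
  # descendant-tip indicator per node (nodes are in increasing time order)
  desc <- matrix(FALSE, nn, n)
  desc[cbind(1:n, 1:n)] <- TRUE
  kids1 <- integer(nn); kids2 <- integer(nn)
  for (v in edges) {
    p <- g$parent[v]
    if (kids1[p] == 0L) kids1[p] <- v else kids2[p] <- v
  }
  for (v in n + order(g$times[(n + 1L):nn])) {
    desc[v, ] <- desc[kids1[v], ] | desc[kids2[v], ]
  }
  S <- sum(muts)
  nd <- rowSums(desc)
  k_mean <- sum(muts * nd * (n - nd)) / (n * (n - 1) / 2)
  mut_edges <- which(muts > 0)
  K <- if (length(mut_edges)) {
    length(unique(apply(desc[mut_edges, , drop = FALSE], 2, paste,
                        collapse = "")))
  } else 1L
  list(S = S, k_mean = k_mean, K = K, muts = muts, n_desc = nd, desc = desc)
}

# Pairwise-difference matrix under the infinite-sites mutation drop above.
genealogy_mutation_diffs <- function(g) {
  st <- genealogy_mutation_stats(g)
  n <- g$n_tip
  d <- matrix(0L, n, n)
  for (v in which(st$muts > 0)) {
    inset <- st$desc[v, ]
    d[inset, !inset] <- d[inset, !inset] + st$muts[v]
    d[!inset, inset] <- d[!inset, inset] + st$muts[v]
  }
  d
}

#' Convert a genealogy to an ape "phylo" tree
#' @param genealogy a `cr_genealogy`.
#' @return an object of class `phylo` with branch lengths in the
#'   genealogy's time units.
#' @export
genealogy_to_phylo <- function(genealogy) {
  g <- genealogy
  n <- g$n_tip; nn <- 2 * n - 1
  # ape convention: tips 1..n, root n+1, internals n+1..2n-1 (root first)
  ord <- order(g$times[(n + 1L):nn], decreasing = TRUE)  # root has max time
  newid <- integer(nn)
  newid[1:n] <- 1:n
  newid[(n + 1L):nn][ord] <- (n + 1L):nn
  nonroot <- which(g$parent > 0L)
  edge <- cbind(newid[g$parent[nonroot]], newid[nonroot])
  elen <- g$times[g$parent[nonroot]] - g$times[nonroot]
  tr <- list(edge = edge, edge.length = elen, tip.label = paste0("t", 1:n),
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a complete data set
#'
#' Draws a genealogy, evolves sequences, and (optionally) writes the FASTA
#' alignment, the tab-separated population map, the newick genealogy and a
#' JSON sidecar echoing the true parameters and seed.
#'
#' @param config a `cr_simconfig`.
#' @param seed integer seed (mandatory for reproducibility).
#' @param dir optional output directory; created if missing.
#' @param prefix file name prefix.
#' @return list with `alignment`, `popmap`, `genealogy`, `config`, `seed`,
#'   and `files` (paths, if written).
#' @export
simulate_dataset <- function(config, seed, dir = NULL, prefix = "sim") {
  set.seed(seed)
  g <- simulate_genealogy(config)
  aln <- evolve_sequences(g, list(freqs = config$freqs, kappa = config$kappa,
                                  alpha = config$alpha, inv = config$inv),
                          config$L)
  demes <- if (!is.null(g$tip_deme)) g$tip_deme else
    rep(seq_along(config$n), config$n)
  pop <- stats::setNames(paste0("pop", demes), aln$ids)
  pm <- cr_popmap(pop)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, paste0(prefix, ".fasta"))
    tsv <- file.path(dir, paste0(prefix, ".popmap.tsv"))
    nwk <- file.path(dir, paste0(prefix, ".nwk"))
    js <- file.path(dir, paste0(prefix, ".truth.json"))
    write_alignment(aln, fa)
    utils::write.table(data.frame(names(pop), unname(pop)), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    ape::write.tree(genealogy_to_phylo(g), nwk)
    truth <- unclass(config)
    truth$alpha <- if (is.null(config$alpha)) NA else config$alpha
    truth$seed <- seed
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
    files <- c(fasta = fa, popmap = tsv, newick = nwk, truth = js)
  }
  list(alignment = aln, popmap = pm, genealogy = g, config = config,
       seed = seed, files = files)
}
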