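#' @section Isolation-with-migration model:
#' A reduced two-population isolation-with-migration sampler for a single
#' non-recombining locus. An ancestral population (scaled size thetaA)
#' splits at scaled time t into two descendant populations (theta1, theta2)
#' that exchange migrants at per-lineage rates m1, m2. All parameters are in
#' per-lineage mutational units: the whole-sequence substitution rate is 1
#' per unit time, the per-pair coalescence rate in deme i is 2/theta_i, and
#' divergence time in years is t/u for a whole-sequence per-generation rate
#' u. The sampler is Metropolis-Hastings over (genealogy, parameters) with
#' uniform priors on [0, bound] for each parameter.
#' @name im-model
NULL

flip_deme <- function(d, k = 1L) ifelse(k %% 2L == 0L, d, 3L - d)

# Demes at the bottom (node) and top (below the split) of every edge.
# Returns valid = FALSE when two lineages coalesce in different demes
# below the split time.
node_demes <- function(g, t) {
  nn <- 2 * g$n_tip - 1
  bottom <- rep(NA_integer_, nn)
  top <- rep(NA_integer_, nn)
  bottom[1:g$n_tip] <- g$tip_deme
  kids <- vector("list", nn)
  for (v in seq_len(nn)) if (g$parent[v] > 0L)
    kids[[g$parent[v]]] <- c(kids[[g$parent[v]]], v)
  ord <- c(1:g$n_tip, g$n_tip + order(g$times[(g$n_tip + 1):nn]))
  for (v in ord) {
    if (v > g$n_tip) {
      ch <- kids[[v]]
      if (g$times[v] < t && length(ch)) {
        tops <- top[ch]
        if (anyNA(tops) || length(unique(tops)) != 1L)
          return(list(valid = FALSE))
        bottom[v] <- tops[1]
      }
    }
    nev <- length(g$mig[[v]])
    top[v] <- if (is.na(bottom[v])) NA_integer_ else flip_deme(bottom[v], nev)
  }
  list(valid = TRUE, bottom = bottom, top = top)
}

# Structured-coalescent log density of a genealogy given IM parameters
# par = c(theta1, theta2, thetaA, t, m1, m2). -Inf when the genealogy is
# inconsistent with the parameters (migration events above the split,
# cross-deme coalescence below it, migration with zero rate, ...).
im_log_prior <- function(par, g) {
  th1 <- par[1]; th2 <- par[2]; thA <- par[3]
  t <- par[4]; m1 <- par[5]; m2 <- par[6]
  if (any(par < 0) || th1 <= 0 || th2 <= 0 || thA <= 0) return(-Inf)
  nn <- 2 * g$n_tip - 1
  dm <- node_demes(g, t)
  if (!dm$valid) return(-Inf)
  # event table: migrations (flip sequence upward from the bottom deme of
  # each edge) and coalescences; type 1=coal1 2=coal2 3=coalA 4=mig1 5=mig2
  lt <- vector("list", nn + 1L); ly <- vector("list", nn + 1L)
  has_ev <- which(lengths(g$mig) > 0)
  for (v in has_ev) {
    mg <- g$mig[[v]]
    if (g$parent[v] == 0L) return(-Inf)   # no edge above the root
    hi <- min(g$times[g$parent[v]], t)
    if (any(mg <= g$times[v]) || any(mg >= hi)) return(-Inf)
    d <- dm$bottom[v]
    if (is.na(d)) return(-Inf)            # edge entirely above the split
    k <- length(mg)
    demes <- if (d == 1L) rep_len(c(1L, 2L), k) else rep_len(c(2L, 1L), k)
    lt[[v]] <- sort(mg); ly[[v]] <- 3L + demes
  }
  ints <- (g$n_tip + 1L):nn
  lt[[nn + 1L]] <- g$times[ints]
  ly[[nn + 1L]] <- ifelse(g$times[ints] < t, dm$bottom[ints], 3L)
  ev_t <- unlist(lt); ev_ty <- unlist(ly)
  if ((m1 == 0 && any(ev_ty == 4L)) || (m2 == 0 && any(ev_ty == 5L)))
    return(-Inf)
  # virtual split marker (type 0) when the history reaches above t
  if (any(ev_t >= t)) { ev_t <- c(ev_t, t); ev_ty <- c(ev_ty, 0L) }
  o <- order(ev_t); ev_t <- ev_t[o]; ev_ty <- ev_ty[o]
  E <- length(ev_t)
  dk1 <- c(0, -1, 0, -1, -1, 1)[ev_ty + 1L]   # type 0..5
  dk2 <- c(0, 0, -1, 0, 1, -1)[ev_ty + 1L]
  k1 <- sum(g$tip_deme == 1L) + cumsum(c(0, dk1[-E]))
  k2 <- sum(g$tip_deme == 2L) + cumsum(c(0, dk2[-E]))
  dt <- diff(c(0, ev_t))
  below <- ev_t <= t
  rate <- ifelse(below,
                 k1 * (k1 - 1) / th1 + k2 * (k2 - 1) / th2 +
                   k1 * m1 + k2 * m2,
                 {
                   kA <- k1 + k2
                   kA * (kA - 1) / thA
                 })
  cnt <- tabulate(ev_ty, nbins = 5L)
  lfac <- cnt[1] * log(2 / th1) + cnt[2] * log(2 / th2) +
    cnt[3] * log(2 / thA) +
    (if (cnt[4] > 0) cnt[4] * log(m1) else 0) +
    (if (cnt[5] > 0) cnt[5] * log(m2) else 0)
  lfac - sum(rate * dt)
}

# Consistency checks used by tests and debug mode.
validate_genealogy <- function(g, t = g$t_split) {
  nn <- 2 * g$n_tip - 1
  stopifnot(length(g$parent) == nn, length(g$times) == nn)
  stopifnot(sum(g$parent == 0L) == 1)
  root <- which(g$parent == 0L)
  stopifnot(length(g$mig[[root]]) == 0, g$times[root] == max(g$times))
  for (v in setdiff(seq_len(nn), root)) {
    stopifnot(g$times[g$parent[v]] > g$times[v])
    mg <- g$mig[[v]]
    if (length(mg))
      stopifnot(all(mg > g$times[v]),
                all(mg < min(g$times[g$parent[v]], t)))
  }
  if (!is.null(g$tip_deme)) stopifnot(node_demes(g, t)$valid)
  invisible(TRUE)
}

# Moment estimate of the HKY transition/transversion rate ratio from mean
# observed transition and transversion proportions (small-divergence
# relation E[ts]/E[tv] ~ kappa (gA gG + gC gT) / (gR gY)).
estimate_kappa <- function(aln) {
  x <- aln_encode(aln)
  f <- as.numeric(table(factor(x, levels = 1:4))); f <- f / sum(f)
  n <- nrow(x)
  ts <- 0; tv <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    a <- x[i, ok]; b <- x[j, ok]
    d <- a != b
    pur <- function(z) z %in% c(1L, 3L)
    tv <- tv + sum(d & (pur(a) != pur(b)))
    ts <- ts + sum(d & (pur(a) == pur(b)))
  }
  if (tv == 0) return(20)                 # saturated upper guard
  gR <- f[1] + f[3]; gY <- f[2] + f[4]
  max((ts / tv) * gR * gY / (f[1] * f[3] + f[2] * f[4]), 0.1)
}

# Pattern-compressed tip partial likelihoods for the pruning algorithm.
im_lik_prep <- function(aln, freqs = NULL, kappa = NULL) {
  x <- aln_encode(aln)
  if (is.null(freqs)) {
    freqs <- as.numeric(table(factor(x, levels = 1:4)))
    freqs <- freqs / sum(freqs)
  }
  if (is.null(kappa)) kappa <- estimate_kappa(aln)
  key <- apply(x, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  w <- as.numeric(table(key)[key[upat]])
  xp <- x[, upat, drop = FALSE]
  npat <- ncol(xp)
  n <- nrow(x)
  tipL <- vector("list", n)
  for (i in seq_len(n)) {
    Lm <- matrix(1, 4, npat)
    known <- !is.na(xp[i, ])
    Lm[, known] <- 0
    Lm[cbind(xp[i, known], which(known))] <- 1
    tipL[[i]] <- Lm
  }
  list(eig = hky_eigen(freqs, kappa), tipL = tipL, w = w, L = ncol(x),
       freqs = freqs, kappa = kappa)
}

im_loglik <- function(g, prep) {
  nn <- 2 * g$n_tip - 1
  kids <- vector("list", nn)
  for (v in seq_len(nn)) if (g$parent[v] > 0L)
    kids[[g$parent[v]]] <- c(kids[[g$parent[v]]], v)
  npat <- length(prep$w)
  partial <- vector("list", nn)
  logscale <- numeric(npat)
  ord <- g$n_tip + order(g$times[(g$n_tip + 1):nn])
  for (v in ord) {
    P <- matrix(1, 4, npat)
    for (c_ in kids[[v]]) {
      b <- (g$times[v] - g$times[c_]) * g$mut_rate / prep$L
      Lc <- if (c_ <= g$n_tip) prep$tipL[[c_]] else partial[[c_]]
      P <- P * (hky_pmat(prep$eig, b) %*% Lc)
    }
    mx <- apply(P, 2, max)
    mx[mx == 0] <- 1
    partial[[v]] <- P / rep(mx, each = 4)
    logscale <- logscale + log(mx)
  }
  root <- ord[length(ord)]
  site <- as.numeric(prep$eig$freqs %*% partial[[root]])
  sum(prep$w * (log(site) + logscale))
}

#' HKY log-likelihood of an alignment on a genealogy
#'
#' Felsenstein pruning under the HKY substitution model with empirical base
#' frequencies and a moment-estimated (fixed) transition/transversion
#' ratio. Branch lengths are node-time differences times the genealogy's
#' per-sequence mutation rate, divided by the number of sites.
#'
#' @param genealogy a `cr_genealogy` whose tips match the alignment rows
#'   in order.
#' @param alignment a `cr_alignment`.
#' @param hky_params optional list with `freqs` and/or `kappa` to override
#'   the empirical estimates.
#' @return the log-likelihood.
#' @export
im_likelihood <- function(genealogy, alignment, hky_params = list()) {
  if (length(alignment$ids) != genealogy$n_tip)
    stop("tip count does not match alignment", call. = FALSE)
  prep <- im_lik_prep(alignment, hky_params$freqs, hky_params$kappa)
  im_loglik(genealogy, prep)
}

# --- proposal moves ----------------------------------------------------

# Uniform node-time slide (multiplicative slide above the lower bound for
# the root). Returns NULL when the move is impossible.
move_time_slide <- function(g, t) {
  n <- g$n_tip; nn <- 2 * n - 1
  v <- n + sample.int(n - 1, 1)
  kids <- which(g$parent == v)
  lo <- max(g$times[kids],
            vapply(kids, function(c_) if (length(g$mig[[c_]]))
              max(g$mig[[c_]]) else -Inf, 0))
  isroot <- g$parent[v] == 0L
  lhr <- 0
  if (isroot) {
    old <- g$times[v] - lo
    new <- old * exp(stats::runif(1, -1, 1))
    lhr <- log(new / old)
    tnew <- lo + new
  } else {
    hi <- min(g$times[g$parent[v]],
              if (length(g$mig[[v]])) min(g$mig[[v]]) else Inf)
    if (hi <= lo) return(NULL)
    tnew <- stats::runif(1, lo, hi)
  }
  g$times[v] <- tnew
  list(g = g, lhr = lhr, tree_changed = TRUE)
}

# Migration pair birth / death on one edge (preserves endpoint demes).
move_mig_pair <- function(g, t) {
  nn <- 2 * g$n_tip - 1
  v <- sample.int(nn, 1)
  if (g$parent[v] == 0L) return(NULL)    # the root has no edge
  lo <- g$times[v]; hi <- min(g$times[g$parent[v]], t)
  len <- hi - lo
  mg <- sort(g$mig[[v]])
  if (stats::runif(1) < 0.5) {            # birth
    if (len <= 0) return(NULL)
    u <- sort(lo + stats::runif(2) * len)
    if (any(mg > u[1] & mg < u[2])) return(NULL) # keep the pair adjacent
    g$mig[[v]] <- sort(c(mg, u))
    lhr <- log(1 / (length(mg) + 1)) - log(2 / len^2)
  } else {                                # death of an adjacent pair
    if (length(mg) < 2L) return(NULL)
    j <- sample.int(length(mg) - 1L, 1)
    u <- mg[c(j, j + 1)]
    g$mig[[v]] <- mg[-c(j, j + 1)]
    lhr <- log(2 / len^2) - log(1 / (length(mg) - 1))
  }
  list(g = g, lhr = lhr, tree_changed = FALSE)
}

# Slide one migration event between its neighbours (symmetric).
move_mig_slide <- function(g, t) {
  cand <- which(lengths(g$mig) > 0 & g$parent > 0L)
  if (!length(cand)) return(NULL)
  v <- cand[sample.int(length(cand), 1)]
  mg <- sort(g$mig[[v]])
  j <- sample.int(length(mg), 1)
  lo <- if (j > 1) mg[j - 1] else g$times[v]
  hi <- if (j < length(mg)) mg[j + 1] else min(g$times[g$parent[v]], t)
  if (hi <= lo) return(NULL)   # e.g. the split time moved below this event
  mg[j] <- stats::runif(1, lo, hi)
  g$mig[[v]] <- mg
  list(g = g, lhr = 0, tree_changed = FALSE)
}

# Subtree detach-reattach respecting deme constraints. The pruned edge
# keeps its migration events; the attachment point must be in the deme the
# pruned lineage occupies at its top (no constraint above the split time).
# The spliced intermediate state (subtree hanging off its old parent node,
# parent's other edge fused) is the same for the forward and the reverse
# proposal, so one target count serves both Hastings terms.
move_spr <- function(g, t, lambda0) {
  n <- g$n_tip; nn <- 2 * n - 1
  root <- which(g$parent == 0L)
  c_ <- sample.int(nn, 1)
  while (c_ == root) c_ <- sample.int(nn, 1)
  p <- g$parent[c_]
  sib <- setdiff(which(g$parent == p), c_)
  q <- g$parent[p]
  if (q == 0L && length(g$mig[[sib]])) return(NULL)
  a_low <- max(g$times[c_],
               if (length(g$mig[[c_]])) max(g$mig[[c_]]) else -Inf)
  old_s <- g$times[p]
  # spliced state: p keeps child c_ only; sib edge fused with p's old edge
  gs <- g
  gs$mig[[sib]] <- sort(c(g$mig[[sib]], g$mig[[p]]))
  gs$mig[[p]] <- numeric(0)
  gs$parent[sib] <- q
  gs$parent[p] <- 0L
  root2 <- if (q == 0L) sib else root
  dms <- node_demes(gs, t)
  if (!dms$valid) return(NULL)
  d_top <- dms$top[c_]
  # pruned component: p, c_ and everything below c_
  insub <- rep(FALSE, nn); insub[c(p, c_)] <- TRUE
  repeat {
    grow <- which(!insub & gs$parent > 0L & insub[pmax(gs$parent, 1L)])
    if (!length(grow)) break
    insub[grow] <- TRUE
  }
  targets <- function(s) {
    vs <- which(!insub & gs$parent > 0L)
    ok <- vs[gs$times[vs] < s & gs$times[gs$parent[vs]] > s]
    if (s < t) {
      keep <- vapply(ok, function(v) {
        d <- dms$bottom[v]
        !is.na(d) && flip_deme(d, sum(gs$mig[[v]] < s)) == d_top
      }, TRUE)
      ok <- ok[keep]
    }
    # attaching above the root is only proposable when the root's edge-to-be
    # carries no migration events (the reverse prune would strand them)
    above <- s > gs$times[root2] && !length(gs$mig[[root2]]) &&
      (s >= t || (!is.na(dms$bottom[root2]) && dms$bottom[root2] == d_top))
    list(edges = ok, above = above, n = length(ok) + above)
  }
  s_new <- a_low + stats::rexp(1, lambda0)
  fwd <- targets(s_new)
  if (fwd$n == 0L) return(NULL)
  rev <- targets(old_s)
  if (rev$n == 0L) return(NULL)            # should not happen
  pick <- sample.int(fwd$n, 1)
  g2 <- gs
  g2$times[p] <- s_new
  if (pick <= length(fwd$edges)) {
    tgt <- fwd$edges[pick]
    ev <- g2$mig[[tgt]]
    g2$mig[[tgt]] <- sort(ev[ev < s_new])
    g2$mig[[p]] <- sort(ev[ev > s_new])
    g2$parent[p] <- g2$parent[tgt]
    g2$parent[tgt] <- p
  } else {                                 # new root above root2
    g2$parent[p] <- 0L
    g2$parent[root2] <- p
  }
  lhr <- (stats::dexp(old_s - a_low, lambda0, log = TRUE) - log(rev$n)) -
         (stats::dexp(s_new - a_low, lambda0, log = TRUE) - log(fwd$n))
  list(g = g2, lhr = lhr, tree_changed = TRUE)
}

# Multiplicative scale move for one parameter.
move_param <- function(par, bounds, delta = 0.7) {
  i <- sample.int(length(par), 1)
  f <- exp(stats::runif(1, -delta, delta))
  par[i] <- par[i] * f
  if (par[i] > bounds[i]) return(NULL)
  list(par = par, lhr = log(f))
}

# Initialize a genealogy consistent with the data's deme labels by
# simulating from the structured coalescent under the starting parameters,
# then relabeling tips to match the alignment rows.
im_init_genealogy <- function(deme, par) {
  n1 <- sum(deme == 1L); n2 <- sum(deme == 2L)
  cfg <- sim_config("im_split", n = c(n1, n2),
                    theta_im = par[1:3], t_split = par[4], m = par[5:6])
  g <- sim_genealogy_im(cfg)
  # sim tips are ordered deme1 then deme2; map to data rows
  ord <- c(which(deme == 1L), which(deme == 2L))   # data index per sim tip
  n <- n1 + n2; nn <- 2 * n - 1
  relab <- seq_len(nn)
  relab[1:n] <- ord
  g2 <- g
  g2$parent[relab] <- ifelse(g$parent == 0L, 0L, relab[pmax(g$parent, 1L)])
  g2$times[relab] <- g$times
  g2$mig <- vector("list", nn)
  for (v in seq_len(nn)) g2$mig[relab[v]] <- g$mig[v]   # [[<- NULL would drop
  g2$mig <- lapply(g2$mig, function(x) if (is.null(x)) numeric(0) else x)
  g2$tip_deme <- deme
  attr(g2, "events") <- NULL
  g2
}

#' Reduced isolation-with-migration MCMC
#'
#' Metropolis-Hastings sampler over (genealogy, parameters) for two
#' descendant populations and one non-recombining locus, with uniform
#' priors on `[0, bound]` for each of (theta1, theta2, thetaA, t, m1, m2).
#' The move set comprises node-time slides, subtree detach-reattach moves
#' respecting deme constraints, migration-event pair birth/death and
#' slides, and multiplicative parameter scale moves. The genealogy prior is
#' the structured-coalescent density under the current parameters; the data
#' likelihood is HKY via Felsenstein pruning.
#'
#' @param alignment a `cr_alignment`.
#' @param popmap2 a `cr_popmap` with exactly two populations covering every
#'   sequence.
#' @param params0 starting values `c(theta1, theta2, thetaA, t, m1, m2)`;
#'   `NULL` draws them uniformly from the priors.
#' @param priors upper bounds for the six uniform priors.
#' @param n_burn,n_steps,thin burn-in, recorded phase length and thinning.
#' @param seed integer seed.
#' @param likelihood set `FALSE` to sample from the prior alone (sampler
#'   validation).
#' @param hky_params optional list overriding `freqs`/`kappa`.
#' @param ess_target warn when the smallest parameter ESS falls below this.
#' @param n_bins histogram bins per parameter.
#' @param debug assert genealogy invariants after every accepted move.
#' @return object of class `cr_im_posterior`: `samples` (data.frame with
#'   the six parameters and `tmrca`), `mode`, `hpd95` (2 x k), `ess`,
#'   `hist` (per-parameter histograms on the prior grid), `accept`
#'   (per-move acceptance rates), `n_recorded`, `priors`.
#' @export
im_mcmc <- function(alignment, popmap2, params0 = NULL,
                    priors = c(theta1 = 100, theta2 = 100, thetaA = 100,
                               t = 10, m1 = 10, m2 = 10),
                    n_burn = 2000, n_steps = 20000, thin = 10, seed = 1,
                    likelihood = TRUE, hky_params = list(),
                    ess_target = 0, n_bins = 200, debug = FALSE) {
  stopifnot(inherits(alignment, "cr_alignment"), inherits(popmap2, "cr_popmap"))
  if (length(popmap2$levels) != 2L)
    stop("exactly 2 populations required", call. = FALSE)
  set.seed(seed)
  deme <- match(popmap2$pop[alignment$ids], popmap2$levels)
  if (anyNA(deme)) stop("unmapped sequences", call. = FALSE)
  prep <- if (likelihood)
    im_lik_prep(alignment, hky_params$freqs, hky_params$kappa) else NULL
  par <- if (is.null(params0)) {
    # data-informed start: scaled sizes near the per-deme mean pairwise
    # differences (so the initial genealogy has the right depth), shallow
    # split, little migration; jittered so independent runs start apart
    pd <- pairwise_differences(alignment)
    ut <- upper.tri(pd$diff)
    kbar <- function(sel) {
      m <- pd$diff[sel, sel]
      mean(m[upper.tri(m)])
    }
    k1 <- kbar(deme == 1L); k2 <- kbar(deme == 2L)
    jit <- exp(stats::runif(4, -0.5, 0.5))
    pmin(pmax(c(k1 * jit[1], k2 * jit[2],
                mean(pd$diff[ut]) / 2 * jit[3],
                0.1 * priors[4] * jit[4],
                stats::runif(2, 0.01, 0.2) * priors[5:6]),
              priors * 0.001), priors * 0.95)
  } else params0
  names(par) <- names(priors)
  g <- NULL
  for (try_ in 1:50) {
    g <- im_init_genealogy(deme, par)
    if (is.finite(im_log_prior(par, g))) break
    g <- NULL
  }
  if (is.null(g)) stop("could not initialize a feasible genealogy",
                       call. = FALSE)
  lp <- im_log_prior(par, g)
  ll <- if (likelihood) im_loglik(g, prep) else 0
  lambda0 <- 2 / max(g$times)
  nrec <- floor(n_steps / thin)
  samples <- matrix(NA_real_, nrec, 7,
                    dimnames = list(NULL, c(names(priors), "tmrca")))
  rec <- 0L
  # "redraw" proposes a complete genealogy from the structured-coalescent
  # prior under the current parameters; proposal and prior cancel, so it is
  # accepted on the likelihood ratio alone (always, when sampling the prior)
  moves <- c("param", "time", "spr", "migpair", "migslide", "retype",
             "redraw", "scale", "tslide")
  # when sampling the prior alone the redraw move is an exact sampler and
  # is weighted up so recorded draws decorrelate quickly
  wts <- c(6, 4, 4, 2, 1, 2, if (likelihood) 1 else 6, 2, 3)
  prop <- stats::setNames(numeric(length(moves)), moves)
  acc <- stats::setNames(numeric(length(moves)), moves)
  total <- n_burn + n_steps
  for (step in seq_len(total)) {
    mv <- sample(moves, 1, prob = wts)
    prop[mv] <- prop[mv] + 1
    if (mv == "redraw") {
      # draw one parameter fresh from its uniform prior and a complete
      # genealogy from the structured-coalescent prior given the updated
      # parameters; priors and proposal cancel, leaving the likelihood ratio
      par2 <- par
      i <- if (stats::runif(1) < 0.5) sample.int(length(par), 1)
           else seq_along(par)
      par2[i] <- stats::runif(length(i), 0, priors[i])
      g2 <- im_init_genealogy(deme, par2)
      lp2 <- im_log_prior(par2, g2)
      if (is.finite(lp2)) {
        ll2 <- if (likelihood) im_loglik(g2, prep) else 0
        if (log(stats::runif(1)) < ll2 - ll) {
          par <- par2; g <- g2; lp <- lp2; ll <- ll2
          acc[mv] <- acc[mv] + 1
          if (debug) validate_genealogy(g, par[4])
        }
      }
    } else if (mv == "tslide") {
      cand <- move_t_window(g, priors[[4]])
      if (!is.null(cand)) {
        par2 <- par; par2[4] <- cand$t
        lp2 <- im_log_prior(par2, g)
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
          par <- par2; lp <- lp2
          acc[mv] <- acc[mv] + 1
        }
      }
    } else if (mv == "param") {
      cand <- move_param(par, priors)
      if (!is.null(cand)) {
        lp2 <- im_log_prior(cand$par, g)
        if (is.finite(lp2) &&
            log(stats::runif(1)) < lp2 - lp + cand$lhr) {
          par <- cand$par; lp <- lp2
          acc[mv] <- acc[mv] + 1
        }
      }
    } else {
      cand <- switch(mv,
                     time = move_time_slide(g, par[4]),
                     spr = move_spr(g, par[4], lambda0),
                     migpair = move_mig_pair(g, par[4]),
                     migslide = move_mig_slide(g, par[4]),
                     retype = move_retype(g, par[4]),
                     scale = move_tree_scale(g, par[4]))
      if (!is.null(cand)) {
        lp2 <- im_log_prior(par, cand$g)
        if (is.finite(lp2)) {
          ll2 <- if (likelihood && cand$tree_changed)
            im_loglik(cand$g, prep) else ll
          if (log(stats::runif(1)) < (lp2 - lp) + (ll2 - ll) + cand$lhr) {
            g <- cand$g; lp <- lp2; ll <- ll2
            acc[mv] <- acc[mv] + 1
            if (debug) validate_genealogy(g, par[4])
          }
        }
      }
    }
    if (step > n_burn && (step - n_burn) %% thin == 0L) {
      rec <- rec + 1L
      samples[rec, ] <- c(par, max(g$times))
    }
  }
  samples <- as.data.frame(samples[seq_len(rec), , drop = FALSE])
  hists <- lapply(seq_along(priors), function(i) {
    br <- seq(0, priors[i], length.out = n_bins + 1)
    h <- graphics::hist(pmin(samples[[i]], priors[i]), breaks = br,
                        plot = FALSE)
    list(mids = h$mids, mass = h$counts / sum(h$counts))
  })
  names(hists) <- names(priors)
  tm <- samples$tmrca
  brt <- seq(0, max(tm) * 1.02 + 1e-9, length.out = n_bins + 1)
  ht <- graphics::hist(tm, breaks = brt, plot = FALSE)
  hists$tmrca <- list(mids = ht$mids, mass = ht$counts / sum(ht$counts))
  mode_of <- function(h) {
    m <- stats::filter(h$mass, rep(1 / 3, 3), sides = 2)
    m[is.na(m)] <- 0
    h$mids[which.max(m)]
  }
  modes <- vapply(hists, mode_of, 0)
  hpds <- vapply(hists, function(h) hpd_from_hist(h, 0.95), c(0, 0))
  rownames(hpds) <- c("lower", "upper")
  ess <- vapply(samples, ess_acf, 0)
  if (ess_target > 0 && min(ess) < ess_target)
    warning(sprintf("under-converged: min ESS %.0f < %d",
                    min(ess), ess_target))
  structure(list(samples = samples, mode = modes, hpd95 = hpds, ess = ess,
                 hist = hists, accept = ifelse(prop > 0, acc / prop, NA),
                 n_recorded = rec, priors = priors,
                 kappa = if (likelihood) prep$kappa else NA),
            class = "cr_im_posterior")
}

# Shortest interval of consecutive histogram bins holding >= `mass` of the
# posterior mass.
hpd_from_hist <- function(h, mass = 0.95) {
  cm <- cumsum(h$mass)
  nb <- length(h$mass)
  half <- (h$mids[2] - h$mids[1]) / 2
  best <- c(h$mids[1] - half, h$mids[nb] + half)
  bestw <- diff(best)
  for (i in seq_len(nb)) {
    lo_mass <- if (i > 1) cm[i - 1] else 0
    j <- which(cm - lo_mass >= mass)
    j <- j[j >= i]
    if (!length(j)) break
    w <- h$mids[j[1]] - h$mids[i] + 2 * half
    if (w < bestw) { bestw <- w; best <- c(h$mids[i] - half, h$mids[j[1]] + half) }
  }
  pmax(best, 0)
}

# Autocorrelation-based effective sample size (initial positive sequence).
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    s <- s + ac[k]
  }
  max(n / (1 + 2 * s), 1)
}

#' @export
print.cr_im_posterior <- function(x, ...) {
  cat("<cr_im_posterior> ", x$n_recorded, " recorded samples\n", sep = "")
  out <- data.frame(mode = x$mode, hpd_lower = x$hpd95[1, ],
                    hpd_upper = x$hpd95[2, ], ESS = round(x$ess))
  print(round(out, 4))
  invisible(x)
}

#' Demographic scaling of an IM posterior
#'
#' Converts the posterior modes to calendar years and effective sizes:
#' divergence years = mode(t)/u x generation time, TMRCA years =
#' mode(TMRCA)/u, and N_ef = theta/(4 u inheritance_scalar) (so that for
#' mtDNA with scalar 0.25, N_ef = theta/u).
#'
#' @param posterior a `cr_im_posterior`.
#' @param u whole-sequence mutation rate per generation.
#' @param generation_years generation time in years.
#' @param inheritance_scalar locus inheritance scalar (0.25 for mtDNA).
#' @return list with `divergence_years`, `tmrca_years`, `N_ef` (one per
#'   theta), each unrounded, plus `rounded` versions to the nearest 100
#'   years.
#' @export
scale_to_demographic_units <- function(posterior, u = 1.88e-4,
                                       generation_years = 1,
                                       inheritance_scalar = 0.25) {
  stopifnot(u > 0, generation_years > 0, inheritance_scalar > 0)
  md <- if (inherits(posterior, "cr_im_posterior")) posterior$mode else posterior
  div <- md[["t"]] / u * generation_years
  tmr <- md[["tmrca"]] / u * generation_years
  nef <- c(theta1 = md[["theta1"]], theta2 = md[["theta2"]],
           thetaA = md[["thetaA"]]) / (4 * u * inheritance_scalar)
  list(divergence_years = div, tmrca_years = tmr, N_ef = nef,
       rounded = list(divergence_years = round(div / 100) * 100,
                      tmrca_years = round(tmr / 100) * 100))
}

#' Write IM posterior summaries to a directory
#'
#' Per-parameter histogram CSVs, a JSON summary (mode, 95% HPD, ESS) and
#' the thinned sample trace as TSV.
#'
#' @param posterior a `cr_im_posterior`.
#' @param dir output directory (created if needed).
#' @export
write_im_posterior <- function(posterior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(posterior$hist)) {
    h <- posterior$hist[[nm]]
    utils::write.csv(data.frame(mid = h$mids, mass = h$mass),
                     file.path(dir, paste0("posterior_", nm, ".csv")),
                     row.names = FALSE)
  }
  summ <- list(mode = as.list(posterior$mode),
               hpd95 = apply(posterior$hpd95, 2, as.list),
               ess = as.list(posterior$ess),
               n_recorded = posterior$n_recorded)
  jsonlite::write_json(summ, file.path(dir, "im_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(posterior$samples, file.path(dir, "im_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Node retype: flip the deme of one internal node below the split and, on
# each adjacent edge, either insert one migration event next to the node or
# delete the nearest one, restoring deme consistency. This is the only move
# that changes the total migration count by an odd number, which the
# sampler needs to reach both parity classes of the event space.
move_retype <- function(g, t) {
  n <- g$n_tip; nn <- 2 * n - 1
  below <- which(g$times[(n + 1):nn] < t) + n
  if (!length(below)) return(NULL)
  v <- below[sample.int(length(below), 1)]
  lhr <- 0
  # child edges: fix the deme at the top end (insert/delete topmost event)
  for (c_ in which(g$parent == v)) {
    mg <- sort(g$mig[[c_]])
    can_rm <- length(mg) > 0
    lo <- max(g$times[c_], if (can_rm) mg[length(mg)] else -Inf)
    width <- g$times[v] - lo
    if (can_rm && stats::runif(1) < 0.5) {
      g$mig[[c_]] <- mg[-length(mg)]
      rem <- g$mig[[c_]]
      lo2 <- max(g$times[c_], if (length(rem)) rem[length(rem)] else -Inf)
      p_add_rev <- if (length(rem)) 0.5 else 1
      lhr <- lhr + log(p_add_rev / (g$times[v] - lo2)) - log(0.5)
    } else {
      u <- stats::runif(1, lo, g$times[v])
      g$mig[[c_]] <- c(mg, u)
      p_add <- if (can_rm) 0.5 else 1
      lhr <- lhr + log(0.5) - log(p_add / width)
    }
  }
  # parent edge: fix the deme at the bottom end (insert/delete lowest event)
  if (g$parent[v] != 0L) {
    mg <- sort(g$mig[[v]])
    can_rm <- length(mg) > 0
    hi <- min(g$times[g$parent[v]], t, if (can_rm) mg[1] else Inf)
    width <- hi - g$times[v]
    if (can_rm && stats::runif(1) < 0.5) {
      g$mig[[v]] <- mg[-1]
      rem <- g$mig[[v]]
      hi2 <- min(g$times[g$parent[v]], t, if (length(rem)) rem[1] else Inf)
      p_add_rev <- if (length(rem)) 0.5 else 1
      lhr <- lhr + log(p_add_rev / (hi2 - g$times[v])) - log(0.5)
    } else {
      if (width <= 0) return(NULL)
      u <- stats::runif(1, g$times[v], hi)
      g$mig[[v]] <- c(u, mg)
      p_add <- if (can_rm) 0.5 else 1
      lhr <- lhr + log(0.5) - log(p_add / width)
    }
  }
  list(g = g, lhr = lhr, tree_changed = FALSE)
}

# Whole-genealogy scale move: multiplies every node time and migration
# event time by a common factor (the split time stays put, so scaled
# states incompatible with it are rejected through the prior). Helps the
# chain traverse the strong correlation between tree depth and the size
# parameters.
move_tree_scale <- function(g, t) {
  n <- g$n_tip; nn <- 2 * n - 1
  f <- exp(stats::runif(1, -0.35, 0.35))
  g$times[(n + 1):nn] <- g$times[(n + 1):nn] * f
  nev <- sum(lengths(g$mig))
  if (nev > 0) g$mig <- lapply(g$mig, function(x) x * f)
  list(g = g, lhr = (n - 1 + nev) * log(f), tree_changed = TRUE)
}

# Split-time window slide: given the genealogy, the split time can move
# freely between the latest migration event and the first coalescence
# (in time order) whose children occupy different demes when demes are
# propagated from the tips without reference to the current split time.
# The window therefore depends on the genealogy alone, and a uniform
# proposal on it is symmetric.
move_t_window <- function(g, t_bound) {
  n <- g$n_tip; nn <- 2 * n - 1
  lo <- if (sum(lengths(g$mig))) max(unlist(g$mig)) else 0
  kids <- vector("list", nn)
  for (v in seq_len(nn)) if (g$parent[v] > 0L)
    kids[[g$parent[v]]] <- c(kids[[g$parent[v]]], v)
  top <- rep(NA_integer_, nn)
  top[1:n] <- flip_deme(g$tip_deme, lengths(g$mig[1:n]))
  hi <- t_bound
  for (v in n + order(g$times[(n + 1):nn])) {
    tops <- top[kids[[v]]]
    if (anyNA(tops) || tops[1] != tops[2]) { hi <- min(hi, g$times[v]); break }
    top[v] <- flip_deme(tops[1], length(g$mig[[v]]))
  }
  if (hi <= lo) return(NULL)
  list(t = stats::runif(1, lo, hi), lhr = 0)
}

# Shortest interval of consecutive histogram bins holding >= `mass` of the
# posterior mass.
hpd_from_hist <- function(h, mass = 0.95) {
  cm <- cumsum(h$mass)
  nb <- length(h$mass)
  half <- (h$mids[2] - h$mids[1]) / 2
  best <- c(h$mids[1] - half, h$mids[nb] + half)
  bestw <- diff(best)
  for (i in seq_len(nb)) {
    lo_mass <- if (i > 1) cm[i - 1] else 0
    j <- which(cm - lo_mass >= mass)
    j <- j[j >= i]
    if (!length(j)) break
    w <- h$mids[j[1]] - h$mids[i] + 2 * half
    if (w < bestw) { bestw <- w; best <- c(h$mids[i] - half, h$mids[j[1]] + half) }
  }
  pmax(best, 0)
}

# Autocorrelation-based effective sample size (initial positive sequence).
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    s <- s + ac[k]
  }
  max(n / (1 + 2 * s), 1)
}

#' @export
print.cr_im_posterior <- function(x, ...) {
  cat("<cr_im_posterior> ", x$n_recorded, " recorded samples\n", sep = "")
  out <- data.frame(mode = x$mode, hpd_lower = x$hpd95[1, ],
                    hpd_upper = x$hpd95[2, ], ESS = round(x$ess))
  print(round(out, 4))
  invisible(x)
}

#' Demographic scaling of an IM posterior
#'
#' Converts the posterior modes to calendar years and effective sizes:
#' divergence years = mode(t)/u x generation time, TMRCA years =
#' mode(TMRCA)/u, and N_ef = theta/(4 u inheritance_scalar) (so that for
#' mtDNA with scalar 0.25, N_ef = theta/u).
#'
#' @param posterior a `cr_im_posterior`.
#' @param u whole-sequence mutation rate per generation.
#' @param generation_years generation time in years.
#' @param inheritance_scalar locus inheritance scalar (0.25 for mtDNA).
#' @return list with `divergence_years`, `tmrca_years`, `N_ef` (one per
#'   theta), each unrounded, plus `rounded` versions to the nearest 100
#'   years.
#' @export
scale_to_demographic_units <- function(posterior, u = 1.88e-4,
                                       generation_years = 1,
                                       inheritance_scalar = 0.25) {
  stopifnot(u > 0, generation_years > 0, inheritance_scalar > 0)
  md <- if (inherits(posterior, "cr_im_posterior")) posterior$mode else posterior
  div <- md[["t"]] / u * generation_years
  tmr <- md[["tmrca"]] / u * generation_years
  nef <- c(theta1 = md[["theta1"]], theta2 = md[["theta2"]],
           thetaA = md[["thetaA"]]) / (4 * u * inheritance_scalar)
  list(divergence_years = div, tmrca_years = tmr, N_ef = nef,
       rounded = list(divergence_years = round(div / 100) * 100,
                      tmrca_years = round(tmr / 100) * 100))
}

#' Write IM posterior summaries to a directory
#'
#' Per-parameter histogram CSVs, a JSON summary (mode, 95% HPD, ESS) and
#' the thinned sample trace as TSV.
#'
#' @param posterior a `cr_im_posterior`.
#' @param dir output directory (created if needed).
#' @export
write_im_posterior <- function(posterior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(posterior$hist)) {
    h <- posterior$hist[[nm]]
    utils::write.csv(data.frame(mid = h$mids, mass = h$mass),
                     file.path(dir, paste0("posterior_", nm, ".csv")),
                     row.names = FALSE)
  }
  summ <- list(mode = as.list(posterior$mode),
               hpd95 = apply(posterior$hpd95, 2, as.list),
               ess = as.list(posterior$ess),
               n_recorded = posterior$n_recorded)
  jsonlite::write_json(summ, file.path(dir, "im_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(posterior$samples, file.path(dir, "im_trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Node retype: flip the deme of one internal node below the split and, on
# each adjacent edge, either insert one migration event next to the node or
# delete the nearest one, restoring deme consistency. This is the only move
# that changes the total migration count by an odd number, which the
# sampler needs to reach both parity classes of the event space.
move_retype <- function(g, t) {
  n <- g$n_tip; nn <- 2 * n - 1
  below <- which(g$times[(n + 1):nn] < t) + n
  if (!length(below)) return(NULL)
  v <- below[sample.int(length(below), 1)]
  lhr <- 0
  # child edges: fix the deme at the top end (insert/delete topmost event)
  for (c_ in which(g$parent == v)) {
    mg <- sort(g$mig[[c_]])
    can_rm <- length(mg) > 0
    lo <- max(g$times[c_], if (can_rm) mg[length(mg)] else -Inf)
    width <- g$times[v] - lo
    if (can_rm && stats::runif(1) < 0.5) {
      g$mig[[c_]] <- mg[-length(mg)]
      rem <- g$mig[[c_]]
      lo2 <- max(g$times[c_], if (length(rem)) rem[length(rem)] else -Inf)
      p_add_rev <- if (length(rem)) 0.5 else 1
      lhr <- lhr + log(p_add_rev / (g$times[v] - lo2)) - log(0.5)
    } else {
      u <- stats::runif(1, lo, g$times[v])
      g$mig[[c_]] <- c(mg, u)
      p_add <- if (can_rm) 0.5 else 1
      lhr <- lhr + log(0.5) - log(p_add / width)
    }
  }
  # parent edge: fix the deme at the bottom end (insert/delete lowest event)
  if (g$parent[v] != 0L) {
    mg <- sort(g$mig[[v]])
    can_rm <- length(mg) > 0
    hi <- min(g$times[g$parent[v]], t, if (can_rm) mg[1] else Inf)
    width <- hi - g$times[v]
    if (can_rm && stats::runif(1) < 0.5) {
      g$mig[[v]] <- mg[-1]
      rem <- g$mig[[v]]
      hi2 <- min(g$times[g$parent[v]], t, if (length(rem)) rem[1] else Inf)
      p_add_rev <- if (length(rem)) 0.5 else 1
      lhr <- lhr + log(p_add_rev / (hi2 - g$times[v])) - log(0.5)
    } else {
      if (width <= 0) return(NULL)
      u <- stats::runif(1, g$times[v], hi)
      g$mig[[v]] <- c(u, mg)
      p_add <- if (can_rm) 0.5 else 1
      lhr <- lhr + log(0.5) - log(p_add / width)
    }
  }
  list(g = g, lhr = lhr, tree_changed = FALSE)
}

# Whole-genealogy scale move: multiplies every node time and migration
# event time by a common factor (the split time stays put, so scaled
# states incompatible with it are rejected through the prior). Helps the
# chain traverse the strong correlation between tree depth and the size
# parameters.
move_tree_scale <- function(g, t) {
  n <- g$n_tip; nn <- 2 * n - 1
  f <- exp(stats::runif(1, -0.35, 0.35))
  g$times[(n + 1):nn] <- g$times[(n + 1):nn] * f
  nev <- sum(lengths(g$mig))
  if (nev > 0) g$mig <- lapply(g$mig, function(x) x * f)
  list(g = g, lhr = (n - 1 + nev) * log(f), tree_changed = TRUE)
}

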