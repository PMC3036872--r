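#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all unordered pairs,
#' normalized to sum to one.
#'
#' @param diff_matrix symmetric non-negative integer matrix of pairwise
#'   difference counts.
#' @return numeric vector of relative frequencies for 0..d_max differences.
#' @export
observed_mismatch <- function(diff_matrix) {
  n <- nrow(diff_matrix)
  if (is.null(n) || n < 2L) stop("need at least 2 sequences", call. = FALSE)
  d <- diff_matrix[upper.tri(diff_matrix)]
  if (any(d < 0)) stop("negative difference counts", call. = FALSE)
  tab <- tabulate(d + 1L, nbins = max(d) + 1L)
  tab / sum(tab)
}

# equilibrium distribution of pairwise differences at scaled size theta
geom_mismatch <- function(theta, d_max) {
  j <- 0:d_max
  if (theta == 0) return(c(1, rep(0, d_max)))
  exp(j * log(theta) - (j + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The transient distribution of pairwise differences \eqn{\tau} mutational
#' time units after an instantaneous change of the scaled population size
#' from \eqn{\theta_0} to \eqn{\theta_1}:
#' \deqn{F_i = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{j=0}^{i} \frac{\tau^j}{j!}\left[\hat F_{i-j}(\theta_0) -
#'   \hat F_{i-j}(\theta_1)\right]}
#' with \eqn{\hat F_j(\theta) = \theta^j/(1+\theta)^{j+1}}. The vector is
#' truncated at `d_max` without renormalization; the unaccounted tail mass
#' is attached as attribute `"tail_mass"`.
#'
#' @param tau time since expansion (mutational units).
#' @param theta0,theta1 scaled sizes before/after the expansion.
#' @param d_max largest difference class.
#' @return numeric vector of expected relative frequencies for 0..d_max.
#' @export
expected_mismatch <- function(tau, theta0, theta1, d_max) {
  if (any(c(tau, theta0, theta1) < 0)) stop("negative parameter", call. = FALSE)
  F1 <- geom_mismatch(theta1, d_max)
  F0 <- geom_mismatch(theta0, d_max)
  if (tau == 0) {
    out <- F0
  } else if (theta1 == 0) {
    # recent epoch coalesces instantly: all pairs older than tau
    out <- F1
  } else {
    damp <- exp(-tau * (theta1 + 1) / theta1)
    lpois <- stats::dpois(0:d_max, tau) * exp(tau)   # tau^j / j!
    diff01 <- F0 - F1
    conv <- vapply(0:d_max, function(i)
      sum(lpois[1:(i + 1)] * diff01[(i + 1):1]), 0)
    out <- F1 + damp * conv
  }
  out <- pmax(out, 0)
  attr(out, "tail_mass") <- max(1 - sum(out), 0)
  out
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2}, where the class after the
#' last observed one is taken as zero (documented end convention). Smooth,
#' unimodal (expansion-like) distributions give small values.
#'
#' @param obs vector of relative frequencies.
#' @return the raggedness index.
#' @export
raggedness <- function(obs) {
  if (length(obs) < 1L) stop("empty mismatch vector", call. = FALSE)
  x <- c(obs, 0)
  sum(diff(x)^2)
}

#' Time scaling for the expansion parameter
#'
#' @param mu_site_per_year substitution rate per site per year.
#' @param L sequence length (sites).
#' @param generation_years generation time in years.
#' @return list with the inputs and `u`, the whole-sequence rate per
#'   generation.
#' @export
time_scaling <- function(mu_site_per_year = 1.9e-7, L = 993,
                         generation_years = 1) {
  stopifnot(mu_site_per_year > 0, L > 0, generation_years > 0)
  list(mu_site_per_year = mu_site_per_year, L = L,
       generation_years = generation_years,
       u = mu_site_per_year * L * generation_years)
}

#' Convert an expansion time to calendar years
#'
#' Uses \eqn{\tau = 2ut}, i.e. years \eqn{= \tau/(2u)} with `u` the
#' whole-sequence mutation rate per generation.
#'
#' @param tau expansion time in mutational units.
#' @param scaling a [time_scaling()] object.
#' @return time in years (unrounded).
#' @export
tau_to_years <- function(tau, scaling = time_scaling()) {
  tau / (2 * scaling$u) * scaling$generation_years
}

mismatch_ssd <- function(par, obs) {
  exp_f <- expected_mismatch(par[1], par[2], par[3], length(obs) - 1L)
  sum((obs - exp_f)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Minimizes the sum of squared deviations between the observed and the
#' expected mismatch distribution over \eqn{(\tau, \theta_0, \theta_1)} by
#' bounded multi-start local optimization, then assesses goodness of fit and
#' parameter uncertainty by a parametric bootstrap: `n_boot` coalescent data
#' sets are simulated under the fitted parameters, each refitted, and the
#' 2.5/97.5 percentiles of the refitted \eqn{\tau} give the 95% CI.
#' `p_SSD` is the fraction of bootstrap SSDs at or above the observed one
#' (the same tail fraction for raggedness gives `p_raggedness`).
#'
#' @param obs observed mismatch vector (relative frequencies).
#' @param n number of sequences behind `obs` (>= 3).
#' @param seed integer seed.
#' @param n_boot bootstrap replicates (0 disables the bootstrap).
#' @param theta1_max upper bound / boundary sentinel for theta1.
#' @return list of class `cr_mismatchfit`: `tau`, `theta0`, `theta1`,
#'   `SSD`, `raggedness`, `CI95_tau`, `p_SSD`, `p_raggedness`, `n_boot`,
#'   `obs`, `expected`.
#' @export
fit_sudden_expansion <- function(obs, n, seed = 1, n_boot = 200,
                                 theta1_max = 99999) {
  if (n < 3) stop("need at least 3 sequences", call. = FALSE)
  if (abs(sum(obs) - 1) > 1e-6) stop("obs must sum to 1", call. = FALSE)
  set.seed(seed)
  fit1 <- fit_mismatch_core(obs, theta1_max)
  d_max <- length(obs) - 1L
  rag <- raggedness(obs)
  ci <- c(NA_real_, NA_real_); p_ssd <- NA_real_; p_rag <- NA_real_
  if (n_boot > 0) {
    taus <- numeric(n_boot); ssds <- numeric(n_boot); rags <- numeric(n_boot)
    cfg <- sim_config("sudden_expansion", n = n, L = 1,
                      theta0 = max(fit1$par[2], 1e-6),
                      theta1 = min(fit1$par[3], theta1_max),
                      tau = fit1$par[1])
    for (b in seq_len(n_boot)) {
      g <- simulate_genealogy(cfg)
      ob <- observed_mismatch(genealogy_mutation_diffs(g))
      fb <- fit_mismatch_core(ob, theta1_max, starts = rbind(fit1$par))
      taus[b] <- fb$par[1]
      ssds[b] <- fb$value
      rags[b] <- raggedness(ob)
    }
    ci <- stats::quantile(taus, c(0.025, 0.975), names = FALSE)
    p_ssd <- mean(ssds >= fit1$value)
    p_rag <- mean(rags >= rag)
  }
  structure(list(tau = fit1$par[1], theta0 = fit1$par[2],
                 theta1 = if (fit1$par[3] >= 0.999 * theta1_max)
                   theta1_max else fit1$par[3],
                 SSD = fit1$value, raggedness = rag,
                 CI95_tau = ci, p_SSD = p_ssd, p_raggedness = p_rag,
                 n_boot = n_boot, obs = obs,
                 expected = as.numeric(expected_mismatch(
                   fit1$par[1], fit1$par[2], fit1$par[3], d_max))),
            class = "cr_mismatchfit")
}

# deterministic multi-start bounded least squares
fit_mismatch_core <- function(obs, theta1_max, starts = NULL) {
  d_max <- length(obs) - 1L
  mean_d <- sum((0:d_max) * obs)
  base_starts <- rbind(
    c(mean_d, 0.01, theta1_max),                 # method-of-moments start
    c(mean_d, mean_d / 2, theta1_max * 0.9),
    c(mean_d / 2, 0.01, 10 * mean_d + 1),
    c(mean_d, 0.01, 10 * mean_d + 1),
    c(1, 1, 100), c(5, 1, 100), c(10, 0.5, 50),
    c(mean_d, mean_d, mean_d + 1),
    c(2 * mean_d, 0.01, theta1_max * 0.9),
    c(0.5, 0.01, max(mean_d, 1)))
  starts <- rbind(starts, base_starts)
  lower <- c(0, 0, 1e-6)
  upper <- c(50, 50, theta1_max)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[s, ], lower), upper)
    ft <- try(stats::optim(p0, mismatch_ssd, obs = obs, method = "L-BFGS-B",
                           lower = lower, upper = upper,
                           control = list(maxit = 500)), silent = TRUE)
    if (inherits(ft, "try-error")) next
    if (is.null(best) || ft$value < best$value) best <- ft
  }
  if (is.null(best)) stop("mismatch fit failed from every start", call. = FALSE)
  best
}

#' @export
print.cr_mismatchfit <- function(x, ...) {
  cat(sprintf("sudden-expansion fit: tau = %.3f, theta0 = %.3g, theta1 = %.4g\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.4g (p = %s), raggedness = %.4g (p = %s)\n",
              x$SSD, format(x$p_SSD), x$raggedness, format(x$p_raggedness)))
  if (!anyNA(x$CI95_tau))
    cat(sprintf("  tau 95%% CI: %.3f - %.3f (n_boot = %d)\n",
                x$CI95_tau[1], x$CI95_tau[2], x$n_boot))
  invisible(x)
}

#' Write observed and fitted mismatch curves as CSV
#' @param fit a `cr_mismatchfit`.
#' @param path output CSV.
#' @export
write_mismatch_csv <- function(fit, path) {
  utils::write.csv(data.frame(differences = seq_along(fit$obs) - 1L,
                              observed = fit$obs, expected = fit$expected),
                   path, row.names = FALSE)
  invisible(path)
}
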