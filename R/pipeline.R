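#' Pipeline run configuration
#'
#' Collects every knob of the full analysis in one validated list, which is
#' echoed into the run report so a run can be reproduced exactly. Per-stage
#' seeds are derived deterministically from the master seed so that stages
#' can be toggled without changing the randomness of the others.
#'
#' @param fasta,popmap input file paths.
#' @param outdir output directory.
#' @param mask_ranges list of 0-based half-open column intervals to drop.
#' @param dist_model distance model for the structure analyses.
#' @param gamma_alpha gamma shape for the TN93+G distances.
#' @param scaling a [time_scaling()] list for the expansion-time report.
#' @param n_reps_neutrality coalescent replicates for the test p-values.
#' @param n_boot_mismatch parametric-bootstrap replicates.
#' @param n_perms_amova,n_perms_pairwise permutation counts.
#' @param amova_groups optional named list grouping populations.
#' @param im settings list for the IM stage (`enabled`, `pops`, `priors`,
#'   `n_burn`, `n_steps`, `thin`) or NULL to skip it.
#' @param seed master seed.
#' @return list of class `cr_runconfig`.
#' @export
run_config <- function(fasta, popmap, outdir, mask_ranges = list(),
                       dist_model = "TN93+G", gamma_alpha = 0.61,
                       scaling = time_scaling(),
                       n_reps_neutrality = 1000, n_boot_mismatch = 200,
                       n_perms_amova = 5000, n_perms_pairwise = 1000,
                       amova_groups = NULL, im = NULL, seed = 1) {
  stopifnot(is.character(fasta), is.character(popmap),
            n_reps_neutrality >= 100, n_boot_mismatch >= 0,
            n_perms_amova >= 0, n_perms_pairwise >= 0,
            dist_model %in% c("p", "TN93", "TN93+G"))
  structure(list(fasta = fasta, popmap = popmap, outdir = outdir,
                 mask_ranges = mask_ranges, dist_model = dist_model,
                 gamma_alpha = gamma_alpha, scaling = scaling,
                 n_reps_neutrality = n_reps_neutrality,
                 n_boot_mismatch = n_boot_mismatch,
                 n_perms_amova = n_perms_amova,
                 n_perms_pairwise = n_perms_pairwise,
                 amova_groups = amova_groups, im = im, seed = seed),
            class = "cr_runconfig")
}

stage_seed <- function(master, stage) {
  # deterministic per-stage seed from the master seed
  (master * 7919 + sum(utf8ToInt(stage)) * 131) %% (2^31 - 1) + 1
}

#' Run the full control-region analysis pipeline
#'
#' Reads the alignment and population map, masks requested columns, and
#' produces: the haplotype frequency table, per-population and pooled
#' diversity and neutrality statistics, the mismatch distribution with its
#' sudden-expansion fit and expansion-time estimate, the AMOVA table,
#' pairwise Phi_ST, the minimum spanning haplotype network, and (if
#' enabled) the two-population isolation-with-migration posterior. All
#' tables are written as CSV under `outdir` along with a machine-readable
#' JSON report.
#'
#' @param config a [run_config()] object.
#' @return the report as an invisible list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cr_runconfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config))
  inp <- read_alignment(config$fasta, config$popmap)
  aln <- mask_sites(inp$alignment, config$mask_ranges)
  pm <- inp$popmap

  # --- variation
  tbl <- collapse_haplotypes(aln, pm)
  write_haplotype_table(tbl, file.path(config$outdir, "haplotype_table.csv"))
  shr <- shared_private_summary(tbl)
  cs <- classify_sites(aln)
  div <- diversity_table(aln, pm)
  report$sites <- cs[c("S", "n_transitions", "n_transversions", "n_indels")]
  report$base_composition <- as.list(cs$base_composition)
  report$shared_private <- shr

  # --- neutrality per population and pooled
  sd_neu <- stage_seed(config$seed, "neutrality")
  neu <- lapply(seq_len(nrow(div)), function(i) {
    p <- div$population[i]
    ids <- if (p == "Total") aln$ids else
      aln$ids[pm$pop[aln$ids] == p]
    sub <- cr_alignment(ids, aln$seqs[match(ids, aln$ids)])
    r <- neutrality_test(sub, n_reps = config$n_reps_neutrality,
                         seed = sd_neu + i)
    data.frame(population = p, D = r$D, p_D = r$p_D, Fs = r$Fs,
               p_Fs = r$p_Fs)
  })
  neu <- do.call(rbind, neu)
  summary_tbl <- merge(div, neu, by = "population", sort = FALSE)
  utils::write.csv(summary_tbl,
                   file.path(config$outdir, "diversity_neutrality.csv"),
                   row.names = FALSE)
  report$diversity <- summary_tbl

  # --- mismatch / expansion
  pd <- pairwise_differences(aln)
  obs <- observed_mismatch(pd$diff)
  fit <- fit_sudden_expansion(obs, n = length(aln$ids),
                              seed = stage_seed(config$seed, "mismatch"),
                              n_boot = config$n_boot_mismatch)
  write_mismatch_csv(fit, file.path(config$outdir, "mismatch.csv"))
  yrs <- tau_to_years(fit$tau, config$scaling)
  report$mismatch <- list(tau = fit$tau, theta0 = fit$theta0,
                          theta1 = fit$theta1, SSD = fit$SSD,
                          p_SSD = fit$p_SSD, raggedness = fit$raggedness,
                          p_raggedness = fit$p_raggedness,
                          CI95_tau = fit$CI95_tau,
                          expansion_years = yrs,
                          expansion_years_rounded = round(yrs / 100) * 100)

  # --- structure (needs at least two populations)
  dmat <- switch(config$dist_model,
                 "p" = {
                   d <- pd$diff / pd$comparable
                   d
                 },
                 "TN93" = tn93_matrix(aln),
                 "TN93+G" = tn93_matrix(aln, gamma = TRUE,
                                        alpha = config$gamma_alpha))
  if (length(pm$levels) >= 2L) {
    am <- amova(dmat^2, pm, groups = config$amova_groups,
                n_perms = config$n_perms_amova,
                seed = stage_seed(config$seed, "amova"))
    write_amova_csv(am, file.path(config$outdir, "amova.csv"))
    pw <- pairwise_phist(dmat^2, pm, n_perms = config$n_perms_pairwise,
                         seed = stage_seed(config$seed, "pairwise"))
    utils::write.csv(pw$phist,
                     file.path(config$outdir, "pairwise_phist.csv"))
    utils::write.csv(pw$p, file.path(config$outdir, "pairwise_phist_p.csv"))
    report$amova <- list(table = am$table, phi = as.list(am$phi),
                         p = as.list(am$p))
    report$pairwise_phist <- list(phist = pw$phist, p = pw$p)
  } else {
    report$amova <- "skipped: single population"
  }

  # --- haplotype network
  hd <- pairwise_differences(cr_alignment(paste0("h", seq_along(tbl$seqs)),
                                          tbl$seqs))
  net <- minimum_spanning_network(tbl, hd$diff)
  write_network_csv(net, file.path(config$outdir, "network_edges.csv"))
  write_network_graphml(net, file.path(config$outdir, "network.graphml"))
  report$network <- list(n_tree_edges = sum(net$in_mst),
                         n_alternative = sum(net$alternative))

  # --- isolation with migration (optional, expensive)
  if (!is.null(config$im) && isTRUE(config$im$enabled)) {
    grpmap <- config$im$pops   # named list: new label -> population labels
    pop2 <- stats::setNames(rep(names(grpmap), lengths(grpmap)),
                            unlist(grpmap))
    pm2 <- cr_popmap(stats::setNames(pop2[pm$pop[aln$ids]], aln$ids))
    post <- im_mcmc(aln, pm2,
                    priors = config$im$priors,
                    n_burn = config$im$n_burn %||% 2000,
                    n_steps = config$im$n_steps %||% 20000,
                    thin = config$im$thin %||% 10,
                    seed = stage_seed(config$seed, "im"))
    write_im_posterior(post, file.path(config$outdir, "im"))
    dem <- scale_to_demographic_units(post, u = config$scaling$u)
    report$im <- list(mode = as.list(post$mode),
                      hpd95 = apply(post$hpd95, 2, as.list),
                      ess = as.list(post$ess),
                      divergence_years = dem$divergence_years,
                      tmrca_years = dem$tmrca_years)
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
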