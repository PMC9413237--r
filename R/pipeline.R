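#' Pipeline configuration
#'
#' Assembles the full configuration for a simulated or re-analyzed screen.
#' Defaults mirror the screening pipeline's stated settings: 4 MCMC chains of
#' 4000 iterations (half warm-up) with Rhat <= 1.2 and doubling to 16,000;
#' vehicle CV gate < 20\%; MAF >= 0.05; suggestive / genome-wide thresholds
#' 1e-5 and 5e-8; TDVF benchmarks 10^(1/2) and 10. Values supplied in
#' \code{...} (or a YAML file) override defaults by name, nested lists merged
#' shallowly per section.
#'
#' @param ... named sections overriding defaults: \code{population},
#'   \code{layout}, \code{substances}, \code{genotypes}, \code{qc},
#'   \code{fit}, \code{activity}, \code{gwas}, \code{seed}.
#' @param file optional YAML file of overrides (applied before \code{...}).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    seed = 1L,
    population = list(n_individuals = 20, mu_log_y0 = 0, sd_log_y0 = 0.05,
                      mu_log_nshift = 0, sd_log_nshift = 0.5,
                      error_scale = 0.05, error_df = 5),
    substances = data.frame(chemical_id = "chem1",
                            mu_log_ec50 = log(10), sd_log_ec50 = 0.5,
                            stringsAsFactors = FALSE),
    layout = list(concentrations = c(0.01, 0.1, 1, 10, 100),
                  n_replicate_plates = 3, n_vehicle_wells = 16,
                  n_positive_wells = 8, vehicle_luminescence_mean = 2e5,
                  vehicle_luminescence_cv = 0.05),
    genotypes = list(n_snps = 500, maf_range = c(0.05, 0.5),
                     n_ancestry_groups = 2,
                     group_proportions = c(106, 40) / 146,
                     group_divergence = 0.05, causal_snps = NULL),
    qc = list(vehicle_cv_max = 20, positive_control_max = 0.05),
    fit = list(n_chains = 4, initial_iterations = 4000,
               rhat_threshold = 1.2, max_iterations = 16000),
    activity = list(threshold_fold = 3),
    tdvf = list(benchmarks = c(default_td = 10^0.5, default_total = 10)),
    gwas = list(maf_threshold = 0.05, k_pcs = 3, suggestive = 1e-5,
                significant = 5e-8, phenotype_scale = "log10", mlma = FALSE)
  )
  apply_over <- function(cfg, over) {
    for (nm in names(over)) {
      if (is.list(cfg[[nm]]) && is.list(over[[nm]]) && !is.data.frame(over[[nm]])) {
        cfg[[nm]][names(over[[nm]])] <- over[[nm]]
      } else cfg[[nm]] <- over[[nm]]
    }
    cfg
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
  cfg <- apply_over(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

derive_seed <- function(seed, stage) {
  # stable per-stage sub-seed, kept within 32-bit integer range
  (as.integer(seed) * 2654435L + sum(utf8ToInt(stage)) * 97L) %% 2147483647L
}

#' Simulate a complete synthetic study
#'
#' Generates the donor population per substance, a full plate set (all
#' substances share each cell line's replicate plates), genotypes with
#' optional planted causal variants, and truth tables for recovery tests;
#' optionally writes everything plus a run manifest with seeds and file
#' checksums to \code{dir}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param dir output directory, or \code{NULL} to skip writing.
#' @param force overwrite existing outputs.
#' @return A list: \code{plates}, \code{genotypes} (simulate_genotypes
#'   result), \code{truth} (per-substance true parameters), \code{manifest}.
#' @export
simulate_study <- function(config, dir = NULL, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  subs <- config$substances
  pops <- list()
  params_long <- list()
  geno <- NULL
  for (i in seq_len(nrow(subs))) {
    spec <- do.call(population_spec, c(
      config$population,
      list(mu_log_ec50 = subs$mu_log_ec50[i], sd_log_ec50 = subs$sd_log_ec50[i],
           seed = derive_seed(config$seed, paste0("pop_", subs$chemical_id[i])))))
    pop <- simulate_population(spec)
    if (i == 1) {
      gspec <- do.call(genotype_sim_spec, c(
        config$genotypes, list(seed = derive_seed(config$seed, "genotypes"))))
      geno <- simulate_genotypes(gspec, pop)
    } else if (!is.null(config$genotypes$causal_snps)) {
      for (j in seq_len(nrow(config$genotypes$causal_snps))) {
        s <- config$genotypes$causal_snps$snp[j]
        pop$log_ec50 <- pop$log_ec50 +
          config$genotypes$causal_snps$beta[j] * geno$genotypes[, s]
      }
      pop$ec50 <- exp(pop$log_ec50)
    }
    if (i == 1) pop <- geno$population
    pop$chemical_id <- subs$chemical_id[i]
    pops[[subs$chemical_id[i]]] <- pop
    params_long[[i]] <- pop[, c("individual_id", "sex", "chemical_id", "y0", "ec50", "n")]
  }
  params <- do.call(rbind, params_long)
  layout <- do.call(plate_layout, config$layout)
  pop_label <- geno$samples$ancestry_group[match(unique(params$individual_id),
                                                 geno$samples$individual_id)]
  plates <- simulate_plates(params, layout,
                            error_scale = config$population$error_scale,
                            error_df = config$population$error_df,
                            seed = derive_seed(config$seed, "plates"),
                            population_label = pop_label)
  truth <- do.call(rbind, pops)
  rownames(truth) <- NULL
  out <- list(plates = plates, genotypes = geno, truth = truth, config = config)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("plates.csv", "genotypes.tsv", "genotypes.vcf",
                              "samples.tsv", "truth.csv", "manifest.json"))
    if (!force && any(file.exists(paths))) {
      stop("output files exist in ", dir, "; use force = TRUE to overwrite")
    }
    write_plateset(plates, paths[1])
    write_genotypes_tsv(geno, paths[2])
    write_genotypes_vcf(geno, paths[3])
    write_sample_info_tsv(geno$samples, paths[4])
    utils::write.csv(truth, paths[5], row.names = FALSE)
    manifest <- list(
      seed = config$seed,
      stage_seeds = list(plates = derive_seed(config$seed, "plates"),
                         genotypes = derive_seed(config$seed, "genotypes")),
      checksums = as.list(tools::md5sum(paths[1:5])),
      created = "synthetic study"
    )
    jsonlite::write_json(manifest, paths[6], auto_unbox = TRUE, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

#' Run the analysis pipeline end to end
#'
#' Normalization and QC (plate-level exclusion), hierarchical Bayesian Hill
#' fitting per substance, EC10 PODs, activity calls, TDVF05 for active
#' substances, and covariate-adjusted GWAS of the POD phenotype with
#' genomic-control diagnostics. Inactive substances are reported but carry no
#' TDVF row and are skipped in the GWAS stage.
#'
#' @param plates a PlateSet data frame (raw luminescence).
#' @param genotypes a \code{\link{simulate_genotypes}}-style list
#'   (\code{genotypes}, \code{map}, \code{samples}), or \code{NULL} to skip
#'   the GWAS stage.
#' @param config a \code{\link{pipeline_config}}.
#' @param dir optional output directory for stage TSVs and the JSON report.
#' @param quiet suppress progress messages.
#' @return A list: \code{qc}, \code{fits}, \code{pods}, \code{activity},
#'   \code{tdvfs}, \code{gwas}, \code{report}.
#' @export
run_pipeline <- function(plates, genotypes = NULL, config = pipeline_config(),
                         dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  norm <- normalize_plates(plates)
  qc <- qc_plates(norm, vehicle_cv_max = config$qc$vehicle_cv_max,
                  positive_control_max = config$qc$positive_control_max)
  n_fail <- sum(!qc$pass)
  say("[qc] %d/%d plates pass", sum(qc$pass), nrow(qc))
  if (n_fail > 0) {
    for (i in which(!qc$pass)) say("[qc] excluded %s: %s", qc$plate_id[i], qc$failure_reasons[i])
  }
  dr <- dose_response_dataset(norm, qc)
  max_conc <- max(dr$concentration_uM)

  substances <- setdiff(unique(dr$chemical_id), c("DMSO", "TAB"))
  fits <- pods <- tdvfs <- list()
  activity <- list()
  for (s in substances) {
    say("[fit] %s", s)
    cfg <- do.call(fit_config, c(config$fit, list(
      seed = derive_seed(config$seed, paste0("fit_", s)))))
    fit <- fit_hill_population(dr[dr$chemical_id == s, ], cfg, substance = s)
    fits[[s]] <- fit
    pod <- pod_table(fit)
    pods[[s]] <- pod
    act <- classify_activity(pod, max_conc,
                             threshold_fold = config$activity$threshold_fold)
    activity[[s]] <- act
    if (act$active) {
      tdvfs[[s]] <- tdvf05(pod, benchmarks = config$tdvf$benchmarks)
      say("[tdvf] %s: median %.3g", s, tdvfs[[s]]$median)
    } else {
      say("[tdvf] %s inactive (median EC10 %.3g > %g x %g uM); no TDVF",
          s, act$population_median_ec10, config$activity$threshold_fold, max_conc)
    }
  }
  activity <- do.call(rbind, activity)
  rownames(activity) <- NULL

  gwas_out <- NULL
  if (!is.null(genotypes) && length(tdvfs)) {
    flt <- filter_maf(genotypes$genotypes, genotypes$map,
                      threshold = config$gwas$maf_threshold)
    pcs <- genotype_pcs(flt$genotypes, k = config$gwas$k_pcs)
    sex <- genotypes$samples$sex
    gwas_out <- list(tables = list(), lambda = list())
    for (s in names(tdvfs)) {
      ph <- pods[[s]]$summary$ec10_median[
        match(rownames(flt$genotypes), pods[[s]]$summary$individual_id)]
      if (config$gwas$phenotype_scale == "log10") ph <- log10(ph)
      tab <- snp_association(ph, flt$genotypes, sex = sex, pcs = pcs,
                             map = flt$map,
                             suggestive = config$gwas$suggestive,
                             significant = config$gwas$significant)
      gwas_out$tables[[s]] <- tab
      gwas_out$lambda[[s]] <- genomic_lambda(tab$p[tab$testable])
      say("[gwas] %s: %d suggestive, %d significant, lambda %.3f", s,
          sum(tab$hit_class == "suggestive", na.rm = TRUE),
          sum(tab$hit_class == "significant", na.rm = TRUE),
          gwas_out$lambda[[s]]$lambda)
    }
    if (length(gwas_out$tables) >= 2) {
      gwas_out$overlap <- overlap_loci(gwas_out$tables,
                                       p_threshold = config$gwas$suggestive)
    }
  }

  report <- list(
    n_plates = nrow(qc), n_plates_passed = sum(qc$pass),
    substances = substances,
    active = activity$substance[activity$active],
    inactive = activity$substance[!activity$active],
    converged = vapply(fits, function(f) f$converged, logical(1)),
    tdvf = lapply(tdvfs, function(v) list(median = v$median, q5 = v$q5,
                                          q95 = v$q95,
                                          exceeds = as.list(v$exceeds))),
    gwas = if (!is.null(gwas_out)) lapply(names(gwas_out$tables), function(s) {
      tab <- gwas_out$tables[[s]]
      list(substance = s,
           n_suggestive = sum(tab$hit_class == "suggestive", na.rm = TRUE),
           n_significant = sum(tab$hit_class == "significant", na.rm = TRUE),
           lambda = gwas_out$lambda[[s]]$lambda)
    }),
    runtime_s = as.numeric(Sys.time() - t0, units = "secs")
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(qc, file.path(dir, "qc_report.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(dr, file.path(dir, "dose_response.csv"), row.names = FALSE)
    for (s in names(pods)) {
      write_pod_table(pods[[s]], file.path(dir, paste0("pod_", s, ".tsv")))
      write_convergence_report(fits[[s]], file.path(dir, paste0("convergence_", s, ".tsv")))
    }
    utils::write.table(activity, file.path(dir, "activity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (length(tdvfs)) write_tdvf_table(tdvfs, file.path(dir, "tdvf.tsv"))
    if (!is.null(gwas_out)) {
      for (s in names(gwas_out$tables)) {
        utils::write.table(gwas_out$tables[[s]],
                           file.path(dir, paste0("gwas_", s, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(qc = qc, dose_response = dr, fits = fits, pods = pods,
       activity = activity, tdvfs = tdvfs, gwas = gwas_out, report = report)
}
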