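#' Per-individual EC10 points of departure from a fitted model
#'
#' Applies the closed-form EC10 to every MCMC draw of every individual's
#' \code{(ec50, n)}, giving the posterior POD distribution per cell line.
#'
#' @param fit a \code{\link{fit_hill_population}} result, or a list with
#'   elements \code{ec50} and \code{n} (draw matrices, draws x individuals).
#' @param substance label; taken from the fit when available.
#' @return An object of class \code{pod_table}: \code{draws} (matrix of EC10,
#'   draws x individuals), \code{summary} (per-individual median and 95\%
#'   interval), \code{substance}.
#' @export
pod_table <- function(fit, substance = NULL) {
  if (inherits(fit, "hill_fit")) {
    ec50 <- fit$draws$ec50; n <- fit$draws$n
    if (is.null(substance)) substance <- fit$substance
  } else {
    ec50 <- fit$ec50; n <- fit$n
    if (is.null(substance)) substance <- "substance"
  }
  draws <- ec10_from_params(ec50, n)
  s <- t(apply(draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  summary <- data.frame(substance = substance,
                        individual_id = colnames(draws),
                        ec10_median = s[, 1], ec10_q2.5 = s[, 2],
                        ec10_q97.5 = s[, 3],
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(draws = draws, summary = summary, substance = substance),
            class = "pod_table")
}

#' Activity call from the population median EC10
#'
#' A substance is called inactive when the population median EC10 exceeds
#' three times the maximum tested concentration (strict inequality);
#' otherwise it is active. The default population median is the median across
#' individuals of each individual's posterior-median EC10; the per-draw
#' alternative takes the across-individual median within each MCMC sample
#' and then the median over samples.
#'
#' @param pod a \code{\link{pod_table}}.
#' @param max_concentration maximum tested concentration (uM).
#' @param rule \code{"posterior_median"} (default) or \code{"per_draw"}.
#' @param threshold_fold multiplier of the maximum concentration (default 3).
#' @return A one-row data frame: \code{substance}, \code{population_median_ec10},
#'   \code{max_concentration}, \code{threshold_fold}, \code{active}.
#' @export
classify_activity <- function(pod, max_concentration,
                              rule = c("posterior_median", "per_draw"),
                              threshold_fold = 3) {
  stopifnot(inherits(pod, "pod_table"))
  rule <- match.arg(rule)
  if (!nrow(pod$summary)) stop("empty POD table")
  med <- switch(rule,
    posterior_median = stats::median(pod$summary$ec10_median),
    per_draw = stats::median(apply(pod$draws, 1, stats::median)))
  data.frame(substance = pod$substance,
             population_median_ec10 = med,
             max_concentration = max_concentration,
             threshold_fold = threshold_fold,
             active = !(med > threshold_fold * max_concentration),
             stringsAsFactors = FALSE)
}

#' Toxicodynamic variability factor TDVF05 with posterior uncertainty
#'
#' Within each MCMC sample, the EC10 quantiles are taken across the
#' individuals of the population; the TDVF05 is the ratio of the median
#' individual's POD to the most sensitive 5th-percentile individual's POD.
#' Repeating this per sample yields the uncertainty distribution of the
#' TDVF05. Quantiles interpolate linearly between order statistics
#' (type 7).
#'
#' @param pod a \code{\link{pod_table}} or a draws x individuals EC10 matrix.
#' @param sensitive_quantile tail quantile defining the sensitive individual
#'   (default 0.05).
#' @param benchmarks reference variability factors flagged in the summary
#'   (default \code{10^0.5} = 3.16, the default toxicodynamic allowance, and
#'   10, the combined toxicokinetic + toxicodynamic default).
#' @return An object of class \code{tdvf_distribution}: \code{samples}
#'   (per-draw TDVF05 values), \code{median}, \code{q5}, \code{q95},
#'   \code{exceeds} (named logical vs each benchmark), \code{substance}.
#' @export
tdvf05 <- function(pod, sensitive_quantile = 0.05,
                   benchmarks = c(default_td = 10^0.5, default_total = 10)) {
  draws <- if (inherits(pod, "pod_table")) pod$draws else as.matrix(pod)
  substance <- if (inherits(pod, "pod_table")) pod$substance else "substance"
  nind <- ncol(draws)
  if (nind < 2) stop("TDVF05 needs at least 2 individuals")
  if (nind < 20) {
    warning("fewer than 20 individuals: the 5th-percentile individual is ",
            "poorly determined")
  }
  q <- apply(draws, 1, stats::quantile,
             probs = c(0.5, sensitive_quantile), type = 7)
  samples <- q[1, ] / q[2, ]
  med <- stats::median(samples)
  structure(list(
    substance = substance,
    samples = samples,
    median = med,
    q5 = unname(stats::quantile(samples, 0.05)),
    q95 = unname(stats::quantile(samples, 0.95)),
    exceeds = stats::setNames(med > benchmarks, names(benchmarks)),
    benchmarks = benchmarks
  ), class = "tdvf_distribution")
}

#' @export
print.tdvf_distribution <- function(x, ...) {
  cat(sprintf("TDVF05 [%s]: median %.3g (90%% CrI %.3g-%.3g)\n",
              x$substance, x$median, x$q5, x$q95))
  for (b in names(x$benchmarks)) {
    cat(sprintf("  exceeds %s benchmark (%.3g): %s\n", b, x$benchmarks[[b]],
                x$exceeds[[b]]))
  }
  invisible(x)
}

#' Cross-substance variability summary
#'
#' Tabulates population-median EC10 and median TDVF05 per substance and
#' computes the Pearson correlation between \code{log10} median EC10 and
#' \code{log10} median TDVF05 (potency-variability relationship).
#'
#' @param pods list of \code{\link{pod_table}} objects (active substances).
#' @param tdvfs list of matching \code{\link{tdvf05}} results.
#' @return A list: \code{table} (per-substance medians and benchmark flags),
#'   \code{correlation} (r, p, flag; the flag marks an undefined correlation
#'   from zero variance).
#' @export
summarize_variability <- function(pods, tdvfs) {
  if (length(pods) < 2) stop("need >= 2 substances to summarize variability")
  if (length(pods) != length(tdvfs)) stop("'pods' and 'tdvfs' must align")
  tab <- do.call(rbind, Map(function(p, v) {
    data.frame(substance = p$substance,
               population_median_ec10 = stats::median(p$summary$ec10_median),
               tdvf05_median = v$median,
               tdvf05_q5 = v$q5, tdvf05_q95 = v$q95,
               exceeds_default_td = unname(v$exceeds[1]),
               exceeds_default_total = unname(v$exceeds[2]),
               stringsAsFactors = FALSE)
  }, pods, tdvfs))
  rownames(tab) <- NULL
  lx <- log10(tab$population_median_ec10)
  ly <- log10(tab$tdvf05_median)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) {
    corr <- list(r = NA_real_, p_value = NA_real_,
                 flag = "zero variance: correlation undefined")
  } else {
    ct <- stats::cor.test(lx, ly, method = "pearson")
    corr <- list(r = unname(ct$estimate), p_value = ct$p.value, flag = NA_character_)
  }
  list(table = tab, correlation = corr)
}

#' Write POD / TDVF / activity outputs as TSV
#' @param pod a \code{pod_table}.
#' @param path output file.
#' @export
write_pod_table <- function(pod, path) {
  utils::write.table(pod$summary, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param tdvfs list of \code{tdvf_distribution} objects.
#' @rdname write_pod_table
#' @export
write_tdvf_table <- function(tdvfs, path) {
  tab <- do.call(rbind, lapply(tdvfs, function(v) {
    data.frame(substance = v$substance, tdvf05_median = v$median,
               tdvf05_q5 = v$q5, tdvf05_q95 = v$q95,
               exceeds_default_td = unname(v$exceeds[1]),
               exceeds_default_total = unname(v$exceeds[2]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
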