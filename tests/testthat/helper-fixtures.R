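# Small in-code fixtures shared across test files.

# Minimal single-plate PlateSet from explicit well values.
make_plate <- function(vehicle, positive = numeric(0), treatment = numeric(0),
                       conc = seq_along(treatment), plate_id = "P1",
                       cell_line = "L001", chemical = "chemA") {
  data.frame(
    plate_id = plate_id,
    cell_line_id = cell_line,
    population_label = NA_character_,
    sex = NA_integer_,
    well_role = c(rep("vehicle", length(vehicle)),
                  rep("positive", length(positive)),
                  rep("treatment", length(treatment))),
    chemical_id = c(rep("DMSO", length(vehicle)), rep("TAB", length(positive)),
                    rep(chemical, length(treatment))),
    concentration_uM = c(rep(0, length(vehicle)), rep(100, length(positive)), conc),
    raw_luminescence = c(vehicle, positive, treatment),
    stringsAsFactors = FALSE
  )
}

# pod_table built directly from EC10 draw matrices (draws x individuals),
# for testing the POD/TDVF operations without an MCMC fit.
make_pod <- function(ec10_draws, substance = "chemA") {
  if (is.null(colnames(ec10_draws))) {
    colnames(ec10_draws) <- sprintf("L%03d", seq_len(ncol(ec10_draws)))
  }
  s <- t(apply(ec10_draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  structure(list(
    draws = ec10_draws,
    summary = data.frame(substance = substance,
                         individual_id = colnames(ec10_draws),
                         ec10_median = s[, 1], ec10_q2.5 = s[, 2],
                         ec10_q97.5 = s[, 3], stringsAsFactors = FALSE),
    substance = substance
  ), class = "pod_table")
}

# Genotype matrix with independent binomial SNPs at given frequencies.
make_genotypes <- function(n, freqs, seed = 1) {
  set.seed(seed)
  G <- sapply(freqs, function(p) stats::rbinom(n, 2, p))
  dimnames(G) <- list(sprintf("S%03d", seq_len(n)),
                      sprintf("snp%05d", seq_along(freqs)))
  G
}
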