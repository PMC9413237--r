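test_that("population simulation is deterministic and respects its spec", {
  spec <- population_spec(n_individuals = 50, seed = 7)
  expect_identical(simulate_population(spec), simulate_population(spec))

  # degenerate variance: everyone shares one EC50
  p0 <- simulate_population(population_spec(n_individuals = 10, sd_log_ec50 = 0, seed = 1))
  expect_equal(length(unique(p0$ec50)), 1)

  # the Hill coefficient is >= 1 by construction, whatever the shift scale
  for (s in 1:5) {
    p <- simulate_population(population_spec(n_individuals = 200,
                                             mu_log_nshift = -2,
                                             sd_log_nshift = 3, seed = s))
    expect_true(all(p$n >= 1))
    expect_true(all(p$ec50 > 0))
  }
})

test_that("population moments converge to the hyperparameters", {
  s <- 0.7
  p <- simulate_population(population_spec(n_individuals = 10000,
                                           mu_log_ec50 = log(5),
                                           sd_log_ec50 = s, seed = 11))
  expect_equal(sd(p$log_ec50), s, tolerance = 0.03)
  expect_equal(mean(p$log_ec50), log(5), tolerance = 3 * s / sqrt(10000) / log(5))
})

test_that("invalid population specs name the offending field", {
  expect_error(population_spec(n_individuals = 1), "n_individuals")
  expect_error(population_spec(sd_log_ec50 = -0.1), "sd_log_ec50")
  expect_error(population_spec(error_df = 0), "error_df")
})

test_that("plate simulation fulfils the layout contract", {
  pop <- simulate_population(population_spec(n_individuals = 3, seed = 2))
  lay <- plate_layout()
  pl <- simulate_plates(pop, lay, chemical_id = "chemA", seed = 5)
  tr <- pl[pl$well_role == "treatment", ]
  # every (chemical, concentration) on every replicate plate of every line
  counts <- table(tr$cell_line_id, tr$concentration_uM)
  expect_true(all(counts == lay$n_replicate_plates))
  expect_equal(sort(unique(tr$concentration_uM)), c(0.01, 0.1, 1, 10, 100))
  expect_equal(sum(pl$well_role == "vehicle"),
               3 * lay$n_replicate_plates * lay$n_vehicle_wells)
  expect_identical(pl, simulate_plates(pop, lay, chemical_id = "chemA", seed = 5))
})

test_that("noiseless wells reproduce the Hill curve analytically", {
  pop <- simulate_population(population_spec(n_individuals = 2, seed = 3))
  lay <- plate_layout(vehicle_luminescence_cv = 0)
  pl <- simulate_plates(pop, lay, error_scale = 0, seed = 5)
  norm <- normalize_plates(pl)
  tr <- norm[norm$well_role == "treatment", ]
  expected <- hill_response(tr$concentration_uM,
                            y0 = pop$y0[match(tr$cell_line_id, pop$individual_id)],
                            ec50 = pop$ec50[match(tr$cell_line_id, pop$individual_id)],
                            n = pop$n[match(tr$cell_line_id, pop$individual_id)])
  expect_equal(tr$normalized_response, expected, tolerance = 1e-12)
  # Hill midpoint sanity: concentration == EC50 gives exactly half baseline
  i1 <- pop[1, ]
  pl2 <- simulate_plates(data.frame(individual_id = "Lx", y0 = i1$y0,
                                    ec50 = 10, n = 3),
                         plate_layout(concentrations = c(1, 10, 100),
                                      vehicle_luminescence_cv = 0),
                         error_scale = 0, seed = 1)
  n2 <- normalize_plates(pl2)
  mid <- n2$normalized_response[n2$well_role == "treatment" & n2$concentration_uM == 10]
  expect_equal(mid, rep(0.5 * i1$y0, 3), tolerance = 1e-12)
})

test_that("positive-control wells read as near-complete kill", {
  pop <- simulate_population(population_spec(n_individuals = 2, seed = 3))
  pl <- simulate_plates(pop, plate_layout(), seed = 6)
  norm <- normalize_plates(pl)
  pos <- norm$normalized_response[norm$well_role == "positive"]
  expect_true(all(pos < 0.02))
})

test_that("genotype simulation has binomial sampling structure", {
  pop <- simulate_population(population_spec(n_individuals = 500, seed = 4))
  gs <- genotype_sim_spec(n_snps = 50, maf_range = c(0.3, 0.3),
                          n_ancestry_groups = 1, group_divergence = 0, seed = 5)
  g <- simulate_genotypes(gs, pop)
  maf <- colMeans(g$genotypes) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 500))
  expect_true(all(abs(maf - 0.3) < 3 * se + 1e-12))
  expect_true(mean(abs(maf - 0.3) < 2 * se) > 0.8)
})

test_that("causal SNPs shift the EC50 phenotype additively and only then", {
  pop <- simulate_population(population_spec(n_individuals = 100, seed = 6))
  g0 <- simulate_genotypes(genotype_sim_spec(n_snps = 20, seed = 7), pop)
  expect_identical(g0$population$ec50, pop$ec50)  # beta = 0 everywhere

  gc <- simulate_genotypes(genotype_sim_spec(
    n_snps = 20, causal_snps = data.frame(snp = 3, beta = 0.5), seed = 7), pop)
  shift <- gc$population$log_ec50 - pop$log_ec50
  expect_equal(shift, 0.5 * gc$genotypes[, 3], ignore_attr = TRUE)

  # planting an effect on a monomorphic SNP is an error
  pop2 <- simulate_population(population_spec(n_individuals = 4, seed = 1))
  expect_error(simulate_genotypes(genotype_sim_spec(
    n_snps = 5, maf_range = c(0.01, 0.01),
    causal_snps = data.frame(snp = 1, beta = 1), seed = 30), pop2),
    "monomorphic")
})

test_that("divergent ancestry groups separate on the leading genotype PC", {
  pop <- simulate_population(population_spec(n_individuals = 120, seed = 8))
  g <- simulate_genotypes(genotype_sim_spec(n_snps = 500, group_divergence = 0.1,
                                            seed = 9), pop)
  pcs <- genotype_pcs(filter_maf(g$genotypes)$genotypes, k = 2)
  r <- abs(cor(pcs[, 1], as.numeric(factor(g$samples$ancestry_group))))
  expect_gt(r, 0.9)
})

test_that("mixture recipes normalize reference values to mass fractions", {
  eq <- build_mixture_recipe(c(a = 2, b = 2, c = 2, d = 2), "POD", "low")
  expect_equal(eq$mass_fraction, rep(0.25, 4))
  r <- build_mixture_recipe(c(a = 9, b = 1), "Exposure", "high")
  expect_equal(r$mass_fraction, c(0.9, 0.1))
  expect_equal(sum(r$mass_fraction), 1, tolerance = 1e-9)
  # a dominating reference value drives its fraction toward 1
  dom <- build_mixture_recipe(c(zinc = 1000, a = 1, b = 1, c = 1), "Exposure", "low")
  expect_gt(dom$mass_fraction[1], 0.99)
  expect_error(build_mixture_recipe(c(a = 1, b = 0)), "positive")
  expect_error(build_mixture_recipe(c(1, 2)), "named")
})

test_that("plate, genotype, and recipe files round-trip", {
  dir <- withr::local_tempdir()
  pop <- simulate_population(population_spec(n_individuals = 3, seed = 2))
  pl <- simulate_plates(pop, plate_layout(), seed = 5)
  write_plateset(pl, file.path(dir, "p.csv"))
  pl2 <- read_plateset(file.path(dir, "p.csv"))
  expect_equal(pl2$raw_luminescence, pl$raw_luminescence)
  expect_equal(pl2$well_role, pl$well_role)

  g <- simulate_genotypes(genotype_sim_spec(n_snps = 12, seed = 3), pop)
  write_genotypes_tsv(g, file.path(dir, "g.tsv"))
  expect_equal(read_genotypes_tsv(file.path(dir, "g.tsv")), g$genotypes,
               ignore_attr = TRUE)

  rec <- build_mixture_recipe(c(a = 3, b = 7), "AC50", "high")
  write_mixture_recipe(rec, file.path(dir, "r.tsv"))
  expect_equal(read_mixture_recipe(file.path(dir, "r.tsv"))$mass_fraction,
               rec$mass_fraction)
})

test_that("the minimal VCF writer round-trips through a VCF parser", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  pop <- simulate_population(population_spec(n_individuals = 5, seed = 2))
  g <- simulate_genotypes(genotype_sim_spec(n_snps = 8, seed = 3), pop)
  write_genotypes_vcf(g, file.path(dir, "g.vcf"))
  G2 <- read_genotypes_vcf(file.path(dir, "g.vcf"))
  expect_equal(unname(G2[rownames(g$genotypes), colnames(g$genotypes)]),
               unname(g$genotypes))
})
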