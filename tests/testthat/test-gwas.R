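test_that("MAF filtering applies the >= 0.05 rule on minor-allele coding", {
  G <- cbind(
    mono = rep(0L, 146),                                  # MAF 0 -> removed
    rare = c(rep(1L, 14), rep(0L, 132)),                  # 14/292 < 0.05 -> removed
    edge = c(rep(1L, 15), rep(0L, 131)),                  # hets only: 15/292 ~ 0.0514
    common = rep_len(c(0L, 1L, 2L), 146),
    flipme = rep_len(c(2L, 2L, 1L), 146)                  # major-allele coded
  )
  flt <- filter_maf(G)
  expect_equal(colnames(flt$genotypes), c("edge", "common", "flipme"))
  expect_true(all(flt$maf <= 0.5))
  expect_true("flipme" %in% flt$flipped)
  # boundary: MAF exactly 0.05 is retained
  G2 <- cbind(exact = c(rep(1L, 10), rep(0L, 90)))
  expect_equal(ncol(filter_maf(G2, threshold = 0.05)$genotypes), 1)
  expect_error(filter_maf(cbind(rep(0L, 50))), "removed all")
})

test_that("genotype PCs are relabeling-invariant and handle k = 0", {
  G <- make_genotypes(60, runif(100, 0.1, 0.5), seed = 3)
  pcs <- genotype_pcs(G, k = 3)
  perm <- sample(nrow(G))
  pcs_perm <- genotype_pcs(G[perm, ], k = 3)
  expect_equal(pcs_perm, pcs[perm, ], tolerance = 1e-8)
  expect_equal(ncol(genotype_pcs(G, k = 0)), 0)
  Gz <- cbind(G, zero = rep(1L, 60))
  expect_error(genotype_pcs(Gz, 2), "zero-variance")
})

test_that("association matches the per-SNP least-squares oracle", {
  set.seed(13)
  G <- make_genotypes(80, runif(50, 0.1, 0.5), seed = 13)
  sex <- rep_len(c(0, 1), 80)
  pcs <- genotype_pcs(G, 2)
  y <- rnorm(80) + 0.6 * G[, 7]
  tab <- snp_association(y, G, sex = sex, pcs = pcs)
  for (j in c(1, 7, 25)) {
    fit <- lm(y ~ G[, j] + sex + pcs)
    co <- summary(fit)$coefficients[2, ]
    expect_equal(tab$beta[j], unname(co[1]))
    expect_equal(tab$se[j], unname(co[2]))
    expect_equal(tab$t[j], unname(co[3]))
    expect_equal(tab$p[j], unname(co[4]))
  }
  expect_lt(tab$p[7], 1e-4)
})

test_that("missing genotypes drop samples per SNP, matching complete-case OLS", {
  set.seed(14)
  G <- make_genotypes(80, runif(20, 0.2, 0.5), seed = 14)
  y <- rnorm(80)
  sex <- rep_len(c(0, 1), 80)
  Gm <- G; Gm[c(3, 10, 44), 5] <- NA
  tab <- snp_association(y, Gm, sex = sex)
  ok <- !is.na(Gm[, 5])
  co <- summary(lm(y[ok] ~ Gm[ok, 5] + sex[ok]))$coefficients[2, ]
  expect_equal(tab$t[5], unname(co[3]))
  expect_equal(tab$p[5], unname(co[4]))
})

test_that("degenerate SNPs are flagged untestable, not fatal", {
  G <- make_genotypes(50, runif(10, 0.2, 0.5), seed = 15)
  G[, 4] <- 1L   # constant
  tab <- snp_association(rnorm(50), G, sex = rep_len(c(0, 1), 50))
  expect_false(tab$testable[4])
  expect_true(is.na(tab$p[4]))
  expect_true(all(tab$testable[-4]))
})

test_that("association statistics are equivariant to phenotype location/scale", {
  set.seed(16)
  G <- make_genotypes(60, runif(30, 0.2, 0.5), seed = 16)
  y <- rnorm(60)
  t1 <- snp_association(y, G)
  t2 <- snp_association(5 * y + 3, G)
  expect_equal(t2$beta, 5 * t1$beta)
  expect_equal(t2$se, 5 * t1$se)
  expect_equal(t2$t, t1$t)
  expect_equal(t2$p, t1$p)
})

test_that("null associations are calibrated", {
  set.seed(17)
  G <- make_genotypes(146, runif(2000, 0.05, 0.5), seed = 17)
  y <- rnorm(146)
  tab <- snp_association(y, G, sex = rep_len(c(0, 1), 146),
                         pcs = genotype_pcs(G, 3))
  p <- tab$p[tab$testable]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  # type-I error at alpha = 1e-3 within 3 binomial SEs of nominal
  alpha <- 1e-3
  expect_lt(abs(mean(p < alpha) - alpha), 3 * sqrt(alpha * (1 - alpha) / length(p)))
  gl <- genomic_lambda(p)
  expect_gt(gl$lambda, 0.9)
  expect_lt(gl$lambda, 1.1)
  expect_true(gl$acceptable)
})

test_that("genomic control lambda matches its analytic anchors", {
  set.seed(18)
  gl <- genomic_lambda(runif(10000))
  expect_gt(gl$lambda, 0.95)
  expect_lt(gl$lambda, 1.05)
  # all p = 0.5 sit exactly at the null median
  expect_equal(genomic_lambda(rep(0.5, 200))$lambda, 1)
  # doubling the chi-square statistics doubles lambda
  chi <- rchisq(20000, 1)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2)$lambda, 2, tolerance = 0.05)
  expect_error(genomic_lambda(c(rep(0.5, 100), 0)), "\\(0, 1\\]")
  expect_error(genomic_lambda(runif(50)), ">= 100")
})

test_that("the GRM identifies duplicates and centers unrelated pairs at zero", {
  G <- make_genotypes(40, runif(800, 0.1, 0.5), seed = 19)
  G[2, ] <- G[1, ]   # duplicated sample
  A <- grm(G)
  expect_equal(A, t(A))
  expect_equal(A[1, 2], A[1, 1], tolerance = 0.05)
  off <- A[upper.tri(A)][-1]
  expect_lt(abs(mean(off)), 0.05)
  expect_equal(mean(diag(A)), 1, tolerance = 0.15)
  expect_error(grm(cbind(G[, 1:5], rep(0L, 40))), "monomorphic")
})

test_that("MLMA with an identity GRM reduces exactly to OLS", {
  set.seed(20)
  G <- make_genotypes(60, runif(100, 0.1, 0.5), seed = 20)
  y <- rnorm(60) + 0.5 * G[, 3]
  sex <- rep_len(c(0, 1), 60)
  pcs <- genotype_pcs(G, 3)
  ols <- snp_association(y, G, sex = sex, pcs = pcs)
  ml <- mlma_association(y, G, diag(60), sex = sex, pcs = pcs)
  expect_equal(ml$t, ols$t, tolerance = 1e-8)
  expect_error(mlma_association(y[1:5], G[1:5, ], diag(5)), "fewer than 10")
})

test_that("the polygenic random effect corrects structure-driven inflation", {
  pop <- simulate_population(population_spec(n_individuals = 146, seed = 9))
  g <- simulate_genotypes(genotype_sim_spec(n_snps = 1500, group_divergence = 0.15,
                                            seed = 10), pop)
  Gf <- filter_maf(g$genotypes)$genotypes
  set.seed(11)
  u <- rnorm(ncol(Gf), 0, 0.05)
  y <- as.numeric(scale(Gf) %*% u) + rnorm(nrow(Gf)) +
    2 * (g$samples$ancestry_group == "G2")
  ols <- snp_association(y, Gf, sex = g$samples$sex)
  ml <- mlma_association(y, Gf, grm(Gf), sex = g$samples$sex)
  l_ols <- genomic_lambda(ols$p[ols$testable])$lambda
  l_ml <- genomic_lambda(ml$p[ml$testable])$lambda
  expect_gt(l_ols, l_ml)
  expect_true(attr(ml, "reml_converged"))
})

test_that("sample-size-weighted z meta-analysis follows the weight algebra", {
  z <- c(a = 1.5, b = -2, c = 0.3)
  expect_equal(meta_z(list(z), list(106))$z_combined, unname(z))
  two <- meta_z(list(z, z), list(50, 50))
  expect_equal(two$z_combined, unname(z) * sqrt(2))
  opp <- meta_z(list(z, -z), list(50, 50))
  expect_equal(opp$z_combined, rep(0, 3))
  expect_equal(opp$p, rep(1, 3))
  expect_error(meta_z(list(z, z[1:2]), list(50, 50)), "mismatched SNP sets")
})

test_that("regional views slice loci and report cross-substance overlap", {
  tab <- data.frame(chrom = c(1, 1, 1, 2), pos = c(100, 500, 900, 500),
                    snp_id = paste0("s", 1:4), p = c(1e-6, 0.5, 1e-3, 1e-7),
                    stringsAsFactors = FALSE)
  rv <- regional_view(tab, chrom = 1, center = 500, width = 400)
  expect_equal(rv$snp_id, c("s1", "s2", "s3"))
  expect_equal(rv$neglog10_p[1], 6)
  expect_equal(nrow(regional_view(tab, chrom = 3, center = 500, width = 1e6)), 0)
  expect_equal(regional_view(tab, chrom = 2, center = 500, width = 0)$snp_id, "s4")

  # a causal SNP shared by 3 phenotypes shows up in the overlap list
  set.seed(22)
  G <- make_genotypes(146, runif(300, 0.2, 0.5), seed = 22)
  tabs <- lapply(1:3, function(i)
    snp_association(rnorm(146) + 1.2 * G[, 42], G))
  names(tabs) <- paste0("chem", 1:3)
  ov <- overlap_loci(tabs, p_threshold = 1e-5, min_substances = 3)
  expect_true("snp00042" %in% ov$snp_id)
  expect_equal(ov$n_substances[ov$snp_id == "snp00042"], 3)
})
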