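#' Minor-allele-frequency filter
#'
#' Verifies minor-allele coding (columns whose allele frequency exceeds 0.5
#' are recoded as \code{2 - x}) and retains SNPs with MAF at or above the
#' threshold, computed over non-missing calls across all samples.
#'
#' @param G samples x SNPs matrix of 0/1/2 allele counts (NA = missing).
#' @param map optional per-SNP table (row per column of \code{G}); subset
#'   alongside, with a \code{maf} column added.
#' @param threshold minimum MAF (default 0.05; \code{>=} rule).
#' @return A list: \code{genotypes} (filtered, minor-allele coded),
#'   \code{map}, \code{maf} (retained SNPs), \code{flipped} (ids recoded).
#' @export
filter_maf <- function(G, map = NULL, threshold = 0.05) {
  G <- as.matrix(G)
  af <- colMeans(G, na.rm = TRUE) / 2
  flip <- which(af > 0.5)
  if (length(flip)) G[, flip] <- 2 - G[, flip]
  maf <- colMeans(G, na.rm = TRUE) / 2
  keep <- which(maf >= threshold)
  if (!length(keep)) stop("MAF filter removed all SNPs")
  if (!is.null(map)) {
    map <- map[keep, , drop = FALSE]
    map$maf <- unname(maf[keep])
  }
  list(genotypes = G[, keep, drop = FALSE], map = map,
       maf = maf[keep], flipped = colnames(G)[flip])
}

snp_ids_of <- function(G) {
  if (is.null(colnames(G))) sprintf("snp%05d", seq_len(ncol(G))) else colnames(G)
}

impute_mean <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- mu[idx[, 2]]
  G
}

#' Genotype principal components for population-structure adjustment
#'
#' PCs of the column-standardized (mean 0, variance 1) genotype matrix after
#' per-SNP mean imputation of missing calls. Scores are deterministic up to
#' sign; the sign is fixed so that each component's largest-magnitude SNP
#' loading is positive.
#'
#' @param G samples x SNPs allele-count matrix (MAF-filtered).
#' @param k number of components (default 3; 0 gives an empty score block).
#' @return samples x k matrix of PC scores (columns \code{PC1..PCk}).
#' @export
genotype_pcs <- function(G, k = 3) {
  G <- impute_mean(as.matrix(G))
  if (k == 0) {
    return(matrix(numeric(0), nrow = nrow(G), ncol = 0,
                  dimnames = list(rownames(G), NULL)))
  }
  if (nrow(G) < k + 1) stop("need more samples than components")
  sds <- apply(G, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance SNPs reached PCA; apply filter_maf first")
  }
  Z <- scale(G)
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    if (sv$v[which.max(abs(sv$v[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  scores
}

# Vectorized OLS of y on (covariates, one SNP at a time); returns the SNP
# coefficient, its SE, t, and two-sided p per SNP. C must include the
# intercept. Rows must be complete.
assoc_core <- function(y, G, C) {
  n <- length(y)
  Q <- qr.Q(qr(C))
  My <- y - Q %*% crossprod(Q, y)
  MG <- G - Q %*% crossprod(Q, G)
  gtg <- colSums(MG^2)
  gty <- as.numeric(crossprod(MG, My))
  df <- n - ncol(C) - 1
  testable <- gtg > 1e-10 * n & df > 0
  beta <- se <- tstat <- p <- rep(NA_real_, ncol(G))
  beta[testable] <- gty[testable] / gtg[testable]
  rss <- sum(My^2) - beta[testable]^2 * gtg[testable]
  rss <- pmax(rss, 0)
  se[testable] <- sqrt(rss / df / gtg[testable])
  tstat[testable] <- beta[testable] / se[testable]
  p[testable] <- 2 * stats::pt(-abs(tstat[testable]), df = df)
  list(beta = beta, se = se, t = tstat, p = p, df = df, testable = testable)
}

hit_class <- function(p, suggestive = 1e-5, significant = 5e-8) {
  cls <- rep("none", length(p))
  cls[!is.na(p) & p < suggestive] <- "suggestive"
  cls[!is.na(p) & p < significant] <- "significant"
  cls[is.na(p)] <- NA_character_
  cls
}

#' Single-variant association with covariate adjustment
#'
#' Ordinary least squares of the phenotype on (intercept, allele count, sex,
#' genotype PCs) per SNP; the association test is the two-sided t-test on the
#' allele-count coefficient. Samples with a missing genotype are dropped for
#' that SNP. SNPs whose allele count is collinear with the covariates (e.g.
#' zero variance) are flagged untestable rather than raising an error.
#'
#' @param phenotype per-sample phenotype (finite for all samples), e.g.
#'   \code{log10} posterior-median EC10.
#' @param G samples x SNPs allele-count matrix (MAF-filtered).
#' @param sex 0/1 covariate, or \code{NULL}.
#' @param pcs samples x k PC score matrix (see \code{\link{genotype_pcs}}),
#'   or \code{NULL}.
#' @param map optional per-SNP table (chrom, pos, maf) carried into the output.
#' @param suggestive,significant hit-class p-value thresholds (defaults
#'   \code{1e-5} and \code{5e-8}).
#' @return A \code{GWASTable} data frame: per SNP \code{beta}, \code{se},
#'   \code{t}, \code{p}, \code{hit_class}, \code{testable}.
#' @export
snp_association <- function(phenotype, G, sex = NULL, pcs = NULL, map = NULL,
                            suggestive = 1e-5, significant = 5e-8) {
  G <- as.matrix(G)
  if (any(!is.finite(phenotype))) stop("phenotype must be finite for all samples")
  if (length(phenotype) != nrow(G)) stop("phenotype length must match samples")
  C <- cbind(intercept = rep(1, nrow(G)), sex = sex, pcs)
  if (qr(C)$rank < ncol(C)) stop("covariate design matrix is rank deficient")

  res <- assoc_core(phenotype, impute_mean(G), C)
  # exact per-SNP handling of missing genotypes: refit dropping those samples
  miss <- which(colSums(is.na(G)) > 0)
  for (j in miss) {
    ok <- !is.na(G[, j])
    if (sum(ok) <= ncol(C) + 1) {
      res$beta[j] <- res$se[j] <- res$t[j] <- res$p[j] <- NA_real_
      res$testable[j] <- FALSE
      next
    }
    rj <- assoc_core(phenotype[ok], G[ok, j, drop = FALSE], C[ok, , drop = FALSE])
    res$beta[j] <- rj$beta; res$se[j] <- rj$se
    res$t[j] <- rj$t; res$p[j] <- rj$p; res$testable[j] <- rj$testable
  }
  out <- data.frame(snp_id = snp_ids_of(G), beta = res$beta, se = res$se,
                    t = res$t, p = res$p,
                    hit_class = hit_class(res$p, suggestive, significant),
                    testable = res$testable, stringsAsFactors = FALSE)
  if (!is.null(map)) out <- cbind(map[, setdiff(names(map), "snp_id"), drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' Genomic-control inflation diagnostics
#'
#' Converts p-values to 1-df chi-square quantiles and reports
#' \code{lambda = median(chisq) / 0.4549} (the null median), together with
#' observed/expected QQ points on the \code{-log10} scale. Lambda within
#' [0.9, 1.1] is flagged acceptable.
#'
#' @param pvals association p-values in (0, 1]; at least 100.
#' @param acceptable_range lambda range considered well calibrated.
#' @return A list: \code{lambda}, \code{acceptable}, \code{qq} (data frame of
#'   expected and observed \code{-log10 p}).
#' @export
genomic_lambda <- function(pvals, acceptable_range = c(0.9, 1.1)) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) < 100) stop("need >= 100 p-values for a stable lambda")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  qq <- data.frame(expected = -log10(stats::ppoints(length(pvals))),
                   observed = -log10(sort(pvals)))
  list(lambda = lambda,
       acceptable = lambda >= acceptable_range[1] & lambda <= acceptable_range[2],
       qq = qq)
}

#' Genetic relationship matrix
#'
#' Standardized-genotype GRM:
#' \deqn{A_{jk} = \frac{1}{M} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' over the M MAF-filtered SNPs, with missing calls mean-imputed. Under
#' Hardy-Weinberg the diagonal averages about 1.
#'
#' @param G samples x SNPs allele-count matrix (MAF-filtered).
#' @return samples x samples symmetric GRM.
#' @export
grm <- function(G) {
  G <- impute_mean(as.matrix(G))
  p <- colMeans(G) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNPs reached the GRM; apply filter_maf first")
  }
  Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  tcrossprod(Z) / ncol(G)
}

#' Mixed-linear-model association (MLMA)
#'
#' Per-SNP association with a polygenic random effect whose covariance is
#' proportional to the GRM: \code{y = C a + g b + u + e}, \code{u ~ N(0,
#' vg A)}, \code{e ~ N(0, ve I)}. The variance components are estimated once
#' by REML on the covariates-only model via the eigendecomposition of the
#' GRM, then every SNP is tested by generalized least squares with the
#' variance structure fixed. With \code{A = I} the weights are constant and
#' the test reduces exactly to OLS.
#'
#' @param phenotype per-sample phenotype.
#' @param G samples x SNPs allele-count matrix.
#' @param A genetic relationship matrix from \code{\link{grm}} (positive
#'   semi-definite).
#' @param sex,pcs covariates as in \code{\link{snp_association}}.
#' @param map optional per-SNP table carried into the output.
#' @param suggestive,significant hit-class thresholds.
#' @return A \code{GWASTable} data frame (as \code{\link{snp_association}})
#'   with attributes \code{h2} (estimated heritability ratio
#'   \code{vg/(vg+ve)}) and \code{reml_converged}.
#' @export
mlma_association <- function(phenotype, G, A, sex = NULL, pcs = NULL,
                             map = NULL, suggestive = 1e-5, significant = 5e-8) {
  G <- impute_mean(as.matrix(G))
  n <- length(phenotype)
  if (n < 10) stop("refusing mixed-model association with fewer than 10 samples")
  C <- cbind(intercept = rep(1, n), sex = sex, pcs)
  eig <- eigen(A, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- as.numeric(crossprod(U, phenotype))
  Cs <- crossprod(U, C)
  p <- ncol(C)

  # profile REML over the variance ratio delta = ve/vg
  reml_neg <- function(log_delta) {
    d <- lam + exp(log_delta)
    w <- 1 / d
    XtWX <- crossprod(Cs, Cs * w)
    b <- solve(XtWX, crossprod(Cs, ys * w))
    r <- ys - Cs %*% b
    s2 <- sum(w * r^2) / (n - p)
    0.5 * ((n - p) * log(s2) + sum(log(d)) + determinant(XtWX)$modulus)
  }
  opt <- stats::optimize(reml_neg, interval = c(-12, 12))
  reml_converged <- opt$minimum > -11.9 && opt$minimum < 11.9
  delta <- exp(opt$minimum)
  h2 <- mean(lam) / (mean(lam) + delta)

  w <- 1 / sqrt(lam + delta)
  yw <- ys * w
  Cw <- Cs * w
  Gw <- crossprod(U, G) * w
  res <- assoc_core(yw, Gw, Cw)
  out <- data.frame(snp_id = snp_ids_of(G), beta = res$beta, se = res$se,
                    t = res$t, p = res$p,
                    hit_class = hit_class(res$p, suggestive, significant),
                    testable = res$testable, stringsAsFactors = FALSE)
  if (!is.null(map)) out <- cbind(map[, setdiff(names(map), "snp_id"), drop = FALSE], out)
  rownames(out) <- NULL
  attr(out, "h2") <- h2
  attr(out, "reml_converged") <- reml_converged
  out
}

#' Sample-size-weighted z-score meta-analysis across ancestry groups
#'
#' Combines per-group association z-scores with weights
#' \code{w_g = sqrt(n_g) / sqrt(sum(n))} (so the weights' squares sum to 1)
#' and converts the combined z to a two-sided normal p-value. SNP sets must
#' align across groups with a consistent effect-allele orientation.
#'
#' @param z_list list of named numeric z-score vectors, one per group.
#' @param n_list corresponding group sample sizes.
#' @return Data frame: \code{snp_id}, \code{z_combined}, \code{p}.
#' @export
meta_z <- function(z_list, n_list) {
  if (length(z_list) != length(n_list)) stop("'z_list' and 'n_list' must align")
  ids <- names(z_list[[1]])
  for (g in seq_along(z_list)) {
    missing <- setdiff(ids, names(z_list[[g]]))
    extra <- setdiff(names(z_list[[g]]), ids)
    if (length(missing) || length(extra)) {
      stop("mismatched SNP sets across groups; missing: ",
           paste(utils::head(c(missing, extra), 10), collapse = ", "))
    }
  }
  nv <- unlist(n_list)
  w <- sqrt(nv) / sqrt(sum(nv))
  zc <- Reduce(`+`, Map(function(z, wg) wg * z[ids], z_list, w))
  data.frame(snp_id = ids, z_combined = unname(zc),
             p = 2 * stats::pnorm(-abs(unname(zc))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regional slice of a GWAS table for locus plots
#'
#' @param gwas_table a GWASTable with \code{chrom} and \code{pos} columns.
#' @param chrom chromosome.
#' @param center center position (bp).
#' @param width half-width of the window (bp); the window is
#'   \code{[center - width, center + width]}.
#' @return The SNPs in the window ordered by position, with a
#'   \code{neglog10_p} column. Empty windows give an empty table.
#' @export
regional_view <- function(gwas_table, chrom, center, width) {
  if (!all(c("chrom", "pos") %in% names(gwas_table))) {
    stop("GWAS table needs 'chrom' and 'pos' columns for regional views")
  }
  sl <- gwas_table[gwas_table$chrom == chrom &
                     gwas_table$pos >= center - width &
                     gwas_table$pos <= center + width, , drop = FALSE]
  sl <- sl[order(sl$pos), , drop = FALSE]
  sl$neglog10_p <- -log10(sl$p)
  rownames(sl) <- NULL
  sl
}

#' Loci shared across substances
#'
#' Lists SNPs reaching the suggestive threshold in at least \code{min_substances}
#' of the supplied per-substance GWAS tables, the cross-substance overlap
#' used to accrue evidence for grouping mixture constituents.
#'
#' @param tables named list of GWASTable data frames.
#' @param p_threshold suggestive threshold (default \code{1e-5}).
#' @param min_substances minimum number of substances sharing the SNP.
#' @return Data frame: \code{snp_id}, \code{n_substances}, \code{substances}.
#' @export
overlap_loci <- function(tables, p_threshold = 1e-5, min_substances = 2) {
  hits <- lapply(tables, function(t) t$snp_id[!is.na(t$p) & t$p < p_threshold])
  all_snps <- unique(unlist(hits))
  if (!length(all_snps)) {
    return(data.frame(snp_id = character(0), n_substances = integer(0),
                      substances = character(0), stringsAsFactors = FALSE))
  }
  counts <- vapply(all_snps, function(s) sum(vapply(hits, function(h) s %in% h, logical(1))),
                   integer(1))
  who <- vapply(all_snps, function(s) {
    paste(names(hits)[vapply(hits, function(h) s %in% h, logical(1))], collapse = ",")
  }, character(1))
  out <- data.frame(snp_id = all_snps, n_substances = counts, substances = who,
                    stringsAsFactors = FALSE)
  out <- out[out$n_substances >= min_substances, , drop = FALSE]
  out[order(-out$n_substances), , drop = FALSE]
}
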