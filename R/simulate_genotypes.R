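#' Specification for simulated genotypes
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium within ancestry
#' groups. Group-level allele frequencies diverge from a shared ancestral
#' frequency via a Balding-Nichols draw with a single Fst-like parameter, so a
#' nonzero \code{group_divergence} yields population structure that genotype
#' principal components can recover. Optional causal SNPs shift each
#' individual's \code{ln EC50} additively by \code{beta} per copy of the
#' allele, planting a mappable toxicodynamic variant.
#'
#' @param n_snps number of SNPs.
#' @param maf_range bounds of the uniform ancestral allele-frequency
#'   distribution; frequencies must lie in (0, 0.5].
#' @param causal_snps \code{NULL} or a data frame with columns \code{snp}
#'   (index) and \code{beta} (effect on \code{ln EC50} per allele copy).
#' @param n_ancestry_groups number of ancestry groups.
#' @param group_proportions relative group sizes (recycled/normalized);
#'   default equal.
#' @param group_divergence Fst-like drift parameter in [0, 1).
#' @param seed integer seed.
#' @return An object of class \code{genotype_sim_spec}.
#' @export
genotype_sim_spec <- function(n_snps = 1000,
                              maf_range = c(0.05, 0.5),
                              causal_snps = NULL,
                              n_ancestry_groups = 2,
                              group_proportions = NULL,
                              group_divergence = 0.05,
                              seed = 1L) {
  if (n_snps < 1) stop("invalid 'n_snps'")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("invalid 'maf_range': allele frequencies must lie in (0, 0.5]")
  }
  if (!is.null(causal_snps)) {
    if (!all(c("snp", "beta") %in% names(causal_snps))) {
      stop("'causal_snps' needs columns snp, beta")
    }
    if (any(causal_snps$snp < 1 | causal_snps$snp > n_snps)) {
      stop("invalid 'causal_snps': indices must be in 1..n_snps")
    }
  }
  if (group_divergence < 0 || group_divergence >= 1) stop("invalid 'group_divergence'")
  if (is.null(group_proportions)) group_proportions <- rep(1, n_ancestry_groups)
  structure(list(
    n_snps = as.integer(n_snps), maf_range = maf_range,
    causal_snps = causal_snps,
    n_ancestry_groups = as.integer(n_ancestry_groups),
    group_proportions = group_proportions / sum(group_proportions),
    group_divergence = group_divergence,
    seed = as.integer(seed)
  ), class = "genotype_sim_spec")
}

#' Simulate genotypes for a donor population
#'
#' Draws a samples-by-SNPs matrix of minor-allele counts (0/1/2) and applies
#' any planted causal effects to the population's \code{ln EC50}.
#'
#' @param gspec a \code{\link{genotype_sim_spec}}.
#' @param population population table from \code{\link{simulate_population}}.
#' @return A list with elements \code{genotypes} (matrix, rownames =
#'   individual ids, colnames = SNP ids), \code{map} (data frame: snp_id,
#'   chrom, pos, ancestral_freq, causal beta), \code{samples} (data frame:
#'   individual_id, sex, ancestry_group), and \code{population} (the input
#'   table with causal shifts applied to \code{ec50}/\code{log_ec50}).
#' @export
simulate_genotypes <- function(gspec, population) {
  stopifnot(inherits(gspec, "genotype_sim_spec"))
  nn <- nrow(population)
  ng <- gspec$n_ancestry_groups
  sizes <- diff(round(cumsum(c(0, gspec$group_proportions)) * nn))
  if (sum(sizes) != nn) sizes[ng] <- sizes[ng] + (nn - sum(sizes))
  group <- rep(sprintf("G%d", seq_len(ng)), times = sizes)

  fst <- gspec$group_divergence
  with_seed(gspec$seed, {
    p_anc <- stats::runif(gspec$n_snps, gspec$maf_range[1], gspec$maf_range[2])
    # Balding-Nichols per-group frequency draw
    pg <- matrix(p_anc, nrow = ng, ncol = gspec$n_snps, byrow = TRUE)
    if (fst > 0) {
      a <- p_anc * (1 - fst) / fst
      b <- (1 - p_anc) * (1 - fst) / fst
      for (g in seq_len(ng)) pg[g, ] <- stats::rbeta(gspec$n_snps, a, b)
    }
    G <- matrix(0L, nrow = nn, ncol = gspec$n_snps)
    for (g in seq_len(ng)) {
      rows <- which(group == sprintf("G%d", g))
      G[rows, ] <- matrix(
        stats::rbinom(length(rows) * gspec$n_snps, 2,
                      rep(pg[g, ], each = length(rows))),
        nrow = length(rows))
    }
  })
  rownames(G) <- population$individual_id
  snp_ids <- sprintf("snp%05d", seq_len(gspec$n_snps))
  colnames(G) <- snp_ids
  chrom <- rep(seq_len(22), length.out = gspec$n_snps)
  pos <- integer(gspec$n_snps)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 1e6 + seq_along(idx) * 10000L
  }
  map <- data.frame(snp_id = snp_ids, chrom = chrom, pos = pos,
                    ancestral_freq = p_anc, beta_true = 0,
                    stringsAsFactors = FALSE)

  pop <- population
  if (!is.null(gspec$causal_snps)) {
    for (j in seq_len(nrow(gspec$causal_snps))) {
      s <- gspec$causal_snps$snp[j]
      if (stats::var(G[, s]) == 0) {
        stop("causal effect planted on monomorphic SNP ", snp_ids[s])
      }
      map$beta_true[s] <- gspec$causal_snps$beta[j]
      pop$log_ec50 <- pop$log_ec50 + gspec$causal_snps$beta[j] * G[, s]
    }
    pop$ec50 <- exp(pop$log_ec50)
  }
  samples <- data.frame(individual_id = population$individual_id,
                        sex = population$sex,
                        ancestry_group = group,
                        stringsAsFactors = FALSE)
  list(genotypes = G, map = map, samples = samples, population = pop)
}

#' Write genotypes as a samples-by-SNPs TSV of 0/1/2 allele counts
#' @param geno result of \code{\link{simulate_genotypes}} or a genotype matrix.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(geno, path) {
  G <- if (is.list(geno)) geno$genotypes else geno
  df <- data.frame(individual_id = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df[[1]]
  storage.mode(G) <- "integer"
  G
}

#' Write sample metadata (sex, ancestry group) as TSV
#' @param samples data frame with individual_id, sex, ancestry_group.
#' @param path output file.
#' @export
write_sample_info_tsv <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal GT-only VCF
#'
#' Unphased diploid GT records with placeholder REF/ALT alleles; allele
#' counts are recoverable as the number of ALT alleles per genotype.
#'
#' @param geno result of \code{\link{simulate_genotypes}} (needs \code{map}).
#' @param path output file (plain text, uncompressed).
#' @export
write_genotypes_vcf <- function(geno, path) {
  G <- geno$genotypes; map <- geno$map
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popvitro_synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  body <- vapply(seq_len(ncol(G)), function(j) {
    paste(c(map$chrom[j], map$pos[j], map$snp_id[j], "A", "G", ".", "PASS",
            ".", "GT", gt[G[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a samples-by-SNPs allele-count matrix
#'
#' Parses GT fields via the vcfR package and counts ALT alleles per call.
#'
#' @param path VCF file.
#' @return Integer matrix (samples x SNPs) of ALT allele counts, with a
#'   \code{map} attribute carrying chrom/pos/id.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  alleles <- strsplit(gsub("\\|", "/", gt), "/")
  counts[] <- vapply(alleles, function(a) {
    if (anyNA(a) || any(a == ".")) NA_integer_ else sum(a != "0")
  }, integer(1))
  G <- t(counts)
  attr(G, "map") <- data.frame(snp_id = rownames(gt),
                               chrom = as.integer(v@fix[, "CHROM"]),
                               pos = as.integer(v@fix[, "POS"]),
                               stringsAsFactors = FALSE)
  G
}
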