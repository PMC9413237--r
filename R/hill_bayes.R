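#' MCMC configuration for the hierarchical Hill fit
#'
#' Defaults mirror the screening pipeline's settings: four chains of 4000
#' iterations each (first half warm-up, discarded), convergence declared when
#' every monitored parameter has potential scale reduction factor
#' \code{Rhat <= 1.2}, and chain length doubled on failure up to 16,000
#' iterations.
#'
#' @param n_chains number of chains (default 4).
#' @param initial_iterations total iterations per chain at the first attempt
#'   (default 4000; half are warm-up).
#' @param rhat_threshold convergence gate (default 1.2).
#' @param max_iterations ceiling for the doubling rule (default 16000).
#' @param seed integer seed; chains get derived seeds.
#' @param priors prior scales, see Details.
#'
#' @details Hyperprior defaults are weakly informative on the natural-log
#' scale: population means \code{ln y0 ~ N(0, 2)} (baseline near 1),
#' \code{ln EC50 ~ N(ln 30, 3)} (covering the 0.01-100 uM design decades),
#' \code{ln(n - 1) ~ N(0, 1)}; half-Normal(1) for all population SDs and
#' half-Normal(0.5) for the residual t scale \code{sigma}.
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(n_chains = 4, initial_iterations = 4000,
                       rhat_threshold = 1.2, max_iterations = 16000,
                       seed = 1L,
                       priors = list(mu_ly0 = c(0, 2),
                                     mu_lx0 = c(log(30), 3),
                                     mu_lz = c(0, 1),
                                     sd_scale = 1,
                                     sigma_scale = 0.5)) {
  if (max_iterations < initial_iterations) {
    stop("'max_iterations' must be >= 'initial_iterations'")
  }
  if (rhat_threshold <= 1) stop("'rhat_threshold' must be > 1")
  if (n_chains < 2) stop("need >= 2 chains for convergence diagnostics")
  structure(list(n_chains = as.integer(n_chains),
                 initial_iterations = as.integer(initial_iterations),
                 rhat_threshold = rhat_threshold,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), priors = priors),
            class = "fit_config")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance comparison: with \code{m} chains of
#' \code{n} retained draws, \code{W} the mean within-chain variance and
#' \code{B/n} the variance of the chain means,
#' \code{Rhat = sqrt(((n-1)/n * W + B/n) / W)}.
#'
#' @param chains a matrix with one column per chain (rows are retained
#'   draws), or a list of equal-length numeric vectors.
#' @return The potential scale reduction factor.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2 || nrow(chains) < 2) {
    stop("need >= 2 chains with >= 2 retained draws each")
  }
  n <- nrow(chains)
  W <- mean(apply(chains, 2, stats::var))
  if (!is.finite(W) || W == 0) {
    stop("zero within-chain variance in all chains: Rhat undefined")
  }
  B_over_n <- stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# JAGS model for the hierarchical random-effects downward Hill model.
# Individual parameters are normal random effects on the natural-log scale;
# the Hill coefficient uses n = 1 + exp(z) so n >= 1 is guaranteed.
# Residuals are scaled Student-t with nu degrees of freedom.
hill_model_string <- function(priors, nu = 5) {
  sprintf("
model {
  for (j in 1:N) {
    mu[j] <- y0[ind[j]] / (1 + pow(x[j] / x0[ind[j]], n[ind[j]]))
    y[j] ~ dt(mu[j], tau, %g)
  }
  for (i in 1:I) {
    ly0[i] ~ dnorm(mu_ly0, prec_ly0)
    lx0[i] ~ dnorm(mu_lx0, prec_lx0)
    lz[i]  ~ dnorm(mu_lz,  prec_lz)
    y0[i] <- exp(ly0[i])
    x0[i] <- exp(lx0[i])
    n[i]  <- 1 + exp(lz[i])
  }
  mu_ly0 ~ dnorm(%g, %g)
  mu_lx0 ~ dnorm(%g, %g)
  mu_lz  ~ dnorm(%g, %g)
  sd_ly0 ~ dnorm(0, %g) T(1.0E-6,)
  sd_lx0 ~ dnorm(0, %g) T(1.0E-6,)
  sd_lz  ~ dnorm(0, %g) T(1.0E-6,)
  sigma  ~ dnorm(0, %g) T(1.0E-6,)
  prec_ly0 <- 1 / (sd_ly0 * sd_ly0)
  prec_lx0 <- 1 / (sd_lx0 * sd_lx0)
  prec_lz  <- 1 / (sd_lz * sd_lz)
  tau <- 1 / (sigma * sigma)
}", nu,
    priors$mu_ly0[1], 1 / priors$mu_ly0[2]^2,
    priors$mu_lx0[1], 1 / priors$mu_lx0[2]^2,
    priors$mu_lz[1], 1 / priors$mu_lz[2]^2,
    1 / priors$sd_scale^2, 1 / priors$sd_scale^2, 1 / priors$sd_scale^2,
    1 / priors$sigma_scale^2)
}

#' Fit the hierarchical Bayesian Hill model for one test substance
#'
#' Samples the joint posterior of every individual's Hill parameters
#' (\code{y0}, \code{ec50}, \code{n}), the population hyperparameters (mean
#' and SD of \code{ln y0}, \code{ln EC50}, \code{ln(n-1)}), and the residual
#' t scale \code{sigma}, given normalized concentration-response data for a
#' panel of cell lines. Wells from replicate plates enter the likelihood as
#' independent observations; vehicle wells (concentration 0) are excluded
#' (they define the normalization, not the substance response). The first
#' half of each chain is discarded as warm-up; if any monitored parameter has
#' \code{Rhat} above the threshold the chain length is doubled and the model
#' refit, up to \code{max_iterations}, after which the fit is flagged
#' non-converged.
#'
#' @param data long-format dose-response data for one substance:
#'   columns \code{cell_line_id}, \code{concentration_uM},
#'   \code{normalized_response} (see \code{\link{dose_response_dataset}}).
#' @param config a \code{\link{fit_config}}.
#' @param nu Student-t degrees of freedom for the residual error (default 5).
#' @param substance label stored with the fit.
#' @param quiet suppress JAGS progress output.
#' @return An object of class \code{hill_fit}: posterior draw matrices
#'   (\code{draws$y0}, \code{draws$ec50}, \code{draws$n}, each total draws x
#'   individuals; \code{draws$hyper} for hyperparameters and sigma), the
#'   per-parameter \code{rhat} table, \code{iterations} actually used per
#'   chain, and a \code{converged} flag.
#' @export
fit_hill_population <- function(data, config = fit_config(), nu = 5,
                                substance = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "fit_config"))
  req <- c("cell_line_id", "concentration_uM", "normalized_response")
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "))
  }
  if (is.null(substance)) {
    substance <- if ("chemical_id" %in% names(data)) data$chemical_id[1] else "substance"
  }
  d <- data[data$concentration_uM > 0 & is.finite(data$normalized_response), ]
  ids <- sort(unique(d$cell_line_id))
  if (length(ids) < 2) stop("need >= 2 individuals to fit the population model")
  nconc <- tapply(d$concentration_uM, d$cell_line_id, function(z) length(unique(z)))
  if (any(nconc < 3)) stop("every individual needs >= 3 tested concentrations")

  jdata <- list(N = nrow(d), I = length(ids), y = d$normalized_response,
                x = d$concentration_uM, ind = match(d$cell_line_id, ids))
  model_txt <- hill_model_string(config$priors, nu = nu)
  monitors <- c("mu_ly0", "mu_lx0", "mu_lz", "sd_ly0", "sd_lx0", "sd_lz",
                "sigma", "ly0", "lx0", "lz")
  inits <- lapply(seq_len(config$n_chains), function(k) {
    list(ly0 = rep(0, length(ids)), lx0 = rep(log(30), length(ids)),
         lz = rep(0, length(ids)),
         mu_ly0 = 0, mu_lx0 = log(30), mu_lz = 0,
         sd_ly0 = 0.5, sd_lx0 = 0.5, sd_lz = 0.5, sigma = 0.1,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.numeric(config$seed) * 1000 + k) %% 2147483647)
  })

  iters <- config$initial_iterations
  history <- integer(0)
  repeat {
    warmup <- iters %/% 2L
    adapt <- min(1000L, warmup)
    jm <- rjags::jags.model(textConnection(model_txt), data = jdata,
                            inits = inits, n.chains = config$n_chains,
                            n.adapt = adapt, quiet = quiet)
    if (warmup > adapt) {
      stats::update(jm, n.iter = warmup - adapt, progress.bar = "none")
    }
    samples <- rjags::coda.samples(jm, variable.names = monitors,
                                   n.iter = iters - warmup,
                                   progress.bar = "none")
    history <- c(history, iters)
    param_names <- colnames(samples[[1]])
    rh <- vapply(param_names, function(p) {
      tryCatch(rhat(sapply(samples, function(ch) as.numeric(ch[, p]))),
               error = function(e) Inf)
    }, numeric(1))
    converged <- all(rh <= config$rhat_threshold)
    if (converged || iters >= config$max_iterations) break
    iters <- min(2L * iters, config$max_iterations)
  }

  draws_mat <- do.call(rbind, lapply(samples, as.matrix))
  col_of <- function(stub) {
    cols <- sprintf("%s[%d]", stub, seq_along(ids))
    draws_mat[, cols, drop = FALSE]
  }
  draws <- list(
    y0 = exp(col_of("ly0")),
    ec50 = exp(col_of("lx0")),
    n = 1 + exp(col_of("lz")),
    hyper = draws_mat[, c("mu_ly0", "mu_lx0", "mu_lz",
                          "sd_ly0", "sd_lx0", "sd_lz", "sigma"), drop = FALSE]
  )
  colnames(draws$y0) <- colnames(draws$ec50) <- colnames(draws$n) <- ids

  structure(list(
    substance = substance,
    individuals = ids,
    draws = draws,
    samples = samples,
    rhat = data.frame(parameter = param_names, rhat = unname(rh),
                      stringsAsFactors = FALSE),
    iterations = iters,
    iteration_history = history,
    converged = converged,
    config = config,
    nu = nu
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hierarchical Hill fit:", x$substance, "\n")
  cat(sprintf("  %d individuals, %d chains x %d iterations (half warm-up)\n",
              length(x$individuals), x$config$n_chains, x$iterations))
  cat(sprintf("  max Rhat %.3f (%s)\n", max(x$rhat$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Posterior summaries of individual-level Hill parameters
#'
#' @param fit a \code{hill_fit}.
#' @param probs quantiles reported alongside the median.
#' @return Data frame per individual: median and quantiles of \code{y0},
#'   \code{ec50}, \code{n}, and the derived \code{ec10}.
#' @export
hill_fit_summary <- function(fit, probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "hill_fit"))
  ec10 <- ec10_from_params(fit$draws$ec50, fit$draws$n)
  qs <- function(m) t(apply(m, 2, stats::quantile, probs = c(0.5, probs)))
  blocks <- lapply(list(y0 = fit$draws$y0, ec50 = fit$draws$ec50,
                        n = fit$draws$n, ec10 = ec10), qs)
  out <- data.frame(substance = fit$substance, individual_id = fit$individuals,
                    stringsAsFactors = FALSE)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    colnames(b) <- paste0(nm, c("_median", sprintf("_q%g", 100 * probs)))
    out <- cbind(out, as.data.frame(b))
  }
  rownames(out) <- NULL
  out
}

#' Write the convergence report of a fit as TSV
#' @param fit a \code{hill_fit}.
#' @param path output file.
#' @export
write_convergence_report <- function(fit, path) {
  rep <- cbind(fit$rhat,
               iterations = fit$iterations,
               converged = fit$converged)
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
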