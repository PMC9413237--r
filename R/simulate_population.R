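#' Specification of a simulated donor population
#'
#' Defines the hyperparameters of the lognormal random-effects structure the
#' downstream hierarchical model assumes: each individual's baseline
#' \code{y0}, EC50, and Hill-coefficient shift \code{n - 1} are lognormal
#' around population means. The Hill coefficient is parameterized as
#' \code{n = 1 + exp(z)} with \code{z} normal, so \code{n >= 1} always holds.
#'
#' @param n_individuals number of donor cell lines (>= 2).
#' @param mu_log_ec50,sd_log_ec50 mean and SD of \code{ln EC50} (natural-log uM).
#' @param mu_log_y0,sd_log_y0 mean and SD of \code{ln y0} (baseline ~ 1.0).
#' @param mu_log_nshift,sd_log_nshift mean and SD of \code{ln(n - 1)}.
#' @param error_scale scale of the Student-t measurement noise applied to
#'   simulated responses (response-fraction units).
#' @param error_df degrees of freedom of the t noise (default 5).
#' @param seed integer seed; identical specs produce identical populations.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(n_individuals = 146,
                            mu_log_ec50 = log(10), sd_log_ec50 = 0.5,
                            mu_log_y0 = 0, sd_log_y0 = 0.05,
                            mu_log_nshift = 0, sd_log_nshift = 0.5,
                            error_scale = 0.05, error_df = 5,
                            seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 2) {
    stop("invalid 'n_individuals': need at least 2 individuals")
  }
  for (f in c("sd_log_ec50", "sd_log_y0", "sd_log_nshift")) {
    v <- get(f)
    if (!is.numeric(v) || !is.finite(v) || v < 0) stop("invalid '", f, "': must be >= 0")
  }
  if (!is.numeric(error_scale) || error_scale < 0) stop("invalid 'error_scale': must be >= 0")
  if (!is.numeric(error_df) || error_df <= 0) stop("invalid 'error_df': must be > 0")
  structure(list(
    n_individuals = as.integer(n_individuals),
    mu_log_ec50 = mu_log_ec50, sd_log_ec50 = sd_log_ec50,
    mu_log_y0 = mu_log_y0, sd_log_y0 = sd_log_y0,
    mu_log_nshift = mu_log_nshift, sd_log_nshift = sd_log_nshift,
    error_scale = error_scale, error_df = error_df,
    seed = as.integer(seed)
  ), class = "population_spec")
}

#' Simulate true Hill parameters for a donor population
#'
#' Draws per-individual Hill parameters from the population model in
#' \code{\link{population_spec}}. Sex is assigned balanced (alternating
#' female/male), mirroring panel designs that select equal male-to-female
#' representation.
#'
#' @param spec a \code{\link{population_spec}}.
#' @return A data frame with one row per individual: \code{individual_id},
#'   \code{sex} (0 = female, 1 = male), \code{y0}, \code{ec50}, \code{n},
#'   and the underlying normal draws \code{log_y0}, \code{log_ec50},
#'   \code{log_nshift}.
#' @export
simulate_population <- function(spec) {
  if (!inherits(spec, "population_spec")) stop("'spec' must be a population_spec")
  nn <- spec$n_individuals
  with_seed(spec$seed, {
    log_y0 <- stats::rnorm(nn, spec$mu_log_y0, spec$sd_log_y0)
    log_ec50 <- stats::rnorm(nn, spec$mu_log_ec50, spec$sd_log_ec50)
    log_nshift <- stats::rnorm(nn, spec$mu_log_nshift, spec$sd_log_nshift)
  })
  data.frame(
    individual_id = sprintf("L%03d", seq_len(nn)),
    sex = rep_len(c(0L, 1L), nn),
    y0 = exp(log_y0),
    ec50 = exp(log_ec50),
    n = 1 + exp(log_nshift),
    log_y0 = log_y0,
    log_ec50 = log_ec50,
    log_nshift = log_nshift,
    stringsAsFactors = FALSE
  )
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so simulation calls do not perturb each other.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}
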