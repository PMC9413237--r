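#' Plate layout specification for the simulated cytotoxicity screen
#'
#' Describes the 384-well plate design the simulator emulates: five 10x serial
#' dilutions spanning 0.01-100 uM, three identical replicate plates per cell
#' line, solvent (0.5\% DMSO) vehicle wells, and 100 uM tetra-octyl ammonium
#' bromide (TAB) positive-control wells expected to show complete
#' cytotoxicity.
#'
#' @param concentrations treatment concentrations in uM, strictly increasing.
#' @param n_replicate_plates identical plates per cell line (default 3).
#' @param n_vehicle_wells vehicle-control wells per plate (default 16).
#' @param n_positive_wells positive-control wells per plate (default 8).
#' @param vehicle_luminescence_mean expected raw luminescence of a vehicle
#'   well (arbitrary luminescence counts).
#' @param vehicle_luminescence_cv coefficient of variation of vehicle wells
#'   (fraction, e.g. 0.05 = 5\%).
#' @param positive_mean_fraction residual signal fraction in positive-control
#'   wells (near-complete kill).
#' @return An object of class \code{plate_layout}.
#' @export
plate_layout <- function(concentrations = c(0.01, 0.1, 1, 10, 100),
                         n_replicate_plates = 3,
                         n_vehicle_wells = 16,
                         n_positive_wells = 8,
                         vehicle_luminescence_mean = 2e5,
                         vehicle_luminescence_cv = 0.05,
                         positive_mean_fraction = 0.005) {
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("'concentrations' must be positive and strictly increasing")
  }
  counts <- c(n_replicate_plates = n_replicate_plates,
              n_vehicle_wells = n_vehicle_wells,
              n_positive_wells = n_positive_wells)
  if (any(counts < 1)) stop("plate counts must be >= 1")
  if (vehicle_luminescence_mean <= 0) stop("'vehicle_luminescence_mean' must be > 0")
  if (vehicle_luminescence_cv < 0) stop("'vehicle_luminescence_cv' must be >= 0")
  structure(list(
    concentrations = as.numeric(concentrations),
    n_replicate_plates = as.integer(n_replicate_plates),
    n_vehicle_wells = as.integer(n_vehicle_wells),
    n_positive_wells = as.integer(n_positive_wells),
    vehicle_luminescence_mean = vehicle_luminescence_mean,
    vehicle_luminescence_cv = vehicle_luminescence_cv,
    positive_mean_fraction = positive_mean_fraction
  ), class = "plate_layout")
}

#' Simulate raw plate luminescence for a donor panel
#'
#' Generates a plate set of raw luminescence counts. Treatment wells follow
#' the downward Hill curve of each individual scaled by the vehicle mean, with
#' multiplicative Student-t noise so that post-normalization residuals match
#' the robust error model the fitting stage assumes. Vehicle wells fluctuate
#' around their mean with the stated CV; positive-control wells carry
#' near-zero signal. Raw counts are truncated at zero (luminescence cannot be
#' negative).
#'
#' @param params per-individual true Hill parameters: a data frame with
#'   columns \code{individual_id}, \code{y0}, \code{ec50}, \code{n}, and
#'   optionally \code{sex} and \code{chemical_id}. Several chemicals may share
#'   a plate by stacking rows with different \code{chemical_id}; listing the
#'   same parameters under two ids emulates intra-plate replicate chemicals.
#' @param layout a \code{\link{plate_layout}}.
#' @param chemical_id chemical label used when \code{params} has no
#'   \code{chemical_id} column.
#' @param error_scale scale of the multiplicative t noise on treatment wells
#'   (response-fraction units); 0 gives noiseless Hill responses.
#' @param error_df degrees of freedom of the t noise.
#' @param seed integer seed.
#' @param population_label optional per-individual ancestry labels (named
#'   character vector or single value).
#' @return A \code{PlateSet} data frame with columns \code{plate_id},
#'   \code{cell_line_id}, \code{population_label}, \code{sex},
#'   \code{well_role} (vehicle / positive / treatment), \code{chemical_id},
#'   \code{concentration_uM}, \code{raw_luminescence}.
#' @export
simulate_plates <- function(params, layout = plate_layout(),
                            chemical_id = "chem1",
                            error_scale = 0.05, error_df = 5,
                            seed = 1L, population_label = NA_character_) {
  stopifnot(inherits(layout, "plate_layout"))
  if (!all(c("individual_id", "y0", "ec50", "n") %in% names(params))) {
    stop("'params' must have columns individual_id, y0, ec50, n")
  }
  if (error_scale < 0) stop("'error_scale' must be >= 0")
  if (error_df <= 0) stop("'error_df' must be > 0")
  if (!"chemical_id" %in% names(params)) params$chemical_id <- chemical_id
  if (!"sex" %in% names(params)) params$sex <- NA_integer_

  ids <- unique(params$individual_id)
  sex_of <- params$sex[match(ids, params$individual_id)]
  pop_of <- if (length(population_label) == length(ids)) population_label
            else rep_len(population_label, length(ids))
  names(pop_of) <- ids

  conc <- layout$concentrations
  vm <- layout$vehicle_luminescence_mean

  rows <- vector("list", length(ids) * layout$n_replicate_plates)
  k <- 0L
  with_seed(seed, {
    for (i in seq_along(ids)) {
      pi <- params[params$individual_id == ids[i], , drop = FALSE]
      for (r in seq_len(layout$n_replicate_plates)) {
        plate <- sprintf("%s_P%d", ids[i], r)
        # vehicle wells: truncated-at-zero normal fluctuation with stated CV
        veh <- pmax(0, vm * (1 + layout$vehicle_luminescence_cv *
                                 stats::rnorm(layout$n_vehicle_wells)))
        # positive controls: residual signal near zero
        pos <- pmax(0, vm * layout$positive_mean_fraction *
                      (1 + layout$vehicle_luminescence_cv *
                         stats::rnorm(layout$n_positive_wells)))
        # treatment wells: one well per chemical x concentration
        tr <- do.call(rbind, lapply(seq_len(nrow(pi)), function(j) {
          mu <- hill_response(conc, y0 = pi$y0[j], ec50 = pi$ec50[j], n = pi$n[j])
          noise <- if (error_scale > 0) error_scale * stats::rt(length(conc), df = error_df) else 0
          data.frame(chemical_id = pi$chemical_id[j],
                     concentration_uM = conc,
                     raw_luminescence = pmax(0, vm * (mu + noise)),
                     stringsAsFactors = FALSE)
        }))
        k <- k + 1L
        rows[[k]] <- data.frame(
          plate_id = plate,
          cell_line_id = ids[i],
          population_label = unname(pop_of[ids[i]]),
          sex = sex_of[i],
          well_role = c(rep("vehicle", layout$n_vehicle_wells),
                        rep("positive", layout$n_positive_wells),
                        rep("treatment", nrow(tr))),
          chemical_id = c(rep("DMSO", layout$n_vehicle_wells),
                          rep("TAB", layout$n_positive_wells),
                          tr$chemical_id),
          concentration_uM = c(rep(0, layout$n_vehicle_wells),
                               rep(100, layout$n_positive_wells),
                               tr$concentration_uM),
          raw_luminescence = c(veh, pos, tr$raw_luminescence),
          stringsAsFactors = FALSE
        )
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a plate set as CSV
#'
#' @param plates a PlateSet data frame (see \code{\link{simulate_plates}}).
#' @param path file path.
#' @return \code{read_plateset} returns the PlateSet data frame.
#' @export
write_plateset <- function(plates, path) {
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plateset
#' @export
read_plateset <- function(path) {
  req <- c("plate_id", "cell_line_id", "well_role", "chemical_id",
           "concentration_uM", "raw_luminescence")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(x))
  if (length(missing)) stop("plate CSV missing columns: ", paste(missing, collapse = ", "))
  x
}
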