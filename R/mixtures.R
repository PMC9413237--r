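#' Build a defined-mixture recipe from per-chemical reference values
#'
#' Defined mixtures are assembled so that each chemical's share of the total
#' stock is proportional to a scenario-specific reference value (an in vivo
#' point of departure, a reference dose, an exposure estimate, or an in vitro
#' AC50), at either the population median ("low") or the upper 95th
#' percentile ("high") of that reference. The mass fraction of chemical j is
#' \code{reference_j / sum(reference)}.
#'
#' @param reference_values named numeric vector of positive per-chemical
#'   reference values (uM-equivalent) for the chosen scenario and level.
#' @param scenario one of \code{"POD"}, \code{"RfD"}, \code{"Exposure"},
#'   \code{"AC50"}.
#' @param level \code{"low"} (median) or \code{"high"} (upper 95th percentile).
#' @return A \code{mixture_recipe} data frame with columns
#'   \code{chemical_id}, \code{scenario}, \code{level},
#'   \code{reference_value}, \code{mass_fraction}; fractions sum to 1.
#' @examples
#' build_mixture_recipe(c(a = 9, b = 1), "Exposure", "low")
#' @export
build_mixture_recipe <- function(reference_values,
                                 scenario = c("POD", "RfD", "Exposure", "AC50"),
                                 level = c("low", "high")) {
  scenario <- match.arg(scenario)
  level <- match.arg(level)
  if (is.null(names(reference_values)) || any(!nzchar(names(reference_values)))) {
    stop("'reference_values' must be a named vector (chemical ids)")
  }
  if (any(!is.finite(reference_values)) || any(reference_values <= 0)) {
    stop("all reference values must be positive")
  }
  out <- data.frame(
    chemical_id = names(reference_values),
    scenario = scenario,
    level = level,
    reference_value = as.numeric(reference_values),
    mass_fraction = as.numeric(reference_values) / sum(reference_values),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mixture_recipe", "data.frame")
  out
}

#' Write / read mixture recipes as TSV
#' @param recipe a \code{mixture_recipe} (or several rbind-ed together).
#' @param path file path.
#' @export
write_mixture_recipe <- function(recipe, path) {
  utils::write.table(recipe, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mixture_recipe
#' @export
read_mixture_recipe <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("mixture_recipe", "data.frame")
  x
}
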