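#' Normalize raw luminescence to same-plate vehicle controls
#'
#' Each well's raw luminescence is divided by the mean of the vehicle (0.5\%
#' DMSO) wells on the same plate, so 1.0 is vehicle-level viability and 0 is
#' full cytotoxicity. Stimulation above vehicle (values > 1) is allowed, not
#' clipped.
#'
#' @param plates a PlateSet data frame (see \code{\link{simulate_plates}}).
#' @return The input with an added \code{normalized_response} column.
#' @export
normalize_plates <- function(plates) {
  req <- c("plate_id", "well_role", "raw_luminescence")
  if (!all(req %in% names(plates))) {
    stop("plates must have columns ", paste(req, collapse = ", "))
  }
  veh <- plates$well_role == "vehicle"
  by_plate <- split(seq_len(nrow(plates)), plates$plate_id)
  out <- plates
  out$normalized_response <- NA_real_
  for (idx in by_plate) {
    v <- idx[veh[idx]]
    if (length(v) == 0) {
      stop("plate ", plates$plate_id[idx[1]], " has no vehicle wells")
    }
    m <- mean(plates$raw_luminescence[v])
    if (!is.finite(m) || m <= 0) {
      stop("plate ", plates$plate_id[idx[1]],
           " has non-positive vehicle mean; cannot normalize")
    }
    out$normalized_response[idx] <- plates$raw_luminescence[idx] / m
  }
  out
}

#' Plate-level quality control
#'
#' Applies the screen's QC gates plate by plate: the coefficient of variation
#' of the raw vehicle wells must be strictly below \code{vehicle_cv_max}
#' percent, and the positive-control (100 uM TAB) wells must show complete
#' cytotoxicity, operationalized as mean normalized response at most
#' \code{positive_control_max}. A failing gate excludes the whole plate.
#'
#' @param plates a PlateSet data frame; normalized internally if needed.
#' @param vehicle_cv_max CV gate in percent (default 20; strict \code{<}).
#' @param positive_control_max maximum mean normalized positive-control
#'   response counted as complete kill (default 0.05).
#' @return A \code{QCReport} data frame: \code{plate_id}, \code{vehicle_cv}
#'   (percent, sample SD / mean of raw vehicle counts), \code{positive_control_mean_response},
#'   \code{pass}, \code{failure_reasons}.
#' @export
qc_plates <- function(plates, vehicle_cv_max = 20, positive_control_max = 0.05) {
  if (!"normalized_response" %in% names(plates)) plates <- normalize_plates(plates)
  plate_ids <- unique(plates$plate_id)
  res <- lapply(plate_ids, function(p) {
    sl <- plates[plates$plate_id == p, ]
    veh <- sl$raw_luminescence[sl$well_role == "vehicle"]
    pos <- sl$normalized_response[sl$well_role == "positive"]
    reasons <- character(0)
    if (length(veh) < 2) {
      cv <- NA_real_
      reasons <- c(reasons, "fewer than 2 vehicle wells: CV undefined")
    } else {
      cv <- stats::sd(veh) / mean(veh) * 100
      if (!(cv < vehicle_cv_max)) {
        reasons <- c(reasons, sprintf("vehicle CV %.3g%% not < %g%%", cv, vehicle_cv_max))
      }
    }
    pm <- if (length(pos)) mean(pos) else NA_real_
    if (!length(pos)) {
      reasons <- c(reasons, "no positive-control wells")
    } else if (!(pm <= positive_control_max)) {
      reasons <- c(reasons, sprintf(
        "positive control incomplete kill (mean response %.3g > %g)",
        pm, positive_control_max))
    }
    data.frame(plate_id = p, vehicle_cv = cv,
               positive_control_mean_response = pm,
               pass = length(reasons) == 0,
               failure_reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pearson correlation between replicate response profiles
#'
#' Standard Pearson r with its two-sided t-test p-value, used both for
#' intra-plate replicate chemicals and for inter-plate reproducibility.
#' Zero variance in either vector makes r undefined; this is flagged rather
#' than returned as a silent NaN.
#'
#' @param responses_a,responses_b paired numeric vectors (length >= 3).
#' @return A list with \code{r}, \code{p_value}, \code{n}, \code{flag}
#'   (\code{NA} or a reason the correlation is undefined).
#' @export
replicate_correlation <- function(responses_a, responses_b) {
  if (length(responses_a) != length(responses_b)) stop("vectors must be paired")
  ok <- is.finite(responses_a) & is.finite(responses_b)
  a <- responses_a[ok]; b <- responses_b[ok]
  if (length(a) < 3) stop("need at least 3 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(a),
                flag = "zero variance: correlation undefined"))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a), flag = NA_character_)
}

#' Inter-plate reproducibility across replicate plates
#'
#' For each cell line, picks a random pair of its replicate plates (seeded)
#' and correlates the normalized treatment responses well by well.
#'
#' @param norm normalized PlateSet (see \code{\link{normalize_plates}}).
#' @param seed seed governing the random plate-pair choice.
#' @return Data frame per cell line: \code{cell_line_id}, \code{plate_a},
#'   \code{plate_b}, \code{r}, \code{p_value}, \code{n}, \code{flag}.
#' @export
interplate_correlation <- function(norm, seed = 1L) {
  tr <- norm[norm$well_role == "treatment", ]
  out <- list()
  with_seed(seed, {
    for (cl in unique(tr$cell_line_id)) {
      sl <- tr[tr$cell_line_id == cl, ]
      plates <- sort(unique(sl$plate_id))
      if (length(plates) < 2) next
      pair <- sample(plates, 2)
      a <- sl[sl$plate_id == pair[1], ]
      b <- sl[sl$plate_id == pair[2], ]
      key <- function(d) paste(d$chemical_id, d$concentration_uM)
      m <- match(key(a), key(b))
      cc <- replicate_correlation(a$normalized_response, b$normalized_response[m])
      out[[cl]] <- data.frame(cell_line_id = cl, plate_a = pair[1], plate_b = pair[2],
                              r = cc$r, p_value = cc$p_value, n = cc$n,
                              flag = cc$flag, stringsAsFactors = FALSE)
    }
  })
  if (!length(out)) stop("no cell line has >= 2 replicate plates")
  rn <- do.call(rbind, out)
  rownames(rn) <- NULL
  rn
}

#' Intra-plate reproducibility from duplicate chemicals
#'
#' Correlates the full concentration-response profiles of two chemicals
#' screened in duplicate on every plate (e.g. the same substance under two
#' labels), per cell line across all its plates.
#'
#' @param norm normalized PlateSet.
#' @param chem_a,chem_b the two duplicate chemical ids.
#' @return Data frame per cell line with \code{r}, \code{p_value}, \code{n},
#'   \code{flag}.
#' @export
intraplate_correlation <- function(norm, chem_a, chem_b) {
  tr <- norm[norm$well_role == "treatment" &
               norm$chemical_id %in% c(chem_a, chem_b), ]
  if (!nrow(tr)) stop("duplicate chemicals not found in plate set")
  out <- lapply(unique(tr$cell_line_id), function(cl) {
    sl <- tr[tr$cell_line_id == cl, ]
    a <- sl[sl$chemical_id == chem_a, ]
    b <- sl[sl$chemical_id == chem_b, ]
    m <- match(paste(a$plate_id, a$concentration_uM),
               paste(b$plate_id, b$concentration_uM))
    cc <- replicate_correlation(a$normalized_response, b$normalized_response[m])
    data.frame(cell_line_id = cl, r = cc$r, p_value = cc$p_value, n = cc$n,
               flag = cc$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble the long-format dose-response dataset from QC-passing plates
#'
#' Drops plates failing QC (plate-level exclusion), keeps treatment wells,
#' and emits the long table the hierarchical model consumes.
#'
#' @param norm normalized PlateSet.
#' @param qc optional \code{QCReport} from \code{\link{qc_plates}}; computed
#'   if missing.
#' @return Data frame: \code{cell_line_id}, \code{chemical_id},
#'   \code{concentration_uM}, \code{replicate} (plate index within cell
#'   line), \code{normalized_response}.
#' @export
dose_response_dataset <- function(norm, qc = NULL) {
  if (is.null(qc)) qc <- qc_plates(norm)
  keep <- qc$plate_id[qc$pass]
  tr <- norm[norm$plate_id %in% keep & norm$well_role == "treatment", ]
  if (!nrow(tr)) stop("no treatment wells remain after QC")
  rep_idx <- stats::ave(as.integer(factor(tr$plate_id)),
                        tr$cell_line_id, FUN = function(z) match(z, sort(unique(z))))
  out <- data.frame(cell_line_id = tr$cell_line_id,
                    chemical_id = tr$chemical_id,
                    concentration_uM = tr$concentration_uM,
                    replicate = rep_idx,
                    normalized_response = tr$normalized_response,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
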