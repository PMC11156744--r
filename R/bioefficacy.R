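#' Bioefficacy index weights
#'
#' The index combines mycelial growth, sporulation and 7-day corrected
#' nymphal mortality as `BI = w_mg*MG + w_sp*SP + w_mo*MO`. The default
#' weights are 0.37, 0.13 and 0.50: half the index is virulence, with
#' the remainder split between the two culture traits that govern mass
#' production and field persistence. Weights must be non-negative and
#' sum to 1.
#'
#' @param w_mg,w_sp,w_mo weights for mycelial growth, sporulation and
#'   mortality.
#' @return A named list of class `bi_weights`.
#' @export
bi_weights <- function(w_mg = 0.37, w_sp = 0.13, w_mo = 0.50) {
  w <- c(w_mg = w_mg, w_sp = w_sp, w_mo = w_mo)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("bi_weights: weights must be finite and >= 0", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-8) {
    stop("bi_weights: weights must sum to 1 (got ", sum(w), ")",
         call. = FALSE)
  }
  structure(as.list(w), class = "bi_weights")
}

#' Bioefficacy index of a fungal strain
#'
#' Weighted score summarizing a strain's usefulness as a biocontrol
#' agent: `BI = 0.37*MG + 0.13*SP + 0.50*MO` with the default weights,
#' where `MG` is mycelial growth (colony diameter, mm), `SP` sporulation
#' (x 10^8 conidia/ml) and `MO` the corrected nymphal mortality (%) at
#' 7 days post spray. All arguments are vectorized.
#'
#' @param MG mycelial growth, mm (>= 0).
#' @param SP sporulation, x 10^8 conidia/ml (>= 0).
#' @param MO corrected mortality at 7 days, percent (0-100).
#' @param weights a [bi_weights()] configuration.
#' @return The index, on the percent scale.
#' @examples
#' bioefficacy_index(59.3, 6.5, 95.1)  # 70.3 after 1-dp rounding
#' @export
bioefficacy_index <- function(MG, SP, MO, weights = bi_weights()) {
  if (!inherits(weights, "bi_weights")) weights <- do.call(bi_weights, weights)
  if (any(!is.finite(MG)) || any(MG < 0)) {
    stop("bioefficacy_index: MG must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(SP)) || any(SP < 0)) {
    stop("bioefficacy_index: SP must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(MO)) || any(MO < 0 | MO > 100)) {
    stop("bioefficacy_index: MO must lie in [0, 100]", call. = FALSE)
  }
  weights$w_mg * MG + weights$w_sp * SP + weights$w_mo * MO
}

# half-open bins on the BI axis; lower bounds of PV..HV
.bi_breaks <- c(0, 20, 30, 40, 50, 60, Inf)
.bi_labels <- c("PV", "LV", "MV", "V", "GV", "HV")

#' Virulence category from the bioefficacy index
#'
#' Fixed-threshold mapping with half-open bins:
#' `[60, Inf)` HV (highly virulent), `[50, 60)` GV (good), `[40, 50)` V
#' (virulent), `[30, 40)` MV (moderate), `[20, 30)` LV (low),
#' `[0, 20)` PV (poor). The printed category bounds leave gaps between
#' integers (e.g. 49 to 50); since BI is continuous the bins are closed
#' on the left and open on the right.
#'
#' @param BI bioefficacy index values (>= 0).
#' @return Factor with levels `HV > GV > V > MV > LV > PV` (ordered by
#'   decreasing virulence).
#' @examples
#' categorize_bi(c(70.3, 45, 19.99))
#' @export
categorize_bi <- function(BI) {
  if (any(!is.finite(BI)) || any(BI < 0)) {
    stop("categorize_bi: BI must be finite and >= 0", call. = FALSE)
  }
  idx <- findInterval(BI, .bi_breaks)  # 1..6
  factor(.bi_labels[idx], levels = rev(.bi_labels))
}

#' Build per-strain summaries from measurement tables
#'
#' Condenses the replicate-level tables into one row per strain: `MG` is
#' the mean of the two perpendicular colony diameters averaged across
#' replicates (at the final growth day present unless `mg_day` is
#' given), `SP` the mean conidial concentration (at `sp_day` or the last
#' day present), `MO3`/`MO5`/`MO7` the corrected mortalities from
#' [mortality_from_counts()], `BI` the index and `category` its
#' virulence class.
#'
#' @param panel list with `strains`, `growth`, `spores`, `bioassay`.
#' @param weights a [bi_weights()] configuration.
#' @param mg_day,sp_day observation day to summarize growth/sporulation
#'   at; default: the latest day present in each table.
#' @return Strain summary data frame (see [write_summaries()]).
#' @export
build_strain_summaries <- function(panel, weights = bi_weights(),
                                   mg_day = NULL, sp_day = NULL) {
  growth <- validate_growth(panel$growth)
  spores <- validate_spores(panel$spores)
  if (is.null(mg_day)) mg_day <- max(growth$day)
  if (is.null(sp_day)) sp_day <- max(spores$day)
  g <- growth[growth$day == mg_day, , drop = FALSE]
  s <- spores[spores$day == sp_day, , drop = FALSE]
  mg <- tapply((g$diameter_a + g$diameter_b) / 2, g$strain_id, mean)
  sp <- tapply(s$conidia_conc, s$strain_id, mean)
  mo <- mortality_from_counts(panel$bioassay)
  ids <- sort(unique(mo$strain_id))
  pick <- function(d) {
    sub <- mo[mo$day == d, , drop = FALSE]
    setNames(sub$mortality, sub$strain_id)[ids]
  }
  out <- data.frame(
    strain_id = ids,
    MG = as.numeric(mg[ids]),
    SP = as.numeric(sp[ids]),
    MO3 = as.numeric(pick(3)),
    MO5 = as.numeric(pick(5)),
    MO7 = as.numeric(pick(7)),
    stringsAsFactors = FALSE
  )
  if (any(!complete.cases(out))) {
    bad <- out$strain_id[!complete.cases(out)]
    stop("build_strain_summaries: incomplete measurements for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out$BI <- bioefficacy_index(out$MG, out$SP, out$MO7, weights)
  out$category <- as.character(categorize_bi(out$BI))
  out
}
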