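# Turning raw batch-culture measurements into analysis-ready records:
# log-linear growth rates from daily fluorescence series, exclusion of
# non-growing cultures, silica normalisations, and simple association
# statistics.

#' Growth rate from an in vivo fluorescence time series
#'
#' Minimum chlorophyll a fluorescence is used as a biomass proxy; the
#' specific growth rate is the ordinary least-squares slope of
#' `ln(F)` against day. The estimator is exact on noise-free exponential
#' series regardless of the sampling times.
#'
#' @param day Measurement days (ascending, >= 3-day span).
#' @param fluorescence Relative fluorescence values (> 0).
#' @return Growth rate, d-1.
#' @examples
#' growth_rate_from_fluorescence(0:4, 100 * exp(0.5 * (0:4)))
#' @export
growth_rate_from_fluorescence <- function(day, fluorescence) {
  stopifnot(length(day) == length(fluorescence))
  if (is.unsorted(day, strictly = TRUE))
    stop("day values must be strictly increasing")
  if (any(fluorescence <= 0))
    stop("fluorescence values must be positive")
  if (max(day) - min(day) < 3)
    stop("fluorescence series must span at least 3 days")
  unname(stats::coef(stats::lm(log(fluorescence) ~ day))[2])
}

#' Flag cultures with zero net growth or mortality
#'
#' Cultures whose growth rate is at or below `threshold` (default 0) are
#' flagged with a machine-readable reason and barred from model fitting,
#' while remaining in the output for reporting.
#'
#' @param records Data frame with a `growth_rate` column.
#' @param threshold Growth rate at or below which a culture is excluded.
#' @return `records` with logical `excluded` and character
#'   `exclusion_reason` columns.
#' @export
apply_exclusions <- function(records, threshold = 0) {
  stopifnot(is.data.frame(records), "growth_rate" %in% names(records))
  mu <- records$growth_rate
  records$excluded <- !is.na(mu) & mu <= threshold
  records$exclusion_reason <- ifelse(
    is.na(mu), NA_character_,
    ifelse(mu < threshold, "mortality",
           ifelse(mu == threshold, "zero net growth", NA_character_)))
  records$exclusion_reason[!records$excluded] <- NA_character_
  records
}

#' Per-cell silica metrics
#'
#' Normalises the dissolved-silicate drawdown over the growth period and
#' the final biogenic silica by the end-point cell abundance. Positive
#' `delta_dsi_per_cell` denotes net uptake; negative uptake is retained
#' but flagged.
#'
#' @param dsi_start,dsi_end Dissolved silicate at start and end,
#'   umol kg-1.
#' @param bsi Biogenic silica at harvest, umol kg-1.
#' @param cells_end Cell abundance at harvest, cells kg-1 (> 0).
#' @return Data frame with `delta_dsi_per_cell`, `bsi_per_cell`
#'   (umol cell-1) and logical `negative_uptake`.
#' @export
silica_metrics <- function(dsi_start, dsi_end, bsi, cells_end) {
  if (any(cells_end <= 0)) stop("cells_end must be positive")
  delta <- (dsi_start - dsi_end) / cells_end
  data.frame(delta_dsi_per_cell = delta,
             bsi_per_cell = bsi / cells_end,
             negative_uptake = delta < 0)
}

#' Coefficient of determination between two variables
#'
#' Squared Pearson correlation, identical to the R-squared of the simple
#' linear regression of `y` on `x`. Used to quantify the association
#' between growth rate and photophysiology (Fv/Fm).
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must vary.
#' @return R-squared in \[0, 1\].
#' @export
rsquared <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("x is constant")
  stats::cor(x, y)^2
}

#' Normalise growth rates to the species maximum
#'
#' Divides each rate by the maximum rate among retained (non-excluded)
#' observations, so the best-performing culture maps to 1. Excluded
#' records never contribute to the maximum but are still scaled.
#'
#' @param rate Growth rates, d-1.
#' @param excluded Optional logical vector flagging records to ignore
#'   when locating the maximum.
#' @return Relative growth rates (retained records lie in \[0, 1\]).
#' @export
relative_growth <- function(rate, excluded = NULL) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(rate))
  keep <- !excluded & is.finite(rate)
  if (!any(keep & rate > 0))
    stop("no retained positive growth rate to normalise by")
  rate / max(rate[keep])
}

#' Build the analysis-ready culture table
#'
#' Joins a one-row-per-culture table with its long-format fluorescence
#' series, computes the log-linear growth rate per culture, applies the
#' zero-growth exclusion rule, speciates the measured start and end
#' (TA, pH) states, and attaches the growth-period mean CO2 and H+
#' assigned to each culture.
#'
#' @param cultures Data frame with columns `culture_id`, `species`,
#'   `ta_start`, `ta_end`, `ph_start`, `ph_end`, `temperature`,
#'   `salinity`, and optionally `dsi_start`, `dsi_end`, `bsi`,
#'   `cells_end`, `fvfm`.
#' @param fluorescence Long data frame with columns `culture_id`, `day`,
#'   `fluorescence`.
#' @param silicate Dissolved silicate passed to speciation, umol kg-1;
#'   defaults to the `dsi_start` column when present, else 0.
#' @param phosphate Phosphate passed to speciation, umol kg-1.
#' @param threshold Exclusion threshold forwarded to
#'   [apply_exclusions()].
#' @return `cultures` augmented with `growth_rate`, `excluded`,
#'   `exclusion_reason`, start/end/mean `co2`, `h_nmol`, `dic` and mean
#'   `pco2`.
#' @export
process_cultures <- function(cultures, fluorescence, silicate = NULL,
                             phosphate = 3, threshold = 0) {
  need <- c("culture_id", "ta_start", "ta_end", "ph_start", "ph_end",
            "temperature", "salinity")
  miss <- setdiff(need, names(cultures))
  if (length(miss))
    stop("cultures table is missing columns: ",
         paste(miss, collapse = ", "))
  if (!all(c("culture_id", "day", "fluorescence") %in% names(fluorescence)))
    stop("fluorescence table needs culture_id, day, fluorescence columns")

  rates <- vapply(cultures$culture_id, function(id) {
    ser <- fluorescence[fluorescence$culture_id == id, ]
    if (nrow(ser) == 0) return(NA_real_)
    ser <- ser[order(ser$day), ]
    growth_rate_from_fluorescence(ser$day, ser$fluorescence)
  }, numeric(1))
  cultures$growth_rate <- rates
  cultures <- apply_exclusions(cultures, threshold)

  if (is.null(silicate))
    silicate <- if ("dsi_start" %in% names(cultures))
      cultures$dsi_start else 0

  out <- lapply(seq_len(nrow(cultures)), function(i) {
    r <- cultures[i, ]
    sil <- rep_len(silicate, nrow(cultures))[i]
    st <- speciate_ta_ph(r$ta_start, r$ph_start, r$temperature,
                         r$salinity, sil, phosphate)
    en <- speciate_ta_ph(r$ta_end, r$ph_end, r$temperature, r$salinity,
                         sil, phosphate)
    data.frame(co2_start = st$co2, co2_end = en$co2,
               co2_mean = (st$co2 + en$co2) / 2,
               h_nmol_mean = (st$h_nmol + en$h_nmol) / 2,
               dic_start = st$dic, dic_end = en$dic,
               dic_mean = (st$dic + en$dic) / 2,
               pco2_mean = (st$pco2 + en$pco2) / 2)
  })
  cbind(cultures, do.call(rbind, out))
}
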