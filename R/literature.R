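# Harmonization of heterogeneous published growth records to the model's
# (CO2, rate) input space, with eligibility screening and per-set plus
# pooled fitting.
#
# Expected record schema (one row per observation):
#   study_id, species, growth_rate, param1_name, param1_value,
#   param2_name, param2_value, ph_scale, temperature, salinity,
#   manipulation
# Parameter names: "co2" (umol kg-1), "ta", "dic" (umol kg-1),
# "ph", "pco2" (uatm). A record is usable when it reports CO2 (or pCO2)
# directly, or any speciation-sufficient pair.

.lit_need <- c("study_id", "species", "growth_rate", "param1_name",
               "param1_value", "param2_name", "param2_value",
               "temperature")

#' Screen published records for model and landscape eligibility
#'
#' Groups records by study and species and flags each group:
#' `model_eligible` when it spans more than 3 distinct CO2 levels
#' (strict reading: 4 or more), `landscape_eligible` when at least two
#' carbonate-chemistry parameters are reported per record, and
#' `acid_base_manipulated` when the stated manipulation is an
#' acid/base (NaOH, Na2CO3, HCl) adjustment rather than aeration.
#'
#' @param records Literature data frame (see the schema above).
#' @return `records` with the three logical flag columns appended.
#' @export
screen_inclusion <- function(records) {
  miss <- setdiff(.lit_need, names(records))
  if (length(miss))
    stop("literature table is missing columns: ",
         paste(miss, collapse = ", "))
  harm <- harmonize_literature(records, quiet = TRUE)
  key <- interaction(records$study_id, records$species, drop = TRUE)
  n_levels <- tapply(harm$co2, key, function(v)
    length(unique(signif(v[is.finite(v)], 6))))
  records$model_eligible <- as.vector(n_levels[key]) > 3
  has2 <- !is.na(records$param1_name) & !is.na(records$param2_name) &
    nzchar(records$param1_name) & nzchar(records$param2_name)
  records$landscape_eligible <- as.vector(tapply(has2, key, all)[key])
  manip <- if ("manipulation" %in% names(records))
    tolower(records$manipulation) else ""
  records$acid_base_manipulated <-
    grepl("naoh|na2co3|hcl|acid|base", manip)
  records
}

#' Harmonize published records to (CO2, relative growth) points
#'
#' Resolves each record's dissolved CO2: taken directly when reported,
#' via Henry's law from pCO2, or by speciation from a reported pair
#' (TA+DIC, TA+pH, TA+pCO2, DIC+pH). Reported pH is converted to the
#' total scale from the declared `ph_scale` (undeclared pH is assumed
#' total, with a warning). Missing salinity defaults to 35 with a
#' warning. Growth rates are normalised within each study-species group
#' to the group maximum. Records that cannot be resolved are returned
#' with `NA` CO2 and a `skip_reason`.
#'
#' @param records Literature data frame.
#' @param quiet Suppress the default-assumption warnings.
#' @return `records` with `co2`, `rel_growth` and `skip_reason` columns.
#' @export
harmonize_literature <- function(records, quiet = FALSE) {
  miss <- setdiff(.lit_need, names(records))
  if (length(miss))
    stop("literature table is missing columns: ",
         paste(miss, collapse = ", "))
  n <- nrow(records)
  sal <- if ("salinity" %in% names(records)) records$salinity
         else rep(NA_real_, n)
  if (anyNA(sal) && !quiet)
    warning("missing salinity defaulted to 35")
  sal[is.na(sal)] <- 35
  scl <- if ("ph_scale" %in% names(records)) records$ph_scale
         else rep(NA_character_, n)

  co2 <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  warned_scale <- FALSE
  for (i in seq_len(n)) {
    pars <- c(records$param1_value[i], records$param2_value[i])
    names(pars) <- tolower(c(records$param1_name[i],
                             records$param2_name[i]))
    pars <- pars[!is.na(pars) & nzchar(names(pars))]
    tmp <- records$temperature[i]
    get <- function(nm) unname(pars[nm])
    has <- function(nm) nm %in% names(pars)
    ph_tot <- NULL
    if (has("ph")) {
      sc <- scl[i]
      if (is.na(sc) || !nzchar(sc)) {
        if (!quiet && !warned_scale) {
          warning("undeclared pH scale assumed total")
          warned_scale <- TRUE
        }
        sc <- "total"
      }
      ph_tot <- ph_to_total(get("ph"), sc, tmp, sal[i])
    }
    res <- tryCatch({
      if (has("co2")) get("co2")
      else if (has("ta") && !is.null(ph_tot))
        speciate_ta_ph(get("ta"), ph_tot, tmp, sal[i],
                       silicate = 0, phosphate = 0)$co2
      else if (has("ta") && has("dic"))
        speciate_ta_dic(get("ta"), get("dic"), tmp, sal[i],
                        silicate = 0, phosphate = 0)$co2
      else if (has("ta") && has("pco2"))
        speciate_ta_pco2(get("ta"), get("pco2"), tmp, sal[i],
                         silicate = 0, phosphate = 0)$co2
      else if (has("dic") && !is.null(ph_tot)) {
        k <- carb_constants(tmp, sal[i])
        h <- 10^(-ph_tot)
        get("dic") * h^2 / (h^2 + k$K1 * h + k$K1 * k$K2)
      } else if (has("pco2")) {
        k <- carb_constants(tmp, sal[i])
        k$K0 * get("pco2")  # uatm -> umol kg-1
      } else NA_real_
    }, error = function(e) NA_real_)
    if (is.na(res))
      reason[i] <- "insufficient or inconsistent carbonate parameters"
    co2[i] <- res
  }
  records$co2 <- co2
  key <- interaction(records$study_id, records$species, drop = TRUE)
  gmax <- tapply(ifelse(is.finite(co2), records$growth_rate, NA),
                 key, function(v)
                   if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  records$rel_growth <- records$growth_rate / as.vector(gmax[key])
  records$skip_reason <- reason
  records
}

#' Fit growth models to every eligible literature set and pool them
#'
#' Applies the bootstrap model choice per study-species set and then
#' fits a pooled "average response" on all harmonized relative-growth
#' points (each point weighted equally).
#'
#' @param records Literature data frame.
#' @param nboot Bootstrap replicates for the per-set model choice.
#' @param seed Integer seed.
#' @return A list with `fits` (named list of `growthfit` per eligible
#'   set) and `pooled` (a `growthfit` on all points from eligible sets).
#' @export
fit_literature <- function(records, nboot = 200L, seed = 1L) {
  records <- screen_inclusion(records)
  harm <- harmonize_literature(records, quiet = TRUE)
  key <- interaction(harm$study_id, harm$species, drop = TRUE)
  fits <- list()
  pooled_pts <- NULL
  for (g in levels(key)) {
    sub <- harm[key == g & is.finite(harm$co2) &
                  is.finite(harm$rel_growth), ]
    if (!nrow(sub) || !isTRUE(sub$model_eligible[1])) next
    fit <- tryCatch(
      growthfit(rel_growth ~ co2, sub, model = "auto", seed = seed,
                select_nboot = nboot),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[g]] <- fit
    pooled_pts <- rbind(pooled_pts,
                        sub[, c("co2", "rel_growth")])
  }
  if (is.null(pooled_pts) || nrow(pooled_pts) < 4)
    stop("no model-eligible literature set")
  pooled <- growthfit(rel_growth ~ co2, pooled_pts, model = "auto",
                      seed = seed, select_nboot = nboot)
  list(fits = fits, pooled = pooled)
}
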