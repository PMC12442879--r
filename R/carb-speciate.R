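# Speciation of the seawater CO2 system on the total pH scale.
# Interface units are umol kg-1 (concentrations) and uatm (pCO2); all
# internal arithmetic is in mol kg-1, converted exactly once at the
# boundary.

UMOL <- 1e-6

# Total alkalinity (mol kg-1) at a given total-scale [H+] and DIC, under a
# carb_constants set.  Nutrient totals in mol kg-1.  The balance is
#   TA = HCO3 + 2 CO3 + B(OH)4 + OH + SiO(OH)3 + (HPO4 + 2 PO4 - H3PO4)
#        - Hfree - HSO4 - HF
.alkalinity <- function(h, dic, k, silicate = 0, phosphate = 0) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3  <- dic * k$K1 * k$K2 / denom
  boh4 <- k$BT * k$KB / (k$KB + h)
  oh   <- k$Kw / h
  hfree <- h / (1 + k$ST / k$KS)
  hso4  <- k$ST / (1 + k$KS / hfree)
  hf    <- k$FT / (1 + k$KF / h)
  dp <- h^3 + k$KP1 * h^2 + k$KP1 * k$KP2 * h + k$KP1 * k$KP2 * k$KP3
  h3po4 <- phosphate * h^3 / dp
  hpo4  <- phosphate * k$KP1 * k$KP2 * h / dp
  po4   <- phosphate * k$KP1 * k$KP2 * k$KP3 / dp
  sioh3 <- silicate * k$KSi / (k$KSi + h)
  hco3 + 2 * co3 + boh4 + oh + sioh3 + hpo4 + 2 * po4 - h3po4 -
    hfree - hso4 - hf
}

# Assemble the one-row carbonate state from pH and DIC (mol kg-1).
.carb_state_row <- function(h, dic, k, silicate, phosphate) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  co2  <- dic * h^2 / denom
  hco3 <- dic * k$K1 * h / denom
  co3  <- dic * k$K1 * k$K2 / denom
  ta <- .alkalinity(h, dic, k, silicate, phosphate)
  data.frame(
    ta = ta / UMOL, dic = dic / UMOL, ph_t = -log10(h),
    h_nmol = h * 1e9,
    co2 = co2 / UMOL, hco3 = hco3 / UMOL, co3 = co3 / UMOL,
    pco2 = co2 / k$K0 / UMOL,
    omega_aragonite = k$Ca * co3 / k$Ksp_arag,
    temperature = k$temperature, salinity = k$salinity,
    silicate = silicate / UMOL, phosphate = phosphate / UMOL)
}

.finish_carb <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("carb_state", "data.frame")
  out
}

#' Speciate the carbonate system from total alkalinity and total-scale pH
#'
#' Closed-form speciation: at known pH every non-carbonate contribution to
#' total alkalinity is fixed, so carbonate alkalinity and hence DIC follow
#' directly from the alkalinity balance without iteration.
#'
#' @param ta Total alkalinity, umol kg-1.
#' @param ph pH on the total hydrogen-ion scale.
#' @param temperature Temperature, degrees Celsius.
#' @param salinity Practical salinity.
#' @param silicate Dissolved silicate, umol kg-1 (default 0).
#' @param phosphate Phosphate, umol kg-1. Defaults to 3, the value assumed
#'   for unmeasured culture media; set 0 for nutrient-free speciation.
#' @return A `carb_state` data frame with one row per input: `ta`, `dic`,
#'   `ph_t`, `h_nmol` (total H+, nmol kg-1), `co2`, `hco3`, `co3`
#'   (umol kg-1), `pco2` (uatm, partial pressure via the solubility
#'   constant, no fugacity correction), `omega_aragonite`, and the input
#'   conditions.
#' @examples
#' speciate_ta_ph(2350, 8.05, 15, 33.06, silicate = 3)
#' @seealso [speciate_ta_dic()], [speciate_ta_pco2()]
#' @export
speciate_ta_ph <- function(ta, ph, temperature, salinity,
                           silicate = 0, phosphate = 3) {
  n <- max(length(ta), length(ph))
  ta <- rep_len(ta, n); ph <- rep_len(ph, n)
  silicate <- rep_len(silicate, n); phosphate <- rep_len(phosphate, n)
  stopifnot(all(is.finite(ta)), all(is.finite(ph)))
  if (any(ta <= 0)) stop("ta must be positive")
  if (any(ph < 4 | ph > 11)) stop("ph must lie in [4, 11] (total scale)")
  k <- carb_constants(temperature, salinity)
  rows <- lapply(seq_len(n), function(i) {
    h <- 10^(-ph[i])
    sil <- silicate[i] * UMOL; pho <- phosphate[i] * UMOL
    nca <- .alkalinity(h, 0, k, sil, pho)
    carb_alk <- ta[i] * UMOL - nca
    if (carb_alk <= 0)
      stop(sprintf(paste0("negative carbonate alkalinity at ta=%g, ph=%g ",
                          "(T=%g, S=%g): inputs are inconsistent"),
                   ta[i], ph[i], temperature, salinity))
    denom <- h^2 + k$K1 * h + k$K1 * k$K2
    dic <- carb_alk * denom / (k$K1 * (h + 2 * k$K2))
    .carb_state_row(h, dic, k, sil, pho)
  })
  .finish_carb(rows)
}

# Bracketed Brent search for the pH solving TA(ph, dic) = ta.
.solve_ph <- function(f, lo = 2, hi = 12) {
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("infeasible TA/DIC pair: no pH root in [2, 12]")
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = 1e-11)$root
}

#' Speciate the carbonate system from total alkalinity and DIC
#'
#' Finds total-scale pH by bracketed root-finding on the alkalinity
#' balance (the balance is strictly monotone in pH, so the root is
#' unique), then fills the remaining carbonate-system fields.
#'
#' @inheritParams speciate_ta_ph
#' @param dic Dissolved inorganic carbon, umol kg-1.
#' @return A `carb_state` data frame; see [speciate_ta_ph()].
#' @examples
#' speciate_ta_dic(2560, 2030, 15, 33.06)
#' @export
speciate_ta_dic <- function(ta, dic, temperature, salinity,
                            silicate = 0, phosphate = 3) {
  n <- max(length(ta), length(dic))
  ta <- rep_len(ta, n); dic <- rep_len(dic, n)
  silicate <- rep_len(silicate, n); phosphate <- rep_len(phosphate, n)
  stopifnot(all(is.finite(ta)), all(is.finite(dic)))
  if (any(ta <= 0) || any(dic <= 0)) stop("ta and dic must be positive")
  k <- carb_constants(temperature, salinity)
  rows <- lapply(seq_len(n), function(i) {
    sil <- silicate[i] * UMOL; pho <- phosphate[i] * UMOL
    target <- ta[i] * UMOL; d <- dic[i] * UMOL
    ph <- .solve_ph(function(p)
      .alkalinity(10^(-p), d, k, sil, pho) - target)
    .carb_state_row(10^(-ph), d, k, sil, pho)
  })
  .finish_carb(rows)
}

#' Speciate the carbonate system from total alkalinity and pCO2
#'
#' Dissolved CO2 is fixed by Henry's law (`CO2 = K0 * pCO2`); pH is then
#' found by bracketed root-finding on the alkalinity balance with CO2
#' held fixed, and DIC follows.
#'
#' @inheritParams speciate_ta_ph
#' @param pco2 CO2 partial pressure, uatm.
#' @return A `carb_state` data frame; see [speciate_ta_ph()].
#' @examples
#' speciate_ta_pco2(2300, 423, 15, 33.06)
#' @export
speciate_ta_pco2 <- function(ta, pco2, temperature, salinity,
                             silicate = 0, phosphate = 3) {
  n <- max(length(ta), length(pco2))
  ta <- rep_len(ta, n); pco2 <- rep_len(pco2, n)
  silicate <- rep_len(silicate, n); phosphate <- rep_len(phosphate, n)
  stopifnot(all(is.finite(ta)), all(is.finite(pco2)))
  if (any(ta <= 0) || any(pco2 < 0)) stop("ta must be > 0 and pco2 >= 0")
  k <- carb_constants(temperature, salinity)
  rows <- lapply(seq_len(n), function(i) {
    sil <- silicate[i] * UMOL; pho <- phosphate[i] * UMOL
    target <- ta[i] * UMOL
    co2 <- k$K0 * pco2[i] * UMOL     # uatm -> atm -> mol kg-1
    ph <- .solve_ph(function(p) {
      h <- 10^(-p)
      hco3 <- co2 * k$K1 / h
      co3 <- hco3 * k$K2 / h
      hco3 + 2 * co3 + .alkalinity(h, 0, k, sil, pho) - target
    })
    h <- 10^(-ph)
    dic <- co2 * (1 + k$K1 / h + k$K1 * k$K2 / h^2)
    .carb_state_row(h, dic, k, sil, pho)
  })
  .finish_carb(rows)
}

#' Mean and spread of the carbonate state over a culture's growth period
#'
#' Element-wise arithmetic mean and standard deviation (n = 2) of every
#' carbonate-system field over the start and end states of a culture, the
#' standard way one condition value is assigned to a batch culture whose
#' chemistry drifts as it grows.
#'
#' @param start,end Single-row `carb_state` objects sharing temperature
#'   and salinity.
#' @return A data frame with one row per carbonate-system field and
#'   columns `field`, `mean`, `sd`.
#' @export
mean_state <- function(start, end) {
  stopifnot(inherits(start, "carb_state"), inherits(end, "carb_state"),
            nrow(start) == 1, nrow(end) == 1)
  if (start$temperature != end$temperature ||
      start$salinity != end$salinity)
    stop("start and end states must share temperature and salinity")
  fields <- c("ta", "dic", "ph_t", "h_nmol", "co2", "hco3", "co3",
              "pco2", "omega_aragonite")
  a <- unlist(start[1, fields]); b <- unlist(end[1, fields])
  data.frame(field = fields, mean = (a + b) / 2,
             sd = abs(a - b) / sqrt(2), row.names = NULL)
}

#' Convert a pH value to the total scale
#'
#' Helper for ingesting published records whose pH is reported on the
#' free, seawater or NBS-free conventions. NBS is not supported (it
#' requires activity coefficients); free and seawater scales convert
#' through the sulfate and fluoride ion pairs.
#'
#' @param ph pH value(s).
#' @param scale One of `"total"`, `"free"`, `"seawater"`.
#' @inheritParams speciate_ta_ph
#' @return pH on the total scale.
#' @export
ph_to_total <- function(ph, scale = c("total", "free", "seawater"),
                        temperature, salinity) {
  scale <- match.arg(scale)
  if (scale == "total") return(ph)
  k <- carb_constants(temperature, salinity)
  kf_free <- k$KF / (1 + k$ST / k$KS)
  h <- 10^(-ph)
  h_tot <- switch(scale,
    free = h * (1 + k$ST / k$KS),
    seawater = h * (1 + k$ST / k$KS) / (1 + k$ST / k$KS + k$FT / kf_free))
  -log10(h_tot)
}

# Total-scale [H+] (mol kg-1) consistent with a given dissolved CO2 and
# DIC (both mol kg-1): closed-form root of CO2 = DIC H^2 / (H^2+K1 H+K1 K2).
.h_from_co2_dic <- function(co2, dic, k) {
  if (co2 >= dic) stop("co2 must be smaller than dic")
  a <- dic - co2
  b <- -co2 * k$K1
  cc <- -co2 * k$K1 * k$K2
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}
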