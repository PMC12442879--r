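# Projection of fitted growth kinetics over alkalinity x carbon space,
# percentile-defined optima, and ocean acidification / alkalinity
# enhancement scenario trajectories and thresholds.

#' Specify a TA x DIC lattice
#'
#' Default spans mirror the culture design: 11 alkalinity levels over
#' 2000--3350 umol kg-1 crossed with 8 DIC levels over
#' 1800--3666.67 umol kg-1 at 15 degrees C, salinity 33.06.
#'
#' @param ta_min,ta_max,ta_n Alkalinity range (umol kg-1) and number of
#'   levels.
#' @param dic_min,dic_max,dic_n DIC range (umol kg-1) and number of
#'   levels.
#' @param temperature,salinity,silicate,phosphate Conditions for
#'   speciation.
#' @return A list of class `"grid_spec"`.
#' @export
grid_spec <- function(ta_min = 2000, ta_max = 3350, ta_n = 11,
                      dic_min = 1800, dic_max = 3666.67, dic_n = 8,
                      temperature = 15, salinity = 33.06,
                      silicate = 3, phosphate = 3) {
  stopifnot(ta_min < ta_max, dic_min < dic_max, ta_n >= 1, dic_n >= 1)
  structure(list(ta = seq(ta_min, ta_max, length.out = ta_n),
                 dic = seq(dic_min, dic_max, length.out = dic_n),
                 temperature = temperature, salinity = salinity,
                 silicate = silicate, phosphate = phosphate),
            class = "grid_spec")
}

#' Predict a relative-growth fitness landscape over TA x DIC space
#'
#' Speciate every lattice cell, evaluate the fitted growth curve at the
#' cell's dissolved CO2 (the model depends on carbonate chemistry only
#' through CO2, and through the tightly co-varying H+), and normalise to
#' the landscape maximum. Cells where the pH root-finder has no solution
#' are masked (`feasible = FALSE`) rather than failing. Negative
#' predicted rates (beyond the inhibition zero-crossing) are floored at
#' zero for the relative scale.
#'
#' @param fit A `growthfit`.
#' @param grid A `grid_spec`.
#' @param fraction Optimum threshold: cells with relative rate >=
#'   `fraction` are flagged as within the optimum (default 0.9).
#' @return A data frame of class `"growth_landscape"` with columns `ta`,
#'   `dic`, `ph_t`, `co2`, `h_nmol`, `pco2`, `rate`, `rel_rate`,
#'   `optimum`, `feasible`.
#' @export
predict_landscape <- function(fit, grid = grid_spec(), fraction = 0.9) {
  stopifnot(inherits(fit, "growthfit"), inherits(grid, "grid_spec"))
  cells <- expand.grid(ta = grid$ta, dic = grid$dic,
                       KEEP.OUT.ATTRS = FALSE)
  spec <- lapply(seq_len(nrow(cells)), function(i)
    tryCatch(speciate_ta_dic(cells$ta[i], cells$dic[i],
                             grid$temperature, grid$salinity,
                             grid$silicate, grid$phosphate),
             error = function(e) NULL))
  feas <- !vapply(spec, is.null, logical(1))
  if (!any(feas)) stop("no feasible cell in the landscape grid")
  out <- cells
  out$ph_t <- out$co2 <- out$h_nmol <- out$pco2 <- NA_real_
  sp <- do.call(rbind, spec[feas])
  out$ph_t[feas] <- sp$ph_t
  out$co2[feas] <- sp$co2
  out$h_nmol[feas] <- sp$h_nmol
  out$pco2[feas] <- sp$pco2
  out$rate <- NA_real_
  out$rate[feas] <- pmax(
    mm_rate(out$co2[feas], fit$params$x, fit$params$y, fit$params$s), 0)
  out$rel_rate <- out$rate / max(out$rate[feas])
  out$optimum <- !is.na(out$rel_rate) & out$rel_rate >= fraction
  out$feasible <- feas
  class(out) <- c("growth_landscape", "data.frame")
  out
}

#' @export
plot.growth_landscape <- function(x, ...) {
  ta <- sort(unique(x$ta)); dic <- sort(unique(x$dic))
  z <- matrix(x$rel_rate[order(x$dic, x$ta)], nrow = length(ta))
  graphics::filled.contour(
    ta, dic, z, xlab = "Total alkalinity (umol kg-1)",
    ylab = "DIC (umol kg-1)",
    main = "Relative growth rate", ...)
  invisible(x)
}

#' CO2 and H+ interval sustaining near-maximal growth
#'
#' The optimum is the set of CO2 concentrations at which the fitted
#' curve predicts at least `fraction` of its maximum rate. Endpoints are
#' found by bracketed root-finding; for the saturating model the upper
#' endpoint is infinite. The H+ interval maps the CO2 endpoints through
#' the carbonate system at a stated reference DIC (closed form, no
#' iteration).
#'
#' @param fit A `growthfit`.
#' @param fraction Fraction of the maximum rate defining the optimum
#'   (in (0, 1); default 0.90, i.e. the 90th percentile of the fitted
#'   maximum).
#' @param reference_dic DIC (umol kg-1) at which CO2 endpoints are
#'   mapped to H+.
#' @param temperature,salinity Conditions for the H+ mapping.
#' @return A list with `co2` (lower/upper, umol kg-1), `h_nmol`
#'   (lower/upper, nmol kg-1), `c_opt`, `vmax`, `fraction`.
#' @export
optimum_interval <- function(fit, fraction = 0.9, reference_dic = 2030,
                             temperature = 15, salinity = 33.06) {
  stopifnot(inherits(fit, "growthfit"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  p <- fit$params
  kin <- fit$kinetics
  target <- fraction * kin$vmax
  f <- function(c) mm_rate(c, p$x, p$y, p$s) - target
  if (fit$model == "mm" || p$s == 0) {
    # saturating: x c/(y+c) = f x  has the closed-form root below
    lo <- fraction * p$y / (1 - fraction)
    hi <- Inf; h_hi <- NA_real_
  } else {
    lo <- stats::uniroot(f, c(1e-12, kin$c_opt), tol = 1e-10)$root
    up <- kin$c_opt * 2
    while (f(up) > 0) up <- up * 2
    hi <- stats::uniroot(f, c(kin$c_opt, up), tol = 1e-10)$root
    h_hi <- NA_real_
  }
  k <- carb_constants(temperature, salinity)
  h_lo <- .h_from_co2_dic(lo * 1e-6, reference_dic * 1e-6, k) * 1e9
  if (is.finite(hi))
    h_hi <- .h_from_co2_dic(hi * 1e-6, reference_dic * 1e-6, k) * 1e9
  list(co2 = c(lower = lo, upper = hi),
       h_nmol = c(lower = h_lo, upper = h_hi),
       c_opt = kin$c_opt, vmax = kin$vmax, fraction = fraction)
}

#' Carbonate-chemistry trajectory of an alkalinity-enhancement scenario
#'
#' Starts from seawater equilibrated with the atmosphere (baseline TA at
#' atmospheric pCO2), adds `delta_ta` of alkalinity at constant DIC (the
#' instantaneous, unequilibrated state), then bridges back toward
#' atmospheric equilibrium: for each equilibration fraction `f` the DIC
#' is adjusted so that pCO2 equals
#' `(1 - f) * pCO2_unequilibrated + f * pCO2_atmosphere` (a linear bridge
#' in pCO2). `f = 1` restores atmospheric pCO2 at a DIC above baseline:
#' the carbon stored by the enhancement.
#'
#' @param ta Baseline total alkalinity, umol kg-1.
#' @param pco2_atm Atmospheric pCO2, uatm.
#' @param delta_ta Alkalinity addition, umol kg-1.
#' @param fractions Air-sea equilibration fractions in \[0, 1\].
#' @param temperature,salinity,silicate,phosphate Conditions.
#' @return A `carb_state` data frame: baseline row, then one row per
#'   equilibration fraction, with columns `stage` and `fraction`
#'   prepended.
#' @examples
#' oae_scenario(2300, 423, 300, fractions = c(0, 0.5, 1))
#' @export
oae_scenario <- function(ta = 2300, pco2_atm = 423, delta_ta = 300,
                         fractions = c(0, 0.25, 0.5, 0.75, 1),
                         temperature = 15, salinity = 33.06,
                         silicate = 0, phosphate = 0) {
  if (any(fractions < 0 | fractions > 1))
    stop("equilibration fractions must lie in [0, 1]")
  base <- speciate_ta_pco2(ta, pco2_atm, temperature, salinity,
                           silicate, phosphate)
  ta_new <- ta + delta_ta
  unequil <- speciate_ta_dic(ta_new, base$dic, temperature, salinity,
                             silicate, phosphate)
  rows <- lapply(fractions, function(f) {
    target <- (1 - f) * unequil$pco2 + f * pco2_atm
    speciate_ta_pco2(ta_new, target, temperature, salinity,
                     silicate, phosphate)
  })
  out <- do.call(rbind, c(list(base), rows))
  out <- cbind(stage = c("baseline",
                         ifelse(fractions == 0, "unequilibrated",
                                "equilibrating")),
               fraction = c(NA, fractions), out)
  class(out) <- c("carb_state", "data.frame")
  out
}

#' Alkalinity addition beyond which growth leaves the optimum
#'
#' From a baseline (TA, DIC) state, adding alkalinity at constant DIC
#' draws down CO2; this finds the smallest addition at which the
#' predicted growth rate falls below `fraction` of the fitted maximum,
#' by bisection on the addition. If the baseline state is already below
#' the optimum the threshold is 0; if growth never leaves the optimum
#' within `max_delta` the threshold is `Inf` (sentinel).
#'
#' @param fit A `growthfit`.
#' @param ta,dic Baseline state, umol kg-1 (defaults: mean surface-ocean
#'   TA 2300, DIC 2030).
#' @param temperature,salinity,silicate,phosphate Conditions.
#' @param fraction Optimum fraction (default 0.9).
#' @param max_delta Largest addition searched, umol kg-1.
#' @param tol Bisection tolerance on the addition, umol kg-1.
#' @return A list with `delta_ta` (umol kg-1, 0 or `Inf` sentinels
#'   possible), and at the threshold state `ph_t`, `co2`, `pco2`.
#' @export
alkalinity_threshold <- function(fit, ta = 2300, dic = 2030,
                                 temperature = 15, salinity = 33.06,
                                 silicate = 0, phosphate = 0,
                                 fraction = 0.9, max_delta = 2000,
                                 tol = 0.01) {
  stopifnot(inherits(fit, "growthfit"))
  p <- fit$params
  target <- fraction * fit$kinetics$vmax
  rate_at <- function(delta) {
    st <- speciate_ta_dic(ta + delta, dic, temperature, salinity,
                          silicate, phosphate)
    list(rate = mm_rate(st$co2, p$x, p$y, p$s), state = st)
  }
  f0 <- rate_at(0)
  if (f0$rate < target)
    return(list(delta_ta = 0, ph_t = f0$state$ph_t, co2 = f0$state$co2,
                pco2 = f0$state$pco2,
                note = "baseline already below optimum"))
  fmax <- rate_at(max_delta)
  if (fmax$rate >= target)
    return(list(delta_ta = Inf, ph_t = NA_real_, co2 = NA_real_,
                pco2 = NA_real_,
                note = paste0("no threshold <= ", max_delta)))
  lo <- 0; hi <- max_delta
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rate_at(mid)$rate >= target) lo <- mid else hi <- mid
  }
  st <- rate_at(hi)$state
  list(delta_ta = hi, ph_t = st$ph_t, co2 = st$co2, pco2 = st$pco2,
       note = NA_character_)
}

#' Upper CO2/H+ tolerance under acidification
#'
#' Maps the upper edge of the growth optimum to pCO2 (via the solubility
#' constant) and to H+ at a reference DIC. For the saturating model no
#' decline exists and a sentinel is returned.
#'
#' @inheritParams optimum_interval
#' @return A list with `co2`, `pco2`, `h_nmol` at the upper optimum
#'   edge, or `NA` values and a `note` for the saturating model.
#' @export
oa_threshold <- function(fit, fraction = 0.9, reference_dic = 2030,
                         temperature = 15, salinity = 33.06) {
  stopifnot(inherits(fit, "growthfit"))
  if (fit$model == "mm" || fit$params$s == 0)
    return(list(co2 = NA_real_, pco2 = NA_real_, h_nmol = NA_real_,
                note = "no upper threshold: saturating model"))
  iv <- optimum_interval(fit, fraction, reference_dic, temperature,
                         salinity)
  k <- carb_constants(temperature, salinity)
  list(co2 = unname(iv$co2["upper"]),
       pco2 = unname(iv$co2["upper"]) * 1e-6 / k$K0 * 1e6,
       h_nmol = unname(iv$h_nmol["upper"]), note = NA_character_)
}

#' Percentage decrease between two values
#'
#' `100 * (from - to) / from`: the convention used when growth or CO2
#' declines are quoted as percentages of the starting value.
#'
#' @param from Starting value (non-zero).
#' @param to Ending value.
#' @return Percentage decrease (positive when `to < from`).
#' @examples
#' percent_decrease(1.38, 0.18)  # ~87
#' percent_decrease(8.9, 0.9)    # ~90
#' @export
percent_decrease <- function(from, to) {
  if (any(from == 0)) stop("'from' must be non-zero")
  100 * (from - to) / from
}
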