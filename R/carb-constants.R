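#' Equilibrium constants of the seawater carbonate system
#'
#' Computes the full set of stoichiometric equilibrium constants needed to
#' speciate the seawater CO2 system on the total hydrogen-ion scale, at
#' surface pressure, from temperature and practical salinity.
#'
#' Formulations are fixed to the set conventionally used for coastal
#' carbonate-chemistry work: Weiss (1974) CO2 solubility; Lueker et al.
#' (2000) carbonic acid dissociation (total scale); Dickson (1990) boric
#' acid and bisulfate; Dickson & Riley (1979) hydrogen fluoride;
#' Millero (1995) water, phosphoric acid and silicic acid (converted from
#' the seawater to the total scale); Mucci (1983) aragonite solubility;
#' Uppstrom (1974) total borate; Riley & Tongudai (1967) calcium.
#' Constants are deterministic: identical inputs give bit-identical output.
#'
#' @param temperature Temperature in degrees Celsius.
#' @param salinity Practical salinity.
#' @return An object of class `"carb_constants"`: a list with components
#'   `K0` (mol kg-1 atm-1), `K1`, `K2`, `KB`, `Kw`, `KS` (free scale),
#'   `KF`, `KSi`, `KP1`, `KP2`, `KP3` (total scale, mol kg-1),
#'   `Ksp_arag` (mol2 kg-2), and the salinity-derived totals `BT`, `Ca`,
#'   `ST`, `FT` (mol kg-1), plus `temperature` and `salinity`.
#' @details The Lueker constants were characterised for roughly
#'   2--35 degrees C and salinity 19--43; a warning is issued outside a
#'   0--40 degrees C, 5--45 salinity envelope. Non-finite inputs are an
#'   error.
#' @examples
#' k <- carb_constants(15, 33.06)
#' k$K1 > k$K2
#' @export
carb_constants <- function(temperature, salinity) {
  if (length(temperature) != 1L || length(salinity) != 1L)
    stop("temperature and salinity must be scalars")
  if (!is.finite(temperature) || !is.finite(salinity))
    stop("temperature and salinity must be finite")
  if (temperature < 0 || temperature > 40)
    warning("temperature ", temperature,
            " degC is outside the 0-40 degC validity envelope")
  if (salinity < 0)
    stop("salinity must be non-negative")
  if (salinity < 5 || salinity > 45)
    warning("salinity ", salinity, " is outside the 5-45 validity envelope")

  s  <- salinity
  tk <- temperature + 273.15
  ln_tk <- log(tk)
  sq_s  <- sqrt(s)

  # Weiss (1974) CO2 solubility, mol kg-1 atm-1
  k0 <- exp(-60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
              s * (0.023517 - 0.023656 * (tk / 100) +
                     0.0047036 * (tk / 100)^2))

  # Lueker et al. (2000) carbonic acid, total scale
  pk1 <- 3633.86 / tk - 61.2172 + 9.6777 * ln_tk -
    0.011555 * s + 0.0001152 * s^2
  pk2 <- 471.78 / tk + 25.929 - 3.16967 * ln_tk -
    0.01781 * s + 0.0001122 * s^2
  k1 <- 10^(-pk1)
  k2 <- 10^(-pk2)

  # salinity-proportional totals, mol kg-1
  ist <- 19.924 * s / (1000 - 1.005 * s)    # ionic strength
  st  <- 0.14 / 96.062 * s / 1.80655        # total sulfate
  ft  <- 0.000067 / 18.998 * s / 1.80655    # total fluoride
  bt  <- 0.000232 / 10.811 * s / 1.80655    # total borate
  ca  <- 0.02128 / 40.087 * s / 1.80655     # calcium

  # Dickson (1990) bisulfate, free scale
  ks <- exp(-4276.1 / tk + 141.328 - 23.093 * ln_tk +
              (-13856 / tk + 324.57 - 47.986 * ln_tk) * sqrt(ist) +
              (35474 / tk - 771.54 + 114.723 * ln_tk) * ist -
              2698 / tk * ist^1.5 + 1776 / tk * ist^2 +
              log(1 - 0.001005 * s))

  # Dickson & Riley (1979) HF, free scale
  kf_free <- exp(1590.2 / tk - 12.641 + 1.525 * sqrt(ist) +
                   log(1 - 0.001005 * s))

  free_to_tot <- 1 + st / ks
  sws_to_tot  <- (1 + st / ks) / (1 + st / ks + ft / kf_free)
  kf <- kf_free * free_to_tot

  # Dickson (1990) boric acid, total scale
  kb <- exp((-8966.90 - 2890.53 * sq_s - 77.942 * s +
               1.728 * s^1.5 - 0.0996 * s^2) / tk +
              148.0248 + 137.1942 * sq_s + 1.62142 * s -
              (24.4344 + 25.085 * sq_s + 0.2474 * s) * ln_tk +
              0.053105 * sq_s * tk)

  # Millero (1995) water, seawater scale -> total
  kw <- exp(148.9802 - 13847.26 / tk - 23.6521 * ln_tk +
              (118.67 / tk - 5.977 + 1.0495 * ln_tk) * sq_s -
              0.01615 * s) * sws_to_tot

  # Millero (1995) phosphoric acid, seawater scale -> total
  kp1 <- exp(-4576.752 / tk + 115.525 - 18.453 * ln_tk +
               (-106.736 / tk + 0.69171) * sq_s +
               (-0.65643 / tk - 0.01844) * s) * sws_to_tot
  kp2 <- exp(-8814.715 / tk + 172.0883 - 27.927 * ln_tk +
               (-160.340 / tk + 1.3566) * sq_s +
               (0.37335 / tk - 0.05778) * s) * sws_to_tot
  kp3 <- exp(-3070.75 / tk - 18.141 +
               (17.27039 / tk + 2.81197) * sq_s +
               (-44.99486 / tk - 0.09984) * s) * sws_to_tot

  # Millero (1995) silicic acid (ionic-strength form), seawater -> total
  sq_i <- sqrt(ist)
  ksi <- exp(-8904.2 / tk + 117.385 - 19.334 * ln_tk +
               (-458.79 / tk + 3.5913) * sq_i +
               (188.74 / tk - 1.5998) * ist +
               (-12.1652 / tk + 0.07871) * ist^2 +
               log(1 - 0.001005 * s)) * sws_to_tot

  # Mucci (1983) aragonite solubility product
  ksp_arag <- 10^(-171.945 - 0.077993 * tk + 2903.293 / tk +
                    71.595 * log10(tk) +
                    (-0.068393 + 0.0017276 * tk + 88.135 / tk) * sq_s -
                    0.10018 * s + 0.0059415 * s^1.5)

  structure(
    list(K0 = k0, K1 = k1, K2 = k2, KB = kb, Kw = kw, KS = ks, KF = kf,
         KSi = ksi, KP1 = kp1, KP2 = kp2, KP3 = kp3, Ksp_arag = ksp_arag,
         BT = bt, Ca = ca, ST = st, FT = ft,
         temperature = temperature, salinity = salinity),
    class = "carb_constants")
}

#' @export
print.carb_constants <- function(x, ...) {
  cat("Seawater carbonate-system constants (total scale, surface pressure)\n")
  cat(sprintf("  temperature %.2f degC, salinity %.2f\n",
              x$temperature, x$salinity))
  cat(sprintf("  pK1 %.4f  pK2 %.4f  K0 %.6f mol kg-1 atm-1\n",
              -log10(x$K1), -log10(x$K2), x$K0))
  cat(sprintf("  pKB %.4f  pKw %.4f  BT %.1f umol kg-1\n",
              -log10(x$KB), -log10(x$Kw), x$BT * 1e6))
  invisible(x)
}
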