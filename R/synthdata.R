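# Synthetic batch-culture experiment generator. Emulates the statistical
# structure of a TA x DIC factorial growth study: speciated start
# conditions, optimum-curve growth with additive Gaussian noise, daily
# fluorescence series with multiplicative lognormal noise, harvest at a
# target DIC drawdown, nitrate-driven alkalinity drift, silica drawdown
# and a growth-coupled Fv/Fm response.

#' Species kinetic profile driving the generator
#'
#' A named ground-truth parameter set. Published-style kinetic
#' quantities (`vmax`, `k_half`, `s`) are converted internally to the
#' raw curve parameters via [kinetic_params()].
#'
#' @param name Species label.
#' @param vmax Maximum growth rate, d-1.
#' @param k_half Half-saturation CO2, umol kg-1.
#' @param s Inhibition coefficient, d-1 per umol kg-1.
#' @param sigma_growth Additive growth-rate noise SD, d-1.
#' @param sigma_fluor Multiplicative fluorescence noise SD (lognormal
#'   sdlog), dimensionless.
#' @param sigma_fvfm Additive noise SD on the coupled Fv/Fm response.
#' @return A list of class `"species_profile"` including the raw
#'   parameters `x`, `y`, `s`.
#' @export
species_profile <- function(name, vmax, k_half, s,
                            sigma_growth = 0.05, sigma_fluor = 0.05,
                            sigma_fvfm = 0.02) {
  p <- kinetic_params(vmax, k_half, s)
  structure(list(name = name, vmax = vmax, k_half = k_half, s = s,
                 x = p$x, y = p$y,
                 sigma_growth = sigma_growth, sigma_fluor = sigma_fluor,
                 sigma_fvfm = sigma_fvfm),
            class = "species_profile")
}

#' Default five-species profile set
#'
#' Kinetic anchors follow published species-level estimates for five
#' coastal diatoms: half-saturation constants of 1.22, 1.21, 0.90, 5.55
#' and 0.44 umol kg-1 CO2, with inhibition coefficients spanning
#' 0.0005 (most tolerant, *Melosira* sp.) to 0.0065 (most sensitive,
#' *P. cuspidata*). Maximum rates are set to plausible batch-culture
#' values (0.6--1.4 d-1) since they are normalised away in
#' relative-growth comparisons.
#'
#' @return A named list of [species_profile()] objects.
#' @export
default_species_profiles <- function() {
  list(
    t_nitzschioides = species_profile("T. nitzschioides", 1.10, 1.22, 0.0020),
    c_affinis       = species_profile("C. affinis",       1.40, 1.21, 0.0030),
    p_cuspidata     = species_profile("P. cuspidata",     1.20, 0.90, 0.0065),
    t_rotula        = species_profile("T. rotula",        0.80, 5.55, 0.0010),
    melosira        = species_profile("Melosira sp.",     0.60, 0.44, 0.0005))
}

#' Factorial experiment design
#'
#' The default crosses 11 alkalinity levels (2000--3350 umol kg-1) with
#' 8 DIC levels (1800--3666.67 umol kg-1) at 15 degrees C, salinity
#' 33.06, media nitrate 48 umol kg-1 and silicate 3 umol kg-1, one
#' culture per cell, harvested at a 5--10% DIC drawdown.
#'
#' @param ta_levels,dic_levels Treatment levels, umol kg-1.
#' @param temperature,salinity Culture conditions.
#' @param nitrate Media nitrate, umol kg-1 (caps the alkalinity gain
#'   from nitrate uptake).
#' @param silicate Media dissolved silicate, umol kg-1.
#' @param phosphate Assumed phosphate, umol kg-1.
#' @param drawdown Two-element range of the target fractional DIC
#'   drawdown at harvest.
#' @param max_co2 Feasibility cap on dissolved CO2, umol kg-1: cells
#'   whose speciated CO2 exceeds it are masked as un-culturable
#'   (strongly supersaturated media outgas during handling).
#' @return A list of class `"experiment_design"`.
#' @export
experiment_design <- function(ta_levels = seq(2000, 3350, length.out = 11),
                              dic_levels = seq(1800, 3666.67,
                                               length.out = 8),
                              temperature = 15, salinity = 33.06,
                              nitrate = 48, silicate = 3, phosphate = 3,
                              drawdown = c(0.05, 0.10),
                              max_co2 = 800) {
  stopifnot(length(drawdown) == 2, all(drawdown > 0 & drawdown < 0.5))
  structure(list(ta_levels = ta_levels, dic_levels = dic_levels,
                 temperature = temperature, salinity = salinity,
                 nitrate = nitrate, silicate = silicate,
                 phosphate = phosphate, drawdown = drawdown,
                 max_co2 = max_co2),
            class = "experiment_design")
}

#' Speciated condition list of a factorial design
#'
#' Crosses the TA and DIC levels, speciates every cell, and drops
#' infeasible cells (no pH root, or dissolved CO2 above the design's
#' culturability cap). Warns when fewer than 67 treatments survive.
#'
#' @param design An [experiment_design()].
#' @return A data frame with one row per feasible condition: `ta`,
#'   `dic`, `ph_t`, `co2`, `h_nmol`, `pco2`. The nominal and feasible
#'   cell counts are attached as attributes `n_nominal`, `n_feasible`.
#' @export
design_matrix <- function(design = experiment_design()) {
  stopifnot(inherits(design, "experiment_design"))
  cells <- expand.grid(ta = design$ta_levels, dic = design$dic_levels,
                       KEEP.OUT.ATTRS = FALSE)
  spec <- lapply(seq_len(nrow(cells)), function(i)
    tryCatch(speciate_ta_dic(cells$ta[i], cells$dic[i],
                             design$temperature, design$salinity,
                             design$silicate, design$phosphate),
             error = function(e) NULL))
  feas <- vapply(spec, function(s)
    !is.null(s) && s$co2 <= design$max_co2, logical(1))
  out <- cbind(cells[feas, , drop = FALSE],
               do.call(rbind, spec[feas])[, c("ph_t", "co2", "h_nmol",
                                              "pco2")])
  rownames(out) <- NULL
  if (nrow(out) < 67)
    warning("only ", nrow(out), " feasible treatments (design aims for ",
            ">= 67)")
  attr(out, "n_nominal") <- nrow(cells)
  attr(out, "n_feasible") <- nrow(out)
  out
}

# One synthetic culture at one speciated condition. Returns the culture
# row and its daily fluorescence series. Uses the current RNG stream.
#
# Growth responds to the carbonate chemistry the culture experiences over
# the growth period, i.e. the mean of the start and harvest states (the
# same condition value the analysis assigns to each culture), not the
# nominal start state: over a 5-10% DIC drawdown the dissolved CO2 can
# shift substantially.
.simulate_one <- function(profile, cond, design, culture_id) {
  noise <- stats::rnorm(1, 0, profile$sigma_growth)
  q <- stats::runif(1, design$drawdown[1], design$drawdown[2])

  end_state <- function(dd) {
    # nitrate assimilation raises TA one-for-one, capped by the media
    # pool; Redfield N:C of 16:106 ties it to the carbon drawdown
    no3 <- min(design$nitrate, 16 / 106 * dd)
    speciate_ta_dic(cond$ta + no3, cond$dic - dd, design$temperature,
                    design$salinity, design$silicate, design$phosphate)
  }

  grew <- mm_rate(cond$co2, profile$x, profile$y, profile$s) + noise > 0
  if (grew) {
    end <- end_state(q * cond$dic)
    true_rate <- mm_rate((cond$co2 + end$co2) / 2,
                         profile$x, profile$y, profile$s)
    rate <- true_rate + noise
    if (rate <= 0) grew <- FALSE        # borderline culture: no net growth
  }
  if (!grew) {
    end <- end_state(0)
    true_rate <- mm_rate(cond$co2, profile$x, profile$y, profile$s)
    rate <- true_rate + noise
  }

  # duration: long enough to see the slope, short enough to cap at two
  # weeks for very slow growers
  dur <- if (rate > 0.2) min(14, max(3, ceiling(log(20) / rate))) else 14
  day <- 0:dur
  f0 <- 100
  fluor <- f0 * exp(rate * day) *
    stats::rlnorm(length(day), 0, profile$sigma_fluor)
  dic_end <- end$dic
  ta_end <- end$ta
  dd <- cond$dic - dic_end

  # cell yield and silica pools all scale with the carbon drawdown, so
  # per-cell silica metrics carry no built-in carbonate-chemistry trend
  cells_end <- if (grew) dd * 1e6 * stats::rlnorm(1, 0, 0.1) else 1e6
  si_uptake <- if (grew)
    min(0.9 * design$silicate,
        0.005 * dd * stats::rlnorm(1, 0, 0.15)) else 0
  bsi <- si_uptake * stats::rlnorm(1, 0, 0.2)

  rel <- max(true_rate, 0) / profile$vmax
  fvfm <- max(0, min(0.8, 0.10 + 0.55 * rel +
                       stats::rnorm(1, 0, profile$sigma_fvfm)))

  list(culture = data.frame(
         culture_id = culture_id, species = profile$name,
         ta_start = cond$ta, ta_end = end$ta,
         ph_start = cond$ph_t, ph_end = end$ph_t,
         temperature = design$temperature, salinity = design$salinity,
         dsi_start = design$silicate,
         dsi_end = design$silicate - si_uptake,
         bsi = bsi, cells_end = cells_end, fvfm = fvfm,
         true_rate = true_rate, sim_rate = rate),
       fluorescence = data.frame(culture_id = culture_id, day = day,
                                 fluorescence = fluor))
}

#' Simulate a complete factorial growth experiment
#'
#' Generates one culture per feasible design cell under a species
#' profile: noisy exponential fluorescence series, start/end TA and pH
#' consistent with the imposed DIC drawdown and nitrate-driven
#' alkalinity gain, per-cell silica and Fv/Fm responses. The same seed
#' yields identical output.
#'
#' @param profile A [species_profile()].
#' @param design An [experiment_design()].
#' @param seed Integer seed.
#' @return A list with `cultures` (one row per culture, including the
#'   generator's `true_rate` for validation) and `fluorescence`
#'   (long format), plus the design `conditions`.
#' @examples
#' sim <- simulate_experiment(default_species_profiles()$melosira,
#'                            seed = 1)
#' nrow(sim$cultures)
#' @export
simulate_experiment <- function(profile, design = experiment_design(),
                                seed = 1L) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(design, "experiment_design"))
  conds <- design_matrix(design)
  sims <- with_seed(seed, lapply(seq_len(nrow(conds)), function(i)
    .simulate_one(profile, conds[i, ], design,
                  sprintf("%s_%03d", gsub("[^A-Za-z]", "",
                                          profile$name), i))))
  list(cultures = do.call(rbind, lapply(sims, `[[`, "culture")),
       fluorescence = do.call(rbind, lapply(sims, `[[`, "fluorescence")),
       conditions = conds, seed = seed)
}
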