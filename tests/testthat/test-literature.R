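test_that("eligibility screening applies the strict level count", {
  base <- data.frame(
    study_id = "s1", species = "sp",
    growth_rate = c(0.4, 0.8, 1.0, 0.9),
    param1_name = "co2", param1_value = c(2, 8, 25, 60),
    param2_name = "ta", param2_value = 2300,
    ph_scale = NA_character_, temperature = 15, salinity = 33,
    manipulation = "NaOH/HCl")
  expect_true(all(screen_inclusion(base)$model_eligible))     # 4 levels
  three <- base[1:3, ]
  expect_false(any(screen_inclusion(three)$model_eligible))   # > 3 strict
  # monotone: adding a level never removes eligibility
  five <- rbind(base, within(base[1, ], param1_value <- 100))
  expect_true(all(screen_inclusion(five)$model_eligible))
  # pH-only records cannot place points on a TA/DIC landscape
  ph_only <- within(base, {param2_name <- NA_character_
                           param2_value <- NA_real_})
  scr <- screen_inclusion(ph_only)
  expect_false(any(scr$landscape_eligible))
  aer <- within(base, manipulation <- "CO2 aeration")
  expect_false(any(screen_inclusion(aer)$acid_base_manipulated))
  expect_error(screen_inclusion(base[, -3]), "missing columns")
})

test_that("harmonization dispatches on the reported parameter pair", {
  rec <- function(p1, v1, p2, v2, scale = NA_character_)
    data.frame(study_id = "s", species = "x", growth_rate = 1,
               param1_name = p1, param1_value = v1, param2_name = p2,
               param2_value = v2, ph_scale = scale, temperature = 15,
               salinity = 33.06, manipulation = "NaOH/HCl")
  # direct CO2 passes through untouched
  expect_equal(harmonize_literature(rec("co2", 12.5, "ta", 2300))$co2,
               12.5)
  # TA + DIC goes through the full solver
  ref <- speciate_ta_dic(2560, 2030, 15, 33.06, 0, 0)
  expect_equal(
    harmonize_literature(rec("ta", 2560, "dic", 2030))$co2, ref$co2,
    tolerance = 1e-9)
  # TA + pH, declared free scale, converts the scale first
  ph_free <- -log10(10^(-ref$ph_t) /
                      (1 + carb_constants(15, 33.06)$ST /
                         carb_constants(15, 33.06)$KS))
  got <- harmonize_literature(rec("ta", 2560, "ph", ph_free, "free"))
  expect_equal(got$co2, ref$co2, tolerance = 1e-6)
  # pCO2 alone fixes CO2 by Henry's law
  k <- carb_constants(15, 33.06)
  expect_equal(
    harmonize_literature(rec("pco2", 423, NA_character_, NA_real_))$co2,
    k$K0 * 423, tolerance = 1e-12)
  # an unusable record is skipped with a reason, not an error
  bad <- suppressWarnings(
    harmonize_literature(rec("ph", 8.1, NA_character_, NA_real_)))
  expect_true(is.na(bad$co2))
  expect_match(bad$skip_reason, "insufficient")
  # undeclared pH scale and missing salinity warn
  expect_warning(harmonize_literature(rec("ta", 2560, "ph", 8.0)),
                 "total")
  nosal <- rec("co2", 10, "ta", 2300); nosal$salinity <- NA_real_
  expect_warning(harmonize_literature(nosal), "35")
})

test_that("harmonization is idempotent and bounds relative growth", {
  lit <- make_literature(default_species_profiles()[1:2])
  h1 <- harmonize_literature(lit, quiet = TRUE)
  h2 <- harmonize_literature(h1, quiet = TRUE)
  expect_identical(h1$co2, h2$co2)
  expect_identical(h1$rel_growth, h2$rel_growth)
  expect_true(all(h1$rel_growth > 0 & h1$rel_growth <= 1))
  expect_equal(max(h1$rel_growth), 1)
})

test_that("per-set fits recover their profiles and pool consistently", {
  profs <- default_species_profiles()[c("c_affinis", "t_rotula")]
  lit <- make_literature(profs, n_levels = 10, sigma = 0.03, seed = 2)
  res <- fit_literature(lit, nboot = 150, seed = 1)
  expect_length(res$fits, 2)
  for (i in 1:2) {
    f <- res$fits[[i]]
    # relative-growth scaling preserves k_half, not vmax
    expect_equal(f$kinetics$k_half, profs[[i]]$k_half, tolerance = 0.35)
  }
  # pooling a single study reproduces that study's fit
  one <- make_literature(profs[1], n_levels = 10, sigma = 0.03,
                         seed = 2)
  res1 <- fit_literature(one, nboot = 150, seed = 1)
  expect_equal(coef(res1$pooled), coef(res1$fits[[1]]),
               tolerance = 1e-6)
})

test_that("known profiles are recovered within bootstrap intervals", {
  profs <- default_species_profiles()[c("c_affinis", "t_rotula",
                                        "p_cuspidata")]
  cover <- logical(0)
  for (trial in 1:12) {
    lit <- make_literature(profs, n_levels = 12, sigma = 0.04,
                           seed = 100 + trial)
    harm <- harmonize_literature(lit, quiet = TRUE)
    for (i in seq_along(profs)) {
      sub <- harm[harm$study_id == paste0("study", i), ]
      f <- growthfit(rel_growth ~ co2, sub, model = "mmi", seed = 1)
      f <- bootstrap_ci(f, nreps = 200, seed = trial)
      ci <- f$boot$ci["k_half", ]
      cover <- c(cover, profs[[i]]$k_half >= ci[["lower"]] &&
                   profs[[i]]$k_half <= ci[["upper"]])
    }
  }
  expect_gte(mean(cover), 0.90)
})
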