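make_fit <- function(vmax = 1.2, k_half = 0.9, s = 0.0065,
                     sigma = 0.02, n = 20, cmax = 150, seed = 3) {
  p <- kinetic_params(vmax, k_half, s)
  d <- curve_points(p$x, p$y, p$s, n = n, cmax = cmax)
  set.seed(seed)
  d$rate <- d$rate + rnorm(n, 0, sigma)
  growthfit(rate ~ co2, d, model = if (s > 0) "mmi" else "mm")
}

test_that("the landscape is a pure function of CO2 along contours", {
  fit <- make_fit()
  land <- predict_landscape(fit, grid_spec())
  feas <- land$feasible
  expect_equal(land$rate[feas],
               pmax(mm_rate(land$co2[feas], coef(fit)[["x"]],
                            coef(fit)[["y"]], coef(fit)[["s"]]), 0))
  # two different (TA, DIC) cells sharing one CO2 predict one rate
  a <- speciate_ta_dic(2300, 2100, 15, 33.06, 3, 3)
  b <- speciate_ta_pco2(3000, a$pco2, 15, 33.06, 3, 3)
  expect_equal(b$co2, a$co2, tolerance = 1e-9)
  ra <- mm_rate(a$co2, coef(fit)[["x"]], coef(fit)[["y"]],
                coef(fit)[["s"]])
  rb <- mm_rate(b$co2, coef(fit)[["x"]], coef(fit)[["y"]],
                coef(fit)[["s"]])
  expect_identical(ra, rb)
  # normalisation: the best feasible cell is exactly 1
  expect_identical(max(land$rel_rate[feas]), 1)
  expect_true(all(land$rel_rate[feas] >= 0 & land$rel_rate[feas] <= 1))
  # bit-reproducibility
  expect_identical(predict_landscape(fit, grid_spec()), land)
})

test_that("optimum sets are nested in the percentile fraction", {
  fit <- make_fit()
  iv95 <- optimum_interval(fit, 0.95)
  iv90 <- optimum_interval(fit, 0.90)
  iv80 <- optimum_interval(fit, 0.80)
  expect_gt(iv95$co2[["lower"]], iv90$co2[["lower"]])
  expect_lt(iv95$co2[["upper"]], iv90$co2[["upper"]])
  expect_gt(iv90$co2[["lower"]], iv80$co2[["lower"]])
  expect_lt(iv90$co2[["upper"]], iv80$co2[["upper"]])
  # fraction -> 1 collapses the interval onto the optimum (the
  # half-width shrinks like sqrt(1 - fraction) near the maximum)
  iv999 <- optimum_interval(fit, 1 - 1e-6)
  expect_equal(iv999$co2[["lower"]], fit$kinetics$c_opt,
               tolerance = 0.01)
  expect_equal(iv999$co2[["upper"]], fit$kinetics$c_opt,
               tolerance = 0.01)
  expect_error(optimum_interval(fit, 1.2), "fraction")
  # landscape optimum flag matches the threshold rule
  land <- predict_landscape(fit, grid_spec(), fraction = 0.9)
  expect_identical(land$optimum,
                   !is.na(land$rel_rate) & land$rel_rate >= 0.9)
})

test_that("a narrow-niche profile has a narrower optimum than a broad one", {
  steno <- make_fit(1.2, 0.90, 0.0065)   # highest CO2/H+ sensitivity
  eury <- make_fit(0.6, 0.44, 0.0005)    # lowest sensitivity
  w_s <- diff(optimum_interval(steno, 0.9)$co2)
  w_e <- diff(optimum_interval(eury, 0.9)$co2)
  expect_lt(w_s, w_e)
})

test_that("alkalinity enhancement scenarios bridge back to equilibrium", {
  sc <- oae_scenario(2300, 423, 300, fractions = c(0, 0.5, 1))
  base <- sc[sc$stage == "baseline", ]
  expect_equal(base$pco2, 423, tolerance = 1e-6)
  uneq <- sc[sc$stage == "unequilibrated", ]
  expect_equal(uneq$dic, base$dic, tolerance = 1e-6)  # constant DIC
  expect_lt(uneq$pco2, base$pco2)
  full <- sc[which(sc$fraction == 1), ]
  expect_equal(full$pco2, 423, tolerance = 1e-3 / 423)
  expect_gt(full$dic, base$dic)    # stored carbon
  # zero addition leaves the baseline untouched at every fraction
  sc0 <- oae_scenario(2300, 423, 0, fractions = c(0, 0.5, 1))
  expect_equal(sc0$pco2, rep(423, 4), tolerance = 1e-6)
  expect_equal(sc0$dic, rep(sc0$dic[1], 4), tolerance = 1e-6)
})

test_that("alkalinity thresholds match a brute-force sweep", {
  fit <- make_fit()
  th <- alkalinity_threshold(fit, ta = 2300, dic = 2030, fraction = 0.9)
  expect_true(is.finite(th$delta_ta))
  # 1 umol kg-1 sweep oracle
  target <- 0.9 * fit$kinetics$vmax
  deltas <- seq(0, 1000, by = 1)
  co2 <- speciate_ta_dic(2300 + deltas, 2030, 15, 33.06,
                         silicate = 0, phosphate = 0)$co2
  rates <- mm_rate(co2, coef(fit)[["x"]], coef(fit)[["y"]],
                   coef(fit)[["s"]])
  sweep_th <- deltas[which(rates < target)[1]]
  expect_lte(abs(th$delta_ta - sweep_th), 1)
  # comparative statics: a higher low-CO2 optimum edge trips earlier
  fussy <- make_fit(0.8, 5.55, 0.0010)
  th_fussy <- alkalinity_threshold(fussy, ta = 2300, dic = 2030,
                                   fraction = 0.9)
  expect_lt(th_fussy$delta_ta, th$delta_ta)
  # an extremely tolerant curve never trips within the bracket
  tough <- make_fit(0.6, 0.05, 1e-6, sigma = 0.001)
  th_tough <- alkalinity_threshold(tough, ta = 2300, dic = 2030,
                                   fraction = 0.5, max_delta = 500)
  expect_identical(th_tough$delta_ta, Inf)
})

test_that("acidification thresholds expose the upper optimum edge", {
  fit <- make_fit()
  oa <- oa_threshold(fit, 0.9)
  iv <- optimum_interval(fit, 0.9)
  expect_equal(oa$co2, iv$co2[["upper"]])
  expect_equal(oa$h_nmol, iv$h_nmol[["upper"]])
  oa95 <- oa_threshold(fit, 0.95)
  expect_lt(oa95$co2, oa$co2)      # nestedness in the fraction
  sat <- make_fit(1.2, 4, 0, sigma = 0.01)
  expect_match(oa_threshold(sat, 0.9)$note, "no upper threshold")
})

test_that("percentage declines follow the reporting convention", {
  expect_equal(percent_decrease(10, 1), 90)
  expect_equal(percent_decrease(2, 2), 0)
  expect_lt(percent_decrease(2, 3), 0)
  expect_error(percent_decrease(0, 1), "non-zero")
})
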