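test_that("rate function obeys its closed-form identities", {
  expect_identical(mm_rate(0, 1.5, 5, 0.005), 0)
  expect_equal(mm_rate(3, 2, 3, 0), 1)        # half saturation at c = y
  expect_equal(mm_rate(33.73, 1.5, 5, 0.005), 1.138, tolerance = 5e-4)
  expect_error(mm_rate(-1, 1, 1), "non-negative")
})

test_that("derived kinetics match the closed-form optimum", {
  d <- derive_kinetics(1.5, 5, 0.005)
  expect_equal(d$c_opt, sqrt(1.5 * 5 / 0.005) - 5, tolerance = 1e-12)
  expect_equal(d$vmax, mm_rate(d$c_opt, 1.5, 5, 0.005))
  expect_equal(mm_rate(d$k_half, 1.5, 5, 0.005), d$vmax / 2,
               tolerance = 1e-9)
  expect_lt(d$k_half, d$c_opt)
  mm <- derive_kinetics(2, 3, 0)
  expect_equal(mm$vmax, 2)
  expect_equal(mm$k_half, 3)
  expect_true(is.na(mm$c_opt))
  expect_error(derive_kinetics(1, 10, 0.2), "monotone")
})

test_that("kinetic_params inverts derive_kinetics", {
  for (case in list(c(1.2, 0.9, 0.0065), c(0.6, 0.44, 0.0005),
                    c(0.8, 5.55, 0.001), c(2, 3, 0))) {
    p <- kinetic_params(case[1], case[2], case[3])
    d <- derive_kinetics(p$x, p$y, p$s)
    expect_equal(d$vmax, case[1], tolerance = 1e-8)
    expect_equal(d$k_half, case[2], tolerance = 1e-8)
  }
})

test_that("the optimum curve has a single interior maximum", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(1, 0.3, 2); y <- runif(1, 0.2, 8)
    s <- runif(1, 1e-4, 8e-3)
    if (x * y / s <= y^2) next
    d <- derive_kinetics(x, y, s)
    cc <- seq(1e-3, d$c_opt * 3, length.out = 400)
    r <- mm_rate(cc, x, y, s)
    asc <- cc < d$c_opt; desc <- cc > d$c_opt
    expect_true(all(diff(r[asc]) > 0))
    expect_true(all(diff(r[desc]) < 0))
    expect_true(all(r <= d$vmax + 1e-12))
  }
})

test_that("noise-free data are refit to high relative accuracy", {
  for (truth in list(c(1.5, 5, 0.005), c(1.2, 0.9, 0.003),
                     c(0.62, 0.45, 5e-4))) {
    d <- curve_points(truth[1], truth[2], truth[3])
    f <- growthfit(rate ~ co2, d, model = "mmi")
    expect_equal(unname(coef(f)), truth, tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("saturating data fitted with the inhibited form give S ~ 0", {
  d <- curve_points(1.5, 5, 0)
  f <- growthfit(rate ~ co2, d, model = "mmi")
  expect_lte(coef(f)[["s"]], 1e-8)
  expect_equal(coef(f)[["x"]], 1.5, tolerance = 1e-6)
  expect_equal(coef(f)[["y"]], 5, tolerance = 1e-6)
})

test_that("rows flagged as excluded never influence the fit", {
  d <- curve_points(1.5, 5, 0.005)
  d$excluded <- FALSE
  d2 <- rbind(d, data.frame(co2 = c(10, 60), rate = c(5, -3),
                            excluded = TRUE))
  f1 <- growthfit(rate ~ co2, d, model = "mmi")
  f2 <- growthfit(rate ~ co2, d2, model = "mmi")
  expect_equal(coef(f2), coef(f1), tolerance = 1e-9)
})

test_that("fit validates its inputs", {
  d <- curve_points(1.5, 5, 0.005, n = 3)
  expect_error(growthfit(rate ~ co2, d, model = "mmi"), "at least 4")
  expect_error(growthfit(rate ~ co2,
                         data.frame(co2 = c(5, 5, 5, 5),
                                    rate = c(1, 1, 1, 1)),
                         model = "mm"), "equal")
})

test_that("bootstrap intervals are deterministic, ordered, order-invariant", {
  d <- curve_points(1.5, 5, 0.005, n = 16, cmax = 250)
  set.seed(99); d$rate <- d$rate + rnorm(16, 0, 0.03)
  f <- growthfit(rate ~ co2, d, model = "mmi")
  b1 <- bootstrap_ci(f, nreps = 200, seed = 7)
  b2 <- bootstrap_ci(f, nreps = 200, seed = 7)
  expect_identical(b1$boot$ci, b2$boot$ci)
  est <- c(coef(f), vmax = f$kinetics$vmax, k_half = f$kinetics$k_half,
           c_opt = f$kinetics$c_opt)
  ci <- b1$boot$ci
  for (q in c("x", "y", "vmax", "k_half", "c_opt")) {
    expect_lte(ci[q, "lower"], est[[q]])
    expect_gte(ci[q, "upper"], est[[q]])
  }
  # equivariance to point order
  perm <- sample(nrow(d))
  f3 <- growthfit(rate ~ co2, d[perm, ], model = "mmi")
  b3 <- bootstrap_ci(f3, nreps = 200, seed = 7)
  expect_equal(b3$boot$ci, b1$boot$ci, tolerance = 1e-6)
})

test_that("noise-free data give collapsed bootstrap intervals", {
  d <- curve_points(1.5, 5, 0.005, n = 14)
  f <- growthfit(rate ~ co2, d, model = "mmi")
  b <- bootstrap_ci(f, nreps = 150, seed = 3)
  expect_lt(max(b$boot$ci[, "upper"] - b$boot$ci[, "lower"]), 1e-5)
  bp <- bootstrap_ci(f, nreps = 150, mode = "parametric", seed = 3)
  expect_lt(max(bp$boot$ci[, "upper"] - bp$boot$ci[, "lower"]), 1e-5)
})

test_that("model selection keeps inhibition only when supported", {
  d_decl <- curve_points(1.2, 1, 0.004, n = 16, cmax = 250)
  set.seed(5); d_decl$rate <- d_decl$rate + rnorm(16, 0, 0.02)
  sel <- select_growth_model(d_decl$co2, d_decl$rate, nreps = 150,
                             seed = 2)
  expect_identical(sel$model, "mmi")
  d_sat <- curve_points(1.2, 4, 0, n = 16)
  set.seed(6); d_sat$rate <- d_sat$rate + rnorm(16, 0, 0.02)
  sel2 <- select_growth_model(d_sat$co2, d_sat$rate, nreps = 150,
                              seed = 2)
  expect_identical(sel2$model, "mm")
  # literature-style four-level design must return a decision
  d4 <- data.frame(co2 = c(2, 8, 25, 60))
  d4$rate <- mm_rate(d4$co2, 1.1, 2, 0) + c(0.01, -0.01, 0.01, -0.01)
  expect_no_error(select_growth_model(d4$co2, d4$rate, nreps = 120,
                                      seed = 3))
})

test_that("growthfit methods are mutually consistent", {
  d <- curve_points(1.5, 5, 0.005, n = 14)
  set.seed(21); d$rate <- d$rate + rnorm(14, 0, 0.03)
  f <- growthfit(rate ~ co2, d, model = "mmi")
  expect_equal(fitted(f) + residuals(f), d$rate)
  expect_equal(predict(f, data.frame(co2 = 10)),
               mm_rate(10, coef(f)[["x"]], coef(f)[["y"]],
                       coef(f)[["s"]]))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(14L, 3L))
  expect_identical(simulate(f, nsim = 3, seed = 1), sims)
  ci <- confint(f, parm = "k_half", nreps = 120, seed = 2)
  expect_identical(rownames(ci), "k_half")
  expect_output(print(summary(bootstrap_ci(f, nreps = 120, seed = 2))),
                "confidence intervals")
})
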