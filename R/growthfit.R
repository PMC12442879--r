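# Optimum-curve growth kinetics: Michaelis-Menten uptake with an optional
# linear inhibition term,
#   V(c) = X c / (Y + c) - S c,   S >= 0,
# fitted to growth rate versus dissolved CO2. With S = 0 this is the
# standard Michaelis-Menten saturation curve (model "mm"); with S > 0 the
# curve has a single interior optimum (model "mmi").

#' Growth rate predicted by the optimum-curve model
#'
#' Evaluates `V(c) = X c / (Y + c) - S c`. With `s = 0` this is the
#' standard Michaelis-Menten form.
#'
#' @param co2 Dissolved CO2, umol kg-1 (non-negative).
#' @param x Uptake amplitude, d-1.
#' @param y Saturation parameter, umol kg-1.
#' @param s Linear inhibition (sensitivity) coefficient,
#'   d-1 per umol kg-1; must be >= 0.
#' @return Growth rate, d-1.
#' @examples
#' mm_rate(33.73, x = 1.5, y = 5, s = 0.005)
#' @export
mm_rate <- function(co2, x, y, s = 0) {
  if (any(co2 < 0)) stop("co2 must be non-negative")
  if (any(s < 0)) stop("s must be non-negative")
  x * co2 / (y + co2) - s * co2
}

#' Derived kinetic quantities of a fitted optimum curve
#'
#' Converts raw curve parameters into the quantities reported for growth
#' kinetics: the maximum rate `vmax`, the CO2 concentration `c_opt` at
#' which it is attained, and the half-saturation constant `k_half`.
#'
#' For `s > 0` the stationary point is `c_opt = sqrt(x y / s) - y`,
#' `vmax = V(c_opt)`, and `k_half` is defined as the ascending-limb
#' concentration at which the rate first reaches `vmax / 2` (found by
#' bracketed root-finding on `(0, c_opt)`); this reduces to the usual
#' Michaelis-Menten meaning in the `s = 0` limit, where `vmax = x`,
#' `k_half = y` and `c_opt` is undefined (`NA`).
#'
#' @inheritParams mm_rate
#' @return A list with `vmax` (d-1), `k_half` (umol kg-1) and `c_opt`
#'   (umol kg-1, `NA` when `s = 0`).
#' @examples
#' derive_kinetics(1.5, 5, 0.005)  # c_opt = sqrt(1500) - 5
#' @export
derive_kinetics <- function(x, y, s = 0) {
  stopifnot(length(x) == 1, length(y) == 1, length(s) == 1)
  if (!(x > 0) || !(y > 0)) stop("x and y must be positive")
  if (s < 0) stop("s must be non-negative")
  if (s == 0)
    return(list(vmax = x, k_half = y, c_opt = NA_real_))
  if (x * y / s <= y^2)
    stop("monotone curve: no interior maximum for these parameters")
  c_opt <- sqrt(x * y / s) - y
  vmax <- mm_rate(c_opt, x, y, s)
  k_half <- stats::uniroot(function(c) mm_rate(c, x, y, s) - vmax / 2,
                           c(1e-12, c_opt), tol = 1e-12)$root
  list(vmax = vmax, k_half = k_half, c_opt = c_opt)
}

#' Raw curve parameters from reported kinetic quantities
#'
#' Inverse of [derive_kinetics()]: recovers `(x, y)` from a target
#' `(vmax, k_half)` at a given inhibition coefficient `s`, by nested
#' bracketed root-finding (vmax is strictly increasing in `x` at fixed
#' `y`; the half-saturation point is strictly increasing in `y`). Used to
#' build generator profiles from published kinetic estimates.
#'
#' @param vmax Target maximum rate, d-1.
#' @param k_half Target half-saturation constant, umol kg-1.
#' @param s Inhibition coefficient, d-1 per umol kg-1.
#' @return A list with `x`, `y`, `s`.
#' @examples
#' p <- kinetic_params(1.2, 0.9, 0.0065)
#' derive_kinetics(p$x, p$y, p$s)
#' @export
kinetic_params <- function(vmax, k_half, s = 0) {
  stopifnot(vmax > 0, k_half > 0, s >= 0)
  if (s == 0) return(list(x = vmax, y = k_half, s = 0))
  x_for_y <- function(y) {
    f <- function(x) derive_kinetics(x, y, s)$vmax - vmax
    lo <- max(vmax, y * s) * (1 + 1e-9)  # interior optimum needs x > y s
    hi <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  g <- function(y) {
    x <- x_for_y(y)
    derive_kinetics(x, y, s)$k_half - k_half
  }
  lo <- k_half; hi <- k_half * 1.5
  while (g(hi) < 0) hi <- hi * 1.5
  while (g(lo) > 0) lo <- lo / 1.5
  y <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  list(x = x_for_y(y), y = y, s = s)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so package code never disturbs user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Core least-squares engine: Levenberg-Marquardt on the residuals with an
# analytic Jacobian, S constrained non-negative. p is c(x, y) or c(x, y, s).
.fit_lm <- function(co2, rate, start, inhibition) {
  resid_fn <- function(p) rate - mm_rate(co2, p[1], p[2],
                                         if (inhibition) p[3] else 0)
  jac_fn <- function(p) {
    d <- p[2] + co2
    j <- cbind(-co2 / d, p[1] * co2 / d^2)
    if (inhibition) j <- cbind(j, co2)
    j
  }
  lower <- if (inhibition) c(1e-10, 1e-10, 0) else c(1e-10, 1e-10)
  # iteration-cap warnings are routine for the discarded multi-start and
  # bootstrap-replicate fits; the best converged solution wins on SSE
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = pmax(start, lower), lower = lower,
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)))
  list(par = fit$par, sse = sum(fit$fvec^2), info = fit$info)
}

# Data-driven starting values: X from the maximum rate, Y from the CO2
# nearest half the maximum rate, S from the terminal slope of the curve.
.start_values <- function(co2, rate, inhibition) {
  rmax <- max(rate)
  x0 <- max(rmax, 1e-3)
  y0 <- co2[which.min(abs(rate - rmax / 2))]
  y0 <- max(y0, 1e-3)
  if (!inhibition) return(c(x0, y0))
  ord <- order(co2)
  n <- length(co2)
  tail_i <- ord[c(max(1, n - 1), n)]
  slope <- diff(rate[tail_i]) / max(diff(co2[tail_i]), 1e-9)
  s0 <- max(-slope, 1e-5)
  c(x0 * 1.2, y0, s0)
}

.fit_multistart <- function(co2, rate, inhibition, seed = 1L,
                            nstart = 5L) {
  base <- .start_values(co2, rate, inhibition)
  starts <- list(base)
  jit <- with_seed(seed, matrix(stats::runif((nstart - 1) * length(base),
                                             -0.7, 0.7),
                                nrow = nstart - 1))
  for (i in seq_len(nstart - 1))
    starts[[i + 1]] <- base * exp(jit[i, ])
  best <- NULL
  for (st in starts) {
    f <- tryCatch(.fit_lm(co2, rate, st, inhibition),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$sse < best$sse)) best <- f
  }
  if (is.null(best))
    stop("growth-model fit failed to converge from any starting value")
  best
}

#' Fit an optimum-curve growth model to growth-rate versus CO2 data
#'
#' Fits the Michaelis-Menten-with-inhibition curve
#' `V(c) = X c / (Y + c) - S c` (model `"mmi"`) or its standard
#' saturating special case with `S = 0` (model `"mm"`) by
#' Levenberg-Marquardt least squares with data-driven, deterministically
#' jittered multi-starts. With `model = "auto"` both forms are fitted and
#' the inhibited form is kept only when the bootstrap confidence interval
#' of `S` excludes zero (i.e. a decline at high CO2 is actually
#' supported); the evidence is stored in the returned object.
#'
#' @param formula A two-sided formula `rate ~ co2`.
#' @param data A data frame containing the variables of `formula`.
#'   Rows flagged in an `excluded` column (if present) are dropped from
#'   fitting but kept in the stored data.
#' @param model `"mmi"`, `"mm"` or `"auto"`.
#' @param seed Integer seed controlling the deterministic multi-start
#'   jitter (and, for `model = "auto"`, the selection bootstrap).
#' @param nstart Number of starting points for the multi-start search.
#' @param select_nboot Bootstrap replicates used by the `"auto"` model
#'   choice.
#' @return An object of class `"growthfit"`: a list with components
#'   `params` (x, y, s), `kinetics` (vmax, k_half, c_opt), `model`
#'   (`"mmi"` or `"mm"`), `r_squared`, `n`, `data`, `seed`, `selection`
#'   (present after `"auto"`), and after [bootstrap_ci()] also `boot`.
#' @examples
#' d <- data.frame(co2 = seq(0.5, 100, length.out = 12))
#' d$rate <- mm_rate(d$co2, 1.5, 5, 0.005)
#' fit <- growthfit(rate ~ co2, d, model = "mmi")
#' coef(fit)
#' @seealso [bootstrap_ci()], [predict.growthfit()], [derive_kinetics()]
#' @export
growthfit <- function(formula, data, model = c("auto", "mmi", "mm"),
                      seed = 1L, nstart = 5L, select_nboot = 200L) {
  model <- match.arg(model)
  mf <- stats::model.frame(formula, data)
  rate <- stats::model.response(mf)
  co2 <- mf[[2L]]
  keep <- rep(TRUE, length(rate))
  if (!is.null(data$excluded)) {
    keep <- !as.logical(data$excluded)[as.integer(rownames(mf))]
    keep[is.na(keep)] <- TRUE
  }
  co2_fit <- co2[keep]; rate_fit <- rate[keep]
  ok <- is.finite(co2_fit) & is.finite(rate_fit)
  co2_fit <- co2_fit[ok]; rate_fit <- rate_fit[ok]
  n <- length(rate_fit)
  if (any(co2_fit < 0)) stop("co2 values must be non-negative")
  if (length(unique(co2_fit)) < 2) stop("co2 values must not all be equal")

  if (model == "auto") {
    sel <- select_growth_model(co2_fit, rate_fit, nreps = select_nboot,
                               seed = seed)
    fit <- growthfit(formula,
                     data.frame(rate = rate_fit, co2 = co2_fit,
                                check.names = FALSE) |>
                       stats::setNames(c(all.vars(formula)[1],
                                         all.vars(formula)[2])),
                     model = sel$model, seed = seed, nstart = nstart)
    fit$selection <- sel
    fit$data <- data.frame(co2 = co2, rate = rate, excluded = !keep)
    return(fit)
  }

  inhibition <- model == "mmi"
  npar <- if (inhibition) 3L else 2L
  if (n < npar + 1L)
    stop("need at least ", npar + 1L, " points to fit model '", model, "'")
  best <- .fit_multistart(co2_fit, rate_fit, inhibition, seed, nstart)
  p <- best$par
  s_hat <- if (inhibition) p[3] else 0
  # boundary fit: an S pinned at zero is the saturating model
  if (inhibition && s_hat <= 1e-12) {
    mm <- .fit_multistart(co2_fit, rate_fit, FALSE, seed, nstart)
    p <- c(mm$par, 0); s_hat <- 0
    best <- mm
  }
  kin <- if (s_hat > 0) derive_kinetics(p[1], p[2], s_hat)
         else list(vmax = p[1], k_half = p[2], c_opt = NA_real_)
  sstot <- sum((rate_fit - mean(rate_fit))^2)
  r2 <- if (sstot > 0) 1 - best$sse / sstot else NA_real_
  structure(list(
    params = list(x = p[1], y = p[2], s = s_hat),
    kinetics = kin,
    model = model, r_squared = r2, n = n,
    data = data.frame(co2 = co2, rate = rate, excluded = !keep),
    seed = seed, nstart = nstart,
    boot = NULL, selection = NULL), class = "growthfit")
}

#' Choose between the inhibited and saturating growth models
#'
#' Fits the inhibited optimum curve, bootstraps its inhibition
#' coefficient `S`, and keeps the inhibited form only when the percentile
#' confidence interval of `S` excludes zero; otherwise a decline in
#' growth at high CO2 is not evident and the standard saturating form is
#' selected.
#'
#' @param co2,rate Paired observations (umol kg-1, d-1).
#' @param nreps Bootstrap replicates (>= 100).
#' @param level Confidence level for the interval on `S`.
#' @param seed Integer seed.
#' @return A list with `model` (`"mmi"` or `"mm"`), the bootstrap
#'   interval `s_ci`, and `s_hat`.
#' @export
select_growth_model <- function(co2, rate, nreps = 200L, level = 0.95,
                                seed = 1L) {
  if (length(co2) < 4) stop("model selection needs at least 4 points")
  d <- data.frame(rate = rate, co2 = co2)
  fit <- tryCatch(growthfit(rate ~ co2, d, model = "mmi", seed = seed),
                  error = function(e) NULL)
  if (is.null(fit) || fit$params$s <= 1e-12)
    return(list(model = "mm", s_ci = c(0, 0),
                s_hat = if (is.null(fit)) NA_real_ else fit$params$s))
  bs <- bootstrap_ci(fit, nreps = nreps, mode = "nonparametric",
                     seed = seed, level = level)
  ci <- bs$boot$ci["s", ]
  model <- if (ci[["lower"]] > 0) "mmi" else "mm"
  list(model = model, s_ci = c(ci[["lower"]], ci[["upper"]]),
       s_hat = fit$params$s)
}

#' Bootstrap confidence intervals for a fitted growth model
#'
#' Nonparametric mode resamples observation pairs with replacement;
#' parametric mode resamples residuals and adds them to fitted values.
#' Every replicate is refit from the point estimate; replicates that fail
#' to converge (or whose parameters admit no interior optimum when one is
#' required) are dropped and counted. Percentile intervals are attached
#' for the raw parameters and the derived kinetic quantities.
#'
#' @param object A `growthfit`.
#' @param nreps Number of bootstrap replicates (>= 100; default 1000).
#' @param mode `"nonparametric"` (default) or `"parametric"`.
#' @param seed Integer seed; the same seed reproduces the intervals
#'   exactly.
#' @param level Confidence level (default 0.95).
#' @return The `growthfit` with a `boot` component: `draws` (retained
#'   parameter and kinetics vectors), `ci` (matrix with rows x, y, s,
#'   vmax, k_half, c_opt), `n_fail`, `mode`, `level`, `seed`.
#' @examples
#' d <- data.frame(co2 = seq(1, 90, length.out = 14))
#' d$rate <- mm_rate(d$co2, 1.5, 5, 0.005) + c(0.02, -0.02)
#' fit <- bootstrap_ci(growthfit(rate ~ co2, d, model = "mmi"),
#'                     nreps = 200, seed = 7)
#' fit$boot$ci
#' @export
bootstrap_ci <- function(object, nreps = 1000L,
                         mode = c("nonparametric", "parametric"),
                         seed = 1L, level = 0.95) {
  stopifnot(inherits(object, "growthfit"))
  mode <- match.arg(mode)
  if (nreps < 100) stop("nreps must be at least 100")
  d <- object$data[!object$data$excluded &
                     is.finite(object$data$co2) &
                     is.finite(object$data$rate), ]
  d <- d[order(d$co2, d$rate), ]   # canonical order: resampling is then
  co2 <- d$co2; rate <- d$rate     # invariant to input row order
  n <- length(rate)
  inhibition <- object$model == "mmi"
  p0 <- with(object$params, if (inhibition) c(x, y, s) else c(x, y))
  fitted0 <- mm_rate(co2, object$params$x, object$params$y,
                     object$params$s)
  res0 <- rate - fitted0

  one_rep <- function(co2_b, rate_b) {
    f <- tryCatch(.fit_lm(co2_b, rate_b, p0, inhibition),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    p <- f$par
    s <- if (inhibition) p[3] else 0
    kin <- tryCatch(
      if (s > 0) derive_kinetics(p[1], p[2], s)
      else list(vmax = p[1], k_half = p[2], c_opt = NA_real_),
      error = function(e) NULL)
    if (is.null(kin)) return(NULL)
    c(x = p[1], y = p[2], s = s, vmax = kin$vmax,
      k_half = kin$k_half, c_opt = kin$c_opt)
  }

  draws <- with_seed(seed, {
    out <- vector("list", nreps)
    for (r in seq_len(nreps)) {
      if (mode == "nonparametric") {
        idx <- sample.int(n, n, replace = TRUE)
        out[[r]] <- one_rep(co2[idx], rate[idx])
      } else {
        rate_b <- fitted0 + sample(res0, n, replace = TRUE)
        out[[r]] <- one_rep(co2, rate_b)
      }
    }
    out
  })
  ok <- !vapply(draws, is.null, logical(1))
  n_fail <- sum(!ok)
  if (n_fail > nreps / 2)
    stop("more than half of the bootstrap replicates failed (",
         n_fail, "/", nreps, ")")
  draws <- do.call(rbind, draws[ok])
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  object$boot <- list(draws = as.data.frame(draws), ci = ci,
                      n_fail = n_fail, mode = mode, level = level,
                      seed = seed, nreps = nreps)
  object
}
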