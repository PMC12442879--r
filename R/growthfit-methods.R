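# S3 methods for "growthfit" objects.

#' @export
print.growthfit <- function(x, ...) {
  lbl <- if (x$model == "mmi")
    "Michaelis-Menten with linear inhibition" else
      "Michaelis-Menten (saturating)"
  cat("Optimum-curve growth model:", lbl, "\n")
  cat(sprintf("  n = %d retained points, R-squared = %.3f\n",
              x$n, x$r_squared))
  cat(sprintf("  X = %.4g d-1, Y = %.4g umol kg-1, S = %.4g\n",
              x$params$x, x$params$y, x$params$s))
  cat(sprintf("  Vmax = %.3f d-1, K1/2 = %.3f umol kg-1%s\n",
              x$kinetics$vmax, x$kinetics$k_half,
              if (is.na(x$kinetics$c_opt)) "" else
                sprintf(", C_opt = %.2f umol kg-1", x$kinetics$c_opt)))
  if (!is.null(x$boot))
    cat(sprintf("  %s bootstrap: %d replicates (%d failed)\n",
                x$boot$mode, x$boot$nreps, x$boot$n_fail))
  invisible(x)
}

#' @export
coef.growthfit <- function(object, ...) {
  with(object$params, c(x = x, y = y, s = s))
}

#' Predict growth rates from a fitted optimum curve
#'
#' @param object A `growthfit`.
#' @param newdata Optional data frame with a `co2` column (or a numeric
#'   vector of CO2 values); defaults to the fitted data.
#' @param ... Unused.
#' @return Predicted growth rates, d-1.
#' @export
predict.growthfit <- function(object, newdata = NULL, ...) {
  co2 <- if (is.null(newdata)) object$data$co2
         else if (is.data.frame(newdata)) newdata$co2
         else as.numeric(newdata)
  mm_rate(co2, object$params$x, object$params$y, object$params$s)
}

#' @export
fitted.growthfit <- function(object, ...) {
  predict(object)
}

#' @export
residuals.growthfit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' Simulate growth observations from a fitted optimum curve
#'
#' Parametric simulation: fitted values plus Gaussian noise with the
#' residual standard deviation of the fit (computed on retained points).
#'
#' @param object A `growthfit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed (the caller's RNG state is restored).
#' @param ... Unused.
#' @return A data frame with one column per simulation, rows matching
#'   the retained fitted data.
#' @export
simulate.growthfit <- function(object, nsim = 1, seed = NULL, ...) {
  keep <- !object$data$excluded
  mu <- predict(object)[keep]
  res <- residuals(object)[keep]
  sigma <- sqrt(sum(res^2) / max(1, length(res) - 3))
  gen <- function() mu + stats::rnorm(length(mu), 0, sigma)
  sims <- if (is.null(seed)) replicate(nsim, gen())
          else with_seed(seed, replicate(nsim, gen()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL,
                                       paste0("sim_", seq_len(nsim)))))
}

#' Bootstrap percentile confidence intervals of a growth fit
#'
#' Requires [bootstrap_ci()] to have been run (or runs it with defaults
#' when the fit carries none).
#'
#' @param object A `growthfit`.
#' @param parm Quantities to report (subset of x, y, s, vmax, k_half,
#'   c_opt).
#' @param level Confidence level; must match the stored bootstrap run,
#'   else the bootstrap is re-run at this level.
#' @param ... Passed on to [bootstrap_ci()] when a run is needed.
#' @return A matrix of lower/upper bounds.
#' @export
confint.growthfit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$boot) || object$boot$level != level)
    object <- bootstrap_ci(object, level = level, ...)
  ci <- object$boot$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.growthfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.growthfit")
}

#' @export
print.summary.growthfit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$boot)) {
    cat(sprintf("  %.0f%% percentile confidence intervals:\n",
                100 * f$boot$level))
    print(round(f$boot$ci, 4))
  }
  if (!is.null(f$selection))
    cat(sprintf("  model choice: '%s' (bootstrap CI of S: [%.4g, %.4g])\n",
                f$model, f$selection$s_ci[1], f$selection$s_ci[2]))
  invisible(x)
}

#' Plot a fitted optimum growth curve
#'
#' Retained points, excluded points (grey), the fitted curve, and, when
#' a bootstrap is attached, a pointwise percentile band.
#'
#' @param x A `growthfit`.
#' @param n_curve Number of curve evaluation points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.growthfit <- function(x, n_curve = 200, ...) {
  d <- x$data
  cc <- seq(0, max(d$co2, na.rm = TRUE) * 1.05, length.out = n_curve)
  pred <- mm_rate(cc, x$params$x, x$params$y, x$params$s)
  graphics::plot(d$co2, d$rate, col = ifelse(d$excluded, "grey60", "black"),
                 pch = 19, xlab = "CO2 (umol kg-1)",
                 ylab = "Growth rate (d-1)", ...)
  if (!is.null(x$boot)) {
    band <- apply(x$boot$draws, 1, function(p)
      mm_rate(cc, p[["x"]], p[["y"]], p[["s"]]))
    qs <- apply(band, 1, stats::quantile,
                probs = c((1 - x$boot$level) / 2,
                          1 - (1 - x$boot$level) / 2))
    graphics::polygon(c(cc, rev(cc)), c(qs[1, ], rev(qs[2, ])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(cc, pred, lwd = 2, col = "steelblue4")
  invisible(x)
}
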