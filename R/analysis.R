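#' Convergence rate at the consensus crossing
#'
#' The convergence rate is the time derivative of the mean cooperativity
#' where it crosses zero, the region where the approach to consensus is
#' exponential. It is estimated as the ordinary least-squares slope over
#' `n_points` recorded points centred on the point closest to zero at the
#' first zero crossing (later re-crossings are ignored); the window is
#' shifted inward when it would overrun the series ends.
#'
#' @param mean_b mean-cooperativity series.
#' @param time matching time grid in sweeps.
#' @param n_points regression window width in points (default 10).
#' @return List of class `rate_estimate`: `rate` (per sweep), `window`
#'   (index range used), `r_squared`, `crossing_time` (linear-interpolated
#'   zero crossing, sweeps).
#' @export
convergence_rate <- function(mean_b, time, n_points = 10L) {
  stopifnot(length(mean_b) == length(time), n_points >= 2L)
  n <- length(mean_b)
  s <- sign(mean_b)
  cross <- which(s[-n] * s[-1L] <= 0 & (s[-n] != 0 | s[-1L] != 0))
  if (any(mean_b == 0)) cross <- sort(unique(c(cross, which(mean_b == 0))))
  if (length(cross) == 0L)
    stop(errorCondition("series never crosses zero",
                        class = c("coopnet_no_crossing", "error")))
  k <- cross[1L]
  k2 <- min(k + 1L, n)
  centre <- if (abs(mean_b[k]) <= abs(mean_b[k2])) k else k2
  np <- min(n_points, n)
  lo <- centre - (np - 1L) %/% 2L
  lo <- min(max(lo, 1L), n - np + 1L)
  win <- lo:(lo + np - 1L)
  fit <- stats::lm(y ~ t, data = data.frame(y = mean_b[win], t = time[win]))
  sst <- sum((mean_b[win] - mean(mean_b[win]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  crossing_time <- if (mean_b[k2] != mean_b[k]) {
    time[k] + (0 - mean_b[k]) * (time[k2] - time[k]) /
      (mean_b[k2] - mean_b[k])
  } else time[k]
  structure(list(rate = unname(stats::coef(fit)[2L]),
                 window = range(win),
                 r_squared = r2,
                 crossing_time = crossing_time),
            class = "rate_estimate")
}

#' Bootstrap rate of an ensemble
#'
#' Rate of the ensemble mean trajectory, with a bootstrap standard error
#' obtained by resampling realizations (rows) with replacement and
#' re-estimating the rate of each resampled ensemble mean.
#'
#' @param result an `ensemble_result`.
#' @param n_boot number of bootstrap resamples.
#' @param n_points regression window, see [convergence_rate()].
#' @param seed seed for the resampling.
#' @return List with `rate`, `se`, `boot` (the resampled rates, `NA` where
#'   a resample never crossed zero) and the full `estimate`.
#' @export
rate_bootstrap <- function(result, n_boot = 200L, n_points = 10L,
                           seed = 1L) {
  stopifnot(inherits(result, "ensemble_result"))
  est <- convergence_rate(colMeans(result$mean_b), result$time, n_points)
  set.seed(as.integer(seed))
  n_real <- nrow(result$mean_b)
  boot <- vapply(seq_len(n_boot), function(b) {
    rows <- sample.int(n_real, n_real, replace = TRUE)
    m <- colMeans(result$mean_b[rows, , drop = FALSE])
    tryCatch(convergence_rate(m, result$time, n_points)$rate,
             coopnet_no_crossing = function(e) NA_real_)
  }, numeric(1))
  list(rate = est$rate, se = stats::sd(boot, na.rm = TRUE), boot = boot,
       estimate = est)
}

#' Convergence rate across a parameter sweep
#'
#' Runs one ensemble per configuration and estimates the rate of each
#' ensemble mean trajectory with a bootstrap standard error. Configurations
#' whose ensemble mean never crosses zero are kept in the table with an
#' `NA` rate and `crossed = FALSE`.
#'
#' @param configs named list: each element a list with fields `network`
#'   (a [network_config()] or [social_network()]), `params`
#'   (a [model_params()]) and optionally `intervention`.
#' @param schedule a [sim_schedule()] shared by all points.
#' @param parameter numeric vector of the swept values, one per config
#'   (defaults to the element names coerced to numbers).
#' @param n_boot bootstrap resamples per point.
#' @return Data frame with columns `parameter`, `rate`, `se`, `r_squared`,
#'   `crossing_time`, `crossed`, `n_realizations`, plus the list of
#'   ensembles as attribute `"ensembles"`.
#' @export
rate_vs_parameter <- function(configs, schedule, parameter = NULL,
                              n_boot = 200L) {
  if (is.null(parameter)) parameter <- as.numeric(names(configs))
  stopifnot(length(parameter) == length(configs))
  ensembles <- vector("list", length(configs))
  rows <- lapply(seq_along(configs), function(k) {
    cf <- configs[[k]]
    res <- run_ensemble(cf$network, cf$params, schedule,
                        intervention = cf$intervention)
    ensembles[[k]] <<- res
    rb <- tryCatch(rate_bootstrap(res, n_boot = n_boot,
                                  seed = schedule$base_seed + k),
                   coopnet_no_crossing = function(e) NULL)
    if (is.null(rb)) {
      data.frame(parameter = parameter[k], rate = NA_real_, se = NA_real_,
                 r_squared = NA_real_, crossing_time = NA_real_,
                 crossed = FALSE, n_realizations = schedule$n_realizations)
    } else {
      data.frame(parameter = parameter[k], rate = rb$rate, se = rb$se,
                 r_squared = rb$estimate$r_squared,
                 crossing_time = rb$estimate$crossing_time, crossed = TRUE,
                 n_realizations = schedule$n_realizations)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "ensembles") <- ensembles
  out
}

#' Tipping-point location by stochastic bisection
#'
#' Finds the external field strength at which the ensemble splits evenly
#' between cooperative and defective outcomes. Each candidate field is
#' scored by the cooperative fraction of a seeded ensemble under
#' capped-horizon classification (see [cooperative_fraction()]); the
#' bracket is narrowed on the 0.5 crossing until its width is at most
#' `tolerance`. The bracket ends are measured first and must straddle 0.5.
#'
#' For testing, `fraction_fun` can replace the simulation by any function
#' `phi -> fraction`.
#'
#' @param network a [network_config()] or [social_network()].
#' @param params a [model_params()]; its `phi` is overridden pointwise.
#' @param schedule a [sim_schedule()]; `n_realizations` is the per-point
#'   ensemble size.
#' @param phi_bracket length-2 numeric, initial search bracket.
#' @param tolerance final bracket width.
#' @param fraction_fun optional override returning the cooperative fraction
#'   at a given field value.
#' @return List of class `tipping_estimate`: `phi_critical` (final bracket
#'   midpoint), `bracket`, `fraction_curve` (data frame of `phi`,
#'   `fraction`, `n`), `n_realizations_per_point`.
#' @export
estimate_tipping_point <- function(network, params, schedule,
                                   phi_bracket = c(0, 0.05),
                                   tolerance = 0.004,
                                   fraction_fun = NULL) {
  stopifnot(length(phi_bracket) == 2L, tolerance > 0)
  lo <- min(phi_bracket); hi <- max(phi_bracket)
  point <- 0L
  measure <- function(phi) {
    point <<- point + 1L
    if (!is.null(fraction_fun)) return(fraction_fun(phi))
    p <- params; p$phi <- phi
    sch <- schedule
    # distinct, reproducible seed block per bisection point
    sch$base_seed <- schedule$base_seed + 10000L * point
    cooperative_fraction(run_ensemble(network, p, sch))
  }
  curve <- data.frame(phi = numeric(0), fraction = numeric(0),
                      n = integer(0))
  note <- function(phi, fr) {
    curve[nrow(curve) + 1L, ] <<- list(phi, fr, schedule$n_realizations)
    fr
  }
  f_lo <- note(lo, measure(lo))
  f_hi <- note(hi, measure(hi))
  if (f_lo >= 0.5 || f_hi < 0.5)
    stop(errorCondition(
      sprintf("bracket does not straddle 0.5: fraction(%g) = %.3f, fraction(%g) = %.3f",
              lo, f_lo, hi, f_hi),
      class = c("coopnet_bracket_error", "error")))
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    f_mid <- note(mid, measure(mid))
    if (f_mid >= 0.5) hi <- mid else lo <- mid
  }
  structure(list(phi_critical = (lo + hi) / 2, bracket = c(lo, hi),
                 fraction_curve = curve,
                 n_realizations_per_point = schedule$n_realizations),
            class = "tipping_estimate")
}

#' @export
print.tipping_estimate <- function(x, ...) {
  cat(sprintf("<tipping_estimate> phi_critical = %.4f (bracket [%.4f, %.4f], %d points x %d realizations)\n",
              x$phi_critical, x$bracket[1], x$bracket[2],
              nrow(x$fraction_curve), x$n_realizations_per_point))
  invisible(x)
}

#' Exponential-stage diagnostics of the approach to consensus
#'
#' For a trajectory converging to full cooperation, fits
#' `log(1 - mean_b)` versus time piecewise after the zero crossing: a
#' two-segment linear fit whose breakpoint is chosen by least squares over
#' a grid of candidate points. The first (mid-stage) segment captures the
#' exponential regime; a late-stage slope smaller in magnitude than the
#' mid-stage slope indicates the slow, fluctuation-limited end game near
#' homogeneity (critical slowing down).
#'
#' @param mean_b mean-cooperativity series.
#' @param time matching time grid (sweeps).
#' @param min_points minimum points per segment.
#' @return List of class `stage_diagnostics`: `applicable`,
#'   `boundary_time`, `mid_slope`, `late_slope`, `r_squared` (of the
#'   two-segment fit), `window` (index range analysed). When the
#'   trajectory does not converge toward +1 the diagnostics are marked
#'   inapplicable.
#' @export
exponential_stage_diagnostics <- function(mean_b, time, min_points = 5L) {
  stopifnot(length(mean_b) == length(time))
  n <- length(mean_b)
  inapplicable <- function() {
    structure(list(applicable = FALSE, boundary_time = NA_real_,
                   mid_slope = NA_real_, late_slope = NA_real_,
                   r_squared = NA_real_, window = c(NA_integer_,
                                                    NA_integer_)),
              class = "stage_diagnostics")
  }
  if (mean_b[n] <= 0.5) return(inapplicable())
  start <- which(mean_b > 0)[1L]
  keep <- which(seq_len(n) >= start & mean_b < 1)
  if (length(keep) < 2L * min_points) return(inapplicable())
  y <- log(1 - mean_b[keep]); t <- time[keep]
  m <- length(y)
  cand <- (min_points):(m - min_points)
  sse <- vapply(cand, function(k) {
    f1 <- stats::lm.fit(cbind(1, t[1:k]), y[1:k])
    f2 <- stats::lm.fit(cbind(1, t[(k + 1):m]), y[(k + 1):m])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }, numeric(1))
  k <- cand[which.min(sse)]
  fit1 <- stats::lm(y1 ~ t1, data = data.frame(y1 = y[1:k], t1 = t[1:k]))
  fit2 <- stats::lm(y2 ~ t2,
                    data = data.frame(y2 = y[(k + 1):m], t2 = t[(k + 1):m]))
  tot <- sum((y - mean(y))^2)
  structure(list(applicable = TRUE, boundary_time = t[k],
                 mid_slope = unname(stats::coef(fit1)[2L]),
                 late_slope = unname(stats::coef(fit2)[2L]),
                 r_squared = 1 - min(sse) / tot,
                 window = c(keep[1L], keep[m])),
            class = "stage_diagnostics")
}
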