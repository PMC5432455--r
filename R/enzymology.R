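# Enzymological characterization math: Michaelis-Menten kinetics,
# catalytic-efficiency and fold/percent arithmetic, first-order thermal
# inactivation half-life, thermal-shift Tm calling, and pH/temperature
# activity profiling.

#' Fit the Michaelis-Menten equation to rate data
#'
#' Least-squares fit of `v = Vmax * S / (Km + S)` by Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Initialization is deterministic:
#' `Vmax0 = 1.05 * max(rate)` and `Km0` the substrate concentration whose
#' rate is closest to `Vmax0 / 2`.
#'
#' @param substrate substrate concentrations (mg/mL), >= 4 distinct
#'   values.
#' @param rate reaction rates (U/mg), positive.
#' @param mw_kda optional enzyme molecular weight (kDa) used to derive
#'   `kcat = Vmax * mw_kda / 60` (U/mg = umol min^-1 mg^-1; kDa =
#'   mg/umol).
#' @return An `xf_mm_fit`: list with `Km`, `Vmax`, `se_Km`, `se_Vmax`,
#'   `r_squared`, `kcat` (or `NA`), `fitted` and the underlying `model`.
#' @export
fit_michaelis_menten <- function(substrate, rate, mw_kda = NULL) {
  if (length(substrate) != length(rate)) stop("substrate/rate length mismatch")
  if (length(unique(substrate)) < 4) {
    stop("at least 4 distinct substrate concentrations are required")
  }
  if (any(rate <= 0)) stop("rates must be positive")
  if (length(unique(rate)) == 1) {
    stop("all rates equal: Km is unidentifiable")
  }
  vmax0 <- 1.05 * max(rate)
  km0 <- substrate[which.min(abs(rate - vmax0 / 2))]
  df <- data.frame(S = substrate, v = rate)
  model <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e))
  )
  est <- stats::coef(model)
  se <- tryCatch(summary(model)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  fitted_v <- stats::fitted(model)
  ss_res <- sum((rate - fitted_v)^2)
  ss_tot <- sum((rate - mean(rate))^2)
  kcat <- if (!is.null(mw_kda)) unname(est["Vmax"]) * mw_kda / 60 else NA_real_
  structure(list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
                 se_Km = unname(se["Km"]), se_Vmax = unname(se["Vmax"]),
                 r_squared = 1 - ss_res / ss_tot, kcat = kcat,
                 fitted = fitted_v, model = model),
            class = "xf_mm_fit")
}

#' @export
print.xf_mm_fit <- function(x, ...) {
  cat(sprintf("<MM fit: Km = %.4g mg/mL, Vmax = %.4g U/mg, r2 = %.4f>\n",
              x$Km, x$Vmax, x$r_squared))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat turnover number, s^-1.
#' @param Km Michaelis constant, mg/mL.
#' @return kcat/Km in mL mg^-1 s^-1.
#' @export
catalytic_efficiency <- function(kcat, Km) {
  if (any(Km == 0)) stop("Km must be non-zero")
  kcat / Km
}

#' Fold change of a value relative to a reference
#' @param value,reference numeric; `reference` non-zero.
#' @export
fold_change <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  value / reference
}

#' Signed percent change of a value relative to a reference
#' @param value,reference numeric; `reference` non-zero.
#' @return `100 * (value - reference) / reference`.
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (value - reference) / reference
}

#' Half-up rounding at the report layer
#'
#' Internal math is kept at full precision; printed tables round half-up
#' (0.05 -> 0.1), unlike base R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fit a thermal-inactivation curve and report the half-life
#'
#' First-order mode fits `ln(residual) = -k t` (no intercept: residual is
#' 1 at time zero by definition) and reports `t_half = ln(2) / k`.
#' Interpolation mode instead returns the time at which the
#' piecewise-linear residual curve first crosses 0.5.
#'
#' @param time incubation times (min), >= 3 points.
#' @param residual residual activity as a fraction of the original; the
#'   time-zero value should be ~1.
#' @param mode `"first-order"` (default) or `"interpolation"`.
#' @return An `xf_inactivation`: list with `k` (min^-1), `t_half` (min),
#'   `mode`.
#' @export
fit_inactivation <- function(time, residual,
                             mode = c("first-order", "interpolation")) {
  mode <- match.arg(mode)
  if (length(time) != length(residual)) stop("time/residual length mismatch")
  if (length(time) < 3) stop("at least 3 time points are required")
  if (any(residual <= 0) || any(residual > 1.2)) {
    stop("residual activities must be in (0, 1.2]")
  }
  ord <- order(time)
  time <- time[ord]
  residual <- residual[ord]
  if (mode == "first-order") {
    fit <- stats::lm(log(residual) ~ 0 + time)
    k <- -unname(stats::coef(fit)[1])
    if (k <= 0) stop("no decay detected: fitted rate constant is not positive")
    t_half <- log(2) / k
  } else {
    below <- which(residual < 0.5)
    if (length(below) == 0) {
      if (any(residual == 0.5)) {
        t_half <- time[which(residual == 0.5)[1]]
        k <- log(2) / t_half
        return(structure(list(k = k, t_half = t_half, mode = mode),
                         class = "xf_inactivation"))
      }
      stop("half-life beyond observation window: residual never falls below 0.5")
    }
    j <- below[1]
    if (j == 1) stop("residual is below 0.5 already at the first time point")
    t_half <- time[j - 1] + (0.5 - residual[j - 1]) *
      (time[j] - time[j - 1]) / (residual[j] - residual[j - 1])
    k <- log(2) / t_half
  }
  structure(list(k = k, t_half = t_half, mode = mode),
            class = "xf_inactivation")
}

#' @export
print.xf_inactivation <- function(x, ...) {
  cat(sprintf("<inactivation (%s): k = %.4g min^-1, t1/2 = %.4g min>\n",
              x$mode, x$k, x$t_half))
  invisible(x)
}

#' Call the melting temperature from a thermal-shift fluorescence curve
#'
#' The derivative melting curve dF/dT is computed by central differences
#' after optional moving-average smoothing; Tm is the temperature of the
#' derivative maximum, refined below grid resolution by parabolic
#' interpolation through the peak and its two neighbours. A derivative
#' maximum at the grid boundary means the unfolding transition is not
#' bracketed by the scan and is an error.
#'
#' @param temperature sorted temperature grid (degrees C), >= 10 points.
#' @param fluorescence fluorescence readings (arbitrary units).
#' @param smoothing_window odd moving-average window length (default 5;
#'   1 disables smoothing).
#' @return An `xf_melt`: list with `tm` (degrees C), `derivative`
#'   (data.frame `temperature`, `dFdT`) and `smoothing`.
#' @export
call_tm <- function(temperature, fluorescence, smoothing_window = 5) {
  if (length(temperature) != length(fluorescence)) {
    stop("temperature/fluorescence length mismatch")
  }
  if (length(temperature) < 10) stop("at least 10 points are required")
  if (is.unsorted(temperature, strictly = TRUE)) {
    stop("temperature grid must be strictly increasing")
  }
  if (smoothing_window %% 2 != 1 || smoothing_window < 1) {
    stop("smoothing_window must be odd and >= 1")
  }
  f <- fluorescence
  if (smoothing_window > 1) {
    f <- as.numeric(stats::filter(fluorescence,
                                  rep(1 / smoothing_window,
                                      smoothing_window),
                                  sides = 2))
  }
  ok <- which(!is.na(f))
  tt <- temperature[ok]
  ff <- f[ok]
  n <- length(tt)
  if (n < 5) stop("too few points remain after smoothing")
  i <- 2:(n - 1)
  d <- (ff[i + 1] - ff[i - 1]) / (tt[i + 1] - tt[i - 1])
  td <- tt[i]
  pk <- which.max(d)
  if (pk == 1 || pk == length(d)) {
    stop("transition not bracketed: derivative peak at the grid boundary")
  }
  # parabolic refinement through (td, d) at pk - 1, pk, pk + 1
  x0 <- td[pk - 1]; x1 <- td[pk]; x2 <- td[pk + 1]
  y0 <- d[pk - 1]; y1 <- d[pk]; y2 <- d[pk + 1]
  denom <- (y0 - 2 * y1 + y2)
  tm <- if (abs(denom) < .Machine$double.eps) x1 else {
    x1 + 0.5 * (x2 - x1) * (y0 - y2) / denom
  }
  structure(list(tm = tm,
                 derivative = data.frame(temperature = td, dFdT = d),
                 smoothing = sprintf("%d-point moving average",
                                     smoothing_window)),
            class = "xf_melt")
}

#' @export
print.xf_melt <- function(x, ...) {
  cat(sprintf("<melt: Tm = %.2f degC (%s)>\n", x$tm, x$smoothing))
  invisible(x)
}

#' Analyze a pH or temperature activity profile
#'
#' Activities are renormalized so the maximum is 100%. The optimum is the
#' grid argmax (ties to the lower `x`); the stable range is the widest
#' contiguous grid run with activity at or above the retention threshold
#' that contains the optimum.
#'
#' @param x pH or temperature grid.
#' @param activity activities (any positive scale).
#' @param retention_threshold stability threshold as a fraction of the
#'   maximum (default 0.85).
#' @return An `xf_profile`: list with `x`, `activity` (percent of max),
#'   `optimum`, `stable_range` (length-2, grid endpoints),
#'   `retention_threshold`.
#' @export
profile_analysis <- function(x, activity, retention_threshold = 0.85) {
  if (length(x) != length(activity)) stop("x/activity length mismatch")
  if (length(x) < 3) stop("at least 3 grid points are required")
  ord <- order(x)
  x <- x[ord]
  activity <- activity[ord]
  act <- 100 * activity / max(activity)
  opt_idx <- which(act == max(act))[1]   # tie -> lower x
  ok <- act >= 100 * retention_threshold
  # contiguous run containing the optimum (the optimum is always >= threshold)
  lo <- opt_idx
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- opt_idx
  while (hi < length(x) && ok[hi + 1]) hi <- hi + 1
  structure(list(x = x, activity = act, optimum = x[opt_idx],
                 stable_range = c(x[lo], x[hi]),
                 retention_threshold = retention_threshold),
            class = "xf_profile")
}

#' @export
print.xf_profile <- function(x, ...) {
  cat(sprintf("<profile: optimum %.4g, stable range [%.4g, %.4g] at >= %.0f%%>\n",
              x$optimum, x$stable_range[1], x$stable_range[2],
              100 * x$retention_threshold))
  invisible(x)
}
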