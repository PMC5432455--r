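test_that("noiseless Michaelis-Menten data are recovered to high precision", {
  g <- gen_mm_curve(Km = 2.32, Vmax = 100, noise_cv = 0)
  fit <- fit_michaelis_menten(g$data$S, g$data$v)
  expect_equal(fit$Km, 2.32, tolerance = 1e-6)
  expect_equal(fit$Vmax, 100, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # v(S = Km) = Vmax / 2 on the fitted curve
  expect_equal(fit$Vmax * fit$Km / (fit$Km + fit$Km), fit$Vmax / 2)
})

test_that("the fit is scale-equivariant in the rates", {
  g <- gen_mm_curve(noise_cv = 0.05, seed = 3)
  f1 <- fit_michaelis_menten(g$data$S, g$data$v)
  f2 <- fit_michaelis_menten(g$data$S, g$data$v * 7)
  expect_equal(f2$Km, f1$Km, tolerance = 1e-6)
  expect_equal(f2$Vmax, 7 * f1$Vmax, tolerance = 1e-6)
})

test_that("5% noise leaves the median recovered Km within 10% of truth", {
  km_hat <- vapply(1:100, function(s) {
    g <- gen_mm_curve(Km = 2.32, Vmax = 100, noise_cv = 0.05, seed = s)
    fit_michaelis_menten(g$data$S, g$data$v)$Km
  }, numeric(1))
  expect_lt(abs(median(km_hat) - 2.32) / 2.32, 0.10)
})

test_that("kinetics input contracts hold", {
  expect_error(fit_michaelis_menten(1:3, c(1, 2, 3)), "4 distinct")
  expect_error(fit_michaelis_menten(1:5, rep(2, 5)), "unidentifiable")
  expect_error(fit_michaelis_menten(1:5, c(-1, 1, 2, 3, 3)), "positive")
})

test_that("kcat follows from Vmax and the molecular weight", {
  g <- gen_mm_curve(Km = 2.32, Vmax = 100, noise_cv = 0)
  fit <- fit_michaelis_menten(g$data$S, g$data$v, mw_kda = 22.1)
  # U/mg * kDa = umol min^-1 mg^-1 * mg umol^-1 = min^-1; /60 -> s^-1
  expect_equal(fit$kcat, 100 * 22.1 / 60, tolerance = 1e-6)
})

test_that("efficiency and change arithmetic reproduce printed kinetics", {
  expect_equal(round_half_up(catalytic_efficiency(1246.8, 2.32)), 537.4)
  expect_equal(round_half_up(catalytic_efficiency(954.1, 3.33)), 286.5)
  expect_equal(round_half_up(percent_change(2.32, 3.33)), -30.3)
  expect_equal(round_half_up(fold_change(3677, 1593)) , 2.3)
  expect_error(catalytic_efficiency(1, 0), "non-zero")
  expect_error(percent_change(1, 0), "non-zero")
  expect_equal(round_half_up(0.05, 1), 0.1)  # half-up, not banker's
  expect_equal(round_half_up(-0.05, 1), -0.1)
})

test_that("first-order inactivation recovers a planted rate exactly", {
  t <- seq(0, 300, by = 30)
  resid <- exp(-log(2) / 71 * t)
  fit <- fit_inactivation(t, resid)
  expect_equal(fit$t_half, 71, tolerance = 1e-6)
  expect_equal(fit$k, log(2) / 71, tolerance = 1e-9)
  # residual exactly 0.5 at t = 240 under first-order through (0, 1)
  t2 <- c(0, 120, 240)
  fit2 <- fit_inactivation(t2, 2^(-t2 / 240))
  expect_equal(fit2$t_half, 240, tolerance = 1e-9)
})

test_that("interpolation mode crosses 0.5 piecewise-linearly", {
  fit <- fit_inactivation(c(0, 10, 20), c(1.0, 0.6, 0.4),
                          mode = "interpolation")
  expect_equal(fit$t_half, 15.0)
  expect_error(fit_inactivation(c(0, 10, 20), c(1, 0.9, 0.8),
                                mode = "interpolation"),
               "beyond observation window")
})

test_that("interpolation and first-order agree on exponential data", {
  t <- seq(0, 200, by = 10)
  resid <- exp(-log(2) / 95 * t)
  fo <- fit_inactivation(t, resid, mode = "first-order")$t_half
  li <- fit_inactivation(t, resid, mode = "interpolation")$t_half
  expect_equal(fo, 95, tolerance = 1e-9)
  expect_lt(abs(li - fo), 10)  # within one grid step
})

test_that("Tm calling finds a planted sigmoid midpoint", {
  g <- gen_melt_curve(tm = 61.3, slope = 1.5, noise_sd = 0)
  res <- call_tm(g$data$temperature, g$data$fluorescence)
  expect_equal(res$tm, 61.3, tolerance = 0.25)
  # a constant baseline does not move the derivative peak
  res2 <- call_tm(g$data$temperature, g$data$fluorescence + 5)
  expect_equal(res2$tm, res$tm, tolerance = 1e-9)
})

test_that("Tm is recovered within a grid step across baselines and scales", {
  for (tm in c(52.3, 56.5, 58.6, 61.3)) {
    for (amp in c(1, 40)) {
      g <- gen_melt_curve(tm = tm, amplitude = amp, baseline = 3,
                          noise_sd = 0)
      expect_lt(abs(call_tm(g$data$temperature, g$data$fluorescence)$tm -
                      tm), 0.5)
    }
  }
})

test_that("the taller of two transitions wins the Tm call", {
  t <- seq(30, 80, by = 0.5)
  f <- 1 / (1 + exp((56.5 - t) / 1.2)) +
    0.4 / (1 + exp((70 - t) / 1.2))
  expect_equal(call_tm(t, f)$tm, 56.5, tolerance = 0.5)
})

test_that("an unbracketed transition is an error", {
  t <- seq(30, 80, by = 0.5)
  rising <- exp((t - 80) / 5)     # derivative still climbing at the edge
  expect_error(call_tm(t, rising), "not bracketed")
  expect_error(call_tm(t[1:5], rising[1:5]), "at least 10")
})

test_that("activity profiles renormalize, find optima and stable ranges", {
  g <- gen_activity_profile(optimum = 60, width = 8, noise_cv = 0)
  prof <- profile_analysis(g$data$x, g$data$activity)
  expect_equal(prof$optimum, 60)
  expect_equal(max(prof$activity), 100)
  expect_equal(prof$stable_range, g$truth$stable_range)
  # plateau exactly spanning pH 4.5-8.5 at the 85% threshold
  ph <- seq(3, 9, by = 0.5)
  act <- ifelse(ph >= 4.5 & ph <= 8.5, 90, 50)
  act[ph == 5.5] <- 100
  prof2 <- profile_analysis(ph, act)
  expect_equal(prof2$optimum, 5.5)
  expect_equal(prof2$stable_range, c(4.5, 8.5))
  # constant profile spans the whole grid; ties pick the lower x
  prof3 <- profile_analysis(ph, rep(7, length(ph)))
  expect_equal(prof3$stable_range, c(3, 9))
  expect_equal(prof3$optimum, 3)
})
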