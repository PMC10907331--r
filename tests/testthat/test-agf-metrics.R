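ref_pars <- list(y0 = 0, B = 500, C = 15, D = 0.5, z = 1)

make_agf <- function(pars, x = seq(0, 30, by = 0.5)) {
  data.frame(charge_nc = x,
             amplitude_uv = do.call(sigmoid_agf, c(list(x = x), pars)))
}

test_that("noiseless sigmoid parameters are recovered to 1e-6", {
  d <- make_agf(ref_pars)
  f <- fit_sigmoid(d$charge_nc, d$amplitude_uv)
  expect_false(f$flagged)
  expect_equal(f$coef$B, 500, tolerance = 1e-6)
  expect_equal(f$coef$C, 15, tolerance = 1e-6)
  expect_equal(f$coef$D, 0.5, tolerance = 1e-6)
  expect_equal(f$coef$z, 1, tolerance = 1e-6)
  expect_lt(abs(f$coef$y0), 1e-3)

  # asymmetric case
  pars2 <- list(y0 = 5, B = 300, C = 10, D = 0.4, z = 2.5)
  f2 <- fit_sigmoid(make_agf(pars2))
  for (nm in names(pars2)) {
    expect_equal(f2$coef[[nm]], pars2[[nm]], tolerance = 1e-5)
  }

  # adding a constant shifts y0 only
  f3 <- fit_sigmoid(d$charge_nc, d$amplitude_uv + 40)
  expect_equal(f3$coef$y0, 40, tolerance = 1e-4)
  expect_equal(f3$coef$C, 15, tolerance = 1e-4)

  expect_error(fit_sigmoid(1:4, 1:4), "6")
})

test_that("fit bias vanishes as additive noise vanishes", {
  set.seed(21)
  x <- seq(0, 30, by = 0.25)
  for (sd in c(5, 0.5)) {
    Cs <- replicate(20, {
      y <- sigmoid_agf(x, 0, 500, 15, 0.5, 1) + rnorm(length(x), 0, sd)
      fit_sigmoid(x, y)$coef$C
    })
    expect_lt(abs(mean(Cs) - 15), 4 * sd / sqrt(20) / 3 + 0.05)
  }
})

test_that("closed-form slope agrees with numerical differentiation", {
  f <- fit_sigmoid(make_agf(ref_pars))
  # z = 1: theta = B D / 4
  expect_equal(agf_slope(f), 62.5, tolerance = 1e-5)
  # x0 = C for the symmetric sigmoid
  expect_equal(agf_inflection(f), f$coef$C, tolerance = 1e-6)

  # central difference of the fitted curve at x0, over random parameters
  set.seed(4)
  for (i in 1:10) {
    pars <- list(y0 = runif(1, -10, 10), B = runif(1, 50, 2000),
                 C = runif(1, 5, 25), D = runif(1, 0.1, 2),
                 z = runif(1, 0.2, 6))
    f <- fit_sigmoid(make_agf(pars, x = seq(-20, 60, by = 0.5)))
    h <- 1e-5
    x0 <- agf_inflection(f)
    num <- (predict(f, x0 + h) - predict(f, x0 - h)) / (2 * h)
    expect_equal(agf_slope(f), num, tolerance = 1e-6)
    # theta is linear in B
    th2 <- with(pars, B * 2 * D * (z / (z + 1))^(z + 1))
    expect_equal(2 * agf_slope(f), th2, tolerance = 1e-4)
  }
})

test_that("threshold is the baseline intersection of the tangent at x0", {
  f <- fit_sigmoid(make_agf(ref_pars))
  # z = 1: x_THR = C - 2/D = 15 - 4
  expect_equal(agf_threshold(f), 11, tolerance = 1e-5)

  set.seed(8)
  for (i in 1:10) {
    pars <- list(y0 = runif(1, -10, 10), B = runif(1, 50, 2000),
                 C = runif(1, 5, 25), D = runif(1, 0.1, 2),
                 z = runif(1, 0.2, 6))
    f <- fit_sigmoid(make_agf(pars, x = seq(-20, 60, by = 0.5)))
    x0 <- agf_inflection(f); thr <- agf_threshold(f)
    # tangent through (x0, y(x0)) with slope theta meets y = y0 at x_THR
    x_tan <- x0 - (predict(f, x0) - f$coef$y0) / agf_slope(f)
    expect_equal(thr, x_tan, tolerance = 1e-6)
    # threshold always precedes the inflection
    expect_lt(thr, x0)
  }
})

test_that("flagged fits are excluded from the metrics", {
  f_bad <- structure(list(coef = NULL, flagged = TRUE), class = "sigmoid_fit")
  expect_error(agf_slope(f_bad), "flagged")
  expect_error(ipg_effect_absolute(f_bad, f_bad), "flagged")
})

test_that("slope-based IPG effects behave arithmetically", {
  f1 <- fit_sigmoid(make_agf(ref_pars))
  expect_equal(ipg_effect_absolute(f1, f1), 0)
  expect_equal(ipg_effect_relative(f1, f1), 1)

  pars2 <- ref_pars; pars2$B <- 1000   # doubled slope
  f2 <- fit_sigmoid(make_agf(pars2))
  expect_equal(ipg_effect_absolute(f1, f2), 62.5, tolerance = 1e-4)
  expect_equal(ipg_effect_relative(f1, f2), 2, tolerance = 1e-5)
  # antisymmetry / amplitude-scale invariance
  expect_equal(ipg_effect_absolute(f2, f1), -ipg_effect_absolute(f1, f2),
               tolerance = 1e-8)
  pars3 <- ref_pars; pars3$B <- 250
  pars4 <- pars2; pars4$B <- 500
  expect_equal(ipg_effect_relative(fit_sigmoid(make_agf(pars3)),
                                   fit_sigmoid(make_agf(pars4))),
               2, tolerance = 1e-5)
})

test_that("ipg_offset recovers a pure horizontal shift", {
  x <- seq(0.25, 30, by = 0.25)
  k <- 1.2
  short <- data.frame(charge_nc = x,
                      amplitude_uv = sigmoid_agf(x, 0, 1000, 12, 0.6, 1))
  long <- data.frame(charge_nc = x,
                     amplitude_uv = sigmoid_agf(k * x, 0, 1000, 12, 0.6, 1))

  r <- ipg_offset(short, long)
  expect_equal(r$offset_db, 20 * log10(k), tolerance = 0.02)

  # identical AGFs: zero offset
  expect_equal(ipg_offset(short, short)$offset_db, 0, tolerance = 1e-9)

  # dual route: automatic range against a manually chosen range
  y_hi <- 20 * log10(max(short$amplitude_uv))
  r_manual <- ipg_offset(short, long, range = c(y_hi - 18, y_hi - 5))
  expect_equal(r$offset_db, r_manual$offset_db, tolerance = 0.05)

  # degenerate input is refused
  flat <- data.frame(charge_nc = x, amplitude_uv = rep(0, length(x)))
  expect_error(ipg_offset(flat, long), "degenerate")
})

test_that("AGF CSV reader accepts both dialects", {
  d <- make_agf(ref_pars)
  p1 <- tempfile(fileext = ".csv")
  write.csv(cbind(d, electrode = 5), p1, row.names = FALSE)
  expect_equal(read_agf_csv(p1)$amplitude_uv, d$amplitude_uv)
  p2 <- tempfile(fileext = ".csv")
  write.csv(setNames(d, c("nC", "uV")), p2, row.names = FALSE)
  expect_equal(read_agf_csv(p2)$charge_nc, d$charge_nc)
  unlink(c(p1, p2))
})
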