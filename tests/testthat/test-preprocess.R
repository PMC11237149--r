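test_that("SNV centres and scales each spectrum with the sample sd", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(snv(c(5, 5, 5)), "zero variance")
  expect_error(snv(3), "at least 2")
  set.seed(1)
  for (i in 1:5) {
    out <- snv(rnorm(50, sd = runif(1, 0.1, 10)))
    expect_lt(abs(mean(out)), 1e-12)
    expect_lt(abs(sd(out) - 1), 1e-12)
  }
})

test_that("MSC inverts additive and multiplicative scatter against the reference", {
  wl <- seq(1300, 1349)
  ref <- sin(wl / 10) + 2
  meta <- data.frame(id = paste0("s", 1:3, ":1"), subject_id = paste0("s", 1:3),
                     replicate = 1L, specimen = "plasma",
                     label3 = c("healthy", "UC", "CD"))
  X <- rbind(2 * ref + 3, ref, 0.5 * ref - 1)
  s <- spectra_set(wl, X, meta)
  out <- msc(s, reference = ref)
  for (i in 1:3) expect_equal(unname(out$absorbance[i, ]), ref, tolerance = 1e-9)

  # refit oracle: regressing corrected spectra on the reference gives
  # slope 1, intercept 0
  set.seed(7)
  Xr <- t(replicate(3, runif(1, 0.5, 2) * ref + runif(1, -1, 1) + rnorm(50, 0, 0.05)))
  sr <- spectra_set(wl, Xr, meta)
  corr <- msc(sr, reference = "mean")
  mean_ref <- colMeans(sr$absorbance)
  for (i in 1:3) {
    fit <- lm(corr$absorbance[i, ] ~ mean_ref)
    expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-9)
    expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-9)
  }

  # degenerate slope: a spectrum uncorrelated with the reference
  s_flat <- spectra_set(wl, rbind(ref, rep(1, 50)), meta[1:2, ])
  expect_error(msc(s_flat, reference = ref), "degenerate slope")
})

test_that("Savitzky-Golay is exact on polynomials and matches a brute-force window fit", {
  wl <- seq(1300, 1350, by = 0.5)
  y2 <- (wl - 1320)^2
  d2 <- savgol(y2, window = 13, poly_order = 2, deriv = 2, step = 0.5)
  expect_equal(d2, rep(2, length(wl)), tolerance = 1e-8)
  ylin <- 3 * wl + 1
  expect_equal(savgol(ylin, 13, 2, 2, 0.5), rep(0, length(wl)),
               tolerance = 1e-8)
  expect_equal(savgol(ylin, 13, 2, 1, 0.5), rep(3, length(wl)),
               tolerance = 1e-8)

  # brute-force oracle: per-window polynomial least squares, every point
  set.seed(42)
  y <- rnorm(41)
  step <- 0.5
  for (case in list(c(7, 2, 0), c(7, 2, 1), c(11, 3, 2), c(13, 2, 2))) {
    w <- case[1]; p <- case[2]; d <- case[3]
    h <- (w - 1) / 2
    out <- savgol(y, w, p, d, step)
    brute <- vapply(seq_along(y), function(i) {
      lo <- min(max(1, i - h), length(y) - w + 1)
      idx <- lo:(lo + w - 1)
      t <- (idx - i) * step
      fit <- lm.fit(outer(t, 0:p, `^`), y[idx])
      factorial(d) * fit$coefficients[d + 1]
    }, numeric(1))
    expect_equal(out, unname(brute), tolerance = 1e-9,
                 label = sprintf("savgol w=%d p=%d d=%d", w, p, d))
  }

  # deriv 0 with poly_order = window - 1 interpolates: identity everywhere
  out_id <- savgol(y, 7, 6, 0, step)
  expect_equal(out_id, y, tolerance = 1e-6)

  # the "12-point symmetric" convention resolves to a 13-point window
  expect_equal(savgol(y, 12, 2, 0, step), savgol(y, 13, 2, 0, step))
  expect_error(savgol(y[1:5], 13, 2, 0), "larger than")
  expect_error(savgol(y, 7, 2, 3), "deriv")
})

test_that("Savitzky-Golay matches the signal package on interior points", {
  skip_if_not_installed("signal")
  set.seed(8)
  y <- rnorm(101)
  for (case in list(c(13, 2, 0), c(13, 3, 1), c(11, 4, 2))) {
    w <- case[1]; p <- case[2]; d <- case[3]
    mine <- savgol(y, w, p, d, step = 0.5)
    ref <- signal::sgolayfilt(y, p = p, n = w, m = d, ts = 0.5)
    interior <- (w %/% 2 + 1):(101 - w %/% 2)
    expect_equal(mine[interior], ref[interior], tolerance = 1e-9)
  }
})

test_that("normalisation methods and their degenerate inputs", {
  expect_equal(normalize_spectrum(c(3, 4), "unit_vector"), c(0.6, 0.8))
  expect_equal(normalize_spectrum(c(2, 4, 6), "min_max"), c(0, 0.5, 1))
  set.seed(3)
  x <- rnorm(30)
  expect_lt(abs(sqrt(sum(normalize_spectrum(x, "unit_vector")^2)) - 1), 1e-12)
  a <- normalize_spectrum(abs(x) + 1, "area", step = 0.5)
  expect_equal(sum(a) * 0.5, 1, tolerance = 1e-12)
  expect_error(normalize_spectrum(rep(0, 5), "unit_vector"), "zero norm")
  expect_error(normalize_spectrum(rep(2, 5), "min_max"), "constant")
  expect_error(normalize_spectrum(c(-1, 1), "area"), "zero area")
})

test_that("detrend removes polynomials of its order exactly", {
  wl <- seq(1300, 1400, by = 2)
  expect_equal(detrend(5 + 0.3 * wl, order = 1, wavelengths = wl),
               rep(0, length(wl)), tolerance = 1e-10)
  expect_equal(detrend((wl - 1350)^2, order = 2, wavelengths = wl),
               rep(0, length(wl)), tolerance = 1e-8)
  x <- sin(wl / 5)
  expect_equal(detrend(x, order = 0), x - mean(x))
  expect_error(detrend(x, order = -1), "order")
})

test_that("linear baseline correction pins the endpoints and ignores added lines", {
  wl <- seq(1300, 1320)
  x <- sin(wl / 3)
  out <- baseline_linear(x, wl)
  expect_equal(out[1], 0)
  expect_equal(out[length(out)], 0)
  expect_equal(baseline_linear(2 + 0.1 * wl, wl), rep(0, length(wl)))
  shifted <- baseline_linear(x + 5 - 0.2 * wl, wl)
  expect_equal(shifted, out, tolerance = 1e-12)
})

test_that("absorbance/transmittance conversion round-trips", {
  expect_equal(to_transmittance(c(0, 1, 2)), c(1, 0.1, 0.01))
  x <- runif(20, 0, 3)
  expect_equal(to_absorbance(to_transmittance(x)), x, tolerance = 1e-12)
  expect_error(to_absorbance(c(0.5, 0)), "> 0")
  expect_error(to_transmittance(c(1, NA)), "finite")
})

test_that("SNV and MSC both cancel pure multiplicative+additive scatter", {
  wl <- seq(1300, 1399)
  ref <- exp(-(wl - 1350)^2 / 200) + 0.2
  for (i in 1:5) {
    b <- runif(1, 0.5, 2); a <- runif(1, -1, 1)
    x <- b * ref + a
    expect_equal(snv(x), snv(ref), tolerance = 1e-9)
  }
})

test_that("pipelines compose, preserve the grid and keep SNV idempotent", {
  s <- strong_plasma(seed = 2)
  expect_equal(apply_pipeline(s, preprocess_spec()), s)  # empty = identity

  once <- apply_pipeline(s, snv_pipe())
  twice <- apply_pipeline(once, snv_pipe())
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-12)

  steps <- list("snv", list(name = "msc"), list(name = "normalize"),
                list(name = "smooth", window = 13),
                list(name = "savgol_derivative", deriv = 2),
                list(name = "detrend", order = 2), "baseline_linear",
                "to_transmittance")
  for (st in steps) {
    out <- apply_pipeline(s, preprocess_spec(list(st)))
    expect_equal(out$wavelengths, s$wavelengths)
    expect_equal(dim(out$absorbance), dim(s$absorbance))
    expect_identical(out$meta, s$meta)
  }
  expect_error(preprocess_spec(list("wavelet")), "unknown pretreatment")
})

test_that("fitted pretreatments freeze calibration statistics (no test leakage)", {
  s <- strong_plasma(seed = 5)
  cal <- subset_spectra(s, 1:30)
  test <- subset_spectra(s, 31:39)
  pipe <- preprocess_spec(list("snv", "msc"))
  fitted <- fit_preprocess(pipe, cal)
  ref <- fitted$steps[[2]]$fitted_reference
  # the MSC reference is the calibration mean after SNV, untouched by test data
  expect_equal(ref, colMeans(apply_pipeline(cal, snv_pipe())$absorbance),
               tolerance = 1e-12, ignore_attr = TRUE)
  out1 <- apply_preprocess(fitted, test)
  # perturbing the test spectra changes nothing about the fit itself
  test2 <- set_absorbance(test, test$absorbance * 2 + 1)
  fitted2 <- fit_preprocess(pipe, cal)
  expect_identical(fitted2$steps[[2]]$fitted_reference, ref)
  # and applying to a scaled+shifted test set gives the same corrected
  # spectra (SNV+MSC cancel the perturbation)
  out2 <- apply_preprocess(fitted, test2)
  expect_equal(out2$absorbance, out1$absorbance, tolerance = 1e-9)
})
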