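# Pretreatment operators for NIR spectra.  All operators preserve the
# wavelength grid (same length, same grid); dataset-level operators (MSC)
# follow a fit-on-train contract inside validation: their statistics are
# estimated on the calibration spectra only and reused on test spectra.

PREPROCESS_STEPS <- c("snv", "msc", "normalize", "smooth", "savgol_derivative",
                      "detrend", "baseline_linear", "to_transmittance",
                      "to_absorbance")

#' Standard normal variate (SNV)
#'
#' Per-spectrum z-scoring, `(x - mean(x)) / sd(x)` with the sample (n-1)
#' standard deviation: removes additive offsets and multiplicative scatter
#' from a single spectrum.
#'
#' @param x numeric vector (one spectrum), length >= 2.
#' @return numeric vector with mean 0 and sd 1.
#' @export
snv <- function(x) {
  if (length(x) < 2L) stop("snv needs at least 2 points")
  s <- stats::sd(x)
  if (s <= 0 || !is.finite(s)) stop("zero variance: cannot SNV a constant spectrum")
  (x - mean(x)) / s
}

msc_matrix <- function(X, ref) {
  if (stats::sd(ref) <= 0) stop("MSC reference spectrum has zero variance")
  t(apply(X, 1L, function(x) {
    fit <- stats::lm.fit(cbind(1, ref), x)
    a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
    if (!is.finite(b) || abs(b) < 1e-12) stop("degenerate slope in MSC fit")
    (x - a) / b
  }))
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum is regressed on a reference spectrum,
#' `x ~ a + b * ref`, and corrected to `(x - a) / b`.  The reference
#' defaults to the data-set mean spectrum.
#'
#' @param s a `SpectraSet` (>= 2 wavelengths).
#' @param reference `"mean"` (default) or a numeric reference spectrum on
#'   the same grid.
#' @return a corrected `SpectraSet`.
#' @export
msc <- function(s, reference = "mean") {
  if (length(s$wavelengths) < 2L) stop("MSC needs at least 2 wavelengths")
  ref <- if (identical(reference, "mean")) colMeans(s$absorbance)
         else as.numeric(reference)
  if (length(ref) != length(s$wavelengths)) {
    stop("MSC reference length does not match the wavelength grid")
  }
  set_absorbance(s, msc_matrix(s$absorbance, ref))
}

# Least-squares polynomial fitting coefficients for a symmetric window of
# `window` points: row d of the returned list element `eval(t0)` gives the
# d-th derivative of the fitted polynomial evaluated at offset t0 (in grid
# units).
savgol_design <- function(window, poly_order) {
  h <- (window - 1L) %/% 2L
  t <- seq(-h, h)
  V <- outer(t, 0:poly_order, `^`)
  # beta = P %*% y, with P = (V'V)^{-1} V'
  P <- solve(crossprod(V), t(V))
  list(P = P, h = h, poly_order = poly_order)
}

savgol_eval_weights <- function(design, t0, deriv) {
  # weights w such that w %*% y = deriv-th derivative of the window fit at t0
  j <- 0:design$poly_order
  fac <- ifelse(j >= deriv, factorial(j) / factorial(pmax(j - deriv, 0L)), 0)
  tp <- ifelse(j >= deriv, t0^(j - deriv), 0)
  drop((fac * tp) %*% design$P)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Fits a least-squares polynomial of degree `poly_order` to a sliding
#' symmetric window and returns the `deriv`-th derivative of the fit at the
#' window centre, scaled by `step^(-deriv)` so derivative spectra are
#' expressed per nm and independent of grid resolution.  Edge points are
#' evaluated off-centre from the first/last full window (polynomial
#' extrapolation).  An even `window` is widened by one point: a symmetric
#' window must be odd, so the conventional "12-point" smoothing setting
#' becomes a 13-point window (12 neighbours plus the centre).
#'
#' @param x numeric vector (one spectrum).
#' @param window window size in points; made odd by adding 1 if even.
#' @param poly_order polynomial degree, `< window`.
#' @param deriv derivative order 0, 1 or 2 (`<= poly_order`).
#' @param step grid spacing in nm (used to scale derivatives).
#' @return numeric vector, same length as `x`.
#' @export
savgol <- function(x, window = 13L, poly_order = 2L, deriv = 0L, step = 1) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  if (window > n) stop("Savitzky-Golay window larger than the spectrum")
  if (poly_order >= window) stop("poly_order must be < window")
  if (deriv > poly_order) stop("deriv must be <= poly_order")
  design <- savgol_design(window, poly_order)
  h <- design$h
  w_centre <- savgol_eval_weights(design, 0, deriv)
  out <- numeric(n)
  # interior: filter with the central weights
  for (i in seq(h + 1L, n - h)) {
    out[i] <- sum(w_centre * x[(i - h):(i + h)])
  }
  # edges: evaluate the first/last full-window fit off-centre
  for (i in seq_len(h)) {
    out[i] <- sum(savgol_eval_weights(design, i - h - 1L, deriv) * x[1:window])
    out[n - i + 1L] <- sum(savgol_eval_weights(design, h - i + 1L, deriv) *
                             x[(n - window + 1L):n])
  }
  out / step^deriv
}

#' Normalize a spectrum
#'
#' @param x numeric vector.
#' @param method `"unit_vector"` (`x / ||x||`), `"min_max"`
#'   (`(x - min) / (max - min)`) or `"area"` (`x / (sum(x) * step)`).
#' @param step grid spacing in nm, used by the area method.
#' @return normalized vector.
#' @export
normalize_spectrum <- function(x, method = c("unit_vector", "min_max", "area"),
                               step = 1) {
  method <- match.arg(method)
  switch(method,
    unit_vector = {
      nrm <- sqrt(sum(x^2))
      if (nrm <= 0) stop("zero norm: cannot unit-vector normalize")
      x / nrm
    },
    min_max = {
      r <- range(x)
      if (r[2L] <= r[1L]) stop("constant spectrum: cannot min-max normalize")
      (x - r[1L]) / (r[2L] - r[1L])
    },
    area = {
      a <- sum(x) * step
      if (abs(a) < 1e-15) stop("zero area: cannot area normalize")
      x / a
    }
  )
}

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial of the given order fitted
#' against wavelength.
#'
#' @param x numeric vector (one spectrum).
#' @param order polynomial order, `0 <= order < length(x)`.
#' @param wavelengths abscissa; defaults to the point index.
#' @return detrended vector (residuals of the fit).
#' @export
detrend <- function(x, order = 2L, wavelengths = seq_along(x)) {
  if (order < 0L || order >= length(x)) stop("invalid detrend order")
  w <- wavelengths - mean(wavelengths)  # centred for numerical stability
  V <- outer(w, 0:order, `^`)
  x - drop(V %*% qr.coef(qr(V), x))
}

#' Linear baseline correction
#'
#' Subtracts the straight line through the first and last points of the
#' spectrum; both endpoints map to exactly 0.
#'
#' @param x numeric vector, length >= 2.
#' @param wavelengths abscissa; defaults to the point index.
#' @return corrected vector.
#' @export
baseline_linear <- function(x, wavelengths = seq_along(x)) {
  n <- length(x)
  if (n < 2L) stop("baseline correction needs at least 2 points")
  slope <- (x[n] - x[1L]) / (wavelengths[n] - wavelengths[1L])
  x - (x[1L] + slope * (wavelengths - wavelengths[1L]))
}

#' Absorbance/transmittance conversion
#'
#' `to_transmittance` maps absorbance to transmittance, `T = 10^(-A)`;
#' `to_absorbance` is its inverse, `A = -log10(T)`.
#'
#' @param x numeric vector.
#' @return converted vector.
#' @export
to_transmittance <- function(x) {
  if (any(!is.finite(x))) stop("non-finite absorbance")
  10^(-x)
}

#' @rdname to_transmittance
#' @export
to_absorbance <- function(x) {
  if (any(x <= 0)) stop("transmittance must be > 0 to convert to absorbance")
  -log10(x)
}

#' An ordered pretreatment recipe
#'
#' @param steps list of steps; each step is either a step name (string) or
#'   a list with a `name` element plus parameters, e.g.
#'   `list(name = "savgol_derivative", window = 13, deriv = 2)`.
#'   Valid names: snv, msc, normalize, smooth, savgol_derivative, detrend,
#'   baseline_linear, to_transmittance, to_absorbance.
#' @param label optional short label used in reports; defaults to the step
#'   names joined by "-" ("raw" for an empty recipe).
#' @return an object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(steps = list(), label = NULL) {
  steps <- lapply(steps, function(st) {
    if (is.character(st)) st <- list(name = st)
    if (is.null(st$name)) stop("pretreatment step without a name")
    if (!st$name %in% PREPROCESS_STEPS) {
      stop("unknown pretreatment step: ", st$name)
    }
    st
  })
  if (is.null(label)) {
    label <- if (length(steps) == 0L) "raw"
             else paste(vapply(steps, `[[`, "", "name"), collapse = "-")
  }
  structure(list(steps = steps, label = label), class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("preprocess_spec:", x$label, "\n")
  invisible(x)
}

step_param <- function(st, name, default) {
  if (!is.null(st[[name]])) st[[name]] else default
}

# Fit one step on the (already partially transformed) calibration matrix
# and return the transformed matrix plus the frozen step (with fitted
# statistics baked in, so it can be replayed on test spectra).
fit_step <- function(st, X, wl) {
  step <- grid_step(wl)
  switch(st$name,
    snv = list(X = t(apply(X, 1L, snv)), step = st),
    msc = {
      ref <- st$reference
      if (is.null(ref) || identical(ref, "mean")) ref <- colMeans(X)
      st$fitted_reference <- as.numeric(ref)
      list(X = msc_matrix(X, st$fitted_reference), step = st)
    },
    normalize = {
      method <- step_param(st, "method", "unit_vector")
      list(X = t(apply(X, 1L, normalize_spectrum, method = method,
                       step = step)), step = st)
    },
    smooth = {
      w <- step_param(st, "window", 13L)
      p <- step_param(st, "poly_order", 2L)
      list(X = t(apply(X, 1L, savgol, window = w, poly_order = p,
                       deriv = 0L, step = step)), step = st)
    },
    savgol_derivative = {
      w <- step_param(st, "window", 13L)
      d <- step_param(st, "deriv", 2L)
      p <- step_param(st, "poly_order", max(2L, d))
      list(X = t(apply(X, 1L, savgol, window = w, poly_order = p,
                       deriv = d, step = step)), step = st)
    },
    detrend = {
      o <- step_param(st, "order", 2L)
      list(X = t(apply(X, 1L, detrend, order = o, wavelengths = wl)),
           step = st)
    },
    baseline_linear = list(
      X = t(apply(X, 1L, baseline_linear, wavelengths = wl)), step = st),
    to_transmittance = list(X = to_transmittance(X), step = st),
    to_absorbance = list(X = to_absorbance(X), step = st),
    stop("unknown pretreatment step: ", st$name)
  )
}

# Replay a frozen step on new spectra (test set) without refitting.
apply_step <- function(st, X, wl) {
  if (st$name == "msc") {
    return(msc_matrix(X, st$fitted_reference))
  }
  fit_step(st, X, wl)$X
}

#' Fit a pretreatment recipe on calibration spectra
#'
#' Walks the recipe over the calibration set, freezing any data-set-level
#' statistics (currently the MSC mean-reference spectrum) so the identical
#' transformation can be replayed on held-out spectra with
#' [apply_preprocess()] — no test information ever enters the fit.
#'
#' @param spec a [preprocess_spec()].
#' @param s calibration `SpectraSet`.
#' @return an object of class `fitted_preprocess`.
#' @export
fit_preprocess <- function(spec, s) {
  X <- s$absorbance
  fitted <- vector("list", length(spec$steps))
  for (i in seq_along(spec$steps)) {
    res <- fit_step(spec$steps[[i]], X, s$wavelengths)
    X <- res$X
    fitted[[i]] <- res$step
  }
  structure(list(steps = fitted, wavelengths = s$wavelengths,
                 label = spec$label, transformed = X),
            class = "fitted_preprocess")
}

#' Apply a fitted pretreatment recipe to spectra
#'
#' @param fitted a `fitted_preprocess` from [fit_preprocess()].
#' @param s a `SpectraSet` on the same wavelength grid.
#' @return a transformed `SpectraSet`.
#' @export
apply_preprocess <- function(fitted, s) {
  if (length(s$wavelengths) != length(fitted$wavelengths) ||
      max(abs(s$wavelengths - fitted$wavelengths)) > 1e-9) {
    stop("wavelength grid does not match the fitted pretreatment")
  }
  X <- s$absorbance
  for (st in fitted$steps) X <- apply_step(st, X, s$wavelengths)
  set_absorbance(s, X)
}

#' Apply a pretreatment recipe to a SpectraSet (self-fit)
#'
#' Fits any data-set-level statistics on `s` itself and transforms `s`.
#' Inside validation, use [fit_preprocess()] on the calibration subset and
#' [apply_preprocess()] on held-out spectra instead.
#'
#' @param s a `SpectraSet`.
#' @param spec a [preprocess_spec()] (an empty recipe is the identity).
#' @return a transformed `SpectraSet`.
#' @export
apply_pipeline <- function(s, spec) {
  apply_preprocess(fit_preprocess(spec, s), s)
}
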