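# The twelve water matrix coordinates (WAMACs) of the 1300-1600 nm first
# overtone of the OH stretch.  Ranges are quoted inclusively, in nm; the
# printed C10/C11 limits share 1482 nm, resolved at lookup time (a boundary
# wavelength belongs to the lower-numbered band).

WAMAC_RANGES <- data.frame(
  band = paste0("C", 1:12),
  low  = c(1336, 1360, 1370, 1380, 1398, 1421, 1432, 1448, 1458, 1472, 1482, 1506),
  high = c(1348, 1366, 1376, 1388, 1418, 1430, 1444, 1454, 1468, 1482, 1495, 1516),
  assignment = c(
    "2v3: H2O asymmetric stretching vibration",
    "OH-.(H2O)1,2,4: water solvation shell",
    "v1 + v3: H2O symmetrical and asymmetric stretching vibration",
    "OH-.(H2O)1,4 solvation shell; O2-.(H2O)4 hydrated superoxide; 2v1",
    "water confined in a local field of ions (trapped water); S0 free water; water with free OH-",
    "water hydration band, H-OH bend and O-H...O",
    "S1: water molecules with 1 hydrogen bond",
    "OH-.(H2O)4,5: water solvation shell",
    "S2: water molecules with 2 hydrogen bonds; 2v2 + v3",
    "S3: water molecules with 3 hydrogen bonds",
    "S4: water molecules with 4 hydrogen bonds",
    "v1 + v2: symmetrical stretching and bending; strongly bound water"
  ),
  stringsAsFactors = FALSE
)

#' The 12 water matrix coordinate (WAMAC) absorbance bands
#'
#' The twelve characteristic water absorbance sub-bands C1..C12 of the
#' 1300-1600 nm first-overtone region, each attributed to a water molecular
#' conformation (free water, 1-4 hydrogen-bonded species, solvation shells).
#'
#' @return a data.frame with columns `band` (C1..C12), `low` and `high`
#'   (band limits in nm, inclusive) and `assignment` (structural
#'   interpretation).
#' @export
wamac_table <- function() WAMAC_RANGES

#' Assign wavelengths to WAMAC bands
#'
#' Each wavelength inside a band's closed interval is tagged with that
#' band's id; 1482 nm, which the printed C10 and C11 limits share, is
#' assigned to C10 (the lower-numbered band).  Wavelengths between bands
#' get `NA`.
#'
#' @param wavelengths numeric vector, nm.
#' @return character vector of band ids (or `NA`) parallel to the input.
#' @export
wamac_band_of <- function(wavelengths) {
  tab <- wamac_table()
  out <- rep(NA_character_, length(wavelengths))
  # reverse order so that earlier (lower-numbered) bands overwrite later
  # ones on a shared boundary wavelength
  for (i in rev(seq_len(nrow(tab)))) {
    hit <- wavelengths >= tab$low[i] - 1e-9 & wavelengths <= tab$high[i] + 1e-9
    out[hit] <- tab$band[i]
  }
  out
}

#' Restrict a SpectraSet to the 12 WAMAC bands
#'
#' Keeps only the wavelengths lying inside one of the twelve water
#' absorbance bands; each kept wavelength is tagged with exactly one band
#' id (accessible via [wamac_band_of()]).
#'
#' @param s a `SpectraSet`.
#' @return a `SpectraSet` on the band-restricted grid.
#' @export
extract_wamac <- function(s) {
  band <- wamac_band_of(s$wavelengths)
  keep <- !is.na(band)
  if (!any(keep)) stop("grid does not overlap any WAMAC band")
  spectra_set(s$wavelengths[keep], s$absorbance[, keep, drop = FALSE], s$meta)
}

#' Aquagram: per-class normalized water-band absorbance
#'
#' After scatter correction (MSC against the data-set mean spectrum, or
#' SNV), the absorbance at every WAMAC wavelength is z-scored across all
#' spectra: `A'(lambda) = (A(lambda) - mu(lambda)) / sigma(lambda)`, with
#' `mu` and `sigma` the pooled mean and sample standard deviation over the
#' whole data set.  The aquagram value of a class at a band is the mean of
#' `A'` over that class's spectra and the band's wavelengths; classes are
#' then compared on a 12-spoke radar chart (see [plot.aquagram()]).
#'
#' @param s a `SpectraSet` whose grid overlaps the WAMAC bands.
#' @param class_field grouping label column: `"label2"` or `"label3"`.
#' @param scatter scatter correction applied before z-scoring: `"msc"`
#'   (default, reference = data-set mean) or `"snv"`.
#' @return an object of class `aquagram`: list with `values` (data.frame
#'   `class`, `band`, `value`), `aprime` (spectra x WAMAC-wavelength matrix
#'   of z-scores), `wavelengths`, `band_of`, `classes`.
#' @export
aquagram <- function(s, class_field = c("label2", "label3"),
                     scatter = c("msc", "snv")) {
  class_field <- match.arg(class_field)
  scatter <- match.arg(scatter)
  if (n_spectra(s) < 2L) stop("aquagram needs at least 2 spectra")

  corrected <- switch(scatter,
    msc = msc(s, reference = "mean"),
    snv = set_absorbance(s, t(apply(s$absorbance, 1L, snv)))
  )
  sw <- extract_wamac(corrected)
  a <- sw$absorbance
  mu <- colMeans(a)
  sigma <- apply(a, 2L, stats::sd)
  if (any(sigma <= 0)) {
    stop("zero standard deviation at wavelength ",
         sw$wavelengths[which(sigma <= 0)[1L]], " nm")
  }
  aprime <- sweep(sweep(a, 2L, mu, "-"), 2L, sigma, "/")

  band <- wamac_band_of(sw$wavelengths)
  g <- sw$meta[[class_field]]
  classes <- sort(unique(g))
  bands <- wamac_table()$band
  values <- do.call(rbind, lapply(classes, function(cl) {
    rows <- g == cl
    data.frame(
      class = cl,
      band = bands,
      value = vapply(bands, function(b) {
        cols <- band == b
        if (!any(cols)) return(NA_real_)
        mean(aprime[rows, cols, drop = FALSE])
      }, numeric(1L)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(values) <- NULL
  structure(
    list(values = values, aprime = aprime, wavelengths = sw$wavelengths,
         band_of = band, classes = classes, scatter = scatter),
    class = "aquagram"
  )
}

#' @export
print.aquagram <- function(x, ...) {
  cat("Aquagram (", x$scatter, " scatter correction)\n", sep = "")
  wide <- stats::reshape(x$values, idvar = "class", timevar = "band",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Radar chart of an aquagram
#'
#' Draws the 12 WAMAC spokes C1..C12 with one closed trace per class.
#'
#' @param x an `aquagram` object.
#' @param col colours, one per class.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.aquagram <- function(x, col = seq_along(x$classes) + 1L, ...) {
  bands <- wamac_table()$band
  k <- length(bands)
  theta <- pi / 2 - 2 * pi * (seq_len(k) - 1L) / k
  rng <- range(x$values$value, na.rm = TRUE)
  rmax <- max(abs(rng)) * 1.2 + 1e-9
  graphics::plot(NA, NA, xlim = c(-rmax, rmax) * 1.2, ylim = c(-rmax, rmax) * 1.2,
                 axes = FALSE, xlab = "", ylab = "", asp = 1, ...)
  for (i in seq_len(k)) {
    graphics::lines(c(0, rmax * cos(theta[i])), c(0, rmax * sin(theta[i])),
                    col = "grey80")
    graphics::text(1.12 * rmax * cos(theta[i]), 1.12 * rmax * sin(theta[i]),
                   bands[i], cex = 0.8)
  }
  for (j in seq_along(x$classes)) {
    v <- x$values$value[x$values$class == x$classes[j]]
    r <- v - min(rng)  # shift so the innermost value sits at the centre
    r <- r / (diff(rng) + 1e-12) * rmax
    graphics::polygon(r * cos(theta), r * sin(theta), border = col[j], lwd = 2)
  }
  graphics::legend("topright", legend = x$classes, col = col, lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Write aquagram values to CSV
#' @param ag an `aquagram` object.
#' @param path output CSV path (columns class, band, value).
#' @return invisibly, `ag`.
#' @export
write_aquagram <- function(ag, path) {
  utils::write.csv(ag$values, path, row.names = FALSE)
  invisible(ag)
}
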