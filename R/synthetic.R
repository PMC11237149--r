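# Seeded generator of water-dominated NIR cohorts.  Spectra are sums of a
# dominant first-overtone water Gaussian near 1450 nm and one narrower
# Gaussian per WAMAC band; disease classes perturb band amplitudes
# fractionally, subjects jitter around their class effect, and every
# replicate picks up multiplicative/additive scatter plus instrument noise
# (exactly the artifacts SNV/MSC are designed to remove).

# Default spectral components: the broad 1450 nm water peak plus one
# component per WAMAC band (centre = band midpoint, sigma = half the band
# width).  Amplitudes in absorbance units for a 1 mm path length.
WATER_PEAK <- list(center = 1450, width = 38, amplitude = 1.0)
DEFAULT_BAND_AMPLITUDE <- 0.02

#' Spectral band components of the synthetic water spectrum
#'
#' One Gaussian component per WAMAC band (centred at the band midpoint,
#' sigma half the band width) plus the broad dominant water component at
#' 1450 nm.
#'
#' @param band_amplitude base absorbance amplitude of each WAMAC component.
#' @return data.frame with columns `id`, `center`, `width`, `amplitude`.
#' @export
band_components <- function(band_amplitude = DEFAULT_BAND_AMPLITUDE) {
  tab <- wamac_table()
  centers <- (tab$low + tab$high) / 2
  # C8 (the solvation-shell band, 1448-1454 nm) carries the canonical
  # water absorbance maximum: its component sits at 1450 nm, not at the
  # band midpoint, so the composite spectrum peaks on the 1450 grid point.
  centers[tab$band == "C8"] <- 1450
  rbind(
    data.frame(id = "water", center = WATER_PEAK$center,
               width = WATER_PEAK$width, amplitude = WATER_PEAK$amplitude,
               stringsAsFactors = FALSE),
    data.frame(id = tab$band, center = centers,
               width = (tab$high - tab$low) / 2, amplitude = band_amplitude,
               stringsAsFactors = FALSE)
  )
}

gaussian_bands <- function(wavelengths, centers, widths, amplitudes) {
  out <- numeric(length(wavelengths))
  for (i in seq_along(centers)) {
    out <- out + amplitudes[i] *
      exp(-(wavelengths - centers[i])^2 / (2 * widths[i]^2))
  }
  out
}

#' Noise-free water-dominated base spectrum
#'
#' Sum of the broad dominant water Gaussian centred at 1450 nm and one
#' narrower Gaussian per WAMAC band; the global maximum sits at the grid
#' point nearest 1450 nm.
#'
#' @param wavelengths numeric vector of wavelengths in nm (1200-1700).
#' @param components component table as from [band_components()].
#' @return numeric absorbance vector.
#' @export
water_base_spectrum <- function(wavelengths, components = band_components()) {
  if (length(wavelengths) == 0L) stop("empty wavelength vector")
  if (any(wavelengths < 1200 | wavelengths > 1700)) {
    stop("wavelengths outside the supported 1200-1700 nm window")
  }
  gaussian_bands(wavelengths, components$center, components$width,
                 components$amplitude)
}

#' Specification of a synthetic cohort
#'
#' @param n_per_class named integer vector, subjects per class; names from
#'   healthy, CD, UC.
#' @param replicates replicate spectra per subject (>= 1).
#' @param effects named list: class -> named numeric vector of fractional
#'   band-amplitude shifts (names C1..C12).  Classes absent from the list
#'   get zero effect.
#' @param noise_sd iid instrument noise sd, absorbance units.
#' @param scatter_slope_sd sd of the multiplicative scatter factor around 1.
#' @param scatter_offset_sd sd of the additive scatter offset, absorbance.
#' @param subject_jitter_frac subject-level jitter of the class effect
#'   (per-band multiplicative, sd as a fraction of the effect).
#' @param subject_band_sd class-independent per-subject random band shift
#'   (fractional sd); nonzero values create subject identity signal without
#'   class signal, used to probe replicate leakage.
#' @param grid numeric `c(low, high)` in nm.
#' @param step grid spacing, nm.
#' @param band_amplitude base absorbance amplitude of the WAMAC components.
#' @param specimen "plasma" or "saliva" (metadata tag only).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(healthy = 3, CD = 2, UC = 8),
                        replicates = 3L,
                        effects = list(),
                        noise_sd = 2e-4,
                        scatter_slope_sd = 0.02,
                        scatter_offset_sd = 0.005,
                        subject_jitter_frac = 0.2,
                        subject_band_sd = 0,
                        grid = c(1280, 1630),
                        step = 0.5,
                        band_amplitude = DEFAULT_BAND_AMPLITUDE,
                        specimen = "plasma",
                        seed = 1L) {
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class)))) {
    stop("n_per_class must be a named vector")
  }
  bad <- setdiff(names(n_per_class), VALID_LABEL3)
  if (length(bad) > 0L) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  if (any(n_per_class < 0)) stop("negative subject count in n_per_class")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  band_ids <- wamac_table()$band
  for (cl in names(effects)) {
    if (!cl %in% VALID_LABEL3) stop("unknown class in effects: ", cl)
    bad_band <- setdiff(names(effects[[cl]]), band_ids)
    if (length(bad_band) > 0L) {
      stop("unknown band id(s) in effects: ", paste(bad_band, collapse = ", "))
    }
  }
  structure(
    list(n_per_class = n_per_class, replicates = as.integer(replicates),
         effects = effects, noise_sd = noise_sd,
         scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         subject_jitter_frac = subject_jitter_frac,
         subject_band_sd = subject_band_sd,
         grid = as.numeric(grid), step = step,
         band_amplitude = band_amplitude,
         specimen = specimen, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Effect directions reported for the plasma and saliva aquagrams: each
# preset encodes which bands move up (+) or down (-) in each disease class
# relative to the healthy baseline, at fractional magnitude `effect`.
preset_effects <- function(name, effect) {
  bands <- wamac_table()$band
  z <- stats::setNames(rep(0, 12L), bands)
  eff <- function(up = character(), down = character()) {
    v <- z; v[up] <- effect; v[down] <- -effect; v
  }
  switch(name,
    plasma_ibd = list(
      # healthy active in C1-C4 and C8; disease depresses them and raises
      # the strongly hydrogen-bonded species C11/C12.  CD additionally
      # shifts the whole C1-C8 / C9-C12 balance.
      UC = eff(up = c("C11", "C12"),
               down = c("C1", "C2", "C3", "C4", "C8")),
      CD = eff(up = c("C9", "C10", "C11", "C12"),
               down = paste0("C", 1:8))
    ),
    saliva_ibd = list(
      # mirrored pattern: disease lowers the 2-4-bond and strongly bound
      # species C9-C12 and raises the free/weakly bound C1-C8 region.
      UC = eff(up = paste0("C", 1:8),
               down = c("C9", "C10", "C11", "C12")),
      CD = eff(up = "C6", down = c("C9", "C10", "C11"))
    ),
    null = list(),
    stop("unknown preset name: ", name)
  )
}

#' Built-in cohort presets
#'
#' `"plasma_ibd"` and `"saliva_ibd"` encode the reported aquagram effect
#' directions for the two specimens in a 13-subject cohort (3 healthy, 2
#' CD, 8 UC; 3 replicates each, 39 spectra) with a band-amplitude effect
#' five times the instrument noise sd (strong separation).  `"null"` is the
#' same cohort with every class effect zero, for type-I-error testing.
#'
#' @param name one of `"plasma_ibd"`, `"saliva_ibd"`, `"null"`.
#' @param effect fractional band-amplitude effect magnitude (default 0.05,
#'   i.e. 5% of the band amplitude).
#' @param seed RNG seed stored in the returned spec.
#' @param ... further arguments passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
preset <- function(name = c("plasma_ibd", "saliva_ibd", "null"),
                   effect = 0.05, seed = 1L, ...) {
  name <- match.arg(name)
  specimen <- if (name == "saliva_ibd") "saliva" else "plasma"
  cohort_spec(effects = preset_effects(name, effect),
              specimen = specimen, seed = seed, ...)
}

#' Generate a synthetic cohort of NIR spectra
#'
#' For every subject, the per-band effect is the class effect times
#' `1 + jitter` (subject-level, per band); every replicate spectrum is
#' `slope * base + offset + noise`, with the base spectrum's band
#' amplitudes scaled by `1 + effect`, `slope ~ 1 + N(0, scatter_slope_sd)`,
#' `offset ~ N(0, scatter_offset_sd)` and iid Gaussian instrument noise.
#' Generation is deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()] (or [preset()]).
#' @return a `SpectraSet` with `n_subjects * replicates` spectra.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  wl <- seq(spec$grid[1L], spec$grid[2L], by = spec$step)
  comp <- band_components(spec$band_amplitude)
  is_band <- comp$id != "water"
  band_ids <- comp$id[is_band]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  rows <- list()
  meta <- list()
  for (cl in names(spec$n_per_class)) {
    n_subj <- spec$n_per_class[[cl]]
    if (n_subj == 0L) next
    class_effect <- stats::setNames(rep(0, sum(is_band)), band_ids)
    if (!is.null(spec$effects[[cl]])) {
      e <- spec$effects[[cl]]
      class_effect[names(e)] <- e
    }
    for (si in seq_len(n_subj)) {
      subject_id <- sprintf("%s_%02d", cl, si)
      jitter <- stats::rnorm(length(class_effect), 0, 1)
      subj_effect <- class_effect * (1 + spec$subject_jitter_frac * jitter) +
        stats::rnorm(length(class_effect), 0, spec$subject_band_sd)
      amps <- comp$amplitude
      amps[is_band] <- amps[is_band] * (1 + subj_effect)
      base <- gaussian_bands(wl, comp$center, comp$width, amps)
      for (r in seq_len(spec$replicates)) {
        slope <- 1 + stats::rnorm(1L, 0, spec$scatter_slope_sd)
        offset <- stats::rnorm(1L, 0, spec$scatter_offset_sd)
        noise <- stats::rnorm(length(wl), 0, spec$noise_sd)
        rows[[length(rows) + 1L]] <- slope * base + offset + noise
        meta[[length(meta) + 1L]] <- data.frame(
          id = paste0(subject_id, ":", r), subject_id = subject_id,
          replicate = r, specimen = spec$specimen, label3 = cl,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stop("cohort spec generates no spectra")
  spectra_set(wl, do.call(rbind, rows), do.call(rbind, meta))
}
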