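#' @keywords internal
"_PACKAGE"

VALID_LABEL3 <- c("healthy", "CD", "UC")
VALID_SPECIMEN <- c("plasma", "saliva")

#' Derive the two-class label from the three-class label
#'
#' Collapses the three-class diagnostic label (healthy / CD / UC) into the
#' two-class screening label: Crohn's Disease and Ulcerative Colitis are both
#' Inflammatory Bowel Disease.
#'
#' @param label3 character vector with values "healthy", "CD" or "UC".
#' @return character vector with values "healthy" or "IBD".
#' @export
derive_label2 <- function(label3) {
  bad <- setdiff(unique(label3), VALID_LABEL3)
  if (length(bad) > 0L) {
    stop("unknown label3 value(s): ", paste(bad, collapse = ", "))
  }
  ifelse(label3 == "healthy", "healthy", "IBD")
}

#' Construct a SpectraSet
#'
#' The container every pipeline stage consumes and emits: a strictly
#' increasing, uniformly spaced wavelength grid (nm), an absorbance matrix
#' (one row per replicate spectrum) and per-spectrum metadata.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing with uniform spacing.
#' @param absorbance numeric matrix, `n_spectra x n_wavelengths`, unitless
#'   absorbance.  Row names (if absent) are taken from `meta$id`.
#' @param meta data.frame with columns `id`, `subject_id`, `replicate`
#'   (integer >= 1), `specimen` ("plasma" or "saliva") and `label3`
#'   ("healthy", "CD" or "UC").  A `label2` column is (re)derived from
#'   `label3`.
#' @return an object of class `SpectraSet`.
#' @export
spectra_set <- function(wavelengths, absorbance, meta) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)

  if (length(wavelengths) == 0L) stop("no wavelengths")
  if (nrow(absorbance) == 0L) stop("no spectra")
  if (ncol(absorbance) != length(wavelengths)) {
    stop("absorbance has ", ncol(absorbance), " columns but ",
         length(wavelengths), " wavelengths were given")
  }
  if (nrow(absorbance) != nrow(meta)) {
    stop("absorbance has ", nrow(absorbance), " rows but metadata has ",
         nrow(meta), " rows")
  }
  if (anyNA(absorbance)) stop("absorbance contains missing values")
  if (length(wavelengths) > 1L) {
    d <- diff(wavelengths)
    if (any(d <= 0)) stop("wavelengths must be strictly increasing")
    # acquisition grids are uniform; band-restricted sets are gapped, so
    # uniformity is not enforced here (grid_step() uses the median spacing)
  }

  required <- c("id", "subject_id", "replicate", "specimen", "label3")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta$id <- as.character(meta$id)
  meta$subject_id <- as.character(meta$subject_id)
  meta$replicate <- as.integer(meta$replicate)
  if (any(meta$replicate < 1L)) stop("replicate index must be >= 1")
  if (anyDuplicated(meta$id)) {
    stop("duplicate spectrum id: ", meta$id[duplicated(meta$id)][1L])
  }
  bad_spec <- setdiff(unique(meta$specimen), VALID_SPECIMEN)
  if (length(bad_spec) > 0L) {
    stop("unknown specimen value(s): ", paste(bad_spec, collapse = ", "))
  }
  meta$label2 <- derive_label2(meta$label3)
  rownames(absorbance) <- meta$id
  colnames(absorbance) <- format_wavelength(wavelengths)
  rownames(meta) <- NULL

  structure(
    list(wavelengths = wavelengths, absorbance = absorbance, meta = meta),
    class = "SpectraSet"
  )
}

format_wavelength <- function(w) formatC(w, format = "fg", digits = 12)

#' @export
print.SpectraSet <- function(x, ...) {
  cat(sprintf(
    "SpectraSet: %d spectra x %d wavelengths (%.1f-%.1f nm @ %.2g nm)\n",
    nrow(x$absorbance), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths),
    if (length(x$wavelengths) > 1L) x$wavelengths[2L] - x$wavelengths[1L] else NA_real_
  ))
  cat("  subjects:", length(unique(x$meta$subject_id)),
      " labels:", paste(sprintf("%s=%d", names(table(x$meta$label3)),
                                table(x$meta$label3)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.SpectraSet <- function(x) dim(x$absorbance)

#' Grid spacing of a wavelength vector
#'
#' Median spacing in nm: equals the acquisition interval on a uniform
#' grid and remains sensible on band-restricted (gapped) grids.
#'
#' @param wavelengths numeric vector of wavelengths (or a `SpectraSet`).
#' @return spacing in nm (1 for a single-point grid).
#' @export
grid_step <- function(wavelengths) {
  if (inherits(wavelengths, "SpectraSet")) wavelengths <- wavelengths$wavelengths
  if (length(wavelengths) < 2L) return(1)
  stats::median(diff(wavelengths))
}

#' Number of spectra in a SpectraSet
#' @param s a `SpectraSet`.
#' @return integer count of spectra (rows).
#' @export
n_spectra <- function(s) nrow(s$absorbance)

#' Keep a subset of spectra (rows) of a SpectraSet
#'
#' @param s a `SpectraSet`.
#' @param idx logical or integer row index.
#' @return a `SpectraSet` with the selected spectra.
#' @export
subset_spectra <- function(s, idx) {
  spectra_set(s$wavelengths, s$absorbance[idx, , drop = FALSE],
              s$meta[idx, , drop = FALSE])
}

#' Replace the absorbance matrix of a SpectraSet
#'
#' Used by pretreatment operators: the grid and metadata are preserved.
#' @param s a `SpectraSet`.
#' @param absorbance replacement matrix with the same dimensions.
#' @return a `SpectraSet`.
#' @export
set_absorbance <- function(s, absorbance) {
  spectra_set(s$wavelengths, absorbance, s$meta)
}

#' A closed wavelength interval in nm
#'
#' @param low,high interval endpoints in nm, `low < high`.
#' @return an object of class `wavelength_range`.
#' @export
wavelength_range <- function(low, high) {
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("wavelength_range requires low < high")
  }
  structure(list(low = low, high = high), class = "wavelength_range")
}

as_wavelength_range <- function(r) {
  if (inherits(r, "wavelength_range")) return(r)
  if (is.numeric(r) && length(r) == 2L) return(wavelength_range(r[1L], r[2L]))
  stop("cannot interpret wavelength range")
}

#' Restrict a SpectraSet to a wavelength window
#'
#' Keeps wavelengths in the closed interval `[low, high]` (both endpoints
#' kept, matching the inclusive way band limits are quoted in the
#' aquaphotomics literature).  Metadata is unchanged.
#'
#' @param s a `SpectraSet`.
#' @param range a [wavelength_range()] or numeric `c(low, high)`; the
#'   default is the 1300-1600 nm first-overtone analysis window.
#' @return a `SpectraSet` on the restricted grid.
#' @export
subset_range <- function(s, range = c(1300, 1600)) {
  r <- as_wavelength_range(range)
  keep <- s$wavelengths >= r$low - 1e-9 & s$wavelengths <= r$high + 1e-9
  if (!any(keep)) {
    stop(sprintf("no wavelengths in range %g-%g nm", r$low, r$high))
  }
  spectra_set(s$wavelengths[keep], s$absorbance[, keep, drop = FALSE], s$meta)
}

#' Read spectra and metadata from CSV
#'
#' The spectra file is a wide CSV: first column the spectrum id, remaining
#' column names numeric wavelengths in nm.  The metadata CSV has columns
#' `id`, `subject_id`, `replicate`, `specimen`, `label3`.  Rows are aligned
#' by id; the wavelength grid is sorted ascending (columns reordered with
#' it).
#'
#' @param path path to the wide spectra CSV.
#' @param meta_path path to the metadata CSV.
#' @return a validated `SpectraSet`.
#' @export
read_spectra <- function(path, meta_path) {
  wide <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(wide) == 0L) stop("no spectra in ", path)
  if (ncol(wide) < 2L) stop("spectra file has no wavelength columns")
  ids <- as.character(wide[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate spectrum id: ", ids[duplicated(ids)][1L])
  }
  wl <- suppressWarnings(as.numeric(names(wide)[-1L]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header cell: ",
         names(wide)[-1L][which(is.na(wl))[1L]])
  }
  a <- as.matrix(wide[, -1L, drop = FALSE])
  storage.mode(a) <- "double"
  ord <- order(wl)
  wl <- wl[ord]
  a <- a[, ord, drop = FALSE]

  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  meta$id <- as.character(meta$id)
  only_spectra <- setdiff(ids, meta$id)
  if (length(only_spectra) > 0L) {
    stop("spectrum without metadata row: ", only_spectra[1L])
  }
  only_meta <- setdiff(meta$id, ids)
  if (length(only_meta) > 0L) {
    stop("metadata row without spectrum: ", only_meta[1L])
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  rownames(a) <- ids
  spectra_set(wl, a, meta)
}

#' Write a SpectraSet to CSV
#'
#' Inverse of [read_spectra()]: writes the wide spectra table and the
#' metadata table.  A read of the written files reproduces the set.
#'
#' @param s a `SpectraSet`.
#' @param path output path for the wide spectra CSV.
#' @param meta_path output path for the metadata CSV.
#' @return invisibly, `s`.
#' @export
write_spectra <- function(s, path, meta_path) {
  wide <- data.frame(id = s$meta$id, check.names = FALSE,
                     stringsAsFactors = FALSE)
  a <- as.data.frame(s$absorbance, check.names = FALSE)
  names(a) <- format_wavelength(s$wavelengths)
  wide <- cbind(wide, a)
  utils::write.csv(wide, path, row.names = FALSE)
  meta <- s$meta[, c("id", "subject_id", "replicate", "specimen", "label3")]
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(s)
}

#' Per-class mean spectra and pairwise difference spectra
#'
#' Arithmetic mean spectrum per class plus every pairwise difference
#' (class A mean - class B mean), the standard first look at a
#' two-group NIR data set.
#'
#' @param s a `SpectraSet`.
#' @param by grouping label: `"label2"` (healthy/IBD) or `"label3"`.
#' @return a list with `wavelengths`, `means` (matrix, one row per class)
#'   and `differences` (named list of vectors, names `"A-B"`).
#' @export
class_mean_spectra <- function(s, by = c("label2", "label3")) {
  by <- match.arg(by)
  g <- s$meta[[by]]
  classes <- sort(unique(g))
  means <- t(vapply(classes, function(cl) {
    idx <- g == cl
    if (!any(idx)) stop("class with zero spectra: ", cl)
    colMeans(s$absorbance[idx, , drop = FALSE])
  }, numeric(length(s$wavelengths))))
  rownames(means) <- classes
  differences <- list()
  if (length(classes) > 1L) {
    for (i in seq_len(length(classes) - 1L)) {
      for (j in seq(i + 1L, length(classes))) {
        differences[[paste0(classes[i], "-", classes[j])]] <-
          means[i, ] - means[j, ]
      }
    }
  }
  list(wavelengths = s$wavelengths, means = means, differences = differences)
}

#' Write a validation report to CSV
#'
#' One row per (model, range, pretreatment, validation scheme, class) cell
#' with sensitivity, specificity, total accuracy (both the weighted and the
#' standard form) and the number of retained principal components.
#'
#' @param report a `validation_report` data.frame as produced by
#'   [run_experiment()] or assembled from [classification_metrics()].
#' @param path output CSV path.
#' @return invisibly, the report.
#' @export
write_results <- function(report, path) {
  cols <- c("model", "range", "pretreatment", "validation", "class",
            "sensitivity", "specificity", "total_accuracy",
            "standard_accuracy", "PCs")
  df <- as.data.frame(report, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
  }
  missing_cols <- setdiff(cols, names(df))
  for (mc in missing_cols) df[[mc]] <- NA
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(report)
}

#' Read a validation report written by [write_results()]
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
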