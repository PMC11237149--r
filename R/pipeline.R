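# Config-driven experiment grid: every (range x pretreatment x model x
# validation) cell is run independently; a failing cell is recorded in the
# report, never fatal (small classes legitimately break some folds).

#' Experiment configuration
#'
#' @param data a `SpectraSet`, or `NULL` to generate from `preset`.
#' @param preset synthetic preset name (see [preset()]) used when `data`
#'   is `NULL`.
#' @param label_field `"label2"` (healthy vs IBD) or `"label3"`
#'   (healthy / CD / UC).
#' @param ranges subset of `"full_1300_1600"`, `"wamac12"`.
#' @param pretreatments list of [preprocess_spec()] recipes (default: raw
#'   spectra only).
#' @param models subset of `"LDA"`, `"QDA"`, `"SVM"`.
#' @param validations subset of `"loo"` (leave-one-subject-out on the full
#'   set) and `"external"` (75/25 calibration/test split; also reports the
#'   calibration resubstitution row).
#' @param pc_threshold cumulative explained-variance threshold (percent).
#' @param frac calibration fraction of the external split.
#' @param unit leave-one-out unit, `"subject"` or `"spectrum"`.
#' @param seed master seed: cohort generation and the external split
#'   derive from it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(data = NULL, preset = "plasma_ibd",
                              label_field = "label2",
                              ranges = c("full_1300_1600", "wamac12"),
                              pretreatments = list(preprocess_spec()),
                              models = "LDA",
                              validations = "loo",
                              pc_threshold = 99, frac = 0.75,
                              unit = "subject", seed = 1L) {
  ranges <- match.arg(ranges, c("full_1300_1600", "wamac12"),
                      several.ok = TRUE)
  models <- toupper(models)
  stopifnot(all(models %in% c("LDA", "QDA", "SVM")),
            all(validations %in% c("loo", "external")),
            length(ranges) > 0L, length(pretreatments) > 0L,
            length(models) > 0L, length(validations) > 0L)
  if (!all(vapply(pretreatments, inherits, logical(1L), "preprocess_spec"))) {
    stop("pretreatments must be a list of preprocess_spec objects")
  }
  structure(
    list(data = data, preset = preset, label_field = label_field,
         ranges = ranges, pretreatments = pretreatments, models = models,
         validations = validations, pc_threshold = pc_threshold,
         frac = frac, unit = unit, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

report_row <- function(model, range, pretreatment, validation, class = NA,
                       sensitivity = NA, specificity = NA,
                       total_accuracy = NA, standard_accuracy = NA,
                       PCs = NA, r2 = NA, rmsec = NA, error = NA) {
  data.frame(model = model, range = range, pretreatment = pretreatment,
             validation = validation, class = class,
             sensitivity = sensitivity, specificity = specificity,
             total_accuracy = total_accuracy,
             standard_accuracy = standard_accuracy, PCs = PCs,
             r2 = r2, rmsec = rmsec, error = error,
             stringsAsFactors = FALSE)
}

metric_rows <- function(cm, model, range, pretreatment, validation, k,
                        r2 = NA, rmsec = NA) {
  met <- classification_metrics(cm)
  do.call(rbind, lapply(seq_len(nrow(met)), function(i) {
    report_row(model, range, pretreatment, validation, met$class[i],
               met$sensitivity[i], met$specificity[i],
               met$total_accuracy[i], met$standard_accuracy[i], k,
               r2, rmsec)
  }))
}

#' Run an experiment grid
#'
#' For every (range x pretreatment x model x validation) cell:
#' subset/extract the wavelength range, apply the pretreatment with
#' fit-on-train semantics, fit PCA and select components at the
#' explained-variance threshold, fit and predict the classifier, and
#' compute per-class quality metrics.  A failing cell contributes a row
#' with the error message instead of aborting the run; the report carries
#' the master seed as an attribute and is byte-identical across runs with
#' the same config and seed.
#'
#' @param cfg an [experiment_config()].
#' @return a `validation_report` data.frame, one row per cell per class.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  s <- if (!is.null(cfg$data)) cfg$data
       else generate_cohort(preset(cfg$preset, seed = cfg$seed))
  s <- subset_range(s, c(1300, 1600))
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (rg in cfg$ranges) {
    s_r <- if (rg == "wamac12") extract_wamac(s) else s
    for (pt in cfg$pretreatments) {
      for (md in cfg$models) {
        for (vl in cfg$validations) {
          cell <- tryCatch({
            if (vl == "loo") {
              fit <- leave_one_out(s_r, pt, md, unit = cfg$unit,
                                   label_field = cfg$label_field,
                                   pc_threshold = cfg$pc_threshold)
              metric_rows(fit$confusion, md, rg, pt$label, "loo_total",
                          fit$k)
            } else {
              split <- split_calibration_test(s_r, cfg$frac,
                                              seed = cfg$seed + 1L)
              ext <- external_validation(split, pt, md,
                                         label_field = cfg$label_field,
                                         pc_threshold = cfg$pc_threshold)
              r2 <- if (is.null(ext$r2)) NA else ext$r2
              rmsec <- if (is.null(ext$rmsec)) NA else ext$rmsec
              rbind(
                metric_rows(ext$calibration_confusion, md, rg, pt$label,
                            "loo_calibration", ext$k, r2, rmsec),
                metric_rows(ext$test_confusion, md, rg, pt$label,
                            "external_test", ext$k, r2, rmsec)
              )
            }
          }, error = function(e) {
            report_row(md, rg, pt$label,
                       if (vl == "loo") "loo_total" else "external_test",
                       error = conditionMessage(e))
          })
          add(cell)
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "seed") <- cfg$seed
  class(report) <- c("validation_report", "data.frame")
  report
}

#' Read an experiment configuration from YAML
#'
#' Recognised top-level keys: `preset`, `spectra`/`meta` (CSV paths,
#' override `preset`), `label_field`, `ranges`, `pretreatments` (list of
#' step lists, each step a name or a `name:`+params mapping), `models`,
#' `validations`, `pc_threshold`, `frac`, `unit`, `seed`.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  data <- NULL
  if (!is.null(y$spectra)) {
    if (is.null(y$meta)) stop("config with 'spectra' needs 'meta'")
    data <- read_spectra(y$spectra, y$meta)
  }
  pretreatments <- if (is.null(y$pretreatments)) list(preprocess_spec())
    else lapply(y$pretreatments, function(p) preprocess_spec(p))
  args <- list(data = data, pretreatments = pretreatments)
  for (key in c("preset", "label_field", "ranges", "models", "validations",
                "pc_threshold", "frac", "unit", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- unlist(y[[key]])
  }
  do.call(experiment_config, args)
}
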