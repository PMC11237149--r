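# Internal (leave-one-out) and external (75/25 calibration/test)
# validation with confusion-matrix quality metrics.  The validation unit
# defaults to the subject: all replicates of a subject travel together, so
# replicate leakage cannot inflate accuracy.

#' One-vs-rest confusion counts
#'
#' For every class: TP, FP, TN, FN with that class as the positive one and
#' everything else pooled as negative.  `TP + FP + TN + FN` equals the
#' number of evaluated units for every class.
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @return an object of class `confusion_matrix`: a data.frame with
#'   columns `class`, `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  classes <- sort(unique(c(truth, pred)))
  out <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(class = cl,
               TP = sum(truth == cl & pred == cl),
               FP = sum(truth != cl & pred == cl),
               TN = sum(truth != cl & pred != cl),
               FN = sum(truth == cl & pred != cl),
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("confusion_matrix", "data.frame"),
            n = length(truth), truth = truth, pred = pred)
}

cm_row <- function(cm, class) {
  i <- match(class, cm$class)
  if (is.na(i)) stop("class not in confusion matrix: ", class)
  cm[i, , drop = FALSE]
}

#' Classification quality metrics
#'
#' Sensitivity `100 * TP / (TP + FN)`, specificity `100 * TN / (TN + FP)`,
#' and two total-accuracy variants: the weighted form
#' `(TN * TN/(TN+FP) + TP * TP/(TP+FN)) / n * 100` (class-prevalence
#' weighted mean of sensitivity and specificity) and the standard form
#' `100 * (TP + TN) / n`.  Metrics with a zero denominator are reported as
#' `NA`, never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @param class the positive class.
#' @return `sensitivity`/`specificity`/`total_accuracy_eq3`/
#'   `standard_accuracy`: a percentage (or `NA`).
#' @export
sensitivity <- function(cm, class) {
  r <- cm_row(cm, class)
  if (r$TP + r$FN == 0L) return(NA_real_)
  100 * r$TP / (r$TP + r$FN)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm, class) {
  r <- cm_row(cm, class)
  if (r$TN + r$FP == 0L) return(NA_real_)
  100 * r$TN / (r$TN + r$FP)
}

#' @rdname sensitivity
#' @export
total_accuracy_eq3 <- function(cm, class) {
  r <- cm_row(cm, class)
  n <- r$TP + r$FP + r$TN + r$FN
  if (n == 0L) stop("empty confusion matrix")
  tn_term <- if (r$TN + r$FP > 0L) r$TN^2 / (r$TN + r$FP) else 0
  tp_term <- if (r$TP + r$FN > 0L) r$TP^2 / (r$TP + r$FN) else 0
  100 * (tn_term + tp_term) / n
}

#' @rdname sensitivity
#' @export
standard_accuracy <- function(cm, class) {
  r <- cm_row(cm, class)
  n <- r$TP + r$FP + r$TN + r$FN
  if (n == 0L) stop("empty confusion matrix")
  100 * (r$TP + r$TN) / n
}

#' Overall multiclass accuracy of a confusion matrix
#' @param cm a [confusion_matrix()].
#' @return percentage of correctly classified units.
#' @export
multiclass_accuracy <- function(cm) {
  100 * sum(cm$TP) / attr(cm, "n")
}

#' Per-class metric table for a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with one row per class: sensitivity, specificity,
#'   total accuracy (weighted form) and standard accuracy.
#' @export
classification_metrics <- function(cm) {
  do.call(rbind, lapply(cm$class, function(cl) {
    data.frame(class = cl,
               sensitivity = sensitivity(cm, cl),
               specificity = specificity(cm, cl),
               total_accuracy = total_accuracy_eq3(cm, cl),
               standard_accuracy = standard_accuracy(cm, cl),
               stringsAsFactors = FALSE)
  }))
}

# Preference order used to break ties toward the disease-positive class
# when aggregating a subject's replicate predictions: the screening intent
# favours sensitivity.
DEFAULT_POSITIVE_ORDER <- c("CD", "UC", "IBD", "healthy")

majority_vote <- function(preds, positive_order = DEFAULT_POSITIVE_ORDER) {
  tab <- table(preds)
  best <- names(tab)[tab == max(tab)]
  if (length(best) == 1L) return(best)
  ranked <- c(intersect(positive_order, best), setdiff(sort(best), positive_order))
  ranked[1L]
}

#' Subject-level stratified calibration/test split
#'
#' Splits at the subject level (all replicates of a subject travel
#' together), stratified by class: per class, `round(frac * n_subjects)`
#' subjects go to the calibration subset, clamped so each side keeps at
#' least one subject per class.  Deterministic given the seed.
#'
#' @param s a `SpectraSet`.
#' @param frac calibration fraction (default 0.75).
#' @param seed RNG seed for the subject shuffle.
#' @param label_field stratification label column (`"label3"` or
#'   `"label2"`).
#' @return list with `calibration` and `test` SpectraSets.
#' @export
split_calibration_test <- function(s, frac = 0.75, seed = 1L,
                                   label_field = c("label3", "label2")) {
  label_field <- match.arg(label_field)
  subj <- unique(s$meta[, c("subject_id", label_field)])
  names(subj)[2L] <- "label"
  counts <- table(subj$label)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    stop("class with fewer than 2 subjects cannot be split: ",
         paste(small, collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  cal_subjects <- character(0)
  for (cl in sort(names(counts))) {
    ids <- sort(subj$subject_id[subj$label == cl])
    n_cal <- min(max(round(frac * length(ids)), 1L), length(ids) - 1L)
    cal_subjects <- c(cal_subjects, sample(ids, n_cal))
  }
  in_cal <- s$meta$subject_id %in% cal_subjects
  list(calibration = subset_spectra(s, in_cal),
       test = subset_spectra(s, !in_cal))
}

# Shared train/predict core: pretreat (fit on train), PCA (fit on train),
# select components, fit classifier on train scores, predict test spectra.
train_and_predict <- function(train, test, pipeline, model_kind,
                              label_field, pc_threshold, model_params) {
  fitted_pre <- fit_preprocess(pipeline, train)
  Xtr <- fitted_pre$transformed
  test_t <- apply_preprocess(fitted_pre, test)
  pca <- pca_fit(Xtr)
  k <- select_components(pca, pc_threshold)
  str <- pca$scores[, seq_len(k), drop = FALSE]
  ste <- pca_project(pca, test_t$absorbance, k)
  m <- fit_model(model_kind, str, train$meta[[label_field]], model_params)
  list(pred = predict_model(m, ste), model = m, k = k,
       train_scores = str, train_labels = train$meta[[label_field]])
}

#' Leave-one-out cross-validation
#'
#' Holds out one unit at a time (a subject and all its replicates by
#' default, or a single spectrum), fits pretreatment statistics, PCA and
#' the classifier on the remainder, and predicts the held-out spectra.
#' With the subject unit, a subject's replicate predictions are aggregated
#' by majority vote; ties break toward the disease-positive class.
#'
#' @param s a `SpectraSet`.
#' @param pipeline a [preprocess_spec()] (default: none / raw).
#' @param model `"LDA"`, `"QDA"` or `"SVM"`.
#' @param unit `"subject"` (default, leakage-safe) or `"spectrum"`.
#' @param label_field `"label2"` or `"label3"`.
#' @param pc_threshold cumulative explained-variance threshold for
#'   component selection (percent).
#' @param model_params list of extra arguments for the classifier fit.
#' @param positive_order tie-break preference for the majority vote.
#' @return list with `confusion` ([confusion_matrix()] at the unit level),
#'   `truth`, `pred`, `units`, `k` (median retained components).
#' @export
leave_one_out <- function(s, pipeline = preprocess_spec(), model = "LDA",
                          unit = c("subject", "spectrum"),
                          label_field = c("label2", "label3"),
                          pc_threshold = 99, model_params = list(),
                          positive_order = DEFAULT_POSITIVE_ORDER) {
  unit <- match.arg(unit)
  label_field <- match.arg(label_field)
  units <- if (unit == "subject") unique(s$meta$subject_id) else s$meta$id
  if (length(units) < 3L) stop("leave-one-out needs at least 3 units")
  unit_col <- if (unit == "subject") "subject_id" else "id"
  all_classes <- sort(unique(s$meta[[label_field]]))
  truth <- character(length(units))
  pred <- character(length(units))
  ks <- integer(length(units))
  for (u in seq_along(units)) {
    held <- s$meta[[unit_col]] == units[u]
    train <- subset_spectra(s, !held)
    test <- subset_spectra(s, held)
    if (!setequal(unique(train$meta[[label_field]]), all_classes)) {
      stop("training fold for unit '", units[u], "' lost an entire class")
    }
    res <- train_and_predict(train, test, pipeline, model, label_field,
                             pc_threshold, model_params)
    truth[u] <- test$meta[[label_field]][1L]
    pred[u] <- if (length(res$pred) > 1L) {
      majority_vote(res$pred, positive_order)
    } else {
      res$pred
    }
    ks[u] <- res$k
  }
  list(confusion = confusion_matrix(truth, pred), truth = truth, pred = pred,
       units = units, k = stats::median(ks))
}

#' External validation on a calibration/test split
#'
#' Fits pretreatment, PCA and the classifier on the calibration subset and
#' predicts the test subset; evaluation is at the subject level (replicate
#' majority vote).  Also returns the calibration-set (resubstitution)
#' confusion and, for SVM, calibration R-squared / RMSEC.
#'
#' @param split a list with `calibration` and `test` SpectraSets, as from
#'   [split_calibration_test()].
#' @inheritParams leave_one_out
#' @return list with `test_confusion`, `calibration_confusion`, `k` and
#'   (for SVM) `r2`, `rmsec`.
#' @export
external_validation <- function(split, pipeline = preprocess_spec(),
                                model = "LDA",
                                label_field = c("label2", "label3"),
                                pc_threshold = 99, model_params = list(),
                                positive_order = DEFAULT_POSITIVE_ORDER) {
  label_field <- match.arg(label_field)
  cal <- split$calibration; test <- split$test
  res <- train_and_predict(cal, test, pipeline, model, label_field,
                           pc_threshold, model_params)
  subject_level <- function(set, preds) {
    subjects <- unique(set$meta$subject_id)
    truth <- vapply(subjects, function(sj)
      set$meta[[label_field]][set$meta$subject_id == sj][1L], character(1L))
    agg <- vapply(subjects, function(sj)
      majority_vote(preds[set$meta$subject_id == sj], positive_order),
      character(1L))
    confusion_matrix(truth, agg)
  }
  cal_pred <- predict_model(res$model, res$train_scores)
  out <- list(test_confusion = subject_level(test, res$pred),
              calibration_confusion = subject_level(cal, cal_pred),
              k = res$k)
  if (toupper(model) == "SVM") {
    stats_cal <- svm_regression_stats(res$model, res$train_scores,
                                      res$train_labels)
    out$r2 <- stats_cal$r2
    out$rmsec <- stats_cal$rmsec
  }
  out
}
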