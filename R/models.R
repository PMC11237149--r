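# PCA decomposition and discriminant / SVM classifiers on PC scores,
# implemented from their defining math.  MASS and e1071 serve as
# independent cross-checks in the test suite only.

as_spectra_matrix <- function(s) {
  if (inherits(s, "SpectraSet")) s$absorbance else as.matrix(s)
}

#' Principal component analysis of a spectra matrix
#'
#' Column-mean-centred singular value decomposition.  The explained
#' variance of component i is `100 * sigma_i^2 / sum(sigma_j^2)` over the
#' full rank, so percentages are comparable regardless of how many
#' components are retained.  Component signs are fixed by making the
#' largest-magnitude loading entry of each component positive, which makes
#' score and loading plots reproducible.
#'
#' @param s a `SpectraSet` or numeric matrix (spectra in rows).
#' @param max_components maximum number of components to retain
#'   (default: full rank).
#' @return an object of class `pca_model` with `mean_spectrum`, `loadings`
#'   (wavelengths x k, orthonormal columns), `scores` (spectra x k),
#'   `explained_pct`, `score_var` and `n`.
#' @export
pca_fit <- function(s, max_components = Inf) {
  X <- as_spectra_matrix(s)
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 spectra")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  if (total <= 1e-24) stop("zero variance: all spectra are identical")
  keep <- sv$d^2 / total > 1e-12          # drop numerically null components
  k <- min(sum(keep), max_components, n - 1L)
  d <- sv$d[seq_len(k)]
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k, k)
  for (j in seq_len(k)) {                  # deterministic sign convention
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(mean_spectrum = mu, loadings = loadings, scores = scores,
         explained_pct = 100 * d^2 / total,
         score_var = d^2 / (n - 1L), n = n),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA:", x$n, "spectra,", ncol(x$loadings), "components\n")
  cat("  explained %:", paste(sprintf("%.1f", utils::head(x$explained_pct, 6)),
                              collapse = " "),
      if (length(x$explained_pct) > 6) "...\n" else "\n")
  invisible(x)
}

#' Project spectra onto a fitted PCA model
#'
#' @param m a `pca_model`.
#' @param s a `SpectraSet` or matrix on the model's wavelength grid.
#' @param k number of components (default: all in the model).
#' @return score matrix (spectra x k).
#' @export
pca_project <- function(m, s, k = ncol(m$loadings)) {
  X <- as_spectra_matrix(s)
  sweep(X, 2L, m$mean_spectrum, "-") %*% m$loadings[, seq_len(k), drop = FALSE]
}

#' Number of components reaching a cumulative explained-variance threshold
#'
#' The smallest k whose cumulative explained variance reaches the
#' threshold (k is at least 1, and capped at the number of components in
#' the model).
#'
#' @param m a `pca_model`.
#' @param threshold_pct cumulative explained variance threshold in percent
#'   (default 99, the usual choice for PCA-LDA calibration).
#' @return integer k.
#' @export
select_components <- function(m, threshold_pct = 99) {
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]")
  }
  cum <- cumsum(m$explained_pct)
  k <- which(cum >= threshold_pct - 1e-9)[1L]
  if (is.na(k)) k <- length(cum)
  max(1L, k)
}

#' Hotelling T-squared outlier screening in PCA score space
#'
#' `T2_i = sum_j score_ij^2 / var_j` over the first k components, with the
#' F-distribution control limit
#' `k (n-1) / (n-k) * F_{1-alpha}(k, n-k)`.
#'
#' @param m a `pca_model`.
#' @param k number of components (`k < n`).
#' @param alpha significance level of the control limit.
#' @return list with `t2` (per spectrum), `limit` and `flagged` (logical).
#' @export
hotelling_t2 <- function(m, k = ncol(m$loadings), alpha = 0.05) {
  n <- m$n
  if (k >= n) stop("Hotelling T2 needs n > k")
  sc <- m$scores[, seq_len(k), drop = FALSE]
  v <- m$score_var[seq_len(k)]
  t2 <- drop(sc^2 %*% (1 / v))
  limit <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  list(t2 = t2, limit = limit, flagged = t2 > limit)
}

# ---- Gaussian discriminant analysis -----------------------------------

# Ridge-stabilised covariance inverse pieces: returns list(inv, logdet).
# Adds ridge * trace/dim to the diagonal, escalating a few times before
# giving up, so the near-singular covariances produced by small classes
# (2-3 subjects) remain usable.
stable_cov_inverse <- function(S, ridge = 1e-8, what = "covariance") {
  d <- ncol(S)
  scale <- sum(diag(S)) / d
  if (!is.finite(scale) || scale <= 0) scale <- 1
  r <- ridge
  for (i in 1:8) {
    ch <- tryCatch(chol(S + diag(r * scale, d)), error = function(e) NULL)
    if (!is.null(ch) && all(diag(ch) > 1e-12 * sqrt(scale))) {
      inv <- chol2inv(ch)
      return(list(inv = inv, logdet = 2 * sum(log(diag(ch)))))
    }
    r <- r * 100
  }
  stop("singular ", what, " in ", d, " dimensions even after ridge regularization")
}

class_means <- function(X, labels, classes) {
  m <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[labels == cl, , drop = FALSE])))
  rownames(m) <- classes
  m
}

check_classes <- function(labels, min_per_class = 2L) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes")
  small <- names(tab)[tab < min_per_class]
  if (length(small) > 0L) {
    stop("class with fewer than ", min_per_class, " samples: ",
         paste(small, collapse = ", "))
  }
  sort(names(tab))
}

#' Linear discriminant analysis on PC scores
#'
#' Gaussian discriminant with a shared pooled covariance
#' `sum_c (n_c - 1) S_c / (n - C)` and (by default) empirical class
#' priors.  Prediction assigns the class maximising
#' `log prior - Mahalanobis^2 / 2`; exact ties break to the first class in
#' sorted class-name order.
#'
#' @param scores numeric matrix (samples x dimensions).
#' @param labels class labels.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`, or a
#'   named numeric vector summing to 1.
#' @param ridge diagonal regularization added (times trace/dim) when the
#'   pooled covariance is near-singular.
#' @return an object of class `lda_model`.
#' @export
lda_fit <- function(scores, labels, priors = "empirical", ridge = 1e-8) {
  X <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- check_classes(labels)
  n <- nrow(X); d <- ncol(X); C <- length(classes)
  means <- class_means(X, labels, classes)
  pooled <- matrix(0, d, d)
  for (cl in classes) {
    Xc <- X[labels == cl, , drop = FALSE]
    pooled <- pooled + stats::cov(Xc) * (nrow(Xc) - 1L)
  }
  pooled <- pooled / (n - C)
  pr <- resolve_priors(priors, labels, classes)
  inv <- stable_cov_inverse(pooled, ridge, "pooled covariance")
  structure(
    list(kind = "LDA", classes = classes, means = means, covariance = pooled,
         cov_inv = inv$inv, priors = pr),
    class = "lda_model"
  )
}

resolve_priors <- function(priors, labels, classes) {
  if (identical(priors, "empirical")) {
    pr <- as.numeric(table(factor(labels, classes))) / length(labels)
  } else if (identical(priors, "uniform")) {
    pr <- rep(1 / length(classes), length(classes))
  } else {
    pr <- as.numeric(priors[classes])
    if (anyNA(pr) || abs(sum(pr) - 1) > 1e-9) stop("invalid priors")
  }
  stats::setNames(pr, classes)
}

#' @rdname lda_fit
#' @param model a fitted `lda_model`.
#' @param newscores matrix of samples to classify.
#' @return `lda_predict`: character vector of predicted labels.
#' @export
lda_predict <- function(model, newscores) {
  X <- as.matrix(newscores)
  disc <- vapply(seq_along(model$classes), function(i) {
    dx <- sweep(X, 2L, model$means[i, ], "-")
    -0.5 * rowSums((dx %*% model$cov_inv) * dx) + log(model$priors[i])
  }, numeric(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X))
  model$classes[apply(disc, 1L, which.max)]
}

#' Quadratic discriminant analysis on PC scores
#'
#' Gaussian discriminant with per-class covariances: assigns the class
#' maximising `log prior - log|S_c|/2 - Mahalanobis^2(x; mu_c, S_c)/2`.
#' Class covariances from small classes are ridge-regularized like the
#' pooled covariance in [lda_fit()].
#'
#' @inheritParams lda_fit
#' @return an object of class `qda_model`.
#' @export
qda_fit <- function(scores, labels, priors = "empirical", ridge = 1e-8) {
  X <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- check_classes(labels)
  means <- class_means(X, labels, classes)
  covs <- lapply(classes, function(cl) {
    Xc <- X[labels == cl, , drop = FALSE]
    S <- stats::cov(Xc)
    stable_cov_inverse(S, ridge, paste0("class '", cl, "' covariance"))
  })
  pr <- resolve_priors(priors, labels, classes)
  structure(
    list(kind = "QDA", classes = classes, means = means, covs = covs,
         priors = pr),
    class = "qda_model"
  )
}

#' @rdname qda_fit
#' @param model a fitted `qda_model`.
#' @param newscores matrix of samples to classify.
#' @export
qda_predict <- function(model, newscores) {
  X <- as.matrix(newscores)
  disc <- vapply(seq_along(model$classes), function(i) {
    dx <- sweep(X, 2L, model$means[i, ], "-")
    -0.5 * model$covs[[i]]$logdet -
      0.5 * rowSums((dx %*% model$covs[[i]]$inv) * dx) + log(model$priors[i])
  }, numeric(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X))
  model$classes[apply(disc, 1L, which.max)]
}

# ---- Soft-margin SVM (SMO) --------------------------------------------

svm_kernel <- function(kernel, gamma) {
  switch(kernel,
    linear = function(A, B) tcrossprod(A, B),
    rbf = function(A, B) {
      an <- rowSums(A^2); bn <- rowSums(B^2)
      exp(-gamma * (outer(an, bn, "+") - 2 * tcrossprod(A, B)))
    },
    stop("unknown kernel: ", kernel)
  )
}

# Sequential minimal optimisation for the binary soft-margin dual.
# Deterministic: the second working-set index maximises |E_i - E_j|.
smo_binary <- function(K, y, C, tol = 1e-4, max_passes = 30L,
                       max_sweeps = 5000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  decision <- function() drop(K %*% (alpha * y)) + b
  passes <- 0L; sweeps <- 0L
  while (passes < max_passes && sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    changed <- 0L
    E <- decision() - y
    for (i in seq_len(n)) {
      Ei <- sum(K[i, ] * alpha * y) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        gap <- abs(E - Ei); gap[i] <- -1
        j <- which.max(gap)
        Ej <- sum(K[j, ] * alpha * y) + b - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        E <- decision() - y
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

#' Soft-margin support vector machine on PC scores
#'
#' Binary SVM trained by sequential minimal optimisation of the dual;
#' multiclass problems use one-vs-one voting with ties broken by summed
#' decision values.  The working-set choice is deterministic, so training
#' is reproducible without touching the RNG.
#'
#' @param scores numeric matrix (samples x dimensions).
#' @param labels class labels (>= 2 classes).
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param C soft-margin cost (> 0), default 1.
#' @param gamma RBF kernel width; default `1 / ncol(scores)`.
#' @param scale standardize each score column to zero mean and unit
#'   variance before training (default `TRUE`, the libsvm convention;
#'   PC scores span orders of magnitude, and an unscaled soft margin at
#'   moderate C underfits tiny-scale inputs).  Prediction applies the
#'   stored training centre/scale.
#' @return an object of class `svm_model`.
#' @export
svm_fit <- function(scores, labels, kernel = c("linear", "rbf"), C = 1,
                    gamma = NULL, scale = TRUE) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be > 0")
  X <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- check_classes(labels, min_per_class = 1L)
  if (scale) {
    centre <- colMeans(X)
    sds <- apply(X, 2L, stats::sd)
    sds[!is.finite(sds) | sds < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, centre, "-"), 2L, sds, "/")
  } else {
    centre <- rep(0, ncol(X)); sds <- rep(1, ncol(X))
  }
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  kf <- svm_kernel(kernel, gamma)
  machines <- list()
  for (i in seq_len(length(classes) - 1L)) {
    for (j in seq(i + 1L, length(classes))) {
      idx <- labels %in% c(classes[i], classes[j])
      Xi <- X[idx, , drop = FALSE]
      yi <- ifelse(labels[idx] == classes[i], 1, -1)
      K <- kf(Xi, Xi)
      fit <- smo_binary(K, yi, C)
      sv <- fit$alpha > 1e-8
      machines[[paste(classes[i], classes[j], sep = "|")]] <- list(
        positive = classes[i], negative = classes[j],
        X = Xi[sv, , drop = FALSE],
        coef = (fit$alpha * yi)[sv], b = fit$b)
    }
  }
  structure(
    list(kind = "SVM", classes = classes, machines = machines,
         kernel = kernel, C = C, gamma = gamma,
         centre = centre, scale = sds),
    class = "svm_model"
  )
}

svm_decision <- function(model, machine, X) {
  kf <- svm_kernel(model$kernel, model$gamma)
  drop(kf(X, machine$X) %*% machine$coef) + machine$b
}

#' @rdname svm_fit
#' @param model a fitted `svm_model`.
#' @param newscores matrix of samples to classify.
#' @export
svm_predict <- function(model, newscores) {
  X <- as.matrix(newscores)
  X <- sweep(sweep(X, 2L, model$centre, "-"), 2L, model$scale, "/")
  classes <- model$classes
  votes <- matrix(0L, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
  sums <- matrix(0, nrow(X), length(classes), dimnames = list(NULL, classes))
  for (m in model$machines) {
    f <- svm_decision(model, m, X)
    pos <- f >= 0
    votes[, m$positive] <- votes[, m$positive] + as.integer(pos)
    votes[, m$negative] <- votes[, m$negative] + as.integer(!pos)
    sums[, m$positive] <- sums[, m$positive] + f
    sums[, m$negative] <- sums[, m$negative] - f
  }
  vapply(seq_len(nrow(X)), function(r) {
    best <- which(votes[r, ] == max(votes[r, ]))
    if (length(best) > 1L) best <- best[which.max(sums[r, best])]
    classes[best[1L]]
  }, character(1L))
}

#' Numeric class coding used for SVM calibration statistics
#'
#' healthy = 0, IBD = 1 for the two-class problem; healthy = 0, UC = 1,
#' CD = 2 for the three-class problem; otherwise 0, 1, ... in sorted
#' class order.
#'
#' @param classes character vector of class names.
#' @return named numeric vector of codes.
#' @export
class_codes <- function(classes) {
  classes <- unique(as.character(classes))
  if (setequal(classes, c("healthy", "IBD"))) {
    return(c(healthy = 0, IBD = 1))
  }
  if (setequal(classes, c("healthy", "UC", "CD"))) {
    return(c(healthy = 0, UC = 1, CD = 2))
  }
  stats::setNames(seq_along(sort(classes)) - 1, sort(classes))
}

#' Calibration R-squared and RMSEC of an SVM classifier
#'
#' Regresses the numeric class codes ([class_codes()]) of the true labels
#' on the codes of the model's fitted (predicted) labels over the
#' calibration set: `R2 = 100 * (1 - SS_res / SS_tot)` (percent) and
#' `RMSEC = sqrt(mean((code - fitted code)^2))`.  A perfect fit gives
#' R2 = 100 and RMSEC = 0.
#'
#' @param model a fitted `svm_model`.
#' @param scores calibration score matrix.
#' @param labels calibration labels.
#' @return list with `r2` (percent) and `rmsec`.
#' @export
svm_regression_stats <- function(model, scores, labels) {
  codes <- class_codes(model$classes)
  obs <- codes[as.character(labels)]
  fit <- codes[svm_predict(model, scores)]
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 100 * (1 - sum((obs - fit)^2) / ss_tot) else NA_real_
  list(r2 = r2, rmsec = sqrt(mean((obs - fit)^2)))
}

# ---- dispatcher used by the validation layer --------------------------

fit_model <- function(kind, scores, labels, params = list()) {
  kind <- toupper(kind)
  switch(kind,
    LDA = do.call(lda_fit, c(list(scores, labels), params)),
    QDA = do.call(qda_fit, c(list(scores, labels), params)),
    SVM = do.call(svm_fit, c(list(scores, labels), params)),
    stop("unknown model kind: ", kind)
  )
}

predict_model <- function(model, scores) {
  switch(model$kind,
    LDA = lda_predict(model, scores),
    QDA = qda_predict(model, scores),
    SVM = svm_predict(model, scores),
    stop("unknown model kind")
  )
}

# ---- JSON serialization ----------------------------------------------

#' Serialize a fitted model to JSON
#'
#' Writes means, covariances, loadings and support vectors as nested
#' arrays for audit.  Supports `pca_model`, `lda_model`, `qda_model` and
#' `svm_model`.
#'
#' @param model a fitted model object.
#' @param path output path for the JSON file.
#' @return invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  to_plain <- function(x) {
    if (is.matrix(x)) return(apply(x, 1L, as.numeric, simplify = FALSE))
    if (is.list(x)) return(lapply(x, to_plain))
    x
  }
  payload <- c(list(type = class(model)[1L]), to_plain(unclass(model)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
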