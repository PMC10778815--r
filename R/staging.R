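# Integrated radiogenomic staging classifiers: five families, recursive
# feature elimination with a per-category cap, sensitivity-first model
# selection, and confusion-matrix evaluation. Positive class = extra-vesical.

STAGE_LEVELS <- c("intra", "extra")

as_stage_factor <- function(x) {
  x <- as.character(x)
  if (!all(x %in% STAGE_LEVELS)) stop("stage labels must be 'intra' or 'extra'")
  factor(x, levels = STAGE_LEVELS)
}

# Gaussian naive Bayes, implemented in vectorized form because the RFE
# search refits thousands of models; prediction-equivalent to
# e1071::naiveBayes (verified in the test suite).
gnb_fit <- function(X, y) {
  st <- lapply(STAGE_LEVELS, function(cl) {
    Z <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Z),
         sd = pmax(apply(Z, 2, stats::sd), 1e-9),
         logprior = log(nrow(Z) / nrow(X)))
  })
  names(st) <- STAGE_LEVELS
  st
}

gnb_predict <- function(fit, X) {
  ll <- vapply(STAGE_LEVELS, function(cl) {
    s <- fit[[cl]]
    rowSums(matrix(stats::dnorm(t(X), s$mu, s$sd, log = TRUE),
                   nrow(X), ncol(X), byrow = TRUE)) + s$logprior
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow(X), 2)
  factor(STAGE_LEVELS[max.col(ll, ties.method = "first")], levels = STAGE_LEVELS)
}

fit_family <- function(family, X, y, hyper = list()) {
  df <- data.frame(X, check.names = FALSE)
  switch(family,
    NB = gnb_fit(X, y),
    SVM = e1071::svm(X, y, kernel = hyper$svm_kernel %||% "linear",
                     cost = hyper$svm_cost %||% 1, scale = FALSE),
    KNN = list(X = X, y = y, k = hyper$knn_k %||% 3),
    LR = suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                     family = stats::binomial(),
                                     control = list(maxit = 50))),
    DT = rpart::rpart(y ~ ., data = cbind(df, y = y), method = "class",
                      control = rpart::rpart.control(
                        maxdepth = hyper$dt_depth %||% 3, minsplit = 4,
                        cp = 0.001, xval = 0)),
    stop("unknown classifier family: ", family))
}

predict_family <- function(family, fit, X, threshold = 0.5) {
  df <- data.frame(X, check.names = FALSE)
  switch(family,
    NB = gnb_predict(fit, X),
    SVM = factor(as.character(stats::predict(fit, X)), levels = STAGE_LEVELS),
    KNN = {
      cl <- class::knn(fit$X, X, fit$y, k = min(fit$k, nrow(fit$X)),
                       use.all = TRUE)
      factor(as.character(cl), levels = STAGE_LEVELS)
    },
    LR = {
      pr <- stats::predict(fit, newdata = df, type = "response")
      factor(ifelse(pr > threshold, "extra", "intra"), levels = STAGE_LEVELS)
    },
    DT = {
      pr <- stats::predict(fit, newdata = df, type = "prob")[, "extra"]
      factor(ifelse(pr > threshold, "extra", "intra"), levels = STAGE_LEVELS)
    })
}

# Stratified fold assignment: within each class, cases are shuffled under
# the seed and dealt round-robin, so every fold's training part keeps both
# classes whenever folds <= min class size.
make_folds <- function(y, k, seed) {
  set.seed(derive_seed(seed, "split"))
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

scale_fit <- function(X) {
  list(center = colMeans(X), scale = pmax(apply(X, 2, stats::sd), 1e-12))
}

scale_apply <- function(sc, X) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# Pooled cross-validated (sensitivity, accuracy) of one feature subset.
cv_score <- function(X, y, family, folds, hyper = list()) {
  pred <- factor(rep(NA_character_, length(y)), levels = STAGE_LEVELS)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) stop("degenerate single-class training fold")
    sc <- scale_fit(X[tr, , drop = FALSE])
    fit <- fit_family(family, scale_apply(sc, X[tr, , drop = FALSE]), y[tr], hyper)
    pred[!tr] <- predict_family(family, fit,
                                scale_apply(sc, X[!tr, , drop = FALSE]))
  }
  m <- evaluate_predictions(pred, y)
  c(sensitivity = m$sensitivity, accuracy = m$accuracy)
}

#' Configuration for model training
#'
#' @param cap Maximum selected features per category (default 8).
#' @param folds Cross-validation folds for subset scoring (default 5,
#'   reduced automatically to the smallest class size).
#' @param seed Integer seed controlling fold assignment.
#' @param hyper Named list of family hyperparameters (`svm_kernel`,
#'   `svm_cost`, `knn_k`, `dt_depth`).
#' @return A list of class `model_config`.
#' @export
model_config <- function(cap = 8, folds = 5, seed = 1, hyper = list()) {
  structure(list(cap = as.integer(cap), folds = as.integer(folds),
                 seed = as.integer(seed), hyper = hyper),
            class = "model_config")
}

#' Train a staging classifier with capped recursive feature elimination
#'
#' Backward elimination over the pooled genomic + radiomic feature set:
#' at each step every candidate removal is scored by stratified
#' cross-validated sensitivity (ties broken by accuracy, then by feature
#' name), the weakest feature is removed, and every visited subset that
#' respects the per-category cap is recorded. The returned model refits the
#' best recorded subset (maximal CV sensitivity, then accuracy, then
#' smaller size) on the full training data, so no more than `cap` features
#' per category are ever retained. Features from the two categories
#' compete on equal terms in the pooled elimination.
#'
#' @param genomic Numeric matrix cases x genomic features (may have zero
#'   columns), rownames = case ids.
#' @param radiomic Numeric matrix cases x radiomic features (may have zero
#'   columns).
#' @param labels Stage labels per case (`"intra"`/`"extra"`), >= 4 cases
#'   per class.
#' @param family One of `"NB"`, `"SVM"`, `"KNN"`, `"LR"`, `"DT"`.
#' @param config A [model_config()].
#' @return An object of class `staging_model`.
#' @export
train_rfe <- function(genomic, radiomic, labels, family = "NB",
                      config = model_config()) {
  y <- as_stage_factor(labels)
  if (min(table(y)) < 4) stop("need >= 4 cases per class")
  genomic <- as_matrix_named(genomic, "G", length(y))
  radiomic <- as_matrix_named(radiomic, "R", length(y))
  X <- cbind(genomic, radiomic)
  if (ncol(X) == 0) stop("no features offered")
  category <- rep(c("genomic", "radiomic"), c(ncol(genomic), ncol(radiomic)))
  names(category) <- colnames(X)
  k <- min(config$folds, min(table(y)))
  folds <- make_folds(y, k, config$seed)
  cap_ok <- function(s) all(table(factor(category[s],
                                         levels = c("genomic", "radiomic"))) <= config$cap)
  # univariate strength (|t|) breaks elimination ties: among removals that
  # leave the CV score unchanged, the weakest feature goes first
  strength <- apply(X, 2, function(v) {
    sp <- stats::sd(v[y == "extra"])^2 / sum(y == "extra") +
      stats::sd(v[y == "intra"])^2 / sum(y == "intra")
    if (sp == 0) 0 else abs(mean(v[y == "extra"]) - mean(v[y == "intra"])) / sqrt(sp)
  })
  s <- colnames(X)
  visited <- list()
  repeat {
    if (cap_ok(s)) {
      sc <- cv_score(X[, s, drop = FALSE], y, family, folds, config$hyper)
      visited[[length(visited) + 1L]] <- list(features = s, score = sc)
    }
    if (length(s) == 1L) break
    cand <- t(vapply(s, function(f) {
      cv_score(X[, setdiff(s, f), drop = FALSE], y, family, folds, config$hyper)
    }, numeric(2)))
    drop_idx <- order(-cand[, "sensitivity"], -cand[, "accuracy"],
                      strength[s], s)[1]
    s <- setdiff(s, s[drop_idx])
  }
  if (length(visited) == 0) stop("per-category cap admits no subset")
  # best CV sensitivity, then accuracy; ties keep the larger subset (the
  # model retains up to the cap rather than collapsing to one predictor)
  sens <- vapply(visited, function(v) v$score[["sensitivity"]], 0)
  acc <- vapply(visited, function(v) v$score[["accuracy"]], 0)
  size <- vapply(visited, function(v) length(v$features), 0L)
  best <- visited[[order(-sens, -acc, -size)[1]]]
  sel <- best$features
  sc <- scale_fit(X[, sel, drop = FALSE])
  fit <- fit_family(family, scale_apply(sc, X[, sel, drop = FALSE]), y,
                    config$hyper)
  structure(list(
    family = family,
    selected_genomic = sel[category[sel] == "genomic"],
    selected_radiomic = sel[category[sel] == "radiomic"],
    fit = fit, scaler = sc, features = sel,
    metadata = list(seed = config$seed, folds = k, cap = config$cap,
                    cv_sensitivity = best$score[["sensitivity"]],
                    cv_accuracy = best$score[["accuracy"]],
                    n_offered = ncol(X))),
    class = "staging_model")
}

as_matrix_named <- function(x, prefix, n_rows) {
  if (is.null(x)) return(matrix(0, n_rows, 0))
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- sprintf("%s%03d", prefix, seq_len(ncol(x)))
  }
  x
}

#' Train a single-omics baseline model
#'
#' [train_rfe()] restricted to one feature category, for the genomic-only
#' and radiomic-only baselines.
#'
#' @param features Numeric matrix cases x features.
#' @param labels Stage labels per case.
#' @param family Classifier family.
#' @param config A [model_config()].
#' @param category `"genomic"` or `"radiomic"`.
#' @return A `staging_model`.
#' @export
train_single_omics <- function(features, labels, family = "NB",
                               config = model_config(),
                               category = c("genomic", "radiomic")) {
  category <- match.arg(category)
  if (category == "genomic") train_rfe(features, NULL, labels, family, config)
  else train_rfe(NULL, features, labels, family, config)
}

#' Predict stage labels for new cases
#'
#' Features are matched by name; a case missing any selected feature is an
#' error (no silent imputation). Permuting feature columns does not change
#' the prediction.
#'
#' @param object A `staging_model`.
#' @param newdata Numeric matrix or data.frame, cases x features, with
#'   column names covering the model's selected features.
#' @param ... Unused.
#' @return Factor of predicted labels (`intra`/`extra`).
#' @export
predict.staging_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(X))
  if (length(missing)) {
    stop("missing selected features in newdata: ",
         paste(missing, collapse = ", "))
  }
  X <- X[, object$features, drop = FALSE]
  if (any(!is.finite(X))) stop("non-finite feature values in newdata")
  predict_family(object$family, object$fit, scale_apply(object$scaler, X))
}

#' @export
print.staging_model <- function(x, ...) {
  cat(sprintf("<staging_model %s: %d genomic + %d radiomic features, CV sens %.2f acc %.2f>\n",
              x$family, length(x$selected_genomic), length(x$selected_radiomic),
              x$metadata$cv_sensitivity, x$metadata$cv_accuracy))
  invisible(x)
}

#' Confusion-matrix evaluation
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/n` with extra-vesical as the positive class. A metric whose
#' denominator is empty (no positive or no negative truth cases) is NA.
#'
#' @param predictions Predicted labels.
#' @param truth True labels, same length.
#' @return List with `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  p <- as_stage_factor(predictions); t <- as_stage_factor(truth)
  if (length(p) != length(t)) stop("predictions and truth differ in length")
  tp <- sum(p == "extra" & t == "extra"); fn <- sum(p == "intra" & t == "extra")
  tn <- sum(p == "intra" & t == "intra"); fp <- sum(p == "extra" & t == "intra")
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(p))
}

#' Percentage-point deltas between model evaluations
#'
#' Pairwise differences (first minus second, in percentage points) of
#' sensitivity, specificity and accuracy between the integrated model and
#' each single-omics baseline, evaluated on the same cases.
#'
#' @param metrics_rgs,metrics_gs,metrics_rs Lists from
#'   [evaluate_predictions()] computed on the same evaluation set.
#' @return Data.frame with one row per model pair and one column per
#'   metric delta.
#' @export
compare_models <- function(metrics_rgs, metrics_gs, metrics_rs) {
  n_of <- function(m) m$tp + m$fn + m$tn + m$fp
  if (length(unique(c(n_of(metrics_rgs), n_of(metrics_gs), n_of(metrics_rs)))) != 1) {
    stop("metrics were not computed on the same evaluation set")
  }
  delta <- function(a, b) {
    data.frame(sensitivity_delta = 100 * (a$sensitivity - b$sensitivity),
               specificity_delta = 100 * (a$specificity - b$specificity),
               accuracy_delta = 100 * (a$accuracy - b$accuracy))
  }
  cbind(data.frame(comparison = c("RGs_vs_Gs", "RGs_vs_Rs"),
                   stringsAsFactors = FALSE),
        rbind(delta(metrics_rgs, metrics_gs), delta(metrics_rgs, metrics_rs)))
}
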