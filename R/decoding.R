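#' Train a linear support vector machine
#'
#' Thin wrapper around `e1071::svm` fixing the choices the decoding pipeline
#' relies on: linear kernel (nonlinearity lives in the manifold embedding, not
#' the classifier), no internal feature scaling (keeps accuracy invariant to
#' rotations of the embedding), regularization `C`.
#'
#' @param x n x d numeric feature matrix.
#' @param y Factor (or coercible) of class labels; at least 2 classes.
#' @param C Soft-margin cost (> 0, default 1).
#' @return A fitted `svm` object.
#' @export
train_linear_svm <- function(x, y, C = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("need at least two classes, got only '", levels(y), "'")
  if (C <= 0) stop("C must be > 0")
  e1071::svm(x = as.matrix(x), y = y, kernel = "linear", cost = C,
             scale = FALSE)
}

# Stratified fold assignment: each class is split into n_folds parts
# ("random": seeded shuffle within class; "contiguous": temporal order).
make_folds <- function(y, n_folds, seed, scheme = c("random", "contiguous")) {
  scheme <- match.arg(scheme)
  y <- as.factor(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < n_folds)
        stop("stage '", cl, "' has ", length(idx),
             " timepoints; need >= n_folds = ", n_folds)
      if (scheme == "random") idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

new_decoding_result <- function(accuracy, per_fold, confusion, scheme,
                                extra = list()) {
  structure(c(list(accuracy = accuracy, per_fold = per_fold,
                   confusion = confusion, scheme = scheme), extra),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Decoding result (", x$scheme, "): accuracy = ",
      sprintf("%.1f%%", 100 * x$accuracy), " over ",
      length(x$per_fold), " folds/rounds\n", sep = "")
  invisible(x)
}

# Rows of coords/labels restricted to scored (non-NA) TRs.
scored_subset <- function(coords, labels) {
  keep <- which(!is.na(labels))
  list(x = coords[keep, , drop = FALSE],
       y = droplevels(factor(as.character(labels)[keep],
                             levels = levels(labels))),
       idx = keep)
}

#' Pairwise (1-vs-1) cross-validated decoding
#'
#' 10-fold (by default) cross-validation of a linear SVM separating two
#' stages on the embedding coordinates. Folds are stratified per stage: each
#' stage's timepoints are divided into `n_folds` parts and fold f tests on
#' part f of both stages.
#'
#' @param embedding A `manifold_embedding` (or T x d coordinate matrix).
#' @param labels [stage_labels()] for the same T timepoints.
#' @param stage_a,stage_b The two stages to separate.
#' @param n_folds Number of folds (default 10).
#' @param C SVM cost (default 1).
#' @param seed Integer seed for the fold assignment.
#' @param fold_scheme `"random"` (default) or `"contiguous"` within-stage
#'   fold assignment.
#' @return A `decoding_result` with mean `accuracy`, `per_fold` accuracies
#'   and a 2 x 2 `confusion` matrix (rows = true stage).
#' @export
crossval_1v1 <- function(embedding, labels, stage_a, stage_b, n_folds = 10L,
                         C = 1, seed = 1L, fold_scheme = "random") {
  coords <- if (inherits(embedding, "manifold_embedding"))
    embedding$coords else as.matrix(embedding)
  sub <- scored_subset(coords, labels)
  keep <- sub$y %in% c(stage_a, stage_b)
  x <- sub$x[keep, , drop = FALSE]
  y <- droplevels(factor(as.character(sub$y[keep]),
                         levels = c(stage_a, stage_b)))
  fold <- make_folds(y, n_folds, seed, fold_scheme)
  conf <- matrix(0L, 2L, 2L, dimnames = list(true = levels(y),
                                             pred = levels(y)))
  per_fold <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- train_linear_svm(x[tr, , drop = FALSE], y[tr], C = C)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    per_fold[f] <- mean(pred == y[!tr])
    conf <- conf + table(true = y[!tr], pred = pred)
  }
  new_decoding_result(mean(per_fold), per_fold, conf, "tenfold_1v1")
}

# Fit K one-vs-all linear SVMs plus a logistic (Platt-style) posterior map
# on training decision values.
fit_1vall <- function(x, y, C) {
  lapply(levels(y), function(cl) {
    yy <- factor(ifelse(y == cl, cl, "rest"), levels = c(cl, "rest"))
    fit <- train_linear_svm(x, yy, C = C)
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")[, 1L]
    cal <- suppressWarnings(
      stats::glm((yy == cl) ~ dv, family = stats::binomial(),
                 data = data.frame(dv = dv)))
    list(svm = fit, cal = cal)
  })
}

predict_1vall <- function(models, classes, x) {
  post <- vapply(models, function(m) {
    dv <- attr(stats::predict(m$svm, x, decision.values = TRUE),
               "decision.values")[, 1L]
    stats::predict(m$cal, newdata = data.frame(dv = dv), type = "response")
  }, numeric(nrow(x)))
  post <- matrix(post, nrow = nrow(x))
  factor(classes[max.col(post, ties.method = "first")], levels = classes)
}

#' Multi-class (1-vs-all) cross-validated decoding
#'
#' For each fold, fits one one-vs-all linear SVM per stage on the training
#' part, fits a monotone logistic map from decision values to posterior
#' probabilities per classifier (Platt-style calibration on training scores),
#' and predicts the stage with the highest posterior on the test part.
#'
#' @inheritParams crossval_1v1
#' @return A `decoding_result` with overall `accuracy` (trace of the pooled
#'   confusion matrix over total tested timepoints), `per_fold` accuracies and
#'   the K x K `confusion` matrix (rows = true stage).
#' @export
crossval_1vall_multiclass <- function(embedding, labels, n_folds = 10L, C = 1,
                                      seed = 1L, fold_scheme = "random") {
  coords <- if (inherits(embedding, "manifold_embedding"))
    embedding$coords else as.matrix(embedding)
  sub <- scored_subset(coords, labels)
  x <- sub$x; y <- sub$y
  if (nlevels(y) < 2L) stop("need >= 2 stages present")
  fold <- make_folds(y, n_folds, seed, fold_scheme)
  k <- nlevels(y)
  conf <- matrix(0L, k, k, dimnames = list(true = levels(y),
                                           pred = levels(y)))
  per_fold <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < k)
      stop("fold ", f, " training part is missing a stage; ",
           "use fewer folds or re-stratify")
    models <- fit_1vall(x[tr, , drop = FALSE], y[tr], C)
    pred <- predict_1vall(models, levels(y), x[!tr, , drop = FALSE])
    per_fold[f] <- mean(pred == y[!tr])
    conf <- conf + table(true = y[!tr], pred = pred)
  }
  new_decoding_result(sum(diag(conf)) / sum(conf), per_fold, conf,
                      "tenfold_1vall")
}

#' Leave-one-subject-out decoding on a group-aligned embedding
#'
#' One round per subject: a multi-class 1-vs-all linear SVM ensemble is
#' trained on all other subjects' aligned coordinates and tested on the
#' held-out subject. A test stage absent from the training subjects is
#' necessarily misclassified and counts as errors.
#'
#' @param coords_list List of aligned coordinate matrices, one per subject.
#' @param labels_list List of matching [stage_labels()].
#' @param C SVM cost (default 1).
#' @return A `decoding_result` with mean round `accuracy`, `per_fold` = one
#'   accuracy per held-out subject and the pooled `confusion` matrix; the
#'   per-round accuracies are the distribution reported for group analysis.
#' @export
leave_one_subject_out <- function(coords_list, labels_list, C = 1) {
  stopifnot(length(coords_list) == length(labels_list),
            length(coords_list) >= 2L)
  coords_list <- lapply(coords_list, function(e)
    if (inherits(e, "manifold_embedding")) e$coords else as.matrix(e))
  subs <- lapply(seq_along(coords_list), function(s)
    scored_subset(coords_list[[s]], labels_list[[s]]))
  all_levels <- sort(unique(unlist(lapply(subs, function(s) levels(s$y)))))
  k <- length(all_levels)
  conf <- matrix(0L, k, k, dimnames = list(true = all_levels,
                                           pred = all_levels))
  rounds <- numeric(length(subs))
  for (s in seq_along(subs)) {
    xtr <- do.call(rbind, lapply(subs[-s], `[[`, "x"))
    ytr <- droplevels(factor(unlist(lapply(subs[-s], function(z)
      as.character(z$y))), levels = all_levels))
    models <- fit_1vall(xtr, ytr, C)
    pred <- predict_1vall(models, levels(ytr), subs[[s]]$x)
    ytest <- factor(as.character(subs[[s]]$y), levels = all_levels)
    rounds[s] <- mean(as.character(pred) == as.character(ytest))
    conf <- conf + table(true = ytest,
                         pred = factor(as.character(pred),
                                       levels = all_levels))
  }
  new_decoding_result(mean(rounds), rounds, conf, "loso")
}

#' Combined uncertainty of averaged pairwise accuracies
#'
#' When an accuracy is reported as the average of m pairwise comparisons, its
#' uncertainty is the root-sum-square of the per-comparison uncertainties
#' divided by m: `(1/m) * sqrt(sum(e_i^2))`.
#'
#' @param errors Non-negative numeric vector of per-comparison accuracy SDs.
#' @return Scalar combined uncertainty (same units as the inputs).
#' @export
combined_uncertainty <- function(errors) {
  if (length(errors) == 0L) stop("empty error list")
  if (any(errors < 0)) stop("uncertainties must be non-negative")
  sqrt(sum(errors^2)) / length(errors)
}
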