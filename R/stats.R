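#' Phase-randomized surrogate time series
#'
#' Builds a null series with the original amplitude spectrum but randomized
#' spectral phases: one uniform phase shift per positive frequency bin, the
#' SAME shift applied to every region (so cross-spectral phase relations are
#' preserved while the temporal alignment with any label track is destroyed).
#' Conjugate symmetry is enforced, the DC bin is untouched, and for even
#' lengths the Nyquist bin receives only a random sign flip (it must stay
#' real).
#'
#' @param ts A [parcellated_ts()].
#' @param seed Integer seed for the phase draws.
#' @return A [parcellated_ts()] of the same shape, band and TR.
#' @export
phase_randomized_surrogate <- function(ts, seed = 1L) {
  stopifnot(inherits(ts, "parcellated_ts"))
  x <- ts$data
  nt <- ncol(x)
  half <- if (nt %% 2L == 0L) nt / 2L - 1L else (nt - 1L) / 2L
  rot <- complex(modulus = 1, argument = 0) * rep(1 + 0i, nt)
  withr::with_seed(seed, {
    if (half > 0L) {
      shifts <- stats::runif(half, 0, 2 * pi)
      rot[2L:(half + 1L)] <- exp(1i * shifts)
      rot[nt - seq_len(half) + 1L] <- Conj(rot[2L:(half + 1L)])
    }
    if (nt %% 2L == 0L)
      rot[nt / 2L + 1L] <- sample(c(-1, 1), 1L)
  })
  xf <- stats::mvfft(t(x))                       # T x N, FFT per region
  xs <- Re(stats::mvfft(xf * rot, inverse = TRUE)) / nt
  parcellated_ts(t(xs), ts$tr_seconds, ts$region_ids, band = ts$band)
}

#' Monte-Carlo p-value against a surrogate ensemble
#'
#' `p = (#\{i : a < a_perm_i\} + 1) / (N_perm + 1)`: the achievable minimum is
#' `1/(N_perm + 1)` and ties between the observed accuracy and a surrogate
#' count in favor of the observed value.
#'
#' @param a Observed accuracy.
#' @param a_perm Numeric vector of surrogate accuracies (length N_perm >= 1).
#' @return p-value in `[1/(N_perm + 1), 1]`.
#' @export
monte_carlo_pvalue <- function(a, a_perm) {
  if (length(a_perm) == 0L) stop("empty surrogate ensemble")
  (sum(a < a_perm) + 1) / (length(a_perm) + 1)
}

#' Benjamini-Hochberg FDR correction
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param alpha Rejection level for the returned flags (default 0.05).
#' @return List with `q` (step-up adjusted values, monotone) and `reject`
#'   (logical, `q <= alpha`).
#' @export
fdr_correct <- function(pvalues, alpha = 0.05) {
  if (any(pvalues <= 0 | pvalues > 1 | !is.finite(pvalues)))
    stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when both samples have at most 10 observations and no ties are
#' present; otherwise the normal approximation with tie correction. Two
#' completely identical samples return p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) return(1)
  exact <- length(x) <= 10L && length(y) <= 10L && !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)$p.value)
  if (!is.finite(p)) 1 else min(1, p)
}

#' ROC curve along a single score dimension
#'
#' Sweeps a decision threshold over all midpoints between consecutive sorted
#' unique scores (plus -Inf and +Inf) and records the true/false positive
#' rates; the AUC is the trapezoidal integral of TPR over FPR. The score
#' orientation ("higher score means positive class") is chosen automatically
#' so that AUC >= 0.5, and recorded.
#'
#' @param scores Numeric vector (e.g. one embedding dimension's coordinates).
#' @param labels Binary labels (factor/character/logical); the second factor
#'   level is the positive class.
#' @param direction `"auto"` (default), `">"` (higher = positive) or `"<"`.
#' @return An object of class `roc_result`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `direction`, and `dimension_index` (NA here; set by
#'   [best_dimension_roc()]).
#' @export
roc_curve <- function(scores, labels, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must contain exactly two classes")
  labels <- droplevels(labels)
  pos <- labels == levels(labels)[2L]
  sweep_one <- function(sc) {
    u <- sort(unique(sc))
    thr <- c(-Inf, (u[-1L] + u[-length(u)]) / 2, Inf)
    if (length(u) == 1L) thr <- c(-Inf, Inf)
    tpr <- vapply(thr, function(t) mean(sc[pos] > t), numeric(1))
    fpr <- vapply(thr, function(t) mean(sc[!pos] > t), numeric(1))
    ord <- order(fpr, tpr)
    auc <- sum(diff(fpr[ord]) * (tpr[ord][-1L] + tpr[ord][-length(ord)]) / 2)
    list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
  }
  r <- sweep_one(scores)
  used <- ">"
  if (direction == "<" || (direction == "auto" && r$auc < 0.5)) {
    r <- sweep_one(-scores)
    r$thresholds <- -r$thresholds
    used <- "<"
  }
  structure(list(thresholds = r$thresholds, tpr = r$tpr, fpr = r$fpr,
                 auc = r$auc, direction = used, dimension_index = NA_integer_),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC =", signif(x$auc, 4), "(direction", x$direction, ")")
  if (!is.na(x$dimension_index))
    cat(", best dimension =", x$dimension_index)
  cat("\n")
  invisible(x)
}

#' Best single-dimension ROC over the leading embedding dimensions
#'
#' Computes the ROC of each of the first `dims_to_scan` embedding dimensions
#' for separating two stages, and returns the one with the largest AUC (ties
#' broken by the lowest dimension index).
#'
#' @param embedding A `manifold_embedding` (or T x d matrix).
#' @param labels [stage_labels()] for the same timepoints.
#' @param stage_a,stage_b The two stages compared.
#' @param dims_to_scan How many leading dimensions to scan (default 3).
#' @return A `roc_result` with `dimension_index` set, plus attribute
#'   `"auc_by_dim"`.
#' @export
best_dimension_roc <- function(embedding, labels, stage_a, stage_b,
                               dims_to_scan = 3L) {
  coords <- if (inherits(embedding, "manifold_embedding"))
    embedding$coords else as.matrix(embedding)
  if (dims_to_scan > ncol(coords))
    stop("dims_to_scan exceeds embedding dimension d = ", ncol(coords))
  keep <- which(!is.na(labels) & as.character(labels) %in% c(stage_a, stage_b))
  y <- factor(as.character(labels)[keep], levels = c(stage_a, stage_b))
  rocs <- lapply(seq_len(dims_to_scan), function(k)
    roc_curve(coords[keep, k], y))
  aucs <- vapply(rocs, `[[`, numeric(1), "auc")
  best <- which.max(aucs)
  out <- rocs[[best]]
  out$dimension_index <- best
  attr(out, "auc_by_dim") <- aucs
  out
}

#' Surrogate-based significance of decoding accuracy
#'
#' Runs the decoding analysis on the observed series and on `n_perm`
#' phase-randomized surrogates, re-running the FULL pipeline (filter -> phase
#' -> coherence states -> CCD -> RMST -> Laplacian eigenmaps -> SVM) for each
#' surrogate, and returns the Monte-Carlo p-value of the observed accuracy
#' against the surrogate ensemble.
#'
#' @param ts An unfiltered (or filtered) [parcellated_ts()].
#' @param labels [stage_labels()] for the same timepoints.
#' @param config A [pipeline_config()]; controls band, RMST, dimension, SVM
#'   and fold parameters.
#' @param n_perm Number of surrogates (default `config$n_perm`).
#' @param scheme `"1vall"` (default) for multi-class decoding or `"1v1"`.
#' @param stage_a,stage_b Stages for `scheme = "1v1"`.
#' @param seed Integer seed; surrogate i uses `seed + i`.
#' @return An object of class `significance_result`: `a` (observed accuracy),
#'   `a_perm`, `p`, `n_perm`.
#' @export
decode_significance <- function(ts, labels, config = pipeline_config(),
                                n_perm = config$n_perm, scheme = "1vall",
                                stage_a = NULL, stage_b = NULL,
                                seed = config$seed) {
  run_once <- function(series) {
    emb <- embed_timeseries(series, config)$le
    if (scheme == "1v1")
      crossval_1v1(emb, labels, stage_a, stage_b, n_folds = config$n_folds,
                   C = config$svm_C, seed = seed,
                   fold_scheme = config$fold_scheme)$accuracy
    else
      crossval_1vall_multiclass(emb, labels, n_folds = config$n_folds,
                                C = config$svm_C, seed = seed,
                                fold_scheme = config$fold_scheme)$accuracy
  }
  a <- run_once(ts)
  a_perm <- vapply(seq_len(n_perm), function(i)
    run_once(phase_randomized_surrogate(ts, seed = seed + i)), numeric(1))
  structure(list(a = a, a_perm = a_perm,
                 p = monte_carlo_pvalue(a, a_perm), n_perm = n_perm),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("Surrogate significance: observed accuracy ",
      sprintf("%.1f%%", 100 * x$a), ", surrogate mean ",
      sprintf("%.1f%%", 100 * mean(x$a_perm)), ", p = ",
      signif(x$p, 4), " (", x$n_perm, " surrogates)\n", sep = "")
  invisible(x)
}
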