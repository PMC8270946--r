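#' Per-stage extreme landmarks of an embedding
#'
#' For each stage, picks the two timepoints whose embedding coordinates have
#' the minimum and maximum Euclidean norm. These 2-per-stage landmark points
#' define the correspondence used to align manifolds across subjects. Norm
#' ties are broken by the smallest timepoint index.
#'
#' @param embedding A `manifold_embedding`.
#' @param labels A [stage_labels()] track matching the embedding rows; `NA`
#'   (unscored) timepoints are ignored.
#' @return An object of class `landmark_set`: list with `X` (d x 2S matrix,
#'   columns ordered stage-min, stage-max per stage), `stages` and `roles`.
#' @export
extract_landmarks <- function(embedding, labels) {
  stopifnot(inherits(embedding, "manifold_embedding"))
  lab <- if (is.factor(labels)) droplevels(factor(as.character(labels),
                                                  levels = levels(labels)))
         else factor(labels)
  if (length(lab) != nrow(embedding$coords))
    stop("labels length does not match embedding rows")
  nrm <- sqrt(rowSums(embedding$coords^2))
  stages <- levels(lab)
  cols <- matrix(0, ncol(embedding$coords), 2L * length(stages))
  for (s in seq_along(stages)) {
    idx <- which(!is.na(lab) & lab == stages[s])
    if (length(idx) < 2L)
      stop("stage '", stages[s], "' has ", length(idx),
           " timepoint(s); need >= 2 for landmarks")
    cols[, 2L * s - 1L] <- embedding$coords[idx[which.min(nrm[idx])], ]
    cols[, 2L * s] <- embedding$coords[idx[which.max(nrm[idx])], ]
  }
  colnames(cols) <- paste(rep(stages, each = 2L), c("min", "max"), sep = ".")
  structure(list(X = cols, stages = stages,
                 roles = rep(c("min", "max"), length(stages))),
            class = "landmark_set")
}

#' Full Procrustes fit between two landmark sets
#'
#' Solves `argmin_T || T X_s - X_ref ||_F` over orthogonal matrices
#' (reflections allowed -- eigenvector sign flips make them physically
#' meaningless between subjects), together with an isotropic scale and a
#' translation, by the closed-form SVD solution on corresponded landmark
#' columns.
#'
#' @param source,reference `landmark_set` objects with identical stage sets
#'   and dimension; columns correspond by (stage, min/max) role.
#' @return An object of class `alignment_transform`: list with `rotation`
#'   (d x d orthogonal, applied to coordinate column vectors), `scale`,
#'   `translation` (length d) and `residual` (Frobenius misfit on the
#'   landmarks after transformation).
#' @export
fit_alignment <- function(source, reference) {
  stopifnot(inherits(source, "landmark_set"),
            inherits(reference, "landmark_set"))
  if (!identical(dim(source$X), dim(reference$X)))
    stop("landmark sets differ in dimension or landmark count")
  if (!identical(source$stages, reference$stages))
    stop("landmark sets cover different stages")
  xs <- t(source$X); xr <- t(reference$X)   # m points x d
  mu_s <- colMeans(xs); mu_r <- colMeans(xr)
  xs_c <- sweep(xs, 2L, mu_s); xr_c <- sweep(xr, 2L, mu_r)
  ss <- sum(xs_c^2)
  if (ss < 1e-24)
    stop("degenerate source landmarks (all coincident): transform undefined")
  sv <- svd(crossprod(xs_c, xr_c))
  q <- sv$u %*% t(sv$v)              # maps row vectors: x_c %*% q
  scale <- sum(sv$d) / ss
  translation <- mu_r - scale * drop(mu_s %*% q)
  fitted <- scale * xs_c %*% q + matrix(mu_r, nrow(xs), ncol(xs), byrow = TRUE)
  structure(list(rotation = t(q), scale = scale, translation = translation,
                 residual = sqrt(sum((fitted - xr)^2))),
            class = "alignment_transform")
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat("Procrustes transform: d =", nrow(x$rotation),
      ", scale =", signif(x$scale, 5),
      ", landmark residual =", signif(x$residual, 5), "\n")
  invisible(x)
}

#' Apply a Procrustes transform to a whole embedding
#'
#' Maps every timepoint coordinate by `scale * rotation %*% x + translation`.
#' The transform is fitted on landmarks only but moves the full point cloud.
#'
#' @param embedding A `manifold_embedding`.
#' @param transform An `alignment_transform` of matching dimension.
#' @return The transformed `manifold_embedding`.
#' @export
apply_alignment <- function(embedding, transform) {
  stopifnot(inherits(embedding, "manifold_embedding"),
            inherits(transform, "alignment_transform"))
  if (ncol(embedding$coords) != nrow(transform$rotation))
    stop("dimension mismatch: embedding d = ", ncol(embedding$coords),
         ", transform d = ", nrow(transform$rotation))
  out <- embedding
  out$coords <- transform$scale * embedding$coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(embedding$coords),
           ncol(embedding$coords), byrow = TRUE)
  colnames(out$coords) <- colnames(embedding$coords)
  out
}

#' Align a group of per-subject embeddings into a common space
#'
#' Default mode aligns every subject onto a reference subject's landmarks.
#' `method = "gpa"` runs generalized Procrustes analysis instead: subjects are
#' iteratively aligned to the mean landmark configuration until the summed
#' residual changes by less than `tol` (max `max_iter` iterations).
#'
#' @param embeddings List of `manifold_embedding`s (equal d).
#' @param labels List of matching [stage_labels()] tracks.
#' @param reference Index of the reference subject (default 1; ignored for
#'   `"gpa"`).
#' @param method `"reference"` (default) or `"gpa"`.
#' @param tol,max_iter GPA convergence controls.
#' @return List with `embeddings` (aligned), `transforms` and `residuals`.
#' @export
align_group <- function(embeddings, labels, reference = 1L,
                        method = c("reference", "gpa"),
                        tol = 1e-8, max_iter = 100L) {
  method <- match.arg(method)
  stopifnot(length(embeddings) == length(labels), length(embeddings) >= 2L)
  lms <- Map(extract_landmarks, embeddings, labels)
  st <- lms[[1L]]$stages
  for (l in lms) if (!identical(l$stages, st))
    stop("subjects cover different stage sets; cannot correspond landmarks")
  if (method == "reference") {
    tfs <- lapply(lms, fit_alignment, reference = lms[[reference]])
  } else {
    ref <- lms[[1L]]
    ref$X <- Reduce(`+`, lapply(lms, `[[`, "X")) / length(lms)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      tfs <- lapply(lms, fit_alignment, reference = ref)
      tot <- sum(vapply(tfs, `[[`, numeric(1), "residual"))
      aligned_x <- Map(function(l, tf) {
        l$X <- tf$scale * t(l$X) %*% t(tf$rotation)
        l$X <- t(l$X) + tf$translation
        l
      }, lms, tfs)
      ref$X <- Reduce(`+`, lapply(aligned_x, `[[`, "X")) / length(lms)
      if (abs(prev - tot) < tol) break
      prev <- tot
    }
  }
  list(embeddings = Map(apply_alignment, embeddings, tfs),
       transforms = tfs,
       residuals = vapply(tfs, `[[`, numeric(1), "residual"))
}
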