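#' Instantaneous phase-coherence matrix
#'
#' Pairwise synchrony between regions at a single timepoint: entry (i, j) is
#' `cos(theta_i - theta_j)`, 1 for in-phase pairs, -1 for antiphase pairs.
#'
#' @param phases_at_t Numeric vector of N phases in radians.
#' @return N x N symmetric matrix with unit diagonal.
#' @export
phase_coherence_matrix <- function(phases_at_t) {
  if (any(!is.finite(phases_at_t)))
    stop("non-finite phase value(s)")
  m <- cos(outer(phases_at_t, phases_at_t, "-"))
  diag(m) <- 1
  m
}

#' Vectorize a coherence matrix into a coherence state
#'
#' Extracts the upper triangle (i < j) in row-major order
#' (1,2), (1,3), ..., (1,N), (2,3), ... -- the coherence vector V(t) that
#' defines the brain coherence state at one timepoint.
#'
#' @param m N x N symmetric matrix.
#' @return Numeric vector of length N(N-1)/2.
#' @export
coherence_vector <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9)
    stop("coherence matrix must be symmetric (tolerance 1e-9)")
  t(m)[lower.tri(m)]
}

#' Coherence states for every timepoint
#'
#' Computes the full set of coherence vectors V(t) from a phase track in one
#' vectorized pass, using cos(a - b) = cos a cos b + sin a sin b over the
#' fixed row-major pair ordering of [coherence_vector()].
#'
#' @param phase A `phase_track` from [instantaneous_phase()], or an N x T
#'   phase matrix in radians.
#' @return Matrix of dimension N(N-1)/2 x T; column t is V(t).
#' @export
coherence_states <- function(phase) {
  ph <- if (inherits(phase, "phase_track")) phase$phases else as.matrix(phase)
  if (any(!is.finite(ph))) stop("non-finite phase value(s)")
  n <- nrow(ph)
  if (n < 2L) stop("need at least 2 regions")
  pr <- pair_index(n)
  cp <- cos(ph); sp <- sin(ph)
  cp[pr$i, , drop = FALSE] * cp[pr$j, , drop = FALSE] +
    sp[pr$i, , drop = FALSE] * sp[pr$j, , drop = FALSE]
}

# Row-major upper-triangle pair ordering shared by coherence_vector().
pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  list(i = i, j = j)
}

#' Coherence connectivity dynamics (CCD) matrix
#'
#' The T x T matrix of cosine similarities between the coherence states of
#' every pair of timepoints:
#' `CCD(ti, tj) = V(ti) . V(tj) / (|V(ti)| |V(tj)|)`.
#' Blocks of high similarity around the diagonal indicate epochs of a stable
#' coherence state.
#'
#' @param states Matrix of coherence vectors, one column per timepoint
#'   (output of [coherence_states()]), or a list of equal-length vectors.
#' @param tr_seconds Optional sampling interval carried as metadata.
#' @return An object of class `ccd_matrix`: list with `matrix` (T x T,
#'   symmetric, unit diagonal, entries in \[-1, 1\]) and `tr_seconds`.
#' @export
ccd <- function(states, tr_seconds = NULL) {
  if (is.list(states)) {
    len <- unique(lengths(states))
    if (length(len) != 1L) stop("all coherence states must have equal length")
    states <- matrix(unlist(states), nrow = len)
  }
  states <- as.matrix(states)
  dimnames(states) <- NULL
  nrm <- sqrt(colSums(states^2))
  bad <- which(nrm == 0)
  if (length(bad) > 0L)
    stop("zero-norm coherence state at timepoint(s): ",
         paste(bad, collapse = ", "))
  u <- sweep(states, 2L, nrm, "/")
  m <- crossprod(u)
  m <- (m + t(m)) / 2
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  structure(list(matrix = m, tr_seconds = tr_seconds), class = "ccd_matrix")
}

#' @export
print.ccd_matrix <- function(x, ...) {
  cat("CCD matrix:", nrow(x$matrix), "x", ncol(x$matrix), "timepoints\n")
  off <- x$matrix[upper.tri(x$matrix)]
  cat("  off-diagonal similarity: mean", signif(mean(off), 4),
      " range [", signif(min(off), 4), ",", signif(max(off), 4), "]\n")
  invisible(x)
}
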