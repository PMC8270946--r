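#' Parcellated BOLD time series
#'
#' Container for one subject's region-by-time BOLD matrix. Rows are brain
#' regions (e.g. the 90 AAL parcels), columns are volumes sampled every
#' `tr_seconds` seconds.
#'
#' @param data Numeric matrix, N regions x T timepoints. All values finite.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param region_ids Optional character vector of N region labels. Defaults to
#'   `"R1" ... "RN"`.
#' @param band Optional length-2 numeric, the (low, high) band in Hz already
#'   applied to `data`; `NULL` for unfiltered data.
#' @return An object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(data, tr_seconds, region_ids = NULL, band = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("time-series matrix must be numeric with no missing/non-finite values")
  if (nrow(data) < 2L)
    stop("need at least 2 regions, got ", nrow(data))
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  if (is.null(region_ids))
    region_ids <- paste0("R", seq_len(nrow(data)))
  if (length(region_ids) != nrow(data))
    stop("region_ids length (", length(region_ids),
         ") does not match number of regions (", nrow(data), ")")
  if (!is.null(band)) {
    band <- as.numeric(band)
    if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
      stop("band must be c(low, high) with 0 < low < high")
  }
  rownames(data) <- region_ids
  structure(list(data = data, tr_seconds = tr_seconds,
                 region_ids = region_ids, band = band),
            class = "parcellated_ts")
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat("Parcellated time series:", nrow(x$data), "regions x",
      ncol(x$data), "TRs, TR =", x$tr_seconds, "s\n")
  if (is.null(x$band)) cat("  band: none (unfiltered)\n")
  else cat("  band:", x$band[1], "-", x$band[2], "Hz\n")
  invisible(x)
}

#' @export
dim.parcellated_ts <- function(x) dim(x$data)

n_trs <- function(ts) ncol(ts$data)
n_regions <- function(ts) nrow(ts$data)

#' Per-TR brain-state labels
#'
#' A categorical track of one state label per fMRI volume, as produced by
#' polysomnographic sleep staging (hypnogram). `NA` marks unscored volumes;
#' these are excluded from decoding.
#'
#' @param labels Character or factor vector, one entry per TR (`NA` allowed).
#' @param stages Character vector, the stage vocabulary (factor level order).
#'   Defaults to the levels present, in order of first appearance.
#' @param subject_id Optional subject identifier.
#' @return An object of class `stage_labels` (a factor with attributes).
#' @export
stage_labels <- function(labels, stages = NULL, subject_id = NULL) {
  labels <- as.character(labels)
  if (is.null(stages))
    stages <- unique(labels[!is.na(labels)])
  unknown <- setdiff(labels[!is.na(labels)], stages)
  if (length(unknown) > 0L)
    stop("unknown stage token(s): ", paste(unknown, collapse = ", "))
  out <- factor(labels, levels = stages)
  attr(out, "subject_id") <- subject_id
  class(out) <- c("stage_labels", "factor")
  out
}

#' @export
print.stage_labels <- function(x, ...) {
  tb <- table(factor(unclass(x), levels = seq_along(levels(x)),
                     labels = levels(x)), useNA = "ifany")
  cat("Stage labels:", length(x), "TRs")
  sid <- attr(x, "subject_id")
  if (!is.null(sid)) cat(" (subject ", sid, ")", sep = "")
  cat("\n")
  print(tb)
  invisible(x)
}
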