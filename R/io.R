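#' Read a parcellated time-series matrix from delimited text
#'
#' Expected layout: rows = regions, columns = TRs, tab-separated. An optional
#' header row of TR indices and an optional first column of region labels are
#' detected automatically (any non-numeric leading row/column).
#'
#' @param path File path.
#' @param tr_seconds Sampling interval in seconds (required; not stored in
#'   the matrix file).
#' @param band Optional band metadata, as in [parcellated_ts()].
#' @param sep Field separator (default tab).
#' @return A [parcellated_ts()].
#' @export
read_timeseries <- function(path, tr_seconds, band = NULL, sep = "\t") {
  if (missing(tr_seconds) || is.null(tr_seconds))
    stop("tr_seconds is required (the matrix file does not store the TR)")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  if (length(unique(lengths(cells))) != 1L)
    stop("ragged rows in ", path, ": row lengths ",
         paste(unique(lengths(cells)), collapse = ", "))
  m <- do.call(rbind, cells)
  has_header <- any(is.na(suppressWarnings(as.numeric(m[1L, -1L]))))
  if (has_header) m <- m[-1L, , drop = FALSE]
  first_col_num <- suppressWarnings(as.numeric(m[, 1L]))
  has_rownames <- any(is.na(first_col_num))
  region_ids <- NULL
  if (has_rownames) {
    region_ids <- m[, 1L]
    m <- m[, -1L, drop = FALSE]
  }
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at data row ", bad[1L], ", column ", bad[2L],
         " of ", path)
  }
  parcellated_ts(num, tr_seconds, region_ids = region_ids, band = band)
}

#' Write a parcellated time-series matrix as delimited text
#'
#' Full double precision (17 significant digits) so write/read round-trips
#' are numerically exact. First column holds region ids, header row holds
#' 0-based TR indices.
#'
#' @param ts A [parcellated_ts()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  stopifnot(inherits(ts, "parcellated_ts"))
  header <- paste(c("region", paste0("t", seq_len(n_trs(ts)) - 1L)),
                  collapse = sep)
  rows <- vapply(seq_len(n_regions(ts)), function(i)
    paste(c(ts$region_ids[i],
            formatC(ts$data[i, ], format = "g", digits = 17)),
          collapse = sep), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read per-TR stage labels from delimited text
#'
#' Two-column file (`tr_index`, `stage`), 0-based TR indices, optional
#' header. TRs absent from the file are marked unscored (`NA`) and excluded
#' from decoding.
#'
#' @param path File path.
#' @param stages Stage vocabulary; defaults to Awake/N1/N2/N3.
#' @param n_trs Track length; defaults to `max(tr_index) + 1`.
#' @param sep Field separator (default tab).
#' @return A [stage_labels()] track.
#' @export
read_labels <- function(path, stages = c("Awake", "N1", "N2", "N3"),
                        n_trs = NULL, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(cells) != 2L))
    stop("labels file must have exactly two columns (tr_index, stage)")
  m <- do.call(rbind, cells)
  if (is.na(suppressWarnings(as.numeric(m[1L, 1L]))))
    m <- m[-1L, , drop = FALSE]
  idx <- suppressWarnings(as.numeric(m[, 1L]))
  if (any(is.na(idx)) || any(idx != floor(idx)) || any(idx < 0))
    stop("tr_index column must contain non-negative integers")
  if (anyDuplicated(idx))
    stop("duplicate tr_index: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  if (is.null(n_trs)) n_trs <- max(idx) + 1L
  lab <- rep(NA_character_, n_trs)
  lab[idx + 1L] <- m[, 2L]
  stage_labels(lab, stages = stages)
}

#' Write per-TR stage labels as delimited text
#'
#' Unscored (`NA`) TRs are omitted, matching what [read_labels()] treats as
#' unscored.
#'
#' @param labels A [stage_labels()] track.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_labels <- function(labels, path, sep = "\t") {
  scored <- which(!is.na(labels))
  writeLines(c(paste("tr_index", "stage", sep = sep),
               paste(scored - 1L, as.character(labels)[scored], sep = sep)),
             path)
  invisible(path)
}

#' Write an embedding (with labels) as a delimited table
#'
#' Columns: `tr_index` (0-based), `dim_1 ... dim_d`, `stage`.
#'
#' @param embedding A `manifold_embedding`.
#' @param labels Optional [stage_labels()].
#' @param path Output path.
#' @export
write_embedding <- function(embedding, path, labels = NULL) {
  df <- data.frame(tr_index = seq_len(nrow(embedding$coords)) - 1L,
                   embedding$coords, check.names = FALSE)
  if (!is.null(labels)) df$stage <- as.character(labels)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable parameters of the analysis with the study defaults: ultraslow
#' band 0.04-0.07 Hz, sixth-order Butterworth, RMST with gamma = 3 and
#' k_n = 5, embedding dimension 7, linear SVM with C = 1 under 10-fold CV,
#' 1000 phase-randomized surrogates, FDR at 0.05.
#'
#' @param band_low_hz,band_high_hz Band edges in Hz.
#' @param filter_order Overall Butterworth band-pass order (even).
#' @param gamma,k_n,k_local RMST parameters (see [rmst()]).
#' @param dim Embedding dimension d.
#' @param svm_C Linear SVM cost.
#' @param n_folds Cross-validation folds.
#' @param n_perm Number of phase-randomized surrogates.
#' @param fdr_alpha FDR level.
#' @param seed Integer master seed.
#' @param fold_scheme `"random"` or `"contiguous"` fold assignment.
#' @param laplacian_weighting `"binary"` or `"similarity"` adjacency.
#' @param reference_subject Index of the Procrustes reference subject.
#' @param trim_trs Edge TRs to drop after filtering (default 0).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(band_low_hz = 0.04, band_high_hz = 0.07,
                            filter_order = 6L, gamma = 3, k_n = 5L,
                            k_local = 1L, dim = 7L, svm_C = 1.0,
                            n_folds = 10L, n_perm = 1000L, fdr_alpha = 0.05,
                            seed = 42L, fold_scheme = "random",
                            laplacian_weighting = "binary",
                            reference_subject = 1L, trim_trs = 0L) {
  cfg <- list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              filter_order = as.integer(filter_order), gamma = gamma,
              k_n = as.integer(k_n), k_local = as.integer(k_local),
              dim = as.integer(dim), svm_C = svm_C,
              n_folds = as.integer(n_folds), n_perm = as.integer(n_perm),
              fdr_alpha = fdr_alpha, seed = as.integer(seed),
              fold_scheme = match.arg(fold_scheme, c("random", "contiguous")),
              laplacian_weighting = match.arg(laplacian_weighting,
                                              c("binary", "similarity")),
              reference_subject = as.integer(reference_subject),
              trim_trs = as.integer(trim_trs))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value file; keys mirror [pipeline_config()] arguments, missing
#' keys take the defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
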