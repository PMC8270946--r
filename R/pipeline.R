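#' Embed one subject's time series on its intrinsic manifold
#'
#' Runs the single-subject chain: band-pass filter (skipped when the input
#' already carries the requested band) -> instantaneous phase -> coherence
#' states -> CCD -> distance -> RMST -> graph Laplacian -> Laplacian
#' eigenmaps, plus the PCA baseline on the filtered region-by-time signal
#' (timepoints as observations).
#'
#' @param ts A [parcellated_ts()].
#' @param config A [pipeline_config()].
#' @return List with `le` and `pca` (`manifold_embedding`s), `graph`
#'   (`state_graph`), `ccd` (`ccd_matrix`) and `filtered`
#'   ([parcellated_ts()]).
#' @export
embed_timeseries <- function(ts, config = pipeline_config()) {
  band <- c(config$band_low_hz, config$band_high_hz)
  filt <- if (!is.null(ts$band) && isTRUE(all.equal(ts$band, band))) ts
          else bandpass(ts, band[1], band[2], config$filter_order,
                        trim_trs = config$trim_trs)
  states <- coherence_states(instantaneous_phase(filt))
  cc <- ccd(states, tr_seconds = filt$tr_seconds)
  graph <- rmst(ccd_to_distance(cc), gamma = config$gamma, k_n = config$k_n,
                k_local = config$k_local)
  lap <- graph_laplacian(graph, weighting = config$laplacian_weighting)
  d_le <- min(config$dim, ncol(cc$matrix) - 1L)
  d_pca <- min(config$dim, dim(filt$data))
  list(le = laplacian_eigenmaps(lap, d_le),
       pca = pca_embedding(t(filt$data), d_pca),
       graph = graph, ccd = cc, filtered = filt)
}

#' Run the full multi-subject analysis
#'
#' Per subject: embedding ([embed_timeseries()]), 1-vs-1 decoding for every
#' stage pair, multi-class 1-vs-all decoding (each with the PCA baseline),
#' and best-single-dimension ROC per stage pair. With more than one subject,
#' manifolds are landmark-Procrustes aligned and leave-one-subject-out
#' decoding is added. With `n_perm > 0`, surrogate significance
#' ([decode_significance()]) is computed for the first subject's multi-class
#' accuracy. The report contains only deterministic quantities (no
#' timestamps), so identical inputs, config and seed give identical reports.
#'
#' @param ts_list A [parcellated_ts()] or list of them (one per subject).
#' @param labels_list Matching [stage_labels()] (or list).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-subject embeddings and
#'   edge lists, the group embedding and `report.json` are written there.
#' @param n_perm Surrogates for the significance stage; default 0 = skip
#'   (set to `config$n_perm` for the full analysis — each surrogate re-runs
#'   the entire pipeline).
#' @param verbose Log one line per stage (default TRUE).
#' @return The report, an S3 list of class `pipeline_report`.
#' @export
run_pipeline <- function(ts_list, labels_list, config = pipeline_config(),
                         out_dir = NULL, n_perm = 0L, verbose = TRUE) {
  if (inherits(ts_list, "parcellated_ts")) ts_list <- list(ts_list)
  if (inherits(labels_list, "stage_labels")) labels_list <- list(labels_list)
  stopifnot(length(ts_list) >= 1L, length(ts_list) == length(labels_list))
  say <- function(...) if (verbose) message("[imanifold] ", ...)
  for (s in seq_along(ts_list))
    if (n_trs(ts_list[[s]]) != length(labels_list[[s]]))
      stop("subject ", s, ": ", n_trs(ts_list[[s]]), " TRs but ",
           length(labels_list[[s]]), " labels")

  subjects <- vector("list", length(ts_list))
  embeddings <- vector("list", length(ts_list))
  for (s in seq_along(ts_list)) {
    say("subject ", s, ": embedding ", n_regions(ts_list[[s]]), " x ",
        n_trs(ts_list[[s]]))
    emb <- embed_timeseries(ts_list[[s]], config)
    embeddings[[s]] <- emb
    labs <- labels_list[[s]]
    present <- levels(labs)[levels(labs) %in% labs[!is.na(labs)]]
    pairs <- if (length(present) >= 2L) utils::combn(present, 2L,
                                                     simplify = FALSE)
             else list()
    res_1v1 <- lapply(pairs, function(p) {
      le <- crossval_1v1(emb$le, labs, p[1], p[2], n_folds = config$n_folds,
                         C = config$svm_C, seed = config$seed,
                         fold_scheme = config$fold_scheme)
      pc <- crossval_1v1(emb$pca, labs, p[1], p[2], n_folds = config$n_folds,
                         C = config$svm_C, seed = config$seed,
                         fold_scheme = config$fold_scheme)
      roc <- best_dimension_roc(emb$le, labs, p[1], p[2],
                                dims_to_scan = min(3L, emb$le$d))
      list(stages = p, accuracy_le = le$accuracy, accuracy_pca = pc$accuracy,
           per_fold_le = le$per_fold, auc = roc$auc,
           roc_dimension = roc$dimension_index)
    })
    mc_le <- crossval_1vall_multiclass(emb$le, labs, n_folds = config$n_folds,
                                       C = config$svm_C, seed = config$seed,
                                       fold_scheme = config$fold_scheme)
    mc_pca <- crossval_1vall_multiclass(emb$pca, labs,
                                        n_folds = config$n_folds,
                                        C = config$svm_C, seed = config$seed,
                                        fold_scheme = config$fold_scheme)
    say("subject ", s, ": 1-vs-all accuracy LE ",
        sprintf("%.3f", mc_le$accuracy), " vs PCA ",
        sprintf("%.3f", mc_pca$accuracy))
    subjects[[s]] <- list(
      n_regions = n_regions(ts_list[[s]]), n_trs = n_trs(ts_list[[s]]),
      rmst_edges = nrow(emb$graph$edges),
      pairwise = res_1v1,
      multiclass = list(accuracy_le = mc_le$accuracy,
                        accuracy_pca = mc_pca$accuracy,
                        per_fold_le = mc_le$per_fold,
                        confusion_le = unclass(mc_le$confusion)))
  }

  group <- NULL
  if (length(ts_list) >= 2L) {
    say("aligning ", length(ts_list), " subjects (reference ",
        config$reference_subject, ")")
    al <- align_group(lapply(embeddings, `[[`, "le"), labels_list,
                      reference = config$reference_subject)
    loso <- leave_one_subject_out(al$embeddings, labels_list, C = config$svm_C)
    say("LOSO accuracy ", sprintf("%.3f", loso$accuracy))
    group <- list(landmark_residuals = al$residuals,
                  loso_accuracy = loso$accuracy,
                  loso_per_round = loso$per_fold,
                  loso_confusion = unclass(loso$confusion))
  }

  significance <- NULL
  if (n_perm > 0L) {
    say("surrogate significance: ", n_perm, " full-pipeline re-runs")
    sig <- decode_significance(ts_list[[1L]], labels_list[[1L]], config,
                               n_perm = n_perm, seed = config$seed)
    significance <- list(observed_accuracy = sig$a,
                         surrogate_accuracies = sig$a_perm,
                         p_value = sig$p, n_perm = n_perm)
  }

  report <- structure(list(config = unclass(config), subjects = subjects,
                           group = group, significance = significance),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_along(embeddings)) {
      write_embedding(embeddings[[s]]$le,
                      file.path(out_dir, sprintf("embedding_%d.tsv", s)),
                      labels_list[[s]])
      utils::write.table(embeddings[[s]]$graph$edges,
                         file.path(out_dir, sprintf("edges_%d.tsv", s)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(ts_list) >= 2L) {
      gdf <- do.call(rbind, lapply(seq_along(al$embeddings), function(s)
        data.frame(subject_id = s,
                   tr_index = seq_len(nrow(al$embeddings[[s]]$coords)) - 1L,
                   al$embeddings[[s]]$coords,
                   stage = as.character(labels_list[[s]]),
                   check.names = FALSE)))
      utils::write.table(gdf, file.path(out_dir, "group_embedding.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Intrinsic-manifold pipeline report:", length(x$subjects),
      "subject(s)\n")
  for (s in seq_along(x$subjects)) {
    sub <- x$subjects[[s]]
    cat(sprintf("  subject %d: 1-vs-all accuracy %.1f%% (PCA %.1f%%)\n", s,
                100 * sub$multiclass$accuracy_le,
                100 * sub$multiclass$accuracy_pca))
  }
  if (!is.null(x$group))
    cat(sprintf("  group LOSO accuracy: %.1f%%\n",
                100 * x$group$loso_accuracy))
  if (!is.null(x$significance))
    cat(sprintf("  surrogate p-value: %.4g (%d surrogates)\n",
                x$significance$p_value, x$significance$n_perm))
  invisible(x)
}
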