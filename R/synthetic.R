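#' Generate a synthetic hypnogram
#'
#' Emits a per-TR stage track made of contiguous runs whose lengths are
#' geometrically distributed (memoryless dwell, mean `dwell_mean_trs`), the
#' simplest model producing hypnogram-like runs. Successive runs never repeat
#' the same stage; the next stage is drawn uniformly from the others. When the
#' track is long enough to expect full coverage
#' (`n_trs >= 4 * dwell_mean_trs * n_stages`) but a stage is missing, the
#' track is regenerated deterministically from a stride of derived seeds
#' (bounded retries). `min_stage_trs` extends the same retry rule to a
#' minimum per-stage TR count, which cross-validated decoding needs.
#'
#' The default dwell of 150 TRs (about 5 minutes at a 2.08 s TR) matches the
#' bout lengths of consolidated NREM sleep; short experimental tracks can
#' lower it.
#'
#' @param n_trs Number of TRs to emit (>= number of stages).
#' @param stages Character vector of stage identifiers.
#' @param dwell_mean_trs Mean dwell time per run, in TRs (>= 1).
#' @param seed Integer seed; fixes the track completely.
#' @param min_stage_trs Regenerate (bounded, deterministic) until every stage
#'   has at least this many TRs; 0 disables (default).
#' @return A [stage_labels()] track of length `n_trs`.
#' @export
generate_hypnogram <- function(n_trs, stages = c("Awake", "N1", "N2", "N3"),
                               dwell_mean_trs = 150, seed = 1L,
                               min_stage_trs = 0L) {
  stages <- as.character(stages)
  if (n_trs < 1L) stop("n_trs must be >= 1")
  if (length(stages) < 1L) stop("need at least one stage id")
  if (n_trs < length(stages))
    stop("cannot cover ", length(stages), " stages in ", n_trs, " TRs")
  if (dwell_mean_trs < 1) stop("dwell_mean_trs must be >= 1")
  if (min_stage_trs * length(stages) > n_trs)
    stop("min_stage_trs = ", min_stage_trs, " is impossible for ",
         length(stages), " stages in ", n_trs, " TRs")
  want_coverage <- n_trs >= 4 * dwell_mean_trs * length(stages)
  for (attempt in 0:60) {
    lab <- draw_hypnogram(n_trs, stages, dwell_mean_trs,
                           seed + 1009L * attempt)
    counts <- table(factor(lab, levels = stages))
    if ((!want_coverage || all(counts > 0)) && all(counts >= min_stage_trs))
      break
    if (attempt == 60L)
      stop("could not satisfy stage coverage after 61 attempts; ",
           "lower min_stage_trs or dwell_mean_trs")
  }
  stage_labels(lab, stages = stages)
}

draw_hypnogram <- function(n_trs, stages, dwell_mean_trs, seed) {
  withr::with_seed(seed, {
  lab <- character(n_trs)
  pos <- 1L
  cur <- sample(stages, 1L)
  while (pos <= n_trs) {
    # geometric run length with mean dwell_mean_trs (support >= 1)
    run <- 1L + stats::rgeom(1L, prob = 1 / dwell_mean_trs)
    end <- min(pos + run - 1L, n_trs)
    lab[pos:end] <- cur
    pos <- end + 1L
    if (length(stages) > 1L)
      cur <- sample(setdiff(stages, cur), 1L)
  }
  lab
  })
}

#' Stage-specific coupling templates
#'
#' Builds one block-diagonal coupling matrix per stage: regions are split into
#' blocks of `block_size` under a stage-specific (seeded) permutation, with
#' coupling strength `coupling` inside blocks and 0 elsewhere. Distinct
#' partitions per stage plant a distinct synchrony pattern for each stage --
#' the structure the phase-coherence pipeline is designed to detect.
#'
#' @param n_regions Number of regions N.
#' @param stages Character vector of stage ids.
#' @param block_size Regions per synchronized block (must divide N).
#' @param coupling Within-block coupling strength (>= 0).
#' @param seed Integer seed controlling the per-stage partitions.
#' @return Named list of N x N symmetric zero-diagonal matrices, one per stage.
#' @export
stage_coupling_templates <- function(n_regions, stages, block_size = 5L,
                                     coupling = 1, seed = 1L) {
  if (n_regions %% block_size != 0L)
    stop("block_size must divide n_regions")
  if (coupling < 0) stop("coupling must be >= 0")
  out <- vector("list", length(stages))
  names(out) <- stages
  for (k in seq_along(stages)) {
    perm <- if (k == 1L) seq_len(n_regions) else
      withr::with_seed(seed + 1000L * k, sample(n_regions))
    grp <- integer(n_regions)
    grp[perm] <- rep(seq_len(n_regions / block_size), each = block_size)
    a <- coupling * outer(grp, grp, "==")
    diag(a) <- 0
    out[[k]] <- a
  }
  out
}

#' Specification of a synthetic multi-stage oscillator run
#'
#' Parameters of the Kuramoto phase model used by [simulate_bold()]. Regions
#' are phase oscillators with natural frequencies in the ultraslow BOLD band;
#' the coupling matrix switches between stage templates according to a label
#' track, so pairwise phase locking (the quantity the pipeline measures) is
#' stage-dependent by construction.
#'
#' @param n_regions Number of regions N.
#' @param templates Named list of N x N symmetric, zero-diagonal, nonnegative
#'   coupling matrices, one per stage (see [stage_coupling_templates()]).
#' @param tr_seconds Sampling interval in seconds (default 2.08).
#' @param freq_range Range in Hz natural frequencies are drawn from
#'   (default `c(0.04, 0.07)`).
#' @param global_gain Global coupling gain K (>= 0, default 1).
#' @param dwell_mean_trs Mean stage dwell in TRs (default 150, consolidated
#'   sleep bouts of ~5 minutes).
#' @param phase_noise_sd Phase diffusion, radians per sqrt(second); default 0.05.
#' @param obs_noise_sd Additive observation noise SD, signal units; default 0.1.
#' @param substeps Euler integration substeps per TR (default 10).
#' @param seed Integer seed; fixes frequencies, initial phases and all noise.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_regions, templates, tr_seconds = 2.08,
                            freq_range = c(0.04, 0.07), global_gain = 1,
                            dwell_mean_trs = 150, phase_noise_sd = 0.05,
                            obs_noise_sd = 0.1, substeps = 10L, seed = 1L) {
  stopifnot(n_regions >= 2L, global_gain >= 0, dwell_mean_trs >= 1,
            phase_noise_sd >= 0, obs_noise_sd >= 0, substeps >= 1L)
  if (is.null(names(templates)) || any(names(templates) == ""))
    stop("templates must be a named list (names = stage ids)")
  for (nm in names(templates)) {
    a <- templates[[nm]]
    if (!is.matrix(a) || nrow(a) != n_regions || ncol(a) != n_regions)
      stop("template '", nm, "' is not ", n_regions, " x ", n_regions)
    if (max(abs(a - t(a))) > 1e-12 || any(diag(a) != 0) || any(a < 0))
      stop("template '", nm,
           "' must be symmetric, nonnegative, with zero diagonal")
  }
  if (freq_range[1] < 0.04 - 1e-12 || freq_range[2] > 0.07 + 1e-12)
    stop("natural frequencies must stay within the 0.04-0.07 Hz band")
  freqs <- withr::with_seed(seed,
    stats::runif(n_regions, freq_range[1], freq_range[2]))
  structure(list(n_regions = n_regions, templates = templates,
                 tr_seconds = tr_seconds, natural_freqs = freqs,
                 global_gain = global_gain, dwell_mean_trs = dwell_mean_trs,
                 phase_noise_sd = phase_noise_sd, obs_noise_sd = obs_noise_sd,
                 substeps = substeps, seed = seed),
            class = "simulation_spec")
}

#' Simulate stage-switching BOLD-like signals
#'
#' Euler-integrates Kuramoto phase dynamics
#' `dtheta_i = 2 pi f_i dt + K sum_j A[s(t)]_ij sin(theta_j - theta_i) dt +
#' phase noise`, with the coupling template A switching per the label track,
#' and observes `cos(theta_i(t))` plus Gaussian noise at each TR. The first
#' TRs after onset contain the synchronization transient; by default they are
#' kept (real recordings contain stage transitions too), `burn_in_trs`
#' prepends and discards extra settling TRs if removal is wanted.
#'
#' @param spec A [simulation_spec()].
#' @param labels A [stage_labels()] track; every level used must have a
#'   template in `spec$templates`.
#' @param burn_in_trs TRs simulated before t = 1 and discarded (default 0).
#' @return A [parcellated_ts()]; the true phase matrix is attached as
#'   attribute `"phases"` for oracle checks.
#' @export
simulate_bold <- function(spec, labels, burn_in_trs = 0L) {
  stopifnot(inherits(spec, "simulation_spec"))
  lab <- as.character(labels)
  if (any(is.na(lab))) stop("labels must not contain NA for simulation")
  missing_t <- setdiff(unique(lab), names(spec$templates))
  if (length(missing_t) > 0L)
    stop("no coupling template for stage(s): ",
         paste(missing_t, collapse = ", "))
  n <- spec$n_regions
  t_total <- length(lab) + burn_in_trs
  lab_full <- c(rep(lab[1L], burn_in_trs), lab)
  dt <- spec$tr_seconds / spec$substeps
  omega <- 2 * pi * spec$natural_freqs
  withr::with_seed(spec$seed + 1L, {
  theta <- stats::runif(n, -pi, pi)
  phases <- matrix(0, n, t_total)
  noise_scale <- spec$phase_noise_sd * sqrt(dt)
  for (t in seq_len(t_total)) {
    a <- spec$templates[[lab_full[t]]]
    for (s in seq_len(spec$substeps)) {
      st <- sin(theta); ct <- cos(theta)
      # sum_j A_ij sin(theta_j - theta_i) via the angle-difference identity
      coupling <- (a %*% st) * ct - (a %*% ct) * st
      theta <- theta + (omega + spec$global_gain * drop(coupling)) * dt
      if (noise_scale > 0)
        theta <- theta + stats::rnorm(n, 0, noise_scale)
    }
    phases[, t] <- theta
  }
  keep <- seq.int(burn_in_trs + 1L, t_total)
  phases <- phases[, keep, drop = FALSE]
  x <- cos(phases)
  if (spec$obs_noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, spec$obs_noise_sd), n)
  })
  out <- parcellated_ts(x, spec$tr_seconds)
  attr(out, "phases") <- ((phases + pi) %% (2 * pi)) - pi
  out
}

#' Simulate one synthetic subject end to end
#'
#' Convenience wrapper: draws a hypnogram and the matching Kuramoto run with
#' a single seed, returning both the series and its ground-truth labels.
#'
#' @param n_trs Number of TRs.
#' @param stages Stage vocabulary (default the four NREM-cycle stages).
#' @param n_regions Number of regions (default 20).
#' @param seed Integer seed.
#' @param templates Optional list of coupling templates; defaults to
#'   [stage_coupling_templates()] with block size `n_regions / 4`.
#' @param min_stage_trs Minimum TRs per stage enforced on the hypnogram;
#'   defaults to enough for 10-fold cross-validation per stage when the track
#'   is long enough (`min(40, n_trs %/% (2 * n_stages))`).
#' @param ... Further arguments passed to [simulation_spec()].
#' @return List with `ts` ([parcellated_ts()]), `labels` ([stage_labels()])
#'   and `spec`.
#' @export
simulate_subject <- function(n_trs, stages = c("Awake", "N1", "N2", "N3"),
                             n_regions = 20L, seed = 1L, templates = NULL,
                             min_stage_trs = NULL, ...) {
  if (is.null(templates))
    templates <- stage_coupling_templates(
      n_regions, stages, block_size = max(2L, n_regions %/% 4L), seed = seed)
  spec <- simulation_spec(n_regions, templates, seed = seed, ...)
  if (is.null(min_stage_trs))
    min_stage_trs <- min(40L, n_trs %/% (2L * length(stages)))
  labels <- generate_hypnogram(n_trs, stages,
                               dwell_mean_trs = spec$dwell_mean_trs,
                               seed = seed + 500L,
                               min_stage_trs = min_stage_trs)
  list(ts = simulate_bold(spec, labels), labels = labels, spec = spec)
}
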