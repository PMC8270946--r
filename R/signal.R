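#' Zero-phase Butterworth band-pass filter
#'
#' Filters every region's time series into the ultraslow BOLD band with a
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`),
#' so the filter contributes no group delay and instantaneous-phase estimates
#' downstream are undistorted.
#'
#' @param ts A [parcellated_ts()].
#' @param low_hz,high_hz Band edges in Hz. Defaults 0.04 and 0.07, the
#'   ultraslow band in which BOLD phase coherence is usually computed.
#' @param order Overall band-pass filter order (must be even; the underlying
#'   design uses `order/2` pole pairs per band edge). Default 6.
#' @param trim_trs Number of TRs to drop from each end after filtering
#'   (edge transients). Default 0: all timepoints are kept and consumers are
#'   expected to tolerate edge artifacts.
#' @return A [parcellated_ts()] with the band recorded in `$band`.
#' @export
bandpass <- function(ts, low_hz = 0.04, high_hz = 0.07, order = 6L,
                     trim_trs = 0L) {
  stopifnot(inherits(ts, "parcellated_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band (", low_hz, ", ", high_hz, ") Hz must satisfy 0 < low < high < ",
         "Nyquist = ", signif(nyq, 6), " Hz")
  if (order < 2L || order %% 2L != 0L)
    stop("filter order must be a positive even integer (band-pass designs ",
         "double the prototype order)")
  if (n_trs(ts) < 3L * order)
    stop("need at least ", 3L * order, " timepoints for stable order-",
         order, " filtering, got ", n_trs(ts))
  bf <- signal::butter(order / 2L, c(low_hz, high_hz) / nyq, type = "pass")
  # mean removal first: keeps the forward-backward pass from smearing the
  # DC offset into edge transients
  filt <- t(apply(ts$data, 1L, function(x) signal::filtfilt(bf, x - mean(x))))
  if (trim_trs > 0L) {
    keep <- seq.int(trim_trs + 1L, ncol(filt) - trim_trs)
    if (length(keep) < 2L) stop("trim_trs removes all timepoints")
    filt <- filt[, keep, drop = FALSE]
  }
  parcellated_ts(filt, ts$tr_seconds, ts$region_ids, band = c(low_hz, high_hz))
}

# Analytic signal of a real vector by the frequency-domain construction:
# zero out negative frequencies, double positive ones, keep DC (and the
# Nyquist bin for even length) untouched.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase via the analytic signal
#'
#' Computes, for each region, the phase of the analytic (Hilbert) signal at
#' every TR. Input should be narrowband (already band-passed); each region is
#' mean-centered first, as the analytic-signal construction requires.
#'
#' @param ts A [parcellated_ts()], normally the output of [bandpass()]. A
#'   warning is raised when no band metadata is present.
#' @return An object of class `phase_track`: list with `phases` (N x T matrix
#'   of radians in (-pi, pi]) and `tr_seconds`.
#' @export
instantaneous_phase <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  if (is.null(ts$band))
    warning("no band metadata: instantaneous phase assumes a narrowband signal")
  sds <- apply(ts$data, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) region(s): ",
         paste(ts$region_ids[sds == 0], collapse = ", "),
         "; phase is undefined")
  ph <- t(apply(ts$data, 1L, function(x) Arg(analytic_signal(x - mean(x)))))
  rownames(ph) <- ts$region_ids
  structure(list(phases = ph, tr_seconds = ts$tr_seconds,
                 region_ids = ts$region_ids),
            class = "phase_track")
}

#' @export
print.phase_track <- function(x, ...) {
  cat("Phase track:", nrow(x$phases), "regions x", ncol(x$phases),
      "TRs (radians)\n")
  invisible(x)
}
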