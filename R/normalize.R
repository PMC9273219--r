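#' Normalize fluorescence to dF/F0
#'
#' Converts raw fluorescence to the standard calcium-imaging quantity
#' dF/F0 = (F - F0)/F0, row-wise per neuron. Two baseline dialects are used
#' in practice and both are provided:
#' \describe{
#'   \item{`lowest_percentile`}{F0 is the mean of the lowest
#'     `ceiling(percentile * frames)` fluorescence values of that neuron
#'     (default lowest 1%) — the multi-neuron convention, robust to neurons
#'     that are active much of the time.}
#'   \item{`trace_mean`}{F0 is the neuron's mean fluorescence — the
#'     single-neuron (AVA) convention.}
#' }
#'
#' @param traces a [calcium_traces()] object.
#' @param mode baseline dialect, `"lowest_percentile"` or `"trace_mean"`.
#' @param percentile fraction of lowest frames used when
#'   `mode = "lowest_percentile"`; default 0.01.
#' @return An object of class `dff_traces` with fields `dff` (matrix, same
#'   shape as input), `f0` (per-neuron baseline vector), `mode`, `percentile`,
#'   `sampling_rate`, `trial_id`, `condition`.
#' @export
normalize_dff <- function(traces, mode = c("lowest_percentile", "trace_mean"),
                          percentile = 0.01) {
  stopifnot(inherits(traces, "calcium_traces"))
  mode <- match.arg(mode)
  vals <- traces$values
  nf <- ncol(vals)
  if (mode == "lowest_percentile") {
    if (!is.numeric(percentile) || percentile <= 0 || percentile > 1) {
      stop("`percentile` must be in (0, 1]", call. = FALSE)
    }
    k <- max(1L, as.integer(ceiling(percentile * nf)))
    f0 <- apply(vals, 1L, function(x) mean(sort(x, partial = k)[seq_len(k)]))
  } else {
    f0 <- rowMeans(vals)
  }
  if (any(f0 <= 0)) {
    stop("baseline F0 <= 0 for neuron(s) ",
         paste(which(f0 <= 0), collapse = ", "),
         ": pathological trace", call. = FALSE)
  }
  dff <- sweep(sweep(vals, 1L, f0, "-"), 1L, f0, "/")
  structure(
    list(dff = dff, f0 = f0, mode = mode,
         percentile = if (mode == "lowest_percentile") percentile else NA_real_,
         sampling_rate = traces$sampling_rate,
         trial_id = traces$trial_id, condition = traces$condition),
    class = "dff_traces"
  )
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf("<dff_traces> %s: %d neurons x %d frames, baseline = %s\n",
              x$trial_id, nrow(x$dff), ncol(x$dff), x$mode))
  invisible(x)
}

#' Signal-to-noise ratio of a fluorescence trace
#'
#' Two estimators:
#' \describe{
#'   \item{`manual_amplitude`}{mirrors by-eye scoring: the caller supplies a
#'     frame window containing the largest sustained transient and a window of
#'     minimal dynamics; SNR = 20*log10(signal amplitude / mean noise
#'     amplitude), amplitudes measured as mean |dF/F0| within each window.}
#'   \item{`automated_power`}{fully automatic: the trace is cut into
#'     non-overlapping windows of `window_s` seconds, mean squared value
#'     (power) computed per window, and SNR = 10*log10(max power / min power).
#'     The ratio is >= 1 by construction, so snr_db >= 0.}
#' }
#'
#' @param trace numeric vector, a single neuron's dF/F0 series.
#' @param method `"manual_amplitude"` or `"automated_power"`.
#' @param sampling_rate Hz.
#' @param window_s window length in seconds for the automated method
#'   (default 10).
#' @param signal_window,noise_window integer frame index vectors, required for
#'   the manual method.
#' @return list with `snr_db`, `method`, `window_s`.
#' @export
compute_snr <- function(trace, method = c("automated_power", "manual_amplitude"),
                        sampling_rate, window_s = 10,
                        signal_window = NULL, noise_window = NULL) {
  method <- match.arg(method)
  trace <- as.numeric(trace)
  if (method == "manual_amplitude") {
    if (is.null(signal_window) || is.null(noise_window)) {
      stop("manual method needs `signal_window` and `noise_window` frame indices",
           call. = FALSE)
    }
    s <- mean(abs(trace[signal_window]))
    n <- mean(abs(trace[noise_window]))
    if (n <= 0) stop("zero noise amplitude: SNR undefined", call. = FALSE)
    list(snr_db = 20 * log10(s / n), method = method, window_s = NA_real_)
  } else {
    wlen <- as.integer(round(window_s * sampling_rate))
    if (wlen < 1L || length(trace) < wlen) {
      stop("trace shorter than one SNR window", call. = FALSE)
    }
    nwin <- length(trace) %/% wlen
    idx <- seq_len(nwin * wlen)
    pw <- tapply(trace[idx]^2, rep(seq_len(nwin), each = wlen), mean)
    if (min(pw) <= 0) stop("zero minimal window power: SNR undefined", call. = FALSE)
    list(snr_db = 10 * log10(max(pw) / min(pw)), method = method,
         window_s = window_s)
  }
}
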