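#' Per-neuron power spectral densities
#'
#' One-sided periodogram of each neuron's full-length trace after per-neuron
#' mean removal; no segmentation or tapering, so spectral resolution is
#' 1/duration (1/600 Hz for a 10-min trial). The DC bin is excluded — mean
#' removal makes it meaningless — and with the scaling used here the
#' remaining bins satisfy Parseval: `sum(power) * df` equals the trace
#' variance (mean squared deviation, denominator n).
#'
#' @param x a `dff_traces` or `deriv_traces` object, or a numeric matrix
#'   (neurons x frames).
#' @param sampling_rate Hz; taken from `x` when it carries one.
#' @return An object of class `psd_set`: `freqs` (Hz, strictly increasing,
#'   DC excluded, up to Nyquist), `power` (neurons x frequencies, units
#'   1/Hz), `df` (bin width), `normalized = FALSE`, `source`
#'   (`"dff"`/`"derivative"`/`"matrix"`), `zero_rows` (indices of all-zero
#'   neurons, whose rows are all-zero power).
#' @export
compute_psd <- function(x, sampling_rate = NULL) {
  if (inherits(x, "dff_traces")) {
    mat <- x$dff; fs <- x$sampling_rate; src <- "dff"
  } else if (inherits(x, "deriv_traces")) {
    mat <- x$ddt; fs <- x$sampling_rate; src <- "derivative"
  } else {
    mat <- as.matrix(x); fs <- sampling_rate; src <- "matrix"
    if (is.null(fs)) stop("`sampling_rate` required for matrix input", call. = FALSE)
  }
  n <- ncol(mat)
  if (n < 64L) stop("need >= 64 frames for a PSD", call. = FALSE)
  nhalf <- n %/% 2L
  freqs <- (1:nhalf) * fs / n
  centered <- mat - rowMeans(mat)
  power <- matrix(0, nrow(mat), nhalf)
  for (i in seq_len(nrow(mat))) {
    X <- fft(centered[i, ])
    p <- Mod(X[2:(nhalf + 1L)])^2 / (fs * n)
    # one-sided: double every bin except Nyquist (present only for even n)
    scale2 <- rep(2, nhalf)
    if (n %% 2L == 0L) scale2[nhalf] <- 1
    power[i, ] <- p * scale2
  }
  zero_rows <- which(apply(centered, 1L, function(r) all(r == 0)))
  structure(
    list(freqs = freqs, power = power, df = fs / n, normalized = FALSE,
         source = src, zero_rows = zero_rows),
    class = "psd_set"
  )
}

#' Condition-mean PSD, normalized to unit total power
#'
#' Averages per-neuron PSDs within each worm, then across worms, and rescales
#' the grand mean so its total power (sum times bin width) is exactly 1.
#' Normalizing removes absolute fluorescence differences between conditions
#' (e.g. age-dependent indicator expression), leaving only the distribution
#' of power across frequencies. The cumulative curve is the running integral
#' of the normalized mean, monotone from ~0 to 1.
#'
#' @param psdsets list of `psd_set` objects (one per worm), identical grids.
#' @return list of class `mean_psd`: `freqs`, `power` (normalized mean),
#'   `df`, `cumulative` (running cumulative power fraction), `n_worms`.
#' @export
mean_normalized_psd <- function(psdsets) {
  if (inherits(psdsets, "psd_set")) psdsets <- list(psdsets)
  if (length(psdsets) == 0L) stop("no PSD sets supplied", call. = FALSE)
  f0 <- psdsets[[1L]]$freqs
  for (p in psdsets) {
    if (length(p$freqs) != length(f0) || any(p$freqs != f0)) {
      stop("PSD frequency grids differ between worms", call. = FALSE)
    }
  }
  per_worm <- vapply(psdsets, function(p) colMeans(p$power),
                     numeric(length(f0)))
  mu <- rowMeans(per_worm)
  df <- psdsets[[1L]]$df
  total <- sum(mu) * df
  if (total <= 0) stop("zero total power in mean PSD", call. = FALSE)
  mu <- mu / total
  list_out <- list(freqs = f0, power = mu, df = df,
                   cumulative = cumsum(mu) * df, n_worms = length(psdsets))
  structure(list_out, class = "mean_psd")
}

#' Spectral edge frequency
#'
#' The smallest grid frequency below which at least a fraction `q` of the
#' total spectral power resides (default q = 0.40, the 40% spectral edge).
#' Reported on the grid without interpolation, so the value is resolved to
#' one bin width. A rightward shift of spectral mass — faster, noisier
#' dynamics — raises the edge.
#'
#' @param psd a `mean_psd`, a `psd_set` (edge per neuron), or a numeric
#'   power vector.
#' @param q power fraction in (0, 1); default 0.40.
#' @param freqs frequency grid, required for vector input.
#' @return For `mean_psd`/vector input, a single edge frequency (Hz). For a
#'   `psd_set`, a numeric vector of per-neuron edges (NA for zero-power
#'   neurons).
#' @export
spectral_edge <- function(psd, q = 0.40, freqs = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must be a single fraction in (0, 1)", call. = FALSE)
  }
  edge1 <- function(pw, fr) {
    tot <- sum(pw)
    if (tot <= 0) return(NA_real_)
    fr[which(cumsum(pw) / tot >= q)[1L]]
  }
  if (inherits(psd, "mean_psd")) {
    edge1(psd$power, psd$freqs)
  } else if (inherits(psd, "psd_set")) {
    apply(psd$power, 1L, edge1, fr = psd$freqs)
  } else {
    if (is.null(freqs)) stop("`freqs` required for vector input", call. = FALSE)
    edge1(as.numeric(psd), freqs)
  }
}
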