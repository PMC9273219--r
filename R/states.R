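#' PCA state-space trajectory of a population recording
#'
#' Principal component analysis with neurons as variables and frames as
#' observations: each frame is a point in neuron-activity space, and the
#' first `k` score series trace the system's trajectory through its
#' low-dimensional activity manifold. Traces are mean-centered per neuron but
#' not variance-scaled, and scores are not whitened, so score amplitude
#' retains the original dF/F0 scale. Component signs are fixed so that each
#' loading vector's largest-magnitude entry is positive.
#'
#' @param dff a `dff_traces` object or numeric matrix (neurons x frames).
#' @param k number of score dimensions to retain (default 3, the plotted
#'   trajectory).
#' @return list of class `pca_trajectory`: `scores` (frames x k),
#'   `explained_var` (fraction per component, all components, sums to 1),
#'   `loadings` (neurons x k), `k`, `sampling_rate` (when known).
#' @export
run_pca <- function(dff, k = 3L) {
  mat <- if (inherits(dff, "dff_traces")) dff$dff else as.matrix(dff)
  fs <- if (inherits(dff, "dff_traces")) dff$sampling_rate else NULL
  if (k > nrow(mat)) stop("`k` exceeds neuron count", call. = FALSE)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, "*")
  structure(
    list(scores = scores, explained_var = ev, loadings = loadings,
         k = as.integer(k), sampling_rate = fs),
    class = "pca_trajectory"
  )
}

#' Angular direction changes along a trajectory
#'
#' At each frame t the trajectory's past displacement P(t) - P(t-w) and
#' future displacement P(t+w) - P(t) are compared (w = `window_s` seconds,
#' default 3 s); the absolute angle between them, in degrees, measures how
#' sharply the population state changes direction. Smooth state cycling gives
#' small angles; stochastic wandering gives the isotropic-vector
#' distribution. Frames where either displacement has zero norm yield an
#' undefined angle (NA), excluded from histograms but counted.
#'
#' @param traj a `pca_trajectory` (uses its k-dimensional scores) or a
#'   numeric matrix frames x dims.
#' @param sampling_rate Hz; taken from `traj` when it carries one.
#' @param window_s half-window in seconds (default 3).
#' @return list of class `angular_changes`: `angles` (degrees in [0, 180],
#'   NA where undefined; one value per valid frame), `frames` (frame indices
#'   of the valid range), `window_s`, `n_undefined`.
#' @export
angular_changes <- function(traj, sampling_rate = NULL, window_s = 3) {
  scores <- if (inherits(traj, "pca_trajectory")) traj$scores else as.matrix(traj)
  fs <- sampling_rate %||%
    (if (inherits(traj, "pca_trajectory")) traj$sampling_rate else NULL)
  if (is.null(fs)) stop("`sampling_rate` required", call. = FALSE)
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  w <- max(1L, as.integer(round(window_s * fs)))
  n <- nrow(scores)
  if (n <= 2L * w) stop("trajectory shorter than 2 windows", call. = FALSE)
  idx <- (w + 1L):(n - w)
  vpast <- scores[idx, , drop = FALSE] - scores[idx - w, , drop = FALSE]
  vfut <- scores[idx + w, , drop = FALSE] - scores[idx, , drop = FALSE]
  np <- sqrt(rowSums(vpast^2))
  nf <- sqrt(rowSums(vfut^2))
  cosang <- rowSums(vpast * vfut) / (np * nf)
  cosang[np == 0 | nf == 0] <- NA_real_
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  structure(
    list(angles = ang, frames = idx, window_s = window_s,
         n_undefined = sum(is.na(ang))),
    class = "angular_changes"
  )
}

#' Probability histogram of angular changes
#'
#' Pools the defined angles of one or more trials (concatenation before
#' binning, so longer trials weigh proportionally) into a probability
#' histogram over [0, 180] degrees, normalized to sum to 1.
#'
#' @param series an `angular_changes` object or a list of them.
#' @param bins number of bins (default 18, width 10 degrees).
#' @return list: `breaks`, `mids`, `prob` (sums to 1), `n_angles`,
#'   `n_undefined`.
#' @export
angle_histogram <- function(series, bins = 18L) {
  if (inherits(series, "angular_changes")) series <- list(series)
  ang <- unlist(lapply(series, function(s) s$angles))
  n_undef <- sum(vapply(series, function(s) s$n_undefined, 0L))
  ang <- ang[!is.na(ang)]
  if (length(ang) == 0L) stop("no defined angles to bin", call. = FALSE)
  breaks <- seq(0, 180, length.out = bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(ang, breaks, rightmost.closed = TRUE,
                                            all.inside = TRUE), 1L), bins),
                     nbins = bins)
  list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
       prob = counts / sum(counts), n_angles = length(ang),
       n_undefined = n_undef)
}

#' Time-time recurrence map of population activity
#'
#' Euclidean distance in full neuron-activity space between every pair of
#' frames, divided by the maximal pairwise distance of the trial so entries
#' lie in [0, 1]. Near-zero off-diagonal bands mark recurring population
#' states (periodicity); an all-equal recording yields an all-zero map
#' (flagged).
#'
#' @param dff a `dff_traces` object or numeric matrix (neurons x frames).
#' @return list of class `recurrence_map`: `dist` (frames x frames,
#'   symmetric, zero diagonal, max 1 unless degenerate), `degenerate`
#'   (TRUE when all frames identical).
#' @export
recurrence_map <- function(dff) {
  mat <- if (inherits(dff, "dff_traces")) dff$dff else as.matrix(dff)
  if (ncol(mat) < 2L) stop("need >= 2 frames", call. = FALSE)
  d <- as.matrix(stats::dist(t(mat)))
  m <- max(d)
  degenerate <- m == 0
  if (!degenerate) d <- d / m
  dimnames(d) <- NULL
  structure(list(dist = d, degenerate = degenerate), class = "recurrence_map")
}
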