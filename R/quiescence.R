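#' Per-frame and global quiescence classification
#'
#' Implements the population quiescence rules. A trial-level high-activity
#' reference (`active_value`) is the mean over the top 25% of frames of the
#' frame-mean dF/F0; a neuron is quiescent at a frame when its dF/F0 lies
#' strictly below one third of that reference; the population is globally
#' quiescent at frames where strictly more than 70% of neurons are quiescent.
#' All three constants are relative to the trial's own activity level, so the
#' classification is invariant to overall fluorescence scale.
#'
#' @param dff a `dff_traces` object or numeric matrix (neurons x frames).
#' @param top_frame_fraction fraction of highest-activity frames defining the
#'   reference (default 0.25).
#' @param quiescence_ratio cutoff as a fraction of `active_value`
#'   (default 1/3).
#' @param global_threshold fraction of quiescent neurons above which a frame
#'   is globally quiescent (default 0.70, strict).
#' @param per_neuron_reference when TRUE, rank frames per neuron instead of
#'   by the trial frame mean (alternative reading of the rule; default
#'   FALSE).
#' @return list of class `quiescence_profile`: `active_value`, `cutoff`,
#'   `frame_quiescent_fraction` (per frame, in [0,1]), `global_quiescent`
#'   (logical per frame), `time_in_quiescence` (mean of `global_quiescent`),
#'   plus the thresholds used.
#' @export
quiescence_profile <- function(dff, top_frame_fraction = 0.25,
                               quiescence_ratio = 1 / 3,
                               global_threshold = 0.70,
                               per_neuron_reference = FALSE) {
  mat <- if (inherits(dff, "dff_traces")) dff$dff else as.matrix(dff)
  nf <- ncol(mat)
  if (nf < 8L) stop("need >= 8 frames", call. = FALSE)
  for (v in c(top_frame_fraction, quiescence_ratio, global_threshold)) {
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("thresholds must be fractions in (0, 1)", call. = FALSE)
    }
  }
  k <- max(1L, as.integer(ceiling(top_frame_fraction * nf)))
  if (per_neuron_reference) {
    active_value <- mean(apply(mat, 1L, function(x) {
      mean(sort(x, decreasing = TRUE)[seq_len(k)])
    }))
  } else {
    frame_mean <- colMeans(mat)
    active_value <- mean(sort(frame_mean, decreasing = TRUE)[seq_len(k)])
  }
  if (active_value <= 0) {
    stop("non-positive high-activity reference: degenerate trial", call. = FALSE)
  }
  cutoff <- active_value * quiescence_ratio
  quiescent <- mat < cutoff
  frac <- colMeans(quiescent)
  global <- frac > global_threshold
  structure(
    list(active_value = active_value, cutoff = cutoff,
         top_frame_fraction = top_frame_fraction,
         quiescence_ratio = quiescence_ratio,
         global_threshold = global_threshold,
         frame_quiescent_fraction = frac,
         global_quiescent = global,
         time_in_quiescence = mean(global)),
    class = "quiescence_profile"
  )
}

#' Pooled distribution of the quiescent-neuron fraction
#'
#' Pools the per-frame fraction of quiescent neurons across trials into a
#' probability histogram over [0, 1] (sums to 1). Aroused and sleep-like
#' states appear as separate modes of this distribution.
#'
#' @param profiles a `quiescence_profile` or list of them.
#' @param bins number of bins (default 20).
#' @return list: `breaks`, `mids`, `prob`, `n_frames`.
#' @export
quiescent_fraction_distribution <- function(profiles, bins = 20L) {
  if (inherits(profiles, "quiescence_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles supplied", call. = FALSE)
  fr <- unlist(lapply(profiles, `[[`, "frame_quiescent_fraction"))
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(fr, breaks, rightmost.closed = TRUE,
                                            all.inside = TRUE), 1L), bins),
                     nbins = bins)
  list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
       prob = counts / sum(counts), n_frames = length(fr))
}

#' Extract a quiescent or quiescence-free trace segment
#'
#' Selects one contiguous window of `segment_frames` frames from a trial:
#' with `want_quiescence = TRUE`, the window maximizing time in global
#' quiescence (earliest such window on ties; must contain some quiescence);
#' with `FALSE`, the earliest window containing no globally quiescent frame.
#' Segments re-enter the metric pipeline unchanged, which is how the effect
#' of quiescence on downstream metrics is isolated.
#'
#' @param traces a `calcium_traces` object.
#' @param profile the trial's `quiescence_profile`.
#' @param segment_frames window length in frames (default 700).
#' @param want_quiescence logical.
#' @return A `calcium_traces` segment (trial_id suffixed), or NULL when no
#'   qualifying window exists.
#' @export
extract_subset <- function(traces, profile, segment_frames = 700L,
                           want_quiescence = TRUE) {
  stopifnot(inherits(traces, "calcium_traces"),
            inherits(profile, "quiescence_profile"))
  n <- n_frames(traces)
  L <- as.integer(segment_frames)
  if (n < L) stop("trial shorter than the requested segment", call. = FALSE)
  g <- as.numeric(profile$global_quiescent)
  # rolling sum of quiescent frames over every window of length L
  cs <- c(0, cumsum(g))
  wins <- cs[(L + 1L):(n + 1L)] - cs[1:(n - L + 1L)]
  if (want_quiescence) {
    best <- which.max(wins)
    if (wins[best] == 0) return(NULL)
    start <- best
  } else {
    clean <- which(wins == 0)
    if (length(clean) == 0L) return(NULL)
    start <- clean[1L]
  }
  seg <- traces$values[, start:(start + L - 1L), drop = FALSE]
  calcium_traces(seg, traces$sampling_rate,
                 trial_id = sprintf("%s[%d:%d]", traces$trial_id, start,
                                    start + L - 1L),
                 condition = traces$condition)
}
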