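#' Select the most dynamically active neurons
#'
#' Ranks neurons by the standard deviation of their dF/F0 trace and returns
#' the indices of the `n_sel` most variable ones (default 40 of 120). This
#' focuses pairwise-correlation analysis on neurons with genuinely dynamic
#' activity rather than static background. Ties are broken toward the lower
#' row index, so the selection is deterministic.
#'
#' @param dff a `dff_traces` object or numeric matrix (neurons x frames).
#' @param n_sel number of neurons to keep (>= 2); may equal the full neuron
#'   count for a no-selection robustness check.
#' @return integer vector of row indices, sorted by decreasing sd.
#' @export
select_active_neurons <- function(dff, n_sel = 40L) {
  mat <- if (inherits(dff, "dff_traces")) dff$dff else as.matrix(dff)
  if (n_sel < 2L) stop("`n_sel` must be >= 2", call. = FALSE)
  if (n_sel > nrow(mat)) stop("`n_sel` exceeds neuron count", call. = FALSE)
  sds <- apply(mat, 1L, stats::sd)
  order(-sds, seq_along(sds))[seq_len(n_sel)]
}

#' Pairwise Pearson correlations of selected differential traces
#'
#' Zero-lag Pearson correlation between the TV-regularized time differentials
#' of every pair of selected neurons, returned as the condensed upper
#' triangle (pair (i,j), i < j, in column-major order of the upper triangle).
#' Correlating differentials rather than raw traces removes slow baseline
#' co-drift and isolates moment-to-moment co-activation; strongly negative
#' values mark functionally opposed (inhibition-like) pairs.
#'
#' @param ddt a `deriv_traces` object or numeric matrix (neurons x frames).
#' @param indices neuron row indices to correlate (>= 2), e.g. from
#'   [select_active_neurons()].
#' @return list of class `pair_correlations`: `selected` (indices), `r`
#'   (condensed vector, length choose(n_sel, 2); NA for pairs involving a
#'   zero-variance neuron), `n_undefined` (count of NA pairs), `pairs`
#'   (two-column matrix of the index pairs).
#' @export
pairwise_correlations <- function(ddt, indices) {
  mat <- if (inherits(ddt, "deriv_traces")) ddt$ddt else as.matrix(ddt)
  indices <- as.integer(indices)
  if (length(indices) < 2L) stop("need >= 2 selected neurons", call. = FALSE)
  sub <- mat[indices, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  cm <- suppressWarnings(stats::cor(t(sub)))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  ut <- upper.tri(cm)
  pairs <- which(ut, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  r <- cm[cbind(pairs[, 1L], pairs[, 2L])]
  structure(
    list(selected = indices, r = r, n_undefined = sum(is.na(r)),
         pairs = cbind(i = indices[pairs[, 1L]], j = indices[pairs[, 2L]])),
    class = "pair_correlations"
  )
}

#' Proportions of strongly negative / positive correlations
#'
#' Fractions of defined neuron pairs with Pearson r strictly below
#' `neg_threshold` (default -0.2) and strictly above `pos_threshold`
#' (default +0.2). The negative proportion is the pipeline's proxy for
#' inhibition-like (anti-correlated) functional coupling; its loss is the
#' aging signature this analysis targets.
#'
#' @param pairs a `pair_correlations` object.
#' @param neg_threshold,pos_threshold tail thresholds (strict inequalities;
#'   boundary values count in neither tail).
#' @return list of class `correlation_proportions`: `neg_prop`, `pos_prop`,
#'   `neg_threshold`, `pos_threshold`, `n_pairs` (defined pairs),
#'   `n_undefined`.
#' @export
correlation_proportions <- function(pairs, neg_threshold = -0.2,
                                    pos_threshold = 0.2) {
  r <- pairs$r[!is.na(pairs$r)]
  if (length(r) == 0L) stop("no defined correlation pairs", call. = FALSE)
  structure(
    list(neg_prop = mean(r < neg_threshold),
         pos_prop = mean(r > pos_threshold),
         neg_threshold = neg_threshold, pos_threshold = pos_threshold,
         n_pairs = length(r), n_undefined = pairs$n_undefined),
    class = "correlation_proportions"
  )
}

#' Pooled correlation probability histogram
#'
#' Pools the condensed correlation vectors of several worms (concatenation,
#' so each worm contributes proportionally to its pair count) and bins them
#' over [-1, 1], normalized to sum to 1.
#'
#' @param sets list of `pair_correlations` objects (or one).
#' @param bins number of bins (default 40, width 0.05).
#' @return list: `breaks` (length bins+1), `mids`, `prob` (sums to 1),
#'   `n_values`.
#' @export
pooled_correlation_histogram <- function(sets, bins = 40L) {
  if (inherits(sets, "pair_correlations")) sets <- list(sets)
  r <- unlist(lapply(sets, function(s) s$r[!is.na(s$r)]))
  if (length(r) == 0L) stop("no defined correlation values to pool", call. = FALSE)
  breaks <- seq(-1, 1, length.out = bins + 1L)
  # mirror-symmetric bin assignment: negative values use left-closed bins,
  # positive values the reflected convention, so r and -r always land in
  # mirrored bins (edge values included)
  assign_bin <- function(v) {
    neg <- v <= 0
    idx <- integer(length(v))
    idx[neg] <- findInterval(v[neg], breaks, rightmost.closed = TRUE,
                             all.inside = TRUE)
    idx[!neg] <- bins + 1L - findInterval(-v[!neg], breaks,
                                          rightmost.closed = TRUE,
                                          all.inside = TRUE)
    pmin(pmax(idx, 1L), bins)
  }
  counts <- tabulate(assign_bin(r), nbins = bins)
  list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
       prob = counts / sum(counts), n_values = length(r))
}
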