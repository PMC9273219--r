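#' Detect candidate ON/OFF transitions in a bistable neuron trace
#'
#' Hysteresis threshold-crossing detector for neurons (AVA-style) that switch
#' between a low and a high activity state. The trace is lightly smoothed
#' (moving average), its dynamic range computed, and an ON candidate emitted
#' when the smoothed trace crosses up through the high threshold after having
#' been below the low threshold; OFF candidates are the reverse. Candidates
#' alternate ON/OFF in time by construction.
#'
#' @param dff numeric vector, single-neuron dF/F0 series.
#' @param sampling_rate Hz.
#' @param high,low hysteresis thresholds as fractions of the dynamic range
#'   (defaults 0.7 / 0.3).
#' @param min_amplitude minimal dynamic range (dF/F0 units) for the trace to
#'   be considered active at all; below it an empty list is returned.
#' @param smooth_s moving-average half-width in seconds (default 0.5).
#' @return data.frame with columns `direction` ("on"/"off") and `frame`
#'   (crossing frame), ordered in time; zero rows for a flat trace.
#' @export
detect_transitions <- function(dff, sampling_rate, high = 0.7, low = 0.3,
                               min_amplitude = 0.1, smooth_s = 0.5) {
  x <- as.numeric(dff)
  n <- length(x)
  if (n < 10 * sampling_rate) stop("trace shorter than 10 s", call. = FALSE)
  k <- max(1L, as.integer(round(smooth_s * sampling_rate)))
  if (k > 1L) {
    kernel <- rep(1 / k, k)
    x <- stats::filter(x, kernel, sides = 2)
    x[is.na(x)] <- dff[is.na(x)]
    x <- as.numeric(x)
  }
  rng <- range(x)
  if (diff(rng) < min_amplitude) {
    return(data.frame(direction = character(), frame = integer()))
  }
  hi <- rng[1] + high * diff(rng)
  lo <- rng[1] + low * diff(rng)
  state <- x[1] > hi  # TRUE = high state
  out_dir <- character()
  out_frame <- integer()
  for (i in 2:n) {
    if (!state && x[i] > hi && x[i - 1] <= hi) {
      state <- TRUE
      out_dir <- c(out_dir, "on")
      out_frame <- c(out_frame, i)
    } else if (state && x[i] < lo && x[i - 1] >= lo) {
      state <- FALSE
      out_dir <- c(out_dir, "off")
      out_frame <- c(out_frame, i)
    }
  }
  data.frame(direction = out_dir, frame = out_frame)
}

#' Fit a hyperbolic-tangent to one activity-state transition
#'
#' Least-squares fit of
#' \deqn{F(t) = b + \tfrac{a}{2}\,(1 + s\,\tanh((t - t_0)/\tau)),}
#' with \eqn{s=+1} for ON and \eqn{s=-1} for OFF transitions, to a window of a
#' dF/F0 trace. Fitting a smooth sigmoid removes the noise dependence of
#' threshold-based timing: the 5-to-95% transition time follows analytically
#' from the time constant as \eqn{2\tau\,\mathrm{atanh}(0.9)}.
#'
#' @param dff numeric vector, the full single-neuron dF/F0 series.
#' @param window integer frame indices of the fit window (>= 8 frames).
#' @param direction `"on"` or `"off"`.
#' @param sampling_rate Hz.
#' @return list of class `transition_event`: `direction`, `t0` (s, absolute),
#'   `tau` (s), `baseline`, `amplitude`, `onset_frame` (first frame at which
#'   the fitted curve passes 5% (ON) / 95% (OFF) of amplitude above baseline),
#'   `transition_time` (s, 5-95%), `fit_rmse`, `ok` (FALSE when the fit
#'   diverged or tau is outside (one frame, window length)).
#' @export
fit_transition_tanh <- function(dff, window, direction = c("on", "off"),
                                sampling_rate) {
  direction <- match.arg(direction)
  window <- as.integer(window)
  if (length(window) < 8L) stop("fit window must span >= 8 frames", call. = FALSE)
  y <- as.numeric(dff[window])
  tt <- (window - 1) / sampling_rate
  s <- if (direction == "on") 1 else -1
  # initialization on a smoothed copy (noise would otherwise dominate the
  # frame-to-frame derivative): t0 at the extreme smoothed-derivative frame,
  # tau from the 25-75% crossing span around it, with window/10 and one
  # frame as fallback starts
  b_init <- min(y)
  a_init <- max(diff(range(y)), 1e-6)
  lv <- (y - b_init) / a_init
  if (direction == "off") lv <- 1 - lv
  k5 <- max(3L, min(as.integer(round(sampling_rate)), length(lv) %/% 4))
  ma <- as.numeric(stats::filter(lv, rep(1 / k5, k5), sides = 2))
  ma[is.na(ma)] <- lv[is.na(ma)]
  i0 <- which.max(diff(ma))
  i0 <- min(i0 + 1L, length(tt))
  t0_init <- tt[i0]
  below <- which(ma[seq_len(i0)] <= 0.25)
  above <- which(ma >= 0.75)
  above <- above[above >= i0]
  tau_est <- if (length(below) && length(above)) {
    span <- tt[above[1L]] - tt[below[length(below)]]
    if (span > 0) span / (2 * atanh(0.5)) else NA_real_
  } else NA_real_
  tau_inits <- unique(stats::na.omit(c(tau_est,
                                       (length(window) / sampling_rate) / 10,
                                       1 / sampling_rate)))
  dat <- data.frame(t = tt, y = y)
  fit <- NULL
  best_rmse <- Inf
  tau_lo <- 1 / sampling_rate / 2
  tau_hi <- length(window) / sampling_rate
  for (tau_init in tau_inits) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a / 2 * (1 + s * tanh((t - t0) / tau)),
        data = dat,
        start = list(b = b_init, a = a_init, t0 = t0_init,
                     tau = max(tau_init, 1e-3)),
        lower = c(b = -Inf, a = 1e-9, t0 = min(tt) - diff(range(tt)),
                  tau = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(cand)) next
    rmse <- sqrt(mean(stats::resid(cand)^2))
    tau_c <- unname(stats::coef(cand)["tau"])
    valid <- is.finite(tau_c) && tau_c > tau_lo && tau_c < tau_hi
    # prefer any valid fit over an invalid one, then lower residual
    better <- if (is.null(fit)) TRUE else {
      was_valid <- {
        tb <- unname(stats::coef(fit)["tau"])
        is.finite(tb) && tb > tau_lo && tb < tau_hi
      }
      (valid && !was_valid) || (valid == was_valid && rmse < best_rmse)
    }
    if (better) {
      fit <- cand
      best_rmse <- rmse
    }
  }
  if (is.null(fit)) {
    return(structure(list(direction = direction, ok = FALSE,
                          transition_time = NA_real_, tau = NA_real_,
                          amplitude = NA_real_, onset_frame = NA_integer_),
                     class = "transition_event"))
  }
  p <- stats::coef(fit)
  tau <- unname(p["tau"])
  ok <- is.finite(tau) && tau > 1 / sampling_rate / 2 &&
    tau < length(window) / sampling_rate
  transition_time <- 2 * tau * atanh(0.9)
  # crossing times of the fitted curve at 5% / 95% of amplitude above baseline
  # F(t) = b + a/2 (1 + s tanh((t-t0)/tau)) crosses b + q a at
  # t = t0 + s * tau * atanh(2q - 1)
  q <- if (direction == "on") 0.05 else 0.95
  t_cross <- unname(p["t0"] + s * tau * atanh(2 * q - 1))
  onset_frame <- max(1L, as.integer(ceiling(t_cross * sampling_rate)) + 1L)
  structure(
    list(direction = direction,
         t0 = unname(p["t0"]), tau = tau,
         baseline = unname(p["b"]), amplitude = unname(p["a"]),
         onset_frame = onset_frame,
         transition_time = transition_time,
         fit_rmse = sqrt(mean(stats::resid(fit)^2)),
         ok = ok),
    class = "transition_event"
  )
}

#' Fit all detected transitions of a trace
#'
#' Convenience wrapper: runs [detect_transitions()] and fits a tanh to a
#' window of `half_window_s` seconds either side of each candidate crossing.
#'
#' @inheritParams detect_transitions
#' @param half_window_s half fit-window width in seconds (default 5).
#' @param ... passed to [detect_transitions()].
#' @return list of `transition_event` objects (failed fits retained with
#'   `ok = FALSE`).
#' @export
fit_all_transitions <- function(dff, sampling_rate, half_window_s = 5, ...) {
  cand <- detect_transitions(dff, sampling_rate, ...)
  n <- length(dff)
  hw <- as.integer(round(half_window_s * sampling_rate))
  lapply(seq_len(nrow(cand)), function(i) {
    w <- max(1L, cand$frame[i] - hw):min(n, cand$frame[i] + hw)
    fit_transition_tanh(dff, w, cand$direction[i], sampling_rate)
  })
}

#' Summarize transition kinetics of a trace
#'
#' Pairs each ON onset with the next OFF onset to form transient bouts, and
#' derives duty ratio (summed bout time over trace time), bout frequency per
#' minute, and mean rise/fall (5-95%) times. A trailing unpaired ON bout is
#' extended to the end of the trace for the duty ratio and flagged.
#'
#' @param events list of `transition_event` objects, time-ordered; events
#'   with `ok = FALSE` are dropped.
#' @param trace_length_s total trace length in seconds.
#' @param sampling_rate Hz.
#' @return list of class `kinetics_summary`: `mean_rise_time`,
#'   `mean_fall_time` (s, NA when no events of that direction),
#'   `duty_ratio`, `transient_frequency` (bouts/min), `n_on`, `n_off`,
#'   `bouts` (data.frame onset_frame/offset_frame/duration),
#'   `open_ended` (TRUE when a trailing ON was closed at trace end).
#' @export
summarize_kinetics <- function(events, trace_length_s, sampling_rate) {
  events <- Filter(function(e) isTRUE(e$ok), events)
  dirs <- vapply(events, `[[`, "", "direction")
  onsets <- vapply(events, function(e) as.numeric(e$onset_frame), 0)
  if (length(events) > 1L && any(diff(onsets) < 0)) {
    stop("events must be time-ordered", call. = FALSE)
  }
  if (length(dirs) && dirs[1] == "off") {
    stop("OFF transition before any ON: cannot pair bouts", call. = FALSE)
  }
  rise <- vapply(events[dirs == "on"], `[[`, 0, "transition_time")
  fall <- vapply(events[dirs == "off"], `[[`, 0, "transition_time")

  bouts <- data.frame(onset_frame = integer(), offset_frame = integer(),
                      duration = numeric())
  open_ended <- FALSE
  i <- 1L
  while (i <= length(events)) {
    if (dirs[i] == "on") {
      j <- i + 1L
      while (j <= length(events) && dirs[j] != "off") j <- j + 1L
      if (j <= length(events)) {
        off_frame <- events[[j]]$onset_frame
      } else {
        off_frame <- as.integer(round(trace_length_s * sampling_rate)) + 1L
        open_ended <- TRUE
      }
      on_frame <- events[[i]]$onset_frame
      bouts <- rbind(bouts, data.frame(
        onset_frame = on_frame, offset_frame = off_frame,
        duration = (off_frame - on_frame) / sampling_rate))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(
    list(
      mean_rise_time = if (length(rise)) mean(rise) else NA_real_,
      mean_fall_time = if (length(fall)) mean(fall) else NA_real_,
      duty_ratio = if (nrow(bouts)) min(1, sum(bouts$duration) / trace_length_s) else 0,
      transient_frequency = nrow(bouts) / (trace_length_s / 60),
      n_on = sum(dirs == "on"), n_off = sum(dirs == "off"),
      bouts = bouts, open_ended = open_ended
    ),
    class = "kinetics_summary"
  )
}

#' Average transition waveforms after alignment
#'
#' ON events are aligned at their fitted 5% crossing frame and OFF events at
#' their 95% crossing frame, then averaged frame-wise across events. Windows
#' truncated by the trace edges contribute only to the frames they cover.
#'
#' @param events list of `transition_event` objects (one direction).
#' @param dff_list list of numeric vectors, the source trace for each event
#'   (recycled if length 1).
#' @param direction `"on"` or `"off"`.
#' @param sampling_rate Hz.
#' @param pre_s,post_s seconds before/after the alignment frame (defaults 5).
#' @return list: `time` (s, 0 = alignment point), `mean`, `sem`, `n_events`.
#' @export
average_aligned_transitions <- function(events, dff_list, direction,
                                        sampling_rate, pre_s = 5, post_s = 5) {
  events <- Filter(function(e) isTRUE(e$ok) && e$direction == direction, events)
  if (length(events) == 0L) stop("no usable events to align", call. = FALSE)
  if (!is.list(dff_list)) dff_list <- list(dff_list)
  if (length(dff_list) == 1L) dff_list <- rep(dff_list, length(events))
  pre <- as.integer(round(pre_s * sampling_rate))
  post <- as.integer(round(post_s * sampling_rate))
  width <- pre + post + 1L
  acc <- matrix(NA_real_, length(events), width)
  for (i in seq_along(events)) {
    tr <- as.numeric(dff_list[[i]])
    a <- events[[i]]$onset_frame
    idx <- (a - pre):(a + post)
    keep <- idx >= 1L & idx <= length(tr)
    acc[i, keep] <- tr[idx[keep]]
  }
  n_per <- colSums(!is.na(acc))
  mu <- colMeans(acc, na.rm = TRUE)
  sem <- apply(acc, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else 0
  })
  mu[n_per == 0L] <- NA_real_
  list(time = (seq_len(width) - pre - 1L) / sampling_rate,
       mean = mu, sem = sem, n_events = length(events))
}
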