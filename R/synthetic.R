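# Seeded generator emulating the statistical structure of head-region
# population recordings: recurrent latent states, excitatory and
# inhibition-modulated neuron groups, slow calcium-indicator kinetics,
# intermittent global quiescence, and measurement noise.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for the population generator
#'
#' Assembles and validates the knobs of [generate_population()]. The
#' defaults describe a healthy young-adult-like recording; [age_preset()]
#' returns the documented young/aged pairs.
#'
#' @param n_neurons neurons per trial (default 120).
#' @param n_active dynamically driven neurons (default 40); the rest carry
#'   weak tonic background activity.
#' @param duration trial length in seconds (default 600).
#' @param sampling_rate Hz (default 2).
#' @param n_states latent states in the recurrent cycle (default 4).
#' @param dwell_mean mean state dwell time in seconds.
#' @param transition_stochasticity probability that a state transition jumps
#'   uniformly instead of following the cycle (0 = deterministic cycling).
#' @param inhibition_scale depth of anti-phase modulation of the
#'   inhibition-coupled group, in [0, 1]; 0 abolishes anti-correlation.
#' @param neg_fraction fraction of active neurons in the anti-phase group
#'   (default 0.3).
#' @param hf_noise_sd additive Gaussian measurement noise, dF/F0 units.
#' @param quiescence_rate global quiescence bouts per minute.
#' @param quiescence_dwell mean bout duration, seconds.
#' @param background_drive tonic dF/F0 drive of non-active neurons
#'   (default 0.3).
#' @param kernel_rise,kernel_decay calcium kernel time constants, seconds
#'   (defaults 1 and 4, slow GCaMP6s-like).
#' @param baseline_f raw fluorescence baseline, arbitrary units (default 100).
#' @param seed integer RNG seed.
#' @return validated list of class `population_config`.
#' @export
population_config <- function(n_neurons = 120L, n_active = 40L,
                              duration = 600, sampling_rate = 2,
                              n_states = 4L, dwell_mean = 12,
                              transition_stochasticity = 0.1,
                              inhibition_scale = 1.0, neg_fraction = 0.3,
                              hf_noise_sd = 0.04,
                              quiescence_rate = 0.02, quiescence_dwell = 30,
                              background_drive = 0.3,
                              kernel_rise = 1.0, kernel_decay = 4.0,
                              baseline_f = 100, seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons), n_active = as.integer(n_active),
              duration = duration, sampling_rate = sampling_rate,
              n_states = as.integer(n_states), dwell_mean = dwell_mean,
              transition_stochasticity = transition_stochasticity,
              inhibition_scale = inhibition_scale, neg_fraction = neg_fraction,
              hf_noise_sd = hf_noise_sd, quiescence_rate = quiescence_rate,
              quiescence_dwell = quiescence_dwell,
              background_drive = background_drive,
              kernel_rise = kernel_rise, kernel_decay = kernel_decay,
              baseline_f = baseline_f, seed = as.integer(seed))
  if (cfg$n_active > cfg$n_neurons) stop("n_active > n_neurons", call. = FALSE)
  for (nm in c("duration", "sampling_rate", "dwell_mean", "quiescence_dwell",
               "kernel_rise", "kernel_decay", "baseline_f")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("`", nm, "` must be positive", call. = FALSE)
    }
  }
  for (nm in c("transition_stochasticity", "inhibition_scale", "neg_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("`", nm, "` must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$hf_noise_sd < 0 || cfg$quiescence_rate < 0) {
    stop("noise sd and quiescence rate must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "population_config")
}

#' Young/aged generator presets
#'
#' Documented configuration pairs expressing the aged phenotype as
#' mechanistic knob changes relative to the young preset: shorter and more
#' stochastic latent-state dwells (erratic trajectories, more
#' high-frequency power), a five-fold weaker anti-phase (inhibition-coupled)
#' modulation (loss of negative correlations), roughly tripled measurement
#' noise, and frequent short sleep-like bouts (0.9/min x ~6 s vs
#' 0.02/min x 30 s, i.e. a few percent vs essentially none of trial time in
#' deep quiescence). The presets are qualitative emulations of young and
#' aged recordings, not fits to any measured data set.
#'
#' @param day 1 (young adult) or 9 (aged).
#' @param seed RNG seed stored in the config.
#' @return a `population_config`.
#' @export
age_preset <- function(day, seed = 1L) {
  if (!day %in% c(1, 9)) stop("unknown preset day: ", day, call. = FALSE)
  if (day == 1) {
    population_config(dwell_mean = 20, transition_stochasticity = 0.1,
                      inhibition_scale = 1.0, hf_noise_sd = 0.03,
                      quiescence_rate = 0.02, quiescence_dwell = 30,
                      seed = seed)
  } else {
    population_config(dwell_mean = 4, transition_stochasticity = 0.7,
                      inhibition_scale = 0.2, hf_noise_sd = 0.11,
                      quiescence_rate = 0.9, quiescence_dwell = 6,
                      seed = seed)
  }
}

# difference-of-exponentials calcium impulse response, unit DC gain so a
# sustained drive of x converges to a dF/F0 plateau of x
calcium_kernel <- function(rise, decay, sampling_rate, length_s = NULL) {
  length_s <- length_s %||% (6 * decay)
  t <- seq(0, length_s, by = 1 / sampling_rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / sum(k)
}

# causal convolution along rows, same length as input
convolve_causal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                         type = "open")
  out[seq_len(n)]
}

# semi-Markov state sequence: Gamma(shape 2) dwells around dwell_mean,
# cycle with probability 1 - stochasticity, else uniform jump
sample_state_sequence <- function(n_frames, n_states, dwell_mean,
                                  stochasticity, sampling_rate) {
  s <- integer(0)
  cur <- 1L
  while (length(s) < n_frames) {
    dwell_s <- rgamma(1L, shape = 2, scale = dwell_mean / 2)
    dwell_f <- max(1L, as.integer(round(dwell_s * sampling_rate)))
    s <- c(s, rep(cur, dwell_f))
    cur <- if (runif(1L) < stochasticity) {
      sample.int(n_states, 1L)
    } else {
      (cur %% n_states) + 1L
    }
  }
  s[seq_len(n_frames)]
}

# Poisson bout arrivals, exponential dwells; returns two-column frame matrix
sample_quiescence_bouts <- function(n_frames, rate_per_min, dwell_mean_s,
                                    sampling_rate) {
  duration_min <- n_frames / sampling_rate / 60
  n_bouts <- rpois(1L, rate_per_min * duration_min)
  if (n_bouts == 0L) return(matrix(integer(0), 0L, 2L,
                                   dimnames = list(NULL, c("from", "to"))))
  starts <- sort(sample.int(n_frames, n_bouts))
  lens <- pmax(1L, as.integer(round(rexp(n_bouts, 1 / dwell_mean_s) *
                                      sampling_rate)))
  ends <- pmin(n_frames, starts + lens - 1L)
  # merge overlaps so intervals are disjoint
  keep_from <- starts[1L]; keep_to <- ends[1L]
  out <- NULL
  for (i in seq_len(n_bouts)[-1L]) {
    if (starts[i] <= keep_to + 1L) {
      keep_to <- max(keep_to, ends[i])
    } else {
      out <- rbind(out, c(keep_from, keep_to))
      keep_from <- starts[i]; keep_to <- ends[i]
    }
  }
  out <- rbind(out, c(keep_from, keep_to))
  colnames(out) <- c("from", "to")
  out
}

#' Generate a synthetic population recording with ground truth
#'
#' Builds a neurons x frames fluorescence matrix from: (i) a semi-Markov
#' latent state cycle; (ii) an excitatory group of active neurons driven,
#' with state-tuned gains, by the activation envelope of the first half of
#' the cycle; (iii) an inhibition-coupled group whose drive mixes the
#' anti-phase of that envelope (weight `inhibition_scale`) with an
#' independent second latent cycle (weight `1 - inhibition_scale`) — at full
#' scale the two groups are strongly anti-correlated, at zero scale the
#' anti-correlation vanishes while within-group co-activation persists;
#' (iv) weak tonic background activity in the remaining neurons; (v) a
#' difference-of-exponentials calcium kernel; (vi) multiplicative global
#' quiescence bouts (signal x 0.05); and (vii) additive Gaussian noise.
#' Output fluorescence is `baseline_f * (1 + dff)`, floored at zero.
#'
#' @param config a [population_config()].
#' @return list: `traces` (a [calcium_traces()]), `truth` (list of class
#'   `synthetic_truth`: `state_sequence`, `state_sequence_alt`,
#'   `active_idx`, `excitatory_idx`, `inhibitory_idx`, `gains`
#'   (neurons x states), `quiescence_bouts` (frame intervals),
#'   `quiescent_frames` (logical), `noise_sd`, `config`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  cfg <- config
  nf <- as.integer(round(cfg$duration * cfg$sampling_rate))
  nn <- cfg$n_neurons
  # lead-in simulated and discarded so the calcium kernel and latent states
  # are in steady state at frame 1 (start-up transients would otherwise
  # contaminate the lowest-percentile baselines downstream)
  lead <- as.integer(round(max(60, 8 * cfg$kernel_decay) * cfg$sampling_rate))
  ntot <- nf + lead
  keep <- (lead + 1L):ntot
  with_local_seed(cfg$seed, {
    s1 <- sample_state_sequence(ntot, cfg$n_states, cfg$dwell_mean,
                                cfg$transition_stochasticity, cfg$sampling_rate)
    s2 <- sample_state_sequence(ntot, cfg$n_states, cfg$dwell_mean,
                                cfg$transition_stochasticity, cfg$sampling_rate)
    half <- seq_len(ceiling(cfg$n_states / 2))
    a <- as.numeric(s1 %in% half)        # excitatory-group envelope
    b <- as.numeric(s2 %in% half)        # independent second latent
    b_eff <- cfg$inhibition_scale * (1 - a) +
      (1 - cfg$inhibition_scale) * b

    active_idx <- sort(sample.int(nn, cfg$n_active))
    n_inh <- as.integer(round(cfg$neg_fraction * cfg$n_active))
    inh_idx <- active_idx[seq_len(n_inh)]
    exc_idx <- setdiff(active_idx, inh_idx)

    gains <- matrix(0, nn, cfg$n_states)
    gains[active_idx, ] <- matrix(runif(cfg$n_active * cfg$n_states, 0.5, 1.5),
                                  cfg$n_active, cfg$n_states)
    amp <- runif(nn, 0.8, 1.2)

    drive <- matrix(0, nn, ntot)
    # per-neuron private slow fluctuation (timescale tied to the state dwell:
    # aged dynamics are faster across the board), so within-group
    # correlations are strong but not degenerate (+1) and the trajectory
    # keeps moving between state transitions
    act_scale <- 2          # driven-group dF/F0 amplitude scale
    priv_kern <- calcium_kernel(cfg$dwell_mean / 6, cfg$dwell_mean / 1.5,
                                cfg$sampling_rate)
    priv <- function() convolve_causal(rnorm(ntot, 0, 1.5), priv_kern)
    for (i in exc_idx) {
      drive[i, ] <- pmax(0, act_scale * (amp[i] * gains[i, s1] * a + priv()))
    }
    for (i in inh_idx) {
      drive[i, ] <- pmax(0, act_scale * (amp[i] * gains[i, s2] * b_eff + priv()))
    }
    # background neurons sit near their ceiling with sparse dips toward zero:
    # modest ongoing activity whose observed minimum (the dF/F0 baseline)
    # is well below the awake level
    bg_idx <- setdiff(seq_len(nn), active_idx)
    for (i in bg_idx) {
      dips <- sample_quiescence_bouts(ntot, 0.5, 5, cfg$sampling_rate)
      gate <- rep(1, ntot)
      for (r in seq_len(nrow(dips))) gate[dips[r, 1L]:dips[r, 2L]] <- 0
      drive[i, ] <- cfg$background_drive * amp[i] * gate
    }

    kern <- calcium_kernel(cfg$kernel_rise, cfg$kernel_decay, cfg$sampling_rate)
    sig <- t(apply(drive, 1L, convolve_causal, kernel = kern))[, keep, drop = FALSE]
    s1 <- s1[keep]; s2 <- s2[keep]

    bouts <- sample_quiescence_bouts(nf, cfg$quiescence_rate,
                                     cfg$quiescence_dwell, cfg$sampling_rate)
    qframes <- rep(FALSE, nf)
    for (r in seq_len(nrow(bouts))) qframes[bouts[r, 1L]:bouts[r, 2L]] <- TRUE
    # quiescence gates the signal down to 5%, with a ~2 s exponential
    # entry/exit emulating the gradual onset of sleep-like bouts; the
    # planted truth is the frames where the gate actually suppresses the
    # signal below 12% of its awake level (deeply quiescent; entry takes
    # a few seconds, so brief bouts plant few or no truth frames)
    gate_target <- ifelse(qframes, 0.05, 1)
    lam <- exp(-1 / (2.0 * cfg$sampling_rate))
    qgate <- numeric(nf)
    prev <- 1
    for (tix in seq_len(nf)) {
      prev <- lam * prev + (1 - lam) * gate_target[tix]
      qgate[tix] <- prev
    }
    sig <- sweep(sig, 2L, qgate, "*")
    qframes <- qgate <= 0.12

    dff <- sig + matrix(rnorm(nn * nf, 0, cfg$hf_noise_sd), nn, nf)
    values <- pmax(cfg$baseline_f * (1 + dff), 0)
    traces <- calcium_traces(values, cfg$sampling_rate,
                             trial_id = sprintf("sim_seed%d", cfg$seed),
                             condition = "synthetic")
    truth <- structure(
      list(state_sequence = s1, state_sequence_alt = s2,
           active_idx = active_idx, excitatory_idx = exc_idx,
           inhibitory_idx = inh_idx, gains = gains,
           quiescence_bouts = bouts, quiescent_frames = qframes,
           noise_sd = cfg$hf_noise_sd, config = cfg),
      class = "synthetic_truth"
    )
    list(traces = traces, truth = truth)
  })
}

#' Generate a bistable single-neuron (AVA-style) trace with planted truth
#'
#' Concatenates tanh-shaped ON/OFF transitions into a binary-dynamics dF/F0
#' trace with known transition parameters, for recovery testing of the
#' kinetics pipeline. Bouts are placed deterministically (first onset after
#' `inter_bout` seconds, then alternating `bout_dwell` active and
#' `inter_bout` inactive); only the additive noise is random.
#'
#' @param n_bouts number of ON/OFF bout pairs.
#' @param tau_on,tau_off tanh time constants, seconds.
#' @param bout_dwell active-state duration (onset midpoint to offset
#'   midpoint), seconds.
#' @param inter_bout inactive gap between bouts, seconds.
#' @param amplitude transient amplitude, dF/F0 (default 1).
#' @param noise_sd additive Gaussian noise sd, dF/F0.
#' @param sampling_rate Hz (default 4, the confocal single-neuron rate).
#' @param duration trace length, seconds (default 600).
#' @param seed RNG seed (noise only).
#' @return list: `dff` (numeric vector), `time` (s), `truth` (data.frame of
#'   planted events: direction, t0, tau, amplitude, onset_frame,
#'   transition_time), `duty_ratio` (planted active fraction from 5%/95%
#'   crossings).
#' @export
generate_ava_trace <- function(n_bouts = 5L, tau_on = 1.0, tau_off = 2.0,
                               bout_dwell = 40, inter_bout = 60,
                               amplitude = 1.0, noise_sd = 0.05,
                               sampling_rate = 4, duration = 600,
                               seed = 1L) {
  period <- bout_dwell + inter_bout
  need <- inter_bout + n_bouts * period
  if (need > duration) stop("bouts do not fit within `duration`", call. = FALSE)
  if (bout_dwell <= 4 * (tau_on + tau_off)) {
    stop("bouts overlap: `bout_dwell` too short for the time constants",
         call. = FALSE)
  }
  nf <- as.integer(round(duration * sampling_rate))
  t <- (seq_len(nf) - 1L) / sampling_rate
  f <- numeric(nf)
  ev <- NULL
  for (k in seq_len(n_bouts)) {
    t_on <- inter_bout + (k - 1L) * period
    t_off <- t_on + bout_dwell
    f <- f + amplitude / 2 * (1 + tanh((t - t_on) / tau_on)) -
      amplitude / 2 * (1 + tanh((t - t_off) / tau_off))
    on_cross <- t_on - tau_on * atanh(0.9)   # ON 5% crossing
    # OFF 95% crossing: a/2*(1 - tanh((t-t0)/tau)) = 0.95a at t0 - tau*atanh(0.9)
    ev <- rbind(ev, data.frame(
      direction = c("on", "off"), t0 = c(t_on, t_off),
      tau = c(tau_on, tau_off), amplitude = amplitude,
      onset_frame = c(as.integer(ceiling(on_cross * sampling_rate)) + 1L,
                      as.integer(ceiling((t_off - tau_off * atanh(0.9)) *
                                           sampling_rate)) + 1L),
      transition_time = 2 * c(tau_on, tau_off) * atanh(0.9)))
  }
  # planted duty: ON onset (5% crossing) to OFF onset (95% crossing)
  on_onsets <- ev$onset_frame[ev$direction == "on"]
  off_onsets <- ev$onset_frame[ev$direction == "off"]
  duty <- sum(off_onsets - on_onsets) / sampling_rate / duration
  dff <- with_local_seed(seed, f + rnorm(nf, 0, noise_sd))
  list(dff = dff, time = t, truth = ev, duty_ratio = duty)
}
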