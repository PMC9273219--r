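#' Compute the per-worm metric row for one trial
#'
#' Runs the full multi-neuron pipeline (normalization, PSD and spectral
#' edge, top-neuron selection, TV differentiation, pairwise correlation
#' proportions, PCA angular-change mass, quiescence fraction) and/or the
#' single-neuron kinetics pipeline on one trial, returning one tidy row.
#' Metrics whose stage fails are set to NA (never silently zero) and the
#' cause recorded in the `errors` attribute.
#'
#' @param traces a [calcium_traces()] object.
#' @param kind `"multi"` (population trial) or `"single"` (AVA-style trial).
#' @param n_sel neurons entering the correlation analysis (default 40).
#' @param edge_q spectral-edge quantile (default 0.40).
#' @param angle_window_s angular-change half-window, seconds (default 3).
#' @param angle_low_deg threshold for the "low angle" mass (default 30).
#' @param psd_on `"dff"` (default) or `"derivative"`: signal the PSD is
#'   computed on.
#' @param tv_alpha,tv_iterations TV differentiation settings.
#' @return one-row [tibble::tibble()] with columns trial_id, condition,
#'   spectral_edge_40, neg_prop, pos_prop, time_in_quiescence, duty_ratio,
#'   mean_rise_time, mean_fall_time, ev1..ev5, angle_low_bin_mass.
#' @export
run_worm_metrics <- function(traces, kind = c("multi", "single"),
                             n_sel = 40L, edge_q = 0.40,
                             angle_window_s = 3, angle_low_deg = 30,
                             psd_on = c("dff", "derivative"),
                             tv_alpha = 0.05, tv_iterations = 100L) {
  kind <- match.arg(kind)
  psd_on <- match.arg(psd_on)
  row <- list(trial_id = traces$trial_id, condition = traces$condition,
              spectral_edge_40 = NA_real_, neg_prop = NA_real_,
              pos_prop = NA_real_, time_in_quiescence = NA_real_,
              duty_ratio = NA_real_, mean_rise_time = NA_real_,
              mean_fall_time = NA_real_,
              ev1 = NA_real_, ev2 = NA_real_, ev3 = NA_real_,
              ev4 = NA_real_, ev5 = NA_real_,
              angle_low_bin_mass = NA_real_)
  errors <- character()
  note <- function(stage, e) {
    errors <<- c(errors, sprintf("%s: %s", stage, conditionMessage(e)))
  }

  if (kind == "multi") {
    dff <- tryCatch(normalize_dff(traces, mode = "lowest_percentile"),
                    error = function(e) { note("normalize", e); NULL })
    if (!is.null(dff)) {
      tryCatch({
        psd_in <- if (psd_on == "dff") dff else
          tv_differentiate(dff, alpha = tv_alpha, iterations = tv_iterations)
        mp <- mean_normalized_psd(list(compute_psd(psd_in)))
        row$spectral_edge_40 <- spectral_edge(mp, q = edge_q)
      }, error = function(e) note("spectral", e))
      tryCatch({
        sel <- select_active_neurons(dff, n_sel = min(n_sel, nrow(dff$dff)))
        ddt_sel <- tv_differentiate(dff$dff[sel, , drop = FALSE],
                                    alpha = tv_alpha,
                                    iterations = tv_iterations,
                                    sampling_rate = dff$sampling_rate)
        pc <- pairwise_correlations(ddt_sel, seq_along(sel))
        props <- correlation_proportions(pc)
        row$neg_prop <- props$neg_prop
        row$pos_prop <- props$pos_prop
      }, error = function(e) note("correlation", e))
      tryCatch({
        traj <- run_pca(dff, k = 3L)
        ang <- angular_changes(traj, sampling_rate = dff$sampling_rate,
                               window_s = angle_window_s)
        a <- ang$angles[!is.na(ang$angles)]
        row$angle_low_bin_mass <- mean(a < angle_low_deg)
        ev <- traj$explained_var
        for (j in 1:5) row[[paste0("ev", j)]] <-
          if (j <= length(ev)) ev[j] else NA_real_
      }, error = function(e) note("states", e))
      tryCatch({
        qp <- quiescence_profile(dff)
        row$time_in_quiescence <- qp$time_in_quiescence
      }, error = function(e) note("quiescence", e))
    }
  } else {
    tryCatch({
      dff1 <- normalize_dff(traces, mode = "trace_mean")
      x <- dff1$dff[1L, ]
      events <- fit_all_transitions(x, traces$sampling_rate)
      ks <- summarize_kinetics(events, traces$duration, traces$sampling_rate)
      row$duty_ratio <- ks$duty_ratio
      row$mean_rise_time <- ks$mean_rise_time
      row$mean_fall_time <- ks$mean_fall_time
    }, error = function(e) note("kinetics", e))
  }
  out <- tibble::as_tibble(row)
  attr(out, "errors") <- errors
  out
}

#' Compare a metric across condition groups
#'
#' One-way ANOVA of one metric across groups, followed by all (or the
#' requested) pairwise contrasts with Sidak adjustment
#' \eqn{p_{adj} = 1 - (1 - p)^m} over the m contrasts performed. Pairwise
#' p-values come from t-tests using the pooled ANOVA residual variance, the
#' conventional post hoc companion to a one-way ANOVA.
#'
#' @param table tibble/data.frame of per-worm metric rows (one row per
#'   trial), with a `condition` column.
#' @param metric column name to compare.
#' @param groups condition labels to include (default: all present).
#' @param contrasts optional list of 2-vectors of group labels; default all
#'   pairs of `groups`.
#' @return list of class `group_comparison`: `metric`, `anova_F`, `anova_p`,
#'   `pairwise` (tibble: group_a, group_b, diff, p, p_adj), `group_means`
#'   (tibble: condition, n, mean, sem).
#' @export
compare_groups <- function(table, metric, groups = NULL, contrasts = NULL) {
  if (!metric %in% names(table)) stop("unknown metric: ", metric, call. = FALSE)
  dat <- data.frame(y = table[[metric]], g = as.character(table$condition))
  dat <- dat[!is.na(dat$y), ]
  groups <- groups %||% unique(dat$g)
  dat <- dat[dat$g %in% groups, ]
  dat$g <- factor(dat$g, levels = groups)
  counts <- tabulate(dat$g, nbins = length(groups))
  if (length(groups) < 2L || any(counts < 2L)) {
    stop("need >= 2 groups with >= 2 values of `", metric, "` each",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1L]]
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]

  if (is.null(contrasts)) {
    contrasts <- utils::combn(groups, 2L, simplify = FALSE)
  }
  m <- length(contrasts)
  pw <- lapply(contrasts, function(cp) {
    ya <- dat$y[dat$g == cp[1L]]; yb <- dat$y[dat$g == cp[2L]]
    se <- sqrt(mse * (1 / length(ya) + 1 / length(yb)))
    tstat <- (mean(ya) - mean(yb)) / se
    p <- 2 * stats::pt(-abs(tstat), df_res)
    tibble::tibble(group_a = cp[1L], group_b = cp[2L],
                   diff = mean(ya) - mean(yb), p = p,
                   p_adj = 1 - (1 - p)^m)
  })
  gm <- do.call(rbind, lapply(groups, function(g) {
    y <- dat$y[dat$g == g]
    tibble::tibble(condition = g, n = length(y), mean = mean(y),
                   sem = stats::sd(y) / sqrt(length(y)))
  }))
  structure(
    list(metric = metric,
         anova_F = an["g", "F value"], anova_p = an["g", "Pr(>F)"],
         pairwise = do.call(rbind, pw), group_means = gm),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F = %.3f, p = %.3g\n",
              x$metric, x$anova_F, x$anova_p))
  print(as.data.frame(x$pairwise), digits = 3)
  invisible(x)
}

#' Plain-text summary report of a metrics table
#'
#' Per-condition mean +/- SEM for each numeric metric, with the ANOVA +
#' Sidak comparison appended when more than one condition is present.
#'
#' @param table per-worm metrics tibble (rows from [run_worm_metrics()]).
#' @param metrics metric columns to report; default all numeric ones.
#' @param file optional path; when given the report is also written there.
#' @return character vector of report lines, invisibly when `file` given.
#' @export
render_report <- function(table, metrics = NULL, file = NULL) {
  if (nrow(table) == 0L) {
    lines <- c("wormdyn metrics report", "", "no data")
  } else {
    num_cols <- names(table)[vapply(table, is.numeric, TRUE)]
    metrics <- metrics %||% num_cols
    conds <- unique(table$condition)
    lines <- c("wormdyn metrics report",
               sprintf("%d trial(s), %d condition(s): %s", nrow(table),
                       length(conds), paste(conds, collapse = ", ")), "")
    for (mname in metrics) {
      vals_ok <- !is.na(table[[mname]])
      if (!any(vals_ok)) next
      lines <- c(lines, sprintf("## %s", mname))
      for (g in conds) {
        y <- table[[mname]][table$condition == g & vals_ok]
        if (length(y) == 0L) {
          lines <- c(lines, sprintf("  %s: no data", g))
        } else {
          lines <- c(lines, sprintf("  %s: %.4g +/- %.3g (n=%d)", g, mean(y),
                                    if (length(y) > 1) sd(y) / sqrt(length(y))
                                    else 0, length(y)))
        }
      }
      enough <- vapply(conds, function(g) {
        sum(table$condition == g & vals_ok) >= 2L
      }, TRUE)
      if (sum(enough) >= 2L) {
        cmp <- compare_groups(table[vals_ok, ], mname,
                              groups = conds[enough])
        lines <- c(lines, sprintf("  ANOVA F = %.3f, p = %.3g",
                                  cmp$anova_F, cmp$anova_p))
        lines <- c(lines, sprintf("    %s vs %s: diff = %+.4g, Sidak p = %.3g",
                                  cmp$pairwise$group_a, cmp$pairwise$group_b,
                                  cmp$pairwise$diff, cmp$pairwise$p_adj))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
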