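#' Difference in cumulative nSOC-derived emissions, amended vs control
#'
#' The priming statistic: at each common time point, `delta_abs =
#' mean_amended - mean_control`, with `se_diff = sqrt(se_amended^2 +
#' se_control^2)` (quadrature) and `percent = 100 * delta_abs /
#' mean_control` (percent change relative to the unamended treatment
#' mean). The confidence interval on the difference uses, by default, a
#' Welch-Satterthwaite t quantile, appropriate for the small replicate
#' numbers of incubation experiments (n = 4 jars); `conf = "z"` uses the
#' 1.96 normal quantile of figure-legend convention. `significant` flags
#' time points whose difference CI excludes zero; the stricter
#' non-overlap rule (the two treatments' own 95% CIs do not overlap) is
#' exposed as `significant_nonoverlap`. The percent-scale SE
#' (`percent_se`) uses the delta method for the ratio of means,
#' propagating control-mean uncertainty.
#'
#' @param summary_amended,summary_control [summarize_treatment()] outputs
#'   for one amended treatment and the matching unamended control of the
#'   same soil; both must cover the identical time grid (no silent
#'   interpolation).
#' @param conf `"welch"` (default) or `"z"`.
#' @return Tibble: soil, amendment, time_h, n_amended, n_control,
#'   mean_amended, mean_control, delta_abs, percent, se_diff, df,
#'   ci_low, ci_high, percent_se, percent_ci_low, percent_ci_high,
#'   significant, significant_nonoverlap.
#' @export
net_difference_series <- function(summary_amended, summary_control,
                                  conf = c("welch", "z")) {
  conf <- match.arg(conf)
  if (length(unique(summary_amended$soil)) != 1L ||
      length(unique(summary_control$soil)) != 1L ||
      summary_amended$soil[1] != summary_control$soil[1]) {
    stop("summaries must each cover exactly one, identical, soil")
  }
  if (!all(summary_control$amendment == "soil")) {
    stop("`summary_control` must be the unamended (\"soil\") treatment")
  }
  a <- dplyr::arrange(summary_amended, .data$time_h)
  c <- dplyr::arrange(summary_control, .data$time_h)
  if (nrow(a) != nrow(c) || !isTRUE(all.equal(a$time_h, c$time_h))) {
    stop("amended and control summaries are on different time grids")
  }
  delta <- a$mean - c$mean
  se_diff <- sqrt(a$se^2 + c$se^2)
  df <- se_diff^4 / (a$se^4 / (a$n - 1) + c$se^4 / (c$n - 1))
  df[!is.finite(df)] <- NA_real_
  # identical replicates give se 0 on both arms: treat as exact
  zero <- is.finite(se_diff) & se_diff == 0
  q <- if (conf == "z") rep(1.96, nrow(a)) else stats::qt(0.975, df)
  q[zero] <- 0
  pct_ok <- c$mean > 0
  percent <- ifelse(pct_ok, 100 * delta / c$mean, NA_real_)
  percent_se <- ifelse(pct_ok,
                       100 * sqrt(a$se^2 / c$mean^2 +
                                    a$mean^2 * c$se^2 / c$mean^4),
                       NA_real_)
  ci_low <- delta - q * se_diff
  ci_high <- delta + q * se_diff
  tibble::tibble(
    soil = a$soil, amendment = a$amendment, time_h = a$time_h,
    n_amended = a$n, n_control = c$n,
    mean_amended = a$mean, mean_control = c$mean,
    delta_abs = delta, percent = percent, se_diff = se_diff, df = df,
    ci_low = ci_low, ci_high = ci_high,
    percent_se = percent_se,
    percent_ci_low = percent - q * percent_se,
    percent_ci_high = percent + q * percent_se,
    significant = ci_low > 0 | ci_high < 0,
    significant_nonoverlap = a$ci_low > c$ci_high | a$ci_high < c$ci_low)
}

#' Priming estimates for every amended treatment in a summary
#'
#' Splits a [summarize_treatment()] table by soil, pairs each amended
#' treatment with that soil's unamended control, and applies
#' [net_difference_series()].
#'
#' @param summary A [summarize_treatment()] output covering controls and
#'   amended treatments.
#' @inheritParams net_difference_series
#' @return Row-bound tibble of [net_difference_series()] results.
#' @export
priming_estimates <- function(summary, conf = c("welch", "z")) {
  conf <- match.arg(conf)
  out <- list()
  for (s in unique(summary$soil)) {
    ss <- summary[summary$soil == s, ]
    ctrl <- ss[ss$amendment == "soil", ]
    if (nrow(ctrl) == 0L) stop("no control summary for soil \"", s, "\"")
    for (a in setdiff(unique(ss$amendment), "soil")) {
      out[[paste(s, a)]] <- net_difference_series(
        ss[ss$amendment == a, ], ctrl, conf = conf)
    }
  }
  dplyr::bind_rows(out)
}

#' Percent change in nSOC-derived emissions at a given day
#'
#' Returns, per (soil, amendment), the percent net change at the nearest
#' measured time point at or before `day`, together with the time
#' actually used.
#'
#' @param estimates Output of [priming_estimates()] /
#'   [net_difference_series()].
#' @param day Evaluation day; must fall within every series.
#' @return Tibble: soil, amendment, day_requested, time_h_used, percent,
#'   percent_defined, significant.
#' @export
percent_change_at <- function(estimates, day) {
  t_req <- day * 24
  one <- function(df) {
    if (t_req > max(df$time_h)) {
      stop("day ", day, " is beyond the end of the series for (",
           df$soil[1], ", ", df$amendment[1], ")")
    }
    ok <- df$time_h <= t_req
    if (!any(ok)) {
      stop("day ", day, " precedes the first measurement for (",
           df$soil[1], ", ", df$amendment[1], ")")
    }
    row <- df[df$time_h == max(df$time_h[ok]), ][1, ]
    tibble::tibble(soil = row$soil, amendment = row$amendment,
                   day_requested = day, time_h_used = row$time_h,
                   percent = row$percent,
                   percent_defined = is.finite(row$percent),
                   significant = row$significant)
  }
  key <- paste(estimates$soil, estimates$amendment)
  dplyr::bind_rows(lapply(split(estimates, key), one))
}

#' Compare estimated priming against simulator ground truth
#'
#' For each (soil, amendment, day) cell of the simulator's truth table,
#' reports the estimated percent change, the true percent, and whether
#' the percent-scale confidence interval covers the truth.
#'
#' @param estimates Output of [priming_estimates()].
#' @param truth The `truth` element of [simulate_incubation()] output (or
#'   its `priming` tibble).
#' @param days Days to assess (default: all days in the truth table that
#'   fall inside the estimate series).
#' @return Tibble: soil, amendment, day, percent_true, percent_est,
#'   ci_low, ci_high, covered.
#' @export
recover_truth <- function(estimates, truth, days = NULL) {
  pr <- if (is.data.frame(truth)) truth else truth$priming
  if (!is.null(days)) pr <- pr[pr$day %in% days, ]
  one <- function(i) {
    row <- pr[i, ]
    est <- estimates[estimates$soil == row$soil &
                       estimates$amendment == row$amendment, ]
    if (nrow(est) == 0L) {
      stop("no estimates for truth cell (", row$soil, ", ",
           row$amendment, ")")
    }
    at <- percent_change_at(est, row$day)
    e <- est[est$time_h == at$time_h_used, ]
    tibble::tibble(soil = row$soil, amendment = row$amendment,
                   day = row$day, percent_true = row$percent_true,
                   percent_est = e$percent,
                   ci_low = e$percent_ci_low, ci_high = e$percent_ci_high,
                   covered = e$percent_ci_low <= row$percent_true &
                     row$percent_true <= e$percent_ci_high)
  }
  dplyr::bind_rows(lapply(seq_len(nrow(pr)), one))
}
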