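#' Proportion of total looking time per AOI within a window
#'
#' PTLT divides the total looking time at each face AOI by the total looking
#' time at the whole face. Samples in the fourth zone (anywhere else,
#' including away from the screen) are excluded from the denominator: its
#' PTLT is zero by convention. The Eyes-Mouth preference score is
#' `PTLT_Eyes - PTLT_Mouth`.
#'
#' @param x Either a character vector of zone labels (`"Eyes"`, `"Mouth"`,
#'   `"RoF"`, `"Other"`, `"away"`) — one per time sample in the window — or
#'   a named numeric vector of per-zone dwell times.
#' @return A list with `ptlt_eyes`, `ptlt_mouth`, `ptlt_rof` (summing to 1
#'   when defined) and `preference` in \[-1, 1\]. All `NA` when the window
#'   contains no on-face time (a missing value, not zero).
#' @export
#' @examples
#' compute_ptlt(c(rep("Eyes", 2), rep("Mouth", 6), rep("RoF", 2)))
compute_ptlt <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (length(x) == 0L) stop("empty window", call. = FALSE)
    bad <- setdiff(unique(x), c(ZONES, "away"))
    if (length(bad) > 0)
      stop("unknown zone labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    dwell <- c(Eyes = sum(x == "Eyes"), Mouth = sum(x == "Mouth"),
               RoF = sum(x == "RoF"))
  } else if (is.numeric(x)) {
    if (is.null(names(x))) names(x) <- ZONES[seq_along(x)]
    dwell <- c(Eyes = unname(x["Eyes"]), Mouth = unname(x["Mouth"]),
               RoF = unname(x["RoF"]))
    dwell[is.na(dwell)] <- 0
    if (any(dwell < 0)) stop("dwell times must be non-negative",
                             call. = FALSE)
  } else {
    stop("x must be a zone-label vector or per-zone dwell times",
         call. = FALSE)
  }
  denom <- sum(dwell)
  if (denom <= 0)
    return(list(ptlt_eyes = NA_real_, ptlt_mouth = NA_real_,
                ptlt_rof = NA_real_, preference = NA_real_))
  p <- dwell / denom
  list(ptlt_eyes = unname(p["Eyes"]), ptlt_mouth = unname(p["Mouth"]),
       ptlt_rof = unname(p["RoF"]),
       preference = unname(p["Eyes"] - p["Mouth"]))
}

#' Baseline-correct preference scores against trial 1
#'
#' Rescales each later trial's Eyes-Mouth preference score relative to the
#' trial-1 score so that corrected scores stay in \[-1, 1\]:
#' `(EM_tn - EM_t1) / (1 - EM_t1)` when `EM_tn > EM_t1`, otherwise
#' `(EM_tn - EM_t1) / (1 + EM_t1)`. A positive corrected score indicates an
#' increased preference for the eyes relative to trial 1. The doubly
#' degenerate case `EM_t1 = EM_tn = -1` is defined as 0.
#'
#' @param raw_scores Numeric vector of raw preference scores (trials
#'   2..n), values in \[-1, 1\]; `NA` allowed.
#' @param trial1 The raw trial-1 preference score (the baseline).
#' @return Numeric vector of corrected scores, same length as `raw_scores`.
#' @export
#' @examples
#' baseline_correct(0.2, trial1 = -0.4)   # 0.6 / 1.4
#' baseline_correct(-0.5, trial1 = 0.5)   # -1.0 / 1.5
baseline_correct <- function(raw_scores, trial1) {
  stopifnot(is.numeric(raw_scores), is.numeric(trial1), length(trial1) == 1L)
  if (is.na(trial1)) return(rep(NA_real_, length(raw_scores)))
  ok <- !is.na(raw_scores)
  if (any(abs(raw_scores[ok]) > 1 + 1e-9) || abs(trial1) > 1 + 1e-9)
    stop("preference scores must lie in [-1, 1]", call. = FALSE)
  out <- rep(NA_real_, length(raw_scores))
  up <- ok & raw_scores > trial1
  dn <- ok & !up
  out[up] <- (raw_scores[up] - trial1) / (1 - trial1)
  out[dn] <- (raw_scores[dn] - trial1) / (1 + trial1)
  # EM_t1 = EM_tn = -1: 0/0 above; defined as "no change"
  out[ok & raw_scores == -1 & trial1 == -1] <- 0
  out
}

#' Per-trial preference scores from gaze records
#'
#' Computes, for every participant x condition x trial, the Eyes-Mouth
#' preference score (PTLT difference) within an analysis window. Works on
#' simulated trajectories ([simulate_experiment()]) and behavioral gaze
#' tables ([read_gaze_table()]) alike; both carry a `zone` or `aoi` column.
#'
#' @param records Data frame with columns `participant`, `condition`,
#'   `trial`, `step`, and `zone` (or `aoi`).
#' @param timeline A [trial_timeline()] defining the windows.
#' @param window `"anticipatory"` or `"detection"`.
#' @return Data frame with one row per participant x condition x trial:
#'   `participant`, `condition`, `trial`, `ptlt_eyes`, `ptlt_mouth`,
#'   `ptlt_rof`, `preference`, `window`.
#' @export
trajectory_scores <- function(records, timeline = trial_timeline(),
                              window = c("anticipatory", "detection")) {
  window <- match.arg(window)
  if (!("zone" %in% names(records)) && "aoi" %in% names(records))
    records$zone <- records$aoi
  need <- c("participant", "condition", "trial", "step", "zone")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  steps <- window_steps(timeline, window)
  sub <- records[records$step %in% steps, , drop = FALSE]
  keys <- unique(sub[, c("participant", "condition", "trial")])
  keys <- keys[order(keys$condition, keys$participant, keys$trial), ,
               drop = FALSE]
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- sub$participant == keys$participant[i] &
      sub$condition == keys$condition[i] & sub$trial == keys$trial[i]
    p <- compute_ptlt(sub$zone[sel])
    data.frame(keys[i, , drop = FALSE], ptlt_eyes = p$ptlt_eyes,
               ptlt_mouth = p$ptlt_mouth, ptlt_rof = p$ptlt_rof,
               preference = p$preference, window = window,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Group-mean score series
#'
#' Averages per-participant score series trial by trial over participants
#' with non-missing values; trials with no data stay missing.
#'
#' @param series Data frame with columns `participant`, `trial`, `score`.
#' @return Data frame with columns `trial`, `score` (one row per trial).
#' @export
group_mean_series <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0L)
    stop("empty score collection", call. = FALSE)
  stopifnot(all(c("trial", "score") %in% names(series)))
  trials <- sort(unique(series$trial))
  score <- vapply(trials, function(tr) {
    v <- series$score[series$trial == tr]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(trial = trials, score = score)
}

#' Baseline-corrected group score series per condition
#'
#' The learning-curve summary: raw per-trial preference scores are
#' baseline-corrected against trial 1 — per participant by default,
#' matching the behavioral analysis, or against the group-mean trial-1
#' score — and averaged across participants for trials 2..n.
#'
#' @param scores Output of [trajectory_scores()] (one condition or several).
#' @param baseline `"participant"` (default) or `"group"`.
#' @return Named list (one entry per condition) of data frames with
#'   columns `trial`, `score`.
#' @export
score_series <- function(scores, baseline = c("participant", "group")) {
  baseline <- match.arg(baseline)
  out <- list()
  for (cond in sort(unique(scores$condition))) {
    sc <- scores[scores$condition == cond, , drop = FALSE]
    if (baseline == "participant") {
      per <- lapply(unique(sc$participant), function(p) {
        s <- sc[sc$participant == p, , drop = FALSE]
        s <- s[order(s$trial), , drop = FALSE]
        t1 <- s$preference[s$trial == 1]
        t1 <- if (length(t1) == 0) NA_real_ else t1[1]
        later <- s[s$trial >= 2, , drop = FALSE]
        data.frame(participant = p, trial = later$trial,
                   score = baseline_correct(later$preference, t1),
                   stringsAsFactors = FALSE)
      })
      out[[cond]] <- group_mean_series(do.call(rbind, per))
    } else {
      gm <- group_mean_series(data.frame(participant = sc$participant,
                                         trial = sc$trial,
                                         score = sc$preference))
      t1 <- gm$score[gm$trial == 1]
      t1 <- if (length(t1) == 0) NA_real_ else t1[1]
      later <- gm[gm$trial >= 2, , drop = FALSE]
      out[[cond]] <- data.frame(trial = later$trial,
                                score = baseline_correct(later$score, t1))
    }
  }
  out
}

#' Linear-regression endpoints of a score series
#'
#' Ordinary least squares of score on trial number over trials 2..n; the
#' retained summary is the fitted value at the first and last trial of the
#' series (the start and end points of the learning curve).
#'
#' @param series Data frame with columns `trial`, `score` (missing trials
#'   are dropped).
#' @return An object of class `endpoint_summary`: list with `start`, `end`,
#'   `slope`, `intercept`, `start_trial`, `end_trial`.
#' @export
#' @examples
#' s <- data.frame(trial = 2:19, score = 0.01 * (2:19 - 2))
#' regression_endpoints(s)  # start 0, end 0.17
regression_endpoints <- function(series) {
  stopifnot(all(c("trial", "score") %in% names(series)))
  s <- series[!is.na(series$score), , drop = FALSE]
  if (nrow(s) < 2L)
    stop("at least 2 non-missing points are required for the regression",
         call. = FALSE)
  fit <- lm(score ~ trial, data = s)
  co <- coef(fit)
  start_trial <- min(s$trial); end_trial <- max(s$trial)
  structure(list(start = unname(co[1] + co[2] * start_trial),
                 end = unname(co[1] + co[2] * end_trial),
                 slope = unname(co[2]), intercept = unname(co[1]),
                 start_trial = start_trial, end_trial = end_trial),
            class = "endpoint_summary")
}

#' @export
print.endpoint_summary <- function(x, ...) {
  cat(sprintf("<endpoints start=%.4f (trial %d) end=%.4f (trial %d)>\n",
              x$start, x$start_trial, x$end, x$end_trial))
  invisible(x)
}

#' Mean squared error between simulated and observed endpoints
#'
#' The model-fit measure: the mean of squared differences between the
#' regression start and end points of simulated and measured learning
#' curves, over all conditions present (2 pairs for an ER-only group, 4 for
#' a two-condition group).
#'
#' @param sim,data Named lists (one [regression_endpoints()] summary per
#'   condition); the condition sets must match.
#' @return The MSE (non-negative scalar).
#' @export
mse_endpoints <- function(sim, data) {
  if (!setequal(names(sim), names(data)))
    stop("condition sets differ between simulation and data endpoints",
         call. = FALSE)
  d2 <- unlist(lapply(names(sim), function(cond) {
    c((sim[[cond]]$start - data[[cond]]$start)^2,
      (sim[[cond]]$end - data[[cond]]$end)^2)
  }))
  mean(d2)
}

#' Learning-curve endpoints of an experiment, per condition
#'
#' Convenience pipeline: per-trial anticipatory-window preference scores,
#' baseline correction, group averaging, and the endpoint regression — per
#' condition.
#'
#' @param records Simulated trajectories or behavioral gaze records.
#' @param timeline A [trial_timeline()].
#' @param window Analysis window (default anticipatory).
#' @param baseline Baseline-correction mode, see [score_series()].
#' @return Named list of `endpoint_summary` objects, one per condition.
#' @export
experiment_endpoints <- function(records, timeline = trial_timeline(),
                                 window = "anticipatory",
                                 baseline = "participant") {
  scores <- trajectory_scores(records, timeline, window)
  lapply(score_series(scores, baseline), regression_endpoints)
}

# ---- fast path used by the grid search (no data frames) ----

# Preference matrix (participants x trials) from raw nested trajectories.
pref_matrix_from_raw <- function(raw_cond, win_idx1) {
  n_part <- length(raw_cond)
  n_trials <- length(raw_cond[[1]])
  out <- matrix(NA_real_, n_part, n_trials)
  for (p in seq_len(n_part)) {
    for (tr in seq_len(n_trials)) {
      cnt <- tabulate(raw_cond[[p]][[tr]][win_idx1], nbins = N_ZONES)
      denom <- cnt[1] + cnt[2] + cnt[3]
      if (denom > 0) out[p, tr] <- (cnt[1] - cnt[2]) / denom
    }
  }
  out
}

# Baseline-corrected group series + endpoints from a preference matrix.
endpoints_from_pref <- function(pref, baseline = "participant") {
  n_trials <- ncol(pref)
  if (baseline == "participant") {
    bc <- do.call(rbind, lapply(seq_len(nrow(pref)), function(p)
      baseline_correct(pref[p, 2:n_trials], pref[p, 1])))
    score <- colMeans(bc, na.rm = TRUE)
    score[is.nan(score)] <- NA_real_
  } else {
    gm <- colMeans(pref, na.rm = TRUE)
    gm[is.nan(gm)] <- NA_real_
    score <- baseline_correct(gm[2:n_trials], gm[1])
  }
  regression_endpoints(data.frame(trial = 2:n_trials, score = score))
}
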