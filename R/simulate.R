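#' Discretized timeline of one trial
#'
#' Each trial is a speech event followed by a non-speech event (eyebrow
#' raise, ER, or lip protrusion, LP). Time is noted in normalized frames:
#' both events are discretized separately, by default into 100 steps of 1%
#' of the event's duration each, so trials of different real durations
#' align. The non-speech event starts at step `t_ER = n_speech_steps`. The
#' anticipatory analysis window is the last 50% of the speech event; the
#' detection window is the whole non-speech event.
#'
#' @param n_speech_steps,n_nonspeech_steps Steps per event (default 100).
#' @param condition `"ER"` or `"LP"`.
#' @param trial Trial index, 1-based.
#' @param speech_duration_ms,nonspeech_duration_ms Real event durations
#'   (defaults: 1800 ms mean sentence duration, 1880 ms fixed event
#'   duration).
#' @return An object of class `trial_timeline`.
#' @export
#' @examples
#' trial_timeline(condition = "ER", trial = 3)
trial_timeline <- function(n_speech_steps = 100L, n_nonspeech_steps = 100L,
                           condition = c("ER", "LP"), trial = 1L,
                           speech_duration_ms = 1800,
                           nonspeech_duration_ms = 1880) {
  condition <- match.arg(condition)
  n_speech_steps <- as.integer(n_speech_steps)
  n_nonspeech_steps <- as.integer(n_nonspeech_steps)
  stopifnot(n_speech_steps >= 2L, n_nonspeech_steps >= 1L, trial >= 1L)
  structure(list(
    n_speech_steps = n_speech_steps,
    n_nonspeech_steps = n_nonspeech_steps,
    n_steps = n_speech_steps + n_nonspeech_steps,
    t_ER = n_speech_steps,
    condition = condition,
    trial = as.integer(trial),
    speech_duration_ms = speech_duration_ms,
    nonspeech_duration_ms = nonspeech_duration_ms),
    class = "trial_timeline")
}

#' Analysis-window steps of a timeline
#'
#' @param timeline A [trial_timeline()].
#' @param window `"anticipatory"` (last 50% of the speech event) or
#'   `"detection"` (whole non-speech event).
#' @return Integer vector of 0-based step indices.
#' @export
window_steps <- function(timeline, window = c("anticipatory", "detection")) {
  window <- match.arg(window)
  if (window == "anticipatory") {
    from <- floor(timeline$n_speech_steps / 2)
    seq.int(from, timeline$n_speech_steps - 1L)
  } else {
    seq.int(timeline$t_ER, timeline$n_steps - 1L)
  }
}

#' Current gaze state
#'
#' @param position Current zone label or index.
#' @param memory A [memory_state()].
#' @return An object of class `gaze_state`.
#' @export
gaze_state <- function(position = "Eyes", memory = memory_state()) {
  structure(list(position = ZONES[zone_index(position)], memory = memory),
            class = "gaze_state")
}

#' Fused attraction distribution at one step
#'
#' Computes the product of the three component distributions at step `t`:
#' the top-down distribution of the trial, the bottom-up distribution from
#' the step's saliency means, and the inversion of the memory belief after
#' it has been diluted and has observed the current position.
#'
#' @param state A [gaze_state()] whose memory summarizes positions before
#'   the current one.
#' @param saliency_step List or stream row with `static` and `dynamic`
#'   per-zone means for step `t`.
#' @param t Time step (0-based).
#' @param timeline A [trial_timeline()].
#' @param params A [gaze_params()].
#' @param td_config A [topdown_config()].
#' @return A fused `zone_distribution`.
#' @export
fused_distribution <- function(state, saliency_step, t, timeline, params,
                               td_config) {
  stopifnot(t >= 0, t < timeline$n_steps)
  td <- top_down_distribution(t, timeline$trial, td_config, params,
                              timeline$t_ER)
  bu <- bottom_up_distribution(saliency_step$static, saliency_step$dynamic,
                               params$theta)
  post <- observe(dilute(state$memory, params$epsilon), state$position,
                  params$p_hit)
  distribution_product(td, bu, invert(post))
}

#' Draw the next gaze position from a fused distribution
#'
#' @param dist A normalized `zone_distribution`.
#' @return A zone label, sampled with R's random number generator (set the
#'   seed for reproducibility).
#' @export
draw_next_position <- function(dist) {
  p <- as.numeric(dist)
  u <- runif(1)
  ZONES[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
}

#' Simulate one trial
#'
#' Runs the full per-step loop: the gaze starts on the eyes with a uniform
#' memory belief; at every step the fused distribution is computed from the
#' trial's top-down distribution, the step's bottom-up saliency and the
#' inverted memory, the next position is drawn from it, and the memory
#' assimilates the draw (dilution then observation). Uses R's RNG; set the
#' seed for reproducibility.
#'
#' @param timeline A [trial_timeline()].
#' @param stream An `aoi_saliency_stream` with `timeline$n_steps` steps.
#' @param params A [gaze_params()].
#' @param td_config A [topdown_config()].
#' @return A `trajectory`: list with `zones` (character vector of length
#'   `n_steps`), `trial`, `condition`.
#' @export
#' @examples
#' tl <- trial_timeline(condition = "ER", trial = 2)
#' st <- aoi_saliency_stream(matrix(0.1, 200, 4), matrix(0.1, 200, 4))
#' set.seed(1)
#' tr <- simulate_trial(tl, st, gaze_params(),
#'                      topdown_config(learning_enabled = TRUE))
#' table(tr$zones)
simulate_trial <- function(timeline, stream, params,
                           td_config = topdown_config()) {
  if (stream$n_steps != timeline$n_steps)
    stop("saliency stream length (", stream$n_steps,
         ") does not match the timeline step count (", timeline$n_steps, ")",
         call. = FALSE)
  td <- topdown_matrix(timeline, td_config, params)
  bu <- bottom_up_matrix(stream, params$theta)
  idx <- .sim_trial_cpp(td, bu, params$epsilon, params$p_hit, 1L)
  structure(list(zones = ZONES[idx], trial = timeline$trial,
                 condition = timeline$condition),
            class = "gaze_trajectory")
}

#' Experiment protocol
#'
#' The default mirrors the behavioral design: 19 test trials per
#' participant, two between-participant conditions (eyebrow raise, ER, and
#' lip protrusion, LP), 20 virtual participants per condition. Top-down
#' learning is enabled only in the ER condition.
#'
#' @param n_trials Trials per participant (>= 2; baseline correction needs
#'   trial 1 plus at least one more).
#' @param conditions Subset of `c("ER", "LP")`.
#' @param n_virtual_participants Virtual participants per condition.
#' @param params A [gaze_params()].
#' @param timeline_template A [trial_timeline()] giving step counts and
#'   durations (its condition/trial fields are overridden per trial).
#' @param master_seed Integer master seed; per-trial seeds are derived from
#'   it deterministically.
#' @return An object of class `sim_protocol`.
#' @export
sim_protocol <- function(n_trials = 19L, conditions = c("ER", "LP"),
                         n_virtual_participants = 20L,
                         params = gaze_params(),
                         timeline_template = trial_timeline(),
                         master_seed = 1L) {
  conditions <- match.arg(conditions, c("ER", "LP"), several.ok = TRUE)
  n_trials <- as.integer(n_trials)
  if (n_trials < 2L)
    stop("n_trials must be >= 2", call. = FALSE)
  structure(list(n_trials = n_trials, conditions = conditions,
                 n_virtual_participants = as.integer(n_virtual_participants),
                 params = params, timeline_template = timeline_template,
                 master_seed = as.integer(master_seed)),
            class = "sim_protocol")
}

# Deterministic per-trial seed below 2^31, derived by a modular Horner hash
# of (master_seed, condition, participant, trial).
trial_seed <- function(master_seed, condition, participant, trial) {
  M <- 2147483647
  s <- as.numeric(master_seed) %% M
  for (k in c(match(condition, c("ER", "LP")), participant, trial))
    s <- (s * 69069 + k) %% M
  as.integer(s)
}

td_config_for <- function(condition) {
  topdown_config(learning_enabled = identical(condition, "ER"))
}

# Internal fast path: integer zone trajectories for every
# condition x participant x trial, without building data frames.
# Returns a nested list [[condition]][[participant]][[trial]] -> integer
# vector of zone indices.
simulate_experiment_raw <- function(protocol, streams) {
  missing_cond <- setdiff(protocol$conditions, names(streams))
  if (length(missing_cond) > 0)
    stop("no saliency stream for condition: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  tmpl <- protocol$timeline_template
  out <- list()
  for (cond in protocol$conditions) {
    stream <- streams[[cond]]
    if (stream$n_steps != tmpl$n_steps)
      stop("saliency stream length does not match the timeline", call. = FALSE)
    cfg <- td_config_for(cond)
    bu <- bottom_up_matrix(stream, protocol$params$theta)
    td_by_trial <- lapply(seq_len(protocol$n_trials), function(tr) {
      tl <- tmpl
      tl$condition <- cond
      tl$trial <- tr
      topdown_matrix(tl, cfg, protocol$params)
    })
    per_part <- vector("list", protocol$n_virtual_participants)
    for (p in seq_len(protocol$n_virtual_participants)) {
      per_trial <- vector("list", protocol$n_trials)
      for (tr in seq_len(protocol$n_trials)) {
        set.seed(trial_seed(protocol$master_seed, cond, p, tr))
        per_trial[[tr]] <- .sim_trial_cpp(td_by_trial[[tr]], bu,
                                          protocol$params$epsilon,
                                          protocol$params$p_hit, 1L)
      }
      per_part[[p]] <- per_trial
    }
    out[[cond]] <- per_part
  }
  out
}

#' Simulate a full experiment
#'
#' One trajectory per condition x virtual participant x trial. Per-trial
#' seeds are derived deterministically from `master_seed`, so a fixed seed
#' reproduces the whole experiment bit-exactly and the same seed schedule
#' can be reused across parameter settings (common random numbers).
#'
#' @param protocol A [sim_protocol()].
#' @param streams Named list of `aoi_saliency_stream`s, one per condition in
#'   the protocol.
#' @return A data frame with columns `participant`, `condition`, `trial`,
#'   `step` (0-based), `zone`.
#' @export
#' @examples
#' pr <- sim_protocol(n_trials = 3, conditions = "ER",
#'                    n_virtual_participants = 2, master_seed = 7)
#' st <- aoi_saliency_stream(matrix(0.1, 200, 4), matrix(0.1, 200, 4))
#' head(simulate_experiment(pr, list(ER = st)))
simulate_experiment <- function(protocol, streams) {
  raw <- simulate_experiment_raw(protocol, streams)
  n_steps <- protocol$timeline_template$n_steps
  rows <- list()
  k <- 1L
  for (cond in names(raw)) {
    for (p in seq_along(raw[[cond]])) {
      for (tr in seq_along(raw[[cond]][[p]])) {
        rows[[k]] <- data.frame(
          participant = sprintf("%s%02d", cond, p),
          condition = cond,
          trial = tr,
          step = 0:(n_steps - 1L),
          zone = ZONES[raw[[cond]][[p]][[tr]]],
          stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  do.call(rbind, rows)
}
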