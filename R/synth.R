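#' Default schematic-face AOI layout
#'
#' A 64 x 64 px schematic face: eyes and mouth rectangles inside a face
#' region, the remainder of the image being the `Other` zone.
#'
#' @return An [aoi_layout()].
#' @export
default_layout <- function() {
  aoi_layout(c(64, 64), eyes = c(16, 12, 48, 24),
             mouth = c(20, 36, 44, 48), face = c(8, 4, 56, 60))
}

#' Synthetic talking-face stimulus specification
#'
#' Describes one schematic stimulus: a speech event (mouth moving) followed
#' by a non-speech event — an eyebrow raise (ER, motion in the eyes region
#' only) or a lip protrusion (LP, motion in the mouth region only). Static
#' contrast is permanently high in the eyes region (sclera/pupil contrast).
#'
#' @param condition `"ER"` or `"LP"`.
#' @param speech_duration_ms Speech-event duration (default 1800 ms, the
#'   mean sentence duration; sentences range 1180-2200 ms).
#' @param nonspeech_duration_ms Non-speech-event duration (fixed 1880 ms).
#' @param fps Frame rate of the rendered sequence (default 25).
#' @param layout An [aoi_layout()].
#' @param mouth_motion Amplitude of mouth intensity modulation during
#'   speech (unitless contrast step).
#' @param event_motion Amplitude of the event-zone modulation during the
#'   non-speech event.
#' @param eye_contrast Static sclera/pupil contrast level in the eyes
#'   region.
#' @return An object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec("ER")
stimulus_spec <- function(condition = c("ER", "LP"),
                          speech_duration_ms = 1800,
                          nonspeech_duration_ms = 1880,
                          fps = 25,
                          layout = default_layout(),
                          mouth_motion = 0.4,
                          event_motion = 0.4,
                          eye_contrast = 0.8) {
  condition <- match.arg(condition)
  stopifnot(speech_duration_ms > 0, nonspeech_duration_ms > 0, fps > 0,
            mouth_motion >= 0, event_motion >= 0,
            eye_contrast >= 0, eye_contrast <= 1)
  structure(list(condition = condition,
                 speech_duration_ms = speech_duration_ms,
                 nonspeech_duration_ms = nonspeech_duration_ms,
                 fps = fps, layout = layout,
                 mouth_motion = mouth_motion, event_motion = event_motion,
                 eye_contrast = eye_contrast),
            class = "stimulus_spec")
}

fill_rect <- function(img, rect, value) {
  # rect is 0-based half-open c(x0, y0, x1, y1); img indexed [y+1, x+1]
  ys <- (rect[2] + 1):rect[4]
  xs <- (rect[1] + 1):rect[3]
  img[ys, xs] <- value
  img
}

# Static base face: background, face fill, sclera patches with dark pupils,
# closed mouth.
base_face <- function(spec) {
  lay <- spec$layout
  w <- lay$image_size[1]; h <- lay$image_size[2]
  img <- matrix(0.2, h, w)
  img <- fill_rect(img, lay$face, 0.55)
  e <- lay$eyes
  ew <- (e[3] - e[1]) / 2
  sclera <- 0.5 + spec$eye_contrast / 2
  pupil <- 0.5 - spec$eye_contrast / 2
  left <- c(e[1] + ew * 0.15, e[2] + 2, e[1] + ew * 0.85, e[4] - 2)
  right <- c(e[1] + ew * 1.15, e[2] + 2, e[1] + ew * 1.85, e[4] - 2)
  for (r in list(left, right)) {
    r <- round(r)
    img <- fill_rect(img, r, sclera)
    cx <- floor((r[1] + r[3]) / 2); cy <- floor((r[2] + r[4]) / 2)
    img <- fill_rect(img, c(cx - 1, cy - 1, cx + 1, cy + 1), pupil)
  }
  m <- lay$mouth
  lip <- round(c(m[1] + 2, (m[2] + m[4]) / 2 - 2, m[3] - 2,
                 (m[2] + m[4]) / 2 + 2))
  img <- fill_rect(img, lip, 0.3)
  img
}

#' Render schematic talking-face frames
#'
#' Produces `round(fps * duration / 1000)` gray frames per event. During the
#' speech event the inner mouth oscillates in intensity (articulation);
#' during the non-speech event the eyes region (ER: a brow band above the
#' eyes) or the mouth region (LP) oscillates, and the speech articulation
#' stops. Eye contrast is static and permanent.
#'
#' @param spec A [stimulus_spec()].
#' @return List of gray matrices in \[0, 1\] (class `stimulus_frames`,
#'   with attributes `n_speech_frames` and `n_event_frames`).
#' @export
#' @examples
#' fr <- make_stimulus_frames(stimulus_spec("ER"))
#' length(fr)  # 45 speech + 47 event frames = 92
make_stimulus_frames <- function(spec) {
  lay <- spec$layout
  n_speech <- round(spec$fps * spec$speech_duration_ms / 1000)
  n_event <- round(spec$fps * spec$nonspeech_duration_ms / 1000)
  base <- base_face(spec)
  m <- lay$mouth
  inner <- round(c(m[1] + 3, m[2] + 3, m[3] - 3, m[4] - 3))
  e <- lay$eyes
  brow <- round(c(e[1] + 2, e[2] + 1, e[3] - 2, e[2] + 3))
  osc <- function(i, period = 8) 0.5 * (1 + sin(2 * pi * i / period))
  frames <- vector("list", n_speech + n_event)
  for (i in seq_len(n_speech)) {
    img <- base
    img <- fill_rect(img, inner, 0.3 + spec$mouth_motion * osc(i))
    frames[[i]] <- img
  }
  for (i in seq_len(n_event)) {
    img <- base
    if (spec$condition == "ER") {
      img <- fill_rect(img, brow, 0.55 - spec$event_motion * osc(i))
    } else {
      img <- fill_rect(img, inner, 0.3 + spec$event_motion * osc(i))
    }
    frames[[n_speech + i]] <- img
  }
  structure(frames, class = "stimulus_frames",
            n_speech_frames = n_speech, n_event_frames = n_event)
}

#' Analytic per-zone saliency streams for a synthetic stimulus
#'
#' Fast path bypassing pixel rendering: per-zone static and dynamic
#' saliency means with the same structure the pixel path produces — static
#' mass concentrated on the eyes (permanent contrast), dynamic mass on the
#' mouth during speech steps, and on the event zone (eyes for ER, mouth for
#' LP) during non-speech steps. Magnitudes follow the spec amplitudes; all
#' zones keep a small floor so no zone is ever strictly impossible.
#'
#' @param spec A [stimulus_spec()].
#' @param timeline A [trial_timeline()] giving the step counts.
#' @return An `aoi_saliency_stream` of `timeline$n_steps` steps.
#' @export
make_saliency_streams <- function(spec, timeline = trial_timeline()) {
  n <- timeline$n_steps
  ns <- timeline$n_speech_steps
  floor_s <- 0.01
  st <- matrix(floor_s, n, N_ZONES)
  st[, 1] <- spec$eye_contrast
  st[, 4] <- floor_s / 2
  dy <- matrix(floor_s / 2, n, N_ZONES)
  speech <- seq_len(ns)
  event <- (ns + 1):n
  dy[speech, 2] <- spec$mouth_motion
  if (spec$condition == "ER") {
    dy[event, 1] <- spec$event_motion
  } else {
    dy[event, 2] <- spec$event_motion
  }
  aoi_saliency_stream(st, dy)
}

#' Generate a synthetic behavioral gaze dataset
#'
#' Stands in for undeposited infant eye-tracking data: simulates the full
#' experiment under `generating_params`, converts the trajectories to the
#' behavioral gaze-record format, and independently replaces each sample by
#' an off-face `"away"` record with probability `lapse_rate`, emulating
#' looks away from the screen (excluded later by the PTLT convention).
#'
#' @param protocol A [sim_protocol()]; its `master_seed` drives all
#'   randomness.
#' @param generating_params A [gaze_params()] used for the simulation.
#' @param lapse_rate Per-sample probability of an away look, in \[0, 0.5\].
#' @param specs Named list of [stimulus_spec()]s per condition (defaults to
#'   the standard schematic stimuli).
#' @param group Group label stored in the records (default `"SYN"`,
#'   marking the dataset as synthetic).
#' @return Data frame with columns `participant`, `group`, `condition`,
#'   `trial`, `step`, `aoi`.
#' @export
make_behavioral_dataset <- function(protocol, generating_params,
                                    lapse_rate = 0.1, specs = NULL,
                                    group = "SYN") {
  if (!is.numeric(lapse_rate) || lapse_rate < 0 || lapse_rate > 0.5)
    stop("lapse_rate must lie in [0, 0.5]", call. = FALSE)
  if (is.null(specs))
    specs <- setNames(lapply(protocol$conditions, stimulus_spec),
                      protocol$conditions)
  streams <- lapply(specs, make_saliency_streams,
                    timeline = protocol$timeline_template)
  pr <- protocol
  pr$params <- generating_params
  traj <- simulate_experiment(pr, streams)
  aoi <- traj$zone
  if (lapse_rate > 0) {
    set.seed(trial_seed(protocol$master_seed, "LP", 999999L, 777L))
    lapse <- runif(nrow(traj)) < lapse_rate
    aoi[lapse] <- "away"
  }
  data.frame(participant = paste0(group, "_", traj$participant),
             group = group, condition = traj$condition, trial = traj$trial,
             step = traj$step, aoi = aoi, stringsAsFactors = FALSE)
}
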