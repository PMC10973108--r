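#' Top-down component configuration
#'
#' The top-down component encodes task knowledge: a base preference for the
#' eyes and mouth of the talker, and — when learning is enabled — an
#' anticipatory boost of the eyes zone that grows with exposure to the
#' eyebrow-raise event. Learning is enabled only for the eyebrow-raise (ER)
#' condition; the lip-protrusion (LP) condition keeps the static priors
#' throughout.
#'
#' @param base_priors Zone distribution of base preferences. Default
#'   (0.45, 0.45, 0.05, 0.05): eyes and mouth equally favoured, little mass
#'   on the rest of the face or elsewhere.
#' @param learning_enabled Logical; `TRUE` for the eyebrow-raise condition.
#' @param exposure_rule How the exposure count T entering the learning and
#'   anticipation formulas relates to the trial index: `"previous"`
#'   (default) counts completed trials, `T = trial - 1`, so trial 1 shows no
#'   learning; `"index"` uses `T = trial` (sensitivity-check variant).
#' @return An object of class `topdown_config`.
#' @export
#' @examples
#' topdown_config(learning_enabled = TRUE)
topdown_config <- function(base_priors = zone_distribution(
                             c(0.45, 0.45, 0.05, 0.05), "top_down"),
                           learning_enabled = FALSE,
                           exposure_rule = c("previous", "index")) {
  exposure_rule <- match.arg(exposure_rule)
  if (!inherits(base_priors, "zone_distribution"))
    base_priors <- zone_distribution(base_priors, "top_down")
  stopifnot(is.logical(learning_enabled), length(learning_enabled) == 1L)
  structure(list(base_priors = base_priors,
                 learning_enabled = learning_enabled,
                 exposure_rule = exposure_rule),
            class = "topdown_config")
}

n_exposures <- function(trial, config) {
  if (config$exposure_rule == "previous") trial - 1L else trial
}

#' Learned (unnormalized) eyes mass after repeated exposures
#'
#' The result of anticipatory learning is modelled directly: after `exposures`
#' presentations of the eyebrow-raise event, the eyes-zone mass becomes
#' `(beta * exposures + 1) * p_eyes`. This is a mass, not a probability — it
#' may exceed 1 and is re-normalized inside [top_down_distribution()].
#'
#' @param beta Learning strength (>= 0).
#' @param exposures Number of prior exposures (>= 0).
#' @param p_eyes Base eyes prior (default 0.45).
#' @return The unnormalized learned eyes mass.
#' @export
#' @examples
#' learned_eyes_mass(5, 1)     # 2.7
#' learned_eyes_mass(0.1, 18)  # 1.26
learned_eyes_mass <- function(beta, exposures, p_eyes = 0.45) {
  if (!is.numeric(beta) || any(beta < 0) || any(!is.finite(beta)))
    stop("beta must be non-negative", call. = FALSE)
  if (!is.numeric(exposures) || any(exposures < 0))
    stop("exposures must be non-negative", call. = FALSE)
  (beta * exposures + 1) * p_eyes
}

#' Onset time of the anticipatory switch
#'
#' The learned eyes preference switches on at `t_a = t_ER - gamma * exposures`
#' (floored at the trial start): with `gamma = 0` the boost only starts at
#' the non-speech event onset `t_ER`; larger `gamma` moves the switch
#' earlier by `gamma` steps per exposure, producing anticipation.
#'
#' @param t_ER Time step of the non-speech event onset.
#' @param gamma Anticipation speed (steps per exposure, >= 0).
#' @param exposures Number of prior exposures (>= 0).
#' @return The onset step `t_a` (>= 0).
#' @export
#' @examples
#' anticipation_onset(100, 1.5, 10)  # 85
#' anticipation_onset(100, 2, 60)    # 0 (clamped at trial start)
anticipation_onset <- function(t_ER, gamma, exposures) {
  if (!is.numeric(gamma) || any(gamma < 0) || any(!is.finite(gamma)))
    stop("gamma must be non-negative", call. = FALSE)
  if (!is.numeric(exposures) || any(exposures < 0))
    stop("exposures must be non-negative", call. = FALSE)
  pmax(0, t_ER - gamma * exposures)
}

#' Top-down distribution at a given step of a given trial
#'
#' Before the anticipation onset (or whenever learning is disabled) the base
#' priors apply. From the onset on, the eyes mass is replaced by the learned
#' mass and the four masses are re-normalized.
#'
#' @param t Time step within the trial (0-based).
#' @param trial Trial index (1-based).
#' @param config A [topdown_config()].
#' @param params A [gaze_params()] (beta and gamma are used).
#' @param t_ER Time step of the non-speech event onset.
#' @return A `zone_distribution` with role `"top_down"`.
#' @export
#' @examples
#' cfg <- topdown_config(learning_enabled = TRUE)
#' p <- gaze_params(beta = 5, gamma = 0)
#' top_down_distribution(150, 2, cfg, p, t_ER = 100)
top_down_distribution <- function(t, trial, config, params, t_ER) {
  stopifnot(trial >= 1)
  base <- as.numeric(config$base_priors)
  if (!config$learning_enabled)
    return(zone_distribution(base, "top_down"))
  expos <- n_exposures(trial, config)
  t_a <- anticipation_onset(t_ER, params$gamma, expos)
  if (t < t_a)
    return(zone_distribution(base, "top_down"))
  masses <- base
  masses[1L] <- learned_eyes_mass(params$beta, expos, p_eyes = base[1L])
  normalize(masses, role = "top_down")
}

# Per-trial top-down matrix (n_steps x 4), rows = steps 0..n-1.
# Vectorized version of top_down_distribution for the simulator.
topdown_matrix <- function(timeline, config, params) {
  n <- timeline$n_steps
  base <- as.numeric(config$base_priors)
  out <- matrix(base, nrow = n, ncol = N_ZONES, byrow = TRUE)
  if (config$learning_enabled) {
    expos <- n_exposures(timeline$trial, config)
    t_a <- anticipation_onset(timeline$t_ER, params$gamma, expos)
    steps <- 0:(n - 1L)
    on <- steps >= t_a
    if (any(on)) {
      m <- base
      m[1L] <- learned_eyes_mass(params$beta, expos, p_eyes = base[1L])
      out[on, ] <- matrix(m / sum(m), nrow = sum(on), ncol = N_ZONES,
                          byrow = TRUE)
    }
  }
  out
}
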