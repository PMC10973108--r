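#' @useDynLib gazesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef predict runif rbinom sd setNames
#' @importFrom utils read.delim write.table head
NULL

# Canonical zone order used everywhere: Eyes, Mouth, RoF (rest of face),
# Other (rest of the image / away from the face).
ZONES <- c("Eyes", "Mouth", "RoF", "Other")
N_ZONES <- 4L

#' Zone labels of the talking-face decomposition
#'
#' The visual scene is decomposed into four areas of interest (AOIs): the
#' eyes, the mouth, the rest of the face (`RoF`), and everything else
#' (`Other`). All probability vectors in the package are ordered this way.
#'
#' @return Character vector of the four zone labels, in canonical order.
#' @export
#' @examples
#' zones()
zones <- function() ZONES

#' Map a zone label or index to its canonical integer index
#'
#' @param zone A zone label (e.g. `"Eyes"`) or an integer index in 1..4.
#' @return Integer index in 1..4.
#' @export
zone_index <- function(zone) {
  if (is.numeric(zone)) {
    idx <- as.integer(zone)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > N_ZONES))
      stop("zone index must be in 1..4", call. = FALSE)
    return(idx)
  }
  idx <- match(as.character(zone), ZONES)
  if (any(is.na(idx)))
    stop("unknown zone label: ", paste(setdiff(zone, ZONES), collapse = ", "),
         call. = FALSE)
  idx
}

DIST_ROLES <- c("bottom_up", "top_down", "memory_inverted", "fused", "history")

#' Construct a probability distribution over the four zones
#'
#' A `zone_distribution` is a length-4 non-negative numeric vector summing to
#' one, tagged with the model component it came from (`role`): bottom-up
#' saliency, top-down task knowledge, inverted selection-history memory, the
#' fused product of the three, or the raw selection-history belief.
#'
#' @param probs Numeric vector of 4 non-negative probabilities summing to 1
#'   (within 1e-9).
#' @param role One of `"bottom_up"`, `"top_down"`, `"memory_inverted"`,
#'   `"fused"`, `"history"`.
#' @return An object of class `zone_distribution`: a named numeric vector
#'   with a `role` attribute.
#' @export
#' @examples
#' zone_distribution(c(0.45, 0.45, 0.05, 0.05), "top_down")
zone_distribution <- function(probs, role = "fused") {
  role <- match.arg(role, DIST_ROLES)
  probs <- as.numeric(probs)
  if (length(probs) != N_ZONES)
    stop("a zone distribution has exactly 4 entries", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1 + 1e-9))
    stop("zone probabilities must be finite and in [0, 1]", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("zone probabilities must sum to 1 (got ", format(sum(probs)), ")",
         call. = FALSE)
  structure(setNames(probs / sum(probs), ZONES),
            role = role, class = "zone_distribution")
}

#' @export
print.zone_distribution <- function(x, ...) {
  cat("<zone_distribution role=", attr(x, "role"), ">\n", sep = "")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Normalize non-negative masses into a zone distribution
#'
#' @param masses Numeric vector of 4 non-negative masses, at least one
#'   positive.
#' @param role Role tag passed to [zone_distribution()].
#' @return A `zone_distribution`.
#' @export
#' @examples
#' normalize(c(2.7, 0.45, 0.05, 0.05), "top_down")
normalize <- function(masses, role = "fused") {
  masses <- as.numeric(masses)
  if (length(masses) != N_ZONES)
    stop("expected 4 masses", call. = FALSE)
  if (any(!is.finite(masses)) || any(masses < 0))
    stop("masses must be finite and non-negative", call. = FALSE)
  s <- sum(masses)
  if (s <= 0)
    stop("cannot normalize all-zero masses", call. = FALSE)
  zone_distribution(masses / s, role = role)
}

#' Fuse component distributions by multiplication
#'
#' The combination step of the model: the bottom-up, top-down and
#' memory-inverted distributions are multiplied elementwise and
#' re-normalized, yielding the fused attraction over zones from which the
#' next gaze position is drawn. The operation is commutative in its
#' arguments; a uniform factor is an identity.
#'
#' @param a,b,c Zone distributions (any roles).
#' @return A `zone_distribution` with role `"fused"`.
#' @export
#' @examples
#' u <- zone_distribution(rep(0.25, 4))
#' td <- zone_distribution(c(0.45, 0.45, 0.05, 0.05), "top_down")
#' distribution_product(td, u, u)  # uniform factors pass td through
distribution_product <- function(a, b, c) {
  m <- as.numeric(a) * as.numeric(b) * as.numeric(c)
  if (sum(m) <= 0)
    stop("degenerate fusion: component distributions have disjoint supports",
         call. = FALSE)
  normalize(m, role = "fused")
}

#' Model parameters
#'
#' Bundles the three free parameters explored by the grid search with the
#' two fixed memory constants.
#'
#' @param beta Strength of top-down learning (>= 0). Scales how fast the
#'   learned preference for the event zone grows across trials.
#' @param gamma Speed of anticipation (>= 0), in normalized time steps per
#'   trial of exposure: how far before the non-speech event onset the
#'   learned preference switches on.
#' @param theta Weight of the static saliency map in the bottom-up mixture,
#'   in \[0, 1\]. 1 = static contrast only (eyes); 0 = motion only.
#' @param epsilon Memory dilution leak per step, in (0, 0.25). Each step,
#'   probability mass leaks uniformly to the other zones so the
#'   selection-history belief decays back to uniform.
#' @param p_hit Observation-model probability assigned to the currently
#'   viewed zone, in (0.25, 1\]. Values near 0.25 make the observation
#'   uninformative.
#' @return An object of class `gaze_params`.
#' @export
#' @examples
#' gaze_params(beta = 2, gamma = 1, theta = 0.25)
gaze_params <- function(beta = 1, gamma = 1, theta = 0.25,
                        epsilon = 0.05, p_hit = 0.9) {
  stopifnot(is.numeric(beta), length(beta) == 1L,
            is.numeric(gamma), length(gamma) == 1L,
            is.numeric(theta), length(theta) == 1L)
  if (!is.finite(beta) || beta < 0)
    stop("beta must be a non-negative real", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0)
    stop("gamma must be a non-negative real", call. = FALSE)
  if (!is.finite(theta) || theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1 / N_ZONES)
    stop("epsilon must lie in (0, 0.25)", call. = FALSE)
  if (!is.finite(p_hit) || p_hit <= 1 / N_ZONES || p_hit > 1)
    stop("p_hit must lie in (0.25, 1]", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, theta = theta,
                 epsilon = epsilon, p_hit = p_hit),
            class = "gaze_params")
}

#' @export
print.gaze_params <- function(x, ...) {
  cat(sprintf(
    "<gaze_params beta=%g gamma=%g theta=%g epsilon=%g p_hit=%g>\n",
    x$beta, x$gamma, x$theta, x$epsilon, x$p_hit))
  invisible(x)
}

#' Fixed inference settings (coherence-variable switches)
#'
#' The model's three coherence variables are fixed: the two combination
#' switches are closed (`lambda_BU = 1`, `lambda_TD = 1`), so the bottom-up
#' and top-down distributions multiply into the fusion, and the memory
#' switch is open (`lambda_IJ = 0`), which turns the selection-history
#' belief into its inversion (recently visited zones become unattractive).
#' Any other setting is rejected: the model is only defined for this
#' configuration.
#'
#' @param lambda_IJ,lambda_BU,lambda_TD Must equal 0, 1 and 1 respectively.
#' @return A list with the three settings.
#' @export
inference_settings <- function(lambda_IJ = 0L, lambda_BU = 1L,
                               lambda_TD = 1L) {
  if (!identical(as.integer(lambda_IJ), 0L) ||
      !identical(as.integer(lambda_BU), 1L) ||
      !identical(as.integer(lambda_TD), 1L))
    stop("the model is defined only for lambda_IJ = 0, lambda_BU = 1, ",
         "lambda_TD = 1", call. = FALSE)
  list(lambda_IJ = 0L, lambda_BU = 1L, lambda_TD = 1L)
}
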