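#' Selection-history memory state
#'
#' The memory component tracks a belief over which zones were recently
#' visually processed. It is a probability distribution over the four zones,
#' updated each step by dilution (uniform leak toward the resting uniform
#' state) and a Bayes observation step that raises the probability of the
#' zone currently viewed.
#'
#' @param belief Numeric vector of 4 non-negative probabilities summing to 1.
#'   Default: uniform (the resting state, also the start of every trial).
#' @return An object of class `memory_state`.
#' @export
#' @examples
#' memory_state()
memory_state <- function(belief = rep(1 / 4, 4)) {
  belief <- as.numeric(belief)
  if (length(belief) != N_ZONES || any(!is.finite(belief)) || any(belief < 0))
    stop("belief must be 4 finite non-negative numbers", call. = FALSE)
  if (abs(sum(belief) - 1) > 1e-9)
    stop("belief must sum to 1", call. = FALSE)
  structure(setNames(belief / sum(belief), ZONES), class = "memory_state")
}

#' @export
print.memory_state <- function(x, ...) {
  cat("<memory_state>\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Dilute the memory belief toward uniform
#'
#' Applies the temporal model of the selection history: each step a small
#' probability `epsilon` leaks from every zone to each other zone (transition
#' matrix with diagonal `1 - 3 * epsilon`, off-diagonal `epsilon`). Without
#' observations, repeated dilution decays the belief back to its uniform
#' resting state.
#'
#' @param state A [memory_state()].
#' @param epsilon Leak per step, in (0, 0.25).
#' @return The diluted `memory_state`.
#' @export
#' @examples
#' dilute(memory_state(c(1, 0, 0, 0)), 0.05)  # (0.85, 0.05, 0.05, 0.05)
dilute <- function(state, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon >= 1 / N_ZONES)
    stop("epsilon must lie in (0, 0.25)", call. = FALSE)
  b <- as.numeric(state)
  # M b with M = (1 - 4 eps) I + eps 11'; b sums to 1
  b <- (1 - N_ZONES * epsilon) * b + epsilon
  memory_state(b / sum(b))
}

#' Assimilate the currently viewed zone into the memory belief
#'
#' The observation model assigns probability `p_hit` to the viewed zone and
#' `(1 - p_hit) / 3` to each other zone; the belief is multiplied by this
#' likelihood and re-normalized, so the viewed zone's recency probability
#' increases.
#'
#' @param state A [memory_state()].
#' @param viewed Zone label or index of the current gaze position.
#' @param p_hit Probability the observation assigns to the viewed zone,
#'   in (0.25, 1\].
#' @return The updated `memory_state`.
#' @export
#' @examples
#' observe(memory_state(), "Eyes", 0.9)  # (0.9, 1/30, 1/30, 1/30)
observe <- function(state, viewed, p_hit) {
  if (!is.numeric(p_hit) || length(p_hit) != 1L || !is.finite(p_hit) ||
      p_hit <= 1 / N_ZONES || p_hit > 1)
    stop("p_hit must lie in (0.25, 1]", call. = FALSE)
  i <- zone_index(viewed)
  lik <- rep((1 - p_hit) / (N_ZONES - 1), N_ZONES)
  lik[i] <- p_hit
  b <- as.numeric(state) * lik
  memory_state(b / sum(b))
}

#' Invert the memory belief into a zones-to-visit distribution
#'
#' Recently visited zones should be avoided, so the selection-history belief
#' is inverted: entry i of the output is `(1 - belief_i) / 3`. The output
#' sums to one by construction (for four zones the complements sum to 3) and
#' reverses the order of the input: the most recently visited zone becomes
#' the least attractive.
#'
#' @param state A [memory_state()].
#' @return A `zone_distribution` with role `"memory_inverted"`.
#' @export
#' @examples
#' invert(memory_state(c(1, 0, 0, 0)))  # (0, 1/3, 1/3, 1/3)
invert <- function(state) {
  b <- as.numeric(state)
  zone_distribution((1 - b) / (N_ZONES - 1), role = "memory_inverted")
}
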