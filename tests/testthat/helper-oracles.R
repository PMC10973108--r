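# Independent brute-force oracles and shared fixtures for the test suite.

uniform_dist <- function(role = "fused")
  zone_distribution(rep(0.25, 4), role)

random_dist <- function(role = "fused") {
  m <- runif(4, min = 0.01, max = 1)
  zone_distribution(m / sum(m), role)
}

random_belief <- function() {
  m <- runif(4, min = 0.001, max = 1)
  memory_state(m / sum(m))
}

# Enumerate-multiply-normalize oracle for the three-way fusion.
oracle_product <- function(a, b, c) {
  p <- as.numeric(a) * as.numeric(b) * as.numeric(c)
  p / sum(p)
}

# Full-joint oracle for one memory filter step (dilute then observe):
# builds the 4x4 joint over (previous zone, current zone), applies the
# observation likelihood of the viewed zone, and marginalizes.
oracle_filter_step <- function(belief, epsilon, viewed_idx, p_hit) {
  z <- 4
  M <- matrix(epsilon, z, z)
  diag(M) <- 1 - (z - 1) * epsilon
  joint <- matrix(0, z, z)
  for (i in seq_len(z))
    for (j in seq_len(z))
      joint[i, j] <- belief[i] * M[i, j]
  lik <- rep((1 - p_hit) / (z - 1), z)
  lik[viewed_idx] <- p_hit
  post <- colSums(joint) * lik
  post / sum(post)
}

# Direct 2-D convolution with an explicit sum-normalized Gaussian kernel
# (interior pixels only; margin must be >= the kernel half-width).
oracle_gauss_blur_interior <- function(img, sigma) {
  size <- 2 * ceiling(3 * sigma) + 1
  half <- (size - 1) / 2
  d <- seq(-half, half)
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (y in (half + 1):(h - half)) {
    for (x in (half + 1):(w - half)) {
      patch <- img[(y - half):(y + half), (x - half):(x + half)]
      out[y, x] <- sum(patch * k)
    }
  }
  out
}

# Simulated trial scheduling re-expressed as plain R (used to cross-check
# the compiled loop): returns the zone index sequence for a given seed.
r_reference_trial <- function(td, bu, epsilon, p_hit, seed) {
  set.seed(seed)
  n <- nrow(td)
  m <- memory_state()
  m <- observe(m, "Eyes", p_hit)
  out <- integer(n)
  out[1] <- 1L
  for (t in seq_len(n - 1)) {
    f <- td[t, ] * bu[t, ] * as.numeric(invert(m))
    f <- f / sum(f)
    u <- runif(1)
    nx <- findInterval(u, cumsum(f), left.open = TRUE) + 1L
    nx <- min(nx, 4L)
    out[t + 1] <- nx
    m <- observe(dilute(m, epsilon), nx, p_hit)
  }
  out
}

default_streams <- function() {
  list(ER = make_saliency_streams(stimulus_spec("ER")),
       LP = make_saliency_streams(stimulus_spec("LP")))
}
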