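test_that("timeline windows follow the event discretization", {
  tl <- trial_timeline()
  expect_identical(tl$n_steps, 200L)
  expect_identical(tl$t_ER, 100L)
  expect_identical(window_steps(tl, "anticipatory"), 50:99)
  expect_identical(window_steps(tl, "detection"), 100:199)
  tl2 <- trial_timeline(n_speech_steps = 50, n_nonspeech_steps = 40)
  expect_identical(window_steps(tl2, "anticipatory"), 25:49)
  expect_identical(window_steps(tl2, "detection"), 50:89)
})

test_that("fused distribution equals the brute-force component product", {
  tl <- trial_timeline(condition = "ER", trial = 7)
  cfg <- topdown_config(learning_enabled = TRUE)
  set.seed(31)
  for (i in 1:100) {
    p <- gaze_params(beta = runif(1, 0, 5), gamma = runif(1, 0, 2),
                     theta = runif(1))
    st <- gaze_state(position = sample(zones(), 1), memory = random_belief())
    sal <- list(static = runif(4, 0.01, 1), dynamic = runif(4, 0.01, 1))
    t <- sample(0:199, 1)
    got <- fused_distribution(st, sal, t, tl, p, cfg)
    td <- top_down_distribution(t, tl$trial, cfg, p, tl$t_ER)
    bu <- bottom_up_distribution(sal$static, sal$dynamic, p$theta)
    mem <- invert(observe(dilute(st$memory, p$epsilon), st$position, p$p_hit))
    expect_equal(as.numeric(got), oracle_product(td, bu, mem),
                 tolerance = 1e-12)
    expect_identical(attr(got, "role"), "fused")
  }
})

test_that("uniform factors leave the top-down distribution as the fusion", {
  tl <- trial_timeline(condition = "ER", trial = 5)
  cfg <- topdown_config(learning_enabled = TRUE)
  p <- gaze_params(beta = 5, gamma = 0, theta = 0.5,
                   p_hit = 0.25 + 1e-9)  # uninformative observation
  st <- gaze_state(memory = memory_state())
  sal <- list(static = rep(0.2, 4), dynamic = rep(0.2, 4))
  got <- fused_distribution(st, sal, 150, tl, p, cfg)
  expect_equal(as.numeric(got),
               as.numeric(top_down_distribution(150, 5, cfg, p, 100)),
               tolerance = 1e-6)
})

test_that("position draws are reproducible and respect degenerate distributions", {
  d <- zone_distribution(c(1, 0, 0, 0))
  set.seed(5)
  expect_true(all(replicate(50, draw_next_position(d)) == "Eyes"))
  u <- zone_distribution(rep(0.25, 4))
  set.seed(99); a <- replicate(100, draw_next_position(u))
  set.seed(99); b <- replicate(100, draw_next_position(u))
  expect_identical(a, b)
})

test_that("the compiled trial loop matches a plain-R reference implementation", {
  tl <- trial_timeline(condition = "ER", trial = 9)
  cfg <- topdown_config(learning_enabled = TRUE)
  p <- gaze_params(beta = 2, gamma = 1, theta = 0.25)
  stream <- make_saliency_streams(stimulus_spec("ER"), tl)
  td <- gazesim:::topdown_matrix(tl, cfg, p)
  bu <- gazesim:::bottom_up_matrix(stream, p$theta)
  for (seed in c(1, 17, 4242)) {
    set.seed(seed)
    cpp <- gazesim:::.sim_trial_cpp(td, bu, p$epsilon, p$p_hit, 1L)
    ref <- r_reference_trial(td, bu, p$epsilon, p$p_hit, seed)
    expect_identical(cpp, ref)
  }
})

test_that("simulated trials start on the eyes and have one zone per step", {
  tl <- trial_timeline(condition = "LP", trial = 1)
  stream <- make_saliency_streams(stimulus_spec("LP"), tl)
  set.seed(8)
  tr <- simulate_trial(tl, stream, gaze_params())
  expect_identical(length(tr$zones), 200L)
  expect_identical(tr$zones[1], "Eyes")
  expect_true(all(tr$zones %in% zones()))
  set.seed(8)
  tr2 <- simulate_trial(tl, stream, gaze_params())
  expect_identical(tr$zones, tr2$zones)
  short <- aoi_saliency_stream(matrix(0.1, 10, 4), matrix(0.1, 10, 4))
  expect_error(simulate_trial(tl, short, gaze_params()), "match")
})

test_that("long-run occupancy matches the collapsed-chain stationary distribution", {
  # In the epsilon -> 1/4 limit the dilution wipes the memory each step, so
  # the belief depends only on the last drawn zone and the gaze process
  # collapses to a 4-state Markov chain that can be solved exactly.
  p_hit <- 0.9
  prior <- c(0.45, 0.45, 0.05, 0.05)   # beta = 0: static top-down priors
  lik <- function(x) { l <- rep((1 - p_hit) / 3, 4); l[x] <- p_hit; l }
  P <- matrix(0, 4, 4)
  for (i in 1:4) {
    b <- lik(i) * 0.25; b <- b / sum(b)
    w <- prior * (1 - b) / 3
    P[i, ] <- w / sum(w)
  }
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)

  tl <- trial_timeline(n_speech_steps = 30000, n_nonspeech_steps = 30000)
  stream <- aoi_saliency_stream(matrix(0.2, 60000, 4), matrix(0.2, 60000, 4))
  params <- gaze_params(beta = 0, gamma = 0, theta = 0.5, epsilon = 0.2499)
  set.seed(314)
  tr <- simulate_trial(tl, stream, params)
  freq <- tabulate(zone_index(tr$zones), nbins = 4) / length(tr$zones)
  expect_equal(freq, stat, tolerance = 0.01)
})

test_that("experiments produce one trajectory per condition, participant and trial", {
  streams <- default_streams()
  pr <- sim_protocol(master_seed = 5)
  raw <- gazesim:::simulate_experiment_raw(pr, streams)
  expect_identical(names(raw), c("ER", "LP"))
  expect_identical(length(raw$ER), 20L)
  expect_identical(length(raw$ER[[1]]), 19L)
  expect_identical(length(raw$ER[[3]][[7]]), 200L)
  expect_identical(2L * 20L * 19L, sum(vapply(raw, function(cc)
    sum(vapply(cc, length, integer(1))), integer(1))))

  # ER-only design (the oldest age group was tested in ER only)
  pr1 <- sim_protocol(conditions = "ER", master_seed = 5)
  raw1 <- gazesim:::simulate_experiment_raw(pr1, streams["ER"])
  expect_identical(length(raw1$ER) * length(raw1$ER[[1]]), 380L)

  expect_error(gazesim:::simulate_experiment_raw(pr, streams["ER"]),
               "no saliency stream")
})

test_that("the master seed reproduces or changes whole experiments", {
  streams <- default_streams()
  pr <- sim_protocol(n_virtual_participants = 3, n_trials = 4,
                     master_seed = 21)
  a <- gazesim:::simulate_experiment_raw(pr, streams)
  b <- gazesim:::simulate_experiment_raw(pr, streams)
  expect_identical(a, b)
  pr2 <- pr; pr2$master_seed <- 22L
  c <- gazesim:::simulate_experiment_raw(pr2, streams)
  expect_false(identical(a, c))
})

test_that("the trajectory data frame mirrors the raw simulation", {
  streams <- default_streams()
  pr <- sim_protocol(n_virtual_participants = 2, n_trials = 3,
                     master_seed = 9)
  df <- simulate_experiment(pr, streams)
  expect_identical(nrow(df), 2L * 2L * 3L * 200L)
  expect_identical(sort(unique(df$condition)), c("ER", "LP"))
  expect_true(all(df$zone %in% zones()))
  one <- df[df$participant == "ER01" & df$trial == 2 & df$condition == "ER", ]
  raw <- gazesim:::simulate_experiment_raw(pr, streams)
  expect_identical(one$zone, zones()[raw$ER[[1]][[2]]])
})

test_that("a static-saliency preference (theta = 1) raises eyes occupancy", {
  streams <- default_streams()
  occ <- function(theta) {
    pr <- sim_protocol(conditions = "ER", n_virtual_participants = 5,
                       params = gaze_params(beta = 0, theta = theta),
                       master_seed = 33)
    raw <- gazesim:::simulate_experiment_raw(pr, streams["ER"])
    mean(unlist(raw$ER) == 1L)
  }
  expect_gt(occ(1), occ(0))
})

test_that("learning produces a positive anticipatory slope only when beta > 0", {
  streams <- default_streams()
  win <- window_steps(trial_timeline(), "anticipatory") + 1L
  gain <- function(beta, seed) {
    pr <- sim_protocol(conditions = "ER",
                       params = gaze_params(beta = beta, gamma = 2, theta = 0),
                       master_seed = seed)
    raw <- gazesim:::simulate_experiment_raw(pr, streams["ER"])
    ep <- gazesim:::endpoints_from_pref(
      gazesim:::pref_matrix_from_raw(raw$ER, win), "group")
    ep$end - ep$start
  }
  g5 <- vapply(1:50, function(s) gain(5, 200 + s), numeric(1))
  g0 <- vapply(1:50, function(s) gain(0, 200 + s), numeric(1))
  expect_gt(mean(g5), 0.1)
  # with beta = 0 the learned mass equals the base prior: the slope is
  # statistically indistinguishable from zero
  expect_lt(abs(mean(g0)), 2 * sd(g0) / sqrt(50))
})
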