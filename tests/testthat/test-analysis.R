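test_that("PTLT divides dwell time by on-face time only", {
  p <- compute_ptlt(c(rep("Eyes", 2), rep("Mouth", 6), rep("RoF", 2)))
  expect_equal(c(p$ptlt_eyes, p$ptlt_mouth, p$ptlt_rof), c(0.2, 0.6, 0.2))
  expect_equal(p$preference, -0.4)

  expect_equal(compute_ptlt(rep("Eyes", 5))$preference, 1)

  # off-face samples are excluded from the denominator
  p2 <- compute_ptlt(c(rep("Eyes", 3), rep("Mouth", 3), rep("Other", 4)))
  expect_equal(c(p2$ptlt_eyes, p2$ptlt_mouth, p2$ptlt_rof), c(0.5, 0.5, 0))
  expect_equal(p2$preference, 0)
  p3 <- compute_ptlt(c(Eyes = 3, Mouth = 3, RoF = 0, Other = 4))
  expect_equal(p3$preference, 0)

  # away samples count as off-face too
  p4 <- compute_ptlt(c("Eyes", "away", "away", "Mouth"))
  expect_equal(p4$ptlt_eyes, 0.5)

  # no on-face time -> missing, not zero
  p5 <- compute_ptlt(rep("away", 10))
  expect_true(is.na(p5$preference))
  expect_error(compute_ptlt(character(0)), "empty")
  expect_error(compute_ptlt(c("Eyes", "Nose")), "unknown")
})

test_that("PTLT components sum to one whenever defined", {
  set.seed(41)
  for (i in 1:50) {
    x <- sample(c(zones(), "away"), 40, replace = TRUE)
    p <- compute_ptlt(x)
    if (!is.na(p$ptlt_eyes)) {
      expect_equal(p$ptlt_eyes + p$ptlt_mouth + p$ptlt_rof, 1,
                   tolerance = 1e-9)
      expect_true(abs(p$preference) <= 1)
    }
  }
})

test_that("baseline correction follows the two-branch rescaling", {
  expect_equal(baseline_correct(0.2, trial1 = -0.4), 0.6 / 1.4,
               tolerance = 1e-12)
  expect_equal(baseline_correct(-0.5, trial1 = 0.5), -1 / 1.5,
               tolerance = 1e-12)
  expect_equal(baseline_correct(0.3, trial1 = 0.3), 0)
  expect_equal(baseline_correct(-1, trial1 = -1), 0)
  expect_true(is.na(baseline_correct(NA_real_, trial1 = 0.1)))
  expect_true(all(is.na(baseline_correct(c(0.1, 0.2), trial1 = NA_real_))))
  expect_error(baseline_correct(1.4, trial1 = 0), "\\[-1, 1\\]")
})

test_that("baseline correction maps [-1, 1] into [-1, 1]", {
  g <- seq(-1, 1, by = 0.05)
  for (t1 in g) {
    out <- baseline_correct(g, trial1 = t1)
    expect_true(all(out >= -1 - 1e-12 & out <= 1 + 1e-12))
    # sign matches the direction of change from baseline
    expect_true(all(sign(out) == sign(g - t1) | g == t1))
  }
})

test_that("group means ignore missing participants trial by trial", {
  s <- data.frame(participant = rep(c("a", "b"), each = 3),
                  trial = rep(2:4, 2),
                  score = c(0.2, NA, 0.4, -0.2, 0.3, NA))
  gm <- group_mean_series(s)
  expect_equal(gm$score, c(0, 0.3, 0.4))
  one <- group_mean_series(data.frame(participant = "a", trial = 2:3,
                                      score = c(0.1, 0.2)))
  expect_equal(one$score, c(0.1, 0.2))
  expect_error(group_mean_series(data.frame()), "empty")
})

test_that("regression endpoints lie on the fitted line", {
  flat <- data.frame(trial = 2:19, score = rep(0.1, 18))
  e <- regression_endpoints(flat)
  expect_equal(e$start, 0.1, tolerance = 1e-12)
  expect_equal(e$end, 0.1, tolerance = 1e-12)

  line <- data.frame(trial = 2:19, score = 0.01 * (2:19 - 2))
  e2 <- regression_endpoints(line)
  expect_equal(e2$start, 0, tolerance = 1e-12)
  expect_equal(e2$end, 0.17, tolerance = 1e-12)
  expect_equal(e2$slope, 0.01, tolerance = 1e-12)

  expect_error(regression_endpoints(data.frame(trial = 2, score = 0.1)),
               "2 non-missing")
  # missing trials are dropped, not imputed
  holes <- line; holes$score[c(3, 9)] <- NA
  e3 <- regression_endpoints(holes)
  expect_equal(e3$slope, 0.01, tolerance = 1e-12)
})

test_that("OLS endpoints are unbiased under symmetric noise", {
  true <- function(tr) 0.02 * (tr - 2) - 0.1
  starts <- ends <- numeric(100)
  set.seed(43)
  for (r in 1:100) {
    s <- data.frame(trial = 2:19,
                    score = true(2:19) + rnorm(18, sd = 0.05))
    e <- regression_endpoints(s)
    starts[r] <- e$start; ends[r] <- e$end
  }
  expect_lt(abs(mean(starts) - true(2)), 2 * sd(starts) / sqrt(100))
  expect_lt(abs(mean(ends) - true(19)), 2 * sd(ends) / sqrt(100))
})

test_that("endpoint regression is equivariant under constant shifts", {
  set.seed(44)
  s <- data.frame(trial = 2:19, score = runif(18, -0.5, 0.5))
  e <- regression_endpoints(s)
  s2 <- s; s2$score <- s2$score + 0.3
  e2 <- regression_endpoints(s2)
  expect_equal(e2$start, e$start + 0.3, tolerance = 1e-12)
  expect_equal(e2$end, e$end + 0.3, tolerance = 1e-12)
})

test_that("the endpoint MSE averages squared differences over all pairs", {
  mk <- function(s, e) structure(list(start = s, end = e),
                                 class = "endpoint_summary")
  sim <- list(ER = mk(0.1, 0.3), LP = mk(0.0, -0.1))
  expect_equal(mse_endpoints(sim, sim), 0)
  data <- list(ER = mk(0.0, 0.4), LP = mk(-0.2, -0.1))
  expect_equal(mse_endpoints(sim, data), (0.01 + 0.01 + 0.04 + 0) / 4)
  sim1 <- list(ER = mk(0.3, -0.1)); data1 <- list(ER = mk(0.0, 0.0))
  expect_equal(mse_endpoints(sim1, data1), 0.05)
  expect_error(mse_endpoints(sim, data1), "condition sets")
})

test_that("trajectory scores and the series pipeline are consistent", {
  streams <- default_streams()
  pr <- sim_protocol(n_virtual_participants = 4, n_trials = 5,
                     master_seed = 60)
  df <- simulate_experiment(pr, streams)
  tl <- trial_timeline()
  sc <- trajectory_scores(df, tl, "anticipatory")
  expect_identical(nrow(sc), 2L * 4L * 5L)
  expect_true(all(abs(sc$preference) <= 1, na.rm = TRUE))

  # the data-frame pipeline and the fast matrix path agree
  raw <- gazesim:::simulate_experiment_raw(pr, streams)
  win <- window_steps(tl, "anticipatory") + 1L
  pm <- gazesim:::pref_matrix_from_raw(raw$ER, win)
  for (p in 1:4) for (tr in 1:5) {
    got <- sc$preference[sc$condition == "ER" &
                         sc$participant == sprintf("ER%02d", p) &
                         sc$trial == tr]
    expect_equal(got, pm[p, tr], tolerance = 1e-12)
  }
  ser <- score_series(sc, baseline = "group")
  ep <- regression_endpoints(ser$ER)
  ep_fast <- gazesim:::endpoints_from_pref(pm, "group")
  expect_equal(ep$start, ep_fast$start, tolerance = 1e-12)
  expect_equal(ep$end, ep_fast$end, tolerance = 1e-12)
})

test_that("detection-window scores see the non-speech event response", {
  streams <- default_streams()
  pr <- sim_protocol(n_virtual_participants = 6, n_trials = 3,
                     params = gaze_params(beta = 0, theta = 0),
                     master_seed = 71)
  df <- simulate_experiment(pr, streams)
  det <- trajectory_scores(df, trial_timeline(), "detection")
  m <- tapply(det$preference, det$condition, mean, na.rm = TRUE)
  # LP: motion stays on the mouth; ER: motion moves to the eyes
  expect_gt(m[["ER"]], m[["LP"]])
})
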