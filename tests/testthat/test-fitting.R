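test_that("the default grid covers the explored parameter lists", {
  g <- parameter_grid()
  expect_equal(g$beta, c(0.1, 0.5, 1, 2, 3, 4, 5))
  expect_equal(g$gamma, c(0.1, 0.5, 1, 1.5, 2))
  expect_equal(g$theta, c(0, 0.05, 0.1, 0.25, 0.5, 0.75, 1))
  expect_identical(length(g$beta) * length(g$gamma) * length(g$theta), 245L)
  expect_error(parameter_grid(beta = c(2, 1)), "increasing")
  expect_error(parameter_grid(theta = c(0, 2)), "domain")
  expect_error(parameter_grid(gamma = numeric(0)), "non-empty")
})

test_that("a self-fit with identical seeds recovers the generating point exactly", {
  streams <- default_streams()
  gen <- gaze_params(beta = 2, gamma = 1, theta = 0.25)
  pr <- sim_protocol(n_virtual_participants = 6, n_trials = 8,
                     master_seed = 303)
  ds <- make_behavioral_dataset(pr, gen, lapse_rate = 0)
  tl <- trial_timeline()
  ep <- lapply(score_series(trajectory_scores(ds, tl), baseline = "group"),
               regression_endpoints)
  small <- parameter_grid(beta = c(1, 2, 3), gamma = c(0.5, 1, 1.5),
                          theta = c(0.1, 0.25, 0.5))
  # n_runs = 1 with the data's own master seed replays the data's seed
  # schedule, so the generating point must reach an exactly zero MSE
  fit <- grid_search(ep, small, pr, streams, n_runs = 1L)
  expect_equal(fit$best_params$beta, 2)
  expect_equal(fit$best_params$gamma, 1)
  expect_equal(fit$best_params$theta, 0.25)
  expect_lt(fit$best_mse, 1e-20)
  expect_identical(nrow(fit$surface), 27L)
})

test_that("the fit surface exports, round-trips and flags flat surfaces", {
  surf <- expand.grid(theta = c(0, 0.5), gamma = c(1), beta = c(1, 2))
  surf <- surf[, c("beta", "gamma", "theta")]
  surf$mse <- c(0.4, 0.2, 0.2, 0.1)
  fr <- structure(list(surface = surf,
                       grid = parameter_grid(beta = c(1, 2), gamma = 1,
                                             theta = c(0, 0.5)),
                       best_mse = 0.1), class = "fit_result")
  out <- export_fit_surface(fr)
  expect_identical(nrow(out), 4L)
  tmp <- tempfile(fileext = ".tsv")
  write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- best_from_surface(read.delim(tmp))
  expect_equal(back$beta, 2); expect_equal(back$theta, 0.5)
  expect_equal(back$mse, 0.1)

  flat <- fr; flat$surface$mse <- rep(0.3, 4)
  expect_warning(export_fit_surface(flat), "no sensitivity")
})

test_that("argmin ties break toward the lowest beta, then gamma, then theta", {
  surf <- expand.grid(theta = c(0, 0.5), gamma = c(0.5, 1), beta = c(1, 2))
  surf <- surf[, c("beta", "gamma", "theta")]
  surf$mse <- rep(0.2, 8)   # all tied
  best <- best_from_surface(surf)
  expect_equal(best$beta, 1)
  expect_equal(best$gamma, 0.5)
  expect_equal(best$theta, 0)
})

test_that("fit diagnostics report sensitivity, robustness and smoothness", {
  grid <- parameter_grid(beta = c(1, 2, 3), gamma = c(1, 2),
                         theta = c(0, 1))
  surf <- expand.grid(theta = grid$theta, gamma = grid$gamma,
                      beta = grid$beta)
  surf <- surf[, c("beta", "gamma", "theta")]
  surf <- surf[order(surf$beta, surf$gamma, surf$theta), ]
  surf$mse <- 0.5
  fr <- structure(list(surface = surf, grid = grid, best_mse = 0.5),
                  class = "fit_result")
  d <- fit_diagnostics(fr)
  expect_equal(d$sensitivity, 1)
  expect_identical(d$robustness_region_size, 12L)
  expect_equal(d$smoothness, 0)

  # single sharp minimum: region of size 1
  surf2 <- surf; surf2$mse <- 0.5
  surf2$mse[surf2$beta == 2 & surf2$gamma == 1 & surf2$theta == 0] <- 0.01
  fr2 <- structure(list(surface = surf2, grid = grid, best_mse = 0.01),
                   class = "fit_result")
  d2 <- fit_diagnostics(fr2)
  expect_identical(d2$robustness_region_size, 1L)
  expect_equal(d2$sensitivity, 50)
  expect_gt(d2$smoothness, 0)
})

test_that("a superset grid can only improve the best MSE", {
  streams <- default_streams()
  pr <- sim_protocol(n_virtual_participants = 3, n_trials = 4,
                     master_seed = 121)
  ds <- make_behavioral_dataset(pr, gaze_params(beta = 2, gamma = 1,
                                                theta = 0.25),
                                lapse_rate = 0.1)
  ep <- lapply(score_series(trajectory_scores(ds), baseline = "group"),
               regression_endpoints)
  prf <- sim_protocol(n_virtual_participants = 3, n_trials = 4,
                      master_seed = 55)
  sub <- parameter_grid(beta = c(1, 3), gamma = 1, theta = 0.25)
  sup <- parameter_grid(beta = c(1, 2, 3), gamma = c(0.5, 1), theta = 0.25)
  f_sub <- grid_search(ep, sub, prf, streams, n_runs = 1L)
  f_sup <- grid_search(ep, sup, prf, streams, n_runs = 1L)
  expect_lte(f_sup$best_mse, f_sub$best_mse)
})

test_that("grid evaluation is reproducible and order-independent", {
  streams <- default_streams()
  gen <- gaze_params(beta = 2, gamma = 1, theta = 0.25)
  pr <- sim_protocol(n_virtual_participants = 4, n_trials = 5,
                     master_seed = 88)
  ds <- make_behavioral_dataset(pr, gen, lapse_rate = 0.1)
  ep <- lapply(score_series(trajectory_scores(ds), baseline = "group"),
               regression_endpoints)
  small <- parameter_grid(beta = c(1, 3), gamma = c(0.5, 1.5),
                          theta = c(0, 0.5))
  prf <- sim_protocol(n_virtual_participants = 4, n_trials = 5,
                      master_seed = 12)
  f1 <- grid_search(ep, small, prf, streams, n_runs = 2L)
  f2 <- grid_search(ep, small, prf, streams, n_runs = 2L)
  expect_identical(f1$surface, f2$surface)
  # evaluating a permuted grid yields the same MSE per point
  perm <- parameter_grid(beta = c(1, 3), gamma = c(0.5, 1.5),
                         theta = c(0, 0.5))
  f3 <- grid_search(ep, perm, prf, streams, n_runs = 2L)
  expect_equal(f1$surface$mse, f3$surface$mse, tolerance = 1e-15)
  expect_error(grid_search(ep["ER"], small, prf, streams),
               "no data endpoints")
})
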