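#' Parameter grid for the three free parameters
#'
#' Default value lists for the grid search: learning strength beta, speed of
#' anticipation gamma, and static-saliency weight theta.
#'
#' @param beta,gamma,theta Strictly increasing non-empty numeric vectors;
#'   beta and gamma non-negative, theta in \[0, 1\].
#' @return An object of class `parameter_grid`.
#' @export
#' @examples
#' parameter_grid()  # 7 x 5 x 7 = 245 combinations
parameter_grid <- function(beta = c(0.1, 0.5, 1, 2, 3, 4, 5),
                           gamma = c(0.1, 0.5, 1, 1.5, 2),
                           theta = c(0, 0.05, 0.1, 0.25, 0.5, 0.75, 1)) {
  chk <- function(v, nm, lo = 0, hi = Inf) {
    if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v)))
      stop(nm, " values must be a non-empty finite numeric vector",
           call. = FALSE)
    if (any(diff(v) <= 0))
      stop(nm, " values must be strictly increasing", call. = FALSE)
    if (any(v < lo) || any(v > hi))
      stop(nm, " values out of domain", call. = FALSE)
    v
  }
  structure(list(beta = chk(beta, "beta"),
                 gamma = chk(gamma, "gamma"),
                 theta = chk(theta, "theta", 0, 1)),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter_grid %d beta x %d gamma x %d theta = %d points>\n",
              length(x$beta), length(x$gamma), length(x$theta),
              length(x$beta) * length(x$gamma) * length(x$theta)))
  invisible(x)
}

#' Grid search over (beta, gamma, theta)
#'
#' For every combination in the grid, simulates a full experiment under the
#' protocol (reusing the same per-trial seed schedule across grid points, so
#' MSE differences reflect parameters rather than sampling noise), computes
#' the anticipatory learning-curve regression endpoints per condition, and
#' scores the combination by the mean squared error against the data
#' endpoints. Ties in the argmin are broken lexicographically (lowest beta,
#' then gamma, then theta).
#'
#' @param data_endpoints Named list of [regression_endpoints()] summaries
#'   (one per condition in the protocol), from behavioral or synthetic data.
#' @param grid A [parameter_grid()].
#' @param protocol A [sim_protocol()]; its `params` supply epsilon and
#'   p_hit, while beta/gamma/theta are taken from the grid.
#' @param streams Named list of `aoi_saliency_stream`s per condition.
#' @param baseline Baseline-correction mode (see [score_series()]). The
#'   default for the model-data comparison is the group-mean baseline.
#' @param n_runs Simulation runs averaged per grid point. Each run is a
#'   full experiment under its own (shared-across-grid-points) seed
#'   schedule; endpoints are averaged over runs before the MSE, so that the
#'   Monte-Carlo error of a grid point's endpoints sits below the endpoint
#'   differences between neighboring grid values.
#' @return An object of class `fit_result`: data frame `surface` (beta,
#'   gamma, theta, mse, and per-condition start/end columns), `best_params`
#'   (a [gaze_params()]), `best_mse`, plus the data endpoints used.
#' @export
grid_search <- function(data_endpoints, grid, protocol, streams,
                        baseline = "group", n_runs = 4L) {
  miss <- setdiff(protocol$conditions, names(data_endpoints))
  if (length(miss) > 0)
    stop("no data endpoints for condition: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss_s <- setdiff(protocol$conditions, names(streams))
  if (length(miss_s) > 0)
    stop("no saliency stream for condition: ",
         paste(miss_s, collapse = ", "), call. = FALSE)
  data_endpoints <- data_endpoints[protocol$conditions]

  tmpl <- protocol$timeline_template
  win_idx1 <- window_steps(tmpl, "anticipatory") + 1L
  pts <- expand.grid(theta = grid$theta, gamma = grid$gamma,
                     beta = grid$beta, KEEP.OUT.ATTRS = FALSE)
  pts <- pts[, c("beta", "gamma", "theta")]
  n_pts <- nrow(pts)
  mse <- numeric(n_pts)
  ep_cols <- list()
  for (cond in protocol$conditions) {
    ep_cols[[paste0("start_", cond)]] <- numeric(n_pts)
    ep_cols[[paste0("end_", cond)]] <- numeric(n_pts)
  }
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1L)
  # one seed schedule per run, shared by every grid point (common random
  # numbers: MSE differences reflect parameters, not sampling); run 1 is
  # the protocol's own schedule, further runs derive fresh ones
  run_seeds <- c(protocol$master_seed,
                 vapply(seq_len(max(0L, n_runs - 1L)), function(r)
                   trial_seed(protocol$master_seed, "ER", r, 424243L),
                   integer(1)))
  for (i in seq_len(n_pts)) {
    pr <- protocol
    pr$params <- gaze_params(beta = pts$beta[i], gamma = pts$gamma[i],
                             theta = pts$theta[i],
                             epsilon = protocol$params$epsilon,
                             p_hit = protocol$params$p_hit)
    acc <- setNames(vector("list", length(protocol$conditions)),
                    protocol$conditions)
    for (r in seq_len(n_runs)) {
      pr$master_seed <- run_seeds[r]
      raw <- simulate_experiment_raw(pr, streams)
      for (cond in protocol$conditions) {
        e <- endpoints_from_pref(pref_matrix_from_raw(raw[[cond]], win_idx1),
                                 baseline)
        acc[[cond]] <- rbind(acc[[cond]], c(e$start, e$end))
      }
    }
    sim_ep <- lapply(acc, function(m)
      list(start = mean(m[, 1]), end = mean(m[, 2])))
    mse[i] <- mse_endpoints(sim_ep, data_endpoints)
    for (cond in protocol$conditions) {
      ep_cols[[paste0("start_", cond)]][i] <- sim_ep[[cond]]$start
      ep_cols[[paste0("end_", cond)]][i] <- sim_ep[[cond]]$end
    }
  }
  surface <- cbind(pts, mse = mse, as.data.frame(ep_cols))
  surface <- surface[order(surface$beta, surface$gamma, surface$theta), ,
                     drop = FALSE]
  rownames(surface) <- NULL
  # argmin with lexicographic tie-breaking on (beta, gamma, theta):
  # the surface is already sorted canonically, so the first minimum wins
  best_i <- which(surface$mse == min(surface$mse))[1]
  best_params <- gaze_params(beta = surface$beta[best_i],
                             gamma = surface$gamma[best_i],
                             theta = surface$theta[best_i],
                             epsilon = protocol$params$epsilon,
                             p_hit = protocol$params$p_hit)
  structure(list(surface = surface, best_params = best_params,
                 best_mse = surface$mse[best_i], grid = grid,
                 conditions = protocol$conditions,
                 data_endpoints = data_endpoints),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result %d grid points; best mse=%.5g at beta=%g gamma=%g theta=%g>\n",
    nrow(x$surface), x$best_mse, x$best_params$beta, x$best_params$gamma,
    x$best_params$theta))
  invisible(x)
}

#' Export the fit surface as a long-format table
#'
#' @param result A [grid_search()] result.
#' @return Data frame (beta, gamma, theta, mse, per-condition endpoints),
#'   sorted by beta, then gamma, then theta — ready for heatmap rendering.
#'   Warns if the surface is completely flat (no sensitivity to the
#'   parameters).
#' @export
export_fit_surface <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  surf <- result$surface
  if (diff(range(surf$mse)) == 0)
    warning("flat fit surface: the MSE shows no sensitivity to the ",
            "parameters", call. = FALSE)
  surf
}

#' Recompute the best parameters from an exported fit surface
#'
#' @param surface A data frame as produced by [export_fit_surface()] (e.g.
#'   re-imported from disk).
#' @return Named list with `beta`, `gamma`, `theta`, `mse` of the argmin
#'   (lexicographic tie-breaking).
#' @export
best_from_surface <- function(surface) {
  stopifnot(all(c("beta", "gamma", "theta", "mse") %in% names(surface)))
  surface <- surface[order(surface$beta, surface$gamma, surface$theta), ,
                     drop = FALSE]
  i <- which(surface$mse == min(surface$mse))[1]
  list(beta = surface$beta[i], gamma = surface$gamma[i],
       theta = surface$theta[i], mse = surface$mse[i])
}

#' Diagnostics of a fit surface
#'
#' Reports three qualities of the fit landscape (values are reported, not
#' enforced): sensitivity — the ratio of the largest to the smallest MSE
#' over the grid; robustness — the number of grid points in the connected
#' region (6-neighborhood over the three grid axes) around the argmin whose
#' MSE is within 10% of the best; smoothness — the mean absolute MSE
#' difference between adjacent grid points.
#'
#' @param result A [grid_search()] result.
#' @return List with `sensitivity`, `robustness_region_size`, `smoothness`.
#' @export
fit_diagnostics <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  surf <- result$surface
  g <- result$grid
  nb <- length(g$beta); ng <- length(g$gamma); nt <- length(g$theta)
  # surface is sorted by beta, gamma, theta -> theta fastest
  arr <- array(surf$mse, dim = c(nt, ng, nb))
  mn <- min(arr); mx <- max(arr)
  sensitivity <- if (mx == mn) 1 else if (mn == 0) Inf else mx / mn
  # connected region within 10% of the best, grown from the argmin
  thr <- if (mn == 0) 1e-12 else mn * 1.1
  ok <- arr <= thr
  seed <- which(arr == mn, arr.ind = TRUE)[1, ]
  inreg <- array(FALSE, dim = dim(arr))
  queue <- list(seed)
  inreg[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (d in 1:3) {
      for (s in c(-1L, 1L)) {
        nx <- cur; nx[d] <- nx[d] + s
        if (nx[d] >= 1 && nx[d] <= dim(arr)[d] &&
            ok[nx[1], nx[2], nx[3]] && !inreg[nx[1], nx[2], nx[3]]) {
          inreg[nx[1], nx[2], nx[3]] <- TRUE
          queue[[length(queue) + 1]] <- nx
        }
      }
    }
  }
  diffs <- c()
  if (nt > 1) diffs <- c(diffs, abs(arr[-1, , ] - arr[-nt, , ]))
  if (ng > 1) diffs <- c(diffs, abs(arr[, -1, ] - arr[, -ng, ]))
  if (nb > 1) diffs <- c(diffs, abs(arr[, , -1] - arr[, , -nb]))
  list(sensitivity = sensitivity,
       robustness_region_size = sum(inreg),
       smoothness = if (length(diffs) > 0) mean(diffs) else 0)
}
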