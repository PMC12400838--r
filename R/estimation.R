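# Parameter estimation: least-squares objective, multistart fitting and
# goodness-of-fit reporting.

#' Observation set
#'
#' Per-cycle observed series used for fitting: any of `power` (W), `Pi`,
#' `ADP`, `PCr` (mM) and `pH`, with optional per-point standard deviations in
#' `*_sd` columns. Rows are aligned to cycles either by a `cycle` column or
#' by a `time_s` column mapped through [map_time_to_cycles()].
#'
#' @param df data frame with a `cycle` or `time_s` column plus observed series
#' @param cycles_per_10s mapping constant for `time_s` (default 6.3)
#' @return object of class `observation_set` (a validated data frame)
#' @export
observation_set <- function(df, cycles_per_10s = 6.3) {
  series <- intersect(c("power", "Pi", "ADP", "PCr", "pH"), names(df))
  if (!length(series)) {
    stop("observation set needs at least one of: power, Pi, ADP, PCr, pH")
  }
  if (!"cycle" %in% names(df)) {
    if (!"time_s" %in% names(df)) stop("need a 'cycle' or 'time_s' column")
    df$cycle <- map_time_to_cycles(df$time_s, cycles_per_10s)
  }
  df <- df[df$cycle >= 1, , drop = FALSE]
  sdcols <- grep("_sd$", names(df), value = TRUE)
  for (sc in sdcols) {
    if (any(!is.na(df[[sc]]) & df[[sc]] <= 0)) {
      stop("standard deviations in '", sc, "' must be positive")
    }
  }
  structure(df, class = c("observation_set", "data.frame"))
}

# model series aligned to observed cycles; power uses the cycle-mean by
# default (cycle-peak selectable)
.model_series <- function(sim, obs, power_mode = "mean") {
  idx <- match(obs$cycle, sim$cycles$cycle)
  if (any(is.na(idx))) {
    stop("alignment error: observed cycles ",
         paste(obs$cycle[is.na(idx)], collapse = ", "),
         " not present in the simulation")
  }
  pow <- if (power_mode == "peak") sim$cycles$peak_force else sim$cycles$mean_power
  if (power_mode == "peak") {
    pow <- sim$cycles$peak_force * sim$config$power_scale * abs(sim$config$dLdt)
  }
  list(power = pow[idx], Pi = sim$cycles$Pi[idx], ADP = sim$cycles$ADP[idx],
       PCr = sim$cycles$PCr[idx], pH = sim$cycles$pH[idx])
}

#' Least-squares objective of the metabolite + power fit
#'
#' For each fitted series the contribution is
#' `sum_j (data_j - model_j)^2 / max(data_j)` -- squared residuals normalized
#' by the series maximum (not its square) -- summed over the Pi, ADP, PCr and
#' power series by default. pH is excluded unless requested (it is reserved
#' for validation).
#'
#' @param params candidate [xb_params()]
#' @param config [protocol_config()]
#' @param activation per-cycle iEMG driving the simulation
#' @param obs an [observation_set()]
#' @param series which series enter the objective (default power, Pi, ADP, PCr)
#' @param power_mode `"mean"` (cycle-mean power; default) or `"peak"`
#' @param fail_value value returned (with a warning) when the simulation
#'   fails for `params`
#' @return scalar objective value
#' @export
objective <- function(params, config, activation, obs,
                      series = c("power", "Pi", "ADP", "PCr"),
                      power_mode = "mean", fail_value = 1e10) {
  res <- tryCatch(
    objective_residuals(params, config, activation, obs, series, power_mode),
    error = function(e) {
      warning("simulation failed in objective: ", conditionMessage(e))
      NULL
    })
  if (is.null(res)) return(fail_value)
  sum(res^2)
}

# residual vector whose sum of squares equals the objective
objective_residuals <- function(params, config, activation, obs,
                                series = c("power", "Pi", "ADP", "PCr"),
                                power_mode = "mean") {
  sim <- simulate_exercise(params, config, activation)
  mod <- .model_series(sim, obs, power_mode)
  unlist(lapply(series, function(sn) {
    d <- obs[[sn]]
    if (is.null(d)) return(numeric(0))
    keep <- !is.na(d)
    (d[keep] - mod[[sn]][keep]) / sqrt(max(d[keep]))
  }))
}

#' Multistart bounded least-squares parameter estimation
#'
#' Repeats a bounded Levenberg-Marquardt fit of the selected free parameters
#' from `n_starts` random start points drawn uniformly (in log10 space)
#' within the bounds, and keeps the solution with the smallest objective.
#' Default bounds are one decade either side of the current value. The fit
#' runs in log10 parameter space, which enforces positivity and puts the
#' heterogeneous rate scales on a common footing.
#'
#' @param obs an [observation_set()]
#' @param config [protocol_config()] used for candidate simulations
#' @param activation per-cycle iEMG trace
#' @param free character vector of parameter names to estimate (any of the
#'   23 kinetic parameters plus `c_XB`)
#' @param start `xb_params` providing fixed values and bound centres
#'   (default [xb_params()])
#' @param bounds list with `lower`/`upper` named vectors (internal units);
#'   default `0.1x` to `10x` the start values
#' @param n_starts number of multistart repetitions
#' @param seed RNG seed for the start draws
#' @param series,power_mode forwarded to [objective()]
#' @param maxiter per-start Levenberg-Marquardt iteration cap
#' @return object of class `xb_fit`: `params` (best-fit `xb_params`),
#'   `f_obj`, `estimates`, per-start table `starts`, and `rmse` report
#' @export
fit_parameters <- function(obs, config, activation, free,
                           start = xb_params(), bounds = NULL,
                           n_starts = 10, seed = 1,
                           series = c("power", "Pi", "ADP", "PCr"),
                           power_mode = "mean", maxiter = 25) {
  stopifnot(n_starts >= 1)
  ok <- c(.estimable_params, "c_XB")
  if (!all(free %in% ok)) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, ok), collapse = ", "))
  }
  x0 <- unlist(start[free])
  lower <- if (is.null(bounds)) 0.1 * x0 else bounds$lower[free]
  upper <- if (is.null(bounds)) 10 * x0 else bounds$upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite for all free parameters")
  }
  llo <- log10(lower); lhi <- log10(upper)

  make_params <- function(lx) {
    p <- start
    p[free] <- as.list(10^lx)
    class(p) <- "xb_params"
    p
  }
  resid_fn <- function(lx) {
    r <- tryCatch(
      objective_residuals(make_params(lx), config, activation, obs,
                          series, power_mode),
      error = function(e) NULL)
    if (is.null(r)) rep(1e6, 4) else r
  }

  set.seed(seed)
  starts <- matrix(runif(n_starts * length(free)), nrow = n_starts)
  starts <- sweep(sweep(starts, 2, lhi - llo, "*"), 2, llo, "+")

  rows <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = llo, upper = lhi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-8)),
      error = function(e) NULL)
    f <- if (is.null(fit)) Inf else sum(fit$fvec^2)
    rows[[i]] <- data.frame(start = i, f_obj = f,
                            converged = !is.null(fit) && fit$info %in% 1:4)
    if (!is.null(fit) && (is.null(best) || f < best$f)) {
      best <- list(fit = fit, f = f, start = i)
    }
  }
  if (is.null(best)) {
    stop("estimation failed: no start converged; see per-start diagnostics")
  }
  params_hat <- make_params(best$fit$par)
  sim <- simulate_exercise(params_hat, config, activation)
  structure(list(
    params = params_hat,
    f_obj = best$f,
    estimates = stats::setNames(10^best$fit$par, free),
    free = free,
    starts = do.call(rbind, rows),
    best_start = best$start,
    rmse = rmse_report(sim, obs)
  ), class = "xb_fit")
}

#' @export
print.xb_fit <- function(x, ...) {
  cat(sprintf("<xb_fit> best of %d starts (start %d), f_obj = %.6g\n",
              nrow(x$starts), x$best_start, x$f_obj))
  print(signif(x$estimates, 5))
  invisible(x)
}

#' RMSE and within-1-SD goodness of fit
#'
#' Per-series root-mean-square error between a simulation and an observation
#' set; where `*_sd` columns are supplied, also the fraction of points whose
#' absolute residual is within one standard deviation.
#'
#' @param sim an `xb_sim` (or `xb_fit$params` re-simulated)
#' @param obs an [observation_set()]
#' @param power_mode forwarded to the model-series extraction
#' @return data frame (series, n, rmse, frac_within_1sd)
#' @export
rmse_report <- function(sim, obs, power_mode = "mean") {
  mod <- .model_series(sim, obs, power_mode)
  series <- intersect(c("power", "Pi", "ADP", "PCr", "pH"), names(obs))
  out <- lapply(series, function(sn) {
    d <- obs[[sn]]
    keep <- !is.na(d)
    if (!sum(keep)) return(NULL)
    resid <- d[keep] - mod[[sn]][keep]
    sdcol <- paste0(sn, "_sd")
    frac <- if (sdcol %in% names(obs)) {
      mean(abs(resid) <= obs[[sdcol]][keep])
    } else NA_real_
    data.frame(series = sn, n = sum(keep), rmse = sqrt(mean(resid^2)),
               frac_within_1sd = frac)
  })
  do.call(rbind, out)
}
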