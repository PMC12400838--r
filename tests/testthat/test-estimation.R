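# Least-squares objective, alignment, goodness-of-fit and fit reproducibility.
# (The full multistart parameter-recovery run lives in the acceptance suite.)

make_obs_fixture <- function(n_cycles = 20) {
  p <- xb_params()
  cfg <- fast_config(n_cycles)
  act <- fast_activation(n_cycles)
  go <- gen_observations(p, cfg, act,
                         synthetic_spec(n_cycles = n_cycles, noise_sd = 0,
                                        obs_interval_s = 1.6))
  list(p = p, cfg = cfg, act = act, obs = go$obs, sim = go$sim)
}

test_that("objective is zero when the model equals the data", {
  fx <- make_obs_fixture()
  expect_equal(objective(fx$p, fx$cfg, fx$act, fx$obs), 0, tolerance = 1e-20)
})

test_that("objective normalizes squared residuals by the series maximum", {
  fx <- make_obs_fixture(10)
  # single-series hand check: data (1, 2) vs model (2, 2) contributes
  # (1-2)^2 / 2 = 0.5 under the max-of-data normalization
  obs1 <- fx$obs
  mod_pi <- fx$sim$cycles$Pi[match(obs1$cycle, fx$sim$cycles$cycle)]
  shift <- obs1
  shift$Pi <- mod_pi + c(1, rep(0, nrow(obs1) - 1))
  f <- objective(fx$p, fx$cfg, fx$act, shift, series = "Pi")
  expect_equal(f, 1 / max(shift$Pi), tolerance = 1e-9)
  # scaling data and model by c scales the contribution by c
  d <- c(1, 2); m <- c(2, 2)
  contrib <- function(d, m) sum((d - m)^2) / max(d)
  expect_equal(contrib(d, m), 0.5)
  expect_equal(contrib(3 * d, 3 * m), 3 * contrib(d, m))
})

test_that("objective is invariant to consistent cycle permutations", {
  fx <- make_obs_fixture(12)
  obs <- fx$obs
  obs$Pi <- obs$Pi * 1.07 # make residuals non-zero
  f1 <- objective(fx$p, fx$cfg, fx$act, obs)
  perm <- sample(nrow(obs))
  obs2 <- obs[perm, ]
  f2 <- objective(fx$p, fx$cfg, fx$act, obs2)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("observation sets map wall-clock time to cycles and validate input", {
  df <- data.frame(time_s = c(10, 20, 30), Pi = c(5, 7, 9))
  obs <- observation_set(df)
  expect_equal(obs$cycle, c(6L, 13L, 19L))
  expect_error(observation_set(data.frame(cycle = 1, lactate = 2)),
               "at least one")
  expect_error(observation_set(data.frame(Pi = 2)), "cycle")
  expect_error(observation_set(data.frame(cycle = 1, Pi = 2, Pi_sd = 0)),
               "positive")
  # unknown cycles are an alignment error against a shorter simulation
  fx <- make_obs_fixture(10)
  bad <- fx$obs
  bad$cycle[1] <- 999L
  expect_error(objective_residuals <- musclexb:::objective_residuals(
    fx$p, fx$cfg, fx$act, bad), "alignment")
})

test_that("rmse_report computes per-series RMSE and the within-1-SD fraction", {
  fx <- make_obs_fixture(15)
  rep0 <- rmse_report(fx$sim, fx$obs)
  expect_true(all(rep0$rmse < 1e-12))
  # constant offset d on one series gives RMSE = d
  obs <- fx$obs
  obs$PCr <- obs$PCr + 0.7
  obs$PCr_sd <- rep(1, nrow(obs))
  rep1 <- rmse_report(fx$sim, obs)
  expect_equal(rep1$rmse[rep1$series == "PCr"], 0.7, tolerance = 1e-9)
  expect_equal(rep1$frac_within_1sd[rep1$series == "PCr"], 1)
  obs$PCr_sd <- rep(0.5, nrow(obs))
  rep2 <- rmse_report(fx$sim, obs)
  expect_equal(rep2$frac_within_1sd[rep2$series == "PCr"], 0)
  # hand-computed residual fixture
  obs2 <- fx$obs
  delta <- seq(-0.2, 0.2, length.out = nrow(obs2))
  obs2$Pi <- obs2$Pi + delta
  rep3 <- rmse_report(fx$sim, obs2)
  expect_equal(rep3$rmse[rep3$series == "Pi"], sqrt(mean(delta^2)),
               tolerance = 1e-9)
})

test_that("a single start from the truth stays at the optimum", {
  fx <- make_obs_fixture(10)
  # center the bounds at truth; the first (and only) start is inside the
  # [0.1x, 10x] box, and the optimum must be a fixed point with f ~ 0
  fit <- fit_parameters(fx$obs, fx$cfg, fx$act, free = c("k_d", "k_Gly"),
                        start = fx$p, n_starts = 3, seed = 2, maxiter = 25)
  expect_lt(fit$f_obj, 1e-6)
  expect_equal(unname(fit$estimates["k_d"]), fx$p$k_d, tolerance = 0.05)
  expect_equal(unname(fit$estimates["k_Gly"]), fx$p$k_Gly, tolerance = 0.05)
})

test_that("noise-free observations close the generation-estimation loop", {
  # end-to-end: generate without noise, perturb nothing, fit two parameters
  # from random starts and land back on the generating truth
  p <- xb_params()
  cfg <- fast_config(n_cycles = 20)
  act <- fast_activation(20)
  go <- gen_observations(p, cfg, act,
                         synthetic_spec(n_cycles = 20, noise_sd = 0,
                                        obs_interval_s = 1.6))
  fit <- fit_parameters(go$obs, cfg, act, free = c("k_d", "c_XB"),
                        n_starts = 4, seed = 3, maxiter = 30)
  expect_lt(abs(fit$estimates[["k_d"]] / p$k_d - 1), 0.05)
  expect_lt(abs(fit$estimates[["c_XB"]] / p$c_XB - 1), 0.05)
})

test_that("fitting is reproducible under a fixed seed", {
  fx <- make_obs_fixture(8)
  f1 <- fit_parameters(fx$obs, fx$cfg, fx$act, free = c("k_d"),
                       n_starts = 2, seed = 42, maxiter = 10)
  f2 <- fit_parameters(fx$obs, fx$cfg, fx$act, free = c("k_d"),
                       n_starts = 2, seed = 42, maxiter = 10)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$starts, f2$starts)
  expect_error(fit_parameters(fx$obs, fx$cfg, fx$act, free = "k_phantom"),
               "unknown free parameter")
})
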