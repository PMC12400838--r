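# Strain grid, PDE stepping, force and the Monte-Carlo oracle.

zero_rates <- list(k_np = 0, k_pn = 0, kd_eff = 0, k1_eff = 0, k2_eff = 0,
                   km2_eff = 0, k3_eff = 0)

test_that("strain grid is uniform with a node exactly at zero", {
  g <- strain_grid()
  expect_true(all(abs(diff(g$s) - g$ds) < 1e-12))
  expect_identical(g$s[g$i0], 0)
  expect_lt(g$s_min, 0)
  expect_gt(g$s_max, 0)
  expect_error(strain_grid(-0.1, 0.5, 480), "s = 0")
})

test_that("attached fractions integrate densities (rectangle and Gaussian)", {
  g <- strain_grid()
  expect_equal(unname(attached_fractions(xb_state(g, N = 1))), c(0, 0, 0))
  # uniform density of height h over width w integrates to h * w
  h <- 3; w <- 0.1
  p1 <- ifelse(g$s > -0.25 & g$s <= -0.25 + w, h, 0)
  st <- xb_state(g, N = 1 - h * w, p1 = p1)
  expect_equal(unname(attached_fractions(st)[1]), h * w, tolerance = 2e-2)
  # unit-mass Gaussian well inside the grid integrates to 1
  gdens <- stats::dnorm(g$s, mean = -0.15, sd = 0.02)
  st2 <- xb_state(g, N = 0, p2 = gdens)
  expect_equal(unname(attached_fractions(st2)[2]), 1, tolerance = 1e-6)
  # mean strain: quadrature against the closed form
  expect_equal(mean_strain(st2, 2), -0.15, tolerance = g$ds)
  expect_error(mean_strain(st2, 3), "no mass")
})

test_that("force vanishes for empty or symmetric strongly bound densities", {
  g <- strain_grid()
  p <- xb_params()
  expect_equal(compute_force(xb_state(g, N = 1), p)$F_XB, 0)
  # p2 symmetric about 0 (odd integrand), p3 = 0: frictional term cancels
  sym <- stats::dnorm(g$s, 0, 0.01) * 0.1
  sym[g$s < -0.1] <- 0 # keep support symmetric within [-0.1, 0.1]
  sym <- sym * rev(sym > 0) # no-op on symmetric support, keeps clarity
  stsym <- xb_state(g, N = 0.9, p2 = stats::dnorm(g$s, 0, 0.01) *
                      as.numeric(abs(g$s) <= 0.1) * 0.1)
  expect_equal(compute_force(stsym, p)$F_XB, 0, tolerance = 1e-9)
  # unit point mass of p3 at s = 0: only the power-stroke term survives
  p3 <- numeric(g$n_nodes); p3[g$i0] <- 1 / g$ds
  st3 <- xb_state(g, N = 0, p3 = p3)
  expect_equal(compute_force(st3, p)$F_XB, p$k_stiff2 * p$delta_r)
})

test_that("force converts to power linearly in the calibration scale", {
  expect_equal(force_to_power(0, 0.68, 1), 0)
  expect_equal(force_to_power(10, 0.68, 2), 2 * force_to_power(10, 0.68, 1))
  expect_equal(force_to_power(10, -0.68, 0.5), 0.5 * 10 * 0.68)
  expect_error(force_to_power(10, 0.68, 0), "scale")
  # calibrating the scale against a force trace recovers the target power
  F_trace <- c(120, 150, 170, 160)
  target <- 5
  scale <- target / mean(F_trace * 0.68)
  expect_equal(mean(force_to_power(F_trace, 0.68, scale)), target)
})

test_that("null dynamics leave the state unchanged and all-N is absorbing", {
  g <- fast_grid()
  p <- xb_params()
  p$k_a <- 1e-300 # suppress the attachment source as well
  class(p) <- "xb_params"
  st <- xb_state(g, N = 0.4, P = 0.3,
                 p1 = stats::dnorm(g$s, -0.05, 0.02) * 0.3)
  out <- step_pde(st, zero_rates, p, dLdt = 0, dt = 1e-3)
  expect_equal(out$N, st$N)
  expect_equal(out$P, st$P)
  expect_equal(out$p1, st$p1)
  # zero activation from all-N start: no path out of N, zero force
  stN <- xb_state(g, N = 1)
  r0 <- c(zero_rates, list())
  r0$k_pn <- 50 # relaxation path on, activation off
  for (i in 1:50) stN <- step_pde(stN, r0, p, dLdt = -0.68, dt = 1e-3)
  expect_equal(stN$N, 1)
  expect_equal(compute_force(stN, p)$F_total, 0)
})

test_that("N/P gating relaxes to the two-state equilibrium", {
  g <- fast_grid()
  p <- xb_params()
  k_np <- 18; k_pn <- 32
  rates <- zero_rates
  rates$k_np <- k_np; rates$k_pn <- k_pn
  # attachment off: pure two-state chain, closed-form equilibrium
  p0 <- xb_params(); p0$k_a <- 1e-12 # suppress attachment path
  class(p0) <- "xb_params"
  st <- xb_state(g, N = 1)
  dt <- 1e-3
  t_end <- 10 / (k_np + k_pn)
  for (i in seq_len(round(t_end / dt))) st <- step_pde(st, rates, p0, 0, dt)
  expect_equal(st$N, k_pn / (k_np + k_pn), tolerance = 1e-3)
  expect_equal(st$P, k_np / (k_np + k_pn), tolerance = 1e-3)
})

test_that("single steps conserve total probability and enforce CFL", {
  g <- fast_grid()
  p <- xb_params()
  met <- late_exercise_met()
  er <- effective_rates(p, met)
  rates <- c(list(k_np = 25, k_pn = 25), er)
  st <- xb_state(g, N = 0.8, P = 0.2)
  for (i in 1:200) {
    st <- step_pde(st, rates, p, dLdt = -0.68, dt = 1e-3)
    expect_lt(abs(state_probability_sum(st) - 1), 1e-6)
  }
  expect_gt(sum(attached_fractions(st)), 0.01) # bridges actually attached
  expect_error(step_pde(st, rates, p, dLdt = -5, dt = 1e-3), "CFL")
})

test_that("MC oracle reproduces closed-form two-state occupancy", {
  # beta * iemg = k_np, detachment chain disabled via k_a ~ 0
  p <- xb_params(beta = 10)
  p$k_a <- 1e-12; class(p) <- "xb_params"
  met <- late_exercise_met()
  set.seed(99)
  r <- mc_oracle(p, met, iemg = rep(0.3, 3), dLdt = -0.68, T_cyc = 1.6,
                 dt = 1e-3, n_bridges = 2e4)
  pP <- 0.3 # equilibrium open fraction after ~5 gate time constants
  expect_lt(abs(r$fractions[["P"]] - pP), 3 * sqrt(pP * (1 - pP) / 2e4) + 2e-3)
  expect_equal(r$fractions[["A1"]] + r$fractions[["A2"]] + r$fractions[["A3"]], 0)
})

test_that("PDE solver matches the MC oracle under clamped metabolites", {
  # scaled-down equivalence run (the acceptance suite runs the full one)
  p <- xb_params()
  met <- late_exercise_met()
  n_cyc <- 2
  dt <- 5e-4
  cfg <- protocol_config(n_cycles = n_cyc, grid = strain_grid(-0.4, 0.1, 201),
                         dt = dt, resting = met)
  sim <- simulate_exercise(p, cfg, rep(0.45, n_cyc),
                           clamp = c("ATP", "ADP", "Pi", "PCr", "Hp"))
  pde <- unlist(sim$cycles[n_cyc, c("N", "P", "A1", "A2", "A3")])
  set.seed(7)
  mc <- mc_oracle(p, met, rep(0.45, n_cyc), dLdt = -0.68, dt = dt,
                  n_bridges = 2e4, s_min = -0.4, s_max = 0.1)
  for (nm in c("N", "P", "A1", "A2", "A3")) {
    expect_lt(abs(pde[[nm]] - mc$fractions[[nm]]),
              3 * mc$se[[nm]] + 0.002) # 3 SE plus discretization allowance
  }
})
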