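# Protocol: initialization, carry-over, full runs, counterfactuals and
# clamp experiments.

test_that("first cycle starts all-N with resting metabolites", {
  cfg <- fast_config()
  init <- initialize_first_cycle(cfg)
  expect_equal(init$state$N, 1)
  expect_equal(init$state$P, 0)
  expect_equal(state_probability_sum(init$state), 1)
  expect_equal(init$met$ATP, 8.2)
})

test_that("carry-over folds attached mass into P and preserves the total", {
  g <- fast_grid()
  d <- function(m, mass) stats::dnorm(g$s, m, 0.02) * mass
  st <- xb_state(g, N = 0.4, P = 0.2, p1 = d(-0.05, 0.1), p2 = d(-0.1, 0.2),
                 p3 = d(-0.15, 0.1))
  post <- carry_over_state(st)
  expect_equal(post$P, 0.6, tolerance = 1e-6)
  expect_equal(post$N, 0.4)
  expect_equal(sum(attached_fractions(post)), 0)
  expect_equal(state_probability_sum(post), state_probability_sum(st),
               tolerance = 1e-12)
  # an all-N end state is unchanged
  stN <- xb_state(g, N = 1)
  expect_equal(carry_over_state(stN)$N, 1)
  expect_equal(carry_over_state(stN)$P, 0)
})

test_that("a single zero-activation cycle produces no force and holds a resting fixed point", {
  # the zero-ADP, zero-Pi rest state is the exact fixed point of the
  # metabolite system; with no activation nothing moves
  rest <- metabolite_state(ADP = 0, Pi = 0)
  cfg <- fast_config(n_cycles = 1, resting = rest)
  sim <- simulate_exercise(xb_params(), cfg, 0)
  expect_equal(sim$cycles$mean_force, 0)
  expect_equal(sim$cycles$Pi, 0)
  expect_equal(sim$cycles$PCr, rest$PCr)
  expect_equal(sim$cycles$N, 1)
})

test_that("probability is conserved and metabolites continuous across cycles", {
  p <- xb_params()
  cfg <- fast_config(n_cycles = 30)
  sim <- simulate_exercise(p, cfg, fast_activation(30))
  expect_lt(sim$diagnostics$max_conservation_error, 1e-6)
  expect_true(all(abs(sim$cycles$prob_sum - 1) < 1e-6))
  # continuity: restarting from the recorded mid-run state reproduces the
  # remainder of the run exactly (metabolites and cross-bridge state carry)
  first <- simulate_exercise(p, fast_config(n_cycles = 15),
                             fast_activation(30)[1:15])
  second <- simulate_exercise(p, fast_config(n_cycles = 15),
                              fast_activation(30)[16:30],
                              init = list(state = first$final_state,
                                          met = first$final_met),
                              carry_first = TRUE)
  expect_equal(second$cycles$Pi, sim$cycles$Pi[16:30], tolerance = 1e-12)
  expect_equal(second$cycles$mean_force, sim$cycles$mean_force[16:30],
               tolerance = 1e-12)
})

test_that("simulation is deterministic", {
  p <- xb_params()
  cfg <- fast_config(n_cycles = 8)
  a <- fast_activation(8)
  s1 <- simulate_exercise(p, cfg, a)
  s2 <- simulate_exercise(p, cfg, a)
  expect_identical(s1$cycles, s2$cycles)
})

test_that("metabolite trajectories have the exercise-onset shapes", {
  p <- xb_params()
  cfg <- protocol_config(n_cycles = 120, grid = fast_grid(), dt = 1e-3)
  sim <- simulate_exercise(p, cfg, gen_activation(synthetic_spec(n_cycles = 120)))
  cc <- sim$cycles
  third <- nrow(cc) %/% 3
  # PCr falls, steeply early and more slowly late
  drop_early <- cc$PCr[1] - cc$PCr[third]
  drop_late <- cc$PCr[2 * third] - cc$PCr[nrow(cc)]
  expect_gt(drop_early, 0)
  expect_gt(drop_early, drop_late)
  # Pi rises from rest toward a plateau: the late change is a small
  # fraction of the early rise
  rise_early <- cc$Pi[third] - cc$Pi[1]
  expect_gt(rise_early, 0)
  expect_lt(abs(cc$Pi[nrow(cc)] - cc$Pi[2 * third]), rise_early)
  # ADP and H+ rise over the exercise (the H+ amplitude is small because
  # the default buffering keeps pH near rest)
  expect_gt(cc$ADP[nrow(cc)], cc$ADP[1])
  expect_gt(10^(-cc$pH[nrow(cc)]), 10^(-cc$pH[1]))
})

test_that("force builds up within the first cycle from the all-N start", {
  p <- xb_params()
  cfg <- fast_config(n_cycles = 3)
  sim <- simulate_exercise(p, cfg, rep(0.36, 3), record_dense = 1)
  first <- sim$dense[sim$dense$cycle == 1, ]
  n1 <- nrow(first)
  # force starts near zero and grows as bridges leave the N state
  expect_lt(first$F_total[5], 0.2 * max(first$F_total))
  expect_gt(first$F_total[n1], 0.5 * max(first$F_total))
  # the first cycle's mean force is depressed relative to the second
  expect_lt(sim$cycles$mean_force[1], sim$cycles$mean_force[2])
})

test_that("constant-activation counterfactual generates less late force", {
  p <- xb_params()
  cfg <- protocol_config(n_cycles = 60, grid = fast_grid(), dt = 1e-3)
  act <- gen_activation(synthetic_spec(n_cycles = 60))
  cmp <- run_constant_activation(p, cfg, act)
  late <- 31:60
  expect_lt(mean(cmp$constant$cycles$mean_force[late]),
            mean(cmp$ramp$cycles$mean_force[late]))
  # identical first-cycle outputs (same initial iEMG)
  expect_equal(cmp$constant$cycles$mean_force[1],
               cmp$ramp$cycles$mean_force[1], tolerance = 1e-12)
  # a constant input trace gives an identical pair
  cmp2 <- run_constant_activation(p, fast_config(n_cycles = 5), rep(0.4, 5))
  expect_identical(cmp2$ramp$cycles, cmp2$constant$cycles)
})

test_that("metabolite clamp sweeps reproduce the reported force directions", {
  p <- xb_params()
  cfg <- protocol_config(n_cycles = 40, grid = fast_grid(), dt = 1e-3)
  base <- simulate_exercise(p, cfg, gen_activation(synthetic_spec(n_cycles = 40)))
  fac <- c(1, 1.5, 2)
  # factor 1 reproduces the continued baseline; extension length is 10%
  pert <- run_metabolite_perturbation(p, cfg, base, "Pi", factors = fac)
  expect_equal(nrow(pert), 3)
  expect_true(all(diff(pert$normalized_force) < 0))   # Pi strictly inhibits
  adp <- run_metabolite_perturbation(p, cfg, base, "ADP", factors = fac)
  # marginal potentiation: positive but small (strict monotonicity of the
  # sweep is asserted on the longer acceptance fixture)
  expect_gt(adp$normalized_force[3], adp$normalized_force[1])
  expect_lt(adp$normalized_force[3] / adp$normalized_force[1] - 1, 0.05)
  hp <- run_metabolite_perturbation(p, cfg, base, "Hp", factors = fac)
  expect_lt(abs(hp$normalized_force[3] / hp$normalized_force[1] - 1), 0.01)
  expect_error(run_metabolite_perturbation(p, cfg, base, "lactate"),
               "unknown species")
})

test_that("the A2-release proton mechanism makes acidosis inhibitory", {
  pv <- xb_params(mechanism = "A2_release")
  cfg <- protocol_config(n_cycles = 40, grid = fast_grid(), dt = 1e-3)
  base <- simulate_exercise(pv, cfg, gen_activation(synthetic_spec(n_cycles = 40)))
  hp <- run_metabolite_perturbation(pv, cfg, base, "Hp", factors = c(1, 1.5, 2))
  expect_true(all(diff(hp$normalized_force) < 0))
})

test_that("steady-cycle force is non-increasing in clamped Pi", {
  p <- xb_params()
  forces <- vapply(c(0, 10, 20, 30, 40), function(Pi_mM) {
    met <- metabolite_state(ATP = 8.2, ADP = 0.02, Pi = Pi_mM, PCr = 15,
                            pH = 7.0)
    cfg <- fast_config(n_cycles = 6, resting = met)
    sim <- simulate_exercise(p, cfg, rep(0.5, 6),
                             clamp = c("ATP", "ADP", "Pi", "PCr", "Hp"))
    sim$cycles$mean_force[6]
  }, numeric(1))
  expect_true(all(diff(forces) <= 0))
})

test_that("the half-cycle waveform runs and respects CFL accounting", {
  cfg <- protocol_config(n_cycles = 4, grid = fast_grid(), dt = 1e-3,
                         velocity_waveform = "half_cycle")
  sim <- simulate_exercise(xb_params(), cfg, rep(0.5, 4))
  expect_lt(sim$diagnostics$max_conservation_error, 1e-6)
  expect_error(protocol_config(grid = fast_grid(), dt = 2e-3,
                               velocity_waveform = "half_cycle", duty = 0.25),
               "CFL")
})
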