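# Exercise protocol: cyclic simulation with carry-over, counterfactuals and
# metabolite clamp experiments.

#' Protocol configuration
#'
#' Describes the repeated plantar-flexion protocol: cycle period, number of
#' cycles, sarcomere sliding speed and waveform, numerical resolution, the
#' resting metabolite state and the force-to-power calibration.
#'
#' @param T_cyc cycle duration (s), default 1.6
#' @param n_cycles number of cycles, default 240
#' @param dLdt sarcomere sliding velocity magnitude (um/s), default 0.68
#' @param duty active fraction of each cycle, default 0.5 (used by the
#'   `half_cycle` waveform)
#' @param velocity_waveform `"constant"` (velocity `dLdt` applied through the
#'   whole cycle; default) or `"half_cycle"` (`dLdt/duty` during the active
#'   fraction, reversed during relaxation so that net displacement is zero)
#' @param resting resting [metabolite_state()] used to initialize cycle 1
#' @param grid [strain_grid()] for the attached-state densities
#' @param dt time step (s), default 2.5e-4; must satisfy the CFL bound for the
#'   chosen grid and waveform
#' @param power_scale calibration constant of [force_to_power()]
#' @param target_power required task power (W); the normalizing "force
#'   required to move the piston" is `target_power / (power_scale * dLdt)`
#' @param cycles_per_10s mapping between wall-clock observations and cycle
#'   index, default 6.3
#' @param F_pee constant parallel-elastic force offset (mN/mm^2), default 0
#' @return object of class `protocol_config`
#' @export
protocol_config <- function(T_cyc = 1.6, n_cycles = 240, dLdt = 0.68,
                            duty = 0.5,
                            velocity_waveform = c("constant", "half_cycle"),
                            resting = metabolite_state(),
                            grid = strain_grid(), dt = 2.5e-4,
                            power_scale = 0.045, target_power = 5,
                            cycles_per_10s = 6.3, F_pee = 0) {
  velocity_waveform <- match.arg(velocity_waveform)
  stopifnot(T_cyc > 0, n_cycles >= 1, duty > 0, duty <= 1, dt > 0,
            power_scale > 0, target_power > 0)
  if (is.null(resting)) stop("config error: resting metabolite state missing")
  spc <- round(T_cyc / dt)
  if (abs(spc * dt - T_cyc) > 1e-9) {
    stop("dt must divide T_cyc into an integer number of steps")
  }
  cfg <- structure(list(
    T_cyc = T_cyc, n_cycles = as.integer(n_cycles), dLdt = dLdt, duty = duty,
    velocity_waveform = velocity_waveform, resting = resting, grid = grid,
    dt = dt, steps_per_cycle = as.integer(spc), power_scale = power_scale,
    target_power = target_power, cycles_per_10s = cycles_per_10s,
    F_pee = F_pee
  ), class = "protocol_config")
  v <- .velocity_profile(cfg)
  if (max(abs(v)) * dt > grid$ds * (1 + 1e-12)) {
    stop(sprintf(
      "CFL violation: max |velocity| * dt = %.3g um exceeds ds = %.3g um; use dt <= %.3g s",
      max(abs(v)) * dt, grid$ds, grid$ds / max(abs(v))))
  }
  cfg
}

# Per-step advection velocity over one cycle. A positive shortening speed
# dLdt drives the strain of attached bridges negative, so the PDE advection
# velocity is -dLdt.
.velocity_profile <- function(config) {
  spc <- config$steps_per_cycle
  if (config$velocity_waveform == "constant") {
    rep(-config$dLdt, spc)
  } else {
    n_act <- max(1L, round(config$duty * spc))
    v_act <- -config$dLdt / config$duty
    v_rel <- -v_act * n_act / max(1L, spc - n_act)
    c(rep(v_act, n_act), rep(v_rel, spc - n_act))
  }
}

#' Required (normalizing) force of a protocol
#'
#' The force needed to deliver `target_power` at the configured sliding
#' speed and power calibration; used to normalize simulated force.
#' @param config a `protocol_config`
#' @return force (mN/mm^2)
#' @export
required_force <- function(config) {
  config$target_power / (config$power_scale * abs(config$dLdt))
}

#' Initialize the first exercise cycle
#'
#' All cross-bridges start in the non-permissible state (N = 1, everything
#' else 0) and the metabolites at their resting values.
#'
#' @param config a [protocol_config()]
#' @return list with `state` (an `xb_state`) and `met` (a `metabolite_state`)
#' @export
initialize_first_cycle <- function(config) {
  list(state = xb_state(config$grid, N = 1, P = 0), met = config$resting)
}

#' Carry the cross-bridge state over a cycle boundary
#'
#' At the start of each new cycle the attached populations are folded back
#' into the permissible pool: `P(t0) = A1 + A2 + A3 + P(tf)`, densities reset
#' to zero, `N` unchanged. The total probability is preserved exactly.
#'
#' @param prev `xb_state` at the end of the previous cycle
#' @return `xb_state` at the start of the next cycle
#' @export
carry_over_state <- function(prev) {
  att <- attached_fractions(prev)
  xb_state(prev$grid, N = prev$N, P = prev$P + sum(att))
}

#' Simulate the cyclic exercise protocol
#'
#' Runs `config$n_cycles` cycles: per cycle the constant normalized iEMG sets
#' the troponin gating rates, the strain-resolved cross-bridge PDE advances
#' with the configured velocity waveform, and the metabolite ODEs are
#' integrated continuously across cycles (final concentrations carried
#' forward); the cross-bridge state is carried over per cycle. The run is
#' fully deterministic.
#'
#' @param params an [xb_params()]
#' @param config a [protocol_config()]
#' @param activation numeric vector of per-cycle normalized iEMG values in
#'   \[0, 1\]; length must equal `config$n_cycles`
#' @param init optional list(state, met) to continue from (default:
#'   [initialize_first_cycle()])
#' @param clamp optional logical/character clamp of metabolite species whose
#'   derivatives are zeroed (names among ATP, ADP, Pi, PCr, Hp)
#' @param carry_first apply the cycle-boundary carry-over before the first
#'   simulated cycle (used when continuing a finished run)
#' @param record_dense if > 0, keep the dense force/power trace thinned by
#'   this factor
#' @return object of class `xb_sim`: `cycles` data frame of per-cycle
#'   summaries (mean/peak force, mean power, normalized force, end-of-cycle
#'   state fractions and metabolites), `final_state`, `final_met`,
#'   `diagnostics`, and optionally `dense`
#' @export
simulate_exercise <- function(params, config, activation, init = NULL,
                              clamp = NULL, carry_first = FALSE,
                              record_dense = 0) {
  validate_params(params)
  if (length(activation) != config$n_cycles) {
    stop("activation length (", length(activation),
         ") must equal n_cycles (", config$n_cycles, ")")
  }
  activation_rates(params$beta, activation) # validates range, names cycle
  if (is.null(init)) init <- initialize_first_cycle(config)
  st <- init$state
  met <- init$met
  clamp_mask <- rep(FALSE, 5)
  names(clamp_mask) <- c("ATP", "ADP", "Pi", "PCr", "Hp")
  if (!is.null(clamp)) {
    if (is.logical(clamp) && length(clamp) == 5) clamp_mask[] <- clamp
    else clamp_mask[match.arg(clamp, names(clamp_mask), several.ok = TRUE)] <- TRUE
  }
  g <- config$grid
  vstep <- .velocity_profile(config)
  pH_ref <- met_pH(config$resting)
  r <- cpp_simulate(.pack_params(params), .mechanism_code(params),
                    g$s, g$i0 - 1L, g$ds, st$N, st$P, st$p1, st$p2, st$p3,
                    .met_vector(met), activation, vstep, config$dt, pH_ref,
                    clamp_mask, carry_first, config$F_pee,
                    config$power_scale, as.integer(record_dense))
  F_req <- required_force(config)
  cycles <- data.frame(
    cycle = seq_len(config$n_cycles), iemg = activation,
    mean_force = r$mean_F, peak_force = r$peak_F, mean_power = r$mean_power,
    normalized_force = r$mean_F / F_req,
    N = r$N, P = r$P, A1 = r$A1, A2 = r$A2, A3 = r$A3,
    ATP = r$ATP, ADP = r$ADP, Pi = r$Pi, PCr = r$PCr,
    pH = -log10(r$Hp * 1e-3), prob_sum = r$prob_sum
  )
  fm <- r$final_met
  out <- structure(list(
    cycles = cycles,
    final_state = xb_state(g, N = r$final_N, P = r$final_P,
                           p1 = r$final_p1, p2 = r$final_p2, p3 = r$final_p3),
    final_met = metabolite_state(ATP = fm[1], ADP = fm[2], Pi = fm[3],
                                 PCr = fm[4], Hp = fm[5],
                                 PCr_0 = params$PCr_0),
    diagnostics = list(
      max_conservation_error = r$max_conservation_error,
      clamp_total = r$clamp_total,
      boundary_to_P_total = r$boundary_to_P_total
    ),
    params = params, config = config, activation = activation
  ), class = "xb_sim")
  if (record_dense > 0) out$dense <- as.data.frame(r$dense)
  out
}

#' @export
print.xb_sim <- function(x, ...) {
  n <- nrow(x$cycles)
  cat(sprintf("<xb_sim> %d cycles of %.3g s (dt = %.3g s)\n",
              n, x$config$T_cyc, x$config$dt))
  cat(sprintf("  final cycle: mean force %.4g mN/mm^2 (normalized %.3g), Pi %.3g mM, PCr %.3g mM, pH %.3f\n",
              x$cycles$mean_force[n], x$cycles$normalized_force[n],
              x$cycles$Pi[n], x$cycles$PCr[n], x$cycles$pH[n]))
  cat(sprintf("  max |probability sum - 1| = %.2e\n",
              x$diagnostics$max_conservation_error))
  invisible(x)
}

#' Constant-activation counterfactual
#'
#' Re-runs the protocol with the normalized iEMG frozen at the first cycle's
#' value, for contrast with the measured (ramping) activation: without the
#' progressive recruitment the model cannot sustain the required force.
#'
#' @inheritParams simulate_exercise
#' @return list with elements `ramp` and `constant`, both `xb_sim`
#' @export
run_constant_activation <- function(params, config, activation) {
  ramp <- simulate_exercise(params, config, activation)
  const <- simulate_exercise(params, config,
                             rep(activation[1], length(activation)))
  list(ramp = ramp, constant = const)
}

#' Metabolite clamp (perturbation) experiment
#'
#' Continues a finished baseline run for an additional
#' `extra_fraction * n_cycles` cycles per factor, with the chosen species
#' held at `factor` times its end-of-baseline concentration and all
#' metabolite derivatives zeroed (see [clamp_controller()]). Activation stays
#' at the last baseline value. Records the end-of-extension cycle-mean force
#' normalized by the required force.
#'
#' @param params an `xb_params`
#' @param config the baseline `protocol_config`
#' @param baseline a completed `xb_sim` from [simulate_exercise()]; if
#'   missing it is run here
#' @param species metabolite to scale ("ATP", "ADP", "Pi", "PCr" or "Hp")
#' @param factors concentration multipliers (default seq(1, 2, by = 0.25))
#' @param extra_fraction extension length as a fraction of `n_cycles`
#'   (default 0.1, i.e. 24 extra cycles for the default 240)
#' @return data frame (species, factor, concentration, mean_force,
#'   normalized_force) with one row per factor
#' @export
run_metabolite_perturbation <- function(params, config, baseline = NULL,
                                        species = "Pi",
                                        factors = seq(1, 2, by = 0.25),
                                        extra_fraction = 0.1) {
  if (is.null(baseline)) {
    baseline <- simulate_exercise(params, config, gen_activation(
      synthetic_spec(n_cycles = config$n_cycles)))
  }
  n_extra <- max(1L, round(extra_fraction * config$n_cycles))
  iemg_last <- baseline$activation[length(baseline$activation)]
  ext_cfg <- config
  ext_cfg$n_cycles <- n_extra
  out <- lapply(factors, function(f) {
    cl <- clamp_controller(baseline$final_met, species, scale = f)
    sim <- simulate_exercise(params, ext_cfg, rep(iemg_last, n_extra),
                             init = list(state = baseline$final_state,
                                         met = cl$met),
                             clamp = cl$clamp, carry_first = TRUE)
    nlast <- nrow(sim$cycles)
    data.frame(species = species, factor = f,
               concentration = cl$met[[species]],
               mean_force = sim$cycles$mean_force[nlast],
               normalized_force = sim$cycles$normalized_force[nlast])
  })
  do.call(rbind, out)
}
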