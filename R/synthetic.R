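# Synthetic study inputs: activation ramps, resting states and noisy
# pseudo-observations for parameter-recovery experiments.

#' Synthetic study specification
#'
#' Describes the emulated exercise study: a monotone normalized-iEMG ramp
#' (36% to 60% over 240 cycles, matching the measured group average), an
#' observation interval of 10 s (the spectroscopy sampling), and Gaussian
#' observation noise with a relative SD per series (default 5%).
#'
#' @param n_cycles number of cycles (default 240)
#' @param iemg_start,iemg_end ramp endpoints in \[0, 1\] (defaults 0.36, 0.60)
#' @param ramp `"linear"` or `"saturating"` (exponential approach)
#' @param noise_sd relative observation noise SD; a single value or a named
#'   vector per series (power, Pi, ADP, PCr, pH)
#' @param jitter_sd SD of optional clipped Gaussian cycle-to-cycle activation
#'   jitter (0 = none)
#' @param obs_interval_s observation sampling interval (s)
#' @param seed RNG seed for noise/jitter
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_cycles = 240, iemg_start = 0.36, iemg_end = 0.60,
                           ramp = c("linear", "saturating"), noise_sd = 0.05,
                           jitter_sd = 0, obs_interval_s = 10, seed = 1) {
  ramp <- match.arg(ramp)
  stopifnot(iemg_start >= 0, iemg_end <= 1, iemg_start <= iemg_end,
            all(noise_sd >= 0), jitter_sd >= 0, n_cycles >= 1)
  structure(list(n_cycles = as.integer(n_cycles), iemg_start = iemg_start,
                 iemg_end = iemg_end, ramp = ramp, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, obs_interval_s = obs_interval_s,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a per-cycle activation trace
#'
#' Monotone ramp from `iemg_start` to `iemg_end` over `n_cycles` with the
#' chosen shape, plus optional clipped Gaussian jitter; deterministic under
#' the spec's seed.
#'
#' @param spec a [synthetic_spec()]
#' @return numeric vector of per-cycle iEMG values in \[0, 1\]
#' @export
gen_activation <- function(spec) {
  n <- spec$n_cycles
  u <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  shape <- if (spec$ramp == "saturating") (1 - exp(-3 * u)) / (1 - exp(-3)) else u
  tr <- spec$iemg_start + (spec$iemg_end - spec$iemg_start) * shape
  if (spec$jitter_sd > 0) {
    set.seed(spec$seed)
    tr <- tr + stats::rnorm(n, 0, spec$jitter_sd)
    tr <- pmin(pmax(tr, 0), 1)
  }
  tr
}

#' Generate a resting metabolite state
#'
#' Defaults: ATP 8.2 mM (the conventional resting reference), Pi 4.0 mM and
#' ADP 8 uM (mid-range of resting values), pH 7.05 and PCr 33 mM (synthetic
#' defaults chosen to sit in the physiological resting range; not taken from
#' any measured table).
#'
#' @param ... overrides passed to [metabolite_state()]
#' @return a `metabolite_state`
#' @export
gen_resting_state <- function(...) {
  metabolite_state(...)
}

#' Generate noisy pseudo-observations from a forward simulation
#'
#' Simulates the protocol, samples power, Pi, ADP, PCr and pH at the
#' observation interval (mapped to cycles via [map_time_to_cycles()]), and
#' adds seeded multiplicative Gaussian noise with the per-series relative
#' SDs. Returns the observations together with the generating truth, for
#' parameter-recovery experiments.
#'
#' @param params generating [xb_params()]
#' @param config [protocol_config()]
#' @param activation per-cycle iEMG trace
#' @param spec a [synthetic_spec()] (noise SDs, interval, seed)
#' @return list with `obs` (an [observation_set()] including `*_sd` columns),
#'   `truth` (the generating parameters) and `sim` (the noiseless run)
#' @export
gen_observations <- function(params, config, activation, spec) {
  sim <- simulate_exercise(params, config, activation)
  t_obs <- seq(spec$obs_interval_s, config$n_cycles * config$T_cyc,
               by = spec$obs_interval_s)
  cyc <- map_time_to_cycles(t_obs, config$cycles_per_10s)
  cyc <- unique(pmin(pmax(cyc, 1L), config$n_cycles))
  idx <- match(cyc, sim$cycles$cycle)
  series <- c("power", "Pi", "ADP", "PCr", "pH")
  sd_of <- function(sn) {
    if (length(spec$noise_sd) > 1) {
      if (!sn %in% names(spec$noise_sd)) 0 else spec$noise_sd[[sn]]
    } else spec$noise_sd
  }
  truth_vals <- list(power = sim$cycles$mean_power[idx],
                     Pi = sim$cycles$Pi[idx], ADP = sim$cycles$ADP[idx],
                     PCr = sim$cycles$PCr[idx], pH = sim$cycles$pH[idx])
  set.seed(spec$seed)
  df <- data.frame(cycle = cyc, time_s = t_obs[seq_along(cyc)])
  for (sn in series) {
    v <- truth_vals[[sn]]
    sdr <- sd_of(sn)
    noise <- if (sdr > 0) stats::rnorm(length(v), 0, sdr) else 0
    df[[sn]] <- v * (1 + noise)
    if (sdr > 0) df[[paste0(sn, "_sd")]] <- sdr * abs(v)
  }
  list(obs = observation_set(df, config$cycles_per_10s), truth = params,
       sim = sim)
}
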