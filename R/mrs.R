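# Measurement-side derivations: 31P-MRS metabolite calculations, muscle
# geometry, sarcomere shortening velocity and the critical-power fit.

#' Diprotonated phosphate concentration
#'
#' `[H2PO4-] = [Pi] / (1 + 10^(pH - 6.75))`: the acid fraction of total
#' inorganic phosphate at the given pH (pK 6.75).
#'
#' @param Pi total inorganic phosphate (mM), >= 0
#' @param pH intracellular pH
#' @return \[H2PO4-\] (mM)
#' @export
h2po4 <- function(Pi, pH) {
  stopifnot(all(Pi >= 0))
  Pi / (1 + 10^(pH - 6.75))
}

#' Free cytosolic ADP from the creatine-kinase equilibrium
#'
#' `ADP = ATP * Cr / (K_CK * PCr * [H+])` with `Cr = total_Cr - PCr` and
#' `[H+] = 10^-pH` (molar). The default equilibrium constant is
#' K_CK = 1.66e9 1/M; at rest PCr is conventionally taken as 85% of the
#' total creatine pool.
#'
#' @param ATP mM
#' @param PCr mM, > 0
#' @param pH intracellular pH
#' @param K_CK creatine-kinase equilibrium constant (1/M)
#' @param total_Cr total creatine pool (mM); default `PCr / 0.85`
#' @return free ADP (mM)
#' @export
adp_from_ck_equilibrium <- function(ATP, PCr, pH, K_CK = 1.66e9,
                                    total_Cr = PCr / 0.85) {
  stopifnot(all(PCr > 0))
  if (any(PCr >= total_Cr + 1e-12)) {
    stop("invalid pool: PCr must be below total creatine away from rest")
  }
  Cr <- total_Cr - PCr
  H <- 10^(-pH) # M
  # ATP, PCr, Cr in mM cancel except one mM factor; result back in mM
  ATP * Cr / (K_CK * 1e-3 * PCr * H) * 1e-3
}

#' Free AMP from the adenylate-kinase equilibrium
#'
#' `AMP = K_eq * ADP^2 / ATP`.
#'
#' @param ATP mM, > 0
#' @param ADP mM
#' @param K_eq adenylate-kinase equilibrium constant (dimensionless, default 1;
#'   supply a Mg2+/pH-corrected value if available)
#' @return AMP (mM)
#' @export
amp_from_adk_equilibrium <- function(ATP, ADP, K_eq = 1) {
  stopifnot(all(ATP > 0))
  K_eq * ADP^2 / ATP
}

#' Fascicle length from ultrasound measurements
#'
#' `FL = visible + h / sin(PA)`: the visible fascicle segment extended to the
#' deep aponeurosis using the pennation angle.
#'
#' @param visible visible fascicle length
#' @param h vertical distance from the visible fascicle end to the deep
#'   aponeurosis (same units)
#' @param PA pennation angle (degrees), 0 < PA <= 90
#' @return fascicle length (same units as inputs)
#' @export
fascicle_length <- function(visible, h, PA) {
  stopifnot(all(visible > 0), all(h >= 0))
  if (any(PA <= 0) || any(PA > 90)) {
    stop("pennation angle must lie in (0, 90] degrees")
  }
  visible + h / sin(PA * pi / 180)
}

#' Sarcomere shortening velocity
#'
#' `dL/dt = dFL / (N_sar * T_cyc)` for a fascicle-level length change, or
#' `dFL / T_cyc` when `dFL` is already per sarcomere.
#'
#' @param dFL fascicle (or per-sarcomere) length change (um)
#' @param T_cyc cycle duration (s), > 0
#' @param N_sar number of sarcomeres in series (default 17600)
#' @param per_sarcomere is `dFL` already a per-sarcomere length change?
#' @return shortening velocity (um/s)
#' @export
shortening_velocity <- function(dFL, T_cyc, N_sar = 17600,
                                per_sarcomere = FALSE) {
  stopifnot(all(T_cyc > 0))
  if (per_sarcomere) dFL / T_cyc else dFL / (N_sar * T_cyc)
}

#' Critical power and W' from power-duration trials
#'
#' Ordinary least squares of the hyperbolic power-duration relationship in
#' its linearized form `P = W' (1/t) + CP`: the slope is the finite work
#' capacity W' (J) and the intercept the critical power CP (W).
#'
#' @param P trial power outputs (W)
#' @param t times to task failure (s), > 0, not all equal
#' @return object of class `critical_power_fit` with `CP`, `W_prime`,
#'   fitted values and residuals
#' @export
fit_critical_power <- function(P, t) {
  stopifnot(length(P) == length(t), length(P) >= 2, all(t > 0))
  if (length(unique(t)) < 2) {
    stop("singular fit: all trial durations are equal")
  }
  inv_t <- 1 / t
  fit <- stats::lm(P ~ inv_t)
  structure(list(
    CP = unname(stats::coef(fit)[1]),
    W_prime = unname(stats::coef(fit)[2]),
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    trials = data.frame(P = P, t = t)
  ), class = "critical_power_fit")
}

#' @export
print.critical_power_fit <- function(x, ...) {
  cat(sprintf("<critical_power_fit> CP = %.4g W, W' = %.4g J (%d trials)\n",
              x$CP, x$W_prime, nrow(x$trials)))
  invisible(x)
}

#' Map wall-clock time to cycle index
#'
#' `round(time_s * cycles_per_10s / 10)`, floored at 1 for positive times
#' (an observation inside the first cycle belongs to cycle 1).
#'
#' @param time_s time since exercise onset (s), >= 0
#' @param cycles_per_10s cycles executed per 10 s (default 6.3)
#' @return integer cycle indices
#' @export
map_time_to_cycles <- function(time_s, cycles_per_10s = 6.3) {
  stopifnot(all(time_s >= 0))
  idx <- round(time_s * cycles_per_10s / 10)
  as.integer(ifelse(time_s > 0, pmax(idx, 1), 0))
}

#' Intracellular pH from the Pi-PCr chemical shift (optional helper)
#'
#' Conventional Henderson-Hasselbalch form of the phosphate titration curve,
#' `pH = pK + log10((delta - delta_min) / (delta_max - delta))`. The
#' constants are the conventional 31P-MRS calibration values and are
#' exposed as arguments; they are not part of the fitted model.
#'
#' @param delta chemical shift difference between Pi and PCr (ppm)
#' @param pK,delta_min,delta_max calibration constants (defaults 6.75, 3.27,
#'   5.69 ppm)
#' @return pH
#' @export
ph_from_shift <- function(delta, pK = 6.75, delta_min = 3.27,
                          delta_max = 5.69) {
  if (any(delta <= delta_min) || any(delta >= delta_max)) {
    stop("chemical shift outside the titration range (",
         delta_min, ", ", delta_max, ") ppm")
  }
  pK + log10((delta - delta_min) / (delta_max - delta))
}
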