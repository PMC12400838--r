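# Model parameters and algebraic rate laws.
#
# Internal unit system: concentrations in mM, strain in um, time in s.
# The human parameter table mixes units (K_ATP and K_H+ in uM, s_3 in nm);
# constructors take table units and convert once, so every downstream
# computation sees a single consistent system.

# table-unit -> internal-unit conversion factors, keyed by field
.table_unit_scale <- c(K_ATP = 1e-3, K_Hp = 1e-3, s_3 = 1e-3)

.param_fields <- c(
  "k_a", "k_d", "k_1", "k_m1", "k_2", "k_m2", "k_3",
  "alpha_1", "alpha_2", "alpha_3", "s_3",
  "K_ATP", "K_ADP", "K_Pi", "K_Hp",
  "k_stiff1", "k_stiff2", "delta_r", "beta",
  "k_CKf", "k_CKr", "k_Gly", "k_Pi_dil", "k_adk",
  "gamma", "PCr_0", "c_XB"
)

# the 23 estimable kinetic parameters (the 22 tabulated + beta)
.estimable_params <- c(
  "k_a", "k_d", "k_1", "k_m1", "k_2", "k_m2", "k_3",
  "alpha_1", "alpha_2", "alpha_3", "s_3",
  "K_ATP", "K_ADP", "K_Pi", "K_Hp", "k_stiff1", "k_stiff2",
  "k_CKf", "k_CKr", "k_Gly", "k_Pi_dil", "k_adk", "beta"
)

#' Cross-bridge and energetics model parameters
#'
#' Builds the full parameter set of the five-state cross-bridge model and its
#' coupled energetics. Defaults are the best-fit human values (plantar-flexion
#' exercise, n = 5 subjects); arguments are given in the units of that table
#' (\code{K_ATP}, \code{K_Hp} in uM, \code{s_3} in nm, everything else
#' mM/um/s based) and converted internally to a single mM/um/s system.
#'
#' @param k_a attachment rate P -> A1 (1/s)
#' @param k_d detachment rate A1 -> P, Pi-gated (1/s)
#' @param k_1,k_m1 forward/backward A1 <-> A2 rates (1/s)
#' @param k_2,k_m2 ratcheting/unratcheting A2 <-> A3 rates (1/s)
#' @param k_3 detachment rate A3 -> P, ATP-gated (1/s)
#' @param alpha_1,alpha_2,alpha_3 strain-sensitivity coefficients (1/um)
#' @param s_3 strain offset at which the A3 detachment kernel is minimal (nm)
#' @param K_ATP,K_Hp dissociation constants (uM)
#' @param K_ADP,K_Pi dissociation constants (mM)
#' @param k_stiff1,k_stiff2 stiffness constants (mN mm^-2 um^-1)
#' @param delta_r effective power-stroke displacement of the ratcheted state
#'   (um); not tabulated in the source data. Default 0.30 um, chosen once so
#'   that with the tabulated stiffness ratio the power-stroke term dominates
#'   the frictional strain term at the default shortening speed (net force
#'   positive, phosphate strongly inhibitory, ADP marginally potentiating,
#'   protons near-neutral under the base mechanism); see the methods vignette
#' @param beta activation rate scale multiplying the normalized iEMG (1/s);
#'   the 23rd estimable parameter. Default 0.2/s: the troponin gate then
#'   equilibrates over a few cycles, which reproduces the multi-cycle
#'   force build-up observed from the all-N start (see the methods vignette)
#' @param k_CKf,k_CKr creatine-kinase rate constants (1/mM/s)
#' @param k_Gly glycolysis rate constant (1/mM/s)
#' @param k_Pi_dil Pi dilution/export rate (1/s)
#' @param k_adk adenylate-kinase rate constant (1/mM/s)
#' @param gamma proton buffering capacity (mM/s per pH unit)
#' @param PCr_0 initial phosphocreatine concentration, reference for the
#'   creatine pool (mM)
#' @param c_XB myosin-site concentration converting cross-bridge cycling flux
#'   (fraction/s) into mM/s of ATP hydrolysis
#' @param mechanism proton-release mechanism: \code{"A3_release"} (protons
#'   modulate ADP retention at A3; default) or \code{"A2_release"} (proton
#'   dissociation gates the A2 -> A3 ratcheting)
#' @return an object of class \code{xb_params}: a named list in internal units
#' @export
xb_params <- function(k_a = 3.6, k_d = 39.7, k_1 = 13.4, k_m1 = 11.8,
                      k_2 = 16.7, k_m2 = 18.9, k_3 = 18.7,
                      alpha_1 = 36.6, alpha_2 = 171.8, alpha_3 = 80.1,
                      s_3 = 2.0, K_ATP = 5956.2, K_ADP = 0.06, K_Pi = 21.2,
                      K_Hp = 0.292, k_stiff1 = 87091.4, k_stiff2 = 28173,
                      delta_r = 0.30, beta = 0.2,
                      k_CKf = 0.43, k_CKr = 0.0026, k_Gly = 0.26,
                      k_Pi_dil = 0.004, k_adk = 28.3,
                      gamma = 20, PCr_0 = 33, c_XB = 0.4,
                      mechanism = c("A3_release", "A2_release")) {
  mechanism <- match.arg(mechanism)
  vals <- list(
    k_a = k_a, k_d = k_d, k_1 = k_1, k_m1 = k_m1, k_2 = k_2, k_m2 = k_m2,
    k_3 = k_3, alpha_1 = alpha_1, alpha_2 = alpha_2, alpha_3 = alpha_3,
    s_3 = s_3, K_ATP = K_ATP, K_ADP = K_ADP, K_Pi = K_Pi, K_Hp = K_Hp,
    k_stiff1 = k_stiff1, k_stiff2 = k_stiff2, delta_r = delta_r, beta = beta,
    k_CKf = k_CKf, k_CKr = k_CKr, k_Gly = k_Gly, k_Pi_dil = k_Pi_dil,
    k_adk = k_adk, gamma = gamma, PCr_0 = PCr_0, c_XB = c_XB
  )
  for (f in names(.table_unit_scale)) {
    vals[[f]] <- vals[[f]] * .table_unit_scale[[f]]
  }
  vals$mechanism <- mechanism
  obj <- structure(vals, class = "xb_params")
  validate_params(obj)
  obj
}

validate_params <- function(p) {
  stopifnot(inherits(p, "xb_params"))
  num <- .param_fields
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", f, "' must be a finite numeric scalar", call. = FALSE)
    }
    if (v <= 0 && !f %in% c("delta_r")) {
      stop("parameter '", f, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
    }
  }
  if (!p$mechanism %in% c("A3_release", "A2_release")) {
    stop("mechanism must be 'A3_release' or 'A2_release'", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.xb_params <- function(x, ...) {
  cat("<xb_params> five-state cross-bridge + energetics parameters",
      "(internal units: mM, um, s)\n")
  cat("  mechanism:", x$mechanism, "\n")
  v <- unlist(x[.param_fields])
  print(signif(v, 6))
  invisible(x)
}

# pack parameters into the fixed-order numeric vector the C++ core expects
.pack_params <- function(p) {
  validate_params(p)
  unname(unlist(p[.param_fields]))
}

.mechanism_code <- function(p) if (identical(p$mechanism, "A2_release")) 1L else 0L

#' Parameter values in the published table units
#'
#' Inverse of the unit conversion applied by [xb_params()]: returns the
#' parameter set as a named list in the units the human parameter table uses
#' (uM for \code{K_ATP}/\code{K_Hp}, nm for \code{s_3}).
#' @param params an `xb_params` object
#' @return named list, table units
#' @export
params_as_table_units <- function(params) {
  validate_params(params)
  out <- params[.param_fields]
  for (f in names(.table_unit_scale)) {
    out[[f]] <- out[[f]] / .table_unit_scale[[f]]
  }
  out$mechanism <- params$mechanism
  out
}

#' Metabolite state
#'
#' Concentrations of the tracked metabolites, all in mM. \code{Hp} is the free
#' proton concentration in mM (so pH = -log10(Hp * 1e-3)); supply either
#' \code{Hp} or \code{pH}. Free creatine is derived as \code{PCr_0 - PCr}.
#'
#' @param ATP,ADP,Pi,PCr concentrations (mM)
#' @param Hp free proton concentration (mM); default from `pH`
#' @param pH intracellular pH, used when `Hp` is missing
#' @param PCr_0 reference phosphocreatine concentration for the creatine pool
#' @return object of class `metabolite_state`
#' @export
metabolite_state <- function(ATP = 8.2, ADP = 0.008, Pi = 4.0, PCr = 33,
                             Hp = NULL, pH = 7.05, PCr_0 = 33) {
  if (is.null(Hp)) Hp <- 10^(-pH) * 1e3
  vals <- c(ATP = ATP, ADP = ADP, Pi = Pi, PCr = PCr, Hp = Hp)
  if (any(!is.finite(vals))) stop("non-finite metabolite concentration")
  neg <- names(vals)[vals < 0]
  if (length(neg)) {
    stop("negative concentration for ", paste(neg, collapse = ", "))
  }
  if (PCr > PCr_0 + 1e-12) {
    stop("invalid creatine pool: PCr (", PCr, ") exceeds PCr_0 (", PCr_0, ")")
  }
  structure(list(ATP = ATP, ADP = ADP, Pi = Pi, PCr = PCr, Hp = Hp,
                 PCr_0 = PCr_0),
            class = "metabolite_state")
}

#' @export
print.metabolite_state <- function(x, ...) {
  cat(sprintf(
    "<metabolite_state> ATP %.3g  ADP %.4g  Pi %.3g  PCr %.3g mM  pH %.3f (Cr %.3g)\n",
    x$ATP, x$ADP, x$Pi, x$PCr, met_pH(x), x$PCr_0 - x$PCr))
  invisible(x)
}

#' pH of a metabolite state
#' @param met a `metabolite_state`
#' @return pH (dimensionless)
#' @export
met_pH <- function(met) -log10(met$Hp * 1e-3)

.met_vector <- function(met) {
  c(met$ATP, met$ADP, met$Pi, met$PCr, met$Hp)
}

#' Activation-dependent troponin gating rates
#'
#' The normalized per-cycle iEMG drives the non-permissible <-> permissible
#' transition: \code{k_np = beta * iemg}, \code{k_pn = beta * (1 - iemg)}, so
#' the gate equilibrates at an open fraction equal to the iEMG with overall
#' relaxation rate beta.
#'
#' @param beta activation rate scale (1/s)
#' @param iemg normalized iEMG value(s) in \[0, 1\]
#' @return list with vectors `k_np` and `k_pn`
#' @export
activation_rates <- function(beta, iemg) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  bad <- which(iemg < 0 | iemg > 1 | !is.finite(iemg))
  if (length(bad)) {
    stop("iemg outside [0, 1] at cycle index ", paste(bad, collapse = ", "))
  }
  list(k_np = beta * iemg, k_pn = beta * (1 - iemg))
}

#' Metabolite-modulated effective transition rates
#'
#' Applies the binding-polynomial modulation of the attached-state rates:
#' Pi gates detachment from and progression out of the weakly bound state
#' (\code{kd_eff}, \code{k1_eff}), while ATP, ADP and protons partition the
#' strongly bound post-stroke state (\code{km2_eff}, \code{k3_eff}). Under
#' the \code{A2_release} mechanism the proton term instead divides the
#' ratcheting rate \code{k2_eff} and is removed from the A3 polynomial.
#'
#' @param params an `xb_params` object
#' @param met a `metabolite_state` (or list with ATP, ADP, Pi, Hp in mM)
#' @return named list of effective rates (1/s): `kd_eff`, `k1_eff`,
#'   `k2_eff`, `km2_eff`, `k3_eff`
#' @export
effective_rates <- function(params, met) {
  validate_params(params)
  conc <- c(ATP = met$ATP, ADP = met$ADP, Pi = met$Pi, Hp = met$Hp)
  neg <- names(conc)[conc < 0]
  if (length(neg)) stop("negative concentration for ", paste(neg, collapse = ", "))
  rPi <- conc[["Pi"]] / params$K_Pi
  rADP <- conc[["ADP"]] / params$K_ADP
  rATP <- conc[["ATP"]] / params$K_ATP
  rH <- conc[["Hp"]] / params$K_Hp
  kd_eff <- params$k_d * rPi / (1 + rPi)
  k1_eff <- params$k_1 / (1 + rPi)
  if (identical(params$mechanism, "A3_release")) {
    D <- 1 + rADP + rATP + rADP * rH
    k2_eff <- params$k_2
  } else {
    D <- 1 + rADP + rATP
    k2_eff <- params$k_2 / (1 + rH)
  }
  list(kd_eff = kd_eff, k1_eff = k1_eff, k2_eff = k2_eff,
       km2_eff = params$k_m2 * rADP / D,
       k3_eff = params$k_3 * rATP / D)
}

#' Save / load a parameter set as JSON
#'
#' Parameter files are flat JSON keyed by the published symbol names, with
#' values in the table units (uM for `K_ATP`/`K_Hp`, nm for `s_3`). Unknown
#' keys are rejected by name.
#'
#' @param params an `xb_params` object
#' @param path file path
#' @return `load_params` returns an `xb_params`; `save_params` the path,
#'   invisibly
#' @export
save_params <- function(params, path) {
  jsonlite::write_json(params_as_table_units(params), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(.param_fields, "mechanism")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown parameter key(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  }
  do.call(xb_params, raw)
}
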