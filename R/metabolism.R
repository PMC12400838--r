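# Metabolic fluxes and the energetics ODE right-hand side.

#' Metabolic fluxes
#'
#' The five mass-action fluxes coupling cross-bridge cycling to the
#' metabolite pools (all mM/s):
#' ATP hydrolysis `J_ATPase = c_XB * k3_eff * int exp(a3 (s+s3)^2) p3 ds`
#' (the A3 -> P detachment flux scaled by the myosin-site concentration
#' `c_XB`), creatine kinase forward `k_CKf [PCr][ADP]` and reverse
#' `k_CKr ([PCr]_0 - [PCr]) [ADP]`, glycolysis `k_Gly [ADP][Pi]`, adenylate
#' kinase `k_adk [ADP]^2`, and Pi dilution/export `k_Pi_dil [Pi]`.
#'
#' @param state an [xb_state()] (for the A3 density)
#' @param met a [metabolite_state()]
#' @param params an [xb_params()]
#' @return named list of fluxes (mM/s)
#' @export
metabolic_fluxes <- function(state, met, params) {
  validate_params(params)
  if (met$PCr > params$PCr_0 + 1e-12) {
    stop("invalid creatine pool: PCr (", met$PCr, " mM) exceeds PCr_0 (",
         params$PCr_0, " mM)")
  }
  er <- effective_rates(params, met)
  w <- .trapz_weights(state$grid)
  kern <- exp(pmin(params$alpha_3 * (state$grid$s + params$s_3)^2, 200))
  J_raw <- er$k3_eff * sum(kern * state$p3 * w) # fraction/s
  list(
    J_ATPase = params$c_XB * J_raw,
    J_CKf = params$k_CKf * met$PCr * met$ADP,
    J_CKr = params$k_CKr * (params$PCr_0 - met$PCr) * met$ADP,
    J_Gly = params$k_Gly * met$ADP * met$Pi,
    J_ADK = params$k_adk * met$ADP^2,
    J_Pidil = params$k_Pi_dil * met$Pi
  )
}

#' Metabolite time derivatives
#'
#' Stoichiometric bookkeeping of the flux vector:
#' `dPi/dt = J_ATPase - J_Gly - J_Pidil`,
#' `dADP/dt = J_ATPase - J_Gly - J_CKf + J_CKr - J_ADK`,
#' `dATP/dt = -dADP/dt`, `dPCr/dt = -J_CKf + J_CKr`, and
#' `dH/dt = 0.6 J_ATPase + J_Gly - J_CKf + J_CKr + gamma (pH(t) - pH_ref)`.
#' The proton stoichiometric coefficient of ATP hydrolysis is 0.6 (the
#' H2PO4-/HPO4 2- ratio at physiological pH) and the buffering term is
#' implemented with the restoring sign (an acid excursion relaxes back
#' toward `pH_ref`).
#'
#' @param fluxes output of [metabolic_fluxes()]
#' @param met current `metabolite_state`
#' @param params an `xb_params`
#' @param pH_ref reference (resting) pH for the buffering term
#' @return named numeric vector of derivatives (mM/s) for ATP, ADP, Pi, PCr, Hp
#' @export
metabolite_derivatives <- function(fluxes, met, params, pH_ref) {
  dADP <- fluxes$J_ATPase - fluxes$J_Gly - fluxes$J_CKf + fluxes$J_CKr -
    fluxes$J_ADK
  c(
    ATP = -dADP,
    ADP = dADP,
    Pi = fluxes$J_ATPase - fluxes$J_Gly - fluxes$J_Pidil,
    PCr = -fluxes$J_CKf + fluxes$J_CKr,
    Hp = 0.6 * fluxes$J_ATPase + fluxes$J_Gly - fluxes$J_CKf + fluxes$J_CKr +
      params$gamma * (met_pH(met) - pH_ref)
  )
}

#' Metabolite clamp specification
#'
#' Builds the clamp used by the perturbation experiments: the varied species
#' is fixed at `scale` times its reference value and the rates of change of
#' the clamped species are forced to zero during integration.
#'
#' @param met reference `metabolite_state` (typically end of the baseline run)
#' @param species the varied species, one of "ATP", "ADP", "Pi", "PCr", "Hp"
#' @param scale multiplicative factor applied to the varied species (> 0)
#' @param clamped character vector of species whose derivatives are zeroed
#'   (default: all five)
#' @return list with the clamped `metabolite_state` and the logical clamp mask
#' @export
clamp_controller <- function(met, species,
                             scale = 1,
                             clamped = c("ATP", "ADP", "Pi", "PCr", "Hp")) {
  all5 <- c("ATP", "ADP", "Pi", "PCr", "Hp")
  if (!species %in% all5) {
    stop("unknown species '", species, "'; must be one of ",
         paste(all5, collapse = ", "))
  }
  if (!all(clamped %in% all5)) {
    stop("clamped set must be a subset of ", paste(all5, collapse = ", "))
  }
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  vals <- list(ATP = met$ATP, ADP = met$ADP, Pi = met$Pi, PCr = met$PCr,
               Hp = met$Hp)
  vals[[species]] <- vals[[species]] * scale
  newmet <- metabolite_state(ATP = vals$ATP, ADP = vals$ADP, Pi = vals$Pi,
                             PCr = min(vals$PCr, met$PCr_0), Hp = vals$Hp,
                             PCr_0 = met$PCr_0)
  mask <- all5 %in% clamped
  names(mask) <- all5
  list(met = newmet, clamp = mask)
}
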