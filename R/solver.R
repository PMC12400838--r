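# Strain grid, cross-bridge state and the strain-resolved PDE solver surface.

#' Uniform strain grid for the attached-state densities
#'
#' The attached states carry a density over cross-bridge strain s (um).
#' Attachment injects probability at s = 0 (a delta source), the sliding
#' velocity advects it (shortening drives attached-bridge strain negative),
#' and the strain-dependent kernels detach it; the grid must therefore
#' contain a node exactly at s = 0 and extend far enough downstream of the
#' advection that the densities have decayed to nothing. The default window
#' \[-0.4, 0.1\] um with 401 nodes (ds = 1.25e-3 um) holds the populated
#' region for the default shortening speed with a wide margin.
#'
#' @param s_min,s_max strain bounds (um), `s_min < 0 < s_max`
#' @param n_nodes number of nodes (uniform spacing)
#' @return object of class `strain_grid` with fields `s`, `ds`, `i0`
#'   (index of the s = 0 node)
#' @export
strain_grid <- function(s_min = -0.4, s_max = 0.1, n_nodes = 401) {
  stopifnot(s_min < 0, s_max > 0, n_nodes >= 3)
  s <- seq(s_min, s_max, length.out = n_nodes)
  ds <- s[2] - s[1]
  i0 <- which.min(abs(s))
  if (abs(s[i0]) > 1e-9 * ds) {
    stop("no node lies at s = 0; choose bounds/n_nodes so that 0 is a node")
  }
  s[i0] <- 0
  structure(list(s = s, ds = ds, n_nodes = n_nodes, s_min = s_min,
                 s_max = s_max, i0 = i0),
            class = "strain_grid")
}

#' Cross-bridge population state
#'
#' Scalar fractions of the detached states (N non-permissible, P permissible)
#' plus strain-resolved densities (1/um) of the three attached states.
#'
#' @param grid a [strain_grid()]
#' @param N,P detached-state fractions
#' @param p1,p2,p3 attached-state density vectors over `grid$s` (default zero)
#' @return object of class `xb_state`
#' @export
xb_state <- function(grid, N = 1, P = 0, p1 = NULL, p2 = NULL, p3 = NULL) {
  z <- numeric(grid$n_nodes)
  p1 <- if (is.null(p1)) z else p1
  p2 <- if (is.null(p2)) z else p2
  p3 <- if (is.null(p3)) z else p3
  stopifnot(length(p1) == grid$n_nodes, length(p2) == grid$n_nodes,
            length(p3) == grid$n_nodes)
  structure(list(N = N, P = P, p1 = p1, p2 = p2, p3 = p3, grid = grid),
            class = "xb_state")
}

#' @export
print.xb_state <- function(x, ...) {
  a <- attached_fractions(x)
  cat(sprintf(
    "<xb_state> N %.4f  P %.4f  A1 %.4f  A2 %.4f  A3 %.4f  (sum %.6f)\n",
    x$N, x$P, a[1], a[2], a[3], state_probability_sum(x)))
  invisible(x)
}

.trapz_weights <- function(grid) {
  w <- rep(grid$ds, grid$n_nodes)
  w[c(1, grid$n_nodes)] <- grid$ds / 2
  w
}

#' Attached-state fractions
#'
#' Trapezoidal integrals of the three attached-state densities over strain.
#' @param state an `xb_state`
#' @return named numeric vector `c(A1=, A2=, A3=)`
#' @export
attached_fractions <- function(state) {
  w <- .trapz_weights(state$grid)
  c(A1 = sum(state$p1 * w), A2 = sum(state$p2 * w), A3 = sum(state$p3 * w))
}

#' Total state-probability sum
#'
#' The conservation sum N + P + integral(p1 + p2 + p3) ds, which the model
#' keeps equal to 1.
#' @param state an `xb_state`
#' @return numeric scalar
#' @export
state_probability_sum <- function(state) {
  unname(state$N + state$P + sum(attached_fractions(state)))
}

#' Mean strain of an attached state
#'
#' @param state an `xb_state`
#' @param which_state 1, 2 or 3 (A1, A2, A3)
#' @return mean strain (um)
#' @export
mean_strain <- function(state, which_state) {
  stopifnot(which_state %in% 1:3)
  p <- state[[paste0("p", which_state)]]
  w <- .trapz_weights(state$grid)
  mass <- sum(p * w)
  if (mass <= 0) {
    stop("mean strain undefined: state A", which_state, " carries no mass")
  }
  sum(state$grid$s * p * w) / mass
}

#' Advance the cross-bridge system by one operator-split step
#'
#' One time step of the five-state strain-resolved system: an implicit
#' (backward Euler) reaction sub-step with the supplied effective rates --
#' attachment deposited into the s = 0 node as `k_a * P / ds`, the
#' strain-dependent kernels exp(-a1 s), exp(+a1 s), exp(-a2 s),
#' exp(a3 (s+s3)^2) applied per node, the A3 -> P flux integrated over strain
#' and returned to P -- followed by first-order upwind advection at velocity
#' `dLdt` with zero inflow. Probability advected past the downwind boundary
#' is routed into P (forced detachment), so the total probability is
#' conserved to round-off.
#'
#' @param state an [xb_state()]
#' @param rates list of effective rates: `k_np`, `k_pn` plus the output of
#'   [effective_rates()] (`kd_eff`, `k1_eff`, `k2_eff`, `km2_eff`, `k3_eff`)
#' @param params an [xb_params()]
#' @param dLdt advection (sliding) velocity (um/s)
#' @param dt time step (s); must satisfy the CFL bound `|dLdt| dt <= ds`
#' @return updated `xb_state`; attributes `J_A3P` (A3 -> P flux, fraction/s),
#'   `boundary_to_P` and `clamp` carry diagnostics
#' @export
step_pde <- function(state, rates, params, dLdt, dt) {
  stopifnot(dt > 0)
  g <- state$grid
  if (abs(dLdt) * dt > g$ds * (1 + 1e-12)) {
    stop(sprintf(
      "CFL violation: |dLdt|*dt = %.3g um exceeds ds = %.3g um; use dt <= %.3g s",
      abs(dLdt) * dt, g$ds, g$ds / abs(dLdt)))
  }
  r <- cpp_step(g$s, g$i0 - 1L, g$ds, state$N, state$P,
                state$p1, state$p2, state$p3,
                rates$k_np, rates$k_pn, rates$kd_eff, rates$k1_eff,
                rates$k2_eff, rates$km2_eff, rates$k3_eff,
                params$k_a, params$k_m1, params$alpha_1, params$alpha_2,
                params$alpha_3, params$s_3, dLdt, dt)
  out <- xb_state(g, N = r$N, P = r$P, p1 = r$p1, p2 = r$p2, p3 = r$p3)
  attr(out, "J_A3P") <- r$J_A3P
  attr(out, "boundary_to_P") <- r$boundary_to_P
  attr(out, "clamp") <- r$clamp
  out
}

#' Force generated by the cross-bridge populations
#'
#' Cross-bridge stress: a frictional term proportional to the mean strain
#' carried by the strongly bound states plus the power-stroke term of the
#' ratcheted state,
#' `F_XB = k_stiff1 * (int s p2 ds + int s p3 ds) + k_stiff2 * delta_r * int p3 ds`.
#' The parallel elastic element contributes `F_PEE`: by default a constant
#' offset (0), or the exponential-in-stretch form
#' `c1 * (exp(c2 * strain_pee) - 1)` when `pee` supplies `c1`, `c2` and
#' `strain_pee`.
#'
#' @param state an `xb_state`
#' @param params an `xb_params`
#' @param pee optional parallel-elastic spec: either a single number (constant
#'   offset, mN/mm^2) or a list with `c1`, `c2`, `strain_pee`
#' @return list with `F_XB`, `F_PEE`, `F_total` (mN/mm^2)
#' @export
compute_force <- function(state, params, pee = 0) {
  w <- .trapz_weights(state$grid)
  s <- state$grid$s
  F_XB <- params$k_stiff1 * (sum(s * state$p2 * w) + sum(s * state$p3 * w)) +
    params$k_stiff2 * params$delta_r * sum(state$p3 * w)
  F_PEE <- if (is.list(pee)) {
    pee$c1 * (exp(pee$c2 * pee$strain_pee) - 1)
  } else {
    pee
  }
  list(F_XB = F_XB, F_PEE = F_PEE, F_total = F_XB + F_PEE)
}

#' Convert force to mechanical power
#'
#' `power = scale * F_total * |dLdt|`; `scale` is the calibration constant
#' mapping sarcomere-level stress x speed to whole-task power (estimable).
#'
#' @param F_total total force (mN/mm^2)
#' @param dLdt sliding velocity (um/s)
#' @param scale calibration constant (> 0)
#' @return power (W)
#' @export
force_to_power <- function(F_total, dLdt, scale) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  scale * F_total * abs(dLdt)
}

#' Monte-Carlo single-bridge oracle
#'
#' Continuous-time Markov simulation of `n_bridges` independent cross-bridges
#' on the same five-state graph, with strain advected along characteristics
#' and reset at attachment, under clamped metabolites. Serves as a stochastic
#' cross-check of the deterministic strain-grid solver: attached fractions
#' should agree within a few binomial standard errors.
#'
#' @param params an `xb_params`
#' @param met clamped `metabolite_state`
#' @param iemg per-cycle normalized activation values
#' @param dLdt advection velocity (um/s)
#' @param T_cyc cycle duration (s)
#' @param dt Markov time step (s)
#' @param n_bridges ensemble size (>= 1e4 recommended)
#' @param s_min,s_max strain window; bridges advected outside are detached
#' @param seed RNG seed (uses R's RNG; set for reproducibility)
#' @param sample_every record ensemble fractions every this many steps (0 = none)
#' @return list with `fractions` (N, P, A1, A2, A3), binomial `se`, `F_XB`,
#'   and a `samples` matrix of time-stamped fractions
#' @export
mc_oracle <- function(params, met, iemg, dLdt, T_cyc = 1.6, dt = 2.5e-4,
                      n_bridges = 1e5, s_min = -0.1, s_max = 0.5,
                      seed = NULL, sample_every = 0) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  act <- activation_rates(params$beta, iemg) # validates iemg
  spc <- as.integer(round(T_cyc / dt))
  r <- cpp_mc_oracle(.pack_params(params), .mechanism_code(params),
                     s_min, s_max, .met_vector(met), iemg, dLdt, dt, spc,
                     as.integer(n_bridges), as.integer(sample_every))
  names(r$fractions) <- names(r$se) <- c("N", "P", "A1", "A2", "A3")
  colnames(r$samples) <- c("t", "N", "P", "A1", "A2", "A3")
  r$samples <- r$samples[seq_len(r$n_samples), , drop = FALSE]
  r
}
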