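# Local central-difference sensitivities and the Latin-hypercube global sweep.

# default scalar reduction: end-of-exercise cycle-mean total force
.default_functional <- function(config, activation, reduction = "mean") {
  force(config); force(activation)
  function(params) {
    sim <- simulate_exercise(params, config, activation)
    n <- nrow(sim$cycles)
    if (reduction == "peak") sim$cycles$peak_force[n] else sim$cycles$mean_force[n]
  }
}

#' Local (central-difference) parameter sensitivity
#'
#' Relative sensitivity of a scalar model output F to parameter i:
#' `S_i = (F(x_i + dx) - F(x_i - dx)) / F(x0) * x_i / (2 dx)`, the
#' normalized central difference at relative step `rel_step` (default 1%).
#' By default F is the end-of-exercise cycle-mean total force; any functional
#' of the parameters can be supplied instead.
#'
#' @param params an [xb_params()] around which to differentiate
#' @param config,activation protocol and activation trace for the default
#'   force functional (ignored when `functional` is given)
#' @param i parameter name (or names) to perturb
#' @param rel_step relative step size (> 0), default 0.01
#' @param functional optional function `params -> scalar` replacing the
#'   default force reduction
#' @param reduction `"mean"` or `"peak"` force for the default functional
#' @return named numeric vector of sensitivities (dimensionless)
#' @export
local_sensitivity <- function(params, config = NULL, activation = NULL,
                              i, rel_step = 0.01, functional = NULL,
                              reduction = "mean") {
  stopifnot(rel_step > 0)
  if (is.null(functional)) {
    functional <- .default_functional(config, activation, reduction)
  }
  F0 <- functional(params)
  if (!is.finite(F0) || F0 == 0) {
    stop("undefined normalization: F(x0) = ", F0)
  }
  vapply(i, function(nm) {
    x0 <- params[[nm]]
    dx <- rel_step * x0
    up <- params; up[[nm]] <- x0 + dx; class(up) <- "xb_params"
    dn <- params; dn[[nm]] <- x0 - dx; class(dn) <- "xb_params"
    (functional(up) - functional(dn)) / F0 * x0 / (2 * dx)
  }, numeric(1))
}

#' Latin-hypercube global sensitivity sweep
#'
#' Samples `n_samples` parameter sets by Latin hypercube within
#' `+-rel_range` (default 10%) of the supplied optimum, evaluates the local
#' sensitivity of every swept parameter at each sampled set, and returns the
#' distribution. Sets whose simulation fails are recorded and excluded.
#'
#' @param params centre (best-fit) [xb_params()]
#' @param config,activation forwarded to the force functional
#' @param parameters which parameters to sweep and differentiate (default:
#'   the 23 estimable kinetic parameters)
#' @param n_samples number of Latin-hypercube samples (>= 2)
#' @param rel_range half-width of the uniform sampling box, relative
#' @param rel_step central-difference step for the local sensitivities
#' @param seed RNG seed (sampling is reproducible under a fixed seed)
#' @param functional optional scalar functional overriding the force reduction
#' @return object of class `xb_sensitivity`: tidy data frame `samples`
#'   (parameter, sample_id, S), the `lhs_matrix`, and `n_failed`
#' @export
global_sensitivity <- function(params, config = NULL, activation = NULL,
                               parameters = .estimable_params,
                               n_samples = 100, rel_range = 0.10,
                               rel_step = 0.01, seed = 1,
                               functional = NULL) {
  stopifnot(n_samples >= 2)
  set.seed(seed)
  U <- lhs::randomLHS(n_samples, length(parameters))
  colnames(U) <- parameters
  x0 <- unlist(params[parameters])
  rows <- vector("list", n_samples)
  n_failed <- 0L
  for (b in seq_len(n_samples)) {
    pb <- params
    pb[parameters] <- as.list(x0 * (1 - rel_range + 2 * rel_range * U[b, ]))
    class(pb) <- "xb_params"
    S <- tryCatch(
      local_sensitivity(pb, config, activation, parameters,
                        rel_step = rel_step, functional = functional),
      error = function(e) NULL)
    if (is.null(S)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[b]] <- data.frame(parameter = parameters, sample_id = b,
                            S = unname(S))
  }
  if (n_failed > 0) {
    message(n_failed, " of ", n_samples,
            " sampled sets failed to simulate and were excluded")
  }
  structure(list(samples = do.call(rbind, rows), lhs_matrix = U,
                 n_failed = n_failed, rel_range = rel_range),
            class = "xb_sensitivity")
}

#' @export
print.xb_sensitivity <- function(x, ...) {
  agg <- stats::aggregate(S ~ parameter, data = x$samples, FUN = stats::median)
  agg <- agg[order(-abs(agg$S)), ]
  cat(sprintf("<xb_sensitivity> %d samples (+-%.0f%%), %d failed\n",
              nrow(x$lhs_matrix), 100 * x$rel_range, x$n_failed))
  cat("median |S| ranking (top 8):\n")
  print(utils::head(agg, 8), row.names = FALSE)
  invisible(x)
}
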