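## Steady states are found the way the analyses define them: integrate
## the ODE system over a long horizon and accept the state once no
## metabolite changes faster than a residual-rate tolerance (default
## 1e-6 mM/min, applied to absolute rates).  The system is non-oscillatory,
## so checkpointed long integration is sufficient; no root polishing is
## applied.

.ss_checkpoints <- function(horizon) {
  cp <- 10^(1:ceiling(log10(horizon)))
  unique(c(0, cp[cp < horizon], horizon))
}

## lean compiled-path solver used everywhere (Monte Carlo included)
.ss_solve <- function(parms, y0, tol = 1e-6, horizon = 1e6) {
  times <- .ss_checkpoints(horizon)
  ## integrator chatter on pathological parameter draws is expected;
  ## non-convergence is decided by the residual criterion below
  sol <- try(suppressWarnings(
    deSolve::lsoda(y = y0, times = times, func = "ed_rhs",
                   parms = parms, dllname = "edflux",
                   initfunc = "ed_init", rtol = 1e-8, atol = 1e-10)),
    silent = TRUE)
  if (inherits(sol, "try-error"))
    return(list(y = rep(NA_real_, 12), converged = FALSE,
                final_time = NA_real_, residual = NA_real_))
  for (i in 2:nrow(sol)) {
    y <- sol[i, -1]
    if (any(!is.finite(y)))
      return(list(y = y, converged = FALSE, final_time = sol[i, 1],
                  residual = NA_real_))
    res <- max(abs(.derivs_from_rates(.rates_from_parms(y, parms))))
    if (res <= tol)
      return(list(y = pmax(y, 0), converged = TRUE, final_time = sol[i, 1],
                  residual = res))
  }
  list(y = pmax(sol[nrow(sol), -1], 0), converged = FALSE,
       final_time = times[length(times)], residual = res)
}

.ss_result <- function(model, sol) {
  conc <- setNames(as.numeric(sol$y), .ed_state_ids())
  fluxes <- if (sol$converged && all(is.finite(conc)))
    .rates_from_parms(conc, model$parms) else NULL
  structure(list(concentrations = conc, fluxes = fluxes,
                 converged = sol$converged, final_time = sol$final_time,
                 max_residual_rate = sol$residual),
            class = "ed_steady_state")
}

#' Integrate a model to steady state
#'
#' Runs the stiff integrator (`lsoda`) over exponentially spaced
#' checkpoints and accepts the first checkpoint at which every
#' `|dX/dt|` falls at or below `tol`.
#'
#' @param model An `ed_model`.
#' @param tol Residual-rate tolerance in mM/min (default `1e-6`).
#' @param horizon Maximal integration time in minutes (default `1e6`);
#'   if the residual criterion is not met by then, `converged` is
#'   `FALSE` and the final state is returned for diagnosis.
#' @param initial_state Optional named start vector (mM) overriding the
#'   model's initial conditions.
#' @return An `ed_steady_state` with `concentrations` (mM), `fluxes`
#'   (mM/min, net per reaction), `converged`, `final_time` and
#'   `max_residual_rate`.
#' @export
steady_state <- function(model, tol = 1e-6, horizon = 1e6,
                         initial_state = NULL) {
  y0 <- model$initial_state
  if (!is.null(initial_state)) {
    initial_state <- .as_state(initial_state)
    if (any(initial_state < 0)) stop("initial concentrations must be >= 0")
    y0 <- initial_state
  }
  .ss_result(model, .ss_solve(model$parms, unname(y0), tol, horizon))
}

#' @export
print.ed_steady_state <- function(x, ...) {
  cat("ED steady state:", if (x$converged) "converged" else "NOT converged",
      "at t =", format(x$final_time), "min; max |dX/dt| =",
      format(x$max_residual_rate, digits = 3), "mM/min\n")
  if (x$converged) print(signif(x$concentrations, 4))
  invisible(x)
}

#' Generic steady-state integration of a user-supplied ODE system
#'
#' Same checkpointed residual-rate criterion as [steady_state()], for
#' arbitrary (small) ODE systems given as R functions; used for
#' closed-form oracles and toy systems.
#'
#' @param rhs Function `(t, y, parms)` returning `list(dy)`.
#' @param y0 Initial state vector.
#' @param parms Parameters passed through to `rhs`.
#' @param tol Residual-rate tolerance.
#' @param horizon Maximal integration time.
#' @return A list with `y`, `converged`, `final_time`,
#'   `max_residual_rate`.
#' @export
integrate_to_steady_state <- function(rhs, y0, parms = NULL, tol = 1e-6,
                                      horizon = 1e6) {
  times <- .ss_checkpoints(horizon)
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = parms,
                        rtol = 1e-8, atol = 1e-10)
  res <- NA_real_
  for (i in 2:nrow(sol)) {
    y <- sol[i, -1, drop = TRUE]
    if (any(!is.finite(y))) break
    res <- max(abs(unlist(rhs(sol[i, 1], y, parms)[[1]])))
    if (res <= tol)
      return(list(y = y, converged = TRUE, final_time = sol[i, 1],
                  max_residual_rate = res))
  }
  list(y = sol[nrow(sol), -1, drop = TRUE], converged = FALSE,
       final_time = times[length(times)], max_residual_rate = res)
}

#' Fluxes at a converged steady state
#'
#' Re-evaluates every reaction rate at the steady concentrations.  At a
#' converged steady state, production equals consumption for every
#' metabolite within the solver tolerance.
#'
#' @param model An `ed_model`.
#' @param ss An `ed_steady_state` from [steady_state()]; must be
#'   converged.
#' @return Named net flux vector (mM/min).
#' @export
steady_state_fluxes <- function(model, ss) {
  if (!isTRUE(ss$converged)) stop("steady state did not converge")
  reaction_rates(ss$concentrations, model)
}

#' Weighted relative change between two steady states
#'
#' For each element (metabolite concentration or reaction flux),
#' `rc_i = ((sim_i - ref_i) / sim_i) * (E_i / sum(E))` with the weights
#' `E_i` taken from the `sim` state, so that large pools/fluxes dominate
#' the aggregate.  Also reports the unweighted mean of the per-element
#' ratios `sim_i / ref_i` and the ratio of summed values (two readings of
#' an aggregate steady-state ratio; the mean of per-element ratios is the
#' default).
#'
#' @param sim,ref Converged `ed_steady_state` objects on the same
#'   topology.
#' @param kind `"metabolite"` or `"flux"`.
#' @return An `ed_comparison`: data frame of per-element values plus
#'   attributes `mean_ratio` and `sum_ratio`.
#' @export
weighted_relative_change <- function(sim, ref,
                                     kind = c("metabolite", "flux")) {
  kind <- match.arg(kind)
  if (!isTRUE(sim$converged) || !isTRUE(ref$converged))
    stop("both steady states must be converged")
  s <- if (kind == "metabolite") sim$concentrations else sim$fluxes
  r <- if (kind == "metabolite") ref$concentrations else ref$fluxes
  if (!identical(names(s), names(r))) stop("element sets differ")
  if (any(s == 0 & r != 0))
    stop("zero simulated value with nonzero reference: ",
         paste(names(s)[s == 0 & r != 0], collapse = ", "))
  keep <- !(s == 0 & r == 0)
  s <- s[keep]; r <- r[keep]
  w <- s / sum(s)
  rc <- (s - r) / s * w
  out <- data.frame(element = names(s), kind = kind, sim = unname(s),
                    ref = unname(r), weight = unname(w), rc = unname(rc),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ed_comparison", "data.frame"),
            mean_ratio = mean(s[r != 0] / r[r != 0]),
            sum_ratio = sum(s) / sum(r))
}

#' @export
print.ed_comparison <- function(x, ...) {
  cat("Steady-state comparison (", x$kind[1], "): mean ratio sim/ref = ",
      signif(attr(x, "mean_ratio"), 4), ", ratio of sums = ",
      signif(attr(x, "sum_ratio"), 4), "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
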