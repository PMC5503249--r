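## Deterministic and stochastic robustness analyses on a parameterized
## model: one-at-a-time finite-difference sensitivities of steady-state
## concentrations to maximal velocities, seeded Monte-Carlo ensembles
## (external = glucose uptake only; internal = all velocities), branch
## knockouts, perturbation of the glycerate-kinase feedforward
## inhibition, and relaxation of the clamped cofactor pools.

#' Relative standard deviation of a sample, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector with at least two values and nonzero mean.
#' @return RSD in percent.
#' @export
relative_standard_deviation <- function(x) {
  if (length(x) < 2) stop("need at least two samples")
  m <- mean(x)
  if (m == 0) stop("zero mean")
  100 * sd(x) / m
}

## multiply the packed velocity entries of a parms vector
.scale_parms <- function(parms, multipliers) {
  idx <- match(names(multipliers), .ed_velocity_order())
  parms[idx] <- parms[idx] * multipliers
  parms
}

#' One-at-a-time sensitivity of a steady state to a velocity parameter
#'
#' `S = ((SS_perturbed - SS_base) / SS_base) / relative_delta`, a
#' one-sided finite difference at the given relative perturbation.
#' `S = 1` means direct proportionality of output to parameter.
#'
#' @param model An `ed_model`.
#' @param parameter A directional velocity name (see
#'   [velocity_names()]), a sink (`v_sinkGAP`, `v_sinkPyr`) or a
#'   degradation rate (`v_degGAP` etc.).
#' @param relative_delta Relative perturbation, e.g. `0.2` or `-0.2`;
#'   must be nonzero.
#' @param metabolites Metabolite ids to report (default all 12).
#' @param base Optional precomputed base `ed_steady_state`.
#' @return Named vector of signed sensitivities.
#' @export
single_parameter_sensitivity <- function(model, parameter,
                                         relative_delta = 0.2,
                                         metabolites = .ed_state_ids(),
                                         base = NULL) {
  if (relative_delta == 0) stop("relative_delta must be nonzero")
  if (!parameter %in% .ed_velocity_order())
    stop("unknown velocity parameter: ", parameter)
  if (is.null(base)) base <- steady_state(model)
  if (!base$converged) stop("base model does not converge")
  parms <- .scale_parms(model$parms,
                        setNames(1 + relative_delta, parameter))
  sol <- .ss_solve(parms, unname(model$initial_state))
  if (!sol$converged)
    stop("perturbed model does not converge for ", parameter)
  conc <- setNames(sol$y, .ed_state_ids())
  ((conc[metabolites] - base$concentrations[metabolites]) /
      base$concentrations[metabolites]) / relative_delta
}

#' Maximal-sensitivity matrix over +/-20% velocity perturbations
#'
#' For every (velocity, metabolite) pair, the signed sensitivity of
#' larger magnitude between the +delta and -delta one-sided finite
#' differences; a sign marker records which perturbation attained the
#' maximum (ties broken toward `+`).  Per-metabolite averages over all
#' rows are appended.
#'
#' @param model An `ed_model`.
#' @param parameters Velocity names forming the rows (default: all
#'   maximal velocities including the influx and both sinks, excluding
#'   degradation rates).
#' @param relative_delta Magnitude of the relative perturbation
#'   (default 0.2).
#' @return An `ed_sensitivity`: matrix `S` (rows = velocities,
#'   columns = metabolites) with attributes `sign_marker` (character
#'   matrix of `"+"`/`"-"`) and `metabolite_average`.
#' @export
sensitivity_matrix <- function(model, parameters = NULL,
                               relative_delta = 0.2) {
  if (is.null(parameters))
    parameters <- setdiff(.ed_velocity_order(),
                          c("v_degGAP", "v_degBPG", "v_degPEP"))
  base <- steady_state(model)
  if (!base$converged) stop("base model does not converge")
  S <- matrix(NA_real_, length(parameters), 12,
              dimnames = list(parameters, .ed_state_ids()))
  marker <- matrix(NA_character_, length(parameters), 12,
                   dimnames = dimnames(S))
  for (p in parameters) {
    up <- single_parameter_sensitivity(model, p, relative_delta,
                                       base = base)
    dn <- single_parameter_sensitivity(model, p, -relative_delta,
                                       base = base)
    take_up <- abs(up) >= abs(dn)
    S[p, ] <- ifelse(take_up, up, dn)
    marker[p, ] <- ifelse(take_up, "+", "-")
  }
  structure(S, class = c("ed_sensitivity", "matrix"),
            sign_marker = marker,
            metabolite_average = colMeans(S))
}

#' @export
print.ed_sensitivity <- function(x, ...) {
  cat("Sensitivity matrix (", nrow(x), "velocities x", ncol(x),
      "metabolites ); largest |S| =",
      signif(x[which.max(abs(x))], 3), "\n")
  print(signif(unclass(x), 2))
  cat("per-metabolite average:\n")
  print(signif(attr(x, "metabolite_average"), 2))
  invisible(x)
}

## shared Monte-Carlo driver: `bounds` is a 2-column matrix (lower,
## upper multipliers... actually natural values) per perturbed velocity
.mc_run <- function(model, draws, extra = NULL,
                    max_failure_fraction = 0.05, tol = 1e-6,
                    horizon = 1e6) {
  n <- nrow(draws)
  base_v <- model$velocities[colnames(draws)]
  conc <- matrix(NA_real_, n, 12,
                 dimnames = list(NULL, .ed_state_ids()))
  ok <- logical(n)
  y0 <- unname(model$initial_state)
  for (i in seq_len(n)) {
    # zeroed velocities (knockouts) stay zero under any draw
    mult <- ifelse(base_v > 0, draws[i, ] / base_v, 1)
    parms <- .scale_parms(model$parms, mult)
    if (!is.null(extra)) parms[extra$index] <- extra$values[i]
    sol <- .ss_solve(parms, y0, tol, horizon)
    ok[i] <- sol$converged
    if (sol$converged) conc[i, ] <- sol$y
  }
  fail <- sum(!ok)
  if (fail > max_failure_fraction * n)
    stop("Monte-Carlo ensemble aborted: ", fail, " of ", n,
         " draws failed to converge")
  kept <- conc[ok, , drop = FALSE]
  mu <- colMeans(kept)
  sdev <- apply(kept, 2, sd)
  stats <- data.frame(
    metabolite = .ed_state_ids(),
    mean = mu,
    sd = sdev,
    # structurally absent metabolites (e.g. KDPG under the spED
    # knockout) have zero mean and zero spread
    rsd = ifelse(mu == 0, 0, 100 * sdev / mu),
    row.names = NULL)
  structure(list(draws = draws, concentrations = conc, ok = ok,
                 stats = stats, n = n, failures = fail),
            class = "ed_mc_ensemble")
}

#' @export
print.ed_mc_ensemble <- function(x, ...) {
  cat("Monte-Carlo ensemble: n =", x$n, "(", x$failures,
      "convergence failures )\n")
  print(transform(x$stats, mean = signif(mean, 4), sd = signif(sd, 3),
                  rsd = round(rsd, 1)))
  invisible(x)
}

#' External Monte-Carlo robustness: perturb the glucose uptake rate
#'
#' Draws the influx velocity uniformly within
#' `[(1-fraction) v, (1+fraction) v]` around its nominal value, re-solves
#' the steady state per draw and reports per-metabolite relative standard
#' deviations.
#'
#' @param model An `ed_model`.
#' @param fraction Half-width of the relative perturbation (default 0.5).
#' @param n Number of draws (default 1000).
#' @param seed Integer seed; ensembles are reproducible given the seed.
#' @param ... Passed to the internal driver (tolerances, failure cap).
#' @return An `ed_mc_ensemble` with `draws`, per-draw steady states and
#'   a per-metabolite `stats` table (mean, sd, rsd in percent).
#' @export
monte_carlo_external <- function(model, fraction = 0.5, n = 1000,
                                 seed = 1, ...) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  v <- model$velocities[["v_up"]]
  set.seed(seed)
  draws <- matrix(runif(n, (1 - fraction) * v, (1 + fraction) * v),
                  ncol = 1, dimnames = list(NULL, "v_up"))
  out <- .mc_run(model, draws, ...)
  out$seed <- seed
  out$bounds <- c(lower = (1 - fraction) * v, upper = (1 + fraction) * v)
  out
}

## uniform bounds for the internal scheme: measured velocities within
## +/- SD, everything else within +/- fraction
.internal_bounds <- function(model, fraction, include_deg, include_sinks) {
  par <- model$parameters
  src <- vmax_source(par)
  nm <- names(par$vmax)
  lo <- hi <- setNames(numeric(0), character(0))
  for (v in nm) {
    base <- model$velocities[[v]]   # mM/min, cofactor-scaled
    rel <- if (base == 0) 0
    else if (src[[v]] == "measured") par$vmax_sd[[v]] / par$vmax[[v]]
    else fraction
    lo[v] <- base * (1 - rel); hi[v] <- base * (1 + rel)
  }
  if (include_sinks)
    for (v in names(par$sink_rates)) {
      base <- model$velocities[[v]]
      lo[v] <- base * (1 - fraction); hi[v] <- base * (1 + fraction)
    }
  if (include_deg)
    for (v in c("v_degGAP", "v_degBPG", "v_degPEP")) {
      base <- model$velocities[[v]]
      lo[v] <- base * (1 - fraction); hi[v] <- base * (1 + fraction)
    }
  cbind(lower = lo, upper = hi)
}

#' Internal Monte-Carlo robustness: perturb all reaction velocities
#'
#' Simultaneously draws every maximal velocity from a uniform
#' distribution -- measured velocities within their measured standard
#' deviation, fitted velocities within `+/- fraction` of their value --
#' and by default also the sink and degradation rates within
#' `+/- fraction`; re-solves the steady state per draw.
#'
#' @param model An `ed_model`.
#' @param fraction Relative half-width for fitted velocities
#'   (default 0.2).
#' @param n Number of draws (default 1000).
#' @param seed Integer seed.
#' @param include_deg,include_sinks Also perturb degradation/sink rates
#'   (default `TRUE`).
#' @param ... Passed to the internal driver.
#' @return An `ed_mc_ensemble`.
#' @export
monte_carlo_internal <- function(model, fraction = 0.2, n = 1000,
                                 seed = 1, include_deg = TRUE,
                                 include_sinks = TRUE, ...) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  b <- .internal_bounds(model, fraction, include_deg, include_sinks)
  set.seed(seed)
  u <- matrix(runif(n * nrow(b)), nrow = n)
  draws <- sweep(u, 2, b[, "upper"] - b[, "lower"], `*`)
  draws <- sweep(draws, 2, b[, "lower"], `+`)
  colnames(draws) <- rownames(b)
  out <- .mc_run(model, draws, ...)
  out$seed <- seed
  out$bounds <- b
  out
}

#' Branch knockout variants
#'
#' `"SP0"` zeroes the maximal velocity of the KDG kinase (first committed
#' step of the semi-phosphorylative branch); `"NP0"` zeroes both
#' directional velocities of the reversible npED aldolase; `"WT"` returns
#' the model unchanged.
#'
#' @param model An `ed_model`.
#' @param variant `"WT"`, `"SP0"` or `"NP0"`.
#' @return A modified `ed_model` copy.
#' @export
knockout <- function(model, variant = c("WT", "SP0", "NP0")) {
  variant <- match.arg(variant)
  zero <- switch(variant,
                 WT = character(0),
                 SP0 = "v_KDGK",
                 NP0 = c("v_KDPGA_np_f", "v_KDPGA_np_r"))
  if (!length(zero)) return(model)
  .with_velocities(model, vmax = setNames(rep(0, length(zero)), zero))
}

#' Knockout-over-wild-type steady-state ratios
#'
#' @param model Wild-type `ed_model`.
#' @param variant Knockout label passed to [knockout()].
#' @param metabolites Metabolite ids to report.
#' @return Named ratio vector `SS(variant)/SS(WT)`.
#' @export
knockout_ratio_vs_wt <- function(model, variant,
                                 metabolites = c("Glc", "DGat", "KDG",
                                                 "GA", "Gly", "Pyr")) {
  wt <- steady_state(model)
  ko <- steady_state(knockout(model, variant))
  if (!wt$converged || !ko$converged)
    stop("both wild-type and knockout models must converge")
  if (any(wt$concentrations[metabolites] == 0))
    stop("zero wild-type steady-state value")
  ko$concentrations[metabolites] / wt$concentrations[metabolites]
}

#' Perturb the glycerate-kinase feedforward inhibition
#'
#' Runs two internal Monte-Carlo ensembles from the same seed (so the
#' velocity draws are identical pair-wise): one with the nominal
#' substrate-inhibition constant of `v_GK`, one with the constant
#' additionally drawn uniformly within `+/- inhibition_fraction` of its
#' value per draw.  Reports both ensembles and the per-metabolite RSD
#' difference.
#'
#' @param model An `ed_model`.
#' @param inhibition_fraction Relative half-width for the `v_GK`
#'   inhibition constant (default 0.2).
#' @param vmax_fraction Relative half-width for the fitted velocities
#'   (default 0.2, as in [monte_carlo_internal()]).
#' @param n Number of draws.
#' @param seed Integer seed shared by both ensembles.
#' @param ... Passed to the internal driver.
#' @return List with `without` and `with` (`ed_mc_ensemble`s) and
#'   `rsd_delta` (RSD with minus RSD without, percentage points).
#' @export
perturb_feedforward <- function(model, inhibition_fraction = 0.2,
                                vmax_fraction = 0.2, n = 1000, seed = 1,
                                ...) {
  b <- .internal_bounds(model, vmax_fraction,
                        include_deg = TRUE, include_sinks = TRUE)
  set.seed(seed)
  u <- matrix(runif(n * nrow(b)), nrow = n)
  draws <- sweep(u, 2, b[, "upper"] - b[, "lower"], `*`)
  draws <- sweep(draws, 2, b[, "lower"], `+`)
  colnames(draws) <- rownames(b)
  ki <- model$parameters$ki[["v_GK.Gly"]]
  ki_draws <- runif(n, (1 - inhibition_fraction) * ki,
                    (1 + inhibition_fraction) * ki)
  without <- .mc_run(model, draws, ...)
  with_ki <- .mc_run(model, draws,
                     extra = list(index = 46L, values = ki_draws), ...)
  without$seed <- with_ki$seed <- seed
  list(without = without, with = with_ki,
       rsd_delta = setNames(with_ki$stats$rsd - without$stats$rsd,
                            with_ki$stats$metabolite))
}

#' Relax the clamped cofactor pools
#'
#' Re-solves the steady state with every clamped cofactor pool (ATP, ADP,
#' NADP+, NADPH, reduced ferredoxin) scaled jointly by `(1 - fraction)`
#' and `(1 + fraction)` and reports the per-metabolite relative changes.
#' With near-saturating pools the changes stay small, which is the
#' justification for folding cofactors into constants.
#'
#' @param model An `ed_model`.
#' @param fraction Relative variation of the pools (default 0.25).
#' @return Data frame with base/down/up concentrations and relative
#'   changes per metabolite.
#' @export
vary_cofactors <- function(model, fraction = 0.25) {
  base <- steady_state(model)
  if (!base$converged) stop("base model does not converge")
  solve_scaled <- function(f) {
    cof <- model$parameters$cofactors
    cof$pools <- cof$pools * f
    m <- .with_velocities(model, cofactors = cof)
    ss <- steady_state(m)
    if (!ss$converged) stop("cofactor-scaled model does not converge")
    ss$concentrations
  }
  dn <- solve_scaled(1 - fraction)
  up <- solve_scaled(1 + fraction)
  data.frame(metabolite = .ed_state_ids(),
             base = unname(base$concentrations),
             down = unname(dn), up = unname(up),
             rel_down = unname(dn / base$concentrations - 1),
             rel_up = unname(up / base$concentrations - 1),
             row.names = NULL)
}
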