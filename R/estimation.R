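## Constrained estimation of the free (unmeasurable) maximal velocities
## and sink rates at both temperatures.  The objective couples the two
## parameterizations: (i) the 80 degC steady state must be reproduced by
## the doubled 70 degC velocities (Van't Hoff consistency), and (ii) the
## simulated 70/80 steady-state ratios of Glc, D-Gat, KDG and Gly must
## match the measured metabolome ratios.  Box constraints keep free
## velocities in (10, 1000) U/g CE, optionally let measured velocities
## move within +/- SD, and a penalty keeps every steady concentration
## below 100 mM.

#' Build a fitting context
#'
#' @param model70,model80 `ed_model` instances at 70 and 80 degC.
#' @param ratio_targets Named target steady-state ratios (70 degC over
#'   80 degC).  Defaults to the measured metabolome ratios
#'   `Glc = 0.97`, `DGat = 1.27`, `KDG = 4.16`, `Gly = 1.91`.
#' @param free Character vector of free velocity names (enzymatic
#'   velocities and/or sinks).  Default: every velocity whose source is
#'   `"fitted"` in the 80 degC parameter set, plus both sinks.
#' @param vmax_bounds Bounds for free enzymatic velocities, U/g CE.
#' @param sink_bounds Bounds for free first-order sink constants, 1/min.
#' @param conc_limit Upper bound on steady concentrations, mM.
#' @param adjust_measured Also let measured velocities vary within their
#'   measured standard deviation (independently per temperature).
#' @param ss_tol,ss_horizon Steady-state solver settings used inside the
#'   objective.
#' @return A `fit_context` list.
#' @export
fit_context <- function(model70, model80,
                        ratio_targets = c(Glc = 0.97, DGat = 1.27,
                                          KDG = 4.16, Gly = 1.91),
                        free = NULL,
                        vmax_bounds = c(10, 1000),
                        sink_bounds = c(1e-3, 10),
                        conc_limit = 100,
                        adjust_measured = FALSE,
                        ss_tol = 1e-6, ss_horizon = 1e6) {
  if (any(ratio_targets <= 0)) stop("ratio targets must be positive")
  if (diff(vmax_bounds) <= 0 || diff(sink_bounds) <= 0)
    stop("bounds must be well-ordered")
  if (is.null(free)) {
    src <- vmax_source(model80$parameters)
    free <- c(names(src)[src == "fitted"],
              names(model80$parameters$sink_rates))
  }
  sinks <- intersect(free, c("v_sinkGAP", "v_sinkPyr"))
  enz <- setdiff(free, sinks)

  par_names <- c(paste0("70.", free), paste0("80.", free))
  lower <- upper <- start <- setNames(numeric(0), character(0))
  for (tm in c("70", "80")) {
    m <- if (tm == "70") model70 else model80
    for (nm in enz) {
      key <- paste0(tm, ".", nm)
      lower[key] <- vmax_bounds[1]; upper[key] <- vmax_bounds[2]
      start[key] <- min(max(m$parameters$vmax[[nm]], vmax_bounds[1]),
                        vmax_bounds[2])
    }
    for (nm in sinks) {
      key <- paste0(tm, ".", nm)
      lower[key] <- sink_bounds[1]; upper[key] <- sink_bounds[2]
      start[key] <- min(max(m$parameters$sink_rates[[nm]], sink_bounds[1]),
                        sink_bounds[2])
    }
    if (adjust_measured) {
      src <- vmax_source(m$parameters)
      for (nm in names(src)[src == "measured"]) {
        key <- paste0(tm, ".", nm)
        v <- m$parameters$vmax[[nm]]
        s <- m$parameters$vmax_sd[[nm]]
        lower[key] <- max(v - s, 0); upper[key] <- v + s
        start[key] <- v
      }
    }
  }
  structure(list(model70 = model70, model80 = model80,
                 ratio_targets = ratio_targets, free = free,
                 lower = lower, upper = upper, start = start,
                 conc_limit = conc_limit, ss_tol = ss_tol,
                 ss_horizon = ss_horizon),
            class = "fit_context")
}

## apply a named candidate ("70.v_up", "80.v_sinkGAP", ...) to the pair
.apply_candidate <- function(candidate, ctx) {
  out <- list()
  for (tm in c("70", "80")) {
    m <- if (tm == "70") ctx$model70 else ctx$model80
    sel <- grepl(paste0("^", tm, "\\."), names(candidate))
    vals <- candidate[sel]
    names(vals) <- sub("^..\\.", "", names(vals))
    sinks <- intersect(names(vals), c("v_sinkGAP", "v_sinkPyr"))
    enz <- setdiff(names(vals), sinks)
    out[[tm]] <- .with_velocities(m, vmax = vals[enz],
                                  sink_rates = vals[sinks])
  }
  out
}

## residual vector; length 12 (Van't Hoff) + #targets + 24 (penalties)
.ssr_residuals <- function(candidate, ctx) {
  nres <- 12 + length(ctx$ratio_targets) + 24
  models <- .apply_candidate(candidate, ctx)
  ss70 <- .ss_solve(models[["70"]]$parms, unname(models[["70"]]$initial_state),
                    ctx$ss_tol, ctx$ss_horizon)
  ss80 <- .ss_solve(models[["80"]]$parms, unname(models[["80"]]$initial_state),
                    ctx$ss_tol, ctx$ss_horizon)
  ## Van't Hoff prediction: doubled 70 degC velocities, 80 degC half-lives
  p70 <- models[["70"]]$parameters
  psim <- vant_hoff_transform(p70, "up10",
                              half_life = models[["80"]]$parameters$half_life)
  msim <- ed_model(psim, network = models[["80"]]$network,
                   pgk_inhibitor = models[["80"]]$pgk_inhibitor)
  sssim <- .ss_solve(msim$parms, unname(msim$initial_state),
                     ctx$ss_tol, ctx$ss_horizon)
  if (!ss70$converged || !ss80$converged || !sssim$converged)
    return(rep(1000, nres))
  c70 <- setNames(ss70$y, .ed_state_ids())
  c80 <- setNames(ss80$y, .ed_state_ids())
  csim <- setNames(sssim$y, .ed_state_ids())
  r_vh <- (c80 - csim) / c80
  tgt <- ctx$ratio_targets
  r_ratio <- (c70[names(tgt)] / c80[names(tgt)] - tgt) / tgt
  pen <- 10 * pmax(0, c(c70, c80) - ctx$conc_limit) / ctx$conc_limit
  unname(c(r_vh, r_ratio, pen))
}

#' Sum-of-squared-residuals objective for the free-parameter fit
#'
#' `SSR = sum(((SS80 - SSsim80)/SS80)^2) + sum(((ratio - target)/target)^2)`
#' where `SSsim80` is the steady state under doubled 70 degC velocities
#' and `ratio` the simulated 70/80 steady-state ratio of each target
#' metabolite, plus a quadratic penalty above the 100 mM concentration
#' cap.  Returns a large sentinel (`1e6`-scale) when any steady state
#' fails to converge, so optimizers can keep searching.
#'
#' @param candidate Named numeric vector; names are
#'   `"<70|80>.<velocity>"`, e.g. `"70.v_up"`, `"80.v_sinkGAP"`.
#' @param ctx A [fit_context()].
#' @return Scalar SSR (>= 0).
#' @export
ssr_objective <- function(candidate, ctx) {
  sum(.ssr_residuals(candidate, ctx)^2)
}

#' Fit the free velocities and sink rates
#'
#' Global-then-local strategy: a cheap objective screen over candidate
#' starting points (the context's current values, lognormal jitters
#' around them, and log-uniform draws over the whole box), followed by
#' bounded Levenberg-Marquardt refinement in log10 parameter space from
#' the `n_starts` best screened candidates.  Deterministic given `seed`.
#'
#' @param ctx A [fit_context()].
#' @param n_starts Number of local refinements (>= 1).
#' @param seed Integer seed for the screening draws.
#' @param maxiter Maximal Levenberg-Marquardt iterations per start.
#' @param n_screen Number of randomly drawn screening candidates.
#' @return An `ed_fit`: best candidate (natural scale), its SSR, the
#'   refitted models, a constraint-satisfaction report and the per-start
#'   trace.
#' @export
fit_free_parameters <- function(ctx, n_starts = 3, seed = 1, maxiter = 60,
                                n_screen = 40) {
  stopifnot(inherits(ctx, "fit_context"))
  lo <- log10(ctx$lower); hi <- log10(ctx$upper)
  resid_log <- function(theta) {
    cand <- setNames(10^theta, names(ctx$start))
    .ssr_residuals(cand, ctx)
  }
  ## screening pool: current values, jitters around them (factor ~2 per
  ## coordinate), and draws over the whole box; non-convergent
  ## candidates score the flat sentinel and are screened out
  set.seed(seed)
  pool <- c(list(log10(ctx$start)),
            lapply(seq_len(max(0, floor(n_screen / 2))), function(i)
              pmin(pmax(log10(ctx$start) + rnorm(length(lo), 0, 0.3),
                        lo), hi)),
            lapply(seq_len(max(0, ceiling(n_screen / 2))), function(i)
              lo + runif(length(lo)) * (hi - lo)))
  scores <- vapply(pool, function(th) sum(resid_log(th)^2), numeric(1))
  starts <- pool[order(scores)][seq_len(min(n_starts, length(pool)))]
  n_starts <- length(starts)
  trace <- data.frame(start = seq_len(n_starts), ssr = NA_real_)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[[i]], lower = unname(lo), upper = unname(hi),
      fn = resid_log,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    trace$ssr[i] <- ssr
    if (is.null(best) || ssr < best$ssr)
      best <- list(theta = fit$par, ssr = ssr, start = i)
  }
  if (is.null(best)) stop("no converging candidate found")
  cand <- setNames(10^best$theta, names(ctx$start))
  models <- .apply_candidate(cand, ctx)
  ss70 <- steady_state(models[["70"]], ctx$ss_tol, ctx$ss_horizon)
  ss80 <- steady_state(models[["80"]], ctx$ss_tol, ctx$ss_horizon)
  report <- list(
    within_bounds = all(cand >= ctx$lower & cand <= ctx$upper),
    ss70_converged = ss70$converged, ss80_converged = ss80$converged,
    conc_below_limit = ss70$converged && ss80$converged &&
      all(c(ss70$concentrations, ss80$concentrations) < ctx$conc_limit))
  structure(list(par = cand, ssr = best$ssr, models = models,
                 steady_states = list(`70` = ss70, `80` = ss80),
                 report = report, trace = trace, seed = seed),
            class = "ed_fit")
}

#' @export
print.ed_fit <- function(x, ...) {
  cat("ED free-parameter fit: SSR =", format(x$ssr, digits = 4),
      "| constraints:",
      if (all(unlist(x$report))) "all satisfied" else "VIOLATED", "\n")
  print(signif(x$par, 4))
  invisible(x)
}

#' Transfer a degradation rate from 70 degC to 80 degC
#'
#' Implements the published estimate for the 1,3-BPG degradation rate at
#' 80 degC: `vdeg80 = vdeg70 / mean(ratios)`.  The published formula is
#' ambiguous about whether the ratios are ratios of half-lives (70/80,
#' > 1, which makes degradation slower at 80 degC) or of degradation
#' rates (70/80, < 1, which makes it faster); this function applies the
#' division literally, and `inverted = TRUE` multiplies instead (the
#' physically expected direction when half-life ratios are supplied).
#'
#' @param vdeg70 Degradation rate at 70 degC (1/min, >= 0).
#' @param ratios Positive ratios (70 degC over 80 degC) of the reference
#'   metabolites' measured half-life quantities.
#' @param inverted Multiply by the mean ratio instead of dividing.
#' @return Degradation rate at 80 degC (1/min).
#' @export
degradation_rate_80_from_70 <- function(vdeg70, ratios, inverted = FALSE) {
  if (vdeg70 < 0) stop("vdeg70 must be non-negative")
  if (!length(ratios)) stop("empty ratio list")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (inverted) vdeg70 * mean(ratios) else vdeg70 / mean(ratios)
}
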