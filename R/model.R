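## Model instance = network + parameter set + initial state, plus the
## packed numeric parameter vector consumed by the compiled ODE core.
## Rate laws (minimal forms consistent with the stated reversibilities):
##   v_up                     zero-order influx
##   irreversible steps       Michaelis-Menten, V*S/(Km+S)
##   reversible steps         two-term reversible MM,
##                            (Vf*S/KmS - Vr*P/KmP)/(1 + S/KmS + P/KmP)
##                            (bimolecular product term for the npED
##                            aldolase, which cleaves KDG into GA + Pyr)
##   v_GK                     substrate-inhibited MM,
##                            V*S/(Km + S*(1 + S/Ki)) -- the glycerate
##                            feedforward throttle
##   v_PGK                    reversible MM times an effector-inhibition
##                            factor 1/(1 + I/Ki), effector configurable
##   sinks / degradation      first-order decay
## Clamped cofactor pools enter as multiplicative saturation factors
## c/(Kc + c) folded into the effective maximal velocities; they are not
## state variables.

## fixed orderings shared with src/ed_rhs.c
.ed_velocity_order <- function() c(
  "v_up", "v_GDH", "v_GAD", "v_KDGK", "v_KDPGA_sp",
  "v_KDPGA_np_f", "v_KDPGA_np_r", "v_GAPDH_f", "v_GAPDH_r", "v_GAPN",
  "v_PGK_f", "v_PGK_r", "v_iPGAM_f", "v_iPGAM_r", "v_GAOR",
  "v_GK", "v_ENO_f", "v_ENO_r", "v_PK", "v_PEPS",
  "v_sinkGAP", "v_sinkPyr", "v_degGAP", "v_degBPG", "v_degPEP")

.ed_km_order <- function() c(
  "v_GDH.Glc", "v_GAD.DGat", "v_KDGK.KDG", "v_KDPGA_sp.KDPG",
  "v_KDPGA_np.KDG", "v_KDPGA_np.GA", "v_KDPGA_np.Pyr",
  "v_GAPDH.GAP", "v_GAPDH.BPG", "v_GAPN.GAP",
  "v_PGK.BPG", "v_PGK.PG3", "v_iPGAM.PG3", "v_iPGAM.PG2",
  "v_GAOR.GA", "v_GK.Gly", "v_ENO.PG2", "v_ENO.PEP",
  "v_PK.PEP", "v_PEPS.Pyr")

## cofactor consumed by each directional velocity (NA = none)
.ed_cofactor_map <- function() c(
  v_up = NA, v_GDH = "NADP", v_GAD = NA, v_KDGK = "ATP", v_KDPGA_sp = NA,
  v_KDPGA_np_f = NA, v_KDPGA_np_r = NA, v_GAPDH_f = "NADP",
  v_GAPDH_r = "NADPH", v_GAPN = "NADP", v_PGK_f = "ADP", v_PGK_r = "ATP",
  v_iPGAM_f = NA, v_iPGAM_r = NA, v_GAOR = "Fd", v_GK = "ATP",
  v_ENO_f = NA, v_ENO_r = NA, v_PK = "ADP", v_PEPS = "ATP")

.cofactor_factors <- function(cofactors) {
  map <- .ed_cofactor_map()
  pools <- cofactors$pools
  kms <- cofactors$km
  vapply(map, function(cf) {
    if (is.na(cf)) 1 else pools[[cf]] / (kms[[cf]] + pools[[cf]])
  }, numeric(1))
}

#' Assemble a runnable model instance
#'
#' Combines a validated network and a kinetic parameter set into a model
#' instance: converts cell-free-extract activities to fluxes, folds the
#' clamped cofactor pools into the effective maximal velocities, derives
#' degradation rates from half-lives, and sets initial conditions
#' (0.1 mM everywhere except Glc and D-Gat, which start at the values
#' implied by balancing their rate laws against the influx).
#'
#' @param parameters An [ed_parameters()] object.
#' @param network An `ed_network` (default topology if omitted).
#' @param initial_state Optional named concentration vector (mM) over the
#'   12 state metabolites, overriding the defaults.
#' @param pgk_inhibitor Metabolite id acting as the effector that inhibits
#'   `v_PGK` (`NA` to disable); must match the `v_PGK.<effector>` Ki
#'   entry.  Default `"PG3"` (product inhibition).
#' @return An object of class `ed_model`.
#' @export
ed_model <- function(parameters, network = build_network(),
                     initial_state = NULL, pgk_inhibitor = "PG3") {
  vnames <- .ed_velocity_order()
  enz <- setdiff(vnames, c("v_sinkGAP", "v_sinkPyr",
                           "v_degGAP", "v_degBPG", "v_degPEP"))
  missing_v <- setdiff(enz, names(parameters$vmax))
  if (length(missing_v))
    stop("parameter set lacks velocities: ", paste(missing_v, collapse = ", "))
  missing_k <- setdiff(.ed_km_order(), names(parameters$km))
  if (length(missing_k))
    stop("parameter set lacks Km values: ", paste(missing_k, collapse = ", "))
  if (!"v_GK.Gly" %in% names(parameters$ki))
    stop("parameter set lacks the v_GK.Gly substrate-inhibition constant")

  fac <- .cofactor_factors(parameters$cofactors)
  v_flux <- scale_activity_to_flux(parameters$vmax[enz],
                                   parameters$volume_factor) * fac[enz]
  deg <- degradation_rates(parameters)
  velocities <- c(v_flux, parameters$sink_rates[c("v_sinkGAP", "v_sinkPyr")],
                  deg)
  names(velocities) <- vnames

  ki_gk <- parameters$ki[["v_GK.Gly"]]
  inh_idx <- 0
  ki_pgk <- Inf
  if (!is.na(pgk_inhibitor)) {
    key <- paste0("v_PGK.", pgk_inhibitor)
    if (!key %in% names(parameters$ki))
      stop("no Ki entry for the v_PGK effector: ", key)
    ki_pgk <- parameters$ki[[key]]
    inh_idx <- match(pgk_inhibitor, .ed_state_ids())
  }
  parms <- c(unname(velocities), unname(parameters$km[.ed_km_order()]),
             ki_gk, ki_pgk, inh_idx)

  state <- setNames(rep(0.1, 12), .ed_state_ids())
  ## influx-balanced starting values for the first two metabolites:
  ## solve V*S/(Km+S) = v_up for S (fall back to 0.1 mM if infeasible)
  vin <- velocities[["v_up"]]
  solve_mm <- function(v, km) if (v > vin) km * vin / (v - vin) else 0.1
  state["Glc"] <- solve_mm(velocities[["v_GDH"]],
                           parameters$km[["v_GDH.Glc"]])
  state["DGat"] <- solve_mm(velocities[["v_GAD"]],
                            parameters$km[["v_GAD.DGat"]])
  if (!is.null(initial_state)) {
    if (is.null(names(initial_state)))
      stop("initial_state must be a named vector")
    if (any(initial_state < 0)) stop("initial concentrations must be >= 0")
    state[names(initial_state)] <- initial_state
  }

  structure(list(network = network, parameters = parameters,
                 velocities = velocities, parms = parms,
                 initial_state = state, pgk_inhibitor = pgk_inhibitor),
            class = "ed_model")
}

#' @export
print.ed_model <- function(x, ...) {
  cat("ED pathway model at", x$parameters$temperature, "degC;",
      "influx", signif(x$velocities[["v_up"]], 4), "mM/min\n")
  invisible(x)
}

## ---------------------------------------------------------------------
## Reference rate-law evaluation in R (mirrors src/ed_rhs.c)
## ---------------------------------------------------------------------

.rates_from_parms <- function(y, p) {
  y <- unname(pmax(y, 0))
  Glc <- y[1]; DGat <- y[2]; KDG <- y[3]; KDPG <- y[4]; GAP <- y[5]
  BPG <- y[6]; PG3 <- y[7]; PG2 <- y[8]; PEP <- y[9]; Pyr <- y[10]
  GA <- y[11]; Gly <- y[12]
  km <- p[26:45]
  ki_gk <- p[46]; ki_pgk <- p[47]; inh_idx <- p[48]

  a <- KDG / km[5]; b <- GA / km[6]; cc <- Pyr / km[7]
  v_np <- (p[6] * a - p[7] * b * cc) / (1 + a + b + cc + b * cc)
  a <- GAP / km[8]; b <- BPG / km[9]
  v_gapdh <- (p[8] * a - p[9] * b) / (1 + a + b)
  a <- BPG / km[11]; b <- PG3 / km[12]
  inh <- if (inh_idx > 0) 1 / (1 + y[inh_idx] / ki_pgk) else 1
  v_pgk <- (p[11] * a - p[12] * b) / (1 + a + b) * inh
  a <- PG3 / km[13]; b <- PG2 / km[14]
  v_ipgam <- (p[13] * a - p[14] * b) / (1 + a + b)
  a <- PG2 / km[17]; b <- PEP / km[18]
  v_eno <- (p[17] * a - p[18] * b) / (1 + a + b)

  c(v_up = p[1],
    v_GDH = p[2] * Glc / (km[1] + Glc),
    v_GAD = p[3] * DGat / (km[2] + DGat),
    v_KDGK = p[4] * KDG / (km[3] + KDG),
    v_KDPGA_sp = p[5] * KDPG / (km[4] + KDPG),
    v_KDPGA_np = v_np,
    v_GAPDH = v_gapdh,
    v_GAPN = p[10] * GAP / (km[10] + GAP),
    v_PGK = v_pgk,
    v_iPGAM = v_ipgam,
    v_GAOR = p[15] * GA / (km[15] + GA),
    v_GK = p[16] * Gly / (km[16] + Gly * (1 + Gly / ki_gk)),
    v_ENO = v_eno,
    v_PK = p[19] * PEP / (km[19] + PEP),
    v_PEPS = p[20] * Pyr / (km[20] + Pyr),
    v_sinkGAP = p[21] * GAP,
    v_sinkPyr = p[22] * Pyr,
    v_degGAP = p[23] * GAP,
    v_degBPG = p[24] * BPG,
    v_degPEP = p[25] * PEP)
}

.derivs_from_rates <- function(v) {
  c(Glc = v[["v_up"]] - v[["v_GDH"]],
    DGat = v[["v_GDH"]] - v[["v_GAD"]],
    KDG = v[["v_GAD"]] - v[["v_KDGK"]] - v[["v_KDPGA_np"]],
    KDPG = v[["v_KDGK"]] - v[["v_KDPGA_sp"]],
    GAP = v[["v_KDPGA_sp"]] - v[["v_GAPDH"]] - v[["v_GAPN"]] -
      v[["v_sinkGAP"]] - v[["v_degGAP"]],
    BPG = v[["v_GAPDH"]] - v[["v_PGK"]] - v[["v_degBPG"]],
    PG3 = v[["v_PGK"]] + v[["v_GAPN"]] - v[["v_iPGAM"]],
    PG2 = v[["v_iPGAM"]] + v[["v_GK"]] - v[["v_ENO"]],
    PEP = v[["v_ENO"]] + v[["v_PEPS"]] - v[["v_PK"]] - v[["v_degPEP"]],
    Pyr = v[["v_KDPGA_sp"]] + v[["v_KDPGA_np"]] + v[["v_PK"]] -
      v[["v_PEPS"]] - v[["v_sinkPyr"]],
    GA = v[["v_KDPGA_np"]] - v[["v_GAOR"]],
    Gly = v[["v_GAOR"]] - v[["v_GK"]])
}

#' Evaluate all reaction rates at a state
#'
#' Net fluxes (mM/min) of the 20 reactions at the given concentrations;
#' reversible reactions report a signed net rate (positive = catabolic
#' direction).
#'
#' @param state Named or ordered concentration vector (mM), length 12.
#' @param model An `ed_model`.
#' @return Named flux vector.
#' @export
reaction_rates <- function(state, model) {
  state <- .as_state(state)
  if (any(state < 0)) stop("concentrations must be non-negative")
  .rates_from_parms(state, model$parms)
}

#' Right-hand side of the ODE system
#'
#' Time derivative of each state metabolite: signed stoichiometry times
#' reaction rates, minus degradation and sink losses.  The clamped
#' cofactors contribute no state equations.
#'
#' @inheritParams reaction_rates
#' @return Named derivative vector (mM/min), length 12.
#' @export
system_derivatives <- function(state, model) {
  state <- .as_state(state)
  .derivs_from_rates(.rates_from_parms(state, model$parms))
}

.as_state <- function(state) {
  ids <- .ed_state_ids()
  if (length(state) != 12) stop("state must have 12 components")
  if (!is.null(names(state))) {
    if (!all(ids %in% names(state))) stop("state names must be the 12 metabolites")
    state <- state[ids]
  } else names(state) <- ids
  state
}

#' Carbon-weighted balance of the derivative vector
#'
#' At any state, the carbon-weighted sum of the time derivatives equals
#' carbon inflow minus outflow:
#' `6 v_up - 3 (v_sinkGAP + v_sinkPyr + v_degGAP + v_degBPG + v_degPEP)`.
#' Used as a stoichiometric-consistency oracle.
#'
#' @inheritParams reaction_rates
#' @return List with `lhs` (carbon-weighted derivative sum) and `rhs`
#'   (inflow minus outflow), both in mM carbon/min.
#' @export
carbon_balance <- function(state, model) {
  v <- reaction_rates(state, model)
  d <- system_derivatives(state, model)
  carbon <- setNames(ed_metabolites()$carbon, ed_metabolites()$id)
  list(lhs = sum(carbon * d[names(carbon)]),
       rhs = 6 * v[["v_up"]] - 3 * (v[["v_sinkGAP"]] + v[["v_sinkPyr"]] +
                                      v[["v_degGAP"]] + v[["v_degBPG"]] +
                                      v[["v_degPEP"]]))
}

## Replace selected velocities (U/g CE for enzymatic, 1/min for sinks) in
## a model, repacking the compiled-parameter vector.  Internal workhorse
## for knockouts, sensitivity and Monte-Carlo perturbation.
.with_velocities <- function(model, vmax = NULL, sink_rates = NULL,
                             deg_rates = NULL, ki = NULL, cofactors = NULL) {
  par <- model$parameters
  if (!is.null(vmax)) par$vmax[names(vmax)] <- vmax
  if (!is.null(sink_rates)) par$sink_rates[names(sink_rates)] <- sink_rates
  if (!is.null(ki)) par$ki[names(ki)] <- ki
  if (!is.null(cofactors)) par$cofactors <- cofactors
  m <- ed_model(par, network = model$network,
                pgk_inhibitor = model$pgk_inhibitor)
  if (!is.null(deg_rates)) {
    idx <- match(names(deg_rates), .ed_velocity_order())
    m$parms[idx] <- deg_rates
    m$velocities[names(deg_rates)] <- deg_rates
  }
  m
}
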