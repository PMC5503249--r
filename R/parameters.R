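## Temperature-indexed kinetic parameter sets.
##
## Maximal velocities are stored as measured in cell-free extract
## (U/g CE, U = umol/min) and converted to intracellular fluxes (mM/min)
## at model build time through the cytosolic protein density factor.
## Km/Ki are in mM and shared across temperatures; half-lives (min) of the
## thermolabile intermediates are temperature-specific and converted to
## first-order decay constants (1/min).

ED_VOLUME_FACTOR <- 0.250 # g protein per mL cytosol: U/g CE -> mM/min

## Default clamped cofactor pools (mM) and their affinity constants (mM).
## Pools are near-saturating so that +/-25% variation barely moves the
## effective velocities (tested as the cofactor-clamp robustness property).
.ed_default_cofactors <- function() {
  list(pools = c(ATP = 2.5, ADP = 0.8, NADP = 0.15, NADPH = 0.25, Fd = 1.0),
       km = c(ATP = 0.15, ADP = 0.08, NADP = 0.03, NADPH = 0.05, Fd = 0.1))
}

#' Convert a metabolite half-life to a first-order degradation rate
#'
#' First-order decay gives `rate = ln(2) / t_half`.
#'
#' @param t_half Half-life in minutes; must be positive.
#' @return Degradation rate in 1/min.
#' @export
half_life_to_degradation_rate <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop("half-life must be positive and finite")
  log(2) / t_half
}

#' Scale a cell-free-extract enzyme activity to an intracellular flux
#'
#' Activities measured in U/g cell-free extract (U = umol/min) are scaled
#' by the cytosolic protein density (g/mL), giving umol/(min mL), i.e.
#' mM/min.
#'
#' @param activity Specific activity in U/g CE (non-negative).
#' @param volume_factor Cytosolic protein density in g/mL (default 0.250).
#' @return Maximal velocity in mM/min.
#' @export
scale_activity_to_flux <- function(activity, volume_factor = ED_VOLUME_FACTOR) {
  if (any(activity < 0)) stop("activity must be non-negative")
  activity * volume_factor
}

#' Construct a temperature-indexed kinetic parameter set
#'
#' @param temperature Temperature in degrees Celsius (70 or 80 for the
#'   shipped parameterizations; any value is accepted).
#' @param vmax Named numeric vector of maximal velocities in U/g CE over
#'   the directional velocity names of the network (see
#'   [velocity_names()]), including the zero-order influx `v_up`.
#' @param vmax_sd Named numeric vector of standard deviations (U/g CE) for
#'   the measured velocities; entries absent or `NA` mark fitted (free)
#'   velocities.
#' @param sink_rates Named first-order rate constants (1/min) for
#'   `v_sinkGAP` and `v_sinkPyr`.
#' @param half_life Named half-lives (min) for the thermolabile
#'   metabolites `GAP`, `BPG`, `PEP`.
#' @param km Named Michaelis constants (mM); names are
#'   `"<reaction>.<metabolite>"`, e.g. `"v_GDH.Glc"`.
#' @param ki Named inhibition constants (mM); `"v_GK.Gly"` (substrate
#'   inhibition of glycerate kinase) and `"v_PGK.<effector>"` (effector
#'   inhibition of phosphoglycerate kinase).
#' @param cofactors Optional list with elements `pools` and `km`
#'   (clamped cofactor concentrations and affinities, mM).
#' @param volume_factor Cytosolic protein density, g/mL.
#' @return An object of class `ed_parameters`.
#' @export
ed_parameters <- function(temperature, vmax, vmax_sd = numeric(0),
                          sink_rates, half_life, km, ki,
                          cofactors = .ed_default_cofactors(),
                          volume_factor = ED_VOLUME_FACTOR) {
  if (any(vmax < 0)) stop("all vmax must be non-negative")
  if (any(sink_rates < 0)) stop("sink rates must be non-negative")
  if (length(vmax_sd) && any(vmax_sd[!is.na(vmax_sd)] < 0))
    stop("vmax standard deviations must be non-negative")
  structure(list(temperature = temperature, vmax = vmax, vmax_sd = vmax_sd,
                 sink_rates = sink_rates, half_life = half_life,
                 km = km, ki = ki, cofactors = cofactors,
                 volume_factor = volume_factor),
            class = "ed_parameters")
}

#' @export
print.ed_parameters <- function(x, ...) {
  src <- vmax_source(x)
  cat("ED kinetic parameter set at", x$temperature, "degC:",
      sum(src == "measured"), "measured +", sum(src == "fitted"),
      "free velocities,", length(x$sink_rates), "sinks,",
      length(x$half_life), "half-lives,", length(x$km), "Km,",
      length(x$ki), "Ki\n")
  invisible(x)
}

#' Measured/fitted provenance of the velocity parameters
#'
#' A velocity is `"measured"` when a standard deviation from the
#' cell-free-extract assays accompanies it, `"fitted"` otherwise.
#'
#' @param params An `ed_parameters` object.
#' @return Named character vector over the velocity names.
#' @export
vmax_source <- function(params) {
  nm <- names(params$vmax)
  measured <- nm %in% names(params$vmax_sd) &
    !is.na(params$vmax_sd[nm])
  setNames(ifelse(measured, "measured", "fitted"), nm)
}

#' Degradation rates derived from the stored half-lives
#'
#' @param params An `ed_parameters` object.
#' @return Named rates (1/min) for `v_degGAP`, `v_degBPG`, `v_degPEP`.
#' @export
degradation_rates <- function(params) {
  hl <- params$half_life[c("GAP", "BPG", "PEP")]
  setNames(half_life_to_degradation_rate(hl),
           c("v_degGAP", "v_degBPG", "v_degPEP"))
}

## ---------------------------------------------------------------------
## Tabular parameter exchange (long TSV)
## ---------------------------------------------------------------------

#' Read kinetic parameter sets from a long-format TSV
#'
#' Expected columns: `reaction`, `parameter_kind`
#' (`vmax|km|ki|half_life|sink|cofactor_pool|cofactor_km`), `metabolite`,
#' `value`, `sd`, `units`, `temperature_C`, `source`.  Temperature-shared
#' rows (Km, Ki, cofactors) carry `NA` in `temperature_C`.
#'
#' @param path Path to the TSV file.
#' @return Named list of `ed_parameters`, one per temperature (names are
#'   the temperatures as character, e.g. `"70"`, `"80"`).
#' @export
read_parameter_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction", "parameter_kind", "metabolite", "value", "sd",
            "units", "temperature_C", "source")
  if (!all(need %in% names(tab)))
    stop("malformed parameter table, expected columns: ",
         paste(need, collapse = ", "))
  shared <- tab[is.na(tab$temperature_C), ]
  km <- shared[shared$parameter_kind == "km", ]
  ki <- shared[shared$parameter_kind == "ki", ]
  km_v <- setNames(km$value, paste0(km$reaction, ".", km$metabolite))
  ki_v <- setNames(ki$value, paste0(ki$reaction, ".", ki$metabolite))
  cof <- .ed_default_cofactors()
  cp <- shared[shared$parameter_kind == "cofactor_pool", ]
  ck <- shared[shared$parameter_kind == "cofactor_km", ]
  if (nrow(cp)) cof$pools[cp$metabolite] <- cp$value
  if (nrow(ck)) cof$km[ck$metabolite] <- ck$value

  temps <- sort(unique(tab$temperature_C[!is.na(tab$temperature_C)]))
  out <- lapply(temps, function(tc) {
    sub <- tab[!is.na(tab$temperature_C) & tab$temperature_C == tc, ]
    vm <- sub[sub$parameter_kind == "vmax", ]
    sk <- sub[sub$parameter_kind == "sink", ]
    hl <- sub[sub$parameter_kind == "half_life", ]
    vmax <- setNames(vm$value, vm$reaction)
    vmax_sd <- setNames(vm$sd, vm$reaction)
    vmax_sd <- vmax_sd[vm$source == "measured" & !is.na(vm$sd)]
    ed_parameters(temperature = tc, vmax = vmax, vmax_sd = vmax_sd,
                  sink_rates = setNames(sk$value, sk$reaction),
                  half_life = setNames(hl$value, hl$metabolite),
                  km = km_v, ki = ki_v, cofactors = cof)
  })
  names(out) <- as.character(temps)
  out
}

#' Write kinetic parameter sets to a long-format TSV
#'
#' Inverse of [read_parameter_table()].
#'
#' @param params_list Named list of `ed_parameters` (names ignored;
#'   temperatures are taken from the objects).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params_list, path) {
  if (inherits(params_list, "ed_parameters")) params_list <- list(params_list)
  rows <- list()
  p1 <- params_list[[1]]
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (i in seq_along(p1$km)) {
    nm <- strsplit(names(p1$km)[i], ".", fixed = TRUE)[[1]]
    add(reaction = nm[1], parameter_kind = "km", metabolite = nm[2],
        value = p1$km[[i]], sd = NA_real_, units = "mM",
        temperature_C = NA_real_, source = "literature")
  }
  for (i in seq_along(p1$ki)) {
    nm <- strsplit(names(p1$ki)[i], ".", fixed = TRUE)[[1]]
    add(reaction = nm[1], parameter_kind = "ki", metabolite = nm[2],
        value = p1$ki[[i]], sd = NA_real_, units = "mM",
        temperature_C = NA_real_, source = "literature")
  }
  for (i in seq_along(p1$cofactors$pools))
    add(reaction = "", parameter_kind = "cofactor_pool",
        metabolite = names(p1$cofactors$pools)[i],
        value = p1$cofactors$pools[[i]], sd = NA_real_, units = "mM",
        temperature_C = NA_real_, source = "literature")
  for (i in seq_along(p1$cofactors$km))
    add(reaction = "", parameter_kind = "cofactor_km",
        metabolite = names(p1$cofactors$km)[i],
        value = p1$cofactors$km[[i]], sd = NA_real_, units = "mM",
        temperature_C = NA_real_, source = "literature")
  for (p in params_list) {
    src <- vmax_source(p)
    for (i in seq_along(p$vmax)) {
      nm <- names(p$vmax)[i]
      add(reaction = nm, parameter_kind = "vmax", metabolite = "",
          value = p$vmax[[i]],
          sd = if (src[[i]] == "measured") p$vmax_sd[[nm]] else NA_real_,
          units = "U/gCE", temperature_C = p$temperature,
          source = src[[i]])
    }
    for (i in seq_along(p$sink_rates))
      add(reaction = names(p$sink_rates)[i], parameter_kind = "sink",
          metabolite = "", value = p$sink_rates[[i]], sd = NA_real_,
          units = "1/min", temperature_C = p$temperature, source = "fitted")
    for (i in seq_along(p$half_life))
      add(reaction = paste0("v_deg", names(p$half_life)[i]),
          parameter_kind = "half_life", metabolite = names(p$half_life)[i],
          value = p$half_life[[i]], sd = NA_real_, units = "min",
          temperature_C = p$temperature, source = "measured")
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
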