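## Synthetic ground-truth generator.  Emulates the statistical structure
## of the study data: cell-free-extract maximal velocities (value +/- SD,
## with a designated subset masked as unmeasurable), Van't Hoff pairing
## of the 70/80 degC parameterizations up to lognormal jitter, measured
## half-lives of the thermolabile intermediates, and noisy steady-state
## metabolite ratios.  Everything is reproducible from (seed, config).

## velocities whose activities the cell-free-extract assays could
## resolve; the rest (influx, KDG kinase, glycerate kinase, both enolase
## directions, the ferredoxin-dependent GAOR, the unassayed reverse
## directions, and the sinks) are "free" and must be fitted
.ed_measured_set <- function() c(
  "v_GDH", "v_GAD", "v_KDPGA_sp", "v_KDPGA_np_f", "v_KDPGA_np_r",
  "v_GAPDH_f", "v_GAPN", "v_PGK_f", "v_iPGAM_f", "v_PK", "v_PEPS")

.ed_free_set <- function() c(
  "v_up", "v_KDGK", "v_GAOR", "v_GK", "v_ENO_f", "v_ENO_r",
  "v_GAPDH_r", "v_PGK_r", "v_iPGAM_r")

#' Default configuration of the synthetic generator
#'
#' Ranges are chosen as field-plausible for cell-free-extract activities
#' of a thermoacidophile's central carbon metabolism: enzymatic
#' velocities within the (10, 1000) U/g CE feasibility box, Km/Ki
#' log-uniform over 0.01-10 mM (the span of typical published values),
#' half-lives of minutes-scale thermolabile intermediates that shorten
#' with temperature, and Van't Hoff pairing `v80 = 2 v70` up to
#' lognormal jitter.
#'
#' @return A named list of generator settings.
#' @export
synthetic_config <- function() {
  list(vmax70_range = c(30, 300),       # U/g CE, measured tier at 70 degC
       vup70_range = c(12, 25),         # influx, U/g CE
       free70_range = c(20, 200),       # unmeasured enzymatic tier
       sink_range = c(0.02, 0.5),       # 1/min
       km_range = c(0.01, 10),          # mM, log-uniform
       ki_range = c(0.1, 5),            # mM, log-uniform
       half_life70_range = c(2, 60),    # min
       half_life_shortening = c(2, 3.5),# t(70)/t(80)
       vant_hoff_sdlog = 0.1,           # jitter of the doubling
       sd_fraction = c(0.05, 0.2),      # measured SD as fraction of value
       conc_limit = 100, max_tries = 200)
}

.runif1 <- function(r) runif(1, r[1], r[2])
.rlogunif <- function(n, r) exp(runif(n, log(r[1]), log(r[2])))

#' Generate a Van't Hoff-paired ground-truth model pair
#'
#' Rejection-samples kinetic parameter sets until both the 70 degC and
#' the 80 degC model converge to steady states with every concentration
#' below the feasibility cap.  The 80 degC velocities equal the doubled
#' 70 degC velocities perturbed by lognormal jitter
#' (`sdlog = config$vant_hoff_sdlog`; set it to 0 for exact doubling).
#'
#' @param seed Integer seed.
#' @param config Settings from [synthetic_config()]; entries can be
#'   overridden by passing a partial list.
#' @return List with `model70`, `model80` (ground-truth `ed_model`s) and
#'   the accepted `parameters` pair.
#' @export
generate_ground_truth <- function(seed = 1, config = list()) {
  cfg <- modifyList(synthetic_config(), config)
  set.seed(seed)
  measured <- .ed_measured_set()
  free <- .ed_free_set()
  for (try in seq_len(cfg$max_tries)) {
    vmax70 <- c(
      setNames(.rlogunif(length(measured), cfg$vmax70_range), measured),
      setNames(.rlogunif(length(free), cfg$free70_range), free))
    vmax70["v_up"] <- .runif1(cfg$vup70_range)
    jit <- exp(rnorm(length(vmax70), 0, cfg$vant_hoff_sdlog))
    vmax80 <- 2 * vmax70 * jit
    sd_frac <- runif(length(measured), cfg$sd_fraction[1],
                     cfg$sd_fraction[2])
    km <- setNames(.rlogunif(length(.ed_km_order()), cfg$km_range),
                   .ed_km_order())
    ki <- setNames(.rlogunif(2, cfg$ki_range), c("v_GK.Gly", "v_PGK.PG3"))
    hl70 <- setNames(.rlogunif(3, cfg$half_life70_range),
                     c("GAP", "BPG", "PEP"))
    hl80 <- hl70 / runif(3, cfg$half_life_shortening[1],
                         cfg$half_life_shortening[2])
    sinks70 <- setNames(.rlogunif(2, cfg$sink_range),
                        c("v_sinkGAP", "v_sinkPyr"))
    sinks80 <- 2 * sinks70 * exp(rnorm(2, 0, cfg$vant_hoff_sdlog))

    mk <- function(temp, vmax, sinks, hl) {
      sds <- setNames(sd_frac * vmax[measured], measured)
      ed_parameters(temperature = temp, vmax = vmax, vmax_sd = sds,
                    sink_rates = sinks, half_life = hl, km = km, ki = ki)
    }
    p70 <- mk(70, vmax70, sinks70, hl70)
    p80 <- mk(80, vmax80, sinks80, hl80)
    m70 <- ed_model(p70); m80 <- ed_model(p80)
    ss70 <- steady_state(m70); ss80 <- steady_state(m80)
    ok <- ss70$converged && ss80$converged &&
      all(c(ss70$concentrations, ss80$concentrations) < cfg$conc_limit) &&
      all(vmax70[free] > 10 & vmax70[free] < 1000) &&
      all(vmax80[free] > 10 & vmax80[free] < 1000)
    if (ok)
      return(list(model70 = m70, model80 = m80,
                  parameters = list(`70` = p70, `80` = p80),
                  steady_states = list(`70` = ss70, `80` = ss80),
                  seed = seed, tries = try))
  }
  stop("sampling budget exhausted: no feasible ground truth in ",
       cfg$max_tries, " tries")
}

#' Generate noisy pseudo-observations from a ground truth
#'
#' Observation level mirrors the study data: (i) a velocity table with
#' the measured tier reported as value +/- SD under multiplicative
#' lognormal noise and the free tier masked, (ii) steady-state
#' metabolite ratios (70 degC over 80 degC) for Glc, D-Gat, KDG and Gly
#' with lognormal noise, and (iii) knockout-over-wild-type ratios at
#' 80 degC.
#'
#' @param ground_truth Output of [generate_ground_truth()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 reproduces the truth exactly).
#' @param seed Integer seed.
#' @return A `synthetic_dataset` list.
#' @export
generate_observations <- function(ground_truth, noise_cv = 0.05,
                                  seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  set.seed(seed)
  lnoise <- function(n) if (noise_cv == 0) rep(1, n) else
    exp(rnorm(n, -0.5 * log(1 + noise_cv^2),
              sqrt(log(1 + noise_cv^2))))
  measured <- .ed_measured_set()
  obs_vmax <- lapply(ground_truth$parameters, function(p) {
    v <- p$vmax[measured] * lnoise(length(measured))
    data.frame(reaction = measured, value = unname(v),
               sd = unname(pmax(noise_cv, 0.02) * v),
               temperature_C = p$temperature, row.names = NULL)
  })
  ss70 <- ground_truth$steady_states[["70"]]$concentrations
  ss80 <- ground_truth$steady_states[["80"]]$concentrations
  targets <- c("Glc", "DGat", "KDG", "Gly")
  ratios <- (ss70[targets] / ss80[targets]) * lnoise(length(targets))
  ## a sampled ground truth need not admit a knockout steady state (the
  ## substrate-inhibited glycerate kinase has finite capacity); report NA
  ## ratios in that case
  ko <- tryCatch(knockout_ratio_vs_wt(ground_truth$model80, "SP0") *
                   lnoise(6),
                 error = function(e)
                   setNames(rep(NA_real_, 6),
                            c("Glc", "DGat", "KDG", "GA", "Gly", "Pyr")))
  structure(list(vmax = do.call(rbind, obs_vmax),
                 ratio_targets = ratios, knockout_ratios = ko,
                 masked = .ed_free_set(), noise_cv = noise_cv,
                 seed = seed),
            class = "synthetic_dataset")
}

#' Load the packaged synthetic parameterization
#'
#' Reads the packaged parameter table (a synthetic stand-in
#' parameterization of the pathway at 70 and 80 degC whose free tier was
#' produced by the package's own constrained fit against the published
#' metabolome ratio targets) and the ratio-target table, and assembles
#' model instances.
#'
#' @return List with `model70`, `model80`, `parameters`,
#'   `ratio_targets` and `knockout_ratios` (the published
#'   knockout-over-wild-type reference ratios, as data).
#' @export
load_fixture_model <- function() {
  pfile <- system.file("extdata", "params_ed_synthetic.tsv",
                       package = "edflux", mustWork = TRUE)
  rfile <- system.file("extdata", "ratio_targets.tsv",
                       package = "edflux", mustWork = TRUE)
  params <- read_parameter_table(pfile)
  if (!all(c("70", "80") %in% names(params)))
    stop("malformed fixture: need 70 and 80 degC parameter sets")
  ratios <- read.delim(rfile, stringsAsFactors = FALSE)
  list(model70 = ed_model(params[["70"]]),
       model80 = ed_model(params[["80"]]),
       parameters = params,
       ratio_targets = setNames(
         ratios$ratio_70_over_80[!is.na(ratios$ratio_70_over_80)],
         ratios$metabolite[!is.na(ratios$ratio_70_over_80)]),
       knockout_ratios = setNames(ratios$knockout_sp0_over_wt_80,
                                  ratios$metabolite))
}
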