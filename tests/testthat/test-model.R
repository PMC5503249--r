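test_that("unit conversions follow their definitions", {
  expect_equal(half_life_to_degradation_rate(log(2)), 1.0)
  expect_equal(half_life_to_degradation_rate(10), log(2) / 10,
               tolerance = 1e-12)
  expect_equal(half_life_to_degradation_rate(10),
               2 * half_life_to_degradation_rate(20))
  expect_error(half_life_to_degradation_rate(0), "positive")

  expect_equal(scale_activity_to_flux(0), 0)
  expect_equal(scale_activity_to_flux(100, 0.250), 25)
  expect_equal(scale_activity_to_flux(1000, 0.250), 250)
  expect_error(scale_activity_to_flux(-1), "non-negative")
})

test_that("irreversible Michaelis-Menten laws hit midpoint and saturation", {
  m <- fx$model80
  km <- m$parameters$km[["v_GDH.Glc"]]
  vmax_eff <- m$velocities[["v_GDH"]]   # mM/min, cofactor-scaled
  st <- setNames(rep(0, 12), ed_metabolites()$id)

  st["Glc"] <- km
  expect_equal(reaction_rates(st, m)[["v_GDH"]], vmax_eff / 2,
               tolerance = 1e-12)
  st["Glc"] <- 1e6 * km
  expect_equal(reaction_rates(st, m)[["v_GDH"]], vmax_eff,
               tolerance = 1e-5)
})

test_that("glycerate kinase is substrate-inhibited with an interior optimum", {
  m <- fx$model80
  km <- m$parameters$km[["v_GK.Gly"]]
  ki <- m$parameters$ki[["v_GK.Gly"]]
  opt <- sqrt(km * ki)                  # maximizer of V S/(Km + S(1+S/Ki))
  st <- setNames(rep(0, 12), ed_metabolites()$id)
  rate_at <- function(gly) {
    st["Gly"] <- gly
    reaction_rates(st, m)[["v_GK"]]
  }
  expect_gt(rate_at(opt), rate_at(10 * opt))
  expect_gt(rate_at(opt), rate_at(opt / 10))
})

test_that("derivatives vanish everywhere except influx at the zero state", {
  m <- fx$model80
  d <- system_derivatives(setNames(rep(0, 12), ed_metabolites()$id), m)
  expect_equal(d[["Glc"]], m$velocities[["v_up"]])
  expect_equal(unname(d[names(d) != "Glc"]), rep(0, 11))
})

test_that("carbon-weighted derivative sum equals inflow minus outflow at random states", {
  m <- fx$model80
  set.seed(42)
  for (i in 1:20) {
    st <- setNames(runif(12, 0, 10), ed_metabolites()$id)
    cb <- carbon_balance(st, m)
    expect_equal(cb$lhs, cb$rhs, tolerance = 1e-9)
  }
})

test_that("compiled and R rate evaluations integrate to the same trajectory", {
  m <- fx$model80
  y0 <- unname(m$initial_state)
  times <- c(0, 0.5, 2, 10)
  sol_c <- deSolve::lsoda(y0, times, func = "ed_rhs", parms = m$parms,
                          dllname = "edflux", initfunc = "ed_init",
                          rtol = 1e-10, atol = 1e-12)
  rhs_r <- function(t, y, p) list(unname(
    edflux:::.derivs_from_rates(edflux:::.rates_from_parms(y, p))))
  sol_r <- deSolve::lsoda(y0, times, func = rhs_r, parms = m$parms,
                          rtol = 1e-10, atol = 1e-12)
  expect_equal(unclass(sol_c), unclass(sol_r), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("model construction sets the documented initial conditions", {
  m <- fx$model80
  init <- m$initial_state
  others <- setdiff(names(init), c("Glc", "DGat"))
  expect_equal(unname(init[others]), rep(0.1, length(others)))
  # Glc and D-Gat start where their rate laws balance the influx
  r <- reaction_rates(init, m)
  expect_equal(r[["v_GDH"]], m$velocities[["v_up"]], tolerance = 1e-9)
  expect_equal(r[["v_GAD"]], m$velocities[["v_up"]], tolerance = 1e-9)
})

test_that("rate evaluation rejects negative concentrations and bad parameters", {
  m <- fx$model80
  st <- m$initial_state
  st["Glc"] <- -1
  expect_error(reaction_rates(st, m), "non-negative")
  p <- fx$parameters[["80"]]
  p$km <- p$km[names(p$km) != "v_GDH.Glc"]
  expect_error(ed_model(p), "lacks Km")
  p2 <- fx$parameters[["80"]]
  p2$ki <- p2$ki[names(p2$ki) != "v_GK.Gly"]
  expect_error(ed_model(p2), "substrate-inhibition")
})

test_that("parameter table round-trips through the TSV dialect", {
  tmp <- tempfile(fileext = ".tsv")
  write_parameter_table(fx$parameters, tmp)
  back <- read_parameter_table(tmp)
  for (tm in c("70", "80")) {
    expect_equal(back[[tm]]$vmax, fx$parameters[[tm]]$vmax)
    expect_equal(back[[tm]]$km, fx$parameters[[tm]]$km)
    expect_equal(back[[tm]]$sink_rates, fx$parameters[[tm]]$sink_rates)
    expect_equal(back[[tm]]$half_life, fx$parameters[[tm]]$half_life)
    expect_equal(vmax_source(back[[tm]]), vmax_source(fx$parameters[[tm]]))
  }
})
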