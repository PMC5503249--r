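test_that("relative standard deviation follows the sample convention", {
  expect_equal(relative_standard_deviation(c(1, 2, 3)), 50)
  expect_equal(relative_standard_deviation(rep(4, 10)), 0)
  x <- rlnorm(20)
  expect_equal(relative_standard_deviation(3.7 * x),
               relative_standard_deviation(x))
  expect_error(relative_standard_deviation(1), "two samples")
  expect_error(relative_standard_deviation(c(-1, 1)), "zero mean")
})

test_that("sensitivity to the influx matches the closed-form glucose response", {
  # Glc* = Km phi / (V - phi): the +20% finite-difference sensitivity has
  # a closed form in the fixture parameters
  m <- fx$model80
  phi <- m$velocities[["v_up"]]
  V <- m$velocities[["v_GDH"]]
  expected <- (1.2 * (V - phi) / (V - 1.2 * phi) - 1) / 0.2
  S <- single_parameter_sensitivity(m, "v_up", 0.2, "Glc",
                                    base = fx_ss[["80"]])
  expect_equal(unname(S), expected, tolerance = 1e-4)
})

test_that("parameters off every path to a metabolite have zero sensitivity", {
  # glucose sits upstream of everything except the influx and its own
  # dehydrogenase; downstream velocities cannot move it
  for (p in c("v_sinkPyr", "v_PK", "v_GAOR"))
    expect_equal(unname(single_parameter_sensitivity(
      fx$model80, p, 0.2, "Glc", base = fx_ss[["80"]])), 0,
      tolerance = 1e-6)
  expect_error(single_parameter_sensitivity(fx$model80, "v_up", 0),
               "nonzero")
  expect_error(single_parameter_sensitivity(fx$model80, "nope", 0.2),
               "unknown velocity")
})

test_that("sensitivity matrix has full dimensions, sign markers and bounded averages", {
  S <- sensitivity_matrix(fx$model80)
  expect_equal(dim(S), c(22, 12))
  expect_true(all(is.finite(S)))
  expect_true(all(attr(S, "sign_marker") %in% c("+", "-")))
  avg <- attr(S, "metabolite_average")
  expect_length(avg, 12)
  expect_equal(unname(avg), unname(colMeans(unclass(S))))
})

test_that("external Monte Carlo is seeded, bounded, and degenerate at fraction zero", {
  ens0 <- monte_carlo_external(fx$model80, fraction = 0, n = 30, seed = 4)
  expect_equal(unname(ens0$stats$rsd), rep(0, 12), tolerance = 1e-8)

  ens <- monte_carlo_external(fx$model80, fraction = 0.5, n = 60, seed = 4)
  v <- fx$model80$velocities[["v_up"]]
  expect_true(all(ens$draws >= 0.5 * v & ens$draws <= 1.5 * v))
  expect_equal(ens$failures, 0)

  again <- monte_carlo_external(fx$model80, fraction = 0.5, n = 60, seed = 4)
  expect_identical(ens$draws, again$draws)
  expect_identical(ens$concentrations, again$concentrations)
  expect_error(monte_carlo_external(fx$model80, fraction = 1.2), "fraction")
})

test_that("internal Monte Carlo collapses to zero spread under zero-width bounds", {
  p <- gt0$parameters[["80"]]
  p$vmax_sd[] <- 0
  m <- ed_model(p)
  ens <- monte_carlo_internal(m, fraction = 0, n = 20, seed = 2)
  expect_equal(unname(ens$stats$rsd), rep(0, 12), tolerance = 1e-8)
})

test_that("internal Monte Carlo respects the measured-SD and fractional bounds", {
  ens <- monte_carlo_internal(fx$model80, fraction = 0.2, n = 40, seed = 8)
  b <- ens$bounds
  for (nm in rownames(b)) {
    expect_true(all(ens$draws[, nm] >= b[nm, "lower"] - 1e-12))
    expect_true(all(ens$draws[, nm] <= b[nm, "upper"] + 1e-12))
  }
  # measured tier spans +/- SD around the velocity, fitted tier +/- 20%
  src <- vmax_source(fx$parameters[["80"]])
  some_meas <- names(src)[src == "measured"][1]
  rel <- fx$parameters[["80"]]$vmax_sd[[some_meas]] /
    fx$parameters[["80"]]$vmax[[some_meas]]
  v <- fx$model80$velocities[[some_meas]]
  expect_equal(unname(b[some_meas, ]), c(v * (1 - rel), v * (1 + rel)),
               tolerance = 1e-12)
})

test_that("branch knockouts zero their target reactions and shift pyruvate as expected", {
  sp <- steady_state(knockout(fx$model80, "SP0"))
  np <- steady_state(knockout(fx$model80, "NP0"))
  wt <- fx_ss[["80"]]
  expect_equal(sp$fluxes[["v_KDGK"]], 0)
  expect_equal(np$fluxes[["v_KDPGA_np"]], 0)
  # semi-phosphorylative branch loses carbon to decay and the
  # gluconeogenic sink, so removing it raises pyruvate; removing the
  # non-phosphorylative branch lowers it
  expect_gt(sp$concentrations[["Pyr"]], wt$concentrations[["Pyr"]])
  expect_lt(np$concentrations[["Pyr"]], wt$concentrations[["Pyr"]])
  expect_error(knockout(fx$model80, "XX"))
})

test_that("knockout/wild-type ratios leave the upstream trunk untouched", {
  ratios <- knockout_ratio_vs_wt(fx$model80, "SP0")
  expect_equal(ratios[["Glc"]], 1, tolerance = 1e-4)
  expect_equal(ratios[["DGat"]], 1, tolerance = 1e-4)
  expect_gt(ratios[["KDG"]], 1)   # bifurcation metabolite accumulates
  expect_gt(ratios[["GA"]], 1)    # npED intermediates rise
})

test_that("pyruvate robustness is preserved under branch deletion", {
  n <- 300
  rsd_pyr <- vapply(c("WT", "SP0", "NP0"), function(v) {
    ens <- monte_carlo_internal(knockout(fx$model80, v), n = n, seed = 21)
    ens$stats$rsd[ens$stats$metabolite == "Pyr"]
  }, numeric(1))
  expect_lt(max(rsd_pyr) - min(rsd_pyr), 3)
})

test_that("feedforward perturbation shares draws and targets glycerate, not pyruvate", {
  ff0 <- perturb_feedforward(fx$model80, inhibition_fraction = 0, n = 25,
                             seed = 6)
  expect_identical(ff0$without$concentrations, ff0$with$concentrations)

  ff <- perturb_feedforward(fx$model80, inhibition_fraction = 0.2,
                            n = 400, seed = 6)
  d <- abs(ff$rsd_delta)
  expect_gt(d[["Gly"]], d[["Pyr"]])
  # pyruvate delivery is insulated: its RSD barely moves relative to the
  # ensemble's own Monte-Carlo error
  mc_err <- ff$without$stats$rsd[ff$without$stats$metabolite == "Pyr"] /
    sqrt(ff$without$n)
  expect_lt(d[["Pyr"]], 3 * mc_err)
})

test_that("relaxing the cofactor clamp barely moves the steady state", {
  vc0 <- vary_cofactors(fx$model80, fraction = 0)
  expect_equal(vc0$rel_down, rep(0, 12), tolerance = 1e-8)
  expect_equal(vc0$rel_up, rep(0, 12), tolerance = 1e-8)

  vc <- vary_cofactors(fx$model80, fraction = 0.25)
  expect_lt(max(abs(c(vc$rel_down, vc$rel_up))), 0.10)
})

test_that("ensemble RSDs are stable in the ensemble size", {
  small <- monte_carlo_internal(fx$model80, n = 1000, seed = 31)
  large <- monte_carlo_internal(fx$model80, n = 4000, seed = 32)
  expect_true(all(abs(small$stats$rsd - large$stats$rsd) < 2))
})
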