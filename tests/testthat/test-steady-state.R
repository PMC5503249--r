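test_that("generic integrator reproduces the closed-form fixed point of a linear system", {
  rhs <- function(t, y, p) list(p["k1"] - p["k2"] * y)
  out <- integrate_to_steady_state(rhs, c(X = 0), c(k1 = 2, k2 = 1))
  expect_true(out$converged)
  expect_equal(unname(out$y), 2.0, tolerance = 1e-6)

  # pure influx has no fixed point
  out2 <- integrate_to_steady_state(function(t, y, p) list(1),
                                    c(X = 0), horizon = 1e3)
  expect_false(out2$converged)
})

test_that("the packaged models converge below the concentration cap", {
  for (tm in c("70", "80")) {
    ss <- fx_ss[[tm]]
    expect_true(ss$converged)
    expect_lte(ss$max_residual_rate, 1e-6)
    expect_true(all(is.finite(ss$concentrations)))
    expect_true(all(ss$concentrations >= 0))
    expect_true(all(ss$concentrations < 100))
  }
})

test_that("per-metabolite production balances consumption at steady state", {
  for (tm in c("70", "80")) {
    m <- if (tm == "70") fx$model70 else fx$model80
    d <- system_derivatives(fx_ss[[tm]]$concentrations, m)
    expect_true(all(abs(d) <= 1e-6))
  }
})

test_that("carbon balance holds at steady state: 6 v_up = 3 sum(outflows)", {
  fl <- fx_ss[["80"]]$fluxes
  outflow <- fl[["v_sinkGAP"]] + fl[["v_sinkPyr"]] + fl[["v_degGAP"]] +
    fl[["v_degBPG"]] + fl[["v_degPEP"]]
  expect_equal(6 * fl[["v_up"]], 3 * outflow, tolerance = 1e-5)
})

test_that("irreversible fluxes are non-negative at steady state", {
  irr <- c("v_up", "v_GDH", "v_GAD", "v_KDGK", "v_KDPGA_sp", "v_GAPN",
           "v_GAOR", "v_GK", "v_PK", "v_PEPS", "v_sinkGAP", "v_sinkPyr",
           "v_degGAP", "v_degBPG", "v_degPEP")
  expect_true(all(fx_ss[["80"]]$fluxes[irr] >= 0))
})

test_that("steady state is independent of the initial conditions", {
  # starts span an order of magnitude around the documented 0.1 mM
  # defaults; far outside that range the feedforward throttle on
  # glycerate kinase bounds the basin of attraction (see the methods
  # vignette)
  ref <- fx_ss[["80"]]$concentrations
  set.seed(99)
  for (i in 1:5) {
    y0 <- setNames(10^runif(12, -2, 0), ed_metabolites()$id)
    ss <- steady_state(fx$model80, initial_state = y0)
    expect_true(ss$converged)
    expect_equal(ss$concentrations, ref, tolerance = 1e-4)
  }
})

test_that("a converged steady state is a fixed point of the integrator", {
  ss <- fx_ss[["80"]]
  again <- steady_state(fx$model80, initial_state = ss$concentrations)
  expect_true(again$converged)
  expect_equal(again$concentrations, ss$concentrations, tolerance = 1e-8)
})

test_that("steady-state fluxes require convergence and match rate re-evaluation", {
  expect_equal(steady_state_fluxes(fx$model80, fx_ss[["80"]]),
               reaction_rates(fx_ss[["80"]]$concentrations, fx$model80))
  bad <- fx_ss[["80"]]; bad$converged <- FALSE
  expect_error(steady_state_fluxes(fx$model80, bad), "converge")
})

test_that("an unbranched three-step chain carries one flux at steady state", {
  # sp-branch knockout plus np-knockout is not a chain; instead check on
  # the np-knockout that the common trunk Glc -> DGat -> KDG carries the
  # influx exactly
  fl <- steady_state(knockout(fx$model80, "NP0"))$fluxes
  expect_equal(unname(fl[c("v_GDH", "v_GAD", "v_KDGK")]),
               rep(fl[["v_up"]], 3), tolerance = 1e-6)
})

test_that("weighted relative change reproduces hand-computed values", {
  sim <- fake_ss(c(A = 2, B = 2))
  ref <- fake_ss(c(A = 1, B = 2))
  cmp <- weighted_relative_change(sim, ref, "metabolite")
  expect_equal(cmp$rc, c(0.25, 0))
  expect_equal(sum(cmp$weight), 1)
  expect_equal(attr(cmp, "mean_ratio"), 1.5)

  ident <- weighted_relative_change(sim, sim, "metabolite")
  expect_equal(ident$rc, c(0, 0))
  expect_equal(attr(ident, "mean_ratio"), 1)

  expect_error(weighted_relative_change(fake_ss(c(A = 0, B = 1)),
                                        fake_ss(c(A = 1, B = 1)),
                                        "metabolite"), "zero simulated")
})
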