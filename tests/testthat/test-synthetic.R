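test_that("ground-truth generation is deterministic and feasible by construction", {
  a <- generate_ground_truth(seed = 55)
  b <- generate_ground_truth(seed = 55)
  expect_identical(a$parameters[["70"]]$vmax, b$parameters[["70"]]$vmax)
  expect_identical(a$parameters[["80"]]$km, b$parameters[["80"]]$km)

  for (tm in c("70", "80")) {
    ss <- a$steady_states[[tm]]
    expect_true(ss$converged)
    expect_true(all(ss$concentrations < 100))
  }
  free <- a$parameters[["80"]]$vmax[edflux:::.ed_free_set()]
  expect_true(all(free > 10 & free < 1000))
})

test_that("zero jitter gives exact Van't Hoff pairing; jitter keeps the mean near 2", {
  expect_equal(gt0$parameters[["80"]]$vmax / gt0$parameters[["70"]]$vmax,
               setNames(rep(2, length(gt0$parameters[["80"]]$vmax)),
                        names(gt0$parameters[["80"]]$vmax)))
  gtj <- generate_ground_truth(seed = 77,
                               config = list(vant_hoff_sdlog = 0.1))
  ratios <- gtj$parameters[["80"]]$vmax / gtj$parameters[["70"]]$vmax
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})

test_that("observations reproduce the truth exactly at zero noise", {
  obs <- generate_observations(gt0, noise_cv = 0, seed = 9)
  ss70 <- gt0$steady_states[["70"]]$concentrations
  ss80 <- gt0$steady_states[["80"]]$concentrations
  tg <- c("Glc", "DGat", "KDG", "Gly")
  expect_equal(obs$ratio_targets, ss70[tg] / ss80[tg])
  v80 <- obs$vmax[obs$vmax$temperature_C == 80, ]
  expect_equal(setNames(v80$value, v80$reaction),
               gt0$parameters[["80"]]$vmax[edflux:::.ed_measured_set()])
  expect_true(all(obs$vmax$sd > 0))
  expect_setequal(obs$masked, edflux:::.ed_free_set())
})

test_that("observed-ratio spread grows with the noise level", {
  spread <- vapply(c(0.05, 0.1, 0.2), function(cv) {
    reps <- vapply(1:40, function(i)
      generate_observations(gt0, noise_cv = cv, seed = 1000 + i)
      $ratio_targets[["Glc"]], numeric(1))
    sd(reps) / mean(reps)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("the packaged parameterization is complete and carries the published targets", {
  expect_equal(length(velocity_names(fx$model80$network,
                                     include_first_order = TRUE)), 25)
  src <- vmax_source(fx$parameters[["80"]])
  expect_equal(sum(src == "measured"), 11)
  expect_equal(sum(src == "fitted"), 9)   # plus two fitted sinks
  expect_length(fx$parameters[["80"]]$sink_rates, 2)
  expect_equal(fx$ratio_targets,
               c(Glc = 0.97, DGat = 1.27, KDG = 4.16, Gly = 1.91))
  expect_equal(fx$knockout_ratios[c("KDG", "GA", "Gly")],
               c(KDG = 2.79, GA = 2.79, Gly = 1.44))
})

test_that("sampling budget exhaustion is reported", {
  expect_error(generate_ground_truth(seed = 1,
                                     config = list(max_tries = 1,
                                                   vup70_range = c(1e4, 1e4))),
               "budget exhausted")
})
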