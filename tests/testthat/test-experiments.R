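test_that("scenario definitions enforce the model invariants", {
  expect_error(scenario(4), "model_id")
  expect_error(scenario(2, evolve_a = FALSE), "Model 3 only")
  expect_error(scenario(1, vg0_l = 0.5), "Model 3 only")
  s3 <- scenario(3, evolve_l = FALSE)
  expect_false(s3$evolve_l)
})

test_that("switching off both segregation variances reproduces the no-evolution model exactly", {
  m2 <- run_scenario(scenario(2), "SO", years = 35)
  m3_frozen <- run_scenario(scenario(3, vg0_a = 0, vg0_l = 0), "SO",
                            years = 35)
  a <- tidy(m2)[tidy(m2)$phase == "scenario", ]
  b <- tidy(m3_frozen)[tidy(m3_frozen)$phase == "scenario", ]
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})

test_that("the no-evolution model with zero trend reproduces the stable baseline", {
  m1 <- run_scenario(scenario(1), "SE", years = 30)
  m2k0 <- run_scenario(scenario(2, k_override = 0), "SE", years = 30)
  a <- tidy(m1)[tidy(m1)$phase == "scenario", ]
  b <- tidy(m2k0)[tidy(m2k0)$phase == "scenario", ]
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})

test_that("locally adapted optima track the climate and order warm above cool", {
  opt <- local_optima()
  # warmer climates carry higher optima (Table ordering: SO vs CW)
  expect_gt(opt$zstar_a[opt$id == "SO"], opt$zstar_a[opt$id == "CW"])
  expect_gt(opt$zstar_l[opt$id == "SO"], opt$zstar_l[opt$id == "CW"])

  # the packaged values are stationary points: re-running the stable
  # dynamics from them moves the means by less than the tolerance
  cl <- climate_location("NO")
  cl$trend <- 0
  z0 <- c(opt$zstar_a[opt$id == "NO"], opt$zstar_l[opt$id == "NO"])
  sim <- run_simulation(default_config(), cl, years = 10, z_init = z0,
                        latch_extinction = FALSE)
  # after the ecological transient the per-year trait displacement is
  # below the relaxation tolerance
  n <- nrow(sim)
  expect_lt(max(abs(sim$topt_A[n] - sim$topt_A[n - 1]),
                abs(sim$topt_L[n] - sim$topt_L[n - 1])), 0.02)

  # shift equivariance: a uniformly warmer world shifts both optima by
  # the same amount (within the convergence tolerance)
  base <- climate_location("SE")
  shifted <- base
  shifted$t_mean <- base$t_mean + 2
  z1 <- find_local_optima(base)
  z2 <- find_local_optima(shifted)
  expect_equal(z2$zstar_a - z1$zstar_a, 2, tolerance = 0.1)
  expect_equal(z2$zstar_l - z1$zstar_l, 2, tolerance = 0.1)
})

test_that("predator segregation variance controls rescue in the expected direction", {
  res <- sensitivity_vg0("NO", species = "ladybird",
                         vg0_values = c(0, 0.3), years = 151)
  # no heritable variation: the predator cannot track the warming trend
  expect_true(res$extinct_L[res$vg0 == 0])
  expect_false(res$extinct_L[res$vg0 == 0.3])
  expect_gt(res$ALP_final[res$vg0 == 0.3], res$ALP_final[res$vg0 == 0])
})

test_that("the swap experiment exchanges the designated climate parameters", {
  res <- swap_experiment("SO", "NO", which = "k", years = 25)
  expect_identical(nrow(res), 4L)
  so <- climate_location("SO"); no <- climate_location("NO")
  expect_equal(res$k[res$location == "SO" & res$run == "swapped"],
               no$trend)
  expect_equal(res$s[res$location == "SO" & res$run == "swapped"],
               so$seasonality)
  expect_equal(res$k[res$location == "NO" & res$run == "swapped"],
               so$trend)
  expect_equal(res$k[res$location == "SO" & res$run == "baseline"],
               so$trend)
})

test_that("the seasonality-trend sweep is deterministically ordered and annotated", {
  sw <- sweep_seasonality_trend("SO", s_values = c(12, 10.9),
                                k_values = c(5.78), years = 25)
  expect_identical(sw$s, c(10.9, 12))
  expect_named(sw, c("s", "k", "AAP_final", "ALP_final",
                     "ALP_last_decade", "extinct_L"))
  # repeated call is byte-identical (the model is deterministic)
  sw2 <- sweep_seasonality_trend("SO", s_values = c(12, 10.9),
                                 k_values = c(5.78), years = 25)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
})
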