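mid_season_state <- function(A = 2e6, L = 5e4, z_a = 20, z_l = 20.3) {
  gen_a <- genetic_state(z_a, inbreeding_f = 0.1)
  gen_l <- genetic_state(z_l)
  list(A = A, L = L, dist_a = genetic_dist(gen_a), gen_a = gen_a,
       gen_l = gen_l)
}

test_that("a daily step balances growth against predation exactly", {
  st <- mid_season_state()
  cfg <- quick_config()
  # choose L so that the mean predation loss equals the mean growth
  r <- sim_step(st, T = 21, dt = 1, config = cfg)$rates
  L_bal <- r$Fbar / r$beta_bar
  st$L <- L_bal
  out <- sim_step(st, T = 21, dt = 1, config = cfg)
  expect_equal(out$A, st$A, tolerance = 1e-9)

  # absent predators exert no predation and stay absent
  st0 <- mid_season_state(L = 0)
  st0$active_l <- FALSE
  out0 <- sim_step(st0, T = 21, dt = 1, config = cfg)
  expect_equal(out0$L, 0)
  expect_equal(out0$rates$Bbar, 0)
  expect_equal(out0$A, st0$A * (1 + out0$rates$Fbar), tolerance = 1e-12)
})

test_that("the step applies selection in the documented order with consistent rates", {
  st <- mid_season_state()
  out <- sim_step(st, T = 23, dt = 1)
  # warm day: directional selection should move both means upward
  expect_gt(out$gen_a$mean_g, st$gen_a$mean_g)
  expect_gt(out$gen_l$mean_g, st$gen_l$mean_g)
  # prey density stays normalized; predator distribution is the normal
  # implied by its updated genetic state
  expect_equal(evorescue:::bv_mass(out$dist_a), 1, tolerance = 1e-8)
  expect_equal(bv_mean(out$dist_l), out$gen_l$mean_g, tolerance = 1e-8)
  expect_equal(bv_var(out$dist_l), out$gen_l$var_g, tolerance = 1e-7)
})

test_that("the sexual switch follows the photoperiod-temperature rule", {
  expect_identical(sexual_switch(T = 10, DL = 12, mean_z_a = 19), 1L)
  # too warm relative to the evolved optimum: no switch regardless of DL
  expect_identical(sexual_switch(T = 20, DL = 12, mean_z_a = 19), 0L)
  # day too long: threshold 15.67 - 0.05 * 0 = 15.67 < 16
  expect_identical(sexual_switch(T = 0, DL = 16, mean_z_a = 19), 0L)
  # exact threshold arithmetic: DL just below -0.05 T + 15.67
  expect_identical(sexual_switch(T = 10, DL = 15.16, mean_z_a = 19), 1L)
  expect_identical(sexual_switch(T = 10, DL = 15.18, mean_z_a = 19), 0L)
})

test_that("overwintering takes 20% of both species once and freezes genetics", {
  st <- list(A = 1e6, L = 5000, phase_a = "active", phase_l = "active",
             gen_a = genetic_state(20), gen_l = genetic_state(20.5))
  out <- overwinter(st)
  expect_equal(out$A, 8e5)
  expect_equal(out$L, 4000)
  expect_identical(out$phase_a, "dormant")
  # genetics untouched, field by field
  expect_identical(out$gen_a, st$gen_a)
  expect_identical(out$gen_l, st$gen_l)
  # idempotent: a dormant state passes through unchanged
  out2 <- overwinter(out)
  expect_identical(out2, out)
})

test_that("a permanently cold climate never opens the season", {
  cold <- climate_params(-20, 2, 0, latitude = 44, label = "cold")
  sim <- run_simulation(default_config(), cold, years = 2,
                        z_init = c(20, 20))
  expect_true(all(sim$AAP == 0))
  expect_true(all(sim$ALP == 0))
  expect_true(all(is.na(sim$aphid_start)))
})

test_that("constant optimal temperature without predators drives prey toward K", {
  warm <- climate_params(20, 0, 0, latitude = 44, label = "warm")
  cfg <- default_config(init = list(L = 0))
  sim <- run_simulation(cfg, warm, years = 1, z_init = c(20, 20),
                        record_daily = TRUE)
  expect_identical(sim$aphid_start, 1L)
  expect_gt(sim$AAP, 0)
  daily <- attr(sim, "daily")
  # logistic limit: near the birth/death balance point below K
  expect_gt(max(daily$A), 0.85 * cfg$ecology$K)
  expect_true(sim$extinct_L)  # a zero predator pool latches extinct
})

test_that("non-evolving runs keep trait means exactly constant", {
  sim <- run_scenario(scenario(2), "NO", years = 30)
  rec <- tidy(sim)[tidy(sim)$phase == "scenario", ]
  expect_equal(length(unique(rec$topt_A)), 1L)
  expect_equal(length(unique(rec$topt_L)), 1L)
  expect_true(all(rec$vg_A == 0))
  expect_true(all(rec$vg_L == 0))
})

test_that("halving the time step changes first-year abundance by under 1%", {
  no <- climate_location("NO")
  z0 <- c(24.58, 24.84)
  s1 <- run_simulation(default_config(), no, years = 1, z_init = z0)
  s2 <- run_simulation(default_config(numerics = list(dt = 0.5)), no,
                       years = 1, z_init = z0)
  expect_equal(s2$AAP / s1$AAP, 1, tolerance = 0.01)
})

test_that("a multi-year run emits one complete summary per year", {
  sim <- run_simulation(default_config(), climate_location("SE"),
                        years = 5, z_init = c(25.70, 26.07))
  expect_identical(nrow(sim), 5L)
  expect_identical(sim$year, 2000:2004)
  expect_named(sim, c("year", "AAP", "ALP", "topt_A", "topt_L", "vg_A",
                      "vg_L", "aphid_start", "ladybird_start",
                      "switch_day", "extinct_L"))
  expect_true(all(sim$AAP >= 0 & sim$ALP >= 0))
  expect_true(all(sim$aphid_start <= sim$switch_day, na.rm = TRUE))
})
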