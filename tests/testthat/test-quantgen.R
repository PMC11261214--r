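test_that("breeding-value distributions normalize and report exact moments", {
  d <- gauss_dist(20, 0.3)
  expect_equal(evorescue:::bv_mass(d), 1, tolerance = 1e-12)
  expect_equal(bv_mean(d), 20, tolerance = 1e-10)
  expect_equal(bv_var(d), 0.3, tolerance = 1e-10)

  # point mass
  p <- bv_dist(19.5, 1)
  expect_true(p$degenerate)
  expect_equal(bv_mean(p), 19.5)
  expect_equal(bv_var(p), 0)

  expect_error(bv_dist(c(1, 2, 4), c(1, 1, 1)), "uniform")
  expect_error(bv_dist(1:3, c(1, -1, 1)), "non-negative")

  # the trapezoid expectation is exact for linear functions: a linear
  # rate averages to the rate at the mean
  lin <- 2 + 0.3 * d$grid
  expect_equal(evorescue:::bv_integrate(d, lin), 2 + 0.3 * bv_mean(d),
               tolerance = 1e-10)
})

test_that("Gaussian reweighting matches the conjugate-Gaussian closed form", {
  m0 <- 20; V <- 0.3; theta <- 20.5; omega2 <- 1
  d <- gauss_dist(m0, V)
  w <- exp(-(d$grid - theta)^2 / (2 * omega2))
  post <- bv_reweight(d, w)
  V_post <- 1 / (1 / V + 1 / omega2)
  m_post <- V_post * (m0 / V + theta / omega2)
  expect_equal(bv_mean(post), m_post, tolerance = 1e-8)
  expect_equal(bv_var(post), V_post, tolerance = 1e-8)
  expect_equal(evorescue:::bv_mass(post), 1, tolerance = 1e-10)
})

test_that("ladybird selection is inert for flat fitness and matches the linear-selection oracle", {
  d <- gauss_dist(20, 0.3)
  out <- select_ladybird(d, rep(0.07, length(d$grid)), 0.07, dt = 1)
  expect_equal(out$density, d$density, tolerance = 1e-12)

  # linear lineage growth w(z) = s z: mean shifts by s V dt / (1 + s m dt)
  s <- 0.01; dt <- 1; m <- 20; V <- 0.3
  out <- select_ladybird(d, s * d$grid, s * m, dt)
  expect_equal(bv_mean(out), m + s * V * dt / (1 + s * m * dt),
               tolerance = 1e-8)

  expect_error(select_ladybird(d, rep(-2, length(d$grid)), -2, 1),
               class = "evorescue_collapse")
})

test_that("aphid selection reproduces direct arithmetic on a five-point grid", {
  grid <- 0:4
  dens <- c(1, 2, 3, 2, 1)
  d <- bv_dist(grid, dens)
  F <- c(0.1, 0.2, 0.0, -0.1, 0.3)
  Bbar <- 0.05
  Fbar <- evorescue:::bv_integrate(d, F)
  out <- select_aphid(d, F, Bbar, Fbar, dt = 1)

  # direct arithmetic (independent of the implementation)
  w <- 1 + F - Bbar
  num <- d$density * w
  mass <- sum(num) - 0.5 * (num[1] + num[length(num)]) # dx = 1
  expect_equal(out$density, num / mass, tolerance = 1e-12)

  # flat F: no selection
  out0 <- select_aphid(d, rep(0.2, 5), 0.1, 0.2, 1)
  expect_equal(out0$density, d$density, tolerance = 1e-12)

  # the phenotype-independent predation term perturbs moments only at
  # O(dt^2): halving dt quarters the Bbar-induced mean shift
  d2 <- gauss_dist(20, 0.3)
  F2 <- 0.01 * (d2$grid - 20)
  mean_shift <- function(dt, Bbar) {
    Fbar <- evorescue:::bv_integrate(d2, F2)
    bv_mean(select_aphid(d2, F2, Bbar, Fbar, dt)) -
      bv_mean(select_aphid(d2, F2, 0, Fbar, dt))
  }
  s1 <- mean_shift(1, 0.02)
  s2 <- mean_shift(0.5, 0.02)
  expect_lt(abs(s1), 1e-4)            # small in absolute terms
  expect_equal(s2 / s1, 0.25, tolerance = 0.1) # scales as dt^2
})

test_that("mutation convolves mass- and mean-preservingly, adding exactly the kernel variance", {
  d <- gauss_dist(20, 0.3)

  expect_identical(mutate_aphid(d, 0), d)

  # narrow kernel: diffusion path
  v_small <- 1e-4
  out <- mutate_aphid(d, v_small)
  expect_equal(evorescue:::bv_mass(out), 1, tolerance = 1e-12)
  expect_equal(bv_mean(out), bv_mean(d), tolerance = 1e-10)
  expect_equal(bv_var(out) - bv_var(d), v_small, tolerance = 1e-8)

  # wide kernel: dense convolution path
  v_big <- 0.01
  out2 <- mutate_aphid(d, v_big)
  expect_equal(bv_mean(out2), bv_mean(d), tolerance = 1e-10)
  expect_equal(bv_var(out2) - bv_var(d), v_big, tolerance = 1e-8)

  # semigroup: two applications compose additively in variance
  ab <- mutate_aphid(mutate_aphid(d, 4e-5), 6e-5)
  once <- mutate_aphid(d, 1e-4)
  expect_equal(bv_var(ab), bv_var(once), tolerance = 1e-9)
  expect_lt(max(abs(ab$density - once$density)), 1e-6)

  # a point mass convolved with the kernel is the kernel
  pm <- bv_dist(20, 1)
  g <- mutate_aphid(pm, 0.09)
  expect_equal(bv_mean(g), 20, tolerance = 1e-10)
  expect_equal(bv_var(g), 0.09, tolerance = 1e-8)
})

test_that("the predator's Bulmer recursion has its textbook fixed points", {
  # no selection, no mutation: V_g stays at the segregation variance
  st <- genetic_state(mean_g = 20, var_g0 = 0.3, var_e = 0.7, h2m = 0)
  d <- genetic_dist(st)
  st1 <- update_ladybird_genetics(st, d, dt = 1)
  expect_equal(st1$var_g, 0.3, tolerance = 1e-9)
  expect_equal(st1$dev, 0, tolerance = 1e-9)

  # constant per-step change c in genetic variance: dev -> 2c
  cval <- 0.005
  st <- genetic_state(mean_g = 0, var_g0 = 0.3, var_e = 0.7, h2m = 0)
  for (i in 1:50) {
    d <- bv_dist_normal(0, st$var_g + cval)
    st <- update_ladybird_genetics(st, d, dt = 1)
  }
  expect_equal(st$dev, 2 * cval, tolerance = 1e-6)
  expect_equal(st$var_g, 0.3 + 2 * cval, tolerance = 1e-6)

  # mutation only: dev' = dev/2 + V_tau * dt
  st <- genetic_state(mean_g = 0, var_g0 = 0.3, var_e = 0.7,
                      h2m = 1e-3, eta = 1 / 7, dev = 0.01)
  d <- genetic_dist(st)
  st1 <- update_ladybird_genetics(st, d, dt = 1)
  expect_equal(st1$dev, 0.01 / 2 + st$var_tau, tolerance = 1e-8)
})

test_that("the prey's annual sexual reset restores variance with the inbreeding discount", {
  d <- gauss_dist(20, 0.25)

  # non-inbred reduction
  st <- genetic_state(mean_g = 20, var_g0 = 0.3, var_e = 0.7, h2m = 0,
                      inbreeding_f = 0)
  st1 <- sexual_reset_aphid(st, 0, d)
  expect_equal(st1$var_g, 0.3)

  # the paper's f = 0.1: (1 - f) V_g0 = 0.27
  st <- genetic_state(mean_g = 20, var_g0 = 0.3, var_e = 0.7, h2m = 0,
                      inbreeding_f = 0.1)
  st1 <- sexual_reset_aphid(st, 0, d)
  expect_equal(st1$var_g, 0.27)
  expect_equal(st1$mean_g, bv_mean(d), tolerance = 1e-10)

  # deviation contracts by (1 - f) / 2 per year without new input
  st <- genetic_state(mean_g = 20, var_g0 = 0.3, var_e = 0.7, h2m = 0,
                      inbreeding_f = 0.1, dev = 0.08)
  devs <- numeric(4)
  for (i in 1:4) {
    st <- sexual_reset_aphid(st, 0, d)
    devs[i] <- st$dev
  }
  expect_equal(devs, 0.08 * 0.45^(1:4), tolerance = 1e-10)

  # alternative parenthesization behind the flag
  st <- genetic_state(mean_g = 20, var_g0 = 0.3, var_e = 0.7, h2m = 0,
                      inbreeding_f = 0.1, dev = 0.1)
  st_flat <- sexual_reset_aphid(st, 0, d, nested = FALSE)
  st_nest <- sexual_reset_aphid(st, 0, d, nested = TRUE)
  expect_equal(st_flat$var_g, 0.9 * 0.3 + 0.045)
  expect_equal(st_nest$var_g, 0.9 * (0.3 + 0.045))
})

test_that("population mean rates match brute-force double quadrature", {
  cfg <- quick_config()
  tpc_a <- evorescue:::tpc_from_config(cfg, "aphid")
  tpc_l <- evorescue:::tpc_from_config(cfg, "ladybird")
  eco <- evorescue:::eco_from_config(cfg)
  dist_a <- gauss_dist(20, 0.3)
  dist_l <- gauss_dist(20.4, 0.25)
  gen_a <- genetic_state(20, var_e = 0.7)
  gen_l <- genetic_state(20.4, var_e = 0.7)
  T <- 22; A <- 1e6; L <- 1e4

  r <- mean_rates(dist_a, dist_l, gen_a, gen_l, T, A, L, tpc_a, tpc_l,
                  eco)

  F_of <- function(phen) {
    s <- ref_shape(T - phen, tpc_a$delta_min, tpc_a$delta_max)
    tpc_a$peak_rate * s * (1 - A / eco$K) - (tpc_a$m0 + tpc_a$m1 * (1 - s))
  }
  Fbar_ref <- brute_mean_rate(dist_a, gen_a$var_e, F_of)
  expect_equal(r$Fbar, Fbar_ref, tolerance = 1e-6)

  w_of <- function(phen) {
    s <- ref_shape(T - phen, tpc_l$delta_min, tpc_l$delta_max)
    s * eco$a * A / ((1 + eco$a * eco$h * A) * eco$qp) -
      (tpc_l$m0 + tpc_l$m1 * (1 - s))
  }
  wbar_ref <- brute_mean_rate(dist_l, gen_l$var_e, w_of)
  expect_equal(r$wbar_l, wbar_ref, tolerance = 1e-6)

  gbar_ref <- brute_mean_rate(dist_l, gen_l$var_e, function(phen) {
    ref_shape(T - phen, tpc_l$delta_min, tpc_l$delta_max)
  })
  expect_equal(r$Bbar, gbar_ref * eco$a * L / (1 + eco$a * eco$h * A),
               tolerance = 1e-6)
  # single beta evaluation serves both prey loss and predator recruitment
  expect_equal(r$Bbar, r$beta_bar * L, tolerance = 1e-12)

  # degenerate limits: point masses and no environmental variance give
  # the pointwise rate exactly
  pa <- bv_dist(20, 1)
  gen0 <- genetic_state(20, var_g0 = 0, var_e = 0, var_g = 0)
  r0 <- mean_rates(pa, bv_dist(20.4, 1), gen0,
                   genetic_state(20.4, var_g0 = 0, var_e = 0, var_g = 0),
                   T, A, L, tpc_a, tpc_l, eco)
  s0 <- ref_shape(T - 20, tpc_a$delta_min, tpc_a$delta_max)
  expect_equal(r0$Fbar,
               tpc_a$peak_rate * s0 * (1 - A / eco$K) -
                 (tpc_a$m0 + tpc_a$m1 * (1 - s0)),
               tolerance = 1e-9)

  expect_error(
    mean_rates(bv_dist(0:4, c(1, 1, 1, 1, 10)) |>
                 (\(d) { d$density <- d$density * 2; d })(),
               dist_l, gen_a, gen_l, T, A, L, tpc_a, tpc_l, eco),
    "not normalized")
})

test_that("every distribution operation preserves normalization and non-negativity", {
  set.seed(42)
  for (rep in 1:5) {
    d <- gauss_dist(runif(1, 15, 25), runif(1, 0.1, 0.5))
    for (step in 1:20) {
      op <- sample(c("select", "mutate", "reweight"), 1)
      d <- switch(op,
        select = {
          F <- 0.2 * ref_shape(runif(1, 10, 30) - d$grid, 18, 6) - 0.1
          select_aphid(d, F, runif(1, 0, 0.1),
                       evorescue:::bv_integrate(d, F), dt = 1)
        },
        mutate = mutate_aphid(d, 10^runif(1, -5, -2)),
        reweight = bv_reweight(d, exp(-(d$grid - mean(d$grid))^2 / 8))
      )
      d <- evorescue:::bv_maintain(d)
      expect_equal(evorescue:::bv_mass(d), 1, tolerance = 1e-8)
      expect_gte(min(d$density), 0)
    }
  }
})

test_that("grid recentering and extension preserve moments", {
  d <- gauss_dist(20, 0.3)
  # skew it so the mean is off-centre
  d <- bv_reweight(d, 1 + 0.15 * (d$grid - 20))
  m <- bv_mean(d); v <- bv_var(d)

  rec <- evorescue:::bv_recenter(d, m + 5 * d$dx)
  expect_equal(bv_mean(rec), m, tolerance = 1e-8)
  expect_equal(bv_var(rec), v, tolerance = 1e-8)

  ext <- evorescue:::bv_extend(d, 40L)
  expect_equal(bv_mean(ext), m, tolerance = 1e-12)
  expect_equal(bv_var(ext), v, tolerance = 1e-12)
  expect_equal(length(ext$grid), length(d$grid) + 80L)

  kept <- evorescue:::bv_maintain(d)
  expect_equal(bv_mean(kept), m, tolerance = 1e-8)
  expect_equal(bv_var(kept), v, tolerance = 1e-8)
})
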