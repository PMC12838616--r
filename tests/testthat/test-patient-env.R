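# Virtual patient: action transform, ODE dynamics, CGM, meal scenarios,
# episode stepping and the POMDP observation window.

test_that("action transform matches the exponential form and its bounds", {
  expect_equal(action_to_insulin(1, 5, 4), 5)
  expect_equal(action_to_insulin(0, 5, 4), 5 * exp(-4))
  expect_equal(action_to_insulin(-1, 5, 4), 5 * exp(-8))
  a <- seq(-1, 1, length.out = 101)
  r <- action_to_insulin(a, 5, 4)
  expect_true(all(diff(r) > 0))
  expect_true(all(r <= 5 & r > 5 * exp(-8) - 1e-12))
  expect_error(action_to_insulin(1.2), "outside")
  expect_error(action_to_insulin(-1.01), "outside")
})

test_that("basal steady state holds under basal insulin with no meals", {
  p <- patient_params(cgm_noise_sd = 0)
  st <- c(p$basal_glucose, 0, 0)
  for (i in 1:100) st <- ode_step(st, p$basal_rate, p, dt = 1)
  expect_equal(st[1], p$basal_glucose, tolerance = 1e-6)
})

test_that("gut carbohydrates raise glucose and insulin lowers it", {
  p <- patient_params(cgm_noise_sd = 0)
  st <- c(p$basal_glucose, 0, 30)  # 30 g in the gut, zero insulin
  st2 <- ode_step(st, 0, p, dt = 1)
  expect_gt(st2[1], st[1])
  # doubled insulin from steady state: below basal within 30 min
  st <- c(p$basal_glucose, 0, 0)
  for (i in 1:30) st <- ode_step(st, 2 * p$basal_rate, p, dt = 1)
  expect_lt(st[1], p$basal_glucose)
})

test_that("fixed-step integration agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- patient_params(cgm_noise_sd = 0)
  rhs <- function(t, y, parms) {
    sx <- p$insulin_sensitivity / p$basal_glucose
    list(c(-p$glucose_effectiveness * (y[1] - p$basal_glucose) -
             y[2] * y[1] + p$meal_absorption_rate * y[3] * p$carb_potency,
           (sx * (parms$u - p$basal_rate) - y[2]) / p$insulin_action_delay,
           -p$meal_absorption_rate * y[3]))
  }
  y0 <- c(p$basal_glucose, 0, 60)
  u <- 0.05
  ref <- deSolve::ode(y0, seq(0, 60, by = 1), rhs, parms = list(u = u),
                      method = "ode45")
  st <- y0
  for (i in 1:60) st <- ode_step(st, u, p, dt = 1)
  expect_equal(unname(st[1]), unname(ref[61, 2]), tolerance = 1e-4)
  expect_equal(unname(st[2]), unname(ref[61, 3]), tolerance = 1e-6)
})

test_that("CGM reading is unbiased, clamped, and reproducible per stream", {
  expect_equal(cgm_read(120, 0), 120)
  r1 <- cgm_read(rep(120, 10), 5, local_rng(9))
  r2 <- cgm_read(rep(120, 10), 5, local_rng(9))
  expect_identical(r1, r2)
  draws <- cgm_read(rep(120, 1e5), 5, local_rng(11))
  expect_equal(stats::sd(draws), 5, tolerance = 0.03)
  expect_true(all(cgm_read(rep(2, 1000), 50, local_rng(1)) >= 1))
})

test_that("zero-jitter scenario realization is the identity on the base plan", {
  ev <- realize_scenario(meal_scenario())
  expect_equal(length(ev), 3)
  expect_equal(vapply(ev, `[[`, numeric(1), "time_of_day"),
               c(420, 720, 1140))
  expect_equal(vapply(ev, `[[`, numeric(1), "carbs"), c(40, 80, 60))
})

test_that("scenario realization is deterministic per seed and respects jitter bounds", {
  sc <- meal_scenario(portion_jitter_frac = 0.3, time_jitter_frac = 0.3,
                      snack_count_range = c(1, 3), seed = 7)
  expect_identical(realize_scenario(sc), realize_scenario(sc))
  base <- c(40, 80, 60)
  for (s in 1:400) {
    sc2 <- meal_scenario(portion_jitter_frac = 0.2, seed = s)
    ev <- realize_scenario(sc2)
    carbs <- vapply(ev, `[[`, numeric(1), "carbs")
    expect_true(all(abs(carbs / base - 1) <= 0.2 + 1e-12))
  }
  # snack count within the requested range; events sorted by time
  sc3 <- meal_scenario(snack_count_range = c(1, 3), seed = 12)
  ev3 <- realize_scenario(sc3)
  expect_true(length(ev3) >= 4 && length(ev3) <= 6)
  times <- vapply(ev3, `[[`, numeric(1), "time_of_day")
  expect_true(all(diff(times) >= 0))
})

test_that("episodes end by the step cap in range and by penalty under overdose", {
  env <- quiet_env()
  tr <- run_episode(env, basal_controller(), seed = 3)
  expect_equal(nrow(tr), 288)
  expect_true(all(tr$reward >= 0 & tr$reward <= 1))
  # full-bore insulin drives severe hypoglycemia: terminal -15
  env2 <- quiet_env()
  tr2 <- run_episode(env2, function(w, e) 1, seed = 3)
  expect_lt(nrow(tr2), 288)
  expect_equal(tr2$reward[nrow(tr2)], -15)
  expect_lt(tr2$true_mgdl[nrow(tr2)], 40)
})

test_that("stepping after termination is rejected and windows keep length k", {
  env <- quiet_env()
  env_reset(env, 1)
  while (!env$terminated) {
    res <- env_step(env, 1)
    expect_length(res$observation$glucose, 12)
    expect_length(res$observation$insulin, 12)
  }
  expect_error(env_step(env, 0), "terminated")
})

test_that("cumulative reward lies in [-15, 288] across random controllers", {
  set.seed(5)
  for (i in 1:4) {
    env <- patient_env()
    ctrl <- function(w, e) runif(1, -1, 1)
    tr <- run_episode(env, ctrl, seed = i)
    s <- sum(tr$reward)
    expect_gte(s, -15)
    expect_lte(s, 288)
  }
})

test_that("noise-free runs of the same controller are bit-identical", {
  tr1 <- run_episode(quiet_env(), basal_controller(), seed = 8)
  tr2 <- run_episode(quiet_env(), basal_controller(), seed = 8)
  expect_identical(tr1, tr2)
})

test_that("episode traces round-trip through CSV", {
  tr <- run_episode(quiet_env(), basal_controller(), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(names(back),
               c("time_min", "cgm_mgdl", "true_mgdl", "insulin_Umin",
                 "reward", "meal_g"))
  expect_equal(back$true_mgdl, tr$true_mgdl, tolerance = 1e-9)
})

test_that("meals enter the gut compartment at their scheduled minute", {
  env <- quiet_env()
  env_reset(env, 1)
  # step i covers clock [5(i-1), 5i): breakfast at minute 420 lands in
  # step 85
  for (i in 1:84) env_step(env, basal_controller()(NULL, env))
  expect_equal(env$state[3], 0, ignore_attr = TRUE)
  res <- env_step(env, basal_controller()(NULL, env))
  expect_equal(res$meal_g, 40)
  expect_gt(env$state[3], 0)
})
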