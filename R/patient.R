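#' Virtual patient parameters
#'
#' Parameters of the synthetic virtual patient: a Bergman-style minimal
#' model (glucose-effectiveness decay towards basal, remote insulin effect
#' with first-order delay, first-order gut carbohydrate absorption). The
#' defaults are chosen so that basal insulin holds glucose at
#' `basal_glucose` and a 50 g meal peaks roughly 60-100 mg/dL above basal
#' within 60-90 minutes.
#'
#' @param insulin_sensitivity Steady-state glucose drop per unit of insulin
#'   ((mg/dL)/U), at basal glucose.
#' @param glucose_effectiveness Insulin-independent glucose decay rate
#'   towards basal (1/min).
#' @param basal_glucose Fasting glucose under basal insulin (mg/dL).
#' @param meal_absorption_rate First-order gut absorption rate (1/min).
#' @param insulin_action_delay Time constant of the remote insulin
#'   compartment (min).
#' @param body_weight Body weight (kg).
#' @param tdi Total daily insulin (U/day); the basal rate is 0.48*tdi/1440
#'   U/min.
#' @param cgm_noise_sd CGM sensor noise standard deviation (mg/dL).
#' @param pump_max_rate Maximum pump infusion rate Imax (U/min).
#' @param cohort `"adult"` or `"child"`. The child preset only increases
#'   insulin sensitivity and lowers weight/TDI; it does not claim fidelity
#'   to paediatric physiology.
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(insulin_sensitivity = 36,
                           glucose_effectiveness = 0.01,
                           basal_glucose = 140,
                           meal_absorption_rate = 0.02,
                           insulin_action_delay = 50,
                           body_weight = 70,
                           tdi = 50,
                           cgm_noise_sd = 5,
                           pump_max_rate = 5,
                           cohort = c("adult", "child")) {
  cohort <- match.arg(cohort)
  if (cohort == "child" && missing(insulin_sensitivity)) {
    insulin_sensitivity <- 54
    if (missing(body_weight)) body_weight <- 35
    if (missing(tdi)) tdi <- 30
  }
  stopifnot(insulin_sensitivity > 0, glucose_effectiveness > 0,
            basal_glucose >= 70, basal_glucose <= 180,
            meal_absorption_rate > 0, insulin_action_delay > 0,
            body_weight > 0, tdi > 0, cgm_noise_sd >= 0, pump_max_rate > 0)
  structure(list(
    insulin_sensitivity = insulin_sensitivity,
    glucose_effectiveness = glucose_effectiveness,
    basal_glucose = basal_glucose,
    meal_absorption_rate = meal_absorption_rate,
    insulin_action_delay = insulin_action_delay,
    body_weight = body_weight,
    tdi = tdi,
    cgm_noise_sd = cgm_noise_sd,
    pump_max_rate = pump_max_rate,
    cohort = cohort,
    # derived: basal infusion (U/min), carb potency (mg/dL per g)
    basal_rate = 0.48 * tdi / 1440,
    carb_potency = insulin_sensitivity * tdi / 500
  ), class = "patient_params")
}

#' Meal event
#' @param time_of_day Minutes since midnight, in \[0, 1440).
#' @param carbs Carbohydrates (g), non-negative.
#' @return An object of class `meal_event`.
#' @export
meal_event <- function(time_of_day, carbs) {
  stopifnot(time_of_day >= 0, time_of_day < 1440, carbs >= 0)
  structure(list(time_of_day = time_of_day, carbs = carbs),
            class = "meal_event")
}

#' Meal scenario
#'
#' A deterministic base meal plan (default three meals: 07:00/40 g,
#' 12:00/80 g, 19:00/60 g) plus a disturbance specification. Time jitter is
#' expressed as a fraction of a 100-minute reference window, so 0.3 means
#' a uniform shift within +/-30 minutes.
#'
#' @param base_meals List of [meal_event()]s.
#' @param portion_jitter_frac Per-meal portion multiplier drawn uniformly in
#'   `[1 - j, 1 + j]`; in \[0, 0.5\].
#' @param time_jitter_frac Per-meal time shift drawn uniformly within
#'   `+/- 100 * time_jitter_frac` minutes; in \[0, 0.5\].
#' @param snack_count_range Integer pair: number of random snacks, within
#'   \[0, 3\].
#' @param snack_carbs_range Gram pair for snack sizes.
#' @param seed Integer seed making the realization deterministic.
#' @return An object of class `meal_scenario`.
#' @export
meal_scenario <- function(base_meals = list(meal_event(420, 40),
                                            meal_event(720, 80),
                                            meal_event(1140, 60)),
                          portion_jitter_frac = 0,
                          time_jitter_frac = 0,
                          snack_count_range = c(0, 0),
                          snack_carbs_range = c(10, 30),
                          seed = 1L) {
  stopifnot(portion_jitter_frac >= 0, portion_jitter_frac <= 0.5,
            time_jitter_frac >= 0, time_jitter_frac <= 0.5,
            length(snack_count_range) == 2,
            all(snack_count_range >= 0), all(snack_count_range <= 3),
            snack_count_range[1] <= snack_count_range[2])
  structure(list(base_meals = base_meals,
                 portion_jitter_frac = portion_jitter_frac,
                 time_jitter_frac = time_jitter_frac,
                 snack_count_range = as.integer(snack_count_range),
                 snack_carbs_range = snack_carbs_range,
                 seed = as.integer(seed)),
            class = "meal_scenario")
}

#' The four dietary benchmark scenarios
#'
#' `fixed` (no disturbance), `portion` (portion sizes jittered +/-30%),
#' `time` (meal times shifted within +/-30 min) and `snacks` (1-3 extra
#' random snacks per day).
#'
#' @param seed Base seed for the disturbed scenarios.
#' @return A named list of [meal_scenario()]s.
#' @export
dietary_scenarios <- function(seed = 1L) {
  list(
    fixed   = meal_scenario(seed = seed),
    portion = meal_scenario(portion_jitter_frac = 0.3, seed = seed),
    time    = meal_scenario(time_jitter_frac = 0.3, seed = seed),
    snacks  = meal_scenario(snack_count_range = c(1, 3), seed = seed)
  )
}

#' Realize a meal scenario into a concrete list of meal events
#'
#' Applies portion and time jitter to the base meals and adds random
#' snacks at uniform times of day. Events landing on the same minute are
#' merged by summing carbs. Deterministic given the scenario seed.
#'
#' @param spec A [meal_scenario()].
#' @return A list of [meal_event()]s sorted by time of day.
#' @export
realize_scenario <- function(spec) {
  stopifnot(inherits(spec, "meal_scenario"))
  rng <- local_rng(spec$seed)
  times <- vapply(spec$base_meals, `[[`, numeric(1), "time_of_day")
  carbs <- vapply(spec$base_meals, `[[`, numeric(1), "carbs")
  n <- length(times)
  if (n > 0 && spec$portion_jitter_frac > 0) {
    carbs <- carbs * rng$runif(n, 1 - spec$portion_jitter_frac,
                               1 + spec$portion_jitter_frac)
  }
  if (n > 0 && spec$time_jitter_frac > 0) {
    shift <- rng$runif(n, -100 * spec$time_jitter_frac,
                       100 * spec$time_jitter_frac)
    times <- pmin(1439, pmax(0, times + shift))
  }
  n_snacks <- if (spec$snack_count_range[2] > 0) {
    rng$sample_int(spec$snack_count_range[1], spec$snack_count_range[2])
  } else 0L
  if (n_snacks > 0) {
    times <- c(times, rng$runif(n_snacks, 360, 1380))
    carbs <- c(carbs, rng$runif(n_snacks, spec$snack_carbs_range[1],
                                spec$snack_carbs_range[2]))
  }
  # merge events falling on the same minute
  minute <- floor(times)
  agg <- tapply(carbs, minute, sum)
  times <- as.numeric(names(agg))
  carbs <- as.numeric(agg)
  ord <- order(times)
  mapply(meal_event, times[ord], carbs[ord], SIMPLIFY = FALSE)
}

#' Agent action to insulin infusion rate
#'
#' Exponential transform `Imax * exp(tau * (a - 1))` mapping the agent's
#' action in \[-1, 1\] onto a strictly positive infusion rate bounded by
#' the pump maximum.
#'
#' @param a Action in \[-1, 1\] (vectorised).
#' @param imax Maximum infusion rate (U/min), default 5.
#' @param tau Shape parameter, default 4.
#' @return Insulin rate(s) in U/min, in `(imax * exp(-2 tau), imax]`.
#' @export
#' @examples
#' action_to_insulin(1)    # 5
#' action_to_insulin(0)    # ~0.0916
action_to_insulin <- function(a, imax = 5, tau = 4) {
  if (any(!is.finite(a)) || any(a < -1) || any(a > 1)) {
    stop("action outside [-1, 1]: policy head bug?")
  }
  stopifnot(imax > 0, tau > 0)
  imax * exp(tau * (a - 1))
}

#' One CGM sensor reading
#'
#' True glucose plus i.i.d. zero-mean Gaussian sensor noise, clamped to be
#' at least 1 mg/dL.
#'
#' @param true_glucose True plasma glucose (mg/dL), positive.
#' @param noise_sd Sensor noise SD (mg/dL).
#' @param rng An RNG stream from [local_rng()]; `NULL` uses the global RNG.
#' @return A reading in mg/dL.
#' @export
cgm_read <- function(true_glucose, noise_sd, rng = NULL) {
  stopifnot(all(true_glucose > 0))
  eps <- if (noise_sd > 0) {
    if (is.null(rng)) stats::rnorm(length(true_glucose), 0, noise_sd)
    else rng$rnorm(length(true_glucose), 0, noise_sd)
  } else 0
  pmax(1, true_glucose + eps)
}

# Minimal-model right-hand side. State: G plasma glucose (mg/dL), X remote
# insulin effect (1/min), D gut carbohydrate mass (g). `u` insulin U/min.
patient_deriv <- function(state, u, p) {
  G <- state[1]; X <- state[2]; D <- state[3]
  sx <- p$insulin_sensitivity / p$basal_glucose
  dG <- -p$glucose_effectiveness * (G - p$basal_glucose) - X * G +
    p$meal_absorption_rate * D * p$carb_potency
  dX <- (sx * (u - p$basal_rate) - X) / p$insulin_action_delay
  dD <- -p$meal_absorption_rate * D
  c(dG, dX, dD)
}

#' Advance the patient ODE by one fixed step
#'
#' Classical RK4 with a fixed step; deterministic given inputs. Glucose is
#' floored at 1 mg/dL after the step.
#'
#' @param state Numeric vector `c(G, X, D)`.
#' @param insulin Infusion rate over the step (U/min), held constant.
#' @param params A [patient_params()].
#' @param dt Step size (min), default 1.
#' @return The advanced state vector.
#' @export
ode_step <- function(state, insulin, params, dt = 1) {
  stopifnot(dt > 0, insulin >= 0)
  if (any(!is.finite(state))) stop("non-finite patient state")
  k1 <- patient_deriv(state, insulin, params)
  k2 <- patient_deriv(state + dt / 2 * k1, insulin, params)
  k3 <- patient_deriv(state + dt / 2 * k2, insulin, params)
  k4 <- patient_deriv(state + dt * k3, insulin, params)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  out[1] <- max(1, out[1])
  if (any(!is.finite(out))) stop("non-finite patient state after step")
  out
}

# vectorised RK4 over a matrix of states (rows = parallel branches) with
# per-row insulin rates; same dynamics as ode_step
rk4_vec <- function(st, rates, p, dt = 1) {
  dv <- function(s) {
    sx <- p$insulin_sensitivity / p$basal_glucose
    cbind(-p$glucose_effectiveness * (s[, 1] - p$basal_glucose) -
            s[, 2] * s[, 1] +
            p$meal_absorption_rate * s[, 3] * p$carb_potency,
          (sx * (rates - p$basal_rate) - s[, 2]) / p$insulin_action_delay,
          -p$meal_absorption_rate * s[, 3])
  }
  k1 <- dv(st); k2 <- dv(st + dt / 2 * k1); k3 <- dv(st + dt / 2 * k2)
  k4 <- dv(st + dt * k3)
  out <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  out[, 1] <- pmax(1, out[, 1])
  out
}

#' Create a closed-loop patient environment
#'
#' Bundles the virtual patient, CGM sensor, insulin pump, a realized meal
#' scenario and the POMDP observation window into a mutable environment
#' stepped every 5 minutes for at most 288 steps (one day).
#'
#' @param params A [patient_params()].
#' @param scenario A [meal_scenario()].
#' @param reward A [reward_spec()].
#' @param risk A [risk_params()].
#' @param k Observation window length (number of 5-min history steps).
#' @param step_min Control step (min).
#' @param max_steps Episode cap (steps).
#' @param action_tau Shape of the action-to-insulin transform.
#' @param reward_on `"cgm"` (default) or `"true"`: glucose signal fed to
#'   the reward.
#' @return An object of class `patient_env` (a mutable environment).
#' @export
patient_env <- function(params = patient_params(),
                        scenario = meal_scenario(),
                        reward = reward_spec(),
                        risk = risk_params(),
                        k = 12, step_min = 5, max_steps = 288,
                        action_tau = 4, reward_on = c("cgm", "true")) {
  reward_on <- match.arg(reward_on)
  e <- new.env(parent = emptyenv())
  e$params <- params; e$scenario <- scenario
  e$reward_spec <- reward; e$risk <- risk
  e$k <- k; e$step_min <- step_min; e$max_steps <- max_steps
  e$action_tau <- action_tau; e$reward_on <- reward_on
  class(e) <- "patient_env"
  env_reset(e, seed = scenario$seed)
  e
}

#' Reset a patient environment
#'
#' Re-realizes the meal scenario, restores the basal steady state and
#' warm-fills the observation window with the initial CGM reading and the
#' basal insulin rate.
#'
#' @param env A [patient_env()].
#' @param seed Episode seed (drives sensor noise and the meal realization).
#' @return The initial observation window (invisibly the env is mutated).
#' @export
env_reset <- function(env, seed = 1L) {
  p <- env$params
  env$rng <- local_rng(derive_seed(seed, "env"))
  sc <- env$scenario
  sc$seed <- derive_seed(seed, "meals")
  env$meals <- realize_scenario(sc)
  env$meal_idx_done <- logical(length(env$meals))
  env$state <- c(G = p$basal_glucose, X = 0, D = 0)
  env$clock <- 0
  env$step_index <- 0L
  env$terminated <- FALSE
  g0 <- cgm_read(p$basal_glucose, p$cgm_noise_sd, env$rng)
  env$window <- list(glucose = rep(g0, env$k),
                     insulin = rep(p$basal_rate, env$k))
  invisible(env$window)
}

#' Current observation window
#' @param env A [patient_env()].
#' @return A list with `glucose` and `insulin` histories (length `k` each).
#' @export
env_observation <- function(env) env$window

# deliver meals scheduled in [t0, t0 + dt) into the gut compartment
deliver_meals <- function(env, t0, dt) {
  carbs <- 0
  for (i in seq_along(env$meals)) {
    m <- env$meals[[i]]
    if (!env$meal_idx_done[i] && m$time_of_day >= t0 &&
        m$time_of_day < t0 + dt) {
      carbs <- carbs + m$carbs
      env$meal_idx_done[i] <- TRUE
    }
  }
  if (carbs > 0) env$state[3] <- env$state[3] + carbs
  carbs
}

#' Step the environment with an explicit insulin rate
#'
#' Lower-level entry used by rule-based controllers (BBI, safety
#' controller) that already work in U/min. Integrates `step_min` minutes of
#' dynamics at 1-min RK4 substeps, reads the CGM, slides the observation
#' window and computes the reward. Termination: true glucose below
#' 40 mg/dL (reward -15) or the episode step cap.
#'
#' @param env A [patient_env()].
#' @param insulin Infusion rate (U/min), clamped to the pump maximum.
#' @return A `step_result` list: `observation`, `reward`, `terminated`,
#'   `true_glucose`, `cgm_glucose`, `insulin_delivered`, `meal_g`.
#' @export
env_step_insulin <- function(env, insulin) {
  if (env$terminated) stop("env_step on a terminated episode")
  p <- env$params
  insulin <- min(max(0, insulin), p$pump_max_rate)
  meal_g <- 0
  for (i in seq_len(env$step_min)) {
    meal_g <- meal_g + deliver_meals(env, env$clock, 1)
    env$state <- ode_step(env$state, insulin, p, dt = 1)
    env$clock <- env$clock + 1
    if (env$clock >= 1440) env$clock <- env$clock - 1440
  }
  env$step_index <- env$step_index + 1L
  true_g <- unname(env$state[1])
  cgm_g <- cgm_read(true_g, p$cgm_noise_sd, env$rng)
  env$window <- list(glucose = c(env$window$glucose[-1], cgm_g),
                     insulin = c(env$window$insulin[-1], insulin))
  if (true_g < 40) {
    reward <- env$reward_spec$severe_penalty
    env$terminated <- TRUE
  } else {
    g_r <- if (env$reward_on == "cgm") cgm_g else true_g
    # the -15 penalty is tied to the (true-glucose) termination event;
    # a noisy sub-40 reading on a surviving step floors at reward 0
    reward <- max(0, glucose_reward(g_r, env$reward_spec, env$risk))
    if (env$step_index >= env$max_steps) env$terminated <- TRUE
  }
  list(observation = env$window, reward = reward,
       terminated = env$terminated, true_glucose = true_g,
       cgm_glucose = cgm_g, insulin_delivered = insulin, meal_g = meal_g)
}

#' Step the environment with an agent action
#'
#' Converts the action in \[-1, 1\] to an infusion rate with
#' [action_to_insulin()] and delegates to [env_step_insulin()].
#'
#' @param env A [patient_env()].
#' @param action Agent action in \[-1, 1\].
#' @return A `step_result` list, see [env_step_insulin()].
#' @export
env_step <- function(env, action) {
  rate <- action_to_insulin(action, env$params$pump_max_rate,
                            env$action_tau)
  env_step_insulin(env, rate)
}

#' Snapshot / restore the internal environment state
#'
#' Used by the truthful-predictor mock and by MPC tests to branch
#' simulations without touching the live episode.
#' @param env A [patient_env()].
#' @return An opaque snapshot list.
#' @export
env_snapshot <- function(env) {
  list(state = env$state, clock = env$clock, step_index = env$step_index,
       terminated = env$terminated, window = env$window,
       meal_idx_done = env$meal_idx_done)
}

#' @rdname env_snapshot
#' @param snap A snapshot from [env_snapshot()].
#' @export
env_restore <- function(env, snap) {
  env$state <- snap$state; env$clock <- snap$clock
  env$step_index <- snap$step_index; env$terminated <- snap$terminated
  env$window <- snap$window; env$meal_idx_done <- snap$meal_idx_done
  invisible(env)
}

#' Run one episode under a controller and record the trace
#'
#' @param env A [patient_env()].
#' @param controller A function `(window, env) -> action in [-1,1]`, or an
#'   object with a `control` method (see [bbi_controller()] and agents).
#' @param seed Episode seed.
#' @return A data frame trace with columns `time_min`, `cgm_mgdl`,
#'   `true_mgdl`, `insulin_Umin`, `reward`, `meal_g`.
#' @export
run_episode <- function(env, controller, seed = 1L) {
  env_reset(env, seed)
  n <- env$max_steps
  time_min <- cgm <- true_g <- ins <- rew <- meal <- numeric(0)
  while (!env$terminated) {
    res <- controller_step(controller, env)
    time_min <- c(time_min, env$clock)
    cgm <- c(cgm, res$cgm_glucose); true_g <- c(true_g, res$true_glucose)
    ins <- c(ins, res$insulin_delivered); rew <- c(rew, res$reward)
    meal <- c(meal, res$meal_g)
  }
  data.frame(time_min = time_min, cgm_mgdl = cgm, true_mgdl = true_g,
             insulin_Umin = ins, reward = rew, meal_g = meal)
}

# dispatch one control step for plain functions and controller objects
controller_step <- function(controller, env) UseMethod("controller_step")

#' @export
controller_step.function <- function(controller, env) {
  env_step(env, controller(env$window, env))
}

#' Write an episode trace to CSV
#' @param trace A trace data frame from [run_episode()].
#' @param path Output file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
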