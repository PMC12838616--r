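#' Basal-bolus insulin therapy parameters
#'
#' Clinical rule-of-thumb parameters derived from the total daily insulin
#' dose: basal rate `BR = 0.48 * TDI` (U/day), carbohydrate-to-insulin
#' ratio `CIR = 500 / TDI` (g/U) and insulin sensitivity factor
#' `ISF = 1800 / TDI` ((mg/dL)/U).
#'
#' @param tdi Total daily insulin (U/day), positive.
#' @param g_target Correction target glucose (mg/dL), default 140.
#' @param cool Binary correction-enable gate (default 1).
#' @param announce_lead Minutes before a meal at which its carbohydrates
#'   are announced and the bolus delivered (default 20).
#' @return An object of class `bbi_params`.
#' @export
#' @examples
#' p <- derive_bbi_params(50)
#' c(p$br, p$cir, p$isf)   # 24, 10, 36
derive_bbi_params <- function(tdi, g_target = 140, cool = 1,
                              announce_lead = 20) {
  if (!is.finite(tdi) || tdi <= 0) stop("tdi must be positive")
  stopifnot(cool %in% c(0, 1), announce_lead >= 0)
  structure(list(tdi = tdi, br = 0.48 * tdi, cir = 500 / tdi,
                 isf = 1800 / tdi, g_target = g_target, cool = cool,
                 announce_lead = announce_lead),
            class = "bbi_params")
}

#' Basal-bolus insulin dose for one control step
#'
#' Continuous basal (`br / 1440` U/min) plus, when carbohydrates are
#' announced, a meal bolus `c_t / CIR` and an optional correction
#' `cool * (g_t - g_target) / ISF`. The total bolus is floored at zero so
#' a negative correction can never cancel insulin below nothing.
#'
#' @param g_t Current glucose (mg/dL).
#' @param c_t Announced carbohydrates for this step (g, 0 when none).
#' @param p A [derive_bbi_params()] object.
#' @return A list with `basal_rate` (U/min) and `bolus` (U).
#' @export
#' @examples
#' bbi_dose(190, 40, derive_bbi_params(50))$bolus   # ~5.389
bbi_dose <- function(g_t, c_t, p) {
  stopifnot(g_t > 0, c_t >= 0)
  bolus <- 0
  if (c_t > 0) {
    bolus <- c_t / p$cir + p$cool * (g_t - p$g_target) / p$isf
    bolus <- max(0, bolus)
  }
  list(basal_rate = p$br / 1440, bolus = bolus)
}

#' Basal-bolus controller for the closed-loop environment
#'
#' Uses the environment's scheduled meal events as announcements: the meal
#' bolus (plus correction) is delivered during the control step starting
#' `announce_lead` minutes before each meal, spread over the step. The
#' controller consumes the observation window's last CGM reading as
#' `g_t` and needs no checkpoint or training.
#'
#' @param params A [derive_bbi_params()]; defaults to the patient's TDI at
#'   step time when `NULL`.
#' @return A controller object usable with [run_episode()].
#' @export
bbi_controller <- function(params = NULL) {
  structure(list(params = params), class = "bbi_controller")
}

#' @export
controller_step.bbi_controller <- function(controller, env) {
  p <- controller$params
  if (is.null(p)) p <- derive_bbi_params(env$params$tdi)
  g_t <- tail_1(env$window$glucose)
  # carbs announced for meals landing in [clock + lead, clock + lead + step)
  t0 <- env$clock + p$announce_lead
  c_t <- 0
  for (m in env$meals) {
    if (m$time_of_day >= t0 && m$time_of_day < t0 + env$step_min) {
      c_t <- c_t + m$carbs
    }
  }
  dose <- bbi_dose(g_t, c_t, p)
  rate <- dose$basal_rate + dose$bolus / env$step_min
  env_step_insulin(env, rate)
}

tail_1 <- function(x) x[length(x)]
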