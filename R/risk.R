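#' Blood-glucose risk index parameters
#'
#' Coefficients of the symmetrised Kovatchev log-transform risk function and
#' the reference glucose range used to normalise it into a reward.
#'
#' @param c1,c2,c3 Risk-transform coefficients. With the defaults the risk is
#'   `scale * (c1 * ((ln g)^c2 - c3))^2`, zero at approximately 112.5 mg/dL.
#' @param scale Overall risk scale (default 10).
#' @param norm_lo,norm_hi Reference glucose range (mg/dL) whose endpoints set
#'   the maximum risk used for reward normalisation; with the defaults both
#'   endpoints carry a risk of about 100.
#' @return An object of class `risk_params`.
#' @export
#' @examples
#' p <- risk_params()
#' risk_index(112.517, p)   # ~ 0
risk_params <- function(c1 = 1.509, c2 = 1.084, c3 = 5.381, scale = 10,
                        norm_lo = 20, norm_hi = 600) {
  stopifnot(c1 > 0, c2 > 0, c3 > 0, scale > 0, norm_lo > 0,
            norm_lo < norm_hi)
  structure(list(c1 = c1, c2 = c2, c3 = c3, scale = scale,
                 norm_lo = norm_lo, norm_hi = norm_hi),
            class = "risk_params")
}

#' Blood-glucose risk index
#'
#' `scale * (c1 * ((ln g)^c2 - c3))^2`: zero at one glucose value
#' (~112.5 mg/dL with defaults), rising towards both hypo- and
#' hyperglycaemia, steeper on the hypoglycaemic side.
#'
#' @param g Glucose (mg/dL), vectorised; must be positive.
#' @param p A [risk_params()] object.
#' @return Non-negative risk values.
#' @export
risk_index <- function(g, p = risk_params()) {
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("glucose values must be finite and positive")
  }
  f <- p$c1 * (log(g)^p$c2 - p$c3)
  p$scale * f^2
}

#' Glucose value at which the risk index is zero
#'
#' Closed form `exp(c3^(1/c2))`: the root of `(ln g)^c2 = c3`.
#'
#' @inheritParams risk_index
#' @return Glucose in mg/dL (~112.517 with defaults).
#' @export
zero_risk_glucose <- function(p = risk_params()) {
  exp(p$c3^(1 / p$c2))
}

#' Normalised per-step reward from the risk index
#'
#' `1 - risk(g) / risk_max`, clamped to \[0, 1\], where `risk_max` is the
#' larger of the risks at the two reference-range endpoints. Equals 1 at the
#' zero-risk glucose.
#'
#' @inheritParams risk_index
#' @return Values in \[0, 1\].
#' @export
normalized_reward <- function(g, p = risk_params()) {
  risk_max <- max(risk_index(p$norm_lo, p), risk_index(p$norm_hi, p))
  pmin(1, pmax(0, 1 - risk_index(g, p) / risk_max))
}

#' Reward specification
#'
#' The three reward shapes compared by the package: `original` (flat
#' normalised reward with a hard -15 penalty below 40 mg/dL), `linear_v1`
#' (the same, with the reward on (40, 70] additionally scaled by a 0.5
#' linear decay ramp), and `spline_v2` (a C1 cubic Hermite ramp from 0 at
#' 40 mg/dL up to the normalised reward at 70 mg/dL, with zero end slopes).
#'
#' @param variant One of `"original"`, `"linear_v1"`, `"spline_v2"`.
#' @param severe_penalty Penalty for severe hypoglycaemia (default -15).
#' @param severe_threshold Severe-hypoglycaemia glucose (default 40 mg/dL).
#' @param hypo_knot Upper knot of the hypoglycaemia ramp (default 70 mg/dL).
#' @param linear_factor Decay factor of the `linear_v1` ramp (default 0.5).
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(variant = c("spline_v2", "original", "linear_v1"),
                        severe_penalty = -15, severe_threshold = 40,
                        hypo_knot = 70, linear_factor = 0.5) {
  variant <- match.arg(variant)
  stopifnot(severe_penalty < 0, severe_threshold < hypo_knot)
  structure(list(variant = variant, severe_penalty = severe_penalty,
                 severe_threshold = severe_threshold, hypo_knot = hypo_knot,
                 linear_factor = linear_factor),
            class = "reward_spec")
}

#' Per-step reward for a next-step glucose value
#'
#' @param g_next Next-step glucose (mg/dL), vectorised.
#' @param spec A [reward_spec()].
#' @param p A [risk_params()].
#' @return Rewards in `{severe_penalty}` union \[0, 1\].
#' @export
#' @examples
#' glucose_reward(39)                      # -15
#' glucose_reward(40)                      # 0 (spline ramp start)
#' glucose_reward(112.517)                 # ~1
glucose_reward <- function(g_next, spec = reward_spec(), p = risk_params()) {
  if (any(!is.finite(g_next)) || any(g_next <= 0)) {
    stop("glucose values must be finite and positive")
  }
  base <- normalized_reward(g_next, p)
  thr <- spec$severe_threshold
  knot <- spec$hypo_knot
  out <- base
  if (spec$variant == "original") {
    out[g_next <= thr] <- spec$severe_penalty
  } else if (spec$variant == "linear_v1") {
    ramp <- g_next > thr & g_next <= knot
    # linear decay: factor 0.5 scaled by position inside (40, 70]
    frac <- (g_next[ramp] - thr) / (knot - thr)
    out[ramp] <- base[ramp] * spec$linear_factor * frac
    out[g_next <= thr] <- spec$severe_penalty
  } else { # spline_v2
    ramp <- g_next >= thr & g_next <= knot
    r_knot <- normalized_reward(knot, p)
    t <- (g_next[ramp] - thr) / (knot - thr)
    # cubic Hermite with zero end slopes: smoothstep from (40, 0) to (70, r70)
    out[ramp] <- r_knot * (3 * t^2 - 2 * t^3)
    out[g_next < thr] <- spec$severe_penalty
  }
  out
}

#' Export a reward curve as a data frame
#'
#' Evaluates the reward on a glucose grid, e.g. for plotting or CSV export.
#'
#' @param spec A [reward_spec()].
#' @param p A [risk_params()].
#' @param from,to,by Glucose grid (mg/dL).
#' @return A data frame with columns `g` and `reward`.
#' @export
reward_curve <- function(spec = reward_spec(), p = risk_params(),
                         from = 20, to = 400, by = 0.5) {
  g <- seq(from, to, by = by)
  data.frame(g = g, reward = glucose_reward(g, spec, p))
}
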