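#' Time in glycemic ranges
#'
#' Fractions of a glucose trace spent in the five standard clinical bins:
#' TBR2 (< 54), TBR1 (54 to < 70), TIR (70 to 180), TAR1 (> 180 to 250)
#' and TAR2 (> 250 mg/dL). Ties at 54 go to TBR1 and ties at 70/180/250 to
#' the less severe bin, so the bins partition the trace and the
#' percentages sum to 100.
#'
#' @param trace Numeric vector of glucose values (mg/dL), nonempty.
#' @return Named numeric vector of percentages
#'   (`tbr2`, `tbr1`, `tir`, `tar1`, `tar2`).
#' @export
#' @examples
#' time_in_ranges(c(50, 60, 100, 200, 300))   # 20 each
time_in_ranges <- function(trace) {
  if (length(trace) == 0) stop("empty glucose trace")
  stopifnot(all(trace > 0))
  n <- length(trace)
  c(tbr2 = sum(trace < 54),
    tbr1 = sum(trace >= 54 & trace < 70),
    tir  = sum(trace >= 70 & trace <= 180),
    tar1 = sum(trace > 180 & trace <= 250),
    tar2 = sum(trace > 250)) / n * 100
}

#' Low and high blood-glucose risk indices
#'
#' Splits the risk index into its hypoglycaemic and hyperglycaemic
#' components: with `f(g) = c1 ((ln g)^c2 - c3)`, LBGI is the trace mean of
#' `scale * f^2` over samples with `f < 0` (0 elsewhere) and HBGI the same
#' over `f > 0`. Their sum equals the mean risk index.
#'
#' @param trace Numeric vector of glucose values (mg/dL), nonempty.
#' @param p A [risk_params()].
#' @return Named vector `c(lbgi, hbgi)`.
#' @export
lbgi_hbgi <- function(trace, p = risk_params()) {
  if (length(trace) == 0) stop("empty glucose trace")
  f <- p$c1 * (log(trace)^p$c2 - p$c3)
  r <- p$scale * f^2
  c(lbgi = mean(r * (f < 0)), hbgi = mean(r * (f > 0)))
}

#' Cumulative episode reward
#'
#' Sum of per-step rewards; flags sums outside the attainable range
#' (one possible terminal penalty of -15, otherwise per-step rewards in
#' \[0, 1\] for at most 288 steps).
#'
#' @param rewards Per-step rewards of one episode.
#' @param max_steps Episode step cap (default 288).
#' @param severe_penalty Terminal penalty (default -15).
#' @return The cumulative reward (scalar).
#' @export
cumulative_reward <- function(rewards, max_steps = 288,
                              severe_penalty = -15) {
  s <- sum(rewards)
  if (s < severe_penalty - 1e-9 || s > max_steps + 1e-9) {
    warning("cumulative reward outside attainable range: invariant breach")
  }
  s
}

#' Paired t test between two matched series
#'
#' Standard two-sided paired t test on the per-pair differences.
#'
#' @param series_a,series_b Equal-length numeric vectors (n >= 2).
#' @return A list with `t` and `p`.
#' @export
paired_t <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b), length(series_a) >= 2)
  d <- series_a - series_b
  if (stats::sd(d) == 0) stop("zero-variance differences: t undefined")
  ht <- stats::t.test(series_a, series_b, paired = TRUE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Glycemic report for a set of episodes
#'
#' @param traces List of episode trace data frames from [run_episode()].
#' @param on `"cgm"` (what a clinic sees, default) or `"true"` glucose.
#' @param p A [risk_params()].
#' @return An object of class `glycemic_report`: the five bin percentages,
#'   LBGI/HBGI, mean and sd of cumulative reward, and `n_episodes`.
#' @export
glycemic_report <- function(traces, on = c("cgm", "true"),
                            p = risk_params()) {
  on <- match.arg(on)
  col <- if (on == "cgm") "cgm_mgdl" else "true_mgdl"
  g <- unlist(lapply(traces, `[[`, col))
  rew <- vapply(traces, function(tr) cumulative_reward(tr$reward),
                numeric(1))
  out <- c(as.list(time_in_ranges(g)), as.list(lbgi_hbgi(g, p)),
           list(mean_reward = mean(rew),
                sd_reward = if (length(rew) > 1) stats::sd(rew) else 0,
                n_episodes = length(traces)))
  structure(out, class = "glycemic_report")
}

#' @export
print.glycemic_report <- function(x, ...) {
  cat(sprintf(
    "Glycemic report over %d episode(s)\n", x$n_episodes))
  cat(sprintf("  TBR2 %6.2f%%  TBR1 %6.2f%%  TIR %6.2f%%  TAR1 %6.2f%%  TAR2 %6.2f%%\n",
              x$tbr2, x$tbr1, x$tir, x$tar1, x$tar2))
  cat(sprintf("  LBGI %6.3f  HBGI %6.3f  reward %7.2f +/- %.2f\n",
              x$lbgi, x$hbgi, x$mean_reward, x$sd_reward))
  invisible(x)
}

#' Run the four-scenario dietary benchmark
#'
#' Evaluates a controller over the fixed, fluctuating-portion,
#' fluctuating-time and random-snack scenarios, `n_episodes` one-day
#' episodes each, and aggregates one glycemic report per scenario.
#'
#' @param controller A controller (function or object).
#' @param params A [patient_params()].
#' @param n_episodes Episodes per scenario (default 100).
#' @param seed Base seed; episode e of scenario s gets an independent
#'   derived seed.
#' @param scenarios Named list of [meal_scenario()]s; defaults to
#'   [dietary_scenarios()].
#' @param ... Passed to [patient_env()].
#' @return A named list of `glycemic_report`s, one per scenario.
#' @export
scenario_suite <- function(controller, params = patient_params(),
                           n_episodes = 100, seed = 1L,
                           scenarios = dietary_scenarios(seed), ...) {
  out <- list()
  for (nm in names(scenarios)) {
    env <- patient_env(params = params, scenario = scenarios[[nm]], ...)
    traces <- lapply(seq_len(n_episodes), function(e) {
      run_episode(env, controller,
                  seed = derive_seed(seed, paste0(nm, "_", e)))
    })
    out[[nm]] <- glycemic_report(traces)
  }
  out
}

#' Format scenario reports as a comparison table
#'
#' @param reports A named list of `glycemic_report`s (or a named list of
#'   such lists, one per method).
#' @return A data frame, one row per (method, scenario).
#' @export
report_table <- function(reports) {
  if (inherits(reports[[1]], "glycemic_report")) reports <- list(reports)
  if (is.null(names(reports))) {
    names(reports) <- paste0("method", seq_along(reports))
  }
  rows <- list()
  for (method in names(reports)) {
    meth_name <- method
    for (sc in names(reports[[method]])) {
      r <- reports[[method]][[sc]]
      rows[[length(rows) + 1]] <- data.frame(
        method = meth_name, scenario = sc, tbr2 = r$tbr2, tbr1 = r$tbr1,
        tir = r$tir, tar1 = r$tar1, tar2 = r$tar2, lbgi = r$lbgi,
        hbgi = r$hbgi, mean_reward = r$mean_reward)
    }
  }
  do.call(rbind, rows)
}
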