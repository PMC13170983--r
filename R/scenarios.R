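# Structural scenario analyses: controlled modifications of the base-case
# inputs, re-run deterministically and probabilistically.

#' Scenario specification
#'
#' A named modification of the base-case inputs. All scales at 1, no horizon
#' override and arm-level costing is exactly the base case.
#'
#' @param name Scenario label (unique within a scenario set).
#' @param mortality_effect_scale In `[0, 1]`: 1 keeps the full mortality
#'   benefit of remission; 0 gives remission the same mortality as diabetes;
#'   intermediate values interpolate the remission death probability between
#'   the two.
#' @param qol_effect_scale In `[0, 1]`: scales the remission utility
#'   increment.
#' @param remission_scale In `[0, 1]`: multiplies the whole remission
#'   schedule (including years 1 and 2).
#' @param costing_mode `"arm"` (base case) or `"arm_by_remission"`: assign
#'   years 1-5 healthcare costs by arm and remission status rather than by
#'   arm only; intervention costs stay assigned by arm regardless.
#' @param horizon_override Optional `"five_year"`.
#' @return List of class `remit_scenario`.
#' @export
scenario_spec <- function(name, mortality_effect_scale = 1,
                          qol_effect_scale = 1, remission_scale = 1,
                          costing_mode = c("arm", "arm_by_remission"),
                          horizon_override = NULL) {
  costing_mode <- match.arg(costing_mode)
  for (s in c(mortality_effect_scale, qol_effect_scale, remission_scale)) {
    if (!is.finite(s) || s < 0 || s > 1) {
      stop("scenario scales must lie in [0, 1]")
    }
  }
  if (!is.null(horizon_override)) {
    horizon_override <- match.arg(horizon_override, "five_year")
  }
  structure(list(name = name,
                 mortality_effect_scale = mortality_effect_scale,
                 qol_effect_scale = qol_effect_scale,
                 remission_scale = remission_scale,
                 costing_mode = costing_mode,
                 horizon_override = horizon_override),
            class = "remit_scenario")
}

#' The packaged scenario set
#'
#' Base case plus the published structural scenarios: halved and removed
#' mortality benefit of remission, halved and removed quality-of-life
#' benefit, remission-status-based healthcare costing, a 5-year time
#' horizon, and a 50% reduction in 12-month remission (with
#' remission-status-based costing, so lesser remission raises healthcare
#' costs).
#'
#' @return List of `remit_scenario` objects.
#' @export
default_scenarios <- function() {
  list(
    scenario_spec("base_case"),
    scenario_spec("mortality_effect_50", mortality_effect_scale = 0.5),
    scenario_spec("mortality_effect_0", mortality_effect_scale = 0),
    scenario_spec("qol_effect_50", qol_effect_scale = 0.5),
    scenario_spec("qol_effect_0", qol_effect_scale = 0),
    scenario_spec("remission_based_costing",
                  costing_mode = "arm_by_remission"),
    scenario_spec("five_year_horizon", horizon_override = "five_year"),
    scenario_spec("remission_50", remission_scale = 0.5,
                  costing_mode = "arm_by_remission")
  )
}

#' Apply a scenario to a set of model inputs
#'
#' Returns modified inputs: remission schedules scaled, remission mortality
#' interpolated between the non-diabetes (scale 1) and diabetes (scale 0)
#' rates, the remission utility decrement moved toward the diabetes
#' decrement, and -- for remission-based costing -- years 1-5 cost means
#' split by remission status (year 1 is unsplit: remission is assessed at 12
#' months).
#'
#' @param spec A [scenario_spec()].
#' @param inputs A `remit_inputs` list.
#' @param cohort Optional `remit_cohort`, required for
#'   `costing_mode = "arm_by_remission"` when the split means must be
#'   estimated from data; if omitted, the packaged split is used.
#' @return Modified `remit_inputs`.
#' @export
apply_scenario <- function(spec, inputs, cohort = NULL) {
  out <- inputs
  if (spec$remission_scale != 1) {
    for (a in names(out$schedule)) {
      sc <- out$schedule[[a]]
      out$schedule[[a]] <- remission_schedule(
        sc$S * spec$remission_scale, sc$extrapolation_rate, sc$cap_years)
    }
  }
  if (spec$mortality_effect_scale != 1) {
    mt <- out$mortality
    mt$q_nondiabetes <- mt$q_diabetes +
      spec$mortality_effect_scale * (mt$q_nondiabetes - mt$q_diabetes)
    out$mortality <- mt
  }
  if (spec$qol_effect_scale != 1) {
    u <- out$utilities
    u$dec_remission <- u$dec_diabetes +
      spec$qol_effect_scale * (u$dec_remission - u$dec_diabetes)
    out$utilities <- u
  }
  if (spec$costing_mode == "arm_by_remission") {
    out$hc_by_remission <- if (is.null(cohort)) {
      list(control = hc_cost_means_by_remission("control", inputs$s_save),
           intervention = hc_cost_means_by_remission("intervention",
                                                     inputs$s_save))
    } else {
      lapply(c(control = "control", intervention = "intervention"),
             function(a) estimate_split_costs(cohort, a))
    }
    out <- split_costing_inputs(out)
  }
  if (!is.null(spec$horizon_override)) {
    out$config$horizon <- spec$horizon_override
  }
  out
}

# KM sampling-average cost means by arm, year and remission status, with
# fallback to the arm mean where a stratum is empty.
estimate_split_costs <- function(cohort, arm) {
  res <- tibble::tibble(year = 1:5, mean_nonremission = NA_real_,
                        mean_remission = NA_real_)
  for (y in 1:5) {
    est <- km_sampling_average(cohort, arm, y, by_remission = TRUE)
    marg <- km_sampling_average(cohort, arm, y)$total_mean
    nr <- est$total_mean[!est$in_remission]
    r <- est$total_mean[est$in_remission]
    res$mean_nonremission[y] <- if (length(nr) == 1) nr else marg
    res$mean_remission[y] <- if (length(r) == 1) r else marg
  }
  res$mean_remission[1] <- NA_real_  # year 1 unsplit
  res
}

# Re-express years 1-5 arm cost means under remission-status costing:
# effective per-survivor mean given the (possibly rescaled) schedule.
split_costing_inputs <- function(inputs) {
  for (a in names(inputs$hc_annual)) {
    split <- inputs$hc_by_remission[[a]]
    S <- inputs$schedule[[a]]$S[1:5]
    m <- split$mean_nonremission
    eff <- m
    has_r <- !is.na(split$mean_remission)
    eff[has_r] <- (1 - S[has_r]) * m[has_r] +
      S[has_r] * split$mean_remission[has_r]
    inputs$hc_annual[[a]] <- eff
  }
  inputs
}

#' Run the full scenario set
#'
#' One PSA per scenario under a shared seed (so differences between rows are
#' attributable to the modification, not sampling noise), assembled into a
#' results table with incremental cost and QALYs, percentile intervals,
#' probability of cost-saving and probability cost-effective at 20,000 GBP
#' per QALY.
#'
#' @param cohort A `remit_cohort`.
#' @param specs List of [scenario_spec()]s including the base case (default
#'   [default_scenarios()]).
#' @param config A [model_config()].
#' @param n_iter PSA iterations per scenario.
#' @param seed Shared integer seed.
#' @param uc A [unit_costs()] list.
#' @param resample Resampling scheme per iteration, as in [run_psa()]:
#'   `"bootstrap"` (centred on the supplied cohort) or `"parametric"`
#'   (centred on the generator truth).
#' @return List of class `remit_scenarios`: `table` (one row per scenario)
#'   and `psa` (the per-scenario `remit_psa` objects).
#' @export
run_scenarios <- function(cohort, specs = default_scenarios(),
                          config = model_config(), n_iter = 1000,
                          seed = 1L, uc = unit_costs(),
                          resample = c("bootstrap", "parametric")) {
  resample <- match.arg(resample)
  nms <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nms)) stop("duplicate scenario names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  psas <- list()
  rows <- list()
  for (spec in specs) {
    psa <- run_psa_scenario(cohort, spec, config, n_iter, seed, uc,
                            resample = resample)
    psas[[spec$name]] <- psa
    rows[[spec$name]] <- tibble::tibble(
      scenario = spec$name,
      incremental_cost = mean(psa$draws$d_cost),
      cost_lower = psa$intervals$lower[1], cost_upper = psa$intervals$upper[1],
      incremental_qaly = mean(psa$draws$d_qaly),
      qaly_lower = psa$intervals$lower[2], qaly_upper = psa$intervals$upper[2],
      p_cost_saving = psa$p_cost_saving,
      p_cost_effective_20k = psa$p_cost_effective_20k)
  }
  structure(list(table = dplyr::bind_rows(rows), psa = psas),
            class = "remit_scenarios")
}

# PSA with a scenario modification applied to every iteration's inputs.
run_psa_scenario <- function(cohort, spec, config = model_config(),
                             n_iter = 1000, seed = 1L, uc = unit_costs(),
                             mortality_cv = .remitce$mortality_cv,
                             thresholds = seq(0, 50000, by = 1000),
                             resample = c("bootstrap", "parametric")) {
  stopifnot(n_iter >= 2)
  resample <- match.arg(resample)
  point <- estimate_inputs(cohort, uc = uc, config = config)
  index <- cohort_index(cohort)
  withr::with_seed(seed, {
    iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
    draws <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      if (resample == "bootstrap") {
        boot <- resample_cohort(cohort, index)
        inputs <- estimate_inputs(boot, uc = uc, config = config,
                                  mortality = point$mortality,
                                  gee_fit = point$gee)
        eff <- rnorm(1, point$gee$estimate, point$gee$se)
        ut <- derive_utility_inputs(
          list(intercept = point$gee$intercept, estimate = eff),
          norms = point$utilities$norms, age = config$start_age,
          fraction_women = config$fraction_women)
        inputs$utilities$dec_diabetes <- ut$dec_diabetes
        inputs$utilities$dec_remission <- ut$dec_remission
      } else {
        par_i <- cohort$params
        par_i$seed <- iter_seeds[it]
        boot <- generate_cohort(par_i)
        inputs <- estimate_inputs(boot, uc = uc, config = config,
                                  mortality = point$mortality)
      }
      inputs$mortality <- draw_mortality(point$mortality, config, mortality_cv)
      inputs <- apply_scenario(spec, inputs, cohort = boot)
      ce <- summarize_ce(run_model(inputs))
      use_5y <- identical(inputs$config$horizon, "five_year")
      dc <- if (use_5y) ce$table$incremental[
        ce$table$metric == "total_cost" & ce$table$horizon == "five_year"]
      else ce$delta_cost
      dq <- if (use_5y) ce$table$incremental[
        ce$table$metric == "qaly" & ce$table$horizon == "five_year"]
      else ce$delta_qaly
      draws[[it]] <- tibble::tibble(iteration = it, d_cost = dc, d_qaly = dq)
    }
    draws <- dplyr::bind_rows(draws)
  })
  curve <- ceac(draws, thresholds)
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE, type = 1)
  structure(list(
    draws = draws, ceac = curve,
    p_cost_saving = mean(draws$d_cost < 0),
    p_cost_effective_20k = curve$probability[curve$threshold == 20000],
    intervals = tibble::tibble(
      metric = c("d_cost", "d_qaly"),
      lower = c(qs(draws$d_cost)[1], qs(draws$d_qaly)[1]),
      upper = c(qs(draws$d_cost)[2], qs(draws$d_qaly)[2])),
    point = NULL, n_iter = n_iter, seed = seed, n_redrawn = 0L
  ), class = "remit_psa")
}
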