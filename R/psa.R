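# Probabilistic sensitivity analysis: arm-stratified bootstrap of the
# participant-level cohort plus Monte-Carlo draws of the utility effect
# (normal on the regression coefficient) and of mortality (beta, matched by
# method of moments).

# Resample a cohort with replacement, stratified by arm at the original arm
# sizes; participant ids are relabelled so repeated draws stay distinct.
# Row indices per participant are precomputed once per table for speed.
resample_cohort <- function(cohort, index = cohort_index(cohort)) {
  p <- cohort$participants
  pick <- unlist(lapply(split(seq_len(nrow(p)), p$arm),
                        function(ix) sample(ix, length(ix), replace = TRUE)),
                 use.names = FALSE)
  old_id <- p$id[pick]
  new_id <- sprintf("B%04d", seq_along(pick))
  relabel <- function(nm) {
    idx <- index[[nm]][old_id]
    rows <- unlist(idx, use.names = FALSE)
    tab <- cohort[[nm]][rows, ]
    tab$id <- rep(new_id, lengths(idx))
    tab
  }
  out <- list(
    participants = { np <- p[pick, ]; np$id <- new_id; np },
    remission_status = relabel("remission_status"),
    annual_costs = relabel("annual_costs"),
    intervention_use = relabel("intervention_use"),
    eq5d = relabel("eq5d"),
    params = cohort$params)
  class(out) <- "remit_cohort"
  out
}

# Named list (per table) of row indices keyed by participant id; ids with no
# rows in a table map to integer(0).
cohort_index <- function(cohort) {
  ids <- cohort$participants$id
  lapply(setNames(nm = c("remission_status", "annual_costs",
                         "intervention_use", "eq5d")), function(nm) {
    tab <- cohort[[nm]]
    idx <- split(seq_len(nrow(tab)), factor(tab$id, levels = ids))
    idx
  })
}

#' One bootstrap iteration of the model inputs
#'
#' Resamples participants with replacement within arm and re-estimates every
#' data-driven input (remission schedules, KM sampling-average costs,
#' beyond-year-5 costing, intervention cost means). Utility and mortality
#' inputs are carried from `point_inputs`; the PSA driver overlays
#' Monte-Carlo draws on them.
#'
#' @param cohort A `remit_cohort`.
#' @param point_inputs The inputs estimated on the original cohort
#'   ([estimate_inputs()]); used for the non-resampled components.
#' @param uc,config See [estimate_inputs()].
#' @param index Optional precomputed [cohort] row index (internal, for
#'   repeated calls).
#' @return A `remit_inputs` list.
#' @export
bootstrap_iteration <- function(cohort, point_inputs, uc = unit_costs(),
                                config = model_config(),
                                index = cohort_index(cohort)) {
  boot <- resample_cohort(cohort, index)
  estimate_inputs(boot, uc = uc, config = config,
                  mortality = point_inputs$mortality,
                  gee_fit = point_inputs$gee)
}

# Beta draw matched to mean m and sd s by method of moments (0 < m < 1).
rbeta_ms <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  v <- s^2
  v <- min(v, m * (1 - m) * 0.99)  # keep shapes positive
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, m * k, (1 - m) * k)
}

# Scale the mortality table by independent beta draws of a reference rate
# per diabetes status (reference age = entry age, sexes pooled by the mix).
draw_mortality <- function(mortality, config, cv) {
  ref <- mortality[mortality$age == config$start_age, ]
  w <- ifelse(ref$sex == "F", config$fraction_women,
              1 - config$fraction_women)
  out <- mortality
  for (col in c("q_diabetes", "q_nondiabetes")) {
    m <- sum(ref[[col]] * w)
    draw <- rbeta_ms(1, m, cv * m)
    out[[col]] <- pmin(out[[col]] * (draw / m), 0.999)
  }
  # remission must never carry higher mortality than diabetes
  out$q_nondiabetes <- pmin(out$q_nondiabetes, out$q_diabetes)
  out
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_iter` iterations, each combining (i) resampled participant-level
#' data with full re-estimation of the data-driven inputs, (ii) Monte-Carlo
#' variation of the remission utility effect, and (iii) beta draws of
#' mortality by diabetes status; the Markov model is run per draw over the
#' configured horizon.
#'
#' Two resampling schemes are available. `"bootstrap"` (the method applied
#' to real trial data) resamples participants with replacement within arm
#' and draws the utility effect from a normal around the fitted regression
#' estimate and robust SE; its draws are centred on the supplied cohort's
#' own point estimates. `"parametric"` draws a fresh cohort from the
#' generator truth each iteration (re-fitting the utility regression on
#' each), so the draws are centred on the known generator parameters; this
#' is the appropriate scheme for calibration studies of the synthetic base
#' case, where the supplied cohort is itself one random draw. See the
#' methods vignette.
#'
#' @param cohort A `remit_cohort`.
#' @param config A [model_config()].
#' @param n_iter Number of iterations (default 1000).
#' @param seed Integer seed; `(seed, n_iter)` fully determine the result.
#' @param uc A [unit_costs()] list.
#' @param mortality_cv SE of the mortality beta draws, as a coefficient of
#'   variation on each reference rate.
#' @param thresholds Willingness-to-pay grid for the CEAC (GBP per QALY).
#' @param resample `"bootstrap"` or `"parametric"` (see Details).
#' @return List of class `remit_psa`: `draws` (tibble, one row per
#'   iteration), `ceac` (tibble `threshold`, `probability`),
#'   `p_cost_saving`, `p_cost_effective_20k`, percentile `intervals`
#'   (2.5/97.5%), `point` (the point-estimate summary), `n_redrawn`.
#' @export
run_psa <- function(cohort, config = model_config(), n_iter = 1000,
                    seed = 1L, uc = unit_costs(),
                    mortality_cv = .remitce$mortality_cv,
                    thresholds = seq(0, 50000, by = 1000),
                    resample = c("bootstrap", "parametric")) {
  stopifnot(n_iter >= 2)
  resample <- match.arg(resample)
  point <- estimate_inputs(cohort, uc = uc, config = config)
  point_ce <- summarize_ce(run_model(point))
  index <- cohort_index(cohort)
  withr::with_seed(seed, {
    iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
    draws <- vector("list", n_iter)
    n_redrawn <- 0L
    it <- 1L
    while (it <= n_iter) {
      if (resample == "bootstrap") {
        inputs <- bootstrap_iteration(cohort, point, uc = uc, config = config,
                                      index = index)
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
        co_i <- generate_cohort(par_i)
        inputs <- estimate_inputs(co_i, uc = uc, config = config,
                                  mortality = point$mortality)
        eff <- inputs$gee$estimate
      }
      inputs$mortality <- draw_mortality(point$mortality, config, mortality_cv)
      ce <- summarize_ce(run_model(inputs))
      row <- tibble::tibble(
        iteration = it,
        cost_intervention_arm = ce$table$intervention[
          ce$table$metric == "total_cost" & ce$table$horizon == "full"],
        cost_control_arm = ce$table$control[
          ce$table$metric == "total_cost" & ce$table$horizon == "full"],
        qaly_intervention_arm = ce$table$intervention[
          ce$table$metric == "qaly" & ce$table$horizon == "full"],
        qaly_control_arm = ce$table$control[
          ce$table$metric == "qaly" & ce$table$horizon == "full"],
        d_cost = ce$delta_cost, d_qaly = ce$delta_qaly,
        d_cost_5y = ce$table$incremental[
          ce$table$metric == "total_cost" & ce$table$horizon == "five_year"],
        d_qaly_5y = ce$table$incremental[
          ce$table$metric == "qaly" & ce$table$horizon == "five_year"],
        utility_effect_draw = eff)
      if (any(!is.finite(c(row$d_cost, row$d_qaly)))) {
        n_redrawn <- n_redrawn + 1L
        message("non-finite draw at iteration ", it, "; redrawn")
        next
      }
      draws[[it]] <- row
      it <- it + 1L
    }
    draws <- dplyr::bind_rows(draws)
  })
  curve <- ceac(draws, thresholds)
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE, type = 1)
  intervals <- tibble::tibble(
    metric = c("d_cost", "d_qaly", "d_cost_5y", "d_qaly_5y"),
    lower = c(qs(draws$d_cost)[1], qs(draws$d_qaly)[1],
              qs(draws$d_cost_5y)[1], qs(draws$d_qaly_5y)[1]),
    upper = c(qs(draws$d_cost)[2], qs(draws$d_qaly)[2],
              qs(draws$d_cost_5y)[2], qs(draws$d_qaly_5y)[2]))
  structure(list(
    draws = draws, ceac = curve,
    p_cost_saving = mean(draws$d_cost < 0),
    p_cost_effective_20k =
      curve$probability[curve$threshold == 20000],
    intervals = intervals, point = point_ce, n_iter = n_iter,
    seed = seed, n_redrawn = n_redrawn
  ), class = "remit_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws with
#' positive net monetary benefit. At threshold 0 this equals the probability
#' of cost-saving exactly.
#'
#' @param draws Tibble with columns `d_cost`, `d_qaly` (one row per draw).
#' @param thresholds Non-empty numeric grid of thresholds (GBP per QALY).
#' @return Tibble `threshold`, `probability`.
#' @export
ceac <- function(draws, thresholds = seq(0, 50000, by = 1000)) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  stopifnot(nrow(draws) >= 1)
  probability <- vapply(thresholds, function(l) {
    mean(l * draws$d_qaly - draws$d_cost > 0)
  }, 0)
  tibble::tibble(threshold = thresholds, probability = probability)
}

#' @export
print.remit_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d, %d redrawn)\n",
              x$n_iter, x$seed, x$n_redrawn))
  cat(sprintf("  incremental cost: %.0f (95%% CI %.0f, %.0f)\n",
              mean(x$draws$d_cost), x$intervals$lower[1], x$intervals$upper[1]))
  cat(sprintf("  incremental QALY: %.3f (95%% CI %.3f, %.3f)\n",
              mean(x$draws$d_qaly), x$intervals$lower[2], x$intervals$upper[2]))
  cat(sprintf("  P(cost-saving) = %.3f; P(cost-effective at 20k) = %.3f\n",
              x$p_cost_saving, x$p_cost_effective_20k))
  invisible(x)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param psa A `remit_psa` (or a tibble like its `ceac` element).
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  curve <- if (inherits(psa, "remit_psa")) psa$ceac else psa
  ggplot2::ggplot(curve, ggplot2::aes(x = threshold, y = probability)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (GBP per QALY)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
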