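# Synthetic participant-level cohort generator. Emulates the data structure
# the analysis assumes -- two arms, annual remission assessments from 12
# months with intermittent missingness and dropout, right-skewed annual
# healthcare costs by category with a shared participant frailty,
# intervention resource use by programme phase, and a repeated-measures
# EQ-5D-3L panel with a true remission utility effect.

#' Generator parameters
#'
#' Defaults are the packaged study conditions: arm size 149, entry age 54,
#' 59% women, 12-month remission 46% (intervention) and 5% (control),
#' maintenance declining to an arm-level 9.7% at year 5, annual dropout
#' hazard 4%, cost means/SDs calibrated to the published per-annum resource
#' use summary, intervention sachets/visits calibrated to the published
#' phase-by-year table, and a true remission utility effect of 0.037.
#'
#' @param n_per_arm Participants per arm (>= 2).
#' @param start_age Entry age in years.
#' @param fraction_women Proportion of women.
#' @param remission_12m_prob Named vector, 12-month remission probability per
#'   arm.
#' @param annual_retention Conditional probability of maintaining remission
#'   through each of years 2-5, given remission at the previous year.
#' @param annual_dropout_hazard Probability of loss to follow-up at each year
#'   boundary (years 2-5).
#' @param dropout_remission_dependence Optional informative-censoring knob:
#'   multiplies the dropout hazard by `1 + dep` for participant-years not in
#'   remission (0 = independent censoring, the default).
#' @param assessment_missing_prob Probability that a single annual remission
#'   assessment is missing despite continued follow-up.
#' @param extension_uptake Proportion of intervention participants in the
#'   years 3-5 extension (governs EQ-5D availability beyond year 2).
#' @param cost_model Tibble of per-category annual cost means/SDs by arm,
#'   year and remission status; see [default_cost_model()].
#' @param cost_frailty_cv Coefficient of variation of the lognormal
#'   participant-level cost frailty shared across categories and years.
#' @param intervention_use_model Tibble of sachet/visit means and SDs by
#'   phase and year; see [default_intervention_use()].
#' @param utility_effect_remission True utility increment while in remission.
#' @param utility_baseline_mean Mean EQ-5D index with diabetes at baseline.
#' @param utility_noise_sd Visit-level noise SD.
#' @param subject_effect_sd Between-subject (exchangeable) SD.
#' @param seed Integer seed; identical parameters and seed give identical
#'   cohorts.
#' @return List of class `remit_params`.
#' @export
generator_params <- function(
    n_per_arm = 149L,
    start_age = 54,
    fraction_women = 0.59,
    remission_12m_prob = c(intervention = 0.46, control = 0.05),
    annual_retention = default_annual_retention(),
    annual_dropout_hazard = 0.04,
    dropout_remission_dependence = 0,
    assessment_missing_prob = 0.05,
    extension_uptake = 0.58,
    cost_model = default_cost_model(),
    cost_frailty_cv = 0.8,
    intervention_use_model = default_intervention_use(),
    utility_effect_remission = 0.037,
    utility_baseline_mean = 0.770200681650838,
    utility_noise_sd = 0.07,
    subject_effect_sd = 0.08,
    seed = 1L) {
  p <- list(n_per_arm = as.integer(n_per_arm), start_age = start_age,
            fraction_women = fraction_women,
            remission_12m_prob = remission_12m_prob,
            annual_retention = annual_retention,
            annual_dropout_hazard = annual_dropout_hazard,
            dropout_remission_dependence = dropout_remission_dependence,
            assessment_missing_prob = assessment_missing_prob,
            extension_uptake = extension_uptake,
            cost_model = cost_model,
            cost_frailty_cv = cost_frailty_cv,
            intervention_use_model = intervention_use_model,
            utility_effect_remission = utility_effect_remission,
            utility_baseline_mean = utility_baseline_mean,
            utility_noise_sd = utility_noise_sd,
            subject_effect_sd = subject_effect_sd,
            seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "remit_params")
}

validate_params <- function(p) {
  chk_prop <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
      stop("generator configuration error: '", nm, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.finite(p$n_per_arm) || p$n_per_arm < 2) {
    stop("generator configuration error: 'n_per_arm' must be >= 2",
         call. = FALSE)
  }
  chk_prop(p$fraction_women, "fraction_women")
  chk_prop(p$remission_12m_prob, "remission_12m_prob")
  chk_prop(p$annual_retention, "annual_retention")
  chk_prop(p$annual_dropout_hazard, "annual_dropout_hazard")
  chk_prop(p$assessment_missing_prob, "assessment_missing_prob")
  chk_prop(p$extension_uptake, "extension_uptake")
  if (length(p$annual_retention) != 4) {
    stop("generator configuration error: 'annual_retention' needs years 2-5",
         call. = FALSE)
  }
  for (nm in c("utility_noise_sd", "subject_effect_sd", "cost_frailty_cv")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("generator configuration error: '", nm, "' must be >= 0",
           call. = FALSE)
    }
  }
  cm <- p$cost_model
  if (any(!is.finite(cm$mean)) || any(cm$mean < 0) || any(cm$sd < 0)) {
    stop("generator configuration error: 'cost_model' means/SDs must be ",
         "non-negative", call. = FALSE)
  }
  invisible(p)
}

#' @rdname generator_params
#' @export
default_annual_retention <- function() {
  m <- .remitce$maintenance
  m[2:5] / m[1:4]
}

#' Default per-category annual cost model
#'
#' Category-level gamma means and SDs by arm, year and remission status.
#' Year-by-arm total means follow the packaged calibrated cost ramp (see the
#' methods vignette); category shares and dispersion follow the published
#' per-annum summary; years 2-5 means are split by remission status so that
#' the remission-vs-non-remission proportional saving equals the packaged
#' `s`, while the arm-year marginal mean is preserved.
#'
#' @return Tibble `arm`, `year`, `remission`, `category`, `mean`, `sd`.
#' @export
default_cost_model <- function() {
  rows <- list()
  for (arm in c("control", "intervention")) {
    shares <- .remitce$cat_means[[arm]] / sum(.remitce$cat_means[[arm]])
    cv <- .remitce$cat_sd_within[[arm]] / .remitce$cat_means[[arm]]
    split <- hc_cost_means_by_remission(arm)
    for (y in 1:5) {
      for (st in c(FALSE, TRUE)) {
        tot <- if (y == 1) {
          hc_cost_means(arm)[1]
        } else if (st) split$mean_remission[y] else split$mean_nonremission[y]
        rows[[length(rows) + 1]] <- tibble::tibble(
          arm = arm, year = y, remission = st,
          category = .remitce$cost_categories,
          mean = tot * shares, sd = tot * shares * cv)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Default intervention resource-use model
#'
#' Sachets and practitioner visits by programme phase and year (means and
#' SDs per participant remaining in the study), calibrated to the published
#' intervention resource-use table. Total diet replacement and food
#' reintroduction occur in year 1 only; weight-loss management and rescue
#' packages continue through year 5.
#'
#' @return Tibble `year`, `phase`, `sachets_mean`, `sachets_sd`,
#'   `visits_mean`, `visits_sd`.
#' @export
default_intervention_use <- function() {
  tibble::tribble(
    ~year, ~phase,               ~sachets_mean, ~sachets_sd, ~visits_mean, ~visits_sd,
    1L, "total_diet_replacement", 388.4, 153.8, 7.8, 2.8,
    1L, "food_reintroduction",     62.6,  49.1, 3.6, 1.8,
    1L, "weight_loss_management",  34.3,  53.0, 4.1, 3.0,
    1L, "rescue",                  24.4,  49.8, 0.8, 1.6,
    2L, "weight_loss_management",  55.8,  91.9, 6.6, 5.2,
    2L, "rescue",                  40.0,  66.3, 1.3, 2.2,
    3L, "weight_loss_management",  24.9,  53.4, 2.1, 2.1,
    3L, "rescue",                  19.4,  44.7, 0.5, 1.1,
    4L, "weight_loss_management",  17.4,  47.1, 1.8, 2.0,
    4L, "rescue",                  26.6,  57.6, 0.7, 1.4,
    5L, "weight_loss_management",  11.9,  36.2, 1.2, 1.4,
    5L, "rescue",                  16.1,  47.2, 0.5, 1.1
  )
}

# Gamma draw parameterised by mean/SD, with a point mass at zero when the
# mean is zero and a degenerate draw when the SD is zero.
rgamma_ms <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  pos <- mean > 0 & sd > 0
  out[mean > 0 & sd == 0] <- mean[mean > 0 & sd == 0]
  if (any(pos)) {
    out[pos] <- rgamma(sum(pos), shape = (mean[pos] / sd[pos])^2,
                       scale = sd[pos]^2 / mean[pos])
  }
  out
}

#' Generate a synthetic trial cohort
#'
#' Draws a participant-level cohort with the statistical structure the
#' analysis assumes. Remission is monotone (absorbing relapse), censoring is
#' an independent discrete annual hazard by default, per-category annual
#' costs are gamma-distributed around remission-dependent means with a
#' shared lognormal participant frailty, and EQ-5D observations follow
#' baseline mean + subject effect + remission effect + noise, clamped to the
#' EQ-5D-3L UK index range.
#'
#' @param params A [generator_params()].
#' @return List of class `remit_cohort` with tibbles `participants`,
#'   `remission_status` (observed annual records, years 2-5),
#'   `annual_costs` (long, by category), `intervention_use`, `eq5d`, plus
#'   the `params`.
#' @export
generate_cohort <- function(params = generator_params()) {
  validate_params(params)
  withr::with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(p) {
  n <- p$n_per_arm
  arms <- rep(c("intervention", "control"), each = n)
  N <- 2L * n
  ids <- sprintf("P%04d", seq_len(N))
  sex <- ifelse(runif(N) < p$fraction_women, "F", "M")

  # --- remission truth: assessed at 12 months, relapse absorbing ----------
  rem12 <- runif(N) < p$remission_12m_prob[arms]
  relapse_year <- rep(NA_integer_, N)
  at_risk <- rem12
  for (t in 2:5) {
    relapses <- at_risk & (runif(N) >= p$annual_retention[t - 1])
    relapse_year[relapses] <- t
    at_risk <- at_risk & !relapses
  }
  in_rem <- function(t) rem12 & (is.na(relapse_year) | relapse_year > t)

  # --- dropout: discrete annual hazard, optional remission dependence -----
  censor_year <- rep(NA_integer_, N)
  still_in <- rep(TRUE, N)
  for (t in 2:5) {
    h <- p$annual_dropout_hazard *
      (1 + p$dropout_remission_dependence * as.numeric(!in_rem(t)))
    dropped <- still_in & (runif(N) < pmin(h, 1))
    censor_year[dropped] <- t - 1L
    still_in <- still_in & !dropped
  }
  last_year <- ifelse(is.na(censor_year), 5L, censor_year)

  extension <- arms == "intervention" & runif(N) < p$extension_uptake

  participants <- tibble::tibble(
    id = ids, arm = arms, sex = sex, age_at_entry = p$start_age,
    extension_participant = extension, remission_12m = rem12,
    relapse_year = relapse_year, censor_year = censor_year)

  # --- observed annual remission records (12-month remitters, years 2-5) --
  rem_ids <- which(rem12)
  status <- tidyr::expand_grid(i = rem_ids, year = 2:5)
  status <- status[status$year <= last_year[status$i], ]
  truth <- ifelse(is.na(relapse_year[status$i]) | status$year < relapse_year[status$i],
                  "in_remission", "relapsed")
  miss <- runif(nrow(status)) < p$assessment_missing_prob
  remission_status <- tibble::tibble(
    id = ids[status$i], arm = arms[status$i], year = status$year,
    status = ifelse(miss, "missing", truth))

  # --- annual healthcare costs by category --------------------------------
  frailty_cv <- p$cost_frailty_cv
  sdlog <- sqrt(log(1 + frailty_cv^2))
  frailty <- if (frailty_cv > 0) rlnorm(N, -sdlog^2 / 2, sdlog) else rep(1, N)
  py <- tibble::tibble(i = rep(seq_len(N), last_year),
                       year = unlist(lapply(last_year, seq_len), use.names = FALSE))
  py$in_remission <- rem12[py$i] & py$year >= 2 &  # year 1 is pre-assessment
    (is.na(relapse_year[py$i]) | relapse_year[py$i] > py$year)
  key <- dplyr::left_join(
    tibble::tibble(arm = arms[py$i], year = py$year,
                   remission = py$in_remission, row = seq_len(nrow(py))),
    p$cost_model, by = c("arm", "year", "remission"),
    relationship = "many-to-many")
  key <- key[order(key$row), ]
  if (any(is.na(key$mean))) {
    bad <- key[is.na(key$mean), ][1, ]
    stop("cost_model has no rows for arm '", bad$arm, "', year ", bad$year,
         ", remission ", bad$remission)
  }
  f <- frailty[py$i[key$row]]
  annual_costs <- tibble::tibble(
    id = ids[py$i[key$row]], arm = key$arm, year = key$year,
    in_remission = key$remission, category = key$category,
    cost = rgamma_ms(nrow(key), key$mean * f, key$sd * f))

  # --- intervention resource use ------------------------------------------
  iu_rows <- which(arms == "intervention")
  iu <- tidyr::expand_grid(i = iu_rows, p$intervention_use_model)
  iu <- iu[iu$year <= last_year[iu$i], ]
  intervention_use <- tibble::tibble(
    id = ids[iu$i], year = iu$year, phase = iu$phase,
    sachets = rgamma_ms(nrow(iu), iu$sachets_mean, iu$sachets_sd),
    visits = rgamma_ms(nrow(iu), iu$visits_mean, iu$visits_sd))

  # --- EQ-5D panel ---------------------------------------------------------
  subj_eff <- rnorm(N, 0, p$subject_effect_sd)
  visits <- dplyr::bind_rows(
    tidyr::expand_grid(i = seq_len(N), visit_year = 0:2),
    tidyr::expand_grid(i = which(extension), visit_year = 3:5))
  visits <- visits[visits$visit_year <= last_year[visits$i], ]
  rem_at_visit <- visits$visit_year >= 1 & rem12[visits$i] &
    (is.na(relapse_year[visits$i]) | relapse_year[visits$i] > visits$visit_year)
  u <- p$utility_baseline_mean + subj_eff[visits$i] +
    p$utility_effect_remission * rem_at_visit +
    rnorm(nrow(visits), 0, p$utility_noise_sd)
  eq5d <- tibble::tibble(
    id = ids[visits$i], arm = arms[visits$i], visit_year = visits$visit_year,
    remission = rem_at_visit, utility = pmin(pmax(u, -0.594), 1))
  eq5d <- dplyr::arrange(eq5d, id, visit_year)

  structure(list(participants = participants,
                 remission_status = remission_status,
                 annual_costs = annual_costs,
                 intervention_use = intervention_use,
                 eq5d = eq5d, params = p),
            class = "remit_cohort")
}

#' @export
print.remit_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf(
    "Synthetic cohort: %d participants (%d per arm), %d observed participant-years\n",
    nrow(p), sum(p$arm == "intervention"),
    nrow(dplyr::distinct(x$annual_costs, id, year))))
  cat(sprintf("  12-month remission: %.0f%% intervention, %.0f%% control\n",
              100 * mean(p$remission_12m[p$arm == "intervention"]),
              100 * mean(p$remission_12m[p$arm == "control"])))
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' Writes the cohort's tables as comma-separated files plus the generator
#' parameters as JSON; [read_cohort()] restores an identical object
#' (missingness markers included).
#'
#' @param cohort A `remit_cohort`.
#' @param path Directory to hold the files (created if needed).
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `remit_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("participants", "remission_status", "annual_costs",
               "intervention_use", "eq5d")) {
    readr::write_csv(cohort[[nm]], file.path(path, paste0(nm, ".csv")),
                     na = "NA")
  }
  par <- unclass(cohort$params)
  par$remission_12m_prob <- as.list(par$remission_12m_prob)
  par$cost_model <- as.data.frame(par$cost_model)
  par$intervention_use_model <- as.data.frame(par$intervention_use_model)
  jsonlite::write_json(par, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read1 <- function(nm, types) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing cohort file: ", f)
    tryCatch(
      readr::read_csv(f, show_col_types = FALSE, progress = FALSE,
                      na = "NA", col_types = types),
      warning = function(w) stop("parse error in ", f, ": ",
                                 conditionMessage(w), call. = FALSE))
  }
  par <- jsonlite::read_json(file.path(path, "params.json"),
                             simplifyVector = TRUE)
  par$cost_model <- tibble::as_tibble(par$cost_model)
  par$intervention_use_model <- tibble::as_tibble(par$intervention_use_model)
  par$remission_12m_prob <- unlist(par$remission_12m_prob)
  params <- do.call(generator_params, par)
  structure(list(
    participants = read1("participants", readr::cols(
      id = "c", arm = "c", sex = "c", age_at_entry = "d",
      extension_participant = "l", remission_12m = "l",
      relapse_year = "i", censor_year = "i")),
    remission_status = read1("remission_status",
                             readr::cols(id = "c", arm = "c", year = "i",
                                         status = "c")),
    annual_costs = read1("annual_costs", readr::cols(
      id = "c", arm = "c", year = "i", in_remission = "l",
      category = "c", cost = "d")),
    intervention_use = read1("intervention_use", readr::cols(
      id = "c", year = "i", phase = "c", sachets = "d", visits = "d")),
    eq5d = read1("eq5d", readr::cols(id = "c", arm = "c", visit_year = "i",
                                     remission = "l", utility = "d")),
    params = params
  ), class = "remit_cohort")
}

#' Simulate a standalone EQ-5D utility panel
#'
#' A reduced generator for utility-model studies: `n` subjects with a fixed
#' number of annual visits, an exchangeable subject effect, and remission
#' trajectories drawn from the packaged 12-month remission probability and
#' retention schedule.
#'
#' @param n Number of subjects.
#' @param visits Number of annual visits after baseline (default 2, i.e.
#'   3 observations per subject).
#' @param p12 12-month remission probability.
#' @param effect True remission utility effect.
#' @param baseline_mean,noise_sd,subject_sd Utility model parameters.
#' @param seed Integer seed.
#' @return Long tibble `id`, `visit_year`, `remission`, `utility`.
#' @export
simulate_utility_panel <- function(n = 300, visits = 2, p12 = 0.46,
                                   effect = 0.037,
                                   baseline_mean = 0.770200681650838,
                                   noise_sd = 0.07, subject_sd = 0.08,
                                   seed = 1L) {
  withr::with_seed(seed, {
    retention <- default_annual_retention()
    rem12 <- runif(n) < p12
    relapse <- rep(NA_integer_, n)
    at_risk <- rem12
    for (t in 2:(visits + 3)) {
      r <- retention[min(t - 1, length(retention))]
      rel <- at_risk & (runif(n) >= r)
      relapse[rel] <- t
      at_risk <- at_risk & !rel
    }
    subj <- rnorm(n, 0, subject_sd)
    grid <- tidyr::expand_grid(i = seq_len(n), visit_year = 0:visits)
    rem <- grid$visit_year >= 1 & rem12[grid$i] &
      (is.na(relapse[grid$i]) | relapse[grid$i] > grid$visit_year)
    u <- baseline_mean + subj[grid$i] + effect * rem +
      rnorm(nrow(grid), 0, noise_sd)
    tibble::tibble(id = sprintf("S%04d", grid$i), visit_year = grid$visit_year,
                   remission = rem, utility = pmin(pmax(u, -0.594), 1))
  })
}
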