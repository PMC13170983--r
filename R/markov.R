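# Three-state Markov cohort engine: type 2 diabetes, remission, death.
# Annual cycles, occupancy evaluated at cycle start, no half-cycle
# correction; the arm-level remission schedule is applied to survivors.

# Run one arm (internally per sex, aggregated by the entry sex mix).
run_arm <- function(schedule, hc_annual, ic_annual, c5nr, s_save,
                    mortality, utilities, config,
                    initial_alive = 1) {
  T_max <- if (config$horizon == "five_year") 5L else
    config$max_age - config$start_age + 1L
  S <- schedule$S
  cap <- schedule$cap_years
  needed <- min(T_max, cap + 1L)
  if (length(S) < needed) {
    stop("remission schedule (length ", length(S), ") is shorter than the ",
         "modelled horizon; extrapolate it first")
  }
  if (length(S) < T_max) S <- c(S, rep(0, T_max - length(S)))
  disc <- discount_factor(seq_len(T_max), config$discount_rate,
                          config$year_one_discounted)
  ages <- config$start_age + seq_len(T_max) - 1L
  w <- c(F = config$fraction_women, M = 1 - config$fraction_women)

  agg <- NULL
  for (sx in c("F", "M")) {
    mt <- mortality[mortality$sex == sx, ]
    mt <- mt[match(ages, mt$age), ]
    if (any(is.na(mt$q_diabetes))) {
      stop("mortality table does not cover ages ",
           min(ages[is.na(mt$q_diabetes)]), "+")
    }
    su <- state_utilities(utilities, ages, sx)
    alive <- numeric(T_max + 1L)
    alive[1] <- initial_alive
    rem <- dia <- numeric(T_max)
    for (t in seq_len(T_max)) {
      rem[t] <- S[t] * alive[t]
      dia[t] <- alive[t] - rem[t]
      alive[t + 1L] <- alive[t] - rem[t] * mt$q_nondiabetes[t] -
        dia[t] * mt$q_diabetes[t]
    }
    alive_t <- alive[seq_len(T_max)]
    hc <- numeric(T_max)
    yr5 <- seq_len(min(5L, T_max))
    hc[yr5] <- hc_annual[yr5] * alive_t[yr5]
    if (T_max > 5L) {
      later <- 6L:T_max
      hc[later] <- c5nr * (dia[later] + (1 - s_save) * rem[later])
    }
    ic <- numeric(T_max)
    ic[yr5] <- ic_annual[yr5] * alive_t[yr5]
    qaly <- rem * su$utility_remission + dia * su$utility_diabetes
    part <- tibble::tibble(
      cycle = seq_len(T_max), age = ages, discount = disc,
      alive = alive_t, remission = rem, diabetes = dia,
      dead = initial_alive - alive_t,
      hc_cost = hc, ic_cost = ic, qaly = qaly)
    part[, -(1:3)] <- part[, -(1:3)] * w[[sx]]
    agg <- if (is.null(agg)) part else {
      agg[, -(1:3)] <- agg[, -(1:3)] + part[, -(1:3)]
      agg
    }
  }
  agg
}

#' Run the cohort model for both arms
#'
#' Propagates the entering cohort (age `config$start_age`,
#' `config$fraction_women` women, all alive with type 2 diabetes) through the
#' three-state structure under each arm's inputs. Each cycle, survivors split
#' into remission (per the arm-level schedule) and diabetes; each alive state
#' experiences its own mortality; healthcare costs are the arm-year
#' Kaplan-Meier sampling-average means applied to the proportion alive
#' (years 1-5) and the control year-5 non-remission cost thereafter, reduced
#' by the remission saving fraction while in remission; intervention costs
#' apply to the intervention arm in years 1-5 only.
#'
#' @param inputs A `remit_inputs` list ([base_case_inputs()] or
#'   [estimate_inputs()]).
#' @param horizon Optional override of `inputs$config$horizon`.
#' @return List of class `remit_trace` with per-arm cycle traces
#'   (`intervention`, `control`) and the `config` used.
#' @export
run_model <- function(inputs, horizon = NULL) {
  config <- inputs$config
  if (!is.null(horizon)) config$horizon <- match.arg(horizon,
                                                     c("lifetime", "five_year"))
  traces <- lapply(c(intervention = "intervention", control = "control"),
                   function(a) {
    run_arm(inputs$schedule[[a]], inputs$hc_annual[[a]], inputs$ic_annual[[a]],
            inputs$c5nr, inputs$s_save, inputs$mortality, inputs$utilities,
            config)
  })
  structure(c(traces, list(config = config)), class = "remit_trace")
}

# Accumulate discounted/undiscounted totals from one arm trace.
arm_totals <- function(tr, years = NULL) {
  if (!is.null(years)) tr <- tr[tr$cycle %in% years, ]
  d <- tr$discount
  list(
    hc_cost = sum(tr$hc_cost * d), ic_cost = sum(tr$ic_cost * d),
    total_cost = sum((tr$hc_cost + tr$ic_cost) * d),
    qaly = sum(tr$qaly * d), life_years = sum(tr$alive),
    life_years_disc = sum(tr$alive * d),
    remission_years = sum(tr$remission),
    remission_years_disc = sum(tr$remission * d)
  )
}

#' Summarise cost-effectiveness from two arm traces
#'
#' Totals per arm (healthcare cost, intervention cost, total cost, QALYs,
#' life-years, remission-years), over 5 years and over the full modelled
#' horizon, with incrementals (intervention minus control) and the ICER or a
#' dominance label when the intervention is both cheaper and more effective.
#'
#' @param trace A `remit_trace` from [run_model()].
#' @return List of class `remit_ce`: `table` (tidy tibble `metric`,
#'   `horizon`, `intervention`, `control`, `incremental`), `icer` (numeric or
#'   `Inf`/`-Inf`), `icer_label` (`"dominant"`, `"dominated"` or the ratio),
#'   `delta_cost`, `delta_qaly` (full-horizon).
#' @export
summarize_ce <- function(trace) {
  horizons <- list(five_year = 1:5,
                   full = seq_len(max(trace$intervention$cycle)))
  rows <- list()
  for (h in names(horizons)) {
    ti <- arm_totals(trace$intervention, horizons[[h]])
    tc <- arm_totals(trace$control, horizons[[h]])
    for (m in names(ti)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = m, horizon = h, intervention = ti[[m]], control = tc[[m]],
        incremental = ti[[m]] - tc[[m]])
    }
  }
  tab <- dplyr::bind_rows(rows)
  dc <- tab$incremental[tab$metric == "total_cost" & tab$horizon == "full"]
  dq <- tab$incremental[tab$metric == "qaly" & tab$horizon == "full"]
  if (dc < 0 && dq > 0) {
    icer <- NA_real_; label <- "dominant"
  } else if (dc > 0 && dq < 0) {
    icer <- NA_real_; label <- "dominated"
  } else if (dq == 0) {
    icer <- sign(dc) * Inf
    label <- "undefined (zero incremental QALYs)"
  } else {
    icer <- dc / dq; label <- sprintf("%.0f per QALY", icer)
  }
  structure(list(table = tab, icer = icer, icer_label = label,
                 delta_cost = dc, delta_qaly = dq,
                 config = trace$config), class = "remit_ce")
}

#' @export
print.remit_ce <- function(x, ...) {
  cat("Cost-effectiveness summary (", x$config$horizon, " horizon)\n", sep = "")
  wide <- x$table
  wide$value <- sprintf("%.3f", wide$incremental)
  for (h in unique(wide$horizon)) {
    cat(" ", h, ":\n", sep = "")
    sub <- wide[wide$horizon == h, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-22s interv %10.2f  control %10.2f  incr %10.3f\n",
                  sub$metric[i], sub$intervention[i], sub$control[i],
                  sub$incremental[i]))
    }
  }
  cat("  cost per QALY:", x$icer_label, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = threshold * incremental QALYs - incremental cost`; positive values
#' favour the intervention.
#'
#' @param result A `remit_ce` (or any list with `delta_cost`, `delta_qaly`).
#' @param threshold Willingness to pay per QALY (GBP, >= 0), vectorised.
#' @return Net monetary benefit in GBP.
#' @export
net_monetary_benefit <- function(result, threshold = 20000) {
  stopifnot(all(threshold >= 0))
  threshold * result$delta_qaly - result$delta_cost
}

# Fast aggregation of the cost inputs (equivalent to km_sampling_average /
# remission_cost_saving_fraction applied year by year, done in one pass).
fast_cost_inputs <- function(cohort) {
  ac <- cohort$annual_costs
  if (nrow(ac) == 0) stop("no observed participant-years")
  pykey <- paste(ac$id, ac$year, sep = "\r")
  keep <- !duplicated(pykey)
  tot <- as.numeric(rowsum(ac$cost, factor(pykey, levels = pykey[keep])))
  arm <- ac$arm[keep]; year <- ac$year[keep]; rem <- ac$in_remission[keep]

  mean_by <- function(sel) {
    if (!any(sel)) return(NA_real_)
    mean(tot[sel])
  }
  hc <- lapply(c(control = "control", intervention = "intervention"),
               function(a) {
    v <- vapply(1:5, function(y) mean_by(arm == a & year == y), 0)
    if (any(is.na(v))) {
      stop("no observed costs for arm '", a, "', year ",
           which(is.na(v))[1])
    }
    v
  })
  c5nr <- mean_by(arm == "control" & year == 5 & !rem)
  if (!is.finite(c5nr)) stop("control year-5 non-remission cost unavailable")
  ratios <- vapply(2:5, function(y) {
    m_nr <- mean_by(year == y & !rem)
    m_r <- mean_by(year == y & rem)
    if (!is.finite(m_nr) || m_nr == 0) {
      stop("non-remission mean cost unavailable or zero in year ", y)
    }
    if (is.na(m_r)) NA_real_ else m_r / m_nr
  }, 0)
  if (all(is.na(ratios))) stop("no remission participant-years in years 2-5")
  list(hc = hc, c5nr = c5nr,
       s_save = min(max(1 - mean(ratios, na.rm = TRUE), 0), 1))
}

# Mean intervention cost per participant-year under observation, years 1..5.
fast_intervention_means <- function(cohort, uc) {
  p <- cohort$participants
  int_ids <- p$id[p$arm == "intervention"]
  last <- ifelse(is.na(p$censor_year), 5L, as.integer(p$censor_year))
  n_obs <- vapply(1:5, function(y) sum(last[p$arm == "intervention"] >= y), 0L)
  iu <- cohort$intervention_use
  per_visit <- uc$practitioner_minute * uc$visit_default_minutes
  cost <- uc$sachet * iu$sachets + per_visit * iu$visits
  by_year <- rowsum(cost, factor(iu$year, levels = 1:5))
  means <- as.numeric(by_year) / pmax(n_obs, 1)
  means[1] <- means[1] + uc$setup_per_participant
  means[n_obs == 0] <- 0
  means
}

#' Estimate model inputs from a participant-level cohort
#'
#' Runs the full estimation chain on a cohort: 12-month remission proportions
#' and Kaplan-Meier maintenance per arm (extrapolated and capped), KM
#' sampling-average annual healthcare costs per arm-year, the control year-5
#' non-remission cost and remission saving fraction for the beyond-year-5
#' rule, unit-costed intervention cost means per year, and utility decrements
#' from the repeated-measures regression. Mortality is not estimable from
#' the trial-style data and is taken from the packaged table.
#'
#' @param cohort A `remit_cohort`.
#' @param uc A [unit_costs()] list.
#' @param config A [model_config()].
#' @param mortality Mortality table (default packaged).
#' @param gee_fit Optionally, a pre-fitted `remit_gee` (or a list with
#'   `intercept` and `estimate`) standing in for the utility regression --
#'   used by the PSA to inject Monte-Carlo draws of the remission effect.
#' @return A `remit_inputs` list; also carries `gee` (the fitted utility
#'   regression) and `p12` for inspection.
#' @export
estimate_inputs <- function(cohort, uc = unit_costs(),
                            config = model_config(),
                            mortality = default_mortality(),
                            gee_fit = NULL) {
  p <- cohort$participants

  schedules <- list(); p12s <- c()
  for (a in c("intervention", "control")) {
    ids_a <- p$id[p$arm == a]
    p12 <- mean(p$remission_12m[p$arm == a])
    rem_ids <- p$id[p$arm == a & p$remission_12m]
    hist <- classify_history(
      cohort$remission_status[cohort$remission_status$arm == a, ],
      ids = rem_ids)
    sched <- km_remission(hist, p12)
    schedules[[a]] <- extrapolate_schedule(sched,
                                           cap_years = config$remission_cap_years)
    p12s[a] <- p12
  }

  costs <- fast_cost_inputs(cohort)
  hc <- costs$hc
  s_save <- costs$s_save
  c5nr <- costs$c5nr

  ic_means <- fast_intervention_means(cohort, uc)

  if (is.null(gee_fit)) gee_fit <- fit_gee_utility(cohort$eq5d)
  norms <- population_norms()
  ut <- derive_utility_inputs(gee_fit, norms, age = config$start_age,
                              fraction_women = config$fraction_women)

  structure(list(
    schedule = schedules,
    hc_annual = hc,
    c5nr = c5nr, s_save = s_save,
    ic_annual = list(control = rep(0, 5), intervention = ic_means),
    mortality = mortality,
    utilities = list(norms = norms, dec_diabetes = ut$dec_diabetes,
                     dec_remission = ut$dec_remission),
    config = config, gee = gee_fit, p12 = p12s
  ), class = "remit_inputs")
}
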