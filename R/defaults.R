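# Packaged calibrated default inputs.
#
# The source trial data are participant-level NHS records and are not publicly
# available; where the publication prints no source values (per-year cost
# means, mortality rates, unit prices, years 3-4 remission), the defaults
# below are explicit calibration choices, solved once so that the
# deterministic base case reproduces the published summary table (5-year
# discounted arm cost totals, control life expectancy, incremental life-years,
# QALYs and lifetime incremental cost). See the methods vignette for the
# calibration rationale; values are frozen here at full precision.

.remitce <- new.env(parent = emptyenv())

# --- study conditions printed in the publication ---------------------------
.remitce$start_age       <- 54
.remitce$fraction_women  <- 0.59
.remitce$discount_rate   <- 0.035
.remitce$n_per_arm       <- 149L
.remitce$remission_cap   <- 10L
.remitce$max_age         <- 110L
.remitce$p12             <- c(intervention = 0.46, control = 0.05)
.remitce$utility_effect  <- 0.037

# Remission maintenance among 12-month remitters, years 1..5. Year-2 value is
# the printed 36%/46%; years 3-4 interpolate geometrically between the printed
# year-2 and year-5 (9.7%) arm-level proportions (calibration choice).
.remitce$maintenance <- local({
  m2 <- 0.36 / 0.46
  k  <- (0.097 / 0.36)^(1 / 3)
  c(1, m2, m2 * k, m2 * k^2, 0.097 / 0.46)
})

# --- calibrated constants (solved in the calibration run, frozen here) -----
# Mortality: annual death probability q(age) = a * exp(b*(age - 54)) for
# people free of diabetes, scaled by `hr` while living with type 2 diabetes;
# female rates are `female_ratio` times male rates at every age.
.remitce$gompertz_b    <- 0.092
.remitce$female_ratio  <- 0.60
.remitce$gompertz_a    <- 0.00776094169755075     # male level at age 54
.remitce$hr_diabetes   <- 1.44685565958983

# Annual healthcare cost means (GBP 2020/21) applied to modelled survivors,
# years 1-5: linear ramp for the control arm, proportional scaling for the
# intervention arm; beyond year 5 the control year-5 non-remission cost is
# applied, with proportional saving `s_save` while in remission.
.remitce$hc_cost_c0    <- 1603.58417415412        # control year-1 mean
.remitce$hc_cost_slope <- 64.7183555805324        # GBP per additional year
.remitce$hc_int_scale  <- 0.734934957686176       # intervention/control ratio
.remitce$s_save        <- 0.810462941217865
.remitce$mortality_cv  <- 0.15                    # PSA beta-draw SE knob

# Intervention unit costs live in inst/extdata/unit_costs.csv (editable);
# the sachet price there is calibrated so the discounted 5-year intervention
# total (set-up + sachets + practitioner time) equals 1691.

# Utility decrements relative to population norms, derived from the repeated
# measures regression: predicted utility with diabetes at baseline age/sex
# over the age-54 norm gives the diabetes decrement; the remission effect
# (0.037) reduces it.
.remitce$dec_diabetes  <- 0.0938815509990145
.remitce$norm_at_entry <- 0.85

# Per-participant mean intervention resource use by year (trial-reported),
# used for the deterministic intervention cost schedule.
.remitce$sachets_year <- c(509.8, 95.9, 44.3, 44.0, 28.1)
.remitce$visits_year  <- c(16.4, 7.9, 2.7, 2.5, 1.6)

# Healthcare cost category shares and dispersion, from the published pooled
# participant-year summary (Table of annual resource use).
.remitce$cost_categories <- c("primary_care", "other", "secondary_care",
                              "hospital", "medicines")
.remitce$cat_means <- list(
  control      = c(428, 44, 347, 690, 300),
  intervention = c(357, 50, 288, 412, 222)
)
# Within-category gamma SDs once a shared participant frailty (CV 0.8) is
# taken out of the published marginal SDs; primary care floored at 0.3 * mean.
.remitce$cat_sd_within <- list(
  control      = c(128.4, 144.8, 457.3, 3087.4, 618.1),
  intervention = c(107.1, 157.7, 429.4, 1760.6, 481.8)
)
.remitce$cost_frailty_cv <- 0.8

#' Annual discount factor
#'
#' Standard UK discounting at 3.5% per annum; by default the first model year
#' is undiscounted (factor exponent `year - 1`).
#'
#' @param year Cycle index (1-based).
#' @param rate Annual discount rate (default 0.035).
#' @param year_one_discounted If `TRUE`, discount from the first year
#'   (exponent `year`).
#' @return Numeric vector of discount factors.
#' @examples
#' discount_factor(1:5)
#' @export
discount_factor <- function(year, rate = 0.035, year_one_discounted = FALSE) {
  stopifnot(all(year >= 1), rate >= 0)
  1 / (1 + rate)^(year - 1 + as.numeric(year_one_discounted))
}

#' Model configuration
#'
#' Bundles the cohort entry characteristics and accounting conventions of the
#' Markov model.
#'
#' @param start_age Age at model entry (years).
#' @param fraction_women Proportion of women in the entering cohort.
#' @param discount_rate Annual discount rate applied to costs and outcomes.
#' @param horizon `"lifetime"` (run to age `max_age` or cohort extinction) or
#'   `"five_year"`.
#' @param max_age Oldest modelled age under the lifetime horizon.
#' @param remission_cap_years Remission is assumed not to persist beyond this
#'   many years from entry.
#' @param year_one_discounted Discounting convention switch; see
#'   [discount_factor()].
#' @return A list with class `remit_config`.
#' @export
model_config <- function(start_age = .remitce$start_age,
                         fraction_women = .remitce$fraction_women,
                         discount_rate = .remitce$discount_rate,
                         horizon = c("lifetime", "five_year"),
                         max_age = .remitce$max_age,
                         remission_cap_years = .remitce$remission_cap,
                         year_one_discounted = FALSE) {
  horizon <- match.arg(horizon)
  stopifnot(discount_rate >= 0, fraction_women >= 0, fraction_women <= 1,
            start_age > 0, max_age > start_age + 5)
  structure(list(start_age = start_age, fraction_women = fraction_women,
                 discount_rate = discount_rate, horizon = horizon,
                 max_age = max_age, remission_cap_years = remission_cap_years,
                 year_one_discounted = year_one_discounted),
            class = "remit_config")
}

#' Mortality table by age, sex and diabetes status
#'
#' Annual probabilities of death follow a Gompertz age schedule for people
#' free of diabetes, with a constant hazard ratio applied while living with
#' type 2 diabetes. The packaged level, slope and hazard ratio are
#' calibration inputs chosen so the base case reproduces the published
#' control-arm life expectancy (23.48 undiscounted life-years from age 54)
#' and incremental survival benefit of remission.
#'
#' @param a Male annual death probability at `age_from`.
#' @param b Gompertz log-slope per year of age.
#' @param hr Hazard ratio (probability scale) for diabetes vs none.
#' @param female_ratio Female/male probability ratio.
#' @param ages Integer vector of ages covered.
#' @return A tibble with columns `age`, `sex`, `q_nondiabetes`, `q_diabetes`.
#' @export
make_mortality_table <- function(a = .remitce$gompertz_a,
                                 b = .remitce$gompertz_b,
                                 hr = .remitce$hr_diabetes,
                                 female_ratio = .remitce$female_ratio,
                                 ages = .remitce$start_age:.remitce$max_age) {
  stopifnot(a > 0, b > 0, hr >= 1, female_ratio > 0)
  grid <- tidyr::expand_grid(age = ages, sex = c("F", "M"))
  level <- ifelse(grid$sex == "F", a * female_ratio, a)
  q_nd <- pmin(level * exp(b * (grid$age - min(ages))), 0.995)
  tibble::tibble(age = grid$age, sex = grid$sex,
                 q_nondiabetes = q_nd,
                 q_diabetes = pmin(q_nd * hr, 0.999))
}

#' @rdname make_mortality_table
#' @export
default_mortality <- function() make_mortality_table()

#' UK population utility norms
#'
#' EQ-5D-3L population-norm utility index by age band and sex, shipped as an
#' editable table in `inst/extdata/eq5d_population_norms.csv`.
#'
#' @param path Optional path to an alternative norms table.
#' @return Tibble with columns `age_lower`, `age_upper`, `sex`, `norm_utility`
#'   and a `source_label` attribute.
#' @export
population_norms <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.remitce$norms_cache)) return(.remitce$norms_cache)
    path <- system.file("extdata", "eq5d_population_norms.csv",
                        package = "remitce", mustWork = TRUE)
    .remitce$norms_cache <- population_norms(path)
    return(.remitce$norms_cache)
  }
  norms <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("age_lower", "age_upper", "sex", "norm_utility", "source_label")
  if (!all(req %in% names(norms))) {
    stop("norms table must have columns: ", paste(req, collapse = ", "))
  }
  norms
}

# Look up the norm for given ages (vectorised) and one sex; ages beyond the
# last band are clamped to it with a one-time warning.
norm_lookup <- function(norms, ages, sex) {
  nb <- norms[norms$sex == sex, ]
  nb <- nb[order(nb$age_lower), ]
  out <- numeric(length(ages))
  over <- ages > max(nb$age_upper)
  if (any(over)) {
    warning("ages beyond norm table clamped to last band", call. = FALSE)
    ages[over] <- max(nb$age_upper)
  }
  idx <- findInterval(ages, nb$age_lower)
  idx[idx < 1] <- 1
  nb$norm_utility[idx]
}

# Per-year healthcare cost means applied to modelled survivors (GBP), years
# 1..5, by arm; the beyond-year-5 input c5nr is the control year-5 mean for
# participants not in remission.
hc_cost_means <- function(arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  ctrl <- .remitce$hc_cost_c0 + .remitce$hc_cost_slope * (0:4)
  if (arm == "control") ctrl else ctrl * .remitce$hc_int_scale
}

# Remission-status-specific cost means implied by the arm-year means, the
# arm-level remission schedule and the proportional saving s: years 2-5 only
# (remission is assessed at 12 months, so year-1 costs are not split).
hc_cost_means_by_remission <- function(arm, s = .remitce$s_save) {
  m <- hc_cost_means(arm)
  sched <- default_schedule(arm)$S[1:5]
  nr <- m
  nr[2:5] <- m[2:5] / (1 - sched[2:5] * s)
  tibble::tibble(year = 1:5, mean_nonremission = nr,
                 mean_remission = c(NA_real_, nr[2:5] * (1 - s)))
}

#' Packaged remission schedule
#'
#' Arm-level proportion in remission at each annual cycle, years 1-5:
#' the 12-month remission proportion times the maintenance curve (see the
#' methods vignette for the interpolated years 3-4).
#'
#' @param arm `"intervention"` or `"control"`.
#' @return A `remission_schedule` object (see [remission_schedule()]).
#' @export
default_schedule <- function(arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  remission_schedule(.remitce$p12[[arm]] * .remitce$maintenance)
}

# Deterministic per-year intervention cost schedule (GBP per participant
# remaining, years 1..5) from the packaged unit costs and trial-mean resource
# use. Control arm costs are zero.
intervention_cost_schedule <- function(uc = unit_costs()) {
  per_visit <- uc$practitioner_minute * uc$visit_default_minutes
  setup <- c(uc$setup_per_participant, 0, 0, 0, 0)
  setup + uc$sachet * .remitce$sachets_year + per_visit * .remitce$visits_year
}

#' Packaged base-case model inputs
#'
#' Assembles the calibrated deterministic inputs of the base case: remission
#' schedules (extrapolated and capped), per-year healthcare cost means, the
#' beyond-year-5 costing rule, intervention costs, mortality and state
#' utilities.
#'
#' @param config A [model_config()].
#' @param uc A [unit_costs()] list.
#' @return A list of class `remit_inputs` accepted by [run_model()].
#' @export
base_case_inputs <- function(config = model_config(), uc = unit_costs()) {
  structure(list(
    schedule = list(
      intervention = extrapolate_schedule(default_schedule("intervention"),
                                          cap_years = config$remission_cap_years),
      control = extrapolate_schedule(default_schedule("control"),
                                     cap_years = config$remission_cap_years)
    ),
    hc_annual = list(control = hc_cost_means("control"),
                     intervention = hc_cost_means("intervention")),
    c5nr = hc_cost_means("control")[5] /
      (1 - default_schedule("control")$S[5] * .remitce$s_save),
    s_save = .remitce$s_save,
    ic_annual = list(control = rep(0, 5),
                     intervention = intervention_cost_schedule(uc)),
    mortality = default_mortality(),
    utilities = list(norms = population_norms(),
                     dec_diabetes = .remitce$dec_diabetes,
                     dec_remission = .remitce$dec_diabetes -
                       .remitce$utility_effect / .remitce$norm_at_entry),
    config = config
  ), class = "remit_inputs")
}
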