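# Shared fixtures and independent oracles used across the test files.

# Flat population-norm table (one band covering all ages, both sexes).
flat_norms <- function(u = 0.8) {
  tibble::tibble(age_lower = rep(18, 2), age_upper = rep(110, 2),
                 sex = c("F", "M"), norm_utility = u,
                 source_label = "test fixture")
}

# Constant mortality table over an age range.
const_mortality <- function(q_d, q_nd, ages = 54:110) {
  tidyr::expand_grid(age = ages, sex = c("F", "M")) |>
    dplyr::mutate(q_nondiabetes = q_nd, q_diabetes = q_d)
}

# Assemble a remit_inputs list by hand.
make_inputs <- function(S_int, S_ctrl = S_int * 0.1,
                        hc_c = rep(1000, 5), hc_i = rep(800, 5),
                        ic_i = rep(100, 5), c5nr = 1000, s_save = 0.5,
                        mortality = const_mortality(0.01, 0.005),
                        dec_d = 0.1, dec_r = 0.05, norms = flat_norms(),
                        config = model_config(), cap_years = 10L) {
  ext <- function(S) extrapolate_schedule(remission_schedule(S),
                                          cap_years = cap_years)
  structure(list(
    schedule = list(intervention = ext(S_int), control = ext(S_ctrl)),
    hc_annual = list(control = hc_c, intervention = hc_i),
    c5nr = c5nr, s_save = s_save,
    ic_annual = list(control = rep(0, 5), intervention = ic_i),
    mortality = mortality,
    utilities = list(norms = norms, dec_diabetes = dec_d,
                     dec_remission = dec_r),
    config = config), class = "remit_inputs")
}

# Independent brute-force cohort-model oracle: plain scalar loops, written
# directly from the model description rather than sharing code with the
# engine. Returns totals for one arm.
oracle_arm <- function(S, hc5, ic5, c5nr, s_save, mortality, dec_d, dec_r,
                       norms, config) {
  T_max <- if (config$horizon == "five_year") 5 else
    config$max_age - config$start_age + 1
  out <- list(hc = 0, ic = 0, qaly = 0, ly = 0, ly_disc = 0, rem = 0,
              rem_disc = 0)
  for (sx in c("F", "M")) {
    w <- if (sx == "F") config$fraction_women else 1 - config$fraction_women
    alive <- 1
    for (t in 1:T_max) {
      age <- config$start_age + t - 1
      disc <- 1 / (1 + config$discount_rate)^(t - 1)
      s_t <- if (t <= length(S)) S[t] else 0
      rem <- s_t * alive
      dia <- alive - rem
      nb <- norms[norms$sex == sx & norms$age_lower <= age &
                    norms$age_upper >= age, ]
      if (nrow(nb) == 0) nb <- norms[norms$sex == sx, ][
        which.max(norms$age_upper[norms$sex == sx]), ]
      u_r <- nb$norm_utility * (1 - dec_r)
      u_d <- nb$norm_utility * (1 - dec_d)
      if (t <= 5) {
        out$hc <- out$hc + w * hc5[t] * alive * disc
        out$ic <- out$ic + w * ic5[t] * alive * disc
      } else {
        out$hc <- out$hc + w * c5nr * (dia + (1 - s_save) * rem) * disc
      }
      out$qaly <- out$qaly + w * (rem * u_r + dia * u_d) * disc
      out$ly <- out$ly + w * alive
      out$ly_disc <- out$ly_disc + w * alive * disc
      out$rem <- out$rem + w * rem
      out$rem_disc <- out$rem_disc + w * rem * disc
      mrow <- mortality[mortality$age == age & mortality$sex == sx, ]
      alive <- alive - rem * mrow$q_nondiabetes - dia * mrow$q_diabetes
    }
  }
  out
}

# Compare a run_model() trace against the oracle for both arms.
expect_matches_oracle <- function(inputs, tol = 1e-10) {
  tr <- run_model(inputs)
  for (a in c("intervention", "control")) {
    S_full <- inputs$schedule[[a]]$S
    o <- oracle_arm(S_full, inputs$hc_annual[[a]], inputs$ic_annual[[a]],
                    inputs$c5nr, inputs$s_save, inputs$mortality,
                    inputs$utilities$dec_diabetes,
                    inputs$utilities$dec_remission,
                    inputs$utilities$norms, tr$config)
    t_a <- tr[[a]]
    d <- t_a$discount
    expect_equal(sum(t_a$hc_cost * d), o$hc, tolerance = tol)
    expect_equal(sum(t_a$ic_cost * d), o$ic, tolerance = tol)
    expect_equal(sum(t_a$qaly * d), o$qaly, tolerance = tol)
    expect_equal(sum(t_a$alive), o$ly, tolerance = tol)
    expect_equal(sum(t_a$remission), o$rem, tolerance = tol)
  }
}

# Empirical survivor function oracle (no censoring): fraction with event
# time strictly greater than t.
empirical_survivor <- function(times, t) mean(times > t)

# Minimal hand-built cohort for the costing tests. `costs` is a tibble with
# id, arm, year, in_remission, and one column per category.
make_cost_cohort <- function(costs, participants = NULL) {
  cats <- setdiff(names(costs), c("id", "arm", "year", "in_remission"))
  long <- tidyr::pivot_longer(costs, dplyr::all_of(cats),
                              names_to = "category", values_to = "cost")
  if (is.null(participants)) {
    participants <- dplyr::distinct(costs, id, arm)
    participants$sex <- "F"
    participants$age_at_entry <- 54
    participants$extension_participant <- FALSE
    participants$remission_12m <- FALSE
    participants$relapse_year <- NA_integer_
    participants$censor_year <- NA_integer_
  }
  structure(list(participants = participants,
                 remission_status = tibble::tibble(
                   id = character(), arm = character(), year = integer(),
                   status = character()),
                 annual_costs = long,
                 intervention_use = tibble::tibble(
                   id = character(), year = integer(), phase = character(),
                   sachets = numeric(), visits = numeric()),
                 eq5d = tibble::tibble(
                   id = character(), arm = character(), visit_year = integer(),
                   remission = logical(), utility = numeric()),
                 params = NULL), class = "remit_cohort")
}

# Printed per-annum healthcare cost summary used by several tests.
table2_means <- list(control = c(primary_care = 428, other = 44,
                                 secondary_care = 347, hospital = 690,
                                 medicines = 300),
                     intervention = c(primary_care = 357, other = 50,
                                      secondary_care = 288, hospital = 412,
                                      medicines = 222))
table2_sds <- list(control = c(330, 149, 535, 3136, 663),
                   intervention = c(294, 163, 487, 1792, 514))
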