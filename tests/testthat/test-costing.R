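# Unit costing and Kaplan-Meier sampling-average cost estimation.

test_that("hospitalisation costing applies excess bed-days beyond the trim point", {
  uc <- unit_costs()
  uc$hospital_episode_base["emergency"] <- 2000
  uc$trim_point["emergency"] <- 5
  uc$excess_bed_day <- 300
  expect_equal(cost_hospitalisation(3, "emergency", uc), 2000)
  expect_equal(cost_hospitalisation(5, "emergency", uc), 2000)  # boundary
  expect_equal(cost_hospitalisation(8, "emergency", uc), 2900)  # 2000 + 3*300
  expect_error(cost_hospitalisation(2, "maternity", uc), "elective")
  expect_error(cost_hospitalisation(-1, "emergency", uc))
})

test_that("packaged unit costs are non-negative 2020/21 GBP", {
  uc <- unit_costs()
  expect_identical(uc$price_year, "2020/21")
  expect_true(all(uc$contact_costs >= 0))
  expect_true(all(uc$hospital_episode_base >= 0))
  expect_gt(uc$sachet, 0)
})

test_that("intervention costing: control arm is always zero, set-up only in year 1", {
  co <- generate_cohort(generator_params(n_per_arm = 50, seed = 4))
  uc <- unit_costs()
  ic <- cost_intervention(co, uc)
  expect_true(all(ic$intervention_cost[ic$arm == "control"] == 0))
  # a participant-year with zero sachets and visits costs 0 (+ setup in y1)
  iu0 <- co$intervention_use
  pid <- iu0$id[iu0$year == 3][1]
  co$intervention_use$sachets[co$intervention_use$id == pid &
                                co$intervention_use$year == 3] <- 0
  co$intervention_use$visits[co$intervention_use$id == pid &
                               co$intervention_use$year == 3] <- 0
  ic2 <- cost_intervention(co, uc)
  expect_equal(ic2$intervention_cost[ic2$id == pid & ic2$year == 3], 0)
  y1 <- ic2$intervention_cost[ic2$id == pid & ic2$year == 1]
  expect_gte(y1, uc$setup_per_participant)
  # negative counts are rejected
  co$intervention_use$sachets[1] <- -2
  expect_error(cost_intervention(co, uc), "non-negative")
})

test_that("annual cost summary reproduces the printed totals from category means", {
  # two participant-years per arm, each exactly at the printed category means
  rows <- list()
  for (a in c("control", "intervention")) {
    for (i in 1:2) {
      rows[[paste(a, i)]] <- tibble::tibble(
        id = paste0(a, i), arm = a, year = i, in_remission = FALSE,
        !!!as.list(table2_means[[a]]))
    }
  }
  co <- make_cost_cohort(dplyr::bind_rows(rows))
  smry <- summarize_annual_costs(co)
  tot <- smry[smry$category == "total", ]
  expect_equal(tot$mean_cost[tot$arm == "control"], 1809)
  expect_equal(tot$mean_cost[tot$arm == "intervention"], 1329)
  expect_equal(tot$mean_cost[tot$arm == "control"] -
                 tot$mean_cost[tot$arm == "intervention"], 480)
  # total row equals the category sum exactly
  for (a in c("control", "intervention")) {
    cats <- smry[smry$arm == a & smry$category != "total", ]
    expect_identical(tot$mean_cost[tot$arm == a], sum(cats$mean_cost))
  }
})

test_that("single participant-year summary flags an undefined SD", {
  co <- make_cost_cohort(tibble::tibble(
    id = "x", arm = "control", year = 1, in_remission = FALSE,
    primary_care = 100, hospital = 50))
  smry <- summarize_annual_costs(co)
  expect_equal(smry$mean_cost[smry$category == "total"], 150)
  expect_true(all(is.na(smry$sd_cost)))
})

test_that("KM sampling average equals the plain mean without censoring", {
  co <- make_cost_cohort(tibble::tibble(
    id = c("a", "b", "c"), arm = "control", year = 2, in_remission = FALSE,
    hospital = c(100, 200, 300)))
  est <- km_sampling_average(co, "control", 2)
  expect_equal(est$total_mean, 200)
  expect_equal(est$n_observed, 3)
  expect_error(km_sampling_average(co, "control", 3), "year 3")
})

test_that("KM sampling average uses only participants under observation", {
  # high-cost participants censored after year 2: year-3 estimate covers the
  # remaining observed subset only
  costs <- dplyr::bind_rows(
    tidyr::expand_grid(id = c("rich1", "rich2"), year = 1:2) |>
      dplyr::mutate(arm = "control", in_remission = FALSE, hospital = 5000),
    tidyr::expand_grid(id = c("mod1", "mod2", "mod3"), year = 1:5) |>
      dplyr::mutate(arm = "control", in_remission = FALSE,
                    hospital = c(700, 800, 900, 950, 1000)[
                      match(id, c("mod1", "mod2", "mod3"))]))
  co <- make_cost_cohort(costs)
  est3 <- km_sampling_average(co, "control", 3)
  expect_equal(est3$total_mean, mean(c(700, 800, 900)))  # brute force subset
  expect_equal(est3$n_observed, 3)
  est1 <- km_sampling_average(co, "control", 1)
  expect_equal(est1$total_mean, mean(c(5000, 5000, 700, 800, 900)))
})

test_that("per-category estimates always sum to the total", {
  co <- generate_cohort(generator_params(n_per_arm = 80, seed = 6))
  for (y in c(1, 4)) {
    est <- km_sampling_average(co, "intervention", y)
    cats <- est[, remitce:::.remitce$cost_categories]
    expect_equal(est$total_mean, sum(cats), tolerance = 1e-12)
  }
  # all costed outputs non-negative
  expect_true(all(co$annual_costs$cost >= 0))
})

test_that("remission cost-saving fraction follows the years 2-5 ratio average", {
  mk <- function(ratios) {
    rows <- lapply(2:5, function(y) {
      tibble::tibble(id = c(paste0("nr", y), paste0("r", y)),
                     arm = "intervention", year = y,
                     in_remission = c(FALSE, TRUE),
                     hospital = c(1000, 1000 * ratios[y - 1]))
    })
    make_cost_cohort(dplyr::bind_rows(rows))
  }
  expect_equal(remission_cost_saving_fraction(mk(c(1, 1, 1, 1))), 0)
  expect_equal(remission_cost_saving_fraction(mk(c(0.5, 0.5, 0.5, 0.5))), 0.5)
  expect_equal(remission_cost_saving_fraction(mk(c(0.8, 0.6, 0.7, 0.9))),
               0.25)  # 1 - mean(ratios)
  # clipped to [0, 1]
  expect_equal(remission_cost_saving_fraction(mk(c(2, 2, 2, 2))), 0)
})
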