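# Synthetic cohort generator: reproducibility, calibration, invariants, I/O.

test_that("identical seed and parameters give identical cohorts", {
  p <- generator_params(n_per_arm = 40, seed = 7)
  expect_identical(generate_cohort(p), generate_cohort(p))
  p2 <- generator_params(n_per_arm = 40, seed = 8)
  expect_false(identical(generate_cohort(p), generate_cohort(p2)))
})

test_that("zero 12-month remission probability forces no remitters", {
  p <- generator_params(n_per_arm = 30, seed = 1,
                        remission_12m_prob = c(intervention = 0,
                                               control = 0))
  co <- generate_cohort(p)
  expect_false(any(co$participants$remission_12m))
  expect_equal(nrow(co$remission_status), 0)
  expect_false(any(co$annual_costs$in_remission))
})

test_that("remission is monotone: relapse is absorbing in every record", {
  co <- generate_cohort(generator_params(n_per_arm = 120, seed = 3,
                                         assessment_missing_prob = 0))
  # truth columns
  p <- co$participants
  expect_true(all(is.na(p$relapse_year) | p$relapse_year > 1))
  # observed statuses: no in_remission after a relapsed record
  bad <- co$remission_status |>
    dplyr::filter(status != "missing") |>
    dplyr::group_by(id) |>
    dplyr::arrange(year, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(status == "relapsed") >= 0))
  expect_true(all(bad$ok))
  # cost records agree with the truth
  ac <- dplyr::distinct(co$annual_costs, id, year, in_remission)
  chk <- dplyr::left_join(ac, p[, c("id", "remission_12m", "relapse_year")],
                          by = "id")
  expect_true(all(!chk$in_remission | chk$remission_12m))
})

test_that("large-sample means converge to the configured values", {
  co <- generate_cohort(generator_params(n_per_arm = 4000, seed = 42))
  # annual cost means per arm-year (year 3) within 2 SE of the marginal mean
  for (a in c("control", "intervention")) {
    y3 <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(co$annual_costs, arm == a, year == 3),
                      id), cost = sum(cost), .groups = "drop")
    se <- sd(y3$cost) / sqrt(nrow(y3))
    expect_lt(abs(mean(y3$cost) - remitce:::hc_cost_means(a)[3]), 2 * se)
  }
  # year-1 sachets within 3 SE of the configured phase-mean total (509.7)
  s1 <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(co$intervention_use, year == 1), id),
    sachets = sum(sachets), .groups = "drop")
  target <- sum(default_intervention_use()$sachets_mean[
    default_intervention_use()$year == 1])
  expect_lt(abs(mean(s1$sachets) - target),
            3 * sd(s1$sachets) / sqrt(nrow(s1)))
  # baseline (visit 0) utility mean near the configured baseline
  base <- co$eq5d$utility[co$eq5d$visit_year == 0]
  expect_lt(abs(mean(base) - co$params$utility_baseline_mean),
            3 * sd(base) / sqrt(length(base)))
})

test_that("a cost model set to the printed per-annum summary reproduces the printed total mean", {
  cm <- dplyr::bind_rows(lapply(c("control", "intervention"), function(a) {
    tidyr::expand_grid(arm = a, year = 1:5, remission = c(FALSE, TRUE)) |>
      dplyr::cross_join(tibble::tibble(
        category = names(table2_means[[a]]),
        mean = unname(table2_means[[a]]),
        sd = table2_sds[[a]]))
  }))
  p <- generator_params(n_per_arm = 10000, seed = 9,
                        remission_12m_prob = c(intervention = 0.46,
                                               control = 0.05),
                        annual_dropout_hazard = 0, cost_frailty_cv = 0,
                        cost_model = cm)
  co <- generate_cohort(p)
  tot <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(co$annual_costs, arm == "intervention"),
                    id, year), cost = sum(cost), .groups = "drop")
  expect_lt(abs(mean(tot$cost) - 1329) / 1329, 0.01)
})

test_that("invalid generator parameters raise errors naming the field", {
  expect_error(generator_params(n_per_arm = 1), "n_per_arm")
  expect_error(generator_params(fraction_women = 1.2), "fraction_women")
  expect_error(generator_params(annual_dropout_hazard = -0.1),
               "annual_dropout_hazard")
  expect_error(generator_params(utility_noise_sd = -1), "utility_noise_sd")
  cm <- default_cost_model()
  cm$mean[1] <- -5
  expect_error(generator_params(cost_model = cm), "cost_model")
})

test_that("EQ-5D utilities stay in the 3L UK index range and remission raises them", {
  co <- generate_cohort(generator_params(n_per_arm = 500, seed = 5))
  expect_true(all(co$eq5d$utility >= -0.594 & co$eq5d$utility <= 1))
  m <- tapply(co$eq5d$utility, co$eq5d$remission, mean)
  expect_gt(m[["TRUE"]], m[["FALSE"]])
  # visits beyond year 2 only for intervention extension participants
  late <- dplyr::filter(co$eq5d, visit_year > 2)
  p <- co$participants
  ext_ids <- p$id[p$extension_participant]
  expect_true(all(late$id %in% ext_ids))
  expect_true(all(late$arm == "intervention"))
})

test_that("cohorts round-trip through delimited files exactly", {
  co <- generate_cohort(generator_params(n_per_arm = 25, seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (nm in c("participants", "remission_status", "annual_costs",
               "intervention_use", "eq5d")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(co[[nm]]),
                 tolerance = 1e-12)
  }
  expect_equal(back$params$seed, co$params$seed)
  expect_equal(back$params$cost_model, co$params$cost_model)
  expect_equal(back$params$remission_12m_prob, co$params$remission_12m_prob)
})

test_that("censored years are absent from the written files, not zero-filled", {
  co <- generate_cohort(generator_params(n_per_arm = 200, seed = 21,
                                         annual_dropout_hazard = 0.2))
  p <- co$participants
  cens3 <- p$id[!is.na(p$censor_year) & p$censor_year == 3][1]
  expect_false(is.na(cens3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ac <- readr::read_csv(file.path(dir, "annual_costs.csv"),
                        show_col_types = FALSE)
  rows <- ac[ac$id == cens3, ]
  expect_setequal(unique(rows$year), 1:3)
  # and the participants file carries the explicit censor year
  pp <- readr::read_csv(file.path(dir, "participants.csv"),
                        show_col_types = FALSE)
  expect_equal(pp$censor_year[pp$id == cens3], 3)
})

test_that("an empty cohort writes header-only files and reads back empty", {
  co <- generate_cohort(generator_params(n_per_arm = 5, seed = 2))
  for (nm in c("participants", "remission_status", "annual_costs",
               "intervention_use", "eq5d")) {
    co[[nm]] <- co[[nm]][0, ]
  }
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  first_line <- readLines(file.path(dir, "participants.csv"))
  expect_length(first_line, 1)  # header only
  back <- read_cohort(dir)
  expect_equal(nrow(back$participants), 0)
  expect_equal(nrow(back$eq5d), 0)
})
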