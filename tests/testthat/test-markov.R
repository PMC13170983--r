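# Markov cohort engine: discounting, occupancy, oracle equality, summaries.

test_that("discount factors follow the first-year-undiscounted convention", {
  expect_equal(discount_factor(1), 1)
  expect_equal(discount_factor(2), 1 / 1.035)
  expect_equal(discount_factor(1:4, rate = 0), rep(1, 4))
  expect_equal(discount_factor(2, year_one_discounted = TRUE), 1 / 1.035^2)
  expect_error(discount_factor(0))
})

test_that("occupancies are conserved and death is absorbing", {
  withr::with_seed(11, {
    for (i in 1:8) {
      S <- sort(runif(5, 0, 0.6), decreasing = TRUE)
      inp <- make_inputs(
        S_int = S,
        hc_c = runif(5, 0, 3000), hc_i = runif(5, 0, 3000),
        mortality = const_mortality(runif(1, 0.01, 0.08),
                                    runif(1, 0.001, 0.01)),
        dec_d = runif(1, 0, 0.3), dec_r = runif(1, 0, 0.2))
      tr <- run_model(inp)
      for (a in c("intervention", "control")) {
        t_a <- tr[[a]]
        expect_true(all(abs(t_a$alive + t_a$dead - 1) < 1e-12))
        expect_true(all(abs(t_a$remission + t_a$diabetes - t_a$alive) < 1e-12))
        expect_true(all(diff(t_a$dead) >= -1e-12))
        expect_true(all(t_a$alive >= -1e-12))
      }
    }
  })
})

test_that("with zero mortality and no discounting, remission-years equal the schedule sum", {
  S <- c(0.46, 0.36, 0.29, 0.21, 0.097)
  inp <- make_inputs(S_int = S, S_ctrl = rep(0, 5),
                     mortality = const_mortality(0, 0),
                     config = model_config(discount_rate = 0))
  ce <- summarize_ce(run_model(inp))
  tab <- ce$table
  ry5 <- tab$intervention[tab$metric == "remission_years" &
                            tab$horizon == "five_year"]
  expect_equal(ry5, sum(S), tolerance = 1e-12)      # 1.417
  ry_full <- tab$intervention[tab$metric == "remission_years" &
                                tab$horizon == "full"]
  ext <- extrapolate_schedule(remission_schedule(S))
  expect_equal(ry_full, sum(ext$S), tolerance = 1e-12)
})

test_that("the engine matches an independent brute-force per-cycle oracle", {
  withr::with_seed(23, {
    for (i in 1:6) {
      inp <- make_inputs(
        S_int = sort(runif(5, 0, 0.7), decreasing = TRUE),
        S_ctrl = sort(runif(5, 0, 0.1), decreasing = TRUE),
        hc_c = runif(5, 500, 3000), hc_i = runif(5, 500, 3000),
        ic_i = runif(5, 0, 1500), c5nr = runif(1, 500, 3000),
        s_save = runif(1), mortality = const_mortality(runif(1, 0.01, 0.1),
                                                       runif(1, 0.005, 0.05)),
        dec_d = runif(1, 0, 0.3), dec_r = runif(1, 0, 0.2),
        config = model_config(max_age = sample(60:110, 1)))
      expect_matches_oracle(inp)
    }
    # and with the packaged base case (age-varying mortality and norms)
    expect_matches_oracle(base_case_inputs())
  })
})

test_that("equal state mortality and utilities make outcomes symmetric", {
  inp <- make_inputs(S_int = c(0.5, 0.4, 0.3, 0.2, 0.1),
                     S_ctrl = rep(0, 5),
                     mortality = const_mortality(0.02, 0.02),
                     dec_d = 0.1, dec_r = 0.1)
  ce <- summarize_ce(run_model(inp))
  tab <- ce$table
  expect_equal(tab$incremental[tab$metric == "life_years" &
                                 tab$horizon == "full"], 0, tolerance = 1e-12)
  expect_equal(ce$delta_qaly, 0, tolerance = 1e-12)
  # QALY difference appears as soon as remission carries a utility benefit
  inp2 <- make_inputs(S_int = c(0.5, 0.4, 0.3, 0.2, 0.1), S_ctrl = rep(0, 5),
                      mortality = const_mortality(0.02, 0.02),
                      dec_d = 0.1, dec_r = 0.05)
  expect_gt(summarize_ce(run_model(inp2))$delta_qaly, 0)
})

test_that("an all-dead entering cohort accumulates nothing", {
  inp <- make_inputs(S_int = c(0.4, 0.3, 0.2, 0.1, 0.05))
  tr0 <- remitce:::run_arm(inp$schedule$intervention,
                           inp$hc_annual$intervention,
                           inp$ic_annual$intervention, inp$c5nr, inp$s_save,
                           inp$mortality, inp$utilities, inp$config,
                           initial_alive = 0)
  expect_true(all(tr0$alive == 0))
  expect_equal(sum(tr0$hc_cost) + sum(tr0$ic_cost) + sum(tr0$qaly), 0)
})

test_that("raising the discount rate weakly lowers every discounted total", {
  rates <- c(0, 0.015, 0.035, 0.06)
  vals <- lapply(rates, function(r) {
    inp <- base_case_inputs(model_config(discount_rate = r))
    ce <- summarize_ce(run_model(inp))
    tab <- ce$table
    c(hc = tab$intervention[tab$metric == "hc_cost" & tab$horizon == "full"],
      qaly = tab$intervention[tab$metric == "qaly" & tab$horizon == "full"],
      ly = tab$intervention[tab$metric == "life_years_disc" &
                              tab$horizon == "full"])
  })
  for (k in seq_len(length(rates) - 1)) {
    expect_true(all(vals[[k + 1]] <= vals[[k]] + 1e-9))
  }
})

test_that("a five-year schedule cannot drive a lifetime run", {
  inp <- make_inputs(S_int = c(0.4, 0.3, 0.2, 0.1, 0.05))
  inp$schedule$intervention <- remission_schedule(c(0.4, 0.3, 0.2, 0.1, 0.05))
  expect_error(run_model(inp), "shorter than")
  expect_silent(run_model(inp, horizon = "five_year"))
})

test_that("summaries report incrementals, dominance and net monetary benefit", {
  res <- list(delta_cost = -496, delta_qaly = 0.08)
  expect_equal(net_monetary_benefit(res, 20000), 2096)
  expect_equal(net_monetary_benefit(res, 0), 496)
  expect_equal(net_monetary_benefit(list(delta_cost = 0, delta_qaly = 0),
                                    20000), 0)
  expect_error(net_monetary_benefit(res, -5))
  # identical arms: all incrementals exactly zero, ICER undefined
  inp <- make_inputs(S_int = c(0.3, 0.2, 0.1, 0.05, 0.02))
  inp$schedule$control <- inp$schedule$intervention
  inp$hc_annual$control <- inp$hc_annual$intervention
  inp$ic_annual$control <- inp$ic_annual$intervention
  ce <- summarize_ce(run_model(inp))
  expect_true(all(ce$table$incremental == 0))
  expect_true(is.infinite(ce$icer) || is.na(ce$icer))
  expect_match(ce$icer_label, "zero incremental QALYs|dominant")
})

test_that("mortality tables respect the remission advantage and age coverage", {
  mt <- default_mortality()
  expect_true(all(mt$q_nondiabetes <= mt$q_diabetes))
  expect_true(all(mt$q_diabetes <= 1 & mt$q_nondiabetes >= 0))
  expect_setequal(unique(mt$sex), c("F", "M"))
  expect_equal(range(mt$age), c(54, 110))
  # engine refuses a table that stops short of the horizon
  inp <- base_case_inputs()
  inp$mortality <- mt[mt$age <= 80, ]
  expect_error(run_model(inp), "cover ages")
})
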