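# Remission history classification, Kaplan-Meier estimation, extrapolation.

status_tbl <- function(...) {
  recs <- list(...)
  dplyr::bind_rows(lapply(recs, function(r) {
    tibble::tibble(id = r[[1]], arm = "intervention",
                   year = as.integer(r[[2]]), status = r[[3]])
  }))
}

test_that("history classification applies the annual-record censoring rules", {
  # recorded relapse at year 3
  h <- classify_history(status_tbl(list("a", 2, "in_remission"),
                                   list("a", 3, "relapsed")))
  expect_equal(h$time, 3); expect_equal(h$event, 1L)
  # missing year deemed reversed because the next record shows reversal
  h <- classify_history(status_tbl(list("b", 2, "missing"),
                                   list("b", 3, "relapsed")))
  expect_equal(h$time, 2); expect_equal(h$event, 1L)
  # censored at the first year with no further record
  h <- classify_history(status_tbl(list("c", 2, "in_remission")))
  expect_equal(h$time, 3); expect_equal(h$event, 0L)
  expect_false(h$observed)
  # a gap bridged by a later remission record is treated as maintained
  h <- classify_history(status_tbl(list("d", 2, "missing"),
                                   list("d", 3, "in_remission")))
  expect_equal(h$time, 4); expect_equal(h$event, 0L)
  # complete follow-up in remission: censored at the final assessment
  h <- classify_history(status_tbl(list("e", 2, "in_remission"),
                                   list("e", 3, "in_remission"),
                                   list("e", 4, "in_remission"),
                                   list("e", 5, "in_remission")))
  expect_equal(h$time, 5); expect_true(h$observed)
})

test_that("remission recorded after relapse is ignored with a warning", {
  tbl <- status_tbl(list("a", 2, "relapsed"), list("a", 3, "in_remission"))
  expect_warning(h <- classify_history(tbl), "ignored")
  expect_equal(h$time, 2); expect_equal(h$event, 1L)
})

test_that("product-limit estimates match hand computations", {
  # 10 remitters, 2 relapse in year 2, no censoring: maintenance 0.8
  hist1 <- tibble::tibble(id = as.character(1:10),
                          time = c(rep(2, 2), rep(5, 8)),
                          event = c(1L, 1L, rep(0L, 8)),
                          observed = TRUE)
  s <- km_remission(hist1, p12 = 0.46)
  expect_equal(s$S[2] / s$S[1], 0.8)
  expect_equal(s$S[1], 0.46)
  # 1 censored before year 2, 2 of the remaining 9 relapse: 7/9
  hist2 <- tibble::tibble(id = as.character(1:10),
                          time = c(2, rep(2, 2), rep(5, 7)),
                          event = c(0L, 1L, 1L, rep(0L, 7)),
                          observed = c(FALSE, rep(TRUE, 9)))
  s2 <- km_remission(hist2, p12 = 1)
  expect_equal(s2$S[2], 7 / 9, tolerance = 1e-12)
  # no remitters: schedule identically zero
  s0 <- km_remission(hist1[0, ], p12 = 0)
  expect_true(all(s0$S == 0))
})

test_that("without censoring the KM estimate equals the empirical survivor function", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(10:60, 1)
      times <- sample(2:5, n, replace = TRUE)
      event <- rep(1L, n)
      # those reaching 5 without relapse are administratively censored
      keep <- runif(n) < 0.7
      event[!keep & times == 5] <- 0L
      h <- tibble::tibble(id = as.character(seq_len(n)), time = times,
                          event = event, observed = TRUE)
      s <- km_remission(h, p12 = 1)
      for (y in 2:5) {
        emp <- mean(times > y | (times == y & event == 0))
        expect_equal(s$S[y], emp, tolerance = 1e-12)
      }
    }
  })
})

test_that("extrapolation declines at the years 1-5 rate and stops at the cap", {
  s <- remission_schedule(c(0.46, 0.36, 0.29, 0.21, 0.097))
  e <- extrapolate_schedule(s, cap_years = 10, horizon = 12)
  r <- (0.097 / 0.46)^(1 / 4)
  expect_equal(e$extrapolation_rate, r)
  expect_equal(e$S[6], 0.097 * r, tolerance = 1e-12)
  expect_equal(e$S[10], 0.097 * r^5, tolerance = 1e-12)
  expect_equal(e$S[11], 0)
  expect_equal(e$S[12], 0)
  expect_true(all(diff(e$S) <= 1e-12))  # non-increasing
  # no decline: constant to the cap, then zero
  flat <- extrapolate_schedule(remission_schedule(rep(0.3, 5)))
  expect_equal(flat$extrapolation_rate, 1)
  expect_equal(flat$S[6:10], rep(0.3, 5))
  expect_equal(flat$S[11], 0)
  # already absorbed: unchanged (zero-padded)
  gone <- extrapolate_schedule(remission_schedule(c(0.4, 0.2, 0.1, 0.05, 0)))
  expect_true(all(gone$S[6:11] == 0))
})

test_that("KM on a large synthetic arm recovers the generator retention", {
  co <- generate_cohort(generator_params(n_per_arm = 3000, seed = 27))
  p <- co$participants
  p12 <- mean(p$remission_12m[p$arm == "intervention"])
  h <- classify_history(
    co$remission_status[co$remission_status$arm == "intervention", ],
    ids = p$id[p$arm == "intervention" & p$remission_12m])
  s <- km_remission(h, p12)
  truth <- 0.46 * remitce:::.remitce$maintenance
  for (y in 1:5) {
    se <- sqrt(truth[y] * (1 - truth[y]) / 3000)
    expect_lt(abs(s$S[y] - truth[y]), 3 * se + 0.002)
  }
})

test_that("schedule validation rejects non-monotone or out-of-range values", {
  expect_error(remission_schedule(c(0.3, 0.4)), "non-increasing")
  expect_error(remission_schedule(c(1.2, 0.5)), "\\[0, 1\\]")
})
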