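# Remission maintenance: history classification, Kaplan-Meier estimation and
# capped extrapolation.

#' Remission schedule constructor
#'
#' Arm-level proportion of the entering cohort in remission at each annual
#' cycle. `S[1]` is the 12-month remission proportion; the schedule must be
#' non-increasing and within `[0, 1]`.
#'
#' @param S Numeric vector of per-cycle remission proportions (year 1 first).
#' @param extrapolation_rate Optional annual retention used beyond the
#'   observed years (filled in by [extrapolate_schedule()]).
#' @param cap_years Remission is assumed extinct beyond this year.
#' @return A list of class `remission_schedule`.
#' @export
remission_schedule <- function(S, extrapolation_rate = NA_real_,
                               cap_years = 10L) {
  stopifnot(is.numeric(S), length(S) >= 1)
  if (any(S < -1e-12 | S > 1 + 1e-12)) stop("schedule values must lie in [0, 1]")
  if (any(diff(S) > 1e-12)) stop("remission schedule must be non-increasing")
  structure(list(S = pmin(pmax(S, 0), 1),
                 extrapolation_rate = extrapolation_rate,
                 cap_years = as.integer(cap_years)),
            class = "remission_schedule")
}

#' Classify annual remission records into event/censoring times
#'
#' Applies the trial's censoring rules to annual remission status records for
#' participants in remission at 12 months. Statuses are taken at annual
#' visits from year 2; relapse is absorbing. For years with no recorded
#' status, remission is deemed reversed at that year if the next available
#' record shows it reversed; otherwise the participant is censored at the
#' first year with no further records. Recorded remission after a recorded
#' relapse triggers a warning and is ignored.
#'
#' @param status_records Tibble with columns `id`, `year` (2-5) and `status`
#'   in `c("in_remission", "relapsed", "missing")`; years absent from the
#'   table are treated as missing with no later record.
#' @param ids Optional vector of 12-month remitter ids to classify (defaults
#'   to every id present in `status_records`).
#' @param last_year Final annual assessment (default 5).
#' @return Tibble `id`, `time` (years from entry), `event` (1 = relapse,
#'   0 = censored) and `observed` (`FALSE` when the censoring year itself had
#'   no recorded status, i.e. the participant was last seen the year before;
#'   [km_remission()] uses this to place such censorings just before the
#'   unrecorded visit).
#' @export
classify_history <- function(status_records, ids = NULL, last_year = 5L) {
  stopifnot(all(c("id", "year", "status") %in% names(status_records)))
  if (is.null(ids)) ids <- unique(status_records$id)
  years <- 2:last_year
  k <- length(years)
  # status code matrix: 0 missing, 1 in remission, 2 relapsed
  st <- matrix(0L, nrow = length(ids), ncol = k,
               dimnames = list(ids, years))
  rec <- status_records[status_records$id %in% ids &
                          status_records$year %in% years, ]
  st[cbind(match(rec$id, ids), match(rec$year, years))] <-
    c(missing = 0L, in_remission = 1L, relapsed = 2L)[rec$status]
  time <- integer(length(ids)); event <- integer(length(ids))
  observed <- rep(TRUE, length(ids))
  for (r in seq_along(ids)) {
    s <- st[r, ]
    first_rel <- which(s == 2L)[1]
    if (!is.na(first_rel)) {
      late_rem <- which(s == 1L)
      if (any(late_rem > first_rel)) {
        warning("id ", ids[r], ": remission recorded after relapse; ignored",
                call. = FALSE)
        s[late_rem[late_rem > first_rel]] <- 0L
      }
      # deemed reversed at the start of the unrecorded run preceding the
      # first recorded relapse
      j <- first_rel
      while (j > 1 && s[j - 1] == 0L) j <- j - 1
      time[r] <- years[j]; event[r] <- 1L
    } else {
      # censored at the first year from which no further record exists
      miss_tail <- k + 1
      while (miss_tail > 1 && s[miss_tail - 1] == 0L) miss_tail <- miss_tail - 1
      if (miss_tail <= k) {
        time[r] <- years[miss_tail]; event[r] <- 0L; observed[r] <- FALSE
      } else {
        time[r] <- as.integer(last_year); event[r] <- 0L
      }
    }
  }
  tibble::tibble(id = ids, time = time, event = event, observed = observed)
}

#' Kaplan-Meier remission schedule for one arm
#'
#' Product-limit estimate of maintenance of remission among 12-month
#' remitters (relapses at an annual visit are processed before censorings at
#' the same visit), scaled by the arm's 12-month remission proportion to give
#' the arm-level proportion in remission at years 1-5.
#'
#' @param histories Output of [classify_history()] for the arm's remitters.
#' @param p12 The arm's 12-month remission proportion.
#' @param last_year Final annual assessment (default 5).
#' @return A [remission_schedule()] over years 1..`last_year`. With no
#'   remitters (`p12 = 0` or empty `histories`) the schedule is identically 0.
#' @export
km_remission <- function(histories, p12, last_year = 5L) {
  stopifnot(p12 >= 0, p12 <= 1)
  if (p12 == 0 || nrow(histories) == 0) {
    return(remission_schedule(rep(0, last_year)))
  }
  # censorings at an unrecorded visit leave the risk set just after the last
  # visit actually observed; recorded censorings tie-break after events
  tt <- histories$time
  if ("observed" %in% names(histories)) {
    tt <- tt - 0.5 * (histories$event == 0 & !histories$observed)
  }
  fit <- survival::survfit(survival::Surv(tt, histories$event) ~ 1)
  maint <- vapply(2:last_year, function(y) {
    s <- summary(fit, times = y, extend = TRUE)$surv
    if (length(s) == 0) 1 else s
  }, 0)
  remission_schedule(p12 * c(1, maint))
}

#' Extrapolate a remission schedule to the cap
#'
#' Beyond the last observed year, the proportion in remission continues to
#' decline at the average annual rate observed between years 1 and 5:
#' `r = (S[5]/S[1])^(1/4)`, so `S[t] = S[5] * r^(t-5)` for `5 < t <= cap`,
#' and `S[t] = 0` beyond the cap. A schedule already at 0 by year 5 is
#' returned unchanged (padded with zeros).
#'
#' @param schedule A [remission_schedule()] over years 1-5.
#' @param cap_years Remission extinct beyond this year (default 10).
#' @param horizon Length of the returned schedule (default `cap_years + 1`;
#'   longer horizons are zero-filled).
#' @return A [remission_schedule()] of length `max(horizon, cap_years + 1)`.
#' @export
extrapolate_schedule <- function(schedule, cap_years = 10L, horizon = NULL) {
  S <- schedule$S
  stopifnot(length(S) >= 5)
  if (is.null(horizon)) horizon <- cap_years + 1L
  horizon <- max(horizon, cap_years + 1L)
  out <- numeric(horizon)
  out[1:5] <- S[1:5]
  if (S[5] > 0 && S[1] > 0) {
    r <- (S[5] / S[1])^(1 / 4)
    t_ext <- 6:min(cap_years, horizon)
    out[t_ext] <- S[5] * r^(t_ext - 5)
  } else {
    r <- NA_real_
  }
  out[seq_len(horizon) > cap_years] <- 0
  remission_schedule(out, extrapolation_rate = r, cap_years = cap_years)
}
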