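# Unit costing of resource use and Kaplan-Meier sampling-average estimation
# of mean annual healthcare cost under right-censoring.

#' Packaged unit-cost table
#'
#' Reads the editable unit-cost table (2020/21 GBP) shipped in
#' `inst/extdata/unit_costs.csv` into a structured list. The table carries
#' intervention unit prices (set-up, sachet, practitioner time), per-contact
#' costs, hospital episode base costs, excess bed-day price and trim points.
#'
#' @param path Optional path to an alternative unit-cost table.
#' @return A list with elements `setup_per_participant`, `sachet`,
#'   `practitioner_minute`, `visit_default_minutes`, `contact_costs`,
#'   `hospital_episode_base`, `excess_bed_day`, `trim_point`, `price_year`
#'   and the raw `table`.
#' @export
unit_costs <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.remitce$uc_cache)) return(.remitce$uc_cache)
    path <- system.file("extdata", "unit_costs.csv",
                        package = "remitce", mustWork = TRUE)
    .remitce$uc_cache <- unit_costs(path)
    return(.remitce$uc_cache)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(value = readr::col_character()))
  get1 <- function(it, numeric = TRUE) {
    v <- tab$value[tab$item == it]
    if (length(v) != 1) stop("unit-cost table is missing item '", it, "'")
    if (numeric) as.numeric(v) else v
  }
  pick <- function(prefix) {
    rows <- tab[startsWith(tab$item, prefix), ]
    setNames(as.numeric(rows$value), sub(prefix, "", rows$item))
  }
  uc <- list(
    setup_per_participant = get1("setup_per_participant"),
    sachet = get1("sachet"),
    practitioner_minute = get1("practitioner_minute"),
    visit_default_minutes = get1("visit_default_minutes"),
    contact_costs = pick("contact_"),
    hospital_episode_base = pick("hospital_episode_"),
    excess_bed_day = get1("excess_bed_day"),
    trim_point = pick("trim_point_"),
    price_year = get1("price_year", numeric = FALSE),
    table = tab
  )
  costs <- c(uc$setup_per_participant, uc$sachet, uc$practitioner_minute,
             uc$contact_costs, uc$hospital_episode_base, uc$excess_bed_day)
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("unit costs must be finite and non-negative")
  }
  uc
}

#' Cost of one hospitalisation episode
#'
#' Base episode cost for the admission category plus excess bed-days beyond
#' the national trim point.
#'
#' @param length_of_stay Length of stay in days (>= 0).
#' @param category Admission category; must match a packaged episode category.
#' @param uc A [unit_costs()] list.
#' @return Episode cost in GBP.
#' @examples
#' cost_hospitalisation(8, "emergency")
#' @export
cost_hospitalisation <- function(length_of_stay, category, uc = unit_costs()) {
  stopifnot(is.numeric(length_of_stay), all(length_of_stay >= 0))
  known <- names(uc$hospital_episode_base)
  if (!category %in% known) {
    stop("unknown admission category '", category, "'; known categories: ",
         paste(known, collapse = ", "))
  }
  base <- uc$hospital_episode_base[[category]]
  trim <- uc$trim_point[[category]]
  base + pmax(0, length_of_stay - trim) * uc$excess_bed_day
}

#' Intervention cost per participant-year
#'
#' Costs the programme resource use of one or more participants: a flat
#' set-up share in year 1, sachets of low-energy formula diet at the packaged
#' sachet price, and practitioner appointment time at the packaged per-minute
#' cost (appointments are costed at `visit_default_minutes` unless the
#' records carry a `minutes` column). Control-arm participants always cost 0.
#'
#' @param cohort A `remit_cohort` (see [generate_cohort()]).
#' @param uc A [unit_costs()] list.
#' @return Tibble `id`, `arm`, `year`, `intervention_cost`, covering every
#'   observed participant-year.
#' @export
cost_intervention <- function(cohort, uc = unit_costs()) {
  if (any(cohort$intervention_use$sachets < 0) ||
      any(cohort$intervention_use$visits < 0)) {
    stop("sachet and visit counts must be non-negative")
  }
  use <- dplyr::summarise(
    dplyr::group_by(cohort$intervention_use, id, year),
    sachets = sum(sachets), visits = sum(visits), .groups = "drop")
  if (any(use$sachets < 0) || any(use$visits < 0)) {
    stop("sachet and visit counts must be non-negative")
  }
  per_visit <- uc$practitioner_minute * uc$visit_default_minutes
  use$intervention_cost <- uc$sachet * use$sachets + per_visit * use$visits +
    ifelse(use$year == 1, uc$setup_per_participant, 0)
  grid <- observed_years(cohort)
  out <- dplyr::left_join(grid, use[, c("id", "year", "intervention_cost")],
                          by = c("id", "year"))
  out$intervention_cost[out$arm == "control"] <- 0
  # intervention participant-years with no resource rows cost 0 (+ setup y1)
  miss <- is.na(out$intervention_cost)
  out$intervention_cost[miss] <-
    ifelse(out$year[miss] == 1 & out$arm[miss] == "intervention",
           uc$setup_per_participant, 0)
  out
}

# Observed participant-years: years 1..censor_year (censor NA = all 5).
observed_years <- function(cohort) {
  p <- cohort$participants
  last <- ifelse(is.na(p$censor_year), 5L, as.integer(p$censor_year))
  tibble::tibble(
    id = rep(p$id, last),
    arm = rep(p$arm, last),
    year = unlist(lapply(last, seq_len), use.names = FALSE)
  )
}

#' Annual healthcare cost summary by arm and category
#'
#' Means and SDs over observed participant-years, per arm and cost category,
#' with a total row per arm equal to the sum of the category rows.
#'
#' @param cohort A `remit_cohort`.
#' @return Tibble `arm`, `category`, `mean_cost`, `sd_cost`, `n_obs`; the
#'   `total` category row has `mean_cost` equal to the category sum and the SD
#'   of participant-year totals.
#' @export
summarize_annual_costs <- function(cohort) {
  ac <- cohort$annual_costs
  if (nrow(ac) == 0) stop("no observed participant-years")
  arms <- unique(cohort$participants$arm)
  if (any(!arms %in% ac$arm)) stop("empty arm in annual cost records")
  by_cat <- dplyr::summarise(
    dplyr::group_by(ac, arm, category),
    mean_cost = mean(cost),
    sd_cost = if (dplyr::n() > 1) sd(cost) else NA_real_,
    n_obs = dplyr::n(), .groups = "drop")
  totals <- dplyr::summarise(
    dplyr::group_by(ac, arm, id, year), cost = sum(cost), .groups = "drop")
  by_tot <- dplyr::summarise(
    dplyr::group_by(totals, arm),
    mean_cost = mean(cost),
    sd_cost = if (dplyr::n() > 1) sd(cost) else NA_real_,
    n_obs = dplyr::n(), .groups = "drop")
  by_tot$category <- "total"
  # force exact additivity of the printed means
  cat_sum <- tapply(by_cat$mean_cost, by_cat$arm, sum)
  by_tot$mean_cost <- as.numeric(cat_sum[by_tot$arm])
  dplyr::arrange(dplyr::bind_rows(by_cat, by_tot), arm)
}

#' Kaplan-Meier sampling-average annual cost
#'
#' Mean annual healthcare cost among participants under observation in a
#' given arm and follow-up year. Under the sampling-average method these
#' means are taken as representative of the modelled surviving cohort, so
#' downstream they multiply the modelled proportion alive.
#'
#' @param cohort A `remit_cohort`.
#' @param arm `"intervention"` or `"control"`.
#' @param year Follow-up year 1-5.
#' @param by_remission If `TRUE`, split the estimate by remission status in
#'   that year.
#' @return Tibble with `arm`, `year`, per-category means, `total_mean` and
#'   `n_observed` (one row, or one per remission status).
#' @export
km_sampling_average <- function(cohort, arm, year, by_remission = FALSE) {
  stopifnot(year %in% 1:5)
  ac <- cohort$annual_costs
  ac <- ac[ac$arm == arm & ac$year == year, ]
  if (nrow(ac) == 0) {
    stop("no observed costs for arm '", arm, "', year ", year)
  }
  key <- if (by_remission) c("arm", "year", "in_remission") else c("arm", "year")
  wide <- tidyr::pivot_wider(ac, names_from = category, values_from = cost)
  cats <- setdiff(names(wide), c("id", "arm", "year", "in_remission"))
  out <- dplyr::summarise(
    dplyr::group_by(wide, dplyr::across(dplyr::all_of(key))),
    dplyr::across(dplyr::all_of(cats), mean),
    n_observed = dplyr::n(), .groups = "drop")
  out$total_mean <- rowSums(out[, cats])
  out
}

# Convenience: vector of KM sampling-average total means for years 1..5.
km_cost_vector <- function(cohort, arm) {
  vapply(1:5, function(y) km_sampling_average(cohort, arm, y)$total_mean, 0)
}

#' Proportional cost-saving during remission
#'
#' The average, over follow-up years 2-5, of one minus the ratio of mean
#' annual cost in remission to mean annual cost not in remission (arms
#' pooled), clipped to `[0, 1]`. Used to discount the beyond-year-5 cost
#' input while modelled cohort members remain in remission.
#'
#' @param cohort A `remit_cohort`.
#' @param years Follow-up years entering the average (default 2:5).
#' @return A single proportion.
#' @export
remission_cost_saving_fraction <- function(cohort, years = 2:5) {
  ac <- cohort$annual_costs[cohort$annual_costs$year %in% years, ]
  totals <- dplyr::summarise(
    dplyr::group_by(ac, id, year, in_remission), cost = sum(cost),
    .groups = "drop")
  ratios <- vapply(years, function(y) {
    ty <- totals[totals$year == y, ]
    m_nr <- mean(ty$cost[!ty$in_remission])
    m_r <- mean(ty$cost[ty$in_remission])
    if (!is.finite(m_nr) || m_nr == 0) {
      stop("non-remission mean cost unavailable or zero in year ", y)
    }
    if (!is.finite(m_r)) NA_real_ else m_r / m_nr
  }, 0)
  if (all(is.na(ratios))) stop("no remission participant-years in years 2-5")
  min(max(1 - mean(ratios, na.rm = TRUE), 0), 1)
}
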