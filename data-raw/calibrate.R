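# Calibration of packaged constants (run during development; results frozen
# into R/defaults.R and inst/extdata/unit_costs.csv).
#
# Targets (printed base case):
#   control undiscounted life expectancy            23.48
#   lifetime incremental QALYs (discounted)          0.080
#   control 5y discounted healthcare cost          7928
#   control lifetime discounted healthcare cost   28476
#   intervention 5y discounted healthcare cost     5837
#   intervention 5y discounted intervention cost   1691
#   lifetime incremental total cost                -496
#   control 5y discounted QALYs                     3.37  (level anchor)
suppressMessages(devtools::load_all(".")  # run from the package root)

cfg <- model_config()
env <- remitce:::.remitce

ctrl_trace <- function() run_arm_ctrl()
run_arm_raw <- function(arm) {
  inp <- base_case_inputs(cfg)
  remitce:::run_arm(inp$schedule[[arm]], inp$hc_annual[[arm]],
                    inp$ic_annual[[arm]], inp$c5nr, inp$s_save,
                    inp$mortality, inp$utilities, cfg)
}
metrics <- function() {
  ce <- summarize_ce(run_model(base_case_inputs(cfg)))
  tab <- ce$table
  g <- function(m, h, col = "incremental") tab[[col]][tab$metric == m & tab$horizon == h]
  list(le_ctrl = g("life_years", "full", "control"),
       dq_life = g("qaly", "full"),
       dq_5y = g("qaly", "five_year"),
       dly = g("life_years", "full"),
       q5_ctrl = g("qaly", "five_year", "control"),
       hc5_ctrl = g("hc_cost", "five_year", "control"),
       hc5_int = g("hc_cost", "five_year", "intervention"),
       hcL_ctrl = g("hc_cost", "full", "control"),
       hcL_int = g("hc_cost", "full", "intervention"),
       ic5_int = g("ic_cost", "five_year", "intervention"),
       dcost_life = g("total_cost", "full"),
       dcost_5y = g("total_cost", "five_year"))
}

# --- step 1: mortality (a, hr) and diabetes decrement ----------------------
solve_dec <- function() {
  f <- function(d) {
    env$dec_diabetes <- d
    metrics()$q5_ctrl - 3.37
  }
  env$dec_diabetes <- uniroot(f, c(0.0, 0.5), tol = 1e-12)$root
}
solve_a <- function() {
  f <- function(a) {
    env$gompertz_a <- a
    metrics()$le_ctrl - 23.48
  }
  env$gompertz_a <- uniroot(f, c(5e-4, 0.02), tol = 1e-14)$root
}
solve_hr <- function() {
  f <- function(hr) {
    env$hr_diabetes <- hr
    solve_a(); solve_dec()
    metrics()$dq_life - 0.080
  }
  env$hr_diabetes <- uniroot(f, c(1.05, 4), tol = 1e-10)$root
  solve_a(); solve_dec()
}
solve_hr()
cat(sprintf("gompertz_a   = %.15g\nhr_diabetes  = %.15g\ndec_diabetes = %.15g\n",
            env$gompertz_a, env$hr_diabetes, env$dec_diabetes))

# --- step 2: intervention unit sachet price for IC total 1691 --------------
uc0 <- unit_costs()
tr_int <- run_arm_raw("intervention")
d <- tr_int$discount; a_int <- tr_int$alive
pv <- uc0$practitioner_minute * uc0$visit_default_minutes
base_part <- sum(d[1:5] * a_int[1:5] *
                   (c(uc0$setup_per_participant, 0, 0, 0, 0) +
                      pv * env$visits_year))
sach_part <- sum(d[1:5] * a_int[1:5] * env$sachets_year)
sachet_price <- (1691 - base_part) / sach_part
cat(sprintf("sachet_price = %.15g\n", sachet_price))
# patch the unit-cost table in place so base_case_inputs() picks it up
uc_path <- file.path("inst/extdata/unit_costs.csv")
tab <- readr::read_csv(uc_path, show_col_types = FALSE,
                       col_types = readr::cols(value = readr::col_character()))
tab$value[tab$item == "sachet"] <- sprintf("%.15g", sachet_price)
readr::write_csv(tab, uc_path)

# --- step 3: healthcare cost ramp and remission saving fraction ------------
solve_costs <- function(s) {
  env$s_save <- s
  # control equations linear in (c0, slope)
  probe <- function(c0, slope) {
    env$hc_cost_c0 <- c0; env$hc_cost_slope <- slope
    m <- metrics(); c(m$hc5_ctrl, m$hcL_ctrl)
  }
  base <- probe(0, 0)
  e1 <- probe(1, 0) - base
  e2 <- probe(0, 1) - base
  sol <- solve(cbind(e1, e2), c(7928, 28476) - base)
  env$hc_cost_c0 <- sol[1]; env$hc_cost_slope <- sol[2]
  # intervention scale linear
  env$hc_int_scale <- 1
  m1 <- metrics()$hc5_int
  env$hc_int_scale <- 5837 / m1
  invisible(sol)
}
f_s <- function(s) {
  solve_costs(s)
  metrics()$dcost_life - (-496)
}
s_root <- uniroot(f_s, c(0.01, 0.99), tol = 1e-12)$root
solve_costs(s_root)
cat(sprintf("hc_cost_c0   = %.15g\nhc_cost_slope= %.15g\nhc_int_scale = %.15g\ns_save       = %.15g\n",
            env$hc_cost_c0, env$hc_cost_slope, env$hc_int_scale, env$s_save))
cat(sprintf("baseline utility mean = %.15g\n",
            0.85 * (1 - env$dec_diabetes)))

# --- verification -----------------------------------------------------------
m <- metrics()
cat("\nverification:\n")
for (nm in names(m)) cat(sprintf("  %-12s %12.4f\n", nm, m[[nm]]))
cat(sprintf("\n  hc means ctrl: %s\n  hc means int : %s\n  c5nr: %.2f\n",
            paste(sprintf('%.1f', hc_cost_means('control')), collapse = ', '),
            paste(sprintf('%.1f', hc_cost_means('intervention')), collapse = ', '),
            base_case_inputs(cfg)$c5nr))
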