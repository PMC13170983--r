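#!/usr/bin/env Rscript
# Stage 6: probabilistic sensitivity analysis. 1000 iterations of the
# arm-stratified bootstrap with Monte-Carlo utility and mortality draws on
# the simulated cohort, plus a parametric run centred on the generator truth
# (the calibration view; see the methods vignette). Emits the draws, the
# cost-effectiveness acceptability curve and its figure.
suppressPackageStartupMessages(library(remitce))

cfg <- read_config("results/config.yaml")
cohort <- read_cohort("results/cohort")
n_iter <- cfg$psa$n_iter

psa <- run_psa(cohort, n_iter = n_iter, seed = cfg$seed + 1L)
print(psa)
readr::write_csv(psa$draws, "results/psa_draws_bootstrap.csv")
readr::write_csv(psa$ceac, "results/ceac_bootstrap.csv")

psa_par <- run_psa(cohort, n_iter = n_iter, seed = cfg$seed + 2L,
                   resample = "parametric")
message("parametric (calibration) run:")
print(psa_par)
readr::write_csv(psa_par$draws, "results/psa_draws_parametric.csv")
readr::write_csv(psa_par$ceac, "results/ceac_parametric.csv")

ggplot2::ggsave("results/ceac.png", plot_ceac(psa), width = 6, height = 4,
                dpi = 150)
message("CEAC figure written to results/ceac.png")
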