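#!/usr/bin/env Rscript
# Simulation study: how often does estimating the parameters of a simple
# linear Gaussian state-space model corrupt the state estimates?
#
# 200 series are simulated at each process SD sigma_eta in
# (0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1), with n = 100, rho = 0.7,
# sigma_eps = 0.1 and known x0 = 0. Each series is fitted twice - all three
# parameters free, and with sigma_eps fixed at its generating value - and
# the smoothed-state RMSE is computed under the estimated and under the
# true parameters.
#
# Writes: results/study_replicates.csv, results/study_summary.csv,
#         results/study_headline.json

suppressPackageStartupMessages(library(ssmcheck))

dir.create("results", showWarnings = FALSE)
cfg <- study_config(base_seed = 20010L, fit_fixed_eps = TRUE)

message("running the 7 x 200 replicate grid (about a minute) ...")
study <- run_study(cfg)

utils::write.csv(study$replicates, "results/study_replicates.csv",
                 row.names = FALSE)

headline <- list(
  pct_exceeding_free = proportion_exceeding(study, 1.5, "free"),
  pct_exceeding_fixed_eps = proportion_exceeding(study, 1.5, "fixed_eps"),
  n_replicates = nrow(study$replicates),
  by_scenario_free = proportion_exceeding(study, 1.5, "free",
                                          by_scenario = TRUE),
  by_scenario_fixed = proportion_exceeding(study, 1.5, "fixed_eps",
                                           by_scenario = TRUE))
jsonlite::write_json(headline, "results/study_headline.json",
                     auto_unbox = TRUE, digits = NA, dataframe = "columns")

sm <- summarize_study(study, "free")
utils::write.csv(sm, "results/study_summary.csv", row.names = FALSE)

message(sprintf(
  "Free fit: %.1f%% of replicates had a state RMSE at least 1.5x the RMSE\nobtained with the true parameters; fixing sigma_eps at truth reduces this\nto %.1f%%.",
  headline$pct_exceeding_free, headline$pct_exceeding_fixed_eps))
message("Per-scenario breakdown (free fit):")
bs <- headline$by_scenario_free
for (i in seq_len(nrow(bs)))
  message(sprintf("  sigma_eta = %-5g  %5.1f%%  (error/process ratio %g)",
                  bs$sigma_eta[i], bs$percent[i], 0.1 / bs$sigma_eta[i]))
message("Estimate distributions (see study_summary.csv): at low sigma_eta the")
message("sigma_eps and rho estimates are bimodal with a mode near zero.")
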