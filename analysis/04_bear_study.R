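#!/usr/bin/env Rscript
# Synthetic movement study: 15 bear-like 2-D displacement series (342 days)
# with voluntary AR(1) movement, additive ice drift, drift observations
# with Gaussian error, and missing days. Each bear is fitted individually
# (drift-corrected univariate model per coordinate), then all bears are
# refitted with a single shared ice measurement-error term.
#
# Writes: results/bear_fits.csv, results/bear_pooled.json

suppressPackageStartupMessages(library(ssmcheck))
dir.create("results", showWarnings = FALSE)

cfg <- bear_sim_config(seed = 20100L)
message(sprintf(
  "simulating %d bears x %d days (rho = %g, sigma_q = %g, sigma_h = %g km/day)",
  cfg$n_bears, cfg$n_days, cfg$rho_u, cfg$sigma_q_u, cfg$sigma_h_u))

tab <- run_bear_study(cfg)
utils::write.csv(tab, "results/bear_fits.csv", row.names = FALSE)

b <- tab$boundary_any
message(sprintf("%d of %d bears have a boundary sigma_h estimate", sum(b),
                nrow(tab)))
message(sprintf("total voluntary displacement d over 342 days: %.0f-%.0f km",
                min(tab$d_hat), max(tab$d_hat)))
if (any(b))
  message(sprintf("boundary bears: d = %s km (study median %.0f km)",
                  paste(round(tab$d_hat[b]), collapse = ", "),
                  stats::median(tab$d_hat)))

# the distortion is an aggregate tendency; measure it over repeated studies
message("repeating the study 8 times to measure the boundary-vs-d association:")
upper <- c(); db <- c(); dn <- c()
for (r in 1:8) {
  rt <- run_bear_study(bear_sim_config(seed = 20100L + 1000L * r))
  rb <- rt$boundary_any
  if (any(rb)) {
    upper <- c(upper, all(rt$d_hat[rb] >= stats::median(rt$d_hat)))
    db <- c(db, rt$d_hat[rb]); dn <- c(dn, rt$d_hat[!rb])
  }
}
message(sprintf(
  "  boundary bears all in the upper half of d in %d of %d studies with\n  boundary estimates; mean d %.0f km (boundary) vs %.0f km (interior) -\n  collapsed error estimates inflate the energy-expenditure proxy",
  sum(upper), length(upper), mean(db), mean(dn)))

# structural remedy: one shared measurement-error term across bears
bears <- simulate_bear_paths(cfg)
pooled <- fit_pooled(bears)
jsonlite::write_json(
  list(sigma_h_u = pooled$u$sigma_h, sigma_h_v = pooled$v$sigma_h,
       loglik_u = pooled$u$loglik, loglik_v = pooled$v$loglik,
       per_bear_u = pooled$u$per_bear, per_bear_v = pooled$v$per_bear),
  "results/bear_pooled.json", auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
message(sprintf(
  "pooled fit: shared sigma_h = (%.2f, %.2f) km/day vs generating value %g",
  pooled$u$sigma_h, pooled$v$sigma_h, cfg$sigma_h_u))
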