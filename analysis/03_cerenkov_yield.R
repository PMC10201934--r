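#!/usr/bin/env Rscript
# Number of emitted Cerenkov photons per photoelectric interaction.
#
# Three conditions: (i) 511 keV with fine stepping (delta-beta = 0.04%),
# where the per-step Frank-Tamm expectation tracks the true velocity
# profile; (ii) 511 keV with unlimited (range-based) stepping in the
# toolkit-faithful pre-step yield mode, which biases the count down because
# a single long step is priced at the pre-step velocity and photons placed
# beyond the local threshold are discarded; (iii) 1,000 keV fine stepping.

library(cerstep)
dir.create("results", showWarnings = FALSE)

bgo <- make_bgo()
tab <- build_loss_tables(bgo)
n_events <- 1000

conditions <- list(
  list(tag = "511keV_db0.04pct", gamma = 0.511, db = 4e-4, mode = "interp"),
  list(tag = "511keV_unlimited", gamma = 0.511, db = NA, mode = "pre"),
  list(tag = "1000keV_db0.02pct", gamma = 1.000, db = 2e-4, mode = "interp")
)

rows <- lapply(seq_along(conditions), function(i) {
  cc <- conditions[[i]]
  set.seed(5300 + i)
  r <- run_events(bgo, cc$gamma, cc$db,
    n_events = n_events, tables = tab,
    beta_mode = cc$mode, trace = FALSE
  )
  s <- summarize_run(r)
  data.frame(
    condition = cc$tag,
    mean_step_um = s$mean_step_um,
    fit_mean = s$cerenkov_fit_mean,
    fit_sigma = s$cerenkov_fit_sigma,
    sample_mean = s$cerenkov_sample_mean
  )
})
yield <- do.call(rbind, rows)
write.csv(yield, "results/cerenkov_yield.csv", row.names = FALSE)
print(yield, digits = 4)

cat(sprintf(
  "\nFine stepping at 511 keV emits %.1f photons/interaction (Gaussian fit);\n",
  yield$fit_mean[1]
))
cat(sprintf(
  "range-based stepping under pre-step yields drops this to %.1f (-%.0f%%),\n",
  yield$fit_mean[2], 100 * (1 - yield$fit_mean[2] / yield$fit_mean[1])
))
cat("the characteristic coarse-step emission bias of stepwise codes.\n")
cat(sprintf(
  "At 1,000 keV fine stepping gives %.1f photons/interaction.\n",
  yield$fit_mean[3]
))
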