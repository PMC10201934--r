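#!/usr/bin/env Rscript
# Directionality of the primary electron and the i-th emitted Cerenkov
# photon, as a function of the electron mean step length.
#
# With range-based steps the first photons are all emitted during the long
# first step and keep the forward direction; with ~0.2 um steps multiple
# scattering randomizes the electron within tens of microns and the later
# photons lose directionality, which shows up as a growing backward
# (180 deg) fraction with emission order.

library(cerstep)
dir.create("results", showWarnings = FALSE)

bgo <- make_bgo()
tab <- build_loss_tables(bgo)
n_events <- 1000

set.seed(6401)
fine <- run_events(bgo, 0.511, 4e-4, n_events = n_events, tables = tab, trace = FALSE)
set.seed(6402)
coarse <- run_events(bgo, 0.511, NA,
  n_events = n_events, tables = tab,
  beta_mode = "pre", trace = FALSE
)

runs <- list(fine = fine, coarse = coarse)

# primary electron emission angles (always forward-peaked)
for (nm in names(runs)) {
  dirs <- runs[[nm]]$tracks[, c("dir_x", "dir_y", "dir_z")]
  ang <- xz_angle(dirs)
  cat(sprintf(
    "%s run: %.0f%% of primary electrons within +/-45 deg of the gamma axis\n",
    nm, 100 * mean(pmin(ang, 360 - ang) <= 45, na.rm = TRUE)
  ))
}

# order-resolved angular histograms of the 1st and 5th Cerenkov photon
hist_rows <- list()
for (nm in names(runs)) {
  for (o in c(1, 5)) {
    h <- order_resolved_angles(runs[[nm]]$photons, o)
    hist_rows[[paste(nm, o)]] <- data.frame(
      run = nm, order = o, angle_deg = h$mids, density = h$density
    )
    flat <- min(h$counts) / max(h$counts)
    cat(sprintf(
      "%s run, photon %d: peak bin at %.0f deg, min/max ratio %.2f\n",
      nm, o, h$mids[which.max(h$counts)], flat
    ))
  }
}
write.csv(do.call(rbind, hist_rows), "results/angular_distributions.csv",
  row.names = FALSE
)

# backward fraction vs emission order
bf <- do.call(rbind, lapply(names(runs), function(nm) {
  data.frame(
    run = nm, order = 1:11,
    backward_fraction = vapply(
      1:11, function(o) backward_fraction(runs[[nm]]$photons, o), numeric(1)
    )
  )
}))
write.csv(bf, "results/backward_fractions.csv", row.names = FALSE)
print(bf, digits = 3)
cat("\nFine stepping: the backward fraction grows with emission order;\n")
cat("range-based stepping keeps all eleven first photons forward.\n")
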