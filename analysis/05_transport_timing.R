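#!/usr/bin/env Rscript
# Cerenkov photon transport and detection timing in the front-coupled
# 3 x 3 x 20 mm crystal.
#
# Forward-emitted photons need at least one pass to the wrapped back face
# before reaching the photodetector at the entrance face (> 20 mm paths);
# photons emitted backward reach it directly on millimetre paths. The mix,
# and hence the detection-time distribution, is set by the electron step
# parameterization upstream.

library(cerstep)
dir.create("results", showWarnings = FALSE)

bgo <- make_bgo()
tab <- build_loss_tables(bgo)
geom <- crystal_geometry()
n_events <- 1000

set.seed(7501)
fine <- run_events(bgo, 0.511, 4e-4, n_events = n_events, geom = geom, tables = tab)
set.seed(7502)
coarse <- run_events(bgo, 0.511, NA,
  n_events = n_events, geom = geom,
  tables = tab, beta_mode = "pre"
)

rows <- list()
hrows <- list()
for (nm in c("fine", "coarse")) {
  run <- if (nm == "fine") fine else coarse
  ph <- run$photons
  det <- detection_histograms(ph)
  frac20 <- mean(ph$path_length[ph$status == "detected"] > 20)
  frac10 <- mean(ph$path_length[ph$status == "detected"] < 10)
  rows[[nm]] <- data.frame(
    run = nm,
    emitted = nrow(ph),
    detected = det$n_detected,
    detected_frac = det$n_detected / nrow(ph),
    mean_path_mm = det$mean_path_mm,
    frac_path_gt20mm = frac20,
    frac_path_lt10mm = frac10,
    mean_transit_ns = det$mean_transit_ns
  )
  hrows[[paste(nm, "path")]] <- data.frame(
    run = nm, hist = "path_mm", mid = det$path$mids, count = det$path$counts
  )
  hrows[[paste(nm, "transit")]] <- data.frame(
    run = nm, hist = "transit_ns", mid = det$transit$mids,
    count = det$transit$counts
  )
}
summary_df <- do.call(rbind, rows)
write.csv(summary_df, "results/transport_timing.csv", row.names = FALSE)
write.csv(do.call(rbind, hrows), "results/transport_histograms.csv",
  row.names = FALSE
)
print(summary_df, digits = 3)

cat(sprintf(
  "\nRange-based stepping: %.0f%% of detected photons travelled > 20 mm,\n",
  100 * summary_df$frac_path_gt20mm[summary_df$run == "coarse"]
))
cat(sprintf(
  "mean transit %.2f ns. Fine stepping raises the short-path (< 10 mm)\n",
  summary_df$mean_transit_ns[summary_df$run == "coarse"]
))
cat(sprintf(
  "fraction to %.0f%% and lowers the mean transit to %.2f ns; the direct\n",
  100 * summary_df$frac_path_lt10mm[summary_df$run == "fine"],
  summary_df$mean_transit_ns[summary_df$run == "fine"]
))
cat("backward component alone arrives in ~0.05-0.07 ns.\n")
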