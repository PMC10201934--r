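# End-to-end experiment driver: delta-beta sweeps from a run configuration,
# with per-run summaries and data files.

.default_delta_beta <- function() {
  c(
    seq(1e-4, 5e-4, by = 1e-4), 0.001, 0.005, 0.01, 0.05,
    seq(0.1, 0.9, by = 0.1), NA # NA = unlimited (default stepping)
  )
}

#' Build a run configuration
#'
#' Collects every knob of a simulation campaign with its default. The
#' default delta-beta sweep covers 0.01-0.05% in 0.01% increments, 0.1, 0.5,
#' 1 and 5%, 10-90% in 10% increments, and the unlimited default stepping
#' (encoded as `NA`).
#'
#' @param material material name (`"BGO"` or `"TlBr"`) or a `cer_material`
#' @param gamma_mev monoenergetic gamma energy, MeV
#' @param n_events photoelectric events per delta-beta value
#' @param delta_beta numeric vector of per-step velocity-change limits
#'   (fractions in (0, 1]; `NA` means unlimited)
#' @param geometry list of [crystal_geometry()] arguments
#' @param seed master seed; run i of the sweep uses `seed + i`
#' @param out_dir output directory for [run_experiment()]
#' @param scintillation also generate (decimated) scintillation photons
#' @param beta_mode per-step emission velocity mode, see [emit_cherenkov()]
#' @param speed_mode optical propagation speed from the `"group"` (default)
#'   or `"phase"` index
#' @param mass_atten_cm2_g photoelectric mass attenuation coefficient of the
#'   gamma, cm^2/g
#' @param source_distance_mm source to crystal entrance distance
#' @return list of class `cer_config`
#' @export
run_config <- function(material = "BGO", gamma_mev = 0.511, n_events = 1000,
                       delta_beta = .default_delta_beta(),
                       geometry = list(), seed = 1, out_dir = "cerstep-out",
                       scintillation = FALSE,
                       beta_mode = c("interp", "pre"),
                       speed_mode = c("group", "phase"),
                       mass_atten_cm2_g = 0.056,
                       source_distance_mm = 10) {
  beta_mode <- match.arg(beta_mode)
  speed_mode <- match.arg(speed_mode)
  if (n_events < 1) stop("n_events must be >= 1")
  db <- delta_beta
  if (any(!is.na(db) & (db <= 0 | db > 1))) {
    stop("delta_beta values must be in (0, 1] or NA for unlimited")
  }
  structure(
    list(
      material = material, gamma_mev = gamma_mev, n_events = n_events,
      delta_beta = delta_beta, geometry = geometry, seed = seed,
      out_dir = out_dir, scintillation = scintillation,
      beta_mode = beta_mode, speed_mode = speed_mode,
      mass_atten_cm2_g = mass_atten_cm2_g,
      source_distance_mm = source_distance_mm
    ),
    class = "cer_config"
  )
}

#' Load / save a run configuration
#'
#' Configurations are plain YAML or JSON mappings of [run_config()]
#' arguments; missing keys take the documented defaults, unknown keys are
#' rejected by name. `"unlimited"` is accepted in `delta_beta` lists and
#' mapped to `NA`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @param config a `cer_config`
#' @return `load_config()` returns a `cer_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(doc)) doc <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(doc), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(doc$delta_beta)) {
    db <- doc$delta_beta
    db <- vapply(db, function(v) {
      if (is.character(v) && v == "unlimited") NA_real_ else as.numeric(v)
    }, numeric(1), USE.NAMES = FALSE)
    doc$delta_beta <- unname(db)
  }
  if (!is.null(doc$geometry)) doc$geometry <- as.list(doc$geometry)
  do.call(run_config, doc)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  doc <- unclass(config)
  doc$delta_beta <- ifelse(is.na(doc$delta_beta), "unlimited",
    as.character(doc$delta_beta)
  )
  if (grepl("\\.ya?ml$", path)) {
    writeLines(yaml::as.yaml(doc), path)
  } else {
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

.resolve_material <- function(material) {
  if (inherits(material, "cer_material")) return(material)
  switch(toupper(material),
    BGO = make_bgo(),
    TLBR = make_tlbr(),
    stop("unknown material: ", material)
  )
}

#' Simulate one batch of photoelectric events at a fixed delta-beta
#'
#' The core simulation loop: for each event a gamma interaction depth is
#' drawn, the photoelectron generated, tracked step by step, Cerenkov (and
#' optionally scintillation) photons emitted along its steps and ray-traced
#' to the photodetector.
#'
#' @param mat a `cer_material` (or name)
#' @param gamma_mev gamma energy, MeV
#' @param delta_beta velocity-change limit per step (fraction), or `NA` /
#'   `NULL` for unlimited
#' @param n_events number of photoelectric events
#' @param geom a `cer_geometry`
#' @param tables optional precomputed `cer_loss_tables`
#' @param beta_mode,speed_mode,scintillation see [run_config()]
#' @param mass_atten_cm2_g,source_distance_mm see [run_config()]
#' @param trace ray-trace the photons (disable for emission-only studies)
#' @return list with `tracks` (per-track summary data frame), `photons`
#'   (all emitted photons with event ids; traced columns appended when
#'   `trace = TRUE`), and the settings used
#' @export
run_events <- function(mat, gamma_mev = 0.511, delta_beta = NA,
                       n_events = 1000, geom = crystal_geometry(),
                       tables = NULL, beta_mode = "interp",
                       speed_mode = "group", scintillation = FALSE,
                       mass_atten_cm2_g = 0.056, source_distance_mm = 10,
                       trace = TRUE) {
  mat <- .resolve_material(mat)
  if (is.null(tables)) tables <- build_loss_tables(mat)
  db <- if (is.null(delta_beta) || is.na(delta_beta)) NULL else delta_beta
  mu <- photoelectric_mu(mat, mass_atten_cm2_g)

  tsum <- vector("list", n_events)
  phot <- vector("list", n_events)
  for (ev in seq_len(n_events)) {
    depth <- sample_interaction_depth(1, mu, geom$length)
    e0 <- make_photoelectron(
      gamma_mev, mat,
      depth = depth, mu = mu,
      source_distance_mm = source_distance_mm,
      crystal_length_mm = geom$length
    )
    trk <- propagate_electron(e0, db, tables, mat)
    ts <- track_summary(trk)
    ts$event <- ev
    ts$shell <- attr(e0, "shell")
    ts$dir_x <- e0$direction[1]
    ts$dir_y <- e0$direction[2]
    ts$dir_z <- e0$direction[3]
    tsum[[ev]] <- ts
    ph <- emit_cherenkov(trk, mat$dispersion, beta_mode = beta_mode)
    if (scintillation) {
      ps <- emit_scintillation(trk, mat$dispersion)
      ph <- rbind(ph, ps)
    }
    if (nrow(ph) > 0) ph$event <- ev
    phot[[ev]] <- ph
  }
  tracks <- do.call(rbind, tsum)
  photons <- do.call(rbind, phot[vapply(phot, nrow, 1L) > 0])
  if (is.null(photons)) {
    photons <- data.frame(
      x = numeric(0), y = numeric(0), z = numeric(0), time = numeric(0),
      energy = numeric(0), dir_x = numeric(0), dir_y = numeric(0),
      dir_z = numeric(0), step = integer(0), kind = character(0),
      order = integer(0), event = integer(0)
    )
  }
  if (trace && nrow(photons) > 0) {
    # electron escape through a face is not modeled: the rare emission
    # points that fall just outside (range << crystal size) are folded
    # back onto the boundary before tracing
    photons$x <- pmin(pmax(photons$x, -geom$hx), geom$hx)
    photons$y <- pmin(pmax(photons$y, -geom$hy), geom$hy)
    photons$z <- pmin(pmax(photons$z, 0), geom$length)
    photons <- trace_photons(photons, geom, mat$dispersion, speed = speed_mode)
  }
  list(
    tracks = tracks, photons = photons,
    material = mat$name, gamma_mev = gamma_mev,
    delta_beta = if (is.null(db)) NA_real_ else db,
    n_events = n_events, beta_mode = beta_mode, speed_mode = speed_mode
  )
}

#' Summarize one simulated run
#'
#' Computes the statistics reported per delta-beta value: two-level
#' step-length averages, the Gaussian-fit per-event Cerenkov count,
#' order-resolved angular distributions and backward fractions, and
#' detection histograms.
#'
#' @param run result of [run_events()]
#' @param orders emission orders for the angular distributions
#' @param bins angular bins over 360 degrees
#' @return list of class `cer_run_summary`
#' @export
summarize_run <- function(run, orders = c(1, 5), bins = 36) {
  st <- track_stats(run$tracks)
  cer <- run$photons[run$photons$kind == "cerenkov", , drop = FALSE]
  counts <- integer(run$n_events)
  if (nrow(cer) > 0) {
    tab <- table(factor(cer$event, levels = seq_len(run$n_events)))
    counts <- as.integer(tab)
  }
  cs <- if (run$n_events >= 50) {
    cerenkov_count_stats(counts)
  } else {
    list(
      fit_mean = mean(counts), fit_sigma = stats::sd(counts),
      sample_mean = mean(counts), n_events = run$n_events
    )
  }
  ang <- lapply(orders, function(o) {
    tryCatch(order_resolved_angles(cer, o, bins), error = function(e) NULL)
  })
  names(ang) <- paste0("order_", orders)
  bf <- vapply(1:11, function(o) {
    tryCatch(backward_fraction(cer, o), error = function(e) NA_real_)
  }, numeric(1))
  det <- NULL
  if (!is.null(cer$status) && any(cer$status == "detected")) {
    det <- detection_histograms(cer)
  }
  structure(
    list(
      material = run$material, gamma_mev = run$gamma_mev,
      delta_beta = run$delta_beta, n_events = run$n_events,
      mean_step_um = st$mean_step_mm * 1000,
      mean_track_um = st$mean_track_mm * 1000,
      mean_steps_per_track = st$mean_steps_per_track,
      cerenkov_fit_mean = cs$fit_mean,
      cerenkov_fit_sigma = cs$fit_sigma,
      cerenkov_sample_mean = cs$sample_mean,
      angular = ang,
      backward_fraction = bf,
      detection = det
    ),
    class = "cer_run_summary"
  )
}

#' @export
print.cer_run_summary <- function(x, ...) {
  db <- if (is.na(x$delta_beta)) "unlimited" else sprintf("%.4g", x$delta_beta)
  cat(sprintf(
    "<cer_run_summary> %s %.3f MeV, delta-beta %s, %d events\n",
    x$material, x$gamma_mev, db, x$n_events
  ))
  cat(sprintf(
    "  mean step %.4g um | track %.4g um | %.2f steps/track\n",
    x$mean_step_um, x$mean_track_um, x$mean_steps_per_track
  ))
  cat(sprintf(
    "  Cerenkov count: fit %.2f (sigma %.2f), sample %.2f\n",
    x$cerenkov_fit_mean, x$cerenkov_fit_sigma, x$cerenkov_sample_mean
  ))
  if (!is.null(x$detection)) {
    cat(sprintf(
      "  detected %d photons, mean path %.2f mm, mean transit %.3f ns\n",
      x$detection$n_detected, x$detection$mean_path_mm,
      x$detection$mean_transit_ns
    ))
  }
  invisible(x)
}

#' Write per-run outputs to disk
#'
#' Writes the run summary as JSON and the track / photon / detected-photon
#' tables as CSV, tagged by the delta-beta value.
#'
#' @param summary a `cer_run_summary`
#' @param run the matching [run_events()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_outputs <- function(summary, run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- if (is.na(run$delta_beta)) "unlimited" else {
    sub("\\.", "p", sprintf("%g", run$delta_beta))
  }
  paths <- c(
    summary = file.path(dir, sprintf("summary_db_%s.json", tag)),
    tracks = file.path(dir, sprintf("tracks_db_%s.csv", tag)),
    photons = file.path(dir, sprintf("photons_db_%s.csv", tag))
  )
  jsonlite::write_json(
    unclass(summary), paths["summary"],
    digits = NA, auto_unbox = TRUE, na = "null", force = TRUE
  )
  utils::write.csv(run$tracks, paths["tracks"], row.names = FALSE)
  utils::write.csv(run$photons, paths["photons"], row.names = FALSE)
  invisible(paths)
}

#' Run a full delta-beta sweep experiment
#'
#' Reproduces the study design end to end: for each delta-beta value in the
#' configuration, simulates `n_events` photoelectric interactions, traces
#' all photons, summarizes, and (optionally) writes the per-run outputs plus
#' a sweep table of the headline quantities. Run i uses seed `seed + i`, so
#' the sweep is reproducible as a whole and per value.
#'
#' @param config a `cer_config` from [run_config()] / [load_config()]
#' @param write write output files under `config$out_dir`
#' @return list with `sweep` (data frame: delta_beta, mean step length,
#'   photon counts, timing) and `summaries` (list of `cer_run_summary`)
#' @export
run_experiment <- function(config, write = TRUE) {
  stopifnot(inherits(config, "cer_config"))
  mat <- .resolve_material(config$material)
  geom <- do.call(crystal_geometry, config$geometry)
  tables <- build_loss_tables(mat)
  n_runs <- length(config$delta_beta)
  summaries <- vector("list", n_runs)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(config$seed + i)
    run <- run_events(
      mat,
      gamma_mev = config$gamma_mev,
      delta_beta = config$delta_beta[i], n_events = config$n_events,
      geom = geom, tables = tables, beta_mode = config$beta_mode,
      speed_mode = config$speed_mode, scintillation = config$scintillation,
      mass_atten_cm2_g = config$mass_atten_cm2_g,
      source_distance_mm = config$source_distance_mm
    )
    s <- summarize_run(run)
    summaries[[i]] <- s
    rows[[i]] <- data.frame(
      delta_beta = config$delta_beta[i],
      mean_step_um = s$mean_step_um,
      mean_track_um = s$mean_track_um,
      mean_steps_per_track = s$mean_steps_per_track,
      cerenkov_fit_mean = s$cerenkov_fit_mean,
      cerenkov_fit_sigma = s$cerenkov_fit_sigma,
      mean_transit_ns = if (is.null(s$detection)) NA_real_ else s$detection$mean_transit_ns,
      mean_path_mm = if (is.null(s$detection)) NA_real_ else s$detection$mean_path_mm
    )
    if (write) write_outputs(s, run, config$out_dir)
  }
  sweep <- do.call(rbind, rows)
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      sweep, file.path(config$out_dir, "sweep.csv"),
      row.names = FALSE
    )
    save_config(config, file.path(config$out_dir, "config.json"))
  }
  list(sweep = sweep, summaries = summaries)
}
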