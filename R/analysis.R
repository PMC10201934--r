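# Run-level statistics: two-level step-length averages, Gaussian-fit photon
# counts, order-resolved angular distributions, backward fractions, and
# detection histograms.

#' Two-level electron step-length statistics
#'
#' The mean step length is the average over tracks of the within-track mean
#' step length, and the mean track length the average over tracks of the
#' summed step length — track-first averaging, not a pooled mean over all
#' steps (the two differ whenever tracks have unequal step counts).
#'
#' @param tracks either a list of `cer_track` objects or a per-track summary
#'   data frame (as produced by [run_events()], with columns `mean_step_mm`,
#'   `track_length_mm`, `n_steps`)
#' @return list with `mean_step_mm`, `mean_track_mm`, `mean_steps_per_track`
#' @export
#' @examples
#' # two tracks with steps {2} and {4, 4} um: track-first mean step is 3 um
track_stats <- function(tracks) {
  if (is.data.frame(tracks)) {
    if (nrow(tracks) == 0) stop("empty track list")
    per_mean <- tracks$mean_step_mm
    per_sum <- tracks$track_length_mm
    per_n <- tracks$n_steps
  } else {
    if (length(tracks) == 0) stop("empty track list")
    per_mean <- vapply(tracks, function(t) mean(t$length), numeric(1))
    per_sum <- vapply(tracks, function(t) sum(t$length), numeric(1))
    per_n <- vapply(tracks, nrow, numeric(1))
  }
  list(
    mean_step_mm = mean(per_mean),
    mean_track_mm = mean(per_sum),
    mean_steps_per_track = mean(per_n)
  )
}

#' Gaussian fit of the per-event Cerenkov count distribution
#'
#' Histograms the per-event emitted photon counts in unit bins and fits
#' `a exp(-(x - mu)^2 / (2 sigma^2))` by Levenberg-Marquardt least squares
#' with Poisson bin weights, returning the fitted mean (not the sample
#' mean). Degenerate inputs (all counts equal, or a fit that fails to
#' converge) fall back to the sample mean and standard deviation.
#'
#' @param event_counts integer vector of per-event photon counts
#' @return list with `fit_mean`, `fit_sigma`, `sample_mean`, `n_events`
#' @export
cerenkov_count_stats <- function(event_counts) {
  n <- length(event_counts)
  if (n < 50) stop("need at least 50 events for a stable fit")
  if (stats::sd(event_counts) == 0) {
    return(list(
      fit_mean = event_counts[1], fit_sigma = 0,
      sample_mean = event_counts[1], n_events = n
    ))
  }
  breaks <- seq(min(event_counts) - 0.5, max(event_counts) + 0.5, by = 1)
  h <- hist(event_counts, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  w <- 1 / pmax(df$y, 1) # Poisson weights
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
      data = df, weights = w,
      start = list(
        a = max(df$y), mu = mean(event_counts), s = max(stats::sd(event_counts), 0.5)
      ),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(
      fit_mean = mean(event_counts), fit_sigma = stats::sd(event_counts),
      sample_mean = mean(event_counts), n_events = n
    ))
  }
  cf <- stats::coef(fit)
  list(
    fit_mean = unname(cf["mu"]), fit_sigma = abs(unname(cf["s"])),
    sample_mean = mean(event_counts), n_events = n
  )
}

#' Polar angle of a momentum projected on the x-z plane
#'
#' Projects the momentum on the x-z plane and returns the angle with
#' respect to the gamma direction (+z), in degrees in `[0, 360)`; 180
#' degrees is backward. Vectors with a vanishing x-z projection are
#' undefined and return `NA`.
#'
#' @param momentum numeric 3-vector, or a matrix / data frame with columns
#'   x, y, z (one row per vector)
#' @return angle(s) in degrees
#' @export
#' @examples
#' xz_angle(c(0, 0, 1)) # 0 (forward)
#' xz_angle(c(1, 0, 1)) # 45
xz_angle <- function(momentum) {
  m <- if (is.null(dim(momentum))) {
    matrix(as.numeric(momentum), ncol = 3)
  } else {
    as.matrix(momentum)
  }
  ang <- atan2(m[, 1], m[, 3]) * 180 / pi
  ang <- ang %% 360
  ang[m[, 1]^2 + m[, 3]^2 < 1e-24] <- NA_real_
  ang
}

# per-event photons of a given emission order, as direction matrix
.order_dirs <- function(photons, order_index) {
  sel <- photons[photons$order == order_index, , drop = FALSE]
  as.matrix(sel[, c("dir_x", "dir_y", "dir_z")])
}

#' Angular distribution of the i-th emitted Cerenkov photon
#'
#' For each event, takes the photon with the requested emission order
#' (events with fewer photons are skipped) and histograms its x-z emission
#' angle; the histogram is normalized to its maximum bin.
#'
#' @param photons data frame with columns `event`, `order`, `dir_x`,
#'   `dir_y`, `dir_z` (Cerenkov photons of a run)
#' @param order_index emission order (1 = first emitted)
#' @param bins number of angular bins over `[0, 360)` degrees
#' @return list with `breaks`, `mids` (degrees), `counts`, `density`
#'   (normalized to max 1) and `n_events` used
#' @export
order_resolved_angles <- function(photons, order_index, bins = 36) {
  if (order_index < 1) stop("order_index must be >= 1")
  dirs <- .order_dirs(photons, order_index)
  ang <- xz_angle(dirs)
  ang <- ang[!is.na(ang)]
  if (length(ang) == 0) stop("no events with a photon of that order")
  breaks <- seq(0, 360, length.out = bins + 1)
  h <- hist(ang, breaks = breaks, plot = FALSE)
  list(
    breaks = breaks, mids = h$mids, counts = h$counts,
    density = h$counts / max(h$counts), n_events = length(ang)
  )
}

#' Backward fraction of the i-th emitted Cerenkov photon
#'
#' Fraction of qualifying events whose i-th photon's x-z angle lies within
#' half a bin of 180 degrees (backward with respect to the gamma).
#'
#' @inheritParams order_resolved_angles
#' @param bin_width_deg width of the backward bin, centred on 180 degrees
#' @return fraction in `[0, 1]`
#' @export
backward_fraction <- function(photons, order_index, bin_width_deg = 10) {
  dirs <- .order_dirs(photons, order_index)
  ang <- xz_angle(dirs)
  ang <- ang[!is.na(ang)]
  if (length(ang) == 0) stop("no events with a photon of that order")
  mean(abs(ang - 180) <= bin_width_deg / 2)
}

#' Histograms of detected-photon path length and detection time
#'
#' @param detected data frame from [trace_photons()], restricted to rows
#'   with `status == "detected"` (other rows are dropped here)
#' @param path_breaks_mm breaks for the path-length histogram (default
#'   log-spaced over 0.1-200 mm)
#' @param time_bin_ns width of the detection-time bins
#' @return list with the two histograms and `mean_path_mm`,
#'   `mean_transit_ns` (detection time minus emission time),
#'   `mean_detection_time_ns`
#' @export
detection_histograms <- function(detected,
                                 path_breaks_mm = 10^seq(-1, log10(200), length.out = 41),
                                 time_bin_ns = 0.02) {
  det <- detected[detected$status == "detected", , drop = FALSE]
  if (nrow(det) == 0) stop("no detected photons")
  pl <- pmin(pmax(det$path_length, min(path_breaks_mm)), max(path_breaks_mm))
  hp <- hist(pl, breaks = path_breaks_mm, plot = FALSE)
  transit <- det$detection_time - det$time
  tb <- seq(0, max(transit) + time_bin_ns, by = time_bin_ns)
  ht <- hist(transit, breaks = tb, plot = FALSE)
  list(
    path = list(breaks = hp$breaks, mids = hp$mids, counts = hp$counts),
    transit = list(breaks = ht$breaks, mids = ht$mids, counts = ht$counts),
    mean_path_mm = mean(det$path_length),
    mean_transit_ns = mean(transit),
    mean_detection_time_ns = mean(det$detection_time),
    n_detected = nrow(det)
  )
}
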