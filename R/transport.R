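# Photoelectric recoil-electron generation and stepwise electron transport
# with the delta-beta-limited step rule.

#' Relativistic kinematics of an electron
#'
#' @param ke kinetic energy, MeV (vectorized)
#' @return list with `beta` and `gamma`
#' @export
#' @examples
#' kinematics(0.420) # beta ~0.8359, gamma ~1.8219
kinematics <- function(ke) {
  if (any(ke < 0)) stop("kinetic energy must be nonnegative")
  gamma <- 1 + ke / physical_constants()$m
  list(beta = sqrt(1 - 1 / gamma^2), gamma = gamma)
}

#' Construct an electron state
#'
#' @param ke kinetic energy, MeV
#' @param position 3-vector, mm
#' @param direction 3-vector (normalized internally)
#' @param time ns
#' @return an object of class `cer_electron_state`
#' @export
electron_state <- function(ke, position = c(0, 0, 0),
                           direction = c(0, 0, 1), time = 0) {
  kin <- kinematics(ke)
  structure(
    list(
      position = as.numeric(position),
      direction = as.numeric(direction) / sqrt(sum(direction^2)),
      ke = ke, beta = kin$beta, gamma = kin$gamma, time = time
    ),
    class = "cer_electron_state"
  )
}

#' Photoelectric attenuation of the gamma in a material
#'
#' Linear attenuation coefficient from a mass attenuation coefficient
#' (default: the photoelectric component for BGO at 511 keV, ~0.056 cm^2/g).
#'
#' @param mat a `cer_material`
#' @param mass_coeff_cm2_g photoelectric mass attenuation coefficient, cm^2/g
#' @return linear coefficient in 1/mm
#' @export
photoelectric_mu <- function(mat, mass_coeff_cm2_g = 0.056) {
  mass_coeff_cm2_g * mat$density / 10
}

#' Sample the gamma interaction depth inside the crystal
#'
#' Exponential interaction depths, resampled until they fall inside the
#' crystal: only gammas that interact photoelectrically in the crystal are
#' kept, so the depth distribution is the exponential truncated to the
#' crystal length.
#'
#' @param n number of depths
#' @param mu linear attenuation coefficient, 1/mm
#' @param crystal_length_mm crystal thickness along the gamma axis
#' @return vector of depths in (0, crystal_length_mm]
#' @export
sample_interaction_depth <- function(n, mu, crystal_length_mm = 20) {
  if (mu <= 0) stop("mu must be positive")
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    d <- stats::rexp(length(todo), rate = mu)
    ok <- d <= crystal_length_mm
    out[todo[ok]] <- d[ok]
    todo <- todo[!ok]
  }
  out
}

# Sauter photoelectron polar angle: f(cos) ~ sin^2 / (1 - beta cos)^4,
# sampled by rejection against a uniform proposal in cos(theta).
.sample_sauter_cos <- function(n, beta) {
  dens <- function(ct) (1 - ct^2) / (1 - beta * ct)^4
  fmax <- max(dens(seq(-1, 1, length.out = 2001))) * 1.0001
  out <- numeric(n)
  todo <- n
  while (todo > 0) {
    ct <- stats::runif(todo, -1, 1)
    keep <- stats::runif(todo) * fmax < dens(ct)
    k <- sum(keep)
    if (k > 0) out[(n - todo + 1):(n - todo + k)] <- ct[keep]
    todo <- todo - k
  }
  out
}

#' Generate a photoelectric recoil electron
#'
#' Chooses the atomic shell by its selection probability, sets the electron
#' kinetic energy to `e_gamma - binding`, and samples the emission direction
#' about the gamma axis (+z) from the Sauter distribution
#' `f(theta) ~ sin^2(theta) / (1 - beta cos(theta))^4`, which concentrates
#' energetic photoelectrons forward. The state clock starts at the gamma
#' flight time from the source to the interaction point.
#'
#' @param e_gamma gamma energy, MeV
#' @param mat a `cer_material`
#' @param depth interaction depth (mm) along +z inside the crystal; sampled
#'   via [sample_interaction_depth()] when `NULL`
#' @param mu linear photoelectric attenuation coefficient (1/mm)
#' @param source_distance_mm distance from source to crystal entrance face
#' @param crystal_length_mm crystal thickness
#' @return a `cer_electron_state`; attribute `"shell"` records the shell
#' @export
make_photoelectron <- function(e_gamma, mat, depth = NULL,
                               mu = photoelectric_mu(mat),
                               source_distance_mm = 10,
                               crystal_length_mm = 20) {
  if (e_gamma <= max(mat$shells$binding)) {
    stop("gamma energy must exceed every shell binding energy")
  }
  if (is.null(depth)) {
    depth <- sample_interaction_depth(1, mu, crystal_length_mm)
  }
  shell_i <- sample.int(nrow(mat$shells), 1, prob = mat$shells$prob)
  ke <- e_gamma - mat$shells$binding[shell_i]
  beta <- kinematics(ke)$beta
  ct <- .sample_sauter_cos(1, beta)
  st <- sqrt(max(0, 1 - ct^2))
  phi <- stats::runif(1, 0, 2 * pi)
  state <- electron_state(
    ke = ke,
    position = c(0, 0, depth),
    direction = c(st * cos(phi), st * sin(phi), ct),
    time = (source_distance_mm + depth) / physical_constants()$c_mm_ns
  )
  attr(state, "shell") <- mat$shells$shell[shell_i]
  state
}

# interpolate a stopping power column of the loss tables
.dedx_at <- function(tables, ke, column = c("col", "total")) {
  column <- match.arg(column)
  y <- if (column == "col") tables$dedx_col else tables$dedx
  stats::approx(tables$ke, y, xout = ke, rule = 2)$y
}

#' Velocity-limited electron step length
#'
#' Implements the step rule: the default physical step is the range-based
#' `dx = range(ke) - range(ke_cut)` (for `ke` below `2 ke_cut`, the full
#' remaining range down to the tracking cutoff, terminating the track). When
#' a maximum per-step velocity change `delta_beta` is imposed and the
#' electron is above the Cerenkov threshold, the candidate step
#' `dl = m (gamma - gamma_f) / (dE/dx)` with
#' `beta_f = beta (1 - delta_beta)` is computed from the ionisation loss,
#' and the smaller of `dl` and `dx` is used. The limit applies only above
#' `beta_threshold` because it is the Cerenkov process that imposes it; a
#' sub-threshold electron steps on the range-based default.
#'
#' @param state a `cer_electron_state`
#' @param delta_beta fractional velocity change per step in (0, 1], or
#'   `NULL`/`Inf` for unlimited (default stepping)
#' @param tables a `cer_loss_tables`
#' @param beta_threshold Cerenkov threshold velocity gating the limit
#'   (0 applies the limit at all energies)
#' @param ke_cut residual energy left after a default range-based step, MeV
#' @param cutoff tracking cutoff energy, MeV
#' @return step length in mm
#' @export
limited_step_length <- function(state, delta_beta, tables,
                                beta_threshold = 0, ke_cut = 0.01,
                                cutoff = 1e-3) {
  ke <- state$ke
  dx <- if (ke > 2 * ke_cut) {
    csda_range(tables, ke) - csda_range(tables, ke_cut)
  } else {
    csda_range(tables, ke) - csda_range(tables, cutoff)
  }
  dx <- max(dx, 0)
  unlimited <- is.null(delta_beta) || !is.finite(delta_beta)
  if (!unlimited && (delta_beta <= 0 || delta_beta > 1)) {
    stop("delta_beta must be in (0, 1] or NULL/Inf for unlimited")
  }
  if (unlimited || state$beta <= beta_threshold) {
    return(dx)
  }
  beta_f <- state$beta * (1 - delta_beta)
  gamma_f <- 1 / sqrt(1 - beta_f^2)
  dl <- physical_constants()$m * (state$gamma - gamma_f) /
    .dedx_at(tables, ke, "col")
  min(dl, dx)
}

#' Multiple-scattering deflection of the electron direction
#'
#' Highland small-angle model: the polar deflection is Gaussian with width
#' `theta0 = 13.6 MeV / (beta c p) * sqrt(step / X0)` (the logarithmic
#' correction is dropped so that deflection variances add over sub-steps),
#' the azimuth uniform.
#'
#' @param state a `cer_electron_state`
#' @param step_length_mm step length in mm
#' @param mat a `cer_material` (for the radiation length X0)
#' @return new unit direction (3-vector)
#' @export
scatter_direction <- function(state, step_length_mm, mat) {
  if (step_length_mm <= 0) stop("step length must be positive")
  theta0 <- highland_theta0(state$beta, state$gamma, step_length_mm, mat$x0_mm)
  theta <- abs(stats::rnorm(1, 0, theta0))
  phi <- stats::runif(1, 0, 2 * pi)
  rotate_direction(state$direction, theta, phi)
}

#' @rdname scatter_direction
#' @param beta,gamma electron kinematic factors
#' @param x0_mm radiation length in mm
#' @export
highland_theta0 <- function(beta, gamma, step_length_mm, x0_mm) {
  p <- gamma * physical_constants()$m * beta # pc in MeV
  13.6 / (beta * p) * sqrt(step_length_mm / x0_mm)
}

#' Rotate a unit vector by polar angle theta about itself
#'
#' Deflects `v` by polar angle `theta` (about the axis `v`) with azimuth
#' `phi` measured in a basis orthogonal to `v`; used for scattering
#' deflections and Cerenkov cone emission.
#'
#' @param v unit 3-vector
#' @param theta polar deflection, rad
#' @param phi azimuth, rad
#' @return unit 3-vector
#' @export
rotate_direction <- function(v, theta, phi) {
  # orthonormal basis (u1, u2, v)
  if (abs(v[3]) < 0.999) a <- c(0, 0, 1) else a <- c(1, 0, 0)
  u1 <- c(
    a[2] * v[3] - a[3] * v[2],
    a[3] * v[1] - a[1] * v[3],
    a[1] * v[2] - a[2] * v[1]
  )
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(
    v[2] * u1[3] - v[3] * u1[2],
    v[3] * u1[1] - v[1] * u1[3],
    v[1] * u1[2] - v[2] * u1[1]
  )
  out <- sin(theta) * (cos(phi) * u1 + sin(phi) * u2) + cos(theta) * v
  out / sqrt(sum(out^2))
}

#' Propagate an electron step by step
#'
#' Tracks the electron until its kinetic energy falls to the cutoff: each
#' iteration computes the (possibly velocity-limited) step length, moves the
#' electron rectilinearly, depletes the energy through the range table,
#' advances the clock with the pre-step velocity, and deflects the direction
#' by multiple scattering. The rectilinear step lengths sum to the CSDA range
#' regardless of `delta_beta`.
#'
#' @inheritParams limited_step_length
#' @param initial a `cer_electron_state` (e.g. from [make_photoelectron()])
#' @param mat a `cer_material`
#' @param msc apply multiple-scattering deflections between steps
#' @param max_steps hard cap on the number of steps
#' @return an object of class `cer_track`: a data frame of steps with
#'   pre/post kinematic state (one row per rectilinear step)
#' @export
propagate_electron <- function(initial, delta_beta, tables, mat,
                               ke_cut = 0.01, cutoff = 1e-3, msc = TRUE,
                               max_steps = 2e6) {
  db <- if (is.null(delta_beta) || !is.finite(delta_beta)) -1 else delta_beta
  if (db > 0 && db > 1) stop("delta_beta must be in (0, 1] or NULL/Inf")
  thr <- cherenkov_threshold(mat$dispersion)
  m <- cpp_propagate(
    initial$ke, initial$position, initial$direction, initial$time,
    db, tables$ke, tables$dedx, tables$dedx_col, tables$range,
    thr$beta, mat$x0_mm, cutoff, ke_cut, msc, as.integer(max_steps)
  )
  colnames(m) <- c(
    "pre_ke", "post_ke", "length",
    "pre_x", "pre_y", "pre_z", "dir_x", "dir_y", "dir_z",
    "pre_time", "post_time", "pre_beta", "post_beta"
  )
  df <- as.data.frame(m)
  df$step <- seq_len(nrow(df))
  structure(df, class = c("cer_track", "data.frame"))
}

#' Per-track summary of a stepwise electron track
#'
#' @param track a `cer_track`
#' @return one-row data frame: number of steps, first/mean step length,
#'   track length (sum of step lengths), initial and final energy
#' @export
track_summary <- function(track) {
  data.frame(
    n_steps = nrow(track),
    first_step_mm = track$length[1],
    mean_step_mm = mean(track$length),
    track_length_mm = sum(track$length),
    ke0 = track$pre_ke[1],
    ke_final = track$post_ke[nrow(track)]
  )
}
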