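# Optical photon transport through the wrapped crystal to the front-coupled
# photodetector.

#' Crystal geometry and surface model
#'
#' A rectangular crystal occupying `x, y` in `[-width/2, width/2]` and `z`
#' in `[0, length]`. The gamma enters along +z; the photodetector is coupled
#' to the z = 0 face through optical grease (front arrangement) and is ideal
#' (detection efficiency 1 for transmitted photons). The other five faces are
#' polished (specular Fresnel against air); photons transmitted through them
#' strike a diffuse reflective wrap and re-enter with the wrap reflectivity,
#' or are lost.
#'
#' @param width_mm,height_mm transverse dimensions (mm)
#' @param length_mm crystal thickness along the gamma axis (mm)
#' @param wrap_reflectivity probability that a photon reaching the wrap is
#'   diffusely returned into the crystal
#' @param n_grease refractive index of the detector coupling layer
#' @param max_reflections boundary interactions before a photon is declared
#'   trapped
#' @return an object of class `cer_geometry`
#' @export
crystal_geometry <- function(width_mm = 3, height_mm = 3, length_mm = 20,
                             wrap_reflectivity = 0.98, n_grease = 1.5,
                             max_reflections = 1000) {
  structure(
    list(
      hx = width_mm / 2, hy = height_mm / 2, length = length_mm,
      wrap_reflectivity = wrap_reflectivity, n_grease = n_grease,
      max_reflections = as.integer(max_reflections)
    ),
    class = "cer_geometry"
  )
}

#' Unpolarized Fresnel interaction at an interface
#'
#' Computes the unpolarized Fresnel reflectance for the incidence angle and
#' randomly either reflects specularly or refracts by Snell's law. Total
#' internal reflection applies when `sin(theta_i) > n2/n1`.
#'
#' @param direction incident unit direction
#' @param face_normal outward unit normal of the interface
#' @param n1,n2 refractive indices on the incident / far side
#' @return list with `type` (`"reflected"` or `"transmitted"`),
#'   `direction` (unit 3-vector) and `reflectance` (the probability used)
#' @export
fresnel_interaction <- function(direction, face_normal, n1, n2) {
  d <- direction / sqrt(sum(direction^2))
  nrm <- face_normal / sqrt(sum(face_normal^2))
  cosi <- sum(d * nrm)
  if (cosi < 0) {
    nrm <- -nrm
    cosi <- -cosi
  }
  sini2 <- max(0, 1 - cosi^2)
  sint2 <- (n1 / n2)^2 * sini2
  reflect <- function() d - 2 * cosi * nrm
  if (sint2 > 1) { # total internal reflection
    return(list(type = "reflected", direction = reflect(), reflectance = 1))
  }
  cost <- sqrt(1 - sint2)
  rs <- ((n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost))^2
  rp <- ((n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi))^2
  r <- (rs + rp) / 2
  if (stats::runif(1) < r) {
    list(type = "reflected", direction = reflect(), reflectance = r)
  } else {
    tdir <- (n1 / n2) * d + (n1 / n2 * cosi - cost) * (-nrm)
    # Snell refraction: tangential component scaled by n1/n2
    tdir <- tdir / sqrt(sum(tdir^2))
    list(type = "transmitted", direction = tdir, reflectance = r)
  }
}

#' Optical photon propagation speed
#'
#' Photons travel at the group velocity `c / n_g(e)`; in a dispersive medium
#' the group index exceeds the phase index, slowing energy transport.
#'
#' @param dispersion a `cer_dispersion`
#' @param energy_ev photon energy, eV (vectorized)
#' @return speed in mm/ns
#' @export
photon_speed <- function(dispersion, energy_ev) {
  physical_constants()$c_mm_ns / group_index(dispersion, energy_ev)
}

#' Trace optical photons through the crystal
#'
#' Ray-traces each photon segment by segment: advance to the nearest face,
#' test exponential bulk absorption over the segment, and resolve the
#' surface interaction (Fresnel against grease at the detector face, where a
#' transmitted photon is detected; Fresnel against air plus diffuse wrap at
#' the other faces). Photons exceeding the reflection cap are declared
#' trapped. The detection time is the emission time plus path length times
#' `n_g/c`.
#'
#' @param photons data frame from [emit_cherenkov()] /
#'   [emit_scintillation()] (columns `x`,`y`,`z`,`time`,`energy`,
#'   `dir_x`,`dir_y`,`dir_z`); extra columns are carried through
#' @param geom a `cer_geometry`
#' @param dispersion a `cer_dispersion`
#' @param speed use the `"group"` (default) or `"phase"` index for the
#'   propagation speed
#' @return the input data frame with columns `status` (one of `"detected"`,
#'   `"absorbed"`, `"wrap_lost"`, `"trapped"`), `path_length` (mm, straight
#'   segments summed), `n_reflections`, and `detection_time` (ns, `NA`
#'   unless detected)
#' @export
trace_photons <- function(photons, geom, dispersion,
                          speed = c("group", "phase")) {
  speed <- match.arg(speed)
  if (nrow(photons) == 0) {
    photons$status <- character(0)
    photons$path_length <- numeric(0)
    photons$n_reflections <- integer(0)
    photons$detection_time <- numeric(0)
    return(photons)
  }
  inside <- abs(photons$x) <= geom$hx + 1e-9 &
    abs(photons$y) <= geom$hy + 1e-9 &
    photons$z >= -1e-9 & photons$z <= geom$length + 1e-9
  if (!all(inside)) stop("photon origin outside the crystal")
  m <- as.matrix(photons[, c(
    "x", "y", "z", "time", "energy", "dir_x", "dir_y", "dir_z"
  )])
  speed_grid <- if (speed == "group") {
    group_index_grid(dispersion)
  } else {
    dispersion$n
  }
  res <- cpp_trace_photons(
    m, geom$hx, geom$hy, geom$length,
    dispersion$energy, dispersion$n, speed_grid,
    dispersion$absorption_mm,
    geom$wrap_reflectivity, geom$n_grease, geom$max_reflections,
    physical_constants()$c_mm_ns
  )
  status <- c("detected", "absorbed", "wrap_lost", "trapped")[res[, 1] + 1]
  photons$status <- status
  photons$path_length <- res[, 2]
  photons$n_reflections <- as.integer(res[, 3])
  photons$detection_time <- ifelse(status == "detected", res[, 4], NA_real_)
  photons
}

#' @rdname trace_photons
#' @param photon a single photon (one-row data frame or list)
#' @export
trace_photon <- function(photon, geom, dispersion,
                         speed = c("group", "phase")) {
  trace_photons(as.data.frame(photon), geom, dispersion, speed = speed)
}
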