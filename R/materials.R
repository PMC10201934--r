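# Material definitions: composition, shells, optical dispersion, derived
# quantities (Cerenkov threshold, mean excitation energy).

#' Physical constants used throughout the simulation
#'
#' Returns the small set of constants the transport and emission code relies
#' on, in the unit system of the package (MeV, mm, ns, eV for optical photon
#' energies).
#'
#' @return A list with elements `m` (electron rest energy, 0.511 MeV),
#'   `alpha` (fine-structure constant), `hc_ev_nm` (Planck constant times
#'   light speed, eV nm), `frank_tamm_prefactor` (2 pi alpha / (h c), photons
#'   per eV per mm for a unit charge) and `c_mm_ns` (vacuum light speed,
#'   mm/ns).
#' @export
#' @examples
#' physical_constants()$frank_tamm_prefactor  # ~36.98 /(eV mm)
physical_constants <- function() {
  alpha <- 1 / 137.035999084
  hc <- 1239.841984 # eV nm
  list(
    m = 0.511,
    alpha = alpha,
    hc_ev_nm = hc,
    frank_tamm_prefactor = 2 * pi * alpha / hc * 1e6, # /(eV mm)
    c_mm_ns = 299.792458
  )
}

#' Convert between photon wavelength (nm) and energy (eV)
#'
#' @param nm wavelength in nanometres
#' @param ev photon energy in electronvolts
#' @return the corresponding energy (eV) or wavelength (nm)
#' @export
energy_from_nm <- function(nm) physical_constants()$hc_ev_nm / nm

#' @rdname energy_from_nm
#' @export
nm_from_energy <- function(ev) physical_constants()$hc_ev_nm / ev

# Elemental reference data for the Bragg additivity rule.
# Z, A: standard atomic number / relative atomic mass.
# i_ev: mean excitation energy of the element (eV); for constituents of a
# condensed compound the usual adjustment is applied in
# mean_excitation_energy(): tabulated condensed value for Z <= 8, 1.13 x the
# elemental value above.
.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "Si", "Ge", "Br", "Y", "Tl", "Bi", "Pb", "Lu"),
  Z = c(1, 6, 7, 8, 14, 32, 35, 39, 81, 83, 82, 71),
  A = c(
    1.008, 12.011, 14.007, 15.999, 28.085, 72.630, 79.904, 88.906,
    204.38, 208.980, 207.2, 174.967
  ),
  i_ev = c(19.2, 78, 82, 95, 173, 350, 343, 420, 810, 823, 823, 694),
  i_condensed_ev = c(19.2, 81, 82, 106, NA, NA, NA, NA, NA, NA, NA, NA),
  stringsAsFactors = FALSE
)

#' Mean excitation energy of a mixture by Bragg additivity
#'
#' Computes the I-value of a compound from its elemental composition using
#' the Bragg additivity rule, `ln I = sum(w Z/A ln I_i) / sum(w Z/A)`, with
#' the standard condensed-phase adjustments to the elemental I-values
#' (fixed condensed values for Z <= 8, a factor 1.13 for heavier
#' constituents). For BGO this yields the accepted 534 eV.
#'
#' @param elements data frame with columns `symbol`, `Z`, `A`, `w`
#'   (mass fraction); `Z`/`A` may be omitted when `symbol` is known.
#' @return mean excitation energy in eV
#' @export
mean_excitation_energy <- function(elements) {
  if (is.null(elements) || nrow(elements) == 0L) {
    stop("element list must be nonempty")
  }
  idx <- match(elements$symbol, .element_table$symbol)
  if (anyNA(idx)) {
    stop(
      "unknown element(s): ",
      paste(elements$symbol[is.na(idx)], collapse = ", ")
    )
  }
  ref <- .element_table[idx, ]
  z <- if (!is.null(elements$Z)) elements$Z else ref$Z
  a <- if (!is.null(elements$A)) elements$A else ref$A
  if (nrow(elements) == 1L) {
    return(ref$i_ev) # a pure element keeps its own I-value
  }
  i_el <- ifelse(is.na(ref$i_condensed_ev), 1.13 * ref$i_ev, ref$i_condensed_ev)
  wza <- elements$w * z / a
  exp(sum(wza * log(i_el)) / sum(wza))
}

.make_dispersion <- function(min_nm, max_nm, n_min_nm, n_max_nm,
                             absorption_mm = 3000, n_points = 21) {
  # grid ascending in energy: max_nm wavelength <-> lowest energy
  e_lo <- energy_from_nm(max_nm)
  e_hi <- energy_from_nm(min_nm)
  e <- seq(e_lo, e_hi, length.out = n_points)
  # linear-in-energy interpolation between the two printed endpoints
  n <- n_max_nm + (n_min_nm - n_max_nm) * (e - e_lo) / (e_hi - e_lo)
  structure(
    list(
      energy = e, n = n,
      absorption_mm = rep(absorption_mm, n_points)
    ),
    class = "cer_dispersion"
  )
}

.validate_material <- function(mat) {
  stopifnot(abs(sum(mat$elements$w) - 1) < 1e-9)
  stopifnot(abs(sum(mat$shells$prob) - 1) < 1e-9)
  stopifnot(all(diff(mat$dispersion$energy) > 0))
  stopifnot(all(mat$dispersion$n > 1))
  mat
}

.new_material <- function(name, density, elements, shells, x0_mm, dispersion) {
  mat <- structure(
    list(
      name = name,
      density = density, # g/cm^3
      elements = elements,
      shells = shells,
      i_ev = mean_excitation_energy(elements),
      x0_mm = x0_mm,
      dispersion = dispersion
    ),
    class = "cer_material"
  )
  .validate_material(mat)
}

#' Bismuth germanate (Bi4Ge3O12)
#'
#' Standard BGO: density 7.13 g/cm^3, stoichiometric mass fractions,
#' photoelectric shells reduced to the bismuth K edge (0.091 MeV) plus one
#' L-M pseudo-shell (0.008 MeV), and a refractive index running from 2.36 at
#' 320 nm to 2.07 at 800 nm, interpolated linearly in photon energy between
#' the two endpoints. The bulk absorption length defaults to 3000 mm,
#' negligible over centimetre paths.
#'
#' @param absorption_mm bulk absorption length (mm) applied across the window
#' @param k_shell_prob probability that a photoelectric interaction involves
#'   the K shell (the remainder goes to the L-M pseudo-shell)
#' @return an object of class `cer_material`
#' @export
#' @examples
#' bgo <- make_bgo()
#' cherenkov_threshold(bgo$dispersion)
make_bgo <- function(absorption_mm = 3000, k_shell_prob = 0.8) {
  elements <- data.frame(
    symbol = c("Bi", "Ge", "O"),
    Z = c(83, 32, 8),
    A = c(208.980, 72.630, 15.999),
    w = c(0.6710, 0.1749, 0.1541),
    stringsAsFactors = FALSE
  )
  elements$w <- elements$w / sum(elements$w)
  shells <- data.frame(
    shell = c("K", "LM"),
    binding = c(0.091, 0.008), # MeV; L-M band 0.001-0.016 collapsed to midpoint
    prob = c(k_shell_prob, 1 - k_shell_prob),
    stringsAsFactors = FALSE
  )
  .new_material(
    name = "BGO", density = 7.13, elements = elements, shells = shells,
    x0_mm = 11.18, # 7.97 g/cm^2 radiation length / 7.13 g/cm^3
    dispersion = .make_dispersion(320, 800, 2.36, 2.07, absorption_mm)
  )
}

#' Thallium bromide
#'
#' TlBr with density 7.56 g/cm^3 and optical properties defined only over
#' the 440-800 nm transmission window. The published mid-band refractive
#' index is ~2.5; in the absence of a tabulated dispersion a gentle linear
#' slope around that value is used and both endpoints are configurable.
#'
#' @param n_440,n_800 refractive index at the window edges
#' @param absorption_mm bulk absorption length (mm)
#' @param k_shell_prob K-shell selection probability (Tl K edge, 0.0855 MeV)
#' @return an object of class `cer_material`
#' @export
make_tlbr <- function(n_440 = 2.55, n_800 = 2.45, absorption_mm = 3000,
                      k_shell_prob = 0.8) {
  elements <- data.frame(
    symbol = c("Tl", "Br"),
    Z = c(81, 35),
    A = c(204.38, 79.904),
    w = c(204.38, 79.904) / (204.38 + 79.904),
    stringsAsFactors = FALSE
  )
  shells <- data.frame(
    shell = c("K", "LM"),
    binding = c(0.0855, 0.008),
    prob = c(k_shell_prob, 1 - k_shell_prob),
    stringsAsFactors = FALSE
  )
  .new_material(
    name = "TlBr", density = 7.56, elements = elements, shells = shells,
    x0_mm = 9.70, # ~7.3 g/cm^2 / 7.56 g/cm^3
    dispersion = .make_dispersion(440, 800, n_440, n_800, absorption_mm)
  )
}

#' Refractive index at a photon energy
#'
#' Piecewise-linear interpolation of the tabulated dispersion. Energies
#' outside the defined optical window are an error: the window is part of the
#' physics (it bounds the Frank-Tamm integral), not a plotting range.
#'
#' @param dispersion a `cer_dispersion` (e.g. `make_bgo()$dispersion`)
#' @param energy_ev photon energy or energies, eV
#' @return interpolated refractive index (vectorized)
#' @export
refractive_index <- function(dispersion, energy_ev) {
  rng <- range(dispersion$energy)
  if (any(energy_ev < rng[1] - 1e-12 | energy_ev > rng[2] + 1e-12)) {
    stop(sprintf(
      "photon energy outside optical window [%.4f, %.4f] eV",
      rng[1], rng[2]
    ))
  }
  stats::approx(dispersion$energy, dispersion$n,
    xout = pmin(pmax(energy_ev, rng[1]), rng[2]), rule = 2
  )$y
}

#' Group index at a photon energy
#'
#' `n_g = n + e dn/de`, with the derivative taken by finite differences on
#' the dispersion grid. The group index sets the optical photon propagation
#' speed; for normal dispersion (dn/de >= 0) n_g >= n.
#'
#' @inheritParams refractive_index
#' @return interpolated group index (vectorized)
#' @export
group_index <- function(dispersion, energy_ev) {
  ng <- group_index_grid(dispersion)
  rng <- range(dispersion$energy)
  if (any(energy_ev < rng[1] - 1e-12 | energy_ev > rng[2] + 1e-12)) {
    stop("photon energy outside optical window")
  }
  stats::approx(dispersion$energy, ng,
    xout = pmin(pmax(energy_ev, rng[1]), rng[2]), rule = 2
  )$y
}

# group index tabulated on the dispersion grid (central differences,
# one-sided at the ends)
group_index_grid <- function(dispersion) {
  e <- dispersion$energy
  n <- dispersion$n
  k <- length(e)
  dnde <- numeric(k)
  dnde[1] <- (n[2] - n[1]) / (e[2] - e[1])
  dnde[k] <- (n[k] - n[k - 1]) / (e[k] - e[k - 1])
  if (k > 2) {
    dnde[2:(k - 1)] <- (n[3:k] - n[1:(k - 2)]) / (e[3:k] - e[1:(k - 2)])
  }
  n + e * dnde
}

#' Cerenkov production threshold of a dispersion
#'
#' Emission requires the particle velocity to exceed the phase velocity of
#' light somewhere in the optical window, i.e. `beta > 1/max(n)`.
#'
#' @inheritParams refractive_index
#' @return list with `beta` (threshold velocity) and `ke_mev` (threshold
#'   electron kinetic energy)
#' @export
cherenkov_threshold <- function(dispersion) {
  b <- 1 / max(dispersion$n)
  m <- physical_constants()$m
  list(beta = b, ke_mev = m * (1 / sqrt(1 - b^2) - 1))
}

#' Write or read a material definition
#'
#' Materials round-trip through a plain JSON or YAML document (name, density,
#' elements, shells, dispersion arrays), which doubles as the configuration
#' dialect for user-defined materials.
#'
#' @param mat a `cer_material`
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`)
#' @return `read_material()` returns a `cer_material`
#' @export
write_material <- function(mat, path) {
  doc <- list(
    name = mat$name, density = mat$density,
    elements = mat$elements, shells = mat$shells,
    x0_mm = mat$x0_mm,
    dispersion = list(
      energy = mat$dispersion$energy,
      n = mat$dispersion$n,
      absorption_mm = mat$dispersion$absorption_mm
    )
  )
  if (grepl("\\.ya?ml$", path)) {
    writeLines(yaml::as.yaml(doc), path)
  } else {
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_material
#' @export
read_material <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .new_material(
    name = doc$name, density = doc$density,
    elements = as.data.frame(doc$elements),
    shells = as.data.frame(doc$shells),
    x0_mm = doc$x0_mm,
    dispersion = structure(
      list(
        energy = as.numeric(doc$dispersion$energy),
        n = as.numeric(doc$dispersion$n),
        absorption_mm = as.numeric(doc$dispersion$absorption_mm)
      ),
      class = "cer_dispersion"
    )
  )
}

#' @export
print.cer_material <- function(x, ...) {
  thr <- cherenkov_threshold(x$dispersion)
  cat(sprintf(
    "<cer_material> %s  rho=%.2f g/cm^3  I=%.1f eV  X0=%.1f mm\n",
    x$name, x$density, x$i_ev, x$x0_mm
  ))
  cat(sprintf(
    "  optical window %.0f-%.0f nm, n in [%.3f, %.3f]\n",
    nm_from_energy(max(x$dispersion$energy)),
    nm_from_energy(min(x$dispersion$energy)),
    min(x$dispersion$n), max(x$dispersion$n)
  ))
  cat(sprintf(
    "  Cerenkov threshold beta=%.4f (KE=%.4f MeV)\n",
    thr$beta, thr$ke_mev
  ))
  invisible(x)
}
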