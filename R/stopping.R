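# Electron energy-loss and range tables built from analytic stopping-power
# formulas. These play the role of the energy-loss (dE/dx) and range tables
# a condensed-history Monte Carlo code builds at initialization.

#' Electron collision stopping power (Berger-Seltzer)
#'
#' Moller-corrected Bethe collision stopping power for electrons, evaluated
#' with the material's mean excitation energy and scaled by density to
#' MeV/mm. The density-effect correction is off by default: below ~1 MeV in
#' the media of interest it is a percent-level correction, and leaving it out
#' keeps the tables a pure function of composition.
#'
#' @param mat a `cer_material`
#' @param ke electron kinetic energy, MeV (vectorized); must be >= 1 keV
#' @return stopping power in MeV/mm
#' @export
collision_stopping_power <- function(mat, ke) {
  if (any(ke < 1e-3 - 1e-12)) stop("kinetic energy below the 1 keV table floor")
  m <- physical_constants()$m
  za <- sum(mat$elements$w * mat$elements$Z / mat$elements$A)
  tau <- ke / m
  gamma <- 1 + tau
  beta2 <- 1 - 1 / gamma^2
  i_ratio <- (mat$i_ev * 1e-6) / m
  f_minus <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / gamma^2
  mass_sp <- 0.153536 / beta2 * za *
    (log(tau^2 * (tau + 2) / (2 * i_ratio^2)) + f_minus) # MeV cm^2/g
  mass_sp * mat$density / 10 # -> MeV/mm
}

#' Approximate radiative stopping power
#'
#' Bremsstrahlung loss estimated from the classic ratio rule
#' `S_rad/S_col ~ KE * Z_eff / 800` (KE in MeV), with the
#' bremsstrahlung-weighted effective Z of the mixture. In BGO this stays
#' below 10% of the total up to 1 MeV; it mainly sharpens the high-energy end
#' of the range table.
#'
#' @inheritParams collision_stopping_power
#' @return stopping power in MeV/mm
#' @export
radiative_stopping_power <- function(mat, ke) {
  zeff <- sum(mat$elements$w * mat$elements$Z^2 / mat$elements$A) /
    sum(mat$elements$w * mat$elements$Z / mat$elements$A)
  collision_stopping_power(mat, ke) * ke * zeff / 800
}

#' Build energy-loss and CSDA range tables for a material
#'
#' Tabulates total stopping power (collision + radiative) on a log-spaced
#' kinetic-energy grid and integrates `dE / (dE/dx)` upward from the grid
#' floor to obtain the continuous-slowing-down (CSDA) range. The collision
#' part is kept separately: the velocity-limited step rule uses the
#' ionisation loss alone (see [limited_step_length()]).
#'
#' @param mat a `cer_material`
#' @param ke_min,ke_max grid limits in MeV (default 1 keV to 2 MeV)
#' @param n_points number of log-spaced grid points
#' @return an object of class `cer_loss_tables`: list with `ke`, `dedx`
#'   (total, MeV/mm), `dedx_col` (collision only), `range` (mm)
#' @export
#' @examples
#' tab <- build_loss_tables(make_bgo())
#' csda_range(tab, 0.420) # ~0.33 mm
build_loss_tables <- function(mat, ke_min = 1e-3, ke_max = 2, n_points = 200) {
  ke <- exp(seq(log(ke_min), log(ke_max), length.out = n_points))
  dedx_col <- collision_stopping_power(mat, ke)
  dedx <- dedx_col + radiative_stopping_power(mat, ke)
  # cumulative trapezoid of 1/dedx over ke
  inv <- 1 / dedx
  rng <- c(0, cumsum((inv[-1] + inv[-n_points]) / 2 * diff(ke)))
  structure(
    list(material = mat$name, ke = ke, dedx = dedx, dedx_col = dedx_col, range = rng),
    class = "cer_loss_tables"
  )
}

#' CSDA range and its inverse along a path
#'
#' `csda_range()` interpolates the range table; `ke_after_path()` gives the
#' kinetic energy after travelling a path length `s`, by inverting the
#' monotone range table. Paths beyond the remaining range clamp to the grid
#' floor energy (the electron is considered stopped).
#'
#' @param tables a `cer_loss_tables`
#' @param ke kinetic energy, MeV (vectorized)
#' @param s path length, mm
#' @return `csda_range()`: range in mm; `ke_after_path()`: energy in MeV
#' @export
csda_range <- function(tables, ke) {
  stats::approx(tables$ke, tables$range, xout = ke, rule = 2)$y
}

#' @rdname csda_range
#' @export
ke_after_path <- function(tables, ke, s) {
  if (any(s < 0)) stop("path length must be nonnegative")
  r <- csda_range(tables, ke) - s
  out <- stats::approx(tables$range, tables$ke, xout = r, rule = 2)$y
  out[r <= tables$range[1]] <- tables$ke[1]
  out
}

#' @export
print.cer_loss_tables <- function(x, ...) {
  cat(sprintf(
    "<cer_loss_tables> %s: %d points, %.0f keV-%.2f MeV, range(max)=%.3f mm\n",
    x$material, length(x$ke), x$ke[1] * 1000, max(x$ke), max(x$range)
  ))
  invisible(x)
}

#' Export loss tables as a data frame / CSV
#'
#' @param tables a `cer_loss_tables`
#' @param path optional CSV path; when given the table is also written there
#' @return data frame with columns `ke_mev`, `dedx_mev_mm`,
#'   `dedx_col_mev_mm`, `range_mm`
#' @export
loss_tables_df <- function(tables, path = NULL) {
  df <- data.frame(
    ke_mev = tables$ke, dedx_mev_mm = tables$dedx,
    dedx_col_mev_mm = tables$dedx_col, range_mm = tables$range
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
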