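# Physical constants (SI)
.R_GAS   <- 8.314       # J mol-1 K-1
.FARADAY <- 96485       # C mol-1

#' Physical constants used by the model
#'
#' @return Named list with the molar gas constant `R` (J mol-1 K-1) and the
#'   Faraday constant `F` (C mol-1).
#' @export
ion_constants <- function() list(R = .R_GAS, F = .FARADAY)

#' Convert pH to free proton concentration in mM
#'
#' A pH of 5.5 corresponds to 10^(-5.5) mol/l, i.e. 3.162e-3 mM. The mM/M
#' conversion factor (1000 by default) is exposed because all concentrations
#' in the model are carried in mM (= mol m-3).
#'
#' @param pH pH value.
#' @param cf conversion factor, mM per M.
#' @return Proton concentration in mM.
#' @export
#' @examples
#' ph_to_mM(5.5)   # 3.162e-3 mM
ph_to_mM <- function(pH, cf = 1000) cf * 10^(-pH)

#' Convert a free proton concentration in mM to pH
#' @param c_mM proton concentration, mM.
#' @param cf conversion factor, mM per M.
#' @return pH value.
#' @export
mM_to_ph <- function(c_mM, cf = 1000) -log10(c_mM / cf)

#' Cell-suspension geometry
#'
#' Builds the geometric and global physical quantities of the experimental
#' system: a monolayer of yeast cells in a measurement bath. Total membrane
#' surface and internal volume are derived from the number of cells and the
#' per-cell surface/volume of a spherical cell; defaults reproduce the
#' monolayer used for MIFE flux recordings (3.6e5 cells of 63.6 um^2 and
#' 50 fL each give Surf = 2.29e-5 m^2 and V_in = 1.8e-11 m^3).
#'
#' @param n_cells number of cells in the monolayer.
#' @param cell_surface_um2 surface area of a single cell, um^2.
#' @param cell_volume_fL volume of a single cell, fL.
#' @param V_out external (bath) volume, m^3.
#' @param temperature temperature, K.
#' @param Cm specific membrane capacitance, F m-2. Not tabulated with the
#'   published parameter sets; the default is the textbook 1 uF cm-2 class
#'   of values.
#' @param pbc proton buffer capacity, mM per pH unit.
#' @param cf concentration conversion factor, mM per M.
#' @return An object of class `ion_geometry`: list with `Surf` (m^2),
#'   `V_in` (m^3), `V_out` (m^3), `T` (K), `Cm` (F m-2), `pbc`, `cf`,
#'   `n_cells`, and the constants `R`, `F`.
#' @export
#' @examples
#' g <- cell_geometry()
#' g$Surf          # 2.29e-5 m^2
cell_geometry <- function(n_cells = 3.6e5,
                          cell_surface_um2 = 63.6,
                          cell_volume_fL = 50,
                          V_out = 2.85e-6,
                          temperature = 296,
                          Cm = 0.01,
                          pbc = 200,
                          cf = 1000) {
  vals <- c(n_cells = n_cells, cell_surface_um2 = cell_surface_um2,
            cell_volume_fL = cell_volume_fL, V_out = V_out,
            temperature = temperature, Cm = Cm, pbc = pbc, cf = cf)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry quantities must be finite and strictly positive")
  geom <- list(
    Surf    = n_cells * cell_surface_um2 * 1e-12,  # um^2 -> m^2
    V_in    = n_cells * cell_volume_fL * 1e-18,    # fL   -> m^3
    V_out   = V_out,
    T       = temperature,
    Cm      = Cm,
    pbc     = pbc,
    cf      = cf,
    n_cells = n_cells,
    R       = .R_GAS,
    F       = .FARADAY
  )
  class(geom) <- "ion_geometry"
  geom
}

#' @export
print.ion_geometry <- function(x, ...) {
  cat("Cell-suspension geometry\n")
  cat(sprintf("  cells: %g   Surf: %.3g m^2   V_in: %.3g m^3   V_out: %.3g m^3\n",
              x$n_cells, x$Surf, x$V_in, x$V_out))
  cat(sprintf("  T: %g K   Cm: %g F/m^2   pbc: %g mM/pH   cf: %g mM/M\n",
              x$T, x$Cm, x$pbc, x$cf))
  invisible(x)
}

# Buffering factor relating proton flux to free-proton concentration change.
# pbc is the buffer capacity (mM of acid per pH unit); dividing by
# ln(10) * c_H gives the dimensionless ratio of total to free proton change.
buffering_factor <- function(pbc, c_H_in_mM) {
  if (c_H_in_mM <= 0) stop("internal proton concentration must be positive")
  pbc / (log(10) * c_H_in_mM)
}
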