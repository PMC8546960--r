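# Four-sector proteome allocation model -----------------------------------
#
# The proteome is partitioned into a ribosomal/translation sector (phi_R), a
# growth-relevant metabolic sector (phi_M), an unused/hedging metabolic
# sector (phi_U) and a growth-rate-independent core sector (phi_Q):
#
#   phi_R + phi_M + phi_U + phi_Q = 1,   phi_max = phi_R + phi_M + phi_U
#
# Under balanced exponential growth the growth rate is linear in the R and M
# sector sizes, lambda = tE * phi_R = mE * phi_M, defining a translational
# efficiency tE and a metabolic efficiency mE, whence mE/tE = phi_R/phi_M.

#' Parameters of the proteome-allocation model
#'
#' Bundles the literature constants that convert raw measurements into
#' proteome fractions and absolute concentrations.
#'
#' @param rho RNA-to-ribosomal-proteome conversion factor applied to the
#'   total-RNA/total-protein mass ratio (dimensionless, default 0.76).
#' @param phi_max Growth-related proteome fraction `1 - phi_Q` available for
#'   redistribution among the R, M and U sectors (default 0.43).
#' @param cell_volume Specific cell volume in microliters per mg dry cell
#'   weight, used to convert micromol/gDCW to mM (default 2.3).
#' @param dcw_factor Gram dry cell weight per liter per OD600 unit
#'   (default 0.44).
#' @return An object of class `allocation_params`.
#' @export
allocation_params <- function(rho = 0.76, phi_max = 0.43,
                              cell_volume = 2.3, dcw_factor = 0.44) {
  assert_number(rho, "rho", lower = 0, strict_lower = TRUE)
  assert_number(phi_max, "phi_max", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  assert_number(dcw_factor, "dcw_factor", lower = 0, strict_lower = TRUE)
  structure(list(rho = rho, phi_max = phi_max, cell_volume = cell_volume,
                 dcw_factor = dcw_factor),
            class = "allocation_params")
}

#' Ribosomal proteome fraction from the RNA/protein ratio
#'
#' `phi_R = (R/P) * rho`: the mass ratio of total RNA to total protein times
#' an empirical conversion factor gives the ribosome-affiliated proteome
#' fraction.
#'
#' @param rp_ratio Total RNA over total protein (microgram/microgram), >= 0.
#' @param rho Conversion factor (default 0.76).
#' @return `phi_R`, a proteome fraction in `[0, 1)`.
#' @export
phi_r_from_rp <- function(rp_ratio, rho = 0.76) {
  stop_if(any(!is.finite(rp_ratio)) || any(rp_ratio < 0),
          "'rp_ratio' must be finite and >= 0")
  assert_number(rho, "rho", lower = 0, strict_lower = TRUE)
  phi_r <- rp_ratio * rho
  stop_if(any(phi_r >= 1),
          "phi_R = R/P * rho >= 1: no proteome fraction left (R/P = %g)",
          max(rp_ratio))
  phi_r
}

#' Solve the four-sector partition
#'
#' Given the measured ribosomal fraction and the transcriptome-derived U/M
#' ratio, closes the partition under the conservation laws: `phi_M =
#' (phi_max - phi_R) / (1 + um_ratio)`, `phi_U = phi_M * um_ratio`,
#' `phi_Q = 1 - phi_max`.
#'
#' @param phi_R Ribosomal proteome fraction, `0 <= phi_R < phi_max`.
#' @param um_ratio Unused-to-metabolic sector ratio `phi_U/phi_M`, >= 0. The
#'   transcriptome U/M fraction ratio is used 1:1 as the proteome ratio
#'   (subsystem-level proportionality assumption).
#' @param params An [allocation_params()] object.
#' @return A one-row `data.frame` with class `sector_fractions`: columns
#'   `phi_R`, `phi_M`, `phi_U`, `phi_Q`, `um_ratio`.
#' @export
solve_sectors <- function(phi_R, um_ratio, params = allocation_params()) {
  assert_number(phi_R, "phi_R", lower = 0)
  assert_number(um_ratio, "um_ratio", lower = 0)
  stop_if(phi_R >= params$phi_max,
          paste0("infeasible partition: phi_R (%.4g) >= phi_max (%.4g), ",
                 "no proteome left for the M sector"),
          phi_R, params$phi_max)
  phi_M <- (params$phi_max - phi_R) / (1 + um_ratio)
  phi_U <- phi_M * um_ratio
  phi_Q <- 1 - params$phi_max
  out <- data.frame(phi_R = phi_R, phi_M = phi_M, phi_U = phi_U,
                    phi_Q = phi_Q, um_ratio = um_ratio)
  class(out) <- c("sector_fractions", "data.frame")
  out
}

#' Translational and metabolic efficiencies
#'
#' From `lambda = tE * phi_R = mE * phi_M`: `tE = lambda/phi_R`,
#' `mE = lambda/phi_M`, and the efficiency ratio `mE/tE = phi_R/phi_M`.
#'
#' @param lambda Growth rate (1/h), > 0.
#' @param fractions A `sector_fractions` row (from [solve_sectors()]) with
#'   positive `phi_R` and `phi_M`.
#' @return A one-row `data.frame`: `lambda`, `tE`, `mE`, `me_te_ratio`.
#' @export
efficiencies <- function(lambda, fractions) {
  assert_number(lambda, "lambda", lower = 0, strict_lower = TRUE)
  phi_R <- fractions$phi_R
  phi_M <- fractions$phi_M
  stop_if(phi_R <= 0 || phi_M <= 0,
          "efficiencies undefined: phi_R and phi_M must be > 0")
  data.frame(lambda = lambda,
             tE = lambda / phi_R,
             mE = lambda / phi_M,
             me_te_ratio = phi_R / phi_M)
}

#' Efficiency-ratio fold change of a mutant relative to wild type
#'
#' @param mutant_ratio,wt_ratio `mE/tE` ratios; `wt_ratio` must be > 0.
#' @return `mutant_ratio / wt_ratio`.
#' @export
fold_change_vs_wt <- function(mutant_ratio, wt_ratio) {
  stop_if(!is.numeric(wt_ratio) || any(wt_ratio <= 0),
          "'wt_ratio' must be > 0")
  mutant_ratio / wt_ratio
}

#' Unused ribosomal fraction
#'
#' Treating the wild-type translational efficiency as the optimum, any R
#' sector beyond what that efficiency requires at the observed growth rate
#' is unused ribosome capacity: `max(0, phi_R - lambda/tE_wt)`.
#'
#' @param phi_R Ribosomal fraction of the strain.
#' @param lambda Growth rate of the strain (1/h).
#' @param tE_wt Wild-type translational efficiency, > 0.
#' @return Unused ribosomal proteome fraction, >= 0. Reported as a
#'   diagnostic; never fed back into the partition.
#' @export
unused_ribosome_fraction <- function(phi_R, lambda, tE_wt) {
  assert_number(tE_wt, "tE_wt", lower = 0, strict_lower = TRUE)
  pmax(0, phi_R - lambda / tE_wt)
}

#' Convert a biomass-specific concentration to millimolar
#'
#' Divides micromoles per gram dry cell weight by the specific cell volume
#' (2.3 microliter/mg = 2.3 mL/g), so units reduce to micromol/mL = mM.
#' Used e.g. to compare intracellular alpha-ketoglutarate with the 1.3 mM
#' inhibition constant of the PTS first enzyme.
#'
#' @param conc_umol_per_gdcw Concentration in micromol/gDCW, >= 0.
#' @param cell_volume Specific cell volume in microliter/mg DCW (default 2.3).
#' @return Concentration in mM.
#' @export
to_millimolar <- function(conc_umol_per_gdcw, cell_volume = 2.3) {
  assert_number(cell_volume, "cell_volume", lower = 0, strict_lower = TRUE)
  stop_if(any(conc_umol_per_gdcw < 0), "concentrations must be >= 0")
  conc_umol_per_gdcw / cell_volume
}
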