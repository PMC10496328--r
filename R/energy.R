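# Distance/orientation-dependent interaction energies (kcal/mol).
# Negative = favorable; every form decays to zero at large distance and
# is minimal at its stated optimum. The exact published forms live in a
# supplement that is not part of this package; these closed forms preserve
# the distance+orientation dependence and every constant is configurable
# through bond_params().

# vectorized dispatch used by the detectors
energy_for <- function(type, distance, angle, sigma, params) {
  d <- distance
  switch(type,
    HBOND = {
      x <- params$hbond$R0 / d
      fac <- ifelse(is.na(angle), 1, cos(angle * pi / 180)^4)
      params$hbond$D0 * (5 * x^12 - 6 * x^10) * fac
    },
    VDW = {
      x <- sigma / d
      params$vdw$epsilon * (x^12 - 2 * x^6)
    },
    IONIC = {
      # unit opposite formal charges, distance-dependent dielectric eps(d) = s*d
      -params$ionic$coulomb_k / (params$ionic$dielectric_slope * d^2)
    },
    PIPI = -params$pipi$E0 * (params$pipi$d_ref / d)^2,
    PICATION = {
      fac <- ifelse(is.na(angle), 1, cos(angle * pi / 180)^2)
      -params$pication$E0 * fac * (params$pication$d_ref / d)^2
    },
    HYDROPHOBIC = {
      p <- params$hydrophobic
      e <- -p$E0 * (1 - (d - p$d_onset) / (params$hydrophobic$d_max - p$d_onset))
      pmin(0, pmax(-p$E0, e))
    },
    CA_CONTACT = rep(0, length(d)),
    stop(sprintf("unknown bond type '%s'", type), call. = FALSE)
  )
}

#' Energy of a single contact
#'
#' Recomputes the energy of a contact record from its type, distance and
#' (where applicable) angle. An angular form evaluated without an angle
#' falls back to the angle-independent factor 1 with a warning.
#'
#' @param contact A single contact: one row of a contact data frame (or a
#'   list with fields `bond_type`, `distance`, `angle`, and `sigma` for
#'   van der Waals contacts).
#' @param params A `bond_params` object.
#' @return Energy in kcal/mol (negative = favorable).
#' @export
bond_energy <- function(contact, params = bond_params()) {
  type <- as.character(contact$bond_type)
  ang <- if (!is.null(contact$angle)) contact$angle else NA_real_
  if (type %in% c("HBOND", "PICATION") && is.na(ang))
    warning(sprintf("%s energy evaluated without an angle; using factor 1", type),
            call. = FALSE)
  sigma <- if (!is.null(contact$sigma)) contact$sigma else NA_real_
  if (type == "VDW" && is.na(sigma))
    stop("bond_energy: VDW contact needs `sigma` (sum of vdW radii)", call. = FALSE)
  energy_for(type, contact$distance, ang, sigma, params)
}
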