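#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D`, where `tau_DA` is the donor lifetime in the
#' presence of the acceptor and `tau_D` the donor-only reference lifetime.
#'
#' @param tau_da_ns Donor lifetime with acceptor, ns (0 < tau_DA < tau_D).
#' @param tau_d_ns Donor-only lifetime, ns.
#' @return Efficiency in (0, 1). Vectorized.
#' @examples
#' fret_efficiency(1.3, 3.0)
#' @export
fret_efficiency <- function(tau_da_ns, tau_d_ns) {
  if (any(tau_da_ns <= 0) || any(tau_d_ns <= 0))
    stop("lifetimes must be positive")
  if (any(tau_da_ns >= tau_d_ns))
    stop("non-physical efficiency: tau_DA must be below tau_D")
  1 - tau_da_ns / tau_d_ns
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts the Forster relation: `r = r0 * ((1 - E) / E)^(1/6)`.
#'
#' @param e Efficiency in (0, 1).
#' @param r0_nm Forster distance of the dye pair, nm (8.4 for
#'   SNAP-Surface 594/Cy5; 7.5 for SNAP-Surface 594/Atto 647N).
#' @return Distance in nm. Vectorized.
#' @examples
#' distance_from_efficiency(0.5, 8.4)   # exactly r0
#' @export
distance_from_efficiency <- function(e, r0_nm) {
  if (any(r0_nm <= 0)) stop("r0_nm must be positive")
  if (any(e <= 0) || any(e >= 1))
    stop("efficiency must lie strictly inside (0, 1): distance undefined at the limits")
  r0_nm * ((1 - e) / e)^(1 / 6)
}

#' Efficiency at a given donor-acceptor distance
#'
#' The forward Forster relation `E = 1 / (1 + (r/r0)^6)`.
#'
#' @param r_nm Distance, nm.
#' @param r0_nm Forster distance, nm.
#' @return Efficiency in (0, 1). Vectorized.
#' @export
efficiency_from_distance <- function(r_nm, r0_nm) {
  if (any(r_nm <= 0) || any(r0_nm <= 0)) stop("distances must be positive")
  1 / (1 + (r_nm / r0_nm)^6)
}

#' Recover the donor-only reference lifetime from peak/distance pairs
#'
#' Given two consistent (lifetime, distance) pairs -- e.g. the two fitted
#' conformational peaks with their reported distances -- solves
#' `tau_D = tau / (1 - E(r))` for each and returns the mean, flagging the
#' result when the two solutions differ by more than `tol` (relative).
#'
#' @param peak_lifetimes_ns Two peak lifetimes, ns.
#' @param peak_distances_nm The corresponding distances, nm.
#' @param r0_nm Forster distance, nm.
#' @param tol Relative spread above which the pairs are flagged inconsistent.
#' @return List with `tau_d_ns` (mean), `solutions`, `spread`, `flagged`.
#' @examples
#' derive_donor_reference(c(1.3, 2.7), c(8, 12), 8.4)
#' @export
derive_donor_reference <- function(peak_lifetimes_ns, peak_distances_nm,
                                   r0_nm, tol = 0.05) {
  stopifnot(length(peak_lifetimes_ns) == 2, length(peak_distances_nm) == 2)
  e <- efficiency_from_distance(peak_distances_nm, r0_nm)
  sols <- peak_lifetimes_ns / (1 - e)
  spread <- abs(diff(sols)) / mean(sols)
  list(tau_d_ns = mean(sols), solutions = sols, spread = spread,
       flagged = spread > tol)
}

#' FRET calibration for a dye pair
#'
#' Bundles the Forster distance and the donor-only reference lifetime used
#' to convert fitted lifetimes into distances.
#'
#' @param r0_nm Forster distance, nm.
#' @param tau_d_ns Donor-only lifetime, ns.
#' @return An object of class `fret_calibration`.
#' @export
fret_calibration <- function(r0_nm = 8.4, tau_d_ns = 3.0) {
  check_scalar(r0_nm, "r0_nm", positive = TRUE)
  check_scalar(tau_d_ns, "tau_d_ns", positive = TRUE)
  structure(list(r0_nm = r0_nm, tau_d_ns = tau_d_ns),
            class = "fret_calibration")
}

#' Convert a fitted lifetime to a donor-acceptor distance
#'
#' Chains [fret_efficiency()] and [distance_from_efficiency()] under one
#' calibration.
#'
#' @param tau_da_ns Donor lifetime(s) with acceptor, ns.
#' @param calibration A [fret_calibration()].
#' @return Data frame with `tau_da_ns`, `efficiency`, `distance_nm`.
#' @examples
#' lifetime_to_distance(c(1.3, 2.7), fret_calibration(8.4, 3.0))
#' @export
lifetime_to_distance <- function(tau_da_ns, calibration = fret_calibration()) {
  stopifnot(inherits(calibration, "fret_calibration"))
  e <- fret_efficiency(tau_da_ns, calibration$tau_d_ns)
  data.frame(tau_da_ns = tau_da_ns, efficiency = e,
             distance_nm = distance_from_efficiency(e, calibration$r0_nm))
}
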