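#' Draw umbrella-sampling windows from a known free-energy surface
#'
#' Generates per-window samples whose density is proportional to
#' `exp(-U(x) - k/2 (x - c_i)^2)` (energies in kT), the stationary density of
#' a harmonically restrained simulation on the surface `U`. Sampling is by
#' exact rejection against the Gaussian proposal implied by the bias, so the
#' windows are an analytic test bed for WHAM reweighting.
#'
#' @param potential Free-energy surface in kT: a function of the collective
#'   variable, finite on `domain`.
#' @param centers Numeric vector of window centres (must lie in `domain`).
#' @param spring_k Harmonic bias constant, kT per CV^2.
#' @param n_samples Samples per window.
#' @param seed Integer seed.
#' @param domain Closed interval on which `potential` is defined.
#' @param cv_name Collective-variable label stored with the windows.
#' @return A list of `umbrella_window` objects, each with fields `center`,
#'   `spring_k`, `samples`, `cv_name`.
#' @examples
#' w <- simulate_umbrella_windows(function(x) 0 * x, centers = 0,
#'                                spring_k = 25, n_samples = 500, seed = 1)
#' sd(w[[1]]$samples)  # ~ 1/sqrt(25)
#' @export
simulate_umbrella_windows <- function(potential, centers, spring_k, n_samples,
                                      seed, domain = NULL,
                                      cv_name = "custom") {
  if (!is.function(potential)) stop("'potential' must be a function")
  if (length(centers) < 1) stop("empty centers rejected")
  check_scalar(spring_k, "spring_k", positive = TRUE)
  check_scalar(n_samples, "n_samples", positive = TRUE)
  sd0 <- 1 / sqrt(spring_k)
  domain <- domain %||% c(min(centers) - 8 * sd0, max(centers) + 8 * sd0)
  if (any(centers < domain[1] | centers > domain[2]))
    stop("centers must lie within the potential domain")
  probe <- potential(seq(domain[1], domain[2], length.out = 2001))
  if (any(!is.finite(probe))) stop("potential must be finite on its domain")

  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    c0 <- centers[i]
    lo <- max(domain[1], c0 - 8 * sd0); hi <- min(domain[2], c0 + 8 * sd0)
    u_min <- min(potential(seq(lo, hi, length.out = 2001)))
    s <- with_seed(child_seed(seed, stage_index("wham"), i), {
      out <- numeric(0)
      while (length(out) < n_samples) {
        x <- stats::rnorm(2 * n_samples, c0, sd0)
        x <- x[x >= domain[1] & x <= domain[2]]
        keep <- stats::runif(length(x)) < exp(-(potential(x) - u_min))
        out <- c(out, x[keep])
      }
      out[seq_len(n_samples)]
    })
    windows[[i]] <- structure(list(center = c0, spring_k = spring_k,
                                   samples = s, cv_name = cv_name),
                              class = "umbrella_window")
  }
  windows
}

#' Simulate coarse-grained bead frames
#'
#' Places labelled beads uniformly in a cubic box, as a fixture for the
#' contact-number and inter-residue distance metrics. ATP-site beads are
#' assigned residue numbers cycling through the canonical ATP-binding-site
#' residue set; lipid beads carry residue 0. A `coords_override` data frame
#' (`bead_id`, `residue`, `group`, `x`, `y`, `z`, coordinates in Angstrom)
#' bypasses random placement entirely.
#'
#' @param n_frames Number of frames.
#' @param n_lipid_beads,n_site_beads,n_other_beads Bead counts per group.
#' @param box_nm Cubic box edge, nm (coordinates are stored in Angstrom).
#' @param seed Integer seed.
#' @param coords_override Optional explicit coordinates (single frame).
#' @return A list of `cg_frame` objects with fields `coordinates` (n x 3
#'   matrix, Angstrom), `residue`, `group`, `box` (Angstrom, or NULL when an
#'   override is supplied).
#' @export
simulate_bead_frames <- function(n_frames, n_lipid_beads, n_site_beads,
                                 box_nm, seed, n_other_beads = 0,
                                 coords_override = NULL) {
  if (!is.null(coords_override)) {
    co <- as.data.frame(coords_override)
    fr <- cg_frame(as.matrix(co[, c("x", "y", "z")]), co$residue, co$group,
                   box = NULL)
    return(rep(list(fr), n_frames))
  }
  check_scalar(n_frames, "n_frames", positive = TRUE)
  check_scalar(n_lipid_beads, "n_lipid_beads", positive = TRUE)
  check_scalar(n_site_beads, "n_site_beads", positive = TRUE)
  check_scalar(box_nm, "box_nm", positive = TRUE)
  box <- box_nm * 10
  site_res <- atp_site_residues()
  n <- n_lipid_beads + n_site_beads + n_other_beads
  group <- rep(c("lipid", "atp_site", "other"),
               times = c(n_lipid_beads, n_site_beads, n_other_beads))
  residue <- c(rep(0L, n_lipid_beads),
               site_res[(seq_len(n_site_beads) - 1L) %% length(site_res) + 1L],
               if (n_other_beads > 0) 2000L + seq_len(n_other_beads) else integer(0))
  lapply(seq_len(n_frames), function(f) {
    xyz <- with_seed(child_seed(seed, stage_index("contacts"), f),
                     matrix(stats::runif(3 * n, 0, box), ncol = 3))
    cg_frame(xyz, residue, group, box = rep(box, 3))
  })
}

#' Coarse-grained frame container
#'
#' @param coordinates n x 3 matrix of bead positions, Angstrom.
#' @param residue Integer residue label per bead.
#' @param group Group label per bead (e.g. "lipid", "atp_site", "other").
#' @param box Optional orthorhombic box dimensions (length 3), Angstrom.
#' @return An object of class `cg_frame`.
#' @export
cg_frame <- function(coordinates, residue, group, box = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must be n x 3")
  if (nrow(coordinates) != length(residue) || nrow(coordinates) != length(group))
    stop("coordinate count must equal label count")
  structure(list(coordinates = coordinates, residue = as.integer(residue),
                 group = as.character(group), box = box),
            class = "cg_frame")
}

#' Canonical ATP-binding-site residue numbers
#'
#' The kinase-domain residues forming the ATP pocket used by the
#' contact-number metric: 694-703, 719, 766-769, 772-773, 817, 820, 831.
#'
#' @return Integer vector of residue numbers.
#' @export
atp_site_residues <- function() {
  as.integer(c(694:703, 719, 766:769, 772:773, 817, 820, 831))
}
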