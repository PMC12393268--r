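#' Contact definition for ATP-site accessibility
#'
#' The contact number counts coarse-grained bead pairs between the lipid
#' membrane and the ATP binding site that are closer than a strict cutoff
#' (16 Angstrom by default, just below the largest radius of the bound ATP
#' analog), serving as a proxy for how strongly the bilayer occludes the
#' nucleotide pocket.
#'
#' @param cutoff_angstrom Strict distance cutoff, Angstrom.
#' @param site_residues Residue numbers defining the ATP binding site.
#' @param partner_group Bead group counted against the site (default
#'   "lipid").
#' @return An object of class `contact_definition`.
#' @export
contact_definition <- function(cutoff_angstrom = 16,
                               site_residues = atp_site_residues(),
                               partner_group = "lipid") {
  check_scalar(cutoff_angstrom, "cutoff_angstrom", positive = TRUE)
  if (length(site_residues) == 0) stop("site residue set must be non-empty")
  structure(list(cutoff_angstrom = cutoff_angstrom,
                 site_residues = as.integer(site_residues),
                 partner_group = partner_group),
            class = "contact_definition")
}

## minimum-image displacement components
min_image <- function(dx, box) {
  if (is.null(box)) return(dx)
  sweep_box <- matrix(box, nrow(dx), 3, byrow = TRUE)
  dx - sweep_box * round(dx / sweep_box)
}

pair_counts_brute <- function(A, B, cutoff, box) {
  n <- 0L
  for (i in seq_len(nrow(A))) {
    dx <- sweep(B, 2, A[i, ])
    dx <- min_image(dx, box)
    n <- n + sum(rowSums(dx^2) < cutoff^2)
  }
  n
}

pair_counts_grid <- function(A, B, cutoff, box) {
  ## cell list with cell edge >= cutoff; wraps cells when a box is present
  if (is.null(box)) {
    lo <- pmin(apply(A, 2, min), apply(B, 2, min))
    span <- pmax(apply(A, 2, max), apply(B, 2, max)) - lo + 1e-9
    wrap <- FALSE
  } else {
    lo <- c(0, 0, 0); span <- box; wrap <- TRUE
    A <- sweep(A, 2, box, "%%"); B <- sweep(B, 2, box, "%%")
  }
  ncell <- pmax(1L, floor(span / cutoff))
  edge <- span / ncell
  cell_idx <- function(X) {
    ix <- floor(sweep(sweep(X, 2, lo), 2, edge, "/"))
    sweep(ix, 2, ncell - 1, pmin)
  }
  cb3 <- cell_idx(B)
  cb <- cb3[, 1] + ncell[1] * (cb3[, 2] + ncell[2] * cb3[, 3]) + 1
  Bsplit <- split(seq_len(nrow(B)), cb)
  ca_idx <- cell_idx(A)
  total <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(A))) {
    neigh <- sweep(offs, 2, ca_idx[i, ], "+")
    if (wrap) neigh <- sweep(neigh, 2, ncell, "%%")
    keep <- neigh[, 1] >= 0 & neigh[, 1] < ncell[1] &
            neigh[, 2] >= 0 & neigh[, 2] < ncell[2] &
            neigh[, 3] >= 0 & neigh[, 3] < ncell[3]
    ids <- unique(neigh[keep, 1] + ncell[1] * (neigh[keep, 2] + ncell[2] * neigh[keep, 3]) + 1)
    cand <- unlist(Bsplit[as.character(ids)], use.names = FALSE)
    if (length(cand) == 0) next
    dx <- sweep(B[cand, , drop = FALSE], 2, A[i, ])
    dx <- min_image(dx, if (wrap) box else NULL)
    total <- total + sum(rowSums(dx^2) < cutoff^2)
  }
  total
}

#' Lipid contact number of the ATP binding site
#'
#' Counts bead pairs (site bead, partner-group bead) with Euclidean distance
#' strictly below the cutoff, with the minimum-image convention when the
#' frame carries box dimensions. Site beads are those whose residue number
#' belongs to the definition's residue set; partner beads are those whose
#' group label equals `partner_group`. The default implementation uses a
#' spatial cell grid; `method = "brute"` is the all-pairs reference.
#'
#' @param frame A [cg_frame()].
#' @param definition A [contact_definition()].
#' @param method "grid" (cell list) or "brute" (all pairs).
#' @return Nonnegative integer pair count.
#' @export
contact_number <- function(frame, definition = contact_definition(),
                           method = c("grid", "brute")) {
  stopifnot(inherits(frame, "cg_frame"), inherits(definition, "contact_definition"))
  method <- match.arg(method)
  is_partner <- frame$group == definition$partner_group
  is_site <- !is_partner & frame$residue %in% definition$site_residues
  if (!any(is_site) || !any(is_partner))
    stop("frame must contain at least one bead in each group")
  A <- frame$coordinates[is_site, , drop = FALSE]
  B <- frame$coordinates[is_partner, , drop = FALSE]
  fn <- if (method == "grid") pair_counts_grid else pair_counts_brute
  as.integer(fn(A, B, definition$cutoff_angstrom, frame$box))
}

#' Distance between two residues' bead centroids
#'
#' Euclidean distance between the centroids of the beads carrying each
#' residue number (minimum image applied to the centroid difference when the
#' frame is boxed). Residue 721 marks the ATP binding site and residue 1186
#' the receptor C-terminus in the canonical use.
#'
#' @param frame A [cg_frame()].
#' @param residue_a,residue_b Residue numbers.
#' @param units "angstrom" (default) or "nm".
#' @return Distance (scalar).
#' @export
residue_distance <- function(frame, residue_a = 721, residue_b = 1186,
                             units = c("angstrom", "nm")) {
  stopifnot(inherits(frame, "cg_frame"))
  units <- match.arg(units)
  ia <- frame$residue == residue_a
  ib <- frame$residue == residue_b
  if (!any(ia) || !any(ib))
    stop("both residues must be present in the frame")
  ca <- colMeans(frame$coordinates[ia, , drop = FALSE])
  cb <- colMeans(frame$coordinates[ib, , drop = FALSE])
  dx <- min_image(matrix(cb - ca, 1, 3), frame$box)
  d <- sqrt(sum(dx^2))
  if (units == "nm") d / 10 else d
}
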