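#' Read and write the plain-text photon container
#'
#' The photon dialect is a CSV with header
#' `molecule_id,macrotime_s,microtime_ns,channel`, one photon per row,
#' possibly holding many molecules. Ground-truth labels from the simulator
#' travel in a sidecar CSV `molecule_id,state,expected_lifetime_ns`.
#'
#' @param traces A list of [photon_trace()] objects (or a single one).
#' @param path Output file.
#' @return `write_photon_csv` returns `path` invisibly; `read_photon_csv`
#'   returns a list of [photon_trace()].
#' @export
write_photon_csv <- function(traces, path) {
  if (inherits(traces, "photon_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(molecule_id = tr$molecule_id, macrotime_s = tr$macrotimes_s,
               microtime_ns = tr$microtimes_ns, channel = tr$channels,
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(molecule_id = character(0), macrotime_s = numeric(0),
                     microtime_ns = numeric(0), channel = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photon_csv
#' @param window_ns TCSPC window attached to the traces on read, ns.
#' @export
read_photon_csv <- function(path, window_ns = 12.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$molecule_id), function(d) {
    d <- d[order(d$macrotime_s), ]
    photon_trace(d$molecule_id[1], untie(d$macrotime_s), d$microtime_ns,
                 d$channel, window_ns)
  })
}

#' Write simulator ground-truth labels
#'
#' @param labels Data frame `molecule_id`, `state`, `expected_lifetime_ns`.
#' @param path Output file.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels[c("molecule_id", "state", "expected_lifetime_ns")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected segments or accepted FRET levels
#'
#' Segments: `molecule_id,channel,start_bin,end_bin,mean_rate`. Levels:
#' `molecule_id,level_index,start_photon,end_photon,n_photons`.
#'
#' @param segments Data frame of segments with a `molecule_id` column.
#' @param path Output file.
#' @export
write_segments_csv <- function(segments, path) {
  utils::write.csv(segments[c("molecule_id", "channel", "start_bin",
                              "end_bin", "mean_rate")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @param levels List of `fret_level` objects.
#' @export
write_levels_csv <- function(levels, path) {
  df <- do.call(rbind, lapply(levels, function(l)
    data.frame(molecule_id = l$molecule_id, level_index = l$level_index,
               start_photon = l$photon_range[1], end_photon = l$photon_range[2],
               n_photons = l$n_photons, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(molecule_id = character(0), level_index = integer(0),
                     start_photon = integer(0), end_photon = integer(0),
                     n_photons = integer(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-bunch lifetime estimates
#'
#' Columns `molecule_id,level_index,bunch_index,n_photons,lifetime_ns,flagged`.
#'
#' @param bunches Data frame from [fit_trace_lifetimes()].
#' @param path Output file.
#' @export
write_bunches_csv <- function(bunches, path) {
  utils::write.csv(bunches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bunches_csv
#' @export
read_bunches_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write umbrella-window samples
#'
#' CSV dialect `window_id,center,spring_k,sample`, one sample per row.
#'
#' @param windows List of `umbrella_window` objects.
#' @param path File path.
#' @return `read_umbrella_csv` returns a list of `umbrella_window`.
#' @export
write_umbrella_csv <- function(windows, path) {
  df <- do.call(rbind, lapply(seq_along(windows), function(i)
    data.frame(window_id = i, center = windows[[i]]$center,
               spring_k = windows[[i]]$spring_k,
               sample = windows[[i]]$samples)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_umbrella_csv
#' @export
read_umbrella_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$window_id), function(d)
    structure(list(center = d$center[1], spring_k = d$spring_k[1],
                   samples = d$sample, cv_name = "custom"),
              class = "umbrella_window"))
}

#' Read coarse-grained bead coordinates
#'
#' Two minimal formats: a CSV `bead_id,residue,group,x,y,z` (coordinates in
#' Angstrom), or a minimal PDB subset (ATOM/HETATM records; beads whose
#' residue name appears in `lipid_resnames` are labelled "lipid", all others
#' "protein").
#'
#' @param path File path.
#' @param box Optional box dimensions, Angstrom.
#' @return A [cg_frame()].
#' @export
read_beads_csv <- function(path, box = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cg_frame(as.matrix(df[c("x", "y", "z")]), df$residue, df$group, box = box)
}

#' @rdname read_beads_csv
#' @param lipid_resnames PDB residue names mapped to the "lipid" group.
#' @export
read_beads_pdb <- function(path, box = NULL,
                           lipid_resnames = c("POPC", "POPS", "DMPC", "CHOL")) {
  lines <- readLines(path)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  resname <- trimws(substr(rec, 18, 21))  # 4-char residue names included
  resid <- as.integer(trimws(substr(rec, 23, 26)))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  group <- ifelse(resname %in% lipid_resnames, "lipid", "protein")
  cg_frame(cbind(x, y, z), resid, group, box = box)
}

#' Read a condition manifest
#'
#' YAML mapping of condition ids to measurement metadata: each entry has
#' `lipid_label`, `egf` (logical), `r0_nm` and optionally `tau_d_ns`.
#'
#' @param path YAML file.
#' @return Data frame `condition_id`, `lipid_label`, `egf`, `r0_nm`,
#'   `tau_d_ns`.
#' @export
read_condition_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(names(y), function(id)
    data.frame(condition_id = id,
               lipid_label = y[[id]]$lipid_label %||% NA_character_,
               egf = isTRUE(y[[id]]$egf),
               r0_nm = y[[id]]$r0_nm %||% 8.4,
               tau_d_ns = y[[id]]$tau_d_ns %||% 3.0,
               stringsAsFactors = FALSE)))
}
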