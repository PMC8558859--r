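# Plain-text interchange: tabular trajectories, umbrella windows with JSON
# metadata, energy records as CSV, PMFs and spectra as two-column text,
# and PDB structure files (via bio3d; PDB is in Angstrom, internal
# coordinates are nm).

#' Read a protofilament layer from a PDB file
#'
#' Reads the first model of a PDB file and returns the layer atom table
#' used by [build_supercell()], converting Angstrom to nm. Works for real
#' cryo-EM protofilament layers (e.g. one layer extracted from the tau
#' fibril structures 5O3L or 6GX5) as well as toy layers written by
#' [write_layer_pdb()].
#'
#' @param file PDB path.
#' @return Data frame with columns `elety`, `resid`, `resno`, `x`, `y`,
#'   `z` (nm).
#' @export
read_layer_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  data.frame(elety = a$elety, resid = a$resid, resno = a$resno,
             x = a$x / 10, y = a$y / 10, z = a$z / 10)
}

#' Write a layer or fibril model to PDB
#'
#' `write_layer_pdb()` writes a single layer; `write_fibril_pdb()` writes
#' a built supercell with per-layer chain identifiers and a CRYST1 record
#' whose c axis carries the periodic cell height `n_layers * rise`.
#' Coordinates are converted from nm to Angstrom. Residue numbers are
#' written per layer (PDB's fixed columns cannot hold the 1000-per-layer
#' global offsets, which remain available in the model's atom table).
#'
#' @param layer,model objects to write.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_layer_pdb <- function(layer, file) {
  check_layer(layer)
  bio3d::write.pdb(file = file, xyz = as.numeric(t(as.matrix(
                     layer[, c("x", "y", "z")]))) * 10,
                   resno = layer$resno, resid = layer$resid,
                   elety = layer$elety)
  invisible(file)
}

#' @rdname write_layer_pdb
#' @export
write_fibril_pdb <- function(model, file) {
  stopifnot(inherits(model, "fibril_model"))
  a <- model$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))) * 10,
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   1.0, 1.0, model$n_layers * model$rise * 10,
                   90, 90, 90)
  lines <- readLines(file)
  writeLines(c(cryst, lines), file)
  invisible(file)
}

#' Read and write tabular ligand trajectories
#'
#' Plain whitespace-separated tables with columns `frame`, `ligand`,
#' `atom`, `x`, `y`, `z` (nm). Ground-truth labels, when present, travel
#' in a sidecar `<file>.truth.tsv`.
#'
#' @param traj a `ligand_trajectory`.
#' @param file path.
#' @return `write_trajectory()` the path invisibly; `read_trajectory()` a
#'   `ligand_trajectory`.
#' @export
write_trajectory <- function(traj, file) {
  utils::write.table(as.data.frame(traj), file, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  truth <- attr(traj, "truth")
  if (!is.null(truth))
    utils::write.table(truth, paste0(file, ".truth.tsv"), row.names = FALSE,
                       quote = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "ligand", "atom", "x", "y", "z") %in% names(d)))
  truth_file <- paste0(file, ".truth.tsv")
  structure(d,
            truth = if (file.exists(truth_file))
              utils::read.table(truth_file, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE),
            class = c("ligand_trajectory", "data.frame"))
}

#' Read and write umbrella-sampling windows
#'
#' One single-column sample file per window (`window_###.tsv`) plus a JSON
#' metadata file (`windows.json`) holding centers, force constants and the
#' temperature.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param dir directory (created if needed).
#' @return `write_umbrella_windows()` the directory invisibly;
#'   `read_umbrella_windows()` the list of windows.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    fn <- sprintf("window_%03d.tsv", i)
    utils::write.table(data.frame(xi = w$samples), file.path(dir, fn),
                       row.names = FALSE, quote = FALSE, sep = "\t")
    list(file = fn, center = w$center, k_umb = w$k_umb,
         temperature = w$temperature)
  })
  jsonlite::write_json(meta, file.path(dir, "windows.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_umbrella_windows
#' @export
read_umbrella_windows <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "windows.json"),
                              simplifyVector = FALSE)
  lapply(meta, function(m) {
    s <- utils::read.table(file.path(dir, m$file), header = TRUE, sep = "\t")
    umbrella_window(m$center, m$k_umb, s$xi, m$temperature)
  })
}

#' Write a PMF, spectrum or density map as plain text
#'
#' PMFs and spectra are written as two-column tables; density maps as a
#' count matrix with bin-center row/column headers.
#'
#' @param x a `pmf_profile`, `spectrum_result` or `density_map`.
#' @param file path.
#' @return The path, invisibly.
#' @export
write_profile <- function(x, file) {
  if (inherits(x, "density_map")) {
    m <- x$counts
    dimnames(m) <- list(sprintf("%.4f", x$x_mid), sprintf("%.4f", x$y_mid))
    utils::write.table(m, file, quote = FALSE, sep = "\t",
                       col.names = NA)
    return(invisible(file))
  }
  d <- if (inherits(x, "pmf_profile"))
    data.frame(xi_nm = x$xi, free_energy_kJ_mol = x$free_energy)
  else if (inherits(x, "spectrum_result"))
    data.frame(energy_eV = x$energy, intensity = x$intensity)
  else stop("unsupported object", call. = FALSE)
  utils::write.table(d, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}
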