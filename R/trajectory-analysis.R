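# Trajectory analysis: axis-collapsed ligand density maps, binding-mode
# classification, mode populations and residence times, ligand planarity,
# and per-residue interaction-energy aggregation.

#' Binding-site definition
#'
#' A binding site is defined by a triad of consecutive residues (e.g.
#' Ile360/Thr361/His362 for site A of the Alzheimer-fold tau fibril), two
#' reference ("anchor") atoms that orient the in-plane axis of the site
#' frame, and a membership cutoff: a ligand is considered bound when its
#' charge center lies within `cutoff` nm of the triad CA centroid
#' (0.7 nm, a typical first-shell contact distance, by default).
#'
#' @param triad three distinct residue numbers.
#' @param his_anchor,ile_anchor lists `list(resno =, elety =)` selecting
#'   the two anchor atoms (named after the His/Ile anchors of tau site A;
#'   any two atoms spanning the site work).
#' @param cutoff membership cutoff in nm (> 0).
#' @return A `site_definition` object.
#' @export
site_definition <- function(triad, his_anchor, ile_anchor, cutoff = 0.7) {
  if (length(triad) != 3 || anyDuplicated(triad))
    stop("triad must be three distinct residue numbers", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be > 0", call. = FALSE)
  stopifnot(is.list(his_anchor), is.list(ile_anchor))
  structure(list(triad = triad, his_anchor = his_anchor,
                 ile_anchor = ile_anchor, cutoff = cutoff),
            class = "site_definition")
}

atom_xyz <- function(fibril, layer, resno, elety) {
  a <- fibril$atoms
  sel <- a$layer == layer & a$resno == resno & a$elety == elety
  if (!any(sel))
    stop(sprintf("atom %s of residue %s not found in layer %d",
                 elety, resno, layer), call. = FALSE)
  as.numeric(a[which(sel)[1], c("x", "y", "z")])
}

#' Local binding-site frame
#'
#' Builds the orthonormal frame used for mode classification: z is the
#' fibril axis, x is the unit projection of (Ile-anchor - His-anchor)
#' perpendicular to z, and y = z x x. The site center is the CA centroid
#' of the triad in the chosen layer.
#'
#' @param fibril a `fibril_model`.
#' @param site a [site_definition()].
#' @param layer 0-indexed layer; defaults to the middle layer.
#' @return List `origin` (site center), `x`, `y`, `z`, `cutoff`.
#' @export
site_frame <- function(fibril, site, layer = NULL) {
  stopifnot(inherits(fibril, "fibril_model"),
            inherits(site, "site_definition"))
  if (is.null(layer)) layer <- (fibril$n_layers - 1L) %/% 2L
  fr <- axis_frame(fibril)
  z <- fr$z
  his <- atom_xyz(fibril, layer, site$his_anchor$resno, site$his_anchor$elety)
  ile <- atom_xyz(fibril, layer, site$ile_anchor$resno, site$ile_anchor$elety)
  v <- (ile - his) - sum((ile - his) * z) * z
  if (sqrt(sum(v^2)) < 1e-9)
    stop("site anchors are collinear with the fibril axis", call. = FALSE)
  x <- unit(v)
  list(origin = triad_centroid(fibril, site, layer),
       x = x, y = cross3(z, x), z = z, cutoff = site$cutoff)
}

# ---- density map -----------------------------------------------------------

#' Axis-collapsed ligand density map
#'
#' Projects the ligand reference atoms of every frame onto the fibril
#' cross-section plane and bins them on a square grid, summing along the
#' fibril axis. With `untwist = TRUE` (default) each point is first rotated
#' about the axis by minus (nearest layer index x generator rotation), so
#' that symmetry-equivalent positions on different layers superpose — the
#' map then shows the ligand density around one protofilament layer, as if
#' all layers were overlaid.
#'
#' @param traj a `ligand_trajectory`.
#' @param fibril the `fibril_model` the trajectory was generated around.
#' @param bin_size grid spacing in nm (> 0).
#' @param untwist logical; undo the per-layer helical rotation before
#'   binning.
#' @param reference_atom ligand atom used as the density marker.
#' @param limits optional list(x =, y =) of length-2 ranges (nm) in the
#'   cross-section frame; defaults to the data extent.
#' @return A `density_map` object: counts matrix with bin-center
#'   coordinates, the per-frame normalized density, and the out-of-domain
#'   count. Invariant: `sum(counts) + out_of_domain` equals the number of
#'   binned reference points.
#' @export
density_map <- function(traj, fibril, bin_size = 0.1, untwist = TRUE,
                        reference_atom = "CHG", limits = NULL) {
  stopifnot(inherits(traj, "ligand_trajectory"),
            inherits(fibril, "fibril_model"))
  if (!is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be > 0", call. = FALSE)
  pts <- traj[traj$atom == reference_atom, , drop = FALSE]
  if (nrow(pts) == 0) stop("trajectory has no reference atoms", call. = FALSE)
  fr <- axis_frame(fibril)
  rel <- sweep(as.matrix(pts[, c("x", "y", "z")]), 2, fr$origin)
  ax <- rel %*% cbind(fr$x, fr$y, fr$z)  # coords in the axis frame
  if (untwist) {
    gen <- generator_rotation(fibril$twist, fibril$screw_order)
    k <- round(ax[, 3] / fibril$rise)
    th <- (-k * gen) * pi / 180
    u <- ax[, 1] * cos(th) - ax[, 2] * sin(th)
    v <- ax[, 1] * sin(th) + ax[, 2] * cos(th)
  } else {
    u <- ax[, 1]; v <- ax[, 2]
  }
  if (is.null(limits))
    limits <- list(x = range(u), y = range(v))
  xb <- seq(floor(limits$x[1] / bin_size) * bin_size,
            limits$x[2] + bin_size, by = bin_size)
  yb <- seq(floor(limits$y[1] / bin_size) * bin_size,
            limits$y[2] + bin_size, by = bin_size)
  inside <- u >= xb[1] & u <= xb[length(xb)] & v >= yb[1] & v <= yb[length(yb)]
  ix <- findInterval(u[inside], xb, rightmost.closed = TRUE)
  iy <- findInterval(v[inside], yb, rightmost.closed = TRUE)
  counts <- matrix(0L, length(xb) - 1L, length(yb) - 1L)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  n_frames <- length(unique(traj$frame))
  structure(list(
    counts = counts,
    x_mid = xb[-1] - bin_size / 2,
    y_mid = yb[-1] - bin_size / 2,
    density = counts / n_frames,
    bin_size = bin_size,
    frame_count = n_frames,
    ligand_count = length(unique(traj$ligand)),
    out_of_domain = sum(!inside),
    untwist = untwist
  ), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map:", nrow(x$counts), "x", ncol(x$counts), "bins of",
      x$bin_size, "nm;", sum(x$counts), "points in domain,",
      x$out_of_domain, "outside\n")
  invisible(x)
}

#' @export
plot.density_map <- function(x, ...) {
  graphics::image(x$x_mid, x$y_mid, x$density,
                  xlab = "x (nm)", ylab = "y (nm)",
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}

#' Position of the density maximum
#'
#' @param map a [density_map()].
#' @return Length-2 bin-center coordinates (nm) of the highest-count bin.
#' @export
density_argmax <- function(map) {
  stopifnot(inherits(map, "density_map"))
  i <- which(map$counts == max(map$counts), arr.ind = TRUE)[1, ]
  c(x = map$x_mid[i[1]], y = map$y_mid[i[2]])
}

# ---- mode classification ---------------------------------------------------

#' Classify the major binding mode of one ligand configuration
#'
#' The major mode combines the up/down (U/D) and left/right (L/R)
#' orientation of the ethyl vector `e = ETC - THZ` (ethyl terminal carbon
#' minus thiazole-ring centroid) in the site frame: U when `e . z > 0`
#' (ties resolved to U), R when `e . y > 0` (ties resolved to L). A ligand
#' whose charge center is farther than the site cutoff from the site
#' center is `"unbound"`.
#'
#' @param atoms named coordinate matrix of the ligand's labeled
#'   pseudo-atoms (rows `THZ`, `ETC`, `CHG` are required).
#' @param frame a [site_frame()].
#' @return One of `"UL"`, `"UR"`, `"DL"`, `"DR"`, `"unbound"`.
#' @export
classify_major_mode <- function(atoms, frame) {
  need <- c("THZ", "ETC", "CHG")
  if (!all(need %in% rownames(atoms)))
    stop("ligand atoms must include labeled rows THZ, ETC, CHG",
         call. = FALSE)
  chg <- atoms["CHG", ]
  if (sqrt(sum((chg - frame$origin)^2)) > frame$cutoff) return("unbound")
  e <- atoms["ETC", ] - atoms["THZ", ]
  ud <- if (sum(e * frame$z) >= 0) "U" else "D"
  lr <- if (sum(e * frame$y) > 0) "R" else "L"
  paste0(ud, lr)
}

#' Classify the minor conformer from two backbone dihedrals
#'
#' Each dihedral is binned by the sign of its cosine (cis-like vs
#' trans-like), giving 4 minor conformers: index
#' `2 * (cos d1 < 0) + (cos d2 < 0)` with `d1` the first (thiazole-ethyl)
#' and `d2` the second (bi-thiophene inter-ring) dihedral.
#'
#' @param atoms named coordinate matrix of ligand pseudo-atoms.
#' @param dihedrals list of two character 4-vectors of atom labels;
#'   defaults to the toy-ligand proxies `(VIN,BZC,THZ,ETC)` and
#'   `(BTC,VIN,BZC,THZ)`.
#' @return Integer 0-3.
#' @export
classify_minor_mode <- function(atoms,
                                dihedrals = list(
                                  c("VIN", "BZC", "THZ", "ETC"),
                                  c("BTC", "VIN", "BZC", "THZ"))) {
  stopifnot(length(dihedrals) == 2)
  d <- vapply(dihedrals, function(q) {
    if (!all(q %in% rownames(atoms)))
      stop("ligand atoms lack dihedral labels: ",
           paste(setdiff(q, rownames(atoms)), collapse = ", "), call. = FALSE)
    dihedral_angle(atoms[q[1], ], atoms[q[2], ], atoms[q[3], ], atoms[q[4], ])
  }, numeric(1))
  as.integer(2 * (cos(d[1] * pi / 180) < 0) + (cos(d[2] * pi / 180) < 0))
}

#' Classify all frames of a ligand trajectory
#'
#' Applies [classify_major_mode()] and, for bound configurations,
#' [classify_minor_mode()] to every (frame, ligand). The site frame is
#' anchored on the layer whose triad centroid is nearest to the ligand, so
#' ligands bound anywhere along the fibril are classified in their local
#' frame.
#'
#' @param traj a `ligand_trajectory`.
#' @param fibril the `fibril_model`.
#' @param site a [site_definition()]; defaults to the trajectory's own
#'   site attribute.
#' @return Data frame `frame`, `ligand`, `major`, `minor` (minor is `NA`
#'   for unbound rows).
#' @export
classify_modes <- function(traj, fibril, site = attr(traj, "site")) {
  stopifnot(inherits(traj, "ligand_trajectory"))
  if (is.null(site)) stop("no site definition available", call. = FALSE)
  frames_by_layer <- lapply(seq_len(fibril$n_layers) - 1L,
                            function(k) site_frame(fibril, site, k))
  centers <- t(vapply(frames_by_layer, `[[`, numeric(3), "origin"))
  key <- interaction(traj$frame, traj$ligand, drop = TRUE)
  split_rows <- split(seq_len(nrow(traj)), key)
  out <- lapply(split_rows, function(rows) {
    at <- as.matrix(traj[rows, c("x", "y", "z")])
    rownames(at) <- traj$atom[rows]
    d2 <- rowSums(sweep(centers, 2, at["CHG", ])^2)
    fr <- frames_by_layer[[which.min(d2)]]
    maj <- classify_major_mode(at, fr)
    data.frame(frame = traj$frame[rows[1]], ligand = traj$ligand[rows[1]],
               major = maj,
               minor = if (maj == "unbound") NA_integer_
                       else classify_minor_mode(at))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$ligand, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mode populations and residence times
#'
#' Fractions of bound frames in each major mode (summing to 1 over bound
#' frames) and mean residence times, computed as the mean contiguous run
#' length of each label along each ligand's frame sequence times the frame
#' interval.
#'
#' @param labels data frame `frame`, `ligand`, `major` (e.g. from
#'   [classify_modes()] or a trajectory's truth attribute).
#' @param frame_interval_ps time per frame, ps.
#' @return List with `fractions` (named, over bound frames),
#'   `residence_ps` (named mean residence times, including `unbound` when
#'   present), and `n_bound`. With no bound frames, `fractions` is empty
#'   and a warning is raised.
#' @export
mode_populations <- function(labels, frame_interval_ps = 20) {
  stopifnot(all(c("frame", "ligand", "major") %in% names(labels)))
  labels <- labels[order(labels$ligand, labels$frame), , drop = FALSE]
  bound <- labels$major[labels$major != "unbound"]
  runs <- do.call(rbind, lapply(split(labels$major, labels$ligand),
                                function(s) {
                                  r <- rle(as.character(s))
                                  data.frame(mode = r$values, len = r$lengths)
                                }))
  residence <- vapply(split(runs$len, runs$mode), mean, numeric(1)) *
    frame_interval_ps
  if (length(bound) == 0) {
    warning("no bound frames: populations are undefined", call. = FALSE)
    return(list(fractions = numeric(0), residence_ps = residence,
                n_bound = 0L))
  }
  lev <- if (all(bound %in% major_modes)) major_modes else sort(unique(bound))
  fr <- table(factor(bound, levels = lev))
  list(fractions = as.numeric(fr / sum(fr)) |> stats::setNames(names(fr)),
       residence_ps = residence,
       n_bound = length(bound))
}

# ---- planarity -------------------------------------------------------------

#' Conjugated-backbone planarity score
#'
#' Sum of `|cos(theta_i)|` over a set of backbone dihedrals. A fully planar
#' conjugated backbone (all dihedrals at 0 or 180 degrees) scores the
#' number of dihedrals; fully twisted (90 degrees) scores 0. For a ligand
#' with four pi-conjugated backbone dihedrals the score lives on `[0, 4]`,
#' the scale on which near-planar amyloid-bound oligothiophenes score
#' around 3.4-3.5.
#'
#' This is one member of the family of planarity descriptors used for
#' luminescent conjugated oligothiophenes; scores from differently defined
#' descriptors are comparable only in order of magnitude.
#'
#' @param atoms named coordinate matrix of ligand atoms.
#' @param dihedral_set list of character 4-vectors of atom labels.
#' @return Numeric score in `[0, length(dihedral_set)]`.
#' @export
planarity <- function(atoms, dihedral_set) {
  stopifnot(length(dihedral_set) >= 1)
  th <- vapply(dihedral_set, function(q) {
    if (!all(q %in% rownames(atoms)))
      stop("atoms lack dihedral labels: ",
           paste(setdiff(q, rownames(atoms)), collapse = ", "), call. = FALSE)
    dihedral_angle(atoms[q[1], ], atoms[q[2], ], atoms[q[3], ], atoms[q[4], ])
  }, numeric(1))
  sum(abs(cos(th * pi / 180)))
}

# ---- interaction-energy aggregation ---------------------------------------

#' Aggregate per-residue interaction energies
#'
#' Frame-averaged Lennard-Jones and Coulomb interaction energies per
#' residue, with population standard deviations (large-n MD averaging
#' convention), and site totals. Totals are the sums of the per-residue
#' means exactly; total standard deviations are the population sd of the
#' per-frame residue-summed energies.
#'
#' @param records data frame `frame`, `residue`, `lj`, `coulomb` (e.g.
#'   from [generate_energy_records()]).
#' @param residues residues making up the site; defaults to all residues
#'   present. Residues requested but absent from the records are an error.
#' @return A `site_energies` object: `per_residue` data frame (`residue`,
#'   `lj`, `lj_sd`, `coulomb`, `coulomb_sd`), `total` (named numeric,
#'   `lj`/`coulomb`), `total_sd`, `n_frames`.
#' @export
aggregate_energies <- function(records, residues = NULL) {
  stopifnot(is.data.frame(records),
            all(c("frame", "residue", "lj", "coulomb") %in% names(records)))
  if (is.null(residues)) residues <- unique(records$residue)
  missing <- setdiff(residues, unique(records$residue))
  if (length(missing))
    stop("residues absent from records: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec <- records[records$residue %in% residues, , drop = FALSE]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  per <- do.call(rbind, lapply(split(rec, factor(rec$residue, residues)),
    function(d) data.frame(residue = d$residue[1],
                           lj = mean(d$lj), lj_sd = pop_sd(d$lj),
                           coulomb = mean(d$coulomb),
                           coulomb_sd = pop_sd(d$coulomb))))
  rownames(per) <- NULL
  by_frame <- rowsum(rec[, c("lj", "coulomb")], rec$frame)
  structure(list(
    per_residue = per,
    total = c(lj = sum(per$lj), coulomb = sum(per$coulomb)),
    total_sd = c(lj = pop_sd(by_frame$lj), coulomb = pop_sd(by_frame$coulomb)),
    n_frames = length(unique(rec$frame))
  ), class = "site_energies")
}

#' @export
print.site_energies <- function(x, ...) {
  cat("site_energies over", x$n_frames, "frame(s):\n")
  print(x$per_residue, digits = 3)
  cat(sprintf("  total LJ %.1f +/- %.1f, Coulomb %.1f +/- %.1f kJ/mol\n",
              x$total["lj"], x$total_sd["lj"],
              x$total["coulomb"], x$total_sd["coulomb"]))
  invisible(x)
}
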