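# Synthetic-data generators. Every downstream stage of the pipeline
# (density maps, mode classification, WHAM, spectra) is validated by
# recovering parameters planted here, so the generators are first-class,
# tested code.

# Deterministic seed splitting: one user-facing integer seed, independent
# streams per sub-task (Lehmer-style mix, kept below 2^31).
split_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(index %% 7 + 1)) s <- (s * 48271) %% 2147483647
  as.integer((s + index) %% 2147483647)
}

ligand_atom_names <- c("BTC", "VIN", "BZC", "THZ", "ETC", "CHG")
major_modes <- c("UL", "UR", "DL", "DR")

#' Configuration for synthetic ligand trajectories
#'
#' Bundles the sampling parameters of [generate_ligand_trajectory()]. The
#' four major binding modes are the up/down (U/D) x left/right (L/R)
#' orientations of the ligand's ethyl group in the binding-site frame; each
#' major mode has four minor conformers from the two rotatable backbone
#' dihedrals. Default mode weights follow the Boltzmann populations
#' estimated for the tau Alzheimer-fold site A
#' (UR 47%, UL 30%, DR 19%, DL 4%).
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_frames,n_ligands trajectory dimensions.
#' @param mode_weights named probability 4-vector over `UL`, `UR`, `DL`,
#'   `DR`; must sum to 1 within 1e-12.
#' @param minor_mode_weights probability 4-vector over the minor conformers
#'   (shared across major modes); must sum to 1 within 1e-12.
#' @param site_center optional length-3 position (nm) of the planted site;
#'   default: triad centroid of the middle layer's site A.
#' @param site_spread isotropic Gaussian spread (nm, > 0) of the ligand
#'   charge center about the site center.
#' @param bulk_fraction probability in `[0, 1]` that a ligand is placed in
#'   bulk (uniform in the simulation box, excluded from the site
#'   neighbourhood) instead of at the site.
#' @param temperature kelvin.
#' @param frame_interval_ps time between stored frames, ps.
#' @return A `synthetic_config` object (list).
#' @export
synthetic_config <- function(seed = 1,
                             n_frames = 1000,
                             n_ligands = 1,
                             mode_weights = c(UL = 0.30, UR = 0.47,
                                              DL = 0.04, DR = 0.19),
                             minor_mode_weights = rep(0.25, 4),
                             site_center = NULL,
                             site_spread = 0.05,
                             bulk_fraction = 0,
                             temperature = 300,
                             frame_interval_ps = 20) {
  stopifnot(length(mode_weights) == 4, length(minor_mode_weights) == 4)
  if (is.null(names(mode_weights))) names(mode_weights) <- major_modes
  stopifnot(setequal(names(mode_weights), major_modes))
  if (any(mode_weights < 0) || abs(sum(mode_weights) - 1) > 1e-12)
    stop("mode_weights must be non-negative and sum to 1", call. = FALSE)
  if (any(minor_mode_weights < 0) || abs(sum(minor_mode_weights) - 1) > 1e-12)
    stop("minor_mode_weights must be non-negative and sum to 1", call. = FALSE)
  if (!is.finite(site_spread) || site_spread <= 0)
    stop("site_spread must be > 0", call. = FALSE)
  if (bulk_fraction < 0 || bulk_fraction > 1)
    stop("bulk_fraction must be in [0, 1]", call. = FALSE)
  stopifnot(n_frames >= 1, n_ligands >= 1, temperature > 0)
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 n_ligands = as.integer(n_ligands),
                 mode_weights = mode_weights[major_modes],
                 minor_mode_weights = minor_mode_weights,
                 site_center = site_center, site_spread = site_spread,
                 bulk_fraction = bulk_fraction, temperature = temperature,
                 frame_interval_ps = frame_interval_ps),
            class = "synthetic_config")
}

#' Generate a toy protofilament layer
#'
#' Builds a planar, C-shaped arc of pseudo-residues emulating the
#' cross-section of an amyloid protofilament (the tau Alzheimer fold is a
#' C-shaped arc of ~73 residues). Each residue has four pseudo-atoms (CA on
#' the arc, CB radially inward, N and C tangential). Residues are numbered
#' from 306 (the first residue of the tau fibril core); when the range
#' covers them, residues 360-362 are labeled Ile/Thr/His as the site-A
#' triad and 349-351 Arg/Val/Gln as the site-B triad, otherwise triads are
#' placed at fixed fractional positions along the arc. Triad definitions
#' are attached as attributes `site_a` and `site_b` ([site_definition()]
#' objects).
#'
#' @param n_residues number of pseudo-residues (>= 3).
#' @param c_shape_radius arc radius in nm.
#' @param seed integer seed (controls small deterministic coordinate
#'   jitter).
#' @param arc_degrees angular span of the open arc.
#' @return A data frame of atom records (`elety`, `resid`, `resno`, `x`,
#'   `y`, `z` in nm) with site attributes; rows lie in the z = 0 plane.
#' @export
generate_toy_layer <- function(n_residues, c_shape_radius = 4.0, seed = 1,
                               arc_degrees = 270) {
  if (length(n_residues) != 1 || !is.finite(n_residues) || n_residues < 3)
    stop("n_residues must be >= 3", call. = FALSE)
  n_residues <- as.integer(n_residues)
  set.seed(split_seed(seed, 101L))
  theta <- seq(-arc_degrees / 2, arc_degrees / 2,
               length.out = n_residues) * pi / 180
  r <- c_shape_radius + stats::rnorm(n_residues, 0, 0.05)
  resno <- 306L + seq_len(n_residues) - 1L
  # site triads: canonical tau numbering when covered, else fractional
  pick_triad <- function(target_first, frac) {
    if (target_first >= resno[1] && (target_first + 2L) <= resno[n_residues])
      target_first + 0:2
    else {
      i <- max(1L, min(n_residues - 2L, round(frac * n_residues)))
      resno[i] + 0:2
    }
  }
  triad_a <- pick_triad(360L, 0.75)
  triad_b <- pick_triad(349L, 0.60)
  resid <- rep("ALA", n_residues)
  resid[match(triad_a, resno)] <- c("ILE", "THR", "HIS")
  resid[match(triad_b, resno)] <- c("ARG", "VAL", "GLN")
  per_res <- lapply(seq_len(n_residues), function(i) {
    ca <- c(r[i] * cos(theta[i]), r[i] * sin(theta[i]), 0)
    radial <- c(cos(theta[i]), sin(theta[i]), 0)
    tangent <- c(-sin(theta[i]), cos(theta[i]), 0)
    xyz <- rbind(CA = ca,
                 CB = ca - 0.15 * radial,
                 N = ca - 0.12 * tangent,
                 C = ca + 0.12 * tangent)
    data.frame(elety = rownames(xyz), resid = resid[i], resno = resno[i],
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               row.names = NULL)
  })
  layer <- do.call(rbind, per_res)
  attr(layer, "site_a") <- site_definition(triad_a,
    his_anchor = list(resno = triad_a[3], elety = "CA"),
    ile_anchor = list(resno = triad_a[1], elety = "CA"))
  attr(layer, "site_b") <- site_definition(triad_b,
    his_anchor = list(resno = triad_b[3], elety = "CA"),
    ile_anchor = list(resno = triad_b[1], elety = "CA"))
  layer
}

# ---- toy ligand ------------------------------------------------------------

# Six labeled pseudo-atoms: bi-thiophene centroid (BTC), vinylene midpoint
# (VIN), benzothiazole centroid (BZC), thiazole-ring centroid (THZ), ethyl
# terminal carbon (ETC) and charge center (CHG = centroid of the others).
# The chain BTC-VIN-BZC-THZ-ETC supports the two conformational dihedrals:
# the backbone dihedral (BTC,VIN,BZC,THZ) about VIN-BZC standing in for the
# bi-thiophene inter-ring rotation, and the ethyl dihedral
# (VIN,BZC,THZ,ETC) about BZC-THZ standing in for the thiazole-ethyl
# rotation.
build_toy_ligand <- function(d_ethyl, d_backbone) {
  p1 <- c(0, 0, 0)
  p2 <- c(0.25, 0, 0)
  p3 <- p2 + 0.25 * c(cos(pi / 3), sin(pi / 3), 0)
  p4 <- place_atom(p1, p2, p3, 0.25, 120, d_backbone)
  p5 <- place_atom(p2, p3, p4, 0.15, 112, d_ethyl)
  xyz <- rbind(p1, p2, p3, p4, p5)
  xyz <- rbind(xyz, colMeans(xyz))
  rownames(xyz) <- ligand_atom_names
  xyz
}

#' Generate a synthetic ligand trajectory with planted binding modes
#'
#' Emulates unbiased MD of fluorescent ligands around a fibril: at every
#' frame each ligand is placed either in bulk (with probability
#' `bulk_fraction`, uniformly in the simulation box but outside the site
#' neighbourhood, mimicking the excluded volume of the protein) or bound at
#' the site-A triad of the (middle layer of the) fibril, with a major
#' binding mode drawn from `mode_weights` and a minor conformer drawn from
#' `minor_mode_weights`. The ethyl group of a bound ligand is oriented
#' along the mode's quadrant of the site frame (45 degrees off both axes,
#' with <= 18 degree angular jitter so the planted quadrant is never
#' crossed), and the two backbone dihedrals are set near 0/180 degrees
#' according to the minor conformer.
#'
#' Ground-truth labels are attached as `attr(, "truth")` (a data frame
#' `frame`, `ligand`, `major`, `minor`) for recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param fibril a `fibril_model` whose template carries a `site_a`
#'   attribute (see [generate_toy_layer()]).
#' @return A `ligand_trajectory` object: data frame with columns `frame`,
#'   `ligand`, `atom`, `x`, `y`, `z` (nm) plus attributes `truth`, `site`,
#'   `frame_interval_ps`, `box`.
#' @export
generate_ligand_trajectory <- function(config, fibril) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(fibril, "fibril_model"))
  site <- attr(fibril$template, "site_a")
  if (is.null(site))
    stop("fibril template has no labeled site triad (attribute 'site_a')",
         call. = FALSE)
  set.seed(split_seed(config$seed, 202L))
  mid_layer <- (fibril$n_layers - 1L) %/% 2L
  # plant modes in the same anchor-defined site frame the classifier uses
  frame <- site_frame(fibril, site, mid_layer)
  site_center <- config$site_center
  if (is.null(site_center)) site_center <- frame$origin
  # box: fibril bounding box padded by 1.5 nm
  xyz_f <- as.matrix(fibril$atoms[, c("x", "y", "z")])
  box <- rbind(apply(xyz_f, 2, min) - 1.5, apply(xyz_f, 2, max) + 1.5)
  all_site_centers <- t(vapply(seq_len(fibril$n_layers) - 1L,
                               function(k) triad_centroid(fibril, site, k),
                               numeric(3)))
  n <- config$n_frames * config$n_ligands
  is_bulk <- stats::runif(n) < config$bulk_fraction
  major <- sample(major_modes, n, replace = TRUE, prob = config$mode_weights)
  minor <- sample(0:3, n, replace = TRUE, prob = config$minor_mode_weights)
  major[is_bulk] <- "unbound"
  minor[is_bulk] <- NA_integer_
  rows <- vector("list", n)
  idx <- expand.grid(ligand = seq_len(config$n_ligands),
                     frame = seq_len(config$n_frames))
  for (i in seq_len(n)) {
    if (is_bulk[i]) {
      xyz <- place_bulk_ligand(box, all_site_centers,
                               exclusion = site$cutoff + 0.2)
    } else {
      xyz <- place_bound_ligand(major[i], minor[i], site_center, frame,
                                config$site_spread)
    }
    rows[[i]] <- data.frame(frame = idx$frame[i], ligand = idx$ligand[i],
                            atom = ligand_atom_names,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            row.names = NULL)
  }
  traj <- do.call(rbind, rows)
  structure(traj,
            truth = data.frame(frame = idx$frame, ligand = idx$ligand,
                               major = major, minor = minor),
            site = site,
            frame_interval_ps = config$frame_interval_ps,
            box = box,
            class = c("ligand_trajectory", "data.frame"))
}

triad_centroid <- function(fibril, site, layer) {
  a <- fibril$atoms
  sel <- a$layer == layer & a$resno %in% site$triad & a$elety == "CA"
  if (!any(sel)) stop("site triad CA atoms not found in fibril", call. = FALSE)
  colMeans(as.matrix(a[sel, c("x", "y", "z")]))
}

place_bound_ligand <- function(major, minor, site_center, frame, spread) {
  bit_eth <- minor %/% 2L          # high bit: ethyl dihedral
  bit_bb <- minor %% 2L            # low bit: backbone dihedral
  jit <- function() stats::runif(1, -60, 60)
  d_eth <- (if (bit_eth) 180 else 0) + jit()
  d_bb <- (if (bit_bb) 180 else 0) + jit()
  xyz <- build_toy_ligand(d_eth, d_bb)
  e_local <- xyz["ETC", ] - xyz["THZ", ]
  sz <- if (substr(major, 1, 1) == "U") 1 else -1
  sy <- if (substr(major, 2, 2) == "R") 1 else -1
  target <- unit(sz * cos(pi / 4) * frame$z + sy * sin(pi / 4) * frame$y)
  # jitter the target direction by <= 18 deg: quadrant signs are preserved
  # since the target sits 45 deg from both axes
  ax <- unit(stats::rnorm(3))
  target <- as.vector(rotation_matrix(ax, stats::runif(1, 0, 18)) %*% target)
  # align local ethyl vector to target, then roll randomly about it
  R1 <- align_rotation(unit(e_local), target)
  R <- rotation_matrix(target, stats::runif(1, 0, 360)) %*% R1
  xyz <- xyz %*% t(R)
  rownames(xyz) <- ligand_atom_names
  anchor <- site_center + stats::rnorm(3, 0, spread)
  sweep(xyz, 2, anchor - xyz["CHG", ], `+`)
}

# rotation taking unit vector a to unit vector b
align_rotation <- function(a, b) {
  v <- cross3(a, b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (sum(a * b) > 0) return(diag(3))
    # antiparallel: 180 deg about any perpendicular
    p <- unit(cross3(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(rotation_matrix(p, 180))
  }
  rotation_matrix(v, atan2(s, sum(a * b)) * 180 / pi)
}

place_bulk_ligand <- function(box, site_centers, exclusion, max_tries = 1000) {
  for (t in seq_len(max_tries)) {
    pos <- stats::runif(3, box[1, ], box[2, ])
    d2 <- rowSums(sweep(site_centers, 2, pos)^2)
    if (min(d2) > exclusion^2) {
      xyz <- build_toy_ligand(stats::runif(1, -180, 180),
                              stats::runif(1, -180, 180))
      R <- rotation_matrix(unit(stats::rnorm(3)), stats::runif(1, 0, 360))
      xyz <- xyz %*% t(R)
      rownames(xyz) <- ligand_atom_names
      return(sweep(xyz, 2, pos - xyz["CHG", ], `+`))
    }
  }
  stop("could not place a bulk ligand outside the site exclusion zone",
       call. = FALSE)
}

# ---- umbrella sampling -----------------------------------------------------

#' Generate umbrella-sampling window series from an analytic potential
#'
#' Draws reaction-coordinate samples from the biased Boltzmann density
#' `exp(-(U(x) + 0.5 k (x - c)^2) / kT)` for each window center `c`, by
#' Metropolis Monte Carlo restricted to the potential's domain. The
#' proposal is uniform with half-width `max(0.05, 3 sqrt(kT/k_umb))` nm —
#' scaled to the window width so that stiff windows mix as fast as soft
#' ones — with 1000 burn-in steps and 10x thinning.
#'
#' @param potential an [analytic_potential()].
#' @param centers sorted window centers (nm).
#' @param k_umb umbrella force constant (kJ/mol/nm^2, > 0); scalar or one
#'   per window.
#' @param n_samples retained samples per window.
#' @param temperature kelvin.
#' @param seed integer seed; windows use independent derived streams.
#' @param thin,burn_in Metropolis thinning factor and burn-in steps.
#' @return List of [umbrella_window()] objects.
#' @export
generate_umbrella_windows <- function(potential, centers, k_umb, n_samples,
                                      temperature = 300, seed = 1,
                                      thin = 10, burn_in = 1000) {
  stopifnot(inherits(potential, "analytic_potential"))
  if (length(centers) == 0) stop("centers must be non-empty", call. = FALSE)
  if (is.unsorted(centers)) stop("centers must be sorted", call. = FALSE)
  if (any(k_umb <= 0)) stop("k_umb must be > 0", call. = FALSE)
  stopifnot(n_samples >= 1, temperature > 0)
  k_umb <- rep(k_umb, length.out = length(centers))
  lapply(seq_along(centers), function(i) {
    x <- metropolis_window(potential, centers[i], k_umb[i], n_samples,
                           temperature, split_seed(seed, 300L + i),
                           thin = thin, burn_in = burn_in)
    umbrella_window(centers[i], k_umb[i], x, temperature)
  })
}

metropolis_window <- function(potential, center, k, n, temperature, seed,
                              thin = 10, burn_in = 1000) {
  set.seed(seed)
  beta <- 1 / (kB_kJ_mol * temperature)
  dom <- potential$domain
  step <- max(0.05, 3 * sqrt(1 / (beta * k)))
  w <- function(x) potential$fun(x) + 0.5 * k * (x - center)^2
  x <- min(max(center, dom[1]), dom[2])
  wx <- w(x)
  ntot <- burn_in + n * thin
  prop <- stats::runif(ntot, -step, step)
  uacc <- stats::runif(ntot)
  out <- numeric(n)
  j <- 0L
  for (i in seq_len(ntot)) {
    xn <- x + prop[i]
    if (xn >= dom[1] && xn <= dom[2]) {
      wn <- w(xn)
      if (uacc[i] < exp(-beta * (wn - wx))) { x <- xn; wx <- wn }
    }
    if (i > burn_in && (i - burn_in) %% thin == 0L) { j <- j + 1L; out[j] <- x }
  }
  out
}

# ---- snapshot energies and interaction records -----------------------------

#' Generate snapshot vertical excitation energies
#'
#' I.i.d. normal draws emulating per-snapshot vertical excitation energies
#' from uncorrelated MD frames (the inhomogeneous-broadening input of
#' snapshot-averaged spectra).
#'
#' @param mean,sigma normal mean and standard deviation (eV, `sigma >= 0`).
#' @param n number of snapshots (0 gives an empty vector).
#' @param seed integer seed.
#' @return Numeric vector of energies (eV).
#' @export
generate_snapshot_energies <- function(mean, sigma, n, seed = 1) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(is.finite(mean), n >= 0)
  if (n == 0) return(numeric(0))
  set.seed(split_seed(seed, 404L))
  stats::rnorm(n, mean, sigma)
}

#' Generate per-frame, per-residue interaction-energy records
#'
#' Draws frame-wise Lennard-Jones and Coulomb interaction energies about
#' stated per-residue means, emulating an MD energy decomposition between
#' a ligand and individual binding-site residues.
#'
#' @param per_residue_means data frame with columns `residue`, `lj`,
#'   `coulomb` (kJ/mol).
#' @param per_residue_sds matching data frame of standard deviations
#'   (>= 0), or a single number recycled to all entries.
#' @param n_frames frames to draw.
#' @param seed integer seed.
#' @return Data frame `frame`, `residue`, `lj`, `coulomb` (kJ/mol).
#' @export
generate_energy_records <- function(per_residue_means, per_residue_sds = 0,
                                    n_frames, seed = 1) {
  m <- per_residue_means
  stopifnot(is.data.frame(m), all(c("residue", "lj", "coulomb") %in% names(m)),
            n_frames >= 1)
  if (is.numeric(per_residue_sds) && length(per_residue_sds) == 1)
    per_residue_sds <- data.frame(residue = m$residue,
                                  lj = per_residue_sds,
                                  coulomb = per_residue_sds)
  s <- per_residue_sds
  stopifnot(is.data.frame(s), nrow(s) == nrow(m))
  if (any(s$lj < 0) || any(s$coulomb < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  set.seed(split_seed(seed, 505L))
  out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    data.frame(frame = seq_len(n_frames), residue = m$residue[i],
               lj = stats::rnorm(n_frames, m$lj[i], s$lj[i]),
               coulomb = stats::rnorm(n_frames, m$coulomb[i], s$coulomb[i]))
  }))
  out[order(out$frame, match(out$residue, m$residue)), , drop = FALSE]
}

#' Reference interaction energies for the tau/bTVBT4 binding sites
#'
#' Per-residue Lennard-Jones and Coulomb interaction energies (mean and
#' standard deviation, kJ/mol) between the ligand bTVBT4 and the residues
#' forming binding site A (Ile360, Thr361, His362) and site B (Arg349,
#' Val350, Gln351) of the Alzheimer-fold tau fibril, as reported from
#' explicit-solvent MD. Used as reference inputs for
#' [generate_energy_records()] and [aggregate_energies()].
#'
#' @return Data frame with columns `site`, `residue`, `lj`, `lj_sd`,
#'   `coulomb`, `coulomb_sd`.
#' @export
tau_site_energy_table <- function() {
  data.frame(
    site = rep(c("A", "B"), each = 3),
    residue = c("ILE360", "THR361", "HIS362",
                "ARG349", "VAL350", "GLN351"),
    lj = c(-50.5, -4.8, -36.7, -73.2, -13.0, -32.0),
    lj_sd = c(7, 2, 8, 13, 4, 11),
    coulomb = c(4.8, -1.8, -24.9, 5.6, -7.8, 1.8),
    coulomb_sd = c(1, 2, 14, 12, 4, 9)
  )
}
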