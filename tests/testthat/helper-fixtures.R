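# Shared fixtures and independent oracles, built in code at test time.

# small odd-layer fibril on a toy C-shaped layer (odd counts close the
# 2-fold screw cell)
toy_fibril <- function(n_res = 31, n_layers = 5, seed = 1) {
  lay <- generate_toy_layer(n_res, c_shape_radius = 3.0, seed = seed)
  build_supercell(lay, n_layers, rise = 0.48,
                  twist = twist_from_layers(n_layers, 2))
}

# straight chain of n atoms with prescribed consecutive dihedrals
# (n - 3 of them), bond 1, bond angle 120 deg; labels A1..An
chain_with_dihedrals <- function(dihedrals) {
  n <- length(dihedrals) + 3L
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(1, 0, 0)
  xyz[3, ] <- xyz[2, ] + c(cos(pi / 3), sin(pi / 3), 0)
  for (i in seq_along(dihedrals))
    xyz[i + 3L, ] <- fibrilsite:::place_atom(xyz[i, ], xyz[i + 1L, ],
                                             xyz[i + 2L, ], 1, 120,
                                             dihedrals[i])
  rownames(xyz) <- paste0("A", seq_len(n))
  xyz
}

# numeric CDF of the biased umbrella density on the potential's domain
# (independent oracle: dense quadrature, no sampling)
biased_cdf <- function(potential, center, k_umb, temperature) {
  beta <- 1 / (kB_kJ_mol * temperature)
  g <- seq(potential$domain[1], potential$domain[2], length.out = 8001)
  w <- potential_energy(potential, g) + 0.5 * k_umb * (g - center)^2
  d <- exp(-beta * (w - min(w)))
  cd <- cumsum(d)
  cd <- (cd - cd[1]) / (cd[length(cd)] - cd[1])
  stats::approxfun(g, cd, yleft = 0, yright = 1)
}

# small ligand trajectory shared across analysis tests
quick_trajectory <- function(fib, n_frames = 300, seed = 7, ...) {
  cfg <- synthetic_config(seed = seed, n_frames = n_frames, ...)
  generate_ligand_trajectory(cfg, fib)
}
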