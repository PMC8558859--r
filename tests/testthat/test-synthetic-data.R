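test_that("toy layer construction: labels, shape, preconditions", {
  lay <- generate_toy_layer(73, c_shape_radius = 4.0, seed = 1)
  expect_equal(length(unique(lay$resno)), 73)
  expect_equal(nrow(lay), 73 * 4)
  expect_true(all(lay$z == 0))
  sa <- attr(lay, "site_a")
  sb <- attr(lay, "site_b")
  expect_equal(sa$triad, 360:362)
  expect_equal(sb$triad, 349:351)
  expect_equal(lay$resid[match(360:362, lay$resno)], c("ILE", "THR", "HIS"))
  # radii stay near the arc radius
  r <- sqrt(lay$x^2 + lay$y^2)
  expect_true(all(abs(r - 4.0) < 0.5))
  expect_error(generate_toy_layer(2), ">= 3")
})

test_that("generators are deterministic in the seed", {
  expect_identical(generate_toy_layer(21, seed = 4),
                   generate_toy_layer(21, seed = 4))
  fib <- toy_fibril()
  cfg <- synthetic_config(seed = 9, n_frames = 50, bulk_fraction = 0.3)
  expect_identical(generate_ligand_trajectory(cfg, fib),
                   generate_ligand_trajectory(cfg, fib))
  pot <- default_double_well()
  expect_identical(
    generate_umbrella_windows(pot, c(0.6, 1.0), 500, 100, seed = 3),
    generate_umbrella_windows(pot, c(0.6, 1.0), 500, 100, seed = 3))
  expect_identical(generate_snapshot_energies(2.5, 0.1, 20, seed = 5),
                   generate_snapshot_energies(2.5, 0.1, 20, seed = 5))
  tab <- data.frame(residue = "X", lj = -10, coulomb = 2)
  expect_identical(generate_energy_records(tab, 1, 10, seed = 6),
                   generate_energy_records(tab, 1, 10, seed = 6))
  # different seeds give different draws
  expect_false(identical(generate_snapshot_energies(2.5, 0.1, 20, seed = 5),
                         generate_snapshot_energies(2.5, 0.1, 20, seed = 6)))
})

test_that("planted major-mode frequencies match a binomial oracle", {
  fib <- toy_fibril()
  w <- c(UL = 0.30, UR = 0.47, DL = 0.04, DR = 0.19)
  n <- 4000
  cfg <- synthetic_config(seed = 21, n_frames = n, mode_weights = w)
  truth <- attr(generate_ligand_trajectory(cfg, fib), "truth")
  freq <- table(factor(truth$major, names(w))) / n
  for (m in names(w)) {
    se <- sqrt(w[m] * (1 - w[m]) / n)
    expect_lt(abs(freq[[m]] - w[[m]]), 3 * se)
  }
})

test_that("bulk-only trajectories never enter the site cutoff", {
  fib <- toy_fibril()
  cfg <- synthetic_config(seed = 2, n_frames = 150, bulk_fraction = 1)
  tr <- generate_ligand_trajectory(cfg, fib)
  site <- attr(tr, "site")
  chg <- as.matrix(tr[tr$atom == "CHG", c("x", "y", "z")])
  centers <- t(sapply(seq_len(fib$n_layers) - 1L, function(k)
    site_frame(fib, site, k)$origin))
  dmin <- apply(chg, 1, function(p)
    sqrt(min(rowSums(sweep(centers, 2, p)^2))))
  expect_true(all(dmin > site$cutoff))
  expect_true(all(attr(tr, "truth")$major == "unbound"))
})

test_that("a degenerate single-mode trajectory is labeled 100% that mode", {
  fib <- toy_fibril()
  cfg <- synthetic_config(seed = 5, n_frames = 120,
                          mode_weights = c(UL = 1, UR = 0, DL = 0, DR = 0))
  tr <- generate_ligand_trajectory(cfg, fib)
  lab <- classify_modes(tr, fib)
  expect_true(all(lab$major == "UL"))
})

test_that("trajectory generation requires a labeled site triad", {
  lay <- generate_toy_layer(9, seed = 1)
  attr(lay, "site_a") <- NULL
  fib <- build_supercell(lay, 3, 0.48, twist_from_layers(3, 2))
  cfg <- synthetic_config(seed = 1, n_frames = 5)
  expect_error(generate_ligand_trajectory(cfg, fib), "site triad")
})

test_that("umbrella window at a harmonic minimum samples the closed form", {
  pot <- analytic_potential("harmonic", list(k = 400, x0 = 1.0),
                            domain = c(0, 2))
  w <- generate_umbrella_windows(pot, 1.0, k_umb = 600, n_samples = 4000,
                                 temperature = 300, seed = 12)[[1]]
  # biased density is exactly Gaussian: sd = sqrt(kT / (k + k_umb))
  sd_true <- sqrt(kB_kJ_mol * 300 / (400 + 600))
  expect_lt(abs(mean(w$samples) - 1.0), 3 * sd_true / sqrt(1000))
  expect_equal(sd(w$samples), sd_true, tolerance = 0.1)
})

test_that("stiff umbrella springs reach the kT/k variance limit", {
  pot <- analytic_potential("harmonic", list(k = 50, x0 = 0.8),
                            domain = c(0, 2))
  k_umb <- 2e4
  w <- generate_umbrella_windows(pot, 1.2, k_umb, 4000, seed = 8)[[1]]
  expect_equal(var(w$samples), kB_kJ_mol * 300 / k_umb, tolerance = 0.15)
})

test_that("umbrella samples follow the analytic biased density (KS sweep)", {
  pot <- analytic_potential("harmonic", list(k = 100, x0 = 1.0),
                            domain = c(0, 2))
  cdf <- biased_cdf(pot, 1.2, 500, 300)
  pass <- vapply(1:100, function(s) {
    w <- generate_umbrella_windows(pot, 1.2, 500, 300, seed = s)[[1]]
    suppressWarnings(stats::ks.test(w$samples, cdf)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("umbrella generation rejects bad arguments", {
  pot <- default_double_well()
  expect_error(generate_umbrella_windows(pot, numeric(0), 500, 10),
               "non-empty")
  expect_error(generate_umbrella_windows(pot, c(1.0, 0.6), 500, 10),
               "sorted")
  expect_error(generate_umbrella_windows(pot, 0.6, -5, 10), "k_umb")
})

test_that("snapshot energies: CLT bound, zero-sigma, empty draws", {
  e <- generate_snapshot_energies(2.567, 0.10, 300, seed = 3)
  expect_lt(abs(mean(e) - 2.567), 3 * 0.10 / sqrt(300))
  expect_equal(generate_snapshot_energies(2.5, 0, 10, seed = 1),
               rep(2.5, 10))
  expect_length(generate_snapshot_energies(2.5, 0.1, 0, seed = 1), 0)
  expect_error(generate_snapshot_energies(2.5, -0.1, 10), "sigma")
})

test_that("energy records recover their planted means", {
  tab <- tau_site_energy_table()
  a <- tab[tab$site == "A", ]
  means <- data.frame(residue = a$residue, lj = a$lj, coulomb = a$coulomb)
  sds <- data.frame(residue = a$residue, lj = a$lj_sd, coulomb = a$coulomb_sd)
  n <- 2000
  rec <- generate_energy_records(means, sds, n_frames = n, seed = 17)
  agg <- aggregate_energies(rec)
  # aggregated LJ total near -91.9 within 3 standard errors of the total
  se_tot <- sqrt(sum(a$lj_sd^2)) / sqrt(n)
  expect_lt(abs(agg$total[["lj"]] - sum(a$lj)), 3 * se_tot)
  per <- agg$per_residue
  for (i in seq_len(nrow(a))) {
    row <- per[per$residue == a$residue[i], ]
    expect_lt(abs(row$lj - a$lj[i]), 3 * a$lj_sd[i] / sqrt(n))
    expect_lt(abs(row$coulomb - a$coulomb[i]),
              3 * a$coulomb_sd[i] / sqrt(n))
  }
  expect_error(generate_energy_records(means,
    data.frame(residue = a$residue, lj = -1, coulomb = 0), 10), ">= 0")
})

test_that("zero-sd records reproduce the inputs exactly, n = 1 included", {
  means <- data.frame(residue = c("R1", "R2"), lj = c(-5, -7),
                      coulomb = c(1, -2))
  agg <- aggregate_energies(generate_energy_records(means, 0, 50, seed = 2))
  expect_equal(agg$per_residue$lj, means$lj)
  expect_equal(agg$total[["lj"]], -12)
  expect_equal(agg$total_sd[["lj"]], 0)
  one <- generate_energy_records(means, 1.5, 1, seed = 9)
  agg1 <- aggregate_energies(one)
  expect_equal(sort(agg1$per_residue$lj), sort(one$lj))
})

test_that("config validation catches malformed weights and spreads", {
  expect_error(synthetic_config(mode_weights = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(synthetic_config(minor_mode_weights = c(1, 1, 1, 1) / 3),
               "sum to 1")
  expect_error(synthetic_config(site_spread = 0), "site_spread")
  expect_error(synthetic_config(bulk_fraction = 1.2), "bulk_fraction")
})
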