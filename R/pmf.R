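# Potentials of mean force from umbrella-sampling windows via the weighted
# histogram analysis method (WHAM), binding free energies, and Boltzmann
# mode populations.

#' Umbrella-sampling window
#'
#' One harmonic-restraint window: reaction-coordinate samples drawn under
#' the bias `0.5 * k_umb * (x - center)^2` at the given temperature.
#'
#' @param center restraint center, nm.
#' @param k_umb force constant, kJ/mol/nm^2 (> 0).
#' @param samples non-empty numeric vector of reaction-coordinate samples
#'   (nm).
#' @param temperature kelvin.
#' @return An `umbrella_window` object.
#' @export
umbrella_window <- function(center, k_umb, samples, temperature = 300) {
  if (!is.finite(k_umb) || k_umb <= 0) stop("k_umb must be > 0", call. = FALSE)
  if (length(samples) == 0 || !all(is.finite(samples)))
    stop("samples must be non-empty and finite", call. = FALSE)
  stopifnot(is.finite(center), temperature > 0)
  structure(list(center = center, k_umb = k_umb,
                 samples = as.numeric(samples), temperature = temperature),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella_window: center %.3f nm, k %.5g kJ/mol/nm^2, %d samples, %g K\n",
              x$center, x$k_umb, length(x$samples), x$temperature))
  invisible(x)
}

#' Weighted-histogram analysis of umbrella-sampling windows
#'
#' Self-consistent WHAM on a 1-D reaction coordinate: the unbiased bin
#' probabilities `p_j` and the per-window free-energy shifts `f_i` are
#' iterated
#' \deqn{p_j = \sum_i h_{ij} / \sum_i N_i e^{-\beta(w_i(x_j) - f_i)},
#'       \quad e^{-\beta f_i} = \sum_j p_j e^{-\beta w_i(x_j)}}
#' until the largest change in any `f_i` drops below `tol`. The PMF is
#' `-kT log p` shifted according to the reference convention: `"bulk"`
#' (default) zeroes the mean over the last `bulk_last` nm of the sampled
#' coordinate, matching profiles whose pulled coordinate flattens in bulk
#' solvent; `"min"` zeroes the global minimum.
#'
#' @param windows list of [umbrella_window()] objects sharing one
#'   temperature.
#' @param bin_width histogram bin width, nm.
#' @param tol convergence tolerance on the shifts, kJ/mol.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual in its message.
#' @param reference `"bulk"` or `"min"`.
#' @param bulk_last width (nm) of the trailing bulk region used by the
#'   `"bulk"` convention.
#' @return A `pmf_profile` object: data frame `xi` (bin centers, nm),
#'   `free_energy` (kJ/mol), `count` (total samples per bin), with the
#'   window metadata, temperature and convergence diagnostics as
#'   attributes.
#' @export
wham <- function(windows, bin_width = 0.02, tol = 1e-8, max_iter = 100000,
                 reference = c("bulk", "min"), bulk_last = 0.5) {
  reference <- match.arg(reference)
  stopifnot(length(windows) >= 1)
  lapply(windows, function(w) stopifnot(inherits(w, "umbrella_window")))
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  beta <- 1 / (kB_kJ_mol * temps[1])
  allx <- unlist(lapply(windows, `[[`, "samples"))
  edges <- seq(floor(min(allx) / bin_width) * bin_width,
               max(allx) + bin_width, by = bin_width)
  mid <- edges[-1] - bin_width / 2
  H <- vapply(windows,
              function(w) graphics::hist(w$samples, breaks = edges,
                                         plot = FALSE)$counts,
              numeric(length(mid)))
  num <- rowSums(H)
  # coverage: the sampled ranges of the windows must form one connected
  # interval (gaps wider than a bin mean WHAM cannot tie the windows
  # together); isolated empty interior bins from sampling tails are fine
  # and are simply dropped from the profile
  rngs <- t(vapply(windows, function(w) range(w$samples), numeric(2)))
  rngs <- rngs[order(rngs[, 1]), , drop = FALSE]
  reach <- rngs[1, 2]
  for (i in seq_len(nrow(rngs))[-1]) {
    if (rngs[i, 1] > reach + bin_width)
      stop("window histograms do not overlap: gap in sampling coverage ",
           sprintf("near %.3f nm", reach), call. = FALSE)
    reach <- max(reach, rngs[i, 2])
  }
  N <- vapply(windows, function(w) length(w$samples), numeric(1))
  bias <- vapply(windows, function(w) 0.5 * w$k_umb * (mid - w$center)^2,
                 numeric(length(mid)))
  ebias <- exp(-beta * bias)
  f <- numeric(length(windows))
  for (it in seq_len(max_iter)) {
    denom <- as.vector(ebias %*% (N * exp(beta * f)))
    p <- num / denom
    fnew <- -log(as.vector(crossprod(ebias, p))) / beta
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
                 max_iter, delta), call. = FALSE)
  keep <- num > 0
  G <- -log(p[keep]) / beta
  prof <- data.frame(xi = mid[keep], free_energy = G, count = num[keep])
  pmf_profile(prof, reference = reference, bulk_last = bulk_last,
              temperature = temps[1], bin_width = bin_width,
              f_shifts = f, iterations = it)
}

#' Assemble a PMF profile from bin centers and free energies
#'
#' Constructor for externally computed profiles (e.g. an analytic curve or
#' a PMF imported from another tool), applying the package's reference
#' conventions. [wham()] returns objects of the same class.
#'
#' @param xi bin centers, nm (sorted).
#' @param free_energy free energies, kJ/mol.
#' @param reference `"bulk"` (zero the mean over the trailing `bulk_last`
#'   nm) or `"min"` (zero the global minimum).
#' @param bulk_last trailing width for the bulk convention, nm.
#' @param temperature kelvin.
#' @return A `pmf_profile` object.
#' @export
as_pmf_profile <- function(xi, free_energy, reference = c("bulk", "min"),
                           bulk_last = 0.5, temperature = 300) {
  reference <- match.arg(reference)
  stopifnot(length(xi) == length(free_energy), !is.unsorted(xi),
            all(is.finite(xi)), all(is.finite(free_energy)))
  pmf_profile(data.frame(xi = xi, free_energy = free_energy,
                         count = NA_real_),
              reference = reference, bulk_last = bulk_last,
              temperature = temperature,
              bin_width = if (length(xi) > 1) stats::median(diff(xi)) else NA)
}

pmf_profile <- function(prof, reference, bulk_last, temperature, bin_width,
                        f_shifts = NULL, iterations = NA_integer_) {
  if (reference == "bulk") {
    lo <- max(prof$xi) - bulk_last
    prof$free_energy <- prof$free_energy -
      mean(prof$free_energy[prof$xi >= lo])
  } else {
    prof$free_energy <- prof$free_energy - min(prof$free_energy)
  }
  structure(prof,
            reference = reference, bulk_last = bulk_last,
            temperature = temperature, bin_width = bin_width,
            f_shifts = f_shifts, iterations = iterations,
            class = c("pmf_profile", "data.frame"))
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$xi, x$free_energy, type = "l",
                 xlab = "reaction coordinate (nm)",
                 ylab = "free energy (kJ/mol)", ...)
  invisible(x)
}

#' Block-bootstrap uncertainty for a WHAM profile
#'
#' Optional diagnostics: resamples each window's time series in
#' contiguous blocks (moving-block bootstrap, which preserves the
#' short-range autocorrelation of Monte Carlo/MD samples), reruns
#' [wham()] per resample, and reports the per-bin standard deviation of
#' the free energy across resamples, after aligning each resampled
#' profile to the reference profile's mean over shared bins.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param n_boot number of bootstrap resamples.
#' @param block_length block size in samples.
#' @param seed integer seed for the resampling.
#' @param ... passed to [wham()].
#' @return Data frame `xi`, `free_energy` (point estimate), `sd`
#'   (bootstrap standard deviation, kJ/mol; `NA` for bins absent from
#'   some resamples).
#' @export
wham_uncertainty <- function(windows, n_boot = 50, block_length = 50,
                             seed = 1, ...) {
  ref <- wham(windows, ...)
  set.seed(split_seed(seed, 606L))
  block_resample <- function(x) {
    n <- length(x)
    nb <- ceiling(n / block_length)
    starts <- sample.int(max(n - block_length + 1L, 1L), nb, replace = TRUE)
    idx <- as.vector(outer(seq_len(block_length) - 1L, starts, `+`))
    x[idx[seq_len(n)]]
  }
  acc <- matrix(NA_real_, length(ref$xi), n_boot)
  for (b in seq_len(n_boot)) {
    wb <- lapply(windows, function(w)
      umbrella_window(w$center, w$k_umb, block_resample(w$samples),
                      w$temperature))
    pb <- tryCatch(wham(wb, ...), error = function(e) NULL)
    if (is.null(pb)) next
    m <- match(round(ref$xi, 9), round(pb$xi, 9))
    g <- pb$free_energy[m]
    acc[, b] <- g - mean(g - ref$free_energy, na.rm = TRUE)
  }
  data.frame(xi = ref$xi, free_energy = ref$free_energy,
             sd = apply(acc, 1, stats::sd, na.rm = TRUE))
}

#' Binding free energy from a PMF
#'
#' Mean PMF over the bulk (unbound) region minus the global minimum.
#' Positive values mean the bound state is favored; the result is
#' non-negative whenever the bulk region is part of the sampled domain.
#'
#' @param pmf a `pmf_profile`.
#' @param bulk_region length-2 interval (nm) representing bulk solvent;
#'   defaults to the last `bulk_last` nm of the profile.
#' @return Binding free energy, kJ/mol.
#' @export
binding_energy <- function(pmf, bulk_region = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(bulk_region))
    bulk_region <- c(max(pmf$xi) - attr(pmf, "bulk_last"), max(pmf$xi))
  stopifnot(length(bulk_region) == 2, bulk_region[1] <= bulk_region[2])
  sel <- pmf$xi >= bulk_region[1] & pmf$xi <= bulk_region[2]
  if (!any(sel))
    stop("bulk region contains no sampled bins", call. = FALSE)
  mean(pmf$free_energy[sel]) - min(pmf$free_energy)
}

#' Boltzmann populations from binding free energies
#'
#' Converts per-mode binding free energies (positive = more strongly
#' bound) into equilibrium populations: `p_i = exp(E_i/kT) / sum_j
#' exp(E_j/kT)`. Invariant under adding a constant to all energies.
#'
#' @param energies named numeric vector of binding free energies, kJ/mol.
#' @param temperature kelvin (> 0).
#' @return Named fractions summing to 1.
#' @export
boltzmann_populations <- function(energies, temperature = 300) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0", call. = FALSE)
  if (any(!is.finite(energies))) stop("energies must be finite", call. = FALSE)
  z <- energies / (kB_kJ_mol * temperature)
  z <- z - max(z)
  p <- exp(z)
  p / sum(p)
}

#' Detect intermediate (secondary) minima in a PMF
#'
#' Finds interior local minima whose prominence — the depth below the
#' lowest barrier separating them from a deeper point of the profile —
#' exceeds a threshold, excluding the global minimum and the domain edges.
#' Shallow secondary wells of this kind appear when a pulled ligand pauses
#' at a weaker site on its way out of a binding cavity.
#'
#' @param pmf a `pmf_profile`.
#' @param prominence minimum prominence, kJ/mol.
#' @return Numeric vector of minimum positions (nm); possibly empty.
#' @export
detect_intermediate_minima <- function(pmf, prominence) {
  stopifnot(inherits(pmf, "pmf_profile"), is.finite(prominence))
  g <- pmf$free_energy
  n <- length(g)
  if (n < 3) return(numeric(0))
  is_min <- which(vapply(2:(n - 1), function(i)
    g[i] < g[i - 1] && g[i] <= g[i + 1], logical(1))) + 1L
  gmin <- which.min(g)
  is_min <- setdiff(is_min, gmin)
  if (!length(is_min)) return(numeric(0))
  prom <- vapply(is_min, function(i) {
    # lowest barrier to reach a deeper point, on either side
    barrier_side <- function(idx_seq) {
      run_max <- -Inf
      for (j in idx_seq) {
        run_max <- max(run_max, g[j])
        if (g[j] < g[i]) return(run_max)
      }
      run_max
    }
    left <- if (i > 1) barrier_side((i - 1):1) else Inf
    right <- if (i < n) barrier_side((i + 1):n) else Inf
    min(left, right) - g[i]
  }, numeric(1))
  pmf$xi[is_min[prom >= prominence]]
}
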