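# Forced-periodic helical fibril construction under screw-axis symmetry.
#
# Amyloid fibrils such as the tau paired helical filament stack identical
# protofilament layers along a helical axis; in the Alzheimer fold two
# C-shaped protofilaments are related by a 2-fold screw axis. Simulating a
# finite periodic fibril requires a per-layer twist that closes the cell:
# n_layers repetitions of the screw generator must accumulate a rotation
# that is a multiple of 360 degrees.
#
# The screw generator used here is a rotation by (360/screw_order + twist)
# degrees about the fibril axis followed by a translation by `rise` along it.
# For a 2-fold screw the generator rotation is (180 + twist): consecutive
# layers are the two screw-related protofilament copies, and `twist` is the
# small deviation from perfect 180-degree staggering. A cell of 185 layers
# under a 2-fold screw therefore closes with twist = 360/(2*185) = 0.97 deg
# per layer, matching a rise of 0.48 nm per layer at 300 K.

layer_columns <- c("elety", "resid", "resno", "x", "y", "z")

check_layer <- function(layer) {
  if (!is.data.frame(layer) || nrow(layer) == 0)
    stop("layer template must be a non-empty data frame", call. = FALSE)
  missing <- setdiff(layer_columns, names(layer))
  if (length(missing))
    stop("layer template lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(layer)
}

#' Per-layer twist that closes a periodic screw-symmetric cell
#'
#' For a periodic fibril cell of `n_layers` layers under a screw axis of
#' order `screw_order`, the per-layer twist (deviation from perfect
#' 360/screw_order staggering) must equal `360 / (screw_order * n_layers)`
#' degrees so that the accumulated rotation over the cell is a multiple of
#' 360 degrees.
#'
#' Note that under a 2-fold screw the generator rotation is `180 + twist`,
#' so a cell built with this twist closes (accumulated rotation a multiple
#' of 360 degrees) only for odd layer counts — the fibril cell of 185
#' layers is of this kind. [build_supercell()] flags closure explicitly.
#'
#' @param n_layers number of layers in the periodic cell (>= 1).
#' @param screw_order order of the screw axis (2 for a 2-fold screw).
#' @return Twist in degrees per layer.
#' @examples
#' twist_from_layers(185, 2)  # 0.973 deg, the tau paired-helical-filament cell
#' @export
twist_from_layers <- function(n_layers, screw_order = 2) {
  if (length(n_layers) != 1 || !is.finite(n_layers) || n_layers < 1 ||
      n_layers != round(n_layers))
    stop("n_layers must be a positive integer", call. = FALSE)
  if (length(screw_order) != 1 || !is.finite(screw_order) || screw_order < 1 ||
      screw_order != round(screw_order))
    stop("screw_order must be a positive integer", call. = FALSE)
  360 / (screw_order * n_layers)
}

# rotation of the screw generator, degrees (mod 360)
generator_rotation <- function(twist, screw_order) {
  (360 / screw_order + twist) %% 360
}

#' Build a helical fibril supercell from one protofilament layer
#'
#' Stacks `n_layers` copies of `layer` under the screw generator: layer k
#' (0-indexed) is the template rotated by `k * (360/screw_order + twist)`
#' degrees about the fibril axis and translated by `k * rise` along it.
#' Positive twist is a right-handed helix about the +z axis.
#'
#' Residue numbers are offset by 1000 per layer (column `resno_global`) and
#' chain identifiers cycle through A-Z per layer so that layers remain
#' addressable after assembly.
#'
#' @param layer data frame with columns `elety`, `resid`, `resno`, `x`, `y`,
#'   `z` (coordinates in nm), e.g. from [generate_toy_layer()] or
#'   [read_layer_pdb()].
#' @param n_layers number of layers to stack (>= 1).
#' @param rise axial translation per layer in nm (> 0).
#' @param twist per-layer twist in degrees (deviation from perfect
#'   staggering; see [twist_from_layers()]).
#' @param screw_order screw-axis order (default 2).
#' @param axis,origin direction and a point of the fibril axis; defaults to
#'   +z through the coordinate origin.
#' @return A `fibril_model` object: list with the atom table `$atoms`
#'   (template columns plus `layer`, `chain`, `resno_global`), the template,
#'   and the geometry parameters. The model is flagged periodic when the
#'   accumulated generator rotation over the cell closes to a multiple of
#'   360 degrees within 1e-9.
#' @examples
#' lay <- generate_toy_layer(21, seed = 1)
#' fib <- build_supercell(lay, n_layers = 10, rise = 0.48,
#'                        twist = twist_from_layers(10, 2))
#' fib
#' @export
build_supercell <- function(layer, n_layers, rise, twist, screw_order = 2,
                            axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  check_layer(layer)
  if (length(n_layers) != 1 || !is.finite(n_layers) || n_layers < 1 ||
      n_layers != round(n_layers))
    stop("n_layers must be a positive integer", call. = FALSE)
  if (!is.finite(rise) || rise <= 0) stop("rise must be > 0", call. = FALSE)
  if (!is.finite(twist) || abs(twist) >= 180)
    stop("twist must satisfy |twist| < 180 degrees", call. = FALSE)
  gen <- generator_rotation(twist, screw_order)
  u <- unit(axis)
  xyz0 <- as.matrix(layer[, c("x", "y", "z")])
  chains <- rep(LETTERS, length.out = n_layers)
  per <- vector("list", n_layers)
  for (k in seq_len(n_layers) - 1L) {
    xyz <- rotate_about_axis(xyz0, u, k * gen, origin)
    xyz <- sweep(xyz, 2, k * rise * u, `+`)
    lk <- layer
    lk$x <- xyz[, 1]; lk$y <- xyz[, 2]; lk$z <- xyz[, 3]
    lk$layer <- k
    lk$chain <- chains[k + 1L]
    lk$resno_global <- lk$resno + 1000L * k
    per[[k + 1L]] <- lk
  }
  closure <- (n_layers * gen) %% 360
  periodic <- min(closure, 360 - closure) < 1e-9
  structure(list(
    atoms = do.call(rbind, per),
    template = layer,
    n_layers = as.integer(n_layers),
    rise = rise,
    twist = twist,
    screw_order = as.integer(screw_order),
    axis = u,
    origin = origin,
    periodic = periodic
  ), class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  cat("fibril_model:", x$n_layers, "layer(s),",
      nrow(x$template), "atoms/layer\n")
  cat(sprintf("  rise %.3f nm, twist %.4f deg, %d-fold screw (generator %.4f deg)\n",
              x$rise, x$twist, x$screw_order,
              generator_rotation(x$twist, x$screw_order)))
  cat("  periodic closure:", if (x$periodic) "yes" else "no", "\n")
  invisible(x)
}

# coordinates of one stored layer as a matrix
layer_coords <- function(model, k) {
  sel <- model$atoms$layer == k
  as.matrix(model$atoms[sel, c("x", "y", "z")])
}

#' Verify the imposed screw symmetry of a fibril model
#'
#' Applies the screw generator to each stored layer k and reports the RMSD
#' against stored layer k+1. For a freshly built model all values are at
#' numerical zero; coordinate perturbations show up proportionally.
#'
#' @param model a `fibril_model`.
#' @return Numeric vector of per-interface RMSDs (nm), length
#'   `n_layers - 1`.
#' @export
verify_symmetry <- function(model) {
  stopifnot(inherits(model, "fibril_model"))
  if (model$n_layers < 2)
    stop("symmetry verification needs at least 2 layers", call. = FALSE)
  gen <- generator_rotation(model$twist, model$screw_order)
  vapply(seq_len(model$n_layers - 1L) - 1L, function(k) {
    mapped <- rotate_about_axis(layer_coords(model, k), model$axis, gen,
                                model$origin)
    mapped <- sweep(mapped, 2, model$rise * model$axis, `+`)
    coord_rmsd(mapped, layer_coords(model, k + 1L))
  }, numeric(1))
}

#' Fibril axis frame
#'
#' Returns an orthonormal frame whose z axis is the fibril axis. The axis
#' direction and line are those of the screw generator stored in the model
#' (they are exact for a built supercell and are carried along by
#' [transform_model()]); estimating the axis from layer centroids is
#' deliberately avoided because for a 2-fold screw the centroids alternate
#' around the axis and a principal-component fit is biased at small layer
#' counts. The frame origin is the centroid of layer 0 projected onto the
#' axis line, and the x axis is the projection of (first atom - centroid)
#' of layer 0 perpendicular to z, so the full frame co-rotates with the
#' coordinates.
#'
#' @param model a `fibril_model`.
#' @return List with `origin`, `x`, `y`, `z` (unit vectors).
#' @export
axis_frame <- function(model) {
  stopifnot(inherits(model, "fibril_model"))
  z <- unit(model$axis)
  c0 <- unname(colMeans(layer_coords(model, 0L)))
  origin <- model$origin + sum((c0 - model$origin) * z) * z
  a1 <- unname(layer_coords(model, 0L)[1, ])
  xv <- (a1 - c0) - sum((a1 - c0) * z) * z
  x <- if (sqrt(sum(xv^2)) < 1e-9) {
    # layer degenerate along z: pick any perpendicular
    unit(cross3(z, if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  } else unit(xv)
  list(origin = origin, x = x, y = cross3(z, x), z = z)
}

#' Rigidly transform a fibril model
#'
#' Applies `xyz -> R xyz + shift` to every atom and to the stored axis and
#' origin, so that derived quantities ([axis_frame()], [verify_symmetry()])
#' transform equivariantly.
#'
#' @param model a `fibril_model`.
#' @param R 3x3 rotation matrix (default identity).
#' @param shift length-3 translation (default zero).
#' @return The transformed `fibril_model`.
#' @export
transform_model <- function(model, R = diag(3), shift = c(0, 0, 0)) {
  stopifnot(inherits(model, "fibril_model"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model$axis <- as.vector(R %*% model$axis)
  model$origin <- as.vector(R %*% model$origin) + shift
  model
}
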