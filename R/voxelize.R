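# Voxelization: map atom-localized feature values onto a regular 3D grid
# with Gaussian kernels whose width is the atomic van der Waals radius,
# rotational data augmentation, per-channel standardization, and the grid
# store.

#' Create a grid specification
#'
#' The grid is a cube of `size` voxels per side, `voxel` Angstrom each,
#' centered on the environment center (the variant residue's C-alpha).
#' Per-axis voxel-center offsets span
#' `[-(size*voxel)/2 + voxel/2, +(size*voxel)/2 - voxel/2]`.
#'
#' @param e A `vxm_environment`, or a length-3 numeric center.
#' @param size Voxels per side (default 20).
#' @param voxel Voxel edge length in Angstrom (default 1).
#' @param rotation 3x3 orthonormal rotation matrix (identity for the origin
#'   grid).
#' @return Object of class `vxm_gridspec`.
#' @export
make_grid_spec <- function(e, size = 20, voxel = 1, rotation = diag(3)) {
  center <- if (inherits(e, "vxm_environment")) e$center else as.numeric(e)
  stopifnot(length(center) == 3, size >= 1, voxel > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort("rotation must be a proper orthonormal 3x3 matrix")
  }
  offsets <- seq(-(size * voxel) / 2 + voxel / 2,
                 (size * voxel) / 2 - voxel / 2, length.out = size)
  structure(list(center = center, size = as.integer(size), voxel = voxel,
                 rotation = rotation, offsets = offsets),
            class = "vxm_gridspec")
}

#' Voxel-center positions of a grid
#'
#' @param spec A `vxm_gridspec`.
#' @return Matrix (size^3 x 3) of voxel-center coordinates in Angstrom, the
#'   first grid axis varying fastest (matching R array filling order).
#' @export
grid_points <- function(spec) {
  g <- as.matrix(expand.grid(x = spec$offsets, y = spec$offsets,
                             z = spec$offsets))
  g <- g %*% t(spec$rotation)
  sweep(g, 2, spec$center, `+`)
}

#' Gaussian mapping of atomic values onto one grid channel
#'
#' Each atom k with value v_k contributes
#' `v_k * exp(-|r - r_k|^2 / (2 sigma_k^2))` to the grid point at position
#' r, where sigma_k is the atom's van der Waals radius. Contributions are
#' evaluated at voxel centers with no truncation radius, so they strictly
#' decrease with distance and grids are linear in the atom values.
#'
#' @param coords Atom coordinate matrix (n x 3).
#' @param values Numeric vector of per-atom feature values (length n).
#' @param sigmas Per-atom Gaussian widths in Angstrom (> 0).
#' @param spec A `vxm_gridspec`.
#' @return 3D numeric array (size x size x size).
#' @export
gaussian_map <- function(coords, values, sigmas, spec) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  stopifnot(length(values) == n, length(sigmas) == n)
  if (n > 0 && any(sigmas <= 0)) abort("Gaussian widths must be positive")
  m <- .gauss_weights(coords, sigmas, spec) %*% matrix(values, ncol = 1)
  array(m, dim = rep(spec$size, 3))
}

# (size^3 x n) matrix of Gaussian kernel evaluations, shared by all channels
.gauss_weights <- function(coords, sigmas, spec) {
  pts <- grid_points(spec)
  if (nrow(coords) == 0) {
    return(matrix(0, nrow(pts), 0))
  }
  d2 <- outer(rowSums(pts^2), rowSums(coords^2), `+`) -
    2 * pts %*% t(coords)
  d2[d2 < 0] <- 0  # numerical noise
  exp(sweep(d2, 2, -2 * sigmas^2, `/`))
}

#' Voxelize an environment's feature matrix
#'
#' Maps every feature channel of `af` onto the grid with [gaussian_map()]
#' (all channels share the same kernel matrix, so this is a single matrix
#' product), producing the rank-4 tensor consumed by the network.
#'
#' @param e A `vxm_environment`.
#' @param af A `vxm_atom_features`.
#' @param spec A `vxm_gridspec`.
#' @param coords Optional replacement atom coordinates (n x 3), used by
#'   [augment()] to map rotated copies; defaults to the environment's.
#' @param augmentation_index Integer tag (0 = origin grid).
#' @param rotation The rotation applied to the coordinates, recorded for
#'   provenance (identity for the origin grid).
#' @return Object of class `vxm_grid`: list with `values` (array size x
#'   size x size x channels), `spec`, `channels`, `variant`,
#'   `augmentation_index`, `rotation`, `atom_coords`.
#' @export
voxelize <- function(e, af, spec, coords = NULL, augmentation_index = 0L,
                     rotation = diag(3)) {
  stopifnot(inherits(e, "vxm_environment"),
            inherits(af, "vxm_atom_features"),
            inherits(spec, "vxm_gridspec"))
  if (any(!is.finite(af$values))) {
    bad <- which(!is.finite(af$values), arr.ind = TRUE)[1, ]
    abort(sprintf("NaN/Inf feature value at atom %d, channel %s",
                  bad[1], af$channels[bad[2]]))
  }
  if (is.null(coords)) coords <- cbind(e$atoms$x, e$atoms$y, e$atoms$z)
  sigmas <- .vdw_radius_of(e$atoms$element)
  w <- .gauss_weights(coords, sigmas, spec)
  vals <- w %*% af$values
  arr <- array(vals, dim = c(rep(spec$size, 3), ncol(af$values)))
  structure(
    list(values = arr, spec = spec, channels = af$channels,
         variant = e$variant,
         augmentation_index = as.integer(augmentation_index),
         rotation = rotation, atom_coords = coords),
    class = "vxm_grid"
  )
}

#' @export
print.vxm_grid <- function(x, ...) {
  cat(sprintf("<vxm_grid> %d^3 x %d channels (augmentation %d)\n",
              x$spec$size, length(x$channels), x$augmentation_index))
  invisible(x)
}

# uniform random rotation matrix from three uniforms (unit quaternion)
.random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Rotational data augmentation
#'
#' Produces the origin grid plus `n` augmented grids. Each augmentation
#' rotates the environment's atom coordinates about the grid center with an
#' independent uniform random rotation (unit-quaternion sampling) and
#' re-maps the (rotation-independent) per-atom feature values. Reproducible
#' given `seed`.
#'
#' @param e A `vxm_environment`.
#' @param af A `vxm_atom_features`.
#' @param spec A `vxm_gridspec`.
#' @param n Number of augmentations (default 5, giving 6 grids).
#' @param seed Integer seed.
#' @return List of `n + 1` `vxm_grid` objects, element 1 being the
#'   identity-rotation origin grid (`augmentation_index` 0).
#' @export
augment <- function(e, af, spec, n = 5, seed = 1L) {
  stopifnot(n >= 0)
  grids <- vector("list", n + 1)
  grids[[1]] <- voxelize(e, af, spec, augmentation_index = 0L)
  if (n == 0) return(grids)
  coords <- cbind(e$atoms$x, e$atoms$y, e$atoms$z)
  centered <- sweep(coords, 2, spec$center, `-`)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(n)) {
    rot <- .random_rotation()
    rc <- sweep(centered %*% t(rot), 2, spec$center, `+`)
    grids[[i + 1]] <- voxelize(e, af, spec, coords = rc,
                               augmentation_index = i, rotation = rot)
  }
  grids
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit / apply per-channel standardization
#'
#' Statistics (mean, sd per channel) are computed over every voxel of the
#' supplied training grids only; validation and test grids must be
#' transformed with the training statistics. Standard deviations are
#' floored at 1e-8 so constant channels map to zero rather than dividing
#' by zero.
#'
#' @param grids Non-empty list of `vxm_grid` objects (the training fold).
#' @return Object of class `vxm_standardizer` with `mean`, `sd`,
#'   `channels`.
#' @export
fit_standardizer <- function(grids) {
  if (length(grids) == 0) abort("cannot fit a standardizer on an empty training set")
  channels <- grids[[1]]$channels
  nc <- length(channels)
  s <- numeric(nc); ss <- numeric(nc); count <- 0
  for (g in grids) {
    m <- matrix(g$values, ncol = nc)
    s <- s + colSums(m)
    ss <- ss + colSums(m^2)
    count <- count + nrow(m)
  }
  mu <- s / count
  varv <- pmax(ss / count - mu^2, 0)
  structure(list(mean = mu, sd = pmax(sqrt(varv), 1e-8),
                 channels = channels),
            class = "vxm_standardizer")
}

#' @rdname fit_standardizer
#' @param stats A `vxm_standardizer`.
#' @param grid A `vxm_grid`.
#' @return The grid with standardized channel values.
#' @export
apply_standardizer <- function(stats, grid) {
  stopifnot(inherits(stats, "vxm_standardizer"), inherits(grid, "vxm_grid"))
  nc <- length(stats$channels)
  m <- matrix(grid$values, ncol = nc)
  m <- sweep(sweep(m, 2, stats$mean, `-`), 2, stats$sd, `/`)
  grid$values <- array(m, dim = dim(grid$values))
  grid$standardized <- TRUE
  grid
}

#' Void-to-occupied voxel ratio
#'
#' A voxel is non-void when at least one atom center falls inside it.
#' Returns the ratio of void to non-void voxels, the grid-sparsity measure
#' compared against prediction scores in the solvent-accessibility
#' analysis.
#'
#' @param g A `vxm_grid`.
#' @return A single number, #void / #non-void.
#' @export
void_ratio <- function(g) {
  stopifnot(inherits(g, "vxm_grid"))
  spec <- g$spec
  rel <- sweep(g$atom_coords, 2, spec$center, `-`)
  half <- spec$size * spec$voxel / 2
  idx <- floor((rel + half) / spec$voxel) + 1
  inside <- rowSums(idx >= 1 & idx <= spec$size) == 3
  idx <- idx[inside, , drop = FALSE]
  if (nrow(idx) == 0) abort("no atom centers inside the grid: void ratio undefined")
  occupied <- length(unique(
    (idx[, 1] - 1) + (idx[, 2] - 1) * spec$size +
      (idx[, 3] - 1) * spec$size^2
  ))
  total <- spec$size^3
  (total - occupied) / occupied
}

#' Save / load a grid store
#'
#' The grid store is a single-file container holding, per variant: the
#' origin and augmented grids in augmentation order, the label, the protein
#' id, and the shared channel registry. `load_grids(save_grids(x))`
#' reproduces the store exactly.
#'
#' @param store A list with `entries` (list of per-variant lists holding
#'   `variant`, `label`, `protein_id`, `grids`) and `channels`.
#' @param path File path.
#' @return `path` invisibly for `save_grids`; the store for `load_grids`.
#' @export
save_grids <- function(store, path) {
  stopifnot(is.list(store), !is.null(store$entries))
  for (en in store$entries) {
    if (is.null(en$label)) abort("grid store entries must carry a label attribute")
    ord <- vapply(en$grids, `[[`, integer(1), "augmentation_index")
    if (!identical(ord, sort(ord))) {
      abort("grids of an entry must be stored in augmentation order")
    }
  }
  saveRDS(store, path)
  invisible(path)
}

#' @rdname save_grids
#' @export
load_grids <- function(path) {
  if (!file.exists(path)) abort(paste0("grid store not found: ", path))
  store <- tryCatch(readRDS(path),
                    error = function(e) abort(paste0("corrupt grid store: ", path)))
  if (is.null(store$entries)) abort("not a grid store (no entries)")
  for (en in store$entries) {
    if (is.null(en$label)) abort("grid store entry is missing its label attribute")
  }
  store
}
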