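# Grid geometry, Gaussian mapping, augmentation, standardization, void
# ratio and the grid store.

test_that("grid lattices span the documented offsets", {
  spec <- make_grid_spec(c(0, 0, 0), size = 20, voxel = 1)
  expect_equal(range(spec$offsets), c(-9.5, 9.5))
  expect_length(spec$offsets, 20)

  one <- make_grid_spec(c(1, 2, 3), size = 1, voxel = 1)
  expect_equal(grid_points(one), matrix(c(1, 2, 3), 1), ignore_attr = TRUE)

  hyper <- make_grid_spec(c(0, 0, 0), size = 15, voxel = 1)
  expect_equal(nrow(grid_points(hyper)), 15^3)

  expect_error(make_grid_spec(c(0, 0, 0), rotation = diag(3) * 2),
               "orthonormal")
})

test_that("Gaussian mapping reproduces closed forms and is linear", {
  spec <- make_grid_spec(c(0, 0, 0), size = 5, voxel = 1)
  # an atom exactly at the central voxel center
  g <- gaussian_map(matrix(c(0, 0, 0), 1), 1, 1.7, spec)
  expect_equal(g[3, 3, 3], 1.0)

  # at distance sigma from a voxel center the kernel is exp(-1/2)
  sigma <- 1.7
  g2 <- gaussian_map(matrix(c(sigma, 0, 0), 1), 1, sigma, spec)
  expect_equal(g2[3, 3, 3], exp(-0.5), tolerance = 1e-12)

  # superposition
  a1 <- matrix(c(0.3, -0.2, 0.7), 1)
  a2 <- matrix(c(-1.1, 0.5, 0.1), 1)
  g_sum <- gaussian_map(rbind(a1, a2), c(2, -1), c(1.7, 1.55), spec)
  g_sep <- gaussian_map(a1, 2, 1.7, spec) + gaussian_map(a2, -1, 1.55, spec)
  expect_equal(g_sum, g_sep, tolerance = 1e-12)

  expect_error(gaussian_map(a1, 1, 0, spec), "positive")
})

test_that("vectorized mapping equals the naive per-voxel per-atom sum", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:10, 1)
    coords <- matrix(runif(3 * n, -4, 4), ncol = 3)
    values <- rnorm(n)
    sigmas <- runif(n, 1.4, 1.9)
    spec <- make_grid_spec(runif(3, -1, 1), size = 6, voxel = 1.5)
    g <- gaussian_map(coords, values, sigmas, spec)
    pts <- grid_points(spec)
    brute <- numeric(nrow(pts))
    for (p in seq_len(nrow(pts))) {
      for (k in seq_len(n)) {
        d2 <- sum((pts[p, ] - coords[k, ])^2)
        brute[p] <- brute[p] + values[k] * exp(-d2 / (2 * sigmas[k]^2))
      }
    }
    expect_equal(c(g), brute, tolerance = 1e-9)
  }
})

test_that("moving an atom farther from a voxel never increases its value", {
  spec <- make_grid_spec(c(0, 0, 0), size = 5, voxel = 1)
  dists <- seq(0, 6, by = 0.25)
  vals <- vapply(dists, function(d) {
    gaussian_map(matrix(c(d, 0, 0), 1), 1, 1.7, spec)[3, 3, 3]
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

voxel_fixture <- function(radius = 50) {
  s <- synth_structure(12, seed = 9, helix_length = 12, id = "vx")
  res <- residue_table(s)
  v_aa <- res$aa[res$resno == 6]
  v <- variant_record("vx", "A", 6, v_aa, setdiff(amino_acids(), v_aa)[1],
                      protein_id = "p")
  e <- extract_environment(s, v, radius = radius)
  ff <- load_forcefield()
  bg <- build_bond_graph(s)
  sasa <- compute_sasa(s, n_points = 240)
  names(sasa) <- as.character(s$atoms$serial)
  af <- assemble_atom_features(e, ff, bg, flat_pssm(s), v, sasa = sasa)
  list(s = s, e = e, af = af)
}

test_that("voxelize produces the documented tensor and flags NaN features", {
  fx <- voxel_fixture()
  spec <- make_grid_spec(fx$e, size = 20, voxel = 1)
  g <- voxelize(fx$e, fx$af, spec)
  expect_equal(dim(g$values), c(20, 20, 20, 31))
  expect_true(all(is.finite(g$values)))

  zero <- fx$af
  zero$values[] <- 0
  g0 <- voxelize(fx$e, zero, spec)
  expect_true(all(g0$values == 0))

  bad <- fx$af
  bad$values[2, 5] <- NaN
  expect_error(voxelize(fx$e, bad, spec), "channel")
})

test_that("augmentation yields n+1 reproducible isometric grids", {
  fx <- voxel_fixture()
  spec <- make_grid_spec(fx$e, size = 8, voxel = 2.5)
  grids <- augment(fx$e, fx$af, spec, n = 5, seed = 11)
  expect_length(grids, 6)
  expect_equal(vapply(grids, `[[`, integer(1), "augmentation_index"), 0:5)
  expect_equal(grids[[1]]$rotation, diag(3))

  # rotations preserve atom-center distances
  center <- spec$center
  d0 <- sqrt(rowSums(sweep(grids[[1]]$atom_coords, 2, center)^2))
  for (k in 2:6) {
    dk <- sqrt(rowSums(sweep(grids[[k]]$atom_coords, 2, center)^2))
    expect_equal(dk, d0, tolerance = 1e-9)
    R <- grids[[k]]$rotation
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }

  # same seed -> bitwise-identical rotations
  again <- augment(fx$e, fx$af, spec, n = 5, seed = 11)
  for (k in 2:6) expect_identical(again[[k]]$rotation, grids[[k]]$rotation)

  # total channel mass is near-invariant for well-contained atoms
  mass <- function(g) sum(abs(g$values[, , , 1]))
  m0 <- mass(grids[[1]])
  for (k in 2:6) expect_lt(abs(mass(grids[[k]]) - m0) / m0, 0.05)
})

test_that("standardization uses training statistics and floors constants", {
  v1 <- array(0, c(3, 3, 3, 2)); v1[, , , 1] <- 5; v1[, , , 2] <- 0
  v2 <- array(0, c(3, 3, 3, 2)); v2[, , , 1] <- 5; v2[, , , 2] <- 2
  g1 <- fake_grid(v1); g2 <- fake_grid(v2)
  std <- fit_standardizer(list(g1, g2))
  t1 <- apply_standardizer(std, g1)
  t2 <- apply_standardizer(std, g2)
  # constant channel value 5 -> all zeros
  expect_true(all(t1$values[, , , 1] == 0))
  expect_true(all(t2$values[, , , 1] == 0))
  # {0, 2} channel -> {-1, +1}
  expect_true(all(abs(t1$values[, , , 2] + 1) < 1e-9))
  expect_true(all(abs(t2$values[, , , 2] - 1) < 1e-9))

  # a third grid is transformed with the training stats, not its own
  v3 <- array(0, c(3, 3, 3, 2)); v3[, , , 2] <- 6
  t3 <- apply_standardizer(std, fake_grid(v3))
  expect_true(all(abs(t3$values[, , , 2] - 5) < 1e-9))

  expect_error(fit_standardizer(list()), "empty")
})

test_that("void ratio counts atom-occupied voxels", {
  # a single atom inside one voxel of a 20^3 grid
  spec <- make_grid_spec(c(0, 0, 0), size = 20, voxel = 1)
  g <- fake_grid(array(0, c(20, 20, 20, 1)))
  g$atom_coords <- matrix(c(0.2, 0.2, 0.2), 1)
  expect_equal(void_ratio(g), (8000 - 1) / 1)

  # atoms in exactly half the voxels of a 2^3 grid
  g2 <- fake_grid(array(0, c(2, 2, 2, 1)))
  g2$spec <- make_grid_spec(c(0, 0, 0), size = 2, voxel = 1)
  g2$atom_coords <- rbind(c(-0.5, -0.5, -0.5), c(0.5, -0.5, -0.5),
                          c(-0.5, 0.5, -0.5), c(0.5, 0.5, -0.5))
  expect_equal(void_ratio(g2), 1.0)

  # no atoms inside the box -> undefined
  g3 <- fake_grid(array(0, c(2, 2, 2, 1)))
  g3$atom_coords <- matrix(c(50, 50, 50), 1)
  expect_error(void_ratio(g3), "undefined")
})

test_that("the grid store round-trips exactly and validates labels", {
  fx <- voxel_fixture()
  spec <- make_grid_spec(fx$e, size = 6, voxel = 3)
  grids <- augment(fx$e, fx$af, spec, n = 5, seed = 2)
  store <- list(entries = list(list(variant = tibble::tibble(id = "v1"),
                                    label = "benign", protein_id = "p1",
                                    grids = grids)),
                channels = fx$af$channels)
  path <- withr::local_tempfile(fileext = ".rds")
  save_grids(store, path)
  back <- load_grids(path)
  expect_identical(back$entries[[1]]$grids[[3]]$values, grids[[3]]$values)
  expect_equal(vapply(back$entries[[1]]$grids, `[[`, integer(1),
                      "augmentation_index"), 0:5)

  broken <- store
  broken$entries[[1]]$label <- NULL
  expect_error(save_grids(broken, path), "label")
  expect_error(load_grids(withr::local_tempfile(fileext = ".rds")),
               "not found")
})
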