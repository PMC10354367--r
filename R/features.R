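# Per-atom feature calculation: bond topology, pairwise nonbonded energies,
# Shrake-Rupley solvent accessibility, normalized B-factors, and the
# assembly of the full multi-channel per-atom feature matrix.

#' Build the covalent bond graph of a structure
#'
#' Bonds are inferred geometrically: two heavy atoms are bonded when their
#' distance is at most the sum of their single-bond covalent radii plus
#' 0.4 Angstrom. From the adjacency, the set of 1-2 (bonded) and 1-3
#' (separated by two bonds) pairs is derived by a two-step graph walk;
#' these pairs are excluded from the pairwise Coulomb and Lennard-Jones
#' sums.
#'
#' @param s A `vxm_structure`.
#' @return An object of class `vxm_bondgraph`: list with `adj` (list of
#'   integer neighbor vectors, indexed by atom row), `excluded` (environment
#'   hash of "i|j" keys, i < j, for all 1-2/1-3 pairs), `serial` (atom
#'   serials in row order).
#' @export
build_bond_graph <- function(s) {
  stopifnot(inherits(s, "vxm_structure"))
  at <- s$atoms
  n <- nrow(at)
  xyz <- cbind(at$x, at$y, at$z)
  rcov <- .covalent_radius_of(at$element)
  adj <- vector("list", n)
  if (n > 1) {
    d2 <- as.matrix(stats::dist(xyz))^2
    thr <- outer(rcov, rcov, `+`) + 0.4
    bonded <- d2 <= thr^2 & d2 > 0
    for (i in seq_len(n)) adj[[i]] <- which(bonded[i, ])
  } else {
    adj[[1]] <- integer(0)
  }
  excl <- new.env(hash = TRUE, parent = emptyenv())
  put <- function(i, j) {
    if (i != j) {
      key <- if (i < j) paste0(i, "|", j) else paste0(j, "|", i)
      assign(key, TRUE, envir = excl)
    }
  }
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      put(i, j)                      # 1-2
      for (k in adj[[j]]) put(i, k)  # 1-3
    }
  }
  structure(list(adj = adj, excluded = excl, serial = at$serial),
            class = "vxm_bondgraph")
}

#' @export
print.vxm_bondgraph <- function(x, ...) {
  cat(sprintf("<vxm_bondgraph> %d atoms, %d bonds, %d excluded 1-2/1-3 pairs\n",
              length(x$adj), sum(lengths(x$adj)) / 2,
              length(ls(x$excluded))))
  invisible(x)
}

#' Is an atom pair excluded from nonbonded sums?
#'
#' @param bg A `vxm_bondgraph`.
#' @param i,j Atom row indices (into the structure the graph was built on).
#' @return Logical.
#' @export
is_excluded_pair <- function(bg, i, j) {
  key <- if (i < j) paste0(i, "|", j) else paste0(j, "|", i)
  exists(key, envir = bg$excluded, inherits = FALSE)
}

# shared machinery: map environment atoms back to structure rows (by serial),
# return pair mask (n_env x n_env) with self and 1-2/1-3 pairs removed
.env_pair_mask <- function(e, bg) {
  idx <- match(e$atoms$serial, bg$serial)
  if (anyNA(idx)) {
    abort("environment atoms are not all present in the bond graph's structure")
  }
  n <- length(idx)
  mask <- matrix(TRUE, n, n)
  diag(mask) <- FALSE
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a < b && is_excluded_pair(bg, idx[a], idx[b])) {
        mask[a, b] <- FALSE
        mask[b, a] <- FALSE
      }
    }
  }
  mask
}

.env_dist_matrix <- function(e) {
  xyz <- cbind(e$atoms$x, e$atoms$y, e$atoms$z)
  as.matrix(stats::dist(xyz))
}

#' Per-atom Coulomb potential sums
#'
#' For every atom in the environment, the sum of pairwise electrostatic
#' potentials K q_i q_j / r_ij over all other environment atoms, excluding
#' pairs separated by up to two covalent bonds. K is [COULOMB_CONSTANT];
#' no distance-dependent dielectric and no shifting function are applied.
#'
#' @param e A `vxm_environment`.
#' @param ff A `vxm_forcefield`.
#' @param bg A `vxm_bondgraph` built on the parent structure.
#' @return Numeric vector (kcal/mol), one value per environment atom.
#' @export
compute_coulomb <- function(e, ff, bg) {
  stopifnot(inherits(e, "vxm_environment"))
  at <- suppressWarnings(ff_assign(e$atoms, ff))
  n <- nrow(at)
  if (n == 0) return(numeric(0))
  if (n == 1) return(0)
  mask <- .env_pair_mask(e, bg)
  r <- .env_dist_matrix(e)
  clash <- which(r == 0 & mask, arr.ind = TRUE)
  if (nrow(clash) > 0) {
    abort(sprintf("atomic clash: atoms %d and %d (serials %d, %d) coincide",
                  clash[1, 1], clash[1, 2],
                  at$serial[clash[1, 1]], at$serial[clash[1, 2]]))
  }
  qq <- outer(at$charge, at$charge)
  pot <- COULOMB_CONSTANT * qq / ifelse(r == 0, Inf, r)
  unname(rowSums(pot * mask))
}

#' Per-atom Lennard-Jones potential sums
#'
#' For every environment atom, the sum of 4 eps_ij ((sig_ij/r)^12 -
#' (sig_ij/r)^6) over the same non-bonded environment pair set as
#' [compute_coulomb()]. Combination rules: sigma by arithmetic mean,
#' epsilon by geometric mean.
#'
#' @inheritParams compute_coulomb
#' @return Numeric vector (kcal/mol), one value per environment atom.
#' @export
compute_vdw <- function(e, ff, bg) {
  stopifnot(inherits(e, "vxm_environment"))
  at <- suppressWarnings(ff_assign(e$atoms, ff))
  n <- nrow(at)
  if (n == 0) return(numeric(0))
  if (n == 1) return(0)
  mask <- .env_pair_mask(e, bg)
  r <- .env_dist_matrix(e)
  clash <- which(r == 0 & mask, arr.ind = TRUE)
  if (nrow(clash) > 0) {
    abort(sprintf("atomic clash: atoms %d and %d (serials %d, %d) coincide",
                  clash[1, 1], clash[1, 2],
                  at$serial[clash[1, 1]], at$serial[clash[1, 2]]))
  }
  sig <- outer(at$sigma, at$sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(at$epsilon, at$epsilon))
  sr6 <- (sig / ifelse(r == 0, Inf, r))^6
  pot <- 4 * eps * (sr6^2 - sr6)
  unname(rowSums(pot * mask))
}

# deterministic golden-spiral unit sphere points
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA computed on the full structure (so burial reflects the
#' whole protein, not just the variant neighborhood) by rolling a probe
#' sphere: each atom's expanded sphere (vdW radius + probe) is sampled on a
#' deterministic golden-spiral lattice and the accessible fraction is the
#' share of sample points not inside any neighbor's expanded sphere.
#'
#' @param s A `vxm_structure`.
#' @param probe Probe radius in Angstrom (water, default 1.4).
#' @param n_points Number of lattice points per sphere (default 960).
#' @return Numeric vector of per-atom SASA (A^2) in atom-row order.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "vxm_structure"))
  at <- s$atoms
  n <- nrow(at)
  if (n == 0) return(numeric(0))
  xyz <- cbind(at$x, at$y, at$z)
  rad <- .vdw_radius_of(at$element) + probe
  pts <- .sphere_points(n_points)
  out <- numeric(n)
  # neighbor lists limit the point-in-sphere tests to plausible occluders
  maxr <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + maxr & seq_len(n) != i)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & dj2 > rad[j]^2
    }
    out[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  out
}

#' Per-residue SASA totals
#'
#' @param s A `vxm_structure`.
#' @param sasa Per-atom SASA from [compute_sasa()] (computed when omitted).
#' @return Tibble with `chain`, `resno`, `icode`, `aa`, `sasa` (A^2).
#' @export
residue_sasa <- function(s, sasa = NULL) {
  if (is.null(sasa)) sasa <- compute_sasa(s)
  at <- s$atoms
  at$sasa <- sasa
  at %>%
    group_by(.data$chain, .data$resno, .data$icode) %>%
    summarise(aa = .data$aa[1], sasa = sum(.data$sasa), .groups = "drop")
}

#' Normalized B-factors
#'
#' Per-structure z-score of the crystallographic B-factor:
#' (b - mean) / sd over all atoms of the structure, with the population
#' standard deviation (so a two-atom structure normalizes to exactly
#' -1/+1). A structure with constant B-factors yields all zeros.
#'
#' @param s A `vxm_structure`.
#' @return Numeric vector, one unitless value per atom in row order.
#' @export
normalized_bfactor <- function(s) {
  stopifnot(inherits(s, "vxm_structure"))
  b <- s$atoms$b
  if (length(b) == 0) return(numeric(0))
  sdb <- sqrt(mean((b - mean(b))^2))
  if (!is.finite(sdb) || sdb == 0) return(rep(0, length(b)))
  (b - mean(b)) / sdb
}
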