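# In-code fixtures shared across the suite. Everything is generated
# programmatically; no binary data on disk.

# minimal atom-table builder with sensible defaults
atom_row <- function(serial, name, element, resname, chain, resno, x, y, z,
                     b = 10, occ = 1, icode = "") {
  tibble::tibble(
    serial = as.integer(serial), name = name, element = element,
    resname = resname, aa = unname(voxmut:::.AA3TO1[resname]),
    chain = chain, resno = as.integer(resno), icode = icode,
    x = x, y = y, z = z, b = b, occ = occ
  )
}

# a single alanine-like residue with 5 heavy atoms around the origin
one_residue_atoms <- function(chain = "A", resno = 1, offset = c(0, 0, 0)) {
  dplyr::bind_rows(
    atom_row(1, "N",  "N", "ALA", chain, resno, -1.2 + offset[1], offset[2], offset[3]),
    atom_row(2, "CA", "C", "ALA", chain, resno,  0.0 + offset[1], offset[2], offset[3]),
    atom_row(3, "C",  "C", "ALA", chain, resno,  1.3 + offset[1], offset[2], offset[3]),
    atom_row(4, "O",  "O", "ALA", chain, resno,  1.8 + offset[1], 1.1 + offset[2], offset[3]),
    atom_row(5, "CB", "C", "ALA", chain, resno,  0.0 + offset[1], 1.5 + offset[2], offset[3])
  )
}

toy_structure <- function(atoms = one_residue_atoms(), id = "toy",
                          method = "X-RAY DIFFRACTION", resolution = 1.8) {
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, id = id, method = method, resolution = resolution)
}

# random heavy-atom cloud inside a sphere; used for voxelization and
# energetics oracles
random_cloud <- function(n, radius = 8, seed = 1, center = c(0, 0, 0)) {
  set.seed(seed)
  els <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  r <- radius * runif(n)^(1 / 3)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  xyz <- sweep(u * r, 2, center, `+`)
  atoms <- tibble::tibble(
    serial = seq_len(n), name = paste0(els, seq_len(n)), element = els,
    resname = "UNK", aa = NA_character_, chain = "A",
    resno = seq_len(n), icode = "", x = xyz[, 1], y = xyz[, 2],
    z = xyz[, 3], b = 10, occ = 1
  )
  atoms
}

# an empty bond graph (no bonds, no exclusions) over a structure
empty_bond_graph <- function(s) {
  structure(list(adj = rep(list(integer(0)), nrow(s$atoms)),
                 excluded = new.env(hash = TRUE, parent = emptyenv()),
                 serial = s$atoms$serial),
            class = "vxm_bondgraph")
}

# a synthetic PSSM over all residues of a structure with constant scores
flat_pssm <- function(s, score = 0, info = 1) {
  res <- residue_table(s)
  out <- list()
  for (ch in unique(res$chain)) {
    rch <- res[res$chain == ch, , drop = FALSE]
    scores <- matrix(score, nrow(rch), 20,
                     dimnames = list(NULL, amino_acids()))
    tbl <- tibble::tibble(resno = rch$resno, aa = rch$aa,
                          info = rep(info, nrow(rch)))
    tbl$scores <- scores
    out[[ch]] <- structure(list(chain = ch, tbl = tbl), class = "vxm_pssm")
  }
  out
}

# fabricate a vxm_grid directly from a value array (for training tests)
fake_grid <- function(values, channels = paste0("ch", seq_len(dim(values)[4])),
                      center = c(0, 0, 0), voxel = 1) {
  spec <- make_grid_spec(center, size = dim(values)[1], voxel = voxel)
  structure(
    list(values = values, spec = spec, channels = channels,
         variant = NULL, augmentation_index = 0L, rotation = diag(3),
         atom_coords = matrix(0, 1, 3)),
    class = "vxm_grid"
  )
}

# quick labeled random-grid task: label-1 grids have channel 1 shifted up
separable_grids <- function(n_per_class, size = 5, channels = 3, shift = 2,
                            seed = 1) {
  set.seed(seed)
  grids <- list(); labels <- character(0)
  for (i in seq_len(2 * n_per_class)) {
    lab <- if (i <= n_per_class) "benign" else "pathogenic"
    v <- array(rnorm(size^3 * channels), dim = c(size, size, size, channels))
    if (lab == "pathogenic") v[, , , 1] <- v[, , , 1] + shift
    grids[[i]] <- fake_grid(v)
    labels <- c(labels, lab)
  }
  list(grids = grids, labels = labels)
}

# write a tiny synthetic bundle (wraps make_dataset with small numbers)
tiny_bundle <- function(dir, n_proteins = 2, variants = 4, seed = 7) {
  cfg <- synth_config(n_proteins = n_proteins, residues_per_protein = 54,
                      variants_per_protein = variants, noise_rate = 0,
                      helix_length = 18, seed = seed)
  make_dataset(cfg, dir)
}
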