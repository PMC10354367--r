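# Force-field table, bond topology, pairwise energetics, solvent
# accessibility, B-factor normalization, PSSM handling and channel
# assembly.

test_that("the shipped force-field table covers canonical residues and falls back by element", {
  ff <- load_forcefield()
  p <- ff_lookup(ff, "ALA", "CA")
  expect_gt(p$vdw_radius, 0)
  expect_false(p$fallback)
  expect_warning(q <- ff_lookup(ff, "XYZ", "ZZ9"), "element defaults")
  expect_true(q$fallback)
  expect_equal(q$charge, 0)

  # per-residue heavy-atom charges sum to the residue's formal charge
  sum_charge <- function(res) {
    keys <- grep(paste0("^", res, "\\|"), names(ff$table), value = TRUE)
    sum(vapply(keys, function(k) ff$table[[k]]$charge, numeric(1)))
  }
  expect_equal(sum_charge("GLY"), 0, tolerance = 1e-9)
  expect_equal(sum_charge("LYS"), 1, tolerance = 1e-9)
  expect_equal(sum_charge("GLU"), -1, tolerance = 1e-9)
})

test_that("bond detection follows covalent radii and the 2-bond exclusion walk", {
  two_atoms <- function(d) {
    toy_structure(dplyr::bind_rows(
      atom_row(1, "C1", "C", "UNK", "A", 1, 0, 0, 0),
      atom_row(2, "C2", "C", "UNK", "A", 1, d, 0, 0)
    ))
  }
  bg <- build_bond_graph(two_atoms(1.5))
  expect_true(2 %in% bg$adj[[1]])
  bg2 <- build_bond_graph(two_atoms(3.0))
  expect_length(bg2$adj[[1]], 0)

  # chain A-B-C: (A, C) separated by two bonds lands in the exclusion set
  chain3 <- toy_structure(dplyr::bind_rows(
    atom_row(1, "C1", "C", "UNK", "A", 1, 0, 0, 0),
    atom_row(2, "C2", "C", "UNK", "A", 1, 1.5, 0, 0),
    atom_row(3, "C3", "C", "UNK", "A", 1, 3.0, 0, 0)
  ))
  bg3 <- build_bond_graph(chain3)
  expect_true(is_excluded_pair(bg3, 1, 3))
  expect_true(is_excluded_pair(bg3, 1, 2))
  expect_false(is_excluded_pair(bg3, 1, 1))
})

charged_ff <- function(charge = 1, sigma = 3, epsilon = 0.2) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(
    "resname\tatom\tcharge\tsigma\tepsilon\tvdw_radius",
    "*\tC\t0\t3.50\t0.066\t1.70",
    "*\tN\t0\t3.25\t0.170\t1.55",
    "*\tO\t0\t2.96\t0.210\t1.52",
    "*\tS\t0\t3.55\t0.250\t1.80",
    "*\tother\t0\t3.55\t0.250\t1.80",
    sprintf("TST\tX1\t%g\t%g\t%g\t2.0", charge, sigma, epsilon),
    sprintf("TST\tX2\t%g\t%g\t%g\t2.0", charge, sigma, epsilon)
  ), path)
  load_forcefield(path)
}

pair_env <- function(d) {
  atoms <- dplyr::bind_rows(
    atom_row(1, "X1", "C", "TST", "A", 1, 0, 0, 0),
    atom_row(2, "CA", "C", "TST", "A", 1, 0.1, 0.8, 0),
    atom_row(3, "X2", "C", "TST", "A", 2, d, 0, 0)
  )
  atoms$aa <- "A"
  s <- toy_structure(atoms)
  v <- variant_record("toy", "A", 1, "A", "V", protein_id = "p")
  extract_environment(s, v, radius = 50)
}

test_that("Coulomb sums match the closed form and honor exclusions", {
  ff <- charged_ff(charge = 1)
  e <- pair_env(1.0)
  s <- toy_structure(e$atoms[, setdiff(names(e$atoms), "dist")])
  bg_free <- empty_bond_graph(s)
  cou <- compute_coulomb(e, ff, bg_free)
  # CA carries charge 0 via fallback; X1 and X2 are +1 at 1 A
  expect_equal(cou[1], 332.0636, tolerance = 1e-6)
  expect_equal(cou[3], 332.0636, tolerance = 1e-6)
  expect_equal(cou[2], 0)

  # bonding the pair removes the interaction entirely
  bg_bonded <- empty_bond_graph(s)
  assign("1|3", TRUE, envir = bg_bonded$excluded)
  cou2 <- compute_coulomb(e, ff, bg_bonded)
  expect_equal(cou2[1], 0)
  expect_equal(cou2[3], 0)
})

test_that("Lennard-Jones sums reproduce the sigma root and epsilon minimum", {
  ff <- charged_ff(charge = 0, sigma = 3, epsilon = 0.2)
  # the CA (needed only to anchor the environment) sits far away so the
  # X1-X2 pair is numerically isolated
  atoms <- dplyr::bind_rows(
    atom_row(1, "X1", "C", "TST", "A", 1, 0, 0, 0),
    atom_row(2, "CA", "C", "TST", "A", 1, 0, 500, 0),
    atom_row(3, "X2", "C", "TST", "A", 2, 3, 0, 0)
  )
  atoms$aa <- "A"
  s <- toy_structure(atoms)
  v <- variant_record("toy", "A", 1, "A", "V", protein_id = "p")
  e <- extract_environment(s, v, radius = 1000)
  vdw <- compute_vdw(e, ff, empty_bond_graph(s))
  expect_equal(vdw[1], 0, tolerance = 1e-9)          # r = sigma -> 0

  atoms$x[3] <- 2^(1 / 6) * 3                        # LJ minimum
  s2 <- toy_structure(atoms)
  e2 <- extract_environment(s2, v, radius = 1000)
  vdw2 <- compute_vdw(e2, ff, empty_bond_graph(s2))
  expect_equal(vdw2[1], -0.2, tolerance = 1e-9)
  expect_equal(vdw2[3], -0.2, tolerance = 1e-9)

  # bonded pairs contribute nothing
  bgb <- empty_bond_graph(s2)
  assign("1|3", TRUE, envir = bgb$excluded)
  expect_equal(compute_vdw(e2, ff, bgb)[1], 0)
})

test_that("per-atom energetics equal an independent brute-force double loop", {
  ff <- load_forcefield()
  for (seed in 1:4) {
    atoms <- random_cloud(12, radius = 5, seed = seed)
    atoms$resname <- "ALA"
    atoms$aa <- "A"
    atoms$name[1] <- "CA"
    s <- toy_structure(atoms)
    v <- variant_record("toy", "A", 1, "A", "V", protein_id = "p")
    e <- extract_environment(s, v, radius = 50)
    bg <- build_bond_graph(s)
    cou <- suppressWarnings(compute_coulomb(e, ff, bg))
    vdw <- suppressWarnings(compute_vdw(e, ff, bg))

    at <- suppressWarnings(voxmut:::ff_assign(e$atoms, ff))
    n <- nrow(at)
    brute_c <- numeric(n); brute_v <- numeric(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        ii <- match(at$serial[i], s$atoms$serial)
        jj <- match(at$serial[j], s$atoms$serial)
        if (is_excluded_pair(bg, ii, jj)) next
        r <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) -
                         c(at$x[j], at$y[j], at$z[j]))^2))
        brute_c[i] <- brute_c[i] +
          COULOMB_CONSTANT * at$charge[i] * at$charge[j] / r
        sg <- (at$sigma[i] + at$sigma[j]) / 2
        ep <- sqrt(at$epsilon[i] * at$epsilon[j])
        brute_v[i] <- brute_v[i] + 4 * ep * ((sg / r)^12 - (sg / r)^6)
      }
    }
    expect_equal(cou, brute_c, tolerance = 1e-9)
    expect_equal(vdw, brute_v, tolerance = 1e-9)
  }
})

test_that("coinciding non-excluded atoms raise a clash error naming both", {
  ff <- load_forcefield()
  atoms <- dplyr::bind_rows(
    atom_row(1, "CA", "C", "ALA", "A", 1, 0, 0, 0),
    atom_row(2, "CB", "C", "ALA", "A", 2, 0, 0, 0)
  )
  s <- toy_structure(atoms)
  v <- variant_record("toy", "A", 1, "A", "V", protein_id = "p")
  e <- extract_environment(s, v, radius = 10)
  expect_error(compute_coulomb(e, ff, empty_bond_graph(s)), "clash")
})

test_that("Shrake-Rupley SASA approaches analytic sphere areas", {
  iso <- toy_structure(atom_row(1, "CA", "C", "ALA", "A", 1, 0, 0, 0))
  a <- compute_sasa(iso)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(a - analytic) / analytic, 0.02)

  # two atoms far apart are each fully exposed
  pair <- toy_structure(dplyr::bind_rows(
    atom_row(1, "CA", "C", "ALA", "A", 1, 0, 0, 0),
    atom_row(2, "CA", "C", "ALA", "A", 2, 100, 0, 0)
  ))
  ap <- compute_sasa(pair)
  expect_equal(ap, rep(a, 2), tolerance = 1e-9)

  # discretization error decreases with lattice density; an isolated atom
  # is exact by construction, so use a two-sphere system whose accessible
  # area has a spherical-cap closed form: equal expanded radii R at
  # center distance d lose a cap of height R - d/2 each
  R <- 1.7 + 1.4
  errs <- vapply(c(240, 960, 3840), function(np) {
    mean(vapply(c(1.7, 2.3, 2.9, 3.7), function(d) {
      exact <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
      two <- toy_structure(dplyr::bind_rows(
        atom_row(1, "CA", "C", "ALA", "A", 1, 0, 0, 0),
        atom_row(2, "CB", "C", "ALA", "A", 1, d, 0, 0)
      ))
      abs(compute_sasa(two, n_points = np)[1] - exact)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2] / (4 * pi * R^2), 0.02)
})

test_that("an atom enclosed by a dense shell has zero accessibility", {
  pts <- voxmut:::.sphere_points(60) * 2.2  # shell of C atoms at 2.2 A
  shell <- tibble::tibble(
    serial = seq_len(nrow(pts)) + 1L, name = "CB", element = "C",
    resname = "ALA", aa = "A", chain = "A",
    resno = seq_len(nrow(pts)) + 1L, icode = "",
    x = pts[, 1], y = pts[, 2], z = pts[, 3], b = 10, occ = 1
  )
  atoms <- dplyr::bind_rows(
    atom_row(1, "CA", "C", "ALA", "A", 1, 0, 0, 0), shell
  )
  s <- toy_structure(atoms)
  sasa <- compute_sasa(s)
  expect_equal(sasa[1], 0)
})

test_that("normalized B-factors are per-structure z-scores", {
  a <- one_residue_atoms()
  a$b <- 20
  expect_equal(normalized_bfactor(toy_structure(a)), rep(0, 5))

  b <- dplyr::bind_rows(
    atom_row(1, "CA", "C", "ALA", "A", 1, 0, 0, 0, b = 10),
    atom_row(2, "CB", "C", "ALA", "A", 1, 1, 0, 0, b = 30)
  )
  z <- normalized_bfactor(toy_structure(b))
  expect_equal(z, c(-1, 1))  # two-point z-score

  s <- synth_structure(24, seed = 5, helix_length = 24)
  expect_lt(abs(mean(normalized_bfactor(s))), 1e-9)
})

test_that("PSSM files round-trip and mapping flags mismatches", {
  s <- synth_structure(12, seed = 2, helix_length = 12, id = "ps")
  res <- residue_table(s)
  keys <- paste(res$chain, res$resno, sep = "|")
  pssm <- synth_pssm(s, keys[c(1, 3)], seed = 4)[["A"]]
  path <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(pssm, path)
  p2 <- read_pssm(path, chain = "A")
  expect_equal(nrow(p2$tbl), 12)
  expect_equal(ncol(p2$tbl$scores), 20)
  expect_equal(p2$tbl$scores, pssm$tbl$scores, ignore_attr = TRUE)
  expect_equal(p2$tbl$info, pssm$tbl$info, tolerance = 0.01)

  m <- map_pssm(s, p2)
  expect_true(all(m$status == "matched"))

  # residue-identity mismatch is flagged
  p3 <- p2
  p3$tbl$aa[2] <- setdiff(amino_acids(), p2$tbl$aa[2])[1]
  m3 <- map_pssm(s, p3)
  expect_equal(sum(m3$status == "mismatch"), 1)

  # missing row for an in-scope residue
  p4 <- p2
  p4$tbl <- p4$tbl[-1, ]
  m4 <- map_pssm(s, p4)
  expect_true("missing" %in% m4$status)
})

test_that("conservation channels are residue-constant and site scores variant-only", {
  s <- synth_structure(12, seed = 2, helix_length = 12, id = "ps")
  res <- residue_table(s)
  v_aa <- res$aa[res$resno == 5]
  v <- variant_record("ps", "A", 5, v_aa, setdiff(amino_acids(), v_aa)[1],
                      protein_id = "p")
  e <- extract_environment(s, v, radius = 50)
  keys <- paste(res$chain, res$resno, sep = "|")
  pssm <- synth_pssm(s, keys[5], seed = 4)
  pf <- pssm_features(e, pssm, v)

  # constant within residue
  for (rn in unique(e$atoms$resno)) {
    rows <- which(e$atoms$resno == rn)
    expect_equal(apply(pf$profile[rows, , drop = FALSE], 2,
                       function(x) length(unique(x))),
                 rep(1, 20), ignore_attr = TRUE)
    expect_length(unique(pf$info_content[rows]), 1)
  }
  # wt/var scores only on the variant residue's atoms
  on_v <- e$atoms$resno == 5
  expect_true(all(pf$wt_score[!on_v] == 0))
  expect_true(all(pf$var_score[!on_v] == 0))
  expect_equal(unique(pf$wt_score[on_v]), 7)   # conserved wildtype column
  expect_equal(unique(pf$var_score[on_v]), -3)

  # a residue with an all-zero profile carries 20 zeros on its atoms
  flat <- flat_pssm(s, score = 0, info = 0)
  pf0 <- pssm_features(e, flat, v)
  expect_true(all(pf0$profile == 0))

  # missing environment rows are a mapping error
  broken <- pssm
  broken[["A"]]$tbl <- broken[["A"]]$tbl[-2, ]
  expect_error(pssm_features(e, broken, v), "missing")
})

test_that("channel assembly matches the registry and density invariants", {
  s <- synth_structure(12, seed = 2, helix_length = 12, id = "ps")
  res <- residue_table(s)
  v_aa <- res$aa[res$resno == 5]
  v <- variant_record("ps", "A", 5, v_aa, setdiff(amino_acids(), v_aa)[1],
                      protein_id = "p")
  e <- extract_environment(s, v, radius = 50)
  ff <- load_forcefield()
  bg <- build_bond_graph(s)
  pssm <- flat_pssm(s, score = 1, info = 2)
  sasa <- compute_sasa(s)
  names(sasa) <- as.character(s$atoms$serial)

  af <- assemble_atom_features(e, ff, bg, pssm, v, config = "all",
                               sasa = sasa)
  expect_length(af$channels, 31)
  expect_equal(af$channels, channel_registry("all"))

  dens <- af$values[, paste0("density.", c("C", "N", "O", "S"))]
  expect_true(all(rowSums(dens) %in% c(0, 1)))
  expect_equal(rowSums(dens) == 1,
               e$atoms$element %in% c("C", "N", "O", "S"))

  expect_length(assemble_atom_features(e, ff, bg, pssm, v,
                                       config = "pssm")$channels, 23)
  expect_length(assemble_atom_features(e, ff, bg, pssm, v,
                                       config = "structural",
                                       sasa = sasa)$channels, 8)
  expect_error(channel_registry("no-such"), "unknown channel")
  expect_error(channel_registry(character(0)), "empty")
  expect_length(feature_groups(), 9)
  expect_equal(sum(lengths(feature_groups())), 31)
})
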