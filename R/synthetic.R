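# Synthetic fixtures: small helical-bundle structures with chemically
# plausible geometry, per-chain conservation profiles, and labeled variant
# tables with a planted buried-and-conserved pathogenic signal. Everything
# is written in the same formats as real inputs (PDB, PSI-BLAST ASCII
# PSSM, TSV variant table) so the full pipeline is exercised end to end.

#' Synthetic dataset configuration
#'
#' @param n_proteins Number of synthetic proteins.
#' @param residues_per_protein Residues per protein (distributed over the
#'   helices of a bundle).
#' @param variants_per_protein Variants sampled per protein.
#' @param noise_rate Probability of flipping a planted label.
#' @param conserved_frac Fraction of residues marked conserved.
#' @param helix_length Residues per helix of the bundle.
#' @param seed Master seed.
#' @return List of class `vxm_synthconfig`.
#' @export
synth_config <- function(n_proteins = 8, residues_per_protein = 126,
                         variants_per_protein = 30, noise_rate = 0.1,
                         conserved_frac = 0.5, helix_length = 18,
                         seed = 1L) {
  stopifnot(n_proteins >= 1, residues_per_protein >= 5,
            variants_per_protein >= 1,
            noise_rate >= 0, noise_rate <= 1,
            conserved_frac >= 0, conserved_frac <= 1)
  structure(list(n_proteins = n_proteins,
                 residues_per_protein = residues_per_protein,
                 variants_per_protein = variants_per_protein,
                 noise_rate = noise_rate, conserved_frac = conserved_frac,
                 helix_length = helix_length, seed = as.integer(seed)),
            class = "vxm_synthconfig")
}

# ideal helix CA trace along z: radius 2.3 A, rise 1.5 A, 100 deg/residue
.helix_ca <- function(n, origin = c(0, 0, 0), flip = FALSE) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  z <- i * 1.5
  if (flip) z <- rev(z)
  cbind(2.3 * cos(th) + origin[1], 2.3 * sin(th) + origin[2], z + origin[3])
}

#' Generate a synthetic helical-bundle structure
#'
#' Builds an idealized alpha-helical bundle: residues are distributed over
#' helices of `helix_length` residues, one chain per helix, helix axes
#' packed on a hexagonal ring around a central helix so that core-facing
#' residues are genuinely buried (burial is verified downstream with the
#' SASA module, not assumed). Each residue carries a backbone (N, CA, C,
#' O) and one pseudo side-chain atom (CB, except glycine); consecutive
#' C-alpha distances within a helix are the canonical ~3.8 A and no two
#' atoms approach closer than 1 A. B-factors increase with radial
#' distance from the bundle axis, mimicking rigid-core/flexible-surface
#' crystallographic behavior.
#'
#' @param n_res Total residue count (>= 5).
#' @param seed Integer seed (sequence and B-factor noise).
#' @param helix_length Residues per helix.
#' @param id Structure identifier.
#' @return A `vxm_structure` with method "X-RAY DIFFRACTION" and
#'   resolution 1.5 A (synthetic structures are always eligible).
#' @export
synth_structure <- function(n_res, seed = 1L, helix_length = 18,
                            id = "synth") {
  stopifnot(n_res >= 5)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_helix <- ceiling(n_res / helix_length)
  ring_r <- 9.5
  axes <- rbind(c(0, 0))
  if (n_helix > 1) {
    ang <- 2 * pi * (seq_len(n_helix - 1) - 1) / max(n_helix - 1, 6)
    axes <- rbind(axes, cbind(ring_r * cos(ang), ring_r * sin(ang)))
  }
  rows <- list()
  serial <- 0L
  res_global <- 0L
  for (h in seq_len(n_helix)) {
    nh <- min(helix_length, n_res - (h - 1) * helix_length)
    ca <- .helix_ca(nh, origin = c(axes[h, 1], axes[h, 2], 0))
    chain <- LETTERS[h]
    aa_seq <- sample(.AA1, nh, replace = TRUE)
    for (i in seq_len(nh)) {
      res_global <- res_global + 1L
      aa <- aa_seq[i]
      resname <- .AA1TO3[aa]
      # local frame: u_prev/u_next along the CA trace, radial unit vector
      u_next <- if (i < nh) .unit(ca[i + 1, ] - ca[i, ]) else .unit(ca[i, ] - ca[i - 1, ])
      u_prev <- if (i > 1) .unit(ca[i - 1, ] - ca[i, ]) else -u_next
      radial <- .unit(c(ca[i, 1] - axes[h, 1], ca[i, 2] - axes[h, 2], 0))
      pos <- list(
        N = ca[i, ] + 1.2 * u_prev,
        CA = ca[i, ],
        C = ca[i, ] + 1.3 * u_next,
        O = ca[i, ] + 1.3 * u_next + 1.23 * .unit(radial + 0.6 * u_next)
      )
      if (aa != "G") pos$CB <- ca[i, ] + 1.53 * radial
      rdist <- sqrt(sum((ca[i, 1:2] - c(0, 0))^2))
      for (an in names(pos)) {
        serial <- serial + 1L
        rows[[serial]] <- tibble(
          serial = serial, name = an,
          element = .classify_element(substr(an, 1, 1)),
          resname = resname, aa = aa, chain = chain, resno = i,
          icode = "", x = pos[[an]][1], y = pos[[an]][2], z = pos[[an]][3],
          b = round(15 + 1.5 * rdist + runif(1, 0, 5), 2), occ = 1
        )
      }
    }
  }
  atoms <- bind_rows(rows)
  new_structure(atoms, id = id, method = "X-RAY DIFFRACTION",
                resolution = 1.5)
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Generate synthetic conservation profiles
#'
#' Builds one PSI-BLAST-dialect profile per chain of the structure.
#' Conserved residues get a sharply peaked profile: wildtype column score
#' +7, all others -3, information content ~4 bits. Non-conserved residues
#' are near-uniform: integer scores between -1 and 1 and information content
#' ~0.4 bits.
#'
#' @param s A `vxm_structure`.
#' @param conserved_set Character vector of conserved residue keys
#'   `"chain|resno"`.
#' @param seed Integer seed.
#' @return Named list of `vxm_pssm`, keyed by chain.
#' @export
synth_pssm <- function(s, conserved_set, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- residue_table(s)
  out <- list()
  for (ch in unique(res$chain)) {
    rch <- res[res$chain == ch, , drop = FALSE]
    n <- nrow(rch)
    scores <- matrix(0, n, 20, dimnames = list(NULL, .AA1))
    info <- numeric(n)
    for (i in seq_len(n)) {
      key <- paste(rch$chain[i], rch$resno[i], sep = "|")
      if (key %in% conserved_set) {
        scores[i, ] <- -3
        scores[i, rch$aa[i]] <- 7
        info[i] <- round(4 + runif(1, -0.3, 0.3), 2)
      } else {
        scores[i, ] <- sample(-1:1, 20, replace = TRUE)
        info[i] <- round(0.4 + runif(1, -0.2, 0.2), 2)
      }
    }
    tbl <- tibble(resno = rch$resno, aa = rch$aa, info = info)
    tbl$scores <- scores
    out[[ch]] <- structure(list(chain = ch, tbl = tbl), class = "vxm_pssm")
  }
  out
}

#' Plant labeled variants on a synthetic structure
#'
#' Samples variant sites across residues (half from residues satisfying
#' the pathogenic rule, half from the rest, so labels come out roughly
#' balanced), assigns the planted label pathogenic <=> (buried and
#' conserved) with burial computed from the structure's own SASA
#' (RSA <= 0.20), then flips each label with probability `noise_rate`.
#' Inheritance tags alternate AD/AR round-robin for the stratified
#' evaluation harness.
#'
#' @param s A `vxm_structure`.
#' @param pssm Profile list from [synth_pssm()] (conservation is taken
#'   from its information content, > 2 bits = conserved).
#' @param cfg A [synth_config()].
#' @param protein_id Protein identifier for the variant rows.
#' @param seed Integer seed (defaults to the config seed).
#' @return Variant tibble in [read_variants()] layout plus hidden columns
#'   `buried`, `conserved`, `true_label` (the pre-noise label).
#' @export
plant_variants <- function(s, pssm, cfg, protein_id = s$id,
                           seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rsasa <- residue_sasa(s)
  acc <- relative_accessibility(rsasa$sasa, rsasa$aa)
  rsasa$buried <- acc$category == "buried"
  info_of <- function(ch, rn) {
    p <- pssm[[ch]]
    p$tbl$info[match(rn, p$tbl$resno)]
  }
  rsasa$conserved <- unname(mapply(function(ch, rn) info_of(ch, rn) > 2,
                                   rsasa$chain, rsasa$resno))
  rsasa$rule <- rsasa$buried & rsasa$conserved
  # drop glycines (no CB) only if variant aa bookkeeping needs it; any
  # canonical residue with a CA can host a variant
  candidates <- rsasa[!is.na(rsasa$aa), , drop = FALSE]
  n_pos <- sum(candidates$rule)
  n_want <- cfg$variants_per_protein
  n_from_rule <- min(n_pos, ceiling(n_want / 2))
  pick_rule <- sample(which(candidates$rule),
                      min(n_from_rule, sum(candidates$rule)))
  pick_rest <- sample(which(!candidates$rule),
                      min(n_want - length(pick_rule), sum(!candidates$rule)))
  picks <- c(pick_rule, pick_rest)
  cand <- candidates[picks, , drop = FALSE]
  n <- nrow(cand)
  var_aa <- vapply(cand$aa, function(a) sample(setdiff(.AA1, a), 1),
                   character(1))
  true_label <- ifelse(cand$rule, "pathogenic", "benign")
  flip <- runif(n) < cfg$noise_rate
  label <- ifelse(flip,
                  ifelse(true_label == "pathogenic", "benign", "pathogenic"),
                  true_label)
  out <- tibble(
    structure_id = s$id, chain = cand$chain, resnum = cand$resno,
    wt = cand$aa, var = var_aa, label = label, protein_id = protein_id,
    inheritance = rep(c("AD", "AR"), length.out = n),
    buried = cand$buried, conserved = cand$conserved,
    true_label = true_label
  )
  out[sample(nrow(out)), , drop = FALSE]
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes, under `dir`: one PDB per protein (`structures/<id>.pdb`), one
#' PSSM per chain (`pssm/<id>_<chain>.pssm`), the combined variant table
#' (`variants.tsv`) and a JSON manifest recording the configuration and
#' per-protein seeds. The bundle is byte-reproducible given the same
#' configuration.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return List with `variants` (tibble), `dir`, `structure_paths`,
#'   `pssm_paths`, `manifest_path`.
#' @export
make_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "vxm_synthconfig"))
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  all_variants <- list()
  structure_paths <- character(0)
  pssm_paths <- character(0)
  for (i in seq_len(cfg$n_proteins)) {
    pid <- sprintf("prot%02d", i)
    seed_i <- cfg$seed + i * 1000L
    s <- synth_structure(cfg$residues_per_protein, seed = seed_i,
                         helix_length = cfg$helix_length, id = pid)
    res <- residue_table(s)
    old <- .Random.seed_save()
    set.seed(seed_i + 1L)
    keys <- paste(res$chain, res$resno, sep = "|")
    conserved <- sample(keys, round(cfg$conserved_frac * length(keys)))
    .Random.seed_restore(old)
    pssm <- synth_pssm(s, conserved, seed = seed_i + 2L)
    vars <- plant_variants(s, pssm, cfg, protein_id = pid,
                           seed = seed_i + 3L)
    sp <- file.path(dir, "structures", paste0(pid, ".pdb"))
    write_pdb(s, sp)
    structure_paths <- c(structure_paths, sp)
    for (ch in names(pssm)) {
      pp <- file.path(dir, "pssm", paste0(pid, "_", ch, ".pssm"))
      write_pssm(pssm[[ch]], pp)
      pssm_paths <- c(pssm_paths, pp)
    }
    all_variants[[i]] <- vars
  }
  variants <- bind_rows(all_variants)
  vpath <- file.path(dir, "variants.tsv")
  write_variants(variants[, c("structure_id", "chain", "resnum", "wt",
                              "var", "label", "protein_id", "inheritance")],
                 vpath)
  manifest <- list(
    config = unclass(cfg),
    n_variants = nrow(variants),
    n_pathogenic = sum(variants$label == "pathogenic"),
    n_benign = sum(variants$label == "benign"),
    structures = basename(structure_paths)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  list(variants = variants, dir = dir, structure_paths = structure_paths,
       pssm_paths = pssm_paths, manifest_path = mpath,
       variants_path = vpath)
}
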