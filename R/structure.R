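# Structure ingestion: parse PDB files into a light S3 container (an atom
# table plus experiment metadata), enforce the eligibility rules used to
# admit structures into the dataset, and extract the variant microenvironment.

#' Construct a structure object
#'
#' Low-level constructor used by [read_pdb()] and the synthetic generator.
#' A structure is an atom table plus experiment metadata; residues are
#' implicit as (chain, resno, icode) groups of the atom table.
#'
#' @param atoms Tibble with columns `serial`, `name`, `element` (one of
#'   C/N/O/S/other), `resname`, `aa` (one-letter code or NA for nonstandard
#'   residues), `chain`, `resno`, `icode`, `x`, `y`, `z`, `b`, `occ`.
#' @param id Structure identifier string.
#' @param method Experimental method label (e.g. "X-RAY DIFFRACTION"),
#'   or `NA` if unknown.
#' @param resolution Resolution in Angstrom, or `NA` if unknown.
#' @return An object of class `vxm_structure`.
#' @export
new_structure <- function(atoms, id = "unknown", method = NA_character_,
                          resolution = NA_real_) {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "name", "element", "resname", "aa", "chain",
              "resno", "icode", "x", "y", "z", "b", "occ")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) > 0 && !all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("atom coordinates must be finite")
  }
  structure(
    list(id = id, method = method, resolution = resolution,
         atoms = as_tibble(atoms)),
    class = "vxm_structure"
  )
}

#' @export
print.vxm_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<vxm_structure> %s: %d atoms, %d residues, %d chain(s)\n",
              x$id, nrow(x$atoms), nrow(res), length(unique(res$chain))))
  cat(sprintf("  method: %s  resolution: %s\n",
              ifelse(is.na(x$method), "?", x$method),
              ifelse(is.na(x$resolution), "?",
                     format(x$resolution, digits = 3))))
  invisible(x)
}

#' Residue table of a structure
#'
#' @param s A `vxm_structure`.
#' @return Tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `resname`, `aa`, `n_atoms`, in file order.
#' @export
residue_table <- function(s) {
  s$atoms %>%
    group_by(.data$chain, .data$resno, .data$icode) %>%
    summarise(resname = .data$resname[1], aa = .data$aa[1],
              n_atoms = n(), .groups = "drop") %>%
    arrange(.data$chain, .data$resno, .data$icode)
}

.residue_key <- function(chain, resno, icode) {
  paste(chain, resno, ifelse(is.na(icode) | icode == "", ".", icode),
        sep = "|")
}

#' Read a protein structure from a PDB file
#'
#' Parses a wwPDB fixed-column file (via bio3d) and post-processes the atom
#' records the way the featurization pipeline expects:
#' water molecules (HOH/DOD) are removed, hydrogens (and deuteriums) are
#' dropped, and alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by altloc identifier order). Elements come from
#' the PDB element column with an atom-name fallback. Experimental method
#' and resolution are taken from the EXPDTA and REMARK 2 header records
#' when present.
#'
#' @param path Path to a PDB file.
#' @param id Structure id; defaults to the file base name.
#' @return A [new_structure()] object.
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read PDB file: ", path))
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                                     hex = TRUE)),
    error = function(e) abort(paste0("failed to parse PDB file ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom

  # drop waters and hydrogens/deuteriums
  at <- at[!(at$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  el <- toupper(trimws(ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                              .element_from_name(at$elety), at$elesy)))
  keep <- !(el %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  el <- el[keep]

  if (nrow(at) == 0) {
    abort(paste0("no protein atoms in ", path, " (empty structure)"))
  }

  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  icode <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)

  atoms <- tibble(
    serial = at$eleno,
    name = trimws(at$elety),
    element = .classify_element(el),
    resname = trimws(at$resid),
    aa = unname(.AA3TO1[trimws(at$resid)]),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    icode = icode,
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    occ = occ,
    alt = alt
  )

  # altloc: for each (residue, atom-name) keep the highest-occupancy record;
  # ties broken by altloc identifier order ("" sorts before "A")
  atoms <- atoms %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$name) %>%
    arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$serial) %>%
    select(-"alt")

  hdr <- .read_pdb_header(path)
  new_structure(atoms, id = id, method = hdr$method,
                resolution = hdr$resolution)
}

# EXPDTA / REMARK 2 header scrape (bio3d does not expose these)
.read_pdb_header <- function(path) {
  lines <- readLines(path, n = 400L, warn = FALSE)
  method <- NA_character_
  resolution <- NA_real_
  exp_line <- grep("^EXPDTA", lines, value = TRUE)
  if (length(exp_line) > 0) {
    method <- trimws(sub("^EXPDTA\\s*", "", exp_line[1]))
  }
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem) > 0) {
    rest <- sub(".*RESOLUTION\\.?", "", rem[1])
    m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
    if (length(m) == 1 && nzchar(m)) resolution <- as.numeric(m)
  }
  list(method = method, resolution = resolution)
}

#' Write a structure to a PDB file
#'
#' Emits wwPDB fixed-column ATOM records (coordinates to 3 decimals,
#' occupancy and B-factor to 2) preceded by EXPDTA and REMARK 2 headers so
#' that method/resolution metadata survive a round-trip through
#' [read_pdb()]. Atom serials are renumbered sequentially on output;
#' serials above 99999 wrap modulo 100000 (the 5-column field limit), a
#' dialect choice that keeps files readable by fixed-column parsers while
#' preserving atom order.
#'
#' @param s A `vxm_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "vxm_structure"))
  at <- s$atoms
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  if (!is.na(s$method)) {
    writeLines(sprintf("EXPDTA    %s", s$method), con)
  }
  if (!is.na(s$resolution)) {
    writeLines(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                       s$resolution), con)
  }
  if (nrow(at) > 0) {
    serial <- seq_len(nrow(at)) %% 100000L
    name4 <- vapply(at$name, function(nm) {
      # atom-name column convention: element right-justified in cols 13-14
      if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    }, character(1))
    el <- ifelse(at$element == "other", "X", at$element)
    rec <- sprintf(
      "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name4, at$resname, at$chain, at$resno,
      ifelse(at$icode == "", " ", at$icode),
      at$x, at$y, at$z, at$occ, at$b, el
    )
    writeLines(rec, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Check dataset eligibility of a structure
#'
#' Structures are admitted only when solved by X-ray crystallography at a
#' resolution better than `max_resolution` (default 3 Angstrom); models from
#' NMR, cryo-EM or with missing metadata are rejected with a reason rather
#' than an error.
#'
#' @param s A `vxm_structure`.
#' @param max_resolution Resolution cutoff in Angstrom (exclusive).
#' @return A list with `accept` (logical) and `reason` (`NA` when accepted,
#'   otherwise one of "method", "resolution", "missing_metadata").
#' @export
check_eligibility <- function(s, max_resolution = 3.0) {
  stopifnot(inherits(s, "vxm_structure"))
  if (is.na(s$method) || is.na(s$resolution)) {
    return(list(accept = FALSE, reason = "missing_metadata"))
  }
  if (!grepl("X-?RAY", toupper(s$method))) {
    return(list(accept = FALSE, reason = "method"))
  }
  if (!(s$resolution < max_resolution)) {
    return(list(accept = FALSE, reason = "resolution"))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Build a variant record
#'
#' @param structure_id Structure the variant is mapped to.
#' @param chain Chain identifier.
#' @param residue_number Residue sequence number of the variant site.
#' @param wildtype_aa,variant_aa One-letter amino-acid codes; must differ.
#' @param label "benign", "pathogenic" or NA (unknown).
#' @param protein_id Protein identifier used for protein-level data splits;
#'   must be non-empty.
#' @param inheritance Optional inheritance mode tag ("AD", "AR" or NA).
#' @return A list of class `vxm_variant`.
#' @export
variant_record <- function(structure_id, chain, residue_number,
                           wildtype_aa, variant_aa, label = NA_character_,
                           protein_id = structure_id,
                           inheritance = NA_character_) {
  wildtype_aa <- toupper(wildtype_aa); variant_aa <- toupper(variant_aa)
  if (!wildtype_aa %in% .AA1 || !variant_aa %in% .AA1) {
    abort("wildtype/variant amino acids must be canonical one-letter codes")
  }
  if (wildtype_aa == variant_aa) {
    abort("wildtype and variant amino acid must differ for a missense variant")
  }
  if (is.null(protein_id) || is.na(protein_id) || !nzchar(protein_id)) {
    abort("protein_id must be non-empty (required for protein-level splits)")
  }
  if (!is.na(label) && !label %in% c("benign", "pathogenic")) {
    abort("label must be 'benign', 'pathogenic' or NA")
  }
  structure(
    list(structure_id = structure_id, chain = chain,
         residue_number = as.integer(residue_number),
         wildtype_aa = wildtype_aa, variant_aa = variant_aa,
         label = label, protein_id = protein_id,
         inheritance = inheritance),
    class = "vxm_variant"
  )
}

#' Extract the local microenvironment of a variant
#'
#' Collects every heavy atom of the structure lying within `radius` of the
#' variant residue's C-alpha atom (inclusive boundary), the set of residues
#' contributing at least one such atom, and the grid center. The variant
#' residue is always a member of the residue set. The C-alpha reference
#' matches the voxel grid being centered on the variant residue's C-alpha.
#'
#' @param s A `vxm_structure`.
#' @param v A `vxm_variant` (or a one-row variant tibble).
#' @param radius Neighborhood radius in Angstrom (default 10).
#' @return An object of class `vxm_environment`: list with `variant`,
#'   `center` (length-3 numeric), `atoms` (tibble with a `dist` column),
#'   `residues` (tibble of contributing residues), `radius`.
#' @export
extract_environment <- function(s, v, radius = 10) {
  stopifnot(inherits(s, "vxm_structure"))
  v <- as_variant(v)
  at <- s$atoms
  in_res <- at$chain == v$chain & at$resno == v$residue_number
  if (!any(in_res)) {
    abort(sprintf("variant residue %s:%d not found in structure %s",
                  v$chain, v$residue_number, s$id))
  }
  res_aa <- at$aa[in_res][1]
  if (is.na(res_aa)) {
    abort(sprintf("variant residue %s:%d in %s is nonstandard (%s) and cannot host a variant",
                  v$chain, v$residue_number, s$id, at$resname[in_res][1]))
  }
  if (res_aa != v$wildtype_aa) {
    abort(sprintf("wildtype mismatch at %s:%d in %s: structure has %s, variant record says %s",
                  v$chain, v$residue_number, s$id, res_aa, v$wildtype_aa))
  }
  ca <- which(in_res & at$name == "CA")
  if (length(ca) == 0) {
    abort(sprintf("variant residue %s:%d in %s has no C-alpha atom",
                  v$chain, v$residue_number, s$id))
  }
  center <- c(at$x[ca[1]], at$y[ca[1]], at$z[ca[1]])

  d <- sqrt((at$x - center[1])^2 + (at$y - center[2])^2 + (at$z - center[3])^2)
  env_atoms <- at[d <= radius, , drop = FALSE]
  env_atoms$dist <- d[d <= radius]

  res_keys <- unique(.residue_key(env_atoms$chain, env_atoms$resno,
                                  env_atoms$icode))
  var_key <- .residue_key(v$chain, v$residue_number,
                          at$icode[in_res][1])
  res_keys <- union(res_keys, var_key)
  residues <- residue_table(s)
  residues <- residues[.residue_key(residues$chain, residues$resno,
                                    residues$icode) %in% res_keys, ,
                       drop = FALSE]

  structure(
    list(variant = v, center = center, atoms = as_tibble(env_atoms),
         residues = residues, radius = radius),
    class = "vxm_environment"
  )
}

#' @export
print.vxm_environment <- function(x, ...) {
  cat(sprintf("<vxm_environment> %s:%d %s>%s  %d atoms / %d residues within %.1f A\n",
              x$variant$chain, x$variant$residue_number,
              x$variant$wildtype_aa, x$variant$variant_aa,
              nrow(x$atoms), nrow(x$residues), x$radius))
  invisible(x)
}

as_variant <- function(v) {
  if (inherits(v, "vxm_variant")) return(v)
  if (is.data.frame(v) && nrow(v) == 1) {
    return(variant_record(v$structure_id, v$chain, v$resnum, v$wt, v$var,
                          label = if ("label" %in% names(v)) v$label else NA_character_,
                          protein_id = if ("protein_id" %in% names(v)) v$protein_id else v$structure_id,
                          inheritance = if ("inheritance" %in% names(v)) v$inheritance else NA_character_))
  }
  abort("expected a vxm_variant or a one-row variant tibble")
}

#' Detect missing residues around a variant environment
#'
#' Crystal structures can have unresolved stretches; when such a gap falls
#' inside the variant neighborhood the feature map is incomplete and the
#' variant must be excluded. A gap is a chain-internal discontinuity in
#' residue numbering whose flanking residues both contribute atoms to the
#' environment (insertion codes are treated as continuity).
#'
#' @param s A `vxm_structure`.
#' @param e A `vxm_environment` from [extract_environment()].
#' @return Tibble with one row per reported gap: `chain`, `before_resno`,
#'   `after_resno`, `n_missing`. Zero rows means the environment is clean;
#'   a non-empty result means the caller should exclude the variant.
#' @export
detect_missing_residues <- function(s, e) {
  stopifnot(inherits(s, "vxm_structure"), inherits(e, "vxm_environment"))
  res <- residue_table(s)
  env_keys <- .residue_key(e$residues$chain, e$residues$resno,
                           e$residues$icode)
  out <- list()
  for (ch in unique(res$chain)) {
    rch <- res[res$chain == ch, , drop = FALSE]
    nums <- sort(unique(rch$resno))
    if (length(nums) < 2) next
    dif <- diff(nums)
    gaps <- which(dif > 1)
    for (g in gaps) {
      before <- nums[g]; after <- nums[g + 1]
      k_before <- .residue_key(ch, before,
                               rch$icode[rch$resno == before][1])
      k_after <- .residue_key(ch, after,
                              rch$icode[rch$resno == after][1])
      if (k_before %in% env_keys && k_after %in% env_keys) {
        out[[length(out) + 1]] <- tibble(
          chain = ch, before_resno = before, after_resno = after,
          n_missing = after - before - 1L
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chain = character(), before_resno = integer(),
                  after_resno = integer(), n_missing = integer()))
  }
  bind_rows(out)
}

#' Read / write a variant table
#'
#' The variant table is a TSV with header columns `structure_id`, `chain`,
#' `resnum`, `wt`, `var`, `label`, `protein_id`, `inheritance` ("" for
#' untagged variants).
#'
#' @param path File path.
#' @return A tibble of variants.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(paste0("variant table not found: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  needed <- c("structure_id", "chain", "resnum", "wt", "var", "label",
              "protein_id")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    abort(paste0("variant table missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"inheritance" %in% names(df)) df$inheritance <- ""
  tibble(
    structure_id = df$structure_id,
    chain = df$chain,
    resnum = as.integer(df$resnum),
    wt = toupper(df$wt),
    var = toupper(df$var),
    label = ifelse(df$label %in% c("benign", "pathogenic"), df$label,
                   NA_character_),
    protein_id = df$protein_id,
    inheritance = ifelse(df$inheritance %in% c("AD", "AR"), df$inheritance,
                         NA_character_)
  )
}

#' @rdname read_variants
#' @param variants Variant tibble as returned by [read_variants()].
#' @export
write_variants <- function(variants, path) {
  df <- as.data.frame(variants)
  df$inheritance <- ifelse(is.na(df$inheritance), "", df$inheritance)
  df$label <- ifelse(is.na(df$label), "", df$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
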