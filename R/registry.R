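# Channel registry: the fixed, documented order of feature channels, plus
# the named subsets used by the ablation experiments, and the assembly of
# the complete per-atom feature matrix.

.CHANNELS_STRUCTURAL <- c("density.C", "density.N", "density.O", "density.S",
                          "charge", "sasa", "coulomb", "vdw")
.CHANNELS_SITE <- c("wt_score", "var_score")
.CHANNELS_CONSERVATION <- c("wt_score", "var_score", "info_content",
                            paste0("pssm.", .AA1))

#' Feature channel registry
#'
#' The default registry carries 31 channels in fixed order: four atomic
#' densities (C, N, O, S), atomic charge, solvent accessibility, Coulomb
#' potential, Lennard-Jones potential, wildtype and variant PSSM scores,
#' PSSM information content, and the 20-column PSSM profile. Named subsets
#' mirror the ablation experiments: `"pssm"` keeps the 23 conservation
#' channels, `"structural"` the 8 physicochemical channels, `"site"` only
#' the two variant-site scores. `"all+bfactor"` appends a normalized
#' B-factor channel (32 channels).
#'
#' @param config One of "all", "pssm", "structural", "site", "all+bfactor",
#'   or an explicit character vector of channel names (validated against
#'   the default registry).
#' @return Ordered character vector of channel names.
#' @export
channel_registry <- function(config = "all") {
  full <- c(.CHANNELS_STRUCTURAL, .CHANNELS_CONSERVATION)
  if (length(config) == 1 && config %in%
      c("all", "pssm", "structural", "site", "all+bfactor")) {
    return(switch(config,
      all = full,
      pssm = .CHANNELS_CONSERVATION,
      structural = .CHANNELS_STRUCTURAL,
      site = .CHANNELS_SITE,
      `all+bfactor` = c(full, "norm_bfactor")
    ))
  }
  bad <- setdiff(config, c(full, "norm_bfactor"))
  if (length(bad) > 0) {
    abort(paste0("unknown channel name(s): ", paste(bad, collapse = ", ")))
  }
  if (length(config) == 0) abort("channel registry must not be empty")
  config
}

#' Feature groups for leave-one-feature-out analysis
#'
#' @return Named list of the nine feature groups of the registry (atomic
#'   densities, charge, solvent accessibility, Coulomb, van der Waals,
#'   wildtype score, variant score, information content, PSSM profile),
#'   each a character vector of channel names.
#' @export
feature_groups <- function() {
  list(
    densities = paste0("density.", c("C", "N", "O", "S")),
    charge = "charge",
    sasa = "sasa",
    coulomb = "coulomb",
    vdw = "vdw",
    wt_score = "wt_score",
    var_score = "var_score",
    info_content = "info_content",
    profile = paste0("pssm.", .AA1)
  )
}

#' Assemble the per-atom feature matrix of an environment
#'
#' Runs every component feature over the environment atoms and stacks them
#' into an atoms-by-channels matrix following [channel_registry()] order.
#' Density channels are element indicators (exactly one of C/N/O/S set, all
#' zero for other elements); conservation channels are residue-level values
#' spread onto atoms.
#'
#' @param e A `vxm_environment`.
#' @param ff A `vxm_forcefield`.
#' @param bg A `vxm_bondgraph` built on the parent structure.
#' @param pssm A `vxm_pssm` or named list of per-chain profiles.
#' @param v Variant record (defaults to the environment's).
#' @param config Channel configuration for [channel_registry()].
#' @param sasa Per-atom SASA of the *full* parent structure, named by atom
#'   serial (required when the registry includes "sasa").
#' @param norm_bfactor Per-atom normalized B-factors of the parent
#'   structure, named by serial (required for "norm_bfactor").
#' @return Object of class `vxm_atom_features`: list with `atoms` (the
#'   environment atom table), `values` (numeric matrix, atoms x channels),
#'   `channels`.
#' @export
assemble_atom_features <- function(e, ff, bg, pssm, v = e$variant,
                                   config = "all", sasa = NULL,
                                   norm_bfactor = NULL) {
  channels <- channel_registry(config)
  at <- e$atoms
  n <- nrow(at)
  vals <- matrix(0, n, length(channels),
                 dimnames = list(NULL, channels))

  dens_ch <- intersect(paste0("density.", c("C", "N", "O", "S")), channels)
  for (ch in dens_ch) {
    el <- sub("density.", "", ch, fixed = TRUE)
    vals[, ch] <- as.numeric(at$element == el)
  }
  if ("charge" %in% channels) {
    vals[, "charge"] <- suppressWarnings(ff_assign(at, ff))$charge
  }
  if ("sasa" %in% channels) {
    if (is.null(sasa)) {
      abort("per-structure SASA values must be supplied to assemble the sasa channel")
    }
    sv <- sasa[as.character(at$serial)]
    if (anyNA(sv)) abort("SASA vector does not cover all environment atoms (name it by serial)")
    vals[, "sasa"] <- as.numeric(sv)
  }
  if ("coulomb" %in% channels) vals[, "coulomb"] <- compute_coulomb(e, ff, bg)
  if ("vdw" %in% channels) vals[, "vdw"] <- compute_vdw(e, ff, bg)

  cons_ch <- intersect(.CHANNELS_CONSERVATION, channels)
  if (length(cons_ch) > 0) {
    pf <- pssm_features(e, pssm, v)
    if ("wt_score" %in% channels) vals[, "wt_score"] <- pf$wt_score
    if ("var_score" %in% channels) vals[, "var_score"] <- pf$var_score
    if ("info_content" %in% channels) vals[, "info_content"] <- pf$info_content
    prof_ch <- intersect(paste0("pssm.", .AA1), channels)
    if (length(prof_ch) > 0) {
      vals[, prof_ch] <- pf$profile[, sub("pssm.", "", prof_ch, fixed = TRUE),
                                    drop = FALSE]
    }
  }
  if ("norm_bfactor" %in% channels) {
    if (is.null(norm_bfactor)) {
      abort("normalized B-factors must be supplied for the norm_bfactor channel")
    }
    bv <- norm_bfactor[as.character(at$serial)]
    if (anyNA(bv)) abort("norm_bfactor vector does not cover all environment atoms")
    vals[, "norm_bfactor"] <- as.numeric(bv)
  }
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite feature value at atom %d, channel %s",
                  bad[1], channels[bad[2]]))
  }
  structure(list(atoms = at, values = vals, channels = channels),
            class = "vxm_atom_features")
}

#' @export
print.vxm_atom_features <- function(x, ...) {
  cat(sprintf("<vxm_atom_features> %d atoms x %d channels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
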