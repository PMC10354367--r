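# Nonbonded parameter handling. The package ships a self-contained,
# versioned parameter table (partial charges per residue/atom name,
# Lennard-Jones sigma/epsilon and van der Waals radii per element) in
# inst/extdata/forcefield.tsv; every energetic and density feature reads
# its parameters through this module, so swapping the table swaps the
# force field everywhere at once.

#' Load the nonbonded parameter table
#'
#' Reads a tab-separated parameter table with columns `resname`, `atom`,
#' `charge`, `sigma`, `epsilon`, `vdw_radius`. Rows with `resname == "*"`
#' are element-level fallbacks keyed by `atom` in {C, N, O, S, other};
#' `NA` sigma/epsilon/vdw_radius on a per-atom row inherit from the
#' fallback for that atom's element. Every heavy atom of the 20 canonical
#' residues must be covered.
#'
#' @param source Path to the parameter TSV. Defaults to the table shipped
#'   with the package.
#' @return An object of class `vxm_forcefield`.
#' @export
load_forcefield <- function(source = system.file("extdata", "forcefield.tsv",
                                                 package = "voxmut")) {
  if (!file.exists(source)) abort(paste0("force-field table not found: ", source))
  df <- tryCatch(
    utils::read.table(source, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) abort(paste0("malformed force-field table: ",
                                     conditionMessage(e)))
  )
  needed <- c("resname", "atom", "charge", "sigma", "epsilon", "vdw_radius")
  if (!all(needed %in% names(df))) {
    abort("force-field table must have columns resname/atom/charge/sigma/epsilon/vdw_radius")
  }
  fallback <- df[df$resname == "*", , drop = FALSE]
  if (!all(c("C", "N", "O", "S", "other") %in% fallback$atom)) {
    abort("force-field table must provide element fallbacks for C, N, O, S, other")
  }
  entries <- df[df$resname != "*", , drop = FALSE]
  if (any(!is.finite(entries$charge))) abort("per-atom charges must be numeric")
  fb <- lapply(seq_len(nrow(fallback)), function(i) as.list(fallback[i, -1]))
  names(fb) <- fallback$atom
  key <- paste(entries$resname, entries$atom, sep = "|")
  if (anyDuplicated(key)) abort("duplicate (resname, atom) entries in force-field table")
  tab <- lapply(seq_len(nrow(entries)), function(i) as.list(entries[i, -1]))
  names(tab) <- key
  structure(list(table = tab, fallback = fb, source = source),
            class = "vxm_forcefield")
}

#' Look up nonbonded parameters for one atom
#'
#' @param ff A `vxm_forcefield` from [load_forcefield()].
#' @param resname Residue name (three-letter, e.g. "ALA").
#' @param atom Atom name (e.g. "CA").
#' @param element Element class used for the fallback path; derived from the
#'   atom name when omitted.
#' @param quiet Suppress the fallback warning.
#' @return A list with `charge`, `sigma`, `epsilon`, `vdw_radius` and
#'   `fallback` (TRUE when the element default was used).
#' @export
ff_lookup <- function(ff, resname, atom, element = NULL, quiet = FALSE) {
  stopifnot(inherits(ff, "vxm_forcefield"))
  if (is.null(element)) {
    element <- .classify_element(.element_from_name(atom))
  }
  fb <- ff$fallback[[element]]
  if (is.null(fb)) fb <- ff$fallback[["other"]]
  hit <- ff$table[[paste(resname, atom, sep = "|")]]
  if (is.null(hit)) {
    if (!quiet) {
      warn(sprintf("no force-field entry for %s/%s; using %s element defaults",
                   resname, atom, element))
    }
    return(list(charge = fb$charge, sigma = fb$sigma, epsilon = fb$epsilon,
                vdw_radius = fb$vdw_radius, fallback = TRUE))
  }
  list(
    charge = hit$charge,
    sigma = if (is.na(hit$sigma)) fb$sigma else hit$sigma,
    epsilon = if (is.na(hit$epsilon)) fb$epsilon else hit$epsilon,
    vdw_radius = if (is.na(hit$vdw_radius)) fb$vdw_radius else hit$vdw_radius,
    fallback = FALSE
  )
}

# vectorized parameter assignment over an atom table; returns the table with
# charge/sigma/epsilon/vdw columns appended (single warning summarizing any
# fallbacks rather than one per atom).
ff_assign <- function(atoms, ff) {
  n <- nrow(atoms)
  charge <- sigma <- epsilon <- vdw <- numeric(n)
  fellback <- character(0)
  for (i in seq_len(n)) {
    p <- ff_lookup(ff, atoms$resname[i], atoms$name[i],
                   element = atoms$element[i], quiet = TRUE)
    if (isTRUE(p$fallback)) {
      fellback <- c(fellback, paste0(atoms$resname[i], "/", atoms$name[i]))
    }
    charge[i] <- p$charge; sigma[i] <- p$sigma
    epsilon[i] <- p$epsilon; vdw[i] <- p$vdw_radius
  }
  if (length(fellback) > 0) {
    warn(sprintf("force-field fallback used for %d atom(s): %s",
                 length(fellback),
                 paste(unique(fellback)[seq_len(min(5, length(unique(fellback))))],
                       collapse = ", ")))
  }
  atoms$charge <- charge
  atoms$sigma <- sigma
  atoms$epsilon <- epsilon
  atoms$vdw <- vdw
  atoms
}
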