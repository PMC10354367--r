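# PSSM handling: read PSI-BLAST ASCII profiles, validate their mapping onto
# structure residues, and spread residue-level conservation scores onto
# atoms.

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the classic PSI-BLAST ASCII matrix dialect: free-text header, then
#' one row per position whose first token is the position number, followed
#' by the residue letter, 20 log-odds columns, optionally 20 weighted
#' percentage columns, and the per-position information content. The
#' information content is read from the file, not recomputed.
#'
#' @param path File path.
#' @param chain Chain identifier the profile belongs to (default "A");
#'   PSI-BLAST profiles are per-chain.
#' @return An object of class `vxm_pssm`: list with `chain` and `tbl`, a
#'   tibble with `resno`, `aa`, `info` and a `scores` matrix column
#'   (20 log-odds columns in [amino_acids()] order).
#' @export
read_pssm <- function(path, chain = "A") {
  if (!file.exists(path)) abort(paste0("PSSM file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  header_order <- NULL
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) == 0 || !nzchar(toks[1])) next
    if (is.null(header_order) && sum(toks %in% .AA1) >= 20 &&
        is.na(suppressWarnings(as.numeric(toks[1])))) {
      # column header line listing amino-acid letters (possibly twice)
      header_order <- toks[toks %in% .AA1][1:20]
      next
    }
    pos <- suppressWarnings(as.integer(toks[1]))
    if (is.na(pos)) next
    if (length(toks) < 22 || !(toks[2] %in% .AA1)) next
    scores <- suppressWarnings(as.numeric(toks[3:22]))
    if (anyNA(scores)) next
    info <- NA_real_
    if (length(toks) >= 44) {
      info <- suppressWarnings(as.numeric(toks[43]))
    } else if (length(toks) == 23) {
      info <- suppressWarnings(as.numeric(toks[23]))
    }
    rows[[length(rows) + 1]] <- list(resno = pos, aa = toks[2],
                                     scores = scores, info = info)
  }
  if (length(rows) == 0) abort(paste0("no PSSM rows parsed from ", path))
  ord <- if (is.null(header_order)) .AA1 else header_order
  score_mat <- do.call(rbind, lapply(rows, `[[`, "scores"))
  colnames(score_mat) <- ord
  score_mat <- score_mat[, .AA1, drop = FALSE]  # canonical column order
  tbl <- tibble(
    resno = vapply(rows, `[[`, integer(1), "resno"),
    aa = vapply(rows, `[[`, character(1), "aa"),
    info = vapply(rows, function(r) r$info %||% NA_real_, numeric(1))
  )
  tbl$scores <- score_mat
  structure(list(chain = chain, tbl = tbl), class = "vxm_pssm")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Counterpart to [read_pssm()], used by the synthetic-data generator so
#' fixtures exercise the same parser as real profiles. Emits the 20
#' log-odds columns, 20 zero percentage columns and the information
#' content / weight trailer.
#'
#' @param p A `vxm_pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "vxm_pssm"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts", con)
  writeLines(paste0("            ", paste(sprintf("%3s", .AA1), collapse = " "),
                    "   ", paste(sprintf("%3s", .AA1), collapse = " ")), con)
  tbl <- p$tbl
  for (i in seq_len(nrow(tbl))) {
    sc <- paste(sprintf("%3d", round(tbl$scores[i, ])), collapse = " ")
    pc <- paste(sprintf("%3d", rep(0L, 20)), collapse = " ")
    writeLines(sprintf("%5d %s  %s   %s  %5.2f %8.2f",
                       tbl$resno[i], tbl$aa[i], sc, pc, tbl$info[i], 0), con)
  }
  invisible(path)
}

#' Validate the PSSM-to-structure mapping
#'
#' Checks, for every residue of the given chain, that the profile has a row
#' at that residue number and that the row's residue letter matches the
#' structure.
#'
#' @param s A `vxm_structure`.
#' @param p A `vxm_pssm`.
#' @return Tibble with `chain`, `resno`, `aa_structure`, `aa_pssm`,
#'   `status` in {"matched", "mismatch", "missing"}.
#' @export
map_pssm <- function(s, p) {
  stopifnot(inherits(s, "vxm_structure"), inherits(p, "vxm_pssm"))
  res <- residue_table(s)
  res <- res[res$chain == p$chain, , drop = FALSE]
  idx <- match(res$resno, p$tbl$resno)
  aa_pssm <- ifelse(is.na(idx), NA_character_, p$tbl$aa[idx])
  status <- dplyr::case_when(
    is.na(idx) ~ "missing",
    !is.na(res$aa) & res$aa == aa_pssm ~ "matched",
    TRUE ~ "mismatch"
  )
  tibble(chain = res$chain, resno = res$resno,
         aa_structure = res$aa, aa_pssm = aa_pssm, status = status)
}

#' Residue-level conservation channels spread onto atoms
#'
#' For every residue in the environment, its 20-column PSSM profile and
#' information content are copied onto each of its constituent atoms. The
#' wildtype and variant scores are evaluated from the profile at the
#' variant position and assigned only to the atoms of the variant residue
#' (zero on all other atoms), following the convention that the two
#' site-specific scores describe the mutated site itself.
#'
#' @param e A `vxm_environment`.
#' @param p A `vxm_pssm` or a named list of them keyed by chain.
#' @param v Variant record; defaults to the environment's variant.
#' @return Tibble with one row per environment atom: `wt_score`,
#'   `var_score`, `info_content` and a 20-column `profile` matrix column.
#' @export
pssm_features <- function(e, p, v = e$variant) {
  stopifnot(inherits(e, "vxm_environment"))
  profs <- if (inherits(p, "vxm_pssm")) setNames(list(p), p$chain) else p
  at <- e$atoms
  n <- nrow(at)
  profile <- matrix(0, n, 20, dimnames = list(NULL, .AA1))
  info <- numeric(n)
  wt_score <- numeric(n)
  var_score <- numeric(n)

  for (ch in unique(at$chain)) {
    pc <- profs[[ch]]
    if (is.null(pc)) {
      abort(sprintf("no PSSM profile supplied for chain %s (variant excluded)", ch))
    }
    rows_ch <- which(at$chain == ch)
    idx <- match(at$resno[rows_ch], pc$tbl$resno)
    if (anyNA(idx)) {
      missing_res <- unique(at$resno[rows_ch][is.na(idx)])
      abort(sprintf("PSSM rows missing for environment residue(s) %s:%s (variant excluded)",
                    ch, paste(missing_res, collapse = ",")))
    }
    profile[rows_ch, ] <- pc$tbl$scores[idx, , drop = FALSE]
    info[rows_ch] <- pc$tbl$info[idx]
  }

  pv <- profs[[v$chain]]
  vrow <- match(v$residue_number, pv$tbl$resno)
  if (is.na(vrow)) {
    abort(sprintf("PSSM row missing at variant position %s:%d",
                  v$chain, v$residue_number))
  }
  on_variant <- at$chain == v$chain & at$resno == v$residue_number
  wt_score[on_variant] <- pv$tbl$scores[vrow, v$wildtype_aa]
  var_score[on_variant] <- pv$tbl$scores[vrow, v$variant_aa]

  out <- tibble(wt_score = wt_score, var_score = var_score,
                info_content = info)
  out$profile <- profile
  out
}
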