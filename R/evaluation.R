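# Evaluation suite: confusion counts, Matthews correlation, ROC/AUC,
# relative solvent accessibility and burial categories, contingency/odds
# ratio analysis, void-ratio correlation, stratified metrics, and the
# feature-ablation harness.

#' Confusion counts at a threshold
#'
#' Pathogenic is the positive class; a variant is called pathogenic when
#' its score strictly exceeds the threshold.
#'
#' @param scores Numeric pathogenic-probability scores.
#' @param labels Character ("benign"/"pathogenic") or 0/1 labels.
#' @param threshold Decision threshold (default 0.5, strict >).
#' @return A list of class `vxm_confusion` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) abort("cannot build confusion counts from empty input")
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  y <- .as_binary_labels(labels)
  pred <- scores > threshold
  structure(list(
    tp = sum(pred & y == 1), fp = sum(pred & y == 0),
    fn = sum(!pred & y == 1), tn = sum(!pred & y == 0)
  ), class = "vxm_confusion")
}

.as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- !labels %in% c("benign", "pathogenic")
    if (any(bad)) abort("labels must be 'benign' or 'pathogenic'")
    as.integer(labels == "pathogenic")
  } else {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    as.integer(labels)
  }
}

#' @export
print.vxm_confusion <- function(x, ...) {
  cat(sprintf("<vxm_confusion> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' binary-classification statistic over all four confusion cells. When any
#' factor of the denominator is zero the coefficient is 0 by convention.
#'
#' @param c A `vxm_confusion` (or list with tp/fp/fn/tn).
#' @return A number between -1 and 1.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  fn <- as.numeric(c$fn); tn <- as.numeric(c$tn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Threshold metrics from confusion counts
#'
#' @param c A `vxm_confusion`.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`,
#'   `accuracy`, `mcc`; rates are `NA` when their denominator is zero.
#' @export
metrics <- function(c) {
  n <- c$tp + c$fp + c$fn + c$tn
  tibble(
    tp = c$tp, fp = c$fp, fn = c$fn, tn = c$tn,
    tpr = if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else NA_real_,
    fpr = if (c$fp + c$tn > 0) c$fp / (c$fp + c$tn) else NA_real_,
    accuracy = (c$tp + c$tn) / n,
    mcc = mcc(c)
  )
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores (ties grouped),
#' accumulating (FPR, TPR) points, and integrates by the trapezoidal rule.
#'
#' @param scores Pathogenic-probability scores.
#' @param labels Labels with both classes present.
#' @return List of class `vxm_roc` with `curve` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_binary_labels(labels)
  if (length(unique(y)) < 2) {
    abort("ROC requires both classes to be present")
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # group ties: cumulative counts at the end of each tie group
  grp_end <- which(!duplicated(ss, fromLast = TRUE))
  cum_tp <- cumsum(ys)[grp_end]
  cum_fp <- cumsum(1 - ys)[grp_end]
  P <- sum(y); N <- sum(1 - y)
  tpr <- c(0, cum_tp / P)
  fpr <- c(0, cum_fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  curve <- tibble(threshold = c(Inf, ss[grp_end]), fpr = fpr, tpr = tpr)
  structure(list(curve = curve, auc = auc), class = "vxm_roc")
}

#' @export
print.vxm_roc <- function(x, ...) {
  cat(sprintf("<vxm_roc> AUC %.4f (%d points)\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' Relative solvent accessibility and burial category
#'
#' Divides the absolute accessibility by the residue's maximum attainable
#' accessibility (embedded Rost-Sander table); residues with RSA above 20%
#' are solvent-exposed, at or below 20% buried.
#'
#' @param abs_sasa Absolute SASA in A^2 (scalar or vector).
#' @param aa One-letter amino-acid code(s).
#' @return Tibble with `rsa` and `category` ("buried"/"exposed").
#' @export
relative_accessibility <- function(abs_sasa, aa) {
  aa <- toupper(aa)
  if (any(!aa %in% names(.MAX_ASA))) {
    abort(paste0("unknown amino acid code(s): ",
                 paste(unique(aa[!aa %in% names(.MAX_ASA)]), collapse = ", ")))
  }
  if (any(abs_sasa < 0)) abort("absolute SASA must be non-negative")
  rsa <- abs_sasa / unname(.MAX_ASA[aa])
  tibble(rsa = rsa, category = ifelse(rsa > 0.20, "exposed", "buried"))
}

#' Odds ratio of a 2x2 contingency table
#'
#' `(a*d) / (b*c)` for the table `[a b; c d]`. When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell and the result is
#' flagged as corrected.
#'
#' @param a,b,c,d Non-negative cell counts, or `a` may be a 2x2 matrix.
#' @return List of class `vxm_odds` with `odds_ratio` and `corrected`.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("contingency cells must be non-negative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  structure(list(odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 corrected = corrected),
            class = "vxm_odds")
}

#' @export
print.vxm_odds <- function(x, ...) {
  cat(sprintf("<vxm_odds> OR = %.4f%s\n", x$odds_ratio,
              if (x$corrected) " (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Void-ratio versus score correlation, per class
#'
#' Pearson correlation between grid sparsity (void-to-occupied voxel
#' ratio) and the pathogenic prediction score, computed separately for
#' pathogenic-labeled and benign-labeled variants.
#'
#' @param void_ratios Numeric vector of per-variant void ratios.
#' @param scores Pathogenic-probability scores.
#' @param labels Variant labels.
#' @return Tibble with `label`, `n`, `pearson_r`.
#' @export
void_score_correlation <- function(void_ratios, scores, labels) {
  stopifnot(length(void_ratios) == length(scores),
            length(scores) == length(labels))
  y <- .as_binary_labels(labels)
  out <- lapply(c(benign = 0, pathogenic = 1), function(cls) {
    idx <- which(y == cls)
    if (length(idx) < 3) {
      abort(sprintf("need at least 3 %s variants for a correlation",
                    ifelse(cls == 1, "pathogenic", "benign")))
    }
    v <- void_ratios[idx]; s <- scores[idx]
    if (stats::sd(v) == 0 || stats::sd(s) == 0) {
      abort("correlation undefined for a constant vector")
    }
    stats::cor(v, s)
  })
  tibble(label = names(out), n = c(sum(y == 0), sum(y == 1)),
         pearson_r = unname(unlist(out)))
}

#' Stratified evaluation
#'
#' Computes the metric set separately per stratum (inheritance mode or
#' burial category). Strata containing a single class are flagged and
#' their AUC omitted; empty strata are skipped with a warning.
#'
#' @param predictions Tibble with `score` (pathogenic probability) per
#'   variant, row-aligned with `variants`.
#' @param variants Variant tibble with `label` and the stratification
#'   column.
#' @param key Stratification key: "inheritance" or "burial" (the latter
#'   expects a `burial` column of "buried"/"exposed").
#' @param threshold Decision threshold.
#' @return Tibble with one row per stratum: `stratum`, `n`, the metric
#'   columns, `auc`, `single_class` flag.
#' @export
stratified_eval <- function(predictions, variants, key = c("inheritance", "burial"),
                            threshold = 0.5) {
  key <- match.arg(key)
  if (!key %in% names(variants)) {
    abort(sprintf("variants have no '%s' column to stratify on", key))
  }
  strata <- variants[[key]]
  keep <- !is.na(strata)
  if (!any(keep)) {
    warn(sprintf("no variants carry a %s tag; nothing to stratify", key))
    return(tibble())
  }
  out <- list()
  for (s in sort(unique(strata[keep]))) {
    idx <- which(keep & strata == s)
    if (length(idx) == 0) next
    lab <- variants$label[idx]
    sc <- predictions$score[idx]
    single <- length(unique(lab)) < 2
    cm <- confusion(sc, lab, threshold)
    m <- metrics(cm)
    m$auc <- if (single) NA_real_ else roc_auc(sc, lab)$auc
    out[[s]] <- bind_cols(tibble(stratum = s, n = length(idx)), m,
                          tibble(single_class = single))
  }
  bind_rows(out)
}

#' Feature-ablation harness
#'
#' Trains one model per channel subset on identical splits, seeds and grid
#' data (channels are subset from the same featurized grids, with
#' standardization refit per subset on the training fold), and reports
#' per-subset test metrics.
#'
#' @param entries Grid-store entries (list per variant with `grids`,
#'   `label`, `protein_id`), unstandardized.
#' @param subsets Named list of channel-name vectors (see
#'   [channel_registry()]), e.g.
#'   `list(all = channel_registry("all"), pssm = channel_registry("pssm"))`.
#' @param train_idx,test_idx Integer indices of training/test entries.
#' @param config A [training_config()].
#' @param netspec Network specification used for every run.
#' @return Tibble with one row per subset: `subset`, `n_channels`, metric
#'   columns, `auc`.
#' @export
feature_ablation <- function(entries, subsets, train_idx, test_idx,
                             config = training_config(),
                             netspec = reduced_network_spec()) {
  if (length(subsets) == 0) abort("no channel subsets supplied")
  out <- list()
  for (nm in names(subsets)) {
    channels <- channel_registry(subsets[[nm]])
    res <- .run_subset(entries, channels, train_idx, test_idx, config, netspec)
    out[[nm]] <- bind_cols(tibble(subset = nm, n_channels = length(channels)),
                           res)
  }
  bind_rows(out)
}

# train/evaluate one channel subset; returns one-row metric tibble
.run_subset <- function(entries, channels, train_idx, test_idx, config,
                        netspec) {
  sub_entry <- function(en) {
    en$grids <- lapply(en$grids, function(g) {
      keep <- match(channels, g$channels)
      if (anyNA(keep)) abort("requested channel absent from grids")
      g$values <- g$values[, , , keep, drop = FALSE]
      g$channels <- channels
      g
    })
    en
  }
  tr <- lapply(entries[train_idx], sub_entry)
  te <- lapply(entries[test_idx], sub_entry)
  tr_grids <- unlist(lapply(tr, `[[`, "grids"), recursive = FALSE)
  tr_labels <- rep(vapply(tr, `[[`, character(1), "label"),
                   vapply(tr, function(e) length(e$grids), integer(1)))
  std <- fit_standardizer(tr_grids)
  tr_grids <- lapply(tr_grids, function(g) apply_standardizer(std, g))
  fit <- train_model(tr_grids, tr_labels, config = config, netspec = netspec)
  scores <- vapply(te, function(en) {
    gs <- lapply(en$grids, function(g) apply_standardizer(std, g))
    predict_variant(fit, gs)$p_pathogenic
  }, numeric(1))
  labels <- vapply(te, `[[`, character(1), "label")
  cm <- confusion(scores, labels)
  m <- metrics(cm)
  m$auc <- roc_auc(scores, labels)$auc
  m
}
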