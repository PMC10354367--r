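# End-to-end pipeline: featurize a variant bundle into a grid store, train
# with protein-level splits, evaluate, and run the burial / sparsity /
# inheritance analyses. These functions are the package's primary
# interface; the shell wrapper in inst/cli drives them.

#' Featurize a variant bundle into a grid store
#'
#' Reads structures, per-chain PSSMs and the variant table from a bundle
#' directory (the layout written by [make_dataset()]), applies the
#' eligibility and completeness rules, computes per-atom features, maps
#' them onto voxel grids and augments by rotation. Variants that cannot be
#' featurized (ineligible structure, missing residues in the environment,
#' unmappable PSSM, wildtype mismatch) are skipped and logged with a
#' reason.
#'
#' @param data_dir Bundle directory containing `structures/`, `pssm/` and
#'   `variants.tsv`.
#' @param grid_size Voxels per grid side (default 20).
#' @param voxel Voxel edge in Angstrom (default 1).
#' @param n_augment Augmentations per variant (default 5).
#' @param channels Channel configuration for [channel_registry()].
#' @param radius Environment radius in Angstrom (default 10).
#' @param seed Base seed for augmentation rotations.
#' @param store_path Optional path; when given the store is saved there.
#' @return A grid store: list with `entries` (per-variant: `variant`
#'   one-row tibble, `label`, `protein_id`, `inheritance`, `grids`,
#'   `residue_rsa`), `channels`, `exclusions` (tibble with reasons),
#'   `params`.
#' @export
featurize_dataset <- function(data_dir, grid_size = 20, voxel = 1,
                              n_augment = 5, channels = "all", radius = 10,
                              seed = 1L, store_path = NULL) {
  vpath <- file.path(data_dir, "variants.tsv")
  variants <- read_variants(vpath)
  ff <- load_forcefield()
  registry <- channel_registry(channels)

  entries <- list()
  excl <- list()
  for (sid in unique(variants$structure_id)) {
    spath <- file.path(data_dir, "structures", paste0(sid, ".pdb"))
    vsub <- variants[variants$structure_id == sid, , drop = FALSE]
    if (!file.exists(spath)) {
      excl[[length(excl) + 1]] <- tibble(structure_id = sid,
                                         resnum = vsub$resnum,
                                         chain = vsub$chain,
                                         reason = "structure_file_missing")
      next
    }
    s <- read_pdb(spath, id = sid)
    elig <- check_eligibility(s)
    if (!elig$accept) {
      excl[[length(excl) + 1]] <- tibble(structure_id = sid,
                                         resnum = vsub$resnum,
                                         chain = vsub$chain,
                                         reason = elig$reason)
      next
    }
    bg <- build_bond_graph(s)
    sasa <- compute_sasa(s)
    names(sasa) <- as.character(s$atoms$serial)
    rsasa <- residue_sasa(s, unname(sasa[as.character(s$atoms$serial)]))
    pssm_files <- list.files(file.path(data_dir, "pssm"),
                             pattern = paste0("^", sid, "_.*\\.pssm$"),
                             full.names = TRUE)
    pssms <- list()
    for (pf in pssm_files) {
      ch <- sub("\\.pssm$", "", sub(paste0("^", sid, "_"), "", basename(pf)))
      pssms[[ch]] <- read_pssm(pf, chain = ch)
    }
    for (k in seq_len(nrow(vsub))) {
      vrow <- vsub[k, , drop = FALSE]
      entry <- tryCatch({
        v <- as_variant(vrow)
        e <- extract_environment(s, v, radius = radius)
        gaps <- detect_missing_residues(s, e)
        if (nrow(gaps) > 0) stop("missing_residues")
        af <- assemble_atom_features(e, ff, bg, pssms, v,
                                     config = registry, sasa = sasa)
        spec <- make_grid_spec(e, size = grid_size, voxel = voxel)
        grids <- augment(e, af, spec, n = n_augment,
                         seed = seed + 7L * k + .structure_seed_offset(sid))
        rr <- rsasa[rsasa$chain == v$chain & rsasa$resno == v$residue_number, ]
        list(variant = vrow, label = vrow$label,
             protein_id = vrow$protein_id,
             inheritance = vrow$inheritance, grids = grids,
             rsa = relative_accessibility(rr$sasa[1], rr$aa[1]))
      }, error = function(err) conditionMessage(err))
      if (is.character(entry)) {
        reason <- if (grepl("missing_residues", entry)) "missing_residues"
          else if (grepl("PSSM", entry)) "pssm_unmapped"
          else if (grepl("mismatch", entry)) "wildtype_mismatch"
          else "featurization_error"
        excl[[length(excl) + 1]] <- tibble(structure_id = sid,
                                           resnum = vrow$resnum,
                                           chain = vrow$chain,
                                           reason = reason)
      } else {
        entries[[length(entries) + 1]] <- entry
      }
    }
  }
  exclusions <- if (length(excl) > 0) bind_rows(excl) else
    tibble(structure_id = character(), resnum = integer(),
           chain = character(), reason = character())
  store <- list(entries = entries, channels = registry,
                exclusions = exclusions,
                params = list(grid_size = grid_size, voxel = voxel,
                              n_augment = n_augment, radius = radius,
                              seed = seed))
  if (!is.null(store_path)) save_grids(store, store_path)
  store
}

# deterministic per-structure seed offset (stable across sessions)
.structure_seed_offset <- function(sid) {
  sum(utf8ToInt(sid) * seq_len(nchar(sid))) %% 10000L
}

#' Train and evaluate with protein-level cross-validation
#'
#' For each fold of a protein-level split: balance the training variants,
#' fit per-channel standardization on the training grids only, train the
#' network, and score every validation variant by its averaged grid
#' probabilities. Scores pooled over folds give each variant exactly one
#' held-out prediction.
#'
#' @param store Grid store from [featurize_dataset()].
#' @param k Number of protein folds.
#' @param config A [training_config()].
#' @param netspec Network architecture.
#' @return List of class `vxm_cv` with `predictions` (tibble: variant
#'   identity, label, fold, `score`), `fits` (per-fold `vxm_fit`),
#'   `folds`.
#' @export
crossvalidate <- function(store, k = 2, config = training_config(),
                          netspec = reduced_network_spec()) {
  entries <- store$entries
  vtab <- bind_rows(lapply(entries, `[[`, "variant"))
  folds <- protein_level_kfold(vtab, k = k, seed = config$seed)
  preds <- list()
  fits <- list()
  for (f in seq_len(k)) {
    val_prot <- folds$validation_proteins[[f]]
    train_idx <- which(!(vtab$protein_id %in% val_prot))
    val_idx <- which(vtab$protein_id %in% val_prot)
    bal <- balance_classes(vtab[train_idx, , drop = FALSE],
                           seed = config$seed + f)
    train_keep <- train_idx[match(
      interaction(bal$structure_id, bal$chain, bal$resnum, bal$var),
      interaction(vtab$structure_id[train_idx], vtab$chain[train_idx],
                  vtab$resnum[train_idx], vtab$var[train_idx])
    )]
    tr_entries <- entries[train_keep]
    tr_grids <- unlist(lapply(tr_entries, `[[`, "grids"), recursive = FALSE)
    tr_labels <- rep(vapply(tr_entries, `[[`, character(1), "label"),
                     vapply(tr_entries, function(e) length(e$grids),
                            integer(1)))
    std <- fit_standardizer(tr_grids)
    tr_grids <- lapply(tr_grids, function(g) apply_standardizer(std, g))
    fit <- train_model(tr_grids, tr_labels, config = config,
                       netspec = netspec)
    fit$standardizer <- std
    fits[[f]] <- fit
    sc <- vapply(entries[val_idx], function(en) {
      gs <- lapply(en$grids, function(g) apply_standardizer(std, g))
      predict_variant(fit, gs)$p_pathogenic
    }, numeric(1))
    preds[[f]] <- bind_cols(vtab[val_idx, , drop = FALSE],
                            tibble(fold = f, score = sc))
  }
  structure(list(predictions = bind_rows(preds), fits = fits,
                 folds = folds),
            class = "vxm_cv")
}

#' Tidy cross-validation predictions
#'
#' @param x A `vxm_cv`.
#' @param ... Unused.
#' @return The pooled per-variant prediction tibble.
#' @export
tidy.vxm_cv <- function(x, ...) x$predictions

#' Cross-validation summary metrics
#'
#' @param x A `vxm_cv`.
#' @param ... Unused.
#' @return One-row tibble: n, tpr, fpr, accuracy, mcc, auc over the pooled
#'   held-out predictions.
#' @export
glance.vxm_cv <- function(x, ...) {
  p <- x$predictions
  cm <- confusion(p$score, p$label)
  m <- metrics(cm)
  m$auc <- roc_auc(p$score, p$label)$auc
  bind_cols(tibble(n = nrow(p)), m)
}

#' Burial / sparsity / inheritance analysis of predictions
#'
#' Runs the three stratification analyses on pooled held-out predictions:
#' a 2x2 correctness-by-burial contingency table with its odds ratio, the
#' per-class Pearson correlation between grid void ratio and prediction
#' score, and inheritance-stratified metrics.
#'
#' @param cv A `vxm_cv` from [crossvalidate()].
#' @param store The grid store the predictions came from.
#' @param threshold Decision threshold.
#' @return List with `burial_table` (2x2 matrix), `burial_odds`
#'   (`vxm_odds`), `void_correlation` (tibble), `inheritance` (tibble from
#'   [stratified_eval()]).
#' @export
analyze_predictions <- function(cv, store, threshold = 0.5) {
  p <- cv$predictions
  entries <- store$entries
  vtab <- bind_rows(lapply(entries, `[[`, "variant"))
  key <- interaction(vtab$structure_id, vtab$chain, vtab$resnum, vtab$var)
  pkey <- interaction(p$structure_id, p$chain, p$resnum, p$var)
  idx <- match(pkey, key)
  burial <- vapply(entries[idx], function(en) en$rsa$category[1],
                   character(1))
  voidr <- vapply(entries[idx], function(en) void_ratio(en$grids[[1]]),
                  numeric(1))
  correct <- (p$score > threshold) == (p$label == "pathogenic")
  tab <- matrix(c(
    sum(correct & burial == "buried"), sum(correct & burial == "exposed"),
    sum(!correct & burial == "buried"), sum(!correct & burial == "exposed")
  ), 2, 2, byrow = TRUE,
  dimnames = list(c("correct", "incorrect"), c("buried", "exposed")))
  odds <- odds_ratio(tab)
  void_cor <- void_score_correlation(voidr, p$score, p$label)
  strat <- if (all(is.na(p$inheritance))) {
    warn("no inheritance tags present; skipping inheritance stratification")
    tibble()
  } else {
    stratified_eval(tibble(score = p$score), p, key = "inheritance",
                    threshold = threshold)
  }
  list(burial_table = tab, burial_odds = odds, void_correlation = void_cor,
       inheritance = strat)
}

#' Desk-scale end-to-end recovery experiment
#'
#' Generates (or reuses) a synthetic bundle with the planted
#' buried-and-conserved pathogenic signal, featurizes it on a coarse grid
#' (the 20 A box kept, voxels enlarged so the reduced network trains in
#' minutes on one CPU), runs protein-level cross-validation with the
#' reduced network, and optionally the channel-ablation comparison.
#'
#' @param dir Working directory for the bundle.
#' @param seed Master seed.
#' @param cfg Synthetic configuration; default [synth_config()] with the
#'   given seed.
#' @param grid_size,voxel Featurization geometry (default 8 voxels of
#'   2.5 A).
#' @param k Protein folds (default 2).
#' @param config Training configuration; defaults to the reduced-run
#'   schedule (learning rate 0.005, weight decay 0.05, batch 64, 10
#'   epochs, dropout 0.5) chosen for stable CPU training of the reduced
#'   network on heavily regularized small samples.
#' @param ablation Run the all/pssm/site channel comparison (default
#'   TRUE).
#' @return List with `cv`, `metrics` (glance tibble), `analysis`,
#'   `ablation` (tibble or NULL), `store`, `bundle`.
#' @export
recovery_experiment <- function(dir = tempfile("voxmut"), seed = 1L,
                                cfg = synth_config(seed = seed),
                                grid_size = 8, voxel = 2.5, k = 2,
                                config = NULL, ablation = TRUE) {
  if (is.null(config)) {
    config <- training_config(learning_rate = 0.005, weight_decay = 0.05,
                              batch_size = 64, epochs = 10, dropout = 0.5,
                              n_augment = 5, k_folds = k, seed = seed)
  }
  bundle <- make_dataset(cfg, dir)
  store <- featurize_dataset(dir, grid_size = grid_size, voxel = voxel,
                             n_augment = config$n_augment, seed = seed)
  cv <- crossvalidate(store, k = k, config = config)
  m <- glance.vxm_cv(cv)
  analysis <- analyze_predictions(cv, store)
  abl <- NULL
  if (ablation) {
    vtab <- bind_rows(lapply(store$entries, `[[`, "variant"))
    folds <- protein_level_kfold(vtab, k = k, seed = config$seed)
    val_prot <- folds$validation_proteins[[1]]
    train_idx <- which(!(vtab$protein_id %in% val_prot))
    test_idx <- which(vtab$protein_id %in% val_prot)
    abl <- feature_ablation(
      store$entries,
      subsets = list(all = channel_registry("all"),
                     pssm = channel_registry("pssm"),
                     site = channel_registry("site")),
      train_idx = train_idx, test_idx = test_idx,
      config = config, netspec = reduced_network_spec()
    )
  }
  list(cv = cv, metrics = m, analysis = analysis, ablation = abl,
       store = store, bundle = bundle)
}
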