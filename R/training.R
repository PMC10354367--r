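# Training protocol: protein-level cross-validation splits, class
# balancing, mini-batch AdamW training with cross-entropy loss, and
# per-variant prediction aggregation over augmented grids.

#' Training configuration
#'
#' Defaults follow the published protocol: AdamW with learning rate 0.001
#' and weight decay 0.005, 10 epochs, mini-batches of 256 grid instances,
#' dropout 0.5, 5 augmentations, 10 folds.
#'
#' @param learning_rate,weight_decay AdamW hyperparameters.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size in grid instances.
#' @param dropout Dropout probability of the fully connected block.
#' @param n_augment Augmentations per variant (grids per variant =
#'   n_augment + 1).
#' @param k_folds Cross-validation folds.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = the
#'   constant schedule of the default protocol).
#' @param seed Run seed.
#' @return A list of class `vxm_config`.
#' @export
training_config <- function(learning_rate = 0.001, weight_decay = 0.005,
                            epochs = 10, batch_size = 256, dropout = 0.5,
                            n_augment = 5, k_folds = 10, lr_decay = 1,
                            seed = 1L) {
  cfg <- list(learning_rate = learning_rate, weight_decay = weight_decay,
              epochs = epochs, batch_size = batch_size, dropout = dropout,
              n_augment = n_augment, k_folds = k_folds,
              lr_decay = lr_decay,
              seed = as.integer(seed))
  if (any(vapply(cfg[1:7], function(x) !is.numeric(x) || x <= 0,
                 logical(1)) & names(cfg)[1:7] != "n_augment")) {
    abort("training configuration values must be positive")
  }
  structure(cfg, class = "vxm_config")
}

#' Protein-level k-fold split
#'
#' Partitions proteins (not variants) into `k` groups so that no protein
#' ever contributes variants to both the training and validation side of a
#' fold — the guard against type-1 circularity, where within-protein
#' similarity inflates performance estimates.
#'
#' @param variants Variant tibble with a `protein_id` column.
#' @param k Number of folds.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return Tibble with one row per fold: `fold`, `train_proteins`,
#'   `validation_proteins` (list columns of protein-id character vectors).
#' @export
protein_level_kfold <- function(variants, k = 10, seed = 1L) {
  if (!"protein_id" %in% names(variants)) {
    abort("variants must carry a protein_id column")
  }
  proteins <- sort(unique(variants$protein_id))
  if (length(proteins) < k) {
    abort(sprintf("cannot make %d folds from %d distinct proteins",
                  k, length(proteins)))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(proteins)
  assignment <- rep_len(seq_len(k), length(proteins))
  out <- lapply(seq_len(k), function(f) {
    val <- shuffled[assignment == f]
    tibble(fold = f,
           train_proteins = list(setdiff(proteins, val)),
           validation_proteins = list(sort(val)))
  })
  bind_rows(out)
}

#' Balanced class subset
#'
#' Down-samples the majority class (without replacement) so benign and
#' pathogenic counts are exactly equal; deterministic given the seed.
#'
#' @param variants Variant tibble with a `label` column containing both
#'   classes.
#' @param seed Integer seed.
#' @return Row-subset of `variants` with equal label counts.
#' @export
balance_classes <- function(variants, seed = 1L) {
  lab <- variants$label
  n_b <- sum(lab == "benign", na.rm = TRUE)
  n_p <- sum(lab == "pathogenic", na.rm = TRUE)
  if (n_b == 0 || n_p == 0) {
    abort("both benign and pathogenic variants are required for balancing")
  }
  m <- min(n_b, n_p)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx_b <- which(lab == "benign")
  idx_p <- which(lab == "pathogenic")
  keep <- sort(c(
    if (n_b > m) sample(idx_b, m) else idx_b,
    if (n_p > m) sample(idx_p, m) else idx_p
  ))
  variants[keep, , drop = FALSE]
}

# grids (list of vxm_grid) -> batch matrix
grids_to_matrix <- function(grids) {
  do.call(rbind, lapply(grids, function(g) c(g$values)))
}

#' Train the classifier
#'
#' Mini-batch training with AdamW and cross-entropy loss. Every augmented
#' grid is treated as a separate training instance; instances are
#' reshuffled each epoch with the run seed. The history records per-epoch
#' mean training loss and, when a validation set is given, validation loss
#' and accuracy at the variant-instance level.
#'
#' @param train_grids List of standardized `vxm_grid` objects.
#' @param train_labels Character vector ("benign"/"pathogenic") parallel to
#'   `train_grids`.
#' @param config A [training_config()].
#' @param netspec A `vxm_netspec`; defaults to the reduced architecture.
#' @param val_grids,val_labels Optional validation instances.
#' @param restarts Maximum number of re-initializations when a run fails to
#'   fit the training data (final mean training loss above `refit_loss`,
#'   i.e. the network never left chance level). The restart decision uses
#'   training loss only; each restart shifts the initialization seed and
#'   halves the learning rate, the standard remedy when a high rate kills
#'   the rectified units early.
#' @param refit_loss Training-loss level treated as a failed fit.
#' @return Object of class `vxm_fit`: list with `net`, `history` (tibble),
#'   `config`, `restarts_used`.
#' @export
train_model <- function(train_grids, train_labels, config = training_config(),
                        netspec = reduced_network_spec(),
                        val_grids = NULL, val_labels = NULL,
                        restarts = 3, refit_loss = 0.65) {
  fit <- .train_once(train_grids, train_labels, config, netspec,
                     val_grids, val_labels)
  tries <- 0
  while (tries < restarts &&
         fit$history$train_loss[nrow(fit$history)] > refit_loss) {
    tries <- tries + 1
    cfg2 <- config
    cfg2$seed <- config$seed + 1000L * tries
    cfg2$learning_rate <- config$learning_rate * 0.5^tries
    fit <- .train_once(train_grids, train_labels, cfg2, netspec,
                       val_grids, val_labels)
  }
  fit$restarts_used <- tries
  fit
}

.train_once <- function(train_grids, train_labels, config, netspec,
                        val_grids, val_labels) {
  stopifnot(length(train_grids) == length(train_labels))
  if (length(train_grids) == 0) abort("empty training set")
  g1 <- train_grids[[1]]
  net <- build_network(netspec, in_channels = length(g1$channels),
                       grid_size = g1$spec$size, seed = config$seed)
  X <- grids_to_matrix(train_grids)
  y <- as.integer(train_labels == "pathogenic")
  Y <- cbind(benign = 1 - y, pathogenic = y)
  Xv <- if (!is.null(val_grids)) grids_to_matrix(val_grids) else NULL
  yv <- if (!is.null(val_labels)) as.integer(val_labels == "pathogenic") else NULL

  state <- .adamw_init(net)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  t_step <- 0
  hist <- list()
  lr_decay <- config$lr_decay %||% 1
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$learning_rate * lr_decay^(ep - 1)
    ord <- sample(nrow(X))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      fw <- forward(net, X[rows, , drop = FALSE], training = TRUE)
      net <- fw$net
      loss <- .cross_entropy(fw$probs, Y[rows, , drop = FALSE])
      if (!is.finite(loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      }
      losses[bi] <- loss
      grads <- .backward(net, fw$caches, fw$probs, Y[rows, , drop = FALSE])
      t_step <- t_step + 1
      upd <- .adamw_step(net, grads, state, t_step,
                         lr = lr_ep,
                         weight_decay = config$weight_decay)
      net <- upd$net
      state <- upd$state
    }
    row <- tibble(epoch = ep, train_loss = mean(losses),
                  val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(Xv)) {
      pv <- forward(net, Xv, training = FALSE)
      row$val_loss <- .cross_entropy(pv, cbind(1 - yv, yv))
      row$val_accuracy <- mean((pv[, "pathogenic"] > 0.5) == (yv == 1))
    }
    hist[[ep]] <- row
  }
  structure(list(net = net, history = bind_rows(hist), config = config),
            class = "vxm_fit")
}

#' @export
print.vxm_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<vxm_fit> %d epochs; final train loss %.4f%s\n",
              nrow(h), h$train_loss[nrow(h)],
              if (!is.na(h$val_accuracy[nrow(h)]))
                sprintf(", val accuracy %.3f", h$val_accuracy[nrow(h)])
              else ""))
  invisible(x)
}

#' Tidy per-epoch training history
#'
#' @param x A `vxm_fit`.
#' @param ... Unused.
#' @return The history tibble (epoch, train_loss, val_loss, val_accuracy).
#' @export
tidy.vxm_fit <- function(x, ...) x$history

#' One-line fit summary
#'
#' @param x A `vxm_fit`.
#' @param ... Unused.
#' @return One-row tibble with epochs, final losses and parameter count.
#' @export
glance.vxm_fit <- function(x, ...) {
  h <- x$history
  tibble(epochs = nrow(h),
         final_train_loss = h$train_loss[nrow(h)],
         final_val_loss = h$val_loss[nrow(h)],
         final_val_accuracy = h$val_accuracy[nrow(h)],
         n_parameters = n_parameters(x$net))
}

#' Aggregate per-variant prediction
#'
#' A variant is scored by the arithmetic mean of the class probabilities of
#' all of its grids (origin plus augmentations; and, when a variant is
#' mapped to several structures, the per-structure means are averaged in
#' turn). The class call is pathogenic when the mean pathogenic
#' probability strictly exceeds 0.5; ties are called benign.
#'
#' @param model A `vxm_fit` or `vxm_network`.
#' @param grids List of `vxm_grid` objects belonging to one variant, or a
#'   list of such lists (one per structure).
#' @return Tibble with `p_benign`, `p_pathogenic`, `call`.
#' @export
predict_variant <- function(model, grids) {
  net <- if (inherits(model, "vxm_fit")) model$net else model
  if (length(grids) == 0) abort("at least one grid is required")
  per_structure <- if (is.list(grids[[1]]) && !inherits(grids[[1]], "vxm_grid")) {
    grids
  } else {
    list(grids)
  }
  struct_means <- vapply(per_structure, function(gs) {
    p <- forward(net, grids_to_matrix(gs), training = FALSE)
    colMeans(p)
  }, numeric(2))
  p <- rowMeans(struct_means)
  tibble(p_benign = unname(p["benign"]),
         p_pathogenic = unname(p["pathogenic"]),
         call = unname(ifelse(p["pathogenic"] > 0.5, "pathogenic", "benign")))
}
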