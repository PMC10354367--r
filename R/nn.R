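# A compact 3D convolutional network engine. Layers operate on flat batch
# matrices (one row per grid; layout: voxel index fastest, channel slowest,
# matching the column-major flattening of a (d, d, d, C) array).
# Convolutions are im2col matrix products against precomputed patch-index
# tables, so all heavy arithmetic is BLAS. Supports forward, backward,
# dropout, batch normalization with running statistics, and AdamW updates.

#' Default network architecture specification
#'
#' The layer stack of the pathogenicity classifier: batch norm on the
#' input; three 3D convolutions (31 filters kernel 2, 64 filters kernel 2,
#' 64 filters kernel 3, all stride 1, each followed by a rectified-linear
#' activation and batch norm) with one max-pooling layer (kernel 2, stride
#' 2) between the second and third convolution; flatten; batch norm; two
#' fully connected layers of 100 units with dropout 0.5; and a final
#' 2-unit softmax giving benign/pathogenic probabilities.
#'
#' @param dropout Dropout probability for the fully connected block.
#' @return Object of class `vxm_netspec` (list of layer descriptors).
#' @export
network_spec <- function(dropout = 0.5) {
  layers <- list(
    list(type = "batchnorm"),
    list(type = "conv3d", filters = 31, kernel = 2),
    list(type = "batchnorm"),
    list(type = "conv3d", filters = 64, kernel = 2),
    list(type = "batchnorm"),
    list(type = "maxpool", kernel = 2, stride = 2),
    list(type = "conv3d", filters = 64, kernel = 3),
    list(type = "batchnorm"),
    list(type = "flatten"),
    list(type = "batchnorm"),
    list(type = "dense", units = 100, activation = "relu"),
    list(type = "dropout", p = dropout),
    list(type = "dense", units = 100, activation = "relu"),
    list(type = "dropout", p = dropout),
    list(type = "dense", units = 2, activation = "softmax")
  )
  structure(list(layers = layers), class = "vxm_netspec")
}

#' Reduced architecture for desk-scale experiments
#'
#' A narrow single-convolution variant of [network_spec()] (one conv layer
#' of `filters` kernel-2 filters, one max pool, one hidden dense layer)
#' used for fast CPU training on coarse grids; same layer vocabulary and
#' contracts as the full network. Input-level dropout discourages the
#' small network from memorizing protein-specific conservation-profile
#' fingerprints, which otherwise dominate at desk-scale sample sizes.
#'
#' @param filters Convolution filter count.
#' @param hidden Hidden dense units.
#' @param dropout Dropout probability before the output layer.
#' @param input_dropout Dropout probability applied to input voxels during
#'   training (0 disables).
#' @return A `vxm_netspec`.
#' @export
reduced_network_spec <- function(filters = 16, hidden = 32, dropout = 0.5,
                                 input_dropout = 0.3) {
  layers <- list(list(type = "batchnorm"))
  if (input_dropout > 0) {
    layers <- c(layers, list(list(type = "dropout", p = input_dropout)))
  }
  layers <- c(layers, list(
    list(type = "conv3d", filters = filters, kernel = 2),
    list(type = "maxpool", kernel = 2, stride = 2),
    list(type = "flatten"),
    list(type = "dense", units = hidden, activation = "relu"),
    list(type = "dropout", p = dropout),
    list(type = "dense", units = 2, activation = "softmax")
  ))
  structure(list(layers = layers), class = "vxm_netspec")
}

# shape arithmetic for one layer; shape = list(d = spatial side or NA after
# flatten, c = channels/units)
.layer_out_shape <- function(layer, shape) {
  switch(layer$type,
    batchnorm = shape,
    dropout = shape,
    conv3d = {
      if (is.na(shape$d)) abort("conv3d after flatten is invalid")
      d <- shape$d - layer$kernel + 1
      if (d <= 0) abort(sprintf("conv3d kernel %d does not fit spatial dim %d",
                                layer$kernel, shape$d))
      list(d = d, c = layer$filters)
    },
    maxpool = {
      if (is.na(shape$d)) abort("maxpool after flatten is invalid")
      d <- shape$d %/% layer$stride
      if (d <= 0) abort("maxpool output dimension is non-positive")
      list(d = d, c = shape$c)
    },
    flatten = list(d = NA_integer_, c = shape$d^3 * shape$c),
    dense = list(d = NA_integer_, c = layer$units),
    abort(paste0("unknown layer type: ", layer$type))
  )
}

#' Layer-by-layer output shapes
#'
#' Pure shape arithmetic (convolution at stride 1: out = in - kernel + 1;
#' pooling: floor division by the stride); no tensors are allocated.
#'
#' @param spec A `vxm_netspec`.
#' @param input_shape Length-4 integer vector (d, d, d, channels).
#' @return Tibble with `layer`, `type`, `output` (pretty string), `d`
#'   (spatial side, NA once flattened), `channels`, `length` (total
#'   activation length).
#' @export
shape_trace <- function(spec, input_shape = c(20, 20, 20, 31)) {
  stopifnot(inherits(spec, "vxm_netspec"), length(input_shape) == 4)
  shape <- list(d = input_shape[1], c = input_shape[4])
  fmt <- function(s) {
    if (is.na(s$d)) format(s$c, big.mark = ",")
    else sprintf("%d x %d x %d x %d", s$d, s$d, s$d, s$c)
  }
  out <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    shape <- .layer_out_shape(ly, shape)
    out[[i]] <- tibble(
      layer = i, type = ly$type, output = fmt(shape),
      d = as.integer(shape$d), channels = as.integer(shape$c),
      length = as.integer(if (is.na(shape$d)) shape$c else shape$d^3 * shape$c)
    )
  }
  bind_rows(out)
}

# im2col index table: matrix (P x k^3*c_in) of 1-based input offsets
.conv_index <- function(d, c_in, k) {
  dout <- d - k + 1
  pos <- expand.grid(ox = 0:(dout - 1), oy = 0:(dout - 1), oz = 0:(dout - 1))
  ker <- expand.grid(kx = 0:(k - 1), ky = 0:(k - 1), kz = 0:(k - 1),
                     ci = 0:(c_in - 1))
  # P x K via outer-style addition of flattened offsets
  base <- pos$ox + pos$oy * d + pos$oz * d^2
  off <- ker$kx + ker$ky * d + ker$kz * d^2 + ker$ci * d^3
  outer(base, off, `+`) + 1L
}

.pool_index <- function(d, c_in, k, stride) {
  dout <- d %/% stride
  pos <- expand.grid(ox = 0:(dout - 1), oy = 0:(dout - 1), oz = 0:(dout - 1),
                     ci = 0:(c_in - 1))
  ker <- expand.grid(kx = 0:(k - 1), ky = 0:(k - 1), kz = 0:(k - 1))
  base <- pos$ox * stride + pos$oy * stride * d + pos$oz * stride * d^2 +
    pos$ci * d^3
  off <- ker$kx + ker$ky * d + ker$kz * d^2
  outer(base, off, `+`) + 1L
}

#' Build a trainable network
#'
#' Instantiates the layer stack of a [network_spec()] for a given input
#' geometry, allocating weights (He-scaled normal initialization for
#' convolution and dense layers, unit gamma / zero beta for batch norm)
#' and precomputing the im2col patch-index tables. The construction fails
#' if any intermediate shape is invalid.
#'
#' @param spec A `vxm_netspec`.
#' @param in_channels Number of input feature channels (default 31).
#' @param grid_size Voxels per grid side (default 20).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `vxm_network`.
#' @export
build_network <- function(spec, in_channels = 31, grid_size = 20, seed = 1L) {
  stopifnot(inherits(spec, "vxm_netspec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shape <- list(d = grid_size, c = in_channels)
  layers <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    inst <- ly
    inst$in_shape <- shape
    out <- .layer_out_shape(ly, shape)
    inst$out_shape <- out
    if (ly$type == "conv3d") {
      K <- ly$kernel^3 * shape$c
      inst$idx <- .conv_index(shape$d, shape$c, ly$kernel)
      inst$W <- matrix(rnorm(K * ly$filters, sd = sqrt(2 / K)), K, ly$filters)
      inst$b <- numeric(ly$filters)
      inst$P <- nrow(inst$idx)
      # precomputed scatter structure for the gradient accumulation
      inst$flat_idx <- c(inst$idx)
      inst$scatter_levels <- sort(unique(inst$flat_idx))
    } else if (ly$type == "maxpool") {
      inst$idx <- .pool_index(shape$d, shape$c, ly$kernel, ly$stride)
    } else if (ly$type == "dense") {
      n_in <- shape$c
      if (!is.na(shape$d)) abort("dense layer requires flattened input")
      inst$W <- matrix(rnorm(n_in * ly$units, sd = sqrt(2 / n_in)),
                       n_in, ly$units)
      inst$b <- numeric(ly$units)
    } else if (ly$type == "batchnorm") {
      # normalization groups: per channel (conv stage) or per unit (flat)
      nc <- shape$c
      inst$P <- if (is.na(shape$d)) 1L else shape$d^3
      inst$gamma <- rep(1, nc)
      inst$beta <- numeric(nc)
      inst$run_mean <- numeric(nc)
      inst$run_var <- rep(1, nc)
      inst$momentum <- 0.1
      inst$eps <- 1e-5
    }
    layers[[i]] <- inst
    shape <- out
  }
  structure(list(layers = layers, in_channels = in_channels,
                 grid_size = grid_size, seed = seed, spec = spec),
            class = "vxm_network")
}

#' @export
print.vxm_network <- function(x, ...) {
  cat(sprintf("<vxm_network> %d layers, input %d^3 x %d, %s parameters\n",
              length(x$layers), x$grid_size, x$in_channels,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param net A `vxm_network`.
#' @return Integer.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(ly) {
    n <- 0
    if (!is.null(ly$W)) n <- n + length(ly$W) + length(ly$b)
    if (!is.null(ly$gamma)) n <- n + length(ly$gamma) + length(ly$beta)
    as.integer(n)
  }, integer(1)))
}

# ---- forward/backward -------------------------------------------------

# X: N x L batch matrix. Returns list(out, cache) in training mode.
.layer_forward <- function(ly, X, training) {
  n <- nrow(X)
  switch(ly$type,
    conv3d = {
      P <- ly$P; f <- ly$filters
      out <- matrix(0, n, P * f)
      patches <- if (training) vector("list", n) else NULL
      for (i in seq_len(n)) {
        pat <- matrix(X[i, ][ly$idx], nrow(ly$idx), ncol(ly$idx))
        z <- pat %*% ly$W
        z <- sweep(z, 2, ly$b, `+`)
        out[i, ] <- c(pmax(z, 0))
        if (training) patches[[i]] <- pat
      }
      list(out = out, cache = list(patches = patches, pre_relu_out = out))
    },
    maxpool = {
      out <- matrix(0, n, nrow(ly$idx))
      amax <- if (training) matrix(0L, n, nrow(ly$idx)) else NULL
      k <- ncol(ly$idx)
      for (i in seq_len(n)) {
        m <- matrix(X[i, ][ly$idx], nrow(ly$idx), k)
        w <- max.col(m, ties.method = "first")
        out[i, ] <- m[cbind(seq_len(nrow(m)), w)]
        if (training) amax[i, ] <- w
      }
      list(out = out, cache = list(argmax = amax))
    },
    flatten = list(out = X, cache = NULL),
    dense = {
      z <- X %*% ly$W
      z <- sweep(z, 2, ly$b, `+`)
      if (identical(ly$activation, "relu")) {
        a <- pmax(z, 0)
        list(out = a, cache = list(X = X, z = z))
      } else if (identical(ly$activation, "softmax")) {
        zs <- z - apply(z, 1, max)
        ez <- exp(zs)
        p <- ez / rowSums(ez)
        list(out = p, cache = list(X = X, probs = p))
      } else {
        list(out = z, cache = list(X = X, z = z))
      }
    },
    dropout = {
      if (training && ly$p > 0) {
        mask <- matrix(runif(length(X)) >= ly$p, nrow(X), ncol(X)) / (1 - ly$p)
        list(out = X * mask, cache = list(mask = mask))
      } else {
        list(out = X, cache = NULL)
      }
    },
    batchnorm = .bn_forward(ly, X, n, ly$P, length(ly$gamma), training),
    abort(paste0("unknown layer type: ", ly$type))
  )
}

# batchnorm helper: columns of X are ordered voxel-fastest within channel,
# i.e. channel c occupies columns (c-1)*P + (1:P); statistics pool the batch
# and all voxel positions of a channel
.bn_forward <- function(ly, X, n, P, nc, training) {
  Xc <- X
  mu <- numeric(nc); va <- numeric(nc)
  if (training) {
    for (cc in seq_len(nc)) {
      cols <- ((cc - 1) * P + 1):(cc * P)
      v <- Xc[, cols]
      mu[cc] <- mean(v)
      va[cc] <- mean((v - mu[cc])^2)
    }
  } else {
    mu <- ly$run_mean
    va <- ly$run_var
  }
  inv <- 1 / sqrt(va + ly$eps)
  out <- Xc
  xhat <- Xc
  for (cc in seq_len(nc)) {
    cols <- ((cc - 1) * P + 1):(cc * P)
    xh <- (Xc[, cols] - mu[cc]) * inv[cc]
    xhat[, cols] <- xh
    out[, cols] <- ly$gamma[cc] * xh + ly$beta[cc]
  }
  cache <- if (training) list(xhat = xhat, inv = inv, mu = mu, va = va) else NULL
  list(out = out, cache = cache)
}

#' Forward pass
#'
#' @param net A `vxm_network`.
#' @param X Batch matrix (rows = grids, flattened voxel-fastest then
#'   channel) or a single `vxm_grid`.
#' @param training Logical; enables dropout and batch-statistics mode.
#' @return In evaluation mode, a matrix of class probabilities with columns
#'   `benign`, `pathogenic`. In training mode, a list with `probs`,
#'   `caches` and `net` (with updated batch-norm running statistics).
#' @export
forward <- function(net, X, training = FALSE) {
  stopifnot(inherits(net, "vxm_network"))
  if (inherits(X, "vxm_grid")) X <- matrix(c(X$values), nrow = 1)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  expected <- net$grid_size^3 * net$in_channels
  if (ncol(X) != expected) {
    abort(sprintf("input length %d does not match network input %d (%d^3 x %d)",
                  ncol(X), expected, net$grid_size, net$in_channels))
  }
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    fw <- .layer_forward(ly, X, training)
    if (training && ly$type == "batchnorm") {
      # update running statistics
      ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * fw$cache$mu
      ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * fw$cache$va
      net$layers[[i]] <- ly
    }
    caches[[i]] <- fw$cache
    X <- fw$out
  }
  colnames(X) <- c("benign", "pathogenic")
  if (!training) return(X)
  list(probs = X, caches = caches, net = net)
}

#' Single-grid prediction
#'
#' @param net A `vxm_network`.
#' @param grid A `vxm_grid` (standardized).
#' @return Named numeric vector with `p_benign` and `p_pathogenic`
#'   (summing to one).
#' @export
predict_grid <- function(net, grid) {
  p <- forward(net, grid, training = FALSE)
  c(p_benign = p[1, "benign"], p_pathogenic = p[1, "pathogenic"])
}

# backward pass: given caches and one-hot targets, return gradients per layer
# (list parallel to net$layers with W/b or gamma/beta entries)
.backward <- function(net, caches, probs, Y) {
  n <- nrow(probs)
  grads <- vector("list", length(net$layers))
  # softmax + cross-entropy gradient
  delta <- (probs - Y) / n
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ch <- caches[[i]]
    if (ly$type == "dense") {
      if (identical(ly$activation, "relu")) {
        delta <- delta * (ch$z > 0)
      }
      grads[[i]] <- list(W = crossprod(ch$X, delta), b = colSums(delta))
      delta <- delta %*% t(ly$W)
    } else if (ly$type == "dropout") {
      if (!is.null(ch)) delta <- delta * ch$mask
    } else if (ly$type == "flatten") {
      # identity on the flat representation
    } else if (ly$type == "batchnorm") {
      nc <- length(ly$gamma); P <- ly$P
      dgamma <- numeric(nc); dbeta <- numeric(nc)
      dx <- delta
      for (cc in seq_len(nc)) {
        cols <- ((cc - 1) * P + 1):(cc * P)
        dy <- delta[, cols, drop = FALSE]
        xh <- ch$xhat[, cols, drop = FALSE]
        dgamma[cc] <- sum(dy * xh)
        dbeta[cc] <- sum(dy)
        m <- length(dy)
        dx[, cols] <- (ly$gamma[cc] * ch$inv[cc]) *
          (dy - sum(dy) / m - xh * sum(dy * xh) / m)
      }
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      delta <- dx
    } else if (ly$type == "maxpool") {
      L_in <- ly$in_shape$d^3 * ly$in_shape$c
      dx <- matrix(0, n, L_in)
      # kernel == stride: pooling windows are disjoint, so the argmax
      # targets of one sample are unique and can be assigned directly
      for (s in seq_len(n)) {
        tgt <- ly$idx[cbind(seq_len(nrow(ly$idx)), ch$argmax[s, ])]
        dx[s, tgt] <- delta[s, ]
      }
      delta <- dx
    } else if (ly$type == "conv3d") {
      P <- ly$P; f <- ly$filters
      L_in <- ly$in_shape$d^3 * ly$in_shape$c
      dW <- matrix(0, nrow(ly$W), ncol(ly$W))
      db <- numeric(f)
      dx <- matrix(0, n, L_in)
      for (s in seq_len(n)) {
        dz <- matrix(delta[s, ], P, f)
        dz <- dz * (matrix(ch$pre_relu_out[s, ], P, f) > 0)
        pat <- ch$patches[[s]]
        dW <- dW + crossprod(pat, dz)
        db <- db + colSums(dz)
        dpat <- dz %*% t(ly$W)
        acc <- rowsum(c(dpat), ly$flat_idx, reorder = TRUE)
        dx[s, ly$scatter_levels] <- acc[, 1]
      }
      grads[[i]] <- list(W = dW, b = db)
      delta <- dx
    }
  }
  grads
}

# AdamW: decoupled weight decay on weight matrices (not biases or batch-norm
# affine parameters)
.adamw_init <- function(net) {
  lapply(net$layers, function(ly) {
    out <- list()
    for (p in c("W", "b", "gamma", "beta")) {
      if (!is.null(ly[[p]])) {
        out[[p]] <- list(m = ly[[p]] * 0, v = ly[[p]] * 0)
      }
    }
    out
  })
}

.adamw_step <- function(net, grads, state, t, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      upd <- mhat / (sqrt(vhat) + eps)
      if (p == "W") upd <- upd + weight_decay * net$layers[[i]][[p]]
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * upd
      state[[i]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

.cross_entropy <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}
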