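#' Architecture configuration for the row-convolution network
#'
#' The classifier is a set of parallel convolution branches applied to the
#' R x R connectome. Branch `k` slides `n_filters` filters of shape
#' `k x R` along the row axis only (valid convolution, stride 1), so each of
#' the `R - k + 1` positions scores `k` adjacent ROI connectivity profiles
#' jointly. Each branch applies `tanh` and a global max over positions,
#' yielding `n_filters` features per branch; branch outputs are concatenated,
#' passed through dropout (training only) and a single dense softmax layer.
#'
#' @param n_rois number of ROIs R (matrix side); default 392.
#' @param branch_lengths strictly increasing filter heights; default `1:7`.
#' @param n_filters filters per branch; default 400.
#' @param keep_prob fraction of concatenated features *kept* by dropout
#'   during training; default 0.25.
#' @param n_classes number of output classes; default 2 (class 0 = control,
#'   class 1 = ASD).
#' @return a `model_config` object.
#' @export
model_config <- function(n_rois = 392L, branch_lengths = 1:7,
                         n_filters = 400L, keep_prob = 0.25,
                         n_classes = 2L) {
  n_rois <- as.integer(n_rois)
  branch_lengths <- as.integer(branch_lengths)
  n_filters <- as.integer(n_filters)
  n_classes <- as.integer(n_classes)
  stopifnot(n_rois >= 1L, n_filters >= 1L, n_classes >= 2L,
            length(branch_lengths) >= 1L, all(branch_lengths >= 1L),
            keep_prob > 0, keep_prob <= 1)
  if (is.unsorted(branch_lengths, strictly = TRUE)) {
    abort("branch_lengths must be strictly increasing", class = "conncnn_config_error")
  }
  if (max(branch_lengths) > n_rois) {
    abort(paste0("largest branch length (", max(branch_lengths),
                 ") exceeds n_rois (", n_rois, ")"),
          class = "conncnn_config_error")
  }
  structure(list(n_rois = n_rois, branch_lengths = branch_lengths,
                 n_filters = n_filters, keep_prob = keep_prob,
                 n_classes = n_classes),
            class = "model_config")
}

#' Optimization settings for network training
#'
#' @param learning_rate step size; default 0.005.
#' @param batch_size minibatch size; default 32.
#' @param epochs passes over the training set; default 300.
#' @param optimizer `"adam"` (adaptive moments, default) or `"sgd"`.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 0.005, batch_size = 32L,
                         epochs = 300L, optimizer = c("adam", "sgd"),
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

#' Exact trainable-parameter count of the architecture
#'
#' Closed form: `F * R * sum(K) + |K| * F` convolution weights and biases
#' plus `|K| * F * C + C` dense weights and biases, for R ROIs, branch
#' heights K, F filters per branch and C classes. The default configuration
#' (R = 392, K = 1..7, F = 400, C = 2) yields 4,398,802. [build_model()]
#' instantiates exactly this many scalars, which is asserted in the test
#' suite.
#'
#' @param config a [model_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "model_config"))
  R <- config$n_rois; K <- config$branch_lengths
  F <- config$n_filters; C <- config$n_classes
  conv <- F * R * sum(K) + length(K) * F
  dense <- length(K) * F * C + C
  as.integer(conv + dense)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Instantiate the network
#'
#' Allocates Glorot-uniform convolution filters and a zero-initialized dense
#' layer according to `config`. The total number of scalars allocated always
#' equals [count_parameters()].
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return a `conncnn_model` object (untrained).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  R <- config$n_rois; K <- config$branch_lengths
  F <- config$n_filters; C <- config$n_classes
  with_seed(seed, {
    conv_w <- lapply(K, function(k) {
      fan_in <- k * R
      lim <- sqrt(6 / (fan_in + F))
      matrix(stats::runif(fan_in * F, -lim, lim), nrow = fan_in, ncol = F)
    })
    conv_b <- lapply(K, function(k) numeric(F))
    nk <- length(K)
    lim <- sqrt(6 / (nk * F + C))
    dense_w <- matrix(stats::runif(nk * F * C, -lim, lim), nrow = nk * F, ncol = C)
    dense_b <- numeric(C)
    structure(list(config = config, conv_w = conv_w, conv_b = conv_b,
                   dense_w = dense_w, dense_b = dense_b,
                   trained = FALSE, loss_trace = numeric(0)),
              class = "conncnn_model")
  })
}

#' Number of scalars actually held by a built model
#' @param model a `conncnn_model`.
#' @return integer count of weight and bias entries.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "conncnn_model"))
  as.integer(sum(vapply(model$conv_w, length, 1L)) +
             sum(vapply(model$conv_b, length, 1L)) +
             length(model$dense_w) + length(model$dense_b))
}

# row-major patch matrix for filter height k: row p = rows p..p+k-1 of X
# flattened row by row; (R - k + 1) x (k * R)
conv_patches <- function(X, k) {
  R <- nrow(X)
  pos <- R - k + 1L
  if (k == 1L) return(X)
  do.call(cbind, lapply(0:(k - 1L), function(s) X[(1L + s):(pos + s), , drop = FALSE]))
}

# stacked patches for a list of inputs (subject-major row blocks)
stack_patches <- function(conns, k) {
  do.call(rbind, lapply(conns, conv_patches, k = k))
}

# forward pass on stacked patch matrices.
# plist: list over branches of (B*pos_k) x (k*R) matrices; returns pooled
# features, softmax probabilities and (optionally) the caches backprop needs.
nn_forward <- function(model, plist, B, dropout_mask = NULL, cache = FALSE) {
  cfg <- model$config
  K <- cfg$branch_lengths; F <- cfg$n_filters
  pooled <- vector("list", length(K))
  argmax <- if (cache) vector("list", length(K)) else NULL
  for (j in seq_along(K)) {
    pos <- cfg$n_rois - K[j] + 1L
    A <- tanh(sweep(plist[[j]] %*% model$conv_w[[j]], 2L, model$conv_b[[j]], "+"))
    m <- matrix(-Inf, B, F)
    idx <- matrix(1L, B, F)
    base <- (seq_len(B) - 1L) * pos
    for (p in seq_len(pos)) {
      slice <- A[base + p, , drop = FALSE]
      upd <- slice > m
      if (any(upd)) {
        m[upd] <- slice[upd]
        idx[upd] <- p
      }
    }
    pooled[[j]] <- m
    if (cache) argmax[[j]] <- idx
  }
  h <- do.call(cbind, pooled)               # B x (|K| * F)
  h_used <- if (is.null(dropout_mask)) h else h * dropout_mask / cfg$keep_prob
  logits <- sweep(h_used %*% model$dense_w, 2L, model$dense_b, "+")
  shifted <- logits - apply(logits, 1L, max)
  expz <- exp(shifted)
  probs <- expz / rowSums(expz)
  out <- list(probs = probs, logits = logits)
  if (cache) {
    out$h <- h; out$h_used <- h_used; out$pooled <- pooled; out$argmax <- argmax
  }
  out
}

# gradients of mean cross-entropy (or of a raw class score when
# score_class is given) w.r.t. all weights; optionally w.r.t. the input.
nn_backward <- function(model, plist, B, fwd, y_onehot = NULL,
                        dropout_mask = NULL, score_class = NULL,
                        input_grad = FALSE) {
  cfg <- model$config
  K <- cfg$branch_lengths; F <- cfg$n_filters; R <- cfg$n_rois
  if (is.null(score_class)) {
    dlogits <- (fwd$probs - y_onehot) / B
  } else {
    dlogits <- matrix(0, B, cfg$n_classes)
    dlogits[, score_class + 1L] <- 1
  }
  g <- list(dense_w = crossprod(fwd$h_used, dlogits),
            dense_b = colSums(dlogits),
            conv_w = vector("list", length(K)),
            conv_b = vector("list", length(K)))
  dh <- dlogits %*% t(model$dense_w)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask / cfg$keep_prob
  if (input_grad) dX <- vector("list", length(K))
  for (j in seq_along(K)) {
    k <- K[j]; pos <- R - k + 1L
    dm <- dh[, ((j - 1L) * F + 1L):(j * F), drop = FALSE]
    dz_val <- dm * (1 - fwd$pooled[[j]]^2)      # tanh' at the max position
    rows <- rep((seq_len(B) - 1L) * pos, times = F) + as.vector(fwd$argmax[[j]])
    cols <- rep(seq_len(F), each = B)
    dZ <- matrix(0, B * pos, F)
    dZ[cbind(rows, cols)] <- as.vector(dz_val)
    g$conv_w[[j]] <- crossprod(plist[[j]], dZ)
    g$conv_b[[j]] <- colSums(dZ)
    if (input_grad) {
      dP <- dZ %*% t(model$conv_w[[j]])         # (B*pos) x (k*R)
      gX <- matrix(0, B * R, R)                  # stacked per-subject grads
      for (s in 0:(k - 1L)) {
        blk <- dP[, (s * R + 1L):((s + 1L) * R), drop = FALSE]
        tgt <- rep((seq_len(B) - 1L) * R, each = pos) + rep((1L + s):(pos + s), B)
        src <- seq_len(B * pos)
        gX[tgt, ] <- gX[tgt, , drop = FALSE] + blk[src, , drop = FALSE]
      }
      dX[[j]] <- gX
    }
  }
  if (input_grad) g$input <- Reduce(`+`, dX)
  g
}

adam_init <- function(model) {
  zero_like <- function(w) {
    if (is.list(w)) lapply(w, zero_like) else w * 0
  }
  list(m = zero_like(model[c("conv_w", "conv_b", "dense_w", "dense_b")]),
       v = zero_like(model[c("conv_w", "conv_b", "dense_w", "dense_b")]),
       t = 0L)
}

adam_update <- function(w, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

#' Train the network on labelled connectomes
#'
#' Minibatch training with categorical cross-entropy loss. The adaptive-moment
#' optimizer is the default; plain SGD is available. Dropout (keeping
#' `keep_prob` of the concatenated features) is applied during training only.
#' Training is fully deterministic given `tconf$seed`: initial shuffling,
#' batch order and dropout masks are all drawn from it, and the caller's RNG
#' state is untouched.
#'
#' @param model a `conncnn_model` from [build_model()].
#' @param connectomes list of R x R connectome matrices.
#' @param labels class labels: factor/character with levels `TC`/`ASD`, or
#'   0/1 integers (1 = ASD).
#' @param tconf a [train_config()].
#' @return the trained model, with the per-epoch mean loss in `$loss_trace`.
#' @export
train <- function(model, connectomes, labels, tconf = train_config()) {
  stopifnot(inherits(model, "conncnn_model"), inherits(tconf, "train_config"))
  y <- encode_labels(labels)
  n <- length(connectomes)
  if (n == 0L) abort("no training subjects", class = "conncnn_data_error")
  if (length(y) != n) abort("labels and connectomes differ in length",
                            class = "conncnn_data_error")
  if (length(unique(y)) < 2L) {
    abort("training set contains a single class", class = "conncnn_data_error")
  }
  cfg <- model$config
  check_input_shape(connectomes[[1L]], cfg$n_rois)
  if (tconf$epochs == 0L) return(model)

  K <- cfg$branch_lengths; R <- cfg$n_rois; C <- cfg$n_classes
  # cache stacked patch matrices when they fit comfortably in memory,
  # otherwise rebuild them per minibatch
  bytes <- 8 * n * sum((R - K + 1) * K * R)
  cache_all <- bytes < 1e9
  if (cache_all) {
    P_full <- lapply(K, function(k) stack_patches(connectomes, k))
  }
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), y + 1L)] <- 1

  with_seed(tconf$seed, {
    st <- adam_init(model)
    keep <- cfg$keep_prob
    nK <- length(K); F <- cfg$n_filters
    for (epoch in seq_len(tconf$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / tconf$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        B <- length(idx)
        plist <- lapply(seq_along(K), function(j) {
          k <- K[j]; pos <- R - k + 1L
          if (cache_all) {
            rows <- rep((idx - 1L) * pos, each = pos) + rep(seq_len(pos), B)
            P_full[[j]][rows, , drop = FALSE]
          } else {
            stack_patches(connectomes[idx], k)
          }
        })
        mask <- if (keep < 1) {
          matrix(stats::runif(B * nK * F) < keep, B, nK * F) * 1
        } else NULL
        fwd <- nn_forward(model, plist, B, dropout_mask = mask, cache = TRUE)
        yb <- Y[idx, , drop = FALSE]
        epoch_loss <- epoch_loss -
          sum(log(pmax(fwd$probs[yb == 1], 1e-12))) / n
        g <- nn_backward(model, plist, B, fwd, y_onehot = yb,
                         dropout_mask = mask)
        st$t <- st$t + 1L
        if (tconf$optimizer == "adam") {
          for (j in seq_along(K)) {
            up <- adam_update(model$conv_w[[j]], g$conv_w[[j]],
                              st$m$conv_w[[j]], st$v$conv_w[[j]],
                              tconf$learning_rate, st$t)
            model$conv_w[[j]] <- up$w; st$m$conv_w[[j]] <- up$m; st$v$conv_w[[j]] <- up$v
            up <- adam_update(model$conv_b[[j]], g$conv_b[[j]],
                              st$m$conv_b[[j]], st$v$conv_b[[j]],
                              tconf$learning_rate, st$t)
            model$conv_b[[j]] <- up$w; st$m$conv_b[[j]] <- up$m; st$v$conv_b[[j]] <- up$v
          }
          up <- adam_update(model$dense_w, g$dense_w, st$m$dense_w,
                            st$v$dense_w, tconf$learning_rate, st$t)
          model$dense_w <- up$w; st$m$dense_w <- up$m; st$v$dense_w <- up$v
          up <- adam_update(model$dense_b, g$dense_b, st$m$dense_b,
                            st$v$dense_b, tconf$learning_rate, st$t)
          model$dense_b <- up$w; st$m$dense_b <- up$m; st$v$dense_b <- up$v
        } else {
          lr <- tconf$learning_rate
          for (j in seq_along(K)) {
            model$conv_w[[j]] <- model$conv_w[[j]] - lr * g$conv_w[[j]]
            model$conv_b[[j]] <- model$conv_b[[j]] - lr * g$conv_b[[j]]
          }
          model$dense_w <- model$dense_w - lr * g$dense_w
          model$dense_b <- model$dense_b - lr * g$dense_b
        }
      }
      model$loss_trace <- c(model$loss_trace, epoch_loss)
    }
    model$trained <- TRUE
    model
  })
}

#' Class probabilities for one or more connectomes
#'
#' Runs the network in inference mode (dropout disabled; deterministic).
#' Column 1 is the control class (class 0), column 2 the ASD class (class 1).
#'
#' @param model a `conncnn_model`.
#' @param inputs a single R x R matrix or a list of them.
#' @return a B x C matrix of probabilities; rows sum to 1.
#' @export
predict_proba <- function(model, inputs) {
  stopifnot(inherits(model, "conncnn_model"))
  if (is.matrix(inputs)) inputs <- list(inputs)
  cfg <- model$config
  for (x in inputs) check_input_shape(x, cfg$n_rois)
  B <- length(inputs)
  plist <- lapply(cfg$branch_lengths, function(k) stack_patches(inputs, k))
  probs <- nn_forward(model, plist, B)$probs
  colnames(probs) <- class_names(cfg$n_classes)
  probs
}

class_names <- function(C) {
  if (C == 2L) c("TC", "ASD") else paste0("class", seq_len(C) - 1L)
}

check_input_shape <- function(x, R) {
  if (!is.matrix(x) || nrow(x) != R || ncol(x) != R) {
    abort(paste0("input must be a ", R, " x ", R, " matrix, got ",
                 paste(dim(x), collapse = " x ")),
          class = "conncnn_shape_error")
  }
  invisible(TRUE)
}

# labels -> integer 0/1 vector (1 = ASD, positive class)
encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("ASD", "TC")
    if (any(bad)) abort("labels must be 'ASD'/'TC' or 0/1",
                        class = "conncnn_data_error")
    return(as.integer(labels == "ASD"))
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    abort("numeric labels must be 0 (control) or 1 (ASD)",
          class = "conncnn_data_error")
  }
  labels
}

#' @export
print.conncnn_model <- function(x, ...) {
  cfg <- x$config
  cat("<conncnn_model> ", if (x$trained) "trained" else "untrained", "\n", sep = "")
  cat("  input: ", cfg$n_rois, " x ", cfg$n_rois,
      "; branches k = ", paste(cfg$branch_lengths, collapse = ","),
      "; ", cfg$n_filters, " filters/branch\n", sep = "")
  cat("  trainable parameters: ", format(n_parameters(x), big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

#' @export
glance.conncnn_model <- function(x, ...) {
  cfg <- x$config
  tibble(n_rois = cfg$n_rois,
         n_branches = length(cfg$branch_lengths),
         n_filters = cfg$n_filters,
         keep_prob = cfg$keep_prob,
         n_classes = cfg$n_classes,
         n_parameters = n_parameters(x),
         trained = x$trained,
         final_loss = if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA_real_)
}
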