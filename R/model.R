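#' Architecture specification of the 3D CNN
#'
#' The default is the two-layer volumetric classifier: a 32-cube input goes
#' through 32 filters of size 9x9x9 with stride 2 (no padding), then 64
#' filters of size 5x5x5 with stride 1, a 2x2x2 max-pool with stride 2, a
#' 128-unit dense layer and a 6-unit softmax output, with Leaky ReLU
#' (alpha = 0.1) after every conv/dense layer and dropout at three sites.
#' The spatial chain is 32 -> 12 -> 8 -> 4 -> flatten 4096 -> 128 -> 6 and
#' the default network holds exactly 804,614 trainable parameters
#' (including biases).
#'
#' @param input_edge Input grid edge length.
#' @param conv1_filters,conv1_kernel,conv1_stride First conv layer.
#' @param conv2_filters,conv2_kernel,conv2_stride Second conv layer.
#' @param pool_size Max-pool window edge (stride equals the window).
#' @param dense1_units Width of the hidden dense layer.
#' @param n_classes Output classes (6 EC classes).
#' @param leaky_relu_alpha Negative-slope coefficient of the activations.
#' @param dropout_rates Length-3 vector: after conv1's activation, after
#'   the pool, after dense1's activation.
#' @return An `architecture_spec` list with derived layer shapes.
#' @export
architecture_spec <- function(input_edge = 32L,
                              conv1_filters = 32L, conv1_kernel = 9L,
                              conv1_stride = 2L,
                              conv2_filters = 64L, conv2_kernel = 5L,
                              conv2_stride = 1L,
                              pool_size = 2L,
                              dense1_units = 128L, n_classes = 6L,
                              leaky_relu_alpha = 0.1,
                              dropout_rates = c(0.2, 0.3, 0.4)) {
  # valid (no-padding) convolution: floor((l - k)/s) + 1, trailing voxels
  # that do not fill a window are dropped
  chk_dim <- function(l_in, k, s, layer) {
    if (k > l_in)
      stop("layer '", layer, "': kernel ", k, " exceeds input edge ", l_in)
    (l_in - k) %/% s + 1L
  }
  o1 <- chk_dim(as.integer(input_edge), as.integer(conv1_kernel),
                as.integer(conv1_stride), "conv1")
  o2 <- chk_dim(o1, as.integer(conv2_kernel), as.integer(conv2_stride), "conv2")
  if (o2 %% pool_size != 0L)
    stop("layer 'pool': edge ", o2, " not divisible by pool size ", pool_size)
  o3 <- o2 %/% as.integer(pool_size)
  if (length(dropout_rates) != 3L || any(dropout_rates < 0 | dropout_rates >= 1))
    stop("dropout_rates must be three rates in [0, 1)")
  structure(list(
    input_edge = as.integer(input_edge),
    conv1 = list(filters = as.integer(conv1_filters),
                 kernel = as.integer(conv1_kernel),
                 stride = as.integer(conv1_stride), out_edge = o1),
    conv2 = list(filters = as.integer(conv2_filters),
                 kernel = as.integer(conv2_kernel),
                 stride = as.integer(conv2_stride), out_edge = o2),
    pool = list(size = as.integer(pool_size), out_edge = o3),
    flat = as.integer(conv2_filters) * o3^3,
    dense1_units = as.integer(dense1_units),
    n_classes = as.integer(n_classes),
    leaky_relu_alpha = leaky_relu_alpha,
    dropout_rates = as.numeric(dropout_rates)),
    class = "architecture_spec")
}

#' Training configuration
#'
#' @param l2_strength L2 regularization strength on conv/dense kernels
#'   (biases are not penalized).  Default 0.001.
#' @param learning_rate,beta1,beta2 Adam optimizer hyperparameters.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param p_flip Per-axis flip probability of the training augmentation.
#' @param class_weighting `"uniform"` (all loss weights 1) or `"adapted"`
#'   (weights from [compute_class_weights()] on the training counts).
#' @param seed Master seed for initialization, shuffling, flip draws and
#'   dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(l2_strength = 0.001, learning_rate = 1e-3,
                            beta1 = 0.9, beta2 = 0.999, epochs = 200L,
                            batch_size = 32L, p_flip = 0.2,
                            class_weighting = c("uniform", "adapted"),
                            seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  if (p_flip < 0 || p_flip > 1) stop("p_flip must be in [0, 1]")
  if (l2_strength < 0 || learning_rate <= 0 || epochs < 0 || batch_size < 1)
    stop("invalid training configuration")
  structure(list(l2_strength = l2_strength, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), p_flip = p_flip,
                 class_weighting = class_weighting, seed = as.integer(seed)),
            class = "training_config")
}

# dims list consumed by the C++ kernels
model_dims <- function(spec) {
  list(l = spec$input_edge,
       k1 = spec$conv1$kernel, s1 = spec$conv1$stride, c1 = spec$conv1$filters,
       k2 = spec$conv2$kernel, s2 = spec$conv2$stride, c2 = spec$conv2$filters,
       pool = spec$pool$size, d1 = spec$dense1_units, nc = spec$n_classes,
       alpha = spec$leaky_relu_alpha)
}

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

#' Build (initialize) the classifier
#'
#' Allocates the network's weights with Glorot-uniform initialization and
#' zero biases; reproducible from `seed`.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return An `enzyvox_model` handle.
#' @export
build_model <- function(spec = architecture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  k1e <- spec$conv1$kernel^3
  k2e <- spec$conv2$kernel^3 * spec$conv1$filters
  params <- with_seed(seed, list(
    W1 = glorot_uniform(spec$conv1$filters, k1e,
                        fan_in = k1e, fan_out = spec$conv1$kernel^3 * spec$conv1$filters),
    b1 = numeric(spec$conv1$filters),
    W2 = glorot_uniform(spec$conv2$filters, k2e,
                        fan_in = k2e, fan_out = spec$conv2$kernel^3 * spec$conv2$filters),
    b2 = numeric(spec$conv2$filters),
    W3 = glorot_uniform(spec$dense1_units, spec$flat,
                        fan_in = spec$flat, fan_out = spec$dense1_units),
    b3 = numeric(spec$dense1_units),
    W4 = glorot_uniform(spec$n_classes, spec$dense1_units,
                        fan_in = spec$dense1_units, fan_out = spec$n_classes),
    b4 = numeric(spec$n_classes)))
  structure(list(spec = spec, params = params, trained = FALSE, seed = seed),
            class = "enzyvox_model")
}

#' @export
print.enzyvox_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0(
    "<enzyvox_model> %s\n",
    "  conv(%d, %d^3, s%d) -> LeakyReLU -> conv(%d, %d^3, s%d) -> LeakyReLU\n",
    "  -> maxpool(%d^3) -> dense(%d) -> LeakyReLU -> dense(%d) -> softmax\n",
    "  %s parameters\n"),
    if (x$trained) "trained" else "initialized",
    s$conv1$filters, s$conv1$kernel, s$conv1$stride,
    s$conv2$filters, s$conv2$kernel, s$conv2$stride,
    s$pool$size, s$dense1_units, s$n_classes,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of weights and biases; with `by_layer = TRUE`, the
#' per-layer breakdown (conv1, conv2, dense1, dense2).
#'
#' @param model An `enzyvox_model`.
#' @param by_layer Return a named per-layer vector instead of the total.
#' @return Integer count, or named integer vector.
#' @examples
#' count_parameters(build_model())  # 804614
#' @export
count_parameters <- function(model, by_layer = FALSE) {
  stopifnot(inherits(model, "enzyvox_model"))
  p <- model$params
  counts <- c(conv1 = length(p$W1) + length(p$b1),
              conv2 = length(p$W2) + length(p$b2),
              dense1 = length(p$W3) + length(p$b3),
              dense2 = length(p$W4) + length(p$b4))
  if (by_layer) counts else sum(counts)
}

#' Class-weighted categorical cross-entropy
#'
#' `L = -sum_x sum_i w_i * delta_{x,i} * log(p_{x,i})`: the summed (not
#' averaged) cross-entropy over samples, where each sample's contribution
#' is scaled by the loss weight of its true class.  With all weights 1
#' this is the standard categorical cross-entropy.
#'
#' @param probs Matrix of predicted class probabilities, one row per
#'   sample, rows summing to 1.
#' @param labels One-hot label matrix of the same shape.
#' @param weights Per-class weights (default all 1); see
#'   [compute_class_weights()].
#' @param epsilon Clamp for vanishing predicted probabilities; a true
#'   class predicted below `epsilon` is clamped with a warning.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels,
                                   weights = rep(1, ncol(as.matrix(probs))),
                                   epsilon = 1e-7) {
  probs <- rbind(probs)
  labels <- rbind(labels)
  stopifnot(identical(dim(probs), dim(labels)))
  if (any(abs(rowSums(labels) - 1) > 1e-8) || !all(labels %in% c(0, 1)))
    stop("labels must be one-hot rows")
  true_ix <- max.col(labels, ties.method = "first")
  p_true <- probs[cbind(seq_len(nrow(probs)), true_ix)]
  if (any(p_true < epsilon)) {
    warning("clamping ", sum(p_true < epsilon),
            " vanishing predicted probabilities at epsilon = ", epsilon)
    p_true <- pmax(p_true, epsilon)
  }
  sum(weights[true_ix] * -log(p_true))
}

# Stack voxel grids (or matrices already flattened) into an n x l^3 matrix.
grids_to_matrix <- function(grids) {
  if (is.matrix(grids)) return(grids)
  if (inherits(grids, "voxel_grid")) grids <- list(grids)
  do.call(rbind, lapply(grids, function(g) as.numeric(g$values)))
}

#' Predict class probabilities for voxel grids
#'
#' Deterministic inference forward pass (dropout disabled).
#'
#' @param model A built or trained `enzyvox_model`.
#' @param grids A [voxel_grid()], list of grids, or an `n x l^3` matrix of
#'   flattened grids.
#' @return Matrix of class probabilities, one row per grid.
#' @export
predict_probs <- function(model, grids) {
  stopifnot(inherits(model, "enzyvox_model"))
  X <- grids_to_matrix(grids)
  if (ncol(X) != model$spec$input_edge^3)
    stop("grid size does not match the model's input edge ",
         model$spec$input_edge)
  pr <- .cnn_forward_cpp(X, model$params, model_dims(model$spec))
  colnames(pr) <- paste0("EC", seq_len(ncol(pr)))
  pr
}

#' Train the classifier
#'
#' Minimizes the class-weighted cross-entropy (plus the L2 kernel penalty)
#' with Adam over mini-batches drawn from the flip-augmented
#' [training_stream()].  With `class_weighting = "uniform"` all class
#' weights are 1; with `"adapted"` they follow [compute_class_weights()]
#' on the training-set class counts.  Validation loss and accuracy are
#' recorded each epoch on unflipped grids.
#'
#' @param model An `enzyvox_model` from [build_model()].
#' @param split A `dataset_split` from [split_dataset()].
#' @param cfg A [training_config()].
#' @param vox_cfg A [voxelizer_config()] matching the model's input edge.
#' @param verbose Print one line per epoch.
#' @return The trained model, with a `history` data frame (epoch,
#'   train_loss, val_loss, val_accuracy) and the resolved class weights
#'   attached.
#' @export
train <- function(model, split, cfg = training_config(),
                  vox_cfg = voxelizer_config(), verbose = FALSE) {
  stopifnot(inherits(model, "enzyvox_model"), inherits(split, "dataset_split"),
            inherits(cfg, "training_config"))
  if (vox_cfg$l != model$spec$input_edge)
    stop("voxelizer grid size must equal the model's input edge")
  n_train <- nrow(split$train)
  if (n_train == 0L) stop("empty training split")

  counts <- tabulate(split$train$ec_class, nbins = 6L)
  cw <- if (cfg$class_weighting == "adapted") {
    if (any(counts == 0L))
      stop("adapted weighting requires at least one training sample per class")
    compute_class_weights(counts)
  } else rep(1, 6)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  model$class_weights <- cw
  model$training_config <- cfg
  model$vox_config <- vox_cfg
  if (cfg$epochs == 0L) {
    model$history <- history
    return(model)
  }

  stream <- training_stream(split, vox_cfg, cfg$p_flip,
                            seed = derive_seed(cfg$seed, 101))

  has_val <- nrow(split$validation) > 0L
  if (has_val) {
    val_grids <- lapply(seq_len(nrow(split$validation)), function(i)
      voxelize(parse_pdb(split$validation$source[i],
                         split$validation$structure_id[i],
                         backbone_atoms = vox_cfg$backbone_atoms),
               vox_cfg))
    Xval <- grids_to_matrix(val_grids)
    Yval_class <- split$validation$ec_class
  }

  dims <- model_dims(model$spec)
  params <- model$params
  opt <- list(m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0), t = 0L)
  adam_step <- function(params, grads, opt, cfg) {
    opt$t <- opt$t + 1L
    for (nm in names(params)) {
      opt$m[[nm]] <- cfg$beta1 * opt$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
      opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
      mhat <- opt$m[[nm]] / (1 - cfg$beta1^opt$t)
      vhat <- opt$v[[nm]] / (1 - cfg$beta2^opt$t)
      params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + 1e-8)
    }
    list(params = params, opt = opt)
  }

  with_seed(derive_seed(cfg$seed, 202), {
    for (epoch in seq_len(cfg$epochs)) {
      items <- lapply(seq_len(n_train), function(i) stream$next_item())
      Xep <- grids_to_matrix(lapply(items, `[[`, "grid"))
      Yep <- do.call(rbind, lapply(items, `[[`, "label"))
      batch_starts <- seq(1L, n_train, by = cfg$batch_size)
      ep_loss <- 0
      for (b in batch_starts) {
        rows <- b:min(b + cfg$batch_size - 1L, n_train)
        res <- .cnn_backprop_cpp(Xep[rows, , drop = FALSE],
                                 Yep[rows, , drop = FALSE],
                                 cw, params, dims,
                                 model$spec$dropout_rates, cfg$l2_strength)
        if (!is.finite(res$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        ep_loss <- ep_loss + res$loss * length(rows)
        grads <- res[c("gW1", "gb1", "gW2", "gb2", "gW3", "gb3", "gW4", "gb4")]
        names(grads) <- sub("^g", "", names(grads))
        st <- adam_step(params, grads, opt, cfg)
        params <- st$params
        opt <- st$opt
      }
      ep_loss <- ep_loss / n_train
      if (has_val) {
        pv <- .cnn_forward_cpp(Xval, params, dims)
        val_acc <- mean(max.col(pv, ties.method = "first") == Yval_class)
        val_loss <- sum(cw[Yval_class] *
                          -log(pmax(pv[cbind(seq_along(Yval_class), Yval_class)],
                                    1e-12))) / length(Yval_class)
      } else {
        val_acc <- NA_real_
        val_loss <- NA_real_
      }
      history[epoch, ] <- list(epoch, ep_loss, val_loss, val_acc)
      if (verbose)
        message(sprintf("epoch %3d  train_loss %.4f  val_loss %s  val_acc %s",
                        epoch, ep_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  })

  model$params <- params
  model$trained <- TRUE
  model$history <- history
  model
}

#' Persist and restore a model
#'
#' The weights go into an RDS checkpoint; a JSON sidecar
#' (`<path>.json`) records the architecture, training and voxelizer
#' configurations so predictions are reproducible.
#'
#' @param model A trained `enzyvox_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "enzyvox_model"))
  saveRDS(model, path)
  sidecar <- list(spec = unclass(model$spec),
                  training_config = if (!is.null(model$training_config))
                    unclass(model$training_config),
                  vox_config = if (!is.null(model$vox_config))
                    unclass(model$vox_config),
                  n_parameters = count_parameters(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "enzyvox_model"))
  model
}

#' Write a training history as CSV
#'
#' @param model A trained model with a `history` entry.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_history <- function(model, path) {
  stopifnot(inherits(model, "enzyvox_model"), !is.null(model$history))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
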