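#' Network architecture configuration
#'
#' Describes one SIR submodel and the six-branch fusion. The defaults follow
#' the reference architecture for 30 x 30 patches: a 3 x 3 stem of 32
#' kernels, a first identity residual block at width 32 on the 15 x 15 map, a
#' secondary-input path concatenated to 64 channels, a 3 x 3 convolution to
#' 128 channels on the 8 x 8 map, a second residual block at width 128, a
#' shape-preserving 2 x 2 pool, and two 256-wide dense layers; fusion
#' concatenates the six 256-vectors into a 256-wide dense layer and a single
#' sigmoid neuron.
#'
#' Residual blocks run 1 x 1 (valid) -> 3 x 3 (same) -> 1 x 1 (valid) on the
#' main path and add the identity shortcut before the final ReLU, so the last
#' width of each block must equal its input channel count.
#'
#' @param patch_size Patch side length (default 30).
#' @param stem_channels Kernels in the stem convolution C1 (default 32).
#' @param rb1_widths Integer triple of main-path widths of residual block 1;
#'   the last entry must equal `stem_channels`.
#' @param c4_channels Kernels in the deep 3 x 3 convolution C4 (default 128).
#' @param rb2_widths Integer triple for residual block 2; last entry must
#'   equal `c4_channels`.
#' @param fc_width Width of the two dense layers F7/F8 (default 256).
#' @param fusion_width Width of the fusion dense layer (default 256).
#' @param variant `"MV-SIR"` (full model), `"MV-I-CNN"` (no secondary input)
#'   or `"MV-CNN"` (no secondary input and each residual block replaced by a
#'   single 3 x 3 convolution of the same width).
#' @return An object of class `net_config`.
#' @export
#' @examples
#' cfg <- net_config()
#' cfg$variant
net_config <- function(patch_size = 30L, stem_channels = 32L,
                       rb1_widths = c(32L, 32L, 32L), c4_channels = 128L,
                       rb2_widths = c(128L, 128L, 128L), fc_width = 256L,
                       fusion_width = 256L,
                       variant = c("MV-SIR", "MV-I-CNN", "MV-CNN")) {
  variant <- match.arg(variant)
  for (v in list(patch_size, stem_channels, c4_channels, fc_width, fusion_width))
    if (!is_count(v) || v < 1) stop_config("net_config: sizes must be positive integers")
  rb1_widths <- as.integer(rb1_widths); rb2_widths <- as.integer(rb2_widths)
  if (length(rb1_widths) != 3L || length(rb2_widths) != 3L)
    stop_config("net_config: residual widths must be integer triples")
  if (rb1_widths[3L] != stem_channels)
    stop_config("net_config: rb1_widths[3] (%d) must equal stem_channels (%d) so the identity skip is addable",
                rb1_widths[3L], stem_channels)
  if (rb2_widths[3L] != c4_channels)
    stop_config("net_config: rb2_widths[3] (%d) must equal c4_channels (%d) so the identity skip is addable",
                rb2_widths[3L], c4_channels)
  structure(list(patch_size = as.integer(patch_size),
                 stem_channels = as.integer(stem_channels),
                 rb1_widths = rb1_widths, c4_channels = as.integer(c4_channels),
                 rb2_widths = rb2_widths, fc_width = as.integer(fc_width),
                 fusion_width = as.integer(fusion_width), variant = variant),
            class = "net_config")
}

#' Training configuration
#'
#' Defaults are the desk-scale settings used throughout the package's
#' synthetic experiments: batch 64, 10 epochs, and a decaying Adam schedule
#' (initial learning rate 2e-2 with per-iteration decay 0.05) sized for the
#' few hundred optimizer steps a desk run performs. The full-scale protocol
#' (learning rate 1e-4, decay 0.01, batch 2000, 100 epochs, 10% validation)
#' is available through the `"paper"` scale preset of [mvsir_config()].
#'
#' @param learning_rate Initial Adam learning rate.
#' @param weight_decay Decay coefficient. With `decay_mode = "lr"` (default)
#'   it is a per-iteration learning-rate decay, `lr_t = lr / (1 + wd * t)` —
#'   the convention of the Keras optimizers' `decay` argument; with `"l2"`
#'   it is an L2 penalty on convolution/dense weights.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param validation_fraction Fraction held out (stratified) for validation,
#'   in (0, 1).
#' @param decay_mode `"lr"` (default) or `"l2"`.
#' @param seed Integer seed for the split, the weight init and the shuffles.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-2, weight_decay = 0.05,
                         batch_size = 64L, epochs = 10L,
                         validation_fraction = 0.10,
                         decay_mode = c("lr", "l2"), seed = 1L) {
  decay_mode <- match.arg(decay_mode)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_config("train_config: learning_rate must be positive")
  if (!is.numeric(weight_decay) || weight_decay < 0)
    stop_config("train_config: weight_decay must be >= 0")
  if (!is_count(batch_size) || batch_size < 1)
    stop_config("train_config: batch_size must be a positive integer")
  if (!is_count(epochs) || epochs < 1)
    stop_config("train_config: epochs must be a positive integer")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_config("train_config: validation_fraction must be in (0, 1)")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 decay_mode = decay_mode, seed = as.integer(seed)),
            class = "train_config")
}

# weight shapes per parameter name, from the architecture
weight_shapes <- function(cfg) {
  stem <- cfg$stem_channels
  cmid <- if (cfg$variant == "MV-SIR") 2L * stem else stem
  h2 <- ((cfg$patch_size + 1L) %/% 2L + 1L) %/% 2L
  shp <- list()
  for (s in 1:6) {
    p <- sprintf("s%d_", s)
    shp[[paste0(p, "c1_w")]] <- c(9L, stem)
    shp[[paste0(p, "c1_b")]] <- c(stem, 1L)
    if (cfg$variant == "MV-CNN") {
      shp[[paste0(p, "pb1_w")]] <- c(9L * stem, stem)
      shp[[paste0(p, "pb1_b")]] <- c(stem, 1L)
      shp[[paste0(p, "pb2_w")]] <- c(9L * cfg$c4_channels, cfg$c4_channels)
      shp[[paste0(p, "pb2_b")]] <- c(cfg$c4_channels, 1L)
    } else {
      shp[[paste0(p, "rb1_w1")]] <- c(stem, cfg$rb1_widths[1])
      shp[[paste0(p, "rb1_b1")]] <- c(cfg$rb1_widths[1], 1L)
      shp[[paste0(p, "rb1_w2")]] <- c(9L * cfg$rb1_widths[1], cfg$rb1_widths[2])
      shp[[paste0(p, "rb1_b2")]] <- c(cfg$rb1_widths[2], 1L)
      shp[[paste0(p, "rb1_w3")]] <- c(cfg$rb1_widths[2], stem)
      shp[[paste0(p, "rb1_b3")]] <- c(stem, 1L)
      shp[[paste0(p, "rb2_w1")]] <- c(cfg$c4_channels, cfg$rb2_widths[1])
      shp[[paste0(p, "rb2_b1")]] <- c(cfg$rb2_widths[1], 1L)
      shp[[paste0(p, "rb2_w2")]] <- c(9L * cfg$rb2_widths[1], cfg$rb2_widths[2])
      shp[[paste0(p, "rb2_b2")]] <- c(cfg$rb2_widths[2], 1L)
      shp[[paste0(p, "rb2_w3")]] <- c(cfg$rb2_widths[2], cfg$c4_channels)
      shp[[paste0(p, "rb2_b3")]] <- c(cfg$c4_channels, 1L)
    }
    if (cfg$variant == "MV-SIR") {
      shp[[paste0(p, "ec1_w")]] <- c(9L, stem)
      shp[[paste0(p, "ec1_b")]] <- c(stem, 1L)
    }
    shp[[paste0(p, "c4_w")]] <- c(9L * cmid, cfg$c4_channels)
    shp[[paste0(p, "c4_b")]] <- c(cfg$c4_channels, 1L)
    shp[[paste0(p, "f7_w")]] <- c(h2 * h2 * cfg$c4_channels, cfg$fc_width)
    shp[[paste0(p, "f7_b")]] <- c(cfg$fc_width, 1L)
    shp[[paste0(p, "f8_w")]] <- c(cfg$fc_width, cfg$fc_width)
    shp[[paste0(p, "f8_b")]] <- c(cfg$fc_width, 1L)
  }
  shp[["fu_w"]] <- c(6L * cfg$fc_width, cfg$fusion_width)
  shp[["fu_b"]] <- c(cfg$fusion_width, 1L)
  shp[["out_w"]] <- c(cfg$fusion_width, 1L)
  shp[["out_b"]] <- c(1L, 1L)
  shp
}

# He-normal initialization (fan-in scaled); biases zero, output layer Xavier
init_weights <- function(cfg, seed) {
  shp <- weight_shapes(cfg)
  with_seed(seed, {
    lapply(stats::setNames(names(shp), names(shp)), function(k) {
      d <- shp[[k]]
      if (grepl("_b[0-9]*$", k)) {
        matrix(0, d[1], d[2])
      } else {
        sd <- if (k == "out_w") sqrt(1 / d[1]) else sqrt(2 / d[1])
        matrix(rnorm(prod(d), sd = sd), d[1], d[2])
      }
    })
  })
}

#' Count trainable parameters
#'
#' @param x A fitted [mvsir()] model, a weight list, or a [net_config()]
#'   (counted without instantiating weights).
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "mvsir")) x <- x$weights
  if (inherits(x, "net_config")) return(sum(vapply(weight_shapes(x), prod, numeric(1))))
  sum(vapply(x, length, numeric(1)))
}

#' Sigmoid activation
#'
#' `sigmoid(z) = 1 / (1 + exp(-z))`, the two-class output activation mapping
#' the fused logit to a nodule probability.
#'
#' @param z Numeric vector of logits.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' sigmoid(0)   # 0.5
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Binary cross-entropy loss
#'
#' `L = -(1/n) * sum(y * log(p) + (1 - y) * log(1 - p))` with predictions
#' clipped to `(eps, 1 - eps)`. Predictions outside `[0, 1]` before clipping
#' are an error.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @param eps Clipping constant (default 1e-7).
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' bce_loss(1, 0.5)   # log(2)
bce_loss <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) stop_config("bce_loss: length mismatch")
  if (any(p < 0 | p > 1)) stop_config("bce_loss: predictions outside [0, 1]")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Apply one identity residual block
#'
#' Main path 1 x 1 (valid, ReLU) -> 3 x 3 (same, ReLU) -> 1 x 1 (valid,
#' linear), identity shortcut added element-wise, then ReLU. Input and output
#' shapes are identical.
#'
#' @param x Numeric `H x W x C` array.
#' @param weights List with elements `w1` (`C x C1`), `b1`, `w2`
#'   (`9*C1 x C2`, 3 x 3 kernel rows ordered offset-major), `b2`, `w3`
#'   (`C2 x C`), `b3`.
#' @return Numeric `H x W x C` array.
#' @export
residual_block <- function(x, weights) {
  d <- dim(x)
  if (length(d) != 3L) stop_config("residual_block: x must be H x W x C")
  A <- t(matrix(x, d[1] * d[2], d[3]))
  out <- nn_residual_block(A, d[1], d[2],
                           as.matrix(weights$w1), as.numeric(weights$b1),
                           as.matrix(weights$w2), as.numeric(weights$b2),
                           as.matrix(weights$w3), as.numeric(weights$b3))
  array(t(out), d)
}

#' Stage shapes of the SIR submodel by forward introspection
#'
#' Runs one dummy patch through a submodel and records the actual shape of
#' every stage's feature map, `(H, W, C)` for convolution/pooling stages and
#' vector lengths for the dense stages.
#'
#' @param x A [net_config()] or a fitted [mvsir()] model.
#' @return Named list of integer shape vectors (stages `input, c1, p2,
#'   block1, secondary, concat, p3, c4, block2, p5, flatten, f7, f8,
#'   fusion_input, fusion, output`; `secondary` only for the MV-SIR variant).
#' @export
#' @examples
#' shapes <- sir_stage_shapes(net_config())
#' shapes$concat   # 15 15 64
sir_stage_shapes <- function(x) {
  if (inherits(x, "mvsir")) return(nn_stage_shapes(x$weights, unclass(x$net_config)))
  stopifnot(inherits(x, "net_config"))
  w <- init_weights(x, seed = 1L)
  nn_stage_shapes(w, unclass(x))
}

# stratified train/validation split
stratified_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    idx0 <- which(labels == 0L); idx1 <- which(labels == 1L)
    n_val0 <- floor(length(idx0) * fraction)
    n_val1 <- floor(length(idx1) * fraction)
    val <- c(if (n_val0 > 0) sample(idx0, n_val0),
             if (n_val1 > 0) sample(idx1, n_val1))
    list(train = setdiff(seq_along(labels), val), val = sort(val))
  })
}

#' Fit the MV-SIR multi-view voxel classifier
#'
#' Trains the six-branch network on aligned VH/SH patch streams with Adam and
#' binary cross-entropy. Each submodel receives its stream's patch as both
#' primary and secondary input; the six 256-wide embeddings are fused and
#' classified by a single sigmoid neuron. The training/validation split is
#' stratified by label; given the same streams, configurations and seed the
#' fit is reproducible (up to floating-point reassociation by the BLAS).
#'
#' @param streams A [build_patch_streams()] object.
#' @param net A [net_config()].
#' @param train A [train_config()].
#' @return An object of class `mvsir`: list with `weights`, `net_config`,
#'   `train_config`, `curve` (per-epoch loss/accuracy for training and
#'   validation), `n_train`, `n_val` and `fingerprint` (variant, stage
#'   shapes, parameter count, seed).
#' @seealso [predict.mvsir()], [predict_cube()], [sir_stage_shapes()]
#' @export
mvsir <- function(streams, net = net_config(), train = train_config()) {
  stopifnot(inherits(streams, "patch_streams"), inherits(net, "net_config"),
            inherits(train, "train_config"))
  n <- length(streams$labels)
  if (n == 0L) stop_config("mvsir: empty patch streams")
  if (length(unique(streams$labels)) < 2L)
    stop_config("mvsir: training set contains a single class")
  if (streams$size != net$patch_size)
    stop_config("mvsir: stream patch size %d != configured patch size %d",
                streams$size, net$patch_size)
  split <- stratified_split(streams$labels, train$validation_fraction,
                            derive_seed(train$seed, "split"))
  if (length(unique(streams$labels[split$train])) < 2L)
    stop_config("mvsir: training split contains a single class")
  weights <- init_weights(net, derive_seed(train$seed, "init"))
  mats <- lapply(stream_names(), function(nm) stream_matrix(streams, nm))
  fit <- nn_train(weights, unclass(net), mats, as.numeric(streams$labels),
                  as.integer(split$train - 1L), as.integer(split$val - 1L),
                  unclass(train), derive_seed(train$seed, "shuffle"))
  shapes <- nn_stage_shapes(fit$weights, unclass(net))
  obj <- structure(list(weights = fit$weights, net_config = net,
                        train_config = train, curve = fit$curve,
                        n_train = length(split$train), n_val = length(split$val),
                        fingerprint = list(variant = net$variant,
                                           patch_size = net$patch_size,
                                           stage_shapes = shapes,
                                           n_params = count_parameters(fit$weights),
                                           seed = train$seed)),
                   class = "mvsir")
  obj
}

#' @export
print.mvsir <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat(sprintf("%s voxel classifier: %s parameters, %d train / %d val patches\n",
              x$net_config$variant,
              format(x$fingerprint$n_params, big.mark = ","),
              x$n_train, x$n_val))
  cat(sprintf("final epoch %d: loss %.4f acc %.3f | val loss %.4f val acc %.3f\n",
              last$epoch, last$loss, last$acc, last$val_loss, last$val_acc))
  invisible(x)
}

#' @export
summary.mvsir <- function(object, ...) {
  print(object)
  cat("\nStage shapes (submodel):\n")
  shp <- object$fingerprint$stage_shapes
  for (nm in names(shp))
    cat(sprintf("  %-14s %s\n", nm, paste(shp[[nm]], collapse = " x ")))
  invisible(object)
}

#' @export
coef.mvsir <- function(object, ...) object$weights

#' Plot MV-SIR learning curves
#'
#' @param x A fitted [mvsir()] model.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.mvsir <- function(x, ...) {
  cv <- x$curve
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::matplot(cv$epoch, cbind(cv$loss, cv$val_loss), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch", ylab = "BCE loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(cv$epoch, cbind(cv$acc, cv$val_acc), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch", ylab = "accuracy", ...)
  invisible(x)
}

#' Predict nodule probabilities from a fitted model
#'
#' @param object A fitted [mvsir()] model.
#' @param newdata A [build_patch_streams()] object (per-patch probabilities)
#'   or a [nodule_cube()] (forwarded to [predict_cube()]).
#' @param type `"prob"` for probabilities, `"class"` for 0/1 at `threshold`.
#' @param threshold Classification threshold for `type = "class"`.
#' @param ... Passed to [predict_cube()] when `newdata` is a cube.
#' @return Numeric vector of probabilities (or 0/1 labels), or a
#'   `prediction_volume` for cube input.
#' @export
predict.mvsir <- function(object, newdata, type = c("prob", "class"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "nodule_cube")) return(predict_cube(object, newdata, ...))
  stopifnot(inherits(newdata, "patch_streams"))
  if (newdata$size != object$net_config$patch_size)
    stop_config("predict.mvsir: stream patch size %d != model patch size %d",
                newdata$size, object$net_config$patch_size)
  mats <- lapply(stream_names(), function(nm) stream_matrix(newdata, nm))
  p <- nn_predict(object$weights, unclass(object$net_config), mats)
  if (type == "class") as.integer(p >= threshold) else p
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is an RDS serialization of the fitted object plus a JSON
#' architecture fingerprint (variant, stage shapes, parameter count, seed)
#' written alongside for provenance.
#'
#' @param model A fitted [mvsir()] model.
#' @param path RDS path; the fingerprint is written to `<path>.json`.
#' @return `save_mvsir` returns `path` invisibly; `load_mvsir` the model.
#' @export
save_mvsir <- function(model, path) {
  stopifnot(inherits(model, "mvsir"))
  saveRDS(model, path)
  jsonlite::write_json(model$fingerprint, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mvsir
#' @export
load_mvsir <- function(path) readRDS(path)
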