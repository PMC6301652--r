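## Classifier layer: the one-dimensional reference convolution used as a
## unit-test oracle, the seven compact CNN presets, a VGG16-style
## architecture with the three fine-tuning handles (truncated head, frozen
## early blocks, reduced learning rate), seeded augmentation, training by
## mini-batch SGD with momentum, prediction, and hard-negative
## bootstrapping.  The numerical engine (im2col + GEMM, hand-rolled
## backprop) lives in src/cnn.cpp and is verified against numerical
## gradients in the tests.

#' Reference 1-D full convolution
#'
#' `y[k] = sum_n x[n] * h[k - n]` with `h` indexed from 0 and out-of-range
#' terms zero, producing `length(x) + length(h) - 1` outputs.  This direct
#' sum is the oracle against which the network's convolution layers are
#' unit-tested; it is deliberately independent of the C++ engine.
#'
#' @param x input sequence (non-empty numeric).
#' @param h filter coefficients (non-empty numeric).
#' @return numeric vector of length `length(x) + length(h) - 1`.
#' @export
convolve_reference <- function(x, h) {
  if (!length(x) || !length(h)) {
    stop("convolve_reference needs non-empty x and h", call. = FALSE)
  }
  n <- length(x); m <- length(h)
  y <- numeric(n + m - 1)
  for (k in seq_along(y)) {
    acc <- 0
    for (i in seq_len(n)) {
      j <- k - i + 1              # h index (1-based); h_{k-n} in 0-based terms
      if (j >= 1 && j <= m) acc <- acc + x[i] * h[j]
    }
    y[k] <- acc
  }
  y
}

## preset table for the seven compact structures:
## list(conv kernels, feature maps, pool kernels, fully connected widths)
## The printed head width is 3; build_structure() replaces it with
## `head_classes` (default 2: planthopper vs benign).
cnn_presets <- list(
  `1` = list(conv = c(3, 3),          maps = c(16, 16),
             pool = c(3, 3),          fc = c(128, 3)),
  `2` = list(conv = c(7, 3),          maps = c(16, 16),
             pool = c(2, 2),          fc = c(156, 4)),
  `3` = list(conv = c(9, 9),          maps = c(16, 16),
             pool = c(3, 3),          fc = c(128, 128, 3)),
  `4` = list(conv = c(7, 5),          maps = c(16, 16),
             pool = c(2, 2),          fc = c(256, 128, 3)),
  `5` = list(conv = c(7, 5, 3),       maps = c(24, 16, 16),
             pool = c(2, 2, 2),       fc = c(256, 128, 3)),
  `6` = list(conv = c(9, 7, 5, 3),    maps = c(32, 128, 128, 128),
             pool = c(3, 3, 3),       fc = c(2048, 2048, 3)),
  `7` = list(conv = c(11, 5, 3, 3, 3), maps = c(96, 256, 384, 384, 256),
             pool = c(3, 3, 3),       fc = c(4096, 4096, 3)))

#' Build one of the seven compact CNN presets
#'
#' Convolution layers use stride 1 with resolution-preserving padding and a
#' rectifier; each max-pooling layer uses the preset's pool kernel with
#' stride 2.  When there are fewer pools than convolutions (presets 6 and
#' 7), pooling follows each of the first `n_pool - 1` convolutions and the
#' final one.  The printed head width (3) is replaced by `head_classes`
#' (default 2); pass `head_classes = 3` to reproduce the printed table.
#'
#' @param structure_id integer 1-7.
#' @param input_size input patch side in pixels.
#' @param input_channels 1 (grayscale) or 3 (RGB).
#' @param head_classes output classes.
#' @return object of class `penyek_cnn_structure`.
#' @export
build_structure <- function(structure_id, input_size = 21,
                            input_channels = 1, head_classes = 2) {
  key <- as.character(structure_id)
  if (!key %in% names(cnn_presets)) {
    stop("unknown CNN structure id '", structure_id, "'; expected 1..7",
         call. = FALSE)
  }
  p <- cnn_presets[[key]]
  nc <- length(p$conv); np <- length(p$pool)
  pool_after <- rep(FALSE, nc)
  if (np >= nc) {
    pool_after[] <- TRUE
  } else {
    pool_after[seq_len(np - 1)] <- TRUE
    pool_after[nc] <- TRUE
  }
  fc <- p$fc
  fc[length(fc)] <- head_classes
  st <- structure(list(
    structure_id = as.integer(structure_id),
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    conv_kernel_sizes = p$conv,
    feature_maps = p$maps,
    pool_kernel_sizes = p$pool,
    pool_after = pool_after,
    fc_outputs = fc,
    head_classes = as.integer(head_classes),
    frozen_conv = 0L,
    activation = "relu",
    head = "softmax",
    n_layers = nc + np + length(fc)),
    class = "penyek_cnn_structure")
  structure_spatial_dims(st)  # validates that pooling fits the input
  st
}

#' Fine-tuning contract for the VGG16-style architecture
#'
#' The three adaptation strategies for a pretrained backbone: use a
#' smaller learning rate, truncate the 1000-class head to `head_classes`,
#' and freeze the first few convolutional blocks.
#'
#' @param base_lr learning rate used when fine-tuning (smaller than the
#'   from-scratch default).
#' @param head_classes classes in the replacement head (>= 2).
#' @param freeze_through_block freeze convolution blocks 1..k (0 = none,
#'   5 = all).
#' @param pretrained_source optional path to a saved weight file; when
#'   given it must be readable (never silently fall back to random
#'   initialization).
#' @return object of class `penyek_finetune_config`.
#' @export
fine_tune_config <- function(base_lr = 1e-5, head_classes = 2,
                             freeze_through_block = 0,
                             pretrained_source = NULL) {
  stopifnot(head_classes >= 2, freeze_through_block >= 0,
            freeze_through_block <= 5, base_lr > 0)
  structure(list(base_lr = base_lr, head_classes = as.integer(head_classes),
                 freeze_through_block = as.integer(freeze_through_block),
                 pretrained_source = pretrained_source),
            class = "penyek_finetune_config")
}

vgg16_block_widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                           c(512, 512, 512), c(512, 512, 512))

#' Build a VGG16-style structure
#'
#' Five blocks of 3x3 same-padding convolutions with widths
#' (64,64), (128,128), (256,256,256), (512,512,512), (512,512,512),
#' separated by 2x2 max pooling with stride 2, followed by three fully
#' connected layers and a softmax head truncated to
#' `ft$head_classes`.  Blocks up to `ft$freeze_through_block` are marked
#' non-trainable.  If `ft$pretrained_source` is set, the weights are loaded
#' from that file and the head re-initialized; an unreadable source is an
#' error.
#'
#' @param ft a [fine_tune_config()].
#' @param input_channels 1 or 3 (a single grayscale channel is fed through
#'   a 1-channel first layer when no RGB pretrained weights are involved).
#' @param input_size input side in pixels; must survive five halvings.
#' @param fc_widths widths of the two hidden fully connected layers
#'   (4096 in the full-size network; reducible for small inputs).
#' @return object of class `penyek_cnn_structure`.
#' @export
build_vgg16 <- function(ft = fine_tune_config(), input_channels = 1,
                        input_size = 224, fc_widths = c(4096, 4096)) {
  stopifnot(inherits(ft, "penyek_finetune_config"))
  widths <- unlist(vgg16_block_widths)
  nconv_per_block <- lengths(vgg16_block_widths)
  nc <- length(widths)
  pool_after <- rep(FALSE, nc)
  pool_after[cumsum(nconv_per_block)] <- TRUE
  frozen <- if (ft$freeze_through_block > 0) {
    sum(nconv_per_block[seq_len(ft$freeze_through_block)])
  } else 0L
  st <- structure(list(
    structure_id = "vgg16",
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    conv_kernel_sizes = rep(3, nc),
    feature_maps = widths,
    pool_kernel_sizes = rep(2, 5),
    pool_after = pool_after,
    fc_outputs = c(fc_widths, ft$head_classes),
    head_classes = ft$head_classes,
    frozen_conv = as.integer(frozen),
    activation = "relu",
    head = "softmax",
    n_layers = nc + 5 + length(fc_widths) + 1),
    class = "penyek_cnn_structure")
  structure_spatial_dims(st)
  if (!is.null(ft$pretrained_source)) {
    if (!file.exists(ft$pretrained_source)) {
      stop("pretrained weight source '", ft$pretrained_source,
           "' is not readable; refusing to fall back to random ",
           "initialization", call. = FALSE)
    }
    attr(st, "pretrained_source") <- ft$pretrained_source
  }
  st
}

#' Spatial sizes through a structure
#'
#' Tracks the square spatial side entering each convolution/pool stage and
#' the flattened size entering the first fully connected layer; errors if a
#' pooling kernel no longer fits.
#'
#' @param st a `penyek_cnn_structure`.
#' @return list with `sizes` (side after each conv block) and
#'   `spatial_before_fc` (side entering the fully connected stage).
#' @export
structure_spatial_dims <- function(st) {
  s <- st$input_size
  sizes <- integer(0)
  for (i in seq_along(st$conv_kernel_sizes)) {
    # same padding: conv preserves the side
    if (st$pool_after[i]) {
      k <- st$pool_kernel_sizes[min(sum(st$pool_after[1:i]),
                                    length(st$pool_kernel_sizes))]
      if (s < k) {
        stop("input size ", st$input_size, " is too small: pooling kernel ",
             k, " does not fit a ", s, "-pixel side at conv layer ", i,
             call. = FALSE)
      }
      s <- (s - k) %/% 2 + 1
    }
    sizes <- c(sizes, s)
  }
  list(sizes = sizes, spatial_before_fc = s)
}

## He-uniform initial weights, drawn from the caller's seeded RNG stream
init_layers <- function(st, seed) {
  with_seed(seed, {
    layers <- list()
    cin <- st$input_channels
    for (i in seq_along(st$conv_kernel_sizes)) {
      k <- st$conv_kernel_sizes[i]
      cout <- st$feature_maps[i]
      fan_in <- k * k * cin
      lim <- sqrt(6 / fan_in)
      W <- matrix(runif(fan_in * cout, -lim, lim), fan_in, cout)
      layers[[length(layers) + 1]] <-
        list(type = "conv", k = as.integer(k), W = W, b = numeric(cout),
             trainable = i > st$frozen_conv)
      if (st$pool_after[i]) {
        kp <- st$pool_kernel_sizes[min(sum(st$pool_after[1:i]),
                                       length(st$pool_kernel_sizes))]
        layers[[length(layers) + 1]] <- list(type = "pool",
                                             k = as.integer(kp))
      }
      cin <- cout
    }
    flat <- structure_spatial_dims(st)$spatial_before_fc^2 * cin
    din <- flat
    fcs <- st$fc_outputs
    for (j in seq_along(fcs)) {
      lim <- sqrt(6 / din)
      W <- matrix(runif(din * fcs[j], -lim, lim), din, fcs[j])
      layers[[length(layers) + 1]] <-
        list(type = "fc", W = W, b = numeric(fcs[j]),
             relu = j < length(fcs), trainable = TRUE)
      din <- fcs[j]
    }
    layers
  })
}

## augmentation ------------------------------------------------------------

#' Augmentation configuration
#'
#' @param rotations base rotation angles in degrees (one augmented copy per
#'   angle in rotation modes).
#' @param jitter_deg uniform jitter added to each base angle.
#' @param max_translation maximum shift per axis as a fraction of the patch
#'   side, in [0, 0.5].
#' @param mode which transformations to apply: `"both"`,
#'   `"rotation_only"`, `"translation_only"` or `"none"`.
#' @param seed RNG seed for angles/shifts.
#' @return object of class `penyek_augment_config`.
#' @export
augment_config <- function(rotations = c(90, 180, 270), jitter_deg = 15,
                           max_translation = 0.1,
                           mode = c("both", "rotation_only",
                                    "translation_only", "none"),
                           seed = 1) {
  mode <- match.arg(mode)
  stopifnot(max_translation >= 0, max_translation <= 0.5, jitter_deg >= 0)
  structure(list(rotations = rotations, jitter_deg = jitter_deg,
                 max_translation = max_translation, mode = mode,
                 seed = seed),
            class = "penyek_augment_config")
}

#' Augment a patch set
#'
#' Emits each input patch followed by one augmented copy per base rotation
#' angle (also in translation-only mode, for count parity across ablation
#' arms).  Rotation copies rotate by `angle + jitter`; translation copies
#' shift by up to `max_translation` of the side per axis, edge replicated;
#' `"both"` does both to each copy.  Labels are preserved and the output is
#' deterministic in (`patches`, `cfg`).
#'
#' @param patches list of patch objects.
#' @param cfg an [augment_config()].
#' @return list of patch objects (length `(1 + n_rotations) * n` unless
#'   `mode = "none"`, which returns the input unchanged).
#' @export
augment <- function(patches, cfg) {
  stopifnot(inherits(cfg, "penyek_augment_config"))
  if (cfg$mode == "none") return(patches)
  n_cop <- length(cfg$rotations)
  with_seed(cfg$seed, {
    out <- vector("list", length(patches) * (1 + n_cop))
    pos <- 1
    for (p in patches) {
      out[[pos]] <- p
      pos <- pos + 1
      side <- dim(p$pixels)[1]
      for (t in seq_len(n_cop)) {
        px <- p$pixels
        if (cfg$mode %in% c("both", "rotation_only")) {
          ang <- cfg$rotations[t] +
            if (cfg$jitter_deg > 0) runif(1, -cfg$jitter_deg,
                                          cfg$jitter_deg) else 0
          px <- rotate_image(px, ang)
        }
        if (cfg$mode %in% c("both", "translation_only")) {
          dr <- round(runif(1, -1, 1) * cfg$max_translation * side)
          dc <- round(runif(1, -1, 1) * cfg$max_translation * side)
          px <- translate_image(px, dr, dc)
        }
        q <- p
        q$pixels <- px
        q$source$augmented <- TRUE
        out[[pos]] <- q
        pos <- pos + 1
      }
    }
    out
  })
}

## training ----------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published hyperparameters: softmax head, mini-batch
#' of 30, initial learning rate 1e-4.  The optimizer is SGD with momentum
#' 0.9 and a constant learning rate; 30 epochs, no early stopping.
#'
#' @param batch_size mini-batch size (>= 1).
#' @param initial_lr learning rate.
#' @param epochs training epochs.
#' @param momentum SGD momentum coefficient.
#' @param seed RNG seed (weight init and shuffle order).
#' @param augment optional [augment_config()] applied to the training set.
#' @return object of class `penyek_train_config`.
#' @export
train_config <- function(batch_size = 30, initial_lr = 1e-4, epochs = 30,
                         momentum = 0.9, seed = 1, augment = NULL) {
  stopifnot(batch_size >= 1, initial_lr >= 0, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, epochs = as.integer(epochs),
                 momentum = momentum, seed = seed, augment = augment),
            class = "penyek_train_config")
}

## class level order: column 1 = benign, column 2 = BPH, so P(BPH) is the
## last column for the default two-class head
class_levels <- function(head_classes = 2) {
  if (head_classes == 2) c("benign", "BPH") else
    c("benign", "BPH", paste0("class", 3:head_classes))
}

patches_to_array <- function(patches, input_size, input_channels) {
  n <- length(patches)
  X <- array(0, c(input_size, input_size, input_channels, n))
  for (i in seq_len(n)) {
    px <- patches[[i]]$pixels
    side <- dim(px)[1]
    if (side != input_size) px <- bilinear_resize(px, input_size, input_size)
    if (input_channels == 1) {
      if (is_rgb_image(px)) px <- rgb_to_gray(px)
      X[, , 1, i] <- px
    } else {
      if (!is_rgb_image(px)) px <- array(rep(px, 3), c(dim(px), 3))
      X[, , , i] <- px
    }
  }
  X / 255
}

patch_labels <- function(patches, levels) {
  lab <- vapply(patches, `[[`, "", "label")
  bad <- setdiff(unique(lab), levels)
  if (length(bad)) {
    stop("unknown patch label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  match(lab, levels) - 1L   # 0-based class index for the engine
}

#' Train a CNN
#'
#' Minimizes softmax cross-entropy by mini-batch SGD with momentum.  The
#' run is deterministic given (`data`, `structure`, `tc`): weights are
#' He-uniform draws and shuffle orders are fixed by `tc$seed`.  Validation
#' loss is computed after each epoch when `val_patches` is given.
#'
#' @param train_patches list of labelled patches (both classes required).
#' @param structure a `penyek_cnn_structure`.
#' @param tc a [train_config()].
#' @param val_patches optional validation patches.
#' @param lr_override optional learning rate replacing `tc$initial_lr`
#'   (used by fine-tuning, which trains with a smaller rate).
#' @return object of class `penyek_train_result`: weights, loss history,
#'   validation loss history and a config echo.
#' @export
train_cnn <- function(train_patches, structure, tc = train_config(),
                      val_patches = NULL, lr_override = NULL) {
  stopifnot(inherits(structure, "penyek_cnn_structure"),
            inherits(tc, "penyek_train_config"))
  levels <- class_levels(structure$head_classes)
  if (!is.null(tc$augment)) train_patches <- augment(train_patches, tc$augment)
  y <- patch_labels(train_patches, levels)
  if (length(unique(y)) < 2) {
    stop("training set contains a single class; need both", call. = FALSE)
  }
  side <- dim(train_patches[[1]]$pixels)[1]
  if (side != structure$input_size) {
    # patches are resized on ingestion; a hard mismatch in channel count
    # would be a caller bug, so surface the expectation
    message("resizing ", side, "px patches to the structure input size ",
            structure$input_size)
  }
  X <- patches_to_array(train_patches, structure$input_size,
                        structure$input_channels)
  n <- length(train_patches)
  layers <- init_layers(structure, tc$seed)
  pre <- attr(structure, "pretrained_source")
  if (!is.null(pre)) {
    layers <- load_pretrained(layers, pre, structure)
  }
  has_val <- !is.null(val_patches) && length(val_patches) > 0
  if (has_val) {
    yval <- patch_labels(val_patches, levels)
    Xval <- patches_to_array(val_patches, structure$input_size,
                             structure$input_channels)
  } else {
    yval <- integer(0)
    Xval <- numeric(0)
  }
  order <- with_seed(tc$seed + 1,
                     if (tc$epochs > 0) {
                       vapply(seq_len(tc$epochs), function(e) sample(n),
                              integer(n))
                     } else {
                       matrix(integer(0), nrow = n, ncol = 0)
                     })
  if (!is.matrix(order)) order <- matrix(order, nrow = n)
  lr <- lr_override %||% tc$initial_lr
  fit <- cpp_cnn_train(as.numeric(X), dim(X), y, as.numeric(Xval), yval,
                       layers, structure$head_classes, tc$epochs,
                       tc$batch_size, lr, tc$momentum, order)
  structure(list(structure = structure, layers = fit$layers,
                 loss_history = fit$loss_history,
                 val_loss_history = fit$val_loss_history,
                 levels = levels, config = tc),
            class = "penyek_train_result")
}

#' Predict class probabilities for patches
#'
#' @param result a `penyek_train_result`.
#' @param patches list of patches matching the trained input size.
#' @return numeric matrix, one row per patch, columns named by class; rows
#'   sum to 1.
#' @export
predict_cnn <- function(result, patches) {
  stopifnot(inherits(result, "penyek_train_result"))
  st <- result$structure
  X <- patches_to_array(patches, st$input_size, st$input_channels)
  probs <- cpp_cnn_forward(as.numeric(X), dim(X), result$layers,
                           st$head_classes)
  colnames(probs) <- result$levels
  probs
}

#' Score P(BPH) for patches
#'
#' @inheritParams predict_cnn
#' @return numeric vector of planthopper probabilities.
#' @export
score_bph <- function(result, patches) {
  predict_cnn(result, patches)[, "BPH"]
}

#' Save / load network weights
#'
#' Weights go to an R-native RDS file accompanied by a JSON sidecar echoing
#' the structure and training configuration for provenance.
#'
#' @param result a `penyek_train_result`.
#' @param path output `.rds` path (sidecar written next to it).
#' @return `load_weights()` returns the `penyek_train_result`.
#' @export
save_weights <- function(result, path) {
  stopifnot(inherits(result, "penyek_train_result"))
  saveRDS(result, path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  st <- result$structure
  jsonlite::write_json(list(
    structure_id = st$structure_id,
    input_size = st$input_size,
    input_channels = st$input_channels,
    conv_kernel_sizes = st$conv_kernel_sizes,
    feature_maps = st$feature_maps,
    pool_kernel_sizes = st$pool_kernel_sizes,
    fc_outputs = st$fc_outputs,
    head_classes = st$head_classes,
    batch_size = result$config$batch_size,
    initial_lr = result$config$initial_lr,
    epochs = result$config$epochs,
    seed = result$config$seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  res <- readRDS(path)
  if (!inherits(res, "penyek_train_result")) {
    stop("'", path, "' does not contain saved network weights",
         call. = FALSE)
  }
  res
}

## load a saved backbone into freshly initialized layers, re-initializing
## the head (the final fully connected layer)
load_pretrained <- function(layers, path, structure) {
  src <- load_weights(path)
  sl <- src$layers
  if (length(sl) != length(layers)) {
    stop("pretrained weights have ", length(sl), " layers; structure needs ",
         length(layers), call. = FALSE)
  }
  for (i in seq_len(length(layers) - 1)) {
    if (!identical(dim(layers[[i]]$W), dim(sl[[i]]$W))) {
      stop("pretrained layer ", i, " shape mismatch", call. = FALSE)
    }
    layers[[i]]$W <- sl[[i]]$W
    layers[[i]]$b <- sl[[i]]$b
  }
  layers   # final layer (head) keeps its fresh initialization
}

#' Hard-negative bootstrapping
#'
#' Per round: score the candidate negatives with the current model, move
#' those with `P(BPH) >= threshold` into the training set as benign
#' examples (hard negatives) and retrain.  Rounds end early when no
#' candidate crosses the threshold.
#'
#' @param result a trained `penyek_train_result`.
#' @param candidate_negatives list of benign-labelled candidate patches.
#' @param train_patches the training set used to fit `result`.
#' @param threshold probability above which a candidate counts as hard.
#' @param rounds maximum bootstrapping rounds.
#' @param val_patches optional validation set for the retraining runs.
#' @return list with `train_patches` (augmented set), `result` (final
#'   model) and `added_per_round` (integer vector).
#' @export
bootstrap_hard_negatives <- function(result, candidate_negatives,
                                     train_patches, threshold = 0.5,
                                     rounds = 1, val_patches = NULL) {
  stopifnot(inherits(result, "penyek_train_result"), rounds >= 0)
  labs <- vapply(candidate_negatives, `[[`, "", "label")
  if (length(labs) && any(labs != "benign")) {
    stop("candidate negatives must all be labelled benign", call. = FALSE)
  }
  added <- integer(0)
  pool <- candidate_negatives
  for (r in seq_len(rounds)) {
    if (!length(pool)) { added <- c(added, 0L); break }
    sc <- score_bph(result, pool)
    hard <- which(sc >= threshold)
    added <- c(added, length(hard))
    if (!length(hard)) break
    train_patches <- c(train_patches, pool[hard])
    pool <- pool[-hard]
    result <- train_cnn(train_patches, result$structure, result$config,
                        val_patches = val_patches)
  }
  list(train_patches = train_patches, result = result,
       added_per_round = added)
}
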