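# Classifier layer: reference convolution, architecture presets, VGG16
# contract, augmentation, training dynamics, prediction and bootstrapping.

test_that("convolve_reference implements the defining sum", {
  expect_equal(convolve_reference(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(convolve_reference(c(1, 1, 1), c(1, 1)), c(1, 2, 2, 1))
  expect_equal(convolve_reference(c(3, -2, 5), c(0, 0, 0)), rep(0, 5))
  expect_error(convolve_reference(numeric(0), 1), "non-empty")
  # linearity in x
  set.seed(41)
  x1 <- runif(6); x2 <- runif(6); h <- runif(3)
  expect_equal(convolve_reference(x1 + 2 * x2, h),
               convolve_reference(x1, h) + 2 * convolve_reference(x2, h))
})

test_that("build_structure validates ids and emits normalized probabilities", {
  expect_error(build_structure(9), "unknown CNN structure")
  st <- build_structure(1, input_size = 21)
  expect_equal(st$conv_kernel_sizes, c(3, 3))
  expect_equal(st$fc_outputs, c(128, 2))          # head truncated to 2
  layers <- penyek:::init_layers(st, 7)
  X <- array(runif(21 * 21 * 2), c(21, 21, 1, 2))
  p <- penyek:::cpp_cnn_forward(as.numeric(X), dim(X), layers, 2L)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)
})

test_that("vgg16 construction honours the fine-tuning contract", {
  ft <- fine_tune_config(head_classes = 2, freeze_through_block = 3)
  st <- build_vgg16(ft, input_channels = 1, input_size = 32,
                    fc_widths = c(32, 16))
  expect_equal(length(st$conv_kernel_sizes), 13)
  expect_equal(st$frozen_conv, 7L)                # blocks 1-3: 2 + 2 + 3
  layers <- penyek:::init_layers(st, 1)
  frozen <- sum(vapply(layers, function(l)
    identical(l$type, "conv") && !l$trainable, TRUE))
  expect_equal(frozen, 7L)
  # 224 input halves five times to 7 before the fully connected stage
  st224 <- build_vgg16(fine_tune_config(), input_size = 224)
  expect_equal(structure_spatial_dims(st224)$spatial_before_fc, 7L)
  # head truncation: output length 2, sums to 1
  X <- array(runif(32 * 32), c(32, 32, 1, 1))
  p <- penyek:::cpp_cnn_forward(as.numeric(X), dim(X), layers, 2L)
  expect_length(p, 2)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(
    build_vgg16(fine_tune_config(pretrained_source = "/no/such/file.rds")),
    "not readable")
  expect_error(fine_tune_config(freeze_through_block = 6))
})

test_that("augment counts, preserves labels, and is deterministic; 90-degree rotations are exact", {
  patches <- make_separable_patches(5, size = 20, seed = 2)
  cfg_none <- augment_config(mode = "none")
  expect_identical(augment(patches, cfg_none), patches)
  cfg_rot <- augment_config(rotations = c(90, 180, 270), jitter_deg = 0,
                            mode = "rotation_only", seed = 3)
  out <- augment(patches, cfg_rot)
  expect_length(out, 40)
  expect_identical(vapply(out, `[[`, "", "label"),
                   rep(vapply(patches, `[[`, "", "label"), each = 4))
  expect_identical(augment(patches, cfg_rot), out)
  # rotation group closure on the raster op itself
  px <- patches[[1]]$pixels
  r4 <- rotate_image(rotate_image(rotate_image(rotate_image(px, 90), 90),
                                  90), 90)
  expect_identical(r4, px)
})

test_that("training is seeded-deterministic with sane degenerate behaviour", {
  patches <- make_separable_patches(15, size = 13, seed = 5)
  st <- build_structure(1, input_size = 13)
  tc <- train_config(batch_size = 10, initial_lr = 1e-3, epochs = 3,
                     seed = 4)
  f1 <- train_cnn(patches, st, tc)
  f2 <- train_cnn(patches, st, tc)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$layers, f2$layers)
  # epochs 0: untouched init, empty loss history
  f0 <- train_cnn(patches, st, train_config(epochs = 0, seed = 4))
  expect_length(f0$loss_history, 0)
  init <- penyek:::init_layers(st, 4)
  expect_equal(f0$layers[[1]]$W, init[[1]]$W)
  # lr 0: weights unchanged after training
  fz <- train_cnn(patches, st, train_config(epochs = 2, initial_lr = 0,
                                            seed = 4))
  expect_equal(fz$layers[[1]]$W, init[[1]]$W)
  expect_true(all(is.finite(unlist(fz$loss_history))))
  # single-class training set is rejected
  one_class <- patches[vapply(patches, `[[`, "", "label") == "BPH"]
  expect_error(train_cnn(one_class, st, tc), "single class")
})

test_that("a compact structure fits separable patches (training accuracy >= 0.95)", {
  patches <- make_separable_patches(100, size = 21, seed = 6)
  st <- build_structure(1, input_size = 21)
  fit <- train_cnn(patches, st,
                   train_config(batch_size = 30, initial_lr = 1e-3,
                                epochs = 20, seed = 1))
  probs <- predict_cnn(fit, patches)
  lab <- vapply(patches, `[[`, "", "label")
  acc <- mean(colnames(probs)[max.col(probs, ties.method = "first")] == lab)
  expect_gte(acc, 0.95)
  # validation loss is tracked per epoch when a validation set is given
  fit2 <- train_cnn(patches[1:150], st,
                    train_config(batch_size = 30, initial_lr = 1e-3,
                                 epochs = 3, seed = 1),
                    val_patches = patches[151:200])
  expect_length(fit2$val_loss_history, 3)
})

test_that("prediction is a batch-equivariant softmax and survives save/load", {
  patches <- make_separable_patches(10, size = 13, seed = 7)
  st <- build_structure(2, input_size = 13)
  fit <- train_cnn(patches, st, train_config(epochs = 2, seed = 2))
  p <- predict_cnn(fit, patches)
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  # permutation equivariance over the batch
  perm <- sample(20)
  expect_equal(predict_cnn(fit, patches[perm]), p[perm, ])
  # duplicated patch gives identical rows
  expect_equal(predict_cnn(fit, patches[c(1, 1)])[1, ],
               predict_cnn(fit, patches[c(1, 1)])[2, ])
  d <- withr::local_tempdir()
  save_weights(fit, file.path(d, "w.rds"))
  expect_true(file.exists(file.path(d, "w.json")))
  back <- load_weights(file.path(d, "w.rds"))
  expect_equal(predict_cnn(back, patches), p)
})

test_that("analytic gradients match numerical differentiation", {
  st <- build_structure(1, input_size = 13)
  layers <- penyek:::init_layers(st, 11)
  set.seed(11)
  X <- array(runif(13 * 13 * 3), c(13, 13, 1, 3))
  y <- c(0L, 1L, 0L)
  lg <- penyek:::cpp_cnn_loss_grad(as.numeric(X), dim(X), y, layers, 2L)
  eps <- 1e-5
  worst <- 0
  for (l in seq_along(layers)) {
    if (identical(layers[[l]]$type, "pool")) next
    for (ii in sample(length(layers[[l]]$W), 4)) {
      lp <- layers; lp[[l]]$W[ii] <- lp[[l]]$W[ii] + eps
      lm <- layers; lm[[l]]$W[ii] <- lm[[l]]$W[ii] - eps
      num <- (penyek:::cpp_cnn_loss_grad(as.numeric(X), dim(X), y, lp,
                                         2L)$loss -
                penyek:::cpp_cnn_loss_grad(as.numeric(X), dim(X), y, lm,
                                           2L)$loss) / (2 * eps)
      ana <- lg$grads[[l]]$W[ii]
      worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("hard-negative bootstrapping respects thresholds and round bounds", {
  patches <- make_separable_patches(20, size = 13, seed = 8)
  st <- build_structure(1, input_size = 13)
  tc <- train_config(batch_size = 10, initial_lr = 1e-3, epochs = 5,
                     seed = 3)
  fit <- train_cnn(patches, st, tc)
  # candidates: benign-looking patches with some hard cases (bright disks)
  cands <- make_separable_patches(10, size = 13, seed = 9)
  cands <- lapply(cands, function(p) { p$label <- "benign"; p })
  out0 <- bootstrap_hard_negatives(fit, cands, patches, threshold = 1.01,
                                   rounds = 1)
  expect_length(out0$train_patches, length(patches))
  expect_equal(out0$added_per_round, 0L)
  outr0 <- bootstrap_hard_negatives(fit, cands, patches, rounds = 0)
  expect_length(outr0$train_patches, length(patches))
  expect_length(outr0$added_per_round, 0)
  mixed <- c(cands, make_separable_patches(3, size = 13, seed = 10)[1:3])
  expect_error(bootstrap_hard_negatives(fit, mixed, patches),
               "labelled benign")
  # directional contract: after one bootstrap round, rescoring leaves no
  # more hard candidates than before (majority over 3 seeds)
  wins <- 0
  for (s in 1:3) {
    tc_s <- train_config(batch_size = 10, initial_lr = 1e-3, epochs = 5,
                         seed = s)
    fit_s <- train_cnn(patches, st, tc_s)
    before <- sum(score_bph(fit_s, cands) >= 0.5)
    bs <- bootstrap_hard_negatives(fit_s, cands, patches, threshold = 0.5,
                                   rounds = 1)
    still <- sum(score_bph(bs$result, cands) >= 0.5)
    if (still <= before) wins <- wins + 1
  }
  expect_gte(wins, 2)
})
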