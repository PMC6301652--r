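# Evaluation harness: fold plans, confusion counts, metric formulas, AUC
# and the experiment runner.

test_that("stratified folds are balanced, deterministic and validated", {
  lab <- rep(c("BPH", "benign"), each = 10)
  cv <- stratified_kfold(lab, 5, seed = 1)
  for (f in 1:5) {
    expect_equal(sum(cv$assignments == f & lab == "BPH"), 2)
    expect_equal(sum(cv$assignments == f & lab == "benign"), 2)
  }
  lab2 <- c(rep("BPH", 11), rep("benign", 10))
  cv2 <- stratified_kfold(lab2, 5, seed = 2)
  sizes <- sort(table(cv2$assignments[lab2 == "BPH"]), decreasing = TRUE)
  expect_equal(as.integer(sizes), c(3L, 2L, 2L, 2L, 2L))
  expect_identical(stratified_kfold(lab, 5, seed = 1)$assignments,
                   cv$assignments)
  expect_error(stratified_kfold(c("BPH", rep("benign", 9)), 5),
               "at least k")
})

test_that("confusion counts match constructed label vectors", {
  y <- rep(c("BPH", "benign"), each = 5)
  perfect <- confusion(y, y)
  expect_equal(c(perfect$fp, perfect$fn), c(0L, 0L))
  flipped <- confusion(ifelse(y == "BPH", "benign", "BPH"), y)
  expect_equal(c(flipped$tp, flipped$tn), c(0L, 0L))
  expect_error(confusion(y[1:3], y), "length")
})

test_that("metrics report undefined denominators as NA and AUC endpoints correctly", {
  all_pos <- confusion(rep("BPH", 5), rep("BPH", 5))
  m <- metrics(all_pos)
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 1)
  truth <- rep(c("BPH", "benign"), each = 10)
  sep <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  expect_equal(auc_rank(sep, truth), 1)
  expect_equal(auc_rank(rep(0.5, 20), truth), 0.5)
})

test_that("run_experiment harness bounds: oracle is perfect, a coin is near chance", {
  lab <- rep(c("BPH", "benign"), 500)
  stubs <- lapply(lab, function(l) {
    structure(list(pixels = NULL, label = l, size = 0,
                   source = list(image_id = "stub", index = NA)),
              class = "penyek_patch")
  })
  cv <- stratified_kfold(lab, 5, seed = 3)
  rep_o <- run_experiment(stubs, list(type = "oracle"), cv)
  expect_equal(rep_o$mean[["accuracy"]], 1)
  rep_c <- run_experiment(stubs, list(type = "coin", seed = 5), cv)
  expect_gte(rep_c$mean[["accuracy"]], 0.44)   # binomial 99% band, n = 1000
  expect_lte(rep_c$mean[["accuracy"]], 0.56)
  # end-to-end determinism of a full arm
  patches <- make_separable_patches(10, size = 13, seed = 4)
  lab2 <- vapply(patches, `[[`, "", "label")
  cv2 <- stratified_kfold(lab2, 4, seed = 1)
  arm <- list(type = "cnn", image_model = "F", structure_id = 1,
              input_size = 13,
              train = train_config(batch_size = 8, epochs = 2, seed = 9))
  r1 <- run_experiment(patches, arm, cv2)
  r2 <- run_experiment(patches, arm, cv2)
  expect_identical(r1$mean, r2$mean)
})

test_that("fold means and the report table agree", {
  patches <- make_separable_patches(8, size = 13, seed = 6)
  lab <- vapply(patches, `[[`, "", "label")
  cv <- stratified_kfold(lab, 4, seed = 2)
  rep <- run_experiment(patches, list(type = "oracle"), cv)
  manual <- mean(vapply(rep$per_fold, `[[`, 0, "accuracy"))
  expect_equal(rep$mean[["accuracy"]], manual, tolerance = 1e-12)
  df <- report_to_df(rep)
  expect_equal(nrow(df), 5)
  expect_equal(df$accuracy[5], rep$mean[["accuracy"]])
})
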