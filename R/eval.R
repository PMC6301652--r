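## Evaluation harness: stratified k-fold cross-validation, confusion-matrix
## metrics (accuracy, sensitivity, specificity, AUC by the rank statistic)
## and the experiment runner that wires patches through an image model into
## a CNN or baseline arm.  The planthopper ("BPH") class is positive
## throughout.

#' Stratified k-fold assignment
#'
#' Per-class seeded shuffle followed by round-robin assignment, so fold
#' class counts differ by at most one.
#'
#' @param labels character vector of class labels.
#' @param k folds (every class needs at least `k` members).
#' @param seed RNG seed.
#' @return object of class `penyek_cv_plan`: list with `k`, `assignments`
#'   (fold index per item) and `seed`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  labels <- as.character(labels)
  assignments <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has ", length(idx),
           " members; need at least k = ", k, call. = FALSE)
    }
    idx <- with_seed(seed + utf8ToInt(substr(cl, 1, 1)), sample(idx))
    assignments[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(k = as.integer(k), assignments = assignments, seed = seed),
            class = "penyek_cv_plan")
}

#' Confusion counts with BPH positive
#'
#' @param predicted,truth equal-length label vectors with values in
#'   `{"BPH", "benign"}`.
#' @param positive the positive class.
#' @return object of class `penyek_confusion`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(predicted, truth, positive = "BPH") {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length (", length(predicted),
         " vs ", length(truth), ")", call. = FALSE)
  }
  p <- predicted == positive
  t <- truth == positive
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "penyek_confusion")
}

#' Mann-Whitney AUC
#'
#' Rank-statistic area under the ROC curve over P(positive) scores, ties
#' counted one half.  Returns `NA` when either class is absent.
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth labels.
#' @param positive positive class.
#' @return AUC in [0, 1] or `NA`.
#' @export
auc_rank <- function(scores, truth, positive = "BPH") {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`; a metric with a zero denominator is reported as `NA`
#' (undefined), never as 0.  AUC is added when scores are supplied.
#'
#' @param counts a [confusion()] result.
#' @param scores optional P(BPH) scores for AUC.
#' @param truth labels matching `scores`.
#' @return object of class `penyek_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `auc` and the counts.
#' @export
metrics <- function(counts, scores = NULL, truth = NULL) {
  stopifnot(inherits(counts, "penyek_confusion"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  auc <- if (!is.null(scores)) auc_rank(scores, truth) else NA_real_
  structure(list(
    accuracy = div(counts$tp + counts$tn, total),
    sensitivity = div(counts$tp, counts$tp + counts$fn),
    specificity = div(counts$tn, counts$tn + counts$fp),
    auc = auc,
    counts = counts),
    class = "penyek_metrics")
}

#' @export
print.penyek_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | sensitivity %.4f | specificity %.4f | AUC %.4f\n",
    x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

## ------------------------------------------------------------------------

#' Prepare classifier inputs for an image model
#'
#' Runs each patch through the binarization chain and the requested image
#' model, returning patches whose pixels are the classifier-ready images
#' (grayscale for models A-F, RGB for model G).
#'
#' @param patches list of RGB patches.
#' @param image_model `"A"`..`"G"`.
#' @param chain named list of [binarize_chain()] parameters.
#' @return list of transformed patches.
#' @export
prepare_model_inputs <- function(patches, image_model = "F",
                                 chain = list()) {
  lapply(patches, function(p) {
    if (image_model == "G") {
      q <- p
      q$pixels <- patch_rgb(p)
      return(q)
    }
    gray <- patch_gray(p)
    mask <- do.call(binarize_chain, c(list(gray), chain))
    q <- p
    q$pixels <- apply_image_model(mask, NULL, image_model)
    q
  })
}

#' Run one cross-validated experiment arm
#'
#' Trains on `k - 1` folds and evaluates on the held-out fold, for every
#' fold of the plan; reports per-fold metrics and their mean (folds with
#' an undefined metric are excluded from that metric's mean, with a
#' warning).  Arms:
#' \describe{
#'   \item{cnn}{`list(type = "cnn", image_model, structure_id or "vgg16",
#'     train = train_config(), chain = list(), finetune =
#'     fine_tune_config())`}
#'   \item{baseline}{`list(type = "baseline", scheme, n_trees, seed)`}
#'   \item{oracle}{returns the true labels (harness upper bound)}
#'   \item{coin}{seeded fair coin (harness lower bound)}
#' }
#'
#' @param patches list of labelled patches.
#' @param arm arm descriptor (see above).
#' @param cv a [stratified_kfold()] plan for `patches`.
#' @param test_transform optional function applied to each held-out patch
#'   before scoring (used by the augmentation ablation, e.g. a random
#'   rotation).
#' @return object of class `penyek_report`: list with `per_fold` (list of
#'   `penyek_metrics`) and `mean` (named numeric vector).
#' @export
run_experiment <- function(patches, arm, cv, test_transform = NULL) {
  stopifnot(inherits(cv, "penyek_cv_plan"),
            length(cv$assignments) == length(patches))
  labels <- vapply(patches, `[[`, "", "label")
  prepared <- NULL
  if (identical(arm$type, "cnn")) {
    prepared <- prepare_model_inputs(patches, arm$image_model %||% "F",
                                     arm$chain %||% list())
  }
  feats_all <- if (identical(arm$type, "baseline")) {
    extract_features(patches, arm$scheme)
  }
  per_fold <- vector("list", cv$k)
  for (fold in seq_len(cv$k)) {
    hold <- which(cv$assignments == fold)
    keep <- which(cv$assignments != fold)
    truth <- labels[hold]
    if (identical(arm$type, "oracle")) {
      pred <- truth
      scores <- as.numeric(truth == "BPH")
    } else if (identical(arm$type, "coin")) {
      scores <- with_seed((arm$seed %||% 1) + fold,
                          runif(length(hold)))
      pred <- ifelse(scores >= 0.5, "BPH", "benign")
    } else if (identical(arm$type, "baseline")) {
      feats <- feats_all
      rf <- train_rf(feats[keep, , drop = FALSE], labels[keep],
                     n_trees = arm$n_trees %||% 200,
                     seed = (arm$seed %||% 1) + fold)
      cls <- classify_rf(rf, feats[hold, , drop = FALSE])
      pred <- cls$labels
      scores <- cls$scores[, "BPH"]
    } else if (identical(arm$type, "cnn")) {
      tc <- arm$train %||% train_config()
      tc$seed <- tc$seed + fold
      st <- if (identical(arm$structure_id, "vgg16")) {
        ft <- arm$finetune %||% fine_tune_config()
        build_vgg16(ft, input_channels = arm$input_channels %||% 1,
                    input_size = arm$input_size %||% 32,
                    fc_widths = arm$fc_widths %||% c(256, 128))
      } else {
        build_structure(arm$structure_id %||% 5,
                        input_size = arm$input_size %||%
                          dim(prepared[[1]]$pixels)[1],
                        input_channels = arm$input_channels %||%
                          if (identical(arm$image_model, "G")) 3 else 1)
      }
      lr_override <- if (identical(arm$structure_id, "vgg16") &&
                         !is.null(arm$finetune)) arm$finetune$base_lr
      fit <- train_cnn(prepared[keep], st, tc, lr_override = lr_override)
      test_patches <- prepared[hold]
      if (!is.null(test_transform)) {
        test_patches <- lapply(test_patches, test_transform)
      }
      probs <- predict_cnn(fit, test_patches)
      scores <- probs[, "BPH"]
      pred <- colnames(probs)[max.col(probs, ties.method = "first")]
    } else {
      stop("unknown experiment arm type '", arm$type, "'", call. = FALSE)
    }
    per_fold[[fold]] <- metrics(confusion(pred, truth), scores, truth)
  }
  mean_of <- function(field) {
    v <- vapply(per_fold, `[[`, 0, field)
    if (anyNA(v)) {
      warning("metric '", field, "' undefined in ", sum(is.na(v)),
              " fold(s); excluded from the mean", call. = FALSE)
    }
    mean(v, na.rm = TRUE)
  }
  structure(list(
    per_fold = per_fold,
    mean = c(accuracy = mean_of("accuracy"),
             sensitivity = mean_of("sensitivity"),
             specificity = mean_of("specificity"),
             auc = mean_of("auc"))),
    class = "penyek_report")
}

#' @export
print.penyek_report <- function(x, ...) {
  cat("cross-validated metrics (mean over", length(x$per_fold), "folds):\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Average test accuracy of several structures on one image model
#'
#' The structure-sweep aggregation mode: runs the compact presets listed in
#' `structure_ids` on one image model and averages the mean CV accuracy
#' across structures (one number per image model).
#'
#' @param patches labelled patches.
#' @param image_model `"A"`..`"G"`.
#' @param structure_ids compact preset ids to sweep.
#' @param cv a CV plan.
#' @param train a [train_config()].
#' @return list with `per_structure` (named accuracies) and `mean`.
#' @export
average_over_structures <- function(patches, image_model,
                                    structure_ids = 1:7, cv,
                                    train = train_config()) {
  accs <- vapply(structure_ids, function(sid) {
    rep <- run_experiment(patches,
                          list(type = "cnn", image_model = image_model,
                               structure_id = sid, train = train),
                          cv)
    rep$mean[["accuracy"]]
  }, 0)
  names(accs) <- paste0("structure_", structure_ids)
  list(per_structure = accs, mean = mean(accs))
}

#' Flatten a report to a data frame
#'
#' @param report a `penyek_report`.
#' @return data frame with one row per fold plus a mean row.
#' @export
report_to_df <- function(report) {
  rows <- lapply(seq_along(report$per_fold), function(i) {
    m <- report$per_fold[[i]]
    data.frame(fold = as.character(i), accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               auc = m$auc, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rbind(df, data.frame(fold = "mean", accuracy = report$mean[["accuracy"]],
                       sensitivity = report$mean[["sensitivity"]],
                       specificity = report$mean[["specificity"]],
                       auc = report$mean[["auc"]],
                       stringsAsFactors = FALSE))
}
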