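#' Assemble a raw-curve classification dataset
#'
#' Stacks the trials into an n-by-p matrix of raw force samples (no
#' manually extracted features) and attaches a binary label per trial:
#' age group (`older`/`younger`) or sex (`female`/`male`).  Rows are
#' ordered by subject id.  The positive class for scores and AUC is the
#' second factor level (`younger` and `male` respectively).  A message is
#' printed when the minority class falls below 35% of the sample, since
#' class imbalance depresses rank-based discrimination scores.
#'
#' @param trials List of [force_trial()] objects in newtons, all of equal
#'   length (ingestion imputes them to the expected sample count).
#' @param subjects Subject table providing the labels.
#' @param target `"age"` or `"sex"`.
#' @return A list of class `curve_dataset` with elements `x` (matrix),
#'   `y` (factor), `target`, `positive`, `subject_id`.
#' @export
build_dataset <- function(trials, subjects, target = c("age", "sex")) {
  target <- match.arg(target)
  if (length(trials) == 0L) {
    stop_toeforce("no trials supplied", "ml_dataset_error")
  }
  ids <- vapply(trials, function(t) t$subject_id, character(1))
  unknown <- setdiff(ids, subjects$subject_id)
  if (length(unknown)) {
    stop_toeforce(paste0("unlabeled subject(s): ", paste(unknown, collapse = ", ")),
                  "ml_dataset_error")
  }
  lens <- vapply(trials, function(t) length(t$force), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_toeforce("all trials must have the same number of samples", "ml_dataset_error")
  }
  units <- vapply(trials, function(t) t$unit, character(1))
  if (any(units != "N")) {
    stop_toeforce("trials must be in newtons; apply to_newtons() first",
                  "trial_unit_error")
  }
  ord <- order(ids)
  trials <- trials[ord]
  ids <- ids[ord]
  x <- do.call(rbind, lapply(trials, function(t) t$force))
  rownames(x) <- ids
  if (any(!is.finite(x))) {
    stop_toeforce("non-finite values in the curve matrix", "ml_dataset_error")
  }
  lab_col <- if (target == "age") "age_group" else "sex"
  levels_ <- if (target == "age") c("older", "younger") else c("female", "male")
  raw <- subjects[[lab_col]][match(ids, subjects$subject_id)]
  if (!all(raw %in% levels_)) {
    stop_toeforce(paste0("labels must be binary over {",
                         paste(levels_, collapse = ", "), "}"),
                  "ml_dataset_error")
  }
  y <- factor(raw, levels = levels_)
  if (nlevels(droplevels(y)) != 2L) {
    stop_toeforce("both classes must be present in the dataset", "ml_dataset_error")
  }
  minority <- min(table(y)) / length(y)
  if (minority < 0.35) {
    message(sprintf(
      "class imbalance: minority class is %.0f%% of the sample; rank-based scores (AUC) may be unstable",
      100 * minority))
  }
  structure(list(x = x, y = y, target = target, positive = levels_[2],
                 subject_id = ids),
            class = "curve_dataset")
}

#' Specify a classifier
#'
#' The three model families used for raw-curve classification on small
#' samples: k-nearest neighbours (Euclidean), a support vector machine,
#' and a random forest.
#'
#' @param model `"knn"`, `"svm"` or `"rf"`.
#' @param k Neighbour count for kNN (5 or 10 are the usual settings).
#' @param kernel SVM kernel (default `"radial"`).
#' @param n_trees Number of random-forest trees.
#' @return A list of class `toe_model_spec`.
#' @export
model_spec <- function(model = c("knn", "svm", "rf"), k = 5,
                       kernel = "radial", n_trees = 100) {
  model <- match.arg(model)
  stopifnot(k >= 1, n_trees >= 1)
  label <- switch(model,
                  knn = sprintf("knn(k=%d)", as.integer(k)),
                  svm = sprintf("svm(%s)", kernel),
                  rf = sprintf("rf(%d trees)", as.integer(n_trees)))
  structure(list(model = model, k = as.integer(k), kernel = kernel,
                 n_trees = as.integer(n_trees), label = label),
            class = "toe_model_spec")
}

# Column standardization fitted on training rows only; near-constant
# columns are left unscaled.
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

# Fit a model and score new rows.  Returns list(class = factor predictions,
# score = continuous score oriented toward the positive class).
fit_and_score <- function(spec, x_train, y_train, x_new, positive) {
  pos <- positive
  if (spec$model == "knn") {
    pred <- class::knn(x_train, x_new, y_train, k = spec$k, prob = TRUE)
    pwin <- attr(pred, "prob")   # vote fraction of the winning class
    score <- ifelse(pred == pos, pwin, 1 - pwin)
    list(class = pred, score = as.numeric(score))
  } else if (spec$model == "svm") {
    fit <- e1071::svm(x_train, y_train, kernel = spec$kernel, scale = FALSE)
    pred <- stats::predict(fit, x_new, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    score <- if (first == pos) dv[, 1] else -dv[, 1]
    list(class = pred, score = as.numeric(score))
  } else {
    fit <- randomForest::randomForest(x_train, y_train, ntree = spec$n_trees)
    prob <- stats::predict(fit, x_new, type = "prob")[, pos]
    list(class = stats::predict(fit, x_new, type = "response"),
         score = as.numeric(prob))
  }
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' Area under the ROC curve computed from ranks: the Mann-Whitney U
#' statistic of the positive-class scores divided by `n1 * n0`, with ties
#' resolved by midranks.  Equals the probability that a randomly chosen
#' positive outranks a randomly chosen negative (ties counting half).
#' 0.5 corresponds to random guessing.
#'
#' @param labels Binary labels: a 2-level factor, logical, or 0/1 vector.
#' @param scores Continuous scores, larger meaning more positive.
#' @param positive The label value treated as positive; defaults to the
#'   second factor level (or `TRUE`/`1`).
#' @return The AUC in \[0, 1\].
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
auc_score <- function(labels, scores, positive = NULL) {
  stopifnot(length(labels) == length(scores))
  if (is.factor(labels)) {
    if (is.null(positive)) positive <- levels(labels)[2]
    pos <- labels == positive
  } else if (is.logical(labels)) {
    pos <- labels
  } else {
    if (is.null(positive)) positive <- 1
    pos <- labels == positive
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_toeforce("AUC needs both classes present", "ml_score_error")
  }
  r <- rank(scores)    # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified assignment of indices into named partitions with given
# fractions; within each class the rounded per-class counts are used and
# the remainder goes to the last partition.
stratified_split <- function(y, fractions) {
  parts <- names(fractions)
  assign <- character(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    n <- length(idx)
    counts <- floor(fractions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    at <- 0
    for (p in seq_along(parts)) {
      take <- idx[seq_len(counts[p]) + at]
      assign[take] <- parts[p]
      at <- at + counts[p]
    }
  }
  assign
}

#' Evaluate a classifier under a single stratified split
#'
#' Splits the dataset into stratified train/validation/test parts, fits
#' the model on the training rows (with per-column standardization fitted
#' on the training data only, since kNN and SVMs are scale-sensitive),
#' and reports validation and test accuracy (%) plus the test AUC from
#' the model's continuous scores.  The whole evaluation is a pure
#' function of `(dataset, spec, split, seed)`.
#'
#' @param dataset A [build_dataset()] result.
#' @param spec A [model_spec()].
#' @param split Named fractions for `train`, `validation`, `test`
#'   (summing to 1).
#' @param seed Integer seed controlling the split and any model
#'   randomness.
#' @param standardize Standardize columns using training statistics.
#' @return A one-row `data.frame` of class `classifier_report`.
#' @export
evaluate_split <- function(dataset, spec,
                           split = c(train = 0.45, validation = 0.25, test = 0.30),
                           seed = 1, standardize = TRUE) {
  stopifnot(inherits(dataset, "curve_dataset"), inherits(spec, "toe_model_spec"))
  if (abs(sum(split) - 1) > 1e-8) {
    stop_toeforce("split fractions must sum to 1", "ml_config_error")
  }
  if (!all(c("train", "validation", "test") %in% names(split))) {
    stop_toeforce("split must name train, validation and test fractions",
                  "ml_config_error")
  }
  with_seed(seed, {
    part <- stratified_split(dataset$y, split)
    for (p in c("train", "validation", "test")) {
      yy <- dataset$y[part == p]
      if (nlevels(droplevels(yy)) != 2L) {
        stop_toeforce(sprintf(
          "the %s stratum is missing a class; try another seed or larger fractions", p),
          "ml_split_error")
      }
    }
    x <- dataset$x
    if (standardize) {
      scaler <- fit_scaler(x[part == "train", , drop = FALSE])
      x <- apply_scaler(x, scaler)
    }
    tr <- part == "train"
    sc_val <- fit_and_score(spec, x[tr, , drop = FALSE], dataset$y[tr],
                            x[part == "validation", , drop = FALSE],
                            dataset$positive)
    sc_test <- fit_and_score(spec, x[tr, , drop = FALSE], dataset$y[tr],
                             x[part == "test", , drop = FALSE],
                             dataset$positive)
    val_acc <- 100 * mean(sc_val$class == dataset$y[part == "validation"])
    test_acc <- 100 * mean(sc_test$class == dataset$y[part == "test"])
    auc <- auc_score(dataset$y[part == "test"], sc_test$score,
                     positive = dataset$positive)
    structure(data.frame(model = spec$label, target = dataset$target,
                         scheme = "split",
                         n_train = sum(tr),
                         n_validation = sum(part == "validation"),
                         n_test = sum(part == "test"),
                         validation_accuracy_pct = val_acc,
                         test_accuracy_pct = test_acc,
                         auc = auc, seed = seed),
              class = c("classifier_report", "data.frame"))
  })
}

#' Evaluate a classifier under stratified k-fold cross-validation
#'
#' Stratified k-fold cross-validation (k = 3 or 5): each fold retains
#' both classes, the model is refit on the remaining folds (with
#' training-only standardization), and held-out accuracies are reported
#' per fold together with a pooled AUC over all out-of-fold scores.
#'
#' @inheritParams evaluate_split
#' @param k_folds 3 or 5.
#' @return A one-row `data.frame` of class `classifier_report` with the
#'   per-fold accuracies in the attribute `"fold_accuracy_pct"`.
#' @export
evaluate_cv <- function(dataset, spec, k_folds = 5, seed = 1,
                        standardize = TRUE) {
  stopifnot(inherits(dataset, "curve_dataset"), inherits(spec, "toe_model_spec"))
  if (!k_folds %in% c(3, 5)) {
    stop_toeforce("k_folds must be 3 or 5", "ml_config_error")
  }
  if (min(table(dataset$y)) < k_folds) {
    stop_toeforce("too few samples in the minority class for stratified folds",
                  "ml_split_error")
  }
  with_seed(seed, {
    fold <- integer(length(dataset$y))
    for (lv in levels(dataset$y)) {
      idx <- sample(which(dataset$y == lv))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    scores <- numeric(length(dataset$y))
    preds <- factor(rep(levels(dataset$y)[1], length(dataset$y)),
                    levels = levels(dataset$y))
    fold_acc <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      x <- dataset$x
      if (standardize) {
        scaler <- fit_scaler(x[tr, , drop = FALSE])
        x <- apply_scaler(x, scaler)
      }
      sc <- fit_and_score(spec, x[tr, , drop = FALSE], dataset$y[tr],
                          x[!tr, , drop = FALSE], dataset$positive)
      scores[!tr] <- sc$score
      preds[!tr] <- sc$class
      fold_acc[f] <- 100 * mean(sc$class == dataset$y[!tr])
    }
    auc <- auc_score(dataset$y, scores, positive = dataset$positive)
    out <- structure(data.frame(model = spec$label, target = dataset$target,
                                scheme = sprintf("%d-fold cv", k_folds),
                                k_folds = k_folds,
                                mean_accuracy_pct = mean(fold_acc),
                                sd_accuracy_pct = stats::sd(fold_acc),
                                auc = auc, seed = seed),
                     class = c("classifier_report", "data.frame"))
    attr(out, "fold_accuracy_pct") <- fold_acc
    out
  })
}
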