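# Pair featureization, classifiers and evaluation metrics.

#' Fuse attribute and behavior vectors of a node
#'
#' Concatenates the 64-d attribute vector and the 64-d behavior vector into
#' the 128-d node representation, attribute first.
#'
#' @param attribute,behavior Numeric vectors of length 64.
#' @return Numeric vector of length 128.
#' @export
fuse <- function(attribute, behavior) {
  if (length(attribute) != 64 || length(behavior) != 64)
    stop("fuse() expects two vectors of length 64", call. = FALSE)
  c(attribute, behavior)
}

# Node feature matrix for the requested ablation mode.
node_feature_matrix <- function(attributes, behavior,
                                mode = c("both", "attribute", "behavior")) {
  mode <- match.arg(mode)
  switch(mode,
         attribute = attributes$values,
         behavior = behavior$values,
         both = {
           stopifnot(identical(rownames(attributes$values),
                               rownames(behavior$values)))
           cbind(attributes$values, behavior$values)
         })
}

#' Build labelled pair samples from positives and negatives
#'
#' Each pair is canonically oriented (node-kind precedence miRNA < lncRNA <
#' protein < drug < disease, ties broken by name) and featureized from the
#' two node representation vectors; the default operator is concatenation
#' (256 features for 128-d nodes), with element-wise `"hadamard"` and
#' `"average"` available for comparison.
#'
#' @param positives,negatives Edge data frames (either may be empty).
#' @param features Node-by-dimension representation matrix with node-key
#'   rownames (see [node_feature_matrix()]).
#' @param operator Pair feature operator.
#' @return List with `x` (feature matrix), `y` (0/1 labels) and `pairs`
#'   (the oriented pair table).
#' @export
make_pairs <- function(positives, negatives, features,
                       operator = c("concat", "hadamard", "average")) {
  operator <- match.arg(operator)
  pairs <- rbind(positives[c("name_a", "kind_a", "name_b", "kind_b")],
                 negatives[c("name_a", "kind_a", "name_b", "kind_b")])
  y <- c(rep(1L, nrow(positives)), rep(0L, nrow(negatives)))
  # canonical orientation by kind precedence, then name
  swap <- kind_rank(pairs$kind_b) < kind_rank(pairs$kind_a) |
    (kind_rank(pairs$kind_b) == kind_rank(pairs$kind_a) &
       pairs$name_b < pairs$name_a)
  if (any(swap)) {
    tn <- pairs$name_a[swap]; tk <- pairs$kind_a[swap]
    pairs$name_a[swap] <- pairs$name_b[swap]
    pairs$kind_a[swap] <- pairs$kind_b[swap]
    pairs$name_b[swap] <- tn; pairs$kind_b[swap] <- tk
  }
  ka <- node_key(pairs$kind_a, pairs$name_a)
  kb <- node_key(pairs$kind_b, pairs$name_b)
  miss <- setdiff(unique(c(ka, kb)), rownames(features))
  if (length(miss) > 0)
    stop("no representation for node(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  fa <- features[ka, , drop = FALSE]
  fb <- features[kb, , drop = FALSE]
  x <- switch(operator,
              concat = cbind(fa, fb),
              hadamard = fa * fb,
              average = (fa + fb) / 2)
  dimnames(x) <- list(NULL, paste0("f", seq_len(ncol(x))))
  list(x = x, y = y, pairs = pairs)
}

#' Train a pair classifier
#'
#' Fits one of five classifiers on pair features with default
#' hyperparameters of the host implementation: `"random_forest"`
#' ([ranger::ranger], probability forest), `"adaboost"` (SAMME boosting of
#' depth-1 rpart stumps, implemented here), `"logistic"` ([stats::glm]),
#' `"naive_bayes"` ([e1071::naiveBayes], Gaussian) or `"xgboost"`
#' ([xgboost::xgboost]).
#'
#' @param x Feature matrix.
#' @param y 0/1 labels (both classes must be present).
#' @param kind Classifier kind; random forest is the pipeline default.
#' @param seed Integer seed.
#' @return An object of class `man_classifier` with a
#'   [predict_scores()] method returning `P(label = 1)`.
#' @export
train_classifier <- function(x, y,
                             kind = c("random_forest", "adaboost",
                                      "logistic", "naive_bayes", "xgboost"),
                             seed = 1) {
  kind <- match.arg(kind)
  y <- as.integer(y)
  if (nrow(x) < 2 || length(unique(y)) < 2)
    stop("need at least two samples with both labels present", call. = FALSE)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- with_seed(seed, switch(
    kind,
    random_forest = {
      df <- as.data.frame(x); df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     num.threads = 1, seed = seed)
    },
    adaboost = adaboost_fit(x, y),
    logistic = {
      df <- as.data.frame(x); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    naive_bayes = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = 100, verbose = 0)
  ))
  structure(list(kind = kind, fit = fit, p = ncol(x), seed = seed),
            class = "man_classifier")
}

#' Score pairs with a trained classifier
#'
#' @param object A `man_classifier`.
#' @param x Feature matrix with the training column count.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_scores <- function(object, x) {
  stopifnot(inherits(object, "man_classifier"), ncol(x) == object$p)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  s <- switch(object$kind,
    random_forest = predict(object$fit, data = as.data.frame(x),
                            num.threads = 1)$predictions[, "1"],
    adaboost = adaboost_score(object$fit, x),
    logistic = as.numeric(predict(object$fit, as.data.frame(x),
                                  type = "response")),
    naive_bayes = predict(object$fit, x, type = "raw")[, "1"],
    xgboost = as.numeric(predict(object$fit,
                                 xgboost::xgb.DMatrix(x, nthread = 1))))
  pmin(pmax(s, 0), 1)
}

#' @export
print.man_classifier <- function(x, ...) {
  cat("Pair classifier:", x$kind, "on", x$p, "features\n")
  invisible(x)
}

# --- discrete AdaBoost (SAMME) over decision stumps -------------------------

adaboost_fit <- function(x, y, n_rounds = 50, maxdepth = 1) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  alpha <- numeric(n_rounds)
  used <- 0L
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2,
                          xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    used <- r
    a <- 0.5 * log((1 - err) / max(err, 1e-10))
    stumps[[r]] <- fit
    alpha[r] <- a
    w <- w * exp(a * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err < 1e-10) break
  }
  if (used == 0L) { # weak learner no better than chance: constant model
    stumps[[1]] <- NULL
    alpha <- numeric(0)
    stumps <- list()
  } else {
    stumps <- stumps[seq_len(used)]
    alpha <- alpha[seq_len(used)]
  }
  list(stumps = stumps, alpha = alpha, base_rate = mean(y))
}

adaboost_score <- function(model, x) {
  if (length(model$stumps) == 0)
    return(rep(model$base_rate, nrow(x)))
  df <- as.data.frame(x)
  margin <- rep(0, nrow(x))
  for (r in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[r]], df,
                                            type = "class")))
    margin <- margin + model$alpha[r] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * margin))
}

# --- metrics ----------------------------------------------------------------

#' Threshold and ranking metrics for scored pairs
#'
#' From the confusion matrix at `threshold`: accuracy, sensitivity
#' (TP / (TP + FN)), specificity (TN / (TN + FP)), precision
#' (TP / (TP + FP)) and the Matthews correlation coefficient.  From the
#' full score ranking: AUC by trapezoidal integration of the ROC curve and
#' AUPR by trapezoidal integration of the precision-recall curve (ties
#' handled by grouping equal scores into one operating point).
#'
#' @param scores Numeric scores, higher meaning more likely associated.
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold Classification threshold (default 0.5).
#' @return Named numeric vector with elements `acc`, `sen`, `spec`,
#'   `prec`, `mcc`, `auc`, `aupr`.
#' @examples
#' evaluate_scores(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  pos <- sum(labels == 1); neg <- sum(labels == 0)

  tp <- sum(scores >= threshold & labels == 1)
  fp <- sum(scores >= threshold & labels == 0)
  fn <- pos - tp; tn <- neg - fp
  acc <- (tp + tn) / (pos + neg)
  sen <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den

  curves <- roc_pr_points(scores, labels)
  auc <- trapezoid(curves$fpr, curves$tpr)
  aupr <- trapezoid(curves$recall, curves$precision)

  c(acc = acc, sen = sen, spec = spec, prec = prec, mcc = mcc,
    auc = auc, aupr = aupr)
}

# Operating points at every distinct score (descending), with the
# degenerate "predict nothing" point prepended.
roc_pr_points <- function(scores, labels) {
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l == 1)
  cum_fp <- cumsum(l == 0)
  last <- which(!duplicated(s, fromLast = TRUE)) # last index of each tie group
  tp <- cum_tp[last]; fp <- cum_fp[last]
  tpr <- c(0, tp / pos)
  fpr <- c(0, fp / neg)
  precision <- tp / (tp + fp)
  # anchor the PR curve at recall 0 with the precision of the top group
  precision <- c(precision[1], precision)
  recall <- c(0, tp / pos)
  list(fpr = fpr, tpr = tpr, recall = recall, precision = precision,
       thresholds = c(Inf, s[last]))
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}
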