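# Leak-safe k-fold cross-validation of the full pipeline, the
# attribute/behavior ablation, and the whole-network fitted model.

#' Cross-validate association prediction on a network
#'
#' Runs k-fold cross-validation with the leak-safe protocol: attribute
#' vectors are computed once from molecule-intrinsic data (they contain no
#' associations), while behavior vectors are re-trained inside every fold
#' on edges that exclude the fold's test positives.  The classifier is
#' trained on the training positives plus an equal number of sampled
#' negatives (drawn outside *all* known edges and outside the fold's test
#' negatives) and scored on the held-out positives and negatives.
#'
#' `embed_scope` controls which edges the per-fold embedding sees:
#' `"all_edges"` embeds every training edge; `"exclude_target_type"`
#' (which requires `target_kind`) embeds only the eight other association
#' types, dropping the target type entirely.  With `target_kind` set, the
#' folds partition the edges of that type only and the remaining types
#' stay in every training set.
#'
#' @param net A `man_network`.
#' @param attributes A `man_attributes` for `net` (see
#'   [encode_attributes()]); may be `NULL` for `feature_mode = "behavior"`.
#' @param k Number of folds (default 5).
#' @param feature_mode `"both"` (default), `"attribute"` or `"behavior"`.
#' @param embed_scope `"all_edges"` (default) or `"exclude_target_type"`.
#' @param target_kind Optional association type defining the prediction
#'   task (see above).
#' @param classifier Classifier kind, see [train_classifier()].
#' @param dim Behavior dimension (default 64).
#' @param samples_per_edge,negatives,rho0 LINE controls, see [train_line()].
#' @param operator Pair feature operator, see [make_pairs()].
#' @param threshold Classification threshold for the confusion metrics.
#' @param stratified_negatives Stratify negative draws by association type.
#' @param seed Top-level seed; all per-fold seeds are derived from it.
#' @return An object of class `man_cv`: per-fold metric table (`folds`),
#'   `mean` and `sd` over folds, per-fold ROC/PR `curves`, and the
#'   configuration.
#' @export
cross_validate <- function(net, attributes = NULL, k = 5,
                           feature_mode = c("both", "attribute", "behavior"),
                           embed_scope = c("all_edges", "exclude_target_type"),
                           target_kind = NULL,
                           classifier = "random_forest", dim = 64,
                           samples_per_edge = 100, negatives = 5,
                           rho0 = 0.025,
                           operator = "concat", threshold = 0.5,
                           stratified_negatives = FALSE, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  embed_scope <- match.arg(embed_scope)
  if (embed_scope == "exclude_target_type" && is.null(target_kind))
    stop("embed_scope = 'exclude_target_type' requires target_kind",
         call. = FALSE)
  if (feature_mode != "behavior" && is.null(attributes))
    stop("feature_mode '", feature_mode, "' needs attribute vectors",
         call. = FALSE)

  folds <- kfold_split(net, k = k, seed = seed, edge_kind = target_kind,
                       stratified = stratified_negatives)
  metric_names <- c("acc", "sen", "spec", "prec", "mcc", "auc", "aupr")
  fold_metrics <- matrix(NA_real_, k, length(metric_names),
                         dimnames = list(NULL, metric_names))
  curves <- vector("list", k)

  for (f in seq_len(k)) {
    fold <- folds[[f]]
    embed_edges <- fold$train_edges
    if (embed_scope == "exclude_target_type")
      embed_edges <- embed_edges[embed_edges$edge_kind != target_kind, ,
                                 drop = FALSE]
    # runtime leak assertion: no held-out association may reach the embedding
    if (length(intersect(edge_key(embed_edges),
                         edge_key(fold$test_positives))) > 0)
      stop("internal error: test positives leaked into the embedding input",
           call. = FALSE)

    behavior <- if (feature_mode == "attribute") NULL else {
      state <- train_line(embed_edges, dim = dim, negatives = negatives,
                          samples_per_edge = samples_per_edge, rho0 = rho0,
                          seed = derive_seed(seed, 10 + f))
      suppressMessages(behavior_vectors(state, net))
    }
    features <- if (feature_mode == "attribute") attributes$values
                else node_feature_matrix(attributes, behavior, feature_mode)

    train_pos <- if (is.null(target_kind)) fold$train_edges
                 else fold$train_edges[fold$train_edges$edge_kind ==
                                         target_kind, , drop = FALSE]
    train_neg <- sample_negatives(net, nrow(train_pos),
                                  seed = derive_seed(seed, 100 + f),
                                  stratified = stratified_negatives,
                                  kinds = target_kind,
                                  exclude = fold$test_negatives)
    stopifnot(nrow(train_neg) == nrow(train_pos)) # balanced training set
    train <- make_pairs(train_pos, train_neg, features, operator = operator)
    model <- train_classifier(train$x, train$y, kind = classifier,
                              seed = derive_seed(seed, 200 + f))
    test <- make_pairs(fold$test_positives, fold$test_negatives, features,
                       operator = operator)
    scores <- predict_scores(model, test$x)
    fold_metrics[f, ] <- evaluate_scores(scores, test$y, threshold)
    curves[[f]] <- roc_pr_points(scores, test$y)
  }

  fold_df <- data.frame(fold = seq_len(k), fold_metrics)
  structure(list(folds = fold_df,
                 mean = colMeans(fold_metrics),
                 sd = apply(fold_metrics, 2, sd),
                 curves = curves,
                 config = list(k = k, feature_mode = feature_mode,
                               embed_scope = embed_scope,
                               target_kind = target_kind,
                               classifier = classifier, dim = dim,
                               samples_per_edge = samples_per_edge,
                               operator = operator, threshold = threshold,
                               seed = seed)),
            class = "man_cv")
}

#' @export
print.man_cv <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat(sprintf("%d-fold cross-validation (%s features, %s classifier%s)\n",
              cfg$k, cfg$feature_mode, cfg$classifier,
              if (is.null(cfg$target_kind)) ""
              else paste0(", target ", cfg$target_kind)))
  tab <- rbind(x$folds[-1], mean = x$mean, sd = x$sd)
  rownames(tab) <- c(paste("fold", x$folds$fold), "mean", "sd")
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.man_cv <- function(object, ...) {
  data.frame(metric = names(object$mean), mean = object$mean,
             sd = object$sd, row.names = NULL)
}

#' Plot per-fold ROC (and optionally PR) curves of a cross-validation run
#'
#' @param x A `man_cv`.
#' @param which `"roc"` (default) or `"pr"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.man_cv <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                   xlab = "False positive rate",
                   ylab = "True positive rate",
                   main = sprintf("ROC, mean AUC = %.4f", x$mean[["auc"]]),
                   ...)
    for (cv in x$curves) graphics::lines(cv$fpr, cv$tpr)
  } else {
    graphics::plot(NULL, xlim = 0:1, ylim = 0:1, xlab = "Recall",
                   ylab = "Precision",
                   main = sprintf("PR, mean AUPR = %.4f", x$mean[["aupr"]]),
                   ...)
    for (cv in x$curves) graphics::lines(cv$recall, cv$precision)
  }
  invisible(x)
}

#' Fit the full association-prediction pipeline on a network
#'
#' Trains the behavior embedding on *all* network edges, fuses it with the
#' supplied attribute vectors, and fits the classifier on all known
#' associations (positives) plus an equal number of sampled non-edges.
#' The result predicts scores for arbitrary admissible node pairs.
#'
#' @inheritParams cross_validate
#' @return An object of class `man_model` with a [predict()] method.
#' @seealso [predict_pairs()]
#' @export
man_fit <- function(net, attributes = NULL,
                    feature_mode = c("both", "attribute", "behavior"),
                    classifier = "random_forest", dim = 64,
                    samples_per_edge = 100, negatives = 5, rho0 = 0.025,
                    operator = "concat", stratified_negatives = FALSE,
                    seed = 1) {
  feature_mode <- match.arg(feature_mode)
  if (feature_mode != "behavior" && is.null(attributes))
    stop("feature_mode '", feature_mode, "' needs attribute vectors",
         call. = FALSE)
  behavior <- if (feature_mode == "attribute") NULL else {
    state <- train_line(net$edges, dim = dim, negatives = negatives,
                        samples_per_edge = samples_per_edge, rho0 = rho0,
                        seed = derive_seed(seed, 1))
    suppressMessages(behavior_vectors(state, net))
  }
  features <- if (feature_mode == "attribute") attributes$values
              else node_feature_matrix(attributes, behavior, feature_mode)
  train_neg <- sample_negatives(net, nrow(net$edges),
                                seed = derive_seed(seed, 2),
                                stratified = stratified_negatives)
  train <- make_pairs(net$edges, train_neg, features, operator = operator)
  model <- train_classifier(train$x, train$y, kind = classifier,
                            seed = derive_seed(seed, 3))
  structure(list(features = features, classifier = model,
                 operator = operator,
                 config = list(feature_mode = feature_mode,
                               classifier = model$kind, dim = dim,
                               seed = seed)),
            class = "man_model")
}

#' @export
print.man_model <- function(x, ...) {
  cat("Fitted association-prediction pipeline\n")
  cat("  features:", x$config$feature_mode, "(", ncol(x$features),
      "dims per node ),", x$config$classifier, "classifier\n")
  cat("  nodes represented:", nrow(x$features), "\n")
  invisible(x)
}

#' Score candidate node pairs with a fitted pipeline
#'
#' @param model A `man_model`.
#' @param pairs Data frame with columns `name_a`, `kind_a`, `name_b`,
#'   `kind_b` (any orientation).
#' @param top_n Optional truncation of the ranked output.
#' @return The pair table with a `score` column, sorted by decreasing
#'   score.
#' @export
predict_pairs <- function(model, pairs, top_n = NULL) {
  stopifnot(inherits(model, "man_model"))
  pairs <- data.frame(name_a = normalize_name(pairs$name_a),
                      kind_a = normalize_kind(pairs$kind_a),
                      name_b = normalize_name(pairs$name_b),
                      kind_b = normalize_kind(pairs$kind_b),
                      stringsAsFactors = FALSE)
  made <- make_pairs(pairs, pairs[0, ], model$features,
                     operator = model$operator)
  out <- pairs
  out$score <- predict_scores(model$classifier, made$x)
  out <- out[order(out$score, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' @export
predict.man_model <- function(object, newdata, top_n = NULL, ...) {
  predict_pairs(object, newdata, top_n = top_n)
}
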