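#' Fit a reference-anchored ancestry classifier on PC scores
#'
#' Trains a probabilistic classifier on the top-k principal-component
#' scores of labeled reference samples (default k = 6). The default engine
#' is a probability random forest; a multinomial logistic engine is
#' available behind the same contract (per-class probabilities summing to
#' 1). Query samples must be projected into the same PC space (see
#' [project_samples()]) before classification.
#'
#' @param reference_scores samples x PCs numeric matrix.
#' @param labels ancestry label per reference sample (>= 2 classes, each
#'   with >= 5 samples).
#' @param k number of leading PCs to use.
#' @param seed integer seed.
#' @param engine `"forest"` (randomized-tree ensemble) or `"multinomial"`.
#' @param num_trees forest size.
#' @return an object of class `ancestry_classifier`.
#' @export
fit_reference_classifier <- function(reference_scores, labels, k = 6,
                                     seed = 1,
                                     engine = c("forest", "multinomial"),
                                     num_trees = 500) {
  engine <- match.arg(engine)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 ancestry labels")
  if (any(table(labels) < 5)) stop("each label needs >= 5 reference samples")
  if (k > ncol(reference_scores))
    stop("k exceeds the available number of PCs")
  X <- as.data.frame(reference_scores[, seq_len(k), drop = FALSE])
  names(X) <- paste0("PC", seq_len(k))
  model <- if (engine == "forest") {
    ranger::ranger(x = X, y = labels, probability = TRUE,
                   num.trees = num_trees, seed = seed,
                   num.threads = 1)
  } else {
    with_seed(seed, nnet::multinom(lab ~ ., data = cbind(lab = labels, X),
                                   trace = FALSE))
  }
  structure(list(model = model, engine = engine, k = k,
                 classes = levels(labels)),
            class = "ancestry_classifier")
}

#' Assign ancestry labels to query samples
#'
#' Predicts per-class membership probabilities for each query sample and
#' assigns the argmax label when its probability exceeds `min_prob`
#' (default 0.5, the >50% rule; stricter thresholds such as 0.9 are
#' supported); otherwise the sample is reported `unassigned`. Setting
#' `min_prob = 0` disables thresholding, as used for second-stage
#' within-continent assignment.
#'
#' @param classifier an `ancestry_classifier`.
#' @param query_scores samples x PCs matrix in the classifier's PC space.
#' @param min_prob assignment probability threshold.
#' @return data.frame with one `P_<label>` column per class, the winning
#'   probability `P_MAX`, and `ASSIGNED` (label or "unassigned").
#' @export
assign_ancestry <- function(classifier, query_scores, min_prob = 0.5) {
  stopifnot(inherits(classifier, "ancestry_classifier"))
  if (ncol(query_scores) < classifier$k)
    stop("query scores have fewer PCs than the classifier uses")
  X <- as.data.frame(query_scores[, seq_len(classifier$k), drop = FALSE])
  names(X) <- paste0("PC", seq_len(classifier$k))
  probs <- if (classifier$engine == "forest") {
    predict(classifier$model, data = X, num.threads = 1)$predictions
  } else {
    p <- predict(classifier$model, newdata = X, type = "probs")
    if (is.null(dim(p))) p <- cbind(1 - p, p,
                                    deparse.level = 0)  # 2-class case
    colnames(p) <- classifier$classes
    p
  }
  probs <- probs[, classifier$classes, drop = FALSE]
  win <- max.col(probs, ties.method = "first")
  p_max <- probs[cbind(seq_len(nrow(probs)), win)]
  assigned <- ifelse(p_max > min_prob, classifier$classes[win],
                     "unassigned")
  out <- as.data.frame(probs)
  names(out) <- paste0("P_", classifier$classes)
  out$P_MAX <- p_max
  out$ASSIGNED <- assigned
  rownames(out) <- rownames(query_scores)
  out
}
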