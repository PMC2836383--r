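# Sample encoding and LOOCV instance-based classification. The scorer is a
# Gaussian-kernel distance-weighted nearest-neighbour model in the KStar
# family of instance-based learners: class evidence for a held-out sample is
# the class-size-normalized sum of exp(-(d/h)^2) kernel weights over training
# samples, with bandwidth h the median pairwise training distance.

#' Encode samples by pathway activities and/or gene expression
#'
#' Assembles a samples x features matrix whose columns are pathway activity
#' levels (L values) and/or single-gene expression rows, in the requested
#' order. This is how a patient is represented by, e.g., the activity levels
#' of the top 10 perturbed pathways, optionally mixed with individual gene
#' profiles for integrated biomarker models.
#'
#' @param activity an `activity_matrix` (may be `NULL` if only genes are
#'   requested).
#' @param dataset an [expression_dataset()] (may be `NULL` if only pathways
#'   are requested); gene ids matched exactly against its rownames.
#' @param pathway_names character vector of pathway features (may be empty).
#' @param gene_names character vector of gene features (may be empty).
#' @param labels optional labels overriding those carried by the inputs.
#' @return object of class `feature_set`: list with `matrix` (samples x
#'   features), `kinds` (`"pathway_L"` or `"gene_expr"` per feature) and
#'   `labels`.
#' @export
encode_samples <- function(activity = NULL, dataset = NULL,
                           pathway_names = character(0),
                           gene_names = character(0), labels = NULL) {
  if (length(pathway_names) == 0L && length(gene_names) == 0L)
    stop("at least one feature must be requested")
  cols <- list(); kinds <- character(0); nms <- character(0)
  if (length(pathway_names)) {
    if (is.null(activity)) stop("pathway features requested without an activity matrix")
    missing <- setdiff(pathway_names, colnames(activity$L))
    if (length(missing))
      stop("unknown pathway name(s): ", paste(missing, collapse = ", "))
    for (p in pathway_names) {
      cols[[length(cols) + 1L]] <- activity$L[, p]
      kinds <- c(kinds, "pathway_L"); nms <- c(nms, p)
    }
  }
  if (length(gene_names)) {
    if (is.null(dataset)) stop("gene features requested without an expression dataset")
    missing <- setdiff(gene_names, rownames(dataset$values))
    if (length(missing))
      stop("unknown gene name(s): ", paste(missing, collapse = ", "))
    for (g in gene_names) {
      cols[[length(cols) + 1L]] <- dataset$values[g, ]
      kinds <- c(kinds, "gene_expr"); nms <- c(nms, g)
    }
  }
  sample_ids <- names(cols[[1L]])
  m <- do.call(cbind, cols)
  dimnames(m) <- list(sample_ids, nms)
  if (is.null(labels)) {
    labels <- if (!is.null(activity) && !is.null(activity$labels))
      activity$labels else if (!is.null(dataset)) dataset$labels else NULL
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (is.null(names(labels))) names(labels) <- sample_ids
    labels <- labels[sample_ids]
  }
  structure(list(matrix = m, kinds = kinds, labels = labels),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d samples x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$kinds), collapse = "+")))
  invisible(x)
}

# Score one held-out vector against a training set.
# Class evidence = mean kernel weight per class; score = evidence_A /
# (evidence_A + evidence_B). Mean (not sum) weights keep the no-information
# case at exactly 0.5 regardless of fold-wise class imbalance.
.instance_score <- function(train, train_labels, test, class_a,
                            bandwidth = NULL) {
  d <- sqrt(colSums((t(train) - test)^2))
  if (is.null(bandwidth)) {
    pd <- stats::dist(train)
    bandwidth <- stats::median(pd)
  }
  w <- if (bandwidth > 0) exp(-(d / bandwidth)^2) else rep(1, length(d))
  is_a <- train_labels == class_a
  e_a <- mean(w[is_a]); e_b <- mean(w[!is_a])
  if (e_a + e_b == 0) return(0.5)
  e_a / (e_a + e_b)
}

#' Leave-one-out cross-validated instance-based scores
#'
#' For each sample: features are z-scored with statistics of the remaining
#' samples only, the instance-based scorer is fit on the remaining samples,
#' and a class-A score in [0, 1] is emitted for the held-out sample. No
#' statistic of the held-out sample ever enters its own fold. The default
#' scorer is a Gaussian-kernel distance-weighted nearest-neighbour model
#' (bandwidth = median pairwise training distance); a different scorer can
#' be plugged in via `scorer`.
#'
#' @param features a `feature_set` with labels.
#' @param class_a label treated as the positive class (default the first
#'   distinct label).
#' @param standardize z-score features per fold (default `TRUE`).
#' @param scorer function `(train, train_labels, test, class_a)` returning a
#'   class-A score; default the Gaussian-kernel instance scorer.
#' @return object of class `evaluation_result`: list with `per_sample_score`
#'   (named numeric), `auc`, `feature_names` and `classifier_config`.
#' @export
loocv_scores <- function(features, class_a = NULL, standardize = TRUE,
                         scorer = NULL) {
  stopifnot(inherits(features, "feature_set"))
  labels <- features$labels
  if (is.null(labels)) stop("feature set has no labels")
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  if (is.null(class_a)) class_a <- classes[1L]
  if (min(table(labels)) < 2L)
    stop("each class needs >= 2 samples for LOOCV")
  m <- features$matrix
  if (anyNA(m)) stop("feature matrix contains undefined values; impute or drop")
  if (is.null(scorer)) scorer <- .instance_score
  n <- nrow(m)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    train <- m[-i, , drop = FALSE]
    test <- m[i, ]
    if (standardize) {
      mu <- colMeans(train)
      sdv <- apply(train, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      train <- sweep(sweep(train, 2L, mu), 2L, sdv, "/")
      test <- (test - mu) / sdv
    }
    scores[i] <- scorer(train, labels[-i], test, class_a)
  }
  names(scores) <- rownames(m)
  structure(list(per_sample_score = scores,
                 auc = auc_score(scores, labels, class_a),
                 feature_names = colnames(m),
                 classifier_config = list(scorer = "gaussian_kernel_nn",
                                          standardize = standardize,
                                          class_a = class_a)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: features [%s], AUC = %.3f\n",
              paste(x$feature_names, collapse = ", "), x$auc))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC = (concordant pairs + 0.5 x tied pairs) / (n_A x n_B), with class A as
#' the positive class: the probability that a random positive outscores a
#' random negative, ties half-credited.
#'
#' @param scores per-sample numeric scores.
#' @param labels per-sample class labels (two classes).
#' @param class_a the positive class (default first distinct label).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels, class_a = NULL) {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` lengths differ")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("both classes must be present")
  if (length(classes) > 2L) stop("exactly two classes required")
  if (is.null(class_a)) class_a <- classes[1L]
  pos <- labels == class_a
  r <- rank(scores)  # midranks: ties get 0.5 credit automatically
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate all feature subsets up to a given size
#'
#' Runs [loocv_scores()] + AUC on every non-empty subset of the feature set
#' of size at most `max_size`, supporting single-versus-integrated biomarker
#' comparisons. Output is sorted by AUC descending; ties broken by smaller
#' subset first, then lexicographic feature names.
#'
#' @param features a `feature_set` with labels.
#' @param max_size largest subset size (guarded at 4; exhaustive enumeration).
#' @param class_a positive class label.
#' @param standardize,scorer passed to [loocv_scores()].
#' @return data frame with columns `features` (names joined by `+`), `size`,
#'   `auc`.
#' @export
evaluate_combinations <- function(features, max_size = 2L, class_a = NULL,
                                  standardize = TRUE, scorer = NULL) {
  stopifnot(inherits(features, "feature_set"))
  p <- ncol(features$matrix)
  if (max_size > p) stop("`max_size` exceeds the number of features")
  if (max_size > 4L) stop("`max_size` is guarded at 4 (exhaustive enumeration)")
  subsets <- list()
  for (s in seq_len(max_size))
    subsets <- c(subsets, utils::combn(p, s, simplify = FALSE))
  rows <- lapply(subsets, function(idx) {
    sub <- structure(list(matrix = features$matrix[, idx, drop = FALSE],
                          kinds = features$kinds[idx],
                          labels = features$labels),
                     class = "feature_set")
    ev <- loocv_scores(sub, class_a = class_a, standardize = standardize,
                       scorer = scorer)
    data.frame(features = paste(colnames(features$matrix)[idx],
                                collapse = "+"),
               size = length(idx), auc = ev$auc)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$auc, out$size, out$features, method = "radix")
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
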