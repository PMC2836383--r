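# Unsupervised hierarchical clustering of activity-encoded samples. Class
# labels never enter the clustering; they are only compared to the resulting
# two-group cut afterwards.

#' Hierarchically cluster samples in feature space
#'
#' Agglomerative clustering of the samples x features matrix. Features are
#' z-scored per column by default so pathways with large mean activity do not
#' dominate the metric. Samples are ordered lexicographically by id before
#' distance computation, which makes the result exactly invariant to input
#' order (including tie-height cases).
#'
#' @param features a `feature_set` (labels, if any, are ignored here).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson between
#'   sample vectors).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @param standardize z-score feature columns first (default `TRUE`).
#' @return object of class `sample_tree`: list with `hclust` (a
#'   [stats::hclust] object over sample ids), `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(features,
                                 distance = c("euclidean", "correlation"),
                                 linkage = c("average", "complete", "single"),
                                 standardize = TRUE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(inherits(features, "feature_set"))
  m <- features$matrix
  if (nrow(m) < 2L) stop("clustering requires >= 2 samples")
  if (anyNA(m))
    stop("undefined feature values present; impute or exclude before clustering")
  m <- m[order(rownames(m), method = "radix"), , drop = FALSE]
  if (standardize) {
    sdv <- apply(m, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    m <- sweep(sweep(m, 2L, colMeans(m)), 2L, sdv, "/")
  }
  d <- if (distance == "euclidean") {
    stats::dist(m)
  } else {
    if (ncol(m) < 2L)
      stop("correlation distance needs >= 2 features")
    stats::as.dist(1 - stats::cor(t(m)))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, distance = distance, linkage = linkage),
            class = "sample_tree")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("sample_tree: %d samples, %s distance, %s linkage\n",
              length(x$hclust$labels), x$distance, x$linkage))
  invisible(x)
}

#' Class composition of the two-group tree cut
#'
#' Cuts the tree into exactly two clusters at the root and reports, for each
#' cluster, its size and per-class composition plus the majority class --
#' the analogue of statements like "one group holds 14 of the 16 VD+
#' samples".
#'
#' @param tree a `sample_tree`.
#' @param labels per-sample class labels, named by sample id or ordered as
#'   the tree's labels.
#' @return data frame with one row per cluster: `cluster`, `size`, one count
#'   column per class, `majority_class`, `majority_count`.
#' @export
two_group_purity <- function(tree, labels) {
  stopifnot(inherits(tree, "sample_tree"))
  ids <- tree$hclust$labels
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels))) stop("labels missing for some samples")
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels length does not match tree leaves")
  }
  cut2 <- stats::cutree(tree$hclust, k = min(2L, length(ids)))
  classes <- sort(unique(labels))
  rows <- lapply(sort(unique(cut2)), function(cl) {
    in_cl <- cut2 == cl
    counts <- vapply(classes, function(x) sum(labels[in_cl] == x),
                     integer(1L))
    top <- which.max(counts)
    out <- data.frame(cluster = cl, size = sum(in_cl))
    for (x in classes) out[[x]] <- counts[[x]]
    out$majority_class <- classes[top]
    out$majority_count <- counts[[top]]
    out
  })
  do.call(rbind, rows)
}

#' Export a sample tree in Newick format
#'
#' Writes the merge tree with branch lengths derived from merge heights
#' (leaves sit at height zero), suitable for dendrogram or unrooted-tree
#' viewers. Leaf names containing Newick metacharacters are quoted.
#'
#' @param tree a `sample_tree`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_newick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "sample_tree"))
    stop("`tree` must be a sample_tree")
  if (length(tree$hclust$labels) < 2L) stop("tree has fewer than 2 leaves")
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Merge table of a sample tree
#'
#' One row per agglomeration step: the two merged items (negative = singleton
#' sample index, positive = earlier merge step) and the merge height. Useful
#' for external dendrogram plotting.
#'
#' @param x a `sample_tree`.
#' @param ... unused.
#' @export
as.data.frame.sample_tree <- function(x, ...) {
  hc <- x$hclust
  lab <- function(i) {
    out <- character(length(i))
    out[i < 0] <- hc$labels[-i[i < 0]]
    out[i > 0] <- paste0("node", i[i > 0])
    out
  }
  data.frame(item1 = lab(hc$merge[, 1L]),
             item2 = lab(hc$merge[, 2L]),
             height = hc$height,
             row.names = NULL)
}
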