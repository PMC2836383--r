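# Perturbation scoring: psc = |t| on pathway activity levels, calibrated by
# class-label permutation. One shared set of permutations is applied to every
# pathway so scores stay comparable across pathways.

# Variance sums below a relative floor are treated as exactly zero so that
# constant columns hit the documented degenerate rules instead of producing
# astronomically large t values from rounding noise.
.zero_var <- function(ss, msq) ss <= 1e-20 * max(1, msq)

#' Perturbation score of one pathway
#'
#' The signed two-sample t-statistic (class A minus class B) on a pathway's
#' per-sample activity levels, and its unsigned value, the perturbation score
#' psc = |t|. Default is the pooled-variance Student form; Welch is available
#' via `var_equal = FALSE`. Degenerate cases: zero variance and zero mean
#' difference give t = 0; zero variance with a nonzero mean difference gives
#' a signed infinite t (psc = Inf), which ranks above all finite scores.
#' Missing activity values are dropped; fewer than 2 defined values in either
#' class makes the pathway unscorable (`NA` with `scorable = FALSE`).
#'
#' @param L_column numeric vector of per-sample activity levels (may contain
#'   `NA` for undefined cells).
#' @param labels per-sample class labels, exactly two distinct values.
#' @param class_a which label is class A (the minuend); default the first
#'   distinct label in `labels` order.
#' @param var_equal pooled-variance Student t (`TRUE`, default) or Welch.
#' @return list with `t_signed`, `psc` and `scorable`.
#' @export
perturbation_score <- function(L_column, labels, class_a = NULL,
                               var_equal = TRUE) {
  labels <- as.character(labels)
  if (length(L_column) != length(labels))
    stop("`L_column` and `labels` lengths differ")
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  if (is.null(class_a)) class_a <- classes[1L]
  ok <- !is.na(L_column)
  xa <- L_column[ok & labels == class_a]
  xb <- L_column[ok & labels != class_a]
  if (length(xa) < 2L || length(xb) < 2L)
    return(list(t_signed = NA_real_, psc = NA_real_, scorable = FALSE))
  na <- length(xa); nb <- length(xb)
  d <- mean(xa) - mean(xb)
  ssa <- sum((xa - mean(xa))^2)
  ssb <- sum((xb - mean(xb))^2)
  msq <- mean(c(xa, xb)^2)
  if (var_equal) {
    s2 <- (ssa + ssb) / (na + nb - 2L)
    if (.zero_var(ssa + ssb, msq)) s2 <- 0
    se <- sqrt(s2 * (1 / na + 1 / nb))
  } else {
    v_a <- ssa / (na - 1L); v_b <- ssb / (nb - 1L)
    if (.zero_var(ssa + ssb, msq)) { v_a <- 0; v_b <- 0 }
    se <- sqrt(v_a / na + v_b / nb)
  }
  t_signed <- if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / se
  list(t_signed = t_signed, psc = abs(t_signed), scorable = TRUE)
}

# Vectorized t engine: signed t for every pathway column of L under each
# row of the 0/1 class-A assignment matrix A (rows = assignments). Handles
# NA cells via indicator weighting. Returns an assignments x pathways matrix;
# cells where either class has < 2 defined values are NA.
.t_stats_matrix <- function(L, A, var_equal = TRUE) {
  W <- !is.na(L)
  L0 <- L; L0[!W] <- 0
  storage.mode(A) <- "double"
  W <- matrix(as.double(W), nrow(L), ncol(L))
  # The class-B side is a direct product (not total minus class A) so that
  # an assignment and its mirror produce bitwise-tied |t| values.
  B <- 1 - A
  n_a <- A %*% W;  n_b <- B %*% W
  s_a <- A %*% L0; s_b <- B %*% L0
  L2 <- L0 * L0
  q_a <- A %*% L2; q_b <- B %*% L2
  n_t <- matrix(colSums(W), nrow(A), ncol(L), byrow = TRUE)
  q_t <- q_a + q_b
  valid <- n_a >= 2 & n_b >= 2
  n_a[!valid] <- NA
  m_a <- s_a / n_a
  m_b <- s_b / n_b
  d <- m_a - m_b
  ss_a <- pmax(q_a - s_a^2 / n_a, 0)
  ss_b <- pmax(q_b - s_b^2 / n_b, 0)
  msq <- pmax(1, q_t / n_t)
  zero <- (ss_a + ss_b) <= 1e-20 * msq
  if (var_equal) {
    s2 <- (ss_a + ss_b) / (n_a + n_b - 2)
    s2[zero] <- 0
    se <- sqrt(s2 * (1 / n_a + 1 / n_b))
  } else {
    v_a <- ss_a / (n_a - 1); v_b <- ss_b / (n_b - 1)
    v_a[zero] <- 0; v_b[zero] <- 0
    se <- sqrt(v_a / n_a + v_b / n_b)
  }
  t_mat <- d / se
  deg <- se == 0 & !is.na(se)
  t_mat[deg & d == 0] <- 0
  t_mat[deg & d != 0] <- sign(d[deg & d != 0]) * Inf
  t_mat[!valid] <- NA
  t_mat
}

.assignment_row <- function(labels, class_a) {
  matrix(as.numeric(labels == class_a), nrow = 1L)
}

#' Score all pathways of an activity matrix
#'
#' Applies [perturbation_score()] to every pathway column.
#'
#' @param activity an `activity_matrix` with labels (or supply `labels`).
#' @param labels optional per-sample labels overriding `activity$labels`.
#' @param class_a label treated as class A; default first distinct label.
#' @param var_equal pooled (default) or Welch t.
#' @return data frame with columns `pathway`, `t_signed`, `psc`, `scorable`,
#'   in activity-matrix column order.
#' @export
score_pathways <- function(activity, labels = NULL, class_a = NULL,
                           var_equal = TRUE) {
  stopifnot(inherits(activity, "activity_matrix"))
  if (is.null(labels)) labels <- activity$labels
  if (is.null(labels)) stop("no class labels available")
  labels <- as.character(labels)
  if (is.null(class_a)) class_a <- unique(labels)[1L]
  t_obs <- drop(.t_stats_matrix(activity$L,
                                .assignment_row(labels, class_a),
                                var_equal = var_equal))
  data.frame(pathway = colnames(activity$L),
             t_signed = t_obs,
             psc = abs(t_obs),
             scorable = !is.na(t_obs),
             row.names = NULL)
}

#' Permutation p-values for pathway perturbation scores
#'
#' The null distribution of psc is built by permuting the sample class labels
#' of the activity matrix; the same permutations (class sizes preserved) are
#' applied to all pathways. In `sampled` mode, B random permutations give
#' p = (c + 1) / (B + 1) with c the number of permutations whose null psc is
#' at least the observed psc (add-one smoothing; the smallest attainable p is
#' 1/(B+1), about 1e-4 at the default B = 10000). In `exhaustive` mode all
#' distinct class-A assignments of the given sizes are enumerated and
#' p = c'/T, with c' counting assignments (including the observed one) whose
#' null psc is at least the observed psc. Ties, including infinite scores,
#' count as "at least". A fixed seed makes sampled output bit-identical.
#'
#' @param activity an `activity_matrix`.
#' @param labels optional labels overriding `activity$labels`.
#' @param B number of sampled permutations (default 10000).
#' @param seed integer seed for the sampled mode (required there).
#' @param mode `"sampled"` or `"exhaustive"`.
#' @param class_a label treated as class A.
#' @param var_equal pooled (default) or Welch t.
#' @param max_exhaustive guard on sample count for exhaustive mode
#'   (default 20).
#' @return data frame with columns `pathway`, `t_signed`, `psc`, `p_value`,
#'   `scorable`, plus attributes `n_permutations` and `mode`. Unscorable
#'   pathways have `NA` p-values.
#' @export
permutation_pvalues <- function(activity, labels = NULL, B = 10000L,
                                seed = NULL,
                                mode = c("sampled", "exhaustive"),
                                class_a = NULL, var_equal = TRUE,
                                max_exhaustive = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(activity, "activity_matrix"))
  if (is.null(labels)) labels <- activity$labels
  if (is.null(labels)) stop("no class labels available")
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("labels must be binary")
  if (is.null(class_a)) class_a <- unique(labels)[1L]
  n <- length(labels)
  n_a <- sum(labels == class_a)

  if (mode == "exhaustive") {
    if (n > max_exhaustive)
      stop(sprintf("exhaustive mode limited to %d samples (got %d)",
                   max_exhaustive, n))
    combs <- utils::combn(n, n_a)
    A <- matrix(0, ncol(combs), n)
    A[cbind(rep(seq_len(ncol(combs)), each = n_a), as.vector(combs))] <- 1
  } else {
    if (B < 1L) stop("B must be >= 1")
    if (is.null(seed)) stop("`seed` is required in sampled mode")
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    A <- matrix(0, B, n)
    for (b in seq_len(B)) A[b, sample.int(n, n_a)] <- 1
  }

  # The observed assignment is evaluated inside the same matrix call as the
  # permutations so that its null score ties the observed score exactly
  # (separate vector/matrix BLAS paths can differ in the last ulp).
  A_all <- rbind(.assignment_row(labels, class_a), A)
  t_all <- .t_stats_matrix(activity$L, A_all, var_equal = var_equal)
  t_obs <- t_all[1L, ]
  psc_obs <- abs(t_obs)
  psc_null <- abs(t_all[-1L, , drop = FALSE])
  scorable <- !is.na(t_obs)
  p <- vapply(seq_len(ncol(psc_null)), function(k) {
    if (!scorable[k]) return(NA_real_)
    nulls <- psc_null[, k]
    nulls <- nulls[!is.na(nulls)]
    c_ge <- sum(nulls >= psc_obs[k])
    if (mode == "exhaustive") c_ge / ncol(combs)
    else (c_ge + 1) / (length(nulls) + 1)
  }, numeric(1L))

  out <- data.frame(pathway = colnames(activity$L), t_signed = t_obs,
                    psc = psc_obs, p_value = p, scorable = scorable,
                    row.names = NULL)
  attr(out, "n_permutations") <- nrow(A)
  attr(out, "mode") <- mode
  out
}

#' Rank pathways by perturbation score
#'
#' Sorts scorable pathways by descending psc (infinite scores first), breaking
#' ties by ascending p-value and then by pathway name, and assigns ranks 1..n.
#' Unscorable pathways are dropped with a warning. The signed t is retained so
#' callers can separate up- from down-perturbed pathways.
#'
#' @param scores data frame with columns `pathway`, `t_signed`, `psc` and
#'   optionally `p_value` and `scorable` (as produced by
#'   [permutation_pvalues()] or [score_pathways()]).
#' @return a `perturbation_table` data frame with columns `pathway`,
#'   `t_signed`, `psc`, `p_value`, `rank`.
#' @export
rank_pathways <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("pathway", "t_signed", "psc") %in% names(scores)))
  if (!"p_value" %in% names(scores)) scores$p_value <- NA_real_
  if ("scorable" %in% names(scores) && any(!scores$scorable)) {
    warning(sum(!scores$scorable), " unscorable pathway(s) excluded: ",
            paste(utils::head(scores$pathway[!scores$scorable], 5L),
                  collapse = ", "))
    scores <- scores[scores$scorable, , drop = FALSE]
  }
  if (nrow(scores) == 0L) stop("no scorable pathway to rank")
  ord <- order(-scores$psc, scores$p_value, scores$pathway,
               method = "radix")
  out <- scores[ord, c("pathway", "t_signed", "psc", "p_value")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("perturbation_table", "data.frame")
  out
}

#' Gene-sharing graph over a pathway subset
#'
#' One node per requested pathway; an undirected edge wherever two pathways'
#' gene sets intersect, annotated with the shared genes. Pathways sharing no
#' gene with any other remain isolated nodes.
#'
#' @param collection a [pathway_collection()].
#' @param subset pathway names to include (default all).
#' @return list of class `overlap_graph` with `nodes` (character) and `edges`
#'   (data frame `from`, `to`, `n_shared`, `shared_genes`; genes joined by
#'   `;`). Edge rows follow the subset order (`from` precedes `to`).
#' @export
overlap_graph <- function(collection, subset = NULL) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (is.null(subset)) subset <- collection$names
  missing <- setdiff(subset, collection$names)
  if (length(missing))
    stop("unknown pathway name(s): ", paste(missing, collapse = ", "))
  sets <- collection$genes[subset]
  n <- length(subset)
  from <- character(0); to <- character(0)
  n_shared <- integer(0); shared <- character(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        common <- intersect(sets[[i]], sets[[j]])
        if (length(common)) {
          from <- c(from, subset[i]); to <- c(to, subset[j])
          n_shared <- c(n_shared, length(common))
          shared <- c(shared, paste(common, collapse = ";"))
        }
      }
    }
  }
  structure(list(nodes = subset,
                 edges = data.frame(from = from, to = to,
                                    n_shared = n_shared,
                                    shared_genes = shared,
                                    row.names = NULL)),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("overlap_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
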