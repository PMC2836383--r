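make_features <- function(m, labels) {
  structure(list(matrix = m, kinds = rep("pathway_L", ncol(m)),
                 labels = labels),
            class = "feature_set")
}

test_that("sample encoding assembles requested pathway and gene columns", {
  sim <- simulate_dataset(sim_config(n_genes = 300, n_pathways = 30,
                                     pathway_size_range = c(4, 10),
                                     n_planted = 2, n_unmeasured_pathways = 0,
                                     seed = 3))
  act <- compute_activity(sim$dataset, sim$collection)
  top10 <- sim$collection$names[1:10]
  fs <- encode_samples(act, pathway_names = top10)
  expect_identical(dim(fs$matrix), c(32L, 10L))
  expect_identical(fs$kinds, rep("pathway_L", 10))
  expect_equal(fs$matrix[, 3], act$L[, top10[3]])

  g <- rownames(sim$dataset$values)[5]
  fs1 <- encode_samples(dataset = sim$dataset, gene_names = g)
  expect_identical(dim(fs1$matrix), c(32L, 1L))
  expect_equal(fs1$matrix[, 1], sim$dataset$values[g, ])

  mixed <- encode_samples(act, sim$dataset, pathway_names = top10[1],
                          gene_names = g)
  expect_identical(mixed$kinds, c("pathway_L", "gene_expr"))
  expect_identical(colnames(mixed$matrix), c(top10[1], g))

  expect_error(encode_samples(act, pathway_names = "NOPE"),
               "unknown pathway name.*NOPE")
  expect_error(encode_samples(dataset = sim$dataset, gene_names = "NOPE"),
               "unknown gene name.*NOPE")
})

test_that("LOOCV separates well-separated classes and flattens no-information data", {
  set.seed(1)
  m <- matrix(c(rnorm(4, 10, 0.1), rnorm(4, 0, 0.1)), ncol = 1,
              dimnames = list(paste0("s", 1:8), "f"))
  lab <- setNames(rep(c("A", "B"), each = 4), rownames(m))
  ev <- loocv_scores(make_features(m, lab))
  expect_true(min(ev$per_sample_score[1:4]) > max(ev$per_sample_score[5:8]))
  expect_equal(ev$auc, 1)

  flat <- matrix(2, 8, 2, dimnames = list(paste0("s", 1:8), c("f1", "f2")))
  ev0 <- loocv_scores(make_features(flat, lab))
  expect_true(all(ev0$per_sample_score == ev0$per_sample_score[1]))
  expect_equal(ev0$auc, 0.5)
})

test_that("LOOCV matches an independently coded leave-one-out loop exactly", {
  set.seed(17)
  m <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("s", 1:10), c("f1", "f2")))
  lab <- setNames(rep(c("A", "B"), each = 5), rownames(m))
  ev <- loocv_scores(make_features(m, lab))
  scorer <- pathmarker:::.instance_score
  for (i in seq_len(10)) {          # reimplemented fold loop
    tr <- m[-i, , drop = FALSE]
    mu <- colMeans(tr); sdv <- apply(tr, 2, sd); sdv[sdv == 0] <- 1
    trz <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
    tez <- (m[i, ] - mu) / sdv
    expect_identical(ev$per_sample_score[[i]], scorer(trz, lab[-i], tez, "A"))
  }
})

test_that("LOOCV guards against degenerate class sizes and undefined values", {
  m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_error(loocv_scores(make_features(m, c("A", "A", "B"))),
               ">= 2 samples")
  m2 <- matrix(c(1, NA, 3, 4, 5, 6, 7, 8), 4,
               dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(loocv_scores(make_features(m2, rep(c("A", "B"), 2))),
               "undefined values")
})

test_that("AUC equals the all-pairs Mann-Whitney count with half-credit ties", {
  # positives (0.9, 0.4) vs negatives (0.8, 0.3): 3 of 4 pairs concordant
  expect_equal(auc_score(c(0.9, 0.4, 0.8, 0.3), c("A", "A", "B", "B")), 0.75)
  expect_equal(auc_score(c(5, 6, 1, 2), c("A", "A", "B", "B")), 1)
  expect_equal(auc_score(rep(0.2, 6), rep(c("A", "B"), 3)), 0.5)

  for (seed in 1:4) {
    set.seed(seed)
    s <- sample(round(runif(12), 1))    # forces ties
    lab <- sample(rep(c("A", "B"), 6))
    pairs <- expand.grid(p = which(lab == "A"), n = which(lab == "B"))
    oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                          ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(auc_score(s, lab, class_a = "A"), oracle, tolerance = 1e-12)
  }
})

test_that("AUC respects label-flip complementarity and monotone invariance", {
  set.seed(9)
  s <- rnorm(14); lab <- sample(rep(c("A", "B"), 7))
  a <- auc_score(s, lab, class_a = "A")
  expect_equal(a + auc_score(s, lab, class_a = "B"), 1)
  expect_equal(auc_score(exp(2 * s) + 1, lab, class_a = "A"), a)
  expect_error(auc_score(s, rep("A", 14)), "both classes")
})

test_that("combination evaluation enumerates subsets and keeps singletons intact", {
  set.seed(23)
  strong <- c(rnorm(5, 4, 0.3), rnorm(5, 0, 0.3))
  m <- cbind(f1 = strong, f2 = rnorm(10), f3 = rnorm(10))
  rownames(m) <- paste0("s", 1:10)
  lab <- setNames(rep(c("A", "B"), each = 5), rownames(m))
  fs <- make_features(m, lab)
  tab <- evaluate_combinations(fs, max_size = 2)
  expect_identical(nrow(tab), 6L)  # 3 singletons + 3 pairs
  # every singleton AUC is reproduced unchanged among the subset results
  for (f in c("f1", "f2", "f3"))
    expect_equal(tab$auc[tab$features == f],
                 loocv_scores(make_features(m[, f, drop = FALSE], lab))$auc)
  expect_error(evaluate_combinations(fs, max_size = 5), "guarded at 4|exceeds")
})

test_that("jointly informative features can outscore every singleton", {
  # radial geometry: class A on a ring, class B at the center, per axis useless
  set.seed(77)
  n <- 12
  theta <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  a <- cbind(cos(theta), sin(theta)) + matrix(rnorm(2 * n, 0, 0.05), n)
  b <- matrix(rnorm(2 * n, 0, 0.05), n)
  m <- rbind(a, b)
  dimnames(m) <- list(sprintf("s%02d", 1:(2 * n)), c("x", "y"))
  lab <- setNames(rep(c("A", "B"), each = n), rownames(m))
  tab <- evaluate_combinations(make_features(m, lab), max_size = 2)
  pair <- tab$auc[tab$features == "x+y"]
  singles <- tab$auc[tab$size == 1]
  expect_gt(pair, max(singles))
})
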