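# In-code fixtures shared across test files.

# Small labelled dataset with known values: 4 genes x 4 samples, 2 per class.
tiny_dataset <- function() {
  v <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                2, 2, 2, 2,
                10, 9, 1, 2), nrow = 4, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3", "G4"),
                              c("s1", "s2", "s3", "s4")))
  expression_dataset(v, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
}

tiny_collection <- function() {
  pathway_collection(list(P1 = c("G1", "G2"),
                          P2 = c("G2", "G3", "G4"),
                          P3 = c("GX", "GY")),
                     descriptions = c("a", "b", "c"))
}

# Random labelled dataset (no pathway structure) for oracle comparisons.
rand_dataset <- function(seed, n_genes = 30, n_a = 4, n_b = 4) {
  set.seed(seed)
  n <- n_a + n_b
  v <- matrix(rnorm(n_genes * n, mean = 7), n_genes, n,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  expression_dataset(v, setNames(rep(c("A", "B"), c(n_a, n_b)),
                                 colnames(v)))
}

rand_collection <- function(seed, n_sets = 10, gene_pool = sprintf("G%03d", 1:30),
                            size_range = c(2, 8)) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(k) {
    s <- sample(seq(size_range[1], size_range[2]), 1)
    sample(gene_pool, s)
  })
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  pathway_collection(sets)
}

# Independent pooled/Welch t oracle via stats::t.test.
oracle_t <- function(xa, xb, var_equal = TRUE) {
  unname(stats::t.test(xa, xb, var.equal = var_equal)$statistic)
}
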