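# End-to-end pipeline: read expression + gene sets + labels, score and rank
# pathway perturbations, encode samples by top-pathway activities, classify
# and cluster. Every artifact is written as deterministic TSV so a fixed
# seed and config give byte-identical outputs.

#' Pipeline run configuration
#'
#' @param expression path to the expression matrix (TSV or GCT).
#' @param gmt path to the gene-set GMT file.
#' @param cls path to the CLS class-label file.
#' @param out_dir output directory (created if needed).
#' @param dialect expression dialect, `"tsv"` or `"gct"`.
#' @param B permutations for p-values (default 10000).
#' @param seed integer RNG seed (default 1).
#' @param mode `"sampled"` or `"exhaustive"` p-value mode.
#' @param var_equal pooled (default) or Welch t.
#' @param top_k pathways used for encoding/clustering (default 10).
#' @param collapse probe-collapsing rule, `"mean"` or `"max"`.
#' @param ignore_case uppercase gene ids before matching.
#' @return a `run_config` list.
#' @export
run_config <- function(expression, gmt, cls, out_dir,
                       dialect = c("tsv", "gct"), B = 10000L, seed = 1L,
                       mode = c("sampled", "exhaustive"), var_equal = TRUE,
                       top_k = 10L, collapse = c("mean", "max"),
                       ignore_case = TRUE) {
  stopifnot(B >= 1L, top_k >= 1L)
  for (p in c(expression, gmt, cls))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(expression = expression, gmt = gmt, cls = cls,
                 out_dir = out_dir, dialect = match.arg(dialect),
                 B = as.integer(B), seed = as.integer(seed),
                 mode = match.arg(mode), var_equal = var_equal,
                 top_k = as.integer(top_k), collapse = match.arg(collapse),
                 ignore_case = ignore_case),
            class = "run_config")
}

.write_manifest <- function(config, extra, path) {
  items <- c(lapply(config[c("dialect", "B", "seed", "mode", "var_equal",
                             "top_k", "collapse", "ignore_case")],
                    as.character),
             list(expression_md5 = unname(tools::md5sum(config$expression)),
                  gmt_md5 = unname(tools::md5sum(config$gmt)),
                  cls_md5 = unname(tools::md5sum(config$cls))),
             lapply(extra, as.character))
  writeLines(paste0(names(items), "=", unlist(items)), path)
}

#' Score pathway perturbations from files
#'
#' Reads the expression matrix, gene sets and class labels; collapses
#' duplicate gene symbols; filters pathways to those with at least one
#' measured gene; computes per-sample activity levels, permutation p-values
#' and the ranked perturbation table; and writes `perturbation.tsv`,
#' `activity.tsv`, `dropped_pathways.txt` and a `run_manifest.txt` recording
#' seed, B, t-variant, input checksums and the mapped/retained
#' sample-pathway instance counts.
#'
#' @param config a [run_config()].
#' @return list with `table` (ranked `perturbation_table`), `activity`,
#'   `dataset`, `retained`, `dropped`, `instances_mapped`,
#'   `instances_retained` and `files`.
#' @export
run_score <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- read_expression(config$expression, config$dialect)
  dataset <- collapse_genes(dataset, config$collapse, config$ignore_case)
  labels <- read_cls(config$cls)
  dataset <- set_labels(dataset, labels)
  collection <- read_gmt(config$gmt)

  act_all <- compute_activity(dataset, collection, config$ignore_case)
  instances_mapped <- count_instances(act_all)
  filt <- filter_measured_pathways(collection, dataset, config$ignore_case)
  activity <- compute_activity(dataset, filt$retained, config$ignore_case)
  instances_retained <- count_instances(activity)

  scored <- permutation_pvalues(activity, B = config$B, seed = config$seed,
                                mode = config$mode,
                                var_equal = config$var_equal)
  tab <- rank_pathways(scored)
  n_in_data <- vapply(tab$pathway, function(p) {
    g <- filt$retained$genes[[p]]
    if (config$ignore_case) g <- toupper(g)
    sum(g %in% rownames(dataset$values))
  }, integer(1L))
  tab$n_genes_in_data <- n_in_data

  files <- file.path(config$out_dir,
                     c("perturbation.tsv", "activity.tsv",
                       "dropped_pathways.txt", "run_manifest.txt"))
  names(files) <- c("perturbation", "activity", "dropped", "manifest")
  write_table(tab, files["perturbation"])
  write_table(as.data.frame(activity), files["activity"])
  writeLines(filt$dropped, files["dropped"])
  .write_manifest(config,
                  list(instances_mapped = instances_mapped,
                       instances_retained = instances_retained,
                       n_pathways_input = length(collection),
                       n_pathways_retained = length(filt$retained)),
                  files["manifest"])
  list(table = tab, activity = activity, dataset = dataset,
       retained = filt$retained, dropped = filt$dropped,
       instances_mapped = instances_mapped,
       instances_retained = instances_retained, files = files)
}

#' Encode samples by top pathways and evaluate biomarker panels
#'
#' Encodes every sample by the activity levels of the `top_k` highest-ranked
#' pathways (optionally extended with explicit pathway or gene features),
#' writes the encoded dataset, then evaluates all feature subsets up to
#' `max_combo` with LOOCV + AUC.
#'
#' @param score a [run_score()] result.
#' @param config the same [run_config()].
#' @param extra_pathways,extra_genes optional explicit features to append.
#' @param max_combo largest feature-subset size evaluated (default 2).
#' @return list with `features` (the `feature_set`), `combos` (subset/AUC
#'   table), `scores` (per-sample LOOCV scores of the full feature set) and
#'   `files`.
#' @export
run_encode_classify <- function(score, config,
                                extra_pathways = character(0),
                                extra_genes = character(0),
                                max_combo = 2L) {
  stopifnot(inherits(config, "run_config"))
  top <- utils::head(score$table$pathway, config$top_k)
  feats <- encode_samples(score$activity, score$dataset,
                          pathway_names = unique(c(top, extra_pathways)),
                          gene_names = extra_genes)
  enc <- data.frame(sample_id = rownames(feats$matrix),
                    class = feats$labels, feats$matrix,
                    check.names = FALSE, row.names = NULL)
  combos <- evaluate_combinations(feats, max_size = max_combo)
  full <- loocv_scores(feats)
  per_sample <- data.frame(sample_id = names(full$per_sample_score),
                           class = feats$labels,
                           score = unname(full$per_sample_score),
                           row.names = NULL)
  files <- file.path(config$out_dir,
                     c("encoded.tsv", "combo_auc.tsv", "loocv_scores.tsv"))
  names(files) <- c("encoded", "combos", "scores")
  write_table(enc, files["encoded"])
  write_table(combos, files["combos"])
  write_table(per_sample, files["scores"])
  list(features = feats, combos = combos, scores = full, files = files)
}

#' Cluster samples on top-pathway activities
#'
#' Unsupervised hierarchical clustering of the encoded samples, with Newick
#' export, a merge-table TSV and the two-group class-purity summary.
#'
#' @param score a [run_score()] result.
#' @param config the same [run_config()].
#' @param distance,linkage passed to [hierarchical_cluster()].
#' @return list with `tree`, `purity` and `files`.
#' @export
run_cluster <- function(score, config, distance = "euclidean",
                        linkage = "average") {
  top <- utils::head(score$table$pathway, config$top_k)
  feats <- encode_samples(score$activity, pathway_names = top)
  tree <- hierarchical_cluster(feats, distance, linkage)
  purity <- two_group_purity(tree, feats$labels)
  files <- file.path(config$out_dir,
                     c("samples.nwk", "merges.tsv", "purity.tsv"))
  names(files) <- c("newick", "merges", "purity")
  export_newick(tree, files["newick"])
  write_table(as.data.frame(tree), files["merges"])
  write_table(purity, files["purity"])
  list(tree = tree, purity = purity, files = files)
}

#' Write a simulated study to disk
#'
#' Emits the expression TSV, GMT, CLS and a ground-truth gene-shift TSV for
#' a [simulate_dataset()] draw, ready to be fed back through [run_score()].
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return named character vector of written file paths.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  files <- file.path(out_dir, c("expression.tsv", "pathways.gmt",
                                "labels.cls", "truth.tsv"))
  names(files) <- c("expression", "gmt", "cls", "truth")
  write_expression(sim$dataset, files["expression"])
  write_gmt(sim$collection, files["gmt"])
  write_cls(unname(sim$truth$labels), files["cls"])
  write_table(data.frame(gene_id = names(sim$truth$gene_shift),
                         true_shift = unname(sim$truth$gene_shift),
                         row.names = NULL),
              files["truth"])
  files
}
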