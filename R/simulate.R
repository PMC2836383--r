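# Synthetic two-class expression data with planted pathway-level effects.
# Emulates the shape of a post-MI ventricular dysfunction study: two balanced
# 16-sample classes, a 639-set canonical-pathway collection of which a couple
# of sets have no measured gene, log-scale intensities with Gaussian noise.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the package targets: 16 + 16 samples,
#' 639 pathways of 10-100 genes drawn from a 15000-gene background, 2 sets
#' built entirely from unmeasured gene ids, unit-SD Gaussian noise on a
#' log-like intensity scale (baselines ~ N(7, 1.5^2)), and a unit mean shift
#' planted in class A for the member genes of the planted pathways.
#'
#' @param n_genes number of measured genes (matrix rows).
#' @param n_samples_per_class integer pair, samples in classes A and B.
#' @param n_pathways total gene sets, including unmeasured ones.
#' @param pathway_size_range integer pair, inclusive set-size range.
#' @param n_planted number of pathways carrying the class-A mean shift
#'   (the first `n_planted` measured sets).
#' @param effect_size mean shift added to planted-pathway member genes in
#'   class A samples, expression units.
#' @param noise_sd per-gene Gaussian noise SD.
#' @param n_unmeasured_pathways sets composed only of gene ids absent from
#'   the matrix (exercises the at-least-one-measured-gene filter); these are
#'   the last entries of the collection.
#' @param gene_overlap_fraction fraction of each set drawn from a small
#'   shared gene pool, controlling cross-set overlap.
#' @param class_names labels for classes A and B.
#' @param seed integer seed; all randomness flows from it through separate
#'   sub-streams for membership, baselines and noise, so changing the sample
#'   count does not perturb pathway membership.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 15000L,
                       n_samples_per_class = c(16L, 16L),
                       n_pathways = 639L,
                       pathway_size_range = c(10L, 100L),
                       n_planted = 10L,
                       effect_size = 1,
                       noise_sd = 1,
                       n_unmeasured_pathways = 2L,
                       gene_overlap_fraction = 0.1,
                       class_names = c("A", "B"),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_class = as.integer(n_samples_per_class),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_planted = as.integer(n_planted),
              effect_size = effect_size,
              noise_sd = noise_sd,
              n_unmeasured_pathways = as.integer(n_unmeasured_pathways),
              gene_overlap_fraction = gene_overlap_fraction,
              class_names = as.character(class_names),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, length(n_samples_per_class) == 2L,
              all(n_samples_per_class >= 1L), n_pathways >= 1L,
              length(pathway_size_range) == 2L,
              pathway_size_range[1L] >= 1L,
              pathway_size_range[1L] <= pathway_size_range[2L],
              n_planted >= 0L, effect_size >= 0, noise_sd > 0,
              n_unmeasured_pathways >= 0L,
              n_unmeasured_pathways <= n_pathways,
              gene_overlap_fraction >= 0, gene_overlap_fraction <= 1,
              length(class_names) == 2L, !anyNA(seed))
    if (n_planted > n_pathways - n_unmeasured_pathways)
      stop("n_planted exceeds the number of measured pathways")
    if (pathway_size_range[2L] > n_genes)
      stop("pathway_size_range exceeds n_genes")
  })
  structure(cfg, class = "sim_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a labelled expression dataset with planted pathway effects
#'
#' Expression values are `baseline_g + noise`, with per-gene baselines drawn
#' once from N(7, 1.5^2) and i.i.d. Gaussian noise of SD `noise_sd`. Every
#' member gene of a planted pathway gets `effect_size` added in class A
#' samples. Pathway membership is sampled without replacement within each
#' set; a configurable fraction of each set comes from a small shared pool to
#' create gene overlap between sets. Unmeasured sets are built from gene ids
#' absent from the matrix. Identical seeds give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (labelled [expression_dataset()]),
#'   `collection` (a [pathway_collection()]) and `truth` (list: `planted`
#'   pathway names, `gene_shift` named per-gene true mean shift, `labels`
#'   per-sample classes).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sub_seeds <- .with_seed(cfg$seed, sample.int(2147483646L, 3L))

  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_a <- cfg$n_samples_per_class[1L]
  n_b <- cfg$n_samples_per_class[2L]
  n <- n_a + n_b
  sample_ids <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(rep(cfg$class_names, c(n_a, n_b)), sample_ids)

  # membership stream
  n_measured_sets <- cfg$n_pathways - cfg$n_unmeasured_pathways
  draw <- function(x, m) x[sample.int(length(x), m)]  # never 1:n fallback
  sizes <- .with_seed(sub_seeds[1L], {
    size_choices <- seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L])
    s <- size_choices[sample.int(length(size_choices), cfg$n_pathways,
                                 replace = TRUE)]
    pool_size <- min(cfg$n_genes, max(cfg$pathway_size_range[2L], 20L))
    pool <- seq_len(pool_size)
    others <- setdiff(seq_len(cfg$n_genes), pool)
    sets <- vector("list", cfg$n_pathways)
    for (k in seq_len(n_measured_sets)) {
      n_ov <- min(round(cfg$gene_overlap_fraction * s[k]), pool_size)
      n_rest <- s[k] - n_ov
      idx <- if (n_ov > 0L && length(others) >= n_rest) {
        c(draw(pool, n_ov), draw(others, n_rest))
      } else {
        draw(seq_len(cfg$n_genes), s[k])
      }
      sets[[k]] <- gene_ids[idx]
    }
    for (k in seq_len(cfg$n_unmeasured_pathways)) {
      kk <- n_measured_sets + k
      sets[[kk]] <- sprintf("UNMEASURED_G%05d", sample.int(10 * s[kk], s[kk]))
    }
    sets
  })
  names(sizes) <- sprintf("PW%04d", seq_len(cfg$n_pathways))
  planted <- names(sizes)[seq_len(cfg$n_planted)]
  descriptions <- rep("synthetic", cfg$n_pathways)
  descriptions[seq_len(cfg$n_planted)] <- "synthetic_planted"
  if (cfg$n_unmeasured_pathways > 0L)
    descriptions[n_measured_sets + seq_len(cfg$n_unmeasured_pathways)] <-
      "synthetic_unmeasured"
  collection <- pathway_collection(sizes, descriptions)

  # baseline stream (depends on n_genes only)
  baseline <- .with_seed(sub_seeds[2L],
                         stats::rnorm(cfg$n_genes, mean = 7, sd = 1.5))

  # noise stream
  noise <- .with_seed(sub_seeds[3L],
                      matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                             cfg$n_genes, n))
  values <- baseline + noise
  dimnames(values) <- list(gene_ids, sample_ids)

  gene_shift <- stats::setNames(numeric(cfg$n_genes), gene_ids)
  if (cfg$n_planted > 0L) {
    shifted <- unique(unlist(collection$genes[planted], use.names = FALSE))
    gene_shift[shifted] <- cfg$effect_size
    values[shifted, labels == cfg$class_names[1L]] <-
      values[shifted, labels == cfg$class_names[1L]] + cfg$effect_size
  }

  list(dataset = expression_dataset(values, labels),
       collection = collection,
       truth = list(planted = planted, gene_shift = gene_shift,
                    labels = labels, config = cfg))
}
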