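#' Construct an expression dataset
#'
#' Bundles a genes x samples matrix of (assumed log-scale, normalized)
#' expression values with optional binary sample class labels. Values may be
#' `NA` ("not measured"); downstream pathway means skip them.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames are sample ids, both unique.
#' @param labels optional character vector of class labels, one per sample,
#'   named by sample id or in column order. Scoring operations require exactly
#'   two distinct labels.
#' @return an object of class `expression_dataset` with elements `values` and
#'   `labels`.
#' @export
expression_dataset <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(values))
      stop("`labels` must have one entry per sample")
    if (!is.null(names(labels))) {
      if (!setequal(names(labels), colnames(values)))
        stop("label names do not match sample ids")
      labels <- labels[colnames(values)]
    } else {
      names(labels) <- colnames(values)
    }
  }
  structure(list(values = values, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Construct a pathway collection
#'
#' A named, ordered list of gene sets (GMT content). Genes are deduplicated
#' within each set; file/argument order is preserved.
#'
#' @param genes named list of character vectors (gene ids per pathway).
#' @param descriptions optional character vector, recycled "" if missing.
#' @return an object of class `pathway_collection` with elements `names`,
#'   `descriptions` and `genes`.
#' @export
pathway_collection <- function(genes, descriptions = NULL) {
  if (!is.list(genes) || is.null(names(genes)) || any(names(genes) == ""))
    stop("`genes` must be a fully named list of character vectors")
  dup <- names(genes)[duplicated(names(genes))]
  if (length(dup))
    stop("duplicate pathway name(s): ", paste(unique(dup), collapse = ", "))
  genes <- lapply(genes, function(g) {
    g <- as.character(g)
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(genes) == 0L))
    stop("empty gene set(s): ",
         paste(names(genes)[lengths(genes) == 0L], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(genes))
  if (length(descriptions) != length(genes))
    stop("`descriptions` length must match `genes`")
  structure(list(names = names(genes),
                 descriptions = as.character(descriptions),
                 genes = genes),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d gene sets (sizes %d-%d)\n",
              length(x$names), min(lengths(x$genes)), max(lengths(x$genes))))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$names)

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

.split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.parse_real <- function(x) {
  x[!nzchar(x) | x %in% c("NA", "na", "NaN")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read an expression matrix from TSV or GCT
#'
#' The plain TSV dialect has a header row of sample ids (first cell is an
#' arbitrary gene-column title) and one row per gene. The GCT v1.2 dialect has
#' a `#1.2` line, a `n_genes n_samples` line, and a `Name`/`Description`
#' header; the Description column is dropped. Empty cells become `NA`.
#' Duplicate ids and ragged rows are hard errors, never repaired.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gct"`.
#' @return an [expression_dataset()] without labels.
#' @export
read_expression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  lines <- .read_lines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks
  if (dialect == "gct") {
    if (length(lines) < 3L || !startsWith(lines[1L], "#1."))
      stop("not a GCT file (missing #1.2 header): ", path)
    dims <- .parse_real(strsplit(trimws(lines[2L]), "[ \t]+")[[1L]])
    if (length(dims) != 2L || anyNA(dims))
      stop("malformed GCT dimension line: ", lines[2L])
    body <- lines[-(1:2)]
    if (length(body) - 1L != dims[1L])
      stop(sprintf("GCT declares %d data rows but file has %d",
                   dims[1L], length(body) - 1L))
    value_start <- 3L  # after Name, Description
  } else {
    body <- lines
    value_start <- 2L
  }
  if (length(body) < 2L) stop("expression file has no data rows: ", path)
  cells <- .split_tsv(body)
  header <- cells[[1L]]
  sample_ids <- header[value_start:length(header)]
  if (dialect == "gct" && length(sample_ids) != dims[2L])
    stop(sprintf("GCT declares %d samples but header has %d",
                 dims[2L], length(sample_ids)))
  n_field <- length(header)
  offset <- if (dialect == "gct") 2L else 0L
  rows <- cells[-1L]
  widths <- lengths(rows)
  bad <- which(widths != n_field)
  if (length(bad))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1L] + 1L + offset, n_field, widths[bad[1L]]))
  gene_ids <- vapply(rows, `[[`, character(1L), 1L)
  vals <- t(vapply(rows,
                   function(r) .parse_real(r[value_start:n_field]),
                   numeric(length(sample_ids))))
  if (length(sample_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(gene_ids, sample_ids)
  expression_dataset(vals)
}

#' Write an expression matrix as TSV or GCT
#'
#' Inverse of [read_expression()]; numeric cells carry 12 significant digits
#' so that a write/read round trip reproduces values well within 1e-9.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @param dialect `"tsv"` or `"gct"`.
#' @export
write_expression <- function(dataset, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))
  body <- vapply(seq_len(nrow(v)), function(i) {
    row <- paste(fmt(v[i, ]), collapse = "\t")
    if (dialect == "gct")
      paste(rownames(v)[i], "na", row, sep = "\t")
    else
      paste(rownames(v)[i], row, sep = "\t")
  }, character(1L))
  if (dialect == "gct") {
    header <- paste(c("Name", "Description", colnames(v)), collapse = "\t")
    lines <- c("#1.2", paste(nrow(v), ncol(v), sep = "\t"), header, body)
  } else {
    lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`. Genes are
#' deduplicated within a set and blank trailing fields dropped. Lines with
#' fewer than three fields and duplicate set names are hard errors.
#'
#' @param path file path.
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  keep <- nzchar(trimws(lines))
  cells <- .split_tsv(lines)
  short <- which(keep & lengths(cells) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                 short[1L]))
  cells <- cells[keep]
  sets <- lapply(cells, function(x) x[-(1:2)])
  names(sets) <- vapply(cells, `[[`, character(1L), 1L)
  pathway_collection(sets,
                     descriptions = vapply(cells, `[[`, character(1L), 2L))
}

#' Write a pathway collection as GMT
#' @param collection a [pathway_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(seq_along(collection$names), function(k) {
    paste(c(collection$names[k], collection$descriptions[k],
            collection$genes[[k]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read binary class labels from a CLS file
#'
#' CLS dialect: line 1 `N 2 1`, line 2 `# labelA labelB`, line 3 one class
#' token per sample, mapping positionally onto the expression matrix's sample
#' order. Tokens may be the label names themselves or 0/1 indices into the
#' line-2 label order. More than two classes, or a token count other than N,
#' is a hard error.
#'
#' @param path file path.
#' @return character vector of length N with the class label of each sample.
#' @export
read_cls <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file must have 3 non-empty lines: ", path)
  head <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  n <- as.integer(head[1L])
  n_class <- as.integer(head[2L])
  if (is.na(n) || is.na(n_class))
    stop("malformed CLS header line: ", lines[1L])
  if (n_class != 2L)
    stop("only two-class CLS files are supported (header declares ",
         n_class, ")")
  lab_line <- strsplit(trimws(lines[2L]), "[ \t]+")[[1L]]
  if (lab_line[1L] != "#") stop("CLS line 2 must start with '#'")
  class_names <- lab_line[-1L]
  if (length(class_names) != 2L)
    stop("CLS line 2 must name exactly 2 classes")
  tokens <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
  if (length(tokens) != n)
    stop(sprintf("CLS declares %d samples but line 3 has %d tokens",
                 n, length(tokens)))
  if (all(tokens %in% c("0", "1"))) {
    out <- class_names[as.integer(tokens) + 1L]
  } else {
    if (!all(tokens %in% class_names))
      stop("CLS tokens not among declared class names: ",
           paste(setdiff(tokens, class_names), collapse = ", "))
    out <- tokens
  }
  if (length(unique(out)) > 2L) stop("more than 2 distinct classes in CLS")
  out
}

#' Write binary class labels as a CLS file
#' @param labels character vector of per-sample class labels (2 classes).
#' @param path output path.
#' @export
write_cls <- function(labels, path) {
  classes <- unique(labels)
  if (length(classes) != 2L) stop("CLS output requires exactly 2 classes")
  writeLines(c(paste(length(labels), 2, 1),
               paste("#", classes[1L], classes[2L]),
               paste(labels, collapse = " ")), path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; numeric columns are rendered with 12
#' significant digits so re-reading reproduces values within 1e-9. Row order
#' is written as given (callers establish the deterministic order).
#'
#' @param rows a non-empty data frame (e.g. a perturbation table or an
#'   activity matrix converted via `as.data.frame`).
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L || ncol(rows) == 0L)
    stop("refusing to write an empty table")
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.12g", out[[j]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Collapse duplicate gene symbols in an expression dataset
#'
#' Gene ids are optionally uppercased (MSigDB symbols are uppercase while
#' platform ids vary), and rows mapping to the same symbol are collapsed by
#' mean (default) or max, ignoring missing cells; a cell that is missing in
#' all collapsed rows stays missing. Row order follows the first occurrence
#' of each symbol.
#'
#' @param dataset an [expression_dataset()].
#' @param method `"mean"` or `"max"`.
#' @param uppercase uppercase gene ids before collapsing (default `TRUE`).
#' @return an [expression_dataset()] with unique gene symbols.
#' @export
collapse_genes <- function(dataset, method = c("mean", "max"),
                           uppercase = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  ids <- rownames(v)
  if (uppercase) ids <- toupper(ids)
  if (!anyDuplicated(ids)) {
    rownames(v) <- ids
    return(expression_dataset(v, dataset$labels))
  }
  uniq <- unique(ids)
  idx <- split(seq_along(ids), factor(ids, levels = uniq))
  agg <- function(i) {
    block <- v[i, , drop = FALSE]
    if (method == "mean") {
      out <- colMeans(block, na.rm = TRUE)
    } else {
      out <- suppressWarnings(apply(block, 2L, max, na.rm = TRUE))
    }
    out[!is.finite(out) & colSums(!is.na(block)) == 0L] <- NA_real_
    out
  }
  res <- t(vapply(idx, agg, numeric(ncol(v))))
  dimnames(res) <- list(uniq, colnames(v))
  expression_dataset(res, dataset$labels)
}

#' Attach class labels to an expression dataset
#' @param dataset an [expression_dataset()].
#' @param labels per-sample class labels (see [expression_dataset()]).
#' @return the dataset with labels set.
#' @export
set_labels <- function(dataset, labels) {
  expression_dataset(dataset$values, labels)
}
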