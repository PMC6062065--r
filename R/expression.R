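#' Construct a two-class expression dataset
#'
#' Container for a genes x samples expression matrix with a binary class
#' label (0 = normal, 1 = disease) per sample.  Validates shape, identifier
#' uniqueness and label completeness; both classes must be non-empty.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @param labels integer vector of 0/1, either named by sample id or in
#'   column order of `values`.
#' @param normalised logical; has the matrix already been z-scored?
#' @param zero_variance optional logical per-gene flag marking rows that had
#'   zero variance before normalisation.
#' @return an object of class `ggi_expression` with elements `values`,
#'   `labels` (named integer), `normalised` and `zero_variance`.
#' @seealso [read_expression()], [zscore_normalise()], [extract_lists()]
#' @export
expression_dataset <- function(values, labels, normalised = FALSE,
                               zero_variance = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  samples <- colnames(values)
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values)) {
      stop("unnamed `labels` must match the sample count")
    }
    names(labels) <- samples
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing)) {
    stop("missing label for sample(s): ", paste(missing, collapse = ", "))
  }
  labels <- labels[samples]
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  labels <- as.integer(labels)
  names(labels) <- samples
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the labels")
  }
  if (any(!is.finite(values))) stop("non-finite expression value")
  if (is.null(zero_variance)) {
    zero_variance <- setNames(rep(FALSE, nrow(values)), rownames(values))
  }
  structure(
    list(values = values, labels = labels, normalised = isTRUE(normalised),
         zero_variance = zero_variance),
    class = "ggi_expression"
  )
}

#' @export
print.ggi_expression <- function(x, ...) {
  cat(sprintf(
    "ggi_expression: %d genes x %d samples (%d class 0, %d class 1), %s\n",
    nrow(x$values), ncol(x$values), sum(x$labels == 0L), sum(x$labels == 1L),
    if (x$normalised) "z-scored" else "raw"))
  invisible(x)
}

#' Gene and sample identifiers of a dataset
#' @param ds a `ggi_expression` object.
#' @return character vector of identifiers.
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(ds) colnames(ds$values)

#' Read a two-class expression dataset from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column of gene ids; the labels file has two columns,
#' `sample_id<TAB>label` with label in \{0, 1\} (a header line is detected
#' and skipped).  Duplicate gene rows are collapsed to their elementwise
#' mean with a warning.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the two-column label TSV.
#' @return an un-normalised [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression matrix needs gene ids plus >=1 sample")
  genes <- as.character(raw[[1]])
  samples <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value for gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing expression value for gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene row(s) by mean: ",
            paste(head(dup, 5), collapse = ", "))
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  dimnames(num) <- list(genes, samples)

  lab_raw <- read.delim(labels_path, header = FALSE, sep = "\t",
                        colClasses = "character")
  if (ncol(lab_raw) < 2) stop("labels file must have two columns")
  if (!lab_raw[1, 2] %in% c("0", "1")) lab_raw <- lab_raw[-1, , drop = FALSE]
  if (any(!lab_raw[[2]] %in% c("0", "1"))) {
    stop("labels must be 0 or 1; offending value: ",
         lab_raw[[2]][which(!lab_raw[[2]] %in% c("0", "1"))[1]])
  }
  labels <- setNames(as.integer(lab_raw[[2]]), as.character(lab_raw[[1]]))
  missing <- setdiff(samples, names(labels))
  if (length(missing)) {
    stop("missing label for sample(s): ", paste(missing, collapse = ", "))
  }
  expression_dataset(num, labels[samples])
}

#' Write an expression dataset back to TSV files
#'
#' Inverse of [read_expression()]; full double precision is kept so a
#' write/read round trip is value-identical.
#'
#' @param ds a `ggi_expression` object.
#' @param matrix_path,labels_path output paths.
#' @return `ds`, invisibly.
#' @export
write_expression <- function(ds, matrix_path, labels_path) {
  df <- data.frame(gene_id = gene_ids(ds),
                   format(ds$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(ds))
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(sample_id = names(ds$labels), label = unname(ds$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' Z-score each gene row across all samples
#'
#' Per gene, across both classes pooled: subtract the row mean and divide
#' by the row sample standard deviation (denominator n - 1).  Rows with
#' zero variance become all-zero and are flagged in `zero_variance` (they
#' are kept, not dropped, so the gene universe stays aligned with the
#' interactome).  The transform is idempotent in effect; re-normalising is
#' a no-op up to rounding.
#'
#' @param ds a `ggi_expression` object.
#' @return the normalised dataset with `normalised = TRUE`.
#' @export
zscore_normalise <- function(ds) {
  stopifnot(inherits(ds, "ggi_expression"))
  v <- ds$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    ggi_log(sum(flat), " zero-variance gene row(s) set to all-zero")
    sdv[flat] <- 1
  }
  out <- (v - mu) / sdv
  out[flat, ] <- 0
  expression_dataset(out, ds$labels, normalised = TRUE,
                     zero_variance = setNames(flat | ds$zero_variance,
                                              rownames(v)))
}

#' Split a gene's expression row by class label
#'
#' Returns the expression value lists of one gene for class-0 and class-1
#' samples, in sample order — the E_L0 / E_L1 lists every pair feature is
#' built from.
#'
#' @param ds a `ggi_expression` object.
#' @param gene gene identifier present in `ds`.
#' @return list with numeric vectors `E_L0` and `E_L1`.
#' @export
extract_lists <- function(ds, gene) {
  stopifnot(inherits(ds, "ggi_expression"))
  if (!gene %in% gene_ids(ds)) stop("unknown gene: ", gene)
  row <- ds$values[gene, ]
  list(E_L0 = unname(row[ds$labels == 0L]),
       E_L1 = unname(row[ds$labels == 1L]))
}
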