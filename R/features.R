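#' Fixed order of the 22 pair features
#'
#' Column order of every feature matrix produced by the package: per-list
#' means, sample standard deviations and max-minus-min ranges for the four
#' class-conditional expression lists of a pair, Welch t statistics for the
#' four list pairings, within-class Pearson correlations, within-class
#' mutual information, and cross-class mutual information per gene (after
#' order-preserving undersampling equalises list lengths).
#'
#' @return character vector of length 22.
#' @export
pair_feature_names <- function() {
  c("Mean_A_L0", "Mean_A_L1", "Mean_B_L0", "Mean_B_L1",
    "SD_A_L0", "SD_A_L1", "SD_B_L0", "SD_B_L1",
    "dMm_A_L0", "dMm_A_L1", "dMm_B_L0", "dMm_B_L1",
    "WT_A_L0_B_L0", "WT_A_L1_B_L1", "WT_A_L0_A_L1", "WT_B_L0_B_L1",
    "PCC_A_L0_B_L0", "PCC_A_L1_B_L1",
    "MI_A_L0_B_L0", "MI_A_L1_B_L1", "MI_A_L0_A_L1", "MI_B_L0_B_L1")
}

#' Construct a gene pair with its four class-conditional expression lists
#'
#' Pair identity is unordered; `gene_a`/`gene_b` keep the order given (the
#' canonical id sorts them).  The two genes must be distinct and observed
#' on the same samples per class.
#'
#' @param gene_a,gene_b gene identifiers.
#' @param E_A_L0,E_A_L1,E_B_L0,E_B_L1 numeric expression lists: gene X in
#'   class-0 / class-1 samples.
#' @return an object of class `ggi_pair`.
#' @export
gene_pair <- function(gene_a, gene_b, E_A_L0, E_A_L1, E_B_L0, E_B_L1) {
  if (gene_a == gene_b) stop("a gene pair needs two distinct genes")
  if (length(E_A_L0) != length(E_B_L0) || length(E_A_L1) != length(E_B_L1)) {
    stop("class list lengths differ between the two genes")
  }
  structure(
    list(gene_a = gene_a, gene_b = gene_b,
         E_A_L0 = as.numeric(E_A_L0), E_A_L1 = as.numeric(E_A_L1),
         E_B_L0 = as.numeric(E_B_L0), E_B_L1 = as.numeric(E_B_L1),
         id = pair_id(gene_a, gene_b)),
    class = "ggi_pair"
  )
}

#' Build a gene pair from a dataset
#' @param ds a normalised `ggi_expression` object.
#' @param gene_a,gene_b gene identifiers present in `ds`.
#' @return a `ggi_pair`.
#' @export
pair_from_dataset <- function(ds, gene_a, gene_b) {
  la <- extract_lists(ds, gene_a)
  lb <- extract_lists(ds, gene_b)
  gene_pair(gene_a, gene_b, la$E_L0, la$E_L1, lb$E_L0, lb$E_L1)
}

#' Welch's t statistic
#'
#' `(mean(x) - mean(y)) / sqrt(s_x^2/|x| + s_y^2/|y|)` with sample
#' variances (denominator n - 1).  Only the statistic is returned — it is
#' used as a feature, not a test.  Degenerate inputs stay finite: if both
#' variance terms are zero the result is 0 for equal means and a signed
#' sentinel of +/-1e12 otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a single number.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  d <- mean(x) - mean(y)
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  if (se2 == 0) {
    if (d == 0) return(0)
    ggi_log("zero-variance Welch t; returning signed sentinel")
    return(sign(d) * 1e12)
  }
  d / sqrt(se2)
}

#' Pearson correlation with a zero-variance guard
#'
#' Standard product-moment correlation; if either input is constant the
#' correlation is undefined and 0 is returned so downstream feature
#' matrices stay finite.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a number in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("pcc: length mismatch")
  stopifnot(length(x) >= 2)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0) return(0)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

# Equal-width bin index over a vector's own [min, max]; a constant vector
# puts all mass in bin 1.
equal_width_bins <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  i <- floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L
  i[i > bins] <- bins
  as.integer(i)
}

#' Mutual information by equal-width binning
#'
#' Discretises `x` and `y` independently into `bins` equal-width bins over
#' each vector's own range and returns
#' `sum p(i,j) log2( p(i,j) / (p(i) p(j)) )` over non-empty joint cells,
#' in bits.  A constant input has zero marginal entropy, so MI is 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param bins number of bins per axis (default 10).
#' @return a non-negative number (bits).
#' @export
mutual_information <- function(x, y, bins = 10) {
  if (length(x) != length(y)) stop("mutual_information: length mismatch")
  stopifnot(length(x) >= 2, bins >= 1)
  n <- length(x)
  bx <- equal_width_bins(x, bins)
  by <- equal_width_bins(y, bins)
  joint <- matrix(tabulate((bx - 1L) * bins + by, bins * bins),
                  nrow = bins, byrow = TRUE) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  cells <- which(joint > 0, arr.ind = TRUE)
  pij <- joint[cells]
  mi <- sum(pij * log2(pij / (px[cells[, 1]] * py[cells[, 2]])))
  max(0, mi)
}

#' Order-preserving random undersampling
#'
#' Draws `target_len` elements uniformly without replacement and returns
#' them in their original relative order; deterministic given `rng_seed`.
#' Used to equalise class list lengths before cross-class mutual
#' information.
#'
#' @param longer numeric vector.
#' @param target_len number of elements to keep (<= `length(longer)`).
#' @param rng_seed integer seed.
#' @return numeric vector of length `target_len`.
#' @export
undersample <- function(longer, target_len, rng_seed) {
  if (target_len > length(longer)) {
    stop("undersample: target_len exceeds input length")
  }
  stopifnot(target_len >= 1)
  if (target_len == length(longer)) return(longer)
  keep <- with_seed(rng_seed, sort(sample.int(length(longer), target_len)))
  longer[keep]
}

# Cross-class MI for one gene: undersample the longer list to the shorter
# one's length (seed derived from the gene id so the A<->B swap symmetry
# is exact), pair elements by position, average over `repeats` draws.
cross_class_mi <- function(l0, l1, bins, rng_seed, gene, repeats = 1) {
  m <- min(length(l0), length(l1))
  vals <- vapply(seq_len(repeats), function(r) {
    s <- derive_seed(rng_seed, paste0(gene, ":", r))
    mutual_information(undersample(l0, m, s),
                       undersample(l1, m, derive_seed(s, "b")), bins)
  }, numeric(1))
  mean(vals)
}

#' Compute the 22-feature vector of a gene pair
#'
#' Fills, in the fixed order of [pair_feature_names()]: the mean, sample
#' standard deviation and range of each of the four class-conditional
#' lists; Welch t for (A_L0, B_L0), (A_L1, B_L1), (A_L0, A_L1),
#' (B_L0, B_L1) — sign convention first minus second; Pearson correlation
#' within each class; mutual information within each class; and
#' cross-class mutual information per gene after undersampling the larger
#' class to the smaller one.
#'
#' @param pair a `ggi_pair`.
#' @param bins histogram bins for mutual information (default 10).
#' @param rng_seed integer seed for the undersampling streams.
#' @param mi_repeats how many undersampling draws to average for the
#'   cross-class MI features (default 1).
#' @return named numeric vector of length 22, always finite.
#' @export
compute_features <- function(pair, bins = 10, rng_seed = 1L, mi_repeats = 1L) {
  stopifnot(inherits(pair, "ggi_pair"))
  lists <- pair[c("E_A_L0", "E_A_L1", "E_B_L0", "E_B_L1")]
  if (any(lengths(lists) < 2)) stop("each expression list needs >= 2 values")
  a0 <- pair$E_A_L0; a1 <- pair$E_A_L1
  b0 <- pair$E_B_L0; b1 <- pair$E_B_L1
  v <- c(
    mean(a0), mean(a1), mean(b0), mean(b1),
    stats::sd(a0), stats::sd(a1), stats::sd(b0), stats::sd(b1),
    max(a0) - min(a0), max(a1) - min(a1),
    max(b0) - min(b0), max(b1) - min(b1),
    welch_t(a0, b0), welch_t(a1, b1), welch_t(a0, a1), welch_t(b0, b1),
    pcc(a0, b0), pcc(a1, b1),
    mutual_information(a0, b0, bins), mutual_information(a1, b1, bins),
    cross_class_mi(a0, a1, bins, rng_seed, pair$gene_a, mi_repeats),
    cross_class_mi(b0, b1, bins, rng_seed, pair$gene_b, mi_repeats)
  )
  setNames(v, pair_feature_names())
}

#' Feature matrix for a list of gene pairs
#'
#' One row per pair in input order, columns fixed as
#' [pair_feature_names()]; row names are canonical pair ids.  Each pair's
#' random stream is derived from `rng_seed` and its gene ids, so rows do
#' not depend on input order and repeated calls are bit-identical.
#'
#' @param pairs non-empty list of `ggi_pair` objects.
#' @inheritParams compute_features
#' @return numeric matrix `length(pairs)` x 22.
#' @export
feature_matrix <- function(pairs, bins = 10, rng_seed = 1L, mi_repeats = 1L) {
  if (!length(pairs)) stop("empty pair list")
  rows <- vapply(pairs, compute_features, numeric(22),
                 bins = bins, rng_seed = rng_seed, mi_repeats = mi_repeats)
  m <- t(rows)
  rownames(m) <- vapply(pairs, `[[`, character(1), "id")
  m
}

#' Write a feature matrix (optionally labelled) to TSV
#'
#' @param X feature matrix from [feature_matrix()].
#' @param path output TSV path.
#' @param labels optional 0/1 vector aligned with the rows.
#' @return `X`, invisibly.
#' @export
write_feature_matrix <- function(X, path, labels = NULL) {
  genes <- do.call(rbind, strsplit(rownames(X), "|", fixed = TRUE))
  df <- data.frame(pair_id = rownames(X), gene_a = genes[, 1],
                   gene_b = genes[, 2],
                   format(X, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.integer(labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(X)
}

#' Read a labelled feature matrix written by [write_feature_matrix()]
#' @param path TSV path.
#' @return list with `X` (matrix) and `labels` (integer vector or NULL).
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  labels <- if ("label" %in% colnames(df)) as.integer(df$label)
  X <- as.matrix(df[, pair_feature_names(), drop = FALSE])
  rownames(X) <- df$pair_id
  list(X = X, labels = labels)
}
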