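#' Derive a child RNG seed from a base seed and a string salt
#'
#' Deterministic 31-ary string hash folded with the base seed, reduced
#' modulo a prime below 2^31 so the result is always a valid R seed.
#' Used to give every gene pair (and every cross-validation fold) its own
#' reproducible random stream.
#'
#' @param seed integer base seed.
#' @param salt character scalar mixed into the hash.
#' @return a single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(salt) == 1L)
  mod <- 2147480009  # prime < 2^31; doubles stay exact throughout
  h <- as.double(seed) %% mod
  for (code in utf8ToInt(as.character(salt))) {
    h <- (h * 31 + code) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonical unordered pair id, lexicographic: "A|B" with A <= B.
pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Normalise an edge container (2+ column data frame or matrix) to a
# canonical data.frame(gene_a, gene_b[, confidence]) with gene_a <= gene_b,
# self-loops rejected and duplicates collapsed (first occurrence kept).
canonical_edges <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x) || ncol(x) < 2) {
    stop("edge set must be a data frame with at least two columns")
  }
  a <- as.character(x[[1]])
  b <- as.character(x[[2]])
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty gene identifier in edge set")
  if (any(a == b)) stop("self-loop in edge set: ", a[which(a == b)[1]])
  out <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 3) out$confidence <- as.numeric(x[[3]])
  keep <- !duplicated(pair_id(out$gene_a, out$gene_b))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Membership of canonical pairs in a canonical edge data.frame.
edges_in <- function(edges, other) {
  pair_id(edges$gene_a, edges$gene_b) %in% pair_id(other$gene_a, other$gene_b)
}

ggi_log <- function(...) {
  message("[ggiforest] ", ...)
}
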