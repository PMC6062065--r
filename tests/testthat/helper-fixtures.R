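# Programmatic fixtures: everything is built in code at test time.

# 3-gene x 4-sample toy TSV pair; returns the two paths.
toy_expression_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                 labels = c(s1 = 0, s2 = 0, s3 = 1, s4 = 1),
                                 dup_gene = FALSE) {
  rows <- c("gene_id\ts1\ts2\ts3\ts4",
            "G1\t1\t2\t3\t4",
            "G2\t5\t5\t5\t5",
            "G3\t2\t4\t6\t8")
  if (dup_gene) rows <- c(rows, "G1\t3\t4\t5\t6")
  mp <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  writeLines(rows, mp)
  writeLines(c("sample_id\tlabel",
               paste(names(labels), labels, sep = "\t")), lp)
  list(matrix = mp, labels = lp)
}

# path graph a-b-c-d, unscored
path_interactome <- function() {
  interactome(data.frame(gene_a = c("a", "b", "c"),
                         gene_b = c("b", "c", "d")))
}

# random gene pair with class sizes drawn in [5, 50]
random_pair <- function(seed) {
  set.seed(seed)
  n0 <- sample(5:50, 1)
  n1 <- sample(5:50, 1)
  gene_pair(paste0("A", seed), paste0("B", seed),
            rnorm(n0, sd = runif(1, 0.5, 2)),
            rnorm(n1, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2)),
            rnorm(n0, sd = runif(1, 0.5, 2)),
            rnorm(n1, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2)))
}

# scaled-down simulation for cheap unit tests
small_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 80L, n_samples_class0 = 12L, n_samples_class1 = 16L,
               n_disease_pairs = 10L, rng_seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# dataset with a perfectly learnable pair structure for classifier tests:
# feature 1 separates the classes, the rest is noise
separable_xy <- function(n = 60, p = 22, seed = 1L) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[, 1] <- y * 4 + rnorm(n, sd = 0.1)
  list(X = X, y = y)
}

# hand-built forest of single-leaf trees with the given class-1 votes
stub_forest <- function(votes) {
  trees <- lapply(votes, function(v) {
    matrix(c(0, 0, 0, 0, 1 - v, v), 1, 6,
           dimnames = list(NULL, c("feature", "threshold", "left", "right",
                                   "n0", "n1")))
  })
  structure(list(trees = trees, importance = setNames(numeric(2), c("x", "y")),
                 n_trees = length(votes), features_per_split = 1L,
                 bootstrap_n = 1L, feature_names = c("x", "y"),
                 class_counts = c(`0` = 1L, `1` = 1L), rng_seed = 0L),
            class = "ggi_forest")
}
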