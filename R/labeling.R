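#' Construct an interactome (undirected gene graph)
#'
#' Edges are stored once in canonical unordered form (lexicographically
#' sorted endpoints); self-loops are rejected and duplicates dropped.  An
#' optional confidence score per edge supports top-fraction filtering.
#'
#' @param edges data frame (or 2/3-column matrix) with gene id columns and
#'   an optional numeric confidence column.
#' @return an object of class `ggi_interactome` wrapping the canonical
#'   edge data frame.
#' @export
interactome <- function(edges) {
  e <- canonical_edges(edges)
  structure(list(edges = e), class = "ggi_interactome")
}

#' @export
print.ggi_interactome <- function(x, ...) {
  cat(sprintf("ggi_interactome: %d edges, %d genes%s\n", nrow(x$edges),
              length(interactome_genes(x)),
              if ("confidence" %in% colnames(x$edges)) ", scored" else ""))
  invisible(x)
}

#' Genes appearing in an interactome
#' @param net a `ggi_interactome`.
#' @return sorted character vector of gene ids.
#' @export
interactome_genes <- function(net) {
  sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
}

#' Read an interactome or answer-set edge list from TSV
#'
#' Expects 2 or 3 tab-separated columns, `gene_a<TAB>gene_b[<TAB>confidence]`;
#' a header line is detected (third field non-numeric or first line matching
#' `gene_a`) and skipped.
#'
#' @param path TSV path.
#' @return a `ggi_interactome`.
#' @export
read_interactome <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) && (identical(tolower(df[1, 1]), "gene_a") ||
                   (ncol(df) >= 3 && is.na(suppressWarnings(as.numeric(df[1, 3])))))) {
    df <- df[-1, , drop = FALSE]
  }
  if (!nrow(df)) stop("empty edge list: ", path)
  interactome(df)
}

#' Write an interactome to TSV
#' @param net a `ggi_interactome`.
#' @param path output path.
#' @return `net`, invisibly.
#' @export
write_interactome <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' Keep the top fraction of edges by confidence
#'
#' Retains the `ceiling(top_fraction * |edges|)` highest-confidence edges
#' (the "top 5 or 10 percent" regime used for scored functional networks).
#' Ties at the cutoff are broken by lexicographic pair id so the result is
#' deterministic.
#'
#' @param net a `ggi_interactome` whose edges all carry confidence when
#'   `top_fraction < 1`.
#' @param top_fraction fraction in (0, 1].
#' @return a filtered `ggi_interactome`.
#' @export
filter_by_confidence <- function(net, top_fraction) {
  stopifnot(inherits(net, "ggi_interactome"),
            top_fraction > 0, top_fraction <= 1)
  if (top_fraction == 1) return(net)
  e <- net$edges
  if (!"confidence" %in% colnames(e) || anyNA(e$confidence)) {
    stop("confidence scores required for top-fraction filtering")
  }
  k <- ceiling(top_fraction * nrow(e))
  ord <- order(-e$confidence, pair_id(e$gene_a, e$gene_b))
  interactome(e[ord[seq_len(k)], , drop = FALSE])
}

#' Boost an answer set by seed-gene neighbourhood expansion
#'
#' Let N1 be all first neighbours of the seed genes in the interactome
#' (iterated `k` times for deeper neighbourhoods).  Returns the answer set
#' plus, in `"incident"` mode, every interactome edge with at least one
#' endpoint in `seeds` union N1, or, in `"induced"` mode, only edges with
#' both endpoints there.  Seeds absent from the interactome contribute
#' nothing; with no seeds the answer set is returned unchanged.
#'
#' @param answer_set data frame of curated positive pairs (2 columns).
#' @param net a `ggi_interactome`.
#' @param seeds character vector of disease seed genes (may be empty).
#' @param k neighbourhood depth (default 1, i.e. first neighbours).
#' @param mode `"incident"` (default) or `"induced"`.
#' @return canonical edge data frame of positives.
#' @export
expand_positives <- function(answer_set, net, seeds, k = 1L,
                             mode = c("incident", "induced")) {
  mode <- match.arg(mode)
  ans <- canonical_edges(answer_set)
  if (!length(seeds)) return(ans)
  e <- net$edges
  reach <- unique(as.character(seeds))
  for (i in seq_len(k)) {
    nb <- c(e$gene_b[e$gene_a %in% reach], e$gene_a[e$gene_b %in% reach])
    reach <- union(reach, nb)
  }
  keep <- if (mode == "incident") {
    e$gene_a %in% reach | e$gene_b %in% reach
  } else {
    e$gene_a %in% reach & e$gene_b %in% reach
  }
  canonical_edges(rbind(ans[, c("gene_a", "gene_b")],
                        e[keep, c("gene_a", "gene_b")]))
}

#' Sample non-interacting negative pairs
#'
#' Draws `n` distinct unordered pairs uniformly from the gene universe,
#' excluding the positives and (by default) every interactome edge, so the
#' class-0 pairs represent non-interacting genes.  Deterministic given
#' `rng_seed`; fails with counts if too few eligible pairs exist.
#'
#' @param positives canonical edge data frame of class-1 pairs.
#' @param gene_universe character vector of candidate gene ids.
#' @param net a `ggi_interactome` whose edges are excluded (set
#'   `exclude_net = FALSE` to exclude only the positives).
#' @param n number of negatives to draw.
#' @param rng_seed integer seed.
#' @param exclude_net exclude all interactome edges (default TRUE).
#' @return canonical edge data frame with `n` rows.
#' @export
sample_negatives <- function(positives, gene_universe, net, n, rng_seed,
                             exclude_net = TRUE) {
  u <- sort(unique(as.character(gene_universe)))
  nu <- length(u)
  if (nu < 2) stop("need at least two genes to sample pairs")
  excl <- positives[, c("gene_a", "gene_b")]
  if (exclude_net) {
    excl <- rbind(excl, net$edges[, c("gene_a", "gene_b")])
  }
  excl <- canonical_edges(excl)
  in_univ <- excl$gene_a %in% u & excl$gene_b %in% u
  n_excl <- sum(in_univ)
  total <- nu * (nu - 1) / 2
  if (total - n_excl < n) {
    stop(sprintf(
      "cannot sample %d negatives: universe of %d genes has %.0f pairs, %d excluded",
      n, nu, total, n_excl))
  }
  excl_ids <- pair_id(excl$gene_a, excl$gene_b)

  neg <- with_seed(rng_seed, {
    if (total <= 200000) {
      # small universe: enumerate all pairs and sample exactly
      cmb <- utils::combn(u, 2)
      ids <- pair_id(cmb[1, ], cmb[2, ])
      ok <- which(!ids %in% excl_ids)
      take <- sample(ok, n)
      data.frame(gene_a = cmb[1, take], gene_b = cmb[2, take],
                 stringsAsFactors = FALSE)
    } else {
      # large universe: rejection-sample (uniform over eligible pairs)
      got <- character(0)
      out_a <- character(n)
      out_b <- character(n)
      found <- 0L
      while (found < n) {
        m <- max(2L * (n - found), 100L)
        i <- sample.int(nu, m, replace = TRUE)
        j <- sample.int(nu, m, replace = TRUE)
        keep <- i != j
        a <- pmin(u[i[keep]], u[j[keep]])
        b <- pmax(u[i[keep]], u[j[keep]])
        ids <- pair_id(a, b)
        new <- !(ids %in% excl_ids) & !(ids %in% got) & !duplicated(ids)
        take <- which(new)
        if (length(take) > n - found) take <- take[seq_len(n - found)]
        idx <- found + seq_along(take)
        out_a[idx] <- a[take]
        out_b[idx] <- b[take]
        got <- c(got, ids[take])
        found <- found + length(take)
      }
      data.frame(gene_a = out_a, gene_b = out_b, stringsAsFactors = FALSE)
    }
  })
  canonical_edges(neg)
}

#' Build the balanced labelled pair set
#'
#' Positives are the curated answer set, boosted by seed neighbourhood
#' expansion when seeds are given, or unioned with the interactome's edges
#' when they are not (the no-seed regime).  Pairs involving genes absent
#' from the expression dataset are dropped (and counted in a log message);
#' negatives are then sampled to match the surviving positive count, so
#' the output is always balanced.
#'
#' @param answer_set data frame of curated positive pairs.
#' @param net a `ggi_interactome`.
#' @param seeds character vector of seed genes, or `NULL` for the no-seed
#'   regime.
#' @param ds a `ggi_expression` dataset defining the gene universe.
#' @param rng_seed integer seed for negative sampling.
#' @param k,mode passed to [expand_positives()].
#' @param exclude_net passed to [sample_negatives()].
#' @param include_net_without_seeds in the no-seed regime, union the
#'   interactome edges into the positives (default TRUE).
#' @return an object of class `ggi_labeled_set`: data frame `pairs` with
#'   columns `gene_a`, `gene_b`, `label` (1/0) and `provenance`
#'   (`answer_set` / `seed_expansion` / `random_negative`).
#' @export
build_labeled_set <- function(answer_set, net, seeds, ds, rng_seed,
                              k = 1L, mode = "incident", exclude_net = TRUE,
                              include_net_without_seeds = TRUE) {
  stopifnot(inherits(net, "ggi_interactome"), inherits(ds, "ggi_expression"))
  ans <- canonical_edges(answer_set)
  pos <- if (!is.null(seeds) && length(seeds)) {
    expand_positives(ans, net, seeds, k = k, mode = mode)
  } else if (include_net_without_seeds) {
    canonical_edges(rbind(ans[, c("gene_a", "gene_b")],
                          net$edges[, c("gene_a", "gene_b")]))
  } else {
    ans
  }
  provenance <- ifelse(edges_in(pos, ans), "answer_set", "seed_expansion")

  universe <- gene_ids(ds)
  present <- pos$gene_a %in% universe & pos$gene_b %in% universe
  if (any(!present)) {
    ggi_log(sum(!present), " positive pair(s) dropped: gene absent from expression data")
  }
  pos <- pos[present, , drop = FALSE]
  provenance <- provenance[present]
  if (!nrow(pos)) stop("no positive pairs remain after gene-universe restriction")

  neg <- sample_negatives(pos, universe, net, nrow(pos), rng_seed,
                          exclude_net = exclude_net)
  pairs <- rbind(
    data.frame(gene_a = pos$gene_a, gene_b = pos$gene_b, label = 1L,
               provenance = provenance, stringsAsFactors = FALSE),
    data.frame(gene_a = neg$gene_a, gene_b = neg$gene_b, label = 0L,
               provenance = "random_negative", stringsAsFactors = FALSE)
  )
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "ggi_labeled_set")
}

#' @export
print.ggi_labeled_set <- function(x, ...) {
  cat(sprintf("ggi_labeled_set: %d positives, %d negatives\n",
              sum(x$pairs$label == 1L), sum(x$pairs$label == 0L)))
  invisible(x)
}

#' Write a labelled pair set to TSV
#' @param ls a `ggi_labeled_set`.
#' @param path output path.
#' @return `ls`, invisibly.
#' @export
write_labeled_set <- function(ls, path) {
  df <- cbind(pair_id = pair_id(ls$pairs$gene_a, ls$pairs$gene_b), ls$pairs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ls)
}

#' Read a seed-gene list (one gene id per line)
#' @param path file path.
#' @return character vector.
#' @export
read_seeds <- function(path) {
  s <- readLines(path)
  s <- trimws(s)
  s[nzchar(s)]
}
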