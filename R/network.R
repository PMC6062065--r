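#' Candidate gene pairs: interactome edges present in a dataset
#'
#' Restricts the interactome to edges whose both genes occur in the
#' expression dataset and returns them as [gene_pair()] objects carrying
#' the class-conditional expression lists — the biologically anchored
#' candidate set a trained model is applied to.
#'
#' @param ds a (normalised) `ggi_expression` dataset.
#' @param net a `ggi_interactome`.
#' @return list of `ggi_pair` objects.
#' @export
candidate_pairs <- function(ds, net) {
  stopifnot(inherits(ds, "ggi_expression"), inherits(net, "ggi_interactome"))
  u <- gene_ids(ds)
  e <- net$edges
  keep <- e$gene_a %in% u & e$gene_b %in% u
  if (!any(keep)) {
    stop("no interactome edge maps into the expression dataset; ",
         "check that gene identifiers use the same namespace")
  }
  e <- e[keep, , drop = FALSE]
  lists <- lapply(setNames(nm = unique(c(e$gene_a, e$gene_b))),
                  extract_lists, ds = ds)
  Map(function(a, b) {
    gene_pair(a, b, lists[[a]]$E_L0, lists[[a]]$E_L1,
              lists[[b]]$E_L0, lists[[b]]$E_L1)
  }, e$gene_a, e$gene_b, USE.NAMES = FALSE)
}

#' Classify candidate pairs into a predicted GGI network
#'
#' Computes the 22 features for every candidate, applies the trained
#' forest, and keeps the pairs predicted to interact (vote score above the
#' 0.5 majority threshold) as the edges of the predicted network.
#'
#' @param model a `ggi_forest`.
#' @param candidates list of `ggi_pair` objects (see [candidate_pairs()]).
#' @param bins,rng_seed,mi_repeats passed to [feature_matrix()].
#' @param seeds optional character vector used to flag seed genes among
#'   the network's nodes.
#' @return an object of class `ggi_network`: list with `edges` (data frame
#'   `gene_a`, `gene_b`, `score`), `nodes` (data frame `node`, `is_seed`).
#' @export
classify_network <- function(model, candidates, bins = 10, rng_seed = 1L,
                             mi_repeats = 1L, seeds = character(0)) {
  stopifnot(inherits(model, "ggi_forest"))
  X <- feature_matrix(candidates, bins = bins, rng_seed = rng_seed,
                      mi_repeats = mi_repeats)
  p <- predict(model, X)
  keep <- p$labels == 1L
  if (!any(keep)) {
    warning("model predicted no interacting pair; empty network returned")
  }
  ed <- data.frame(
    gene_a = vapply(candidates[keep], `[[`, character(1), "gene_a"),
    gene_b = vapply(candidates[keep], `[[`, character(1), "gene_b"),
    score = p$scores[keep], stringsAsFactors = FALSE)
  if (nrow(ed)) {
    swap <- ed$gene_a > ed$gene_b
    tmp <- ed$gene_a[swap]
    ed$gene_a[swap] <- ed$gene_b[swap]
    ed$gene_b[swap] <- tmp
    ed <- ed[order(pair_id(ed$gene_a, ed$gene_b)), , drop = FALSE]
    rownames(ed) <- NULL
  }
  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  structure(
    list(edges = ed,
         nodes = data.frame(node = nodes, is_seed = nodes %in% seeds,
                            stringsAsFactors = FALSE)),
    class = "ggi_network"
  )
}

#' @export
print.ggi_network <- function(x, ...) {
  cat(sprintf("ggi_network: %d nodes, %d predicted edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a predicted network
#' @param net a `ggi_network`.
#' @return named integer vector, one entry per node.
#' @export
network_degrees <- function(net) {
  nodes <- net$nodes$node
  d <- table(factor(c(net$edges$gene_a, net$edges$gene_b), levels = nodes))
  setNames(as.integer(d), nodes)
}

#' Extract the top-degree hub subnetwork
#'
#' Ranks nodes by degree in the predicted network (ties broken by
#' lexicographic id), takes the top `top_k` as hubs, and returns the
#' expanded subnetwork: the hubs, all their direct neighbours, and every
#' predicted edge with at least one hub endpoint (hub-hub edges
#' included).  `mode = "induced"` instead keeps only edges with both
#' endpoints among the hubs.
#'
#' @param net a non-empty `ggi_network`.
#' @param top_k number of hub genes (default 20); if it exceeds the node
#'   count, all nodes are used with a warning.
#' @param mode `"expanded"` (default) or `"induced"`.
#' @return list with `hubs` (character), `nodes` (data frame `node`,
#'   `degree` in the full network, `is_hub`, `is_seed`), `edges` (data
#'   frame `gene_a`, `gene_b`, `score`).
#' @export
hub_subnetwork <- function(net, top_k = 20L, mode = c("expanded", "induced")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ggi_network"))
  if (!nrow(net$edges)) stop("empty predicted network")
  deg <- network_degrees(net)
  if (top_k > length(deg)) {
    warning("top_k exceeds node count; using all ", length(deg), " nodes")
    top_k <- length(deg)
  }
  ord <- order(-deg, names(deg))
  hubs <- names(deg)[ord[seq_len(top_k)]]
  e <- net$edges
  keep <- if (mode == "expanded") {
    e$gene_a %in% hubs | e$gene_b %in% hubs
  } else {
    e$gene_a %in% hubs & e$gene_b %in% hubs
  }
  sub_edges <- e[keep, , drop = FALSE]
  rownames(sub_edges) <- NULL
  sub_nodes <- sort(unique(c(sub_edges$gene_a, sub_edges$gene_b, hubs)))
  seeds <- net$nodes$node[net$nodes$is_seed]
  list(
    hubs = hubs,
    nodes = data.frame(node = sub_nodes,
                       degree = as.integer(deg[sub_nodes]),
                       is_hub = sub_nodes %in% hubs,
                       is_seed = sub_nodes %in% seeds,
                       stringsAsFactors = FALSE),
    edges = sub_edges
  )
}

#' Correlation audit of novel predictions
#'
#' For predicted edges absent from the answer set — the novel GGIs —
#' recomputes the within-class Pearson correlation and mutual information
#' from the expression data and summarises their means and standard
#' deviations.  Low values confirm that these pairs could not have been
#' recovered by a correlation threshold.
#'
#' @param net a `ggi_network`.
#' @param answer_set data frame of curated positive pairs.
#' @param ds the (normalised) `ggi_expression` the network was predicted
#'   from.
#' @param bins histogram bins for mutual information.
#' @return list with `table` (per-edge PCC_L0, PCC_L1, MI_L0, MI_L1) and
#'   `summary` (mean and SD per statistic); both empty when every
#'   prediction is already in the answer set.
#' @export
correlation_audit <- function(net, answer_set, ds, bins = 10) {
  stopifnot(inherits(net, "ggi_network"), inherits(ds, "ggi_expression"))
  ans <- canonical_edges(answer_set)
  novel <- net$edges[!edges_in(net$edges, ans), , drop = FALSE]
  stats_names <- c("PCC_L0", "PCC_L1", "MI_L0", "MI_L1")
  if (!nrow(novel)) {
    empty <- data.frame(matrix(numeric(0), 0, 4,
                               dimnames = list(NULL, stats_names)))
    return(list(table = cbind(novel[, c("gene_a", "gene_b")], empty),
                summary = data.frame(statistic = stats_names,
                                     mean = NA_real_, sd = NA_real_)))
  }
  rows <- t(apply(novel, 1, function(r) {
    la <- extract_lists(ds, r[["gene_a"]])
    lb <- extract_lists(ds, r[["gene_b"]])
    c(pcc(la$E_L0, lb$E_L0), pcc(la$E_L1, lb$E_L1),
      mutual_information(la$E_L0, lb$E_L0, bins),
      mutual_information(la$E_L1, lb$E_L1, bins))
  }))
  colnames(rows) <- stats_names
  tab <- cbind(novel[, c("gene_a", "gene_b")], as.data.frame(rows))
  rownames(tab) <- NULL
  list(
    table = tab,
    summary = data.frame(statistic = stats_names,
                         mean = colMeans(rows),
                         sd = apply(rows, 2, stats::sd),
                         row.names = NULL)
  )
}

#' Write a predicted network as TSV and SIF edge lists
#'
#' @param net a `ggi_network`.
#' @param tsv_path path for the `gene_a<TAB>gene_b<TAB>score` table.
#' @param sif_path optional path for a SIF export (`gene_a ggi gene_b`).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, tsv_path, sif_path = NULL) {
  write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sif_path)) {
    writeLines(paste(net$edges$gene_a, "ggi", net$edges$gene_b), sif_path)
  }
  invisible(net)
}

#' Write a hub-subnetwork report to TSV
#' @param sub result of [hub_subnetwork()].
#' @param nodes_path path for the node table (node, degree, is_hub, is_seed).
#' @param edges_path optional path for the subnetwork edge table.
#' @return `sub`, invisibly.
#' @export
write_subnetwork <- function(sub, nodes_path, edges_path = NULL) {
  write.table(sub$nodes, nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(edges_path)) {
    write.table(sub$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(sub)
}
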