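make_network <- function(edges, seeds = character(0)) {
  # assemble a ggi_network by hand for topology tests
  ed <- ggiforest:::canonical_edges(edges)
  ed$score <- if (is.null(edges$score)) 1 else edges$score
  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  structure(list(edges = ed,
                 nodes = data.frame(node = nodes, is_seed = nodes %in% seeds,
                                    stringsAsFactors = FALSE)),
            class = "ggi_network")
}

test_that("candidate_pairs restricts the interactome to the dataset", {
  sim <- simulate_dataset(small_config(7L))
  ds <- suppressMessages(zscore_normalise(sim$dataset))
  net <- interactome(rbind(sim$net$edges[1:5, c("gene_a", "gene_b")],
                           data.frame(gene_a = "MISSING", gene_b = "G0001")))
  cand <- candidate_pairs(ds, net)
  expect_length(cand, 5)
  ids <- vapply(cand, `[[`, character(1), "id")
  expect_setequal(ids, ggiforest:::pair_id(sim$net$edges$gene_a[1:5],
                                           sim$net$edges$gene_b[1:5]))
  # expression lists come from extract_lists
  l <- extract_lists(ds, cand[[1]]$gene_a)
  expect_equal(cand[[1]]$E_A_L0, l$E_L0)

  lost <- interactome(data.frame(gene_a = "x1", gene_b = "x2"))
  expect_error(candidate_pairs(ds, lost), "identifier")
})

test_that("classify_network keeps voted pairs with their scores", {
  sim <- simulate_dataset(small_config(8L))
  ds <- suppressMessages(zscore_normalise(sim$dataset))
  ls <- build_labeled_set(sim$answer_set, sim$net, sim$seeds, ds, rng_seed = 8L)
  pairs <- Map(pair_from_dataset, list(ds), ls$pairs$gene_a, ls$pairs$gene_b)
  X <- feature_matrix(pairs, rng_seed = 8L)
  model <- train_forest(X, ls$pairs$label, t = 50, rng_seed = 8L)

  cand <- candidate_pairs(ds, sim$net)
  net1 <- classify_network(model, cand, rng_seed = 8L, seeds = sim$seeds)
  net2 <- classify_network(model, cand, rng_seed = 8L, seeds = sim$seeds)
  expect_identical(net1$edges, net2$edges)        # determinism
  expect_true(all(net1$edges$score > 0.5))
  expect_setequal(net1$nodes$node, unique(c(net1$edges$gene_a, net1$edges$gene_b)))

  # edge scores equal predict() on the same feature rows
  Xc <- feature_matrix(cand, rng_seed = 8L)
  sc <- predict(model, Xc)$scores
  names(sc) <- rownames(Xc)
  expect_equal(net1$edges$score,
               unname(sc[ggiforest:::pair_id(net1$edges$gene_a,
                                             net1$edges$gene_b)]))

  # a model that always votes 0 yields an empty network with a warning
  null_model <- stub_forest(c(0, 0, 0))
  null_model$feature_names <- pair_feature_names()
  expect_warning(empty <- classify_network(null_model, cand, rng_seed = 8L),
                 "no interacting pair")
  expect_equal(nrow(empty$edges), 0)
})

test_that("a trained model recovers planted pairs in a fresh application set", {
  train_sim <- simulate_dataset(simulation_config(rng_seed = 1L))
  ds <- suppressMessages(zscore_normalise(train_sim$dataset))
  ls <- build_labeled_set(train_sim$answer_set, train_sim$net, train_sim$seeds,
                          ds, rng_seed = 1L)
  pairs <- Map(pair_from_dataset, list(ds), ls$pairs$gene_a, ls$pairs$gene_b)
  model <- train_forest(feature_matrix(pairs, rng_seed = 1L),
                        ls$pairs$label, rng_seed = 1L)

  app_sim <- simulate_dataset(simulation_config(rng_seed = 2L))
  app_ds <- suppressMessages(zscore_normalise(app_sim$dataset))
  cand <- candidate_pairs(app_ds, app_sim$net)
  net <- classify_network(model, cand, rng_seed = 2L, seeds = app_sim$seeds)
  truth_ids <- ggiforest:::pair_id(app_sim$truth$gene_a, app_sim$truth$gene_b)
  pred_ids <- ggiforest:::pair_id(net$edges$gene_a, net$edges$gene_b)
  expect_gte(mean(truth_ids %in% pred_ids), 0.9)
  # background edges are mostly rejected
  expect_lt(nrow(net$edges), length(cand) / 2)
})

test_that("hub_subnetwork handles the star graph and tie rules", {
  star <- make_network(data.frame(gene_a = "c0", gene_b = paste0("l", 1:5)))
  sub <- hub_subnetwork(star, top_k = 1)
  expect_equal(sub$hubs, "c0")
  expect_equal(nrow(sub$edges), 5)                # whole star kept
  expect_equal(sort(sub$nodes$node), sort(c("c0", paste0("l", 1:5))))
  expect_warning(all_nodes <- hub_subnetwork(star, top_k = 99), "top_k")
  expect_equal(length(all_nodes$hubs), 6)
  empty_net <- make_network(data.frame(gene_a = "a", gene_b = "b"))
  empty_net$edges <- empty_net$edges[0, ]
  expect_error(hub_subnetwork(empty_net, 1), "empty")
})

test_that("hub ranking equals brute-force degree sort on random graphs", {
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(50, 0.1)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(gene_a = sprintf("n%02d", el[, 1]),
                        gene_b = sprintf("n%02d", el[, 2]))
    net <- make_network(edges)
    sub <- hub_subnetwork(net, top_k = 10)
    expect_identical(sub$hubs, oracle_top_degrees(net$edges, 10))
    # every subnetwork edge touches a hub; hub degrees preserved
    expect_true(all(sub$edges$gene_a %in% sub$hubs |
                    sub$edges$gene_b %in% sub$hubs))
    sub_deg <- table(c(sub$edges$gene_a, sub$edges$gene_b))
    full_deg <- network_degrees(net)
    for (h in sub$hubs) {
      expect_equal(unname(sub_deg[h]), unname(full_deg[h]),
                   ignore_attr = TRUE)
    }
    # induced mode only keeps hub-hub edges
    ind <- hub_subnetwork(net, top_k = 10, mode = "induced")
    expect_true(all(ind$edges$gene_a %in% sub$hubs &
                    ind$edges$gene_b %in% sub$hubs))
  }
})

test_that("correlation_audit recomputes statistics for novel edges only", {
  sim <- simulate_dataset(small_config(9L))
  ds <- suppressMessages(zscore_normalise(sim$dataset))
  net <- make_network(sim$net$edges[1:8, c("gene_a", "gene_b")])

  # all predictions inside the answer set -> empty audit
  full_ans <- net$edges[, c("gene_a", "gene_b")]
  aud0 <- correlation_audit(net, full_ans, ds)
  expect_equal(nrow(aud0$table), 0)

  ans <- net$edges[1:3, c("gene_a", "gene_b")]
  aud <- correlation_audit(net, ans, ds)
  expect_equal(nrow(aud$table), 5)
  expect_named(aud$summary, c("statistic", "mean", "sd"))
  # recomputation oracle on one audited edge
  r <- aud$table[1, ]
  la <- extract_lists(ds, r$gene_a)
  lb <- extract_lists(ds, r$gene_b)
  expect_equal(r$PCC_L0, oracle_pcc(la$E_L0, lb$E_L0), tolerance = 1e-12)
  expect_equal(r$MI_L1, oracle_mi(la$E_L1, lb$E_L1, 10), tolerance = 1e-12)
})

test_that("planted novel predictions stay under the correlation cap", {
  sim <- simulate_dataset(small_config(10L))
  ds <- suppressMessages(zscore_normalise(sim$dataset))
  truth_net <- make_network(sim$truth)
  empty_ans <- data.frame(gene_a = character(0), gene_b = character(0))
  aud <- correlation_audit(truth_net, empty_ans, ds)
  expect_lt(mean(abs(aud$table$PCC_L0)), 0.3)
  expect_lt(mean(abs(aud$table$PCC_L1)), 0.3)
})

test_that("network and subnetwork writers round-trip", {
  dir <- withr::local_tempdir()
  net <- make_network(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                                 score = c(0.8, 0.9)), seeds = "a")
  write_network(net, file.path(dir, "net.tsv"), file.path(dir, "net.sif"))
  back <- read_network(file.path(dir, "net.tsv"), seeds = "a")
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)
  expect_match(readLines(file.path(dir, "net.sif"))[1], " ggi ")
  sub <- hub_subnetwork(net, top_k = 1)
  write_subnetwork(sub, file.path(dir, "nodes.tsv"), file.path(dir, "edges.tsv"))
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  expect_named(nodes, c("node", "degree", "is_hub", "is_seed"))
})
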