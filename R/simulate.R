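#' Configuration for the synthetic two-class benchmark
#'
#' Describes the generative world the pipeline is tested in: background
#' genes are i.i.d. standard normal in both classes; each planted disease
#' pair's two genes gain, in the disease class only, a mean shift, an
#' inflated standard deviation and independent per-sample heterogeneity
#' noise.  Because the two genes' perturbations are drawn independently,
#' planted pairs are class-discriminative through their marginal
#' statistics while their within-class linear correlation stays weak; a
#' rejection step enforces `|PCC| < max_abs_pcc` in both classes so the
#' "correlation fails, pair features succeed" regime holds by
#' construction, not on average.
#'
#' Defaults are the package's reference benchmark: 500 genes, 60 + 60
#' samples, 100 planted pairs, mean shift 0.8, SD inflation 1.5,
#' heterogeneity SD 0.5, PCC cap 0.3.
#'
#' @param n_genes total genes (background + planted).
#' @param n_samples_class0,n_samples_class1 class sizes (>= 4 each).
#' @param n_disease_pairs planted disease pairs (2 genes each, disjoint).
#' @param heterogeneity_sd SD of the per-sample disease-class noise.
#' @param mean_shift disease-class mean offset for planted genes.
#' @param sd_inflation disease-class SD multiplier for planted genes.
#' @param max_abs_pcc rejection cap on within-class |PCC| of planted
#'   pairs, in `[0, 1)`.
#' @param interactome_degree_param edges added per node by the scale-free
#'   background-interactome model (preferential attachment).
#' @param seed_fraction fraction of planted genes exported as disease
#'   seeds.
#' @param answer_fraction fraction of planted pairs exported as the
#'   curated answer set.
#' @param max_retries rejection-sampling retries per planted pair.
#' @param rng_seed integer seed.
#' @return a validated list of class `ggi_sim_config`.
#' @export
simulation_config <- function(n_genes = 500L, n_samples_class0 = 60L,
                              n_samples_class1 = 60L, n_disease_pairs = 100L,
                              heterogeneity_sd = 0.5, mean_shift = 0.8,
                              sd_inflation = 1.5, max_abs_pcc = 0.3,
                              interactome_degree_param = 2L,
                              seed_fraction = 0.2, answer_fraction = 0.5,
                              max_retries = 100L, rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_class0 = as.integer(n_samples_class0),
              n_samples_class1 = as.integer(n_samples_class1),
              n_disease_pairs = as.integer(n_disease_pairs),
              heterogeneity_sd = heterogeneity_sd, mean_shift = mean_shift,
              sd_inflation = sd_inflation, max_abs_pcc = max_abs_pcc,
              interactome_degree_param = as.integer(interactome_degree_param),
              seed_fraction = seed_fraction,
              answer_fraction = answer_fraction,
              max_retries = as.integer(max_retries),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_genes > 0, cfg$n_disease_pairs >= 0,
            cfg$n_samples_class0 >= 4, cfg$n_samples_class1 >= 4,
            cfg$heterogeneity_sd >= 0, cfg$sd_inflation > 0,
            cfg$max_abs_pcc >= 0, cfg$max_abs_pcc < 1,
            cfg$interactome_degree_param >= 1,
            cfg$seed_fraction > 0, cfg$seed_fraction <= 1,
            cfg$answer_fraction > 0, cfg$answer_fraction <= 1,
            cfg$max_retries >= 1)
  if (cfg$n_genes < 2 * cfg$n_disease_pairs + 3) {
    stop("n_genes must leave at least 3 background genes beyond the planted pairs")
  }
  structure(cfg, class = "ggi_sim_config")
}

#' Simulate a complete synthetic benchmark
#'
#' Generates, under one seed: a raw two-class expression dataset with
#' planted disease pairs (see [simulation_config()]); an interactome made
#' of the planted pairs plus a scale-free preferential-attachment graph
#' over the background genes (uniform random edge confidences); a seed
#' list (random subset of planted genes); an answer set (random subset of
#' planted pairs); and the full planted truth table.  Identical seeds give
#' bit-identical output.
#'
#' The background graph deliberately avoids the planted genes: the planted
#' pairs are the interactome's disease module, so seed-neighbour expansion
#' recovers disease pairs rather than arbitrary background edges.
#'
#' @param cfg a `ggi_sim_config`.
#' @return list with `dataset` (raw `ggi_expression`), `net`
#'   (`ggi_interactome`), `seeds` (character), `answer_set` (edge data
#'   frame), `truth` (edge data frame of all planted pairs), `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "ggi_sim_config"))
  with_seed(cfg$rng_seed, {
    n0 <- cfg$n_samples_class0
    n1 <- cfg$n_samples_class1
    width <- max(4L, nchar(as.character(cfg$n_genes)))
    genes <- sprintf(paste0("G%0", width, "d"), seq_len(cfg$n_genes))
    samples <- c(sprintf("N%03d", seq_len(n0)), sprintf("D%03d", seq_len(n1)))
    labels <- setNames(rep(c(0L, 1L), c(n0, n1)), samples)

    vals <- matrix(rnorm(cfg$n_genes * (n0 + n1)), nrow = cfg$n_genes,
                   dimnames = list(genes, samples))

    planted_genes <- if (cfg$n_disease_pairs > 0) {
      sample(genes, 2L * cfg$n_disease_pairs)
    } else {
      character(0)
    }
    truth <- if (cfg$n_disease_pairs > 0) {
      canonical_edges(data.frame(
        gene_a = planted_genes[seq_len(cfg$n_disease_pairs) * 2L - 1L],
        gene_b = planted_genes[seq_len(cfg$n_disease_pairs) * 2L],
        stringsAsFactors = FALSE))
    } else {
      data.frame(gene_a = character(0), gene_b = character(0))
    }

    disease_row <- function() {
      c(rnorm(n0),
        rnorm(n1, mean = cfg$mean_shift, sd = cfg$sd_inflation) +
          rnorm(n1, sd = cfg$heterogeneity_sd))
    }
    for (i in seq_len(nrow(truth))) {
      ga <- truth$gene_a[i]
      gb <- truth$gene_b[i]
      ok <- FALSE
      for (try in seq_len(cfg$max_retries)) {
        ra <- disease_row()
        rb <- disease_row()
        if (abs(pcc(ra[seq_len(n0)], rb[seq_len(n0)])) < cfg$max_abs_pcc &&
            abs(pcc(ra[n0 + seq_len(n1)], rb[n0 + seq_len(n1)])) < cfg$max_abs_pcc) {
          vals[ga, ] <- ra
          vals[gb, ] <- rb
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("rejection sampling failed for a planted pair; ",
             "loosen max_abs_pcc or increase max_retries")
      }
    }

    background <- setdiff(genes, planted_genes)
    bg <- igraph::sample_pa(length(background),
                            m = cfg$interactome_degree_param,
                            directed = FALSE)
    bge <- igraph::as_edgelist(bg, names = FALSE)
    edges <- rbind(
      data.frame(gene_a = background[bge[, 1]], gene_b = background[bge[, 2]],
                 stringsAsFactors = FALSE),
      truth[, c("gene_a", "gene_b")])
    edges$confidence <- runif(nrow(edges))
    net <- interactome(edges)

    seeds <- if (length(planted_genes)) {
      sort(sample(planted_genes,
                  max(1L, round(cfg$seed_fraction * length(planted_genes)))))
    } else {
      character(0)
    }
    answer_set <- if (nrow(truth)) {
      idx <- sort(sample(nrow(truth),
                         max(1L, round(cfg$answer_fraction * nrow(truth)))))
      truth[idx, , drop = FALSE]
    } else {
      truth
    }
    rownames(answer_set) <- NULL

    list(dataset = expression_dataset(vals, labels),
         net = net, seeds = seeds, answer_set = answer_set, truth = truth,
         config = cfg)
  })
}

#' Write all benchmark fixtures in the formats the pipeline reads
#'
#' Emits `expression.tsv`, `labels.tsv`, `interactome.tsv`, `seeds.txt`,
#' `answer_set.tsv` and `truth.tsv` under `dir`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             interactome = file.path(dir, "interactome.tsv"),
             seeds = file.path(dir, "seeds.txt"),
             answer_set = file.path(dir, "answer_set.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(sim$dataset, paths[["expression"]], paths[["labels"]])
  write_interactome(sim$net, paths[["interactome"]])
  writeLines(sim$seeds, paths[["seeds"]])
  write.table(sim$answer_set, paths[["answer_set"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
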