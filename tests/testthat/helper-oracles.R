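# Independent brute-force oracles for the 22 pair features and the
# network operations.  Formulas are computed through different code paths
# (stats-library calls, explicit entropy sums, degree tables) than the
# package implementation; only the seed-derivation helper is shared, since
# the undersampling stream is itself part of the contract under test.

oracle_welch <- function(x, y) unname(t.test(x, y)$statistic)

oracle_pcc <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  unname(cor(x, y))
}

# equal-width binning per the stated rule, then MI = H(X) + H(Y) - H(X,Y)
oracle_bin <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  pmin(bins, floor((v - r[1]) / (r[2] - r[1]) * bins) + 1)
}

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

oracle_mi <- function(x, y, bins = 10) {
  bx <- oracle_bin(x, bins)
  by <- oracle_bin(y, bins)
  hx <- oracle_entropy(table(bx))
  hy <- oracle_entropy(table(by))
  hxy <- oracle_entropy(table(paste(bx, by)))
  max(0, hx + hy - hxy)
}

oracle_undersample <- function(v, m, seed) {
  if (m == length(v)) return(v)
  if (!exists(".Random.seed", globalenv())) set.seed(0)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v[sort(sample.int(length(v), m))]
}

oracle_cross_mi <- function(l0, l1, bins, rng_seed, gene) {
  m <- min(length(l0), length(l1))
  s <- derive_seed(rng_seed, paste0(gene, ":1"))
  oracle_mi(oracle_undersample(l0, m, s),
            oracle_undersample(l1, m, derive_seed(s, "b")), bins)
}

oracle_features <- function(pair, bins = 10, rng_seed = 1L) {
  a0 <- pair$E_A_L0; a1 <- pair$E_A_L1
  b0 <- pair$E_B_L0; b1 <- pair$E_B_L1
  c(Mean_A_L0 = mean(a0), Mean_A_L1 = mean(a1),
    Mean_B_L0 = mean(b0), Mean_B_L1 = mean(b1),
    SD_A_L0 = sd(a0), SD_A_L1 = sd(a1), SD_B_L0 = sd(b0), SD_B_L1 = sd(b1),
    dMm_A_L0 = diff(range(a0)), dMm_A_L1 = diff(range(a1)),
    dMm_B_L0 = diff(range(b0)), dMm_B_L1 = diff(range(b1)),
    WT_A_L0_B_L0 = oracle_welch(a0, b0), WT_A_L1_B_L1 = oracle_welch(a1, b1),
    WT_A_L0_A_L1 = oracle_welch(a0, a1), WT_B_L0_B_L1 = oracle_welch(b0, b1),
    PCC_A_L0_B_L0 = oracle_pcc(a0, b0), PCC_A_L1_B_L1 = oracle_pcc(a1, b1),
    MI_A_L0_B_L0 = oracle_mi(a0, b0, bins), MI_A_L1_B_L1 = oracle_mi(a1, b1, bins),
    MI_A_L0_A_L1 = oracle_cross_mi(a0, a1, bins, rng_seed, pair$gene_a),
    MI_B_L0_B_L1 = oracle_cross_mi(b0, b1, bins, rng_seed, pair$gene_b))
}

oracle_top_degrees <- function(edges, k) {
  deg <- sort(table(c(edges$gene_a, edges$gene_b)), decreasing = TRUE)
  # stable tie-break on name: order by (-count, name)
  nm <- names(deg)
  ord <- order(-as.integer(deg), nm)
  nm[ord][seq_len(min(k, length(nm)))]
}
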