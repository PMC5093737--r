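# Shared fixtures, built in code at test time.

# binary matrix from a list of gene -> altered sample indices
make_altmat <- function(hits, n_samples,
                        samples = sprintf("s%02d", seq_len(n_samples))) {
  genes <- names(hits)
  m <- matrix(0L, length(genes), n_samples,
              dimnames = list(genes, samples))
  for (g in genes) m[g, hits[[g]]] <- 1L
  alteration_matrix(m)
}

# perfect mutual exclusivity: gene i altered in counts[i] private samples
disjoint_matrix <- function(counts, genes = LETTERS[seq_along(counts)]) {
  n <- sum(counts)
  hits <- list()
  at <- 0L
  for (i in seq_along(counts)) {
    hits[[genes[[i]]]] <- at + seq_len(counts[[i]])
    at <- at + counts[[i]]
  }
  make_altmat(hits, n)
}

# random MES instance: |V| genes, n samples, alteration density p
random_instance <- function(n_genes, n_samples, p = 0.3) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  m <- matrix(as.integer(stats::runif(n_genes * n_samples) < p),
              n_genes, n_samples,
              dimnames = list(genes, sprintf("s%03d", seq_len(n_samples))))
  alteration_matrix(m)
}

# simple path graph A - B - C - ...
line_network <- function(k, genes = LETTERS[seq_len(k)]) {
  gene_network(cbind(genes[-k], genes[-1L]))
}

# small end-to-end study used by several suites
toy_study <- function(seed = 11L, n_nodes = 60L, n_samples = 40L) {
  set.seed(seed)
  net <- generate_test_network(n_nodes, 4)
  # a small walker cap keeps the planted pathway below the signal-sample
  # count at these cohort sizes
  cfg <- simulation_config(n_samples = n_samples, rng_seed = seed,
                           max_target_edges = 8L)
  simulate_study(cfg, net)
}

# independent pairwise-concordance AUC oracle (ties count one half)
auc_concordance <- function(ranked, truth, universe) {
  rk <- stats::setNames(rep(length(ranked$gene) + 1, length(universe)),
                        universe)
  rk[ranked$gene] <- ranked$rank
  pos <- rk[universe %in% truth]
  neg <- rk[!universe %in% truth]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p < n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
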