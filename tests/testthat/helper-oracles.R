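# Independent oracles and small fixture builders shared across the suite.

# Exhaustive-enumeration hypergeometric upper tail: draw n of N items of
# which items 1..m are successes; fraction of draws with > k successes.
enum_hyper_tail <- function(N, m, n, k) {
  if (n == 0L) return(as.numeric(k < 0))
  subsets <- utils::combn(N, n)
  succ <- colSums(matrix(subsets <= m, nrow = n))
  mean(succ > k)
}

# Hand step-up Benjamini-Hochberg, written independently of p.adjust.
bh_oracle <- function(p) {
  M <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(M)
  run <- Inf
  for (i in M:1) {
    run <- min(run, sorted[i] * M / i)
    adj[i] <- min(run, 1)
  }
  out <- numeric(M)
  out[o] <- adj
  out
}

# Random per-gene statistics table with a controllable significant
# fraction (p-values a uniform/near-zero mixture, fold changes log-normal).
random_stats <- function(n_genes, frac_sig = 0.1, seed = 1) {
  set.seed(seed)
  sig <- runif(n_genes) < frac_sig
  p <- ifelse(sig, runif(n_genes, 0, 0.005), runif(n_genes, 0.02, 1))
  data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
             fold_change = 2^rnorm(n_genes, 0, 1),
             p_value = p,
             stringsAsFactors = FALSE)
}

random_sets <- function(gene_ids, n_sets = 10, size_range = c(8, 25),
                        seed = 1) {
  set.seed(seed)
  members <- lapply(seq_len(n_sets), function(i) {
    sample(gene_ids, sample(seq(size_range[1], size_range[2]), 1))
  })
  names(members) <- sprintf("P%02d", seq_len(n_sets))
  gene_set_collection(members)
}
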