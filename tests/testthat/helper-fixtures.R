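# Small in-code fixtures shared across test files.

# tiny omics matrix: 3 features, 2 tumor + 2 normal samples
tiny_omics <- function(values = matrix(c(2, 3, 5, 4, 6, 10, 1, 1, 1, 2, 2, 2),
                                       nrow = 3),
                       type = "expression") {
  dimnames(values) <- list(c("gA", "gB", "gC"),
                           c("s1_tumor", "s2_tumor", "s1_normal",
                             "s2_normal"))
  omics_matrix(values, group = c("tumor", "tumor", "normal", "normal"),
               pair = c("s1", "s2", "s1", "s2"), type = type)
}

# gene models on one chromosome, both strands
tiny_genes <- function() {
  data.frame(gene_id = c("gA", "gB", "gC"), chromosome = "chr1",
             tss = c(10000L, 50000L, 90000L), strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}

# fast small simulation config for tests; any argument can be overridden
fast_config <- function(...) {
  defaults <- list(n_pairs = 15, n_genes = 200, n_ei = 10, n_es = 5,
                   network_nodes = 200, edges_per_new_node = 4,
                   n_drivers = 2, cohort_n = 60)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# order-independent edge-list fingerprint for comparing igraph networks
edge_fingerprint <- function(g) {
  el <- igraph::as_edgelist(g)
  el <- t(apply(el, 1, sort))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# independent all-pairs AUC oracle
auc_all_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# independent hypergeometric upper-tail oracle by direct enumeration
hyper_tail_oracle <- function(a, b, K, N) {
  n <- a + b
  total <- 0
  for (x in max(0, n - (N - K)):min(K, n))
    if (x >= a) total <- total + choose(K, x) * choose(N - K, n - x)
  total / choose(N, n)
}
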