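#' Load an undirected protein-interaction network from an edge list
#'
#' Reads a tab-separated edge list whose first two columns are gene symbols
#' (extra columns, e.g. confidence scores, are ignored). The graph is
#' undirected and simple: reciprocal and duplicate edges are merged and
#' self-loops dropped; removal counts are recorded as graph attributes.
#'
#' @param path edge-list file (plain or gzip, CRLF tolerated), or a two-column
#'   data.frame / matrix of endpoints.
#' @param header whether the file has a header line (default FALSE).
#' @return An undirected simple [igraph::igraph] object.
#' @export
load_network <- function(path, header = FALSE) {
  if (is.character(path)) {
    if (!file.exists(path))
      stop("cannot read edge list '", path, "': no such file")
    first <- readLines(path, n = 1L)
    if (length(first) == 0 || !nzchar(trimws(first))) {
      warning("empty edge list: returning empty network")
      return(igraph::make_empty_graph(0, directed = FALSE))
    }
    edges <- tryCatch(
      utils::read.delim(path, header = header, stringsAsFactors = FALSE),
      error = function(e) stop("cannot read edge list '", path, "': ",
                               conditionMessage(e)))
    if (nrow(edges) == 0) {
      warning("empty edge list: returning empty network")
      return(igraph::make_empty_graph(0, directed = FALSE))
    }
    if (ncol(edges) < 2)
      stop("edge list must have at least two columns (line 1 has ",
           ncol(edges), ")")
    edges <- edges[, 1:2]
  } else {
    edges <- as.data.frame(path)[, 1:2]
  }
  bad <- which(is.na(edges[[1]]) | is.na(edges[[2]]) |
                 edges[[1]] == "" | edges[[2]] == "")
  if (length(bad))
    stop("malformed edge at line ", bad[1] + as.integer(header))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  simple <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  simple$n_self_loops_removed <- n_loops
  simple$n_duplicate_edges_removed <-
    igraph::ecount(g) - n_loops - igraph::ecount(simple)
  simple
}

#' Induced subnetwork on a gene set
#'
#' Subgraph on the intersection of `genes` with the network's nodes, keeping
#' only edges with both endpoints inside.
#'
#' @param net an igraph network.
#' @param genes character vector of gene symbols.
#' @return list with `graph` (the induced subgraph), `n_nodes`, `n_edges` and
#'   `mean_degree` within the subgraph.
#' @export
induced_subnetwork <- function(net, genes) {
  keep <- intersect(genes, igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, keep)
  n <- igraph::vcount(sub)
  list(graph = sub, n_nodes = n, n_edges = igraph::ecount(sub),
       mean_degree = if (n > 0) mean(igraph::degree(sub)) else NA_real_)
}

#' One-sided Fisher enrichment p-value (hypergeometric upper tail)
#'
#' Exact p-value of the one-sided (enrichment) Fisher test on the 2x2 table
#' `[[a, b], [K - a, N - K - b]]`: the probability of observing `a` or more
#' marked neighbors when drawing `a + b` genes without replacement from a
#' population of `N` genes containing `K` marked ones,
#' `P(X >= a) = sum_{x >= a} C(K, x) C(N - K, n - x) / C(N, n)` with
#' `n = a + b`. Computed exactly by log-factorial accumulation (no normal or
#' chi-square approximation).
#'
#' @param a marked (e.g. EI/ES) neighbors of the tested gene.
#' @param b unmarked neighbors; `a + b` is the gene's degree.
#' @param K marked genes in the background population.
#' @param N background population size (all network genes).
#' @return the upper-tail p-value in (0, 1].
#' @examples
#' fisher_enrichment_tail(4, 12, 205, 17381)  # 3.06e-05
#' @export
fisher_enrichment_tail <- function(a, b, K, N) {
  stopifnot(length(a) == 1, length(b) == 1, length(K) == 1, length(N) == 1)
  if (any(c(a, b, K, N) < 0) || a + b > N || a > K || K > N || b > N - K)
    stop("inconsistent 2x2 margins")
  n <- a + b
  hi <- min(K, n)
  if (a == 0) return(1)
  x <- a:hi
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(logp)
  min(exp(m + log(sum(exp(logp - m)))), 1)
}

#' Per-gene neighborhood enrichment of a marked gene set
#'
#' For each tested gene, counts its direct network neighbors inside
#' (`ei_neighbors`, a) and outside (`other_neighbors`, b) the background set
#' of marked genes, and scores enrichment with the one-sided Fisher
#' (hypergeometric) tail against the full network as population: `K` marked
#' genes present in the network, `N` network nodes. The gene itself is never
#' counted as its own neighbor. Adjusted p-values are computed over all
#' tested genes.
#'
#' @param net an igraph network.
#' @param background_set character vector of marked genes (e.g. EI/ES genes);
#'   intersected with the network's nodes.
#' @param test_genes genes to score; default all background-set members with
#'   degree >= 1.
#' @param adjust multiplicity adjustment for the `q_value` column:
#'   `"BH"` (default) or `"bonferroni"`.
#' @return data.frame, one row per tested gene, sorted by p-value:
#'   `gene_id`, `ei_neighbors`, `other_neighbors`, `background_set_size`,
#'   `network_size`, `proportion`, `p_value`, `q_value`, `degree_zero` flag.
#' @export
neighborhood_enrichment <- function(net, background_set, test_genes = NULL,
                                    adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  nodes <- igraph::V(net)$name
  bg <- intersect(background_set, nodes)
  K <- length(bg)
  N <- length(nodes)
  deg <- igraph::degree(net)
  if (is.null(test_genes)) {
    test_genes <- bg[deg[bg] >= 1]
  } else {
    test_genes <- intersect(test_genes, nodes)
  }
  if (length(test_genes) == 0)
    return(data.frame(gene_id = character(), ei_neighbors = integer(),
                      other_neighbors = integer(),
                      background_set_size = integer(),
                      network_size = integer(), proportion = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      degree_zero = logical(), stringsAsFactors = FALSE))
  bg_set <- bg
  rows <- lapply(test_genes, function(g) {
    nb <- igraph::neighbors(net, g)$name
    nb <- setdiff(nb, g)
    a <- sum(nb %in% bg_set)
    b <- length(nb) - a
    if (length(nb) == 0) {
      data.frame(gene_id = g, ei_neighbors = 0L, other_neighbors = 0L,
                 proportion = 0, p_value = 1, degree_zero = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = g, ei_neighbors = a, other_neighbors = b,
                 proportion = a / (a + b),
                 p_value = fisher_enrichment_tail(a, b, K, N),
                 degree_zero = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$background_set_size <- K
  out$network_size <- N
  out$q_value <- if (adjust == "BH") bh_adjust(out$p_value) else
    pmin(out$p_value * nrow(out), 1)
  out <- out[order(out$p_value, out$gene_id),
             c("gene_id", "ei_neighbors", "other_neighbors",
               "background_set_size", "network_size", "proportion",
               "p_value", "q_value", "degree_zero")]
  rownames(out) <- NULL
  out
}

#' Select epigenetically altered driver genes
#'
#' Keeps genes whose adjusted enrichment p-value is strictly below
#' `fdr_threshold` and whose marked-neighbor proportion strictly exceeds
#' `proportion_threshold`, sorted by p-value.
#'
#' @param results data.frame from [neighborhood_enrichment()].
#' @param fdr_threshold default 0.05.
#' @param proportion_threshold default 0.10.
#' @return the selected subset of `results`, sorted by ascending p-value.
#' @export
select_drivers <- function(results, fdr_threshold = 0.05,
                           proportion_threshold = 0.10) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            proportion_threshold > 0, proportion_threshold < 1)
  keep <- results$q_value < fdr_threshold &
    results$proportion > proportion_threshold
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree distribution of a network
#'
#' @param net an igraph network.
#' @return data.frame with `degree` and `count`; counts sum to the node
#'   count.
#' @export
degree_distribution <- function(net) {
  if (igraph::vcount(net) == 0)
    return(data.frame(degree = integer(), count = integer()))
  tab <- table(igraph::degree(net))
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}
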