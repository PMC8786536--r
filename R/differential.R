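#' Two-sided Wilcoxon rank-sum test
#'
#' Unpaired two-group comparison. When both groups have at most
#' `exact_limit` observations the two-sided p-value is exact: all
#' `C(n, n_a)` assignments of the pooled (average) ranks are enumerated and
#' the probability of a rank sum at least as far from its null expectation as
#' the observed one is returned, which handles ties exactly. For larger
#' groups the normal approximation with tie and continuity correction is
#' used.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @param exact_limit largest group size for which the exact enumeration is
#'   used (default 10).
#' @return list with `statistic` (Mann-Whitney U for `group_a`) and
#'   `p_value` in (0, 1].
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, exact_limit = 10) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0)
    stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L)          # no variation at all
    return(list(statistic = na * nb / 2, p_value = 1))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  u <- w_obs - na * (na + 1) / 2
  if (na <= exact_limit && nb <= exact_limit) {
    n <- na + nb
    mu <- na * (n + 1) / 2
    sets <- utils::combn(n, na)
    w_all <- colSums(matrix(r[sets], nrow = na))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    res <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE))
    p <- res$p.value
  }
  list(statistic = unname(u), p_value = min(max(p, 0), 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`p * m / rank` with cumulative minimum, clipped
#' at 1). Satisfies `q >= p` elementwise and preserves the p-value ordering.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NAs propagated).
#' @return adjusted q-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. A constant input vector has
#' no defined rank correlation and yields `NA`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in \[-1, 1\], or `NA` for degenerate input.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

group_stats <- function(mat) {
  s <- split_groups(mat)
  list(mean_tumor = rowMeans(s$tumor), mean_normal = rowMeans(s$normal),
       tumor = s$tumor, normal = s$normal)
}

wilcoxon_by_row <- function(tumor, normal, exact_limit = 10) {
  vapply(seq_len(nrow(tumor)), function(i) {
    wilcoxon_rank_sum(tumor[i, ], normal[i, ], exact_limit)$p_value
  }, numeric(1))
}

#' Call differential expression between tumor and normal samples
#'
#' Per-gene Wilcoxon rank-sum test of tumor vs normal expression with a
#' Benjamini-Hochberg FDR correction. The fold change is computed on
#' pseudocounted group means: `log2((mean_tumor + pc) / (mean_normal + pc))`.
#' A gene is called up when `log2FC > lfc_threshold` and `q < fdr_threshold`
#' (strict inequalities), down for the mirrored condition.
#'
#' @param expr gene-level expression `omics_matrix` with both groups present.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param fdr_threshold FDR threshold on the BH-adjusted p (default 0.05).
#' @param pseudocount added to both group means before the ratio (default 1).
#' @return data.frame with one row per gene: `gene_id`, `mean_tumor`,
#'   `mean_normal`, `log2_fold_change`, `p_value`, `q_value`, `direction`
#'   (`up` / `down` / `none`).
#' @export
call_differential_expression <- function(expr, lfc_threshold = 1,
                                         fdr_threshold = 0.05,
                                         pseudocount = 1) {
  g <- groups_of(expr)
  if (!all(c("tumor", "normal") %in% g))
    stop("expression matrix must contain both tumor and normal samples")
  st <- group_stats(expr)
  lfc <- log2((st$mean_tumor + pseudocount) / (st$mean_normal + pseudocount))
  p <- wilcoxon_by_row(st$tumor, st$normal)
  q <- bh_adjust(p)
  direction <- rep("none", nrow(expr))
  direction[lfc > lfc_threshold & q < fdr_threshold] <- "up"
  direction[lfc < -lfc_threshold & q < fdr_threshold] <- "down"
  data.frame(gene_id = rownames(expr), mean_tumor = st$mean_tumor,
             mean_normal = st$mean_normal, log2_fold_change = lfc,
             p_value = p, q_value = q, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differential promoter methylation
#'
#' Per-gene Wilcoxon rank-sum test on promoter beta values. Direction is
#' assigned from the raw p-value (no FDR correction and no effect-size
#' threshold): up when `p < p_threshold` and the tumor-minus-normal beta
#' difference is positive, down when negative. A zero difference is `none`.
#'
#' @param meth gene-level methylation `omics_matrix` with both groups.
#' @param p_threshold raw p-value threshold (default 0.05).
#' @return data.frame per gene: `gene_id`, `mean_tumor`, `mean_normal`,
#'   `delta_beta`, `p_value`, `q_value` (BH, reported for reference),
#'   `direction`.
#' @export
call_differential_methylation <- function(meth, p_threshold = 0.05) {
  g <- groups_of(meth)
  if (!all(c("tumor", "normal") %in% g))
    stop("methylation matrix must contain both tumor and normal samples")
  st <- group_stats(meth)
  delta <- st$mean_tumor - st$mean_normal
  p <- wilcoxon_by_row(st$tumor, st$normal)
  direction <- rep("none", nrow(meth))
  direction[p < p_threshold & delta > 0] <- "up"
  direction[p < p_threshold & delta < 0] <- "down"
  data.frame(gene_id = rownames(meth), mean_tumor = st$mean_tumor,
             mean_normal = st$mean_normal, delta_beta = delta,
             p_value = p, q_value = bh_adjust(p), direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify epigenetically induced / suppressed genes
#'
#' Combines differential-expression and differential-methylation calls:
#' a gene is epigenetically induced (EI) when its expression is up and its
#' promoter methylation is down; epigenetically suppressed (ES) when
#' expression is down and methylation is up. Every other combination, and any
#' gene missing from either call set, is `none`.
#'
#' @param de data.frame from [call_differential_expression()].
#' @param dm data.frame from [call_differential_methylation()].
#' @return data.frame per gene (union of both sets): `gene_id`,
#'   `expression_direction`, `methylation_direction`, `epigenetic_class`
#'   (`EI` / `ES` / `none`).
#' @export
classify_ei_es <- function(de, dm) {
  genes <- sort(union(de$gene_id, dm$gene_id))
  ed <- de$direction[match(genes, de$gene_id)]
  md <- dm$direction[match(genes, dm$gene_id)]
  ed[is.na(ed)] <- "none"; md[is.na(md)] <- "none"
  cls <- rep("none", length(genes))
  cls[ed == "up" & md == "down"] <- "EI"
  cls[ed == "down" & md == "up"] <- "ES"
  data.frame(gene_id = genes, expression_direction = ed,
             methylation_direction = md, epigenetic_class = cls,
             stringsAsFactors = FALSE)
}

#' Filter EI/ES calls by negative methylation-expression correlation
#'
#' Computes per gene the Spearman correlation between promoter methylation
#' and expression across all samples (tumor and normal pooled) and keeps
#' EI/ES genes with `rho < rho_threshold` (strict; default 0, i.e. a negative
#' correlation). Genes with undefined rho (constant values) are removed.
#'
#' @param calls data.frame from [classify_ei_es()].
#' @param expr,meth gene-level omics matrices sharing samples.
#' @param rho_threshold keep genes with rho strictly below this (default 0).
#' @return `calls` restricted to EI/ES genes, with `spearman_rho` and
#'   `passes_correlation_filter` columns; only passing genes are returned.
#' @export
correlation_filter <- function(calls, expr, meth, rho_threshold = 0) {
  if (!identical(colnames(expr), colnames(meth)))
    stop("expression and methylation matrices must share samples")
  sel <- calls[calls$epigenetic_class %in% c("EI", "ES"), , drop = FALSE]
  sel <- sel[sel$gene_id %in% rownames(expr) &
               sel$gene_id %in% rownames(meth), , drop = FALSE]
  rho <- vapply(sel$gene_id, function(g)
    spearman_correlation(unclass(meth)[g, ], unclass(expr)[g, ]),
    numeric(1))
  sel$spearman_rho <- unname(rho)
  sel$passes_correlation_filter <- !is.na(rho) & rho < rho_threshold
  out <- sel[sel$passes_correlation_filter, , drop = FALSE]
  rownames(out) <- NULL
  out
}
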