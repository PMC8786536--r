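#' Convert FPKM expression values to TPM
#'
#' Rescales each sample column so that it sums to one million: for gene i in
#' sample j, `tpm[i, j] = fpkm[i, j] / sum_i fpkm[i, j] * 1e6`. This is the
#' standard within-sample renormalization from fragments per kilobase million
#' to transcripts per million and is idempotent.
#'
#' @param expr an `omics_matrix` of non-negative expression values.
#' @return An `omics_matrix` whose columns each sum to 1e6.
#' @examples
#' m <- omics_matrix(matrix(c(2, 3, 5), 3, 1,
#'                          dimnames = list(c("a", "b", "c"), "s1")),
#'                   group = "tumor")
#' fpkm_to_tpm(m)[, 1]
#' @export
fpkm_to_tpm <- function(expr) {
  v <- unclass(expr)
  cs <- colSums(v)
  zero <- !is.finite(cs) | cs <= 0
  if (any(zero))
    stop("sample column(s) with zero total expression: ",
         paste(colnames(v)[zero], collapse = ", "))
  out <- sweep(v, 2, cs, "/") * 1e6
  omics_matrix(out, group = groups_of(expr), pair = attr(expr, "pair"),
               type = "expression")
}

#' Filter methylation probes
#'
#' Drops probes that are absent from the probe annotation ("empty" probes that
#' cannot be placed on the genome) and probes whose fraction of missing beta
#' values exceeds `max_na_frac`. The default policy removes a probe with any
#' missing value.
#'
#' @param beta an `omics_matrix` of probe beta values (probes x samples).
#' @param annot data.frame of probe annotation with columns `probe_id`,
#'   `chromosome`, `position` (1-based CpG coordinate).
#' @param max_na_frac maximum tolerated fraction of missing values per probe;
#'   default 0 (any missing value removes the probe).
#' @return The filtered `omics_matrix`; attributes `n_unannotated` and
#'   `n_missing` record how many probes each rule removed.
#' @export
filter_probes <- function(beta, annot, max_na_frac = 0) {
  stopifnot(is.data.frame(annot),
            all(c("probe_id", "chromosome", "position") %in% names(annot)))
  v <- unclass(beta)
  annotated <- rownames(v) %in% annot$probe_id
  na_frac <- rowMeans(is.na(v))
  keep <- annotated & na_frac <= max_na_frac
  n_unannot <- sum(!annotated)
  n_missing <- sum(annotated & na_frac > max_na_frac)
  if (!any(keep))
    message("filter_probes: no probes retained")
  out <- omics_matrix(v[keep, , drop = FALSE], group = groups_of(beta),
                      pair = attr(beta, "pair"), type = "methylation")
  attr(out, "n_unannotated") <- n_unannot
  attr(out, "n_missing") <- n_missing
  out
}

#' Promoter window around a transcription start site
#'
#' Computes the 1-based inclusive genomic interval covering
#' `upstream_bp` bases upstream to `downstream_bp` bases downstream of the
#' TSS. Upstream/downstream follow the gene's strand when `stranded = TRUE`
#' (the interval is mirrored on the minus strand); with `stranded = FALSE`
#' every gene is treated as plus-strand. Windows that would run off the start
#' of the chromosome are clamped at position 1.
#'
#' @param gene one-row data.frame (or list) with `gene_id`, `chromosome`,
#'   `tss`, `strand`.
#' @param upstream_bp,downstream_bp window extent in bases (defaults 800/200).
#' @param stranded mirror the window on the minus strand (default TRUE).
#' @return data.frame with `gene_id`, `chromosome`, `start`, `end`.
#' @examples
#' promoter_window(list(gene_id = "g", chromosome = "chr1",
#'                      tss = 10000, strand = "+"))
#' @export
promoter_window <- function(gene, upstream_bp = 800, downstream_bp = 200,
                            stranded = TRUE) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  strand <- as.character(gene$strand)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  tss <- as.integer(gene$tss)
  if (tss < 1) stop("tss must be >= 1")
  minus <- stranded && strand == "-"
  start <- if (minus) tss - downstream_bp else tss - upstream_bp
  end <- if (minus) tss + upstream_bp else tss + downstream_bp
  if (start < 1) start <- 1L
  data.frame(gene_id = as.character(gene$gene_id),
             chromosome = as.character(gene$chromosome),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Map CpG probes to gene promoter windows
#'
#' A probe is assigned to a gene when it lies on the same chromosome and its
#' position falls inside the gene's promoter window (1-based inclusive
#' bounds). A probe inside overlapping promoters contributes to every
#' overlapped gene. Overlap is computed with GenomicRanges.
#'
#' @param annot probe annotation data.frame (`probe_id`, `chromosome`,
#'   `position`).
#' @param genes gene model data.frame (`gene_id`, `chromosome`, `tss`,
#'   `strand`).
#' @inheritParams promoter_window
#' @return data.frame with columns `gene_id`, `probe_id`, sorted by gene then
#'   probe; attribute `unmapped_genes` lists genes with zero probes.
#' @export
map_probes_to_promoters <- function(annot, genes, upstream_bp = 800,
                                    downstream_bp = 200, stranded = TRUE) {
  stopifnot(all(c("probe_id", "chromosome", "position") %in% names(annot)),
            all(c("gene_id", "chromosome", "tss", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(annot$probe_id)) stop("duplicate probe ids")
  if (nrow(annot) == 0 || nrow(genes) == 0) {
    out <- data.frame(gene_id = character(), probe_id = character(),
                      stringsAsFactors = FALSE)
    attr(out, "unmapped_genes") <- as.character(genes$gene_id)
    return(out)
  }
  win <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    promoter_window(genes[i, ], upstream_bp, downstream_bp, stranded)))
  prom <- GenomicRanges::GRanges(win$chromosome,
                                 IRanges::IRanges(win$start, win$end))
  probes <- GenomicRanges::GRanges(annot$chromosome,
                                   IRanges::IRanges(annot$position,
                                                    annot$position))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(probes, prom))
  out <- data.frame(gene_id = win$gene_id[S4Vectors::subjectHits(hits)],
                    probe_id = annot$probe_id[S4Vectors::queryHits(hits)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped_genes") <-
    sort(setdiff(genes$gene_id, out$gene_id))
  out
}

#' Aggregate probe betas to gene promoter methylation
#'
#' For each gene with at least one mapped probe, the promoter methylation
#' level per sample is the unweighted mean of its probes' beta values. Genes
#' with no mapped probe are absent from the output; rows are sorted by gene
#' id.
#'
#' @param beta probe-level `omics_matrix`.
#' @param mapping data.frame with `gene_id`, `probe_id` as returned by
#'   [map_probes_to_promoters()].
#' @return gene-level methylation `omics_matrix`.
#' @export
aggregate_promoter_methylation <- function(beta, mapping) {
  stopifnot(all(c("gene_id", "probe_id") %in% names(mapping)))
  missing <- setdiff(mapping$probe_id, rownames(beta))
  if (length(missing))
    stop("mapped probe(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  v <- unclass(beta)
  by_gene <- split(mapping$probe_id, mapping$gene_id)  # split sorts by gene id
  genes <- names(by_gene)
  out <- t(vapply(by_gene, function(p) colMeans(v[p, , drop = FALSE]),
                  numeric(ncol(v))))
  if (length(genes) == 1L) {
    out <- matrix(out, nrow = 1, dimnames = list(genes, colnames(v)))
  } else {
    rownames(out) <- genes
  }
  omics_matrix(out, group = groups_of(beta), pair = attr(beta, "pair"),
               type = "methylation")
}
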