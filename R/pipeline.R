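#' Pipeline configuration
#'
#' Collects the input file paths and every analysis threshold for
#' [run_pipeline()]. Thresholds default to the published criteria: promoter
#' window 800 bp upstream / 200 bp downstream of the TSS, differential
#' expression at |log2 fold change| > 1 with BH FDR < 0.05, differential
#' promoter methylation at raw p < 0.05, Spearman rho < 0, and driver
#' selection at enrichment FDR < 0.05 with marked-neighbor proportion > 0.10.
#'
#' @param expr_file,beta_file,probe_annot_file,gene_model_file,network_file
#'   input paths (see [read_omics_matrix()], [load_network()]).
#' @param samples_file optional sample-group table; NULL infers groups from
#'   `_tumor` / `_normal` suffixes.
#' @param clinical_file optional clinical CSV; when given, the marker-level
#'   association, log-rank and Cox stages run.
#' @param expression_unit `"fpkm"` (converted to TPM) or `"tpm"` (used as
#'   is).
#' @param upstream_bp,downstream_bp,stranded promoter window parameters.
#' @param lfc_threshold,fdr_threshold,meth_p_threshold,rho_threshold
#'   differential-stage thresholds.
#' @param driver_fdr,driver_proportion driver-selection criteria.
#' @param adjust multiplicity adjustment for the enrichment q-values
#'   (`"BH"` or `"bonferroni"`).
#' @param correction continuity-correction policy for clinical chi-squared
#'   associations (`"none"` or `"yates"`).
#' @param outdir optional output directory for stage TSVs and the run
#'   manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr_file, beta_file, probe_annot_file,
                            gene_model_file, network_file,
                            samples_file = NULL, clinical_file = NULL,
                            expression_unit = c("fpkm", "tpm"),
                            upstream_bp = 800, downstream_bp = 200,
                            stranded = TRUE,
                            lfc_threshold = 1, fdr_threshold = 0.05,
                            meth_p_threshold = 0.05, rho_threshold = 0,
                            driver_fdr = 0.05, driver_proportion = 0.10,
                            adjust = c("BH", "bonferroni"),
                            correction = c("none", "yates"),
                            outdir = NULL) {
  cfg <- list(expr_file = expr_file, beta_file = beta_file,
              probe_annot_file = probe_annot_file,
              gene_model_file = gene_model_file,
              network_file = network_file, samples_file = samples_file,
              clinical_file = clinical_file,
              expression_unit = match.arg(expression_unit),
              upstream_bp = upstream_bp, downstream_bp = downstream_bp,
              stranded = stranded, lfc_threshold = lfc_threshold,
              fdr_threshold = fdr_threshold,
              meth_p_threshold = meth_p_threshold,
              rho_threshold = rho_threshold, driver_fdr = driver_fdr,
              driver_proportion = driver_proportion,
              adjust = match.arg(adjust),
              correction = match.arg(correction), outdir = outdir)
  stopifnot(cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            cfg$meth_p_threshold > 0, cfg$meth_p_threshold < 1,
            cfg$driver_fdr > 0, cfg$driver_fdr < 1,
            cfg$upstream_bp >= 0, cfg$downstream_bp >= 0)
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the integrated methylation-expression driver-gene pipeline
#'
#' Executes the stages in order: read inputs; convert expression to TPM (if
#' declared FPKM); filter probes and aggregate promoter methylation over the
#' TSS window; call differential expression and differential promoter
#' methylation; classify EI/ES genes; apply the negative Spearman correlation
#' filter; map the filtered genes onto the interaction network; score
#' per-gene neighborhood enrichment; and select drivers. When a clinical
#' table is supplied, the marker-level vs TNM-stage association, the two-group
#' log-rank comparison and univariate + multivariate Cox models run as a
#' validation stage. With `outdir` set, every stage output is written as TSV
#' together with a manifest recording the configuration hash and row counts;
#' identical inputs and configuration reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `epidriver_run` with elements `expr`, `meth`
#'   (gene-level matrices), `de`, `dm`, `calls`, `filtered`, `subnetwork`
#'   summary, `enrichment`, `drivers`, optional `clinical`, and `counts`
#'   (the gene funnel per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- NULL
  if (!is.null(config$samples_file))
    samples <- stage("samples", utils::read.delim(config$samples_file,
                                                  stringsAsFactors = FALSE))
  expr <- stage("read expression",
                read_omics_matrix(config$expr_file, samples, "expression"))
  beta <- stage("read methylation",
                read_omics_matrix(config$beta_file, samples, "methylation"))
  annot <- stage("read probe annotation",
                 utils::read.delim(config$probe_annot_file,
                                   stringsAsFactors = FALSE))
  genes <- stage("read gene models",
                 utils::read.delim(config$gene_model_file,
                                   stringsAsFactors = FALSE))
  net <- stage("read network", load_network(config$network_file))

  if (config$expression_unit == "fpkm")
    expr <- stage("fpkm_to_tpm", fpkm_to_tpm(expr))
  beta <- stage("filter_probes", filter_probes(beta, annot))
  mapping <- stage("map_probes_to_promoters",
                   map_probes_to_promoters(annot, genes, config$upstream_bp,
                                           config$downstream_bp,
                                           config$stranded))
  meth <- stage("aggregate_promoter_methylation",
                aggregate_promoter_methylation(beta, mapping))

  shared <- intersect(rownames(expr), rownames(meth))
  expr_g <- expr[shared, ]
  meth_g <- meth[shared, ]
  de <- stage("differential expression",
              call_differential_expression(expr_g, config$lfc_threshold,
                                           config$fdr_threshold))
  dm <- stage("differential methylation",
              call_differential_methylation(meth_g,
                                            config$meth_p_threshold))
  calls <- stage("classify_ei_es", classify_ei_es(de, dm))
  filtered <- stage("correlation_filter",
                    correlation_filter(calls, expr_g, meth_g,
                                       config$rho_threshold))
  sub <- stage("induced_subnetwork",
               induced_subnetwork(net, filtered$gene_id))
  enrichment <- stage("neighborhood_enrichment",
                      neighborhood_enrichment(net, filtered$gene_id,
                                              adjust = config$adjust))
  drivers <- stage("select_drivers",
                   select_drivers(enrichment, config$driver_fdr,
                                  config$driver_proportion))

  clinical <- NULL
  if (!is.null(config$clinical_file)) {
    clin <- stage("read clinical",
                  utils::read.csv(config$clinical_file,
                                  stringsAsFactors = FALSE))
    clinical <- stage("clinical validation",
                      validate_clinical(clin, config$correction))
  }

  counts <- c(genes_shared = length(shared),
              expression_up = sum(de$direction == "up"),
              expression_down = sum(de$direction == "down"),
              methylation_up = sum(dm$direction == "up"),
              methylation_down = sum(dm$direction == "down"),
              ei = sum(calls$epigenetic_class == "EI"),
              es = sum(calls$epigenetic_class == "ES"),
              ei_filtered = sum(filtered$epigenetic_class == "EI"),
              es_filtered = sum(filtered$epigenetic_class == "ES"),
              subnetwork_nodes = sub$n_nodes,
              drivers = nrow(drivers))
  res <- structure(list(expr = expr_g, meth = meth_g, de = de, dm = dm,
                        calls = calls, filtered = filtered,
                        subnetwork = sub[c("n_nodes", "n_edges",
                                           "mean_degree")],
                        enrichment = enrichment, drivers = drivers,
                        clinical = clinical, counts = counts,
                        config = config),
                   class = "epidriver_run")
  if (!is.null(config$outdir)) write_run(res, config)
  res
}

# clinical validation stage: marker vs TNM association, log-rank, Cox
validate_clinical <- function(clin, correction = "none") {
  need <- c("marker_level", "tnm_stage", "follow_up", "event")
  if (!all(need %in% names(clin)))
    stop("clinical table lacks column(s): ",
         paste(setdiff(need, names(clin)), collapse = ", "))
  tab <- table(clin$tnm_stage, clin$marker_level)
  assoc <- if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
               all(colSums(tab) > 0))
    chi_square_2x2(tab, correction) else NULL
  two_groups <- length(unique(clin$marker_level)) >= 2
  lr <- if (two_groups)
    logrank_test(clin$follow_up, clin$event, clin$marker_level) else NULL
  km <- lapply(split(clin, clin$marker_level), function(d)
    kaplan_meier(d$follow_up, d$event))
  covars <- intersect(c("marker_level", "age", "gender", "pathogenesis",
                        "alt", "ast", "tb", "alb", "tnm_stage",
                        "tumor_size"), names(clin))
  covars <- covars[vapply(covars, function(v)
    length(unique(clin[[v]])) > 1, logical(1))]
  cox <- if (two_groups && sum(clin$event) >= 2)
    cox_fit(clin, covars, type = "both") else NULL
  list(association = assoc, km = km, logrank = lr, cox = cox)
}

write_run <- function(res, config) {
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) utils::write.table(
    x, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(res$de, "differential_expression.tsv")
  wt(res$dm, "differential_methylation.tsv")
  wt(res$calls, "epigenetic_calls.tsv")
  wt(res$filtered, "correlated_calls.tsv")
  wt(res$enrichment, "neighborhood_enrichment.tsv")
  wt(res$drivers, "drivers.tsv")
  cfg <- unclass(config)
  cfg$outdir <- NULL
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("epidriver"))),
    sprintf("config_hash: %s",
            paste(format(unlist(cfg)), collapse = "|")),
    sprintf("%s: %d", names(res$counts), res$counts))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}

#' @export
print.epidriver_run <- function(x, ...) {
  cat("Integrated methylation-expression driver analysis\n")
  cat(sprintf("  genes analyzed: %d\n", x$counts["genes_shared"]))
  cat(sprintf("  differential expression: %d up / %d down\n",
              x$counts["expression_up"], x$counts["expression_down"]))
  cat(sprintf("  differential methylation: %d up / %d down\n",
              x$counts["methylation_up"], x$counts["methylation_down"]))
  cat(sprintf("  epigenetic classes: %d EI / %d ES (%d / %d after rho < %g)\n",
              x$counts["ei"], x$counts["es"], x$counts["ei_filtered"],
              x$counts["es_filtered"], x$config$rho_threshold))
  cat(sprintf("  EI/ES subnetwork: %d nodes, mean degree %.2f\n",
              x$subnetwork$n_nodes, x$subnetwork$mean_degree))
  cat(sprintf("  drivers (FDR < %g, proportion > %g): %s\n",
              x$config$driver_fdr, x$config$driver_proportion,
              if (nrow(x$drivers)) paste(x$drivers$gene_id, collapse = ", ")
              else "none"))
  if (!is.null(x$clinical) && !is.null(x$clinical$logrank))
    cat(sprintf("  clinical: log-rank p = %.3g, association p = %s\n",
                x$clinical$logrank$p_value,
                if (is.null(x$clinical$association)) "NA" else
                  format(signif(x$clinical$association$p_value, 3))))
  invisible(x)
}
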