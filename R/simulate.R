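#' Simulation configuration
#'
#' Bundles every parameter of the synthetic tumor/normal multi-omics,
#' interaction-network and survival-cohort generators. Defaults emulate the
#' study conditions the pipeline targets: 41 matched tumor/normal pairs, a
#' small minority of epigenetically induced (EI) and suppressed (ES) genes
#' with anticorrelated expression/promoter-methylation shifts, a scale-free
#' interaction network with mean degree about 20 in which four planted
#' drivers concentrate EI/ES neighbors, and an 80-patient cohort whose
#' marker-high patients carry a hazard ratio of 4.465.
#'
#' @param n_pairs tumor/normal sample pairs (default 41).
#' @param n_genes total simulated genes (default 2000).
#' @param n_probes_per_gene inclusive range of CpG probes per promoter
#'   (default `c(1, 3)`).
#' @param n_ei,n_es planted EI / ES gene counts (defaults 60 / 20).
#' @param expr_effect log2 expression shift added to planted EI tumor samples
#'   and subtracted for ES (default 2).
#' @param meth_effect beta-scale promoter-methylation shift subtracted from
#'   planted EI tumor samples and added for ES (default 0.3).
#' @param coupling strength of the shared per-sample latent factor that
#'   enters expression positively and methylation negatively in planted
#'   genes, producing their negative Spearman correlation (default 0.8).
#' @param expr_sd,meth_sd residual noise standard deviations on the log2
#'   expression and logit beta scales (defaults 0.6 / 0.4).
#' @param network_nodes nodes of the background interaction network
#'   (default 2000; must be >= `n_genes`).
#' @param edges_per_new_node preferential-attachment edges per added node
#'   (default 10, giving mean degree about 20).
#' @param n_drivers planted driver genes, drawn from the planted EI/ES genes
#'   (default 4).
#' @param driver_wiring fraction of each planted driver's neighbors rewired
#'   to EI/ES-labeled nodes (default 0.5).
#' @param cohort_n patients in the survival cohort (default 80).
#' @param marker_log_hr planted log hazard ratio for marker-high patients
#'   (default `log(4.465)`).
#' @param stage_assoc log-odds increase of advanced (III-IV) TNM stage for
#'   marker-high patients (default 2.2); stage has no direct hazard effect.
#' @param baseline_hazard exponential event rate for marker-low patients, per
#'   month (default `log(2) / 50`, median survival 50 months).
#' @param follow_up_horizon administrative censoring horizon in months
#'   (default 120); censoring times are uniform on (0, horizon].
#' @param seed integer random seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 41, n_genes = 2000,
                       n_probes_per_gene = c(1, 3),
                       n_ei = 60, n_es = 20,
                       expr_effect = 2, meth_effect = 0.3, coupling = 0.8,
                       expr_sd = 0.6, meth_sd = 0.4,
                       network_nodes = 2000, edges_per_new_node = 10,
                       n_drivers = 4, driver_wiring = 0.5,
                       cohort_n = 80, marker_log_hr = log(4.465),
                       stage_assoc = 2.2,
                       baseline_hazard = log(2) / 50,
                       follow_up_horizon = 120, seed = 1) {
  cfg <- list(n_pairs = n_pairs, n_genes = n_genes,
              n_probes_per_gene = n_probes_per_gene, n_ei = n_ei,
              n_es = n_es, expr_effect = expr_effect,
              meth_effect = meth_effect, coupling = coupling,
              expr_sd = expr_sd, meth_sd = meth_sd,
              network_nodes = network_nodes,
              edges_per_new_node = edges_per_new_node,
              n_drivers = n_drivers, driver_wiring = driver_wiring,
              cohort_n = cohort_n, marker_log_hr = marker_log_hr,
              stage_assoc = stage_assoc, baseline_hazard = baseline_hazard,
              follow_up_horizon = follow_up_horizon, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pairs < 1 || n_genes < 1)
      stop("n_pairs and n_genes must be positive")
    if (n_ei + n_es > n_genes) stop("n_ei + n_es must not exceed n_genes")
    if (expr_effect < 0 || meth_effect < 0 || coupling < 0)
      stop("effect sizes must be non-negative")
    if (meth_effect > 0.44)
      stop("meth_effect would push planted betas outside [0, 1]")
    if (driver_wiring < 0 || driver_wiring > 1)
      stop("driver_wiring must lie in [0, 1]")
    if (network_nodes < n_genes)
      stop("network_nodes must be at least n_genes")
    if (n_drivers > n_ei + n_es)
      stop("n_drivers must not exceed the planted EI/ES count")
    if (cohort_n < 2) stop("cohort_n must be at least 2")
    if (follow_up_horizon <= 0) stop("follow-up horizon must be positive")
  })
  invisible(cfg)
}

# location m per element such that E[plogis(m + s * Z)] = target, Z std
# normal; Newton iteration with a fixed quadrature grid (vectorized)
logit_normal_location <- function(target, s) {
  zg <- seq(-6, 6, length.out = 201)
  w <- stats::dnorm(zg)
  w <- w / sum(w)
  m <- stats::qlogis(target)
  shift <- outer(s, zg)
  for (i in 1:30) {
    q <- stats::plogis(m + shift)
    e <- drop(q %*% w)
    d <- drop((q * (1 - q)) %*% w)
    step <- (e - target) / pmax(d, 1e-12)
    m <- m - step
    if (max(abs(step)) < 1e-12) break
  }
  m
}

# run expr with the RNG seeded at seed + offset, restoring the caller's RNG
with_seed <- function(seed, offset, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

#' Simulate paired tumor/normal expression and promoter methylation
#'
#' Generates gene-level expression (log-normal per gene, effects additive on
#' the log2 scale), a CpG probe beta matrix (logit-normal per probe around a
#' gene-level promoter mean), probe annotation placing each gene's probes
#' inside its promoter window, gene models, and the planted truth labels.
#' Planted EI genes have tumor expression raised by `expr_effect` log2 units
#' and tumor promoter betas lowered by `meth_effect` (ES genes mirrored), and
#' share a per-sample latent factor between expression (positive sign) and
#' methylation (negative sign) with weight `coupling`, so their promoter
#' methylation and expression are negatively correlated across samples.
#'
#' @param config a [sim_config()].
#' @return list with `expr` and `beta` (`omics_matrix` objects; beta is
#'   probe-level), `probe_annotation`, `gene_models`, and `truth`
#'   (data.frames `genes` with planted class and driver flag).
#' @export
simulate_omics <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, 0L, {
    G <- config$n_genes
    n <- config$n_pairs
    genes <- sprintf("g%04d", seq_len(G))
    class <- rep("null", G)
    ei <- seq_len(config$n_ei)
    es <- config$n_ei + seq_len(config$n_es)
    class[ei] <- "EI"
    class[es] <- "ES"
    planted <- class != "null"
    # drivers are a subset of the planted EI/ES genes (sampled here so the
    # network generator sees the same labels)
    driver <- rep(FALSE, G)
    if (config$n_drivers > 0) {
      idx <- which(planted)
      driver[idx[sample.int(length(idx), config$n_drivers)]] <- TRUE
    }

    samples <- c(sprintf("p%02d_tumor", seq_len(n)),
                 sprintf("p%02d_normal", seq_len(n)))
    group <- rep(c("tumor", "normal"), each = n)
    pair <- rep(sprintf("p%02d", seq_len(n)), 2)

    # per-gene baselines
    mu <- stats::rnorm(G, mean = 5, sd = 1.5)          # log2 expression
    base_beta <- stats::runif(G, 0.1, 0.9)
    base_beta[planted] <- stats::runif(sum(planted), 0.4, 0.6)
    lo <- 0.02
    if (any(base_beta[planted] - config$meth_effect < lo) ||
        any(base_beta[planted] + config$meth_effect > 1 - lo))
      stop("meth_effect pushes planted betas outside [0, 1]")

    tumor_ind <- matrix(rep(group == "tumor", each = G), nrow = G)
    dir_e <- ifelse(class == "EI", 1, ifelse(class == "ES", -1, 0))
    z <- matrix(stats::rnorm(G * 2 * n), G)            # shared latent factor
    couple <- ifelse(planted, config$coupling, 0)
    log2_expr <- mu + dir_e * config$expr_effect * tumor_ind +
      couple * z +
      matrix(stats::rnorm(G * 2 * n, sd = config$expr_sd), G)
    expr_vals <- 2^log2_expr
    dimnames(expr_vals) <- list(genes, samples)

    # probes per gene, placed inside the promoter window
    rng <- seq(config$n_probes_per_gene[1], config$n_probes_per_gene[2])
    npp <- rng[sample.int(length(rng), G, replace = TRUE)]
    tss <- 100000L * seq_len(G)
    strand <- sample(c("+", "-"), G, replace = TRUE)
    gene_models <- data.frame(gene_id = genes, chromosome = "chr1",
                              tss = tss, strand = strand,
                              stringsAsFactors = FALSE)
    offset <- unlist(lapply(npp, function(k) sample(-800:200, k)))
    gidx <- rep(seq_len(G), npp)
    pos <- ifelse(strand[gidx] == "+", tss[gidx] + offset,
                  tss[gidx] - offset)
    probe_annotation <- data.frame(
      probe_id = sprintf("cg%05d", seq_along(gidx)),
      chromosome = "chr1", position = as.integer(pos),
      stringsAsFactors = FALSE)

    # probe betas: logit-normal around the group-level promoter target,
    # sharing -z with expression for planted genes; the logit location is
    # solved so the marginal beta mean equals the target (the plain
    # logit(target) location would shrink group means toward 0.5)
    target <- base_beta - dir_e * config$meth_effect * tumor_ind
    target <- pmin(pmax(target, lo), 1 - lo)
    sdev <- sqrt(couple^2 + config$meth_sd^2)
    loc_tumor <- logit_normal_location(target[, 1], sdev)
    loc_normal <- logit_normal_location(target[, ncol(target)], sdev)
    logit_target <- loc_normal + (loc_tumor - loc_normal) * tumor_ind
    P <- length(gidx)
    logit_beta <- logit_target[gidx, , drop = FALSE] -
      (couple * z)[gidx, , drop = FALSE] +
      matrix(stats::rnorm(P * 2 * n, sd = config$meth_sd), P)
    beta_vals <- stats::plogis(logit_beta)
    dimnames(beta_vals) <- list(probe_annotation$probe_id, samples)

    list(expr = omics_matrix(expr_vals, group, pair, "expression"),
         beta = omics_matrix(beta_vals, group, pair, "methylation"),
         probe_annotation = probe_annotation,
         gene_models = gene_models,
         truth = data.frame(gene_id = genes, class = class,
                            driver = driver, stringsAsFactors = FALSE))
  })
}

#' Simulate a scale-free interaction network with planted driver wiring
#'
#' The background network is grown by preferential attachment
#' ([igraph::sample_pa()]), giving the heavy-tailed degree distribution of
#' curated protein-interaction resources. Nodes are named after the simulated
#' genes (plus anonymous nodes when `network_nodes > n_genes`). For each
#' planted driver, a fraction `driver_wiring` of its incident edges is
#' rewired so the other endpoint is an EI/ES-labeled node, planting an
#' enriched neighborhood; the graph stays simple and undirected.
#'
#' @param config a [sim_config()].
#' @param labels truth data.frame from [simulate_omics()] (`truth` element),
#'   with columns `gene_id`, `class`, `driver`.
#' @return an undirected simple igraph network.
#' @export
simulate_network <- function(config, labels) {
  validate_sim_config(config)
  stopifnot(all(c("gene_id", "class", "driver") %in% names(labels)))
  with_seed(config$seed, 1L, {
    Nn <- config$network_nodes
    g <- igraph::sample_pa(Nn, m = config$edges_per_new_node,
                           directed = FALSE)
    extra <- Nn - nrow(labels)
    igraph::V(g)$name <- c(labels$gene_id,
                           if (extra > 0) sprintf("x%04d", seq_len(extra)))
    # shuffle the node-name assignment so planted genes are not biased
    # toward the oldest (highest-degree) preferential-attachment nodes
    igraph::V(g)$name <- sample(igraph::V(g)$name)
    marked <- labels$gene_id[labels$class != "null"]
    drivers <- labels$gene_id[labels$driver]
    for (d in drivers) {
      nb <- igraph::neighbors(g, d)$name
      k <- round(config$driver_wiring * length(nb))
      if (k == 0) next
      pool <- setdiff(marked, c(d, nb))
      k <- min(k, length(pool))
      drop_nb <- sample(nb, k)
      add_nb <- sample(pool, k)
      g <- igraph::delete_edges(g, igraph::get_edge_ids(
        g, rbind(rep(d, k), drop_nb)))
      g <- igraph::add_edges(g, rbind(rep(d, k), add_nb))
    }
    igraph::simplify(g)
  })
}

#' Simulate a survival cohort with a planted marker effect
#'
#' Each patient carries a latent binary marker state (high with probability
#' 1/2). Staining scores are drawn uniformly from \{3, 4\} for marker-high
#' and \{1, 2\} for marker-low patients, so the IHC dichotomization recovers
#' the latent state. Survival times are exponential with the baseline hazard
#' multiplied by `exp(marker_log_hr)` for marker-high patients; censoring is
#' independent uniform on (0, follow_up_horizon]. TNM stage is associated
#' with the marker through `stage_assoc` (log-odds scale) but has no direct
#' hazard effect; the remaining clinicopathological covariates are
#' independent binary draws.
#'
#' @param config a [sim_config()].
#' @return data.frame, one row per patient: `patient_id`, `staining_score`,
#'   `marker_level`, binary covariates (`age`, `gender`, `pathogenesis`,
#'   `alt`, `ast`, `tb`, `alb`, `tumor_size`), `tnm_stage`, `follow_up`,
#'   `event`, and the latent `marker_state`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, 2L, {
    n <- config$cohort_n
    high <- stats::rbinom(n, 1, 0.5)
    score <- ifelse(high == 1, sample(3:4, n, replace = TRUE),
                    sample(1:2, n, replace = TRUE))
    p_adv <- stats::plogis(stats::qlogis(0.08) + config$stage_assoc * high)
    stage <- ifelse(stats::rbinom(n, 1, p_adv) == 1, "III-IV", "I-II")
    rate <- config$baseline_hazard * exp(config$marker_log_hr * high)
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::runif(n, 0, config$follow_up_horizon)
    event <- as.integer(t_event <= t_cens)
    cov2 <- function(levels) factor(sample(levels, n, replace = TRUE),
                                    levels = levels)
    data.frame(
      patient_id = sprintf("pt%03d", seq_len(n)),
      staining_score = as.integer(score),
      marker_level = dichotomize(score, "ihc"),
      age = cov2(c("<=55", ">55")), gender = cov2(c("female", "male")),
      pathogenesis = cov2(c("HBV", "other")),
      alt = cov2(c("<=35", ">35")), ast = cov2(c("<=31", ">31")),
      tb = cov2(c("<=12", ">12")), alb = cov2(c("<=40", ">40")),
      tumor_size = cov2(c("<=5cm", ">5cm")),
      tnm_stage = factor(stage, levels = c("I-II", "III-IV")),
      follow_up = pmin(t_event, t_cens), event = event,
      marker_state = ifelse(high == 1, "high", "low"),
      stringsAsFactors = FALSE)
  })
}

#' Write a simulation bundle to tab-separated files
#'
#' Writes the formats the pipeline reads: `expression.tsv`, `beta.tsv`
#' (matrices with a header of sample ids and first column of row ids),
#' `probe_annotation.tsv`, `gene_models.tsv`, `samples.tsv` (sample id,
#' group, pair), `network.tsv` (edge list), `clinical.csv` and
#' `truth_labels.tsv`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of written file paths.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  omics <- simulate_omics(config)
  net <- simulate_network(config, omics$truth)
  cohort <- simulate_cohort(config)
  f <- function(x) file.path(outdir, x)
  write_matrix_tsv(omics$expr, f("expression.tsv"), "gene_id")
  write_matrix_tsv(omics$beta, f("beta.tsv"), "probe_id")
  utils::write.table(omics$probe_annotation, f("probe_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(omics$gene_models, f("gene_models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(omics$expr),
               group = groups_of(omics$expr),
               pair = attr(omics$expr, "pair")),
    f("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(igraph::as_edgelist(net), f("network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(cohort, f("clinical.csv"), row.names = FALSE)
  utils::write.table(omics$truth, f("truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(vapply(c("expression.tsv", "beta.tsv", "probe_annotation.tsv",
                     "gene_models.tsv", "samples.tsv", "network.tsv",
                     "clinical.csv", "truth_labels.tsv"), f, character(1)))
}
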