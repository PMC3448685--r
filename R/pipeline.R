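#' Bonferroni threshold for the interaction scan
#'
#' Always derived from the executed-test count, never hard-coded:
#' `alpha / N`.
#'
#' @param n_tests number of executed interaction tests.
#' @param alpha family-wise error target.
#' @return the per-test weighted-p threshold.
#' @export
interaction_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests > 0, alpha > 0)
  alpha / n_tests
}

# map arbitrary (snp_id, chrom, pos) rows to named regions
map_positions_to_regions <- function(snp_df, regions) {
  out <- vector("list", nrow(snp_df))
  for (i in seq_len(nrow(snp_df))) {
    hit <- interval_contains(regions, snp_df$chrom[i], snp_df$pos[i])
    if (any(hit)) {
      out[[i]] <- data.frame(snp_id = snp_df$snp_id[i],
                             region = regions$name[hit],
                             chrom = snp_df$chrom[i], pos = snp_df$pos[i],
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(snp_id = character(0), region = character(0),
                      chrom = character(0), pos = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Run the discovery workflow
#'
#' Orchestrates the full discovery pipeline: genotype QC, assignment of
#' SNPs to pri-miRNA and 3'UTR intervals, LD-proxy lookup for
#' ungenotyped 3utrSNP targets, probe filtering, selection accounting,
#' the marginal miSNP scan, and the Levene-weighted interaction scan.
#' Thresholds are derived from executed-test counts, and the returned
#' log records every effective parameter and count so `N` is auditable.
#'
#' @param G a [genotype_matrix()] of genotyped SNPs.
#' @param E expression matrix (samples x probes).
#' @param covariates covariate data frame with `sample_id`.
#' @param annotations an `annotation_set`.
#' @param target_catalog optional data frame of ungenotyped 3utrSNP
#'   targets (`snp_id`, `chrom`, `pos`) to be represented by LD proxies.
#' @param reference optional [genotype_matrix()] holding target
#'   genotypes for proxy lookup (reference panel); required when
#'   `target_catalog` is given.
#' @param thresholds a [qc_thresholds()].
#' @param alpha family-wise error target.
#' @param window cis window in bp.
#' @param r2_min proxy acceptance threshold.
#' @param weighting `"levene"` or `"none"` for the interaction scan.
#' @return a `discovery_run` list: `qc`, `selection`
#'   (`selection_report`), `marginal` (scan data frame), `interaction`
#'   (`interaction_scan`), `thresholds`, `log` (character).
#' @export
run_discovery <- function(G, E, covariates, annotations,
                          target_catalog = NULL, reference = NULL,
                          thresholds = qc_thresholds(), alpha = 0.05,
                          window = 1e6, r2_min = 0.90,
                          weighting = "levene") {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  miss <- setdiff(rownames(G$dosage),
                  intersect(rownames(E), covariates$sample_id))
  if (length(miss) > 0) {
    stop("sample id(s) missing from expression/covariates: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  say("samples: %d", nrow(G$dosage))
  Gq <- qc_filter_snps(G, thresholds)
  rep_qc <- attr(Gq, "qc_report")
  say("QC: %d of %d SNPs retained (maf>%g, call>%g, hwe>%g); removed: maf=%d call_rate=%d hwe=%d",
      ncol(Gq$dosage), ncol(G$dosage), thresholds$maf_min,
      thresholds$call_rate_min, thresholds$hwe_p_min,
      sum(rep_qc$removed_by == "maf", na.rm = TRUE),
      sum(rep_qc$removed_by == "call_rate", na.rm = TRUE),
      sum(rep_qc$removed_by == "hwe", na.rm = TRUE))
  mi_asgn <- map_snps_to_regions(Gq, annotations$mirna)
  utr_asgn <- map_snps_to_regions(Gq, annotations$utr3)
  utr_proxies <- data.frame(target = utr_asgn$snp_id,
                            proxy = utr_asgn$snp_id, r2 = 1,
                            stringsAsFactors = FALSE)
  if (!is.null(target_catalog) && nrow(target_catalog) > 0) {
    if (is.null(reference)) stop("target_catalog given without a reference panel")
    cand <- setdiff(colnames(Gq$dosage), target_catalog$snp_id)
    for (i in seq_len(nrow(target_catalog))) {
      px <- select_proxy(target_catalog$snp_id[i], cand, Gq,
                         r2_min = r2_min, G_target = reference)
      if (!is.null(px)) utr_proxies <- rbind(utr_proxies, px)
    }
    t_asgn <- map_positions_to_regions(target_catalog, annotations$utr3)
    t_asgn <- t_asgn[t_asgn$snp_id %in% utr_proxies$target, , drop = FALSE]
    utr_asgn <- rbind(utr_asgn, t_asgn)
    say("proxy lookup: %d of %d targets tagged at r2>=%g",
        sum(target_catalog$snp_id %in% utr_proxies$target),
        nrow(target_catalog), r2_min)
  }
  eligible <- filter_probes(annotations$probes)
  say("probes: %d of %d eligible (perfect quality, no SNP in probe)",
      nrow(eligible), nrow(annotations$probes))
  sel <- build_selection_report(mi_asgn, utr_asgn, eligible, utr_proxies)
  say("selection: %d miSNPs (%d miRNAs); interaction units: %d",
      sel$n_misnp, sel$n_mirna_distinct, nrow(sel$units))
  mi_ids <- unique(mi_asgn$snp_id)
  Gmi <- genotype_matrix(Gq$dosage[, mi_ids, drop = FALSE],
                         Gq$snps[match(mi_ids, Gq$snps$snp_id), ])
  marginal <- run_marginal_scan(Gmi, E, covariates, eligible,
                                alpha = alpha, window = window)
  say("marginal scan: %d tests, threshold %.3g, %d significant",
      nrow(marginal), attr(marginal, "threshold"),
      sum(marginal$significant))
  inter <- run_interaction_scan(Gq, E, covariates, sel$units, mi_ids,
                                alpha = alpha, weighting = weighting)
  say("interaction scan: N=%d (of %d attempted), threshold %.3g, %d significant",
      inter$dimensions$N, inter$dimensions$N + nrow(inter$skipped),
      inter$threshold, sum(inter$records$significant))
  structure(list(qc = rep_qc, selection = sel, marginal = marginal,
                 interaction = inter,
                 thresholds = list(
                   marginal = attr(marginal, "threshold"),
                   interaction = inter$threshold, alpha = alpha),
                 log = log),
            class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("discovery_run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Run the replication workflow
#'
#' Re-tests the significant discovery interactions in an independent
#' cohort with [replicate_interactions()] (standard Bonferroni over the
#' replicable hits; disease status enters through the covariate table).
#'
#' @param hits significant records from a discovery `interaction_scan`
#'   (SNP/probe ids remapped to replication proxies beforehand, if
#'   needed).
#' @param G,E,covariates replication-cohort data.
#' @param alpha family-wise error target.
#' @return the [replicate_interactions()] data frame plus a `log`
#'   attribute.
#' @export
run_replication <- function(hits, G, E, covariates, alpha = 0.05) {
  out <- replicate_interactions(hits, G, E, covariates, alpha = alpha)
  attr(out, "log") <- sprintf(
    "replication: %d hits, %d replicable, threshold %.3g, %d replicated",
    nrow(out), attr(out, "k"), attr(out, "threshold"),
    sum(out$replicated))
  out
}

#' Family-wise error of the weighted scan under a global null
#'
#' Monte-Carlo estimate of the probability that a Levene-weighted
#' interaction scan declares at least one significant test when no
#' interaction exists. Each replicate simulates a cohort with
#' `n_units` 3utrSNP/probe units and `n_misnp` miSNPs, with
#' genotype-dependent residual variance planted at a fraction of the
#' units (so the Levene weights are genuinely informative but the
#' interaction null still holds), then runs the full weighted scan.
#'
#' @param n_reps number of replicate scans.
#' @param seed master seed; each replicate uses a derived substream.
#' @param n_samples cohort size per replicate.
#' @param n_units number of (3utrSNP, probe) units.
#' @param n_misnp number of miSNPs.
#' @param het_fraction fraction of units with a variance-heterogeneity
#'   plan.
#' @param alpha family-wise error target of the scan.
#' @param weighting `"levene"` or `"none"`.
#' @return list with `fwer`, `n_false` (replicates with >= 1 call),
#'   `n_reps`, `n_tests` (executed tests in the first replicate).
#' @export
fwer_null_scan <- function(n_reps = 500, seed, n_samples = 300,
                           n_units = 10, n_misnp = 20,
                           het_fraction = 0.2, alpha = 0.05,
                           weighting = "levene") {
  if (missing(seed)) stop("seed is mandatory")
  genes <- sprintf("g%02d", seq_len(n_units))
  utr_ids <- sprintf("u%02d", seq_len(n_units))
  mi_ids <- sprintf("mi%02d", seq_len(n_misnp))
  probe_ids <- sprintf("P_%s", genes)
  probes <- data.frame(probe_id = probe_ids, gene = genes,
                       chrom = "chr1", start1 = 1e6 * seq_len(n_units),
                       end1 = 1e6 * seq_len(n_units) + 999,
                       quality = "perfect", contains_snp = FALSE,
                       stringsAsFactors = FALSE)
  n_het <- round(het_fraction * n_units)
  units <- data.frame(gene = genes, utr_proxy = utr_ids,
                      probe_id = probe_ids, stringsAsFactors = FALSE)
  n_false <- 0
  n_tests <- NA_integer_
  for (r in seq_len(n_reps)) {
    rep_seed <- substream_seed(seed, 100 + r)
    set.seed(rep_seed)
    mafs <- round(stats::runif(n_units + n_misnp, 0.2, 0.5), 2)
    snps <- data.frame(snp_id = c(utr_ids, mi_ids), chrom = "chr1",
                       pos = seq_len(n_units + n_misnp),
                       maf = mafs, stringsAsFactors = FALSE)
    vp <- if (n_het > 0) {
      data.frame(snp_id = utr_ids[seq_len(n_het)],
                 probe_id = probe_ids[seq_len(n_het)],
                 sd0 = 0.3, sd1 = 0.45, sd2 = 0.6,
                 stringsAsFactors = FALSE)
    } else NULL
    cfg <- scenario_config(n_samples = n_samples, snps = snps,
                           probes = probes, variance_plan = vp,
                           noise_sd = 0.3, seed = rep_seed)
    b <- simulate_scenario(cfg)
    scan <- run_interaction_scan(b$genotypes, b$expression,
                                 b$covariates, units, mi_ids,
                                 alpha = alpha, weighting = weighting)
    if (r == 1) n_tests <- scan$dimensions$N
    if (any(scan$records$significant)) n_false <- n_false + 1
  }
  list(fwer = n_false / n_reps, n_false = n_false, n_reps = n_reps,
       n_tests = n_tests)
}
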