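#' Miniature end-to-end scenario with known truth
#'
#' Builds a reduced replica of the study design the pipeline targets:
#' 30 miSNPs in pri-miRNA intervals, ~100 3utrSNPs across 60 genes with
#' a realistic per-gene histogram, ~200 probes (some failing the
#' quality / SNP-in-probe filters), six ungenotyped 3utrSNPs tagged by
#' genotyped LD proxies (two of them sharing one proxy, so the proxy map
#' is many-to-one), two planted miSNP x 3utrSNP interactions, one
#' mediation chain (a cis-regulated gene driving three trans targets),
#' and genotype-dependent residual variance at two null units to give
#' the Levene prioritization something to rank. The truth ledger holds
#' every planted parameter plus the expected selection histogram.
#'
#' @param n_samples cohort size (default 800).
#' @param seed master seed (mandatory).
#' @return list with `genotypes` (genotyped SNPs only), `reference`
#'   (full panel including ungenotyped targets, for proxy lookup),
#'   `expression`, `covariates`, `annotations` (`annotation_set`),
#'   `target_catalog` (ungenotyped 3utrSNPs), and `truth`.
#' @export
make_miniature_study <- function(n_samples = 800, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_samples <= 0) stop("n_samples must be positive")
  # --- 60 interaction genes: per-gene genotyped 3utrSNP counts ---
  gene_counts <- c(rep(1, 34), rep(2, 14), rep(3, 7), rep(4, 3), 5, 6)
  genes <- sprintf("g%02d", seq_len(60))
  gene_chrom <- paste0("chr", (seq_len(60) - 1) %% 6 + 1)
  utr_start1 <- 2e6 * seq_len(60) + 1e4
  utr_end1 <- utr_start1 + 3999   # 4 kb 3'UTRs
  utr3 <- interval_from_1based(gene_chrom, utr_start1, utr_end1,
                               name = genes)
  set.seed(substream_seed(seed, 10))  # MAF draws are part of the design
  utr_snps <- do.call(rbind, lapply(seq_len(60), function(i) {
    k <- gene_counts[i]
    data.frame(snp_id = sprintf("u%02d_%d", i, seq_len(k)),
               chrom = gene_chrom[i],
               pos = utr_start1[i] + 100 * seq_len(k),
               maf = round(stats::runif(k, 0.15, 0.5), 2),
               gene = genes[i], stringsAsFactors = FALSE)
  }))
  # --- 30 miSNPs in 28 pri-miRNA intervals (two host a second SNP) ---
  mi_chrom <- paste0("chr", (seq_len(28) - 1) %% 4 + 7)
  mi_start1 <- 3e6 * seq_len(28) + 5e4
  # mir-003 (hosting the mediator miSNP mi03) sits cis to gene m001 on chr13
  mi_chrom[3] <- "chr13"
  mi_start1[3] <- 2e6 + 5e4   # 50 kb from gene m001's probe span
  mirna <- interval_from_1based(mi_chrom, mi_start1, mi_start1 + 99,
                                name = sprintf("mir-%03d", seq_len(28)))
  mi_pos <- c(mi_start1 + 10, mi_start1[1] + 50, mi_start1[2] + 50)
  misnp <- data.frame(
    snp_id = sprintf("mi%02d", seq_len(30)),
    chrom = c(mi_chrom, mi_chrom[1], mi_chrom[2]),
    pos = mi_pos,
    maf = round(stats::runif(30, 0.2, 0.5), 2),
    stringsAsFactors = FALSE)
  # --- 100 marginal-only genes with one probe each ---
  mgenes <- sprintf("m%03d", seq_len(100))
  mchrom <- paste0("chr", (seq_len(100) - 1) %% 6 + 13)
  mstart1 <- 2e6 * ceiling(seq_len(100) / 6) + 1e5 * ((seq_len(100) - 1) %% 6)
  # --- probes ---
  p_int <- data.frame(  # one eligible probe per interaction gene
    probe_id = sprintf("P_%s", genes), gene = genes, chrom = gene_chrom,
    start1 = utr_end1 + 500, end1 = utr_end1 + 1700,
    quality = "perfect", contains_snp = FALSE, stringsAsFactors = FALSE)
  p_int2 <- data.frame(  # second probe for the first ten genes
    probe_id = sprintf("P_%s_b", genes[1:10]), gene = genes[1:10],
    chrom = gene_chrom[1:10], start1 = utr_end1[1:10] + 2000,
    end1 = utr_end1[1:10] + 3200, quality = "perfect",
    contains_snp = FALSE, stringsAsFactors = FALSE)
  p_marg <- data.frame(
    probe_id = sprintf("P_%s", mgenes), gene = mgenes, chrom = mchrom,
    start1 = mstart1, end1 = mstart1 + 1200, quality = "perfect",
    contains_snp = FALSE, stringsAsFactors = FALSE)
  p_bad <- data.frame(  # filter-exercising probes: bad quality / SNP inside
    probe_id = c(sprintf("P_%s_q", genes[11:25]),
                 sprintf("P_%s_s", genes[26:35])),
    gene = c(genes[11:25], genes[26:35]),
    chrom = c(gene_chrom[11:25], gene_chrom[26:35]),
    start1 = c(utr_end1[11:25] + 2000, utr_end1[26:35] + 2000),
    end1 = c(utr_end1[11:25] + 3200, utr_end1[26:35] + 3200),
    quality = c(rep("good", 15), rep("perfect", 10)),
    contains_snp = c(rep(FALSE, 15), rep(TRUE, 10)),
    stringsAsFactors = FALSE)
  probes <- rbind(p_int, p_int2, p_marg, p_bad)
  # --- six ungenotyped 3utrSNP targets tagged by genotyped proxies ---
  # targets t1..t6 sit in the 3'UTRs of g01..g06; proxies px1..px5 sit
  # just outside; t5 and t6 share px5 (t6 is a perfect copy of t5).
  tg_idx <- 1:6
  target_catalog <- data.frame(
    snp_id = sprintf("t%d", tg_idx), chrom = gene_chrom[tg_idx],
    pos = utr_start1[tg_idx] + 2000, gene = genes[tg_idx],
    stringsAsFactors = FALSE)
  proxy_ids <- sprintf("px%d", 1:5)
  ld_pairs <- data.frame(
    snp1 = sprintf("t%d", 1:5), snp2 = proxy_ids,
    f_AB = 0.295, f_Ab = 0.005, f_aB = 0.005, f_ab = 0.695,
    chrom1 = gene_chrom[1:5], pos1 = utr_start1[1:5] + 2000,
    chrom2 = gene_chrom[1:5], pos2 = utr_end1[1:5] + 6000,
    stringsAsFactors = FALSE)
  # --- effect plan ---
  interactions <- data.frame(
    snp1 = c("u20_1", "u40_1"), snp2 = c("mi05", "mi12"),
    probe_id = c("P_g20", "P_g40"), beta = c(0.5, -0.6),
    stringsAsFactors = FALSE)
  additive <- data.frame(snp_id = "mi03", probe_id = "P_m001", beta = 0.5,
                         stringsAsFactors = FALSE)
  mediation <- data.frame(
    mediator_probe = "P_m001",
    target_probe = c("P_m002", "P_m003", "P_m004"),
    beta = 0.4, stringsAsFactors = FALSE)
  variance_plan <- data.frame(  # heterogeneity at two null units
    snp_id = c("u30_1", "u31_1"), probe_id = c("P_g30", "P_g31"),
    sd0 = 0.3, sd1 = 0.45, sd2 = 0.6, stringsAsFactors = FALSE)
  cfg <- scenario_config(
    n_samples = n_samples,
    snps = rbind(
      utr_snps[, c("snp_id", "chrom", "pos", "maf")],
      misnp),
    ld_pairs = ld_pairs,
    probes = probes,
    additive = additive, interactions = interactions,
    mediation = mediation, variance_plan = variance_plan,
    noise_sd = 0.3, seed = seed)
  bundle <- simulate_scenario(cfg)
  G_full <- bundle$genotypes
  # duplicate t5 as t6 (perfect copy: shares px5 as proxy)
  dup <- G_full$dosage[, "t5", drop = FALSE]
  colnames(dup) <- "t6"
  G_full <- genotype_matrix(
    cbind(G_full$dosage, dup),
    rbind(G_full$snps,
          data.frame(snp_id = "t6", chrom = gene_chrom[6],
                     pos = utr_start1[6] + 2000, major = "A", minor = "B",
                     stringsAsFactors = FALSE)))
  genotyped <- setdiff(colnames(G_full$dosage), target_catalog$snp_id)
  G_typed <- genotype_matrix(G_full$dosage[, genotyped, drop = FALSE],
                             G_full$snps[match(genotyped, G_full$snps$snp_id), ])
  ann <- annotation_set(mirna, utr3, probes_internal(probes))
  # expected per-gene histogram: baseline counts +1 for g01..g06 (targets)
  expected_counts <- gene_counts
  expected_counts[tg_idx] <- expected_counts[tg_idx] + 1
  hist_tab <- table(expected_counts)
  truth_hist <- data.frame(n_utrsnp = as.integer(names(hist_tab)),
                           n_genes = as.integer(hist_tab))
  bundle$truth$histogram <- truth_hist
  bundle$truth$n_misnp <- 30
  bundle$truth$n_mirna_distinct <- 28
  bundle$truth$n_3utrsnp <- nrow(utr_snps) + 6
  bundle$truth$n_3utrsnp_proxies <- nrow(utr_snps) + 5
  bundle$truth$proxy_map <- data.frame(
    target = sprintf("t%d", 1:6),
    proxy = c(proxy_ids, "px5"), stringsAsFactors = FALSE)
  list(genotypes = G_typed, reference = G_full,
       expression = bundle$expression, covariates = bundle$covariates,
       annotations = ann, target_catalog = target_catalog,
       truth = bundle$truth)
}

# probe annotation table in internal 0-based half-open coordinates
probes_internal <- function(probes) {
  data.frame(probe_id = probes$probe_id, gene = probes$gene,
             chrom = probes$chrom, start = probes$start1 - 1,
             end = probes$end1, quality = probes$quality,
             contains_snp = probes$contains_snp, stringsAsFactors = FALSE)
}
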