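#!/usr/bin/env Rscript

# Stage 2 — genotype QC and selection of analysis units.
#
# Applies the discovery QC thresholds (MAF > 0.01, call rate > 0.98,
# exact HWE p > 1e-4), maps surviving SNPs into pri-miRNA and 3'UTR
# intervals, finds LD proxies (r2 >= 0.90) for the ungenotyped 3utrSNP
# targets, filters probes to perfect-quality SNP-free ones, and writes
# the selection accounting: the per-gene 3utrSNP histogram and the
# (gene, probe, 3utrSNP-proxy) units the interaction scan will test.

suppressMessages(library(misnpscan))
dir.create("results", showWarnings = FALSE)

sc <- make_miniature_study(n_samples = 800, seed = 1)

Gq <- qc_filter_snps(sc$genotypes, qc_thresholds())
qc <- attr(Gq, "qc_report")
cat(sprintf("QC: %d of %d SNPs retained\n", ncol(Gq$dosage),
            ncol(sc$genotypes$dosage)))
write_results(qc, "results/qc_report.tsv")

mi_asgn <- map_snps_to_regions(Gq, sc$annotations$mirna)
utr_asgn <- map_snps_to_regions(Gq, sc$annotations$utr3)
cat(sprintf("assignments: %d miSNPs in %d pri-miRNAs; %d genotyped 3utrSNPs\n",
            length(unique(mi_asgn$snp_id)), length(unique(mi_asgn$region)),
            length(unique(utr_asgn$snp_id))))

utr_proxies <- data.frame(target = utr_asgn$snp_id, proxy = utr_asgn$snp_id,
                          r2 = 1)
for (i in seq_len(nrow(sc$target_catalog))) {
  px <- select_proxy(sc$target_catalog$snp_id[i],
                     setdiff(colnames(Gq$dosage), sc$target_catalog$snp_id),
                     Gq, r2_min = 0.90, G_target = sc$reference)
  if (!is.null(px)) {
    utr_proxies <- rbind(utr_proxies, px)
    cat(sprintf("proxy: %s tagged by %s (r2 = %.3f)\n",
                px$target, px$proxy, px$r2))
  }
}

eligible <- filter_probes(sc$annotations$probes)
cat(sprintf("probes: %d of %d eligible\n", nrow(eligible),
            nrow(sc$annotations$probes)))

targets_in_utr <- merge(sc$target_catalog,
                        utr_proxies[utr_proxies$target != utr_proxies$proxy, ],
                        by.x = "snp_id", by.y = "target")
utr_all <- rbind(utr_asgn,
                 data.frame(snp_id = targets_in_utr$snp_id,
                            region = targets_in_utr$gene,
                            chrom = targets_in_utr$chrom,
                            pos = targets_in_utr$pos))
sel <- build_selection_report(mi_asgn, utr_all, eligible, utr_proxies)
print(sel)
write_results(sel$histogram, "results/selection_histogram.tsv")
write_results(sel$units, "results/selection_units.tsv")
tot <- histogram_totals(sel$histogram)
cat(sprintf("histogram totals: %d genes, %d proxy-derivable 3utrSNPs (%d distinct proxies)\n",
            tot$n_genes, tot$n_utrsnp_total, sel$n_3utrsnp_proxies))
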