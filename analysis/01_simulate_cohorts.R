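#!/usr/bin/env Rscript

# Stage 1 — simulate the discovery and replication cohorts.
#
# Builds the miniature two-cohort study the rest of the workflow analyses:
# a discovery cohort of 800 individuals and a replication cohort of 700
# (with a disease-status covariate), sharing one generating truth: two
# planted miSNP x 3utrSNP interactions, one cis-mediated trans-regulation
# chain, LD proxies for six ungenotyped 3utrSNPs, and genotype-dependent
# residual variance at two null units. Both cohorts are fully determined
# by their seeds, so later stages rebuild them instead of reading bulky
# intermediate files; this stage records the planted truth tables.

suppressMessages(library(misnpscan))
dir.create("results", showWarnings = FALSE)

disc <- make_miniature_study(n_samples = 800, seed = 1)
repl <- make_miniature_study(n_samples = 700, seed = 2)

cat(sprintf("discovery: %d samples, %d genotyped SNPs, %d probes\n",
            nrow(disc$genotypes$dosage), ncol(disc$genotypes$dosage),
            ncol(disc$expression)))
cat(sprintf("replication: %d samples (disease status added at analysis time)\n",
            nrow(repl$genotypes$dosage)))

write_results(disc$truth$interactions, "results/truth_interactions.tsv")
write_results(disc$truth$mediation, "results/truth_mediation.tsv")
write_results(disc$truth$variance_plan, "results/truth_variance_plan.tsv")
write_results(disc$truth$histogram, "results/truth_utr_histogram.tsv")
write_results(disc$truth$proxy_map, "results/truth_proxy_map.tsv")

cat("planted truth written to results/truth_*.tsv\n")
cat(sprintf("planted: %d interactions, %d mediated targets, %d proxies (%d shared)\n",
            nrow(disc$truth$interactions), nrow(disc$truth$mediation),
            nrow(disc$truth$proxy_map),
            sum(duplicated(disc$truth$proxy_map$proxy))))
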