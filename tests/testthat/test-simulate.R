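make_toy_config <- function(seed, n = 400, vp = NULL, inter = NULL,
                            med = NULL, addv = NULL) {
  snps <- data.frame(snp_id = c("u1", "m1"), chrom = "chr1",
                     pos = c(1000, 2000), maf = c(0.3, 0.4),
                     stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = c("PA", "PB", "PC"),
                       gene = c("gA", "gB", "gC"), chrom = "chr1",
                       start1 = c(1e6, 2e6, 3e6), end1 = c(1e6, 2e6, 3e6) + 999,
                       quality = "perfect", contains_snp = FALSE,
                       stringsAsFactors = FALSE)
  scenario_config(n_samples = n, snps = snps, probes = probes,
                  additive = addv, interactions = inter, mediation = med,
                  variance_plan = vp, noise_sd = 0.3, seed = seed)
}

test_that("the generator is bit-reproducible for a fixed seed", {
  cfg <- make_toy_config(seed = 7)
  b1 <- simulate_scenario(cfg)
  b2 <- simulate_scenario(cfg)
  expect_identical(b1$genotypes$dosage, b2$genotypes$dosage)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$covariates, b2$covariates)
  b3 <- simulate_scenario(cfg, seed = 8)
  expect_false(identical(b1$genotypes$dosage, b3$genotypes$dosage))
})

test_that("independent SNPs are drawn under Hardy-Weinberg at the given MAF", {
  ok <- 0
  for (r in 1:30) {
    cfg <- scenario_config(
      n_samples = 10000,
      snps = data.frame(snp_id = "s", chrom = "chr1", pos = 1, maf = 0.3),
      probes = data.frame(probe_id = "P", gene = "g", chrom = "chr1",
                          start1 = 1, end1 = 10, quality = "perfect",
                          contains_snp = FALSE),
      seed = 100 + r)
    g <- simulate_genotypes(cfg)$dosage[, 1]
    counts <- tabulate(g + 1, 3)
    if (hwe_exact_test(counts[1], counts[2], counts[3]) > 1e-4) ok <- ok + 1
    expect_lt(abs(mean(g) / 2 - 0.3), 0.02)
  }
  expect_gte(ok, 28)
})

test_that("LD pairs reproduce the specified haplotype structure", {
  cfg <- scenario_config(
    n_samples = 10000,
    snps = data.frame(snp_id = "s", chrom = "chr1", pos = 1, maf = 0.3),
    ld_pairs = data.frame(snp1 = "a", snp2 = "b", f_AB = 0.4, f_Ab = 0.1,
                          f_aB = 0.1, f_ab = 0.4),
    probes = data.frame(probe_id = "P", gene = "g", chrom = "chr1",
                        start1 = 1, end1 = 10, quality = "perfect",
                        contains_snp = FALSE),
    seed = 50)
  G <- simulate_genotypes(cfg)
  r2 <- snp_pair_r2(G$dosage[, "a"], G$dosage[, "b"])
  expect_lt(abs(r2 - 0.36), 0.03)  # closed form for these frequencies
})

test_that("an empty effect plan gives expression independent of genotype", {
  set.seed(60)
  cfg <- make_toy_config(seed = 61, n = 300)
  ps <- numeric(60)
  for (r in 1:60) {
    b <- simulate_scenario(cfg, seed = 1000 + r)
    ps[r] <- fit_additive_model(
      b$expression[, "PA"], b$genotypes$dosage[, "u1"],
      b$covariates[, c("age", "sex")])$p
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a planted interaction effect is recovered by the fitted model", {
  cfg <- make_toy_config(
    seed = 62, n = 800,
    inter = data.frame(snp1 = "u1", snp2 = "m1", probe_id = "PA",
                       beta = 0.5, stringsAsFactors = FALSE))
  b <- simulate_scenario(cfg)
  m <- interaction_model(b$expression[, "PA"], b$genotypes$dosage[, "u1"],
                         b$genotypes$dosage[, "m1"],
                         b$covariates[, c("age", "sex")])
  expect_lt(abs(m$beta_int - 0.5), 2 * m$se_int)
})

test_that("the variance plan produces detectable Levene signal", {
  cfg <- make_toy_config(
    seed = 63, n = 900,
    vp = data.frame(snp_id = "u1", probe_id = "PA", sd0 = 1, sd1 = 1.5,
                    sd2 = 2, stringsAsFactors = FALSE))
  hits <- 0
  for (r in 1:40) {
    b <- simulate_scenario(cfg, seed = 2000 + r)
    lv <- levene_test(b$expression[, "PA"], b$genotypes$dosage[, "u1"],
                      b$covariates[, c("age", "sex")])
    if (lv$q < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 36)  # >= 90% of replicates at these magnitudes
})

test_that("mediation chains generate in order and cycles are errors", {
  cfg <- make_toy_config(
    seed = 64, n = 500,
    addv = data.frame(snp_id = "m1", probe_id = "PA", beta = 0.5),
    med = data.frame(mediator_probe = "PA", target_probe = "PB",
                     beta = 0.4, stringsAsFactors = FALSE))
  b <- simulate_scenario(cfg)
  # downstream gene associates with the SNP, and adjusting for the
  # mediator removes the association
  un <- fit_additive_model(b$expression[, "PB"], b$genotypes$dosage[, "m1"],
                           b$covariates[, c("age", "sex")])
  expect_lt(un$p, 1e-4)
  ad <- conditional_association(b$expression[, "PB"],
                                b$genotypes$dosage[, "m1"],
                                b$covariates[, c("age", "sex")],
                                adjusters = b$expression[, "PA"])
  expect_gt(ad$p, 0.001)
  cyc <- make_toy_config(
    seed = 65,
    med = data.frame(mediator_probe = c("PA", "PB"),
                     target_probe = c("PB", "PA"), beta = 0.2,
                     stringsAsFactors = FALSE))
  expect_error(simulate_scenario(cyc), "cyclic")
})

test_that("config validation rejects bad frequencies and dangling references", {
  snps <- data.frame(snp_id = "s", chrom = "chr1", pos = 1, maf = 0.3)
  probes <- data.frame(probe_id = "P", gene = "g", chrom = "chr1",
                       start1 = 1, end1 = 10, quality = "perfect",
                       contains_snp = FALSE)
  expect_error(scenario_config(100, snps, probes,
                               ld_pairs = data.frame(snp1 = "a", snp2 = "b",
                                                     f_AB = 0.9, f_Ab = 0.2,
                                                     f_aB = 0, f_ab = 0),
                               seed = 1), "frequency")
  expect_error(scenario_config(100, snps, probes,
                               additive = data.frame(snp_id = "nope",
                                                     probe_id = "P",
                                                     beta = 1),
                               seed = 1), "unknown SNP")
  expect_error(scenario_config(100, snps, probes), "seed")
})

test_that("the miniature study scenario has the planted structure", {
  sc <- make_miniature_study(n_samples = 300, seed = 5)
  expect_equal(sc$truth$n_misnp, 30)
  expect_equal(sc$truth$n_mirna_distinct, 28)
  expect_equal(sum(sc$truth$histogram$n_genes), 60)
  expect_equal(nrow(sc$annotations$probes), 195)
  expect_equal(nrow(sc$target_catalog), 6)
  # targets are genotyped in the reference panel but not in the cohort
  expect_true(all(sc$target_catalog$snp_id %in%
                    colnames(sc$reference$dosage)))
  expect_false(any(sc$target_catalog$snp_id %in%
                     colnames(sc$genotypes$dosage)))
  # the shared proxy tags two targets
  expect_equal(sum(sc$truth$proxy_map$proxy == "px5"), 2)
})
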