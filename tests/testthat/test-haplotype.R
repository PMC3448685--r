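test_that("expected haplotype dosages: unambiguous pairs and conservation", {
  h <- haplotype_freqs(0.4, 0.1, 0.1, 0.4)
  D <- expected_haplotype_dosages(c(0, 2, 0, 2, 1), c(0, 2, 2, 0, 0), h)
  expect_equal(unname(D[1, ]), c(0, 0, 0, 2))  # (0,0) -> two ab
  expect_equal(unname(D[2, ]), c(2, 0, 0, 0))  # (2,2) -> two AB
  expect_equal(unname(D[3, ]), c(0, 0, 2, 0))  # (0,2) -> two aB
  expect_equal(unname(D[4, ]), c(0, 2, 0, 0))  # (2,0) -> two Ab
  expect_equal(unname(D[5, ]), c(0, 1, 0, 1))  # (1,0) -> Ab + ab
  expect_equal(unname(rowSums(D)), rep(2, 5))
})

test_that("double heterozygotes get the posterior phase split", {
  h <- haplotype_freqs(0.4, 0.1, 0.1, 0.4)
  D <- expected_haplotype_dosages(1, 1, h)
  # P(AB/ab) = 2*0.4*0.4 / (2*0.4*0.4 + 2*0.1*0.1) = 16/17
  expect_equal(unname(D[1, "AB"]), 16 / 17, tolerance = 1e-12)
  expect_equal(unname(D[1, "ab"]), 16 / 17, tolerance = 1e-12)
  expect_equal(unname(D[1, "Ab"]), 1 / 17, tolerance = 1e-12)
  expect_equal(sum(D[1, ]), 2, tolerance = 1e-12)
  # conservation holds for every genotype combination
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  Dall <- expected_haplotype_dosages(g$g1, g$g2, h)
  expect_equal(unname(rowSums(Dall)), rep(2, 9))
})

test_that("a genotype incompatible with the frequencies is an error", {
  h <- haplotype_freqs(0.5, 0, 0, 0.5)
  expect_error(expected_haplotype_dosages(0, 2, h), "frequency 0")
  # missing genotypes propagate as NA rows
  D <- expected_haplotype_dosages(c(NA, 0), c(1, 0), h)
  expect_true(all(is.na(D[1, ])))
})

test_that("with no double heterozygotes the regression uses exact counts", {
  set.seed(40)
  n <- 300
  g1 <- sample(c(0, 2), n, replace = TRUE, prob = c(0.6, 0.4))
  g2 <- rbinom(n, 2, 0.3)
  h <- suppressWarnings(em_haplotype_frequencies(g1, g2))
  D <- expected_haplotype_dosages(g1, g2, h)
  expect_true(all(D %in% 0:2))
  y <- 7 + 0.3 * D[, "AB"] - 0.2 * D[, "aB"] + rnorm(n, 0, 0.4)
  res <- haplotype_effect_regression(y, D, NULL, h)
  # identical to OLS on the known dosage columns
  est <- setdiff(res$effects$haplotype, res$reference)
  X <- cbind(1, D[, est])
  orc <- ne_oracle(X, y)
  expect_equal(res$effects$beta[match(est, res$effects$haplotype)],
               unname(orc$beta[-1]), tolerance = 1e-8)
})

test_that("planted haplotype effects are recovered within their CIs", {
  set.seed(41)
  n <- 1500
  freqs <- c(AB = 0.399, Ab = 0.061, aB = 0.155, ab = 0.385)
  betas <- c(AB = 0, Ab = -0.231, aB = 0.018, ab = -0.258)
  hap1 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  hap2 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  g1 <- (hap1 %in% c("AB", "Ab")) + (hap2 %in% c("AB", "Ab"))
  g2 <- (hap1 %in% c("AB", "aB")) + (hap2 %in% c("AB", "aB"))
  age <- runif(n, 35, 74); sex <- rbinom(n, 1, 0.5)
  y <- 7 + betas[hap1] + betas[hap2] + 0.002 * age + 0.05 * sex +
    rnorm(n, 0, 0.3)
  h <- em_haplotype_frequencies(g1, g2)
  D <- expected_haplotype_dosages(g1, g2, h)
  res <- haplotype_effect_regression(y, D, data.frame(age = age, sex = sex), h)
  expect_equal(res$reference, "AB")
  for (hp in c("Ab", "aB", "ab")) {
    row <- res$effects[res$effects$haplotype == hp, ]
    expect_lt(abs(row$beta - betas[hp]), 4 * row$se)
  }
  expect_lt(res$global_p, 1e-10)
  expect_gt(res$global_r2, 0)
})

test_that("covariate-only expression yields null haplotype effects", {
  set.seed(42)
  n <- 600
  h <- haplotype_freqs(0.4, 0.1, 0.1, 0.4)
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  idx <- sample(nrow(g), n, replace = TRUE,
                prob = c(2, 1, 1, 1, 2, 1, 1, 1, 2))
  age <- runif(n, 35, 74)
  y <- 7 + 0.01 * age + rnorm(n, 0, 0.4)
  hh <- em_haplotype_frequencies(g$g1[idx], g$g2[idx])
  D <- expected_haplotype_dosages(g$g1[idx], g$g2[idx], hh)
  res <- haplotype_effect_regression(y, D, data.frame(age = age), hh)
  for (i in which(res$effects$haplotype != res$reference)) {
    expect_lt(abs(res$effects$beta[i]), 4 * res$effects$se[i])
  }
})

test_that("homogeneity contrast is zero for equal background effects", {
  # direct construction: equal allele-1 effect on both backgrounds
  res <- structure(list(
    effects = data.frame(haplotype = c("ab", "AB", "Ab", "aB"),
                         frequency = c(0.4, 0.3, 0.15, 0.15),
                         beta = c(0, 0.5, 0.3, 0.2),
                         se = c(NA, 0.05, 0.05, 0.05)),
    reference = "ab", hap_names = c("AB", "Ab", "aB"),
    hap_vcov = diag(0.0025, 3), df = 500), class = "haplotype_effect_result")
  # (AB - aB) - (Ab - ab) = (0.5 - 0.2) - (0.3 - 0) = 0
  ht <- homogeneity_test(res)
  expect_true(ht$usable)
  expect_equal(ht$estimate, 0, tolerance = 1e-12)
})

test_that("a background-dependent allelic effect is detected", {
  set.seed(43)
  n <- 1400
  freqs <- c(AB = 0.3, Ab = 0.25, aB = 0.25, ab = 0.2)
  # allele A adds +0.65 per copy on background B, +0.23 on background b
  hap_eff <- c(AB = 0.65, Ab = 0.23, aB = 0, ab = 0)
  hap1 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  hap2 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  g1 <- (hap1 %in% c("AB", "Ab")) + (hap2 %in% c("AB", "Ab"))
  g2 <- (hap1 %in% c("AB", "aB")) + (hap2 %in% c("AB", "aB"))
  y <- 7 + hap_eff[hap1] + hap_eff[hap2] + rnorm(n, 0, 0.4)
  h <- em_haplotype_frequencies(g1, g2)
  D <- expected_haplotype_dosages(g1, g2, h)
  res <- haplotype_effect_regression(y, D, NULL, h)
  ht <- homogeneity_test(res)
  expect_true(ht$usable)
  expect_lt(ht$p, 1e-6)
  # contrast recovers the planted difference 0.65 - 0.23
  expect_lt(abs(ht$estimate - 0.42), 4 * ht$se)
})

test_that("homogeneity p and the product-term p rank scenarios alike", {
  set.seed(44)
  n <- 500
  p_hom <- p_int <- numeric(40)
  for (r in 1:40) {
    b_int <- runif(1, 0, 0.35)
    g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
    y <- 7 + 0.2 * g1 + b_int * g1 * g2 + rnorm(n, 0, 0.4)
    m <- interaction_model(y, g1, g2)
    h <- em_haplotype_frequencies(g1, g2)
    D <- expected_haplotype_dosages(g1, g2, h)
    ht <- homogeneity_test(haplotype_effect_regression(y, D, NULL, h))
    p_int[r] <- m$p_interaction
    p_hom[r] <- ht$p
  }
  expect_gt(cor(log(p_int), log(p_hom), method = "spearman"), 0.9)
})

test_that("haplotype_analysis wires EM, dosages, regression and LD together", {
  set.seed(45)
  n <- 400
  hap_freq <- c(0.35, 0.15, 0.15, 0.35)
  h1 <- sample(1:4, n, TRUE, hap_freq); h2 <- sample(1:4, n, TRUE, hap_freq)
  dos <- cbind(s1 = (h1 %in% 1:2) + (h2 %in% 1:2),
               s2 = (h1 %in% c(1, 3)) + (h2 %in% c(1, 3)))
  G <- toy_genotypes(dos)
  E <- cbind(PX = 7 + 0.3 * dos[, "s1"] + rnorm(n, 0, 0.4))
  rownames(E) <- rownames(G$dosage)
  out <- haplotype_analysis(G, E, "s1", "s2", "PX")
  expect_s3_class(out$effects, "haplotype_effect_result")
  expect_true(out$ld$r2 > 0 && out$ld$r2 < 1)
  expect_equal(sum(out$freqs), 1, tolerance = 1e-9)
  expect_true(out$homogeneity$usable)
})
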