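test_that("interaction fit is exact when y is the product term", {
  grid <- expand.grid(gu = 0:2, gm = 0:2)
  gu <- rep(grid$gu, 4); gm <- rep(grid$gm, 4)
  y <- gu * gm
  m <- interaction_model(y, gu, gm)
  expect_false(m$skipped)
  expect_equal(m$beta_int, 1, tolerance = 1e-12)
})

test_that("interaction fit matches the normal-equations oracle", {
  set.seed(20)
  n <- 300
  gu <- rbinom(n, 2, 0.3); gm <- rbinom(n, 2, 0.45)
  age <- runif(n, 35, 74); sex <- rbinom(n, 1, 0.5)
  y <- 7 + 0.1 * gu - 0.05 * gm + 0.2 * gu * gm + 0.01 * age +
    0.1 * sex + rnorm(n, 0, 0.5)
  m <- interaction_model(y, gu, gm, data.frame(age = age, sex = sex))
  orc <- ne_oracle(cbind(1, gu, gm, gu * gm, age, sex), y)
  expect_equal(m$beta_int, unname(orc$beta[4]), tolerance = 1e-8)
  expect_equal(m$se_int, unname(orc$se[4]), tolerance = 1e-8)
  expect_equal(m$p_interaction, unname(orc$p[4]), tolerance = 1e-8)
})

test_that("degenerate interaction designs are skipped with reasons", {
  n <- 100
  y <- rnorm(n)
  gu <- rbinom(n, 2, 0.4)
  expect_equal(interaction_model(y, rep(0, n), gu)$skip_reason,
               "constant_3utrSNP")
  expect_equal(interaction_model(y, gu, rep(2, n))$skip_reason,
               "constant_miSNP")
  # perfect LD between the two SNPs: rank deficient
  m <- interaction_model(y, gu, gu)
  expect_true(m$skipped)
})

test_that("interaction test is calibrated under a homoskedastic null", {
  set.seed(21)
  n <- 300
  rej <- mean(replicate(2000, {
    gu <- rbinom(n, 2, 0.3); gm <- rbinom(n, 2, 0.4)
    y <- 7 + 0.1 * gu + rnorm(n)
    interaction_model(y, gu, gm)$p_interaction < 0.05
  }))
  ci_half <- 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rej - 0.05), ci_half)
})

test_that("Levene test reproduces the hand-computed worked example", {
  lv <- levene_test(c(1, 3, 0, 4, 2), c(0, 0, 1, 1, 1))
  expect_equal(lv$statistic, 0.15, tolerance = 1e-12)
  expect_equal(lv$df1, 1); expect_equal(lv$df2, 3)
  expect_equal(lv$q, pf(0.15, 1, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(lv$q, 2), 0.72)
  # scale invariance of the F statistic
  lv2 <- levene_test(10 * c(1, 3, 0, 4, 2), c(0, 0, 1, 1, 1))
  expect_equal(lv2$statistic, lv$statistic, tolerance = 1e-12)
  expect_equal(lv2$q, lv$q, tolerance = 1e-12)
})

test_that("Levene test agrees with car::leveneTest", {
  skip_if_not_installed("car")
  set.seed(22)
  y <- rnorm(90, 0, rep(c(1, 1.5, 2), each = 30))
  g <- rep(0:2, each = 30)
  lv <- levene_test(y, g)
  ref <- car::leveneTest(y, factor(g), center = mean)
  expect_equal(lv$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(lv$q, ref[1, "Pr(>F)"], tolerance = 1e-10)
  # Brown-Forsythe variant
  lvm <- levene_test(y, g, center = "median")
  refm <- car::leveneTest(y, factor(g), center = median)
  expect_equal(lvm$statistic, refm[1, "F value"], tolerance = 1e-10)
})

test_that("Levene test detects a genuine variance difference", {
  set.seed(23)
  hits <- mean(replicate(500, {
    y <- c(rnorm(200, 0, 1), rnorm(200, 0, 2))
    levene_test(y, rep(0:1, each = 200))$q < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("Levene with fewer than two usable groups is unusable", {
  lv <- levene_test(rnorm(10), rep(0, 10))
  expect_false(lv$usable)
  # covariate residualization leaves the test valid
  set.seed(24)
  age <- runif(120, 35, 74)
  y <- 5 + 0.1 * age + rnorm(120)
  g <- rbinom(120, 2, 0.4)
  lv <- levene_test(y, g, covariates = data.frame(age = age))
  expect_true(lv$usable)
  expect_true(lv$q > 0 && lv$q <= 1)
})

test_that("weights standardize to mean 1 and reduce to Bonferroni when flat", {
  q <- c(u1 = 0.5, u2 = 0.5, u3 = 0.5)
  tests <- rep(names(q), each = 4)
  w <- compute_weights(q, tests)
  expect_equal(w, rep(1, 12))
  # all q = 1: uniform fallback
  expect_equal(compute_weights(c(u1 = 1, u2 = 1), c("u1", "u2")), c(1, 1))
  # arbitrary q: weights sum to N
  set.seed(25)
  for (i in 1:10) {
    q <- setNames(runif(8, 1e-10, 1), paste0("u", 1:8))
    tests <- sample(names(q), 50, replace = TRUE)
    w <- compute_weights(q, tests)
    expect_equal(sum(w), length(tests), tolerance = 1e-9)
    expect_true(all(w >= 0))
  }
  expect_error(compute_weights(c(u1 = 0), "u1"), "lie in")
  expect_error(compute_weights(c(u1 = 0.5), c("u1", "u2")), "missing")
})

test_that("weighted decision divides by the weight and thresholds at alpha/N", {
  # unit weight: weighted p equals the raw p (plain Bonferroni)
  d <- weighted_decision(c(1e-6, 4e-4, 6e-4), c(1, 1, 1), 100, 0.05)
  expect_equal(d$weighted_p, c(1e-6, 4e-4, 6e-4))
  expect_equal(d$significant, c(TRUE, TRUE, FALSE))
  # upweighting rescues a borderline p; zero weight never significant
  d <- weighted_decision(c(1e-3, 1e-9), c(10, 0), 100, 0.05)
  expect_equal(d$weighted_p, c(1e-4, Inf))
  expect_equal(d$significant, c(TRUE, FALSE))
})

test_that("scan invariants: weight sum, Bonferroni equivalence, ordering", {
  set.seed(26)
  n <- 250
  n_units <- 6; n_mi <- 8
  utr_ids <- paste0("u", 1:n_units); mi_ids <- paste0("m", 1:n_mi)
  dos <- sapply(c(utr_ids, mi_ids), function(i) rbinom(n, 2, 0.35))
  G <- toy_genotypes(dos)
  E <- sapply(paste0("P", 1:n_units), function(i) rnorm(n, 7, 0.5))
  rownames(E) <- rownames(G$dosage)
  cv <- data.frame(sample_id = rownames(E), age = runif(n, 35, 74),
                   sex = rbinom(n, 1, 0.5))
  units <- data.frame(gene = paste0("g", 1:n_units), utr_proxy = utr_ids,
                      probe_id = paste0("P", 1:n_units),
                      stringsAsFactors = FALSE)
  scan <- run_interaction_scan(G, E, cv, units, mi_ids)
  expect_equal(scan$dimensions$N, n_units * n_mi)
  expect_equal(sum(scan$records$weight), scan$dimensions$N,
               tolerance = 1e-9)
  expect_equal(scan$records$weighted_p,
               scan$records$p_interaction / scan$records$weight,
               tolerance = 1e-12)
  expect_false(is.unsorted(scan$records$weighted_p))
  # with weighting off the decisions equal standard Bonferroni
  scan0 <- run_interaction_scan(G, E, cv, units, mi_ids, weighting = "none")
  expect_equal(scan0$records$weight, rep(1, scan0$dimensions$N))
  expect_equal(scan0$records$significant,
               scan0$records$p_interaction < 0.05 / scan0$dimensions$N)
  # empty selection: no tests, no decisions
  empty <- run_interaction_scan(G, E, cv, units[0, ], mi_ids)
  expect_equal(empty$dimensions$N, 0)
  expect_equal(nrow(empty$records), 0)
})

test_that("skipped tests are excluded from N and from the weights", {
  set.seed(27)
  n <- 200
  dos <- cbind(u1 = rbinom(n, 2, 0.4), u2 = rbinom(n, 2, 0.4),
               m1 = rbinom(n, 2, 0.3))
  dos <- cbind(dos, m2 = dos[, "u1"])  # perfect LD with u1: rank deficient
  G <- toy_genotypes(dos)
  E <- cbind(P1 = rnorm(n, 7), P2 = rnorm(n, 7))
  rownames(E) <- rownames(G$dosage)
  units <- data.frame(gene = c("g1", "g2"), utr_proxy = c("u1", "u2"),
                      probe_id = c("P1", "P2"), stringsAsFactors = FALSE)
  scan <- run_interaction_scan(G, E, NULL, units, c("m1", "m2"))
  expect_equal(nrow(scan$skipped), 1)
  expect_equal(scan$skipped$skip_reason, "rank_deficient")
  expect_equal(scan$dimensions$N, 3)
  expect_equal(sum(scan$records$weight), 3, tolerance = 1e-9)
  expect_equal(scan$threshold, 0.05 / 3)
})

test_that("a planted interaction is recovered as the top weighted hit", {
  set.seed(28)
  n <- 800
  n_units <- 10; n_mi <- 20
  utr_ids <- paste0("u", 1:n_units); mi_ids <- paste0("m", 1:n_mi)
  units <- data.frame(gene = paste0("g", 1:n_units), utr_proxy = utr_ids,
                      probe_id = paste0("P", 1:n_units),
                      stringsAsFactors = FALSE)
  recovered <- 0; clean <- 0
  n_reps <- 20
  for (r in 1:n_reps) {
    dos <- sapply(c(utr_ids, mi_ids), function(i) rbinom(n, 2, 0.35))
    G <- toy_genotypes(dos)
    E <- sapply(paste0("P", 1:n_units), function(i) rnorm(n, 7, 0.5))
    E[, "P3"] <- E[, "P3"] + 0.5 * dos[, "u3"] * dos[, "m7"]
    rownames(E) <- rownames(G$dosage)
    scan <- run_interaction_scan(G, E, NULL, units, mi_ids)
    top <- scan$records[1, ]
    hit <- top$utr_snp == "u3" && top$mi_snp == "m7" && top$significant
    if (hit) recovered <- recovered + 1
    # tests at the true unit with other miSNPs inherit the interaction's
    # induced variance heterogeneity (and its Levene upweighting), so the
    # clean-scan check is over the unaffected units
    others <- scan$records[scan$records$utr_snp != "u3", ]
    if (!any(others$significant)) clean <- clean + 1
  }
  expect_gte(recovered, n_reps - 1)
  expect_gte(clean, n_reps - 1)
})

test_that("weighted scan controls FWER under a homoskedastic global null", {
  fw <- fwer_null_scan(n_reps = 100, seed = 29, het_fraction = 0,
                       n_units = 8, n_misnp = 10, n_samples = 200)
  ci_upper <- 0.05 + 2.576 * sqrt(0.05 * 0.95 / 100)
  expect_lte(fw$fwer, ci_upper)
})

test_that("Levene weighting beats plain Bonferroni on a true heteroskedastic hit", {
  set.seed(30)
  n <- 400; n_units <- 10; n_mi <- 10
  utr_ids <- paste0("u", 1:n_units); mi_ids <- paste0("m", 1:n_mi)
  units <- data.frame(gene = paste0("g", 1:n_units), utr_proxy = utr_ids,
                      probe_id = paste0("P", 1:n_units),
                      stringsAsFactors = FALSE)
  wins_w <- 0; wins_b <- 0
  for (r in 1:30) {
    dos <- sapply(c(utr_ids, mi_ids), function(i) rbinom(n, 2, 0.35))
    G <- toy_genotypes(dos)
    E <- sapply(paste0("P", 1:n_units), function(i) rnorm(n, 7, 0.5))
    # borderline interaction: genuine variance signal at the true unit
    E[, "P3"] <- E[, "P3"] + 0.22 * dos[, "u3"] * dos[, "m7"]
    rownames(E) <- rownames(G$dosage)
    sw <- run_interaction_scan(G, E, NULL, units, mi_ids)
    sb <- run_interaction_scan(G, E, NULL, units, mi_ids, weighting = "none")
    true_w <- sw$records$significant[sw$records$utr_snp == "u3" &
                                       sw$records$mi_snp == "m7"]
    true_b <- sb$records$significant[sb$records$utr_snp == "u3" &
                                       sb$records$mi_snp == "m7"]
    wins_w <- wins_w + true_w
    wins_b <- wins_b + true_b
  }
  expect_gte(wins_w, wins_b)
})

test_that("replication uses Bonferroni over replicable hits with sign check", {
  # threshold arithmetic: 8 replicable hits at alpha 0.05
  set.seed(31)
  n <- 700
  make_cohort <- function(seed) {
    set.seed(seed)
    dos <- cbind(u1 = rbinom(n, 2, 0.4), m1 = rbinom(n, 2, 0.35),
                 u2 = rbinom(n, 2, 0.4), m2 = rbinom(n, 2, 0.35))
    G <- toy_genotypes(dos)
    E <- cbind(P1 = 7 + 0.4 * dos[, "u1"] * dos[, "m1"] + rnorm(n, 0, 0.5),
               P2 = rnorm(n, 7, 0.5))
    rownames(E) <- rownames(G$dosage)
    cv <- data.frame(sample_id = rownames(E), age = runif(n, 35, 74),
                     sex = rbinom(n, 1, 0.5), status = rbinom(n, 1, 0.48))
    list(G = G, E = E, cv = cv)
  }
  rep_cohort <- make_cohort(99)
  hits <- data.frame(
    probe_id = c("P1", "P2", "P1"), utr_snp = c("u1", "u2", "u_absent"),
    mi_snp = c("m1", "m2", "m1"), beta_int = c(0.4, 0.1, 0.2),
    stringsAsFactors = FALSE)
  out <- run_replication(hits, rep_cohort$G, rep_cohort$E, rep_cohort$cv)
  expect_equal(attr(out, "k"), 2)  # absent proxy excluded from k
  expect_equal(attr(out, "threshold"), 0.05 / 2)
  expect_true(out$replicated[1])   # true interaction replicates
  expect_false(out$replicated[2])  # null does not
  expect_false(out$replicable[3])
})
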