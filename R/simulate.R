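#' Deterministic substream seeds
#'
#' Every generator takes one user-facing seed and derives per-component
#' substream seeds through this fixed scheme, so a single seed
#' reproduces the whole bundle bit-for-bit while components stay
#' independent of each other's draw counts. Results stay below 2^31.
#'
#' @param seed integer master seed.
#' @param index non-negative component index.
#' @return derived integer seed.
#' @export
substream_seed <- function(seed, index) {
  ((as.numeric(seed) %% 1000003) * 1009 + index * 7919) %% 2147483647
}

#' Scenario configuration for the synthetic generator
#'
#' Describes a genotype-expression scenario with known ground truth:
#' SNPs (independent, Hardy-Weinberg at the given MAF) and LD pairs
#' (drawn as two haplotypes per sample from explicit four-haplotype
#' frequencies), probes, covariate effects, and an effect plan of
#' additive terms, interaction terms, mediator chains and a
#' genotype-dependent residual-sd (variance-heterogeneity) plan.
#'
#' @param n_samples number of individuals.
#' @param snps data frame `snp_id`, `chrom`, `pos`, `maf` for
#'   independent SNPs.
#' @param ld_pairs optional data frame `snp1`, `snp2`, `f_AB`, `f_Ab`,
#'   `f_aB`, `f_ab` for jointly drawn SNP pairs (these ids must not
#'   appear in `snps`).
#' @param probes probe annotation data frame (`probe_id`, `gene`,
#'   `chrom`, `start1`, `end1`, `quality`, `contains_snp`).
#' @param additive optional data frame `snp_id`, `probe_id`, `beta`.
#' @param interactions optional data frame `snp1`, `snp2`, `probe_id`,
#'   `beta`.
#' @param mediation optional data frame `mediator_probe`,
#'   `target_probe`, `beta` (targets receive `beta` times the mediator's
#'   simulated expression; chains must be acyclic).
#' @param variance_plan optional data frame `snp_id`, `probe_id`, `sd0`,
#'   `sd1`, `sd2`: residual sd per genotype class of `snp_id`,
#'   overriding `noise_sd` for that probe.
#' @param covariate_effects list with `age_slope`, `sex_offset`,
#'   `status_offset` applied to every probe.
#' @param noise_sd default residual sd.
#' @param with_status simulate a disease-status covariate
#'   (replication-cohort style).
#' @param seed mandatory master seed.
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(n_samples, snps, probes, ld_pairs = NULL,
                            additive = NULL, interactions = NULL,
                            mediation = NULL, variance_plan = NULL,
                            covariate_effects = list(age_slope = 0.002,
                                                     sex_offset = 0.05,
                                                     status_offset = 0),
                            noise_sd = 0.3, with_status = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  all_ids <- c(snps$snp_id, ld_pairs$snp1, ld_pairs$snp2)
  if (anyDuplicated(all_ids)) stop("duplicated SNP id across snps/ld_pairs")
  if (any(snps$maf < 0 | snps$maf > 0.5)) stop("MAF must lie in [0, 0.5]")
  if (!is.null(ld_pairs)) {
    fr <- as.matrix(ld_pairs[, c("f_AB", "f_Ab", "f_aB", "f_ab")])
    if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-9)) {
      stop("invalid haplotype frequency vector in ld_pairs")
    }
  }
  check_refs <- function(d, cols_snp, cols_probe) {
    if (is.null(d)) return(invisible())
    for (cc in cols_snp) {
      if (!all(d[[cc]] %in% all_ids)) stop("effect plan names unknown SNP")
    }
    for (cc in cols_probe) {
      if (!all(d[[cc]] %in% probes$probe_id)) stop("effect plan names unknown probe")
    }
  }
  check_refs(additive, "snp_id", "probe_id")
  check_refs(interactions, c("snp1", "snp2"), "probe_id")
  check_refs(mediation, character(0), c("mediator_probe", "target_probe"))
  check_refs(variance_plan, "snp_id", "probe_id")
  structure(list(
    n_samples = n_samples, snps = snps, ld_pairs = ld_pairs,
    probes = probes, additive = additive, interactions = interactions,
    mediation = mediation, variance_plan = variance_plan,
    covariate_effects = covariate_effects, noise_sd = noise_sd,
    with_status = with_status, seed = seed
  ), class = "scenario_config")
}

#' Simulate genotypes for a scenario
#'
#' Independent SNPs are drawn as two Bernoulli(MAF) haplotypes per
#' sample (Hardy-Weinberg); LD pairs are drawn as two four-category
#' haplotypes per sample from the specified frequencies and collapsed to
#' dosages.
#'
#' @param config a [scenario_config()].
#' @param seed overrides the config seed when given.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  set.seed(substream_seed(seed, 1))
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  cols <- list()
  meta <- list()
  for (i in seq_len(nrow(config$snps))) {
    maf <- config$snps$maf[i]
    cols[[config$snps$snp_id[i]]] <-
      stats::rbinom(n, 1, maf) + stats::rbinom(n, 1, maf)
    meta[[length(meta) + 1]] <- data.frame(
      snp_id = config$snps$snp_id[i], chrom = config$snps$chrom[i],
      pos = config$snps$pos[i], major = "A", minor = "B",
      stringsAsFactors = FALSE)
  }
  if (!is.null(config$ld_pairs)) {
    for (i in seq_len(nrow(config$ld_pairs))) {
      p <- config$ld_pairs[i, ]
      f <- c(p$f_AB, p$f_Ab, p$f_aB, p$f_ab)
      h1 <- sample.int(4, n, replace = TRUE, prob = f)
      h2 <- sample.int(4, n, replace = TRUE, prob = f)
      cols[[p$snp1]] <- (h1 %in% c(1, 2)) + (h2 %in% c(1, 2))
      cols[[p$snp2]] <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
      for (sid in c(p$snp1, p$snp2)) {
        meta[[length(meta) + 1]] <- data.frame(
          snp_id = sid, chrom = if ("chrom1" %in% names(p) && sid == p$snp1)
            p$chrom1 else if ("chrom2" %in% names(p) && sid == p$snp2)
              p$chrom2 else "chrU",
          pos = if ("pos1" %in% names(p) && sid == p$snp1) p$pos1
            else if ("pos2" %in% names(p) && sid == p$snp2) p$pos2 else i,
          major = "A", minor = "B", stringsAsFactors = FALSE)
      }
    }
  }
  dosage <- do.call(cbind, cols)
  rownames(dosage) <- sample_ids
  genotype_matrix(dosage, do.call(rbind, meta))
}

#' Simulate the covariate table
#'
#' Age uniform on 35-74 years, sex Bernoulli(0.5); when requested, a
#' disease-status indicator Bernoulli(0.48), emulating a
#' case-enriched replication cohort.
#'
#' @param config a [scenario_config()].
#' @param seed overrides the config seed when given.
#' @return covariate data frame with `sample_id`.
#' @export
simulate_covariates <- function(config, seed = config$seed) {
  set.seed(substream_seed(seed, 2))
  n <- config$n_samples
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = stats::runif(n, 35, 74),
    sex = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )
  if (isTRUE(config$with_status)) out$status <- stats::rbinom(n, 1, 0.48)
  out
}

#' Simulate expression under the effect plan
#'
#' Each probe's expression is intercept + additive dosage terms +
#' interaction product terms + mediator contributions + covariate terms
#' + Gaussian noise whose sd is either the global `noise_sd` or, for
#' probes in the variance plan, a per-sample sd indexed by the genotype
#' of the named SNP (this is what gives the Levene prioritization
#' genuine signal). Mediator chains are generated in topological order;
#' a cyclic plan is an error.
#'
#' @param G a [genotype_matrix()] from [simulate_genotypes()].
#' @param covariates covariate data frame from [simulate_covariates()].
#' @param config the [scenario_config()].
#' @param seed overrides the config seed when given.
#' @return expression matrix, samples x probes.
#' @export
simulate_expression <- function(G, covariates, config, seed = config$seed) {
  set.seed(substream_seed(seed, 3))
  n <- config$n_samples
  probes <- config$probes$probe_id
  # topological order over mediator edges
  order_probes <- probes
  if (!is.null(config$mediation)) {
    med <- config$mediation
    order_probes <- character(0)
    remaining <- probes
    repeat {
      ready <- remaining[!remaining %in%
        med$target_probe[med$mediator_probe %in% remaining]]
      if (length(ready) == 0) {
        if (length(remaining) > 0) stop("cyclic mediator chain")
        break
      }
      order_probes <- c(order_probes, ready)
      remaining <- setdiff(remaining, ready)
      if (length(remaining) == 0) break
    }
  }
  ce <- config$covariate_effects
  base <- ce$age_slope * covariates$age + ce$sex_offset * covariates$sex
  if (!is.null(covariates$status) && !is.null(ce$status_offset)) {
    base <- base + ce$status_offset * covariates$status
  }
  E <- matrix(NA_real_, n, length(probes),
              dimnames = list(rownames(G$dosage), probes))
  for (pid in order_probes) {
    mu <- rep(7, n) + base  # log-scale array intensities sit around 7
    if (!is.null(config$additive)) {
      ad <- config$additive[config$additive$probe_id == pid, , drop = FALSE]
      for (i in seq_len(nrow(ad))) {
        mu <- mu + ad$beta[i] * G$dosage[, ad$snp_id[i]]
      }
    }
    if (!is.null(config$interactions)) {
      ia <- config$interactions[config$interactions$probe_id == pid, ,
                                drop = FALSE]
      for (i in seq_len(nrow(ia))) {
        mu <- mu + ia$beta[i] * G$dosage[, ia$snp1[i]] *
          G$dosage[, ia$snp2[i]]
      }
    }
    if (!is.null(config$mediation)) {
      me <- config$mediation[config$mediation$target_probe == pid, ,
                             drop = FALSE]
      for (i in seq_len(nrow(me))) {
        mu <- mu + me$beta[i] * E[, me$mediator_probe[i]]
      }
    }
    sd_vec <- rep(config$noise_sd, n)
    if (!is.null(config$variance_plan)) {
      vp <- config$variance_plan[config$variance_plan$probe_id == pid, ,
                                 drop = FALSE]
      if (nrow(vp) > 0) {
        g <- G$dosage[, vp$snp_id[1]]
        sd_vec <- c(vp$sd0[1], vp$sd1[1], vp$sd2[1])[g + 1]
        sd_vec[is.na(sd_vec)] <- config$noise_sd
      }
    }
    E[, pid] <- mu + stats::rnorm(n, 0, sd_vec)
  }
  E
}

#' Simulate a full scenario bundle
#'
#' @param config a [scenario_config()].
#' @param seed overrides the config seed when given.
#' @return list with `genotypes`, `expression`, `covariates`,
#'   `annotations` placeholder-free probe table, and `truth` (the
#'   planted-parameter ledger).
#' @export
simulate_scenario <- function(config, seed = config$seed) {
  G <- simulate_genotypes(config, seed)
  cv <- simulate_covariates(config, seed)
  E <- simulate_expression(G, cv, config, seed)
  list(genotypes = G, expression = E, covariates = cv,
       probes = config$probes,
       truth = list(additive = config$additive,
                    interactions = config$interactions,
                    mediation = config$mediation,
                    variance_plan = config$variance_plan,
                    noise_sd = config$noise_sd,
                    covariate_effects = config$covariate_effects))
}
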