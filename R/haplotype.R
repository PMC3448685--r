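#' Expected two-locus haplotype dosages per sample
#'
#' Converts unphased dosage pairs into per-sample counts of the four
#' haplotypes AB, Ab, aB, ab (A/B = counted minor alleles). Eight of the
#' nine genotype combinations are phase-unambiguous and yield integer
#' counts; double heterozygotes are resolved to their posterior-expected
#' counts under the supplied haplotype frequencies:
#' `P(AB/ab) = f_AB f_ab / (f_AB f_ab + f_Ab f_aB)`. Dosages of each
#' sample always sum to 2.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA).
#' @param h a `haplotype_freqs` object (e.g. from
#'   [em_haplotype_frequencies()]).
#' @return numeric matrix, samples x 4 (columns AB, Ab, aB, ab); `NA`
#'   rows where either genotype is missing.
#' @export
expected_haplotype_dosages <- function(g1, g2, h) {
  stopifnot(inherits(h, "haplotype_freqs"), length(g1) == length(g2))
  n <- length(g1)
  D <- matrix(NA_real_, n, 4, dimnames = list(names(g1),
                                              c("AB", "Ab", "aB", "ab")))
  # integer haplotype counts for the 8 unambiguous genotype pairs
  fixed <- list(
    "0|0" = c(0, 0, 0, 2), "0|1" = c(0, 0, 1, 1), "0|2" = c(0, 0, 2, 0),
    "1|0" = c(0, 1, 0, 1), "1|2" = c(1, 0, 1, 0),
    "2|0" = c(0, 2, 0, 0), "2|1" = c(1, 1, 0, 0), "2|2" = c(2, 0, 0, 0)
  )
  for (key in names(fixed)) {
    gg <- as.numeric(strsplit(key, "|", fixed = TRUE)[[1]])
    idx <- which(!is.na(g1) & !is.na(g2) & g1 == gg[1] & g2 == gg[2])
    if (length(idx)) {
      need <- fixed[[key]] > 0
      if (any(need & h < 1e-12)) {
        stop("observed genotype (", key, ") requires haplotype ",
             paste(colnames(D)[need & h < 1e-12], collapse = ","),
             " which has frequency 0")
      }
      D[idx, ] <- matrix(fixed[[key]], length(idx), 4, byrow = TRUE)
    }
  }
  dh <- which(!is.na(g1) & !is.na(g2) & g1 == 1 & g2 == 1)
  if (length(dh)) {
    num <- unname(h["AB"] * h["ab"])
    den <- num + unname(h["Ab"] * h["aB"])
    if (den == 0) stop("double heterozygote incompatible with haplotype frequencies")
    post <- num / den
    D[dh, ] <- matrix(c(post, 1 - post, 1 - post, post),
                      length(dh), 4, byrow = TRUE)
  }
  D
}

#' Two-SNP haplotype-effect regression
#'
#' Regresses expression on the expected dosages of the non-reference
#' haplotypes plus covariates, assuming additive per-copy haplotype
#' effects. The reference haplotype is the most frequent one (ties
#' broken lexicographically by label), so each coefficient is the
#' per-copy effect of carrying that haplotype instead of the reference.
#' Haplotypes with (near-)zero frequency are dropped from the design
#' with a warning, and the global test is an F-test of all haplotype
#' terms against the covariate-only model.
#'
#' @param y expression vector.
#' @param dosages samples x 4 haplotype dosage matrix from
#'   [expected_haplotype_dosages()].
#' @param covariates covariate data frame / matrix, or `NULL`.
#' @param h the `haplotype_freqs` used (for frequencies and reference
#'   choice).
#' @param conf_level confidence level for per-haplotype CIs.
#' @return a `haplotype_effect_result`: data frame `effects` (haplotype,
#'   frequency, beta, ci_lo, ci_hi; reference beta fixed at 0), plus
#'   `reference`, `global_p`, `global_r2` (variance explained by the
#'   haplotype terms), `n_used`, `vcov` of the haplotype coefficients.
#' @export
haplotype_effect_regression <- function(y, dosages, covariates = NULL,
                                        h, conf_level = 0.95) {
  stopifnot(inherits(h, "haplotype_freqs"))
  ok <- complete_rows(y, dosages, covariates)
  y <- y[ok]; dos <- dosages[ok, , drop = FALSE]
  haps <- colnames(dos)
  freq <- as.numeric(h)[match(haps, names(h))]
  ref <- haps[order(-freq, haps)][1]
  present <- freq > 1e-8 | haps == ref
  dropped <- haps[!present]
  if (length(dropped)) {
    warning("haplotype(s) with zero frequency dropped from design: ",
            paste(dropped, collapse = ", "))
  }
  est_haps <- setdiff(haps[present], ref)
  cv <- covariate_design(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[ok, , drop = FALSE], length(y))
  X <- cbind(cv, dos[, est_haps, drop = FALSE])
  fit <- ols_core(X, y)
  if (fit$rank < ncol(X)) {
    # collapse to the estimable set (e.g. only two haplotypes present)
    aliased <- colnames(X)[is.na(fit$beta)]
    warning("rank-deficient haplotype design; dropping: ",
            paste(aliased, collapse = ", "))
    est_haps <- setdiff(est_haps, aliased)
    X <- cbind(cv, dos[, est_haps, drop = FALSE])
    fit <- ols_core(X, y)
  }
  hap_idx <- ncol(cv) + seq_along(est_haps)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, fit$df)
  eff <- data.frame(
    haplotype = c(ref, est_haps),
    frequency = as.numeric(h)[match(c(ref, est_haps), names(h))],
    beta = c(0, unname(fit$beta[hap_idx])),
    se = c(NA_real_, unname(fit$se[hap_idx])),
    stringsAsFactors = FALSE
  )
  eff$ci_lo <- eff$beta - tcrit * eff$se
  eff$ci_hi <- eff$beta + tcrit * eff$se
  # global F-test of all haplotype terms vs covariate-only model
  fit0 <- ols_core(cv, y)
  dfn <- length(est_haps)
  fstat <- ((fit0$rss - fit$rss) / dfn) / fit$sigma2
  global_p <- stats::pf(fstat, dfn, fit$df, lower.tail = FALSE)
  structure(list(
    effects = eff, reference = ref,
    global_p = global_p,
    global_f = fstat,
    global_r2 = fit$r_squared - fit0$r_squared,
    n_used = fit$n,
    hap_vcov = fit$vcov[hap_idx, hap_idx, drop = FALSE],
    hap_names = est_haps,
    df = fit$df
  ), class = "haplotype_effect_result")
}

#' @export
print.haplotype_effect_result <- function(x, ...) {
  cat(sprintf("haplotype effects (reference %s; n = %d)\n",
              x$reference, x$n_used))
  print(x$effects, row.names = FALSE, digits = 4)
  cat(sprintf("global: R2 = %.3f, p = %.3g\n", x$global_r2, x$global_p))
  invisible(x)
}

#' Homogeneity test of one SNP's allelic effect across backgrounds
#'
#' Wald test of whether the per-copy effect of the first SNP's minor
#' allele is the same on both backgrounds of the second SNP:
#' `H0: [beta(AB) - beta(aB)] = [beta(Ab) - beta(ab)]`, using the
#' haplotype-coefficient covariance matrix (the reference coefficient is
#' 0 with no sampling variance). This is the haplotype-scale analogue of
#' the product-term interaction test. All four haplotypes must be
#' estimable.
#'
#' @param result a `haplotype_effect_result` with all four haplotypes.
#' @return list with `estimate` (the contrast), `se`, `p` (two-sided,
#'   t-distribution on the residual df); or `usable = FALSE` when a
#'   haplotype is inestimable.
#' @export
homogeneity_test <- function(result) {
  stopifnot(inherits(result, "haplotype_effect_result"))
  all_haps <- c("AB", "Ab", "aB", "ab")
  if (!all(all_haps %in% result$effects$haplotype) ||
      length(result$hap_names) != 3) {
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                usable = FALSE))
  }
  # contrast on (AB - aB) - (Ab - ab) over the full coefficient vector
  beta_full <- stats::setNames(rep(0, 4), all_haps)
  beta_full[result$hap_names] <-
    result$effects$beta[match(result$hap_names, result$effects$haplotype)]
  cvec <- stats::setNames(c(1, -1, -1, 1), all_haps)  # AB - Ab - aB + ab
  est <- sum(cvec * beta_full)
  V <- matrix(0, 4, 4, dimnames = list(all_haps, all_haps))
  V[result$hap_names, result$hap_names] <- result$hap_vcov
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  tval <- est / se
  list(estimate = est, se = se,
       p = 2 * stats::pt(abs(tval), result$df, lower.tail = FALSE),
       usable = TRUE)
}

#' Convenience wrapper: haplotype analysis of one SNP pair
#'
#' Runs the EM, expected-dosage construction, effect regression and
#' homogeneity test for a pair of genotyped SNPs against one probe.
#'
#' @param G a [genotype_matrix()].
#' @param E expression matrix.
#' @param snp1,snp2 SNP ids (columns of `G`).
#' @param probe_id probe id (column of `E`).
#' @param covariates covariate data frame with `sample_id`, or `NULL`.
#' @return list with `freqs`, `ld`, `effects`
#'   (`haplotype_effect_result`) and `homogeneity`.
#' @export
haplotype_analysis <- function(G, E, snp1, snp2, probe_id,
                               covariates = NULL) {
  samples <- intersect(rownames(G$dosage), rownames(E))
  g1 <- G$dosage[samples, snp1]
  g2 <- G$dosage[samples, snp2]
  h <- em_haplotype_frequencies(g1, g2)
  dos <- expected_haplotype_dosages(g1, g2, h)
  cvm <- NULL
  if (!is.null(covariates)) {
    cv <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
    cvm <- cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
  }
  res <- haplotype_effect_regression(E[samples, probe_id], dos, cvm, h)
  list(freqs = h, ld = ld_from_haplotypes(h), effects = res,
       homogeneity = homogeneity_test(res))
}
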