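#' Additive SNP-expression association model
#'
#' Ordinary least squares of expression on dosage (0/1/2, treated as
#' numeric for additive allele effects) plus covariates, on complete
#' cases. The reported `r2_increment` is the variance explained by the
#' SNP term alone: R-squared of the full model minus R-squared of the
#' model without the dosage term, on the same samples.
#'
#' @param y expression vector.
#' @param g dosage vector (0/1/2/NA).
#' @param covariates data frame / matrix of per-sample covariates (e.g.
#'   age, sex), or `NULL`.
#' @param extra_covariates optional additional adjusters (vector, matrix
#'   or data frame), appended to the design; used by
#'   [conditional_association()].
#' @return an `association_result` list: `beta`, `se`, `p`,
#'   `r2_increment`, `n_used`, `df`, plus the full coefficient table.
#' @export
fit_additive_model <- function(y, g, covariates = NULL,
                               extra_covariates = NULL) {
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.matrix(as.data.frame(extra_covariates))
    storage.mode(extra_covariates) <- "double"
  }
  ok <- complete_rows(y, g, covariates, extra_covariates)
  y <- y[ok]; g <- g[ok]
  cv <- covariate_design(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[ok, , drop = FALSE], length(y))
  if (!is.null(extra_covariates)) {
    cv <- cbind(cv, extra_covariates[ok, , drop = FALSE])
  }
  if (length(unique(g)) < 2) {
    stop("degenerate predictor: dosage constant in complete cases")
  }
  X <- cbind(cv[, 1, drop = FALSE], g = g, cv[, -1, drop = FALSE])
  if (length(y) < ncol(X) + 2) stop("too few complete cases for the model")
  fit <- ols_core(X, y)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$beta)]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  tst <- ols_coef_test(fit, 2L)
  fit0 <- ols_core(X[, -2, drop = FALSE], y)
  structure(list(beta = tst$beta, se = tst$se, p = tst$p,
                 r2_increment = fit$r_squared - fit0$r_squared,
                 n_used = fit$n, df = fit$df,
                 coefficients = fit$beta, vcov = fit$vcov),
            class = "association_result")
}

#' Classify an association as cis or trans
#'
#' Cis means same chromosome and a nearest-edge distance from the SNP to
#' the probe's annotated interval of at most `window` bases (closed
#' boundary: a distance exactly equal to the window is cis). Everything
#' else, including any inter-chromosomal pair, is trans.
#'
#' @param snp_chrom,snp_pos SNP chromosome and 1-based position.
#' @param probe_interval a single-row [genomic_intervals()] for the
#'   probe.
#' @param window cis window in bp (default 1 Mb).
#' @param known_chroms optional vector of valid chromosome labels; an
#'   unknown label is an error.
#' @return list with `label` (`"cis"` or `"trans"`) and `distance` (bp;
#'   `Inf` across chromosomes).
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, probe_interval,
                               window = 1e6, known_chroms = NULL) {
  stopifnot(inherits(probe_interval, "genomic_intervals"),
            nrow(probe_interval) == 1)
  if (!is.null(known_chroms) &&
      !all(c(snp_chrom, probe_interval$chrom) %in% known_chroms)) {
    stop("unknown chromosome label")
  }
  d <- interval_distance(probe_interval, snp_chrom, snp_pos)
  list(label = if (is.finite(d) && d <= window) "cis" else "trans",
       distance = d)
}

#' Find the best cis eSNP for a probe
#'
#' Among candidate association results for one probe, returns the cis
#' SNP (within `window` of the probe) with the smallest p-value among
#' those with `p < p_max`; `NULL` if none qualifies. Ties on p are
#' broken by larger `|beta|`, then by SNP id. The tested SNP itself may
#' be returned when it is the strongest cis signal.
#'
#' @param results data frame with columns `snp_id`, `chrom`, `pos`,
#'   `beta`, `p`.
#' @param probe_interval the probe's [genomic_intervals()] row.
#' @param p_max eligibility threshold (default 5.5e-5).
#' @param window cis window in bp.
#' @return the selected `snp_id`, or `NULL`.
#' @export
find_best_cis_esnp <- function(results, probe_interval, p_max = 5.5e-5,
                               window = 1e6) {
  if (nrow(results) == 0) return(NULL)
  is_cis <- vapply(seq_len(nrow(results)), function(i) {
    classify_cis_trans(results$chrom[i], results$pos[i], probe_interval,
                       window = window)$label == "cis"
  }, logical(1))
  cand <- results[is_cis & results$p < p_max, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(cand$p, -abs(cand$beta), cand$snp_id), , drop = FALSE]
  cand$snp_id[1]
}

#' Conditional (adjusted) association model
#'
#' Refits the additive model with adjusters appended as covariates: best
#' cis eSNP dosages to test whether a signal is explained by LD with a
#' local regulatory variant, and/or mediator expression vectors to test
#' whether a trans signal acts through a cis-regulated gene. An adjuster
#' perfectly collinear with the dosage is an error.
#'
#' @inheritParams fit_additive_model
#' @param adjusters vector, matrix or data frame of adjustment variables
#'   (eSNP dosages and/or mediator expression).
#' @return an `association_result`, as [fit_additive_model()].
#' @export
conditional_association <- function(y, g, covariates = NULL, adjusters) {
  fit_additive_model(y, g, covariates, extra_covariates = adjusters)
}

#' Pairwise expression correlation matrix
#'
#' Pearson correlations between probes, computed on complete cases per
#' pair; the diagonal is 1. Zero-variance probes yield `NA` entries and
#' a warning.
#'
#' @param E expression matrix (samples x probes).
#' @param probe_ids columns to include (default all).
#' @return symmetric correlation matrix.
#' @export
correlation_matrix <- function(E, probe_ids = colnames(E)) {
  sub <- E[, probe_ids, drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 samples")
  sds <- apply(sub, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning("zero-variance probe(s): correlations undefined (NA): ",
            paste(probe_ids[sds == 0 | is.na(sds)], collapse = ", "))
  }
  suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
}

#' Bonferroni threshold for the marginal scan
#'
#' The marginal genome-wide threshold is always derived from the number
#' of executed tests: `alpha / (n_misnp * n_probes)`.
#'
#' @param n_misnp,n_probes counts of miSNPs and probes actually tested.
#' @param alpha family-wise error target.
#' @return the per-test significance threshold.
#' @export
marginal_threshold <- function(n_misnp, n_probes, alpha = 0.05) {
  stopifnot(n_misnp > 0, n_probes > 0, alpha > 0)
  alpha / (n_misnp * n_probes)
}

#' Run the marginal miSNP-expression scan
#'
#' Fits [fit_additive_model()] for every (miSNP, probe) pair, classifies
#' each association cis/trans against the probe's annotated interval,
#' and applies the Bonferroni threshold derived from the executed test
#' count.
#'
#' @param G a [genotype_matrix()] restricted to the miSNP proxies.
#' @param E expression matrix (samples x probes), sample ids matching
#'   `G`.
#' @param covariates covariate data frame aligned with samples.
#' @param probes probe annotation data frame (internal coordinates).
#' @param alpha family-wise error target.
#' @param window cis window in bp.
#' @return data frame with one row per executed test: estimates, p,
#'   `cis_trans`, `distance`, `significant`; attribute `"threshold"`.
#' @export
run_marginal_scan <- function(G, E, covariates, probes, alpha = 0.05,
                              window = 1e6) {
  samples <- intersect(rownames(G$dosage), rownames(E))
  if (length(samples) == 0) stop("no shared samples between genotypes and expression")
  cv <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  cvm <- cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
  rows <- list()
  for (pi in seq_len(nrow(probes))) {
    pid <- probes$probe_id[pi]
    if (!pid %in% colnames(E)) next
    y <- E[samples, pid]
    p_iv <- genomic_intervals(probes$chrom[pi], probes$start[pi],
                              probes$end[pi], name = pid)
    for (si in seq_len(ncol(G$dosage))) {
      g <- G$dosage[samples, si]
      res <- tryCatch(fit_additive_model(y, g, cvm), error = function(e) NULL)
      if (is.null(res)) next
      ct <- classify_cis_trans(G$snps$chrom[si], G$snps$pos[si], p_iv,
                               window = window)
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = G$snps$snp_id[si], probe_id = pid,
        gene = probes$gene[pi], beta = res$beta, se = res$se, p = res$p,
        r2_increment = res$r2_increment, n_used = res$n_used,
        cis_trans = ct$label, distance = ct$distance,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), probe_id = character(0),
               gene = character(0), beta = numeric(0), se = numeric(0),
               p = numeric(0), r2_increment = numeric(0),
               n_used = integer(0), cis_trans = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  thr <- if (nrow(out) > 0) {
    marginal_threshold(length(unique(out$snp_id)),
                       length(unique(out$probe_id)), alpha)
  } else NA_real_
  out$significant <- if (nrow(out) > 0) out$p < thr else logical(0)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}
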