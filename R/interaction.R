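#' Pairwise SNP x SNP interaction model
#'
#' Ordinary least squares of expression on both dosages (0/1/2) and
#' their product term, plus covariates, on complete cases; the reported
#' test is the two-sided t-test on the product term. Degenerate designs
#' (a constant dosage or product, or rank deficiency from e.g. perfect
#' LD between the two SNPs) are not fitted: the returned record carries
#' `skipped = TRUE` and the reason, and such tests are excluded from the
#' scan's test count `N`.
#'
#' @param y expression vector.
#' @param g_utr,g_mi dosage vectors for the 3utrSNP and the miSNP.
#' @param covariates data frame / matrix of covariates, or `NULL`.
#' @return list with `beta_int`, `se_int`, `p_interaction`, `n_used`,
#'   `skipped`, `skip_reason`.
#' @export
interaction_model <- function(y, g_utr, g_mi, covariates = NULL) {
  ok <- complete_rows(y, g_utr, g_mi, covariates)
  y <- y[ok]; g_utr <- g_utr[ok]; g_mi <- g_mi[ok]
  prod_term <- g_utr * g_mi
  skip <- function(reason) list(beta_int = NA_real_, se_int = NA_real_,
                                p_interaction = NA_real_,
                                n_used = length(y), skipped = TRUE,
                                skip_reason = reason)
  if (length(unique(g_utr)) < 2) return(skip("constant_3utrSNP"))
  if (length(unique(g_mi)) < 2) return(skip("constant_miSNP"))
  if (length(unique(prod_term)) < 2) return(skip("constant_product"))
  cv <- covariate_design(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[ok, , drop = FALSE], length(y))
  X <- cbind(cv[, 1, drop = FALSE], g_utr = g_utr, g_mi = g_mi,
             g_int = prod_term, cv[, -1, drop = FALSE])
  if (length(y) < ncol(X) + 2) return(skip("too_few_samples"))
  fit <- ols_core(X, y)
  if (fit$rank < ncol(X)) return(skip("rank_deficient"))
  tst <- ols_coef_test(fit, 4L)
  list(beta_int = tst$beta, se_int = tst$se, p_interaction = tst$p,
       n_used = fit$n, skipped = FALSE, skip_reason = NA_character_)
}

#' Levene test for expression-variance heterogeneity across genotypes
#'
#' Tests equality of expression variance across the genotype classes of
#' a SNP. Expression is first residualized on the covariates (matching
#' the covariate set of the regression models), then the classic Levene
#' statistic is computed: absolute deviations of the residuals from
#' their genotype-class center, compared by one-way ANOVA with
#' `(k - 1, n - k)` degrees of freedom. `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param y expression vector.
#' @param g genotype class labels (dosages 0/1/2).
#' @param covariates covariates to residualize on, or `NULL`.
#' @param center `"mean"` (classic Levene) or `"median"`
#'   (Brown-Forsythe).
#' @param min_group_n groups smaller than this are dropped before the
#'   test.
#' @return list with `statistic` (F), `df1`, `df2`, `q` (upper-tail
#'   p-value), `n_groups`; or all-`NA` with `usable = FALSE` when fewer
#'   than two usable groups remain.
#' @export
levene_test <- function(y, g, covariates = NULL,
                        center = c("mean", "median"), min_group_n = 2) {
  center <- match.arg(center)
  ok <- complete_rows(y, g, covariates)
  y <- y[ok]; g <- g[ok]
  if (!is.null(covariates)) {
    cv <- covariate_design(as.data.frame(covariates)[ok, , drop = FALSE],
                           length(y))
    y <- ols_core(cv, y)$residuals
  }
  grp <- factor(g)
  keep_lvl <- names(which(table(grp) >= min_group_n))
  use <- grp %in% keep_lvl
  y <- y[use]; grp <- droplevels(grp[use])
  k <- nlevels(grp)
  if (k < 2) {
    return(list(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                q = NA_real_, n_groups = k, usable = FALSE))
  }
  ctr <- if (center == "mean") {
    tapply(y, grp, mean)
  } else {
    tapply(y, grp, stats::median)
  }
  z <- abs(y - ctr[as.integer(grp)])
  n <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, grp, mean)
  ng <- tabulate(grp)
  ssb <- sum(ng * (zg - zbar)^2)
  ssw <- sum((z - zg[as.integer(grp)])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, df1 = k - 1, df2 = n - k,
       q = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       n_groups = k, usable = TRUE)
}

#' Standardized Levene weights for the weighted-Bonferroni correction
#'
#' Each test unit u (a 3utrSNP-proxy/probe pair) carries a Levene
#' p-value `q_u`; its weight is proportional to `-log(q_u)` and the
#' weights are standardized to mean 1 over the `N` executed tests:
#' `w_u = (-log q_u) * N / sum_i(-log q_u(i))`, the sum running over
#' tests (each contributing its unit's q). The log base cancels in the
#' normalization. If every q equals 1 the weights are undefined (0/0)
#' and the procedure falls back to uniform weights `w = 1`, i.e.
#' standard Bonferroni.
#'
#' @param unit_q named numeric vector: Levene q per test unit, in
#'   `(0, 1]`.
#' @param test_units character vector, one entry per executed test,
#'   naming that test's unit (names must exist in `unit_q`).
#' @return numeric vector of weights, one per executed test; mean 1.
#' @export
compute_weights <- function(unit_q, test_units) {
  if (length(test_units) == 0) return(numeric(0))
  q <- unit_q[test_units]
  if (anyNA(q)) stop("missing Levene q for unit(s): ",
                     paste(unique(test_units[is.na(q)]), collapse = ", "))
  if (any(q <= 0 | q > 1)) stop("Levene q must lie in (0, 1]")
  raw <- -log(q)
  s <- sum(raw)
  if (s == 0) return(rep(1, length(raw)))  # all q = 1: uniform fallback
  unname(raw * length(raw) / s)
}

#' Weighted-Bonferroni decision
#'
#' Divides the interaction p-value by its standardized weight and
#' declares genome-wide significance when the weighted p-value is below
#' `alpha / N`. With unit weights this is the standard Bonferroni rule.
#'
#' @param p_interaction interaction p-value(s).
#' @param w standardized weight(s) (mean 1 over tests).
#' @param n_tests total number of executed tests `N`.
#' @param alpha family-wise error target.
#' @return list with `weighted_p` and logical `significant`.
#' @export
weighted_decision <- function(p_interaction, w, n_tests, alpha = 0.05) {
  if (any(w < 0)) stop("weights must be >= 0")
  weighted_p <- ifelse(w > 0, p_interaction / w, Inf)
  list(weighted_p = weighted_p,
       significant = weighted_p < alpha / n_tests)
}

#' Run the full miSNP x 3utrSNP interaction scan
#'
#' For every interaction test unit (3utrSNP proxy, probe) from the
#' selection, computes one Levene q on the covariate-residualized probe
#' expression across the 3utrSNP genotypes, then tests that unit against
#' every miSNP with [interaction_model()]. Degenerate tests are skipped
#' with a recorded reason and excluded from the executed-test count `N`
#' and from the weight normalization. Weighted-Bonferroni decisions are
#' taken at `alpha`, and the output is deterministically ordered by
#' weighted p ascending, ties by (probe, 3utrSNP, miSNP).
#'
#' @param G a [genotype_matrix()] holding the 3utrSNP proxies and miSNP
#'   proxies.
#' @param E expression matrix (samples x probes).
#' @param covariates covariate data frame with `sample_id`.
#' @param units data frame of test units: `gene`, `utr_proxy`,
#'   `probe_id` (e.g. the `units` element of a `selection_report`).
#' @param misnp_ids character vector of miSNP (proxy) ids to test.
#' @param alpha family-wise error target.
#' @param weighting `"levene"` (default) or `"none"` (standard
#'   Bonferroni, all weights 1).
#' @param center centering for the Levene test.
#' @param min_group_n minimum genotype-class size in the Levene test.
#' @return an `interaction_scan` list: `records` (one row per executed
#'   test), `skipped` (reasons), `dimensions` (`N_utr`, `N_miSNP`, `N`),
#'   `threshold` (`alpha / N`), `alpha`.
#' @export
run_interaction_scan <- function(G, E, covariates, units, misnp_ids,
                                 alpha = 0.05,
                                 weighting = c("levene", "none"),
                                 center = c("mean", "median"),
                                 min_group_n = 2) {
  weighting <- match.arg(weighting)
  center <- match.arg(center)
  samples <- intersect(rownames(G$dosage), rownames(E))
  if (length(samples) == 0) stop("no shared samples between genotypes and expression")
  cvm <- NULL
  if (!is.null(covariates)) {
    cv <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
    cvm <- cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
  }
  dimnames_ok <- units$probe_id %in% colnames(E) &
    units$utr_proxy %in% colnames(G$dosage)
  units <- units[dimnames_ok, , drop = FALSE]
  # one Levene q per (3utrSNP proxy, probe) unit
  unit_key <- paste(units$utr_proxy, units$probe_id, sep = "|")
  unit_q <- rep(NA_real_, nrow(units))
  names(unit_q) <- unit_key
  for (ui in seq_len(nrow(units))) {
    lev <- levene_test(E[samples, units$probe_id[ui]],
                       G$dosage[samples, units$utr_proxy[ui]],
                       covariates = cvm, center = center,
                       min_group_n = min_group_n)
    unit_q[ui] <- if (isTRUE(lev$usable)) lev$q else NA_real_
  }
  unusable <- is.na(unit_q)
  if (any(unusable)) {
    warning(sum(unusable), " unit(s) dropped: Levene test undefined")
  }
  recs <- vector("list", nrow(units) * length(misnp_ids))
  ri <- 0
  for (ui in which(!unusable)) {
    y <- E[samples, units$probe_id[ui]]
    gu <- G$dosage[samples, units$utr_proxy[ui]]
    for (mid in misnp_ids) {
      m <- interaction_model(y, gu, G$dosage[samples, mid], cvm)
      ri <- ri + 1
      recs[[ri]] <- data.frame(
        gene = units$gene[ui], probe_id = units$probe_id[ui],
        utr_snp = units$utr_proxy[ui], mi_snp = mid,
        beta_int = m$beta_int, se_int = m$se_int,
        p_interaction = m$p_interaction, n_used = m$n_used,
        levene_q = unit_q[ui], skipped = m$skipped,
        skip_reason = m$skip_reason, stringsAsFactors = FALSE)
    }
  }
  all_rows <- if (ri > 0) do.call(rbind, recs[seq_len(ri)]) else
    data.frame(gene = character(0), probe_id = character(0),
               utr_snp = character(0), mi_snp = character(0),
               beta_int = numeric(0), se_int = numeric(0),
               p_interaction = numeric(0), n_used = integer(0),
               levene_q = numeric(0), skipped = logical(0),
               skip_reason = character(0), stringsAsFactors = FALSE)
  skipped <- all_rows[all_rows$skipped, , drop = FALSE]
  run <- all_rows[!all_rows$skipped, , drop = FALSE]
  N <- nrow(run)
  if (N > 0) {
    if (weighting == "levene") {
      key <- paste(run$utr_snp, run$probe_id, sep = "|")
      run$weight <- compute_weights(unit_q, key)
    } else {
      run$weight <- rep(1, N)
    }
    dec <- weighted_decision(run$p_interaction, run$weight, N, alpha)
    run$weighted_p <- dec$weighted_p
    run$significant <- dec$significant
    run <- run[order(run$weighted_p, run$probe_id, run$utr_snp,
                     run$mi_snp), , drop = FALSE]
    rownames(run) <- NULL
  } else {
    run$weight <- numeric(0)
    run$weighted_p <- numeric(0)
    run$significant <- logical(0)
  }
  structure(list(
    records = run, skipped = skipped,
    dimensions = list(N_utr = length(unique(unit_key[!unusable])),
                      N_miSNP = length(misnp_ids), N = N),
    threshold = if (N > 0) alpha / N else NA_real_,
    alpha = alpha
  ), class = "interaction_scan")
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat(sprintf(paste0(
    "interaction_scan: N = %d executed tests (%d units x %d miSNPs, ",
    "%d skipped)\n  threshold alpha/N = %.3g; %d significant\n"),
    x$dimensions$N, x$dimensions$N_utr, x$dimensions$N_miSNP,
    nrow(x$skipped), x$threshold, sum(x$records$significant)))
  invisible(x)
}

#' Test discovery hits for replication in an independent cohort
#'
#' Refits each discovery interaction in the replication data (same
#' model, with any extra replication covariates such as disease status
#' already included in `covariates`), using the standard Bonferroni
#' threshold `alpha / k` over the `k` replicable hits. Hits whose proxy
#' pair is absent from the replication panel are marked non-replicable
#' and excluded from `k`. A hit replicates when its p-value passes the
#' threshold and (by default) the interaction coefficient's sign agrees
#' with discovery.
#'
#' @param hits data frame of discovery hits with columns `probe_id`,
#'   `utr_snp`, `mi_snp`, `beta_int` (discovery estimates; SNP ids may
#'   be remapped to replication proxies beforehand).
#' @param G,E,covariates replication-cohort data, as in
#'   [run_interaction_scan()].
#' @param alpha family-wise error target.
#' @param check_sign require sign consistency with discovery (default
#'   TRUE).
#' @return data frame: per-hit replication `beta_int`, `p`,
#'   `replicable`, `replicated`; attribute `"threshold"` = `alpha / k`.
#' @export
replicate_interactions <- function(hits, G, E, covariates, alpha = 0.05,
                                   check_sign = TRUE) {
  samples <- intersect(rownames(G$dosage), rownames(E))
  cvm <- NULL
  if (!is.null(covariates)) {
    cv <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
    cvm <- cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
  }
  out <- hits
  out$replicable <- hits$utr_snp %in% colnames(G$dosage) &
    hits$mi_snp %in% colnames(G$dosage) &
    hits$probe_id %in% colnames(E)
  out$rep_beta_int <- NA_real_
  out$rep_p <- NA_real_
  for (i in which(out$replicable)) {
    m <- interaction_model(E[samples, hits$probe_id[i]],
                           G$dosage[samples, hits$utr_snp[i]],
                           G$dosage[samples, hits$mi_snp[i]], cvm)
    if (m$skipped) {
      out$replicable[i] <- FALSE
    } else {
      out$rep_beta_int[i] <- m$beta_int
      out$rep_p[i] <- m$p_interaction
    }
  }
  k <- sum(out$replicable)
  thr <- if (k > 0) alpha / k else NA_real_
  sign_ok <- if (check_sign) {
    sign(out$rep_beta_int) == sign(out$beta_int)
  } else TRUE
  out$replicated <- out$replicable & !is.na(out$rep_p) &
    out$rep_p < thr & sign_ok
  attr(out, "threshold") <- thr
  attr(out, "k") <- k
  out
}
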