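#' Genotype QC thresholds
#'
#' Defaults follow common discovery-cohort practice for array genotypes:
#' MAF > 0.01, call rate > 0.98, exact Hardy-Weinberg p > 1e-4. A
#' replication-style set (call rate > 0.95, HWE p > 1e-5) can be obtained
#' by overriding the fields.
#'
#' @param maf_min,call_rate_min,hwe_p_min thresholds in `[0, 1]`; a SNP
#'   is kept only if its statistic is strictly above each.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.98,
                          hwe_p_min = 1e-4) {
  vals <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(vals < 0 | vals > 1)) stop("QC thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: all
#' heterozygote counts compatible with the minor-allele total are
#' enumerated, and the p-value is the summed probability of outcomes no
#' more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return the exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no called genotypes")
  n_minor <- 2 * n_bb + n_ab
  if (n_minor > n) { # ensure "minor" really is the rarer allele
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    n_minor <- 2 * n_bb + n_ab
  }
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # P(n_ab = h | allele counts) via log factorials
  lf <- lgamma(seq_len(2 * n + 1))  # lf[k+1] = log(k!)
  lfac <- function(k) lf[k + 1]
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) + lfac(n) - lfac(hom_maj) - lfac(h) - lfac(hom_min) -
      (lfac(2 * n) - lfac(n_minor) - lfac(2 * n - n_minor))
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  if (length(obs) == 0) stop("heterozygote count incompatible with allele total")
  sum(pr[pr <= pr[obs] * (1 + 1e-12)])
}

#' Filter SNPs on MAF, call rate and Hardy-Weinberg equilibrium
#'
#' Filters are applied in the order MAF, call rate, HWE, and a per-filter
#' removal report is attached. A SNP with zero called genotypes is
#' removed at the call-rate step.
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `genotype_matrix`, with attribute `"qc_report"`
#'   (data frame of per-SNP statistics and the filter, if any, that
#'   removed it).
#' @export
qc_filter_snps <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  dos <- G$dosage
  n_called <- colSums(!is.na(dos))
  call_rate <- n_called / nrow(dos)
  maf <- ifelse(n_called > 0, colMeans(dos, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(maf, 1 - maf)  # orientation-free frequency of the rarer allele
  hwe_p <- rep(NA_real_, ncol(dos))
  removed_by <- rep(NA_character_, ncol(dos))
  removed_by[is.na(maf) | !(maf > thresholds$maf_min)] <- "maf"
  keep <- is.na(removed_by)
  removed_by[keep & !(call_rate > thresholds$call_rate_min)] <- "call_rate"
  keep <- is.na(removed_by)
  for (j in which(keep)) {
    g <- dos[, j]
    hwe_p[j] <- hwe_exact_test(sum(g == 0, na.rm = TRUE),
                               sum(g == 1, na.rm = TRUE),
                               sum(g == 2, na.rm = TRUE))
    if (!(hwe_p[j] > thresholds$hwe_p_min)) removed_by[j] <- "hwe"
  }
  keep <- is.na(removed_by)
  report <- data.frame(snp_id = G$snps$snp_id, maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p,
                       removed_by = removed_by, stringsAsFactors = FALSE)
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         G$snps[keep, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic SNPs
#' from unphased dosages. Only double heterozygotes are phase-ambiguous;
#' the EM starts at linkage equilibrium and iterates the expected phase
#' split of double heterozygotes until the largest frequency change is
#' below `tol`. Allele "A"/"B" denote the counted (minor) alleles of the
#' two SNPs, so `f_AB` is the frequency of the haplotype carrying both
#' minor alleles.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) for the two SNPs; pairwise
#'   complete cases are used.
#' @param tol convergence tolerance on frequencies.
#' @param max_iter iteration cap.
#' @return a `haplotype_freqs` object: numeric `c(f_AB, f_Ab, f_aB,
#'   f_ab)` with attributes `n` (pairs used), `loglik` (final
#'   log-likelihood), `iterations`, and `degenerate` (TRUE when a locus
#'   is monomorphic in the pair-complete subset).
#' @export
em_haplotype_frequencies <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2) stop("need at least 2 pairwise-complete genotype pairs")
  counts <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  p_A <- mean(g1) / 2
  p_B <- mean(g2) / 2
  degenerate <- p_A %in% c(0, 1) || p_B %in% c(0, 1)
  if (degenerate) {
    warning("monomorphic SNP in pair-complete subset; degenerate haplotype frequencies")
  }
  # known haplotype counts from the 8 unambiguous genotype classes
  # (hap order: AB, Ab, aB, ab)
  known <- c(
    AB = 2 * counts["2", "2"] + counts["2", "1"] + counts["1", "2"],
    Ab = 2 * counts["2", "0"] + counts["2", "1"] + counts["1", "0"],
    aB = 2 * counts["0", "2"] + counts["0", "1"] + counts["1", "2"],
    ab = 2 * counts["0", "0"] + counts["0", "1"] + counts["1", "0"]
  )
  ndh <- counts["1", "1"]  # double heterozygotes: AB/ab or Ab/aB
  f <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  names(f) <- c("AB", "Ab", "aB", "ab")
  loglik <- function(f) {
    ll <- sum(known * log(pmax(f, 1e-300)))
    if (ndh > 0) ll <- ll + ndh * log(pmax(2 * f["AB"] * f["ab"] +
                                           2 * f["Ab"] * f["aB"], 1e-300))
    unname(ll)
  }
  it <- 0
  ll_trace <- loglik(f)
  repeat {
    it <- it + 1
    if (ndh > 0) {
      num <- f["AB"] * f["ab"]
      den <- num + f["Ab"] * f["aB"]
      phase <- if (den > 0) unname(num / den) else 0.5
    } else {
      phase <- 0
    }
    newf <- known + ndh * c(phase, 1 - phase, 1 - phase, phase)
    newf <- newf / (2 * n)
    delta <- max(abs(newf - f))
    f <- newf
    ll_trace <- c(ll_trace, loglik(f))
    if (delta < tol || it >= max_iter) break
  }
  structure(f, class = "haplotype_freqs", n = n, loglik = loglik(f),
            loglik_trace = ll_trace, iterations = it,
            degenerate = degenerate)
}

#' @param f_AB,f_Ab,f_aB,f_ab frequencies of the four ordered haplotypes.
#' @rdname em_haplotype_frequencies
#' @export
haplotype_freqs <- function(f_AB, f_Ab, f_aB, f_ab) {
  f <- c(AB = f_AB, Ab = f_Ab, aB = f_aB, ab = f_ab)
  if (any(f < 0)) stop("haplotype frequencies must be >= 0")
  if (abs(sum(f) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  structure(f, class = "haplotype_freqs",
            degenerate = (f["AB"] + f["Ab"]) %in% c(0, 1) ||
                         (f["AB"] + f["aB"]) %in% c(0, 1))
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Computes the allele-covariance `D = f_AB - p_A p_B`, the normalized
#' `D' = |D| / D_max` and the squared correlation
#' `r2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param h a `haplotype_freqs` object.
#' @return list with `D`, `D_prime`, `r2`, and the two counted-allele
#'   frequencies `p_A`, `p_B`.
#' @export
ld_from_haplotypes <- function(h) {
  stopifnot(inherits(h, "haplotype_freqs"))
  p_A <- unname(h["AB"] + h["Ab"])
  p_B <- unname(h["AB"] + h["aB"])
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1)) {
    stop("LD undefined: a locus is monomorphic")
  }
  D <- unname(h["AB"]) - p_A * p_B
  D_max <- if (D > 0) {
    min(p_A * (1 - p_B), (1 - p_A) * p_B)
  } else {
    min(p_A * p_B, (1 - p_A) * (1 - p_B))
  }
  D_prime <- if (D == 0) 0 else abs(D) / D_max
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  list(D = D, D_prime = D_prime, r2 = r2, p_A = p_A, p_B = p_B)
}

#' Pairwise r2 between two dosage vectors via EM haplotype frequencies
#'
#' @inheritParams em_haplotype_frequencies
#' @return squared haplotype correlation, or `NA` if undefined.
#' @export
snp_pair_r2 <- function(g1, g2) {
  h <- suppressWarnings(em_haplotype_frequencies(g1, g2))
  if (attr(h, "degenerate")) return(NA_real_)
  ld_from_haplotypes(h)$r2
}

#' Select an LD proxy for a target SNP
#'
#' Among candidate genotyped SNPs, returns the one with maximal pairwise
#' r2 to the target (r2 from EM haplotype frequencies), provided it
#' reaches `r2_min`. A target that is itself among the candidates is its
#' own proxy with r2 = 1. Ties are broken by smaller genomic distance to
#' the target, then lexicographic SNP id.
#'
#' @param target_id target SNP id (must be a column of `G_target`).
#' @param candidate_ids character vector of candidate SNP ids in `G`.
#' @param G a [genotype_matrix()] holding the candidates (and the target,
#'   if genotyped).
#' @param r2_min minimum acceptable r2 (default 0.90).
#' @param G_target optional genotype matrix holding the target genotypes
#'   if different from `G`; samples are matched by id.
#' @return data frame row `target`, `proxy`, `r2`, or `NULL` if no
#'   candidate reaches `r2_min`.
#' @export
select_proxy <- function(target_id, candidate_ids, G, r2_min = 0.90,
                         G_target = G) {
  if (length(candidate_ids) == 0) return(NULL)
  if (target_id %in% candidate_ids) {
    return(data.frame(target = target_id, proxy = target_id, r2 = 1,
                      stringsAsFactors = FALSE))
  }
  if (!target_id %in% colnames(G_target$dosage)) {
    stop("target genotypes unavailable: ", target_id)
  }
  common <- intersect(rownames(G_target$dosage), rownames(G$dosage))
  gt <- G_target$dosage[common, target_id]
  tpos <- G_target$snps$pos[match(target_id, G_target$snps$snp_id)]
  r2 <- vapply(candidate_ids, function(id)
    snp_pair_r2(gt, G$dosage[common, id]), numeric(1))
  dist <- abs(G$snps$pos[match(candidate_ids, G$snps$snp_id)] - tpos)
  ok <- !is.na(r2) & r2 >= r2_min
  if (!any(ok)) return(NULL)
  ord <- order(-r2, dist, candidate_ids)
  best <- ord[ok[ord]][1]
  data.frame(target = target_id, proxy = candidate_ids[best],
             r2 = unname(r2[best]), stringsAsFactors = FALSE)
}
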