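# Independent oracles and in-code fixtures shared across the suite.
# These deliberately avoid the package's own code paths.

# OLS by explicit normal equations: beta = (X'X)^-1 X'y
ne_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- drop(solve(XtX, crossprod(X, y)))
  resid <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = beta, se = se, df = df,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

# Two-locus haplotype MLE by 1-D grid over the double-het phase split.
# Haplotype counting is re-derived here independently of the package.
grid_em_oracle <- function(g1, g2, grid_n = 20001) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  known <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  ndh <- 0
  for (i in seq_len(n)) {
    a <- g1[i]; b <- g2[i]
    if (a == 1 && b == 1) { ndh <- ndh + 1; next }
    # split each genotype into two haplotype alleles (phase known here)
    a_alleles <- c(rep(1, a), rep(0, 2 - a))
    b_alleles <- c(rep(1, b), rep(0, 2 - b))
    # when only one locus is het the pairing is irrelevant for counts
    for (k in 1:2) {
      hap <- paste0(ifelse(a_alleles[k] == 1, "A", "a"),
                    ifelse(b_alleles[k] == 1, "B", "b"))
      key <- c(AB = "AB", Ab = "Ab", aB = "aB", ab = "ab")[hap]
      known[key] <- known[key] + 1
    }
  }
  # a double het contributes one AB + one ab with fraction t, else Ab + aB
  ll_of <- function(ts) {
    fAB <- (known["AB"] + ndh * ts) / (2 * n)
    fAb <- (known["Ab"] + ndh * (1 - ts)) / (2 * n)
    faB <- (known["aB"] + ndh * (1 - ts)) / (2 * n)
    fab <- (known["ab"] + ndh * ts) / (2 * n)
    known["AB"] * log(pmax(fAB, 1e-300)) +
      known["Ab"] * log(pmax(fAb, 1e-300)) +
      known["aB"] * log(pmax(faB, 1e-300)) +
      known["ab"] * log(pmax(fab, 1e-300)) +
      ndh * log(pmax(2 * fAB * fab + 2 * fAb * faB, 1e-300))
  }
  ts <- seq(0, 1, length.out = grid_n)
  ll <- ll_of(ts)
  t0 <- ts[which.max(ll)]
  # local refinement around the coarse argmax
  step <- 1 / (grid_n - 1)
  tf <- seq(max(0, t0 - 2 * step), min(1, t0 + 2 * step),
            length.out = 40001)
  llf <- ll_of(tf)
  tbest <- tf[which.max(llf)]
  best <- (known + ndh * c(tbest, 1 - tbest, 1 - tbest, tbest)) / (2 * n)
  list(freqs = best, loglik = max(llf))
}

# Exact HWE p-value by direct enumeration with ordinary factorials
# (independent of the package's log-gamma implementation).
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_minor <- 2 * n_bb + n_ab
  if (n_minor > n) {
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    n_minor <- 2 * n_bb + n_ab
  }
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  pr <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    exp(h * log(2) + lfactorial(n) - lfactorial(hom_maj) - lfactorial(h) -
          lfactorial(hom_min) - lfactorial(2 * n) + lfactorial(n_minor) +
          lfactorial(2 * n - n_minor))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# write a tiny VCF to a temp file and return the path
write_test_vcf <- function(body_lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    body_lines), path)
  path
}

# small genotype matrix from a dosage matrix with default metadata
toy_genotypes <- function(dosage, chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 1000
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("snp%02d", seq_len(ncol(dosage)))
  }
  genotype_matrix(dosage, data.frame(
    snp_id = colnames(dosage), chrom = chrom, pos = pos,
    major = "A", minor = "B", stringsAsFactors = FALSE))
}
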