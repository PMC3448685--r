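# Shared least-squares core.
#
# Every regression in the package (marginal, conditional, interaction,
# haplotype-effect) goes through ols_core(): a QR fit via stats::lm.fit
# plus the usual normal-theory summaries. Keeping one code path makes the
# oracle tests (stats::lm and an explicit normal-equations solve) cover
# all of them, and keeps the per-test cost low enough for the simulation
# scans, which run hundreds of thousands of fits.

ols_core <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  p <- ncol(X)
  n <- length(y)
  df <- n - r
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv_r <- chol2inv(R)
  # map back to original column order (pivoting), NA for aliased columns
  se <- rep(NA_real_, p)
  se[fit$qr$pivot[seq_len(r)]] <- sqrt(diag(XtXinv_r) * sigma2)
  vcov <- matrix(NA_real_, p, p)
  vcov[fit$qr$pivot[seq_len(r)], fit$qr$pivot[seq_len(r)]] <- XtXinv_r * sigma2
  beta <- fit$coefficients  # NA for aliased columns
  tss <- sum((y - mean(y))^2)
  list(beta = beta, se = se, vcov = vcov, df = df, rss = rss,
       sigma2 = sigma2, rank = r, n = n,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       residuals = fit$residuals, fitted = y - fit$residuals)
}

# t-test summaries for one coefficient of an ols_core fit
ols_coef_test <- function(fit, idx) {
  b <- fit$beta[idx]
  s <- fit$se[idx]
  tval <- b / s
  p <- 2 * stats::pt(abs(tval), fit$df, lower.tail = FALSE)
  list(beta = unname(b), se = unname(s), t = unname(tval), p = unname(p))
}

# design matrix [1, covariates] from a covariate data frame (possibly NULL)
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    cbind("(Intercept)" = 1, cv)
  }
}

# rows with no missing values across a list of vectors/matrices
complete_rows <- function(...) {
  parts <- list(...)
  ok <- rep(TRUE, NROW(parts[[1]]))
  for (p in parts) {
    if (is.null(p)) next
    if (is.matrix(p) || is.data.frame(p)) {
      ok <- ok & stats::complete.cases(p)
    } else {
      ok <- ok & !is.na(p)
    }
  }
  ok
}
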