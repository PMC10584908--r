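# Polygenic-score evaluation: scoring from weights, incremental R-squared
# (or pseudo-R-squared) over a covariate-only baseline with percentile
# bootstrap confidence intervals, and standardized-difference comparison of
# two scores.

#' Construct a PGS evaluation cohort
#'
#' @param dosages individuals x SNPs allele-dosage matrix (values in [0, 2]).
#' @param weights per-SNP PGS weights aligned to the dosage columns.
#' @param phenotypes data.frame of outcome columns (continuous, or binary
#'   coded 0/1), one row per individual.
#' @param covariates data.frame of covariates (e.g. age, sex, and ten
#'   genetic principal components), one row per individual.
#' @export
pgs_cohort <- function(dosages, weights, phenotypes, covariates) {
  dosages <- as.matrix(dosages)
  if (length(weights) != ncol(dosages)) {
    stop("weights not aligned to dosage columns: ", length(weights),
         " vs ", ncol(dosages))
  }
  if (nrow(phenotypes) != nrow(dosages) || nrow(covariates) != nrow(dosages)) {
    stop("phenotype/covariate rows not aligned to dosage rows")
  }
  for (nm in names(phenotypes)) {
    v <- phenotypes[[nm]]
    u <- unique(v[!is.na(v)])
    if (all(u %in% c(0, 1)) && length(u) <= 2) phenotypes[[nm]] <- as.numeric(v)
  }
  structure(list(dosages = dosages, weights = as.numeric(weights),
                 phenotypes = as.data.frame(phenotypes),
                 covariates = as.data.frame(covariates)),
            class = "pgs_cohort")
}

#' Compute per-individual polygenic scores
#'
#' `score_i = sum_j dosage_ij * weight_j`, standardized to mean 0, SD 1 for
#' regression (the raw sums are kept as an attribute).
#'
#' @param cohort `pgs_cohort`.
#' @param weights optional alternative weight vector (e.g. a second score).
#' @return Standardized numeric score vector with attribute `raw`.
#' @export
score_pgs <- function(cohort, weights = NULL) {
  w <- if (is.null(weights)) cohort$weights else as.numeric(weights)
  if (length(w) != ncol(cohort$dosages)) {
    stop("weights not aligned to dosage columns")
  }
  raw <- drop(cohort$dosages %*% w)
  s <- if (sd(raw) > 0) (raw - mean(raw)) / sd(raw) else raw
  attr(s, "raw") <- raw
  s
}

.is_binary <- function(y) all(stats::na.omit(unique(y)) %in% c(0, 1))

.pseudo_r2 <- function(dev, dev_null, n, type) {
  cs <- 1 - exp((dev - dev_null) / n)
  if (type == "nagelkerke") cs / (1 - exp(-dev_null / n)) else 1 - dev / dev_null
}

#' Incremental R-squared of a polygenic score over a covariate baseline
#'
#' Fits a baseline model with the covariates only and a full model with
#' covariates plus the standardized score, and reports the difference in
#' variance explained: ordinary R-squared for continuous outcomes (linear
#' regression), pseudo-R-squared for binary outcomes (logistic regression;
#' Nagelkerke by default, McFadden by flag). The confidence interval is a
#' percentile bootstrap over individuals with a fixed seed. Rows with
#' missing values are removed listwise (count reported).
#'
#' @param cohort `pgs_cohort`.
#' @param outcome name of the phenotype column.
#' @param score per-individual score from [score_pgs()]; computed from the
#'   cohort's own weights when omitted.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @param pseudo pseudo-R-squared flavour for binary outcomes.
#' @param adjusted use adjusted R-squared (continuous outcomes only).
#'   Plain incremental R-squared is non-negative by construction, so its
#'   percentile bootstrap interval can never reach 0; the adjusted variant
#'   is approximately centred under a null score and is the right choice
#'   for null-calibration checks.
#' @return list of class `pgs_result`: `outcome`, `family`, `incr_r2`,
#'   `ci_lo`, `ci_hi`, `coef` (PGS coefficient), `se`, `n`, `n_dropped`.
#' @export
incremental_r2 <- function(cohort, outcome, score = NULL, n_boot = 1000,
                           seed, pseudo = c("nagelkerke", "mcfadden"),
                           adjusted = FALSE) {
  pseudo <- match.arg(pseudo)
  if (!(outcome %in% names(cohort$phenotypes))) {
    stop("outcome not found: ", outcome)
  }
  if (is.null(score)) score <- score_pgs(cohort)
  y <- cohort$phenotypes[[outcome]]
  C <- as.matrix(cohort$covariates)
  ok <- complete.cases(y, C, score)
  n_dropped <- sum(!ok)
  y <- y[ok]; C <- C[ok, , drop = FALSE]; s <- score[ok]
  n <- length(y)
  family <- if (.is_binary(y)) "logistic" else "linear"

  X0 <- cbind(1, C)
  X1 <- cbind(X0, PGS = s)
  delta <- function(idx) {
    yi <- y[idx]
    X0i <- X0[idx, , drop = FALSE]; X1i <- X1[idx, , drop = FALSE]
    if (family == "linear") {
      tss <- sum((yi - mean(yi))^2)
      r0 <- 1 - sum(stats::lm.fit(X0i, yi)$residuals^2) / tss
      r1 <- 1 - sum(stats::lm.fit(X1i, yi)$residuals^2) / tss
      if (adjusted) {
        ni <- length(yi)
        r0 <- 1 - (1 - r0) * (ni - 1) / (ni - ncol(X0i))
        r1 <- 1 - (1 - r1) * (ni - 1) / (ni - ncol(X1i))
      }
    } else {
      if (length(unique(yi)) < 2) return(NA_real_)
      d_null <- -2 * sum(ifelse(yi == 1, log(mean(yi)), log(1 - mean(yi))))
      f0 <- stats::glm.fit(X0i, yi, family = binomial())
      f1 <- stats::glm.fit(X1i, yi, family = binomial())
      r0 <- .pseudo_r2(f0$deviance, d_null, length(yi), pseudo)
      r1 <- .pseudo_r2(f1$deviance, d_null, length(yi), pseudo)
    }
    r1 - r0
  }
  est <- delta(seq_len(n))

  # PGS coefficient and SE from the full-model design-matrix fit
  p <- ncol(X1)
  if (family == "linear") {
    fit <- stats::lm.fit(X1, y)
    sigma2 <- sum(fit$residuals^2) / (n - p)
    xtx_inv <- chol2inv(chol(crossprod(X1)))
    coef_pgs <- fit$coefficients[p]
    se_pgs <- sqrt(sigma2 * xtx_inv[p, p])
  } else {
    fit <- suppressWarnings(stats::glm.fit(X1, y, family = binomial()))
    if (!fit$converged || any(fit$fitted.values < 1e-10) ||
        any(fit$fitted.values > 1 - 1e-10)) {
      return(structure(list(outcome = outcome, family = family,
                            incr_r2 = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, coef = NA_real_, se = NA_real_,
                            n = n, n_dropped = n_dropped,
                            note = "logistic fit did not converge (separation?)"),
                       class = "pgs_result"))
    }
    info_inv <- chol2inv(chol(crossprod(X1 * sqrt(fit$weights))))
    coef_pgs <- fit$coefficients[p]
    se_pgs <- sqrt(info_inv[p, p])
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (missing(seed)) stop("a bootstrap seed is required")
    set.seed(seed)
    reps <- vapply(seq_len(n_boot),
                   function(b) delta(sample.int(n, n, replace = TRUE)),
                   numeric(1))
    ci <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE, type = 6))
  }
  structure(list(outcome = outcome, family = family, incr_r2 = est,
                 ci_lo = ci[1], ci_hi = ci[2],
                 coef = unname(coef_pgs), se = unname(se_pgs),
                 n = n, n_dropped = n_dropped),
            class = "pgs_result")
}

#' Compare two sets of polygenic-score results
#'
#' Per outcome, the standardized difference of the absolute PGS
#' coefficients, `z = (|coef_A| - |coef_B|)/sqrt(se_A^2 + se_B^2)` (a
#' negative z means the A score is attenuated relative to B), with a
#' two-sided p-value; plus the incremental-R-squared difference in
#' percentage points and the rank correlation of the coefficient vectors.
#'
#' @param resA,resB lists of `pgs_result` over matched outcomes.
#' @return list: per-outcome data.frame `table`, `rank_correlation`.
#' @export
compare_pgs <- function(resA, resB) {
  oa <- vapply(resA, `[[`, "", "outcome")
  ob <- vapply(resB, `[[`, "", "outcome")
  if (!setequal(oa, ob) || length(oa) != length(ob)) {
    stop("outcome mismatch between result sets")
  }
  resB <- resB[match(oa, ob)]
  g <- function(res, f) vapply(res, `[[`, numeric(1), f)
  ca <- g(resA, "coef"); cb <- g(resB, "coef")
  sa <- g(resA, "se"); sb <- g(resB, "se")
  z <- (abs(ca) - abs(cb)) / sqrt(sa^2 + sb^2)
  tab <- data.frame(outcome = oa, coef_a = ca, coef_b = cb,
                    z = z, p = 2 * pnorm(-abs(z)),
                    d_incr_r2_pp = (g(resA, "incr_r2") - g(resB, "incr_r2")) * 100)
  rc <- if (length(ca) >= 3) cor(ca, cb, method = "spearman") else NA_real_
  list(table = tab, rank_correlation = rc)
}
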