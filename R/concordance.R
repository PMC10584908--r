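# Coefficient-concordance checks between full-data and down-sampled GWAS:
# greedy LD clumping to define lead SNPs, exact binomial sign-concordance
# testing, outlier flagging against full-data confidence intervals, and the
# regression of down-sampled on full-data coefficients.

#' Greedy LD clumping to define lead SNPs
#'
#' Among SNPs below the significance threshold, repeatedly selects the
#' remaining SNP with the smallest p-value and removes all SNPs in LD
#' (`r2 >= r2_thresh`) with it. Equal p-values are broken by lexicographic
#' SNP id for determinism. The retained set has pairwise LD r2 below the
#' threshold.
#'
#' @param ss validated `sumstats` table.
#' @param ld symmetric LD r-squared matrix with unit diagonal, dimnames
#'   covering the significant SNPs.
#' @param p_thresh significance threshold (default genome-wide 5e-8).
#' @param r2_thresh LD pruning threshold (default 0.1).
#' @return list of class `lead_snps`: `snp_ids` in selection order,
#'   `p_thresh`, `r2_thresh`.
#' @export
ld_clump <- function(ss, ld, p_thresh = 5e-8, r2_thresh = 0.1) {
  dt <- data.table::as.data.table(ss)
  sig <- dt[!is.na(P) & P < p_thresh]
  out <- character(0)
  if (nrow(sig)) {
    if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
      stop("ld must be a square matrix")
    }
    if (max(abs(ld - t(ld))) > 1e-8) stop("ld matrix is not symmetric")
    if (!all(sig$SNP %in% rownames(ld))) {
      stop("ld matrix missing significant SNPs: ",
           paste(head(setdiff(sig$SNP, rownames(ld)), 5), collapse = ", "))
    }
    data.table::setorder(sig, P, SNP)  # ties broken by snp id
    remaining <- sig$SNP
    while (length(remaining)) {
      lead <- remaining[1]
      out <- c(out, lead)
      r2 <- ld[lead, remaining]
      remaining <- remaining[r2 < r2_thresh]
    }
  }
  structure(list(snp_ids = out, p_thresh = p_thresh, r2_thresh = r2_thresh),
            class = "lead_snps")
}

#' Sign concordance with an exact binomial test
#'
#' A SNP counts as concordant when its full-data and down-sampled
#' coefficients (BETA where present, otherwise Z) share the same sign;
#' exact zeros count as discordant. The one-sided exact binomial test asks
#' whether true concordance is below the near-perfect null `p0` (default
#' 0.99): `p = P(Bin(n, p0) <= k)` for `k` observed successes.
#'
#' @param full,down row-aligned `sumstats` tables (see [harmonize_pair()]).
#' @param subset SNP ids to test (e.g. lead SNPs); default all shared rows.
#' @param p0 null concordance probability.
#' @return list: `n_snps`, `n_concordant`, `prop_concordant`, `binom_p`.
#' @export
sign_concordance <- function(full, down, subset = NULL, p0 = 0.99) {
  al <- .align_subset(full, down, subset)
  ef <- .effect_col(al$full); ed <- .effect_col(al$down)
  conc <- sign(ef) == sign(ed) & sign(ef) != 0
  k <- sum(conc); n <- length(conc)
  list(n_snps = n, n_concordant = k,
       prop_concordant = k / n,
       binom_p = pbinom(k, n, p0))
}

.effect_col <- function(dt) {
  if ("BETA" %in% names(dt) && !anyNA(dt$BETA)) dt$BETA else dt$Z
}

.align_subset <- function(full, down, subset) {
  f <- data.table::as.data.table(full)
  d <- data.table::as.data.table(down)
  if (is.null(subset)) subset <- intersect(f$SNP, d$SNP)
  if (inherits(subset, "lead_snps")) subset <- subset$snp_ids
  if (!length(subset)) stop("empty SNP subset")
  fi <- match(subset, f$SNP); di <- match(subset, d$SNP)
  if (anyNA(fi) || anyNA(di)) stop("subset SNPs missing from the tables")
  list(full = f[fi], down = d[di])
}

#' Power of the sign-concordance design
#'
#' Exact power of the one-sided binomial test of `H0: concordance = p0`
#' against a true concordance `p_true < p0`: the rejection region is the
#' largest `k` with `P(Bin(n, p0) <= k) <= alpha`, and power is
#' `P(Bin(n, p_true) <= k)`. With no rejection region (n too small) power
#' is 0, with a warning.
#'
#' @param n number of independent SNPs tested.
#' @param p0 null concordance.
#' @param p_true assumed true concordance, `0 < p_true < p0`.
#' @param alpha test level.
#' @export
design_power <- function(n, p0 = 0.99, p_true, alpha = 0.05) {
  stopifnot(n >= 1, p_true > 0, p_true < p0, p0 < 1)
  k <- qbinom(alpha, n, p0)                    # smallest k with P(<=k) >= alpha
  while (k >= 0 && pbinom(k, n, p0) > alpha) k <- k - 1
  if (k < 0) {
    warning("no rejection region exists at this n and level")
    return(0)
  }
  pbinom(k, n, p_true)
}

#' Flag down-sampled coefficients outside full-data confidence intervals
#'
#' Flags SNP j when the down-sampled coefficient falls outside
#' `full_beta_j +/- q * full_se_j`, with `q` the normal quantile at
#' `(1 + level)/2` (1.96 at the default 95% level). The returned flags can
#' be attached to the table as its `OUTLIER` column for [write_sumstats()].
#'
#' @param full,down row-aligned `sumstats` tables; `full` must carry BETA
#'   and SE, `down` must carry BETA.
#' @param level confidence level of the full-data interval.
#' @return list: integer `flags` (named by SNP), `n_outliers`, `n_snps`.
#' @export
outlier_flags <- function(full, down, level = 0.95) {
  al <- .align_subset(full, down, NULL)
  f <- al$full; d <- al$down
  if (!all(c("BETA", "SE") %in% names(f)) || anyNA(f$SE)) {
    stop("full table must carry BETA and SE to form confidence intervals")
  }
  if (!("BETA" %in% names(d))) stop("down table must carry BETA")
  q <- qnorm((1 + level) / 2)
  flags <- as.integer(d$BETA < f$BETA - q * f$SE | d$BETA > f$BETA + q * f$SE)
  names(flags) <- f$SNP
  list(flags = flags, n_outliers = sum(flags), n_snps = length(flags))
}

#' Regression of down-sampled on full-data coefficients
#'
#' Ordinary least squares of the down-sampled coefficients on their
#' full-data counterparts (absolute values by default), reporting the
#' intercept, slope, adjusted R-squared, and Wald p-values for the
#' hypotheses intercept = 0 and slope = 1. A slope near unity with a near
#' zero intercept and high adjusted R-squared indicates the down-sampling
#' induced little coefficient attenuation.
#'
#' @param full,down row-aligned `sumstats` tables.
#' @param subset SNP ids (or a `lead_snps` object); at least 3.
#' @param absolute regress absolute coefficients (default) or signed.
#' @return list: `intercept`, `slope`, `adj_r2`, `p_intercept_zero`,
#'   `p_slope_one`, `intercept_se`, `slope_se`, `n`.
#' @export
coefficient_regression <- function(full, down, subset = NULL, absolute = TRUE) {
  al <- .align_subset(full, down, subset)
  x <- .effect_col(al$full); y <- .effect_col(al$down)
  if (length(x) < 3) stop("need at least 3 SNPs for the regression")
  if (absolute) { x <- abs(x); y <- abs(y) }
  if (var(x) == 0) stop("degenerate design: zero variance in full-data coefficients")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  est <- coef(sm)
  t_slope1 <- (est["x", "Estimate"] - 1) / est["x", "Std. Error"]
  list(intercept = unname(est["(Intercept)", "Estimate"]),
       slope = unname(est["x", "Estimate"]),
       intercept_se = unname(est["(Intercept)", "Std. Error"]),
       slope_se = unname(est["x", "Std. Error"]),
       adj_r2 = sm$adj.r.squared,
       p_intercept_zero = unname(est["(Intercept)", "Pr(>|t|)"]),
       p_slope_one = unname(2 * pt(abs(t_slope1), df = fit$df.residual,
                                   lower.tail = FALSE)),
       n = length(x))
}

#' Full concordance report for an aligned pair
#'
#' Runs the three coefficient-concordance checks (sign concordance, outlier
#' flags, coefficient regression) on a SNP subset, typically lead SNPs.
#'
#' @inheritParams coefficient_regression
#' @param p0 null concordance for the binomial test.
#' @param level confidence level for outlier flagging.
#' @return list of class `concordance_report`.
#' @export
concordance_report <- function(full, down, subset = NULL, p0 = 0.99,
                               level = 0.95, absolute = TRUE) {
  al <- .align_subset(full, down, subset)
  sc <- sign_concordance(al$full, al$down, p0 = p0)
  of <- tryCatch(outlier_flags(al$full, al$down, level = level),
                 error = function(e) NULL)
  cr <- coefficient_regression(al$full, al$down, absolute = absolute)
  structure(list(n_snps = sc$n_snps,
                 prop_concordant = sc$prop_concordant,
                 binom_p = sc$binom_p,
                 n_outliers = if (is.null(of)) NA_integer_ else of$n_outliers,
                 outlier_flags = if (is.null(of)) NULL else of$flags,
                 reg_intercept = cr$intercept, reg_slope = cr$slope,
                 reg_adj_r2 = cr$adj_r2,
                 p_intercept_zero = cr$p_intercept_zero,
                 p_slope_one = cr$p_slope_one),
            class = "concordance_report")
}
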