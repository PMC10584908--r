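# LD Score regression: univariate (heritability + intercept), bivariate
# (genetic covariance / correlation), and the Step-1 key signal indicators.
# All standard errors are delete-one-block jackknives over contiguous SNP
# blocks; regressions are computed from per-block sufficient statistics so
# jackknifing costs O(m + n_blocks), not O(m * n_blocks).

.CHI2_MEDIAN_1DF <- 0.4549364  # median of the central chi-square, 1 df

#' Construct an LD-score panel
#'
#' @param snp character vector of marker names.
#' @param l2 non-negative LD scores (sum of squared correlations with
#'   neighbouring SNPs, unitless).
#' @param m_total number of SNPs M used as the heritability denominator;
#'   defaults to the panel length, must be at least the number of rows.
#' @return data.table of class `ld_panel` with columns SNP, L2 and an
#'   `m_total` attribute.
#' @export
ld_panel <- function(snp, l2, m_total = length(snp)) {
  stopifnot(length(snp) == length(l2))
  if (any(l2 < 0, na.rm = TRUE)) stop("LD scores must be non-negative")
  if (m_total < length(snp)) stop("m_total smaller than number of panel SNPs")
  dt <- data.table::data.table(SNP = as.character(snp), L2 = as.numeric(l2))
  data.table::setattr(dt, "m_total", as.numeric(m_total))
  data.table::setattr(dt, "class", c("ld_panel", class(dt)))
  dt[]
}

#' Read an LD-score panel file
#'
#' Tab-delimited file with SNP and L2 columns (gzip-transparent). The SNP
#' count M is read from a sidecar file (a single integer) when given,
#' otherwise set to the number of rows.
#'
#' @param path panel file path.
#' @param m_path optional sidecar file holding M.
#' @export
read_ld_panel <- function(path, m_path = NULL) {
  dt <- .fread_auto(path, header = TRUE)
  names(dt) <- toupper(names(dt))
  if (!all(c("SNP", "L2") %in% names(dt))) {
    stop("LD panel needs SNP and L2 columns")
  }
  m <- if (!is.null(m_path)) scan(m_path, what = numeric(), quiet = TRUE)[1] else nrow(dt)
  ld_panel(dt$SNP, dt$L2, m_total = max(m, nrow(dt)))
}

# contiguous block labels in file order (positions not required)
.block_labels <- function(m, n_blocks) {
  n_blocks <- max(2L, min(as.integer(n_blocks), m))
  as.integer(cut(seq_len(m), n_blocks, labels = FALSE))
}

# Weighted least squares of y on [1, x] via per-block sufficient statistics.
# Returns the full-sample fit and the n_blocks delete-one-block fits.
.wls_jack <- function(x, y, w, blocks) {
  s <- rowsum(cbind(w, w * x, w * x^2, w * y, w * x * y), blocks)
  tot <- colSums(s)
  fit1 <- function(v) {
    v <- as.numeric(v)
    det <- v[1] * v[3] - v[2]^2
    if (abs(det) < .Machine$double.eps * v[1]^2) {
      stop("degenerate design: zero variance in regressor")
    }
    slope <- (v[1] * v[5] - v[2] * v[4]) / det
    c(intercept = (v[4] - slope * v[2]) / v[1], slope = slope)
  }
  est <- fit1(tot)
  reps <- t(vapply(seq_len(nrow(s)),
                   function(i) fit1(tot - s[i, ]), numeric(2)))
  colnames(reps) <- c("intercept", "slope")
  list(est = est, reps = reps)
}

# delete-one-block jackknife SE; reps is n_blocks x p
.jack_se <- function(reps) {
  g <- nrow(reps)
  dev <- sweep(reps, 2, colMeans(reps))
  sqrt((g - 1) / g * colSums(dev^2))
}

#' Mean chi-square and genomic inflation factor
#'
#' The genomic inflation factor lambda_GC is the median chi-square divided
#' by the median of the central 1-df chi-square distribution (0.4549364).
#'
#' @param ss validated `sumstats` table with finite Z for at least one SNP.
#' @return list with `mean_chi2` and `lambda_gc`.
#' @export
chi2_stats <- function(ss) {
  z <- ss$Z[is.finite(ss$Z)]
  if (!length(z)) stop("no finite Z statistics")
  chi2 <- z^2
  list(mean_chi2 = mean(chi2),
       lambda_gc = median(chi2) / .CHI2_MEDIAN_1DF)
}

#' Attenuation / stratification bias ratio
#'
#' Defined as (intercept - 1) / (mean chi-square - 1): the share of test
#' statistic inflation not attributable to polygenic signal. Undefined
#' (returned as NA with a warning) when the mean chi-square is at or below 1.
#'
#' @param intercept LD Score regression intercept.
#' @param mean_chi2 mean chi-square of the summary statistics.
#' @export
attenuation_ratio <- function(intercept, mean_chi2) {
  out <- (intercept - 1) / (mean_chi2 - 1)
  bad <- !is.na(mean_chi2) & mean_chi2 <= 1
  if (any(bad)) {
    warning("attenuation ratio undefined for mean chi-square <= 1")
    out[bad] <- NA_real_
  }
  out
}

# Merge sumstats with panel; returns data.table with Z, L2, NEFF columns.
# Per-SNP effective N is used when present, otherwise N.
.match_panel <- function(ss, panel, min_snps = 200L) {
  dt <- data.table::as.data.table(ss)
  dt <- dt[!is.na(Z)]
  idx <- match(dt$SNP, panel$SNP)
  keep <- !is.na(idx)
  dt <- dt[keep]
  dt[, L2 := panel$L2[idx[keep]]]
  dt[, NEFF := if ("EFF_N" %in% names(dt) && !anyNA(EFF_N)) EFF_N else N]
  if (nrow(dt) < min_snps) {
    stop("insufficient data: only ", nrow(dt), " SNPs matched to the LD panel")
  }
  dt
}

# Two-step LDSC fit: an unweighted pass seeds the variance model, the
# weighted pass gives the estimate. Returns the weighted fit plus the
# seeded expectations ex (used as marginal variance terms by the bivariate
# weights, so that identical inputs get mathematically identical weights).
.ldsc_uni_fit <- function(z, neff, l2, m, blocks) {
  x <- neff * l2 / m
  p1 <- .wls_jack(x, z^2, rep(1, length(z)), blocks)
  ex <- p1$est[1] + p1$est[2] * x
  fit <- .wls_jack(x, z^2, .ldsc_weights(l2, ex), blocks)
  fit$ex <- ex
  fit
}

# LDSC heteroskedasticity weights, seeded by a first-pass fit.
# E_j = intercept + N_j * slope * l_j / M is the modelled E[chi2_j].
.ldsc_weights <- function(l2, ex1, ex2 = ex1, cross = NULL) {
  base <- 1 / pmax(l2, 1)
  if (is.null(cross)) {
    base / (2 * pmax(ex1, 0.1)^2)
  } else {
    base / (pmax(ex1, 0.1) * pmax(ex2, 0.1) + cross^2)
  }
}

#' Univariate LD Score regression
#'
#' Regresses per-SNP chi-square statistics on `N * l_j / M` with a free
#' intercept, per the expectation `E[chi2_j] = intercept + N h2 l_j / M`.
#' Two-step heteroskedasticity weights (an unweighted pass seeds the
#' variance model `1/max(l,1) * 1/(2 E[chi2]^2)`); standard errors by
#' delete-one-block jackknife over contiguous SNP blocks. SNPs with
#' chi-square above `chi2_max` (default `max(80, 0.001 N)`) are dropped
#' before the regression, mirroring standard LDSC outlier handling.
#'
#' @param ss validated `sumstats` table.
#' @param panel `ld_panel`.
#' @param n_blocks number of jackknife blocks (default 200).
#' @param chi2_max chi-square truncation threshold, or NULL for the default.
#' @return list of class `ldsc_h2`: h2, h2_se, intercept, intercept_se,
#'   mean_chi2, lambda_gc, n_snps, m, and the jackknife replicates.
#' @export
univariate_ldsc <- function(ss, panel, n_blocks = 200, chi2_max = NULL) {
  dt <- .match_panel(ss, panel)
  m <- attr(panel, "m_total")
  chi2 <- dt$Z^2
  nbar <- mean(dt$NEFF)
  if (is.null(chi2_max)) chi2_max <- max(80, 0.001 * nbar)
  keep <- chi2 <= chi2_max
  dt <- dt[keep]; chi2 <- chi2[keep]
  stats <- chi2_stats(dt)

  blocks <- .block_labels(nrow(dt), n_blocks)
  fit <- .ldsc_uni_fit(dt$Z, dt$NEFF, dt$L2, m, blocks)
  se <- .jack_se(fit$reps)

  structure(list(h2 = unname(fit$est["slope"]),
                 h2_se = unname(se[2]),
                 intercept = unname(fit$est["intercept"]),
                 intercept_se = unname(se[1]),
                 mean_chi2 = stats$mean_chi2,
                 lambda_gc = stats$lambda_gc,
                 n_snps = nrow(dt), m = m, n_blocks = nrow(fit$reps),
                 reps = fit$reps, blocks = blocks, snp = dt$SNP),
            class = "ldsc_h2")
}

#' Bivariate LD Score regression (genetic correlation)
#'
#' Regresses the product `z1_j z2_j` on `sqrt(N1 N2) l_j / M` with a free
#' intercept; the slope is the genetic covariance and the intercept absorbs
#' sample overlap. The genetic correlation is
#' `rg = gcov / sqrt(h2_1 h2_2)` with both heritabilities estimated on the
#' same harmonized SNP set and jackknife blocks, and its standard error is
#' a joint delete-one-block jackknife over all three regressions. rg is not
#' clipped to [-1, 1]; out-of-range values are flagged (`rg_out_of_range`).
#'
#' @param ss1,ss2 validated `sumstats` tables.
#' @param panel `ld_panel`.
#' @param n_blocks number of jackknife blocks.
#' @return list of class `ldsc_rg`: rg, se, gcov, gcov_int, per-trait h2,
#'   and diagnostics.
#' @export
bivariate_ldsc <- function(ss1, ss2, panel, n_blocks = 200) {
  hp <- harmonize_pair(ss1, ss2)
  d1 <- .match_panel(hp$full, panel)
  d2 <- data.table::as.data.table(hp$down)[SNP %in% d1$SNP]
  d2[, NEFF := if ("EFF_N" %in% names(d2) && !anyNA(EFF_N)) EFF_N else N]
  m <- attr(panel, "m_total")

  # joint chi-square truncation so both traits see the same SNPs
  keep <- d1$Z^2 <= max(80, 0.001 * mean(d1$NEFF)) &
          d2$Z^2 <= max(80, 0.001 * mean(d2$NEFF))
  d1 <- d1[keep]; d2 <- d2[keep]
  if (nrow(d1) < 200) stop("insufficient data after harmonization")
  l2 <- d1$L2
  blocks <- .block_labels(nrow(d1), n_blocks)

  f1 <- .ldsc_uni_fit(d1$Z, d1$NEFF, l2, m, blocks)
  f2 <- .ldsc_uni_fit(d2$Z, d2$NEFF, l2, m, blocks)

  xg <- sqrt(d1$NEFF * d2$NEFF) * l2 / m
  y <- d1$Z * d2$Z
  p1 <- .wls_jack(xg, y, rep(1, length(y)), blocks)
  excr <- p1$est[1] + p1$est[2] * xg
  fg <- .wls_jack(xg, y,
                  .ldsc_weights(l2, f1$ex, f2$ex, cross = excr), blocks)

  h2_1 <- unname(f1$est["slope"]); h2_2 <- unname(f2$est["slope"])
  gcov <- unname(fg$est["slope"])
  if (h2_1 <= 0 || h2_2 <= 0) {
    return(structure(list(rg = NA_real_, se = NA_real_, gcov = gcov,
                          gcov_int = unname(fg$est["intercept"]),
                          h2_1 = h2_1, h2_2 = h2_2,
                          rg_out_of_range = NA,
                          note = "non-positive heritability; rg undefined"),
                     class = "ldsc_rg"))
  }
  rg <- gcov / sqrt(h2_1 * h2_2)
  rg_reps <- fg$reps[, "slope"] /
    sqrt(pmax(f1$reps[, "slope"], 1e-12) * pmax(f2$reps[, "slope"], 1e-12))
  rg_se <- .jack_se(cbind(rg_reps))[1]
  if (abs(rg) > 1) warning("estimated |rg| exceeds 1 (reported unclipped)")
  structure(list(rg = rg, se = rg_se, gcov = gcov,
                 gcov_int = unname(fg$est["intercept"]),
                 gcov_se = .jack_se(fg$reps)[2],
                 h2_1 = h2_1, h2_2 = h2_2,
                 rg_out_of_range = abs(rg) > 1,
                 n_snps = nrow(d1), n_blocks = nrow(fg$reps)),
            class = "ldsc_rg")
}

#' Key signal indicators for one summary-statistics file
#'
#' The five Step-1 indicators: effective sample size, SNP heritability
#' (observed scale) with jackknife SE, mean chi-square, genomic inflation
#' factor, and the attenuation/stratification bias ratio.
#'
#' @param ss validated `sumstats` table.
#' @param panel `ld_panel`.
#' @param cohorts optional cohort table for [effective_sample_size()];
#'   when absent, per-SNP `EFF_N` (or `N`) maxima are used.
#' @param n_blocks jackknife blocks.
#' @return list of class `key_indicators`.
#' @export
key_indicators <- function(ss, panel, cohorts = NULL, n_blocks = 200) {
  fit <- univariate_ldsc(ss, panel, n_blocks = n_blocks)
  eff_n <- if (!is.null(cohorts)) {
    effective_sample_size(cohorts)
  } else if ("EFF_N" %in% names(ss) && !anyNA(ss$EFF_N)) {
    max(ss$EFF_N)
  } else {
    max(ss$N)
  }
  ratio <- if (fit$mean_chi2 > 1) {
    attenuation_ratio(fit$intercept, fit$mean_chi2)
  } else NA_real_
  structure(list(eff_n = eff_n,
                 h2 = fit$h2, h2_se = fit$h2_se,
                 mean_chi2 = fit$mean_chi2,
                 lambda_gc = fit$lambda_gc,
                 intercept = fit$intercept, intercept_se = fit$intercept_se,
                 ratio = ratio),
            class = "key_indicators")
}

#' Key indicators for a full / down-sampled pair, with deltas
#'
#' Computes [key_indicators()] for both files plus the percentage changes
#' `(down - full)/full * 100` for effective sample size, mean chi-square and
#' genomic inflation factor, and absolute differences for heritability and
#' the attenuation ratio.
#'
#' @param full,down validated `sumstats` tables.
#' @param cohorts_full,cohorts_down optional cohort tables.
#' @param panel `ld_panel`.
#' @param n_blocks jackknife blocks.
#' @export
key_indicators_pair <- function(full, down, panel,
                                cohorts_full = NULL, cohorts_down = NULL,
                                n_blocks = 200) {
  kf <- key_indicators(full, panel, cohorts_full, n_blocks)
  kd <- key_indicators(down, panel, cohorts_down, n_blocks)
  pct <- function(a, b) (b - a) / a * 100
  list(full = kf, down = kd,
       delta = list(eff_n_pct = pct(kf$eff_n, kd$eff_n),
                    mean_chi2_pct = pct(kf$mean_chi2, kd$mean_chi2),
                    lambda_gc_pct = pct(kf$lambda_gc, kd$lambda_gc),
                    h2_abs = kd$h2 - kf$h2,
                    ratio_abs = kd$ratio - kf$ratio))
}
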