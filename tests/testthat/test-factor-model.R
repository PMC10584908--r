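# genetic covariance estimation and the single-factor genomic SEM fit

test_that("exact rank-one-plus-diagonal input is reproduced perfectly", {
  lam <- c(0.77, 0.69, 0.66, 0.58, 0.54, 0.51, 0.49)
  S <- outer(lam, lam); diag(S) <- 1
  gc <- as_genetic_covariance(S)
  fit <- fit_single_factor(gc)
  expect_equal(unname(fit$loadings), lam, tolerance = 1e-6)
  expect_equal(unname(fit$residuals), 1 - lam^2, tolerance = 1e-6)
  expect_lt(fit$srmr, 1e-8)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$df, 7 * 8 / 2 - 14)
  # invariant to a global sign flip of the loadings (canonical orientation)
  fit2 <- fit_single_factor(as_genetic_covariance(outer(-lam, -lam) + diag(1 - lam^2)))
  expect_equal(fit2$loadings, fit$loadings, tolerance = 1e-6)
})

test_that("duplicated traits give equal diagonal and off-diagonal covariance", {
  sim <- simulate_sumstats_pair(test_panel, h2 = 0.3, seed = 6)
  gc <- genetic_covariance(list(a = sim$full, b = sim$full), test_panel)
  expect_equal(gc$S[1, 1], gc$S[2, 2], tolerance = 1e-6)
  expect_equal(gc$S[1, 2], gc$S[1, 1], tolerance = 1e-6)
})

test_that("genetic covariance recovers the generator truth and permutes consistently", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  sim <- simulate_factor_traits(test_panel, loadings = lam, seed = 5)
  gc <- genetic_covariance(sim$traits, test_panel)
  # S_tu = sqrt(h2_t h2_u) * rg_tu with h2 = lam^2 and rg = lam_t lam_u
  S_true <- outer(lam, lam)^2
  diag(S_true) <- lam^2
  se <- matrix(0, 4, 4)
  se[lower.tri(se, diag = TRUE)] <- sqrt(diag(gc$V))
  se[upper.tri(se)] <- t(se)[upper.tri(se)]
  expect_true(all(abs(gc$S - S_true) < 2.5 * se))

  # permuting trait order permutes S and the stored matrices consistently
  perm <- c(3, 1, 4, 2)
  gc2 <- genetic_covariance(sim$traits[perm], test_panel)
  expect_equal(unname(gc2$S), unname(gc$S[perm, perm]), tolerance = 1e-10)
})

test_that("the factor fit recovers simulated loadings and classifies fit quality", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.5, 0.4, 0.4)
  sim <- simulate_factor_traits(test_panel, loadings = lam, seed = 6)
  gc <- genetic_covariance(sim$traits, test_panel)
  fit <- fit_single_factor(gc)
  # recovery within 3 SE per loading (joint check across 7 parameters)
  expect_true(all(abs(fit$loadings - lam) < 3 * fit$loading_se))
  # the generator satisfies the model, so fit indices classify "good fit"
  expect_gt(fit$cfi, 0.9)
  expect_lt(fit$srmr, 0.08)
  expect_true(all(fit$residuals >= 0))
})

test_that("Heywood cases are bounded at zero and flagged, not fatal", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.95
  R[1, 3] <- R[3, 1] <- 0.95
  R[2, 3] <- R[3, 2] <- 0.80   # implies loading_1 > 1
  expect_warning(fit <- fit_single_factor(as_genetic_covariance(R)),
                 "Heywood")
  expect_true(any(fit$heywood))
  expect_true(all(fit$residuals >= 0))
})

test_that("factor-fit comparisons standardize differences correctly", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  S <- outer(lam, lam); diag(S) <- 1
  gc <- as_genetic_covariance(S)
  fit <- fit_single_factor(gc)
  cmp <- compare_factor_fits(fit, fit)
  expect_true(all(cmp$z == 0))
  expect_false(any(cmp$significant))

  # hand-built fits: published RISK loading change 0.54 (0.03) -> 0.56 (0.03)
  mkfit <- function(l, se) {
    structure(list(traits = "t1", loadings = c(t1 = l),
                   loading_se = c(t1 = se), residuals = c(t1 = 1 - l^2),
                   residual_se = c(t1 = se)), class = "factor_fit")
  }
  cmp <- compare_factor_fits(mkfit(0.54, 0.03), mkfit(0.56, 0.03))
  expect_equal(cmp$z[1], -0.4714, tolerance = 1e-3)
  expect_false(cmp$significant[1])
  cmp <- compare_factor_fits(mkfit(0.5, 0.01), mkfit(0.6, 0.01))
  expect_equal(cmp$z[1], -7.071, tolerance = 1e-3)
  expect_true(cmp$significant[1])
  expect_error(compare_factor_fits(mkfit(0.5, 0.01), fit), "structure")
})

test_that("the factor GWAS is exact on consistent signal and calibrated on noise", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  fit <- fit_single_factor(as_genetic_covariance(outer(lam, lam) + diag(1 - lam^2)))
  # consistent signal: snp_cov = b * loadings recovers b exactly
  b <- 0.02
  sc <- list(est = matrix(b * lam, 1), se = matrix(0.01, 1, 4), snp = "rs1")
  out <- factor_gwas(gc = list(S = diag(lam^2)), fit = fit, snp_cov = sc)
  expect_equal(out$BETA, b, tolerance = 1e-8)

  # isotropic sampling structure reduces GLS to OLS
  y <- c(0.01, 0.02, -0.01, 0.005)
  sc <- list(est = matrix(y, 1), se = matrix(0.03, 1, 4), snp = "rs1")
  out <- factor_gwas(gc = NULL, fit = fit, snp_cov = sc)
  expect_equal(out$BETA, sum(lam * y) / sum(lam^2), tolerance = 1e-8)

  # null SNPs: z is standard normal, so |z| < 2 for ~95% of SNPs
  set.seed(7)
  m <- 1000
  se <- matrix(runif(m * 4, 0.01, 0.05), m)
  est <- matrix(rnorm(m * 4, 0, as.vector(se)), m)
  out <- factor_gwas(gc = NULL, fit = fit,
                     snp_cov = list(est = est, se = se,
                                    snp = paste0("rs", 1:m)))
  expect_gte(mean(abs(out$Z) < 2), 0.93)

  # causal SNPs: mean recovered effect matches the truth
  set.seed(8)
  bt <- 0.015
  est <- matrix(rep(bt * lam, each = m), m) + matrix(rnorm(m * 4, 0, as.vector(se)), m)
  out <- factor_gwas(gc = NULL, fit = fit,
                     snp_cov = list(est = est, se = se,
                                    snp = paste0("rs", 1:m)))
  expect_lt(abs(mean(out$BETA) - bt), 2 * sd(out$BETA) / sqrt(m))
})

test_that("the factor pipeline runs end to end on per-SNP covariances", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  sim <- simulate_factor_traits(test_panel, loadings = lam, seed = 9)
  gc <- genetic_covariance(sim$traits, test_panel)
  fit <- fit_single_factor(gc)
  fg <- factor_gwas(gc, fit)
  expect_equal(nrow(fg), length(gc$snp))
  expect_true(all(is.finite(fg$Z)))
  # factor-level signal exceeds the null baseline
  expect_gt(mean(fg$Z^2), 1)
})
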