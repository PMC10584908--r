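# LD Score regression core: chi-square summaries, attenuation ratio,
# univariate and bivariate regressions with jackknife standard errors

test_that("chi-square summaries match their definitions", {
  mk <- function(z) as_sumstats(data.frame(
    SNP = paste0("rs", seq_along(z)), A1 = "A", A2 = "G", Z = z,
    P = pmax(2 * pnorm(-abs(z)), 1e-300), N = 1000))
  # degenerate all-zero case: P = 1 everywhere, chi2 = 0
  cs <- chi2_stats(mk(rep(0, 10)))
  expect_equal(cs$mean_chi2, 0)
  expect_equal(cs$lambda_gc, 0)
  # constant unit chi-square: lambda is 1/median(chi2_1)
  cs <- chi2_stats(mk(rep(1, 10)))
  expect_equal(cs$mean_chi2, 1)
  expect_equal(cs$lambda_gc, 1 / 0.4549364, tolerance = 1e-7)
  # null simulation: mean chi2 concentrates at 1 (CLT band)
  set.seed(42)
  m <- 50000
  cs <- chi2_stats(mk(rnorm(m)))
  expect_lt(abs(cs$mean_chi2 - 1), 3 * sqrt(2 / m))
})

test_that("attenuation ratio reproduces published cells and edge cases", {
  expect_equal(round(attenuation_ratio(1.036, 1.869), 3), 0.041)
  expect_equal(round(attenuation_ratio(1.037, 2.062), 3), 0.035)
  expect_equal(attenuation_ratio(1.0, 2.5), 0)
  expect_warning(out <- attenuation_ratio(1.02, 0.99), "undefined")
  expect_true(is.na(out))
  # strictly increasing in the intercept at fixed mean chi-square
  ratios <- attenuation_ratio(seq(1.0, 1.2, by = 0.02), 1.9)
  expect_true(all(diff(ratios) > 0))
})

test_that("univariate LDSC recovers heritability and intercept from its own model", {
  sim <- simulate_sumstats_pair(test_panel, h2 = 0.30, intercept = 1.00,
                                seed = 1)
  fit <- univariate_ldsc(sim$full, test_panel)
  expect_lt(abs(fit$h2 - 0.30), 2 * fit$h2_se)
  expect_lt(abs(fit$intercept - 1.00), 2 * fit$intercept_se)

  # confounding shifts the intercept, not the slope
  simc <- simulate_sumstats_pair(test_panel, h2 = 0.30, intercept = 1.05,
                                 seed = 2)
  fitc <- univariate_ldsc(simc$full, test_panel)
  expect_lt(abs(fitc$intercept - 1.05), 2 * fitc$intercept_se)
  expect_lt(abs(fitc$h2 - 0.30), 2 * fitc$h2_se)

  # flat response: all chi-square exactly 1
  flat <- as_sumstats(data.frame(
    SNP = test_panel$SNP, A1 = "A", A2 = "G",
    Z = rep(c(1, -1), length.out = nrow(test_panel)),
    P = 0.3173105, N = 50000))
  fitf <- univariate_ldsc(flat, test_panel)
  expect_lt(abs(fitf$h2), 1e-6)
  expect_lt(abs(fitf$intercept - 1), 1e-6)

  # too few matched SNPs is an informative error
  expect_error(univariate_ldsc(toy_sumstats(), test_panel), "insufficient")
})

test_that("jackknife standard errors are invariant to reversing the file", {
  sim <- simulate_sumstats_pair(test_panel, h2 = 0.3, seed = 3)
  fwd <- univariate_ldsc(sim$full, test_panel)
  rev_ss <- sim$full[nrow(sim$full):1]
  rev_panel <- ld_panel(rev(test_panel$SNP), rev(test_panel$L2),
                        attr(test_panel, "m_total"))
  bwd <- univariate_ldsc(rev_ss, rev_panel)
  expect_equal(bwd$h2, fwd$h2, tolerance = 1e-12)
  expect_equal(bwd$h2_se, fwd$h2_se, tolerance = 1e-10)
})

test_that("bivariate LDSC behaves at the self, independent, and correlated poles", {
  sim <- simulate_sumstats_pair(test_panel, h2 = 0.3, seed = 1)
  # self-correlation is exactly 1, genetic covariance equals h2
  self <- suppressWarnings(bivariate_ldsc(sim$full, sim$full, test_panel))
  expect_equal(self$rg, 1, tolerance = 1e-6)
  expect_equal(self$gcov, self$h2_1, tolerance = 1e-10)

  # independent traits: rg indistinguishable from 0
  a <- simulate_sumstats_pair(test_panel, h2 = 0.3, seed = 2)
  b <- simulate_sumstats_pair(test_panel, h2 = 0.3, seed = 20)
  indep <- bivariate_ldsc(a$full, b$full, test_panel)
  expect_lt(abs(indep$rg), 2 * indep$se)

  # correlated traits at rg = 0.7: mean recovery over replicates
  ests <- vapply(1:8, function(s) {
    simf <- simulate_factor_traits(test_panel,
                                   loadings = c(sqrt(0.7), sqrt(0.7)),
                                   h2 = c(0.4, 0.4), seed = s)
    bivariate_ldsc(simf$traits[[1]], simf$traits[[2]], test_panel)$rg
  }, 1)
  expect_lt(abs(mean(ests) - 0.7), 3 * sd(ests) / sqrt(8))

  # symmetric in its arguments
  simf <- simulate_factor_traits(test_panel,
                                 loadings = c(sqrt(0.7), sqrt(0.7)),
                                 h2 = c(0.4, 0.4), seed = 3)
  rg <- bivariate_ldsc(simf$traits[[1]], simf$traits[[2]], test_panel)
  rg_ba <- bivariate_ldsc(simf$traits[[2]], simf$traits[[1]], test_panel)
  expect_equal(rg$rg, rg_ba$rg, tolerance = 1e-12)
})

test_that("key indicator deltas are zero for identical inputs and track EffN", {
  sim <- simulate_sumstats_pair(test_panel, h2 = 0.3, seed = 4)
  ki <- key_indicators_pair(sim$full, sim$full, test_panel)
  expect_equal(ki$delta$eff_n_pct, 0)
  expect_equal(ki$delta$mean_chi2_pct, 0)
  expect_equal(ki$delta$lambda_gc_pct, 0)
  expect_equal(ki$delta$h2_abs, 0)

  # with cohort tables, EffN comes from the 4V(1-V)N bookkeeping
  co_full <- data.frame(label = c("A", "B"), v = c(0.5, 0.1),
                        n = c(1000, 5000))
  ki2 <- key_indicators(sim$full, test_panel, cohorts = co_full)
  expect_equal(ki2$eff_n, 2800)

  # down-sampling the pair reduces EffN by the generator's known fraction
  kp <- key_indicators_pair(sim$full, sim$down, test_panel)
  expect_equal(kp$delta$eff_n_pct,
               (sim$truth$eff_n_down - sim$truth$eff_n_full) /
                 sim$truth$eff_n_full * 100)
})

test_that("h2 estimation is unbiased within Monte Carlo error over replicates", {
  # replicated recovery at h2 = 0.2: mean bias within 3 SD/sqrt(n_rep)
  n_rep <- 12
  est <- vapply(seq_len(n_rep), function(s) {
    sim <- simulate_sumstats_pair(test_panel, h2 = 0.2, seed = 200 + s)
    univariate_ldsc(sim$full, test_panel)$h2
  }, 1)
  expect_lt(abs(mean(est) - 0.2), 3 * sd(est) / sqrt(n_rep))
})
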