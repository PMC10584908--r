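# coefficient-concordance checks and LD clumping

test_that("greedy clumping handles vacuous, singleton and block cases", {
  ss <- as_sumstats(data.frame(
    SNP = paste0("rs", 1:6), A1 = "A", A2 = "G",
    Z = 8, P = c(1e-10, 2e-10, 5e-10, 1e-9, 8e-10, 3e-10), N = 1e5))
  # no SNP significant at an impossible threshold
  ld <- diag(6); dimnames(ld) <- list(ss$SNP, ss$SNP)
  expect_length(ld_clump(ss, ld, p_thresh = 1e-20)$snp_ids, 0)

  # single significant SNP
  one <- ss[1]
  expect_equal(ld_clump(one, ld[1, 1, drop = FALSE])$snp_ids, "rs1")

  # two blocks (within r2 = 0.5, between 0): exactly the per-block minima
  blocks <- rep(1:2, each = 3)
  ld2 <- (outer(blocks, blocks, "==")) * 0.5
  diag(ld2) <- 1
  dimnames(ld2) <- list(ss$SNP, ss$SNP)
  got <- ld_clump(ss, ld2)$snp_ids
  expect_setequal(got, c("rs1", "rs6"))  # min p in each block
  expect_equal(got, clump_oracle(ss, ld2))

  # malformed matrices are rejected
  asym <- ld2; asym[1, 2] <- 0.9
  expect_error(ld_clump(ss, asym), "symmetric")
})

test_that("clumped lead sets match the independent oracle and are order-invariant", {
  set.seed(99)
  for (i in 1:25) {
    m <- sample(4:12, 1)
    A <- matrix(runif(m * m), m)
    ld <- (A + t(A)) / 2; diag(ld) <- 1
    ld[ld < 0.5] <- 0  # sparse LD
    snp <- paste0("s", sample(100, m))
    dimnames(ld) <- list(snp, snp)
    ss <- as_sumstats(data.frame(
      SNP = snp, A1 = "A", A2 = "G", Z = 8,
      P = 10^-runif(m, 7, 12), N = 1e5))
    got <- ld_clump(ss, ld)$snp_ids
    expect_equal(got, clump_oracle(ss, ld))
    # invariant to input row order
    perm <- sample(m)
    got2 <- ld_clump(ss[perm], ld[perm, perm])$snp_ids
    expect_equal(got2, got)
    # validity: pairwise r2 below threshold, maximality
    if (length(got) > 1) {
      expect_true(max(ld[got, got][lower.tri(diag(length(got)))]) < 0.1)
    }
    rest <- setdiff(snp[ss$P < 5e-8], got)
    for (s in rest) expect_true(any(ld[s, got] >= 0.1))
  }
})

test_that("sign concordance uses the one-sided exact binomial test", {
  mk <- function(beta) as_sumstats(data.frame(
    SNP = paste0("rs", seq_along(beta)), A1 = "A", A2 = "G",
    BETA = beta, SE = 0.01, Z = beta / 0.01,
    P = pmax(2 * pnorm(-abs(beta / 0.01)), 1e-300), N = 1e5))
  # perfect concordance cannot reject the 99% null: p = 1
  b <- rnorm(842, 0, 0.05); b[b == 0] <- 0.01
  sc <- sign_concordance(mk(b), mk(b))
  expect_equal(sc$prop_concordant, 1)
  expect_equal(sc$binom_p, 1)

  # 95 of 100 concordant: exact enumeration oracle
  b <- abs(rnorm(100)) + 0.01
  b2 <- b; b2[1:5] <- -b2[1:5]
  sc <- sign_concordance(mk(b), mk(b2))
  expect_equal(sc$prop_concordant, 0.95)
  expect_equal(sc$binom_p, sum(dbinom(0:95, 100, 0.99)), tolerance = 1e-12)

  # all-zero down coefficients count as discordant
  sc <- sign_concordance(mk(b), mk(rep(0, 100)))
  expect_equal(sc$prop_concordant, 0)

  # symmetric under joint sign flip
  sc1 <- sign_concordance(mk(b), mk(b2))
  sc2 <- sign_concordance(mk(-b), mk(-b2))
  expect_equal(sc1$prop_concordant, sc2$prop_concordant)
  expect_equal(sc1$binom_p, sc2$binom_p)
})

test_that("the 99%-null binomial design has the advertised power", {
  expect_gte(design_power(150, 0.99, p_true = 0.95), 0.80)
  # size respects the level under the null boundary
  k <- qbinom(0.05, 150, 0.99)
  while (pbinom(k, 150, 0.99) > 0.05) k <- k - 1
  expect_lte(pbinom(k, 150, 0.99), 0.05)
  # monotone in n and in p_true (exact enumeration over a grid)
  expect_lt(design_power(10, 0.99, p_true = 0.95),
            design_power(150, 0.99, p_true = 0.95))
  ns <- c(50, 150, 400, 1000)
  pw <- vapply(ns, function(n) design_power(n, 0.99, p_true = 0.95), 1)
  expect_true(all(diff(pw) >= 0))
  pts <- c(0.90, 0.93, 0.95, 0.97)
  pw <- vapply(pts, function(p) design_power(300, 0.99, p_true = p), 1)
  expect_true(all(diff(pw) <= 0))
  # degenerate design: no rejection region
  expect_warning(p0 <- design_power(1, 0.5, p_true = 0.3), "no rejection")
  expect_equal(p0, 0)
})

test_that("outlier flags reproduce the confidence-interval rule exactly", {
  mk <- function(beta, se = 0.05) as_sumstats(data.frame(
    SNP = paste0("rs", seq_along(beta)), A1 = "A", A2 = "G",
    BETA = beta, SE = se, Z = beta / se,
    P = pmax(2 * pnorm(-abs(beta / se)), 1e-300), N = 1e5))
  full <- mk(rep(0.10, 3))
  # center of the interval: never flagged
  expect_equal(outlier_flags(full, full)$n_outliers, 0)
  # 0.21 lies above 0.10 + 1.96 * 0.05 = 0.198
  down <- mk(c(0.21, 0.15, 0.10))
  of <- outlier_flags(full, down)
  expect_equal(unname(of$flags), c(1L, 0L, 0L))
  # brute-force re-check on random tables
  set.seed(5)
  fb <- rnorm(200, 0, 0.1); fs <- runif(200, 0.01, 0.1)
  db <- fb + rnorm(200, 0, 0.15)
  f <- as_sumstats(data.frame(SNP = paste0("rs", 1:200), A1 = "A", A2 = "G",
                              BETA = fb, SE = fs, Z = fb / fs,
                              P = pmax(2 * pnorm(-abs(fb / fs)), 1e-300),
                              N = 1e5))
  d <- data.table::copy(f); d[, BETA := db]
  of <- outlier_flags(f, d)
  manual <- as.integer(db < fb - qnorm(0.975) * fs | db > fb + qnorm(0.975) * fs)
  expect_equal(unname(of$flags), manual)
})

test_that("coefficient regression detects identity, exact attenuation, and noisy attenuation", {
  mk <- function(beta) as_sumstats(data.frame(
    SNP = paste0("rs", seq_along(beta)), A1 = "A", A2 = "G",
    BETA = beta, SE = 0.01, Z = beta / 0.01,
    P = pmax(2 * pnorm(-abs(beta / 0.01)), 1e-300), N = 1e5))
  set.seed(4)
  b <- abs(rnorm(842, 0, 0.02)) + 1e-4
  # identity: intercept 0, slope 1, adj R2 = 1
  cr <- suppressWarnings(coefficient_regression(mk(b), mk(b)))
  expect_equal(cr$intercept, 0, tolerance = 1e-10)
  expect_equal(cr$slope, 1, tolerance = 1e-10)
  expect_equal(cr$adj_r2, 1, tolerance = 1e-10)

  # exact attenuation by 0.9: slope recovered, unity rejected
  cr <- suppressWarnings(coefficient_regression(mk(b[1:20]), mk(0.9 * b[1:20])))
  expect_equal(cr$slope, 0.9, tolerance = 1e-10)
  expect_lt(cr$p_slope_one, 0.05)

  # noisy attenuation at the published magnitude (slope ~0.898)
  d <- 0.898 * b + rnorm(842, 0, 0.002)
  cr <- coefficient_regression(mk(b), mk(abs(d)), absolute = TRUE)
  expect_lt(abs(cr$slope - 0.898), 2 * cr$slope_se)

  expect_error(coefficient_regression(mk(rep(0.1, 5)), mk(rep(0.1, 5))),
               "degenerate")
})
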