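# Shared fixtures built in code. The LD-score panel is the most expensive
# shared input, so it is generated once per test run.

test_panel <- simulate_ld_scores(20000, seed = 1)

# a tiny hand-written sumstats table
toy_sumstats <- function() {
  as_sumstats(data.frame(
    SNP = c("rs1", "rs2", "rs3"),
    CHR = c(1, 1, 2), BP = c(100, 200, 300),
    A1 = c("A", "C", "G"), A2 = c("G", "T", "A"),
    BETA = c(0.10, -0.05, 0.02), SE = c(0.02, 0.01, 0.01),
    Z = c(5, -5, 2),
    P = c(5.7e-7, 5.7e-7, 0.0455),
    N = c(1000, 1000, 1000)))
}

# random valid sumstats table for round-trip / property tests
random_sumstats <- function(n, seed) {
  set.seed(seed)
  se <- runif(n, 0.005, 0.05)
  beta <- rnorm(n, 0, 0.03)
  z <- beta / se
  as_sumstats(data.frame(
    SNP = paste0("rs", sample.int(1e6, n)),
    A1 = sample(c("A", "C", "G", "T"), n, TRUE),
    A2 = NA_character_, BETA = beta, SE = se, Z = z,
    P = 2 * pnorm(-abs(z)), N = sample(1e4:1e5, n, TRUE)
  ) |> transform(A2 = vapply(A1, function(a) {
    sample(setdiff(c("A", "C", "G", "T"), a), 1)
  }, "")))
}

# independent sequential-filter implementation of LD clumping used as the
# oracle: scan SNPs in (p, id) order, keep those below r2 with all kept.
clump_oracle <- function(ss, ld, p_thresh = 5e-8, r2_thresh = 0.1) {
  sig <- ss[!is.na(ss$P) & ss$P < p_thresh, ]
  sig <- sig[order(sig$P, sig$SNP), ]
  kept <- character(0)
  for (s in sig$SNP) {
    if (!length(kept) || all(ld[s, kept] < r2_thresh)) kept <- c(kept, s)
  }
  kept
}
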