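# Synthetic-data generators with known ground truth: LD-score panels,
# paired full/down-sampled summary statistics under the LD Score regression
# model with cohort structure and heterogeneity, single-factor multi-trait
# panels, block LD matrices for clumping, and an individual-level PGS
# cohort. All generators are deterministic per seed.

#' Simulate an LD-score panel
#'
#' LD scores are drawn from a right-skewed gamma distribution
#' (shape 3, rate 3; mean 1, positive support) — enough dispersion for a
#' well-conditioned LD Score regression while keeping the average score at
#' its normalized value of 1.
#'
#' @param m_snps number of SNPs (>= 1000).
#' @param seed RNG seed.
#' @return `ld_panel` with SNP ids `rs1..rsM` and `m_total = m_snps`.
#' @export
simulate_ld_scores <- function(m_snps, seed) {
  stopifnot(m_snps >= 1000)
  set.seed(seed)
  ld_panel(paste0("rs", seq_len(m_snps)), rgamma(m_snps, shape = 3, rate = 3),
           m_total = m_snps)
}

.eff_n_per_cohort <- function(cohorts) {
  ch <- .as_cohorts(cohorts)
  ifelse(is.na(ch$v), ch$n, 4 * ch$v * (1 - ch$v) * ch$n)
}

#' Simulate a full / down-sampled pair of GWAS summary statistics
#'
#' Per SNP j, a shared standardized marginal effect `b_j ~ N(0, h2 l_j/M)`
#' (genetic variance proportional to the LD score, so the LD Score
#' regression is exactly well-specified). Each cohort k observes
#' `b_j + delta_jk + e_jk` with cohort-specific heterogeneity
#' `delta_jk ~ N(0, tau^2 l_j/M)` and sampling noise
#' `e_jk ~ N(0, intercept/EffN_k)` (the intercept parameter injects
#' uniform confounding inflation). Cohorts are combined by inverse-variance
#' meta-analysis over all cohorts (full) and over the retained cohorts
#' (down). Because the heterogeneity scales with the LD score it behaves as
#' cohort-private genetic signal, so tau > 0 drives the full/down genetic
#' correlation below 1 — the regime where a down-sampled release needs
#' auditing.
#'
#' @param panel `ld_panel`.
#' @param h2 shared-effect heritability in [0, 1]. With tau > 0 each
#'   version's total heritability is `h2 + tau^2 * sum(w_k^2)` with w the
#'   meta-analysis weights (reported in the truth record).
#' @param intercept target LDSC intercept (1 = no confounding).
#' @param cohorts cohort table (`label`, `v`, `n`); default two continuous
#'   cohorts of 30,000 and 20,000.
#' @param drop_cohorts labels excluded from the down-sampled twin.
#' @param tau cohort heterogeneity SD scale (>= 0).
#' @param seed RNG seed.
#' @return list: `full`, `down` (validated `sumstats`), `truth` (b, tau,
#'   expected h2 per version, expected rg between versions, EffN values).
#' @export
simulate_sumstats_pair <- function(panel, h2 = 0.3, intercept = 1.0,
                                   cohorts = data.frame(
                                     label = c("A", "B"),
                                     v = NA_real_,
                                     n = c(30000, 20000)),
                                   drop_cohorts = "B",
                                   tau = 0, seed = 1) {
  stopifnot(h2 >= 0, h2 <= 1, tau >= 0, intercept >= 0)
  ch <- .as_cohorts(cohorts)
  if (!all(drop_cohorts %in% ch$label)) stop("unknown cohort label in drop_cohorts")
  set.seed(seed)
  m <- nrow(panel)
  M <- attr(panel, "m_total")
  l2 <- panel$L2
  gsd <- sqrt(h2 * l2 / M)
  b <- rnorm(m, 0, gsd)

  neff_k <- .eff_n_per_cohort(ch)
  K <- nrow(ch)
  est <- matrix(0, m, K)
  tsd <- tau * sqrt(l2 / M)
  for (k in seq_len(K)) {
    est[, k] <- b + rnorm(m, 0, tsd) + rnorm(m, 0, sqrt(intercept / neff_k[k]))
  }

  meta <- function(idx) {
    w <- neff_k[idx]
    beta <- drop(est[, idx, drop = FALSE] %*% w) / sum(w)
    effn <- sum(w)
    se <- 1 / sqrt(effn)
    z <- beta / se
    as_sumstats(data.table::data.table(
      SNP = panel$SNP, A1 = "A", A2 = "G",
      BETA = beta, SE = se, Z = z,
      P = 2 * pnorm(-abs(z)),
      N = sum(ch$n[idx]), EFF_N = effn))
  }
  ret <- which(!(ch$label %in% drop_cohorts))
  full <- meta(seq_len(K))
  down <- meta(ret)

  wf <- neff_k / sum(neff_k)
  wd <- numeric(K); wd[ret] <- neff_k[ret] / sum(neff_k[ret])
  h2f <- h2 + tau^2 * sum(wf^2)
  h2d <- h2 + tau^2 * sum(wd^2)
  gcov <- h2 + tau^2 * sum(wf * wd)
  list(full = full, down = down,
       truth = list(b = b, h2 = h2, tau = tau, intercept = intercept,
                    h2_full = h2f, h2_down = h2d,
                    rg_full_down = gcov / sqrt(h2f * h2d),
                    eff_n_full = sum(neff_k), eff_n_down = sum(neff_k[ret]),
                    cohorts = ch, drop_cohorts = drop_cohorts))
}

#' Simulate a single-factor panel of trait summary statistics
#'
#' Per SNP, a shared factor effect `f_j ~ N(0, l_j/M)` plus trait-specific
#' residual genetic effects, scaled so trait t has heritability `h2_t` and
#' every trait pair has genetic correlation `lambda_t lambda_u`:
#' `g_jt = sqrt(h2_t) (lambda_t f_j + sqrt(1 - lambda_t^2) u_jt)`.
#'
#' @param panel `ld_panel`.
#' @param loadings standardized factor loadings, all |lambda| <= 1.
#' @param h2 per-trait heritabilities (default `loadings^2`).
#' @param n per-trait sample sizes (recycled).
#' @param intercept per-trait LDSC intercepts (recycled).
#' @param seed RNG seed.
#' @return list: named list `traits` of validated `sumstats`, `truth`
#'   (loadings, h2, implied rg matrix).
#' @export
simulate_factor_traits <- function(panel, loadings, h2 = loadings^2,
                                   n = 50000, intercept = 1.0, seed = 1) {
  T <- length(loadings)
  if (any(abs(loadings) > 1)) stop("loadings must lie in [-1, 1]")
  stopifnot(length(h2) == T, all(h2 >= 0 & h2 <= 1))
  n <- rep_len(n, T); intercept <- rep_len(intercept, T)
  set.seed(seed)
  m <- nrow(panel); M <- attr(panel, "m_total")
  l2 <- panel$L2
  base_sd <- sqrt(l2 / M)
  f <- rnorm(m, 0, base_sd)
  traits <- vector("list", T)
  for (t in seq_len(T)) {
    u <- rnorm(m, 0, base_sd)
    g <- sqrt(h2[t]) * (loadings[t] * f + sqrt(1 - loadings[t]^2) * u)
    z <- sqrt(n[t]) * g + rnorm(m, 0, sqrt(intercept[t]))
    traits[[t]] <- as_sumstats(data.table::data.table(
      SNP = panel$SNP, A1 = "A", A2 = "G",
      BETA = z / sqrt(n[t]), SE = 1 / sqrt(n[t]), Z = z,
      P = 2 * pnorm(-abs(z)), N = n[t], EFF_N = n[t]))
  }
  names(traits) <- paste0("trait", seq_len(T))
  rg <- outer(loadings, loadings); diag(rg) <- 1
  list(traits = traits,
       truth = list(loadings = loadings, h2 = h2, rg_matrix = rg,
                    factor = f, n = n))
}

#' Simulate a block LD matrix with per-SNP p-values
#'
#' Block-diagonal LD structure: r-squared `r^2` within blocks, 0 between,
#' 1 on the diagonal. P-values are drawn below the genome-wide threshold
#' with a unique minimum per block, so greedy clumping has an unambiguous
#' expected answer of one lead SNP per block (for `r^2` above the pruning
#' threshold).
#'
#' @param n_blocks number of LD blocks.
#' @param block_size SNPs per block.
#' @param r within-block correlation, `0 <= r < 1`.
#' @param seed RNG seed.
#' @return list: `ld` matrix, `ss` minimal `sumstats` table, `blocks`
#'   block index per SNP.
#' @export
simulate_ld_blocks <- function(n_blocks, block_size, r, seed = 1) {
  stopifnot(r >= 0, r < 1)
  set.seed(seed)
  m <- n_blocks * block_size
  snp <- paste0("rs", seq_len(m))
  blocks <- rep(seq_len(n_blocks), each = block_size)
  ld <- (outer(blocks, blocks, "==")) * r^2
  diag(ld) <- 1
  dimnames(ld) <- list(snp, snp)
  p <- 10^(-runif(m, 8.5, 12))     # all genome-wide significant, all distinct
  while (anyDuplicated(p)) p <- 10^(-runif(m, 8.5, 12))
  z <- qnorm(p / 2, lower.tail = FALSE)
  ss <- as_sumstats(data.table::data.table(
    SNP = snp, A1 = "A", A2 = "G", Z = z, P = p, N = 1e5))
  list(ld = ld, ss = ss, blocks = blocks)
}

#' Simulate an individual-level cohort for PGS evaluation
#'
#' Dosages are Binomial(2, maf) with maf uniform on (0.05, 0.5); the PGS
#' weights are fixed normal draws. The continuous outcome is built as
#' `sqrt(target) * score_std + covariate effects + noise`, calibrated so
#' the population incremental R-squared of the standardized score over the
#' covariates (age, sex, ten principal components; joint variance share
#' 0.2) equals `target_incr_r2`. A binary outcome is derived by
#' liability-thresholding the continuous one at 30% prevalence.
#'
#' @param n_ind individuals.
#' @param m_snps SNPs in the score.
#' @param target_incr_r2 population incremental R-squared in [0, 1).
#' @param seed RNG seed.
#' @return list: `cohort` (a `pgs_cohort` with outcomes `y_cont`,
#'   `y_bin`), `truth` (target, realized sample variance shares).
#' @export
simulate_pgs_cohort <- function(n_ind, m_snps = 200, target_incr_r2, seed) {
  stopifnot(target_incr_r2 >= 0, target_incr_r2 < 1)
  set.seed(seed)
  maf <- runif(m_snps, 0.05, 0.5)
  dos <- matrix(rbinom(n_ind * m_snps, 2, rep(maf, each = n_ind)),
                nrow = n_ind)
  colnames(dos) <- paste0("rs", seq_len(m_snps))
  w <- rnorm(m_snps)
  raw <- drop(dos %*% w)
  s <- (raw - mean(raw)) / sd(raw)

  cov_var <- 0.2
  age <- rnorm(n_ind, 50, 10)
  sex <- rbinom(n_ind, 1, 0.5)
  pcs <- matrix(rnorm(n_ind * 10), n_ind)
  colnames(pcs) <- paste0("PC", 1:10)
  Xs <- scale(cbind(age, sex, pcs))
  gamma <- rnorm(12)
  gamma <- gamma / sqrt(sum(gamma^2)) * sqrt(cov_var)
  cpart <- drop(Xs %*% gamma)
  noise_var <- max(1 - target_incr_r2 - cov_var, 1e-8)
  y <- sqrt(target_incr_r2) * s + cpart + rnorm(n_ind, 0, sqrt(noise_var))
  y_bin <- as.numeric(y > quantile(y, 0.7))

  cohort <- pgs_cohort(
    dosages = dos, weights = w,
    phenotypes = data.frame(y_cont = y, y_bin = y_bin),
    covariates = data.frame(age = age, sex = sex, pcs))
  list(cohort = cohort,
       truth = list(target_incr_r2 = target_incr_r2,
                    realized_score_var_share =
                      target_incr_r2 / (target_incr_r2 + cov_var + noise_var),
                    prevalence_bin = mean(y_bin)))
}
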