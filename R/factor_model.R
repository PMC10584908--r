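# Genomic-SEM-style machinery: estimation of the genetic covariance matrix
# S and its sampling covariance V by joint block jackknife over the LDSC
# regressions; a confirmatory single-factor fit with unit-variance
# identification by diagonally weighted least squares; and a per-SNP
# factor-level GWAS by generalized least squares on the loading vector.

# half-vectorization (lower triangle, column-major, diagonal included)
.vech <- function(M) M[lower.tri(M, diag = TRUE)]

.vech_index <- function(T) {
  idx <- which(lower.tri(matrix(0, T, T), diag = TRUE), arr.ind = TRUE)
  idx[, c(2, 1), drop = FALSE]  # (row >= col) -> pairs (col, row) ordered
}

.unvech <- function(v, T) {
  M <- matrix(0, T, T)
  M[lower.tri(M, diag = TRUE)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

#' Construct a genetic covariance object from matrices
#'
#' Wraps a genetic covariance matrix S (heritabilities on the diagonal,
#' genetic covariances off it) and, optionally, the sampling covariance V
#' of its unique elements, into the object [fit_single_factor()] consumes.
#' With `V = NULL` the factor fit uses unit weights.
#'
#' @param S symmetric T x T genetic covariance matrix.
#' @param V optional sampling covariance of `vech(S)` (lower triangle,
#'   column-major).
#' @param traits trait labels.
#' @export
as_genetic_covariance <- function(S, V = NULL, traits = colnames(S)) {
  T <- nrow(S)
  stopifnot(ncol(S) == T, max(abs(S - t(S))) < 1e-8)
  if (is.null(traits)) traits <- paste0("trait", seq_len(T))
  if (any(diag(S) <= 0)) {
    warning("non-positive diagonal in S; affected traits cannot be standardized")
  }
  D <- 1 / sqrt(pmax(diag(S), .Machine$double.eps))
  S_std <- diag(D) %*% S %*% diag(D)
  dimnames(S) <- dimnames(S_std) <- list(traits, traits)
  V_std <- NULL
  if (!is.null(V)) {
    k <- T * (T + 1) / 2
    stopifnot(nrow(V) == k, ncol(V) == k)
    # delta-method transform of V to the standardized scale
    J <- .std_jacobian(S)
    V_std <- J %*% V %*% t(J)
  }
  structure(list(traits = traits, S = S, V = V, S_std = S_std, V_std = V_std),
            class = "genetic_covariance")
}

# Jacobian of vech(standardized S) w.r.t. vech(S)
.std_jacobian <- function(S) {
  T <- nrow(S)
  pairs <- .vech_index(T)
  k <- nrow(pairs)
  pos <- matrix(0L, T, T)
  pos[lower.tri(pos, diag = TRUE)] <- seq_len(k)
  pos[upper.tri(pos)] <- t(pos)[upper.tri(pos)]
  d <- diag(S)
  J <- matrix(0, k, k)
  for (r in seq_len(k)) {
    i <- pairs[r, 2]; j <- pairs[r, 1]   # element S_ij, i >= j
    J[r, pos[i, j]] <- 1 / sqrt(d[i] * d[j])
    if (i != j) {
      J[r, pos[i, i]] <- J[r, pos[i, i]] - S[i, j] / (2 * d[i]^1.5 * sqrt(d[j]))
      J[r, pos[j, j]] <- J[r, pos[j, j]] - S[i, j] / (2 * d[j]^1.5 * sqrt(d[i]))
    } else {
      J[r, pos[i, i]] <- 0  # standardized diagonal is identically 1
    }
  }
  J
}

#' Genetic covariance and sampling covariance across traits
#'
#' Fills the genetic covariance matrix S with univariate LDSC slopes
#' (diagonal) and bivariate LDSC slopes (off-diagonal), all computed on the
#' shared harmonized SNP intersection with common jackknife blocks, and
#' estimates the sampling covariance V of the unique elements of S by a
#' joint delete-one-block jackknife.
#'
#' @param traits named list of validated `sumstats` tables (length >= 2).
#' @param panel `ld_panel`.
#' @param n_blocks jackknife blocks (default 200).
#' @return Object of class `genetic_covariance` with S, V, standardized
#'   S_std/V_std, LDSC intercept matrix, and the aligned per-SNP Z and
#'   effective-N matrices needed for [factor_gwas()].
#' @export
genetic_covariance <- function(traits, panel, n_blocks = 200) {
  T <- length(traits)
  stopifnot(T >= 2)
  labels <- names(traits)
  if (is.null(labels)) labels <- paste0("trait", seq_len(T))

  # harmonize all traits to the first trait's allele coding
  ref <- data.table::as.data.table(traits[[1]])
  aligned <- vector("list", T)
  aligned[[1]] <- ref
  shared <- ref$SNP
  for (t in seq_len(T)[-1]) {
    hp <- harmonize_pair(ref, traits[[t]])
    aligned[[t]] <- hp$down
    shared <- intersect(shared, hp$down$SNP)
  }
  aligned <- lapply(aligned, function(d) d[match(shared, d$SNP)])

  pidx <- match(shared, panel$SNP)
  keep <- !is.na(pidx)
  if (sum(keep) < 200) stop("insufficient shared SNPs matched to the LD panel")
  aligned <- lapply(aligned, function(d) d[keep])
  l2 <- panel$L2[pidx[keep]]
  m <- attr(panel, "m_total")

  Zm <- vapply(aligned, function(d) d$Z, numeric(sum(keep)))
  Nm <- vapply(aligned, function(d) {
    if ("EFF_N" %in% names(d) && !anyNA(d$EFF_N)) d$EFF_N else d$N
  }, numeric(sum(keep)))

  # joint chi-square truncation across traits
  thr <- pmax(80, 0.001 * colMeans(Nm))
  keep2 <- rowSums(sweep(Zm^2, 2, thr, ">")) == 0
  Zm <- Zm[keep2, , drop = FALSE]; Nm <- Nm[keep2, , drop = FALSE]
  l2 <- l2[keep2]
  mres <- nrow(Zm)
  blocks <- .block_labels(mres, n_blocks)
  g <- max(blocks)

  uni <- lapply(seq_len(T), function(t) {
    .ldsc_uni_fit(Zm[, t], Nm[, t], l2, m, blocks)
  })

  k <- T * (T + 1) / 2
  pairs <- .vech_index(T)
  est <- numeric(k)
  reps <- matrix(0, g, k)
  I <- matrix(NA_real_, T, T, dimnames = list(labels, labels))
  pos <- 0L
  for (r in seq_len(k)) {
    j <- pairs[r, 1]; i <- pairs[r, 2]   # i >= j
    if (i == j) {
      est[r] <- uni[[i]]$est["slope"]
      reps[, r] <- uni[[i]]$reps[, "slope"]
      I[i, i] <- uni[[i]]$est["intercept"]
    } else {
      x <- sqrt(Nm[, i] * Nm[, j]) * l2 / m
      y <- Zm[, i] * Zm[, j]
      p1 <- .wls_jack(x, y, rep(1, mres), blocks)
      excr <- p1$est[1] + p1$est[2] * x
      fg <- .wls_jack(x, y, .ldsc_weights(l2, uni[[i]]$ex, uni[[j]]$ex,
                                          cross = excr), blocks)
      est[r] <- fg$est["slope"]
      reps[, r] <- fg$reps[, "slope"]
      I[i, j] <- I[j, i] <- fg$est["intercept"]
    }
  }
  dev <- sweep(reps, 2, colMeans(reps))
  V <- (g - 1) / g * crossprod(dev)

  S <- .unvech(est, T)
  dimnames(S) <- list(labels, labels)
  gc <- as_genetic_covariance(S, V, traits = labels)
  gc$intercepts <- I
  gc$n_blocks <- g
  gc$snp <- aligned[[1]]$SNP[keep2]
  gc$Z <- Zm
  gc$Neff <- Nm
  colnames(gc$Z) <- colnames(gc$Neff) <- labels
  gc
}

#' Fit a single-factor model to a genetic covariance matrix
#'
#' Confirmatory one-factor model with unit-variance identification fitted
#' by diagonally weighted least squares on the standardized genetic
#' covariance matrix: minimize `(s - sigma(theta))' W (s - sigma(theta))`
#' with `s = vech(S_std)`, `sigma = vech(lambda lambda' + diag(psi))`,
#' `W = diag(V_std)^-1`. Residual variances are profiled as
#' `psi = 1 - lambda^2` and bounded at zero (Heywood cases flagged, not
#' fatal). The model chi-square is the full-V quadratic form of the
#' residuals; CFI is computed against the independence baseline and SRMR is
#' the root mean square standardized residual. Loadings are canonicalized
#' so the largest-magnitude loading is positive.
#'
#' @param gc `genetic_covariance` object.
#' @param max_iter optimizer iteration cap.
#' @return list of class `factor_fit`: `loadings`, `loading_se`,
#'   `residuals`, `residual_se`, `chi2_model`, `df`, `cfi`, `srmr`, `aic`,
#'   `heywood`, `converged`.
#' @export
fit_single_factor <- function(gc, max_iter = 500) {
  R <- gc$S_std
  T <- nrow(R)
  if (any(!is.finite(R))) stop("genetic covariance matrix not standardizable")
  s <- .vech(R)
  k <- length(s)
  pairs <- .vech_index(T)
  offdiag <- pairs[, 1] != pairs[, 2]

  if (!is.null(gc$V_std)) {
    vdiag <- pmax(diag(gc$V_std), 0)
    # zero-variance elements (the fixed standardized diagonal) get the
    # largest finite off-diagonal weight rather than an infinite one
    floor_v <- min(vdiag[offdiag & vdiag > 0], na.rm = TRUE)
    w <- 1 / pmax(vdiag, floor_v)
  } else {
    w <- rep(1, k)
  }
  w_off <- w[offdiag]
  pen_w <- max(w)

  io <- pairs[offdiag, 2]; jo <- pairs[offdiag, 1]
  obj <- function(lam) {
    res <- s[offdiag] - lam[io] * lam[jo]
    pen <- pmax(lam^2 - 1, 0)
    sum(w_off * res^2) + pen_w * sum(pen^2)
  }
  grad <- function(lam) {
    res <- s[offdiag] - lam[io] * lam[jo]
    g <- numeric(T)
    contrib <- -2 * w_off * res
    for (t in seq_len(T)) {
      g[t] <- sum(contrib[io == t] * lam[jo[io == t]]) +
              sum(contrib[jo == t] * lam[io[jo == t]])
    }
    g + pen_w * 4 * pmax(lam^2 - 1, 0) * lam
  }

  # initialize from the leading eigenvector of the standardized matrix
  eg <- eigen(R, symmetric = TRUE)
  lam0 <- eg$vectors[, 1] * sqrt(max(eg$values[1], 0.1))
  lam0 <- pmin(pmax(lam0, -0.95), 0.95)
  opt <- optim(lam0, obj, grad, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-14))
  lam <- opt$par
  if (sum(lam[which.max(abs(lam))]) < 0) lam <- -lam  # canonical sign
  heywood <- lam^2 > 1 + 1e-10
  if (any(heywood)) {
    warning("Heywood case: residual variance bounded at 0 for trait(s) ",
            paste(gc$traits[heywood], collapse = ", "))
  }
  psi <- pmax(1 - lam^2, 0)
  gnorm <- sqrt(sum(grad(lam)^2))
  if (opt$convergence != 0 && gnorm > 1e-6) {
    stop("factor fit failed to converge; gradient norm ", signif(gnorm, 3))
  }

  sigma <- .vech(outer(lam, lam) + diag(psi))
  resid <- s - sigma

  df <- k - 2 * T
  chi2_model <- .resid_chi2(resid, gc$V_std)
  resid_base <- s - .vech(diag(T))
  chi2_base <- .resid_chi2(resid_base, gc$V_std)
  df_base <- k - T
  cfi <- if (is.na(chi2_model)) NA_real_ else {
    1 - max(0, chi2_model - df) / max(chi2_base - df_base, 1e-12)
  }
  srmr <- sqrt(mean(resid^2))
  aic <- if (is.na(chi2_model)) NA_real_ else chi2_model + 2 * (2 * T)

  ses <- .dwls_param_se(lam, psi, w, gc$V_std, pairs)

  structure(list(traits = gc$traits,
                 loadings = setNames(lam, gc$traits),
                 loading_se = setNames(ses$lambda, gc$traits),
                 residuals = setNames(psi, gc$traits),
                 residual_se = setNames(ses$psi, gc$traits),
                 chi2_model = chi2_model, df = df,
                 chi2_base = chi2_base, df_base = df_base,
                 cfi = cfi, srmr = srmr, aic = aic,
                 heywood = heywood, converged = TRUE,
                 gradient_norm = gnorm),
            class = "factor_fit")
}

# residual quadratic form against the full sampling covariance
# (Moore-Penrose inverse; zero-variance directions drop out). Without a
# sampling covariance the unit-weight sum of squares is reported, which
# keeps the CFI classification meaningful for exactly model-implied input.
.resid_chi2 <- function(resid, V) {
  if (is.null(V)) return(sum(resid^2))
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  tol <- max(eg$values) * 1e-8
  keep <- eg$values > tol
  if (!any(keep)) return(NA_real_)
  u <- crossprod(eg$vectors[, keep, drop = FALSE], resid)
  drop(sum(u^2 / eg$values[keep]))
}

# DWLS sandwich covariance of (lambda, psi)
.dwls_param_se <- function(lam, psi, w, V, pairs) {
  T <- length(lam)
  k <- nrow(pairs)
  J <- matrix(0, k, 2 * T)
  for (r in seq_len(k)) {
    j <- pairs[r, 1]; i <- pairs[r, 2]
    J[r, i] <- J[r, i] + lam[j]
    J[r, j] <- J[r, j] + lam[i]
    if (i == j) J[r, T + i] <- 1
  }
  if (is.null(V)) {
    return(list(lambda = rep(NA_real_, T), psi = rep(NA_real_, T)))
  }
  WJ <- w * J
  bread <- tryCatch(solve(crossprod(J, WJ)), error = function(e) NULL)
  if (is.null(bread)) {
    return(list(lambda = rep(NA_real_, T), psi = rep(NA_real_, T)))
  }
  meat <- crossprod(WJ, V %*% WJ)
  cv <- bread %*% meat %*% bread
  se <- sqrt(pmax(diag(cv), 0))
  list(lambda = se[seq_len(T)], psi = se[T + seq_len(T)])
}

#' Compare two single-factor fits parameter by parameter
#'
#' For each loading and residual variance, the standardized difference
#' `z = (a - b)/sqrt(se_a^2 + se_b^2)`, its two-sided p-value, and a
#' Bonferroni-adjusted significance flag.
#'
#' @param fitA,fitB `factor_fit` objects over the same traits.
#' @param alpha family-wise level for the Bonferroni flag.
#' @return data.frame with one row per parameter.
#' @export
compare_factor_fits <- function(fitA, fitB, alpha = 0.05) {
  if (!identical(fitA$traits, fitB$traits)) {
    stop("factor fits have different trait structure")
  }
  par_a <- c(fitA$loadings, fitA$residuals)
  par_b <- c(fitB$loadings, fitB$residuals)
  se_a <- c(fitA$loading_se, fitA$residual_se)
  se_b <- c(fitB$loading_se, fitB$residual_se)
  z <- (par_a - par_b) / sqrt(se_a^2 + se_b^2)
  z[par_a == par_b] <- 0   # identical parameters differ by exactly zero
  p <- 2 * pnorm(-abs(z))
  data.frame(parameter = c(paste0("loading_", fitA$traits),
                           paste0("residual_", fitA$traits)),
             est_a = unname(par_a), est_b = unname(par_b),
             se_a = unname(se_a), se_b = unname(se_b),
             z = unname(z), p = unname(p),
             significant = unname(p < alpha / length(z)))
}

#' Per-SNP genetic covariances with the traits
#'
#' Builds the SNP-trait genetic covariance vectors the factor GWAS
#' regresses on the loading vector: `cov_jt = z_jt sqrt(h2_t) / sqrt(N_jt)`
#' on the standardized-trait scale, with sampling SE `sqrt(h2_t / N_jt)`.
#'
#' @param gc `genetic_covariance` from [genetic_covariance()] (it carries
#'   the aligned Z and effective-N matrices).
#' @return list with matrices `est` and `se` (SNPs x traits) and `snp`.
#' @export
snp_genetic_covariances <- function(gc) {
  if (is.null(gc$Z)) stop("gc does not carry per-SNP data; use genetic_covariance()")
  h2 <- pmax(diag(gc$S), 0)
  sc <- sqrt(h2)
  est <- sweep(gc$Z / sqrt(gc$Neff), 2, sc, "*")
  se <- sweep(1 / sqrt(gc$Neff), 2, sc, "*")
  list(est = est, se = se, snp = gc$snp)
}

#' Factor-level GWAS from SNP-trait covariances
#'
#' For each SNP, regresses its vector of SNP-trait genetic covariances on
#' the factor loading vector by generalized least squares with weights from
#' the per-trait sampling variances of those covariances:
#' `beta_j = (lambda' W_j lambda)^-1 lambda' W_j y_j`,
#' `W_j = diag(1/se_jt^2)`, with `SE_j = (lambda' W_j lambda)^-1/2`. This
#' reduces to ordinary least squares when the sampling structure is
#' isotropic. SNPs with a singular weight matrix get NA with a diagnostic
#' count.
#'
#' @param gc `genetic_covariance` object.
#' @param fit converged `factor_fit`.
#' @param snp_cov optional list with `est`/`se` matrices as produced by
#'   [snp_genetic_covariances()]; computed from `gc` when omitted.
#' @return data.table: SNP, BETA (effect on the latent factor), SE, Z, P.
#' @export
factor_gwas <- function(gc, fit, snp_cov = NULL) {
  if (is.null(snp_cov)) snp_cov <- snp_genetic_covariances(gc)
  lam <- unname(fit$loadings)
  y <- snp_cov$est
  se2 <- snp_cov$se^2
  stopifnot(ncol(y) == length(lam))
  wy <- y / se2
  wl2 <- sweep(1 / se2, 2, lam^2, "*")
  denom <- rowSums(wl2)
  num <- rowSums(sweep(wy, 2, lam, "*"))
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad)) warning(sum(bad), " SNP(s) with singular weight matrix; set to NA")
  beta <- ifelse(bad, NA_real_, num / denom)
  se <- ifelse(bad, NA_real_, 1 / sqrt(denom))
  z <- beta / se
  # implied per-SNP sample size on the standardized scale (SE = 1/sqrt(N)),
  # the usual bookkeeping for latent-factor association statistics
  data.table::data.table(SNP = snp_cov$snp, BETA = beta, SE = se, Z = z,
                         P = 2 * pnorm(-abs(z)),
                         N = 1 / se^2, EFF_N = 1 / se^2)
}
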