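# Comparison of externally produced estimate vectors (gene-property
# results, genetic correlations with other traits): rank correlations,
# per-item difference tests, and confidence-interval overlap tables.

#' Construct an estimate vector
#'
#' A labelled vector of point estimates with optional standard errors
#' and/or 95% confidence bounds (derived as est +/- 1.96 SE when only SEs
#' are given).
#'
#' @param labels item names (tissues, developmental stages, traits, ...).
#' @param est point estimates.
#' @param se optional standard errors.
#' @param ci_lo,ci_hi optional explicit 95% bounds.
#' @export
estimate_vector <- function(labels, est, se = NULL, ci_lo = NULL, ci_hi = NULL) {
  n <- length(labels)
  stopifnot(length(est) == n)
  if (!is.null(se)) {
    stopifnot(length(se) == n)
    if (is.null(ci_lo)) ci_lo <- est - qnorm(0.975) * se
    if (is.null(ci_hi)) ci_hi <- est + qnorm(0.975) * se
  }
  if (!is.null(ci_lo) && any(ci_lo > est | est > ci_hi, na.rm = TRUE)) {
    stop("confidence bounds must bracket the point estimates")
  }
  structure(list(labels = as.character(labels), est = as.numeric(est),
                 se = se, ci_lo = ci_lo, ci_hi = ci_hi),
            class = "estimate_vector")
}

#' Read an estimate vector from a TSV file
#'
#' Expects columns `label`, `est` and either `se` or `ci_lo`/`ci_hi`
#' (case-insensitive) — the shape of gene-property output tables and
#' genetic-correlation tables.
#'
#' @param path file path.
#' @export
read_estimate_vector <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  names(dt) <- tolower(names(dt))
  if (!all(c("label", "est") %in% names(dt))) {
    stop("estimate table needs 'label' and 'est' columns")
  }
  estimate_vector(dt$label, dt$est,
                  se = if ("se" %in% names(dt)) dt$se else NULL,
                  ci_lo = if ("ci_lo" %in% names(dt)) dt$ci_lo else NULL,
                  ci_hi = if ("ci_hi" %in% names(dt)) dt$ci_hi else NULL)
}

.align_vectors <- function(a, b) {
  if (length(a$labels) != length(b$labels) || !setequal(a$labels, b$labels) ||
      anyDuplicated(a$labels)) {
    off <- union(setdiff(a$labels, b$labels), setdiff(b$labels, a$labels))
    stop("label mismatch between estimate vectors: ",
         paste(head(off, 5), collapse = ", "))
  }
  idx <- match(a$labels, b$labels)
  b$est <- b$est[idx]
  if (!is.null(b$se)) b$se <- b$se[idx]
  if (!is.null(b$ci_lo)) { b$ci_lo <- b$ci_lo[idx]; b$ci_hi <- b$ci_hi[idx] }
  b$labels <- a$labels
  list(a = a, b = b)
}

#' Spearman rank correlation of two estimate vectors
#'
#' Average ranks for ties; items matched by label.
#'
#' @param a,b `estimate_vector`s with identical label sets, length >= 3.
#' @export
rank_correlation <- function(a, b) {
  al <- .align_vectors(a, b)
  if (length(al$a$est) < 3) stop("need at least 3 matched items")
  cor(al$a$est, al$b$est, method = "spearman")
}

#' Per-item difference tests between two estimate vectors
#'
#' Large-sample z-test on each difference,
#' `z = (a - b)/sqrt(se_a^2 + se_b^2)`, with a two-sided normal p-value.
#' Dependence between the two estimate sets (shared samples) is ignored,
#' which is conservative when screening for absent differences.
#'
#' @param a,b `estimate_vector`s carrying standard errors.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @param alpha significance level for flags.
#' @return data.frame with label, estimates, z, p, flag.
#' @export
estimate_difference_tests <- function(a, b, correction = c("none", "bonferroni"),
                                      alpha = 0.05) {
  correction <- match.arg(correction)
  al <- .align_vectors(a, b)
  if (is.null(al$a$se) || is.null(al$b$se)) {
    stop("both vectors must carry standard errors")
  }
  z <- (al$a$est - al$b$est) / sqrt(al$a$se^2 + al$b$se^2)
  p <- 2 * pnorm(-abs(z))
  thr <- if (correction == "bonferroni") alpha / length(z) else alpha
  data.frame(label = al$a$labels, est_a = al$a$est, est_b = al$b$est,
             z = z, p = p, flag = p < thr)
}

#' Confidence-interval overlap table
#'
#' For each item, whether b's point estimate falls inside a's 95% interval
#' (`point_in_ci`), and separately whether the two intervals intersect
#' (`ci_intersect`), with summary fractions.
#'
#' @param a,b `estimate_vector`s with CIs present or derivable from SEs.
#' @return list: per-item data.frame `table`, `frac_point_in_ci`,
#'   `frac_ci_intersect`.
#' @export
ci_overlap_table <- function(a, b) {
  al <- .align_vectors(a, b)
  if (is.null(al$a$ci_lo)) stop("vector 'a' has no confidence bounds")
  pin <- al$b$est >= al$a$ci_lo & al$b$est <= al$a$ci_hi
  inter <- if (!is.null(al$b$ci_lo)) {
    al$b$ci_lo <= al$a$ci_hi & al$a$ci_lo <= al$b$ci_hi
  } else rep(NA, length(pin))
  list(table = data.frame(label = al$a$labels, point_in_ci = pin,
                          ci_intersect = inter),
       frac_point_in_ci = mean(pin),
       frac_ci_intersect = if (all(is.na(inter))) NA_real_ else mean(inter))
}
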