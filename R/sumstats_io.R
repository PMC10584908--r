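# Reading, validation, harmonization and writing of GWAS summary statistics.
# A summary-statistics table is a data.table with (at least) the columns
# SNP, A1, A2, Z, P, N; optional CHR, BP, BETA, SE, EFF_N, OUTLIER.

.VALID_ALLELES <- c("A", "C", "G", "T")
.P_FLOOR <- 1e-300  # p-values read as 0 are floored here to avoid -log10 overflow

# gzip-transparent fread: .gz files are decompressed through a base
# connection so no optional helper package is needed
.fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' Construct and validate a summary-statistics table
#'
#' Normalizes column types, uppercases alleles, recomputes Z from BETA/SE
#' where needed, floors zero p-values, and enforces the table invariants
#' (unique SNP ids, valid alleles, p in (0, 1]).
#'
#' @param x data.frame with columns `SNP`, `A1`, `A2`, `P`, `N` and either
#'   `Z` or both `BETA` and `SE`; optional `CHR`, `BP`, `EFF_N`, `OUTLIER`.
#' @return A validated `data.table` (class `sumstats`).
#' @export
as_sumstats <- function(x) {
  dt <- data.table::as.data.table(x)
  need <- c("SNP", "A1", "A2", "P", "N")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (!("Z" %in% names(dt)) && !all(c("BETA", "SE") %in% names(dt))) {
    stop("missing mandatory column(s): Z (or BETA and SE)")
  }
  dt[, `:=`(SNP = as.character(SNP),
            A1 = toupper(as.character(A1)),
            A2 = toupper(as.character(A2)))]
  for (col in intersect(c("BETA", "SE", "Z", "P", "N", "EFF_N"), names(dt))) {
    data.table::set(dt, j = col, value = suppressWarnings(as.numeric(dt[[col]])))
  }
  if (!("Z" %in% names(dt))) dt[, Z := BETA / SE]
  if ("P" %in% names(dt)) dt[!is.na(P) & P == 0, P := .P_FLOOR]
  # Z must agree with BETA/SE where both are carried; the file Z is replaced
  # and the disagreement surfaced to the caller via the load report.
  n_zfix <- 0L
  if (all(c("BETA", "SE") %in% names(dt))) {
    ok <- !is.na(dt$BETA) & !is.na(dt$SE) & dt$SE > 0 & !is.na(dt$Z)
    bad <- ok & abs(dt$Z - dt$BETA / dt$SE) > 1e-6 * pmax(1, abs(dt$Z))
    n_zfix <- sum(bad)
    if (n_zfix > 0) dt[bad, Z := BETA / SE]
  }
  keep <- !is.na(dt$Z) & !is.na(dt$P) & !is.na(dt$N) &
    dt$P > 0 & dt$P <= 1 & dt$N > 0 &
    dt$A1 %in% .VALID_ALLELES & dt$A2 %in% .VALID_ALLELES & dt$A1 != dt$A2
  n_drop <- sum(!keep)
  dt <- dt[keep]
  if (nrow(dt) == 0L) stop("empty table after filtering invalid rows")
  if (anyDuplicated(dt$SNP)) stop("duplicate SNP ids in table")
  data.table::setattr(dt, "load_report",
                      list(n_dropped = n_drop, n_z_recomputed = n_zfix))
  data.table::setattr(dt, "class", c("sumstats", class(dt)))
  dt[]
}

#' Read GWAS summary statistics
#'
#' Reads whitespace/tab-delimited summary statistics (gzip-transparent).
#' The `generic` dialect requires SNP, A1, A2, P, N and either Z or
#' BETA + SE; the `ldsc` dialect requires SNP, A1, A2, Z, N (P is then
#' derived from Z). Rows with unparseable numerics are dropped and counted
#' in the attached load report (`attr(x, "load_report")`).
#'
#' @param path file path.
#' @param dialect `"generic"` or `"ldsc"`.
#' @return A validated `sumstats` data.table.
#' @export
read_sumstats <- function(path, dialect = c("generic", "ldsc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- .fread_auto(path, header = TRUE, colClasses = list(character = 1))
  names(dt) <- toupper(names(dt))
  if (dialect == "ldsc") {
    need <- c("SNP", "A1", "A2", "Z", "N")
    miss <- setdiff(need, names(dt))
    if (length(miss)) {
      stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
    }
    zt <- suppressWarnings(as.numeric(dt$Z))
    dt[, P := 2 * pnorm(-abs(zt))]
    dt[!is.na(P) & P == 0, P := .P_FLOOR]
  }
  as_sumstats(dt)
}

#' Write GWAS summary statistics
#'
#' Writes a tab-delimited file whose round-trip read reproduces the table.
#' With `include_flags = TRUE` a final integer `OUTLIER` column (0/1) is
#' written so downstream users can filter SNPs whose down-sampled
#' coefficients deviate from the full-data estimates.
#'
#' @param table validated `sumstats` table.
#' @param path output path (`.gz` suffix compresses).
#' @param include_flags write the `OUTLIER` indicator column?
#' @export
write_sumstats <- function(table, path, include_flags = FALSE) {
  out <- data.table::copy(data.table::as.data.table(table))
  if (include_flags) {
    if (!("OUTLIER" %in% names(out))) out[, OUTLIER := 0L]
    out[, OUTLIER := as.integer(OUTLIER)]
    cols <- c(setdiff(names(out), "OUTLIER"), "OUTLIER")
    data.table::setcolorder(out, cols)
  } else if ("OUTLIER" %in% names(out)) {
    out[, OUTLIER := NULL]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Effective sample size of a meta-analyzed case-control GWAS
#'
#' For binary traits the effective sample size of cohort k is
#' 4 V_k (1 - V_k) N_k, with V_k the case proportion, summed over cohorts;
#' for continuous traits (all V missing) it is the total sample size.
#'
#' @param cohorts data.frame (or list of lists) with columns/fields `label`,
#'   `v` (case proportion in (0,1), or NA for continuous), `n` (cohort size).
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(cohorts) {
  ch <- .as_cohorts(cohorts)
  if (nrow(ch) == 0L) stop("empty cohort list")
  if (all(is.na(ch$v))) return(sum(ch$n))
  if (anyNA(ch$v)) {
    stop("mixed cohort types: v present for some cohorts and missing for others")
  }
  if (any(ch$v <= 0 | ch$v >= 1)) stop("case proportion v must lie in (0, 1)")
  sum(4 * ch$v * (1 - ch$v) * ch$n)
}

.as_cohorts <- function(cohorts) {
  if (is.data.frame(cohorts)) {
    ch <- data.table::as.data.table(cohorts)
  } else {
    ch <- data.table::rbindlist(lapply(cohorts, function(c) {
      data.table::data.table(
        label = if (is.null(c$label)) NA_character_ else as.character(c$label),
        v = if (is.null(c$v)) NA_real_ else as.numeric(c$v),
        n = as.numeric(c$n))
    }))
  }
  if (!("v" %in% names(ch))) ch[, v := NA_real_]
  if (!("label" %in% names(ch))) ch[, label := paste0("cohort", seq_len(.N))]
  if (any(is.na(ch$n) | ch$n <= 0)) stop("cohort sizes must be positive")
  ch
}

.complement <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

.is_ambiguous <- function(a1, a2) a2 == .complement(a1)  # A/T and C/G pairs

#' Align a down-sampled table to its full-data counterpart
#'
#' Intersects the two tables on SNP id and reconciles allele coding: where
#' the down-sampled A1/A2 are swapped relative to the full table, the
#' down-sampled effect sign is flipped; strand flips (allele complements)
#' are resolved; strand-ambiguous SNPs (A/T, C/G) are dropped or kept per
#' `ambiguous_policy`. Irreconcilable allele pairs are dropped and counted,
#' never silently kept.
#'
#' @param full,down validated `sumstats` tables.
#' @param ambiguous_policy `"drop"` (default; strand cannot be resolved
#'   without allele frequencies) or `"keep"`.
#' @return List with row-aligned `full` and `down` tables and a `log` of
#'   counts (shared, sign-flipped, strand-flipped, ambiguous dropped,
#'   irreconcilable dropped).
#' @export
harmonize_pair <- function(full, down, ambiguous_policy = c("drop", "keep")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  f <- data.table::as.data.table(full)
  d <- data.table::as.data.table(down)
  shared <- intersect(f$SNP, d$SNP)
  f <- f[match(shared, SNP)]
  d <- d[match(shared, SNP)]

  amb <- .is_ambiguous(f$A1, f$A2) | .is_ambiguous(d$A1, d$A2)
  n_amb <- 0L
  if (ambiguous_policy == "drop" && any(amb)) {
    n_amb <- sum(amb)
    f <- f[!amb]; d <- d[!amb]
  }

  same  <- d$A1 == f$A1 & d$A2 == f$A2
  swap  <- d$A1 == f$A2 & d$A2 == f$A1
  flip  <- d$A1 == .complement(f$A1) & d$A2 == .complement(f$A2)
  fswap <- d$A1 == .complement(f$A2) & d$A2 == .complement(f$A1)
  # ambiguous SNPs kept on request match both 'same' and 'fswap' (etc.);
  # treat them as same-strand
  fswap <- fswap & !same & !swap
  flip  <- flip & !same & !swap
  bad <- !(same | swap | flip | fswap)
  n_bad <- sum(bad)
  if (n_bad) { f <- f[!bad]; d <- d[!bad]
               same <- same[!bad]; swap <- swap[!bad]
               flip <- flip[!bad]; fswap <- fswap[!bad] }

  negate <- swap | fswap
  if (any(negate)) {
    d[negate, Z := -Z]
    if ("BETA" %in% names(d)) d[negate, BETA := -BETA]
  }
  d[, A1 := f$A1]
  d[, A2 := f$A2]

  list(full = f[], down = d[],
       log = list(n_shared = length(shared),
                  n_sign_flipped = sum(negate),
                  n_strand_flipped = sum(flip | fswap),
                  n_ambiguous_dropped = n_amb,
                  n_irreconcilable_dropped = n_bad))
}
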