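# Orchestration of the six audit steps over a configuration, producing a
# machine-readable report (JSON) and a human-readable markdown rendering
# generated from the same structure.

#' Build an audit configuration
#'
#' Collects inputs and thresholds for [run_audit()]. Steps whose inputs are
#' absent are skipped and noted; steps 2-3 can be disabled explicitly for
#' univariate audits.
#'
#' @param full,down full-data and down-sampled summary statistics
#'   (`sumstats` objects or file paths).
#' @param panel `ld_panel` or file path.
#' @param steps integer subset of 1:6 to run.
#' @param cohorts_full,cohorts_down optional cohort tables for effective
#'   sample sizes.
#' @param ld optional LD r-squared matrix (or path to a square TSV with SNP
#'   id header row/column) for lead-SNP clumping.
#' @param traits_full,traits_down optional named lists of `sumstats` (or
#'   paths) for the factor steps; `full`/`down` stand in for the factor
#'   GWAS in step 3 when the factor panels are absent.
#' @param estimates_full,estimates_down optional `estimate_vector`s (or
#'   paths) for steps 4-5.
#' @param pgs_cohort_obj optional `pgs_cohort` for step 6.
#' @param weights_full,weights_down optional PGS weight vectors for step 6.
#' @param outcomes outcome names for step 6.
#' @param p_thresh,r2_thresh,p0,alpha,ci_level,n_boot thresholds.
#' @param n_blocks jackknife blocks.
#' @param seed RNG seed for bootstraps.
#' @export
audit_config <- function(full = NULL, down = NULL, panel = NULL,
                         steps = 1:6,
                         cohorts_full = NULL, cohorts_down = NULL,
                         ld = NULL,
                         traits_full = NULL, traits_down = NULL,
                         estimates_full = NULL, estimates_down = NULL,
                         pgs_cohort_obj = NULL,
                         weights_full = NULL, weights_down = NULL,
                         outcomes = NULL,
                         p_thresh = 5e-8, r2_thresh = 0.1, p0 = 0.99,
                         alpha = 0.05, ci_level = 0.95, n_boot = 1000,
                         n_blocks = 200, seed = 1) {
  stopifnot(all(steps %in% 1:6), p_thresh > 0, p_thresh < 1,
            r2_thresh > 0, r2_thresh <= 1, p0 > 0, p0 < 1,
            alpha > 0, alpha < 1, ci_level > 0, ci_level < 1)
  structure(as.list(environment()), class = "audit_config")
}

.load_ss <- function(x) {
  if (is.null(x) || inherits(x, "sumstats")) return(x)
  if (is.character(x)) return(read_sumstats(x))
  as_sumstats(x)
}

.load_panel <- function(x) {
  if (is.null(x) || inherits(x, "ld_panel")) return(x)
  read_ld_panel(x)
}

.load_ld <- function(x) {
  if (is.null(x) || is.matrix(x)) return(x)
  dt <- data.table::fread(x, header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

.load_ev <- function(x) {
  if (is.null(x) || inherits(x, "estimate_vector")) return(x)
  read_estimate_vector(x)
}

.try_step <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Run the six-step comparability audit
#'
#' Executes the configured steps and returns a report list mirroring them:
#' key-indicator deltas and concordance checks (step 1), factor-fit
#' comparison (step 2), factor-level signal and detection power (step 3),
#' estimate-vector comparisons (steps 4-5), and PGS evaluation (step 6).
#' A full/down genetic correlation whose 95% CI excludes 1 triggers the
#' "evaluate comparability" advisory. Step failures are recorded in the
#' report without aborting later steps.
#'
#' @param cfg `audit_config`.
#' @return list of class `audit_report`.
#' @export
run_audit <- function(cfg) {
  stopifnot(inherits(cfg, "audit_config"))
  full <- .load_ss(cfg$full); down <- .load_ss(cfg$down)
  panel <- .load_panel(cfg$panel)
  rep <- list(steps_run = integer(0), advisories = character(0))

  if (1 %in% cfg$steps && !is.null(full) && !is.null(down) && !is.null(panel)) {
    rep$step1 <- .try_step({
      ki <- key_indicators_pair(full, down, panel,
                                cfg$cohorts_full, cfg$cohorts_down,
                                n_blocks = cfg$n_blocks)
      hp <- harmonize_pair(full, down)
      rg <- bivariate_ldsc(full, down, panel, n_blocks = cfg$n_blocks)
      ld <- .load_ld(cfg$ld)
      subset <- if (!is.null(ld)) {
        ld_clump(hp$full, ld, cfg$p_thresh, cfg$r2_thresh)$snp_ids
      } else {
        hp$full$SNP[hp$full$P < max(cfg$p_thresh, 1e-5)]
      }
      conc <- if (length(subset) >= 3) {
        concordance_report(hp$full, hp$down, subset,
                           p0 = cfg$p0, level = cfg$ci_level)
      } else NULL
      list(indicators = ki, rg_full_down = rg[c("rg", "se")],
           n_subset = length(subset), concordance = conc)
    })
    rep$steps_run <- c(rep$steps_run, 1L)
    if (is.null(rep$step1$error)) {
      rg <- rep$step1$rg_full_down
      if (!is.na(rg$rg) && rg$rg + qnorm(0.975) * rg$se < 1) {
        rep$advisories <- c(rep$advisories,
          "full/down genetic correlation significantly below 1: evaluate comparability (steps 2-6)")
      } else {
        rep$advisories <- c(rep$advisories,
          "full/down genetic correlation compatible with 1: versions comparable")
      }
    }
  }

  tf <- lapply(cfg$traits_full, .load_ss)
  td <- lapply(cfg$traits_down, .load_ss)
  fits <- NULL
  if (2 %in% cfg$steps && length(tf) >= 3 && length(td) >= 3 && !is.null(panel)) {
    st2 <- .try_step({
      gcf <- genetic_covariance(tf, panel, n_blocks = cfg$n_blocks)
      gcd <- genetic_covariance(td, panel, n_blocks = cfg$n_blocks)
      list(gcf = gcf, gcd = gcd,
           fa = fit_single_factor(gcf), fb = fit_single_factor(gcd))
    })
    if (is.null(st2$error)) {
      fits <- st2
      good <- function(f) !is.na(f$cfi) && f$cfi > 0.9 && f$srmr < 0.08
      keep <- c("loadings", "loading_se", "cfi", "srmr", "aic",
                "chi2_model", "df")
      rep$step2 <- list(fit_full = st2$fa[keep], fit_down = st2$fb[keep],
                        good_fit_full = good(st2$fa),
                        good_fit_down = good(st2$fb),
                        comparison = compare_factor_fits(st2$fa, st2$fb))
    } else {
      rep$step2 <- st2
    }
    rep$steps_run <- c(rep$steps_run, 2L)
  }

  if (3 %in% cfg$steps) {
    rep$step3 <- .try_step({
      pair <- if (!is.null(fits)) {
        list(full = factor_gwas(fits$gcf, fits$fa),
             down = factor_gwas(fits$gcd, fits$fb))
      } else if (!is.null(full) && !is.null(down)) {
        hp <- harmonize_pair(full, down)
        list(full = hp$full, down = hp$down)
      } else stop("step 3 needs either factor panels or a full/down pair")
      csf <- chi2_stats(pair$full); csd <- chi2_stats(pair$down)
      effn <- function(ss, fallback) {
        if ("EFF_N" %in% names(ss) && !anyNA(ss$EFF_N)) max(ss$EFF_N)
        else if ("N" %in% names(ss)) max(ss$N) else fallback
      }
      nf <- effn(pair$full, NA); nd <- effn(pair$down, NA)
      gws <- pair$down[!is.na(pair$down$P) & pair$down$P < cfg$p_thresh, ]
      med_r2 <- if (nrow(gws) && !is.na(nd)) {
        median(squared_std_coeff(gws$Z, nd))
      } else NA_real_
      list(mean_chi2_full = csf$mean_chi2, mean_chi2_down = csd$mean_chi2,
           mean_chi2_pct = (csd$mean_chi2 - csf$mean_chi2) / csf$mean_chi2 * 100,
           lambda_gc_pct = (csd$lambda_gc - csf$lambda_gc) / csf$lambda_gc * 100,
           eff_n_full = nf, eff_n_down = nd,
           median_gws_r2 = med_r2,
           power_loss_pp = if (!is.na(med_r2) && !is.na(nf)) {
             power_difference(nf, nd, med_r2, alpha = cfg$p_thresh)
           } else NA_real_,
           power_curve_full = if (!is.na(nf)) power_curve(nf) else NULL,
           power_curve_down = if (!is.na(nd)) power_curve(nd) else NULL)
    })
    rep$steps_run <- c(rep$steps_run, 3L)
  }

  ef <- .load_ev(cfg$estimates_full); ed <- .load_ev(cfg$estimates_down)
  if (any(c(4, 5) %in% cfg$steps) && !is.null(ef) && !is.null(ed)) {
    out <- .try_step({
      list(spearman = rank_correlation(ef, ed),
           differences = if (!is.null(ef$se) && !is.null(ed$se)) {
             estimate_difference_tests(ef, ed)
           } else NULL,
           ci_overlap = if (!is.null(ef$ci_lo)) ci_overlap_table(ef, ed) else NULL)
    })
    for (s in intersect(c(4, 5), cfg$steps)) {
      rep[[paste0("step", s)]] <- out
      rep$steps_run <- c(rep$steps_run, as.integer(s))
    }
  }

  if (6 %in% cfg$steps && !is.null(cfg$pgs_cohort_obj) &&
      !is.null(cfg$weights_full) && !is.null(cfg$weights_down)) {
    rep$step6 <- .try_step({
      co <- cfg$pgs_cohort_obj
      outs <- cfg$outcomes
      if (is.null(outs)) outs <- names(co$phenotypes)
      eval_set <- function(w, off) lapply(outs, function(o) {
        incremental_r2(co, o, score = score_pgs(co, w),
                       n_boot = cfg$n_boot, seed = cfg$seed + off)
      })
      ra <- eval_set(cfg$weights_down, 0L)
      rb <- eval_set(cfg$weights_full, 1L)
      list(down = lapply(ra, unclass), full = lapply(rb, unclass),
           comparison = compare_pgs(ra, rb))
    })
    rep$steps_run <- c(rep$steps_run, 6L)
  }

  skipped <- setdiff(1:6, rep$steps_run)
  if (length(skipped)) {
    rep$skipped_steps <- skipped
    if (all(c(2, 3) %in% skipped) && 1 %in% rep$steps_run) {
      rep$mode <- "univariate audit (factor steps not run)"
    }
  }
  class(rep) <- "audit_report"
  rep
}

#' Write an audit report as JSON plus a markdown rendering
#'
#' The markdown is generated from the same list as the JSON, so the two
#' never diverge.
#'
#' @param report `audit_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_audit <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, "audit.json")
  jsonlite::write_json(.json_safe(unclass(report)), jp,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  mp <- file.path(dir, "audit.md")
  writeLines(render_audit_markdown(report), mp)
  invisible(c(json = jp, markdown = mp))
}

.json_safe <- function(x) {
  if (is.list(x)) return(lapply(x, .json_safe))
  if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
  x
}

#' Render an audit report as markdown
#'
#' @param report `audit_report`.
#' @return Character vector of markdown lines.
#' @export
render_audit_markdown <- function(report) {
  fmt <- function(x, d = 4) {
    ifelse(is.na(x), "NA", formatC(x, digits = d, format = "g"))
  }
  out <- c("# Down-sampled GWAS comparability audit", "")
  for (a in report$advisories) out <- c(out, paste("- **Advisory:**", a))
  if (!is.null(report$mode)) out <- c(out, paste("- Mode:", report$mode))
  out <- c(out, "")
  s1 <- report$step1
  if (!is.null(s1)) {
    out <- c(out, "## Step 1: signal loss in the univariate pair", "")
    if (!is.null(s1$error)) {
      out <- c(out, paste("Failed:", s1$error), "")
    } else {
      d <- s1$indicators$delta
      out <- c(out,
        sprintf("- Effective N: %s -> %s (%s%%)",
                fmt(s1$indicators$full$eff_n), fmt(s1$indicators$down$eff_n),
                fmt(d$eff_n_pct, 3)),
        sprintf("- Mean chi-square: %s -> %s (%s%%)",
                fmt(s1$indicators$full$mean_chi2),
                fmt(s1$indicators$down$mean_chi2), fmt(d$mean_chi2_pct, 3)),
        sprintf("- lambda_GC change: %s%%; h2 change: %s; ratio change: %s",
                fmt(d$lambda_gc_pct, 3), fmt(d$h2_abs), fmt(d$ratio_abs)),
        sprintf("- rg(full, down) = %s (SE %s)",
                fmt(s1$rg_full_down$rg), fmt(s1$rg_full_down$se)))
      cc <- s1$concordance
      if (!is.null(cc)) {
        out <- c(out, sprintf(
          "- Concordance on %d SNPs: %s concordant (binomial p = %s), %s outliers; regression slope %s, intercept %s, adj R2 %s",
          cc$n_snps, fmt(cc$prop_concordant), fmt(cc$binom_p),
          fmt(cc$n_outliers, 0), fmt(cc$reg_slope), fmt(cc$reg_intercept),
          fmt(cc$reg_adj_r2)))
      }
      out <- c(out, "")
    }
  }
  s2 <- report$step2
  if (!is.null(s2)) {
    out <- c(out, "## Step 2: single-factor model stability", "")
    if (!is.null(s2$error)) {
      out <- c(out, paste("Failed:", s2$error), "")
    } else {
      out <- c(out,
        sprintf("- Full fit: CFI %s, SRMR %s (%s); down fit: CFI %s, SRMR %s (%s)",
                fmt(s2$fit_full$cfi), fmt(s2$fit_full$srmr),
                if (s2$good_fit_full) "good fit" else "poor fit",
                fmt(s2$fit_down$cfi), fmt(s2$fit_down$srmr),
                if (s2$good_fit_down) "good fit" else "poor fit"),
        sprintf("- Parameters significantly different after Bonferroni: %d of %d",
                sum(s2$comparison$significant), nrow(s2$comparison)), "")
    }
  }
  s3 <- report$step3
  if (!is.null(s3)) {
    out <- c(out, "## Step 3: factor-level signal and detection power", "")
    if (!is.null(s3$error)) {
      out <- c(out, paste("Failed:", s3$error), "")
    } else {
      out <- c(out,
        sprintf("- Mean chi-square: %s -> %s (%s%%); lambda_GC change %s%%",
                fmt(s3$mean_chi2_full), fmt(s3$mean_chi2_down),
                fmt(s3$mean_chi2_pct, 3), fmt(s3$lambda_gc_pct, 3)),
        sprintf("- Median GWS r2 = %s; power loss at that effect size: %s pp",
                fmt(s3$median_gws_r2), fmt(s3$power_loss_pp, 3)), "")
    }
  }
  for (s in c(4, 5)) {
    ss <- report[[paste0("step", s)]]
    if (is.null(ss)) next
    ttl <- if (s == 4) "gene-property estimate pattern" else
      "genetic correlations with other traits"
    out <- c(out, sprintf("## Step %d: %s", s, ttl), "")
    if (!is.null(ss$error)) {
      out <- c(out, paste("Failed:", ss$error), "")
    } else {
      out <- c(out, sprintf("- Spearman rank correlation: %s", fmt(ss$spearman)))
      if (!is.null(ss$differences)) {
        out <- c(out, sprintf("- Items with significant differences: %d of %d",
                              sum(ss$differences$flag), nrow(ss$differences)))
      }
      if (!is.null(ss$ci_overlap)) {
        out <- c(out, sprintf("- Fraction of points inside counterpart CI: %s",
                              fmt(ss$ci_overlap$frac_point_in_ci)))
      }
      out <- c(out, "")
    }
  }
  s6 <- report$step6
  if (!is.null(s6)) {
    out <- c(out, "## Step 6: polygenic-score explanatory power", "")
    if (!is.null(s6$error)) {
      out <- c(out, paste("Failed:", s6$error), "")
    } else {
      for (r in s6$down) {
        out <- c(out, sprintf(
          "- %s (down-sampled PGS): incremental R2 = %s [%s, %s]",
          r$outcome, fmt(r$incr_r2), fmt(r$ci_lo), fmt(r$ci_hi)))
      }
      tab <- s6$comparison$table
      out <- c(out, sprintf(
        "- Standardized coefficient differences (down vs full): %s",
        paste(sprintf("%s z=%s", tab$outcome, fmt(tab$z, 3)), collapse = "; ")),
        "")
    }
  }
  out
}
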