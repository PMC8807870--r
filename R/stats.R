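#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities (margins fixed) of
#' all tables whose probability does not exceed that of the observed table,
#' with a 1e-7 relative slack to absorb floating-point ties. The effect
#' estimate is the sample cross-product odds ratio `(a d)/(b c)`, with the
#' Haldane-Anscombe +0.5 correction applied to every cell if and only if any
#' cell is zero; the 95% CI is the Woolf log-OR normal approximation on the
#' (possibly corrected) table.
#'
#' @param a,b,c,d Cell counts: `a`/`b` the first row, `c`/`d` the second.
#' @return A `crh_enrichment` object: list with `table`, `odds_ratio`,
#'   `p_value`, `ci_low`, `ci_high`, `corrected`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_crhub("cells must be non-negative integers", "crhub_validation_error")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop_crhub("2x2 table has an empty margin; odds ratio undefined",
               "crhub_validation_error")
  }
  m <- a + c          # first-column margin
  n <- b + d
  k <- a + b          # first-row margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)

  structure(list(
    table = matrix(cells, 2, 2, byrow = TRUE,
                   dimnames = list(c("row1", "row2"), c("yes", "no"))),
    odds_ratio = unname(or),
    p_value = p,
    ci_low = unname(ci[1]),
    ci_high = unname(ci[2]),
    corrected = corrected
  ), class = "crh_enrichment")
}

#' @export
print.crh_enrichment <- function(x, ...) {
  cat(sprintf(
    "<crh_enrichment> OR = %.3g [%.3g, %.3g], two-sided Fisher p = %.3g%s\n",
    x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
    if (x$corrected) " (Haldane-corrected)" else ""
  ))
  print(x$table)
  invisible(x)
}

#' @describeIn fisher_exact_2x2 One-row tibble with cells, OR, CI, p-value.
#' @param x A `crh_enrichment`.
#' @param ... Unused.
#' @method tidy crh_enrichment
#' @export
tidy.crh_enrichment <- function(x, ...) {
  tibble(
    a = x$table[1, 1], b = x$table[1, 2],
    c = x$table[2, 1], d = x$table[2, 2],
    odds_ratio = x$odds_ratio, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, corrected = x$corrected
  )
}

#' Benjamini-Hochberg adjustment and selection
#'
#' `bh_adjust()` wraps the standard step-up false-discovery-rate adjustment;
#' `bh_select()` returns the mask of hypotheses with adjusted p at most
#' `threshold` (default 0.05, the cutoff used to call disease-associated
#' genes from gene-level association p-values).
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @param threshold Adjusted-p cutoff for selection.
#' @return Adjusted p-values (`bh_adjust`) or a logical mask (`bh_select`).
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop_crhub("p-values must lie in (0, 1]", "crhub_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' @rdname bh_adjust
#' @export
bh_select <- function(pvalues, threshold = 0.05) {
  bh_adjust(pvalues) <= threshold
}

# Half-open point-in-interval membership for SNP positions (0-based pos).
snps_in_intervals <- function(snps, intervals) {
  if (nrow(snps) == 0 || nrow(intervals) == 0) return(rep(FALSE, nrow(snps)))
  pts <- tibble(chrom = snps$chrom, start = snps$pos, end = snps$pos + 1)
  seq_len(nrow(snps)) %in% overlap_index(pts, intervals)$query_idx
}

#' SNP enrichment in an annotation at a significance threshold
#'
#' Restricts to SNPs falling in either of two disjoint annotation sets (for
#' example hub elements versus candidate-hub elements) and tests the 2x2
#' table {in A vs in B} x {p <= p_thresh vs not} with [fisher_exact_2x2()].
#' With `comparator = "genome"`, B is implicitly all SNPs outside A. SNP
#' positions are 0-based; a SNP on an interval's start base is inside, on its
#' end base outside (half-open).
#'
#' @param snps Tibble `snp_id`, `chrom`, `pos`, `pvalue`.
#' @param annot_a Interval tibble of the annotation of interest.
#' @param annot_b Interval tibble of the comparator annotation (ignored when
#'   `comparator = "genome"`).
#' @param p_thresh Association p-value threshold defining "significant".
#' @param comparator `"annotation"` (default, uses `annot_b`) or `"genome"`.
#' @return A `crh_enrichment`.
#' @export
snp_threshold_enrichment <- function(snps, annot_a, annot_b = NULL, p_thresh,
                                     comparator = c("annotation", "genome")) {
  comparator <- match.arg(comparator)
  assert_columns(snps, c("chrom", "pos", "pvalue"), "SNP table")
  in_a <- snps_in_intervals(snps, annot_a)
  in_b <- if (comparator == "genome") {
    !in_a
  } else {
    if (is.null(annot_b)) {
      stop_crhub("`annot_b` required for comparator = 'annotation'")
    }
    snps_in_intervals(snps, annot_b)
  }
  keep <- in_a | in_b
  if (!any(keep)) {
    stop_crhub("no SNP falls in either annotation set",
               "crhub_validation_error")
  }
  sig <- snps$pvalue <= p_thresh
  fisher_exact_2x2(
    a = sum(in_a & sig), b = sum(in_a & !sig),
    c = sum(!in_a & keep & sig), d = sum(!in_a & keep & !sig)
  )
}

#' Fold enrichment of significant SNPs in an annotation
#'
#' `snp_fold_enrichment()` computes
#' (significant SNPs in annotation / all significant SNPs) divided by
#' (SNPs in annotation / all SNPs); an annotation covering every SNP has
#' fold 1. `relative_fold_enrichment()` is the ratio of the fold for the
#' annotation of interest to the fold for its candidate comparator.
#'
#' @param snps Tibble `chrom`, `pos`, `pvalue`.
#' @param annotation,annot_a,annot_cand Interval tibbles.
#' @param p_thresh Significance threshold.
#' @return A positive number.
#' @export
snp_fold_enrichment <- function(snps, annotation, p_thresh) {
  assert_columns(snps, c("chrom", "pos", "pvalue"), "SNP table")
  sig <- snps$pvalue <= p_thresh
  if (!any(sig)) {
    stop_crhub("no significant SNP at this threshold",
               "crhub_validation_error")
  }
  inside <- snps_in_intervals(snps, annotation)
  if (!any(inside)) {
    stop_crhub("no SNP overlaps the annotation; fold undefined",
               "crhub_validation_error")
  }
  (sum(sig & inside) / sum(sig)) / (sum(inside) / length(inside))
}

#' @rdname snp_fold_enrichment
#' @export
relative_fold_enrichment <- function(snps, annot_a, annot_cand, p_thresh) {
  snp_fold_enrichment(snps, annot_a, p_thresh) /
    snp_fold_enrichment(snps, annot_cand, p_thresh)
}

#' Rank-based two-sample and paired tests
#'
#' Wilcoxon rank-sum (`mode = "rank_sum"`) or signed-rank
#' (`mode = "signed_rank"`, paired) test with a two-sided alternative. The
#' null is enumerated exactly for small samples (pairs `n <= 10`;
#' `min(n, m) <= 8` for rank-sum) without ties; otherwise the normal
#' approximation with tie correction (and no continuity correction) is used.
#'
#' @param x,y Numeric samples; equal length required for `signed_rank`.
#' @param mode `"rank_sum"` or `"signed_rank"`.
#' @return Tibble `statistic`, `p_value`, `method`, `exact`.
#' @export
rank_tests <- function(x, y, mode = c("rank_sum", "signed_rank")) {
  mode <- match.arg(mode)
  if (mode == "signed_rank") {
    if (length(x) != length(y)) {
      stop_crhub("signed-rank test requires paired inputs of equal length",
                 "crhub_validation_error")
    }
    if (all(x - y == 0)) {
      stop_crhub("all paired differences are zero", "crhub_validation_error")
    }
    d <- x - y
    d <- d[d != 0]
    has_ties <- anyDuplicated(abs(d)) > 0
    exact <- length(d) <= 10 && !has_ties
    ht <- suppressWarnings(stats::wilcox.test(
      x, y, paired = TRUE, exact = exact, correct = FALSE
    ))
  } else {
    has_ties <- anyDuplicated(c(x, y)) > 0
    exact <- min(length(x), length(y)) <= 8 && !has_ties
    ht <- suppressWarnings(stats::wilcox.test(
      x, y, exact = exact, correct = FALSE
    ))
  }
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = mode, exact = exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks with average ranks on ties.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  cor(x, y, method = "spearman")
}

#' Logistic regression of gene disease status on hub features
#'
#' Fits, by maximum likelihood, a logistic regression of a binary gene
#' outcome (disease-associated or not) on RNA level, the number of
#' connections to distal elements, an active-distal-element covariate and
#' monogamy status. The active-distal covariate is by default the indicator
#' of a gene's proportion of active distal elements exceeding the across-gene
#' 90th percentile (`active_distal = "indicator"`); `"raw"` uses the
#' proportion itself.
#'
#' @param genes Tibble with the outcome column and covariate columns
#'   `rna_level`, `n_connections`, `prop_active_distal`, `monogamous`.
#' @param outcome Name of the logical/0-1 outcome column (default
#'   `"scz_associated"`).
#' @param covariates Character vector of covariate columns; the special name
#'   `"prop_active_distal"` is transformed per `active_distal`.
#' @param active_distal `"indicator"` or `"raw"`.
#' @return A `crh_logit` object with [tidy()] (per-covariate ORs and Wald 95%
#'   CIs) and [glance()] methods.
#' @export
logistic_fit <- function(genes, outcome = "scz_associated",
                         covariates = c("rna_level", "n_connections",
                                        "prop_active_distal", "monogamous"),
                         active_distal = c("indicator", "raw")) {
  active_distal <- match.arg(active_distal)
  assert_columns(genes, c(outcome, covariates), "gene table")
  df <- genes[, c(outcome, covariates)]
  names(df)[1] <- ".y"
  df$.y <- as.integer(df$.y)
  # logical covariates become 0/1 so coefficient names stay the column names
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.logical),
                                        as.integer))
  bad_cov <- purrr::map_lgl(df[-1], ~ !all(is.finite(as.numeric(.x))))
  if (any(bad_cov)) {
    stop_crhub(sprintf("covariate '%s' has non-finite values",
                       names(df[-1])[bad_cov][1]),
               "crhub_validation_error")
  }
  if (length(unique(df$.y)) < 2) {
    stop_crhub("outcome has a single class", "crhub_validation_error")
  }
  if ("prop_active_distal" %in% covariates && active_distal == "indicator") {
    p90 <- quantile(df$prop_active_distal, 0.9, type = 1)
    df$prop_active_distal <- as.integer(df$prop_active_distal > p90)
    names(df)[names(df) == "prop_active_distal"] <- "active_distal_p90"
  }
  covs <- setdiff(names(df), ".y")
  const <- covs[purrr::map_lgl(df[covs], ~ length(unique(.x)) < 2)]
  if (length(const) > 0) {
    stop_crhub(sprintf("constant covariate: %s", const[1]),
               "crhub_validation_error")
  }
  rhs <- if (length(covs) == 0) "1" else paste(covs, collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- glm(fml, data = df, family = binomial(),
             control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (any(abs(coef(fit)) > 15)) {
    stop_crhub(paste(
      "apparent perfect separation (|coefficient| > 15 on the logit scale);",
      "consider a penalized fit"
    ), "crhub_separation_error")
  }
  structure(list(fit = fit, outcome = outcome, covariates = covs,
                 active_distal = active_distal, n = nrow(df)),
            class = "crh_logit")
}

#' @export
print.crh_logit <- function(x, ...) {
  cat(sprintf("<crh_logit> outcome '%s' on %d genes\n", x$outcome, x$n))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn logistic_fit Per-term estimates: log-odds, SE, Wald z and p,
#'   odds ratio with 95% CI.
#' @param x A `crh_logit`.
#' @param ... Unused.
#' @method tidy crh_logit
#' @export
tidy.crh_logit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  tibble(
    term = rownames(sm),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(sm[, "z value"]),
    p_value = unname(sm[, "Pr(>|z|)"]),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est - qnorm(0.975) * se)),
    ci_high = exp(unname(est + qnorm(0.975) * se))
  )
}

#' @describeIn logistic_fit Model-level summary.
#' @method glance crh_logit
#' @export
glance.crh_logit <- function(x, ...) {
  tibble(
    n = x$n,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    converged = x$fit$converged
  )
}

#' Intraclass correlation of expression within hubs
#'
#' One-way random-intercept variance components fitted by the ANOVA method
#' of moments with the unbalanced-group correction
#' (`n0 = (N - sum(n_i^2)/N) / (k - 1)`); a negative between-group variance
#' estimate is truncated at zero. The ICC is
#' `sigma2_between / (sigma2_between + sigma2_within)`: the share of
#' expression variance attributable to hub membership.
#'
#' @param data Data frame of per-gene values.
#' @param value Column of expression values (tidy-eval).
#' @param group Column of hub ids (tidy-eval).
#' @return A `crh_icc` object with `sigma2_between`, `sigma2_within`, `icc`,
#'   `k` (groups) and `n` (observations); has [tidy()] and [glance()].
#' @export
icc_fit <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  ni <- table(g)
  if (length(ni) < 2) {
    stop_crhub("at least two groups are required", "crhub_validation_error")
  }
  k <- length(ni)
  N <- length(v)
  gm <- tapply(v, g, mean)
  ssw <- sum((v - gm[g])^2)
  ssb <- sum(ni * (gm - mean(v))^2)
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max(0, (msb - msw) / n0)
  structure(list(
    sigma2_between = s2b, sigma2_within = msw,
    icc = s2b / (s2b + msw), k = k, n = N
  ), class = "crh_icc")
}

#' @export
print.crh_icc <- function(x, ...) {
  cat(sprintf(
    "<crh_icc> ICC = %.3f (sigma2_between = %.3g, sigma2_within = %.3g; %d groups, %d obs)\n",
    x$icc, x$sigma2_between, x$sigma2_within, x$k, x$n
  ))
  invisible(x)
}

#' @describeIn icc_fit One-row tibble of the variance components and ICC.
#' @param x A `crh_icc`.
#' @param ... Unused.
#' @method tidy crh_icc
#' @export
tidy.crh_icc <- function(x, ...) {
  tibble(sigma2_between = x$sigma2_between, sigma2_within = x$sigma2_within,
         icc = x$icc)
}

#' @describeIn icc_fit Group/observation counts.
#' @method glance crh_icc
#' @export
glance.crh_icc <- function(x, ...) tibble(k = x$k, n = x$n)

#' Hub size strata by promoter count
#'
#' Assigns each hub to the published strata: small (at most 3 promoters),
#' medium (more than 3, at most 25) or large (more than 25). Boundaries are
#' closed as printed.
#'
#' @param crh_set A `crh_set`, or a numeric vector of promoter counts.
#' @return Factor with levels `small`, `medium`, `large` (plus a `crh_id`'d
#'   tibble when given a `crh_set`).
#' @export
stratify_crhs <- function(crh_set) {
  if (inherits(crh_set, "crh_set")) {
    np <- crh_set$crhs$n_promoters
    return(tibble(crh_id = crh_set$crhs$crh_id,
                  n_promoters = np, stratum = stratify_crhs(np)))
  }
  np <- crh_set
  cut(np, breaks = c(-Inf, 3, 25, Inf), labels = c("small", "medium", "large"))
}

#' Prepare a binary SNP annotation for heritability partitioning
#'
#' Extends every interval by `extend` bp on both sides (clipped at 0), merges
#' the result into disjoint intervals, and annotates each SNP 1 if its
#' position falls inside the merged set, else 0 — the thin-annot convention
#' used by LD-score regression tooling. The regression itself is not run
#' here.
#'
#' @param intervals Interval tibble.
#' @param snps Tibble `snp_id`, `chrom`, `pos` (0-based).
#' @param extend Extension in bp each side (default 500).
#' @return List with `annot` (tibble `CHR`, `BP`, `SNP`, `ANNOT`; `BP` is the
#'   1-based position) and `merged` (the merged interval tibble).
#' @export
prepare_ldsc_annotation <- function(intervals, snps, extend = 500) {
  assert_columns(snps, c("snp_id", "chrom", "pos"), "SNP table")
  ext <- dplyr::mutate(intervals,
                       start = pmax(0, .data$start - extend),
                       end = .data$end + extend)
  merged <- merge_intervals(ext)
  inside <- snps_in_intervals(snps, merged)
  list(
    annot = tibble(CHR = snps$chrom, BP = snps$pos + 1, SNP = snps$snp_id,
                   ANNOT = as.integer(inside)),
    merged = merged
  )
}

#' @rdname prepare_ldsc_annotation
#' @param annot The `annot` tibble from `prepare_ldsc_annotation()`.
#' @param path Output TSV path.
#' @export
write_thin_annot <- function(annot, path) {
  readr::write_tsv(annot, path, progress = FALSE)
  invisible(path)
}

#' Read a SNP association table
#'
#' Reads the conventional four-column GWAS summary TSV (`SNP`, `CHR`, `BP`,
#' `P`; `BP` 1-based) into the package's 0-based internal form.
#'
#' @param path TSV path with header.
#' @return Tibble `snp_id`, `chrom`, `pos` (0-based), `pvalue`.
#' @export
read_snps <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("SNP", "CHR", "BP", "P"), "SNP file")
  tibble(snp_id = df$SNP, chrom = as.character(df$CHR),
         pos = df$BP - 1, pvalue = df$P)
}

#' @rdname read_snps
#' @param snps Tibble `snp_id`, `chrom`, `pos`, `pvalue`.
#' @export
write_snps <- function(snps, path) {
  readr::write_tsv(
    tibble(SNP = snps$snp_id, CHR = snps$chrom, BP = snps$pos + 1,
           P = snps$pvalue),
    path, progress = FALSE
  )
  invisible(path)
}
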