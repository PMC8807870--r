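test_that("Fisher exact worked examples and conventions", {
  r1 <- fisher_exact_2x2(2, 1, 1, 2)
  expect_equal(r1$odds_ratio, 4)
  expect_equal(r1$p_value, 1)
  expect_false(r1$corrected)

  r2 <- fisher_exact_2x2(5, 0, 0, 5)
  expect_equal(r2$p_value, 2 / 252)
  expect_equal(r2$odds_ratio, 121)   # Haldane-corrected (5.5*5.5)/(0.5*0.5)
  expect_true(r2$corrected)

  r3 <- fisher_exact_2x2(3, 3, 3, 3)
  expect_equal(r3$odds_ratio, 1)
  expect_equal(r3$p_value, 1)

  # CI contains the estimate when all cells positive
  expect_lte(r1$ci_low, r1$odds_ratio)
  expect_gte(r1$ci_high, r1$odds_ratio)

  expect_error(fisher_exact_2x2(0, 0, 3, 4), class = "crhub_validation_error")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), class = "crhub_validation_error")

  td <- tidy(r2)
  expect_equal(td$a, 5)
  expect_true(td$corrected)
})

test_that("Fisher p-values agree with stats::fisher.test on random tables", {
  withr::local_seed(10)
  for (i in 1:200) {
    cells <- rpois(4, 6) + c(1, 0, 0, 1)
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
        (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) next
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    want <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(got$p_value, want$p.value, tolerance = 1e-6)
  }
})

test_that("BH adjustment matches the naive step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), class = "crhub_validation_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "crhub_validation_error")

  withr::local_seed(77)
  for (i in 1:200) {
    p <- runif(sample(2:40, 1))^2
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation invariance up to reordering
  p <- runif(25)
  ord <- sample(25)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
  expect_true(all(bh_adjust(p) >= p))

  expect_equal(bh_select(c(1e-6, 0.5, 0.9)), c(TRUE, FALSE, FALSE))
})

test_that("SNP threshold enrichment respects half-open membership", {
  annot_a <- tibble::tibble(chrom = "chr1", start = 100, end = 200, id = "A")
  annot_b <- tibble::tibble(chrom = "chr1", start = 300, end = 400, id = "B")
  snps <- tibble::tibble(
    snp_id = paste0("rs", 1:6), chrom = "chr1",
    pos = c(100, 199, 200, 300, 350, 500),   # 200 is outside [100, 200)
    pvalue = c(0.001, 0.5, 0.5, 0.001, 0.6, 0.5)
  )
  res <- snp_threshold_enrichment(snps, annot_a, annot_b, p_thresh = 0.01)
  expect_equal(unname(res$table[1, ]), c(1, 1))   # two SNPs in A, one sig
  expect_equal(unname(res$table[2, ]), c(1, 1))
  expect_equal(res$odds_ratio, 1)

  # genome comparator uses all SNPs outside A
  res2 <- snp_threshold_enrichment(snps, annot_a, p_thresh = 0.01,
                                   comparator = "genome")
  expect_equal(sum(res2$table), 6)

  expect_error(
    snp_threshold_enrichment(dplyr::mutate(snps, pos = pos + 1e6),
                             annot_a, annot_b, p_thresh = 0.01),
    class = "crhub_validation_error"
  )
})

test_that("fold enrichment arithmetic, identity and duplication invariance", {
  # 10/100 significant in annotation, 50/1000 overall -> fold 2
  snps <- tibble::tibble(
    snp_id = paste0("rs", 1:1000), chrom = "chr1", pos = seq_len(1000) * 10,
    pvalue = 1
  )
  snps$pos[1:100] <- seq_len(100)        # inside [0, 101)
  snps$pvalue[1:10] <- 1e-4              # significant inside
  snps$pvalue[101:140] <- 1e-4           # significant outside
  annot <- tibble::tibble(chrom = "chr1", start = 0, end = 101, id = "A")
  expect_equal(snp_fold_enrichment(snps, annot, 0.01), 2)

  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 1e5, id = "W")
  expect_equal(snp_fold_enrichment(snps, whole, 0.01), 1)

  dup <- dplyr::bind_rows(snps, snps)
  expect_equal(snp_fold_enrichment(dup, annot, 0.01),
               snp_fold_enrichment(snps, annot, 0.01))

  expect_equal(relative_fold_enrichment(snps, annot, whole, 0.01), 2)
  expect_error(snp_fold_enrichment(dplyr::mutate(snps, pvalue = 1),
                                   annot, 0.01),
               class = "crhub_validation_error")
})

test_that("rank tests: exactness thresholds, ties and worked cases", {
  expect_equal(spearman_rho(1:10, exp(1:10)), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)

  x <- c(1, 2, 3, 4, 5)
  same <- rank_tests(x, x, mode = "rank_sum")
  expect_equal(same$p_value, 1)
  expect_false(same$exact)     # ties force the normal approximation

  # exact enumeration equals the full permutation oracle for n = m = 5
  withr::local_seed(15)
  a <- runif(5)
  b <- runif(5) + 0.3
  got <- rank_tests(a, b, mode = "rank_sum")
  expect_true(got$exact)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[1:5]) - 5 * 6 / 2
  perms <- utils::combn(10, 5)
  stats_null <- apply(perms, 2, function(ix) sum(r[ix]) - 15)
  mu <- 5 * 5 / 2
  p_oracle <- mean(abs(stats_null - mu) >= abs(obs - mu) - 1e-9)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)

  d1 <- c(1.2, 2.5, 3.1, 0.4)
  d2 <- c(0.8, 2.0, 3.0, 0.1)
  sr <- rank_tests(d1, d2, mode = "signed_rank")
  expect_true(sr$exact)
  expect_error(rank_tests(d1, d1, mode = "signed_rank"),
               class = "crhub_validation_error")
  expect_error(rank_tests(d1, d2[1:3], mode = "signed_rank"),
               class = "crhub_validation_error")
})

test_that("logistic fit: closed-form intercept, invariances, guards", {
  genes <- tibble::tibble(scz = rep(c(TRUE, FALSE), c(25, 75)))
  fit <- logistic_fit(genes, outcome = "scz", covariates = character(0))
  expect_equal(tidy(fit)$estimate, log(1 / 3), tolerance = 1e-8)

  withr::local_seed(21)
  n <- 400
  df <- tibble::tibble(
    rna_level = rnorm(n),
    n_connections = rpois(n, 3),
    prop_active_distal = runif(n),
    monogamous = runif(n) < 0.3
  )
  lin <- -0.5 + 0.6 * df$rna_level - 0.2 * df$n_connections +
    0.8 * (df$prop_active_distal > quantile(df$prop_active_distal, 0.9)) +
    0.5 * df$monogamous
  df$scz_associated <- runif(n) < plogis(lin)
  fit1 <- logistic_fit(df)
  td1 <- tidy(fit1)
  expect_equal(nrow(td1), 5)
  expect_true(all(c("active_distal_p90") %in% td1$term))

  # duplicated data: identical estimates, narrower CIs
  fit2 <- logistic_fit(dplyr::bind_rows(df, df))
  td2 <- tidy(fit2)
  expect_equal(td2$estimate, td1$estimate, tolerance = 1e-6)
  expect_true(all(td2$ci_high - td2$ci_low <
                    td1$ci_high - td1$ci_low))

  # raw-proportion variant keeps the original covariate name
  fit3 <- logistic_fit(df, active_distal = "raw")
  expect_true("prop_active_distal" %in% tidy(fit3)$term)

  # separation and constant-covariate guards
  sep <- tibble::tibble(
    x = c(rep(0, 20), rep(1, 20)),
    scz_associated = c(rep(FALSE, 20), rep(TRUE, 20))
  )
  expect_error(logistic_fit(sep, covariates = "x"),
               class = "crhub_separation_error")
  expect_error(
    logistic_fit(dplyr::mutate(df, rna_level = 1)),
    class = "crhub_validation_error"
  )
  expect_error(
    logistic_fit(dplyr::mutate(df, scz_associated = TRUE)),
    class = "crhub_validation_error"
  )
  expect_true(glance(fit1)$converged)
})

test_that("ICC method-of-moments estimator and strata boundaries", {
  # equal group means with residual noise -> ICC 0
  df0 <- tibble::tibble(
    g = rep(letters[1:10], each = 8),
    y = rep(5, 80) + rep(c(-1, 1), 40)
  )
  expect_equal(icc_fit(df0, y, g)$icc, 0)

  expect_error(icc_fit(df0[df0$g == "a", ], y, g),
               class = "crhub_validation_error")

  # cross-check against lme4 on an unbalanced simulated set
  withr::local_seed(9)
  k <- 60
  ni <- sample(3:12, k, replace = TRUE)
  g <- rep(seq_len(k), ni)
  y <- rnorm(k, 0, sqrt(1))[g] + rnorm(length(g), 0, sqrt(3))
  df <- tibble::tibble(g = g, y = y)
  got <- icc_fit(df, y, g)
  lf <- lme4::lmer(y ~ 1 + (1 | g), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  icc_lmm <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(got$icc, icc_lmm, tolerance = 0.05)

  st <- stratify_crhs(c(1, 3, 4, 25, 26))
  expect_equal(as.character(st),
               c("small", "small", "medium", "medium", "large"))
})

test_that("heritability annotation preparation extends, merges, annotates", {
  iv <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000, id = "e1")
  snps <- tibble::tibble(
    snp_id = c("near", "far", "inside"), chrom = "chr1",
    pos = c(600, 499, 1500)
  )
  prep <- prepare_ldsc_annotation(iv, snps, extend = 500)
  ann <- stats::setNames(prep$annot$ANNOT, prep$annot$SNP)
  expect_equal(ann[["near"]], 1L)     # 400 bp upstream after extension
  expect_equal(ann[["far"]], 0L)      # 501 bp upstream stays out
  expect_equal(ann[["inside"]], 1L)
  expect_equal(prep$annot$BP, c(601, 500, 1501))   # 1-based output

  # merged bp >= raw bp, merging absorbed the extension overlaps
  two <- tibble::tibble(chrom = "chr1", start = c(0, 1200), end = c(1000, 1400))
  m <- prepare_ldsc_annotation(two, snps, extend = 500)$merged
  expect_gte(sum(m$end - m$start), sum(two$end - two$start))
  expect_equal(nrow(m), 1)   # 500-bp extensions bridge the 200-bp gap

  f <- withr::local_tempfile()
  write_thin_annot(prep$annot, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), 3)
})

test_that("SNP IO round-trips through the 1-based file convention", {
  snps <- tibble::tibble(snp_id = c("rs1", "rs2"), chrom = c("chr1", "chr2"),
                         pos = c(0, 999), pvalue = c(0.5, 1e-6))
  f <- withr::local_tempfile()
  write_snps(snps, f)
  back <- read_snps(f)
  expect_equal(back, snps)
})
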