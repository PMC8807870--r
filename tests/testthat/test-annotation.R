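test_that("compartment category uses the farthest elements", {
  comp <- tibble::tibble(
    chrom = "chr1", start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
    label = c("A", "B", "A")
  )
  expect_equal(
    compartment_category(mk_span_crh(c(100, 200), c(2100, 2200)), comp)$category,
    "AA"
  )
  expect_equal(
    compartment_category(mk_span_crh(c(100, 200), c(1100, 1200)), comp)$category,
    "AB"
  )
  expect_equal(
    compartment_category(mk_span_crh(c(1100, 1200), c(1500, 1600)), comp)$category,
    "BB"
  )
  # extreme element outside all calls -> unassigned
  expect_equal(
    compartment_category(mk_span_crh(c(100, 200), c(5000, 5100)), comp)$category,
    "unassigned"
  )
  # maximal overlap decides: element mostly in B
  expect_equal(
    compartment_category(mk_span_crh(c(900, 1400), c(1500, 1600)), comp)$category,
    "BB"
  )
  expect_error(
    compartment_category(mk_span_crh(c(0, 10), c(20, 30)),
                         dplyr::mutate(comp, label = "X")),
    class = "crhub_validation_error"
  )
})

test_that("compartment category is invariant to node order", {
  pairs <- tibble::tibble(
    gene_id = c("P1", "P1"), element_id = c("E1", "E2"), chrom = "chr1",
    element_start = c(2500, 400), element_end = c(2600, 500),
    tss = 1500, abc_score = 0.5, functional = TRUE
  )
  comp <- tibble::tibble(chrom = "chr1", start = c(0, 2000),
                         end = c(1000, 3000), label = c("A", "B"))
  a <- compartment_category(build_crhs(pairs), comp)
  b <- compartment_category(build_crhs(pairs[2:1, ]), comp)
  expect_equal(a$category, b$category)
  expect_equal(a$category, "AB")
})

test_that("TAD overlap counts and histogram satisfy the pair-count identity", {
  tads <- tibble::tibble(chrom = "chr1", start = c(0, 1000),
                         end = c(1000, 2000), id = c("T1", "T2"))
  inside <- mk_span_crh(c(100, 200), c(500, 600))
  expect_equal(tad_overlap_count(inside, tads)$n_tads, 1L)
  crossing <- mk_span_crh(c(800, 900), c(1100, 1200))
  expect_equal(tad_overlap_count(crossing, tads)$n_tads, 2L)

  overlapping_tads <- tibble::tibble(chrom = "chr1", start = c(0, 500),
                                     end = c(1000, 1500))
  expect_error(tad_overlap_count(inside, overlapping_tads),
               class = "crhub_validation_error")

  # sum_k k * (#TADs with k hubs) = total (CRH, TAD) overlap pairs
  withr::local_seed(31)
  sim <- simulate_crh_dataset(small_fixture_config(seed = 4))
  pairs <- suppressWarnings(compute_abc_scores(
    sim$landscape$elements, sim$landscape$promoters, sim$contacts
  ))
  crhs <- build_crhs(functional_pairs(threshold_pairs(pairs, 0.012)),
                     promoters = sim$landscape$promoters)
  tads2 <- sim$landscape$annotations$tads
  per_crh <- tad_overlap_count(crhs, tads2)
  hist <- tads_with_k_crhs(crhs, tads2)
  expect_equal(sum(hist$k * hist$n_tads), sum(per_crh$n_tads))
  # gapless tiling: every hub overlaps at least one TAD
  expect_true(all(per_crh$n_tads >= 1))
})

test_that("region-set enrichment builds the right table and handles zeros", {
  iv <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e,
                                      id = paste0("x", seq_along(s)))
  regions <- iv(c(0, 1000), c(500, 1500))
  all_in <- region_set_enrichment(iv(c(10, 1010), c(20, 1020)),
                                  iv(c(5000, 6000), c(5100, 6100)),
                                  regions)
  expect_true(all_in$corrected)
  expect_gt(all_in$odds_ratio, 1)
  # identical overlap rates -> OR = 1
  same <- region_set_enrichment(iv(c(10, 5000), c(20, 5100)),
                                iv(c(30, 6000), c(40, 6100)), regions)
  expect_equal(same$odds_ratio, 1)
})

test_that("planted overlap excess is detected in most seeded replicates", {
  detected <- vapply(1:50, function(seed) {
    set.seed(seed)
    n <- 150
    regions <- tibble::tibble(chrom = "chr1", start = seq(0, by = 2000,
                                                          length.out = 50),
                              end = seq(1000, by = 2000, length.out = 50))
    place <- function(n, p_in) {
      hit <- runif(n) < p_in
      start <- ifelse(hit,
                      sample(regions$start, n, replace = TRUE) + 100,
                      sample(regions$end, n, replace = TRUE) + 100)
      tibble::tibble(chrom = "chr1", start = start, end = start + 200,
                     id = paste0("e", seq_len(n)))
    }
    res <- region_set_enrichment(place(n, 0.6), place(n, 0.3), regions)
    res$odds_ratio > 1 && res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("state profiles count multi-overlaps per broad group", {
  states <- tibble::tibble(
    chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
    label = c("1_TssA", "18_Quies")
  )
  quies_only <- tibble::tibble(chrom = "chr1", start = 1200, end = 1300,
                               id = "q")
  prof <- state_profile(quies_only, states)
  expect_equal(prof$group_proportions$group, "InactiveRepressor")
  expect_equal(prof$group_proportions$prop, 1)

  straddle <- tibble::tibble(chrom = "chr1", start = 900, end = 1100,
                             id = "s")
  prof2 <- state_profile(straddle, states)
  expect_setequal(prof2$group_proportions$group,
                  c("Active", "InactiveRepressor"))
  expect_equal(prof2$group_proportions$prop, c(1, 1))

  expect_error(
    state_profile(straddle, dplyr::mutate(states, label = "19_Bogus")),
    class = "crhub_validation_error"
  )

  # proportions match a bitmask oracle on a toy genome
  withr::local_seed(8)
  els <- tibble::as_tibble(random_intervals(40, chroms = "chr1",
                                            max_pos = 1900))
  prof3 <- state_profile(els, states)
  for (st in prof3$state_proportions$state) {
    block <- states[states$label == st, ]
    manual <- mean(vapply(seq_len(nrow(els)), function(i) {
      min(els$end[i], block$end) - max(els$start[i], block$start) >= 1
    }, logical(1)))
    expect_equal(
      prof3$state_proportions$prop[prof3$state_proportions$state == st],
      manual
    )
  }

  # the full 18-state grouping is complete and disjoint
  g <- chromatin_state_grouping()
  expect_equal(nrow(g), 18)
  expect_equal(anyDuplicated(g$state), 0)
  expect_setequal(unique(g$group),
                  c("Active", "WeaklyActive", "InactiveRepressor"))
})

test_that("state combinations take the minimal covering prefix", {
  # coverages {A:50, B:30, C:20} at 0.8 -> {A, B}
  states <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 50, 80), end = c(50, 80, 100),
    label = c("1_TssA", "5_Tx", "18_Quies")
  )
  crh <- mk_span_crh(c(0, 40), c(40, 100))  # covers all 100 bp
  comb <- state_combination(crh, states, coverage_fraction = 0.8)
  expect_equal(comb$combination, "1_TssA+5_Tx")
  expect_equal(comb$n_states, 2L)

  single <- state_combination(
    crh, tibble::tibble(chrom = "chr1", start = 0, end = 100,
                        label = "9_EnhA1"),
    coverage_fraction = 0.3
  )
  expect_equal(single$combination, "9_EnhA1")

  # zero coverage -> flagged empty combination
  off <- state_combination(
    crh, tibble::tibble(chrom = "chr2", start = 0, end = 100,
                        label = "1_TssA")
  )
  expect_true(off$zero_coverage)
  expect_equal(off$combination, "")

  expect_error(state_combination(crh, states, coverage_fraction = 0),
               class = "crhub_validation_error")
})

test_that("minimal-prefix size equals the subset-enumeration oracle", {
  withr::local_seed(44)
  vocab <- chromatin_state_grouping()$state
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    cov <- sort(sample.int(100, k), decreasing = TRUE)
    labels <- sample(vocab, k)
    # lay the states consecutively over one hub span
    edges <- cumsum(c(0, cov))
    states <- tibble::tibble(chrom = "chr1", start = edges[-length(edges)],
                             end = edges[-1], label = labels)
    crh <- mk_span_crh(c(0, 1), c(1, sum(cov)))
    comb <- state_combination(crh, states, coverage_fraction = 0.8)
    expect_equal(comb$n_states, oracle_min_subset(cov, 0.8))
    # census: class sizes sum to the number of covered hubs
    cen <- combination_census(comb)
    expect_equal(sum(cen$by_combination$n_crhs), 1)
  }
})
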