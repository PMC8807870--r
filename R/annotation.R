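#' Grouping of the 18 chromatin states into broad activity categories
#'
#' The Roadmap 18-state ChromHMM vocabulary collapsed into three broad
#' categories: Active (TSS, flanking, transcribed, genic and active
#' enhancers, ZNF/repeats), WeaklyActive (weak transcription, weak and
#' bivalent enhancers/TSS) and InactiveRepressor (heterochromatin, Polycomb
#' repressed, quiescent).
#'
#' @return Tibble `state`, `group`.
#' @export
chromatin_state_grouping <- function() {
  tibble(
    state = c(
      "1_TssA", "2_TssFlnk", "3_TssFlnkU", "4_TssFlnkD", "5_Tx",
      "7_EnhG1", "8_EnhG2", "9_EnhA1", "10_EnhA2", "12_ZNF/Rpts",
      "6_TxWk", "11_EnhWk", "14_TssBiv", "15_EnhBiv",
      "13_Het", "16_ReprPC", "17_ReprPCWk", "18_Quies"
    ),
    group = c(
      rep("Active", 10),
      rep("WeaklyActive", 4),
      rep("InactiveRepressor", 4)
    )
  )
}

#' Compartment category of each hub
#'
#' A hub is assigned to a compartment pair via its two farthest elements: the
#' node with minimal start and the node with maximal end. Each is assigned to
#' the A/B compartment block it overlaps most (ties toward A); the hub
#' category is `AA`, `BB`, `AB` (labels differ) or `unassigned` when either
#' extreme element overlaps no compartment call.
#'
#' @param crh_set A `crh_set`.
#' @param compartments Interval tibble with a `label` column in `{A, B}`.
#' @return Tibble `crh_id`, `left_label`, `right_label`, `category`.
#' @export
compartment_category <- function(crh_set, compartments) {
  stopifnot(inherits(crh_set, "crh_set"))
  assert_columns(compartments, c("chrom", "start", "end", "label"),
                 "compartments")
  if (!all(compartments$label %in% c("A", "B"))) {
    stop_crhub("compartment labels must be 'A' or 'B'",
               "crhub_validation_error")
  }
  assign_one <- function(node_rows) {
    # maximal-overlap compartment; ties toward A; NA if no overlap
    idx <- overlap_index(node_rows, compartments)
    if (nrow(idx) == 0) return(rep(NA_character_, nrow(node_rows)))
    lab <- rep(NA_character_, nrow(node_rows))
    best <- idx |>
      dplyr::mutate(label = compartments$label[.data$subject_idx]) |>
      dplyr::group_by(.data$query_idx) |>
      dplyr::arrange(dplyr::desc(.data$overlap_bp), .data$label,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    lab[best$query_idx] <- best$label
    lab
  }
  extremes <- crh_set$nodes |>
    dplyr::group_by(.data$crh_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      left_start = .data$start[which.min(.data$start)],
      left_end = .data$end[which.min(.data$start)],
      right_start = .data$start[which.max(.data$end)],
      right_end = .data$end[which.max(.data$end)],
      .groups = "drop"
    )
  left_lab <- assign_one(tibble(chrom = extremes$chrom,
                                start = extremes$left_start,
                                end = extremes$left_end))
  right_lab <- assign_one(tibble(chrom = extremes$chrom,
                                 start = extremes$right_start,
                                 end = extremes$right_end))
  category <- dplyr::case_when(
    is.na(left_lab) | is.na(right_lab) ~ "unassigned",
    left_lab == right_lab & left_lab == "A" ~ "AA",
    left_lab == right_lab ~ "BB",
    TRUE ~ "AB"
  )
  tibble(crh_id = extremes$crh_id, left_label = left_lab,
         right_label = right_lab, category = category)
}

#' Distribution of hub compartment categories
#'
#' Reports the category distribution both over all hubs (unconditional) and
#' restricted to hubs assigned to compartments (conditional).
#'
#' @param categories Output of [compartment_category()].
#' @return Tibble `category`, `n`, `prop_all`, `prop_assigned`.
#' @export
compartment_distribution <- function(categories) {
  n_all <- nrow(categories)
  n_assigned <- sum(categories$category != "unassigned")
  categories |>
    dplyr::count(.data$category) |>
    dplyr::mutate(
      prop_all = .data$n / n_all,
      prop_assigned = ifelse(.data$category == "unassigned", NA_real_,
                             .data$n / n_assigned)
    )
}

check_disjoint <- function(x, what) {
  self <- overlap_index(x, x)
  if (any(self$query_idx != self$subject_idx)) {
    stop_crhub(sprintf("%s intervals overlap each other", what),
               "crhub_validation_error")
  }
  invisible(x)
}

#' TADs overlapped by each hub, and hubs per TAD
#'
#' Overlap geometry uses the hub span (leftmost node start to rightmost node
#' end). `tad_overlap_count()` counts distinct TADs overlapping each hub
#' span; `tads_with_k_crhs()` histograms, over TADs, the number of hub spans
#' overlapping each.
#'
#' @param crh_set A `crh_set`.
#' @param tads Disjoint interval tibble of TAD calls (any caller).
#' @return For `tad_overlap_count()`, tibble `crh_id`, `n_tads`; for
#'   `tads_with_k_crhs()`, tibble `k`, `n_tads` (including `k = 0`).
#' @export
tad_overlap_count <- function(crh_set, tads) {
  stopifnot(inherits(crh_set, "crh_set"))
  check_disjoint(tads, "TAD")
  spans <- crh_spans(crh_set)
  hits <- overlap_index(spans, tads)
  counts <- table(factor(hits$query_idx, levels = seq_len(nrow(spans))))
  tibble(crh_id = spans$id, n_tads = as.integer(counts))
}

#' @rdname tad_overlap_count
#' @export
tads_with_k_crhs <- function(crh_set, tads) {
  stopifnot(inherits(crh_set, "crh_set"))
  check_disjoint(tads, "TAD")
  spans <- crh_spans(crh_set)
  hits <- overlap_index(spans, tads)
  per_tad <- table(factor(hits$subject_idx, levels = seq_len(nrow(tads))))
  tibble(k = as.integer(per_tad)) |>
    dplyr::count(.data$k, name = "n_tads") |>
    dplyr::arrange(.data$k)
}

crh_spans <- function(crh_set) {
  tibble(
    chrom = crh_set$crhs$chrom,
    start = crh_set$crhs$span_start,
    end = crh_set$crhs$span_end,
    id = crh_set$crhs$crh_id
  )
}

#' Enrichment of hub elements in a region set
#'
#' Tests whether hub elements overlap a region set (e.g., FIREs, ENCODE
#' candidate elements, active chromatin states) more often than candidate
#' elements, via a two-sided Fisher's exact test on the 2x2 table
#' {in hub vs candidate} x {overlaps region vs not}. Overlap means at least
#' 1 bp.
#'
#' @param in_elements Interval tibble of hub elements.
#' @param candidate_elements Interval tibble of candidate elements (disjoint
#'   from `in_elements`).
#' @param regions Interval tibble of the region set.
#' @return A `crh_enrichment` object (see [fisher_exact_2x2()]).
#' @export
region_set_enrichment <- function(in_elements, candidate_elements, regions) {
  olap <- function(x) {
    if (nrow(x) == 0) return(logical(0))
    seq_len(nrow(x)) %in% overlap_index(x, regions)$query_idx
  }
  in_hit <- olap(in_elements)
  cand_hit <- olap(candidate_elements)
  fisher_exact_2x2(
    a = sum(in_hit), b = sum(!in_hit),
    c = sum(cand_hit), d = sum(!cand_hit)
  )
}

#' Chromatin-state profile of hub elements
#'
#' For each element, the chromatin states it overlaps by at least 1 bp, and
#' the proportion of elements overlapping each state and each broad group.
#' Elements can count toward several states, so proportions need not sum
#' to 1.
#'
#' @param elements Interval tibble (with `id`).
#' @param states Interval tibble with a `label` column from the 18-state
#'   vocabulary.
#' @param grouping State-to-group map, default [chromatin_state_grouping()].
#' @return List with `per_element` (element x state hits),
#'   `state_proportions` and `group_proportions` tibbles.
#' @export
state_profile <- function(elements, states,
                          grouping = chromatin_state_grouping()) {
  assert_columns(states, c("chrom", "start", "end", "label"), "states")
  unknown <- setdiff(unique(states$label), grouping$state)
  if (length(unknown) > 0) {
    stop_crhub(sprintf("unknown chromatin state label '%s'", unknown[1]),
               "crhub_validation_error")
  }
  if (!"id" %in% names(elements)) {
    elements$id <- paste0(elements$chrom, ":", elements$start, "-", elements$end)
  }
  n_el <- nrow(elements)
  idx <- overlap_index(elements, states)
  per_element <- tibble(
    id = elements$id[idx$query_idx],
    state = states$label[idx$subject_idx],
    overlap_bp = idx$overlap_bp
  ) |>
    dplyr::left_join(grouping, by = "state")
  state_proportions <- per_element |>
    dplyr::distinct(.data$id, .data$state) |>
    dplyr::count(.data$state) |>
    dplyr::mutate(prop = .data$n / n_el)
  group_proportions <- per_element |>
    dplyr::distinct(.data$id, .data$group) |>
    dplyr::count(.data$group) |>
    dplyr::mutate(prop = .data$n / n_el)
  list(per_element = per_element,
       state_proportions = state_proportions,
       group_proportions = group_proportions)
}

#' Dominant chromatin-state combination per hub
#'
#' Sums, over a hub's elements, the bp of overlap with each chromatin state;
#' sorts states by coverage (descending; ties broken by state name) and
#' returns the minimal prefix whose coverage reaches `coverage_fraction` of
#' the hub's total state coverage. Hubs with zero state coverage get an empty
#' combination and are flagged.
#'
#' @param crh_set A `crh_set`.
#' @param states Interval tibble with `label`.
#' @param coverage_fraction Fraction of total coverage the combination must
#'   reach, in (0, 1]; default 0.8.
#' @return Tibble `crh_id`, `combination` (states collapsed with `+`),
#'   `n_states`, `coverage_achieved`, `total_bp`, `zero_coverage`.
#' @export
state_combination <- function(crh_set, states, coverage_fraction = 0.8) {
  stopifnot(inherits(crh_set, "crh_set"))
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    stop_crhub("`coverage_fraction` must be in (0, 1]",
               "crhub_validation_error")
  }
  nodes <- crh_set$nodes
  idx <- overlap_index(
    tibble(chrom = nodes$chrom, start = nodes$start, end = nodes$end),
    states
  )
  cov <- tibble(
    crh_id = nodes$crh_id[idx$query_idx],
    state = states$label[idx$subject_idx],
    bp = idx$overlap_bp
  ) |>
    dplyr::group_by(.data$crh_id, .data$state) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop")
  if (nrow(cov) == 0) {
    return(tibble(
      crh_id = crh_set$crhs$crh_id, total_bp = 0, n_states = 0L,
      combination = "", coverage_achieved = NA_real_, zero_coverage = TRUE
    ))
  }
  per_crh <- cov |>
    dplyr::group_by(.data$crh_id) |>
    dplyr::arrange(dplyr::desc(.data$bp), .data$state, .by_group = TRUE) |>
    dplyr::summarise(
      total_bp = sum(.data$bp),
      n_states = min(which(cumsum(.data$bp) >=
                             coverage_fraction * sum(.data$bp))),
      combination = paste(.data$state[seq_len(n_states)], collapse = "+"),
      coverage_achieved = sum(.data$bp[seq_len(n_states)]) / sum(.data$bp),
      .groups = "drop"
    )
  out <- tibble(crh_id = crh_set$crhs$crh_id) |>
    dplyr::left_join(per_crh, by = "crh_id") |>
    dplyr::mutate(
      zero_coverage = is.na(.data$total_bp),
      combination = ifelse(.data$zero_coverage, "", .data$combination),
      n_states = ifelse(.data$zero_coverage, 0L, .data$n_states),
      total_bp = ifelse(.data$zero_coverage, 0, .data$total_bp)
    )
  out
}

#' Census of unique state combinations across hubs
#'
#' @param combinations Output of [state_combination()].
#' @return List with `by_combination` (tibble `combination`, `n_crhs`) and
#'   scalars `n_unique` (combinations occurring exactly once) and
#'   `prop_unique` (fraction of hubs with non-zero coverage carrying a
#'   combination seen only once).
#' @export
combination_census <- function(combinations) {
  nz <- dplyr::filter(combinations, !.data$zero_coverage)
  by_comb <- dplyr::count(nz, .data$combination, name = "n_crhs")
  n_unique <- sum(by_comb$n_crhs == 1)
  list(
    by_combination = dplyr::arrange(by_comb, dplyr::desc(.data$n_crhs)),
    n_unique = n_unique,
    prop_unique = if (nrow(nz)) n_unique / nrow(nz) else NA_real_
  )
}
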