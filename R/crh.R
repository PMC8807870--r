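#' Build cis-regulatory hubs from functional pairs
#'
#' A cis-regulatory hub (CRH) is a connected component of the bipartite graph
#' whose two node classes are gene promoters and distal elements and whose
#' edges are the functional ABC pairs. Components are computed with igraph
#' and labelled deterministically by genomic position of their leftmost node,
#' so the result is invariant to input pair order.
#'
#' @param pairs Functional pair tibble (rows of [compute_abc_scores()];
#'   if a `functional` column is present only functional rows are used).
#' @param promoters Optional promoter tibble ([make_promoters()]) supplying
#'   promoter window coordinates; when absent the TSS carried by `pairs` is
#'   used as a point interval. When supplied, pairs referencing unknown genes
#'   raise an error.
#' @param elements Optional element tibble; when supplied, pairs referencing
#'   unknown elements raise an error.
#' @return An object of class `crh_set`: a list with tibbles `crhs` (one row
#'   per hub with derived metrics), `nodes` (one row per node with class,
#'   degree and role) and `edges` (one row per functional pair with its
#'   `crh_id`).
#' @export
build_crhs <- function(pairs, promoters = NULL, elements = NULL) {
  if ("functional" %in% names(pairs)) pairs <- dplyr::filter(pairs, .data$functional)
  assert_columns(pairs, c("gene_id", "element_id"), "pair table")
  if (!is.null(promoters)) {
    unknown <- setdiff(pairs$gene_id, promoters$gene_id)
    if (length(unknown) > 0) {
      stop_crhub(sprintf("pair references unknown promoter '%s'", unknown[1]),
                 "crhub_contract_error")
    }
  }
  if (!is.null(elements)) {
    unknown <- setdiff(pairs$element_id, elements$element_id)
    if (length(unknown) > 0) {
      stop_crhub(sprintf("pair references unknown element '%s'", unknown[1]),
                 "crhub_contract_error")
    }
  }
  if (nrow(pairs) == 0) {
    return(empty_crh_set())
  }

  # Distinct namespaces for the two node classes.
  pv <- paste0("P|", pairs$gene_id)
  ev <- paste0("E|", pairs$element_id)
  g <- igraph::graph_from_edgelist(cbind(pv, ev), directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  deg <- igraph::degree(g)

  nodes <- tibble(
    vertex = vnames,
    node_class = ifelse(startsWith(vnames, "P|"), "promoter", "distal"),
    node_id = substring(vnames, 3),
    component = comp$membership[vnames],
    degree = as.integer(deg[vnames])
  )

  # Node coordinates: promoter window (or TSS point), element interval.
  prom_coord <- if (!is.null(promoters)) {
    promoters |>
      dplyr::transmute(node_id = .data$gene_id, chrom = .data$chrom,
                       start = as.numeric(.data$start),
                       end = as.numeric(.data$end))
  } else {
    pairs |>
      dplyr::distinct(.data$gene_id, .data$chrom, .data$tss) |>
      dplyr::transmute(node_id = .data$gene_id, chrom = .data$chrom,
                       start = as.numeric(.data$tss),
                       end = as.numeric(.data$tss) + 1)
  }
  el_coord <- pairs |>
    dplyr::distinct(.data$element_id, .data$chrom,
                    .data$element_start, .data$element_end) |>
    dplyr::transmute(node_id = .data$element_id, chrom = .data$chrom,
                     start = as.numeric(.data$element_start),
                     end = as.numeric(.data$element_end))
  coords <- dplyr::bind_rows(
    dplyr::mutate(prom_coord, node_class = "promoter"),
    dplyr::mutate(el_coord, node_class = "distal")
  )
  nodes <- dplyr::left_join(nodes, coords, by = c("node_id", "node_class")) |>
    dplyr::mutate(midpoint = interval_midpoint(.data$start, .data$end))
  if (any(is.na(nodes$start))) {
    stop_crhub("node without coordinates in pair table", "crhub_contract_error")
  }

  # Deterministic hub ids ordered by (chrom, leftmost start).
  comp_order <- nodes |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(chrom = min(.data$chrom), left = min(.data$start),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$left)
  comp_order$crh_id <- sprintf("CRH_%04d", seq_len(nrow(comp_order)))
  nodes <- dplyr::left_join(
    nodes, comp_order[, c("component", "crh_id")], by = "component"
  )

  # Roles: monogamous = node of a 2-node hub; in larger hubs degree 1 is
  # 1-1-N and degree >= 2 is polygamous.
  comp_sizes <- dplyr::count(nodes, .data$crh_id, name = "n_nodes")
  nodes <- nodes |>
    dplyr::left_join(comp_sizes, by = "crh_id") |>
    dplyr::mutate(role = dplyr::case_when(
      .data$n_nodes == 2 ~ "monogamous",
      .data$degree == 1 ~ "one_one_N",
      TRUE ~ "polygamous"
    ))

  edges <- pairs |>
    dplyr::mutate(crh_id = nodes$crh_id[match(paste0("P|", pairs$gene_id),
                                              nodes$vertex)])

  crhs <- nodes |>
    dplyr::group_by(.data$crh_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      n_promoters = sum(.data$node_class == "promoter"),
      n_distal = sum(.data$node_class == "distal"),
      n_elements = dplyr::n(),
      prop_distal = .data$n_distal / .data$n_elements,
      mean_pair_distance = mean_pairwise_distance(.data$midpoint),
      span_start = min(.data$start),
      span_end = max(.data$end),
      .groups = "drop"
    )
  n_edges <- dplyr::count(edges, .data$crh_id, name = "n_edges")
  crhs <- dplyr::left_join(crhs, n_edges, by = "crh_id") |>
    dplyr::relocate("n_edges", .after = "n_elements") |>
    dplyr::arrange(.data$crh_id)

  nodes <- nodes |>
    dplyr::select("crh_id", "node_id", "node_class", "chrom", "start", "end",
                  "midpoint", "degree", "role") |>
    dplyr::arrange(.data$crh_id, dplyr::desc(.data$node_class), .data$node_id)

  structure(list(crhs = crhs, nodes = nodes, edges = edges),
            class = "crh_set")
}

empty_crh_set <- function() {
  structure(list(
    crhs = tibble(
      crh_id = character(), chrom = character(), n_promoters = integer(),
      n_distal = integer(), n_elements = integer(), n_edges = integer(),
      prop_distal = double(), mean_pair_distance = double(),
      span_start = double(), span_end = double()
    ),
    nodes = tibble(
      crh_id = character(), node_id = character(), node_class = character(),
      chrom = character(), start = double(), end = double(),
      midpoint = double(), degree = integer(), role = character()
    ),
    edges = tibble(crh_id = character(), gene_id = character(),
                   element_id = character())
  ), class = "crh_set")
}

#' @export
print.crh_set <- function(x, ...) {
  cat(sprintf(
    "<crh_set> %d hubs, %d nodes (%d promoters / %d distal), %d edges\n",
    nrow(x$crhs), nrow(x$nodes),
    sum(x$nodes$node_class == "promoter"),
    sum(x$nodes$node_class == "distal"),
    nrow(x$edges)
  ))
  if (nrow(x$crhs) > 0) {
    cat(sprintf("  hub size: median %g elements, range %d-%d\n",
                median(x$crhs$n_elements), min(x$crhs$n_elements),
                max(x$crhs$n_elements)))
  }
  invisible(x)
}

#' @describeIn build_crhs One row per hub with derived metrics.
#' @param x A `crh_set`.
#' @param ... Unused.
#' @method tidy crh_set
#' @export
tidy.crh_set <- function(x, ...) x$crhs

#' @describeIn build_crhs One-row global summary (hub, node, edge counts,
#'   monogamous fraction, median hub size).
#' @method glance crh_set
#' @export
glance.crh_set <- function(x, ...) {
  tibble(
    n_crhs = nrow(x$crhs),
    n_nodes = nrow(x$nodes),
    n_promoters = sum(x$nodes$node_class == "promoter"),
    n_distal = sum(x$nodes$node_class == "distal"),
    n_edges = nrow(x$edges),
    prop_monogamous_crhs = if (nrow(x$crhs)) mean(x$crhs$n_elements == 2) else NA_real_,
    median_elements = if (nrow(x$crhs)) median(x$crhs$n_elements) else NA_real_
  )
}

#' Node role taxonomy of a hub set
#'
#' Every node gets exactly one role: `monogamous` (member of a two-node hub,
#' an exclusive promoter-element pair), `one_one_N` (degree-1 node inside a
#' hub of three or more nodes — its unique partner is shared), or
#' `polygamous` (degree at least 2). Roles partition nodes within each class.
#'
#' @param crh_set A `crh_set` from [build_crhs()].
#' @return Tibble `crh_id`, `node_id`, `node_class`, `degree`, `role`.
#' @export
classify_roles <- function(crh_set) {
  stopifnot(inherits(crh_set, "crh_set"))
  crh_set$nodes |>
    dplyr::select("crh_id", "node_id", "node_class", "degree", "role")
}

#' Role proportions by node class
#'
#' Convenience census over [classify_roles()]: per node class, the count and
#' proportion of nodes in each role, reported both over all nodes of the
#' class and over nodes in hubs of three or more nodes (two denominators,
#' since published summaries are ambiguous about which is meant).
#'
#' @param crh_set A `crh_set`.
#' @return Tibble `node_class`, `role`, `n`, `prop_all`, `prop_large_crh`.
#' @export
role_census <- function(crh_set) {
  roles <- classify_roles(crh_set)
  sizes <- crh_set$crhs[, c("crh_id", "n_elements")]
  roles <- dplyr::left_join(roles, sizes, by = "crh_id")
  roles |>
    dplyr::group_by(.data$node_class, .data$role) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(prop_all = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      roles |>
        dplyr::filter(.data$n_elements >= 3) |>
        dplyr::count(.data$node_class, .data$role, name = "n_large") |>
        dplyr::group_by(.data$node_class) |>
        dplyr::mutate(prop_large_crh = .data$n_large / sum(.data$n_large)) |>
        dplyr::ungroup() |>
        dplyr::select("node_class", "role", "prop_large_crh"),
      by = c("node_class", "role")
    )
}

#' Degree distributions per node class
#'
#' Counts of node degree by class with the empirical CDF. Use
#' [nearest_rank_percentile()] on the underlying degrees for percentile
#' summaries (e.g., the 80th percentile of connections).
#'
#' @param crh_set A `crh_set`.
#' @return Tibble `node_class`, `degree`, `n`, `cum_prop`.
#' @export
degree_profile <- function(crh_set) {
  stopifnot(inherits(crh_set, "crh_set"))
  crh_set$nodes |>
    dplyr::count(.data$node_class, .data$degree) |>
    dplyr::group_by(.data$node_class) |>
    dplyr::arrange(.data$degree, .by_group = TRUE) |>
    dplyr::mutate(cum_prop = cumsum(.data$n) / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Candidate element and promoter sets
#'
#' The enrichment comparators: candidate distal elements are DNAse peaks that
#' do not overlap any functional distal element by even 1 bp; candidate
#' promoters belong to genes absent from every hub.
#'
#' @param dnase_peaks Interval tibble of DNAse peaks (with `id`).
#' @param functional_elements Interval tibble of functional distal elements.
#' @param all_genes Gene table (`gene_id`, `chrom`, `strand`, `tss`).
#' @param crh_set A `crh_set`.
#' @param promoter_width Width for candidate promoter windows (bp).
#' @return List with tibbles `candidate_distal` and `candidate_promoters`.
#' @export
build_candidate_sets <- function(dnase_peaks, functional_elements, all_genes,
                                 crh_set, promoter_width = 500) {
  stopifnot(inherits(crh_set, "crh_set"))
  assert_columns(dnase_peaks, c("chrom", "start", "end"), "dnase_peaks")
  if (!"id" %in% names(dnase_peaks)) {
    dnase_peaks$id <- paste0(dnase_peaks$chrom, ":", dnase_peaks$start, "-",
                             dnase_peaks$end)
  }
  hit_ids <- if (nrow(functional_elements) > 0) {
    unique(overlap_hits(dnase_peaks, functional_elements)$query_id)
  } else character()
  candidate_distal <- dplyr::filter(dnase_peaks, !.data$id %in% hit_ids)
  crh_genes <- crh_set$nodes$node_id[crh_set$nodes$node_class == "promoter"]
  candidate_genes <- dplyr::filter(all_genes, !.data$gene_id %in% crh_genes)
  list(
    candidate_distal = candidate_distal,
    candidate_promoters = make_promoters(candidate_genes, promoter_width)
  )
}

#' Classify pair replication across two samples
#'
#' For each functional pair in a reference sample, asks how it appears in a
#' second sample: `Direct` when the matched promoter-element pair is itself a
#' functional pair there; `SameCRH_NoDirect` when both matched endpoints fall
#' in one hub of the other sample without a direct edge; `NoConnection` when
#' both endpoints exist in the other sample but not in a common hub; and
#' `NotFound` when either endpoint has no match. Endpoints are matched by
#' coordinate overlap (any overlap by default; raise `min_frac` to require a
#' reciprocal overlap fraction), promoters via their promoter windows.
#'
#' @param pairs_ref,pairs_other Functional pair tibbles of the two samples.
#' @param crhs_other `crh_set` built from `pairs_other`.
#' @param promoters_ref,promoters_other Promoter tibbles for the two samples.
#' @param min_frac Minimum reciprocal overlap fraction for a match (default 0
#'   = any overlap).
#' @return `pairs_ref` with a `replication` factor column.
#' @export
classify_pair_replication <- function(pairs_ref, pairs_other, crhs_other,
                                      promoters_ref, promoters_other,
                                      min_frac = 0) {
  stopifnot(inherits(crhs_other, "crh_set"))

  match_by_overlap <- function(q, s, qid, sid) {
    if (nrow(q) == 0 || nrow(s) == 0) {
      return(tibble(from = character(), to = character()))
    }
    q2 <- tibble(chrom = q$chrom, start = q$start, end = q$end, id = q[[qid]])
    s2 <- tibble(chrom = s$chrom, start = s$start, end = s$end, id = s[[sid]])
    idx <- overlap_index(q2, s2)
    if (nrow(idx) == 0) return(tibble(from = character(), to = character()))
    frac_q <- idx$overlap_bp / (q2$end[idx$query_idx] - q2$start[idx$query_idx])
    frac_s <- idx$overlap_bp / (s2$end[idx$subject_idx] - s2$start[idx$subject_idx])
    keep <- pmin(frac_q, frac_s) >= min_frac
    idx <- idx[keep, , drop = FALSE]
    # best match = largest overlap
    idx |>
      dplyr::mutate(from = q2$id[.data$query_idx], to = s2$id[.data$subject_idx]) |>
      dplyr::group_by(.data$from) |>
      dplyr::slice_max(.data$overlap_bp, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("from", "to")
  }

  el_ref <- dplyr::distinct(pairs_ref, .data$element_id, .data$chrom,
                            start = .data$element_start, end = .data$element_end)
  el_oth <- dplyr::distinct(pairs_other, .data$element_id, .data$chrom,
                            start = .data$element_start, end = .data$element_end)
  el_map <- match_by_overlap(el_ref, el_oth, "element_id", "element_id")
  pr_map <- match_by_overlap(promoters_ref, promoters_other,
                             "gene_id", "gene_id")

  other_edges <- paste(pairs_other$gene_id, pairs_other$element_id)
  node_crh <- crhs_other$nodes
  crh_of <- function(ids, class) {
    node_crh$crh_id[match(paste(class, ids), paste(node_crh$node_class,
                                                   node_crh$node_id))]
  }

  g_to <- pr_map$to[match(pairs_ref$gene_id, pr_map$from)]
  e_to <- el_map$to[match(pairs_ref$element_id, el_map$from)]
  exists_g <- !is.na(g_to)
  exists_e <- !is.na(e_to)
  direct <- exists_g & exists_e & paste(g_to, e_to) %in% other_edges
  crh_g <- crh_of(g_to, "promoter")
  crh_e <- crh_of(e_to, "distal")
  same_crh <- exists_g & exists_e & !is.na(crh_g) & !is.na(crh_e) &
    crh_g == crh_e & !direct

  replication <- dplyr::case_when(
    direct ~ "Direct",
    same_crh ~ "SameCRH_NoDirect",
    exists_g & exists_e ~ "NoConnection",
    TRUE ~ "NotFound"
  )
  dplyr::mutate(pairs_ref, replication = factor(
    replication,
    levels = c("Direct", "SameCRH_NoDirect", "NoConnection", "NotFound")
  ))
}

#' Write a hub set to TSV files
#'
#' Writes three files under `dir`: `crh_summary.tsv` (one row per hub),
#' `crh_nodes.tsv` (membership with degree and role) and `crh_edges.tsv`.
#'
#' @param crh_set A `crh_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_crh_set <- function(crh_set, dir) {
  stopifnot(inherits(crh_set, "crh_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(crh_set$crhs, file.path(dir, "crh_summary.tsv"), progress = FALSE)
  readr::write_tsv(crh_set$nodes, file.path(dir, "crh_nodes.tsv"), progress = FALSE)
  readr::write_tsv(crh_set$edges, file.path(dir, "crh_edges.tsv"), progress = FALSE)
  invisible(dir)
}
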