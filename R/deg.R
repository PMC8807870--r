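#' Structure views for SNP-to-DEG linkage
#'
#' Three ways of grouping genes with the distal regulatory DNA that can carry
#' noncoding risk variants: whole hubs (`crh_structures()`), single
#' promoter-distal-element pairs (`pair_structures()`), and TADs
#' (`tad_structures()`, genes by TSS containment, distal elements by full
#' containment). Each returns one row per structure with list-columns
#' `gene_ids` and `distal` (interval tibble of the structure's distal
#' elements).
#'
#' @param crh_set A `crh_set`.
#' @return Tibble `kind`, `structure_id`, `gene_ids` (list), `distal` (list).
#' @export
crh_structures <- function(crh_set) {
  stopifnot(inherits(crh_set, "crh_set"))
  nodes <- crh_set$nodes
  by_crh <- split(seq_len(nrow(nodes)), nodes$crh_id)
  tibble(
    kind = "crh",
    structure_id = names(by_crh),
    gene_ids = unname(purrr::map(by_crh, function(i) {
      nodes$node_id[i][nodes$node_class[i] == "promoter"]
    })),
    distal = unname(purrr::map(by_crh, function(i) {
      d <- i[nodes$node_class[i] == "distal"]
      tibble(chrom = nodes$chrom[d], start = nodes$start[d],
             end = nodes$end[d], id = nodes$node_id[d])
    }))
  )
}

#' @rdname crh_structures
#' @param pairs Functional pair tibble.
#' @export
pair_structures <- function(pairs) {
  if ("functional" %in% names(pairs)) pairs <- dplyr::filter(pairs, .data$functional)
  assert_columns(pairs, c("gene_id", "element_id", "chrom",
                          "element_start", "element_end"), "pair table")
  tibble(
    kind = "ep_pair",
    structure_id = paste(pairs$gene_id, pairs$element_id, sep = "|"),
    gene_ids = purrr::map(pairs$gene_id, identity),
    distal = purrr::pmap(
      list(pairs$chrom, pairs$element_start, pairs$element_end,
           pairs$element_id),
      function(ch, s, e, id) tibble(chrom = ch, start = s, end = e, id = id)
    )
  )
}

#' @rdname crh_structures
#' @param tads Disjoint TAD interval tibble (with `id`).
#' @param genes Gene table (`gene_id`, `chrom`, `tss`).
#' @param functional_elements Interval tibble of functional distal elements
#'   (with `id`).
#' @export
tad_structures <- function(tads, genes, functional_elements) {
  check_disjoint(tads, "TAD")
  if (!"id" %in% names(tads)) {
    tads$id <- paste0(tads$chrom, ":", tads$start, "-", tads$end)
  }
  tss_pts <- tibble(chrom = genes$chrom, start = genes$tss,
                    end = genes$tss + 1)
  g_hit <- overlap_index(tss_pts, tads)
  # distal element fully inside the TAD
  e_hit <- overlap_index(functional_elements, tads)
  if (nrow(e_hit) > 0) {
    full <- e_hit$overlap_bp ==
      (functional_elements$end[e_hit$query_idx] -
         functional_elements$start[e_hit$query_idx])
    e_hit <- e_hit[full, , drop = FALSE]
  }
  tibble(
    kind = "tad",
    structure_id = tads$id,
    gene_ids = purrr::map(seq_len(nrow(tads)), function(t) {
      genes$gene_id[g_hit$query_idx[g_hit$subject_idx == t]]
    }),
    distal = purrr::map(seq_len(nrow(tads)), function(t) {
      q <- e_hit$query_idx[e_hit$subject_idx == t]
      tibble(chrom = functional_elements$chrom[q],
             start = functional_elements$start[q],
             end = functional_elements$end[q],
             id = functional_elements$id[q])
    })
  )
}

#' Assign clumped noncoding SNPs to structures
#'
#' A SNP is assigned to a structure when it falls inside one of the
#' structure's distal elements (half-open containment); a SNP can be
#' assigned to several structures. SNPs falling inside any promoter window
#' are never assigned — only distal regulatory DNA counts. No association
#' p-value threshold is applied: clumped SNPs already represent the
#' strongest signal per genomic window.
#'
#' @param structures Output of one of the [crh_structures()] constructors.
#' @param snps Tibble `snp_id`, `chrom`, `pos`.
#' @param promoters Promoter tibble used to exclude promoter SNPs (optional).
#' @return `structures` with list-column `assigned_snps` and integer
#'   `n_snps`.
#' @export
assign_structure_snps <- function(structures, snps, promoters = NULL) {
  assert_columns(snps, c("snp_id", "chrom", "pos"), "SNP table")
  if (!is.null(promoters) && nrow(promoters) > 0) {
    in_prom <- snps_in_intervals(snps, promoters)
    snps <- snps[!in_prom, , drop = FALSE]
  }
  structures$assigned_snps <- purrr::map(structures$distal, function(d) {
    if (nrow(d) == 0 || nrow(snps) == 0) return(character(0))
    unique(snps$snp_id[snps_in_intervals(snps, d)])
  })
  structures$n_snps <- lengths(structures$assigned_snps)
  structures
}

#' DEG proportions per structure and kind-level summary
#'
#' For each structure, the proportion of its genes that are differentially
#' expressed; structures with zero genes are excluded with a warning. The
#' summary, per structure kind, reports the fraction of structures with at
#' least one assigned SNP and the median DEG proportion over that subset,
#' plus pairwise rank-sum comparisons of the per-structure proportions
#' between kinds.
#'
#' @param structures Structures with `assigned_snps` (see
#'   [assign_structure_snps()]); multiple kinds may be row-bound.
#' @param deg_genes Character vector of DEG gene ids.
#' @return List with `per_structure`, `summary` and `tests` tibbles.
#' @export
deg_proportions <- function(structures, deg_genes) {
  n_genes <- lengths(structures$gene_ids)
  if (any(n_genes == 0)) {
    rlang::warn(sprintf("%d structure(s) with zero genes excluded",
                        sum(n_genes == 0)))
    structures <- structures[n_genes > 0, , drop = FALSE]
  }
  per <- structures |>
    dplyr::mutate(
      n_genes = lengths(.data$gene_ids),
      n_deg = purrr::map_int(.data$gene_ids,
                             ~ length(intersect(unique(.x), deg_genes))),
      deg_proportion = .data$n_deg / .data$n_genes
    ) |>
    dplyr::select("kind", "structure_id", "n_genes", "n_deg",
                  "deg_proportion", "n_snps")
  summary <- per |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(
      n_structures = dplyr::n(),
      frac_with_snp = mean(.data$n_snps >= 1),
      median_deg_prop_with_snp = median(
        .data$deg_proportion[.data$n_snps >= 1]
      ),
      .groups = "drop"
    )
  kinds <- unique(per$kind)
  tests <- if (length(kinds) >= 2) {
    combos <- utils::combn(kinds, 2, simplify = FALSE)
    purrr::map_dfr(combos, function(kk) {
      a <- per$deg_proportion[per$kind == kk[1] & per$n_snps >= 1]
      b <- per$deg_proportion[per$kind == kk[2] & per$n_snps >= 1]
      if (length(a) == 0 || length(b) == 0) {
        return(tibble(kind_a = kk[1], kind_b = kk[2],
                      statistic = NA_real_, p_value = NA_real_))
      }
      rt <- rank_tests(a, b, mode = "rank_sum")
      tibble(kind_a = kk[1], kind_b = kk[2],
             statistic = rt$statistic, p_value = rt$p_value)
    })
  } else {
    tibble(kind_a = character(), kind_b = character(),
           statistic = double(), p_value = double())
  }
  list(per_structure = per, summary = summary, tests = tests)
}

#' DEG enrichment of hub genes versus candidate genes
#'
#' Two-sided Fisher's exact test on {in hub vs candidate} x {DEG vs not}.
#'
#' @param genes Tibble with logical columns `in_crh` and `deg`.
#' @return A `crh_enrichment`.
#' @export
deg_crh_enrichment <- function(genes) {
  assert_columns(genes, c("in_crh", "deg"), "gene table")
  g <- dplyr::filter(genes, !is.na(.data$in_crh) & !is.na(.data$deg))
  fisher_exact_2x2(
    a = sum(g$in_crh & g$deg), b = sum(g$in_crh & !g$deg),
    c = sum(!g$in_crh & g$deg), d = sum(!g$in_crh & !g$deg)
  )
}
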