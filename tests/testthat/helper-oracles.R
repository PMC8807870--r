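# Independent oracles and fixture builders used across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package code paths it checks.

# Quadratic all-pairs overlap scan (half-open arithmetic).
oracle_overlaps <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      ov <- min(query$end[i], subject$end[j]) -
        max(query$start[i], subject$start[j])
      if (ov >= 1) {
        out[[length(out) + 1]] <- data.frame(
          query_id = query$id[i], subject_id = subject$id[j],
          overlap_bp = ov
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      overlap_bp = integer()))
  }
  do.call(rbind, out)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                             max_width = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE),
    id = paste0("iv", seq_len(n))
  )
}

# Bitmask union of covered bases on a toy genome.
oracle_covered_bp <- function(intervals, genome_len = 2e4) {
  by_chrom <- split(intervals, intervals$chrom)
  sum(vapply(by_chrom, function(df) {
    mask <- logical(genome_len)
    for (i in seq_len(nrow(df))) {
      mask[(df$start[i] + 1):df$end[i]] <- TRUE
    }
    sum(mask)
  }, numeric(1)))
}

# Union-find connected components over a bipartite edge list.
oracle_components <- function(gene_id, element_id) {
  nodes <- unique(c(paste0("P|", gene_id), paste0("E|", element_id)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(gene_id)) {
    a <- find(paste0("P|", gene_id[k]))
    b <- find(paste0("E|", element_id[k]))
    if (a != b) parent[[a]] <- b
  }
  vapply(nodes, find, character(1))
}

# Per-node brute-force role classifier on a bipartite edge list.
oracle_roles <- function(gene_id, element_id) {
  comp <- oracle_components(gene_id, element_id)
  deg <- table(c(paste0("P|", gene_id), paste0("E|", element_id)))
  comp_size <- table(comp)
  data.frame(
    vertex = names(comp),
    role = vapply(names(comp), function(v) {
      if (comp_size[[comp[[v]]]] == 2) "monogamous"
      else if (deg[[v]] == 1) "one_one_N"
      else "polygamous"
    }, character(1)),
    row.names = NULL
  )
}

# Naive O(m^2) Benjamini-Hochberg: adj_i = min over j with p_j >= p_i of
# p_j * m / rank_j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(p[p >= p[i]] * m / r[p >= p[i]]))
  }, numeric(1))
}

# Full hypergeometric enumeration via choose(), independent of dhyper.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exhaustive threshold scan for calibrate_threshold.
oracle_calibrate <- function(pairs, target, bounds) {
  cand <- sort(unique(pairs$abc_score))
  cand <- cand[cand > 0]
  best <- NULL
  for (th in cand) {
    keep <- pairs$abc_score >= th
    if (!any(keep)) next
    m <- mean(table(pairs$gene_id[keep]))
    if (m < bounds[1] || m > bounds[2]) next
    if (is.null(best) || abs(m - target) < best$dev - 1e-12 ||
        (abs(abs(m - target) - best$dev) <= 1e-12 && th > best$th)) {
      best <- list(th = th, mean = m, dev = abs(m - target))
    }
  }
  best
}

# Minimal covering subset size by exhaustive enumeration.
oracle_min_subset <- function(coverage, frac) {
  total <- sum(coverage)
  k <- length(coverage)
  for (size in 1:k) {
    combos <- utils::combn(k, size, simplify = FALSE)
    if (any(vapply(combos, function(ix) sum(coverage[ix]) >= frac * total,
                   logical(1)))) {
      return(size)
    }
  }
  k
}

# Minimal functional-pair table over an edge list, with invented spread-out
# coordinates (used wherever only graph structure matters).
mk_pairs <- function(edges, chrom = "chr1") {
  # coordinates derive from the numeric id suffix, so they are invariant to
  # the order in which edges are listed
  genes <- unique(edges$gene_id)
  els <- unique(edges$element_id)
  num <- function(x) match(x, sort(unique(x)))
  tss <- stats::setNames(num(genes) * 10000, genes)
  est <- stats::setNames(5000 + num(els) * 10000, els)
  tibble::tibble(
    gene_id = edges$gene_id, element_id = edges$element_id, chrom = chrom,
    element_start = est[edges$element_id],
    element_end = est[edges$element_id] + 1000,
    tss = tss[edges$gene_id], abc_score = 0.5, functional = TRUE
  )
}

# A 2-node hub whose extreme nodes sit at the given coordinate windows.
mk_span_crh <- function(left, right, chrom = "chr1") {
  pairs <- tibble::tibble(
    gene_id = "P1", element_id = "E1", chrom = chrom,
    element_start = right[1], element_end = right[2],
    tss = mean(left), abc_score = 1, functional = TRUE
  )
  pr <- tibble::tibble(gene_id = "P1", chrom = chrom, tss = mean(left),
                       start = left[1], end = left[2])
  build_crhs(pairs, promoters = pr)
}

# Internal accessors used by contact-matrix tests.
contact_bins_for_test <- function(m, i, j) crhub:::contact_bins(m, i, j)

# Occupied-row sums of a sparse symmetric contact matrix (diagonal once).
row_sums_for_test <- function(m) {
  ent <- m$entries
  bins <- sort(unique(c(ent$bin_i, ent$bin_j)))
  vapply(bins, function(b) {
    sum(ent$count[ent$bin_i == b]) +
      sum(ent$count[ent$bin_j == b & ent$bin_i != b])
  }, numeric(1))
}

# Small, fast fixture for tests that only need structure, not scale.
small_fixture_config <- function(seed = 1, snp_density = 5e-4, ...) {
  fixture_config(
    seed = seed,
    n_chrom = 1, chrom_length = 1e7,
    n_genes = 40, n_elements = 150,
    planted_hubs = c(
      rep(list(c(1L, 1L)), 4), rep(list(c(1L, 3L)), 3),
      rep(list(c(2L, 4L)), 2), list(c(3L, 6L))
    ),
    snp_density = snp_density,
    ...
  )
}

# Recover the hub partition from a simulated dataset; returns ARI.
planted_recovery_ari <- function(sim, threshold = sim$config$abc_threshold) {
  pairs <- suppressWarnings(compute_abc_scores(
    sim$landscape$elements, sim$landscape$promoters, sim$contacts
  ))
  crhs <- build_crhs(functional_pairs(threshold_pairs(pairs, threshold)),
                     promoters = sim$landscape$promoters)
  truth <- sim$landscape$truth$nodes
  m <- match(paste(truth$node_class, truth$node_id),
             paste(crhs$nodes$node_class, crhs$nodes$node_id))
  if (any(is.na(m))) return(NA_real_)
  if (nrow(crhs$nodes) != nrow(truth)) return(NA_real_)
  recovery_ari(truth$hub_id, crhs$nodes$crh_id[m])
}
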