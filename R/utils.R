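# Internal helpers shared across modules.

# Abort with a classed condition so tests can target specific failures.
stop_crhub <- function(msg, class = "crhub_error") {
  rlang::abort(msg, class = c(class, "crhub_error"))
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_crhub(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "crhub_contract_error")
  }
  invisible(df)
}

# Mean absolute difference over all unordered pairs of a numeric vector,
# computed in O(n log n) via the sorted-order identity
# sum_{i<j} (x_(j) - x_(i)) = sum_i (2i - 1 - n) x_(i).
mean_pairwise_distance <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  xs <- sort(x)
  tot <- sum((2 * seq_len(n) - 1 - n) * xs)
  tot / (n * (n - 1) / 2)
}

#' Nearest-rank percentile
#'
#' The smallest sample value such that at least `p` percent of the sample is
#' less than or equal to it (the convention used for degree summaries such as
#' the 80th percentile of connections).
#'
#' @param x Numeric vector.
#' @param p Percentile in (0, 100].
#' @return A single value from `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  stopifnot(p > 0, p <= 100)
  xs <- sort(x)
  xs[max(1L, ceiling(p / 100 * length(xs)))]
}

# Interval midpoints under 0-based half-open coordinates.
interval_midpoint <- function(start, end) (start + end) / 2

# IRanges view of a tidy interval tibble (1-based closed for IRanges).
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# Overlap widths for a chrom-partitioned pair of interval tibbles; returns
# row indices into query/subject plus overlap bp. Zero-width results dropped.
overlap_index <- function(query, subject) {
  shared <- intersect(unique(query$chrom), unique(subject$chrom))
  out <- purrr::map(shared, function(ch) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::findOverlaps(
      as_iranges(query[qi, , drop = FALSE]),
      as_iranges(subject[si, , drop = FALSE])
    )
    if (length(hits) == 0) return(NULL)
    qh <- qi[S4Vectors::queryHits(hits)]
    sh <- si[S4Vectors::subjectHits(hits)]
    bp <- pmin(query$end[qh], subject$end[sh]) -
      pmax(query$start[qh], subject$start[sh])
    tibble(query_idx = qh, subject_idx = sh, overlap_bp = bp)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(
      query_idx = integer(), subject_idx = integer(), overlap_bp = integer()
    ))
  }
  dplyr::arrange(out, .data$query_idx, .data$subject_idx)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] used to score recovery of
#' planted hub partitions. Both arguments are label vectors over the same
#' items (order matters, label values do not).
#'
#' @param truth,estimate Label vectors of equal length.
#' @return A single number; 1 means identical partitions.
#' @export
recovery_ari <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  mclust::adjustedRandIndex(truth, estimate)
}

#' Census of associated-gene counts across hubs
#'
#' Summarises, over a vector giving the number of disease-associated genes in
#' each hub, how many hubs carry at least one associated gene and how many
#' carry several, as counts and rounded percentages, plus the mean and max
#' count among hubs with at least one.
#'
#' @param n_assoc_per_crh Integer vector, one entry per hub.
#' @return A one-row tibble with columns `n_crhs`, `n_with_assoc`,
#'   `pct_with_assoc`, `n_with_several`, `pct_with_several`, `mean_assoc`,
#'   `max_assoc`.
#' @export
associated_gene_census <- function(n_assoc_per_crh) {
  stopifnot(is.numeric(n_assoc_per_crh), all(n_assoc_per_crh >= 0))
  n <- length(n_assoc_per_crh)
  with1 <- sum(n_assoc_per_crh >= 1)
  withk <- sum(n_assoc_per_crh >= 2)
  pos <- n_assoc_per_crh[n_assoc_per_crh >= 1]
  tibble(
    n_crhs = n,
    n_with_assoc = with1,
    pct_with_assoc = round(100 * with1 / n),
    n_with_several = withk,
    pct_with_several = round(100 * withk / n),
    mean_assoc = if (length(pos)) mean(pos) else NA_real_,
    max_assoc = if (length(pos)) max(pos) else NA_real_
  )
}
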