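#' Construct a binned intra-chromosomal contact matrix
#'
#' A contact matrix is stored sparsely as an upper-triangle tibble of
#' `(bin_i, bin_j, count)` with `bin_i <= bin_j`; symmetry is implicit.
#' Duplicate and transposed input entries are folded together by summation.
#'
#' @param entries Tibble or data frame with columns `bin_i`, `bin_j`, `count`.
#' @param chrom Chromosome label.
#' @param bin_size Bin width in bp (default 10 kb, the working resolution of
#'   the hub analyses).
#' @param chrom_length Optional chromosome length in bp, used to range-check
#'   position queries.
#' @param normalization `"raw"` or `"balanced"`.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(entries, chrom, bin_size = 10000,
                           chrom_length = NULL, normalization = "raw") {
  assert_columns(entries, c("bin_i", "bin_j", "count"), "contact entries")
  if (bin_size <= 0) stop_crhub("`bin_size` must be positive")
  if (any(entries$count < 0)) {
    stop_crhub("negative contact counts are not allowed",
               "crhub_validation_error")
  }
  if (any(entries$bin_i < 0 | entries$bin_j < 0)) {
    stop_crhub("bin indices must be >= 0", "crhub_validation_error")
  }
  ent <- tibble(
    bin_i = pmin(entries$bin_i, entries$bin_j),
    bin_j = pmax(entries$bin_i, entries$bin_j),
    count = as.numeric(entries$count)
  ) |>
    dplyr::group_by(.data$bin_i, .data$bin_j) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$count != 0) |>
    dplyr::arrange(.data$bin_i, .data$bin_j)
  structure(
    list(chrom = chrom, bin_size = bin_size, entries = ent,
         chrom_length = chrom_length, normalization = normalization),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s, bin_size=%d bp, %d non-zero entries (%s)\n",
    x$chrom, as.integer(x$bin_size), nrow(x$entries), x$normalization
  ))
  invisible(x)
}

#' Load a contact matrix from a TSV contact list
#'
#' Reads a three-column `bin_i<TAB>bin_j<TAB>count` list. A JSON sidecar
#' (`<path>.json`, as written by [write_contacts()]) supplies `chrom`,
#' `bin_size`, `chrom_length` and `normalization` when present; explicit
#' arguments override it.
#'
#' @param path Path to the TSV file.
#' @param chrom,bin_size,chrom_length See [contact_matrix()]; defaults come
#'   from the sidecar when available.
#' @return A `contact_matrix`.
#' @export
load_contacts <- function(path, chrom = NULL, bin_size = NULL,
                          chrom_length = NULL) {
  if (!file.exists(path)) {
    stop_crhub(sprintf("file does not exist: %s", path), "crhub_io_error")
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  chrom <- chrom %||% meta$chrom %||% "chrUnknown"
  bin_size <- bin_size %||% meta$bin_size %||% 10000
  chrom_length <- chrom_length %||% meta$chrom_length
  df <- readr::read_tsv(path, col_names = c("bin_i", "bin_j", "count"),
                        col_types = "iid", progress = FALSE,
                        show_col_types = FALSE)
  contact_matrix(df, chrom = chrom, bin_size = bin_size,
                 chrom_length = unlist(chrom_length),
                 normalization = meta$normalization %||% "raw")
}

#' Write a contact matrix to TSV plus JSON sidecar
#'
#' @param mat A `contact_matrix`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(mat, path) {
  stopifnot(inherits(mat, "contact_matrix"))
  readr::write_tsv(mat$entries, path, col_names = FALSE, progress = FALSE)
  jsonlite::write_json(
    list(chrom = mat$chrom, bin_size = mat$bin_size,
         chrom_length = mat$chrom_length,
         normalization = mat$normalization),
    paste0(path, ".json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' Query contact counts at base-pair positions
#'
#' Looks up the count for the bin pair containing two positions
#' (`floor(pos / bin_size)`), adding `pseudocount`. Symmetric in its position
#' arguments; absent pairs return `pseudocount`. Vectorised over positions.
#'
#' @param mat A `contact_matrix`.
#' @param posA,posB Base positions (bp) on the matrix chromosome.
#' @param pseudocount Added to every returned count (default 0).
#' @return Numeric vector of counts.
#' @export
contact <- function(mat, posA, posB, pseudocount = 0) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (!is.null(mat$chrom_length) &&
      any(c(posA, posB) >= mat$chrom_length | c(posA, posB) < 0)) {
    stop_crhub(sprintf(
      "position beyond chromosome %s length %d",
      mat$chrom, as.integer(mat$chrom_length)
    ), "crhub_validation_error")
  }
  bi <- floor(posA / mat$bin_size)
  bj <- floor(posB / mat$bin_size)
  contact_bins(mat, bi, bj) + pseudocount
}

# Bin-level lookup (vectorised); returns 0 for absent pairs.
contact_bins <- function(mat, bin_i, bin_j) {
  lo <- pmin(bin_i, bin_j)
  hi <- pmax(bin_i, bin_j)
  key <- paste(lo, hi)
  ent_key <- paste(mat$entries$bin_i, mat$entries$bin_j)
  v <- mat$entries$count[match(key, ent_key)]
  v[is.na(v)] <- 0
  v
}

#' Balance a contact matrix to uniform row sums
#'
#' Applies symmetric iterative proportional scaling (a doubly-stochastic
#' scaling of the same family as Knight-Ruiz balancing) so that, over bins
#' with at least one contact, all row sums equal a common constant. Structural
#' zeros are preserved. A scaling is guaranteed to exist when the matrix has
#' total support — in practice, when occupied bins carry a self-interaction
#' diagonal entry, as binned contact maps do; sparsity patterns without total
#' support end in the non-convergence error.
#'
#' @param mat A `contact_matrix`.
#' @param tol Convergence tolerance: maximum relative deviation of
#'   occupied-row sums from their mean.
#' @param max_iter Iteration cap; non-convergence raises an error carrying the
#'   last residual.
#' @return A `contact_matrix` with `normalization = "balanced"`.
#' @export
balance <- function(mat, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(mat, "contact_matrix"))
  ent <- mat$entries
  if (nrow(ent) == 0) {
    out <- mat
    out$normalization <- "balanced"
    return(out)
  }
  bins <- sort(unique(c(ent$bin_i, ent$bin_j)))
  i <- match(ent$bin_i, bins)
  j <- match(ent$bin_j, bins)
  v <- ent$count
  n <- length(bins)
  rowsum_sparse <- function(v) {
    rs <- numeric(n)
    # off-diagonal entries contribute to both rows; diagonal once
    rs_i <- tapply(v, i, sum)
    rs[as.integer(names(rs_i))] <- rs[as.integer(names(rs_i))] + rs_i
    off <- i != j
    if (any(off)) {
      rs_j <- tapply(v[off], j[off], sum)
      rs[as.integer(names(rs_j))] <- rs[as.integer(names(rs_j))] + rs_j
    }
    rs
  }
  resid <- Inf
  for (iter in seq_len(max_iter)) {
    rs <- rowsum_sparse(v)
    if (any(rs == 0)) {
      stop_crhub("occupied bin with zero row sum; cannot balance",
                 "crhub_validation_error")
    }
    target <- mean(rs)
    resid <- max(abs(rs / target - 1))
    if (resid < tol) break
    d <- sqrt(rs / target)
    v <- v / (d[i] * d[j])
  }
  if (resid >= tol) {
    stop_crhub(sprintf(
      "balancing did not converge after %d iterations (residual %.3g)",
      max_iter, resid
    ), "crhub_convergence_error")
  }
  out <- contact_matrix(
    tibble(bin_i = ent$bin_i, bin_j = ent$bin_j, count = v),
    chrom = mat$chrom, bin_size = mat$bin_size,
    chrom_length = mat$chrom_length, normalization = "balanced"
  )
  out
}
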