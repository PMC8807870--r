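#' Read genomic intervals from BED-family files
#'
#' Parses BED3/BED6, ENCODE narrowPeak (10 column) or bedGraph files into a
#' tidy interval table. Coordinates are kept in the native BED convention:
#' 0-based, half-open `[start, end)`. A `signal` column is attached from
#' narrowPeak column 7 (signalValue) or bedGraph column 4.
#'
#' @param path Path to the file.
#' @param format One of `"bed"`, `"narrowPeak"`, `"bedGraph"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `id`, `strand`
#'   (where available), `signal` (narrowPeak/bedGraph) and `label` (the BED
#'   name column), sorted by `(chrom, start)`. Rows lacking a name get a
#'   positional `id` of the form `chrom:start-end`.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "bedGraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_crhub(sprintf("file does not exist: %s", path), "crhub_io_error")
  }
  spec <- switch(format,
    bed = list(
      names = c("chrom", "start", "end", "name", "score", "strand"),
      types = "ciicdc", min_cols = 3L
    ),
    narrowPeak = list(
      names = c("chrom", "start", "end", "name", "score", "strand",
                "signal", "pvalue", "qvalue", "peak"),
      types = "ciicdcdddi", min_cols = 10L
    ),
    bedGraph = list(
      names = c("chrom", "start", "end", "signal"),
      types = "ciid", min_cols = 4L
    )
  )
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE,
    show_col_types = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      id = character(), strand = character(), signal = double()
    ))
  }
  if (ncol(raw) < spec$min_cols) {
    stop_crhub(sprintf(
      "%s file has %d column(s); at least %d required",
      format, ncol(raw), spec$min_cols
    ), "crhub_parse_error")
  }
  n_use <- min(ncol(raw), length(spec$names))
  df <- raw[, seq_len(n_use)]
  names(df) <- spec$names[seq_len(n_use)]

  parse_int_col <- function(x, col) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad) > 0) {
      stop_crhub(sprintf(
        "malformed %s value '%s' at line %d", col, x[bad[1]], bad[1]
      ), "crhub_parse_error")
    }
    v
  }
  df$start <- parse_int_col(df$start, "start")
  df$end <- parse_int_col(df$end, "end")
  if ("signal" %in% names(df)) df$signal <- as.numeric(df$signal)

  bad <- which(df$end <= df$start | df$start < 0)
  if (length(bad) > 0) {
    stop_crhub(sprintf(
      "invalid interval at line %d: [%s, %s) on %s",
      bad[1], df$start[bad[1]], df$end[bad[1]], df$chrom[bad[1]]
    ), "crhub_validation_error")
  }

  out <- as_tibble(df)
  out$id <- if ("name" %in% names(out) && !all(is.na(out$name))) {
    ifelse(is.na(out$name) | out$name == ".",
           paste0(out$chrom, ":", out$start, "-", out$end), out$name)
  } else {
    paste0(out$chrom, ":", out$start, "-", out$end)
  }
  if (!"strand" %in% names(out)) out$strand <- "."
  keep <- intersect(
    c("chrom", "start", "end", "id", "strand", "signal", "name", "score",
      "pvalue", "qvalue", "peak"),
    names(out)
  )
  dplyr::arrange(out[, keep], .data$chrom, .data$start, .data$end)
}

#' Write genomic intervals to a BED-family file
#'
#' Inverse of [read_intervals()]; coordinates are written unchanged (0-based
#' half-open), so a write/read round trip reproduces them exactly.
#'
#' @param x Interval tibble with `chrom`, `start`, `end` and, depending on
#'   `format`, `id`/`strand`/`signal`.
#' @param path Output path.
#' @param format One of `"bed"`, `"narrowPeak"`, `"bedGraph"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "narrowPeak", "bedGraph")) {
  format <- match.arg(format)
  assert_columns(x, c("chrom", "start", "end"), "interval table")
  col_or <- function(nm, default) {
    if (nm %in% names(x)) x[[nm]] else default
  }
  out <- switch(format,
    bed = data.frame(
      x$chrom, x$start, x$end,
      col_or("id", "."), col_or("score", 0), col_or("strand", ".")
    ),
    narrowPeak = data.frame(
      x$chrom, x$start, x$end,
      col_or("id", "."), col_or("score", 0), col_or("strand", "."),
      col_or("signal", 0), col_or("pvalue", -1), col_or("qvalue", -1),
      col_or("peak", -1)
    ),
    bedGraph = data.frame(x$chrom, x$start, x$end, col_or("signal", 0))
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Build promoter windows around annotated TSSs
#'
#' Each gene's promoter is a fixed-width window centred on its TSS
#' (`[tss - width/2, tss + width/2)`), clipped at position 0. The default
#' width of 500 bp matches the promoter definition used throughout the hub
#' analyses; the window is symmetric because sidedness is a convention, not a
#' measurement.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @param width Total window width in bp; even and positive.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `start`, `end`.
#' @export
make_promoters <- function(genes, width = 500) {
  assert_columns(genes, c("gene_id", "chrom", "tss"), "gene table")
  if (!is.numeric(width) || width <= 0 || width %% 2 != 0) {
    stop_crhub("`width` must be a positive even number of bp",
               "crhub_validation_error")
  }
  bad <- which(is.na(genes$tss))
  if (length(bad) > 0) {
    stop_crhub(sprintf("gene '%s' has no TSS", genes$gene_id[bad[1]]),
               "crhub_validation_error")
  }
  half <- width / 2
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    strand = if ("strand" %in% names(genes)) genes$strand else ".",
    tss = as.numeric(genes$tss),
    start = pmax(0, genes$tss - half),
    end = genes$tss + half
  )
}

#' All pairwise overlaps between two interval sets
#'
#' Reports every (query, subject) pair overlapping by at least 1 bp under
#' 0-based half-open arithmetic; intervals that merely touch (`[0,10)` vs
#' `[10,20)`) do not overlap. Strand is ignored.
#'
#' @param query,subject Interval tibbles with `chrom`, `start`, `end` and an
#'   `id` column (a positional id is generated when absent).
#' @return A tibble `query_id`, `subject_id`, `overlap_bp`.
#' @export
overlap_hits <- function(query, subject) {
  for (nm in c("query", "subject")) {
    df <- get(nm)
    assert_columns(df, c("chrom", "start", "end"), nm)
  }
  qid <- query$id %||% paste0("q", seq_len(nrow(query)))
  sid <- subject$id %||% paste0("s", seq_len(nrow(subject)))
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  overlap_bp = integer()))
  }
  idx <- overlap_index(query, subject)
  tibble(
    query_id = qid[idx$query_idx],
    subject_id = sid[idx$subject_idx],
    overlap_bp = as.integer(idx$overlap_bp)
  )
}

#' Merge an interval set into disjoint intervals
#'
#' Collapses overlapping — and, at `gap = 0`, directly abutting — intervals
#' into their union. Intervals separated by at most `gap` bp are merged.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @param gap Maximum separation in bp bridged by the merge; non-negative.
#' @return Disjoint, sorted interval tibble (`chrom`, `start`, `end`, `id`).
#' @export
merge_intervals <- function(x, gap = 0) {
  assert_columns(x, c("chrom", "start", "end"), "interval table")
  if (gap < 0) stop_crhub("`gap` must be non-negative", "crhub_validation_error")
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  id = character()))
  }
  out <- x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      red <- IRanges::reduce(as_iranges(df), min.gapwidth = gap + 1)
      tibble(start = IRanges::start(red) - 1L, end = IRanges::end(red))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
  out$id <- paste0(out$chrom, ":", out$start, "-", out$end)
  out
}
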