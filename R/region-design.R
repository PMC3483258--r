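# Cross-species promoter-region design: hit filtering, overlap merging,
# length filtering with symmetric extension. Intervals are tibbles with
# columns chrom/start/end (0-based half-open) plus optional strand/species.

interval_tbl <- function(df, arg = "intervals") {
  df <- as_tibble(df)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("`", arg, "` needs columns chrom, start, end", call. = FALSE)
  }
  if (nrow(df) && any(df$start < 0 | df$start >= df$end)) {
    stop("`", arg, "` has invalid intervals (need 0 <= start < end)", call. = FALSE)
  }
  df
}

#' Parse a region string into a 0-based half-open interval
#'
#' Region strings such as `"chr12:51281338-51281660"` use 1-based inclusive
#' coordinates (the convention of genome browsers and publication tables);
#' internally all intervals are 0-based half-open, so `start` is decremented
#' by one on read.
#'
#' @param text Character vector of `"chrN:a-b"` strings (commas allowed in
#'   numbers).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' parse_region_string("chr12:51281338-51281660")
#' @export
parse_region_string <- function(text) {
  m <- stringr::str_match(text, "^\\s*([^:\\s]+):([0-9,]+)-([0-9,]+)\\s*$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop("malformed region string: ", paste(text[bad], collapse = ", "),
         call. = FALSE)
  }
  a <- as.numeric(gsub(",", "", m[, 3]))
  b <- as.numeric(gsub(",", "", m[, 4]))
  if (any(a < 1 | a > b)) {
    stop("malformed region string (need 1 <= a <= b): ",
         paste(text[a < 1 | a > b], collapse = ", "), call. = FALSE)
  }
  tibble(chrom = m[, 2], start = a - 1, end = b)
}

#' Read / write BED intervals
#'
#' Standard BED: 0-based half-open, tab-separated, first three columns
#' chrom/start/end with optional name, score, strand.
#'
#' @param path File path.
#' @return `read_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end` and, when present in the file, `name` and `strand`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- nm[seq_len(ncol(df))]
  interval_tbl(df[intersect(nm[c(1:4, 6)], names(df))], "bed")
}

#' @rdname read_bed
#' @param df Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `strand`).
#' @export
write_bed <- function(df, path) {
  df <- interval_tbl(df)
  out <- tibble(chrom = df$chrom, start = df$start, end = df$end,
                name = df[["name"]] %||% ".",
                score = 0L,
                strand = df[["strand"]] %||% ".")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Filter alignment hits to uniquely placed queries
#'
#' Given a table of alignment hits of species-A query regions against a
#' species-B genome, drops every query with more than `max_hits` hits
#' (ambiguously placed regions) and keeps the best-scoring target interval
#' for each surviving query.
#'
#' @param hits A data frame with columns `query` (query region id), target
#'   interval columns `chrom`, `start`, `end` (species B), and `score`.
#' @param max_hits Maximum allowed number of hits per query; queries
#'   exceeding it are removed entirely. Default `1` demands unique placement;
#'   `2` is a laxer mode tolerating one secondary hit.
#'
#' @return A tibble of target intervals (one row per retained query), with
#'   the `query` column preserved.
#' @export
select_orthologous_regions <- function(hits, max_hits = 1L) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble(query = character(), chrom = character(),
                  start = numeric(), end = numeric(), score = numeric()))
  }
  hits <- as_tibble(hits)
  stopifnot(all(c("query", "chrom", "start", "end", "score") %in% names(hits)))
  hits |>
    dplyr::group_by(.data$query) |>
    dplyr::filter(dplyr::n() <= max_hits) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("query", "chrom", "start", "end", "score")
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals on the same genome into the disjoint, sorted
#' intervals covering exactly the same bases (delegates to
#' [GenomicRanges::reduce()]). Bookended intervals (`end == start`) are
#' merged too.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @return A tibble of disjoint sorted intervals.
#' @export
merge_overlapping <- function(intervals) {
  intervals <- interval_tbl(intervals)
  if (nrow(intervals) == 0L) return(intervals[c("chrom", "start", "end")])
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
  red <- GenomicRanges::reduce(gr)
  red <- GenomicRanges::sort(red)
  tibble(chrom = as.character(GenomicRanges::seqnames(red)),
         start = GenomicRanges::start(red) - 1,
         end = GenomicRanges::end(red))
}

#' Length-filter merged regions and extend to a target length
#'
#' Regions shorter than `min_length` are removed (short merged alignments are
#' likely spurious orthology or high divergence). Surviving regions shorter
#' than `target_length` are extended symmetrically to exactly
#' `target_length`; an odd remainder puts the extra base on the 3' (end)
#' side. Extension is clipped at chromosome bounds and clipped regions are
#' flagged.
#'
#' @param intervals Interval tibble.
#' @param min_length Minimum merged-region length kept (bp). Default 1700.
#' @param target_length Final design length (bp). Default 2700.
#' @param chrom_bounds Optional named vector or data frame
#'   (`chrom`, `length`) of chromosome lengths for clipping.
#'
#' @return A tibble of intervals of length `target_length` (shorter only when
#'   clipped, with `clipped = TRUE`).
#' @export
filter_and_extend <- function(intervals, min_length = 1700L,
                              target_length = 2700L, chrom_bounds = NULL) {
  if (target_length < min_length) {
    stop("`target_length` must be >= `min_length`", call. = FALSE)
  }
  intervals <- interval_tbl(intervals)
  out <- dplyr::filter(intervals, .data$end - .data$start >= min_length)
  if (nrow(out) == 0L) return(dplyr::mutate(out, clipped = logical(0)))
  deficit <- pmax(0, target_length - (out$end - out$start))
  add5 <- floor(deficit / 2)    # extra base from an odd remainder goes 3'
  add3 <- deficit - add5
  start_new <- out$start - add5
  end_new <- out$end + add3
  lo <- 0
  hi <- Inf
  if (!is.null(chrom_bounds)) {
    if (is.data.frame(chrom_bounds)) {
      chrom_bounds <- setNames(chrom_bounds$length, chrom_bounds$chrom)
    }
    hi <- unname(chrom_bounds[out$chrom])
    hi[is.na(hi)] <- Inf
  }
  clipped <- start_new < lo | end_new > hi
  out$start <- pmax(start_new, lo)
  out$end <- pmin(end_new, hi)
  out$clipped <- clipped
  out
}
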