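# Global pairwise alignment of bisulfite-converted promoter sequences and
# mapping of orthologous CpG sites through alignment columns.

#' Alignment scoring scheme
#'
#' Affine gap scoring for [align_pair()]: a gap of length k costs
#' `gap_open + (k - 1) * gap_extend` beyond its first base, i.e. the first
#' gapped base costs `gap_open` and each further base `gap_extend`.
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Penalty of a length-1 gap (default 4, applied negatively).
#' @param gap_extend Penalty per additional gapped base (default 1).
#' @return A list of class `aln_scoring`.
#' @export
aln_scoring <- function(match = 1, mismatch = -1, gap_open = 4, gap_extend = 1) {
  stopifnot(gap_open > 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "aln_scoring")
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (via
#' [Biostrings::pairwiseAlignment()]). Intended for orthologous promoter
#' regions after [bisulfite_convert()] in `"methylated_CpG"` mode, so that
#' CpG cytosines survive conversion and anchor the alignment.
#'
#' @param seq_a,seq_b DNA strings (non-empty, not all `N`).
#' @param scoring An [aln_scoring()] object.
#' @param end_gap_free If `TRUE`, terminal gaps are unpenalized
#'   ("overlap"-style global alignment).
#'
#' @return A list of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, and `columns`, a
#'   tibble mapping each alignment column to the 0-based position in each
#'   sequence (`NA` at a gap).
#' @examples
#' aln <- align_pair("ACGTACGT", "ACGACGT")
#' aln$aligned_b
#' @export
align_pair <- function(seq_a, seq_b, scoring = aln_scoring(),
                       end_gap_free = FALSE) {
  seq_a <- check_dna(seq_a, "seq_a"); seq_b <- check_dna(seq_b, "seq_b")
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  if (grepl("^N+$", seq_a) || grepl("^N+$", seq_b)) {
    stop("cannot align a sequence consisting only of N", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE
  )
  # Biostrings charges gapOpening + k*gapExtension for a length-k gap, so a
  # first-base cost of `gap_open` means gapOpening = gap_open - gap_extend.
  fit <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b,
    type = if (end_gap_free) "overlap" else "global",
    substitutionMatrix = mat,
    gapOpening = scoring$gap_open - scoring$gap_extend,
    gapExtension = scoring$gap_extend
  )
  a <- as.character(Biostrings::alignedPattern(fit))
  b <- as.character(Biostrings::alignedSubject(fit))
  structure(list(aligned_a = a, aligned_b = b,
                 score = Biostrings::score(fit),
                 columns = alignment_columns(a, b)),
            class = "pairwise_alignment")
}

#' Column map of a gapped alignment
#'
#' @param aligned_a,aligned_b Equal-length gapped strings (`-` for gaps).
#' @return A tibble with `column` (1-based alignment column) and `pos_a`,
#'   `pos_b`: 0-based positions in the ungapped sequences, `NA` at gaps.
#' @export
alignment_columns <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned strings must have equal length", call. = FALSE)
  }
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  pos_a <- cumsum(ca != "-") - 1L
  pos_b <- cumsum(cb != "-") - 1L
  pos_a[ca == "-"] <- NA_integer_
  pos_b[cb == "-"] <- NA_integer_
  tibble(column = seq_along(ca), pos_a = as.integer(pos_a),
         pos_b = as.integer(pos_b))
}

#' Map orthologous CpG sites through an alignment
#'
#' Two CpG sites are orthologous when their cytosines occupy the same
#' alignment column. Pairing is one-to-one by construction (a column holds at
#' most one position per sequence).
#'
#' @param aln A `pairwise_alignment` from [align_pair()], or any object with
#'   a `columns` tibble.
#' @param sites_a,sites_b CpG site tibbles from [find_cpg_sites()] (0-based
#'   `pos` of the C in the respective ungapped sequence), or bare integer
#'   vectors of positions.
#'
#' @return A tibble with `pos_a`, `pos_b`, `column`, one row per orthologous
#'   site pair, ascending in `column`.
#' @export
map_orthologous_sites <- function(aln, sites_a, sites_b) {
  pa <- if (is.data.frame(sites_a)) sites_a$pos else as.integer(sites_a)
  pb <- if (is.data.frame(sites_b)) sites_b$pos else as.integer(sites_b)
  cols <- aln$columns
  max_a <- suppressWarnings(max(cols$pos_a, na.rm = TRUE))
  max_b <- suppressWarnings(max(cols$pos_b, na.rm = TRUE))
  if (length(pa) && max(pa) > max_a || length(pb) && max(pb) > max_b) {
    stop("site positions exceed the aligned sequence length", call. = FALSE)
  }
  hit <- cols$pos_a %in% pa & cols$pos_b %in% pb
  tibble(pos_a = cols$pos_a[hit], pos_b = cols$pos_b[hit],
         column = cols$column[hit])
}
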