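# Sequence-level primitives: CpG detection, CpG observed/expected ratio,
# in-silico bisulfite conversion, FASTA I/O.

check_dna <- function(seq, arg = "seq") {
  if (!is.character(seq)) stop("`", arg, "` must be a character vector", call. = FALSE)
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("`", arg, "` contains non-IUPAC characters (allowed: A, C, G, T, N)",
         call. = FALSE)
  }
  seq
}

#' Locate CpG dinucleotides in a DNA sequence
#'
#' Scans the plus strand for `CG` dinucleotides. Because CpG is its own
#' reverse complement, enumerating one strand is sufficient; positions refer
#' to the cytosine.
#'
#' @param seq A single DNA string (A/C/G/T/N; case-insensitive).
#' @param id Optional sequence identifier carried into the output.
#' @param base Coordinate base for reported positions, `0` (default) or `1`.
#'
#' @return A tibble with columns `seq_id` and `pos` (position of the C,
#'   ascending), one row per CpG site. An empty sequence yields zero rows.
#' @examples
#' find_cpg_sites("ACGT")
#' find_cpg_sites("CGCG")
#' @export
find_cpg_sites <- function(seq, id = "seq", base = 0L) {
  stopifnot(length(seq) == 1L, base %in% c(0L, 1L))
  seq <- check_dna(seq)
  if (nchar(seq) < 2L) {
    return(fast_tbl(seq_id = character(), pos = integer()))
  }
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  pos <- if (m[1] == -1L) integer() else as.integer(m) - 1L + base
  fast_tbl(seq_id = rep(id, length(pos)), pos = pos)
}

#' Observed/expected CpG ratio
#'
#' Computes the classical CpG density statistic
#' \deqn{CpGo/e = \frac{N_{CpG}}{N_C \cdot N_G} \cdot L}
#' where counts and the effective length `L` ignore `N` bases. Values near 1
#' indicate CpG-island-like sequence; bulk vertebrate DNA sits near 0.2-0.4
#' because of CpG depletion by deamination.
#'
#' @param seq A single DNA string.
#' @param max_n_frac Sequences with a higher fraction of `N` are flagged with
#'   a `low_quality` warning (the ratio is still returned). Default 0.5.
#'
#' @return A single non-negative number.
#' @examples
#' cpg_oe_ratio("ACGT") # 1/(1*1) * 4 = 4
#' cpg_oe_ratio("CGCG") # 2/(2*2) * 4 = 2
#' @export
cpg_oe_ratio <- function(seq, max_n_frac = 0.5) {
  stopifnot(length(seq) == 1L)
  seq <- check_dna(seq)
  n_n <- stringr::str_count(seq, "N")
  len <- nchar(seq) - n_n
  if (nchar(seq) > 0 && n_n / nchar(seq) > max_n_frac) {
    warning("low_quality: more than ", round(100 * max_n_frac),
            "% of bases are N", call. = FALSE)
  }
  n_c <- stringr::str_count(seq, "C")
  n_g <- stringr::str_count(seq, "G")
  if (n_c * n_g == 0) {
    stop("CpG o/e ratio undefined: sequence needs at least one C and one G",
         call. = FALSE)
  }
  n_cpg <- nrow(find_cpg_sites(seq))
  (n_cpg / (n_c * n_g)) * len
}

#' In-silico bisulfite conversion
#'
#' Mimics bisulfite chemistry on sequence text: every cytosine outside a CpG
#' context is converted to thymine (unmethylated C reads as T after PCR). In
#' `"methylated_CpG"` mode (the default) CpG cytosines are retained, which
#' preserves CpG positions and lets converted sequences anchor a cross-species
#' alignment; in `"unmethylated_CpG"` mode CpG cytosines are converted too.
#'
#' @param seq A single DNA string.
#' @param mode `"methylated_CpG"` or `"unmethylated_CpG"`.
#' @return The converted sequence (same length as the input).
#' @examples
#' bisulfite_convert("ACGTCA")                       # "ACGTTA"
#' bisulfite_convert("ACGTCA", "unmethylated_CpG")   # "ATGTTA"
#' @export
bisulfite_convert <- function(seq, mode = c("methylated_CpG", "unmethylated_CpG")) {
  mode <- match.arg(mode)
  stopifnot(length(seq) == 1L)
  seq <- check_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  # C not followed by G -> T; final-position C has no following G
  out <- gsub("C(?!G)", "T", seq, perl = TRUE)
  if (mode == "unmethylated_CpG") out <- gsub("CG", "TG", out, fixed = TRUE)
  out
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = unname(as.character(x)))
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param df A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path) {
  stopifnot(all(c("id", "seq") %in% names(df)))
  x <- Biostrings::DNAStringSet(setNames(df$seq, df$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
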