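# Unit-table TSV I/O, pipeline configuration and run manifests.
#
# Unit-table dialect: tab-separated, UTF-8, "." decimal, literal "NA" for
# missing; columns `region_id`, `unit_id`, optional `member_sites`
# (comma-separated CpG positions), then one column per sample named
# "<species>:<sample>". Any other column is carried through as row metadata.

#' Read a CpG-unit methylation table
#'
#' @param path Path to a unit-table TSV (format above).
#' @return A long tibble with columns `region_id`, `unit_id`, metadata
#'   columns, `species`, `sample`, `meth`. Values are validated to `[0, 1]`.
#'   An empty file yields an empty tibble with a warning.
#' @export
read_unit_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE, na = "NA")
  empty <- tibble(region_id = character(), unit_id = character(),
                  species = character(), sample = character(),
                  meth = numeric())
  if (nrow(df) == 0L) {
    warning("empty unit table: ", path, call. = FALSE)
    return(empty)
  }
  if (!all(c("region_id", "unit_id") %in% names(df))) {
    stop("unit table needs region_id and unit_id columns: ", path,
         call. = FALSE)
  }
  dup <- duplicated(df[c("region_id", "unit_id")])
  if (any(dup)) {
    stop("duplicate unit ids in ", path, " (row ", which(dup)[1] + 1L, ")",
         call. = FALSE)
  }
  sample_cols <- grep("^[^:]+:[^:]+$", names(df), value = TRUE)
  if (length(sample_cols) == 0L) {
    stop("no sample columns (named species:sample) in ", path, call. = FALSE)
  }
  long <- df |>
    dplyr::mutate(dplyr::across(dplyr::all_of(sample_cols), as.numeric)) |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols), names_to = "declared",
                        values_to = "meth") |>
    tidyr::separate("declared", into = c("species", "sample"), sep = ":")
  bad <- which(!is.na(long$meth) & (long$meth < 0 | long$meth > 1))
  if (length(bad)) {
    stop("methylation value out of [0,1] in ", path, " (unit ",
         long$unit_id[bad[1]], ", sample ", long$sample[bad[1]], ": ",
         long$meth[bad[1]], ")", call. = FALSE)
  }
  long
}

#' Write a CpG-unit methylation table
#'
#' @param units Long tibble as returned by [read_unit_table()] (columns
#'   `region_id`, `unit_id`, optional `member_sites`, `species`, `sample`,
#'   `meth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unit_table <- function(units, path) {
  units <- as_tibble(units)
  stopifnot(all(c("region_id", "unit_id", "species", "sample", "meth")
                %in% names(units)))
  wide <- units |>
    tidyr::unite("declared", "species", "sample", sep = ":") |>
    tidyr::pivot_wider(names_from = "declared", values_from = "meth")
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Pipeline configuration defaults
#'
#' Bundles every tunable constant of the analysis: promoter geometry,
#' region-design filters, windowing, DMR criteria, binning, lineage
#' threshold. Serializes losslessly to JSON via [write_manifest()].
#'
#' @param window_size Profile window (bp). Default 540.
#' @param promoter_start,promoter_end Promoter span relative to the TSS
#'   (defaults -2200 and +500; length must equal `target_region`).
#' @param min_region,target_region Region-design length filter and final
#'   design length (bp); defaults 1700 and 2700.
#' @param max_hits Maximum alignment hits per query in
#'   [select_orthologous_regions()]. Default 1.
#' @param unit_max_gap CpG-unit grouping gap (bp). Default 15.
#' @param diff_threshold,alpha,correction DMR criteria (see
#'   [test_config()]).
#' @param min_bin_size Minimum regions per CpGo/e bin. Default 40.
#' @param delta Lineage-classification threshold. Default 0.2.
#' @param seed Integer seed announced in every manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_size = 540L, promoter_start = -2200L,
                            promoter_end = 500L, min_region = 1700L,
                            target_region = 2700L, max_hits = 1L,
                            unit_max_gap = 15L, diff_threshold = 0.2,
                            alpha = 0.05,
                            correction = "benjamini_hochberg",
                            min_bin_size = 40L, delta = 0.2, seed = 1L) {
  cfg <- list(window_size = window_size, promoter_start = promoter_start,
              promoter_end = promoter_end, min_region = min_region,
              target_region = target_region, max_hits = max_hits,
              unit_max_gap = unit_max_gap, diff_threshold = diff_threshold,
              alpha = alpha, correction = correction,
              min_bin_size = min_bin_size, delta = delta,
              seed = as.integer(seed))
  if (promoter_end - promoter_start != target_region) {
    stop("promoter span must equal target_region", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a JSON run manifest
#'
#' Records the resolved configuration, the seed, the package version and
#' the output files of a run, sufficient to re-run bit-identically.
#'
#' @param config A `pipeline_config` or `sim_config`.
#' @param path Output JSON path.
#' @param files Optional character vector of files produced by the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, files = character()) {
  jsonlite::write_json(
    list(package = "orthomethr",
         version = as.character(utils::packageVersion("orthomethr")),
         config = unclass(config),
         files = files),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a manifest back
#' @param path Manifest JSON path.
#' @return A list.
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
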