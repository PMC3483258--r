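# Promoter-profile analyses: fixed-width windows over promoter regions,
# binning by CpG observed/expected ratio, and rank correlations of
# methylation with CpG density and with expression.

#' Tile a promoter region into windows
#'
#' Left-aligned tiling from the region 5' end. With the promoter span used
#' throughout (default -2200 bp to +500 bp around the TSS), each window gets
#' its signed distance to the TSS and the window whose midpoint is closest
#' to the TSS is flagged.
#'
#' @param region_length Region length in bp (default 2700).
#' @param size,step Window size and step in bp; defaults 540/540 give
#'   contiguous windows (five of them for a 2700 bp region).
#' @param promoter_start Signed offset of the region 5' end relative to the
#'   TSS (default -2200).
#' @return A tibble with `window`, `start`, `end` (0-based half-open, region
#'   coordinates), `tss_start`, `tss_end` (TSS-relative), and
#'   `closest_to_tss`.
#' @examples
#' make_windows(2700)
#' @export
make_windows <- function(region_length = 2700L, size = 540L, step = size,
                         promoter_start = -2200L) {
  if (size > region_length) {
    stop("window size exceeds the region length", call. = FALSE)
  }
  stopifnot(size > 0, step > 0)
  starts <- seq(0L, region_length - size, by = step)
  out <- tibble(window = seq_along(starts),
                start = starts, end = starts + size,
                tss_start = starts + promoter_start,
                tss_end = starts + size + promoter_start)
  mid <- (out$tss_start + out$tss_end) / 2
  out$closest_to_tss <- abs(mid) == min(abs(mid))
  out
}

#' Bin regions by CpG observed/expected ratio
#'
#' Half-open bins `[x, x + width)` on the CpGo/e value computed on the
#' TSS-proximal window; bins holding fewer than `min_bin_size` regions are
#' dropped. The bin label is the lower bound (a label of 0.2 means CpGo/e
#' in [0.2, 0.3) at the default width).
#'
#' @param data A tibble with columns `cpg_oe` and `meth` (one row per
#'   region).
#' @param width Bin width (default 0.1).
#' @param min_bin_size Minimum regions per retained bin (default 40).
#' @return A tibble (`bin`, `n`, `mean_meth`), ascending in `bin`.
#' @export
bin_by_cpgoe <- function(data, width = 0.1, min_bin_size = 40L) {
  data <- as_tibble(data)
  stopifnot(all(c("cpg_oe", "meth") %in% names(data)), width > 0)
  data |>
    dplyr::mutate(bin = floor(.data$cpg_oe / width) * width) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_meth = mean(.data$meth, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_bin_size) |>
    dplyr::arrange(.data$bin)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value from the asymptotic t approximation
#' (the default), or the exact permutation distribution for `n <= 10`
#' without ties. Thin wrapper over [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors, `n >= 4` complete pairs.
#' @param exact Use the exact null distribution (only for small tie-free
#'   samples).
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  tibble(rho = unname(fit$estimate), p_value = fit$p.value, n = length(x))
}

#' Per-window methylation-expression correlation profile
#'
#' Spearman correlation between window-level promoter methylation and gene
#' expression, computed per window index across regions. Mirrors the sliding
#' window analysis relating methylation at different distances from the TSS
#' to expression.
#'
#' @param window_meth Tibble (`region_id`, `window`, `meth`).
#' @param expression Tibble (`region_id`, `expression`), one value per
#'   region (average over samples upstream if needed).
#' @return A tibble (`window`, `rho`, `p_value`, `n`).
#' @export
methylation_expression_profile <- function(window_meth, expression) {
  window_meth <- as_tibble(window_meth)
  expression <- as_tibble(expression)
  stopifnot(all(c("region_id", "window", "meth") %in% names(window_meth)),
            all(c("region_id", "expression") %in% names(expression)))
  shared <- intersect(window_meth$region_id, expression$region_id)
  if (length(shared) < 10L) {
    stop("need at least 10 regions shared between methylation and ",
         "expression tables (got ", length(shared), ")", call. = FALSE)
  }
  df <- dplyr::inner_join(window_meth, expression, by = "region_id")
  df |>
    dplyr::group_by(window = .data$window) |>
    dplyr::group_modify(\(d, key) spearman_cor(d$meth, d$expression)) |>
    dplyr::ungroup()
}

#' Plot a binned CpG-density/methylation profile
#'
#' @param data Output of [bin_by_cpgoe()].
#' @return A ggplot object (bar chart of mean methylation per CpGo/e bin).
#' @export
plot_cpgoe_profile <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = factor(round(.data$bin, 2)),
                                     y = .data$mean_meth)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "CpG o/e bin (lower bound)", y = "mean methylation") +
    ggplot2::theme_minimal()
}
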