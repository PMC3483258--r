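# Region- and unit-level cross-species differential methylation:
# NA-tolerant means, pooled-variance two-sample t test, multiple-testing
# correction, and the two-criterion DMR call (|delta| > threshold AND
# adjusted p < alpha).

#' Differential-methylation test configuration
#'
#' @param diff_threshold Minimum absolute between-species difference for a
#'   DMR call (strict `>`). Default 0.2.
#' @param alpha Significance level on the adjusted p (strict `<`). Default
#'   0.05.
#' @param correction Multiple-testing correction: `"benjamini_hochberg"`
#'   (default) or `"bonferroni"`.
#' @param min_samples_per_species Minimum non-missing samples per species for
#'   a comparison; fewer and the comparison is skipped with a reason.
#'   Default 2.
#' @param test `"pooled_t"` (pooled-variance Student t, default) or
#'   `"welch_t"`.
#' @return A list of class `test_config`.
#' @export
test_config <- function(diff_threshold = 0.2, alpha = 0.05,
                        correction = c("benjamini_hochberg", "bonferroni"),
                        min_samples_per_species = 2L,
                        test = c("pooled_t", "welch_t")) {
  stopifnot(alpha > 0, alpha < 1, diff_threshold >= 0, diff_threshold <= 1,
            min_samples_per_species >= 1)
  structure(list(diff_threshold = diff_threshold, alpha = alpha,
                 correction = match.arg(correction),
                 min_samples_per_species = as.integer(min_samples_per_species),
                 test = match.arg(test)),
            class = "test_config")
}

#' Two-sample t test with degenerate-case handling
#'
#' Pooled-variance Student t by default (df = nA + nB - 2), two-sided.
#' Missing values are dropped. When the pooled variance is exactly zero the
#' t distribution degenerates: a nonzero mean difference yields p = 0
#' (underflow sentinel), a zero difference p = 1.
#'
#' @param x,y Numeric vectors (at least 2 non-missing values each).
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) variance.
#' @return A tibble with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @examples
#' pooled_t_test(c(0.148, 0.145, 0.160), c(0.540, 0.540, 0.530))
#' @export
pooled_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 non-missing values per group", call. = FALSE)
  }
  d <- mean(x) - mean(y)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(tibble(statistic = if (d == 0) 0 else sign(d) * Inf,
                  df = length(x) + length(y) - 2,
                  p_value = if (d == 0) 1 else 0,
                  mean_x = mean(x), mean_y = mean(y)))
  }
  fit <- stats::t.test(x, y, var.equal = var_equal)
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni, via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @param n Number of tests in the adjustment universe; defaults to the
#'   number of non-missing p-values, but can be set larger when the vector is
#'   a subset of a wider batch.
#' @return Adjusted p-values, same length as `p`.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni"),
                           n = sum(!is.na(p))) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = switch(method, benjamini_hochberg = "BH",
                                     bonferroni = "bonferroni"), n = n)
}

#' Between-species difference of means
#'
#' `delta = mean(species_a samples) - mean(species_b samples)`, skipping
#' missing values; `NA` (with a warning-free reason attribute unavailable in
#' a bare number) when either species has fewer than `min_samples`
#' non-missing values.
#'
#' @param value Numeric vector of per-sample values.
#' @param species Character vector, same length, labelling each value.
#' @param species_a,species_b The two species to contrast (A minus B).
#' @param min_samples Minimum non-missing per species. Default 2.
#' @return A single number, or `NA` if a species has too few values.
#' @examples
#' species_difference(c(0.225, 0.235, 0.242, 0.951, 0.801, 0.738),
#'                    rep(c("human", "macaque"), each = 3),
#'                    "human", "macaque")
#' @export
species_difference <- function(value, species, species_a, species_b,
                               min_samples = 2L) {
  a <- value[species == species_a]; b <- value[species == species_b]
  if (sum(!is.na(a)) < min_samples || sum(!is.na(b)) < min_samples) {
    return(NA_real_)
  }
  mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
}

#' Per-sample region methylation means over paired units
#'
#' Averages each sample's unit values within a region, using only units that
#' are orthologously paired (when `keep` is supplied), skipping missing unit
#' values; the sample mean is missing when all of its unit values are
#' missing. Regions with zero paired units are dropped and reported in the
#' `dropped` attribute.
#'
#' @param units Long unit table: tibble with columns `region_id`, `unit_id`,
#'   `species`, `sample`, `meth`.
#' @param keep Optional tibble (`region_id`, `species`, `unit_id`) of units
#'   retained by orthologous pairing; `NULL` uses all units.
#' @return A tibble (`region_id`, `species`, `sample`, `mean_meth`,
#'   `n_units`).
#' @export
region_means <- function(units, keep = NULL) {
  units <- as_tibble(units)
  stopifnot(all(c("region_id", "unit_id", "species", "sample", "meth")
                %in% names(units)))
  all_regions <- unique(units$region_id)
  if (!is.null(keep)) {
    units <- dplyr::semi_join(units, as_tibble(keep),
                              by = c("region_id", "species", "unit_id"))
  }
  out <- units |>
    dplyr::group_by(.data$region_id, .data$species, .data$sample) |>
    dplyr::summarise(
      mean_meth = if (all(is.na(.data$meth))) NA_real_
                  else mean(.data$meth, na.rm = TRUE),
      n_units = dplyr::n(), .groups = "drop")
  attr(out, "dropped") <- setdiff(all_regions, unique(out$region_id))
  out
}

#' Cross-species differential-methylation test
#'
#' Runs the two-species comparison for every feature (region or paired CpG
#' unit group) in `data`: species means, difference, two-sample t test, and
#' a multiple-testing adjustment across all tested features, followed by the
#' two-criterion DMR verdict `|delta| > diff_threshold` AND
#' `p_adj < alpha` (both strict).
#'
#' @param data A tibble with columns `id`, `species`, `sample`, `value`
#'   (per-sample methylation means; `NA` allowed).
#' @param species_a,species_b Species to contrast (`delta` = A minus B).
#' @param config A [test_config()].
#' @return An object of class `dmr_comparison`; see [tidy.dmr_comparison()].
#' @export
diff_test <- function(data, species_a, species_b, config = test_config()) {
  data <- as_tibble(data)
  stopifnot(all(c("id", "species", "sample", "value") %in% names(data)))
  one <- function(df) {
    a <- df$value[df$species == species_a]
    b <- df$value[df$species == species_b]
    na_ok <- sum(!is.na(a)); nb_ok <- sum(!is.na(b))
    if (na_ok < config$min_samples_per_species ||
        nb_ok < config$min_samples_per_species) {
      return(tibble(mean_a = NA_real_, mean_b = NA_real_, delta = NA_real_,
                    n_a = na_ok, n_b = nb_ok, statistic = NA_real_,
                    df = NA_real_, p_value = NA_real_,
                    reason = "too_few_samples"))
    }
    tt <- pooled_t_test(a, b, var_equal = config$test == "pooled_t")
    tibble(mean_a = tt$mean_x, mean_b = tt$mean_y,
           delta = tt$mean_x - tt$mean_y, n_a = na_ok, n_b = nb_ok,
           statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
           reason = NA_character_)
  }
  res <- data |>
    dplyr::group_by(id = .data$id) |>
    dplyr::group_modify(\(df, key) one(df)) |>
    dplyr::ungroup()
  res$p_adj <- adjust_pvalues(res$p_value, config$correction)
  res$dmr <- !is.na(res$delta) & !is.na(res$p_adj) &
    abs(res$delta) > config$diff_threshold & res$p_adj < config$alpha
  structure(list(table = res, config = config,
                 species = c(a = species_a, b = species_b)),
            class = "dmr_comparison")
}

#' Apply the two-criterion DMR call to a comparison table
#'
#' @param comparisons A `dmr_comparison` or a tibble with columns `delta`
#'   and `p_adj`.
#' @param config A [test_config()] providing `diff_threshold` and `alpha`.
#' @return The input with a logical `dmr` column recomputed under `config`.
#' @export
call_dmrs <- function(comparisons, config = test_config()) {
  if (inherits(comparisons, "dmr_comparison")) {
    comparisons$config <- config
    comparisons$table <- call_dmrs(comparisons$table, config)
    return(comparisons)
  }
  comparisons <- as_tibble(comparisons)
  comparisons$dmr <- !is.na(comparisons$delta) & !is.na(comparisons$p_adj) &
    abs(comparisons$delta) > config$diff_threshold &
    comparisons$p_adj < config$alpha
  comparisons
}

#' Region-level DMR analysis from a unit table
#'
#' Convenience pipeline: per-sample region means over paired units, then
#' [diff_test()] across regions.
#'
#' @inheritParams region_means
#' @inheritParams diff_test
#' @export
region_compare <- function(units, species_a, species_b, keep = NULL,
                           config = test_config()) {
  rm <- region_means(units, keep = keep)
  out <- diff_test(
    dplyr::rename(rm, id = "region_id", value = "mean_meth"),
    species_a, species_b, config
  )
  out$level <- "region"
  out
}

#' Unit-level comparison of paired CpG unit groups
#'
#' For every paired (possibly merged) unit group, each sample's value is the
#' mean over the group's member units on that sample's species side (missing
#' values skipped); groups then go through [diff_test()], with adjustment
#' across all compared groups.
#'
#' @param units Long unit table (`region_id`, `unit_id`, `species`,
#'   `sample`, `meth`).
#' @param pairing A tibble mapping units to paired groups: columns
#'   `region_id`, `group_id`, `species`, `unit_id`.
#' @inheritParams diff_test
#' @export
unit_compare <- function(units, pairing, species_a, species_b,
                         config = test_config()) {
  units <- as_tibble(units)
  pairing <- as_tibble(pairing)
  stopifnot(all(c("region_id", "group_id", "species", "unit_id")
                %in% names(pairing)))
  grouped <- dplyr::inner_join(units, pairing,
                               by = c("region_id", "species", "unit_id"))
  per_sample <- grouped |>
    dplyr::group_by(.data$region_id, .data$group_id, .data$species,
                    .data$sample) |>
    dplyr::summarise(
      value = if (all(is.na(.data$meth))) NA_real_
              else mean(.data$meth, na.rm = TRUE),
      .groups = "drop") |>
    tidyr::unite("id", "region_id", "group_id", sep = "#", remove = FALSE)
  out <- diff_test(per_sample, species_a, species_b, config)
  out$table <- tidyr::separate(out$table, "id", into = c("region_id", "group_id"),
                               sep = "#", remove = FALSE)
  out$level <- "unit"
  out
}

#' @export
print.dmr_comparison <- function(x, ...) {
  g <- glance(x)
  cat("<dmr_comparison> ", g$n_tested, " ", x$level %||% "feature",
      "(s) tested, ", g$n_dmr, " DMR call(s) at |delta| > ",
      x$config$diff_threshold, ", adj. p < ", x$config$alpha, "\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Tidy / summarise a differential-methylation comparison
#'
#' `tidy()` returns the per-feature table (id, species means, `delta`, test
#' statistic, raw and adjusted p, `dmr` verdict, skip reason); `glance()` a
#' one-row summary.
#'
#' @param x A `dmr_comparison`.
#' @param ... Unused.
#' @export
tidy.dmr_comparison <- function(x, ...) x$table

#' @rdname tidy.dmr_comparison
#' @export
glance.dmr_comparison <- function(x, ...) {
  tibble(n_tested = sum(is.na(x$table$reason)),
         n_skipped = sum(!is.na(x$table$reason)),
         n_dmr = sum(x$table$dmr, na.rm = TRUE),
         diff_threshold = x$config$diff_threshold,
         alpha = x$config$alpha,
         correction = x$config$correction,
         test = x$config$test)
}

#' Volcano-style plot of a comparison
#'
#' Effect size (between-species difference) against `-log10` adjusted p,
#' with the two DMR decision thresholds drawn as dashed lines.
#'
#' @param object A `dmr_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_comparison <- function(object, ...) {
  df <- dplyr::filter(object$table, !is.na(.data$delta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$dmr)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$config$diff_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("methylation difference (%s - %s)",
                              object$species[["a"]], object$species[["b"]]),
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "DMR") +
    ggplot2::theme_minimal()
}

#' Write a comparison to TSV (and optionally a JSON summary)
#'
#' @param x A `dmr_comparison`.
#' @param path Output TSV path.
#' @param json_path Optional path for a JSON summary (glance + config).
#' @export
write_comparison <- function(x, path, json_path = NULL) {
  tab <- dplyr::mutate(
    tidy(x),
    dplyr::across(dplyr::any_of(c("mean_a", "mean_b", "delta")),
                  \(v) round(v, 3)),
    dplyr::across(dplyr::any_of(c("p_value", "p_adj")), \(v) signif(v, 2))
  )
  readr::write_tsv(tab, path, na = "NA", progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(c(as.list(glance(x)), unclass(x$config)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
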