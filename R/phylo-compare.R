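# Lineage-specific methylation classification over >= 3 species with an
# outgroup, operationalizing the qualitative gain/loss patterns of
# multi-species bisulfite comparisons.

#' Classify a lineage-specific methylation pattern
#'
#' Given one mean methylation level per species and a rooted tree with a
#' designated outgroup, decides between: `no_change` (all pairwise
#' differences within `delta`); a single-species `lineage_specific_increase`
#' or `lineage_specific_decrease` — exactly one ingroup species deviates
#' from the median of the remaining species by more than `delta` while the
#' remaining species span at most `delta`; `multi_species_divergence`
#' otherwise; and `unresolved` when a deviant exists but the outgroup has no
#' value, so the direction of change cannot be polarized. The median (not
#' the mean) of the non-focal species is used for robustness with only a
#' few comparators.
#'
#' @param data Tibble with columns `species` and `meth` (one value per
#'   species, in `[0, 1]`), or a named numeric vector.
#' @param tree A rooted tree (`ape::phylo` or a newick string) containing
#'   the species; only the tip set is used.
#' @param outgroup Name of the outgroup species (may be absent from `data`,
#'   e.g. when no orthologous region exists in that genome).
#' @param delta Deviation threshold on the methylation scale; defaults to
#'   the DMR effect threshold 0.2. This numeric rule is this package's
#'   operationalization of an otherwise qualitative classification.
#'
#' @return A one-row tibble: `pattern`, `focal_species`, `effect_size`
#'   (signed deviation of the focal species from the median of the others),
#'   `n_species`.
#' @examples
#' classify_lineage_pattern(
#'   c(human = 0.2, chimp = 0.85, macaque = 0.9, rat = 0.8),
#'   tree = "(((human,chimp),macaque),rat);", outgroup = "rat"
#' )
#' @export
classify_lineage_pattern <- function(data, tree = NULL, outgroup = NULL,
                                     delta = 0.2) {
  if (is.numeric(data)) {
    data <- tibble(species = names(data), meth = unname(data))
  }
  data <- as_tibble(data)
  stopifnot(all(c("species", "meth") %in% names(data)),
            delta > 0, delta < 1)
  data <- dplyr::filter(data, !is.na(.data$meth))
  if (anyDuplicated(data$species)) {
    stop("one methylation value per species required", call. = FALSE)
  }
  if (nrow(data) < 3L) {
    stop("classification needs at least 3 species with data", call. = FALSE)
  }
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    missing_sp <- setdiff(data$species, tree$tip.label)
    if (length(missing_sp)) {
      stop("species not in tree: ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    }
  }
  vals <- setNames(data$meth, data$species)
  outgroup_present <- !is.null(outgroup) && outgroup %in% names(vals)
  ingroup <- if (!is.null(outgroup)) setdiff(names(vals), outgroup)
             else names(vals)

  if (diff(range(vals)) <= delta) {
    return(tibble(pattern = "no_change", focal_species = NA_character_,
                  effect_size = NA_real_, n_species = length(vals)))
  }
  dev <- purrr::map_dfr(ingroup, function(sp) {
    rest <- vals[setdiff(names(vals), sp)]
    tibble(species = sp,
           deviation = vals[[sp]] - median(rest),
           rest_range = diff(range(rest)))
  })
  hits <- dplyr::filter(dev, abs(.data$deviation) > delta,
                        .data$rest_range <= delta)
  if (nrow(hits) == 1L) {
    if (!outgroup_present && !is.null(outgroup)) {
      return(tibble(pattern = "unresolved",
                    focal_species = hits$species,
                    effect_size = hits$deviation, n_species = length(vals)))
    }
    return(tibble(
      pattern = if (hits$deviation > 0) "lineage_specific_increase"
                else "lineage_specific_decrease",
      focal_species = hits$species, effect_size = hits$deviation,
      n_species = length(vals)))
  }
  tibble(pattern = "multi_species_divergence", focal_species = NA_character_,
         effect_size = NA_real_, n_species = length(vals))
}

#' Classify many regions at once
#'
#' @param data Tibble with columns `region_id`, `species`, `meth`.
#' @inheritParams classify_lineage_pattern
#' @return One row per region: the [classify_lineage_pattern()] output plus
#'   `region_id`.
#' @export
classify_lineages <- function(data, tree = NULL, outgroup = NULL,
                              delta = 0.2) {
  as_tibble(data) |>
    dplyr::group_by(region_id = .data$region_id) |>
    dplyr::group_modify(\(d, key)
      classify_lineage_pattern(d[c("species", "meth")], tree = tree,
                               outgroup = outgroup, delta = delta)) |>
    dplyr::ungroup()
}

#' Plot per-species methylation for a set of regions
#'
#' @param data Tibble (`region_id`, `species`, `meth`), optionally with a
#'   `se` column drawn as error bars.
#' @return A ggplot object, one panel per region.
#' @export
plot_lineage_methylation <- function(data) {
  data <- as_tibble(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$species, y = .data$meth)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~region_id) +
    ggplot2::labs(x = NULL, y = "methylation level") +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
  if ("se" %in% names(data)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$meth - .data$se, ymax = .data$meth + .data$se),
      width = 0.2)
  }
  p
}
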