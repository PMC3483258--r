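# Orthologous CpG-unit pairing. A CpG unit (the minimum readout of
# MassARRAY/EpiTYPER-style assays) is one or several consecutive CpG sites
# measured as a single value. Units of two species are paired through
# orthologous CpG sites; because sites can be lost on either lineage, several
# short units on one side may need to be merged to pair a longer unit on the
# other side. The pairing is the connected components of the bipartite
# unit graph induced by orthologous site pairs, with eligibility checks.

#' Group CpG sites into units
#'
#' Groups consecutive CpG sites whose inter-site distance is below
#' `max_gap` into one unit — a proxy for assay fragmentation, which
#' determines real CpG units.
#'
#' @param sites Integer vector of CpG positions (0-based, C of the CpG), or a
#'   tibble from [find_cpg_sites()].
#' @param max_gap Sites closer than this many bp join one unit (strict `<`).
#'   Default 15.
#' @return A tibble with columns `unit_id` (1-based, 5' to 3') and `pos`,
#'   one row per site.
#' @export
group_cpg_units <- function(sites, max_gap = 15L) {
  pos <- if (is.data.frame(sites)) sites$pos else as.integer(sites)
  pos <- sort(unique(pos))
  if (length(pos) == 0L) return(fast_tbl(unit_id = integer(), pos = integer()))
  new_unit <- c(TRUE, diff(pos) >= max_gap)
  fast_tbl(unit_id = cumsum(new_unit), pos = pos)
}

check_units <- function(units, arg) {
  units <- as_tibble(units)
  if (!all(c("unit_id", "pos") %in% names(units))) {
    stop("`", arg, "` needs columns unit_id, pos", call. = FALSE)
  }
  if (anyDuplicated(units$pos)) {
    stop("`", arg, "`: a site belongs to more than one unit", call. = FALSE)
  }
  # units must partition sites into consecutive runs
  u <- units[order(units$pos), ]
  runs <- rle(as.vector(u$unit_id))
  if (anyDuplicated(runs$values)) {
    stop("`", arg, "`: units overlap (not consecutive runs of sites)",
         call. = FALSE)
  }
  units
}

#' Pair CpG units across two species
#'
#' Builds a bipartite graph with one edge per orthologous site pair linking
#' the unit containing the site in species A to the unit containing it in
#' species B. Connected components with at least one edge become one paired
#' (merged) unit group per side. A component is rejected when a member
#' site's orthologous counterpart is a CpG that lies outside the component:
#' in a unit of another component (`conflicting_partner`) or in no measured
#' unit at all (`ineligible_counterpart`) — in both cases the "pairable"
#' definition (every unmatched site lacks a CpG on the counterpart) is
#' violated. Units with no orthologous site are excluded with reason
#' `no_orthologous_site`.
#'
#' @param units_a,units_b Unit tibbles (`unit_id`, `pos`) as from
#'   [group_cpg_units()]; the measured units of each species.
#' @param site_pairs Orthologous site pairs (`pos_a`, `pos_b`) as from
#'   [map_orthologous_sites()]. Pairs may involve CpG sites outside the
#'   measured units; these make the adjacent component ineligible.
#'
#' @return A list of class `paired_units`: `groups`, a tibble with
#'   `group_id`, list-columns `units_a`/`units_b` (member unit ids) and
#'   `sites_a`/`sites_b` (member site positions), and `n_site_pairs`;
#'   `excluded`, a tibble (`species`, `unit_id`, `reason`).
#' @export
pair_cpg_units <- function(units_a, units_b, site_pairs) {
  units_a <- check_units(units_a, "units_a")
  units_b <- check_units(units_b, "units_b")
  site_pairs <- as_tibble(site_pairs)

  ua_ids <- sort(unique(units_a$unit_id))
  ub_ids <- sort(unique(units_b$unit_id))
  unit_of_a <- setNames(units_a$unit_id, units_a$pos)
  unit_of_b <- setNames(units_b$unit_id, units_b$pos)

  # edges between measured units; pairs touching unmeasured CpGs kept aside
  ea <- unname(unit_of_a[as.character(site_pairs$pos_a)])
  eb <- unname(unit_of_b[as.character(site_pairs$pos_b)])
  measured <- !is.na(ea) & !is.na(eb)

  # connected components over the bipartite unit graph (label propagation)
  lab_a <- setNames(seq_along(ua_ids), ua_ids)
  lab_b <- setNames(seq_along(ub_ids) + length(ua_ids), ub_ids)
  if (any(measured)) {
    pa <- as.character(ea[measured]); pb <- as.character(eb[measured])
    repeat {
      joint <- pmin(lab_a[pa], lab_b[pb])
      changed <- FALSE
      for (i in seq_along(joint)) {
        if (lab_a[pa[i]] > joint[i]) { lab_a[pa[i]] <- joint[i]; changed <- TRUE }
        if (lab_b[pb[i]] > joint[i]) { lab_b[pb[i]] <- joint[i]; changed <- TRUE }
      }
      if (!changed) break
    }
  }

  edge_units_a <- unique(ea[measured]); edge_units_b <- unique(eb[measured])
  excl_species <- character(); excl_unit <- list(); excl_reason <- character()
  g_units_a <- list(); g_units_b <- list(); g_sites_a <- list()
  g_sites_b <- list(); g_pairs <- integer()
  gid <- 0L

  comp_a <- lab_a[as.character(ua_ids)]
  comp_b <- lab_b[as.character(ub_ids)]
  pair_unmeasured <- is.na(ea) | is.na(eb)
  for (lab in sort(unique(c(lab_a[as.character(edge_units_a)],
                            lab_b[as.character(edge_units_b)])))) {
    mem_a <- ua_ids[comp_a == lab]
    mem_b <- ub_ids[comp_b == lab]
    sa <- units_a$pos[units_a$unit_id %in% mem_a]
    sb <- units_b$pos[units_b$unit_id %in% mem_b]
    in_comp <- measured & ea %in% mem_a & eb %in% mem_b
    # eligibility: any member site whose counterpart CpG escapes the component
    touch <- (site_pairs$pos_a %in% sa) | (site_pairs$pos_b %in% sb)
    stray <- touch & !in_comp
    if (any(stray)) {
      reason <- if (any(stray & !pair_unmeasured)) "conflicting_partner"
                else "ineligible_counterpart"
      excl_species <- c(excl_species, rep("A", length(mem_a)),
                        rep("B", length(mem_b)))
      excl_unit <- c(excl_unit, list(mem_a), list(mem_b))
      excl_reason <- c(excl_reason,
                       rep(reason, length(mem_a) + length(mem_b)))
      next
    }
    gid <- gid + 1L
    g_units_a[[gid]] <- mem_a; g_units_b[[gid]] <- mem_b
    g_sites_a[[gid]] <- sort(sa); g_sites_b[[gid]] <- sort(sb)
    g_pairs[gid] <- sum(in_comp)
  }

  no_edge_a <- setdiff(ua_ids, edge_units_a)
  no_edge_b <- setdiff(ub_ids, edge_units_b)
  excl_species <- c(excl_species, rep("A", length(no_edge_a)),
                    rep("B", length(no_edge_b)))
  excl_unit <- c(excl_unit, list(no_edge_a), list(no_edge_b))
  excl_reason <- c(excl_reason,
                   rep("no_orthologous_site",
                       length(no_edge_a) + length(no_edge_b)))

  structure(list(
    groups = fast_tbl(group_id = seq_len(gid),
                      units_a = g_units_a, units_b = g_units_b,
                      sites_a = g_sites_a, sites_b = g_sites_b,
                      n_site_pairs = g_pairs),
    excluded = fast_tbl(species = excl_species,
                        unit_id = unlist(excl_unit) %||% integer(),
                        reason = excl_reason)
  ), class = "paired_units")
}

#' @export
print.paired_units <- function(x, ...) {
  cat("<paired_units> ", nrow(x$groups), " paired group(s), ",
      nrow(x$excluded), " excluded unit(s)\n", sep = "")
  invisible(x)
}

#' Tidy a paired-unit set
#'
#' @param x A `paired_units` object.
#' @param ... Unused.
#' @return One row per unit per species with its fate: `group_id` for paired
#'   units, `reason` for excluded ones.
#' @export
tidy.paired_units <- function(x, ...) {
  paired <- dplyr::bind_rows(
    tidyr::unnest(dplyr::select(x$groups, "group_id", unit_id = "units_a"),
                  "unit_id") |> dplyr::mutate(species = "A"),
    tidyr::unnest(dplyr::select(x$groups, "group_id", unit_id = "units_b"),
                  "unit_id") |> dplyr::mutate(species = "B")
  )
  dplyr::bind_rows(
    dplyr::mutate(paired, status = "paired", reason = NA_character_),
    dplyr::mutate(x$excluded, status = "excluded", group_id = NA_integer_)
  ) |>
    dplyr::arrange(.data$species, .data$unit_id) |>
    dplyr::select("species", "unit_id", "status", "group_id", "reason")
}

#' Stack per-region pairings into a unit-to-group mapping
#'
#' Converts a named list of [pair_cpg_units()] results (one per region) into
#' the long mapping consumed by [unit_compare()] and [region_means()].
#'
#' @param pairings Named list of `paired_units`, names = region ids.
#' @param species_a,species_b Species names to substitute for the A/B sides.
#' @return A tibble (`region_id`, `group_id`, `species`, `unit_id`).
#' @export
pairing_table <- function(pairings, species_a, species_b) {
  purrr::imap_dfr(pairings, function(p, rid) {
    td <- dplyr::filter(tidy(p), .data$status == "paired")
    tibble(region_id = rid, group_id = td$group_id,
           species = ifelse(td$species == "A", species_a, species_b),
           unit_id = td$unit_id)
  })
}

#' Write a paired-unit table to TSV
#'
#' @param x A `paired_units` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_units <- function(x, path) {
  flat <- function(v) purrr::map_chr(v, \(z) paste(z, collapse = ","))
  g <- dplyr::mutate(x$groups,
                     units_a = flat(.data$units_a), units_b = flat(.data$units_b),
                     sites_a = flat(.data$sites_a), sites_b = flat(.data$sites_b))
  out <- dplyr::left_join(tidy(x), dplyr::select(g, "group_id", "units_a",
                                                 "units_b", "sites_a", "sites_b"),
                          by = "group_id")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
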