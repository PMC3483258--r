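# Seeded synthetic-data generator. Emulates the statistical structure the
# cross-species analysis assumes: orthologous promoter sequences diverging
# by CpG loss along a species tree, CpG-unit-level methylation readouts with
# between-species shifts at designated DMRs, beta-distributed individual
# variation, missingness, and expression negatively coupled to promoter
# methylation. It does not emulate enrichment/array signal or sequencing
# reads.

#' Simulation configuration
#'
#' Holds the study-design constants of a simulated two-species (or
#' multi-species) promoter methylation comparison. Defaults mirror a
#' MassARRAY-style validation design: 2700 bp promoter regions spanning
#' -2200 bp to +500 bp around the TSS, 3 individuals per species, effect
#' size 0.4 at planted DMRs, beta concentration 50 (within-species spreads
#' of roughly 0.01-0.1).
#'
#' @param n_regions Number of promoter regions.
#' @param region_length Region length (bp); must be a multiple of
#'   `window_size`. Default 2700.
#' @param n_samples_per_species Individuals per species. Default 3.
#' @param dmr_fraction Fraction of regions planted as true DMRs.
#' @param dmr_effect Methylation shift applied to one species at a planted
#'   DMR, in `[0, 1]`. Default 0.4.
#' @param noise_concentration Beta concentration of individual variation
#'   (`Inf` = no noise). Default 50.
#' @param na_rate Probability a unit x sample value is masked missing.
#' @param cpg_loss_rate Per-branch probability an ancestral CpG site is lost
#'   (C to T change). A single value applies to every branch of the tree; a
#'   named vector (by tip) draws losses per tip path instead.
#' @param unit_max_gap CpG-unit grouping gap (bp), see [group_cpg_units()].
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param tree Newick string or `ape::phylo` with branch lengths; tips name
#'   the simulated species.
#' @param outgroup Optional outgroup tip; with 3+ tips, planted DMR shifts
#'   are assigned to ingroup tips only.
#' @param window_size Profile window (bp), used to validate
#'   `region_length`. Default 540.
#' @param expression_intercept,expression_slope,expression_sd Parameters of
#'   the expression link `expr = intercept - slope * methylation + noise`;
#'   `expression_slope > 0` enforces the negative coupling.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 100L, region_length = 2700L,
                       n_samples_per_species = 3L, dmr_fraction = 0.1,
                       dmr_effect = 0.4, noise_concentration = 50,
                       na_rate = 0.02, cpg_loss_rate = 0.05,
                       unit_max_gap = 15L, seed = 1L,
                       tree = "(human:1,macaque:1);", outgroup = NULL,
                       window_size = 540L, expression_intercept = 8,
                       expression_slope = 4, expression_sd = 0.5) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree) || !inherits(tree, "phylo") || length(tree$tip.label) < 2) {
    stop("configuration error: `tree` must resolve to a tree with >= 2 tips",
         call. = FALSE)
  }
  props <- c(dmr_fraction = dmr_fraction, dmr_effect = dmr_effect,
             na_rate = na_rate)
  if (any(props < 0 | props > 1)) {
    stop("configuration error: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "),
         " must lie in [0, 1]", call. = FALSE)
  }
  if (any(cpg_loss_rate < 0 | cpg_loss_rate > 1)) {
    stop("configuration error: cpg_loss_rate must lie in [0, 1]",
         call. = FALSE)
  }
  if (region_length <= 0) {
    stop("configuration error: region_length must be positive", call. = FALSE)
  }
  if (region_length %% window_size != 0) {
    stop("configuration error: region_length must be a multiple of ",
         "window_size", call. = FALSE)
  }
  stopifnot(n_regions >= 1, n_samples_per_species >= 1,
            noise_concentration > 0, unit_max_gap >= 2,
            expression_slope > 0, expression_sd >= 0)
  if (!is.null(outgroup) && !outgroup %in% tree$tip.label) {
    stop("configuration error: outgroup not a tree tip", call. = FALSE)
  }
  structure(list(
    n_regions = as.integer(n_regions),
    region_length = as.integer(region_length),
    n_samples_per_species = as.integer(n_samples_per_species),
    dmr_fraction = dmr_fraction, dmr_effect = dmr_effect,
    noise_concentration = noise_concentration, na_rate = na_rate,
    cpg_loss_rate = cpg_loss_rate, unit_max_gap = as.integer(unit_max_gap),
    seed = as.integer(seed), tree = tree, outgroup = outgroup,
    window_size = as.integer(window_size),
    expression_intercept = expression_intercept,
    expression_slope = expression_slope, expression_sd = expression_sd
  ), class = "sim_config")
}

# one ancestral promoter: background flanks, CpG-island-like core (elevated
# G+C), incidental CpGs destroyed, then n_cpg CpG dinucleotides planted
# (70% in the core) so CpG o/e spans roughly 0.2-1.2 across regions
generate_ancestral <- function(L, target_oe) {
  core <- seq(floor(L / 3) + 1L, floor(2 * L / 3))
  s <- character(L)
  flank <- setdiff(seq_len(L), core)
  s[flank] <- sample(c("A", "C", "G", "T"), length(flank), replace = TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3))
  s[core] <- sample(c("A", "C", "G", "T"), length(core), replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2))
  cg <- which(s[-L] == "C" & s[-1] == "G")
  s[cg + 1L] <- "A"  # C->..A destroys the dinucleotide, cannot create one
  n_c <- sum(s == "C"); n_g <- sum(s == "G")
  n_cpg <- max(1L, round(target_oe * n_c * n_g / L))
  pool <- seq_len(L - 1L)
  w <- ifelse(pool %in% (core - 1L) | pool %in% core, 0.7, 0.3)
  cand <- sample(pool, min(length(pool), 4L * n_cpg), prob = w)
  keep <- integer(0)
  for (p in cand) {               # enforce >= 2 bp spacing between planted Cs
    if (length(keep) == n_cpg) break
    if (all(abs(keep - p) >= 2L)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  s[keep] <- "C"; s[keep + 1L] <- "G"
  list(seq = paste(s, collapse = ""), cpg_pos = keep - 1L)  # 0-based
}

# per-branch CpG loss along the tree; returns, per tip, the indices of lost
# ancestral sites
evolve_losses <- function(tree, n_sites, rate) {
  tips <- tree$tip.label
  if (!is.null(names(rate))) {
    missing_sp <- setdiff(tips, names(rate))
    if (length(missing_sp)) {
      stop("cpg_loss_rate names must cover every tip", call. = FALSE)
    }
    return(lapply(setNames(tips, tips),
                  \(sp) which(runif(n_sites) < rate[[sp]])))
  }
  n_nodes <- max(tree$edge)
  lost <- vector("list", n_nodes)
  root <- length(tips) + 1L
  lost[[root]] <- integer(0)
  remaining <- seq_len(nrow(tree$edge))
  while (length(remaining)) {
    progressed <- FALSE
    for (i in remaining) {
      parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
      if (!is.null(lost[[parent]])) {
        lost[[child]] <- union(lost[[parent]], which(runif(n_sites) < rate))
        remaining <- setdiff(remaining, i)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("tree edges do not connect to the root", call. = FALSE)
  }
  setNames(lapply(seq_along(tips), \(i) sort(lost[[i]])), tips)
}

#' Simulate orthologous promoter sequences
#'
#' Draws one ancestral promoter per region and evolves it along the
#' configured species tree: each ancestral CpG site is independently lost
#' (C to T) per branch with probability `cpg_loss_rate`; surviving sites
#' stay at their ancestral coordinates (no indel process), and their
#' cross-species orthology is recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_sequences`: `sequences` (tibble `species`,
#'   `region_id`, `id`, `seq`), `ancestral` (tibble `region_id`, `seq`,
#'   `cpg_oe`), `sites` (tibble `region_id`, `site_id`, `pos`, `species`,
#'   `retained`), and the `config`.
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tips <- config$tree$tip.label
  L <- config$region_length
  region_ids <- sprintf("region_%04d", seq_len(config$n_regions))

  anc <- vector("list", config$n_regions)
  seqs <- vector("list", config$n_regions)
  sites <- vector("list", config$n_regions)
  for (r in seq_len(config$n_regions)) {
    target_oe <- runif(1, 0.2, 1.2)
    a <- generate_ancestral(L, target_oe)
    n_sites <- length(a$cpg_pos)
    lost <- evolve_losses(config$tree, n_sites, config$cpg_loss_rate)
    chars <- strsplit(a$seq, "")[[1]]
    sp_seq <- vapply(tips, function(sp) {
      s <- chars
      if (length(lost[[sp]])) s[a$cpg_pos[lost[[sp]]] + 1L] <- "T"
      paste(s, collapse = "")
    }, character(1))
    anc[[r]] <- fast_tbl(region_id = region_ids[r], seq = a$seq,
                         cpg_oe = cpg_oe_ratio(a$seq))
    seqs[[r]] <- fast_tbl(species = tips, region_id = region_ids[r],
                          id = paste0(tips, "|", region_ids[r]),
                          seq = unname(sp_seq))
    sites[[r]] <- fast_tbl(
      region_id = region_ids[r],
      site_id = rep(seq_len(n_sites), length(tips)),
      pos = rep(a$cpg_pos, length(tips)),
      species = rep(tips, each = n_sites),
      retained = unlist(lapply(tips,
                               \(sp) !seq_len(n_sites) %in% lost[[sp]]))
    )
  }
  structure(list(sequences = dplyr::bind_rows(seqs),
                 ancestral = dplyr::bind_rows(anc),
                 sites = dplyr::bind_rows(sites),
                 config = config),
            class = "sim_sequences")
}

next_seed <- function(seed) {
  if (seed >= .Machine$integer.max) seed - 1L else seed + 1L
}

#' Simulate methylation, unit tables and expression
#'
#' Region baseline methylation is a decreasing logistic function of the
#' ancestral region's CpG o/e ratio (CpG-dense promoters are lowly
#' methylated). Planted DMR regions shift one species by `dmr_effect`; the
#' shift direction is random where both directions fit in `[0, 1]` and
#' otherwise points away from the nearer boundary (shifts that still leave
#' the interval are clipped and counted). Individual per-site values are
#' beta-distributed around the species mean with the configured
#' concentration; CpG-unit values average their member sites; unit x sample
#' entries are masked missing at `na_rate`; per-sample expression follows
#' `intercept - slope * (sample promoter methylation) + Gaussian noise`.
#'
#' @param config A [sim_config()].
#' @param seqs A `sim_sequences` from [simulate_sequences()] (defaults to
#'   simulating them from `config`).
#' @return A list of class `meth_sim` with elements `units` (long unit
#'   table), `site_values`, `true_region_means`, `dmr_truth`, `expression`,
#'   plus the `sim_sequences` fields; `n_clipped` counts clipped shifts.
#' @export
simulate_methylation <- function(config, seqs = simulate_sequences(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(seqs, "sim_sequences"))
  set.seed(next_seed(config$seed))
  tips <- config$tree$tip.label
  region_ids <- unique(seqs$ancestral$region_id)
  n_reg <- length(region_ids)
  n_samp <- config$n_samples_per_species
  conc <- config$noise_concentration

  baseline <- plogis(-4 * (seqs$ancestral$cpg_oe - 0.7))
  names(baseline) <- region_ids

  # planted DMRs: one affected (ingroup) species each, direction away from
  # the nearer boundary when only one direction fits
  n_dmr <- round(config$dmr_fraction * n_reg)
  dmr_regions <- if (n_dmr > 0) sort(sample(region_ids, n_dmr)) else character()
  eligible <- if (!is.null(config$outgroup) && length(tips) >= 3)
    setdiff(tips, config$outgroup) else tips
  mu <- matrix(rep(baseline, each = length(tips)), nrow = length(tips),
               dimnames = list(tips, region_ids))
  n_clipped <- 0L
  truth <- vector("list", length(dmr_regions))
  for (k in seq_along(dmr_regions)) {
    r <- dmr_regions[k]
    sp <- if (length(eligible) > 1) sample(eligible, 1) else eligible
    up_ok <- baseline[[r]] + config$dmr_effect <= 1
    dn_ok <- baseline[[r]] - config$dmr_effect >= 0
    sgn <- if (up_ok && dn_ok) sample(c(-1, 1), 1)
           else if (up_ok) 1 else if (dn_ok) -1 else sample(c(-1, 1), 1)
    shifted <- baseline[[r]] + sgn * config$dmr_effect
    clipped <- shifted < 0 || shifted > 1
    if (clipped) n_clipped <- n_clipped + 1L
    mu[sp, r] <- min(1, max(0, shifted))
    truth[[k]] <- tibble(region_id = r, species = sp, sign = sgn,
                         effect = config$dmr_effect, clipped = clipped)
  }
  if (n_clipped > 0) {
    warning(n_clipped, " DMR shift(s) clipped to [0, 1]", call. = FALSE)
  }

  sample_ids <- paste0("s", seq_len(n_samp))
  site_vals <- vector("list", n_reg * length(tips))
  unit_rows <- vector("list", n_reg * length(tips))
  expr_rows <- vector("list", n_reg * length(tips))
  idx <- 0L
  sites_by_region <- split(seqs$sites, seqs$sites$region_id)

  for (r in region_ids) {
    sr <- sites_by_region[[r]]
    for (sp in tips) {
      idx <- idx + 1L
      pos <- sr$pos[sr$species == sp & sr$retained]
      if (length(pos) == 0L) next
      m <- min(1 - 1e-3, max(1e-3, mu[sp, r]))
      vals <- if (is.infinite(conc)) {
        matrix(m, nrow = length(pos), ncol = n_samp)
      } else {
        matrix(rbeta(length(pos) * n_samp, m * conc, (1 - m) * conc),
               nrow = length(pos))
      }
      units <- group_cpg_units(pos, config$unit_max_gap)
      # unit value = mean of member-site values, per sample
      uval <- rowsum(vals, group = units$unit_id, reorder = TRUE) /
        as.vector(table(units$unit_id))
      n_units <- nrow(uval)
      if (config$na_rate > 0) {
        uval[runif(length(uval)) < config$na_rate] <- NA_real_
      }
      member <- vapply(split(units$pos, units$unit_id),
                       \(p) paste(p, collapse = ","), character(1))
      unit_rows[[idx]] <- fast_tbl(
        region_id = r,
        unit_id = rep(sprintf("u%02d", seq_len(n_units)), n_samp),
        member_sites = rep(unname(member), n_samp),
        species = sp,
        sample = rep(sample_ids, each = n_units),
        meth = as.vector(uval)
      )
      n_pos <- length(pos)
      site_vals[[idx]] <- fast_tbl(
        region_id = r, species = sp,
        pos = rep(pos, n_samp),
        sample = rep(sample_ids, each = n_pos),
        value = as.vector(vals)
      )
      sample_meth <- colMeans(vals)
      expr_rows[[idx]] <- fast_tbl(
        region_id = r, species = sp, sample = sample_ids,
        meth = sample_meth,
        expression = config$expression_intercept -
          config$expression_slope * sample_meth +
          rnorm(n_samp, 0, config$expression_sd)
      )
    }
  }

  structure(list(
    config = config,
    sequences = seqs$sequences, ancestral = seqs$ancestral,
    sites = seqs$sites,
    units = dplyr::bind_rows(unit_rows),
    site_values = dplyr::bind_rows(site_vals),
    true_region_means = tibble(
      region_id = rep(region_ids, each = length(tips)),
      species = rep(tips, n_reg),
      mu = as.vector(mu)),
    dmr_truth = if (length(truth)) dplyr::bind_rows(truth) else
      tibble(region_id = character(), species = character(),
             sign = numeric(), effect = numeric(), clipped = logical()),
    expression = dplyr::bind_rows(expr_rows),
    n_clipped = n_clipped
  ), class = "meth_sim")
}

#' One-call simulation wrapper
#'
#' @inheritParams simulate_methylation
#' @export
simulate_methylome <- function(config) {
  simulate_methylation(config, simulate_sequences(config))
}

#' @export
print.meth_sim <- function(x, ...) {
  cat("<meth_sim> ", x$config$n_regions, " regions x ",
      length(x$config$tree$tip.label), " species, ",
      nrow(x$dmr_truth), " planted DMR(s), seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' True orthologous site pairs of a simulation
#'
#' Sites retained in both named species; because the generator has no indel
#' process, orthologous sites share their ancestral coordinate.
#'
#' @param sim A `meth_sim` or `sim_sequences`.
#' @param species_a,species_b Species names (default: first two tips).
#' @return A tibble (`region_id`, `pos_a`, `pos_b`).
#' @export
true_site_pairs <- function(sim, species_a = NULL, species_b = NULL) {
  tips <- sim$config$tree$tip.label
  species_a <- species_a %||% tips[1]
  species_b <- species_b %||% tips[2]
  wide <- sim$sites |>
    dplyr::filter(.data$species %in% c(species_a, species_b)) |>
    tidyr::pivot_wider(names_from = "species", values_from = "retained")
  both <- wide[[species_a]] & wide[[species_b]]
  tibble(region_id = wide$region_id[both],
         pos_a = wide$pos[both], pos_b = wide$pos[both])
}

#' Pair the CpG units of a simulated dataset
#'
#' Runs [pair_cpg_units()] region by region on the simulation's true
#' orthologous site pairs (no alignment step is needed: the generator has
#' no indel process, so orthologous sites share coordinates), returning the
#' unit-to-group mapping in the generator's unit naming.
#'
#' @param sim A `meth_sim`.
#' @param species_a,species_b Species to pair (default: first two tips).
#' @return A tibble (`region_id`, `group_id`, `species`, `unit_id`)
#'   suitable for [unit_compare()] and the `keep` argument of
#'   [region_means()].
#' @export
pair_simulated_units <- function(sim, species_a = NULL, species_b = NULL) {
  tips <- sim$config$tree$tip.label
  species_a <- species_a %||% tips[1]
  species_b <- species_b %||% tips[2]
  tp <- true_site_pairs(sim, species_a, species_b)
  tp_by_region <- split(tp[c("pos_a", "pos_b")], tp$region_id)
  sa <- dplyr::filter(sim$sites, .data$species == species_a, .data$retained)
  sb <- dplyr::filter(sim$sites, .data$species == species_b, .data$retained)
  pos_a <- split(sa$pos, sa$region_id)
  pos_b <- split(sb$pos, sb$region_id)
  out <- lapply(unique(sim$sites$region_id), function(r) {
    pa <- pos_a[[r]]; pb <- pos_b[[r]]
    if (is.null(pa) || is.null(pb) || !length(pa) || !length(pb)) return(NULL)
    pu <- pair_cpg_units(
      group_cpg_units(pa, sim$config$unit_max_gap),
      group_cpg_units(pb, sim$config$unit_max_gap),
      tp_by_region[[r]] %||% tibble(pos_a = integer(), pos_b = integer())
    )
    g <- pu$groups
    na <- lengths(g$units_a); nb <- lengths(g$units_b)
    data.frame(
      region_id = r,
      group_id = c(rep(g$group_id, na), rep(g$group_id, nb)),
      species = c(rep(species_a, sum(na)), rep(species_b, sum(nb))),
      unit_id = c(unlist(g$units_a), unlist(g$units_b))
    )
  })
  out <- as_tibble(dplyr::bind_rows(out))
  out$unit_id <- sprintf("u%02d", as.integer(out$unit_id))
  out
}

#' Window-level methylation of a simulation
#'
#' Mean per-site methylation (over samples) within contiguous windows, per
#' region and species.
#'
#' @param sim A `meth_sim`.
#' @param size Window size (bp); defaults to the configured `window_size`.
#' @return A tibble (`region_id`, `species`, `window`, `meth`).
#' @export
window_methylation <- function(sim, size = sim$config$window_size) {
  stopifnot(inherits(sim, "meth_sim"))
  sim$site_values |>
    dplyr::mutate(window = floor(.data$pos / size) + 1L) |>
    dplyr::group_by(.data$region_id, .data$species, .data$window) |>
    dplyr::summarise(meth = mean(.data$value), .groups = "drop")
}

#' CpG o/e of each simulated region on a chosen window
#'
#' @param sim A `meth_sim` or `sim_sequences`.
#' @param species Species whose sequence to profile.
#' @param window `"tss"` (the TSS-proximal window under the configured
#'   promoter span), an integer window index, or `"full"`.
#' @param promoter_start Region 5' offset to the TSS. Default -2200.
#' @return A tibble (`region_id`, `cpg_oe`).
#' @export
region_cpgoe <- function(sim, species, window = "tss",
                         promoter_start = -2200L) {
  cfg <- sim$config
  seqs <- dplyr::filter(sim$sequences, .data$species == !!species)
  if (identical(window, "full")) {
    return(tibble(region_id = seqs$region_id,
                  cpg_oe = vapply(seqs$seq, cpg_oe_ratio, numeric(1),
                                  USE.NAMES = FALSE)))
  }
  grid <- make_windows(cfg$region_length, cfg$window_size,
                       promoter_start = promoter_start)
  w <- if (identical(window, "tss")) grid[grid$closest_to_tss, ][1, ]
       else grid[grid$window == window, ]
  sub <- substr(seqs$seq, w$start + 1L, w$end)
  tibble(region_id = seqs$region_id,
         cpg_oe = vapply(sub, cpg_oe_ratio, numeric(1), USE.NAMES = FALSE))
}

#' Write a simulated dataset to disk
#'
#' Per-species FASTA and unit-table TSV, a BED of region spans, truth and
#' expression TSVs, and a JSON manifest with the resolved configuration and
#' seed.
#'
#' @param sim A `meth_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "meth_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tips <- sim$config$tree$tip.label
  files <- character()
  for (sp in tips) {
    fa <- file.path(dir, paste0(sp, ".fasta"))
    write_fasta(dplyr::filter(sim$sequences, .data$species == sp), fa)
    ut <- file.path(dir, paste0(sp, "_units.tsv"))
    write_unit_table(dplyr::filter(sim$units, .data$species == sp), ut)
    files <- c(files, setNames(c(fa, ut), paste0(sp, c("_fasta", "_units"))))
  }
  bed <- file.path(dir, "regions.bed")
  write_bed(tibble(chrom = unique(sim$ancestral$region_id), start = 0,
                   end = sim$config$region_length,
                   name = unique(sim$ancestral$region_id)), bed)
  truth <- file.path(dir, "dmr_truth.tsv")
  readr::write_tsv(sim$dmr_truth, truth, na = "NA", progress = FALSE)
  expr <- file.path(dir, "expression.tsv")
  readr::write_tsv(sim$expression, expr, na = "NA", progress = FALSE)
  manifest <- file.path(dir, "manifest.json")
  cfg <- sim$config
  cfg$tree <- ape::write.tree(cfg$tree)
  write_manifest(cfg, manifest,
                 files = basename(c(files, bed, truth, expr)))
  files <- c(files, bed = bed, truth = truth, expression = expr,
             manifest = manifest)
  invisible(files)
}
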