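# one moderate simulation shared by several property checks
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_regions = 200, dmr_fraction = 0.1,
                        cpg_loss_rate = 0.2, na_rate = 0.05, seed = 81)
      cache <<- suppressWarnings(simulate_methylome(cfg))
    }
    cache
  }
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_regions = 6, seed = 5)
  s1 <- simulate_methylome(cfg)
  s2 <- simulate_methylome(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$units, s2$units)
  expect_identical(s1$expression, s2$expression)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the data
  s3 <- simulate_methylome(sim_config(n_regions = 6, seed = 6))
  expect_false(identical(s1$units$meth, s3$units$meth))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(dmr_fraction = 1.2), "dmr_fraction")
  expect_error(sim_config(region_length = 0), "positive")
  expect_error(sim_config(region_length = 1000, window_size = 540),
               "multiple")
  expect_error(sim_config(tree = NULL), "tree")
  expect_error(sim_config(tree = "(human:1,macaque:1);", outgroup = "rat"),
               "outgroup")
})

test_that("CpG loss limits behave as expected", {
  # no loss: both species carry the full ancestral site set
  cfg0 <- sim_config(n_regions = 3, cpg_loss_rate = 0, seed = 7)
  s0 <- simulate_sequences(cfg0)
  expect_true(all(s0$sites$retained))
  expect_equal(s0$sequences$seq[s0$sequences$species == "human"],
               s0$sequences$seq[s0$sequences$species == "macaque"])

  # saturated loss on one lineage: that species retains nothing
  cfg1 <- sim_config(n_regions = 3,
                     cpg_loss_rate = c(human = 0, macaque = 1), seed = 7)
  s1 <- simulate_sequences(cfg1)
  expect_true(all(s1$sites$retained[s1$sites$species == "human"]))
  expect_false(any(s1$sites$retained[s1$sites$species == "macaque"]))
  expect_equal(nrow(find_cpg_sites(
    s1$sequences$seq[s1$sequences$species == "macaque"][1])), 0L)
})

test_that("site retention stays within the binomial interval of the loss rate", {
  sim <- shared_sim()
  sites <- sim$sites
  for (sp in c("human", "macaque")) {
    kept <- sites$retained[sites$species == sp]
    n <- length(kept)
    ci <- qbinom(c(0.005, 0.995), n, 0.8) / n
    expect_gte(mean(kept), ci[1])
    expect_lte(mean(kept), ci[2])
  }
})

test_that("species sequences only differ from the ancestor at lost sites", {
  sim <- shared_sim()
  r <- sim$ancestral$region_id[1]
  anc <- strsplit(sim$ancestral$seq[1], "")[[1]]
  for (sp in c("human", "macaque")) {
    s <- strsplit(sim$sequences$seq[sim$sequences$region_id == r &
                                      sim$sequences$species == sp], "")[[1]]
    diffs <- which(anc != s)
    lost <- sim$sites[sim$sites$region_id == r & sim$sites$species == sp &
                        !sim$sites$retained, ]
    expect_equal(diffs, sort(lost$pos) + 1L)
    expect_true(all(s[diffs] == "T"))
  }
})

test_that("degenerate noise collapses unit values onto the species mean", {
  cfg <- sim_config(n_regions = 4, noise_concentration = Inf, na_rate = 0,
                    dmr_fraction = 0, seed = 9)
  sim <- simulate_methylome(cfg)
  joined <- dplyr::inner_join(sim$units, sim$true_region_means,
                              by = c("region_id", "species"))
  expect_true(all(abs(joined$meth - joined$mu) < 1e-12))
  expect_false(anyNA(sim$units$meth))
})

test_that("methylation values are valid fractions and NAs match the rate", {
  sim <- shared_sim()
  v <- sim$units$meth
  expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
  n <- length(v)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(mean(is.na(v)), ci[1])
  expect_lte(mean(is.na(v)), ci[2])
})

test_that("non-DMR regions share species-level means; DMR truth records sign", {
  sim <- shared_sim()
  mu <- tidyr::pivot_wider(sim$true_region_means, names_from = "species",
                           values_from = "mu")
  null_regions <- setdiff(mu$region_id, sim$dmr_truth$region_id)
  expect_true(all(mu$human[mu$region_id %in% null_regions] ==
                    mu$macaque[mu$region_id %in% null_regions]))
  joined <- dplyr::inner_join(sim$dmr_truth, mu, by = "region_id")
  shifted <- ifelse(joined$species == "human", joined$human, joined$macaque)
  other <- ifelse(joined$species == "human", joined$macaque, joined$human)
  expect_true(all(sign(shifted - other) == joined$sign))
  # unclipped shifts carry the full effect
  expect_true(all(abs((shifted - other)[!joined$clipped] - 0.4 *
                        joined$sign[!joined$clipped]) < 1e-12))
})

test_that("simulated methylation falls with CpG density and suppresses
           expression", {
  sim <- shared_sim()
  oe <- region_cpgoe(sim, "human", window = "tss")
  meth <- dplyr::summarise(
    dplyr::group_by(sim$units[sim$units$species == "human", ], region_id),
    meth = mean(meth, na.rm = TRUE), .groups = "drop")
  joined <- dplyr::inner_join(oe, meth, by = "region_id")
  ct <- spearman_cor(joined$cpg_oe, joined$meth)
  expect_lt(ct$rho, 0)
  expect_lt(ct$p_value, 1e-6)

  ex <- dplyr::summarise(
    dplyr::group_by(sim$expression[sim$expression$species == "human", ],
                    region_id),
    expression = mean(expression), .groups = "drop")
  em <- dplyr::inner_join(meth, ex, by = "region_id")
  expect_lt(spearman_cor(em$meth, em$expression)$rho, 0)
})

test_that("unit grouping in the generator respects the configured gap", {
  sim <- shared_sim()
  human_units <- dplyr::distinct(
    sim$units[sim$units$species == "human",
              c("region_id", "unit_id", "member_sites")])
  pos_lists <- lapply(strsplit(human_units$member_sites, ","), as.integer)
  # within a unit, consecutive sites are closer than the gap
  within_ok <- vapply(pos_lists, function(p)
    length(p) == 1 || all(diff(p) < 15), logical(1))
  expect_true(all(within_ok))
})

test_that("datasets write a complete, re-loadable bundle with a manifest", {
  cfg <- sim_config(n_regions = 4, seed = 13)
  sim <- simulate_methylome(cfg)
  dir <- withr::local_tempdir()
  files <- write_dataset(sim, dir)
  expect_true(all(file.exists(files)))

  units_back <- read_unit_table(files[["human_units"]])
  orig <- sim$units[sim$units$species == "human", ]
  expect_equal(nrow(units_back), nrow(orig))
  expect_equal(sort(unique(units_back$sample)), sort(unique(orig$sample)))

  fa <- read_fasta(files[["human_fasta"]])
  expect_equal(nrow(fa), 4L)
  expect_equal(nchar(fa$seq), rep(2700L, 4))

  man <- read_manifest(files[["manifest"]])
  expect_equal(man$config$seed, 13L)
  expect_equal(man$config$n_regions, 4L)
  expect_true("regions.bed" %in% man$files)
})
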