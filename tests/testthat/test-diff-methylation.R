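h_dmr8 <- c(0.148, 0.145, 0.160); m_dmr8 <- c(0.540, 0.540, 0.530)
h_dmr13 <- c(0.400, 0.355, 0.446); m_dmr13 <- c(0.183, 0.170, 0.130)

test_that("pooled t test reproduces published region-level p values", {
  expect_equal(signif(pooled_t_test(h_dmr8, m_dmr8)$p_value, 2), 2.8e-07)
  expect_equal(signif(pooled_t_test(h_dmr13, m_dmr13)$p_value, 2), 1.5e-03)
  expect_equal(pooled_t_test(h_dmr8, m_dmr8)$df, 4)

  # degenerate cases
  same <- pooled_t_test(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  flat <- pooled_t_test(c(0.1, 0.1), c(0.9, 0.9))
  expect_equal(flat$p_value, 0)          # zero variance, nonzero difference
  grp <- c(0.3, 0.5, 0.4)
  expect_equal(pooled_t_test(grp, grp)$p_value, 1)
  expect_error(pooled_t_test(0.5, c(0.1, 0.2)), "at least 2")
  # NA values are dropped before testing
  expect_equal(pooled_t_test(c(h_dmr8, NA), m_dmr8)$p_value,
               pooled_t_test(h_dmr8, m_dmr8)$p_value)
})

test_that("species differences match published values and are antisymmetric", {
  sp <- rep(c("human", "macaque"), each = 3)
  expect_equal(
    round(species_difference(c(0.225, 0.235, 0.242, 0.951, 0.801, 0.738),
                             sp, "human", "macaque"), 3), -0.596)
  expect_equal(round(species_difference(c(h_dmr13, m_dmr13), sp,
                                        "human", "macaque"), 3), 0.239)
  expect_equal(species_difference(c(h_dmr13, m_dmr13), sp,
                                  "macaque", "human"),
               -species_difference(c(h_dmr13, m_dmr13), sp,
                                   "human", "macaque"))
  expect_equal(species_difference(rep(0.4, 6), sp, "human", "macaque"), 0)
  # too few non-missing values in one species
  expect_true(is.na(species_difference(c(0.1, NA, NA, 0.5, 0.6, 0.7), sp,
                                       "human", "macaque")))
})

test_that("p-value adjustment matches reference implementations", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(signif(adjust_pvalues(6.22e-05, "bonferroni", n = 3), 2),
               1.9e-04)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(51)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    p[sample(length(p), 2)] <- NA
    expect_equal(adjust_pvalues(p), oracle_bh(p))
    # BH-adjusted p never below raw p
    ok <- !is.na(p)
    expect_true(all(adjust_pvalues(p)[ok] >= p[ok]))
  }
})

test_that("region means skip missing units and require paired units only", {
  units <- tibble::tibble(
    region_id = "r1",
    unit_id = rep(c("u1", "u2", "u3"), each = 2),
    species = "human",
    sample = rep(c("s1", "s2"), 3),
    meth = c(0.41, 0.2, NA, 0.3, 0.41, NA)
  )
  rm_all <- region_means(units)
  expect_equal(rm_all$mean_meth[rm_all$sample == "s1"], 0.41)  # NA skipped
  expect_equal(rm_all$mean_meth[rm_all$sample == "s2"], 0.25)

  keep <- tibble::tibble(region_id = "r1", species = "human",
                         unit_id = c("u1", "u2"))
  rm_kept <- region_means(units, keep = keep)
  expect_equal(rm_kept$n_units, c(2L, 2L))
  expect_equal(rm_kept$mean_meth[rm_kept$sample == "s2"], 0.25)

  # all units missing for a sample -> missing mean
  units$meth[units$sample == "s1"] <- NA
  expect_true(is.na(region_means(units)$mean_meth[1]))

  # region with zero paired units is dropped and reported
  none <- region_means(units, keep = keep[0, ])
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "dropped"), "r1")
})

test_that("the DMR verdict needs both a large effect and a small adjusted p", {
  data <- tibble::tibble(
    id = rep(c("big", "small_effect", "flat"), each = 6),
    species = rep(rep(c("human", "macaque"), each = 3), 3),
    sample = rep(paste0("s", 1:3), 6),
    value = c(0.225, 0.235, 0.242, 0.951, 0.801, 0.738,   # |delta| = 0.60
              0.400, 0.410, 0.405, 0.550, 0.552, 0.551,   # |delta| = 0.15
              0.50, 0.52, 0.48, 0.50, 0.51, 0.49)
  )
  res <- diff_test(data, "human", "macaque")
  tab <- generics::tidy(res)
  expect_true(tab$dmr[tab$id == "big"])
  expect_false(tab$dmr[tab$id == "small_effect"])  # p tiny but effect < 0.2
  expect_true(tab$p_adj[tab$id == "small_effect"] < 0.05)
  expect_false(tab$dmr[tab$id == "flat"])
  expect_equal(generics::glance(res)$n_dmr, 1L)

  # strict threshold: |delta| exactly 0.2 is not enough
  border <- tibble::tibble(delta = c(0.2, 0.21), p_adj = c(1e-6, 1e-6))
  expect_equal(call_dmrs(border)$dmr, c(FALSE, TRUE))
  alpha_edge <- tibble::tibble(delta = 0.5, p_adj = 0.05)
  expect_false(call_dmrs(alpha_edge)$dmr)
})

test_that("unit-level comparison reproduces published paired-unit rows", {
  mk <- function(id, h, m) tibble::tibble(
    region_id = "r", unit_id = paste0(id, "_u1"),
    species = rep(c("human", "macaque"), each = 3),
    sample = rep(paste0("s", 1:3), 2), meth = c(h, m), group = id
  )
  units <- dplyr::bind_rows(
    mk("g1", c(0.26, 0.24, 0.25), c(0.73, 0.72, 0.73)),
    mk("g2", c(0.01, 0.03, 0.03), c(0.77, 0.69, 0.60)),
    mk("g3", c(0.41, NA, 0.41), c(0.17, 0.12, 0.14)),
    mk("g4", c(0.1, NA, NA), c(0.2, 0.3, 0.4))
  )
  pairing <- dplyr::distinct(units[c("region_id", "group", "species",
                                     "unit_id")])
  names(pairing)[2] <- "group_id"
  res <- unit_compare(units[1:5], pairing, "human", "macaque")
  tab <- generics::tidy(res)
  expect_equal(round(tab$delta[tab$group_id == "g1"], 2), -0.48)
  expect_equal(signif(tab$p_value[tab$group_id == "g1"], 2), 2.3e-07)
  expect_equal(round(tab$delta[tab$group_id == "g2"], 2), -0.66)
  # one missing human sample: computed on the 2 remaining values
  expect_equal(round(tab$delta[tab$group_id == "g3"], 2), 0.27)
  expect_equal(tab$n_a[tab$group_id == "g3"], 2L)
  # below the 2-sample minimum: skipped with a reason
  expect_equal(tab$reason[tab$group_id == "g4"], "too_few_samples")
  expect_true(is.na(tab$p_value[tab$group_id == "g4"]))
})

test_that("merged unit groups average member units per sample", {
  units <- tibble::tibble(
    region_id = "r",
    unit_id = c("a1", "a1", "b1", "b1", "b2", "b2"),
    species = c("human", "human", "macaque", "macaque", "macaque", "macaque"),
    sample = c("s1", "s2", "s1", "s2", "s1", "s2"),
    meth = c(0.5, 0.6, 0.2, 0.4, 0.4, NA)
  )
  pairing <- tibble::tibble(region_id = "r", group_id = 1L,
                            species = c("human", "macaque", "macaque"),
                            unit_id = c("a1", "b1", "b2"))
  res <- unit_compare(units, pairing, "human", "macaque",
                      config = test_config(min_samples_per_species = 1))
  tab <- generics::tidy(res)
  # macaque s1 = mean(0.2, 0.4); s2 = 0.4 (NA member skipped)
  expect_equal(tab$mean_b, mean(c(0.3, 0.4)))
  expect_equal(tab$mean_a, 0.55)
})

test_that("comparison report writes rounded TSV plus JSON summary", {
  data <- tibble::tibble(
    id = rep("r1", 6),
    species = rep(c("human", "macaque"), each = 3),
    sample = rep(paste0("s", 1:3), 2),
    value = c(h_dmr8, m_dmr8)
  )
  res <- diff_test(data, "human", "macaque")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_comparison(res, tsv, js)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$delta, -0.386)
  expect_equal(back$p_value, 2.8e-07)
  expect_equal(jsonlite::read_json(js)$n_dmr, 1L)
})
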