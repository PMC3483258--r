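units_from <- function(...) {
  groups <- list(...)
  tibble::tibble(
    unit_id = rep(seq_along(groups), lengths(groups)),
    pos = unlist(groups)
  )
}

test_that("consecutive CpG sites group into units below the gap threshold", {
  u <- group_cpg_units(c(0, 5, 30, 40, 100), max_gap = 15)
  expect_equal(u$unit_id, c(1, 1, 2, 2, 3))
  # strict inequality: a gap of exactly max_gap starts a new unit
  expect_equal(group_cpg_units(c(0, 15), max_gap = 15)$unit_id, c(1, 2))
  expect_equal(group_cpg_units(c(0, 14), max_gap = 15)$unit_id, c(1, 1))
  expect_equal(nrow(group_cpg_units(integer())), 0L)
})

test_that("short units merge to pair a long counterpart unit", {
  # A: one unit {s1, s2}; B: two short units {t1}, {t2}
  a <- units_from(c(10, 20))
  b <- units_from(10, 20)
  pu <- pair_cpg_units(a, b, tibble::tibble(pos_a = c(10, 20),
                                            pos_b = c(10, 20)))
  expect_equal(nrow(pu$groups), 1L)
  expect_equal(pu$groups$units_a[[1]], 1)
  expect_equal(sort(pu$groups$units_b[[1]]), c(1, 2))   # merged
  expect_equal(pu$groups$n_site_pairs, 2L)
  expect_equal(nrow(pu$excluded), 0L)
})

test_that("units without orthologous sites are excluded with a reason", {
  a <- units_from(c(10, 20), 50)
  b <- units_from(c(10, 20))
  pu <- pair_cpg_units(a, b, tibble::tibble(pos_a = c(10, 20),
                                            pos_b = c(10, 20)))
  expect_equal(nrow(pu$groups), 1L)
  expect_equal(pu$excluded$unit_id, 2)
  expect_equal(pu$excluded$reason, "no_orthologous_site")
  expect_equal(pu$excluded$species, "A")
})

test_that("a counterpart CpG outside any measured unit rejects the component", {
  # site 20 in A's unit pairs with a B CpG that is not in a measured unit
  a <- units_from(c(10, 20))
  b <- units_from(10)   # B's CpG at 20 exists but was not measured
  pu <- pair_cpg_units(a, b, tibble::tibble(pos_a = c(10, 20),
                                            pos_b = c(10, 20)))
  expect_equal(nrow(pu$groups), 0L)
  expect_true(all(pu$excluded$reason == "ineligible_counterpart"))
  expect_setequal(paste0(pu$excluded$species, pu$excluded$unit_id),
                  c("A1", "B1"))
})

test_that("unmatched sites without a counterpart CpG are permitted", {
  # A's second site has no pair at all (CpG lost in B): still pairable
  a <- units_from(c(10, 20))
  b <- units_from(10)
  pu <- pair_cpg_units(a, b, tibble::tibble(pos_a = 10, pos_b = 10))
  expect_equal(nrow(pu$groups), 1L)
})

test_that("overlapping units are rejected as input error", {
  bad <- tibble::tibble(unit_id = c(1, 2, 1), pos = c(0, 5, 10))
  expect_error(pair_cpg_units(bad, units_from(0), tibble::tibble(
    pos_a = 0, pos_b = 0)), "overlap")
})

test_that("pairing is symmetric and conserves units", {
  set.seed(41)
  for (i in 1:60) {
    inst <- random_pairing_instance()
    pu <- pair_cpg_units(inst$units_a, inst$units_b, inst$site_pairs)
    # conservation: every input unit is either paired or excluded
    n_a <- length(unique(inst$units_a$unit_id))
    n_b <- length(unique(inst$units_b$unit_id))
    expect_equal(sum(lengths(pu$groups$units_a)) +
                   sum(pu$excluded$species == "A"), n_a)
    expect_equal(sum(lengths(pu$groups$units_b)) +
                   sum(pu$excluded$species == "B"), n_b)
    # symmetry: swapping species mirrors the pairing
    mirrored <- pair_cpg_units(inst$units_b, inst$units_a,
                               tibble::tibble(pos_a = inst$site_pairs$pos_b,
                                              pos_b = inst$site_pairs$pos_a))
    expect_equal(lapply(pu$groups$units_a, sort),
                 lapply(mirrored$groups$units_b, sort))
    expect_equal(lapply(pu$groups$units_b, sort),
                 lapply(mirrored$groups$units_a, sort))
  }
})

test_that("pairing matches the independent graph oracle", {
  set.seed(42)
  for (i in 1:120) {
    inst <- random_pairing_instance()
    got <- canon_paired(pair_cpg_units(inst$units_a, inst$units_b,
                                       inst$site_pairs))
    want <- oracle_pair_units(inst$units_a, inst$units_b, inst$site_pairs)
    expect_equal(got$paired, want$paired)
  }
})

test_that("tidy() flattens groups and exclusions into one row per unit", {
  a <- units_from(c(10, 20), 50)
  b <- units_from(10, 20)
  pu <- pair_cpg_units(a, b, tibble::tibble(pos_a = c(10, 20),
                                            pos_b = c(10, 20)))
  td <- generics::tidy(pu)
  expect_equal(nrow(td), 4L)   # 2 A units + 2 B units, one row each
  expect_equal(sum(td$status == "excluded"), 1L)
  pt <- pairing_table(list(r1 = pu), "human", "macaque")
  expect_setequal(unique(pt$species), c("human", "macaque"))
  expect_equal(nrow(pt), 3L)   # paired units only
})
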