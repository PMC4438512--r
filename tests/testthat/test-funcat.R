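cat_tbl <- function(nog_id, categories) {
  tibble::tibble(member_id = paste0(nog_id, ".m"), nog_id = nog_id,
                 categories = categories)
}

test_that("category profiles split multi-letter annotations fractionally", {
  cat <- cat_tbl(c("NOG_A", "NOG_B", "NOG_C", "NOG_D"),
                 c("U", "S", "US", NA))
  p <- category_profile(c("NOG_A", "NOG_B"), cat)
  expect_equal(p$proportion[p$category == "U"], 0.5)
  expect_equal(p$proportion[p$category == "S"], 0.5)

  # "US" contributes 1/2 to each letter
  p2 <- category_profile("NOG_C", cat)
  expect_equal(p2$count, c(0.5, 0.5))
  expect_equal(sum(p2$proportion), 1)

  # uncategorized and unknown NOGs excluded from proportions but counted
  p3 <- category_profile(c("NOG_A", "NOG_D", "NOG_X"), cat)
  expect_equal(attr(p3, "set_size"), 1L)
  expect_equal(attr(p3, "n_uncategorized"), 2L)
  expect_equal(sum(p3$proportion), 1)

  # empty set
  p4 <- category_profile(character(0), cat)
  expect_equal(nrow(p4), 0L)
  expect_equal(attr(p4, "set_size"), 0L)
})

test_that("count-each mode gives every letter a full count", {
  cat <- cat_tbl(c("NOG_A", "NOG_C"), c("U", "US"))
  p <- category_profile(c("NOG_A", "NOG_C"), cat, mode = "each")
  expect_equal(p$count[p$category == "U"], 2)
  expect_equal(p$count[p$category == "S"], 1)
})

test_that("fractional proportions sum to one over random annotation sets", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    cats <- vapply(seq_len(n), function(j) {
      paste(sample(cog_categories(), sample(1:3, 1)), collapse = "")
    }, character(1))
    cat <- cat_tbl(paste0("N", seq_len(n)), cats)
    p <- category_profile(cat$nog_id, cat)
    expect_equal(sum(p$proportion), 1, tolerance = 1e-9)
    expect_equal(sum(p$count), n, tolerance = 1e-9)
  }
})

test_that("overabundance is the specific/total proportion ratio", {
  # total: 10/100 in U; specific: 4/20 in U -> ratio 2.0
  total <- tibble::tibble(category = c("U", "K"), count = c(10, 90),
                          proportion = c(0.1, 0.9))
  uniq <- tibble::tibble(category = c("U", "K"), count = c(4, 16),
                         proportion = c(0.2, 0.8))
  oa <- overabundance(uniq, total)
  expect_equal(oa$ratio[oa$category == "U"], 2.0)

  # identical proportions -> all ratios 1
  oa1 <- overabundance(total, total)
  expect_true(all(oa1$ratio == 1))

  # category absent from the specific set -> ratio 0
  uniq0 <- tibble::tibble(category = "K", count = 20, proportion = 1)
  oa0 <- overabundance(uniq0, total)
  expect_equal(oa0$ratio[oa0$category == "U"], 0)

  # category absent from the total set -> undefined
  uniq_v <- tibble::tibble(category = "V", count = 1, proportion = 1)
  oa_v <- overabundance(uniq_v, total)
  expect_true(is.na(oa_v$ratio[oa_v$category == "V"]))
})

test_that("overabundance is scale-invariant", {
  total <- tibble::tibble(category = c("U", "S", "K"), count = c(10, 20, 70),
                          proportion = c(0.1, 0.2, 0.7))
  uniq <- tibble::tibble(category = c("U", "S", "K"), count = c(5, 10, 5),
                         proportion = c(0.25, 0.5, 0.25))
  doubled <- function(p) dplyr::mutate(p, count = count * 2)
  expect_equal(overabundance(doubled(uniq), doubled(total))$ratio,
               overabundance(uniq, total)$ratio)
})

test_that("taxa above the abundance threshold are counted strictly", {
  ratios <- tibble::tibble(
    taxon_key = rep(c("P1", "P2", "P3"), each = 2),
    category = rep(c("U", "S"), 3),
    ratio = c(1.5, 1.0, 1.1, 1.3, 1.3, 1.2))
  fl <- flag_abundant(ratios)
  expect_equal(fl$n_above[fl$category == "U"], 2L)
  # exactly 1.2 is not "more than 1.2 times"
  expect_equal(fl$n_above[fl$category == "S"], 1L)
  expect_equal(flag_abundant(ratios, threshold = 10)$n_above, c(0L, 0L))
})

test_that("enrichment test matches exact enumeration for totals up to 100", {
  cases <- expand.grid(n_total = c(10, 37, 100), frac_k = c(0.1, 0.4),
                       frac_n = c(0.2, 0.5))
  for (i in seq_len(nrow(cases))) {
    n_total <- cases$n_total[i]
    k_total <- max(1, round(cases$frac_k[i] * n_total))
    n_unique <- max(1, round(cases$frac_n[i] * n_total))
    for (k_unique in unique(c(max(0, n_unique - (n_total - k_total)),
                              min(k_total, n_unique),
                              round(min(k_total, n_unique) / 2)))) {
      expect_equal(
        enrichment_test(k_unique, n_unique, k_total, n_total),
        enum_hyper_p(k_unique, n_unique, k_total, n_total),
        tolerance = 1e-12,
        label = sprintf("p(%d;%d,%d,%d)", k_unique, n_unique, k_total, n_total))
    }
  }
})

test_that("enrichment test behaves at the null and in extremes", {
  # proportions equal at large n: far from significant
  expect_gt(enrichment_test(20, 200, 100, 1000), 0.5)
  # all 20 specific NOGs in a 10% category: overwhelming enrichment
  expect_lt(enrichment_test(20, 20, 30, 300), 1e-6)
  # degenerate tables
  expect_equal(enrichment_test(0, 0, 10, 100), 1)
  expect_equal(enrichment_test(0, 10, 0, 100), 1)
})

test_that("the per-taxon table carries ratios and p-values for a built DB", {
  sim <- simulate_taxonomy(sim_config(children = c(2, 2, 1, 1, 1, 1),
                                      genomes_per_species = 2,
                                      pool_size = 30, core_size = 120,
                                      seed = 21))
  db <- build_db(sim$profiles, sim$lineages, min_genes = 0)
  fc <- funcat_table(db, sim$catalog)
  expect_setequal(unique(fc$taxon_key), c("P1", "P2"))
  expect_true(all(fc$p_value >= 0 & fc$p_value <= 1))
  expect_true(all(is.na(fc$ratio) | fc$ratio >= 0))
  # planted 1.5x S-weighting in node pools: S should be overabundant in
  # the taxon-specific sets of both phyla
  s_rows <- fc[fc$category == "S", ]
  expect_true(all(s_rows$ratio > 1))
})
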