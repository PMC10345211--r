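# A small hand-built pool over the toy_meddra() hierarchy.
agg_pool <- function() {
  tibble::tibble(
    sex = factor(rep(c("female", "male"), each = 5),
                 levels = c("female", "male")),
    drug = rep(c("diazepam", "diazepam", "zolpidem", "zolpidem", "diazepam"),
               2),
    pt = rep(c("somnolence", "agitation", "somnolence", "insomnia",
               "nausea"), 2),
    a = 10L, aexp = 2, ic = 2,
    ic025 = c(1.2, 0.5, 0.8, 2.0, 0.3,
              1.0, -0.3, 0.4, 1.5, 0.2),
    prr = 5, ror = 5,
    in_pool2 = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

test_that("cIC025 sums a drug's in-group values per mode", {
  pool <- agg_pool()
  map <- toy_meddra()
  # female diazepam in 'neurological nec': 1.2 + 0.5
  expect_equal(
    cumulative_ic025(pool[pool$sex == "female", ], map, "diazepam",
                     "neurological nec", level = "hlg"), 1.7)
  # male diazepam pool1-positive: agitation (-0.3) never contributes
  expect_equal(
    cumulative_ic025(pool[pool$sex == "male", ], map, "diazepam",
                     "neurological nec", level = "hlg",
                     mode = "pool1-positive"), 1.0)
  # drug with no in-group record
  expect_equal(
    cumulative_ic025(pool[pool$sex == "female", ], map, "zaleplon",
                     "neurological nec", level = "hlg"), 0)
  expect_error(
    cumulative_ic025(pool, map, "diazepam", "no-such-group", level = "hlg"),
    "unknown")
})

test_that("ScIC025 is additive over drugs and over the AE decomposition", {
  pool <- agg_pool()
  map <- toy_meddra()
  f <- pool[pool$sex == "female", ]
  sc <- summed_cumulative_ic025(f, map, "neurological nec", level = "hlg")
  by_drug <- cumulative_ic025(f, map, "diazepam", "neurological nec", "hlg") +
    cumulative_ic025(f, map, "zolpidem", "neurological nec", "hlg")
  expect_equal(sc, by_drug, tolerance = 1e-9)
  by_ae <- decompose_group(f, map, "neurological nec", level = "hlg")
  expect_equal(sum(by_ae$cic025), sc, tolerance = 1e-9)
  expect_equal(summed_cumulative_ic025(f, map, "gi signs", level = "hlg"),
               0.3)
})

test_that("additivity holds on random pools against brute force", {
  map <- build_toy_hierarchy(3, 2, 5)
  withr::with_seed(42, {
    for (rep in 1:5) {
      pool <- tibble::tibble(
        sex = factor(sample(c("female", "male"), 60, TRUE),
                     levels = c("female", "male")),
        drug = sample(letters[1:6], 60, TRUE),
        pt = sample(map$pt, 60, TRUE),
        a = 10L, aexp = 1, ic = 1,
        ic025 = stats::rnorm(60), prr = 5, ror = 5
      ) |> dplyr::distinct(sex, drug, pt, .keep_all = TRUE)
      pool$in_pool2 <- pool$ic025 > 0
      for (soc in unique(map$soc)) {
        sc <- summed_cumulative_ic025(pool, map, soc, level = "soc")
        # brute force: positive screened records whose PT is in the SOC
        in_soc <- pool$pt %in% map$pt[map$soc == soc]
        brute <- sum(pool$ic025[in_soc & pool$in_pool2 & pool$ic025 > 0])
        expect_equal(sc, brute, tolerance = 1e-9)
      }
    }
  })
})

test_that("drug percentages follow the formula and sum to 100 per SOC", {
  pool <- agg_pool()
  map <- toy_meddra()
  f <- pool[pool$sex == "female", ]
  sc <- summed_cumulative_ic025(f, map, "nervous system", level = "soc")
  pct_dia <- drug_percentage(f, map, "diazepam", "nervous system")
  expect_equal(pct_dia, 100 * 1.7 / sc, tolerance = 1e-9)
  pct_zol <- drug_percentage(f, map, "zolpidem", "nervous system")
  expect_equal(pct_dia + pct_zol, 100, tolerance = 1e-6)
  # single-drug SOC
  expect_equal(drug_percentage(f, map, "zolpidem", "psychiatric"), 100)
  # zero-denominator sentinel
  empty <- f[f$ic025 < 0, ]
  expect_true(is.na(drug_percentage(empty, map, "diazepam",
                                    "nervous system")))
})

test_that("report percentages come from raw counts and sum to 100", {
  rows <- tibble::tibble(
    sex = factor("female", levels = c("female", "male")),
    drug = "diazepam",
    pt = c("somnolence", "agitation", "insomnia", "nausea"),
    count = c(20, 10, 130, 40)
  )
  map <- toy_meddra()
  expect_equal(report_percentage(rows, map, "diazepam", "neurological nec"),
               15)
  parts <- vapply(unique(map$hlg), function(g) {
    report_percentage(rows, map, "diazepam", g)
  }, numeric(1))
  expect_equal(sum(parts), 100, tolerance = 1e-6)
  expect_error(report_percentage(rows, map, "zaleplon", "gi signs"),
               "no reports")
})

test_that("drug ranking sorts by value with alphabetical tie-break", {
  pool <- tibble::tibble(
    sex = factor("female", levels = c("female", "male")),
    drug = c("yy", "aa", "mm"),
    pt = c("somnolence", "sedation", "agitation"),
    a = 10L, aexp = 1, ic = 1,
    ic025 = c(2.0, 1.0, 2.0), prr = 5, ror = 5, in_pool2 = TRUE
  )
  map <- toy_meddra()
  ranked <- rank_drugs(pool, map, "neurological nec", level = "hlg",
                       top_k = 10)
  expect_equal(ranked$drug, c("mm", "yy", "aa"))
  expect_equal(ranked$rank, 1:3)
  # deterministic across runs; top_k larger than drug count returns all
  expect_identical(ranked,
                   rank_drugs(pool, map, "neurological nec", level = "hlg",
                              top_k = 10))
  expect_equal(nrow(rank_drugs(pool, map, "neurological nec", level = "hlg",
                               top_k = 2)), 2)
})

test_that("group decomposition sums per PT, honours cutoffs and merges", {
  pool <- agg_pool()
  map <- toy_meddra()
  f <- pool[pool$sex == "female", ]
  dec <- decompose_group(f, map, "neurological nec", level = "hlg")
  # two drugs on somnolence: 1.2 + 0.8
  expect_equal(dec$cic025[dec$pt == "somnolence"], 2.0)
  # combined-sex cutoff: strict threshold retains only the PT above it
  pool_cut <- tibble::tibble(
    sex = factor(rep(c("female", "male"), 2), levels = c("female", "male")),
    drug = "diazepam",
    pt = c("somnolence", "somnolence", "agitation", "agitation"),
    a = 10L, aexp = 1, ic = 1,
    ic025 = c(16, 15, 14, 15), prr = 5, ror = 5, in_pool2 = TRUE
  )
  kept <- decompose_group(pool_cut, map, "neurological nec", level = "hlg",
                          cutoff = 30)
  expect_setequal(unique(kept$pt), "somnolence")
  # merged groups equal the union of their parts
  merged <- decompose_group(f, map, c("nervous system", "psychiatric"),
                            level = "soc")
  parts <- dplyr::bind_rows(
    decompose_group(f, map, "nervous system", level = "soc"),
    decompose_group(f, map, "psychiatric", level = "soc"))
  expect_equal(sum(merged$cic025), sum(parts$cic025), tolerance = 1e-9)
})

test_that("aggregation commutes with record permutation", {
  map <- build_toy_hierarchy(2, 2, 4)
  pool <- tibble::tibble(
    sex = factor("male", levels = c("female", "male")),
    drug = rep(c("a", "b"), 8), pt = rep(map$pt, 1),
    a = 10L, aexp = 1, ic = 1,
    ic025 = seq(-0.5, 1, length.out = 16), prr = 5, ror = 5,
    in_pool2 = TRUE
  )
  shuffled <- pool[rev(seq_len(nrow(pool))), ]
  expect_equal(
    as.data.frame(aggregate_ic025(pool, map, "soc")),
    as.data.frame(aggregate_ic025(shuffled, map, "soc")))
})

test_that("unmapped PTs are excluded from aggregation but counted", {
  map <- toy_meddra()
  pool <- tibble::tibble(
    sex = factor("female", levels = c("female", "male")),
    drug = "diazepam", pt = c("somnolence", "mystery term"),
    a = 10L, aexp = 1, ic = 1, ic025 = c(1, 1), prr = 5, ror = 5,
    in_pool2 = TRUE
  )
  agg <- aggregate_ic025(pool, map, "soc")
  expect_equal(sum(agg$cic025), 1)
  expect_equal(attr(agg, "n_unmapped"), 1)
})
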