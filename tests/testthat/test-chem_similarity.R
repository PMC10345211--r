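test_that("shape distances follow D = 1 - S/S_max with max-over-conformers", {
  report <- tibble::tibble(
    query = c("a_1", "a_1", "a_1", "a_1", "b_1"),
    db    = c("b_1", "b_1", "b_1", "c_1", "c_1"),
    shape_tanimoto = 0.5, color_tanimoto = 0.5,
    tanimoto_combo = c(0.8, 1.4, 1.1, 2.0, 1.0)
  )
  d <- shape_distance_matrix(report, "combo")
  # three conformer pairings {0.8, 1.4, 1.1} -> S = 1.4, D = 0.3
  expect_equal(d["a_1", "b_1"], 0.3, tolerance = 1e-12)
  expect_equal(d["a_1", "c_1"], 0)       # combo 2.0 -> identical shapes
  expect_equal(d["b_1", "c_1"], 0.5)     # combo 1.0 -> D = 0.5
  expect_equal(diag(d), stats::setNames(rep(0, 3), rownames(d)))
  expect_equal(d, t(d))
})

test_that("asymmetric listings symmetrize by the maximum of both directions", {
  report <- tibble::tibble(
    query = c("a_1", "b_1"), db = c("b_1", "a_1"),
    shape_tanimoto = 0.1, color_tanimoto = 0.1,
    tanimoto_combo = c(1.0, 1.6)
  )
  d <- shape_distance_matrix(report, "combo")
  expect_equal(d["a_1", "b_1"], 1 - 1.6 / 2)
})

test_that("scores outside their range are rejected naming the row", {
  report <- tibble::tibble(query = "a_1", db = "b_1",
                           shape_tanimoto = 0.5, color_tanimoto = 0.5,
                           tanimoto_combo = 2.3)
  expect_error(shape_distance_matrix(report, "combo"), "row 1")
  # shape score uses S_max = 1
  report2 <- tibble::tibble(query = "a_1", db = "b_1",
                            shape_tanimoto = 0.6, color_tanimoto = 0.2,
                            tanimoto_combo = 0.8)
  d <- shape_distance_matrix(report2, "shape")
  expect_equal(d["a_1", "b_1"], 0.4)
})

test_that("distance-matrix invariants hold on random reports of any order", {
  for (seed in 1:5) {
    ids <- sprintf("cmp%d_1", 1:6)
    report <- simulate_similarity_report(ids, seed = seed)
    d <- shape_distance_matrix(report, "combo")
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    # invariance to row order of the input report
    shuffled <- report[rev(seq_len(nrow(report))), ]
    expect_equal(shape_distance_matrix(shuffled, "combo"), d)
  }
})

test_that("PCA standardises, fixes signs, and orders variance", {
  ids <- sprintf("c%02d", 1:12)
  x <- simulate_descriptors(ids, n_features = 8, seed = 4)
  p <- fingerprint_pca(x, n_components = 3)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)
  # declared sign convention: largest-magnitude loading positive
  for (j in 1:3) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # identical compounds get identical score rows
  x2 <- rbind(x, x[1, , drop = FALSE])
  rownames(x2)[13] <- "dup"
  p2 <- fingerprint_pca(x2, 2)
  expect_equal(unname(p2$scores["dup", ]), unname(p2$scores[ids[1], ]),
               tolerance = 1e-9)
  # constant features dropped with a warning; excess components error
  xc <- cbind(x, const = 1)
  expect_warning(fingerprint_pca(xc, 2), "constant")
  expect_error(fingerprint_pca(x[1:3, ], 5), "rank")
})

test_that("collinear points leave a single informative component", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  rownames(x) <- c("p", "q", "r")
  p <- fingerprint_pca(x, 1)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  expect_error(fingerprint_pca(x, 2), "rank")
})

test_that("hcluster matches a naive agglomeration oracle on small sets", {
  for (seed in 1:4) {
    ids <- sprintf("m%d_1", 1:7)
    d <- shape_distance_matrix(simulate_similarity_report(ids, seed), "combo")
    for (linkage in c("average", "single", "complete")) {
      hc <- hcluster(d, linkage)
      expect_equal(hc$height, naive_agglomerate_heights(d, linkage),
                   tolerance = 1e-12)
      expect_true(all(diff(hc$height) >= -1e-12))
    }
  }
})

test_that("hcluster merges the closest items first", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, dimnames = list(c("a", "b", "c"),
                                                 c("a", "b", "c")))
  hc <- hcluster(d)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_equal(hc$height[1], 0.1)
  # identical items merge at height 0
  d0 <- d; d0["a", "b"] <- d0["b", "a"] <- 0
  expect_equal(hcluster(d0)$height[1], 0)
})

test_that("dendrograms export as Newick and merge tables", {
  ids <- sprintf("z%d_1", 1:5)
  hc <- hcluster(shape_distance_matrix(simulate_similarity_report(ids, 2),
                                       "combo"))
  nwk <- tempfile(fileext = ".nwk")
  tsv <- tempfile(fileext = ".tsv")
  tab <- export_dendrogram(hc, newick = nwk, merges = tsv)
  expect_equal(nrow(tab), 4)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, ids)
})

test_that("profile comparison pairs pool-2 tops with pool-1 counterparts", {
  map <- toy_meddra()
  pool1 <- tibble::tibble(
    sex = factor("female", levels = c("female", "male")),
    drug = c("eszopiclone", "eszopiclone", "zopiclone", "zopiclone"),
    pt = c("insomnia", "somnolence", "insomnia", "agitation"),
    a = 10L, aexp = 1, ic = 1,
    ic025 = c(3.0, 1.5, -0.8, 2.0), prr = 5, ror = 5
  )
  pool2 <- screen_signals(dplyr::mutate(pool1, prr = 5), keep_all = FALSE)
  cmp <- profile_compare(pool1, pool2, map, "eszopiclone", "zopiclone",
                         groups = c("nervous system", "psychiatric"),
                         level = "soc", k = 10)
  esz <- cmp[cmp$focal_drug == "eszopiclone", ]
  # negative pool-1 value of the comparator appears as-is
  expect_equal(esz$ic025_other[esz$pt == "insomnia"], -0.8)
  # comparator lacking any record: explicit marker, not a value
  expect_false(esz$other_has_record[esz$pt == "somnolence"])
  expect_true(is.na(esz$ic025_other[esz$pt == "somnolence"]))
  # self-comparison gives identical columns
  self <- profile_compare(pool1, pool2, map, "zopiclone", "zopiclone",
                          groups = "nervous system", level = "soc")
  expect_equal(self$ic025_focal, self$ic025_other)
  expect_true(all(table(cmp$focal_drug) <= 10))
})
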