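# Fixture builders and independent oracles shared across the suite.

# Write a small report table to a temp file and return the path.
write_report_fixture <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  if (ext == "csv") {
    readr::write_csv(df, path)
  } else {
    readr::write_tsv(df, path)
  }
  path
}

# The 4-pair toy stratum used by the contingency examples:
# {(X,ae1):3, (X,ae2):2, (Y,ae1):1, (Y,ae2):4}.
toy_stratum <- function(sex = "female") {
  tibble::tibble(
    sex = factor(sex, levels = c("female", "male")),
    drug = c("x", "x", "y", "y"),
    pt = c("ae1", "ae2", "ae1", "ae2"),
    count = c(3L, 2L, 1L, 4L)
  )
}

# Random single-sex report fixture with a fixed seed.
random_stratum <- function(seed, n_drugs = 6, n_pts = 10, n_rows = 40,
                           sex = "female") {
  withr::with_seed(seed, {
    tibble::tibble(
      sex = factor(sex, levels = c("female", "male")),
      drug = sample(sprintf("d%02d", seq_len(n_drugs)), n_rows, TRUE),
      pt = sample(sprintf("p%02d", seq_len(n_pts)), n_rows, TRUE),
      count = sample.int(5, n_rows, TRUE)
    ) |>
      dplyr::group_by(sex, drug, pt) |>
      dplyr::summarise(count = sum(count), .groups = "drop")
  })
}

# Independent oracle for pool-1 scoring: a naive double loop over every
# observed (drug, pt) pair via build_contingency and the scalar metric
# functions.
naive_score_loop <- function(rows) {
  pairs <- unique(rows[, c("drug", "pt")])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    t <- build_contingency(rows, pairs$drug[i], pairs$pt[i])
    tibble::tibble(
      sex = unique(rows$sex), drug = pairs$drug[i], pt = pairs$pt[i],
      a = as.integer(t$a), aexp = compute_aexp(t), ic = compute_ic(t),
      ic025 = compute_ic025(t), prr = compute_prr(t), ror = compute_ror(t)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), drug, pt)
}

# Independent agglomeration oracle: naive O(n^3) average/single/complete
# linkage over a distance matrix, returning the sequence of merge heights.
naive_agglomerate_heights <- function(d, linkage = "average") {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  link <- switch(linkage, average = mean, single = min, complete = max)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- link(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Toy MedDRA map with a handful of real-looking terms.
toy_meddra <- function() {
  map <- tibble::tibble(
    pt = c("somnolence", "sedation", "agitation", "logorrhoea",
            "insomnia", "nausea"),
    hlt = c("hlt_sed", "hlt_sed", "hlt_par", "hlt_par", "hlt_slp", "hlt_gi"),
    hlg = c("neurological nec", "neurological nec", "neurological nec",
            "neurological nec", "sleep disturbances", "gi signs"),
    soc = c("nervous system", "nervous system", "nervous system",
            "nervous system", "psychiatric", "gastrointestinal")
  )
  attr(map, "meddra_version") <- "toy"
  map
}
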