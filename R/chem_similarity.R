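#' Convert a pairwise conformer-similarity report into a shape-distance matrix
#'
#' Consumes a ROCS-style report with one row per evaluated conformer
#' pairing of two stereoisomers (ids follow the `name_k` suffix
#' convention, e.g. `zopiclone_1`) and similarity scores ShapeTanimoto and
#' ColorTanimoto in \[0, 1\] and TanimotoCombo in \[0, 2\]. For each
#' stereoisomer pair the maximum score over all listed conformer pairings
#' (in either direction) is taken, then converted to the shape distance
#' `D = 1 - S / S_max` with `S_max = 2` for the combo score and 1
#' otherwise. The diagonal is forced to 0; pairs never evaluated remain
#' `NA` (flagged undefined).
#'
#' @param report Tibble/data.frame with columns `query`, `db` and the
#'   score columns `shape_tanimoto`, `color_tanimoto`, `tanimoto_combo`
#'   (only the chosen one is required).
#' @param score `"combo"`, `"shape"` or `"color"`.
#' @return Symmetric numeric matrix with stereoisomer ids as dimnames,
#'   entries in \[0, 1\], zero diagonal.
#' @export
shape_distance_matrix <- function(report, score = c("combo", "shape",
                                                    "color")) {
  score <- match.arg(score)
  if (nrow(report) == 0L) stop("similarity report is empty")
  col <- switch(score, combo = "tanimoto_combo", shape = "shape_tanimoto",
                color = "color_tanimoto")
  if (!col %in% names(report)) {
    stop("similarity report lacks score column '", col, "'")
  }
  s_max <- if (score == "combo") 2 else 1
  s <- as.numeric(report[[col]])
  bad <- which(is.na(s) | s < 0 | s > s_max)
  if (length(bad)) {
    stop("score out of range [0, ", s_max, "] in report row ", bad[1])
  }
  labels <- sort(unique(c(as.character(report$query),
                          as.character(report$db))))
  d <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  best <- stats::aggregate(
    s,
    by = list(i = pmin(as.character(report$query), as.character(report$db)),
              j = pmax(as.character(report$query), as.character(report$db))),
    FUN = max)
  d[cbind(best$i, best$j)] <- 1 - best$x / s_max
  d[cbind(best$j, best$i)] <- 1 - best$x / s_max
  diag(d) <- 0
  d
}

#' Simulate a conformer-similarity report
#'
#' Synthetic fixture generator: draws a latent configuration of compounds,
#' derives pairwise combo similarities from their distances, and emits a
#' report with several conformer pairings per pair (the reported score is
#' never above the latent maximum). Deterministic for a fixed seed.
#'
#' @param ids Stereoisomer ids.
#' @param seed Integer seed.
#' @param n_conf Conformer pairings listed per pair.
#' @return Report tibble consumable by [shape_distance_matrix()].
#' @export
simulate_similarity_report <- function(ids, seed = 1L, n_conf = 3L) {
  stopifnot(length(ids) >= 2L)
  with_local_seed(seed, {
    k <- length(ids)
    pos <- matrix(stats::runif(k * 2), k)
    pairs <- utils::combn(k, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      s_true <- 2 * exp(-2 * sqrt(sum((pos[i, ] - pos[j, ])^2)))
      s <- s_true * sort(stats::runif(n_conf, 0.6, 1))
      s[n_conf] <- s_true
      tibble::tibble(query = ids[i], db = ids[j],
                     shape_tanimoto = s / 2, color_tanimoto = s / 2,
                     tanimoto_combo = s)
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a molecular-descriptor matrix
#'
#' Synthetic physico-chemical descriptor fixture: compounds fall into
#' latent clusters with Gaussian within-cluster scatter.
#'
#' @param ids Compound ids.
#' @param n_features Descriptor count.
#' @param n_clusters Latent clusters.
#' @param seed Integer seed.
#' @return Numeric matrix (compounds x features) with row names `ids`;
#'   attribute `"cluster"` carries the ground-truth assignment.
#' @export
simulate_descriptors <- function(ids, n_features = 20L, n_clusters = 3L,
                                 seed = 1L) {
  with_local_seed(seed, {
    k <- length(ids)
    cl <- rep_len(seq_len(n_clusters), k)
    centers <- matrix(stats::rnorm(n_clusters * n_features, sd = 4),
                      n_clusters)
    x <- centers[cl, ] + matrix(stats::rnorm(k * n_features), k)
    dimnames(x) <- list(ids, sprintf("f%03d", seq_len(n_features)))
    attr(x, "cluster") <- stats::setNames(cl, ids)
    x
  })
}

#' PCA of a descriptor matrix
#'
#' Standardises every descriptor to zero mean / unit variance (constant
#' descriptors are dropped with a warning), projects onto the leading
#' principal components, and fixes each component's sign so that its
#' largest-magnitude loading is positive (PCA is otherwise only defined up
#' to sign).
#'
#' @param descriptors Numeric matrix, compounds x features, no missing
#'   values, at least 2 compounds.
#' @param n_components Components to keep; must not exceed the rank of the
#'   standardised matrix.
#' @return List with `scores` (compounds x components), `loadings`,
#'   `explained` (variance fractions, non-increasing).
#' @export
fingerprint_pca <- function(descriptors, n_components = 2L) {
  x <- as.matrix(descriptors)
  if (anyNA(x)) stop("descriptor matrix contains missing values")
  if (nrow(x) < 2L) stop("need at least 2 compounds")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant descriptor(s)")
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-10)
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds matrix rank (", rank, ")")
  }
  idx <- seq_len(n_components)
  rot <- p$rotation[, idx, drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x[, idx, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(rot, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained = p$sdev^2 / sum(p$sdev^2))
}

#' Agglomerative clustering of compounds
#'
#' Hierarchical clustering over a distance matrix or PCA scores (for
#' scores, Euclidean distances are used). Labels are put in alphabetical
#' order before clustering so ties resolve deterministically; merge
#' heights are non-decreasing for the supported linkages.
#'
#' @param x Symmetric distance matrix (e.g. from
#'   [shape_distance_matrix()]), a `dist`, or a numeric score matrix.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return An [stats::hclust] object.
#' @export
hcluster <- function(x, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(x, "dist")) {
    d <- x
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             isTRUE(all.equal(unname(x), unname(t(x))))) {
    if (anyNA(x)) stop("distance matrix has undefined (NA) pairs")
    ord <- order(rownames(x))
    d <- stats::as.dist(x[ord, ord])
  } else {
    m <- as.matrix(x)
    d <- stats::dist(m[order(rownames(m)), , drop = FALSE])
  }
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram
#'
#' Writes the merge tree as Newick (via `ape`) and/or as a tidy merge
#' table (one row per agglomeration step with its height).
#'
#' @param hc An [stats::hclust] object.
#' @param newick,merges Optional output paths.
#' @return Invisibly, the merge table.
#' @export
export_dendrogram <- function(hc, newick = NULL, merges = NULL) {
  tab <- tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
  if (!is.null(newick)) {
    ape::write.tree(ape::as.phylo(hc), file = newick)
  }
  if (!is.null(merges)) readr::write_tsv(tab, merges)
  invisible(tab)
}

#' Compare the adverse-event profiles of two drugs
#'
#' For the focal drug, the `k` preferred terms with the highest IC025
#' within a declared group scope (from pool 2), each paired with the other
#' drug's IC025 for the same term drawn from pool 1 -- so negative
#' associations of the comparator are visible. A term for which the
#' comparator has no pool-1 record at all is marked `other_has_record =
#' FALSE` (explicitly distinct from a negative IC025). Run once per
#' direction; `profile_compare()` returns both.
#'
#' @param pool1,pool2 Single-sex pools.
#' @param map Hierarchy map.
#' @param drug_a,drug_b The two drugs.
#' @param groups Group names defining the scope (merged union).
#' @param level `"hlg"` or `"soc"`.
#' @param k Terms per direction.
#' @return Tibble with columns `focal_drug`, `other_drug`, `rank`, `pt`,
#'   `ic025_focal`, `ic025_other`, `other_has_record`.
#' @export
profile_compare <- function(pool1, pool2, map, drug_a, drug_b, groups,
                            level = c("hlg", "soc"), k = 10L) {
  level <- match.arg(level)
  one_way <- function(focal, other) {
    path2 <- meddra_lookup(map, pool2$pt)
    top <- pool2[pool2$drug == focal & path2$mapped &
                   path2[[level]] %in% groups, ] |>
      dplyr::arrange(dplyr::desc(.data$ic025), .data$pt) |>
      dplyr::slice_head(n = k)
    other_rec <- pool1[pool1$drug == other, c("pt", "ic025")]
    idx <- match(top$pt, other_rec$pt)
    tibble::tibble(
      focal_drug = focal, other_drug = other,
      rank = seq_len(nrow(top)), pt = top$pt,
      ic025_focal = top$ic025,
      ic025_other = other_rec$ic025[idx],
      other_has_record = !is.na(idx)
    )
  }
  dplyr::bind_rows(one_way(drug_a, drug_b), one_way(drug_b, drug_a))
}
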