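#' Pair female and male signals per drug--event key
#'
#' Outer join of the two sex-specific pools on (drug, pt). A pair present
#' in only one pool keeps `NA` on the absent side -- these are the
#' "points on the axes" of the sex-contrast scatter: the pair failed at
#' least one screening criterion in the other sex.
#'
#' @param pool_f,pool_m Female and male signal pools (typically pool 2).
#' @return Tibble `drug`, `pt`, `ic025_f`, `ic025_m`.
#' @export
pair_signals <- function(pool_f, pool_m) {
  f <- tibble::tibble(drug = pool_f$drug, pt = pool_f$pt,
                      ic025_f = pool_f$ic025)
  m <- tibble::tibble(drug = pool_m$drug, pt = pool_m$pt,
                      ic025_m = pool_m$ic025)
  dplyr::full_join(f, m, by = c("drug", "pt")) |>
    dplyr::arrange(.data$drug, .data$pt)
}

#' Classify paired signals by sex dominance
#'
#' For pairs with a positive IC025 in both sexes the ratio
#' `max(ic025_f, ic025_m) / min(ic025_f, ic025_m)` is computed; pairs at or
#' above the threshold are `female_dominant` or `male_dominant` according
#' to which sex holds the larger value, the rest are `balanced`. Pairs with
#' a signal on one side only (the other side absent, or present but not
#' positive -- a ratio of signed log quantities is not meaningful) are
#' `female_only` / `male_only`; their ratio is undefined (`NA`) and the
#' threshold does not apply to them. Pairs positive in neither sex are
#' `balanced` with `NA` ratio. The classification is exhaustive and
#' mutually exclusive, and symmetric under swapping the sex labels.
#'
#' @param paired Output of [pair_signals()].
#' @param threshold Dominance ratio threshold (> 1); default 2 (the 2:1
#'   filter).
#' @return `paired` plus columns `ratio` and `class`.
#' @export
classify_pairs <- function(paired, threshold = 2.0) {
  if (threshold <= 1) stop("threshold must be > 1")
  f <- paired$ic025_f
  m <- paired$ic025_m
  f_pos <- !is.na(f) & f > 0
  m_pos <- !is.na(m) & m > 0
  ratio <- rep(NA_real_, nrow(paired))
  both <- f_pos & m_pos
  ratio[both] <- pmax(f[both], m[both]) / pmin(f[both], m[both])
  cls <- rep("balanced", nrow(paired))
  cls[f_pos & !m_pos] <- "female_only"
  cls[m_pos & !f_pos] <- "male_only"
  cls[both & ratio >= threshold & f > m] <- "female_dominant"
  cls[both & ratio >= threshold & m > f] <- "male_dominant"
  dplyr::mutate(paired, ratio = ratio,
                class = factor(cls, levels = c("balanced", "female_dominant",
                                               "male_dominant", "female_only",
                                               "male_only")))
}

#' Filter paired signals to the sex-divergent subset
#'
#' Keeps the dominant pairs (both sexes positive, ratio at or above the
#' threshold) and the one-sex-only pairs, which are routed to their own
#' buckets untouched by the ratio. Balanced pairs are dropped.
#'
#' @inheritParams classify_pairs
#' @return Classified tibble restricted to non-balanced classes.
#' @export
ratio_filter <- function(paired, threshold = 2.0) {
  cls <- classify_pairs(paired, threshold)
  cls[cls$class != "balanced", ]
}

#' Top adverse events for one sex among divergent pairs
#'
#' Within the chosen subset (`"dominant"`: pairs where that sex holds the
#' larger positive signal; `"only"`: pairs with a signal in that sex
#' alone), sums that sex's IC025 per preferred term across drugs and
#' returns the top `k` terms with the per-drug breakdown preserved.
#'
#' @param filtered Output of [ratio_filter()] (or [classify_pairs()]).
#' @param sex `"female"` or `"male"`.
#' @param k Number of terms (full list if fewer exist).
#' @param which `"dominant"` or `"only"`.
#' @return List with `top` (tibble `pt`, `total_ic025`, `rank`) and
#'   `breakdown` (tibble `pt`, `drug`, `ic025` for the retained terms).
#' @export
top_sex_specific <- function(filtered, sex = c("female", "male"), k = 20L,
                             which = c("dominant", "only")) {
  sex <- match.arg(sex)
  which <- match.arg(which)
  cls <- paste0(sex, "_", ifelse(which == "dominant", "dominant", "only"))
  sub <- filtered[filtered$class == cls, ]
  val <- if (sex == "female") sub$ic025_f else sub$ic025_m
  breakdown <- tibble::tibble(pt = sub$pt, drug = sub$drug, ic025 = val)
  top <- breakdown |>
    dplyr::group_by(.data$pt) |>
    dplyr::summarise(total_ic025 = sum(.data$ic025), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_ic025), .data$pt) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number())
  list(top = top,
       breakdown = dplyr::arrange(breakdown[breakdown$pt %in% top$pt, ],
                                  .data$pt, .data$drug))
}

#' Top contributing drugs among divergent pairs
#'
#' Companion of [top_sex_specific()]: per-drug sums of the dominant sex's
#' IC025 over its divergent pairs.
#'
#' @inheritParams top_sex_specific
#' @param k Number of drugs (default 10).
#' @return Tibble `drug`, `total_ic025`, `rank`.
#' @export
top_contributing_drugs <- function(filtered, sex = c("female", "male"),
                                   k = 10L, which = c("dominant", "only")) {
  sex <- match.arg(sex)
  which <- match.arg(which)
  cls <- paste0(sex, "_", ifelse(which == "dominant", "dominant", "only"))
  sub <- filtered[filtered$class == cls, ]
  val <- if (sex == "female") sub$ic025_f else sub$ic025_m
  tibble::tibble(drug = sub$drug, ic025 = val) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(total_ic025 = sum(.data$ic025), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_ic025), .data$drug) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number())
}
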