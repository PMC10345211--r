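#' Aggregate IC025 values up the hierarchy
#'
#' Workhorse behind the cumulative statistics: attaches the hierarchy path
#' to each signal record, restricts to the chosen aggregation mode, and
#' returns the per-(sex, group, drug) sums of IC025. Two modes exist
#' because both appear in practice: `"pool2"` sums the records that passed
#' the screen, `"pool1-positive"` sums every record with a positive IC025
#' regardless of the screen. Negative IC025 values never contribute in
#' either mode. Records whose PT is absent from the map are excluded from
#' aggregation (they remain in the pools) and counted in the
#' `"n_unmapped"` attribute.
#'
#' @param pool Signal tibble (pool 1 with `in_pool2` flags, or pool 2).
#' @param map Hierarchy map ([load_meddra_map()] / [build_toy_hierarchy()]).
#' @param level `"hlg"` or `"soc"`.
#' @param mode `"pool2"` or `"pool1-positive"`.
#' @param groups Optional character vector restricting (and, when length
#'   > 1, merging) groups; see [decompose_group()] for merged-group
#'   semantics.
#' @return Tibble `sex`, `group`, `drug`, `cic025`.
#' @export
aggregate_ic025 <- function(pool, map, level = c("hlg", "soc"),
                            mode = c("pool2", "pool1-positive"),
                            groups = NULL) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  recs <- restrict_mode(pool, mode)
  path <- meddra_lookup(map, recs$pt)
  n_unmapped <- sum(!path$mapped)
  recs$group <- path[[level]]
  recs <- recs[path$mapped, ]
  if (!is.null(groups)) {
    known <- unique(map[[level]])
    bad <- setdiff(groups, known)
    if (length(bad)) stop("unknown ", level, " group: ",
                          paste(bad, collapse = ", "))
    recs <- recs[recs$group %in% groups, ]
    if (length(groups) > 1L) recs$group <- paste(sort(groups), collapse = " + ")
  }
  out <- recs |>
    dplyr::group_by(.data$sex, .data$group, .data$drug) |>
    dplyr::summarise(cic025 = sum(.data$ic025), .groups = "drop") |>
    dplyr::arrange(.data$sex, .data$group, .data$drug)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "mode") <- mode
  out
}

#' Cumulative IC025 (cIC025) of one drug within a group
#'
#' The sum of the drug's (positive) IC025 values over the preferred terms
#' that map into the group, at HLG or SOC level.
#'
#' @inheritParams aggregate_ic025
#' @param drug Drug name.
#' @param group Group name (single HLG or SOC), or a character vector of
#'   group names treated as a merged group.
#' @return A single number (0 when the drug has no in-group record).
#' @export
cumulative_ic025 <- function(pool, map, drug, group,
                             level = c("hlg", "soc"),
                             mode = c("pool2", "pool1-positive")) {
  agg <- aggregate_ic025(pool, map, level, mode, groups = group)
  val <- agg$cic025[agg$drug == drug]
  if (length(val) == 0L) 0 else sum(val)
}

#' Summed cumulative IC025 (ScIC025) of a group
#'
#' The sum of cIC025 over every contributing drug -- the group's total
#' signal mass.
#'
#' @inheritParams cumulative_ic025
#' @return A single number (0 for an empty group).
#' @export
summed_cumulative_ic025 <- function(pool, map, group,
                                    level = c("hlg", "soc"),
                                    mode = c("pool2", "pool1-positive")) {
  agg <- aggregate_ic025(pool, map, level, mode, groups = group)
  sum(agg$cic025)
}

#' ScIC025 table over all groups
#'
#' @inheritParams aggregate_ic025
#' @return Tibble `sex`, `group`, `scic025`, sorted by descending value
#'   within sex.
#' @export
scic025_table <- function(pool, map, level = c("hlg", "soc"),
                          mode = c("pool2", "pool1-positive")) {
  aggregate_ic025(pool, map, level, mode) |>
    dplyr::group_by(.data$sex, .data$group) |>
    dplyr::summarise(scic025 = sum(.data$cic025), .groups = "drop") |>
    dplyr::arrange(.data$sex, dplyr::desc(.data$scic025), .data$group)
}

#' Drug percentage within a SOC
#'
#' `100 * cIC025(drug, SOC) / ScIC025(SOC)` -- the share of the class
#' signal carried by one drug. Undefined (`NA`) when the SOC's ScIC025 is
#' zero.
#'
#' @inheritParams cumulative_ic025
#' @param soc SOC name.
#' @return Percentage in \[0, 100\] or `NA`.
#' @export
drug_percentage <- function(pool, map, drug, soc,
                            mode = c("pool2", "pool1-positive")) {
  denom <- summed_cumulative_ic025(pool, map, soc, level = "soc", mode = mode)
  if (denom <= 0) return(NA_real_)
  100 * cumulative_ic025(pool, map, drug, soc, level = "soc", mode = mode) /
    denom
}

#' Report percentage of a drug within an HLG
#'
#' `100 * (drug's report count with PTs in the HLG) / (drug's total report
#' count)` -- computed from raw report counts, not IC values.
#'
#' @param rows Single-sex report tibble.
#' @param map Hierarchy map.
#' @param drug Drug name (must have at least one report).
#' @param hlg HLG name, or character vector treated as a merged group.
#' @return Percentage in \[0, 100\].
#' @export
report_percentage <- function(rows, map, drug, hlg) {
  dr <- rows[rows$drug == drug, ]
  if (nrow(dr) == 0L || sum(dr$count) == 0) {
    stop("drug '", drug, "' has no reports")
  }
  path <- meddra_lookup(map, dr$pt)
  100 * sum(dr$count[path$mapped & path$hlg %in% hlg]) / sum(dr$count)
}

#' Rank drugs by their cumulative contribution to a group
#'
#' Drugs sorted by descending cIC025 within the scope; ties broken
#' alphabetically by drug name, so rankings are reproducible.
#'
#' @inheritParams cumulative_ic025
#' @param sex Optional `"female"`/`"male"` restriction; default ranks each
#'   sex separately.
#' @param top_k Number of drugs to return per sex (all if larger than the
#'   drug count).
#' @return Tibble `sex`, `group`, `drug`, `cic025`, `rank`.
#' @export
rank_drugs <- function(pool, map, group, level = c("hlg", "soc"),
                       mode = c("pool2", "pool1-positive"),
                       sex = NULL, top_k = 10L) {
  agg <- aggregate_ic025(pool, map, level, mode, groups = group)
  if (!is.null(sex)) agg <- agg[agg$sex %in% sex, ]
  agg |>
    dplyr::arrange(.data$sex, dplyr::desc(.data$cic025), .data$drug) |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup()
}

#' Decompose a group into its adverse events
#'
#' Per preferred term, the cumulative IC025 across all contributing drugs,
#' per sex. `group` may name several HLGs or SOCs: they are treated as a
#' merged group (set union of records; a record contributes once even if
#' its PT sits under more than one merged parent). An optional
#' combined-sex cutoff retains only PTs whose female + male cumulative
#' value exceeds it.
#'
#' @inheritParams aggregate_ic025
#' @param group Character vector of group names to merge.
#' @param cutoff Optional combined-sex cumulative-IC025 cutoff (strict >).
#' @param per_drug If `TRUE`, keep the per-drug breakdown (`sex`, `pt`,
#'   `drug`, `ic025`) instead of the per-PT sums.
#' @return Tibble `sex`, `pt`, `cic025` (or the per-drug breakdown).
#' @export
decompose_group <- function(pool, map, group, level = c("hlg", "soc"),
                            mode = c("pool2", "pool1-positive"),
                            cutoff = NULL, per_drug = FALSE) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  recs <- restrict_mode(pool, mode)
  path <- meddra_lookup(map, recs$pt)
  known <- unique(map[[level]])
  bad <- setdiff(group, known)
  if (length(bad)) stop("unknown ", level, " group: ",
                        paste(bad, collapse = ", "))
  recs <- recs[path$mapped & path[[level]] %in% group, ]
  recs <- dplyr::distinct(recs, .data$sex, .data$drug, .data$pt,
                          .keep_all = TRUE)
  per_pt <- recs |>
    dplyr::group_by(.data$sex, .data$pt) |>
    dplyr::summarise(cic025 = sum(.data$ic025), .groups = "drop")
  if (!is.null(cutoff)) {
    tot <- per_pt |>
      dplyr::group_by(.data$pt) |>
      dplyr::summarise(both = sum(.data$cic025), .groups = "drop")
    keep_pt <- tot$pt[tot$both > cutoff]
    per_pt <- per_pt[per_pt$pt %in% keep_pt, ]
    recs <- recs[recs$pt %in% keep_pt, ]
  }
  if (per_drug) {
    dplyr::arrange(recs[, c("sex", "pt", "drug", "ic025")],
                   .data$sex, .data$pt, .data$drug)
  } else {
    dplyr::arrange(per_pt, .data$sex, dplyr::desc(.data$cic025), .data$pt)
  }
}

restrict_mode <- function(pool, mode) {
  if (mode == "pool2") {
    recs <- if ("in_pool2" %in% names(pool)) pool[pool$in_pool2, ] else pool
    recs[recs$ic025 > 0, ]
  } else {
    pool[pool$ic025 > 0, ]
  }
}
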