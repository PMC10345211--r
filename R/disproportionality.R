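#' Build a 2x2 contingency table for one drug--event pair
#'
#' For a single-sex report table, partitions the total combination count
#' into: `a` = the drug of interest with the event of interest, `b` = all
#' other drugs with the event, `c` = the drug with all other events,
#' `d` = all other drugs with all other events. The background for `b` and
#' `d` is every other drug present in the table (whole-database
#' comparator), not only drugs on the active list.
#'
#' @param rows Single-sex report tibble (columns `drug`, `pt`, `count`).
#' @param drug,pt The pair of interest. A drug or PT absent from `rows`
#'   yields `a = 0`, not an error.
#' @return List with elements `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(rows, drug, pt) {
  if (nrow(rows) == 0L) stop("empty report table")
  if (length(unique(rows$sex)) > 1L) {
    stop("contingency tables are built per sex stratum; got mixed sexes")
  }
  n <- sum(rows$count)
  a <- sum(rows$count[rows$drug == drug & rows$pt == pt])
  drug_total <- sum(rows$count[rows$drug == drug])
  pt_total <- sum(rows$count[rows$pt == pt])
  list(a = a, b = pt_total - a, c = drug_total - a,
       d = n - pt_total - drug_total + a, n = n)
}

#' Information component (IC)
#'
#' `IC = log2((a + 0.5) / (aexp + 0.5))` with the expected count
#' `aexp = (a + b)(a + c) / n`. The 0.5 continuity correction keeps the
#' ratio positive, so IC is finite for every valid table.
#'
#' @param t A contingency table from [build_contingency()], or a list/data
#'   frame with numeric (vector) elements `a`, `b`, `c`, `d`.
#' @return IC in bits (vectorised).
#' @export
compute_ic <- function(t) {
  m <- ct_counts(t)
  log2((m$a + 0.5) / (compute_aexp(t) + 0.5))
}

#' Expected count under independence
#' @inheritParams compute_ic
#' @return `aexp = (a + b)(a + c) / n`.
#' @export
compute_aexp <- function(t) {
  m <- ct_counts(t)
  n <- m$a + m$b + m$c + m$d
  if (any(n == 0)) stop("contingency table has zero total")
  (m$a + m$b) * (m$a + m$c) / n
}

#' Lower 95% credibility bound of the IC (IC025)
#'
#' Closed-form approximation
#' `IC025 = IC - 3.3 (a + 0.5)^(-1/2) - 2 (a + 0.5)^(-3/2)`;
#' strictly below IC for every table. `IC025 > 0` is the conventional
#' signal criterion.
#'
#' @inheritParams compute_ic
#' @return IC025 in bits (vectorised).
#' @export
compute_ic025 <- function(t) {
  m <- ct_counts(t)
  compute_ic(t) - 3.3 * (m$a + 0.5)^(-1 / 2) - 2 * (m$a + 0.5)^(-3 / 2)
}

#' Proportional reporting ratio (PRR)
#'
#' `PRR = (a / (a + c)) / (b / (b + d))`. Undefined when the drug has no
#' reports (`a + c = 0`), the background has none (`b + d = 0`), or the
#' event never occurs in the background (`b = 0`); undefined values are
#' returned as the explicit sentinel `NA` (never infinity) and are excluded
#' from screening.
#'
#' @inheritParams compute_ic
#' @return PRR (vectorised), `NA` where undefined.
#' @export
compute_prr <- function(t) {
  m <- ct_counts(t)
  out <- (m$a / (m$a + m$c)) / (m$b / (m$b + m$d))
  out[m$a + m$c == 0 | m$b + m$d == 0 | m$b == 0] <- NA_real_
  out
}

#' Reporting odds ratio (ROR)
#'
#' `ROR = (a d) / (b c)`, `NA` sentinel when `b c = 0`.
#'
#' @inheritParams compute_ic
#' @return ROR (vectorised), `NA` where undefined.
#' @export
compute_ror <- function(t) {
  m <- ct_counts(t)
  out <- (m$a * m$d) / (m$b * m$c)
  out[m$b * m$c == 0] <- NA_real_
  out
}

#' Score every drug--event pair of one sex stratum (pool 1)
#'
#' Builds the 2x2 table and all four disproportionality statistics for
#' every (drug, preferred term) pair with at least one co-mention, for
#' drugs on the active list (all observed pairs if `drug_list` is `NULL`).
#' Vectorised, but numerically identical to calling [build_contingency()]
#' and the per-metric functions pair by pair.
#'
#' @param rows Single-sex report tibble.
#' @param drug_list Optional drug list ([load_drug_list()]) restricting the
#'   drugs of interest; other drugs still contribute to the background.
#' @return Pool-1 tibble with columns `sex`, `drug`, `pt`, `a`, `aexp`,
#'   `ic`, `ic025`, `prr`, `ror`.
#' @export
score_all_pairs <- function(rows, drug_list = NULL) {
  if (nrow(rows) == 0L) stop("empty report table")
  sexes <- unique(as.character(rows$sex))
  if (length(sexes) > 1L) stop("score_all_pairs expects a single sex stratum")
  n <- sum(rows$count)
  pair <- rows |>
    dplyr::group_by(.data$drug, .data$pt) |>
    dplyr::summarise(a = sum(.data$count), .groups = "drop")
  drug_tot <- stats::aggregate(count ~ drug, rows, sum)
  pt_tot <- stats::aggregate(count ~ pt, rows, sum)
  if (!is.null(drug_list)) {
    pair <- pair[pair$drug %in% drug_list$canonical, ]
    if (nrow(pair) == 0L) {
      warning("no reports for any drug on the active list; empty pool")
    }
  }
  a <- pair$a
  drug_total <- drug_tot$count[match(pair$drug, drug_tot$drug)]
  pt_total <- pt_tot$count[match(pair$pt, pt_tot$pt)]
  tab <- list(a = a, b = pt_total - a, c = drug_total - a,
              d = n - pt_total - drug_total + a)
  tibble::tibble(
    sex = factor(rep(sexes, nrow(pair)), levels = c("female", "male")),
    drug = pair$drug, pt = pair$pt,
    a = a, aexp = compute_aexp(tab),
    ic = compute_ic(tab), ic025 = compute_ic025(tab),
    prr = compute_prr(tab), ror = compute_ror(tab)
  ) |> dplyr::arrange(.data$drug, .data$pt)
}

#' Screen pool 1 into pool 2
#'
#' Retains records with `prr > prr_min` and `ic025 > ic025_min` (both
#' strict) and `a >= a_min`. Records with an undefined (NA) PRR are
#' excluded. The defaults are the conventional screen: PRR > 2, IC025 > 0,
#' five or more records.
#'
#' @param pool1 Pool-1 tibble from [score_all_pairs()] (any number of
#'   sexes bound together).
#' @param prr_min,ic025_min,a_min Screening thresholds.
#' @param keep_all If `TRUE`, return every pool-1 record with an
#'   `in_pool2` flag; if `FALSE` (default) return only the retained
#'   records (pool 2), still carrying `in_pool2 = TRUE`.
#' @return Tibble with the pool-1 columns plus `in_pool2`.
#' @export
screen_signals <- function(pool1, prr_min = 2, ic025_min = 0, a_min = 5,
                           keep_all = FALSE) {
  flag <- !is.na(pool1$prr) & pool1$prr > prr_min &
    pool1$ic025 > ic025_min & pool1$a >= a_min
  out <- dplyr::mutate(pool1, in_pool2 = flag)
  if (keep_all) out else out[flag, ]
}

#' Write / read a signal pool
#'
#' Tidy TSV serialisation of pool 1 or pool 2; round-trip safe.
#' @param pool Pool tibble.
#' @param path TSV path.
#' @export
write_pool <- function(pool, path) {
  readr::write_tsv(dplyr::mutate(pool, sex = as.character(.data$sex)), path)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  cols <- readr::cols(sex = readr::col_character(),
                      drug = readr::col_character(),
                      pt = readr::col_character(),
                      a = readr::col_integer(),
                      in_pool2 = readr::col_logical(),
                      .default = readr::col_double())
  pool <- readr::read_tsv(path, col_types = cols, progress = FALSE)
  pool$sex <- factor(pool$sex, levels = c("female", "male"))
  if ("in_pool2" %in% names(pool)) pool$in_pool2 <- as.logical(pool$in_pool2)
  pool
}

ct_counts <- function(t) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(t)))
  lapply(t[c("a", "b", "c", "d")], as.numeric)
}
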