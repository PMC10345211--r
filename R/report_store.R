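#' Read and normalise a spontaneous adverse-event report table
#'
#' Reads a long-format report table with one row per drug--adverse-event
#' co-mention (optionally pre-aggregated via a `count` column), normalises
#' drug names against a drug list, drops rows whose sex is not recorded as
#' female or male, applies an optional exclusion list, and aggregates
#' duplicate (sex, drug, pt) keys by summing their counts.
#'
#' The counting unit throughout the package is the drug--adverse-event
#' combination: one retained row with `count = k` stands for `k` co-mentions
#' of that drug with that preferred term in reports of that sex.
#'
#' @param path Path to a CSV or TSV file (gzip accepted) with columns
#'   `sex`, `drug`, `pt` and optionally `count`. Header required.
#' @param drug_list Optional drug list from [load_drug_list()]; synonyms are
#'   mapped to their canonical name. Drugs not on the list are retained
#'   under their own normalised name -- they form the "all other drugs"
#'   background of the disproportionality analysis.
#' @param exclusions Optional tibble/data.frame with columns `sex`, `drug`,
#'   `pt` naming row keys to drop (e.g. an externally curated list of
#'   offspring-related records in female reports). Keys are matched after
#'   normalisation.
#' @param quiet Suppress the ingestion log message.
#'
#' @return A tibble with columns `sex` (factor, levels `female`, `male`),
#'   `drug`, `pt`, `count`, one row per retained (sex, drug, pt) key.
#'   The attribute `"ingest_log"` records per-category drop counts; total
#'   input count equals retained count plus logged drops (conservation).
#' @export
load_reports <- function(path, drug_list = NULL, exclusions = NULL,
                         quiet = FALSE) {
  raw <- read_table_auto(path)
  if (nrow(raw) == 0L) stop("report table is empty: ", path)
  for (col in c("sex", "drug", "pt")) {
    if (!col %in% names(raw)) {
      stop("report table is missing required column '", col, "'")
    }
  }
  if (!"count" %in% names(raw)) raw$count <- 1L
  count_num <- suppressWarnings(as.numeric(raw$count))
  bad <- which(is.na(count_num) | count_num < 1 |
                 count_num != round(count_num))
  if (length(bad) > 0L) {
    stop("unparseable or non-positive count in row ", bad[1],
         " (value '", raw$count[bad[1]], "')")
  }
  rows <- tibble::tibble(
    sex   = normalize_sex(raw$sex),
    drug  = normalize_drug(raw$drug),
    pt    = tolower(trimws(as.character(raw$pt))),
    count = as.integer(count_num)
  )

  total_in <- sum(rows$count)
  log <- list(total_input = total_in)

  keep <- !is.na(rows$sex)
  log$dropped_unknown_sex <- sum(rows$count[!keep])
  rows <- rows[keep, ]

  if (!is.null(drug_list)) {
    rows$drug <- map_synonyms(rows$drug, drug_list)
  }

  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    excl_key <- paste(normalize_sex(exclusions$sex),
                      normalize_drug(exclusions$drug),
                      tolower(trimws(exclusions$pt)), sep = "\r")
    row_key <- paste(rows$sex, rows$drug, rows$pt, sep = "\r")
    hit <- row_key %in% excl_key
    log$dropped_excluded <- sum(rows$count[hit])
    rows <- rows[!hit, ]
  } else {
    log$dropped_excluded <- 0L
  }

  rows <- rows |>
    dplyr::group_by(.data$sex, .data$drug, .data$pt) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$sex, .data$drug, .data$pt)

  log$total_retained <- sum(rows$count)
  stopifnot(log$total_retained + log$dropped_unknown_sex +
              log$dropped_excluded == total_in)
  if (!quiet) {
    message(sprintf(
      "load_reports: %d combinations in, %d retained (%d unknown-sex, %d excluded dropped)",
      log$total_input, log$total_retained,
      log$dropped_unknown_sex, log$dropped_excluded))
  }
  attr(rows, "ingest_log") <- log
  rows
}

#' Read a drug list with synonyms
#'
#' @param path TSV with columns `canonical` and `synonyms` (pipe-separated;
#'   may be empty). Names are normalised to lowercase/trimmed.
#' @return A tibble with columns `canonical` (unique) and `synonyms`
#'   (list column). Synonym sets must be disjoint across entries.
#' @export
load_drug_list <- function(path) {
  raw <- read_table_auto(path)
  for (col in c("canonical", "synonyms")) {
    if (!col %in% names(raw)) {
      stop("drug list is missing required column '", col, "'")
    }
  }
  canonical <- normalize_drug(raw$canonical)
  if (anyDuplicated(canonical)) {
    stop("duplicate canonical drug name after normalisation: ",
         canonical[duplicated(canonical)][1])
  }
  syn <- lapply(raw$synonyms, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character())
    unique(normalize_drug(strsplit(s, "|", fixed = TRUE)[[1]]))
  })
  all_syn <- unlist(syn)
  if (anyDuplicated(all_syn)) {
    stop("synonym appears under more than one canonical drug: ",
         all_syn[duplicated(all_syn)][1])
  }
  tibble::tibble(canonical = canonical, synonyms = syn)
}

#' Read a MedDRA-style mapping table
#'
#' Maps each preferred term (PT) to its high-level term (HLT), high-level
#' group (HLG) and system organ class (SOC). Each PT must map to exactly
#' one path; duplicate identical rows are deduplicated, conflicting
#' duplicates are a hard error.
#'
#' @param path TSV with columns `pt`, `hlt`, `hlg`, `soc`. A leading
#'   comment line of the form `# version: 22.1` supplies the dictionary
#'   version; alternatively pass `version` directly.
#' @param version Optional version string overriding the file header.
#' @return A tibble with columns `pt`, `hlt`, `hlg`, `soc` and attribute
#'   `"meddra_version"`.
#' @export
load_meddra_map <- function(path, version = NULL) {
  if (is.null(version)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    first <- readLines(con, n = 1L)
    close(con)
    m <- regmatches(first, regexec("^#\\s*version:\\s*(\\S+)", first))[[1]]
    if (length(m) == 2L) version <- m[2]
  }
  raw <- read_table_auto(path, comment = "#")
  for (col in c("pt", "hlt", "hlg", "soc")) {
    if (!col %in% names(raw)) {
      stop("MedDRA map is missing required column '", col, "'")
    }
  }
  map <- tibble::tibble(
    pt  = tolower(trimws(raw$pt)),
    hlt = trimws(raw$hlt),
    hlg = trimws(raw$hlg),
    soc = trimws(raw$soc)
  ) |> dplyr::distinct()
  dup <- map$pt[duplicated(map$pt)]
  if (length(dup) > 0L) {
    stop("PT mapped to conflicting hierarchy paths: ",
         paste(unique(dup), collapse = ", "))
  }
  if (is.null(version)) {
    warning("MedDRA map has no version header; version set to 'unspecified'")
    version <- "unspecified"
  }
  attr(map, "meddra_version") <- version
  map
}

#' Look up the hierarchy path of preferred terms
#'
#' @param map A map from [load_meddra_map()] or [build_toy_hierarchy()].
#' @param pt Character vector of preferred terms.
#' @return Tibble with columns `pt`, `hlt`, `hlg`, `soc`, `mapped`. PTs
#'   absent from the map are returned with `mapped = FALSE` and `NA` path
#'   components -- an explicit "unmapped" sentinel, never a default group.
#' @export
meddra_lookup <- function(map, pt) {
  q <- tibble::tibble(pt = tolower(trimws(pt)))
  out <- dplyr::left_join(q, map, by = "pt")
  out$mapped <- !is.na(out$soc)
  out
}

#' Split a report table by sex
#'
#' @param rows Report tibble from [load_reports()] or [generate_reports()].
#' @return Named list with elements `female` and `male`; the two parts are
#'   disjoint and exhaustive over the input rows.
#' @export
split_by_sex <- function(rows) {
  list(female = rows[rows$sex == "female", ],
       male   = rows[rows$sex == "male", ])
}

#' Write a normalised report table
#'
#' Round-trip safe with [load_reports()]: loading the written file
#' reproduces identical rows.
#' @param rows Report tibble.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @export
write_reports <- function(rows, path) {
  readr::write_tsv(dplyr::mutate(rows, sex = as.character(.data$sex)), path)
  invisible(path)
}

# -- internal helpers --------------------------------------------------------

read_table_auto <- function(path, comment = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, comment = comment,
                    show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("f", "female")] <- "female"
  out[x %in% c("m", "male")] <- "male"
  factor(out, levels = c("female", "male"))
}

normalize_drug <- function(x) {
  tolower(trimws(as.character(x)))
}

map_synonyms <- function(drug, drug_list) {
  syn_tab <- tibble::tibble(
    synonym   = unlist(drug_list$synonyms),
    canonical = rep(drug_list$canonical,
                    lengths(drug_list$synonyms))
  )
  idx <- match(drug, syn_tab$synonym)
  ifelse(is.na(idx), drug, syn_tab$canonical[idx])
}
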