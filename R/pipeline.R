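#' Assemble a pipeline configuration
#'
#' Collects the inputs and tuning knobs of the end-to-end analysis:
#' ingest, sex split, per-pair scoring (pool 1), screening (pool 2),
#' hierarchy aggregation and sex contrast. All referenced files must
#' exist when the pipeline starts; the configuration round-trips
#' losslessly through JSON.
#'
#' @param reports Path to the report table, or a report tibble.
#' @param meddra Path to the hierarchy map, or a map tibble.
#' @param drugs Optional path to the drug list, or a drug-list tibble.
#' @param exclusions Optional exclusion-key table (path or tibble).
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param prr_min,ic025_min,a_min Screening thresholds.
#' @param mode Aggregation mode, `"pool2"` or `"pool1-positive"`.
#' @param ratio_threshold Sex-contrast dominance threshold.
#' @param group_unions Named list of merged groups, e.g.
#'   `list(neuropsychiatric = c("soc_1", "soc_2"))`.
#' @param agg_level `"hlg"` or `"soc"` for the main aggregation pass.
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reports, meddra, drugs = NULL, exclusions = NULL,
                            out_dir = tempfile("vigiprof_run_"),
                            prr_min = 2, ic025_min = 0, a_min = 5,
                            mode = c("pool2", "pool1-positive"),
                            ratio_threshold = 2.0,
                            group_unions = list(),
                            agg_level = c("soc", "hlg"),
                            seed = 1L) {
  mode <- match.arg(mode)
  agg_level <- match.arg(agg_level)
  stopifnot(prr_min > 0, a_min >= 1, ratio_threshold > 1)
  for (p in list(reports, meddra, drugs, exclusions)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      stop("input file not found: ", p)
    }
  }
  structure(list(reports = reports, meddra = meddra, drugs = drugs,
                 exclusions = exclusions, out_dir = out_dir,
                 prr_min = prr_min, ic025_min = ic025_min, a_min = a_min,
                 mode = mode, ratio_threshold = ratio_threshold,
                 group_unions = group_unions, agg_level = agg_level,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes ingest, sex split, pool-1 scoring, pool-2 screening, ScIC025
#' aggregation (including declared group unions) and the sex contrast,
#' writing one tidy TSV per stage plus a JSON manifest that records the
#' seed, row and combination counts at every stage, the aggregation mode
#' and a hash of the configuration -- everything needed to regenerate the
#' outputs.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  drug_list <- stage("drug_list", {
    if (is.character(config$drugs)) load_drug_list(config$drugs)
    else config$drugs
  })
  excl <- stage("exclusions", {
    if (is.character(config$exclusions)) read_table_auto(config$exclusions)
    else config$exclusions
  })
  rows <- stage("ingest", {
    if (is.character(config$reports)) {
      load_reports(config$reports, drug_list, excl, quiet = quiet)
    } else config$reports
  })
  map <- stage("meddra", {
    if (is.character(config$meddra)) load_meddra_map(config$meddra)
    else config$meddra
  })

  strata <- split_by_sex(rows)
  pools1 <- stage("score", lapply(strata, score_all_pairs, drug_list = drug_list))
  pool1 <- dplyr::bind_rows(pools1)
  screened <- stage("screen", screen_signals(
    pool1, config$prr_min, config$ic025_min, config$a_min, keep_all = TRUE))
  pool2 <- screened[screened$in_pool2, ]

  write_pool(screened, file.path(config$out_dir, "pool1.tsv"))
  write_pool(pool2, file.path(config$out_dir, "pool2.tsv"))

  agg <- stage("aggregate", {
    base <- scic025_table(screened, map, level = config$agg_level,
                          mode = config$mode)
    unions <- lapply(names(config$group_unions), function(nm) {
      g <- config$group_unions[[nm]]
      a <- aggregate_ic025(screened, map, level = config$agg_level,
                           mode = config$mode, groups = g)
      a |>
        dplyr::group_by(.data$sex) |>
        dplyr::summarise(scic025 = sum(.data$cic025), .groups = "drop") |>
        dplyr::mutate(group = nm, .after = "sex")
    })
    dplyr::bind_rows(base, dplyr::bind_rows(unions))
  })
  readr::write_tsv(dplyr::mutate(agg, sex = as.character(.data$sex)),
                   file.path(config$out_dir, "scic025.tsv"))

  contrast <- stage("contrast", {
    paired <- pair_signals(pool2[pool2$sex == "female", ],
                           pool2[pool2$sex == "male", ])
    classify_pairs(paired, config$ratio_threshold)
  })
  readr::write_tsv(dplyr::mutate(contrast, class = as.character(.data$class)),
                   file.path(config$out_dir, "sex_contrast.tsv"))

  ingest_log <- attr(rows, "ingest_log")
  manifest <- list(
    package_version = as.character(utils::packageVersion("vigiprof")),
    seed = config$seed,
    mode = config$mode,
    agg_level = config$agg_level,
    thresholds = list(prr_min = config$prr_min, ic025_min = config$ic025_min,
                      a_min = config$a_min,
                      ratio_threshold = config$ratio_threshold),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    counts = list(
      combinations_total = sum(rows$count),
      combinations_female = sum(rows$count[rows$sex == "female"]),
      combinations_male = sum(rows$count[rows$sex == "male"]),
      pool1_records = nrow(pool1),
      pool1_drugs = length(unique(pool1$drug)),
      pool2_records = nrow(pool2),
      pool2_drugs = length(unique(pool2$drug)),
      contrast_pairs = nrow(contrast),
      ingest = if (!is.null(ingest_log)) ingest_log else NULL
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
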