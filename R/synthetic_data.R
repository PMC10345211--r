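#' Configure a synthetic spontaneous-report simulation
#'
#' Defines a FAERS-like generating process with known ground truth: for each
#' sex, (drug, event) pairs are drawn from the independence table
#' `p(drug) * p(pt)`, optionally distorted by injected signals that multiply
#' the joint probability of chosen (drug, pt, sex) cells by a factor `lam`
#' (`lam = 1` is the null). After injection the table is renormalised per
#' sex, so `lam` is interpretable as a relative reporting-rate multiplier up
#' to the total injected mass.
#'
#' @param n_reports Reports (drug--event combinations) per sex. Either a
#'   single number or a named vector with elements `female` and `male`.
#' @param drugs Named numeric vector of drug marginal probabilities
#'   (must sum to 1 within 1e-9).
#' @param pts Named numeric vector of preferred-term marginal probabilities
#'   (must sum to 1 within 1e-9).
#' @param injections Tibble/data.frame with columns `drug`, `pt`, `sex`
#'   (`"female"`, `"male"` or `"both"`) and `lam` (> 0), or `NULL` for the
#'   pure null.
#' @param seed Integer seed; the single source of randomness for the
#'   generator.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_reports, drugs, pts, injections = NULL,
                              seed = 1L) {
  if (length(n_reports) == 1L && is.null(names(n_reports))) {
    n_reports <- c(female = n_reports, male = n_reports)
  }
  stopifnot(all(c("female", "male") %in% names(n_reports)),
            all(n_reports >= 1))
  if (abs(sum(drugs) - 1) > 1e-9) stop("drug marginals must sum to 1")
  if (abs(sum(pts) - 1) > 1e-9) stop("PT marginals must sum to 1")
  if (is.null(names(drugs)) || is.null(names(pts))) {
    stop("drug and PT marginals must be named")
  }
  if (!is.null(injections)) {
    injections <- tibble::as_tibble(injections)
    stopifnot(all(c("drug", "pt", "sex", "lam") %in% names(injections)))
    if (any(injections$lam <= 0)) stop("injection lam must be > 0")
    unknown_drug <- setdiff(injections$drug, names(drugs))
    if (length(unknown_drug)) {
      stop("injection references unknown drug: ",
           paste(unknown_drug, collapse = ", "))
    }
    unknown_pt <- setdiff(injections$pt, names(pts))
    if (length(unknown_pt)) {
      stop("injection references unknown PT: ",
           paste(unknown_pt, collapse = ", "))
    }
    if (!all(injections$sex %in% c("female", "male", "both"))) {
      stop("injection sex must be 'female', 'male' or 'both'")
    }
  }
  structure(list(n_reports = n_reports, drugs = drugs, pts = pts,
                 injections = injections, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation conditions
#'
#' The reference generating process used throughout the package's own
#' analyses: 30 drugs and 150 preferred terms with Zipf-shaped marginal
#' probabilities (`p(rank r) proportional to 1/r`), emulating the skewed
#' report volumes of a spontaneous-report database, and 200,000
#' drug--event combinations per sex.
#'
#' @param n_reports Reports per sex (default 200000).
#' @param n_drugs,n_pts Vocabulary sizes.
#' @param injections,seed Passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(n_reports = 2e5, n_drugs = 30, n_pts = 150,
                               injections = NULL, seed = 1L) {
  zipf <- function(k, prefix) {
    p <- 1 / seq_len(k)
    stats::setNames(p / sum(p), sprintf("%s%03d", prefix, seq_len(k)))
  }
  simulation_config(n_reports, zipf(n_drugs, "drug"), zipf(n_pts, "pt"),
                    injections = injections, seed = seed)
}

#' The study's signal-injection design
#'
#' Five distinct (drug, pt) cells at mid-rank marginals, with reporting-rate
#' multipliers lam in {4, 8, 16}, injected in both sexes. The baseline
#' expected pair counts under the default conditions are in the tens, the
#' rare-event regime in which the empirical PRR approximates lam.
#'
#' @return Tibble with columns `drug`, `pt`, `sex`, `lam`.
#' @export
study_injections <- function() {
  tibble::tibble(
    drug = c("drug005", "drug008", "drug010", "drug012", "drug015"),
    pt   = c("pt010",   "pt015",   "pt020",   "pt025",   "pt030"),
    sex  = "both",
    lam  = c(4, 8, 16, 4, 8)
  )
}

#' Generate a synthetic report table
#'
#' Multinomial sampling over the renormalised per-sex joint probability
#' table. Identical seed gives identical output; the generated total equals
#' the configured `n_reports` per sex exactly.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return Report tibble (columns `sex`, `drug`, `pt`, `count`) valid as
#'   [load_reports()] output.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_local_seed(config$seed, {
    parts <- lapply(c("female", "male"), function(sx) {
      joint <- outer(config$drugs, config$pts)
      inj <- config$injections
      if (!is.null(inj)) {
        inj_sx <- inj[inj$sex %in% c(sx, "both"), ]
        for (i in seq_len(nrow(inj_sx))) {
          joint[inj_sx$drug[i], inj_sx$pt[i]] <-
            joint[inj_sx$drug[i], inj_sx$pt[i]] * inj_sx$lam[i]
        }
      }
      p <- as.vector(joint / sum(joint))
      counts <- as.vector(stats::rmultinom(1, config$n_reports[[sx]], p))
      keep <- counts > 0L
      grid <- expand.grid(drug = names(config$drugs), pt = names(config$pts),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      tibble::tibble(sex = sx, drug = grid$drug[keep], pt = grid$pt[keep],
                     count = counts[keep])
    })
    dplyr::bind_rows(parts)
  })
  out$sex <- factor(out$sex, levels = c("female", "male"))
  dplyr::arrange(out, .data$sex, .data$drug, .data$pt)
}

#' Build a toy three-level hierarchy
#'
#' Deterministic synthetic MedDRA-style map for tests and simulations:
#' `n_soc` system organ classes, each holding `n_hlg_per_soc` high-level
#' groups, each holding `n_pt_per_hlg` preferred terms (one HLT per HLG).
#'
#' @param n_soc,n_hlg_per_soc,n_pt_per_hlg Positive integers.
#' @return Map tibble as from [load_meddra_map()], version `"toy"`.
#' @export
build_toy_hierarchy <- function(n_soc, n_hlg_per_soc, n_pt_per_hlg) {
  if (any(c(n_soc, n_hlg_per_soc, n_pt_per_hlg) < 1)) {
    stop("all hierarchy dimensions must be >= 1")
  }
  grid <- expand.grid(pt_i = seq_len(n_pt_per_hlg),
                      hlg_i = seq_len(n_hlg_per_soc),
                      soc_i = seq_len(n_soc),
                      KEEP.OUT.ATTRS = FALSE)
  map <- tibble::tibble(
    pt  = sprintf("pt_s%d_g%d_p%d", grid$soc_i, grid$hlg_i, grid$pt_i),
    hlt = sprintf("hlt_s%d_g%d", grid$soc_i, grid$hlg_i),
    hlg = sprintf("hlg_s%d_g%d", grid$soc_i, grid$hlg_i),
    soc = sprintf("soc_%d", grid$soc_i)
  )
  attr(map, "meddra_version") <- "toy"
  map
}

#' Attach a toy hierarchy to a simulated vocabulary
#'
#' Assigns the PT names of a simulation config to the PTs of a toy
#' hierarchy in order, so simulated reports can be aggregated. The
#' hierarchy must have at least as many PT slots as the vocabulary.
#'
#' @param config A `sim_config`.
#' @param n_soc,n_hlg_per_soc Hierarchy shape; PTs per HLG is derived.
#' @return Map tibble whose `pt` column is the config's PT vocabulary.
#' @export
toy_hierarchy_for <- function(config, n_soc = 3, n_hlg_per_soc = 2) {
  n_pt <- length(config$pts)
  per_hlg <- ceiling(n_pt / (n_soc * n_hlg_per_soc))
  map <- build_toy_hierarchy(n_soc, n_hlg_per_soc, per_hlg)
  map <- map[seq_len(n_pt), ]
  map$pt <- names(config$pts)
  attr(map, "meddra_version") <- "toy"
  map
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
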