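#' Default drug catalogue for the simulator
#'
#' A small catalogue of QT-relevant and background drugs with marginal
#' exposure probabilities in the low single-percent range typical of a
#' spontaneous-reporting database, level-5 ATC codes, optional synonym
#' variants (emitted in place of the canonical name for a share of
#' mentions) and optional ambiguous aliases (unresolvable names the
#' curation step must discard).
#'
#' @return tibble with columns `name`, `p_exposure`, `atc_codes`
#'   (semicolon-separated), `synonym`, `ambiguous_alias`.
#' @export
default_drug_catalogue <- function() {
  tibble::tibble(
    name = c("furosemide", "quetiapine", "citalopram", "ondansetron",
             "metoprolol", "omeprazole", "acetaminophen",
             "acetylsalicylic acid", "amiodarone", "levothyroxine sodium"),
    p_exposure = c(0.030, 0.025, 0.020, 0.020, 0.030, 0.030, 0.040,
                   0.035, 0.015, 0.020),
    atc_codes = c("C03CA01", "N05AH04", "N06AB04", "A04AA01", "C07AB02",
                  "A02BC01", "N02BE01", "B01AC06;N02BA01", "C01BD01",
                  "H03AA01"),
    synonym = c(NA, NA, NA, NA, NA, NA, "paracetamol", "aspirin", NA, NA),
    ambiguous_alias = c(NA, NA, NA, NA, "beta blocker nos", NA, NA,
                        "pain reliever nos", NA, NA)
  )
}

.default_pt_baseline_odds <- function() {
  c("Electrocardiogram QT prolonged" = 0.006,
    "Ventricular tachycardia" = 0.005,
    "Torsade de pointes" = 0.004,
    "Long QT syndrome" = 0.002,
    "Electrocardiogram QT interval abnormal" = 0.0015,
    "Long QT syndrome congenital" = 0.0005)
}

.filler_pts <- c("Nausea", "Headache", "Dizziness", "Fatigue", "Rash",
                 "Vomiting", "Diarrhoea", "Pyrexia", "Dyspnoea",
                 "Pruritus", "Insomnia", "Arthralgia")

.default_demographics <- function() {
  list(
    qualification = c(physician = 0.35, `other health professional` = 0.30,
                      pharmacist = 0.10, consumer = 0.19, lawyer = 0.01,
                      unknown = 0.05),
    sex = c(female = 0.54, male = 0.40, unknown = 0.06),
    country = c(US = 0.58, GB = 0.08, JP = 0.07, FR = 0.06, CA = 0.05,
                DE = 0.05, IT = 0.03, ES = 0.03, AU = 0.02, BR = 0.02,
                NL = 0.01),
    age_mean = 62, age_sd = 18, age_missing = 0.08,
    outcome_probs = c(hospitalization = 0.50, death = 0.12,
                      `life-threatening` = 0.08, disability = 0.03,
                      other = 0.35)
  )
}

#' Simulation configuration
#'
#' Fixes every knob of the synthetic report-stream generator: background
#' report count, study window, drug catalogue with marginal exposure
#' probabilities, per-PT baseline odds, planted per-(drug, PT)
#' multiplicative odds (`ror`), curation-noise rates, follow-up rate,
#' demographic samplers and the seed that determines the full stream.
#'
#' @param n_reports number of distinct reports to generate.
#' @param seed integer seed; the stream is fully determined by it.
#' @param window a [study_window] for receipt dates.
#' @param drugs drug catalogue tibble as in [default_drug_catalogue()].
#' @param pt_baseline_odds named numeric vector of baseline odds for the
#'   six narrow PTs.
#' @param planted optional tibble (`drug`, `pt`, `ror`) of planted
#'   association strengths; pairs not listed have odds multiplier 1.
#' @param missing_generic_rate share of primary-suspect mentions emitted
#'   with no generic name.
#' @param ambiguous_rate share of primary-suspect mentions emitted under
#'   the drug's ambiguous alias (only drugs with an alias).
#' @param synonym_rate share of primary-suspect mentions emitted under
#'   the drug's synonym variant (only drugs with a variant).
#' @param duplicate_rate share of surviving primary-suspect mentions
#'   repeated within the same report.
#' @param followup_rate share of reports re-issued as a follow-up record
#'   with the same report ID and a later receipt date.
#' @param multi_suspect mark every exposed drug as primary suspect
#'   instead of exactly one.
#' @param demographics list of samplers, see the default in the source.
#' @return an object of class `faers_sim_config`.
#' @export
faers_sim_config <- function(n_reports = 5000, seed = 1,
                             window = study_window("2004-01-01", "2022-12-31"),
                             drugs = default_drug_catalogue(),
                             pt_baseline_odds = .default_pt_baseline_odds(),
                             planted = NULL,
                             missing_generic_rate = 0.05,
                             ambiguous_rate = 0.03,
                             synonym_rate = 0.5,
                             duplicate_rate = 0.03,
                             followup_rate = 0.02,
                             multi_suspect = FALSE,
                             demographics = .default_demographics()) {
  drugs <- tibble::as_tibble(drugs)
  stopifnot(
    n_reports >= 1,
    inherits(window, "study_window"),
    all(c("name", "p_exposure", "atc_codes") %in% names(drugs)),
    all(drugs$p_exposure >= 0 & drugs$p_exposure <= 1),
    all(pt_baseline_odds > 0),
    setequal(names(pt_baseline_odds), qt_smq()$pts$name)
  )
  rates <- c(missing_generic_rate, ambiguous_rate, synonym_rate,
             duplicate_rate, followup_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (!"synonym" %in% names(drugs)) drugs$synonym <- NA_character_
  if (!"ambiguous_alias" %in% names(drugs)) drugs$ambiguous_alias <- NA_character_
  if (anyDuplicated(fold_name(drugs$name))) {
    stop("catalogue drug names must be unique", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("drug", "pt", "ror") %in% names(planted)),
              all(planted$ror > 0),
              all(fold_name(planted$drug) %in% fold_name(drugs$name)),
              all(planted$pt %in% qt_smq()$pts$name))
  }
  structure(
    list(n_reports = as.integer(n_reports), seed = as.integer(seed),
         window = window, drugs = drugs,
         pt_baseline_odds = pt_baseline_odds[qt_smq()$pts$name],
         planted = planted,
         missing_generic_rate = missing_generic_rate,
         ambiguous_rate = ambiguous_rate, synonym_rate = synonym_rate,
         duplicate_rate = duplicate_rate, followup_rate = followup_rate,
         multi_suspect = multi_suspect, demographics = demographics),
    class = "faers_sim_config"
  )
}

# planted odds multipliers as a D x 6 matrix (default 1)
.planted_matrix <- function(config) {
  pts <- qt_smq()$pts$name
  D <- nrow(config$drugs)
  R <- matrix(1, D, length(pts),
              dimnames = list(fold_name(config$drugs$name), pts))
  if (!is.null(config$planted)) {
    for (i in seq_len(nrow(config$planted))) {
      R[fold_name(config$planted$drug[i]), config$planted$pt[i]] <-
        config$planted$ror[i]
    }
  }
  R
}

#' Synonym table implied by a simulation config
#'
#' Builds the curation inputs matching the generator's name noise: each
#' catalogue synonym variant maps to its canonical name, each ambiguous
#' alias is listed as ambiguous.
#'
#' @param config a `faers_sim_config`.
#' @return a [synonym_table].
#' @export
sim_synonym_table <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  has_syn <- !is.na(config$drugs$synonym)
  synonym_table(
    map = stats::setNames(config$drugs$name[has_syn],
                          config$drugs$synonym[has_syn]),
    ambiguous = config$drugs$ambiguous_alias[!is.na(config$drugs$ambiguous_alias)]
  )
}

#' ATC map implied by a simulation config
#' @param config a `faers_sim_config`.
#' @return an [atc_map].
#' @export
sim_atc_map <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  config$drugs |>
    dplyr::select("name", "atc_codes") |>
    tidyr::separate_rows("atc_codes", sep = ";") |>
    dplyr::rename(generic_name = "name", atc_code = "atc_codes") |>
    atc_map()
}

.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic openFDA-style report stream with ground truth
#'
#' Samples, per report: exposed drugs (independent Bernoulli per
#' catalogue drug); each narrow PT with odds equal to its baseline odds
#' times the product of the planted multipliers of the exposed drugs;
#' one exposed drug as primary suspect (all of them under
#' `multi_suspect`), the rest concomitant/interacting; filler non-target
#' reactions; demographics and outcomes. Name noise (missing generic
#' names, ambiguous aliases, synonym variants), within-report duplicate
#' mentions and follow-up re-issues are injected at the configured rates
#' and tallied into the ground truth so the curation ledger can be
#' checked exactly. Deterministic given the config seed.
#'
#' @param config a [faers_sim_config()].
#' @return an object of class `faers_sim`: list with
#'   * `reports` — a [faers_reports] stream (follow-ups appended last),
#'   * `truth` — list with `target_record_seqs`, `target_report_ids`,
#'     `n_reports`, `n_followups`, `planted` (full multiplier matrix) and
#'     `ledger` (the intended curation tallies over target reports),
#'   * `synonyms`, `atc` — the matching curation inputs.
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  cat_ <- config$drugs
  D <- nrow(cat_)
  pts <- qt_smq()$pts$name
  R <- .planted_matrix(config)

  # exposure and event matrices
  E <- matrix(stats::runif(n * D), n, D) <
    matrix(cat_$p_exposure, n, D, byrow = TRUE)
  logodds <- matrix(log(config$pt_baseline_odds), n, length(pts),
                    byrow = TRUE) + (E * 1) %*% log(R)
  V <- matrix(stats::runif(n * length(pts)), n, length(pts)) <
    stats::plogis(logodds)

  # drug mention rows (one per exposed report-drug pair)
  pair <- which(E, arr.ind = TRUE)
  rep_i <- pair[, 1]
  drug_i <- pair[, 2]
  if (config$multi_suspect) {
    is_ps <- rep(TRUE, length(rep_i))
  } else {
    u <- stats::runif(length(rep_i))
    o <- order(rep_i, -u)
    first <- !duplicated(rep_i[o])
    is_ps <- logical(length(rep_i))
    is_ps[o] <- first
  }
  characterization <- ifelse(is_ps, 1L,
                             sample(c(2L, 3L), length(rep_i), replace = TRUE,
                                    prob = c(0.85, 0.15)))

  has_alias <- !is.na(cat_$ambiguous_alias)[drug_i]
  has_syn <- !is.na(cat_$synonym)[drug_i]
  u2 <- stats::runif(length(rep_i))
  m <- config$missing_generic_rate
  ab <- ifelse(has_alias, config$ambiguous_rate, 0)
  sy <- ifelse(has_syn, config$synonym_rate, 0)
  category <- rep("clean", length(rep_i))
  category[is_ps & u2 < m] <- "missing"
  category[is_ps & u2 >= m & u2 < m + ab] <- "ambiguous"
  category[is_ps & u2 >= m + ab & u2 < m + ab + sy] <- "synonym"
  category[!is_ps] <- "concomitant"

  emitted_name <- cat_$name[drug_i]
  emitted_name[category == "synonym"] <- cat_$synonym[drug_i][category == "synonym"]
  emitted_name[category == "ambiguous"] <- cat_$ambiguous_alias[drug_i][category == "ambiguous"]
  emitted_name[category == "missing"] <- NA_character_
  # some concomitant mentions lack a generic name too (excluded earlier
  # in the cascade, so they never reach the missing-name tally)
  conc_missing <- category == "concomitant" & stats::runif(length(rep_i)) < 0.1
  emitted_name[conc_missing] <- NA_character_

  # within-report duplicate mentions of the surviving suspect
  can_dup <- category %in% c("clean", "synonym")
  dup <- can_dup & stats::runif(length(rep_i)) < config$duplicate_rate

  drugs_long <- tibble::tibble(
    record_seq = c(rep_i, rep_i[dup]),
    characterization = c(characterization, rep(1L, sum(dup))),
    raw_name = toupper(cat_$name[c(drug_i, drug_i[dup])]),
    generic_name = c(emitted_name, emitted_name[dup]),
    category = c(category, category[dup]),
    is_dup = c(rep(FALSE, length(rep_i)), rep(TRUE, sum(dup))),
    canonical = fold_name(cat_$name)[c(drug_i, drug_i[dup])]
  ) |>
    dplyr::arrange(.data$record_seq, .data$is_dup) |>
    dplyr::group_by(.data$record_seq) |>
    dplyr::mutate(drug_seq = dplyr::row_number()) |>
    dplyr::ungroup()

  # reactions: matched target PTs plus filler terms
  hit <- which(V, arr.ind = TRUE)
  target_reac <- tibble::tibble(record_seq = hit[, 1], pt = pts[hit[, 2]])
  n_fill <- 1L + stats::rpois(n, 0.8)
  filler <- tibble::tibble(
    record_seq = rep(seq_len(n), n_fill),
    pt = sample(.filler_pts, sum(n_fill), replace = TRUE)
  ) |>
    dplyr::distinct()
  reactions <- dplyr::bind_rows(target_reac, filler) |>
    dplyr::arrange(.data$record_seq)

  # demographics
  dem <- config$demographics
  age <- round(stats::rnorm(n, dem$age_mean, dem$age_sd))
  age <- pmin(pmax(age, 1), 100)
  age[stats::runif(n) < dem$age_missing] <- NA_real_
  out_flags <- lapply(names(dem$outcome_probs), function(o) {
    stats::runif(n) < dem$outcome_probs[[o]]
  })
  outcome_str <- do.call(paste, c(
    purrr::map2(out_flags, names(dem$outcome_probs),
                ~ ifelse(.x, .y, "")), sep = "|"))
  outcomes <- lapply(strsplit(outcome_str, "|", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    if (length(v)) v else "unknown"
  })

  span <- as.integer(config$window$end - config$window$start)
  receipt <- config$window$start + sample.int(span + 1L, n, replace = TRUE) - 1L

  country <- .sample_cat(n, dem$country)
  country[stats::runif(n) < 0.03] <- NA_character_

  reports <- tibble::tibble(
    record_seq = seq_len(n),
    report_id = sprintf("SIM%08d", seq_len(n)),
    receipt_date = receipt,
    qualification = .sample_cat(n, dem$qualification),
    country = country,
    sex = .sample_cat(n, dem$sex),
    age_years = as.numeric(age),
    outcomes = outcomes
  )

  # follow-up re-issues: identical content, later receipt date, appended
  fu <- which(stats::runif(n) < config$followup_rate)
  if (length(fu)) {
    new_seq <- n + seq_along(fu)
    fu_reports <- reports[fu, ]
    fu_reports$record_seq <- new_seq
    fu_reports$receipt_date <- pmin(
      fu_reports$receipt_date + sample(30:365, length(fu), replace = TRUE),
      config$window$end)
    seq_map <- stats::setNames(new_seq, fu)
    remap <- function(df) {
      df <- df[df$record_seq %in% fu, ]
      df$record_seq <- unname(seq_map[as.character(df$record_seq)])
      df
    }
    reports <- dplyr::bind_rows(reports, fu_reports)
    reactions <- dplyr::bind_rows(reactions, remap(reactions))
    drugs_long <- dplyr::bind_rows(drugs_long, remap(drugs_long))
  }

  stream <- faers_reports(
    reports,
    reactions,
    dplyr::select(drugs_long, "record_seq", "drug_seq", "characterization",
                  "raw_name", "generic_name")
  )

  # ground truth: intended curation tallies over target reports
  # (one retained version per report; follow-ups carry identical content)
  target_seq <- which(rowSums(V) > 0)
  td <- drugs_long[drugs_long$record_seq %in% target_seq, ]
  surv <- td[td$characterization == 1L &
               td$category %in% c("clean", "synonym"), ]
  surviving_pairs <- dplyr::distinct(surv, .data$record_seq, .data$canonical)
  ledger <- tibble::tibble(
    n_drug_mentions_total = nrow(td),
    n_excluded_non_primary_suspect = sum(td$characterization != 1L),
    n_excluded_missing_generic = sum(td$characterization == 1L &
                                       td$category == "missing"),
    n_excluded_ambiguous = sum(td$characterization == 1L &
                                 td$category == "ambiguous"),
    n_merged_synonyms = sum(td$characterization == 1L &
                              td$category == "synonym"),
    n_excluded_duplicates = nrow(surv) - nrow(surviving_pairs),
    n_surviving_mentions = nrow(surviving_pairs),
    n_final_drugs = dplyr::n_distinct(surviving_pairs$canonical)
  )

  structure(
    list(
      reports = stream,
      truth = list(
        target_record_seqs = target_seq,
        target_report_ids = sprintf("SIM%08d", target_seq),
        n_reports = n,
        n_followups = length(fu),
        planted = R,
        ledger = ledger
      ),
      synonyms = sim_synonym_table(config),
      atc = sim_atc_map(config),
      config = config
    ),
    class = "faers_sim"
  )
}

#' @export
print.faers_sim <- function(x, ...) {
  cat(sprintf(
    "<faers_sim> %d report(s) (+%d follow-up record(s)), %d target report(s), seed %d\n",
    x$truth$n_reports, x$truth$n_followups,
    length(x$truth$target_record_seqs), x$config$seed))
  invisible(x)
}

#' Analytic expected contingency table under a simulation config
#'
#' Computes the expected cell counts (a, b, c, d) of the pipeline's
#' two-by-two table for one (drug, scope) pair by exact enumeration over
#' the 2^D drug-exposure patterns of the generator's sampling scheme,
#' including the primary-suspect assignment and the name-noise survival
#' probability. Serves as the independent oracle the empirical tables
#' converge to at large n.
#'
#' @param config a [faers_sim_config()] (catalogue of at most 16 drugs).
#' @param drug canonical catalogue drug name.
#' @param scope a narrow PT name or the SMQ name.
#' @return one-row tibble (`drug`, `scope`, `a`, `b`, `c`, `d`) of
#'   expected counts (real numbers).
#' @export
expected_contingency <- function(config, drug, scope) {
  stopifnot(inherits(config, "faers_sim_config"))
  cat_ <- config$drugs
  D <- nrow(cat_)
  if (D > 16) stop("exact enumeration supported for at most 16 drugs", call. = FALSE)
  pts <- qt_smq()$pts$name
  smq_name <- qt_smq()$name
  scope_idx <- match(fold_name(scope), fold_name(c(pts, smq_name)))
  if (is.na(scope_idx)) stop("unknown scope: ", scope, call. = FALSE)
  x_idx <- match(fold_name(drug), fold_name(cat_$name))
  if (is.na(x_idx)) stop("drug not in catalogue: ", drug, call. = FALSE)

  R <- .planted_matrix(config)
  p <- cat_$p_exposure
  P <- as.matrix(expand.grid(rep(list(0:1), D)))
  pr_pat <- exp(P %*% log(pmax(p, .Machine$double.xmin)) +
                  (1 - P) %*% log(pmax(1 - p, .Machine$double.xmin)))
  pr_pat <- as.numeric(pr_pat)

  odds <- exp(matrix(log(config$pt_baseline_odds), nrow(P), length(pts),
                     byrow = TRUE) + P %*% log(R))
  p_pt <- odds / (1 + odds)
  p_event <- if (scope_idx <= length(pts)) {
    p_pt[, scope_idx]
  } else {
    1 - apply(1 - p_pt, 1, prod)
  }

  k <- rowSums(P)
  w_ps <- if (config$multi_suspect) {
    pr_pat * P[, x_idx]
  } else {
    pr_pat * P[, x_idx] / pmax(k, 1)
  }
  s_x <- 1 - config$missing_generic_rate -
    (!is.na(cat_$ambiguous_alias[x_idx])) * config$ambiguous_rate
  n <- config$n_reports
  a <- n * sum(w_ps * p_event) * s_x
  c_ <- n * sum(w_ps * (1 - p_event)) * s_x
  n_event <- n * sum(pr_pat * p_event)
  b <- n_event - a
  d <- n - a - b - c_
  tibble::tibble(drug = fold_name(drug),
                 scope = c(pts, smq_name)[scope_idx],
                 a = a, b = b, c = c_, d = d)
}
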