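#' Exposure index over a report collection
#'
#' Applies the same primary-suspect curation rules used for the drug list
#' (characterization 1, present generic name, non-ambiguous after
#' normalization, synonym-merged, one row per report-drug pair) to
#' *every* report in a collection, after deduplicating report versions.
#' This defines "exposed to drug" for the comparator columns of the
#' two-by-two contingency tables.
#'
#' @param x a [faers_reports] collection (the full dataset, not just
#'   targets).
#' @param synonyms a [synonym_table].
#' @return tibble (`record_seq`, `report_id`, `drug`) of surviving
#'   primary-suspect exposures, with attribute `n_total` = number of
#'   unique reports after deduplication.
#' @export
build_exposure_index <- function(x, synonyms = synonym_table()) {
  stopifnot(inherits(x, "faers_reports"))
  retained <- .dedupe_records(x)
  drugs <- dplyr::semi_join(x$drugs, retained, by = "record_seq")
  ps <- extract_primary_suspects(drugs)
  named <- ps$suspects
  canonical <- if (nrow(named)) normalize_name(named$generic_name, synonyms) else character(0)
  idx <- tibble::tibble(record_seq = named$record_seq, drug = canonical) |>
    dplyr::filter(!is.na(.data$drug)) |>
    dplyr::distinct() |>
    dplyr::left_join(dplyr::select(retained, "record_seq", "report_id"),
                     by = "record_seq") |>
    dplyr::select("record_seq", "report_id", "drug")
  attr(idx, "n_total") <- dplyr::n_distinct(retained$report_id)
  idx
}

.scope_event_seqs <- function(scope, targets, smq) {
  scopes <- c(smq$pts$name, smq$name)
  hit <- match(fold_name(scope), fold_name(scopes))
  if (is.na(hit)) {
    stop("unknown scope: ", scope,
         " (expected one of the six narrow PTs or the SMQ name)",
         call. = FALSE)
  }
  scope <- scopes[hit]
  if (scope == smq$name) {
    unique(targets$matched$record_seq)
  } else {
    targets$matched$record_seq[targets$matched$pt == scope]
  }
}

#' Build a two-by-two contingency table
#'
#' For one (drug, scope) pair, counts unique reports into the classic
#' disproportionality layout: `a` = exposed with the event of interest,
#' `b` = event without the drug, `c` = drug with other events, `d` =
#' neither; `a + b + c + d` equals the unique-report total of the
#' dataset. "Exposed" means the drug is a surviving primary suspect in
#' the report; "event" means the report matched the scope (one narrow PT
#' or the whole SMQ).
#'
#' @param drug canonical drug name.
#' @param scope a narrow PT name or the SMQ name (case-insensitive).
#' @param targets a `target_report_set`.
#' @param index exposure index from [build_exposure_index()] over the
#'   same dataset.
#' @param smq the [smq_definition].
#' @return one-row tibble (`drug`, `scope`, `a`, `b`, `c`, `d`).
#' @export
build_contingency <- function(drug, scope, targets, index, smq = qt_smq()) {
  stopifnot(inherits(targets, "target_report_set"))
  n_total <- attr(index, "n_total") %||% targets$n_total_database
  event_seqs <- .scope_event_seqs(scope, targets, smq)
  exposed_seqs <- index$record_seq[fold_name(index$drug) == fold_name(drug)]
  a <- length(intersect(exposed_seqs, event_seqs))
  b <- length(event_seqs) - a
  c_ <- length(exposed_seqs) - a
  d <- n_total - a - b - c_
  tibble::tibble(drug = fold_name(drug), scope = scope,
                 a = a, b = b, c = c_, d = d)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' Computes, per table, `ROR = (a/c)/(b/d) = ad/bc` with the Woolf
#' 95% confidence interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' If any cell is zero the interval is undefined, so the
#' Haldane-Anscombe continuity correction adds 0.5 to all four cells
#' (flagged in `corrected`); `n_cases` always reports the uncorrected
#' `a`, which governs the three-case rule. With `correct = FALSE`,
#' zero-cell tables yield `NA` estimates instead (and classify negative).
#'
#' @param a,b,c,d non-negative integer cell counts (vectors), or pass a
#'   data frame with columns `a`, `b`, `c`, `d` as `a` alone.
#' @param correct apply the +0.5 continuity correction to zero-cell
#'   tables (default `TRUE`).
#' @return tibble with columns `a`, `b`, `c`, `d`, `n_cases`, `ror`,
#'   `ci_low`, `ci_high`, `corrected`, `signal`.
#' @examples
#' compute_ror(3, 1, 1, 3) # ROR 9, CI lower limit about 0.367
#' @export
compute_ror <- function(a, b = NULL, c = NULL, d = NULL, correct = TRUE) {
  if (is.data.frame(a)) {
    df <- a
    stopifnot(all(c("a", "b", "c", "d") %in% names(df)))
    a <- df$a; b <- df$b; c <- df$c; d <- df$d
  }
  stopifnot(length(b) == length(a), length(c) == length(a),
            length(d) == length(a))
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative", call. = FALSE)
  n_cases <- a
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (correct) {
    shift <- ifelse(corrected, 0.5, 0)
    aa <- a + shift; bb <- b + shift; cc <- c + shift; dd <- d + shift
    ror <- (aa * dd) / (bb * cc)
    se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
    ci_low <- exp(log(ror) - 1.96 * se)
    ci_high <- exp(log(ror) + 1.96 * se)
  } else {
    ror <- ifelse(corrected, NA_real_, (a * d) / (b * c))
    se <- ifelse(corrected, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
    ci_low <- exp(log(ror) - 1.96 * se)
    ci_high <- exp(log(ror) + 1.96 * se)
    corrected <- rep(FALSE, length(a))
  }
  tibble::tibble(
    a = a, b = b, c = c, d = d, n_cases = n_cases,
    ror = ror, ci_low = ci_low, ci_high = ci_high,
    corrected = corrected,
    signal = classify_signal(n_cases, ci_low)
  )
}

#' Classify a disproportionality signal
#'
#' A signal is positive iff there are at least three cases
#' (`n_cases >= 3`) and the lower limit of the 95% confidence interval is
#' strictly greater than 1; otherwise (including an undefined interval)
#' it is negative.
#'
#' @param n_cases integer vector of case counts (cell `a`).
#' @param ci_low numeric vector of CI lower limits (`NA` allowed).
#' @return character vector, `"positive"` or `"negative"`.
#' @examples
#' classify_signal(2, 5)      # negative: too few cases
#' classify_signal(100, 1)    # negative: strict inequality at 1
#' classify_signal(3, 1.0001) # positive
#' @export
classify_signal <- function(n_cases, ci_low) {
  ifelse(n_cases >= 3 & !is.na(ci_low) & ci_low > 1, "positive", "negative")
}

#' Detect all signals for a curated drug list
#'
#' Runs the full disproportionality screen: for every curated drug and
#' each of the seven scopes (six narrow PTs plus the SMQ), builds the
#' two-by-two table against the dataset-wide comparator and computes the
#' ROR, its confidence interval, and the signal classification. Exactly
#' seven results per drug; deterministic.
#'
#' @param targets a `target_report_set`.
#' @param reports the full [faers_reports] dataset providing the
#'   comparator population, or a precomputed exposure index from
#'   [build_exposure_index()].
#' @param drug_list a `drug_list` from [build_drug_list()] (or a
#'   character vector of canonical drug names).
#' @param synonyms the [synonym_table] used during curation (ignored when
#'   `reports` is already an index).
#' @param smq the [smq_definition].
#' @param correct continuity-correction toggle, see [compute_ror()].
#' @return an object of class `ror_screen`: a tibble (`drug`, `scope`,
#'   `a`, `b`, `c`, `d`, `n_cases`, `ror`, `ci_low`, `ci_high`,
#'   `corrected`, `signal`) with attributes `n_total`, `smq_name`,
#'   `scopes`.
#' @export
detect_all_signals <- function(targets, reports, drug_list,
                               synonyms = synonym_table(), smq = qt_smq(),
                               correct = TRUE) {
  stopifnot(inherits(targets, "target_report_set"))
  index <- if (inherits(reports, "faers_reports")) {
    build_exposure_index(reports, synonyms)
  } else {
    reports
  }
  n_total <- attr(index, "n_total") %||% targets$n_total_database
  drugs <- if (inherits(drug_list, "drug_list")) drug_list$drugs$drug else drug_list
  drugs <- unique(fold_name(drugs))
  scopes <- c(smq$pts$name, smq$name)

  index <- dplyr::filter(index, .data$drug %in% drugs)
  n_exposed <- index |>
    dplyr::count(.data$drug, name = "n_exposed")

  event_long <- dplyr::bind_rows(
    dplyr::select(targets$matched, "record_seq", scope = "pt"),
    tibble::tibble(record_seq = unique(targets$matched$record_seq),
                   scope = smq$name)
  )
  n_event <- event_long |>
    dplyr::count(.data$scope, name = "n_event")

  a_tbl <- index |>
    dplyr::inner_join(event_long, by = "record_seq",
                      relationship = "many-to-many") |>
    dplyr::count(.data$drug, .data$scope, name = "a")

  grid <- tidyr::expand_grid(drug = drugs, scope = scopes) |>
    dplyr::left_join(a_tbl, by = c("drug", "scope")) |>
    dplyr::left_join(n_exposed, by = "drug") |>
    dplyr::left_join(n_event, by = "scope") |>
    dplyr::mutate(
      a = dplyr::coalesce(.data$a, 0L),
      n_exposed = dplyr::coalesce(.data$n_exposed, 0L),
      n_event = dplyr::coalesce(.data$n_event, 0L),
      b = .data$n_event - .data$a,
      c = .data$n_exposed - .data$a,
      d = n_total - .data$a - .data$b - .data$c
    )

  res <- compute_ror(grid$a, grid$b, grid$c, grid$d, correct = correct)
  out <- dplyr::bind_cols(
    dplyr::select(grid, "drug", "scope"),
    res
  ) |>
    dplyr::arrange(.data$drug, match(.data$scope, scopes))
  structure(out, class = c("ror_screen", class(out)),
            n_total = n_total, smq_name = smq$name, scopes = scopes)
}

#' @export
tidy.ror_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ror_screen")
  attr(out, "n_total") <- NULL
  attr(out, "smq_name") <- NULL
  attr(out, "scopes") <- NULL
  out
}

#' @export
glance.ror_screen <- function(x, ...) {
  tibble::tibble(
    n_drugs = dplyr::n_distinct(x$drug),
    n_scopes = dplyr::n_distinct(x$scope),
    n_results = nrow(x),
    n_positive = sum(x$signal == "positive"),
    n_corrected = sum(x$corrected),
    n_total_reports = attr(x, "n_total")
  )
}
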