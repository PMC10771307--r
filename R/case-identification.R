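#' Match a report's reactions against the narrow-scope SMQ
#'
#' Case-insensitive, whitespace-trimmed matching of reaction PT names
#' against the definition's narrow-scope PTs. A report is a target report
#' iff at least one PT matches.
#'
#' @param pts character vector of reaction PT names as reported.
#' @param smq an [smq_definition] (default [qt_smq()]).
#' @return character vector of matched PT names in the definition's
#'   canonical casing (possibly empty).
#' @examples
#' match_target_pts(c("electrocardiogram qt prolonged", "Nausea"))
#' @export
match_target_pts <- function(pts, smq = qt_smq()) {
  stopifnot(inherits(smq, "smq_definition"))
  keys <- fold_name(smq$pts$name)
  hit <- match(fold_name(pts), keys)
  unique(smq$pts$name[hit[!is.na(hit)]])
}

# Deduplicate record versions: keep, per report_id, the version with the
# latest receipt date, breaking ties by stream position (last seen wins).
# Missing dates sort earliest, so a dated version beats an undated one.
.dedupe_records <- function(x) {
  r <- x$reports
  o <- order(r$report_id, r$receipt_date, seq_len(nrow(r)),
             na.last = FALSE, method = "radix")
  idx <- o[!duplicated(r$report_id[o], fromLast = TRUE)]
  r[sort(idx), ]
}

.subset_records <- function(x, record_seqs) {
  faers_reports(
    dplyr::filter(x$reports, .data$record_seq %in% record_seqs),
    dplyr::filter(x$reactions, .data$record_seq %in% record_seqs),
    dplyr::filter(x$drugs, .data$record_seq %in% record_seqs)
  )
}

#' Identify target reports via the narrow-scope SMQ
#'
#' Deduplicates report versions (same safety report ID: the version with
#' the latest receipt date is kept, ties broken in favour of the record
#' seen last) and flags as target every retained report whose reaction
#' list matches at least one narrow-scope PT.
#'
#' @param x a [faers_reports] collection (may contain follow-up versions).
#' @param smq an [smq_definition] (default [qt_smq()]).
#' @return an object of class `target_report_set`: a list with
#'   * `data` — [faers_reports] restricted to the retained target records,
#'   * `matched` — tibble (`record_seq`, `report_id`, `pt`) of matched
#'     narrow PTs per retained target report (canonical casing),
#'   * `n_total_database` — number of unique report IDs screened,
#'   * `n_records_screened` — raw record count including follow-ups.
#' @export
identify_targets <- function(x, smq = qt_smq()) {
  stopifnot(inherits(x, "faers_reports"), inherits(smq, "smq_definition"))
  retained <- .dedupe_records(x)
  key_tbl <- tibble::tibble(key = fold_name(smq$pts$name),
                            pt_canonical = smq$pts$name)
  matched <- x$reactions |>
    dplyr::semi_join(retained, by = "record_seq") |>
    dplyr::mutate(key = fold_name(.data$pt)) |>
    dplyr::inner_join(key_tbl, by = "key") |>
    dplyr::distinct(.data$record_seq, .data$pt_canonical) |>
    dplyr::rename(pt = "pt_canonical") |>
    dplyr::left_join(dplyr::select(retained, "record_seq", "report_id"),
                     by = "record_seq") |>
    dplyr::select("record_seq", "report_id", "pt") |>
    dplyr::arrange(.data$record_seq)

  target_seqs <- unique(matched$record_seq)
  structure(
    list(
      data = .subset_records(x, target_seqs),
      matched = matched,
      n_total_database = dplyr::n_distinct(retained$report_id),
      n_records_screened = nrow(x$reports)
    ),
    class = "target_report_set"
  )
}

#' @export
print.target_report_set <- function(x, ...) {
  cat(sprintf(
    "<target_report_set> %d target report(s) of %d unique reports screened (%d raw records)\n",
    nrow(x$data$reports), x$n_total_database, x$n_records_screened))
  invisible(x)
}

#' Number of retained target reports
#' @param x a `target_report_set`.
#' @return integer count.
#' @export
n_targets <- function(x) {
  stopifnot(inherits(x, "target_report_set"))
  nrow(x$data$reports)
}

.age_band <- function(age) {
  breaks <- c(0, seq(10, 100, by = 10), Inf)
  labels <- c("0-10", paste(seq(11, 91, by = 10), seq(20, 100, by = 10), sep = "-"),
              ">100")
  out <- as.character(cut(age, breaks = breaks, labels = labels,
                          include.lowest = TRUE, right = TRUE))
  out[is.na(age)] <- "missing"
  out
}

.tabulate_pct <- function(values, n_total, order_by = c("value", "count")) {
  order_by <- match.arg(order_by)
  tab <- tibble::tibble(category = values) |>
    dplyr::count(.data$category, name = "n")
  tab <- if (order_by == "count") {
    dplyr::arrange(tab, dplyr::desc(.data$n), .data$category)
  } else {
    dplyr::arrange(tab, .data$category)
  }
  dplyr::mutate(tab, pct = percentage(.data$n, n_total))
}

#' Summarize report characteristics
#'
#' Tabulates the retained target reports by report year, submitter
#' qualification, country, sex, decadal age band, patient outcome, and
#' matched narrow PT. Year, submitter, country, sex and age tables are
#' single-membership (counts sum to the number of reports); outcome and
#' PT tables are multi-membership (one report can contribute to several
#' rows). Percentages are of the target-report total, half-up at one
#' decimal.
#'
#' @param targets a `target_report_set` from [identify_targets()].
#' @return named list of tibbles (`year`, `submitter`, `country`, `sex`,
#'   `age`, `outcome`, `pt`), each with columns `category`, `n`, `pct`.
#'   The country table carries a `rank` column; records with no country
#'   fall in an `"unknown"` row excluded from ranking.
#' @export
summarize_characteristics <- function(targets) {
  stopifnot(inherits(targets, "target_report_set"))
  rep_tbl <- targets$data$reports
  n <- nrow(rep_tbl)
  if (n == 0) stop("empty target set: nothing to summarize", call. = FALSE)

  year <- .tabulate_pct(format(rep_tbl$receipt_date, "%Y"), n)
  submitter <- .tabulate_pct(rep_tbl$qualification, n, order_by = "count")
  sex <- .tabulate_pct(rep_tbl$sex, n, order_by = "count")
  age <- .tabulate_pct(.age_band(rep_tbl$age_years), n)

  country_vals <- dplyr::coalesce(rep_tbl$country, "unknown")
  country <- .tabulate_pct(country_vals, n, order_by = "count")
  known <- country$category != "unknown"
  country$rank <- NA_integer_
  country$rank[known] <- dplyr::min_rank(dplyr::desc(country$n[known]))

  outcome <- .tabulate_pct(unlist(rep_tbl$outcomes), n, order_by = "count")
  pt <- .tabulate_pct(targets$matched$pt, n, order_by = "count")

  list(year = year, submitter = submitter, country = country, sex = sex,
       age = age, outcome = outcome, pt = pt)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.target_report_set <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$data$reports),
    n_total_database = x$n_total_database,
    n_records_screened = x$n_records_screened,
    n_matched_pt_pairs = nrow(x$matched)
  )
}

#' @export
tidy.target_report_set <- function(x, ...) {
  x$matched
}
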