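#' Tie-aware ranked reporting proportions
#'
#' Ranks tallies by count and keeps the top `top_n` rows plus every row
#' tied with the boundary (rank-`top_n`) count, annotating the ties
#' rather than silently truncating — mirroring the footnote style of
#' ranked summary figures. Proportions are `100 * count / total`,
#' half-up at `digits` decimals.
#'
#' @param tallies tibble with columns `name` and `n_reports`.
#' @param total positive denominator (reports in scope).
#' @param top_n how many ranks to keep (default 10).
#' @param digits decimal places for the proportion (default 2, the
#'   precision used on ranked figure surfaces).
#' @return tibble (`rank`, `name`, `n_reports`, `proportion`,
#'   `tied_at_boundary`) ordered by rank then name, with attribute
#'   `ties_note` describing boundary ties (or `NULL`).
#' @export
reporting_proportions <- function(tallies, total, top_n = 10, digits = 2) {
  tallies <- tibble::as_tibble(tallies)
  stopifnot(all(c("name", "n_reports") %in% names(tallies)),
            top_n >= 1, total > 0)
  ranked <- tallies |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$n_reports))) |>
    dplyr::arrange(.data$rank, .data$name)
  if (nrow(ranked) > top_n) {
    boundary <- ranked$n_reports[order(-ranked$n_reports)][top_n]
    ranked <- dplyr::filter(ranked, .data$n_reports >= boundary)
    ranked$tied_at_boundary <- ranked$n_reports == boundary &
      sum(ranked$n_reports == boundary) > 1
  } else {
    ranked$tied_at_boundary <- FALSE
  }
  out <- ranked |>
    dplyr::mutate(proportion = percentage(.data$n_reports, total, digits)) |>
    dplyr::select("rank", "name", "n_reports", "proportion",
                  "tied_at_boundary")
  tied <- out$name[out$tied_at_boundary]
  attr(out, "ties_note") <- if (length(tied) > 1) {
    sprintf("%d entries share the boundary count: %s",
            length(tied), paste(tied, collapse = ", "))
  }
  out
}

#' Top reported drugs or drug classes in a scope
#'
#' Convenience wrapper assembling the per-scope tallies from a curated
#' drug list and ranking them with [reporting_proportions()]. The
#' denominator is the number of target reports matching the scope; for
#' classes, a report counts once per ATC second-level class among its
#' surviving primary suspects (multi-membership, so class proportions
#' may sum above 100%).
#'
#' @param drug_list a `drug_list` from [build_drug_list()].
#' @param targets the `target_report_set` it was built from.
#' @param scope a narrow PT name or the SMQ name.
#' @param by `"drug"` or `"class"`.
#' @param top_n,digits passed to [reporting_proportions()].
#' @param smq the [smq_definition].
#' @return a ranked tibble as from [reporting_proportions()], with
#'   attribute `n_scope_reports`.
#' @export
top_reported <- function(drug_list, targets, scope = NULL,
                         by = c("drug", "class"), top_n = 10, digits = 2,
                         smq = qt_smq()) {
  by <- match.arg(by)
  stopifnot(inherits(drug_list, "drug_list"),
            inherits(targets, "target_report_set"))
  scope <- scope %||% smq$name
  event_seqs <- .scope_event_seqs(scope, targets, smq)
  if (length(event_seqs) == 0) {
    out <- tibble::tibble(rank = integer(0), name = character(0),
                          n_reports = integer(0), proportion = numeric(0),
                          tied_at_boundary = logical(0))
    attr(out, "n_scope_reports") <- 0L
    return(out)
  }
  pairs <- dplyr::filter(drug_list$survivors,
                         .data$record_seq %in% event_seqs)
  tallies <- if (by == "drug") {
    dplyr::count(pairs, .data$drug, name = "n_reports") |>
      dplyr::rename(name = "drug")
  } else {
    pairs |>
      dplyr::inner_join(
        drug_list$drugs |>
          dplyr::select("drug", "atc_classes") |>
          tidyr::separate_rows("atc_classes", sep = ";") |>
          dplyr::rename(atc_class = "atc_classes"),
        by = "drug"
      ) |>
      dplyr::distinct(.data$record_seq, .data$atc_class) |>
      dplyr::count(.data$atc_class, name = "n_reports") |>
      dplyr::rename(name = "atc_class")
  }
  out <- reporting_proportions(tallies, total = length(event_seqs),
                               top_n = top_n, digits = digits)
  attr(out, "n_scope_reports") <- length(event_seqs)
  out
}

#' Positive-signal counts per drug and their distribution
#'
#' Sums the positive signals of each drug over its seven scopes and
#' tabulates the distribution of that count from 7 down to 0; the bin
#' counts sum to the number of drugs. A matrix that does not carry
#' exactly seven scopes per drug is rejected.
#'
#' @param screen a `ror_screen` from [detect_all_signals()], or any
#'   tibble with columns `drug`, `scope`, `signal`.
#' @param digits decimal places for the percentage column.
#' @return an object of class `positive_signal_summary`: list with
#'   `per_drug` (tibble `drug`, `n_positive`), `distribution` (tibble
#'   `n_positive` 7..0, `n_drugs`, `pct`), `n_drugs`, and
#'   `n_at_least_one`.
#' @export
count_positive_signals <- function(screen, digits = 1) {
  df <- tibble::as_tibble(screen)
  stopifnot(all(c("drug", "scope", "signal") %in% names(df)))
  per_scope <- dplyr::count(df, .data$drug, name = "n_scopes")
  if (nrow(per_scope) == 0 || any(per_scope$n_scopes != 7L)) {
    stop("incomplete signal matrix: every drug needs exactly 7 scopes",
         call. = FALSE)
  }
  per_drug <- df |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(n_positive = sum(.data$signal == "positive"),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_positive), .data$drug)
  n_drugs <- nrow(per_drug)
  n_drugs_total <- n_drugs
  distribution <- tibble::tibble(n_positive = 7:0) |>
    dplyr::left_join(dplyr::count(per_drug, .data$n_positive, name = "n_drugs"),
                     by = "n_positive") |>
    dplyr::mutate(n_drugs = dplyr::coalesce(.data$n_drugs, 0L),
                  pct = percentage(.data$n_drugs, n_drugs_total, digits))
  structure(
    list(per_drug = per_drug, distribution = distribution,
         n_drugs = n_drugs,
         n_at_least_one = sum(per_drug$n_positive >= 1)),
    class = "positive_signal_summary"
  )
}

#' @export
print.positive_signal_summary <- function(x, ...) {
  cat(sprintf(
    "<positive_signal_summary> %d drug(s); %d with at least one positive signal\n",
    x$n_drugs, x$n_at_least_one))
  print(x$distribution, ...)
  invisible(x)
}

#' @export
tidy.positive_signal_summary <- function(x, ...) x$distribution

#' @export
glance.positive_signal_summary <- function(x, ...) {
  tibble::tibble(n_drugs = x$n_drugs, n_at_least_one = x$n_at_least_one,
                 n_positive_total = sum(x$per_drug$n_positive))
}

#' ATC-class signal distribution per scope
#'
#' For each second-level ATC class and scope, partitions the drugs with
#' at least one report in that scope into positive- and negative-signal
#' drugs according to that scope's classification. Drugs mapping to
#' several classes count in each (multi-membership); unmapped drugs
#' aggregate under `"unmapped"`.
#'
#' @param screen a `ror_screen` from [detect_all_signals()].
#' @param drug_list the `drug_list` the screen was run on.
#' @param scope optional single scope to restrict to (default: all
#'   seven).
#' @return tibble (`scope`, `atc_class`, `n_drugs`, `n_positive`,
#'   `n_negative`), classes ordered by total drug count within scope.
#' @export
atc_signal_distribution <- function(screen, drug_list, scope = NULL) {
  stopifnot(inherits(drug_list, "drug_list"))
  df <- tibble::as_tibble(screen)
  if (!is.null(scope)) {
    keep_scope <- scope
    df <- dplyr::filter(df, .data$scope %in% keep_scope)
  }
  classes <- drug_list$drugs |>
    dplyr::select("drug", "atc_classes") |>
    tidyr::separate_rows("atc_classes", sep = ";") |>
    dplyr::rename(atc_class = "atc_classes")
  in_scope <- drug_list$counts |>
    dplyr::filter(.data$n_reports >= 1) |>
    dplyr::distinct(.data$drug, .data$scope)
  df |>
    dplyr::inner_join(in_scope, by = c("drug", "scope")) |>
    dplyr::inner_join(classes, by = "drug",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$scope, .data$atc_class) |>
    dplyr::summarise(
      n_drugs = dplyr::n(),
      n_positive = sum(.data$signal == "positive"),
      n_negative = sum(.data$signal == "negative"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$scope, dplyr::desc(.data$n_drugs), .data$atc_class)
}
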