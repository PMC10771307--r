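#' Drug-name synonym table
#'
#' Maps raw or variant generic names to canonical ingredient names and
#' lists names deemed ambiguous (to be excluded from the drug list). All
#' keys and values are stored case-folded and whitespace-trimmed. The map
#' must be its own fixed point (applying it twice equals applying it
#' once), and ambiguous names must not also be synonym keys.
#'
#' @param map named character vector: `names(map)` are variant names,
#'   values the canonical names.
#' @param ambiguous character vector of names to exclude as ambiguous.
#' @return an object of class `synonym_table`.
#' @examples
#' synonym_table(c(paracetamol = "acetaminophen"), ambiguous = "multivitamins")
#' @export
synonym_table <- function(map = character(0), ambiguous = character(0)) {
  keys <- fold_name(names(map) %||% character(0))
  vals <- fold_name(unname(map))
  ambiguous <- fold_name(ambiguous)
  if (length(map) && anyDuplicated(keys)) {
    stop("duplicate synonym keys", call. = FALSE)
  }
  if (any(vals %in% keys)) {
    stop("synonym map is not a fixed point: a canonical name is also a key",
         call. = FALSE)
  }
  if (any(ambiguous %in% keys)) {
    stop("ambiguous names must be disjoint from synonym keys", call. = FALSE)
  }
  structure(list(map = stats::setNames(vals, keys), ambiguous = ambiguous),
            class = "synonym_table")
}

#' @export
print.synonym_table <- function(x, ...) {
  cat(sprintf("<synonym_table> %d synonym(s), %d ambiguous name(s)\n",
              length(x$map), length(x$ambiguous)))
  invisible(x)
}

#' Read a synonym table from TSV
#'
#' Expects a UTF-8 TSV with header columns `raw_name`, `canonical_name`,
#' `flag`, where `flag` is `synonym` (map raw to canonical) or
#' `ambiguous` (exclude raw; `canonical_name` ignored).
#'
#' @param path TSV file path.
#' @return a [synonym_table].
#' @export
read_synonym_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("raw_name", "flag")
  if (!all(need %in% names(df))) {
    stop("synonym TSV needs columns raw_name, canonical_name, flag",
         call. = FALSE)
  }
  syn <- dplyr::filter(df, .data$flag == "synonym")
  amb <- dplyr::filter(df, .data$flag == "ambiguous")
  synonym_table(
    map = stats::setNames(syn$canonical_name, syn$raw_name),
    ambiguous = amb$raw_name
  )
}

#' Drug to ATC code mapping
#'
#' Maps canonical generic names to level-5 ATC codes (pattern
#' letter-digit-digit-letter-letter-digit-digit); the second-level
#' therapeutic class is the first three characters. A drug may map to
#' several codes (multi-membership across classes).
#'
#' @param codes tibble or data.frame with columns `generic_name` and
#'   `atc_code`.
#' @return an object of class `atc_map` (a tibble with an added
#'   `atc_class` column; names case-folded).
#' @export
atc_map <- function(codes) {
  codes <- tibble::as_tibble(codes)
  stopifnot(all(c("generic_name", "atc_code") %in% names(codes)))
  bad <- !grepl("^[A-Za-z][0-9]{2}[A-Za-z]{2}[0-9]{2}$", codes$atc_code)
  if (any(bad)) {
    stop("malformed ATC code(s): ",
         paste(utils::head(codes$atc_code[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- codes |>
    dplyr::transmute(
      generic_name = fold_name(.data$generic_name),
      atc_code = toupper(.data$atc_code),
      atc_class = substr(toupper(.data$atc_code), 1, 3)
    ) |>
    dplyr::distinct()
  structure(out, class = c("atc_map", class(out)))
}

#' Read an ATC mapping from TSV
#'
#' Expects a UTF-8 TSV with header columns `generic_name`, `atc_code`.
#'
#' @param path TSV file path.
#' @return an [atc_map].
#' @export
read_atc_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  atc_map(df)
}

#' Normalize a raw drug name
#'
#' Case-folds and trims the name, flags ambiguous names, and maps synonym
#' variants to their canonical ingredient. Unmapped names are returned as
#' their folded selves. The operation is idempotent.
#'
#' @param raw character vector of non-empty raw generic names.
#' @param syn a [synonym_table].
#' @return character vector of canonical names; ambiguous names become
#'   `NA` (the only source of `NA` in the output, since empty input is an
#'   error).
#' @examples
#' syn <- synonym_table(c(paracetamol = "acetaminophen"))
#' normalize_name("Paracetamol", syn)
#' @export
normalize_name <- function(raw, syn = synonym_table()) {
  stopifnot(inherits(syn, "synonym_table"))
  if (any(is.na(raw)) || any(!nzchar(stringr::str_trim(raw)))) {
    stop("raw drug names must be non-empty", call. = FALSE)
  }
  folded <- fold_name(raw)
  out <- folded
  hit <- match(folded, names(syn$map))
  out[!is.na(hit)] <- unname(syn$map[hit[!is.na(hit)]])
  out[folded %in% syn$ambiguous] <- NA_character_
  out
}

#' Extract primary-suspect generic names from drug mentions
#'
#' Filters a drug-mention table to entries with characterization code 1
#' (primary suspect) and a present generic name, tallying exclusions by
#' reason.
#'
#' @param drugs a drug-mention tibble with columns `record_seq`,
#'   `characterization`, `generic_name` (e.g. `x$drugs` of a
#'   [faers_reports] object).
#' @return list with `suspects` (tibble `record_seq`, `generic_name`),
#'   `n_non_primary`, `n_missing_generic`.
#' @export
extract_primary_suspects <- function(drugs) {
  drugs <- tibble::as_tibble(drugs)
  stopifnot(all(c("record_seq", "characterization", "generic_name") %in%
                  names(drugs)))
  is_ps <- drugs$characterization == 1L
  ps <- drugs[is_ps, ]
  missing_name <- is.na(ps$generic_name)
  list(
    suspects = tibble::tibble(record_seq = ps$record_seq[!missing_name],
                              generic_name = ps$generic_name[!missing_name]),
    n_non_primary = sum(!is_ps),
    n_missing_generic = sum(missing_name)
  )
}

.pt_count_cols <- function(smq) smq$pts$name

#' Curate the primary-suspect drug list
#'
#' Applies the exclusion cascade to the drug mentions of the target
#' reports: (1) drop non-primary-suspect mentions; (2) drop mentions with
#' no generic name; (3) normalize names — ambiguous names are excluded,
#' synonym variants merged to their canonical ingredient; (4) collapse
#' within-report repeats of the same canonical ingredient (each surplus
#' mention tallied as a duplicate). Each surviving (report, drug) pair
#' contributes one report to the drug's SMQ-level count and to the count
#' of every narrow PT that report matched.
#'
#' @param targets a `target_report_set` from [identify_targets()].
#' @param synonyms a [synonym_table].
#' @param atc an [atc_map] (drugs absent from it are classed
#'   `"unmapped"`).
#' @param smq the [smq_definition] used for identification.
#' @return an object of class `drug_list`: a list with
#'   * `drugs` — tibble (`drug`, `atc_codes`, `atc_classes`,
#'     `n_reports_smq`), ordered by descending SMQ-level count then name;
#'   * `counts` — long tibble (`drug`, `scope`, `n_reports`) over the six
#'     PTs and the SMQ scope;
#'   * `survivors` — tibble (`record_seq`, `report_id`, `drug`) of
#'     surviving report-drug pairs;
#'   * `ledger` — one-row tibble of curation tallies
#'     (`n_drug_mentions_total`, `n_excluded_non_primary_suspect`,
#'     `n_excluded_missing_generic`, `n_excluded_ambiguous`,
#'     `n_merged_synonyms`, `n_excluded_duplicates`,
#'     `n_surviving_mentions`, `n_final_drugs`).
#' @export
build_drug_list <- function(targets, synonyms = synonym_table(),
                            atc = NULL, smq = qt_smq()) {
  stopifnot(inherits(targets, "target_report_set"),
            inherits(synonyms, "synonym_table"))
  if (nrow(targets$data$reports) == 0) {
    stop("empty target set: no drugs to curate", call. = FALSE)
  }
  drugs <- targets$data$drugs
  n_total <- nrow(drugs)

  ps <- extract_primary_suspects(drugs)
  named <- ps$suspects

  canonical <- if (nrow(named)) normalize_name(named$generic_name, synonyms) else character(0)
  n_ambiguous <- sum(is.na(canonical))
  n_merged <- sum(!is.na(canonical) & canonical != fold_name(named$generic_name))
  kept <- tibble::tibble(record_seq = named$record_seq,
                         drug = canonical)[!is.na(canonical), ]

  survivors <- dplyr::distinct(kept, .data$record_seq, .data$drug)
  n_duplicates <- nrow(kept) - nrow(survivors)
  survivors <- dplyr::left_join(
    survivors,
    dplyr::select(targets$data$reports, "record_seq", "report_id"),
    by = "record_seq"
  ) |>
    dplyr::select("record_seq", "report_id", "drug")

  smq_counts <- survivors |>
    dplyr::count(.data$drug, name = "n_reports") |>
    dplyr::mutate(scope = smq$name)
  pt_counts <- survivors |>
    dplyr::inner_join(dplyr::select(targets$matched, "record_seq", "pt"),
                      by = "record_seq",
                      relationship = "many-to-many") |>
    dplyr::count(.data$drug, .data$pt, name = "n_reports") |>
    dplyr::rename(scope = "pt")
  counts <- dplyr::bind_rows(pt_counts, smq_counts) |>
    dplyr::select("drug", "scope", "n_reports")

  drug_tbl <- smq_counts |>
    dplyr::transmute(drug = .data$drug, n_reports_smq = .data$n_reports) |>
    dplyr::arrange(dplyr::desc(.data$n_reports_smq), .data$drug)

  if (!is.null(atc)) {
    stopifnot(inherits(atc, "atc_map"))
    atc_agg <- atc |>
      tibble::as_tibble() |>
      dplyr::filter(.data$generic_name %in% drug_tbl$drug) |>
      dplyr::group_by(.data$generic_name) |>
      dplyr::summarise(
        atc_codes = paste(sort(unique(.data$atc_code)), collapse = ";"),
        atc_classes = paste(sort(unique(.data$atc_class)), collapse = ";"),
        .groups = "drop"
      )
    drug_tbl <- drug_tbl |>
      dplyr::left_join(atc_agg, by = c(drug = "generic_name"))
  } else {
    drug_tbl$atc_codes <- NA_character_
    drug_tbl$atc_classes <- NA_character_
  }
  drug_tbl <- drug_tbl |>
    dplyr::mutate(
      atc_codes = dplyr::coalesce(.data$atc_codes, ""),
      atc_classes = dplyr::coalesce(
        dplyr::if_else(.data$atc_classes == "", NA_character_, .data$atc_classes),
        "unmapped")
    ) |>
    dplyr::select("drug", "atc_codes", "atc_classes", "n_reports_smq")

  ledger <- tibble::tibble(
    n_drug_mentions_total = n_total,
    n_excluded_non_primary_suspect = ps$n_non_primary,
    n_excluded_missing_generic = ps$n_missing_generic,
    n_excluded_ambiguous = n_ambiguous,
    n_merged_synonyms = n_merged,
    n_excluded_duplicates = n_duplicates,
    n_surviving_mentions = nrow(survivors),
    n_final_drugs = nrow(drug_tbl)
  )

  structure(
    list(drugs = drug_tbl, counts = counts, survivors = survivors,
         ledger = ledger, smq_name = smq$name),
    class = "drug_list"
  )
}

#' @export
print.drug_list <- function(x, ...) {
  cat(sprintf("<drug_list> %d curated drug(s) from %d surviving mention(s)\n",
              nrow(x$drugs), x$ledger$n_surviving_mentions))
  print(utils::head(x$drugs, 10), ...)
  invisible(x)
}

#' @export
tidy.drug_list <- function(x, ...) x$drugs

#' @export
glance.drug_list <- function(x, ...) x$ledger

#' Drugs per event group
#'
#' Counts, for each narrow PT subgroup and for the SMQ overall, the drugs
#' reported as surviving primary suspect in at least one report of that
#' scope, with percentages of the final drug-list size (half-up, one
#' decimal).
#'
#' @param x a `drug_list`, or a long tibble (`drug`, `scope`,
#'   `n_reports`) of per-scope report counts.
#' @param smq the [smq_definition] naming the scopes.
#' @param digits decimal places for the percentage column.
#' @return tibble (`scope`, `n_drugs`, `pct`), PT rows first (descending
#'   drug count) and the SMQ row last.
#' @export
drugs_per_group <- function(x, smq = qt_smq(), digits = 1) {
  counts <- if (inherits(x, "drug_list")) x$counts else tibble::as_tibble(x)
  stopifnot(all(c("drug", "scope", "n_reports") %in% names(counts)))
  if (nrow(counts) == 0) stop("empty drug list", call. = FALSE)
  smq_scope <- smq$name
  n_final <- dplyr::n_distinct(counts$drug)
  tab <- counts |>
    dplyr::filter(.data$n_reports >= 1) |>
    dplyr::distinct(.data$drug, .data$scope) |>
    dplyr::count(.data$scope, name = "n_drugs")
  pt_rows <- tab |>
    dplyr::filter(.data$scope != smq_scope) |>
    dplyr::arrange(dplyr::desc(.data$n_drugs), .data$scope)
  smq_row <- dplyr::filter(tab, .data$scope == smq_scope)
  dplyr::bind_rows(pt_rows, smq_row) |>
    dplyr::mutate(pct = percentage(.data$n_drugs, n_final, digits))
}
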