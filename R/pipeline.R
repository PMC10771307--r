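#' Pipeline configuration
#'
#' Collects every run-time choice of the end-to-end analysis in one
#' object (or YAML file): input stream, study window, curation tables,
#' ranking depth, percentage precisions, comparator-denominator mode and
#' continuity-correction toggle.
#'
#' @param input path to an openFDA-dialect NDJSON/JSON report stream.
#' @param outdir output directory (created if absent).
#' @param synonyms a [synonym_table] or a TSV path for
#'   [read_synonym_table()]; `NULL` for an empty table.
#' @param atc an [atc_map] or a TSV path for [read_atc_map()]; `NULL`
#'   to leave drugs unclassed.
#' @param window optional [study_window] or length-2 character vector of
#'   dates; reports outside it are excluded at read time.
#' @param top_n ranking depth for the reporting-proportion tables.
#' @param digits_rank decimals on ranked proportion surfaces (default 2).
#' @param digits_table decimals on tabular percentage surfaces (default 1).
#' @param denominator `"database"` (comparator = all unique reports in
#'   the input, the default) or `"targets-only"` (comparator restricted
#'   to target reports).
#' @param correct continuity-correction toggle, see [compute_ror()].
#' @return an object of class `faers_pipeline_config`.
#' @export
faers_pipeline_config <- function(input, outdir, synonyms = NULL, atc = NULL,
                                  window = NULL, top_n = 10,
                                  digits_rank = 2, digits_table = 1,
                                  denominator = c("database", "targets-only"),
                                  correct = TRUE) {
  denominator <- match.arg(denominator)
  stopifnot(top_n >= 1)
  if (is.character(synonyms)) synonyms <- read_synonym_table(synonyms)
  if (is.null(synonyms)) synonyms <- synonym_table()
  if (is.character(atc)) atc <- read_atc_map(atc)
  if (is.character(window)) window <- study_window(window[1], window[2])
  structure(
    list(input = input, outdir = outdir, synonyms = synonyms, atc = atc,
         window = window, top_n = top_n, digits_rank = digits_rank,
         digits_table = digits_table, denominator = denominator,
         correct = correct),
    class = "faers_pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys mirroring the arguments of [faers_pipeline_config()];
#' `window` is a list with `start` and `end`, `synonyms`/`atc` are TSV
#' paths.
#'
#' @param path YAML file path.
#' @return a `faers_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  faers_pipeline_config(
    input = y$input, outdir = y$outdir,
    synonyms = y$synonyms, atc = y$atc,
    window = if (!is.null(y$window)) c(y$window$start, y$window$end),
    top_n = y$top_n %||% 10,
    digits_rank = y$digits_rank %||% 2,
    digits_table = y$digits_table %||% 1,
    denominator = y$denominator %||% "database",
    correct = y$correct %||% TRUE
  )
}

.write_csv <- function(df, dir, name) {
  readr::write_csv(tibble::as_tibble(df), file.path(dir, name))
}

#' Run the full screening pipeline
#'
#' Executes the six analysis stages end to end: read the report stream,
#' identify target reports with the narrow-scope SMQ, summarize report
#' characteristics, curate the primary-suspect drug list with its
#' exclusion ledger, run the seven-scope disproportionality screen, and
#' integrate the summary surfaces (drugs per group, ranked reporting
#' proportions for drugs and ATC classes, positive-signal-count
#' distribution, ATC-class signal distribution). All tables are written
#' as CSV into the output directory together with a `manifest.json`
#' recording configuration and stage counts; outputs are deterministic
#' for fixed inputs.
#'
#' @param config a [faers_pipeline_config()] or a YAML path for
#'   [read_pipeline_config()].
#' @param smq the [smq_definition] (default [qt_smq()]).
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with every stage result and the manifest.
#' @export
run_faers_pipeline <- function(config, smq = qt_smq(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "faers_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  stream <- read_faers_reports(config$input, window = config$window)
  log_line("read", "%d record(s) parsed, %d skipped, %d outside window",
           nrow(stream$reports), nrow(attr(stream, "skip_log")),
           attr(stream, "n_window_excluded"))

  targets <- identify_targets(stream, smq)
  log_line("identify", "%d target report(s) of %d unique reports",
           n_targets(targets), targets$n_total_database)
  if (n_targets(targets) == 0) {
    stop("case-identification: no target reports matched the SMQ",
         call. = FALSE)
  }

  chars <- summarize_characteristics(targets)
  for (panel in names(chars)) {
    .write_csv(chars[[panel]], config$outdir,
               sprintf("characteristics_%s.csv", panel))
  }
  log_line("characteristics", "%d panel table(s) written", length(chars))

  dl <- build_drug_list(targets, config$synonyms, config$atc, smq)
  .write_csv(dl$drugs, config$outdir, "drug_list.csv")
  .write_csv(dl$ledger, config$outdir, "curation_ledger.csv")
  log_line("curate", "%d drug(s) from %d mention(s)",
           nrow(dl$drugs), dl$ledger$n_drug_mentions_total)

  background <- if (config$denominator == "targets-only") {
    targets$data
  } else {
    stream
  }
  screen <- detect_all_signals(targets, background, dl,
                               synonyms = config$synonyms, smq = smq,
                               correct = config$correct)
  .write_csv(tidy(screen), config$outdir, "signal_matrix.csv")
  log_line("signals", "%d result(s) (%d positive)", nrow(screen),
           sum(screen$signal == "positive"))

  per_group <- drugs_per_group(dl, smq, digits = config$digits_table)
  .write_csv(per_group, config$outdir, "drugs_per_group.csv")

  scopes <- c(smq$pts$name, smq$name)
  rank_tables <- list()
  for (by in c("drug", "class")) {
    ranked <- purrr::map(scopes, function(sc) {
      tab <- top_reported(dl, targets, scope = sc, by = by,
                          top_n = config$top_n,
                          digits = config$digits_rank, smq = smq)
      dplyr::mutate(tab, scope = sc, .before = 1)
    })
    rank_tables[[by]] <- dplyr::bind_rows(ranked)
    .write_csv(rank_tables[[by]], config$outdir,
               sprintf("top_reported_%s.csv", by))
  }

  pos <- count_positive_signals(screen, digits = config$digits_table)
  .write_csv(pos$distribution, config$outdir, "positive_signal_distribution.csv")
  .write_csv(pos$per_drug, config$outdir, "positive_signals_per_drug.csv")

  atc_dist <- atc_signal_distribution(screen, dl)
  .write_csv(atc_dist, config$outdir, "atc_signal_distribution.csv")
  log_line("summarize", "%d drug(s) with at least one positive signal",
           pos$n_at_least_one)

  manifest <- list(
    package = "faersqt",
    version = as.character(utils::packageVersion("faersqt")),
    config = list(
      input = config$input, denominator = config$denominator,
      top_n = config$top_n, digits_rank = config$digits_rank,
      digits_table = config$digits_table, correct = config$correct,
      window = if (!is.null(config$window)) {
        list(start = format(config$window$start),
             end = format(config$window$end))
      }
    ),
    counts = list(
      records_read = attr(stream, "n_records_read"),
      records_parsed = nrow(stream$reports),
      records_skipped = nrow(attr(stream, "skip_log")),
      records_window_excluded = attr(stream, "n_window_excluded"),
      unique_reports = targets$n_total_database,
      target_reports = n_targets(targets),
      curated_drugs = nrow(dl$drugs),
      signal_results = nrow(screen),
      positive_signals = sum(screen$signal == "positive"),
      drugs_with_positive_signal = pos$n_at_least_one
    ),
    ledger = as.list(dl$ledger)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    stream = stream, targets = targets, characteristics = chars,
    drug_list = dl, screen = screen, drugs_per_group = per_group,
    top_reported = rank_tables, positive_signals = pos,
    atc_distribution = atc_dist, manifest = manifest
  ))
}
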