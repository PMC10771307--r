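#' Standardized MedDRA query definitions
#'
#' An `smq_definition` bundles an SMQ name, its MedDRA code, and the
#' narrow-scope preferred terms (PTs) that identify reports of the medical
#' condition with little doubt.
#'
#' @param name SMQ display name.
#' @param code MedDRA integer code for the SMQ.
#' @param pts tibble with columns `name` (PT string) and `code` (8-digit
#'   MedDRA integer).
#' @return an object of class `smq_definition`.
#' @export
smq_definition <- function(name, code, pts) {
  pts <- tibble::as_tibble(pts)
  stopifnot(
    is.character(name), length(name) == 1L, nzchar(name),
    length(code) == 1L, is.numeric(code), code > 0,
    all(c("name", "code") %in% names(pts)), nrow(pts) > 0
  )
  if (any(!nzchar(pts$name)) || any(pts$code <= 0)) {
    stop("preferred terms need non-empty names and positive codes", call. = FALSE)
  }
  if (anyDuplicated(pts[c("name", "code")])) {
    stop("duplicate (name, code) pair in PT set", call. = FALSE)
  }
  structure(
    list(name = name, code = as.integer(code),
         pts = tibble::tibble(name = pts$name, code = as.integer(pts$code))),
    class = "smq_definition"
  )
}

#' The torsade de pointes / QT prolongation narrow-scope SMQ
#'
#' Returns the fixed six-PT narrow-scope definition of the
#' "Torsade de pointes/QT prolongation" standardized MedDRA query
#' (SMQ code 20000001) used to identify target adverse-event reports.
#' Narrow-scope PTs leave essentially no doubt that the report describes
#' QT prolongation or torsade de pointes.
#'
#' @return an [smq_definition] with six preferred terms.
#' @examples
#' qt_smq()$pts
#' @export
qt_smq <- function() {
  smq_definition(
    name = "Torsade de pointes/QT prolongation (SMQ)",
    code = 20000001L,
    pts = tibble::tibble(
      name = c(
        "Electrocardiogram QT prolonged",
        "Ventricular tachycardia",
        "Torsade de pointes",
        "Long QT syndrome",
        "Electrocardiogram QT interval abnormal",
        "Long QT syndrome congenital"
      ),
      code = c(10014387L, 10047302L, 10044066L, 10024803L,
               10063748L, 10057926L)
    )
  )
}

#' @export
print.smq_definition <- function(x, ...) {
  cat("<smq_definition> ", x$name, " [", x$code, "]\n", sep = "")
  print(x$pts, ...)
  invisible(x)
}

#' Study window
#'
#' A pair of calendar dates delimiting the report receipt dates under study.
#'
#' @param start,end `Date` or parseable date strings; `start <= end`.
#' @return an object of class `study_window`.
#' @examples
#' study_window("2004-01-01", "2022-12-31")
#' @export
study_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(!is.na(start), !is.na(end))
  if (start > end) stop("window start must not exceed end", call. = FALSE)
  structure(list(start = start, end = end), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("<study_window> ", format(x$start), " .. ", format(x$end), "\n", sep = "")
  invisible(x)
}

# ---- the relational report container -------------------------------------

#' Adverse-event report collection
#'
#' A `faers_reports` object holds a collection of adverse-event reports in
#' relational (tidy) form, keyed by an internal `record_seq` identifier so
#' that multiple versions of the same safety report ID (follow-ups) can
#' coexist before deduplication:
#'
#' * `$reports` — one row per record: `record_seq`, `report_id`,
#'   `receipt_date`, `qualification`, `country`, `sex`, `age_years`,
#'   `outcomes` (list-column of outcome codes).
#' * `$reactions` — one row per reported reaction: `record_seq`, `pt`.
#' * `$drugs` — one row per drug mention: `record_seq`, `drug_seq`,
#'   `characterization` (1 = primary suspect, 2 = concomitant,
#'   3 = interacting), `raw_name`, `generic_name`.
#'
#' @param reports,reactions,drugs tibbles with the columns listed above.
#' @return an object of class `faers_reports`.
#' @export
faers_reports <- function(reports, reactions, drugs) {
  reports <- tibble::as_tibble(reports)
  reactions <- tibble::as_tibble(reactions)
  drugs <- tibble::as_tibble(drugs)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(reports, c("record_seq", "report_id", "receipt_date", "qualification",
                  "country", "sex", "age_years", "outcomes"), "reports")
  need(reactions, c("record_seq", "pt"), "reactions")
  need(drugs, c("record_seq", "drug_seq", "characterization",
                "raw_name", "generic_name"), "drugs")
  if (anyDuplicated(reports$record_seq)) {
    stop("record_seq must be unique", call. = FALSE)
  }
  if (any(is.na(reports$report_id)) || any(!nzchar(reports$report_id))) {
    stop("every record needs a non-empty report_id", call. = FALSE)
  }
  if (!all(reactions$record_seq %in% reports$record_seq) ||
      !all(drugs$record_seq %in% reports$record_seq)) {
    stop("orphan record_seq in child table", call. = FALSE)
  }
  if (!all(reports$record_seq %in% reactions$record_seq)) {
    stop("every record needs at least one reaction PT", call. = FALSE)
  }
  if (any(!drugs$characterization %in% c(1L, 2L, 3L))) {
    stop("drug characterization must be 1, 2 or 3", call. = FALSE)
  }
  structure(list(reports = reports, reactions = reactions, drugs = drugs),
            class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf(
    "<faers_reports> %d record(s), %d unique report ID(s), %d reaction row(s), %d drug row(s)\n",
    nrow(x$reports), dplyr::n_distinct(x$reports$report_id),
    nrow(x$reactions), nrow(x$drugs)))
  invisible(x)
}

#' Number of records in a report collection
#' @param x a [faers_reports] object.
#' @return integer record count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  nrow(x$reports)
}

# openFDA enumerations (documented numeric codes); anything unmapped
# becomes "unknown" rather than an error, since the characteristics
# summaries must tolerate real-world sloppiness.
.qualification_codes <- c(
  "1" = "physician", "2" = "pharmacist", "3" = "other health professional",
  "4" = "lawyer", "5" = "consumer"
)
.sex_codes <- c("1" = "male", "2" = "female")
.outcome_fields <- c(
  seriousnessdeath = "death",
  seriousnesshospitalization = "hospitalization",
  seriousnesslifethreatening = "life-threatening",
  seriousnessdisabling = "disability",
  seriousnessother = "other"
)

.parse_faers_date <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(as.Date(NA))
  x <- as.character(x)
  d <- if (grepl("^\\d{8}$", x)) {
    as.Date(x, format = "%Y%m%d")
  } else if (grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    as.Date(x)
  } else {
    as.Date(NA)
  }
  d
}

# onset-age unit codes: 800 decade, 801 year, 802 month, 803 week,
# 804 day, 805 hour
.age_to_years <- function(age, unit) {
  if (is.null(age) || is.na(suppressWarnings(as.numeric(age)))) return(NA_real_)
  age <- as.numeric(age)
  unit <- as.character(unit %||% "801")
  mult <- switch(unit,
    "800" = 10, "801" = 1, "802" = 1 / 12, "803" = 7 / 365.25,
    "804" = 1 / 365.25, "805" = 1 / 8766, NA_real_)
  out <- age * mult
  if (is.na(out) || out < 0) NA_real_ else out
}

.parse_record_core <- function(record, record_seq) {
  if (!is.list(record)) stop("record is not a JSON object", call. = FALSE)
  report_id <- record$safetyreportid
  if (is.null(report_id) || !nzchar(as.character(report_id))) {
    stop("record lacks a safety report ID", call. = FALSE)
  }
  report_id <- as.character(report_id)
  patient <- record$patient
  reactions <- patient$reaction
  pts <- character(0)
  if (!is.null(reactions)) {
    pts <- vapply(reactions, function(r) {
      as.character(r$reactionmeddrapt %||% NA_character_)
    }, character(1))
    pts <- pts[!is.na(pts) & nzchar(pts)]
  }
  if (length(pts) == 0) {
    stop("record lacks a reaction PT list", call. = FALSE)
  }

  qual_code <- as.character(record$primarysource$qualification %||% "")
  qualification <- unname(.qualification_codes[qual_code])
  if (is.na(qualification) || is.null(qualification)) qualification <- "unknown"

  country <- record$primarysource$reportercountry %||% record$occurcountry
  country <- if (is.null(country) || !nzchar(as.character(country))) {
    NA_character_
  } else {
    as.character(country)
  }

  sex_code <- as.character(patient$patientsex %||% "")
  sex <- unname(.sex_codes[sex_code])
  if (is.na(sex) || is.null(sex)) sex <- "unknown"

  age_years <- .age_to_years(patient$patientonsetage,
                             patient$patientonsetageunit)

  outcomes <- unname(.outcome_fields[
    names(.outcome_fields)[vapply(names(.outcome_fields), function(f) {
      identical(as.character(record[[f]] %||% ""), "1")
    }, logical(1))]
  ])
  if (length(outcomes) == 0) outcomes <- "unknown"

  drug_rows <- NULL
  if (!is.null(patient$drug) && length(patient$drug)) {
    drug_rows <- purrr::imap(patient$drug, function(d, i) {
      chr <- suppressWarnings(as.integer(d$drugcharacterization %||% NA))
      if (is.na(chr) || !chr %in% 1:3) chr <- NA_integer_
      gn <- d$openfda$generic_name
      gn <- if (is.null(gn) || length(gn) == 0) NA_character_ else as.character(gn[[1]])
      if (!is.na(gn) && !nzchar(gn)) gn <- NA_character_
      rn <- d$medicinalproduct %||% NA_character_
      rn <- if (is.na(rn) || !nzchar(as.character(rn))) NA_character_ else as.character(rn)
      list(drug_seq = i, characterization = chr, raw_name = rn, generic_name = gn)
    })
    drug_rows <- purrr::keep(drug_rows, ~ !is.na(.x$characterization))
  }

  list(
    reports = tibble::tibble(
      record_seq = record_seq,
      report_id = report_id,
      receipt_date = .parse_faers_date(record$receiptdate),
      qualification = qualification,
      country = country,
      sex = sex,
      age_years = age_years,
      outcomes = list(outcomes)
    ),
    reactions = tibble::tibble(record_seq = record_seq, pt = pts),
    drugs = if (length(drug_rows)) {
      tibble::tibble(
        record_seq = record_seq,
        drug_seq = vapply(drug_rows, `[[`, integer(1), "drug_seq"),
        characterization = vapply(drug_rows, `[[`, integer(1), "characterization"),
        raw_name = vapply(drug_rows, `[[`, character(1), "raw_name"),
        generic_name = vapply(drug_rows, `[[`, character(1), "generic_name")
      )
    } else {
      tibble::tibble(record_seq = integer(0), drug_seq = integer(0),
                     characterization = integer(0), raw_name = character(0),
                     generic_name = character(0))
    }
  )
}

#' Parse a single openFDA drug-event record
#'
#' Maps one parsed JSON object (openFDA drug-event dialect) onto the
#' [faers_reports] column set. Unrecognised fields are ignored; missing
#' optional fields become `NA`/`"unknown"`, never fabricated values.
#' A record with no safety report ID or no reaction list is malformed and
#' raises an error (the stream reader skips and logs such records).
#'
#' @param record a list as returned by [jsonlite::fromJSON] with
#'   `simplifyVector = FALSE` on one record.
#' @return a one-record [faers_reports] object.
#' @export
parse_report <- function(record) {
  parts <- .parse_record_core(record, record_seq = 1L)
  faers_reports(parts$reports, parts$reactions, parts$drugs)
}

.bind_parts <- function(parts) {
  faers_reports(
    dplyr::bind_rows(purrr::map(parts, "reports")),
    dplyr::bind_rows(purrr::map(parts, "reactions")),
    dplyr::bind_rows(purrr::map(parts, "drugs"))
  )
}

#' Read a stream of openFDA drug-event records
#'
#' Reads newline-delimited JSON or a JSON array (optionally inside the
#' openFDA `{"results": [...]}` envelope); the dialect is auto-detected
#' from the first non-whitespace character. Malformed records are skipped
#' and logged, not fatal. With a [study_window], records whose receipt
#' date falls outside the window (or is missing) are excluded and counted.
#'
#' @param path file path to read.
#' @param window optional [study_window] to filter on receipt date.
#' @return a [faers_reports] object with attributes `skip_log` (tibble of
#'   skipped record indices and reasons), `n_window_excluded`, and
#'   `n_records_read`.
#' @export
read_faers_reports <- function(path, window = NULL) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  first <- stringr::str_sub(stringr::str_trim(txt), 1, 1)
  records <- if (identical(first, "[")) {
    jsonlite::fromJSON(txt, simplifyVector = FALSE)
  } else if (identical(first, "{") &&
             grepl('^\\s*\\{\\s*"results"', txt)) {
    jsonlite::fromJSON(txt, simplifyVector = FALSE)$results
  } else if (identical(first, "{")) {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(stringr::str_trim(lines))]
    lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
               error = function(e) structure(list(), class = "faersqt_bad_json"))
    })
  } else {
    stop("cannot detect record dialect (expected NDJSON or JSON array)",
         call. = FALSE)
  }

  parts <- vector("list", length(records))
  skip <- list()
  kept <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (inherits(rec, "faersqt_bad_json")) {
      skip[[length(skip) + 1L]] <- tibble::tibble(record = i, reason = "invalid JSON")
      next
    }
    p <- tryCatch(.parse_record_core(rec, record_seq = kept + 1L),
                  error = function(e) conditionMessage(e))
    if (is.character(p)) {
      skip[[length(skip) + 1L]] <- tibble::tibble(record = i, reason = p)
      next
    }
    kept <- kept + 1L
    parts[[kept]] <- p
  }
  parts <- parts[seq_len(kept)]

  n_window_excluded <- 0L
  if (!is.null(window) && kept > 0) {
    stopifnot(inherits(window, "study_window"))
    inside <- vapply(parts, function(p) {
      d <- p$reports$receipt_date
      !is.na(d) && d >= window$start && d <= window$end
    }, logical(1))
    n_window_excluded <- sum(!inside)
    parts <- parts[inside]
    # renumber so record_seq stays dense and in file order
    parts <- purrr::imap(parts, function(p, i) {
      p$reports$record_seq <- i
      if (nrow(p$reactions)) p$reactions$record_seq <- i
      if (nrow(p$drugs)) p$drugs$record_seq <- i
      p
    })
  }

  out <- if (length(parts)) {
    .bind_parts(parts)
  } else {
    faers_reports(
      tibble::tibble(record_seq = integer(0), report_id = character(0),
                     receipt_date = as.Date(character(0)),
                     qualification = character(0), country = character(0),
                     sex = character(0), age_years = numeric(0),
                     outcomes = list()),
      tibble::tibble(record_seq = integer(0), pt = character(0)),
      tibble::tibble(record_seq = integer(0), drug_seq = integer(0),
                     characterization = integer(0), raw_name = character(0),
                     generic_name = character(0))
    )
  }
  attr(out, "skip_log") <- if (length(skip)) {
    dplyr::bind_rows(skip)
  } else {
    tibble::tibble(record = integer(0), reason = character(0))
  }
  attr(out, "n_window_excluded") <- n_window_excluded
  attr(out, "n_records_read") <- length(records)
  out
}

.outcome_to_fields <- function(outcomes) {
  fields <- names(.outcome_fields)[match(outcomes, .outcome_fields)]
  fields[!is.na(fields)]
}

#' Write reports as canonical NDJSON
#'
#' Emits one openFDA-dialect JSON object per line, inverse to
#' [read_faers_reports]: reading the written file back reproduces the
#' same field values.
#'
#' @param x a [faers_reports] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_faers_reports <- function(x, path) {
  stopifnot(inherits(x, "faers_reports"))
  reac_by <- split(x$reactions$pt, x$reactions$record_seq)
  drugs_split <- split(x$drugs, x$drugs$record_seq)

  qual_back <- stats::setNames(names(.qualification_codes), .qualification_codes)
  sex_back <- stats::setNames(names(.sex_codes), .sex_codes)

  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(x$reports))) {
    row <- x$reports[i, ]
    seq_i <- as.character(row$record_seq)
    rec <- list(safetyreportid = row$report_id)
    if (!is.na(row$receipt_date)) {
      rec$receiptdate <- format(row$receipt_date, "%Y%m%d")
    }
    ps <- list()
    if (row$qualification != "unknown") {
      ps$qualification <- unname(qual_back[row$qualification])
    }
    if (!is.na(row$country)) ps$reportercountry <- row$country
    if (length(ps)) rec$primarysource <- ps
    for (f in .outcome_to_fields(row$outcomes[[1]])) rec[[f]] <- "1"

    patient <- list()
    if (row$sex != "unknown") patient$patientsex <- unname(sex_back[row$sex])
    if (!is.na(row$age_years)) {
      patient$patientonsetage <- as.character(row$age_years)
      patient$patientonsetageunit <- "801"
    }
    patient$reaction <- lapply(reac_by[[seq_i]] %||% character(0),
                               function(p) list(reactionmeddrapt = p))
    dr <- drugs_split[[seq_i]]
    if (!is.null(dr) && nrow(dr)) {
      patient$drug <- lapply(seq_len(nrow(dr)), function(j) {
        d <- list(drugcharacterization = as.character(dr$characterization[j]))
        if (!is.na(dr$raw_name[j])) d$medicinalproduct <- dr$raw_name[j]
        if (!is.na(dr$generic_name[j])) {
          d$openfda <- list(generic_name = list(dr$generic_name[j]))
        }
        d
      })
    }
    rec$patient <- patient
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Construct an openFDA API search expression
#'
#' Builds (but never sends) the search string that would retrieve all
#' reports carrying any of the definition's narrow-scope PTs within the
#' study window, for documentation and reproducibility.
#'
#' @param smq an [smq_definition].
#' @param window a [study_window].
#' @return a single search string; deterministic for fixed inputs.
#' @examples
#' build_api_query(qt_smq(), study_window("2004-01-01", "2022-12-31"))
#' @export
build_api_query <- function(smq, window) {
  stopifnot(inherits(smq, "smq_definition"), inherits(window, "study_window"))
  pts <- paste0('"', smq$pts$name, '"', collapse = "+OR+")
  sprintf(
    "patient.reaction.reactionmeddrapt.exact:(%s)+AND+receiptdate:[%s+TO+%s]",
    pts, format(window$start, "%Y%m%d"), format(window$end, "%Y%m%d")
  )
}
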