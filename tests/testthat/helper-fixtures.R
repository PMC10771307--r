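# Builders for small openFDA-dialect records and streams used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

fx_record <- function(id, date = "20200115", reactions = "Nausea",
                      drugs = list(), sex = NULL, age = NULL,
                      qualification = NULL, country = NULL,
                      outcomes = character(0), extra = list()) {
  rec <- list(safetyreportid = id)
  if (!is.null(date)) rec$receiptdate <- date
  ps <- list()
  if (!is.null(qualification)) ps$qualification <- qualification
  if (!is.null(country)) ps$reportercountry <- country
  if (length(ps)) rec$primarysource <- ps
  for (f in outcomes) rec[[f]] <- "1"
  patient <- list()
  if (!is.null(sex)) patient$patientsex <- sex
  if (!is.null(age)) {
    patient$patientonsetage <- as.character(age)
    patient$patientonsetageunit <- "801"
  }
  patient$reaction <- lapply(reactions, function(p) list(reactionmeddrapt = p))
  if (length(drugs)) {
    patient$drug <- lapply(drugs, function(d) {
      out <- list(drugcharacterization = as.character(d$char %||% 1))
      if (!is.null(d$raw)) out$medicinalproduct <- d$raw
      if (!is.null(d$generic)) out$openfda <- list(generic_name = list(d$generic))
      out
    })
  }
  rec$patient <- patient
  for (nm in names(extra)) rec[[nm]] <- extra[[nm]]
  rec
}

# write records as NDJSON and read them back through the package reader
fx_stream <- function(records, window = NULL, path = tempfile(fileext = ".ndjson")) {
  writeLines(vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
  }, character(1)), path)
  read_faers_reports(path, window = window)
}

# a drug entry shorthand
fx_drug <- function(generic = NULL, char = 1, raw = NULL) {
  list(generic = generic, char = char, raw = raw)
}
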