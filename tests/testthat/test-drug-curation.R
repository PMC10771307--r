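syn_basic <- synonym_table(
  map = c(paracetamol = "acetaminophen", aspirin = "acetylsalicylic acid"),
  ambiguous = "multivitamins"
)

test_that("normalize_name folds, merges synonyms, flags ambiguity, idempotently", {
  expect_equal(normalize_name("Paracetamol", syn_basic), "acetaminophen")
  expect_equal(normalize_name("FUROSEMIDE ", syn_basic), "furosemide")
  expect_true(is.na(normalize_name("Multivitamins", syn_basic)))
  expect_equal(normalize_name(c("ASPIRIN", "aspirin "), syn_basic),
               rep("acetylsalicylic acid", 2))
  # idempotence on resolvable names
  once <- normalize_name(c("Paracetamol", "Quetiapine"), syn_basic)
  expect_equal(normalize_name(once, syn_basic), once)
  expect_error(normalize_name("", syn_basic), "non-empty")
  expect_error(normalize_name(c("ok", NA), syn_basic), "non-empty")
})

test_that("synonym_table enforces fixed-point and disjointness invariants", {
  expect_error(synonym_table(c(a = "b", b = "c")), "fixed point")
  expect_error(synonym_table(c(a = "b"), ambiguous = "a"), "disjoint")
})

test_that("synonym and ATC tables round-trip through TSV", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("raw_name\tcanonical_name\tflag",
               "paracetamol\tacetaminophen\tsynonym",
               "multivitamins\t\tambiguous"), tsv)
  syn <- read_synonym_table(tsv)
  expect_equal(normalize_name("paracetamol", syn), "acetaminophen")
  expect_true(is.na(normalize_name("multivitamins", syn)))

  atsv <- tempfile(fileext = ".tsv")
  writeLines(c("generic_name\tatc_code",
               "furosemide\tC03CA01",
               "acetylsalicylic acid\tB01AC06",
               "acetylsalicylic acid\tN02BA01"), atsv)
  atc <- read_atc_map(atsv)
  expect_s3_class(atc, "atc_map")
  expect_setequal(atc$atc_class[atc$generic_name == "acetylsalicylic acid"],
                  c("B01", "N02"))
  writeLines(c("generic_name\tatc_code", "x\tBAD"), atsv)
  expect_error(read_atc_map(atsv), "malformed ATC")
})

test_that("extract_primary_suspects keeps characterization-1 named entries and tallies the rest", {
  recs <- list(fx_record("R1", reactions = "Torsade de pointes",
                         drugs = list(fx_drug("furosemide", 1),
                                      fx_drug("aspirin", 2),
                                      fx_drug(char = 1))))  # PS, name missing
  x <- fx_stream(recs)
  ps <- extract_primary_suspects(x$drugs)
  expect_equal(ps$suspects$generic_name, "furosemide")
  expect_equal(ps$n_non_primary, 1L)
  expect_equal(ps$n_missing_generic, 1L)
  empty <- extract_primary_suspects(x$drugs[0, ])
  expect_equal(nrow(empty$suspects), 0L)
  expect_equal(empty$n_non_primary + empty$n_missing_generic, 0L)
})

test_that("the curation cascade counts every exclusion on a hand-built report set", {
  recs <- list(
    # quetiapine repeated as primary suspect: one survivor, one duplicate
    fx_record("R1", reactions = "Torsade de pointes",
              drugs = list(fx_drug("quetiapine", 1), fx_drug("quetiapine", 1))),
    # paracetamol + aspirin variants merge; concomitant excluded
    fx_record("R2", reactions = c("Torsade de pointes", "Long QT syndrome"),
              drugs = list(fx_drug("Paracetamol", 1), fx_drug("ibuprofen", 2))),
    # ambiguous name dropped, second suspect survives
    fx_record("R3", reactions = "Long QT syndrome",
              drugs = list(fx_drug("multivitamins", 1),
                           fx_drug("acetaminophen", 1))),
    # missing generic name dropped
    fx_record("R4", reactions = "Torsade de pointes",
              drugs = list(fx_drug(char = 1), fx_drug("quetiapine", 1)))
  )
  tg <- identify_targets(fx_stream(recs))
  dl <- build_drug_list(tg, syn_basic)
  led <- dl$ledger

  expect_equal(led$n_drug_mentions_total, 8L)
  expect_equal(led$n_excluded_non_primary_suspect, 1L)
  expect_equal(led$n_excluded_missing_generic, 1L)
  expect_equal(led$n_excluded_ambiguous, 1L)
  expect_equal(led$n_merged_synonyms, 1L)      # Paracetamol -> acetaminophen
  expect_equal(led$n_excluded_duplicates, 1L)  # repeated quetiapine in R1
  expect_equal(led$n_surviving_mentions, 4L)
  expect_equal(led$n_final_drugs, 2L)
  # conservation across the cascade
  expect_equal(
    led$n_drug_mentions_total,
    led$n_excluded_non_primary_suspect + led$n_excluded_missing_generic +
      led$n_excluded_ambiguous + led$n_excluded_duplicates +
      led$n_surviving_mentions
  )

  counts <- dl$counts
  smq_name <- qt_smq()$name
  # quetiapine: R1 and R4 -> SMQ count 2
  expect_equal(counts$n_reports[counts$drug == "quetiapine" &
                                  counts$scope == smq_name], 2L)
  # acetaminophen in R2 which matched two PTs: both per-PT counts 1, SMQ 1
  aceta <- counts[counts$drug == "acetaminophen", ]
  expect_equal(aceta$n_reports[aceta$scope == smq_name], 2L)  # R2 + R3
  expect_equal(aceta$n_reports[aceta$scope == "Torsade de pointes"], 1L)
  expect_equal(aceta$n_reports[aceta$scope == "Long QT syndrome"], 2L)
  # ordering: descending SMQ count, ties alphabetical
  expect_equal(dl$drugs$drug, c("acetaminophen", "quetiapine"))
})

test_that("curation is order-independent and SMQ drug set is the per-PT union", {
  sim <- simulate_faers(faers_sim_config(n_reports = 3000, seed = 5))
  tg <- identify_targets(sim$reports)
  dl <- build_drug_list(tg, sim$synonyms, sim$atc)

  # permute the record order and rebuild
  set.seed(99)
  perm <- sample(nrow(sim$reports$reports))
  shuffled <- faers_reports(
    sim$reports$reports[perm, ],
    sim$reports$reactions,
    sim$reports$drugs
  )
  dl2 <- build_drug_list(identify_targets(shuffled), sim$synonyms, sim$atc)
  expect_equal(dl2$drugs, dl$drugs)
  expect_equal(dplyr::arrange(dl2$counts, drug, scope),
               dplyr::arrange(dl$counts, drug, scope))

  smq_name <- qt_smq()$name
  pt_drugs <- unique(dl$counts$drug[dl$counts$scope != smq_name])
  smq_drugs <- dl$counts$drug[dl$counts$scope == smq_name]
  expect_setequal(pt_drugs, smq_drugs)
  # every curated drug appears in at least one report
  expect_true(all(dl$drugs$n_reports_smq >= 1))
})

test_that("unmapped drugs fall into the unmapped ATC bucket", {
  recs <- list(fx_record("R1", reactions = "Torsade de pointes",
                         drugs = list(fx_drug("novel compound x", 1))))
  dl <- build_drug_list(identify_targets(fx_stream(recs)), syn_basic,
                        atc_map(tibble::tibble(generic_name = "furosemide",
                                               atc_code = "C03CA01")))
  expect_equal(dl$drugs$atc_classes, "unmapped")
})

test_that("drugs_per_group reports group sizes as percentages of the drug list", {
  # all drugs in every group
  counts <- tidyr::expand_grid(
    drug = c("a", "b"),
    scope = c(qt_smq()$pts$name, qt_smq()$name)
  ) |> dplyr::mutate(n_reports = 1L)
  tab <- drugs_per_group(counts)
  expect_true(all(tab$pct == 100.0))
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$scope[7], qt_smq()$name)
})
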