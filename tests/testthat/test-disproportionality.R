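# independent brute-force evaluation: odds of exposure among cases over
# odds among non-cases, log-variance from the cell reciprocals
ror_oracle <- function(a, b, c, d) {
  ror <- (a / c) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, ci_low = exp(log(ror) - 1.96 * se),
       ci_high = exp(log(ror) + 1.96 * se))
}

test_that("compute_ror reproduces hand-evaluated tables", {
  sym <- compute_ror(5, 5, 5, 5)
  expect_equal(sym$ror, 1)
  expect_lt(sym$ci_low, 1)
  expect_gt(sym$ci_high, 1)
  expect_equal(sym$signal, "negative")

  r <- compute_ror(3, 1, 1, 3)
  expect_equal(r$ror, 9)
  expect_equal(r$ci_low, exp(log(9) - 1.96 * sqrt(1 / 3 + 1 + 1 + 1 / 3)))
  expect_equal(round(r$ci_low, 3), 0.367)
  expect_equal(r$signal, "negative")  # a = 3 but CI crosses 1
  expect_false(r$corrected)

  # zero cell: Haldane-Anscombe correction on all four cells
  z <- compute_ror(3, 1, 0, 3)
  expect_true(z$corrected)
  expect_equal(z$n_cases, 3L)
  expect_equal(z$ror, (3.5 * 3.5) / (1.5 * 0.5))
  expect_equal(z$ci_low,
               exp(log(z$ror) - 1.96 * sqrt(1 / 3.5 + 1 / 1.5 + 1 / 0.5 + 1 / 3.5)))
  # correction disabled: undefined estimate, negative signal
  nz <- compute_ror(3, 1, 0, 3, correct = FALSE)
  expect_true(is.na(nz$ror))
  expect_equal(nz$signal, "negative")
})

test_that("compute_ror agrees with the brute-force oracle on random tables", {
  set.seed(2024)
  n <- 2000
  cells <- matrix(sample.int(1e6, 4 * n, replace = TRUE), ncol = 4)
  got <- compute_ror(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
  want <- ror_oracle(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
  expect_equal(got$ror, want$ror, tolerance = 1e-12)
  expect_equal(got$ci_low, want$ci_low, tolerance = 1e-12)
  expect_equal(got$ci_high, want$ci_high, tolerance = 1e-12)
  expect_false(any(got$corrected))
})

test_that("swapping exposure columns inverts the ROR and mirrors the CI", {
  set.seed(7)
  a <- sample(1:500, 50); b <- sample(1:500, 50)
  c <- sample(1:500, 50); d <- sample(1:500, 50)
  fwd <- compute_ror(a, b, c, d)
  rev <- compute_ror(b, a, d, c)
  expect_equal(rev$ror, 1 / fwd$ror, tolerance = 1e-12)
  expect_equal(rev$ci_low, 1 / fwd$ci_high, tolerance = 1e-12)
  expect_equal(rev$ci_high, 1 / fwd$ci_low, tolerance = 1e-12)
})

test_that("scaling all cells by k shrinks the log-CI width by exactly sqrt(1/k)", {
  base <- compute_ror(12, 34, 56, 78)
  for (k in c(4, 9, 25)) {
    scaled <- compute_ror(12 * k, 34 * k, 56 * k, 78 * k)
    expect_equal(log(scaled$ci_high) - log(scaled$ci_low),
                 (log(base$ci_high) - log(base$ci_low)) * sqrt(1 / k),
                 tolerance = 1e-12)
    expect_equal(scaled$ror, base$ror, tolerance = 1e-12)
  }
})

test_that("classify_signal equals the (a >= 3) AND (ci_low > 1) truth table", {
  expect_equal(classify_signal(2, 5.0), "negative")       # too few cases
  expect_equal(classify_signal(3, 1.0001), "positive")
  expect_equal(classify_signal(100, 1.0), "negative")     # strict inequality
  expect_equal(classify_signal(3, NA), "negative")
  # exhaustive sweep over a grid
  grid <- expand.grid(n = 0:6, ci = c(0.5, 0.999, 1, 1.001, 2, NA))
  got <- classify_signal(grid$n, grid$ci)
  want <- ifelse(grid$n >= 3 & !is.na(grid$ci) & grid$ci > 1,
                 "positive", "negative")
  expect_equal(got, want)
})

test_that("build_contingency counts unique reports into the 2x2 layout", {
  # 100 reports; 10 with the event; drugx suspect in 4 event + 6 non-event
  recs <- purrr::map(1:100, function(i) {
    event <- i <= 10
    exposed <- i %in% c(1:4, 11:16)
    fx_record(sprintf("R%03d", i),
              reactions = if (event) "Torsade de pointes" else "Nausea",
              drugs = if (exposed) list(fx_drug("drugx", 1)) else list())
  })
  stream <- fx_stream(recs)
  tg <- identify_targets(stream)
  idx <- build_exposure_index(stream)
  tab <- build_contingency("drugx", "Torsade de pointes", tg, idx)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 4L, b = 6L, c = 6L, d = 84L))
  expect_equal(sum(tab$a, tab$b, tab$c, tab$d), 100)
  # never-suspect drug: a = 0, c = 0
  tab0 <- build_contingency("ghost", "Torsade de pointes", tg, idx)
  expect_equal(c(tab0$a, tab0$c), c(0L, 0L))
  expect_error(build_contingency("drugx", "Not a scope", tg, idx),
               "unknown scope")
})

test_that("the screen yields exactly seven deterministic results per drug", {
  sim <- simulate_faers(faers_sim_config(n_reports = 4000, seed = 3))
  tg <- identify_targets(sim$reports)
  dl <- build_drug_list(tg, sim$synonyms, sim$atc)
  scr <- detect_all_signals(tg, sim$reports, dl, sim$synonyms)

  expect_equal(nrow(scr), 7L * nrow(dl$drugs))
  per_drug <- dplyr::count(tibble::as_tibble(scr), drug)
  expect_true(all(per_drug$n == 7L))
  # marginals: a + b equals the scope's event count, table total the database
  smq_name <- qt_smq()$name
  expect_true(all(scr$a + scr$b + scr$c + scr$d == tg$n_total_database))
  ab <- scr$a + scr$b
  expect_true(all(ab[scr$scope == smq_name] == n_targets(tg)))
  # SMQ containment: a(SMQ) >= a(PT) for every drug
  wide <- tibble::as_tibble(scr) |>
    dplyr::group_by(drug) |>
    dplyr::summarise(a_smq = a[scope == smq_name], a_max_pt = max(a[scope != smq_name]))
  expect_true(all(wide$a_smq >= wide$a_max_pt))
  # a = 0 scopes are negative
  expect_true(all(scr$signal[scr$a == 0] == "negative"))
  # determinism
  scr2 <- detect_all_signals(tg, sim$reports, dl, sim$synonyms)
  expect_identical(tidy(scr), tidy(scr2))
})
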