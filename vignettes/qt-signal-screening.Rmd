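---
title: "Disproportionality screening for drug-induced QT prolongation and torsade de pointes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening for drug-induced QT prolongation and torsade de pointes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersqt)
```

## The problem and the model

Spontaneous-reporting databases such as FAERS collect post-marketing
adverse-event reports in which reporters name the reactions (coded as
MedDRA preferred terms, PTs) and the drugs involved, marking one or more
drugs as *primary suspect*. Disproportionality analysis asks whether a
drug is named as suspect in reports of an event of interest more often
than would be expected from its share among all other reports. It
estimates reporting association, not incidence or causation: there is no
exposure denominator, reporting is voluntary, and stimulated-reporting
dynamics can distort drug-level counts.

`faersqt` implements this screen for QT-interval prolongation and torsade
de pointes (TdP). Case reports are identified with the narrow scope of the
standardized MedDRA query (SMQ) "Torsade de pointes/QT prolongation"
(`qt_smq()`), six PTs chosen to leave essentially no doubt about the
condition: electrocardiogram QT prolonged, ventricular tachycardia,
torsade de pointes, long QT syndrome, electrocardiogram QT interval
abnormal, and long QT syndrome congenital. Matching is by PT name,
case-insensitive and whitespace-collapsed, because openFDA reaction
entries carry names rather than numeric codes; the MedDRA codes are
retained for provenance.

For a drug $x$ and an event scope $s$ (one PT, or the SMQ = the union of
the six), unique reports are cross-classified into the two-by-two table
with cells $a$ (suspect $x$, event $s$), $b$ (other reports with event
$s$), $c$ (suspect $x$, other events) and $d$ (the remainder). The
reporting odds ratio and its Woolf-type confidence interval are

$$\mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95\%} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\Big).$$

A signal is **positive** iff $a \ge 3$ and the lower CI limit exceeds 1
*strictly*; everything else — too few cases, an interval reaching 1, or an
undefined interval — is negative. Each curated drug is screened in all
seven scopes, and the per-drug count of positive signals (0–7) is the
integrated risk summary.

## Pipeline stages and the decisions behind them

**Parsing and deduplication.** Records arrive as newline-delimited JSON or
a JSON array (auto-detected), in the openFDA drug-event field layout.
Malformed records (no safety-report ID, no reaction list) are skipped and
logged rather than fatal; unknown fields are ignored; unmapped enumeration
values become `"unknown"`, since the characteristics summaries must
tolerate real-world sloppiness. FAERS follow-up versions share the safety
report ID, so deduplication keys on the report ID alone and keeps the
version with the latest receipt date (ties: last in stream order). The
receipt date also anchors the study window; the source offers several date
fields and no canonical choice, so this is a documented package decision,
configurable only through which field the parser maps.

**Curation cascade.** Drug mentions of target reports pass, in order:
(1) non-primary-suspect mentions are dropped (characterization ≠ 1);
(2) suspect mentions with no generic name are dropped; (3) names are
case-folded and trimmed, ambiguous names (per the user-supplied synonym
table) are excluded, synonym variants are merged onto their canonical
ingredient; (4) repeats of the same canonical ingredient *within one
report* collapse to a single mention, each surplus tallied as a duplicate.
Duplicate collapsing is defined on canonical names and therefore must run
after synonym merging — the one place where the ledger's field order does
not match the execution order. "Duplicate" is read as within-report
repetition because every downstream count is a per-report count; an
across-corpus reading would conflate it with ordinary repeated reporting.
The `CurationLedger` makes the cascade auditable and closes the
conservation identity: total mentions = non-primary + missing-name +
ambiguous + duplicates + surviving mentions.

**Comparator population.** The default denominator is every unique report
in the supplied dataset, the natural analogue of comparing against "cases
with other reported AEs" database-wide; a targets-only comparator is
available as a config option (`denominator = "targets-only"`) for
within-case-series contrasts. Exposure means *surviving primary suspect*:
concomitant co-medication counts as unexposed.

**Zero cells.** The Woolf interval is undefined with an empty cell, so the
Haldane–Anscombe correction adds 0.5 to all four cells, flagged via
`corrected`; the uncorrected $a$ still governs the three-case rule. This
keeps every drug scorable and is standard pharmacovigilance practice. The
correction can be disabled (`correct = FALSE`), in which case zero-cell
tables yield `NA` estimates and classify negative.

**No multiplicity adjustment.** The screen reports all 7·(number of
drugs) raw classifications without multiple-testing correction, as is
conventional for hypothesis-generating disproportionality screens; with
many drugs a few marginal positive signals are expected by chance, which
the synthetic null experiments below make visible.

**Rounding.** All printed percentages round half-up (`round_half_up()`),
fixed by the tabulated convention in this literature where 43.75% prints
as 43.8% — base R's round-half-to-even would print 43.7%. Tabular
surfaces carry one decimal, ranked reporting-proportion surfaces two; both
are configurable per call and in the pipeline config.

**Ranked tables.** Top-N reporting proportions use target-report counts
within each scope as denominators (proportions of reports, multi-counting
classes when a report carries drugs of several ATC classes). Entries tied
with the rank-N boundary count are retained and annotated instead of
silently truncated.

## The synthetic-data generator

`simulate_faers()` emits the same record dialect the parser reads, with
known ground truth. Per report it samples: independent drug exposures
from the catalogue's marginal probabilities; each narrow PT as a Bernoulli
draw whose odds are the PT's baseline odds times the product of the
planted multipliers $\rho_{d,\mathrm{pt}}$ over *exposed* drugs; one
exposed drug as primary suspect, uniformly (all of them under
`multi_suspect`), the rest concomitant/interacting; filler non-target
reactions; demographics, outcomes and receipt dates. Curation noise is
injected at configurable rates — missing generic names, ambiguous aliases,
synonym variants, within-report duplicate mentions, follow-up re-issues —
and every injection is tallied at generation time, so the curation ledger
can be compared with ground truth *exactly*, not statistically.

Default conditions are what a practitioner would call a plausible
spontaneous-reporting corpus for this event family: per-drug exposure
probabilities of 1.5–4%, per-PT baseline odds of 0.0005–0.006 (rare
events, with ECG QT prolonged the most common PT and congenital long QT
syndrome the rarest), 5% missing generic names, 3% ambiguous aliases (for
drugs that have one), 50% synonym-variant usage (for drugs with a
variant), 3% duplicate mentions, 2% follow-ups, and demographic mixes
resembling published report-characteristics panels (≈54% female, age
centred in the 60s, hospitalization the dominant outcome). One
pseudo-random stream is fully determined by the seed; replicate
experiments derive child seeds as base + replicate index.

Because the planted association acts multiplicatively on the odds scale
through all exposed drugs, the large-sample ROR for a planted pair equals
$\rho$ only in the rare-event, low-co-exposure limit. Two small
systematic deviations remain at the defaults: a drug exposed but not
chosen as suspect contributes its elevated event odds to the comparator,
and curation noise moves a random share of suspect reports into the
comparator — together an attenuation of a few percent at $\rho = 8$. The
analytic oracle `expected_contingency()` (exact enumeration over the
$2^D$ exposure patterns, including suspect assignment and name-noise
survival) quantifies exactly this: the empirical pipeline cells are tested
against it, and the coverage experiment shows the 95% CI still covers the
planted value at its nominal rate under these conditions. Exposures are
sampled independently across drugs, so there is no exposure-correlation
confounding unless a user builds it into a custom catalogue.

What the generator deliberately does *not* emulate: real FAERS marginal
drug frequencies, secular reporting trends (Weber effect, notoriety bias),
correlated co-prescription, indication channelling, and free-text name
misspellings beyond the synonym table. Passing tests therefore validate
the *mechanics* of identification, curation, estimation and integration —
not robustness to those real-world biases, which no synthetic null can
confer.

## Verification at a glance

The test suite checks, among others: exact hand-enumerated curation
cascades; an independent brute-force re-evaluation of the ROR formula on
10,000 random tables (agreement to 1e-12 relative error); the exact
antisymmetry (column swap inverts the ROR and mirrors the CI) and
CI-width scaling ($\sqrt{1/k}$ under cell scaling by $k$) identities; the
classification truth table including both boundaries ($a = 2$ with a large
ROR, and a lower limit of exactly 1, are negative); empirical-versus-
analytic cell convergence at $n = 10^5$; exact ledger-versus-ground-truth
equality under all noise channels; and a planted-signal recovery
experiment — $\rho = 8$ on one (drug, PT) pair, $n = 50{,}000$ reports,
200 replicates — in which the 95% CI covers the planted value at its
nominal rate, the pair classifies positive in essentially every
replicate, and null pairs stay within the expected false-positive band.
Smaller corpora (500–20,000 reports) exercise the end-to-end pipeline,
its determinism, and its failure modes (empty target set aborts with a
stage-attributed error).

## Known limitations

* ROR is the only estimator; PRR, IC/BCPNN and EBGM are out of scope.
* Signals are statistical reporting associations; they carry no exposure
  denominator and no causal interpretation.
* Deduplication is exact on the safety-report ID; probabilistic record
  linkage across distinct IDs is not attempted.
* The synonym and ATC tables are user-supplied; the package ships no
  licensed dictionary and no automated RxNorm/ATC lookup.
* Query construction for the openFDA API is provided for documentation
  and reproducibility; there is no HTTP client.
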