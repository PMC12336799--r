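---
title: "Harmonizing OAR structure names: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing OAR structure names: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnomen)
library(dplyr)
```

rtnomen standardizes clinical radiotherapy structure names to the AAPM
TG-263 nomenclature and quantifies how much an automated renaming can be
trusted. This vignette explains the underlying models and procedures, the
parameters that matter, what the synthetic benchmark does and does not
show, and the design decisions taken where more than one reasonable choice
existed.

## The vocabulary model

TG-263 is a *closed* vocabulary: a prediction is right only if it is the
exact standard spelling. The lexicon therefore models each standard name as
a decomposition into

* an **organ concept** (`concept_id`) shared by all variants of one
  organ-at-risk — `Kidney_L`, `Kidney_R` and `Kidneys` all carry the
  concept `kidney`;
* a **laterality** (left / right / bilateral / none), carried by `_L`/`_R`
  suffixes in the standard spelling;
* an optional **spatial qualifier** token (`Cerv`, `Thor`, `Prox`, ...)
  for regional substructures such as `SpinalCord_Cerv`;
* a **plurality** (singular / plural) distinguishing `Kidney_L` from
  `Kidneys`;
* multilingual **synonyms** tagged by language (`en`, `de`, `nl`), which
  include common clinical abbreviations.

Synonyms are data, not code: the bundled lexicon
(`inst/extdata/tg263_lexicon.tsv`, 101 entries) is a curated subset — the
complete TG-263 list is an external copyrighted document — and new
languages or entries are added by editing the file. Loading validates three
invariants: unique standard names, each normalized synonym mapped to
exactly one concept, and left/right siblings of a concept differing only in
the laterality token.

Name *resolution* (`parse_name()`, `same_concept()`) proceeds in three
stages: exact standard-name match; whole-string synonym match after
normalization (lowercase, punctuation and underscores to spaces, digits
dropped); and marker stripping, where laterality tokens (`l`, `li`,
`links`, `rechts`, `bds`, ...), qualifier aliases (`cervical`,
`thorakal`, `prox`, ...) and bilateral/plural markers are removed and the
residue is matched against the synonym table. Components reported for a
name come from the name's own markers plus the matched synonym's
attributes — not from the best-matching lexicon entry — so that `"Kidney"`
parses as singular even though the closest entries are `Kidney_L/R` and
`Kidneys`. This distinction is what makes plurality and laterality errors
detectable downstream.

## The renaming backends

Backends implement one contract: a name in, a prediction out (predicted
standard name or the no-match sentinel, a low/medium/high confidence, and
the verbatim raw reply). At `temperature = 0` a backend must be
deterministic; at `temperature > 0` it samples among its top candidates
restricted to the `top_p` nucleus mass.

The bundled **mock backend** is a deterministic multilingual fuzzy matcher:
normalize → detect markers → translate the residue through the synonym
table → if no exact synonym hits, rank concepts by normalized edit-distance
similarity → compose the detected laterality/qualifier/plurality into the
concept's matching entry. Its tunables:

* `threshold` (default **0.72**, dimensionless similarity in [0, 1]): the
  cutoff below which the answer is "no match". The default was chosen once
  so that all clean synthetic spellings (exact synonyms and standard names,
  similarity 1) pass and random strings (similarity typically < 0.5) fail,
  with a margin for one-to-two-character typos.
* `fuzzy_margin` (default 0.1): scores within this band above the threshold
  report `low` confidence; clear fuzzy hits report `medium`; exact hits
  `high`.

The **remote backend** speaks the common chat-completion protocol,
forwarding `temperature` and `top_p` verbatim and parsing the reply with
the same grammar. Transport failures are retried a bounded number of times
and then recorded per item — a batch run never aborts. The **simulated
backend** is a programmable test double: per item it errs with a configured
probability, constructs its wrong answer to belong to a requested error
category using the lexicon structure, and in sampling mode deviates from
its modal answer with a configured variability rate. The configuration
carries *two* variability rates (wrong items, correct items) because the
canonical uncertainty experiment needs wrong answers to fluctuate while
correct answers stay stable; a single shared rate is the special case of
setting both equal.

Prompt construction mirrors the five-part design that works well for
few-shot renaming: (1) task instructions, (2) language and abbreviation
rules including the instruction to answer "no match" when nothing fits,
(3) output-format and confidence rules, (4) few-shot input/output examples,
and (5) the full TG-263 list together with exactly one input name per
prompt. Wording lives in a replaceable template file because prompt
engineering is configuration, not code. The reply grammar
(`name: <x> | confidence: <low|medium|high>`) is imposed on all backends;
the parser takes the *last* well-formed block so reasoning models may emit
arbitrary chain-of-thought before the answer, and unparseable replies
become a data state (`parse_ok = FALSE`, confidence `missing`), never an
exception.

## Accuracy and the error taxonomy

Two accuracies are reported. **Unique accuracy** is the fraction of
distinct raw names renamed correctly — correctness being exact,
case-sensitive string equality after whitespace trimming, with the no-match
sentinel equal only to itself. **Overall accuracy** weights each unique
name by its multiplicity in the full corpus; a single frequent name renamed
wrongly can therefore depress overall accuracy far below unique accuracy,
which is exactly the phenomenon the two-metric design is meant to surface.
Case sensitivity is an interpretation (one could argue for
case-insensitive matching), but TG-263 prescribes exact capitalization and
a reordered-but-correctly-capitalized prediction is still not the standard
spelling; the choice is applied consistently across scoring,
deduplication, and label counting.

Misassignments are classified by a deterministic cascade, first match wins:

1. equality → `NONE`;
2. prediction is the sentinel → `NO_MATCH`;
3. same concept, laterality or spatial qualifier differs →
   `LATERALITY_OR_LOCALITY`;
4. same concept, plurality differs → `PLURALITY`;
5. same concept via synonym resolution, not the exact spelling →
   `MISSPELLING`;
6. otherwise → `WRONG_OAR`.

Left/right and regional designations (cervical, superior, ...) share one
category because clinically they are the same failure mode — the right
organ with the wrong spatial designation. The precedence (locality before
plurality before misspelling) resolves borderline cases that differ in
several respects at once; it was fixed once, so the classifier is a total
function. Automating this classification — historically a manual task — is
a deliberate design choice for reproducibility; the cascade's five worked
examples are pinned in the test suite:

```{r taxonomy}
lex <- load_lexicon()
classify_error(
  c("SpinalCord", "Kidney", "Pharynx", no_match(), "Lacrimal_Gland_L"),
  c("SpinalCord_Cerv", "Kidneys", "Musc_Constrict", "Sphincter_Anal", "Glnd_Lacrimal_L"),
  lex
)
```

## Uncertainty estimation

Two complementary error-flagging signals are computed.

**Self-reported confidence.** The low/medium/high rating requested in the
prompt is coded low-or-medium = 1, high = 0 and correlated with the error
indicator (wrong = 1) via the phi coefficient — the Pearson correlation of
two binary variables, `(ad − bc) / √((a+b)(c+d)(a+c)(b+d))` on the 2×2
table. Degenerate margins (e.g. constant confidence) make phi undefined;
the result is then a flagged not-a-value rather than 0, so "undefined"
can never be read as "no association". Missing confidence (unparseable
replies) is conservatively coded as low: an unreadable answer should be
flagged for review.

**Monte-Carlo label entropy.** Each name is renamed `k` times (default
k = 10) in sampling mode (temperature 1, top-p 0.95). With `p_i` the
relative frequency of the i-th distinct predicted label, the Shannon
entropy is `H = −Σ p_i ln p_i`. The natural logarithm is used and recorded
in the output metadata; the base only rescales `H`, and the detector flag
`H > 0` is base-invariant, so all classifier metrics are unaffected by this
choice. The flag itself is implemented exactly as "at least two distinct
trimmed labels" — no floating-point tolerance, since `H > 0 ⇔ n ≥ 2`.
Entropy as a binary error detector is then scored on a cohort with known
correctness: condition positive = the deterministic (temperature 0)
prediction is wrong; test positive = `H > 0`; sensitivity, specificity and
phi follow the standard confusion-matrix definitions. Two readings were
possible for the reference run (the deterministic prediction vs. the
majority sampled label); the deterministic prediction is used, because
that is the prediction a clinical pipeline would actually act on.
Items with failed samples are excluded from the metrics and counted, never
imputed.

## The synthetic benchmark

The generator emulates the statistical structure of a pooled multi-center
corpus: TG-263 ground truths corrupted into center-specific spellings in
English, German and Dutch, expanded with a heavy-tailed duplicate
distribution so that the full corpus is an order of magnitude larger than
its unique-name view. Defaults, chosen once as a realistic profile:

* language mix 30 % English / 35 % German / 35 % Dutch, with centers
  assigned consistently (German names from center C, Dutch from A/B);
* operator rates: no-op 0.20, translate 0.30, abbreviate 0.15,
  laterality-notation change 0.10, plurality change 0.05, misspell 0.10
  (1–2 random character edits), case/separator change 0.10;
* duplicate multiplicity from a truncated discrete power law
  `P(m) ∝ m^-2.2`, capped at 200 — a few names dominate the corpus, most
  appear once, which is what makes unique and overall accuracy genuinely
  different quantities.

The corruption operators are intentionally the inverse of the mock
backend's normalization steps: operators the mock can invert (translation,
marker abbreviation) leave accuracy near 1, operators it cannot always
invert (aggressive truncation, multi-edit misspellings) pull it down, so
benchmark difficulty is tunable through the operator mix. Every record
stores its ground truth and realized operator, giving exact references for
all downstream metrics.

What passing on synthetic corpora does *not* show: real center-specific
abbreviation inventories are richer than the bundled tables, real
misspellings are not uniform character edits, ground-truth labels in real
corpora carry annotator disagreement, and a real LLM backend has failure
modes (hallucinated names, format drift) that the mock cannot exhibit.
Synthetic results validate the *pipeline and metrics*, not any claim about
LLM renaming quality.

## Numerical and degenerate-input choices

* Deduplication keys on the trimmed raw name, case-sensitively by default
  ("Herz" and "HERZ" may be meaningfully different center conventions); a
  switch merges case variants.
* Candidate ties in the mock backend break deterministically in lexicon
  order; entry selection within a concept prefers laterality, then
  qualifier, then plurality agreement with the detected markers.
* Empty inputs: empty batches produce empty outputs; empty record sets for
  summary statistics raise errors rather than returning NaN; the empty
  label list is invalid for entropy.
* All randomness flows through per-run seeds (`withr::with_seed`); no
  global RNG state is mutated, and two identically-seeded end-to-end runs
  produce byte-identical report files (no timestamps are embedded).
* Exclusion filtering tags every excluded record with the first matching
  rule, so the manual-curation step it replaces remains auditable.

The verification suite sizes its experiments to run in minutes on one CPU:
error-rate recovery uses n = 2000 simulated items per error rate (three
binomial standard errors of discrimination), the entropy experiment uses
the canonical 15 correct + 15 incorrect cohort at k = 10, and oracle
equivalence checks (entropy against direct evaluation of the formula, phi
against Pearson on expanded vectors) use 1000 random instances at 1e-12
tolerance.

## Known limitations

* The bundled lexicon is a 101-entry subset; names outside it resolve to
  "no match" even when a full TG-263 entry exists. Supply the complete
  list via `load_lexicon()` for production use.
* DICOM reading supports the two little-endian uncompressed transfer
  syntaxes and reads name metadata only; there is no write-back of renamed
  structures into DICOM.
* Target volumes and planning structures are out of scope by design — they
  are excluded by the ingest filter, not renamed.
* The mock backend is a terminology matcher, not a language model; it
  cannot resolve names requiring clinical context (e.g. bare "CervMyelum"
  without separators is beyond its tokenizer).
* Region (head-and-neck / thorax / abdomen) breakdowns require an explicit
  `region` column; anatomical region is never inferred from names.
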