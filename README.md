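# rtnomen

Harmonizing radiotherapy organ-at-risk (OAR) structure names to the AAPM
TG-263 nomenclature.

Radiotherapy structure sets accumulate center-specific, multilingual names
("Niere li", "Traenendruese re.", "myelum", "CervMyelum") for the same
anatomical structures. rtnomen is for medical physicists and radiation
oncology data engineers who need to map such names onto the closed TG-263
vocabulary (`Kidney_L`, `Glnd_Lacrimal_R`, `SpinalCord`, ...) at scale, and —
just as importantly — need to know *when not to trust* an automated mapping.

The package provides the full pipeline:

- **ingest** — extract ROI names from DICOM RT Structure Set files (name
  metadata only, never contour geometry) or tabular exports; exclude target
  volumes (PTV/CTV/GTV/...) and auxiliary planning structures via a
  transparent, tag-audited rule set; deduplicate into the unique-name view
  with conserved multiplicities.
- **harmonize** — build the five-part renaming prompt (task instructions;
  language/abbreviation rules incl. the "no match" rule; output-format and
  confidence rules; few-shot examples; the TG-263 name list plus one input
  name) and dispatch it to a pluggable backend. A deterministic multilingual
  fuzzy-matching backend (`backend_mock()`) is bundled; chat-completion HTTP
  endpoints are supported (`backend_remote()`). Replies are parsed by a
  strict grammar that tolerates chain-of-thought preambles.
- **evaluate** — *unique accuracy* (fraction of distinct raw names renamed
  correctly, exact case-sensitive match) and *overall accuracy*
  (multiplicity-weighted over all name instances), per center and region,
  plus an automated five-category error taxonomy: wrong OAR,
  laterality/locality, plurality, misspelling, no match.
- **uncertainty** — the phi (binary Pearson) correlation between
  self-reported confidence and errors, and Monte-Carlo label-entropy
  estimation: k repeated stochastic inferences (temperature 1, top-p 0.95),
  Shannon entropy `H(p) = -Σᵢ pᵢ ln pᵢ` over the distinct predicted labels,
  and `H > 0` as a binary error detector with sensitivity/specificity/phi.
- **synthetic** — a seeded generator of labeled multilingual corpora
  (translation, abbreviation, laterality-notation, plurality, misspelling
  and case/separator corruptions with a heavy-tailed duplicate distribution)
  and a programmable simulated backend, so the whole stack is testable
  without clinical data.

A curated TG-263 subset (101 entries with English/German/Dutch synonyms)
ships with the package; the documented tabular format lets you drop in the
complete TG-263 list.

## Worked example

```r
library(rtnomen)
library(dplyr)

lex     <- load_lexicon()          # bundled TG-263 subset
backend <- backend_mock(lex)       # deterministic multilingual backend

raw <- tibble::tibble(
  raw_name     = c("Niere li", "Niere li", "Traenendruese re.", "myelum",
                   "Hart", "Hart", "Hart", "PTV56", "Couch"),
  center_id    = c("C", "C", "C", "A", "B", "B", "B", "C", "A"),
  ground_truth = c("Kidney_L", "Kidney_L", "Glnd_Lacrimal_R", "SpinalCord",
                   "Heart", "Heart", "Heart", NA, NA)
)

parts <- filter_structures(raw)    # drops PTV56 (target) and Couch (aux)
uniq  <- deduplicate(parts$kept)
uniq
#> # A tibble: 4 × 4
#>   raw_name          multiplicity source_centers ground_truth
#>   <chr>                    <int> <chr>          <chr>
#> 1 Hart                         3 B              Heart
#> 2 Niere li                     2 C              Kidney_L
#> 3 Traenendruese re.            1 C              Glnd_Lacrimal_R
#> 4 myelum                       1 A              SpinalCord

pred <- rename_batch(uniq, backend)
pred %>% select(raw_name, predicted_name, confidence)
#> # A tibble: 4 × 3
#>   raw_name          predicted_name  confidence
#>   <chr>             <chr>           <chr>
#> 1 Hart              Heart           high
#> 2 Niere li          Kidney_L        high
#> 3 Traenendruese re. Glnd_Lacrimal_R high
#> 4 myelum            SpinalCord      high

scored <- score_predictions(
  pred %>% left_join(uniq %>% select(raw_name, ground_truth, multiplicity),
                     by = "raw_name"),
  lex
)
accuracy_report(scored)
#> <accuracy_report>
#>   unique accuracy:  1.0000  (4 distinct names)
#>   overall accuracy: 1.0000  (7 name instances)
```

The Dutch "Hart" (3 occurrences), the German abbreviated "Niere li" and
"Traenendruese re.", and the Latin-derived "myelum" are all resolved to their
TG-263 spellings; unique accuracy counts each distinct name once, overall
accuracy weights "Hart" three times. Wrong predictions would be broken down
by `classify_error()` into the five categories, and
`uncertainty_profile()` / `entropy_error_metrics()` quantify which
predictions a stochastic backend is unstable about.

A command-line front end wrapping the same functions lives at
`inst/cli/rtnomen.R` (subcommands `extract`, `rename`, `evaluate`,
`uncertainty`, `simulate`).

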