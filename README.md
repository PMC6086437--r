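# ffascreen

Screening and ranking of microbial strains — originally cyanobacteria — for
their potential as free-fatty-acid (FFA) producing cell factories, based on
the makeup of their predicted proteomes.

Experimentally evaluating strains as chassis candidates for FFA production
is slow and done one strain at a time. `ffascreen` screens whole cohorts in
silico instead: a curated panel of criterion proteins with **positive**,
**negative** or **required** impact on FFA production, organized into
orthologous groups (OGs), is matched against each proteome; the resulting
presence/absence features are scored, normalized, ranked and categorized.

## The method

1. **Feature generation.** Homology evidence (BLAST tabular, outfmt 6) and
   domain evidence (HMMER domtblout) are combined under a stringent
   *domain-completeness* rule: a hit counts only if its e-value passes the
   threshold (default 1e-5) **and** the subject protein carries *every*
   domain family of the query criterion protein. Retained hits become a
   per-strain profile: hit counts, presence, and OG satisfaction (a group is
   satisfied when any member is present — so a backup enzyme catalyzing the
   same step, e.g. EC 2.7.9.1 for EC 2.7.9.2, counts).
2. **Scoring.** The raw score is the signed weighted sum
   *s* = Σ<sub>c</sub> *w*<sub>c</sub> *x*<sub>c</sub> with
   *w*<sub>c</sub> > 0 for positive/required criteria and *w*<sub>c</sub> < 0
   for negative ones (unit magnitudes by default). Raw scores are min-max
   normalized to [0, 1] over the cohort, ranked descending, and categorized:
   **Top-ranked** (strictly above the upper reference strain), **Positive**
   (above the lower boundary strain), **Negative** (the rest). The lower
   boundary is the lowest-scoring strain of the K-means (k = 2, solved
   exactly in 1-D) cluster containing the positive reference strains.

Weights can be calibrated against reference strains with
`calibrate_weights()` (maximum normalized margin between positive and
negative references), and each screened strain gets engineering
recommendations: insert/overexpress missing positive or required proteins,
delete/underexpress present negative ones. A dependency-free Smith–Waterman
fallback aligner (`internal_search()`) makes the whole pipeline runnable
without external search binaries, and a synthetic-data generator
(`make_panel()`, `make_proteome()`, `make_cohort()`) produces panels,
proteomes, evidence files and cohorts with known ground truth.

See `vignette("ffa-screening")` for the model, parameter meanings and
design decisions.

## Worked example

Rank a synthetic 140-strain cohort and screen a new candidate strain:

```r
library(ffascreen)

panel <- make_panel(seed = 1)   # synthetic stand-in for a curated panel
panel
#> ffa_panel: 64 criteria (40 positive, 12 negative, 12 required), 64 OGs (12 required), 64 sequences

cohort  <- make_cohort(panel, cohort_spec(seed = 1))  # 140 strains + 4 references
ranking <- score_cohort(cohort$profiles, panel, refs = cohort$ref_config)
head(as.data.frame(ranking), 5)
#>   strain_id raw_score normalized_score rank category
#> 1   REFPOS1        51        1.0000000    1 Positive
#> 2   REFPOS2        49        0.9661017    2 Positive
#> 3    SYN042        35        0.7288136    3 Positive
#> 4    SYN122        35        0.7288136    4 Positive
#> 5    SYN037        33        0.6949153    5 Positive
table(ranking$category)
#> Top-ranked   Positive   Negative
#>          0         52         92
```

Every strain gets exactly one category; nothing is Top-ranked here because
the best strain *is* the upper reference. The normalized score of the
rank-1 strain is 1 by construction of the min-max scale. Now screen a new
proteome carrying every positive and required criterion (and no negative
one), using the internal fallback aligner for homology evidence:

```r
ids <- panel$criteria$criterion_id[panel$criteria$impact != "negative"]
new_strain <- make_proteome(panel, ids, cohort_spec(n_strains = 1, seed = 2),
                            strain_id = "CANDIDATE")
hits     <- internal_search(panel, new_strain$proteome)
filtered <- filter_domain_complete(hits,
                                   criterion_domains(panel),
                                   parse_domtblout(new_strain$domtbl))
profile  <- build_profile("CANDIDATE", filtered, panel)
profile
#> strain_profile 'CANDIDATE': 52/64 criteria present, 52/64 OGs satisfied


res <- evaluate_new_strain(profile, attr(ranking, "raw_scores"),
                           unit_weights(panel), cohort$ref_config,
                           panel = panel)
res
#> ffa_evaluation 'CANDIDATE': score 1.0000, category Top-ranked, rank 1/145, 0 recommendation(s)
```

The candidate dominates the cohort — all 12 required OGs satisfied, no
negative-impact protein present — so it takes rank 1, normalized score 1,
category Top-ranked, and the recommendation list is empty (nothing to
insert or delete). A strain with gaps instead receives one
insert/overexpress suggestion per missing positive criterion and per
unsatisfied required OG, and one delete/underexpress suggestion per present
negative criterion.

File-based workflows (`run_simulate()`, `run_rank()`, `run_screen()`) read
and write panel TSV/FASTA, per-strain FASTA + BLAST tabular + domtblout,
cohort CSVs and JSON strain reports; `inst/cli/ffascreen.R` exposes them as
a command-line script with `screen`, `rank` and `simulate` subcommands.

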