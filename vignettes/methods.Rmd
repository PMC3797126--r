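---
title: "Tracking sentence provenance across database releases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking sentence provenance across database releases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoprov)
```

## The model

`annoprov` treats the free-text annotation of a versioned protein
database as a corpus of *sentences* observed at discrete *releases*.
Three modelling commitments shape everything else:

1. **The sentence is the unit of propagation.** Curators copy
   annotation between entries at roughly sentence granularity, so two
   entries sharing a normalised sentence are treated as evidence of
   propagation (or, rarely, coincidence — the classification protocol's
   second question exists precisely to separate the two). Sentences are
   compared case-insensitively: only the normalised form (lower-cased,
   whitespace-collapsed) is stored, and the original casing is
   discarded.

2. **An entry is its accession lineage.** Entries merge: one primary
   accession absorbs others as secondaries. The index therefore groups
   accessions into *lineages* — connected components of the
   shared-accession graph across all releases — and every statistic and
   detector operates on lineages. Without this, a merge would read as a
   simultaneous removal and insertion and corrupt every pattern.

3. **Absence requires an observation opportunity.** Early Swiss-Prot
   and TrEMBL release calendars were unsynchronised. A sentence is only
   "absent" from a database at a release that database actually
   published; dates at which only the other database released
   contribute no evidence. This is what keeps the *striping* artefact
   of interleaved calendars out of the transient and reappearing
   detectors, and it is why the release calendar is an explicit,
   validated input (`release_calendar()`) rather than something
   inferred from file names.

## Extraction pipeline

Flat-file records are parsed for identity (ID/AC lines) and comment
payload (CC lines). Cleaning removes, in order: the copyright/licence
block (any run of lines bounded by dashed rules containing a marker
phrase — the exact block text changed across eras, so the markers are
configurable); topic headings (`-!- LABEL:` with an upper-case label);
and property *keys* (`Key=` tokens whose `=` immediately follows the
key). Property values are retained: interaction lines such as
`Self; NbExp=2; IntAct=EBI-311928, ...` clean to
`self; 2; ebi-311928, ...`, keeping the evidence counts and identifiers
as sentence text. Equations are untouched because their `=` is
space-separated.

Segmentation is deliberately block-aware. Within a topic block a
sentence ends at a full stop followed by whitespace or end of text,
except after a known abbreviation (`e.g.`, `approx.`, `et al.`, single
initials, ...; the lexicon is a configurable argument because no
published rule list exists for the historical corpus) — decimal points
never split because no whitespace follows them. A block's trailing
fragment with no terminal stop *is* a sentence: topic blocks and list
items are frequently unterminated, and block boundaries are the only
reliable signal that such a fragment has ended. Treating the block
boundary as a sentence boundary is therefore part of the segmentation
definition, not a convenience; `extract_comment_text()` still exposes
the joined cleaned text for inspection.

Exact sentence counts on pathological inputs (nested semicolon lists,
interaction line groups) depend on the abbreviation lexicon and cannot
be made bit-identical to any particular historical tool; the tests pin
the behaviour of this implementation instead.

## Pattern definitions and their edge cases

All four detectors are pure set computations over the occurrence
triples; each has a brute-force re-implementation in the test suite
that enumerates its definition directly, and the two are required to
agree exactly on seeded corpora.

* *Missing origin.* Origin set = lineages at the earliest occurrence
  date; terminal set = lineages at the latest. The hit requires an
  empty intersection **and** a non-origin lineage retaining the
  sentence at a release strictly after every origin lineage lost it
  (the retention clause is what makes "the copy outlived its origin"
  literal). Historical and still-present sentences are flagged
  identically, distinguished by an `extant` marker, because both carry
  quality signal. Multi-lineage origins are allowed: at major-release
  granularity a sentence can genuinely first appear in several entries
  at once.

* *Reappearing entry.* Present/absent/present for one lineage at three
  existing releases of one database. The gap must be a real release.

* *Transient.* A (lineage, database) appearance confined to one release
  with an existing successor release. Appearances only at a database's
  newest release are never flagged — the removal has not had a chance
  to happen.

* *TrEMBL origin.* All earliest-dated occurrences in TrEMBL and a later
  Swiss-Prot occurrence. A first appearance in both halves of a
  synchronised pair is ambiguous and deliberately not flagged.

One hit is recorded per (sentence, pattern); the evidence column lists
every supporting (lineage, release) pair. This matches the reporting
convention of counting *sentences*, not events.

## The classification protocol

Only the first question (how many entries has the sentence ever reached
— counted as lineages over the whole history) and the tree logic are
automated; questions 2–4 require reading the entries' historical
context and are read from an answers table. Parameters, with defaults:

| parameter            | default | meaning                                         |
|----------------------|---------|-------------------------------------------------|
| `too_many_threshold` | 100     | entry count above which analysis is infeasible  |
| `min_len`            | 20      | characters; sampling keeps strictly longer ones |
| `step`               | 100     | sampling period in length-sorted rank           |

The tree consults Q2 → Q3 → Q4 in order; `NO` at Q2 or Q3 yields
*accurate*, Q4 separates *erroneous* (`YES`) from *inconsistent*
(`NO`), and an `UNSURE` at any consulted question yields *possibly
erroneous* — the class exists exactly for "not enough evidence", so any
uncertainty short-circuits to it. Length-stratified sampling sorts by
(length, text) — the text tie-break makes the subsample invariant to
input order — and selects ranks `step, 2·step, ...`, i.e. it starts at
rank `step`, which is what "every hundredth sentence" yields for a
population of a few thousand.

Report arithmetic rounds **half away from zero** (`round_half_up()`):
percentages to one decimal, extrapolations
`count / n_analysed × base_total` to the nearest integer. Base R's
banker's rounding differs on exact halves, which extrapolation bases in
the thousands do hit.

## The synthetic corpus generator

The generator exists so that every stage — parsing, segmentation,
lineage resolution, statistics, detection — can be verified against
ground truth that is correct *by construction*. Its default
configuration describes the study conditions the package is designed
for: a release calendar spanning the three naming eras (six
unsynchronised early releases, then synchronised major and monthly
pairs sharing dates, both databases closing on the same final date); 25
background entries per database; a sentence pool exercising the risky
segmentation cases (abbreviations, decimals, unterminated topic blocks,
property-bearing interaction lines); a per-release copy probability of
0.15 to mimic rising reuse; two entry merges; unannotated-entry
probabilities of 0.1 (Swiss-Prot) and 0.5 (TrEMBL), reflecting the
reviewed section's much denser annotation; and a handful of planted
instances of each pattern.

Background annotation is constructed to be pattern-free — background
sentences persist from acquisition to the end of their database, never
cross databases, and survive merges because the absorbing entry adopts
them — so the planted labels are exhaustive, and detector output can be
required to equal the manifest *exactly* (precision and recall 1), not
merely to include it. Feasibility of the planted counts is validated
against the calendar up front (a transient needs a successor release; a
TrEMBL origin needs a later Swiss-Prot release and a shared final
date), and violations are configuration errors naming the constraint.

What the generator does **not** emulate: real annotation text and its
edit distance structure (sentences are copied verbatim or not at all,
never mutated); sequence data; the size and growth curves of the real
archives; and cross-database propagation beyond the planted
TrEMBL-to-Swiss-Prot route. A green test suite therefore demonstrates
correctness of the set-operation machinery on corpora whose structure
matches the real archives, not fidelity to the real archives' content —
full-archive figures require downloading the historical releases, which
is a documented user step.

Test and acceptance problem sizes — twenty seeded corpora of about
forty entries over six release events, plus a fourteen-row default
calendar — were chosen as the smallest sizes at which every pattern,
era structure and merge interaction is exercised simultaneously.

## Numerical and degenerate-input choices

* Empty corpus, empty release, unknown release: counts are zeros,
  averages are `NA` (absent values, not zeros), unknown identifiers are
  errors.
* An accession claimed by two entries within one release is a hard
  error naming both claimants — it would make lineage resolution
  ambiguous.
* Whitespace-only input to `normalize_sentence()` is an error by
  design: it can only arise from a segmentation bug upstream.
* Chart specifications serialise canonically (stable ordering, fixed
  digit handling), so identical inputs give byte-identical JSON; X
  categories order by first-appearance date with a lexicographic
  tie-break; charts with more than 100 lineages keep the first 100 and
  record the overflow count rather than degrading silently.
* The generator restores the caller's RNG state, and the same seed
  yields byte-identical files and manifest.

## Known limitations

Provenance is *inferred*: the first observed occurrence at
major-release granularity is taken as the origin, so sentences that
originated outside the corpus or within unarchived minor releases are
attributed to their first archived appearance. Verbatim matching cannot
follow a sentence through rewording (sentence evolution would need
similarity matching, which is out of scope). Classification questions
2–4 remain expert judgements; the package guarantees only that the same
answers always produce the same class.
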