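---
title: "Constrained decoding for pathology code series: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained decoding for pathology code series: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathocode)
```

## The annotation problem

Dutch pathology reports are indexed by *code series*: ordered sequences of
thesaurus codes summarizing the report's conclusion. A series names, in this
order, at least one **topography** (T, the anatomical site), at least one
**procedure** (P, e.g. biopsy or excision) — which cytology reports may
omit — and at least one **diagnosis** (morphology M, or the related
categories D/E/F). Further codes, such as a secondary topography marking a
metastatic site, may follow the first diagnosis without restriction. Each
report carries one or more series; terms within a series are serialized
with asterisks, series with newlines (`huid*excisie*dermale naevus`).

A free-text generation model asked to produce such annotations can
hallucinate codes that do not exist, violate the T–P–diagnosis structure,
or combine codes that have never been used together. `pathocode`
implements the constrained-decoding remedy: a rooted directed acyclic
graph (DAG) is built from historically observed, rule-filtered
annotations, and at every generation step the candidate set is masked down
to the DAG's valid continuations. Four guarantees follow by construction:
only previously annotated codes can be emitted; every emitted series is
rule-valid; only observed code successions occur; and the sequence can end
only after a diagnosis, so no truncated series is ever produced.

## The constraint DAG

`build_dag()` inserts every rule-valid series of the training annotations
into the graph: the first term becomes (or reuses) a child of the root,
each later term a child of its predecessor's node. After every morphology
term, an end-of-sequence (EOS) marker is recorded as a valid continuation.
`valid_continuations()` then answers the decoder's per-step query and
`enumerate_paths()` provides a brute-force oracle over all complete
sequences.

```{r fig-dag}
th <- thesaurus(
  code = c("T01000", "T29000", "TYY960", "P11400", "P11200",
           "M87400", "M76720", "M40000", "M09450"),
  term = c("huid", "pleura", "links", "biopt", "excisie",
           "dermale naevus", "verruca seborrhoica", "ontsteking",
           "geen afwijking"),
  categories = c("T", "T", "T", "P", "P", "M", "M", "M", "M"))
dag <- build_dag(c("huid*excisie*dermale naevus",
                   "huid*links*biopt*verruca seborrhoica*ontsteking",
                   "pleura*links*biopt*geen afwijking"), th)
valid_continuations(dag)
valid_continuations(dag, c("huid", "links", "biopt"))
length(enumerate_paths(dag))
```

Three design points were genuinely open and are resolved as follows.

**Node identity.** A pure term-keyed graph can become cyclic: if one
historical series orders two topographies `a b` and another orders them
`b a`, term-keyed edges `a→b` and `b→a` close a loop. Nodes are therefore
keyed by *(phase, term)*, where the phase is the state of the series rule
machine after consuming the term (`TOPOGRAPHY`, `PROCEDURE`, `DIAGNOSIS`,
`POST`). This reproduces the intended sharing — a laterality term following
two different topographies is one node, reachable from both — while
stratifying across phases. In the rare case where an edge *within* a phase
would still close a cycle, the successor node is duplicated with an
incremented deduplication index; all observed successions are preserved
and a topological order always exists (property-tested over randomized
insertion orders).

**EOS policy.** The construction marks EOS after morphology terms only
(`eos_policy = "M"`), because the minimal requirement is one topography
and one *morphology*; a configuration flag widens it to all diagnosis
categories. A consequence: a series whose final term cannot carry EOS
under the active policy (for example one ending on a trailing secondary
topography) would be inserted but not terminable, breaking the guarantee
that every inserted series is a complete root-to-EOS path. Such series are
therefore filtered at build time and counted in `rejected_count`, while
`validate_series()` itself continues to accept them — validation and
generability are deliberately distinct notions.

**Multiple series.** How several series of one report are serialized into
a single decoder output is not fixed by the archive's conventions. The
package's minimal extension is an optional series-separator token, valid
exactly where EOS is valid and resetting traversal to the root; it is off
by default, and all evaluation treats annotations as sets of series.

## Decoding

`decode()` implements group-wise diverse beam search over a pluggable
scorer: beams are split into groups; groups decode round-robin within a
step, and a unit already chosen this step by an earlier group is penalized
by the diversity penalty per prior occurrence (a Hamming penalty). The
default parameters — 6 beams, 2 groups, penalty 0.3, maximum 128 output
units — are the tuned decoding configuration for this task. With
constraints on, units outside `valid_continuations()` receive `-Inf`
before top-k selection, so the mask is hard and every finished beam is
generatable by the DAG.

Choices the decoding literature leaves open are fixed for determinism:
final ranking uses the length-normalized total log-score (mean log-score
per scored unit, EOS included; normalization exponent 1), and ties break
lexicographically on the emitted sequence. With a beam width at least the
number of DAG paths and one group, the search is exhaustive and provably
returns the brute-force argmax (tested against `enumerate_paths()`
scoring). A unit the DAG permits but the scorer does not know receives a
large finite floor rather than `-Inf`, so constrained decoding cannot
dead-end on a vocabulary mismatch.

The scorer contract — `scorer(source, prefix)` returning named log-scores
over candidate next units — stands in for a fine-tuned
sequence-to-sequence model, which is out of scope here. Three toy scorers
are provided: `uniform`, an add-one-smoothed `bigram` estimated from
reference annotations, and `lexical` (bigram plus a bonus of 2 for units
whose term occurs in the source conclusion). They are deliberately weak;
their purpose is to exercise the mask, not to reach archive-scale
accuracy. The masking effect is visible precisely because they are weak:
with the lexical scorer, unconstrained decoding drifts into repeated or
truncated unit sequences, while the same scorer under the DAG mask always
emits complete, rule-valid series.

## Evaluation stack

*Corpus BLEU* is computed on annotation strings after flattening `*` and
newlines to spaces: BLEU-4 on the 0–100 scale, the 13a international
tokenization, brevity penalty, and exponential smoothing of zero n-gram
counts (the floor doubling per zero-count order). The implementation is
checked to four decimals against an independently written reference
implementation of the same published algorithm on 100 seeded random
corpora (frozen expected values).

*Paired bootstrap.* System comparisons resample report indices with
replacement (default 1000 times), recomputing BLEU from per-item
sufficient statistics, which makes the resampling a cheap matrix product.
The confidence interval is the 95% percentile half-width; the p-value is
the two-sided paired value — twice the fraction of resamples whose BLEU
difference contradicts (or zeroes) the full-data sign, capped at 1. The
exact recipe behind published annotation-model comparisons is not
specified anywhere; this one is documented, deterministic under a seed,
and empirically conservative: over 200 simulated null corpora of 200
items, the rejection rate at α = 0.05 stays below 0.07.

*Per-code scores* reduce each report's prediction and reference to term
multisets pooled over series (series alignment within a report is
arbitrary, so pooling avoids an artificial pairing), then micro-count
tp/fp/fn per code. Cumulative-frequency binning sorts codes by descending
support and cuts at equal increments of cumulative support, boundary codes
to the earlier bin; both 10 and 20 bins are meaningful, 20 is the
default. Subgroup analysis stratifies by report type and the inclusive
conclusion-length bins 0–80, 81–200, 201–400 and 401+ characters (up to
12 cells). WER/CER/MER/WIL/WIP use the same tokenization and standard
edit-distance definitions.

*Retrieval.* A query is a disjunction of conjunctive clauses; a clause
must co-occur within one series (a series is the unit of a coherent
diagnosis; `across_series = TRUE` relaxes this). A patient is retrieved
iff at least one of their reports matches. `compare_retrieval()` reports
the O/M set algebra at patient and report level, and `classify_miss()` is
an explicitly heuristic proxy for a manual miss audit: no output → no
codes; no query term mentioned in the conclusion → absence of relevant
information; at least half the reference units reproduced but the
query-required code missing → essential code not recognized; otherwise
wrong codes. The 50% overlap threshold is plumbing, not a validated
classifier.

## The synthetic generator

Nationwide pathology data is proprietary, so everything above is exercised
on a seeded generator whose defaults emulate the published corpus
statistics:

* three report types with log-normal conclusion lengths matched to the
  reported median/IQR in tokens — histology 15 (9–26), cytology 11
  (7–17), autopsy 124 (65–207) — bridged to character-based length bins
  via a characters-per-token factor (default 7), since the published
  length unit is token-like while the subgroup bins are in characters;
* codes per annotation 4 (3–5) / 4 (3–5) / 4 (3–8) per type;
* series drawn as topographies, then procedure (omitted with probability
  0.5 only in cytology), then morphologies — rule-valid by construction
  and always ending on a diagnosis;
* a Zipf rank-frequency law over the merged code vocabulary. Categories
  are interleaved deterministically into the global rank order
  (category *c*'s *i*-th code at position (i−0.5)·total/n&#99;), so the
  head of the distribution mixes sites, procedures and diagnoses and the
  skew does not depend on the seed. The exponent default 0.95 was
  calibrated once, on 10,000-report corpora, against the published
  occurrence shares — the five most frequent codes carrying 25.9% and the
  top twenty 49.2% of all code occurrences — and then frozen (measured
  26.4–27.7% and 47.8–48.0% across seeds);
* patients owning geometric blocks of reports, planted code queries with
  recorded ground-truth patient sets, and an optional noise channel that
  applies exactly one validity-preserving edit per drawn annotation
  (drop a non-mandatory unit, substitute a diagnosis by a sibling, or
  drop an extra series), emulating the incomplete-or-incorrect character
  of real historical annotations.

What the generator does **not** emulate: real linguistic structure
(conclusions are filler words around embedded terms — sufficient for a
lexical scorer, useless for a real language model), inter-code clinical
correlation beyond succession frequencies, temporal drift, and
rule-based comparison annotators. Tests passing on this corpus
therefore demonstrate the correctness of the constraint, decoding and
evaluation machinery — not clinical annotation quality.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen so the full suite
completes on a single CPU: worked-example graphs for exact checks;
70–160-report corpora for property tests; ~1,000 constrained decodes for
the compliance sweep; 50 brute-forceable DAGs (≤200 paths) for the
beam-search oracle; 200 null corpora × 1000 resamples for bootstrap
calibration; and one 10,000-report corpus for the frequency-skew
calibration. The held-out generability check (a DAG built on ~4,000
reports regenerating ≥99% of fresh annotations from the same
distribution) uses a proportionally reduced vocabulary (5 topographies, 2
procedures, 6 diagnoses), since succession coverage is a function of the
data-to-vocabulary ratio and the archive-scale setting — about a million
records — is out of reach at desk scale.

Other numerical details: term matching is case-insensitive and
whitespace-normalized (dictation artifacts); combination codes are split
greedily left-to-right preferring thesaurus-known parts; scores are exact
log sums (no renormalization after masking, since ranking is
scale-invariant); and every stochastic component takes an explicit seed
and restores the caller's RNG state.

## Known limitations

The scorer contract is term-level: a subword adapter would be needed to
connect a real tokenizer, and the DAG intentionally does not model
probabilities — it is a pure constraint structure. The miss-reason
classifier is a labelled heuristic. Query semantics implement the minimal
reading of "combinations of codes" (no negation, no hierarchy). BLEU on
annotation strings measures token agreement with historical references,
which are themselves imperfect; the retrieval comparison exists precisely
because BLEU alone does not capture fitness for patient retrieval.
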