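# pathocode

Constrained decoding and evaluation for pathology-report code series.

Pathology archives index reports with *code series* — ordered thesaurus
codes summarizing a report's conclusion: at least one topography (T, the
anatomical site), a procedure (P; optional in cytology), then a diagnosis
(morphology M, or D/E/F), optionally followed by further codes. Generative
models asked to produce such annotations can hallucinate nonexistent
codes, break the T–P–diagnosis structure, or combine codes that never
co-occur. `pathocode` is for researchers building or evaluating automatic
annotation systems for such archives. It provides:

* **codeseries** — parsing, serialization and rule validation of codes
  (including combination codes such as `T96000P11100`), series,
  multi-series annotations and report records;
* **dagbuild** — a rooted, multi-parent directed acyclic graph of
  rule-filtered, historically observed code successions, whose
  root-to-EOS paths are exactly the permitted outputs
  (`build_dag()`, `valid_continuations()`, `is_generatable()`,
  `enumerate_paths()`);
* **decoding** — greedy and group-wise diverse beam search (defaults:
  6 beams, 2 groups, diversity penalty 0.3) over a pluggable next-unit
  scorer, with hard DAG masking so every constrained output is a known,
  rule-valid series; toy scorers (uniform / bigram / lexical) stand in
  for a neural model;
* **evalmetrics** — corpus BLEU (13a tokenization, exponential
  smoothing) with paired-bootstrap confidence intervals and p-values,
  type × length subgroup tables, per-code precision/recall/F1 with
  cumulative-frequency binning, and WER/CER/MER/WIL/WIP;
* **retrieval** — case-based evaluation: code queries (disjunctions of
  within-series conjunctions) run against original vs model annotations,
  O/M set algebra at patient and report level, and a heuristic
  miss-reason classifier;
* **synthdata** — a fully seeded generator of thesauri and annotated
  report corpora (three report types with realistic length and
  codes-per-annotation distributions, Zipf-skewed code usage, patients
  owning multiple reports, planted queries, annotation noise), so the
  whole stack is testable without proprietary data.

At every decoding step the DAG is queried for the valid continuations of
the current prefix; everything else is scored `-Inf`. Four guarantees
follow by construction: no out-of-thesaurus codes, rule-valid series,
only historically observed successions, and termination only after a
diagnosis code.

## Worked example

Build the constraint DAG from three historical annotations, then decode a
conclusion with the lexical toy scorer:

```r
library(pathocode)

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
dag
#> <annotation_dag: 9 nodes, 3 series inserted, 0 rejected, EOS policy M>

valid_continuations(dag, c("huid", "links", "biopt"))
#> [1] "verruca seborrhoica" "geen afwijking"

train <- data.frame(report_id = paste0("r", 1:3), patient_id = "p1",
                    type = "T", year = 2020, conclusion = "x",
                    annotation = c("huid*excisie*dermale naevus",
                                   "huid*links*biopt*verruca seborrhoica*ontsteking",
                                   "pleura*links*biopt*geen afwijking"))
sc <- toy_scorers(train, th)
res <- decode("links huidbiopt met verruca seborrhoica", sc$lexical,
              decode_params(), dag)
```

The ranked beams (normalized log-scores):

```
1. huid*links*biopt*verruca seborrhoica               norm log-score -0.167
2. huid*links*biopt*verruca seborrhoica*ontsteking    norm log-score -0.308
3. huid*links*biopt*geen afwijking                    norm log-score -0.428
```

The top beam reproduces the reference annotation for that conclusion
(`corpus_bleu` = 100 against `huid*links*biopt*verruca seborrhoica`). The
graph admits exactly 7 complete sequences (`enumerate_paths(dag)`), and
every decoded output is one of them — by construction, for any scorer.

Command-line wrappers for the full pipeline (simulate → build-dag →
decode → evaluate → retrieve) live in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", package = "pathocode"))')
Rscript $CLI/simulate.R --out corpus --seed 5 --reports 120,40,40
Rscript $CLI/build-dag.R --reports corpus/reports.jsonl \
        --thesaurus corpus/thesaurus.tsv --out dag.json
Rscript $CLI/decode.R --reports corpus/reports.jsonl \
        --thesaurus corpus/thesaurus.tsv --dag dag.json --out pred.tsv
```

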