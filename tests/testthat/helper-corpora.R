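# Deterministic random fixtures shared across tests.

# Small fixed thesaurus mirroring the three-sample worked construction:
# skin/pleura topographies, laterality, biopsy/excision procedures and four
# morphologies.
fig_thesaurus <- function() {
  thesaurus(
    code = c("T01000", "T29000", "TYY960", "P11400", "P11200",
             "M87400", "M76720", "M40000", "M09450"),
    term = c("huid", "pleura", "links", "biopt", "excisie",
             "dermale naevus", "verruca seborrhoica", "ontsteking",
             "geen afwijking"),
    categories = c("T", "T", "T", "P", "P", "M", "M", "M", "M"))
}

fig_annotations <- function() {
  c("huid*excisie*dermale naevus",
    "huid*links*biopt*verruca seborrhoica*ontsteking",
    "pleura*links*biopt*geen afwijking")
}

fig_dag <- function() build_dag(fig_annotations(), fig_thesaurus())

# A random hypothesis/reference corpus of annotation-like strings, a pure
# function of the seed. Strings mix plain words, asterisk separators,
# digits and sentence punctuation to exercise the tokenizer.
random_bleu_corpus <- function(seed) {
  pool_words <- c("huid", "biopt", "links", "rechts", "excisie", "naevus",
                  "carcinoom", "ontsteking", "geen", "afwijking", "cel",
                  "klier", "plaveisel", "adeno", "basaal", "obductie",
                  "lichaam", "maligne", "benigne", "graad")
  withr_seed <- function(expr) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    n <- sample(3:15, 1)
    vocab <- sample(pool_words, sample(6:15, 1))
    mk <- function(len) {
      toks <- sample(vocab, len, replace = TRUE)
      if (runif(1) < 0.3) toks <- c(toks, sample(1:3, 1))
      sep <- if (runif(1) < 0.5) "*" else " "
      s <- paste(toks, collapse = sep)
      if (runif(1) < 0.2) s <- paste0(s, ".")
      s
    }
    ref <- vapply(seq_len(n), function(i) mk(sample(2:9, 1)), character(1))
    hyp <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.25) ref[i] else mk(sample(1:9, 1))
    }, character(1))
    list(hyp = hyp, ref = ref)
  })
}

# A randomized rule-conformant corpus + DAG for property tests.
random_synth_setup <- function(seed, n_reports = c(T = 40L, C = 15L, S = 15L),
                               ...) {
  cfg <- generator_config(seed = seed, n_reports = n_reports,
                          n_topography = 25L, n_procedure = 10L,
                          n_diagnosis = 40L, ...)
  th <- generate_thesaurus(cfg)
  corpus <- generate_corpus(th, cfg)
  list(cfg = cfg, th = th, corpus = corpus)
}
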