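# Greedy and diverse beam-search decoding over a pluggable next-unit scorer,
# optionally masked by an annotation DAG so that only observed, rule-valid
# code series can be produced.

#' Decoding parameters
#'
#' @param num_beams total number of beams (must be divisible by
#'   `num_groups`). The defaults (6 beams, 2 groups, diversity penalty 0.3)
#'   follow the tuned decoding configuration for this task.
#' @param num_groups number of diverse beam groups.
#' @param diversity_penalty non-negative penalty subtracted from a unit's
#'   log-score once per time that unit was already chosen, at the same step,
#'   by a beam in an earlier group (Hamming diversity).
#' @param max_length maximum output length in annotation units.
#' @param mode `"beam"` or `"greedy"` (greedy forces a single beam).
#' @param constrained if `TRUE`, units outside the DAG's valid continuations
#'   are masked out before selection.
#' @return list of class `decode_params`.
#' @export
decode_params <- function(num_beams = 6L, num_groups = 2L,
                          diversity_penalty = 0.3, max_length = 128L,
                          mode = c("beam", "greedy"), constrained = TRUE) {
  mode <- match.arg(mode)
  if (mode == "greedy") {
    num_beams <- 1L
    num_groups <- 1L
  }
  stopifnot(num_beams >= 1L, num_groups >= 1L,
            num_beams %% num_groups == 0L,
            diversity_penalty >= 0, max_length >= 1L)
  structure(list(num_beams = as.integer(num_beams),
                 num_groups = as.integer(num_groups),
                 diversity_penalty = diversity_penalty,
                 max_length = as.integer(max_length),
                 mode = mode, constrained = constrained),
            class = "decode_params")
}

# Scores missing from a scorer's vocabulary but permitted by the DAG are
# given this finite floor so constrained decoding never dead-ends merely
# because the scorer has a narrower vocabulary than the DAG.
SCORE_FLOOR <- -1e6

#' Decode an annotation for a conclusion text
#'
#' Implements group-wise diverse beam search: beam groups decode in
#' round-robin at every step, and within a step a unit already chosen by an
#' earlier group is penalized by `diversity_penalty` per prior occurrence.
#' When `params$constrained` is `TRUE`, units outside
#' [valid_continuations()] receive `-Inf` before top-k selection, so every
#' emitted sequence is generatable by the DAG. A beam finishes when it
#' selects the EOS unit; all beams finish at `max_length`. Results are
#' ranked by length-normalized total log-score (mean log-score per scored
#' unit, EOS included), ties broken lexicographically.
#'
#' @param source the conclusion text handed to the scorer.
#' @param scorer a scorer function, see [toy_scorers()]: called as
#'   `scorer(source, prefix)` and returning a named numeric vector of
#'   log-scores over candidate next units (including [EOS_TOKEN]).
#' @param params a [decode_params()] object.
#' @param dag an `annotation_dag`; required when `params$constrained`.
#' @return list of decode results, each a list with `sequence` (terms,
#'   EOS stripped), `score` (total log-score), `norm_score`, `finished`
#'   (ended by EOS rather than the length cap) and `beam_rank`.
#' @export
decode <- function(source, scorer, params = decode_params(), dag = NULL) {
  if (params$constrained && is.null(dag)) {
    pathocode_error("MISSING_DAG", "constrained decoding requires a DAG")
  }
  G <- params$num_groups
  k <- params$num_beams %/% G
  pen <- params$diversity_penalty

  empty_beam <- list(seq = character(0), score = 0, steps = 0L,
                     finished = FALSE)
  groups <- rep(list(list(empty_beam)), G)

  seq_key <- function(seq) paste(seq, collapse = "\x01")

  candidate_scores <- function(beam, step_counts) {
    sc <- scorer(source, beam$seq)
    if (!is.numeric(sc) || is.null(names(sc)) || !any(is.finite(sc))) {
      pathocode_error("SCORER_FAILURE", "scorer returned no finite scores")
    }
    if (params$constrained) {
      allowed <- valid_continuations(dag, beam$seq)
      if (!length(allowed)) {
        pathocode_error("DEAD_END", "constrained decoding reached a dead end")
      }
      missing <- setdiff(allowed, names(sc))
      if (length(missing)) {
        sc <- c(sc, stats::setNames(rep(SCORE_FLOOR, length(missing)),
                                    missing))
      }
      sc[setdiff(names(sc), allowed)] <- -Inf
    }
    if (pen > 0 && length(step_counts)) {
      shared <- intersect(names(sc), names(step_counts))
      sc[shared] <- sc[shared] - pen * step_counts[shared]
    }
    sc[is.finite(sc)]
  }

  for (step in seq_len(params$max_length)) {
    step_counts <- numeric(0)
    any_active <- FALSE
    for (g in seq_len(G)) {
      beams <- groups[[g]]
      if (all(vapply(beams, `[[`, logical(1), "finished"))) next
      any_active <- TRUE
      cand_score <- numeric(0)
      cand_key <- character(0)
      cand <- list()
      add_cand <- function(beam, key) {
        cand[[length(cand) + 1L]] <<- beam
        cand_score[length(cand)] <<- beam$score
        cand_key[length(cand)] <<- key
      }
      for (b in beams) {
        if (b$finished) {
          add_cand(b, seq_key(c(b$seq, EOS_TOKEN)))
          next
        }
        sc <- candidate_scores(b, step_counts)
        # each beam can place at most k candidates into the group's top-k,
        # so its own top-k (score desc, unit name as tie-break, matching
        # the global sequence-key order) is a sufficient preselection
        top <- order(-sc, names(sc))[seq_len(min(k, length(sc)))]
        sc <- sc[top]
        for (u in names(sc)) {
          nb <- b
          nb$score <- b$score + sc[[u]]
          nb$steps <- b$steps + 1L
          if (identical(u, EOS_TOKEN)) {
            nb$finished <- TRUE
          } else {
            nb$seq <- c(b$seq, u)
          }
          add_cand(nb, seq_key(c(nb$seq, if (nb$finished) EOS_TOKEN)))
        }
      }
      keep <- order(-cand_score, cand_key)[seq_len(min(k, length(cand)))]
      groups[[g]] <- cand[keep]
      # record this step's chosen units for later groups' diversity penalty
      if (pen > 0) {
        for (b in groups[[g]]) {
          if (b$steps != step) next  # beam finished at an earlier step
          u <- if (length(b$seq) >= step) b$seq[step] else EOS_TOKEN
          step_counts[u] <- (if (u %in% names(step_counts))
            step_counts[[u]] else 0) + 1
        }
      }
    }
    if (!any_active) break
  }

  results <- list()
  for (g in seq_len(G)) {
    for (b in groups[[g]]) {
      if (!length(b$seq) && !b$finished) next
      results[[length(results) + 1L]] <- list(
        sequence = b$seq, score = b$score,
        norm_score = b$score / max(b$steps, 1L),
        finished = b$finished)
    }
  }
  norm <- vapply(results, `[[`, numeric(1), "norm_score")
  keys <- vapply(results, function(b) seq_key(b$sequence), character(1))
  ord <- order(-norm, keys)
  results <- results[ord]
  for (i in seq_along(results)) results[[i]]$beam_rank <- i
  results
}

#' Toy next-unit scorers
#'
#' Desk-scale stand-ins for a fine-tuned sequence-to-sequence model,
#' honouring the scorer contract used by [decode()].
#'
#' * `uniform`: equal log-score `log(1/V)` over the whole vocabulary.
#' * `bigram`: add-one-smoothed log-frequency of a unit given the previous
#'   unit, estimated from the reference annotations of `reports` (each
#'   series contributes transitions from a begin marker through its terms
#'   to EOS).
#' * `lexical`: the bigram score plus a fixed bonus for units whose term
#'   occurs, case-insensitively, as a substring of the source conclusion.
#'
#' @param reports data.frame of report records (see [read_reports()]) whose
#'   `annotation` column supplies the training transitions.
#' @param th a `palga_thesaurus`; its terms define the vocabulary.
#' @param lexical_bonus additive log-score bonus for source-mentioned terms.
#' @return named list of scorer functions `uniform`, `bigram`, `lexical`.
#' @export
toy_scorers <- function(reports, th, lexical_bonus = 2.0) {
  vocab <- c(unique(th$term), EOS_TOKEN)
  V <- length(vocab)

  uniform <- function(source, prefix) {
    stats::setNames(rep(log(1 / V), V), vocab)
  }

  BOS <- "\x02BOS"
  counts <- new.env(parent = emptyenv())
  bump <- function(prev, nxt) {
    row <- counts[[prev]]
    if (is.null(row)) row <- numeric(0)
    row[nxt] <- (if (nxt %in% names(row)) row[[nxt]] else 0) + 1
    assign(prev, row, envir = counts)
  }
  if (!is.null(reports) && nrow(reports)) {
    for (text in reports$annotation) {
      ann <- tryCatch(parse_annotation(text), error = function(e) NULL)
      if (is.null(ann)) next
      for (series in ann) {
        prev <- BOS
        for (t in series) {
          bump(prev, t)
          prev <- t
        }
        bump(prev, EOS_TOKEN)
      }
    }
  }

  bigram <- function(source, prefix) {
    prev <- if (length(prefix)) prefix[[length(prefix)]] else BOS
    row <- counts[[prev]]
    n_prev <- if (is.null(row)) 0 else sum(row)
    sc <- stats::setNames(rep(log(1 / (n_prev + V)), V), vocab)
    if (!is.null(row)) {
      shared <- intersect(names(row), vocab)
      sc[shared] <- log((row[shared] + 1) / (n_prev + V))
    }
    sc
  }

  lexical <- function(source, prefix) {
    sc <- bigram(source, prefix)
    terms <- setdiff(vocab, EOS_TOKEN)
    hit <- vapply(terms, function(t) {
      grepl(t, source, fixed = TRUE, ignore.case = FALSE) ||
        grepl(tolower(t), tolower(source), fixed = TRUE)
    }, logical(1))
    sc[terms[hit]] <- sc[terms[hit]] + lexical_bonus
    sc
  }

  list(uniform = uniform, bigram = bigram, lexical = lexical)
}

#' Decode a batch of reports to an annotation table
#'
#' Convenience wrapper running [decode()] on every report and keeping the
#' top-ranked sequence.
#'
#' @param reports data.frame of report records.
#' @param scorer a scorer function.
#' @param params a [decode_params()].
#' @param dag optional `annotation_dag`.
#' @return data.frame with `report_id` and `prediction` (serialized
#'   annotation string; empty when nothing could be decoded).
#' @export
decode_reports <- function(reports, scorer, params = decode_params(),
                           dag = NULL) {
  preds <- vapply(seq_len(nrow(reports)), function(i) {
    res <- decode(reports$conclusion[i], scorer, params, dag)
    if (!length(res)) return("")
    paste(res[[1]]$sequence, collapse = "*")
  }, character(1))
  data.frame(report_id = reports$report_id, prediction = preds,
             stringsAsFactors = FALSE)
}
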