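# Seeded synthetic-data generator: thesauri, rule-conformant annotated
# report corpora with a heavy-tailed code frequency distribution, patients
# owning multiple reports, planted retrieval queries, and annotation noise.

#' Generator configuration
#'
#' Defaults emulate the published corpus statistics: three report types
#' with distinct conclusion-length distributions (log-normal, matched to
#' median/IQR in tokens: histology 15 (9--26), cytology 11 (7--17), autopsy
#' 124 (65--207)), codes per annotation 4 (3--5) / 4 (3--5) / 4 (3--8),
#' and a Zipf-like code usage distribution whose exponent is calibrated so
#' the five most frequent codes carry about a quarter of all code
#' occurrences and the top twenty about half.
#'
#' @param seed integer seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @param n_topography,n_procedure,n_diagnosis vocabulary sizes per
#'   category (diagnosis codes are morphology, category M).
#' @param combination_rate fraction of additional combination (T+P) codes
#'   added to the thesaurus.
#' @param zipf_exponent exponent of the rank-frequency law for code
#'   sampling weights.
#' @param n_reports named integer vector, reports per type `T`, `C`, `S`.
#' @param length_median,length_q1,length_q3 named numeric vectors (per
#'   type) of conclusion length quantiles, in tokens.
#' @param codes_median,codes_q1,codes_q3 named numeric vectors (per type)
#'   of codes-per-annotation quantiles.
#' @param multi_series_rate probability that a report carries an extra
#'   code series.
#' @param p_omit_procedure probability that a cytology series omits its
#'   procedure code.
#' @param mention_rate probability that an annotation term is actually
#'   spelled out in the synthesized conclusion text.
#' @param noise_rate per-annotation probability of one injected edit (see
#'   [inject_noise()]).
#' @param patient_geom_p geometric parameter for extra reports per
#'   patient: a patient owns `1 + rgeom(patient_geom_p)` reports.
#' @param chars_per_token average characters per token used to bridge
#'   token-based lengths and character-based length bins.
#' @param n_queries number of planted retrieval queries.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_topography = 120L, n_procedure = 40L, n_diagnosis = 260L,
    combination_rate = 0.03,
    zipf_exponent = 0.95,
    n_reports = c(T = 300L, C = 100L, S = 100L),
    length_median = c(T = 15, C = 11, S = 124),
    length_q1 = c(T = 9, C = 7, S = 65),
    length_q3 = c(T = 26, C = 17, S = 207),
    codes_median = c(T = 4, C = 4, S = 4),
    codes_q1 = c(T = 3, C = 3, S = 3),
    codes_q3 = c(T = 5, C = 5, S = 8),
    multi_series_rate = 0.2,
    p_omit_procedure = 0.5,
    mention_rate = 0.8,
    noise_rate = 0.1,
    patient_geom_p = 0.6,
    chars_per_token = 7,
    n_queries = 4L) {
  cfg <- as.list(environment())
  stopifnot(all(c("T", "C", "S") %in% names(cfg$n_reports)),
            cfg$zipf_exponent > 0,
            cfg$noise_rate >= 0, cfg$noise_rate <= 1,
            cfg$multi_series_rate >= 0, cfg$multi_series_rate <= 1,
            cfg$n_topography >= 1, cfg$n_procedure >= 1,
            cfg$n_diagnosis >= 2)
  class(cfg) <- "generator_config"
  cfg
}

# log-normal parameters from a (median, q1, q3) triple
lnorm_params <- function(median, q1, q3) {
  c(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# pronounceable synthetic word, deterministic given the RNG state
synth_word <- function(n_syll = sample(2:4, 1)) {
  cons <- c("b", "d", "g", "h", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u", "aa", "ee", "oo")
  paste0(paste0(sample(cons, n_syll, TRUE), sample(vow, n_syll, TRUE)),
         collapse = "")
}

#' Generate a synthetic thesaurus
#'
#' Emits unique codes per category (one uppercase category letter plus
#' five digits) with pronounceable synthetic terms, a small fraction of
#' combination codes, and Zipf-law base sampling weights: codes of all
#' categories are merged into one global rank order and code `r` gets
#' weight `r^-zipf_exponent`. Combination codes carry no sampling weight.
#'
#' @param config a [generator_config()].
#' @return a `palga_thesaurus` with extra columns `weight` and `rank`.
#' @export
generate_thesaurus <- function(config = generator_config()) {
  with_local_seed(config$seed, {
    n_cat <- c(T = config$n_topography, P = config$n_procedure,
               M = config$n_diagnosis)
    total <- sum(n_cat)
    codes <- character(0)
    cats <- character(0)
    for (cl in names(n_cat)) {
      body <- sprintf("%05d", sample.int(99999L, n_cat[[cl]]))
      codes <- c(codes, paste0(cl, body))
      cats <- c(cats, rep(cl, n_cat[[cl]]))
    }
    terms <- character(total)
    seen <- character(0)
    for (i in seq_len(total)) {
      repeat {
        w <- synth_word()
        # occasional multiword terms, as in real thesauri
        if (stats::runif(1) < 0.15) w <- paste(w, synth_word())
        if (!(w %in% seen)) break
      }
      seen <- c(seen, w)
      terms[i] <- w
    }
    # global rank order interleaving the categories deterministically:
    # category c's i-th code sits at global position (i - 0.5) * total /
    # n_c, so the head of the distribution mixes topographies, procedures
    # and diagnoses in fixed proportion and the frequency skew does not
    # depend on the seed
    pos <- numeric(total)
    for (cl in names(n_cat)) {
      sel <- which(cats == cl)
      pos[sel] <- (seq_along(sel) - 0.5) * total / n_cat[[cl]]
    }
    rank <- order(order(pos))
    weight <- rank^(-config$zipf_exponent)

    n_comb <- max(0L, round(config$combination_rate * total))
    if (n_comb > 0) {
      t_codes <- codes[cats == "T"]
      p_codes <- codes[cats == "P"]
      comb <- unique(paste0(sample(t_codes, n_comb, TRUE),
                            sample(p_codes, n_comb, TRUE)))
      comb_terms <- vapply(seq_along(comb), function(i) {
        repeat {
          w <- synth_word()
          if (!(w %in% seen)) break
        }
        seen <<- c(seen, w)
        w
      }, character(1))
      codes <- c(codes, comb)
      cats <- c(cats, rep("TP", length(comb)))
      terms <- c(terms, comb_terms)
      rank <- c(rank, rep(NA_integer_, length(comb)))
      weight <- c(weight, rep(0, length(comb)))
    }
    th <- thesaurus(codes, terms, cats)
    th$weight <- weight
    th$rank <- rank
    th
  })
}

# draw a positive integer from a log-normal matched to median/IQR
draw_count <- function(n, median, q1, q3, lo, hi) {
  p <- lnorm_params(median, q1, q3)
  pmin(hi, pmax(lo, round(stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]))))
}

#' Generate a synthetic annotated report corpus
#'
#' Per report: the type is fixed by the configured counts; the number of
#' codes and the conclusion length follow the type's log-normal; each
#' series is drawn as topographies, then a procedure (omitted with the
#' configured probability only in cytology), then morphologies, sampling
#' codes by category-conditional Zipf weights -- so every clean annotation
#' is rule-valid by construction and ends on a diagnosis. The conclusion
#' text embeds each annotated term with probability `mention_rate` among
#' filler words. Reports are partitioned over patients, retrieval queries
#' are planted with their ground-truth patient sets, and (when
#' `noise_rate > 0`) a noised copy of every annotation is produced.
#'
#' @param th a thesaurus from [generate_thesaurus()].
#' @param config the same [generator_config()].
#' @return list of class `synthetic_corpus`: `thesaurus`, `reports` (with
#'   `annotation` = clean and `annotation_noised` columns), `patients`
#'   (patient to report map), `queries` (each with `query` and
#'   `truth_patients`/`truth_reports`), `noise_log`, `config`.
#' @export
generate_corpus <- function(th, config = generator_config()) {
  atomic <- is.na(th$rank) == FALSE
  pool <- list(
    T = which(th$categories == "T" & atomic),
    P = which(th$categories == "P" & atomic),
    M = which(th$categories == "M" & atomic)
  )
  draw_codes <- function(cat, k) {
    idx <- pool[[cat]]
    k <- min(k, length(idx))
    idx[sample.int(length(idx), k, replace = FALSE,
                   prob = th$weight[idx])]
  }

  corpus <- with_local_seed(config$seed + 1L, {
    types <- rep(names(config$n_reports), config$n_reports)
    types <- sample(types)
    n <- length(types)
    report_id <- sprintf("R%06d", seq_len(n))

    # patients: consecutive blocks of 1 + geometric extra reports
    patient_of <- character(n)
    i <- 1L
    pid <- 0L
    while (i <= n) {
      pid <- pid + 1L
      size <- 1L + stats::rgeom(1, config$patient_geom_p)
      block <- i:min(n, i + size - 1L)
      patient_of[block] <- sprintf("P%05d", pid)
      i <- i + size
    }

    make_series <- function(rtype, n_codes) {
      omit_p <- rtype == "C" && stats::runif(1) < config$p_omit_procedure
      n_p <- if (omit_p) 0L else 1L
      n_t <- if (n_codes - n_p >= 3L && stats::runif(1) < 0.3) 2L else 1L
      n_m <- max(1L, n_codes - n_p - n_t)
      idx <- c(draw_codes("T", n_t),
               if (n_p) draw_codes("P", n_p),
               draw_codes("M", n_m))
      th$term[idx]
    }

    annotations <- character(n)
    conclusions <- character(n)
    for (r in seq_len(n)) {
      ty <- types[r]
      n_codes <- draw_count(1, config$codes_median[[ty]],
                            config$codes_q1[[ty]], config$codes_q3[[ty]],
                            lo = 3, hi = 14)
      extra <- stats::runif(1) < config$multi_series_rate && n_codes >= 6
      series <- if (extra) {
        k <- n_codes %/% 2L
        list(make_series(ty, k), make_series(ty, n_codes - k))
      } else {
        list(make_series(ty, n_codes))
      }
      annotations[r] <- serialize_annotation(series)

      terms <- unlist(series, use.names = FALSE)
      mentioned <- terms[stats::runif(length(terms)) < config$mention_rate]
      target <- draw_count(1, config$length_median[[ty]],
                           config$length_q1[[ty]], config$length_q3[[ty]],
                           lo = 3, hi = 600)
      n_fill <- max(0L, target - length(mentioned))
      filler <- if (n_fill) {
        vapply(seq_len(n_fill), function(i) synth_word(), character(1))
      } else character(0)
      words <- sample(c(mentioned, filler))
      conclusions[r] <- paste0(paste(words, collapse = " "), ".")
    }

    reports <- data.frame(
      report_id = report_id, patient_id = patient_of, type = types,
      year = sample(2013:2023, n, replace = TRUE),
      conclusion = conclusions, annotation = annotations,
      stringsAsFactors = FALSE)
    reports$length_chars <- nchar(reports$conclusion)

    # planted queries: single-diagnosis clauses and topography+diagnosis
    # pairs taken from observed series
    queries <- list()
    all_series <- unlist(lapply(annotations,
                                function(a) parse_annotation(a)),
                         recursive = FALSE)
    m_terms <- th$term[pool$M]
    for (q in seq_len(config$n_queries)) {
      if (q %% 2L == 1L) {
        used <- unlist(all_series, use.names = FALSE)
        freq <- table(used[used %in% m_terms])
        member <- sample(names(freq), 1, prob = as.numeric(freq))
        qu <- code_query(sprintf("query_%02d", q), list(member))
      } else {
        s <- all_series[[sample.int(length(all_series), 1)]]
        cats <- resolve_terms(s, th)$category
        qu <- code_query(sprintf("query_%02d", q),
                         list(c(s[match("T", cats)], s[match("M", cats)])))
      }
      queries[[q]] <- qu
    }
    list(reports = reports, queries = queries)
  })

  reports <- corpus$reports
  queries <- lapply(corpus$queries, function(qu) {
    hit <- run_query(qu, reports, th = th)
    list(query = qu, truth_patients = hit$patient_ids,
         truth_reports = hit$report_ids)
  })

  noised <- inject_noise(reports$annotation, th,
                         noise_rate = config$noise_rate,
                         seed = config$seed + 2L)
  reports$annotation_noised <- noised$annotations

  structure(
    list(thesaurus = th, reports = reports,
         patients = reports[, c("patient_id", "report_id")],
         queries = queries, noise_log = noised$log, config = config),
    class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus: %d reports (%s), %d codes, %d queries, %d noised>\n",
    nrow(x$reports),
    paste(names(table(x$reports$type)), table(x$reports$type),
          sep = "=", collapse = " "),
    nrow(x$thesaurus), length(x$queries), nrow(x$noise_log)))
  invisible(x)
}

#' Inject annotation noise
#'
#' With probability `noise_rate` per annotation, applies exactly one edit
#' drawn uniformly from the applicable members of: drop a non-mandatory
#' unit (one whose removal keeps the series valid and still ending on a
#' diagnosis), substitute a diagnosis unit by a same-category sibling, or
#' drop a whole extra series. Substitution is always applicable, so an
#' edit can always be made; rule validity is preserved by construction.
#'
#' @param annotations character vector of serialized clean annotations.
#' @param th the thesaurus resolving the terms.
#' @param noise_rate probability in \[0, 1\] of editing each annotation.
#' @param seed RNG seed (applied locally).
#' @return list with `annotations` (same length, edited where drawn) and
#'   `log` (data.frame `index`, `edit`, `detail`).
#' @export
inject_noise <- function(annotations, th, noise_rate, seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate <= 1)
  m_terms <- th$term[th$categories == "M"]
  with_local_seed(seed, {
    out <- annotations
    log <- list()
    for (i in seq_along(annotations)) {
      if (stats::runif(1) >= noise_rate) next
      ann <- parse_annotation(annotations[i])

      droppable <- list()
      for (s in seq_along(ann)) {
        for (u in seq_along(ann[[s]])) {
          trimmed <- ann[[s]][-u]
          if (!length(trimmed)) next
          cats <- resolve_terms(trimmed, th)$category
          ok <- validate_series(trimmed, "T", th)$valid &&
            cats[length(cats)] == "M"
          if (ok) droppable[[length(droppable) + 1L]] <- c(s, u)
        }
      }
      edits <- c("substitute",
                 if (length(droppable)) "drop_unit",
                 if (length(ann) > 1L) "drop_series")
      edit <- if (length(edits) == 1L) edits else sample(edits, 1)

      if (edit == "drop_unit") {
        pick <- droppable[[sample.int(length(droppable), 1)]]
        detail <- ann[[pick[1]]][pick[2]]
        ann[[pick[1]]] <- ann[[pick[1]]][-pick[2]]
      } else if (edit == "drop_series") {
        s <- sample(2:length(ann), 1)
        detail <- serialize_annotation(ann[s])
        ann[s] <- NULL
      } else {
        # substitute a diagnosis unit by a same-category sibling
        cand <- list()
        for (s in seq_along(ann)) {
          cats <- resolve_terms(ann[[s]], th)$category
          for (u in which(cats == "M")) {
            cand[[length(cand) + 1L]] <- c(s, u)
          }
        }
        pick <- cand[[sample.int(length(cand), 1)]]
        old <- ann[[pick[1]]][pick[2]]
        sib <- sample(setdiff(m_terms, old), 1)
        ann[[pick[1]]][pick[2]] <- sib
        detail <- paste(old, "->", sib)
      }
      out[i] <- serialize_annotation(ann)
      log[[length(log) + 1L]] <- data.frame(
        index = i, edit = edit, detail = detail, stringsAsFactors = FALSE)
    }
    list(annotations = out,
         log = if (length(log)) do.call(rbind, log)
               else data.frame(index = integer(0), edit = character(0),
                               detail = character(0)))
  })
}

#' Top-k code occurrence share
#'
#' Fraction of all code occurrences (over all series of all clean
#' annotations) carried by the `k` most frequent codes.
#'
#' @param corpus a `synthetic_corpus` (or character vector of serialized
#'   annotations).
#' @param k number of top codes.
#' @return a fraction in \[0, 1\].
#' @export
top_code_share <- function(corpus, k) {
  anns <- if (inherits(corpus, "synthetic_corpus"))
    corpus$reports$annotation else corpus
  units <- unlist(lapply(anns, function(a) {
    unlist(parse_annotation(a), use.names = FALSE)
  }), use.names = FALSE)
  freq <- sort(table(units), decreasing = TRUE)
  sum(freq[seq_len(min(k, length(freq)))]) / sum(freq)
}

#' Write a synthetic corpus to a directory
#'
#' Writes `thesaurus.tsv`, `reports.jsonl`, `patients.tsv`,
#' `queries.json` and `noise_log.tsv`.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_thesaurus(corpus$thesaurus, file.path(dir, "thesaurus.tsv"))
  write_reports(corpus$reports, file.path(dir, "reports.jsonl"))
  utils::write.table(corpus$patients, file.path(dir, "patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qs <- lapply(corpus$queries, function(q) {
    list(name = q$query$name, clauses = q$query$clauses,
         truth_patients = q$truth_patients)
  })
  jsonlite::write_json(qs, file.path(dir, "queries.json"),
                       auto_unbox = TRUE)
  utils::write.table(corpus$noise_log, file.path(dir, "noise_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
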