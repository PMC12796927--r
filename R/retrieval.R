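# Case-based retrieval evaluation: run code queries against annotation
# sets, compare the patients/reports retrieved under original vs model
# annotations, and classify why a model missed a report.

#' Construct a code query
#'
#' A query is a disjunction of conjunctive clauses. A series matches a
#' clause iff it contains every clause member (order-free); a report
#' matches the query iff any of its series matches any clause. Members may
#' be terms or raw codes; with a thesaurus, either form of a unit matches.
#'
#' @param name query label.
#' @param clauses list of character vectors, each a non-empty set of
#'   required codes/terms.
#' @return list of class `code_query`.
#' @export
code_query <- function(name, clauses) {
  stopifnot(length(clauses) >= 1L,
            all(vapply(clauses, length, 1L) >= 1L))
  structure(list(name = name, clauses = lapply(clauses, as.character)),
            class = "code_query")
}

#' Read queries from JSON
#'
#' Format: an array of objects `{name, clauses: [[member, ...], ...]}`.
#' @param path JSON file.
#' @return list of `code_query` objects.
#' @export
read_queries <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(obj, function(q) {
    code_query(q$name, lapply(q$clauses, function(cl) unlist(cl)))
  })
}

# identifier set (normalized terms + codes) for a vector of series terms
series_identifiers <- function(terms, th = NULL) {
  ids <- norm_term(terms)
  if (!is.null(th)) {
    codes <- resolve_terms(terms, th)$code
    ids <- c(ids, codes[!is.na(codes)])
  }
  ids
}

query_member_ids <- function(member, th = NULL) {
  ids <- norm_term(member)
  if (!is.null(th)) {
    i <- match(member, th$code)
    if (!is.na(i)) ids <- c(ids, member, norm_term(th$term[i]))
    j <- match(norm_term(member), norm_term(th$term))
    if (!is.na(j)) ids <- c(ids, th$code[j])
  }
  unique(ids)
}

#' Does one annotation match a query?
#'
#' Report-level predicate underlying [run_query()].
#'
#' @param annotation serialized annotation string or `palga_annotation`.
#' @param query a [code_query()].
#' @param th optional `palga_thesaurus`.
#' @param across_series allow a clause to span series.
#' @return logical.
#' @export
annotation_matches_query <- function(annotation, query, th = NULL,
                                     across_series = FALSE) {
  ann <- if (inherits(annotation, "palga_annotation")) annotation
    else tryCatch(parse_annotation(annotation), error = function(e) NULL)
  if (is.null(ann)) return(FALSE)
  member_ids <- lapply(query$clauses, function(cl) {
    lapply(cl, query_member_ids, th = th)
  })
  unit_pool <- if (across_series) {
    list(series_identifiers(unlist(ann, use.names = FALSE), th))
  } else {
    lapply(ann, series_identifiers, th = th)
  }
  for (pool in unit_pool) {
    for (clause in member_ids) {
      hit <- all(vapply(clause, function(ids) any(ids %in% pool),
                        logical(1)))
      if (hit) return(TRUE)
    }
  }
  FALSE
}

#' Run a code query over annotated reports
#'
#' A patient is retrieved iff the query hits at least one of their reports.
#'
#' @param query a [code_query()].
#' @param reports data.frame of report records (`report_id`, `patient_id`).
#' @param annotations character vector of serialized annotations aligned
#'   with `reports` (defaults to `reports$annotation`).
#' @param th optional `palga_thesaurus` so terms and codes cross-match.
#' @param across_series if `TRUE`, a clause may be satisfied by codes from
#'   different series of the same report; by default a clause must
#'   co-occur within one series.
#' @return list with `report_ids` and `patient_ids` (character vectors).
#' @export
run_query <- function(query, reports, annotations = NULL, th = NULL,
                      across_series = FALSE) {
  if (is.null(annotations)) annotations <- reports$annotation
  stopifnot(length(annotations) == nrow(reports))
  hits <- vapply(annotations, annotation_matches_query, logical(1),
                 query = query, th = th, across_series = across_series,
                 USE.NAMES = FALSE)
  list(report_ids = reports$report_id[hits],
       patient_ids = unique(reports$patient_id[hits]))
}

#' Compare retrieval under original vs model annotations
#'
#' Computes the retrieved sets O (original annotations) and M (model
#' annotations) and their set algebra O\\M, M\\O and O&M at both patient
#' and report level.
#'
#' @param reports data.frame of report records.
#' @param original,model character vectors of serialized annotations
#'   aligned with `reports`.
#' @inheritParams run_query
#' @return list of class `retrieval_result` with per-level (`patients`,
#'   `reports`) sublists holding `O`, `M`, `O_only`, `M_only`, `both`
#'   (character sets) and matching counts `n_*`.
#' @export
compare_retrieval <- function(reports, original, model, query, th = NULL,
                              across_series = FALSE) {
  ro <- run_query(query, reports, original, th, across_series)
  rm_ <- run_query(query, reports, model, th, across_series)
  algebra <- function(O, M) {
    res <- list(O = O, M = M, O_only = setdiff(O, M),
                M_only = setdiff(M, O), both = intersect(O, M))
    counts <- lapply(res, length)
    names(counts) <- paste0("n_", names(res))
    c(res, counts)
  }
  structure(list(query = query$name,
                 patients = algebra(ro$patient_ids, rm_$patient_ids),
                 reports = algebra(ro$report_ids, rm_$report_ids)),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  p <- x$patients
  cat(sprintf(
    "<retrieval_result '%s': patients O=%d M=%d O\\M=%d M\\O=%d both=%d>\n",
    x$query, p$n_O, p$n_M, p$n_O_only, p$n_M_only, p$n_both))
  invisible(x)
}

#' Classify why a model missed a retrieved report
#'
#' A heuristic proxy for a manual audit of misses (reports retrieved by the
#' original annotations but not by the model's):
#' * `NO_CODES` -- the model produced no annotation at all;
#' * `ABSENCE_OF_RELEVANT_INFORMATION` -- no query member (nor its
#'   thesaurus synonym) occurs in the conclusion text;
#' * `ESSENTIAL_CODE_NOT_RECOGNIZED` -- the model output shares at least
#'   half of the reference's units but lacks a query-required code;
#' * `WRONG_CODES` -- anything else.
#'
#' @param report one-row data.frame (or list) with a `conclusion` field.
#' @param model_annotation the model's serialized annotation (may be
#'   empty).
#' @param query the [code_query()] that missed.
#' @param reference_annotation the original serialized annotation.
#' @param th optional `palga_thesaurus`.
#' @param overlap_threshold share of reference units the model must
#'   reproduce to count as "essential code not recognized" (default 0.5).
#' @return one of the four reason strings.
#' @export
classify_miss <- function(report, model_annotation, query,
                          reference_annotation, th = NULL,
                          overlap_threshold = 0.5) {
  if (annotation_matches_query(model_annotation, query, th)) {
    pathocode_error("NOT_A_MISS", "the model annotation matches the query")
  }
  model_units <- tryCatch(
    unlist(parse_annotation(model_annotation), use.names = FALSE),
    error = function(e) character(0))
  if (!length(model_units)) return("NO_CODES")

  members <- unique(unlist(lapply(query$clauses, function(cl) {
    unlist(lapply(cl, function(m) {
      ids <- norm_term(m)
      if (!is.null(th)) {
        i <- match(m, th$code)
        if (!is.na(i)) ids <- c(ids, norm_term(th$term[i]))
      }
      ids
    }))
  })))
  concl <- norm_term(report$conclusion)
  mentioned <- any(vapply(members, function(m) grepl(m, concl, fixed = TRUE),
                          logical(1)))
  if (!mentioned) return("ABSENCE_OF_RELEVANT_INFORMATION")

  ref_units <- tryCatch(
    unlist(parse_annotation(reference_annotation), use.names = FALSE),
    error = function(e) character(0))
  if (length(ref_units)) {
    mu <- table(norm_term(model_units))
    ru <- table(norm_term(ref_units))
    shared <- intersect(names(mu), names(ru))
    overlap <- sum(pmin(mu[shared], ru[shared])) / sum(ru)
    if (overlap >= overlap_threshold) return("ESSENTIAL_CODE_NOT_RECOGNIZED")
  }
  "WRONG_CODES"
}

#' Tally miss reasons over the reports missed by a model
#'
#' Applies [classify_miss()] to every report-level miss (in O\\M) of a
#' [compare_retrieval()] result.
#'
#' @inheritParams compare_retrieval
#' @param result a `retrieval_result` for the same inputs.
#' @return named integer vector over the four reasons.
#' @export
miss_reason_tally <- function(reports, original, model, query, result,
                              th = NULL) {
  reasons <- c("ABSENCE_OF_RELEVANT_INFORMATION",
               "ESSENTIAL_CODE_NOT_RECOGNIZED", "WRONG_CODES", "NO_CODES")
  tally <- stats::setNames(integer(length(reasons)), reasons)
  idx <- match(result$reports$O_only, reports$report_id)
  for (i in idx) {
    r <- classify_miss(reports[i, ], model[i], query, original[i], th)
    tally[r] <- tally[r] + 1L
  }
  tally
}
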