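# Category letters of the pathology thesaurus. T = topography, P = procedure;
# M (morphology), D (disease), E (etiology) and F (function) jointly form the
# diagnosis group.
CATEGORY_LETTERS <- c("T", "P", "M", "D", "E", "F")
DIAGNOSIS_CATEGORIES <- c("M", "D", "E", "F")

#' Special decoding tokens
#'
#' `EOS_TOKEN` marks the end of a generated code series; `SERIES_SEP_TOKEN`
#' optionally separates consecutive series in a single decoded sequence.
#' @export
EOS_TOKEN <- "<EOS>"

#' @rdname EOS_TOKEN
#' @export
SERIES_SEP_TOKEN <- "<SEP>"

pathocode_error <- function(code, message, ...) {
  stop(structure(
    class = c(code, "pathocode_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Construct a thesaurus table
#'
#' A thesaurus maps annotation terms to codes. Each row holds one code: the
#' raw code string (e.g. `"T01000"`), the display term (e.g. `"huid"`), and
#' the category letters of its atomic parts (e.g. `"T"`, or `"TP"` for a
#' combination code).
#'
#' @param code character vector of raw code strings.
#' @param term character vector of display terms, same length.
#' @param categories character vector of concatenated category letters per
#'   code (one letter per atomic part).
#' @return a `data.frame` of class `palga_thesaurus` with columns `code`,
#'   `term`, `categories`.
#' @export
thesaurus <- function(code, term, categories) {
  stopifnot(length(code) == length(term), length(term) == length(categories))
  df <- data.frame(code = as.character(code), term = as.character(term),
                   categories = as.character(categories),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$code)) {
    pathocode_error("DUPLICATE_CODE", "thesaurus codes must be unique")
  }
  class(df) <- c("palga_thesaurus", "data.frame")
  df
}

#' Read / write a thesaurus TSV
#'
#' The on-disk format is a tab-separated table with columns `code`, `term`,
#' `category_letters`.
#'
#' @param path file path.
#' @return `read_thesaurus` returns a `palga_thesaurus`.
#' @export
read_thesaurus <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  thesaurus(df$code, df$term, df$category_letters)
}

#' @rdname read_thesaurus
#' @param th a `palga_thesaurus`.
#' @export
write_thesaurus <- function(th, path) {
  out <- data.frame(code = th$code, term = th$term,
                    category_letters = th$categories)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

norm_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Resolve terms against a thesaurus
#'
#' Matching is case-insensitive and whitespace-normalized. Unknown terms get
#' `NA` code and category.
#'
#' @param terms character vector of annotation terms.
#' @param th a `palga_thesaurus`.
#' @return data.frame with columns `term`, `code`, `categories`, `category`
#'   (primary category = category of the first atomic part).
#' @export
resolve_terms <- function(terms, th) {
  idx <- match(norm_term(terms), norm_term(th$term))
  data.frame(
    term = terms,
    code = th$code[idx],
    categories = th$categories[idx],
    category = substr(th$categories[idx], 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Parse a raw thesaurus code
#'
#' Splits a (possibly combination) code into its atomic parts. An atomic part
#' is one category letter (`T`, `P`, `M`, `D`, `E`, `F`) followed by one or
#' more uppercase letters or digits. With a thesaurus, splitting is greedy
#' left-to-right, preferring the longest thesaurus-known code at each
#' position; without one, a new part starts at every category letter.
#'
#' @param raw raw code string, e.g. `"TYY980"` or `"T96000P11100"`.
#' @param th optional `palga_thesaurus` used for boundary detection and term
#'   lookup.
#' @param strict if `TRUE`, raise `UNKNOWN_CODE` when an atomic part is
#'   absent from the thesaurus.
#' @return a list of class `palga_code`: `raw`, `categories` (letter per
#'   part), `parts` (atomic code strings), `term` (display term or `NA`).
#' @export
parse_code <- function(raw, th = NULL, strict = FALSE) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    pathocode_error("MALFORMED_CODE", "empty or non-string code")
  }
  well_formed <- function(p) grepl("^[TPMDEF][A-Z0-9]+$", p)
  n <- nchar(raw)
  parts <- character(0)
  pos <- 1L
  while (pos <= n) {
    rest <- substr(raw, pos, n)
    part <- NULL
    if (!is.null(th)) {
      # longest thesaurus-known atomic code starting here
      cand <- th$code[nchar(th$categories) == 1L &
                        startsWith(rest, th$code)]
      if (length(cand)) part <- cand[which.max(nchar(cand))]
    }
    if (is.null(part)) {
      # maximal run up to (not including) the next category letter
      body <- substr(rest, 2, nchar(rest))
      nxt <- regexpr("[TPMDEF]", body)
      part <- if (nxt > 0) substr(rest, 1, nxt) else rest
    }
    if (!well_formed(part)) {
      pathocode_error("MALFORMED_CODE",
                      sprintf("malformed code part '%s' in '%s'", part, raw))
    }
    parts <- c(parts, part)
    pos <- pos + nchar(part)
  }
  if (paste(parts, collapse = "") != raw) {
    pathocode_error("MALFORMED_CODE", sprintf("cannot segment '%s'", raw))
  }
  if (strict && !is.null(th) && !all(parts %in% th$code)) {
    pathocode_error("UNKNOWN_CODE",
                    sprintf("unknown code part(s) in '%s'", raw))
  }
  term <- NA_character_
  if (!is.null(th)) {
    i <- match(raw, th$code)
    if (!is.na(i)) term <- th$term[i]
  }
  structure(
    list(raw = raw, categories = substr(parts, 1, 1), parts = parts,
         term = term),
    class = "palga_code"
  )
}

#' @export
print.palga_code <- function(x, ...) {
  cat(sprintf("<palga_code %s [%s]%s>\n", x$raw,
              paste(x$categories, collapse = ""),
              if (is.na(x$term)) "" else paste0(" ", x$term)))
  invisible(x)
}

#' Parse and serialize annotations
#'
#' An annotation is one or more code series. In serialized form, terms within
#' a series are separated by an asterisk and series by a newline. Leading and
#' trailing whitespace around each term is trimmed.
#'
#' @param text serialized annotation string.
#' @return `parse_annotation` returns a `palga_annotation`: a list of
#'   character vectors, one per series.
#' @examples
#' a <- parse_annotation("huid*excisie*dermale naevus")
#' serialize_annotation(a)
#' @export
parse_annotation <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    pathocode_error("EMPTY_SERIES", "empty annotation text")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  series <- lapply(lines, function(l) {
    terms <- trimws(strsplit(l, "*", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (!length(terms)) pathocode_error("EMPTY_SERIES", "series with no terms")
    terms
  })
  structure(series, class = "palga_annotation")
}

#' @rdname parse_annotation
#' @param a a `palga_annotation` (or plain list of term vectors).
#' @export
serialize_annotation <- function(a) {
  paste(vapply(a, paste, "", collapse = "*"), collapse = "\n")
}

#' @export
print.palga_annotation <- function(x, ...) {
  cat(serialize_annotation(x), "\n")
  invisible(x)
}

# Flatten a series of terms into per-part category letters, keeping the
# serial order of parts (combination codes contribute several parts).
# Returns NULL when any term is unresolvable.
series_part_categories <- function(terms, th) {
  res <- resolve_terms(terms, th)
  if (anyNA(res$categories)) return(NULL)
  unlist(strsplit(res$categories, ""), use.names = FALSE)
}

#' Validate a code series against the annotation rules
#'
#' A series must contain, in this order of first occurrence, at least one
#' topography (T), at least one procedure (P) -- waived for cytology reports
#' (`report_type = "C"`) -- and at least one diagnosis (M, D, E or F). Codes
#' after the first diagnosis are unrestricted. A combination code satisfies
#' each category it contains and its internal part order contributes to the
#' order check.
#'
#' @param terms character vector of terms forming one series.
#' @param report_type `"T"` (histology), `"C"` (cytology) or `"S"` (autopsy).
#' @param th a `palga_thesaurus` resolving each term's categories.
#' @return list of class `validation_result`: `valid` (logical) and
#'   `violations` (character vector drawn from `MISSING_TOPOGRAPHY`,
#'   `MISSING_PROCEDURE`, `MISSING_DIAGNOSIS`, `ORDER_VIOLATION`,
#'   `MALFORMED_CODE`, `EMPTY_SERIES`).
#' @export
validate_series <- function(terms, report_type, th) {
  stopifnot(report_type %in% c("T", "C", "S"))
  violations <- character(0)
  if (length(terms) == 0L) {
    violations <- "EMPTY_SERIES"
  } else {
    cats <- series_part_categories(terms, th)
    if (is.null(cats)) {
      violations <- "MALFORMED_CODE"
    } else {
      first_t <- match("T", cats)
      first_p <- match("P", cats)
      first_d <- suppressWarnings(min(match(DIAGNOSIS_CATEGORIES, cats),
                                      na.rm = TRUE))
      if (is.infinite(first_d)) first_d <- NA_integer_
      if (is.na(first_t)) violations <- c(violations, "MISSING_TOPOGRAPHY")
      if (is.na(first_p) && report_type != "C") {
        violations <- c(violations, "MISSING_PROCEDURE")
      }
      if (is.na(first_d)) violations <- c(violations, "MISSING_DIAGNOSIS")
      if (!is.na(first_t) && !is.na(first_d)) {
        ok <- if (!is.na(first_p)) {
          first_t < first_p && first_p < first_d
        } else {
          first_t < first_d
        }
        if (!ok) violations <- c(violations, "ORDER_VIOLATION")
      }
    }
  }
  structure(list(valid = length(violations) == 0L, violations = violations),
            class = "validation_result")
}

#' Validate every series of an annotation
#'
#' @param a a `palga_annotation`.
#' @inheritParams validate_series
#' @return logical: `TRUE` iff the annotation has at least one series and
#'   every series is valid.
#' @export
validate_annotation <- function(a, report_type, th) {
  length(a) >= 1L &&
    all(vapply(a, function(s) validate_series(s, report_type, th)$valid,
               logical(1)))
}

#' Read / write report records
#'
#' Reports are stored as JSON lines with fields `report_id`, `patient_id`,
#' `type` (T/C/S), `year`, `conclusion` and `annotation` (serialized in the
#' asterisk/newline dialect). `length_chars` is derived on read.
#'
#' @param path JSONL file path.
#' @return a data.frame with one row per report.
#' @export
read_reports <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(report_id = as.character(r$report_id),
               patient_id = as.character(r$patient_id),
               type = as.character(r$type),
               year = as.integer(r$year),
               conclusion = as.character(r$conclusion),
               annotation = as.character(r$annotation),
               stringsAsFactors = FALSE)
  }))
  if (!all(df$type %in% c("T", "C", "S"))) {
    pathocode_error("MALFORMED_CODE", "report type must be one of T, C, S")
  }
  df$length_chars <- nchar(df$conclusion)
  df
}

#' @rdname read_reports
#' @param reports data.frame of report records.
#' @export
write_reports <- function(reports, path) {
  cols <- c("report_id", "patient_id", "type", "year", "conclusion",
            "annotation")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    writeLines(jsonlite::toJSON(as.list(reports[i, cols]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
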