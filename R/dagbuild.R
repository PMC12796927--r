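# Constraint DAG over observed annotation sequences.
#
# Nodes are keyed by (phase, term, dedup_index) where phase is the state of
# the series rule machine after consuming the term:
#   TOPOGRAPHY -> no procedure or diagnosis seen yet
#   PROCEDURE  -> a procedure seen, no diagnosis yet
#   DIAGNOSIS  -> the term that introduces the first diagnosis
#   POST       -> anything after the first diagnosis
# Phase-keying lets the same term be shared across parents within a phase
# (e.g. a laterality term following two different topographies) while
# preventing the cycles that pure term-keying would allow. When an edge
# within a phase would still close a cycle, the successor is duplicated
# with an incremented dedup index.

DAG_PHASES <- c("ROOT", "TOPOGRAPHY", "PROCEDURE", "DIAGNOSIS", "POST")

next_phase <- function(cur_phase, cats) {
  if (cur_phase %in% c("DIAGNOSIS", "POST")) return("POST")
  if (any(cats %in% DIAGNOSIS_CATEGORIES)) return("DIAGNOSIS")
  if ("P" %in% cats || cur_phase == "PROCEDURE") return("PROCEDURE")
  "TOPOGRAPHY"
}

#' Build the annotation constraint DAG
#'
#' Inserts every rule-valid code series of the given annotations into a
#' rooted directed acyclic graph whose root-to-EOS paths are exactly the
#' permitted decoding outputs. Series that fail [validate_series()], contain
#' terms the thesaurus cannot resolve, or end on a term that cannot take an
#' EOS under `eos_policy` are rejected (counted, never raised).
#'
#' @param annotations list of [parse_annotation()] results, or a character
#'   vector of serialized annotation strings.
#' @param th a `palga_thesaurus`.
#' @param report_types optional character vector (one of `"T"`, `"C"`,
#'   `"S"` per annotation) used by the rule filter; defaults to `"T"`.
#' @param eos_policy `"M"` (EOS only after morphology terms, the default) or
#'   `"diagnosis"` (EOS after any of M, D, E, F).
#' @param series_sep if `TRUE`, record a series-separator edge after every
#'   non-final series of a multi-series annotation, allowing the decoder to
#'   emit several series in one sequence.
#' @return an object of class `annotation_dag`.
#' @export
build_dag <- function(annotations, th, report_types = NULL,
                      eos_policy = c("M", "diagnosis"), series_sep = FALSE) {
  eos_policy <- match.arg(eos_policy)
  eos_cats <- if (eos_policy == "M") "M" else DIAGNOSIS_CATEGORIES
  if (is.character(annotations)) {
    annotations <- lapply(annotations, parse_annotation)
  }
  if (is.null(report_types)) report_types <- rep("T", length(annotations))
  stopifnot(length(report_types) == length(annotations))

  # growable node store
  nodes <- new.env(parent = emptyenv())
  nodes$term <- NA_character_
  nodes$phase <- "ROOT"
  nodes$dedup <- 0L
  nodes$category <- NA_character_
  nodes$eos <- FALSE
  nodes$sep <- FALSE
  nodes$children <- list(integer(0))
  key2id <- new.env(parent = emptyenv())

  reachable <- function(from, target) {
    if (from == target) return(TRUE)
    stack <- from
    seen <- integer(0)
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (cur == target) return(TRUE)
      if (cur %in% seen) next
      seen <- c(seen, cur)
      stack <- c(stack, nodes$children[[cur]])
    }
    FALSE
  }

  new_node <- function(key, term, phase, dedup, category) {
    id <- length(nodes$term) + 1L
    nodes$term[id] <- term
    nodes$phase[id] <- phase
    nodes$dedup[id] <- dedup
    nodes$category[id] <- category
    nodes$eos[id] <- FALSE
    nodes$sep[id] <- FALSE
    nodes$children[[id]] <- integer(0)
    assign(key, id, envir = key2id)
    id
  }

  step <- function(cur, term, phase, category) {
    kids <- nodes$children[[cur]]
    hit <- kids[nodes$term[kids] == term & nodes$phase[kids] == phase]
    if (length(hit)) return(hit[[1]])
    dedup <- 0L
    repeat {
      key <- paste(phase, term, dedup, sep = "\r")
      id <- key2id[[key]]
      if (is.null(id)) {
        id <- new_node(key, term, phase, dedup, category)
        break
      }
      if (!reachable(id, cur)) break
      dedup <- dedup + 1L
    }
    nodes$children[[cur]] <- c(nodes$children[[cur]], id)
    id
  }

  inserted <- 0L
  rejected <- 0L
  for (i in seq_along(annotations)) {
    ann <- annotations[[i]]
    rtype <- report_types[[i]]
    n_series <- length(ann)
    accepted_ends <- integer(0)
    for (s in seq_len(n_series)) {
      terms <- ann[[s]]
      res <- resolve_terms(terms, th)
      vr <- validate_series(terms, rtype, th)
      final_ok <- !anyNA(res$category) &&
        res$category[length(terms)] %in% eos_cats
      if (!vr$valid || !final_ok) {
        rejected <- rejected + 1L
        next
      }
      cur <- 1L
      phase <- "ROOT"
      for (j in seq_along(terms)) {
        cats <- strsplit(res$categories[j], "")[[1]]
        phase <- next_phase(phase, cats)
        cur <- step(cur, terms[j], phase, res$category[j])
        if (res$category[j] %in% eos_cats) nodes$eos[cur] <- TRUE
      }
      inserted <- inserted + 1L
      accepted_ends <- c(accepted_ends, cur)
    }
    if (series_sep && length(accepted_ends) > 1L) {
      for (e in accepted_ends[-length(accepted_ends)]) nodes$sep[e] <- TRUE
    }
  }

  structure(
    list(term = nodes$term, phase = nodes$phase, dedup = nodes$dedup,
         category = nodes$category, eos_allowed = nodes$eos,
         sep_allowed = nodes$sep, children = nodes$children, root = 1L,
         source_count = inserted, rejected_count = rejected,
         eos_policy = eos_policy, series_sep = series_sep),
    class = "annotation_dag"
  )
}

#' @export
print.annotation_dag <- function(x, ...) {
  cat(sprintf(
    "<annotation_dag: %d nodes, %d series inserted, %d rejected, EOS policy %s%s>\n",
    length(x$term) - 1L, x$source_count, x$rejected_count, x$eos_policy,
    if (x$series_sep) ", series separator on" else ""))
  invisible(x)
}

# Walk a term prefix from the root; returns the node id or NA when the
# prefix leaves the graph. A series-separator token resets to root.
dag_traverse <- function(dag, prefix) {
  cur <- dag$root
  for (t in prefix) {
    if (dag$series_sep && identical(t, SERIES_SEP_TOKEN)) {
      if (!dag$sep_allowed[cur]) return(NA_integer_)
      cur <- dag$root
      next
    }
    kids <- dag$children[[cur]]
    hit <- kids[dag$term[kids] == t]
    if (!length(hit)) return(NA_integer_)
    cur <- hit[[1]]
  }
  cur
}

#' Valid continuations of a decoding prefix
#'
#' @param dag an `annotation_dag`.
#' @param prefix character vector of already-generated terms (possibly
#'   empty); may contain the series separator when the DAG was built with
#'   `series_sep = TRUE`.
#' @return character vector of allowed next units: child terms of the node
#'   reached by `prefix`, plus [EOS_TOKEN] when the node can end a series
#'   and [SERIES_SEP_TOKEN] when a further series may start.
#' @export
valid_continuations <- function(dag, prefix = character(0)) {
  cur <- dag_traverse(dag, prefix)
  if (is.na(cur)) {
    pathocode_error("UNREACHABLE_PREFIX",
                    paste("prefix not in DAG:", paste(prefix, collapse = "*")))
  }
  out <- dag$term[dag$children[[cur]]]
  if (dag$eos_allowed[cur]) out <- c(out, EOS_TOKEN)
  if (dag$series_sep && dag$sep_allowed[cur]) out <- c(out, SERIES_SEP_TOKEN)
  out
}

#' Can the DAG generate a sequence?
#'
#' `TRUE` iff the terms form a root path whose final node allows EOS.
#'
#' @inheritParams valid_continuations
#' @param sequence character vector of terms (without the EOS token).
#' @export
is_generatable <- function(dag, sequence) {
  if (!length(sequence)) return(FALSE)
  cur <- dag_traverse(dag, sequence)
  !is.na(cur) && dag$eos_allowed[cur]
}

#' Enumerate all complete sequences of a DAG
#'
#' Depth-first enumeration of root-to-EOS paths, children in insertion
#' order; at a node that allows EOS the path is emitted before descending.
#' Series-separator edges are not expanded: each returned sequence is a
#' single series.
#'
#' @inheritParams valid_continuations
#' @param max_count stop after this many sequences.
#' @return list of character vectors.
#' @export
enumerate_paths <- function(dag, max_count = 10000L) {
  stopifnot(max_count >= 1L)
  out <- vector("list", 0L)
  rec <- function(node, path) {
    if (length(out) >= max_count) return()
    if (dag$eos_allowed[node]) {
      out[[length(out) + 1L]] <<- path
      if (length(out) >= max_count) return()
    }
    for (child in dag$children[[node]]) {
      rec(child, c(path, dag$term[child]))
    }
  }
  rec(dag$root, character(0))
  out
}

#' Number of root-to-EOS paths
#'
#' Exact path count by memoized traversal (no enumeration), useful for
#' sizing beam widths.
#' @inheritParams valid_continuations
#' @export
count_paths <- function(dag) {
  memo <- rep(NA_real_, length(dag$term))
  rec <- function(node) {
    if (!is.na(memo[node])) return(memo[node])
    n <- as.numeric(dag$eos_allowed[node])
    for (child in dag$children[[node]]) n <- n + rec(child)
    memo[node] <<- n
    n
  }
  rec(dag$root)
}

#' Serialize / load a DAG as JSON
#'
#' Node-link format: a `nodes` array (id, term, phase, dedup, category,
#' eos_allowed, sep_allowed), an `edges` array of `[parent, child]` id
#' pairs in insertion order, the root id, and build metadata.
#'
#' @param dag an `annotation_dag`.
#' @param path output file.
#' @export
write_dag <- function(dag, path) {
  ids <- seq_along(dag$term)
  nodes <- data.frame(id = ids, term = dag$term, phase = dag$phase,
                      dedup = dag$dedup, category = dag$category,
                      eos_allowed = dag$eos_allowed,
                      sep_allowed = dag$sep_allowed)
  edges <- do.call(rbind, lapply(ids, function(i) {
    kids <- dag$children[[i]]
    if (!length(kids)) return(NULL)
    cbind(i, kids)
  }))
  obj <- list(nodes = nodes,
              edges = if (is.null(edges)) matrix(integer(0), ncol = 2)
                      else unname(edges),
              root = dag$root,
              meta = list(source_count = dag$source_count,
                          rejected_count = dag$rejected_count,
                          eos_policy = dag$eos_policy,
                          series_sep = dag$series_sep))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_dag
#' @export
read_dag <- function(path) {
  obj <- jsonlite::fromJSON(path)
  n <- nrow(obj$nodes)
  children <- rep(list(integer(0)), n)
  if (length(obj$edges)) {
    for (k in seq_len(nrow(obj$edges))) {
      p <- obj$edges[k, 1]
      children[[p]] <- c(children[[p]], obj$edges[k, 2])
    }
  }
  structure(
    list(term = as.character(obj$nodes$term), phase = obj$nodes$phase,
         dedup = as.integer(obj$nodes$dedup),
         category = as.character(obj$nodes$category),
         eos_allowed = obj$nodes$eos_allowed,
         sep_allowed = obj$nodes$sep_allowed, children = children,
         root = obj$root, source_count = obj$meta$source_count,
         rejected_count = obj$meta$rejected_count,
         eos_policy = obj$meta$eos_policy,
         series_sep = obj$meta$series_sep),
    class = "annotation_dag"
  )
}
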