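# Quantitative evaluation of predicted annotations: corpus BLEU with paired
# bootstrap significance, per-code precision/recall/F1 with cumulative
# frequency binning, length x type subgroup stratification, and
# edit-distance error rates.

# run code with a locally scoped RNG seed, restoring global state after
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Tokenize an annotation string for scoring
#'
#' Replaces the asterisk and newline separators with spaces, applies the
#' 13a-style international tokenization (punctuation split off, periods and
#' commas separated unless inside numbers), and splits on whitespace, so
#' that tokens are terms and the words of multiword terms.
#'
#' @param x character vector of annotation strings.
#' @return list of character token vectors.
#' @export
tokenize_annotation <- function(x) {
  x <- gsub("[*\n]", " ", x)
  x <- tok13a(x)
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

tok13a <- function(x) {
  x <- gsub("<skipped>", "", x, fixed = TRUE)
  x <- gsub("-\n", "", x, fixed = TRUE)
  x <- gsub("\n", " ", x, fixed = TRUE)
  x <- gsub("&quot;", "\"", x, fixed = TRUE)
  x <- gsub("&amp;", "&", x, fixed = TRUE)
  x <- gsub("&lt;", "<", x, fixed = TRUE)
  x <- gsub("&gt;", ">", x, fixed = TRUE)
  x <- paste0(" ", x, " ")
  # punctuation ranges of the v13a tokenizer
  x <- gsub("([\\{-\\~\\[-\\` -\\&\\(-\\+\\:-\\@/])", " \\1 ", x, perl = TRUE)
  x <- gsub("([^0-9])([\\.,])", "\\1 \\2 ", x, perl = TRUE)
  x <- gsub("([\\.,])([^0-9])", " \\1 \\2", x, perl = TRUE)
  x <- gsub("([0-9])(-)", "\\1 \\2 ", x, perl = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

ngram_counts <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(integer(0))
  grams <- vapply(seq_len(L - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "\x01")
  }, character(1))
  table(grams)
}

# Per-item sufficient statistics for BLEU-4: clipped match and total
# counts for n = 1..4, then hypothesis and reference length.
bleu_stats <- function(hyp_tokens, ref_tokens) {
  out <- numeric(10)
  for (n in 1:4) {
    hc <- ngram_counts(hyp_tokens, n)
    total <- sum(hc)
    correct <- 0
    if (total > 0) {
      rc <- ngram_counts(ref_tokens, n)
      shared <- intersect(names(hc), names(rc))
      if (length(shared)) {
        correct <- sum(pmin(as.numeric(hc[shared]), as.numeric(rc[shared])))
      }
    }
    out[n] <- correct
    out[4 + n] <- total
  }
  out[9] <- length(hyp_tokens)
  out[10] <- length(ref_tokens)
  out
}

bleu_stats_matrix <- function(hypotheses, references) {
  ht <- tokenize_annotation(hypotheses)
  rt <- tokenize_annotation(references)
  t(vapply(seq_along(ht), function(i) bleu_stats(ht[[i]], rt[[i]]),
           numeric(10)))
}

# BLEU from summed statistics, exponential smoothing of zero match counts
# (the floor doubles at each zero-count order, as in the mteval scorer).
bleu_from_stats <- function(s) {
  hyp_len <- s[9]
  ref_len <- s[10]
  if (hyp_len == 0) return(0)
  smooth <- 1
  logsum <- 0
  for (n in 1:4) {
    total <- s[4 + n]
    correct <- s[n]
    if (total == 0) {
      p <- 0
    } else if (correct == 0) {
      smooth <- smooth * 2
      p <- 100 / (smooth * total)
    } else {
      p <- 100 * correct / total
    }
    logsum <- logsum + (if (p > 0) log(p) else -9999999999)
  }
  bp <- if (hyp_len > ref_len) 1 else exp(1 - ref_len / hyp_len)
  bp * exp(logsum / 4)
}

check_aligned <- function(hypotheses, references) {
  if (length(hypotheses) != length(references)) {
    pathocode_error("LENGTH_MISMATCH",
                    "hypotheses and references differ in length")
  }
  if (!length(references)) {
    pathocode_error("EMPTY_CORPUS", "no hypothesis/reference pairs")
  }
}

#' Corpus BLEU over annotation strings
#'
#' BLEU-4 on the 0--100 scale with brevity penalty, 13a tokenization and
#' exponentially smoothed zero counts, computed after flattening each
#' annotation's separators to spaces.
#'
#' @param hypotheses,references character vectors of serialized annotation
#'   strings, aligned by report.
#' @return a single number in \[0, 100\].
#' @export
corpus_bleu <- function(hypotheses, references) {
  check_aligned(hypotheses, references)
  bleu_from_stats(colSums(bleu_stats_matrix(hypotheses, references)))
}

#' Paired bootstrap comparison of two systems' BLEU
#'
#' Resamples report indices with replacement `n_resamples` times and
#' recomputes corpus BLEU for both systems on each resample. The reported
#' confidence interval is the 95% percentile half-width; the p-value is the
#' two-sided paired bootstrap value: twice the fraction of resamples whose
#' BLEU difference contradicts (or zeroes) the full-data difference, capped
#' at 1.
#'
#' @param hyp_a,hyp_b hypothesis strings of systems A (reference system)
#'   and B.
#' @param references reference annotation strings.
#' @param n_resamples number of bootstrap resamples (>= 100).
#' @param seed RNG seed for the resampling (applied locally).
#' @param alpha significance level for the direction call.
#' @return list of class `comparison_result`: `bleu_a`, `bleu_b`,
#'   `ci_a`, `ci_b`, `n_items`, `p_value`, `direction` (`"+"`, `"-"` or
#'   `"n.s."`, the sign of B relative to A).
#' @export
paired_bootstrap <- function(hyp_a, hyp_b, references, n_resamples = 1000L,
                             seed = NULL, alpha = 0.05) {
  check_aligned(hyp_a, references)
  check_aligned(hyp_b, references)
  stopifnot(n_resamples >= 100L)
  n <- length(references)
  sa <- bleu_stats_matrix(hyp_a, references)
  sb <- bleu_stats_matrix(hyp_b, references)
  bleu_a <- bleu_from_stats(colSums(sa))
  bleu_b <- bleu_from_stats(colSums(sb))
  delta_full <- bleu_b - bleu_a

  counts <- with_local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                  nrow = n_resamples)
    tab <- apply(idx, 1, tabulate, nbins = n)
    if (n == 1L) matrix(tab, ncol = 1L) else t(tab)
  })
  agg_a <- counts %*% sa
  agg_b <- counts %*% sb
  boot_a <- apply(agg_a, 1, bleu_from_stats)
  boot_b <- apply(agg_b, 1, bleu_from_stats)

  ci <- function(v) unname(diff(stats::quantile(v, c(0.025, 0.975))) / 2)
  if (delta_full == 0) {
    p <- 1
  } else {
    contra <- mean((boot_b - boot_a) * sign(delta_full) <= 0)
    p <- min(1, 2 * contra)
  }
  direction <- if (p < alpha && delta_full > 0) "+"
    else if (p < alpha && delta_full < 0) "-" else "n.s."
  structure(list(bleu_a = bleu_a, bleu_b = bleu_b,
                 ci_a = ci(boot_a), ci_b = ci(boot_b), n_items = n,
                 p_value = p, direction = direction),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("A: %.1f +/- %.1f  B: %.1f +/- %.1f  (n=%d)  p=%.4g  %s\n",
              x$bleu_a, x$ci_a, x$bleu_b, x$ci_b, x$n_items, x$p_value,
              x$direction))
  invisible(x)
}

ann_units <- function(x, by = "term", th = NULL) {
  ann <- if (inherits(x, "palga_annotation")) x
    else tryCatch(parse_annotation(x), error = function(e) NULL)
  if (is.null(ann)) return(character(0))
  units <- unlist(ann, use.names = FALSE)
  if (by == "code") {
    stopifnot(!is.null(th))
    codes <- resolve_terms(units, th)$code
    units <- ifelse(is.na(codes), units, codes)
  }
  units
}

#' Per-code precision, recall and F1
#'
#' Each report's prediction and reference are reduced to multisets of
#' annotation units pooled over all series. Per code: `tp` is the summed
#' per-report minimum of predicted and reference counts, `fp` and `fn` the
#' summed surpluses; precision, recall and F1 come from these micro counts.
#'
#' @param predictions,references aligned vectors/lists of serialized
#'   annotations or `palga_annotation` objects.
#' @param by `"term"` (default) scores the term strings; `"code"` maps
#'   terms to their thesaurus codes first.
#' @param th `palga_thesaurus`, required for `by = "code"`.
#' @return data.frame of class `code_scores` with columns `code`,
#'   `support`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, sorted by
#'   decreasing support.
#' @export
per_code_scores <- function(predictions, references, by = c("term", "code"),
                            th = NULL) {
  by <- match.arg(by)
  if (length(predictions) != length(references)) {
    pathocode_error("LENGTH_MISMATCH",
                    "predictions and references differ in length")
  }
  tp <- new.env(parent = emptyenv())
  fp <- new.env(parent = emptyenv())
  fn <- new.env(parent = emptyenv())
  bump <- function(e, code, v) {
    if (v > 0) assign(code, (get0(code, envir = e, ifnotfound = 0)) + v, e)
  }
  for (i in seq_along(references)) {
    pu <- table(ann_units(predictions[[i]], by, th))
    ru <- table(ann_units(references[[i]], by, th))
    codes <- union(names(pu), names(ru))
    for (cd in codes) {
      p <- if (cd %in% names(pu)) pu[[cd]] else 0
      r <- if (cd %in% names(ru)) ru[[cd]] else 0
      bump(tp, cd, min(p, r))
      bump(fp, cd, max(0, p - r))
      bump(fn, cd, max(0, r - p))
    }
  }
  codes <- sort(unique(c(ls(tp), ls(fp), ls(fn))))
  g <- function(e, cd) get0(cd, envir = e, ifnotfound = 0)
  df <- do.call(rbind, lapply(codes, function(cd) {
    tpv <- g(tp, cd); fpv <- g(fp, cd); fnv <- g(fn, cd)
    prec <- if (tpv + fpv > 0) tpv / (tpv + fpv) else 0
    rec <- if (tpv + fnv > 0) tpv / (tpv + fnv) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(code = cd, support = tpv + fnv, tp = tpv, fp = fpv, fn = fnv,
               precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$support, df$code), ]
  rownames(df) <- NULL
  class(df) <- c("code_scores", "data.frame")
  df
}

#' Mean F1 in cumulative-frequency bins
#'
#' Codes are sorted by descending support and partitioned into `n_bins`
#' bins of (approximately) equal cumulative support share; a code falling
#' exactly on a boundary goes to the earlier bin. The most frequent codes
#' therefore concentrate in the first bins.
#'
#' @param scores a `code_scores` table from [per_code_scores()].
#' @param n_bins number of bins (default 20).
#' @return data.frame with `bin`, `n_codes`, `mean_f1`, `mean_support`,
#'   `total_support`.
#' @export
frequency_binned_f1 <- function(scores, n_bins = 20L) {
  stopifnot(n_bins >= 1L)
  sc <- scores[order(-scores$support, scores$code), ]
  sc <- sc[sc$support > 0, ]
  total <- sum(sc$support)
  width <- total / n_bins
  bin <- pmin(n_bins, ceiling(cumsum(sc$support) / width))
  agg <- lapply(sort(unique(bin)), function(b) {
    rows <- sc[bin == b, ]
    data.frame(bin = b, n_codes = nrow(rows), mean_f1 = mean(rows$f1),
               mean_support = mean(rows$support),
               total_support = sum(rows$support))
  })
  do.call(rbind, agg)
}

#' Report length bin
#'
#' Inclusive character bins 0--80, 81--200, 201--400 and 401+ on the
#' conclusion text length.
#' @param length_chars integer vector of conclusion character counts.
#' @return factor with levels `0-80`, `81-200`, `201-400`, `400+`.
#' @export
length_bin <- function(length_chars) {
  cut(length_chars, breaks = c(-1, 80, 200, 400, Inf),
      labels = c("0-80", "81-200", "201-400", "400+"))
}

#' Subgroup BLEU comparison by report type and length
#'
#' Splits the corpus into report type x length-bin cells (up to 3 x 4 = 12)
#' and runs [paired_bootstrap()] of every system against the named
#' reference system within each populated cell.
#'
#' @param reports data.frame of report records with `type`, `conclusion`
#'   and `annotation` columns.
#' @param predictions named list of character vectors (one serialized
#'   prediction per report, aligned with `reports`), one entry per system.
#' @param reference_system name of the baseline system in `predictions`.
#' @param n_resamples,seed bootstrap settings.
#' @return data.frame with one row per (type, bin, system): `count`,
#'   `bleu`, `ci`, and for non-reference systems `p_value` and
#'   `direction`. Empty cells carry `count = 0` and no statistics.
#' @export
subgroup_analysis <- function(reports, predictions, reference_system,
                              n_resamples = 1000L, seed = NULL) {
  stopifnot(reference_system %in% names(predictions))
  stopifnot(all(vapply(predictions, length, 1L) == nrow(reports)))
  bins <- length_bin(nchar(reports$conclusion))
  out <- list()
  cell_seed <- seed
  for (ty in c("T", "C", "S")) {
    for (b in levels(bins)) {
      sel <- which(reports$type == ty & bins == b)
      for (sys in names(predictions)) {
        row <- data.frame(type = ty, bin = b, system = sys,
                          count = length(sel), bleu = NA_real_,
                          ci = NA_real_, p_value = NA_real_,
                          direction = NA_character_,
                          stringsAsFactors = FALSE)
        if (length(sel)) {
          refs <- reports$annotation[sel]
          if (sys == reference_system) {
            row$bleu <- corpus_bleu(predictions[[sys]][sel], refs)
          } else {
            cmp <- paired_bootstrap(predictions[[reference_system]][sel],
                                    predictions[[sys]][sel], refs,
                                    n_resamples = n_resamples,
                                    seed = cell_seed)
            row$bleu <- cmp$bleu_b
            row$ci <- cmp$ci_b
            row$p_value <- cmp$p_value
            row$direction <- cmp$direction
          }
        }
        out[[length(out) + 1L]] <- row
      }
      if (!is.null(cell_seed)) cell_seed <- cell_seed + 1L
    }
  }
  do.call(rbind, out)
}

#' Edit-distance error rates
#'
#' Word error rate (WER), character error rate (CER), match error rate
#' (MER), word information lost (WIL) and preserved (WIP), computed on the
#' same tokenization as [corpus_bleu()] and aggregated over the corpus.
#'
#' @inheritParams corpus_bleu
#' @return named list `wer`, `cer`, `mer`, `wil`, `wip`.
#' @export
error_rate_metrics <- function(hypotheses, references) {
  check_aligned(hypotheses, references)
  ht <- tokenize_annotation(hypotheses)
  rt <- tokenize_annotation(references)
  S <- D <- I <- N <- P <- 0
  cer_edits <- cer_n <- 0
  for (i in seq_along(ht)) {
    vocab <- unique(c(rt[[i]], ht[[i]]))
    enc <- function(tok) {
      if (!length(tok)) return("")
      intToUtf8(match(tok, vocab) + 256L)
    }
    d <- utils::adist(enc(rt[[i]]), enc(ht[[i]]), counts = TRUE)
    cnt <- attr(d, "counts")[1, 1, ]
    I <- I + cnt[["ins"]]
    D <- D + cnt[["del"]]
    S <- S + cnt[["sub"]]
    N <- N + length(rt[[i]])
    P <- P + length(ht[[i]])
    rs <- paste(rt[[i]], collapse = " ")
    hs <- paste(ht[[i]], collapse = " ")
    cer_edits <- cer_edits + as.numeric(utils::adist(rs, hs))
    cer_n <- cer_n + nchar(rs)
  }
  H <- N - S - D
  wip <- if (N > 0 && P > 0) (H / N) * (H / P) else 0
  list(
    wer = if (N > 0) (S + D + I) / N else 0,
    cer = if (cer_n > 0) cer_edits / cer_n else 0,
    mer = if (H + S + D + I > 0) (S + D + I) / (H + S + D + I) else 0,
    wil = 1 - wip,
    wip = wip
  )
}
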