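mk_reports <- function(annotations, patients = NULL) {
  n <- length(annotations)
  data.frame(
    report_id = sprintf("r%02d", seq_len(n)),
    patient_id = if (is.null(patients)) sprintf("p%02d", seq_len(n))
                 else patients,
    type = "T", year = 2020, conclusion = paste("tekst", seq_len(n)),
    annotation = annotations, stringsAsFactors = FALSE)
}

test_that("clause matching is order-free within a single series", {
  q <- code_query("q", list(c("a", "b")))
  hit <- mk_reports("a*x*b")
  expect_equal(run_query(q, hit)$report_ids, "r01")
  # clause members split across two series do not match
  split <- mk_reports("a*p*m\nb*p*m")
  expect_length(run_query(q, split)$report_ids, 0)
  # unless across-series matching is requested
  expect_equal(run_query(q, split, across_series = TRUE)$report_ids, "r01")
  # disjunction over clauses
  q2 <- code_query("q2", list(c("zz"), c("x")))
  expect_equal(run_query(q2, hit)$report_ids, "r01")
})

test_that("a patient is retrieved when any of their reports matches", {
  q <- code_query("q", list("a"))
  reports <- mk_reports(c("x*y", "a*y"), patients = c("p1", "p1"))
  res <- run_query(q, reports)
  expect_equal(res$patient_ids, "p1")
  expect_equal(res$report_ids, "r02")
})

test_that("queries cross-match terms and codes through the thesaurus", {
  th <- fig_thesaurus()
  reports <- mk_reports("huid*biopt*ontsteking")
  by_code <- code_query("q", list("M40000"))
  expect_equal(run_query(by_code, reports, th = th)$report_ids, "r01")
  by_term <- code_query("q", list("ontsteking"))
  expect_equal(run_query(by_term, reports, th = th)$report_ids, "r01")
  expect_length(run_query(by_code, reports)$report_ids, 0)
})

test_that("retrieval comparison obeys the partition identities", {
  q <- code_query("q", list("a"))
  reports <- mk_reports(c("a*m", "a*m", "x*y"),
                        patients = c("p1", "p2", "p3"))
  original <- c("a*m", "a*m", "x*y")
  model <- c("a*m", "x*y", "a*m")   # p1 both, p2 original-only, p3 model-only
  res <- compare_retrieval(reports, original, model, q)
  p <- res$patients
  expect_equal(p$n_O, 2)
  expect_equal(p$n_M, 2)
  expect_equal(p$n_O_only, 1)
  expect_equal(p$n_M_only, 1)
  expect_equal(p$n_both, 1)
  expect_equal(p$n_O_only + p$n_both, p$n_O)
  expect_equal(p$n_M_only + p$n_both, p$n_M)
})

test_that("degenerate comparisons collapse as expected", {
  q <- code_query("q", list("a"))
  reports <- mk_reports(c("a*m", "b*m", "a*c"))
  same <- compare_retrieval(reports, reports$annotation,
                            reports$annotation, q)
  expect_length(same$patients$O_only, 0)
  expect_length(same$patients$M_only, 0)
  expect_setequal(same$patients$both, same$patients$O)

  empty <- compare_retrieval(reports, reports$annotation,
                             rep("", nrow(reports)), q)
  expect_length(empty$patients$M, 0)
  expect_setequal(empty$patients$O_only, empty$patients$O)
})

test_that("partition identities hold on randomized fixtures", {
  setup <- random_synth_setup(61)
  reports <- setup$corpus$reports
  for (entry in setup$corpus$queries) {
    res <- compare_retrieval(reports, reports$annotation,
                             reports$annotation_noised, entry$query,
                             th = setup$th)
    for (lvl in list(res$patients, res$reports)) {
      expect_equal(lvl$n_O_only + lvl$n_both, lvl$n_O)
      expect_equal(lvl$n_M_only + lvl$n_both, lvl$n_M)
    }
    # every matched patient owns at least one matched report
    hit <- run_query(entry$query, reports,
                     reports$annotation_noised, th = setup$th)
    owners <- unique(reports$patient_id[
      reports$report_id %in% hit$report_ids])
    expect_setequal(hit$patient_ids, owners)
    # ground truth recorded at generation time matches a fresh run
    expect_setequal(run_query(entry$query, reports,
                              th = setup$th)$patient_ids,
                    entry$truth_patients)
  }
})

test_that("query matching is monotone in the annotation", {
  set.seed(55)
  q <- code_query("q", list(c("a", "b")))
  for (i in 1:20) {
    terms <- sample(letters[1:6], sample(1:5, 1), replace = TRUE)
    ann <- paste(terms, collapse = "*")
    grown <- paste(c(terms, sample(letters[1:6], 2, TRUE)), collapse = "*")
    before <- annotation_matches_query(ann, q)
    after <- annotation_matches_query(grown, q)
    if (before) expect_true(after)
  }
})

test_that("miss classification follows the reason taxonomy", {
  th <- fig_thesaurus()
  q <- code_query("q", list("ontsteking"))
  report <- list(conclusion = "huid biopt met ontsteking")

  expect_equal(classify_miss(report, "", q, "huid*biopt*ontsteking", th),
               "NO_CODES")
  off_topic <- list(conclusion = "volledig andere tekst")
  expect_equal(
    classify_miss(off_topic, "huid*biopt*geen afwijking", q,
                  "huid*biopt*ontsteking", th),
    "ABSENCE_OF_RELEVANT_INFORMATION")
  # model reproduces the reference minus the single query code
  expect_equal(
    classify_miss(report, "huid*biopt*geen afwijking", q,
                  "huid*biopt*ontsteking*geen afwijking", th),
    "ESSENTIAL_CODE_NOT_RECOGNIZED")
  expect_equal(
    classify_miss(report, "pleura*excisie*dermale naevus", q,
                  "huid*biopt*ontsteking", th),
    "WRONG_CODES")
  expect_error(
    classify_miss(report, "huid*biopt*ontsteking", q,
                  "huid*biopt*ontsteking", th),
    class = "NOT_A_MISS")
})

test_that("miss-reason tallies cover exactly the report-level misses", {
  q <- code_query("q", list("a"))
  reports <- mk_reports(c("a*m", "a*n", "x*y", "a*z"))
  reports$conclusion <- c("bevat a", "niets relevants", "bevat a", "a hier")
  original <- reports$annotation
  model <- c("a*m", "b*c", "x*y", "")
  res <- compare_retrieval(reports, original, model, q)
  tally <- miss_reason_tally(reports, original, model, q, res)
  expect_equal(sum(tally), res$reports$n_O_only)
  expect_equal(unname(tally[["NO_CODES"]]), 1)
})

test_that("query JSON files round-trip", {
  qs <- list(code_query("first", list(c("a", "b"), "c")),
             code_query("second", list("d")))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(qs, function(q) list(name = q$name, clauses = q$clauses)),
    path, auto_unbox = TRUE)
  back <- read_queries(path)
  expect_equal(back[[1]]$name, "first")
  expect_equal(back[[1]]$clauses, list(c("a", "b"), "c"))
  expect_equal(back[[2]]$clauses, list("d"))
})
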