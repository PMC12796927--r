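test_that("a single training series builds the printed three-node chain", {
  dag <- build_dag(fig_annotations()[1], fig_thesaurus())
  # root + one node per term
  expect_equal(length(dag$term) - 1L, 3L)
  expect_equal(valid_continuations(dag), "huid")
  expect_equal(valid_continuations(dag, "huid"), "excisie")
  expect_equal(valid_continuations(dag, c("huid", "excisie")),
               "dermale naevus")
  expect_equal(
    valid_continuations(dag, c("huid", "excisie", "dermale naevus")),
    EOS_TOKEN)
  expect_length(enumerate_paths(dag), 1)
})

test_that("shared terms get one node per phase across different parents", {
  dag <- fig_dag()
  expect_setequal(valid_continuations(dag), c("huid", "pleura"))
  expect_setequal(valid_continuations(dag, "huid"), c("excisie", "links"))
  expect_setequal(valid_continuations(dag, c("huid", "links", "biopt")),
                  c("verruca seborrhoica", "geen afwijking"))
  expect_true(EOS_TOKEN %in% valid_continuations(
    dag, c("huid", "links", "biopt", "verruca seborrhoica")))
  # "links" is shared: one TOPOGRAPHY-phase node reachable from both roots
  expect_setequal(valid_continuations(dag, c("pleura", "links")), "biopt")
  expect_equal(length(enumerate_paths(dag)), 7)
  expect_error(valid_continuations(dag, c("huid", "biopt")),
               class = "UNREACHABLE_PREFIX")
})

test_that("rule-violating series are counted and leave the graph unchanged", {
  th <- fig_thesaurus()
  good <- fig_annotations()
  bad <- "biopt*huid*ontsteking"           # procedure before topography
  dag0 <- build_dag(good, th)
  dag1 <- build_dag(c(good, bad), th)
  expect_equal(dag1$rejected_count, dag0$rejected_count + 1L)
  expect_equal(dag1$source_count, dag0$source_count)
  expect_equal(dag1$term, dag0$term)
  expect_equal(dag1$children, dag0$children)
})

test_that("sequence generatability requires a full root-to-EOS path", {
  dag <- fig_dag()
  for (a in fig_annotations()) {
    expect_true(is_generatable(dag, parse_annotation(a)[[1]]))
  }
  expect_false(is_generatable(dag, c("huid", "biopt")))
  expect_false(is_generatable(dag, character(0)))
  # a valid prefix that stops before a diagnosis is not generatable
  expect_false(is_generatable(dag, c("huid", "links", "biopt")))
})

test_that("path enumeration truncates deterministically", {
  dag <- fig_dag()
  expect_length(enumerate_paths(dag, max_count = 2), 2)
  expect_identical(enumerate_paths(dag)[1:2], enumerate_paths(dag, 2))
  expect_equal(count_paths(dag), 7)
})

test_that("enumerated paths are sound and inserted series generatable", {
  for (seed in c(3, 17, 59)) {
    setup <- random_synth_setup(seed)
    reports <- setup$corpus$reports
    dag <- build_dag(reports$annotation, setup$th,
                     report_types = reports$type)
    expect_equal(dag$rejected_count, 0)
    paths <- enumerate_paths(dag, max_count = 400)
    waived <- any(reports$type == "C")
    for (p in paths) {
      expect_true(
        validate_series(p, if (waived) "C" else "T", setup$th)$valid,
        info = paste(seed, paste(p, collapse = "*")))
    }
    for (a in reports$annotation) {
      for (s in parse_annotation(a)) {
        expect_true(is_generatable(dag, s))
      }
    }
  }
})

test_that("the graph stays acyclic under randomized insertion orders", {
  skip_if_not_installed("igraph")
  setup <- random_synth_setup(23)
  anns <- setup$corpus$reports$annotation
  types <- setup$corpus$reports$type
  for (rep in 1:5) {
    set.seed(100 + rep)
    ord <- sample(seq_along(anns))
    dag <- build_dag(anns[ord], setup$th, report_types = types[ord])
    edges <- do.call(rbind, lapply(seq_along(dag$children), function(i) {
      kids <- dag$children[[i]]
      if (length(kids)) cbind(i, kids) else NULL
    }))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    expect_true(igraph::is_dag(g))
  }
})

test_that("within-phase repeat orderings are deduplicated, not cyclic", {
  skip_if_not_installed("igraph")
  th <- thesaurus(
    code = c("T10000", "T20000", "P10000", "M10000"),
    term = c("alfa", "beta", "biopt", "laesie"),
    categories = c("T", "T", "P", "M"))
  dag <- build_dag(c("alfa*beta*biopt*laesie", "beta*alfa*biopt*laesie"),
                   th)
  expect_true(is_generatable(dag, c("alfa", "beta", "biopt", "laesie")))
  expect_true(is_generatable(dag, c("beta", "alfa", "biopt", "laesie")))
  edges <- do.call(rbind, lapply(seq_along(dag$children), function(i) {
    kids <- dag$children[[i]]
    if (length(kids)) cbind(i, kids) else NULL
  }))
  expect_true(igraph::is_dag(
    igraph::graph_from_edgelist(edges, directed = TRUE)))
  # one of the two term nodes had to be duplicated
  expect_true(any(dag$dedup > 0))
})

test_that("inserting the same annotations twice changes nothing", {
  th <- fig_thesaurus()
  anns <- fig_annotations()
  d1 <- build_dag(anns, th)
  d2 <- build_dag(c(anns, anns), th)
  expect_equal(d2$term, d1$term)
  expect_equal(d2$children, d1$children)
  expect_equal(d2$eos_allowed, d1$eos_allowed)
  expect_equal(d2$source_count, 2L * d1$source_count)
})

test_that("every edge reflects an observed succession in some series", {
  setup <- random_synth_setup(31)
  anns <- setup$corpus$reports$annotation
  dag <- build_dag(anns, setup$th,
                   report_types = setup$corpus$reports$type)
  observed <- new.env(parent = emptyenv())
  for (a in anns) {
    for (s in parse_annotation(a)) {
      if (length(s) > 1) {
        for (j in seq_len(length(s) - 1)) {
          assign(paste(s[j], s[j + 1], sep = "\r"), TRUE, observed)
        }
      }
    }
  }
  for (i in seq_along(dag$children)) {
    if (i == dag$root) next
    for (k in dag$children[[i]]) {
      key <- paste(dag$term[i], dag$term[k], sep = "\r")
      expect_true(isTRUE(observed[[key]]), info = key)
    }
  }
})

test_that("EOS policy widens to D/E/F diagnoses when configured", {
  th <- thesaurus(
    code = c("T10000", "P10000", "M10000", "D10000"),
    term = c("huid", "biopt", "laesie", "lupus"),
    categories = c("T", "P", "M", "D"))
  ann <- "huid*biopt*lupus"
  strict <- build_dag(ann, th, eos_policy = "M")
  wide <- build_dag(ann, th, eos_policy = "diagnosis")
  # under the morphology-only policy the D-final series is filtered out
  expect_equal(strict$rejected_count, 1L)
  expect_false(is_generatable(strict, c("huid", "biopt", "lupus")))
  expect_equal(wide$rejected_count, 0L)
  expect_true(is_generatable(wide, c("huid", "biopt", "lupus")))
})

test_that("series separator support records restartable boundaries", {
  th <- fig_thesaurus()
  ann <- "huid*biopt*ontsteking\npleura*biopt*geen afwijking"
  dag <- build_dag(ann, th, series_sep = TRUE)
  cont <- valid_continuations(dag, c("huid", "biopt", "ontsteking"))
  expect_true(SERIES_SEP_TOKEN %in% cont)
  after_sep <- valid_continuations(
    dag, c("huid", "biopt", "ontsteking", SERIES_SEP_TOKEN))
  expect_setequal(after_sep, c("huid", "pleura"))
  expect_true(is_generatable(
    dag, c("huid", "biopt", "ontsteking", SERIES_SEP_TOKEN,
           "pleura", "biopt", "geen afwijking")))
  # off by default
  dag0 <- build_dag(ann, th)
  expect_false(SERIES_SEP_TOKEN %in%
                 valid_continuations(dag0, c("huid", "biopt", "ontsteking")))
})

test_that("DAG JSON serialization round-trips structure and metadata", {
  dag <- fig_dag()
  path <- withr::local_tempfile(fileext = ".json")
  write_dag(dag, path)
  back <- read_dag(path)
  expect_equal(back$term, dag$term)
  expect_equal(back$children, dag$children)
  expect_equal(back$eos_allowed, dag$eos_allowed)
  expect_equal(back$source_count, dag$source_count)
  expect_equal(lapply(enumerate_paths(back), identity),
               lapply(enumerate_paths(dag), identity))
})

test_that("adding a sequence never removes previously reachable outputs", {
  setup <- random_synth_setup(77)
  anns <- setup$corpus$reports$annotation[1:30]
  th <- setup$th
  types <- setup$corpus$reports$type[1:30]
  for (k in c(10, 20)) {
    before <- enumerate_paths(build_dag(anns[1:k], th, types[1:k]),
                              max_count = 500)
    after_dag <- build_dag(anns[1:(k + 5)], th, types[1:(k + 5)])
    for (p in before) {
      expect_true(is_generatable(after_dag, p))
    }
  }
})
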