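# Outcome lexicon construction and mention classification.

np_of <- function(..., head = NULL) {
  lem <- c(...)
  tibble::tibble(
    pmid = "t", sent_index = 0L, head_id = 1L,
    head_lemma = if (is.null(head)) lem[length(lem)] else head,
    lemmas = list(lem), surface = paste(lem, collapse = " "),
    start = 0L, end = 1L, provenance = "literal"
  )
}

classify_class <- function(lex, ...) {
  m <- classify_noun_phrase(np_of(...), lex)
  if (is.null(m)) NULL else list(class = m$outcome_class,
                                 negated = m$negated)
}

test_that("lexicon construction validates class assignments", {
  lex <- build_outcome_lexicon()
  expect_s3_class(lex, "outcome_lexicon")
  expect_true("cell" %in% lex$cell_terms)
  # a term in two primary classes is a hard error naming the term
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tclass\tmatch\tprovenance",
               "cell\tcell\tcomponent\tx",
               "growth\tproliferation\tcomponent\tx",
               "growth\tdeath\tcomponent\tx",
               "death\tdeath\tcomponent\tx"), bad)
  expect_error(build_outcome_lexicon(bad), "growth")
  # an empty primary class is a misconfiguration
  nodeath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tclass\tmatch\tprovenance",
               "cell\tcell\tcomponent\tx",
               "growth\tproliferation\tcomponent\tx"), nodeath)
  expect_error(build_outcome_lexicon(nodeath), "death")
})

test_that("combination, standalone and exclusion rules classify phrases", {
  lex <- test_outcome_lex()
  expect_equal(classify_class(lex, "necrotic", "cell", "death"),
               list(class = "death", negated = FALSE))
  expect_equal(classify_class(lex, "hepatocyte", "death"),
               list(class = "death", negated = FALSE))
  expect_equal(classify_class(lex, "apoptosis"),
               list(class = "death", negated = FALSE))
  # robust to extra modifiers (set semantics)
  expect_equal(classify_class(lex, "cultured", "gastric", "cancer", "cell",
                              "proliferation"),
               list(class = "proliferation", negated = FALSE))
  # exclusions always beat positive matches
  expect_null(classify_class(lex, "tumor", "necrosis", "factor"))
  expect_null(classify_class(lex, "cell", "death", "pathway"))
  expect_null(classify_class(lex, "peroxisome", "proliferation"))
  # cell term only -> general cell change
  expect_equal(classify_class(lex, "cancer", "cell")$class, "cell_general")
  expect_null(classify_class(lex, "liver", "tissue"))
})

test_that("outcome-level negation markers and anti- prefixes set the flag", {
  lex <- test_outcome_lex()
  expect_equal(classify_class(lex, "antiproliferative", "effect"),
               list(class = "proliferation", negated = TRUE))
  expect_equal(classify_class(lex, "cell", "growth", "inhibition"),
               list(class = "proliferation", negated = TRUE))
  expect_equal(classify_class(lex, "cell", "loss"),
               list(class = "proliferation", negated = TRUE))
  expect_equal(classify_class(lex, "antiapoptotic", "effect"),
               list(class = "death", negated = TRUE))
  # pro- strips without negating; arrest is death-class, not a negation
  expect_equal(classify_class(lex, "proapoptotic", "effect"),
               list(class = "death", negated = FALSE))
  expect_equal(classify_class(lex, "cell", "cycle", "arrest"),
               list(class = "death", negated = FALSE))
})

test_that("canonical top outcome expressions reproduce their classes and flags", {
  lex <- test_outcome_lex()
  # (lemmatized expression, expected class, expected negation flag)
  cases <- list(
    list(c("cell", "proliferation"), "proliferation", FALSE),
    list(c("cell", "growth"), "proliferation", FALSE),
    list(c("antiproliferative", "effect"), "proliferation", TRUE),
    list(c("antiproliferative", "activity"), "proliferation", TRUE),
    list(c("cellular", "proliferation"), "proliferation", FALSE),
    list(c("lymphocyte", "proliferation"), "proliferation", FALSE),
    list(c("mitotic", "index"), "proliferation", FALSE),
    list(c("tumor", "cell", "proliferation"), "proliferation", FALSE),
    list(c("t", "cell", "proliferation"), "proliferation", FALSE),
    list(c("cellular", "accumulation"), "proliferation", FALSE),
    list(c("hepatocyte", "proliferation"), "proliferation", FALSE),
    list(c("cell", "loss"), "proliferation", TRUE),
    list(c("cell", "growth", "inhibition"), "proliferation", TRUE),
    list(c("apoptosis"), "death", FALSE),
    list(c("cell", "death"), "death", FALSE),
    list(c("necrosis"), "death", FALSE),
    list(c("cell", "apoptosis"), "death", FALSE),
    list(c("cell", "cycle", "arrest"), "death", FALSE),
    list(c("apoptotic", "cell", "death"), "death", FALSE),
    list(c("apoptotic", "cell"), "death", FALSE),
    list(c("tumor", "necrosis"), "death", FALSE),
    list(c("program", "cell", "death"), "death", FALSE),
    list(c("apoptotic", "effect"), "death", FALSE),
    list(c("apoptosis", "induction"), "death", FALSE),
    list(c("antiapoptotic", "effect"), "death", TRUE),
    list(c("neuronal", "cell", "death"), "death", FALSE),
    list(c("apoptotic"), "death", FALSE),
    list(c("proapoptotic", "effect"), "death", FALSE),
    list(c("kill", "cell"), "death", FALSE),
    list(c("neuronal", "apoptosis"), "death", FALSE),
    list(c("acute", "tubular", "necrosis"), "death", FALSE)
  )
  for (cs in cases) {
    got <- do.call(classify_class, c(list(lex), as.list(cs[[1]])))
    expect_false(is.null(got), label = paste(cs[[1]], collapse = " "))
    expect_equal(got$class, cs[[2]],
                 label = paste(cs[[1]], collapse = " "))
    expect_equal(got$negated, cs[[3]],
                 label = paste0(paste(cs[[1]], collapse = " "), " negation"))
  }
})

test_that("classification is order-insensitive to modifier permutation", {
  lex <- test_outcome_lex()
  perms <- list(c("necrotic", "cell", "death"),
                c("death", "necrotic", "cell"),
                c("cell", "death", "necrotic"))
  res <- lapply(perms, function(p) {
    do.call(classify_class, c(list(lex), as.list(p)))
  })
  expect_true(all(vapply(res, function(r) r$class == "death", TRUE)))
})

test_that("prepositional constructions yield governor_dependent mentions", {
  lex <- test_outcome_lex()
  m5 <- detect_prepositional_outcome(parse_sent5(), lex)
  expect_equal(nrow(m5), 1L)
  expect_equal(m5$outcome_class, "proliferation")
  expect_false(m5$negated)
  expect_equal(m5$form, "proliferation_cultured gastric cancer cell")
  # loss of <cells> is a negated proliferation outcome
  ploss <- pt(
    "loss|loss|NOUN|0|root",
    "of|of|ADP|4|case",
    "dopaminergic|dopaminergic|ADJ|4|amod",
    "neurons|neuron|NOUN|1|nmod"
  )
  ml <- detect_prepositional_outcome(ploss, lex)
  expect_equal(ml$outcome_class, "proliferation")
  expect_true(ml$negated)
  expect_equal(ml$form, "loss_dopaminergic neuron")
  # growth of non-cell material is not an outcome
  m5all <- find_outcome_mentions(parse_sent5(), lex)
  expect_false(any(grepl("xenograft", m5all$form)))
})
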