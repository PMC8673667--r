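# Anchor lexicon expansion, anchor matching, claim-level negation, claim
# extraction and the change-in-cells reapplication rule.

test_that("anchor config loads with the documented category sizes", {
  cfg <- read_anchor_config()
  counts <- anchor_category_counts(cfg)
  expect_setequal(counts$category,
                  c("increase", "decrease", "general_change", "causality"))
  # an unknown category token is a hard error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("base\tcategory", "wibble\tsideways"), bad)
  expect_error(read_anchor_config(bad), "sideways")
})

test_that("base verbs expand to tenses and nominalizations", {
  lex <- expand_anchor_lexicon(tibble::tibble(
    base = c("inhibit", "induce", "grow", "stimulate", "lose"),
    category = c("decrease", "increase", "increase", "increase", "decrease")
  ))
  forms_of <- function(b) lex$forms$form[lex$forms$base == b]
  expect_true(all(c("inhibit", "inhibits", "inhibited", "inhibiting",
                    "inhibition") %in% forms_of("inhibit")))
  expect_true("induction" %in% forms_of("induce"))
  expect_true(all(c("growth", "grew", "grown") %in% forms_of("grow")))
  expect_true("stimulation" %in% forms_of("stimulate"))
  expect_true("loss" %in% forms_of("lose"))
  # deterministic
  lex2 <- expand_anchor_lexicon(lex$entries)
  expect_equal(lex$forms, lex2$forms)
})

test_that("anchor occurrences carry base and category", {
  alex <- test_anchor_lex()
  occ <- match_anchors(parse_sent7(), alex)
  expect_setequal(occ$base[occ$form %in% c("attenuates", "triggered")],
                  c("attenuate", "trigger"))
  expect_equal(occ$category[occ$base == "attenuate"], "decrease")
  expect_equal(occ$category[occ$base == "trigger"], "increase")
  empty <- pt("Cells|cell|NOUN|2|nsubj", "sleep|sleep|VERB|0|root")
  expect_equal(nrow(match_anchors(empty, alex)), 0L)
})

test_that("claim-level negation covers cue constructions", {
  # neither ... nor on the anchor's subject
  p3 <- parse_sent3()
  a3 <- match_anchors(p3, test_anchor_lex())
  expect_true(detect_claim_negation(p3, a3$id[a3$base == "inhibit"]))
  # failed to <verb>
  pf <- pt(
    "It|it|PRON|2|nsubj", "failed|fail|VERB|0|root", "to|to|PART|4|mark",
    "stimulate|stimulate|VERB|2|xcomp", "growth|growth|NOUN|4|obj")
  expect_true(detect_claim_negation(pf, 4L))
  # plain anchor is not negated
  p6 <- parse_sent6()
  a6 <- match_anchors(p6, test_anchor_lex())
  expect_false(detect_claim_negation(p6, a6$id[a6$base == "inhibit"]))
})

test_that("worked sentences yield their documented claims", {
  olex <- test_outcome_lex()
  alex <- test_anchor_lex()

  # one sentence can carry two claims of opposite direction on one outcome
  c7 <- sentence_claims(parse_sent7(), olex, alex)
  expect_equal(nrow(c7), 2L)
  expect_setequal(c7$anchor_base, c("attenuate", "trigger"))
  expect_true(all(c7$outcome_class == "death"))
  d7 <- reconcile_direction(c7$polarity, c7$claim_negated,
                            c7$outcome_negated)
  expect_setequal(as.character(d7), c("Refute", "Support"))

  # prepositional outcome with a direct path to the anchor
  c6 <- sentence_claims(parse_sent6(), olex, alex)
  expect_equal(nrow(c6), 1L)
  expect_equal(c6$outcome_class, "proliferation")
  expect_equal(c6$path_kind, "direct")
  expect_equal(as.character(reconcile_direction(
    c6$polarity, c6$claim_negated, c6$outcome_negated)), "Refute")

  # negated refuting evidence through a coordinated subject
  c3 <- sentence_claims(parse_sent3(), olex, alex)
  expect_equal(nrow(c3), 1L)
  expect_true(c3$claim_negated)
  expect_equal(as.character(reconcile_direction(
    c3$polarity, c3$claim_negated, c3$outcome_negated)), "NegatedRefute")

  # observation: no agent phrase
  co <- sentence_claims(parse_observation(), olex, alex)
  co <- co[co$outcome_class == "proliferation", ]
  expect_equal(co$claim_type, "observation")
  expect_equal(co$polarity, "up")

  # anchors with no reachable mention yield nothing
  lone <- pt("Enzyme|enzyme|NOUN|2|nsubj",
             "increased|increase|VERB|0|root",
             "activity|activity|NOUN|2|obj")
  expect_equal(nrow(sentence_claims(lone, olex, alex)), 0L)
})

test_that("claim extraction is monotone in the anchor lexicon", {
  olex <- test_outcome_lex()
  small <- expand_anchor_lexicon(tibble::tibble(
    base = "inhibit", category = "decrease"))
  full <- test_anchor_lex()
  for (p in list(parse_sent6(), parse_sent7(), parse_sent3())) {
    m <- find_outcome_mentions(p, olex)
    a <- extract_claims(p, m, small)
    b <- extract_claims(p, m, full)
    key <- function(x) paste(x$anchor_base, x$mention_head_id)
    expect_true(all(key(a) %in% key(b)))
  }
})

test_that("the reapplication rule derives primary outcomes from cell changes", {
  olex <- test_outcome_lex()
  alex <- test_anchor_lex()
  # an increase in cells is captured as supporting cell proliferation
  up <- pt(
    "Results|result|NOUN|2|nsubj", "showed|show|VERB|0|root",
    "an|a|DET|4|det", "increase|increase|NOUN|2|obj",
    "in|in|ADP|6|case", "cells|cell|NOUN|4|nmod", ".|.|PUNCT|2|punct")
  cu <- sentence_claims(up, olex, alex)
  expect_equal(cu$outcome_class, "proliferation")
  expect_equal(cu$outcome_form, "increase_cell")
  expect_equal(cu$syntactic_form, "derived_from_change")
  expect_equal(as.character(reconcile_direction(
    cu$polarity, cu$claim_negated, cu$outcome_negated)), "Support")
  # a decrease in cells is captured as supporting cell death
  dn <- pt(
    "Results|result|NOUN|2|nsubj", "showed|show|VERB|0|root",
    "a|a|DET|4|det", "decrease|decrease|NOUN|2|obj",
    "in|in|ADP|6|case", "hepatocytes|hepatocyte|NOUN|4|nmod",
    ".|.|PUNCT|2|punct")
  cd <- sentence_claims(dn, olex, alex)
  expect_equal(cd$outcome_class, "death")
  expect_equal(as.character(reconcile_direction(
    cd$polarity, cd$claim_negated, cd$outcome_negated)), "Support")
  # an outer anchor acting on the derived mention takes over the claim
  outer <- pt(
    "It|it|PRON|2|nsubj", "inhibited|inhibit|VERB|0|root",
    "the|the|DET|4|det", "increase|increase|NOUN|2|obj",
    "in|in|ADP|6|case", "cells|cell|NOUN|4|nmod", ".|.|PUNCT|2|punct")
  co <- sentence_claims(outer, olex, alex)
  expect_equal(nrow(co), 1L)
  expect_equal(co$anchor_base, "inhibit")
  expect_equal(co$outcome_class, "proliferation")
  expect_equal(as.character(reconcile_direction(
    co$polarity, co$claim_negated, co$outcome_negated)), "Refute")
  # neutral changes on cells stay general; reapplication is idempotent
  nc <- pt(
    "It|it|PRON|2|nsubj", "affected|affect|VERB|0|root",
    "the|the|DET|4|det", "cells|cell|NOUN|2|obj", ".|.|PUNCT|2|punct")
  cn <- sentence_claims(nc, olex, alex)
  expect_equal(cn$outcome_class, "cell_general")
  again <- apply_reapplication_rule(cn, nc, alex)
  expect_equal(nrow(again), nrow(cn))
})

test_that("measurement nominals bridge anchors to outcomes", {
  olex <- test_outcome_lex()
  alex <- test_anchor_lex()
  p <- pt(
    "Cadmium|cadmium|PROPN|2|nsubj", "increased|increase|VERB|0|root",
    "the|the|DET|4|det", "amount|amount|NOUN|2|obj",
    "of|of|ADP|7|case", "cell|cell|NOUN|7|compound",
    "death|death|NOUN|4|nmod", ".|.|PUNCT|2|punct")
  cl <- sentence_claims(p, olex, alex)
  expect_equal(cl$path_kind, "measurement")
  expect_equal(cl$outcome_class, "death")
  expect_equal(cl$claim_type, "explicit")
})
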