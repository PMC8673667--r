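# Normalization, segmentation, itemized-list expansion, parse plumbing.

test_that("normalize_text strips accents and carons and is idempotent", {
  expect_equal(normalize_text("café"), "cafe")
  expect_equal(normalize_text("ASCII stays."), "ASCII stays.")
  # brute-force per-character oracle over the shipped mapping table
  tbl <- claimscope:::ascii_fold_table()
  fold1 <- function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(vapply(chars, function(ch) {
      if (ch %in% names(tbl)) tbl[[ch]] else ch
    }, ""), collapse = "")
  }
  for (s in c("Kočí", "naïve", "Müller–Świątek", "β-catenin")) {
    expect_equal(normalize_text(s), fold1(s))
  }
  expect_equal(normalize_text("Kočí"), "Koci")
  expect_equal(normalize_text(normalize_text("Kočí—naïve")),
               normalize_text("Kočí—naïve"))
})

test_that("sentence segmentation respects biomedical abbreviations", {
  expect_length(segment_sentences("Cells died. Proliferation rose."), 2L)
  expect_length(segment_sentences("Smith et al. found apoptosis."), 1L)
  expect_length(
    segment_sentences("Dosing was i.v. Daily checks followed."), 1L)
  expect_length(
    segment_sentences("See Fig. 2 for details. Growth fell."), 2L)
  three <- "First one. Second one! Third one?"
  units <- segment_sentences(three)
  expect_equal(units, c("First one.", "Second one!", "Third one?"))
})

test_that("segment_abstract assigns contiguous 0-based indices", {
  rec <- tibble::tibble(
    pmid = "p1", title = "", language = "eng",
    sections = list(tibble::tibble(
      label = c("background", "results"),
      text = c("One here. Two here.", "Three here.")
    )),
    chemicals = list(character())
  )
  sents <- segment_abstract(rec)
  expect_equal(sents$index, 0:2)
  expect_equal(sents$section_label, c("background", "background", "results"))
})

test_that("itemized lists expand into preamble plus items", {
  # numbered list with a preamble
  s <- paste0(
    "Four categories represented a positive correlation: ",
    "(1) increasing abnormal CEA with progressing disease, ",
    "(2) decreasing abnormal CEA with disease regression, ",
    "(3) unchanged abnormal CEA with stable disease, ",
    "(4) change from normal to abnormal CEA with progressive disease.")
  out <- expand_itemized_list(s)
  expect_length(out, 5L)
  expect_equal(out[1], "Four categories represented a positive correlation")
  expect_match(out[2], "^increasing abnormal CEA")
  expect_match(out[5], "^change from normal")
  # no markers: identity
  expect_equal(expand_itemized_list("No markers here."), "No markers here.")
  # alphabetic series with empty preamble
  ab <- expand_itemized_list("(a) growth rose, (b) death fell")
  expect_equal(ab, c("growth rose", "death fell"))
  # a lone marker never fires
  expect_equal(expand_itemized_list("Only (1) one item."),
               "Only (1) one item.")
})

test_that("list expansion loses no characters beyond markers/separators", {
  cases <- c(
    "Preamble: (1) alpha beta, (2) gamma delta, (3) epsilon.",
    "(a) first part; (b) second part; (c) third part.",
    "(i) one, (ii) two."
  )
  for (s in cases) {
    out <- expand_itemized_list(s)
    kept <- gsub("[^a-z]", "", tolower(paste(out, collapse = " ")))
    # residue of the original after dropping the marker letters themselves
    src <- gsub("\\((?:\\d+|[a-h]|i{1,3}|iv|v)\\)", "", s)
    src <- gsub("[^a-z]", "", tolower(src))
    expect_equal(kept, src, label = s)
  }
})

test_that("parse construction enforces single root and ordered spans", {
  p <- parse_from_tokens(c(
    "Cells|cell|NOUN|2|nsubj",
    "grew|grow|VERB|0|root",
    ".|.|PUNCT|2|punct"
  ))
  expect_s3_class(p, "parsed_sentence")
  expect_equal(sum(p$tokens$head == 0L), 1L)
  expect_equal(p$text, "Cells grew.")
  expect_equal(p$tokens$start, c(0L, 6L, 10L))
  expect_error(
    parse_from_tokens(c("a|a|DET|0|root", "b|b|NOUN|0|root")),
    "exactly one root")
})

test_that("CoNLL-U round trip preserves parses; gold backend looks up", {
  fx <- generate_fixtures(random_fixture_spec(n_abstracts = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(fx$parses, path)
  back <- read_conllu(path)
  expect_setequal(names(back), names(fx$parses))
  k <- names(fx$parses)[1]
  expect_equal(back[[k]]$tokens, fx$parses[[k]]$tokens)
  expect_equal(back[[k]]$text, fx$parses[[k]]$text)
  backend <- gold_parse_backend(path)
  sent <- list(pmid = fx$parses[[k]]$pmid, index = fx$parses[[k]]$index,
               section_label = "results")
  expect_equal(parse_dependencies(sent, backend)$tokens,
               fx$parses[[k]]$tokens)
  expect_error(parse_dependencies(sent, NULL), "gold_parse_backend")
  expect_error(backend(list(pmid = "nope", index = 99L)), "no gold parse")
})

test_that("Stanford-style labels normalize to the canonical dialect", {
  expect_equal(normalize_deprel(c("dobj", "nsubjpass", "prep_of",
                                  "conj_and", "nn", "nsubj:pass")),
               c("obj", "nsubj_pass", "nmod", "conj", "compound",
                 "nsubj_pass"))
})
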