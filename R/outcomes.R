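# Target-outcome lexicon and outcome-mention classification.
#
# The two primary outcomes are cell proliferation (an increase in the number
# of cells through growth and division) and cell death (including apoptotic
# and necrotic expressions); the secondary outcome captures any other cell
# change. Multi-word outcome expressions are deconstructed into <cell> x
# <proliferation> / <cell> x <death> component sets, so a phrase matches when
# it contains at least one cell term and one proliferation (or death) term,
# which makes matching robust to additional modifiers. Single-word
# expressions (e.g. "apoptosis") match standalone. Exclusion filters veto
# pathway / factor- / peroxisom- phrases so e.g. "tumor necrosis factor" is
# never an outcome.

#' Build the target-outcome lexicon
#'
#' Assembles the component term sets (cell / proliferation / death),
#' standalone single-word (and fixed multi-word) expressions, exclusion
#' filters and outcome-level negation markers from a TSV file with columns
#' `term`, `class`, `match` (`component` or `standalone`) and `provenance`.
#' The shipped seed file collects every outcome expression the packaged rule
#' set is documented against plus standard synonyms; it is configuration,
#' meant to be extended for a new corpus.
#'
#' @param path Path to the lexicon TSV (defaults to the shipped seed file).
#' @param exclusion_substrings Phrase-level veto substrings.
#' @param exclusion_prefixes Word-prefix vetoes.
#' @param negation_markers Lemmas that negate an outcome from inside the
#'   phrase (second negation level; e.g. "loss", "inhibition"). Note
#'   "arrest" is deliberately not a marker: cell-cycle-arrest expressions are
#'   death-class outcomes, not negations.
#' @param negation_prefixes Prefixes that negate (default `"anti"`).
#' @param neutral_prefixes Prefixes stripped without negating (default
#'   `"pro"`, so "proapoptotic" is a plain death-class match).
#' @return Object of class `outcome_lexicon`.
#' @export
build_outcome_lexicon <- function(path = cs_extdata("outcome_terms.tsv"),
                                  exclusion_substrings = c("pathway",
                                                           "pathways"),
                                  exclusion_prefixes = c("factor",
                                                         "peroxisom"),
                                  negation_markers = c("loss", "inhibition"),
                                  negation_prefixes = "anti",
                                  neutral_prefixes = "pro") {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("term", "class", "match") %in% names(raw)))
  raw$term <- str_to_lower(raw$term)
  comp <- raw[raw$match == "component", ]
  classes <- c("cell", "proliferation", "death")
  sets <- map(classes, ~ unique(comp$term[comp$class == .x])) |>
    setNames(classes)
  for (cl in c("proliferation", "death")) {
    if (!length(sets[[cl]])) {
      abort(paste0("outcome lexicon has no ", cl, " terms"))
    }
  }
  if (!length(sets$cell)) abort("outcome lexicon has no cell terms")
  dup <- intersect(sets$proliferation, sets$death)
  dup <- c(dup, intersect(sets$cell, c(sets$proliferation, sets$death)))
  if (length(dup)) {
    abort(paste0("term(s) assigned to two primary classes: ",
                 paste(unique(dup), collapse = ", ")))
  }
  standalone <- raw[raw$match == "standalone", ]
  if (anyDuplicated(standalone$term)) {
    abort("duplicate standalone terms in outcome lexicon")
  }
  structure(
    list(
      cell_terms = sets$cell,
      proliferation_terms = sets$proliferation,
      death_terms = sets$death,
      standalone = setNames(standalone$class, standalone$term),
      exclusion_substrings = exclusion_substrings,
      exclusion_prefixes = exclusion_prefixes,
      negation_markers = negation_markers,
      negation_prefixes = negation_prefixes,
      neutral_prefixes = neutral_prefixes
    ),
    class = "outcome_lexicon"
  )
}

empty_mentions <- function() {
  tibble(pmid = character(), sent_index = integer(), head_id = integer(),
         outcome_class = character(), negated = logical(),
         syntactic_form = character(), form = character(),
         surface = character())
}

# strip a negating/neutral prefix and look the remainder up in the primary
# class sets; returns list(class=..., negated=...) or NULL
prefix_match <- function(lemma, lex) {
  prim <- function(x) {
    if (x %in% lex$proliferation_terms ||
        identical(unname(lex$standalone[x]), "proliferation")) {
      return("proliferation")
    }
    if (x %in% lex$death_terms ||
        identical(unname(lex$standalone[x]), "death")) {
      return("death")
    }
    NULL
  }
  for (pre in lex$negation_prefixes) {
    if (str_starts(lemma, pre) && nchar(lemma) > nchar(pre)) {
      stem <- str_sub(lemma, nchar(pre) + 1L)
      stem <- str_replace_all(stem, "^-", "")
      cl <- prim(stem)
      if (!is.null(cl)) return(list(class = cl, negated = TRUE))
    }
  }
  for (pre in lex$neutral_prefixes) {
    if (str_starts(lemma, pre) && nchar(lemma) > nchar(pre)) {
      stem <- str_replace_all(str_sub(lemma, nchar(pre) + 1L), "^-", "")
      cl <- prim(stem)
      if (!is.null(cl)) return(list(class = cl, negated = FALSE))
    }
  }
  NULL
}

classify_lemmas <- function(lemmas, lex) {
  lemmas <- str_to_lower(lemmas)
  # exclusions always win over any positive match
  if (any(map_lgl(lemmas, function(l) {
    any(str_detect(l, fixed(lex$exclusion_substrings)))
  }))) {
    return(NULL)
  }
  if (any(map_lgl(lemmas, function(l) {
    any(str_starts(l, lex$exclusion_prefixes))
  }))) {
    return(NULL)
  }
  negated <- any(lemmas %in% lex$negation_markers)
  phrase <- paste(lemmas, collapse = " ")
  # standalone expressions (single- or fixed multi-word)
  for (term in names(lex$standalone)) {
    hit <- if (str_detect(term, " ")) {
      str_detect(phrase, regex(paste0("\\b", escape_regex(term), "\\b")))
    } else {
      term %in% lemmas
    }
    if (hit) {
      return(list(class = unname(lex$standalone[term]), negated = negated))
    }
  }
  # anti-/pro- prefixed forms of primary terms
  for (l in lemmas) {
    pm <- prefix_match(l, lex)
    if (!is.null(pm)) {
      return(list(class = pm$class, negated = negated || pm$negated))
    }
  }
  # <cell> x <death> / <cell> x <proliferation> combinations (set semantics,
  # so extra modifiers and word order never matter); death wins when a phrase
  # carries terms of both primary classes (e.g. "growth arrest")
  has_cell <- any(lemmas %in% lex$cell_terms)
  if (has_cell && any(lemmas %in% lex$death_terms)) {
    return(list(class = "death", negated = negated))
  }
  if (has_cell && any(lemmas %in% lex$proliferation_terms)) {
    return(list(class = "proliferation", negated = negated))
  }
  if (has_cell) return(list(class = "cell_general", negated = negated))
  NULL
}

#' Classify a noun phrase as an outcome mention
#'
#' Applies the exclusion filters, then standalone terms, then prefixed
#' (anti-/pro-) forms, then the cell x proliferation / cell x death
#' combination rule; a phrase containing a cell term but no primary term
#' becomes a `cell_general` mention, so the three classes partition mentions.
#' Outcome-level negation is set when a negation marker lemma (or an
#' anti-prefixed form) occurs inside the phrase.
#'
#' @param np One row of the noun-phrase tibble from [extract_noun_phrases()].
#' @param lex An `outcome_lexicon`.
#' @return A one-row mention tibble, or `NULL` when the phrase is not an
#'   outcome.
#' @export
classify_noun_phrase <- function(np, lex) {
  res <- classify_lemmas(np$lemmas[[1]], lex)
  if (is.null(res)) return(NULL)
  tibble(
    pmid = np$pmid, sent_index = np$sent_index, head_id = np$head_id,
    outcome_class = res$class, negated = res$negated,
    syntactic_form = "noun_phrase",
    form = paste(str_to_lower(np$lemmas[[1]]), collapse = " "),
    surface = np$surface,
    provenance = np$provenance
  )
}

# class of a governing outcome nominal for prepositional constructions
governor_class <- function(lemma, lex) {
  lemma <- str_to_lower(lemma)
  if (lemma %in% names(lex$standalone)) {
    return(list(class = unname(lex$standalone[lemma]),
                negated = lemma %in% lex$negation_markers))
  }
  if (lemma %in% lex$proliferation_terms) {
    return(list(class = "proliferation",
                negated = lemma %in% lex$negation_markers))
  }
  if (lemma %in% lex$death_terms) {
    return(list(class = "death", negated = lemma %in% lex$negation_markers))
  }
  NULL
}

#' Detect prepositional-phrase outcome mentions
#'
#' A proliferation/death nominal governing a cell-term phrase through a
#' preposition ("proliferation of cultured gastric cancer cells", "loss of
#' dopaminergic neurons") yields a mention anchored at the governing nominal.
#' Normalized forms use the underscore dialect `governor_dependent` (e.g.
#' `"loss_dopaminergic neuron"`).
#'
#' @param parse A `parsed_sentence`.
#' @param lex An `outcome_lexicon`.
#' @param nps Optional precomputed noun phrases (see
#'   [extract_noun_phrases()]).
#' @return Mention tibble with `syntactic_form == "prepositional"` (possibly
#'   empty).
#' @export
detect_prepositional_outcome <- function(parse, lex, nps = NULL) {
  tk <- parse$tokens
  nps <- nps %||% extract_noun_phrases(parse)
  out <- list()
  govs <- tk[tk$upos %in% NOMINAL_UPOS, ]
  for (i in seq_len(nrow(govs))) {
    g <- govs[i, ]
    gc <- governor_class(g$lemma, lex)
    if (is.null(gc)) next
    deps <- tok_children(tk, g$id, "nmod")
    for (d in deps$id) {
      dep_np <- nps[nps$head_id == d, ]
      if (!nrow(dep_np)) next
      for (j in seq_len(nrow(dep_np))) {
        lem <- str_to_lower(dep_np$lemmas[[j]])
        cls <- classify_lemmas(lem, lex)
        if (is.null(cls)) next
        has_cell <- any(lem %in% lex$cell_terms) ||
          cls$class == "cell_general"
        if (!has_cell) next
        out[[length(out) + 1L]] <- tibble(
          pmid = parse$pmid, sent_index = parse$index, head_id = g$id,
          outcome_class = gc$class,
          negated = gc$negated || isTRUE(cls$negated),
          syntactic_form = "prepositional",
          form = paste0(str_to_lower(g$lemma), "_",
                        paste(lem, collapse = " ")),
          surface = paste(g$form, "of", dep_np$surface[j])
        )
      }
    }
  }
  if (!length(out)) return(empty_mentions())
  distinct(bind_rows(out), head_id, form, .keep_all = TRUE)
}

#' Find all outcome mentions in a sentence
#'
#' Unions noun-phrase mentions (after coordinated-ellipsis resolution) with
#' prepositional-construction mentions. When a prepositional mention shares
#' its governing token with a bare noun-phrase mention (e.g. "death" inside
#' "death of hepatocytes"), the richer prepositional mention is kept.
#'
#' @inheritParams detect_prepositional_outcome
#' @param stats,threshold Passed to [extract_noun_phrases()].
#' @return Mention tibble.
#' @export
find_outcome_mentions <- function(parse, lex, stats = NULL, threshold = 1L) {
  nps <- extract_noun_phrases(parse, stats = stats, threshold = threshold)
  np_mentions <- bind_rows(map(seq_len(nrow(nps)), function(i) {
    classify_noun_phrase(nps[i, ], lex)
  }))
  prep <- detect_prepositional_outcome(parse, lex, nps = nps)
  if (nrow(prep) && nrow(np_mentions)) {
    np_mentions <- np_mentions[!np_mentions$head_id %in% prep$head_id, ]
  }
  if (nrow(np_mentions)) {
    # an elided phrase and its bare literal remnant describe one occurrence:
    # when an expanded mention shares head and class with a literal mention
    # whose lemmas are a subset of it, keep only the expanded form
    lemma_sets <- str_split(np_mentions$form, " ")
    drop <- map_lgl(seq_len(nrow(np_mentions)), function(i) {
      if (np_mentions$provenance[i] != "literal") return(FALSE)
      any(map_lgl(seq_len(nrow(np_mentions)), function(j) {
        j != i &&
          np_mentions$provenance[j] == "ellipsis_expanded" &&
          np_mentions$head_id[j] == np_mentions$head_id[i] &&
          np_mentions$outcome_class[j] == np_mentions$outcome_class[i] &&
          all(lemma_sets[[i]] %in% lemma_sets[[j]])
      }))
    })
    np_mentions <- np_mentions[!drop, ]
  }
  res <- bind_rows(np_mentions, prep)
  if (!nrow(res)) return(empty_mentions())
  res$provenance <- NULL
  distinct(res, head_id, form, .keep_all = TRUE) |> arrange(head_id)
}
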