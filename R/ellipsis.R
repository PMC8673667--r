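# Detection and expansion of elliptical coordinated compound noun phrases
# (CCNPs), where authors elide shared words: backward ("T and B cells" for
# "T cells and B cells"), forward ("cell death and proliferation" for "cell
# death and cell proliferation") and complex ("normal human and animal cells",
# where both a shared pre-modifier and a shared head distribute). Resolving
# these before lexicon matching is what lets the outcome matcher see fully
# spelled-out phrases.

NOMINAL_UPOS <- c("NOUN", "PROPN")
CONJUNCT_UPOS <- c("NOUN", "PROPN", "ADJ")
NP_MOD_RELS <- c("amod", "compound", "nummod", "nmod_poss")

#' Detect candidate coordinated-ellipsis constructions
#'
#' Scans conjunction arcs among nominal/adjectival tokens and classifies each
#' coordination as a forward, backward or complex ellipsis candidate
#' according to which side of the conjuncts carries the shared material.
#' Coordinations of complete heads with nothing elided (e.g. "mice and
#' rats") yield no candidate.
#'
#' @param parse A `parsed_sentence`.
#' @return List of candidates; each has `conjuncts` (token ids),
#'   `shared_head` (id or NA), `shared_mods` (ids) and
#'   `pattern` in `c("forward", "backward", "complex")`.
#' @export
detect_ccnp_candidates <- function(parse) {
  tk <- parse$tokens
  firsts <- unique(tk$head[tk$deprel == "conj"])
  firsts <- firsts[firsts != 0L]
  out <- list()
  for (c1 in firsts) {
    row1 <- tk[tk$id == c1, ]
    if (!row1$upos %in% CONJUNCT_UPOS) next
    rest <- tk$id[tk$deprel == "conj" & tk$head == c1 &
                    tk$upos %in% CONJUNCT_UPOS]
    if (!length(rest)) next
    conj <- sort(c(c1, rest))
    cand <- NULL
    if (row1$deprel %in% NP_MOD_RELS) {
      # conjuncts jointly modify a following head: backward or complex.
      # every other pre-modifier of the head distributes with it ("striatal
      # and cortical cell loss" -> "striatal cell loss", "cortical cell
      # loss"); a shared modifier *preceding* the conjuncts marks the
      # complex pattern ("normal human and animal cells")
      h <- tk[tk$id == row1$head, ]
      if (nrow(h) == 1L && h$upos %in% NOMINAL_UPOS && h$id > max(conj)) {
        premods <- tok_children(tk, h$id, NP_MOD_RELS)
        premods <- setdiff(premods$id[premods$id < h$id], conj)
        cand <- list(
          conjuncts = conj, shared_head = h$id, shared_mods = premods,
          pattern = if (any(premods < min(conj))) "complex" else "backward"
        )
      }
    } else if (row1$upos %in% NOMINAL_UPOS) {
      # first conjunct is a head noun carrying pre-modifiers that the later
      # conjuncts elide: forward
      premods <- tok_children(tk, c1, NP_MOD_RELS)
      premods <- premods$id[premods$id < c1]
      if (length(premods) && all(rest > c1)) {
        cand <- list(
          conjuncts = conj, shared_head = NA_integer_,
          shared_mods = premods, pattern = "forward"
        )
      }
    }
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

own_premods <- function(tk, id, exclude = integer()) {
  ch <- tok_children(tk, id, NP_MOD_RELS)
  sort(setdiff(ch$id[ch$id < id], exclude))
}

np_row <- function(tk, parse, head_id, mod_ids, provenance,
                   span_ids = NULL) {
  ord <- sort(c(mod_ids, head_id))
  span_ids <- span_ids %||% ord
  tibble(
    pmid = parse$pmid, sent_index = parse$index,
    head_id = head_id,
    head_lemma = tk$lemma[tk$id == head_id],
    lemmas = list(tk$lemma[match(ord, tk$id)]),
    surface = paste(tk$form[match(ord, tk$id)], collapse = " "),
    start = min(tk$start[tk$id %in% span_ids]),
    end = max(tk$end[tk$id %in% span_ids]),
    provenance = provenance
  )
}

#' Expand a coordinated-ellipsis candidate into full noun phrases
#'
#' Distributes the shared head and/or shared modifiers across every conjunct.
#' The whole expansion is rejected when any resulting phrase would contain a
#' repeated word; when modifier-head co-occurrence statistics are supplied,
#' an expansion is accepted only if every implied (modifier, head) pair has
#' corpus support at or above `threshold`, otherwise acceptance is rule-only.
#' On rejection the literal (unexpanded) conjunct phrases are returned.
#'
#' @param candidate One element from [detect_ccnp_candidates()].
#' @param parse The `parsed_sentence` the candidate came from.
#' @param stats Optional [ccnp_stats()] tibble (`modifier`, `head`, `n`).
#' @param threshold Minimum co-occurrence count for heuristic acceptance.
#' @return Noun-phrase tibble; expanded rows have
#'   `provenance == "ellipsis_expanded"` and carry the span of the
#'   originating coordination.
#' @export
expand_candidate <- function(candidate, parse, stats = NULL, threshold = 1L) {
  tk <- parse$tokens
  conj <- candidate$conjuncts
  span_ids <- sort(unique(c(
    conj, candidate$shared_mods,
    if (!is.na(candidate$shared_head)) candidate$shared_head
  )))
  phrases <- map(conj, function(cj) {
    own <- own_premods(tk, cj, exclude = c(conj, candidate$shared_mods))
    if (candidate$pattern == "forward") {
      list(head = cj, mods = sort(c(candidate$shared_mods, own)))
    } else {
      list(head = candidate$shared_head,
           mods = sort(c(candidate$shared_mods, own, cj)))
    }
  })
  # repeated-word rejection rule
  repeated <- map_lgl(phrases, function(ph) {
    lem <- tk$lemma[match(c(ph$mods, ph$head), tk$id)]
    anyDuplicated(lem) > 0L
  })
  # modifier-head co-occurrence heuristic (only when stats are available)
  supported <- TRUE
  if (!is.null(stats) && nrow(stats)) {
    pairs <- map(phrases, function(ph) {
      if (candidate$pattern == "forward") {
        tibble(modifier = tk$lemma[match(candidate$shared_mods, tk$id)],
               head = tk$lemma[tk$id == ph$head])
      } else {
        tibble(modifier = tk$lemma[match(setdiff(ph$mods,
                                                 candidate$shared_mods),
                                         tk$id)],
               head = tk$lemma[tk$id == ph$head])
      }
    }) |> bind_rows()
    joined <- left_join(pairs, stats, by = c("modifier", "head"))
    supported <- all(!is.na(joined$n) & joined$n >= threshold)
  }
  if (any(repeated) || !supported) {
    # literal fallback: each conjunct with only its own modifiers
    return(bind_rows(map(conj, function(cj) {
      np_row(tk, parse, cj, own_premods(tk, cj, exclude = conj), "literal")
    })))
  }
  bind_rows(map(phrases, function(ph) {
    np_row(tk, parse, ph$head, ph$mods, "ellipsis_expanded",
           span_ids = span_ids)
  }))
}

#' Accumulate modifier-head co-occurrence statistics
#'
#' Counts how often each modifier lemma appears with each head lemma in the
#' literal noun phrases of a set of parses. Accumulation is
#' order-independent; persist with [write_ccnp_stats()].
#'
#' @param parses List of `parsed_sentence` objects.
#' @param prior Optional existing stats tibble to add to.
#' @return Tibble with columns `modifier`, `head`, `n`.
#' @export
ccnp_stats <- function(parses, prior = NULL) {
  rows <- map(parses, function(p) {
    tk <- p$tokens
    heads <- tk$id[tk$upos %in% NOMINAL_UPOS]
    bind_rows(map(heads, function(h) {
      mods <- own_premods(tk, h)
      if (!length(mods)) return(NULL)
      tibble(modifier = tk$lemma[match(mods, tk$id)],
             head = tk$lemma[tk$id == h])
    }))
  }) |> bind_rows()
  if (!is.null(prior)) rows <- bind_rows(prior[, c("modifier", "head")] |>
      tidyr::uncount(prior$n), rows)
  if (!nrow(rows)) return(tibble(modifier = character(), head = character(),
                                 n = integer()))
  rows |> count(modifier, head, name = "n") |> arrange(modifier, head)
}

#' @rdname ccnp_stats
#' @param stats Stats tibble.
#' @param path TSV path.
#' @export
write_ccnp_stats <- function(stats, path) {
  readr::write_tsv(stats, path, progress = FALSE)
  invisible(path)
}

#' @rdname ccnp_stats
#' @export
read_ccnp_stats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Extract noun phrases from a parse, with ellipsis resolution
#'
#' Returns the union of literal noun phrases (each nominal head with its
#' modifier subtree) and every accepted coordinated-ellipsis expansion.
#' Duplicate phrases (same head and modifier lemmas) are removed with literal
#' provenance preferred, so literal phrases are always a subset of the
#' output.
#'
#' @inheritParams expand_candidate
#' @return Noun-phrase tibble (see [expand_candidate()] for columns).
#' @export
extract_noun_phrases <- function(parse, stats = NULL, threshold = 1L) {
  tk <- parse$tokens
  heads <- tk$id[tk$upos %in% NOMINAL_UPOS]
  literal <- bind_rows(map(heads, function(h) {
    np_row(tk, parse, h, own_premods(tk, h), "literal")
  }))
  cands <- detect_ccnp_candidates(parse)
  expanded <- bind_rows(map(cands, expand_candidate, parse = parse,
                            stats = stats, threshold = threshold))
  all_np <- bind_rows(literal, expanded)
  if (!nrow(all_np)) {
    return(tibble(pmid = character(), sent_index = integer(),
                  head_id = integer(), head_lemma = character(),
                  lemmas = list(), surface = character(), start = integer(),
                  end = integer(), provenance = character()))
  }
  key <- map_chr(all_np$lemmas, paste, collapse = " ")
  pref <- order(factor(all_np$provenance,
                       levels = c("literal", "ellipsis_expanded")))
  all_np <- all_np[pref, ][!duplicated(paste(all_np$head_lemma, key)[pref]), ]
  arrange(all_np, start, head_id)
}
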