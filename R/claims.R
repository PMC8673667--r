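# Claim extraction: bind anchor occurrences to outcome mentions through
# dependency paths, detect claim-level negation, distinguish explicit claims
# (changed entity + responsible entity) from observations (changed entity
# only), and reapply the syntactic rules to changes-in-cells so that "an
# increase in cells" is captured as cell proliferation and "a decrease in
# cells" as cell death.

DEFAULT_MEASUREMENT_TERMS <- c(
  "amount", "level", "rate", "degree", "extent", "number", "index",
  "percentage", "proportion", "frequency"
)

CLAIM_NEG_CUES <- c("not", "no", "never", "neither", "nor", "without")
NEG_GOVERNORS <- c("fail", "lack", "absence", "inability", "unable")

DIRECT_RELS <- c("obj", "dobj", "nsubj", "nsubj_pass", "iobj")
PREP_RELS <- c("nmod", "obl")

#' Detect claim-level negation of an anchor occurrence
#'
#' The claim (relation-level) negation is distinct from outcome-level
#' negation inside the noun phrase. An anchor is claim-negated when a
#' negation cue governs it: a `neg`/`advmod` "not"/"never" on the anchor, a
#' determiner "no" on a nominal anchor ("had no effect"), a pre-conjunction
#' "neither" on the anchor or its subject ("Neither A nor B inhibited ..."),
#' a "without" marker, or a negating governor such as "failed to <verb>" or
#' "lack of <nominal>".
#'
#' @param parse A `parsed_sentence`.
#' @param anchor_id Token id of the anchor occurrence.
#' @param cues,governors Editable cue lemma sets.
#' @return Logical scalar.
#' @export
detect_claim_negation <- function(parse, anchor_id,
                                  cues = CLAIM_NEG_CUES,
                                  governors = NEG_GOVERNORS) {
  tk <- parse$tokens
  deps <- tok_children(tk, anchor_id)
  lem <- str_to_lower(deps$lemma)
  if (any(deps$deprel == "neg")) return(TRUE)
  if (any(lem %in% cues &
            deps$deprel %in% c("advmod", "det", "neg", "cc_preconj",
                               "case", "mark"))) {
    return(TRUE)
  }
  # cue attached to the anchor's subject ("Neither sulfide nor sulfone ...")
  subj <- deps$id[deps$deprel %in% c("nsubj", "nsubj_pass")]
  for (s in subj) {
    sd <- tok_children(tk, s)
    if (any(str_to_lower(sd$lemma) %in% cues &
              sd$deprel %in% c("cc_preconj", "det", "neg"))) {
      return(TRUE)
    }
  }
  # negating governor: "failed to stimulate", "lack of inhibition"
  p <- tok_parent(tk, anchor_id)
  if (!is.null(p) && nrow(p)) {
    rel <- tk$deprel[tk$id == anchor_id]
    if (str_to_lower(p$lemma) %in% governors &&
        rel %in% c("xcomp", "ccomp", "nmod", "obj")) {
      return(TRUE)
    }
  }
  FALSE
}

anchor_polarity <- function(category) {
  dplyr::case_match(category,
    "increase" ~ "up",
    "decrease" ~ "down",
    .default = "neutral"
  )
}

# reach set for a mention head: the head itself plus conjunction chain
# parents, so an anchor governing the first conjunct also claims the others
mention_reach <- function(tk, head_id) {
  ids <- head_id
  cur <- head_id
  repeat {
    row <- tk[tk$id == cur, ]
    if (nrow(row) != 1L || row$deprel != "conj" || row$head == 0L) break
    cur <- row$head
    ids <- c(ids, cur)
  }
  ids
}

# classify the dependency path from anchor a_id to a token t reachable from
# the mention; returns "direct", "prepositional", "measurement" or NA
path_kind_for <- function(tk, a_id, targets, measurement_terms) {
  a_deps <- tok_children(tk, a_id)
  a_row <- tk[tk$id == a_id, ]
  # direct argument arc
  if (any(a_deps$id %in% targets & a_deps$deprel %in% DIRECT_RELS)) {
    return("direct")
  }
  # participial / adjectival anchor modifying the mention head
  if (a_row$head %in% targets && a_row$deprel %in% c("amod", "acl",
                                                     "acl_relcl") &&
      a_row$upos %in% c("VERB", "ADJ")) {
    return("direct")
  }
  # one prepositional link
  if (any(a_deps$id %in% targets & a_deps$deprel %in% PREP_RELS)) {
    return("prepositional")
  }
  # measurement nominal bridging anchor and outcome ("the amount of ...")
  bridges <- a_deps[a_deps$deprel %in% c(DIRECT_RELS, PREP_RELS), ]
  for (b in bridges$id) {
    if (!str_to_lower(tk$lemma[tk$id == b]) %in% measurement_terms) next
    b_deps <- tok_children(tk, b, "nmod")
    if (any(b_deps$id %in% targets)) return("measurement")
  }
  # participial bridge: a nominal anchor whose modifying participle takes the
  # mention as object ("effects promoting cell growth")
  parts <- a_deps[a_deps$deprel %in% c("acl", "acl_relcl", "xcomp") &
                    a_deps$upos == "VERB", ]
  for (v in parts$id) {
    v_deps <- tok_children(tk, v, c(DIRECT_RELS, PREP_RELS))
    if (any(v_deps$id %in% targets)) return("prepositional")
  }
  NA_character_
}

empty_claims <- function() {
  tibble(
    pmid = character(), sent_index = integer(),
    anchor_id = integer(), anchor_base = character(),
    anchor_form = character(), anchor_category = character(),
    polarity = character(), claim_negated = logical(),
    claim_type = character(), path_kind = character(),
    outcome_class = character(), outcome_negated = logical(),
    outcome_form = character(), syntactic_form = character(),
    mention_head_id = integer()
  )
}

#' Extract claim instances from a parsed sentence
#'
#' One claim per (anchor occurrence, reachable outcome mention), where
#' reachable means a direct argument arc, a single prepositional link
#' ("induction of apoptosis"), or a measurement nominal bridging anchor and
#' outcome ("the amount of cell death"). Polarity derives from the anchor
#' category (increase -> up, decrease -> down, general change / causality ->
#' neutral). A claim is `explicit` when the anchor has an agent/subject
#' phrase distinct from the outcome, otherwise an `observation`. One
#' sentence may yield several claims with conflicting directions.
#'
#' @param parse A `parsed_sentence`.
#' @param mentions Mention tibble from [find_outcome_mentions()].
#' @param anchor_lex An `anchor_lexicon`.
#' @param measurement_terms Configurable measurement-nominal lemmas.
#' @return Claim tibble (possibly empty).
#' @export
extract_claims <- function(parse, mentions, anchor_lex,
                           measurement_terms = DEFAULT_MEASUREMENT_TERMS) {
  anchors <- match_anchors(parse, anchor_lex)
  if (!nrow(anchors) || !nrow(mentions)) return(empty_claims())
  # a token that heads an outcome mention is an outcome, not a change anchor
  # (e.g. "loss" also matches the decrease verb "lose"; "growth" matches
  # "grow"): drop such occurrences before pairing
  anchors <- anchors[!anchors$id %in% mentions$head_id, , drop = FALSE]
  if (!nrow(anchors)) return(empty_claims())
  tk <- parse$tokens
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    for (j in seq_len(nrow(mentions))) {
      m <- mentions[j, ]
      if (m$head_id == a$id) next  # an anchor never claims itself
      targets <- mention_reach(tk, m$head_id)
      if (a$id %in% targets) next
      pk <- path_kind_for(tk, a$id, targets, measurement_terms)
      if (is.na(pk)) next
      a_deps <- tok_children(tk, a$id)
      subj <- a_deps$id[a_deps$deprel %in% c("nsubj", "obl_agent")]
      has_agent <- length(setdiff(subj, targets)) > 0L
      out[[length(out) + 1L]] <- tibble(
        pmid = parse$pmid, sent_index = parse$index,
        anchor_id = a$id, anchor_base = a$base, anchor_form = a$form,
        anchor_category = a$category,
        polarity = anchor_polarity(a$category),
        claim_negated = detect_claim_negation(parse, a$id),
        claim_type = if (has_agent) "explicit" else "observation",
        path_kind = pk,
        outcome_class = m$outcome_class,
        outcome_negated = m$negated,
        outcome_form = m$form,
        syntactic_form = m$syntactic_form,
        mention_head_id = m$head_id
      )
    }
  }
  if (!length(out)) return(empty_claims())
  bind_rows(out)
}

#' Reapply the syntactic rules to changes in cells
#'
#' A directional change on a general cell mention implicitly names a primary
#' outcome: an up-polarity claim on a `cell_general` mention mints a derived
#' proliferation mention and a down-polarity claim mints a derived death
#' mention (`syntactic_form = "derived_from_change"`, normalized to the
#' underscore dialect, e.g. `"increase_cell"`). The claim rules are then
#' rerun against the derived mentions so an outer anchor can act on them
#' ("inhibited the increase in ... cells" -> refuting proliferation). When no
#' outer anchor claims a derived mention, the originating claim itself is
#' retargeted with polarity reset to up, so that "a decrease in cells" is
#' supporting evidence for cell death. Reapplication is idempotent.
#'
#' @param claims First-pass claim tibble from [extract_claims()].
#' @inheritParams extract_claims
#' @return Updated claim tibble.
#' @export
apply_reapplication_rule <- function(claims, parse, anchor_lex,
                                     measurement_terms =
                                       DEFAULT_MEASUREMENT_TERMS) {
  if (!nrow(claims)) return(claims)
  src <- claims |>
    filter(outcome_class == "cell_general", polarity %in% c("up", "down"))
  if (!nrow(src)) return(claims)
  derived <- src |>
    mutate(
      outcome_class = if_else(polarity == "up", "proliferation", "death"),
      form = paste0(anchor_base, "_", outcome_form),
      head_id = anchor_id,
      negated = outcome_negated,
      syntactic_form = "derived_from_change"
    ) |>
    select(pmid, sent_index, head_id, outcome_class, negated,
           syntactic_form, form) |>
    mutate(surface = form) |>
    distinct(head_id, form, .keep_all = TRUE)
  second <- extract_claims(parse, derived, anchor_lex, measurement_terms)
  # the inner anchor of a consumed claim never re-claims its own derivation
  second <- second |> filter(!mention_head_id %in% src$anchor_id |
                               anchor_id != mention_head_id)
  claimed_heads <- unique(second$mention_head_id)
  keep <- claims |>
    filter(!(outcome_class == "cell_general" &
               polarity %in% c("up", "down")))
  retarget <- src |>
    filter(!anchor_id %in% claimed_heads) |>
    mutate(
      outcome_class = if_else(polarity == "up", "proliferation", "death"),
      outcome_form = paste0(anchor_base, "_", outcome_form),
      syntactic_form = "derived_from_change",
      polarity = "up"
    )
  bind_rows(keep, retarget, second) |>
    distinct(anchor_id, mention_head_id, outcome_form, .keep_all = TRUE) |>
    arrange(anchor_id, mention_head_id)
}

#' Extract reconciled claims for one sentence
#'
#' Convenience driver: outcome mentions (with ellipsis resolution), anchor
#' matching, claim extraction and the change-in-cells reapplication rule.
#'
#' @param parse A `parsed_sentence`.
#' @param outcome_lex An `outcome_lexicon`.
#' @param anchor_lex An `anchor_lexicon`.
#' @param stats,threshold Passed to [find_outcome_mentions()].
#' @param measurement_terms Passed to [extract_claims()].
#' @return Claim tibble.
#' @export
sentence_claims <- function(parse, outcome_lex, anchor_lex, stats = NULL,
                            threshold = 1L,
                            measurement_terms = DEFAULT_MEASUREMENT_TERMS) {
  mentions <- find_outcome_mentions(parse, outcome_lex, stats = stats,
                                    threshold = threshold)
  claims <- extract_claims(parse, mentions, anchor_lex, measurement_terms)
  apply_reapplication_rule(claims, parse, anchor_lex, measurement_terms)
}
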