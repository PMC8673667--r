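# Synthetic MEDLINE-style corpus generator with planted, templated claims.
#
# Each abstract is instantiated from a seeded template grammar combining
# anchors (sampled by category), outcome expressions (by class and negation
# form, including the underscore dialect and coordinated/elided variants) and
# negation cues. The generator emits the corpus XML, gold dependency parses
# for every sentence, and a ground-truth evidence-record table whose
# directions come from the generator's own hand-coded 12-state lookup - not
# from the pipeline's reconciliation code - so the full-pipeline round trip
# is a genuine dual-route check. Templates use only constructions the rule
# set claims to handle; "hard mode" adds distractor sentences (background
# claims, excluded phrases) that must yield zero records.

FIXTURE_CHEMICALS <- c("Genistein", "Cadmium", "Arsenic", "Thiobenzamide",
                       "Sulindac", "Irinotecan", "Styrene", "Pyridine")

# independent transcription of the twelve-state reconciliation table
TRUTH_DIRECTION <- tibble::tribble(
  ~polarity, ~claim_negated, ~outcome_negated, ~direction,
  "up",      FALSE, FALSE, "Support",
  "neutral", FALSE, FALSE, "Neutral",
  "down",    FALSE, FALSE, "Refute",
  "up",      TRUE,  FALSE, "NegatedSupport",
  "neutral", TRUE,  FALSE, "NegatedNeutral",
  "down",    TRUE,  FALSE, "NegatedRefute",
  "up",      FALSE, TRUE,  "Refute",
  "neutral", FALSE, TRUE,  "Neutral",
  "down",    FALSE, TRUE,  "Support",
  "up",      TRUE,  TRUE,  "NegatedRefute",
  "neutral", TRUE,  TRUE,  "NegatedNeutral",
  "down",    TRUE,  TRUE,  "NegatedSupport"
)

truth_direction <- function(polarity, claim_negated, outcome_negated) {
  i <- which(TRUTH_DIRECTION$polarity == polarity &
               TRUTH_DIRECTION$claim_negated == claim_negated &
               TRUTH_DIRECTION$outcome_negated == outcome_negated)
  TRUTH_DIRECTION$direction[i]
}

#' Build one claim-plan row
#'
#' @param outcome_class `"proliferation"`, `"death"` or `"cell_general"`.
#' @param polarity `"up"`, `"neutral"` or `"down"`.
#' @param claim_negated,outcome_negated Negation levels to plant.
#' @param path_kind `"direct"`, `"prepositional"` or `"measurement"`.
#' @param coordinated Plant a forward-elided coordination
#'   ("cell death and proliferation"), yielding one record per conjunct.
#' @return One-row plan tibble.
#' @export
claim_plan <- function(outcome_class, polarity, claim_negated = FALSE,
                       outcome_negated = FALSE, path_kind = "direct",
                       coordinated = FALSE) {
  tibble(outcome_class = outcome_class, polarity = polarity,
         claim_negated = claim_negated, outcome_negated = outcome_negated,
         path_kind = path_kind, coordinated = coordinated)
}

#' Specify a synthetic corpus
#'
#' @param claim_plans List of per-abstract plan tibbles (rows from
#'   [claim_plan()]).
#' @param chemicals Chemical name per abstract (recycled); must be single
#'   tokens so surface tagging and the template grammar agree.
#' @param structured Logical per abstract (recycled): labeled sections or a
#'   single unlabeled block.
#' @param seed Integer seed; the same seed and spec give byte-identical
#'   output.
#' @param hard_mode Add distractor sentences that must yield zero records.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(claim_plans, chemicals = FIXTURE_CHEMICALS,
                         structured = TRUE, seed = 1L, hard_mode = FALSE) {
  n <- length(claim_plans)
  structure(
    list(
      claim_plans = claim_plans,
      chemicals = rep_len(chemicals, n),
      structured = rep_len(structured, n),
      seed = as.integer(seed),
      hard_mode = isTRUE(hard_mode)
    ),
    class = "fixture_spec"
  )
}

#' Draw a random fixture specification from the template grammar
#'
#' Used by property-style tests: samples abstracts whose claim plans cover
#' the grammar (all outcome classes, polarities, negation levels, path kinds
#' and the coordinated variant) uniformly at random.
#'
#' @param n_abstracts Number of abstracts.
#' @param max_claims Maximum planted claims per abstract.
#' @inheritParams fixture_spec
#' @return A `fixture_spec`.
#' @export
random_fixture_spec <- function(n_abstracts = 6, max_claims = 4, seed = 1L,
                                structured = TRUE, hard_mode = FALSE) {
  with_seed(seed, {
    plans <- map(seq_len(n_abstracts), function(i) {
      k <- sample(max_claims, 1)
      bind_rows(map(seq_len(k), function(j) {
        coordinated <- runif(1) < 0.2
        path <- if (coordinated) "direct" else
          sample(c("direct", "prepositional", "measurement"), 1)
        cls <- if (coordinated) sample(c("proliferation", "death"), 1) else
          sample(c("proliferation", "death", "cell_general"), 1)
        oneg <- if (coordinated || cls == "cell_general") FALSE else
          runif(1) < 0.3
        claim_plan(cls, sample(c("up", "neutral", "down"), 1),
                   claim_negated = runif(1) < 0.3, outcome_negated = oneg,
                   path_kind = path, coordinated = coordinated)
      }))
    })
    chems <- sample(FIXTURE_CHEMICALS, n_abstracts, replace = TRUE)
    fixture_spec(plans, chems, structured = structured, seed = seed,
                 hard_mode = hard_mode)
  })
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- template grammar -------------------------------------------------------

VERB_POOL <- list(
  up = c("induce", "increase", "stimulate", "trigger", "enhance"),
  down = c("inhibit", "reduce", "suppress", "attenuate", "decrease"),
  neutral = c("affect", "alter", "modulate", "influence")
)
VERB_PAST <- c(
  induce = "induced", increase = "increased", stimulate = "stimulated",
  trigger = "triggered", enhance = "enhanced", inhibit = "inhibited",
  reduce = "reduced", suppress = "suppressed", attenuate = "attenuated",
  decrease = "decreased", affect = "affected", alter = "altered",
  modulate = "modulated", influence = "influenced"
)
NOMINAL_POOL <- list(
  up = c("induction", "increase", "elevation"),
  down = c("reduction", "suppression", "decrease"),
  neutral = c("effect", "influence")
)
# noun-phrase outcome expressions: list of token rows (form, lemma) with the
# last token the head and earlier tokens compound/amod modifiers
OUTCOME_NP <- list(
  proliferation_plain = list(
    list(c("cell", "cell", "NOUN"), c("proliferation", "proliferation",
                                      "NOUN")),
    list(c("cell", "cell", "NOUN"), c("growth", "growth", "NOUN")),
    list(c("cellular", "cellular", "ADJ"), c("proliferation",
                                             "proliferation", "NOUN"))
  ),
  proliferation_negated = list(
    list(c("cell", "cell", "NOUN"), c("loss", "loss", "NOUN")),
    list(c("antiproliferative", "antiproliferative", "ADJ"),
         c("activity", "activity", "NOUN")),
    list(c("neuronal", "neuronal", "ADJ"), c("cell", "cell", "NOUN"),
         c("loss", "loss", "NOUN"))
  ),
  death_plain = list(
    list(c("apoptosis", "apoptosis", "NOUN")),
    list(c("cell", "cell", "NOUN"), c("death", "death", "NOUN")),
    list(c("necrosis", "necrosis", "NOUN"))
  ),
  death_negated = list(
    list(c("antiapoptotic", "antiapoptotic", "ADJ"),
         c("activity", "activity", "NOUN"))
  ),
  cell_general_plain = list(
    list(c("hepatocytes", "hepatocyte", "NOUN")),
    list(c("lymphocytes", "lymphocyte", "NOUN")),
    list(c("cancer", "cancer", "NOUN"), c("cells", "cell", "NOUN"))
  )
)

np_key <- function(outcome_class, outcome_negated) {
  paste0(outcome_class, if (outcome_negated) "_negated" else "_plain")
}

validate_plan_entry <- function(plan, i, j) {
  msg <- function(why) {
    abort(paste0("unsatisfiable plan entry (abstract ", i, ", claim ", j,
                 "): ", why))
  }
  if (plan$coordinated) {
    if (plan$path_kind != "direct") {
      msg("coordinated outcomes are only templated on the direct path")
    }
    if (plan$outcome_negated) {
      msg("coordinated outcomes are not templated with outcome negation")
    }
    if (!plan$outcome_class %in% c("proliferation", "death")) {
      msg("coordinated outcomes need a primary class")
    }
  }
  if (plan$outcome_class == "cell_general" && plan$outcome_negated) {
    msg("no negated general-cell expression in the template grammar")
  }
  if (is.null(OUTCOME_NP[[np_key(plan$outcome_class,
                                 plan$outcome_negated)]])) {
    msg("no outcome expression for this class/negation combination")
  }
  invisible(TRUE)
}

# assemble token rows (form, lemma, upos, head(local), deprel) into a parse
assemble_sentence <- function(rows, pmid, index, section_label) {
  tk <- tibble(
    form = map_chr(rows, 1), lemma = map_chr(rows, 2),
    upos = map_chr(rows, 3), head = as.integer(map_chr(rows, 4)),
    deprel = map_chr(rows, 5)
  )
  parsed_sentence(tk, pmid = pmid, index = index,
                  section_label = section_label)
}

r5 <- function(form, lemma, upos, head, deprel) {
  c(form, lemma, upos, as.character(head), deprel)
}

# outcome NP token rows attached under `attach` with relation `rel`;
# returns list(rows, head_local) with local ids starting at `offset` + 1
np_rows <- function(np, offset, attach, rel) {
  n <- length(np)
  head_local <- offset + n
  rows <- map(seq_len(n), function(k) {
    t <- np[[k]]
    if (k == n) {
      r5(t[1], t[2], t[3], attach, rel)
    } else {
      r5(t[1], t[2], t[3], head_local,
         if (t[3] == "ADJ") "amod" else "compound")
    }
  })
  list(rows = rows, head_local = head_local, n = n)
}

# build one claim sentence; returns list(parse_rows, truth rows)
build_claim_sentence <- function(plan, chemical) {
  pol <- plan$polarity
  truth_rows <- function(classes, polarity = pol) {
    tibble(outcome_class = classes,
           direction = map_chr(classes, function(cl) {
             eff_pol <- polarity
             oneg <- plan$outcome_negated
             if (plan$outcome_class == "cell_general" &&
                 cl != "cell_general") {
               # derived change-in-cells record: class absorbs directionality
               eff_pol <- "up"
               oneg <- FALSE
             }
             truth_direction(eff_pol, plan$claim_negated, oneg)
           }))
  }
  remapped_class <- if (plan$outcome_class == "cell_general" &&
                        pol %in% c("up", "down")) {
    if (pol == "up") "proliferation" else "death"
  } else {
    plan$outcome_class
  }
  if (plan$path_kind == "prepositional") {
    nom <- sample(NOMINAL_POOL[[pol]], 1)
    det <- if (plan$claim_negated) c("no", "no") else c("an", "a")
    prep <- if (nom %in% c("effect", "influence")) c("on", "on") else
      if (plan$outcome_class == "cell_general") c("in", "in") else
        c("of", "of")
    np <- sample(OUTCOME_NP[[np_key(plan$outcome_class,
                                    plan$outcome_negated)]], 1)[[1]]
    # Results showed an induction of apoptosis .
    rows <- list(
      r5("Results", "result", "NOUN", 2, "nsubj"),
      r5("showed", "show", "VERB", 0, "root"),
      r5(det[1], det[2], "DET", 5, "det"),
      r5(nom, nom, "NOUN", 2, "obj")
    )
    # determiner and preposition land around the nominal anchor
    rows[[3]][4] <- "4"
    npr <- np_rows(np, offset = 5, attach = 4, rel = "nmod")
    rows <- c(rows, list(r5(prep[1], prep[2], "ADP", npr$head_local,
                            "case")), npr$rows)
    rows <- c(rows, list(r5(".", ".", "PUNCT", 2, "punct")))
    return(list(rows = rows, truth = truth_rows(remapped_class)))
  }
  verb <- sample(VERB_POOL[[pol]], 1)
  subj <- r5(chemical, str_to_lower(chemical), "PROPN", NA, "nsubj")
  if (plan$claim_negated) {
    # CHEM did not VERB ...
    vb_id <- 4
    rows <- list(
      { s <- subj; s[4] <- "4"; s },
      r5("did", "do", "AUX", 4, "aux"),
      r5("not", "not", "PART", 4, "advmod"),
      r5(verb, verb, "VERB", 0, "root")
    )
  } else {
    vb_id <- 2
    rows <- list(
      { s <- subj; s[4] <- "2"; s },
      r5(VERB_PAST[[verb]], verb, "VERB", 0, "root")
    )
  }
  if (plan$path_kind == "measurement") {
    # ... the amount of OUTCOME .
    off <- length(rows)
    rows <- c(rows, list(
      r5("the", "the", "DET", off + 2, "det"),
      r5("amount", "amount", "NOUN", vb_id, "obj")
    ))
    amt_id <- length(rows)
    npr <- np_rows(sample(OUTCOME_NP[[np_key(plan$outcome_class,
                                             plan$outcome_negated)]],
                          1)[[1]],
                   offset = length(rows) + 1, attach = amt_id, rel = "nmod")
    rows <- c(rows, list(r5("of", "of", "ADP", npr$head_local, "case")),
              npr$rows, list(r5(".", ".", "PUNCT", vb_id, "punct")))
    return(list(rows = rows, truth = truth_rows(remapped_class)))
  }
  if (plan$coordinated) {
    # ... cell death and proliferation . (forward ellipsis)
    first <- if (plan$outcome_class == "death") c("death", "proliferation")
      else c("proliferation", "death")
    off <- length(rows)
    head1 <- off + 2
    rows <- c(rows, list(
      r5("cell", "cell", "NOUN", head1, "compound"),
      r5(first[1], first[1], "NOUN", vb_id, "obj"),
      r5("and", "and", "CCONJ", head1 + 2, "cc"),
      r5(first[2], first[2], "NOUN", head1, "conj"),
      r5(".", ".", "PUNCT", vb_id, "punct")
    ))
    return(list(rows = rows, truth = truth_rows(first)))
  }
  # direct: ... OUTCOME .
  npr <- np_rows(sample(OUTCOME_NP[[np_key(plan$outcome_class,
                                           plan$outcome_negated)]], 1)[[1]],
                 offset = length(rows), attach = vb_id, rel = "obj")
  rows <- c(rows, npr$rows, list(r5(".", ".", "PUNCT", vb_id, "punct")))
  list(rows = rows, truth = truth_rows(remapped_class))
}

filler_sentences <- function(chemical, n) {
  pool <- list(
    list(
      r5("The", "the", "DET", 3, "det"),
      r5("biological", "biological", "ADJ", 3, "amod"),
      r5("role", "role", "NOUN", 6, "nsubj"),
      r5("of", "of", "ADP", 5, "case"),
      r5(chemical, str_to_lower(chemical), "PROPN", 3, "nmod"),
      r5("remains", "remain", "VERB", 0, "root"),
      r5("unclear", "unclear", "ADJ", 6, "xcomp"),
      r5(".", ".", "PUNCT", 6, "punct")
    ),
    list(
      r5("Cultures", "culture", "NOUN", 3, "nsubj_pass"),
      r5("were", "be", "AUX", 3, "aux_pass"),
      r5("exposed", "expose", "VERB", 0, "root"),
      r5("to", "to", "ADP", 5, "case"),
      r5(chemical, str_to_lower(chemical), "PROPN", 3, "obl"),
      r5("for", "for", "ADP", 8, "case"),
      r5("two", "two", "NUM", 8, "nummod"),
      r5("days", "day", "NOUN", 3, "obl"),
      r5(".", ".", "PUNCT", 3, "punct")
    ),
    list(
      r5("Samples", "sample", "NOUN", 3, "nsubj_pass"),
      r5("were", "be", "AUX", 3, "aux_pass"),
      r5("collected", "collect", "VERB", 0, "root"),
      r5("at", "at", "ADP", 6, "case"),
      r5("three", "three", "NUM", 6, "nummod"),
      r5("timepoints", "timepoint", "NOUN", 3, "obl"),
      r5(".", ".", "PUNCT", 3, "punct")
    )
  )
  map(seq_len(n), function(i) pool[[(i - 1L) %% length(pool) + 1L]])
}

distractor_background <- function(chemical) {
  list(
    r5("Previous", "previous", "ADJ", 2, "amod"),
    r5("work", "work", "NOUN", 3, "nsubj"),
    r5("reported", "report", "VERB", 0, "root"),
    r5("that", "that", "SCONJ", 5, "mark"),
    r5(chemical, str_to_lower(chemical), "PROPN", 6, "nsubj"),
    r5("increased", "increase", "VERB", 3, "ccomp"),
    r5("apoptosis", "apoptosis", "NOUN", 6, "obj"),
    r5(".", ".", "PUNCT", 3, "punct")
  )
}

distractor_results <- function() {
  list(
    list(
      r5("The", "the", "DET", 4, "det"),
      r5("tumor", "tumor", "NOUN", 3, "compound"),
      r5("necrosis", "necrosis", "NOUN", 4, "compound"),
      r5("factor", "factor", "NOUN", 5, "compound"),
      r5("pathway", "pathway", "NOUN", 8, "nsubj_pass"),
      r5("was", "be", "AUX", 8, "aux_pass"),
      r5("also", "also", "ADV", 8, "advmod"),
      r5("examined", "examine", "VERB", 0, "root"),
      r5(".", ".", "PUNCT", 8, "punct")
    ),
    list(
      r5("Peroxisome", "peroxisome", "NOUN", 2, "compound"),
      r5("proliferation", "proliferation", "NOUN", 4, "nsubj_pass"),
      r5("was", "be", "AUX", 4, "aux_pass"),
      r5("unchanged", "unchanged", "ADJ", 0, "root"),
      r5(".", ".", "PUNCT", 4, "punct")
    )
  )
}

sentence_text <- function(rows) {
  forms <- map_chr(rows, 1)
  glue_space <- !str_detect(forms, "^[,.;:!?)]") & seq_along(forms) > 1L
  paste0(ifelse(glue_space, " ", ""), forms, collapse = "")
}

#' Generate a synthetic corpus with gold parses and ground truth
#'
#' Instantiates every abstract of a [fixture_spec()]: templated claim
#' sentences in a results section (plus background/methods filler and,
#' in hard mode, distractor sentences that must contribute nothing),
#' byte-identical for a fixed spec and seed.
#'
#' @param spec A `fixture_spec`.
#' @param dir Optional output directory; when given, writes `corpus.xml`
#'   (PubMed-style), `parses.conllu` (gold parses) and `truth.tsv`.
#' @return List with `records` (abstract tibble), `parses` (named list of
#'   gold parses for every sentence), `truth` (expected evidence records:
#'   `pmid`, `chemical`, `outcome_class`, `direction`) and `spec`.
#' @export
generate_fixtures <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    records <- list()
    parses <- list()
    truth <- list()
    for (i in seq_along(spec$claim_plans)) {
      plan <- spec$claim_plans[[i]]
      chem <- spec$chemicals[[i]]
      pm <- sprintf("9%06d", i)
      for (j in seq_len(nrow(plan))) validate_plan_entry(plan[j, ], i, j)
      built <- map(seq_len(nrow(plan)), function(j) {
        build_claim_sentence(plan[j, ], chem)
      })
      claim_rows <- map(built, "rows")
      if (spec$hard_mode) {
        claim_rows <- c(claim_rows, distractor_results())
      }
      n_claims <- length(claim_rows)
      n_fill <- max(2L, ceiling(1.5 * n_claims))
      bg_rows <- c(
        if (spec$hard_mode) list(distractor_background(chem)),
        filler_sentences(chem, n_fill - 1L)
      )
      all_rows <- c(bg_rows, claim_rows)
      n_bg <- length(bg_rows)
      sec_labels <- c(rep("background", n_bg - 1L), "methods",
                      rep("results", n_claims))
      # keep planted sentences strictly inside the final 40% (and the
      # background distractor outside it) so the positional heuristic
      # selects the right sentences in unstructured abstracts too
      stopifnot((n_bg + 1) / length(all_rows) > 0.6,
                1 / length(all_rows) <= 0.6)
      texts <- map_chr(all_rows, sentence_text)
      sections <- if (spec$structured[[i]]) {
        tibble(label = sec_labels, text = texts) |>
          group_by(label = factor(label, levels = unique(sec_labels))) |>
          summarise(text = paste(text, collapse = " "), .groups = "drop") |>
          mutate(label = as.character(label))
      } else {
        tibble(label = "unlabeled", text = paste(texts, collapse = " "))
      }
      records[[i]] <- tibble(
        pmid = pm,
        title = paste("Cellular outcomes after", chem, "exposure"),
        language = "eng",
        sections = list(sections),
        chemicals = list(character())
      )
      for (k in seq_along(all_rows)) {
        p <- assemble_sentence(all_rows[[k]], pmid = pm, index = k - 1L,
                               section_label = sec_labels[k])
        parses[[parse_key(pm, k - 1L)]] <- p
      }
      truth[[i]] <- bind_rows(map(built, "truth")) |>
        mutate(pmid = pm, chemical = chem, .before = 1)
    }
    res <- list(
      records = bind_rows(records),
      parses = parses,
      truth = bind_rows(truth) |>
        select(pmid, chemical, outcome_class, direction),
      spec = spec
    )
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_medline_xml(res$records, file.path(dir, "corpus.xml"))
      write_conllu(res$parses, file.path(dir, "parses.conllu"))
      readr::write_tsv(res$truth, file.path(dir, "truth.tsv"),
                       progress = FALSE)
    }
    res
  })
}

#' Run the full pipeline over generated fixtures
#'
#' Convenience wrapper used by the round-trip integration contract: tags the
#' generated records with the shipped chemical lexicons, runs
#' [extract_evidence()] with the gold-parse backend, and returns both the
#' recovered records and the planted truth.
#'
#' @param fixtures Result of [generate_fixtures()].
#' @param ... Passed to [extract_evidence()].
#' @return List with `records` (recovered evidence records) and `truth`.
#' @export
run_fixture_pipeline <- function(fixtures, ...) {
  tagged <- tag_chemicals(fixtures$records)
  recovered <- extract_evidence(tagged, gold_parse_backend(fixtures$parses),
                                ...)
  list(records = recovered, truth = fixtures$truth)
}
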