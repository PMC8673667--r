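# End-to-end driver: abstract records + parses -> evidence records.

#' Extract evidence records from a tagged corpus
#'
#' Runs the full pipeline over a corpus: sentence segmentation (with
#' normalization and itemized-list expansion), result/conclusion selection,
#' dependency parsing through the configured backend, outcome-mention
#' detection with coordinated-ellipsis resolution, anchor-based claim
#' extraction with the change-in-cells reapplication rule, direction
#' reconciliation, and fan-out over the abstract's chemical tags.
#'
#' @param records Abstract-record tibble, ideally already passed through
#'   [tag_chemicals()].
#' @param backend Parser backend (see [gold_parse_backend()]).
#' @param outcome_lex An `outcome_lexicon`; defaults to the shipped seed.
#' @param anchor_lex An `anchor_lexicon`; defaults to the shipped seed.
#' @param classifier Section classifier for unstructured abstracts.
#' @param stats,threshold Modifier-head co-occurrence statistics for ellipsis
#'   acceptance.
#' @param quiet Suppress per-abstract warnings about untagged records.
#' @return Evidence-record tibble (see [to_evidence_records()]).
#' @export
extract_evidence <- function(records, backend,
                             outcome_lex = build_outcome_lexicon(),
                             anchor_lex = expand_anchor_lexicon(),
                             classifier = heuristic_section_classifier,
                             stats = NULL, threshold = 1L, quiet = FALSE) {
  all_recs <- map(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    sents <- segment_abstract(rec)
    sel <- select_result_conclusion(rec, classifier = classifier,
                                    sentences = sents)
    if (!nrow(sel)) return(NULL)
    claims <- map(seq_len(nrow(sel)), function(j) {
      parse <- parse_dependencies(sel[j, ], backend)
      sentence_claims(parse, outcome_lex, anchor_lex, stats = stats,
                      threshold = threshold)
    }) |> bind_rows()
    if (!nrow(claims)) return(NULL)
    chems <- rec$chemicals[[1]]
    if (quiet && !length(chems)) chems <- "untagged"
    to_evidence_records(claims, chems)
  })
  out <- bind_rows(compact(all_recs))
  if (!nrow(out)) return(to_evidence_records(empty_claims()))
  out
}
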