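# Reconciliation of claim polarity with both negation levels onto the
# six-step evidence direction scale:
#   Refute < NegatedRefute < Neutral < NegatedNeutral < NegatedSupport <
#   Support
# Negation can occur within the outcome noun phrase or within the relation,
# so there are 12 raw claim states (3 polarities x 2 negation levels); the
# raw states are preserved on every record for audit while the six-step
# scale is the display and aggregation unit.

#' The six evidence directions, in increasing support order
#'
#' @return An ordered factor of the six direction levels.
#' @export
evidence_directions <- function() {
  factor(DIRECTION_LEVELS, levels = DIRECTION_LEVELS, ordered = TRUE)
}

flip_polarity <- function(polarity, outcome_negated) {
  # outcome negation inverts directionality; a doubly flipped polarity is the
  # original (the flip is an involution) and neutral is a fixed point
  if_else(outcome_negated,
          dplyr::case_match(polarity, "up" ~ "down", "down" ~ "up",
                            .default = polarity),
          polarity)
}

#' Reconcile polarity and negations into an evidence direction
#'
#' The reconciliation is the composition of two steps: outcome-level negation
#' flips up and down (neutral is fixed), then claim-level negation prefixes
#' "Negated". The resulting map over the full 2 x 3 x 2 input space is
#' exactly the twelve-row reconciliation table; e.g. a non-negated decrease
#' of a negated outcome ("reduction in cell loss") is Support, and a negated
#' increase of a negated outcome ("did not induce cell loss") is
#' NegatedRefute.
#'
#' @param polarity Character vector in `c("up", "neutral", "down")`.
#' @param claim_negated,outcome_negated Logical vectors.
#' @return Ordered factor on the six-step scale.
#' @export
#' @examples
#' reconcile_direction("up", FALSE, FALSE)    # Support
#' reconcile_direction("down", FALSE, TRUE)   # Support
#' reconcile_direction("neutral", TRUE, FALSE) # NegatedNeutral
reconcile_direction <- function(polarity, claim_negated, outcome_negated) {
  stopifnot(all(polarity %in% c("up", "neutral", "down")))
  eff <- flip_polarity(polarity, outcome_negated)
  base <- dplyr::case_match(eff, "up" ~ "Support", "neutral" ~ "Neutral",
                            "down" ~ "Refute")
  lab <- if_else(claim_negated, paste0("Negated", base), base)
  factor(lab, levels = DIRECTION_LEVELS, ordered = TRUE)
}

#' Convert claims into evidence records
#'
#' One evidence record per claim per chemical tag of the abstract, the unit
#' of all downstream aggregation. Untagged abstracts yield records with the
#' sentinel chemical `"untagged"` and a warning. Duplicate identical claims
#' within one abstract remain distinct records (claim-level counting needs
#' them).
#'
#' @param claims Claim tibble (from [sentence_claims()] or
#'   [extract_claims()]), for one abstract.
#' @param chemicals Character vector of the abstract's chemical tags.
#' @return Evidence-record tibble: `pmid`, `chemical`, `outcome_class`,
#'   `direction`, plus the raw claim state columns.
#' @export
to_evidence_records <- function(claims, chemicals = character()) {
  if (!nrow(claims)) {
    return(tibble(pmid = character(), chemical = character(),
                  outcome_class = character(),
                  direction = evidence_directions()[0],
                  polarity = character(), claim_negated = logical(),
                  outcome_negated = logical(), outcome_form = character(),
                  anchor_base = character(), sent_index = integer(),
                  claim_type = character()))
  }
  if (!length(chemicals)) {
    warn(paste0("abstract ", claims$pmid[1],
                " has no chemical tags; using sentinel 'untagged'"))
    chemicals <- "untagged"
  }
  base <- claims |>
    mutate(direction = reconcile_direction(polarity, claim_negated,
                                           outcome_negated)) |>
    select(pmid, outcome_class, direction, polarity, claim_negated,
           outcome_negated, outcome_form, anchor_base, sent_index,
           claim_type)
  tidyr::crossing(chemical = chemicals, base) |>
    select(pmid, chemical, outcome_class, direction, everything())
}

#' Serialize / read evidence records as a tidy TSV
#'
#' @param records Evidence-record tibble.
#' @param path File path.
#' @return `path` invisibly, or the records tibble for the reader.
#' @export
write_evidence_records <- function(records, path) {
  out <- records |> mutate(direction = as.character(direction))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_evidence_records
#' @export
read_evidence_records <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(direction = factor(direction, levels = DIRECTION_LEVELS,
                              ordered = TRUE))
}
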