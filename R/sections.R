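# Restriction of claim extraction to result/conclusion sentences, so that
# extracted claims reflect a study's own findings rather than its motivation
# or cited prior work. Structured abstracts pass their declared labels
# through; unstructured abstracts go through a pluggable classifier whose
# shipped default is a positional + lexical heuristic.

RESULTS_CUE_REGEX <- paste0(
  "^(results?|findings?|conclusions?|in conclusion|in summary|overall|",
  "taken together|altogether|collectively|we (found|conclude|show|",
  "demonstrate|observed|report)|our (results|findings|data|study))\\b"
)

#' Heuristic result/conclusion sentence classifier
#'
#' Flags a sentence when it falls in the final 40% of an unstructured
#' abstract or opens with a results cue ("Results ...", "We found ...",
#' "In conclusion ..."). This is the shipped default for the classifier
#' plug-in contract: a function taking the ordered sentence texts of one
#' abstract and returning a per-sentence tibble of `is_result_or_conclusion`
#' and `score` in `[0, 1]`.
#'
#' @param texts Character vector of one abstract's sentences, in order.
#' @return Tibble with columns `is_result_or_conclusion`, `score`.
#' @export
heuristic_section_classifier <- function(texts) {
  n <- length(texts)
  if (n == 0L) {
    return(tibble(is_result_or_conclusion = logical(), score = double()))
  }
  pos <- seq_len(n) / n
  positional <- pos > 0.6
  lexical <- str_detect(str_to_lower(texts), regex(RESULTS_CUE_REGEX))
  tibble(
    is_result_or_conclusion = positional | lexical,
    score = pmin(1, 0.5 + 0.25 * positional + 0.25 * lexical)
  )
}

#' Train a simple result/conclusion sentence classifier
#'
#' Fits a logistic regression on the structured abstracts present in a
#' corpus (relative sentence position, results-cue indicator, log length),
#' mirroring the train-on-structured design: declared result/conclusion
#' labels are the supervision. The returned function satisfies the
#' classifier plug-in contract and can replace the shipped heuristic for
#' unstructured abstracts.
#'
#' @param records Abstract-record tibble; only structured records are used.
#' @param threshold Probability cut-off for the positive class.
#' @return A classifier function `(texts) -> tibble(is_result_or_conclusion,
#'   score)`.
#' @export
train_section_classifier <- function(records, threshold = 0.5) {
  feats <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (!is_structured(rec)) next
    sents <- segment_abstract(rec)
    if (!nrow(sents)) next
    feats[[length(feats) + 1L]] <- sents |>
      mutate(
        y = section_label %in% c("results", "conclusions"),
        rel_pos = (index + 1) / n(),
        cue = str_detect(str_to_lower(text), regex(RESULTS_CUE_REGEX)),
        len = log1p(nchar(text))
      )
  }
  train <- bind_rows(feats)
  if (!nrow(train) || length(unique(train$y)) < 2L) {
    abort("need structured abstracts with both positive and negative sentences")
  }
  # perfectly separable corpora (e.g. clean templated abstracts) trip glm's
  # separation warnings; the fitted probabilities are still usable
  fit <- suppressWarnings(
    glm(y ~ rel_pos + cue + len, data = train, family = binomial())
  )
  function(texts) {
    n <- length(texts)
    newd <- tibble(
      rel_pos = if (n) seq_len(n) / n else double(),
      cue = str_detect(str_to_lower(texts), regex(RESULTS_CUE_REGEX)),
      len = log1p(nchar(texts))
    )
    p <- if (n) unname(predict(fit, newd, type = "response")) else double()
    tibble(is_result_or_conclusion = p >= threshold, score = p)
  }
}

#' Is an abstract structured?
#'
#' An abstract with at least one canonical (non-`unlabeled`) section heading
#' is treated as structured; mixed abstracts therefore count as structured
#' and their unlabeled sentences are simply never selected.
#'
#' @param record One abstract record.
#' @return Logical scalar.
#' @export
is_structured <- function(record) {
  secs <- if (is.data.frame(record)) record$sections[[1]] else record$sections
  any(secs$label %in% setdiff(CANONICAL_SECTIONS, "unlabeled"))
}

#' Select result/conclusion sentences of an abstract
#'
#' For structured abstracts, sentences whose declared section label is
#' `results` or `conclusions` are selected (`source = "declared"`, score 1);
#' declared labels always override prediction. For unstructured abstracts the
#' classifier decides (`source = "predicted"`); when no classifier is given
#' the shipped positional heuristic is used with a warning.
#'
#' @param record One abstract record.
#' @param classifier Classifier function per the plug-in contract, or `NULL`.
#' @param sentences Optional precomputed sentence tibble from
#'   [segment_abstract()].
#' @return The selected rows of the sentence tibble, with `score` and
#'   `source` columns added. Every input sentence receives exactly one
#'   prediction; the selection is a subset with no duplicates.
#' @export
select_result_conclusion <- function(record, classifier = NULL,
                                     sentences = NULL) {
  sents <- sentences %||% segment_abstract(record)
  if (!nrow(sents)) {
    return(mutate(sents, score = double(), source = character()))
  }
  if (is_structured(record)) {
    out <- sents |>
      filter(section_label %in% c("results", "conclusions")) |>
      mutate(score = 1, source = "declared")
    return(out)
  }
  if (is.null(classifier)) {
    warn("no section classifier supplied; using positional heuristic")
    classifier <- heuristic_section_classifier
  }
  pred <- classifier(sents$text)
  stopifnot(nrow(pred) == nrow(sents))
  sents |>
    mutate(score = pred$score, source = "predicted") |>
    filter(pred$is_result_or_conclusion)
}
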