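# Aggregation of evidence records into claim-level and abstract-level
# summaries per (chemical, outcome), the proliferation-versus-death decision
# comparison, and waffle-plot rendering. Claim-level counting counts every
# record; abstract-level counting counts each abstract at most once per
# (direction, outcome) - an abstract may still appear under several
# directions, which is why abstract-level percentages can sum above 100%.

new_evidence_summary <- function(counts, level) {
  structure(counts, level = level,
            class = c("evidence_summary", class(counts)))
}

complete_directions <- function(counts) {
  counts |>
    tidyr::complete(
      tidyr::nesting(chemical, outcome_class),
      direction = evidence_directions(),
      fill = list(n = 0L)
    ) |>
    arrange(chemical, outcome_class, direction)
}

#' Claim-level evidence counts
#'
#' Counts every evidence record, grouped by (chemical, outcome, direction).
#'
#' @param records Evidence-record tibble.
#' @return An `evidence_summary` tibble (`chemical`, `outcome_class`,
#'   `direction`, `n`) with attribute `level = "claim"`.
#' @export
count_claims <- function(records) {
  counts <- records |>
    count(chemical, outcome_class, direction, .drop = FALSE) |>
    filter(!is.na(chemical)) |>
    complete_directions()
  new_evidence_summary(counts, "claim")
}

#' Abstract-level evidence counts
#'
#' Counts distinct abstracts per (chemical, outcome, direction): an abstract
#' repeating one claim five times still counts once.
#'
#' @inheritParams count_claims
#' @return An `evidence_summary` with attribute `level = "abstract"`.
#' @export
count_abstracts <- function(records) {
  counts <- records |>
    distinct(pmid, chemical, outcome_class, direction) |>
    count(chemical, outcome_class, direction, .drop = FALSE) |>
    filter(!is.na(chemical)) |>
    complete_directions()
  new_evidence_summary(counts, "abstract")
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat("<evidence_summary level=", attr(x, "level"), ">\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy evidence_summary
#' @export
tidy.evidence_summary <- function(x, ...) {
  as_tibble(x) |> mutate(level = attr(x, "level"), .before = 1)
}

#' @method glance evidence_summary
#' @export
glance.evidence_summary <- function(x, ...) {
  as_tibble(x) |>
    group_by(chemical, outcome_class) |>
    summarise(
      n_total = sum(n),
      n_support = sum(n[direction == "Support"]),
      n_refute = sum(n[direction == "Refute"]),
      n_neutral = sum(n[direction == "Neutral"]),
      n_negated = sum(n[direction %in% c("NegatedRefute", "NegatedNeutral",
                                         "NegatedSupport")]),
      .groups = "drop"
    ) |>
    mutate(level = attr(x, "level"), .before = 1)
}

verdict_of <- function(prolif, death) {
  dplyr::case_when(
    is.na(prolif) | is.na(death) ~ NA_character_,
    prolif > death ~ "Prolif",
    death > prolif ~ "Death",
    .default = "Tie"
  )
}

#' Compare proliferation versus death evidence per chemical
#'
#' Computes the five decision measures: (A) retrieved-abstract counts, (B)
#' supporting-abstract counts and percentages, and (C) supporting-claim
#' counts and percentages, each with a Prolif/Death/Tie verdict. Supporting
#' measures count the plain `Support` direction only by default (set
#' `support_directions` to include `NegatedRefute` if desired); percentage
#' denominators are abstracts (claims) with at least one extracted claim for
#' that outcome. Zero denominators give missing percentages; equal pairs are
#' reported as `Tie`, never broken arbitrarily.
#'
#' @param records Evidence-record tibble (result/conclusion claims).
#' @param retrieved Optional tibble `chemical`, `outcome_class`,
#'   `n_abstracts` of retrieval-step counts; defaults to distinct PMIDs with
#'   at least one claim in `records`.
#' @param support_directions Directions counted as supporting.
#' @return A `decision_comparison` tibble: one row per (chemical, measure)
#'   with `prolif`, `death`, `verdict`.
#' @export
compare_outcomes <- function(records, retrieved = NULL,
                             support_directions = "Support") {
  prim <- records |> filter(outcome_class %in% c("proliferation", "death"))
  if (is.null(retrieved)) {
    retrieved <- prim |>
      distinct(pmid, chemical, outcome_class) |>
      count(chemical, outcome_class, name = "n_abstracts")
  }
  claim_tot <- prim |> count(chemical, outcome_class, name = "n_claims")
  claim_sup <- prim |>
    filter(direction %in% support_directions) |>
    count(chemical, outcome_class, name = "n_support_claims")
  abs_tot <- prim |>
    distinct(pmid, chemical, outcome_class) |>
    count(chemical, outcome_class, name = "n_abstracts_with_claim")
  abs_sup <- prim |>
    filter(direction %in% support_directions) |>
    distinct(pmid, chemical, outcome_class) |>
    count(chemical, outcome_class, name = "n_support_abstracts")
  stats <- list(retrieved, claim_tot, claim_sup, abs_tot, abs_sup) |>
    Reduce(function(a, b) full_join(a, b, by = c("chemical",
                                                 "outcome_class")), x = _) |>
    mutate(across(where(is.numeric), ~ tidyr::replace_na(.x, 0L)))
  wide <- stats |>
    tidyr::pivot_longer(cols = -c(chemical, outcome_class),
                        names_to = "measure") |>
    mutate(outcome = if_else(outcome_class == "proliferation",
                             "prolif", "death")) |>
    select(-outcome_class) |>
    tidyr::pivot_wider(names_from = outcome, values_from = value,
                       values_fill = 0)
  pick <- function(m) {
    wide |> filter(measure == m) |> select(chemical, prolif, death)
  }
  pct <- function(num, den) {
    num |>
      left_join(den, by = "chemical", suffix = c("_num", "_den")) |>
      mutate(
        prolif = if_else(prolif_den > 0, 100 * prolif_num / prolif_den,
                         NA_real_),
        death = if_else(death_den > 0, 100 * death_num / death_den,
                        NA_real_)
      ) |>
      select(chemical, prolif, death)
  }
  measures <- list(
    retrieved_abstracts = pick("n_abstracts"),
    supporting_abstracts = pick("n_support_abstracts"),
    supporting_abstract_pct = pct(pick("n_support_abstracts"),
                                  pick("n_abstracts_with_claim")),
    supporting_claims = pick("n_support_claims"),
    supporting_claim_pct = pct(pick("n_support_claims"), pick("n_claims"))
  )
  out <- imap(measures, function(df, nm) mutate(df, measure = nm)) |>
    bind_rows() |>
    mutate(verdict = verdict_of(prolif, death)) |>
    select(chemical, measure, prolif, death, verdict) |>
    arrange(chemical)
  structure(out, class = c("decision_comparison", class(out)))
}

# -- waffle plots -------------------------------------------------------------

DIRECTION_PALETTE <- c(
  Refute = "#d7191c", NegatedRefute = "#fdae61", Neutral = "#bdbdbd",
  NegatedNeutral = "#878787", NegatedSupport = "#a6d96a",
  Support = "#1a9641"
)

#' Lay out an evidence summary as waffle cells
#'
#' One cell per counted unit (or per `units_per_cell`), filled row-major in
#' the six-step direction order from least to most supportive.
#'
#' @param summary An `evidence_summary`.
#' @param units_per_cell Scaling factor: one cell represents this many units
#'   (counts are rounded up per direction).
#' @param ncol Number of cells per waffle row.
#' @return Tidy tibble `chemical`, `outcome_class`, `direction`, `x`, `y`.
#' @export
waffle_data <- function(summary, units_per_cell = 1, ncol = 10) {
  df <- as_tibble(summary) |> filter(n > 0)
  if (!nrow(df)) {
    return(tibble(chemical = character(), outcome_class = character(),
                  direction = evidence_directions()[0], x = integer(),
                  y = integer()))
  }
  df |>
    mutate(cells = as.integer(ceiling(n / units_per_cell))) |>
    group_by(chemical, outcome_class) |>
    arrange(direction, .by_group = TRUE) |>
    reframe(direction = rep(direction, cells)) |>
    group_by(chemical, outcome_class) |>
    mutate(x = (row_number() - 1L) %% ncol + 1L,
           y = (row_number() - 1L) %/% ncol + 1L) |>
    ungroup()
}

#' Render a waffle plot of an evidence summary
#'
#' Directions are colored along the six-step order with a fixed legend; the
#' tidy cell table is always returned alongside the figure so plots stay
#' auditable. An all-supportive summary renders entirely green.
#'
#' @inheritParams waffle_data
#' @param path Optional file path; when given the plot is saved there
#'   (format from the extension, e.g. `.png`, `.svg`).
#' @param width,height Device size in inches when saving.
#' @return Invisibly, a list with `plot` (a ggplot, or `NULL` for an empty
#'   summary, with a warning) and `data` (the tidy cell table).
#' @export
render_waffle <- function(summary, path = NULL, units_per_cell = 1,
                          ncol = 10, width = 7, height = 5) {
  cells <- waffle_data(summary, units_per_cell, ncol)
  if (!nrow(cells)) {
    warn("empty evidence summary: no waffle image produced")
    return(invisible(list(plot = NULL, data = cells)))
  }
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = x, y = y,
                                           fill = direction)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.6) +
    ggplot2::scale_fill_manual(values = DIRECTION_PALETTE,
                               limits = DIRECTION_LEVELS,
                               drop = FALSE, name = "Direction") +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(chemical ~ outcome_class) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom",
                   strip.text = ggplot2::element_text(size = 9))
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
  }
  invisible(list(plot = p, data = cells))
}

#' @method autoplot evidence_summary
#' @export
#' @importFrom ggplot2 autoplot
autoplot.evidence_summary <- function(object, ...) {
  render_waffle(object, ...)$plot
}
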