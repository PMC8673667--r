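# MEDLINE/PubMed XML ingestion, chemical tagging via synonym lexicons, and
# the shipped configuration tables (heading map, chemical synonym lists).

#' Default heading normalization map
#'
#' Maps the section headings found on `<AbstractText Label=...>` attributes
#' onto the five canonical labels (`background`, `objective`, `methods`,
#' `results`, `conclusions`). Unknown headings map to `unlabeled`. The table
#' is a shipped, editable TSV (`heading_map.tsv`).
#'
#' @return Tibble with columns `heading`, `label`.
#' @export
default_heading_map <- function() {
  readr::read_tsv(cs_extdata("heading_map.tsv"), show_col_types = FALSE,
                  progress = FALSE)
}

map_heading <- function(x, heading_map) {
  key <- str_to_lower(str_trim(x))
  i <- match(key, str_to_lower(heading_map$heading))
  out <- heading_map$label[i]
  out[is.na(out)] <- "unlabeled"
  out
}

#' Read MEDLINE/PubMed citation XML into abstract records
#'
#' Parses single-citation files or baseline bundles (`<PubmedArticleSet>`),
#' returning one record per citation in input order. Structured-abstract
#' section labels are normalized through a configurable heading map; any
#' markup nested inside `<AbstractText>` is stripped; non-English records are
#' flagged via the `language` column, not dropped.
#'
#' @param path Path to a MEDLINE XML file.
#' @param heading_map Heading-normalization table, see [default_heading_map()].
#' @return Tibble with columns `pmid`, `title`, `language`, `sections`
#'   (list-column of per-record tibbles with `label`, `text`) and `chemicals`
#'   (list-column, empty until [tag_chemicals()] is called).
#' @export
read_medline_xml <- function(path, heading_map = default_heading_map()) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      abort(paste0("malformed MEDLINE XML in '", path, "': ",
                   conditionMessage(e)))
    }
  )
  cits <- xml2::xml_find_all(doc, "//MedlineCitation")
  if (length(cits) == 0L) cits <- list(doc)
  recs <- map(cits, function(cit) {
    pm <- xml2::xml_text(xml2::xml_find_first(cit, ".//PMID"))
    title <- xml2::xml_text(
      xml2::xml_find_first(cit, ".//Article/ArticleTitle"))
    lang <- xml2::xml_text(xml2::xml_find_first(cit, ".//Article/Language"))
    abst <- xml2::xml_find_all(cit, ".//Article/Abstract/AbstractText")
    if (length(abst) == 0L) {
      warn(paste0("record ", pm, " has no AbstractText; empty sections"))
      sections <- tibble(label = character(), text = character())
    } else {
      labels <- xml2::xml_attr(abst, "Label")
      nlm <- xml2::xml_attr(abst, "NlmCategory")
      labels[is.na(labels)] <- nlm[is.na(labels)]
      lab <- ifelse(is.na(labels), "unlabeled",
                    map_heading(labels, heading_map))
      sections <- tibble(label = lab, text = map_chr(abst, xml2::xml_text))
    }
    tibble(
      pmid = pm,
      title = ifelse(is.na(title), "", title),
      language = ifelse(is.na(lang), "eng", str_to_lower(lang)),
      sections = list(sections),
      chemicals = list(character())
    )
  })
  out <- bind_rows(recs)
  if (anyDuplicated(out$pmid)) {
    warn("duplicate PMIDs in corpus")
  }
  out
}

#' Write abstract records back to MEDLINE-style XML
#'
#' Inverse of [read_medline_xml()] (used by the fixture generator and for the
#' round-trip contract): section labels and texts survive a write/read cycle.
#'
#' @param records Abstract-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(records, path) {
  doc <- xml2::xml_new_root("PubmedArticleSet")
  canonical_upper <- c(
    background = "BACKGROUND", objective = "OBJECTIVE", methods = "METHODS",
    results = "RESULTS", conclusions = "CONCLUSIONS"
  )
  for (i in seq_len(nrow(records))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", records$pmid[i])
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle", records$title[i])
    xml2::xml_add_child(a, "Language", records$language[i])
    secs <- records$sections[[i]]
    if (nrow(secs)) {
      ab <- xml2::xml_add_child(a, "Abstract")
      for (j in seq_len(nrow(secs))) {
        node <- xml2::xml_add_child(ab, "AbstractText", secs$text[j])
        if (secs$label[j] != "unlabeled") {
          xml2::xml_set_attr(node, "Label",
                             canonical_upper[[secs$label[j]]])
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Default chemical synonym lexicons
#'
#' Reads the shipped chemical synonym table: the 27 xenobiotic chemicals of
#' the packaged study scope with a small seed synonym list each. The table is
#' configuration, not ground truth; extend it with your own synonyms (the
#' original selection was driven by PubChem synonym lists reviewed by a
#' domain expert, and the raw search strings may be stored alongside for
#' provenance only).
#'
#' @param path TSV with columns `chemical_id`, `name`, `synonym` (one synonym
#'   per line).
#' @return Tibble with one row per chemical: `chemical_id`, `name`,
#'   `synonyms` (list-column).
#' @export
read_chemical_lexicons <- function(path = cs_extdata("chemicals.tsv")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("chemical_id", "name", "synonym") %in% names(raw)))
  raw |>
    group_by(chemical_id, name) |>
    summarise(synonyms = list(unique(synonym)), .groups = "drop") |>
    arrange(chemical_id)
}

#' Tag abstract records with the chemicals they mention
#'
#' Case-insensitive surface matching on word boundaries against each
#' chemical's synonym list, over the title and every section text. A record
#' may carry several tags (abstracts often mention more than one chemical).
#' This is scope filtering, not chemical named-entity recognition.
#'
#' @param records Abstract-record tibble from [read_medline_xml()].
#' @param lexicons Chemical lexicon tibble from [read_chemical_lexicons()].
#' @return `records` with the `chemicals` list-column filled with chemical
#'   names.
#' @export
tag_chemicals <- function(records, lexicons = read_chemical_lexicons()) {
  if (is.null(lexicons) || nrow(lexicons) == 0L) {
    abort("empty chemical lexicon list")
  }
  if (any(map_int(lexicons$synonyms, length) == 0L)) {
    abort("every chemical lexicon needs at least one synonym")
  }
  pats <- map_chr(lexicons$synonyms, function(s) {
    paste0("\\b(", paste(map_chr(s, escape_regex), collapse = "|"), ")\\b")
  })
  records$chemicals <- map(seq_len(nrow(records)), function(i) {
    hay <- paste(records$title[i],
                 paste(records$sections[[i]]$text, collapse = " "))
    hit <- map_lgl(pats, ~ str_detect(hay, regex(.x, ignore_case = TRUE)))
    lexicons$name[hit]
  })
  records
}

escape_regex <- function(x) {
  str_replace_all(x, "([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1")
}
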