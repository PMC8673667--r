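# Anchor-term lexicon: directionality verbs (increase / decrease / general
# change) and causality verbs, expanded from base forms to all tenses and
# nominalized forms before matching against abstract text. The shipped seed
# list puts the three directionality categories at 58 + 86 + 71 = 215 bases;
# the counts are configuration, not ground truth, and the file is editable.

ANCHOR_CATEGORIES <- c("increase", "decrease", "general_change", "causality")

# curated irregular inflections and nominalizations; suffix rules cover the
# regular cases and deliberately over-generate (a non-word form simply never
# matches real text)
IRREGULAR_FORMS <- list(
  grow = c("grew", "grown", "growth"),
  rise = c("rose", "risen", "rise"),
  fall = c("fell", "fallen", "fall"),
  lose = c("lost", "loss"),
  lead = c("led"),
  bring = c("brought"),
  make = c("made"),
  drive = c("drove", "driven"),
  give = c("gave", "given"),
  arise = c("arose", "arisen"),
  shrink = c("shrank", "shrunk", "shrinkage"),
  speed = c("sped"),
  slow = c("slowdown"),
  "break" = c("broke", "broken"),
  begin = c("began", "begun"),
  become = c("became"),
  upregulate = c("upregulation", "up-regulation"),
  downregulate = c("downregulation", "down-regulation")
)

double_final <- function(base) {
  # consonant doubling for short CVC stems (stop -> stopped)
  str_detect(base, "[^aeiouwxy][aeiou][bdgklmnprt]$") & nchar(base) <= 5
}

inflect_verb <- function(base) {
  s_form <- if (str_detect(base, "(s|sh|ch|x|z|o)$")) {
    paste0(base, "es")
  } else if (str_detect(base, "[^aeiou]y$")) {
    paste0(str_sub(base, 1, -2), "ies")
  } else {
    paste0(base, "s")
  }
  stem <- if (double_final(base)) {
    paste0(base, str_sub(base, -1, -1))
  } else base
  past <- if (str_detect(base, "e$")) {
    paste0(base, "d")
  } else if (str_detect(base, "[^aeiou]y$")) {
    paste0(str_sub(base, 1, -2), "ied")
  } else {
    paste0(stem, "ed")
  }
  ger <- if (str_detect(base, "[^e]e$|ue$")) {
    paste0(str_sub(base, 1, -2), "ing")
  } else {
    paste0(stem, "ing")
  }
  c(base, s_form, past, ger)
}

nominalize_verb <- function(base) {
  out <- character()
  if (str_detect(base, "ate$")) {
    out <- c(out, str_replace_all(base, "ate$", "ation"))
  }
  if (str_detect(base, "(uce)$")) {
    out <- c(out, str_replace_all(base, "uce$", "uction"))
  }
  if (str_detect(base, "ize$")) {
    out <- c(out, str_replace_all(base, "ize$", "ization"))
  }
  if (str_detect(base, "ify$")) {
    out <- c(out, str_replace_all(base, "ify$", "ification"))
  }
  if (str_detect(base, "e$")) {
    out <- c(out, paste0(str_sub(base, 1, -2), "ion"),
             paste0(str_sub(base, 1, -2), "al"))
  } else {
    out <- c(out, paste0(base, "ion"))
  }
  out <- c(out, paste0(base, "ment"), paste0(base, "ance"))
  unique(out)
}

#' Read the anchor-term configuration
#'
#' @param path TSV with columns `base`, `category`; category must be one of
#'   `increase`, `decrease`, `general_change`, `causality`. Unknown category
#'   tokens are a hard error.
#' @return Tibble of base entries.
#' @export
read_anchor_config <- function(path = cs_extdata("anchors.tsv")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  stopifnot(all(c("base", "category") %in% names(raw)))
  bad <- setdiff(unique(raw$category), ANCHOR_CATEGORIES)
  if (length(bad)) {
    abort(paste0("unknown anchor category token(s): ",
                 paste(bad, collapse = ", ")))
  }
  dup <- raw$base[duplicated(raw$base)]
  if (length(dup)) {
    abort(paste0("anchor base(s) in more than one category: ",
                 paste(unique(dup), collapse = ", ")))
  }
  raw
}

#' Expand base anchor verbs to all tenses and nominalized forms
#'
#' Each base verb is expanded to its 3rd-person, past, participle and gerund
#' inflections plus nominalizations via suffix rules
#' (-tion/-sion/-ment/-ance/-al and friends) and a curated irregular table
#' (grow -> growth, lose -> loss). Expansion is deterministic and the base
#' form is always included.
#'
#' @param base_entries Tibble from [read_anchor_config()] (or any tibble with
#'   `base`, `category`).
#' @return Object of class `anchor_lexicon`: list with `entries` (the input)
#'   and `forms` (tibble `form`, `base`, `category`).
#' @export
expand_anchor_lexicon <- function(base_entries = read_anchor_config()) {
  bad <- setdiff(unique(base_entries$category), ANCHOR_CATEGORIES)
  if (length(bad)) {
    abort(paste0("unknown anchor category token(s): ",
                 paste(bad, collapse = ", ")))
  }
  forms <- pmap(base_entries, function(base, category, ...) {
    irr <- IRREGULAR_FORMS[[base]] %||% character()
    tibble(
      form = unique(c(inflect_verb(base), nominalize_verb(base), irr)),
      base = base, category = category
    )
  }) |> bind_rows()
  # a form generated for two bases resolves to the first listed
  forms <- forms[!duplicated(forms$form), ]
  structure(list(entries = base_entries, forms = forms),
            class = "anchor_lexicon")
}

#' Summarise anchor lexicon category sizes
#'
#' @param lex An `anchor_lexicon` (or base-entry tibble).
#' @return Tibble with `category`, `n_bases`.
#' @export
anchor_category_counts <- function(lex = expand_anchor_lexicon()) {
  entries <- if (inherits(lex, "anchor_lexicon")) lex$entries else lex
  entries |> count(category, name = "n_bases") |> arrange(category)
}

#' Match anchor occurrences in a parsed sentence
#'
#' Every token whose lemma or lower-cased surface form matches an expanded
#' anchor form becomes an occurrence tagged with its base verb and category.
#'
#' @param parse A `parsed_sentence`.
#' @param lex An `anchor_lexicon`.
#' @return Tibble with columns `id`, `form`, `base`, `category` (possibly
#'   empty).
#' @export
match_anchors <- function(parse, lex) {
  tk <- parse$tokens
  key <- str_to_lower(tk$lemma)
  alt <- str_to_lower(tk$form)
  i <- match(key, lex$forms$form)
  j <- match(alt, lex$forms$form)
  i[is.na(i)] <- j[is.na(i)]
  hit <- !is.na(i)
  tibble(
    id = tk$id[hit],
    form = tk$form[hit],
    base = lex$forms$base[i[hit]],
    category = lex$forms$category[i[hit]]
  )
}
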