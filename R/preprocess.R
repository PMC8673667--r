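# Text normalization, biomedical sentence segmentation and itemized-list
# expansion. All downstream rule modules consume the SentenceUnit tibble
# produced here: one row per sentence with 0-based contiguous indices per
# abstract and character offsets that are 0-based half-open throughout.

# Extended-ASCII -> ASCII approximation table. Accents, tildes, carons and
# similar diacritics are stripped; ligatures expand; characters outside the
# table pass through unchanged so the mapping is total and idempotent.
ascii_fold_table <- function() {
  c(
    "à" = "a", "á" = "a", "â" = "a", "ã" = "a",
    "ä" = "a", "å" = "a", "ā" = "a", "ă" = "a",
    "ç" = "c", "ć" = "c", "č" = "c",
    "è" = "e", "é" = "e", "ê" = "e", "ë" = "e",
    "ě" = "e", "ē" = "e", "ę" = "e",
    "ì" = "i", "í" = "i", "î" = "i", "ï" = "i",
    "ñ" = "n", "ń" = "n", "ň" = "n",
    "ò" = "o", "ó" = "o", "ô" = "o", "õ" = "o",
    "ö" = "o", "ō" = "o", "ø" = "o",
    "ù" = "u", "ú" = "u", "û" = "u", "ü" = "u",
    "ů" = "u", "ū" = "u",
    "ý" = "y", "ÿ" = "y",
    "ď" = "d", "đ" = "d",
    "ř" = "r", "ŕ" = "r",
    "š" = "s", "ś" = "s", "ş" = "s",
    "ť" = "t", "ţ" = "t",
    "ž" = "z", "ź" = "z", "ż" = "z",
    "ł" = "l", "ľ" = "l",
    "À" = "A", "Á" = "A", "Â" = "A", "Ã" = "A",
    "Ä" = "A", "Å" = "A",
    "Ç" = "C", "Č" = "C",
    "È" = "E", "É" = "E", "Ê" = "E", "Ë" = "E",
    "Ì" = "I", "Í" = "I", "Î" = "I", "Ï" = "I",
    "Ñ" = "N",
    "Ò" = "O", "Ó" = "O", "Ô" = "O", "Õ" = "O",
    "Ö" = "O", "Ø" = "O",
    "Ù" = "U", "Ú" = "U", "Û" = "U", "Ü" = "U",
    "Š" = "S", "Ž" = "Z", "Ř" = "R", "Ď" = "D",
    "ß" = "ss", "æ" = "ae", "Æ" = "AE",
    "œ" = "oe", "Œ" = "OE",
    "‘" = "'", "’" = "'", "“" = "\"", "”" = "\"",
    "–" = "-", "—" = "-", " " = " ", "µ" = "u"
  )
}

#' Replace extended-ASCII characters with ASCII approximations
#'
#' Accented letters, carons, tildes and common typographic punctuation in the
#' extended ASCII / Latin ranges are mapped onto plain ASCII approximations
#' (e.g. `"café"` becomes `"cafe"`, `"Kočí"` becomes `"Koci"`). Characters not
#' covered by the shipped mapping table pass through unchanged, so the
#' function is total and idempotent.
#'
#' @param raw Character vector of raw text.
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_text("café")
normalize_text <- function(raw) {
  tbl <- ascii_fold_table()
  str_replace_all(raw, setNames(unname(tbl), names(tbl)))
}

#' Default biomedical abbreviation list
#'
#' Reads the shipped abbreviation file (one abbreviation per line, trailing
#' period included). Sentence segmentation never breaks after these tokens.
#' The list is editable: pass your own vector to [segment_sentences()].
#'
#' @return Character vector of abbreviations such as `"et al."`, `"i.v."`.
#' @export
default_abbreviations <- function() {
  readLines(cs_extdata("abbreviations.txt"), warn = FALSE) |>
    str_trim() |>
    (\(x) x[nzchar(x) & !str_starts(x, "#")])()
}

#' Segment a section text into sentences
#'
#' Splits on `.`, `!` or `?` followed by whitespace and an upper-case letter,
#' digit or opening parenthesis, unless the token ending at the candidate
#' boundary is a known abbreviation, a single capital initial (`"J."`), or an
#' internally dotted token (`"i.v."`, `"E.coli"`).
#'
#' @param section_text One string of (already normalized) section text.
#' @param abbreviations Character vector of abbreviations that never terminate
#'   a sentence. Defaults to the shipped biomedical list.
#' @return Character vector of sentences, trimmed, empty sentences dropped.
#' @export
#' @examples
#' segment_sentences("Cells died. Proliferation rose.")
segment_sentences <- function(section_text,
                              abbreviations = default_abbreviations()) {
  stopifnot(length(section_text) == 1L)
  txt <- str_trim(section_text)
  if (!nzchar(txt)) return(character())
  abb <- str_to_lower(abbreviations)

  # candidate boundaries: terminator + space + sentence-opening character
  m <- str_locate_all(txt, "[.!?]+(?=\\s+[A-Z0-9(\"])")[[1]]
  if (nrow(m) == 0L) return(txt)
  cuts <- integer()
  for (i in seq_len(nrow(m))) {
    endpos <- m[i, "end"]
    before <- str_sub(txt, 1L, endpos)
    last_tok <- str_match(before, "(\\S+)$")[, 2]
    lt <- str_to_lower(last_tok)
    if (lt %in% abb) next
    # single capital initial: "J." / "A."
    if (str_detect(last_tok, "^[A-Z]\\.$")) next
    # internally dotted tokens keep their final period inside the sentence
    if (str_detect(last_tok, "^\\S+\\.\\S+\\.?$")) next
    cuts <- c(cuts, endpos)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(txt))
  out <- str_trim(str_sub(txt, starts, ends))
  out[nzchar(out)]
}

item_marker_regex <- function(kind) {
  switch(kind,
    numeric = "\\((\\d{1,2})\\)",
    alpha = "\\(([a-h])\\)",
    roman = "\\((i{1,3}|iv|v|vi{0,3}|ix|x)\\)"
  )
}

roman_value <- function(x) {
  vals <- c(i = 1, ii = 2, iii = 3, iv = 4, v = 5, vi = 6, vii = 7,
            viii = 8, ix = 9, x = 10)
  unname(vals[x])
}

# find a marker series of >= 2 ascending markers starting at 1/a/i
find_marker_series <- function(text) {
  for (kind in c("numeric", "alpha", "roman")) {
    pat <- item_marker_regex(kind)
    loc <- str_locate_all(text, pat)[[1]]
    if (nrow(loc) < 2L) next
    labs <- str_match_all(text, pat)[[1]][, 2]
    vals <- switch(kind,
      numeric = as.integer(labs),
      alpha = match(labs, letters),
      roman = roman_value(labs)
    )
    # keep the longest ascending run starting at 1
    ok <- which(vals == seq_along(vals))
    if (length(ok) >= 2L && all(seq_len(length(ok)) == ok)) {
      keep <- seq_len(max(ok))
      return(list(kind = kind, start = loc[keep, 1], end = loc[keep, 2]))
    }
  }
  NULL
}

#' Expand an itemized list sentence into its constituent parts
#'
#' Sentences that enumerate items with `(1) ... (2) ...`, `(a) ... (b) ...` or
#' `(i) ... (ii) ...` interfere with dependency parsing, so they are expanded:
#' the preamble (text before the first marker, if non-empty after trimming
#' punctuation) becomes the first sentence and each item becomes its own
#' sentence with the marker stripped. A series must contain at least two
#' ascending markers to fire; anything else is returned unchanged.
#'
#' @param sentence_text One sentence string.
#' @return Character vector: either the input unchanged or preamble + items.
#' @export
#' @examples
#' expand_itemized_list("Two effects: (1) growth rose, (2) death fell.")
expand_itemized_list <- function(sentence_text) {
  stopifnot(length(sentence_text) == 1L)
  series <- find_marker_series(sentence_text)
  if (is.null(series)) return(sentence_text)
  starts <- series$start
  ends <- series$end
  pre <- str_trim(str_sub(sentence_text, 1L, starts[1] - 1L))
  pre <- str_replace_all(pre, "[:;,\\s]+$", "")
  pieces <- character()
  if (nzchar(pre)) pieces <- pre
  item_starts <- ends + 1L
  item_ends <- c(starts[-1] - 1L, nchar(sentence_text))
  for (i in seq_along(item_starts)) {
    it <- str_trim(str_sub(sentence_text, item_starts[i], item_ends[i]))
    it <- str_replace_all(it, "^[:;,\\s]+|[;,\\s]+$", "")
    if (nzchar(it)) pieces <- c(pieces, it)
  }
  pieces
}

#' Segment an abstract record into sentence units
#'
#' Normalizes each section, segments it into sentences, expands itemized
#' lists, and assigns contiguous 0-based indices across the whole abstract in
#' section order. These indices are the keys used by gold-parse backends.
#'
#' @param record One row of an abstract-record tibble (see
#'   [read_medline_xml()]), or a list with `pmid` and `sections` fields.
#' @param abbreviations Passed to [segment_sentences()].
#' @return Tibble with columns `pmid`, `section_label`, `index`, `text`.
#' @export
segment_abstract <- function(record, abbreviations = default_abbreviations()) {
  sections <- record$sections
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    sections <- record$sections[[1]]
    pm <- record$pmid
  } else {
    pm <- record$pmid
  }
  rows <- list()
  for (i in seq_len(nrow(sections))) {
    sents <- segment_sentences(normalize_text(sections$text[i]), abbreviations)
    sents <- unlist(lapply(sents, expand_itemized_list), use.names = FALSE)
    if (length(sents)) {
      rows[[length(rows) + 1L]] <- tibble(
        pmid = pm, section_label = sections$label[i], text = sents
      )
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(pmid = character(), section_label = character(), text = character())
  out$index <- seq_len(nrow(out)) - 1L
  out[, c("pmid", "section_label", "index", "text")]
}
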