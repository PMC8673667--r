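# Dependency-parse representation and the pluggable parser backend contract.
#
# The rule modules are written once against a canonical relation-label set
# (Universal-Dependencies style, with ":" replaced by "_"); a shipped alias
# table translates Stanford-basic labels so gold parses may use either
# dialect. The package deliberately does not implement a syntactic parser:
# parses come from an external tool or from gold-parse fixture files in
# CoNLL-U format, which keeps every downstream rule test independent of a
# specific parser build.

DEPREL_ALIASES <- c(
  # Stanford basic -> canonical UD-style
  dobj = "obj", nsubjpass = "nsubj_pass", auxpass = "aux_pass",
  csubjpass = "csubj_pass", pobj = "nmod", prep = "case", nn = "compound",
  num = "nummod", agent = "obl_agent", preconj = "cc_preconj",
  poss = "nmod_poss", rcmod = "acl_relcl", partmod = "acl", vmod = "acl",
  quantmod = "advmod", tmod = "obl_tmod"
)

#' Normalize a dependency relation label to the canonical dialect
#'
#' Lower-cases, replaces `:` with `_`, drops subtype suffixes of `conj` and
#' `nmod` produced by collapsed Stanford dependencies (`conj_and` -> `conj`,
#' `nmod_of` / `prep_of` -> `nmod`), and applies the Stanford-basic alias
#' table so rules are written once.
#'
#' @param x Character vector of relation labels.
#' @return Character vector of canonical labels.
#' @export
normalize_deprel <- function(x) {
  x <- str_replace_all(str_to_lower(x), ":", "_")
  x <- str_replace_all(x, "^conj_.*$", "conj")
  x <- str_replace_all(x, "^(nmod|prep)_.+$", "nmod")
  hit <- x %in% names(DEPREL_ALIASES)
  x[hit] <- DEPREL_ALIASES[x[hit]]
  x
}

#' Construct a parsed sentence
#'
#' The in-memory parse is a token tibble plus sentence metadata. Tokens are
#' 1-based ids in surface order; `head` is the id of the governor (0 for the
#' single root); `deprel` is normalized via [normalize_deprel()]. Character
#' spans are 0-based half-open offsets into `text`; when `text` is omitted it
#' is reconstructed by joining forms with spaces (punctuation attaches
#' without a preceding space).
#'
#' @param tokens Data frame with columns `form`, `lemma`, `upos`, `head`,
#'   `deprel` (and optionally `id`, `start`, `end`).
#' @param pmid,index,section_label,text Sentence metadata.
#' @return Object of class `parsed_sentence`.
#' @export
parsed_sentence <- function(tokens, pmid = NA_character_, index = NA_integer_,
                            section_label = NA_character_, text = NULL) {
  tokens <- as_tibble(tokens)
  if (!"id" %in% names(tokens)) tokens$id <- seq_len(nrow(tokens))
  tokens$deprel <- normalize_deprel(tokens$deprel)
  tokens$head <- as.integer(tokens$head)
  if (sum(tokens$head == 0L) != 1L) {
    abort("a parsed sentence must have exactly one root token")
  }
  if (any(tokens$head > nrow(tokens) | tokens$head < 0L)) {
    abort("token head indices out of range")
  }
  if (is.null(text) || !all(c("start", "end") %in% names(tokens))) {
    # rebuild text and spans from forms
    glue_space <- !str_detect(tokens$form, "^[,.;:!?)]") &
      seq_len(nrow(tokens)) > 1L
    pos <- 0L
    starts <- ends <- integer(nrow(tokens))
    parts <- character(nrow(tokens))
    for (i in seq_len(nrow(tokens))) {
      if (glue_space[i]) pos <- pos + 1L
      starts[i] <- pos
      pos <- pos + nchar(tokens$form[i])
      ends[i] <- pos
    }
    if (is.null(text)) {
      text <- paste0(ifelse(glue_space, " ", ""), tokens$form, collapse = "")
    }
    tokens$start <- starts
    tokens$end <- ends
  }
  if (is.unsorted(tokens$start) || any(tokens$end[-nrow(tokens)] >
        tokens$start[-1])) {
    abort("token spans must be ordered and non-overlapping")
  }
  tokens <- tokens[, c("id", "form", "lemma", "upos", "head", "deprel",
                       "start", "end")]
  structure(
    list(pmid = pmid, index = as.integer(index),
         section_label = section_label, text = text, tokens = tokens),
    class = "parsed_sentence"
  )
}

#' @export
print.parsed_sentence <- function(x, ...) {
  cat("<parsed_sentence ", x$pmid, ":", x$index, "> ", x$text, "\n", sep = "")
  print(x$tokens[, c("id", "form", "lemma", "upos", "head", "deprel")])
  invisible(x)
}

parse_key <- function(pmid, index) paste0(pmid, ":", index)

# -- CoNLL-U reading/writing (gold-parse fixture format) ----------------------

#' Write parses to a CoNLL-U file
#'
#' Sentence metadata is carried in `# pmid =`, `# sent_index =`, `# section =`
#' and `# text =` comment lines; character offsets travel in the MISC column
#' as `SpanStart=..|SpanEnd=..`.
#'
#' @param parses List of `parsed_sentence` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(parses, path) {
  blocks <- map_chr(parses, function(p) {
    hdr <- c(
      paste0("# pmid = ", p$pmid),
      paste0("# sent_index = ", p$index),
      paste0("# section = ", p$section_label),
      paste0("# text = ", p$text)
    )
    rows <- pmap(p$tokens, function(id, form, lemma, upos, head, deprel,
                                    start, end, ...) {
      paste(id, form, lemma, upos, "_", "_", head, deprel, "_",
            paste0("SpanStart=", start, "|SpanEnd=", end), sep = "\t")
    })
    paste(c(hdr, unlist(rows)), collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read gold parses from a CoNLL-U file
#'
#' @param path Path to a CoNLL-U file written by [write_conllu()] (or by any
#'   tool emitting the standard 10-column format with the same metadata
#'   comments).
#' @return Named list of `parsed_sentence` objects keyed `"<pmid>:<index>"`.
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grp <- cumsum(c(TRUE, !nzchar(lines[-length(lines)])))
  blocks <- split(lines, grp)
  parses <- list()
  for (bl in blocks) {
    bl <- bl[nzchar(bl)]
    if (!length(bl)) next
    meta <- bl[str_starts(bl, "#")]
    body <- bl[!str_starts(bl, "#")]
    get_meta <- function(key) {
      m <- str_match(meta, paste0("^# ", key, " = (.*)$"))[, 2]
      m <- m[!is.na(m)]
      if (length(m)) m[1] else NA_character_
    }
    fields <- str_split(body, "\t")
    tok <- tibble(
      id = as.integer(map_chr(fields, 1)),
      form = map_chr(fields, 2),
      lemma = map_chr(fields, 3),
      upos = map_chr(fields, 4),
      head = as.integer(map_chr(fields, 7)),
      deprel = map_chr(fields, 8)
    )
    misc <- map_chr(fields, 10)
    sp <- str_match(misc, "SpanStart=(\\d+)\\|SpanEnd=(\\d+)")
    txt <- get_meta("text")
    if (!any(is.na(sp[, 2]))) {
      tok$start <- as.integer(sp[, 2])
      tok$end <- as.integer(sp[, 3])
    }
    p <- parsed_sentence(
      tok, pmid = get_meta("pmid"),
      index = as.integer(get_meta("sent_index")),
      section_label = get_meta("section"),
      text = if (is.na(txt)) NULL else txt
    )
    parses[[parse_key(p$pmid, p$index)]] <- p
  }
  parses
}

# -- backend contract ---------------------------------------------------------

#' Gold-parse backend
#'
#' Returns a parser backend that looks sentences up in a store of gold parses
#' keyed by pmid and sentence index, the file-backed contract used by all rule
#' tests.
#'
#' @param source Either a named list of `parsed_sentence` objects (as returned
#'   by [read_conllu()]) or a path to a CoNLL-U file / directory of `.conllu`
#'   files.
#' @return A function `(sentence_unit) -> parsed_sentence`.
#' @export
gold_parse_backend <- function(source) {
  store <- if (is.character(source)) {
    files <- if (dir.exists(source)) {
      list.files(source, pattern = "\\.conllu$", full.names = TRUE)
    } else source
    Reduce(c, lapply(files, read_conllu))
  } else {
    source
  }
  function(sentence) {
    key <- parse_key(sentence$pmid, sentence$index)
    p <- store[[key]]
    if (is.null(p)) {
      abort(paste0("no gold parse for sentence ", key))
    }
    p$section_label <- sentence$section_label %||% p$section_label
    p
  }
}

#' Parse a sentence through a pluggable backend
#'
#' @param sentence One row of the sentence-unit tibble from
#'   [segment_abstract()] (needs `pmid`, `index`, `text`).
#' @param backend A backend function such as [gold_parse_backend()]. There is
#'   no built-in statistical parser; calling without a backend is an error.
#' @return A `parsed_sentence`.
#' @export
parse_dependencies <- function(sentence, backend = NULL) {
  if (is.null(backend)) {
    abort(paste0(
      "no parser backend configured; supply an external backend or use ",
      "gold_parse_backend() with CoNLL-U fixture parses"
    ))
  }
  backend(sentence)
}

#' Build a parse from compact token strings
#'
#' Convenience constructor for hand-written gold parses: each token is a
#' string `"form|lemma|upos|head|deprel"` with `head` the 1-based index of
#' the governor (0 for the root).
#'
#' @param tokens Character vector of token strings.
#' @param pmid,index,section_label Sentence metadata.
#' @return A `parsed_sentence`.
#' @export
#' @examples
#' parse_from_tokens(c(
#'   "Cadmium|cadmium|PROPN|2|nsubj",
#'   "induced|induce|VERB|0|root",
#'   "apoptosis|apoptosis|NOUN|2|obj",
#'   ".|.|PUNCT|2|punct"
#' ))
parse_from_tokens <- function(tokens, pmid = NA_character_,
                              index = NA_integer_,
                              section_label = NA_character_) {
  fields <- str_split(tokens, fixed("|"))
  stopifnot(all(lengths(fields) == 5L))
  tk <- tibble(
    form = map_chr(fields, 1), lemma = map_chr(fields, 2),
    upos = map_chr(fields, 3), head = as.integer(map_chr(fields, 4)),
    deprel = map_chr(fields, 5)
  )
  parsed_sentence(tk, pmid = pmid, index = index,
                  section_label = section_label)
}

# small tree helpers used by the rule modules
tok_children <- function(tokens, id, rels = NULL) {
  ch <- tokens[tokens$head == id, , drop = FALSE]
  if (!is.null(rels)) ch <- ch[ch$deprel %in% rels, , drop = FALSE]
  ch
}

tok_parent <- function(tokens, id) {
  h <- tokens$head[tokens$id == id]
  if (length(h) != 1L || h == 0L) return(NULL)
  tokens[tokens$id == h, , drop = FALSE]
}
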