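---
title: "Extracting directed cell-outcome evidence from biomedical abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting directed cell-outcome evidence from biomedical abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimscope)
library(dplyr)
```

## The problem

Chemical risk assessments synthesize the literature in four steps:
retrieval, extraction, verification and analysis. Automated tools mostly
stop at retrieval — they count how many abstracts *mention* an outcome. But
an abstract that reports "X did **not** induce apoptosis" is evidence
*against* an association, and counting it alongside supporting studies
misleads a decision maker. claimscope implements the extraction step as a
transparent, rule-based pipeline: it finds mentions of three cell-level
outcomes — **cell proliferation** (an increase in the number of cells
through growth and division), **cell death** (including apoptotic and
necrotic expressions) and **general cell changes** (neither of the former)
— and characterizes every claim about them as supporting, neutral or
refuting, with negation tracked at two levels. Because every decision is a
dictionary entry or a dependency-path rule, the scope of a synthesis is
explicit and reproducible, which is what a public-policy setting demands of
an automated aid.

## The model

A **claim** binds an *anchor term* (a verb, or its inflection or
nominalization, signaling change) to an *outcome mention* through a
dependency path. The anchor's category fixes the claim polarity:

* increase anchors (induce, stimulate, elevate, ...) → polarity `up`;
* decrease anchors (inhibit, attenuate, reduce, ...) → polarity `down`;
* general-change and causality anchors (affect, effect, cause, ...) →
  polarity `neutral` (a change is asserted, its direction is not).

Negation is reconciled at two independent levels. *Claim-level* negation
negates the change relation itself ("did **not** inhibit", "**failed** to
stimulate", "**neither** A **nor** B increased"). *Outcome-level* negation
lives inside the outcome phrase ("cell **loss**", "**anti**proliferative
activity", "growth **inhibition**"). Three polarities times two binary
negation levels give twelve raw claim states, which collapse onto a
six-step ordered evidence scale:

> Refute < NegatedRefute < Neutral < NegatedNeutral < NegatedSupport <
> Support

by a two-step algebra: outcome negation flips `up` and `down` (neutral is a
fixed point, and the flip is an involution), then claim negation prefixes
"Negated". So "reduction in cell loss" is (down, outcome-negated) →
Support, and "did not induce neuronal cell loss" is (up, claim-negated,
outcome-negated) → NegatedRefute. `reconcile_direction()` implements the
algebra and the test suite verifies it against a hand-transcribed
twelve-row table; both negation flags and the polarity are preserved on
every record for audit.

One sentence may carry several claims with conflicting directions
("attenuates necrotic death triggered by Cd" yields a Refute from
*attenuates* and a Support from *triggered*, on the same outcome); the
pipeline keeps all of them. No judgment of veracity, statistical
significance or claim importance is attempted.

## Pipeline stages and their parameters

**Ingestion** (`read_medline_xml()`, `tag_chemicals()`). MEDLINE citation
XML is read one record per citation; structured-abstract headings are
normalized through a shipped, editable map (`heading_map.tsv`; unknown
headings become `unlabeled`). Chemical scope is reproduced locally by
case-insensitive word-boundary matching of synonym lists
(`chemicals.tsv`, 27 seed chemicals); this is surface scope filtering, not
chemical NER, and a record may carry several tags.

**Preprocessing** (`normalize_text()`, `segment_sentences()`,
`expand_itemized_list()`). Extended-ASCII characters are folded to ASCII
approximations by a total, idempotent mapping table. Sentence boundaries
respect a shipped biomedical abbreviation list (editable,
`abbreviations.txt`). Itemized lists written as `(1) ... (2) ...` (also
`(a)`/`(i)` series; at least two ascending markers required) are expanded
into the preamble plus one sentence per item before parsing, because such
lists degrade dependency parses. List expansion happens before parsing, so
gold-parse keys use post-expansion sentence indices (0-based, contiguous
across the abstract).

**Parsing** (`parse_dependencies()`). The package does not ship a
syntactic parser. Parses come through a pluggable backend; the shipped
backend (`gold_parse_backend()`) loads gold parses from CoNLL-U files
keyed by PMID and sentence index, so every rule is testable without a
parser build. Relation labels are normalized to a single canonical dialect
(`normalize_deprel()`), with an alias table translating Stanford-basic
labels (dobj → obj, nsubjpass → nsubj_pass, prep/pobj → nmod, ...), so the
rules are written once.

**Coordinated ellipsis** (`extract_noun_phrases()`). Authors elide shared
words in coordinations: *backward* ("T and B cells" → T cells, B cells),
*forward* ("cell death and proliferation" → cell death, cell
proliferation) and *complex* ("normal human and animal cells" → normal
human cells, normal animal cells). Candidates are read off conjunction
arcs; shared heads and shared modifiers distribute over every conjunct,
including head pre-modifiers that sit between the conjuncts and the head
("striatal and cortical cell loss" → striatal cell loss, cortical cell
loss). Two acceptance mechanisms are implemented: a rule — an expansion
that would repeat a word is rejected wholesale — and a heuristic —
when modifier–head co-occurrence statistics are available
(`ccnp_stats()`), every implied (modifier, head) pair must have corpus
support at or above a threshold (default 1, tunable; on small corpora the
rule-only mode is the default). Hyphenated compounds are single tokens and
never split. When an elided phrase and its bare literal remnant would
describe the same occurrence (the remnant's lemmas are a subset of the
expansion on the same head), only the expansion is kept.

**Outcome matching** (`build_outcome_lexicon()`,
`find_outcome_mentions()`). Outcome expressions are matched by set
semantics over phrase lemmas: a phrase is proliferation if it carries at
least one cell term and one proliferation term, death analogously, and
`cell_general` when only a cell term fires — so extra modifiers never
break a match and the classes partition mentions. Single-word expressions
(apoptosis, necrosis, ...) match standalone. Exclusion filters veto any
phrase containing "pathway(s)" or a word starting with "factor" or
"peroxisom", and the veto always beats a positive match (so "tumor
necrosis factor" is never cell death). Outcome-level negation markers are
the lemmas *loss* and *inhibition* plus the prefix *anti-* (with *pro-*
stripped neutrally); *arrest* is deliberately not a marker — cell-cycle
arrest is a death-class outcome. Prepositional constructions
("proliferation of cultured gastric cancer cells", "loss of dopaminergic
neurons") yield mentions anchored at the governing nominal, normalized to
an underscore dialect (`loss_dopaminergic neuron`). Where a phrase carries
terms of both primary classes ("growth arrest") death wins; the shipped
seed lexicon records a provenance for every term and is meant to be
extended. Viability phrases are treated as cell terms, so "loss of cell
viability" is a negated proliferation outcome.

**Section restriction** (`select_result_conclusion()`). Only result and
conclusion sentences feed claim extraction, so an author's motivation or
account of prior work is never mined as a finding. Declared labels always
win; abstracts with at least one canonical heading count as structured.
For unstructured abstracts a pluggable classifier decides; the shipped
default flags sentences in the final 40% of the abstract or opening with a
results cue ("Results ...", "We found ...", "In conclusion ..."), and
`train_section_classifier()` fits a logistic model on the structured
abstracts of the user's own corpus (mirroring the train-on-structured
design that a transformer-based classifier would use; the plug-in contract
is the architecture, the model is replaceable).

**Claim extraction** (`sentence_claims()`). Anchor occurrences are matched
on lemma or surface against the expanded anchor lexicon; a token that
heads an outcome mention is an outcome, not an anchor (this matters where
nominalizations collide: *loss* is also the noun of *lose*, *growth* of
*grow*). Reachability from anchor to mention is one of: a direct argument
arc (including a participial anchor modifying the mention head, as in
"MPP-induced neuron loss"); one prepositional link ("induction of
apoptosis"); a measurement nominal bridge ("the amount of cell death";
measurement terms are configuration: amount, level, rate, degree, extent,
number, index, ...); or a participial bridge from a nominal anchor
("effects promoting cell growth"). Conjunction arcs are transparent on the
mention side, so a coordination-expanded mention reached through its first
conjunct still claims. A claim is `explicit` when the anchor carries an
agent or subject phrase distinct from the outcome, else an `observation`;
passive subjects are treated as the changed entity.

**Reapplication for changes-in-cells.** A directional change on a
`cell_general` mention implicitly names a primary outcome: an increase in
cells *is* cell proliferation and a decrease *is* cell death. Such claims
mint a derived mention (`derived_from_change`, normalized like
`increase_cell`) headed at the inner anchor token, and the rules rerun
against the derived mentions so an outer anchor can act on them
("inhibited the increase in ... cells" → refuting proliferation). When no
outer anchor takes over, the originating claim is retargeted with its
polarity reset to `up`, because the directionality has been absorbed into
the class — "a decrease in cells" is *supporting* evidence for cell death.
A second application finds no remaining `cell_general` directional claims,
so the rule is idempotent. Causality anchors never contribute
directionality; only increase/decrease anchors mint derived mentions.

**Aggregation and reporting** (`count_claims()`, `count_abstracts()`,
`compare_outcomes()`, `render_waffle()`). Claim-level counting counts
every record; abstract-level counting counts each abstract at most once
per (direction, outcome) — an abstract can still appear under several
directions, so abstract-level percentages may sum above 100%.
Abstract-level counts never exceed claim-level counts, a property the test
suite checks on random corpora. The decision comparison computes, per
chemical, retrieved-abstract counts, supporting-abstract counts and
percentages, and supporting-claim counts and percentages, each with a
Prolif/Death/Tie verdict; "supporting" means the plain Support direction
only (a flag widens it), percentage denominators are abstracts (claims)
with at least one extracted claim for the outcome, ties are reported as
ties, and zero denominators render as missing. Waffle plots draw one cell
per counted unit (or per configurable scaling factor) colored along the
six-step order with a fixed legend, and always return the tidy cell table
alongside the figure so plots stay auditable.

## The synthetic-data generator

`generate_fixtures()` instantiates seeded MEDLINE-style abstracts from a
template grammar covering exactly the constructions the rule set claims to
handle: direct, prepositional and measurement paths; claim negation via
"did not <verb>" and "no <nominal>"; outcome negation via loss- and
anti-forms; forward-elided coordinations ("cell death and proliferation");
structured and unstructured section layouts. Each abstract carries
background/methods filler so planted claim sentences sit strictly in the
final 40%, which is what the positional section heuristic assumes; a "hard
mode" adds distractors — a claim about the chemical in the background
section, a "tumor necrosis factor pathway" sentence, an unchanged
"peroxisome proliferation" sentence — that must contribute nothing. The
generator emits the corpus XML, gold parses for every sentence and a
ground-truth record table whose directions come from its own hand-coded
twelve-state lookup, *not* from `reconcile_direction()`, so the round-trip
integration test (100% recovery, zero false records) is a genuine
dual-route check.

What the generator does not emulate: free prose variation, parser errors,
anaphora, hedging, passive constructions beyond the templated ones, and
section-heading noise. Passing the round trip therefore shows the rule
machinery is internally consistent, not that recall on real abstracts is
high; on real corpora the gold-parse backend is replaced by an external
parser, which becomes the dominant error source.

## Numerical and design choices

* The shipped anchor file fixes the three directionality categories at
  58 increase + 86 decrease + 71 general-change = 215 bases, with 60
  causality bases; all counts are configuration. The seed lists contain
  every anchor the packaged rules are documented against, padded with
  standard biomedical change verbs. *contribute* is an increase anchor and
  *cause*, *kill*, *arrest* are causality (neutral-polarity) anchors.
* Inflection/nominalization expansion over-generates by design (suffix
  rules plus a curated irregular table: grow→growth, lose→loss); a
  generated non-word never matches real text, so over-generation is safe,
  while under-generation loses claims.
* Character offsets are 0-based half-open everywhere; token ids are
  1-based within a sentence; sentence indices are 0-based within an
  abstract.
* The ellipsis acceptance threshold defaults to 1 co-occurrence because
  desk-scale corpora cannot support a higher cut; it is exposed as a
  parameter.
* Ties in the decision comparison are never broken arbitrarily; `Tie` is a
  first-class verdict.
* Duplicate identical claims within one abstract are kept as distinct
  claim-level records — collapsing them is exactly the difference between
  claim-level and abstract-level counting, which is the point of reporting
  both.
* Untagged abstracts produce records under a sentinel `untagged` chemical
  with a warning rather than silently disappearing.
* "Was not inhibited" constructions could be read pragmatically as an
  affirmation that the outcome persisted; the rules resolve them
  mechanically as a negated decrease (NegatedRefute), keeping the algebra
  uniform. The raw states on each record let a downstream consumer apply a
  different reading.

## Problem sizes used in the checks

The shipped tests and the acceptance script run on synthetic corpora of 2
to 10 abstracts (one to four planted claims each, plus the 90-abstract
exhaustive grammar sweep), the 24 reconciliation-table snippets and the
worked three-abstract aggregation example; the whole suite completes in
about a minute on one core. These sizes exercise every rule branch; they
are not a corpus-scale benchmark, and corpus-scale summary statistics are
out of scope by design.

## Known limitations

* Accuracy on real text is bounded by the external dependency parser and
  the seed lexicons; both are configuration, and the package makes
  extending them cheap rather than pretending completeness.
* Only the changed entity is modeled; comparison, association and
  implicit claim types are out of scope, as are agent normalization and
  statistical-significance filtering.
* Chemical tagging is surface matching; it reproduces scope filtering of a
  search, not entity recognition.
* Non-English abstracts are flagged and skipped by convention, not
  translated.
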