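# Hand-written gold dependency parses for the worked example sentences and
# the twelve-row reconciliation table's 24 snippets, plus small shared
# lexicon objects. Parses use the compact "form|lemma|upos|head|deprel"
# token notation of parse_from_tokens().

test_outcome_lex <- function() build_outcome_lexicon()
test_anchor_lex <- function() expand_anchor_lexicon()

pt <- function(..., pmid = "t", index = 0L) {
  parse_from_tokens(c(...), pmid = pmid, index = index)
}

# "Neither sulindac sulfide nor sulfone inhibited cell proliferation ..."
parse_sent3 <- function() pt(
  "Neither|neither|CCONJ|3|cc_preconj",
  "sulindac|sulindac|NOUN|3|compound",
  "sulfide|sulfide|NOUN|6|nsubj",
  "nor|nor|CCONJ|5|cc",
  "sulfone|sulfone|NOUN|3|conj",
  "inhibited|inhibit|VERB|0|root",
  "cell|cell|NOUN|8|compound",
  "proliferation|proliferation|NOUN|6|obj",
  ".|.|PUNCT|6|punct",
  pmid = "7606732"
)

# "... Gadd45alpha was induced in both p53-effective and p53-defective
# cells after cadmium treatment ..."
parse_sent4 <- function() pt(
  "Gadd45alpha|gadd45alpha|PROPN|3|nsubj_pass",
  "was|be|AUX|3|aux_pass",
  "induced|induce|VERB|0|root",
  "in|in|ADP|9|case",
  "both|both|CCONJ|6|cc_preconj",
  "p53-effective|p53-effective|ADJ|9|amod",
  "and|and|CCONJ|8|cc",
  "p53-defective|p53-defective|ADJ|6|conj",
  "cells|cell|NOUN|3|obl",
  "after|after|ADP|12|case",
  "cadmium|cadmium|NOUN|12|compound",
  "treatment|treatment|NOUN|3|obl",
  ".|.|PUNCT|3|punct",
  pmid = "17174997"
)

# "Enzastaurin suppressed the proliferation of cultured gastric cancer
# cells and the growth of gastric carcinoma xenografts."
parse_sent5 <- function() pt(
  "Enzastaurin|enzastaurin|PROPN|2|nsubj",
  "suppressed|suppress|VERB|0|root",
  "the|the|DET|4|det",
  "proliferation|proliferation|NOUN|2|obj",
  "of|of|ADP|9|case",
  "cultured|cultured|ADJ|9|amod",
  "gastric|gastric|ADJ|9|amod",
  "cancer|cancer|NOUN|9|compound",
  "cells|cell|NOUN|4|nmod",
  "and|and|CCONJ|12|cc",
  "the|the|DET|12|det",
  "growth|growth|NOUN|4|conj",
  "of|of|ADP|16|case",
  "gastric|gastric|ADJ|16|amod",
  "carcinoma|carcinoma|NOUN|16|compound",
  "xenografts|xenograft|NOUN|12|nmod",
  ".|.|PUNCT|2|punct",
  pmid = "18339873"
)

# "Released irinotecan inhibited the proliferation of U251 malignant
# glioma cells."
parse_sent6 <- function() pt(
  "Released|release|VERB|2|amod",
  "irinotecan|irinotecan|NOUN|3|nsubj",
  "inhibited|inhibit|VERB|0|root",
  "the|the|DET|5|det",
  "proliferation|proliferation|NOUN|3|obj",
  "of|of|ADP|10|case",
  "U251|u251|PROPN|10|compound",
  "malignant|malignant|ADJ|10|amod",
  "glioma|glioma|NOUN|10|compound",
  "cells|cell|NOUN|5|nmod",
  ".|.|PUNCT|3|punct",
  pmid = "24460101"
)

# "We show here that Nec-1 also effectively attenuates necrotic death
# triggered by Cd."
parse_sent7 <- function() pt(
  "We|we|PRON|2|nsubj",
  "show|show|VERB|0|root",
  "here|here|ADV|2|advmod",
  "that|that|SCONJ|8|mark",
  "Nec-1|nec-1|PROPN|8|nsubj",
  "also|also|ADV|8|advmod",
  "effectively|effectively|ADV|8|advmod",
  "attenuates|attenuate|VERB|2|ccomp",
  "necrotic|necrotic|ADJ|10|amod",
  "death|death|NOUN|8|obj",
  "triggered|trigger|VERB|10|acl",
  "by|by|ADP|13|case",
  "Cd|cd|PROPN|11|obl_agent",
  ".|.|PUNCT|2|punct",
  pmid = "19135076"
)

# "Results show a statistically significant increase in cell proliferation."
parse_observation <- function() pt(
  "Results|result|NOUN|2|nsubj",
  "show|show|VERB|0|root",
  "a|a|DET|6|det",
  "statistically|statistically|ADV|5|advmod",
  "significant|significant|ADJ|6|amod",
  "increase|increase|NOUN|2|obj",
  "in|in|ADP|9|case",
  "cell|cell|NOUN|9|compound",
  "proliferation|proliferation|NOUN|6|nmod",
  ".|.|PUNCT|2|punct"
)

# 24 snippets spanning the twelve-row reconciliation map, one noun-phrase
# and one non-noun realization per row, each with the anchor whose claim
# the row illustrates and the expected direction. "Was not inhibited" is a
# negated decrease and reconciles to NegatedRefute like any other; the
# genuine NegatedSupport case of the claim-negated up-polarity row is the
# "failed to stimulate" realization.
table1_snippets <- function() {
  list(
    list(name = "up/plain NP: increased cell proliferation",
         anchor = "increase", class = "proliferation", expect = "Support",
         parse = pt(
           "Treatment|treatment|NOUN|2|nsubj",
           "increased|increase|VERB|0|root",
           "cell|cell|NOUN|4|compound",
           "proliferation|proliferation|NOUN|2|obj",
           ".|.|PUNCT|2|punct")),
    list(name = "up/plain NN: induced proliferation of cells",
         anchor = "induce", class = "proliferation", expect = "Support",
         parse = pt(
           "It|it|PRON|2|nsubj",
           "induced|induce|VERB|0|root",
           "proliferation|proliferation|NOUN|2|obj",
           "of|of|ADP|7|case",
           "mammary|mammary|ADJ|7|amod",
           "epithelial|epithelial|ADJ|7|amod",
           "cells|cell|NOUN|3|nmod",
           ".|.|PUNCT|2|punct")),
    list(name = "neutral/plain NP: effects of agents on cell proliferation",
         anchor = "effect", class = "proliferation", expect = "Neutral",
         parse = pt(
           "The|the|DET|3|det",
           "short-term|short-term|ADJ|3|amod",
           "effects|effect|NOUN|11|nsubj_pass",
           "of|of|ADP|6|case",
           "various|various|ADJ|6|amod",
           "agents|agent|NOUN|3|nmod",
           "on|on|ADP|9|case",
           "cell|cell|NOUN|9|compound",
           "proliferation|proliferation|NOUN|3|nmod",
           "were|be|AUX|11|aux_pass",
           "examined|examine|VERB|0|root",
           ".|.|PUNCT|11|punct")),
    list(name = "neutral/plain NN: effects promoting cell growth",
         anchor = "effect", class = "proliferation", expect = "Neutral",
         parse = pt(
           "Effects|effect|NOUN|6|nsubj_pass",
           "promoting|promote|VERB|1|acl",
           "cell|cell|NOUN|4|compound",
           "growth|growth|NOUN|2|obj",
           "were|be|AUX|6|aux_pass",
           "observed|observe|VERB|0|root",
           ".|.|PUNCT|6|punct")),
    list(name = "down/plain NP: inhibit DLD-1 cell growth",
         anchor = "inhibit", class = "proliferation", expect = "Refute",
         parse = pt(
           "The|the|DET|2|det",
           "compound|compound|NOUN|4|nsubj",
           "directly|directly|ADV|4|advmod",
           "inhibited|inhibit|VERB|0|root",
           "DLD-1|dld-1|PROPN|7|compound",
           "cell|cell|NOUN|7|compound",
           "growth|growth|NOUN|4|obj",
           ".|.|PUNCT|4|punct")),
    list(name = "down/plain NN: down-regulates proliferation of cells",
         anchor = "down-regulate", class = "proliferation",
         expect = "Refute",
         parse = pt(
           "It|it|PRON|2|nsubj",
           "down-regulates|down-regulate|VERB|0|root",
           "proliferation|proliferation|NOUN|2|obj",
           "of|of|ADP|6|case",
           "choriocarcinoma|choriocarcinoma|NOUN|6|compound",
           "cells|cell|NOUN|3|nmod",
           ".|.|PUNCT|2|punct")),
    list(name = "negated-up NP: proliferation was not inhibited",
         anchor = "inhibit", class = "proliferation",
         expect = "NegatedRefute",
         parse = pt(
           "Cell|cell|NOUN|2|compound",
           "proliferation|proliferation|NOUN|5|nsubj_pass",
           "was|be|AUX|5|aux_pass",
           "not|not|PART|5|advmod",
           "inhibited|inhibit|VERB|0|root",
           "by|by|ADP|8|case",
           "the|the|DET|8|det",
           "treatment|treatment|NOUN|5|obl_agent",
           ".|.|PUNCT|5|punct")),
    list(name = "negated-up NN: failed to stimulate the growth",
         anchor = "stimulate", class = "proliferation",
         expect = "NegatedSupport",
         parse = pt(
           "The|the|DET|2|det",
           "extract|extract|NOUN|3|nsubj",
           "failed|fail|VERB|0|root",
           "to|to|PART|5|mark",
           "stimulate|stimulate|VERB|3|xcomp",
           "the|the|DET|7|det",
           "growth|growth|NOUN|5|obj",
           "of|of|ADP|10|case",
           "WY-1|wy-1|PROPN|10|compound",
           "cells|cell|NOUN|7|nmod",
           ".|.|PUNCT|3|punct")),
    list(name = "negated-neutral NP: had no effects on cell proliferation",
         anchor = "effect", class = "proliferation",
         expect = "NegatedNeutral",
         parse = pt(
           "The|the|DET|2|det",
           "treatment|treatment|NOUN|3|nsubj",
           "had|have|VERB|0|root",
           "no|no|DET|5|det",
           "effects|effect|NOUN|3|obj",
           "on|on|ADP|8|case",
           "cell|cell|NOUN|8|compound",
           "proliferation|proliferation|NOUN|5|nmod",
           ".|.|PUNCT|3|punct")),
    list(name = "negated-neutral NN: no influence on the proliferation",
         anchor = "influence", class = "proliferation",
         expect = "NegatedNeutral",
         parse = pt(
           "It|it|PRON|2|nsubj",
           "had|have|VERB|0|root",
           "no|no|DET|5|det",
           "apparent|apparent|ADJ|5|amod",
           "influence|influence|NOUN|2|obj",
           "on|on|ADP|8|case",
           "the|the|DET|8|det",
           "proliferation|proliferation|NOUN|5|nmod",
           "of|of|ADP|11|case",
           "stem|stem|NOUN|11|compound",
           "cells|cell|NOUN|8|nmod",
           ".|.|PUNCT|2|punct")),
    list(name = "negated-down NP: did not inhibit cell growth",
         anchor = "inhibit", class = "proliferation",
         expect = "NegatedRefute",
         parse = pt(
           "The|the|DET|2|det",
           "compound|compound|NOUN|5|nsubj",
           "did|do|AUX|5|aux",
           "not|not|PART|5|advmod",
           "inhibit|inhibit|VERB|0|root",
           "cell|cell|NOUN|7|compound",
           "growth|growth|NOUN|5|obj",
           ".|.|PUNCT|5|punct")),
    list(name = "negated-down NN: growth of cells was not inhibited",
         anchor = "inhibit", class = "proliferation",
         expect = "NegatedRefute",
         parse = pt(
           "Growth|growth|NOUN|9|nsubj_pass",
           "of|of|ADP|4|case",
           "HepG2|hepg2|PROPN|4|compound",
           "cells|cell|NOUN|1|nmod",
           "in|in|ADP|6|case",
           "culture|culture|NOUN|1|nmod",
           "was|be|AUX|9|aux_pass",
           "not|not|PART|9|advmod",
           "inhibited|inhibit|VERB|0|root",
           "by|by|ADP|12|case",
           "the|the|DET|12|det",
           "compound|compound|NOUN|9|obl_agent",
           ".|.|PUNCT|9|punct")),
    list(name = "up/neg-outcome NP: MPP-induced neuron loss",
         anchor = "induce", class = "proliferation", expect = "Refute",
         parse = pt(
           "MPP|mpp|PROPN|2|nsubj",
           "induced|induce|VERB|5|amod",
           "sympathetic|sympathetic|ADJ|5|amod",
           "neuron|neuron|NOUN|5|compound",
           "loss|loss|NOUN|7|nsubj_pass",
           "was|be|AUX|7|aux_pass",
           "observed|observe|VERB|0|root",
           ".|.|PUNCT|7|punct")),
    list(name = "up/neg-outcome NN: contributes to the loss of neurons",
         anchor = "contribute", class = "proliferation", expect = "Refute",
         parse = pt(
           "The|the|DET|2|det",
           "chemical|chemical|NOUN|3|nsubj",
           "contributes|contribute|VERB|0|root",
           "to|to|ADP|6|case",
           "the|the|DET|6|det",
           "loss|loss|NOUN|3|obl",
           "of|of|ADP|9|case",
           "such|such|ADJ|9|amod",
           "neurons|neuron|NOUN|6|nmod",
           ".|.|PUNCT|3|punct")),
    list(name = "neutral/neg-outcome NP: effect on antiproliferative activity",
         anchor = "effect", class = "proliferation", expect = "Neutral",
         parse = pt(
           "A|a|DET|4|det",
           "strong|strong|ADJ|4|amod",
           "synergistic|synergistic|ADJ|4|amod",
           "effect|effect|NOUN|11|nsubj_pass",
           "on|on|ADP|9|case",
           "antiproliferative|antiproliferative|ADJ|9|amod",
           "and|and|CCONJ|8|cc",
           "proapoptotic|proapoptotic|ADJ|6|conj",
           "activity|activity|NOUN|4|nmod",
           "was|be|AUX|11|aux_pass",
           "found|find|VERB|0|root",
           ".|.|PUNCT|11|punct")),
    list(name = "neutral/neg-outcome NN: effect on loss of thymocytes",
         anchor = "effect", class = "proliferation", expect = "Neutral",
         parse = pt(
           "The|the|DET|2|det",
           "effect|effect|NOUN|8|nsubj_pass",
           "on|on|ADP|4|case",
           "loss|loss|NOUN|2|nmod",
           "of|of|ADP|6|case",
           "thymocytes|thymocyte|NOUN|4|nmod",
           "is|be|AUX|8|aux_pass",
           "discussed|discuss|VERB|0|root",
           ".|.|PUNCT|8|punct")),
    list(name = "down/neg-outcome NP: reduction in striatal and cortical cell loss",
         anchor = "reduce", class = "proliferation", expect = "Support",
         parse = pt(
           "A|a|DET|2|det",
           "reduction|reduction|NOUN|10|nsubj_pass",
           "in|in|ADP|8|case",
           "striatal|striatal|ADJ|8|amod",
           "and|and|CCONJ|6|cc",
           "cortical|cortical|ADJ|4|conj",
           "cell|cell|NOUN|8|compound",
           "loss|loss|NOUN|2|nmod",
           "was|be|AUX|10|aux_pass",
           "seen|see|VERB|0|root",
           ".|.|PUNCT|10|punct")),
    list(name = "down/neg-outcome NN: diminish bulbectomy-induced loss of neurons",
         anchor = "diminish", class = "proliferation", expect = "Support",
         parse = pt(
           "The|the|DET|2|det",
           "treatment|treatment|NOUN|3|nsubj",
           "diminished|diminish|VERB|0|root",
           "bulbectomy-induced|bulbectomy-induced|ADJ|5|amod",
           "loss|loss|NOUN|3|obj",
           "of|of|ADP|8|case",
           "NRD|nrd|PROPN|8|compound",
           "neurons|neuron|NOUN|5|nmod",
           ".|.|PUNCT|3|punct")),
    list(name = "negated-up/neg-outcome NP: did not induce neuronal cell loss",
         anchor = "induce", class = "proliferation",
         expect = "NegatedRefute",
         parse = pt(
           "PQ|pq|PROPN|4|nsubj",
           "did|do|AUX|4|aux",
           "not|not|PART|4|advmod",
           "induce|induce|VERB|0|root",
           "neuronal|neuronal|ADJ|7|amod",
           "cell|cell|NOUN|7|compound",
           "loss|loss|NOUN|4|obj",
           ".|.|PUNCT|4|punct")),
    list(name = "negated-up/neg-outcome NN: did not induce the loss of DA neurons",
         anchor = "induce", class = "proliferation",
         expect = "NegatedRefute",
         parse = pt(
           "The|the|DET|2|det",
           "compound|compound|NOUN|5|nsubj",
           "did|do|AUX|5|aux",
           "not|not|PART|5|advmod",
           "induce|induce|VERB|0|root",
           "the|the|DET|7|det",
           "loss|loss|NOUN|5|obj",
           "of|of|ADP|10|case",
           "DA|da|PROPN|10|compound",
           "neurons|neuron|NOUN|7|nmod",
           ".|.|PUNCT|5|punct")),
    list(name = "negated-neutral/neg-outcome NP: no effect on antiproliferative activity",
         anchor = "effect", class = "proliferation",
         expect = "NegatedNeutral",
         parse = pt(
           "It|it|PRON|2|nsubj",
           "had|have|VERB|0|root",
           "no|no|DET|5|det",
           "appreciable|appreciable|ADJ|5|amod",
           "effect|effect|NOUN|2|obj",
           "on|on|ADP|9|case",
           "its|its|PRON|9|nmod_poss",
           "antiproliferative|antiproliferative|ADJ|9|amod",
           "activity|activity|NOUN|5|nmod",
           ".|.|PUNCT|2|punct")),
    list(name = "negated-neutral/neg-outcome NN: no effect on loss of cell viability",
         anchor = "effect", class = "proliferation",
         expect = "NegatedNeutral",
         parse = pt(
           "It|it|PRON|2|nsubj",
           "had|have|VERB|0|root",
           "no|no|DET|4|det",
           "effect|effect|NOUN|2|obj",
           "on|on|ADP|6|case",
           "loss|loss|NOUN|4|nmod",
           "of|of|ADP|9|case",
           "cell|cell|NOUN|9|compound",
           "viability|viability|NOUN|6|nmod",
           ".|.|PUNCT|2|punct")),
    list(name = "negated-down/neg-outcome NP: did not prevent TH-positive cell loss",
         anchor = "prevent", class = "proliferation",
         expect = "NegatedSupport",
         parse = pt(
           "The|the|DET|2|det",
           "treatment|treatment|NOUN|5|nsubj",
           "did|do|AUX|5|aux",
           "not|not|PART|5|advmod",
           "prevent|prevent|VERB|0|root",
           "TH-positive|th-positive|ADJ|8|amod",
           "cell|cell|NOUN|8|compound",
           "loss|loss|NOUN|5|obj",
           ".|.|PUNCT|5|punct")),
    list(name = "negated-down/neg-outcome NN: did not prevent the loss of goblet cells",
         anchor = "prevent", class = "proliferation",
         expect = "NegatedSupport",
         parse = pt(
           "The|the|DET|2|det",
           "agent|agent|NOUN|5|nsubj",
           "did|do|AUX|5|aux",
           "not|not|PART|5|advmod",
           "prevent|prevent|VERB|0|root",
           "the|the|DET|7|det",
           "loss|loss|NOUN|5|obj",
           "of|of|ADP|11|case",
           "conjunctival|conjunctival|ADJ|11|amod",
           "goblet|goblet|NOUN|11|compound",
           "cells|cell|NOUN|7|nmod",
           ".|.|PUNCT|5|punct"))
  )
}

# directions of the claims a snippet yields for its illustrated anchor/class
snippet_directions <- function(sn, olex, alex) {
  cl <- sentence_claims(sn$parse, olex, alex)
  cl <- cl[cl$anchor_base == sn$anchor & cl$outcome_class == sn$class, ]
  as.character(reconcile_direction(cl$polarity, cl$claim_negated,
                                   cl$outcome_negated))
}
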