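# claimscope

Transparent, rule-based extraction of directed cell-outcome evidence from
MEDLINE/PubMed abstracts, for chemical risk-assessment decision support.

## The problem

Automated literature tools for risk assessment usually stop at the
*retrieval* step: they count abstracts that mention an outcome. But an
abstract stating that a chemical "did **not** induce apoptosis" is evidence
*against* an association. claimscope automates the *extraction* step: it
finds mentions of three cell-level outcomes — **cell proliferation** (an
increase in the number of cells through growth and division), **cell
death** (including apoptosis and necrosis) and **general cell changes** —
and characterizes every claim about them as supporting, neutral or
refuting, tracking negation both in the relation ("failed to stimulate")
and inside the outcome phrase ("cell loss", "antiproliferative"). Because
every decision is a dictionary entry or a dependency-path rule, inclusion
and exclusion criteria stay explicit, which is what a public-policy
setting requires.

## The model

A claim binds an **anchor term** (a change verb, or an inflection or
nominalization of one: *inhibit, inhibits, inhibited, inhibition, ...*) to
an **outcome mention** through a dependency path (direct argument,
prepositional link, or a measurement-nominal bridge such as "the amount of
cell death"). The anchor category fixes polarity *p* ∈ {up, neutral,
down}; with claim-level negation *c* and outcome-level negation *o*, the
evidence direction is

```
direction(p, c, o) = prefix_Negated^c ( flip^o (p) )
```

where `flip` swaps up ↔ down (neutral fixed) and the result maps onto the
six-step ordered scale

```
Refute < NegatedRefute < Neutral < NegatedNeutral < NegatedSupport < Support
```

So "reduction in cell loss" → (down, –, ¬) → **Support**, and "did not
induce neuronal cell loss" → (up, ¬, ¬) → **NegatedRefute**. Before
matching, coordinated elliptical noun phrases are resolved ("T and B
cells" → T cells + B cells; "cell death and proliferation" → cell death +
cell proliferation), and only result/conclusion sentences are mined.
Evidence is aggregated per (chemical, outcome) at claim level (every
record) and abstract level (each abstract once per direction) and shown as
waffle plots.

## Worked example

The package ships a seeded generator for MEDLINE-style abstracts with
planted claims and gold dependency parses, so the whole pipeline runs
offline. Here three abstracts about thiobenzamide plant supporting,
refuting and neutral proliferation claims:

```r
library(claimscope)
library(dplyr)

spec <- fixture_spec(
  list(
    bind_rows(claim_plan("proliferation", "up"),
              claim_plan("proliferation", "up")),
    bind_rows(claim_plan("proliferation", "up"),
              claim_plan("proliferation", "up"),
              claim_plan("proliferation", "down"),
              claim_plan("proliferation", "neutral")),
    bind_rows(claim_plan("proliferation", "up"),
              claim_plan("proliferation", "up"))
  ),
  chemicals = "Thiobenzamide", seed = 27
)
fx <- generate_fixtures(spec)
fx$records$sections[[2]]$text[3]
#> [1] "Thiobenzamide induced cell proliferation. Thiobenzamide induced
#>      cell proliferation. Thiobenzamide inhibited cell proliferation.
#>      Thiobenzamide modulated cellular proliferation."

records <- extract_evidence(tag_chemicals(fx$records),
                            gold_parse_backend(fx$parses))
count_claims(records)
#> <evidence_summary level=claim>
#> # A tibble: 6 x 4
#>   chemical      outcome_class direction          n
#>   <chr>         <chr>         <ord>          <int>
#> 1 Thiobenzamide proliferation Refute             1
#> 2 Thiobenzamide proliferation NegatedRefute      0
#> 3 Thiobenzamide proliferation Neutral            1
#> 4 Thiobenzamide proliferation NegatedNeutral     0
#> 5 Thiobenzamide proliferation NegatedSupport     0
#> 6 Thiobenzamide proliferation Support            6
```

Eight claims: six supporting, one refuting, one neutral. At abstract level
the same records count each abstract once per direction — three
supporting, one refuting, one neutral abstracts:

```r
glance(count_abstracts(records))
#> # A tibble: 1 x 8
#>   level    chemical      outcome_class n_total n_support n_refute n_neutral n_negated
#>   <chr>    <chr>         <chr>           <int>     <int>    <int>     <int>     <int>
#> 1 abstract Thiobenzamide proliferation       5         3        1         1         0
```

The gap between "6 of 8 claims support" and "3 of 3 abstracts contain a
supporting claim" is exactly why both levels are reported.
`render_waffle(count_claims(records))` draws the eight cells (six green)
with the tidy cell table alongside; `compare_outcomes()` computes the
proliferation-versus-death decision measures per chemical, each with a
Prolif/Death/Tie verdict.

On real data, replace the generator with `read_medline_xml()` +
`tag_chemicals()` and supply parses from your syntactic parser through
`gold_parse_backend()`-style CoNLL-U files (the package deliberately does
not bundle a parser). All lexicons — anchors, outcome terms, chemicals,
abbreviations, heading map — are editable TSV/text files under
`inst/extdata/`. A thin command-line wrapper lives at
`inst/scripts/claimscope.R` (`fixtures`, `extract`, `report`
subcommands).

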