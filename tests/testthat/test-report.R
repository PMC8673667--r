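# Claim- vs abstract-level aggregation, the decision comparison, waffles.

# the three worked-example abstracts: [S,S], [S,S,R,N], [S,S] for one
# chemical and outcome
table2_records <- function() {
  dirs <- list(c("Support", "Support"),
               c("Support", "Support", "Refute", "Neutral"),
               c("Support", "Support"))
  purrr::imap(dirs, function(d, i) {
    tibble::tibble(
      pmid = paste0("a", i), chemical = "Thiobenzamide",
      outcome_class = "proliferation",
      direction = factor(d, levels = levels(evidence_directions()),
                         ordered = TRUE)
    )
  }) |> dplyr::bind_rows()
}

test_that("claim counting reproduces the worked aggregation example", {
  cc <- count_claims(table2_records())
  get <- function(d) cc$n[cc$direction == d]
  expect_equal(get("Support"), 6L)
  expect_equal(get("Refute"), 1L)
  expect_equal(get("Neutral"), 1L)
  expect_equal(sum(cc$n), 8L)
  expect_equal(attr(cc, "level"), "claim")
})

test_that("abstract counting dedups within direction but not across", {
  ca <- count_abstracts(table2_records())
  get <- function(d) ca$n[ca$direction == d]
  expect_equal(get("Support"), 3L)
  expect_equal(get("Refute"), 1L)
  expect_equal(get("Neutral"), 1L)
  expect_equal(attr(ca, "level"), "abstract")
  # an abstract repeating one claim five times counts once
  rep5 <- tibble::tibble(
    pmid = "r", chemical = "X", outcome_class = "death",
    direction = factor(rep("Support", 5),
                       levels = levels(evidence_directions()),
                       ordered = TRUE))
  expect_equal(sum(count_abstracts(rep5)$n), 1L)
  # empty input gives all-zero counts
  expect_equal(sum(count_claims(table2_records()[0, ])$n), 0L)
})

test_that("abstract-level counts never exceed claim-level counts", {
  for (seed in c(2, 19, 57)) {
    res <- run_fixture_pipeline(
      generate_fixtures(random_fixture_spec(6, seed = seed)), quiet = TRUE)
    cc <- tidy(count_claims(res$records))
    ca <- tidy(count_abstracts(res$records))
    j <- dplyr::inner_join(cc, ca,
                           by = c("chemical", "outcome_class", "direction"),
                           suffix = c("_claim", "_abs"))
    expect_true(all(j$n_abs <= j$n_claim))
    expect_equal(sum(cc$n), nrow(res$records))
  }
})

# build records reproducing given support/total counts per outcome
synth_counts <- function(chem, outcome, n_abs_support, n_abs_total,
                         n_claim_support, n_claim_total) {
  lv <- levels(evidence_directions())
  support_abs <- purrr::map(seq_len(n_abs_support), function(i) {
    tibble::tibble(pmid = paste0(outcome, "s", i), direction = "Support")
  })
  other_abs <- purrr::map(seq_len(n_abs_total - n_abs_support), function(i) {
    tibble::tibble(pmid = paste0(outcome, "o", i), direction = "Neutral")
  })
  base <- dplyr::bind_rows(support_abs, other_abs)
  extra_support <- tibble::tibble(
    pmid = paste0(outcome, "s", 1),
    direction = rep("Support", n_claim_support - n_abs_support))
  extra_other <- tibble::tibble(
    pmid = paste0(outcome, "o", 1),
    direction = rep("Neutral",
                    n_claim_total - n_claim_support -
                      (n_abs_total - n_abs_support)))
  dplyr::bind_rows(base, extra_support, extra_other) |>
    dplyr::mutate(chemical = chem, outcome_class = outcome,
                  direction = factor(direction, levels = lv,
                                     ordered = TRUE))
}

test_that("the decision comparison reproduces the genistein worked row", {
  # retrieved 1,674 prolif vs 1,039 death abstracts; 486/1,097 vs 677/856
  # supporting abstracts (44.3% vs 79.1%); 668/1,871 vs 1,307/2,105
  # supporting claims (35.7% vs 62.1%)
  recs <- dplyr::bind_rows(
    synth_counts("Genistein", "proliferation", 486, 1097, 668, 1871),
    synth_counts("Genistein", "death", 677, 856, 1307, 2105)
  )
  retrieved <- tibble::tibble(
    chemical = "Genistein",
    outcome_class = c("proliferation", "death"),
    n_abstracts = c(1674L, 1039L)
  )
  cmp <- compare_outcomes(recs, retrieved)
  v <- function(m) cmp[cmp$measure == m, ]
  expect_equal(v("retrieved_abstracts")$verdict, "Prolif")
  expect_equal(v("supporting_abstracts")$verdict, "Death")
  expect_equal(round(v("supporting_abstract_pct")$prolif, 1), 44.3)
  expect_equal(round(v("supporting_abstract_pct")$death, 1), 79.1)
  expect_equal(v("supporting_abstract_pct")$verdict, "Death")
  expect_equal(v("supporting_claims")$prolif, 668)
  expect_equal(v("supporting_claims")$death, 1307)
  expect_equal(round(v("supporting_claim_pct")$prolif, 1), 35.7)
  expect_equal(round(v("supporting_claim_pct")$death, 1), 62.1)
  expect_equal(v("supporting_claim_pct")$verdict, "Death")
})

test_that("verdicts are antisymmetric and ties are reported as ties", {
  lv <- levels(evidence_directions())
  mk <- function(np, nd) {
    dplyr::bind_rows(
      tibble::tibble(pmid = paste0("p", seq_len(np)),
                     outcome_class = "proliferation"),
      tibble::tibble(pmid = paste0("d", seq_len(nd)),
                     outcome_class = "death")
    ) |>
      dplyr::mutate(chemical = "X",
                    direction = factor("Support", levels = lv,
                                       ordered = TRUE))
  }
  a <- compare_outcomes(mk(5, 2))
  b <- compare_outcomes(mk(2, 5))
  expect_equal(a$verdict[a$measure == "supporting_claims"], "Prolif")
  expect_equal(b$verdict[b$measure == "supporting_claims"], "Death")
  tie <- compare_outcomes(mk(3, 3))
  expect_true(all(tie$verdict == "Tie"))
  # zero denominators render as missing percentages
  zero <- compare_outcomes(mk(3, 3)[0, ],
                           retrieved = tibble::tibble(
                             chemical = "X",
                             outcome_class = c("proliferation", "death"),
                             n_abstracts = c(1L, 0L)))
  pct <- zero[zero$measure == "supporting_abstract_pct", ]
  expect_true(all(is.na(pct$prolif)))
})

test_that("waffle layout emits one cell per unit in direction order", {
  wd <- waffle_data(count_claims(table2_records()))
  expect_equal(nrow(wd), 8L)
  expect_equal(sum(wd$direction == "Support"), 6L)
  # directions come out ordered least- to most-supportive
  expect_false(is.unsorted(as.integer(wd$direction)))
  # scaling factor shrinks cell counts
  wd2 <- waffle_data(count_claims(table2_records()), units_per_cell = 2)
  expect_equal(nrow(wd2), sum(ceiling(c(1, 1, 6) / 2)))
  # empty summary -> no image, warning, table only
  empty <- count_claims(table2_records()[0, ])
  expect_warning(out <- render_waffle(empty), "empty")
  expect_null(out$plot)
  expect_equal(nrow(out$data), 0L)
})

test_that("waffle rendering returns an auditable plot + table pair", {
  summ <- count_claims(table2_records())
  out <- render_waffle(summ)
  expect_s3_class(out$plot, "ggplot")
  expect_equal(nrow(out$data), 8L)
  expect_s3_class(autoplot(summ), "ggplot")
  g <- glance(summ)
  expect_equal(g$n_support, 6L)
  expect_equal(g$n_total, 8L)
})
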