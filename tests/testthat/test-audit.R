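test_that("citation parsing handles brackets, groups, bare tokens, and malformed ids", {
  inst <- parse_citations("X silences Y [PMC12345].")
  expect_equal(nrow(inst), 1)
  expect_identical(inst$pmcids[[1]], "PMC12345")
  expect_true(inst$terminal[1])

  inst <- parse_citations("Multiple sources agree [PMC1, PMC2, PMC3].")
  expect_equal(nrow(inst), 1)
  expect_identical(inst$pmcids[[1]], c("PMC1", "PMC2", "PMC3"))

  expect_equal(nrow(parse_citations("Bad citation [PMCabc] here.")), 0)
  expect_equal(nrow(parse_citations("No citations at all.")), 0)

  inst <- parse_citations("Mid PMC7 claim continues. Tail claim [PMC8].")
  expect_equal(nrow(inst), 2)
  expect_false(inst$terminal[1])
  expect_true(inst$terminal[2])
  expect_equal(inst$sentence_index, c(1L, 2L))
})

test_that("adequacy passes at exactly 0.5 references per sentence", {
  s4 <- "One fact [PMC1]. Two here. Three more [PMC2]. Four ends."
  inst <- parse_citations(s4)
  expect_true(check_adequacy(s4, inst)$passed)          # 2 refs / 4 sentences
  s4b <- "One fact [PMC1]. Two here. Three more. Four ends."
  rep_b <- check_adequacy(s4b, parse_citations(s4b))
  expect_false(rep_b$passed)                            # 1 / 4 = 0.25
  expect_equal(rep_b$detail$ratio, 0.25)
  s1 <- "A single uncited claim."
  expect_false(check_adequacy(s1, parse_citations(s1))$passed)
  expect_error(check_adequacy("", parse_citations("")), "no sentences")
})

test_that("formatting flags numeric markers, PMIDs, DOIs, and malformed groups", {
  ok <- "Claim one [PMC123]. Claim two [PMC456, PMC789]."
  expect_true(check_formatting(ok, parse_citations(ok))$passed)
  for (bad in c("Claim [1].", "Claim (see PMID: 12345).",
                "Claim doi:10.1000/xyz here.", "Claim [PMCabc].",
                "Claim (PMC123).")) {
    rep <- check_formatting(bad, parse_citations(bad))
    expect_false(rep$passed)
    expect_gt(length(rep$detail$offending), 0)
  }
  # lenient mode accepts parenthesized PMC citations
  lenient <- check_thresholds(bracket_mode = "lenient")
  s <- "Claim (PMC123)."
  expect_true(check_formatting(s, parse_citations(s), lenient)$passed)
})

test_that("realness requires cited ids to exist in the context", {
  ctx <- make_test_context(seed = 21)
  ids <- unique(ctx$sentences$pmcid)
  good <- sprintf("A claim [%s].", ids[1])
  expect_true(check_realness(parse_citations(good), ctx)$passed)
  bad <- "A claim [PMC9999999]."
  rep <- check_realness(parse_citations(bad), ctx)
  expect_false(rep$passed)
  expect_identical(rep$detail$offending, "PMC9999999")
  # no citations at all: realness vacuously passes (adequacy owns absence)
  expect_true(check_realness(parse_citations("No refs."), ctx)$passed)
})

test_that("placement fails trailing blocks but tolerates rare mid-sentence citations", {
  good <- "One claim [PMC1]. Another claim [PMC2]."
  expect_true(check_placement(parse_citations(good), good)$passed)
  trail <- "One claim. Another claim. [PMC1, PMC2, PMC3]"
  rep <- check_placement(parse_citations(trail), trail)
  expect_false(rep$passed)
  expect_true(rep$detail$all_trailing)
  # a single terminal citation on a one-sentence summary is fine
  single <- "Only claim [PMC1]."
  expect_true(check_placement(parse_citations(single), single)$passed)
  # 1 of 10 instances mid-sentence stays within the 0.2 tolerance
  ten <- paste(c(sprintf("Claim %d [PMC%d].", 1:9, 1:9),
                 "Mid PMC10 claim continues."), collapse = " ")
  expect_true(check_placement(parse_citations(ten), ten)$passed)
  # 3 of 10 exceeds it
  mixed <- paste(c(sprintf("Claim %d [PMC%d].", 1:7, 1:7),
                   sprintf("Mid PMC%d claim continues.", 8:10)), collapse = " ")
  expect_false(check_placement(parse_citations(mixed), mixed)$passed)
})

test_that("concentration caps any instance at half the references, small totals exempt", {
  s <- "A [PMC1, PMC2]. B [PMC3]. C [PMC4]."
  expect_true(check_concentration(parse_citations(s))$passed)  # 2 of 4 = 50%
  s <- "A [PMC1, PMC2, PMC3]. B [PMC4]."
  rep <- check_concentration(parse_citations(s))
  expect_false(rep$passed)                                     # 3 of 4 = 75%
  expect_equal(rep$detail$max_instance, 3L)
  s <- "Single citation [PMC1]."
  rep <- check_concentration(parse_citations(s))
  expect_true(rep$passed)
  expect_true(rep$detail$exempt)
})

test_that("checks run in fixed order and the first failure picks the rescue", {
  ctx <- make_test_context(seed = 22)
  clean <- make_defective_summary(defect_spec("none", ctx, seed = 1))
  audit <- run_reference_checks(clean, ctx)
  expect_true(audit$passed)
  expect_identical(names(audit$reports),
                   c("adequacy", "formatting", "realness", "placement",
                     "concentration"))

  invented <- make_defective_summary(defect_spec("invented_pmcid", ctx, seed = 1))
  audit <- run_reference_checks(invented, ctx)
  expect_identical(audit$first_failure, "realness")
  expect_identical(audit$rescue_template, "rescue_identifier")

  # failing adequacy and placement together selects adequacy (first in order)
  both <- "One claim. Another claim. Third claim. Fourth claim. [PMC1]"
  audit <- run_reference_checks(both, ctx)
  expect_false(audit$reports$adequacy$passed)
  expect_false(audit$reports$placement$passed)
  expect_identical(audit$first_failure, "adequacy")
  expect_identical(audit$rescue_template, "rescue_adequacy")
})

test_that("adding a terminal citation never flips adequacy pass to fail", {
  ctx <- make_test_context(seed = 23)
  ids <- unique(ctx$sentences$pmcid)
  for (seed in 1:10) {
    s <- make_defective_summary(defect_spec("none", ctx, seed = seed))
    before <- check_adequacy(s, parse_citations(s))$passed
    s2 <- paste0(s, sprintf(" A further statement [%s].", ids[1]))
    after <- check_adequacy(s2, parse_citations(s2))$passed
    expect_false(before && !after)
  }
})

test_that("checks are pure: same inputs give identical reports", {
  ctx <- make_test_context(seed = 24)
  s <- make_defective_summary(defect_spec("stacked_refs", ctx, seed = 2))
  expect_identical(run_reference_checks(s, ctx), run_reference_checks(s, ctx))
})

test_that("audit reports serialize to JSON with exit-style pass flag", {
  ctx <- make_test_context(seed = 25)
  s <- make_defective_summary(defect_spec("none", ctx, seed = 1))
  js <- audit_to_json(run_reference_checks(s, ctx))
  parsed <- jsonlite::fromJSON(js)
  expect_true(parsed$passed)
  expect_equal(length(parsed$checks), 5)
})
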