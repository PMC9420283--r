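test_that("the packaged registry loads with 16 validated estimates", {
  ev <- dairy_evidence()
  expect_s3_class(ev, "tbl_df")
  expect_equal(nrow(ev), 16)
  expect_true(all(ev$srre > 0 & ev$ci_lower > 0))
  expect_true(all(ev$ci_lower <= ev$srre & ev$srre <= ev$ci_upper))
  expect_true(all(ev$n_studies >= 1))
})

test_that("reading tolerates an empty table and reports schema/row problems", {
  empty <- write_evidence_csv(make_estimate()[0, ])
  expect_equal(nrow(read_evidence(empty)), 0)

  no_srre <- make_estimate()
  no_srre$srre <- NULL
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(no_srre, p)
  expect_error(read_evidence(p), "srre", class = "dairyburden_schema_error")

  bad <- dplyr::bind_rows(make_estimate(), make_estimate(srre = -0.5, ci_lower = -0.6))
  expect_error(validate_evidence(bad), "row 2", class = "dairyburden_validation_error")

  inverted_ci <- make_estimate(ci_lower = 0.96, ci_upper = 0.80, srre = 0.85)
  expect_error(validate_evidence(inverted_ci), "bracket",
               class = "dairyburden_validation_error")
})

test_that("significance gate requires the whole CI below the null", {
  cases <- tibble::tibble(
    srre = c(0.85, 1.06, 1.11, 0.90),
    ci_upper = c(0.95, 1.22, 1.78, 1.00) # last two: touching/crossing 1
  )
  expect_equal(is_protective_significant(cases), c(TRUE, FALSE, FALSE, FALSE))

  # one CI at exactly 1.00 on the lower bound, upper above: still excluded
  marginal <- make_estimate(srre = 1.11, ci_lower = 1.00, ci_upper = 1.78)
  expect_false(is_protective_significant(marginal))

  # the 14 registry rows that feed the analysis all pass
  ev <- dairy_evidence()
  expect_equal(sum(is_protective_significant(ev)), 14)
})

test_that("select_primary prefers recency, then study count, then author", {
  recency <- dplyr::bind_rows(
    make_estimate(outcome_id = "cvd", first_author = "Gholami",
                  pub_year = 2017L, n_studies = 16L, srre = 0.90,
                  ci_lower = 0.81, ci_upper = 0.99),
    make_estimate(outcome_id = "cvd", first_author = "Older",
                  pub_year = 2011L, n_studies = 30L, srre = 0.90,
                  ci_lower = 0.81, ci_upper = 0.99)
  )
  expect_equal(select_primary(recency)$first_author, "Gholami")

  ties <- dplyr::bind_rows(
    make_estimate(outcome_id = "t2d", pub_year = 2017L, n_studies = 21L,
                  first_author = "Schwingshackl"),
    make_estimate(outcome_id = "t2d", pub_year = 2017L, n_studies = 9L,
                  first_author = "Aardvark")
  )
  expect_equal(select_primary(ties)$n_studies, 21L)

  author_tie <- dplyr::bind_rows(
    make_estimate(outcome_id = "t2d", pub_year = 2017L, n_studies = 9L,
                  first_author = "Zed"),
    make_estimate(outcome_id = "t2d", pub_year = 2017L, n_studies = 9L,
                  first_author = "Abel")
  )
  expect_equal(select_primary(author_tie)$first_author, "Abel")

  single <- make_estimate()
  expect_equal(select_primary(single), tibble::as_tibble(single))
  expect_error(select_primary(single[0, ]), class = "dairyburden_domain_error")
  mixed <- dplyr::bind_rows(make_estimate(outcome_id = "a"),
                            make_estimate(outcome_id = "b"))
  expect_error(select_primary(mixed), class = "dairyburden_domain_error")
})

test_that("select_primary is invariant to candidate order", {
  candidates <- dplyr::bind_rows(
    make_estimate(first_author = "Mid", pub_year = 2015L, n_studies = 12L),
    make_estimate(first_author = "New", pub_year = 2019L, n_studies = 3L),
    make_estimate(first_author = "Big", pub_year = 2015L, n_studies = 40L)
  )
  for (seed in 1:10) {
    withr::with_seed(seed, {
      shuffled <- candidates[sample(nrow(candidates)), ]
      expect_equal(select_primary(shuffled)$first_author, "New")
    })
  }
})

test_that("build_analysis_set applies both gates and the primary rule", {
  ev <- dairy_evidence()
  catalog <- us_dalys_2019()
  set <- build_analysis_set(ev, catalog)
  expect_equal(nrow(set), 14)
  expect_equal(
    as.integer(table(factor(set$exposure_category,
                            c("total_dairy", "milk", "low_fat_dairy", "high_fat_dairy")))),
    c(6L, 2L, 4L, 2L)
  )
  expect_true(all(set$ci_upper < 1))
  excl <- attr(set, "exclusions")
  expect_setequal(excl$outcome_id, "prostate_cancer")
  expect_setequal(excl$rule, "not_significant")

  # significant outcome without a burden entry drops at the catalogue gate
  with_osteo <- dplyr::bind_rows(
    ev, make_estimate(outcome_id = "osteoporosis", srre = 0.80,
                      ci_lower = 0.70, ci_upper = 0.92)
  )
  set2 <- build_analysis_set(with_osteo, catalog)
  expect_equal(nrow(set2), 14)
  excl2 <- attr(set2, "exclusions")
  expect_true(any(excl2$outcome_id == "osteoporosis" & excl2$rule == "no_daly_entry"))

  # duplicated topic resolves to the primary estimate, older one audited
  with_dupe <- dplyr::bind_rows(
    ev, make_estimate(outcome_id = "breast_cancer", first_author = "Hypothetical",
                      pub_year = 2005L, n_studies = 3L)
  )
  set3 <- build_analysis_set(with_dupe, catalog)
  expect_equal(nrow(set3), 14)
  breast <- set3[set3$outcome_id == "breast_cancer" &
                   set3$exposure_category == "total_dairy", ]
  expect_equal(breast$first_author, "Dong")
  expect_true(any(attr(set3, "exclusions")$rule == "superseded"))

  # nothing significant -> legal empty result
  dull <- make_estimate(srre = 1.05, ci_lower = 0.95, ci_upper = 1.15)
  expect_equal(nrow(build_analysis_set(dull, catalog)), 0)
})

test_that("build_analysis_set output is invariant to input row order", {
  ev <- dairy_evidence()
  catalog <- us_dalys_2019()
  reference <- build_analysis_set(ev, catalog)
  attr(reference, "exclusions") <- NULL
  for (seed in 1:5) {
    withr::with_seed(seed, {
      shuffled <- ev[sample(nrow(ev)), ]
      out <- build_analysis_set(shuffled, catalog)
      attr(out, "exclusions") <- NULL
      expect_equal(out, reference)
    })
  }
})
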