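# Evaluation statistics and the end-to-end mock-library screen.

test_that("two-SD clone classification follows the band rules", {
  st <- classifier_stats(pos_mean = 1.0, pos_sd = 0.08,
                         neg_mean = 0.15, neg_sd = 0.05)
  expect_identical(classify_clone(1.0, st), "positive")
  expect_identical(classify_clone(0.15, st), "negative")
  # midway between disjoint bands
  expect_identical(classify_clone(0.5, st), "ambiguous")
  expect_identical(classify_clone(c(0.9, 0.2, 0.55), st),
                   c("positive", "negative", "ambiguous"))
  # overlapping bands: positive precedence plus a warning
  st2 <- classifier_stats(pos_mean = 0.5, pos_sd = 0.2,
                          neg_mean = 0.3, neg_sd = 0.2)
  expect_warning(cls <- classify_clone(0.4, st2), "overlap")
  expect_identical(cls, "positive")
})

test_that("true positive rate rounds to integer percent", {
  expect_identical(true_positive_rate(34, 38), 89)
  expect_identical(true_positive_rate(0, 17), 0)
  expect_identical(true_positive_rate(17, 17), 100)
  expect_error(true_positive_rate(5, 0), class = "aads_data_error")
  expect_error(true_positive_rate(6, 5), class = "aads_data_error")
})

test_that("enrichment factors follow the fraction-ratio and odds-ratio conventions", {
  same <- enrichment_counts(10, 90, 10, 90)
  expect_equal(enrichment_zinchenko(same), 1, tolerance = 1e-12)
  expect_equal(enrichment_baret(same), 1, tolerance = 1e-12)
  # 1:100 before, 34:4 after (frozen independent arithmetic)
  ec <- enrichment_counts(1, 100, 34, 4)
  expect_equal(enrichment_zinchenko(ec), 90.36842, tolerance = 1e-6)
  expect_equal(enrichment_baret(ec), 850, tolerance = 1e-12)
  expect_error(enrichment_zinchenko(enrichment_counts(0, 100, 3, 4)),
               class = "aads_data_error")
  expect_warning(
    eb <- enrichment_baret(enrichment_counts(1, 100, 5, 0)), "unbounded")
  expect_identical(eb, Inf)
})

test_that("odds-ratio enrichment dominates fraction-ratio above the identity", {
  withr::with_seed(31, {
    for (i in 1:50) {
      pb <- sample(1:20, 1); nb <- sample(50:500, 1)
      pa <- sample(5:60, 1); na_ <- sample(1:30, 1)
      ec <- enrichment_counts(pb, nb, pa, na_)
      ez <- enrichment_zinchenko(ec)
      if (ez > 1) expect_gte(enrichment_baret(ec), ez)
    }
  })
})

test_that("outcome tallies are exact fractions that sum to one", {
  oc <- data.frame(category = c(rep("correct_positive", 3),
                                rep("false_negative", 1),
                                rep("partial_false_positive", 2),
                                rep("correct_negative", 2)),
                   alone = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  tl <- tally_outcomes(oc)
  expect_equal(tl[["correct_positive"]], 3 / 8, tolerance = 1e-12)
  expect_equal(tl[["partial_false_positive"]], 2 / 8, tolerance = 1e-12)
  expect_equal(sum(tl[names(tl) != "correct"]), 1, tolerance = 1e-12)
  # the not-alone correct droplet does not count as correctly sorted
  expect_equal(tl[["correct"]], 4 / 8, tolerance = 1e-12)
  expect_error(tally_outcomes(data.frame(category = character())),
               class = "aads_data_error")
  # random lists conserve mass
  withr::with_seed(32, {
    cats <- c("correct_positive", "correct_negative", "false_positive",
              "false_negative", "partial_false_positive",
              "partial_false_negative")
    for (i in 1:10) {
      oc2 <- data.frame(category = sample(cats, 200, replace = TRUE))
      expect_equal(sum(tally_outcomes(oc2)[cats]), 1, tolerance = 1e-12)
    }
  })
})

test_that("the mock screen is reproducible and enriches a 1:100 library", {
  sc <- run_mock_screen(n_droplets = 4000, seed = 41)
  sc2 <- run_mock_screen(n_droplets = 4000, seed = 41)
  expect_identical(sc$counts, sc2$counts)
  expect_identical(sc$tally, sc2$tally)
  expect_identical(sc$clones, sc2$clones)

  # sanity bound under the default calibration (not a literature match)
  expect_gt(sc$enrichment_zinchenko, 50)
  expect_equal(sum(sc$tally[names(sc$tally) != "correct"]), 1,
               tolerance = 1e-12)
  # a 1:100 library at lambda 0.3 has mostly empty/negative droplets
  expect_gt(sc$counts$neg_before, 50 * sc$counts$pos_before)
  rep <- screen_report(sc)
  expect_true(all(c("tp_rate_percent", "enrichment_zinchenko", "correct")
                  %in% rep$key))
})

test_that("ideal separation and junction give perfect recovered purity", {
  sc <- run_mock_screen(n_droplets = 4000, seed = 42,
                        junction = junction_params(applied_force = 100),
                        assay = classifier_stats(pos_mean = 1, pos_sd = 0.02,
                                                 neg_mean = 0.1, neg_sd = 0.02))
  # every droplet in the positive pool is truly positive and every positive
  # was recovered
  expect_identical(sc$counts$neg_after, 0L)
  expect_identical(sc$counts$pos_after, sc$counts$pos_before)
  # every re-assayed clone is genuinely positive; the two-SD band itself
  # excludes ~2% of genuine positives by construction, so the rate is
  # near-perfect rather than identically 100
  expect_true(all(sc$clones$true_label == "positive"))
  expect_gte(sc$tp_rate, 89)
})
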