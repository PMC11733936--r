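test_that("enrichment factor follows (a/n)/(A/N)", {
  expect_equal(enrichment_factor(5, 5, 20, 100), 5)
  expect_equal(enrichment_factor(1, 5, 20, 100), 1)
  expect_equal(enrichment_factor(0, 5, 20, 100), 0)
  # whole library always gives exactly 1
  for (A in c(1, 7, 20)) expect_identical(enrichment_factor(A, 100, A, 100), 1)
  expect_error(enrichment_factor(6, 5, 20, 100), "a <= min")
  expect_error(enrichment_factor(1, 5, 120, 100), "A <= N")
})

test_that("enrichment curves hit the limit shapes", {
  perfect <- data.frame(compound_id = paste0("c", 1:10),
                        label = rep(c("ACTIVE", "DECOY"), c(3, 7)),
                        docking_score = 1:10)
  cv <- rank_and_curve(perfect, "docking_score", "lower")
  expect_equal(cv$fraction_actives_found[cv$fraction_screened == 0.3], 1)
  expect_equal(cv$fraction_screened[1], 0)
  expect_equal(cv$fraction_actives_found[1], 0)
  expect_equal(utils::tail(cv$fraction_actives_found, 1), 1)
  expect_true(all(diff(cv$fraction_actives_found) >= 0))
  # anti-perfect ranking finds nothing until the last A compounds
  anti <- perfect
  anti$docking_score <- 10:1
  cva <- rank_and_curve(anti, "docking_score", "lower")
  expect_equal(cva$fraction_actives_found[cva$fraction_screened == 0.7], 0)
  # one-class input names the missing class
  expect_error(rank_and_curve(perfect[perfect$label == "DECOY", ]),
               "ACTIVE")
})

test_that("ranking is invariant under monotone score transforms", {
  rec <- make_screen_records(20, 80, seed = 4)
  cv1 <- rank_and_curve(rec, "docking_score", "lower")
  rec2 <- rec
  rec2$docking_score <- exp(rec$docking_score / 2) # monotone increasing
  cv2 <- rank_and_curve(rec2, "docking_score", "lower")
  expect_equal(as.data.frame(cv1), as.data.frame(cv2))
  expect_equal(attr(cv1, "auc"), attr(cv2, "auc"))
  expect_equal(roc_auc(rec, "docking_score", "lower"),
               roc_auc(rec2, "docking_score", "lower"))
})

test_that("ROC AUC equals brute-force pairwise counting", {
  expect_equal(roc_auc(make_screen_records(5, 10, separation = 100)), 1)
  rev_rec <- make_screen_records(5, 10, separation = -100)
  expect_equal(roc_auc(rev_rec), 0)
  # 50-record fixture incl. ties, against the explicit pair loop
  rec <- make_screen_records(15, 35, separation = 1, seed = 6)
  rec$docking_score <- round(rec$docking_score, 1)  # force some ties
  oriented <- -rec$docking_score
  expect_equal(roc_auc(rec, "docking_score", "lower"),
               brute_force_auc(oriented, rec$label == "ACTIVE"),
               tolerance = 1e-12)
})

test_that("random scores give AUC near one half", {
  rec <- make_screen_records(400, 1600, separation = 0, seed = 11)
  expect_equal(roc_auc(rec), 0.5, tolerance = 0.06)
})

test_that("enrichment at a fraction uses floor(n) with n >= 1", {
  rec <- make_screen_records(20, 80, separation = 100, seed = 2)
  # top 5% of 100 = 5 compounds, all active under perfect separation
  expect_equal(enrichment_at_fraction(rec, 0.05), 5)
  # tiny fraction still selects one compound
  expect_equal(enrichment_at_fraction(rec, 0.001), 5)
  expect_error(enrichment_at_fraction(rec, 0), "fraction")
})

test_that("hit rates by bin partition the records", {
  rec <- data.frame(score = c(1, 2, 3, 11, 12, 25),
                    hit = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  tab <- hit_rate_by_bin(rec, "score", c(0, 10, 20, 30))
  expect_equal(tab$n, c(3L, 2L, 1L))
  expect_equal(tab$hit_rate, c(2 / 3, 1 / 2, 0))
  expect_equal(sum(tab$n), nrow(rec))
  # weighted mean of bin rates recovers the overall rate
  expect_equal(sum(tab$n * tab$hit_rate) / sum(tab$n), mean(rec$hit))
  # single all-covering bin is the overall rate
  one <- hit_rate_by_bin(rec, "score", c(0, 30))
  expect_equal(one$hit_rate, 0.5)
  # empty bins report n = 0 and an undefined (not zero) rate
  gap <- hit_rate_by_bin(rec, "score", c(0, 13, 20, 30))
  expect_equal(gap$n[2], 0L)
  expect_true(is.na(gap$hit_rate[2]))
  expect_error(hit_rate_by_bin(rec, "score", c(0, 10, 10)), "increasing")
  expect_error(hit_rate_by_bin(rec, "score", c(2, 30)), "cover")
})
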