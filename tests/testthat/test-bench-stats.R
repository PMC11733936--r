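test_that("regression metrics match direct formula evaluation", {
  ident <- data.frame(observed = c(-3, -2, -1), predicted = c(-3, -2, -1))
  m <- regression_metrics(ident)
  expect_equal(c(m$r_squared, m$rmse, m$mue), c(1, 0, 0))
  off <- data.frame(observed = c(-3, -2, -1, 0),
                    predicted = c(-2, -1, 0, 1))
  m2 <- regression_metrics(off)
  expect_equal(c(m2$r_squared, m2$rmse, m2$mue), c(1, 1, 1))
  # 5-point hand-worked table against independent arithmetic
  obs <- c(-5.2, -4.1, -3.3, -2.8, -1.9)
  pred <- c(-4.8, -4.5, -2.9, -3.1, -1.2)
  m3 <- regression_metrics(data.frame(observed = obs, predicted = pred))
  e <- pred - obs
  r_manual <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(m3$r_squared, r_manual^2, tolerance = 1e-12)
  expect_equal(m3$rmse, sqrt(sum(e^2) / 5), tolerance = 1e-12)
  expect_equal(m3$mue, sum(abs(e)) / 5, tolerance = 1e-12)
  expect_equal(m3$n, 5L)
  expect_error(
    regression_metrics(data.frame(observed = c(1, 1, 1),
                                  predicted = c(1, 2, 3))),
    "constant")
  expect_error(regression_metrics(data.frame(observed = 1:2,
                                             predicted = 1:2)), "3")
})

test_that("R^2 is affine invariant and RMSE dominates MUE", {
  set.seed(12)
  for (k in 1:100) {
    df <- data.frame(observed = rnorm(8), predicted = rnorm(8))
    m <- regression_metrics(df)
    expect_gte(m$rmse, m$mue)
    df2 <- df
    df2$predicted <- -1.7 * df$predicted + 4
    expect_equal(regression_metrics(df2)$r_squared, m$r_squared,
                 tolerance = 1e-10)
  }
})

test_that("per-target normalization maps onto each observed range", {
  rec <- data.frame(
    target_id = rep(c("A", "B"), each = 3),
    observed = c(-6, -4, -2, -9, -8, -5),
    predicted = c(0, 1, 2, 10, 30, 20)
  )
  out <- per_target_range_normalize(rec)
  a <- out$records[out$records$target_id == "A", ]
  b <- out$records[out$records$target_id == "B", ]
  expect_equal(a$predicted, c(-6, -4, -2))        # already affine in obs
  expect_equal(b$predicted, c(-9, -5, -7))        # (10,30,20) -> [-9,-5]
  expect_equal(out$n_targets_dropped, 0)
  # within-target rank correlation is untouched
  expect_equal(cor(b$predicted, c(10, 30, 20), method = "spearman"), 1)
})

test_that("singleton targets are refused unless explicitly dropped", {
  rec <- data.frame(
    target_id = c(rep("A", 3), paste0("S", 1:38)),
    observed = c(-6, -4, -2, rnorm(38)),
    predicted = c(1, 2, 3, rnorm(38))
  )
  expect_error(per_target_range_normalize(rec), "drop_singletons")
  out <- per_target_range_normalize(rec, drop_singletons = TRUE)
  expect_equal(out$n_targets_dropped, 38)
  expect_equal(nrow(out$records), 3)
  expect_setequal(out$dropped_targets, paste0("S", 1:38))
})

test_that("record filtering removes excluded classes with a removal log", {
  rec <- make_bench_records()
  rec$binding_mode_class <- rep(c("type-1", "type-2", "allosteric"), 4)
  # empty rules are the identity
  none <- filter_records(rec, filter_rules())
  expect_identical(none$records, rec)
  expect_equal(nrow(none$removal_log), 0)
  # one class excluded: exact survivor set
  f1 <- filter_records(rec, filter_rules("type-2"))
  expect_equal(nrow(f1$records), 8)
  expect_false(any(f1$records$binding_mode_class == "type-2"))
  expect_equal(f1$removal_log$n_removed, 4)
  # everything excluded: empty output, full log
  all_gone <- filter_records(
    rec, filter_rules(c("type-1", "type-2", "allosteric")))
  expect_equal(nrow(all_gone$records), 0)
  expect_equal(sum(all_gone$removal_log$n_removed), 12)
})

test_that("error-band fractions count inclusively and grow with the band", {
  exact <- data.frame(observed = 1:4, predicted = 1:4)
  expect_equal(unname(error_band_fractions(exact, 0)), 1)
  rec <- data.frame(observed = c(0, 0, 0),
                    predicted = c(0.5, 1.5, 2.5))
  expect_equal(unname(error_band_fractions(rec, c(1, 2))), c(1 / 3, 2 / 3))
  expect_equal(unname(error_band_fractions(rec, Inf)), 1)
  # boundary inclusive
  expect_equal(unname(error_band_fractions(
    data.frame(observed = 0, predicted = 1), 1)), 1)
  set.seed(3)
  for (k in 1:10) {
    df <- data.frame(observed = rnorm(20), predicted = rnorm(20))
    fr <- error_band_fractions(df, c(0.5, 1, 2, 4))
    expect_true(all(diff(fr) >= 0))
  }
  expect_error(error_band_fractions(rec, -1), "nonnegative")
})
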