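test_that("aggregate_replicates computes mean, CV and presence flags", {
  s <- aggregate_replicates(make_obs(c(2, 4)), required_k = 2, of_n = 2)
  expect_equal(s$mean_ratio, 3)
  expect_equal(s$cv, sqrt(2) / 3, tolerance = 1e-6)  # 0.4714

  s <- aggregate_replicates(make_obs(c(5, 5, 5)), required_k = 2, of_n = 3)
  expect_equal(s$mean_ratio, 5)
  expect_equal(s$cv, 0)

  # 1 of 3 present under a 2-of-3 rule fails presence
  s <- aggregate_replicates(make_obs(1.5), required_k = 2, of_n = 3)
  expect_true(grepl("PRESENCE_FAIL", s$flags))
  expect_true(is.na(s$mean_ratio))

  # capped replicate propagates a CAPPED flag
  s <- aggregate_replicates(make_obs(c(20, 18), capped = c(TRUE, FALSE)))
  expect_true(grepl("CAPPED", s$flags))
})

test_that("duplicate (site, condition, replicate) rows are rejected by name", {
  obs <- rbind(make_obs(c(2, 4)), make_obs(3)[1, ])
  expect_error(aggregate_replicates(obs), "duplicate.*P1_C10")
})

test_that("filter_changed applies the conjunction reading", {
  s <- rbind(
    aggregate_replicates(make_obs(c(2, 4), site = "P1_C1")),     # cv .47
    aggregate_replicates(make_obs(c(1, 3.5), site = "P1_C2")),   # cv .79
    aggregate_replicates(make_obs(c(1.1, 1.1), site = "P1_C3"))
  )
  s$cv[3] <- 0.9  # unchanged site with terrible CV is still retained
  f <- filter_changed(s)
  expect_false(grepl("CV_FAIL", f$flags[f$site_id == "P1_C1"]))
  expect_true(grepl("CV_FAIL", f$flags[f$site_id == "P1_C2"]))
  expect_false(grepl("CV_FAIL", f$flags[f$site_id == "P1_C3"]))
  # alternative reading: CV alone removes
  f2 <- filter_changed(s, mode = "cv_only")
  expect_true(grepl("CV_FAIL", f2$flags[f2$site_id == "P1_C3"]))
})

test_that("flag assignment equals a brute-force recount from raw ratios", {
  set.seed(21)
  tr <- simulate_truth(200, seed = 21)
  obs <- simulate_isotop(tr, c(H2O2_10mM = 10), n_replicates = 2,
                         noise_cv = 0.3, dropout_rate = 0.2, seed = 22)
  s <- filter_changed(aggregate_replicates(obs, 2, 2))
  for (i in seq_len(nrow(s))) {
    r <- obs$ratio_LH[obs$site_id == s$site_id[i]]
    if (length(r) < 2) {
      expect_true(grepl("PRESENCE_FAIL", s$flags[i]))
    } else {
      expect_equal(s$mean_ratio[i], mean(r))
      cv_fail <- mean(r) > 2 && sd(r) / mean(r) > 0.5
      expect_equal(grepl("CV_FAIL", s$flags[i]), cv_fail)
    }
  }
})

test_that("classify_sensitivity uses the top dose and reports a slope", {
  expect_equal(
    classify_sensitivity(c(`1` = 1.0, `2.5` = 1.1, `5` = 1.0,
                           `10` = 1.2))$class, "resistant")
  cl <- classify_sensitivity(c(`1` = 2.1, `2.5` = 3.5, `5` = 8.0,
                               `10` = 13.0))
  expect_equal(cl$class, "high")
  expect_gt(cl$slope, 0)
  # single-dose boundary case: 2 <= 3 < 5
  expect_equal(classify_sensitivity(c(`10` = 3.0))$class, "moderate")
  expect_error(classify_sensitivity(numeric(0)), "no doses")
})

test_that("implied_oxidation inverts the competition ratio model", {
  expect_equal(implied_oxidation(1), 0)
  expect_equal(implied_oxidation(2), 50)
  expect_equal(implied_oxidation(13.3), 100 * (1 - 1 / 13.3),
               tolerance = 1e-12)  # 92.48
  expect_warning(val <- implied_oxidation(0.5), "floored")
  expect_equal(val, 0)
  expect_error(implied_oxidation(0), "positive")
})

test_that("median_summary uses retained rows and midpoint ties", {
  s <- do.call(rbind, lapply(1:4, function(i)
    aggregate_replicates(make_obs(rep(c(1, 2, 3, 10)[i], 2),
                                  site = sprintf("P1_C%d", i)))))
  m <- median_summary(s)
  expect_equal(m$median_ratio, 2.5)  # even-count midpoint
  m3 <- median_summary(s[1:3, ])
  expect_equal(m3$median_ratio, 2)
  # flagged rows are excluded
  s$flags[4] <- "CV_FAIL"
  expect_equal(median_summary(s)$median_ratio, 2)
  s$flags <- "CV_FAIL"
  expect_error(median_summary(s), "no retained")
})

test_that("aggregate -> filter -> classify is invariant to row order", {
  tr <- simulate_truth(100, seed = 31)
  doses <- c(H2O2_1mM = 1, H2O2_2.5mM = 2.5, H2O2_5mM = 5, H2O2_10mM = 10)
  obs <- simulate_isotop(tr, doses, seed = 32)
  run <- function(o) {
    classify_sites(filter_changed(aggregate_replicates(o, 2, 2)), doses)
  }
  set.seed(33)
  shuffled <- obs[sample(nrow(obs)), ]
  expect_equal(run(obs), run(shuffled))
})

test_that("zero-noise medians are non-decreasing in dose", {
  doses <- c(H2O2_1mM = 1, H2O2_2.5mM = 2.5, H2O2_5mM = 5, H2O2_10mM = 10)
  tr <- simulate_truth(150, seed = 41)
  obs <- simulate_isotop(tr, doses, noise_cv = 0, dropout_rate = 0,
                         seed = 42)
  s <- filter_changed(aggregate_replicates(obs, 2, 2))
  med <- median_summary(s)
  med <- med[match(names(doses), med$condition), ]
  expect_true(all(diff(med$median_ratio) >= 0))
})
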