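test_that("tabulation cross-tabulates index against reference in accrual order", {
  rec <- data.frame(order = 1:3, reference = c(1, 1, 0), index = c(1, 0, 0))
  tab <- tabulate_accuracy(rec)
  expect_identical(c(tab$TP, tab$FN, tab$TN, tab$FP), c(1L, 1L, 1L, 0L))
  # upto = 0: all-zero table, accuracies not evaluable
  tab0 <- tabulate_accuracy(rec, 0)
  expect_identical(c(tab0$TP, tab0$FN, tab0$TN, tab0$FP), c(0L, 0L, 0L, 0L))
  expect_true(is.na(tab0$sensitivity) && is.na(tab0$specificity))
  # first interim cut of the first simulated cohort: 67% / 81%
  tab46 <- tabulate_accuracy(fixture_cohort("sim_cohort1.csv"), 46)
  expect_identical(c(tab46$TP + tab46$FN, tab46$TN + tab46$FP), c(15L, 31L))
  expect_identical(format_boundary(tab46$sensitivity), "67%")
  expect_identical(format_boundary(tab46$specificity), "81%")
  expect_error(tabulate_accuracy(rec, 4), "between")
})

test_that("count and percent stopping rules are dual", {
  # failures >= r  <=>  accuracy estimate <= 1 - r/n, for every count
  des <- endpoint_design("FNR", p0 = 0.75, anchor_size = 200)
  for (n in c(1:25, 50, 100, 199, 200)) {
    r <- futility_boundary_count(n, des)
    failures <- 0:n
    expect_identical(failures >= r, (1 - failures / n) <= (1 - r / n))
  }
})

test_that("estimates exactly on the boundary trigger stopping", {
  des <- sim_design_by_positives()
  # sensitivity 31/50 = 62% equals the stage boundary 1 - 19/50: stop
  tab <- structure(list(TP = 31L, FN = 19L, TN = 40L, FP = 2L,
                        sensitivity = 31 / 50, specificity = 40 / 42),
                   class = "accuracy_table")
  res <- evaluate_interim(des, tab, stage = 3L)
  expect_identical(res$sens_decision, "Stop for futility")
  expect_identical(res$decision, "Stop for futility")
  # one failure fewer: continue
  tab2 <- structure(list(TP = 32L, FN = 18L, TN = 40L, FP = 2L,
                         sensitivity = 32 / 50, specificity = 40 / 42),
                    class = "accuracy_table")
  expect_identical(evaluate_interim(des, tab2, stage = 3L)$decision,
                   "Continue")
})

test_that("empty endpoint groups are not evaluable and never stop", {
  des <- sim_design_by_total()
  # all participants disease-negative, specificity dreadful
  rec <- data.frame(order = 1:30, reference = 0L,
                    index = rep(c(1L, 1L, 1L, 0L), length.out = 30))
  res <- evaluate_interim(des, tabulate_accuracy(rec), stage = 1L)
  expect_identical(res$sens_decision, "Not evaluable")
  expect_identical(res$spec_decision, "Stop for futility")
  expect_identical(res$decision, "Stop for futility")
  # under the both-endpoint rule a lone evaluable endpoint cannot stop
  des_both <- sim_design_by_total(futility_rule = "both")
  res2 <- evaluate_interim(des_both, tabulate_accuracy(rec), stage = 1L)
  expect_identical(res2$decision, "Continue")
})

test_that("stopping under the both-endpoint rule implies stopping under either", {
  des_e <- sim_design_by_positives()
  des_b <- sim_design_by_positives(futility_rule = "both")
  set.seed(31)
  for (s in sample.int(1e6, 25)) {
    co <- simulate_cohort(cohort_scenario(0.35, 0.55, 0.75, 220, seed = s))
    stop_b <- any(monitor_dta(des_b, co)$decision == "Stop for futility")
    stop_e <- any(monitor_dta(des_e, co)$decision == "Stop for futility")
    if (stop_b) expect_true(stop_e)
  }
})

test_that("monitoring stops emitting after the first overall stop and is prefix-stable", {
  des <- sim_design_by_total()
  d1 <- fixture_cohort("sim_cohort1.csv")
  res <- monitor_dta(des, d1)
  expect_identical(nrow(res), 3L)  # terminated at the third interim
  expect_identical(res$decision, c("Continue", "Continue",
                                   "Stop for futility"))
  # truncating records after the stop changes nothing
  trunc <- d1[1:150, ]
  expect_identical(monitor_dta(des, trunc)[], res[])
  # records shorter than the first scheduled point: no analyses
  expect_identical(nrow(monitor_dta(des, d1[1:10, ])), 0L)
})
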