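test_that("group-size projections partition totals and hit the worked anchors", {
  des <- sim_design_by_total()
  proj <- project_group_sizes(des)
  expect_identical(proj$positives + proj$negatives, proj$total)
  expect_identical(proj$positives, c(9L, 26L, 53L, 70L))
  expect_identical(proj$negatives[4], 130L)
  # by-positives: negatives projected through the prevalence odds
  des2 <- sim_design_by_positives()
  proj2 <- project_group_sizes(des2)
  expect_identical(proj2$negatives, c(28L, 46L, 93L, 130L))
  # case-study projection: 150 cases at 30% prevalence -> 350 negatives
  proj3 <- project_group_sizes(raptor_design("desirable"))
  expect_identical(proj3$positives[3], 150L)
  expect_identical(proj3$negatives[3], 350L)
})

test_that("design validation rejects inconsistent schedules", {
  expect_error(dta_design(0, "total", c(25), 200, 0.75, 0.9), "prevalence")
  expect_error(dta_design(0.35, "total", c(25, 200), 200,
                          sens_p0 = 0.75, spec_p0 = 0.9), "below")
  expect_error(dta_design(0.35, "total", c(75, 25), 200,
                          sens_p0 = 0.75, spec_p0 = 0.9), "increasing")
})

test_that("realized stage sizes retain overshoot and report unreached stages", {
  d1 <- fixture_cohort("sim_cohort1.csv")
  d2 <- fixture_cohort("sim_cohort2.csv")
  # by-positives: the 15th positive arrives with participant 46
  rs <- realized_stage_sizes(sim_design_by_positives(), d1)
  expect_identical(rs$n[1:3], c(46L, 63L, 128L))
  expect_identical(rs$n_pos[1:3], c(15L, 25L, 50L))
  expect_identical(rs$n_neg[1:3], c(31L, 38L, 78L))
  # by-total: at 150 participants dataset 2 holds 72 positives
  rs2 <- realized_stage_sizes(sim_design_by_total(), d2)
  expect_identical(rs2$n_pos, c(16L, 44L, 72L, 89L))
  expect_identical(rs2$n_neg[3], 78L)
  # later stages never shrink
  expect_true(all(diff(rs$n[rs$reached]) > 0))
  # empty accrual reaches nothing (and is not an error)
  empty <- data.frame(order = integer(), reference = integer(),
                      index = integer())
  expect_true(all(!realized_stage_sizes(sim_design_by_total(),
                                        empty)$reached))
  # accrual short of a milestone: stage flagged unreached
  rs3 <- realized_stage_sizes(sim_design_by_total(), d1[1:80, ])
  expect_identical(rs3$reached, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("batched accrual cuts at the first batch boundary crossing the milestone", {
  bd <- fixture_cohort("raptor_bd_veritor_synthetic.csv")
  rs <- realized_stage_sizes(raptor_design("desirable"), bd)
  # milestones 50/100/150 positive cases realize as 52/103/150
  expect_identical(rs$n_pos, c(52L, 103L, 150L))
  sd <- fixture_cohort("raptor_sd_biosensor_synthetic.csv")
  rs_sd <- realized_stage_sizes(raptor_design("desirable"), sd)
  expect_identical(rs_sd$n_pos, c(53L, 103L, 150L))
})

test_that("target re-estimation preserves the required positive count", {
  des <- sim_design_by_total()
  # 70 positives at observed prevalence 25% need 280 participants
  expect_identical(reestimate_target(des, 0.25)$target, 280L)
  # observed equal to assumed: identity
  expect_identical(reestimate_target(des, 0.35), des)
  # ratios that are integers up to floating error stay exact
  expect_identical(reestimate_target(dta_design(0.5, "total", 75, 300,
                                                0.75, 0.9), 0.3)$target,
                   500L)
  expect_error(reestimate_target(des, 1), "prevalence")
})

test_that("design YAML round-trips through the documented schema", {
  des <- sim_design_by_positives(futility_rule = "both")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_design(des, path)
  back <- read_design(path)
  expect_identical(back, des)
  # schema violations name the offending field
  yaml::write_yaml(list(prevalence = 0.35), path)
  expect_error(read_design(path), "schedule")
  yaml::write_yaml(list(prevalence = 0.35,
                        schedule = list(by = "total", points = list(25),
                                        target = 200),
                        sensitivity = list(p0 = 0.75)), path)
  expect_error(read_design(path), "specificity")
})
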