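test_that("endpoint design validates inputs and warns on assumption breaks", {
  expect_error(endpoint_design("FNR", p0 = 0, anchor_size = 10), "p0")
  expect_error(endpoint_design("FNR", p0 = 1.2, anchor_size = 10), "p0")
  expect_error(endpoint_design("FNR", p0 = 0.8, alpha = 0, anchor_size = 10),
               "alpha")
  expect_error(endpoint_design("FNR", p0 = 0.8, stage_sizes = c(10, 5),
                               anchor_size = 20), "strictly increasing")
  expect_error(endpoint_design("FNR", p0 = 0.8, stage_sizes = c(0, 5),
                               anchor_size = 20), "positive")
  # monitored error proportion must be below one half: warn, don't fail
  expect_warning(endpoint_design("FNR", p0 = 0.4, anchor_size = 50),
                 "0.5")
  # more than five analyses in total: warn, don't fail
  expect_warning(endpoint_design("FNR", p0 = 0.8,
                                 stage_sizes = c(5, 10, 15, 20, 25),
                                 anchor_size = 30),
                 "five")
  expect_silent(endpoint_design("FNR", p0 = 0.8,
                                stage_sizes = c(5, 10, 15, 20),
                                anchor_size = 30))
  # interim sizes may overshoot the anchor (observed accrual)
  expect_silent(endpoint_design("FNR", p0 = 0.8, stage_sizes = c(25, 72),
                                anchor_size = 70))
})

test_that("futility counts reproduce the worked boundary examples", {
  sens70 <- endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
                            anchor_size = 70)
  # 75 participants / 29 positives: r = 14, accuracy boundary 52%
  expect_identical(futility_boundary_count(29, sens70), 14L)
  expect_identical(format_boundary(1 - 14 / 29), "52%")
  # 25 participants / 8 positives: r = 9 > 8, unattainable, shown as dash
  expect_identical(futility_boundary_count(8, sens70), 9L)
  expect_identical(format_boundary(1 - 9 / 8), "-")
  # first by-positives interim: r = 11, 1 - 11/15 = 26.7% displays as 27%
  expect_identical(futility_boundary_count(15, sens70), 11L)
  expect_identical(format_boundary(1 - 11 / 15), "27%")
  # stringent case-study profile: 52 cases anchored to 150, r = 6 -> 88.5%
  raptor <- endpoint_design("FNR", p0 = 0.97, stage_sizes = c(50, 100),
                            anchor_size = 150)
  expect_identical(futility_boundary_count(52, raptor), 6L)
  expect_identical(format_boundary(1 - 6 / 52, precision = 1), "88.5%")
})

test_that("boundary_set evaluates every stage including the final anchor", {
  sens <- endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
                          anchor_size = 70)
  bs <- boundary_set(sens)
  expect_s3_class(bs, "boundary_set")
  expect_identical(bs$n, c(15L, 25L, 50L, 70L))
  expect_identical(format_boundary(bs$boundary[1:3]),
                   c("27%", "48%", "62%"))
  # observed accrual replaces planned sizes; the anchor stays planned
  obs <- boundary_set(sens, stage_sizes = c(8, 29, 58))
  expect_identical(format_boundary(obs$boundary), c("-", "52%", "64%"))
  # degenerate single-stage design: same formula at n_g = n_G
  single <- endpoint_design("FNR", p0 = 0.75, anchor_size = 70)
  expect_identical(boundary_set(single)$futility,
                   futility_boundary_count(70, sens))
})

test_that("futility counts are non-decreasing and interim boundaries sit strictly below p0", {
  designs <- list(
    endpoint_design("FNR", p0 = 0.75, stage_sizes = c(15, 25, 50),
                    anchor_size = 70),
    endpoint_design("FPR", p0 = 0.90, stage_sizes = c(28, 46, 93),
                    anchor_size = 130),
    endpoint_design("FNR", p0 = 0.97, stage_sizes = c(50, 100),
                    anchor_size = 150),
    endpoint_design("FPR", p0 = 0.95, stage_sizes = c(117, 233),
                    anchor_size = 350))
  for (d in designs) {
    bs <- boundary_set(d)
    expect_true(all(diff(bs$futility) >= 0))
    G <- nrow(bs)
    defined <- which(bs$boundary >= 0)
    interim_defined <- setdiff(defined, G)
    # stronger evidence at interims: boundary strictly below p0,
    # and the final boundary is the closest to p0
    expect_true(all(bs$boundary[interim_defined] < d$p0))
    expect_true(all(bs$boundary[G] >= bs$boundary[interim_defined]))
  }
})

test_that("boundary arithmetic rejects invalid stage sizes", {
  sens <- endpoint_design("FNR", p0 = 0.75, anchor_size = 70)
  expect_error(futility_boundary_count(0, sens), "positive")
  expect_error(futility_boundary_count(2.5, sens), "positive")
  expect_error(boundary_set(sens, stage_sizes = c(20, 20)),
               "strictly increasing")
})
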