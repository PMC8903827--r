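test_that("study 1 experiment 1 plans satisfy all printed counts", {
  plan <- build_study1_exp1(seed = 11)
  expect_equal(nrow(plan), 96)
  expect_equal(as.integer(table(plan$gaze_direction)), rep(32L, 3))
  cells <- table(plan$species, plan$level)
  expect_true(all(cells == 12))
  expect_equal(mean(table(plan$stimulus_id)), 4.8)
  expect_true(all(plan$polarity == "normal"))
  # within-block level progression L1 x3, L2 x3, L3 x3, L4 x3
  expect_equal(plan$level[plan$block == 1],
               rep(c(1, 2, 3, 4), each = 3))
  validate_plan(plan)
})

test_that("study 1 experiment 2 plans cross polarity with species and level", {
  plan <- build_study1_exp2(seed = 5, first_species = "human")
  expect_equal(nrow(plan), 96)
  cells <- table(plan$species, plan$level, plan$polarity)
  expect_true(all(cells == 12))
  # block polarity pattern N N R R N N R R
  pol <- plan$polarity[!duplicated(plan$block)]
  expect_equal(pol, c("normal", "normal", "reversed", "reversed",
                      "normal", "normal", "reversed", "reversed"))
  expect_true(all(plan$polarity[plan$block <= 2] == "normal"))
  expect_equal(as.integer(table(plan$gaze_direction)), rep(32L, 3))
  expect_equal(plan$species[1], "human")
  validate_plan(plan)
})

test_that("study 2 sessions satisfy the visual-search counts", {
  plan <- build_study2_session(seed = 3, level = 2.5)
  expect_equal(nrow(plan), 48)
  expect_equal(as.integer(table(plan$target_location)), rep(16L, 3))
  expect_true(all(table(plan$stimulus_id) == 4))
  expect_equal(as.integer(table(plan$role)), c(24L, 24L))
  # blocks: six baseline (L1) then six test trials
  b1 <- plan[plan$block == 1, ]
  expect_equal(b1$level, rep(c(1, 2.5), each = 6))
  expect_equal(b1$role, rep(c("baseline", "test"), each = 6))
  expect_equal(attr(plan, "phase"), "test")
  validate_plan(plan)
})

test_that("an L1 session has no baseline/test split", {
  plan <- build_study2_session(seed = 4, level = 1)
  expect_true(all(plan$level == 1))
  expect_true(all(plan$role == "baseline"))
  expect_equal(attr(plan, "phase"), "pre-test")
  expect_true(all(target_trials(plan)))
})

test_that("plans are byte-identical under the same seed", {
  expect_identical(build_study1_exp1(99), build_study1_exp1(99))
  expect_identical(build_study1_exp2(99), build_study1_exp2(99))
  expect_identical(build_study2_session(99, 3, "reversed"),
                   build_study2_session(99, 3, "reversed"))
  expect_false(identical(build_study1_exp1(99), build_study1_exp1(100)))
})

test_that("balancing and sequencing contracts hold across many seeds", {
  for (seed in 1:1000) {
    plan <- build_study1_exp1(seed)
    expect_true(validate_plan(plan))
  }
  for (seed in 1:150) {
    expect_true(validate_plan(build_study1_exp2(seed)))
    expect_true(validate_plan(build_study2_session(seed, 3.5)))
  }
})

test_that("direction marginals stay balanced across seeds in experiment 2", {
  counts <- vapply(1:100, function(s) {
    unname(table(build_study1_exp2(s)$gaze_direction))
  }, integer(3))
  expect_true(all(counts == 32L))
})

test_that("validate_plan detects injected violations", {
  plan <- build_study1_exp1(1)
  bad <- plan
  bad$gaze_direction[1:3] <- "left"
  expect_error(validate_plan(bad), "successive")
  bad2 <- plan
  bad2$stimulus_id[2] <- bad2$stimulus_id[1]
  expect_error(validate_plan(bad2))
})
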