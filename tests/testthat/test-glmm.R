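test_that("with no random effects the fit matches a direct ML oracle", {
  plan <- build_study1_exp1(seed = 31)
  resp <- simulate_responses(plan, observer_presets("full"), 6, seed = 32)
  spec <- model_spec(c("species", "level"), random = character(0),
                     controls = FALSE)
  fit <- fit_glmm(resp, spec)
  d <- gazevis:::prepare_model_frame(resp, spec)
  X <- model.matrix(~ species * level, d)
  b_oracle <- oracle_logistic(X, d$correct)
  expect_lt(max(abs(fit$coefficients[, "Estimate"] - b_oracle)), 1e-6)
})

test_that("an intercept-only fit on balanced data recovers logit(p)", {
  n <- 400
  d <- data.frame(correct = rep(c(1L, 0L), times = c(300, 100)),
                  species = rep(c("chimpanzee", "human"), each = 200))
  spec <- model_spec("species", random = character(0), interactions = FALSE,
                     controls = FALSE)
  fit0 <- gazevis:::fit_with_terms(gazevis:::prepare_model_frame(d, spec),
                                   spec, character(0))
  expect_equal(unname(fit0$coefficients[1, "Estimate"]), qlogis(0.75),
               tolerance = 1e-8)
})

test_that("the likelihood-ratio test matches a deviance-difference oracle", {
  set.seed(33)
  n <- 500
  d <- data.frame(species = rep(c("chimpanzee", "human"), each = n / 2),
                  block = 1L, trial_in_block = 1L)
  d$correct <- rbinom(n, 1, ifelse(d$species == "human", 0.85, 0.55))
  spec <- model_spec("species", random = character(0), controls = FALSE)
  full <- fit_glmm(d, spec)
  red <- gazevis:::fit_with_terms(gazevis:::prepare_model_frame(d, spec),
                                  spec, character(0))
  res <- lrt(full, red)
  # oracle: deviance difference of the two hand-specified glms
  g1 <- glm(correct ~ species, binomial(), d)
  g0 <- glm(correct ~ 1, binomial(), d)
  expect_equal(res$chisq, deviance(g0) - deviance(g1), tolerance = 1e-8)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 1e-6)
})

test_that("identical models give chisq 0 and p 1; df counts factor levels", {
  plan <- build_study1_exp1(seed = 34)
  resp <- simulate_responses(plan, observer_presets("null"), 3, seed = 35)
  spec <- model_spec(c("species", "level"), random = character(0),
                     controls = FALSE)
  fit <- fit_glmm(resp, spec)
  self <- lrt(fit, fit)
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)
  # dropping the 4-level factor's main effect costs 3 df
  d <- gazevis:::prepare_model_frame(resp, spec)
  no_lv <- gazevis:::fit_with_terms(d, spec, "species")
  expect_equal(lrt(fit, no_lv)$df, 6L)  # level (3 df) + species:level (3 df)
  add <- gazevis:::fit_with_terms(d, spec, c("species", "level"))
  expect_equal(lrt(add, no_lv)$df, 3L)
})

test_that("nesting violations and data mismatches are rejected", {
  plan <- build_study1_exp1(seed = 36)
  resp <- simulate_responses(plan, observer_presets("null"), 3, seed = 37)
  spec <- model_spec(c("species", "level"), random = character(0),
                     controls = FALSE)
  fit <- fit_glmm(resp, spec)
  d <- gazevis:::prepare_model_frame(resp, spec)
  red <- gazevis:::fit_with_terms(d, spec, "species")
  expect_error(lrt(red, fit), "nested")
  half <- gazevis:::fit_with_terms(d[1:100, ], spec, "species")
  expect_error(lrt(fit, half), "different numbers")
})

test_that("pruning drops interactions under the null and keeps a true 3-way", {
  plan <- build_study1_exp2(seed = 38)
  null_resp <- simulate_responses(plan, observer_presets("null"), 8, seed = 39)
  spec <- model_spec(c("species", "level", "polarity"),
                     random = character(0), controls = FALSE)
  pr <- prune_and_test(null_resp, spec, alpha = 0.05)
  expect_false(pr$simple_effects_needed)
  # lower-order terms were tested in the reduced (additive) model
  tested <- vapply(pr$tests, function(t) t$term, character(1))
  expect_true(all(c("species", "level", "polarity") %in% tested))
  expect_equal(tested[1], "species:level:polarity")

  full_resp <- simulate_responses(plan, observer_presets("full"), 40, seed = 40)
  pr2 <- prune_and_test(full_resp, spec, alpha = 0.05)
  expect_equal(pr2$tests[[1]]$term, "species:level:polarity")
  expect_true(pr2$tests[[1]]$significant)
  expect_true(pr2$simple_effects_needed)
  expect_length(pr2$tests, 1L)  # testing stops at the significant 3-way
})

test_that("simple effects test the focal factor within each stratum", {
  plan <- build_study1_exp2(seed = 41)
  resp <- simulate_responses(plan, observer_presets("full"), 40, seed = 42)
  se <- simple_effects(resp, focal = "species",
                       split_by = c("level", "polarity"), alpha = 0.05 / 2)
  expect_equal(nrow(se), 4L)  # two levels x two polarities
  expect_true(all(c("chisq", "df", "p", "significant") %in% names(se)))
  expect_true(all(se$df == 1L, na.rm = TRUE))
  # invariant to stratum ordering
  se2 <- simple_effects(resp[sample(nrow(resp)), ], focal = "species",
                        split_by = c("level", "polarity"), alpha = 0.05 / 2)
  expect_equal(se$chisq, se2$chisq, tolerance = 1e-8)
})

test_that("a null stratum rejects at about the nominal alpha", {
  plan <- build_study1_exp1(seed = 43)
  spec1 <- model_spec("species", random = character(0), controls = FALSE)
  set.seed(44)
  p_vals <- replicate(400, {
    resp <- simulate_responses(plan, observer_presets("null"), 2,
                               seed = sample.int(1e6, 1))
    d <- gazevis:::prepare_model_frame(resp, spec1)
    full <- gazevis:::fit_with_terms(d, spec1, "species")
    red <- gazevis:::fit_with_terms(d, spec1, character(0))
    lrt(full, red)$p
  })
  rate <- mean(p_vals < 0.05)
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / 400) + 0.01)
})

test_that("dispersion is scale-stable and detects overdispersion", {
  set.seed(45)
  n <- 1200
  d <- data.frame(species = rep(c("chimpanzee", "human"), each = n / 2))
  d$correct <- rbinom(n, 1, 0.75)
  spec <- model_spec("species", random = character(0), interactions = FALSE,
                     controls = FALSE)
  fit <- fit_glmm(d, spec)
  expect_gt(fit$dispersion, 0.8)
  expect_lt(fit$dispersion, 1.2)
  # duplicating the data leaves dispersion approximately unchanged
  fit2 <- fit_glmm(rbind(d, d), spec)
  expect_equal(fit2$dispersion, fit$dispersion, tolerance = 0.01)
  # cluster-level probability mixing induces dispersion > 1 in an aggregated
  # (binomial-count) view; emulate with strongly heterogeneous clusters
  k <- 60
  p_cl <- rbeta(k, 2, 2)
  d3 <- data.frame(species = "chimpanzee",
                   cluster = rep(seq_len(k), each = 20))
  d3$correct <- rbinom(nrow(d3), 1, p_cl[d3$cluster])
  agg <- aggregate(correct ~ cluster, d3, sum)
  pr <- (agg$correct - mean(agg$correct)) /
    sqrt(mean(agg$correct) / 20 * (1 - mean(agg$correct) / 20) * 20)
  expect_gt(sum(pr^2) / (k - 1), 1.5)
})

test_that("glmer and glm agree when random-effect variance is negligible", {
  plan <- build_study1_exp1(seed = 46)
  resp <- simulate_responses(plan, observer_params(
    intercept = 0.8, species = 0.6, level = c(L2 = -0.3, L3 = -0.8, L4 = -1.4),
    guess = 0), 8, seed = 47)
  spec_glm <- model_spec(c("species", "level"), random = character(0),
                         controls = FALSE)
  spec_mm <- model_spec(c("species", "level"),
                        random = c("participant_id", "stimulus_id"),
                        controls = FALSE)
  f_glm <- fit_glmm(resp, spec_glm)
  f_mm <- fit_glmm(resp, spec_mm)
  # data were generated with zero random-effect variance: the GLMM collapses
  # onto the logistic regression
  expect_lt(max(abs(f_mm$coefficients[, "Estimate"] -
                    f_glm$coefficients[, "Estimate"])), 0.05)
  expect_lt(max(f_mm$ranef_sd), 0.25)
})

test_that("uncorrelated random slopes are dummy-coded as separate terms", {
  plan <- build_study1_exp1(seed = 54)
  resp <- simulate_responses(plan, observer_params(
    intercept = 1, species = 0.5, sd_participant = 0.4,
    sd_participant_slopes = c(species = 0.4), guess = 0), 12, seed = 55)
  spec <- model_spec("species", random = c("participant_id", "stimulus_id"),
                     slopes = "full", controls = FALSE)
  fit <- fit_glmm(resp, spec)
  # one variance per slope dummy, no slope-intercept covariance estimated
  re_terms <- lme4::findbars(fit$formula)
  expect_length(re_terms, 3L)  # two intercepts + one species slope
  expect_true(any(grepl("\\.sl_specieshuman", names(fit$ranef_sd))))
  expect_true(fit$converged)
})

test_that("bootstrap CIs are deterministic, ordered, and shrink with units", {
  plan <- build_study1_exp1(seed = 48)
  resp <- simulate_responses(plan, observer_presets("species-only"), 8,
                             seed = 49)
  ci <- bootstrap_ci(resp, "participant_id", n_resamples = 500, seed = 50)
  ci_again <- bootstrap_ci(resp, "participant_id", n_resamples = 500, seed = 50)
  expect_identical(ci, ci_again)
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)

  all_correct <- data.frame(correct = 1L, participant_id = rep(1:4, each = 5))
  ci1 <- bootstrap_ci(all_correct, "participant_id", 200, seed = 51)
  expect_equal(c(ci1$lower, ci1$estimate, ci1$upper), c(1, 1, 1))

  big <- simulate_responses(plan, observer_presets("species-only"), 32,
                            seed = 52)
  ci_big <- bootstrap_ci(big, "participant_id", n_resamples = 500, seed = 53)
  ratio <- (ci_big$upper - ci_big$lower) / (ci$upper - ci$lower)
  expect_lt(ratio, 0.75)  # ~halves when units x4

  expect_error(bootstrap_ci(data.frame(correct = 1, participant_id = 1),
                            "participant_id"), "at least 2")
})
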