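test_that("post-test probability follows the odds form of Bayes' theorem", {
  # an uninformative test leaves the probability unchanged
  expect_identical(post_test_probability(0.5, 1), 0.5)
  # contingency oracle: prevalence 0.10, sens 0.90, spec 0.90 (LR+ = 9);
  # per 1000: 90 TP, 90 FP, so P(D | T+) = 90 / 180
  sens <- 0.9; spec <- 0.9
  tp <- 1000 * 0.1 * sens; fp <- 1000 * 0.9 * (1 - spec)
  expect_equal(post_test_probability(0.1, sens / (1 - spec)), tp / (tp + fp),
               tolerance = 1e-12)
  # vanishing prevalence drives the post-test probability to zero
  expect_lt(post_test_probability(1e-12, 50), 1e-9)
  expect_error(post_test_probability(0, 2))
  expect_error(post_test_probability(0.5, -1))
})

test_that("required LR is the exact inverse and falls with prevalence", {
  expect_equal(required_lr(0.2, 0.2), 1, tolerance = 1e-12)
  expect_equal(required_lr(0.05, 0.5), 19, tolerance = 1e-12)
  expect_equal(required_lr(0.2, 0.5), 4, tolerance = 1e-12)
  # round trip to machine precision
  set.seed(31)
  for (i in 1:50) {
    p <- runif(1, 0.01, 0.99); q <- runif(1, 0.01, 0.99)
    expect_equal(post_test_probability(p, required_lr(p, q)), q,
                 tolerance = 1e-12)
  }
  # strictly decreasing in pretest for a fixed target
  pre <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(required_lr(pre, 0.5)) < 0))
})

test_that("post-test probability is strictly increasing in LR and pretest", {
  lr <- c(0.1, 0.5, 1, 2, 5, 20, 100)
  expect_true(all(diff(post_test_probability(0.2, lr)) > 0))
  pre <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(post_test_probability(pre, 3)) > 0))
})

test_that("likelihood ratios derive correctly from sensitivity/specificity", {
  bp <- branch_perf(0.8, 0.9)
  expect_equal(bp$lr_pos, 8, tolerance = 1e-12)
  expect_equal(bp$lr_neg, 2 / 9, tolerance = 1e-12)
  expect_true(bp$lr_pos > 1 && bp$lr_neg < 1) # informative test
})

test_that("closed form agrees with Bernoulli simulation", {
  set.seed(7)
  for (i in 1:5) {
    prev <- runif(1, 0.05, 0.4)
    sens <- runif(1, 0.6, 0.95)
    spec <- runif(1, 0.6, 0.95)
    n <- 20000L
    disease <- runif(n) < prev
    test_pos <- ifelse(disease, runif(n) < sens, runif(n) < (1 - spec))
    emp <- mean(disease[test_pos])
    theo <- post_test_probability(prev, sens / (1 - spec))
    se <- sqrt(theo * (1 - theo) / sum(test_pos))
    expect_lt(abs(emp - theo), 3 * se)
  }
})

random_grid <- function(k = 5L) {
  roc_grid(cutoff = sort(runif(k, 1, 200)),
           sensitivity = sort(runif(k, 0.3, 0.99), decreasing = TRUE),
           specificity = sort(runif(k, 0.3, 0.99)))
}

test_that("cutoff choice matches an exhaustive grid scan", {
  set.seed(53)
  for (i in 1:40) {
    g <- random_grid()
    pre <- runif(1, 0.02, 0.5)
    target <- runif(1, 0.2, 0.95)
    got <- choose_cutoff(g, pre, target)
    post <- post_test_probability(pre, g$sensitivity / (1 - g$specificity))
    qual <- which(post >= target)
    if (length(qual)) {
      expect_true(got$achieved_target)
      expect_identical(got$cutoff, g$cutoff[min(qual)])
    } else {
      expect_false(got$achieved_target)
      expect_identical(got$cutoff, g$cutoff[which.max(post)])
    }
  }
})

test_that("a higher pre-test probability never needs a higher cutoff", {
  # the comorbidity rule: raised pretest allows the same target with a
  # lower (more sensitive) cutoff
  set.seed(61)
  for (i in 1:40) {
    g <- random_grid()
    target <- runif(1, 0.3, 0.9)
    p1 <- runif(1, 0.02, 0.3)
    p2 <- runif(1, p1, 0.6)
    expect_lte(choose_cutoff(g, p2, target)$cutoff,
               choose_cutoff(g, p1, target)$cutoff)
  }
})

test_that("trivially reachable targets return the lowest cutoff", {
  g <- roc_grid(c(10, 20, 40), c(0.9, 0.8, 0.7), c(0.6, 0.8, 0.9))
  res <- choose_cutoff(g, 0.5, 0.5)
  expect_identical(res$cutoff, 10)
  unreachable <- choose_cutoff(g, 0.01, 0.99)
  expect_false(unreachable$achieved_target)
})

test_that("Wilson score intervals match the score test", {
  for (x in c(0, 3, 17, 50)) {
    got <- wilson_interval(x, 50)
    ref <- stats::prop.test(x, 50, correct = FALSE)$conf.int
    expect_equal(got[1L], ref[1L], tolerance = 1e-8)
    expect_equal(got[2L], ref[2L], tolerance = 1e-8)
  }
})

test_that("branch performance is exact on separable synthetic data", {
  alg <- build_fixture_algorithm()
  # cases engineered so 'very_severe_disease' fires exactly on its label
  make <- function(i, danger) {
    ans <- list(comorbidity = FALSE, convulsions = danger,
                unable_to_drink = FALSE, vomits_everything = FALSE,
                lethargic = FALSE, fever = FALSE, cough = FALSE,
                chest_indrawing = FALSE, muac = 14, spo2 = 97,
                resp_rate = 30, crp = 5)
    structure(list(case_id = sprintf("c%02d", i), age_days = 500, sex = "m",
                   weight_kg = 12, answers = ans, estimated = logical(0),
                   label = if (danger) "vsd" else "well"),
              class = "patient_case")
  }
  cases <- c(lapply(1:10, make, danger = TRUE),
             lapply(11:30, make, danger = FALSE))
  bp <- branch_performance(alg, "very_severe_disease", cases, "vsd")
  expect_identical(unname(bp$counts), c(10L, 0L, 0L, 20L))
  expect_identical(bp$sensitivity, 1)
  expect_identical(bp$specificity, 1)
  expect_true(is.na(bp$lr_pos)) # spec = 1: LR+ undefined, reported as NA
  # all-positive label set: specificity undefined, not fabricated
  all_pos <- branch_performance(alg, "very_severe_disease",
                                lapply(1:10, make, danger = TRUE), "vsd")
  expect_true(is.na(all_pos$specificity))
})

test_that("empirical branch performance tracks the generator's design", {
  alg <- build_fixture_algorithm()
  cases <- generate_cases(n = 400, seed = 19)
  bp <- branch_performance(alg, "hypoxaemia", cases, "hypoxaemic")
  # hypoxaemic profile: SpO2 ~ N(86, 2.5) => P(SpO2 < 90) ~ 0.945
  design_sens <- pnorm(90, 86, 2.5)
  se <- sqrt(design_sens * (1 - design_sens) /
               (bp$counts["tp"] + bp$counts["fn"]))
  expect_lt(abs(bp$sensitivity - design_sens), 4 * se + 0.01)
  expect_gt(bp$specificity, 0.9)
})
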