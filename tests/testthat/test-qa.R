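test_that("lint is empty on the clean fixture", {
  expect_identical(nrow(lint_algorithm(build_fixture_algorithm())), 0L)
})

test_that("lint flags every seeded defect class and nothing else", {
  alg <- build_fixture_algorithm()
  for (defect in c("cycle", "dangling_reference", "interval_gap",
                   "interval_overlap", "unreachable_diagnosis",
                   "dose_out_of_bounds", "band_gap")) {
    f <- lint_algorithm(corrupt_algorithm(alg, defect))
    expect_identical(unique(f$code), defect, label = defect)
    expect_gte(nrow(f), 1L)
  }
})

test_that("lint catches a severe diagnosis stripped of its referral", {
  alg <- build_fixture_algorithm()
  alg$diagnoses$hypoxaemia$managements <- "follow_up_3d"
  f <- lint_algorithm(alg, check_posology = FALSE)
  expect_identical(unique(f$code), "missing_referral")
  expect_identical(unique(f$subject), "hypoxaemia")
})

test_that("exhaustive reachability agrees with the documented space bound", {
  alg <- build_fixture_algorithm()
  expect_lte(assignment_space_size(alg), 2^16)
  # forcing the heuristic path emits an explicit warning finding
  f <- lint_algorithm(alg, check_posology = FALSE, max_enumeration = 10)
  expect_true("reachability_heuristic" %in% f$code)
  expect_false("unreachable_diagnosis" %in% f$code)
})

test_that("vectorized proposal agrees with the scalar engine", {
  alg <- build_fixture_algorithm()
  en <- enumerate_assignments(alg)
  pv <- propose_diagnoses_vec(alg, en$answers)
  set.seed(3)
  rows <- sample.int(en$n, 40L)
  value_for <- function(nd, aid) {
    if (nd$answer_domain != "numeric")

      return(if (nd$answer_domain == "boolean") aid == "present" else aid)
    a <- nd$answers[[match(aid, vapply(nd$answers, `[[`, character(1), "id"))]]
    (a$lo + min(a$hi, a$lo + 10)) / 2
  }
  for (r in rows) {
    aid <- vapply(en$answers, `[[`, character(1), r)
    age_band <- aid[["age_band"]]
    age <- c(age_0_2m = 30, age_2_12m = 200, age_1_5y = 800,
             age_5y_plus = 3000)[[age_band]]
    st <- start_consultation(alg, list(age_days = age, weight_kg = 10))
    repeat {
      items <- next_items(st)
      if (!length(items)) break
      nd <- items[[1L]]
      st <- record_answer(st, nd$id, value_for(nd, aid[[nd$id]]))
    }
    st <- propose_diagnoses(st)
    expect_setequal(names(st$proposals), colnames(pv$kept)[pv$kept[r, ]])
    expect_identical(referral_flag(st), pv$referral[r])
    expect_identical(st$proposals[[1L]]$diagnosis$severity, pv$top_tier[r])
  }
})

test_that("corpus runs are deterministic and isolate per-case failures", {
  alg <- build_fixture_algorithm()
  cases <- generate_cases(n = 40, seed = 29)
  # inject one case outside the algorithm's age range
  cases[[7L]]$age_days <- 6000
  t1 <- run_corpus(alg, cases)
  t2 <- run_corpus(alg, cases)
  expect_identical(t1, t2)
  expect_false(is.na(t1$error[7L]))
  expect_match(t1$error[7L], "wrong algorithm")
  expect_identical(sum(!is.na(t1$error)), 1L)
  expect_true(all(nzchar(t1$diagnoses[-7L])))
})

test_that("non-regression of an algorithm against itself is empty", {
  alg <- build_fixture_algorithm()
  cases <- generate_cases(n = 60, seed = 37)
  d <- non_regression(alg, alg, cases)
  expect_true(d$empty)
  expect_identical(d$n_changed, 0L)
  expect_identical(unname(d$summary), rep(0L, 4L))
})

test_that("a CRP cutoff change diffs exactly the predicted case set", {
  alg_old <- build_fixture_algorithm(crp_cutoffs = c(10, 40))
  alg_new <- build_fixture_algorithm(crp_cutoffs = c(10, 60),
                                     version_id = "demo-1.1.0")
  cases <- generate_cases(n = 300, seed = 43)
  d <- non_regression(alg_old, alg_new, cases)
  # oracle: recompute the affected set directly from raw case inputs —
  # febrile, no comorbidity (the lowered cutoff is unchanged), CRP crossing
  # [40, 60), and no severe classification masking the branch
  predicted <- vapply(cases, function(cs) {
    a <- cs$answers
    isTRUE(a$fever) && !isTRUE(a$comorbidity) &&
      a$crp >= 40 && a$crp < 60 && !severe_condition_true(cs)
  }, logical(1))
  expect_identical(which(d$per_case$changed), which(predicted))
  # threshold moves never touch question flow or referral status
  expect_identical(d$summary[["items"]], 0L)
  expect_identical(d$summary[["referral"]], 0L)
})

test_that("adding a mild diagnosis never changes referral flags", {
  alg_old <- build_fixture_algorithm()
  alg_new <- build_fixture_algorithm(version_id = "demo-1.2.0")
  alg_new$diagnoses$cough_advice <- diagnosis(
    "cough_advice", "Simple cough advice", "mild",
    cnd_atom("cough", "present"), managements = "home_advice")
  cases <- generate_cases(n = 100, seed = 47)
  d <- non_regression(alg_old, alg_new, cases)
  expect_identical(d$summary[["referral"]], 0L)
  expect_identical(d$summary[["items"]], 0L)
  expect_true(all(grepl("^\\+cough_advice$|^$", d$per_case$diagnoses_delta)))
})

test_that("expectation-based unit checks pass and fail where intended", {
  alg <- build_fixture_algorithm()
  base <- list(comorbidity = FALSE, convulsions = FALSE,
               unable_to_drink = FALSE, vomits_everything = FALSE,
               lethargic = FALSE, fever = FALSE, cough = FALSE,
               chest_indrawing = FALSE, muac = 14, spo2 = 97,
               resp_rate = 30, crp = 5)
  mk <- function(id, ov) structure(
    list(case_id = id, age_days = 500, sex = "f", weight_kg = 12,
         answers = modifyList(base, ov), estimated = logical(0),
         label = NA_character_), class = "patient_case")
  cases <- list(
    mk("danger", list(convulsions = TRUE)),
    mk("bacterial", list(fever = TRUE, crp = 90)),
    mk("well", list()))
  expectations <- list(
    list(case_id = "danger", diagnoses = "very_severe_disease",
         referral = TRUE, drugs = "ceftriaxone"),
    list(case_id = "bacterial",
         diagnoses = c("bacterial_fever"), referral = FALSE),
    list(case_id = "well", diagnoses = "home_care", referral = FALSE))
  rep <- unit_check(alg, cases, expectations)
  expect_true(all(rep$pass))
  # a deliberately wrong expectation fails, naming the case
  wrong <- list(list(case_id = "well", diagnoses = "pneumonia",
                     referral = FALSE))
  rep2 <- unit_check(alg, cases, wrong)
  expect_false(rep2$pass)
  expect_identical(rep2$case_id, "well")
  expect_match(rep2$detail, "diagnoses differ")
})

test_that("expectations are evaluated pre-review, like branch performance", {
  # refusal happens after proposal: unit checks and the 2x2 counts both see
  # the algorithm's own output
  alg <- build_fixture_algorithm()
  cs <- generate_cases(n = 1, seed = 55)[[1L]]
  cs$answers$convulsions <- TRUE
  st <- replay_case(alg, cs)
  st <- review_diagnosis(st, "very_severe_disease", "refuse", "disagree")
  out <- run_corpus(alg, list(cs))
  expect_match(out$diagnoses, "very_severe_disease")
})
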