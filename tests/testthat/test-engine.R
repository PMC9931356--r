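make_case <- function(overrides = list(), age_days = 400, weight_kg = 12) {
  answers <- list(comorbidity = FALSE, convulsions = FALSE,
                  unable_to_drink = FALSE, vomits_everything = FALSE,
                  lethargic = FALSE, fever = FALSE, cough = FALSE,
                  chest_indrawing = FALSE, muac = 14, spo2 = 97,
                  resp_rate = 30, crp = 5)
  answers[names(overrides)] <- overrides
  structure(list(case_id = "manual", age_days = age_days, sex = "f",
                 weight_kg = weight_kg, answers = answers,
                 estimated = logical(0), label = NA_character_),
            class = "patient_case")
}

test_that("consultation start enforces the algorithm's age range", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 10))
  expect_s3_class(st, "consultation")
  expect_identical(next_items(st)[[1L]]$stage, "registration")
  expect_error(start_consultation(alg, list(age_days = 16 * 365, weight_kg = 40)),
               "wrong algorithm")
  # young infant: valid, and the age band auto-answer lands in the 0-2m band
  st2 <- start_consultation(alg, list(age_days = 30, weight_kg = 4))
  expect_identical(st2$answered$age_band$answer, "age_0_2m")
})

test_that("questions surface stage by stage, danger signs before branches", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 12))
  first <- next_items(st)
  expect_true(all(vapply(first, `[[`, character(1), "stage") == "registration"))
  st <- record_answer(st, "comorbidity", FALSE)
  second <- next_items(st)
  expect_true(all(vapply(second, `[[`, character(1), "stage") == "danger_signs"))
})

test_that("display conditions gate questions until definitely true", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 12))
  askable <- function(s) vapply(next_items(s), `[[`, character(1), "id")
  st <- record_answer(st, "comorbidity", FALSE)
  for (n in danger_sign_nodes(alg)) st <- record_answer(st, n, FALSE)
  # fever unanswered: CRP display condition unknown, node hidden
  expect_false("crp" %in% askable(st))
  st <- record_answer(st, "fever", TRUE)
  st <- record_answer(st, "cough", FALSE)
  # resp_rate needs cough: stays hidden; CRP appears once signs are done
  expect_false("resp_rate" %in% askable(st))
  for (n in c("chest_indrawing", "muac", "spo2"))
    st <- record_answer(st, n, if (n == "chest_indrawing") FALSE else
      if (n == "muac") 14 else 97)
  expect_identical(askable(st), "crp")
  expect_error(record_answer(st, "resp_rate", 40), "not currently askable")
})

test_that("numeric values map to their threshold categories", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 12))
  st <- record_answer(st, "comorbidity", FALSE)
  for (n in danger_sign_nodes(alg)) st <- record_answer(st, n, FALSE)
  st <- record_answer(st, "fever", FALSE)
  st <- record_answer(st, "cough", TRUE)
  st <- record_answer(st, "muac", 12.0)
  expect_identical(st$answered$muac$answer, "muac_low")
  st <- record_answer(st, "spo2", 89)
  expect_identical(st$answered$spo2$answer, "spo2_low")
  # boundary belongs to the upper category: half-open intervals
  st <- record_answer(st, "muac", 12.5)
  expect_identical(st$answered$muac$answer, "muac_ok")
  expect_error(record_answer(st, "resp_rate", 200), "outside admissible")
})

test_that("estimated values are stored with a sub-optimal warning", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 12))
  st <- record_answer(st, "comorbidity", FALSE)
  for (n in danger_sign_nodes(alg)) st <- record_answer(st, n, FALSE)
  st <- record_answer(st, "fever", FALSE)
  st <- record_answer(st, "cough", TRUE)
  st <- record_answer(st, "chest_indrawing", FALSE)
  st <- record_answer(st, "muac", 14)
  st <- record_answer(st, "spo2", 97)
  st <- record_answer(st, "resp_rate", 55, estimated = TRUE)
  codes <- vapply(st$warnings, `[[`, character(1), "code")
  expect_true("estimated_value" %in% codes)
  # estimation is only allowed where declared
  expect_error(record_answer(st, "crp", 5, estimated = TRUE), "not estimable")
  st <- propose_diagnoses(st)
  rec <- finalize_consultation(st)
  expect_true(rec$answers$resp_rate$estimated)
  expect_true(any(vapply(rec$warnings, `[[`, character(1), "code") ==
                    "estimated_value"))
  expect_identical(rec$version_id, alg$meta$version_id)
})

test_that("re-entering the same answer is idempotent", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 12))
  st1 <- record_answer(st, "comorbidity", FALSE)
  st2 <- record_answer(st1, "comorbidity", FALSE)
  expect_identical(st1$answered, st2$answered)
  expect_identical(st1$warnings, st2$warnings)
})

test_that("emergency interrupt returns guidance anywhere and is side-effect free", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 12))
  # on a fresh state, before anything is answered
  em <- trigger_emergency(st)
  expect_gte(length(em$guidance), 1L)
  expect_true(any(vapply(em$guidance, `[[`, character(1), "kind") ==
                    "referral"))
  expect_identical(length(em$state$emergency_log), 1L)
  # mid-consultation: askable items identical before and after
  st <- record_answer(st, "comorbidity", FALSE)
  before <- vapply(next_items(st), `[[`, character(1), "id")
  em2 <- trigger_emergency(st)
  after <- vapply(next_items(em2$state), `[[`, character(1), "id")
  expect_identical(after, before)
  # two interrupts, order preserved
  em3 <- trigger_emergency(em2$state)
  expect_identical(vapply(em3$state$emergency_log, `[[`, integer(1), "seq"),
                   1:2)
  # clinical outputs unaffected by interrupting
  cs <- make_case(list(fever = TRUE, crp = 80))
  plain <- replay_case(alg, cs)
  st4 <- start_consultation(alg, list(age_days = cs$age_days,
                                      weight_kg = cs$weight_kg))
  st4 <- trigger_emergency(st4)$state
  repeat {
    items <- next_items(st4)
    if (!length(items)) break
    st4 <- record_answer(st4, items[[1L]]$id, cs$answers[[items[[1L]]$id]])
  }
  st4 <- propose_diagnoses(st4)
  expect_identical(names(st4$proposals), names(plain$proposals))
})

test_that("diagnosis proposal is severity-first with referral for danger signs", {
  alg <- build_fixture_algorithm()
  st <- replay_case(alg, make_case(list(convulsions = TRUE)))
  top <- st$proposals[[1L]]$diagnosis
  expect_identical(top$severity, "emergency")
  expect_true(referral_flag(st))
  # a fever with high CRP and no severe signs lands on the bacterial branch
  st2 <- replay_case(alg, make_case(list(fever = TRUE, crp = 80)))
  expect_true("bacterial_fever" %in% names(st2$proposals))
  expect_false(referral_flag(st2))
  st2 <- propose_treatments(st2)
  expect_true("amoxicillin" %in% vapply(st2$treatments, `[[`, character(1),
                                        "drug"))
  # nothing at all: the supportive-care catch-all, alone
  st3 <- replay_case(alg, make_case())
  expect_identical(names(st3$proposals), "home_care")
})

test_that("comorbidity lowers the effective CRP cutoff", {
  alg <- build_fixture_algorithm() # cutoffs 10 (comorbid) / 40 (standard)
  mid_crp <- list(fever = TRUE, crp = 25)
  st <- replay_case(alg, make_case(mid_crp))
  expect_false("bacterial_fever" %in% names(st$proposals))
  st2 <- replay_case(alg, make_case(c(mid_crp, list(comorbidity = TRUE))))
  expect_true("bacterial_fever" %in% names(st2$proposals))
})

test_that("explanation traces replay to true on their own", {
  alg <- build_fixture_algorithm()
  cases <- generate_cases(n = 60, seed = 5)
  for (cs in cases) {
    st <- replay_case(alg, cs)
    for (p in st$proposals)
      expect_true(isTRUE(replay_trace(alg, p$trace)),
                  label = paste(cs$case_id, p$diagnosis$id))
  }
})

test_that("review decisions drive treatments and keep the audit trail", {
  alg <- build_fixture_algorithm()
  st <- replay_case(alg, make_case(list(fever = TRUE, crp = 80, cough = TRUE,
                                        resp_rate = 55)))
  expect_setequal(names(st$proposals), c("pneumonia", "bacterial_fever"))
  # refuse one moderate diagnosis: its drug disappears (shared drug kept via
  # the other indication, so refuse both to check absence)
  st_r <- review_diagnosis(st, "pneumonia", "refuse", "clinical judgement")
  st_r <- review_diagnosis(st_r, "bacterial_fever", "refuse", "viral impression")
  st_r <- propose_treatments(st_r)
  expect_identical(length(st_r$treatments), 0L)
  # accepting twice is idempotent
  st_a <- review_diagnosis(st, "pneumonia", "accept")
  st_a2 <- review_diagnosis(st_a, "pneumonia", "accept")
  expect_identical(st_a$reviewed, st_a2$reviewed)
  expect_error(review_diagnosis(st, "home_care", "accept"), "not proposed")
  # refusing a severe diagnosis keeps a prominent warning in the export
  st_sev <- replay_case(alg, make_case(list(convulsions = TRUE)))
  st_sev <- review_diagnosis(st_sev, "very_severe_disease", "refuse",
                             "disagree")
  rec <- finalize_consultation(st_sev)
  expect_true(any(vapply(rec$warnings, `[[`, character(1), "code") ==
                    "refused_referral"))
  expect_identical(rec$reviewed$very_severe_disease$decision, "refuse")
})

test_that("stockouts fall back to flagged alternatives", {
  alg <- build_fixture_algorithm()
  st <- replay_case(alg, make_case(list(cough = TRUE, resp_rate = 55),
                                   weight_kg = 10))
  st1 <- propose_treatments(st)
  amox <- Filter(function(tr) tr$drug == "amoxicillin", st1$treatments)[[1L]]
  expect_false(amox$substituted)
  expect_identical(amox$dose$mg, 250) # 25 mg/kg at 10 kg
  st2 <- propose_treatments(st, stockout = "amoxicillin")
  alt <- Filter(function(tr) tr$indication == "pneumonia", st2$treatments)[[1L]]
  expect_identical(alt$drug, "cotrimoxazole")
  expect_true(alt$substituted)
  expect_true(alt$dose$within_bounds)
})

test_that("duplicate drugs merge to the most severe indication", {
  alg <- build_fixture_algorithm()
  st <- replay_case(alg, make_case(list(fever = TRUE, crp = 80, cough = TRUE,
                                        resp_rate = 55)))
  st <- propose_treatments(st)
  amox <- Filter(function(tr) tr$drug == "amoxicillin", st$treatments)
  expect_identical(length(amox), 1L)
})

test_that("finalization requires the diagnosis phase", {
  alg <- build_fixture_algorithm()
  st <- start_consultation(alg, list(age_days = 400, weight_kg = 12))
  expect_error(finalize_consultation(st), "diagnosis phase")
})

test_that("answer order never changes the clinical outputs", {
  alg <- build_fixture_algorithm()
  cases <- generate_cases(n = 25, seed = 9)
  set.seed(99)
  for (cs in cases) {
    ref <- replay_case(alg, cs)
    ref <- propose_treatments(ref)
    for (r in 1:3) {
      alt <- replay_case(alg, cs, shuffle = TRUE)
      alt <- propose_treatments(alt)
      expect_identical(names(alt$proposals), names(ref$proposals))
      expect_identical(vapply(alt$treatments, `[[`, character(1), "drug"),
                       vapply(ref$treatments, `[[`, character(1), "drug"))
      expect_identical(referral_flag(alt), referral_flag(ref))
    }
  }
})

test_that("adding a danger sign never lowers the top severity tier", {
  alg <- build_fixture_algorithm()
  cases <- generate_cases(n = 30, seed = 13)
  tier_rank <- function(st)
    match(st$proposals[[1L]]$diagnosis$severity,
          c("emergency", "severe", "moderate", "mild"))
  for (cs in cases) {
    base <- tier_rank(replay_case(alg, cs))
    for (sign in danger_sign_nodes(alg)) {
      cs2 <- cs
      cs2$answers[[sign]] <- TRUE
      expect_lte(tier_rank(replay_case(alg, cs2)), base)
    }
  }
})
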