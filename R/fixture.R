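#' Build the packaged demo algorithm
#'
#' A small but complete pediatric triage algorithm exercising every feature
#' of the representation: IMCI-style danger signs feeding emergency/severe
#' classifications with referral managements (severity-first architecture),
#' a MUAC node with the < 12.5 cm malnutrition category, an SpO2 node with
#' the < 90% hypoxaemia category, a fever complaint gating a CRP test with a
#' standard cutoff and a lowered comorbidity cutoff, a respiratory branch
#' with age-dependent fast-breathing thresholds, a composite AT_LEAST
#' clinical-impression item, three drugs with weight-band dosing tables and
#' stockout alternatives, and a supportive-care catch-all. All clinical
#' parameter values are invented demo content except the two canonical
#' screening thresholds (MUAC 12.5 cm, SpO2 90%).
#'
#' @param crp_cutoffs Numeric `c(low, standard)`: the lowered comorbidity
#'   cutoff and the standard cutoff (mg/L) splitting the CRP answers.
#' @param muac_cutoff MUAC malnutrition threshold, cm.
#' @param spo2_cutoff Hypoxaemia threshold, percent.
#' @param rr_thresholds Fast-breathing thresholds (breaths/min) for the
#'   interval answers; must be 3 increasing values out of the fixed interval
#'   edges `c(30, 40, 50)` variant grid (the edges themselves are
#'   configurable).
#' @param dose_targets Named list overriding dosing-rule fields, keyed by
#'   rule id (advanced; used for randomized variants).
#' @param version_id Version string stamped into the content.
#' @return A validated `clinical_algorithm`.
#' @export
build_fixture_algorithm <- function(crp_cutoffs = c(10, 40),
                                    muac_cutoff = 12.5,
                                    spo2_cutoff = 90,
                                    rr_thresholds = c(30, 40, 50),
                                    dose_targets = NULL,
                                    version_id = "demo-1.0.0") {
  stopifnot(length(crp_cutoffs) == 2L, crp_cutoffs[1L] < crp_cutoffs[2L],
            length(rr_thresholds) == 3L, !is.unsorted(rr_thresholds))
  t1 <- rr_thresholds[1L]; t2 <- rr_thresholds[2L]; t3 <- rr_thresholds[3L]
  atom <- cnd_atom

  nodes <- list(
    node("age_band", "registration", "background", "Age band",
         answer_domain = "numeric", unit = "days", range = c(0, 5475),
         derived_from = "age_days",
         answers = list(
           answer("age_0_2m", "Below 2 months", 0, 60),
           answer("age_2_12m", "2-12 months", 60, 365),
           answer("age_1_5y", "1-5 years", 365, 1825),
           answer("age_5y_plus", "5 years and above", 1825, 5475))),
    node("comorbidity", "registration", "background",
         "Known chronic comorbidity"),
    node("convulsions", "danger_signs", "sign",
         "Convulsions during this illness",
         referral_triggering = TRUE, emergency_relevant = TRUE),
    node("unable_to_drink", "danger_signs", "sign",
         "Unable to drink or breastfeed", referral_triggering = TRUE),
    node("vomits_everything", "danger_signs", "sign", "Vomits everything",
         referral_triggering = TRUE),
    node("lethargic", "danger_signs", "sign", "Lethargic or unconscious",
         referral_triggering = TRUE, emergency_relevant = TRUE),
    node("fever", "complaints", "complaint", "History of fever"),
    node("cough", "complaints", "complaint", "Cough or difficulty breathing"),
    node("chest_indrawing", "signs", "sign", "Lower chest wall indrawing"),
    node("muac", "signs", "measurement", "Mid-upper arm circumference",
         answer_domain = "numeric", unit = "cm", range = c(6, 30),
         referral_triggering = TRUE, estimable = TRUE,
         answers = list(
           answer("muac_low", sprintf("< %g cm", muac_cutoff), 6, muac_cutoff),
           answer("muac_ok", sprintf(">= %g cm", muac_cutoff), muac_cutoff, 30))),
    node("spo2", "signs", "measurement", "Oxygen saturation",
         answer_domain = "numeric", unit = "%", range = c(50, 100),
         referral_triggering = TRUE,
         answers = list(
           answer("spo2_low", sprintf("< %g%%", spo2_cutoff), 50, spo2_cutoff),
           answer("spo2_ok", sprintf(">= %g%%", spo2_cutoff), spo2_cutoff, 100))),
    node("resp_rate", "signs", "measurement", "Respiratory rate",
         answer_domain = "numeric", unit = "breaths/min", range = c(10, 120),
         estimable = TRUE,
         display_condition = atom("cough", "present"),
         answers = list(
           answer("rr_low", sprintf("< %g", t1), 10, t1),
           answer("rr_mid", sprintf("%g-%g", t1, t2), t1, t2),
           answer("rr_high", sprintf("%g-%g", t2, t3), t2, t3),
           answer("rr_very_high", sprintf(">= %g", t3), t3, 120))),
    node("crp", "tests", "test", "C-reactive protein",
         answer_domain = "numeric", unit = "mg/L", range = c(0, 200),
         display_condition = atom("fever", "present"),
         answers = list(
           answer("crp_low", sprintf("< %g", crp_cutoffs[1L]), 0, crp_cutoffs[1L]),
           answer("crp_mid", sprintf("%g-%g", crp_cutoffs[1L], crp_cutoffs[2L]),
                  crp_cutoffs[1L], crp_cutoffs[2L]),
           answer("crp_high", sprintf(">= %g", crp_cutoffs[2L]),
                  crp_cutoffs[2L], 200)))
  )

  # age-dependent fast-breathing thresholds: >= t3 under 1 year, >= t2 at
  # 1-5 years, >= t1 at 5 years and above
  fast_breathing <- cnd_or(
    cnd_and(cnd_or(atom("age_band", "age_0_2m"), atom("age_band", "age_2_12m")),
            atom("resp_rate", "rr_very_high")),
    cnd_and(atom("age_band", "age_1_5y"),
            cnd_or(atom("resp_rate", "rr_high"),
                   atom("resp_rate", "rr_very_high"))),
    cnd_and(atom("age_band", "age_5y_plus"),
            cnd_or(atom("resp_rate", "rr_mid"), atom("resp_rate", "rr_high"),
                   atom("resp_rate", "rr_very_high"))))

  nonsevere_branches <- c("pneumonia", "bacterial_fever",
                          "uncomplicated_fever", "home_care")
  diagnoses <- list(
    diagnosis("very_severe_disease", "Very severe disease", "emergency",
              cnd_or(atom("convulsions", "present"), atom("lethargic", "present")),
              managements = c("ref_urgent", "emergency_abc"),
              treatments = list(treatment("ceftriaxone",
                                          alternatives = "benzylpenicillin")),
              excludes = nonsevere_branches),
    diagnosis("severe_febrile_illness", "Severe febrile illness", "severe",
              cnd_or(atom("unable_to_drink", "present"),
                     atom("vomits_everything", "present"),
                     cnd_at_least(2,
                                  atom("chest_indrawing", "present"),
                                  atom("spo2", "spo2_low"),
                                  atom("muac", "muac_low"))),
              managements = "ref_urgent",
              treatments = list(treatment("ceftriaxone",
                                          alternatives = "benzylpenicillin")),
              excludes = nonsevere_branches),
    diagnosis("hypoxaemia", "Hypoxaemia", "severe",
              atom("spo2", "spo2_low"),
              managements = "ref_urgent",
              excludes = nonsevere_branches),
    diagnosis("acute_malnutrition", "Acute malnutrition", "severe",
              atom("muac", "muac_low"),
              managements = "ref_nutrition",
              excludes = nonsevere_branches),
    diagnosis("pneumonia", "Pneumonia (fast breathing)", "moderate",
              cnd_and(atom("cough", "present"), fast_breathing),
              managements = "follow_up_3d",
              treatments = list(treatment("amoxicillin",
                                          alternatives = "cotrimoxazole")),
              excludes = "home_care"),
    diagnosis("bacterial_fever", "Febrile illness, likely bacterial", "moderate",
              cnd_and(atom("fever", "present"),
                      cnd_or(atom("crp", "crp_high"),
                             cnd_and(atom("comorbidity", "present"),
                                     atom("crp", "crp_mid")))),
              managements = "follow_up_3d",
              treatments = list(treatment("amoxicillin",
                                          alternatives = "cotrimoxazole")),
              excludes = c("uncomplicated_fever", "home_care")),
    diagnosis("uncomplicated_fever", "Uncomplicated febrile illness", "mild",
              atom("fever", "present"),
              managements = "fever_advice",
              treatments = list(treatment("paracetamol")),
              excludes = "home_care"),
    diagnosis("home_care", "No specific condition: supportive home care",
              "mild", cnd_true(), managements = "home_advice")
  )

  managements <- list(
    management("ref_urgent", "Urgent referral to hospital", "referral"),
    management("ref_nutrition", "Referral to nutrition programme", "referral"),
    management("emergency_abc",
               "Emergency supportive care: airway, breathing, circulation, glucose",
               "pre_referral"),
    management("follow_up_3d", "Follow-up visit in 3 days", "follow_up"),
    management("fever_advice", "Antipyretic and fluid advice", "counselling"),
    management("home_advice", "Home-care counselling, return if worse",
               "counselling")
  )

  drugs <- list(
    drug("ceftriaxone", "Ceftriaxone (pre-referral)",
         list(formulation("injection", strength = 250, increment = 0.5))),
    drug("benzylpenicillin", "Benzylpenicillin (pre-referral)",
         list(formulation("injection", strength = 200, increment = 0.5))),
    drug("amoxicillin", "Amoxicillin suspension",
         list(formulation("suspension", strength = 25, increment = 1))),
    drug("cotrimoxazole", "Cotrimoxazole dispersible tablet",
         list(formulation("dispersible_tablet", strength = 120, increment = 0.5))),
    drug("paracetamol", "Paracetamol syrup",
         list(formulation("syrup", strength = 24, increment = 1)))
  )

  AGE_ALL <- c(0, 5475)
  rules <- list(
    dosing_rule("cef_vsd", "ceftriaxone", "very_severe_disease",
                AGE_ALL[1], AGE_ALL[2], 2, 30, 80, 50, 100, 2000, 1, 1),
    dosing_rule("cef_sfi", "ceftriaxone", "severe_febrile_illness",
                AGE_ALL[1], AGE_ALL[2], 2, 30, 80, 50, 100, 2000, 1, 1),
    dosing_rule("pen_vsd", "benzylpenicillin", "very_severe_disease",
                AGE_ALL[1], AGE_ALL[2], 2, 30, 50, 30, 75, 2400, 1, 1),
    dosing_rule("pen_sfi", "benzylpenicillin", "severe_febrile_illness",
                AGE_ALL[1], AGE_ALL[2], 2, 30, 50, 30, 75, 2400, 1, 1),
    dosing_rule("amox_pneu_lo", "amoxicillin", "pneumonia",
                AGE_ALL[1], AGE_ALL[2], 2, 10, 25, 15, 35, 1000, 2, 5),
    dosing_rule("amox_pneu_hi", "amoxicillin", "pneumonia",
                AGE_ALL[1], AGE_ALL[2], 10, 30, 25, 15, 35, 1000, 2, 5),
    dosing_rule("amox_bact_lo", "amoxicillin", "bacterial_fever",
                AGE_ALL[1], AGE_ALL[2], 2, 10, 25, 15, 35, 1000, 2, 5),
    dosing_rule("amox_bact_hi", "amoxicillin", "bacterial_fever",
                AGE_ALL[1], AGE_ALL[2], 10, 30, 25, 15, 35, 1000, 2, 5),
    dosing_rule("cotri_pneu", "cotrimoxazole", "pneumonia",
                AGE_ALL[1], AGE_ALL[2], 2, 30, 24, 15, 36, 1920, 2, 5),
    dosing_rule("cotri_bact", "cotrimoxazole", "bacterial_fever",
                AGE_ALL[1], AGE_ALL[2], 2, 30, 24, 15, 36, 1920, 2, 5),
    dosing_rule("para_fever", "paracetamol", "uncomplicated_fever",
                AGE_ALL[1], AGE_ALL[2], 2, 30, 12, 8, 16, 500, 4, 3)
  )
  if (!is.null(dose_targets)) {
    rules <- lapply(rules, function(r) {
      ov <- dose_targets[[r$id]]
      if (!is.null(ov)) r[names(ov)] <- ov
      r
    })
  }

  build_algorithm(clinical_algorithm(
    name = "mini-triage-demo", country = "demo", version_id = version_id,
    age_range = c(0, 5475),
    stages = c("registration", "danger_signs", "complaints", "signs", "tests"),
    nodes = nodes, diagnoses = diagnoses, managements = managements,
    drugs = drugs, dosing_rules = rules,
    emergency_guidance = c("emergency_abc", "ref_urgent")))
}

#' Danger-sign node ids of an algorithm
#'
#' The boolean referral-triggering nodes of the danger-sign stage: the IMCI
#' screening signs whose presence mandates severe classification and
#' referral.
#'
#' @param alg A `clinical_algorithm`.
#' @return Character vector of node ids.
#' @export
danger_sign_nodes <- function(alg) {
  names(Filter(function(nd)
    nd$stage == "danger_signs" && nd$referral_triggering &&
      nd$answer_domain == "boolean", alg$nodes))
}
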