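# Shared oracles and small fixtures, built in code at test time.

# Independent brute-force dose minimizer: enumerate every dispensable
# quantity up to the absolute max and pick the in-bounds candidate closest
# to the target, tie toward the lower quantity. Returns NULL when no
# candidate is in bounds.
brute_force_dose <- function(rule, formulation, weight_kg) {
  step_mg <- formulation$increment * formulation$strength
  best <- NULL
  best_err <- Inf
  k <- 1L
  repeat {
    mg <- k * step_mg
    if (mg > rule$abs_max + 1e-9) break
    mgkg <- mg / weight_kg
    if (mgkg >= rule$min && mgkg <= rule$max) {
      err <- abs(mgkg - rule$target)
      if (err < best_err - 1e-12) { # strict improvement only: tie stays lower
        best <- k
        best_err <- err
      }
    }
    k <- k + 1L
  }
  if (is.null(best)) NULL
  else list(increments = best, quantity = best * formulation$increment,
            mg = best * step_mg, mg_per_kg = best * step_mg / weight_kg)
}

# A tiny two-stage algorithm for engine edge-case tests.
tiny_algorithm <- function() {
  clinical_algorithm(
    name = "tiny", country = "demo", version_id = "t-1",
    age_range = c(0, 3650),
    stages = c("s1", "s2"),
    nodes = list(
      node("a", "s1", "complaint", "A?"),
      node("b", "s2", "sign", "B?",
           display_condition = cnd_atom("a", "present")),
      node("m", "s2", "measurement", "M", answer_domain = "numeric",
           unit = "u", range = c(0, 10), estimable = TRUE,
           answers = list(answer("m_low", "low", 0, 5),
                          answer("m_high", "high", 5, 10)))
    ),
    diagnoses = list(
      diagnosis("dx_ab", "A and B", "severe",
                cnd_and(cnd_atom("a", "present"), cnd_atom("b", "present")),
                managements = "ref"),
      diagnosis("dx_rest", "Default", "mild", cnd_true(),
                managements = "advice", excludes = character())
    ),
    managements = list(management("ref", "Refer", "referral"),
                       management("advice", "Advice", "counselling")),
    emergency_guidance = character()
  )
}

# Random condition generator over a fixed atom universe, for property tests.
random_condition <- function(nodes, depth = 3) {
  if (depth == 0 || runif(1) < 0.35) {
    nd <- sample(names(nodes), 1L)
    return(cnd_atom(nd, sample(nodes[[nd]], 1L)))
  }
  op <- sample(c("and", "or", "not", "at_least"), 1L)
  if (op == "not") return(cnd_not(random_condition(nodes, depth - 1L)))
  k <- sample(2:3, 1L)
  args <- replicate(k, random_condition(nodes, depth - 1L), simplify = FALSE)
  if (op == "and") do.call(cnd_and, args)
  else if (op == "or") do.call(cnd_or, args)
  else {
    atoms <- replicate(k, {
      nd <- sample(names(nodes), 1L)
      cnd_atom(nd, sample(nodes[[nd]], 1L))
    }, simplify = FALSE)
    do.call(cnd_at_least, c(list(k = sample.int(k, 1L)), atoms))
  }
}

# All severe/emergency danger-branch truth, straight from raw case inputs:
# the direct predicted-set oracle used by non-regression localization checks.
severe_condition_true <- function(cs, muac_cutoff = 12.5, spo2_cutoff = 90) {
  a <- cs$answers
  isTRUE(a$convulsions) || isTRUE(a$lethargic) ||
    isTRUE(a$unable_to_drink) || isTRUE(a$vomits_everything) ||
    (isTRUE(a$chest_indrawing) + (a$spo2 < spo2_cutoff) +
       (a$muac < muac_cutoff)) >= 2 ||
    a$spo2 < spo2_cutoff || a$muac < muac_cutoff
}
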