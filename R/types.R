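#' Construct an algorithm node (one question or measurement)
#'
#' A node is one item the clinician answers during a consultation: a
#' complaint, symptom, sign, measurement, laboratory test or background item.
#' Its `answer_domain` is boolean (answers `present`/`absent`), categorical
#' (explicit answer list) or numeric (a unit, an admissible half-open range
#' `[lo, hi)` and answers defined by threshold intervals that partition it).
#'
#' @param id Unique node id.
#' @param stage Stage name; must be one of the algorithm's stages.
#' @param kind One of `complaint`, `symptom`, `sign`, `measurement`, `test`,
#'   `background`, `calculated`.
#' @param label Human-readable question text.
#' @param answer_domain `"boolean"`, `"categorical"` or `"numeric"`.
#' @param answers For categorical/numeric nodes, a list of [answer()] objects.
#'   Numeric answers carry `lo`/`hi` interval bounds (half-open `[lo, hi)`;
#'   `NULL` bounds default to the admissible range ends).
#' @param unit,range For numeric nodes: measurement unit and admissible range
#'   `c(lo, hi)`, interpreted as `[lo, hi)`.
#' @param display_condition Optional condition gating whether the node is
#'   asked at all.
#' @param referral_triggering Flag: the node participates in severe/emergency
#'   classification and is highlighted as referral-relevant.
#' @param estimable Flag: the value may be estimated rather than measured
#'   (recorded with a sub-optimal warning).
#' @param emergency_relevant Flag: shown with the emergency guidance.
#' @param derived_from Optional demographic field (`"age_days"`) the node is
#'   auto-answered from at consultation start.
#' @param help Optional help text or media reference (opaque string).
#' @return A `tt_node` object.
#' @export
node <- function(id, stage, kind, label,
                 answer_domain = c("boolean", "categorical", "numeric"),
                 answers = NULL, unit = NULL, range = NULL,
                 display_condition = NULL, referral_triggering = FALSE,
                 estimable = FALSE, emergency_relevant = FALSE,
                 derived_from = NULL, help = NULL) {
  answer_domain <- match.arg(answer_domain)
  kinds <- c("complaint", "symptom", "sign", "measurement", "test",
             "background", "calculated")
  if (!kind %in% kinds) stopf("node '%s': unknown kind '%s'", id, kind)
  if (answer_domain == "boolean" && is.null(answers)) {
    answers <- list(answer("present", "Present"), answer("absent", "Absent"))
  }
  if (answer_domain == "numeric") {
    if (is.null(unit) || is.null(range))
      stopf("node '%s': numeric nodes need unit and range", id)
    range <- as.numeric(range)
    # resolve open-ended answer bounds against the admissible range
    answers <- lapply(answers, function(a) {
      a$lo <- as.numeric(a$lo %||% range[1L])
      a$hi <- as.numeric(a$hi %||% range[2L])
      a
    })
  }
  structure(list(
    id = id, stage = stage, kind = kind, label = label,
    answer_domain = answer_domain, answers = answers,
    unit = unit, range = range,
    display_condition = display_condition,
    referral_triggering = isTRUE(referral_triggering),
    estimable = isTRUE(estimable),
    emergency_relevant = isTRUE(emergency_relevant),
    derived_from = derived_from, help = help
  ), class = "tt_node")
}

#' Construct an answer option
#'
#' @param id Answer id, unique within its node.
#' @param label Display label (defaults to the id).
#' @param lo,hi For answers of numeric nodes: the half-open interval
#'   `[lo, hi)` of values mapped to this answer. `NULL` defaults to the
#'   parent node's admissible bound.
#' @return A `tt_answer` object.
#' @export
answer <- function(id, label = id, lo = NULL, hi = NULL) {
  structure(list(id = id, label = label, lo = num_or_null(lo),
                 hi = num_or_null(hi)),
            class = "tt_answer")
}

#' Construct a diagnosis (classification) entry
#'
#' @param id Unique diagnosis id.
#' @param label Display label.
#' @param severity One of `emergency`, `severe`, `moderate`, `mild`
#'   (decreasing urgency). Severe and emergency diagnoses must carry a
#'   referral management.
#' @param condition The [conditions] expression that proposes the diagnosis.
#' @param managements Character vector of management ids (referral, advice,
#'   follow-up).
#' @param treatments List of [treatment()] entries.
#' @param excludes Character vector of diagnosis ids suppressed when this one
#'   holds (e.g. severe classifications suppress the specific-treatment
#'   branches).
#' @return A `tt_diagnosis` object.
#' @export
diagnosis <- function(id, label, severity, condition, managements = character(),
                      treatments = list(), excludes = character()) {
  if (!severity %in% SEVERITY_LEVELS)
    stopf("diagnosis '%s': unknown severity '%s'", id, severity)
  structure(list(id = id, label = label, severity = severity,
                 condition = condition, managements = as_chr(managements),
                 treatments = treatments, excludes = as_chr(excludes)),
            class = "tt_diagnosis")
}

#' Construct a treatment entry of a diagnosis
#'
#' @param drug First-line drug id.
#' @param rule Dosing-rule set id is not needed: rules are selected by
#'   (drug, indication, age, weight); this argument is the *indication*
#'   override and defaults to the owning diagnosis.
#' @param alternatives Character vector of alternative drug ids, tried in
#'   order when the first-line drug is stocked out.
#' @return A `tt_treatment` object.
#' @export
treatment <- function(drug, alternatives = character(), rule = NULL) {
  structure(list(drug = drug, alternatives = as_chr(alternatives),
                 rule = rule),
            class = "tt_treatment")
}

#' Construct a management entry
#'
#' @param id Unique management id.
#' @param label Display label.
#' @param kind One of `referral`, `pre_referral`, `counselling`, `follow_up`.
#' @return A `tt_management` object.
#' @export
management <- function(id, label, kind = c("referral", "pre_referral",
                                           "counselling", "follow_up")) {
  kind <- match.arg(kind)
  structure(list(id = id, label = label, kind = kind), class = "tt_management")
}

#' Construct a drug definition
#'
#' @param id Unique drug id.
#' @param name Drug name.
#' @param formulations List of [formulation()] objects (at least one).
#' @return A `tt_drug` object.
#' @export
drug <- function(id, name, formulations) {
  structure(list(id = id, name = name, formulations = formulations),
            class = "tt_drug")
}

#' Construct a drug formulation
#'
#' @param form One of `tablet`, `dispersible_tablet`, `syrup`, `suspension`,
#'   `injection`.
#' @param strength Strength in mg per dispensing unit: mg per tablet for
#'   (dispersible) tablets, mg per ml for liquids and injections.
#' @param increment Smallest dispensable amount in dispensing units, e.g.
#'   `0.5` for half tablets or `1` for whole ml.
#' @return A `tt_formulation` object.
#' @export
formulation <- function(form = c("tablet", "dispersible_tablet", "syrup",
                                 "suspension", "injection"),
                        strength, increment) {
  form <- match.arg(form)
  stopifnot(strength > 0, increment > 0)
  structure(list(form = form, strength = as.numeric(strength),
                 increment = as.numeric(increment)),
            class = "tt_formulation")
}

#' Construct a weight- and age-band dosing rule
#'
#' A rule applies to patients inside its band, the half-open product
#' `[age_lo, age_hi)` days x `[weight_lo, weight_hi)` kg, and specifies a
#' target dose in mg per kg per dose, the tolerated interval around it, and
#' an absolute per-dose ceiling.
#'
#' @param id Unique rule id.
#' @param drug Drug id the rule doses.
#' @param indication Diagnosis id the rule applies to.
#' @param age_lo,age_hi Age band in days, half-open.
#' @param weight_lo,weight_hi Weight band in kg, half-open.
#' @param target Target dose, mg/kg/dose.
#' @param min,max Tolerated achieved dose interval, mg/kg/dose (closed).
#' @param abs_max Absolute maximum mg per dose.
#' @param frequency Doses per day.
#' @param duration Days of treatment.
#' @return A `tt_dosing_rule` object.
#' @export
dosing_rule <- function(id, drug, indication, age_lo, age_hi,
                        weight_lo, weight_hi, target, min, max, abs_max,
                        frequency, duration) {
  structure(list(id = id, drug = drug, indication = indication,
                 age_lo = as.numeric(age_lo), age_hi = as.numeric(age_hi),
                 weight_lo = as.numeric(weight_lo),
                 weight_hi = as.numeric(weight_hi),
                 target = as.numeric(target), min = as.numeric(min),
                 max = as.numeric(max), abs_max = as.numeric(abs_max),
                 frequency = as.numeric(frequency),
                 duration = as.numeric(duration)),
            class = "tt_dosing_rule")
}

#' Assemble a clinical algorithm
#'
#' Collects the registries into a `clinical_algorithm` object. Terminology
#' codes are auto-assigned (deterministically, from id and version) to any
#' node or diagnosis missing one. Construction does *not* validate; call
#' [validate_algorithm()] or build from a document with [build_algorithm()],
#' which does.
#'
#' @param name,country,version_id Algorithm metadata.
#' @param age_range Applicable patient age range in days, half-open
#'   `[min_days, max_days)`.
#' @param stages Ordered character vector of stage names.
#' @param nodes,diagnoses,managements,drugs List of the respective objects
#'   (authoring order is preserved and meaningful).
#' @param dosing_rules List of [dosing_rule()] objects.
#' @param emergency_guidance Character vector of management ids shown on
#'   emergency interrupt.
#' @param terminology Named character vector id -> stable code; missing
#'   entries are auto-derived.
#' @return A `clinical_algorithm` object.
#' @export
clinical_algorithm <- function(name, country, version_id, age_range, stages,
                               nodes, diagnoses, managements = list(),
                               drugs = list(), dosing_rules = list(),
                               emergency_guidance = character(),
                               terminology = character()) {
  named <- function(xs) setNames(xs, vapply(xs, `[[`, character(1), "id"))
  alg <- structure(list(
    meta = list(name = name, country = country, version_id = version_id,
                age_min_days = as.numeric(age_range[1L]),
                age_max_days = as.numeric(age_range[2L])),
    stages = as_chr(stages),
    nodes = named(nodes),
    diagnoses = named(diagnoses),
    managements = named(managements),
    drugs = named(drugs),
    dosing_rules = named(dosing_rules),
    emergency_guidance = as_chr(emergency_guidance),
    terminology = unlist(terminology) %||% setNames(character(), character())
  ), class = "clinical_algorithm")
  alg$terminology <- assign_terminology(alg)
  alg
}

# stable codes for nodes and diagnoses lacking one
assign_terminology <- function(alg) {
  ids <- c(names(alg$nodes), names(alg$diagnoses))
  codes <- alg$terminology
  missing <- setdiff(ids, names(codes))
  auto <- vapply(missing, terminology_code, character(1),
                 version_id = alg$meta$version_id)
  out <- c(codes, auto)[ids]
  names(out) <- ids
  out
}

#' @export
print.clinical_algorithm <- function(x, ...) {
  cat(sprintf("<clinical_algorithm> %s (%s) version %s\n",
              x$meta$name, x$meta$country, x$meta$version_id))
  cat(sprintf("  age range: [%g, %g) days\n",
              x$meta$age_min_days, x$meta$age_max_days))
  cat(sprintf("  %d stages, %d nodes, %d diagnoses, %d managements, %d drugs, %d dosing rules\n",
              length(x$stages), length(x$nodes), length(x$diagnoses),
              length(x$managements), length(x$drugs), length(x$dosing_rules)))
  invisible(x)
}
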