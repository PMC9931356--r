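#' Start a consultation
#'
#' Creates an empty consultation state for one patient encounter. Background
#' nodes declared with `derived_from = "age_days"` are auto-answered from the
#' demographics so that age-banded logic (e.g. age-dependent respiratory-rate
#' thresholds, young-infant branches) can gate later questions.
#'
#' @param alg A validated `clinical_algorithm`.
#' @param demographics List with `age_days`, `weight_kg` and optionally `sex`.
#' @return A `consultation` state object. Engine functions are functional:
#'   they return an updated copy of the state.
#' @export
start_consultation <- function(alg, demographics) {
  age <- as.numeric(demographics$age_days)
  if (is.na(age) || age < 0 || age >= 20 * 365.25)
    stopf("age_days %s outside the sane range [0, 20 years)", age)
  if (!(age >= alg$meta$age_min_days && age < alg$meta$age_max_days))
    stopf("patient age %g days outside algorithm range [%g, %g): wrong algorithm selected",
          age, alg$meta$age_min_days, alg$meta$age_max_days)
  if (!is.null(demographics$weight_kg) && !(demographics$weight_kg > 0))
    stopf("weight must be positive")
  state <- structure(list(
    alg = alg,
    # ask order (stage, then topological, then authoring), computed once
    node_seq = names(alg$nodes)[node_order_index(alg)],
    version_id = alg$meta$version_id,
    demographics = list(age_days = age,
                        weight_kg = num_or_null(demographics$weight_kg),
                        sex = demographics$sex %||% NA_character_),
    answered = list(),     # node_id -> list(value, answer, estimated, order)
    order_counter = 0L,
    emergency_log = list(),
    proposals = NULL,
    reviewed = list(),
    treatments = NULL,
    warnings = list(),
    finalized = FALSE
  ), class = "consultation")
  # auto-answer demographic-derived background nodes
  for (nd in alg$nodes) {
    if (is.null(nd$derived_from)) next
    val <- switch(nd$derived_from,
                  age_days = age,
                  stopf("unknown derived_from '%s'", nd$derived_from))
    state <- store_answer(state, nd, val, estimated = FALSE)
  }
  state
}

answer_ids <- function(nd) vapply(nd$answers, `[[`, character(1), "id")

# map a raw value to the node's answer id
categorize_value <- function(nd, value) {
  if (nd$answer_domain == "boolean") {
    if (is.logical(value)) return(if (value) "present" else "absent")
    value <- as.character(value)
    if (!value %in% answer_ids(nd))
      stopf("node '%s': boolean answer must be TRUE/FALSE or present/absent", nd$id)
    return(value)
  }
  if (nd$answer_domain == "categorical") {
    value <- as.character(value)
    if (!value %in% answer_ids(nd))
      stopf("node '%s': unknown answer '%s'", nd$id, value)
    return(value)
  }
  value <- as.numeric(value)
  if (is.na(value) || value < nd$range[1L] || value >= nd$range[2L])
    stopf("node '%s': value %s outside admissible range [%g, %g) %s",
          nd$id, format(value), nd$range[1L], nd$range[2L], nd$unit %||% "")
  for (a in nd$answers)
    if (value >= a$lo && value < a$hi) return(a$id)
  stopf("node '%s': no answer interval covers %g", nd$id, value)
}

store_answer <- function(state, nd, value, estimated) {
  aid <- categorize_value(nd, value)
  prev <- state$answered[[nd$id]]
  ord <- if (!is.null(prev)) prev$order else {
    state$order_counter <- state$order_counter + 1L
    state$order_counter
  }
  state$answered[[nd$id]] <- list(value = value, answer = aid,
                                  estimated = isTRUE(estimated), order = ord)
  if (isTRUE(estimated)) {
    state$warnings[[length(state$warnings) + 1L]] <- list(
      code = "estimated_value", node = nd$id,
      message = sprintf("value of '%s' was estimated, not measured (sub-optimal)",
                        nd$label))
  }
  state
}

current_answer_map <- function(state) {
  vapply(state$answered, `[[`, character(1), "answer")
}

#' Next askable items
#'
#' Returns the nodes the clinician should be asked next: the unanswered
#' nodes of the earliest stage that has any, whose display condition is
#' absent or evaluates *definitely true* under three-valued logic (a
#' condition still unknown keeps its node hidden until enough answers are
#' in). Order is stage order, then topological order of the dependency
#' graph, then authoring order. An empty result means all stages are
#' exhausted and the consultation moves to the diagnosis phase.
#'
#' @param state A `consultation`.
#' @return List of `tt_node` objects (possibly empty).
#' @export
next_items <- function(state) {
  stopifnot(!state$finalized)
  alg <- state$alg
  answers <- current_answer_map(state)
  items <- list()
  stage <- NULL
  for (nid in state$node_seq) { # already stage/topo/authoring ordered
    nd <- alg$nodes[[nid]]
    if (!is.null(stage) && nd$stage != stage) {
      if (length(items)) break # earliest stage with askable items wins
      stage <- NULL
    }
    if (!is.null(nd$derived_from)) next
    if (nid %in% names(state$answered)) next
    ok <- if (is.null(nd$display_condition)) TRUE
          else eval_condition(nd$display_condition, answers)
    if (isTRUE(ok)) {
      items[[length(items) + 1L]] <- nd
      stage <- nd$stage
    }
  }
  items
}

#' Record an answer
#'
#' Stores a value for a currently askable node. Numeric values are mapped to
#' their threshold-interval answer; estimated values are stored identically
#' but flagged, and a sub-optimal warning is kept for the export. Re-entering
#' the same value for an already answered node is a no-op; re-answering with
#' a new value updates it (earlier gated-off answers are never deleted).
#'
#' @param state A `consultation`.
#' @param node_id Node to answer.
#' @param value Logical (boolean nodes), answer id (categorical) or number
#'   (numeric nodes).
#' @param estimated Flag: value was estimated, not measured. Only allowed on
#'   nodes declared `estimable`.
#' @return The updated state.
#' @export
record_answer <- function(state, node_id, value, estimated = FALSE) {
  stopifnot(!state$finalized)
  nd <- state$alg$nodes[[node_id]]
  if (is.null(nd)) stopf("unknown node '%s'", node_id)
  if (isTRUE(estimated) && !nd$estimable)
    stopf("node '%s' is not estimable", node_id)
  answered <- node_id %in% names(state$answered)
  if (!answered) {
    askable <- vapply(next_items(state), `[[`, character(1), "id")
    if (!node_id %in% askable)
      stopf("node '%s' is not currently askable", node_id)
  } else if (identical(state$answered[[node_id]]$value, value) &&
             identical(state$answered[[node_id]]$estimated, isTRUE(estimated))) {
    return(state) # idempotent re-entry
  }
  store_answer(state, nd, value, estimated)
}

#' Trigger the emergency interrupt
#'
#' Immediately returns the algorithm's emergency guidance (its
#' `emergency_guidance` managements and any `emergency_relevant` node
#' labels), at any point of the consultation, and appends an interrupt
#' record to the state. The consultation resumes exactly where it left off:
#' the interrupt has no effect on any later clinical output.
#'
#' @param state A `consultation`.
#' @return List with `guidance` (list of management objects) and `state`
#'   (updated, with the interrupt logged).
#' @export
trigger_emergency <- function(state) {
  stopifnot(!state$finalized)
  guidance <- state$alg$managements[state$alg$emergency_guidance]
  state$emergency_log[[length(state$emergency_log) + 1L]] <- list(
    seq = length(state$emergency_log) + 1L,
    answered_at = length(state$answered))
  list(guidance = guidance, state = state)
}

# Resolve every node to answered / gated-false / unresolved, walking the
# dependency graph topologically. Atoms on gated-off nodes are false at
# diagnosis time: the question was legitimately never asked.
resolve_nodes <- function(alg, answers, seq = NULL) {
  gated <- character(0)
  unresolved <- character(0)
  seq <- seq %||% names(alg$nodes)[node_order_index(alg)]
  for (nd in alg$nodes[seq]) {
    if (nd$id %in% names(answers)) next
    shown <- if (is.null(nd$display_condition)) TRUE
             else eval_condition(nd$display_condition, answers, gated)
    if (isFALSE(shown)) gated <- c(gated, nd$id)
    else unresolved <- c(unresolved, nd$id)
  }
  list(gated = gated, unresolved = unresolved)
}

#' Propose diagnoses with explanation traces
#'
#' Evaluates every diagnosis condition against the recorded answers (atoms
#' on nodes gated off by a false display condition count as false), removes
#' diagnoses suppressed by an active `excludes` of a kept higher-priority
#' diagnosis, and orders the result severity-first: emergency, severe,
#' moderate, mild, ties broken by authoring order. Each proposal carries an
#' explanation trace: the minimal set of answers that made its condition
#' true, for presenting the decision-tree logic to the clinician.
#'
#' @param state A `consultation` whose stages are exhausted
#'   ([next_items()] empty).
#' @return The updated state; `state$proposals` is the ordered list of
#'   `list(diagnosis, trace)` entries.
#' @export
propose_diagnoses <- function(state) {
  stopifnot(!state$finalized)
  alg <- state$alg
  answers <- current_answer_map(state)
  res <- resolve_nodes(alg, answers, seq = state$node_seq)
  # any atom referenced by a diagnosis condition must be resolved
  need <- unique(unlist(lapply(alg$diagnoses,
                               function(d) condition_atoms(d$condition)$node)))
  bad <- intersect(need, res$unresolved)
  if (length(bad))
    stopf("cannot propose diagnoses: unresolved nodes: %s",
          paste(bad, collapse = ", "))
  active <- Filter(function(d)
    isTRUE(eval_condition(d$condition, answers, res$gated)), alg$diagnoses)
  # severity-first priority order, authoring order within tier
  pr <- order(vapply(active, function(d) severity_rank(d$severity), numeric(1)),
              match(names(active), names(alg$diagnoses)))
  active <- active[pr]
  kept <- list()
  suppressed <- character(0)
  for (d in active) {
    if (d$id %in% suppressed) next
    kept[[d$id]] <- d
    suppressed <- union(suppressed, d$excludes)
  }
  state$proposals <- lapply(kept, function(d) {
    sup <- support_assignment(d$condition, answers, res$gated, want = TRUE)
    list(diagnosis = d, trace = explanation_trace(alg, d, sup))
  })
  names(state$proposals) <- names(kept)
  state
}

explanation_trace <- function(alg, dx, support) {
  atoms <- lapply(names(support), function(nid) {
    nd <- alg$nodes[[nid]]
    aid <- support[[nid]]
    list(node = nid, node_label = nd$label, answer = aid,
         answer_label = if (is.na(aid)) "not present (branch not taken)"
                        else {
                          a <- nd$answers[[match(aid, answer_ids(nd))]]
                          a$label
                        })
  })
  structure(list(diagnosis = dx$id, atoms = atoms, support = support),
            class = "tt_explanation")
}

#' Replay an explanation trace against its condition
#'
#' Soundness check used by tests and the UI layer: only the trace's atoms
#' are answered (gated entries stay ruled out) and the diagnosis condition
#' must still evaluate true.
#'
#' @param alg The algorithm.
#' @param trace A `tt_explanation` from [propose_diagnoses()].
#' @return `TRUE`/`FALSE`/`NA`.
#' @export
replay_trace <- function(alg, trace) {
  dx <- alg$diagnoses[[trace$diagnosis]]
  replay_support(dx$condition, trace$support)
}

#' Review a proposed diagnosis
#'
#' Records the clinician's accept/refuse decision. Refused diagnoses
#' contribute no treatments; refusing a severe or emergency (referral
#' carrying) diagnosis keeps a prominent warning in the final record — the
#' engine respects clinical autonomy but preserves the audit trail.
#'
#' @param state A `consultation` after [propose_diagnoses()].
#' @param diagnosis_id A proposed diagnosis id.
#' @param decision `"accept"` or `"refuse"`.
#' @param reason Free-text reason (required for refusals in spirit; stored).
#' @return The updated state.
#' @export
review_diagnosis <- function(state, diagnosis_id,
                             decision = c("accept", "refuse"), reason = "") {
  stopifnot(!state$finalized)
  decision <- match.arg(decision)
  if (is.null(state$proposals) || !diagnosis_id %in% names(state$proposals))
    stopf("diagnosis '%s' was not proposed", diagnosis_id)
  state$reviewed[[diagnosis_id]] <- list(decision = decision, reason = reason)
  dx <- state$alg$diagnoses[[diagnosis_id]]
  if (decision == "refuse" && dx$severity %in% c("emergency", "severe")) {
    already <- any(vapply(state$warnings, function(w)
      identical(w$code, "refused_referral") && identical(w$node, diagnosis_id),
      logical(1)))
    if (!already)
      state$warnings[[length(state$warnings) + 1L]] <- list(
        code = "refused_referral", node = diagnosis_id,
        message = sprintf("clinician refused %s diagnosis '%s' carrying a referral",
                          dx$severity, dx$label))
  }
  state
}

#' Propose treatments with doses and stockout alternatives
#'
#' For every accepted (or unreviewed — inaction never silently drops care)
#' proposed diagnosis, selects the applicable dosing rule for the patient's
#' age and weight and computes a practical dispensable dose. If the
#' first-line drug is stocked out, the first available listed alternative is
#' dosed instead and the substitution flagged. The same drug indicated by
#' several diagnoses is dispensed once, keeping the most severe indication.
#'
#' @param state A `consultation` after [propose_diagnoses()].
#' @param stockout Character vector of drug ids currently unavailable.
#' @return The updated state; `state$treatments` is a list of entries with
#'   `drug`, `dose` (a `tt_dose_result`), `indication`, `substituted`,
#'   `first_line`.
#' @export
propose_treatments <- function(state, stockout = character()) {
  stopifnot(!state$finalized)
  if (is.null(state$proposals)) stopf("propose_diagnoses must run first")
  alg <- state$alg
  age <- state$demographics$age_days
  weight <- state$demographics$weight_kg
  if (is.null(weight)) stopf("patient weight required for dosing")
  accepted <- Filter(function(p) {
    rv <- state$reviewed[[p$diagnosis$id]]
    is.null(rv) || rv$decision == "accept"
  }, state$proposals)
  out <- list()
  for (p in accepted) {
    dx <- p$diagnosis
    for (tr in dx$treatments) {
      indication <- tr$rule %||% dx$id
      cand <- c(tr$drug, tr$alternatives)
      avail <- setdiff(cand, stockout)
      if (length(avail) == 0L) {
        out[[length(out) + 1L]] <- list(
          drug = tr$drug, indication = dx$id, severity = dx$severity,
          dose = NULL, substituted = FALSE, first_line = tr$drug,
          error = "drug and all alternatives stocked out")
        next
      }
      chosen <- avail[1L]
      rule <- select_rule(chosen, indication, age, weight, alg$dosing_rules)
      form <- alg$drugs[[chosen]]$formulations[[1L]]
      dose <- compute_dose(rule, form, weight)
      out[[length(out) + 1L]] <- list(
        drug = chosen, indication = dx$id, severity = dx$severity,
        dose = dose, substituted = !identical(chosen, tr$drug),
        first_line = tr$drug, error = NULL)
    }
  }
  # merge duplicate drugs, keeping the most severe indication
  if (length(out) > 1L) {
    keep <- list()
    for (e in out) {
      prev <- keep[[e$drug]]
      if (is.null(prev) ||
          severity_rank(e$severity) < severity_rank(prev$severity))
        keep[[e$drug]] <- e
    }
    out <- unname(keep)
  }
  state$treatments <- out
  state
}

#' Referral flag of the current proposals
#'
#' `TRUE` when any kept proposed diagnosis (pre-review) carries a management
#' of kind `referral`.
#'
#' @param state A `consultation` after [propose_diagnoses()].
#' @return Logical flag.
#' @export
referral_flag <- function(state) {
  if (is.null(state$proposals)) stopf("propose_diagnoses must run first")
  any(vapply(state$proposals, function(p) {
    kinds <- vapply(state$alg$managements[p$diagnosis$managements],
                    `[[`, character(1), "kind")
    any(kinds == "referral")
  }, logical(1)))
}

#' Finalize a consultation into an immutable export record
#'
#' @param state A `consultation` after [propose_diagnoses()] (and usually
#'   [propose_treatments()]).
#' @return A `consultation_record`: demographics, every answer with its
#'   estimated flag, the emergency log, proposals, review decisions,
#'   treatments, warnings and the algorithm `version_id` (so non-regression
#'   runs can attribute outputs to content versions).
#' @export
finalize_consultation <- function(state) {
  if (is.null(state$proposals))
    stopf("cannot finalize before the diagnosis phase")
  rec <- structure(list(
    algorithm = state$alg$meta$name,
    version_id = state$version_id,
    demographics = state$demographics,
    answers = lapply(state$answered, function(a)
      list(value = a$value, answer = a$answer, estimated = a$estimated,
           order = a$order)),
    emergency_log = state$emergency_log,
    proposed = names(state$proposals),
    explanations = lapply(state$proposals, function(p) p$trace),
    reviewed = state$reviewed,
    treatments = state$treatments,
    referral = referral_flag(state),
    warnings = state$warnings
  ), class = "consultation_record")
  rec
}
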