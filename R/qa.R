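# QA machinery: static lint, exhaustive assignment sweeps, batch corpus
# execution, expectation checks, and non-regression diffing between
# algorithm content versions.

#' Enumerate all complete answer assignments of an algorithm
#'
#' Every node contributes one column of answer ids; rows are the full cross
#' product. Used for exhaustive reachability and severity-first sweeps; the
#' caller is responsible for checking [assignment_space_size()] first.
#'
#' @param alg A `clinical_algorithm`.
#' @return List with `answers` (named list: node id -> character vector, all
#'   the same length) and `n` (number of assignments).
#' @export
enumerate_assignments <- function(alg) {
  domains <- lapply(alg$nodes, answer_ids)
  grid <- expand.grid(domains, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  list(answers = as.list(grid), n = nrow(grid))
}

#' @rdname enumerate_assignments
#' @export
assignment_space_size <- function(alg) {
  prod(vapply(alg$nodes, function(nd) length(nd$answers), numeric(1)))
}

# Apply display gating to complete assignments: walking nodes topologically,
# a node whose display condition evaluates false in a row is gated there and
# its atoms count false downstream.
gating_masks <- function(alg, answers, n) {
  gated <- list()
  ord <- node_order_index(alg)
  for (nd in alg$nodes[ord]) {
    if (is.null(nd$display_condition)) next
    shown <- eval_condition_vec(nd$display_condition, answers, n, gated)
    g <- !(shown %in% TRUE)
    if (any(g)) gated[[nd$id]] <- g
  }
  gated
}

#' Vectorized diagnosis proposal over complete assignments
#'
#' Evaluates every diagnosis condition over all rows, applies display
#' gating and the severity-ordered exclusion pass, and summarizes per row.
#' Semantically identical to running [propose_diagnoses()] on each
#' assignment (the scalar engine is the reference; tests cross-check).
#'
#' @param alg A `clinical_algorithm`.
#' @param answers Named list node id -> character vector of answer ids (all
#'   equal length), e.g. from [enumerate_assignments()].
#' @return List with `kept` (logical matrix rows x diagnoses: proposed after
#'   exclusion), `active` (before exclusion), `top_tier` (character),
#'   `referral` (logical).
#' @export
propose_diagnoses_vec <- function(alg, answers) {
  n <- length(answers[[1L]])
  gated <- gating_masks(alg, answers, n)
  dxs <- alg$diagnoses
  active <- vapply(dxs, function(d)
    eval_condition_vec(d$condition, answers, n, gated) %in% TRUE, logical(n))
  if (n == 1L) active <- matrix(active, nrow = 1L,
                                dimnames = list(NULL, names(dxs)))
  pr <- order(vapply(dxs, function(d) severity_rank(d$severity), numeric(1)),
              seq_along(dxs))
  kept <- active
  suppressed <- matrix(FALSE, n, length(dxs), dimnames = list(NULL, names(dxs)))
  for (i in pr) {
    d <- dxs[[i]]
    kept[, d$id] <- active[, d$id] & !suppressed[, d$id]
    for (e in d$excludes)
      suppressed[, e] <- suppressed[, e] | kept[, d$id]
  }
  tiers <- vapply(dxs, function(d) severity_rank(d$severity), numeric(1))
  rank_mat <- sweep((!kept) * 99, 2L, tiers, `+`) # kept -> its tier rank
  top <- SEVERITY_LEVELS[apply(rank_mat, 1L, min)]
  has_ref <- vapply(dxs, function(d) {
    kinds <- vapply(alg$managements[d$managements], `[[`, character(1), "kind")
    any(kinds == "referral")
  }, logical(1))
  referral <- as.logical(kept %*% has_ref > 0)
  list(kept = kept, active = active, top_tier = top, referral = referral)
}

#' Static lint of clinical content
#'
#' Aggregates every automated static check into one deterministic finding
#' list: the structural validation of [validate_algorithm()] (cycles,
#' dangling references, interval gaps/overlaps, missing referral
#' managements, dosing-rule bounds), diagnosis reachability, and the full
#' posology sweep of [verify_posology()]. Reachability is decided *exactly*
#' by exhaustive enumeration of all answer assignments when the assignment
#' space is at most `max_enumeration` rows; beyond that a per-atom
#' heuristic is used and an explicit warning finding is emitted.
#'
#' @param alg A `clinical_algorithm` (parsed, not necessarily valid).
#' @param check_posology Run the dosing sweep (on its default grids).
#' @param max_enumeration Exhaustive-reachability size bound.
#' @return Data frame of findings: `severity`, `code`, `subject`, `message`.
#' @export
lint_algorithm <- function(alg, check_posology = TRUE,
                           max_enumeration = 2^20) {
  findings <- validate_algorithm(alg)
  structural_error <- any(findings$code %in%
                            c("cycle", "dangling_reference",
                              "malformed_condition", "duplicate_id"))
  # reachability: skip diagnoses whose conditions dangle; skip entirely on a
  # cyclic dependency graph (gating order undefined)
  if (!any(findings$code == "cycle")) {
    dangling_ok <- vapply(alg$diagnoses, function(d) {
      at <- condition_atoms(d$condition)
      all(at$node %in% names(alg$nodes))
    }, logical(1))
    size <- assignment_space_size(alg)
    if (size <= max_enumeration) {
      en <- enumerate_assignments(alg)
      gated <- gating_masks(alg, en$answers, en$n)
      for (d in alg$diagnoses[dangling_ok]) {
        sat <- eval_condition_vec(d$condition, en$answers, en$n, gated)
        if (!any(sat %in% TRUE))
          findings <- rbind(findings, data.frame(
            severity = "error", code = "unreachable_diagnosis",
            subject = d$id,
            message = sprintf("no answer assignment satisfies the condition of '%s'",
                              d$id), stringsAsFactors = FALSE))
      }
    } else {
      findings <- rbind(findings, data.frame(
        severity = "warning", code = "reachability_heuristic",
        subject = alg$meta$name,
        message = sprintf("assignment space %g exceeds %g: reachability checked per-atom only",
                          size, max_enumeration), stringsAsFactors = FALSE))
      for (d in alg$diagnoses[dangling_ok]) {
        at <- condition_atoms(d$condition)
        ok <- mapply(function(nid, aid) aid %in% answer_ids(alg$nodes[[nid]]),
                     at$node, at$answer)
        if (length(ok) && !any(ok))
          findings <- rbind(findings, data.frame(
            severity = "error", code = "unreachable_diagnosis", subject = d$id,
            message = sprintf("'%s': no referenced atom can ever hold", d$id),
            stringsAsFactors = FALSE))
      }
    }
  }
  if (check_posology && !structural_error) {
    pos <- verify_posology(alg)
    if (nrow(pos))
      findings <- rbind(findings, data.frame(
        severity = "error", code = pos$code,
        subject = ifelse(is.na(pos$rule_id), pos$drug, pos$rule_id),
        message = pos$message, stringsAsFactors = FALSE))
  }
  findings[order(findings$code, findings$subject, findings$message), ,
           drop = FALSE] |> `rownames<-`(NULL)
}

#' Replay one patient case through the consultation engine
#'
#' Starts a consultation, repeatedly answers the next askable items from the
#' case's answer map (in engine order, or in a randomized order to exercise
#' order-invariance) and runs the diagnosis proposal.
#'
#' @param alg A validated `clinical_algorithm`.
#' @param case A patient case (see [generate_cases()]).
#' @param shuffle Answer askable items in random order instead of engine
#'   order (uses the current RNG stream).
#' @return The consultation state after [propose_diagnoses()].
#' @export
replay_case <- function(alg, case, shuffle = FALSE) {
  st <- start_consultation(alg, list(age_days = case$age_days,
                                     weight_kg = case$weight_kg,
                                     sex = case$sex))
  repeat {
    items <- next_items(st)
    if (!length(items)) break
    nd <- if (shuffle) items[[sample.int(length(items), 1L)]] else items[[1L]]
    if (!nd$id %in% names(case$answers))
      stopf("case %s has no answer for askable node '%s'",
            case$case_id %||% "?", nd$id)
    est <- nd$estimable && isTRUE(unname(case$estimated[nd$id]))
    # nd came from next_items, so the askability pre-check can be skipped
    st <- store_answer(st, nd, case$answers[[nd$id]], estimated = est)
  }
  propose_diagnoses(st)
}

#' Run a case corpus through an algorithm
#'
#' Batch replay: each case is executed independently; failures are recorded
#' per row and the run continues. The output is a deterministic function of
#' the inputs (identical reruns are identical).
#'
#' @param alg A validated `clinical_algorithm`.
#' @param cases List of patient cases.
#' @param stockout Drug ids unavailable for treatment proposal.
#' @return Data frame, one row per case: `case_id`, `label`, `diagnoses`,
#'   `treatments` (comma-joined, proposal order), `referral`, `n_warnings`,
#'   `items_asked`, `error` (`NA` when clean).
#' @export
run_corpus <- function(alg, cases, stockout = character()) {
  rows <- lapply(cases, function(cs) {
    res <- tryCatch({
      st <- replay_case(alg, cs)
      st <- propose_treatments(st, stockout = stockout)
      data.frame(
        case_id = cs$case_id %||% NA_character_,
        label = cs$label %||% NA_character_,
        diagnoses = paste(names(st$proposals), collapse = ","),
        treatments = paste(vapply(st$treatments, `[[`, character(1), "drug"),
                           collapse = ","),
        referral = referral_flag(st),
        n_warnings = length(st$warnings),
        items_asked = length(st$answered),
        error = NA_character_,
        stringsAsFactors = FALSE)
    }, error = function(e) data.frame(
      case_id = cs$case_id %||% NA_character_,
      label = cs$label %||% NA_character_,
      diagnoses = "", treatments = "", referral = NA,
      n_warnings = NA_integer_, items_asked = NA_integer_,
      error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Non-regression diff between two algorithm versions
#'
#' Replays the same corpus through both versions and diffs the clinical
#' outputs per case: items asked, proposed diagnoses, treatments and the
#' referral flag. An empty diff certifies that the content change did not
#' alter any output on the corpus; a threshold change must produce diffs
#' only in the cases whose inputs cross it.
#'
#' @param alg_old,alg_new Validated algorithms sharing the corpus age range.
#' @param cases List of patient cases.
#' @param stockout Drug ids unavailable in both runs.
#' @return Object of class `regression_diff`: `per_case` data frame
#'   (`case_id`, `items_delta`, `diagnoses_delta`, `treatments_delta`,
#'   `referral_delta`, `changed`), `summary` named counts, `n_changed`,
#'   `empty` flag.
#' @export
non_regression <- function(alg_old, alg_new, cases, stockout = character()) {
  old <- run_corpus(alg_old, cases, stockout)
  new <- run_corpus(alg_new, cases, stockout)
  setdiff2 <- function(a, b) {
    a <- strsplit(a, ",", fixed = TRUE)[[1L]]
    b <- strsplit(b, ",", fixed = TRUE)[[1L]]
    added <- setdiff(b, a); removed <- setdiff(a, b)
    paste(c(sprintf("+%s", added), sprintf("-%s", removed)), collapse = " ")
  }
  per_case <- data.frame(
    case_id = old$case_id,
    items_delta = new$items_asked - old$items_asked,
    diagnoses_delta = mapply(setdiff2, old$diagnoses, new$diagnoses,
                             USE.NAMES = FALSE),
    treatments_delta = mapply(setdiff2, old$treatments, new$treatments,
                              USE.NAMES = FALSE),
    referral_delta = new$referral != old$referral,
    stringsAsFactors = FALSE)
  per_case$changed <- per_case$items_delta != 0 |
    per_case$diagnoses_delta != "" | per_case$treatments_delta != "" |
    per_case$referral_delta %in% TRUE
  summary <- c(items = sum(per_case$items_delta != 0),
               diagnoses = sum(per_case$diagnoses_delta != ""),
               treatments = sum(per_case$treatments_delta != ""),
               referral = sum(per_case$referral_delta %in% TRUE))
  structure(list(per_case = per_case, summary = summary,
                 n_changed = sum(per_case$changed),
                 empty = !any(per_case$changed),
                 version_old = alg_old$meta$version_id,
                 version_new = alg_new$meta$version_id),
            class = "regression_diff")
}

#' @export
print.regression_diff <- function(x, ...) {
  cat(sprintf("<regression_diff> %s -> %s: %d of %d case(s) changed\n",
              x$version_old, x$version_new, x$n_changed, nrow(x$per_case)))
  if (!x$empty)
    cat(sprintf("  deltas: %s\n",
                paste(sprintf("%s=%d", names(x$summary), x$summary),
                      collapse = ", ")))
  invisible(x)
}

#' Expectation-based unit check of algorithm content
#'
#' Fictional cases with known intended outputs: each expectation names a
#' case and the diagnosis ids, referral flag and (optionally) drug ids the
#' algorithm must produce for it. Outputs are compared pre-review.
#'
#' @param alg A validated `clinical_algorithm`.
#' @param cases List of patient cases (ids must cover the expectations).
#' @param expectations List of `list(case_id =, diagnoses =, referral =,
#'   drugs = NULL)` entries.
#' @return Data frame: `case_id`, `pass`, `expected`, `actual`, `detail`.
#' @export
unit_check <- function(alg, cases, expectations) {
  ids <- vapply(cases, function(cs) cs$case_id %||% NA_character_, character(1))
  out <- run_corpus(alg, cases)
  rows <- lapply(expectations, function(ex) {
    i <- match(ex$case_id, ids)
    if (is.na(i))
      return(data.frame(case_id = ex$case_id, pass = FALSE,
                        expected = "", actual = "",
                        detail = "case not found in corpus",
                        stringsAsFactors = FALSE))
    got_dx <- sort(strsplit(out$diagnoses[i], ",", fixed = TRUE)[[1L]])
    want_dx <- sort(as_chr(ex$diagnoses))
    ok <- identical(got_dx, want_dx) &&
      identical(out$referral[i], isTRUE(ex$referral))
    detail <- character(0)
    if (!identical(got_dx, want_dx)) detail <- c(detail, "diagnoses differ")
    if (!identical(out$referral[i], isTRUE(ex$referral)))
      detail <- c(detail, "referral flag differs")
    if (!is.null(ex$drugs)) {
      got_tr <- sort(strsplit(out$treatments[i], ",", fixed = TRUE)[[1L]])
      if (!identical(got_tr, sort(as_chr(ex$drugs)))) {
        ok <- FALSE
        detail <- c(detail, "treatments differ")
      }
    }
    data.frame(case_id = ex$case_id, pass = ok,
               expected = paste(want_dx, collapse = ","),
               actual = out$diagnoses[i],
               detail = paste(detail, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
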