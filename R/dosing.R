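#' Select the dosing rule applicable to a patient
#'
#' Finds the unique rule for (drug, indication) whose age x weight band
#' contains the patient, under the half-open `[lo, hi)` band convention (a
#' patient exactly on a boundary belongs to the upper band).
#'
#' @param drug Drug id.
#' @param indication Diagnosis id.
#' @param age_days Patient age in days.
#' @param weight_kg Patient weight in kg.
#' @param rules List of [dosing_rule()] objects (e.g. `alg$dosing_rules`).
#' @return The matching `tt_dosing_rule`.
#' @export
select_rule <- function(drug, indication, age_days, weight_kg, rules) {
  hits <- Filter(function(r)
    r$drug == drug && r$indication == indication &&
      in_band(age_days, r$age_lo, r$age_hi) &&
      in_band(weight_kg, r$weight_lo, r$weight_hi),
    rules)
  if (length(hits) == 0L)
    stopf("coverage gap: no dosing band for drug '%s' (%s) at age %g d, weight %g kg",
          drug, indication, age_days, weight_kg)
  if (length(hits) > 1L)
    stopf("band overlap: rules %s all cover drug '%s' (%s) at age %g d, weight %g kg",
          paste(vapply(hits, `[[`, character(1), "id"), collapse = ", "),
          drug, indication, age_days, weight_kg)
  hits[[1L]]
}

#' Compute a practical dispensable dose
#'
#' The ideal dose is `target` mg/kg times the weight; the dispensed quantity
#' is the multiple of the formulation's smallest dispensable increment whose
#' achieved mg/kg is closest to the target, restricted to candidates whose
#' achieved dose lies inside the tolerated `[min, max]` mg/kg interval and
#' whose total mg does not exceed the absolute per-dose maximum. Ties break
#' deterministically toward the lower quantity (never silently overdose).
#'
#' @param rule A `tt_dosing_rule` applicable to this weight.
#' @param formulation A `tt_formulation` of the rule's drug.
#' @param weight_kg Patient weight in kg.
#' @return A `tt_dose_result`: `quantity` (dispensing units, a multiple of
#'   the increment), `increments` (count of increments), `mg` (total mg),
#'   `mg_per_kg` (achieved), `within_bounds`, `rule_id`, `form`, and a
#'   human `rendering` (tablets in halves, liquids in ml to one decimal).
#' @export
compute_dose <- function(rule, formulation, weight_kg) {
  stopifnot(weight_kg > 0)
  step_mg <- formulation$increment * formulation$strength
  k_max <- floor(rule$abs_max / step_mg + 1e-9)
  if (k_max < 1L)
    stopf("formulation unusable: one increment of %s already exceeds the absolute max %g mg",
          formulation$form, rule$abs_max)
  k <- seq_len(k_max)
  mg <- k * step_mg
  mgkg <- mg / weight_kg
  ok <- mgkg >= rule$min & mgkg <= rule$max
  if (!any(ok))
    stopf("formulation unusable at %g kg: no dispensable quantity achieves %g-%g mg/kg (rule '%s')",
          weight_kg, rule$min, rule$max, rule$id)
  cand <- k[ok]
  err <- abs(mgkg[ok] - rule$target)
  # closest to target; tie toward the lower quantity (cand is increasing)
  best <- cand[which.min(err)]
  quantity <- best * formulation$increment
  tablets <- formulation$form %in% c("tablet", "dispersible_tablet")
  structure(list(
    quantity = quantity,
    increments = best,
    mg = best * step_mg,
    mg_per_kg = best * step_mg / weight_kg,
    within_bounds = TRUE,
    rule_id = rule$id,
    form = formulation$form,
    rendering = if (tablets) sprintf("%g tablet(s)", quantity)
                else sprintf("%.1f ml", quantity)
  ), class = "tt_dose_result")
}

#' Verify a whole posology table across the weight/age grid
#'
#' Automates table-wide dose verification: for every (drug, indication)
#' pair used by any diagnosis treatment (first-line and alternatives), every
#' formulation and every grid point, checks that exactly one band applies
#' (otherwise a coverage gap / band overlap finding) and that a practical
#' in-bounds dose exists (otherwise a dose finding naming the rule). An
#' empty report means the table is verified.
#'
#' @param alg A `clinical_algorithm`.
#' @param weight_grid Numeric vector of weights (kg); default 2.0-25.0 kg in
#'   0.1 kg steps.
#' @param age_grid Numeric vector of ages (days); default 0-15 years in
#'   30-day steps.
#' @return Data frame of findings: `code` (`band_gap`, `band_overlap`,
#'   `dose_out_of_bounds`), `drug`, `indication`, `rule_id`, `weight`,
#'   `age`, `message`. Zero rows iff verified.
#' @export
verify_posology <- function(alg,
                            weight_grid = seq(2, 25, by = 0.1),
                            age_grid = seq(0, 15 * 365 - 1, by = 30)) {
  weight_grid <- round(weight_grid, 6)
  f <- list()
  add <- function(code, drug, indication, rule_id, weight, age, message) {
    f[[length(f) + 1L]] <<- data.frame(code = code, drug = drug,
                                       indication = indication,
                                       rule_id = rule_id, weight = weight,
                                       age = age, message = message,
                                       stringsAsFactors = FALSE)
  }
  pairs <- list()
  for (dx in alg$diagnoses) for (tr in dx$treatments) {
    ind <- tr$rule %||% dx$id
    for (d in c(tr$drug, tr$alternatives)) pairs[[paste(d, ind)]] <- c(d, ind)
  }
  for (p in pairs) {
    d <- p[1L]; ind <- p[2L]
    rules <- Filter(function(r) r$drug == d && r$indication == ind,
                    alg$dosing_rules)
    # coverage: count bands over the age x weight grid
    nmatch <- matrix(0L, length(age_grid), length(weight_grid))
    for (r in rules) {
      ain <- in_band(age_grid, r$age_lo, r$age_hi)
      win <- in_band(weight_grid, r$weight_lo, r$weight_hi)
      nmatch <- nmatch + outer(ain, win)
    }
    if (any(nmatch == 0L)) {
      idx <- which(nmatch == 0L, arr.ind = TRUE)[1L, ]
      ws <- weight_grid[sort(unique(which(nmatch == 0L, arr.ind = TRUE)[, 2L]))]
      add("band_gap", d, ind, NA_character_, ws[1L], age_grid[idx[1L]],
          sprintf("no dosing band covers weights %g-%g kg at age %g d (drug %s, %s)",
                  min(ws), max(ws), age_grid[idx[1L]], d, ind))
    }
    if (any(nmatch > 1L)) {
      idx <- which(nmatch > 1L, arr.ind = TRUE)[1L, ]
      add("band_overlap", d, ind, NA_character_, weight_grid[idx[2L]],
          age_grid[idx[1L]],
          sprintf("multiple dosing bands cover age %g d, weight %g kg (drug %s, %s)",
                  age_grid[idx[1L]], weight_grid[idx[2L]], d, ind))
    }
    # dose attainability: per rule, vectorized over the weights in its band
    forms <- alg$drugs[[d]]$formulations
    if (is.null(forms)) next
    for (r in rules) for (fo in forms) {
      ws <- weight_grid[in_band(weight_grid, r$weight_lo, r$weight_hi)]
      if (!length(ws)) next
      step_mg <- fo$increment * fo$strength
      k_max <- floor(r$abs_max / step_mg + 1e-9)
      if (k_max < 1L) {
        add("dose_out_of_bounds", d, ind, r$id, ws[1L], r$age_lo,
            sprintf("rule '%s': one %s increment exceeds abs max", r$id, fo$form))
        next
      }
      mg <- seq_len(k_max) * step_mg
      # weight x candidate matrix of achieved mg/kg
      mgkg <- outer(1 / ws, mg)
      attainable <- apply(mgkg >= r$min & mgkg <= r$max, 1L, any)
      if (!all(attainable)) {
        bad <- ws[!attainable]
        add("dose_out_of_bounds", d, ind, r$id, bad[1L], r$age_lo,
            sprintf("rule '%s' (%s): no in-bounds dose at %d weight(s), e.g. %g kg",
                    r$id, fo$form, length(bad), bad[1L]))
      }
    }
  }
  if (length(f) == 0L)
    return(data.frame(code = character(), drug = character(),
                      indication = character(), rule_id = character(),
                      weight = numeric(), age = numeric(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, f)
  out[order(out$code, out$drug, out$indication), , drop = FALSE] |>
    `rownames<-`(NULL)
}
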