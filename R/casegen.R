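#' Define a condition generative profile
#'
#' A profile describes how synthetic patients with one underlying condition
#' present: a Bernoulli probability for each boolean sign and a distribution
#' for each numeric measurement. Numeric draws are truncated to the node's
#' admissible range.
#'
#' @param label Gold condition label.
#' @param weight Prevalence weight (profile weights are normalized to sum
#'   to 1 across a profile set).
#' @param booleans Named numeric vector node id -> P(present).
#' @param numeric Named list node id -> distribution spec, one of
#'   `list(dist = "truncnorm", mean =, sd =)`,
#'   `list(dist = "lognormal", meanlog =, sdlog =)`,
#'   `list(dist = "normal_by_age", means = c(age_band_answer = mean, ...), sd =)`.
#' @return A `condition_profile` object.
#' @export
condition_profile <- function(label, weight, booleans, numeric) {
  stopifnot(weight > 0, all(booleans >= 0 & booleans <= 1))
  structure(list(label = label, weight = weight, booleans = booleans,
                 numeric = numeric),
            class = "condition_profile")
}

#' Default generative profiles for the demo algorithm
#'
#' Six conditions — well child, viral URTI, pneumonia-like illness, febrile
#' illness with bacterial indication (severe presentation), acute
#' malnutrition, hypoxaemic illness — with prevalences skewed toward
#' non-severe presentations, emulating an outpatient population in which few
#' non-severe children have a condition requiring antibiotics. All values
#' are demo content.
#'
#' @return Named list of [condition_profile()] objects (weights sum to 1).
#' @export
default_condition_profiles <- function() {
  rr <- function(m1, m2, m3, m4, sd)
    list(dist = "normal_by_age",
         means = c(age_0_2m = m1, age_2_12m = m2, age_1_5y = m3,
                   age_5y_plus = m4), sd = sd)
  profs <- list(
    condition_profile("well_child", 0.50,
      booleans = c(comorbidity = 0.05, convulsions = 0.002,
                   unable_to_drink = 0.002, vomits_everything = 0.002,
                   lethargic = 0.002, fever = 0.05, cough = 0.10,
                   chest_indrawing = 0.01),
      numeric = list(
        muac = list(dist = "truncnorm", mean = 14.5, sd = 1.2),
        spo2 = list(dist = "truncnorm", mean = 96.5, sd = 1.2),
        resp_rate = rr(42, 36, 28, 22, 5),
        crp = list(dist = "lognormal", meanlog = log(3), sdlog = 0.8))),
    condition_profile("viral_urti", 0.25,
      booleans = c(comorbidity = 0.05, convulsions = 0.005,
                   unable_to_drink = 0.005, vomits_everything = 0.01,
                   lethargic = 0.005, fever = 0.90, cough = 0.80,
                   chest_indrawing = 0.03),
      numeric = list(
        muac = list(dist = "truncnorm", mean = 14.5, sd = 1.2),
        spo2 = list(dist = "truncnorm", mean = 96, sd = 1.4),
        resp_rate = rr(46, 38, 30, 24, 5),
        crp = list(dist = "lognormal", meanlog = log(8), sdlog = 0.7))),
    condition_profile("pneumonia", 0.10,
      booleans = c(comorbidity = 0.08, convulsions = 0.01,
                   unable_to_drink = 0.02, vomits_everything = 0.02,
                   lethargic = 0.01, fever = 0.85, cough = 0.98,
                   chest_indrawing = 0.45),
      numeric = list(
        muac = list(dist = "truncnorm", mean = 14.0, sd = 1.3),
        spo2 = list(dist = "truncnorm", mean = 93, sd = 2.2),
        resp_rate = rr(62, 56, 47, 37, 5),
        crp = list(dist = "lognormal", meanlog = log(35), sdlog = 0.6))),
    condition_profile("severe_febrile", 0.05,
      booleans = c(comorbidity = 0.12, convulsions = 0.25,
                   unable_to_drink = 0.40, vomits_everything = 0.35,
                   lethargic = 0.30, fever = 0.95, cough = 0.40,
                   chest_indrawing = 0.35),
      numeric = list(
        muac = list(dist = "truncnorm", mean = 13.5, sd = 1.5),
        spo2 = list(dist = "truncnorm", mean = 93, sd = 2.8),
        resp_rate = rr(58, 52, 44, 34, 6),
        crp = list(dist = "lognormal", meanlog = log(60), sdlog = 0.7))),
    condition_profile("malnutrition", 0.07,
      booleans = c(comorbidity = 0.15, convulsions = 0.005,
                   unable_to_drink = 0.02, vomits_everything = 0.01,
                   lethargic = 0.01, fever = 0.20, cough = 0.15,
                   chest_indrawing = 0.02),
      numeric = list(
        muac = list(dist = "truncnorm", mean = 11.8, sd = 0.8),
        spo2 = list(dist = "truncnorm", mean = 96, sd = 1.4),
        resp_rate = rr(44, 38, 30, 24, 5),
        crp = list(dist = "lognormal", meanlog = log(6), sdlog = 0.7))),
    condition_profile("hypoxaemic", 0.03,
      booleans = c(comorbidity = 0.10, convulsions = 0.05,
                   unable_to_drink = 0.08, vomits_everything = 0.05,
                   lethargic = 0.08, fever = 0.60, cough = 0.70,
                   chest_indrawing = 0.50),
      numeric = list(
        muac = list(dist = "truncnorm", mean = 14.0, sd = 1.3),
        spo2 = list(dist = "truncnorm", mean = 86, sd = 2.5),
        resp_rate = rr(60, 54, 45, 35, 6),
        crp = list(dist = "lognormal", meanlog = log(20), sdlog = 0.7)))
  )
  names(profs) <- vapply(profs, `[[`, character(1), "label")
  profs
}

# inverse-cdf draw from a normal truncated to [lo, hi)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  u <- runif(n, plnorm(max(lo, 0), meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  qlnorm(u, meanlog, sdlog)
}

#' @importFrom stats plnorm pnorm qlnorm dnorm
NULL

draw_numeric <- function(spec, nd, age_band) {
  lo <- nd$range[1L]; hi <- nd$range[2L]
  eps <- (hi - lo) * 1e-9 # keep draws strictly inside the half-open range
  v <- switch(spec$dist,
    truncnorm = rtrunc_norm(1L, spec$mean, spec$sd, lo, hi - eps),
    lognormal = rtrunc_lnorm(1L, spec$meanlog, spec$sdlog, lo, hi - eps),
    normal_by_age = rtrunc_norm(1L, spec$means[[age_band]], spec$sd, lo, hi - eps),
    stopf("unknown distribution '%s'", spec$dist))
  v
}

#' Generate labelled synthetic patient cases
#'
#' Each case samples a gold condition by prevalence weight and draws every
#' predictor from that condition's generative spec; demographics are drawn
#' from a simple pediatric age/weight model. Fully reproducible under the
#' same seed.
#'
#' @param profiles Named list of [condition_profile()]s (defaults to
#'   [default_condition_profiles()]).
#' @param n Number of cases.
#' @param seed Integer RNG seed.
#' @param alg The algorithm the cases target (defines admissible ranges);
#'   defaults to the demo fixture.
#' @param age_range_days Age sampling range, uniform, half-open.
#' @param p_estimated Probability that an estimable measurement is flagged
#'   as estimated rather than measured.
#' @return List of `patient_case` objects: `case_id`, `age_days`, `sex`,
#'   `weight_kg`, `answers` (named list: logical for boolean nodes, numbers
#'   for numeric ones), `estimated` (named logical), `label`.
#' @export
generate_cases <- function(profiles = default_condition_profiles(), n,
                           seed = 1L, alg = build_fixture_algorithm(),
                           age_range_days = c(60, 1825),
                           p_estimated = 0.1) {
  stopifnot(n > 0)
  w <- vapply(profiles, `[[`, numeric(1), "weight")
  if (any(w <= 0)) stopf("prevalence weights must be positive")
  w <- w / sum(w)
  for (p in profiles) {
    for (nid in names(p$booleans))
      if (is.null(alg$nodes[[nid]])) stopf("profile '%s': unknown node '%s'",
                                           p$label, nid)
    for (nid in names(p$numeric))
      if (is.null(alg$nodes[[nid]]) ||
          alg$nodes[[nid]]$answer_domain != "numeric")
        stopf("profile '%s': '%s' is not a numeric node", p$label, nid)
  }
  age_node <- Filter(function(nd) identical(nd$derived_from, "age_days"),
                     alg$nodes)
  set.seed(seed)
  labels <- sample(names(profiles), n, replace = TRUE, prob = w)
  estimable <- names(Filter(function(nd) nd$estimable, alg$nodes))
  lapply(seq_len(n), function(i) {
    p <- profiles[[labels[i]]]
    age <- floor(runif(1L, age_range_days[1L], age_range_days[2L]))
    weight <- round(min(29.5, max(2.5, 3.3 + 2.2 * age / 365.25 +
                                    rnorm(1L, 0, 1.2))), 1)
    band <- if (length(age_node))
      categorize_value(age_node[[1L]], age) else NA_character_
    ans <- list()
    for (nid in names(p$booleans))
      ans[[nid]] <- runif(1L) < p$booleans[[nid]]
    for (nid in names(p$numeric)) {
      v <- round(draw_numeric(p$numeric[[nid]], alg$nodes[[nid]], band), 1)
      rg <- alg$nodes[[nid]]$range
      # rounding to 0.1 must not push a draw onto the excluded upper bound
      ans[[nid]] <- max(rg[1L], min(v, rg[2L] - 0.1))
    }
    est <- setNames(runif(length(estimable)) < p_estimated, estimable)
    est <- est & estimable %in% names(ans)
    structure(list(case_id = sprintf("case-%06d", i),
                   age_days = age, sex = sample(c("f", "m"), 1L),
                   weight_kg = weight, answers = ans,
                   estimated = est, label = labels[i]),
              class = "patient_case")
  })
}

#' Expected post-truncation means of a profile's numeric predictors
#'
#' Closed-form means of the truncated sampling distributions used by
#' [generate_cases()] — the analytic reference for generator-fidelity
#' checks. For `normal_by_age` specs one mean per age band is returned.
#'
#' @param profile A [condition_profile()].
#' @param alg Algorithm defining the admissible ranges.
#' @return Named list node id -> expected mean (scalar, or named vector per
#'   age band).
#' @export
expected_numeric_means <- function(profile, alg = build_fixture_algorithm()) {
  tn_mean <- function(mean, sd, lo, hi) {
    a <- (lo - mean) / sd; b <- (hi - mean) / sd
    mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  tln_mean <- function(meanlog, sdlog, lo, hi) {
    lo <- max(lo, .Machine$double.xmin)
    a <- (log(lo) - meanlog) / sdlog; b <- (log(hi) - meanlog) / sdlog
    exp(meanlog + sdlog^2 / 2) *
      (pnorm(b - sdlog) - pnorm(a - sdlog)) / (pnorm(b) - pnorm(a))
  }
  out <- list()
  for (nid in names(profile$numeric)) {
    spec <- profile$numeric[[nid]]
    rg <- alg$nodes[[nid]]$range
    out[[nid]] <- switch(spec$dist,
      truncnorm = tn_mean(spec$mean, spec$sd, rg[1L], rg[2L]),
      lognormal = tln_mean(spec$meanlog, spec$sdlog, rg[1L], rg[2L]),
      normal_by_age = vapply(spec$means, tn_mean, numeric(1),
                             sd = spec$sd, lo = rg[1L], hi = rg[2L]))
  }
  out
}

#' Inject a single content defect into an algorithm
#'
#' Returns a minimally modified copy exhibiting exactly the requested defect
#' class, for exercising the QA machinery. The result deliberately violates
#' an invariant, so it bypasses [build_algorithm()] validation; feed it to
#' [lint_algorithm()] or [verify_posology()].
#'
#' @param alg A `clinical_algorithm` (typically the demo fixture).
#' @param defect One of `cycle`, `dangling_reference`, `interval_gap`,
#'   `interval_overlap`, `unreachable_diagnosis`, `dose_out_of_bounds`,
#'   `band_gap`.
#' @param target Optional id of the entity to corrupt; defaults to a
#'   fixture-appropriate choice per class.
#' @return The defective `clinical_algorithm` variant.
#' @export
corrupt_algorithm <- function(alg,
                              defect = c("cycle", "dangling_reference",
                                         "interval_gap", "interval_overlap",
                                         "unreachable_diagnosis",
                                         "dose_out_of_bounds", "band_gap"),
                              target = NULL) {
  defect <- match.arg(defect)
  pick_numeric <- function() {
    target %||% names(Filter(function(nd)
      nd$answer_domain == "numeric" && is.null(nd$derived_from) &&
        length(nd$answers) >= 2L, alg$nodes))[1L]
  }
  switch(defect,
    cycle = {
      ids <- target %||% head(names(Filter(function(nd)
        nd$answer_domain == "boolean" && is.null(nd$display_condition),
        alg$nodes)), 2L)
      if (length(ids) < 2L) stopf("cycle defect needs two boolean nodes")
      alg$nodes[[ids[1L]]]$display_condition <- cnd_atom(ids[2L], "present")
      alg$nodes[[ids[2L]]]$display_condition <- cnd_atom(ids[1L], "present")
    },
    dangling_reference = {
      # default to a branch whose nodes carry no referral-triggering flag, so
      # the corruption breaks exactly one invariant
      id <- target %||% (if ("bacterial_fever" %in% names(alg$diagnoses))
        "bacterial_fever" else names(alg$diagnoses)[
          vapply(alg$diagnoses, function(d) d$condition$op != "true",
                 logical(1))][1L])
      alg$diagnoses[[id]]$condition <- cnd_atom("ghost_node", "present")
    },
    interval_gap = {
      id <- pick_numeric()
      nd <- alg$nodes[[id]]
      top <- length(nd$answers)
      mid <- (nd$answers[[top]]$lo + nd$answers[[top]]$hi) / 2
      alg$nodes[[id]]$answers[[top]]$lo <- mid # opens a gap below it
    },
    interval_overlap = {
      id <- pick_numeric()
      nd <- alg$nodes[[id]]
      mid <- (nd$answers[[1L]]$lo + nd$answers[[1L]]$hi) / 2
      alg$nodes[[id]]$answers[[2L]]$lo <- mid # overlaps answer 1's top half
    },
    unreachable_diagnosis = {
      id <- target %||% "uncomplicated_fever"
      dx <- alg$diagnoses[[id]]
      if (is.null(dx)) stopf("unknown diagnosis '%s'", id)
      at <- condition_atoms(dx$condition)
      nd <- alg$nodes[[at$node[1L]]]
      aids <- answer_ids(nd)
      # contradiction: the same node must hold two different answers at once
      alg$diagnoses[[id]]$condition <- cnd_and(cnd_atom(nd$id, aids[1L]),
                                               cnd_atom(nd$id, aids[2L]))
    },
    dose_out_of_bounds = {
      id <- target %||% "para_fever"
      r <- alg$dosing_rules[[id]]
      if (is.null(r)) stopf("unknown dosing rule '%s'", id)
      # shrink the tolerated interval around the target so tightly that no
      # dispensable increment can land inside it at most weights
      alg$dosing_rules[[id]]$min <- r$target * 0.999
      alg$dosing_rules[[id]]$max <- r$target * 1.001
    },
    band_gap = {
      id <- target %||% "amox_pneu_lo"
      if (is.null(alg$dosing_rules[[id]])) stopf("unknown dosing rule '%s'", id)
      alg$dosing_rules[[id]] <- NULL
    })
  alg
}

#' Write / read a line-delimited case corpus
#'
#' One case per line, JSON-encoded, the batch interchange format for
#' [run_corpus()] and the command-line tools.
#'
#' @param cases List of patient cases.
#' @param path File path.
#' @return `read_cases` returns the list of cases; `write_cases` the path,
#'   invisibly.
#' @export
write_cases <- function(cases, path) {
  lines <- vapply(cases, function(cs) {
    cs <- unclass(cs)
    cs$estimated <- as.list(cs$estimated) # named object, not a bare array
    as.character(jsonlite::toJSON(cs, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  lapply(readLines(path), function(l) {
    cs <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    cs$age_days <- as.numeric(cs$age_days)
    cs$weight_kg <- as.numeric(cs$weight_kg)
    cs$answers <- lapply(cs$answers, function(v)
      if (is.logical(v)) v else as.numeric(v))
    est <- vapply(cs$estimated, isTRUE, logical(1))
    cs$estimated <- setNames(est, names(cs$estimated))
    structure(cs, class = "patient_case")
  })
}
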