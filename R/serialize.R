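FORMAT_VERSION <- 1L

# ---- condition <-> document -------------------------------------------------

condition_to_doc <- function(cond) {
  if (is.null(cond)) return(NULL)
  switch(cond$op,
    true = list(op = "true"),
    atom = list(op = "atom", node = cond$node, answer = cond$answer),
    at_least = list(op = "at_least", k = as.numeric(cond$k),
                    args = lapply(cond$args, condition_to_doc)),
    list(op = cond$op, args = lapply(cond$args, condition_to_doc))
  )
}

condition_from_doc <- function(doc) {
  if (is.null(doc)) return(NULL)
  switch(doc$op,
    true = cnd_true(),
    atom = cnd_atom(as.character(doc$node), as.character(doc$answer)),
    at_least = do.call(cnd_at_least,
                       c(list(k = as.numeric(doc$k)),
                         lapply(doc$args, condition_from_doc))),
    and = do.call(cnd_and, lapply(doc$args, condition_from_doc)),
    or = do.call(cnd_or, lapply(doc$args, condition_from_doc)),
    not = cnd_not(condition_from_doc(doc$args[[1L]])),
    stopf("unknown condition op '%s' in document", doc$op)
  )
}

# ---- algorithm <-> document -------------------------------------------------
#
# The document is the canonical plain-list form: fixed key order, registries
# as arrays in authoring order, every optional field emitted explicitly (or
# dropped when NULL/empty in a fixed way), all numbers doubles. Both dialects
# (YAML authoring, JSON exchange) render this same structure, so two
# serializations of equal algorithms are byte-identical.

#' Canonical plain-list document form of an algorithm
#'
#' @param alg A `clinical_algorithm`.
#' @return A nested plain list, suitable for YAML/JSON rendering; the inverse
#'   is [from_document()].
#' @export
as_document <- function(alg) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  node_doc <- function(nd) drop_null(list(
    id = nd$id, stage = nd$stage, kind = nd$kind, label = nd$label,
    answer_domain = nd$answer_domain,
    unit = nd$unit,
    range = if (!is.null(nd$range)) as.list(as.numeric(nd$range)),
    answers = lapply(nd$answers, function(a) drop_null(list(
      id = a$id, label = a$label, lo = a$lo, hi = a$hi))),
    display_condition = condition_to_doc(nd$display_condition),
    referral_triggering = nd$referral_triggering,
    estimable = nd$estimable,
    emergency_relevant = nd$emergency_relevant,
    derived_from = nd$derived_from,
    help = nd$help))
  dx_doc <- function(dx) list(
    id = dx$id, label = dx$label, severity = dx$severity,
    condition = condition_to_doc(dx$condition),
    managements = as.list(dx$managements),
    treatments = lapply(dx$treatments, function(tr) drop_null(list(
      drug = tr$drug, alternatives = as.list(tr$alternatives),
      rule = tr$rule))),
    excludes = as.list(dx$excludes))
  list(
    format_version = as.numeric(FORMAT_VERSION),
    meta = list(name = alg$meta$name, country = alg$meta$country,
                version_id = alg$meta$version_id,
                age_min_days = alg$meta$age_min_days,
                age_max_days = alg$meta$age_max_days),
    stages = as.list(alg$stages),
    nodes = lapply(unname(alg$nodes), node_doc),
    diagnoses = lapply(unname(alg$diagnoses), dx_doc),
    managements = lapply(unname(alg$managements), function(m)
      list(id = m$id, label = m$label, kind = m$kind)),
    drugs = lapply(unname(alg$drugs), function(d) list(
      id = d$id, name = d$name,
      formulations = lapply(d$formulations, function(fo) list(
        form = fo$form, strength = fo$strength, increment = fo$increment)))),
    dosing_rules = lapply(unname(alg$dosing_rules), function(r) list(
      id = r$id, drug = r$drug, indication = r$indication,
      age_lo = r$age_lo, age_hi = r$age_hi,
      weight_lo = r$weight_lo, weight_hi = r$weight_hi,
      target = r$target, min = r$min, max = r$max, abs_max = r$abs_max,
      frequency = r$frequency, duration = r$duration)),
    emergency_guidance = as.list(alg$emergency_guidance),
    terminology = as.list(alg$terminology)
  )
}

#' Rebuild an algorithm from its document form
#'
#' @param doc A nested list as produced by [as_document()] or parsed from a
#'   YAML/JSON algorithm file.
#' @return A `clinical_algorithm` (not yet validated).
#' @export
from_document <- function(doc) {
  fv <- as.integer(doc$format_version %||% NA)
  if (is.na(fv) || fv != FORMAT_VERSION)
    stopf("unsupported or missing format_version (expected %d)", FORMAT_VERSION)
  req <- function(x, field, where) {
    if (is.null(x)) stopf("parse error: missing '%s' in %s", field, where)
    x
  }
  nodes <- lapply(doc$nodes, function(nd) node(
    id = req(nd$id, "id", "node"),
    stage = req(nd$stage, "stage", nd$id %||% "node"),
    kind = req(nd$kind, "kind", nd$id),
    label = nd$label %||% nd$id,
    answer_domain = nd$answer_domain %||% "boolean",
    answers = if (!is.null(nd$answers))
      lapply(nd$answers, function(a)
        answer(as.character(a$id), a$label %||% as.character(a$id),
               lo = a$lo, hi = a$hi)),
    unit = nd$unit, range = if (!is.null(nd$range)) as.numeric(unlist(nd$range)),
    display_condition = condition_from_doc(nd$display_condition),
    referral_triggering = isTRUE(nd$referral_triggering),
    estimable = isTRUE(nd$estimable),
    emergency_relevant = isTRUE(nd$emergency_relevant),
    derived_from = nd$derived_from, help = nd$help))
  diagnoses <- lapply(doc$diagnoses, function(dx) diagnosis(
    id = req(dx$id, "id", "diagnosis"),
    label = dx$label %||% dx$id,
    severity = req(dx$severity, "severity", dx$id),
    condition = condition_from_doc(req(dx$condition, "condition", dx$id)),
    managements = as_chr(dx$managements),
    treatments = lapply(dx$treatments, function(tr)
      treatment(as.character(tr$drug), alternatives = as_chr(tr$alternatives),
                rule = tr$rule)),
    excludes = as_chr(dx$excludes)))
  managements <- lapply(doc$managements, function(m)
    management(as.character(m$id), m$label %||% as.character(m$id),
               kind = as.character(m$kind)))
  drugs <- lapply(doc$drugs, function(d)
    drug(as.character(d$id), d$name %||% as.character(d$id),
         formulations = lapply(d$formulations, function(fo)
           formulation(as.character(fo$form), fo$strength, fo$increment))))
  rules <- lapply(doc$dosing_rules, function(r)
    dosing_rule(r$id, r$drug, r$indication, r$age_lo, r$age_hi,
                r$weight_lo, r$weight_hi, r$target, r$min, r$max, r$abs_max,
                r$frequency, r$duration))
  clinical_algorithm(
    name = req(doc$meta$name, "meta.name", "document"),
    country = doc$meta$country %||% "",
    version_id = req(doc$meta$version_id, "meta.version_id", "document"),
    age_range = c(as.numeric(doc$meta$age_min_days),
                  as.numeric(doc$meta$age_max_days)),
    stages = as_chr(doc$stages),
    nodes = nodes, diagnoses = diagnoses, managements = managements,
    drugs = drugs, dosing_rules = rules,
    emergency_guidance = as_chr(doc$emergency_guidance),
    terminology = setNames(as_chr(doc$terminology),
                           names(doc$terminology %||% character())))
}

#' Serialize an algorithm to text
#'
#' Renders the canonical document: identical algorithms serialize to
#' byte-identical text, and `from_document()` of the parsed text reproduces
#' the algorithm exactly (round-trip identity).
#'
#' @param alg A `clinical_algorithm`.
#' @param format `"yaml"` (authoring dialect) or `"json"` (canonical
#'   exchange dialect).
#' @return A single character string.
#' @export
serialize_algorithm <- function(alg, format = c("yaml", "json")) {
  format <- match.arg(format)
  doc <- as_document(alg)
  if (format == "yaml") {
    yaml::as.yaml(doc, precision = 15L)
  } else {
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE))
  }
}

#' Write an algorithm file
#'
#' @inheritParams serialize_algorithm
#' @param path Output file; extension `.json` selects the JSON dialect,
#'   anything else YAML, unless `format` is given.
#' @export
write_algorithm <- function(alg, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "yaml"
  writeLines(serialize_algorithm(alg, format), path, useBytes = TRUE)
  invisible(path)
}

#' Build a validated algorithm from a document file
#'
#' Parses a YAML or JSON algorithm document, reconstructs the
#' `clinical_algorithm`, auto-assigns terminology codes to any node or
#' diagnosis lacking one, and runs full structural validation, reporting
#' *every* violated invariant (not just the first).
#'
#' @param path Path to an algorithm document, or a `clinical_algorithm` /
#'   document list (validated in place).
#' @return A validated `clinical_algorithm`.
#' @export
build_algorithm <- function(path) {
  alg <- if (inherits(path, "clinical_algorithm")) path
         else if (is.list(path)) from_document(path)
         else from_document(read_document(path))
  findings <- validate_algorithm(alg)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    stopf("algorithm validation failed with %d error(s):\n%s", nrow(errs),
          paste(sprintf("  [%s] %s: %s", errs$code, errs$subject, errs$message),
                collapse = "\n"))
  }
  alg
}

read_document <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Compare two algorithms for content equality
#'
#' @param a,b `clinical_algorithm` objects.
#' @return `TRUE` iff their canonical documents are identical.
#' @export
algorithm_equal <- function(a, b) identical(as_document(a), as_document(b))
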