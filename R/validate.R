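#' Static structural validation of a clinical algorithm
#'
#' Checks every structural invariant of the content and returns *all*
#' violations at once (an algorithm author needs the full defect list, not
#' the first failure): id uniqueness, reference resolution, acyclicity of
#' display-condition dependencies, age-range sanity, numeric answer intervals
#' (pairwise disjoint, jointly covering the admissible range under the
#' half-open `[lo, hi)` convention), referral-triggering nodes appearing in
#' some severe/emergency condition, severe/emergency diagnoses carrying a
#' referral management, irreflexive exclusions, condition well-formedness,
#' and dosing-rule bounds and band disjointness.
#'
#' @param alg A `clinical_algorithm`.
#' @return A data frame of findings with columns `severity` (`error` /
#'   `warning`), `code`, `subject`, `message`; zero rows if clean.
#' @seealso [lint_algorithm()] for the full QA pass including reachability
#'   and posology.
#' @export
validate_algorithm <- function(alg) {
  f <- list()
  add <- function(code, subject, message, severity = "error") {
    f[[length(f) + 1L]] <<- data.frame(severity = severity, code = code,
                                       subject = subject, message = message,
                                       stringsAsFactors = FALSE)
  }
  node_ids <- names(alg$nodes)
  dx_ids <- names(alg$diagnoses)

  # id uniqueness across all registries
  all_ids <- c(node_ids, dx_ids, names(alg$managements), names(alg$drugs),
               names(alg$dosing_rules))
  for (dup in unique(all_ids[duplicated(all_ids)]))
    add("duplicate_id", dup, sprintf("id '%s' used by more than one entity", dup))

  # age range
  if (!isTRUE(alg$meta$age_min_days < alg$meta$age_max_days))
    add("age_range", alg$meta$name, "age range must satisfy min_days < max_days")

  check_condition_refs <- function(cond, subject) {
    ok <- TRUE
    if (!is_condition(cond)) {
      add("malformed_condition", subject, "condition is not a condition object")
      return(FALSE)
    }
    if (cond$op == "atom") {
      nd <- alg$nodes[[cond$node]]
      if (is.null(nd)) {
        add("dangling_reference", subject,
            sprintf("condition references undeclared node '%s'", cond$node))
        ok <- FALSE
      } else if (!cond$answer %in% vapply(nd$answers, `[[`, character(1), "id")) {
        add("dangling_reference", subject,
            sprintf("condition references unknown answer '%s' of node '%s'",
                    cond$answer, cond$node))
        ok <- FALSE
      }
    } else if (cond$op != "true") {
      if (cond$op == "at_least" && cond$k > length(cond$args)) {
        add("malformed_condition", subject,
            sprintf("AT_LEAST k=%g exceeds %d atoms", cond$k, length(cond$args)))
        ok <- FALSE
      }
      for (a in cond$args) ok <- check_condition_refs(a, subject) && ok
    }
    ok
  }

  # nodes
  for (nd in alg$nodes) {
    if (!nd$stage %in% alg$stages)
      add("unknown_stage", nd$id, sprintf("stage '%s' not declared", nd$stage))
    if (!is.null(nd$display_condition))
      check_condition_refs(nd$display_condition, nd$id)
    if (nd$answer_domain == "numeric") {
      lo <- vapply(nd$answers, `[[`, numeric(1), "lo")
      hi <- vapply(nd$answers, `[[`, numeric(1), "hi")
      ord <- order(lo)
      lo <- lo[ord]; hi <- hi[ord]
      if (any(lo < nd$range[1L]) || any(hi > nd$range[2L]))
        add("interval_bounds", nd$id,
            "answer interval bounds fall outside the admissible range")
      if (length(lo)) {
        if (lo[1L] > nd$range[1L])
          add("interval_gap", nd$id,
              sprintf("values in [%g, %g) map to no answer", nd$range[1L], lo[1L]))
        if (hi[length(hi)] < nd$range[2L])
          add("interval_gap", nd$id,
              sprintf("values in [%g, %g) map to no answer",
                      hi[length(hi)], nd$range[2L]))
        if (length(lo) > 1L) {
          gaps <- which(lo[-1L] > hi[-length(hi)])
          for (g in gaps)
            add("interval_gap", nd$id,
                sprintf("values in [%g, %g) map to no answer", hi[g], lo[g + 1L]))
          overlaps <- which(lo[-1L] < hi[-length(hi)])
          for (g in overlaps)
            add("interval_overlap", nd$id,
                sprintf("answer intervals overlap on [%g, %g)", lo[g + 1L],
                        min(hi[g], hi[g + 1L])))
        }
      } else {
        add("interval_gap", nd$id, "numeric node declares no answers")
      }
    }
  }

  # dependency graph acyclicity
  g <- dependency_graph(alg)
  cyc <- find_cycle(g)
  if (!is.null(cyc))
    add("cycle", cyc[1L],
        sprintf("display-condition dependency cycle: %s",
                paste(cyc, collapse = " -> ")))

  # diagnoses
  referral_ids <- names(Filter(function(m) m$kind == "referral", alg$managements))
  for (dx in alg$diagnoses) {
    check_condition_refs(dx$condition, dx$id)
    for (m in dx$managements)
      if (!m %in% names(alg$managements))
        add("dangling_reference", dx$id,
            sprintf("management '%s' not declared", m))
    for (tr in dx$treatments) {
      for (d in c(tr$drug, tr$alternatives))
        if (!d %in% names(alg$drugs))
          add("dangling_reference", dx$id, sprintf("drug '%s' not declared", d))
    }
    for (e in dx$excludes) {
      if (identical(e, dx$id))
        add("reflexive_exclusion", dx$id, "diagnosis excludes itself")
      else if (!e %in% dx_ids)
        add("dangling_reference", dx$id,
            sprintf("excluded diagnosis '%s' not declared", e))
    }
    if (dx$severity %in% c("emergency", "severe") &&
        !any(dx$managements %in% referral_ids))
      add("missing_referral", dx$id,
          sprintf("%s diagnosis lacks a referral management", dx$severity))
  }

  # referral-triggering nodes must feed a severe/emergency condition
  severe_atoms <- unique(unlist(lapply(
    Filter(function(d) d$severity %in% c("emergency", "severe"), alg$diagnoses),
    function(d) condition_atoms(d$condition)$node)))
  for (nd in alg$nodes)
    if (nd$referral_triggering && !nd$id %in% severe_atoms)
      add("referral_node_unused", nd$id,
          "referral-triggering node appears in no severe/emergency condition")

  # managements referenced by emergency guidance
  for (m in alg$emergency_guidance)
    if (!m %in% names(alg$managements))
      add("dangling_reference", m,
          sprintf("emergency guidance management '%s' not declared", m))

  # drugs and dosing rules
  for (d in alg$drugs)
    if (length(d$formulations) < 1L)
      add("no_formulation", d$id, "drug has no formulation")
  rules <- alg$dosing_rules
  for (r in rules) {
    if (!r$drug %in% names(alg$drugs))
      add("dangling_reference", r$id, sprintf("drug '%s' not declared", r$drug))
    if (!r$indication %in% dx_ids)
      add("dangling_reference", r$id,
          sprintf("indication '%s' not declared", r$indication))
    if (!(r$min <= r$target && r$target <= r$max))
      add("dose_bounds", r$id, "requires min <= target <= max")
  }
  # band disjointness within (drug, indication)
  keys <- vapply(rules, function(r) paste(r$drug, r$indication), character(1))
  for (k in unique(keys)) {
    grp <- rules[keys == k]
    if (length(grp) < 2L) next
    for (i in seq_len(length(grp) - 1L)) for (j in seq(i + 1L, length(grp))) {
      a <- grp[[i]]; b <- grp[[j]]
      if (a$age_lo < b$age_hi && b$age_lo < a$age_hi &&
          a$weight_lo < b$weight_hi && b$weight_lo < a$weight_hi)
        add("band_overlap", a$id,
            sprintf("dosing bands '%s' and '%s' overlap for %s", a$id, b$id, k))
    }
  }

  if (length(f) == 0L)
    return(data.frame(severity = character(), code = character(),
                      subject = character(), message = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, f)
  out[order(out$code, out$subject, out$message), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Display-condition dependency graph
#'
#' Directed graph on node ids with an edge `u -> v` whenever node `v`'s
#' display condition references node `u` (so `u` must be resolvable before
#' `v` can be shown). The graph must be acyclic for the algorithm to be
#' executable; [find_cycle()] reports a violating path.
#'
#' @param alg A `clinical_algorithm`.
#' @return An [igraph::graph] object whose vertices are the node ids.
#' @export
dependency_graph <- function(alg) {
  ids <- names(alg$nodes)
  edges <- character(0)
  for (nd in alg$nodes) {
    if (is.null(nd$display_condition)) next
    refs <- intersect(unique(condition_atoms(nd$display_condition)$node), ids)
    if (length(refs)) edges <- c(edges, rbind(refs, nd$id))
  }
  igraph::graph_from_data_frame(
    d = if (length(edges)) as.data.frame(matrix(edges, ncol = 2, byrow = TRUE))
        else data.frame(from = character(), to = character()),
    directed = TRUE,
    vertices = data.frame(name = ids))
}

#' Find a directed cycle in a dependency graph
#'
#' @param g An igraph directed graph.
#' @return `NULL` if acyclic; otherwise a character vector of vertex names
#'   tracing one cycle, first vertex repeated at the end.
#' @export
find_cycle <- function(g) {
  if (igraph::is_dag(g)) return(NULL)
  ids <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g), mode = "out"),
                function(v) v$name)
  names(adj) <- ids
  state <- setNames(rep(0L, length(ids)), ids) # 0 unseen, 1 on stack, 2 done
  path <- character(0)
  found <- NULL
  dfs <- function(u) {
    if (!is.null(found)) return()
    state[u] <<- 1L
    path <<- c(path, u)
    for (v in adj[[u]]) {
      if (!is.null(found)) return()
      if (state[v] == 1L) {
        i <- match(v, path)
        found <<- c(path[i:length(path)], v)
        return()
      }
      if (state[v] == 0L) dfs(v)
    }
    state[u] <<- 2L
    path <<- path[-length(path)]
  }
  for (u in ids) if (state[u] == 0L && is.null(found)) dfs(u)
  found
}

# topological ordering index for question sequencing; authoring order breaks
# ties deterministically
node_order_index <- function(alg) {
  g <- dependency_graph(alg)
  topo <- tryCatch(igraph::topo_sort(g, mode = "out")$name,
                   error = function(e) names(alg$nodes))
  stage_idx <- match(vapply(alg$nodes, `[[`, character(1), "stage"), alg$stages)
  topo_idx <- match(names(alg$nodes), topo)
  auth_idx <- seq_along(alg$nodes)
  order(stage_idx, topo_idx, auth_idx)
}
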