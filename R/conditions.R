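#' Boolean condition expressions over question answers
#'
#' Conditions are expression trees whose leaves are atoms `(node_id,
#' answer_id)`: an atom is true when that node was answered with that answer.
#' Trees combine atoms with `AND`, `OR`, `NOT` and `AT_LEAST(k, atoms)`, the
#' latter expressing composite clinical-impression items such as "at least 2
#' of these signs". Evaluation is three-valued (Kleene): an atom on an
#' unanswered node is *unknown*, and unknowns propagate through the
#' connectives, so a condition only resolves when enough answers are in.
#'
#' @param node,answer Atom coordinates: a node id and one of its answer ids.
#' @param ... Sub-conditions (for `cnd_and`/`cnd_or`) or atoms (for
#'   `cnd_at_least`).
#' @param x A sub-condition to negate.
#' @param k Minimum number of atoms that must be true.
#' @return A condition object (class `tt_condition`).
#' @examples
#' cnd <- cnd_and(cnd_atom("fever", "present"),
#'                cnd_or(cnd_atom("crp", "crp_high"),
#'                       cnd_atom("comorbidity", "present")))
#' eval_condition(cnd, c(fever = "present"))          # NA: crp unknown
#' eval_condition(cnd, c(fever = "present", crp = "crp_high"))
#' @name conditions
NULL

new_condition <- function(op, ...) {
  structure(c(list(op = op), list(...)), class = "tt_condition")
}

#' @rdname conditions
#' @export
cnd_atom <- function(node, answer) {
  stopifnot(is.character(node), length(node) == 1L,
            is.character(answer), length(answer) == 1L)
  new_condition("atom", node = node, answer = answer)
}

#' @rdname conditions
#' @export
cnd_and <- function(...) new_condition("and", args = list(...))

#' @rdname conditions
#' @export
cnd_or <- function(...) new_condition("or", args = list(...))

#' @rdname conditions
#' @export
cnd_not <- function(x) new_condition("not", args = list(x))

#' @rdname conditions
#' @export
cnd_at_least <- function(k, ...) {
  args <- list(...)
  if (k > length(args)) stopf("AT_LEAST k=%d exceeds %d listed atoms", k, length(args))
  new_condition("at_least", k = as.numeric(k), args = args)
}

#' @rdname conditions
#' @export
cnd_true <- function() new_condition("true")

is_condition <- function(x) inherits(x, "tt_condition")

#' Evaluate a condition under three-valued logic
#'
#' @param cond A condition built with the `cnd_*` constructors.
#' @param answers Named character vector or list mapping node id to the
#'   recorded answer id. Unlisted nodes are *unknown*.
#' @param gated Character vector of node ids whose display condition resolved
#'   false: atoms on those nodes evaluate false (the question was legitimately
#'   never asked), not unknown.
#' @return `TRUE`, `FALSE` or `NA` (unknown).
#' @export
eval_condition <- function(cond, answers = character(), gated = character()) {
  stopifnot(is_condition(cond))
  answers <- unlist(answers)
  switch(cond$op,
    true = TRUE,
    atom = {
      if (cond$node %in% gated) return(FALSE)
      a <- if (length(answers)) unname(answers[cond$node]) else NA_character_
      if (is.na(a)) NA else identical(a, cond$answer)
    },
    and = {
      vals <- vapply(cond$args, eval_condition, logical(1),
                     answers = answers, gated = gated)
      all(vals) # Kleene: FALSE dominates, then NA
    },
    or = {
      vals <- vapply(cond$args, eval_condition, logical(1),
                     answers = answers, gated = gated)
      any(vals)
    },
    not = !eval_condition(cond$args[[1L]], answers, gated),
    at_least = {
      vals <- vapply(cond$args, eval_condition, logical(1),
                     answers = answers, gated = gated)
      n_true <- sum(vals, na.rm = TRUE)
      n_unk <- sum(is.na(vals))
      if (n_true >= cond$k) TRUE
      else if (n_true + n_unk < cond$k) FALSE
      else NA
    },
    stopf("unknown condition op '%s'", cond$op)
  )
}

#' List the atoms referenced by a condition
#'
#' @inheritParams eval_condition
#' @return Data frame with columns `node`, `answer`, one row per atom
#'   occurrence.
#' @export
condition_atoms <- function(cond) {
  stopifnot(is_condition(cond))
  if (cond$op == "atom")
    return(data.frame(node = cond$node, answer = cond$answer,
                      stringsAsFactors = FALSE))
  if (cond$op == "true")
    return(data.frame(node = character(), answer = character()))
  do.call(rbind, lapply(cond$args, condition_atoms))
}

# ---- vectorized evaluation over complete assignments ------------------------
#
# `answers` is a named list: node id -> character vector (one assignment per
# row). `gated` is NULL or a named list: node id -> logical vector (TRUE =
# this row never asks that node). Used by exhaustive enumeration (lint
# reachability, severity-first sweeps), where every node carries an answer.

eval_condition_vec <- function(cond, answers, n, gated = NULL) {
  switch(cond$op,
    true = rep(TRUE, n),
    atom = {
      col <- answers[[cond$node]]
      if (is.null(col)) return(rep(NA, n))
      v <- col == cond$answer
      g <- gated[[cond$node]]
      if (!is.null(g)) v[g] <- FALSE
      v
    },
    and = Reduce(`&`, lapply(cond$args, eval_condition_vec,
                             answers = answers, n = n, gated = gated)),
    or = Reduce(`|`, lapply(cond$args, eval_condition_vec,
                            answers = answers, n = n, gated = gated)),
    not = !eval_condition_vec(cond$args[[1L]], answers, n, gated),
    at_least = {
      m <- vapply(cond$args, eval_condition_vec, logical(n),
                  answers = answers, n = n, gated = gated)
      if (n == 1L) m <- matrix(m, nrow = 1L)
      n_true <- rowSums(m, na.rm = TRUE)
      n_unk <- rowSums(is.na(m))
      ifelse(n_true >= cond$k, TRUE, ifelse(n_true + n_unk < cond$k, FALSE, NA))
    },
    stopf("unknown condition op '%s'", cond$op)
  )
}

# ---- explanation support ----------------------------------------------------
#
# Minimal supporting assignment: the smallest set of (node -> answer) entries
# that, replayed alone (all other nodes unknown), still makes the condition
# true. Entries with answer NA mean "this node is known not to hold any of its
# atoms" (it was gated off); replay treats such nodes' atoms as false.

support_assignment <- function(cond, answers, gated, want = TRUE) {
  entry <- function(node) {
    a <- if (length(answers)) unname(unlist(answers)[node]) else NA_character_
    if (is.na(a) || node %in% gated) a <- NA_character_
    setNames(list(a), node)
  }
  merge2 <- function(a, b) c(a, b[setdiff(names(b), names(a))])
  val <- eval_condition(cond, answers, gated)
  if (!identical(val, want)) stopf("condition does not evaluate to %s", want)
  switch(cond$op,
    true = if (want) list() else stopf("constant true cannot be false"),
    atom = entry(cond$node),
    and = {
      if (want) {
        Reduce(merge2, lapply(cond$args, support_assignment,
                              answers = answers, gated = gated, want = TRUE))
      } else {
        i <- which(vapply(cond$args, function(a)
          isFALSE(eval_condition(a, answers, gated)), logical(1)))[1L]
        support_assignment(cond$args[[i]], answers, gated, want = FALSE)
      }
    },
    or = {
      if (want) {
        i <- which(vapply(cond$args, function(a)
          isTRUE(eval_condition(a, answers, gated)), logical(1)))[1L]
        support_assignment(cond$args[[i]], answers, gated, want = TRUE)
      } else {
        Reduce(merge2, lapply(cond$args, support_assignment,
                              answers = answers, gated = gated, want = FALSE))
      }
    },
    not = support_assignment(cond$args[[1L]], answers, gated, want = !want),
    at_least = {
      vals <- vapply(cond$args, function(a) eval_condition(a, answers, gated),
                     logical(1))
      if (want) {
        idx <- head(which(vals %in% TRUE), cond$k)
        Reduce(merge2, lapply(cond$args[idx], support_assignment,
                              answers = answers, gated = gated, want = TRUE))
      } else {
        # enough definite falses that at most k-1 atoms can ever be true
        need <- length(cond$args) - cond$k + 1
        idx <- head(which(vals %in% FALSE), need)
        Reduce(merge2, lapply(cond$args[idx], support_assignment,
                              answers = answers, gated = gated, want = FALSE))
      }
    }
  )
}

# Replay a support assignment: entries with NA answers are treated as gated.
replay_support <- function(cond, support) {
  support <- unlist(support) %||% setNames(character(), character())
  gated <- names(support)[is.na(support)]
  eval_condition(cond, support[!is.na(support)], gated)
}
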