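#' Contexts, mapping rules and multi-context systems
#'
#' A *context* is an independent knowledge source: a named defeasible theory
#' plus a preference rank (lower = more trusted, used only for tie-breaks).
#' Contexts are interlinked by *mapping rules* (also called bridge rules):
#' defeasible rules whose body literals live in other contexts, written
#' `"context_id:literal"`, and whose head is local to the owning context.
#' Mapping rules are always evaluated defeasibly so that imported knowledge
#' can be defeated during conflict resolution, and carry a numeric priority
#' which feeds straight into the local engine's superiority relation.
#'
#' @param id identifier string.
#' @param theory a [dfl_theory()] for the context.
#' @param rank integer preference rank; defaults to declaration order in
#'   [build_mcs()].
#' @return `dfl_context()` a context object; `dfl_mapping()` a one-row
#'   mapping tibble.
#' @export
dfl_context <- function(id, theory, rank = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(theory, "dfl_theory"))
  structure(list(id = id, theory = theory, rank = as.integer(rank)),
            class = "dfl_context")
}

#' @rdname dfl_context
#' @param owner id of the context the rule belongs to (where its head lives).
#' @param body character vector of `"context:literal"` references; entries
#'   naming the owner itself are kept as ordinary local body literals.
#' @param head head literal, local to `owner`.
#' @param priority mapping priority (higher fires over lower on conflict).
#' @export
dfl_mapping <- function(id, owner, body, head, priority = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(owner), length(owner) == 1L)
  check_literal(head, "mapping head")
  bad <- !grepl("^[^:]+:~?[^:~][^:]*$", body)
  if (any(bad)) abort(paste0("mapping body entries must be 'context:literal', got: ",
                             body[bad][1]))
  tibble::tibble(id = id, owner = owner, body = list(as.character(body)),
                 head = head, priority = as.integer(priority))
}

split_ref <- function(x) {
  pos <- regexpr(":", x, fixed = TRUE)
  list(context = substr(x, 1L, pos - 1L), literal = substring(x, pos + 1L))
}

#' Assemble a multi-context system
#'
#' Validates that context ids are unique, every mapping's owner and every
#' context referenced in a mapping body exists, and fills in missing
#' preference ranks by declaration order. The inter-context dependency graph
#' (owner depends on the contexts named in its mapping bodies) is recorded
#' for inspection; cycles in it are legal and handled by
#' [distributed_query()].
#'
#' @param contexts list of [dfl_context()] objects.
#' @param mappings tibble of mapping rules (`dplyr::bind_rows()` of
#'   [dfl_mapping()] calls), or `NULL`.
#' @return an object of class `dfl_mcs`.
#' @export
build_mcs <- function(contexts, mappings = NULL) {
  if (inherits(contexts, "dfl_context")) contexts <- list(contexts)
  ids <- vapply(contexts, `[[`, "", "id")
  if (anyDuplicated(ids)) abort(paste0("duplicate context id: ", ids[duplicated(ids)][1]))
  for (i in seq_along(contexts)) {
    if (is.na(contexts[[i]]$rank)) contexts[[i]]$rank <- i
  }
  names(contexts) <- ids
  if (is.null(mappings)) {
    mappings <- dfl_mapping("..drop", "x", character(), "x")[0, ]
  }
  mappings <- tibble::as_tibble(mappings)
  if (nrow(mappings)) {
    if (anyDuplicated(mappings$id)) {
      abort(paste0("duplicate mapping id: ", mappings$id[duplicated(mappings$id)][1]))
    }
    refs <- unique(c(mappings$owner,
                     vapply(unlist(mappings$body), function(b) split_ref(b)$context, "")))
    missing <- setdiff(refs, ids)
    if (length(missing)) abort(paste0("mapping references unknown context: ", missing[1]))
  }
  deps <- if (nrow(mappings)) {
    dplyr::distinct(dplyr::bind_rows(purrr::map(seq_len(nrow(mappings)), function(i) {
      foreign <- vapply(mappings$body[[i]], function(b) split_ref(b)$context, "")
      foreign <- setdiff(foreign, mappings$owner[i])
      tibble::tibble(from = rep(mappings$owner[i], length(foreign)), to = foreign)
    })))
  } else {
    tibble::tibble(from = character(), to = character())
  }
  structure(list(contexts = contexts, mappings = mappings, dependencies = deps),
            class = "dfl_mcs")
}

#' @export
print.dfl_mcs <- function(x, ...) {
  cat("<dfl_mcs> ", length(x$contexts), " contexts, ", nrow(x$mappings),
      " mapping rules\n", sep = "")
  for (ctx in x$contexts) {
    cat("  ", ctx$id, " (rank ", ctx$rank, "): ", nrow(ctx$theory$rules),
        " rules, ", length(ctx$theory$facts), " facts\n", sep = "")
  }
  invisible(x)
}

context_ranks <- function(mcs) {
  setNames(vapply(mcs$contexts, `[[`, 1L, "rank"), names(mcs$contexts))
}

# Resolve the mappings owned by `context_id` against the rest of the MCS.
# Foreign body literals are answered by recursive distributed queries with an
# explicit call history; a branch that revisits a (context, literal) pair in
# its own history is cut and counted as unprovable, tainting the result.
# Returns the context theory augmented with every applicable mapping as a
# defeasible rule, plus the taint flag and foreign support used.
augment_context <- function(mcs, context_id, history = character()) {
  ctx <- mcs$contexts[[context_id]]
  maps <- dplyr::filter(mcs$mappings, .data$owner == context_id)
  taint <- FALSE
  extra <- list()
  support <- tibble::tibble(context = character(), rule_id = character())
  if (nrow(maps)) {
    for (i in seq_len(nrow(maps))) {
      local_body <- character()
      applicable <- TRUE
      for (b in maps$body[[i]]) {
        ref <- split_ref(b)
        if (ref$context == context_id) {
          local_body <- c(local_body, ref$literal)
          next
        }
        ans <- distributed_query(mcs, ref$context, ref$literal, history = history)
        if (ans$value == "positive") {
          support <- dplyr::bind_rows(support, ans$support)
        } else {
          applicable <- FALSE
          if (ans$value == "undefined") taint <- TRUE
          break
        }
      }
      if (applicable) {
        extra[[length(extra) + 1L]] <- dfl_rule(maps$id[i], "defeasible",
                                                body = local_body,
                                                head = maps$head[i],
                                                priority = maps$priority[i])
        support <- dplyr::bind_rows(
          support, tibble::tibble(context = context_id, rule_id = maps$id[i]))
      }
    }
  }
  theory <- dfl_theory(facts = ctx$theory$facts,
                       rules = dplyr::bind_rows(c(list(ctx$theory$rules), extra)),
                       superiority = ctx$theory$superiority)
  list(theory = theory, taint = taint,
       support = dplyr::distinct(support))
}

#' Query a literal across the multi-context system
#'
#' Resolves the literal in the named context with the local engine after
#' importing every applicable mapping rule; foreign body literals are
#' resolved by recursive queries to their owning contexts. A call history
#' guarantees termination on cyclic mapping graphs: a branch that would
#' revisit a pending (context, literal) pair evaluates as unprovable, and if
#' such a cut could have decided the outcome the answer is flagged
#' `undefined` rather than `negative`.
#'
#' @param mcs a [build_mcs()] object.
#' @param context_id the context to ask.
#' @param literal the literal to prove defeasibly in that context.
#' @param history internal recursion guard; leave at default.
#' @return a `dfl_query_answer`: list with `value` (`"positive"`,
#'   `"negative"` or `"undefined"`) and `support`, a tibble of
#'   (context, rule_id) pairs used.
#' @export
distributed_query <- function(mcs, context_id, literal, history = character()) {
  stopifnot(inherits(mcs, "dfl_mcs"))
  if (!context_id %in% names(mcs$contexts)) {
    abort(paste0("unknown context: ", context_id))
  }
  check_literal(literal)
  key <- paste0(context_id, "::", literal)
  if (key %in% history) {
    return(query_answer("undefined"))
  }
  aug <- augment_context(mcs, context_id, history = c(history, key))
  if (prove(aug$theory, literal, "+d")) {
    local_support <- supporting_rules(aug$theory, literal)
    support <- dplyr::bind_rows(
      tibble::tibble(context = context_id, rule_id = local_support),
      aug$support)
    return(query_answer("positive", dplyr::distinct(support)))
  }
  query_answer(if (aug$taint) "undefined" else "negative")
}

query_answer <- function(value,
                         support = tibble::tibble(context = character(),
                                                  rule_id = character())) {
  structure(list(value = value,
                 support = dplyr::arrange(support, .data$context, .data$rule_id)),
            class = "dfl_query_answer")
}

#' @export
print.dfl_query_answer <- function(x, ...) {
  cat("<dfl_query_answer> ", x$value, "\n", sep = "")
  if (nrow(x$support)) print(x$support)
  invisible(x)
}

# Supportive non-defeater rules for `literal` whose bodies are defeasibly
# provable (used only for support reporting).
supporting_rules <- function(theory, literal) {
  r <- theory$rules
  idx <- which(r$head == literal & r$kind != "defeater")
  hits <- vapply(idx, function(i)
    all(vapply(r$body[[i]], function(b) prove(theory, b, "+d"), logical(1))),
    logical(1))
  ids <- r$id[idx][hits]
  if (literal %in% theory$facts) ids <- c(ids, "<fact>")
  sort(ids)
}

#' Pick the winning mapping rule among conflicting candidates
#'
#' Implements the priority-based conflict resolution applied when several
#' mapping rules with complementary heads are simultaneously applicable: the
#' rule with the strictly highest priority fires; ties fall back to the
#' owning context's preference rank (lower rank = more trusted), then to
#' lexicographic rule id, so the choice is always deterministic.
#'
#' @param candidates tibble of applicable mapping rules (columns `id`,
#'   `owner`, `priority`).
#' @param ranks named integer vector of context preference ranks; defaults
#'   to first-appearance order of the owners.
#' @return the single winning row of `candidates`.
#' @export
resolve_mapping_conflict <- function(candidates, ranks = NULL) {
  candidates <- tibble::as_tibble(candidates)
  if (!nrow(candidates)) abort("no candidate mapping rules to resolve")
  if (is.null(ranks)) {
    owners <- unique(candidates$owner)
    ranks <- setNames(seq_along(owners), owners)
  }
  ord <- order(-candidates$priority, ranks[candidates$owner], candidates$id)
  candidates[ord[1], ]
}

#' Check whether the system is in equilibrium
#'
#' The system is in equilibrium when every context's beliefs, after all
#' mapping rules have been resolved across the system, are consistent: no
#' atom is defeasibly concluded with both signs (a strict contradiction),
#' and no atom is left *unresolved* — supported with both signs by
#' applicable rules of equal standing so that the engine can conclude
#' neither, i.e. the system cannot reach a decision. Assigning priorities to
#' the conflicting mapping rules removes unresolved conflicts and restores
#' equilibrium.
#'
#' @param mcs a [build_mcs()] object.
#' @return list with `consistent` (logical) and `conflicts`, a tibble of
#'   (context, atom, type) rows, `type` one of `"contradiction"`,
#'   `"unresolved"`.
#' @export
equilibrium_check <- function(mcs) {
  stopifnot(inherits(mcs, "dfl_mcs"))
  conflicts <- tibble::tibble(context = character(), atom = character(),
                              type = character())
  for (id in names(mcs$contexts)) {
    aug <- augment_context(mcs, id)$theory
    concs <- all_conclusions(aug)
    strict <- conflicting_literals(concs)
    if (length(strict)) {
      conflicts <- dplyr::bind_rows(
        conflicts, tibble::tibble(context = id, atom = strict,
                                  type = "contradiction"))
    }
    amb <- unresolved_atoms(aug, concs)
    amb <- setdiff(amb, strict)
    if (length(amb)) {
      conflicts <- dplyr::bind_rows(
        conflicts, tibble::tibble(context = id, atom = amb,
                                  type = "unresolved"))
    }
  }
  conflicts <- dplyr::arrange(conflicts, .data$context, .data$atom)
  list(consistent = nrow(conflicts) == 0L, conflicts = conflicts)
}

# Atoms supported with both signs by applicable non-defeater rules while the
# engine concludes neither sign: the blocked-ambiguity signature of an
# unresolved inter-context conflict.
unresolved_atoms <- function(theory, concs) {
  plus <- concs$literal[concs$tag == "+d"]
  supported <- function(lit) {
    lit %in% theory$facts ||
      any(vapply(which(theory$rules$head == lit & theory$rules$kind != "defeater"),
                 function(i) all(theory$rules$body[[i]] %in% plus), logical(1)))
  }
  atoms <- theory_atoms(theory)
  hit <- vapply(atoms, function(a) {
    pos <- a; neg <- paste0("~", a)
    supported(pos) && supported(neg) && !(pos %in% plus) && !(neg %in% plus)
  }, logical(1))
  sort(atoms[hit])
}
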