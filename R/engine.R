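#' Defeasible-logic proof tags
#'
#' The engine computes the four standard proof tags of propositional
#' defeasible logic, written in ASCII: `+D` / `-D` for definite provability
#' and refutability (derivable from facts and strict rules alone), and
#' `+d` / `-d` for defeasible provability and refutability. The adopted
#' proof conditions are the ambiguity-blocking variant with team defeat: a
#' rule attacking a candidate conclusion may be counter-defeated by *any*
#' applicable supporting rule that is superior to it, not only the one that
#' put the conclusion forward.
#'
#' Superiority between two rules with complementary heads is decided by an
#' explicit superiority pair when one exists (in either direction it
#' overrides numbers), otherwise by the numeric `priority` field (strictly
#' higher wins). Equal priority and no explicit pair means neither rule
#' defeats the other, so both conclusions are blocked (skeptical behaviour).
#'
#' @name proof-tags
#' @keywords internal
NULL

PROOF_TAGS <- c("+D", "-D", "+d", "-d")

# Indexed form of a theory used by the fixpoint loop.
index_theory <- function(theory, extra_atoms = character()) {
  atoms <- union(theory_atoms(theory), extra_atoms)
  lits <- if (length(atoms)) c(atoms, paste0("~", atoms)) else character()
  r <- theory$rules
  list(
    facts = theory$facts,
    lits = lits,
    ids = r$id,
    kinds = r$kind,
    heads = r$head,
    bodies = r$body,
    prios = r$priority,
    sup_key = paste(theory$superiority$winner, theory$superiority$loser),
    by_head = split(seq_len(nrow(r)), factor(r$head, levels = unique(r$head)))
  )
}

rules_for <- function(ix, lit, supportive = FALSE) {
  idx <- ix$by_head[[lit]] %||% integer()
  if (supportive && length(idx)) idx <- idx[ix$kinds[idx] != "defeater"]
  idx
}

# t beats s? Explicit pairs (either direction) override numeric priority.
rule_beats <- function(ix, t, s) {
  kt <- paste(ix$ids[t], ix$ids[s])
  ks <- paste(ix$ids[s], ix$ids[t])
  if (kt %in% ix$sup_key) return(TRUE)
  if (ks %in% ix$sup_key) return(FALSE)
  ix$prios[t] > ix$prios[s]
}

#' Compute every tagged conclusion of a theory
#'
#' Runs a bottom-up least-fixpoint evaluation of the proof conditions over
#' all literals whose atoms appear in the theory. Because every condition is
#' monotone in the set of already-derived tagged conclusions, the fixpoint
#' exists, is unique, and coincides with the recursive proof-theoretic
#' reading in which a derivation that cycles back on itself fails: a
#' tagged literal is derived exactly when it has a well-founded proof tree.
#' This also guarantees termination on every finite theory, looping rules
#' included.
#'
#' @param theory a [dfl_theory()].
#' @return a tibble with columns `literal`, `atom`, `negated`, `tag`
#'   (`+D`, `-D`, `+d`, `-d`), one row per derivable tagged conclusion.
#' @examples
#' th <- dfl_theory(facts = "p", rules = dfl_rule("r1", "strict", "p", "q"))
#' all_conclusions(th)
#' @export
all_conclusions <- function(theory) {
  stopifnot(inherits(theory, "dfl_theory"))
  ix <- index_theory(theory)
  st <- engine_fixpoint(ix)
  lits <- ix$lits
  out <- purrr::map(PROOF_TAGS, function(tag) {
    hit <- lits[st[[tag]][lits]]
    tibble::tibble(literal = hit, tag = tag)
  })
  res <- dplyr::bind_rows(out)
  res <- dplyr::mutate(res, atom = lit_atom(.data$literal),
                       negated = lit_negated(.data$literal))
  dplyr::arrange(dplyr::select(res, "literal", "atom", "negated", "tag"),
                 .data$atom, .data$negated, .data$tag)
}

engine_fixpoint <- function(ix) {
  lits <- ix$lits
  st <- lapply(PROOF_TAGS, function(t) setNames(logical(length(lits)), lits))
  names(st) <- PROOF_TAGS
  if (!length(lits)) return(st)
  repeat {
    changed <- FALSE
    for (q in lits) {
      nq <- lit_complement(q)
      strict_q <- rules_for(ix, q)
      supp_q <- rules_for(ix, q, supportive = TRUE)
      att_q <- rules_for(ix, nq)

      if (!st$`+D`[[q]]) {
        ok <- q %in% ix$facts ||
          any(vapply(strict_q[ix$kinds[strict_q] == "strict"], function(r)
            all(st$`+D`[ix$bodies[[r]]]), logical(1)))
        if (ok) { st$`+D`[[q]] <- TRUE; changed <- TRUE }
      }
      if (!st$`-D`[[q]]) {
        sr <- strict_q[ix$kinds[strict_q] == "strict"]
        ok <- !(q %in% ix$facts) &&
          all(vapply(sr, function(r)
            any(st$`-D`[ix$bodies[[r]]]), logical(1)))
        if (ok) { st$`-D`[[q]] <- TRUE; changed <- TRUE }
      }
      if (!st$`+d`[[q]]) {
        ok <- st$`+D`[[q]] ||
          (st$`-D`[[nq]] &&
             any(vapply(supp_q, function(r)
               all(st$`+d`[ix$bodies[[r]]]), logical(1))) &&
             all(vapply(att_q, function(s) {
               any(st$`-d`[ix$bodies[[s]]]) ||
                 any(vapply(supp_q, function(t)
                   all(st$`+d`[ix$bodies[[t]]]) && rule_beats(ix, t, s),
                   logical(1)))
             }, logical(1))))
        if (ok) { st$`+d`[[q]] <- TRUE; changed <- TRUE }
      }
      if (!st$`-d`[[q]]) {
        ok <- st$`-D`[[q]] &&
          (st$`+D`[[nq]] ||
             all(vapply(supp_q, function(r)
               any(st$`-d`[ix$bodies[[r]]]), logical(1))) ||
             any(vapply(att_q, function(s) {
               all(st$`+d`[ix$bodies[[s]]]) &&
                 all(vapply(supp_q, function(t)
                   any(st$`-d`[ix$bodies[[t]]]) || !rule_beats(ix, t, s),
                   logical(1)))
             }, logical(1))))
        if (ok) { st$`-d`[[q]] <- TRUE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  st
}

#' Prove a single tagged conclusion
#'
#' @param theory a [dfl_theory()].
#' @param literal a literal string (`~` for strong negation). Atoms that do
#'   not occur in the theory are handled: they are definitely and defeasibly
#'   refuted.
#' @param tag one of `"+D"`, `"-D"`, `"+d"`, `"-d"` (see [proof-tags]).
#' @return `TRUE` iff the tagged conclusion is derivable.
#' @export
prove <- function(theory, literal, tag = "+d") {
  stopifnot(inherits(theory, "dfl_theory"), tag %in% PROOF_TAGS)
  check_literal(literal)
  ix <- index_theory(theory, extra_atoms = lit_atom(literal))
  st <- engine_fixpoint(ix)
  unname(st[[tag]][[literal]])
}

#' Atoms concluded with both signs
#'
#' Scans a conclusion table for atoms with `+d` on both the positive and the
#' negated literal. Under the skeptical proof conditions this is only
#' possible when the strict part of the theory is itself inconsistent
#' (e.g. contradictory facts); an empty result certifies local consistency.
#'
#' @param conclusions output of [all_conclusions()].
#' @return character vector of conflicted atom names.
#' @export
conflicting_literals <- function(conclusions) {
  if (!nrow(conclusions)) return(character())
  pos <- dplyr::filter(conclusions, .data$tag == "+d")
  both <- dplyr::summarise(dplyr::group_by(pos, .data$atom),
                           conflict = any(.data$negated) && any(!.data$negated),
                           .groups = "drop")
  sort(both$atom[both$conflict])
}
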