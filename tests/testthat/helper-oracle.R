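# Independent proof-condition oracle.
#
# A direct recursive transcription of the ambiguity-blocking, team-defeat
# inference conditions for the four proof tags, memoized with an
# "in-progress" marker carried on the call path: a query that cycles back
# into a pending (tag, literal) pair fails on that branch. Results computed
# while such a cut was live ("tainted") are never cached, so the memo only
# holds path-independent answers. This is written against the inference
# conditions themselves and shares no code with the package engine.

oracle_engine <- function(theory) {
  rules <- theory$rules
  facts <- theory$facts
  sup_keys <- paste(theory$superiority$winner, theory$superiority$loser)
  beats <- function(t, s) {
    if (paste(rules$id[t], rules$id[s]) %in% sup_keys) return(TRUE)
    if (paste(rules$id[s], rules$id[t]) %in% sup_keys) return(FALSE)
    rules$priority[t] > rules$priority[s]
  }
  memo <- new.env(parent = emptyenv())
  eval_q <- function(lit, tag, path) {
    key <- paste(tag, lit)
    cached <- memo[[key]]
    if (!is.null(cached)) return(list(val = cached, taint = FALSE))
    if (key %in% path) return(list(val = FALSE, taint = TRUE))
    path <- c(path, key)
    taint <- FALSE
    sub <- function(l, tg) {
      r <- eval_q(l, tg, path)
      taint <<- taint || r$taint
      r$val
    }
    all_body <- function(i, tg)
      all(vapply(rules$body[[i]], sub, logical(1), tg))
    any_body <- function(i, tg)
      any(vapply(rules$body[[i]], sub, logical(1), tg))
    nl <- cdlsentinel::lit_complement(lit)
    strict_q <- which(rules$head == lit & rules$kind == "strict")
    supp_q <- which(rules$head == lit & rules$kind != "defeater")
    att_q <- which(rules$head == nl)
    val <- switch(
      tag,
      "+D" = lit %in% facts ||
        any(vapply(strict_q, function(r) all_body(r, "+D"), logical(1))),
      "-D" = !(lit %in% facts) &&
        all(vapply(strict_q, function(r) any_body(r, "-D"), logical(1))),
      "+d" = sub(lit, "+D") ||
        (sub(nl, "-D") &&
           any(vapply(supp_q, function(r) all_body(r, "+d"), logical(1))) &&
           all(vapply(att_q, function(s) {
             any_body(s, "-d") ||
               any(vapply(supp_q, function(t)
                 all_body(t, "+d") && beats(t, s), logical(1)))
           }, logical(1)))),
      "-d" = sub(lit, "-D") &&
        (sub(nl, "+D") ||
           all(vapply(supp_q, function(r) any_body(r, "-d"), logical(1))) ||
           any(vapply(att_q, function(s) {
             all_body(s, "+d") &&
               all(vapply(supp_q, function(t)
                 any_body(t, "-d") || !beats(t, s), logical(1)))
           }, logical(1))))
    )
    if (!taint) memo[[key]] <- val
    list(val = val, taint = taint)
  }
  function(lit, tag) eval_q(lit, tag, character())$val
}

oracle_prove <- function(theory, literal, tag) {
  oracle_engine(theory)(literal, tag)
}

# Full tagged-conclusion table via the oracle, same shape as all_conclusions().
oracle_conclusions <- function(theory) {
  atoms <- cdlsentinel::theory_atoms(theory)
  if (!length(atoms)) {
    return(tibble::tibble(literal = character(), atom = character(),
                          negated = logical(), tag = character()))
  }
  ask <- oracle_engine(theory)
  lits <- c(atoms, paste0("~", atoms))
  grid <- expand.grid(literal = lits, tag = c("+D", "-D", "+d", "-d"),
                      stringsAsFactors = FALSE)
  hit <- mapply(ask, grid$literal, grid$tag)
  out <- tibble::tibble(literal = grid$literal[hit], tag = grid$tag[hit])
  out$atom <- cdlsentinel::lit_atom(out$literal)
  out$negated <- cdlsentinel::lit_negated(out$literal)
  dplyr::arrange(out[, c("literal", "atom", "negated", "tag")],
                 atom, negated, tag)
}

# Forward-chaining closure of the facts under all non-defeater rules,
# ignoring conflict handling entirely (valid only for theories without
# complementary heads or defeaters).
forward_closure <- function(theory) {
  derived <- theory$rules$kind != "defeater"
  rules <- theory$rules[derived, ]
  known <- theory$facts
  repeat {
    fire <- vapply(seq_len(nrow(rules)), function(i)
      all(rules$body[[i]] %in% known) && !(rules$head[i] %in% known),
      logical(1))
    if (!any(fire)) break
    known <- unique(c(known, rules$head[fire]))
  }
  sort(unique(known))
}
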