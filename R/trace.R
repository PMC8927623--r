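#' Finite-trace temporal checks
#'
#' A trace is the ordered event log of a run: a tibble with `tick`, `kind`
#' (`observation`, `message`, `alert`, `flag`, `heartbeat`, `crs`) and a
#' `payload` list-column. A *tick-state* is the set of events sharing a
#' tick, and a trace proposition is any predicate mapping a tick-state to a
#' single logical (it must be total — never error). `holds_globally()` is
#' the finite-trace "globally" operator G (true iff the proposition holds at
#' every tick-state, vacuously true on an empty trace);
#' `holds_eventually()` is the finite-trace "eventually" operator F (true
#' iff it holds at one or more tick-states, false on an empty trace). The
#' two are dual: `F(p) == !G(!p)`.
#'
#' @param trace a trace tibble.
#' @param prop a function `(tick_events) -> TRUE/FALSE` where `tick_events`
#'   is the sub-tibble of events at one tick.
#' @return a single logical.
#' @examples
#' tr <- tibble::tibble(tick = c(1L, 2L), kind = c("observation", "alert"),
#'                      payload = list(list(), list()))
#' holds_eventually(tr, prop_any("alert"))
#' holds_globally(tr, prop_none("flag"))
#' @export
holds_globally <- function(trace, prop) {
  all(eval_per_tick(trace, prop))
}

#' @rdname holds_globally
#' @export
holds_eventually <- function(trace, prop) {
  any(eval_per_tick(trace, prop))
}

eval_per_tick <- function(trace, prop) {
  trace <- tibble::as_tibble(trace)
  ticks <- unique(trace$tick)
  vapply(ticks, function(t) isTRUE(prop(trace[trace$tick == t, ])), logical(1))
}

#' Common trace propositions
#'
#' `prop_any(kind)` holds at a tick-state containing at least one event of
#' the given kind (optionally filtered by a payload predicate);
#' `prop_none(kind)` is its negation; `prop_not(p)` negates any proposition.
#'
#' @param kind event kind string.
#' @param where optional predicate on the event payload.
#' @param p a proposition.
#' @return a trace proposition.
#' @export
prop_any <- function(kind, where = NULL) {
  force(kind); force(where)
  function(tick_events) {
    rows <- tick_events[tick_events$kind == kind, ]
    if (!nrow(rows)) return(FALSE)
    if (is.null(where)) return(TRUE)
    any(vapply(rows$payload, function(p) isTRUE(where(p)), logical(1)))
  }
}

#' @rdname prop_any
#' @export
prop_none <- function(kind, where = NULL) {
  prop_not(prop_any(kind, where))
}

#' @rdname prop_any
#' @export
prop_not <- function(p) {
  force(p)
  function(tick_events) !isTRUE(p(tick_events))
}

trace_messages <- function(trace) {
  rows <- trace[trace$kind == "message", ]
  if (!nrow(rows)) {
    return(tibble::tibble(performative = character(), sender = character(),
                          receiver = character(), content = character(),
                          tick = integer()))
  }
  dplyr::bind_rows(purrr::map(rows$payload, function(p)
    tibble::as_tibble(p[c("performative", "sender", "receiver", "content", "tick")])))
}

#' Ask/tell protocol pairing
#'
#' Checks that every `ask(j, i, phi)` in the trace is eventually (at the
#' same tick or later) answered by a `tell(i, j, phi)` — same content,
#' reversed endpoints — or that the asked agent holds a standing tell rule
#' for that content. Unmatched asks are reported.
#'
#' @param trace a trace tibble.
#' @param standing_tells optional tibble (`agent`, `content`) of standing
#'   tell rules.
#' @return tibble of unmatched ask messages (empty when the protocol holds).
#' @export
check_ask_tell_pairing <- function(trace, standing_tells = NULL) {
  msgs <- trace_messages(trace)
  asks <- dplyr::filter(msgs, .data$performative == "ask")
  tells <- dplyr::filter(msgs, .data$performative == "tell")
  if (!nrow(asks)) return(asks)
  matched <- vapply(seq_len(nrow(asks)), function(i) {
    a <- asks[i, ]
    hit <- any(tells$sender == a$receiver & tells$receiver == a$sender &
                 tells$content == a$content & tells$tick >= a$tick)
    if (!hit && !is.null(standing_tells)) {
      hit <- any(standing_tells$agent == a$receiver &
                   standing_tells$content == a$content)
    }
    hit
  }, logical(1))
  asks[!matched, ]
}

#' Danger-level calculus
#'
#' The danger level is high (`"H"`) when exactly one of the two triggering
#' state formulas is detected, and escalates to severe (`"S"`) when both
#' hold together. With neither detected there is no danger level.
#'
#' @param phi_detected,psi_detected logical flags for the two state formulas.
#' @return `"H"`, `"S"`, or `NULL` when neither formula is detected.
#' @export
danger_level <- function(phi_detected, psi_detected) {
  stopifnot(is.logical(phi_detected), is.logical(psi_detected))
  if (phi_detected && psi_detected) return("S")
  if (phi_detected || psi_detected) return("H")
  NULL
}
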