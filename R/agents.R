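#' FIPA-style agent messages
#'
#' Messages carry a performative (`tell`, `ask` or `alert`), sender and
#' receiver agent ids, a free-text content field and the tick at which they
#' were sent. The encoded wire form mirrors the bracketed list layout used
#' by agent simulators:
#' `["Emergency Situation" "performative:alert" "sender:1" "content:"
#' "Abnormal BP Detected" "receiver:2" "tick:3"]`.
#'
#' @param performative one of `"tell"`, `"ask"`, `"alert"`.
#' @param sender,receiver distinct agent ids.
#' @param content message body; must not contain double quotes.
#' @param tick non-negative integer send time.
#' @return a one-row tibble with the five message fields.
#' @export
new_message <- function(performative = c("tell", "ask", "alert"),
                        sender, receiver, content, tick) {
  performative <- match.arg(performative)
  stopifnot(is.character(sender), is.character(receiver),
            nzchar(sender), nzchar(receiver))
  if (identical(sender, receiver)) abort("sender and receiver must differ")
  if (grepl('"', content)) abort("message content must not contain double quotes")
  tick <- as.integer(tick)
  if (is.na(tick) || tick < 0L) abort("tick must be a non-negative integer")
  tibble::tibble(performative = performative, sender = sender,
                 receiver = receiver, content = as.character(content),
                 tick = tick)
}

subject_for <- function(performative) {
  c(alert = "Emergency Situation", tell = "Information", ask = "Query")[[performative]]
}

#' @rdname new_message
#' @param msg a one-row message tibble.
#' @export
encode_message <- function(msg) {
  msg <- tibble::as_tibble(msg)
  stopifnot(nrow(msg) == 1L)
  sprintf('["%s" "performative:%s" "sender:%s" "content:" "%s" "receiver:%s" "tick:%d"]',
          subject_for(msg$performative), msg$performative, msg$sender,
          msg$content, msg$receiver, msg$tick)
}

#' @rdname new_message
#' @param text an encoded message string.
#' @export
decode_message <- function(text) {
  pat <- paste0('^\\["([^"]*)" "performative:(tell|ask|alert)" "sender:([^"]*)" ',
                '"content:" "([^"]*)" "receiver:([^"]*)" "tick:([0-9]+)"\\]$')
  m <- regmatches(text, regexec(pat, text))[[1]]
  if (!length(m)) abort("malformed message string")
  new_message(performative = m[3], sender = m[4], receiver = m[6],
              content = m[5], tick = as.integer(m[7]))
}

#' Sensor agents from a spec table
#'
#' One agent per sensor: patient-care (`PC_Agent`) vitals and environmental
#' (`Env_Agent`) sensors, each owning its sensor's inclusive normal range.
#' Rule-instance priorities default to PC over Env, reflecting that patient
#' care outranks environmental monitoring when conflicts are resolved.
#'
#' @param specs a [default_specs()]-shaped tibble.
#' @param priorities named numeric vector of per-group default priorities.
#' @return agent tibble (`id`, `sensor`, `group`, `lo`, `hi`, `unit`,
#'   `context`, `priority`, `severe_above`).
#' @export
sensor_agents <- function(specs = default_specs(),
                          priorities = c(PC_Agent = 2, Env_Agent = 1)) {
  dplyr::transmute(specs,
                   id = paste0(.data$sensor, "_agent"),
                   sensor = .data$sensor, group = .data$group,
                   lo = .data$lo, hi = .data$hi, unit = .data$unit,
                   context = .data$context,
                   priority = as.integer(priorities[.data$group]),
                   severe_above = .data$severe_above)
}

#' Observe one reading with one agent
#'
#' Implements the data-acquisition step: boundary values are normal
#' (the range is inclusive), and an alert message to the controller is
#' produced exactly when the value falls strictly outside `[lo, hi]`.
#'
#' @param agent one row of [sensor_agents()].
#' @param reading one row of a [generate_stream()] tibble.
#' @param controller id of the controller agent the alert is addressed to.
#' @return a one-row alert message tibble, or `NULL` for an in-range value.
#' @export
observe <- function(agent, reading, controller = "controller") {
  agent <- tibble::as_tibble(agent); reading <- tibble::as_tibble(reading)
  stopifnot(nrow(agent) == 1L, nrow(reading) == 1L)
  if (!identical(agent$sensor, reading$sensor)) {
    abort(paste0("sensor mismatch: agent monitors ", agent$sensor,
                 ", reading is for ", reading$sensor))
  }
  if (!identical(agent$unit, reading$unit)) {
    abort(paste0("unit mismatch for ", agent$sensor, ": expected ", agent$unit,
                 ", got ", reading$unit))
  }
  if (!is.finite(reading$value)) abort("non-finite sensor value")
  if (reading$value >= agent$lo && reading$value <= agent$hi) return(NULL)
  new_message("alert", sender = agent$id, receiver = controller,
              content = paste0("Abnormal ", agent$sensor, " Detected"),
              tick = reading$tick)
}

#' Conflicting-rule-set construction
#'
#' When several rule instances fire at the same tick, the instances whose
#' head literals contradict each other (complementary heads) are gathered
#' into the conflicting rule set; instances that conflict with nothing stay
#' out and act on their own. A single fired rule, or a set with no
#' conflicting pair, yields no conflict set at all.
#'
#' @param fired tibble of fired rule instances with columns `rule_id`,
#'   `group`, `priority`, `head`.
#' @param tick the tick at which they fired.
#' @return `NULL`, or a list (`members` tibble, `tick`) of class `cdl_crs`.
#' @export
build_crs <- function(fired, tick) {
  fired <- tibble::as_tibble(fired)
  if (nrow(fired) <= 1L) return(NULL)
  conflicts <- vapply(seq_len(nrow(fired)), function(i)
    any(fired$head[-i] == lit_complement(fired$head[i])), logical(1))
  if (!any(conflicts)) return(NULL)
  members <- dplyr::arrange(fired[conflicts, ], .data$rule_id)
  structure(list(members = members, tick = as.integer(tick)), class = "cdl_crs")
}

#' Select the rule instance that acts
#'
#' The winner is the maximum of a total order: numeric priority first
#' (highest wins), then agent group (`PC_Agent` beats `Env_Agent`), then
#' lexicographic rule id — so the selection is deterministic and
#' permutation-invariant.
#'
#' @param crs a [build_crs()] result, or a bare instance tibble.
#' @return the single winning instance row.
#' @export
select_rule <- function(crs) {
  members <- if (inherits(crs, "cdl_crs")) crs$members else tibble::as_tibble(crs)
  if (!nrow(members)) abort("empty conflicting rule set")
  grp <- match(members$group, c("PC_Agent", "Env_Agent"))
  if (anyNA(grp)) abort(paste0("unknown agent group: ", members$group[is.na(grp)][1]))
  members[order(-members$priority, grp, members$rule_id)[1], ]
}

#' Authorities alerted for a rule instance
#'
#' Patient-care instances alert the medical chain (doctor, caretaker, next
#' of kin); environmental instances alert the civil chain (fire department,
#' emergency response unit, police department).
#'
#' @param instance a one-row instance tibble with a `group` column.
#' @return character vector of authorities.
#' @export
route_alert <- function(instance) {
  instance <- tibble::as_tibble(instance)
  stopifnot(nrow(instance) == 1L)
  switch(instance$group,
         PC_Agent = c("doctor", "caretaker", "next_of_kin"),
         Env_Agent = c("fire_department", "emergency_response_unit",
                       "police_department"),
         abort(paste0("unknown agent group: ", instance$group)))
}

empty_trace <- function() {
  tibble::tibble(tick = integer(), kind = character(), payload = list())
}

# internal event representation: a bare list row, materialized by world_trace()
event_row <- function(tick, kind, payload) {
  list(tick = as.integer(tick), kind = kind, payload = payload)
}

#' Materialize a world's event log as a trace tibble
#'
#' Events are stored in insertion order; ticks are non-decreasing and events
#' within a tick keep the deterministic order in which the monitoring cycle
#' produced them.
#'
#' @param world a [make_world()] object.
#' @return a trace tibble (`tick`, `kind`, `payload` list-column).
#' @export
world_trace <- function(world) {
  ev <- world$events
  if (!length(ev)) return(empty_trace())
  tibble::tibble(tick = vapply(ev, `[[`, 1L, "tick"),
                 kind = vapply(ev, `[[`, "", "kind"),
                 payload = lapply(ev, `[[`, "payload"))
}

#' Create a monitoring world
#'
#' Bundles the agents, the controller, the halt flag and an initially empty
#' trace. *Claim rules* say which decision literal each sensor supports when
#' its reading is normal or abnormal; the default roster claims `emergency`
#' on any abnormal reading, at the agent's group priority.
#'
#' @param agents a [sensor_agents()] tibble.
#' @param claims claim-rule tibble (`rule_id`, `sensor`, `trigger` in
#'   `normal`/`abnormal`, `head`, `priority`, `group`); defaults to
#'   [default_claims()].
#' @param controller controller agent id.
#' @return a `cdl_world` list.
#' @export
make_world <- function(agents, claims = default_claims(agents),
                       controller = "controller") {
  agents <- dplyr::arrange(tibble::as_tibble(agents), .data$id)
  structure(list(agents = agents, claims = tibble::as_tibble(claims),
                 controller = controller, flag = 0L, state = "RUNNING",
                 tick = 0L, events = list()),
            class = "cdl_world")
}

#' @rdname make_world
#' @export
default_claims <- function(agents) {
  dplyr::transmute(agents,
                   rule_id = paste0("r_", .data$sensor),
                   sensor = .data$sensor, trigger = "abnormal",
                   head = "emergency", priority = .data$priority,
                   group = .data$group)
}

#' Halt-flag semantics
#'
#' The flag is set from outside the system by the alerted authority. Value 1
#' means the authority has taken over: the world halts and processes no
#' further observations until an explicit reboot. Value 0 means no takeover:
#' the world keeps gathering contextual information. `world_reboot()`
#' returns a halted world to `RUNNING` with the flag and any pending
#' conflict state cleared.
#'
#' @param world a [make_world()] object.
#' @param value 0 or 1.
#' @return the updated world.
#' @export
step_flag <- function(world, value) {
  stopifnot(inherits(world, "cdl_world"), value %in% c(0L, 1L))
  world$flag <- as.integer(value)
  world$state <- if (value == 1L) "HALTED" else "RUNNING"
  world$events[[length(world$events) + 1L]] <- event_row(
    world$tick, "flag", list(flag = as.integer(value), state = world$state))
  world
}

#' @rdname step_flag
#' @export
world_reboot <- function(world) {
  stopifnot(inherits(world, "cdl_world"))
  world$flag <- 0L
  world$state <- "RUNNING"
  world$events[[length(world$events) + 1L]] <- event_row(
    world$tick, "flag", list(flag = 0L, state = "RUNNING", reboot = TRUE))
  world
}

#' Advance the world by one tick of readings
#'
#' Runs the monitoring cycle: every agent observes its reading (agent id
#' order), abnormal readings send alert messages to the controller, the
#' fired claim instances are checked for conflicts (conflicting-rule-set
#' construction), the winning instance is selected and its authorities are
#' routed, and every event is appended to the trace in a fixed order. When
#' an alert fires the controller also asks the source agent to confirm and
#' receives a tell back, so the trace exercises the ask/tell protocol.
#' A halted world ignores readings entirely (no-op).
#'
#' @param world a [make_world()] object.
#' @param readings tibble of one reading per agent sensor, all at one tick.
#' @return the updated world; cumulated events via [world_trace()].
#' @export
run_tick <- function(world, readings) {
  stopifnot(inherits(world, "cdl_world"))
  if (world$state == "HALTED") return(world)
  readings <- tibble::as_tibble(readings)
  stopifnot(nrow(readings) >= 1L, length(unique(readings$tick)) == 1L)
  tick <- as.integer(readings$tick[1])
  world$tick <- tick
  ag <- world$agents
  m <- match(ag$sensor, readings$sensor)
  present <- which(!is.na(m))
  value <- readings$value[m]
  if (any(bad <- readings$unit[m][present] != ag$unit[present])) {
    abort(paste0("unit mismatch for ", ag$sensor[present][bad][1]))
  }
  if (any(!is.finite(value[present]))) abort("non-finite sensor value")
  ev <- world$events
  push <- function(e) ev[[length(ev) + 1L]] <<- e
  is_abn <- !is.na(m) & (value < ag$lo | value > ag$hi)
  for (i in present) {
    push(event_row(tick, "observation",
                   list(agent = ag$id[i], sensor = ag$sensor[i],
                        value = value[i], unit = ag$unit[i])))
  }
  for (i in which(is_abn)) {
    push(event_row(tick, "message",
                   list(performative = "alert", sender = ag$id[i],
                        receiver = world$controller,
                        content = paste0("Abnormal ", ag$sensor[i], " Detected"),
                        tick = tick)))
  }
  abnormal <- ag$sensor[is_abn]
  # fired claim instances for this tick's normal/abnormal pattern
  cl <- world$claims
  keep <- cl$sensor %in% readings$sensor &
    ((cl$trigger == "abnormal" & cl$sensor %in% abnormal) |
       (cl$trigger == "normal" & !cl$sensor %in% abnormal))
  fired <- cl[keep, c("rule_id", "group", "priority", "head", "sensor")]
  crs <- build_crs(fired, tick)
  acted <- fired
  if (!is.null(crs)) {
    winner <- select_rule(crs)
    push(event_row(tick, "crs",
                   list(members = crs$members$rule_id, selected = winner$rule_id)))
    acted <- rbind(fired[!fired$rule_id %in% crs$members$rule_id, ], winner)
    acted <- acted[order(acted$rule_id), ]
  }
  # alerts: acted instances triggered by an abnormal reading
  alerting <- acted[acted$sensor %in% abnormal, ]
  phi <- any(ag$group[is_abn] == "PC_Agent")
  psi <- any(ag$group[is_abn] == "Env_Agent")
  base_severity <- switch(danger_level(phi, psi) %||% "none",
                          H = "high", S = "severe", "normal")
  for (j in seq_len(nrow(alerting))) {
    inst <- alerting[j, ]
    i <- which(ag$sensor == inst$sensor)[1]
    severity <- base_severity
    if (!is.na(ag$severe_above[i]) && value[i] >= ag$severe_above[i]) {
      severity <- "severe"
    }
    push(event_row(tick, "alert",
                   list(source = ag$id[i], literal = inst$head,
                        rule_id = inst$rule_id, severity = severity,
                        route = route_alert(inst))))
    push(event_row(tick, "message",
                   list(performative = "ask", sender = world$controller,
                        receiver = ag$id[i], content = inst$head, tick = tick)))
    push(event_row(tick, "message",
                   list(performative = "tell", sender = ag$id[i],
                        receiver = world$controller, content = inst$head,
                        tick = tick)))
  }
  world$events <- ev
  world
}

#' @export
print.cdl_world <- function(x, ...) {
  cat("<cdl_world> ", nrow(x$agents), " agents, state ", x$state,
      ", flag ", x$flag, ", ", length(x$events), " trace events\n", sep = "")
  invisible(x)
}
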