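agents <- sensor_agents()
agent_row <- function(kind) agents[agents$sensor == kind, ]
reading <- function(kind, value, tick = 1L) {
  sp <- default_specs()
  tibble::tibble(tick = as.integer(tick), sensor = kind, value = value,
                 unit = sp$unit[sp$sensor == kind])
}

test_that("observe alerts exactly on strictly out-of-range values", {
  hr <- agent_row("heart_rate")
  expect_null(observe(hr, reading("heart_rate", 82)))
  msg <- observe(hr, reading("heart_rate", 59))
  expect_identical(msg$performative, "alert")
  expect_identical(msg$receiver, "controller")
  expect_match(msg$content, "Abnormal heart_rate")
  # inclusive boundaries are normal
  expect_null(observe(hr, reading("heart_rate", 60)))
  expect_null(observe(hr, reading("heart_rate", 100)))
  expect_null(observe(agent_row("body_temperature"),
                      reading("body_temperature", 99)))
  # a CO reading at the 30 ppm danger threshold is far outside its range
  expect_s3_class(observe(agent_row("co"), reading("co", 30)), "tbl_df")
})

test_that("observe validates sensor, unit and finiteness", {
  hr <- agent_row("heart_rate")
  expect_error(observe(hr, reading("co", 2)), "sensor mismatch")
  bad_unit <- reading("heart_rate", 70)
  bad_unit$unit <- "Hz"
  expect_error(observe(hr, bad_unit), "unit mismatch")
  expect_error(observe(hr, reading("heart_rate", NaN)), "non-finite")
})

test_that("messages round-trip through the wire encoding", {
  m <- new_message("alert", "1", "2", "Abnormal BP Detected", 3L)
  enc <- encode_message(m)
  expect_match(enc, '"sender:1"', fixed = TRUE)
  expect_match(enc, '"receiver:2"', fixed = TRUE)
  expect_match(enc, "Emergency Situation", fixed = TRUE)
  expect_identical(decode_message(enc), m)

  set.seed(42)
  for (i in 1:25) {
    m <- new_message(sample(c("tell", "ask", "alert"), 1),
                     sample(letters, 1), sample(LETTERS, 1),
                     paste(sample(c(letters, " ", ":", "."), 12, TRUE),
                           collapse = ""),
                     sample(0:500, 1))
    expect_identical(decode_message(encode_message(m)), m)
  }
  expect_error(decode_message("garbage"), "malformed")
  expect_error(new_message("tell", "a", "a", "x", 1), "must differ")
  expect_error(new_message("tell", "a", "b", 'has "quotes"', 1), "quotes")
  expect_error(new_message("tell", "a", "b", "x", -1), "non-negative")
})

instance <- function(id, group = "PC_Agent", priority = 1L, head = "emergency",
                     sensor = "heart_rate") {
  tibble::tibble(rule_id = id, group = group, priority = as.integer(priority),
                 head = head, sensor = sensor)
}

test_that("conflict sets contain exactly the mutually conflicting instances", {
  expect_null(build_crs(instance("r1"), tick = 1))
  two <- dplyr::bind_rows(instance("r1", head = "emergency"),
                          instance("r2", head = "~emergency"))
  crs <- build_crs(two, tick = 2)
  expect_identical(nrow(crs$members), 2L)
  # two conflicting + one independent: the independent one stays out
  three <- dplyr::bind_rows(two, instance("r3", head = "hazard"))
  crs <- build_crs(three, tick = 3)
  expect_setequal(crs$members$rule_id, c("r1", "r2"))
  # pairwise-conflict oracle over every member
  for (i in seq_len(nrow(crs$members))) {
    expect_true(any(crs$members$head[-i] ==
                      lit_complement(crs$members$head[i])))
  }
  # multiple rules but no conflicting pair
  expect_null(build_crs(dplyr::bind_rows(instance("r1"),
                                         instance("r3", head = "hazard")),
                        tick = 4))
})

test_that("rule selection follows priority, then PC over Env, then id", {
  cands <- dplyr::bind_rows(instance("r_lo", priority = 2),
                            instance("r_hi", priority = 5, head = "~emergency"))
  expect_identical(select_rule(build_crs(cands, 1))$rule_id, "r_hi")
  tie_groups <- dplyr::bind_rows(
    instance("r_env", group = "Env_Agent", priority = 3, head = "~emergency"),
    instance("r_pc", group = "PC_Agent", priority = 3))
  expect_identical(select_rule(build_crs(tie_groups, 1))$rule_id, "r_pc")
  expect_identical(select_rule(instance("only"))$rule_id, "only")
  # permutation invariance
  set.seed(1)
  base <- dplyr::bind_rows(instance("r_a", priority = 2),
                           instance("r_b", priority = 2, head = "~emergency"),
                           instance("r_c", group = "Env_Agent", priority = 2))
  picks <- vapply(1:10, function(i)
    select_rule(base[sample(nrow(base)), ])$rule_id, "")
  expect_identical(unique(picks), "r_a")
  expect_error(select_rule(instance("x")[0, ]), "empty")
})

test_that("authority routing is fixed per agent group", {
  expect_identical(route_alert(instance("r", group = "PC_Agent")),
                   c("doctor", "caretaker", "next_of_kin"))
  expect_identical(route_alert(instance("r", group = "Env_Agent")),
                   c("fire_department", "emergency_response_unit",
                     "police_department"))
  expect_error(route_alert(instance("r", group = "Robot_Agent")),
               "unknown agent group")
})

tick_readings <- function(tick, overrides = list()) {
  sp <- default_specs()
  value <- sp$baseline
  for (k in names(overrides)) value[sp$sensor == k] <- overrides[[k]]
  tibble::tibble(tick = as.integer(tick), sensor = sp$sensor, value = value,
                 unit = sp$unit)
}

test_that("a quiet tick logs observations only; an anomaly alerts its route", {
  w <- make_world(agents)
  w <- run_tick(w, tick_readings(1))
  tr <- world_trace(w)
  expect_identical(unique(tr$kind), "observation")
  expect_identical(nrow(tr), nrow(agents))

  w <- run_tick(w, tick_readings(2, list(body_temperature = 103)))
  tr <- world_trace(w)
  alerts <- tr[tr$kind == "alert", ]
  expect_identical(nrow(alerts), 1L)
  p <- alerts$payload[[1]]
  expect_identical(p$source, "body_temperature_agent")
  expect_identical(p$route, c("doctor", "caretaker", "next_of_kin"))
  expect_identical(p$severity, "high")
  # the alert message reached the controller first
  msgs <- tr[tr$kind == "message", ]
  expect_true(any(vapply(msgs$payload, function(m)
    m$performative == "alert" && m$receiver == "controller", logical(1))))
})

test_that("alert emission matches per-reading observe on random ticks", {
  set.seed(7)
  for (i in 1:10) {
    rd <- tick_readings(i)
    # randomly knock some sensors out of range
    knock <- runif(nrow(rd)) < 0.3
    rd$value[knock] <- rd$value[knock] + 1e6
    w <- run_tick(make_world(agents), rd)
    tr <- world_trace(w)
    emitted <- sort(vapply(
      tr$payload[tr$kind == "message"],
      function(p) if (p$performative == "alert") p$sender else NA_character_,
      NA_character_))
    expected <- sort(unlist(lapply(seq_len(nrow(agents)), function(j) {
      m <- observe(agents[j, ], rd[rd$sensor == agents[j, ]$sensor, ])
      if (is.null(m)) NULL else m$sender
    })))
    expect_identical(emitted[!is.na(emitted)], expected)
  }
})

test_that("conflicting PC and Env instances at equal priority yield one PC alert", {
  eq_agents <- sensor_agents(priorities = c(PC_Agent = 1, Env_Agent = 1))
  claims <- default_claims(eq_agents)
  claims$head[claims$sensor == "co"] <- "~emergency"
  w <- make_world(eq_agents, claims = claims)
  w <- run_tick(w, tick_readings(1, list(heart_rate = 130, co = 40)))
  tr <- world_trace(w)
  alerts <- tr[tr$kind == "alert", ]
  expect_identical(nrow(alerts), 1L)
  expect_identical(alerts$payload[[1]]$source, "heart_rate_agent")
  expect_identical(alerts$payload[[1]]$route[1], "doctor")
  crs_ev <- tr[tr$kind == "crs", ]
  expect_identical(nrow(crs_ev), 1L)
  expect_setequal(crs_ev$payload[[1]]$members, c("r_heart_rate", "r_co"))
})

test_that("the halt flag freezes the world until reboot", {
  w <- make_world(agents)
  w <- run_tick(w, tick_readings(1))
  w <- step_flag(w, 1L)
  expect_identical(w$state, "HALTED")
  n_before <- length(w$events)
  w <- run_tick(w, tick_readings(2, list(heart_rate = 200)))
  expect_identical(length(w$events), n_before)  # no-op while halted
  w <- world_reboot(w)
  expect_identical(w$state, "RUNNING")
  expect_identical(w$flag, 0L)
  w <- run_tick(w, tick_readings(3, list(heart_rate = 200)))
  tr <- world_trace(w)
  expect_identical(sum(tr$kind == "alert"), 1L)
  expect_true(all(tr$tick[tr$kind == "alert"] == 3L))
})

test_that("severity escalates when both patient and environment misbehave", {
  w <- run_tick(make_world(agents),
                tick_readings(1, list(heart_rate = 130, co2 = 5000)))
  tr <- world_trace(w)
  sev <- vapply(tr$payload[tr$kind == "alert"], `[[`, "", "severity")
  expect_true(all(sev == "severe"))
  # CO at its own escalation threshold is severe even alone
  w2 <- run_tick(make_world(agents), tick_readings(1, list(co = 30)))
  tr2 <- world_trace(w2)
  sev2 <- vapply(tr2$payload[tr2$kind == "alert"], `[[`, "", "severity")
  expect_identical(sev2, "severe")
})
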