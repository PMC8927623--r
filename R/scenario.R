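#' Load and validate a scenario configuration
#'
#' A scenario YAML wires the whole system together: which sensors run (all
#' ten by default), the agent group priorities, extra claim rules, the
#' contexts with their inline theories, the mapping rules between contexts,
#' the anomaly schedule, authority flag/reboot events, the seed and the run
#' length. Validation resolves every cross-reference (scheduled sensors,
#' claim sensors, agent contexts, mapping targets) and reports all problems
#' at once.
#'
#' @param path path to a scenario YAML file.
#' @return a validated `cdl_scenario` object.
#' @seealso the bundled `parkinsons_case_study.yaml` and
#'   `netlogo_replica.yaml` under `system.file("extdata", package =
#'   "cdlsentinel")`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  scenario_from_list(yaml::yaml.load_file(path))
}

#' @rdname load_scenario
#' @param doc a list with the same structure as the YAML document.
#' @export
scenario_from_list <- function(doc) {
  stopifnot(is.list(doc))
  specs <- default_specs()
  if (!is.null(doc$sensors)) {
    specs <- dplyr::filter(specs, .data$sensor %in% unlist(doc$sensors))
  }
  priorities <- c(PC_Agent = 2, Env_Agent = 1)
  if (!is.null(doc$priorities)) {
    priorities[names(doc$priorities)] <- unlist(doc$priorities)
  }
  agents <- sensor_agents(specs, priorities)
  claims <- default_claims(agents)
  if (!is.null(doc$claims)) {
    extra <- dplyr::bind_rows(purrr::map(doc$claims, function(cl) {
      tibble::tibble(rule_id = cl$rule_id, sensor = cl$sensor,
                     trigger = cl$trigger %||% "abnormal",
                     head = cl$head %||% "emergency",
                     priority = as.integer(cl$priority %||% 0L),
                     group = cl$group %||% "PC_Agent")
    }))
    claims <- dplyr::bind_rows(claims, extra)
  }
  contexts <- purrr::map(doc$contexts, function(cx) {
    dfl_context(cx$id, theory_from_list(cx$theory),
                rank = cx$rank %||% NA_integer_)
  })
  mappings <- if (length(doc$mappings)) {
    dplyr::bind_rows(purrr::map(doc$mappings, function(m) {
      dfl_mapping(m$id, m$owner, as.character(unlist(m$body)), m$head,
                  priority = m$priority %||% 0L)
    }))
  } else {
    NULL
  }
  schedule <- if (length(doc$schedule)) {
    anomaly_schedule(
      tick = vapply(doc$schedule, function(s) as.integer(s$tick), 1L),
      sensor = vapply(doc$schedule, function(s) as.character(s$sensor), ""),
      value = vapply(doc$schedule, function(s) as.numeric(s$value), 1))
  } else {
    anomaly_schedule()
  }
  authority_events <- if (length(doc$authority_events)) {
    dplyr::bind_rows(purrr::map(doc$authority_events, function(e) {
      tibble::tibble(tick = as.integer(e$tick),
                     action = e$action %||% "flag",
                     value = as.integer(e$value %||% 0L))
    }))
  } else {
    tibble::tibble(tick = integer(), action = character(), value = integer())
  }
  cfg <- structure(list(
    name = doc$name %||% "scenario",
    seed = doc$seed, ticks = doc$ticks,
    heartbeat_interval = doc$heartbeat_interval %||% 0L,
    specs = specs, agents = agents, claims = claims,
    contexts = contexts, mappings = mappings,
    schedule = schedule, authority_events = authority_events,
    contradiction = doc$contradiction), class = "cdl_scenario")
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  errs <- character()
  if (is.null(cfg$seed)) errs <- c(errs, "scenario must set a seed")
  if (is.null(cfg$ticks) || cfg$ticks < 1) errs <- c(errs, "scenario must set ticks >= 1")
  unknown <- setdiff(cfg$schedule$sensor, cfg$specs$sensor)
  if (length(unknown)) {
    errs <- c(errs, paste0("schedule references unknown sensor: ",
                           paste(unknown, collapse = ", ")))
  }
  unknown <- setdiff(cfg$claims$sensor, cfg$specs$sensor)
  if (length(unknown)) {
    errs <- c(errs, paste0("claim rule references unknown sensor: ",
                           paste(unknown, collapse = ", ")))
  }
  ctx_ids <- vapply(cfg$contexts, `[[`, "", "id")
  unknown <- setdiff(cfg$agents$context, ctx_ids)
  if (length(ctx_ids) && length(unknown)) {
    errs <- c(errs, paste0("agent context not defined: ",
                           paste(unknown, collapse = ", ")))
  }
  bad <- cfg$authority_events$action[!cfg$authority_events$action %in% c("flag", "reboot")]
  if (length(bad)) errs <- c(errs, paste0("unknown authority action: ", bad[1]))
  if (length(errs)) abort(paste0("invalid scenario:\n- ", paste(errs, collapse = "\n- ")))
  if (length(cfg$contexts)) build_mcs(cfg$contexts, cfg$mappings)  # mapping refs
  cfg
}

#' @export
print.cdl_scenario <- function(x, ...) {
  cat("<cdl_scenario> ", x$name, ": ", nrow(x$agents), " sensor agents, ",
      length(x$contexts), " contexts, seed ", x$seed, ", ", x$ticks,
      " ticks\n", sep = "")
  invisible(x)
}

stream_seed <- function(seed, i) as.integer((as.numeric(seed) * 131 + i) %% 2147483629)

# MCS with the tick's normal/abnormal observations asserted as facts.
mcs_with_observations <- function(contexts, mappings, agents, abnormal) {
  ctxs <- purrr::map(contexts, function(cx) {
    mine <- agents[agents$context == cx$id, ]
    facts <- paste0(ifelse(mine$sensor %in% abnormal, "abnormal_", "normal_"),
                    mine$sensor)
    dfl_context(cx$id,
                dfl_theory(facts = union(cx$theory$facts, facts),
                           rules = cx$theory$rules,
                           superiority = cx$theory$superiority),
                rank = cx$rank)
  })
  build_mcs(ctxs, mappings)
}

#' Run a monitoring scenario end to end
#'
#' Generates one synthetic stream per sensor (per-sensor seeds derived from
#' the scenario seed, so a fixed seed reproduces the run byte for byte),
#' then advances the agent world tick by tick: authority flag/reboot events
#' are applied first, a heartbeat event is logged at the configured
#' interval, agents observe and alert, conflicting rule sets are resolved
#' and authorities routed. At each monitored tick the multi-context system
#' is re-checked for equilibrium with the tick's normal/abnormal
#' observations asserted as context facts.
#'
#' @param config a [load_scenario()] object.
#' @param seed optional seed override.
#' @param ticks optional run-length override.
#' @return a `cdl_run` with fields `trace`, `alerts`, `alert_counts`,
#'   `equilibrium`, `readings`, `exit_state`, `flag`.
#' @export
run_scenario <- function(config, seed = NULL, ticks = NULL) {
  stopifnot(inherits(config, "cdl_scenario"))
  seed <- seed %||% config$seed
  ticks <- as.integer(ticks %||% config$ticks)
  specs <- config$specs
  streams <- purrr::map(seq_len(nrow(specs)), function(i)
    generate_stream(specs[i, ], ticks, seed = stream_seed(seed, i),
                    schedule = config$schedule))
  names(streams) <- specs$sensor
  if (!is.null(config$contradiction)) {
    cc <- config$contradiction
    streams <- inject_contradiction(
      streams, specs, tick = cc$tick,
      calm_sensor = cc$calm_sensor %||% "co",
      calm_value = cc$calm_value %||% 2,
      alarm_sensor = cc$alarm_sensor %||% "heart_rate",
      alarm_value = cc$alarm_value %||% 130)
  }
  readings <- dplyr::arrange(dplyr::bind_rows(streams), .data$tick, .data$sensor)
  by_tick <- split(readings, readings$tick)
  world <- make_world(config$agents, claims = config$claims)
  has_mcs <- length(config$contexts) > 0
  eq_cache <- list()
  eq_rows <- vector("list", ticks)
  hb <- config$heartbeat_interval
  for (t in seq_len(ticks)) {
    evs <- config$authority_events[config$authority_events$tick == t, ]
    for (k in seq_len(nrow(evs))) {
      world$tick <- t
      world <- if (evs$action[k] == "reboot") world_reboot(world)
               else step_flag(world, evs$value[k])
    }
    if (world$state == "HALTED") {
      if (has_mcs) eq_rows[[t]] <- tibble::tibble(tick = t, consistent = NA,
                                                  n_conflicts = NA_integer_)
      next
    }
    if (hb > 0 && t %% hb == 0) {
      world$events[[length(world$events) + 1L]] <- event_row(
        t, "heartbeat", list(status = "Continuously Monitoring"))
    }
    rt <- by_tick[[t]]
    world <- run_tick(world, rt)
    if (has_mcs) {
      abn <- abnormal_sensors(config$agents, rt)
      key <- paste0("abn:", paste(abn, collapse = "|"))
      if (is.null(eq_cache[[key]])) {
        mcs_t <- mcs_with_observations(config$contexts, config$mappings,
                                       config$agents, abn)
        eq_cache[[key]] <- equilibrium_check(mcs_t)
      }
      eq <- eq_cache[[key]]
      eq_rows[[t]] <- tibble::tibble(tick = t, consistent = eq$consistent,
                                     n_conflicts = nrow(eq$conflicts))
    }
  }
  trace <- world_trace(world)
  alerts <- alert_table(trace)
  structure(list(
    name = config$name, seed = seed, ticks = ticks,
    trace = trace, alerts = alerts,
    alert_counts = dplyr::count(alerts, .data$route_group, name = "alerts"),
    equilibrium = if (has_mcs) dplyr::bind_rows(eq_rows) else NULL,
    readings = readings,
    exit_state = world$state, flag = world$flag), class = "cdl_run")
}

abnormal_sensors <- function(agents, readings) {
  m <- match(readings$sensor, agents$sensor)
  out <- !is.na(m) &
    (readings$value < agents$lo[m] | readings$value > agents$hi[m])
  sort(readings$sensor[out])
}

alert_table <- function(trace) {
  rows <- trace[trace$kind == "alert", ]
  if (!nrow(rows)) {
    return(tibble::tibble(tick = integer(), source = character(),
                          literal = character(), severity = character(),
                          route = character(), route_group = character()))
  }
  dplyr::bind_rows(purrr::map(seq_len(nrow(rows)), function(i) {
    p <- rows$payload[[i]]
    tibble::tibble(tick = rows$tick[i], source = p$source, literal = p$literal,
                   severity = p$severity,
                   route = paste(p$route, collapse = ","),
                   route_group = if (identical(p$route[1], "doctor"))
                     "medical" else "civil")
  }))
}

#' @export
print.cdl_run <- function(x, ...) {
  cat("<cdl_run> ", x$name, " (seed ", x$seed, ", ", x$ticks, " ticks): ",
      nrow(x$alerts), " alerts, exit ", x$exit_state, "\n", sep = "")
  if (!is.null(x$equilibrium)) {
    ok <- x$equilibrium$consistent
    cat("equilibrium held at ", sum(ok, na.rm = TRUE), "/", sum(!is.na(ok)),
        " monitored ticks\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cdl_run <- function(x, ...) x$alerts

#' @exportS3Method generics::glance
glance.cdl_run <- function(x, ...) {
  eq <- x$equilibrium
  tibble::tibble(
    name = x$name, seed = x$seed, ticks = x$ticks,
    n_events = nrow(x$trace), n_alerts = nrow(x$alerts),
    n_messages = sum(x$trace$kind == "message"),
    equilibrium_ok = if (is.null(eq)) NA else
      all(eq$consistent[!is.na(eq$consistent)]),
    exit_state = x$exit_state, flag = x$flag)
}

#' Plot a run: sensor streams, normal bands and alerts
#'
#' @param object a `cdl_run`.
#' @param sensors optional subset of sensors to show.
#' @param ... ignored.
#' @return a ggplot object: one facet per sensor, shaded normal range,
#'   vertical dashed lines at alert ticks.
#' @exportS3Method ggplot2::autoplot
autoplot.cdl_run <- function(object, sensors = NULL, ...) {
  readings <- object$readings
  if (!is.null(sensors)) {
    readings <- dplyr::filter(readings, .data$sensor %in% sensors)
  }
  bands <- dplyr::distinct(
    dplyr::select(sensor_agents(), "sensor", "lo", "hi"))
  bands <- dplyr::semi_join(bands, readings, by = "sensor")
  alert_ticks <- object$alerts
  p <- ggplot2::ggplot(readings, ggplot2::aes(x = .data$tick, y = .data$value)) +
    ggplot2::geom_rect(data = bands, inherit.aes = FALSE,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = .data$lo, ymax = .data$hi),
                       fill = "grey85", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~sensor, scales = "free_y") +
    ggplot2::labs(x = "tick", y = NULL,
                  title = paste0(object$name, " (seed ", object$seed, ")"))
  if (nrow(alert_ticks)) {
    p <- p + ggplot2::geom_vline(data = alert_ticks,
                                 ggplot2::aes(xintercept = .data$tick),
                                 linetype = "dashed", colour = "red")
  }
  p
}

payload_json <- function(p) {
  as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA))
}

#' Export and re-import run artifacts
#'
#' `export_run()` writes either the full trace as JSON-lines (one event per
#' line: `{"tick":..,"kind":"..","payload":{..}}`) or the alert summary as
#' CSV. `read_trace_jsonl()` parses a JSONL trace back into the trace
#' tibble; export followed by import round-trips the trace exactly.
#'
#' @param result a `cdl_run` (or a bare trace tibble for `format =
#'   "jsonl"`).
#' @param path output file path.
#' @param format `"jsonl"` (trace) or `"csv"` (alert summary).
#' @return `path`, invisibly.
#' @export
export_run <- function(result, path, format = c("jsonl", "csv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0("unknown format: ", format[1])))
  trace <- if (inherits(result, "cdl_run")) result$trace else tibble::as_tibble(result)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(trace)), function(i)
      sprintf('{"tick":%d,"kind":"%s","payload":%s}', trace$tick[i],
              trace$kind[i], payload_json(trace$payload[[i]])), "")
    writeLines(lines, path)
  } else {
    alerts <- if (inherits(result, "cdl_run")) result$alerts else alert_table(trace)
    write.csv(alerts, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_run
#' @export
read_trace_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(empty_trace())
  rows <- purrr::map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  tibble::tibble(tick = vapply(rows, function(r) as.integer(r$tick), 1L),
                 kind = vapply(rows, function(r) as.character(r$kind), ""),
                 payload = purrr::map(rows, "payload"))
}
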