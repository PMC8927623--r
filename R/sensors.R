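#' Default sensor specifications for the monitoring case study
#'
#' One row per sensor kind with its unit, inclusive normal range
#' `[lo, hi]` (boundary values count as normal), a baseline mean used by the
#' stream generator, the agent group (`PC_Agent` for patient-care vitals,
#' `Env_Agent` for environmental sensors), the owning context, and optional
#' severity annotations.
#'
#' Documented clinical ranges: heart rate 60–100 bpm (typical 82),
#' body temperature 97–99 °F, ECG interval 0.6–1.2 s, EMG amplitude
#' 50 μV–30 mV (0.05–30 mV), EEG 8 Hz and above normal with 7 Hz or less
#' abnormal in awake adults (recorded as `abnormal_below`; the same 7 Hz
#' figure is sometimes attributed to EMG — it is kept on the EEG spec and
#' flagged here rather than silently reassigned). Carbon monoxide: 0.5–5 ppm
#' typical for homes with gas stoves, 5–15 ppm with a properly fixed stove
#' (the normal range is the union 0.5–15 ppm), and 30 ppm or more signals a
#' badly fitted stove — kept as the `severe_above` escalation threshold.
#'
#' Defaults without a documented case-study threshold (marked GENERIC in
#' the scenario configs; ordinary clinical/building norms): systolic BP 90–120 mmHg, diastolic BP 60–80 mmHg, CO2 350–1000
#' ppm, room temperature 18–27 °C, EEG upper bound 30 Hz.
#'
#' @return tibble with columns `sensor`, `unit`, `lo`, `hi`, `baseline`,
#'   `spread`, `group`, `context`, `severe_above`, `abnormal_below`.
#' @examples
#' default_specs()
#' @export
default_specs <- function() {
  spec <- function(sensor, unit, lo, hi, group, context,
                   baseline = (lo + hi) / 2, severe_above = NA_real_,
                   abnormal_below = NA_real_) {
    tibble::tibble(sensor = sensor, unit = unit, lo = lo, hi = hi,
                   baseline = baseline, spread = 0.1 * (hi - lo),
                   group = group, context = context,
                   severe_above = severe_above,
                   abnormal_below = abnormal_below)
  }
  dplyr::bind_rows(
    spec("systolic_bp", "mmHg", 90, 120, "PC_Agent", "smart_hospital"),
    spec("diastolic_bp", "mmHg", 60, 80, "PC_Agent", "smart_hospital"),
    spec("body_temperature", "F", 97, 99, "PC_Agent", "smart_hospital", baseline = 98.1),
    spec("heart_rate", "bpm", 60, 100, "PC_Agent", "smart_hospital", baseline = 82),
    spec("eeg", "Hz", 8, 30, "PC_Agent", "smart_hospital", abnormal_below = 7),
    spec("ecg_interval", "s", 0.6, 1.2, "PC_Agent", "smart_hospital", baseline = 0.9),
    spec("emg", "mV", 0.05, 30, "PC_Agent", "smart_hospital"),
    spec("co", "ppm", 0.5, 15, "Env_Agent", "smart_home", baseline = 2.5,
         severe_above = 30),
    spec("co2", "ppm", 350, 1000, "Env_Agent", "smart_home"),
    spec("room_temperature", "C", 18, 27, "Env_Agent", "smart_home")
  )
}

#' Build an anomaly schedule
#'
#' @param tick,sensor,value parallel vectors: at each `tick` the named
#'   sensor's reading is replaced verbatim by `value`.
#' @return tibble with columns `tick`, `sensor`, `value`.
#' @export
anomaly_schedule <- function(tick = integer(), sensor = character(),
                             value = numeric()) {
  stopifnot(length(tick) == length(sensor), length(sensor) == length(value),
            all(is.finite(value)) || !length(value))
  tibble::tibble(tick = as.integer(tick), sensor = as.character(sensor),
                 value = as.numeric(value))
}

#' Generate a synthetic sensor stream
#'
#' One reading per tick. Unscheduled ticks draw from a normal distribution
#' centred on the spec's baseline (spread = 10% of the range width by
#' default), truncated to the normal range so that, absent a schedule, no
#' reading can ever trigger an alert. Scheduled ticks take the scheduled
#' value exactly. The same seed always reproduces the same stream.
#'
#' @param spec a single row of [default_specs()] (or a compatible tibble).
#' @param ticks number of ticks (> 0); readings are at ticks `1..ticks`.
#' @param seed integer seed for this stream.
#' @param schedule an [anomaly_schedule()]; entries for other sensors are
#'   ignored, entries outside `1..ticks` are an error.
#' @return tibble with columns `tick`, `sensor`, `value`, `unit`.
#' @export
generate_stream <- function(spec, ticks, seed, schedule = anomaly_schedule()) {
  spec <- tibble::as_tibble(spec)
  stopifnot(nrow(spec) == 1L, ticks > 0)
  sched <- dplyr::filter(tibble::as_tibble(schedule), .data$sensor == spec$sensor)
  if (nrow(sched) && any(sched$tick < 1L | sched$tick > ticks)) {
    abort("schedule tick outside the run length")
  }
  values <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    rtruncnorm(ticks, spec$baseline, spec$spread, spec$lo, spec$hi)
  })
  if (nrow(sched)) values[sched$tick] <- sched$value
  tibble::tibble(tick = seq_len(ticks), sensor = spec$sensor,
                 value = values, unit = spec$unit)
}

# Inverse-CDF truncated normal; degenerate spread collapses to the mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(qnorm(p, mean, sd), lo), hi)
}

#' Inject a cross-context contradiction into a set of streams
#'
#' Overwrites two sensors in *different* contexts at one tick with values
#' chosen so that one context's rules support one sign of a decision literal
#' while the other context supports its complement (e.g. the smart home
#' reads a perfectly normal CO level and exports "all clear" while the
#' hospital sees a tachycardic heart rate and derives an emergency), forcing
#' the multi-context system to invoke priority-based conflict resolution.
#'
#' @param streams named list of stream tibbles (one per sensor) as produced
#'   by [generate_stream()].
#' @param specs the sensor spec table (for context membership checks).
#' @param tick tick at which to plant the contradiction.
#' @param calm_sensor,calm_value sensor forced to an in-range value.
#' @param alarm_sensor,alarm_value sensor forced to an out-of-range value.
#' @return the modified list of streams.
#' @export
inject_contradiction <- function(streams, specs, tick,
                                 calm_sensor = "co", calm_value = 2,
                                 alarm_sensor = "heart_rate", alarm_value = 130) {
  for (s in c(calm_sensor, alarm_sensor)) {
    if (!s %in% names(streams)) abort(paste0("no stream for sensor: ", s))
  }
  ctx <- setNames(specs$context, specs$sensor)
  if (ctx[[calm_sensor]] == ctx[[alarm_sensor]]) {
    abort("contradiction sensors must live in different contexts")
  }
  for (pair in list(c(calm_sensor, calm_value), c(alarm_sensor, alarm_value))) {
    st <- streams[[pair[1]]]
    if (!tick %in% st$tick) abort("tick outside the generated stream")
    st$value[st$tick == as.integer(tick)] <- as.numeric(pair[2])
    streams[[pair[1]]] <- st
  }
  streams
}
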