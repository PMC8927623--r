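# Shared fixture builders.

all_literals <- function(atoms) {
  if (!length(atoms)) return(character())
  c(atoms, paste0("~", atoms))
}

rules_of <- function(...) dplyr::bind_rows(...)

# Random theory restricted to positive literals, strict/defeasible rules and
# no defeaters: the regime where defeasible provability must coincide with
# plain forward chaining.
random_positive_theory <- function(seed, n_rules = 8, n_atoms = 5) {
  set.seed(seed)
  atoms <- letters[seq_len(sample(n_atoms, 1))]
  k <- sample(0:n_rules, 1)
  rules <- NULL
  if (k > 0) {
    rules <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      dfl_rule(sprintf("r%02d", i),
               kind = sample(c("strict", "defeasible"), 1),
               body = sample(atoms, min(length(atoms), sample(0:2, 1))),
               head = sample(atoms, 1),
               priority = sample(0:3, 1))
    }))
  }
  dfl_theory(facts = sample(atoms, min(length(atoms), sample(0:2, 1))),
             rules = rules)
}

# Random event trace over a small alphabet of kinds.
random_trace <- function(seed, max_ticks = 8) {
  set.seed(seed)
  n <- sample(0:max_ticks, 1)
  if (n == 0) {
    return(tibble::tibble(tick = integer(), kind = character(),
                          payload = list()))
  }
  kinds <- sample(c("observation", "message", "alert", "flag"), n, replace = TRUE)
  tibble::tibble(tick = sort(sample(1:max_ticks, n, replace = TRUE)),
                 kind = kinds, payload = replicate(n, list(), simplify = FALSE))
}

# Two-context home/hospital MCS used across the MCS tests: the home exports
# an all-clear or a CO alert, the hospital weighs them against its own
# heart-rate rule.
home_hospital_mcs <- function(home_facts = character(),
                              hospital_facts = character(),
                              local_priority = 2L, import_priority = 1L) {
  home <- dfl_context("smart_home", dfl_theory(
    facts = home_facts,
    rules = rules_of(
      dfl_rule("h_co_alert", "defeasible", "abnormal_co", "co_alert", 1L),
      dfl_rule("h_all_clear", "defeasible", "normal_co", "all_clear", 1L))),
    rank = 2L)
  hospital <- dfl_context("smart_hospital", dfl_theory(
    facts = hospital_facts,
    rules = rules_of(
      dfl_rule("r_hr", "defeasible", "abnormal_heart_rate", "emergency",
               local_priority))),
    rank = 1L)
  build_mcs(list(hospital, home), dplyr::bind_rows(
    dfl_mapping("m_co_alert", "smart_hospital", "smart_home:co_alert",
                "emergency", priority = import_priority + 1L),
    dfl_mapping("m_all_clear", "smart_hospital", "smart_home:all_clear",
                "~emergency", priority = import_priority)))
}

parkinsons_path <- function() {
  system.file("extdata", "parkinsons_case_study.yaml", package = "cdlsentinel")
}

netlogo_path <- function() {
  system.file("extdata", "netlogo_replica.yaml", package = "cdlsentinel")
}
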