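test_that("build_mcs validates ids and mapping references", {
  solo <- build_mcs(dfl_context("home", dfl_theory(facts = "p")))
  expect_s3_class(solo, "dfl_mcs")
  expect_identical(nrow(solo$dependencies), 0L)

  two <- home_hospital_mcs()
  expect_setequal(names(two$contexts), c("smart_home", "smart_hospital"))

  expect_error(build_mcs(list(dfl_context("a", dfl_theory()),
                              dfl_context("a", dfl_theory()))),
               "duplicate context id")
  expect_error(
    build_mcs(dfl_context("home", dfl_theory()),
              dfl_mapping("m1", "home", "clinic:fever", "emergency")),
    "unknown context: clinic")
  expect_error(
    build_mcs(dfl_context("home", dfl_theory()),
              dfl_mapping("m1", "clinic", "home:fever", "emergency")),
    "unknown context: clinic")
})

test_that("a two-way linked pair of contexts yields a 2-cycle dependency graph", {
  a <- dfl_context("smart_home", dfl_theory(facts = "p"))
  b <- dfl_context("smart_hospital", dfl_theory(facts = "q"))
  mcs <- build_mcs(list(a, b), dplyr::bind_rows(
    dfl_mapping("m1", "smart_home", "smart_hospital:q", "imported_q"),
    dfl_mapping("m2", "smart_hospital", "smart_home:p", "imported_p")))
  deps <- mcs$dependencies
  expect_setequal(paste(deps$from, deps$to),
                  c("smart_home smart_hospital", "smart_hospital smart_home"))
})

test_that("a single-context MCS answers exactly like the local engine", {
  for (s in c(3, 9, 17, 23, 31, 42, 55, 61, 77, 90)) {
    th <- random_theory(seed = s)
    mcs <- build_mcs(dfl_context("only", th))
    atoms <- theory_atoms(th)
    for (lit in all_literals(atoms)) {
      ans <- distributed_query(mcs, "only", lit)
      expect_identical(ans$value == "positive", prove(th, lit, "+d"),
                       info = paste("seed", s, "lit", lit))
      expect_false(ans$value == "undefined")
    }
  }
})

test_that("an exported alert crosses contexts through a mapping rule", {
  mcs <- home_hospital_mcs(home_facts = "abnormal_co")
  ans <- distributed_query(mcs, "smart_hospital", "emergency")
  expect_identical(ans$value, "positive")
  expect_true("m_co_alert" %in% ans$support$rule_id)
  expect_true(any(ans$support$context == "smart_home" &
                    ans$support$rule_id == "h_co_alert"))
  # with nothing abnormal the import does not fire
  calm <- home_hospital_mcs()
  expect_identical(distributed_query(calm, "smart_hospital", "emergency")$value,
                   "negative")
  expect_error(distributed_query(calm, "clinic", "emergency"), "unknown context")
})

test_that("cyclically dependent mappings terminate and answer undefined", {
  a <- dfl_context("a", dfl_theory())
  b <- dfl_context("b", dfl_theory())
  mcs2 <- build_mcs(list(a, b), dplyr::bind_rows(
    dfl_mapping("m_ab", "a", "b:q", "p"),
    dfl_mapping("m_ba", "b", "a:p", "q")))
  ans <- distributed_query(mcs2, "a", "p")
  expect_identical(ans$value, "undefined")

  # 3-context cycle
  cs <- lapply(c("a", "b", "c"), function(i) dfl_context(i, dfl_theory()))
  mcs3 <- build_mcs(cs, dplyr::bind_rows(
    dfl_mapping("m1", "a", "b:q", "p"),
    dfl_mapping("m2", "b", "c:r", "q"),
    dfl_mapping("m3", "c", "a:p", "r")))
  expect_identical(distributed_query(mcs3, "a", "p")$value, "undefined")

  # a cycle plus an independent grounded mapping: the grounded part decides
  grounded <- build_mcs(
    list(dfl_context("a", dfl_theory()), dfl_context("b", dfl_theory(facts = "s"))),
    dplyr::bind_rows(
      dfl_mapping("m_ab", "a", "b:q", "p"),
      dfl_mapping("m_ba", "b", "a:p", "q"),
      dfl_mapping("m_s", "a", "b:s", "p")))
  expect_identical(distributed_query(grounded, "a", "p")$value, "positive")
})

test_that("distributed queries are deterministic with stable support sets", {
  mcs <- home_hospital_mcs(home_facts = "abnormal_co")
  a1 <- distributed_query(mcs, "smart_hospital", "emergency")
  a2 <- distributed_query(mcs, "smart_hospital", "emergency")
  expect_identical(a1, a2)
})

test_that("mapping conflict resolution follows priority, rank, then id", {
  cands <- tibble::tibble(id = c("m_low", "m_high"),
                          owner = c("ctx1", "ctx2"),
                          priority = c(2L, 5L))
  expect_identical(resolve_mapping_conflict(cands)$id, "m_high")
  expect_identical(resolve_mapping_conflict(cands[1, ])$id, "m_low")
  tie <- tibble::tibble(id = c("m_b", "m_a"), owner = c("ctx2", "ctx1"),
                        priority = c(3L, 3L))
  expect_identical(
    resolve_mapping_conflict(tie, ranks = c(ctx1 = 1L, ctx2 = 2L))$id, "m_a")
  expect_identical(
    resolve_mapping_conflict(tie, ranks = c(ctx1 = 2L, ctx2 = 1L))$id, "m_b")
  same <- tibble::tibble(id = c("m_b", "m_a"), owner = c("ctx1", "ctx1"),
                         priority = c(3L, 3L))
  expect_identical(resolve_mapping_conflict(same)$id, "m_a")
  expect_error(resolve_mapping_conflict(same[0, ]), "no candidate")
})

test_that("equilibrium holds for empty and calm systems, fails on contradiction", {
  expect_true(equilibrium_check(build_mcs(list()))$consistent)

  bad <- build_mcs(dfl_context("ctx", dfl_theory(facts = c("p", "~p"))))
  eq <- equilibrium_check(bad)
  expect_false(eq$consistent)
  expect_identical(eq$conflicts$context, "ctx")
  expect_identical(eq$conflicts$atom, "p")
  expect_identical(eq$conflicts$type, "contradiction")

  expect_true(equilibrium_check(home_hospital_mcs(home_facts = "normal_co"))$consistent)
})

test_that("complementary imports into a third context resolve by mapping priority", {
  # two source contexts push opposite conclusions into a decision context
  calm <- dfl_context("home", dfl_theory(facts = "all_clear"))
  alarmed <- dfl_context("ward", dfl_theory(facts = "tachycardia"))
  decision <- dfl_context("decider", dfl_theory())
  mk <- function(p_emergency, p_all_clear) build_mcs(
    list(decision, calm, alarmed), dplyr::bind_rows(
      dfl_mapping("m_emergency", "decider", "ward:tachycardia", "emergency",
                  priority = p_emergency),
      dfl_mapping("m_calm", "decider", "home:all_clear", "~emergency",
                  priority = p_all_clear)))

  prioritized <- mk(2L, 1L)
  eq <- equilibrium_check(prioritized)
  expect_true(eq$consistent)
  expect_identical(distributed_query(prioritized, "decider", "emergency")$value,
                   "positive")

  flat <- mk(1L, 1L)
  eq_flat <- equilibrium_check(flat)
  expect_false(eq_flat$consistent)
  expect_identical(eq_flat$conflicts$atom, "emergency")
  expect_identical(eq_flat$conflicts$type, "unresolved")
  expect_identical(distributed_query(flat, "decider", "emergency")$value,
                   "negative")
})
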