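test_that("rate constants follow the passage algebra", {
  rc <- rate_constants(evolution_params())
  expect_equal(rc$k_init, 0.6 / 64)
  expect_equal(rc$k_init, 0.009375)
  expect_equal(rc$k_decay, 0.04 / 64)
  expect_equal(rc$k_mut, 0.04 / 448)
  expect_equal(rc$k_mut, 8.93e-5, tolerance = 1e-3)
  expect_equal(rc$k_mut_effective, 0.04 / 4032)
  rc2 <- rate_constants(evolution_params(capture_kinetics = "per_neighbor"))
  expect_equal(rc2$k_mut_effective, 0.04 / 448)
})

test_that("parameter validation enforces the probability budget", {
  expect_error(evolution_params(p_init = 1.2), "\\[0, 1\\]")
  expect_error(evolution_params(p_decay = 0.6, p_mut = 0.5), "exceed 1")
  expect_error(evolution_params(p_mut = 0.2,
                                capture_kinetics = "per_neighbor"),
               "per_neighbor")
  expect_error(evolution_params(stop = "everything"), "stop")
})

test_that("a passage realizes at most one event and always advances", {
  # no initiation possible: empty table is untouched apart from the clock
  set.seed(1)
  ct <- passage(coding_table(), evolution_params(p_init = 0))
  expect_identical(assigned_count(ct), 0L)
  expect_identical(ct$passages, 1L)
  expect_true(all(ct$counters == 0L))
  # full table with certain decay: exactly one decay
  set.seed(2)
  ct <- passage(sgc(), evolution_params(p_decay = 1, p_mut = 0))
  expect_identical(assigned_count(ct), 63L)
  expect_identical(ct$counters[["decays"]], 1L)
})

test_that("conservation and counter monotonicity hold through a run", {
  set.seed(3)
  params <- evolution_params(wobble_mode = "continuous", p_rand = 0.3)
  ct <- coding_table()
  prev <- ct
  for (i in 1:400) {
    ct <- passage(ct, params)
    expect_identical(ct$passages, prev$passages + 1L)
    expect_true(all(ct$counters >= prev$counters))
    # at most one event counter moves per passage, except a wobble
    # extension accompanying an initiation or capture
    delta <- ct$counters - prev$counters
    expect_lte(sum(delta[c("initiations", "decays",
                           "mutational_captures")]), 1L)
    expect_lte(sum(delta), 2L)
    expect_identical(assigned_count(ct) + sum(is.na(ct$assignment)), 64L)
    prev <- ct
  }
})

test_that("identical seed and parameters give bit-identical histories", {
  params <- evolution_params(stop = list(n_functions = 18), seed = 99)
  a <- evolve(params, log_events = TRUE)
  b <- evolve(params, log_events = TRUE)
  expect_identical(a$log, b$log)
  expect_identical(assignment(a$table), assignment(b$table))
  expect_identical(a$table$counters, b$table$counters)
})

test_that("evolve honours each stopping rule", {
  set.seed(4)
  r <- evolve(evolution_params(stop = "complete", wobble_mode = "none",
                               p_rand = 1, max_passages = 2e5))
  expect_false(r$timed_out)
  expect_identical(n_functions(r$table), 22L)
  set.seed(5)
  r <- evolve(evolution_params(stop = list(max_passages = 500)))
  expect_identical(r$table$passages, 500L)
  expect_false(r$timed_out)
  set.seed(6)
  r <- evolve(evolution_params(stop = list(n_functions = 20)))
  expect_gte(n_functions(r$table), 20L)
})

test_that("the hard passage cap reports a timeout instead of looping", {
  set.seed(7)
  r <- evolve(evolution_params(stop = "complete", p_rand = 0,
                               max_passages = 200))
  expect_true(r$timed_out)
  expect_identical(r$table$passages, 200L)
})

test_that("late wobble is applied when the stopping rule is met", {
  set.seed(8)
  r <- evolve(evolution_params(stop = list(n_functions = 20),
                               wobble_mode = "late"))
  expect_gt(r$table$counters[["wobble_initiations"]], 0L)
  a <- assignment(r$table)
  for (t in triplets()) {
    p <- wobble_partner(t)
    expect_false(xor(is.na(a[[t]]), is.na(a[[p]])))
  }
  # no late wobble for "none", nor on timeouts
  set.seed(9)
  r <- evolve(evolution_params(stop = list(n_functions = 20),
                               wobble_mode = "none"))
  expect_identical(r$table$counters[["wobble_initiations"]], 0L)
})

test_that("event logs record initiations, decays and captures", {
  params <- evolution_params(stop = list(max_passages = 2000), p_rand = 1,
                             wobble_mode = "none", seed = 10)
  r <- evolve(params, log_events = TRUE)
  expect_true(all(r$log$event %in% c("initiation", "decay", "capture")))
  cnt <- table(factor(r$log$event,
                      c("initiation", "decay", "capture")))
  expect_identical(as.integer(cnt),
                   as.integer(r$table$counters[c("initiations", "decays",
                                                 "mutational_captures")]))
  expect_true(all(r$log$triplet %in% triplets()))
})

test_that("observed event rates recover the kinetic laws", {
  # initiation: first order in unassigned triplets, intercept p_init
  set.seed(11)
  r0 <- measure_event_rates(0, 1500)
  expect_equal(r0$rate[r0$event == "initiation"], 0.6, tolerance = 0.05)
  expect_equal(r0$rate[r0$event == "decay"], 0)
  # decay: first order in assigned triplets, maximum p_decay at 64
  r64 <- measure_event_rates(64, 1500)
  expect_equal(r64$rate[r64$event == "decay"], 0.04, tolerance = 0.4)
  expect_equal(r64$rate[r64$event == "initiation"], 0)
  expect_equal(r64$rate[r64$event == "capture"], 0)
})

test_that("the expected free neighborhood is u/7", {
  # for an assigned triplet in a table with u unassigned triplets overall,
  # the expected number of free neighbors is 9u/63 = u/7
  set.seed(12)
  for (u in c(14, 35)) {
    nf <- vapply(1:400, function(i) {
      a <- sample(triplets(), 64 - u)
      t <- sample(a, 1)
      sum(!neighborhood(t) %in% a)
    }, numeric(1))
    expect_equal(mean(nf), u / 7, tolerance = 0.1)
  }
})
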