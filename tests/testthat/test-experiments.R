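test_that("random tables are full and unordered on average", {
  set.seed(1)
  t <- make_random_table()
  expect_identical(assigned_count(t), 64L)
  pv <- t(vapply(1:150, function(i) progress_values(make_random_table()),
                 numeric(3)))
  expect_equal(unname(colMeans(pv)), c(0, 0, 0), tolerance = 0.1)
})

test_that("mixed tables interpolate between the SGC and randomness", {
  expect_equal(unname(progress_values(make_mixed_table(0))), c(1, 1, 1))
  set.seed(2)
  pv1 <- t(vapply(1:100, function(i) progress_values(make_mixed_table(1)),
                  numeric(3)))
  expect_equal(unname(colMeans(pv1)), c(0, 0, 0), tolerance = 0.15)
  expect_error(make_mixed_table(1.5), "fraction")
})

test_that("distance progress falls linearly with the random fraction", {
  set.seed(3)
  fr <- c(0.2, 0.4, 0.6, 0.8)
  d <- vapply(fr, function(f)
    mean(vapply(1:150, function(i)
      progress_values(make_mixed_table(f))[["distance"]], numeric(1))),
    numeric(1))
  expect_equal(d, 1 - fr, tolerance = 0.08)
  # spacing and dPR decay faster than distance at intermediate fractions
  sp <- mean(vapply(1:150, function(i)
    progress_values(make_mixed_table(0.5))[["spacing"]], numeric(1)))
  expect_lt(sp, 0.5)
})

test_that("SGC seeding reproduces the code at k = 64 and counts inits", {
  set.seed(4)
  full <- seed_sgc_subset(64)
  a <- assignment(full); s <- assignment(sgc())
  # wobble extensions may override the SGC only inside its two mixed
  # wobble groups (AUA/AUG Ile/Met and UGA/UGG Ter/Trp)
  expect_identical(a[!names(a) %in% c("AUA", "AUG", "UGA", "UGG")],
                   s[!names(s) %in% c("AUA", "AUG", "UGA", "UGG")])
  full_nw <- seed_sgc_subset(64, wobble = FALSE)
  expect_identical(assignment(full_nw), assignment(sgc()))
  expect_identical(full_nw$counters[["initiations"]], 64L)
  bare <- seed_sgc_subset(10, wobble = FALSE)
  expect_identical(assigned_count(bare), 10L)
  expect_error(seed_sgc_subset(0), "1..64")
})

test_that("16 SGC wobble seedings encode about 12.35 functions", {
  set.seed(5)
  nf <- vapply(1:600, function(i) n_functions(seed_sgc_subset(16)),
               numeric(1))
  expect_equal(mean(nf), 12.35, tolerance = 0.2 / 12.35)
  # and sit near SGC-level order before any evolution
  pv <- t(vapply(1:100, function(i)
    progress_values(seed_sgc_subset(16)), numeric(3)))
  expect_true(all(colMeans(pv, na.rm = TRUE) > 0.8))
})

test_that("event-rate sweep shows the expected kinetic shapes", {
  set.seed(6)
  expect_equal(measure_event_rates(0, 300)$rate[2:3], c(0, 0))
  r64 <- measure_event_rates(64, 300)$rate
  expect_equal(r64[c(1, 3)], c(0, 0))
  caps <- vapply(c(8, 32, 56), function(k)
    measure_event_rates(k, 3000)$rate[3], numeric(1))
  expect_gt(caps[2], caps[1])     # capture is second order: maximal at 32
  expect_gt(caps[2], caps[3])
})

test_that("population summaries are coherent", {
  pop <- run_population(40, evolution_params(stop = list(n_functions = 16),
                                             wobble_mode = "none",
                                             seed = 7),
                        thresholds = c(0.5, 0.9))
  expect_identical(nrow(pop$tables), 40L)
  expect_true(all(pop$tables$n_functions >= 16))
  x <- pop$tables$passages
  expect_equal(pop$summary["passages", "sem"],
               stats::sd(x) / sqrt(40))
  expect_identical(sum(pop$histogram$count), 40L)
  expect_true(all(pop$joint >= 0 & pop$joint <= 1))
  expect_gte(pop$joint[["ge_0.5"]], pop$joint[["ge_0.9"]])
  expect_identical(pop$n_timed_out, 0L)
  expect_output(print(pop), "population of 40")
})

test_that("population TSV round-trips", {
  dir <- withr::local_tempdir()
  pop <- run_population(8, evolution_params(stop = list(n_functions = 10),
                                            wobble_mode = "none", seed = 8))
  paths <- write_population_tsv(pop, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(paths[1])
  expect_identical(nrow(back), 8L)
  expect_true(all(c("spacing", "distance", "dpr") %in% names(back)))
})

test_that("capture mechanisms order code quality as expected", {
  # amplify the capture signal with per-neighbor kinetics so mechanism
  # differences dominate sampling noise at modest n
  run_mech <- function(kind, n = 250) {
    pop <- run_population(n, evolution_params(
      mechanism = capture_mechanism(kind),
      capture_kinetics = "per_neighbor",
      stop = list(n_functions = 20), seed = 9))
    colMeans(pop$tables[, c("spacing", "distance", "dpr")], na.rm = TRUE)
  }
  coevo <- run_mech("coevo_pr")
  para <- run_mech("pr1")
  expect_gt(para[["dpr"]], coevo[["dpr"]])          # paralogy: chemical order
  expect_gt(coevo[["spacing"]], para[["spacing"]])  # coevolution: grouping
  expect_gt(coevo[["distance"]], para[["distance"]])
})

test_that("joint progress declines as random assignment grows", {
  jf <- vapply(c(0, 0.2), function(pr) {
    pop <- run_population(150, evolution_params(
      p_rand = pr, stop = list(n_functions = 20), seed = 10))
    pop$joint[["ge_0.9"]]
  }, numeric(1))
  expect_gt(jf[1], jf[2])
  expect_lt(jf[2], 0.05)   # beyond 15% random the SGC vicinity empties
})

test_that("the command line front end runs its subcommands", {
  dir <- withr::local_tempdir()
  out <- utils::capture.output(
    sgc_cli(c("population", "--n", "5", "--seed", "3", "--out", dir,
              "--stop", "n_functions:10", "--wobble_mode", "none")))
  expect_true(file.exists(file.path(dir, "population_tables.tsv")))
  cfg <- file.path(dir, "cfg.txt")
  writeLines(c("n: 4", "stop: n_functions:8", "wobble_mode: none"), cfg)
  out <- utils::capture.output(
    sgc_cli(c("run", "--config", cfg, "--out", dir, "--seed", "2")))
  expect_true(file.exists(file.path(dir, "events.tsv")))
  expect_error(sgc_cli(character()), "usage")
})
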