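# Population harness: table generators and the experiments used to
# characterize the model (event-rate kinetics, steady state, seeded starts,
# populations of evolutions with order statistics).

#' Fully random coding table
#'
#' All 64 triplets assigned independently and uniformly over the 22
#' functions.  Populations of such tables define the random baselines of the
#' three order indices.
#'
#' @return A `coding_table`.
#' @export
#' @examples
#' set.seed(1)
#' spacing_index(make_random_table())   # about 2.28
make_random_table <- function() {
  .new_ct(sample.int(.N_FUNS, 64L, replace = TRUE))
}

#' Mixed SGC/random coding table
#'
#' A full table in which `ceiling(64 * fraction_random)` uniformly chosen
#' triplets carry uniform random functions and the remainder carry their
#' SGC functions.  Scanning the fraction maps how each progress value
#' responds to random assignment (distance responds linearly; spacing and
#' dPR are more sensitive).
#'
#' @param fraction_random fraction in \[0, 1\] of randomized triplets.
#' @return A `coding_table`.
#' @export
make_mixed_table <- function(fraction_random) {
  if (fraction_random < 0 || fraction_random > 1)
    stop("fraction_random must lie in [0, 1]")
  asg <- sgc()$assignment
  k <- as.integer(ceiling(64 * fraction_random))
  if (k > 0) {
    p <- sample.int(64L, k)
    asg[p] <- sample.int(.N_FUNS, k, replace = TRUE)
  }
  .new_ct(asg)
}

#' Seed a table with randomly chosen SGC assignments
#'
#' Performs `k` initiations on uniformly chosen free triplets, each
#' receiving its own SGC function; with `wobble = TRUE` each initiation
#' extends to its free wobble partner per [assign_with_wobble()] (so more
#' than `k` triplets may end up assigned).  Sixteen such wobble seedings
#' encode about 12.4 distinct functions on average and already approximate
#' SGC-level order.
#'
#' @param k number of initiations (1..64).
#' @param wobble extend each seeding by wobble (default `TRUE`).
#' @param p_wob wobble probability for third-base U/G triplets.
#' @return A `coding_table` with `k` initiations recorded.
#' @export
#' @examples
#' set.seed(1)
#' n_functions(seed_sgc_subset(16))
seed_sgc_subset <- function(k, wobble = TRUE, p_wob = 0.5) {
  k <- as.integer(k)
  if (k < 1L || k > 64L) stop("k must lie in 1..64")
  sgca <- sgc()$assignment
  ct <- coding_table()
  for (i in seq_len(k)) {
    free <- which(is.na(ct$assignment))
    if (!length(free)) break   # wobble may fill the table before k seedings
    t <- free[sample.int(length(free), 1L)]
    if (wobble) {
      ct <- assign_with_wobble(ct, t - 1L, .FUNS[sgca[t]], p_wob)
    } else {
      ct$assignment[t] <- sgca[t]
    }
    ct$counters["initiations"] <- ct$counters["initiations"] + 1L
  }
  ct
}

#' Measure per-passage event rates at a given occupancy
#'
#' Builds `n_tables` tables preloaded with `k` randomly chosen SGC triplets
#' (no wobble), applies exactly one passage to each, and returns the
#' observed events/passage for initiation, decay and mutational capture
#' with standard errors.  Sweeping `k` exposes the kinetic laws: initiation
#' is first order in unassigned triplets (slope -p_init/64), decay first
#' order in assigned triplets (slope p_decay/64), and capture second order,
#' maximal at 32 assigned.
#'
#' @param k_assigned number of preloaded SGC triplets (0..64).
#' @param n_tables number of replicate tables.
#' @param params an [evolution_params()].
#' @return Data frame with one row per event type: rate and sem.
#' @export
measure_event_rates <- function(k_assigned, n_tables = 1000,
                                params = evolution_params(p_rand = 1)) {
  k <- as.integer(k_assigned)
  if (k < 0L || k > 64L) stop("k_assigned must lie in 0..64")
  sgca <- sgc()$assignment
  pp <- .prep_params(params)
  ev <- matrix(0, n_tables, 3)
  for (i in seq_len(n_tables)) {
    asg <- rep(NA_integer_, 64L)
    if (k > 0L) {
      p <- sample.int(64L, k)
      asg[p] <- sgca[p]
    }
    st <- .new_state(.new_ct(asg))
    .step(st, pp)
    if (!is.null(st$ev)) ev[i, st$ev[1L]] <- 1
  }
  data.frame(event = c("initiation", "decay", "capture"),
             rate = colMeans(ev),
             sem = apply(ev, 2, stats::sd) / sqrt(n_tables))
}

#' Run a population of independent evolutions
#'
#' Evolves `n` independent tables under `params`, computes per-table order
#' statistics and progress values, and summarizes the population: means and
#' standard errors of passages, counters and progress values; joint-progress
#' fractions at the requested thresholds; a duration histogram in
#' `hist_window`-passage windows with the off-scale tail reported as its own
#' bin; and tallies of timeouts and undefined indices.
#'
#' @param n number of evolutions.
#' @param params an [evolution_params()].
#' @param constants progress normalization constants
#'   (default [norm_constants()]).
#' @param thresholds joint-progress thresholds to report (default 0.9).
#' @param hist_window histogram window in passages (default 50).
#' @param hist_max durations beyond this go to the off-scale bin
#'   (default 20 windows).
#' @return A `population_summary`: list with `tables` (per-table data
#'   frame), `summary` (means and sems), `joint` (named fractions),
#'   `histogram`, `n_timed_out`, `n_undefined`, `n`, `params`.
#' @export
#' @examples
#' set.seed(42)
#' pop <- run_population(20, evolution_params(stop = list(n_functions = 15),
#'                                            wobble_mode = "none"))
#' pop$summary["spacing", ]
run_population <- function(n, params = evolution_params(),
                           constants = norm_constants(),
                           thresholds = 0.9, hist_window = 50,
                           hist_max = 20 * hist_window) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(params$seed)) { set.seed(params$seed); params$seed <- NULL }
  ref <- sgc(); pr <- polar_requirement()
  rows <- vector("list", n)
  timed <- logical(n)
  for (i in seq_len(n)) {
    res <- evolve(params)
    tab <- res$table
    timed[i] <- res$timed_out
    pv <- progress_values(tab, constants, ref, pr)
    rows[[i]] <- data.frame(
      id = i, passages = tab$passages,
      initiations = tab$counters[["initiations"]],
      decays = tab$counters[["decays"]],
      mutational_captures = tab$counters[["mutational_captures"]],
      wobble_initiations = tab$counters[["wobble_initiations"]],
      assigned = assigned_count(tab), n_functions = n_functions(tab),
      spacing = pv[["spacing"]], distance = pv[["distance"]],
      dpr = pv[["dpr"]], timed_out = res$timed_out)
  }
  tables <- do.call(rbind, rows)
  num <- c("passages", "initiations", "decays", "mutational_captures",
           "wobble_initiations", "assigned", "n_functions",
           "spacing", "distance", "dpr")
  summ <- t(vapply(num, function(v) {
    x <- tables[[v]]
    c(mean = mean(x, na.rm = TRUE),
      sem = stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  }, numeric(2)))
  joint <- vapply(thresholds, function(th)
    as.numeric(joint_progress_fraction(tables, th)), numeric(1))
  names(joint) <- paste0("ge_", thresholds)
  breaks <- seq(0, hist_max, by = hist_window)
  inb <- tables$passages[tables$passages <= hist_max]
  cnt <- if (length(inb))
    table(cut(inb, breaks, include.lowest = TRUE, right = TRUE))
    else table(cut(numeric(), breaks))
  histogram <- data.frame(window_start = breaks[-length(breaks)],
                          window_end = breaks[-1],
                          count = as.integer(cnt))
  histogram <- rbind(histogram,
                     data.frame(window_start = hist_max, window_end = Inf,
                                count = sum(tables$passages > hist_max)))
  structure(list(tables = tables, summary = as.data.frame(summ),
                 joint = joint, histogram = histogram,
                 n_timed_out = sum(timed),
                 n_undefined = sum(!stats::complete.cases(
                   tables[, c("spacing", "distance", "dpr")])),
                 n = n, params = params),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population of %d evolutions (%d timed out, %d undefined)\n",
              x$n, x$n_timed_out, x$n_undefined))
  print(round(x$summary, 4))
  cat("joint progress fractions:",
      paste(sprintf("%s=%.4f", names(x$joint), x$joint), collapse = "  "),
      "\n")
  invisible(x)
}

#' Write population results as TSV
#'
#' Emits the per-table rows, the summary and the duration histogram of a
#' [run_population()] result as tab-separated files under `dir`.
#'
#' @param pop a `population_summary`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_population_tsv <- function(pop, dir = ".", prefix = "population") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("tables", "summary", "histogram"),
                                 ".tsv"))
  utils::write.table(pop$tables, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  s <- cbind(statistic = rownames(pop$summary), pop$summary)
  utils::write.table(s, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(pop$histogram, paths[3], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
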