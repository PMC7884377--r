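# The per-passage stochastic kernel and the evolution driver.
#
# One passage examines one uniformly chosen triplet and realizes at most one
# event:
#   unassigned triplet: with probability p_init an initiation occurs; the
#     function is uniform over the 22 functions with probability p_rand and
#     otherwise the SGC's own assignment of that triplet;
#   assigned triplet: with probability p_decay the assignment decays; failing
#     that, with probability p_mut a mutational capture is attempted - one of
#     the nine single-mutation neighbors is chosen uniformly and, if free,
#     captured for a function drawn from the capture mechanism.  A capture
#     attempt that lands on an occupied neighbor consumes the passage.
# Under continuous wobble, initiations (and, by default, captures) extend to
# the free wobble partner per the simplified Crick rules.
#
# The default capture kinetics ("single_mutant") make the observed capture
# rate second order, proportional to assigned*(64 - assigned), with an
# effective rate constant p_mut/4032 per triplet pair per passage.  The
# alternative "per_neighbor" kinetics give every free neighbor its own
# p_mut-sized slice of the event window (effective constant p_mut/448); see
# rate_constants() and the package vignette for the correspondence and for
# why single_mutant is the default.
#
# State lives in an environment during a run (reference semantics keep the
# per-passage cost low in pure R); coding_table objects are materialized at
# the boundaries.

#' Evolution parameters
#'
#' Bundles the per-passage probabilities, wobble mode, capture mechanism and
#' stopping rule of an evolution run.
#'
#' @param p_init probability that an examined unassigned triplet is
#'   initiated.
#' @param p_decay probability that an examined assigned triplet decays.
#' @param p_mut probability governing mutational capture by an examined
#'   assigned triplet.
#' @param p_wob wobble probability for third-base U/G triplets (third-base
#'   C/A triplets always extend; see [assign_with_wobble()]).
#' @param p_rand probability that an initiation is uniformly random over the
#'   22 functions rather than SGC-like.
#' @param wobble_mode `"none"` (no wobble), `"continuous"` (wobble from the
#'   first initiation onward) or `"late"` (evolve without wobble, then
#'   [apply_late_wobble()] once the stopping rule is met).
#' @param mechanism a [capture_mechanism()].
#' @param stop stopping rule: `list(n_functions = k)`, `"full"` (64
#'   assignments), `"complete"` (22 functions) or `list(max_passages = n)`
#'   (run exactly n passages).
#' @param max_passages hard cap guarding non-terminating runs; reaching it
#'   flags the result as timed out.
#' @param seed optional integer seed applied at the start of [evolve()].
#' @param capture_kinetics `"single_mutant"` (default) or `"per_neighbor"`.
#' @param wobble_on_capture under continuous wobble, whether captures also
#'   extend to the free wobble partner (default `TRUE`).
#' @return An `evolution_params` list.
#' @export
#' @examples
#' evolution_params(stop = list(n_functions = 20))
evolution_params <- function(p_init = 0.6, p_decay = 0.04, p_mut = 0.04,
                             p_wob = 0.5, p_rand = 0.1,
                             wobble_mode = c("late", "continuous", "none"),
                             mechanism = capture_mechanism("coevo_pr"),
                             stop = list(n_functions = 20),
                             max_passages = 1e6, seed = NULL,
                             capture_kinetics = c("single_mutant",
                                                  "per_neighbor"),
                             wobble_on_capture = TRUE) {
  wobble_mode <- match.arg(wobble_mode)
  capture_kinetics <- match.arg(capture_kinetics)
  for (p in c(p_init, p_decay, p_mut, p_wob, p_rand))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (p_decay + p_mut > 1)
    stop("p_decay + p_mut must not exceed 1")
  if (capture_kinetics == "per_neighbor" && p_decay + 9 * p_mut > 1)
    stop("per_neighbor kinetics need p_decay + 9*p_mut <= 1")
  .validate_stop(stop)
  structure(list(p_init = p_init, p_decay = p_decay, p_mut = p_mut,
                 p_wob = p_wob, p_rand = p_rand, wobble_mode = wobble_mode,
                 mechanism = mechanism, stop = stop,
                 max_passages = max_passages, seed = seed,
                 capture_kinetics = capture_kinetics,
                 wobble_on_capture = wobble_on_capture),
            class = "evolution_params")
}

.validate_stop <- function(stop) {
  ok <- (is.character(stop) && length(stop) == 1 &&
           stop %in% c("full", "complete")) ||
        (is.list(stop) && length(stop) == 1 &&
           names(stop) %in% c("n_functions", "max_passages") &&
           is.numeric(stop[[1]]))
  if (!ok) stop("stop must be 'full', 'complete', list(n_functions=) or ",
                "list(max_passages=)")
  invisible(stop)
}

#' Kinetic rate constants implied by the passage probabilities
#'
#' The passage algebra (probability of selecting a reactant times the
#' probability of its reaction) corresponds to first-order initiation and
#' decay constants `k_init = p_init/64` and `k_decay = p_decay/64` (per
#' passage), and to a second-order capture constant `k_mut = p_mut/448`
#' (per triplet pair per passage) when every free neighbor carries its own
#' p_mut-sized reaction probability (`"per_neighbor"` kinetics: an assigned
#' triplet expects `9u/63 = u/7` free neighbors when `u` triplets are
#' unassigned overall, whence 448 = 64*7).  Under the default
#' `"single_mutant"` kinetics the single uniformly chosen mutant divides
#' that window by 9, giving an effective constant `p_mut/4032`; both are
#' second order in assigned*(unassigned) with the capture rate maximal at
#' 32 assigned triplets.
#'
#' @param params an `evolution_params`.
#' @return Named list `k_init`, `k_decay`, `k_mut` (the per-neighbor
#'   constant `p_mut/448`) and `k_mut_effective` (the constant of the
#'   kinetics actually configured).
#' @export
#' @examples
#' rate_constants(evolution_params())$k_init  # 0.009375
rate_constants <- function(params = evolution_params()) {
  list(k_init = params$p_init / 64,
       k_decay = params$p_decay / 64,
       k_mut = params$p_mut / 448,
       k_mut_effective = if (params$capture_kinetics == "per_neighbor")
         params$p_mut / 448 else params$p_mut / 4032)
}

# -- internal kernel ---------------------------------------------------------

.prep_params <- function(params) {
  third <- (0:63) %% 4L
  list(p_init = params$p_init, p_decay = params$p_decay,
       p_mut = params$p_mut, p_rand = params$p_rand,
       mechanism = params$mechanism,
       cont_wobble = params$wobble_mode == "continuous",
       wobble_on_capture = params$wobble_on_capture,
       single = params$capture_kinetics == "single_mutant",
       pweff = ifelse(third == 1L | third == 2L, 1, params$p_wob),
       sgca = sgc()$assignment)
}

.new_state <- function(table) {
  st <- new.env(parent = emptyenv())
  st$asg <- table$assignment
  st$counters <- unname(table$counters)
  st$passages <- table$passages
  st$fcnt <- tabulate(st$asg[!is.na(st$asg)], .N_FUNS)
  st$nfun <- sum(st$fcnt > 0L)
  st$nasg <- sum(st$fcnt)
  st$ev <- NULL
  st
}

.table_from_state <- function(st) {
  .new_ct(st$asg, stats::setNames(st$counters, .COUNTERS), st$passages)
}

.st_place <- function(st, t, fi) {
  st$asg[t] <- fi
  st$nasg <- st$nasg + 1L
  n <- st$fcnt[fi] + 1L
  st$fcnt[fi] <- n
  if (n == 1L) st$nfun <- st$nfun + 1L
}

.st_wob_extend <- function(st, t, fi, pp) {
  if (stats::runif(1) < pp$pweff[t]) {
    q <- .PARTNER[t]
    if (is.na(st$asg[q])) {
      .st_place(st, q, fi)
      st$counters[4L] <- st$counters[4L] + 1L
    }
  }
}

# one passage; mutates st, records the event (if any) in st$ev
.step <- function(st, pp) {
  t <- sample.int(64L, 1L)
  f <- st$asg[t]
  r <- stats::runif(1)
  st$ev <- NULL
  if (is.na(f)) {
    if (r < pp$p_init) {
      fi <- if (pp$p_rand > 0 && stats::runif(1) < pp$p_rand)
        sample.int(.N_FUNS, 1L) else pp$sgca[t]
      .st_place(st, t, fi)
      st$counters[1L] <- st$counters[1L] + 1L
      st$ev <- c(1L, t, fi)
      if (pp$cont_wobble) .st_wob_extend(st, t, fi, pp)
    }
  } else if (r < pp$p_decay) {
    st$asg[t] <- NA_integer_
    st$nasg <- st$nasg - 1L
    n <- st$fcnt[f] - 1L
    st$fcnt[f] <- n
    if (n == 0L) st$nfun <- st$nfun - 1L
    st$counters[2L] <- st$counters[2L] + 1L
    st$ev <- c(2L, t, f)
  } else if (pp$single) {
    if (r < pp$p_decay + pp$p_mut) {
      s <- .NEIGHBORS[t, sample.int(9L, 1L)]
      if (is.na(st$asg[s])) {
        fi <- .capture_draw(pp$mechanism, f)
        .st_place(st, s, fi)
        st$counters[3L] <- st$counters[3L] + 1L
        st$ev <- c(3L, s, fi)
        if (pp$cont_wobble && pp$wobble_on_capture)
          .st_wob_extend(st, s, fi, pp)
      }
    }
  } else {                          # per_neighbor kinetics
    nbs <- .NEIGHBORS[t, ]
    free <- nbs[is.na(st$asg[nbs])]
    nf <- length(free)
    if (nf && r < pp$p_decay + nf * pp$p_mut) {
      s <- if (nf == 1L) free else free[sample.int(nf, 1L)]
      fi <- .capture_draw(pp$mechanism, f)
      .st_place(st, s, fi)
      st$counters[3L] <- st$counters[3L] + 1L
      st$ev <- c(3L, s, fi)
      if (pp$cont_wobble && pp$wobble_on_capture)
        .st_wob_extend(st, s, fi, pp)
    }
  }
  st$passages <- st$passages + 1L
  invisible(st)
}

#' Advance a coding table by one passage
#'
#' Runs a single passage of the stochastic kernel on `table` (see
#' [evolve()] for the event structure).  Passages with no event are legal
#' outcomes; the passage clock always advances by one and at most one event
#' counter increments.
#'
#' @param table a `coding_table`.
#' @param params an [evolution_params()].
#' @return The updated `coding_table`.
#' @export
#' @examples
#' set.seed(1)
#' passage(coding_table(), evolution_params())
passage <- function(table, params = evolution_params()) {
  st <- .new_state(table)
  .step(st, .prep_params(params))
  .table_from_state(st)
}

#' Evolve a coding table to a stopping criterion
#'
#' Repeats passages from `table` (an empty table by default) until the
#' stopping rule in `params` is met or the hard passage cap is reached.
#' For `wobble_mode = "late"`, [apply_late_wobble()] runs once the rule is
#' met (but not on timeouts or fixed-passage runs).  Evolutions that hit
#' `max_passages` without meeting the rule are returned with
#' `timed_out = TRUE` rather than dropped: complete-code targets under
#' continuous wobble can take orders of magnitude longer than 20-function
#' targets, and the timeout tally is itself a result.
#'
#' @param params an [evolution_params()].
#' @param table starting `coding_table` (default empty).
#' @param log_events if `TRUE`, also return a data frame of events
#'   (passage, event, triplet, function).
#' @return List with elements `table` (the final `coding_table`),
#'   `timed_out` (logical) and, when requested, `log`.
#' @export
#' @examples
#' set.seed(7)
#' res <- evolve(evolution_params(stop = list(n_functions = 12),
#'                                wobble_mode = "none"))
#' n_functions(res$table)
evolve <- function(params = evolution_params(), table = coding_table(),
                   log_events = FALSE) {
  if (!is.null(params$seed)) set.seed(params$seed)
  pp <- .prep_params(params)
  st <- .new_state(table)
  stp <- params$stop
  fixed <- is.list(stp) && identical(names(stp), "max_passages")
  target_fun <- if (is.list(stp) && identical(names(stp), "n_functions"))
    as.integer(stp$n_functions) else NA_integer_
  want_full <- identical(stp, "full")
  n_fixed <- if (fixed) as.integer(stp$max_passages) else NA_integer_
  cap <- as.integer(params$max_passages)
  log <- if (log_events) vector("list", 256) else NULL
  nlog <- 0L
  met <- FALSE
  start <- st$passages
  repeat {
    done <- if (fixed) st$passages - start >= n_fixed
            else if (!is.na(target_fun)) st$nfun >= target_fun
            else if (want_full) st$nasg == 64L
            else st$nfun == .N_FUNS
    if (done) { met <- TRUE; break }
    if (st$passages - start >= cap) break
    .step(st, pp)
    if (log_events && !is.null(st$ev)) {
      nlog <- nlog + 1L
      if (nlog > length(log)) log <- c(log, vector("list", length(log)))
      log[[nlog]] <- c(st$passages, st$ev)
    }
  }
  tab <- .table_from_state(st)
  if (met && params$wobble_mode == "late" && !fixed)
    tab <- apply_late_wobble(tab)
  out <- list(table = tab, timed_out = !met)
  if (log_events) {
    m <- do.call(rbind, log[seq_len(nlog)])
    out$log <- if (is.null(m))
      data.frame(passage = integer(), event = character(),
                 triplet = character(), fun = character())
    else data.frame(passage = m[, 1],
                    event = c("initiation", "decay", "capture")[m[, 2]],
                    triplet = .TRIPLETS[m[, 3]], fun = .FUNS[m[, 4]])
  }
  out
}
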