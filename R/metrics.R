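# Code-order statistics.  Three indices locate a coding table between fully
# random assignment and the standard genetic code:
#   spacing  - pooled mean mutational distance between triplets carrying the
#              same function within one table (compactness of coding);
#   distance - pooled mean mutational distance from a table's triplets to the
#              SGC triplets of the same functions (proximity to the SGC);
#   dPR      - mean |polar requirement difference| over single-mutation
#              triplet pairs assigned to differing amino acids (chemical
#              order of the mutational neighborhoods).
# Each is linearly rescaled to a "progress value": 0 at the random baseline,
# 1 at SGC level.

#' Spacing index: mutational grouping of identical functions
#'
#' Pooled mean Hamming distance over all unordered pairs of triplets that
#' carry the same function, pooled across all 22 functions (total distance
#' over total pair count, not a mean of per-function means).  Functions with
#' fewer than two triplets contribute no pairs.
#'
#' @param x a `coding_table`.
#' @return Mean mutations per same-function pair, in \[1, 3\] for tables
#'   whose triplets are distinct.  Errors if no same-function pair exists.
#' @export
#' @examples
#' spacing_index(sgc())      # 1.30
spacing_index <- function(x) {
  asg <- x$assignment
  tot <- 0; n <- 0L
  for (f in unique(asg[!is.na(asg)])) {
    p <- which(!is.na(asg) & asg == f)
    m <- length(p)
    if (m >= 2L) {
      tot <- tot + sum(.HAMMING[p, p]) / 2
      n <- n + (m * (m - 1L)) %/% 2L
    }
  }
  if (n == 0L) stop("spacing undefined: no function has two assigned triplets")
  tot / n
}

#' Distance index: mutational distance to a reference code
#'
#' Pooled mean Hamming distance over all cross pairs (t, s) with t assigned
#' in `x`, s assigned in `reference`, and both carrying the same function;
#' every cross pair of distinct triplets is counted once and the total is
#' normalized by the pair count.  Self pairs (the same triplet carrying the
#' same function in both tables) are excluded: with them, the random
#' baseline would average (0 + 9 + 54 + 81)/64 = 2.25 rather than the
#' closed-form 2.28571 that random tables are measured to attain.  A
#' consequence is that `distance_index(sgc(), sgc())` equals the SGC
#' spacing (1.30), which is the SGC baseline used in progress
#' normalization.
#'
#' @param x a `coding_table`.
#' @param reference the comparison table (default the SGC).
#' @return Mean mutations per cross pair.  Errors if the tables share no
#'   function.
#' @export
distance_index <- function(x, reference = sgc()) {
  a <- x$assignment; b <- reference$assignment
  tot <- 0; n <- 0
  for (f in intersect(unique(a[!is.na(a)]), unique(b[!is.na(b)]))) {
    pa <- which(!is.na(a) & a == f)
    pb <- which(!is.na(b) & b == f)
    tot <- tot + sum(.HAMMING[pa, pb, drop = FALSE])
    n <- n + length(pa) * length(pb) - length(intersect(pa, pb))
  }
  if (n == 0) stop("distance undefined: tables share no function")
  tot / n
}

#' dPR index: chemical order of mutational neighborhoods
#'
#' Over all unordered triplet pairs one mutation apart in which both
#' triplets are assigned to amino acids (Ini/Ter never contribute) and the
#' amino acids differ, the mean absolute polar-requirement difference.
#' Identical-residue neighbor pairs are not counted, so dPR measures
#' chemical grouping, not coding proximity.
#'
#' @param x a `coding_table`.
#' @param pr named polar-requirement vector (default [polar_requirement()]).
#' @return Mean |PR difference| per counted pair.  Errors when no pair of
#'   differing, PR-bearing amino acids sits one mutation apart.
#' @export
#' @examples
#' dpr_index(sgc())   # 2.069
dpr_index <- function(x, pr = polar_requirement()) {
  prf <- unname(pr[.FUNS])          # NA for Ini/Ter and any missing aa
  f1 <- x$assignment[.NEIGHBOR_PAIRS[, 1]]
  f2 <- x$assignment[.NEIGHBOR_PAIRS[, 2]]
  v1 <- prf[f1]
  v2 <- prf[f2]
  # pairs of *differing amino acids*: residues sharing a PR value (e.g.
  # Leu/Ile) still count, contributing a zero difference
  keep <- !is.na(v1) & !is.na(v2) & f1 != f2
  if (!any(keep)) stop("dPR undefined: no differing amino-acid neighbor pair")
  mean(abs(v1[keep] - v2[keep]))
}

#' Progress value of an index
#'
#' Linear rescaling `(random - system) / (random - sgc)`: 0 at the random
#' baseline, 1 at SGC order.  Values below 0 (more disperse than random) and
#' above 1 (more ordered than the SGC) are legitimate.
#'
#' @param system_index observed index value.
#' @param random_index random-table baseline for that index.
#' @param sgc_index SGC baseline for that index.
#' @return Numeric progress value.
#' @export
#' @examples
#' progress(1.792, 2.284, 1.30)  # 0.5
progress <- function(system_index, random_index, sgc_index) {
  den <- random_index - sgc_index
  if (any(den == 0)) stop("degenerate normalization: random == SGC index")
  (random_index - system_index) / den
}

#' Normalization constants for progress values
#'
#' Random-table and SGC baselines for the three indices.  The random
#' constants default to the published Monte-Carlo values for 1000 fully
#' random tables (spacing 2.284, distance 2.286, dPR 2.98; spacing and
#' distance both estimate the closed-form 2.28571 of
#' [analytic_random_pair_distance()] and are statistically identical).  The
#' SGC constants are computed exactly from the packaged fixture so that
#' progress of the SGC is 1 by construction.
#'
#' @param recompute if `TRUE`, re-estimate the random constants by
#'   simulating `n` fully random tables instead of using the published
#'   values.
#' @param n number of random tables when recomputing.
#' @param pr polar-requirement vector for dPR.
#' @return List with elements `random` and `sgc`, each a named numeric
#'   vector `(spacing, distance, dpr)`.
#' @export
norm_constants <- function(recompute = FALSE, n = 1000,
                           pr = polar_requirement()) {
  sgc_c <- .cache("sgc_norm", {
    s <- sgc()
    c(spacing = spacing_index(s), distance = distance_index(s, s),
      dpr = dpr_index(s, polar_requirement()))
  })
  if (!recompute) {
    rand_c <- c(spacing = 2.284, distance = 2.286, dpr = 2.98)
  } else {
    m <- vapply(seq_len(n), function(i) {
      t <- make_random_table()
      c(spacing_index(t), distance_index(t), dpr_index(t, pr))
    }, numeric(3))
    rand_c <- c(spacing = mean(m[1, ]), distance = mean(m[2, ]),
                dpr = mean(m[3, ]))
  }
  list(random = rand_c, sgc = sgc_c)
}

#' Progress triple of a coding table
#'
#' Computes spacing, distance and dPR and rescales each with [progress()].
#' Indices that are undefined for the table (e.g. no same-function pair)
#' propagate as `NA`.
#'
#' @param x a `coding_table`.
#' @param constants normalization constants from [norm_constants()].
#' @param reference reference table for the distance index.
#' @param pr polar-requirement vector.
#' @return Named numeric vector `(spacing, distance, dpr)` of progress
#'   values.
#' @export
#' @examples
#' progress_values(sgc())   # c(1, 1, 1)
progress_values <- function(x, constants = norm_constants(),
                            reference = sgc(), pr = polar_requirement()) {
  idx <- c(spacing = tryCatch(spacing_index(x), error = function(e) NA_real_),
           distance = tryCatch(distance_index(x, reference),
                               error = function(e) NA_real_),
           dpr = tryCatch(dpr_index(x, pr), error = function(e) NA_real_))
  progress(idx, constants$random, constants$sgc)
}

#' Fraction of tables with joint progress above a threshold
#'
#' The fraction of a population whose spacing, distance and dPR progress
#' values are simultaneously at or above `threshold` (0.9 delineates the
#' "vicinity of the SGC").  Rows with any undefined progress value are
#' counted as not exceeding the threshold and their number is reported via
#' the `"n_undefined"` attribute.
#'
#' @param pv data frame or matrix with columns `spacing`, `distance`, `dpr`
#'   of progress values (e.g. the `tables` element of [run_population()]).
#' @param threshold joint progress threshold.
#' @return Fraction in \[0, 1\].
#' @export
joint_progress_fraction <- function(pv, threshold = 0.9) {
  pv <- as.data.frame(pv)
  if (!nrow(pv)) stop("empty collection of progress triples")
  m <- as.matrix(pv[, c("spacing", "distance", "dpr")])
  bad <- apply(m, 1L, anyNA)
  ok <- !bad & m[, 1] >= threshold & m[, 2] >= threshold & m[, 3] >= threshold
  structure(mean(ok), n_undefined = sum(bad))
}

#' Closed-form random pair distance
#'
#' The exact mean mutational distance from any triplet to the 63 others:
#' 9 triplets lie 1 mutation away, 27 lie 2 away and 27 lie 3 away, so the
#' mean is (9*1 + 27*2 + 27*3)/63 = 2.28571.  This is the analytic value
#' that the Monte-Carlo spacing and distance baselines of random tables
#' estimate.
#'
#' @return The exact value 144/63.
#' @export
#' @examples
#' analytic_random_pair_distance()  # 2.28571...
analytic_random_pair_distance <- function() {
  (9 * 1 + 27 * 2 + 27 * 3) / 63
}

#' Size of the coding-table configuration space
#'
#' The number of ways to assign triplets to 20 amino acids with unassigned
#' functions allowed: 20^64 (about 1.8e83) for unconstrained non-wobbling
#' codes, or 20^32 (about 4.3e41) when assignment acts on the 32 two-codon
#' wobble groups.  These analytic counts frame why an undirected search of
#' code space cannot find the SGC, and why mostly-SGC-like initiation
#' confines evolution to a negotiable neighborhood instead.
#'
#' @param wobble count wobble-group assignments instead of single triplets.
#' @return A double (the counts exceed integer range).
#' @export
#' @examples
#' code_space_size()        # 20^64
#' code_space_size(TRUE)    # 20^32
code_space_size <- function(wobble = FALSE) {
  if (wobble) 20^32 else 20^64
}
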