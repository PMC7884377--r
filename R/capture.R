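# Capture mechanisms: the rule mapping the function of an assigned triplet
# (the source) to the function given to a neighborhood triplet it captures.
# Six ordered mechanisms are modeled, plus a fully random control:
#   random   - uniform over all 22 functions (control);
#   coevo    - uniform over the source's biosynthetically related amino
#              acids (coevolutionary pathway extension);
#   coevo_pr - as coevo, but partners are weighted linearly toward smaller
#              polar-requirement difference;
#   pr1..pr4 - paralogy: a uniform step of up to N nonzero places up or down
#              the PR-sorted amino-acid list; steps that leave the list
#              default to the source amino acid itself (0 PR change).
# An Ini or Ter source always propagates its own function (no PR is defined
# for the start/stop signals); likewise an amino acid with no coevolution
# partner under coevo/coevo_pr.

.MECHANISMS <- c("random", "coevo", "coevo_pr", "pr1", "pr2", "pr3", "pr4")

#' Construct a capture mechanism
#'
#' @param kind one of `"random"`, `"coevo"`, `"coevo_pr"`, `"pr1"`, `"pr2"`,
#'   `"pr3"`, `"pr4"` (the latter four are the 0±N polar-requirement
#'   paralogy rules).
#' @param coevo_map coevolution map for the coevolutionary kinds
#'   (default [coevolution_map()]).
#' @param pr polar-requirement vector (default [polar_requirement()]);
#'   orders the PR list for the paralogy kinds (ties broken alphabetically)
#'   and weights `coevo_pr`.
#' @param epsilon small positive floor added to the `coevo_pr` linear
#'   weights so the chemically farthest partner keeps nonzero probability.
#' @param include_zero if `TRUE`, the paralogy kinds draw offsets uniformly
#'   from -N..N including 0 instead of the default 2N nonzero offsets.
#' @return A `capture_mechanism` object for [choose_capture_function()].
#' @export
#' @examples
#' m <- capture_mechanism("pr2")
#' set.seed(1); choose_capture_function(m, "Leu")
capture_mechanism <- function(kind = .MECHANISMS, coevo_map = coevolution_map(),
                              pr = polar_requirement(), epsilon = 0.1,
                              include_zero = FALSE) {
  kind <- match.arg(kind)
  mech <- list(kind = kind, include_zero = include_zero)
  if (kind %in% c("coevo", "coevo_pr")) {
    if (is.null(coevo_map)) stop("coevolution map required for ", kind)
    partners <- lapply(.FUNS, function(f) {
      if (!f %in% names(coevo_map)) integer() else
        match(coevo_map[[f]], .FUNS)
    })
    mech$partners <- partners
    if (kind == "coevo_pr") {
      if (is.null(pr)) stop("polar requirements required for coevo_pr")
      if (epsilon <= 0) stop("epsilon must be positive")
      prf <- unname(pr[.FUNS])
      mech$weights <- lapply(seq_along(partners), function(i) {
        p <- partners[[i]]
        if (!length(p)) return(numeric())
        d <- abs(prf[i] - prf[p])
        w <- max(d) - d + epsilon     # linear, rising as |dPR| falls
        w / sum(w)
      })
    }
  }
  if (grepl("^pr[1-4]$", kind)) {
    if (is.null(pr)) stop("polar requirements required for ", kind)
    mech$span <- as.integer(sub("pr", "", kind))
    ord <- order(pr[.AA], .AA)        # PR-sorted list, ties alphabetical
    mech$sorted <- match(.AA[ord], .FUNS)       # rank -> function id
    rank <- rep(NA_integer_, .N_FUNS)
    rank[mech$sorted] <- seq_len(20)
    mech$rank <- rank                            # function id -> rank
  }
  class(mech) <- "capture_mechanism"
  mech
}

#' @export
print.capture_mechanism <- function(x, ...) {
  cat("capture mechanism:", x$kind, "\n")
  invisible(x)
}

# fast internal draw on function ids
.capture_draw <- function(mech, fi) {
  switch(mech$kind,
    random = sample.int(.N_FUNS, 1L),
    coevo = {
      p <- mech$partners[[fi]]
      if (!length(p)) fi else p[sample.int(length(p), 1L)]
    },
    coevo_pr = {
      p <- mech$partners[[fi]]
      if (!length(p)) fi
      else p[sample.int(length(p), 1L, prob = mech$weights[[fi]])]
    },
    { # pr1..pr4
      r <- mech$rank[fi]
      if (is.na(r)) return(fi)        # Ini/Ter source: same function
      n <- mech$span
      off <- if (mech$include_zero) sample.int(2L * n + 1L, 1L) - n - 1L
             else {
               o <- sample.int(2L * n, 1L)
               if (o > n) o - n else -o
             }
      r2 <- r + off
      if (r2 < 1L || r2 > 20L) fi else mech$sorted[r2]
    })
}

#' Draw the function for a captured triplet
#'
#' Applies a capture mechanism to the function of the capturing (source)
#' triplet and returns the function the captured triplet will carry.  Uses
#' R's global random number stream.
#'
#' @param mechanism a `capture_mechanism`.
#' @param source the source function name (one of [code_functions()]).
#' @return A function name.
#' @export
choose_capture_function <- function(mechanism, source) {
  if (!inherits(mechanism, "capture_mechanism"))
    stop("not a capture_mechanism")
  fi <- match(source, .FUNS)
  if (is.na(fi)) stop("unknown function: ", source)
  .FUNS[.capture_draw(mechanism, fi)]
}
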