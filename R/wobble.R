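# Simplified Crick wobble.  With only natural nucleotides, third-position
# G:U pairing makes an acceptor whose anticodon wobble position is G read
# both XYC and XYU, and one whose wobble position is U read both XYA and
# XYG.  The 64 triplets therefore fall into 32 two-member wobble groups
# (XYU/XYC and XYA/XYG).  The rule is asymmetric: XYC and XYA cannot be
# assigned alone - their only readers also read the partner - whereas XYU
# and XYG admit a wobble or non-wobble acceptor choice, so wobble extension
# there occurs with probability p_wob.  A coding triplet is permitted only
# one acceptor: extension never overwrites an existing assignment.

# partner position for each of the 64 positions (third base U<->C, A<->G)
.make_partner <- function() {
  third <- (0:63) %% 4L
  swap <- c(1L, 0L, 3L, 2L)[third + 1L]
  (0:63) - third + swap + 1L
}
.PARTNER <- .make_partner()

#' Wobble partner of a triplet
#'
#' The other member of the triplet's two-codon wobble group: XYU pairs with
#' XYC and XYA with XYG.  Partnering is an involution and the 32 groups
#' partition the codon space.
#'
#' @param t triplet(s) as strings or canonical 0-63 indices.
#' @return Character vector of partner triplets.
#' @export
#' @examples
#' wobble_partner("UUU")  # "UUC"
#' wobble_partner("GGA")  # "GGG"
wobble_partner <- function(t) .TRIPLETS[.PARTNER[.tpos(t)]]

# wobble extension probability for a 1-based position under the simplified
# Crick rules: 1 for third-base C or A (obligatory pairing), p_wob for U or G
.p_wob_eff <- function(pos, p_wob) {
  third <- (pos - 1L) %% 4L
  ifelse(third == 1L | third == 2L, 1, p_wob)
}

#' Assign a triplet with probabilistic wobble extension
#'
#' Assigns function `f` to the unassigned triplet `t`; the wobble partner
#' receives the same function when it is currently free, with probability 1
#' for triplets ending in C or A (which exist only as wobble-pair members)
#' and probability `p_wob` for triplets ending in U or G (where a
#' non-wobbling acceptor is an alternative).  An occupied partner is never
#' overwritten.  Each wobble extension increments the `wobble_initiations`
#' counter.
#'
#' @param table a `coding_table`.
#' @param t an unassigned triplet.
#' @param f a function name from [code_functions()].
#' @param p_wob wobble probability for third-base U/G triplets.
#' @return The updated `coding_table`.
#' @export
assign_with_wobble <- function(table, t, f, p_wob = 0.5) {
  p <- .tpos(t)
  if (!is.na(table$assignment[p]))
    stop("triplet ", .TRIPLETS[p], " already assigned")
  fi <- match(f, .FUNS)
  if (is.na(fi)) stop("unknown function: ", f)
  table$assignment[p] <- fi
  if (stats::runif(1) < .p_wob_eff(p, p_wob)) {
    q <- .PARTNER[p]
    if (is.na(table$assignment[q])) {
      table$assignment[q] <- fi
      table$counters["wobble_initiations"] <-
        table$counters["wobble_initiations"] + 1L
    }
  }
  table
}

#' Late wobble: extend a finished code wherever possible
#'
#' For a table evolved without wobble, adds wobble everywhere it fits: every
#' assigned triplet whose partner is unassigned donates its function to the
#' partner.  Groups whose two members already carry (possibly different)
#' functions are left unchanged.  The sweep visits triplets in ascending
#' canonical order and extensions made during the sweep do not themselves
#' extend, but because extension never overwrites, the result is
#' order-independent.  Each extension increments `wobble_initiations`.
#'
#' @param table a `coding_table`.
#' @return The updated `coding_table`.
#' @export
#' @examples
#' apply_late_wobble(coding_table(c(UUU = "Phe")))
apply_late_wobble <- function(table) {
  asg0 <- table$assignment            # pre-sweep state: no cascading
  for (p in seq_len(64)) {
    if (!is.na(asg0[p])) {
      q <- .PARTNER[p]
      if (is.na(table$assignment[q])) {
        table$assignment[q] <- asg0[p]
        table$counters["wobble_initiations"] <-
          table$counters["wobble_initiations"] + 1L
      }
    }
  }
  table
}
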