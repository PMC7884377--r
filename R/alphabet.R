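# Codon space: 64 triplets over {U,C,A,G}, canonical index 16*b1 + 4*b2 + b3
# with U,C,A,G -> 0..3.  All internal machinery works on 1-based positions
# into the canonical triplet vector; the 0-based index is the documented
# user-facing convention.

.BASES <- c("U", "C", "A", "G")

.make_triplets <- function() {
  g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

.TRIPLETS <- .make_triplets()

#' The 22 coding functions
#'
#' The function alphabet of the simulator: the 20 standard amino acids
#' (three-letter codes, alphabetical), translation initiation (`"Ini"`) and
#' termination (`"Ter"`).
#'
#' @return Character vector of length 22.
#' @export
#' @examples
#' code_functions()
code_functions <- function() .FUNS

.FUNS <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
           "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
           "Tyr", "Val", "Ini", "Ter")
.AA <- .FUNS[1:20]
.N_FUNS <- 22L

#' Triplets of the codon space
#'
#' All 64 RNA triplets in canonical order.  The canonical (0-based) index of
#' a triplet is `16*b1 + 4*b2 + b3` with bases U, C, A, G scored 0 to 3, so
#' the vector position of triplet `t` is `triplet_index(t) + 1`.
#'
#' @return Character vector of length 64.
#' @export
#' @examples
#' triplets()[1]     # "UUU"
#' triplets()[64]    # "GGG"
triplets <- function() .TRIPLETS

#' Canonical 0-63 index of a triplet
#'
#' @param t character vector of triplets (e.g. `"AUG"`).
#' @return Integer vector of indices in 0..63.
#' @export
#' @examples
#' triplet_index("UUU")  # 0
#' triplet_index("GGG")  # 63
triplet_index <- function(t) {
  i <- match(toupper(t), .TRIPLETS)
  if (anyNA(i)) stop("not a triplet over {U,C,A,G}: ",
                     paste(t[is.na(i)], collapse = ", "))
  i - 1L
}

# position (1..64) helper, vectorised, validating
.tpos <- function(t) {
  if (is.numeric(t)) {
    t <- as.integer(t)
    if (any(t < 0L | t > 63L)) stop("triplet index out of 0..63")
    return(t + 1L)
  }
  triplet_index(t) + 1L
}

#' Mutational (Hamming) distance between triplets
#'
#' Number of base substitutions needed to superpose two triplets; always in
#' 0..3.  Vectorised and symmetric.
#'
#' @param a,b triplets as strings (or canonical 0-63 indices).
#' @return Integer vector of distances.
#' @export
#' @examples
#' hamming("UUU", "UUC")  # 1
#' hamming("UUU", "AGC")  # 3
hamming <- function(a, b) {
  .HAMMING[cbind(.tpos(a), .tpos(b))]
}

# 64 x 64 distance matrix, built once at load
.make_hamming <- function() {
  i <- 0:63
  b <- cbind(i %/% 16L, (i %/% 4L) %% 4L, i %% 4L)
  h <- matrix(0L, 64, 64)
  for (p in 1:3) h <- h + outer(b[, p], b[, p], "!=")
  matrix(as.integer(h), 64, 64)
}
.HAMMING <- .make_hamming()

# 64 x 9 neighbor positions (1-based): the single-substitution mutants
.make_neighbors <- function() {
  nb <- matrix(0L, 64, 9)
  for (t in 0:63) {
    b <- c(t %/% 16L, (t %/% 4L) %% 4L, t %% 4L)
    k <- 1L
    for (p in 1:3) for (v in 0:3) if (v != b[p]) {
      bb <- b; bb[p] <- v
      nb[t + 1L, k] <- bb[1] * 16L + bb[2] * 4L + bb[3] + 1L
      k <- k + 1L
    }
  }
  nb
}
.NEIGHBORS <- .make_neighbors()

# 288 x 2 matrix of unordered neighbor pairs (positions), each pair once
.make_neighbor_pairs <- function() {
  a <- rep(seq_len(64), each = 9)
  b <- as.vector(t(.NEIGHBORS))
  keep <- a < b
  cbind(a[keep], b[keep])
}
.NEIGHBOR_PAIRS <- .make_neighbor_pairs()

#' Mutational neighborhood of a triplet
#'
#' The nine triplets one substitution away (three alternatives at each of the
#' three codon positions).  Mutational captures act within this set.
#'
#' @param t a single triplet (string or canonical index).
#' @return Character vector of 9 triplets.
#' @export
#' @examples
#' neighborhood("UUU")
neighborhood <- function(t) {
  p <- .tpos(t)
  if (length(p) != 1L) stop("one triplet at a time")
  .TRIPLETS[.NEIGHBORS[p, ]]
}
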