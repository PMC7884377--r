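# Independent brute-force oracles, string-based and loop-based on purpose:
# they share no machinery with the package's index/matrix implementation.

oracle_hamming <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# a: named character vector triplet -> function (assigned triplets only)
oracle_spacing <- function(a) {
  tot <- 0; n <- 0
  for (f in unique(a)) {
    ts <- names(a)[a == f]
    m <- length(ts)
    if (m >= 2) for (i in 1:(m - 1)) for (j in (i + 1):m) {
      tot <- tot + oracle_hamming(ts[i], ts[j]); n <- n + 1
    }
  }
  if (n == 0) stop("no pair")
  tot / n
}

# cross pairs of distinct triplets carrying the same function
oracle_distance <- function(a, b) {
  tot <- 0; n <- 0
  for (f in intersect(unique(a), unique(b))) {
    for (t in names(a)[a == f]) for (s in names(b)[b == f]) if (t != s) {
      tot <- tot + oracle_hamming(t, s); n <- n + 1
    }
  }
  if (n == 0) stop("no pair")
  tot / n
}

oracle_dpr <- function(a, pr = polar_requirement()) {
  ts <- names(a)
  tot <- 0; n <- 0
  if (length(ts) >= 2) for (i in seq_along(ts)) for (j in seq_along(ts)) {
    if (i < j && oracle_hamming(ts[i], ts[j]) == 1) {
      f1 <- a[[i]]; f2 <- a[[j]]
      if (f1 %in% names(pr) && f2 %in% names(pr) && f1 != f2) {
        tot <- tot + abs(pr[[f1]] - pr[[f2]]); n <- n + 1
      }
    }
  }
  if (n == 0) stop("no pair")
  tot / n
}

# a random partial table as a named character vector (and its coding_table)
random_partial <- function(k) {
  ts <- sample(triplets(), k)
  fs <- sample(code_functions(), k, replace = TRUE)
  stats::setNames(fs, ts)
}

as_table <- function(a) coding_table(a)

# shared scratch for expensive acceptance populations
.acc_cache <- new.env(parent = emptyenv())
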