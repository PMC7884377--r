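# The coding_table S3 class: a partial map triplet -> function with event
# counters and a passage clock.  Internally the assignment is an integer
# vector of length 64 over positions in code_functions() (NA = unassigned);
# the public accessors speak triplet and function names.

.COUNTERS <- c("initiations", "decays", "mutational_captures",
               "wobble_initiations")

.new_ct <- function(asg = rep(NA_integer_, 64),
                    counters = stats::setNames(integer(4), .COUNTERS),
                    passages = 0L) {
  structure(list(assignment = asg, counters = counters,
                 passages = passages),
            class = "coding_table")
}

#' Create a coding table
#'
#' A coding table is a partial assignment of the 64 triplets to the 22
#' functions of [code_functions()], together with event counters
#' (initiations, decays, mutational captures, wobble initiations) and a
#' passage clock.  At most one function per triplet, always.
#'
#' @param assignment named character vector, names are triplets and values
#'   functions; omitted triplets are unassigned.
#' @return A `coding_table`.
#' @export
#' @examples
#' ct <- coding_table(c(UUU = "Phe", UUC = "Phe"))
#' assigned_count(ct)
coding_table <- function(assignment = character()) {
  ct <- .new_ct()
  if (length(assignment)) {
    p <- .tpos(names(assignment))
    f <- match(assignment, .FUNS)
    if (anyNA(f)) stop("unknown function: ",
                       paste(unique(assignment[is.na(f)]), collapse = ", "))
    if (anyDuplicated(p)) stop("a triplet may carry only one function")
    ct$assignment[p] <- f
  }
  ct
}

#' @export
print.coding_table <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.coding_table <- function(x, ...) {
  # 16 x 4 grid in standard layout: rows = first base x third base,
  # columns = second base
  cell <- function(p) {
    f <- x$assignment[p]
    if (is.na(f)) "---" else .FUNS[f]
  }
  hdr <- sprintf("%-4s %-5s %-5s %-5s %-5s", "", .BASES, "", "", "")
  hdr <- paste0("     ", paste(sprintf("%-5s", .BASES), collapse = " "))
  out <- c(sprintf("coding table: %d/64 assigned, %d functions, %d passages",
                   assigned_count(x), n_functions(x), x$passages),
           paste0("  counters: ",
                  paste(sprintf("%s=%d", .COUNTERS, x$counters),
                        collapse = " ")),
           hdr)
  for (b1 in 0:3) for (b3 in 0:3) {
    row <- sprintf("%s..%s", .BASES[b1 + 1], .BASES[b3 + 1])
    cells <- vapply(0:3, function(b2)
      sprintf("%-5s", cell(b1 * 16L + b2 * 4L + b3 + 1L)), "")
    out <- c(out, paste0(row, "  ", paste(cells, collapse = " ")))
  }
  out
}

#' @rdname coding_table
#' @param x a `coding_table`.
#' @export
assignment <- function(x) {
  stats::setNames(ifelse(is.na(x$assignment), NA_character_,
                         .FUNS[x$assignment]), .TRIPLETS)
}

#' @rdname coding_table
#' @export
assigned_count <- function(x) sum(!is.na(x$assignment))

#' Number of distinct encoded functions
#'
#' Counts the distinct functions currently assigned, `Ini` and `Ter`
#' included.  With `aug_dual = TRUE` the start signal is additionally
#' considered encoded whenever AUG carries Met, mirroring the dual Met/start
#' role of AUG in the standard code.
#'
#' @param x a `coding_table`.
#' @param aug_dual count Ini as present when AUG is Met (default `FALSE`).
#' @return Integer count in 0..22.
#' @export
n_functions <- function(x, aug_dual = FALSE) {
  f <- unique(x$assignment[!is.na(x$assignment)])
  if (aug_dual) {
    ini <- match("Ini", .FUNS)
    if (!(ini %in% f) &&
        identical(x$assignment[.tpos("AUG")], match("Met", .FUNS)))
      f <- c(f, ini)
  }
  length(f)
}

#' @rdname coding_table
#' @export
is_full <- function(x) assigned_count(x) == 64L

#' @rdname coding_table
#' @param aug_dual see [n_functions()].
#' @export
is_complete <- function(x, aug_dual = FALSE) n_functions(x, aug_dual) == 22L

#' The standard genetic code
#'
#' The 64-triplet standard genetic code (SGC) as a fully assigned coding
#' table.  AUG is stored as Met; UAA, UAG and UGA are Ter.  The start
#' signal is treated as a first-class function only where it is explicitly
#' assigned (see [n_functions()] for the switchable AUG convention).
#'
#' @return A `coding_table` with all 64 triplets assigned.
#' @export
#' @examples
#' sgc()
#' spacing_index(sgc())  # 1.30
sgc <- function() {
  .cache("sgc_table", {
    d <- utils::read.delim(.extdata("sgc_table.tsv"),
                           stringsAsFactors = FALSE)
    ct <- coding_table(stats::setNames(d$function., d$triplet))
    ct
  })
}

#' Polar requirement values
#'
#' Dimensionless chromatography-derived polarity scale for the 20 amino
#' acids.  The default is the corrected scale (molecular-dynamics
#' re-evaluation of the chromatographic values, which suffered artifacts for
#' Cys and Trp); `corrected = FALSE` returns the original chromatographic
#' values.
#'
#' @param corrected logical; use the corrected scale (default).
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' polar_requirement()["Trp"]
polar_requirement <- function(corrected = TRUE) {
  d <- .cache("pr_table",
              utils::read.delim(.extdata("polar_requirement.tsv"),
                                stringsAsFactors = FALSE))
  stats::setNames(if (corrected) d$pr_corrected else d$pr_original,
                  d$amino_acid)
}

#' Coevolutionary conversion map
#'
#' Biosynthetic precursor/product relations between amino acids (pathway
#' extensions plus common interconversions), used by the coevolutionary
#' capture mechanisms.  The packaged list is a best-effort transcription of
#' the classic pathway pairs and is treated as symmetric; any user-supplied
#' two-column TSV (`amino_acid`, `related_aa`) can replace it.
#'
#' @param file optional path to a replacement TSV.
#' @return Named list: for each amino acid, the character vector of its
#'   biosynthetically related amino acids (possibly empty).
#' @export
#' @examples
#' coevolution_map()$Asp
coevolution_map <- function(file = NULL) {
  read_map <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    bad <- setdiff(unique(c(d$amino_acid, d$related_aa)), .AA)
    if (length(bad)) stop("not amino acids: ", paste(bad, collapse = ", "))
    m <- stats::setNames(vector("list", 20), .AA)
    for (i in seq_len(nrow(d))) {
      a <- d$amino_acid[i]; b <- d$related_aa[i]
      m[[a]] <- union(m[[a]], b)
      m[[b]] <- union(m[[b]], a)   # symmetric closure
    }
    lapply(m, function(v) if (is.null(v)) character() else sort(v))
  }
  if (!is.null(file)) return(read_map(file))
  .cache("coevo_map", read_map(.extdata("coevolution_map.tsv")))
}

# -- internals ---------------------------------------------------------------

.pkg_env <- new.env(parent = emptyenv())

.cache <- function(key, value) {
  if (!exists(key, envir = .pkg_env, inherits = FALSE))
    assign(key, value, envir = .pkg_env)
  get(key, envir = .pkg_env, inherits = FALSE)
}

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "sgcevolve")
  if (p == "") p <- file.path("inst", "extdata", f)  # pre-install fallback
  p
}

# integer assignment of the SGC, cached
.sgc_asg <- function() sgc()$assignment
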