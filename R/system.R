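#' Define a discrete variable system
#'
#' A variable system fixes the universe of discrete variables over which RA
#' structures, DAGs and contingency tables are defined: an ordered set of
#' distinct names and a cardinality (number of states, at least 2) for each.
#' Notation is concatenative ("ABD"), so names are single characters by
#' default; multi-character names are allowed but then structure strings must
#' separate variable tokens with commas.
#'
#' @param names character vector of distinct, non-empty variable names.
#' @param cardinalities integer vector of state counts (recycled), each >= 2.
#' @return An object of class `ra_system` with elements `names` and `card`.
#' @examples
#' ra_system(c("A", "B", "C", "D"))
#' ra_system(c("A", "B", "Z"), cardinalities = c(2, 3, 2))
#' @export
ra_system <- function(names, cardinalities = 2L) {
  names <- as.character(names)
  if (length(names) == 0L || anyDuplicated(names) || any(!nzchar(names)))
    stop("variable names must be distinct and non-empty")
  card <- as.integer(rep_len(cardinalities, length(names)))
  if (any(is.na(card)) || any(card < 2L))
    stop("every cardinality must be an integer >= 2")
  structure(list(names = names, card = stats::setNames(card, names)),
            class = "ra_system")
}

#' @export
print.ra_system <- function(x, ...) {
  cat("Variable system:",
      paste0(x$names, "(", x$card, ")", collapse = " "), "\n")
  invisible(x)
}

#' Default four-variable binary system
#'
#' Convenience constructor for the canonical examples: `n` binary variables
#' named A, B, C, ... (the neutral-system convention).  With
#' `dv = TRUE` the last variable is renamed Z, the directed-system
#' convention for the dependent variable.
#'
#' @param n number of variables (1..26).
#' @param dv logical; rename the last variable to "Z".
#' @return An `ra_system`.
#' @examples
#' abcd_system()        # A B C D
#' abcd_system(dv = TRUE)  # A B C Z
#' @export
abcd_system <- function(n = 4L, dv = FALSE) {
  stopifnot(n >= 1L, n <= 26L)
  nm <- LETTERS[seq_len(n)]
  if (dv) nm[n] <- "Z"
  ra_system(nm)
}

sys_check_vars <- function(system, vars) {
  bad <- setdiff(vars, system$names)
  if (length(bad))
    stop("unknown variable token(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

## sort variables into system order (alphabetical when names are A,B,C,...)
sys_sort <- function(system, vars) {
  vars <- unique(vars)
  vars[order(match(vars, system$names))]
}

sys_collapse <- function(system, vars) {
  sep <- if (all(nchar(system$names) == 1L)) "" else ","
  paste(sys_sort(system, vars), collapse = sep)
}

#' Construct an independence statement
#'
#' The triple (left \eqn{\perp} right | given): the variables in `left` are
#' jointly independent of those in `right` conditional on `given`.  These
#' statements are the semantic currency in which RA structures and Bayesian
#' networks are compared.
#'
#' @param left,right non-empty, disjoint character vectors of variables.
#' @param given conditioning set (possibly empty), disjoint from both.
#' @return An object of class `ind_statement`.
#' @examples
#' ind_statement("A", c("B", "C"), "D")
#' @export
ind_statement <- function(left, right, given = character()) {
  left <- sort(unique(as.character(left)))
  right <- sort(unique(as.character(right)))
  given <- sort(unique(as.character(given)))
  if (!length(left) || !length(right))
    stop("left and right sets must be non-empty")
  if (length(intersect(left, right)) || length(intersect(left, given)) ||
      length(intersect(right, given)))
    stop("left, right and given must be pairwise disjoint")
  structure(list(left = left, right = right, given = given),
            class = "ind_statement")
}

#' @export
format.ind_statement <- function(x, ...) {
  ## display convention from the published tables: when exactly one side is a
  ## single variable it is printed on the left; two single variables print in
  ## alphabetical order; two compound sides keep their roles.
  left <- x$left; right <- x$right
  swap <- (length(left) == 1L && length(right) == 1L && right < left) ||
    (length(left) > 1L && length(right) == 1L)
  if (swap) { tmp <- left; left <- right; right <- tmp }
  s <- paste0("(", paste(left, collapse = ", "), " ⊥ ",
              paste(right, collapse = ", "))
  if (length(x$given))
    s <- paste0(s, " | ", paste(x$given, collapse = ", "))
  paste0(s, ")")
}

#' @export
print.ind_statement <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## canonical key for an elementary (pair) statement
elem_key <- function(x, y, given) {
  p <- sort(c(x, y))
  paste0(p[1L], "_", p[2L], "|", paste(sort(given), collapse = ""))
}

## every elementary statement (x ⊥ y | S) over a system: the full semantic set.
## returns data.frame with columns x, y, given (list), key
elementary_grid <- function(system) {
  nm <- system$names
  n <- length(nm)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    rest <- nm[-c(i, j)]
    subs <- subset_list(rest)
    for (s in subs)
      rows[[length(rows) + 1L]] <- list(x = nm[i], y = nm[j], given = s,
                                        key = elem_key(nm[i], nm[j], s))
  }
  rows
}

## all subsets (including empty) of a character vector, as a list
subset_list <- function(vars) {
  n <- length(vars)
  if (n == 0L) return(list(character()))
  out <- vector("list", 2^n)
  for (m in 0:(2^n - 1L))
    out[[m + 1L]] <- vars[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
  out
}

#' Enumerate the independence statements of a system
#'
#' Lists every statement of the five forms used to characterize a structure
#' over `n` variables: marginal statements of a single variable against a
#' right-hand set of any size, and conditional statements between two single
#' variables.  The deduplication convention follows the printed four-variable
#' table exactly: single-vs-single marginal statements and pair statements
#' conditioned on a proper subset are listed once per unordered pair, while
#' compound right-hand sides and pair statements conditioned on all remaining
#' variables are listed once per left variable.  (For four variables this
#' yields 6 + 12 + 4 + 12 + 12 = 46 statements.)
#'
#' @param system an [ra_system()].
#' @return list of [ind_statement()] objects.
#' @export
enumerate_independence_statements <- function(system) {
  nm <- system$names
  n <- length(nm)
  if (n < 2L) stop("need at least two variables")
  out <- list()
  add <- function(l, r, g) out[[length(out) + 1L]] <<- ind_statement(l, r, g)
  ## marginal, single right: unordered pairs
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) add(nm[i], nm[j], character())
  ## marginal, compound right (size 2 .. n-1): one per ordered left variable
  for (x in nm) {
    rest <- setdiff(nm, x)
    for (k in seq_along(rest)) if (k >= 2L) {
      for (r in utils::combn(rest, k, simplify = FALSE)) add(x, r, character())
    }
  }
  ## conditional pair, |S| < n-2: unordered pairs
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    rest <- nm[-c(i, j)]
    for (k in seq_along(rest)) if (k < length(rest)) {
      for (s in utils::combn(rest, k, simplify = FALSE)) add(nm[i], nm[j], s)
    }
  }
  ## conditional pair given all remaining variables: ordered
  if (n >= 3L) for (x in nm) for (y in setdiff(nm, x))
    add(x, y, setdiff(nm, c(x, y)))
  out
}
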