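## RA / extended-BN notation: parsing, canonical printing, antichain algebra.

#' Create an RA structure from relations
#'
#' An RA structure is a set of relations (subsets of the system's variables)
#' forming an antichain whose union covers every variable, e.g. AD:BD:CD.
#' Parts may carry subscript blocks (see [parse_structure()]) encoding
#' V-structure independencies; a structure with no subscripts is a plain RA
#' model.
#'
#' @param system an [ra_system()].
#' @param relations list of character vectors (one per relation).
#' @param subs optional list (parallel to `relations`) of subscript blocks;
#'   each block is a list of character-vector groups.
#' @return An object of class `ra_structure`.
#' @examples
#' s <- abcd_system()
#' ra_structure(s, list(c("A", "D"), c("B", "D"), c("C", "D")))
#' @export
ra_structure <- function(system, relations, subs = NULL) {
  if (!length(relations)) stop("a structure needs at least one relation")
  relations <- lapply(relations, function(r) {
    r <- sys_sort(system, r)
    if (!length(r)) stop("empty relation")
    sys_check_vars(system, r)
    r
  })
  if (is.null(subs)) subs <- rep(list(list()), length(relations))
  stopifnot(length(subs) == length(relations))
  subs <- lapply(seq_along(subs), function(i) {
    lapply(subs[[i]], function(block)
      lapply(block, function(g) {
        g <- sys_sort(system, g)
        if (!all(g %in% relations[[i]]))
          stop("subscript variables must lie inside their host relation")
        g
      }))
  })
  ## merge exact duplicate relations (pooling their subscript blocks) and
  ## drop plain parts embedded in a strictly larger part
  keys <- vapply(relations, function(r) sys_collapse(system, r), "")
  keep <- rep(TRUE, length(relations))
  for (i in seq_along(relations)) {
    if (!keep[i]) next
    for (j in seq_along(relations)) {
      if (i == j || !keep[j] || !keep[i]) next
      if (identical(keys[i], keys[j]) && i > j) {
        subs[[j]] <- unique(c(subs[[j]], subs[[i]]))
        keep[i] <- FALSE
      } else if (!identical(keys[i], keys[j]) &&
                 all(relations[[i]] %in% relations[[j]]) &&
                 length(subs[[i]]) == 0L) {
        keep[i] <- FALSE
      }
    }
  }
  relations <- relations[keep]; subs <- subs[keep]
  if (!setequal(unlist(relations), system$names))
    stop("relations must jointly cover every variable of the system")
  x <- structure(list(system = system, relations = relations, subs = subs),
                 class = "ra_structure")
  canonical_order(x)
}

## sort relations (descending size, then lexicographic) and subscript groups
canonical_order <- function(x) {
  sys <- x$system
  relkey <- vapply(x$relations, function(r) sys_collapse(sys, r), "")
  ord <- order(-lengths(x$relations), relkey)
  x$relations <- x$relations[ord]
  x$subs <- lapply(x$subs[ord], function(blocks) {
    blocks <- lapply(blocks, function(b) {
      gk <- vapply(b, function(g) sys_collapse(sys, g), "")
      b[order(-lengths(b), gk)]
    })
    bk <- vapply(blocks, function(b)
      paste(vapply(b, function(g) sys_collapse(sys, g), ""), collapse = ":"), "")
    blocks[order(bk)]
  })
  x
}

#' @export
print.ra_structure <- function(x, ...) {
  cat(canonical_text(x), "\n")
  invisible(x)
}

#' @export
format.ra_structure <- function(x, ...) canonical_text(x)

#' Parse RA / extended-BN notation
#'
#' Grammar: `structure := part (':' part)*`;
#' `part := VARS ['_' substructure '_']`;
#' `substructure := VARS (':' VARS)*`.  Whitespace is ignored.  With
#' single-character variable names, `VARS` is a concatenation of tokens
#' ("ABD"); multi-character names are comma-separated.  A subscript block
#' such as `BCD_B:C_` records independencies internal to a relation (here,
#' B and C marginally independent inside the triadic BCD relation); plain
#' parts have no block.  Duplicate relations are merged silently, as are
#' plain relations embedded in a larger relation.
#'
#' @param text notation string, e.g. `"AD:BD:CD"` or `"BCD_B:C_:A"`.
#' @param system an [ra_system()].
#' @return An `ra_structure`.
#' @examples
#' s <- abcd_system()
#' parse_structure("AD:BD:CD", s)
#' parse_structure("BCD_B:C_:A", s)
#' @export
parse_structure <- function(text, system) {
  txt <- gsub("[[:space:]]", "", text)
  if (!nzchar(txt)) stop("empty structure string")
  ## split on ':' not inside '_..._'
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L; cuts <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "_") depth <- 1L - depth
    else if (chars[i] == ":" && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(chars))
  parts <- mapply(function(s, e)
    if (s > e) "" else paste(chars[s:e], collapse = ""), starts, ends)
  if (any(!nzchar(parts))) stop("empty relation")
  relations <- list(); subs <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^([^_]+)((_[^_]+_)*)$", p))[[1]]
    if (length(m) == 0L || !nzchar(m[2]))
      stop("malformed part: ", p)
    relations[[length(relations) + 1L]] <- split_vars(m[2], system)
    blocks <- list()
    rest <- m[3]
    while (nzchar(rest)) {
      bm <- regmatches(rest, regexec("^_([^_]+)_(.*)$", rest))[[1]]
      groups <- lapply(strsplit(bm[2], ":", fixed = TRUE)[[1]],
                       split_vars, system = system)
      if (length(groups) < 2L)
        stop("a subscript block needs at least two groups: ", p)
      blocks[[length(blocks) + 1L]] <- groups
      rest <- bm[3]
    }
    subs[[length(subs) + 1L]] <- blocks
  }
  ra_structure(system, relations, subs)
}

split_vars <- function(s, system) {
  toks <- if (all(nchar(system$names) == 1L)) strsplit(s, "")[[1]]
          else strsplit(s, ",", fixed = TRUE)[[1]]
  sys_check_vars(system, toks)
  sys_sort(system, toks)
}

#' Canonical notation string of a structure
#'
#' Variables are printed in system order within each relation; relations are
#' sorted by descending size then lexicographically (a convention -- the
#' notation itself is order-free); subscript groups likewise.  The round trip
#' `parse_structure(canonical_text(x), system)` reproduces `x`.
#'
#' @param x an `ra_structure`.
#' @return A notation string.
#' @export
canonical_text <- function(x) {
  sys <- x$system
  x <- canonical_order(x)
  parts <- vapply(seq_along(x$relations), function(i) {
    p <- sys_collapse(sys, x$relations[[i]])
    for (block in x$subs[[i]]) {
      p <- paste0(p, "_",
                  paste(vapply(block, function(g) sys_collapse(sys, g), ""),
                        collapse = ":"), "_")
    }
    p
  }, "")
  paste(parts, collapse = ":")
}

#' Reduce a set of relations to its maximal antichain
#'
#' Relations include all of their embedded relations, so a relation strictly
#' contained in another carries no extra constraint and is dropped.
#'
#' @param relations list of character vectors.
#' @return list of character vectors, the maximal elements.
#' @examples
#' maximal_relations(list(c("A","B","C"), c("A","B"), "C"))
#' @export
maximal_relations <- function(relations) {
  if (!length(relations)) stop("empty relation set")
  relations <- lapply(relations, function(r) sort(unique(as.character(r))))
  relations <- unique(relations)
  keep <- vapply(seq_along(relations), function(i) {
    !any(vapply(seq_along(relations), function(j) {
      i != j && all(relations[[i]] %in% relations[[j]]) &&
        length(relations[[i]]) < length(relations[[j]])
    }, TRUE))
  }, TRUE)
  relations[keep]
}

## plain relation-set key (subscripts ignored) for comparing RA structures
relset_key <- function(x) {
  paste(sort(vapply(x$relations, function(r) paste(sort(r), collapse = ""), "")),
        collapse = ":")
}

## is x a plain RA structure (no subscript blocks)?
is_plain <- function(x) all(lengths(x$subs) == 0L)

## the independence statements encoded by subscript blocks:
## groups G1..Gk with common intersection S give the chain
## (G_i \ S  ⊥  union of later groups \ S | S).
subscript_statements <- function(x) {
  out <- list()
  for (i in seq_along(x$subs)) for (block in x$subs[[i]]) {
    S <- Reduce(intersect, block)
    res <- lapply(block, function(g) setdiff(g, S))
    for (j in seq_len(length(res) - 1L)) {
      rhs <- unique(unlist(res[(j + 1L):length(res)]))
      out[[length(out) + 1L]] <- ind_statement(res[[j]], rhs, S)
    }
  }
  out
}

#' Test two structures or DAGs for unlabeled isomorphism
#'
#' TRUE when some bijection of variable names maps one object onto the other:
#' for RA structures the relation sets must coincide, for DAGs the directed
#' edge sets.  General ("unlabeled") graphs are the equivalence classes of
#' this relation.  Decided by exhaustive permutation, which is the right tool
#' at the small n for which the lattices are enumerable.
#'
#' @param a,b two `ra_structure`s or two `bn_dag`s over systems of equal size.
#' @param fix character vector of variable names that the bijection must map
#'   to themselves (used for directed systems, where the DV is distinguished).
#' @return logical.
#' @examples
#' s3 <- ra_system(c("A","B","C"))
#' unlabeled_isomorphic(parse_structure("AB:BC", s3), parse_structure("AB:AC", s3))
#' @export
unlabeled_isomorphic <- function(a, b, fix = character()) {
  if (!identical(class(a), class(b)))
    stop("cannot compare objects of different kinds")
  if (inherits(a, "ra_structure")) {
    key <- relset_key
    nm <- a$system$names
    if (length(b$system$names) != length(nm)) stop("systems differ in size")
    relabel <- function(x, perm) {
      x$relations <- lapply(x$relations, function(r) unname(perm[r]))
      x
    }
  } else if (inherits(a, "bn_dag")) {
    key <- function(d) paste(sort(paste0(d$edges[, 1L], ">", d$edges[, 2L])),
                             collapse = ";")
    nm <- a$system$names
    if (length(b$system$names) != length(nm)) stop("systems differ in size")
    relabel <- function(x, perm) {
      if (nrow(x$edges))
        x$edges <- cbind(unname(perm[x$edges[, 1L]]),
                         unname(perm[x$edges[, 2L]]))
      x
    }
  } else stop("unsupported object kind")
  target <- key(b)
  for (perm in var_permutations(nm, b$system$names, fix)) {
    if (identical(key(relabel(a, perm)), target)) return(TRUE)
  }
  FALSE
}

## all bijections from `from` names onto `to` names, fixing `fix`
var_permutations <- function(from, to, fix = character()) {
  free_from <- setdiff(from, fix)
  free_to <- setdiff(to, fix)
  stopifnot(length(free_from) == length(free_to))
  perms <- perm_matrix(length(free_from))
  out <- vector("list", nrow(perms))
  for (i in seq_len(nrow(perms))) {
    map <- stats::setNames(c(free_to[perms[i, ]], fix), c(free_from, fix))
    out[[i]] <- map
  }
  out
}

## all permutations of 1..n as a matrix (n! rows); n is small here
perm_matrix <- function(n) {
  if (n == 0L) return(matrix(integer(), 1L, 0L))
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
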