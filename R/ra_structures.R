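## RA neutral and directed structure lattices, loop detection and RA
## independence semantics.

#' Loop test for an RA structure (Graham reduction)
#'
#' A structure is loopless iff its hypergraph of relations is acyclic, decided
#' by Graham reduction: repeatedly delete variables appearing in exactly one
#' relation and relations contained in another; the structure is loopless iff
#' the reduction empties it.  Loopless structures are decomposable: their
#' maximum-entropy solution has closed form, while loopy structures need
#' iterative proportional fitting.
#'
#' @param structure an `ra_structure` (subscripts, if any, are ignored).
#' @return logical: TRUE when the structure has a loop.
#' @examples
#' s <- abcd_system()
#' has_loop(parse_structure("AB:BC:CD:AD", s))  # TRUE
#' has_loop(parse_structure("AD:BD:CD", s))     # FALSE
#' @export
has_loop <- function(structure) {
  rels <- lapply(structure$relations, identity)
  repeat {
    if (length(rels) <= 1L) return(FALSE)
    changed <- FALSE
    ## drop relations contained in another
    keep <- vapply(seq_along(rels), function(i)
      !any(vapply(seq_along(rels), function(j)
        i != j && all(rels[[i]] %in% rels[[j]]) &&
          !(length(rels[[i]]) == length(rels[[j]]) && i > j), TRUE)), TRUE)
    if (!all(keep)) { rels <- rels[keep]; changed <- TRUE }
    ## drop variables appearing in exactly one relation
    tab <- table(unlist(rels))
    solo <- names(tab)[tab == 1L]
    if (length(solo)) {
      rels <- lapply(rels, function(r) setdiff(r, solo))
      rels <- rels[lengths(rels) > 0L]
      changed <- TRUE
    }
    if (length(rels) <= 1L) return(FALSE)
    if (!changed) return(TRUE)
  }
}

#' Children of an RA structure in the neutral lattice
#'
#' Deleting a (non-singleton) maximal relation exposes its embedded relations:
#' the child keeps the other relations plus all facets of the deleted one and
#' reduces to the maximal antichain, so every variable stays covered
#' (singletons surface where needed and are themselves never deletable).
#'
#' @param structure an `ra_structure` without subscripts.
#' @return list of `ra_structure`, deduplicated and canonical.
#' @examples
#' s <- abcd_system()
#' ra_children(parse_structure("ABCD", s))  # ABC:ABD:ACD:BCD
#' @export
ra_children <- function(structure) {
  sys <- structure$system
  rels <- structure$relations
  out <- list(); seen <- character()
  for (i in seq_along(rels)) {
    if (length(rels[[i]]) < 2L) next
    facets <- utils::combn(rels[[i]], length(rels[[i]]) - 1L,
                           simplify = FALSE)
    cand <- maximal_relations(c(rels[-i], facets))
    child <- ra_structure(sys, cand)
    key <- canonical_text(child)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- child
    }
  }
  out
}

## co-occurrence adjacency of a structure: variables adjacent iff they share
## a relation
cooccurrence_adj <- function(structure) {
  nm <- structure$system$names
  adj <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (r in structure$relations)
    if (length(r) >= 2L) adj[r, r] <- TRUE
  diag(adj) <- FALSE
  adj
}

## graph separation: are x and y disconnected after removing S?
graph_separated <- function(adj, x, y, S = character()) {
  keep <- setdiff(rownames(adj), S)
  sub <- adj[keep, keep, drop = FALSE]
  !und_connected(sub, x, y)
}

ra_elementary <- function(structure) {
  adj <- cooccurrence_adj(structure)
  keys <- character()
  for (e in elementary_grid(structure$system))
    if (graph_separated(adj, e$x, e$y, e$given)) keys <- c(keys, e$key)
  sort(keys)
}

#' Independencies of an RA structure
#'
#' (x \eqn{\perp} y | S) holds iff S separates x and y in the co-occurrence
#' graph (variables adjacent when they share a relation); compound right-hand
#' sides hold by composition.  For loopless structures the display list is
#' obtained through the equivalent decomposable DAG; for loopy structures a
#' local-Markov style list is returned.
#'
#' @param structure an `ra_structure`.
#' @return An `ind_set` (see [independencies()]).
#' @examples
#' s <- abcd_system()
#' ra_independencies(parse_structure("AD:BD:CD", s))
#' @export
ra_independencies <- function(structure) {
  elem <- ra_elementary(structure)
  display <- if (!has_loop(structure)) {
    bn_display_list(dag_of_loopless(structure))
  } else {
    ra_display_loopy(structure)
  }
  structure(list(elementary = elem, display = display), class = "ind_set")
}

## decomposable DAG of a loopless structure: maximum cardinality search on the
## (chordal) co-occurrence graph, edges directed from earlier to later in the
## MCS order (ties broken toward later system order, mirroring the display
## convention).  The result has no V-structures and the same independencies.
dag_of_loopless <- function(structure) {
  adj <- cooccurrence_adj(structure)
  nm <- rownames(adj)
  order <- character()
  remaining <- nm
  while (length(remaining)) {
    score <- vapply(remaining, function(v) sum(adj[v, order]), 0)
    best <- remaining[score == max(score)]
    v <- best[which.max(match(best, nm))]
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  edges <- matrix(character(), 0L, 2L)
  for (j in seq_along(order)) {
    earlier <- order[seq_len(j - 1L)]
    pa <- earlier[adj[order[j], earlier]]
    if (length(pa)) edges <- rbind(edges, cbind(pa, order[j]))
  }
  bn_dag(structure$system, edges)
}

## display list for loopy structures: per variable, the local Markov statement
## (x ⊥ non-neighbors | neighbors), deduplicated against statements already
## implied as mirror images.
ra_display_loopy <- function(structure) {
  adj <- cooccurrence_adj(structure)
  nm <- rownames(adj)
  out <- list(); seen <- character()
  for (x in nm) {
    bd <- nm[adj[x, ]]
    rest <- setdiff(nm, c(x, bd))
    rest <- rest[vapply(rest, function(y) graph_separated(adj, x, y, bd), TRUE)]
    if (!length(rest)) next
    key <- paste(sort(c(x, rest)), collapse = "")
    mirror <- any(vapply(out, function(s)
      setequal(c(s$left, s$right), c(x, rest)) && setequal(s$given, bd), TRUE))
    if (!mirror) out[[length(out) + 1L]] <- ind_statement(x, rest, bd)
  }
  merge_contraction(out)
}

#' The RA neutral-system lattice
#'
#' Transitive closure of the relation-deletion child rule from the saturated
#' structure (the single relation over all variables) down to full
#' independence.  Specific structures are the distinct canonical structures;
#' general classes group them by unlabeled hypergraph isomorphism.  For four
#' variables: 114 specific structures in 20 general classes, 10 of them
#' loopless.
#'
#' @param system an [ra_system()].
#' @return An object of class `ra_lattice`: `structures` (list), `keys`
#'   (canonical texts), `children` (list of integer index vectors, the
#'   hierarchy), `loopless` (logical), `general` (list of integer index
#'   vectors), `elementary` (list of key vectors).
#' @export
ra_lattice <- function(system) {
  top <- ra_structure(system, list(system$names))
  structures <- list(top)
  keys <- canonical_text(top)
  children <- list(integer())
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    kids <- ra_children(structures[[i]])
    idx <- integer()
    for (ch in kids) {
      k <- canonical_text(ch)
      j <- match(k, keys)
      if (is.na(j)) {
        structures[[length(structures) + 1L]] <- ch
        keys <- c(keys, k)
        children[[length(children) + 1L]] <- integer()
        j <- length(structures)
        queue <- c(queue, j)
      }
      idx <- c(idx, j)
    }
    children[[i]] <- sort(unique(idx))
  }
  finish_lattice(system, structures, keys, children, kind = "ra-neutral")
}

finish_lattice <- function(system, structures, keys, children, kind,
                           fix = character()) {
  loopless <- vapply(structures, function(s) !has_loop(s), TRUE)
  elementary <- lapply(structures, ra_elementary)
  sigs <- vapply(structures, function(s)
    relset_signature(s, fix = fix), "")
  groups <- split(seq_along(structures), sigs)
  groups <- lapply(groups[order(vapply(groups, min, 0L))], unname)
  structure(list(system = system, structures = structures, keys = keys,
                 children = children, loopless = loopless,
                 elementary = elementary, general = unname(groups),
                 kind = kind),
            class = "ra_lattice")
}

## canonical relation-set signature under variable permutation (optionally
## fixing some variables) -- unlabeled hypergraph isomorphism classes
relset_signature <- function(structure, fix = character()) {
  nm <- structure$system$names
  best <- NULL
  for (perm in var_permutations(nm, nm, fix)) {
    key <- paste(sort(vapply(structure$relations, function(r)
      paste(sort(unname(perm[r])), collapse = ""), "")), collapse = ":")
    if (is.null(best) || key < best) best <- key
  }
  best
}

#' @export
print.ra_lattice <- function(x, ...) {
  cat(sprintf("%s lattice: %d specific structures, %d general classes (%d loopless specific)\n",
              x$kind, length(x$structures), length(x$general),
              sum(x$loopless)))
  invisible(x)
}

#' Directed-system specification
#'
#' Splits a system into explanatory variables (IVs) and a single dependent
#' variable (DV), conventionally named Z.
#'
#' @param system an [ra_system()].
#' @param dv name of the dependent variable (default: last variable).
#' @return list with `ivs` and `dv`, class `directed_spec`.
#' @export
directed_spec <- function(system, dv = system$names[length(system$names)]) {
  sys_check_vars(system, dv)
  stopifnot(length(dv) == 1L)
  structure(list(system = system, ivs = setdiff(system$names, dv), dv = dv),
            class = "directed_spec")
}

#' Conventional RA directed-system lattice
#'
#' Models for predicting a single DV: every structure contains the "IV
#' relation" (all IVs jointly) plus a non-empty antichain of DV-containing
#' relations -- the DV alone being allowed, giving the independence model
#' IVs:Z.  Structures where the IV relation is embedded are canonicalized
#' (the top is the saturated relation, not IVs:ALL).  For three IVs this
#' yields 19 specific structures in 9 general classes (classes fix the DV and
#' permute only IVs).
#'
#' @param system an [ra_system()].
#' @param spec a [directed_spec()] (default: last variable is the DV).
#' @return An `ra_lattice` (kind `"ra-directed"`).
#' @export
conventional_directed_lattice <- function(system,
                                          spec = directed_spec(system)) {
  sets <- dv_antichains(spec)
  structures <- lapply(sets, function(Tset)
    ra_structure(system, c(list(spec$ivs),
                           lapply(Tset, function(s) c(s, spec$dv)))))
  keys <- vapply(structures, canonical_text, "")
  ord <- order(keys)
  structures <- structures[ord]; keys <- keys[ord]
  children <- directed_children(structures, keys, spec)
  ## general classes group by unrestricted isomorphism: the directed lattices
  ## label their general graphs by the neutral general graph they belong to
  finish_lattice(system, structures, keys, children, kind = "ra-directed")
}

## all non-empty antichains of subsets of the IV set (each subset s standing
## for the relation s + DV)
dv_antichains <- function(spec) {
  subs <- subset_list(spec$ivs)   # 2^k subsets incl. empty ({} -> DV alone)
  fam <- list()
  for (m in seq_len(2^length(subs)) - 1L) {
    pick <- subs[bitwAnd(m, bitwShiftL(1L, seq_along(subs) - 1L)) > 0L]
    if (!length(pick)) next
    is_anti <- TRUE
    if (length(pick) > 1L) {
      for (i in seq_along(pick)) for (j in seq_along(pick)) {
        if (i != j && all(pick[[i]] %in% pick[[j]])) { is_anti <- FALSE; break }
      }
    }
    if (is_anti) fam[[length(fam) + 1L]] <- pick
  }
  fam
}

## hierarchy within a directed lattice: child = delete one non-singleton
## DV-relation (down-closure style), IV relation kept
directed_children <- function(structures, keys, spec) {
  lapply(structures, function(st) {
    kids <- integer()
    for (i in seq_along(st$relations)) {
      r <- st$relations[[i]]
      if (!(spec$dv %in% r) || length(r) < 2L) next
      facets <- utils::combn(r, length(r) - 1L, simplify = FALSE)
      facets <- c(facets, list(spec$ivs))   # IV relation always present
      cand <- maximal_relations(c(st$relations[-i], facets,
                                  list(spec$dv)))
      child <- ra_structure(st$system, cand)
      j <- match(canonical_text(child), keys)
      if (!is.na(j)) kids <- c(kids, j)
    }
    sort(unique(kids))
  })
}

#' Augmented RA directed-system lattice
#'
#' Adds to the conventional lattice the "primed" variants obtained by removing
#' the IV relation (re-covering dropped IVs with singletons).  A primed
#' variant is retained only when it has at least two DV-containing relations
#' -- with a single one, its maximum-entropy prediction of the DV is identical
#' to its unprimed parent's -- plus the full-independence structure
#' A:B:...:Z.  For three IVs: 31 specific structures in 12 general classes.
#'
#' @inheritParams conventional_directed_lattice
#' @return An `ra_lattice` (kind `"ra-augmented"`); primed members are flagged
#'   in the `primed` field.
#' @export
augmented_directed_lattice <- function(system, spec = directed_spec(system)) {
  conv <- conventional_directed_lattice(system, spec)
  structures <- conv$structures
  keys <- conv$keys
  primed_of <- rep(NA_integer_, length(structures))
  for (i in seq_along(conv$structures)) {
    st <- conv$structures[[i]]
    zrels <- Filter(function(r) spec$dv %in% r, st$relations)
    if (length(zrels) < 2L) next
    covered <- unique(unlist(zrels))
    singles <- as.list(setdiff(spec$ivs, covered))
    child <- ra_structure(system, c(zrels, singles))
    k <- canonical_text(child)
    if (!(k %in% keys)) {
      structures[[length(structures) + 1L]] <- child
      keys <- c(keys, k)
      primed_of[length(structures)] <- i
    }
  }
  ## the natural independence model of the primed graphs
  bottom <- ra_structure(system, as.list(system$names))
  kb <- canonical_text(bottom)
  if (!(kb %in% keys)) {
    structures[[length(structures) + 1L]] <- bottom
    keys <- c(keys, kb)
    primed_of[length(structures)] <- NA_integer_
  }
  ## hierarchy: conventional edges, unprimed -> primed links, and deletion
  ## edges among the added structures
  children <- vector("list", length(structures))
  for (i in seq_along(structures)) children[[i]] <- integer()
  for (i in seq_along(conv$children)) children[[i]] <- conv$children[[i]]
  for (j in seq_along(primed_of)) {
    if (!is.na(primed_of[j]))
      children[[primed_of[j]]] <- sort(unique(c(children[[primed_of[j]]], j)))
  }
  extra <- which(seq_along(structures) > length(conv$structures))
  for (j in extra) {
    for (ch in ra_children(structures[[j]])) {
      k <- match(canonical_text(ch), keys)
      if (!is.na(k)) children[[j]] <- sort(unique(c(children[[j]], k)))
    }
  }
  lat <- finish_lattice(system, structures, keys, children,
                        kind = "ra-augmented")
  lat$primed <- seq_along(structures) > length(conv$structures)
  lat
}

#' JSON export of a lattice
#'
#' @param lattice an `ra_lattice`.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
lattice_json <- function(lattice, path = NULL) {
  gen_id <- integer(length(lattice$structures))
  for (g in seq_along(lattice$general)) gen_id[lattice$general[[g]]] <- g
  entries <- lapply(seq_along(lattice$structures), function(i) {
    list(id = i,
         notation = lattice$keys[i],
         relations = lapply(lattice$structures[[i]]$relations, identity),
         general_class_id = gen_id[i],
         loopless = lattice$loopless[i],
         children = lattice$children[[i]])
  })
  obj <- list(schema = "rabn-lattice-1", kind = lattice$kind,
              variables = lattice$system$names, structures = entries)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' DOT export of a lattice diagram
#'
#' @param lattice an `ra_lattice`.
#' @return character scalar with DOT source (nodes labeled by notation,
#'   hierarchy edges from parent to child).
#' @export
lattice_dot <- function(lattice) {
  nodes <- paste0("  n", seq_along(lattice$keys), " [label=\"",
                  lattice$keys, "\"];")
  edges <- unlist(lapply(seq_along(lattice$children), function(i)
    if (length(lattice$children[[i]]))
      paste0("  n", i, " -> n", lattice$children[[i]], ";")))
  paste(c("digraph lattice {", nodes, edges, "}"), collapse = "\n")
}
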