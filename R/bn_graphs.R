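## Bayesian-network topologies: DAG enumeration, d-separation, Markov
## equivalence, CPDAGs, factorization, and extended-notation generation.

#' Construct a labeled DAG
#'
#' @param system an [ra_system()].
#' @param edges two-column character matrix (or data.frame) of parent -> child
#'   pairs; may have zero rows for the empty graph.
#' @return An object of class `bn_dag`.
#' @examples
#' s <- abcd_system()
#' bn_dag(s, rbind(c("B", "D"), c("C", "D")))
#' @export
bn_dag <- function(system, edges = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), 0L, 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    stopifnot(ncol(edges) == 2L)
    sys_check_vars(system, as.vector(edges))
    if (any(edges[, 1L] == edges[, 2L])) stop("self-edges are not allowed")
    if (anyDuplicated(paste0(edges[, 1L], ">", edges[, 2L])))
      stop("duplicate edge")
    both <- paste0(pmin(edges[, 1L], edges[, 2L]), "-",
                   pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(both)) stop("a pair of variables has edges both ways")
  }
  d <- structure(list(system = system, edges = edges), class = "bn_dag")
  if (!is_acyclic(adj_matrix(d))) stop("graph contains a directed cycle")
  d
}

## n x n logical adjacency matrix, adj[i, j] == TRUE iff names[i] -> names[j]
adj_matrix <- function(dag) {
  nm <- dag$system$names
  a <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  if (nrow(dag$edges)) a[dag$edges] <- TRUE
  a
}

is_acyclic <- function(adj) {
  remaining <- rep(TRUE, nrow(adj))
  repeat {
    if (!any(remaining)) return(TRUE)
    indeg <- colSums(adj[remaining, remaining, drop = FALSE])
    src <- which(remaining)[indeg == 0L]
    if (!length(src)) return(FALSE)
    remaining[src] <- FALSE
  }
}

parents_of <- function(dag, v) dag$edges[dag$edges[, 2L] == v, 1L]
children_of <- function(dag, v) dag$edges[dag$edges[, 1L] == v, 2L]

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG over", paste(x$system$names, collapse = ","), ":",
      dag_text(x), "\n")
  invisible(x)
}

#' Serialize / parse the DAG text format
#'
#' Edges are written `"parent>child"` joined by semicolons; isolated nodes are
#' appended as bare tokens, e.g. `"B>D;C>D;A"`.
#'
#' @param dag a `bn_dag`.
#' @return `dag_text()`: a string; `parse_dag()`: a `bn_dag`.
#' @examples
#' s <- abcd_system()
#' parse_dag("B>D;C>D;A", s)
#' @export
dag_text <- function(dag) {
  nm <- dag$system$names
  used <- unique(as.vector(dag$edges))
  parts <- character()
  if (nrow(dag$edges)) {
    e <- paste0(dag$edges[, 1L], ">", dag$edges[, 2L])
    parts <- sort(e)
  }
  iso <- setdiff(nm, used)
  paste(c(parts, iso), collapse = ";")
}

#' @rdname dag_text
#' @param text DAG text format string.
#' @param system an [ra_system()].
#' @export
parse_dag <- function(text, system) {
  toks <- strsplit(gsub("[[:space:]]", "", text), ";", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  is_edge <- grepl(">", toks, fixed = TRUE)
  edges <- do.call(rbind, lapply(toks[is_edge], function(t) {
    p <- strsplit(t, ">", fixed = TRUE)[[1]]
    if (length(p) != 2L) stop("malformed edge token: ", t)
    p
  }))
  sys_check_vars(system, toks[!is_edge])
  bn_dag(system, edges)
}

#' Enumerate all labeled DAGs of a system
#'
#' Every unordered variable pair is either unconnected or oriented one of two
#' ways; cyclic assignments are discarded.  Order is deterministic.  For four
#' variables this yields 543 DAGs; growth is hyper-exponential, so enumeration
#' is refused above `max_n`.
#'
#' @param system an [ra_system()].
#' @param max_n refusal bound for exhaustive enumeration (default 6).
#' @return list of `bn_dag`.
#' @export
enumerate_dags <- function(system, max_n = 6L) {
  nm <- system$names
  n <- length(nm)
  if (n > max_n)
    stop("exhaustive DAG enumeration refused for n > ", max_n,
         " (hyper-exponential growth); raise max_n to force")
  if (n == 1L) return(list(bn_dag(system)))
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  out <- list()
  state <- integer(np)  # 0 none, 1 i->j, 2 j->i
  repeat {
    a <- matrix(FALSE, n, n, dimnames = list(nm, nm))
    for (k in seq_len(np)) {
      if (state[k] == 1L) a[pairs[1L, k], pairs[2L, k]] <- TRUE
      else if (state[k] == 2L) a[pairs[2L, k], pairs[1L, k]] <- TRUE
    }
    if (is_acyclic(a)) {
      idx <- which(a, arr.ind = TRUE)
      e <- if (nrow(idx)) cbind(nm[idx[, 1L]], nm[idx[, 2L]])
           else matrix(character(), 0L, 2L)
      out[[length(out) + 1L]] <-
        structure(list(system = system, edges = e), class = "bn_dag")
    }
    ## increment base-3 counter
    k <- 1L
    while (k <= np) {
      state[k] <- state[k] + 1L
      if (state[k] <= 2L) break
      state[k] <- 0L; k <- k + 1L
    }
    if (k > np) break
  }
  out
}

#' Skeleton and V-structures of a DAG
#'
#' The skeleton is the undirected edge set.  A V-structure is a pair of edges
#' converging on a common child whose parents are not themselves adjacent;
#' V-structures are what distinguish BN independence semantics from RA.
#'
#' @param dag a `bn_dag`.
#' @return `skeleton()`: character vector of sorted `"X-Y"` pairs;
#'   `v_structures()`: character vector `"parent1>child<parent2"` with
#'   parent1 < parent2.
#' @examples
#' s <- ra_system(c("A","B","C"))
#' v_structures(parse_dag("A>B;C>B", s))
#' @export
skeleton <- function(dag) {
  if (!nrow(dag$edges)) return(character())
  sort(paste0(pmin(dag$edges[, 1L], dag$edges[, 2L]), "-",
              pmax(dag$edges[, 1L], dag$edges[, 2L])))
}

#' @rdname skeleton
#' @export
v_structures <- function(dag) {
  sk <- skeleton(dag)
  out <- character()
  for (v in dag$system$names) {
    pa <- parents_of(dag, v)
    if (length(pa) < 2L) next
    cmb <- utils::combn(sort(pa), 2L)
    for (k in seq_len(ncol(cmb))) {
      p1 <- cmb[1L, k]; p2 <- cmb[2L, k]
      if (!(paste0(p1, "-", p2) %in% sk))
        out <- c(out, paste0(p1, ">", v, "<", p2))
    }
  }
  sort(out)
}

#' Markov equivalence of two DAGs
#'
#' Two DAGs over the same system are Markov equivalent iff they have the same
#' skeleton and the same V-structures, hence identical d-separation
#' independencies.
#'
#' @param d1,d2 `bn_dag` objects over the same system.
#' @return logical.
#' @export
markov_equivalent <- function(d1, d2) {
  if (!identical(d1$system$names, d2$system$names))
    stop("DAGs are over different systems")
  identical(skeleton(d1), skeleton(d2)) &&
    identical(v_structures(d1), v_structures(d2))
}

#' d-separation
#'
#' Tests whether `x` and `y` are d-separated given the set `given`, via the
#' moral ancestral graph: restrict to the ancestors of \{x, y\} and the
#' conditioning set, marry co-parents, drop orientation, delete the
#' conditioning set, and test connectivity.  This is equivalent to the
#' active-trail criterion (colliders open only when the collider or one of its
#' descendants is conditioned on).
#'
#' @param dag a `bn_dag`.
#' @param x,y distinct variable names, neither in `given`.
#' @param given conditioning set (possibly empty).
#' @return logical: TRUE when separated (independence holds).
#' @examples
#' s <- ra_system(c("A","B","C"))
#' d_separated(parse_dag("A>B;C>B", s), "A", "C")           # TRUE
#' d_separated(parse_dag("A>B;C>B", s), "A", "C", "B")      # FALSE
#' @export
d_separated <- function(dag, x, y, given = character()) {
  nm <- dag$system$names
  sys_check_vars(dag$system, c(x, y, given))
  if (x == y || x %in% given || y %in% given)
    stop("x, y and the conditioning set must be distinct")
  adj <- adj_matrix(dag)
  anc <- ancestral_set(adj, c(x, y, given))
  sub <- adj[anc, anc, drop = FALSE]
  und <- sub | t(sub)
  ## marry parents sharing a child within the ancestral set
  for (v in seq_len(nrow(sub))) {
    pa <- which(sub[, v])
    if (length(pa) >= 2L) und[pa, pa] <- TRUE
  }
  diag(und) <- FALSE
  keep <- setdiff(rownames(und), given)
  und <- und[keep, keep, drop = FALSE]
  !und_connected(und, x, y)
}

ancestral_set <- function(adj, vars) {
  nm <- rownames(adj)
  inset <- nm %in% vars
  repeat {
    pa_of_inset <- rowSums(adj[, inset, drop = FALSE]) > 0
    grown <- inset | pa_of_inset
    if (identical(grown, inset)) break
    inset <- grown
  }
  nm[inset]
}

und_connected <- function(und, x, y) {
  nm <- rownames(und)
  seen <- nm == x
  frontier <- seen
  while (any(frontier)) {
    nxt <- (colSums(und[frontier, , drop = FALSE]) > 0) & !seen
    seen <- seen | nxt
    frontier <- nxt
  }
  seen[match(y, nm)]
}

## full elementary independence set of a DAG: sorted keys of all true
## (x ⊥ y | S) statements
bn_elementary <- function(dag) {
  keys <- character()
  for (e in elementary_grid(dag$system))
    if (d_separated(dag, e$x, e$y, e$given)) keys <- c(keys, e$key)
  sort(keys)
}

## ---- minimal display list ------------------------------------------------

## Vertex order: repeatedly take, among vertices whose parents are all
## placed, the one latest in system order.  Statements are the ordered local
## Markov basis (x ⊥ predecessors \ parents | parents), empty ones dropped.
## A contraction merge then pools (L1 ⊥ R | S) with (L2 ⊥ R | S ∪ L1) into
## (L1 ∪ L2 ⊥ R | S), which produces compound-left statements such as
## (A, D ⊥ B, C) for two disconnected dyads.
bn_display_list <- function(dag) {
  nm <- dag$system$names
  placed <- character()
  stmts <- list()
  while (length(placed) < length(nm)) {
    avail <- setdiff(nm, placed)
    ok <- avail[vapply(avail, function(v)
      all(parents_of(dag, v) %in% placed), TRUE)]
    v <- ok[which.max(match(ok, nm))]
    pa <- sort(parents_of(dag, v))
    r <- setdiff(placed, pa)
    if (length(r))
      stmts[[length(stmts) + 1L]] <- ind_statement(v, r, pa)
    placed <- c(placed, v)
  }
  merge_contraction(stmts)
}

merge_contraction <- function(stmts) {
  ## a statement is an unordered pair of sides; try every orientation of a
  ## and b for the contraction pattern (X ⊥ R | S), (Y ⊥ R | S ∪ X) =>
  ## (X, Y ⊥ R | S)
  repeat {
    merged <- FALSE
    for (i in seq_along(stmts)) {
      for (j in seq_along(stmts)) {
        if (i == j) next
        a <- stmts[[i]]; b <- stmts[[j]]
        for (asides in list(list(a$left, a$right), list(a$right, a$left))) {
          for (bsides in list(list(b$left, b$right), list(b$right, b$left))) {
            X <- asides[[1L]]; R <- asides[[2L]]
            Y <- bsides[[1L]]; Rb <- bsides[[2L]]
            if (setequal(R, Rb) && setequal(b$given, c(a$given, X))) {
              stmts[[i]] <- ind_statement(c(X, Y), R, a$given)
              stmts[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) return(stmts)
  }
}

#' Independencies of a DAG
#'
#' Applies d-separation to every elementary statement (x \eqn{\perp} y | S) of
#' the system; the full set of true statements characterizes the DAG up to
#' Markov equivalence.  A compound statement (x \eqn{\perp} Y | S) with a
#' set-valued right side holds iff each elementary component holds
#' (composition is valid for graph separation).  Also returns a compact
#' display list (an ordered local-Markov basis) of the kind printed in
#' summaries of these models.
#'
#' @param dag a `bn_dag`.
#' @return An object of class `ind_set`: list with `elementary` (sorted keys
#'   `"X_Y|S"`) and `display` (list of [ind_statement()]).
#' @export
independencies <- function(dag) {
  structure(list(elementary = bn_elementary(dag),
                 display = bn_display_list(dag)),
            class = "ind_set")
}

#' @export
print.ind_set <- function(x, ...) {
  if (!length(x$display)) cat("none\n")
  else cat(paste(vapply(x$display, format, ""), collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.ind_set <- function(x, ...) {
  if (!length(x$display)) "none"
  else paste(vapply(x$display, format, ""), collapse = ", ")
}

## ---- equivalence classes ---------------------------------------------------

#' Markov equivalence ("specific") classes of all DAGs of a system
#'
#' Enumerates every labeled DAG and partitions by (skeleton, V-structures).
#' Each class records a deterministic representative (the member with the
#' lexicographically smallest edge list), all member DAGs, the full elementary
#' independence set, the display list, and the extended notation.  For four
#' variables there are 185 classes over 543 DAGs.
#'
#' @param system an [ra_system()].
#' @param max_n refusal bound passed to [enumerate_dags()].
#' @return list of objects of class `bn_class`.
#' @export
specific_classes <- function(system, max_n = 6L) {
  dags <- enumerate_dags(system, max_n = max_n)
  keys <- vapply(dags, function(d)
    paste(paste(skeleton(d), collapse = ";"),
          paste(v_structures(d), collapse = ";"), sep = "|"), "")
  groups <- split(seq_along(dags), keys)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    members <- dags[groups[[g]]]
    etxt <- vapply(members, dag_text, "")
    rep_dag <- members[[order(etxt)[1L]]]
    ind <- independencies(rep_dag)
    out[[g]] <- structure(list(
      system = system,
      rep = rep_dag,
      members = members[order(etxt)],
      n_members = length(members),
      skeleton = skeleton(rep_dag),
      v_structures = v_structures(rep_dag),
      elementary = ind$elementary,
      display = ind$display,
      notation = bn_notation(rep_dag)
    ), class = "bn_class")
  }
  out[order(vapply(out, function(cl) dag_text(cl$rep), ""))]
}

#' @export
print.bn_class <- function(x, ...) {
  cat("BN specific class:", canonical_text(x$notation),
      sprintf("[%d DAG%s, rep %s]\n", x$n_members,
              if (x$n_members > 1L) "s" else "", dag_text(x$rep)))
  invisible(x)
}

## canonical unlabeled signature of an elementary independence set:
## lexicographically smallest relabeling of the key set.  Assumes
## single-character variable names (always true for enumerated lattices).
unlabeled_signature <- function(elementary, names)
  unlabeled_signature_fix(elementary, names)

#' General (unlabeled) classes from specific classes
#'
#' Groups equivalence classes whose independence sets coincide under some
#' relabeling of the variables.  Works for both BN specific classes and RA
#' structures (any list of objects carrying an `elementary` field plus a
#' grouping signature).  For BNs at n = 4 the 185 specific classes collapse to
#' 20 general classes.
#'
#' @param specific list of `bn_class` objects (from [specific_classes()]).
#' @param fix variable names that relabelings must fix (directed systems).
#' @return list of `graph_class` objects: `members` (indices into `specific`),
#'   `rep` (first member), `size` (number of specific classes).
#' @export
general_classes <- function(specific, fix = character()) {
  stopifnot(length(specific) > 0L)
  nm <- specific[[1L]]$system$names
  sigs <- vapply(specific, function(cl)
    unlabeled_signature_fix(cl$elementary, nm, fix), "")
  groups <- split(seq_along(specific), sigs)
  groups <- groups[order(vapply(groups, min, 0L))]
  lapply(groups, function(idx) {
    structure(list(members = idx, rep = specific[[idx[1L]]],
                   size = length(idx)),
              class = "graph_class")
  })
}

unlabeled_signature_fix <- function(elementary, names, fix = character()) {
  best <- NULL
  for (perm in var_permutations(names, names, fix)) {
    relab <- vapply(elementary, function(k) {
      m <- regmatches(k, regexec("^(.+)_(.+)\\|(.*)$", k))[[1]]
      g <- if (nzchar(m[4])) sort(unname(perm[strsplit(m[4], "")[[1]]])) else character()
      elem_key(perm[[m[2]]], perm[[m[3]]], g)
    }, "", USE.NAMES = FALSE)
    sig <- paste(sort(relab), collapse = ",")
    if (is.null(best) || sig < best) best <- sig
  }
  if (is.null(best)) "" else best
}

#' @export
print.graph_class <- function(x, ...) {
  cat("General class with", x$size, "specific member(s); rep:",
      if (inherits(x$rep, "bn_class")) canonical_text(x$rep$notation)
      else canonical_text(x$rep), "\n")
  invisible(x)
}

#' CPDAG (essential graph) of a Markov equivalence class
#'
#' An edge is directed in the CPDAG iff every member of the class orients it
#' the same way; otherwise it is undirected.  V-structure edges are always
#' directed.
#'
#' @param class a `bn_class` (from [specific_classes()]).
#' @return list with `directed` (two-column matrix) and `undirected`
#'   (character vector of `"X-Y"` pairs), class `bn_pdag`.
#' @export
cpdag <- function(class) {
  stopifnot(inherits(class, "bn_class"))
  edir <- list()
  for (m in class$members) {
    if (!nrow(m$edges)) next
    for (k in seq_len(nrow(m$edges))) {
      pair <- paste0(pmin(m$edges[k, 1L], m$edges[k, 2L]), "-",
                     pmax(m$edges[k, 1L], m$edges[k, 2L]))
      edir[[pair]] <- union(edir[[pair]],
                            paste0(m$edges[k, 1L], ">", m$edges[k, 2L]))
    }
  }
  directed <- matrix(character(), 0L, 2L)
  undirected <- character()
  for (pair in names(edir)) {
    if (length(edir[[pair]]) == 1L) {
      pc <- strsplit(edir[[pair]], ">", fixed = TRUE)[[1]]
      directed <- rbind(directed, pc)
    } else undirected <- c(undirected, pair)
  }
  structure(list(system = class$system, directed = directed,
                 undirected = sort(undirected)),
            class = "bn_pdag")
}

#' @export
print.bn_pdag <- function(x, ...) {
  d <- if (nrow(x$directed))
    paste(paste0(x$directed[, 1L], ">", x$directed[, 2L]), collapse = ";")
    else ""
  cat("PDAG directed: {", d, "} undirected: {",
      paste(x$undirected, collapse = ";"), "}\n")
  invisible(x)
}

#' Factorization of a DAG
#'
#' One term p(node | parents) per node; terms multiply to the joint
#' distribution of any BN with this topology.
#'
#' @param dag a `bn_dag`.
#' @return list of terms (each `list(child, parents)`) with attribute
#'   `"text"`, e.g. `"p(A|CD)p(B|CD)p(C)p(D|C)"`.
#' @export
factorization <- function(dag) {
  nm <- dag$system$names
  terms <- lapply(nm, function(v)
    list(child = v, parents = sort(parents_of(dag, v))))
  txt <- paste(vapply(terms, function(t) {
    if (length(t$parents))
      paste0("p(", t$child, "|", paste(t$parents, collapse = ""), ")")
    else paste0("p(", t$child, ")")
  }, ""), collapse = "")
  attr(terms, "text") <- txt
  terms
}

#' Moral graph of a DAG
#'
#' The skeleton plus an edge between every pair of parents sharing a child
#' ("marrying" the parents).  Its maximal cliques are the relations of the
#' DAG's extended-notation representation.
#'
#' @param dag a `bn_dag`.
#' @return character vector of undirected `"X-Y"` pairs.
#' @export
moral_graph <- function(dag) {
  edges <- skeleton(dag)
  for (v in dag$system$names) {
    pa <- sort(parents_of(dag, v))
    if (length(pa) >= 2L) {
      cmb <- utils::combn(pa, 2L)
      edges <- c(edges, paste0(cmb[1L, ], "-", cmb[2L, ]))
    }
  }
  sort(unique(edges))
}

## maximal cliques of an undirected graph given as "X-Y" pair strings;
## isolated vertices come back as singleton cliques.  Brute force over
## subsets; fine for the small n of these lattices.
max_cliques <- function(names, pairs) {
  adj <- matrix(FALSE, length(names), length(names),
                dimnames = list(names, names))
  for (p in pairs) {
    xy <- strsplit(p, "-", fixed = TRUE)[[1]]
    adj[xy[1L], xy[2L]] <- adj[xy[2L], xy[1L]] <- TRUE
  }
  subsets <- subset_list(names)
  cl <- Filter(function(s) {
    length(s) >= 1L &&
      all(adj[s, s, drop = FALSE] | diag(length(s)) > 0)
  }, subsets)
  maximal_relations(cl)
}

#' Extended notation of a DAG
#'
#' The relations are the maximal cliques of the moral graph (isolated
#' variables become singleton relations), joined by colons.  Every display
#' independence statement whose variables all lie inside a clique is attached
#' to that clique (to every containing clique) as a subscript block; statements
#' spanning cliques are already carried by the colon structure.  DAGs without
#' V-structures get plain RA notation.
#'
#' @param dag a `bn_dag`.
#' @return An `ra_structure` (with subscripts when V-structures are present).
#' @examples
#' s <- abcd_system()
#' canonical_text(bn_notation(parse_dag("B>D;C>D;A", s)))  # "BCD_B:C_:A"
#' @export
bn_notation <- function(dag) {
  sys <- dag$system
  sk <- skeleton(dag)
  cliques <- max_cliques(sys$names, moral_graph(dag))
  ## independence pairs inside each clique: members non-adjacent in the
  ## skeleton (i.e. adjacent in the moral graph only by marriage), with their
  ## minimal d-separating set (smallest, then lexicographically first)
  blocks <- lapply(cliques, function(K) {
    if (length(K) < 2L) return(list())
    prs <- utils::combn(K, 2L, simplify = FALSE)
    prs <- Filter(function(p)
      !(paste0(p[1L], "-", p[2L]) %in% sk), prs)
    if (!length(prs)) return(list())
    seps <- lapply(prs, function(p) min_separator(dag, p[1L], p[2L]))
    ## only statements wholly inside the clique can be subscripted
    keep <- vapply(seps, function(s) !is.null(s) && all(s %in% K), TRUE)
    prs <- prs[keep]; seps <- seps[keep]
    if (!length(prs)) return(list())
    bysep <- split(seq_along(prs),
                   vapply(seps, function(s) paste(s, collapse = ""), ""))
    lapply(unname(bysep), function(idx) {
      S <- seps[[idx[1L]]]
      U <- sort(unique(unlist(prs[idx])))
      ## connect members of U not separated as a pair (with this S); the
      ## components are the subscript groups (each printed with S attached)
      comp <- stats::setNames(seq_along(U), U)
      sep_pair <- function(u, v) any(vapply(prs[idx], function(p)
        setequal(p, c(u, v)), TRUE))
      repeat {
        changed <- FALSE
        for (u in U) for (v in U) {
          if (u != v && comp[u] != comp[v] && !sep_pair(u, v)) {
            comp[comp == comp[v]] <- comp[u]
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      lapply(unname(split(U, comp)), function(g) sort(unique(c(g, S))))
    })
  })
  ra_structure(sys, cliques, blocks)
}

## minimal d-separating set for a non-adjacent pair: smallest subset of the
## remaining variables (ties broken lexicographically); NULL when none exists
min_separator <- function(dag, u, v) {
  rest <- setdiff(dag$system$names, c(u, v))
  cand <- subset_list(rest)
  keys <- vapply(cand, function(s) paste(sort(s), collapse = ""), "")
  cand <- cand[order(lengths(cand), keys)]
  for (s in cand) if (d_separated(dag, u, v, s)) return(sort(s))
  NULL
}

#' DOT export of a DAG or PDAG
#'
#' @param x a `bn_dag` or `bn_pdag`.
#' @param name graph name.
#' @return character scalar with DOT source.
#' @export
to_dot <- function(x, name = "g") {
  if (inherits(x, "bn_dag")) {
    body <- c(paste0("  ", x$system$names, ";"),
              if (nrow(x$edges))
                paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L], ";"))
    paste(c(paste0("digraph ", name, " {"), body, "}"), collapse = "\n")
  } else if (inherits(x, "bn_pdag")) {
    und <- vapply(strsplit(x$undirected, "-", fixed = TRUE),
                  function(p) paste0("  ", p[1L], " -> ", p[2L],
                                     " [dir=none];"), "")
    body <- c(paste0("  ", x$system$names, ";"),
              if (nrow(x$directed))
                paste0("  ", x$directed[, 1L], " -> ", x$directed[, 2L], ";"),
              und)
    paste(c(paste0("digraph ", name, " {"), body, "}"), collapse = "\n")
  } else stop("unsupported object")
}
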