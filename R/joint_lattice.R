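## The joint RA-BN neutral-system lattice, organized by Rho graphs
## (unlabeled variable-adjacency graphs).

## canonical form of an undirected graph given as "X-Y" pairs over `names`:
## lexicographically smallest edge list over all vertex relabelings
rho_key <- function(names, pairs) {
  n <- length(names)
  best <- NULL
  for (perm in var_permutations(names, names)) {
    relab <- vapply(pairs, function(p) {
      xy <- unname(perm[strsplit(p, "-", fixed = TRUE)[[1]]])
      paste0(min(xy), "-", max(xy))
    }, "")
    key <- paste(sort(relab), collapse = ";")
    if (is.null(best) || key < best) best <- key
  }
  if (is.null(best)) "" else best
}

#' Rho graph of a model
#'
#' The unlabeled undirected variable-adjacency graph: for an RA structure,
#' variables are adjacent when they share a relation (co-occurrence graph);
#' for a DAG or BN class, the skeleton.  Every RA or BN graph corresponds to
#' exactly one Rho graph, which is what lets the two lattices be merged.
#'
#' @param model an `ra_structure`, `bn_dag` or `bn_class`.
#' @return An object of class `rho_graph` (canonical edge key + edge count).
#' @export
rho_of <- function(model) {
  if (inherits(model, "bn_class")) model <- model$rep
  if (inherits(model, "ra_structure")) {
    adj <- cooccurrence_adj(model)
    nm <- rownames(adj)
    pairs <- character()
    for (i in seq_len(nrow(adj) - 1L)) for (j in (i + 1L):nrow(adj))
      if (adj[i, j]) pairs <- c(pairs, paste0(nm[i], "-", nm[j]))
    names <- nm
  } else if (inherits(model, "bn_dag")) {
    pairs <- skeleton(model)
    names <- model$system$names
  } else stop("unsupported model kind")
  structure(list(n = length(names), key = rho_key(names, pairs),
                 n_edges = length(pairs)),
            class = "rho_graph")
}

#' @export
print.rho_graph <- function(x, ...) {
  cat(sprintf("Rho graph on %d nodes, %d edges: {%s}\n",
              x$n, x$n_edges, x$key))
  invisible(x)
}

#' The Rho lattice
#'
#' All undirected graphs on n unlabeled nodes, ordered from the complete graph
#' down to the edgeless graph, with hierarchy links for single-edge deletion.
#' Eleven graphs for n = 4.
#'
#' @param system an [ra_system()].
#' @return list of `rho_graph` objects with a `children` attribute (list of
#'   index vectors).
#' @export
rho_lattice <- function(system) {
  nm <- system$names
  n <- length(nm)
  allpairs <- if (n >= 2L) {
    cmb <- utils::combn(nm, 2L)
    paste0(cmb[1L, ], "-", cmb[2L, ])
  } else character()
  np <- length(allpairs)
  seen <- character(); graphs <- list(); edgesets <- list()
  for (m in seq_len(2^np) - 1L) {
    pairs <- allpairs[bitwAnd(m, bitwShiftL(1L, seq_len(np) - 1L)) > 0L]
    key <- rho_key(nm, pairs)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      graphs[[length(graphs) + 1L]] <-
        structure(list(n = n, key = key, n_edges = length(pairs)),
                  class = "rho_graph")
      edgesets[[length(edgesets) + 1L]] <- pairs
    }
  }
  ord <- order(-vapply(graphs, function(g) g$n_edges, 0L),
               vapply(graphs, function(g) g$key, ""))
  graphs <- graphs[ord]; edgesets <- edgesets[ord]
  keys <- vapply(graphs, function(g) g$key, "")
  children <- lapply(seq_along(graphs), function(i) {
    kids <- integer()
    for (k in seq_along(edgesets[[i]])) {
      childkey <- rho_key(nm, edgesets[[i]][-k])
      kids <- c(kids, match(childkey, keys))
    }
    sort(unique(kids))
  })
  attr(graphs, "children") <- children
  graphs
}

#' RA-BN equivalence
#'
#' An RA structure and a BN class are equivalent when they define the same
#' family of distributions: the RA structure is loopless, the BN class has no
#' V-structures, and their independence sets coincide (under some relabeling
#' for general graphs, under the identity labeling for specific graphs).
#' Loopy RA structures are never equivalent to a BN (their maximum-entropy
#' families are not factorizable on a DAG) and V-structured BN classes are
#' never equivalent to an RA structure.
#'
#' @param ra_model an `ra_structure`.
#' @param bn_class a `bn_class` (from [specific_classes()]).
#' @param general logical: compare up to variable relabeling (general graphs)
#'   or under the identity labeling (specific graphs, default).
#' @return logical.
#' @export
equivalent_ra_bn <- function(ra_model, bn_class, general = FALSE) {
  stopifnot(inherits(ra_model, "ra_structure"), inherits(bn_class, "bn_class"))
  if (has_loop(ra_model)) return(FALSE)
  if (length(bn_class$v_structures)) return(FALSE)
  ra_el <- ra_elementary(ra_model)
  if (!general)
    return(identical(ra_el, bn_class$elementary))
  nm <- ra_model$system$names
  identical(unlabeled_signature(ra_el, nm),
            unlabeled_signature(bn_class$elementary, nm))
}

#' Build the joint RA-BN neutral-system lattice
#'
#' Generates the RA lattice and the BN specific classes, buckets both by Rho
#' graph, and pairs equivalent RA/BN entries (identical labeled independence
#' sets, RA loopless, BN V-structure-free).  Reports, per Rho graph and in
#' total, the RA-only structures (those with loops), the BN-only classes
#' (those with V-structures) and the equivalent pairs, at both the specific
#' and the general level.  For four variables: 53 RA-only + 124 BN-only + 61
#' equivalent = 238 specific graphs; 10 + 10 + 10 = 30 general graphs.
#'
#' @param system an [ra_system()].
#' @return An object of class `joint_lattice`.
#' @export
build_joint <- function(system) {
  ra <- ra_lattice(system)
  bn <- specific_classes(system)
  nm <- system$names

  ra_el <- vapply(ra$elementary, function(e) paste(e, collapse = ","), "")
  bn_el <- vapply(bn, function(cl) paste(cl$elementary, collapse = ","), "")
  bn_vfree <- vapply(bn, function(cl) length(cl$v_structures) == 0L, TRUE)

  ## specific-level pairing: loopless RA <-> V-free BN with equal labeled sets
  pair_bn <- rep(NA_integer_, length(ra$structures))
  for (i in seq_along(ra$structures)) {
    if (!ra$loopless[i]) next
    j <- which(bn_vfree & bn_el == ra_el[i])
    if (length(j) == 1L) pair_bn[i] <- j
    else if (length(j) > 1L)
      stop("independence set matched several V-free BN classes")  # cannot happen
  }
  paired_bn <- pair_bn[!is.na(pair_bn)]

  rho_ra <- vapply(ra$structures, function(s) rho_of(s)$key, "")
  rho_bn <- vapply(bn, function(cl) rho_of(cl)$key, "")
  rhos <- rho_lattice(system)
  rho_keys <- vapply(rhos, function(g) g$key, "")

  entries <- lapply(seq_along(rhos), function(r) {
    ra_idx <- which(rho_ra == rho_keys[r])
    bn_idx <- which(rho_bn == rho_keys[r])
    list(rho = rhos[[r]],
         equivalent = cbind(ra = ra_idx[!is.na(pair_bn[ra_idx])],
                            bn = pair_bn[ra_idx[!is.na(pair_bn[ra_idx])]]),
         ra_only = ra_idx[is.na(pair_bn[ra_idx])],
         bn_only = setdiff(bn_idx, paired_bn))
  })

  ## general level: group RA and BN general classes, pair by unlabeled
  ## signature restricted to loopless / V-free
  ra_gen_sig <- vapply(ra$general, function(idx)
    unlabeled_signature(ra$elementary[[idx[1L]]], nm), "")
  ra_gen_loopless <- vapply(ra$general, function(idx)
    ra$loopless[idx[1L]], TRUE)
  bn_gen <- general_classes(bn)
  bn_gen_sig <- vapply(bn_gen, function(g)
    unlabeled_signature(g$rep$elementary, nm), "")
  bn_gen_vfree <- vapply(bn_gen, function(g)
    length(g$rep$v_structures) == 0L, TRUE)
  gen_pairs <- sum(ra_gen_loopless & ra_gen_sig %in% bn_gen_sig[bn_gen_vfree])

  counts <- list(
    ra_specific = length(ra$structures),
    bn_specific = length(bn),
    equivalent_specific = length(paired_bn),
    total_specific = length(ra$structures) + length(bn) - length(paired_bn),
    ra_general = length(ra$general),
    bn_general = length(bn_gen),
    equivalent_general = gen_pairs,
    total_general = length(ra$general) + length(bn_gen) - gen_pairs)

  structure(list(system = system, ra = ra, bn = bn, bn_general = bn_gen,
                 entries = entries, counts = counts),
            class = "joint_lattice")
}

#' @export
print.joint_lattice <- function(x, ...) {
  c <- x$counts
  cat(sprintf("Joint RA-BN lattice (%d variables):\n",
              length(x$system$names)))
  cat(sprintf("  general:  %d RA + %d BN - %d equivalent = %d\n",
              c$ra_general, c$bn_general, c$equivalent_general,
              c$total_general))
  cat(sprintf("  specific: %d RA + %d BN - %d equivalent = %d\n",
              c$ra_specific, c$bn_specific, c$equivalent_specific,
              c$total_specific))
  invisible(x)
}

#' JSON export of the joint lattice keyed by Rho graph
#'
#' @param joint a `joint_lattice`.
#' @param path optional output file.
#' @return JSON string.
#' @export
joint_json <- function(joint, path = NULL) {
  entries <- lapply(joint$entries, function(e) {
    list(rho = e$rho$key, rho_edges = e$rho$n_edges,
         equivalent = lapply(seq_len(nrow(e$equivalent)), function(r)
           list(ra = joint$ra$keys[e$equivalent[r, "ra"]],
                bn = canonical_text(joint$bn[[e$equivalent[r, "bn"]]]$notation))),
         ra_only = joint$ra$keys[e$ra_only],
         bn_only = vapply(joint$bn[e$bn_only], function(cl)
           canonical_text(cl$notation), ""))
  })
  obj <- list(schema = "rabn-joint-1", counts = joint$counts,
              entries = entries)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
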