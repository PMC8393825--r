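## BN directed-system lattice: DV eligibility, prediction equivalence,
## least-df representatives, and RA equivalents.

#' Eligible dependent variables of a DAG
#'
#' By convention any node may be the DV except a parent node within a
#' V-structure (conditioning the prediction on such a node would exploit
#' independencies unique to BN that have no RA counterpart; those models are
#' deferred, see [dv_parent_demo()]).
#'
#' @param dag a `bn_dag`.
#' @return character vector of eligible node names.
#' @examples
#' s <- abcd_system()
#' eligible_dvs(parse_dag("B>D;C>D;A", s))  # A and D
#' @export
eligible_dvs <- function(dag) {
  ## a V-structure is a convergence of edges on a node with at least one
  ## non-adjacent parent pair; every edge into such a node is part of the
  ## convergence, so every parent of a collision node is excluded
  vchild <- unique(vapply(v_structures(dag), function(v)
    strsplit(v, "[><]")[[1]][2L], ""))
  vp <- unique(unlist(lapply(vchild, function(c) parents_of(dag, c))))
  setdiff(dag$system$names, vp)
}

## deterministic audit tables for prediction-signature comparison: strictly
## positive Dirichlet(1) tables from a fixed internal seed stream
audit_tables <- function(system, k = 2L, seed = 986L) {
  lapply(seq_len(k), function(i) {
    d <- random_distribution(system, seed = seed + i)
    contingency_table(system, d$probs * 1e4)
  })
}

## numeric prediction signature: fitted p(dv | IVs) on each audit table.
## Rounded to 6 digits before comparison: equal predictions agree to float
## noise (~1e-15) while distinct rational predictions on generic Dirichlet
## tables differ by far more than 1e-6.
prediction_signature <- function(model, dv, tables, digits = 6L) {
  vals <- unlist(lapply(tables, function(tb) {
    fit <- if (inherits(model, "bn_dag")) fit_bn(model, tb)
           else fit_maxent(model, tb)
    as.vector(predict_dv(fit, dv))
  }))
  paste(formatC(round(vals, digits), format = "f", digits = digits),
        collapse = ",")
}

#' Prediction equivalence of two models
#'
#' Two models over the same system with the same DV predict equivalently when
#' the conditional of the DV given all IVs, computed from each model's fitted
#' distribution, is the same function of the data.  Decided numerically on
#' generic strictly positive audit tables (tolerance 1e-8): equality there is
#' equality everywhere for these rational functions, up to events of measure
#' zero.
#'
#' @param m1,m2 `bn_dag`, `bn_class` or `ra_structure` models.
#' @param dv the dependent variable name.
#' @param tables optional list of `contingency_table`s to audit on (default:
#'   two seeded Dirichlet tables).
#' @return logical.
#' @export
predictively_equivalent <- function(m1, m2, dv, tables = NULL) {
  if (inherits(m1, "bn_class")) m1 <- m1$rep
  if (inherits(m2, "bn_class")) m2 <- m2$rep
  stopifnot(identical(m1$system$names, m2$system$names))
  sys_check_vars(m1$system, dv)
  if (is.null(tables)) tables <- audit_tables(m1$system)
  identical(prediction_signature(m1, dv, tables),
            prediction_signature(m2, dv, tables))
}

#' The BN directed-system lattice
#'
#' Restricts the BN specific classes to those where the DV is eligible (not a
#' V-structure parent), partitions them by prediction equivalence, and
#' retains from each partition the class with the fewest degrees of freedom
#' (ties broken by canonical edge list).  For four variables this compresses
#' 185 specific classes to 18 retained ones, in 8 general classes.
#'
#' @param system an [ra_system()].
#' @param dv the dependent variable (default: last variable).
#' @param specific optional precomputed [specific_classes()] result.
#' @return list with `retained` (list of `bn_class`), `groups` (list mapping
#'   each retained class to the indices of its predictively equivalent
#'   classes), `n_general` (number of general classes among the retained),
#'   `eligible` (indices of eligible classes), class `bn_directed_lattice`.
#' @export
bn_directed_lattice <- function(system, dv = system$names[length(system$names)],
                                specific = NULL) {
  if (is.null(specific)) specific <- specific_classes(system)
  eligible <- which(vapply(specific, function(cl)
    dv %in% eligible_dvs(cl$rep), TRUE))
  tables <- audit_tables(system)
  sigs <- vapply(specific[eligible], function(cl)
    prediction_signature(cl$rep, dv, tables), "")
  groups <- split(eligible, sigs)
  retained_idx <- vapply(groups, function(idx) {
    dfs <- vapply(specific[idx], function(cl) degrees_of_freedom(cl$rep), 0)
    cand <- idx[dfs == min(dfs)]
    cand[order(vapply(specific[cand], function(cl) dag_text(cl$rep), ""))][1L]
  }, 0L)
  ord <- order(retained_idx)
  retained_idx <- retained_idx[ord]
  groups <- groups[ord]
  retained <- specific[retained_idx]
  nm <- system$names
  gen_sigs <- vapply(retained, function(cl)
    unlabeled_signature(cl$elementary, nm), "")
  structure(list(system = system, dv = dv,
                 retained = retained, retained_idx = unname(retained_idx),
                 groups = unname(groups),
                 n_general = length(unique(gen_sigs)),
                 eligible = eligible, specific = specific),
            class = "bn_directed_lattice")
}

#' @export
print.bn_directed_lattice <- function(x, ...) {
  cat(sprintf("BN directed lattice (DV %s): %d retained specific classes in %d general classes\n",
              x$dv, length(x$retained), x$n_general))
  invisible(x)
}

#' RA equivalent of a retained BN prediction model
#'
#' Finds, in the augmented RA directed-system lattice, the structure whose
#' fitted (maximum-entropy) prediction of the DV matches the BN model's
#' closed-form prediction on generic data.  Every retained four-variable BN
#' class has such an equivalent.  When both a conventional structure and its
#' primed variant predict identically (the DV-margin predictors IVs:Z and
#' A:B:...:Z), the conventional member is returned.
#'
#' @param bn_model a `bn_class` or `bn_dag` retained in the directed lattice.
#' @param dv the dependent variable name.
#' @param augmented optional precomputed [augmented_directed_lattice()].
#' @param tables optional audit tables.
#' @return The matching `ra_structure`; error if no structure matches.
#' @export
ra_equivalent_of <- function(bn_model, dv, augmented = NULL, tables = NULL) {
  if (inherits(bn_model, "bn_class")) bn_model <- bn_model$rep
  system <- bn_model$system
  if (is.null(augmented))
    augmented <- augmented_directed_lattice(system, directed_spec(system, dv))
  if (is.null(tables)) tables <- audit_tables(system)
  target <- prediction_signature(bn_model, dv, tables)
  hits <- which(vapply(seq_along(augmented$structures), function(i)
    identical(prediction_signature(augmented$structures[[i]], dv, tables),
              target), TRUE))
  if (!length(hits))
    stop("no structure in the augmented directed lattice matches this prediction")
  if (length(hits) > 1L) {
    conv <- hits[!augmented$primed[hits]]
    hits <- if (length(conv)) conv else hits
  }
  augmented$structures[[hits[1L]]]
}

#' Demonstration: the DV as a V-structure parent
#'
#' Models in which the DV is a parent node within a V-structure are excluded
#' from the directed lattice, because their predictions are genuinely
#' different from any RA model.  This demo exhibits the discrepancy on a
#' three-variable system A, B, Z: the collider-at-Z model (A -> Z <- B) fits
#' p(Z|AB) directly, while the collider-at-B model (A -> B <- Z), in which Z
#' is a V-structure parent, yields a conditional q(Z|AB) built from
#' p(B|A,Z) p(A) p(Z) that differs on generic data.
#'
#' @param seed seed for the synthetic joint distribution.
#' @return list with the two conditional arrays `p_z_given_ab`,
#'   `q_z_given_ab` and their maximum absolute difference `max_diff`.
#' @export
dv_parent_demo <- function(seed = 1L) {
  sys <- ra_system(c("A", "B", "Z"))
  dist <- random_distribution(sys, seed = seed)
  tb <- contingency_table(sys, dist$probs * 1e4)
  collider_at_z <- parse_dag("A>Z;B>Z", sys)   # ABZ_A:B_, DV is the child
  collider_at_b <- parse_dag("A>B;Z>B", sys)   # ABZ_A:Z_, DV is a parent
  p <- predict_dv(fit_bn(collider_at_z, tb), "Z")
  q <- predict_dv(fit_bn(collider_at_b, tb), "Z")
  list(p_z_given_ab = p, q_z_given_ab = q,
       max_diff = max(abs(p - q), na.rm = TRUE))
}
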