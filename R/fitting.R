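## Fitting structures to contingency data: closed-form BN factorization,
## maximum-entropy IPF for RA structures, information measures, model
## comparison, and lattice search.

#' Construct a contingency table
#'
#' A dense table of non-negative counts over the full state space of a
#' system.  States of variable `V` with cardinality k are labeled
#' `v0 ... v(k-1)` unless dimnames are supplied.
#'
#' @param system an [ra_system()].
#' @param counts numeric array (or vector in row-major state order) of
#'   non-negative counts; dimensions must match the cardinalities.
#' @return An object of class `contingency_table` with fields `system`,
#'   `counts` (named array) and `n`.
#' @examples
#' s <- ra_system(c("A", "B"))
#' contingency_table(s, c(10, 5, 5, 10))
#' @export
contingency_table <- function(system, counts) {
  card <- unname(system$card)
  if (is.null(dim(counts))) {
    stopifnot(length(counts) == prod(card))
    counts <- array(as.numeric(counts), dim = card)
  }
  stopifnot(identical(unname(dim(counts)), as.integer(card)))
  if (any(counts < 0)) stop("negative count")
  dimnames(counts) <- state_labels(system)
  structure(list(system = system, counts = counts, n = sum(counts)),
            class = "contingency_table")
}

state_labels <- function(system) {
  lapply(seq_along(system$names), function(i)
    paste0(tolower(system$names[i]), seq_len(system$card[i]) - 1L))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table over", paste(x$system$names, collapse = ","),
      "- n =", x$n, "\n")
  invisible(x)
}

#' Construct a joint distribution
#'
#' @param system an [ra_system()].
#' @param probs numeric array or vector of probabilities (non-negative,
#'   summing to 1 within 1e-12; renormalized exactly).
#' @return An object of class `joint_distribution`.
#' @export
joint_distribution <- function(system, probs) {
  card <- unname(system$card)
  if (is.null(dim(probs))) {
    stopifnot(length(probs) == prod(card))
    probs <- array(as.numeric(probs), dim = card)
  }
  if (any(probs < 0)) stop("negative probability")
  s <- sum(probs)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1")
  probs <- probs / s
  dimnames(probs) <- state_labels(system)
  structure(list(system = system, probs = probs), class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat("Joint distribution over", paste(x$system$names, collapse = ","),
      "- H =", round(entropy_bits(x), 4), "bits\n")
  invisible(x)
}

## empirical distribution of a table (counts normalized)
empirical_distribution <- function(table) {
  if (table$n <= 0) stop("empty table")
  joint_distribution(table$system, table$counts / table$n)
}

## margin of an array over variables `vars` (by name)
array_margin <- function(arr, system, vars) {
  idx <- match(vars, system$names)
  apply(arr, idx, sum)
}

#' Closed-form BN fit
#'
#' The maximum-likelihood distribution with the DAG's factorization: the
#' product of empirical conditionals p(node | parents).  Parent states with
#' zero empirical mass get a uniform conditional (a determinism choice; the
#' cells carry no likelihood weight).
#'
#' @param dag a `bn_dag`.
#' @param table a `contingency_table` over the same system.
#' @return A `joint_distribution`.
#' @export
fit_bn <- function(dag, table) {
  stopifnot(identical(dag$system$names, table$system$names))
  if (table$n <= 0) stop("empty table")
  sys <- table$system
  p <- table$counts / table$n
  fit <- array(1, dim = dim(p))
  for (v in sys$names) {
    pa <- sort(parents_of(dag, v))
    fam <- array_margin(p, sys, sys_sort(sys, c(v, pa)))
    cond <- if (length(pa)) conditional_family(fam, sys, v, pa) else fam
    fit <- fit * spread_to_full(cond, sys, sys_sort(sys, c(v, pa)))
  }
  joint_distribution(sys, fit)
}

## conditional p(v | pa) from the family margin (array over sorted c(v, pa));
## zero-mass parent states become uniform over v
conditional_family <- function(fam, system, v, pa) {
  vars <- sys_sort(system, c(v, pa))
  vpos <- match(v, vars)
  papos <- setdiff(seq_along(vars), vpos)
  denom <- apply(fam, papos, sum)
  cond <- sweep(fam, papos, denom, "/")
  cond[!is.finite(cond)] <- 1 / dim(fam)[vpos]
  cond
}

## broadcast an array over `vars` (sorted in system order) to the full state
## space
spread_to_full <- function(arr, system, vars) {
  nm <- system$names
  card <- unname(system$card)
  pos <- match(vars, nm)
  perm_target <- c(pos, setdiff(seq_along(nm), pos))
  full <- array(rep(as.vector(arr), prod(card[setdiff(seq_along(nm), pos)])),
                dim = c(card[pos], card[setdiff(seq_along(nm), pos)]))
  aperm(full, order(perm_target))
}

#' Maximum-entropy fit of an RA structure (IPF)
#'
#' Iterative proportional fitting from a uniform start, cycling over the
#' structure's relations and rescaling to match each empirical relation
#' margin, until the largest absolute margin discrepancy falls below `tol`.
#' The fixed point is the maximum-entropy distribution with those margins.
#' Loopless structures converge in one sweep to the closed-form decomposable
#' product; loopy structures genuinely iterate.
#'
#' @param structure an `ra_structure` (subscripts ignored -- a plain RA
#'   model).
#' @param table a `contingency_table`.
#' @param tol convergence tolerance on margins (default 1e-9).
#' @param max_sweeps iteration cap (default 10000).
#' @return A `joint_distribution` with attributes `iterations` (sweeps used)
#'   and `residual` (final max margin discrepancy).
#' @export
fit_maxent <- function(structure, table, tol = 1e-9, max_sweeps = 10000L) {
  stopifnot(identical(structure$system$names, table$system$names))
  if (table$n <= 0) stop("empty table")
  sys <- table$system
  p <- table$counts / table$n
  q <- array(1 / length(p), dim = dim(p))
  targets <- lapply(structure$relations, function(r) array_margin(p, sys, r))
  it <- 0L; resid <- Inf
  repeat {
    it <- it + 1L
    for (k in seq_along(structure$relations)) {
      r <- structure$relations[[k]]
      cur <- array_margin(q, sys, r)
      ratio <- targets[[k]] / cur
      ratio[!is.finite(ratio)] <- 0   # zero target margin: cell mass -> 0
      q <- q * spread_to_full(ratio, sys, r)
    }
    resid <- max(vapply(seq_along(structure$relations), function(k)
      max(abs(array_margin(q, sys, structure$relations[[k]]) - targets[[k]])),
      0))
    if (resid < tol || it >= max_sweeps) break
  }
  if (resid >= tol)
    warning(sprintf("IPF did not converge in %d sweeps (residual %.3g)",
                    it, resid))
  out <- joint_distribution(sys, q)
  attr(out, "iterations") <- it
  attr(out, "residual") <- resid
  out
}

#' Closed-form fit of a loopless RA structure
#'
#' Decomposable product formula obtained from a Graham-reduction elimination
#' order: the product of clique margins divided by separator margins.  Used
#' as the independent cross-check of the IPF fixed point.
#'
#' @param structure a loopless `ra_structure`.
#' @param table a `contingency_table`.
#' @return A `joint_distribution`.
#' @export
fit_loopless <- function(structure, table) {
  if (has_loop(structure)) stop("structure has a loop; use fit_maxent")
  dag <- dag_of_loopless(structure)
  fit_bn(dag, table)
}

#' Shannon entropy in bits
#'
#' @param dist a `joint_distribution`.
#' @return entropy H in bits (log base 2).
#' @export
entropy_bits <- function(dist) {
  p <- as.vector(dist$probs)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information-theoretic transmission (KL divergence in bits)
#'
#' T(p : q) = sum p log2(p/q), the information lost when q models p; zero iff
#' the distributions agree on p's support, infinite when q is zero where p is
#' positive.
#'
#' @param p,q `joint_distribution`s over the same system.
#' @return transmission in bits (possibly `Inf`).
#' @export
transmission_bits <- function(p, q) {
  stopifnot(identical(p$system$names, q$system$names))
  pv <- as.vector(p$probs); qv <- as.vector(q$probs)
  pos <- pv > 0
  if (any(qv[pos] == 0)) return(Inf)
  sum(pv[pos] * log2(pv[pos] / qv[pos]))
}

#' Degrees of freedom of a model
#'
#' RA structure: one u-term per non-empty subset in the down-closure of the
#' relations, each contributing the product of (cardinality - 1) over its
#' variables.  DAG: per node, (cardinality - 1) times the product of parent
#' cardinalities.  The two formulas agree on every equivalent RA/BN pair,
#' which is what makes least-df comparisons across the methods meaningful.
#'
#' @param model an `ra_structure` or `bn_dag`.
#' @return integer degrees of freedom.
#' @examples
#' s <- abcd_system()
#' degrees_of_freedom(parse_structure("AD:BD:CD", s))  # 7
#' @export
degrees_of_freedom <- function(model) {
  sys <- model$system
  if (inherits(model, "ra_structure")) {
    subsets <- unique(unlist(lapply(model$relations, function(r)
      lapply(Filter(length, subset_list(r)), function(s)
        paste(sort(s), collapse = "\r"))), use.names = FALSE))
    sum(vapply(strsplit(subsets, "\r", fixed = TRUE), function(s)
      prod(sys$card[s] - 1L), 0))
  } else if (inherits(model, "bn_dag")) {
    sum(vapply(sys$names, function(v) {
      pa <- parents_of(model, v)
      (sys$card[[v]] - 1L) * prod(sys$card[pa])
    }, 0))
  } else stop("unsupported model kind")
}

#' Likelihood-ratio (chi-square) test between nested fits
#'
#' The statistic is 2 n sum p ln(p/q) between the two fitted distributions
#' (the candidate q nested in the reference p), referred to a chi-square with
#' the df difference.  Callers assert nestedness; `ddf` must be positive.
#'
#' @param model_fit,reference_fit `joint_distribution`s fitted to `table`.
#' @param table the data (`contingency_table`).
#' @param model_df,reference_df degrees of freedom of the two models.
#' @return list with `statistic`, `ddf`, `p_value`.
#' @export
lr_test <- function(model_fit, reference_fit, table, model_df, reference_df) {
  ddf <- abs(reference_df - model_df)
  if (ddf == 0L) stop("models have equal degrees of freedom (ddf = 0)")
  tbits <- transmission_bits(reference_fit, model_fit)
  stat <- 2 * table$n * log(2) * tbits
  list(statistic = stat, ddf = ddf,
       p_value = stats::pchisq(stat, df = ddf, lower.tail = FALSE))
}

#' Information criteria of a fit
#'
#' AIC = -2 loglik + 2 df; BIC = -2 loglik + df ln(n), with the log-likelihood
#' of the observed table under the fitted distribution.
#'
#' @param fit a `joint_distribution`.
#' @param table the data.
#' @param df degrees of freedom of the fitted model.
#' @return list with `loglik`, `aic`, `bic`.
#' @export
information_criteria <- function(fit, table, df) {
  cnt <- as.vector(table$counts)
  pr <- as.vector(fit$probs)
  pos <- cnt > 0
  ll <- if (any(pr[pos] == 0)) -Inf else sum(cnt[pos] * log(pr[pos]))
  list(loglik = ll, aic = -2 * ll + 2 * df, bic = -2 * ll + df * log(table$n))
}

#' Conditional prediction of a DV
#'
#' p(dv | all other variables), the renormalized slice of the joint per IV
#' state; IV states with zero mass are returned as NA (undefined).
#'
#' @param dist a `joint_distribution`.
#' @param dv variable name.
#' @return array of the same shape as the joint holding p(dv | rest).
#' @export
predict_dv <- function(dist, dv) {
  sys <- dist$system
  sys_check_vars(sys, dv)
  ivpos <- which(sys$names != dv)
  denom <- apply(dist$probs, ivpos, sum)
  out <- sweep(dist$probs, ivpos, denom, "/")
  out[!is.finite(out)] <- NA_real_
  out
}

#' Fit a model to data
#'
#' Dispatcher producing a full fit report: a `bn_dag` is fitted in closed
#' form, an `ra_structure` by IPF (closed form when loopless gives the same
#' answer).  Reports entropy, transmission against the data, the
#' likelihood-ratio statistic against the reference (default: the data
#' itself, i.e. the saturated model), df, AIC and BIC.
#'
#' @param model an `ra_structure` or `bn_dag`.
#' @param table a `contingency_table`.
#' @param reference optional reference `joint_distribution` (default: the
#'   empirical distribution) with `reference_df` its df (default: saturated).
#' @param reference_df df of the reference model.
#' @return An object of class `fit_result`.
#' @export
fit_model <- function(model, table, reference = NULL, reference_df = NULL) {
  data_dist <- empirical_distribution(table)
  sat_df <- prod(table$system$card) - 1L
  if (is.null(reference)) {
    reference <- data_dist
    reference_df <- sat_df
  }
  if (inherits(model, "bn_dag")) {
    fitted <- fit_bn(model, table)
    iters <- 0L
  } else {
    fitted <- fit_maxent(model, table)
    iters <- attr(fitted, "iterations")
  }
  df <- degrees_of_freedom(model)
  tbits <- transmission_bits(data_dist, fitted)
  ic <- information_criteria(fitted, table, df)
  ddf <- abs(reference_df - df)
  lr <- if (ddf > 0)
    lr_test(fitted, reference, table, df, reference_df)
  else list(statistic = 0, ddf = 0L, p_value = 1)
  structure(list(model = model, fitted = fitted, df = df,
                 entropy_bits = entropy_bits(fitted),
                 transmission_bits = tbits,
                 lr_stat = lr$statistic, ddf = lr$ddf, p_value = lr$p_value,
                 loglik = ic$loglik, aic = ic$aic, bic = ic$bic,
                 ipf_iterations = iters),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  lbl <- if (inherits(x$model, "bn_dag")) dag_text(x$model)
         else canonical_text(x$model)
  cat(sprintf("Fit %s: df=%d H=%.4f T=%.6f bits LR=%.3f (ddf=%d, p=%.4g) AIC=%.2f BIC=%.2f\n",
              lbl, x$df, x$entropy_bits, x$transmission_bits, x$lr_stat,
              x$ddf, x$p_value, x$aic, x$bic))
  invisible(x)
}

#' Exploratory lattice search
#'
#' Greedy (or beam) traversal of a structure lattice along its hierarchy
#' edges.  Downward search starts at the saturated top and follows child
#' links; upward search starts at the bottom (most independent) structure and
#' follows parent links.  At each level the best `width` candidates under the
#' criterion are kept; the search stops when no neighbor improves on the
#' incumbent.
#'
#' @param lattice an `ra_lattice`.
#' @param table a `contingency_table` over the lattice's system.
#' @param direction `"up"` or `"down"`.
#' @param criterion `"bic"`, `"aic"` or `"chi2"` (for `"chi2"`, a move is an
#'   improvement when the step is statistically warranted at `alpha`:
#'   downward moves must not lose significant information, upward moves must
#'   gain significantly).
#' @param width beam width (default 1, greedy).
#' @param alpha significance level for the chi2 criterion.
#' @return list with `selected` (index), `path` (data.frame log of visited
#'   structures) and `fits` (list of `fit_result` for the final beam).
#' @export
search_lattice <- function(lattice, table, direction = c("up", "down"),
                           criterion = c("bic", "aic", "chi2"),
                           width = 1L, alpha = 0.05) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  if (!length(lattice$structures)) stop("empty lattice")
  parents <- invert_children(lattice$children)
  nstruct <- length(lattice$structures)
  roots <- if (direction == "down") which(lengths(parents) == 0L)
  else which(lengths(lattice$children) == 0L)
  ## degenerate fallback: single structure
  if (!length(roots)) roots <- 1L
  score_of <- function(fr) switch(criterion, bic = fr$bic, aic = fr$aic,
                                  chi2 = fr$bic)
  fits <- vector("list", nstruct)
  get_fit <- function(i) {
    if (is.null(fits[[i]]))
      fits[[i]] <<- fit_model(lattice$structures[[i]], table)
    fits[[i]]
  }
  beam <- utils::head(roots[order(vapply(roots, function(i)
    score_of(get_fit(i)), 0))], width)
  path <- data.frame(step = 0L, structure = lattice$keys[beam],
                     score = vapply(beam, function(i) score_of(get_fit(i)), 0),
                     stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- unique(unlist(lapply(beam, function(i)
      if (direction == "down") lattice$children[[i]] else parents[[i]])))
    cand <- setdiff(cand, beam)
    if (!length(cand)) break
    improved <- logical(length(cand))
    for (k in seq_along(cand)) {
      best_cur <- min(vapply(beam, function(i) score_of(get_fit(i)), 0))
      if (criterion == "chi2") {
        ## compare candidate against the current incumbent by LR test
        inc <- beam[which.min(vapply(beam, function(i)
          score_of(get_fit(i)), 0))]
        fi <- get_fit(inc); fc <- get_fit(cand[k])
        lo <- if (fc$df < fi$df) fc else fi   # simpler model
        hi <- if (fc$df < fi$df) fi else fc
        ddf <- hi$df - lo$df
        if (ddf == 0L) { improved[k] <- FALSE; next }
        lt <- lr_test(lo$fitted, hi$fitted, table, lo$df, hi$df)
        improved[k] <- if (direction == "down")
          lt$p_value > alpha   # simplification loses no significant info
        else lt$p_value < alpha  # added complexity is warranted
      } else {
        improved[k] <- score_of(get_fit(cand[k])) < best_cur
      }
    }
    cand <- cand[improved]
    if (!length(cand)) break
    beam <- utils::head(cand[order(vapply(cand, function(i)
      score_of(get_fit(i)), 0))], width)
    path <- rbind(path, data.frame(step = step,
                                   structure = lattice$keys[beam],
                                   score = vapply(beam, function(i)
                                     score_of(get_fit(i)), 0),
                                   stringsAsFactors = FALSE))
  }
  sel <- beam[which.min(vapply(beam, function(i) score_of(get_fit(i)), 0))]
  list(selected = sel, selected_key = lattice$keys[sel], path = path,
       fit = get_fit(sel))
}

invert_children <- function(children) {
  parents <- vector("list", length(children))
  for (i in seq_along(children)) parents[[i]] <- integer()
  for (i in seq_along(children)) for (j in children[[i]])
    parents[[j]] <- c(parents[[j]], i)
  lapply(parents, function(p) sort(unique(p)))
}
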