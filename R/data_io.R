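## Readers/writers for discrete multivariate data and the synthetic-data
## generator that makes every other module testable without downloads.

#' Read discrete data from CSV
#'
#' Two dialects: `"case"` has one row per observation (columns are
#' variables); `"contingency"` has state columns plus a final `count` column.
#' Values are state labels; cardinalities are inferred from the observed
#' levels unless a system is supplied, in which case labels must match the
#' system's `v0 ... v(k-1)` scheme (or be integers 0..k-1).
#'
#' @param path CSV file path.
#' @param format `"case"` or `"contingency"`.
#' @param system optional [ra_system()] fixing variables and cardinalities.
#' @return A `contingency_table`.
#' @export
read_table <- function(path, format = c("case", "contingency"),
                       system = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (format == "contingency") {
    if (!("count" %in% names(df))) stop("contingency CSV needs a 'count' column")
    counts <- as.numeric(df[["count"]])
    if (any(is.na(counts)) || any(counts < 0))
      stop("malformed or negative count")
    df <- df[setdiff(names(df), "count")]
  } else {
    counts <- rep(1, nrow(df))
  }
  if (!ncol(df)) stop("no variable columns")
  if (is.null(system)) {
    levs <- lapply(df, function(col) sort(unique(col)))
    if (any(lengths(levs) < 2L))
      stop("every variable needs at least two observed states; supply a system")
    system <- ra_system(names(df), lengths(levs))
  } else {
    stopifnot(setequal(names(df), system$names))
    df <- df[system$names]
    levs <- state_labels(system)
    names(levs) <- system$names
    for (v in system$names) {
      col <- df[[v]]
      if (all(grepl("^[0-9]+$", col))) col <- paste0(tolower(v), col)
      if (!all(col %in% levs[[v]]))
        stop("unknown state for variable ", v)
      df[[v]] <- col
    }
  }
  labels <- state_labels(system)
  arr <- array(0, dim = unname(system$card), dimnames = labels)
  idx <- as.matrix(as.data.frame(lapply(seq_along(system$names), function(i)
    match(df[[i]], labels[[i]]))))
  if (anyNA(idx)) stop("unknown state label in data")
  for (r in seq_len(nrow(idx))) arr[matrix(idx[r, ], 1L)] <-
      arr[matrix(idx[r, ], 1L)] + counts[r]
  contingency_table(system, arr)
}

#' Write a contingency table to CSV
#'
#' @param table a `contingency_table`.
#' @param path output CSV path.
#' @param format `"contingency"` (state columns + count) or `"case"`
#'   (one row per observation; counts must be integral).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, format = c("contingency", "case")) {
  format <- match.arg(format)
  grid <- expand.grid(dimnames(table$counts), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- table$system$names
  cnt <- as.vector(table$counts)
  if (format == "contingency") {
    grid$count <- cnt
    utils::write.csv(grid[grid$count > 0, , drop = FALSE], path,
                     row.names = FALSE, quote = FALSE)
  } else {
    if (any(cnt != round(cnt))) stop("case format needs integral counts")
    rows <- grid[rep(seq_len(nrow(grid)), cnt), , drop = FALSE]
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

## run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random strictly positive joint distribution
#'
#' Drawn from a symmetric Dirichlet with concentration 1 over the full state
#' space; the generic-position input for numeric audits.
#'
#' @param system an [ra_system()].
#' @param seed integer seed.
#' @return A `joint_distribution`.
#' @export
random_distribution <- function(system, seed) {
  k <- prod(system$card)
  g <- with_seed(seed, stats::rgamma(k, shape = 1))
  g <- pmax(g, 1e-12)
  joint_distribution(system, g / sum(g))
}

#' Synthetic-data specification
#'
#' Describes a generating model for [sample_from_model()].  For an RA
#' structure the generating distribution is the maximum-entropy projection of
#' a seed distribution onto the structure (so its relation margins are the
#' seed's): with `effect_strength = NULL` the seed is Dirichlet(1); with a
#' numeric strength s in (0, 1) the seed is the mixture
#' (1 - s) Dirichlet + s "agreement" mass concentrated on states where all
#' variables take the same level, giving controllably strong dependence
#' within every relation.  For a DAG, conditional tables are drawn
#' Dirichlet(1) per node and parent state.
#'
#' @param model an `ra_structure` or `bn_dag`.
#' @param n sample size (>= 1).
#' @param seed integer seed.
#' @param effect_strength NULL or a value in (0, 1) (RA models only;
#'   0.6 is a strong effect for binary variables).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model, n, seed, effect_strength = NULL) {
  stopifnot(n >= 1)
  if (!is.null(effect_strength))
    stopifnot(effect_strength > 0, effect_strength < 1)
  structure(list(model = model, n = as.integer(n), seed = as.integer(seed),
                 effect_strength = effect_strength),
            class = "synthetic_spec")
}

generating_distribution <- function(spec) {
  model <- spec$model
  sys <- model$system
  if (inherits(model, "bn_dag")) {
    probs <- with_seed(spec$seed, {
      fitarr <- array(1, dim = unname(sys$card))
      for (v in sys$names) {
        pa <- sort(parents_of(model, v))
        vars <- sys_sort(sys, c(v, pa))
        fam_dim <- unname(sys$card[vars])
        g <- array(stats::rgamma(prod(fam_dim), 1), dim = fam_dim)
        cond <- if (length(pa)) conditional_family(g, sys, v, pa)
                else g / sum(g)
        fitarr <- fitarr * spread_to_full(cond, sys, vars)
      }
      fitarr
    })
    return(joint_distribution(sys, probs))
  }
  ## RA structure: maximum-entropy projection of a seed distribution
  seed_dist <- random_distribution(sys, spec$seed)
  probs <- seed_dist$probs
  if (!is.null(effect <- spec$effect_strength)) {
    agree <- array(0, dim = dim(probs))
    lev <- min(sys$card)
    for (l in seq_len(lev))
      agree[matrix(rep(l, length(sys$names)), 1L)] <- 1 / lev
    probs <- (1 - effect) * probs + effect * agree
  }
  tb <- contingency_table(sys, probs * 1e6)
  fit_maxent(model, tb)
}

#' Sample observations from a synthetic model
#'
#' Multinomial sampling from the generating distribution of a
#' [synthetic_spec()]; the exact generating distribution is returned with the
#' draw so recovery experiments can compare against the truth.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `cases` (data.frame, one row per observation), `table`
#'   (`contingency_table` of the same draw) and `distribution` (the exact
#'   generating `joint_distribution`).
#' @export
sample_from_model <- function(spec) {
  dist <- generating_distribution(spec)
  sys <- dist$system
  counts <- with_seed(spec$seed + 1L,
                      stats::rmultinom(1L, spec$n, as.vector(dist$probs))[, 1L])
  arr <- array(counts, dim = dim(dist$probs), dimnames = dimnames(dist$probs))
  tb <- contingency_table(sys, arr)
  grid <- expand.grid(dimnames(arr), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- sys$names
  cases <- grid[rep(seq_len(nrow(grid)), counts), , drop = FALSE]
  rownames(cases) <- NULL
  list(cases = cases, table = tb, distribution = dist)
}
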