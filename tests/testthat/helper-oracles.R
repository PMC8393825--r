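# Independent numeric oracles, written against first principles rather than
# package internals: a brute-force joint distribution for a DAG with random
# conditional tables, and conditional mutual information computed from a
# state-indexed data frame.

# random DAG on binary variables: random topological order + edge coin flips
oracle_random_dag <- function(system, p_edge = 0.5) {
  nm <- sample(system$names)
  edges <- NULL
  n <- length(nm)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, c(nm[i], nm[j]))
    }
  }
  bn_dag(system, edges)
}

# joint distribution as a data frame of states and probabilities, built by
# explicit enumeration: p(state) = prod over nodes of a Dirichlet-drawn
# conditional p(node = s | parents = pa(state))
oracle_joint <- function(dag) {
  nm <- dag$system$names
  card <- unname(dag$system$card)
  grid <- expand.grid(lapply(card, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nm
  prob <- rep(1, nrow(grid))
  for (v in nm) {
    pa <- dag$edges[dag$edges[, 2L] == v, 1L]
    kv <- card[match(v, nm)]
    if (length(pa)) {
      pagrid <- unique(grid[pa])
      for (r in seq_len(nrow(pagrid))) {
        g <- stats::rgamma(kv, 1) + 1e-4
        cpt <- g / sum(g)
        sel <- rep(TRUE, nrow(grid))
        for (p in pa) sel <- sel & grid[[p]] == pagrid[r, p]
        prob[sel] <- prob[sel] * cpt[grid[[v]][sel]]
      }
    } else {
      g <- stats::rgamma(kv, 1) + 1e-4
      cpt <- g / sum(g)
      prob <- prob * cpt[grid[[v]]]
    }
  }
  grid$p <- prob
  grid
}

# conditional mutual information I(x; y | S) in bits from an oracle joint
oracle_cmi <- function(joint, x, y, S = character()) {
  key <- function(cols) {
    if (!length(cols)) return(rep("", nrow(joint)))
    do.call(paste, c(joint[cols], sep = "\r"))
  }
  agg <- function(cols) {
    k <- key(cols)
    tapply(joint$p, k, sum)[k]
  }
  pxyS <- agg(c(x, y, S))
  pxS <- agg(c(x, S))
  pyS <- agg(c(y, S))
  pS <- if (length(S)) agg(S) else rep(1, nrow(joint))
  sum(joint$p * log2((pxyS * pS) / (pxS * pyS)))
}
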