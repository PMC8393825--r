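test_that("DAG enumeration counts are exact at small n", {
  expect_length(enumerate_dags(ra_system(c("A", "B"))), 3L)
  expect_length(enumerate_dags(ra_system(c("A", "B", "C"))), 25L)
  big <- ra_system(LETTERS[1:7])
  expect_error(enumerate_dags(big), "n > 6")
})

test_that("skeleton and V-structures follow the definitions", {
  s3 <- ra_system(c("A", "B", "C"))
  collider <- parse_dag("A>B;C>B", s3)
  expect_identical(skeleton(collider), c("A-B", "B-C"))
  expect_identical(v_structures(collider), "A>B<C")
  chain <- parse_dag("A>B;B>C", s3)
  expect_identical(v_structures(chain), character())
  ## adjacent parents do not converge into a V-structure
  s <- abcd_system()
  married <- parse_dag("B>D;C>D;B>C;A", s)
  expect_identical(v_structures(married), character())
})

test_that("Markov equivalence is same skeleton + same V-structures", {
  s3 <- ra_system(c("A", "B", "C"))
  expect_true(markov_equivalent(parse_dag("A>B;B>C", s3),
                                parse_dag("C>B;B>A", s3)))
  expect_false(markov_equivalent(parse_dag("A>B;C>B", s3),
                                 parse_dag("A>B;B>C", s3)))
  ## the three topologies of the two-triangle class are mutually equivalent
  s <- abcd_system()
  bn2 <- parse_dag("C>A;D>A;C>B;D>B;C>D", s)
  bn2b <- parse_dag("C>A;D>A;C>B;D>B;D>C", s)
  expect_true(markov_equivalent(bn2, bn2b))
})

test_that("markov equivalence coincides with equal independence sets (n = 3)", {
  s3 <- ra_system(c("A", "B", "C"))
  dags <- enumerate_dags(s3)
  els <- lapply(dags, function(d) independencies(d)$elementary)
  for (i in seq_along(dags)) for (j in seq_along(dags)) {
    expect_identical(markov_equivalent(dags[[i]], dags[[j]]),
                     identical(els[[i]], els[[j]]))
  }
})

test_that("d-separation verdicts match the published examples", {
  s <- abcd_system()
  bn2 <- parse_dag("C>A;D>A;C>B;D>B;C>D", s)
  expect_true(d_separated(bn2, "A", "B", c("C", "D")))
  expect_false(d_separated(bn2, "A", "B", "C"))
  s3 <- ra_system(c("A", "B", "C"))
  collider <- parse_dag("A>B;C>B", s3)
  expect_true(d_separated(collider, "A", "C"))
  expect_false(d_separated(collider, "A", "C", "B"))
  expect_error(d_separated(collider, "A", "A"), "distinct")
})

test_that("d-separation agrees with a numeric CMI oracle", {
  ## package verdict vs conditional mutual information of an independently
  ## computed factorized joint; the full 200-instance audit runs in the
  ## acceptance suite
  s <- abcd_system()
  set.seed(55)
  for (i in seq_len(40)) {
    dag <- oracle_random_dag(s)
    joint <- oracle_joint(dag)
    vars <- sample(s$names, 2L)
    Ssize <- sample(0:2, 1L)
    S <- sample(setdiff(s$names, vars), Ssize)
    sep <- d_separated(dag, vars[1L], vars[2L], S)
    cmi <- oracle_cmi(joint, vars[1L], vars[2L], S)
    if (sep) expect_lt(cmi, 1e-10) else expect_gt(cmi, 1e-9)
  }
})

test_that("independence sets and display lists match the published rows", {
  s <- abcd_system()
  bn17 <- parse_dag(bn_rep_rows$BN17$dag, s)
  expect_identical(display_set(independencies(bn17)),
                   sort(c("(B ⊥ C)", "(A ⊥ B, C, D)")))
  full <- parse_dag(bn_rep_rows$BN1$dag, s)
  expect_length(independencies(full)$display, 0L)
  expect_length(independencies(full)$elementary, 0L)
  empty <- parse_dag("A;B;C;D", s)
  expect_identical(display_set(independencies(empty)),
                   sort(bn_rep_rows$BN20$ind))
  expect_length(independencies(empty)$elementary, 24L)
})

test_that("specific and general classes have the known counts", {
  s3 <- ra_system(c("A", "B", "C"))
  sp3 <- specific_classes(s3)
  expect_length(sp3, 11L)
  expect_identical(sum(vapply(sp3, function(cl) cl$n_members, 0L)), 25L)
  expect_length(general_classes(sp3), 5L)
  ## n = 4 counts are asserted in the acceptance suite; here: cached reuse
  sp <- specific4()
  expect_length(sp, 185L)
  expect_identical(sum(vapply(sp, function(cl) cl$n_members, 0L)), 543L)
})

test_that("CPDAG directs exactly the invariant edges", {
  s3 <- ra_system(c("A", "B", "C"))
  sp3 <- specific_classes(s3)
  keyed <- vapply(sp3, function(cl) dag_text(cl$rep), "")
  chain <- sp3[[match("A>B;B>C", keyed)]]
  pd <- cpdag(chain)
  expect_identical(nrow(pd$directed), 0L)
  expect_identical(pd$undirected, c("A-B", "B-C"))
  collider <- sp3[[match("A>B;C>B", keyed)]]
  pd2 <- cpdag(collider)
  expect_identical(length(pd2$undirected), 0L)
  expect_setequal(paste0(pd2$directed[, 1], ">", pd2$directed[, 2]),
                  c("A>B", "C>B"))
  ## the no-V chain class over skeleton B-D-C excludes the collider at D:
  ## both edges stay undirected yet the collider is a different class
  sp <- specific4()
  keys4 <- vapply(sp, function(cl) dag_text(cl$rep), "")
  fork <- sp[[match("B>C;B>D;A", keys4)]]   # B-D, B-C chain class? no: B>C;B>D
  pdf <- cpdag(fork)
  expect_identical(nrow(pdf$directed), 0L)
})

test_that("factorization strings list p(node | parents)", {
  s <- abcd_system()
  for (nm in c("BN2", "BN19", "BN20")) {
    d <- parse_dag(bn_rep_rows[[nm]]$dag, s)
    expect_identical(norm_terms(attr(factorization(d), "text")),
                     norm_terms(bn_rep_rows[[nm]]$terms))
  }
})

test_that("factorization with random conditionals multiplies to a distribution", {
  s <- abcd_system()
  set.seed(77)
  for (i in seq_len(10)) {
    dag <- oracle_random_dag(s)
    joint <- oracle_joint(dag)
    expect_equal(sum(joint$p), 1, tolerance = 1e-12)
  }
})

test_that("moral graph marries co-parents", {
  s3 <- ra_system(c("A", "B", "C"))
  expect_identical(moral_graph(parse_dag("A>B;C>B", s3)),
                   c("A-B", "A-C", "B-C"))
  expect_identical(moral_graph(parse_dag("A>B;B>C", s3)), c("A-B", "B-C"))
  s <- abcd_system()
  expect_identical(moral_graph(parse_dag("B>D;C>D;A", s)),
                   c("B-C", "B-D", "C-D"))
})

test_that("extended notation reproduces the published examples", {
  s <- abcd_system()
  expect_identical(canonical_text(bn_notation(parse_dag("B>D;C>D;A", s))),
                   "BCD_B:C_:A")
  expect_identical(canonical_text(bn_notation(parse_dag(bn_rep_rows$BN4$dag, s))),
                   "ABCD_AC:BC_")
  expect_identical(canonical_text(bn_notation(parse_dag(bn_rep_rows$BN8$dag, s))),
                   "ACD_C:D_:BCD_C:D_")
})

test_that("DAG text format round-trips and rejects malformed input", {
  s <- abcd_system()
  for (txt in c("B>D;C>D;A", "A;B;C;D", "A>B;A>C;B>C;A>D;B>D;C>D")) {
    d <- parse_dag(txt, s)
    expect_identical(dag_text(parse_dag(dag_text(d), s)), dag_text(d))
  }
  expect_error(parse_dag("A>B;B>A", s), "both ways")
  expect_error(bn_dag(s, rbind(c("A","B"), c("B","C"), c("C","A"))), "cycle")
  expect_error(parse_dag("A>Q", s), "unknown variable")
})
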