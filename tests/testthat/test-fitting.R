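test_that("closed-form BN fits match their defining special cases", {
  s <- abcd_system()
  uni <- contingency_table(s, rep(10, 16))
  f_empty <- fit_bn(parse_dag("A;B;C;D", s), uni)
  expect_equal(as.vector(f_empty$probs), rep(1 / 16, 16), tolerance = 1e-12)
  ## the complete DAG reproduces the empirical distribution exactly
  tb <- contingency_table(s, random_distribution(s, 11)$probs * 2e3)
  f_full <- fit_bn(parse_dag(bn_rep_rows$BN1$dag, s), tb)
  expect_equal(as.vector(f_full$probs), as.vector(tb$counts / tb$n),
               tolerance = 1e-12)
  ## a margin-assembled fit matches manual assembly: p(D|C)p(C)p(A)p(B)
  d19 <- parse_dag("C>D;A;B", s)
  f19 <- fit_bn(d19, tb)
  p <- tb$counts / tb$n
  pa_ <- apply(p, 1, sum); pb <- apply(p, 2, sum)
  pcd <- apply(p, c(3, 4), sum)   # p(C, D) = p(C) p(D|C)
  manual <- outer(outer(pa_, pb), pcd)
  expect_equal(as.vector(f19$probs), as.vector(manual), tolerance = 1e-12)
})

test_that("IPF reaches the max-entropy fixed point", {
  s <- abcd_system()
  tb <- contingency_table(s, random_distribution(s, 12)$probs * 1e4)
  ## loopless: closed form in one sweep
  st <- parse_structure("AB:BC", ra_system(c("A", "B", "C")))
  tb3 <- contingency_table(ra_system(c("A", "B", "C")),
                           random_distribution(ra_system(c("A", "B", "C")),
                                               13)$probs * 1e3)
  f <- fit_maxent(st, tb3)
  p3 <- tb3$counts / tb3$n
  pab <- apply(p3, c(1, 2), sum); pbc <- apply(p3, c(2, 3), sum)
  pb <- apply(p3, 2, sum)
  manual <- array(0, dim = dim(p3))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    manual[i, j, k] <- pab[i, j] * pbc[j, k] / pb[j]
  expect_equal(as.vector(f$probs), as.vector(manual), tolerance = 1e-10)
  ## product of univariate margins
  f_ind <- fit_maxent(parse_structure("A:B:C:D", s), tb)
  marg <- lapply(1:4, function(i) apply(tb$counts / tb$n, i, sum))
  expect_equal(as.vector(f_ind$probs),
               as.vector(outer(outer(outer(marg[[1]], marg[[2]]),
                                     marg[[3]]), marg[[4]])),
               tolerance = 1e-10)
  ## loopy triangle: margins reproduced at the fixed point
  s3 <- ra_system(c("A", "B", "C"))
  tri <- parse_structure("AB:BC:CA", s3)
  f_tri <- fit_maxent(tri, tb3)
  for (r in tri$relations) {
    got <- apply(f_tri$probs, match(r, s3$names), sum)
    want <- apply(tb3$counts / tb3$n, match(r, s3$names), sum)
    expect_lt(max(abs(got - want)), 1e-8)
  }
  expect_gt(attr(f_tri, "iterations"), 1L)
})

test_that("the maxent projection never lowers entropy", {
  s <- abcd_system()
  set.seed(21)
  lat3 <- ra_lattice(ra_system(c("A", "B", "C")))
  for (i in 1:5) {
    tb <- contingency_table(s, random_distribution(s, 500 + i)$probs * 1e3)
    hdata <- entropy_bits(joint_distribution(s, tb$counts / tb$n))
    for (txt in c("AD:BD:CD", "AB:BC:CD:AD", "ABC:D")) {
      f <- fit_maxent(parse_structure(txt, s), tb)
      expect_gte(entropy_bits(f) + 1e-10, hdata)
    }
  }
})

test_that("entropy and transmission behave as information measures", {
  s <- abcd_system()
  u <- joint_distribution(s, rep(1 / 16, 16))
  expect_equal(entropy_bits(u), 4)
  d <- random_distribution(s, 14)
  expect_equal(transmission_bits(d, d), 0)
  expect_gt(transmission_bits(d, u), 0)
  ## zero model mass where data has support: infinite transmission
  q <- d$probs; q[1] <- 0; q <- q / sum(q)
  expect_identical(transmission_bits(d, joint_distribution(s, q)), Inf)
})

test_that("transmission to sampled data vanishes under the true structure", {
  s <- abcd_system()
  st <- parse_structure("AC:BC:D", s)
  sm <- sample_from_model(synthetic_spec(st, n = 1e5, seed = 31))
  fit <- fit_maxent(st, sm$table)
  expect_lt(transmission_bits(empirical_distribution(sm$table), fit), 0.001)
})

test_that("degrees of freedom follow the u-term and per-node formulas", {
  s <- abcd_system()
  expect_identical(degrees_of_freedom(parse_structure("ABCD", s)), 15)
  expect_identical(degrees_of_freedom(parse_structure("A:B:C:D", s)), 4)
  expect_identical(degrees_of_freedom(parse_structure("AD:BD:CD", s)), 7)
  expect_identical(degrees_of_freedom(parse_dag("D>A;D>B;D>C", s)), 7)
  ## a three-state variable changes both formulas coherently
  s3c <- ra_system(c("A", "B"), cardinalities = c(3, 2))
  expect_identical(degrees_of_freedom(parse_structure("AB", s3c)), 5)
  expect_identical(degrees_of_freedom(parse_dag("A>B", s3c)), 5)
})

test_that("likelihood-ratio test matches its formula and rejects only real effects", {
  s <- abcd_system()
  tb <- contingency_table(s, random_distribution(s, 15)$probs * 1e4)
  f <- fit_maxent(parse_structure("AD:BD:CD", s), tb)
  ref <- empirical_distribution(tb)
  lt <- lr_test(f, ref, tb, model_df = 7, reference_df = 15)
  expect_equal(lt$statistic,
               2 * tb$n * log(2) * transmission_bits(ref, f),
               tolerance = 1e-10)
  expect_identical(lt$ddf, 8)
  expect_error(lr_test(f, ref, tb, 7, 7), "ddf = 0")
  ## identical fits give statistic 0, p = 1
  lt0 <- lr_test(ref, ref, tb, 15, 4)
  expect_equal(lt0$statistic, 0)
  expect_equal(lt0$p_value, 1)
  ## strong dependence is detected decisively
  sm <- sample_from_model(synthetic_spec(parse_structure("AD:BD:CD", s),
                                         n = 1e4, seed = 32,
                                         effect_strength = 0.6))
  fit_alt <- fit_maxent(parse_structure("AD:BD:CD", s), sm$table)
  fit_null <- fit_maxent(parse_structure("A:B:C:D", s), sm$table)
  lt2 <- lr_test(fit_null, fit_alt, sm$table, 4, 7)
  expect_lt(lt2$p_value, 1e-6)
})

test_that("information criteria match an independently coded evaluation", {
  s <- abcd_system()
  tb <- contingency_table(s, random_distribution(s, 16)$probs * 3e3)
  st <- parse_structure("AD:BD:CD", s)
  f <- fit_maxent(st, tb)
  ic <- information_criteria(f, tb, df = 7)
  ll <- sum(as.vector(tb$counts) * log(as.vector(f$probs)))
  expect_equal(ic$aic, -2 * ll + 2 * 7, tolerance = 1e-10)
  expect_equal(ic$bic, -2 * ll + 7 * log(tb$n), tolerance = 1e-10)
  ## equal loglik, lower df -> lower BIC
  ic_sat <- information_criteria(empirical_distribution(tb), tb, df = 15)
  expect_gt(ic_sat$bic - ic_sat$loglik * -2,
            ic$bic - ic$loglik * -2 - 1e-9)
})

test_that("predict_dv renormalizes slices and is constant under independence", {
  s <- abcd_system()
  tb <- contingency_table(s, random_distribution(s, 17)$probs * 1e3)
  f_ind <- fit_maxent(parse_structure("A:B:C:D", s), tb)
  pz <- predict_dv(f_ind, "D")
  ## every IV state shows the same conditional: the D margin
  md <- apply(tb$counts / tb$n, 4, sum)
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_equal(as.vector(pz[i, j, k, ]), as.vector(md), tolerance = 1e-9)
})

test_that("lattice search recovers generating structures", {
  s <- abcd_system()
  lat <- ra4()
  sm <- sample_from_model(synthetic_spec(parse_structure("AD:BD:CD", s),
                                         n = 1e5, seed = 41,
                                         effect_strength = 0.6))
  up <- search_lattice(lat, sm$table, direction = "up", criterion = "bic")
  expect_identical(up$selected_key, "AD:BD:CD")
  sm0 <- sample_from_model(synthetic_spec(parse_structure("A:B:C:D", s),
                                          n = 1e4, seed = 42))
  up0 <- search_lattice(lat, sm0$table, direction = "up", criterion = "bic")
  expect_identical(up0$selected_key, "A:B:C:D")
  ## downward search from the saturated model reaches the same structure
  down <- search_lattice(lat, sm$table, direction = "down", criterion = "bic")
  expect_identical(down$selected_key, "AD:BD:CD")
  ## the path log starts at the search root
  expect_identical(up$path$structure[1L], "A:B:C:D")
  expect_identical(down$path$structure[1L], "ABCD")
})

test_that("transmission decreases monotonically up any hierarchy chain", {
  s <- abcd_system()
  lat <- ra4()
  tb <- contingency_table(s, random_distribution(s, 18)$probs * 1e4)
  data_dist <- empirical_distribution(tb)
  ## walk one chain bottom -> top following reversed hierarchy edges
  parents <- rabn:::invert_children(lat$children)
  i <- match("A:B:C:D", lat$keys)
  t_prev <- Inf
  while (TRUE) {
    tr <- transmission_bits(data_dist,
                            fit_maxent(lat$structures[[i]], tb))
    expect_lte(tr, t_prev + 1e-10)
    t_prev <- tr
    if (!length(parents[[i]])) break
    i <- parents[[i]][1L]
  }
  expect_lt(t_prev, 1e-12)  # the saturated model reproduces the data
})
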