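test_that("shared miRNA bookkeeping is plain set arithmetic", {
  ints <- data.frame(
    mirna_id = c("a", "b", "c", "d", "c", "d", "e"),
    target_id = c("L1", "L1", "L1", "L1", "M1", "M1", "M1"))
  r <- shared_mirnas("L1", "M1", ints, universe = letters[1:10])
  expect_equal(r$shared, c("c", "d"))
  expect_equal(c(r$k, r$K, r$n, r$N), c(2, 4, 3, 10))

  # restricting the universe drops d everywhere
  r2 <- shared_mirnas("L1", "M1", ints, universe = setdiff(letters[1:10], "d"))
  expect_equal(r2$shared, "c")
  expect_equal(c(r2$k, r2$K, r2$n, r2$N), c(1, 3, 2, 9))

  # disjoint targeting sets share nothing
  ints2 <- data.frame(mirna_id = c("a", "b"), target_id = c("L1", "M1"))
  expect_equal(shared_mirnas("L1", "M1", ints2, letters[1:5])$k, 0)
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_pvalue(0, 3, 2, 8), 1)
  expect_equal(hypergeom_pvalue(2, 4, 3, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(4, 4, 4, 4), 1)
  expect_error(hypergeom_pvalue(5, 4, 3, 10), "usage error")

  # spot-check the full enumeration oracle on a grid (the exhaustive
  # N <= 12 sweep runs in the acceptance suite)
  for (N in c(5, 9, 12)) for (K in 0:N) for (n in c(0, 2, N)) {
    if (n > N) next
    for (k in 0:min(K, n)) {
      expect_equal(hypergeom_pvalue(k, K, n, N),
                   oracle_hyper_upper(k, K, n, N), tolerance = 1e-12)
    }
  }
})

test_that("pair correlation matches the direct covariance formula", {
  r <- pair_correlation(1:4, 2 * (1:4) + 1)
  expect_equal(r$r, 1)
  expect_equal(pair_correlation(1:4, -(1:4))$r, -1)

  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r2 <- pair_correlation(x, y)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2$r, oracle, tolerance = 1e-12)
  tstat <- oracle * sqrt(2 / (1 - oracle^2))
  expect_equal(r2$p, 2 * pt(abs(tstat), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_warning(flat <- pair_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(flat$r))
  expect_error(pair_correlation(1:2, 1:2), "usage error")
})

test_that("regulation similarity follows its closed form and symmetry", {
  expect_equal(regulation_similarity(-0.5, -0.5), 1)
  expect_equal(regulation_similarity(-0.5, 0.5), 0)
  expect_equal(regulation_similarity(c(-0.4, -0.6), c(-0.4, -0.3)),
               13 / 18, tolerance = 1e-12)
  # both-zero positions contribute the minimal term
  expect_equal(regulation_similarity(c(0, -0.5), c(0, -0.5)), 0.5)

  set.seed(6)
  for (i in 1:20) {
    a <- runif(4, -1, 1); b <- runif(4, -1, 1)
    expect_equal(regulation_similarity(a, b), regulation_similarity(b, a))
  }
  a <- c(-0.3, 0.7, 0.1)
  expect_equal(regulation_similarity(a, a), 1)
  expect_lt(regulation_similarity(a, a + c(0.1, 0, 0)), 1)
  expect_error(regulation_similarity(numeric(0), numeric(0)), "usage error")
})

make_pair_fixture <- function(strength = 0.9, n = 40, seed = 31) {
  set.seed(seed)
  z <- rnorm(n)
  noise <- function() rnorm(n, sd = 0.4)
  E <- rbind(L1 = 5 + strength * z + noise(),
             M1 = 6 + strength * z + noise(),
             M2 = 6 + noise())
  # a, b, c target the candidate pair; d..j pad the measured universe
  # (they regulate an unmeasured transcript) so overlap is not forced
  Emir <- rbind(a = 4 - strength * z + noise(),
                b = 4 - strength * z + noise(),
                c = 4 + noise())
  for (mi in letters[4:10]) Emir <- rbind(Emir, noise() + 4)
  rownames(Emir) <- letters[1:10]
  cols <- sprintf("T%02d", 1:n)
  colnames(E) <- cols; colnames(Emir) <- cols
  grp <- setNames(factor(rep("tumour", n), levels = c("normal", "tumour")),
                  cols)
  list(expr = expr_matrix(E, log = TRUE, groups = grp),
       mir = expr_matrix(Emir, log = TRUE, groups = grp),
       ints = data.frame(
         mirna_id = c("a", "b", "a", "b", "c", "c", letters[4:10]),
         target_id = c("L1", "L1", "M1", "M1", "M1", "L1",
                       rep("OTHER", 7))))
}

test_that("pair inference applies the three evidence lines and the gates", {
  fx <- make_pair_fixture()
  pairs <- infer_cerna_pairs("L1", c("M1", "M2"), c("a", "b", "c"),
                             fx$expr, fx$mir, fx$ints)
  # M2 has no interactions at all -> never evaluated
  expect_equal(pairs$mRNA, "M1")
  expect_equal(pairs$n_shared, 3)  # a, b, c all shared
  expect_true(pairs$passed)
  expect_gt(pairs$cor_r, 0.5)
  expect_gt(pairs$reg_sim, 0.5)

  # min_shared gating: demanding more shared DE miRNAs than exist drops it
  none <- infer_cerna_pairs("L1", "M1", c("a", "b", "c"), fx$expr, fx$mir,
                            fx$ints, min_shared = 4L)
  expect_equal(nrow(none), 0L)

  # k = 0: pair without shared miRNAs is absent, not failed
  ints0 <- data.frame(mirna_id = c("a", "b"), target_id = c("L1", "M1"))
  p0 <- infer_cerna_pairs("L1", "M1", c("a", "b"), fx$expr, fx$mir, ints0)
  expect_equal(nrow(p0), 0L)

  # tightening any threshold never adds a passed pair
  loose <- infer_cerna_pairs("L1", "M1", c("a", "b", "c"), fx$expr, fx$mir,
                             fx$ints)
  for (tight in list(list(hyper_cut = 1e-12), list(cor_cut = 1e-12),
                     list(regsim_cut = 0.999), list(min_shared = 4L))) {
    args <- c(list("L1", "M1", c("a", "b", "c"), fx$expr, fx$mir, fx$ints),
              tight)
    t <- do.call(infer_cerna_pairs, args)
    expect_lte(sum(t$passed), sum(loose$passed))
  }
})

test_that("an uncorrelated pair fails the correlation evidence", {
  fx <- make_pair_fixture(strength = 0)
  pairs <- infer_cerna_pairs("L1", "M1", c("a", "b", "c"), fx$expr, fx$mir,
                             fx$ints)
  expect_false(any(pairs$passed))
})

test_that("network assembly is tripartite with set-semantics deduplication", {
  pairs <- data.frame(
    lncRNA = c("SNHG1", "SNHG1", "SNHG1"),
    mRNA = c("E2F8", "LMNB2", "FANCE"),
    shared_mirnas = c("hsa-miR-421,hsa-miR-377-3p", "hsa-miR-330-5p",
                      "hsa-miR-326"),
    passed = TRUE, stringsAsFactors = FALSE)
  net <- build_network(pairs)
  st <- network_stats(net)
  # 1 lncRNA + 4 miRNAs + 3 mRNAs
  expect_equal(st$n_nodes, 8L)
  expect_equal(sum(net$nodes$biotype == "miRNA"), 4L)
  # 4 lnc-mir edges + 4 mir-mrna edges
  expect_equal(st$n_edges, 8L)
  expect_equal(st$degree$id[1], "SNHG1")  # hub by degree
  expect_equal(st$degree$degree[1], 4L)

  # edges connect only lnc-mir or mir-mrna endpoints
  bt <- setNames(net$nodes$biotype, net$nodes$id)
  lm <- net$edges[net$edges$relation == "lnc_mir", ]
  expect_true(all(bt[lm$source] == "lncRNA" & bt[lm$target] == "miRNA"))
  mm <- net$edges[net$edges$relation == "mir_mrna", ]
  expect_true(all(bt[mm$source] == "miRNA" & bt[mm$target] == "mRNA"))

  # two pairs sharing a miRNA: node counted once, edges deduplicated
  pairs2 <- data.frame(lncRNA = c("L1", "L2"), mRNA = c("M1", "M1"),
                       shared_mirnas = c("x", "x"), passed = TRUE)
  net2 <- build_network(pairs2)
  expect_equal(sum(net2$nodes$id == "x"), 1L)
  expect_equal(nrow(net2$edges), 3L)  # L1-x, L2-x, x-M1
  ev <- net2$edges$evidence[net2$edges$source == "x"]
  expect_equal(ev, "L1|M1;L2|M1")

  # no passed pairs -> empty network
  empty <- build_network(pairs[pairs$lncRNA == "none", ])
  expect_equal(network_stats(empty)$n_nodes, 0L)
  expect_equal(network_stats(empty)$n_edges, 0L)
})

test_that("planted triples are recovered end to end from simulated data", {
  res <- run_pipeline(sim_config(seed = 11))
  truth_pairs <- vapply(res$data$truth$triples,
                        function(t) paste(t$lncrna, t$mrna), "")
  passed <- res$pairs[res$pairs$passed, ]
  got <- paste(passed$lncRNA, passed$mRNA)
  expect_gte(sum(truth_pairs %in% got), 4L)
})
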