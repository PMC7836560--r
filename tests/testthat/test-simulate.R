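small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_tumour = 20, n_normal = 20, n_mrna = 100, n_lncrna = 30,
         n_mirna = 30, n_triples = 2),
    list(...))
  do.call(sim_config, args)
}

test_that("identical config and seed give byte-identical output", {
  a <- simulate_dataset(small_cfg(seed = 5))
  b <- simulate_dataset(small_cfg(seed = 5))
  expect_identical(a$rna$counts, b$rna$counts)
  expect_identical(a$mirna$counts, b$mirna$counts)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("null configuration plants nothing", {
  d <- simulate_dataset(small_cfg(seed = 3, frac_de = 0,
                                  triple_strength = 1e-12))
  expect_equal(nrow(d$truth$de_genes), 0L)
  expect_true(all(d$rna$counts >= 0))
  expect_true(all(d$rna$counts == round(d$rna$counts)))
})

test_that("ground truth ids all resolve in the generated tables", {
  d <- simulate_dataset(small_cfg(seed = 9))
  all_genes <- c(rownames(d$rna$counts), rownames(d$mirna$counts))
  expect_true(all(d$truth$de_genes$gene_id %in% all_genes))
  for (t in d$truth$triples) {
    expect_true(t$lncrna %in% rownames(d$rna$counts))
    expect_true(t$mrna %in% rownames(d$rna$counts))
    expect_true(all(t$mirnas %in% rownames(d$mirna$counts)))
  }
  expect_true(all(names(d$truth$surv_effects) %in% all_genes))
  expect_true(all(d$interactions$mirna_id %in% rownames(d$mirna$counts)))
  expect_true(all(d$interactions$target_id %in% rownames(d$rna$counts)))
  expect_true(all(d$annotation$gene_id %in% all_genes) &&
                all(all_genes %in% d$annotation$gene_id))
})

test_that("planted triples realise the signed correlation pattern", {
  # 20 replicate datasets at the study settings; every planted triple
  # should show corr(lnc, mRNA) > 0 and both miRNA correlations < 0 in
  # at least 90% of triple-replicates
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    d <- simulate_expression(sim_config(seed = 100 + s, n_mrna = 60,
                                        n_lncrna = 20, n_mirna = 20,
                                        n_triples = 5,
                                        triple_strength = 0.8))
    lr <- log2(sweep(d$rna$counts, 2, colSums(d$rna$counts), "/") * 1e6 + 1)
    lm <- log2(sweep(d$mirna$counts, 2, colSums(d$mirna$counts), "/") * 1e6 + 1)
    for (t in d$truth$triples) {
      ok <- cor(lr[t$lncrna, ], lr[t$mrna, ]) > 0 &&
        all(vapply(t$mirnas, function(mi)
          cor(lm[mi, ], lr[t$lncrna, ]) < 0 &&
            cor(lm[mi, ], lr[t$mrna, ]) < 0, logical(1)))
      hits <- hits + ok; total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("interaction table is forced by construction when background is off", {
  d <- simulate_expression(small_cfg(seed = 2, n_triples = 1,
                                     bg_edge_prob = 0))
  ints <- simulate_interactions(small_cfg(seed = 2, n_triples = 1,
                                          bg_edge_prob = 0), d$truth)
  expect_equal(nrow(ints), 6L)  # 3 miRNAs x {lncRNA, mRNA}
  expect_equal(sum(ints$target_id == d$truth$triples[[1]]$lncrna), 3L)

  d0 <- simulate_expression(small_cfg(seed = 2, n_triples = 0,
                                      bg_edge_prob = 0))
  ints0 <- simulate_interactions(small_cfg(seed = 2, n_triples = 0,
                                           bg_edge_prob = 0), d0$truth)
  expect_equal(nrow(ints0), 0L)
})

test_that("background edge count is binomial at the configured rate", {
  cfg <- sim_config(n_mrna = 900, n_lncrna = 100, n_mirna = 100,
                    n_triples = 0, bg_edge_prob = 0.01, seed = 8)
  d <- simulate_expression(cfg)
  ints <- simulate_interactions(cfg, d$truth)
  # 100 miRNAs x 1000 targets; mean 1000, SD sqrt(990)
  expect_lt(abs(nrow(ints) - 1000), 3 * sqrt(1000 * 0.99))
})

test_that("unplanted genes follow the configured NB mean-variance law", {
  cfg <- sim_config(n_tumour = 150, n_normal = 150, n_mrna = 300,
                    n_lncrna = 10, n_mirna = 10, n_triples = 0,
                    frac_de = 0, nb_dispersion = 0.1,
                    lib_size_range = c(2e6, 2e6), seed = 21)
  d <- simulate_expression(cfg)
  m <- d$rna$counts[sprintf("MRNA%04d", 1:300), ]
  mu <- rowMeans(m); v <- apply(m, 1, var)
  big <- mu > 200  # dispersion dominates Poisson noise
  phi_hat <- median((v[big] - mu[big]) / mu[big]^2)
  expect_gt(phi_hat, 0.07)
  expect_lt(phi_hat, 0.13)
})

test_that("clinical records cover tumour samples only, with valid fields", {
  d <- simulate_dataset(small_cfg(seed = 4))
  tum <- names(d$rna$groups)[d$rna$groups == "tumour"]
  expect_setequal(d$clinical$sample_id, tum)
  expect_true(all(d$clinical$time > 0))
  expect_true(all(d$clinical$event %in% c(0, 1)))

  # censor_rate = 0 -> everyone has an event
  d0 <- simulate_dataset(small_cfg(seed = 4, censor_rate = 0))
  expect_true(all(d0$clinical$event == 1))
})

test_that("a planted hazard of log 2 is recovered by the O/E estimator", {
  # 60 replicates: HR estimate for the planted gene within [1.5, 2.7]
  # in at least 90% of them (200 tumour samples, no censoring)
  ok <- 0L
  for (s in 1:60) {
    cfg <- sim_config(n_tumour = 200, n_normal = 2, n_mrna = 5,
                      n_lncrna = 1, n_mirna = 1, n_triples = 0,
                      frac_de = 0, censor_rate = 0,
                      surv_genes = "MRNA0001", surv_beta = log(2),
                      seed = 300 + s)
    d <- simulate_dataset(cfg)
    lc <- cpm_matrix(d$rna, log = TRUE)
    scr <- suppressMessages(suppressWarnings(
      gene_survival_screen(lc, d$clinical, genes = "MRNA0001")))
    ok <- ok + (scr$HR >= 1.5 && scr$HR <= 2.7)
  }
  expect_gte(ok / 60, 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_tumour = 0), "positive")
  expect_error(sim_config(frac_de = 1.2), "frac_de")
  expect_error(sim_config(triple_strength = 1), "triple_strength")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  bad_truth <- list(triples = list(list(lncrna = "NOPE", mirnas = "MIR0001",
                                        mrna = "MRNA0001")))
  expect_error(simulate_interactions(small_cfg(), bad_truth), "consistency")
  d <- simulate_expression(small_cfg(seed = 1))
  d$truth$surv_effects <- c(GHOST = 0.5)
  expect_error(simulate_clinical(small_cfg(), d$rna, d$truth), "consistency")
})
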