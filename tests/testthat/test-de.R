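make_logcpm <- function(E, groups) {
  expr_matrix(E, log = TRUE, prior_count = 0.5,
              groups = setNames(factor(groups, levels = c("normal", "tumour")),
                                colnames(E)))
}

test_that("variance prior: degenerate and simulated recovery cases", {
  # zero excess spread -> infinite prior df at the common value
  p <- estimate_prior(rep(2, 50), df = 10)
  expect_equal(p$d0, Inf)
  expect_equal(p$s0sq, 2, tolerance = 1e-8)

  expect_error(estimate_prior(3, df = 10), "estimation error")

  # scaled-F simulation with known d0 = 4, s0^2 = 2, 5000 genes
  set.seed(17)
  d0 <- 4; s0sq <- 2; df <- 10
  true_s2 <- s0sq * d0 / rchisq(5000, df = d0)
  s2 <- true_s2 * rchisq(5000, df = df) / df
  p2 <- estimate_prior(s2, df = df)
  expect_gte(p2$d0, 3); expect_lte(p2$d0, 5.5)
  expect_gte(p2$s0sq, 1.8); expect_lte(p2$s0sq, 2.2)
})

test_that("moderated t handles exact and limiting cases", {
  set.seed(5)
  E <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  grp <- rep(c("tumour", "normal"), each = 4)
  # force one gene to have identical group means
  E["g01", ] <- c(1, 2, 3, 4, 4, 3, 2, 1)
  res <- moderated_t(make_logcpm(E, grp))
  r1 <- res[res$gene == "g01", ]
  expect_equal(r1$logFC, 0)
  expect_equal(r1$t, 0)
  expect_equal(r1$P.Value, 1)

  # d0 = 0 limit reproduces the ordinary pooled two-sample t
  res0 <- moderated_t(make_logcpm(E, grp), prior = list(d0 = 0, s0sq = 1))
  ordinary <- apply(E, 1, function(x)
    t.test(x[1:4], x[5:8], var.equal = TRUE)$statistic)
  expect_equal(res0$t, unname(ordinary), tolerance = 1e-10)

  # swap group labels: logFC and t negate, p unchanged
  resw <- moderated_t(make_logcpm(E, rev(grp)))
  expect_equal(resw$logFC, -res$logFC, tolerance = 1e-12)
  expect_equal(resw$P.Value, res$P.Value, tolerance = 1e-12)

  expect_error(moderated_t(make_logcpm(E[, 1:3], grp[1:3])), "2 samples")
})

test_that("moderated t agrees with the limma lmFit/eBayes route", {
  set.seed(23)
  E <- matrix(rnorm(200 * 12, sd = rep(sqrt(0.5 + rchisq(200, 3) / 6), 12)),
              200, 12,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:12)))
  grp <- rep(c("normal", "tumour"), each = 6)
  E[, grp == "tumour"] <- E[, grp == "tumour"] +
    rep(rnorm(200, 0, 1), sum(grp == "tumour"))
  res <- moderated_t(make_logcpm(E, grp))

  design <- model.matrix(~ factor(grp, levels = c("normal", "tumour")))
  fit <- limma::eBayes(limma::lmFit(E, design), trend = FALSE)
  expect_equal(res$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$P.Value, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "usage error")
  # adjusted >= raw, in [0,1]
  set.seed(2); p <- runif(100)^2
  a <- bh_adjust(p)
  expect_true(all(a >= p - 1e-12) && all(a <= 1))
})

test_that("classification matches the published thresholds and is monotone", {
  tab <- data.frame(
    gene = c("SNHG1", "LMNB2", "FANCE", "E2F8", "weakFC", "weakP"),
    logFC = c(1.495397836, 1.115366226, 1.459672439, 3.729047657, 0.9, 1.5),
    P.Value = c(6.43e-18, 5.95e-13, 9.12e-14, 8.89e-27, 1e-10, 0.5),
    adj.P.Val = c(6.43e-18, 5.95e-13, 9.12e-14, 8.89e-27, 1e-10, 0.5))
  cls <- classify_de(tab, fc_threshold = 2, p_threshold = 0.01)
  expect_equal(cls, c("up", "up", "up", "up", "ns", "ns"))

  # monotone: shrinking p or growing |logFC| never demotes a call
  set.seed(3)
  base <- data.frame(logFC = runif(200, -3, 3), P.Value = runif(200),
                     adj.P.Val = runif(200))
  c0 <- classify_de(base)
  better <- transform(base, adj.P.Val = adj.P.Val / 10,
                      logFC = logFC * 1.5)
  c1 <- classify_de(better)
  expect_false(any(c0 %in% c("up", "down") & c1 == "ns"))
})

test_that("volcano table caps -log10 FDR and flags p = 0", {
  res <- data.frame(gene = c("a", "b", "c"), logFC = c(1, -2, 3),
                    P.Value = c(0.01, 1, 0), adj.P.Val = c(0.01, 1, 0),
                    class = c("ns", "ns", "up"))
  v <- volcano_table(res, cap = 300)
  expect_equal(v$neg_log10_fdr, c(2, 0, 300))
  expect_equal(v$capped, c(FALSE, FALSE, TRUE))
})

test_that("null data keep the raw p < 0.01 rate near nominal", {
  # 8 replicate null datasets, 2000 genes, 20+20 samples
  rates <- vapply(1:8, function(s) {
    set.seed(400 + s)
    E <- matrix(rnorm(2000 * 40), 2000, 40,
                dimnames = list(sprintf("g%04d", 1:2000),
                                sprintf("s%02d", 1:40)))
    res <- moderated_t(make_logcpm(E, rep(c("tumour", "normal"), each = 20)))
    mean(res$P.Value < 0.01)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.01), 0.005)
  # BH keeps discoveries at or below nominal under the null
  expect_lt(mean(rates), 0.02)
})
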