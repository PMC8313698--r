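test_that("average logFC follows the de-logged group-mean definition", {
  set.seed(11)
  x_loy <- log1p(rexp(5, 1 / 3)); x_norm <- log1p(rexp(5, 1 / 5))
  x <- c(x_loy, x_norm)
  grp <- rep(c("LOY", "NORMAL"), each = 5)
  # direct arithmetic on the stated formula
  expected <- log(mean(exp(x_loy) - 1) + 1) - log(mean(exp(x_norm) - 1) + 1)
  expect_equal(avg_logfc(x, grp, "RNA"), expected)
  expect_equal(avg_logfc(x, grp == "LOY", "RNA"), expected)
  # ADT: plain difference of CLR means
  expect_equal(avg_logfc(x, grp, "ADT"), mean(x_loy) - mean(x_norm))
  # symmetry and antisymmetry
  expect_equal(avg_logfc(c(x_loy, x_loy),
                         rep(c("LOY", "NORMAL"), each = 5), "RNA"), 0)
  flipped <- rep(c("NORMAL", "LOY"), each = 5)
  expect_equal(avg_logfc(x, flipped, "RNA"), -expected)
  expect_error(avg_logfc(x, rep("LOY", 10), "RNA"), "non-empty")
})

test_that("percent change is the exponential transform of the logFC", {
  expect_equal(pct_from_logfc(0), 0)
  expect_equal(pct_from_logfc(log(2)), 100)
  expect_equal(pct_from_logfc(-0.31), 100 * (exp(-0.31) - 1))
  expect_error(pct_from_logfc(Inf), "finite")
})

test_that("protein LR test handles degenerate analytes and recovers effects", {
  set.seed(12)
  n <- 2000
  grp <- rep(c("LOY", "NORMAL"), c(200, 1800))
  cov <- data.frame(donor = sample(c("D1", "D2"), n, TRUE),
                    n_umi = rnorm(n, 5000, 500))
  # constant analyte carries no information
  out <- protein_lr_test(rep(1.3, n), grp, cov)
  expect_equal(out$p_raw, 1)
  # injected -0.3 CLR shift is detected with the right sign
  x <- rnorm(n, 0, 0.35) - 0.3 * (grp == "LOY")
  out2 <- protein_lr_test(x, grp, cov)
  expect_lt(out2$p_raw, 0.05)
  expect_lt(out2$coefficient, 0)
  # analyte exactly collinear with a covariate: flagged, no test
  expect_warning(out3 <- protein_lr_test(as.numeric(cov$donor == "D1"),
                                         grp, cov), "aliased")
  expect_equal(out3$p_raw, 1)
})

test_that("separation triggers the Firth-penalized fallback", {
  set.seed(13)
  grp <- rep(c("LOY", "NORMAL"), each = 20)
  x <- c(rnorm(20, 3), rnorm(20, -3))  # perfectly separable
  expect_warning(out <- protein_lr_test(x, grp), "Firth")
  expect_true(out$separation)
  expect_true(out$p_raw > 0 && out$p_raw < 0.001)
  expect_gt(out$coefficient, 0)
})

test_that("the protein LR test holds its size under the null", {
  set.seed(14)
  rej <- vapply(1:200, function(i) {
    n <- 400
    grp <- rep(c("LOY", "NORMAL"), c(60, 340))
    x <- rnorm(n)
    protein_lr_test(x, grp)$p_raw < 0.05
  }, logical(1))
  # 99% binomial envelope around 0.05 at 200 reps
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.095)
})

test_that("hurdle test combines detection and continuous channels", {
  set.seed(15)
  n <- 600
  grp <- rep(c("LOY", "NORMAL"), c(150, 450))
  cov <- data.frame(n_umi = rnorm(n, 5000, 300))
  # no zeros: reduces to the continuous part, checked against an lm oracle
  x <- rnorm(n, 2, 0.5) - 0.4 * (grp == "LOY")
  out <- rna_hurdle_test(x, grp, cov)
  expect_equal(out$df_discrete, 0L)
  expect_equal(out$df_continuous, 1L)
  X0 <- cbind(1, cov$n_umi)
  rss0 <- sum(lm.fit(X0, x)$residuals^2)
  rss1 <- sum(lm.fit(cbind(X0, grp == "LOY"), x)$residuals^2)
  expect_equal(out$stat, n * log(rss0 / rss1))
  # detection-only effect: discrete channel carries the signal
  p_det <- ifelse(grp == "LOY", 0.35, 0.7)
  x2 <- ifelse(runif(n) < p_det, rexp(n, 1) + 0.5, 0)
  out2 <- rna_hurdle_test(x2, grp, cov)
  expect_equal(out2$df, 2L)
  expect_lt(out2$p_raw, 0.01)
  # continuous-only test on the same data is blind to it
  pos <- x2 > 0
  rss0 <- sum(lm.fit(X0[pos, ], x2[pos])$residuals^2)
  rss1 <- sum(lm.fit(cbind(X0, grp == "LOY")[pos, ], x2[pos])$residuals^2)
  p_cont <- pchisq(sum(pos) * log(rss0 / rss1), 1, lower.tail = FALSE)
  expect_gt(p_cont, 0.05)
  # all-zero analyte: nothing to test
  expect_warning(out3 <- rna_hurdle_test(rep(0, n), grp, cov),
                 "no estimable")
  expect_equal(out3$p_raw, 1)
})

test_that("BH adjustment matches hand-computed and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(16)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # NA p-values are carried through, not dropped
  p <- c(0.01, NA, 0.04)
  expect_equal(is.na(bh_adjust(p)), is.na(p))
})

test_that("pooled logistic model attributes effects correctly", {
  set.seed(17)
  n <- 3000
  type <- sample(c("B", "NK", "CD4_T"), n, TRUE)
  donor <- sample(paste0("D", 1:4), n, TRUE)
  loy <- rbinom(n, 1, 0.1) == 1
  cov <- data.frame(donor = donor, n_umi = rnorm(n, 5000, 400),
                    pct_mito = runif(n, 1.5, 5), cell_type = type)
  grp <- ifelse(loy, "LOY", "NORMAL")
  # global CD99 reduction in LOY cells: negative z
  x <- rnorm(n, 0, 0.4) - 0.3 * loy
  out <- pooled_overall_test(x, grp, cov, "CD99", "ADT")
  expect_lt(out$z, -2)
  expect_equal(sign(out$z), sign(out$coefficient))
  expect_lt(out$p, 0.05)
  # analyte that is (almost) a donor indicator gets no credit
  x2 <- as.numeric(donor == "D1") + rnorm(n, 0, 1e-3)
  out2 <- pooled_overall_test(x2, grp, cov, "CD99", "ADT")
  expect_lt(abs(out2$z), 2.5)
  # exact collinearity is refused outright
  expect_error(pooled_overall_test(as.numeric(donor == "D1"), grp, cov),
               "aliased")
})

test_that("null pooled analyte rarely looks significant", {
  set.seed(18)
  z <- vapply(1:100, function(i) {
    n <- 500
    loy <- rbinom(n, 1, 0.12) == 1
    cov <- data.frame(n_umi = rnorm(n, 5000, 400))
    pooled_overall_test(rnorm(n), ifelse(loy, "LOY", "NORMAL"), cov)$z
  }, numeric(1))
  expect_gte(mean(abs(z) < 1.96), 0.88)
})

test_that("the differential table obeys its internal identities", {
  sim <- simulate_citeseq(fast_cfg(n_cells_per_donor = 1000, seed = 22))
  res <- quiet_analyze(sim$rna, sim$adt, sim$sheet)
  tab <- res$differential
  expect_equal(nrow(tab), 24)
  expect_setequal(tab$assay, c("RNA", "ADT"))
  ok <- !is.na(tab$avg_logfc)
  expect_true(all(abs(tab$pct_change[ok] -
                        100 * (exp(tab$avg_logfc[ok]) - 1)) < 1e-9))
  expect_true(all(tab$p_adj[ok] >= tab$p_raw[ok] - 1e-12, na.rm = TRUE))
  expect_equal(tab$p_adj, bh_oracle_with_na(tab$p_raw))
})
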