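test_that("the seed fixes the entire dataset", {
  s1 <- simulate_citeseq(fast_cfg(n_cells_per_donor = 100, seed = 31))
  s2 <- simulate_citeseq(fast_cfg(n_cells_per_donor = 100, seed = 31))
  expect_identical(as.matrix(s1$rna$values), as.matrix(s2$rna$values))
  expect_identical(as.matrix(s1$adt$values), as.matrix(s2$adt$values))
  expect_identical(s1$sheet, s2$sheet)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_citeseq(fast_cfg(n_cells_per_donor = 100, seed = 32))
  expect_false(identical(as.matrix(s1$rna$values),
                         as.matrix(s3$rna$values)))
  # schema is stable across seeds
  expect_identical(feature_ids(s1$rna), feature_ids(s3$rna))
  expect_identical(feature_ids(s1$adt), feature_ids(s3$adt))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(type_proportions = c(B = 0.5, NK = 0.4)),
               "sum to 1")
  expect_error(simulation_config(msy_dropout = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(msy_gene_count = 40), "msy_gene_count")
})

test_that("zero LOY fractions generate no LOY cells", {
  cfg <- fast_cfg(n_cells_per_donor = 100, seed = 33,
                  loy_fraction_per_type = c(B = 0, CD14_mono = 0,
                                            CD16_mono = 0, NK = 0,
                                            CD8_T = 0, CD4_T = 0, OTHER = 0))
  sim <- simulate_citeseq(cfg)
  expect_false(any(sim$truth$true_loy))
})

test_that("realized LOY fractions track the configured study percentages", {
  cfg <- fast_cfg(n_cells_per_donor = 1250, seed = 34)
  sim <- simulate_citeseq(cfg)
  tab <- table(sim$truth$true_type)
  for (ct in c("B", "CD14_mono", "CD16_mono", "NK", "CD8_T", "CD4_T")) {
    p <- cfg$loy_fraction_per_type[[ct]]
    n <- tab[[ct]]
    realized <- mean(sim$truth$true_loy[sim$truth$true_type == ct])
    expect_lt(abs(realized - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("normal cells always carry MSY transcripts at zero dropout", {
  sim <- simulate_citeseq(fast_cfg(n_cells_per_donor = 1000, seed = 35))
  msy <- gene_sets(default_gene_annotation())$msy
  msy_tot <- Matrix::colSums(
    sim$rna$values[intersect(msy, feature_ids(sim$rna)), ])
  expect_true(all(msy_tot[!sim$truth$true_loy] > 0))
  expect_true(all(msy_tot[sim$truth$true_loy] == 0))
})

test_that("false-LOY rate rises with dropout and falls with depth", {
  rate <- function(dropout, meanlog) {
    cfg <- simulation_config(
      n_cells_per_donor = 750, n_background_genes = 50, doublet_rate = 0,
      msy_dropout = dropout, seed = 36,
      depth_lognormal_params = c(meanlog = meanlog, sdlog = 0.3))
    sim <- simulate_citeseq(cfg)
    calls <- suppressMessages(suppressWarnings(
      call_loy(sim$rna, gene_sets(default_gene_annotation()))))
    normal <- !sim$truth$true_loy
    mean(calls$status[normal] == "LOY")
  }
  grid <- expand.grid(dropout = c(0, 0.5, 0.9),
                      meanlog = log(c(2500, 6000, 15000)))
  grid$rate <- mapply(rate, grid$dropout, grid$meanlog)
  for (ml in unique(grid$meanlog)) {
    r <- grid$rate[grid$meanlog == ml]
    expect_true(all(diff(r) >= 0))       # monotone in dropout
  }
  for (d in unique(grid$dropout)) {
    r <- grid$rate[grid$dropout == d]
    expect_true(all(diff(r) <= 0))       # monotone (down) in depth
  }
  expect_equal(grid$rate[grid$dropout == 0], rep(0, 3))
  expect_gt(max(grid$rate), 0.1)
})

test_that("injected CD99 effects are realized on the estimator scale", {
  cfg <- fast_cfg(n_cells_per_donor = 4000, seed = 37)
  sim <- simulate_citeseq(cfg)
  clr <- clr_normalize(sim$adt)
  tt <- sim$truth
  b <- tt$true_type == "B"
  est <- mean(clr$values["CD99", b & tt$true_loy]) -
    mean(clr$values["CD99", b & !tt$true_loy])
  expect_lt(abs(est - cfg$adt_effects[["B"]]), 0.07)
  # null integrity: the lineage-marker ADT is unaffected by LOY
  nk <- tt$true_type == "NK"
  null_diff <- mean(clr$values["CD56", nk & tt$true_loy]) -
    mean(clr$values["CD56", nk & !tt$true_loy])
  expect_lt(abs(null_diff), 0.06)
})

test_that("QC rejects a realistic minority, enriched for doublets", {
  cfg <- simulation_config(n_cells_per_donor = 750, doublet_rate = 0.05,
                           seed = 38)
  sim <- simulate_citeseq(cfg)
  qc <- apply_qc(compute_qc(sim$rna))
  fail_frac <- mean(!qc$kept[!sim$truth$is_doublet])
  expect_gt(fail_frac, 0.03)
  expect_lt(fail_frac, 0.30)
  gene_reject <- !is.na(qc$rejection_reason) & qc$rejection_reason == "genes"
  r_doublet <- mean(gene_reject[sim$truth$is_doublet])
  r_singlet <- mean(gene_reject[!sim$truth$is_doublet])
  expect_gt(r_doublet, 2 * r_singlet)
})

test_that("fixtures round-trip through the 10x reader", {
  sim <- simulate_citeseq(simulation_config(
    n_cells_per_donor = 40, seed = 39, n_background_genes = 60,
    doublet_rate = 0))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir, gzip = TRUE)
  rna <- read_10x(file.path(dir, "rna"), assay = "RNA")
  adt <- read_10x(file.path(dir, "adt"), assay = "ADT")
  expect_equal(as.matrix(rna$values), as.matrix(sim$rna$values))
  expect_equal(as.matrix(adt$values), as.matrix(sim$adt$values))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), ncol(sim$rna$values))
  sheet <- read_sample_sheet(file.path(dir, "samples.csv"))
  expect_setequal(sheet$barcode, barcodes(rna))
  expect_true(file.exists(file.path(dir, "config.txt")))
})
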