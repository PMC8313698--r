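test_that("the LOY rule is absence of MSY with autosomal evidence", {
  sets <- gene_sets(toy_annotation())
  v <- matrix(0, 6, 3,
              dimnames = list(c("RPS4Y1", "DDX3Y", "EIF1AY", "CD99",
                                "A1", "A2"),
                              c("loy", "normal", "undet")))
  v["A1", "loy"] <- 3000
  v["CD99", "loy"] <- 5          # PAR counts must not rescue a LOY call
  v["RPS4Y1", "normal"] <- 1
  calls <- suppressMessages(call_loy(count_matrix(v, assay = "RNA"), sets))
  expect_equal(calls$status, c("LOY", "NORMAL", "UNDETERMINED"))
  expect_equal(calls$msy_umi, c(0L, 1L, 0L))
})

test_that("an empty MSY set is a configuration error", {
  sets <- gene_sets(toy_annotation())
  sets$msy <- character(0)
  m <- random_counts(5, 3)
  expect_error(call_loy(m, sets), "MSY")
})

test_that("calls equal a dense brute-force classification on random cells", {
  set.seed(8)
  ann <- toy_annotation()
  sets <- gene_sets(ann)
  m <- random_counts(15, 1000, lambda = 0.05,
                     genes = ann$symbol)
  calls <- suppressMessages(call_loy(m, sets))
  dense <- as.matrix(m$values)
  msy_sum <- colSums(dense[sets$msy, ])
  auto_sum <- colSums(dense[setdiff(rownames(dense),
                                    c(sets$msy, sets$par, sets$x_nonpar)), ])
  oracle <- ifelse(msy_sum > 0, "NORMAL",
                   ifelse(auto_sum > 0, "LOY", "UNDETERMINED"))
  expect_equal(calls$status, unname(oracle))
  expect_equal(calls$msy_umi, unname(as.integer(msy_sum)))
  # determinism: no RNG involvement
  expect_identical(calls, suppressMessages(call_loy(m, sets)))
})

test_that("LOY frequencies are direct per-type proportions with Wilson CIs", {
  calls <- data.frame(barcode = sprintf("c%04d", 1:1500),
                      msy_umi = rep(c(0L, 1L), c(70, 1430)),
                      autosomal_umi = 100L,
                      status = rep(c("LOY", "NORMAL"), c(70, 1430)))
  # 56 LOY B cells among 1000 reconstructs the 5.6% B-cell frequency
  types <- c(rep("B", 56), rep("NK", 14), rep("B", 944), rep("NK", 486))
  freq <- loy_frequencies(calls, types)
  b <- freq[freq$cell_type == "B", ]
  expect_equal(b$n_cells, 1000)
  expect_equal(b$pct_loy, 5.6)
  # counting oracle on a shuffled copy
  set.seed(9)
  perm <- sample(nrow(calls))
  freq2 <- loy_frequencies(calls[perm, ], types[perm])
  expect_equal(freq2[order(freq2$cell_type), ],
               freq[order(freq$cell_type), ], ignore_attr = TRUE)
})

test_that("zero LOY gives 0% with CI lower bound 0", {
  calls <- data.frame(barcode = sprintf("c%d", 1:50), msy_umi = 1L,
                      autosomal_umi = 10L, status = "NORMAL")
  freq <- loy_frequencies(calls, rep("NK", 50))
  expect_equal(freq$pct_loy, 0)
  expect_equal(freq$ci_lo, 0)
  expect_gt(freq$ci_hi, 0)
})

test_that("UNDETERMINED calls are refused by the tabulator", {
  calls <- data.frame(barcode = "c1", msy_umi = 0L, autosomal_umi = 0L,
                      status = "UNDETERMINED")
  expect_error(loy_frequencies(calls, "B"), "UNDETERMINED")
})
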