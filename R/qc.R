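#' @name qc_filter
#' @title Per-cell quality control
#'
#' @description
#' Three per-cell criteria on the RNA assay: an upper bound on the number of
#' expressed genes (droplets with unusually many genes are likely doublets),
#' a lower bound on total UMI counts (dead or low-quality cells), and a
#' closed window on the percentage of mitochondrial counts. Defaults:
#' at most 2000 expressed genes, at least 2500 UMI, 1.5-5% mitochondrial
#' content, all boundaries inclusive on the kept side except the gene bound
#' ("more than 2000" is excluded, so exactly 2000 is kept).
NULL

#' Compute per-cell QC metrics
#'
#' @param m RNA [count_matrix()].
#' @param mito_symbols Symbols of mitochondrial genes; default is every
#'   feature whose symbol starts with `"MT-"`.
#' @return Data frame with columns `barcode`, `n_genes`, `n_umi`, `pct_mito`
#'   (0-100 scale; defined as 0 for an all-zero cell).
#' @export
compute_qc <- function(m, mito_symbols = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$assay != "RNA") stop("QC input error: RNA assay required")
  if (is.null(mito_symbols))
    mito_symbols <- grep("^MT-", feature_ids(m), value = TRUE)
  v <- m$values
  n_umi <- .colsums(v)
  n_genes <- .colsums(v > 0)
  mito <- intersect(mito_symbols, feature_ids(m))
  mito_umi <- if (length(mito) > 0) .colsums(v[mito, , drop = FALSE]) else
    rep(0, ncol(v))
  pct_mito <- ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0)
  data.frame(barcode = barcodes(m), n_genes = as.integer(n_genes),
             n_umi = as.integer(n_umi), pct_mito = pct_mito,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' QC thresholds
#'
#' @param max_genes Cells with more expressed genes are rejected.
#' @param min_umi Minimum total UMI count required.
#' @param mito_lo,mito_hi Closed mitochondrial-percentage window (0-100
#'   scale).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_genes = 2000, min_umi = 2500,
                          mito_lo = 1.5, mito_hi = 5.0) {
  if (mito_lo > mito_hi)
    stop("QC configuration error: mito_lo > mito_hi")
  structure(list(max_genes = max_genes, min_umi = min_umi,
                 mito_lo = mito_lo, mito_hi = mito_hi),
            class = "qc_thresholds")
}

#' Apply the QC criteria
#'
#' A cell is kept iff `n_genes <= max_genes`, `n_umi >= min_umi` and
#' `mito_lo <= pct_mito <= mito_hi`. Rejected cells carry the first failing
#' criterion in the fixed order genes, umi, mito.
#'
#' @param metrics Output of [compute_qc()].
#' @param thresholds A [qc_thresholds()] object.
#' @return `metrics` with added logical `kept` and character
#'   `rejection_reason` (`NA` for kept cells).
#' @export
apply_qc <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"),
            all(c("n_genes", "n_umi", "pct_mito") %in% names(metrics)))
  fail_genes <- metrics$n_genes > thresholds$max_genes
  fail_umi <- metrics$n_umi < thresholds$min_umi
  fail_mito <- metrics$pct_mito < thresholds$mito_lo |
    metrics$pct_mito > thresholds$mito_hi
  reason <- rep(NA_character_, nrow(metrics))
  reason[fail_mito] <- "mito"
  reason[fail_umi] <- "umi"
  reason[fail_genes] <- "genes"
  metrics$kept <- !(fail_genes | fail_umi | fail_mito)
  metrics$rejection_reason <- reason
  metrics
}
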