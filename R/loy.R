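#' @name loy_caller
#' @title LOY calling from MSY transcript absence
#'
#' @description
#' A cell is classified as LOY when it expresses autosomal genes but carries
#' no transcript from the male-specific region of chromosome Y (MSY). The
#' rule is applied to raw counts - presence or absence of transcripts is a
#' count-level statement - and PAR genes (notably CD99) are excluded from the
#' MSY sum because their X-linked copy is retained in LOY cells and would
#' mask the signal. Cells with neither MSY nor autosomal counts are
#' `UNDETERMINED` and excluded downstream; after QC they should not occur.
NULL

#' Call LOY status per cell
#'
#' @param m RNA [count_matrix()] of raw counts.
#' @param sets Output of [gene_sets()]. MSY genes are those of `sets$msy`
#'   present in the matrix; every feature outside the `msy`, `par` and
#'   `x_nonpar` sets counts towards the autosomal sum (features absent from
#'   the annotation are treated as autosomal).
#' @return Data frame with columns `barcode`, `msy_umi`, `autosomal_umi`,
#'   `status` (`"LOY"`, `"NORMAL"` or `"UNDETERMINED"`).
#' @export
call_loy <- function(m, sets) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$assay != "RNA") stop("LOY input error: RNA assay required")
  feats <- feature_ids(m)
  msy <- intersect(sets$msy, feats)
  if (length(sets$msy) == 0 || length(msy) == 0)
    stop("LOY configuration error: no MSY genes present; ",
         "LOY is undefined without an MSY gene set")
  non_autosomal <- unique(c(sets$msy, sets$par, sets$x_nonpar))
  autosomal <- setdiff(feats, non_autosomal)
  v <- m$values
  msy_umi <- .colsums(v[msy, , drop = FALSE])
  autosomal_umi <- if (length(autosomal) > 0)
    .colsums(v[autosomal, , drop = FALSE]) else rep(0, ncol(v))
  status <- ifelse(msy_umi > 0, "NORMAL",
                   ifelse(autosomal_umi > 0, "LOY", "UNDETERMINED"))
  message(sprintf("LOY calls: %d LOY, %d NORMAL, %d UNDETERMINED (%d cells)",
                  sum(status == "LOY"), sum(status == "NORMAL"),
                  sum(status == "UNDETERMINED"), length(status)))
  data.frame(barcode = barcodes(m), msy_umi = as.integer(msy_umi),
             autosomal_umi = as.integer(autosomal_umi), status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Wilson score interval for a binomial proportion (no continuity correction)
.wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' LOY frequency per cell type
#'
#' @param calls Output of [call_loy()]; no `UNDETERMINED` calls allowed.
#' @param types Cell-type label per cell: either a vector parallel to
#'   `calls`, or named by barcode.
#' @return Data frame with columns `cell_type`, `n_cells`, `n_loy`,
#'   `pct_loy` and the Wilson 95% interval `ci_lo`, `ci_hi` (percent scale).
#' @export
loy_frequencies <- function(calls, types) {
  if (any(calls$status == "UNDETERMINED"))
    stop("LOY input error: UNDETERMINED calls must be removed before ",
         "tabulating frequencies")
  if (is.factor(types)) {
    empty <- setdiff(levels(types), unique(as.character(types)))
    if (length(empty) > 0)
      warning("empty cell-type group(s) omitted: ",
              paste(empty, collapse = ", "), call. = FALSE)
    types <- as.character(types)
  }
  if (!is.null(names(types))) types <- types[calls$barcode]
  if (length(types) != nrow(calls) || anyNA(types))
    stop("LOY input error: every call needs a cell-type label")
  out <- lapply(unique(types), function(ct) {
    idx <- types == ct
    n <- sum(idx)
    x <- sum(calls$status[idx] == "LOY")
    ci <- .wilson_ci(x, n)
    data.frame(cell_type = ct, n_cells = n, n_loy = x,
               pct_loy = 100 * x / n, ci_lo = 100 * ci[["lo"]],
               ci_hi = 100 * ci[["hi"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
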