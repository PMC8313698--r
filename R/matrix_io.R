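#' @name matrix_io
#' @title Count-matrix containers and 10x-dialect I/O
#'
#' @description
#' RNA and ADT counts are held as sparse features-by-cells integer matrices
#' (`count_matrix` objects) and serialized in the 10x Genomics triple dialect:
#' a MatrixMarket coordinate file plus `features.tsv` and `barcodes.tsv`
#' (optionally gzip-compressed). RNA and ADT are always two separate matrices
#' sharing barcodes; they are never concatenated into one feature space
#' because different normalizations apply.
NULL

#' Default ADT antibody panel
#'
#' The seven surface proteins measured by the assay: the PAR-encoded CD99 and
#' six lineage markers encoded by autosomal genes.
#'
#' @return Character vector of protein names.
#' @export
adt_panel <- function() c("CD99", "CD19", "CD14", "CD16", "CD56", "CD8", "CD4")

#' Construct a sparse count matrix
#'
#' @param values Features-by-cells matrix of non-negative integer counts
#'   (dense or any `Matrix` sparse class; stored as `dgCMatrix`).
#' @param feature_ids Feature symbols (defaults to `rownames(values)`).
#' @param barcodes Cell barcodes (defaults to `colnames(values)`).
#' @param assay `"RNA"` or `"ADT"`.
#' @return A `count_matrix` object: a list with elements `values`, `assay`.
#' @export
count_matrix <- function(values, feature_ids = rownames(values),
                         barcodes = colnames(values),
                         assay = c("RNA", "ADT")) {
  assay <- match.arg(assay)
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(feature_ids) || is.null(barcodes))
    stop("count matrix input error: feature_ids and barcodes are required")
  if (length(feature_ids) != nrow(values) || length(barcodes) != ncol(values))
    stop("count matrix format error: dimension mismatch between matrix (",
         nrow(values), " x ", ncol(values), ") and feature/barcode lists (",
         length(feature_ids), ", ", length(barcodes), ")")
  if (length(values@x) > 0) {
    if (any(values@x < 0))
      stop("count matrix format error: negative entries")
    if (any(values@x != round(values@x)))
      stop("count matrix format error: non-integer entries")
  }
  if (anyDuplicated(feature_ids))
    stop("count matrix input error: duplicate feature ids")
  if (anyDuplicated(barcodes))
    stop("count matrix input error: duplicate barcodes")
  dimnames(values) <- list(as.character(feature_ids), as.character(barcodes))
  structure(list(values = values, assay = assay), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s assay: %d features x %d cells, %d nonzero\n",
              x$assay, nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' Feature ids of a count or normalized matrix
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Character vector.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Cell barcodes of a count or normalized matrix
#' @param x A `count_matrix` or `normalized_matrix`.
#' @return Character vector.
#' @export
barcodes <- function(x) colnames(x$values)

.open_maybe_gz <- function(dir, base) {
  plain <- file.path(dir, base)
  gz <- paste0(plain, ".gz")
  if (file.exists(plain)) plain else if (file.exists(gz)) gz else NA_character_
}

.read_tsv_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  read.delim(con, header = FALSE, stringsAsFactors = FALSE, quote = "",
             blank.lines.skip = FALSE)
}

#' Read a 10x-dialect count directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped. Features files may have one column (symbol) or
#' the 10x v3 layout (id, symbol, type); the symbol column is used when
#' present.
#'
#' @param dir Directory path.
#' @param assay `"RNA"` or `"ADT"`.
#' @return A [count_matrix()].
#' @export
read_10x <- function(dir, assay = c("RNA", "ADT")) {
  assay <- match.arg(assay)
  if (!dir.exists(dir)) stop("10x input error: no such directory: ", dir)
  mtx <- .open_maybe_gz(dir, "matrix.mtx")
  feat <- .open_maybe_gz(dir, "features.tsv")
  if (is.na(feat)) feat <- .open_maybe_gz(dir, "genes.tsv")
  bc <- .open_maybe_gz(dir, "barcodes.tsv")
  if (is.na(mtx) || is.na(feat) || is.na(bc))
    stop("10x format error: directory must contain matrix.mtx, ",
         "features.tsv (or genes.tsv) and barcodes.tsv (optionally .gz)")
  if (grepl("\\.gz$", mtx)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(readLines(gzfile(mtx)), tmp)
    mtx <- tmp
  }
  m <- Matrix::readMM(mtx)
  features <- .read_tsv_lines(feat)
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  bcs <- .read_tsv_lines(bc)[[1]]
  if (nrow(m) != length(symbols))
    stop("10x format error: matrix declares ", nrow(m), " features but ",
         "features file has ", length(symbols), " rows")
  if (ncol(m) != length(bcs))
    stop("10x format error: matrix declares ", ncol(m), " cells but ",
         "barcodes file has ", length(bcs), " rows")
  count_matrix(m, feature_ids = symbols, barcodes = bcs, assay = assay)
}

#' Write a count matrix in the 10x dialect
#'
#' Emits `matrix.mtx` (MatrixMarket `coordinate integer general`, 1-based
#' indices), `features.tsv` and `barcodes.tsv` so that [read_10x()] recovers
#' the matrix exactly.
#'
#' @param x A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the three files.
#' @return Invisibly, the directory path.
#' @export
write_10x <- function(x, dir, gzip = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("10x I/O error: cannot create directory ", dir)
  v <- x$values
  ijx <- Matrix::summary(v)  # 1-based triplets
  ext <- if (gzip) ".gz" else ""
  open_out <- function(base) {
    p <- file.path(dir, paste0(base, ext))
    if (gzip) gzfile(p, "wt") else file(p, "wt")
  }
  con <- open_out("matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(v), ncol(v), nrow(ijx))), con)
  write.table(data.frame(ijx$i, ijx$j, as.integer(ijx$x)), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE, sep = " ")
  close(con)
  con <- open_out("features.tsv")
  fid <- feature_ids(x)
  ftype <- if (x$assay == "ADT") "Antibody Capture" else "Gene Expression"
  write.table(data.frame(fid, fid, ftype), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE, sep = "\t")
  close(con)
  con <- open_out("barcodes.tsv")
  writeLines(barcodes(x), con)
  close(con)
  invisible(dir)
}

#' Read a per-cell sample sheet
#'
#' CSV with columns `barcode`, `donor`, `library_prep_batch`,
#' `sequencing_batch`.
#'
#' @param path CSV path.
#' @return Data frame with the four columns as character.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("barcode", "donor", "library_prep_batch", "sequencing_batch")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0)
    stop("sample sheet format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$barcode))
    stop("sample sheet input error: duplicate barcodes")
  sheet[required]
}

#' Pool count matrices and sample sheets from several samples
#'
#' Barcodes are suffixed with `-<sample index>` so pooled barcodes are unique
#' even when the same droplet barcode occurs in two samples. Feature panels
#' must be identical (same symbols, same order) across samples.
#'
#' @param matrices List of [count_matrix()] objects of one assay.
#' @param sheets List of sample sheets parallel to `matrices`.
#' @return List with elements `matrix` (pooled `count_matrix`) and `sheet`
#'   (pooled data frame).
#' @export
merge_samples <- function(matrices, sheets) {
  stopifnot(length(matrices) >= 1, length(matrices) == length(sheets))
  ref <- feature_ids(matrices[[1]])
  assay <- matrices[[1]]$assay
  for (m in matrices[-1]) {
    if (!identical(feature_ids(m), ref))
      stop("merge input error: feature panels differ across samples")
    if (!identical(m$assay, assay))
      stop("merge input error: assays differ across samples")
  }
  pooled_vals <- vector("list", length(matrices))
  pooled_sheets <- vector("list", length(matrices))
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    sheet <- sheets[[s]]
    if (!setequal(sheet$barcode, barcodes(m)))
      stop("merge input error: sample ", s,
           " sheet barcodes do not match matrix barcodes")
    sheet <- sheet[match(barcodes(m), sheet$barcode), , drop = FALSE]
    new_bc <- paste0(barcodes(m), "-", s)
    v <- m$values
    colnames(v) <- new_bc
    sheet$barcode <- new_bc
    pooled_vals[[s]] <- v
    pooled_sheets[[s]] <- sheet
  }
  pooled <- do.call(cbind, pooled_vals)
  sheet <- do.call(rbind, pooled_sheets)
  rownames(sheet) <- NULL
  list(matrix = count_matrix(pooled, assay = assay), sheet = sheet)
}
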