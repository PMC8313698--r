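#' @name annotation
#' @title Gene-region annotation: MSY, PAR, X and autosomes
#'
#' @description
#' The LOY caller needs to know which gene symbols lie in the male-specific
#' region of chromosome Y (MSY) and which are pseudoautosomal (PAR). PAR genes
#' such as CD99 sit on both X and Y; their X-linked copy is retained in LOY
#' cells, so they must never contribute to the MSY transcript sum that defines
#' a LOY call. The annotation is a static, versioned table shipped with the
#' package; no live genome-database queries are performed.
NULL

.REGION_CLASSES <- c("MSY", "PAR", "X_nonPAR", "AUTOSOME")

#' Read a gene-region annotation table
#'
#' Reads a tab-delimited annotation with header columns `symbol`,
#' `chromosome` and `region_class` (one of `MSY`, `PAR`, `X_nonPAR`,
#' `AUTOSOME`). MSY entries must be on chromosome Y and PAR entries must be
#' flagged as present on both X and Y (e.g. chromosome `"X;Y"`).
#'
#' @param path Path to the TSV file.
#' @return A `gene_annotation` data frame with one row per symbol.
#' @seealso [default_gene_annotation()] for the table shipped with the
#'   package, [gene_sets()] for the derived symbol sets.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8")
  gene_annotation(tab)
}

#' Construct and validate a gene annotation
#'
#' @param tab Data frame with columns `symbol`, `chromosome`, `region_class`.
#' @return The validated data frame with class `gene_annotation`.
#' @export
gene_annotation <- function(tab) {
  required <- c("symbol", "chromosome", "region_class")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("annotation format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) stop("annotation input error: table is empty")
  tab <- tab[required]
  tab$symbol <- as.character(tab$symbol)
  tab$chromosome <- as.character(tab$chromosome)
  tab$region_class <- as.character(tab$region_class)
  dup <- unique(tab$symbol[duplicated(tab$symbol)])
  if (length(dup) > 0)
    stop("annotation input error: duplicate symbol(s): ",
         paste(head(dup, 5), collapse = ", "))
  bad <- setdiff(unique(tab$region_class), .REGION_CLASSES)
  if (length(bad) > 0)
    stop("annotation format error: unknown region_class value(s): ",
         paste(bad, collapse = ", "))
  msy_off_y <- tab$region_class == "MSY" & tab$chromosome != "Y"
  if (any(msy_off_y))
    stop("annotation input error: MSY gene(s) not on chromosome Y: ",
         paste(tab$symbol[msy_off_y], collapse = ", "))
  par_bad <- tab$region_class == "PAR" &
    !(grepl("X", tab$chromosome) & grepl("Y", tab$chromosome))
  if (any(par_bad))
    stop("annotation input error: PAR gene(s) must be flagged on both X ",
         "and Y: ", paste(tab$symbol[par_bad], collapse = ", "))
  class(tab) <- c("gene_annotation", "data.frame")
  tab
}

#' Annotation table shipped with the package
#'
#' Expressed MSY genes, PAR1 genes (including CD99), the mitochondrial
#' protein-coding genes and common marker genes, frozen from a fixed genome
#' annotation release.
#'
#' @return A `gene_annotation` data frame.
#' @export
default_gene_annotation <- function() {
  read_gene_annotation(system.file("extdata", "gene_annotation.tsv",
                                   package = "loycite", mustWork = TRUE))
}

#' Derive the region symbol sets from an annotation
#'
#' @param ann A `gene_annotation`.
#' @return A list with character vectors `msy`, `par`, `x_nonpar` and
#'   `autosomal`. The four sets are pairwise disjoint and jointly cover every
#'   annotated symbol; PAR symbols never appear in `msy`.
#' @export
gene_sets <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  list(
    msy = ann$symbol[ann$region_class == "MSY"],
    par = ann$symbol[ann$region_class == "PAR"],
    x_nonpar = ann$symbol[ann$region_class == "X_nonPAR"],
    autosomal = ann$symbol[ann$region_class == "AUTOSOME"]
  )
}

#' Resolve feature symbols to region classes
#'
#' Symbols absent from the annotation are classified `AUTOSOME` with a single
#' consolidated warning, so feature files containing symbols outside the
#' frozen table still process.
#'
#' @param symbols Character vector of feature symbols.
#' @param ann A `gene_annotation`.
#' @return Named character vector of region classes, parallel to `symbols`.
#' @export
resolve_region <- function(symbols, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  idx <- match(symbols, ann$symbol)
  out <- ann$region_class[idx]
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    warning(n_missing, " feature symbol(s) not in the annotation; ",
            "classified as AUTOSOME", call. = FALSE)
    out[is.na(idx)] <- "AUTOSOME"
  }
  names(out) <- symbols
  out
}
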