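#' @name normalize
#' @title RNA log-normalization, ADT centered log-ratio, display scaling
#'
#' @description
#' RNA counts are normalized per cell to a fixed scale factor and
#' log-transformed: `value = ln(1 + count * scale_factor / total)`. ADT
#' counts are treated as compositional within the per-cell antibody panel and
#' normalized with the centered log-ratio: `value = ln(1 + count) - mean_j
#' ln(1 + count_j)` across the panel (per-cell margin by default; the
#' per-feature-across-cells convention is available via `margin`). A 0-1
#' min-max scaling per cell-type group is provided for display only and never
#' feeds the statistics. Natural logarithms throughout.
NULL

#' Construct a normalized matrix
#'
#' @param values Real-valued features-by-cells matrix (sparse or dense) with
#'   dimnames.
#' @param assay `"RNA"` or `"ADT"`.
#' @param method `"LOG_SF"`, `"CLR"` or `"MINMAX"`.
#' @return A `normalized_matrix` object.
#' @export
normalized_matrix <- function(values, assay = c("RNA", "ADT"),
                              method = c("LOG_SF", "CLR", "MINMAX")) {
  assay <- match.arg(assay)
  method <- match.arg(method)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("normalized matrix input error: dimnames required")
  structure(list(values = values, assay = assay, method = method),
            class = "normalized_matrix")
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %s/%s: %d features x %d cells\n",
              x$assay, x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Log-normalize RNA counts to a fixed scale factor
#'
#' `value(g, c) = ln(1 + count(g, c) * scale_factor / n_umi(c))`. Zeros map
#' to zero, so sparsity is preserved.
#'
#' @param m RNA [count_matrix()].
#' @param scale_factor Positive scale factor (default 10,000).
#' @return A `normalized_matrix` with method `LOG_SF`.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$assay != "RNA") stop("normalization input error: RNA assay required")
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("normalization configuration error: scale_factor must be positive")
  v <- m$values
  totals <- .colsums(v)
  if (any(totals == 0))
    stop("normalization input error: cell(s) with zero total count; ",
         "apply QC first")
  # map each stored nonzero to its column total
  col_of_x <- rep.int(seq_len(ncol(v)), diff(v@p))
  v@x <- log1p(v@x * scale_factor / totals[col_of_x])
  normalized_matrix(v, assay = "RNA", method = "LOG_SF")
}

#' Centered log-ratio normalization of ADT counts
#'
#' @param m ADT [count_matrix()] with at least 2 proteins.
#' @param margin `"cell"` (default): center `ln(1 + x)` across the protein
#'   panel within each cell; `"feature"`: center across cells within each
#'   protein.
#' @return A `normalized_matrix` with method `CLR` (dense).
#' @export
clr_normalize <- function(m, margin = c("cell", "feature")) {
  stopifnot(inherits(m, "count_matrix"))
  margin <- match.arg(margin)
  if (m$assay != "ADT") stop("normalization input error: ADT assay required")
  if (nrow(m$values) < 2)
    stop("normalization configuration error: CLR is degenerate for a ",
         "single-protein panel")
  lv <- log1p(as.matrix(m$values))
  v <- if (margin == "cell") {
    sweep(lv, 2L, colMeans(lv), "-")
  } else {
    sweep(lv, 1L, rowMeans(lv), "-")
  }
  normalized_matrix(v, assay = "ADT", method = "CLR")
}

#' Min-max scale values to \[0, 1\] within groups
#'
#' Display-only linear adjustment: `(x - min) / (max - min)` within each
#' group. A constant group maps to all zeros with a warning.
#'
#' @param x Numeric vector of per-cell analyte values.
#' @param group Grouping labels (e.g. cell types), same length as `x`.
#' @return Numeric vector in `[0, 1]`, same order as `x`.
#' @export
minmax_scale <- function(x, group) {
  stopifnot(length(x) == length(group))
  out <- numeric(length(x))
  constant_groups <- character(0)
  for (g in unique(group)) {
    idx <- which(group == g)
    rng <- range(x[idx])
    if (rng[1] == rng[2]) {
      out[idx] <- 0
      constant_groups <- c(constant_groups, as.character(g))
    } else {
      out[idx] <- (x[idx] - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (length(constant_groups) > 0)
    warning("constant group(s) mapped to 0 in min-max scaling: ",
            paste(constant_groups, collapse = ", "), call. = FALSE)
  out
}
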