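#' @name cell_typing
#' @title Marker-based leukocyte typing from ADT evidence
#'
#' @description
#' Each of the six targeted leukocyte types has one diagnostic surface
#' marker: CD19 (B cells), CD14 (classical monocytes), CD16 (non-classical
#' monocytes), CD56 (NK cells), CD8 (CD8 T cells) and CD4 (CD4 T cells).
#' A cell is assigned the type of its highest CLR-normalized marker when that
#' marker is positive and clears the runner-up by a margin; otherwise the
#' cell is `OTHER`. CD99 is pan-leukocyte and is never a typing marker. The
#' one exception to the margin rule is the CD14/CD16 pair: monocytes often
#' carry both, so a cell whose top two markers are CD14 and CD16 is resolved
#' by the larger value.
NULL

#' Default marker-to-type panel
#'
#' @return Named character vector mapping marker protein to cell-type label.
#' @export
marker_panel <- function() {
  c(CD19 = "B", CD14 = "CD14_mono", CD16 = "CD16_mono",
    CD56 = "NK", CD8 = "CD8_T", CD4 = "CD4_T")
}

#' Assign a leukocyte type to each cell
#'
#' @param adt_clr CLR-normalized ADT `normalized_matrix`.
#' @param panel Marker panel, as from [marker_panel()].
#' @param margin Minimum CLR gap between top and second marker (default 0.5).
#' @return Data frame with columns `barcode`, `assigned_type`, `top_marker`,
#'   `top_marker_clr`, `second_marker_clr`.
#' @export
assign_types <- function(adt_clr, panel = marker_panel(), margin = 0.5) {
  stopifnot(inherits(adt_clr, "normalized_matrix"))
  if (adt_clr$method != "CLR")
    stop("typing input error: CLR-normalized ADT values required")
  markers <- names(panel)
  missing_markers <- setdiff(markers, rownames(adt_clr$values))
  if (length(missing_markers) > 0)
    stop("typing configuration error: marker(s) missing from the ADT ",
         "panel: ", paste(missing_markers, collapse = ", "))
  v <- adt_clr$values[markers, , drop = FALSE]
  n <- ncol(v)
  # running top-2 across markers, iterated in alphabetical order so that
  # exact ties resolve independently of panel order
  top_clr <- rep(-Inf, n); second_clr <- rep(-Inf, n)
  top_marker <- rep(NA_character_, n); second_marker <- rep(NA_character_, n)
  for (mk in sort(markers)) {
    x <- v[mk, ]
    beats_top <- x > top_clr
    second_clr[beats_top] <- top_clr[beats_top]
    second_marker[beats_top] <- top_marker[beats_top]
    top_clr[beats_top] <- x[beats_top]
    top_marker[beats_top] <- mk
    beats_second <- !beats_top & x > second_clr
    second_clr[beats_second] <- x[beats_second]
    second_marker[beats_second] <- mk
  }
  mono_pair <- (top_marker == "CD14" & second_marker == "CD16") |
    (top_marker == "CD16" & second_marker == "CD14")
  ok <- top_clr > 0 & (mono_pair | (top_clr - second_clr) >= margin)
  assigned <- ifelse(ok, unname(panel[top_marker]), "OTHER")
  data.frame(barcode = colnames(v), assigned_type = assigned,
             top_marker = top_marker, top_marker_clr = top_clr,
             second_marker_clr = second_clr,
             row.names = NULL, stringsAsFactors = FALSE)
}
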