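#' @name cli_report
#' @title End-to-end pipeline orchestration
#'
#' @description
#' `run_pipeline()` chains QC, normalization, LOY calling, marker typing and
#' the differential tests over an on-disk input (10x-dialect RNA and ADT
#' directories plus a sample sheet), writing tidy TSV outputs and a JSON run
#' manifest. `analyze_cells()` is the same chain on in-memory objects, which
#' the simulator-based tests use directly. `make_figures()` reduces a run to
#' the per-type, per-group summary numbers a violin/box display needs.
NULL

#' Analyze count matrices in memory
#'
#' QC, normalization (RNA log to scale factor 10,000; ADT centered
#' log-ratio), LOY calling on raw counts of QC-passed cells, marker typing,
#' per-type differential tests with joint BH correction, pooled overall CD99
#' models, and per-type LOY frequencies.
#'
#' @param rna RNA [count_matrix()].
#' @param adt ADT [count_matrix()] sharing barcodes with `rna`.
#' @param sheet Sample sheet data frame (`barcode`, `donor`,
#'   `library_prep_batch`, `sequencing_batch`).
#' @param annotation A `gene_annotation`; default is the shipped table.
#' @param thresholds [qc_thresholds()].
#' @param clr_margin CLR margin convention, `"cell"` or `"feature"`.
#' @param typing_margin CLR margin for [assign_types()].
#' @param min_cells Minimum per-group cells for a per-type test.
#' @return List with `qc`, `calls`, `types`, `frequencies`, `differential`,
#'   `pooled`, the normalized matrices, `covariates` and per-stage cell
#'   counts `stage_cells`.
#' @export
analyze_cells <- function(rna, adt, sheet,
                          annotation = default_gene_annotation(),
                          thresholds = qc_thresholds(),
                          clr_margin = "cell", typing_margin = 0.5,
                          min_cells = 20) {
  stopifnot(inherits(rna, "count_matrix"), inherits(adt, "count_matrix"))
  if (!setequal(barcodes(rna), barcodes(adt)))
    stop("pipeline input error [qc]: RNA and ADT barcodes differ")
  if (!setequal(sheet$barcode, barcodes(rna)))
    stop("pipeline input error [qc]: sample sheet does not cover the ",
         "matrix barcodes")
  sets <- gene_sets(annotation)

  qc <- apply_qc(compute_qc(rna), thresholds)
  kept <- qc$barcode[qc$kept]
  rna_kept <- count_matrix(rna$values[, kept, drop = FALSE], assay = "RNA")
  adt_kept <- count_matrix(adt$values[, kept, drop = FALSE], assay = "ADT")

  rna_norm <- log_normalize(rna_kept)
  adt_clr <- clr_normalize(adt_kept, margin = clr_margin)

  calls <- call_loy(rna_kept, sets)
  determined <- calls$status != "UNDETERMINED"
  if (any(!determined))
    warning(sum(!determined), " UNDETERMINED cell(s) excluded from tests",
            call. = FALSE)
  calls_det <- calls[determined, , drop = FALSE]

  types <- assign_types(adt_clr, margin = typing_margin)
  type_of <- setNames(types$assigned_type, types$barcode)

  covariates <- data.frame(
    barcode = kept,
    sheet[match(kept, sheet$barcode),
          c("donor", "library_prep_batch", "sequencing_batch")],
    qc[match(kept, qc$barcode), c("n_umi", "pct_mito")],
    row.names = NULL, stringsAsFactors = FALSE)

  differential <- run_differential(rna_norm, adt_clr, calls_det, types,
                                   covariates, min_cells = min_cells)

  pooled_cov <- covariates[match(calls_det$barcode, covariates$barcode), ]
  pooled_cov$cell_type <- unname(type_of[calls_det$barcode])
  pooled_cov <- pooled_cov[setdiff(names(pooled_cov), "barcode")]
  pooled <- rbind(
    pooled_overall_test(rna_norm$values["CD99", calls_det$barcode],
                        calls_det$status, pooled_cov, "CD99", "RNA"),
    pooled_overall_test(adt_clr$values["CD99", calls_det$barcode],
                        calls_det$status, pooled_cov, "CD99", "ADT"))

  frequencies <- loy_frequencies(
    calls_det, setNames(type_of[calls_det$barcode], calls_det$barcode))

  list(qc = qc, calls = calls, types = types, frequencies = frequencies,
       differential = differential, pooled = pooled,
       rna_norm = rna_norm, adt_clr = adt_clr, covariates = covariates,
       stage_cells = c(input = ncol(rna$values), qc_kept = length(kept),
                       normalized = ncol(rna_norm$values),
                       called = nrow(calls), typed = nrow(types),
                       tested = nrow(calls_det)))
}

#' Run the full pipeline over on-disk inputs
#'
#' Reads the 10x-dialect RNA and ADT directories and the sample sheet, runs
#' [analyze_cells()], and writes `qc_report.tsv`, `loy_calls.tsv`,
#' `cell_types.tsv`, `loy_frequencies.tsv`, `differential_results.tsv`,
#' `pooled_overall.tsv` and `manifest.json` into `out_dir`.
#'
#' @param rna_dir,adt_dir 10x-dialect input directories.
#' @param samples_csv Sample sheet path.
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [analyze_cells()].
#' @return Invisibly, the [analyze_cells()] result list.
#' @export
run_pipeline <- function(rna_dir, adt_dir, samples_csv, out_dir, ...) {
  stage <- "read"
  res <- withCallingHandlers(
    tryCatch({
      rna <- read_10x(rna_dir, assay = "RNA")
      adt <- read_10x(adt_dir, assay = "ADT")
      sheet <- read_sample_sheet(samples_csv)
      stage <- "analyze"
      warnings_seen <- character(0)
      out <- withCallingHandlers(
        analyze_cells(rna, adt, sheet, ...),
        warning = function(w) {
          warnings_seen <<- c(warnings_seen, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      attr(out, "warnings") <- warnings_seen
      out
    }, error = function(e) {
      stop("pipeline error [", stage, "]: ", conditionMessage(e),
           call. = FALSE)
    }))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("pipeline error [write]: cannot create ", out_dir)
  wtsv <- function(df, name) write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wtsv(res$qc, "qc_report.tsv")
  wtsv(res$calls, "loy_calls.tsv")
  wtsv(res$types, "cell_types.tsv")
  wtsv(res$frequencies, "loy_frequencies.tsv")
  wtsv(res$differential, "differential_results.tsv")
  wtsv(res$pooled, "pooled_overall.tsv")
  manifest <- list(
    tool = "loycite",
    version = as.character(packageVersion("loycite")),
    inputs = list(rna = rna_dir, adt = adt_dir, samples = samples_csv),
    stage_cells = as.list(res$stage_cells),
    status_counts = as.list(table(res$calls$status)),
    warnings = attr(res, "warnings"))
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Per-type distribution summaries for display
#'
#' For each targeted cell type, analyte (CD99 and the type's own marker),
#' assay and LOY group: the min-max-scaled (within type x analyte x assay)
#' quartiles, median and cell count - the numbers a violin/box display
#' needs. Scaling is display-only. Types where one group is empty get `NA`
#' rows with a warning.
#'
#' @param res Result of [analyze_cells()] / [run_pipeline()].
#' @param plot If `TRUE` and ggplot2 is installed, also return a violin/box
#'   plot of the scaled values in attribute `"plot"`.
#' @return Data frame with columns `cell_type`, `analyte`, `assay`, `group`,
#'   `n`, `median`, `q1`, `q3`, `min`, `max` (all on the 0-1 scale).
#' @export
make_figures <- function(res, plot = FALSE) {
  stopifnot(is.list(res), !is.null(res$differential))
  calls <- res$calls[res$calls$status %in% c("LOY", "NORMAL"), ]
  type_of <- setNames(res$types$assigned_type, res$types$barcode)
  panel <- marker_panel()
  rows <- list()
  scaled_long <- list()
  empty_groups <- character(0)
  for (ct in unname(panel)) {
    cells <- calls$barcode[type_of[calls$barcode] == ct]
    grp <- setNames(calls$status, calls$barcode)[cells]
    marker <- names(panel)[match(ct, panel)]
    for (analyte in c("CD99", marker)) {
      for (assay in c("RNA", "ADT")) {
        mat <- if (assay == "RNA") res$rna_norm else res$adt_clr
        x <- mat$values[analyte, cells]
        both <- length(cells) >= 2 && any(grp == "LOY") &&
          any(grp == "NORMAL")
        sx <- if (length(cells) >= 2)
          suppressWarnings(minmax_scale(as.numeric(x),
                                        rep(ct, length(x)))) else
          rep(NA_real_, length(x))
        for (g in c("LOY", "NORMAL")) {
          xi <- sx[grp == g]
          if (length(xi) == 0 || !both) {
            if (length(xi) == 0)
              empty_groups <- c(empty_groups, paste0(ct, "/", g))
            rows[[length(rows) + 1L]] <- data.frame(
              cell_type = ct, analyte = analyte, assay = assay, group = g,
              n = length(xi), median = NA_real_, q1 = NA_real_,
              q3 = NA_real_, min = NA_real_, max = NA_real_,
              stringsAsFactors = FALSE)
          } else {
            q <- quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
              cell_type = ct, analyte = analyte, assay = assay, group = g,
              n = length(xi), median = q[2], q1 = q[1], q3 = q[3],
              min = min(xi), max = max(xi), stringsAsFactors = FALSE)
          }
        }
        if (both && analyte == "CD99")
          scaled_long[[length(scaled_long) + 1L]] <- data.frame(
            cell_type = ct, assay = assay, group = unname(grp),
            value = unname(sx), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(empty_groups) > 0)
    warning("empty group(s), NA summaries emitted: ",
            paste(unique(empty_groups), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (plot && requireNamespace("ggplot2", quietly = TRUE) &&
      length(scaled_long) > 0) {
    long <- do.call(rbind, scaled_long)
    attr(out, "plot") <- ggplot2::ggplot(
      long, ggplot2::aes(x = cell_type, y = value, fill = group)) +
      ggplot2::geom_violin(position = ggplot2::position_dodge(0.8),
                           alpha = 0.6, scale = "width") +
      ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8),
                            width = 0.15, outlier.size = 0.3) +
      ggplot2::facet_wrap(~assay) +
      ggplot2::labs(x = NULL, y = "CD99 (scaled 0-1)", fill = "status")
  }
  out
}
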