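# shared fixtures and independent oracles, built in code

# textbook Benjamini-Hochberg step-up: sort, multiply by m/i, running
# minimum from the right, cap at 1 (independent of the package path)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

bh_oracle_with_na <- function(p) {
  out <- rep(NA_real_, length(p))
  out[!is.na(p)] <- bh_oracle(p[!is.na(p)])
  out
}

toy_annotation <- function() {
  gene_annotation(data.frame(
    symbol = c("RPS4Y1", "DDX3Y", "EIF1AY", "CD99", "XIST",
               paste0("A", 1:10)),
    chromosome = c("Y", "Y", "Y", "X;Y", "X", rep("1", 10)),
    region_class = c("MSY", "MSY", "MSY", "PAR", "X_nonPAR",
                     rep("AUTOSOME", 10)),
    stringsAsFactors = FALSE))
}

# small random raw count matrix with guaranteed-unique dimnames
random_counts <- function(n_genes, n_cells, assay = "RNA", lambda = 2,
                          genes = sprintf("G%03d", seq_len(n_genes))) {
  m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
              dimnames = list(genes, sprintf("BC%04d", seq_len(n_cells))))
  count_matrix(m, assay = assay)
}

# reduced-panel generator profile used for replicate-heavy checks; the
# quantities those checks measure do not depend on background panel size
fast_cfg <- function(...) {
  simulation_config(n_background_genes = 300, doublet_rate = 0, ...)
}

# muffle only warnings matching a pattern (e.g. the expected donor/batch
# aliasing warning), letting anything unexpected through
suppress_matching <- function(expr, pattern) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl(pattern, conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

quiet_analyze <- function(...) {
  suppress_matching(
    suppressMessages(analyze_cells(...)),
    "rank-deficient|fewer than|UNDETERMINED|Firth")
}
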