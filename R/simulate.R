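#' @name synthetic_citeseq
#' @title Seeded synthetic CITE-seq generator with ground truth
#'
#' @description
#' Generates RNA and ADT count matrices, a per-cell sample sheet and a truth
#' table with the statistical structure the analysis chain assumes: six
#' leukocyte types at realistic proportions plus a small `OTHER` population,
#' per-type LOY fractions, negative-binomial counts over a configurable gene
#' panel, MSY transcript absence in LOY cells, CD99 dosage reduction in LOY
#' cells with per-type effect sizes, donor/batch/depth/mitochondrial-content
#' confounders, dropout of MSY detection as an explicit knob, and doublets
#' formed by summing two cells of the same donor. The seed fixes the entire
#' dataset.
NULL

.MSY_SYMBOLS <- c("RPS4Y1", "ZFY", "USP9Y", "DDX3Y", "UTY", "TMSB4Y",
                  "NLGN4Y", "KDM5D", "EIF1AY", "RPS4Y2", "PRKY", "TXLNGY")
.MITO_SYMBOLS <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                   "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                   "MT-ND5", "MT-ND6", "MT-CYB")

#' Simulation configuration
#'
#' Defaults encode the study conditions: four donors, two sequencing batches
#' (two donors' libraries partly sequenced in a pilot run), six leukocyte
#' types plus `OTHER`, per-type LOY fractions of 5.6% (B), 15.2% (CD14
#' monocytes), 15.0% (CD16 monocytes), 20.9% (NK), 8.6% (CD8 T) and 2.4%
#' (CD4 T), and per-type CD99 effect sizes (natural-log fold changes in LOY
#' cells) for both assays. Effects are parameterized on the scale of the
#' analysis-side estimator: count-mean multipliers are chosen so that the
#' average log fold change computed downstream targets the configured value
#' (for ADT this includes the centered-log-ratio closure factor `p/(p-1)`;
#' for RNA the log1p pseudocount).
#'
#' @param n_cells_per_donor Singlet cells per donor.
#' @param donors Number of donors.
#' @param type_proportions Named proportions over the six types and `OTHER`;
#'   must sum to 1.
#' @param loy_fraction_per_type Named per-type LOY probabilities.
#' @param rna_effects,adt_effects Named per-type CD99 log fold changes
#'   injected in LOY cells (RNA / ADT assay).
#' @param nb_dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param depth_lognormal_params `c(meanlog, sdlog)` of per-cell RNA depth.
#' @param mito_beta_params `c(shape1, shape2)` of the Beta draw rescaled
#'   into `mito_window` for in-window cells.
#' @param mito_window Mitochondrial fraction window (proportion scale)
#'   matching the QC criterion.
#' @param mito_outlier_frac Fraction of cells drawn outside the window.
#' @param msy_gene_count Number of MSY genes simulated (up to 12).
#' @param msy_dropout Probability that a truly present MSY gene yields zero
#'   observed counts (applied per gene and cell after the draw).
#' @param doublet_rate Fraction of additional doublet droplets.
#' @param batch_scale_factors Named depth multipliers per sequencing batch.
#' @param n_background_genes Autosomal background panel size.
#' @param cd99_rna_fraction CD99 share of the non-mitochondrial
#'   transcriptome.
#' @param msy_rna_fraction Total MSY share in normal cells (calibrated so
#'   the expected MSY total per normal cell is well above detection at
#'   median depth).
#' @param marker_rna_fraction_on,marker_rna_fraction_off Lineage-marker gene
#'   share in its own type / other types.
#' @param adt_background_mean,adt_marker_mean,cd99_adt_mean,nk_cd8_adt_mean
#'   ADT count means: nonspecific background, lineage marker in its own
#'   type, CD99 (all leukocytes), dim CD8 on NK cells.
#' @param adt_sdlog Log-normal sd of the per-cell ADT size factor.
#' @param seed Integer seed fixing the dataset.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_cells_per_donor = 1250,
    donors = 4,
    type_proportions = c(B = 0.12, CD14_mono = 0.15, CD16_mono = 0.05,
                         NK = 0.10, CD8_T = 0.20, CD4_T = 0.33,
                         OTHER = 0.05),
    loy_fraction_per_type = c(B = 0.056, CD14_mono = 0.152,
                              CD16_mono = 0.150, NK = 0.209, CD8_T = 0.086,
                              CD4_T = 0.024, OTHER = 0.08),
    rna_effects = c(B = -0.32, CD14_mono = -0.23, CD16_mono = -0.12,
                    NK = -0.17, CD8_T = -0.05, CD4_T = -0.09, OTHER = 0),
    adt_effects = c(B = -0.31, CD14_mono = -0.07, CD16_mono = -0.09,
                    NK = -0.05, CD8_T = -0.11, CD4_T = -0.08, OTHER = 0),
    nb_dispersion = 10,
    depth_lognormal_params = c(meanlog = log(6000), sdlog = 0.45),
    mito_beta_params = c(shape1 = 2.5, shape2 = 2.5),
    mito_window = c(0.015, 0.05),
    mito_outlier_frac = 0.07,
    msy_gene_count = 12,
    msy_dropout = 0,
    doublet_rate = 0.01,
    batch_scale_factors = c(pilot = 1, main = 1.25),
    n_background_genes = 2400,
    cd99_rna_fraction = 0.0015,
    msy_rna_fraction = 0.0012,
    marker_rna_fraction_on = 0.004,
    marker_rna_fraction_off = 2e-4,
    adt_background_mean = 30,
    adt_marker_mean = 300,
    cd99_adt_mean = 250,
    nk_cd8_adt_mean = 60,
    adt_sdlog = 0.3,
    seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("simulation configuration error: type proportions must sum to 1")
  types <- names(type_proportions)
  for (field in c("loy_fraction_per_type", "rna_effects", "adt_effects")) {
    if (!all(types %in% names(cfg[[field]])))
      stop("simulation configuration error: ", field,
           " must name every type in type_proportions")
  }
  if (any(loy_fraction_per_type < 0 | loy_fraction_per_type > 1) ||
      msy_dropout < 0 || msy_dropout > 1 ||
      doublet_rate < 0 || doublet_rate > 1 ||
      mito_outlier_frac < 0 || mito_outlier_frac > 1)
    stop("simulation configuration error: fractions and probabilities must ",
         "lie in [0, 1]")
  if (msy_gene_count < 1 || msy_gene_count > length(.MSY_SYMBOLS))
    stop("simulation configuration error: msy_gene_count must be in 1..",
         length(.MSY_SYMBOLS))
  structure(cfg, class = "simulation_config")
}

.random_barcodes <- function(n) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), 14 * k, replace = TRUE),
                nrow = k)
    paste0(do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE)), "-1")
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' Simulate a CITE-seq experiment
#'
#' @param config A [simulation_config()].
#' @return List with elements `rna` and `adt` ([count_matrix()] objects
#'   sharing barcodes), `sheet` (sample sheet data frame), `truth` (data
#'   frame `barcode`, `true_type`, `true_loy`, `is_doublet`) and `config`.
#' @export
simulate_citeseq <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  types <- names(cfg$type_proportions)
  n <- cfg$n_cells_per_donor * cfg$donors
  donor <- rep(seq_len(cfg$donors), each = cfg$n_cells_per_donor)
  cell_type <- sample(types, n, replace = TRUE, prob = cfg$type_proportions)
  loy <- rbinom(n, 1, cfg$loy_fraction_per_type[cell_type]) == 1

  lib_batch <- ifelse(donor <= ceiling(cfg$donors / 2), "L1", "L2")
  # libraries of the first two donors were partly sequenced in a pilot run
  seq_batch <- ifelse(donor <= min(2, cfg$donors) & runif(n) < 0.3,
                      "pilot", "main")
  depth <- rlnorm(n, cfg$depth_lognormal_params[["meanlog"]],
                  cfg$depth_lognormal_params[["sdlog"]]) *
    cfg$batch_scale_factors[seq_batch]

  is_outlier <- runif(n) < cfg$mito_outlier_frac
  f_mito <- cfg$mito_window[1] + diff(cfg$mito_window) *
    rbeta(n, cfg$mito_beta_params[["shape1"]], cfg$mito_beta_params[["shape2"]])
  low_side <- runif(n) < 0.5
  f_mito[is_outlier & low_side] <-
    runif(sum(is_outlier & low_side), 0.002, 0.012)
  f_mito[is_outlier & !low_side] <-
    runif(sum(is_outlier & !low_side), 0.055, 0.12)

  # gene panel: background, lineage markers, CD99 (PAR), MSY, mitochondrial
  markers <- names(marker_panel())
  msy_genes <- .MSY_SYMBOLS[seq_len(cfg$msy_gene_count)]
  bg_genes <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  genes <- c(bg_genes, markers, "CD99", msy_genes, .MITO_SYMBOLS)
  G <- length(genes)
  bg_idx <- seq_along(bg_genes)
  marker_idx <- setNames(match(markers, genes), markers)
  cd99_idx <- match("CD99", genes)
  msy_idx <- match(msy_genes, genes)
  mito_idx <- match(.MITO_SYMBOLS, genes)
  nonmito_idx <- setdiff(seq_len(G), mito_idx)

  bg_w <- exp(rnorm(length(bg_genes), 0, 1.2))
  bg_w <- bg_w / sum(bg_w)
  msy_w <- exp(rnorm(length(msy_genes), 0, 0.5))
  msy_w <- msy_w / sum(msy_w)
  mito_w <- exp(rnorm(length(.MITO_SYMBOLS), 0, 0.8))
  mito_w <- mito_w / sum(mito_w)

  # RNA LOY multiplier on the CD99 count mean, compensating the log1p
  # pseudocount of the downstream estimator (M = expected normalized mean)
  M <- cfg$cd99_rna_fraction * 1e4
  rna_mult <- ((M + 1) * exp(cfg$rna_effects) - 1) / M
  rna_mult <- pmax(rna_mult, 1e-6)
  # ADT LOY multiplier, compensating the CLR closure across the p proteins
  p_panel <- length(adt_panel())
  adt_mult <- exp(cfg$adt_effects * p_panel / (p_panel - 1))

  rna <- matrix(0, nrow = G, ncol = n)
  for (ct in types) {
    for (is_loy in c(FALSE, TRUE)) {
      idx <- which(cell_type == ct & loy == is_loy)
      if (length(idx) == 0) next
      prof <- numeric(G)
      prof[marker_idx] <- cfg$marker_rna_fraction_off
      own <- markers[match(ct, marker_panel())]
      if (!is.na(own)) prof[marker_idx[own]] <- cfg$marker_rna_fraction_on
      prof[cd99_idx] <- cfg$cd99_rna_fraction *
        if (is_loy) rna_mult[[ct]] else 1
      if (!is_loy) prof[msy_idx] <- cfg$msy_rna_fraction * msy_w
      prof[bg_idx] <- bg_w * (1 - sum(prof[nonmito_idx]))
      scale_vec <- depth[idx] * (1 - f_mito[idx])
      mu <- prof[nonmito_idx] %o% scale_vec
      rna[nonmito_idx, idx] <- rnbinom(length(mu), mu = mu,
                                       size = cfg$nb_dispersion)
    }
  }
  mu_mito <- mito_w %o% (depth * f_mito)
  rna[mito_idx, ] <- rnbinom(length(mu_mito), mu = mu_mito,
                             size = cfg$nb_dispersion)

  # normal cells carry MSY transcripts by construction: condition the MSY
  # block on a positive total, then thin with the explicit dropout knob
  normal_cells <- which(!loy)
  msy_tot <- colSums(rna[msy_idx, normal_cells, drop = FALSE])
  fix <- normal_cells[msy_tot == 0]
  if (length(fix) > 0) {
    gene_pick <- sample(msy_idx, length(fix), replace = TRUE, prob = msy_w)
    rna[cbind(gene_pick, fix)] <- 1
  }
  if (cfg$msy_dropout > 0) {
    keep <- matrix(rbinom(length(msy_idx) * length(normal_cells), 1,
                          1 - cfg$msy_dropout),
                   nrow = length(msy_idx))
    rna[msy_idx, normal_cells] <- rna[msy_idx, normal_cells, drop = FALSE] *
      keep
  }

  proteins <- adt_panel()
  adt_mu <- matrix(cfg$adt_background_mean, nrow = length(proteins), ncol = n,
                   dimnames = list(proteins, NULL))
  for (ct in setdiff(types, "OTHER")) {
    own <- names(marker_panel())[match(ct, marker_panel())]
    adt_mu[own, cell_type == ct] <- cfg$adt_marker_mean
  }
  adt_mu["CD8", cell_type == "NK"] <- cfg$nk_cd8_adt_mean
  adt_mu["CD99", ] <- cfg$cd99_adt_mean *
    ifelse(loy, adt_mult[cell_type], 1)
  adt_size_factor <- rlnorm(n, 0, cfg$adt_sdlog)
  adt_mu <- sweep(adt_mu, 2L, adt_size_factor, "*")
  adt <- matrix(rnbinom(length(adt_mu), mu = adt_mu,
                        size = cfg$nb_dispersion),
                nrow = length(proteins))

  # doublets: two cells of the same donor in one droplet, counts summed
  n_doublets <- round(cfg$doublet_rate * n)
  if (n_doublets > 0) {
    parent1 <- integer(n_doublets); parent2 <- integer(n_doublets)
    for (k in seq_len(n_doublets)) {
      d <- sample(cfg$donors, 1)
      pair <- sample(which(donor == d), 2)
      parent1[k] <- pair[1]; parent2[k] <- pair[2]
    }
    rna <- cbind(rna, rna[, parent1, drop = FALSE] +
                   rna[, parent2, drop = FALSE])
    adt <- cbind(adt, adt[, parent1, drop = FALSE] +
                   adt[, parent2, drop = FALSE])
    donor <- c(donor, donor[parent1])
    lib_batch <- c(lib_batch, lib_batch[parent1])
    seq_batch <- c(seq_batch, seq_batch[parent1])
    cell_type <- c(cell_type, cell_type[parent1])
    loy <- c(loy, loy[parent1])
  }
  n_total <- n + n_doublets
  bc <- .random_barcodes(n_total)

  rownames(rna) <- genes
  colnames(rna) <- bc
  rownames(adt) <- proteins
  colnames(adt) <- bc
  sheet <- data.frame(barcode = bc, donor = sprintf("D%d", donor),
                      library_prep_batch = lib_batch,
                      sequencing_batch = unname(seq_batch),
                      stringsAsFactors = FALSE)
  truth <- data.frame(barcode = bc, true_type = cell_type,
                      true_loy = loy,
                      is_doublet = rep(c(FALSE, TRUE), c(n, n_doublets)),
                      stringsAsFactors = FALSE)
  list(rna = count_matrix(rna, assay = "RNA"),
       adt = count_matrix(adt, assay = "ADT"),
       sheet = sheet, truth = truth, config = cfg)
}

#' Write a simulated experiment as an on-disk fixture
#'
#' Emits `rna/` and `adt/` 10x-dialect directories, `samples.csv`,
#' `truth.tsv` and a flat `config.txt` key-value serialization of the full
#' configuration for provenance.
#'
#' @param sim Output of [simulate_citeseq()].
#' @param dir Output directory.
#' @param gzip Compress the matrix files.
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(sim, dir, gzip = FALSE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("fixture I/O error: cannot create directory ", dir)
  write_10x(sim$rna, file.path(dir, "rna"), gzip = gzip)
  write_10x(sim$adt, file.path(dir, "adt"), gzip = gzip)
  write.csv(sim$sheet, file.path(dir, "samples.csv"), row.names = FALSE,
            quote = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cfg <- sim$config
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    val <- if (!is.null(names(v)) && length(v) > 1)
      paste(names(v), unname(v), sep = ":", collapse = ",") else
      paste(unname(v), collapse = ",")
    paste(k, "=", val)
  }, character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
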