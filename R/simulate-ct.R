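#' Configuration for synthetic single-cell qPCR arrays
#'
#' Describes 96.96-style dynamic arrays (cells x genes matrices of Ct values)
#' with two planted cell subpopulations per array, per-entry dropout recorded
#' as the sentinel value 999, and a small number of planted housekeeping
#' outlier cells whose housekeeping Ct is shifted far beyond 3 s.d. of the
#' across-cell spread.
#'
#' @param n_donors number of donors; one array is generated per donor.
#' @param cells_per_array cells per array (chamber count, <= 96).
#' @param n_genes genes per array (assay count); the first gene is the
#'   housekeeping gene `GAPDH`.
#' @param cluster_means 2 x `n_genes` matrix of true log2 expression means
#'   for the two planted subpopulations. Default: housekeeping at 12 for
#'   both groups, all other genes at 6, with a 20-gene block raised to 10
#'   (separation 4 log2exp) in group 2.
#' @param dropout_rate per-entry probability of an undetected read (sentinel
#'   999); a scalar, or a length-`n_genes` vector of per-gene rates.
#' @param housekeeping_outlier_cells number of cells per array whose
#'   housekeeping Ct is shifted by +8 cycles.
#' @param ct_noise_sd measurement noise s.d. in Ct units.
#' @param rng_seed integer seed.
#' @return An object of class `ct_sim_config`.
#' @export
ct_sim_config <- function(n_donors = 3L,
                          cells_per_array = 96L,
                          n_genes = 96L,
                          cluster_means = NULL,
                          dropout_rate = 0.2,
                          housekeeping_outlier_cells = 2L,
                          ct_noise_sd = 0.5,
                          rng_seed = 1L) {
  stop_if_not_count(n_donors, "n_donors")
  stop_if_not_count(cells_per_array, "cells_per_array", min = 4L)
  if (cells_per_array > 96L) stop("`cells_per_array` must be <= 96", call. = FALSE)
  stop_if_not_count(n_genes, "n_genes", min = 2L)
  if (is.null(cluster_means)) {
    cluster_means <- matrix(6, 2, n_genes)
    cluster_means[, 1] <- 12  # housekeeping
    block <- seq(2L, min(21L, n_genes))
    cluster_means[2, block] <- 10
  }
  if (!is.matrix(cluster_means) || nrow(cluster_means) != 2L ||
      ncol(cluster_means) != n_genes) {
    stop("`cluster_means` must be a 2 x n_genes matrix", call. = FALSE)
  }
  if (length(dropout_rate) == 1L) dropout_rate <- rep(dropout_rate, n_genes)
  if (length(dropout_rate) != n_genes || any(dropout_rate < 0) ||
      any(dropout_rate >= 1)) {
    stop("`dropout_rate` must be in [0, 1), scalar or per-gene", call. = FALSE)
  }
  if (housekeeping_outlier_cells < 0 ||
      housekeeping_outlier_cells >= cells_per_array) {
    stop("`housekeeping_outlier_cells` must be < cells_per_array", call. = FALSE)
  }
  if (ct_noise_sd < 0) stop("`ct_noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_donors = as.integer(n_donors),
                 cells_per_array = as.integer(cells_per_array),
                 n_genes = as.integer(n_genes),
                 cluster_means = cluster_means,
                 dropout_rate = as.numeric(dropout_rate),
                 housekeeping_outlier_cells = as.integer(housekeeping_outlier_cells),
                 ct_noise_sd = ct_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "ct_sim_config")
}

CT_UNDETECTED <- 999

#' Simulate raw single-cell qPCR Ct arrays with planted subpopulations
#'
#' Each array holds `cells_per_array` cells split evenly (at random) between
#' the two planted subpopulations. True Ct values are generated as
#' `24 - log2exp + noise` (the inverse of the limit-of-detection transform at
#' its default), clamped to (0, 40]; undetected entries are then overlaid
#' completely at random per entry at the per-gene dropout rate and recorded
#' as 999. Housekeeping outlier cells get their housekeeping Ct shifted by
#' +8 cycles before the dropout overlay.
#'
#' @param cfg a [ct_sim_config()].
#' @return A list with `arrays` (named list of cells x genes Ct matrices,
#'   cell ids as rownames, gene names as colnames with `GAPDH` first),
#'   `metadata` (data frame: array id, donor), and `truth` (`labels` mapping
#'   cell id to `"group1"`/`"group2"`, plus `outlier_cells`).
#' @export
simulate_ct_arrays <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  with_seed(cfg$rng_seed, {
    genes <- c("GAPDH", sprintf("gene%02d", seq_len(cfg$n_genes - 1L)))
    arrays <- list()
    labels <- character(0)
    outliers <- character(0)
    for (a in seq_len(cfg$n_donors)) {
      id <- sprintf("donor%d", a)
      cells <- sprintf("%s_cell%02d", id, seq_len(cfg$cells_per_array))
      grp <- sample(rep(1:2, length.out = cfg$cells_per_array))
      log2exp <- cfg$cluster_means[grp, , drop = FALSE]
      ct <- 24 - log2exp +
        matrix(rnorm(length(log2exp), 0, cfg$ct_noise_sd),
               nrow(log2exp), ncol(log2exp))
      out_cells <- if (cfg$housekeeping_outlier_cells > 0) {
        sample(seq_len(cfg$cells_per_array), cfg$housekeeping_outlier_cells)
      } else integer(0)
      ct[out_cells, 1] <- ct[out_cells, 1] + 8
      ct <- pmin(pmax(ct, 0.1), 40)
      drop_mask <- matrix(rbinom(length(ct), 1L,
                                 rep(cfg$dropout_rate, each = nrow(ct))) == 1L,
                          nrow(ct), ncol(ct))
      ct[drop_mask] <- CT_UNDETECTED
      dimnames(ct) <- list(cells, genes)
      arrays[[id]] <- ct
      labels <- c(labels, setNames(paste0("group", grp), cells))
      outliers <- c(outliers, cells[out_cells])
    }
    list(arrays = arrays,
         metadata = data.frame(array = names(arrays),
                               donor = seq_len(cfg$n_donors),
                               stringsAsFactors = FALSE),
         truth = list(stage = "ct", labels = labels,
                      outlier_cells = outliers, config = cfg))
  })
}
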