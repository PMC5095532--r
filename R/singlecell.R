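## Single-cell qPCR pipeline: per-gene missing-value rules, LOD transform,
## housekeeping QC, Winsorization, z-scores, Manhattan distances, minimum
## spanning tree, Ward clustering, group comparison, gene correlation.

#' Per-gene missing-value handling for raw Ct columns
#'
#' Applies the two-branch rule for undetected reads (sentinel 999)
#' interspersed among positive reads (Ct below `positive_cutoff`): if fewer
#' than `positive_fraction` of the reads in the gene column are positive,
#' the whole gene is considered undetectable for the array and every entry
#' is set to 999; otherwise each 999 entry is replaced by the mean of the
#' positive reads. The rule is idempotent.
#'
#' @param ct_values numeric vector of Ct values for one gene column.
#' @param positive_cutoff Ct threshold defining a positive read (default 25).
#' @param positive_fraction minimum fraction of positive reads for the gene
#'   to count as detectable (default 0.10).
#' @return Processed Ct vector with attribute `provenance` (`"measured"`,
#'   `"imputed"` or `"undetectable"` per entry).
#' @export
process_gene_column <- function(ct_values, positive_cutoff = 25,
                                positive_fraction = 0.10) {
  if (!length(ct_values)) stop("empty gene column", call. = FALSE)
  positive <- ct_values < positive_cutoff
  prov <- rep("measured", length(ct_values))
  if (mean(positive) < positive_fraction) {
    ct_values[] <- CT_UNDETECTED
    prov[] <- "undetectable"
  } else {
    missing <- ct_values == CT_UNDETECTED
    if (any(missing)) {
      ct_values[missing] <- mean(ct_values[positive])
      prov[missing] <- "imputed"
    }
  }
  attr(ct_values, "provenance") <- prov
  ct_values
}

#' Limit-of-detection transform from Ct to log2 expression
#'
#' `log2exp = max(0, LOD - Ct)`: one Ct cycle below the limit of detection
#' corresponds to one doubling of expression. The sentinel 999 and any Ct at
#' or beyond the LOD map to 0.
#'
#' @param ct Ct value(s); must be nonnegative.
#' @param lod limit of detection in Ct cycles (platform default 24).
#' @return Nonnegative log2 expression value(s).
#' @export
ct_to_log2exp <- function(ct, lod = 24) {
  if (any(ct < 0)) stop("negative Ct values are invalid", call. = FALSE)
  out <- lod - ct
  out[out < 0] <- 0
  attr(out, "provenance") <- NULL
  out
}

#' Convert a raw Ct array to a log2 expression matrix
#'
#' Convenience wrapper: applies [process_gene_column()] to each gene column
#' of one array, then [ct_to_log2exp()].
#'
#' @param ct_array cells x genes Ct matrix (999 = undetected).
#' @param lod,positive_cutoff,positive_fraction see the underlying rules.
#' @return cells x genes log2 expression matrix with a `provenance`
#'   attribute matrix.
#' @export
ct_array_to_expression <- function(ct_array, lod = 24, positive_cutoff = 25,
                                   positive_fraction = 0.10) {
  processed <- apply(ct_array, 2, process_gene_column,
                     positive_cutoff = positive_cutoff,
                     positive_fraction = positive_fraction)
  prov <- apply(ct_array, 2, function(col)
    attr(process_gene_column(col, positive_cutoff, positive_fraction),
         "provenance"))
  expr <- ct_to_log2exp(processed, lod = lod)
  dimnames(expr) <- dimnames(ct_array)
  dimnames(prov) <- dimnames(ct_array)
  attr(expr, "provenance") <- prov
  expr
}

#' Housekeeping-based cell quality control
#'
#' Removes cells without housekeeping expression (log2exp of 0), then cells
#' whose housekeeping expression deviates from the retained-cell mean by
#' more than `sd_limit` standard deviations.
#'
#' @param expr cells x genes log2 expression matrix.
#' @param housekeeping housekeeping gene name (default `"GAPDH"`).
#' @param sd_limit outlier threshold in s.d. units (default 3).
#' @return List with `expr` (filtered matrix) and `removed` (data frame:
#'   `cell`, `reason` in `"no_expression"`/`"outlier"`).
#' @export
qc_cells <- function(expr, housekeeping = "GAPDH", sd_limit = 3) {
  if (!housekeeping %in% colnames(expr)) {
    stop(sprintf("housekeeping gene '%s' not in gene list", housekeeping),
         call. = FALSE)
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("cell", seq_len(nrow(expr)))
  }
  hk <- expr[, housekeeping]
  no_expr <- hk == 0
  kept <- expr[!no_expr, , drop = FALSE]
  removed <- data.frame(cell = rownames(expr)[no_expr],
                        reason = rep("no_expression", sum(no_expr)),
                        stringsAsFactors = FALSE)
  if (nrow(kept)) {
    hk2 <- kept[, housekeeping]
    s <- sd(hk2)
    outlier <- if (is.na(s) || s == 0) rep(FALSE, length(hk2))
               else abs(hk2 - mean(hk2)) > sd_limit * s
    removed <- rbind(removed,
                     data.frame(cell = rownames(kept)[outlier],
                                reason = rep("outlier", sum(outlier)),
                                stringsAsFactors = FALSE))
    kept <- kept[!outlier, , drop = FALSE]
  }
  if (!nrow(kept)) stop("quality control removed every cell", call. = FALSE)
  list(expr = kept, removed = removed)
}

#' Winsorize one gene's expression values
#'
#' Caps values below the `lower_q` quantile at that quantile and values
#' above the `upper_q` quantile at that quantile (defaults: 5th and 95th
#' percentiles), containing transcriptional-burst extremes without removing
#' cells. Quantiles use linear interpolation between order statistics
#' (`type = 7`); the convention is configurable because different software
#' disagrees on it.
#'
#' @param values numeric vector (one gene across retained cells).
#' @param lower_q,upper_q quantile bounds.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return Winsorized vector; vectors of fewer than 3 values are returned
#'   unchanged with a warning.
#' @export
winsorize_gene <- function(values, lower_q = 0.05, upper_q = 0.95, type = 7) {
  if (length(values) < 3L) {
    warning("fewer than 3 values; returned unchanged")
    return(values)
  }
  q <- quantile(values, c(lower_q, upper_q), type = type, names = FALSE)
  pmin(pmax(values, q[1]), q[2])
}

#' Per-gene z-scores over the combined matrix
#'
#' Standardizes each gene to mean 0 and unit sample s.d. (n - 1 denominator)
#' across all retained cells of the arrays under comparison. Zero-variance
#' genes get z-scores of 0 and are flagged.
#'
#' @param expr cells x genes matrix.
#' @return z-score matrix with attribute `zero_variance` (logical per gene).
#' @export
zscore_genes <- function(expr) {
  if (nrow(expr) < 2L) stop("need at least 2 cells", call. = FALSE)
  mu <- colMeans(expr)
  s <- apply(expr, 2, sd)
  flat <- s == 0
  s[flat] <- 1
  z <- sweep(sweep(expr, 2, mu), 2, s, "/")
  z[, flat] <- 0
  attr(z, "zero_variance") <- flat
  z
}

#' Manhattan distances between cells
#'
#' `D(a, b) = sum_g |z_ag - z_bg|` over the gene parameters.
#'
#' @param z cells x genes z-score matrix (no missing entries).
#' @return Symmetric cells x cells distance matrix with zero diagonal.
#' @export
manhattan_distances <- function(z) {
  if (anyNA(z)) stop("missing entries are not allowed", call. = FALSE)
  as.matrix(dist(z, method = "manhattan"))
}

#' Minimum spanning tree of a cell distance matrix
#'
#' Prim's algorithm on the dense distance matrix with deterministic
#' tie-breaking: among equal-weight candidate edges the one with the
#' smallest (row, column) index pair is chosen.
#'
#' @param dist_mat complete symmetric distance matrix.
#' @return An object of class `spanning_tree`: data frame with columns
#'   `from`, `to`, `distance` (n - 1 rows).
#' @export
minimum_spanning_tree <- function(dist_mat) {
  n <- nrow(dist_mat)
  if (is.null(n) || n < 2L) stop("need at least 2 cells", call. = FALSE)
  ids <- rownames(dist_mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  # best known connection of each outside vertex to the tree
  best_w <- dist_mat[, 1]
  best_from <- rep(1L, n)
  edges <- data.frame(from = character(n - 1L), to = character(n - 1L),
                      distance = numeric(n - 1L), stringsAsFactors = FALSE)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    # ties: smallest weight, then smallest tree index, then smallest new index
    o <- cand[order(best_w[cand], best_from[cand], cand)][1]
    edges[k, ] <- list(ids[best_from[o]], ids[o], best_w[o])
    in_tree[o] <- TRUE
    upd <- !in_tree & dist_mat[, o] < best_w
    best_w[upd] <- dist_mat[upd, o]
    best_from[upd] <- o
  }
  structure(edges, class = c("spanning_tree", "data.frame"))
}

#' Ward hierarchical clustering of cells
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on the
#' Euclidean geometry of the z-score matrix (`hclust` method `ward.D2`),
#' cut into `k` clusters. Pass a subset of cells to subdivide a cluster
#' (see [subdivide_cluster()]).
#'
#' @param z cells x genes z-score matrix, or a pre-computed [stats::dist]
#'   object (e.g. Manhattan distances, if that geometry is preferred).
#' @param k number of clusters (1 <= k <= n cells).
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (named integer vector) and `hclust` (the tree).
#' @export
ward_cluster <- function(z, k) {
  d <- if (inherits(z, "dist")) z else dist(z, method = "euclidean")
  n <- attr(d, "Size")
  stop_if_not_count(k, "k")
  if (k > n) stop("`k` exceeds the number of cells", call. = FALSE)
  hc <- hclust(d, method = "ward.D2")
  structure(list(labels = cutree(hc, k), hclust = hc),
            class = "cluster_assignment")
}

#' Subdivide one cluster by a further Ward cut
#'
#' Re-clusters the cells of a chosen cluster into `k` subgroups, mirroring
#' the two-stage identification of subgroups within the stimulated-cell
#' cluster.
#'
#' @param z cells x genes z-score matrix.
#' @param assignment a [ward_cluster()] result.
#' @param cluster cluster label to subdivide.
#' @param k number of subgroups.
#' @return A `cluster_assignment` for the subdivided cells only.
#' @export
subdivide_cluster <- function(z, assignment, cluster, k) {
  cells <- names(assignment$labels)[assignment$labels == cluster]
  if (length(cells) < k) stop("cluster smaller than `k`", call. = FALSE)
  ward_cluster(z[cells, , drop = FALSE], k)
}

#' Compare gene expression between two cell groups
#'
#' Per gene: group means, mean difference, and a two-sided two-sample
#' t-test. Following the study's convention, an F test of equal variances
#' decides between the pooled-variance t-test and Welch's correction.
#'
#' @param expr cells x genes expression (or z-score) matrix.
#' @param labels named group labels covering the rows of `expr`.
#' @param groups the two group labels to compare.
#' @param genes genes of interest (default all).
#' @return Data frame: `gene`, `mean_1`, `mean_2`, `difference`,
#'   `t_statistic`, `p_value`, `test` (`"pooled"`/`"welch"`), sorted by
#'   `p_value`.
#' @export
compare_groups <- function(expr, labels, groups = NULL, genes = NULL) {
  labels <- labels[rownames(expr)]
  if (is.null(groups)) groups <- head(sort(unique(labels)), 2L)
  if (length(groups) != 2L) stop("exactly two groups are required", call. = FALSE)
  a <- expr[labels == groups[1], , drop = FALSE]
  b <- expr[labels == groups[2], , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 cells", call. = FALSE)
  }
  if (is.null(genes)) genes <- colnames(expr)
  res <- lapply(genes, function(g) {
    x <- a[, g]; y <- b[, g]
    if (sd(x) == 0 && sd(y) == 0) {
      # degenerate: constant in both groups
      return(data.frame(gene = g, mean_1 = mean(x), mean_2 = mean(y),
                        difference = mean(x) - mean(y),
                        t_statistic = 0,
                        p_value = if (mean(x) == mean(y)) 1 else 0,
                        test = "degenerate", stringsAsFactors = FALSE))
    }
    welch <- sd(x) > 0 && sd(y) > 0 && var.test(x, y)$p.value < 0.05
    tt <- t.test(x, y, var.equal = !welch)
    data.frame(gene = g, mean_1 = mean(x), mean_2 = mean(y),
               difference = mean(x) - mean(y),
               t_statistic = unname(tt$statistic),
               p_value = tt$p.value,
               test = if (welch) "welch" else "pooled",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value), , drop = FALSE]
}

#' Gene-gene correlation matrix across cells
#'
#' Pairwise correlation between gene vectors across the selected cells
#' (Pearson by default; Spearman available). Zero-variance genes have
#' undefined correlations, which are set to 0 and flagged.
#'
#' @param z cells x genes matrix (z-scores or expression).
#' @param cells optional cell subset (names or indices).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return genes x genes correlation matrix with attribute `zero_variance`.
#' @export
gene_correlation_matrix <- function(z, cells = NULL,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(cells)) z <- z[cells, , drop = FALSE]
  if (nrow(z) < 3L) stop("need at least 3 cells", call. = FALSE)
  flat <- apply(z, 2, sd) == 0
  cc <- suppressWarnings(cor(z, method = method))
  cc[flat, ] <- 0
  cc[, flat] <- 0
  diag(cc) <- ifelse(flat, 0, 1)
  attr(cc, "zero_variance") <- flat
  cc
}

#' Run the full single-cell qPCR pipeline on a set of arrays
#'
#' Per-array missing-value handling and LOD transform, merge into a combined
#' matrix, housekeeping QC, per-gene Winsorization, per-gene z-scores, and a
#' Ward cut into `k` clusters.
#'
#' @param arrays named list of cells x genes Ct matrices.
#' @param k number of clusters for the Ward cut.
#' @param lod,positive_cutoff,positive_fraction preprocessing parameters.
#' @param housekeeping,sd_limit QC parameters.
#' @param winsor_q lower/upper Winsorization quantiles.
#' @return List with `expr` (merged, QC'd, Winsorized log2exp matrix), `z`,
#'   `qc` (removed-cell report), `clusters` (a `cluster_assignment`).
#' @export
sc_pipeline <- function(arrays, k = 2L, lod = 24, positive_cutoff = 25,
                        positive_fraction = 0.10, housekeeping = "GAPDH",
                        sd_limit = 3, winsor_q = c(0.05, 0.95)) {
  expr <- do.call(rbind, lapply(arrays, ct_array_to_expression, lod = lod,
                                positive_cutoff = positive_cutoff,
                                positive_fraction = positive_fraction))
  qc <- qc_cells(expr, housekeeping = housekeeping, sd_limit = sd_limit)
  wins <- apply(qc$expr, 2, winsorize_gene,
                lower_q = winsor_q[1], upper_q = winsor_q[2])
  rownames(wins) <- rownames(qc$expr)
  z <- zscore_genes(wins)
  list(expr = wins, z = z, qc = qc$removed,
       clusters = ward_cluster(z, k))
}
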