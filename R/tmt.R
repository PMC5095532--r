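## TMT time-course screen: PSM -> protein rollup, baseline-band filtering
## (Method 1) and model-based mixture clustering (Method 2).

#' Roll PSM reporter intensities up to protein abundance profiles
#'
#' For each PSM the reporter channel intensities are normalized to the
#' time-zero channel (reference normalization, `x_i / x_1`); a protein's
#' abundance at each time point is the median of its PSM ratios, reported on
#' the log10 scale so that the time-zero column is exactly 0. Only proteins
#' supported by at least `min_unique_peptides` distinct unique-to-group
#' peptides are retained.
#'
#' @param psms PSM table: a data frame with columns `protein`, `peptide`,
#'   `unique` (logical), optionally `condition`, and one intensity column per
#'   time point named `t<hours>` (e.g. `t0`, `t8`, ...), time zero first.
#' @param min_unique_peptides minimum distinct unique peptides per protein.
#' @return An object of class `abundance_matrix`: a list with
#'   `log10_abundance` (proteins x time points, colnames in hours),
#'   `n_unique_peptides` (named count per retained protein) and `condition`.
#' @details PSMs whose reference (time-zero) intensity is not strictly
#'   positive cannot be ratio-normalized and are dropped with a warning.
#'   Multiplying all channels of a PSM by a positive constant leaves its
#'   ratios, and hence the rollup, unchanged.
#' @export
rollup_proteins <- function(psms, min_unique_peptides = 2L) {
  int_cols <- grep("^t[0-9]+$", names(psms), value = TRUE)
  if (length(int_cols) < 2L) {
    stop("PSM table must contain intensity columns t0, t8, ...", call. = FALSE)
  }
  tp <- as.numeric(sub("^t", "", int_cols))
  int_cols <- int_cols[order(tp)]
  tp <- sort(tp)
  if (tp[1] != 0) stop("time-zero column `t0` is required", call. = FALSE)

  intens <- as.matrix(psms[, int_cols])
  ref <- intens[, 1]
  bad <- !is.finite(ref) | ref <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d PSM(s) with non-positive reference intensity",
                    sum(bad)))
    psms <- psms[!bad, , drop = FALSE]
    intens <- intens[!bad, , drop = FALSE]
    ref <- ref[!bad]
  }
  if (nrow(psms) == 0L) stop("no usable PSMs", call. = FALSE)

  ratios <- intens / ref
  prot <- psms$protein
  upep <- tapply(psms$peptide[psms$unique], prot[psms$unique],
                 function(p) length(unique(p)))
  keep <- names(upep)[!is.na(upep) & upep >= min_unique_peptides]
  keep <- sort(keep)
  mat <- matrix(NA_real_, length(keep), length(tp),
                dimnames = list(keep, as.character(tp)))
  for (j in seq_along(tp)) {
    med <- tapply(ratios[, j], prot, median)
    mat[, j] <- log10(med[keep])
  }
  structure(list(log10_abundance = mat,
                 n_unique_peptides = upep[keep],
                 condition = if (!is.null(psms$condition)) psms$condition[1] else NA_character_),
            class = "abundance_matrix")
}

#' Derive the unstimulated-control baseline band
#'
#' The band envelope is anchored at one control time point (8 h by default):
#' `upper` is the maximum log10 relative abundance across control proteins at
#' the anchor time and `lower` the minimum (or `-upper` with
#' `lower = "symmetric"`). A control data set whose largest 8-h fold change
#' is 1.35 yields the +0.13 log10 threshold used to screen stimulated
#' profiles.
#'
#' @param control control-condition abundance matrix (an `abundance_matrix`
#'   or plain log10 matrix with time-point colnames).
#' @param anchor_time anchor time in hours (must be a sampled time point).
#' @param upper_override optional fixed upper edge (log10), e.g. `0.13`.
#' @param lower `"min"` (default) or `"symmetric"` (`-upper`).
#' @return An object of class `baseline_band`: list with `upper`, `lower`,
#'   `source`.
#' @export
derive_baseline_band <- function(control, anchor_time = 8,
                                 upper_override = NULL,
                                 lower = c("min", "symmetric")) {
  lower <- match.arg(lower)
  mat <- as_abundance_matrix(control)
  if (nrow(mat) == 0L) stop("empty control matrix", call. = FALSE)
  col <- match(as.character(anchor_time), colnames(mat))
  if (is.na(col)) stop("`anchor_time` is not a sampled time point", call. = FALSE)
  up <- if (!is.null(upper_override)) upper_override else max(mat[, col])
  lo <- switch(lower, min = min(mat[, col]), symmetric = -up)
  if (lo > 0) lo <- 0
  if (up < 0) up <- 0
  structure(list(upper = up, lower = lo,
                 source = sprintf("control envelope at %s h%s", anchor_time,
                                  if (!is.null(upper_override)) " (upper overridden)" else "")),
            class = "baseline_band")
}

#' Filter candidate regulators against the baseline band (Method 1)
#'
#' A protein is a candidate when its `M(IFNg)` profile exceeds the band's
#' upper edge at some time within `early_window` hours and stays above it at
#' every sampled time from `sustain_from` hours through the last time point,
#' while its `M(IL-4)` profile falls below the band's lower edge at some time
#' point. If a control matrix is supplied, the protein's own control profile
#' must additionally remain inside the band at all time points.
#'
#' @param ifng,il4 abundance matrices for the IFN-gamma and IL-4 stimulated
#'   conditions (shared protein ids and time grid).
#' @param band a [derive_baseline_band()] result.
#' @param control optional control abundance matrix for a per-protein
#'   containment check.
#' @param early_window latest time (h) by which the rise must appear.
#' @param sustain_from first time (h) from which the rise must be sustained.
#' @return A `candidate_list` data frame with columns `protein`, `method`.
#' @export
filter_candidates <- function(ifng, il4, band, control = NULL,
                              early_window = 24, sustain_from = 24) {
  ifng <- as_abundance_matrix(ifng)
  il4 <- as_abundance_matrix(il4)
  shared <- intersect(rownames(ifng), rownames(il4))
  if (length(shared) < max(nrow(ifng), nrow(il4))) {
    warning("protein universes differ; restricting to their intersection")
  }
  if (!is.null(control)) {
    control <- as_abundance_matrix(control)
    shared <- intersect(shared, rownames(control))
  }
  tp <- time_cols(ifng)
  early <- tp > 0 & tp <= early_window
  late <- tp >= sustain_from

  ifng <- ifng[shared, , drop = FALSE]
  il4 <- il4[shared, , drop = FALSE]
  rises <- apply(ifng[, early, drop = FALSE] > band$upper, 1, any)
  sustained <- apply(ifng[, late, drop = FALSE] > band$upper, 1, all)
  falls <- apply(il4 > band$lower, 1, function(x) any(!x))
  ok <- rises & sustained & falls
  if (!is.null(control)) {
    ctrl <- control[shared, , drop = FALSE]
    inside <- apply(ctrl >= band$lower & ctrl <= band$upper, 1, all)
    ok <- ok & inside
  }
  candidate_list(shared[ok], method = "filter")
}

candidate_list <- function(proteins, method, species = NA_character_) {
  proteins <- as.character(proteins)
  structure(data.frame(protein = proteins,
                       method = rep_len(method, length(proteins)),
                       species = rep_len(species, length(proteins)),
                       stringsAsFactors = FALSE),
            class = c("candidate_list", "data.frame"))
}

#' Sum-normalize linear-scale profiles
#'
#' Scales each profile (row) of a nonnegative linear-ratio matrix to sum to
#' one across time points, the normalization used before mixture clustering
#' so that the relationships between time points, rather than overall
#' abundance, drive the fit. All-zero profiles are dropped with a warning.
#'
#' @param mat nonnegative matrix, profiles in rows. Log10 abundance matrices
#'   should be converted with `10^x` first.
#' @return Matrix of the same shape (minus dropped rows) with unit row sums.
#' @export
sum_normalize <- function(mat) {
  mat <- as_abundance_matrix(mat)
  if (any(mat < 0)) stop("profiles must be nonnegative (linear ratio scale)",
                         call. = FALSE)
  s <- rowSums(mat)
  if (any(s == 0)) {
    warning(sprintf("dropping %d all-zero profile(s)", sum(s == 0)))
    mat <- mat[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  mat / s
}

#' Cluster protein profiles with a finite Gaussian mixture (Method 2)
#'
#' Fits Gaussian mixtures over a range of cluster counts by
#' expectation-maximization and selects the number of clusters by Bayesian
#' Information Criterion; profiles are hard-assigned to the cluster of
#' maximum posterior responsibility. Diagonal per-cluster covariances are
#' the default (stable for 6-point profiles); the full-covariance families
#' can be requested through `model_names`.
#'
#' @param profiles matrix of profiles in rows (typically [sum_normalize()]d
#'   linear profiles).
#' @param K_range candidate cluster counts.
#' @param model_names mclust covariance model names; default the diagonal
#'   family.
#' @return An object of class `cluster_model`: list with `K`, `assignment`
#'   (named), `bic` (per fitted K, larger is better), `means` (K x time
#'   matrix) and the underlying `fit`.
#' @export
cluster_profiles <- function(profiles, K_range = 1:9,
                             model_names = c("EII", "VII", "EEI", "VEI", "EVI", "VVI")) {
  profiles <- as_abundance_matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  K_range <- K_range[K_range >= 1 & K_range <= nrow(profiles)]
  if (!length(K_range)) stop("`K_range` outside [1, n_profiles]", call. = FALSE)

  if (nrow(unique(profiles)) == 1L) {
    # no structure at all: a single degenerate component
    return(structure(list(K = 1L,
                          assignment = setNames(rep(1L, nrow(profiles)),
                                                rownames(profiles)),
                          bic = c(`1` = NA_real_),
                          means = matrix(profiles[1, ], 1,
                                         dimnames = list("1", colnames(profiles))),
                          fit = NULL),
                     class = "cluster_model"))
  }
  fit <- Mclust(profiles, G = K_range, modelNames = model_names,
                        verbose = FALSE)
  if (is.null(fit)) stop("EM failed to fit any requested cluster count",
                         call. = FALSE)
  bic_by_K <- apply(fit$BIC, 1, function(r) suppressWarnings(max(r, na.rm = TRUE)))
  bic_by_K[!is.finite(bic_by_K)] <- NA_real_
  if (any(is.na(bic_by_K))) {
    warning("EM did not converge for some cluster counts; those K were skipped")
  }
  means <- t(fit$parameters$mean)
  dimnames(means) <- list(seq_len(fit$G), colnames(profiles))
  structure(list(K = fit$G,
                 assignment = setNames(fit$classification, rownames(profiles)),
                 bic = bic_by_K,
                 means = means,
                 fit = fit),
            class = "cluster_model")
}

# Trend labels for a cluster's mean log10 profile: operationalizes the
# visual inspection of cluster trends. `increasing` / `decreasing` refer to
# excursions above/below time zero; `within_band` to band containment.
cluster_trends <- function(model, log10_mat, band, tol = 0) {
  log10_mat <- as_abundance_matrix(log10_mat)
  ids <- intersect(names(model$assignment), rownames(log10_mat))
  out <- lapply(seq_len(model$K), function(k) {
    members <- ids[model$assignment[ids] == k]
    if (!length(members)) {
      return(list(increasing = FALSE, decreasing = FALSE, within_band = TRUE))
    }
    m <- colMeans(log10_mat[members, , drop = FALSE])
    list(increasing = any(m > tol),
         decreasing = any(m < -tol),
         within_band = all(m >= band$lower & m <= band$upper))
  })
  out
}

#' Select candidate proteins from condition-wise cluster models (Method 2)
#'
#' A protein is selected when it belongs to a cluster whose mean log10
#' profile rises above time zero at any time point in `M(IFNg)`, to a
#' cluster whose mean falls below time zero at any time point in `M(IL-4)`,
#' and to a cluster whose mean stays within the baseline band in `M(-)`.
#'
#' @param models named list of [cluster_profiles()] results with elements
#'   `ifng`, `il4`, `control`.
#' @param ifng,il4,control the corresponding log10 abundance matrices used
#'   to evaluate cluster mean trends.
#' @param band a [derive_baseline_band()] result.
#' @param tol half-width of the dead zone around zero when calling a cluster
#'   mean "increasing"/"decreasing".
#' @return A `candidate_list` data frame (`method = "cluster"`).
#' @export
select_clusters <- function(models, ifng, il4, control, band, tol = 0) {
  stopifnot(all(c("ifng", "il4", "control") %in% names(models)))
  tr_i <- cluster_trends(models$ifng, ifng, band, tol)
  tr_4 <- cluster_trends(models$il4, il4, band, tol)
  tr_c <- cluster_trends(models$control, control, band, tol)
  shared <- Reduce(intersect, list(names(models$ifng$assignment),
                                   names(models$il4$assignment),
                                   names(models$control$assignment)))
  ok <- vapply(shared, function(p) {
    tr_i[[models$ifng$assignment[p]]]$increasing &&
      tr_4[[models$il4$assignment[p]]]$decreasing &&
      tr_c[[models$control$assignment[p]]]$within_band
  }, logical(1))
  candidate_list(shared[ok], method = "cluster")
}

#' Intersect candidate lists across species
#'
#' Prioritizes candidates found in both species' screens. Identifiers are
#' matched by uppercased gene symbol by default; a two-column `id_map`
#' (`from`, `to`) can supply an explicit orthology mapping applied to both
#' lists. Unmapped identifiers are excluded and counted in a message.
#'
#' @param list_a,list_b `candidate_list` data frames (or character vectors).
#' @param id_map optional data frame with columns `from`, `to`.
#' @return A `candidate_list` tagged `species = "both"`, with `method`
#'   combining the per-list tags.
#' @export
intersect_species <- function(list_a, list_b, id_map = NULL) {
  ids <- function(x) if (is.data.frame(x)) x$protein else as.character(x)
  map <- function(x) {
    if (is.null(id_map)) return(toupper(x))
    m <- id_map$to[match(toupper(x), toupper(id_map$from))]
    n_unmapped <- sum(is.na(m))
    if (n_unmapped > 0) {
      message(sprintf("%d identifier(s) not covered by id_map were excluded",
                      n_unmapped))
    }
    toupper(m)
  }
  a <- map(ids(list_a)); b <- map(ids(list_b))
  common <- sort(intersect(a[!is.na(a)], b[!is.na(b)]))
  method_a <- if (is.data.frame(list_a)) list_a$method[1] else "a"
  method_b <- if (is.data.frame(list_b)) list_b$method[1] else "b"
  out <- candidate_list(common,
                        method = if (identical(method_a, method_b)) method_a
                                 else paste(method_a, method_b, sep = "+"),
                        species = "both")
  out
}

#' Row z-score matrix and dendrogram ordering for heat maps
#'
#' Centers and scales each profile to mean 0 and s.d. 1 (`z = (x - mean) /
#' s.d.`), then orders rows by the leaf order of an average-linkage
#' hierarchical tree on Euclidean distances. Constant rows get z-scores of 0
#' with a warning.
#'
#' @param profiles matrix with profiles in rows (at least 2 rows).
#' @return List with `z` (row-standardized matrix in original row order),
#'   `order` (leaf order indices), and `hclust` (the tree).
#' @export
heatmap_matrix <- function(profiles) {
  profiles <- as_abundance_matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(profiles, 1, sd)
  z <- (profiles - rowMeans(profiles)) / sds
  if (any(sds == 0)) {
    warning(sprintf("%d constant row(s); z-scores set to 0", sum(sds == 0)))
    z[sds == 0, ] <- 0
  }
  hc <- hclust(dist(z, method = "euclidean"), method = "average")
  list(z = z, order = hc$order, hclust = hc)
}
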