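## Independent brute-force oracles used to cross-check the implementation.
## These deliberately share no code with the package internals.

# Naive double-loop Manhattan distance.
naive_manhattan <- function(z) {
  n <- nrow(z)
  D <- matrix(0, n, n, dimnames = list(rownames(z), rownames(z)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(abs(z[i, ] - z[j, ]))
  }
  D
}

# Naive covariance / (sigma * sigma) Pearson correlation.
naive_correlation <- function(z) {
  g <- ncol(z)
  R <- matrix(NA_real_, g, g, dimnames = list(colnames(z), colnames(z)))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    x <- z[, i]; y <- z[, j]
    R[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      ((length(x) - 1) * sd(x) * sd(y))
  }
  R
}

# Exhaustive minimum spanning tree: enumerate all (n-1)-edge subsets of the
# complete graph, keep acyclic connected ones, return the minimal total
# weight. Feasible for n <= 6.
exhaustive_mst_weight <- function(D) {
  n <- nrow(D)
  pairs <- t(combn(n, 2))
  w <- D[pairs]
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    # union-find acyclicity check
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}

# Hand-rolled breadth-first search distances from one vertex over an
# edge-list representation.
bfs_distances <- function(edges, nodes, from) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- setNames(rep(Inf, length(nodes)), nodes)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!is.finite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

# Closed-form random walk with restart: p = r (I - (1 - r) W)^{-1} p0,
# with W the column-normalized adjacency matrix (dense linear algebra).
rwr_closed_form <- function(A, seeds, r) {
  W <- sweep(A, 2, pmax(colSums(A), 1), "/")
  p0 <- setNames(numeric(nrow(A)), rownames(A))
  p0[seeds] <- 1 / length(seeds)
  p <- r * solve(diag(nrow(A)) - (1 - r) * W, p0)
  setNames(as.numeric(p), rownames(A))
}

# Greedy Ward merging from first principles: at each step merge the pair of
# clusters with the smallest increase in within-cluster sum of squares.
# Returns the sequence of merged leaf-sets.
greedy_ward_merges <- function(points) {
  clusters <- lapply(seq_len(nrow(points)), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      a <- points[clusters[[i]], , drop = FALSE]
      b <- points[clusters[[j]], , drop = FALSE]
      delta <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
        sum((colMeans(a) - colMeans(b))^2)
      if (delta < best[1]) best <- c(delta, i, j)
    }
    merged <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  merges
}

# Greedy average-linkage merging on Euclidean distances; returns merged
# leaf-sets in order.
greedy_average_linkage <- function(z) {
  D <- as.matrix(dist(z))
  clusters <- lapply(seq_len(nrow(z)), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    merged <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  merges
}

# Leaf-sets produced by an hclust merge matrix, in merge order.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[k, ], function(m)
      if (m < 0) -m else sets[[m]]))
    sets[[k]] <- sort(members)
  }
  sets
}

# Small helper: PSM table row for hand-built fixtures.
psm_row <- function(protein, peptide, ratios, base = 1e6, psm_id = NULL,
                    condition = "M(IFNg)") {
  intens <- as.list(base * ratios)
  names(intens) <- paste0("t", c(0, 8, 12, 24, 48, 72))
  cbind(data.frame(psm_id = if (is.null(psm_id)) paste0(protein, "_", peptide) else psm_id,
                   protein = protein, peptide = peptide, unique = TRUE,
                   condition = condition, stringsAsFactors = FALSE),
        as.data.frame(intens))
}

# Log10 abundance matrix with standard time columns.
abund <- function(..., timepoints = c(0, 8, 12, 24, 48, 72)) {
  rows <- list(...)
  mat <- do.call(rbind, rows)
  colnames(mat) <- as.character(timepoints)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("P", seq_len(nrow(mat)))
  mat
}
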