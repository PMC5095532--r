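#' Configuration for the synthetic functional interactome
#'
#' Describes a preferential-attachment random graph with two designated seed
#' genes (their degrees topped up to `seed_neighbor_counts`), one disease
#' module planted in the immediate vicinity of the seed neighbourhood, and
#' several distal disease modules drawn from nodes at graph distance greater
#' than 2 from every seed neighbour. A random `expressed_fraction` of genes is
#' marked as expressed in macrophages.
#'
#' @param n_genes number of genes (graph order).
#' @param attachment_parameter edges added per node during preferential
#'   attachment; 1 gives a sparse tree-like backbone with a heavy-tailed
#'   degree distribution, which keeps shortest-path distances informative at
#'   this graph size.
#' @param proximal_module_size,distal_module_size sizes of the planted
#'   disease modules; must be smaller than `n_genes`.
#' @param n_distal_modules number of distal modules.
#' @param seed_neighbor_counts length-2 vector: target first-neighbour counts
#'   of the two seed genes.
#' @param expressed_fraction fraction of genes marked expressed, in (0, 1].
#' @param proximal_radius the proximal module is sampled from nodes within
#'   this graph distance of the seed neighbour set (0 = from the neighbours
#'   themselves); must be <= 2 so the planted module stays in the
#'   2-neighbourhood.
#' @param rng_seed integer seed.
#' @return An object of class `net_sim_config`.
#' @export
net_sim_config <- function(n_genes = 3000L,
                           attachment_parameter = 1L,
                           proximal_module_size = 30L,
                           distal_module_size = 30L,
                           n_distal_modules = 3L,
                           seed_neighbor_counts = c(15L, 30L),
                           expressed_fraction = 0.8,
                           proximal_radius = 1L,
                           rng_seed = 1L) {
  stop_if_not_count(n_genes, "n_genes", min = 10L)
  stop_if_not_count(attachment_parameter, "attachment_parameter")
  stop_if_not_count(proximal_module_size, "proximal_module_size")
  stop_if_not_count(distal_module_size, "distal_module_size")
  stop_if_not_count(n_distal_modules, "n_distal_modules")
  if (proximal_module_size >= n_genes || distal_module_size >= n_genes) {
    stop("module sizes must be smaller than `n_genes`", call. = FALSE)
  }
  if (length(seed_neighbor_counts) != 2L) {
    stop("`seed_neighbor_counts` must have length 2", call. = FALSE)
  }
  stop_if_not_prob(expressed_fraction, "expressed_fraction", open_left = TRUE)
  if (!proximal_radius %in% 0:2) {
    stop("`proximal_radius` must be 0, 1 or 2", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 attachment_parameter = as.integer(attachment_parameter),
                 proximal_module_size = as.integer(proximal_module_size),
                 distal_module_size = as.integer(distal_module_size),
                 n_distal_modules = as.integer(n_distal_modules),
                 seed_neighbor_counts = as.integer(seed_neighbor_counts),
                 expressed_fraction = expressed_fraction,
                 proximal_radius = as.integer(proximal_radius),
                 rng_seed = as.integer(rng_seed)),
            class = "net_sim_config")
}

#' Simulate a functional interactome with planted disease modules
#'
#' Builds a connected preferential-attachment graph, designates two seed
#' genes whose degrees are topped up to the configured first-neighbour
#' counts, and plants one proximal disease module (sampled from within
#' `proximal_radius` of the seed neighbour set, i.e. inside its
#' 2-neighbourhood) plus `n_distal_modules` distal modules (sampled
#' uniformly from nodes farther than distance 2 from every seed neighbour).
#'
#' @param cfg a [net_sim_config()].
#' @return A list with elements `network` (an undirected [igraph] graph with
#'   named vertices), `disease_modules` (named list of gene vectors; the
#'   planted proximal module is named `"proximal"`), `seeds` (the two seed
#'   gene names), `expressed` (expressed gene names), and `truth` (labels
#'   mapping each module name to `"proximal"`/`"distal"`).
#' @export
simulate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "net_sim_config"))
  with_seed(cfg$rng_seed, {
    g <- igraph::sample_pa(cfg$n_genes, m = cfg$attachment_parameter,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("g%05d", seq_len(cfg$n_genes))
    seeds <- sample(igraph::V(g)$name, 2L)
    for (i in 1:2) {
      s <- seeds[i]
      need <- cfg$seed_neighbor_counts[i] - igraph::degree(g, s)
      if (need > 0) {
        pool <- setdiff(igraph::V(g)$name,
                        c(s, names(igraph::neighbors(g, s))))
        g <- igraph::add_edges(g, as.vector(rbind(s, sample(pool, need))))
      }
    }
    nbrs <- unique(c(names(igraph::neighbors(g, seeds[1])),
                     names(igraph::neighbors(g, seeds[2]))))
    d_min <- apply(igraph::distances(g, v = nbrs), 2, min)
    eligible <- setdiff(names(d_min)[d_min <= cfg$proximal_radius], seeds)
    elsewhere <- setdiff(names(d_min)[d_min > 2], seeds)
    if (length(eligible) < cfg$proximal_module_size) {
      stop("proximal neighbourhood smaller than requested module size",
           call. = FALSE)
    }
    needed <- cfg$distal_module_size * cfg$n_distal_modules
    if (length(elsewhere) < needed) {
      stop("not enough distal genes for the requested distal modules; ",
           "increase `n_genes` or decrease module sizes", call. = FALSE)
    }
    modules <- list(proximal = sample(eligible, cfg$proximal_module_size))
    for (i in seq_len(cfg$n_distal_modules)) {
      modules[[paste0("distal", i)]] <- sample(elsewhere, cfg$distal_module_size)
    }
    expressed <- sample(igraph::V(g)$name,
                        round(cfg$expressed_fraction * cfg$n_genes))
    labels <- setNames(c("proximal", rep("distal", cfg$n_distal_modules)),
                       names(modules))
    list(network = g,
         disease_modules = modules,
         seeds = seeds,
         expressed = expressed,
         truth = list(stage = "network", labels = labels, config = cfg))
  })
}
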