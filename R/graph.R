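# Per-species pocket-similarity graphs: max-normalised weighted and
# thresholded unweighted graphs, singleton detection (alignment-based,
# pre-threshold), Leiden community detection, and three null models
# (degree-preserving rewiring, same-density random graphs, score-matrix
# permutation).

#' Restrict a similarity matrix to a pocket subset
#'
#' Induced submatrix over the given pocket ids (e.g. the pockets
#' surviving quality filters), preserving order of `ids`.
#'
#' @param sim a [similarity_matrix()].
#' @param ids pocket ids to keep.
#' @return a [similarity_matrix()].
#' @export
subset_similarity <- function(sim, ids) {
  ids <- intersect(ids, sim$pocket_ids)
  sc <- sim$scores[ids, ids, drop = FALSE]
  tri <- Matrix::which(sc != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  similarity_matrix(ids, tri[, 1], tri[, 2], sc[tri], species = sim$species)
}

#' Build a pocket-similarity graph
#'
#' Normalises raw alignment scores by the species maximum and keeps both a
#' weighted graph over all scored pairs and an unweighted graph with an
#' edge wherever the normalised score strictly exceeds `edge_threshold`.
#'
#' @param sim a [similarity_matrix()].
#' @param edge_threshold normalised-score cutoff; edges require a strictly
#'   greater value.
#' @return list of class `pocket_graph` with `species`, `nodes`,
#'   `weighted` and `unweighted` igraph objects, and `normalization_max`.
#' @export
build_graph <- function(sim, edge_threshold = 0.1) {
  sc <- sim$scores
  if (any(sc@x < 0)) stop("negative raw similarity score", call. = FALSE)
  nmax <- if (Matrix::nnzero(sc) > 0L) max(sc@x) else NA_real_
  n <- length(sim$pocket_ids)
  tri <- Matrix::which(sc != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  w <- if (nrow(tri) > 0L) sc[tri] / nmax else numeric()
  weighted <- igraph::graph_from_data_frame(
    data.frame(from = sim$pocket_ids[tri[, 1]], to = sim$pocket_ids[tri[, 2]],
               weight = w),
    directed = FALSE,
    vertices = data.frame(name = sim$pocket_ids)
  )
  keep <- w > edge_threshold
  unweighted <- igraph::graph_from_data_frame(
    data.frame(from = sim$pocket_ids[tri[keep, 1]],
               to = sim$pocket_ids[tri[keep, 2]]),
    directed = FALSE,
    vertices = data.frame(name = sim$pocket_ids)
  )
  structure(
    list(species = sim$species, nodes = sim$pocket_ids, weighted = weighted,
         unweighted = unweighted, normalization_max = nmax,
         edge_threshold = edge_threshold),
    class = "pocket_graph"
  )
}

#' @export
print.pocket_graph <- function(x, ...) {
  cat(sprintf(
    "<pocket_graph %s: %d nodes, %d weighted / %d thresholded edges>\n",
    x$species, length(x$nodes), igraph::ecount(x$weighted),
    igraph::ecount(x$unweighted)))
  invisible(x)
}

#' Alignment-based singletons
#'
#' Pockets with no nonzero raw alignment score to any other pocket of the
#' species (defined on the raw matrix, before normalisation and
#' thresholding).
#'
#' @param sim a [similarity_matrix()].
#' @return character vector of singleton pocket ids.
#' @export
find_singletons <- function(sim) {
  deg <- Matrix::rowSums(sim$scores != 0)
  sim$pocket_ids[deg == 0]
}

#' Connected components under a raw-score threshold
#'
#' Sets an edge wherever the raw score is at least `raw_threshold` and
#' counts connected components; size-1 components are reported as
#' singletons.
#'
#' @param sim a [similarity_matrix()].
#' @param raw_threshold raw-score edge cutoff (inclusive).
#' @return a clustering result (see [clustering_result()]).
#' @export
components_at_threshold <- function(sim, raw_threshold) {
  sc <- sim$scores
  tri <- Matrix::which(sc != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2] & sc[tri] >= raw_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = sim$pocket_ids[tri[, 1]], to = sim$pocket_ids[tri[, 2]]),
    directed = FALSE, vertices = data.frame(name = sim$pocket_ids)
  )
  comp <- igraph::components(g)
  membership <- split(sim$pocket_ids, comp$membership)
  sizes <- vapply(membership, length, 1L)
  clustering_result(
    species = sim$species,
    communities = unname(membership[sizes >= 2L]),
    singletons = unlist(membership[sizes == 1L], use.names = FALSE)
  )
}

#' Assemble a clustering result
#'
#' @param species species mnemonic.
#' @param communities list of node-id vectors, each of size >= 2.
#' @param singletons character vector of isolated node ids.
#' @param threshold_isolated nodes isolated by edge thresholding only
#'   (tracked separately from alignment-based singletons).
#' @return list of class `clustering_result` with `n_unique` =
#'   communities + singletons and `largest_community`.
#' @export
clustering_result <- function(species, communities, singletons,
                              threshold_isolated = character()) {
  sizes <- vapply(communities, length, 1L)
  stopifnot(all(sizes >= 2L))
  all_nodes <- c(unlist(communities, use.names = FALSE), singletons,
                 threshold_isolated)
  if (anyDuplicated(all_nodes)) {
    stop("communities and singletons must partition the node set", call. = FALSE)
  }
  structure(
    list(species = species, communities = communities,
         singletons = as.character(singletons),
         threshold_isolated = as.character(threshold_isolated),
         n_communities = length(communities),
         n_singletons = length(singletons),
         n_unique = length(communities) + length(singletons),
         largest_community = if (length(sizes)) max(sizes) else 0L),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "<clustering_result %s: %d communities + %d singletons = %d unique (largest %d)>\n",
    x$species, x$n_communities, x$n_singletons, x$n_unique,
    x$largest_community))
  invisible(x)
}

#' Leiden community detection on a pocket graph
#'
#' Runs the Leiden algorithm (constant Potts model objective) on the
#' non-singleton subgraph; degree-0 nodes of the chosen graph are held out
#' as singleton-type nodes and never merged. Partition communities of size
#' 1 (possible on thresholded graphs) are reported as
#' `threshold_isolated`.
#'
#' @param graph a [build_graph()] result.
#' @param resolution Leiden resolution parameter.
#' @param weighted use the normalised-score-weighted graph instead of the
#'   thresholded unweighted one.
#' @param seed RNG seed for reproducible refinement.
#' @param singletons alignment-based singleton ids (from
#'   [find_singletons()]); defaults to the degree-0 nodes of the chosen
#'   graph.
#' @return a [clustering_result()].
#' @export
leiden_communities <- function(graph, resolution = 0.01, weighted = FALSE,
                               seed = 1L, singletons = NULL) {
  g <- if (weighted) graph$weighted else graph$unweighted
  deg <- igraph::degree(g)
  iso <- names(deg)[deg == 0]
  if (is.null(singletons)) {
    singletons <- iso
    threshold_iso <- character()
  } else {
    threshold_iso <- setdiff(iso, singletons)
  }
  core <- igraph::delete_vertices(g, iso)
  communities <- list()
  part_iso <- character()
  if (igraph::vcount(core) > 0L) {
    withr_seed <- function(expr) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      expr
    }
    memb <- withr_seed(igraph::cluster_leiden(
      core, objective_function = "CPM", resolution = resolution,
      weights = if (weighted) igraph::E(core)$weight else NULL,
      n_iterations = 5
    ))
    groups <- split(igraph::V(core)$name, igraph::membership(memb))
    sizes <- vapply(groups, length, 1L)
    communities <- unname(groups[sizes >= 2L])
    part_iso <- unlist(groups[sizes == 1L], use.names = FALSE)
  }
  clustering_result(
    species = graph$species, communities = communities,
    singletons = singletons,
    threshold_isolated = c(threshold_iso, part_iso)
  )
}

#' Degree-preserving rewiring null model
#'
#' Randomises the unweighted graph by double-edge swaps, preserving every
#' node's degree and introducing no self-loops or multi-edges.
#'
#' @param graph a [build_graph()] result.
#' @param n_swaps number of attempted swaps; defaults to 10 x edge count,
#'   enough to mix the edge set.
#' @param seed RNG seed.
#' @return a `pocket_graph` with the rewired unweighted graph.
#' @export
rewire_degree_preserving <- function(graph, n_swaps = NULL, seed = 1L) {
  g <- graph$unweighted
  if (is.null(n_swaps)) n_swaps <- 10L * max(igraph::ecount(g), 1L)
  set.seed(seed)
  rg <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  out <- graph
  out$unweighted <- rg
  out$weighted <- rg
  out
}

#' Same-density random-graph null model
#'
#' Uniform random graph with the same node and edge counts as the
#' unweighted graph.
#'
#' @param graph a [build_graph()] result.
#' @param seed RNG seed.
#' @return a `pocket_graph` with the random unweighted graph.
#' @export
random_graph_same_density <- function(graph, seed = 1L) {
  g <- graph$unweighted
  set.seed(seed)
  rg <- igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
  igraph::V(rg)$name <- igraph::V(g)$name
  out <- graph
  out$unweighted <- rg
  out$weighted <- rg
  out
}

#' Score-matrix permutation null model
#'
#' Redistributes the multiset of nonzero off-diagonal scores over
#' uniformly random distinct off-diagonal positions, keeping the matrix
#' symmetric.
#'
#' @param sim a [similarity_matrix()].
#' @param seed RNG seed.
#' @return a [similarity_matrix()] with permuted scores.
#' @export
randomize_score_matrix <- function(sim, seed = 1L) {
  sc <- sim$scores
  n <- length(sim$pocket_ids)
  tri <- Matrix::which(sc != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  m <- nrow(tri)
  scores <- if (m > 0L) sc[tri] else numeric()
  set.seed(seed)
  n_pairs <- n * (n - 1) / 2
  pos <- sample.int(n_pairs, m)
  # map linear upper-triangle index (column-major) back to (i, j)
  j <- ceiling((sqrt(8 * pos + 1) + 1) / 2)
  i <- pos - (j - 1) * (j - 2) / 2
  similarity_matrix(sim$pocket_ids, i = as.integer(i), j = as.integer(j),
                    score = sample(scores), species = sim$species)
}

#' Community-size histogram with log-log slope
#'
#' Tabulates community sizes and fits an ordinary least-squares line to
#' log(frequency) against log(size), summarising the heavy-tailed size
#' distribution.
#'
#' @param result a [clustering_result()].
#' @return list with `histogram` (data.frame `size`, `frequency`) and
#'   `loglog_slope` (`NA` with fewer than 3 distinct sizes).
#' @export
cluster_size_histogram <- function(result) {
  sizes <- vapply(result$communities, length, 1L)
  tab <- table(sizes)
  hist <- data.frame(size = as.integer(names(tab)),
                     frequency = as.integer(tab))
  slope <- NA_real_
  if (nrow(hist) >= 3L) {
    # frequency-weighted fit: sparse tail bins carry large log-count
    # noise and would otherwise dominate the slope
    fit <- stats::lm(log(frequency) ~ log(size), data = hist,
                     weights = hist$frequency)
    slope <- unname(stats::coef(fit)[2])
  }
  list(histogram = hist, loglog_slope = slope)
}
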