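# Cross-species power-law scaling of pocketome diversity: ordinary least
# squares of ln(unique pocket clusters) on ln(fold clusters), and null
# fits obtained by re-clustering randomized similarity graphs.

#' Per-species cluster statistics
#'
#' @param species character vector of mnemonics.
#' @param n_fs fold-cluster counts (proteome-diversity proxy).
#' @param n_pocket_clusters unique pockets (communities + singletons).
#' @param n_communities communities only.
#' @return data.frame of class `species_cluster_stats`.
#' @export
species_cluster_stats <- function(species, n_fs, n_pocket_clusters,
                                  n_communities = NA_integer_) {
  df <- data.frame(
    species = as.character(species), n_fs = as.numeric(n_fs),
    n_pocket_clusters = as.numeric(n_pocket_clusters),
    n_communities = as.numeric(n_communities), stringsAsFactors = FALSE
  )
  if (any(df$n_fs < 0 | df$n_pocket_clusters < 0, na.rm = TRUE)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  ok <- is.na(df$n_communities) | df$n_pocket_clusters >= df$n_communities
  if (!all(ok)) {
    stop("n_pocket_clusters must be >= n_communities", call. = FALSE)
  }
  class(df) <- c("species_cluster_stats", "data.frame")
  df
}

#' Fit the proteome-to-pocketome power law
#'
#' Ordinary least squares of `ln(response)` on `ln(n_fs)` across species.
#' The slope is the scaling exponent `a` of `N_pockets ~ N_FS^a`; the
#' intercept is reported on the natural-log scale, and the Pearson
#' correlation is computed on the log-log pairs.
#'
#' @param stats a [species_cluster_stats()] data.frame.
#' @param response `"unique"` (communities + singletons) or
#'   `"communities"`.
#' @return list of class `scaling_fit` with `slope`, `intercept`,
#'   `pearson_r`, `n_points`.
#' @export
fit_power_law <- function(stats, response = c("unique", "communities")) {
  response <- match.arg(response)
  y <- if (response == "unique") stats$n_pocket_clusters else stats$n_communities
  x <- stats$n_fs
  if (any(is.na(y)) || any(y <= 0) || any(x <= 0)) {
    stop("all counts must be > 0 for a log-log fit", call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = stats::cor(lx, ly), n_points = length(x)),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit: slope %.3f, intercept %.3f, r %.3f, n %d>\n",
              x$slope, x$intercept, x$pearson_r, x$n_points))
  invisible(x)
}

#' Null-model scaling exponents
#'
#' For each replicate, randomizes every species' similarity graph with the
#' chosen null model, re-clusters it with the Leiden algorithm, recounts
#' unique pockets (communities + singletons) and refits the power law.
#' Alignment-based singletons keep degree 0 under the rewiring and
#' score-permutation nulls and remain singletons.
#'
#' @param sims list of [similarity_matrix()] objects (one per species).
#' @param n_fs named numeric vector of fold-cluster counts keyed by
#'   species mnemonic.
#' @param null_kind `"degree_preserving"`, `"erdos_renyi"`, or
#'   `"score_permutation"`.
#' @param n_replicates number of randomization runs (>= 2).
#' @param seed base RNG seed; replicate r uses `seed + r`.
#' @param edge_threshold,resolution graph and Leiden parameters.
#' @param response passed to [fit_power_law()].
#' @return list with `mean`, `sd`, and `slopes` (per replicate).
#' @export
null_scaling <- function(sims, n_fs,
                         null_kind = c("degree_preserving", "erdos_renyi",
                                       "score_permutation"),
                         n_replicates = 5L, seed = 1L, edge_threshold = 0.1,
                         resolution = 0.01, response = "unique") {
  null_kind <- match.arg(null_kind)
  if (n_replicates < 2L) {
    stop("at least 2 replicates are needed for a standard deviation",
         call. = FALSE)
  }
  slopes <- vapply(seq_len(n_replicates), function(r) {
    st <- do.call(rbind, lapply(sims, function(sim) {
      rseed <- (seed + r * 1009L + abs(sum(utf8ToInt(sim$species)))) %% .Machine$integer.max
      if (null_kind == "score_permutation") {
        sim_r <- randomize_score_matrix(sim, seed = rseed)
        g <- build_graph(sim_r, edge_threshold)
        singles <- find_singletons(sim_r)
      } else {
        g <- build_graph(sim, edge_threshold)
        g <- if (null_kind == "degree_preserving") {
          rewire_degree_preserving(g, seed = rseed)
        } else {
          random_graph_same_density(g, seed = rseed)
        }
        singles <- NULL
      }
      cl <- leiden_communities(g, resolution = resolution, seed = rseed,
                               singletons = singles)
      species_cluster_stats(sim$species, n_fs[[sim$species]], cl$n_unique,
                            cl$n_communities)
    }))
    fit_power_law(st, response = response)$slope
  }, 0)
  list(mean = mean(slopes), sd = stats::sd(slopes), slopes = slopes,
       null_kind = null_kind)
}
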