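# End-to-end orchestration: load inputs, filter, match and enrich,
# compute descriptors, cluster similarity graphs, fit the scaling law,
# and map embedding entropy; every stage writes a TSV and logs record
# counts, and a summary JSON collects the per-species and per-class
# statistics.

#' Pipeline configuration
#'
#' @param input_dir directory laid out as by [write_synthetic_inputs()]:
#'   `structures/`, `pae/`, `pockets/`, `similarity/`, `proteins.tsv`,
#'   `annotations.tsv`, `ontology.tsv`, `fold_clusters.tsv`,
#'   `fold_cluster_counts.tsv`, `domains.tsv`, `embeddings.tsv`,
#'   `embedding_labels.tsv`.
#' @param output_dir where stage outputs are written.
#' @param seed master seed for all stochastic stages.
#' @param filters a [filter_config()].
#' @param edge_threshold,resolution similarity-graph parameters.
#' @param sasa_points sphere points per atom for SASA.
#' @param projection_method,tsne_iterations,perplexity projection stage.
#' @param entropy_bins,entropy_min_count entropy-grid geometry.
#' @param entropy_label label column for the entropy map (`"kingdom"` or
#'   `"species"`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, seed = 1L,
                            filters = filter_config(), edge_threshold = 0.1,
                            resolution = 0.01, sasa_points = 960L,
                            projection_method = "tsne",
                            tsne_iterations = 500L, perplexity = 50,
                            entropy_bins = 50L, entropy_min_count = 20L,
                            entropy_label = "kingdom") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every threshold of the analysis is a named key; omitted keys fall
#' back to the package defaults.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  filt <- do.call(filter_config, y$filters %||% list())
  y$filters <- NULL
  do.call(pipeline_config, c(y, list(filters = filt)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pocketome pipeline
#'
#' Stages run in order: load, filter, annotate/enrich, descriptors,
#' cluster, scaling, embedding entropy. Each stage writes its table to
#' the output directory and logs record counts; `summary.json` collects
#' the per-species pocket and clustering statistics, the enrichment
#' table and the scaling fit. Outputs are identical under identical
#' seeds.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(cfg) {
  ind <- cfg$input_dir
  required <- c("proteins.tsv", "annotations.tsv", "ontology.tsv",
                "fold_cluster_counts.tsv", "pockets", "similarity",
                "structures", "pae", "embeddings.tsv", "embedding_labels.tsv")
  missing <- required[!file.exists(file.path(ind, required))]
  if (length(missing) > 0L) {
    stop("missing pipeline input(s): ",
         paste(file.path(ind, missing), collapse = ", "), call. = FALSE)
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  set.seed(cfg$seed)

  # -- load ---------------------------------------------------------------
  proteins <- run_stage("load", {
    meta <- utils::read.delim(file.path(ind, "proteins.tsv"),
                              stringsAsFactors = FALSE)
    plist <- lapply(seq_len(nrow(meta)), function(r) {
      id <- meta$protein_id[r]
      st <- read_structure_confidence(file.path(ind, "structures",
                                                paste0(id, ".pdb")))
      pae <- read_pae_json(file.path(ind, "pae", paste0(id, ".json")))
      protein_record(
        protein_id = id, species = meta$species[r], sequence = st$sequence,
        ca_coords = st$ca_coords, plddt = st$plddt, pae = pae,
        is_fragment = meta$is_fragment[r],
        tm_checks_passed = meta$tm_checks_passed[r]
      )
    })
    stats::setNames(plist, meta$protein_id)
  })
  pockets <- run_stage("load", {
    files <- list.files(file.path(ind, "pockets"), full.names = TRUE,
                        pattern = "\\.csv$")
    do.call(rbind, lapply(files, read_p2rank_table))
  })
  pipeline_log("load", "%d proteins, %d pockets", length(proteins),
               nrow(pockets))

  # -- filter -------------------------------------------------------------
  filtered <- run_stage("filter", filter_cohort(pockets, proteins, cfg$filters))
  utils::write.table(
    data.frame(reason = names(filtered$counts),
               n_pockets = as.integer(filtered$counts)),
    out("filter_summary.tsv"), sep = "\t", row.names = FALSE, quote = FALSE
  )
  pipeline_log("filter", "%d of %d pockets pass", nrow(filtered$pockets),
               nrow(pockets))

  # -- annotate / enrich --------------------------------------------------
  enrichment <- run_stage("enrich", {
    sites <- read_annotation_table(file.path(ind, "annotations.tsv"))
    ontology <- read_ontology(file.path(ind, "ontology.tsv"))
    split_sites <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s) {
      prot <- proteins[[sites$protein_id[s]]]
      coords <- stats::setNames(list(prot$ca_coords), prot$chain)
      split_interchain_site(sites[s, ], coords,
                            min_residues = cfg$filters$min_known_site_residues)
    }))
    matches <- match_known_to_predicted(split_sites, filtered$pockets)
    classes <- lapply(split_sites$ligand_chebi, assign_compound_class, ontology)
    enr <- enrichment_table(matches$found, classes)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pipeline_log("enrich", "%d sites (%d found), %d classes",
                 nrow(split_sites), sum(matches$found), nrow(enr))
    list(table = enr, n_sites = nrow(split_sites),
         n_found = sum(matches$found))
  })

  # -- descriptors --------------------------------------------------------
  descriptors <- run_stage("descriptors", {
    d <- compute_descriptors(filtered$pockets, proteins,
                             n_points = cfg$sasa_points)
    utils::write.table(d, out("descriptors.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pipeline_log("descriptors", "%d pockets described", nrow(d))
    d
  })

  # -- cluster ------------------------------------------------------------
  clusterings <- run_stage("cluster", {
    files <- list.files(file.path(ind, "similarity"), pattern = "\\.tsv$",
                        full.names = TRUE)
    res <- lapply(files, function(f) {
      species <- sub("\\.tsv$", "", basename(f))
      nodes_file <- sub("\\.tsv$", ".nodes", f)
      ids <- if (file.exists(nodes_file)) readLines(nodes_file) else NULL
      sim <- read_similarity_matrix(f, pocket_ids = ids, species = species)
      g <- build_graph(sim, cfg$edge_threshold)
      leiden_communities(g, resolution = cfg$resolution, seed = cfg$seed,
                         singletons = find_singletons(sim))
    })
    tab <- do.call(rbind, lapply(res, function(cl) data.frame(
      species = cl$species, n_communities = cl$n_communities,
      n_singletons = cl$n_singletons,
      singleton_fraction = round(cl$n_singletons /
                                   (cl$n_singletons +
                                      sum(lengths(cl$communities)) +
                                      length(cl$threshold_isolated)), 2),
      n_unique = cl$n_unique, largest_community = cl$largest_community,
      stringsAsFactors = FALSE
    )))
    utils::write.table(tab, out("clustering.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pipeline_log("cluster", "%d species clustered", nrow(tab))
    list(results = res, table = tab)
  })

  # -- scaling ------------------------------------------------------------
  scaling <- run_stage("scaling", {
    fs <- utils::read.delim(file.path(ind, "fold_cluster_counts.tsv"),
                            stringsAsFactors = FALSE)
    tab <- clusterings$table
    st <- species_cluster_stats(
      tab$species, fs$n_fs[match(tab$species, fs$species)],
      tab$n_unique, tab$n_communities
    )
    fit <- fit_power_law(st)
    jsonlite::write_json(
      list(slope = fit$slope, intercept = fit$intercept,
           pearson_r = fit$pearson_r, n_points = fit$n_points),
      out("scaling.json"), auto_unbox = TRUE, digits = NA
    )
    pipeline_log("scaling", "exponent %.3f (r %.3f)", fit$slope, fit$pearson_r)
    fit
  })

  # -- embedding entropy --------------------------------------------------
  entropy <- run_stage("embed", {
    emb <- read_embeddings(file.path(ind, "embeddings.tsv"),
                           file.path(ind, "embedding_labels.tsv"))
    proj <- project_embeddings(emb, method = cfg$projection_method,
                               seed = cfg$seed, perplexity = cfg$perplexity,
                               n_iter = cfg$tsne_iterations)
    utils::write.table(
      data.frame(pocket_id = emb$pocket_ids, proj$coords),
      out("projection.tsv"), sep = "\t", row.names = FALSE, quote = FALSE
    )
    grid <- binned_entropy(proj, emb$labels[[cfg$entropy_label]],
                           cfg$entropy_bins, cfg$entropy_bins,
                           cfg$entropy_min_count)
    gm <- grid$entropy
    df <- data.frame(
      x_bin = rep(seq_len(nrow(gm)), ncol(gm)),
      y_bin = rep(seq_len(ncol(gm)), each = nrow(gm)),
      count = as.vector(grid$count), entropy = as.vector(gm)
    )
    utils::write.table(df, out("entropy_grid.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pipeline_log("embed", "%d pockets projected (%s), %d bins occupied",
                 length(emb$pocket_ids), cfg$projection_method,
                 sum(grid$count > 0))
    grid
  })

  summary <- list(
    n_proteins = length(proteins),
    n_pockets_input = nrow(pockets),
    n_pockets_pass = nrow(filtered$pockets),
    filter_counts = as.list(filtered$counts),
    n_sites = enrichment$n_sites,
    n_found = enrichment$n_found,
    found_fraction = enrichment$n_found / enrichment$n_sites,
    enrichment = enrichment$table,
    clustering = clusterings$table,
    scaling = list(slope = scaling$slope, intercept = scaling$intercept,
                   pearson_r = scaling$pearson_r),
    seed = cfg$seed
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(summary)
}
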