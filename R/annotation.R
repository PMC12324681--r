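# Known-site processing and enrichment statistics: splitting inter-chain
# sites into spatial components, matching known sites to predicted pockets
# by residue overlap, ascending the compound ontology to class roots,
# Fisher exact enrichment with Benjamini-Yekutieli correction, domain
# classification and singleton/non-singleton descriptor contrasts.

#' Split an inter-chain site into spatial components
#'
#' Builds a graph on the site residues with edges between residues whose
#' C-alpha atoms lie within `distance_threshold` (inclusive) and returns
#' one site per connected component. Components smaller than
#' `min_residues` are dropped.
#'
#' @param site one-row slice of a [known_site_table()].
#' @param ca_coords_by_chain named list (by chain id) of n x 3 C-alpha
#'   coordinate matrices, rows indexed by residue sequence number.
#' @param distance_threshold C-alpha adjacency cutoff in Angstrom.
#' @param min_residues minimum residues per retained component.
#' @return a [known_site_table()] with one row per retained component;
#'   component suffixes `.1`, `.2`, ... are appended when splitting occurs.
#' @export
split_interchain_site <- function(site, ca_coords_by_chain,
                                  distance_threshold = 12, min_residues = 4L) {
  res <- if (is.list(site$residues) && !is.data.frame(site$residues)) {
    site$residues[[1]]
  } else {
    site$residues
  }
  coords <- t(vapply(seq_len(nrow(res)), function(r) {
    m <- ca_coords_by_chain[[res$chain[r]]]
    if (is.null(m) || nrow(m) < res$index[r]) {
      stop("missing C-alpha coordinate for residue ",
           residue_keys(res[r, ]), call. = FALSE)
    }
    m[res$index[r], ]
  }, numeric(3)))
  d <- as.matrix(stats::dist(coords))
  adj <- d <= distance_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  keep <- which(tabulate(comp) >= min_residues)
  if (length(keep) == 0L) {
    return(known_site_table(character(), character(), list(), character()))
  }
  parts <- lapply(seq_along(keep), function(k) res[comp == keep[k], , drop = FALSE])
  ids <- if (length(keep) == 1L && max(comp) == 1L) {
    site$site_id[1]
  } else {
    paste(site$site_id[1], seq_along(keep), sep = ".")
  }
  known_site_table(ids, rep(site$protein_id[1], length(keep)), parts,
                   rep(site$ligand_chebi[1], length(keep)))
}

#' Match known sites to predicted pockets
#'
#' A known site is "found" when it shares at least one (chain, index)
#' residue with a predicted pocket of the same protein.
#'
#' @param known a [known_site_table()].
#' @param predicted a [pocket_table()].
#' @return data.frame with columns `site_id`, `found` (logical) and
#'   `matched_pockets` (list-column of pocket ids).
#' @export
match_known_to_predicted <- function(known, predicted) {
  pocket_keys <- lapply(predicted$residues, residue_keys)
  out <- data.frame(site_id = known$site_id, found = FALSE,
                    stringsAsFactors = FALSE)
  matched <- vector("list", nrow(known))
  for (s in seq_len(nrow(known))) {
    keys <- residue_keys(known$residues[[s]])
    cand <- which(predicted$protein_id == known$protein_id[s])
    hits <- cand[vapply(cand, function(p) any(keys %in% pocket_keys[[p]]), TRUE)]
    out$found[s] <- length(hits) > 0L
    matched[[s]] <- predicted$pocket_id[hits]
  }
  out$matched_pockets <- matched
  out
}

# Transitive parents of `id`, with cycle detection by iterative DFS
# (gray = on the current path, black = finished).
ontology_ancestors <- function(id, ontology) {
  state <- new.env(parent = emptyenv())  # "gray" or "black"
  seen <- character()
  visit_stack <- list(list(node = id, next_parent = 1L))
  get_parents <- function(u) ontology$edges[[u]]
  assign(id, "gray", envir = state)
  while (length(visit_stack) > 0L) {
    top <- visit_stack[[length(visit_stack)]]
    parents <- get_parents(top$node)
    if (top$next_parent > length(parents)) {
      assign(top$node, "black", envir = state)
      seen <- c(seen, top$node)
      visit_stack[[length(visit_stack)]] <- NULL
    } else {
      visit_stack[[length(visit_stack)]]$next_parent <- top$next_parent + 1L
      p <- parents[[top$next_parent]]
      st <- if (exists(p, envir = state)) get(p, envir = state) else "white"
      if (st == "gray") {
        stop("cycle detected in compound ontology near ", p, call. = FALSE)
      }
      if (st == "white") {
        assign(p, "gray", envir = state)
        visit_stack[[length(visit_stack) + 1L]] <- list(node = p, next_parent = 1L)
      }
    }
  }
  unique(seen)
}

#' Assign a ligand to compound classes
#'
#' Ascends the child-to-parent ontology edges transitively from the given
#' compound id and returns every class whose root set is reached. A ligand
#' reaching no class root is assigned `"Other compounds"`; a ligand may
#' belong to several classes.
#'
#' @param chebi_id compound identifier (e.g. `"CHEBI:30616"`).
#' @param ontology a [compound_ontology()].
#' @return character vector of class names.
#' @export
assign_compound_class <- function(chebi_id, ontology) {
  if (is.na(chebi_id)) return(character())
  anc <- ontology_ancestors(chebi_id, ontology)
  classes <- names(ontology$class_roots)[
    vapply(ontology$class_roots, function(roots) any(roots %in% anc), TRUE)
  ]
  if (length(classes) == 0L) "Other compounds" else classes
}

#' Sample odds ratio for a compound class
#'
#' For a class with `a` found and `b` not-found sites among overall totals
#' `F` found and `NF` not found, the cross-product odds ratio
#' `(a/b) / ((F-a)/(NF-b))`. Zero cells give 0 or `Inf` as forced by the
#' formula.
#'
#' @param a,b class-level found / not-found counts.
#' @param f,nf overall unique-site found / not-found totals.
#' @return sample odds ratio.
#' @export
sample_odds_ratio <- function(a, b, f, nf) {
  if (a > f || b > nf) stop("class counts exceed totals", call. = FALSE)
  (a / b) / ((f - a) / (nf - b))
}

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]].
fisher_exact_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Ligand-class enrichment among found sites
#'
#' Per class, tests whether sites of that class are enriched or depleted
#' among the "found" sites relative to all other classes, using the
#' two-sided Fisher exact test on the 2x2 table
#' `[[a, b], [F - a, NF - b]]`. Odds ratios are sample (cross-product)
#' odds ratios and p-values are Benjamini-Yekutieli adjusted across
#' classes. Because a ligand may map to several classes, per-class counts
#' may sum to more than the unique-site totals `F` and `NF`; the totals
#' are always counted over unique sites.
#'
#' @param found logical vector over unique sites.
#' @param classes list (aligned with `found`) of character vectors of class
#'   names per site.
#' @return data.frame with columns `class_name`, `n_found`, `n_not_found`,
#'   `odds_ratio`, `p_value`, `p_adj`, ordered by decreasing class size.
#' @export
enrichment_table <- function(found, classes) {
  stopifnot(length(found) == length(classes))
  f_tot <- sum(found)
  nf_tot <- sum(!found)
  all_classes <- unique(unlist(classes, use.names = FALSE))
  rows <- lapply(all_classes, function(cl) {
    in_class <- vapply(classes, function(x) cl %in% x, TRUE)
    a <- sum(found & in_class)
    b <- sum(!found & in_class)
    data.frame(
      class_name = cl, n_found = a, n_not_found = b,
      odds_ratio = sample_odds_ratio(a, b, f_tot, nf_tot),
      p_value = fisher_exact_p(a, b, f_tot - a, nf_tot - b),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BY")
  out[order(-(out$n_found + out$n_not_found)), , drop = FALSE]
}

#' Classify a pocket by domain context
#'
#' A pocket is assigned every domain interval containing at least one of
#' its residues. Categories: `no_domain` (no residue in any domain),
#' `single_domain`, `inter_domain` (two or more distinct domain ids),
#' `domain_no_domain` (at least one residue inside and one outside any
#' domain). The `duf` flag is set when all assigned domains are domains of
#' unknown function.
#'
#' @param pocket_residues residue set of the pocket.
#' @param domains [domain_table()] rows for the pocket's protein.
#' @return list with `category`, `domain_ids` and `duf`.
#' @export
classify_pocket_domains <- function(pocket_residues, domains) {
  idx <- pocket_residues$index
  if (nrow(domains) == 0L) {
    return(list(category = "no_domain", domain_ids = character(), duf = FALSE))
  }
  hit <- vapply(seq_len(nrow(domains)), function(d) {
    any(idx >= domains$start[d] & idx <= domains$end[d])
  }, TRUE)
  covered <- vapply(idx, function(i) {
    any(i >= domains$start & i <= domains$end)
  }, TRUE)
  ids <- unique(domains$domain_id[hit])
  category <- if (length(ids) == 0L) {
    "no_domain"
  } else if (!all(covered)) {
    "domain_no_domain"
  } else if (length(ids) >= 2L) {
    "inter_domain"
  } else {
    "single_domain"
  }
  duf <- length(ids) > 0L && all(domains$is_duf[hit])
  list(category = category, domain_ids = ids, duf = duf)
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric samples.
#' @return standardized mean difference `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Contrast descriptor distributions between two pocket groups
#'
#' Per descriptor column: Welch two-sample t-test p-value, Cohen's d with
#' pooled standard deviation, and group medians. Typically used to
#' contrast singleton against non-singleton pockets.
#'
#' @param descriptors data.frame of descriptor values (one row per pocket).
#' @param group logical or two-level factor aligned with rows; `TRUE` (or
#'   the first level) defines group 1.
#' @param columns descriptor columns to test; defaults to all numeric.
#' @return data.frame with columns `property`, `cohens_d`, `p_value`,
#'   `median_group1`, `median_group2`.
#' @export
contrast_groups <- function(descriptors, group, columns = NULL) {
  if (is.logical(group)) {
    g1 <- group
  } else {
    group <- as.factor(group)
    stopifnot(nlevels(group) == 2L)
    g1 <- group == levels(group)[1]
  }
  if (is.null(columns)) {
    columns <- names(descriptors)[vapply(descriptors, is.numeric, TRUE)]
  }
  rows <- lapply(columns, function(cl) {
    x <- descriptors[[cl]][g1]
    y <- descriptors[[cl]][!g1]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    d <- cohens_d(x, y)
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y)$p.value
    }
    data.frame(property = cl, cohens_d = d, p_value = p,
               median_group1 = stats::median(x), median_group2 = stats::median(y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
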