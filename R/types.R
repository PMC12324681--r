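# Domain types shared across the pipeline.
#
# Residue sets are data.frames with columns `chain` (single-letter id) and
# `index` (1-based residue sequence number); pockets and known sites carry
# them as list-columns. Coordinates are in Angstrom throughout.

#' Construct a residue set
#'
#' @param chain character vector of chain identifiers.
#' @param index integer vector of 1-based residue sequence numbers.
#' @return data.frame with columns `chain` and `index`, duplicates removed.
#' @export
residue_set <- function(chain, index) {
  chain <- as.character(chain)
  index <- as.integer(index)
  if (length(chain) == 1L && length(index) > 1L) chain <- rep(chain, length(index))
  stopifnot(length(chain) == length(index))
  if (any(is.na(index)) || any(index < 1L)) {
    stop("residue indices must be integers >= 1", call. = FALSE)
  }
  if (any(is.na(chain)) || any(!nzchar(chain))) {
    stop("chain identifiers must be non-empty", call. = FALSE)
  }
  df <- unique(data.frame(chain = chain, index = index, stringsAsFactors = FALSE))
  df[order(df$chain, df$index), , drop = FALSE]
}

residue_keys <- function(res) paste(res$chain, res$index, sep = "_")

parse_residue_tokens <- function(tokens) {
  tokens <- tokens[nzchar(tokens)]
  parts <- regmatches(tokens, regexec("^([A-Za-z0-9])_([0-9]+)$", tokens))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed residue token(s): ", paste(tokens[bad], collapse = ", "),
         call. = FALSE)
  }
  residue_set(
    chain = vapply(parts, `[`, "", 2L),
    index = as.integer(vapply(parts, `[`, "", 3L))
  )
}

format_residue_tokens <- function(res) paste(residue_keys(res), collapse = " ")

#' Construct a protein record
#'
#' Bundles the per-protein information the pipeline consumes: sequence,
#' C-alpha (and optionally all-atom) coordinates, per-residue model
#' confidence (pLDDT, 0-100), the pairwise predicted-aligned-error matrix
#' (Angstrom), fragment status, the number of passed transmembrane-model
#' quality checks (0-6, `NA` for soluble proteins) and a fold-cluster id.
#'
#' @param protein_id accession string.
#' @param species species mnemonic (e.g. `"ECOLI"`).
#' @param sequence one-letter amino-acid string.
#' @param ca_coords numeric matrix, residues x 3, C-alpha positions.
#' @param plddt numeric vector of per-residue confidence in \[0, 100\].
#' @param pae square numeric matrix of predicted aligned errors (may be
#'   asymmetric; never symmetrised).
#' @param atom_coords optional data.frame with columns `residue` (index),
#'   `atom`, `element`, `x`, `y`, `z` for all-atom SASA computation.
#' @param is_fragment logical; fragment entries are excluded by the filters.
#' @param tm_checks_passed integer 0-6 or `NA` (soluble).
#' @param fold_cluster fold-cluster id string or `NA`.
#' @param chain chain identifier for the single modelled chain.
#' @return object of class `protein_record`.
#' @export
protein_record <- function(protein_id, species, sequence, ca_coords, plddt, pae,
                           atom_coords = NULL, is_fragment = FALSE,
                           tm_checks_passed = NA_integer_,
                           fold_cluster = NA_character_, chain = "A") {
  n <- nchar(sequence)
  plddt <- as.numeric(plddt)
  if (length(plddt) != n) stop("plddt length must equal sequence length", call. = FALSE)
  if (any(plddt < 0 | plddt > 100)) stop("plddt values must lie in [0, 100]", call. = FALSE)
  pae <- as.matrix(pae)
  if (nrow(pae) != n || ncol(pae) != n) {
    stop("pae must be a square matrix with side equal to the sequence length",
         call. = FALSE)
  }
  if (any(pae < 0)) stop("pae entries must be >= 0", call. = FALSE)
  ca_coords <- as.matrix(ca_coords)
  if (nrow(ca_coords) != n || ncol(ca_coords) != 3L) {
    stop("ca_coords must be an n x 3 matrix", call. = FALSE)
  }
  if (!is.na(tm_checks_passed) &&
      (tm_checks_passed < 0L || tm_checks_passed > 6L)) {
    stop("tm_checks_passed must be in [0, 6] or NA", call. = FALSE)
  }
  structure(
    list(
      protein_id = protein_id, species = species, sequence = sequence,
      ca_coords = ca_coords, atom_coords = atom_coords, plddt = plddt,
      pae = pae, is_fragment = isTRUE(is_fragment),
      tm_checks_passed = as.integer(tm_checks_passed),
      fold_cluster = fold_cluster, chain = chain
    ),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record %s (%s): %d residues, mean pLDDT %.1f%s>\n",
              x$protein_id, x$species, nchar(x$sequence), mean(x$plddt),
              if (x$is_fragment) ", fragment" else ""))
  invisible(x)
}

protein_length <- function(p) nchar(p$sequence)

#' Construct a pocket table
#'
#' One row per predicted pocket, with the residue set held as a list-column.
#'
#' @param pocket_id,protein_id character vectors.
#' @param rank integer rank (>= 1) within the protein.
#' @param probability ligandability probability score in \[0, 1\].
#' @param residues list of residue sets (see [residue_set()]).
#' @return data.frame of class `pocket_table`.
#' @export
pocket_table <- function(pocket_id, protein_id, rank, probability, residues) {
  rank <- as.integer(rank)
  probability <- as.numeric(probability)
  if (any(probability < 0 | probability > 1)) {
    stop("pocket probability must lie in [0, 1]", call. = FALSE)
  }
  if (any(rank < 1L)) stop("pocket rank must be >= 1", call. = FALSE)
  if (any(vapply(residues, nrow, 1L) == 0L)) {
    stop("pocket residue sets must be non-empty", call. = FALSE)
  }
  df <- data.frame(
    pocket_id = as.character(pocket_id), protein_id = as.character(protein_id),
    rank = rank, probability = probability, stringsAsFactors = FALSE
  )
  df$residues <- residues
  class(df) <- c("pocket_table", "data.frame")
  df
}

#' Construct a known-site table
#'
#' Annotated binding sites with an optional ligand compound identifier
#' (ChEBI id, `NA` when no ligand is recorded).
#'
#' @param site_id,protein_id character vectors.
#' @param residues list of residue sets.
#' @param ligand_chebi character vector of ChEBI ids or `NA`.
#' @return data.frame of class `known_site_table`.
#' @export
known_site_table <- function(site_id, protein_id, residues, ligand_chebi = NA) {
  if (any(vapply(residues, nrow, 1L) == 0L)) {
    stop("known-site residue sets must be non-empty", call. = FALSE)
  }
  df <- data.frame(
    site_id = as.character(site_id), protein_id = as.character(protein_id),
    ligand_chebi = as.character(ligand_chebi), stringsAsFactors = FALSE
  )
  df$residues <- residues
  class(df) <- c("known_site_table", "data.frame")
  df
}

#' Construct a sparse pocket-similarity matrix
#'
#' Symmetric non-negative alignment scores between pockets of one species.
#' An absent (zero) entry means the pair could not be aligned; the diagonal
#' is ignored. Input triplets are completed symmetrically.
#'
#' @param pocket_ids ordered character vector of pocket ids (the node set,
#'   including pockets with no alignments).
#' @param i,j indices or pocket ids of scored pairs.
#' @param score non-negative alignment scores.
#' @param species species mnemonic.
#' @return object of class `similarity_matrix` with a sparse symmetric
#'   `scores` slot.
#' @export
similarity_matrix <- function(pocket_ids, i = integer(), j = integer(),
                              score = numeric(), species = NA_character_) {
  pocket_ids <- as.character(pocket_ids)
  if (anyDuplicated(pocket_ids)) stop("pocket_ids must be unique", call. = FALSE)
  if (is.character(i)) i <- match(i, pocket_ids)
  if (is.character(j)) j <- match(j, pocket_ids)
  if (any(is.na(i)) || any(is.na(j))) {
    stop("similarity entries refer to unknown pocket ids", call. = FALSE)
  }
  if (any(score < 0)) stop("similarity scores must be >= 0", call. = FALSE)
  off <- i != j
  i <- i[off]; j <- j[off]; score <- score[off]
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    stop("duplicate similarity triplet(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  n <- length(pocket_ids)
  scores <- Matrix::sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = c(score, score), dims = c(n, n),
    dimnames = list(pocket_ids, pocket_ids)
  )
  structure(list(species = species, pocket_ids = pocket_ids, scores = scores),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  nz <- Matrix::nnzero(x$scores) / 2
  cat(sprintf("<similarity_matrix %s: %d pockets, %d scored pairs>\n",
              x$species, length(x$pocket_ids), as.integer(nz)))
  invisible(x)
}

#' Construct an embedding set
#'
#' Pocket embedding vectors (one fixed-length numeric vector per pocket)
#' with aligned per-pocket labels.
#'
#' @param pocket_ids character vector.
#' @param vectors numeric matrix, pockets x 128.
#' @param labels data.frame aligned with `pocket_ids`; typically carries
#'   `species`, `kingdom` and `compound_class` columns.
#' @param dim required embedding dimension (default 128).
#' @return object of class `embedding_set`.
#' @export
embedding_set <- function(pocket_ids, vectors, labels = NULL, dim = 128L) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != dim) {
    stop("embedding vectors must have length ", dim, call. = FALSE)
  }
  if (nrow(vectors) != length(pocket_ids)) {
    stop("vectors and pocket_ids disagree in length", call. = FALSE)
  }
  if (!is.null(labels) && nrow(labels) != length(pocket_ids)) {
    stop("labels must be aligned with pocket_ids", call. = FALSE)
  }
  rownames(vectors) <- pocket_ids
  structure(list(pocket_ids = as.character(pocket_ids), vectors = vectors,
                 labels = labels),
            class = "embedding_set")
}

#' Construct a compound ontology
#'
#' A directed child-to-parent edge relation over compound identifiers plus
#' the named class roots used for compound-class assignment.
#'
#' @param children,parents character vectors defining child -> parent edges.
#' @param class_roots named list mapping class name to a character vector of
#'   root ids; defaults to [compound_classes()].
#' @return object of class `compound_ontology`.
#' @export
compound_ontology <- function(children, parents, class_roots = compound_classes()) {
  children <- as.character(children); parents <- as.character(parents)
  stopifnot(length(children) == length(parents))
  if (any(children == parents)) {
    stop("ontology must not contain self-edges", call. = FALSE)
  }
  edges <- split(parents, children)
  structure(list(edges = edges, class_roots = class_roots),
            class = "compound_ontology")
}

#' Compound classes and their ontology roots
#'
#' The twelve ligand compound classes used throughout the enrichment
#' analysis, each mapped to the ChEBI identifiers that act as its ontology
#' roots. Ligands reaching none of these roots fall into the catch-all
#' `"Other compounds"` class.
#'
#' @return Named list of character vectors of root ChEBI ids.
#' @export
compound_classes <- function() {
  list(
    "Nucleobases, nucleosides & nucleotides" =
      c("CHEBI:18282", "CHEBI:33838", "CHEBI:36976"),
    "Inorganic ions" = "CHEBI:36914",
    "Carbohydrates & derivatives" = c("CHEBI:16646", "CHEBI:63299"),
    "Amino acids & derivatives" = c("CHEBI:33709", "CHEBI:35238", "CHEBI:83821"),
    "Lipids" = "CHEBI:18059",
    "Hetero nuclear clusters" = "CHEBI:33733",
    "Oligo- & polypeptides" = c("CHEBI:25676", "CHEBI:15841"),
    "Monosaccharides & derivatives" = c("CHEBI:35381", "CHEBI:63367"),
    "Glycans" = c("CHEBI:37163", "CHEBI:167559"),
    "Hemes" = "CHEBI:30413",
    "Nucleic acids" = c("CHEBI:16991", "CHEBI:33697")
  )
}

#' Construct a domain-annotation table
#'
#' @param protein_id,domain_id character vectors.
#' @param start,end 1-based inclusive residue bounds.
#' @param is_duf logical; domain of unknown function.
#' @return data.frame of class `domain_table`.
#' @export
domain_table <- function(protein_id, domain_id, start, end, is_duf = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("domain intervals require start <= end", call. = FALSE)
  if (any(start < 1L)) stop("domain intervals are 1-based", call. = FALSE)
  df <- data.frame(
    protein_id = as.character(protein_id), domain_id = as.character(domain_id),
    start = start, end = end, is_duf = rep_len(as.logical(is_duf), length(start)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("domain_table", "data.frame")
  df
}
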