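# Readers and writers for the file formats the pipeline consumes:
# pocket prediction CSVs, structure files with per-residue confidence,
# predicted-aligned-error JSON, annotation/fold-cluster/domain TSVs,
# similarity triplets, embedding matrices and compound-ontology edge lists.

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a pocket prediction table
#'
#' Parses the CSV dialect used by pocket prediction tools: one row per
#' pocket with columns `name`, `rank`, `probability` and `residue_ids`
#' (space-separated `CHAIN_INDEX` tokens). Extra columns are ignored.
#'
#' @param path CSV file path.
#' @param protein_id protein accession the pockets belong to; defaults to
#'   the file name without extension.
#' @return a [pocket_table()].
#' @export
read_p2rank_table <- function(path, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  require_columns(df, c("name", "rank", "probability", "residue_ids"), path)
  if (nrow(df) == 0L) {
    return(pocket_table(character(), character(), integer(), numeric(), list()))
  }
  residues <- lapply(seq_len(nrow(df)), function(r) {
    tokens <- strsplit(trimws(df$residue_ids[r]), "[[:space:]]+")[[1]]
    tryCatch(parse_residue_tokens(tokens), error = function(e) {
      stop("row ", r + 1L, " of '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  pocket_table(
    pocket_id = paste(protein_id, df$name, sep = "."),
    protein_id = protein_id, rank = df$rank, probability = df$probability,
    residues = residues
  )
}

#' Write a pocket prediction table
#'
#' @param pockets a [pocket_table()] for a single protein.
#' @param path output CSV path.
#' @export
write_p2rank_table <- function(pockets, path) {
  stopifnot(length(unique(pockets$protein_id)) <= 1L)
  name <- sub("^[^.]*\\.", "", pockets$pocket_id)
  df <- data.frame(
    name = name, rank = pockets$rank, probability = pockets$probability,
    residue_ids = vapply(pockets$residues, format_residue_tokens, ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-residue model confidence from a structure file
#'
#' Reads a PDB or mmCIF structure in which per-residue confidence (pLDDT)
#' is stored in the B-factor column, as in AlphaFold model files. The
#' confidence value is taken from each residue's C-alpha atom.
#'
#' @param path structure file (`.pdb`, `.ent`, or `.cif`).
#' @return list with `sequence` (one-letter string), `ca_coords`
#'   (n x 3 matrix) and `plddt` (numeric vector).
#' @export
read_structure_confidence <- function(path) {
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    suppressWarnings(bio3d::read.cif(path))  # beta-status warning is noise
  } else {
    bio3d::read.pdb(path)
  }
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0L) {
    stop("structure file '", path, "' contains no atoms", call. = FALSE)
  }
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  res_key <- paste(atoms$chain, atoms$resno)
  ord <- !duplicated(res_key)
  keys <- res_key[ord]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_keys <- paste(ca$chain, ca$resno)
  missing_ca <- setdiff(keys, ca_keys)
  if (length(missing_ca) > 0L) {
    stop("residue(s) without a C-alpha atom in '", path, "': ",
         paste(missing_ca, collapse = ", "), call. = FALSE)
  }
  mixed <- vapply(split(atoms$b, res_key), function(b) diff(range(b)) > 1e-6, TRUE)
  if (any(mixed)) {
    warning("mixed B-factors within residue(s) ",
            paste(names(mixed)[mixed], collapse = ", "),
            "; using the C-alpha value", call. = FALSE)
  }
  ca <- ca[match(keys, ca_keys), , drop = FALSE]
  aa3 <- toupper(ca$resid)
  unknown <- setdiff(unique(aa3), names(aa_one_letter))
  if (length(unknown) > 0L) {
    stop("nonstandard residue type(s) in '", path, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ca_xyz <- unname(as.matrix(ca[, c("x", "y", "z")]))
  colnames(ca_xyz) <- c("x", "y", "z")
  list(
    sequence = paste(aa_one_letter[aa3], collapse = ""),
    ca_coords = ca_xyz,
    plddt = as.numeric(ca$b)
  )
}

#' Write a protein record as a PDB file
#'
#' Writes C-alpha (and, when present, all-atom) coordinates with the
#' per-residue confidence value in the B-factor column of every atom of
#' the residue, mirroring the layout of model-database structure files.
#'
#' @param protein a [protein_record()].
#' @param path output PDB path.
#' @export
write_protein_pdb <- function(protein, path) {
  aa1 <- strsplit(protein$sequence, "")[[1]]
  if (!is.null(protein$atom_coords)) {
    at <- protein$atom_coords
    resno <- at$residue
    elety <- at$atom
    elesy <- at$element
    xyz <- as.matrix(at[, c("x", "y", "z")])
  } else {
    resno <- seq_along(aa1)
    elety <- rep("CA", length(aa1))
    elesy <- rep("C", length(aa1))
    xyz <- protein$ca_coords
  }
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_along(resno),
    ifelse(nchar(elety) < 4L, paste0(" ", elety), elety),
    aa_three_letter[aa1[resno]], protein$chain, resno,
    xyz[, 1], xyz[, 2], xyz[, 3], 1.00, protein$plddt[resno], elesy
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a predicted-aligned-error matrix from JSON
#'
#' Expects a JSON object (optionally wrapped in a one-element array, as in
#' model-database downloads) with key `predicted_aligned_error` holding a
#' square list of lists. The matrix is kept exactly as stored; PAE is
#' directional and never symmetrised.
#'
#' @param path JSON file path.
#' @return square numeric matrix (Angstrom).
#' @export
read_pae_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  if (is.null(names(obj)) && length(obj) >= 1L) obj <- obj[[1]]
  rows <- obj[["predicted_aligned_error"]]
  if (is.null(rows)) {
    stop("'", path, "' has no 'predicted_aligned_error' key", call. = FALSE)
  }
  lens <- vapply(rows, length, 1L)
  if (length(unique(lens)) != 1L || lens[1] != length(rows)) {
    stop("'", path, "': predicted_aligned_error must be a square matrix",
         call. = FALSE)
  }
  pae <- do.call(rbind, lapply(rows, as.numeric))
  if (any(pae < 0)) {
    stop("'", path, "': negative predicted-aligned-error entries", call. = FALSE)
  }
  pae
}

#' Write a predicted-aligned-error matrix as JSON
#'
#' @param pae square numeric matrix.
#' @param path output path.
#' @export
write_pae_json <- function(pae, path) {
  pae <- as.matrix(pae)
  stopifnot(nrow(pae) == ncol(pae))
  rows <- lapply(seq_len(nrow(pae)), function(i) pae[i, ])
  jsonlite::write_json(list(predicted_aligned_error = rows), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a known-binding-site annotation table
#'
#' TSV with columns `protein_id`, `site_id`, `residue_ids` (space-separated
#' `CHAIN_INDEX` tokens) and `ligand_chebi` (may be empty: no known ligand).
#'
#' @param path TSV path.
#' @return a [known_site_table()].
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  require_columns(df, c("protein_id", "site_id", "residue_ids", "ligand_chebi"), path)
  residues <- lapply(df$residue_ids, function(s) {
    parse_residue_tokens(strsplit(trimws(s), "[[:space:]]+")[[1]])
  })
  known_site_table(df$site_id, df$protein_id, residues, df$ligand_chebi)
}

#' Write a known-binding-site annotation table
#' @param sites a [known_site_table()].
#' @param path output TSV path.
#' @export
write_annotation_table <- function(sites, path) {
  df <- data.frame(
    protein_id = sites$protein_id, site_id = sites$site_id,
    residue_ids = vapply(sites$residues, format_residue_tokens, ""),
    ligand_chebi = ifelse(is.na(sites$ligand_chebi), "", sites$ligand_chebi),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fold-cluster assignments
#'
#' TSV with columns `protein_id` and `fold_cluster`.
#'
#' @param path TSV path.
#' @return named character vector protein_id -> fold-cluster id.
#' @export
read_fold_clusters <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("protein_id", "fold_cluster"), path)
  stats::setNames(as.character(df$fold_cluster), df$protein_id)
}

#' Write fold-cluster assignments
#' @param clusters named character vector protein_id -> fold-cluster id.
#' @param path output TSV path.
#' @export
write_fold_clusters <- function(clusters, path) {
  utils::write.table(
    data.frame(protein_id = names(clusters), fold_cluster = unname(clusters)),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a sparse pocket-similarity matrix from triplets
#'
#' TSV with columns `pocket_i`, `pocket_j`, `score`; each unordered pair
#' may appear once and is completed symmetrically. Pockets with no scored
#' pair are included via `pocket_ids`.
#'
#' @param path triplet TSV path.
#' @param pocket_ids full node set; defaults to the ids present in triplets.
#' @param species species mnemonic.
#' @return a [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, pocket_ids = NULL, species = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("pocket_i", "pocket_j", "score"), path)
  if (is.null(pocket_ids)) {
    pocket_ids <- sort(unique(c(df$pocket_i, df$pocket_j)))
  }
  similarity_matrix(pocket_ids, df$pocket_i, df$pocket_j, df$score,
                    species = species)
}

#' Write a similarity matrix as triplets
#' @param sim a [similarity_matrix()].
#' @param path output TSV path.
#' @export
write_similarity_matrix <- function(sim, path) {
  tri <- Matrix::which(sim$scores != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  df <- data.frame(
    pocket_i = sim$pocket_ids[tri[, 1]], pocket_j = sim$pocket_ids[tri[, 2]],
    score = sim$scores[tri], stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pocket embeddings
#'
#' Dense TSV with a `pocket_id` column and 128 numeric columns `e1`..`e128`,
#' plus an optional labels TSV keyed by `pocket_id`.
#'
#' @param path embedding TSV path.
#' @param labels_path optional labels TSV path.
#' @return an [embedding_set()].
#' @export
read_embeddings <- function(path, labels_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, "pocket_id", path)
  vec_cols <- setdiff(names(df), "pocket_id")
  if (length(vec_cols) != 128L) {
    stop("'", path, "': expected 128 embedding columns, found ",
         length(vec_cols), call. = FALSE)
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    require_columns(labels, "pocket_id", labels_path)
    labels <- labels[match(df$pocket_id, labels$pocket_id), , drop = FALSE]
    rownames(labels) <- NULL
  }
  embedding_set(df$pocket_id, as.matrix(df[, vec_cols]), labels)
}

#' Write pocket embeddings
#' @param emb an [embedding_set()].
#' @param path embedding TSV path.
#' @param labels_path optional labels TSV path.
#' @export
write_embeddings <- function(emb, path, labels_path = NULL) {
  df <- data.frame(pocket_id = emb$pocket_ids, stringsAsFactors = FALSE)
  vec <- emb$vectors
  colnames(vec) <- paste0("e", seq_len(ncol(vec)))
  df <- cbind(df, as.data.frame(vec, row.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path) && !is.null(emb$labels)) {
    lab <- cbind(data.frame(pocket_id = emb$pocket_ids), emb$labels)
    lab <- lab[, !duplicated(names(lab)), drop = FALSE]
    utils::write.table(lab, labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a compound-ontology edge list
#'
#' TSV with columns `child` and `parent` (compound ids).
#'
#' @param path TSV path.
#' @param class_roots named list of class-root id sets; defaults to
#'   [compound_classes()].
#' @return a [compound_ontology()].
#' @export
read_ontology <- function(path, class_roots = compound_classes()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("child", "parent"), path)
  compound_ontology(df$child, df$parent, class_roots)
}

#' Write a compound-ontology edge list
#' @param ontology a [compound_ontology()].
#' @param path output TSV path.
#' @export
write_ontology <- function(ontology, path) {
  df <- data.frame(
    child = rep(names(ontology$edges), lengths(ontology$edges)),
    parent = unlist(ontology$edges, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a domain-annotation table
#'
#' TSV with columns `protein_id`, `domain_id`, `start`, `end`, `is_duf`.
#'
#' @param path TSV path.
#' @return a [domain_table()].
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("protein_id", "domain_id", "start", "end", "is_duf"), path)
  domain_table(df$protein_id, df$domain_id, df$start, df$end, as.logical(df$is_duf))
}

#' Write a domain-annotation table
#' @param domains a [domain_table()].
#' @param path output TSV path.
#' @export
write_domain_table <- function(domains, path) {
  utils::write.table(as.data.frame(domains), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
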