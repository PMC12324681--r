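# Reference summary counts from an eleven-species pocketome survey,
# bundled as package data. These serve as worked-example inputs for the
# enrichment and scaling statistics (odds ratios from per-class counts,
# correlation of proteome and pocketome sizes, singleton fractions).

#' Reference per-species proteome and pocketome counts
#'
#' Eleven model-organism proteomes with the number of predicted
#' structures (after fragment/length exclusion), annotated ("known")
#' pockets, experimentally supported annotated pockets, and predicted
#' pockets surviving the 0.5 probability cut.
#'
#' @return data.frame with one row per species.
#' @export
reference_species_counts <- function() {
  data.frame(
    species = c("ECOLI", "YEAST", "CANAL", "ARATH", "ORYSJ", "MAIZE",
                "SOYBN", "DROME", "CAEEL", "MOUSE", "HUMAN"),
    kingdom = c("Bacteria", "Fungi", "Fungi", "Plantae", "Plantae", "Plantae",
                "Plantae", "Animalia", "Animalia", "Animalia", "Animalia"),
    n_structures = c(3813, 5623, 5622, 24778, 30708, 35165, 47539, 12389,
                     17819, 20367, 19268),
    n_known_pockets = c(1014, 1207, 400, 4668, 1925, 681, 1220, 1110, 1091,
                        4439, 4451),
    n_known_experimental = c(224, 109, 11, 169, 25, 9, 0, 19, 10, 146, 975),
    n_predicted_pockets = c(2648, 3000, 3124, 11075, 10618, 13177, 20915,
                            5867, 8850, 10133, 8108),
    stringsAsFactors = FALSE
  )
}

#' Reference ligand-class recovery counts
#'
#' Per compound class, the number of annotated sites recovered ("found")
#' and missed ("not found") by pocket prediction at the 0.5 probability
#' cut, over totals of 11,662 found and 10,709 not-found unique sites.
#' Because ligands may map to several classes, the per-class found
#' column sums to slightly more than the unique-site total.
#'
#' @return data.frame with one row per compound class.
#' @export
reference_class_counts <- function() {
  data.frame(
    class_name = c(
      "Nucleobases, nucleosides & nucleotides", "Inorganic ions",
      "Other compounds", "Carbohydrates & derivatives",
      "Amino acids & derivatives", "Lipids", "Hetero nuclear clusters",
      "Oligo- & polypeptides", "Monosaccharides & derivatives", "Glycans",
      "Hemes", "Nucleic acids"
    ),
    n_found = c(8092, 1191, 1114, 548, 260, 173, 84, 79, 71, 73, 13, 0),
    n_not_found = c(2244, 7265, 296, 103, 135, 94, 433, 92, 34, 4, 2, 7),
    stringsAsFactors = FALSE
  )
}

#' Reference unique-site recovery totals
#'
#' @return list with `found` and `not_found` unique annotated-site counts.
#' @export
reference_found_totals <- function() {
  list(found = 11662, not_found = 10709)
}

#' Reference per-species clustering statistics
#'
#' Communities and singletons found by Leiden clustering of the
#' within-species pocket-similarity graphs of the reference survey.
#'
#' @return data.frame with one row per species.
#' @export
reference_clustering_counts <- function() {
  data.frame(
    species = c("ECOLI", "YEAST", "CANAL", "ARATH", "ORYSJ", "MAIZE",
                "SOYBN", "DROME", "CAEEL", "MOUSE", "HUMAN"),
    n_communities = c(273, 335, 300, 823, 780, 966, 1376, 514, 617, 708, 682),
    n_singletons = c(1076, 1182, 1293, 1532, 1711, 1879, 1792, 1688, 2225,
                     1805, 1705),
    largest_community = c(185, 133, 124, 893, 924, 1086, 1868, 328, 406,
                          1068, 516),
    stringsAsFactors = FALSE
  )
}
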