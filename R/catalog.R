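## vOTU catalog: per-population genome metadata anchoring every rule.

.nucleic_types <- c("dsDNA", "ssRNA")
.source_libraries <- c("dna_virome", "total_metagenome", "metatranscriptome")

#' Construct and validate a vOTU catalog
#'
#' The catalog records, per viral population (vOTU): genome length, nucleic
#' acid type, the library its contig was assembled from, and evidence flags
#' used by downstream rules (provirus status, membership of a viral cluster
#' containing a known temperate phage, nucleotide-identity match to a known
#' species). Length floors follow the recovery criteria: dsDNA contigs are
#' >= 10 kb except proviral sequences, retained down to > 5 kb.
#'
#' @param df data.frame with columns `votu_id`, `genome_length_bp`,
#'   `nucleic_type` ("dsDNA"/"ssRNA"), `source_library` ("dna_virome",
#'   "total_metagenome", "metatranscriptome"), and logicals `is_provirus`,
#'   `vc_with_known_temperate`, `known_species_match`.
#' @return A validated `votu_catalog` data.frame.
#' @export
votu_catalog <- function(df) {
  needed <- c("votu_id", "genome_length_bp", "nucleic_type", "source_library",
              "is_provirus", "vc_with_known_temperate", "known_species_match")
  for (col in needed) {
    if (!col %in% names(df)) stop2("catalog is missing column '", col, "'")
  }
  df <- as.data.frame(df)[needed]
  df$votu_id <- as.character(df$votu_id)
  dup <- df$votu_id[duplicated(df$votu_id)]
  if (length(dup)) {
    stop2("duplicate votu_id: ", paste(unique(dup), collapse = ", "))
  }
  df$genome_length_bp <- as.integer(df$genome_length_bp)
  assert_that(all(df$genome_length_bp > 0), "genome_length_bp must be > 0")
  bad <- setdiff(unique(df$nucleic_type), .nucleic_types)
  if (length(bad)) stop2("unknown nucleic_type: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$source_library), .source_libraries)
  if (length(bad)) {
    stop2("unknown source_library: ", paste(bad, collapse = ", "))
  }
  for (col in c("is_provirus", "vc_with_known_temperate",
                "known_species_match")) {
    df[[col]] <- as.logical(df[[col]])
    assert_that(!anyNA(df[[col]]), paste0(col, " must be TRUE/FALSE"))
  }
  ds <- df$nucleic_type == "dsDNA"
  short_pro <- ds & df$is_provirus & df$genome_length_bp < 5000L
  short_full <- ds & !df$is_provirus & df$genome_length_bp < 10000L
  if (any(short_pro)) {
    stop2("proviral dsDNA vOTUs shorter than 5 kb: ",
          paste(df$votu_id[short_pro], collapse = ", "))
  }
  if (any(short_full)) {
    stop2("non-proviral dsDNA vOTUs shorter than 10 kb: ",
          paste(df$votu_id[short_full], collapse = ", "))
  }
  class(df) <- c("votu_catalog", "data.frame")
  df
}

#' Read a vOTU catalog table
#'
#' @param path TSV file with the [votu_catalog()] columns.
#' @return A `votu_catalog` data.frame.
#' @export
read_votu_catalog <- function(path) {
  votu_catalog(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

genome_lengths <- function(catalog) {
  setNames(catalog$genome_length_bp, catalog$votu_id)
}
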