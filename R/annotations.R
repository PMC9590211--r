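## Gene annotations: GFF3 gene models plus a functional side table carrying
## COG letters, Pfam domain hits and (for ssRNA phages) core-gene roles.
## GFF3 is 1-based inclusive; internally coordinates are 0-based half-open,
## converted at this single entry point.

.core_roles <- c("MP", "CP", "RdRp")

#' Construct and validate a gene annotation table
#'
#' @param df data.frame with columns `gene_id`, `votu_id`, `start_bp`,
#'   `end_bp` (0-based half-open), `cog_letter` (single letter or ""),
#'   `pfam_domains` (semicolon-separated accessions or ""),
#'   `core_gene_role` ("MP"/"CP"/"RdRp" or ""), `full_length` (logical).
#' @param catalog Optional [votu_catalog()]; if given, every `votu_id`
#'   must exist in it.
#' @return A validated `gene_annotation` data.frame with `gene_length_bp`.
#' @export
gene_annotation <- function(df, catalog = NULL) {
  needed <- c("gene_id", "votu_id", "start_bp", "end_bp", "cog_letter",
              "pfam_domains", "core_gene_role", "full_length")
  for (col in needed) {
    if (!col %in% names(df)) stop2("annotation is missing column '", col, "'")
  }
  df <- as.data.frame(df)[needed]
  df$gene_id <- as.character(df$gene_id)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop2("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  }
  df$votu_id <- as.character(df$votu_id)
  df$start_bp <- as.integer(df$start_bp)
  df$end_bp <- as.integer(df$end_bp)
  bad <- df$end_bp <= df$start_bp
  if (any(bad)) {
    stop2("end <= start for gene(s): ", paste(df$gene_id[bad], collapse = ", "))
  }
  df$gene_length_bp <- df$end_bp - df$start_bp
  df$cog_letter <- ifelse(is.na(df$cog_letter), "", as.character(df$cog_letter))
  df$pfam_domains <- ifelse(is.na(df$pfam_domains), "",
                            as.character(df$pfam_domains))
  df$core_gene_role <- ifelse(is.na(df$core_gene_role), "",
                              as.character(df$core_gene_role))
  bad <- setdiff(setdiff(unique(df$core_gene_role), ""), .core_roles)
  if (length(bad)) {
    stop2("unknown core_gene_role: ", paste(bad, collapse = ", "))
  }
  df$full_length <- as.logical(df$full_length)
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(df$votu_id), catalog$votu_id)
    if (length(unknown)) {
      stop2("genes reference unknown vOTU(s): ",
            paste(unknown, collapse = ", "))
    }
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

pfam_sets <- function(annotations) {
  lapply(strsplit(annotations$pfam_domains, ";", fixed = TRUE),
         function(x) x[nzchar(x)])
}

gene_lengths <- function(annotations) {
  setNames(annotations$gene_length_bp, annotations$gene_id)
}

#' Read gene annotations from GFF3 plus a functional side table
#'
#' The GFF3 `seqid` is the owning vOTU and each record's `ID` attribute is
#' the gene id; GFF3 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention (so a GFF3 gene at 1..300 becomes
#' `(0, 300)`, length 300). The side table is a TSV keyed by `gene_id` with
#' columns `cog_letter`, `pfam_domains` (semicolon-separated; empty allowed),
#' and optionally `core_gene_role` and `full_length`. Side-table rows for
#' gene ids absent from the GFF3 are skipped with a warning reporting the
#' count.
#'
#' @param gff3_path GFF3 file of gene models.
#' @param function_table_path TSV functional annotation keyed by `gene_id`.
#' @param catalog Optional [votu_catalog()] for vOTU cross-checking.
#' @return A `gene_annotation` data.frame.
#' @export
read_gene_annotations <- function(gff3_path, function_table_path,
                                  catalog = NULL) {
  gff <- as.data.frame(rtracklayer::readGFF(gff3_path))
  assert_that(nrow(gff) > 0, "empty GFF3")
  gene_id <- as.character(gff$ID)
  assert_that(!anyNA(gene_id), "GFF3 records must carry an ID attribute")
  genes <- data.frame(
    gene_id = gene_id,
    votu_id = as.character(gff$seqid),
    start_bp = as.integer(gff$start) - 1L,  # 1-based inclusive -> 0-based
    end_bp = as.integer(gff$end),
    stringsAsFactors = FALSE
  )
  fun <- read.delim(function_table_path, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = NULL)
  assert_that("gene_id" %in% names(fun),
              "function table is missing column 'gene_id'")
  orphan <- !fun$gene_id %in% genes$gene_id
  if (any(orphan)) {
    warning(sum(orphan), " function row(s) for gene ids absent from GFF3 ",
            "were skipped", call. = FALSE)
    fun <- fun[!orphan, , drop = FALSE]
  }
  idx <- match(genes$gene_id, fun$gene_id)
  pick <- function(col, default) {
    if (col %in% names(fun)) {
      v <- fun[[col]][idx]
      v[is.na(v)] <- default
      v
    } else {
      rep(default, nrow(genes))
    }
  }
  genes$cog_letter <- as.character(pick("cog_letter", ""))
  genes$pfam_domains <- as.character(pick("pfam_domains", ""))
  genes$core_gene_role <- as.character(pick("core_gene_role", ""))
  genes$full_length <- as.logical(pick("full_length", TRUE))
  gene_annotation(genes, catalog = catalog)
}
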