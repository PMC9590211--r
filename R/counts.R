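## CountBundle: the raw per-sample read-count inputs produced upstream by
## read mapping — one vOTU x sample matrix per DNA library type, a gene x
## sample metatranscriptome matrix, per-library sequencing depths, and the
## breadth-of-coverage matrix driving presence calls.

#' Construct and validate a count bundle
#'
#' @param dna_counts Named list of vOTU x sample integer matrices, one per
#'   DNA library type (`dna_virome`, `total_metagenome`). A library may be
#'   absent.
#' @param rna_gene_counts gene x sample integer matrix of metatranscriptome
#'   read counts.
#' @param library_sizes Named list of per-sample total read counts (named
#'   numeric vectors), keyed by library type incl. `metatranscriptome`.
#' @param coverage_breadth Named list of vOTU x sample matrices in `[0, 1]`,
#'   keyed by DNA library type: the fraction of genome positions covered
#'   at least once.
#' @return A `count_bundle` list.
#' @export
count_bundle <- function(dna_counts, rna_gene_counts, library_sizes,
                         coverage_breadth) {
  assert_that(is.list(dna_counts) && length(dna_counts) >= 1,
              "dna_counts must be a non-empty named list")
  dna_counts <- lapply(dna_counts, as_count_matrix, what = "dna_counts")
  rna_gene_counts <- as_count_matrix(rna_gene_counts, what = "rna_gene_counts")
  for (lib in names(coverage_breadth)) {
    b <- as.matrix(coverage_breadth[[lib]])
    assert_that(all(b >= 0 & b <= 1), "coverage breadth must be in [0, 1]")
    coverage_breadth[[lib]] <- b
  }
  for (lib in names(dna_counts)) {
    m <- dna_counts[[lib]]
    ls <- library_sizes[[lib]]
    assert_that(!is.null(ls), paste("missing library_sizes for", lib))
    assert_that(all(colnames(m) %in% names(ls)),
                paste("library_sizes for", lib, "missing samples"))
    nonzero <- colSums(m) > 0
    assert_that(all(ls[colnames(m)][nonzero] > 0),
                "library size must be > 0 for samples with nonzero counts")
  }
  structure(list(dna_counts = dna_counts,
                 rna_gene_counts = rna_gene_counts,
                 library_sizes = library_sizes,
                 coverage_breadth = coverage_breadth),
            class = "count_bundle")
}

#' @export
print.count_bundle <- function(x, ...) {
  cat("count_bundle:",
      paste(names(x$dna_counts), collapse = "+"), "DNA libraries;",
      nrow(x$rna_gene_counts), "genes x",
      ncol(x$rna_gene_counts), "samples RNA\n")
  invisible(x)
}

#' Read a count bundle from a directory of TSV matrices
#'
#' Expects the file layout written by [write_count_bundle()] /
#' [simulate_bundle()]: `counts_<library>.tsv`, `breadth_<library>.tsv`,
#' `rna_gene_counts.tsv`, `library_sizes.tsv` (columns library, sample_id,
#' reads).
#'
#' @param dir Directory containing the TSV files.
#' @return A `count_bundle`.
#' @export
read_count_bundle <- function(dir) {
  libs <- c("dna_virome", "total_metagenome")
  dna <- list(); breadth <- list()
  for (lib in libs) {
    cf <- file.path(dir, paste0("counts_", lib, ".tsv"))
    bf <- file.path(dir, paste0("breadth_", lib, ".tsv"))
    if (file.exists(cf)) dna[[lib]] <- read_matrix_tsv(cf)
    if (file.exists(bf)) breadth[[lib]] <- read_matrix_tsv(bf)
  }
  rna <- read_matrix_tsv(file.path(dir, "rna_gene_counts.tsv"))
  ls_df <- read.delim(file.path(dir, "library_sizes.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
  library_sizes <- lapply(split(ls_df, ls_df$library), function(d) {
    setNames(d$reads, d$sample_id)
  })
  count_bundle(dna, rna, library_sizes, breadth)
}

#' Write a count bundle as TSV matrices
#'
#' @param bundle A `count_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lib in names(bundle$dna_counts)) {
    write_matrix_tsv(bundle$dna_counts[[lib]],
                     file.path(dir, paste0("counts_", lib, ".tsv")))
  }
  for (lib in names(bundle$coverage_breadth)) {
    write_matrix_tsv(bundle$coverage_breadth[[lib]],
                     file.path(dir, paste0("breadth_", lib, ".tsv")))
  }
  write_matrix_tsv(bundle$rna_gene_counts,
                   file.path(dir, "rna_gene_counts.tsv"))
  ls_df <- do.call(rbind, lapply(names(bundle$library_sizes), function(lib) {
    v <- bundle$library_sizes[[lib]]
    data.frame(library = lib, sample_id = names(v), reads = unname(v),
               stringsAsFactors = FALSE)
  }))
  write_table_tsv(ls_df, file.path(dir, "library_sizes.tsv"))
  invisible(dir)
}
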