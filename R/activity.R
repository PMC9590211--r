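## Metatranscriptome activity: group-level low-count filtering, gene-level
## relative activity (TPM as defined for this pipeline: RPKM-form, columns
## not rescaled), and the >= 1 transcribed gene per 10 kb activity rule.

#' Filter gene-level metatranscriptome counts by group support
#'
#' For each gene and each treatment group (compartment x rotation x
#' growth stage), if the summed count over the group's replicates is below
#' `min_group_reads` (default 4, inclusive bound: a sum of exactly 4
#' passes), the gene's count is set to zero in every replicate of that
#' group; otherwise counts pass unchanged. A gene may pass in one group
#' and be zeroed in another. The filter is idempotent.
#'
#' @param rna_gene_counts gene x sample integer matrix.
#' @param design [sample_design()] covering all count columns.
#' @param min_group_reads Minimum group-summed reads (default 4).
#' @param per_replicate If `TRUE`, apply the threshold per replicate
#'   instead of to the group sum (alternative reading; default `FALSE`).
#' @param log Optional stage log environment.
#' @return Filtered gene x sample matrix.
#' @export
filter_gene_counts <- function(rna_gene_counts, design, min_group_reads = 4,
                               per_replicate = FALSE, log = NULL) {
  m <- as_count_matrix(rna_gene_counts, "rna_gene_counts")
  missing <- setdiff(colnames(m), design$sample_id)
  if (length(missing)) {
    stop2("samples missing from design: ", paste(missing, collapse = ", "))
  }
  groups <- design$group[match(colnames(m), design$sample_id)]
  out <- m
  if (per_replicate) {
    out[out < min_group_reads] <- 0
  } else {
    for (g in unique(groups)) {
      cols <- which(groups == g)
      gsum <- rowSums(m[, cols, drop = FALSE])
      out[gsum < min_group_reads, cols] <- 0
    }
  }
  log_add(log,
          n_nonzero_in = sum(m > 0),
          n_nonzero_out = sum(out > 0))
  out
}

#' Gene-level relative activity (TPM, RPKM-form)
#'
#' `TPM(g, s) = count(g, s) / (l_g / 1e3) / (M_s / 1e6)`. Note this is the
#' stated normalisation by gene length and library depth only — columns
#' are NOT rescaled to sum to 1e6, so column sums generally differ from
#' 1e6 (unlike the conventional transcripts-per-million definition).
#'
#' @param filtered_counts gene x sample matrix (after
#'   [filter_gene_counts()]).
#' @param gene_lengths Named vector of gene lengths (bp).
#' @param library_size Named vector of per-sample metatranscriptome depths.
#' @return Numeric gene x sample matrix.
#' @export
compute_gene_tpm <- function(filtered_counts, gene_lengths, library_size) {
  compute_cpm(filtered_counts, gene_lengths, library_size)
}

#' Classify active vOTUs per sample
#'
#' A vOTU is active in a sample when metatranscriptome reads map to at
#' least 1 gene per 10 kb of its genome: with `k(i, s)` the number of the
#' vOTU's genes with filtered count > 0 in the sample, active iff
#' `k(i, s) * 1e4 >= genome_length_bp(i)` (equivalently `k >= ceil(L/1e4)`).
#' vOTUs with no annotated genes are never active (warned about).
#'
#' @param filtered_counts gene x sample matrix (after
#'   [filter_gene_counts()]).
#' @param catalog [votu_catalog()].
#' @param annotations [gene_annotation()] linking genes to vOTUs.
#' @param log Optional stage log environment.
#' @return List with logical `active` (vOTU x sample) and integer
#'   `active_gene_count` (vOTU x sample, the `k` matrix).
#' @export
call_active_votus <- function(filtered_counts, catalog, annotations,
                              log = NULL) {
  unknown <- setdiff(rownames(filtered_counts), annotations$gene_id)
  if (length(unknown)) {
    stop2("counts for unannotated gene(s): ",
          paste(head(unknown, 5), collapse = ", "))
  }
  votus <- catalog$votu_id
  no_genes <- setdiff(votus, unique(annotations$votu_id))
  if (length(no_genes)) {
    warning(length(no_genes), " vOTU(s) with zero annotated genes are never ",
            "active", call. = FALSE)
  }
  gene_votu <- annotations$votu_id[match(rownames(filtered_counts),
                                         annotations$gene_id)]
  expressed <- filtered_counts > 0
  k <- rowsum(expressed + 0, gene_votu)
  full_k <- matrix(0L, nrow = length(votus), ncol = ncol(filtered_counts),
                   dimnames = list(votus, colnames(filtered_counts)))
  full_k[rownames(k), ] <- k
  L <- genome_lengths(catalog)
  active <- full_k * 1e4 >= L[votus]
  log_add(log, n_active_calls = sum(active))
  list(active = active, active_gene_count = full_k)
}

#' Summed relative activity of gene sets
#'
#' For each gene set, per sample: the summed TPM over the set and its
#' fraction of total summed TPM, plus group means with 95% confidence
#' intervals over replicates.
#'
#' @param gene_tpm gene x sample TPM matrix.
#' @param design [sample_design()] covering the samples.
#' @param gene_sets Named list of gene-id vectors (subsets of the rows).
#' @return List with `per_sample` (set, sample_id, summed_tpm, fraction)
#'   and `group_summary` (set, group, mean fraction, ci_lo, ci_hi).
#' @export
summarize_activity <- function(gene_tpm, design, gene_sets) {
  total <- colSums(gene_tpm)
  per_sample <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    genes <- intersect(gene_sets[[nm]], rownames(gene_tpm))
    if (length(genes) == 0) {
      warning("empty gene set '", nm, "'", call. = FALSE)
      s <- setNames(numeric(ncol(gene_tpm)), colnames(gene_tpm))
    } else {
      s <- colSums(gene_tpm[genes, , drop = FALSE])
    }
    frac <- ifelse(total > 0, s / total, NA_real_)
    data.frame(set = nm, sample_id = names(s), summed_tpm = unname(s),
               fraction = unname(frac), stringsAsFactors = FALSE)
  }))
  grp <- design$group[match(per_sample$sample_id, design$sample_id)]
  per_sample$group <- grp
  group_summary <- do.call(rbind, lapply(
    split(per_sample, list(per_sample$set, per_sample$group), drop = TRUE),
    function(d) {
      x <- d$fraction[!is.na(d$fraction)]
      n <- length(x)
      m <- if (n) mean(x) else NA_real_
      half <- if (n > 1) qt(0.975, n - 1) * sd(x) / sqrt(n) else 0
      data.frame(set = d$set[1], group = d$group[1], mean_fraction = m,
                 ci_lo = m - half, ci_hi = m + half,
                 stringsAsFactors = FALSE)
    }))
  rownames(group_summary) <- NULL
  list(per_sample = per_sample, group_summary = group_summary)
}
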