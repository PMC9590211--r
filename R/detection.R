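## Presence calling from breadth of coverage, CPM normalisation, DNA-library
## aggregation, accumulation curves, and greedy length-sorted dedup
## clustering from a pairwise-identity table.

#' Call vOTU presence from breadth of coverage
#'
#' A vOTU is considered present in a sample when at least 75% of its contig
#' length is covered at >= 1x by reads from that sample's library
#' (inclusive threshold).
#'
#' @param coverage_breadth vOTU x sample matrix in `[0, 1]`, or a named
#'   list of such matrices (one per DNA library type).
#' @param threshold Minimum breadth (default 0.75, inclusive).
#' @param log Optional stage log environment.
#' @return For a single matrix, a logical matrix. For a list, a list with
#'   one logical matrix per library plus `merged` (elementwise OR).
#' @export
call_presence <- function(coverage_breadth, threshold = 0.75, log = NULL) {
  assert_that(is.numeric(threshold) && threshold >= 0 && threshold <= 1,
              "breadth threshold must be in [0, 1]")
  one <- function(b) {
    b <- as.matrix(b)
    assert_that(all(b >= 0 & b <= 1), "breadth values must be in [0, 1]")
    p <- b >= threshold
    empty <- colSums(b) == 0
    if (any(empty)) {
      warning("all-zero breadth column(s): ",
              paste(colnames(b)[empty], collapse = ", "), call. = FALSE)
    }
    p
  }
  if (is.list(coverage_breadth)) {
    pres <- lapply(coverage_breadth, one)
    merged <- Reduce(`|`, pres)
    log_add(log, n_present_merged = sum(merged))
    c(pres, list(merged = merged))
  } else {
    p <- one(coverage_breadth)
    log_add(log, n_present = sum(p))
    p
  }
}

#' Relative abundance as counts per kilobase million (CPM)
#'
#' `CPM(i, s) = count(i, s) / (L_i / 1e3) / (N_s / 1e6)`: read counts
#' normalised by genome length (kb) and library sequencing depth (millions
#' of reads). This is the RPKM-form normalisation; columns are not rescaled.
#'
#' @param counts vOTU x sample integer matrix.
#' @param genome_lengths Named vector of genome lengths (bp) covering all
#'   rows of `counts`.
#' @param library_size Named vector of per-sample total reads covering all
#'   columns of `counts`.
#' @return Numeric matrix of CPM values.
#' @export
compute_cpm <- function(counts, genome_lengths, library_size) {
  counts <- as_count_matrix(counts)
  L <- genome_lengths[rownames(counts)]
  N <- library_size[colnames(counts)]
  assert_that(!anyNA(L), "genome_lengths missing for some vOTUs")
  assert_that(!anyNA(N), "library_size missing for some samples")
  assert_that(all(L > 0), "genome lengths must be > 0")
  zero_bad <- N == 0 & colSums(counts) > 0
  if (any(zero_bad)) {
    stop2("zero library size with nonzero counts: ",
          paste(colnames(counts)[zero_bad], collapse = ", "))
  }
  N[N == 0] <- 1  # all-zero column: CPM stays 0
  sweep(counts / (L / 1e3), 2, N / 1e6, "/")
}

#' Aggregate DNA virome and total metagenome CPM values
#'
#' Per vOTU per sample, the median of the available library CPM values is
#' taken (the median of two values is their mean; a value from a single
#' available library is used as is). Cells absent from both libraries
#' become 0 (tallied per vOTU in the log). If `presence` is given, the
#' merged presence mask is applied after aggregation so that abundance
#' support never exceeds presence support.
#'
#' @param cpm_virome,cpm_metagenome vOTU x sample CPM matrices (either may
#'   be `NULL`); non-`NULL` matrices must share dimnames.
#' @param presence Optional logical matrix (merged presence) used to mask.
#' @param log Optional stage log environment.
#' @return Numeric vOTU x sample matrix of aggregated CPM.
#' @export
aggregate_dna_libraries <- function(cpm_virome, cpm_metagenome,
                                    presence = NULL, log = NULL) {
  mats <- Filter(Negate(is.null), list(cpm_virome, cpm_metagenome))
  assert_that(length(mats) >= 1, "at least one CPM matrix is required")
  if (length(mats) == 2) check_aligned(mats[[1]], mats[[2]], "CPM matrices")
  if (length(mats) == 1) {
    agg <- mats[[1]]
  } else {
    agg <- (mats[[1]] + mats[[2]]) / 2  # median of two = mean
  }
  if (!is.null(log)) {
    log_add(log, n_votus = nrow(agg), n_samples = ncol(agg))
  }
  if (!is.null(presence)) {
    check_aligned(agg, presence, "CPM and presence")
    agg[!presence] <- 0
  }
  agg
}

#' vOTU accumulation curve
#'
#' Mean cumulative richness (number of distinct vOTUs detected) over the
#' first `k` samples, `k = 1..S`, averaged over sample orderings. The
#' default `"exact"` method computes the exact permutation average in
#' closed form: `E|union k| = sum_v [1 - choose(S - z_v, k)/choose(S, k)]`
#' where `z_v` is the number of samples detecting vOTU `v`. Method
#' `"permute"` Monte-Carlo averages over `n_permutations` random orderings.
#'
#' @param presence Logical vOTU x sample matrix.
#' @param n_permutations Number of random orderings for `method =
#'   "permute"`.
#' @param seed RNG seed for `method = "permute"`.
#' @param method `"exact"` (default) or `"permute"`.
#' @return data.frame with columns `k` and `richness` (monotone
#'   non-decreasing in `k`).
#' @export
accumulation_curve <- function(presence, n_permutations = 100, seed = 1,
                               method = c("exact", "permute")) {
  method <- match.arg(method)
  presence <- as.matrix(presence) > 0
  S <- ncol(presence)
  assert_that(S >= 1, "at least one sample is required")
  z <- rowSums(presence)
  z <- z[z > 0]
  if (method == "exact") {
    rich <- vapply(seq_len(S), function(k) {
      # P(vOTU v absent from a k-subset) = choose(S - z_v, k) / choose(S, k)
      sum(1 - exp(lchoose(S - z, k) - lchoose(S, k)))
    }, numeric(1))
  } else {
    rich <- with_seed(seed, {
      acc <- numeric(S)
      for (p in seq_len(n_permutations)) {
        ord <- sample.int(S)
        seen <- rep(FALSE, nrow(presence))
        for (k in seq_len(S)) {
          seen <- seen | presence[, ord[k]]
          acc[k] <- acc[k] + sum(seen)
        }
      }
      acc / n_permutations
    })
  }
  data.frame(k = seq_len(S), richness = rich)
}

#' Greedy length-sorted dedup clustering from pairwise identities
#'
#' CD-HIT-like semantics: contigs are sorted by descending length (ties
#' broken lexicographically by id) and processed in order; each contig
#' joins the first existing cluster whose representative it matches at
#' `identity >= id_threshold` and `aligned fraction >= cov_threshold`
#' (both inclusive), otherwise it founds a new cluster. The representative
#' is the longest member (the founder, by construction). Missing pairs are
#' treated as below threshold; self-pairs are ignored. This is greedy
#' clustering against representatives, not single linkage.
#'
#' @param pairwise_table data.frame with columns `a`, `b`, `identity`,
#'   `aligned_fraction` (of the shorter contig).
#' @param lengths Named vector of contig lengths covering all ids.
#' @param id_threshold Minimum identity (default 0.95).
#' @param cov_threshold Minimum aligned fraction (default 0.95).
#' @return data.frame with columns `id`, `representative`.
#' @export
greedy_dedup <- function(pairwise_table, lengths, id_threshold = 0.95,
                         cov_threshold = 0.95) {
  ids <- names(lengths)
  assert_that(!is.null(ids), "lengths must be a named vector")
  pt <- pairwise_table
  pt <- pt[pt$a != pt$b, , drop = FALSE]
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  lut_id <- setNames(pt$identity, key(pt$a, pt$b))
  lut_cov <- setNames(pt$aligned_fraction, key(pt$a, pt$b))
  ord <- ids[order(-lengths[ids], ids)]
  reps <- character(0)
  assign <- setNames(character(length(ord)), ord)
  for (id in ord) {
    placed <- FALSE
    for (r in reps) {
      k <- key(id, r)
      idy <- lut_id[[k]] %||% 0
      cov <- lut_cov[[k]] %||% 0
      if (idy >= id_threshold && cov >= cov_threshold) {
        assign[[id]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[[id]] <- id
    }
  }
  data.frame(id = names(assign), representative = unname(assign),
             stringsAsFactors = FALSE)
}
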